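#' Build bias-attenuating reference genomes
#'
#' Aligners penalise mismatches against the reference, so reads carrying the
#' non-reference allele at a heterozygous SNP are systematically lost and
#' allelic ratios are inflated toward the reference allele. Two reference
#' constructions attenuate this bias:
#'
#' * `mask_reference()` replaces the reference base at every catalogued SNP
#'   with the IUPAC ambiguity character covering both alleles, so neither
#'   allele is penalised (a "masked" genome, one genome-wide alignment).
#' * `switch_alleles()` replaces the reference base with the variant base at
#'   targeted SNPs; counting the "reference" allele in both the standard and
#'   the switched alignment gives each allele a turn at being favoured.
#'
#' Both functions validate the catalogued reference allele against the genome
#' base at each position. Disagreements (common in public catalogs because of
#' strand or assembly-build discrepancies) are skipped with a warning and
#' reported in the audit table unless `strict = TRUE`, in which case they are
#' an error. Sites beyond the end of their chromosome are always an error.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector) of
#'   chromosome sequences over A/C/G/T/N.
#' @param sites A data frame of biallelic SNVs with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, e.g. from [read_variant_sites()].
#' @param strict If `TRUE`, a catalogued ref allele that disagrees with the
#'   genome base aborts instead of being skipped.
#' @return A `DNAStringSet` with `metadata()` fields `provenance`
#'   (`"iupac_masked"` or `"allele_switched"`) and `audit` (a tibble of
#'   skipped sites with a `reason` column; zero rows when nothing was
#'   skipped). Retrieve the audit with [masking_audit()].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
#' sites <- tibble::tibble(chrom = "chr1", pos = 4L, ref = "T", alt = "C")
#' as.character(mask_reference(g, sites))   # "ACGYACGTAC"
#' as.character(switch_alleles(g, sites))   # "ACGCACGTAC"
#' @seealso [iupac_code()], [read_variant_sites()]
#' @export
mask_reference <- function(genome, sites, strict = FALSE) {
  edit_reference(genome, sites, mode = "mask", strict = strict)
}

#' @rdname mask_reference
#' @export
switch_alleles <- function(genome, sites, strict = FALSE) {
  edit_reference(genome, sites, mode = "switch", strict = strict)
}

edit_reference <- function(genome, sites, mode, strict = FALSE) {
  genome <- as_genome(genome)
  sites <- validate_sites(sites)

  missing_chrom <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(sprintf(
      "catalog chromosome(s) absent from genome: %s",
      paste(missing_chrom, collapse = ", ")
    ))
  }
  beyond <- sites$pos < 1L | sites$pos > Biostrings::width(genome)[
    match(sites$chrom, names(genome))
  ]
  if (any(beyond)) {
    abort(sprintf(
      "%d site(s) lie outside their chromosome (first: %s:%d)",
      sum(beyond), sites$chrom[which(beyond)[1]], sites$pos[which(beyond)[1]]
    ))
  }

  genome_base <- site_bases(genome, sites)
  mismatch <- genome_base != sites$ref
  if (any(mismatch) && strict) {
    abort(sprintf(
      "catalogued ref disagrees with genome at %d site(s) (first: %s:%d genome=%s catalog=%s)",
      sum(mismatch), sites$chrom[which(mismatch)[1]],
      sites$pos[which(mismatch)[1]],
      genome_base[which(mismatch)[1]], sites$ref[which(mismatch)[1]]
    ))
  }
  audit <- sites[mismatch, , drop = FALSE]
  if (nrow(audit) > 0) {
    audit$genome_base <- genome_base[mismatch]
    audit$reason <- "ref_mismatch"
    warn(sprintf(
      "skipped %d site(s) whose catalogued ref allele disagrees with the genome",
      nrow(audit)
    ))
  } else {
    audit$genome_base <- character(0)
    audit$reason <- character(0)
  }

  keep <- sites[!mismatch, , drop = FALSE]
  new_letter <- switch(mode,
    mask = iupac_code(keep$ref, keep$alt),
    switch = keep$alt
  )
  out <- genome
  for (chrom in unique(keep$chrom)) {
    i <- keep$chrom == chrom
    out[[chrom]] <- Biostrings::replaceLetterAt(
      out[[chrom]], at = keep$pos[i], letter = paste(new_letter[i], collapse = "")
    )
  }
  S4Vectors::metadata(out) <- list(
    provenance = if (mode == "mask") "iupac_masked" else "allele_switched",
    audit = as_tibble(audit),
    n_edited = nrow(keep)
  )
  out
}

#' Retrieve the audit table of a modified reference genome
#'
#' @param genome A genome returned by [mask_reference()] or
#'   [switch_alleles()].
#' @return A tibble of skipped catalog sites (zero rows if none).
#' @export
masking_audit <- function(genome) {
  S4Vectors::metadata(genome)$audit %||% tibble()
}

#' Resolve masked positions back to the catalogued reference allele
#'
#' Undoes [mask_reference()]: every catalogued position is set back to its
#' `ref` base. Masking followed by resolution reproduces the standard genome
#' exactly, which is the integrity check used in the test suite.
#'
#' @inheritParams mask_reference
#' @return A `DNAStringSet` with provenance `"standard"`.
#' @export
resolve_to_reference <- function(genome, sites) {
  genome <- as_genome(genome)
  sites <- validate_sites(sites)
  out <- genome
  for (chrom in unique(sites$chrom)) {
    i <- sites$chrom == chrom
    out[[chrom]] <- Biostrings::replaceLetterAt(
      out[[chrom]], at = sites$pos[i], letter = paste(sites$ref[i], collapse = "")
    )
  }
  S4Vectors::metadata(out) <- list(provenance = "standard")
  out
}

as_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      abort("a character-vector genome needs chromosome names")
    }
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet")) {
    abort("`genome` must be a DNAStringSet or a named character vector")
  }
  genome
}

site_bases <- function(genome, sites) {
  out <- character(nrow(sites))
  for (chrom in unique(sites$chrom)) {
    i <- sites$chrom == chrom
    out[i] <- as.character(Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(sites$pos[i], width = 1L)
    ))
  }
  out
}

validate_sites <- function(sites) {
  sites <- as_tibble(sites)
  needed <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(needed, names(sites))
  if (length(missing) > 0) {
    abort(sprintf("`sites` lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- toupper(as.character(sites$ref))
  sites$alt <- toupper(as.character(sites$alt))
  bad <- !(sites$ref %in% DNA_BASES_) | !(sites$alt %in% DNA_BASES_) |
    sites$ref == sites$alt
  if (any(bad)) {
    abort(sprintf(
      "%d catalog record(s) are not biallelic SNVs over ACGT; filter with read_variant_sites() first",
      sum(bad)
    ))
  }
  sites
}

#' Write a genome to FASTA
#'
#' Sequences are written uppercase at a fixed line width of 60 characters.
#'
#' @param genome A `DNAStringSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path, width = 60L)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file path.
#' @return A `DNAStringSet` named by the first word of each header.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
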