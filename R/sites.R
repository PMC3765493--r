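#' Read a SNP catalog from VCF or TSV
#'
#' Reads a site catalog and keeps only biallelic single-nucleotide variants
#' over A/C/G/T; indels and multiallelic records are dropped with a message
#' reporting how many were skipped. VCF coordinates are 1-based, as is the
#' internal representation.
#'
#' Accepted TSV layouts (tab-separated, `#` comments ignored):
#' * columns `chrom`, `pos`, `ref`, `alt` (header required), optionally
#'   `site_id` and `gene`;
#' * three columns `chrom`, `pos`, `ref>alt` with no header (dbSNP-style
#'   dumps).
#'
#' @param path Path to a `.vcf` (uncompressed or gzipped) or `.tsv` file.
#' @return A tibble with columns `chrom`, `pos` (integer, 1-based), `ref`,
#'   `alt`, `site_id`, plus `gene`/`region_class` set to `NA` until
#'   [annotate_sites()] fills them. The number of skipped non-SNV records is
#'   in `attr(x, "n_skipped")`.
#' @export
read_variant_sites <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    raw <- tibble(
      chrom = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = toupper(fix$REF),
      alt = toupper(fix$ALT),
      site_id = ifelse(is.na(fix$ID) | fix$ID == ".", NA_character_, fix$ID)
    )
  } else {
    first <- readLines(path, n = 1L)
    if (grepl("chrom", first, ignore.case = TRUE)) {
      raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
      names(raw) <- tolower(names(raw))
      if (!"site_id" %in% names(raw)) raw$site_id <- NA_character_
      raw <- raw[, intersect(c("chrom", "pos", "ref", "alt", "site_id", "gene"),
                             names(raw))]
    } else {
      raw <- readr::read_tsv(
        path, col_names = c("chrom", "pos", "allele_pair"),
        comment = "#", show_col_types = FALSE
      )
      parts <- strsplit(raw$allele_pair, ">", fixed = TRUE)
      raw$ref <- toupper(vapply(parts, `[`, "", 1L))
      raw$alt <- toupper(vapply(parts, `[`, "", 2L))
      raw$allele_pair <- NULL
      raw$site_id <- NA_character_
    }
    raw$pos <- as.integer(raw$pos)
    raw$ref <- toupper(raw$ref)
    raw$alt <- toupper(raw$alt)
  }

  is_snv <- raw$ref %in% DNA_BASES_ & raw$alt %in% DNA_BASES_ &
    raw$ref != raw$alt
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    inform(sprintf(
      "dropped %d non-biallelic-SNV record(s) (indels or multiallelic)",
      n_skipped
    ))
  }
  out <- as_tibble(raw[is_snv, , drop = FALSE])
  no_id <- is.na(out$site_id)
  out$site_id[no_id] <- paste0(out$chrom[no_id], ":", out$pos[no_id])
  if (!"gene" %in% names(out)) out$gene <- NA_character_
  out$region_class <- NA_character_
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read gene intervals from BED or GFF/GTF
#'
#' Intervals are imported with `rtracklayer` (BED 0-based half-open
#' coordinates are converted to 1-based closed on read). For GFF/GTF only
#' `exon` and UTR features are kept and mapped to region classes `exonic`
#' and `UTR`; for BED the `name` column supplies the gene symbol, optionally
#' suffixed `":<region_class>"` (default `exonic`).
#'
#' @param path Path to a `.bed`, `.gff`/`.gff3` or `.gtf` file.
#' @return A tibble with columns `chrom`, `start`, `end` (1-based closed),
#'   `gene`, `region_class`.
#' @export
read_gene_intervals <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    nm <- as.character(df$name %||% rep(NA_character_, nrow(df)))
    parts <- strsplit(nm, ":", fixed = TRUE)
    gene <- vapply(parts, `[`, "", 1L)
    klass <- vapply(parts, function(p) if (length(p) > 1) p[2] else "exonic", "")
    tibble(
      chrom = as.character(df$seqnames), start = df$start, end = df$end,
      gene = gene, region_class = klass
    )
  } else {
    type <- tolower(as.character(df$type))
    keep <- type %in% c("exon", "five_prime_utr", "three_prime_utr", "utr")
    df <- df[keep, , drop = FALSE]
    gene <- df$gene_id %||% df$gene %||% df$Name %||% df$ID
    tibble(
      chrom = as.character(df$seqnames), start = df$start, end = df$end,
      gene = as.character(gene),
      region_class = ifelse(tolower(as.character(df$type)) == "exon",
                            "exonic", "UTR")
    )
  }
}

sites_as_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L)
  )
}
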