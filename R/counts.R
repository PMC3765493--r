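#' Tally allelic read counts at heterozygous SNPs
#'
#' Computes, for each catalogued site, the number of aligned reads carrying
#' the reference allele (`ref_count`), the variant allele (`var_count`) or
#' any other base (`other_count`). Reads with a deletion or clipped bases at
#' the site position contribute to none of the three. The pileup itself is
#' delegated to [Rsamtools::pileup()]; plain-text SAM input is converted to
#' a temporary sorted BAM first.
#'
#' Sites on chromosomes absent from the alignment header are returned with
#' zero counts and a warning; sites covered by no read are returned with
#' zeros (not an error).
#'
#' @param alignments Path to a SAM or BAM file (coordinate-sorted or not;
#'   sorting is handled internally).
#' @param sites A site catalog tibble (see [read_variant_sites()]).
#' @param sample_id Sample label attached to every returned row.
#' @param min_mapq Minimum mapping quality for a read to count (default 1).
#' @param min_base_quality Minimum base quality at the site (default 13).
#' @return A tibble: one row per catalog site with `sample_id`, `ref_count`,
#'   `var_count`, `other_count` appended to the site columns.
#' @examples
#' \dontrun{
#' counts <- count_alleles("aln.sam", sites, sample_id = "S1")
#' }
#' @export
count_alleles <- function(alignments, sites, sample_id,
                          min_mapq = 1L, min_base_quality = 13L) {
  sites <- validate_sites(sites)
  bam <- as_sorted_bam(alignments)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  known <- sites$chrom %in% names(hdr)
  if (!all(known)) {
    warn(sprintf(
      "%d site(s) on chromosome(s) absent from the alignment header; reported with zero counts",
      sum(!known)
    ))
  }

  zero <- tibble(site_row = seq_len(nrow(sites)),
                 A = 0, C = 0, G = 0, T = 0)
  if (any(known)) {
    which_gr <- sites_as_granges(sites[known, , drop = FALSE])
    p <- Rsamtools::pileup(
      bam,
      scanBamParam = Rsamtools::ScanBamParam(which = which_gr),
      pileupParam = Rsamtools::PileupParam(
        max_depth = 10000L,
        min_base_quality = as.integer(min_base_quality),
        min_mapq = as.integer(min_mapq),
        min_nucleotide_depth = 1L,
        distinguish_strands = FALSE,
        distinguish_nucleotides = TRUE,
        ignore_query_Ns = TRUE,
        include_deletions = FALSE,
        include_insertions = FALSE
      )
    )
    if (nrow(p) > 0) {
      p <- p[p$nucleotide %in% DNA_BASES_, , drop = FALSE]
      key <- paste0(as.character(p$seqnames), ":", p$pos)
      site_key <- paste0(sites$chrom, ":", sites$pos)
      idx <- match(key, site_key)
      ok <- !is.na(idx)
      for (b in DNA_BASES_) {
        sel <- ok & as.character(p$nucleotide) == b
        tallied <- tapply(p$count[sel], idx[sel], sum)
        if (length(tallied) > 0) {
          zero[[b]][as.integer(names(tallied))] <-
            zero[[b]][as.integer(names(tallied))] + as.numeric(tallied)
        }
      }
    }
  }

  base_mat <- as.matrix(zero[, DNA_BASES_])
  ref_count <- base_mat[cbind(seq_len(nrow(sites)), match(sites$ref, DNA_BASES_))]
  var_count <- base_mat[cbind(seq_len(nrow(sites)), match(sites$alt, DNA_BASES_))]
  other_count <- rowSums(base_mat) - ref_count - var_count
  out <- sites
  out$sample_id <- sample_id
  out$ref_count <- as.integer(ref_count)
  out$var_count <- as.integer(var_count)
  out$other_count <- as.integer(other_count)
  out
}

as_sorted_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- path
    if (!file.exists(paste0(bam, ".bai"))) {
      sorted <- tempfile(fileext = "")
      bam <- Rsamtools::sortBam(bam, sorted)
      Rsamtools::indexBam(bam)
    }
    return(bam)
  }
  stem <- tempfile()
  bam <- Rsamtools::asBam(path, stem, overwrite = TRUE)  # sorts and indexes
  bam
}

#' Filter allelic counts for informative heterozygous expression
#'
#' Retains sites where both alleles are observed with at least
#' `min_per_allele` reads (default 3, i.e. 6 informative reads total) and the
#' lower-expressed allele makes up at least `min_minor_fraction` of the
#' informative reads (default 5%). `other_count` is ignored: informative
#' depth is `ref_count + var_count`. The filter is idempotent and preserves
#' row order.
#'
#' @param counts A tibble with `ref_count` and `var_count` columns.
#' @param min_per_allele Minimum reads per allele.
#' @param min_minor_fraction Minimum minor-allele fraction of informative
#'   reads.
#' @return The retained rows of `counts`.
#' @examples
#' x <- tibble::tibble(ref_count = c(3, 10, 100), var_count = c(3, 0, 4))
#' filter_allelic_counts(x)  # keeps only the first row
#' @export
filter_allelic_counts <- function(counts, min_per_allele = 3,
                                  min_minor_fraction = 0.05) {
  counts <- as_tibble(counts)
  depth <- counts$ref_count + counts$var_count
  minor <- pmin(counts$ref_count, counts$var_count)
  keep <- counts$ref_count >= min_per_allele &
    counts$var_count >= min_per_allele &
    depth > 0 & minor / depth >= min_minor_fraction
  counts[keep, , drop = FALSE]
}

#' Assign catalog sites to genes and region classes
#'
#' Overlaps each site with gene intervals. A site inside an interval inherits
#' that interval's `gene` and `region_class`; a site overlapping intervals of
#' several genes is duplicated, one annotated copy per gene (with a warning
#' and `multi_gene = TRUE`), so gene-level AEI stays computable for each. A
#' site overlapping no interval is classed `intergenic`. Downstream ratio
#' analysis uses only exonic and UTR sites ([exonic_sites()]).
#'
#' @param sites Site catalog tibble.
#' @param gene_intervals Tibble from [read_gene_intervals()] (columns
#'   `chrom`, `start`, `end`, `gene`, `region_class`).
#' @return `sites` with `gene`, `region_class` and `multi_gene` filled;
#'   possibly more rows than the input if sites hit several genes.
#' @export
annotate_sites <- function(sites, gene_intervals) {
  sites <- as_tibble(sites)
  gi <- as_tibble(gene_intervals)
  q <- sites_as_granges(sites)
  s <- GenomicRanges::GRanges(gi$chrom, IRanges::IRanges(gi$start, gi$end))
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  # distinct (site, gene) pairs; a gene with several overlapping exons
  # still yields one annotated copy
  pair <- tibble(site_row = qh, gene = gi$gene[sh],
                 region_class = gi$region_class[sh])
  pair <- dplyr::distinct(pair, .data$site_row, .data$gene, .keep_all = TRUE)

  n_genes <- table(pair$site_row)
  multi <- as.integer(names(n_genes)[n_genes > 1])
  if (length(multi) > 0) {
    warn(sprintf(
      "%d site(s) overlap intervals of more than one gene; emitting one annotated copy per gene",
      length(multi)
    ))
  }

  hit_rows <- sites[pair$site_row, , drop = FALSE]
  hit_rows$gene <- pair$gene
  hit_rows$region_class <- pair$region_class
  hit_rows$multi_gene <- pair$site_row %in% multi

  miss <- setdiff(seq_len(nrow(sites)), unique(qh))
  miss_rows <- sites[miss, , drop = FALSE]
  if (nrow(miss_rows) > 0) {
    miss_rows$gene <- NA_character_
    miss_rows$region_class <- "intergenic"
    miss_rows$multi_gene <- FALSE
  }
  out <- bind_rows(hit_rows, miss_rows)
  arrange(out, .data$chrom, .data$pos, .data$gene)
}

#' Keep only exonic and UTR sites
#'
#' @param sites Annotated site or count tibble with a `region_class` column.
#' @return The rows whose `region_class` is `exonic`, `ncRNA_exonic` or
#'   `UTR`.
#' @export
exonic_sites <- function(sites) {
  filter(as_tibble(sites),
         .data$region_class %in% c("exonic", "ncRNA_exonic", "UTR"))
}

#' Merge nearby SNPs into single observations
#'
#' SNPs within a short genomic window likely reside on the same sequenced
#' fragments and are not independent observations, so their folded ratios
#' are averaged into one. Clustering is greedy left-to-right within each
#' gene x sample: walking sites in position order, a new cluster starts
#' whenever a site lies more than `window_bp` from the *first* site of the
#' current cluster. Each cluster contributes one row whose `folded_ratio` is
#' the arithmetic mean of its members.
#'
#' @param observations Tibble with columns `gene`, `sample_id`, `chrom`,
#'   `pos` and `folded_ratio` (see [allelic_ratio()]).
#' @param window_bp Window width in basepairs (default 100).
#' @return One row per cluster with `pos` (first member), `n_sites`,
#'   `site_ids` (comma-separated when present) and the averaged
#'   `folded_ratio`.
#' @examples
#' obs <- tibble::tibble(
#'   gene = "G1", sample_id = "S1", chrom = "chr1",
#'   pos = c(10, 90, 180), folded_ratio = c(2, 3, 4)
#' )
#' merge_snp_windows(obs)  # clusters {10, 90} and {180}
#' @export
merge_snp_windows <- function(observations, window_bp = 100) {
  obs <- as_tibble(observations)
  if (!"site_id" %in% names(obs)) obs$site_id <- NA_character_
  obs %>%
    group_by(.data$gene, .data$sample_id, .data$chrom) %>%
    arrange(.data$pos, .by_group = TRUE) %>%
    mutate(cluster = anchor_clusters(.data$pos, window_bp)) %>%
    group_by(.data$gene, .data$sample_id, .data$chrom, .data$cluster) %>%
    summarise(
      pos = .data$pos[1],
      n_sites = dplyr::n(),
      site_ids = paste(.data$site_id, collapse = ","),
      folded_ratio = mean(.data$folded_ratio),
      .groups = "drop"
    ) %>%
    select(-"cluster") %>%
    arrange(.data$gene, .data$sample_id, .data$chrom, .data$pos)
}

# Greedy anchored clustering: positions must be sorted ascending.
anchor_clusters <- function(pos, window_bp) {
  cl <- integer(length(pos))
  if (length(pos) == 0) return(cl)
  current <- 1L
  anchor <- pos[1]
  cl[1] <- current
  for (i in seq_along(pos)[-1]) {
    if (pos[i] - anchor > window_bp) {
      current <- current + 1L
      anchor <- pos[i]
    }
    cl[i] <- current
  }
  cl
}
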