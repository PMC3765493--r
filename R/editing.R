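#' Fraction of reads carrying the edited base
#'
#' @param edited_count,total_count Non-negative integers (vectorized);
#'   `edited_count <= total_count`. A site with zero total depth in a sample
#'   is uncovered there: the fraction is `NA` and the sample is excluded
#'   from per-site means.
#' @return `edited_count / total_count` in \[0, 1\], `NA` where
#'   `total_count` is 0.
#' @examples
#' editing_fraction(c(50, 30, 0), c(100, 30, 25))
#' @export
editing_fraction <- function(edited_count, total_count) {
  if (any(edited_count < 0 | total_count < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  if (any(edited_count > total_count, na.rm = TRUE)) {
    abort("edited_count exceeds total_count")
  }
  ifelse(total_count == 0, NA_real_, edited_count / total_count)
}

#' Summarise editing counts per site and condition
#'
#' Builds the per-site summary used by the retention filters: for each site
#' within each condition (e.g. "regions" for brain regions of one donor,
#' "dlpfc" for one region across donors), the number of samples with any
#' edited read, the mean read depth, the mean editing fraction across
#' covered samples (as a percentage) and its standard error.
#'
#' @param counts Tibble with columns `site_id`, `condition`, `sample_id`,
#'   `edited_count`, `total_count`, and optionally site annotation columns
#'   (`chrom`, `pos`, `gene`, `region_class`, `homology_flag`) which are
#'   carried through.
#' @return A tibble with one row per site x condition: `n_supporting`,
#'   `n_covered`, `avg_depth`, `mean_fraction` (%), `sem_fraction` (%), and
#'   a list-column `fractions` of per-sample fractions (covered samples
#'   only) for downstream confidence-interval checks.
#' @export
summarize_editing_sites <- function(counts) {
  counts <- as_tibble(counts)
  needed <- c("site_id", "condition", "sample_id", "edited_count", "total_count")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  carry <- intersect(c("chrom", "pos", "gene", "region_class", "homology_flag"),
                     names(counts))
  counts$fraction <- editing_fraction(counts$edited_count, counts$total_count)
  counts %>%
    group_by(.data$site_id, .data$condition) %>%
    summarise(
      across(dplyr::all_of(carry), dplyr::first),
      n_supporting = sum(.data$edited_count > 0 & .data$total_count > 0),
      n_covered = sum(.data$total_count > 0),
      avg_depth = mean(.data$total_count),
      mean_fraction = 100 * mean(.data$fraction, na.rm = TRUE),
      sem_fraction = 100 * sd(.data$fraction, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$fraction))),
      fractions = list(.data$fraction[!is.na(.data$fraction)]),
      .groups = "drop"
    )
}

#' Retain editing sites with reproducible support and depth
#'
#' A catalogued editing site is kept only if, in *every* condition, (a) at
#' least `min_support[condition]` samples show at least one edited read and
#' (b) the average read depth is strictly greater than `min_avg_depth`.
#' Sites with a truthy `homology_flag` column (mapping ambiguity due to
#' pseudogenes, supplied as input, not computed) are excluded as well.
#' Excluded rows are returned with `excluded_reason` set
#' (`low_support`, `low_depth`, `homology_flag`); retained rows carry
#' `"none"`. The filter is monotone: raising either threshold never adds a
#' site.
#'
#' @param summaries Output of [summarize_editing_sites()].
#' @param min_support Named integer vector of per-condition support minima,
#'   e.g. `c(regions = 5, dlpfc = 8)` (a single unnamed value applies to
#'   all conditions).
#' @param min_avg_depth Depth that the per-condition average must exceed
#'   (strict `>`, default 10).
#' @return `summaries` with an `excluded_reason` column; retained sites are
#'   `filter(x, excluded_reason == "none")`.
#' @export
filter_editing_sites <- function(summaries,
                                 min_support = c(regions = 5, dlpfc = 8),
                                 min_avg_depth = 10) {
  s <- as_tibble(summaries)
  conditions <- unique(s$condition)
  if (is.null(names(min_support)) && length(min_support) == 1) {
    min_support <- setNames(rep(min_support, length(conditions)), conditions)
  }
  missing_cond <- setdiff(conditions, names(min_support))
  if (length(missing_cond) > 0) {
    abort(sprintf("no min_support given for condition(s): %s",
                  paste(missing_cond, collapse = ", ")))
  }
  per_row_support_ok <- s$n_supporting >= min_support[s$condition]
  per_row_depth_ok <- s$avg_depth > min_avg_depth

  by_site <- tibble(site_id = s$site_id,
                    support_ok = per_row_support_ok,
                    depth_ok = per_row_depth_ok) %>%
    group_by(.data$site_id) %>%
    summarise(support_ok = all(.data$support_ok),
              depth_ok = all(.data$depth_ok))
  s <- left_join(s, by_site, by = "site_id")

  homology <- if ("homology_flag" %in% names(s)) {
    !is.na(s$homology_flag) & as.logical(s$homology_flag)
  } else {
    rep(FALSE, nrow(s))
  }
  s$excluded_reason <- dplyr::case_when(
    homology ~ "homology_flag",
    !s$support_ok ~ "low_support",
    !s$depth_ok ~ "low_depth",
    TRUE ~ "none"
  )
  select(s, -"support_ok", -"depth_ok")
}

#' Flag sites whose variant fraction is consistent with a reference error
#'
#' If every sample expresses essentially only the "variant" allele at a
#' catalogued site, the reference base is likely wrong for the population
#' rather than the site being edited. The rule: build a `confidence`-level
#' t-interval for the mean per-sample variant fraction; if its upper bound
#' reaches 1.0 (complete mapping to the variant allele), exclude the site.
#' With a single covered sample the interval is not evaluable and the site
#' is retained with a warning.
#'
#' @param fractions Numeric vector of per-sample variant fractions in
#'   \[0, 1\] (one site; `NA`s dropped). Order-invariant.
#' @param confidence Confidence level (default 0.95).
#' @return `TRUE` (exclude) or `FALSE` (retain), with attributes
#'   `ci_upper` and `mean`.
#' @examples
#' exclude_reference_errors(c(0.45, 0.55, 0.50, 0.48))  # FALSE
#' exclude_reference_errors(c(1, 1, 1, 1))              # TRUE
#' @export
exclude_reference_errors <- function(fractions, confidence = 0.95) {
  x <- fractions[!is.na(fractions)]
  if (length(x) < 2) {
    warn("fewer than 2 covered samples; reference-error check not evaluable, site retained")
    return(structure(FALSE, ci_upper = NA_real_, mean = mean(x)))
  }
  m <- mean(x)
  sem <- sd(x) / sqrt(length(x))
  upper <- m + qt(1 - (1 - confidence) / 2, df = length(x) - 1) * sem
  structure(upper >= 1, ci_upper = upper, mean = m)
}

#' Correlation of editing extent between two conditions
#'
#' Pearson correlation (and its square) of per-site mean editing fractions
#' measured in two conditions over the same sites, e.g. brain regions of
#' one individual versus one region across individuals.
#'
#' @param a,b Numeric vectors of per-site mean editing levels, same site
#'   order, length >= 3.
#' @return A tibble with `r`, `r_squared` and `n`.
#' @export
editing_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) abort("need at least 3 paired sites")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("zero variance in one condition; correlation undefined")
  }
  r <- cor(a, b)
  tibble(r = r, r_squared = r^2, n = length(a))
}

#' Compare editing variability between two conditions
#'
#' Tests whether per-site editing variability (summarised as the SEM of the
#' editing fraction across samples) differs between two conditions over the
#' same retained sites. Default is a paired two-sided Wilcoxon signed-rank
#' test, robust at the small site counts these surveys retain; identical
#' inputs return p = 1 directly (all paired differences are zero, leaving
#' the signed-rank statistic undefined). An F-type variance-ratio
#' alternative on the pooled SEMs is available via `method = "f"`.
#'
#' @param sem_a,sem_b Per-site SEMs for conditions A and B, paired over the
#'   same sites.
#' @param method `"wilcoxon"` (paired signed-rank, default) or `"f"`
#'   (variance ratio, unpaired).
#' @return A tibble with `statistic`, `p_value`, `method` and `n`, plus the
#'   per-site SEM table as attribute `sems`.
#' @export
compare_editing_variability <- function(sem_a, sem_b,
                                        method = c("wilcoxon", "f")) {
  method <- match.arg(method)
  stopifnot(length(sem_a) == length(sem_b))
  sems <- tibble(sem_a = sem_a, sem_b = sem_b, diff = sem_a - sem_b)
  if (method == "wilcoxon") {
    if (all(sems$diff == 0)) {
      out <- tibble(statistic = 0, p_value = 1,
                    method = "wilcoxon_signed_rank", n = nrow(sems))
    } else {
      wt <- suppressWarnings(
        wilcox.test(sem_a, sem_b, paired = TRUE, exact = TRUE)
      )
      out <- tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                    method = "wilcoxon_signed_rank", n = nrow(sems))
    }
  } else {
    ft <- var.test(sem_a, sem_b)
    out <- tibble(statistic = unname(ft$statistic), p_value = ft$p.value,
                  method = "variance_ratio_F", n = nrow(sems))
  }
  attr(out, "sems") <- sems
  out
}

#' A-to-I editing survey of human brain: 12 retained sites
#'
#' Per-site summary of A-to-I RNA editing at the 12 catalogued sites (in 8
#' genes) retained by the survey filters in two conditions: across 10 brain
#' regions of a single donor (`regions`) and across 13 dorsolateral
#' prefrontal cortex samples from different donors (`dlpfc`). For each
#' condition: the number of samples displaying editing, the average read
#' depth, the mean editing percentage and its standard error. These are
#' published summary values, included as a reference input for
#' cross-condition analyses.
#'
#' @return A tibble with one row per site: `gene`, `position`,
#'   `position_in_gene`, and per condition `n_<cond>`, `depth_<cond>`,
#'   `pct_<cond>`, `sem_<cond>`.
#' @examples
#' panel <- brain_editing_sites()
#' editing_correlation(panel$pct_regions, panel$pct_dlpfc)
#' @export
brain_editing_sites <- function() {
  tibble::tribble(
    ~gene, ~position, ~position_in_gene,
    ~n_regions, ~depth_regions, ~pct_regions, ~sem_regions,
    ~n_dlpfc, ~depth_dlpfc, ~pct_dlpfc, ~sem_dlpfc,
    "CCDC75/EIF2AK2", "chr2:37327702", "intergenic",
    8, 11.4, 59.8, 8.0, 8, 22.2, 32.0, 8.7,
    "CTSB", "chr8:11702542", "3'UTR",
    10, 16.8, 99.4, 0.6, 8, 11.0, 87.3, 4.0,
    "FTX", "chrX:73499965", "exonic (ncRNA)",
    9, 62.0, 31.8, 2.8, 10, 116.3, 27.1, 2.2,
    "GRIA2", "chr4:158257875", "exonic (non-synonymous)",
    10, 32.3, 88.9, 4.6, 13, 56.0, 97.5, 0.6,
    "GRIA2", "chr4:158257879", "exonic (synonymous)",
    8, 35.9, 21.0, 2.7, 8, 75.5, 16.4, 0.8,
    "GRIK2", "chr6:102337689", "exonic (non-synonymous)",
    10, 19.2, 44.5, 3.9, 13, 18.9, 37.2, 3.8,
    "GRIK2", "chr6:102337702", "exonic (non-synonymous)",
    9, 18.2, 62.0, 3.7, 13, 17.1, 63.9, 5.7,
    "MTRNR2L1", "chr17:22021971", "intergenic",
    10, 1595.7, 98.0, 0.1, 10, 1796.7, 96.9, 0.5,
    "PAR-SN", "chr15:25227816", "exonic (ncRNA)",
    9, 11.6, 67.8, 8.2, 13, 29.6, 79.4, 2.0,
    "PAR-SN", "chr15:25227838", "exonic (ncRNA)",
    7, 12.1, 43.5, 5.3, 11, 26.1, 35.4, 2.6,
    "PAR-SN", "chr15:25227854", "exonic (ncRNA)",
    5, 14.4, 25.4, 5.6, 8, 26.6, 22.1, 2.8,
    "TRUB2", "chr9:131071533", "3'UTR",
    5, 11.2, 54.6, 9.9, 11, 15.1, 59.8, 4.6
  )
}
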