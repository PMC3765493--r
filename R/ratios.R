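#' Fold allelic counts onto an orientation-free ratio scale
#'
#' Without haplotype phasing the direction of an allelic ratio is arbitrary:
#' 2-fold and 0.5-fold both mean a 2-fold difference between alleles, and
#' SNPs with strand-ambiguous alleles (C/G, A/T) could be reported either
#' way. All ratios are therefore folded via `10^|log10(ref/var)|`, which is
#' >= 1 and symmetric under swapping the alleles, so multiple SNPs in the
#' same gene can be combined. The logit score, `ln(max(ref, var) /
#' min(ref, var))`, is the log of the larger over the smaller count and is
#' used as a predictor of confirmed AEI (see [fit_aei_logistic()]).
#'
#' @param counts Tibble with positive `ref_count` and `var_count` columns
#'   (run [filter_allelic_counts()] first; zero counts are an error).
#' @param logit_base Base of the logit-score logarithm (default `exp(1)`,
#'   i.e. natural log).
#' @return `counts` with columns `raw_ratio`, `log10_ratio`, `folded_ratio`
#'   and `logit_score` appended.
#' @examples
#' allelic_ratio(tibble::tibble(ref_count = c(20, 10), var_count = c(10, 20)))
#' @export
allelic_ratio <- function(counts, logit_base = exp(1)) {
  counts <- as_tibble(counts)
  bad <- counts$ref_count <= 0 | counts$var_count <= 0
  if (any(bad)) {
    where <- if ("site_id" %in% names(counts)) {
      paste(head(counts$site_id[bad], 3), collapse = ", ")
    } else {
      paste("row", paste(head(which(bad), 3), collapse = ", "))
    }
    abort(sprintf(
      "allelic ratio undefined for %d site(s) with a zero allele count (%s); apply filter_allelic_counts() first",
      sum(bad), where
    ))
  }
  counts %>%
    mutate(
      raw_ratio = .data$ref_count / .data$var_count,
      log10_ratio = log10(.data$raw_ratio),
      # 10^|log10(r)| computed as max/min so reciprocal pairs fold
      # bit-identically
      folded_ratio = pmax(.data$ref_count, .data$var_count) /
        pmin(.data$ref_count, .data$var_count),
      logit_score = log(
        pmax(.data$ref_count, .data$var_count) /
          pmin(.data$ref_count, .data$var_count),
        base = logit_base
      )
    )
}

#' Combine folded allelic ratios within genes
#'
#' A single low-depth SNP is a noisy AEI estimate; averaging the folded
#' ratios of all (window-merged) SNPs of a gene attenuates that error. For
#' each gene x sample this returns the arithmetic mean of the folded ratios,
#' their sample standard deviation (n - 1 denominator; `NA` for a single
#' observation), the mean on the |log10| scale as a diagnostic, and an
#' equal-weight Cochran's Q heterogeneity statistic over the log10 folded
#' ratios (`sum((y_i - mean(y))^2)`; a stand-in for an inverse-variance
#' weighted Q, since per-observation variances are not modelled here).
#'
#' @param observations Tibble with `gene`, `sample_id` and `folded_ratio`
#'   columns, typically from [merge_snp_windows()].
#' @return A tibble with one row per gene x sample: `n_obs`, `mean_folded`,
#'   `sd_folded`, `mean_log10`, `het_q`.
#' @examples
#' obs <- allelic_ratio(
#'   tibble::tibble(ref_count = c(20, 10), var_count = c(10, 20),
#'                  gene = "G1", sample_id = "S1")
#' )
#' combine_gene_ratios(obs)  # raw ratios 2.0 and 0.5 combine to 2.0
#' @export
combine_gene_ratios <- function(observations) {
  obs <- as_tibble(observations)
  if (nrow(obs) == 0) abort("no observations to combine")
  if (!"sample_id" %in% names(obs)) obs$sample_id <- "sample"
  obs %>%
    group_by(.data$gene, .data$sample_id) %>%
    summarise(
      n_obs = dplyr::n(),
      mean_folded = mean(.data$folded_ratio),
      sd_folded = ifelse(dplyr::n() >= 2, sd(.data$folded_ratio), NA_real_),
      mean_log10 = mean(log10(.data$folded_ratio)),
      het_q = sum((log10(.data$folded_ratio) -
                     mean(log10(.data$folded_ratio)))^2),
      .groups = "drop"
    )
}

#' Call allelic expression imbalance per gene
#'
#' Three calling rules of increasing stringency, all pure functions of the
#' gene-level summary returned by [combine_gene_ratios()]:
#'
#' * **permissive** — mean folded ratio at or above `threshold` (default
#'   2) with at least `min_obs` observations (default 2; single-SNP genes
#'   are never called).
#' * **stringent_2sd** — mean minus two standard deviations still at or
#'   above `threshold` (default 1.5). Genes with one observation have no
#'   SD and are ineligible (`FALSE`).
#' * **stringent_sdthird** — SD no greater than one third of the mean, and
#'   mean at or above `threshold` (default 2). Same single-observation
#'   ineligibility.
#'
#' `call_aei()` applies one rule and appends a logical `aei_call` column
#' (plus `call_reason` explaining ineligible rows); the three `call_*()`
#' helpers return bare logical vectors.
#'
#' @param genes Tibble from [combine_gene_ratios()] (columns `n_obs`,
#'   `mean_folded`, `sd_folded`).
#' @param mode One of `"permissive"`, `"stringent_2sd"`,
#'   `"stringent_sdthird"`.
#' @param threshold Fold-ratio threshold; defaults depend on the rule as
#'   described above.
#' @param min_obs Minimum observations per gene (permissive rule).
#' @return `call_aei()`: `genes` with `aei_call` and `call_reason` columns.
#'   `call_permissive()`, `call_stringent_2sd()`, `call_stringent_sdthird()`:
#'   a logical vector.
#' @examples
#' g <- tibble::tibble(gene = "G1", sample_id = "S1", n_obs = 2,
#'                     mean_folded = 2.5, sd_folded = 0.4)
#' call_permissive(g)
#' call_stringent_2sd(g)   # 2.5 - 0.8 = 1.7 >= 1.5
#' @export
call_aei <- function(genes,
                     mode = c("permissive", "stringent_2sd", "stringent_sdthird"),
                     threshold = NULL, min_obs = 2) {
  mode <- match.arg(mode)
  genes <- as_tibble(genes)
  call <- switch(mode,
    permissive = call_permissive(genes, threshold %||% 2, min_obs),
    stringent_2sd = call_stringent_2sd(genes, threshold %||% 1.5),
    stringent_sdthird = call_stringent_sdthird(genes, threshold %||% 2)
  )
  genes$aei_call <- call
  genes$call_reason <- dplyr::case_when(
    mode != "permissive" & genes$n_obs < 2 ~ "ineligible_single_obs",
    call ~ "aei",
    TRUE ~ "no_aei"
  )
  genes
}

#' @rdname call_aei
#' @export
call_permissive <- function(genes, threshold = 2, min_obs = 2) {
  genes$n_obs >= min_obs & genes$mean_folded >= threshold
}

#' @rdname call_aei
#' @export
call_stringent_2sd <- function(genes, threshold = 1.5) {
  eligible <- genes$n_obs >= 2 & !is.na(genes$sd_folded)
  eligible & (genes$mean_folded - 2 * genes$sd_folded) >= threshold
}

#' @rdname call_aei
#' @export
call_stringent_sdthird <- function(genes, threshold = 2) {
  eligible <- genes$n_obs >= 2 & !is.na(genes$sd_folded)
  eligible & genes$sd_folded <= genes$mean_folded / 3 &
    genes$mean_folded >= threshold
}

#' Normalize a SNaPshot cDNA peak-height ratio by its gDNA ratio
#'
#' In the SNaPshot primer-extension assay, fluorescent peak heights for the
#' two alleles carry dye- and primer-specific biases. The genomic DNA of the
#' same heterozygous individual is a built-in 1:1 standard, so dividing the
#' cDNA ref/var peak ratio by the gDNA ref/var peak ratio cancels the assay
#' bias and yields the allelic mRNA ratio.
#'
#' @param cdna_ratio,gdna_ratio Positive peak-height ratios (ref/var);
#'   vectorized.
#' @return `cdna_ratio / gdna_ratio`.
#' @examples
#' normalize_snapshot(1.6, 0.8)  # 2.0
#' @export
normalize_snapshot <- function(cdna_ratio, gdna_ratio) {
  if (any(cdna_ratio <= 0) || any(gdna_ratio <= 0)) {
    abort("peak-height ratios must be positive")
  }
  cdna_ratio / gdna_ratio
}
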