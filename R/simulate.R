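#' Configuration for the allelic-expression simulator
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' The bias model is deliberately minimal: every read is assigned an allele
#' by a binomial draw from the true allelic ratio, and each variant-carrying
#' read is then lost independently with probability `bias_beta`, emulating
#' aligners that penalise the variant allele as a mismatch against the
#' standard reference. Under this model the expected observed raw ratio is
#' `true_ratio / (1 - bias_beta)`. Alignment against a masked reference
#' treats both alleles as matches, so masked-mode generation forces the
#' loss probability to zero.
#'
#' The default `bias_beta = 0.33` reproduces the attenuation scale seen
#' when standard-alignment ratios are compared with bias-corrected ones
#' (a 3-fold standard ratio corresponding to roughly a 2-fold corrected
#' ratio); the default editing panel mirrors the 12-site brain survey
#' ([brain_editing_sites()]): two conditions of 10 and 13 samples.
#'
#' @param n_genes Number of simulated genes.
#' @param snps_per_gene Integer range `c(min, max)` of heterozygous SNPs
#'   per gene.
#' @param true_ratio True allelic fold (ref/var) per gene; scalar or length
#'   `n_genes`.
#' @param depth Mean informative read depth per site.
#' @param bias_beta Probability in \[0, 1) that a variant-carrying read is
#'   lost during standard alignment.
#' @param n_samples Number of samples.
#' @param depth_model `"poisson"` (total reads per site ~ Poisson(depth))
#'   or `"fixed"` (exactly `depth`).
#' @param read_length Simulated read length (bp) for [simulate_reads()].
#' @param editing_true_fractions True per-site editing fractions for
#'   [simulate_editing_panel()]; defaults to the 12 observed brain levels.
#' @param editing_samples Named vector of samples per condition.
#' @param editing_depth Mean read depth per editing site and sample.
#' @param seed Integer seed; every generator is a pure function of the
#'   configuration, so a fixed seed gives byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20,
                       snps_per_gene = c(1, 4),
                       true_ratio = 1,
                       depth = 100,
                       bias_beta = 0.33,
                       n_samples = 1,
                       depth_model = c("poisson", "fixed"),
                       read_length = 50,
                       editing_true_fractions = brain_editing_sites()$pct_regions / 100,
                       editing_samples = c(regions = 10, dlpfc = 13),
                       editing_depth = 30,
                       seed = 1L) {
  depth_model <- match.arg(depth_model)
  if (bias_beta < 0 || bias_beta >= 1) {
    abort("bias_beta must be in [0, 1)")
  }
  if (any(true_ratio < 0)) abort("true_ratio must be non-negative")
  if (!length(true_ratio) %in% c(1L, n_genes)) {
    abort("true_ratio must be a scalar or one value per gene")
  }
  if (length(snps_per_gene) == 1) snps_per_gene <- rep(snps_per_gene, 2)
  structure(
    list(
      n_genes = as.integer(n_genes),
      snps_per_gene = as.integer(snps_per_gene),
      true_ratio = rep_len(true_ratio, n_genes),
      depth = depth,
      bias_beta = bias_beta,
      n_samples = as.integer(n_samples),
      depth_model = depth_model,
      read_length = as.integer(read_length),
      editing_true_fractions = editing_true_fractions,
      editing_samples = editing_samples,
      editing_depth = editing_depth,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Deterministic site layout: genes laid head-to-tail on one chromosome,
# SNPs at least `gap` apart so simulated reads never span two sites.
sim_site_layout <- function(cfg, gap = 3L * cfg$read_length) {
  withr_seed(cfg$seed, {
    n_snps <- sample(seq(cfg$snps_per_gene[1], cfg$snps_per_gene[2]),
                     cfg$n_genes, replace = TRUE)
    rows <- vector("list", cfg$n_genes)
    gene_start <- 1000L
    for (g in seq_len(cfg$n_genes)) {
      offsets <- cumsum(sample(gap:(2L * gap), n_snps[g], replace = TRUE))
      pos <- gene_start + offsets
      ref <- sample(DNA_BASES_, n_snps[g], replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES_, b), 1), "")
      rows[[g]] <- tibble(
        chrom = "chrS", pos = as.integer(pos),
        ref = ref, alt = unname(alt),
        site_id = sprintf("sim%d_%d", g, seq_len(n_snps[g])),
        gene = sprintf("GENE%03d", g),
        region_class = "exonic",
        true_ratio = cfg$true_ratio[g]
      )
      gene_start <- max(pos) + 10L * gap
    }
    bind_rows(rows)
  })
}

# evaluate `expr` under a local RNG state seeded with `seed + offset`
withr_seed <- function(seed, expr, offset = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed + offset)
  expr
}

#' Simulate per-site allelic counts under reference bias
#'
#' For each site and sample: total informative reads are drawn (Poisson or
#' fixed), split between reference and variant alleles with
#' `p_ref = true_ratio / (1 + true_ratio)`, and each variant read is then
#' deleted with probability `bias_beta`. The returned table carries both
#' the observed counts and the ground truth, so parameter recovery is
#' directly testable: the expected observed raw ratio is
#' `true_ratio / (1 - bias_beta)`.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with one row per site x sample: site columns, the
#'   observed `ref_count`/`var_count`/`other_count`, and truth columns
#'   `true_ratio`, `true_var_count` (variant reads before bias loss),
#'   `bias_beta`.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sites <- sim_site_layout(cfg)
  withr_seed(cfg$seed, offset = 1L, {
    grid <- tidyr::expand_grid(
      sites,
      sample_id = sprintf("S%02d", seq_len(cfg$n_samples))
    )
    n <- nrow(grid)
    total <- switch(cfg$depth_model,
      poisson = rpois(n, cfg$depth),
      fixed = rep(as.integer(round(cfg$depth)), n)
    )
    p_ref <- grid$true_ratio / (1 + grid$true_ratio)
    ref_reads <- rbinom(n, total, p_ref)
    true_var <- total - ref_reads
    grid$ref_count <- ref_reads
    grid$var_count <- rbinom(n, true_var, 1 - cfg$bias_beta)
    grid$other_count <- 0L
    grid$true_var_count <- true_var
    grid$bias_beta <- cfg$bias_beta
    grid
  })
}

#' Toy reference genome covering the simulated site layout
#'
#' Generates a random A/C/G/T chromosome long enough for the layout of
#' `cfg`, with the layout's reference alleles planted at the catalogued
#' positions (so the genome and the catalog agree, as [mask_reference()]
#' requires).
#'
#' @param cfg A [sim_config()].
#' @return A `DNAStringSet` with one chromosome `chrS`.
#' @export
simulate_genome <- function(cfg) {
  sites <- sim_site_layout(cfg)
  len <- max(sites$pos) + 10L * cfg$read_length
  withr_seed(cfg$seed, offset = 2L, {
    seq <- paste(sample(DNA_BASES_, len, replace = TRUE), collapse = "")
    g <- Biostrings::DNAStringSet(setNames(seq, "chrS"))
    g[["chrS"]] <- Biostrings::replaceLetterAt(
      g[["chrS"]], at = sites$pos, letter = paste(sites$ref, collapse = "")
    )
    S4Vectors::metadata(g) <- list(provenance = "standard")
    g
  })
}

#' Simulate placed reads with planted alleles
#'
#' Emits an aligned read set (no aligner involved: positions are planted)
#' in which each read covers exactly one catalogued site and carries the
#' reference or variant base there according to the same draws as
#' [simulate_counts()]. In `"standard"` mode each variant-carrying read is
#' dropped with probability `bias_beta`, modelling mismatch penalisation
#' against the standard reference; in `"masked"` mode the ambiguity
#' character matches both alleles at zero penalty, so no read is dropped.
#' Both modes share the same seed-determined draws, so at every site
#' standard-mode `var_count` <= masked-mode `var_count`.
#'
#' @param cfg A [sim_config()].
#' @param genome Companion genome, default [simulate_genome()] of the same
#'   configuration.
#' @param mode `"standard"` or `"masked"`.
#' @return A tibble of reads (`qname`, `chrom`, `pos`, `cigar`, `seq`) with
#'   attributes `truth` (per-site planted counts after mode-specific loss)
#'   and `sites` (the site catalog). Write to SAM with [write_sam()].
#' @export
simulate_reads <- function(cfg, genome = simulate_genome(cfg),
                           mode = c("standard", "masked")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "sim_config"))
  sites <- sim_site_layout(cfg)
  L <- cfg$read_length
  chrom_len <- Biostrings::width(genome)[match("chrS", names(genome))]
  if (any(sites$pos > chrom_len)) abort("genome shorter than site layout")

  withr_seed(cfg$seed, offset = 3L, {
    per_site <- pmap(
      list(sites$pos, sites$ref, sites$alt, sites$true_ratio, sites$site_id),
      function(pos, ref, alt, ratio, id) {
        total <- switch(cfg$depth_model,
          poisson = rpois(1, cfg$depth),
          fixed = as.integer(round(cfg$depth))
        )
        is_ref <- runif(total) < ratio / (1 + ratio)
        dropped <- !is_ref & runif(total) < cfg$bias_beta
        offset <- sample.int(L, total, replace = TRUE) - 1L
        start <- pmax(1L, pmin(pos - offset, chrom_len - L + 1L))
        tibble(
          site_id = id, site_pos = pos,
          allele = ifelse(is_ref, ref, alt),
          is_ref = is_ref, dropped_in_standard = dropped,
          start = start
        )
      }
    ) %>% list_rbind()

    if (mode == "standard") {
      kept <- per_site[!per_site$dropped_in_standard, , drop = FALSE]
    } else {
      kept <- per_site
    }

    seqs <- as.character(Biostrings::extractAt(
      genome[["chrS"]],
      IRanges::IRanges(kept$start, width = L)
    ))
    at <- kept$site_pos - kept$start + 1L
    seqs <- vapply(seq_along(seqs), function(i) {
      s <- seqs[i]
      substr(s, at[i], at[i]) <- kept$allele[i]
      s
    }, "")

    reads <- tibble(
      qname = sprintf("read_%s_%06d", mode, seq_len(nrow(kept))),
      chrom = "chrS",
      pos = kept$start,
      mapq = 60L,
      cigar = sprintf("%dM", L),
      seq = seqs
    )
    observed <- kept %>%
      group_by(.data$site_id) %>%
      summarise(ref_count = sum(.data$is_ref),
                var_count = sum(!.data$is_ref), .groups = "drop")
    truth <- sites %>%
      select("site_id", "chrom", "pos", "ref", "alt", "gene", "true_ratio") %>%
      left_join(observed, by = "site_id") %>%
      tidyr::replace_na(list(ref_count = 0L, var_count = 0L))
    attr(reads, "truth") <- truth
    attr(reads, "sites") <- sites
    attr(reads, "mode") <- mode
    reads
  })
}

#' Write simulated reads as a SAM file
#'
#' Emits a minimal valid plain-text SAM (header with `@SQ` lines taken from
#' the genome, unpaired forward reads, uniform base quality) suitable for
#' [count_alleles()].
#'
#' @param reads Tibble from [simulate_reads()].
#' @param genome The companion `DNAStringSet`.
#' @param path Output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  genome <- as_genome(genome)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome))
  )
  qual <- strrep("I", nchar(reads$seq))
  body <- sprintf(
    "%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
    reads$qname, reads$chrom, reads$pos, reads$mapq, reads$cigar,
    reads$seq, qual
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a two-condition RNA-editing panel with known truth
#'
#' For each catalogued editing site, both conditions share the same true
#' editing fraction; per sample, read depth is drawn (Poisson or fixed) and
#' the edited-read count is binomial at the true fraction. As depth grows
#' the per-condition mean fractions converge to the shared truth, so the
#' cross-condition correlation tends to 1.
#'
#' @param cfg A [sim_config()]; uses `editing_true_fractions`,
#'   `editing_samples`, `editing_depth`, `depth_model`, `seed`.
#' @return A tibble with one row per site x condition x sample:
#'   `site_id`, `condition`, `sample_id`, `edited_count`, `total_count`,
#'   `true_fraction`.
#' @export
simulate_editing_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fr <- cfg$editing_true_fractions
  if (any(fr < 0 | fr > 1)) abort("editing fractions must be in [0, 1]")
  withr_seed(cfg$seed, offset = 4L, {
    grid <- tidyr::expand_grid(
      site = seq_along(fr),
      condition = names(cfg$editing_samples)
    ) %>%
      mutate(n_samples = unname(cfg$editing_samples[.data$condition])) %>%
      tidyr::uncount(.data$n_samples, .id = "sample_n")
    n <- nrow(grid)
    total <- switch(cfg$depth_model,
      poisson = rpois(n, cfg$editing_depth),
      fixed = rep(as.integer(round(cfg$editing_depth)), n)
    )
    tibble(
      site_id = sprintf("edit%02d", grid$site),
      condition = grid$condition,
      sample_id = sprintf("%s_%02d", grid$condition, grid$sample_n),
      total_count = total,
      edited_count = rbinom(n, total, fr[grid$site]),
      true_fraction = fr[grid$site]
    )
  })
}
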