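PIPELINE_KEYS_ <- c(
  "genome_fasta", "variant_catalog", "alignments", "counts_tsv",
  "gene_intervals", "editing_counts_tsv", "sample_id",
  "min_per_allele", "min_minor_fraction", "window_bp",
  "aei_threshold", "aei_mode", "min_obs",
  "min_support", "min_avg_depth", "ci_level",
  "strict_ref_check", "seed", "out_dir"
)

#' Read a pipeline configuration file
#'
#' Plain `key = value` lines (one per line, `#` comments and blank lines
#' ignored). Unknown keys are rejected so a typo cannot silently fall back
#' to a default; every effective value, default or not, is echoed into the
#' run log by [run_pipeline()].
#'
#' @param path Path to the configuration file.
#' @return A named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) {
    abort(sprintf("malformed config line(s): %s",
                  paste(lines[bad], collapse = "; ")))
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  unknown <- setdiff(keys, PIPELINE_KEYS_)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- as.list(vals)
  names(cfg) <- keys
  numeric_keys <- c("min_per_allele", "min_minor_fraction", "window_bp",
                    "aei_threshold", "min_obs", "min_avg_depth", "ci_level",
                    "seed")
  for (k in intersect(numeric_keys, names(cfg))) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  if ("strict_ref_check" %in% names(cfg)) {
    cfg$strict_ref_check <- toupper(cfg$strict_ref_check) %in% c("TRUE", "1", "YES")
  }
  cfg
}

#' Run the AEI pipeline end to end
#'
#' Orchestrates mask -> count -> filter -> annotate -> fold -> merge ->
#' combine -> call (and, when an editing count table is supplied, the
#' editing survey), writing one TSV per stage, a JSON summary of record
#' counts surviving each filter, and a log that echoes every effective
#' parameter. Given the same configuration and seed the outputs are
#' byte-identical across runs; each stage writes a fresh file and never
#' mutates an earlier stage's output.
#'
#' @param config A named list (see [read_pipeline_config()] for keys) or a
#'   path to a `key = value` configuration file. Required: either
#'   `alignments` (SAM/BAM) plus `variant_catalog`, or a precomputed
#'   `counts_tsv`. Optional: `genome_fasta` (enables the masking stage),
#'   `gene_intervals`, `editing_counts_tsv`.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with the per-stage tibbles (`counts`,
#'   `filtered`, `observations`, `merged`, `genes`, `calls`, optionally
#'   `editing`) and the `summary` list written to JSON.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS_)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- config
  out_dir <- out_dir %||% cfg$out_dir %||% abort("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  defaults <- list(
    sample_id = "sample", min_per_allele = 3, min_minor_fraction = 0.05,
    window_bp = 100, aei_threshold = NULL, aei_mode = "permissive",
    min_obs = 2, min_support = "regions=5,dlpfc=8", min_avg_depth = 10,
    ci_level = 0.95, strict_ref_check = FALSE, seed = 1
  )
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  set.seed(as.integer(cfg$seed))

  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- c(
    sprintf("aeikit run_pipeline %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    "effective configuration:",
    vapply(PIPELINE_KEYS_, function(k) {
      sprintf("  %s = %s", k,
              if (is.null(cfg[[k]])) "<unset>" else paste(cfg[[k]], collapse = ","))
    }, "")
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  summary <- list(seed = as.integer(cfg$seed))

  sites <- NULL
  if (!is.null(cfg$variant_catalog)) {
    sites <- stage("catalog", read_variant_sites(cfg$variant_catalog))
    summary$n_catalog_sites <- nrow(sites)
  }

  if (!is.null(cfg$genome_fasta) && !is.null(sites)) {
    stage("mask", {
      genome <- read_genome_fasta(cfg$genome_fasta)
      masked <- mask_reference(genome, sites, strict = isTRUE(cfg$strict_ref_check))
      write_genome_fasta(masked, file.path(out_dir, "masked.fa"))
      readr::write_tsv(masking_audit(masked), file.path(out_dir, "mask_audit.tsv"))
      summary$n_masked <- S4Vectors::metadata(masked)$n_edited
      summary$n_mask_skipped <- nrow(masking_audit(masked))
    })
  }

  counts <- stage("count", {
    if (!is.null(cfg$alignments)) {
      if (is.null(sites)) abort("alignments given without a variant_catalog")
      count_alleles(cfg$alignments, sites, sample_id = cfg$sample_id)
    } else if (!is.null(cfg$counts_tsv)) {
      readr::read_tsv(cfg$counts_tsv, show_col_types = FALSE)
    } else {
      abort("need either `alignments` + `variant_catalog` or `counts_tsv`")
    }
  })
  readr::write_tsv(counts, file.path(out_dir, "counts.tsv"))
  summary$n_counted_sites <- nrow(counts)

  if (!is.null(cfg$gene_intervals)) {
    counts <- stage("annotate", {
      gi <- read_gene_intervals(cfg$gene_intervals)
      annotate_sites(counts, gi)
    })
    counts <- exonic_sites(counts)
    summary$n_exonic_sites <- nrow(counts)
  }

  filtered <- stage("filter", filter_allelic_counts(
    counts, cfg$min_per_allele, cfg$min_minor_fraction
  ))
  readr::write_tsv(filtered, file.path(out_dir, "filtered_counts.tsv"))
  summary$n_filtered_sites <- nrow(filtered)

  result <- list(counts = counts, filtered = filtered)
  if (nrow(filtered) > 0 && all(c("gene", "pos") %in% names(filtered))) {
    observations <- stage("ratio", allelic_ratio(filtered))
    merged <- stage("merge", merge_snp_windows(observations, cfg$window_bp))
    genes <- stage("combine", combine_gene_ratios(merged))
    calls <- stage("call", call_aei(
      genes, mode = cfg$aei_mode,
      threshold = cfg$aei_threshold, min_obs = cfg$min_obs
    ))
    readr::write_tsv(merged, file.path(out_dir, "merged_observations.tsv"))
    readr::write_tsv(calls, file.path(out_dir, "aei_calls.tsv"))
    summary$n_merged_observations <- nrow(merged)
    summary$n_genes_tested <- nrow(genes)
    summary$n_aei_calls <- sum(calls$aei_call)
    result <- c(result, list(observations = observations, merged = merged,
                             genes = genes, calls = calls))
  }

  if (!is.null(cfg$editing_counts_tsv)) {
    editing <- stage("edit-survey", {
      ec <- readr::read_tsv(cfg$editing_counts_tsv, show_col_types = FALSE)
      ms <- parse_min_support(cfg$min_support)
      summarize_editing_sites(ec) %>%
        filter_editing_sites(min_support = ms,
                             min_avg_depth = cfg$min_avg_depth) %>%
        mutate(reference_error = map_dbl(.data$fractions, function(f) {
          as.numeric(suppressWarnings(
            exclude_reference_errors(f, cfg$ci_level)
          ))
        }) > 0) %>%
        select(-"fractions")
    })
    readr::write_tsv(editing, file.path(out_dir, "editing_sites.tsv"))
    summary$n_editing_sites <- length(unique(editing$site_id))
    summary$n_editing_retained <- length(unique(
      editing$site_id[editing$excluded_reason == "none" & !editing$reference_error]
    ))
    result$editing <- editing
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(log_lines, "stage record counts:",
               sprintf("  %s = %s", names(summary), unlist(summary))),
             log_path)
  result$summary <- summary
  invisible(result)
}

parse_min_support <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  if (all(lengths(parts) == 2)) {
    setNames(as.numeric(vapply(parts, `[`, "", 2L)),
             trimws(vapply(parts, `[`, "", 1L)))
  } else {
    as.numeric(x)
  }
}
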