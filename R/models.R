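#' Regress corrected against standard-alignment allelic ratios
#'
#' To estimate how much a bias-attenuating alignment (IUPAC-masked or
#' allele-switched reference) shrinks allelic ratios, the |log10| folded
#' ratios from the corrected alignment are regressed by ordinary least
#' squares against those from the standard alignment at the same SNPs. The
#' fitted line maps any standard-alignment fold to its corrected
#' equivalent via [predict_fold()] (e.g. a slope below 1 means standard
#' alignment systematically overstates allelic imbalance).
#'
#' @param pairs Tibble with columns `log10_standard` and `log10_corrected`
#'   (one row per paired SNP measurement). At least 3 finite pairs with
#'   non-degenerate x-variance are required.
#' @return An object of class `aei_lm` with elements `slope`, `intercept`,
#'   `r_squared`, `aic`, `n` and the underlying `lm` fit. Supports
#'   [tidy()], [glance()], [autoplot()] and [predict_fold()].
#' @examples
#' pairs <- tibble::tibble(log10_standard = log10(c(1, 2, 3, 4)),
#'                         log10_corrected = log10(c(1, 2, 3, 4)))
#' fit <- compare_alignment_methods(pairs)
#' predict_fold(fit, 3)
#' @export
compare_alignment_methods <- function(pairs) {
  pairs <- as_tibble(pairs)
  needed <- c("log10_standard", "log10_corrected")
  if (!all(needed %in% names(pairs))) {
    abort("`pairs` needs columns log10_standard and log10_corrected")
  }
  ok <- is.finite(pairs$log10_standard) & is.finite(pairs$log10_corrected)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 3) abort("need at least 3 finite pairs")
  if (sd(pairs$log10_standard) == 0) {
    abort("standard-alignment ratios are constant; slope is not identifiable")
  }
  fit <- lm(log10_corrected ~ log10_standard, data = pairs)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = summary(fit)$r.squared,
      aic = AIC(fit),
      n = nrow(pairs),
      lm = fit
    ),
    class = "aei_lm"
  )
}

#' Corrected fold ratio predicted for a standard-alignment fold
#'
#' Evaluates the fitted line of [compare_alignment_methods()] on the fold
#' scale: `10^(intercept + slope * log10(fold))`.
#'
#' @param fit An `aei_lm` object.
#' @param fold Standard-alignment folded ratio(s), >= 1.
#' @return Predicted corrected fold(s).
#' @export
predict_fold <- function(fit, fold) {
  stopifnot(inherits(fit, "aei_lm"))
  10^(fit$intercept + fit$slope * log10(fold))
}

#' @export
print.aei_lm <- function(x, ...) {
  cat("Allelic-ratio method comparison (OLS on |log10| folded ratios)\n")
  cat(sprintf("  n = %d pairs\n", x$n))
  cat(sprintf("  slope = %.4f, intercept = %.4f, r^2 = %.3f, AIC = %.1f\n",
              x$slope, x$intercept, x$r_squared, x$aic))
  cat(sprintf("  a 3-fold standard ratio maps to a %.2f-fold corrected ratio\n",
              predict_fold(x, 3)))
  invisible(x)
}

#' @export
tidy.aei_lm <- function(x, ...) {
  s <- unname(summary(x$lm)$coefficients)
  tibble(
    term = c("intercept", "log10_standard"),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @export
glance.aei_lm <- function(x, ...) {
  tibble(r.squared = x$r_squared, AIC = x$aic, nobs = x$n,
         slope = x$slope, intercept = x$intercept)
}

#' Logistic prediction of confirmed AEI from RNA-seq ratio features
#'
#' Fits a maximum-likelihood logistic regression predicting whether a gene's
#' AEI is confirmed by an orthogonal assay (e.g. a SNaPshot allelic ratio at
#' or above 1.5-fold) from RNA-seq-derived features. The baseline predictor
#' is the logit score, `ln(larger count / smaller count)`; candidate
#' covariates include `n_extra_snps x logit_score` (an interaction-style
#' term for genes with additional SNPs) and the within-gene heterogeneity
#' `het_q`. Competing feature sets are compared by AIC (lower is better).
#'
#' @param data Tibble holding the label column and all feature columns; at
#'   least 10 labelled records with no missing features.
#' @param features Character vector of feature column names (default
#'   `"logit_score"`).
#' @param label Name of the logical/0-1 outcome column (default
#'   `"aei_confirmed"`).
#' @return An `aei_logit` object with the `glm` fit, `aic` (`NA` under
#'   complete separation), `separation` flag, `features` and `n`. Supports
#'   [tidy()] and [glance()].
#' @examples
#' \dontrun{
#' m1 <- fit_aei_logistic(d, features = "logit_score")
#' m2 <- fit_aei_logistic(d, features = c("logit_score", "het_q"))
#' glance(m1)$AIC - glance(m2)$AIC
#' }
#' @export
fit_aei_logistic <- function(data, features = "logit_score",
                             label = "aei_confirmed") {
  data <- as_tibble(data)
  missing_cols <- setdiff(c(features, label), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  d <- data[, c(label, features)]
  if (!all(complete.cases(d))) abort("missing values in label or features")
  if (nrow(d) < 10) abort("need at least 10 labelled records")
  y <- as.integer(as.logical(d[[label]]))
  if (length(unique(y)) < 2) {
    abort("all labels identical; logistic fit is degenerate")
  }
  form <- stats::as.formula(
    paste0("`", label, "` ~ ", paste0("`", features, "`", collapse = " + "))
  )
  d[[label]] <- y
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # glm can converge silently under complete separation, with fitted
  # probabilities at machine 0/1; flag that case too
  p <- stats::fitted(fit)
  if (!separation && all(abs(p - y) < 1e-7)) separation <- TRUE
  structure(
    list(
      glm = fit,
      aic = if (separation) NA_real_ else AIC(fit),
      separation = separation,
      features = features,
      n = nrow(d)
    ),
    class = "aei_logit"
  )
}

#' @export
print.aei_logit <- function(x, ...) {
  cat("Logistic AEI predictor:", paste(x$features, collapse = " + "), "\n")
  cat(sprintf("  n = %d, AIC = %s%s\n", x$n,
              ifelse(is.na(x$aic), "unavailable", sprintf("%.1f", x$aic)),
              if (x$separation) " (complete separation)" else ""))
  invisible(x)
}

#' @export
tidy.aei_logit <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  terms <- gsub("`", "", rownames(s))
  terms[terms == "(Intercept)"] <- "intercept"
  s <- unname(s)
  tibble(
    term = terms,
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @export
glance.aei_logit <- function(x, ...) {
  tibble(AIC = x$aic, nobs = x$n, separation = x$separation,
         deviance = x$glm$deviance, null.deviance = x$glm$null.deviance)
}

#' Cross-tabulate AEI concordance between two assays at a fold threshold
#'
#' Counts how often two assays agree on calling AEI at `threshold` (both at
#' or above, both below, or discordant), e.g. RNA-seq folded ratios against
#' SNaPshot folded ratios.
#'
#' @param fold_a,fold_b Paired folded ratios from the two assays.
#' @param threshold Fold threshold defining AEI (default 1.5).
#' @return A tibble with `a_aei`, `b_aei` (logical) and `n`, plus
#'   `agreement` attributes: of the pairs where assay A calls AEI, how many
#'   B confirms, and likewise for non-AEI.
#' @export
concordance_table <- function(fold_a, fold_b, threshold = 1.5) {
  stopifnot(length(fold_a) == length(fold_b))
  a <- fold_a >= threshold
  b <- fold_b >= threshold
  out <- tibble(a_aei = a, b_aei = b) %>%
    dplyr::count(.data$a_aei, .data$b_aei, name = "n")
  attr(out, "confirmed_aei") <- c(sum(a & b), sum(a))
  attr(out, "confirmed_no_aei") <- c(sum(!a & !b), sum(!a))
  out
}
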