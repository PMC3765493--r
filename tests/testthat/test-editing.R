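# Editing fractions, retention filters, reference-error CI, and
# cross-condition statistics.

test_that("editing_fraction is edited/total with uncovered samples as NA", {
  expect_equal(editing_fraction(c(50, 30, 0), c(100, 30, 25)),
               c(0.5, 1.0, 0.0))
  expect_true(is.na(editing_fraction(0, 0)))
  expect_error(editing_fraction(5, 3), "exceeds")
  expect_error(editing_fraction(-1, 3), "non-negative")
})

make_panel_counts <- function() {
  # site e1: solid support and depth everywhere
  # site e2: supported in only 3 of 10 "regions" samples
  # site e3: avg depth exactly 10 in dlpfc (fails the strict > 10 rule)
  rows <- list()
  add <- function(site, cond, n, edited, total) {
    tibble::tibble(site_id = site, condition = cond,
                   sample_id = paste0(cond, "_", seq_len(n)),
                   edited_count = edited, total_count = total)
  }
  dplyr::bind_rows(
    add("e1", "regions", 10, rep(6, 10), rep(20, 10)),
    add("e1", "dlpfc", 13, rep(8, 13), rep(20, 13)),
    add("e2", "regions", 10, c(rep(4, 3), rep(0, 7)), rep(20, 10)),
    add("e2", "dlpfc", 13, rep(4, 13), rep(20, 13)),
    add("e3", "regions", 10, rep(5, 10), rep(15, 10)),
    add("e3", "dlpfc", 13, rep(5, 13), rep(10, 13))
  )
}

test_that("summarize_editing_sites computes support, depth, mean % and SEM", {
  s <- summarize_editing_sites(make_panel_counts())
  e1r <- s[s$site_id == "e1" & s$condition == "regions", ]
  expect_equal(e1r$n_supporting, 10L)
  expect_equal(e1r$avg_depth, 20)
  expect_equal(e1r$mean_fraction, 30)
  expect_equal(e1r$sem_fraction, 0)
  e2r <- s[s$site_id == "e2" & s$condition == "regions", ]
  expect_equal(e2r$n_supporting, 3L)
})

test_that("filter_editing_sites applies per-condition support and strict depth rules", {
  s <- summarize_editing_sites(make_panel_counts())
  f <- filter_editing_sites(s, min_support = c(regions = 5, dlpfc = 8),
                            min_avg_depth = 10)
  reason <- function(site) unique(f$excluded_reason[f$site_id == site])
  expect_equal(reason("e1"), "none")
  expect_equal(reason("e2"), "low_support")  # 3 of 10 regions
  expect_equal(reason("e3"), "low_depth")    # dlpfc avg exactly 10, not > 10
  # depth 10.1 would pass: nudge e3 dlpfc depth up
  counts <- make_panel_counts()
  counts$total_count[counts$site_id == "e3" & counts$condition == "dlpfc"][1] <- 11.3
  f2 <- filter_editing_sites(summarize_editing_sites(counts),
                             min_support = c(regions = 5, dlpfc = 8))
  expect_equal(unique(f2$excluded_reason[f2$site_id == "e3"]), "none")
})

test_that("filter is monotone in both thresholds", {
  s <- summarize_editing_sites(make_panel_counts())
  retained <- function(f) unique(f$site_id[f$excluded_reason == "none"])
  base <- retained(filter_editing_sites(s, c(regions = 3, dlpfc = 3), 5))
  tighter_support <- retained(filter_editing_sites(s, c(regions = 8, dlpfc = 8), 5))
  tighter_depth <- retained(filter_editing_sites(s, c(regions = 3, dlpfc = 3), 18))
  expect_true(all(tighter_support %in% base))
  expect_true(all(tighter_depth %in% base))
})

test_that("homology-flagged sites are excluded as input flags, not computed", {
  counts <- make_panel_counts()
  counts$homology_flag <- counts$site_id == "e1"
  f <- filter_editing_sites(summarize_editing_sites(counts))
  expect_equal(unique(f$excluded_reason[f$site_id == "e1"]), "homology_flag")
})

test_that("reference-error exclusion uses a t-interval against 100%", {
  expect_true(exclude_reference_errors(c(1, 1, 1, 1)))
  expect_false(exclude_reference_errors(c(0.45, 0.55, 0.50, 0.48)))
  # frozen hand-computed t-interval: mean 0.985, sem 0.0064550,
  # t_{0.975,3} = 3.182446 -> upper bound 1.005543 >= 1 -> exclude
  res <- exclude_reference_errors(c(0.97, 0.99, 1.00, 0.98))
  expect_true(res[1])
  expect_equal(attr(res, "ci_upper"), 1.005543, tolerance = 1e-6)
  # order invariance
  expect_equal(
    attr(exclude_reference_errors(c(0.99, 0.98, 1.00, 0.97)), "ci_upper"),
    attr(res, "ci_upper")
  )
  # single sample: not evaluable, retained with warning
  expect_warning(single <- exclude_reference_errors(0.9), "retained")
  expect_false(single[1])
})

test_that("editing_correlation matches direct Pearson computation and its invariances", {
  panel <- brain_editing_sites()
  r <- editing_correlation(panel$pct_regions, panel$pct_dlpfc)
  expect_equal(r$r, cor(panel$pct_regions, panel$pct_dlpfc))
  expect_equal(r$n, 12L)
  expect_equal(editing_correlation(1:5, 1:5)$r_squared, 1)
  inv <- editing_correlation(panel$pct_regions, 100 - panel$pct_regions)
  expect_equal(inv$r, -1)
  expect_equal(inv$r_squared, 1)
  # affine invariance
  shifted <- editing_correlation(panel$pct_regions + 7, panel$pct_dlpfc * 2)
  expect_equal(shifted$r, r$r)
  expect_error(editing_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("variability comparison: identical SEMs give p = 1, a large shift is detected", {
  sems <- brain_editing_sites()$sem_regions
  same <- compare_editing_variability(sems, sems)
  expect_equal(same$p_value, 1)
  shifted <- compare_editing_variability(sems + 20, sems)
  expect_lt(shifted$p_value, 0.05)
  f <- compare_editing_variability(sems, sems * 3, method = "f")
  expect_equal(f$method, "variance_ratio_F")
})

test_that("the two brain conditions show no significant difference in editing variability", {
  panel <- brain_editing_sites()
  res <- compare_editing_variability(panel$sem_regions, panel$sem_dlpfc)
  expect_gt(res$p_value, 0.05)
})
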