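# aeikit

Measuring **allelic expression imbalance (AEI)** — unequal RNA output from
the two alleles of a gene in a heterozygous individual — is a direct way to
detect *cis*-acting regulatory variants, and the same per-site allelic read
counts also quantify A-to-I RNA editing. The obstacle in RNA-seq is
**reference mapping bias**: aligners penalise reads carrying the
non-reference allele as mismatches, so variant alleles are systematically
undercounted and allelic ratios are inflated toward the reference.

`aeikit` is an R toolkit for this analysis, aimed at anyone quantifying
allele-specific expression or editing from aligned RNA-seq reads:

* **Bias-attenuating references** — build a genome with IUPAC ambiguity
  codes (R, Y, S, W, K, M) at catalogued SNPs so neither allele is
  penalised, or switch reference alleles to variant alleles at targeted
  sites.
* **Allelic counting** — pile up reference/variant/other reads at
  heterozygous SNPs from SAM/BAM, filter to informative sites (≥ 3 reads
  per allele, minor allele ≥ 5% of informative reads), annotate to genes,
  and merge SNPs within 100 bp into single observations.
* **AEI statistics** — fold ratios onto an orientation-free scale,
  combine SNPs within genes, and call AEI under permissive and stringent
  rules; compare alignment strategies by regression on log ratios; predict
  orthogonally-confirmed AEI with a logistic/AIC harness; normalise
  SNaPshot peak-height ratios.
* **RNA-editing survey** — per-site editing fractions across samples,
  support/depth retention filters, reference-error exclusion by
  confidence interval, and cross-condition correlation and variability
  tests.
* **Ground-truthed simulation** — a generative model of reference bias
  (each variant-carrying read lost with probability β) so every stage is
  verifiable against known truth.

## The model in brief

For a heterozygous SNP with `ref` and `var` informative read counts, the
raw allelic ratio is `r = ref/var`. Because haplotype phase is unknown,
ratios are folded:

```
folded = 10^|log10(r)|        (≥ 1; 2-fold and 0.5-fold both fold to 2)
logit score = ln(max(ref,var) / min(ref,var))
```

Folded ratios of SNPs within 100 bp are averaged (they likely sit on the
same library fragments), and a gene × sample estimate is the arithmetic
mean of its merged observations. Calling rules:

* *permissive*: mean folded ratio ≥ 2 with ≥ 2 observations;
* *stringent (2 SD)*: mean − 2·SD ≥ 1.5;
* *stringent (SD/3)*: SD ≤ mean/3 and mean ≥ 2.

The bias simulator draws `total ~ Poisson(depth)`, assigns reads to
alleles with `p_ref = r_true/(1 + r_true)`, and deletes each variant read
with probability β, so the expected observed raw ratio is
`r_true/(1 − β)` — masked-reference alignment corresponds to β = 0.

## Worked example

Simulate 150 genes with a true 2-fold allelic imbalance at depth 80 under
reference bias β = 0.33, then run the count → filter → fold → merge →
combine → call pipeline:

```r
library(aeikit)

cfg <- sim_config(n_genes = 150, snps_per_gene = c(2, 3), true_ratio = 2,
                  depth = 80, bias_beta = 0.33, seed = 7)

calls <- simulate_counts(cfg) |>
  filter_allelic_counts() |>       # ≥3 reads/allele, minor ≥5%
  allelic_ratio() |>               # fold + logit score
  merge_snp_windows() |>           # 100-bp window averaging
  combine_gene_ratios() |>         # gene × sample mean, SD, Q
  call_aei(mode = "permissive")    # mean ≥ 2 with ≥ 2 observations

calls
#> # A tibble: 150 × 9
#>   gene    sample_id n_obs mean_folded sd_folded mean_log10   het_q aei_call
#> 1 GENE001 S01           3        3.75    0.677       0.569 0.0117  TRUE
#> 2 GENE002 S01           2        2.75    0.354       0.438 0.00313 TRUE
#> 3 GENE003 S01           2        3.32    0.259       0.520 0.00115 TRUE
#> ...
sum(calls$aei_call)
#> [1] 148
```

The mean gene-level folded ratio is 3.14 under bias but 2.08 when the
same configuration is rerun with `bias_beta = 0` — the simulated standard
alignment inflates a true 2-fold imbalance to roughly 3-fold
(`2/(1 − 0.33) ≈ 3`), which is exactly why masked-reference alignment
matters before calling AEI at a 2-fold threshold.

The editing survey works the same way on tabular counts; the packaged
12-site brain reference panel illustrates the cross-condition statistics:

```r
panel <- brain_editing_sites()
editing_correlation(panel$pct_regions, panel$pct_dlpfc)
#>       r r_squared     n
#> 1 0.939     0.882    12
compare_editing_variability(panel$sem_regions, panel$sem_dlpfc)
#>   statistic p_value method                   n
#> 1        57   0.176 wilcoxon_signed_rank    12
```

Editing levels are tightly correlated between brain regions and
individuals (r² ≈ 0.88) and their variability does not differ
significantly (p = 0.18).

A command-line wrapper over the same functions is included at
`inst/cli/aeikit.R` (subcommands `mask-ref`, `switch-ref`, `count`,
`aei-call`, `compare-methods`, `edit-survey`, `simulate`, `run`).

## Package layout

* `R/` — reference masking, counting/filtering/merging, ratio and AEI
  statistics, editing survey, simulators, pipeline orchestration, plots.
* `vignettes/aeikit-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, simulator scope, limitations.
* `tests/testthat/` — unit, property and acceptance tests.
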