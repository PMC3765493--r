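---
title: "Measuring allelic expression imbalance with mapping-bias correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring allelic expression imbalance with mapping-bias correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeikit)
```

## The problem

A heterozygous individual carries two alleles of every autosomal gene. If a
*cis*-acting regulatory variant sits on one haplotype, the two alleles are
transcribed unequally, and the ratio of allele-specific read counts at any
heterozygous exonic SNP measures that imbalance directly — within one
sample, so *trans*-acting and environmental influences cancel. The same
per-site counts, read at catalogued A-to-I editing positions, quantify RNA
editing.

RNA-seq makes this measurable transcriptome-wide, but aligners score a
read against one reference sequence. A read carrying the non-reference
allele pays a mismatch penalty that a reference-allele read does not, so
variant alleles are systematically undercounted (*reference mapping
bias*) and allelic ratios are inflated toward the reference allele. Left
uncorrected, this manufactures apparent imbalance where there is none.

## Bias-attenuating references

`aeikit` implements two constructions:

* **IUPAC masking** (`mask_reference()`): every catalogued biallelic SNP
  position in the genome is replaced by the ambiguity character covering
  exactly its two alleles (R = A/G, Y = C/T, S = C/G, W = A/T, K = G/T,
  M = A/C). An ambiguity-aware aligner then scores both alleles as
  matches. One genome-wide alignment suffices.
* **Allele switching** (`switch_alleles()`): at targeted SNPs the
  reference base is replaced by the variant base. Counting the favoured
  allele in the standard and the switched alignment gives each allele a
  turn at being the reference.

Both validate the catalogued reference allele against the genome base.
Disagreements — routine in public catalogs because of strand flips and
assembly-build drift — are skipped with a warning and written to an audit
table rather than aborting; `strict = TRUE` upgrades them to errors.
Indels and multiallelic records are dropped on read
(`read_variant_sites()`) because ambiguity characters encode exactly two
single-base alternatives. Masking is invertible: resolving every masked
position back to its catalogued reference allele
(`resolve_to_reference()`) reproduces the input byte for byte, and the
test suite asserts this round trip, the involution of double allele
switching, and that the number of changed bases equals the number of
accepted catalog records.

An assumption worth stating: the package models an ambiguity character as
matching both alleles at zero penalty. Real aligners differ in how they
score ambiguity codes; the simulator (below) encodes the zero-penalty
idealisation, which is the upper bound of what masking can achieve.

## From reads to gene-level AEI

**Counting** (`count_alleles()`) piles up reads over each catalogued site
(via `Rsamtools`); a read contributes to `ref_count`, `var_count` or
`other_count` according to its base at the position, and reads with a
deletion or clipping there contribute to none. Defaults MAPQ ≥ 1 and base
quality ≥ 13 are ordinary pileup hygiene, configurable and logged; no
duplicate-read removal is applied.

**Filtering** (`filter_allelic_counts()`): a site is informative when
both alleles have ≥ 3 reads (so ≥ 6 informative reads) and the
lower-expressed allele is ≥ 5% of informative reads. Six reads is far too
few to call imbalance at a single SNP with statistical confidence; the
filter's purpose is to admit sites into *gene-level aggregation*, which is
where the error is attenuated. `other_count` is excluded from ratio
arithmetic throughout.

**Folding** (`allelic_ratio()`): haplotype phase is unknown and C/G and
A/T SNPs are strand-ambiguous, so the raw ratio `r = ref/var` is folded to
`10^|log10(r)| ≥ 1`. Numerically the package computes this as
`max(ref, var)/min(ref, var)`, which is the same quantity but makes
folding of reciprocal pairs bit-identical. Two SNPs of one gene at 2-fold
and 0.5-fold therefore both fold to 2 and combine to a 2-fold gene
estimate. The logit score `ln(max/min)` is carried alongside as the
predictor used by the logistic harness.

**Window merging** (`merge_snp_windows()`): SNPs within 100 bp likely sit
on the same library fragments and are not independent, so their folded
ratios are averaged into one observation. The clustering rule had to be
chosen (a window alone does not define clusters): greedy left-to-right,
anchored on the first SNP of the current cluster — a new cluster starts
when a site is more than `window_bp` from the anchor. It is deterministic
and order-independent given position-sorted input; sites at positions 10,
90, 180 with a 100-bp window cluster as {10, 90} and {180}.

**Combination** (`combine_gene_ratios()`): the gene × sample estimate is
the arithmetic mean of merged folded ratios, with the sample SD
(n − 1 denominator) and an equal-weight heterogeneity statistic
`Q = Σ(yᵢ − ȳ)²` over log10 folded ratios. Combining on the linear folded
scale (rather than averaging |log10| values and exponentiating) keeps the
gene estimate and the SD-based stringency rules on the same fold scale
that the calling thresholds are stated on; the |log10|-scale mean is
retained in `mean_log10` as a diagnostic. The Q statistic uses unit
weights because per-observation sampling variances are not modelled; it
is a dispersion index, not a calibrated chi-square, and is labelled as
such wherever it is reported.

**Calling** (`call_aei()`): three rules, all pure functions of
(`n_obs`, `mean_folded`, `sd_folded`):

| rule | default threshold | condition |
|---|---|---|
| permissive | 2.0 | `n_obs ≥ 2` and `mean ≥ 2` |
| stringent (2 SD) | 1.5 | `mean − 2·SD ≥ 1.5` |
| stringent (SD/3) | 2.0 | `SD ≤ mean/3` and `mean ≥ 2` |

Genes with one observation have no SD and are ineligible for the
stringent rules (returned `FALSE` with reason `ineligible_single_obs`);
the permissive rule excludes them by its `min_obs = 2` requirement. The
2-fold default on masked-alignment estimates is deliberately above the
1.5-fold level usually considered biologically meaningful, absorbing the
residual upward noise of low-depth ratio estimates. No multiple-testing
correction is applied anywhere: the thresholds are screening
configuration, not inference, and downstream confirmation is expected.

## Comparing correction methods

`compare_alignment_methods()` regresses |log10| folded ratios from a
corrected alignment on those from standard alignment (OLS, with
intercept — forcing the line through the origin would presume the
correction vanishes at balance, which is exactly what is under test).
`predict_fold()` evaluates the fitted line on the fold scale. The
logistic harness (`fit_aei_logistic()`) predicts orthogonally-confirmed
AEI from the logit score, optionally adding an
`extra-SNPs × logit` interaction-style term and the heterogeneity Q, and
compares feature sets by AIC; complete separation is detected (including
the silent-convergence case) and flagged with AIC reported unavailable.
The logit uses the natural log by default (`logit_base` is an argument).
`normalize_snapshot()` implements the cDNA/gDNA peak-ratio normalisation
of the SNaPshot assay: the heterozygote's genomic DNA is an intrinsic 1:1
standard, so dividing cancels dye and primer bias.

## The RNA-editing survey

Editing fractions are per-sample `edited/total`, with uncovered samples
(`total = 0`) excluded from means. A site is retained
(`filter_editing_sites()`) only if every condition shows at least
`min_support` samples with an edited read (defaults 5 of 10 brain
regions, 8 of 13 DLPFC samples, configurable per condition) and average
depth strictly greater than 10 reads. "% edited" is the mean of
per-sample fractions — not a pooled-count fraction — because the SEM
across samples is reported alongside it and both should describe the same
distribution.

Sites where essentially all samples express only the variant allele are
more plausibly reference errors than editing: `exclude_reference_errors()`
builds a t-interval on per-sample fractions (mean ± t·SEM at 95% by
default) and excludes the site when the upper bound reaches 100%. The
t-interval was chosen because the rule is about the distribution of
fractions across samples; a pooled-binomial interval would be dominated
by the deepest sample. With one covered sample the check is not evaluable
and the site is retained with a warning. Pseudogene/homology exclusion is
accepted as an input flag column (`homology_flag`), never computed —
homology search is out of scope.

Cross-condition comparison uses Pearson correlation of per-site mean
fractions (`editing_correlation()`) and, for variability, a paired
two-sided Wilcoxon signed-rank test on per-site SEMs
(`compare_editing_variability()`) — chosen for robustness at the dozen or
so sites these filters retain, with an F-type variance-ratio alternative
behind `method = "f"`. Identical SEM vectors return p = 1 directly, since
all-zero differences leave the signed-rank statistic undefined. The
packaged `brain_editing_sites()` table (12 sites, two conditions) is the
reference input for these statistics.

## The simulator and what it does (not) show

`simulate_counts()` / `simulate_reads()` implement a single-parameter
bias model: `total ~ Poisson(depth)` (or fixed), allele assignment with
`p_ref = r/(1+r)`, independent loss of each variant read with probability
`bias_beta`. Hence `E[observed ratio] ≈ true_ratio/(1 − β)`, a
closed-form oracle the tests assert within 2% at high depth.
`simulate_reads()` plants reads directly (no aligner), sharing the
allele and loss draws between modes so standard-mode variant counts are
pointwise ≤ masked-mode counts under one seed; `write_sam()` emits valid
plain-text SAM for the counting stage, and pileup recovers the planted
counts exactly. `simulate_editing_panel()` gives two conditions the same
true per-site fractions with binomial sampling, so their correlation
tends to 1 as depth grows.

Defaults are the package's reference conditions: `bias_beta = 0.33`
(the attenuation scale at which a 3-fold biased ratio corresponds to a
roughly 2-fold corrected one, since 2/(1 − 0.33) ≈ 3), depth 100 per
site (mid-range for well-expressed exonic SNPs), 1–4 SNPs per gene, and
an editing panel of 12 sites in conditions of 10 and 13 samples at depth
30, with true fractions set to the packaged brain panel levels. Site
layouts space SNPs at least three read lengths apart so each simulated
read covers exactly one site. All generators are pure functions of the
configuration: fixed seed, byte-identical output.

What passing these tests does **not** show: the simulator has no
sequencing errors, no splice junctions, no duplicated or homologous loci,
no mismatch-penalty alignment mechanics (loss is independent per read,
not a function of read quality or position), and no overdispersion beyond
Poisson/binomial sampling. Real data adds all of these; the simulator
validates the *arithmetic and plumbing* of the pipeline and the
*direction and magnitude* of the bias correction under an idealised
mechanism, not the behaviour of any particular aligner.

Test and acceptance runs use deliberately modest problem sizes — up to
200 sites at depth 500 for bias recovery, 100 logistic replicates at
n = 120, depth 10⁵ only for the asymptotic editing-correlation check —
sizes at which the asserted tolerances (e.g. 5% on mean ratio recovery)
are comfortably above Monte-Carlo noise.

## Numerical and degenerate-input choices

* Coordinates are 1-based internally; BED input is converted on read.
* FASTA output is uppercase at 60 columns.
* A catalog site beyond its chromosome end is an error (not skippable).
* Zero allele counts make a ratio undefined: `allelic_ratio()` errors and
  names the offending sites rather than producing infinities.
* `filter_allelic_counts()` is idempotent; boundary cases sit exactly on
  the stated thresholds ((3,3) passes; average editing depth 10.0 fails
  the strict "> 10").
* OLS with fewer than 3 pairs or zero x-variance errors; logistic fits
  need ≥ 10 labelled records and both label classes.
* Pipeline configuration rejects unknown keys, echoes every effective
  value into the run log, and stage failures name the stage.

## Limitations

* Gene annotation is simple interval overlap; a site in two genes' exons
  yields one observation per gene (flagged `multi_gene`), which
  double-counts reads across genes but keeps both genes measurable.
* The heterogeneity statistic is unweighted; with strongly varying site
  depths an inverse-variance weighting would discriminate better.
* Editing-site discovery is out of scope: only catalogued sites are
  quantified.
* The toolkit quantifies and screens; it does not assign statistical
  significance to individual gene calls, by design.
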