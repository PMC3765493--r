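# Allelic counting from alignments, site filters, annotation, window merging.

test_that("count_alleles tallies ref/var/other reads at a site", {
  # 10-bp reads over chr1; site at pos 5 (ref A, alt G)
  sam <- withr::local_tempfile(fileext = ".sam")
  mk_read <- function(base) paste0("CGTA", base, "CGTAC")
  reads <- tibble::tibble(
    pos = 1L, mapq = 60L, cigar = "10M",
    seq = c(rep(mk_read("A"), 5), rep(mk_read("G"), 3), mk_read("T"))
  )
  write_toy_sam(sam, chrom = "chr1", chrom_len = 100L, reads = reads)
  sites <- toy_sites(pos = 5, ref = "A", alt = "G")
  counts <- count_alleles(sam, sites, sample_id = "S1")
  expect_equal(counts$ref_count, 5L)
  expect_equal(counts$var_count, 3L)
  expect_equal(counts$other_count, 1L)
  expect_equal(counts$sample_id, "S1")
})

test_that("reads with deletions or clipping at the site contribute to no count", {
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- tibble::tibble(
    pos = c(1L, 1L, 1L, 6L),
    mapq = 60L,
    cigar = c("10M", "4M2D6M", "4M6S", "5M"),
    seq = c("CGTAACGTAC",        # covers pos 5 with A
            "CGTACGTACG",        # deletion spans pos 5-6
            "CGTACGTACG",        # clipped from pos 5 on
            "CGTAC")             # starts after pos 5
  )
  write_toy_sam(sam, chrom = "chr1", chrom_len = 100L, reads = reads)
  counts <- count_alleles(sam, toy_sites(pos = 5, ref = "A", alt = "G"), "S1")
  expect_equal(counts$ref_count + counts$var_count + counts$other_count, 1L)
})

test_that("uncovered sites give zeros and unknown chromosomes warn", {
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- tibble::tibble(pos = 1L, mapq = 60L, cigar = "10M",
                          seq = "CGTAACGTAC")
  write_toy_sam(sam, chrom = "chr1", chrom_len = 100L, reads = reads)
  sites <- toy_sites(chrom = c("chr1", "chr9"), pos = c(50, 5),
                     ref = c("A", "A"), alt = c("G", "G"))
  expect_warning(counts <- count_alleles(sam, sites, "S1"), "absent")
  expect_equal(counts$ref_count, c(0L, 0L))
  expect_equal(counts$var_count, c(0L, 0L))
})

test_that("count_alleles recovers planted counts from the simulator exactly", {
  cfg <- sim_config(n_genes = 5, snps_per_gene = c(1, 3), depth = 40,
                    bias_beta = 0.3, depth_model = "fixed", seed = 11)
  genome <- simulate_genome(cfg)
  for (mode in c("masked", "standard")) {
    reads <- simulate_reads(cfg, genome, mode = mode)
    sam <- withr::local_tempfile(fileext = ".sam")
    write_sam(reads, genome, sam)
    counts <- count_alleles(sam, attr(reads, "sites"), "S1")
    m <- dplyr::inner_join(counts, attr(reads, "truth"), by = "site_id",
                           suffix = c("_obs", "_true"))
    expect_equal(m$ref_count_obs, m$ref_count_true)
    expect_equal(m$var_count_obs, m$var_count_true)
    expect_true(all(m$other_count == 0))
  }
})

test_that("filter_allelic_counts applies the 3-reads-per-allele and 5% rules", {
  x <- toy_counts(ref = c(3, 10, 100, 6, 0), var = c(3, 0, 4, 100, 10))
  kept <- filter_allelic_counts(x)
  # (3,3) boundary retained; (10,0), (100,4) (4/104 < 5%) and (0,10)
  # removed; (6,100) passes the 5% rule (6/106 = 5.7%)
  expect_equal(kept$site_id, c("s1", "s4"))
  expect_equal(kept$ref_count[1], 3L)
  # idempotence and subset property
  expect_identical(filter_allelic_counts(kept), kept)
  expect_true(all(kept$site_id %in% x$site_id))
})

test_that("filter thresholds are configurable", {
  x <- toy_counts(ref = c(2, 10), var = c(2, 3))
  expect_equal(nrow(filter_allelic_counts(x, min_per_allele = 2)), 2L)
  expect_equal(nrow(filter_allelic_counts(x, min_per_allele = 2,
                                          min_minor_fraction = 0.5)), 1L)
})

test_that("annotate_sites assigns genes, duplicates multi-gene sites, classes orphans intergenic", {
  gi <- tibble::tibble(
    chrom = "chr1", start = c(100L, 150L, 500L), end = c(200L, 250L, 600L),
    gene = c("GENE1", "GENE2", "GENE3"),
    region_class = c("exonic", "exonic", "UTR")
  )
  sites <- toy_sites(pos = c(150, 50, 180, 550), ref = "A", alt = "G")
  expect_warning(ann <- annotate_sites(sites, gi), "more than one gene")
  at <- function(p) ann[ann$pos == p, ]
  expect_equal(sort(at(150)$gene), c("GENE1", "GENE2"))
  expect_true(all(at(150)$multi_gene))
  expect_equal(at(180)$gene, c("GENE1", "GENE2"))
  expect_equal(at(50)$region_class, "intergenic")
  expect_equal(at(550)$region_class, "UTR")
  # only exonic/UTR proceed to ratio analysis
  expect_false(50 %in% exonic_sites(ann)$pos)
  expect_true(550 %in% exonic_sites(ann)$pos)
})

test_that("merge_snp_windows clusters greedily anchored on the first site", {
  obs <- tibble::tibble(
    gene = "G1", sample_id = "S1", chrom = "chr1",
    pos = c(10, 90, 180), site_id = c("a", "b", "c"),
    folded_ratio = c(2, 3, 4)
  )
  m <- merge_snp_windows(obs, window_bp = 100)
  # 90 - 10 <= 100 joins the first cluster; 180 - 10 > 100 starts a new one
  expect_equal(nrow(m), 2L)
  expect_equal(m$pos, c(10, 180))
  expect_equal(m$folded_ratio, c(2.5, 4))
  expect_equal(m$n_sites, c(2L, 1L))

  # two sites within a window average; far sites stay separate
  near <- merge_snp_windows(obs[obs$pos %in% c(10, 90), ][, ], 100)
  expect_equal(near$folded_ratio, 2.5)
  far <- merge_snp_windows(
    dplyr::mutate(obs[1:2, ], pos = c(10, 200)), 100
  )
  expect_equal(nrow(far), 2L)
})

test_that("merging never increases observations and preserves equal-size means", {
  set.seed(3)
  obs <- tibble::tibble(
    gene = "G1", sample_id = "S1", chrom = "chr1",
    pos = sort(sample(1:2000, 30)),
    folded_ratio = runif(30, 1, 4)
  )
  m <- merge_snp_windows(obs, 100)
  expect_lte(nrow(m), nrow(obs))
  # pairs exactly 50 bp apart -> all clusters size 2 -> grand mean preserved
  paired <- tibble::tibble(
    gene = "G1", sample_id = "S1", chrom = "chr1",
    pos = as.vector(rbind(seq(1, by = 1000, length.out = 10),
                          seq(51, by = 1000, length.out = 10))),
    folded_ratio = runif(20, 1, 4)
  )
  pm <- merge_snp_windows(paired, 100)
  expect_equal(pm$n_sites, rep(2L, 10))
  expect_equal(mean(pm$folded_ratio), mean(paired$folded_ratio))
})
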