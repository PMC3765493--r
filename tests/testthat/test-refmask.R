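test_that("iupac_code maps every unordered base pair to its ambiguity letter", {
  expect_equal(iupac_code("A", "G"), "R")
  expect_equal(iupac_code("C", "T"), "Y")
  expect_equal(iupac_code("C", "G"), "S")
  expect_equal(iupac_code("A", "T"), "W")
  expect_equal(iupac_code("G", "T"), "K")
  expect_equal(iupac_code("A", "C"), "M")
  # symmetry over all 6 pairs, vectorized, case-insensitive
  pairs <- t(combn(c("A", "C", "G", "T"), 2))
  expect_equal(iupac_code(pairs[, 1], pairs[, 2]),
               iupac_code(pairs[, 2], pairs[, 1]))
  expect_equal(iupac_code("a", "g"), "R")
  expect_error(iupac_code("A", "A"), "identical")
  expect_error(iupac_code("A", "N"), "non-ACGT")
})

test_that("mask_reference substitutes exactly the catalogued positions", {
  g <- toy_genome()
  masked <- mask_reference(g, toy_sites(pos = 4, ref = "T", alt = "C"))
  expect_equal(as.character(masked), c(chr1 = "ACGYACGTAC"))
  expect_equal(S4Vectors::metadata(masked)$provenance, "iupac_masked")

  two <- mask_reference(g, toy_sites(pos = c(2, 7), ref = c("C", "G"),
                                     alt = c("T", "A")))
  expect_equal(as.character(two), c(chr1 = "AYGTACRTAC"))
  expect_equal(S4Vectors::metadata(two)$n_edited, 2L)
})

test_that("masking an empty catalog is the identity", {
  g <- toy_genome()
  masked <- mask_reference(g, toy_sites(pos = integer(0), ref = character(0),
                                        alt = character(0)))
  expect_equal(as.character(masked), as.character(g))
  expect_equal(nrow(masking_audit(masked)), 0L)
})

test_that("ref-mismatch sites are skipped with a warning and audited; strict aborts", {
  g <- toy_genome()
  sites <- toy_sites(pos = c(4, 5), ref = c("T", "C"), alt = c("C", "G"))
  # genome base at pos 5 is A, catalog claims C
  expect_warning(masked <- mask_reference(g, sites), "disagrees")
  expect_equal(as.character(masked), c(chr1 = "ACGYACGTAC"))
  audit <- masking_audit(masked)
  expect_equal(nrow(audit), 1L)
  expect_equal(audit$pos, 5L)
  expect_equal(audit$genome_base, "A")
  expect_equal(audit$reason, "ref_mismatch")
  expect_error(mask_reference(g, sites, strict = TRUE), "disagrees")
})

test_that("a site beyond the chromosome end is an error", {
  expect_error(
    mask_reference(toy_genome(), toy_sites(pos = 11, ref = "A", alt = "G")),
    "outside"
  )
})

test_that("masking then resolving ambiguity codes reproduces the genome byte for byte", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  g <- Biostrings::DNAStringSet(c(chrA = seq))
  pos <- sort(sample(500, 40))
  ref <- substring(seq, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  sites <- toy_sites(chrom = "chrA", pos = pos, ref = ref, alt = unname(alt))

  masked <- mask_reference(g, sites)
  # changed-base count equals accepted catalog size
  diffs <- which(strsplit(as.character(masked), "")[[1]] !=
                   strsplit(seq, "")[[1]])
  expect_equal(diffs, pos)
  # each masked letter covers exactly ref and alt
  expect_equal(substring(as.character(masked), pos, pos),
               iupac_code(sites$ref, sites$alt))
  restored <- resolve_to_reference(masked, sites)
  expect_equal(as.character(restored), as.character(g))
})

test_that("switch_alleles plants the variant base and is an involution", {
  g <- toy_genome()
  s <- toy_sites(pos = 4, ref = "T", alt = "C")
  switched <- switch_alleles(g, s)
  expect_equal(as.character(switched), c(chr1 = "ACGCACGTAC"))
  expect_equal(S4Vectors::metadata(switched)$provenance, "allele_switched")
  # empty target list is the identity
  empty <- switch_alleles(g, s[0, ])
  expect_equal(as.character(empty), as.character(g))
  # switching back with ref/alt swapped restores the original
  back <- switch_alleles(switched, toy_sites(pos = 4, ref = "C", alt = "T"))
  expect_equal(as.character(back), as.character(g))
})

test_that("switch involution holds on random toy genomes", {
  set.seed(99)
  for (i in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
    g <- Biostrings::DNAStringSet(c(chr = seq))
    pos <- sort(sample(200, 15))
    ref <- substring(seq, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    s <- toy_sites(chrom = "chr", pos = pos, ref = ref, alt = unname(alt))
    round <- switch_alleles(
      switch_alleles(g, s),
      toy_sites(chrom = "chr", pos = pos, ref = unname(alt), alt = ref)
    )
    expect_equal(as.character(round), as.character(g))
  }
})

test_that("FASTA output round-trips at 60-column width", {
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(c(chrZ = seq))
  path <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, path)
  lines <- readLines(path)
  expect_equal(lines[1], ">chrZ")
  expect_true(all(nchar(lines[2:3]) == 60))
  expect_equal(as.character(read_genome_fasta(path)), c(chrZ = seq))
})
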