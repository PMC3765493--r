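# Small in-code fixtures shared across test files.

toy_genome <- function(seqs = c(chr1 = "ACGTACGTAC")) {
  Biostrings::DNAStringSet(seqs)
}

toy_sites <- function(chrom = "chr1", pos, ref, alt, ...) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, ...)
}

# counts table ready for allelic_ratio()
toy_counts <- function(ref, var, gene = "G1", sample_id = "S1",
                       chrom = "chr1", pos = seq_along(ref) * 1000L) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    site_id = paste0("s", seq_along(ref)),
    gene = gene, sample_id = sample_id,
    ref_count = as.integer(ref), var_count = as.integer(var),
    other_count = 0L
  )
}

# hand-written SAM with reads planted over one site
write_toy_sam <- function(path, chrom = "chr1", chrom_len = 100L, reads) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    sprintf("r%03d\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            i, chrom, r$pos, r$mapq, r$cigar, r$seq, strrep("I", nchar(r$seq)))
  }, "")
  writeLines(c(header, body), path)
  path
}
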