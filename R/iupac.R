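#' Two-base IUPAC ambiguity code for a biallelic SNP
#'
#' Maps an unordered pair of distinct canonical bases to the single-letter
#' IUPAC ambiguity character that represents exactly those two bases
#' (R = A/G, Y = C/T, S = C/G, W = A/T, K = G/T, M = A/C). The code is
#' symmetric in its arguments, so `iupac_code("A", "G")` and
#' `iupac_code("G", "A")` both return `"R"`.
#'
#' @param ref_base,alt_base Character vectors of single bases in
#'   `A`/`C`/`G`/`T` (case-insensitive). Recycled to a common length.
#' @return A character vector of ambiguity codes.
#' @examples
#' iupac_code("A", "G")
#' iupac_code(c("C", "C"), c("T", "G"))
#' @export
iupac_code <- function(ref_base, alt_base) {
  ref <- toupper(as.character(ref_base))
  alt <- toupper(as.character(alt_base))
  if (length(ref) != length(alt)) {
    n <- max(length(ref), length(alt))
    ref <- rep_len(ref, n)
    alt <- rep_len(alt, n)
  }
  bad <- !(ref %in% DNA_BASES_) | !(alt %in% DNA_BASES_)
  if (any(bad)) {
    abort(sprintf(
      "non-ACGT base in pair(s): %s",
      paste(unique(paste0(ref[bad], "/", alt[bad])), collapse = ", ")
    ))
  }
  same <- ref == alt
  if (any(same)) {
    abort(sprintf(
      "ref and alt alleles are identical (%s); a SNP needs two distinct bases",
      paste(unique(ref[same]), collapse = ", ")
    ))
  }
  key <- ifelse(ref < alt, paste0(ref, alt), paste0(alt, ref))
  unname(IUPAC_PAIRS_[key])
}

DNA_BASES_ <- c("A", "C", "G", "T")

IUPAC_PAIRS_ <- c(
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M"
)

# Inverse map: ambiguity letter -> the two bases it covers.
IUPAC_EXPAND_ <- setNames(names(IUPAC_PAIRS_), IUPAC_PAIRS_)
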