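BASES <- c("A", "C", "G", "T")

#' Diploid genotypes over the four DNA bases
#'
#' All ten unordered allele pairs, in the canonical `"X/Y"` notation used
#' throughout the package (alleles sorted alphabetically, so a C/A
#' heterozygote is written `"A/C"`).
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' diploid_genotypes()
diploid_genotypes <- function() {
  pairs <- expand.grid(a1 = BASES, a2 = BASES, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a1 <= pairs$a2, ]
  paste(pairs$a1, pairs$a2, sep = "/")
}

#' Build a canonical genotype string from two alleles
#'
#' @param a1,a2 Single-character allele vectors (recycled).
#' @return Character vector of `"X/Y"` genotypes with alleles sorted.
#' @export
genotype_string <- function(a1, a2) {
  stopifnot(all(a1 %in% BASES), all(a2 %in% BASES))
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

## split "X/Y" genotypes into a two-column character matrix
gt_alleles <- function(genotype) {
  parts <- strsplit(genotype, "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    abort(paste0("malformed genotype string: ", genotype[bad][1]))
  }
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  if (!all(m %in% BASES)) {
    abort("genotype alleles must be one of A, C, G, T")
  }
  m
}

## Watson-Crick complement
complement_base <- function(x) chartr("ACGT", "TGCA", x)

## genotype from an alt-allele dosage at a C reference site
genotype_from_dosage <- function(dosage, alt) {
  stopifnot(all(dosage %in% 0:2))
  out <- character(length(dosage))
  out[dosage == 0] <- "C/C"
  out[dosage == 1] <- genotype_string(rep("C", sum(dosage == 1)), alt[dosage == 1])
  out[dosage == 2] <- genotype_string(alt[dosage == 2], alt[dosage == 2])
  out
}

is_heterozygous <- function(genotype) {
  al <- gt_alleles(genotype)
  al[, 1] != al[, 2]
}
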