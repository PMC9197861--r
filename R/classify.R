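#' Allele call for clone genotyping
#'
#' @param signature Canonical signature string, or "REF" for an unmodified
#'   allele.
#' @param strain Strain of origin at a heterozygous locus: "BL6", "CAST" or
#'   "unassigned" (lesion erased the informative SNPs, or locus not
#'   informative).
#' @param read_count Supporting reads.
#' @return An object of class `allele_call` with a derived `frame_effect`.
#' @export
allele_call <- function(signature, strain = "unassigned", read_count = NA_integer_) {
  stopifnot(is.character(signature), length(signature) == 1L,
            strain %in% c("BL6", "CAST", "unassigned"))
  fe <- if (identical(signature, "REF")) "reference" else frame_effect(signature)
  structure(list(signature = signature, strain = strain,
                 read_count = read_count, frame_effect = fe),
            class = "allele_call")
}

#' Classify a clone genotype as perfect, in-frame or good
#'
#' Screen admission rules for NGS-validated knockout clones:
#' \describe{
#'   \item{perfect}{all detectable alleles are frame-disrupting and, where the
#'     locus carries strain-informative SNPs, there are exactly two alleles,
#'     one BL6 and one CAST. Very likely a functional null.}
#'   \item{in-frame}{any allele likely to remain functional: an unmodified
#'     allele or a frame-preserving indel smaller than 30 bp.}
#'   \item{good}{everything else - more than two alleles, a single allele at
#'     a locus without informative SNPs, in-frame deletions of 30 bp or
#'     larger (likely deleterious), or frame-disrupting alleles that could
#'     not be assigned to a strain.}
#' }
#'
#' @param alleles List of `allele_call` (at least one).
#' @param snp_informative Does the locus carry strain-distinguishing SNPs?
#' @return `"perfect"`, `"in-frame"` or `"good"`.
#' @export
classify_clone <- function(alleles, snp_informative = TRUE) {
  if (!is.list(alleles) || length(alleles) == 0L) {
    stop("at least one allele call is required")
  }
  stopifnot(all(vapply(alleles, inherits, logical(1), "allele_call")))
  sizes <- vapply(alleles, function(a) {
    if (identical(a$signature, "REF")) 0L else {
      abs(signed_size(a$signature))
    }
  }, integer(1))
  frames <- vapply(alleles, `[[`, character(1), "frame_effect")
  preserving <- frames %in% c("in-frame", "reference")

  if (any(preserving & sizes < 30L)) return("in-frame")
  if (any(preserving)) return("good") # in-frame indel >= 30 bp

  # all alleles frame-disrupting
  strains <- vapply(alleles, `[[`, character(1), "strain")
  if (length(alleles) == 2L) {
    if (snp_informative) {
      if (setequal(strains, c("BL6", "CAST"))) return("perfect")
      return("good") # strain-unassignable at an informative locus
    }
    return("perfect") # strain requirement not applicable
  }
  "good" # single allele at a non-informative locus, or > 2 alleles
}
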