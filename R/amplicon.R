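#' Amplicon target with an annotated Cas9 cut site
#'
#' @param id Target identifier.
#' @param sequence Uppercase ACGT string.
#' @param guide_start 0-based start of the 20 nt protospacer.
#' @param pam_strand "+" or "-": strand carrying the NGG PAM.
#' @param cut_index 0-based position of the first base 3' of the blunt cut.
#'   Cas9 cuts between the 3rd and 4th nucleotide 5' of the PAM on the
#'   annotated strand.
#' @param min_flank Minimum bases required on each side of the cut (the short
#'   amplicon must leave room for deletions and primer annealing).
#' @return An object of class `amplicon_target`.
#' @export
amplicon_target <- function(id, sequence, guide_start, pam_strand, cut_index,
                            min_flank = 40L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (grepl("[^ACGT]", sequence)) stop("sequence must be uppercase ACGT only")
  n <- nchar(sequence)
  cut_index <- as.integer(cut_index)
  if (cut_index < min_flank || n - cut_index < min_flank) {
    stop("cut_index leaves less than ", min_flank, " bp flank on one side")
  }
  stopifnot(pam_strand %in% c("+", "-"))
  if (pam_strand == "+") {
    pam <- substr(sequence, cut_index + 5L, cut_index + 6L)
    if (pam != "GG") stop("no NGG PAM at the expected position (+ strand): ",
                          "cut must fall 3 bp 5' of the PAM")
  } else {
    pam <- substr(sequence, cut_index - 5L, cut_index - 4L)
    if (pam != "CC") stop("no NGG PAM at the expected position (- strand)")
  }
  structure(
    list(id = id, sequence = sequence, guide_start = as.integer(guide_start),
         pam_strand = pam_strand, cut_index = cut_index, length = n),
    class = "amplicon_target"
  )
}

#' @export
print.amplicon_target <- function(x, ...) {
  cat("<amplicon_target> ", x$id, ": ", x$length, " bp, cut at ", x$cut_index,
      " (PAM strand ", x$pam_strand, ")\n", sep = "")
  invisible(x)
}

#' Generate a random amplicon with a valid cut-site annotation
#'
#' Draws a random sequence at the requested GC content and stamps a
#' protospacer + NGG PAM so that the blunt cut falls mid-amplicon, between
#' the 3rd and 4th nucleotide 5' of the PAM, with at least 40 bp of flank on
#' each side. Typical short-range Cas9 amplicons are 244-283 bp.
#'
#' @param length Amplicon length in bp (200-400).
#' @param gc GC fraction in \[0.2, 0.8\].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return An `amplicon_target`.
#' @export
#' @examples
#' amp <- generate_amplicon(283, 0.5, seed = 1)
#' amp$length
generate_amplicon <- function(length, gc = 0.5, seed = 1L) {
  if (length < 200 || length > 400) {
    stop("length must be in [200, 400] bp (got ", length, ")")
  }
  if (gc < 0.2 || gc > 0.8) stop("gc must be in [0.2, 0.8]")
  cut_index <- as.integer(length %/% 2L)
  if (cut_index < 40L || length - cut_index < 40L) {
    stop("length ", length, " too short to leave 40 bp flanks around the cut")
  }
  with_stream(seed, "amplicon", {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(probs), length, replace = TRUE, prob = probs)
    # PAM starts 3 bp 3' of the cut on the + strand; force the GG.
    pam_start <- cut_index + 3L
    bases[pam_start + 2L] <- "G" # 0-based pam_start+1
    bases[pam_start + 3L] <- "G" # 0-based pam_start+2
    amplicon_target(
      id = sprintf("amp_len%d_seed%d", length, as.integer(seed)),
      sequence = paste(bases, collapse = ""),
      guide_start = pam_start - 20L,
      pam_strand = "+",
      cut_index = cut_index
    )
  })
}
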