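#' Microhomology and canonical placement of a deletion
#'
#' A deletion flanked by repeated sequence can be placed at several positions
#' that all yield the same mutant molecule; the shared flanking sequence is
#' the microhomology (MH). For the deletion of `sequence[start:end)` (0-based,
#' half-open) the MH length is `l + r`, where `r` is the longest common prefix
#' of the suffixes starting at `start` and `end`, and `l` the longest common
#' suffix of the prefixes ending before `start` and `end`. `mh + 1` equals the
#' number of equivalent same-size placements.
#'
#' The canonical representation is the maximal ambiguity interval: `left` is
#' the 0-based index of the last unmodified base before the leftmost
#' equivalent placement (-1 if none), `right` the index of the first
#' unmodified base after the rightmost placement (`nchar(sequence)` if none),
#' so that `right - left - 1 == (end - start) + mh`.
#'
#' @param sequence Reference sequence (character scalar, ACGT).
#' @param start,end 0-based half-open interval of the deleted bases.
#' @return List with elements `mh`, `left`, `right` (0-based reference
#'   indices of the ambiguity-interval boundaries).
#' @export
#' @examples
#' deletion_microhomology("TTAGCAGCTT", 2, 5) # mh 3
deletion_microhomology <- function(sequence, start, end) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (!(start >= 0 && start < end && end <= n)) {
    stop("deletion interval [", start, ",", end, ") out of bounds or empty ",
         "for sequence of length ", n)
  }
  s <- charToRaw(sequence)
  # r: extend to the right while base after the interval matches base at start
  r <- 0L
  while (end + r + 1L <= n && s[start + r + 1L] == s[end + r + 1L]) r <- r + 1L
  # l: extend to the left while base before the interval matches base at end-1
  l <- 0L
  while (start - l >= 1L && s[start - l] == s[end - l]) l <- l + 1L
  list(mh = l + r, left = start - l - 1L, right = end + r)
}

#' Microhomology of an insertion
#'
#' The inserted sequence may match the reference flank on either side of the
#' insertion point (a "templated" insertion). MH is the larger of the longest
#' suffix of the left flank that is also a suffix of the insert, and the
#' longest prefix of the right flank that is also a prefix of the insert;
#' it never exceeds the insert length. When both flanks match, the maximum is
#' taken (the tie rule is a package convention).
#'
#' @param sequence Reference sequence (character scalar).
#' @param pos 0-based position the insert is placed before.
#' @param ins Inserted sequence (non-empty character scalar).
#' @return Integer MH length, `0 <= mh <= nchar(ins)`.
#' @export
insertion_microhomology <- function(sequence, pos, ins) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(ins), length(ins) == 1L, nzchar(ins))
  n <- nchar(sequence)
  stopifnot(pos >= 0, pos <= n)
  s <- charToRaw(sequence)
  b <- charToRaw(ins)
  k <- length(b)
  left <- 0L
  while (left < k && pos - left >= 1L && s[pos - left] == b[k - left]) {
    left <- left + 1L
  }
  right <- 0L
  while (right < k && pos + right + 1L <= n && s[pos + right + 1L] == b[right + 1L]) {
    right <- right + 1L
  }
  max(left, right)
}

# Left-canonical placement of an insertion: while the last inserted base
# equals the reference base just left of the insertion point, rotate the
# insert and shift the point left. All equivalent placements of the same
# insert then map to one (pos, ins) pair.
canonical_insertion <- function(sequence, pos, ins) {
  s <- charToRaw(sequence)
  b <- charToRaw(ins)
  k <- length(b)
  while (pos >= 1L && s[pos] == b[k]) {
    b <- c(b[k], b[-k])
    pos <- pos - 1L
  }
  list(pos = pos, ins = rawToChar(b))
}
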