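#' Canonical microhomology-annotated indel signature
#'
#' A signature encodes one indel event in cut-relative coordinates: the base
#' immediately 5' of the Cas9 blunt cut is position -1, the base immediately
#' 3' of it is position 0 (no position is skipped across the cut). `left` is
#' the last unmodified base left of the maximal ambiguity interval, `right`
#' the first unmodified base right of it. For a pure deletion
#' `right - left - 1 == size + mh`; for a pure insertion the interval is the
#' bare junction (`right - left - 1 == 0`) and `mh <= size`. Compound events
#' (deletion plus insertion at one junction) carry the deleted-span boundaries
#' with `size` equal to the net length change and MH computed on the deleted
#' span only.
#'
#' @param kind "D" (net-deleting) or "I" (net-inserting).
#' @param size Positive integer, the magnitude of the net length change.
#' @param left,right Cut-relative ambiguity-interval boundaries.
#' @param mh Non-negative integer microhomology length.
#' @param inserted_seq Inserted bases, if any ("" for a pure deletion).
#' @param compound Logical; TRUE when the event mixes deleted and inserted
#'   bases, which relaxes the pure-event boundary invariants.
#' @return An object of class `indel_signature`.
#' @seealso [parse_signature()], [format_signature()]
#' @export
indel_signature <- function(kind, size, left, right, mh,
                            inserted_seq = "", compound = FALSE) {
  stopifnot(kind %in% c("D", "I"))
  size <- as.integer(size); left <- as.integer(left)
  right <- as.integer(right); mh <- as.integer(mh)
  if (is.na(size) || size < 1L) stop("size must be a positive integer")
  if (mh < 0L) stop("mh must be non-negative")
  if (right <= left) stop("right boundary must exceed left boundary")
  if (!compound) {
    if (kind == "D") {
      if (right - left - 1L != size + mh) {
        stop("deletion invariant violated: right - left - 1 (",
             right - left - 1L, ") != size + mh (", size + mh, ")")
      }
    } else {
      if (right - left - 1L != 0L) {
        stop("insertion invariant violated: right - left - 1 must be 0")
      }
      if (mh > size) stop("insertion mh cannot exceed its size")
      if (nchar(inserted_seq) != size) {
        stop("inserted_seq length must equal size for a pure insertion")
      }
    }
  }
  structure(
    list(kind = kind, size = size, left = left, right = right, mh = mh,
         inserted_seq = inserted_seq, compound = isTRUE(compound)),
    class = "indel_signature"
  )
}

#' @export
print.indel_signature <- function(x, ...) {
  cat(format_signature(x),
      if (x$compound) " (compound)" else "", "\n", sep = "")
  invisible(x)
}

#' Format an indel signature as its canonical string
#'
#' The canonical form is `"{D|I}{size}_L{left}C{mh}R{right}"`, e.g.
#' `"D10_L-13C2R0"`: a 10 bp deletion whose last unmodified bases sit 13 left
#' of the cut and at the cut, with 2 bp of microhomology mappable at either
#' end of the interval.
#'
#' @param sig An `indel_signature`.
#' @return Character scalar; `parse_signature(format_signature(s))`
#'   reproduces `s` for pure events.
#' @export
format_signature <- function(sig) {
  stopifnot(inherits(sig, "indel_signature"))
  sprintf("%s%d_L%dC%dR%d", sig$kind, sig$size, sig$left, sig$mh, sig$right)
}

#' Parse a canonical signature string
#'
#' @param text Character scalar such as `"D10_L-13C2R0"`.
#' @return An `indel_signature`. Malformed input raises an error naming the
#'   offending field.
#' @export
#' @examples
#' parse_signature("D10_L-13C2R0")
parse_signature <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^([A-Za-z])([0-9]+)_L(-?[0-9]+)C([0-9]+)R(-?[0-9]+)$", text))[[1]]
  if (length(m) == 0L) {
    if (!grepl("^[DI]", text)) stop("bad signature kind in '", text,
                                    "': must start with D or I")
    if (!grepl("^[DI][0-9]+_", text)) stop("bad size field in '", text, "'")
    if (!grepl("_L-?[0-9]+", text)) stop("bad left (L) field in '", text, "'")
    if (!grepl("C[0-9]+", text)) stop("bad microhomology (C) field in '",
                                      text, "'")
    stop("bad right (R) field in '", text, "'")
  }
  if (!m[2] %in% c("D", "I")) stop("bad signature kind '", m[2],
                                   "': must be D or I")
  indel_signature(kind = m[2], size = as.integer(m[3]),
                  left = as.integer(m[4]), right = as.integer(m[6]),
                  mh = as.integer(m[5]),
                  inserted_seq = if (m[2] == "I") strrep("N", as.integer(m[3]))
                                 else "")
}

#' Reading-frame effect of an indel
#'
#' The net length change (-size for deletions, +size for insertions) decides
#' the frame: a multiple of 3 preserves it, anything else disrupts it.
#'
#' @param sig An `indel_signature` or a canonical signature string.
#' @return `"in-frame"` or `"frameshift"`.
#' @export
frame_effect <- function(sig) {
  if (is.character(sig)) sig <- parse_signature(sig)
  stopifnot(inherits(sig, "indel_signature"))
  net <- if (sig$kind == "D") -sig$size else sig$size
  if (net %% 3L == 0L) "in-frame" else "frameshift"
}

# Signed size of a signature string vector: deletions negative, insertions
# positive. Vectorized; used by profile summaries.
signed_size <- function(signatures) {
  kind <- substr(signatures, 1L, 1L)
  size <- as.integer(sub("^[DI]([0-9]+)_.*$", "\\1", signatures))
  ifelse(kind == "D", -size, size)
}

# MH length parsed from a signature string vector.
signature_mh <- function(signatures) {
  as.integer(sub("^.*C([0-9]+)R.*$", "\\1", signatures))
}
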