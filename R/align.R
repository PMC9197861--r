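#' Canonical signature of an aligned indel event
#'
#' Converts a raw indel event in reference coordinates (0-based, half-open)
#' into its canonical, cut-relative, microhomology-annotated signature.
#' Deletions are canonicalized to the maximal ambiguity interval via
#' [deletion_microhomology()]; insertions are left-aligned first and their MH
#' computed via [insertion_microhomology()]. Compound events (deleted span
#' plus inserted bases at one junction) take kind and size from the net
#' length change, with MH and boundaries computed on the deleted span only;
#' a length-neutral compound event has no net indel and returns `NULL`.
#'
#' @param event List with `ref_start`, `ref_end` (0-based half-open deleted
#'   interval; equal for a pure insertion) and `ins` (inserted bases, "" for
#'   a pure deletion).
#' @param amplicon An `amplicon_target` supplying the sequence and cut site.
#' @return An `indel_signature`, or `NULL` for a length-neutral event.
#' @export
to_signature <- function(event, amplicon) {
  stopifnot(inherits(amplicon, "amplicon_target"))
  seq <- amplicon$sequence
  cut <- amplicon$cut_index
  s <- as.integer(event$ref_start)
  e <- as.integer(event$ref_end)
  ins <- if (is.null(event$ins) || is.na(event$ins)) "" else event$ins
  del <- e - s
  net <- nchar(ins) - del

  if (del > 0L && nchar(ins) == 0L) { # pure deletion
    can <- deletion_microhomology(seq, s, e)
    return(indel_signature("D", del, can$left - cut, can$right - cut, can$mh))
  }
  if (del == 0L && nchar(ins) > 0L) { # pure insertion
    can <- canonical_insertion(seq, s, ins)
    mh <- insertion_microhomology(seq, can$pos, can$ins)
    return(indel_signature("I", nchar(ins), can$pos - 1L - cut,
                           can$pos - cut, mh, inserted_seq = can$ins))
  }
  if (del == 0L && nchar(ins) == 0L) stop("empty event")
  if (net == 0L) return(NULL)
  can <- deletion_microhomology(seq, s, e)
  indel_signature(if (net < 0L) "D" else "I", abs(net),
                  can$left - cut, can$right - cut, can$mh,
                  inserted_seq = ins, compound = TRUE)
}

# Extract indel events from one pair of gapped alignment strings
# (pattern = read, subject = reference). Returns a data.frame of events in
# 0-based half-open reference coordinates; adjacent deletion/insertion runs
# at one junction are merged into a compound event.
alignment_events <- function(pat, sub) {
  p <- strsplit(pat, "", fixed = TRUE)[[1]]
  s <- strsplit(sub, "", fixed = TRUE)[[1]]
  gap_p <- p == "-" # deletion relative to reference
  gap_s <- s == "-" # insertion relative to reference
  state <- integer(length(p)) # 0 match col, 1 del, 2 ins
  state[gap_p] <- 1L
  state[gap_s] <- 2L
  refpos <- cumsum(!gap_s) # reference position AFTER this column (1-based)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- list()
  i <- 1L
  nruns <- length(r$values)
  while (i <= nruns) {
    if (r$values[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < nruns && r$values[j + 1L] != 0L) j <- j + 1L
    cols <- starts[i]:ends[j]
    del_cols <- cols[state[cols] == 1L]
    ins_cols <- cols[state[cols] == 2L]
    if (length(del_cols)) {
      ref_start <- refpos[del_cols[1L]] - 1L
      ref_end <- refpos[del_cols[length(del_cols)]]
    } else {
      ref_start <- refpos[cols[1L]] # pure insertion point (0-based)
      ref_end <- ref_start
    }
    ev[[length(ev) + 1L]] <- data.frame(
      ref_start = ref_start, ref_end = ref_end,
      ins = paste(p[ins_cols], collapse = ""),
      stringsAsFactors = FALSE)
    i <- j + 1L
  }
  if (!length(ev)) {
    return(data.frame(ref_start = integer(), ref_end = integer(),
                      ins = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, ev)
}

#' Align reads to an amplicon and extract indel events
#'
#' Global (end-to-end) alignment with affine gap penalties (match +2,
#' mismatch -2, gap open -6, gap extend -0.5), delegated to
#' [Biostrings::pairwiseAlignment()]. Identical reads are aligned once.
#' Reads shorter than 30 nt or aligning with under `min_identity` identity
#' are flagged unalignable and carry no events. Raw gap placement from the
#' aligner is irrelevant downstream: [to_signature()] canonicalizes every
#' event to its maximal ambiguity interval.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] (names kept).
#' @param amplicon An `amplicon_target`.
#' @param min_identity Minimum fraction of matching columns (default 0.6).
#' @return List with one element per read: list of `events` (data.frame in
#'   0-based half-open reference coordinates) and `alignable` flag.
#' @export
align_read <- function(reads, amplicon, min_identity = 0.6) {
  stopifnot(inherits(amplicon, "amplicon_target"))
  seqs <- as.character(reads)
  nms <- names(seqs)
  uniq <- unique(seqs)
  short <- nchar(uniq) < 30L
  res_uniq <- vector("list", length(uniq))
  names(res_uniq) <- uniq
  for (u in uniq[short]) {
    res_uniq[[u]] <- list(events = alignment_events("", ""), alignable = FALSE)
  }
  todo <- uniq[!short]
  if (length(todo)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -2, baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(todo),
      subject = Biostrings::DNAString(amplicon$sequence),
      type = "global", substitutionMatrix = mat,
      gapOpening = 6, gapExtension = 0.5)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    for (k in seq_along(todo)) {
      pa <- ap[k]; su <- as_[k]
      pc <- strsplit(pa, "", fixed = TRUE)[[1]]
      sc <- strsplit(su, "", fixed = TRUE)[[1]]
      ident <- sum(pc == sc & pc != "-") / length(pc)
      if (ident < min_identity) {
        res_uniq[[todo[k]]] <- list(events = alignment_events("", ""),
                                    alignable = FALSE)
      } else {
        res_uniq[[todo[k]]] <- list(events = alignment_events(pa, su),
                                    alignable = TRUE)
      }
    }
  }
  out <- res_uniq[seqs]
  names(out) <- nms
  out
}

#' Call canonical indel signatures for a read set
#'
#' Runs [align_read()] and [to_signature()] over a read set and returns one
#' call per read. Substitution-only reads are called `REF`; unalignable reads
#' are flagged and excluded from profiles. Reads with several separate indels
#' are classified by the event nearest the cut (the assay's signatures are
#' single-event); the others are counted in `n_events`.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet].
#' @param amplicon An `amplicon_target`.
#' @param min_identity Passed to [align_read()].
#' @return data.frame with columns `read_id`, `signature` ("REF",
#'   "unalignable", or a canonical signature), `mh`, `frame`, `n_events`.
#' @export
call_reads <- function(reads, amplicon, min_identity = 0.6) {
  seqs <- as.character(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  aligned <- align_read(seqs, amplicon, min_identity = min_identity)
  cut <- amplicon$cut_index

  call_one <- function(a) {
    if (!a$alignable) {
      return(list(signature = "unalignable", mh = NA_integer_,
                  frame = NA_character_, n_events = 0L))
    }
    ev <- a$events
    if (nrow(ev) == 0L) {
      return(list(signature = "REF", mh = 0L, frame = "reference",
                  n_events = 0L))
    }
    if (nrow(ev) > 1L) {
      mid <- (ev$ref_start + ev$ref_end) / 2
      ev <- ev[which.min(abs(mid - cut)), , drop = FALSE]
    }
    sig <- to_signature(as.list(ev[1L, ]), amplicon)
    if (is.null(sig)) {
      return(list(signature = "REF", mh = 0L, frame = "reference",
                  n_events = nrow(a$events)))
    }
    list(signature = format_signature(sig), mh = sig$mh,
         frame = frame_effect(sig), n_events = nrow(a$events))
  }

  # one call per unique sequence, fanned back out to reads
  uniq <- unique(seqs)
  per_uniq <- lapply(uniq, function(u) call_one(aligned[[match(u, seqs)]]))
  names(per_uniq) <- uniq
  calls <- per_uniq[seqs]
  data.frame(
    read_id = ids,
    signature = vapply(calls, `[[`, character(1), "signature"),
    mh = vapply(calls, `[[`, integer(1), "mh"),
    frame = vapply(calls, `[[`, character(1), "frame"),
    n_events = vapply(calls, `[[`, integer(1), "n_events"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
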