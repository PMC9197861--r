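#' Expected indel-class frequencies for a clone at one amplicon
#'
#' Builds the generative indel spectrum implied by a clone's pathway weights.
#' The NHEJ-like component is a fixed small-indel table: a 1 bp insertion
#' duplicating the base 5' of the cut (the dominant templated-insertion
#' motif), and 1-3 bp deletions at the cut (weights 0.35/0.25/0.20/0.20).
#' The MMEJ-like component scans the amplicon for deletion intervals of
#' 5-30 bp spanning the cut whose flanks share at least 1 bp of true
#' microhomology, and samples `n_classes` of them weighted by MH length
#' (mass within the component is also proportional to MH). Components are
#' mixed with weights `nhej_weight : mmej_weight`, and the visible classes
#' are scaled to sum to `1 - large_del_prob`: the remaining mass is lost to
#' large deletions the short amplicon cannot see.
#'
#' Which MMEJ classes are picked depends only on the amplicon, `n_classes`
#' and `seed` - never on the weights - so expectations are comparable across
#' clones and monotone in `mmej_weight`.
#'
#' @param amplicon An `amplicon_target`.
#' @param effect A `genotype_effect`.
#' @param n_classes Number of MMEJ deletion classes to include.
#' @param seed Integer seed for the class draw.
#' @return A `profile_model`: list with `events` (data.frame of signature,
#'   coordinates, inserted sequence, MH, signed size, component and expected
#'   frequency), `large_del_prob`, `effect` and `amplicon_id`. Frequencies
#'   plus `large_del_prob` sum to 1.
#' @export
sample_profile <- function(amplicon, effect, n_classes = 8L, seed = 1L) {
  stopifnot(inherits(amplicon, "amplicon_target"),
            inherits(effect, "genotype_effect"))
  seq <- amplicon$sequence
  cut <- amplicon$cut_index

  nhej <- data.frame(
    ref_start = c(cut, cut - 1L, cut - 1L, cut - 2L),
    ref_end = c(cut, cut, cut + 1L, cut + 1L),
    ins = c(substr(seq, cut, cut), "", "", ""),
    weight = c(0.35, 0.25, 0.20, 0.20),
    component = "nhej",
    stringsAsFactors = FALSE
  )

  # All MMEJ-compatible deletion intervals: 5-30 bp, spanning the cut, with
  # >= 1 bp of sequence-supported microhomology. Equivalent placements
  # collapse onto one canonical signature.
  cand <- list()
  for (size in 5:30) {
    starts <- seq.int(max(0L, cut + 1L - size), cut - 1L)
    for (s in starts) {
      e <- s + size
      if (e > amplicon$length) next
      mh <- deletion_microhomology(seq, s, e)$mh
      if (mh >= 1L) {
        cand[[length(cand) + 1L]] <- data.frame(
          ref_start = s, ref_end = e, ins = "", weight = mh,
          component = "mmej", stringsAsFactors = FALSE)
      }
    }
  }
  mmej <- if (length(cand)) do.call(rbind, cand) else nhej[0, ]
  if (nrow(mmej)) {
    sig <- vapply(seq_len(nrow(mmej)), function(i) {
      format_signature(to_signature(
        list(ref_start = mmej$ref_start[i], ref_end = mmej$ref_end[i],
             ins = ""), amplicon))
    }, character(1))
    keep <- !duplicated(sig)
    mmej <- mmej[keep, , drop = FALSE]
    if (nrow(mmej) > n_classes) {
      idx <- with_stream(seed, "mmej_classes",
                         sample.int(nrow(mmej), n_classes, prob = mmej$weight))
      mmej <- mmej[sort(idx), , drop = FALSE]
    }
  }
  if (nrow(mmej) == 0L && effect$mmej_weight > 0) {
    warning("amplicon ", amplicon$id, " has no microhomology-supported ",
            "deletion site; MMEJ mass reassigned to the NHEJ component")
  }

  w_m <- if (nrow(mmej)) {
    effect$mmej_weight / (effect$nhej_weight + effect$mmej_weight)
  } else 0
  nhej$freq <- (1 - w_m) * nhej$weight / sum(nhej$weight)
  if (nrow(mmej)) mmej$freq <- w_m * mmej$weight / sum(mmej$weight)
  events <- rbind(nhej, mmej)
  events$freq <- events$freq / sum(events$freq) * (1 - effect$large_del_prob)

  events$signature <- vapply(seq_len(nrow(events)), function(i) {
    format_signature(to_signature(
      list(ref_start = events$ref_start[i], ref_end = events$ref_end[i],
           ins = events$ins[i]), amplicon))
  }, character(1))
  events$mh <- signature_mh(events$signature)
  events$size <- signed_size(events$signature)
  events$weight <- NULL
  rownames(events) <- NULL

  structure(
    list(amplicon_id = amplicon$id, effect = effect,
         large_del_prob = effect$large_del_prob, events = events),
    class = "profile_model"
  )
}

#' @export
print.profile_model <- function(x, ...) {
  cat("<profile_model> ", x$effect$clone_id, " at ", x$amplicon_id, ": ",
      nrow(x$events), " indel classes, large-deletion mass ",
      signif(x$large_del_prob, 3), "\n", sep = "")
  invisible(x)
}

# Apply one indel event (0-based half-open deletion interval plus optional
# insertion) to a reference sequence.
apply_event <- function(sequence, ref_start, ref_end, ins = "") {
  paste0(substr(sequence, 1L, ref_start), ins,
         substr(sequence, ref_end + 1L, nchar(sequence)))
}

#' Simulate amplicon reads from a profile model
#'
#' Draws `depth` reads by a multinomial over alleles: unmodified reference
#' with probability `1 - efficiency`, each visible indel class with
#' probability `efficiency * freq`. Large-deletion alleles do not amplify in
#' a short-range PCR and are excluded (weights renormalized). Each read is
#' the full edited amplicon with i.i.d. substitution errors at `error_rate`.
#' Read names encode the generating allele (`read000001|truth=D2_L-2C1R1`)
#' so callers can be scored against the truth.
#'
#' @param model A `profile_model` from [sample_profile()].
#' @param amplicon The matching `amplicon_target`.
#' @param depth Number of reads (>= 1).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet]; names carry the truth tag.
#' @export
sample_reads <- function(model, amplicon, depth, error_rate = 0, seed = 1L) {
  stopifnot(inherits(model, "profile_model"),
            inherits(amplicon, "amplicon_target"))
  if (depth < 1) stop("depth must be >= 1")
  stopifnot(error_rate >= 0, error_rate < 1)
  eff <- model$effect$efficiency
  ev <- model$events
  w <- c(REF = 1 - eff, stats::setNames(eff * ev$freq, ev$signature))
  w <- w / sum(w) # drops the non-amplifiable large-deletion mass
  alleles <- c(amplicon$sequence, vapply(seq_len(nrow(ev)), function(i) {
    apply_event(amplicon$sequence, ev$ref_start[i], ev$ref_end[i], ev$ins[i])
  }, character(1)))

  with_stream(seed, "reads", {
    counts <- as.vector(stats::rmultinom(1L, depth, w))
    idx <- rep.int(seq_along(w), counts)
    seqs <- alleles[idx]
    if (error_rate > 0) {
      lens <- nchar(seqs)
      nerr <- stats::rbinom(length(seqs), lens, error_rate)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(lens[i], nerr[i])
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    names(seqs) <- sprintf("read%06d|truth=%s", seq_along(seqs),
                           names(w)[idx])
    Biostrings::DNAStringSet(seqs)
  })
}

#' Simulate called read counts directly from a profile model
#'
#' Multinomial draw of `depth` reads over the amplifiable alleles (reference
#' plus visible indel classes), skipping read construction and alignment.
#' Equivalent in distribution to [sample_reads()] followed by an error-free
#' [call_reads()]; used for simulation studies where only the called profile
#' matters.
#'
#' @param model A `profile_model` from [sample_profile()].
#' @param depth Number of reads (>= 1).
#' @param seed Integer seed.
#' @param sample_id Sample identifier for the resulting profile.
#' @return An `indel_profile`.
#' @export
sample_profile_counts <- function(model, depth, seed = 1L,
                                  sample_id = model$effect$clone_id) {
  stopifnot(inherits(model, "profile_model"))
  if (depth < 1) stop("depth must be >= 1")
  eff <- model$effect$efficiency
  ev <- model$events
  w <- c(1 - eff, eff * ev$freq)
  w <- w / sum(w)
  counts <- with_stream(seed, paste0("counts:", sample_id),
                        as.vector(stats::rmultinom(1L, depth, w)))
  indel_profile(stats::setNames(counts[-1L], ev$signature),
                ref_reads = counts[1L], sample_id = sample_id)
}
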