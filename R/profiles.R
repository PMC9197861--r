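#' Per-sample indel profile
#'
#' Aggregated read counts per canonical signature for one sample. Reference
#' reads count toward the total and the mutated fraction but are excluded
#' from the signature distribution: profile frequencies are over mutated
#' reads only.
#'
#' @param counts Named non-negative integer vector (signature -> reads).
#' @param ref_reads Reads calling the unmodified reference.
#' @param sample_id Sample identifier.
#' @return An object of class `indel_profile` with fields `sample_id`,
#'   `counts`, `ref_reads`, `total_reads`, `mutated_fraction` and a parsed
#'   `meta` table (signed size and MH per signature).
#' @export
indel_profile <- function(counts, ref_reads = 0L, sample_id = "sample") {
  stopifnot(is.numeric(counts), !is.null(names(counts)) || length(counts) == 0L,
            all(counts >= 0), ref_reads >= 0)
  counts <- counts[counts > 0]
  if (length(counts)) {
    counts <- tapply(counts, names(counts), sum) # merge duplicate signatures
    counts <- counts[order(names(counts))]
  }
  counts <- stats::setNames(as.numeric(counts), names(counts))
  total <- sum(counts) + ref_reads
  meta <- if (length(counts)) {
    data.frame(signature = names(counts),
               size = signed_size(names(counts)),
               mh = signature_mh(names(counts)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(signature = character(), size = integer(), mh = integer())
  }
  structure(
    list(sample_id = sample_id, counts = counts,
         ref_reads = as.numeric(ref_reads), total_reads = total,
         mutated_fraction = if (total > 0) sum(counts) / total else NA_real_,
         meta = meta),
    class = "indel_profile"
  )
}

#' @export
print.indel_profile <- function(x, ...) {
  cat("<indel_profile> ", x$sample_id, ": ", length(x$counts),
      " signatures, ", format(x$total_reads), " reads (mutated fraction ",
      signif(x$mutated_fraction, 3), ")\n", sep = "")
  invisible(x)
}

#' Signature frequencies over mutated reads
#'
#' @param profile An `indel_profile`.
#' @return Named numeric vector summing to 1 (empty if no mutated reads).
#' @export
profile_freq <- function(profile) {
  stopifnot(inherits(profile, "indel_profile"))
  tot <- sum(profile$counts)
  if (tot == 0) return(stats::setNames(numeric(0), character(0)))
  profile$counts / tot
}

#' Build a profile from a table of per-read signature calls
#'
#' @param calls data.frame as returned by [call_reads()] (needs a `signature`
#'   column; "unalignable" reads are dropped with a message).
#' @param sample_id Sample identifier.
#' @return An `indel_profile`.
#' @export
build_profile <- function(calls, sample_id = "sample") {
  stopifnot(is.data.frame(calls), "signature" %in% names(calls))
  if (nrow(calls) == 0L) stop("no reads: cannot build a profile")
  sig <- calls$signature
  bad <- sig == "unalignable"
  if (any(bad)) {
    message(sum(bad), " unalignable read(s) excluded from ", sample_id)
    sig <- sig[!bad]
  }
  if (length(sig) == 0L) stop("no alignable reads in ", sample_id)
  ref <- sum(sig == "REF")
  tab <- table(sig[sig != "REF"])
  indel_profile(stats::setNames(as.numeric(tab), names(tab)),
                ref_reads = ref, sample_id = sample_id)
}

#' Remove indels implying loss of more than `max_loss` bases
#'
#' Deletions larger than the threshold are filtered out (strictly greater:
#' a deletion of exactly `max_loss` bp is retained); in short-range PCR such
#' reads are usually primer-dimers, not genuine alleles. The removed read
#' mass is recorded in `attr(, "removed_reads")`.
#'
#' @param profile An `indel_profile`.
#' @param max_loss Threshold in bp (default 150).
#' @return Filtered `indel_profile`.
#' @export
filter_large_loss <- function(profile, max_loss = 150L) {
  stopifnot(inherits(profile, "indel_profile"))
  drop <- profile$meta$size < -max_loss
  removed <- sum(profile$counts[drop])
  if (removed > 0) {
    message("filter_large_loss: removed ", removed, " read(s) in ",
            sum(drop), " signature(s) from ", profile$sample_id)
  }
  out <- indel_profile(profile$counts[!drop], ref_reads = profile$ref_reads,
                       sample_id = profile$sample_id)
  if (sum(out$counts) == 0 && removed > 0) {
    warning("all mutated reads of ", profile$sample_id,
            " removed by the large-loss filter")
  }
  attr(out, "removed_reads") <- removed
  out
}

#' Drop samples with too few remaining reads
#'
#' Samples whose post-filter total is below `min_reads` are removed. When a
#' grouping (clone x guide) is supplied, a warning is raised for any group
#' losing all of its samples - downstream clone calls need at least one.
#'
#' @param profiles List of `indel_profile`.
#' @param min_reads Minimum post-filter total (default 400; "fewer than" is
#'   strict, so a sample with exactly 400 reads is kept).
#' @param groups Optional character vector (same length) of clone x guide
#'   labels.
#' @return The retained sub-list, with dropped sample ids in
#'   `attr(, "dropped")`.
#' @export
filter_min_reads <- function(profiles, min_reads = 400L, groups = NULL) {
  stopifnot(is.list(profiles),
            all(vapply(profiles, inherits, logical(1), "indel_profile")))
  totals <- vapply(profiles, `[[`, numeric(1), "total_reads")
  keep <- totals >= min_reads
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(profiles))
    lost <- setdiff(unique(groups), unique(groups[keep]))
    if (length(lost)) {
      warning("group(s) lost all samples to the read-count filter: ",
              paste(lost, collapse = ", "))
    }
  }
  out <- profiles[keep]
  attr(out, "dropped") <- vapply(profiles[!keep], `[[`, character(1),
                                 "sample_id")
  out
}

#' Downsample a profile to a fixed read total
#'
#' Multivariate hypergeometric draw without replacement over all reads
#' (reference and mutated alike), modelling physical subsampling of the read
#' pool. The result has exactly `depth` reads.
#'
#' @param profile An `indel_profile` with `total_reads >= depth`.
#' @param depth Target total (default 450, a typical lowest common
#'   denominator across samples).
#' @param seed Integer seed.
#' @return Downsampled `indel_profile`.
#' @export
downsample_profile <- function(profile, depth = 450L, seed = 1L) {
  stopifnot(inherits(profile, "indel_profile"))
  if (profile$total_reads < depth) {
    stop("profile ", profile$sample_id, " has ", profile$total_reads,
         " reads, fewer than the requested depth ", depth)
  }
  if (profile$total_reads == depth) return(profile)
  pool <- c(REF = profile$ref_reads, profile$counts)
  drawn <- with_stream(seed, paste0("downsample:", profile$sample_id), {
    idx <- sample.int(sum(pool), depth)
    cls <- rep.int(seq_along(pool), pool)
    tabulate(cls[idx], nbins = length(pool))
  })
  names(drawn) <- names(pool)
  indel_profile(drawn[-1L], ref_reads = drawn[[1L]],
                sample_id = profile$sample_id)
}

#' Aggregate a profile into signed-size bins
#'
#' Frequencies over mutated reads are binned by signed indel size (deletions
#' negative, insertions positive). Mass beyond the tails is pooled into the
#' boundary bins, the usual display convention for indel spectra.
#'
#' @param profile An `indel_profile`.
#' @param left_tail,right_tail Outermost bins (defaults -30 and +10).
#' @return Named numeric vector over `left_tail:right_tail` summing to 1.
#' @export
aggregate_by_size <- function(profile, left_tail = -30L, right_tail = 10L) {
  stopifnot(inherits(profile, "indel_profile"), left_tail < right_tail)
  bins <- seq.int(left_tail, right_tail)
  out <- stats::setNames(numeric(length(bins)), bins)
  f <- profile_freq(profile)
  if (!length(f)) return(out)
  size <- pmin(pmax(profile$meta$size, left_tail), right_tail)
  agg <- tapply(f, size, sum)
  out[names(agg)] <- agg
  out
}

#' Summary statistics of an indel profile
#'
#' Mean signed indel size and mean microhomology length, both frequency-
#' weighted over mutated reads, plus the mutated fraction. A sample with no
#' mutated reads yields a flagged empty summary (NA statistics).
#'
#' @param profile An `indel_profile`.
#' @return List of class `profile_summary`: `mean_indel_size` (bp, deletions
#'   negative), `mean_mh` (bp), `mutated_fraction`, `n_mutated`, `empty`.
#' @export
summarize_profile <- function(profile) {
  stopifnot(inherits(profile, "indel_profile"))
  f <- profile_freq(profile)
  if (!length(f)) {
    return(structure(list(sample_id = profile$sample_id,
                          mean_indel_size = NA_real_, mean_mh = NA_real_,
                          mutated_fraction = profile$mutated_fraction,
                          n_mutated = 0, empty = TRUE),
                     class = "profile_summary"))
  }
  structure(
    list(sample_id = profile$sample_id,
         mean_indel_size = sum(f * profile$meta$size),
         mean_mh = sum(f * profile$meta$mh),
         mutated_fraction = profile$mutated_fraction,
         n_mutated = sum(profile$counts), empty = FALSE),
    class = "profile_summary"
  )
}

#' @export
print.profile_summary <- function(x, ...) {
  cat("<profile_summary> ", x$sample_id, ": mean size ",
      signif(x$mean_indel_size, 4), " bp, mean MH ", signif(x$mean_mh, 4),
      " bp, mutated fraction ", signif(x$mutated_fraction, 3), "\n", sep = "")
  invisible(x)
}

#' Per-indel relative frequency change versus a control profile
#'
#' For each signature present in the control profile at or above
#' `min_control_freq`, the relative change
#' `(f_sample - f_control) / f_control * 100` (percent). Complete loss of an
#' indel is -100%; +100% is a doubled frequency; values are unbounded above.
#'
#' @param sample_profile,control_profile `indel_profile` objects (the control
#'   is typically the pooled profile of all control samples).
#' @param min_control_freq Minimum control frequency for a signature to be
#'   reported (default 0.003).
#' @return data.frame with `signature`, `control_freq`, `sample_freq`,
#'   `change_pct`.
#' @export
indel_frequency_change <- function(sample_profile, control_profile,
                                   min_control_freq = 0.003) {
  stopifnot(inherits(sample_profile, "indel_profile"),
            inherits(control_profile, "indel_profile"))
  fc <- profile_freq(control_profile)
  fc <- fc[fc >= min_control_freq]
  if (!length(fc)) {
    return(data.frame(signature = character(), control_freq = numeric(),
                      sample_freq = numeric(), change_pct = numeric()))
  }
  fs <- profile_freq(sample_profile)
  sample_freq <- ifelse(names(fc) %in% names(fs), fs[names(fc)], 0)
  data.frame(
    signature = names(fc),
    control_freq = as.numeric(fc),
    sample_freq = as.numeric(sample_freq),
    change_pct = (as.numeric(sample_freq) - as.numeric(fc)) /
      as.numeric(fc) * 100,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pool several profiles into one combined profile
#'
#' Read counts (mutated and reference) are summed across samples, e.g. to
#' form the combined control profile against which per-clone changes are
#' measured.
#'
#' @param profiles List of `indel_profile`.
#' @param sample_id Identifier for the pooled profile.
#' @return An `indel_profile`.
#' @export
pool_profiles <- function(profiles, sample_id = "pooled") {
  stopifnot(is.list(profiles), length(profiles) > 0,
            all(vapply(profiles, inherits, logical(1), "indel_profile")))
  counts <- unlist(lapply(profiles, `[[`, "counts"))
  names(counts) <- unlist(lapply(profiles, function(p) names(p$counts)))
  ref <- sum(vapply(profiles, `[[`, numeric(1), "ref_reads"))
  indel_profile(counts, ref_reads = ref, sample_id = sample_id)
}
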