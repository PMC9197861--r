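#' Simulate a plate-structured flow-cytometry screen
#'
#' Emulates the arrayed %-positive readout: every clone is measured on every
#' plate, a plate being one replicate of one staining condition. Two
#' conditions are simulated by default: `"del"`, the intronic-guide readout
#' whose %-positive equals `100 * large_del_prob` (cells that lost reporter
#' expression carry a large deletion), and `"mut"`, a weak exonic-guide
#' readout tracking overall mutagenic efficiency
#' (`100 * efficiency * mut_scale`; the default scale 0.15 puts control
#' clones near 12%, a realistic weak-guide readout). Each plate adds a shared
#' batch offset (`N(0, batch_sd)`) and each well i.i.d. noise
#' (`N(0, noise_sd)`); values are truncated to \[0, 100\].
#'
#' @param effects List of `genotype_effect` (>= 3 controls required).
#' @param n_plates Replicate plates per condition (>= 2).
#' @param batch_sd SD of the per-plate offset (percentage points).
#' @param noise_sd SD of the per-well noise (percentage points).
#' @param seed Integer seed.
#' @param conditions Character vector of condition labels to simulate.
#' @param mut_scale Weak-guide readout per unit efficiency.
#' @return A `flow_sim`: list with `matrix` (clones x plates, %-positive),
#'   `meta` (plate, condition, replicate), and `truth` (per-clone generative
#'   parameters, per-plate offsets, seed).
#' @export
simulate_flow <- function(effects, n_plates = 4L, batch_sd = 5, noise_sd = 2,
                          seed = 1L, conditions = c("del", "mut"),
                          mut_scale = 0.15) {
  stopifnot(is.list(effects), length(effects) > 0,
            all(vapply(effects, inherits, logical(1), "genotype_effect")))
  if (n_plates < 2L) stop("at least 2 plates per condition are required")
  roles <- vapply(effects, `[[`, character(1), "role")
  if (sum(roles == "control") < 3L) {
    stop("at least 3 control clones are required")
  }
  clones <- vapply(effects, `[[`, character(1), "clone_id")
  meta <- expand.grid(replicate = seq_len(n_plates), condition = conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$plate <- sprintf("%s_r%d", meta$condition, meta$replicate)
  meta <- meta[, c("plate", "condition", "replicate")]

  truth_pct <- vapply(effects, function(ef) {
    c(del = 100 * ef$large_del_prob,
      mut = 100 * ef$efficiency * mut_scale)[conditions]
  }, numeric(length(conditions)))
  truth_pct <- matrix(truth_pct, nrow = length(conditions),
                      dimnames = list(conditions, clones))

  with_stream(seed, "flow", {
    offsets <- stats::setNames(stats::rnorm(nrow(meta), 0, batch_sd),
                               meta$plate)
    m <- sapply(seq_len(nrow(meta)), function(j) {
      truth_pct[meta$condition[j], ] + offsets[j] +
        stats::rnorm(length(clones), 0, noise_sd)
    })
    m <- pmin(pmax(m, 0), 100)
    dimnames(m) <- list(clones, meta$plate)
    structure(
      list(matrix = m, meta = meta,
           truth = list(
             effects = effects, plate_offsets = offsets,
             true_pct = t(truth_pct), seed = as.integer(seed))),
      class = "flow_sim"
    )
  })
}

#' @export
print.flow_sim <- function(x, ...) {
  cat("<flow_sim> ", nrow(x$matrix), " clones x ", ncol(x$matrix),
      " plates (", paste(unique(x$meta$condition), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
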