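#' Per-plate z-scores of a %-positive matrix
#'
#' Each plate (column) is standardized across clones: `z = (x - mean) / sd`
#' with the unbiased SD. Standardizing per plate removes plate-level offsets
#' and the overall magnitude of mutagenesis, leaving relative clone behaviour.
#'
#' @param m Clones x plates numeric matrix (a `flow_sim` is accepted).
#' @return Matrix of the same shape; each column has mean 0 and SD 1.
#' @export
plate_zscores <- function(m) {
  if (inherits(m, "flow_sim")) m <- m$matrix
  m <- as.matrix(m)
  mu <- colMeans(m)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds < 1e-12)) {
    stop("constant plate column(s): ",
         paste(colnames(m)[sds < 1e-12], collapse = ", "),
         " (zero SD, cannot z-score)")
  }
  sweep(sweep(m, 2L, mu), 2L, sds, `/`)
}

#' Rank-2 PCA regression of plate z-scores
#'
#' PCA with plates as observations and clones as features: in an arrayed
#' screen the leading components separate plates by guide and sampling day,
#' while later components carry replicate-batch structure. The returned
#' matrix is the rank-`n_pc` reconstruction (top components plus the
#' per-clone means), i.e. the data with everything outside the leading
#' plate-level structure regressed away.
#'
#' @param raw_z Clones x plates matrix from [plate_zscores()].
#' @param n_pc Number of components kept (default 2; reduced with a warning
#'   if the centered matrix has lower rank).
#' @return Clones x plates matrix of the same shape, with the kept singular
#'   values in `attr(, "sdev")`.
#' @export
pca_regress <- function(raw_z, n_pc = 2L) {
  raw_z <- as.matrix(raw_z)
  if (ncol(raw_z) < 3L || nrow(raw_z) < 3L) {
    stop("need at least 3 plates and 3 clones for PCA regression")
  }
  x <- t(raw_z) # plates as observations
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sv <- svd(xc)
  rank <- sum(sv$d > 1e-9 * max(sv$d, 1))
  if (n_pc > rank) {
    warning("requested ", n_pc, " components but centered rank is ", rank,
            "; using ", rank)
    n_pc <- rank
  }
  idx <- seq_len(n_pc)
  recon <- sv$u[, idx, drop = FALSE] %*%
    (sv$d[idx] * t(sv$v[, idx, drop = FALSE]))
  out <- t(sweep(recon, 2L, ctr, `+`))
  dimnames(out) <- dimnames(raw_z)
  attr(out, "sdev") <- sv$d[idx] / sqrt(max(1, nrow(x) - 1L))
  out
}

#' Control-referenced z-scores per staining condition
#'
#' For each condition (e.g. guide x day), a clone's score is the mean of its
#' regressed values over that condition's plates; scores are then expressed
#' as z-scores relative to the mean and SD of the control clones, so the
#' control set has mean 0 and SD 1 per condition by construction.
#'
#' @param regressed Clones x plates matrix from [pca_regress()].
#' @param control_ids Row names of control clones.
#' @param conditions Named character vector mapping plate -> condition.
#' @return Clones x conditions matrix of control-referenced z-scores, with
#'   the raw per-condition scores in `attr(, "scores")`.
#' @export
control_z <- function(regressed, control_ids, conditions) {
  regressed <- as.matrix(regressed)
  stopifnot(!is.null(rownames(regressed)), !is.null(colnames(regressed)),
            all(colnames(regressed) %in% names(conditions)),
            all(control_ids %in% rownames(regressed)))
  conds <- unique(unname(conditions[colnames(regressed)]))
  scores <- vapply(conds, function(cond) {
    plates <- colnames(regressed)[conditions[colnames(regressed)] == cond]
    rowMeans(regressed[, plates, drop = FALSE])
  }, numeric(nrow(regressed)))
  scores <- matrix(scores, nrow = nrow(regressed),
                   dimnames = list(rownames(regressed), conds))
  z <- scores
  for (cond in conds) {
    mu <- mean(scores[control_ids, cond])
    sd <- stats::sd(scores[control_ids, cond])
    if (sd < 1e-8) stop("control SD is (near) zero for condition ", cond)
    z[, cond] <- (scores[, cond] - mu) / sd
  }
  attr(z, "scores") <- scores
  z
}

#' Large-deletion versus mutagenesis indices
#'
#' Pairs each clone's control-referenced z-score in the large-deletion
#' condition (intronic guide: expression loss requires a deletion reaching
#' the nearest exon) with its score in the mutagenesis condition (weak exonic
#' guide tracking overall cutting efficiency). An ordinary least-squares line
#' is fitted to the control clones; residuals from that control trend isolate
#' deletion-specific effects from mere efficiency differences.
#'
#' @param cz Clones x conditions matrix from [control_z()].
#' @param control_ids Control clone ids.
#' @param deletion_condition,mutagenesis_condition Column names in `cz`.
#' @return List of class `flow_indices`: `indices` data.frame (clone,
#'   large_deletion, mutagenesis, residual, is_control) and `fit` (the
#'   control-clone `lm`).
#' @export
deletion_vs_mutagenesis <- function(cz, control_ids,
                                    deletion_condition = "del",
                                    mutagenesis_condition = "mut") {
  cz <- as.matrix(cz)
  stopifnot(all(c(deletion_condition, mutagenesis_condition) %in% colnames(cz)),
            all(control_ids %in% rownames(cz)))
  df <- data.frame(
    clone = rownames(cz),
    large_deletion = cz[, deletion_condition],
    mutagenesis = cz[, mutagenesis_condition],
    is_control = rownames(cz) %in% control_ids,
    row.names = NULL, stringsAsFactors = FALSE
  )
  fit <- stats::lm(large_deletion ~ mutagenesis, data = df[df$is_control, ])
  df$residual <- df$large_deletion -
    stats::predict(fit, newdata = df)
  structure(list(indices = df, fit = fit), class = "flow_indices")
}
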