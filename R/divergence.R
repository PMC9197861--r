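#' Symmetrized Kullback-Leibler divergence between two indel profiles
#'
#' Both profiles are restricted to the union of their signature supports;
#' a pseudocount is added to every class (Jeffreys-style smoothing keeps the
#' divergence finite when one sample misses a class) and counts are
#' renormalized. Returns `0.5 * (KL(P||Q) + KL(Q||P))` in nats; non-negative
#' and symmetric, 0 iff the smoothed distributions are identical.
#'
#' @param p,q `indel_profile` objects or named count vectors.
#' @param pseudocount Added to each union-support class (default 0.5).
#' @param include_ref Should reference reads enter the support as their own
#'   class? Default FALSE: profiles are spectra over mutated reads.
#' @return Non-negative numeric scalar (nats).
#' @export
symmetrized_kl <- function(p, q, pseudocount = 0.5, include_ref = FALSE) {
  cp <- if (inherits(p, "indel_profile")) {
    if (include_ref) c(p$counts, REF = p$ref_reads) else p$counts
  } else p
  cq <- if (inherits(q, "indel_profile")) {
    if (include_ref) c(q$counts, REF = q$ref_reads) else q$counts
  } else q
  stopifnot(is.numeric(cp), is.numeric(cq))
  support <- union(names(cp), names(cq))
  if (length(support) == 0L) stop("empty union support: no signatures in ",
                                  "either profile")
  a <- numeric(length(support)); names(a) <- support
  b <- a
  a[names(cp)] <- a[names(cp)] + cp
  b[names(cq)] <- b[names(cq)] + cq
  a <- a + pseudocount
  b <- b + pseudocount
  if (any(a <= 0) || any(b <= 0)) {
    stop("non-positive smoothed counts; increase the pseudocount")
  }
  a <- a / sum(a)
  b <- b / sum(b)
  0.5 * sum((a - b) * (log(a) - log(b)))
}

#' Pairwise divergence matrix over a set of samples
#'
#' @param profiles Named list of `indel_profile` (or named count vectors).
#' @param pseudocount,include_ref Passed to [symmetrized_kl()].
#' @return Symmetric matrix with zero diagonal, sample ids as dimnames.
#' @export
kl_matrix <- function(profiles, pseudocount = 0.5, include_ref = FALSE) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  ids <- names(profiles)
  if (is.null(ids)) {
    ids <- vapply(profiles, function(p) {
      if (inherits(p, "indel_profile")) p$sample_id else NA_character_
    }, character(1))
    if (anyNA(ids)) ids <- sprintf("sample%03d", seq_along(profiles))
  }
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n == 1L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- symmetrized_kl(profiles[[i]], profiles[[j]],
                                           pseudocount = pseudocount,
                                           include_ref = include_ref)
    }
  }
  m
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared dissimilarities, `B = -1/2 * C D^2 C`, takes
#' the eigendecomposition of `B` and returns the top-`k` eigenvectors scaled
#' by the square root of their eigenvalues. Negative eigenvalues (the
#' dissimilarity is not exactly Euclidean) are dropped with a warning when
#' they limit the requested dimension. Axes are defined up to sign and
#' rotation; downstream tests use Mahalanobis distances, which are invariant.
#'
#' @param d Symmetric non-negative dissimilarity matrix (e.g. [kl_matrix()]).
#' @param k Target dimension (default 2).
#' @return List of class `mds_embedding`: `points` (n x k), `eigenvalues`
#'   (all n, descending).
#' @export
classical_mds <- function(d, k = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n == ncol(d), all(is.finite(d)), all(d >= 0),
            max(abs(d - t(d))) < 1e-8)
  cmat <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * cmat %*% (d^2) %*% cmat
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  tol <- 1e-9 * max(abs(eig$values), 1)
  npos <- sum(eig$values > tol)
  k_eff <- min(k, npos)
  if (k_eff < k) {
    warning("only ", npos, " positive eigenvalue(s): embedding reduced from ",
            k, " to ", k_eff, " informative dimension(s), rest zero-filled")
  }
  pts <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
  if (k_eff > 0L) {
    pts[, seq_len(k_eff)] <- eig$vectors[, seq_len(k_eff), drop = FALSE] %*%
      diag(sqrt(eig$values[seq_len(k_eff)]), k_eff, k_eff)
  }
  structure(list(points = pts, eigenvalues = eig$values),
            class = "mds_embedding")
}

#' Fit the bivariate-normal control null in embedding space
#'
#' @param embedding An `mds_embedding` (or a plain coordinate matrix).
#' @param control_ids Row names of the control samples (>= 3).
#' @return List of class `control_null`: `mean`, `covariance` (unbiased,
#'   checked positive-definite).
#' @export
control_null <- function(embedding, control_ids) {
  pts <- if (inherits(embedding, "mds_embedding")) embedding$points
         else as.matrix(embedding)
  stopifnot(!is.null(rownames(pts)))
  missing <- setdiff(control_ids, rownames(pts))
  if (length(missing)) stop("control samples not in embedding: ",
                            paste(missing, collapse = ", "))
  if (length(control_ids) < 3L) stop("at least 3 control samples required")
  ctl <- pts[control_ids, , drop = FALSE]
  mu <- colMeans(ctl)
  sigma <- stats::cov(ctl)
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) stop("singular control covariance: controls do not span the ",
                "embedding plane")
  structure(list(mean = mu, covariance = sigma, n = length(control_ids)),
            class = "control_null")
}

#' Chi-squared p-values for divergence from the control null
#'
#' Squared Mahalanobis distance of each sample to the fitted control normal;
#' for a point from that bivariate normal the squared distance is chi-squared
#' with 2 degrees of freedom, so `p = P(chisq_2 > d^2)` (upper tail).
#'
#' @param embedding An `mds_embedding` or coordinate matrix.
#' @param null A `control_null`.
#' @return data.frame with `sample_id`, `dsq`, `p`.
#' @export
divergence_pvalues <- function(embedding, null) {
  pts <- if (inherits(embedding, "mds_embedding")) embedding$points
         else as.matrix(embedding)
  stopifnot(inherits(null, "control_null"),
            ncol(pts) == length(null$mean))
  dsq <- stats::mahalanobis(pts, null$mean, null$covariance)
  data.frame(sample_id = rownames(pts), dsq = as.numeric(dsq),
             p = stats::pchisq(dsq, df = ncol(pts), lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Replicate-consistent significance calls with FDR correction
#'
#' Benjamini-Hochberg correction is applied across all samples of one guide
#' (controls included); a clone is called significantly different from
#' controls only if every one of its replicates has FDR-corrected `q < alpha`.
#'
#' @param pvalues data.frame from [divergence_pvalues()].
#' @param replicate_map Named character vector mapping `sample_id` -> clone.
#' @param alpha Per-replicate FDR threshold (default 0.01).
#' @return List of class `significance_table`: `samples` (sample_id, clone,
#'   dsq, p, q) and `clones` (clone, n_replicates, significant).
#' @export
call_significant <- function(pvalues, replicate_map, alpha = 0.01) {
  stopifnot(is.data.frame(pvalues),
            all(c("sample_id", "p") %in% names(pvalues)),
            all(pvalues$sample_id %in% names(replicate_map)))
  samples <- pvalues
  samples$clone <- unname(replicate_map[samples$sample_id])
  samples$q <- stats::p.adjust(samples$p, method = "BH")
  agg <- tapply(samples$q, samples$clone, function(q) all(q < alpha))
  nrep <- tapply(samples$q, samples$clone, length)
  clones <- data.frame(clone = names(agg),
                       n_replicates = as.integer(nrep[names(agg)]),
                       significant = as.logical(agg),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(samples = samples, clones = clones, alpha = alpha),
            class = "significance_table")
}

#' @export
print.significance_table <- function(x, ...) {
  cat("<significance_table> ", nrow(x$samples), " samples, ",
      nrow(x$clones), " clones; ", sum(x$clones$significant),
      " significant at all-replicate q < ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Full divergence test of a sample cohort
#'
#' One-call wrapper over the divergence stage: pairwise symmetrized KL,
#' classical MDS to `k` dimensions, bivariate-normal control null,
#' chi-squared p-values and replicate-consistent FDR calls.
#'
#' @param profiles Named list of `indel_profile` (names are sample ids).
#' @param replicate_map Named character vector, sample id -> clone id.
#' @param control_clones Clone ids of the control set.
#' @param alpha Per-replicate FDR threshold.
#' @param pseudocount,include_ref Passed to [symmetrized_kl()].
#' @param k Embedding dimension.
#' @return A `significance_table` with the embedding in
#'   `attr(, "embedding")`.
#' @export
divergence_test <- function(profiles, replicate_map, control_clones,
                            alpha = 0.01, pseudocount = 0.5,
                            include_ref = FALSE, k = 2L) {
  stopifnot(!is.null(names(profiles)),
            all(names(profiles) %in% names(replicate_map)))
  km <- kl_matrix(profiles, pseudocount = pseudocount,
                  include_ref = include_ref)
  emb <- classical_mds(km, k = k)
  ctl_samples <- names(profiles)[replicate_map[names(profiles)] %in%
                                   control_clones]
  null <- control_null(emb, ctl_samples)
  pv <- divergence_pvalues(emb, null)
  out <- call_significant(pv, replicate_map, alpha = alpha)
  attr(out, "embedding") <- emb
  out
}
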