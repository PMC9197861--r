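test_that("symmetrized KL has the metric-like sanity properties", {
  for (s in 1:100) {
    p <- random_profile(2 * s)
    q <- random_profile(2 * s + 1)
    d_pq <- symmetrized_kl(p, q)
    expect_gte(d_pq, 0)
    expect_equal(d_pq, symmetrized_kl(q, p), tolerance = 1e-12)
    expect_equal(symmetrized_kl(p, p), 0, tolerance = 1e-14)
  }
  expect_error(
    symmetrized_kl(indel_profile(setNames(numeric(0), character(0)), 10),
                   indel_profile(setNames(numeric(0), character(0)), 10)),
    "empty union")
})

test_that("two-class divergence matches the closed-form hand evaluation", {
  # P = (0.9, 0.1), Q = (0.1, 0.9), no smoothing:
  # 0.5 * sum((p-q) log(p/q)) = 0.8 * log(9)
  v <- symmetrized_kl(c(a = 0.9, b = 0.1), c(a = 0.1, b = 0.9),
                      pseudocount = 0)
  expect_equal(v, 0.8 * log(9), tolerance = 1e-9)
})

test_that("divergence matrices are consistent with the scalar operation", {
  profs <- setNames(lapply(1:5, random_profile),
                    sprintf("s%d", 1:5))
  m <- kl_matrix(profs)
  expect_true(isSymmetric(m))
  expect_equal(unname(diag(m)), rep(0, 5))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m[i, j], symmetrized_kl(profs[[i]], profs[[j]]),
                 tolerance = 1e-12)
  }
  # single sample: 1x1 zero matrix
  expect_equal(unname(kl_matrix(profs[1])), matrix(0, 1, 1))
  # permutation consistency
  perm <- c(3, 1, 5, 2, 4)
  m2 <- kl_matrix(profs[perm])
  expect_equal(m2, m[perm, perm])
})

test_that("classical MDS reproduces Euclidean configurations exactly", {
  x <- c(0, 1, 3, 7) # 4 collinear points
  d <- as.matrix(dist(x))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  emb <- suppressWarnings(classical_mds(d, k = 2))
  expect_lt(max(abs(as.matrix(dist(emb$points)) - d)), 1e-9)
  expect_equal(emb$points[, 2], setNames(rep(0, 4), letters[1:4]))
  expect_true(all(diff(emb$eigenvalues) <= 1e-9))

  # identical samples: all-zero coordinates
  dz <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  embz <- suppressWarnings(classical_mds(dz, k = 2))
  expect_equal(unname(embz$points), matrix(0, 3, 2))

  # planar configuration: exact in 2-d, and matching stats::cmdscale
  set.seed(5)
  pts <- matrix(rnorm(16), 8, 2)
  d2 <- as.matrix(dist(pts))
  dimnames(d2) <- list(sprintf("p%d", 1:8), sprintf("p%d", 1:8))
  emb2 <- classical_mds(d2, k = 2)
  expect_lt(max(abs(as.matrix(dist(emb2$points)) - d2)), 1e-9)
  ref <- stats::cmdscale(d2, k = 2)
  expect_lt(max(abs(as.matrix(dist(ref)) - as.matrix(dist(emb2$points)))),
            1e-9)
})

test_that("control null fitting recovers simulated moments", {
  set.seed(11)
  pts <- matrix(rnorm(2 * 10000), ncol = 2,
                dimnames = list(sprintf("c%05d", 1:10000), NULL))
  null <- control_null(pts, rownames(pts))
  expect_lt(max(abs(null$mean)), 0.05)
  expect_lt(max(abs(null$covariance - diag(2))), 0.05)

  # singular controls rejected
  same <- matrix(1, 4, 2, dimnames = list(letters[1:4], NULL))
  expect_error(control_null(same, letters[1:4]), "singular")
  expect_error(control_null(pts, rownames(pts)[1:2]), "at least 3")

  # Mahalanobis distances are invariant to affine maps of the plane
  amat <- matrix(c(2, 0.5, -1, 3), 2, 2)
  ctl <- pts[1:50, ]
  trans <- ctl %*% t(amat) + matrix(c(5, -2), 50, 2, byrow = TRUE)
  rownames(trans) <- rownames(ctl)
  d1 <- divergence_pvalues(ctl, control_null(ctl, rownames(ctl)))
  d2 <- divergence_pvalues(trans, control_null(trans, rownames(trans)))
  expect_equal(d1$dsq, d2$dsq, tolerance = 1e-9)
})

test_that("chi-squared p-values behave at the anchor points", {
  null <- structure(list(mean = c(0, 0), covariance = diag(2), n = 10),
                    class = "control_null")
  pts <- rbind(at_mean = c(0, 0), far = c(3, 0.35))
  pv <- divergence_pvalues(pts, null)
  expect_equal(pv$p[1], 1)
  # d^2 = 9.21034 is exactly p = 0.01 for chi-squared with 2 df
  pts2 <- rbind(x = c(sqrt(9.21034), 0))
  expect_equal(divergence_pvalues(pts2, null)$p, 0.01, tolerance = 1e-6)
})

test_that("replicate rule requires every replicate below alpha after BH", {
  pv <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    dsq = 1,
    p = c(0.00001, 0.02, 0.0001, 0.00012, 0.9, 0.95))
  rmap <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
  st <- call_significant(pv, rmap, alpha = 0.01)
  got <- setNames(st$clones$significant, st$clones$clone)
  expect_true(got[["B"]])
  expect_false(got[["C"]])
  # A: one replicate's BH-adjusted p crosses alpha -> not significant
  qa <- st$samples$q[st$samples$clone == "A"]
  expect_false(all(qa < 0.01))
  expect_false(got[["A"]])

  # all p = 1: nothing significant
  pv1 <- transform(pv, p = 1)
  expect_false(any(call_significant(pv1, rmap)$clones$significant))
  expect_true(all(call_significant(pv1, rmap)$samples$q >=
                    call_significant(pv1, rmap)$samples$p - 1e-15))
})

test_that("null squared distances average 2 and give uniform p-values", {
  set.seed(23)
  n <- 10000
  pts <- matrix(rnorm(2 * n), ncol = 2,
                dimnames = list(sprintf("s%05d", 1:n), NULL))
  null <- structure(list(mean = c(0, 0), covariance = diag(2), n = n),
                    class = "control_null")
  pv <- divergence_pvalues(pts, null)
  expect_equal(mean(pv$dsq), 2, tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(pv$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
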