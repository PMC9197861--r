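test_that("plate z-scores standardize each plate across clones", {
  m <- cbind(p1 = c(10, 20, 30), p2 = c(5, 5, 8))
  rownames(m) <- c("a", "b", "c")
  z <- plate_zscores(m)
  expect_equal(unname(z[, "p1"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))

  m2 <- cbind(p1 = c(10, 20, 30), p2 = c(7, 7, 7))
  expect_error(plate_zscores(m2), "constant|zero SD")
})

test_that("rank-2 PCA regression reconstructs rank-2 data exactly", {
  set.seed(3)
  n_clone <- 12; n_plate <- 6
  # build plates x clones data whose centered part has rank exactly 2
  u1 <- rnorm(n_plate); u1 <- u1 - mean(u1)
  u2 <- rnorm(n_plate); u2 <- u2 - mean(u2)
  v1 <- rnorm(n_clone); v2 <- rnorm(n_clone)
  ctr <- rnorm(n_clone)
  x <- outer(rep(1, n_plate), ctr) + outer(u1, v1) + outer(u2, v2)
  raw_z <- t(x)
  dimnames(raw_z) <- list(sprintf("c%02d", 1:n_clone),
                          sprintf("p%d", 1:n_plate))
  reg <- pca_regress(raw_z, n_pc = 2)
  expect_lt(max(abs(reg - raw_z)), 1e-9)

  # projection never increases variance
  set.seed(4)
  noisy <- raw_z + matrix(rnorm(length(raw_z)), nrow(raw_z))
  reg2 <- pca_regress(noisy, n_pc = 2)
  expect_lte(var(as.vector(reg2)), var(as.vector(noisy)))

  # rank deficit triggers a warning and a reduced reconstruction
  flat <- outer(rep(1, n_plate), ctr) + outer(u1, v1)
  expect_warning(pca_regress(t(flat), n_pc = 2), "rank")
})

test_that("structure outside the leading components is regressed away", {
  set.seed(9)
  n_clone <- 20; n_plate <- 8
  u1 <- rnorm(n_plate); u1 <- u1 - mean(u1)
  u2 <- rnorm(n_plate); u2 <- u2 - mean(u2)
  # batch direction orthogonal to u1, u2 in plate space
  batch <- residuals(lm(rnorm(n_plate) ~ u1 + u2))
  signal <- outer(u1, rnorm(n_clone)) * 8 + outer(u2, rnorm(n_clone)) * 6
  bmat <- outer(batch, rnorm(n_clone)) * 0.5
  x <- signal + bmat
  raw_z <- t(x)
  dimnames(raw_z) <- list(sprintf("c%02d", 1:n_clone),
                          sprintf("p%d", 1:n_plate))
  reg <- pca_regress(raw_z, n_pc = 2)
  residual <- raw_z - reg
  # what was removed is (essentially exactly) the injected batch component
  expect_gt(cor(as.vector(residual), as.vector(t(bmat))), 0.99)
})

test_that("control-referenced z-scores standardize the control set", {
  set.seed(21)
  clones <- sprintf("c%02d", 1:10)
  controls <- clones[1:4]
  plates <- c("del_r1", "del_r2", "mut_r1", "mut_r2")
  conditions <- setNames(c("del", "del", "mut", "mut"), plates)
  reg <- matrix(rnorm(40), 10, 4, dimnames = list(clones, plates))
  cz <- control_z(reg, controls, conditions)
  expect_equal(unname(colMeans(cz[controls, ])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(cz[controls, ], 2, sd)), c(1, 1),
               tolerance = 1e-12)

  # clone exactly at the control mean scores 0; +2 SD scores 2
  scores <- attr(cz, "scores")
  mu <- mean(scores[controls, "del"]); s <- sd(scores[controls, "del"])
  reg2 <- reg
  reg2["c05", c("del_r1", "del_r2")] <- mu
  reg2["c06", c("del_r1", "del_r2")] <- mu + 2 * s
  cz2 <- control_z(reg2, controls, conditions)
  expect_equal(unname(cz2["c05", "del"]), 0, tolerance = 1e-12)
  expect_equal(unname(cz2["c06", "del"]), 2, tolerance = 1e-12)

  # constant controls cannot be referenced
  reg3 <- reg
  reg3[controls, c("del_r1", "del_r2")] <- 1
  expect_error(control_z(reg3, controls, conditions), "control SD")
})

test_that("deletion and mutagenesis indices separate deletion-specific clones", {
  effs <- cohort_effects(n_control = 12, n_nhej = 6, n_mmej = 6,
                         jitter_sd = 0.2, seed = 2)
  clones <- vapply(effs, `[[`, character(1), "clone_id")
  controls <- clones[vapply(effs, `[[`, character(1), "role") == "control"]
  # inject a clone with elevated deletions but control-level efficiency
  effs <- c(effs, list(genotype_effect("hot", role = "experimental",
                                       large_del_prob = 0.4)))
  fs <- simulate_flow(effs, n_plates = 4, batch_sd = 5, noise_sd = 1,
                      seed = 3)
  cz <- control_z(pca_regress(plate_zscores(fs$matrix)), controls,
                  setNames(fs$meta$condition, fs$meta$plate))
  di <- deletion_vs_mutagenesis(cz, controls)
  hot <- di$indices[di$indices$clone == "hot", ]
  expect_gt(hot$residual, 2)
  # index-pair shift invariance: adding a constant to both indices moves the
  # intercept, not the slope
  cz_shift <- cz + 1
  di2 <- deletion_vs_mutagenesis(cz_shift, controls)
  expect_equal(unname(coef(di2$fit)["mutagenesis"]),
               unname(coef(di$fit)["mutagenesis"]), tolerance = 1e-9)
})

test_that("flow scores recover simulated large-deletion truth", {
  effs <- cohort_effects(n_control = 14, n_nhej = 13, n_mmej = 13,
                         jitter_sd = 0.3, seed = 8)
  clones <- vapply(effs, `[[`, character(1), "clone_id")
  controls <- clones[vapply(effs, `[[`, character(1), "role") == "control"]
  fs <- simulate_flow(effs, n_plates = 4, batch_sd = 5, noise_sd = 2,
                      seed = 9)
  cz <- control_z(pca_regress(plate_zscores(fs$matrix)), controls,
                  setNames(fs$meta$condition, fs$meta$plate))
  ldp <- vapply(effs, `[[`, numeric(1), "large_del_prob")
  rho <- cor(cz[clones, "del"], ldp, method = "spearman")
  expect_gte(rho, 0.9)
})
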