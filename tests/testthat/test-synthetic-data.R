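test_that("amplicon generation respects geometry, PAM and determinism", {
  amp <- generate_amplicon(283, 0.5, seed = 1)
  expect_s3_class(amp, "amplicon_target")
  expect_equal(amp$length, 283L)
  expect_equal(nchar(amp$sequence), 283L)
  # cut lies 3 bp 5' of an NGG PAM with >= 40 bp flanks
  expect_equal(substr(amp$sequence, amp$cut_index + 5, amp$cut_index + 6), "GG")
  expect_gte(amp$cut_index, 40L)
  expect_gte(amp$length - amp$cut_index, 40L)

  amp2 <- generate_amplicon(283, 0.5, seed = 1)
  expect_identical(amp$sequence, amp2$sequence)
  expect_false(identical(amp$sequence,
                         generate_amplicon(283, 0.5, seed = 2)$sequence))

  expect_error(generate_amplicon(60, 0.5, 1), "length|flank")
  expect_error(generate_amplicon(283, 0.1, 1), "gc")
})

test_that("profile models mix NHEJ and MMEJ components as specified", {
  amp <- fixture_amplicon()

  # degenerate mixture: no MMEJ -> only small indels
  pm0 <- sample_profile(amp, genotype_effect("x", mmej_weight = 0,
                                             large_del_prob = 0), seed = 1)
  active <- pm0$events[pm0$events$freq > 0, ]
  expect_true(all(abs(active$size) <= 3))

  # conservation: visible frequencies + large-deletion mass == 1
  pm <- sample_profile(amp, genotype_effect("c", role = "control"), seed = 1)
  expect_equal(sum(pm$events$freq) + pm$large_del_prob, 1, tolerance = 1e-12)

  # MMEJ deletions carry genuine sequence-supported microhomology
  mmej <- pm$events[pm$events$component == "mmej", ]
  expect_true(all(mmej$mh >= 1))
  expect_true(all(mmej$size <= -5 & mmej$size >= -30))

  # control defaults are deletion-dominated (negative expected size)
  esize <- sum(pm$events$freq * pm$events$size) / sum(pm$events$freq)
  expect_lt(esize, 0)
})

test_that("expected MH and |size| increase monotonically in mmej_weight", {
  amp <- fixture_amplicon()
  grid <- c(0.25, 0.5, 1, 2, 4)
  stats_at <- vapply(grid, function(w) {
    pm <- sample_profile(amp, genotype_effect("x", mmej_weight = w,
                                              large_del_prob = 0), seed = 1)
    f <- pm$events$freq / sum(pm$events$freq)
    c(mh = sum(f * pm$events$mh), abssize = abs(sum(f * pm$events$size)))
  }, numeric(2))
  expect_true(all(diff(stats_at["mh", ]) > 0))
  expect_true(all(diff(stats_at["abssize", ]) > 0))
})

test_that("read simulation is deterministic and byte-identical per seed", {
  amp <- fixture_amplicon()
  model <- sample_profile(amp, genotype_effect("c", role = "control"),
                          seed = 1)
  r1 <- sample_reads(model, amp, depth = 200, error_rate = 0.001, seed = 9)
  r2 <- sample_reads(model, amp, depth = 200, error_rate = 0.001, seed = 9)
  expect_identical(as.character(r1), as.character(r2))

  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))

  expect_error(sample_reads(model, amp, depth = 0, seed = 1), "depth")
})

test_that("count-level sampling matches read-level sampling in expectation", {
  amp <- fixture_amplicon()
  model <- sample_profile(amp, genotype_effect("c", role = "control"),
                          seed = 1)
  prof <- sample_profile_counts(model, depth = 20000, seed = 5)
  # visible-class frequencies should track the model within multinomial noise
  f <- profile_freq(prof)
  expf <- model$events$freq / sum(model$events$freq)
  names(expf) <- model$events$signature
  shared <- intersect(names(f), names(expf))
  expect_gt(length(shared), 8)
  expect_lt(max(abs(f[shared] - expf[shared])), 0.02)
  # mutated fraction ~ efficiency net of large-deletion loss
  eff <- model$effect$efficiency
  expected_mut <- eff * sum(model$events$freq) /
    (1 - eff * model$large_del_prob)
  expect_equal(prof$mutated_fraction, expected_mut, tolerance = 0.05)
})

test_that("flow simulation has the promised mean, batch and bounds", {
  effs <- cohort_effects(n_control = 4, n_nhej = 2, n_mmej = 2,
                         jitter_sd = 0, seed = 1)

  # noiseless plates equal 100 * large_del_prob exactly
  fs0 <- simulate_flow(effs, n_plates = 2, batch_sd = 0, noise_sd = 0,
                       seed = 1)
  ldp <- vapply(effs, `[[`, numeric(1), "large_del_prob")
  del_plates <- fs0$meta$plate[fs0$meta$condition == "del"]
  for (pl in del_plates) {
    expect_equal(unname(fs0$matrix[, pl]), unname(100 * ldp))
  }

  # between-plate variance of column means tracks batch_sd^2 (Monte Carlo)
  fs <- simulate_flow(effs, n_plates = 500, batch_sd = 5, noise_sd = 0,
                      seed = 2, conditions = "del")
  expect_equal(var(colMeans(fs$matrix)), 25, tolerance = 0.2 * 25)

  # truncation to [0, 100]
  effs0 <- lapply(effs, function(e) {
    e$large_del_prob <- 0; e
  })
  fs3 <- simulate_flow(effs0, n_plates = 3, batch_sd = 0, noise_sd = 10,
                       seed = 3, conditions = "del")
  expect_true(all(fs3$matrix >= 0))

  expect_error(simulate_flow(effs, n_plates = 1, seed = 1), "2 plates")
  expect_error(simulate_flow(effs[5:8], n_plates = 2, seed = 1), "control")
})

test_that("stage seeds derive deterministically and stay below 2^31", {
  s1 <- derive_seed(123L, "reads")
  expect_identical(s1, derive_seed(123L, "reads"))
  expect_false(s1 == derive_seed(123L, "flow"))
  expect_false(s1 == derive_seed(124L, "reads"))
  expect_lt(derive_seed(2^31 - 1, "x"), 2^31)
  expect_gte(derive_seed(0L, "x"), 1L)
})
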