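test_that("profile construction aggregates calls and tracks reference reads", {
  calls <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    signature = c(rep("REF", 50), rep("D2_L-2C1R2", 25), rep("I1_L-1C1R0", 25)),
    stringsAsFactors = FALSE
  )
  p <- build_profile(calls, "s1")
  expect_equal(p$mutated_fraction, 0.5)
  f <- profile_freq(p)
  expect_equal(unname(f["D2_L-2C1R2"]), 0.5)
  expect_equal(unname(f["I1_L-1C1R0"]), 0.5)
  expect_equal(p$total_reads, 100)

  expect_error(build_profile(calls[0, ]), "no reads")

  # duplicate signatures merge
  p2 <- indel_profile(c("D2_L-2C1R2" = 10, "D2_L-2C1R2" = 10), 0, "s2")
  expect_equal(unname(p2$counts["D2_L-2C1R2"]), 20)
  expect_equal(length(p2$counts), 1L)
})

test_that("large-loss filter is strict at the boundary and idempotent", {
  p <- indel_profile(c("D151_L-80C2R74" = 5, "D150_L-80C2R73" = 5,
                       "D2_L-2C1R2" = 90), 100, "s")
  f1 <- filter_large_loss(p, max_loss = 150)
  expect_false("D151_L-80C2R74" %in% names(f1$counts))
  expect_true("D150_L-80C2R73" %in% names(f1$counts))
  expect_equal(attr(f1, "removed_reads"), 5)

  f2 <- filter_large_loss(f1, max_loss = 150)
  expect_identical(f1$counts, f2$counts)
  expect_equal(attr(f2, "removed_reads"), 0)

  # profile with no deletions is unchanged
  pi <- indel_profile(c("I5_L-1C0R0" = 10), 5, "s")
  expect_identical(filter_large_loss(pi)$counts, pi$counts)

  # everything filtered: flagged
  pd <- indel_profile(c("D200_L-110C2R93" = 10), 0, "s")
  expect_warning(filter_large_loss(pd), "all mutated reads")
})

test_that("read-count filter drops samples strictly below the minimum", {
  mk <- function(total, id) {
    indel_profile(c("D2_L-2C1R2" = total - 10), ref_reads = 10,
                  sample_id = id)
  }
  profs <- list(a = mk(399, "a"), b = mk(400, "b"), c = mk(1000, "c"))
  kept <- filter_min_reads(profs, min_reads = 400)
  expect_setequal(names(kept), c("b", "c"))
  expect_equal(attr(kept, "dropped"), c(a = "a"))

  # all retained when everything passes
  expect_length(filter_min_reads(profs[2:3], 400), 2L)

  # warning when a clone x guide group loses every sample
  expect_warning(
    filter_min_reads(profs, 400, groups = c("g1", "g2", "g2")),
    "g1")
})

test_that("downsampling is exact, without replacement and unbiased", {
  p <- indel_profile(c("D2_L-2C1R2" = 600, "I1_L-1C1R0" = 300), 300, "s")
  d <- downsample_profile(p, depth = 450, seed = 1)
  expect_equal(d$total_reads, 450)
  # never introduces unseen signatures; counts bounded by originals
  expect_true(all(names(d$counts) %in% names(p$counts)))
  expect_true(all(d$counts <= p$counts[names(d$counts)]))
  expect_lte(d$ref_reads, p$ref_reads)

  # identity at depth == total
  expect_identical(downsample_profile(p, depth = p$total_reads)$counts,
                   p$counts)
  expect_error(downsample_profile(p, depth = 2000), "fewer")

  # expectation preserved (hypergeometric mean): freq(D2) over seeds
  f0 <- profile_freq(p)[["D2_L-2C1R2"]]
  fs <- vapply(1:400, function(s) {
    profile_freq(downsample_profile(p, 450, seed = s))[["D2_L-2C1R2"]]
  }, numeric(1))
  se <- sd(fs) / sqrt(length(fs))
  expect_lt(abs(mean(fs) - f0), 3 * se + 1e-12)
})

test_that("size aggregation pools tails and conserves mass", {
  p <- indel_profile(c("D35_L-20C2R18" = 1), 0, "s")
  agg <- aggregate_by_size(p)
  expect_equal(unname(agg[["-30"]]), 1)

  p2 <- indel_profile(c("I1_L-1C1R0" = 10), 0, "s")
  expect_equal(unname(aggregate_by_size(p2)[["1"]]), 1)

  for (s in 1:5) {
    pr <- random_profile(s)
    expect_equal(sum(aggregate_by_size(pr)), 1, tolerance = 1e-12)
  }
})

test_that("profile summaries are frequency-weighted and mixture-linear", {
  p <- indel_profile(c("D2_L-2C1R2" = 50, "I1_L-1C1R0" = 50), 0, "s")
  sm <- summarize_profile(p)
  expect_equal(sm$mean_indel_size, -0.5)

  p2 <- indel_profile(c("D10_L-13C2R0" = 10), 0, "s")
  expect_equal(summarize_profile(p2)$mean_mh, 2)

  # pure-REF sample: flagged empty summary
  pref <- indel_profile(setNames(numeric(0), character(0)), 100, "ref_only")
  expect_true(summarize_profile(pref)$empty)

  # linearity: summary of a lambda-mixture equals mixed summaries
  a <- random_profile(11); b <- random_profile(12)
  lambda <- 0.3
  fa <- profile_freq(a); fb <- profile_freq(b)
  mixed <- c(fa * lambda, fb * (1 - lambda))
  pm <- indel_profile(1e6 * mixed, 0, "mix") # counts proportional to mix
  sa <- summarize_profile(a); sb <- summarize_profile(b)
  smix <- summarize_profile(pm)
  expect_equal(smix$mean_indel_size,
               lambda * sa$mean_indel_size + (1 - lambda) * sb$mean_indel_size,
               tolerance = 1e-9)
  expect_equal(smix$mean_mh,
               lambda * sa$mean_mh + (1 - lambda) * sb$mean_mh,
               tolerance = 1e-9)
})

test_that("per-indel frequency changes follow the relative-change scale", {
  ctrl <- indel_profile(c("D2_L-2C1R2" = 50, "I1_L-1C1R0" = 50), 0, "ctrl")
  # complete loss is -100%
  s0 <- indel_profile(c("I1_L-1C1R0" = 100), 0, "s0")
  chg <- indel_frequency_change(s0, ctrl)
  expect_equal(chg$change_pct[chg$signature == "D2_L-2C1R2"], -100)
  # equal frequency is 0%
  expect_equal(indel_frequency_change(ctrl, ctrl)$change_pct, c(0, 0))
  # doubled frequency is +100%
  ctrl2 <- indel_profile(c("D2_L-2C1R2" = 10, "I1_L-1C1R0" = 90), 0, "c2")
  s2 <- indel_profile(c("D2_L-2C1R2" = 20, "I1_L-1C1R0" = 80), 0, "s2")
  chg2 <- indel_frequency_change(s2, ctrl2)
  expect_equal(chg2$change_pct[chg2$signature == "D2_L-2C1R2"], 100)
  # rare control indels are excluded
  ctrl3 <- indel_profile(c("D2_L-2C1R2" = 1, "I1_L-1C1R0" = 999), 0, "c3")
  chg3 <- indel_frequency_change(s2, ctrl3, min_control_freq = 0.003)
  expect_false("D2_L-2C1R2" %in% chg3$signature)
})
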