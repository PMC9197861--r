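# Shared fixtures and independent oracles, built in code at test time.

fixture_amplicon <- function(seed = 1L, length = 283L) {
  generate_amplicon(length, gc = 0.5, seed = seed)
}

# Exhaustive placement oracle for deletion microhomology: the number of
# equal-size deletion intervals producing the identical mutant string,
# minus one. Independent of the fast flank-extension implementation.
mh_oracle <- function(sequence, start, end) {
  size <- end - start
  n <- nchar(sequence)
  starts <- 0:(n - size)
  mutants <- vapply(starts, function(s) {
    paste0(substr(sequence, 1L, s), substr(sequence, s + size + 1L, n))
  }, character(1))
  sum(mutants == mutants[starts == start]) - 1L
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A random indel profile over synthetic signatures (counts).
random_profile <- function(seed, n_classes = 10L, total = 1000L,
                           sample_id = paste0("rnd", seed)) {
  set.seed(seed)
  sizes <- sample(1:30, n_classes, replace = TRUE)
  kinds <- sample(c("D", "I"), n_classes, replace = TRUE, prob = c(0.7, 0.3))
  mh <- ifelse(kinds == "I", 0L, sample(0:3, n_classes, replace = TRUE))
  left <- -sample(1:15, n_classes, replace = TRUE)
  right <- ifelse(kinds == "D", left + sizes + mh + 1L, left + 1L)
  sig <- sprintf("%s%d_L%dC%dR%d", kinds, sizes, left, mh, right)
  keep <- !duplicated(sig)
  counts <- as.numeric(rmultinom(1, total, runif(sum(keep)) + 0.05))
  indel_profile(setNames(counts, sig[keep]), ref_reads = 100,
                sample_id = sample_id)
}

# Cohort of count-level profiles for divergence simulations: `n_controls`
# controls labelled first, all samples drawn from the models given per clone.
simulate_cohort_profiles <- function(models, replicates, depth, seed) {
  profiles <- list()
  replicate_map <- character()
  for (i in seq_along(models)) {
    clone <- models[[i]]$effect$clone_id
    for (r in seq_len(replicates)) {
      sid <- sprintf("%s_rep%d", clone, r)
      profiles[[sid]] <- sample_profile_counts(
        models[[i]], depth = depth,
        seed = derive_seed(seed, paste0("s:", sid)), sample_id = sid)
      replicate_map[sid] <- clone
    }
  }
  list(profiles = profiles, replicate_map = replicate_map)
}
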