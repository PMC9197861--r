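#' Run configuration for the end-to-end synthetic screen
#'
#' Bundles every threshold of the analysis with the simulation sizes. The
#' analysis thresholds default to the assay's standard values: deletions
#' losing more than 150 bp are filtered, samples need at least 400 remaining
#' reads, optional downsampling to 450 reads, per-replicate FDR threshold
#' 0.01, per-indel reporting floor 0.003, KL pseudocount 0.5.
#'
#' @param seed Root seed for every stochastic stage.
#' @param n_control,n_nhej,n_mmej Cohort composition (see [cohort_effects()]).
#' @param n_replicates Sequencing replicates per clone.
#' @param depth Reads per sample.
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @param amplicon_length,gc Amplicon geometry.
#' @param max_loss,min_reads,downsample_depth,alpha,min_control_freq,pseudocount
#'   Analysis thresholds; `downsample_depth = NULL` disables downsampling.
#' @param n_plates,batch_sd,noise_sd Flow-screen structure.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_control = 12L, n_nhej = 9L, n_mmej = 9L,
                       n_replicates = 2L, depth = 1000L, error_rate = 0.001,
                       amplicon_length = 283L, gc = 0.5,
                       max_loss = 150L, min_reads = 400L,
                       downsample_depth = NULL, alpha = 0.01,
                       min_control_freq = 0.003, pseudocount = 0.5,
                       n_plates = 4L, batch_sd = 5, noise_sd = 2) {
  cfg <- as.list(environment())
  thresholds <- c("max_loss", "min_reads", "alpha", "min_control_freq",
                  "pseudocount")
  bad <- thresholds[vapply(cfg[thresholds], function(v) v <= 0, logical(1))]
  if (length(bad)) stop("thresholds must be positive: ",
                        paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Run the full synthetic screen end to end
#'
#' Simulates a cohort of repair-deficient clones and executes both assay
#' arms: the sequencing arm (reads -> signature calls -> filtered profiles ->
#' KL divergence -> MDS -> control-null significance) and the flow arm
#' (plate matrix -> plate z-scores -> rank-2 PCA regression ->
#' control-referenced z-scores -> deletion/mutagenesis indices), then ties
#' them together with the cross-assay association (per-clone mean
#' microhomology and mean indel size versus the large-deletion score). Every
#' filter logs what it removed; rerunning with the same config is
#' deterministic.
#'
#' @param config A `run_config`.
#' @param outdir Optional directory: when given, profiles, tables and ground
#'   truth are written there as TSV/JSON/FASTA.
#' @return List with `amplicon`, `effects`, `profiles`, `summaries`,
#'   `significance`, `flow` (`control_z`, `indices`), `association` and
#'   `truth`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  amp <- generate_amplicon(config$amplicon_length, config$gc,
                           seed = derive_seed(seed, "amp"))
  effects <- cohort_effects(config$n_control, config$n_nhej, config$n_mmej,
                            seed = derive_seed(seed, "effects"))
  clone_ids <- vapply(effects, `[[`, character(1), "clone_id")
  control_ids <- clone_ids[vapply(effects, `[[`, character(1), "role") ==
                             "control"]

  # --- sequencing arm ---
  profiles <- list()
  replicate_map <- character()
  for (ef in effects) {
    model <- sample_profile(amp, ef, seed = derive_seed(seed, "classes"))
    for (r in seq_len(config$n_replicates)) {
      sid <- sprintf("%s_rep%d", ef$clone_id, r)
      reads <- sample_reads(model, amp, depth = config$depth,
                            error_rate = config$error_rate,
                            seed = derive_seed(seed, paste0("reads:", sid)))
      calls <- call_reads(reads, amp)
      prof <- filter_large_loss(build_profile(calls, sample_id = sid),
                                max_loss = config$max_loss)
      profiles[[sid]] <- prof
      replicate_map[sid] <- ef$clone_id
    }
  }
  profiles <- filter_min_reads(profiles, min_reads = config$min_reads,
                               groups = unname(replicate_map[names(profiles)]))
  if (!is.null(config$downsample_depth)) {
    profiles <- lapply(profiles, downsample_profile,
                       depth = config$downsample_depth,
                       seed = derive_seed(seed, "downsample"))
  }
  replicate_map <- replicate_map[names(profiles)]

  km <- kl_matrix(profiles, pseudocount = config$pseudocount)
  emb <- classical_mds(km, k = 2L)
  control_samples <- names(replicate_map)[replicate_map %in% control_ids]
  null <- control_null(emb, control_samples)
  pv <- divergence_pvalues(emb, null)
  sig <- call_significant(pv, replicate_map, alpha = config$alpha)

  summaries <- lapply(profiles, summarize_profile)
  summary_df <- data.frame(
    sample_id = names(summaries),
    clone = unname(replicate_map[names(summaries)]),
    mean_indel_size = vapply(summaries, `[[`, numeric(1), "mean_indel_size"),
    mean_mh = vapply(summaries, `[[`, numeric(1), "mean_mh"),
    mutated_fraction = vapply(summaries, `[[`, numeric(1),
                              "mutated_fraction"),
    row.names = NULL, stringsAsFactors = FALSE
  )

  # --- flow arm ---
  fs <- simulate_flow(effects, n_plates = config$n_plates,
                      batch_sd = config$batch_sd, noise_sd = config$noise_sd,
                      seed = derive_seed(seed, "flowsim"))
  cz <- control_z(pca_regress(plate_zscores(fs$matrix)), control_ids,
                  stats::setNames(fs$meta$condition, fs$meta$plate))
  indices <- deletion_vs_mutagenesis(cz, control_ids)

  # --- cross-assay association ---
  clone_mh <- tapply(summary_df$mean_mh, summary_df$clone, mean)
  clone_size <- tapply(summary_df$mean_indel_size, summary_df$clone, mean)
  shared <- intersect(names(clone_mh), rownames(cz))
  assoc <- list(
    mh_vs_deletion = fit_line(as.numeric(clone_mh[shared]),
                              as.numeric(cz[shared, "del"])),
    size_vs_mh = fit_line(as.numeric(clone_size[shared]),
                          as.numeric(clone_mh[shared])),
    nested = nested_model_test(
      as.numeric(cz[shared, "del"]),
      x_reduced = cbind(mh = as.numeric(clone_mh[shared])),
      x_full = cbind(mh = as.numeric(clone_mh[shared]),
                     size = as.numeric(clone_size[shared])))
  )

  truth <- list(
    seed = as.integer(seed),
    effects = lapply(effects, unclass),
    plate_offsets = as.list(fs$truth$plate_offsets)
  )

  res <- list(amplicon = amp, effects = effects, profiles = profiles,
              summaries = summary_df, kl = km, embedding = emb,
              significance = sig,
              flow = list(sim = fs, control_z = cz, indices = indices),
              association = assoc, truth = truth,
              replicate_map = replicate_map)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(amp, file.path(outdir, "amplicon.fa"))
    for (sid in names(profiles)) {
      write_profile_tsv(profiles[[sid]],
                        file.path(outdir, paste0("profile_", sid, ".tsv")))
    }
    write_tsv(summary_df, file.path(outdir, "profile_summaries.tsv"))
    write_tsv(sig$samples, file.path(outdir, "significance_samples.tsv"))
    write_tsv(sig$clones, file.path(outdir, "significance_clones.tsv"))
    write_tsv(indices$indices, file.path(outdir, "flow_indices.tsv"))
    write_truth_json(truth, file.path(outdir, "truth.json"))
  }
  res
}
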