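#!/usr/bin/env Rscript
# Stage 1: simulate the raw data for both assay arms.
#
# Generates the 283 bp amplicon around the cut site, a cohort of control,
# NHEJ-deficient and MMEJ-deficient clones, per-sample amplicon reads
# (2 replicates per clone) and the plate-structured flow-cytometry screen.
# Ground truth is exported for the recovery checks in later stages.

suppressPackageStartupMessages(library(indelscope))

seed <- 20260926L
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

amp <- generate_amplicon(283, gc = 0.5, seed = derive_seed(seed, "amp"))
write_fasta(amp, file.path(outdir, "amplicon.fa"))
message("amplicon: ", amp$id, " (", amp$length, " bp, cut at ",
        amp$cut_index, ")")

# sequencing cohort kept small (12 clones x 2 replicates at depth 800) so the
# read-level caller stage stays quick; the flow arm uses the full 30 clones
seq_effects <- cohort_effects(n_control = 6L, n_nhej = 3L, n_mmej = 3L,
                              seed = derive_seed(seed, "seq_cohort"))
flow_effects <- cohort_effects(seed = derive_seed(seed, "flow_cohort"))

meta <- data.frame(sample_id = character(), clone = character(),
                   role = character(), fastq = character())
for (ef in seq_effects) {
  model <- sample_profile(amp, ef, seed = derive_seed(seed, "classes"))
  for (r in 1:2) {
    sid <- sprintf("%s_rep%d", ef$clone_id, r)
    reads <- sample_reads(model, amp, depth = 800, error_rate = 0.001,
                          seed = derive_seed(seed, paste0("reads:", sid)))
    fq <- file.path(outdir, paste0(sid, ".fq"))
    write_fastq(reads, fq)
    meta <- rbind(meta, data.frame(sample_id = sid, clone = ef$clone_id,
                                   role = ef$role, fastq = fq))
  }
}
write_tsv(meta, file.path(outdir, "samples.tsv"))
message(nrow(meta), " read sets written (depth 800, error rate 0.001)")

fs <- simulate_flow(flow_effects, n_plates = 4, batch_sd = 5, noise_sd = 2,
                    seed = derive_seed(seed, "flow"))
write_tsv(cbind(clone = rownames(fs$matrix), as.data.frame(fs$matrix)),
          file.path(outdir, "flow_matrix.tsv"))
write_tsv(fs$meta, file.path(outdir, "flow_meta.tsv"))
message("flow screen: ", nrow(fs$matrix), " clones x ", ncol(fs$matrix),
        " plates")

truth <- list(
  seed = seed,
  seq_effects = lapply(seq_effects, unclass),
  flow_effects = lapply(flow_effects, unclass),
  plate_offsets = as.list(fs$truth$plate_offsets)
)
write_truth_json(truth, file.path(outdir, "truth.json"))
message("ground truth exported to ", file.path(outdir, "truth.json"))
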