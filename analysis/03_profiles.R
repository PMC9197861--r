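#!/usr/bin/env Rscript
# Stage 3: build, filter and summarize indel profiles.
#
# Per-sample signature calls become count profiles; deletions losing more
# than 150 bp are filtered (primer-dimer guard), samples with fewer than 400
# remaining reads are dropped, and per-sample summaries (mean signed indel
# size, mean microhomology, mutated fraction) are tabulated. A pooled control
# profile supports the per-indel relative-change table.

suppressPackageStartupMessages(library(indelscope))

callsdir <- "results/calls"
outdir <- "results/profiles"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

meta <- read_tsv("results/data/samples.tsv")
profiles <- list()
for (i in seq_len(nrow(meta))) {
  calls <- read_tsv(file.path(callsdir, paste0(meta$sample_id[i],
                                               "_calls.tsv")))
  prof <- build_profile(calls, sample_id = meta$sample_id[i])
  profiles[[meta$sample_id[i]]] <- filter_large_loss(prof, max_loss = 150)
}
profiles <- filter_min_reads(profiles, min_reads = 400,
                             groups = meta$clone[match(names(profiles),
                                                       meta$sample_id)])
dropped <- attr(profiles, "dropped")
message(length(profiles), " samples retained, ",
        length(dropped), " dropped by the 400-read rule")

for (sid in names(profiles)) {
  write_profile_tsv(profiles[[sid]], file.path(outdir, paste0(sid, ".tsv")))
}

summaries <- do.call(rbind, lapply(names(profiles), function(sid) {
  s <- summarize_profile(profiles[[sid]])
  data.frame(sample_id = sid,
             clone = meta$clone[match(sid, meta$sample_id)],
             role = meta$role[match(sid, meta$sample_id)],
             mean_indel_size = s$mean_indel_size, mean_mh = s$mean_mh,
             mutated_fraction = s$mutated_fraction)
}))
write_tsv(summaries, file.path(outdir, "profile_summaries.tsv"))

ctl_ids <- names(profiles)[summaries$role == "control"]
pooled <- pool_profiles(profiles[ctl_ids], sample_id = "pooled_controls")
write_profile_tsv(pooled, file.path(outdir, "pooled_controls.tsv"))

# per-indel change vs pooled controls, for indels >= 0.3% in controls
for (sid in setdiff(names(profiles), ctl_ids)) {
  chg <- indel_frequency_change(profiles[[sid]], pooled,
                                min_control_freq = 0.003)
  write_tsv(chg, file.path(outdir, paste0(sid, "_vs_controls.tsv")))
}

# size histogram of the pooled controls (display convention: tails pooled)
hist <- aggregate_by_size(pooled)
write_tsv(data.frame(size = as.integer(names(hist)), freq = as.numeric(hist)),
          file.path(outdir, "pooled_controls_size_histogram.tsv"))
message("mean control indel size ",
        sprintf("%.2f", mean(summaries$mean_indel_size[summaries$role ==
                                                         "control"])),
        " bp; mean MH ",
        sprintf("%.2f", mean(summaries$mean_mh[summaries$role == "control"])),
        " bp")
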