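#!/usr/bin/env Rscript
# Stage 6: cross-assay association.
#
# Links the sequencing arm's per-clone profile summaries to the generative
# large-deletion truth (the flow arm measures the same quantity with noise):
# squared Pearson correlations for mean microhomology and mean indel size,
# the OLS slope coupling MH to indel size, and a chi-squared test on nested
# linear models asking whether indel size adds information beyond MH.

suppressPackageStartupMessages(library(indelscope))

outdir <- "results/association"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

sm <- read_tsv("results/profiles/profile_summaries.tsv")
truth <- read_truth_json("results/data/truth.json")
ldp <- setNames(truth$seq_effects$large_del_prob,
                truth$seq_effects$clone_id)

clone_mh <- tapply(sm$mean_mh, sm$clone, mean)
clone_size <- tapply(sm$mean_indel_size, sm$clone, mean)
clones <- intersect(names(clone_mh), names(ldp))

r2_mh <- pearson_r2(ldp[clones], clone_mh[clones])
r2_size <- pearson_r2(ldp[clones], clone_size[clones])
size_mh <- fit_line(clone_size[clones], clone_mh[clones])
nested <- nested_model_test(
  100 * ldp[clones],
  x_reduced = cbind(mh = as.numeric(clone_mh[clones])),
  x_full = cbind(mh = as.numeric(clone_mh[clones]),
                 size = as.numeric(clone_size[clones])))

res <- data.frame(
  quantity = c("r2_mh_vs_large_deletion", "r2_size_vs_large_deletion",
               "slope_mh_per_bp_size", "bp_size_per_bp_mh",
               "nested_p_value", "nested_deviance_delta",
               "nested_df_full", "nested_df_reduced"),
  value = c(r2_mh, r2_size, size_mh$slope, 1 / size_mh$slope,
            nested$p_value, nested$deviance_delta,
            nested$df_pair[["full"]], nested$df_pair[["reduced"]])
)
write_tsv(res, file.path(outdir, "association.tsv"))

message(sprintf("R2(mean MH, large-deletion prob)   = %.1f%%", 100 * r2_mh))
message(sprintf("R2(mean size, large-deletion prob) = %.1f%%", 100 * r2_size))
message(sprintf("MH-size coupling: 1 bp more MH per %.1f bp of indel size",
                abs(1 / size_mh$slope)))
message(sprintf(paste0("nested models (MH alone vs MH + size): p = %.3f, ",
                       "deviance %.3f, residual df = %d, %d"),
                nested$p_value, nested$deviance_delta,
                nested$df_pair[["full"]], nested$df_pair[["reduced"]]))
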