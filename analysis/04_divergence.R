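#!/usr/bin/env Rscript
# Stage 4: which clones' indel profiles differ significantly from controls?
#
# Pairwise symmetrized KL divergence over filtered profiles, classical MDS to
# two dimensions, a bivariate-normal null fitted to the control samples,
# chi-squared (df = 2) p-values from squared Mahalanobis distance, BH
# correction across all samples, and a clone call that requires every
# replicate to reach FDR-corrected p < 0.01.

suppressPackageStartupMessages(library(indelscope))

profdir <- "results/profiles"
outdir <- "results/divergence"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

meta <- read_tsv(file.path(profdir, "profile_summaries.tsv"))
profiles <- setNames(
  lapply(meta$sample_id, function(sid) {
    read_profile_tsv(file.path(profdir, paste0(sid, ".tsv")))
  }), meta$sample_id)
rmap <- setNames(meta$clone, meta$sample_id)
control_clones <- unique(meta$clone[meta$role == "control"])

km <- kl_matrix(profiles, pseudocount = 0.5)
write_tsv(cbind(sample_id = rownames(km), as.data.frame(km)),
          file.path(outdir, "kl_matrix.tsv"))

st <- divergence_test(profiles, rmap, control_clones, alpha = 0.01)
emb <- attr(st, "embedding")
write_tsv(data.frame(sample_id = rownames(emb$points),
                     mds1 = emb$points[, 1], mds2 = emb$points[, 2]),
          file.path(outdir, "mds_embedding.tsv"))
write_tsv(st$samples, file.path(outdir, "significance_samples.tsv"))
write_tsv(st$clones, file.path(outdir, "significance_clones.tsv"))

hits <- st$clones$clone[st$clones$significant &
                          !st$clones$clone %in% control_clones]
message("significant clones (all replicates q < 0.01): ",
        if (length(hits)) paste(hits, collapse = ", ") else "none")
message("control clones flagged: ",
        sum(st$clones$significant & st$clones$clone %in% control_clones))
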