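#!/usr/bin/env Rscript
# Stage 5: normalize the flow screen and score clones.
#
# Per-plate z-scores remove plate offsets and overall mutagenesis magnitude;
# rank-2 PCA regression (plates as observations) keeps only the leading
# guide/day structure; control-referenced z-scores per condition yield the
# large-deletion and mutagenesis indices, with an OLS control trend whose
# residuals isolate deletion-specific effects. Scores are checked against
# the simulator's exported truth.

suppressPackageStartupMessages(library(indelscope))

datadir <- "results/data"
outdir <- "results/flow"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

fm <- read_tsv(file.path(datadir, "flow_matrix.tsv"))
m <- as.matrix(fm[, -1]); rownames(m) <- fm$clone
meta <- read_tsv(file.path(datadir, "flow_meta.tsv"))
truth <- read_truth_json(file.path(datadir, "truth.json"))
eff <- truth$flow_effects # data.frame after JSON simplification
controls <- eff$clone_id[eff$role == "control"]

raw_z <- plate_zscores(m)
regressed <- pca_regress(raw_z, n_pc = 2)
cz <- control_z(regressed, controls, setNames(meta$condition, meta$plate))

write_tsv(cbind(clone = rownames(raw_z), as.data.frame(raw_z)),
          file.path(outdir, "raw_z.tsv"))
write_tsv(cbind(clone = rownames(regressed), as.data.frame(regressed)),
          file.path(outdir, "regressed_z.tsv"))
write_tsv(cbind(clone = rownames(cz), as.data.frame(cz)),
          file.path(outdir, "control_z.tsv"))

di <- deletion_vs_mutagenesis(cz, controls)
write_tsv(di$indices, file.path(outdir, "indices.tsv"))

ldp <- setNames(eff$large_del_prob, eff$clone_id)
rho <- cor(cz[names(ldp), "del"], ldp, method = "spearman")
message(sprintf("Spearman rho (deletion z vs true large-deletion prob): %.3f",
                rho))
message(sprintf("control-trend slope (deletion ~ mutagenesis): %.3f",
                unname(coef(di$fit)["mutagenesis"])))
top <- di$indices[order(-di$indices$residual), ][1:5, ]
message("largest positive deletion-specific residuals: ",
        paste(top$clone, collapse = ", "))
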