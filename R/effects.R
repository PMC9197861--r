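#' Generative repair-pathway effect of one clone
#'
#' Encodes the qualitative model behind the screen: repaired alleles are a
#' mixture of an NHEJ-like component (1 bp insertions, 1-3 bp deletions,
#' little microhomology) and an MMEJ-like component (5-30 bp deletions placed
#' at genuine flanking microhomology). NHEJ prevents large deletions; MMEJ and
#' resection promote them. Unless given explicitly, the probability that an
#' allele is lost to a large deletion (invisible to the short amplicon)
#' couples to the MMEJ share of repair:
#' `large_del_prob = 0.36 * mmej_weight / (nhej_weight + mmej_weight)`,
#' which puts control clones near 12%, NHEJ-deficient clones around 20-25%
#' and MMEJ/resection-deficient clones near 1%.
#'
#' @param clone_id Clone identifier.
#' @param gene_label Gene the clone is deficient for ("" for controls).
#' @param role "control" or "experimental".
#' @param nhej_weight,mmej_weight Non-negative mixture weights; their ratio
#'   sets the balance of the two repair pathways. At least one must be
#'   positive.
#' @param large_del_prob Probability in \[0,1\] that a cut allele becomes a
#'   large deletion; `NULL` uses the coupling above.
#' @param efficiency Fraction of alleles cut, in \[0,1\].
#' @return An object of class `genotype_effect`.
#' @export
genotype_effect <- function(clone_id, gene_label = "", role = "experimental",
                            nhej_weight = 1, mmej_weight = 0.5,
                            large_del_prob = NULL, efficiency = 0.8) {
  stopifnot(role %in% c("control", "experimental"),
            nhej_weight >= 0, mmej_weight >= 0,
            efficiency >= 0, efficiency <= 1)
  if (nhej_weight + mmej_weight <= 0) {
    stop("nhej_weight + mmej_weight must be positive")
  }
  mmej_frac <- mmej_weight / (nhej_weight + mmej_weight)
  if (is.null(large_del_prob)) large_del_prob <- 0.36 * mmej_frac
  stopifnot(large_del_prob >= 0, large_del_prob <= 1)
  structure(
    list(clone_id = clone_id, gene_label = gene_label, role = role,
         nhej_weight = nhej_weight, mmej_weight = mmej_weight,
         large_del_prob = large_del_prob, efficiency = efficiency),
    class = "genotype_effect"
  )
}

#' Default synthetic cohort of repair-deficient clones
#'
#' Builds a screen-sized cohort: control clones (NHEJ:MMEJ weights 1:0.5),
#' NHEJ-deficient clones (MMEJ weight tripled, shifting repair toward larger,
#' microhomology-bearing deletions and more large deletions) and
#' MMEJ-deficient clones (MMEJ weight 0.04, few large deletions). Clone-level
#' biological variability is emulated by log-normal jitter on `mmej_weight`
#' (controls in real screens vary considerably).
#'
#' @param n_control,n_nhej,n_mmej Clones per class (default 12 + 9 + 9 = 30).
#' @param jitter_sd SD of the log-normal jitter on `mmej_weight`; 0 disables.
#' @param seed Integer root seed.
#' @return List of `genotype_effect`, length `n_control + n_nhej + n_mmej`.
#' @export
cohort_effects <- function(n_control = 12L, n_nhej = 9L, n_mmej = 9L,
                           jitter_sd = 0.3, seed = 1L) {
  base <- data.frame(
    class = rep(c("control", "nhej_deficient", "mmej_deficient"),
                c(n_control, n_nhej, n_mmej)),
    mmej = rep(c(0.5, 1.5, 0.04), c(n_control, n_nhej, n_mmej)),
    stringsAsFactors = FALSE
  )
  with_stream(seed, "cohort", {
    jit <- exp(stats::rnorm(nrow(base), 0, jitter_sd))
    lapply(seq_len(nrow(base)), function(i) {
      cls <- base$class[i]
      genotype_effect(
        clone_id = sprintf("%s_%02d", sub("_deficient", "", cls), i),
        gene_label = switch(cls, control = "", nhej_deficient = "NHEJcore",
                            mmej_deficient = "MMEJcore"),
        role = if (cls == "control") "control" else "experimental",
        nhej_weight = 1,
        mmej_weight = base$mmej[i] * jit[i]
      )
    })
  })
}
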