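# indelscope

Profiling of Cas9 double-strand-break repair outcomes from amplicon
sequencing and arrayed flow-cytometry screens.

Repair of a Cas9 cut is a competition between non-homologous end joining
(NHEJ: perfect repair or small indels, little junctional homology) and
resection-dependent, microhomology-mediated end joining (MMEJ: larger
deletions annealed at short repeats, plus *large deletions* that short-range
sequencing cannot see at all). `indelscope` implements the full analysis
chain for screens that map these pathways across panels of
repair-gene-deficient clones:

* **Signature calling** — global affine-gap alignment of amplicon reads and
  canonicalization of every indel into a cut-relative,
  microhomology-annotated signature. A deletion's placement is ambiguous
  when its flanks share sequence; the canonical form is the maximal
  ambiguity interval, written `D{size}_L{left}C{mh}R{right}` (e.g.
  `D10_L-13C2R0`: 10 bp deletion, last unmodified bases 13 left of the cut
  and at the cut, 2 bp of microhomology; `right − left − 1 = size + mh`).
  The microhomology length satisfies `mh + 1 = number of equivalent
  placements`, enforced against an exhaustive oracle.
* **Indel profiles** — per-sample signature spectra with the assay's
  standard filters (deletions losing > 150 bp removed; samples with < 400
  remaining reads dropped; optional exact downsampling to 450 reads by
  hypergeometric draw), size histograms with pooled tails, and summaries
  (mean signed indel size, mean microhomology).
* **Divergence screen** — symmetrized Kullback–Leibler divergence
  `½[KL(P‖Q) + KL(Q‖P)]` over union supports with pseudocount 0.5,
  classical (Torgerson) MDS to two dimensions, a bivariate-normal null
  fitted to control samples, p-values from the χ²₂ tail of squared
  Mahalanobis distances, Benjamini–Hochberg correction across all samples
  of a guide, and a clone call requiring **every** replicate at q < 0.01.
* **Flow screen** — per-plate z-scores of %-positive matrices, rank-2 PCA
  regression (plates as observations) to keep only the leading guide/day
  structure, control-referenced z-scores per condition, and large-deletion
  vs mutagenesis indices with an OLS control trend.
* **Association** — Pearson R², OLS slopes (bp of microhomology per bp of
  indel size) and a χ² test on nested linear models.
* **Synthetic data** — a generator for amplicons, clone genotype effects,
  reads with truth-encoding names, and batch-structured flow plates, used
  by every recovery test.

## Worked example

```r
library(indelscope)

amp <- generate_amplicon(283, gc = 0.5, seed = 1)       # cut mid-amplicon, NGG PAM
eff <- genotype_effect("ctrl", role = "control")        # NHEJ:MMEJ = 1:0.5
model <- sample_profile(amp, eff, seed = 1)             # expected indel classes
reads <- sample_reads(model, amp, depth = 1000, error_rate = 0.001, seed = 4)
calls <- call_reads(reads, amp)                          # one signature per read
head(calls$signature, 3)
#> [1] "REF" "REF" "REF"

prof <- filter_large_loss(build_profile(calls, "ctrl_rep1"))
summarize_profile(prof)
#> <profile_summary> ctrl_rep1: mean size -7.858 bp, mean MH 1.319 bp,
#>   mutated fraction 0.772
```

The negative mean size says deletions dominate; the mean microhomology near
1.3 bp reflects the control balance between NHEJ-like small indels and
MMEJ-like, microhomology-bearing deletions. Truth-encoding read names let
you score the caller directly:

```r
mean(calls$signature == sub(".*truth=", "", names(reads)))
#> [1] 0.999
```

## The analysis workflow

`analysis/` holds the numbered drivers for the complete synthetic screen;
each stage reads the previous stage's tables from `results/` and narrates
what it found:

```sh
Rscript analysis/01_simulate.R      # amplicon, cohort, reads, flow plates, truth
Rscript analysis/02_call_indels.R   # alignment + signature calls per read
Rscript analysis/03_profiles.R      # filters, summaries, per-indel changes
Rscript analysis/04_divergence.R    # KL -> MDS -> control null -> clone calls
Rscript analysis/05_flow_screen.R   # z-scores -> PCA regression -> indices
Rscript analysis/06_association.R   # cross-assay correlations, nested models
```

A run at the default seed detects all six simulated pathway-deficient
clones with no control false positives, recovers the simulated
large-deletion truth with Spearman ρ = 0.97 from the flow arm, and finds
1 bp of additional microhomology per ~25 bp of indel size across clones.
`run_pipeline(run_config(seed = 1))` performs the same chain in one call.

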