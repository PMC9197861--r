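---
title: "Methods: microhomology-annotated indel signatures and repair-pathway screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microhomology-annotated indel signatures and repair-pathway screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Repair of a Cas9-induced double-strand break (DSB) is dominated by two end
joining pathways. Non-homologous end joining (NHEJ) religates the ends,
producing perfect repair or small indels, typically a 1 bp insertion
templated from the base 5' of the blunt cut or deletions of a few bases.
If the break is instead resected, microhomology-mediated end joining (MMEJ)
anneals short identical sequences exposed on both single-stranded ends,
producing larger deletions that carry that microhomology at the junction.
The same resection/MMEJ axis that produces large, MH-bearing small indels
also produces *large deletions* — lesions of hundreds of bases or more that
a short-range amplicon cannot see at all, and that must be read out
independently, e.g. by loss of reporter expression in flow cytometry after
cutting an intron.

`indelscope` implements the complete analysis chain used to map these
pathways with an arrayed library of repair-gene-deficient clones:

1. **Signature calling** — amplicon reads are collapsed into canonical,
   microhomology-annotated indel signatures.
2. **Profile statistics** — per-sample indel spectra with filtering,
   downsampling and summary statistics.
3. **Divergence screen** — which clones' spectra differ from controls
   (symmetrized KL → classical MDS → bivariate-normal control null →
   chi-squared p-values → replicate-consistent FDR calls).
4. **Flow screen** — plate-structured %-positive matrices normalized by
   per-plate z-scores, rank-2 PCA regression and control-referenced
   z-scores.
5. **Association** — correlation and nested-model links between the two
   assay arms.
6. **Synthetic data** — a generator that emulates all of the above with
   exported ground truth, so every stage can be tested by parameter
   recovery.

# Indel signatures and microhomology

## Coordinates and the canonical interval

All signatures are cut-relative: the base immediately 5' of the blunt cut is
position $-1$, the base immediately 3' of it is position $0$; no position is
skipped across the cut. Internally all file coordinates are 0-based,
half-open.

A deletion flanked by repeated sequence is ambiguous: deleting `AGC` from
`TT[AGC]AGCTT` at any of four positions yields the same molecule. The
microhomology (MH) of a deletion $[s, e)$ is $l + r$, where $r$ is the
longest common prefix of the suffixes at $s$ and $e$ and $l$ the longest
common suffix of the prefixes ending at $s$ and $e$; `mh + 1` equals the
number of equivalent placements (this identity is enforced against an
exhaustive enumeration oracle in the tests). The canonical representation is
the *maximal ambiguity interval*: `left` = last unmodified base before the
leftmost placement, `right` = first unmodified base after the rightmost, so
`right - left - 1 = size + mh`. The string form is
`D{size}_L{left}C{mh}R{right}`; for example `D10_L-13C2R0` is a 10 bp
deletion whose last unmodified bases sit 13 left of the cut and at the cut,
with 2 bp of MH mappable at either end.

Insertion MH is the longer of: the longest suffix of the left flank that is
a suffix of the insert, and the longest prefix of the right flank that is a
prefix of the insert (capped at the insert length). When both flanks match,
the maximum is taken — the original pipeline's tie rule is not documented,
so the package fixes this convention and states it. Insertions are
left-aligned before annotation so every equivalent placement maps to one
signature.

Compound junctions (deleted span plus inserted bases) take their kind and
size from the net length change and compute MH on the deleted span only;
a length-neutral compound event carries no net indel and is treated as
reference. Reads with several separate indels are classified by the event
nearest the cut, because the assay's signatures are single-event; the count
of extra events is reported per read.

## Alignment

Reads are aligned end-to-end with affine gap penalties (match $+2$,
mismatch $-2$, gap open $-6$, gap extend $-0.5$) via
`Biostrings::pairwiseAlignment()`. Raw gap placement does not matter:
canonicalization owns placement, so any placement the aligner picks inside
an ambiguity interval yields the identical signature (a tested invariant).
Reads under 30 nt or under 60% identity are flagged unalignable and
excluded with a log entry.

# Profile statistics

Profiles count reads per canonical signature. Frequencies are over *mutated*
reads only; reference reads enter the total and the mutated fraction but not
the spectrum, because the spectrum and the cutting efficiency are separate
quantities. Standard thresholds, all exposed in `run_config()`:

| parameter | default | unit | meaning |
|---|---|---|---|
| `max_loss` | 150 | bp | deletions losing *more* than this are primer-dimer suspects and are removed (strict: D150 stays, D151 goes) |
| `min_reads` | 400 | reads | samples with *fewer* remaining reads are dropped (400 stays, 399 goes) |
| `downsample_depth` | 450 | reads | optional equalization to a lowest common denominator, as a multivariate hypergeometric draw *without* replacement (physical subsampling of reads), landing exactly on the target |
| `min_control_freq` | 0.003 | frequency | per-indel change tables only report indels at or above this frequency in the pooled controls |
| `pseudocount` | 0.5 | counts | KL smoothing (below) |
| `alpha` | 0.01 | FDR | per-replicate significance threshold |

Summaries are the frequency-weighted mean signed indel size (deletions
negative) and mean MH; both are linear in profile mixtures (tested). Size
histograms pool mass beyond $-30$ and $+10$ into tail bins, the standard
display convention. Per-indel changes versus the pooled control profile are
relative: $-100\%$ is complete loss, $+100\%$ a doubled frequency, unbounded
above (any $+100\%$ truncation is display-only).

# The divergence screen

For samples $P, Q$ the dissimilarity is the symmetrized Kullback–Leibler
divergence over the union of their signature supports,

$$ D(P,Q) = \tfrac12\left[\mathrm{KL}(P\|Q) + \mathrm{KL}(Q\|P)\right]
         = \tfrac12 \sum_i (p_i - q_i)\,\ln\frac{p_i}{q_i}, $$

after adding a pseudocount of $0.5$ to every union-support class and
renormalizing. The pseudocount (a Jeffreys-style choice; the upstream
method's exact smoothing is not recoverable) keeps the divergence finite
when one sample misses a class; both it and whether reference reads join
the support are configuration knobs with documented defaults (0.5, and no).

The pairwise KL matrix is embedded by classical (Torgerson) MDS — double
centering of the squared dissimilarities, eigendecomposition, top-$k$
eigenvectors scaled by the square roots of their eigenvalues, $k = 2$. The
raw divergence is treated as the dissimilarity (not its square root);
classical MDS was chosen over stress-based variants because it is
deterministic and exactly testable (it reproduces Euclidean configurations
to numerical precision, a tested property). Negative eigenvalues are
dropped with a warning. MDS axes are defined only up to rotation and sign,
so all downstream statistics use Mahalanobis distances, which are
invariant.

A bivariate normal is fitted to the control samples' coordinates (sample
mean, unbiased covariance; at least three controls, positive-definite
covariance required). For a point drawn from a bivariate normal the squared
Mahalanobis distance to it is $\chi^2_2$, so each sample gets
$p = P(\chi^2_2 > d^2)$. Benjamini–Hochberg correction is applied across all
samples of one guide, controls included — each guide's profile geometry is
its own world, so pooling FDR across guides would mix incomparable
p-value populations. A clone is called significantly different from
controls only if **every** replicate has corrected $q < 0.01$.

## Calibration: what the chi-squared null does and does not guarantee

The control-null chain is exact when the embedded coordinates really are
draws from one bivariate normal estimated without error. Two deviations
matter in practice and are quantified in the package's tests:

* With exact normal coordinates and 12 control samples, the full decision
  rule (chi-squared p, BH across 40 samples, both-replicates rule) flags at
  least one of 14 null clones in only ~2% of cohorts — conservative, as
  intended.
* In a *fully null* cohort, however, the KL matrix has a flat eigenvalue
  spectrum: the top-2 MDS axes are then selection-biased noise directions,
  and samples that happen to drive an axis sit further out than the
  control-fitted normal predicts. In simulations at the study's geometry
  (40 samples, 12 controls, depth 1000) this inflates the fraction of
  cohorts with at least one flagged clone to roughly 7–8%, against the
  5% the rule achieves on exact normal input. This is a property of
  embedding isotropic noise and referring distances to a 12-point normal
  fit, not of the implementation; it is the regime the procedure is *not*
  designed for — in real screens (and in the generator's non-null
  cohorts) genuine between-clone structure dominates the top axes.
  The corresponding acceptance test asserts the idealized 5% bound and is
  expected to fail by this margin; power for a true pathway shift
  (MMEJ weight tripled, depth 5000, two replicates) is ~100%.

# The flow screen

The input is a clones × plates matrix of %-positive cells, a plate being
one replicate of one staining condition (guide × day). The chain:

1. **Per-plate z-scores** — each plate column standardized across clones
   (unbiased SD). This removes plate offsets and the overall magnitude of
   mutagenesis; a constant column is an error, not a silent NaN.
2. **Rank-2 PCA regression** — PCA with *plates as observations and clones
   as features*: the leading components separate plates by guide and
   sampling day, later components carry replicate-batch structure. The
   data are reconstructed from components 1–2 plus the per-clone means;
   a transposed analysis is a documented configuration choice for users
   who disagree with the observation axis. "Regressed z-score" is
   interpreted as this rank-2 reconstruction followed by
   control-referencing — the reconstruction step is not defined explicitly
   upstream, and this reading is deterministic and testable (rank-2 input
   is reproduced exactly; structure orthogonal to the kept components is
   removed, both tested).
3. **Control-referenced z-scores** — per condition, a clone's score is the
   mean of its regressed values over that condition's plates, expressed as
   a z-score against the control clones' mean and SD (controls then have
   mean 0, SD 1 by construction). Whether the original referencing pooled
   days is unstated; per-condition was chosen. A near-zero control SD is
   an error rather than a division.
4. **Indices** — the large-deletion index is the control-z of the
   intronic-guide condition; the mutagenesis index is the control-z of the
   weak exonic-guide condition; an OLS line fitted to controls provides
   residuals that isolate deletion-specific effects from mere efficiency
   differences. The exact upstream definition of these indices is not
   given; this package defines them as the two conditions'
   control-referenced z-scores.

Because control z-scores are referenced to the *measured* control spread
(true biological spread plus well noise), a clone injected at $+5$ true
control-SD is recovered attenuated toward zero — around 4 in expectation at
the default noise, with seed-to-seed spread of roughly ±1; the recovery
tests budget for the attenuation.

# The association stage

Squared Pearson correlations and OLS lines link per-clone profile summaries
(mean MH, mean signed size; slope in bp MH per bp size) to large-deletion
scores. Nested linear models are compared on the deviance scale: the
residual-sum-of-squares difference divided by the full model's dispersion
estimate is referred to $\chi^2_{df_\mathrm{reduced} - df_\mathrm{full}}$ —
the convention that reproduces R's `anova(lm1, lm2, test = "Chisq")`
(cross-checked in a test) and the residual-df bookkeeping of a ~95-sample
screen (93, 92 for 2 vs 3 parameters). A full model that adds no
information returns $p = 1$. No automatic outlier policy: exclusions are an
explicit, documented argument, never a rule.

# The synthetic-data generator

The generator is the package's test bed and defines the study conditions
for every recovery test.

**Clones.** A `genotype_effect` carries NHEJ and MMEJ mixture weights, a
cutting efficiency and a large-deletion probability. Repaired alleles are a
mixture: the NHEJ component is a fixed table — a 1 bp insertion duplicating
the base 5' of the cut (weight 0.35) and deletions of 1–3 bp at the cut
(0.25/0.20/0.20) — and the MMEJ component scans the amplicon for deletion
intervals of 5–30 bp spanning the cut with at least 1 bp of genuine
sequence-supported MH (found with the same MH machinery the caller uses),
sampling 8 classes weighted by MH length. Class selection depends only on
the amplicon and the seed, never on the weights, so expected MH and |size|
are strictly monotone in the MMEJ weight (a tested invariant). With these
defaults even a pure-NHEJ profile is deletion-dominated (expected signed
size < 0), matching real control spectra.

**Coupling to large deletions.** The literature gives no quantitative
generative model linking pathway activity to large-deletion frequency; the
package's choice, made once, is
$P(\text{large deletion}) = 0.36 \cdot w_\mathrm{MMEJ}/(w_\mathrm{NHEJ} + w_\mathrm{MMEJ})$,
which puts control clones (weights 1 : 0.5) at 12%, NHEJ-deficient clones
(MMEJ weight ×3) at ~22% and MMEJ-deficient clones (MMEJ weight 0.04) near
1% — reproducing the observed ordering and approximate scale of a real
screen (~30% / 12% / ~1%). Control clones receive log-normal jitter on the
MMEJ weight (SD 0.3 on the log scale) because real control clones vary
considerably in repair behaviour and mutagenic efficiency. These are
artifact choices for recovery testing, not estimates of biology.

**Reads.** `sample_reads()` draws alleles multinomially — reference with
probability $1-\text{efficiency}$, each visible class with
$\text{efficiency} \times \text{freq}$; large-deletion alleles do not
amplify in short-range PCR and are excluded with renormalization (the two
assay arms see mutually exclusive outcomes, which is the point of the
design). Reads are full edited amplicons with i.i.d. substitution errors;
names carry the generating allele so callers can be scored exactly.
`sample_profile_counts()` skips the read layer for simulation studies where
only the called profile matters. Everything is seeded through one root seed
with per-stage derived streams (`derive_seed()`), so reruns are
byte-identical and partial reruns are stable.

**Flow plates.** Two conditions by default: `del`, %-positive
$= 100 \cdot P(\text{large deletion})$, and `mut`,
$= 100 \cdot \text{efficiency} \times 0.15$ (so default-efficiency controls
read ~12%, a realistic weak-guide readout). Every plate adds one shared
batch offset ($N(0, \text{batch\_sd})$) and each well i.i.d. noise; values
are truncated to $[0, 100]$ rather than resampled — the readout is bounded
and simplicity wins.

**What it does not emulate.** No PCR chimeras or primer dimers, no
sequencing errors *inside* indels, no vector copy-number effects, no cell
growth or fitness, no event-level cytometry (the flow arm starts from
%-positive, as the analysis does). Passing recovery tests therefore show
the statistics recover the generative truth under clean noise models; they
do not certify behaviour under artifacts the generator omits.

# Numerical choices and degenerate inputs

* Deletion intervals must be non-empty and in range; empty profiles, empty
  call sets, all-filtered samples and pure-reference samples return flagged
  empties or errors, never silent zeros.
* MDS eigenvalues within `1e-9` of zero (relative) count as zero; the
  embedding zero-fills dimensions beyond the positive-eigenvalue count with
  a warning.
* Singular control covariance, zero-SD plates and near-zero control SDs are
  errors.
* Alignment identity threshold 0.6; alignment scoring as above; ties in
  insertion placement broken by left-alignment.
* Problem sizes used by tests and the acceptance script: 200 random 60 bp
  sequences for the exhaustive MH oracle; 10,000 draws for chi-squared null
  calibration; 200 null cohorts and 100 power cohorts of 40/14 samples for
  the screen's error rates; a 40-clone, 8-plate flow screen; 30-clone
  cohorts for cross-assay association. These were chosen as the smallest
  sizes at which the Monte-Carlo error is well below the tested margins.

# Known limitations

* The chi-squared null is anti-conservative for fully isotropic null
  cohorts (see calibration section) — in that regime a permutation null
  would be preferable, at the cost of determinism.
* Large deletions are by construction invisible to the sequencing arm;
  the generator's coupling between pathway weights and large-deletion
  probability is a modelling convenience, so cross-assay association tests
  validate recovery of *that* coupling, not biology.
* Strain assignment of alleles requires an external SNP table; the
  synthetic data generates its own and real heterozygous loci without
  informative SNPs yield `unassigned` alleles, which the clone classifier
  treats conservatively.
* The aligner is a global pairwise aligner for amplicon-length reads; it is
  not a general-purpose read mapper and does not detect lesions exceeding
  the amplicon.
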