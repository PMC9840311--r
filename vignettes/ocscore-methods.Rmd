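---
title: "Fragmentomic OC scoring: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmentomic OC scoring: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plasma cell-free DNA (cfDNA) is fragmented by endogenous nucleases around
nucleosomes, so its fragment sizes, end sequences, and genome-wide coverage
carry regulatory and somatic information about the tissues shedding it. In
ovarian-cancer liquid biopsy, the tumor-derived subpopulation (ctDNA) shifts
four measurable feature families relative to healthy plasma:

1. **Fragment size** — ctDNA is shorter than the 167-bp chromatosome-protected
   mono-nucleosomal peak, so the per-megabase ratio of short (90–150 bp) to
   long (151–220 bp) fragments rises, in a position-dependent way.
2. **5'-end motifs** — nucleases have sequence preferences; the 256-dimensional
   frequency profile of the first four reference bases at each 5' fragment
   terminus shifts with disease.
3. **Nucleosome footprints (NF)** — at transcription start sites, coverage dips
   over the nucleosome-depleted region (NDR, −150 to +50 bp relative to the
   TSS in the transcription frame). Expression changes in the tumor deepen or
   flatten that dip for specific genes.
4. **Copy number** — multi-megabase somatic gains and losses tilt binned
   coverage relative to a healthy baseline panel.

`ocscore` implements the full scoring pipeline over these families —
feature extraction from aligned fragment coordinates (BED), a Wilcoxon /
LASSO selection cascade, per-family linear-SVM scorers, logistic stacking
into a "logistic score", and the final **OC score = logistic score + CNV
score** — together with a synthetic cohort generator so that every stage is
testable without sequencing data.

## Feature definitions

* **Motif profile.** Each double-stranded fragment contributes two 5'
  termini: the reference 4-mer at `[start, start+4)` and the reverse
  complement of the 4-mer at `[end-4, end)`. Both ends are counted because a
  double-stranded fragment has two 5' ends; windows containing non-ACGT
  bases or running off a chromosome are skipped, not imputed. Frequencies
  are zero-pseudocount and sum to 1.
* **Fragmentation profile.** The genome (never a Y chromosome) is tiled
  into 1-Mb bins; a fragment belongs to the bin holding its midpoint, so a
  boundary-straddling fragment is counted exactly once. The per-bin ratio
  is `(n_short + 0.5) / (n_long + 0.5)`; the half-count pseudocount keeps
  empty and sparse bins finite and is the package's own device (real
  cohorts at sequencing depth rarely have empty megabase bins).
* **NF score.** For each gene, `NF = (bg_depth − ndr_depth) / bg_depth`,
  with depths measured as fragment-base overlap per bp over the NDR
  (−150/+50, strand-mirrored for minus-strand genes) and the ±2000 bp
  promoter window *minus* the NDR. The relative form makes NF
  depth-independent; `NF = 0` conventionally when the background has no
  coverage, which is exactly what the downstream zero-fraction filter
  screens out. An absolute coverage difference was the other candidate; it
  was rejected because it scales with sequencing depth and would make
  cross-sample rank tests depth-confounded.
* **CNV score.** Depth is counted per 2-kb window by fragment midpoint,
  normalized to mean 1, GC-corrected by dividing by the window's GC-decile
  median depth (deciles under 10 windows merge into a neighbour), and
  z-scored against a healthy panel (per-window mean and sd across ≥5
  training healthy samples, sd floored at `0.05·mean`). Windows with
  `|z| > 3` seed candidate segments, which extend through adjacent windows
  with same-direction `|z| > 1`, tolerating runs of at most 2 windows below
  the extension threshold; merged spans over 2 Mb are emitted and the
  burden is `sum(|mean z| × span in Mb) / 100`. The extension rule is the
  package's reading of "connecting significant windows with adjacent
  windows": requiring *every* window in a multi-megabase event to clear the
  seed threshold would shatter real events, because a 15% depth shift sits
  near `z ≈ 3` per 2-kb window even at high depth, so roughly half the
  windows of a true event would fail a seed-only rule and no event could
  ever span 2 Mb. Seeding at 3, extending at 1, keeps the null clean (a
  false event would need a thousand-window same-sign run, which the tests
  confirm never happens) while making true events contiguous. The score
  constant keeps typical burdens O(1) so the additive OC score is not
  CNV-dominated; the published score equation is not public, so this score
  is a declared stand-in with the same qualitative behaviour (zero under
  the null, increasing in burden).

## Selection and models

The cascade order is fixed and train-only where it is label-dependent:

* NF: drop genes with `NF = 0` in more than 10% of *all* samples (a
  missingness filter, so using the whole cohort leaks no labels), then
  train-set Wilcoxon `p ≥ 0.001`, then LASSO.
* Motifs: train-set Wilcoxon `p ≥ 0.05`, then LASSO.
* Fragmentation bins: LASSO only.
* CNV: never selected or modelled — it enters the OC score directly.

Wilcoxon tests use the Mann–Whitney normal approximation with tie and
continuity corrections (the form that scales to feature screening; at tiny
n it agrees with the exact permutation distribution to a few hundredths,
which the test suite checks explicitly). The LASSO penalty is chosen at
minimum mean cross-validated deviance over a 50-point path with seeded
stratified folds — the permissive choice, consistent with a screening step
that hands tens of features to the SVM, rather than the sparser 1-SE rule.

Per-family scorers are linear-kernel SVMs (high-dimension / low-n regime;
deterministic and calibratable), cost chosen by stratified 10-fold
cross-validated accuracy, decision values mapped to probabilities by a
sigmoid fit on out-of-fold decision values only, and a per-family cutoff at
the accuracy-maximizing train-score threshold (ties resolved toward higher
specificity). The three probabilities are stacked through

\[ Z = b_0 + b_{NF}\,\mathrm{NF} + b_{Frag}\,\mathrm{Fragment} +
b_{Motif}\,\mathrm{Motif}, \qquad
\mathrm{Logistic\ Score} = \frac{e^Z}{1+e^Z}, \]

and the OC score adds the CNV burden. Two integration modes exist:
`"paper"` pins the published coefficients `(−2.48, 2.84, 2.01, 0.56)` and
is provided for formula fidelity — the scale of the original score inputs
was never published, so those coefficients cannot be expected to reproduce
downstream performance — while `"refit"` (the pipeline default) re-fits the
stacking by unpenalized maximum likelihood on training scores, with a small
ridge fallback under perfect separation. Classification uses the
Youden-optimal training cutoff (ties toward higher specificity) with
`score ≥ cutoff ⇒ OC` everywhere.

## The synthetic cohort generator

The generator emulates exactly the statistical structure the pipeline
assumes, with a machine-readable truth set:

* **Genome** — by default three 30-Mb chromosomes (no Y) with smoothly
  drifting regional GC in [0.32, 0.58], 100 TSSs per chromosome on a 6-kb
  grid at least 2 kb from chromosome ends, and planted truth: two CNV
  segments (a 6-Mb gain at ratio 1.5, a 5-Mb loss at 0.6), 30 NDR-altered
  genes, and a ±bias set of 32 4-mers.
* **Lengths** — healthy law: 85% mono-nucleosomal discretized Laplace
  (location 167 bp, scale 14) + 15% di-nucleosomal normal (334, 25); tumor
  law identical but located at 150 bp. The Laplace was chosen over a normal
  for the mono-nucleosomal component because real cfDNA length histograms
  have a sharp single-bp peak: a normal of realistic width is flat on top,
  and its 1-bp histogram mode would be a coin flip among 166–168 at any
  practical sample size, while the Laplace pins the mode at 167 robustly.
* **Placement** — fragment starts are uniform, re-weighted by a nucleosome
  occupancy function around TSSs (190-bp-period sinusoid of amplitude
  0.25, occupancy 0.8 inside the NDR), via joint rejection sampling over
  (start, length). Fragments that would overrun a chromosome end are
  resampled, never clipped.
* **Tumor class** — an OC sample at tumor fraction *f* draws each fragment
  from the tumor law with probability *f* (component counts drawn first,
  then each component rejection-sampled separately, so differing acceptance
  rates cannot distort the mixture). Tumor-law fragments additionally see:
  NDR protection of altered genes multiplied by `1 − depletion_depth`
  (default 0.9), per-region sampling multiplied by planted copy ratios, and
  cut sites re-weighted by the class motif bias (1.3× on the `AC`-prefixed
  16-mer set, 0.75× on the `GG`-prefixed set) at both termini.
* **Cohort** — 100 HC / 59 OC, HC split half/half and OC split 2/3 (by
  ceiling, reproducing a 40/19 split of 59 cases), tumor-fraction strata
  `{0.1, 0.2, 0.3}` cycled over OC samples as a stand-in for stage, with
  one BED per sample, a manifest TSV and a truth JSON. Everything is
  byte-reproducible from the master seed.

The NDR parameters (`ndr_occupancy = 0.8`, `depletion_depth = 0.9`) were
calibrated once so that the per-gene NF contrast between classes is a
detectable effect (standardized effect around 1–2 at a few-hundred-fold
promoter coverage) — i.e., so the generator actually carries the signal the
selection cascade is designed to find; they were then frozen.

**What the generator does not emulate:** GC-dependent coverage bias (the
GC-correction step is exercised on constructed depth vectors instead),
mappability gaps and blacklisted regions, sub-nucleosomal and di-nucleosomal
fine structure beyond the two-component law, 10-bp periodicity of cut
sites, germline CNVs, batch effects, and sequencing error. Passing tests on
synthetic cohorts therefore demonstrate the pipeline's correctness and
internal consistency — not clinical performance, and published cohort
metrics are deliberately not targets.

## Problem sizes and numerical choices

Desk-scale test conditions were chosen once, from power considerations, and
are stated here as the package's own choices:

* The end-to-end cohort runs at 20,000 fragments per sample on the 90-Mb
  default genome. At that depth the motif and fragmentation families
  separate clearly; the per-gene NF statistic is noise-dominated (a 4-kb
  promoter window catches ~0.2 fragments), so the NF block is typically
  empty and its scorer falls back to a constant 0.5 — the honest behaviour
  of the filter cascade at low coverage, and the reason the NF-specific
  tests use compact, promoter-dense genomes at a few-hundred-fold coverage
  where the statistic has power.
* CNV segment recovery is tested at ~800 fragments per 2-kb window: the
  planted 15% shift (ratio 1.5 at f = 0.3) sits near `z ≈ 2.4–3` per
  window, so recovery requires the sampling noise of a window's depth to be
  small against the panel's floored sd. Null specificity is tested at a
  realistic shallow depth, where the same thresholds produce no calls.
* Ties: all thresholds use `≥`; cutoff ties resolve toward higher
  specificity, then the higher cutoff; LASSO and SVM cost ties resolve
  toward the stronger penalty (larger λ via `cv.glmnet`, smaller cost).
* Degenerate inputs: all-identical groups give Wilcoxon p = 1; empty
  selections yield constant-0.5 scorers with warnings rather than errors;
  all-zero depth vectors are rejected; undefined rates (0/0) are reported
  as `NA`, never 0.
* Reproducibility: every stochastic step takes an explicit seed derived
  from the master seed; artifacts carry an md5 configuration hash and
  readers refuse to mix artifacts across configurations.

## Known limitations

* The CNV burden equation is a stand-in (see above); absolute CNV scores
  are not comparable to the published ones.
* Paper-mode integration coefficients are illustrative only, because the
  original score scale is unpublished.
* The subgroup sensitivity analysis keys off simulated tumor-fraction
  strata; no clinical-stage equivalence is claimed.
* Real-data ingestion expects aligned, deduplicated fragment coordinates
  (BED3); alignment and read-level QC are out of scope.
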