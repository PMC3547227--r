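---
title: "Models and methods behind reflQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reflQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflQC)
```

`reflQC` implements the statistical layer of diffraction data
reduction — everything between "integrated intensities with sigmas"
and "a quality table you can put next to another instrument's" — plus
the header-metadata plumbing that makes cross-instrument reprocessing
possible in the first place. This vignette is the package's own
account of the models, the constants, and the design decisions, in
the order a dataset meets them.

## 1. Header metadata and pixel codecs

Vendor image headers rarely carry everything an independent
data-processing program needs. The two parsers normalise line-oriented
text renditions of the R-AXIS image-plate and Bruker CCD header
dialects into one `ImageMetadata` object; the grammars are documented
in `inst/extdata/README.md`. Two deliberate simplifications:

* Headers are treated as **line-oriented ASCII fixtures**. The binary
  layouts of the real formats are not reproduced — only their
  information content, which is what the audit is about.
* Fields the dialect *cannot* express are entered in the
  `missingFields` ledger at parse time with their documented defaults
  in force: the R-AXIS dialect has no gain (default 1.0 ADU/photon),
  no fast/slow pixel-axis convention and no goniometer-layout
  description; neither dialect records the spindle rotation sense
  unless the (often empty) `a4cSpindle` field is populated.

`auditMetadata()` turns that ledger plus the correction-provenance
slots (`CORRECT`/`WARFIL`/`DARK`, relevant for vendor-corrected CCD
images) into a findings table. It is monotone by construction:
removing header information can only add findings.

The pixel codecs implement the two overflow conventions exactly.
Bruker: 1 byte per pixel, value 255 is a sentinel consuming the next
overflow-table entry in raster order, then the baseline offset (4th
`NEXP` field) is subtracted from every pixel; encoding is exact for
any non-negative integer ADU value. R-AXIS: unsigned 16-bit storage
where values ≥ 32768 decode to `(v − 32768) × R`; the scale ratio `R`
travels in the header (`ImhCompression RATIO 8` in the fixtures,
default 8). Values below 32768 and multiples of `R` round-trip
exactly; anything else is encoded to the nearest grid point and
flagged lossy rather than silently truncated.

## 2. Cells, Laue classes, unique reflections

Only orthogonal cells are supported (`1/d² = h²/a² + k²/b² + l²/c²`);
the tetragonal/orthorhombic crystals this package targets need nothing
more, and `dSpacing()` refuses anything else rather than silently
using a wrong metric. The two Laue classes are generated as explicit
integer-matrix groups (validity methods check closure, cardinality
and the presence of −I). The asymmetric-unit representative of an
orbit is its **lexicographic maximum** — a total, convention-free rule
with no possible ties, at the price of not matching any particular
program's ASU choice (irrelevant here: only orbit identity matters).

Completeness denominators are defined at the **Laue level**:
`generateUnique()` does not remove space-group systematic absences.
For a P4₃2₁2-style crystal the absent reflections are a vanishing
fraction of the unique set at the resolutions involved, and defining
completeness against the Laue-unique set keeps the 4/mmm-vs-mmm
comparison internally consistent.

## 3. The synthetic-data generator

`simulateDataset()` produces unmerged observations with the
statistical structure the downstream analysis assumes, and returns
ground truth beside them.

* **Intensities.** Acentric-Wilson: `I_true ~ Exp(mean = C·exp(−2B·s²))`
  with `s = 1/(2d)`. Centric reflections are not distinguished — a
  simplification that leaves every downstream statistic exercised but
  makes the intensity distribution slightly cleaner than real data.
* **Symmetry breaking.** Uniques are enumerated under mmm. For each
  4/mmm-equivalent pair `(h,k,l)/(k,h,l)` the second member is
  `τ·I₁ + (1−τ)·I_indep`. τ = 1 restores exact tetragonal equality;
  τ < 1 preserves the marginal mean but not an exactly exponential
  marginal — acceptable, since only the induced covariance matters to
  the Laue comparison.
* **Noise.** Gaussian with variance
  `K_true·(k₀ + I_true) + (g_true·I_true)²`,
  `k₀ = σ²_dark + σ²_read + σ²_bg`. Gaussian rather than literal
  Poisson counts: the analysis operates in the large-count regime
  where the variance decomposition is the operative model. The
  *delivered* sigma is `√(k₀ + max(I,0))` — the first two terms only,
  mirroring what integration programs report — so error-model
  refinement has something real to recover. Matching delivered to
  true variance term-by-term gives the analytic mapping the tests
  assert: **K ≈ K_true, g ≈ g_true/√K_true**.
* **Multiplicity and incompleteness.** Observations per unique ~
  Poisson(target redundancy), thinned by `pObserve`; observation
  indices are scattered over the mmm orbit by random sign changes so
  merging must really do the ASU mapping.
* **Ice.** Observations inside a contamination window are inflated by
  `excessFactor` with probability `contaminationFraction`, *without*
  sigma inflation, and recorded in a ground-truth column.

Defaults are the study conditions the package emulates: a = b =
78.53, c = 37.36 Å (tetragonal lysozyme habit), B = 15 Å², scale C =
1000 ADU, σ_dark/σ_read/σ_bg = 2/3/5 ADU, target redundancy 20 (home
source data sets of this kind show roughly 12–31), pObserve = 0.98,
τ = 1, ice off. Default ice windows, when switched on, sit at the
three strongest hexagonal-ice spacings 3.90/3.67/3.44 Å with
half-width 0.05 Å; excess factor 10 and contamination fraction 0.3
are package conventions, not measured values. The default resolution
range is 20–2.5 Å, a desk-scale compromise (≈ 8500 mmm-uniques,
≈ 170 000 observations, seconds to simulate and merge); the
Wilson-recovery checks instead use 1.7 Å — the resolution such
crystals actually reach — because slope precision is what that test
is about (≈ 25 000 uniques, ≈ 0.2 Å² standard error on B).

What the generator does **not** emulate: per-image geometry (no
pixels, profiles or orientations), crystal slippage, absorption or
scale drift between batches, centric statistics, and anomalous
differences. Passing tests therefore demonstrate the statistics are
computed correctly and recover planted effects — not that the package
corrects geometric or scaling pathologies of real images.

## 4. Merging and the residuals

Group means are inverse-variance weighted (`w = 1/σ²`), matching
scaling-program practice; `σ_⟨I⟩ = (Σw)^{−1/2}`. R_merge, R_meas and
R_pim use the standard definitions over groups with n ≥ 2, with the
per-term ordering guarantee `R_pim ≤ R_merge ≤ R_meas`. Singleton
groups count toward completeness and redundancy but not the
residuals. Negative merged intensities are permitted (no truncation),
and merged ⟨I/σ⟩ is the per-group mean of `I_mean/σ_mean` — whether a
table's printed value pools observations or averages groups is rarely
stated; the per-group mean is implemented and documented. Shells are
equal-group-count (default 10), ordered from low to high resolution;
the outer shell is the last one, shown in brackets by the report
printer. Shell completeness uses interval edges at midpoints between
adjacent shells so every reference reflection lands in exactly one
shell.

## 5. Error model: χ², (K, g), rejection

The merging χ² is

> χ² = Σ_h (N_h/(N_h−1)) Σ_i (I_i − ⟨I⟩_h)²/σ_i² / Σ_h N_h ,

i.e. the per-observation average of normalised squared deviations
with the N/(N−1) factor undoing the variance absorbed by the group
mean. Written this way its null expectation is exactly 1 for any mix
of group sizes — an averaging convention chosen deliberately, since a
plain per-group average of the bracketed terms would have expectation
≈ mean redundancy rather than 1 and could never be "close to 1" on
healthy data.

`refineErrorModel()` bins groups by ⟨I⟩ (10 equal-count bins) and
minimises `Σ_b (χ²_b(K,g) − 1)²` for
`σ²_new = K[σ² + (g⟨I⟩)²]` over K ∈ [0.1, 10] (log scale),
g ∈ [0, 0.2], by a 17 × 21 grid start refined with L-BFGS-B —
deterministic, derivative-free in effect, and insensitive to the
starting point. Two numerical choices matter:

* **Fixed group means.** ⟨I⟩ is computed once from delivered-sigma
  weights and held fixed during the search. K rescales all weights
  uniformly (no effect on means) and g perturbs them only mildly;
  freezing the means keeps the objective smooth and cheap.
* **Robust bin χ².** Each bin's χ² is estimated as the *median* of
  the per-observation terms rescaled by `qchisq(0.5, 1)` (null
  expectation exactly 1), not their mean. Refinement necessarily runs
  *before* outlier rejection, and a mean-based estimate lets gross
  outliers (ice spikes, zingers) inflate the refined model until the
  subsequent 4σ test is blind to exactly the observations it exists
  to remove; the median ignores them. `robust = FALSE` restores the
  plain mean. On clean data the two agree.

Degenerate input (zero intensity spread) triggers a warning and the
K = 1, g = 0 fallback rather than an optimizer failure.

`rejectOutliers()` iterates (≤ 5 sweeps) flagging observations with
`|I − center|/σ >` 4 (two-sided — symmetric outliers are equally
invalid, although rejection quotes are usually written one-sided).
The consensus center is the **unweighted median** of unflagged
members when ≥ 3 remain, the weighted mean for pairs. The median is
essential, not cosmetic: with ~30 % one-sided contamination a
1/σ²-weighted mean is dragged far enough that *clean* observations
exceed 4σ and simultaneous two-sided flagging can empty the group.
Groups with fewer than 3 unflagged members are not arbitrated (a
discordant pair gives no way to tell which member is wrong), and
groups reduced below two members stop participating.

## 6. Ice rings and exclusions

`detectIceRings()` compares the median group intensity inside a
candidate window (half-width 0.05 Å) with the median of the two
flanking windows of equal width. The raw score divides the shift by
the asymptotic standard error of the window median
(`1.4826·MAD_flank·√(π/(2n_in))`) — the *spread* of Wilson
intensities (CV ≈ 1) would mask any plausible ring, so the standard
error of the location estimate is the right denominator. Because that
asymptotic is approximate and the Wilson falloff tilts the local
baseline, the raw score is then standardised against an empirical
null: the identical statistic evaluated at decoy centers tiled across
the data's resolution range (excluding candidate neighbourhoods), via
`(z − med_decoy)/(1.4826·MAD_decoy)`. The calibrated score is
compared with the threshold (default 4); with fewer than 8 usable
decoys the raw score is used directly. All constants are arguments.

Window exclusion (`applyExclusions()`) is per-resolution-region and
deliberately independent of the per-observation 4σ path, so their
interplay can be studied: on highly redundant data the 4σ stage
removes asymmetric ice contamination by itself and the window stage
finds nothing left — the expected behaviour, visible in the
pipeline's worked example. A `lowResCutoff` flags reflections at very
low scattering angle (beam-stop shadow region) the same way.

## 7. Wilson B and Laue discrimination

`wilsonFit()` performs OLS of `ln⟨I⟩_shell` on shell-mean s² over
equal-count shells (default target 20, floor 3, ≥ 20 groups per
shell), restricted to d ≤ 4.5 Å to stay out of the solvent-dominated
non-Wilson regime. B = −slope/2; shells with non-positive mean
intensity are dropped; fewer than three usable shells is a hard
"fit failed" error rather than a garbage number. The estimator is
equivariant under intensity rescaling (lnC shifts, B unchanged).

`laueCompare()` merges the same observations under both classes and
chooses mmm iff `R_meas(4/mmm) − R_meas(mmm) > 0.02`. R_meas rather
than R_merge because it is multiplicity-corrected: merging under the
finer class halves group sizes, which deflates R_merge even when
nothing is wrong. The 0.02 threshold separates a genuine symmetry
break (R_meas pairs like 0.18 vs 0.13) from the noise-level
differences seen at τ = 1, while remaining far below the gap a real
break produces; it is a package convention, exposed as an argument.

## 8. Pipeline

`runPipeline()` fixes the stage order simulate → merge → refine →
apply → reject → de-ice → Wilson → Laue comparison, writes every
stage's table to disk, logs one structured line per stage, and is
deterministic given the seed. Working statistics (error model,
rejection) run under mmm — correct whatever the true symmetry — and
the final report statistics use the class the comparison selects.
The report mirrors the one-column-per-dataset layout of data-processing
statistics tables, outer-shell values in brackets.

## 9. Known limitations

* No absorption/batch scaling (the upstream scaling program's job),
  no geometric post-refinement, no image-level corrections.
* Only orthogonal cells and the 4/mmm / mmm pair; no general
  space-group machinery, no twinning tests.
* The generator's noise is Gaussian and acentric-only; recovery
  results quantify estimator correctness under the stated model, not
  robustness to every real-data pathology.
* The error-model and ice-detection constants (bin count, decoy
  spacing, thresholds) are documented conventions; all are arguments
  with the defaults stated above.
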