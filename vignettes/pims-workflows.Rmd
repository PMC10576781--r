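---
title: "Models and design choices in pimsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in pimsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pimsr)
```

`pimsr` turns tables of individually detected ions from proteoform imaging
experiments into charge-assigned mass spectra, MS² target lists, acquisition
methods, quantitative region statistics, images and database annotations.
This vignette explains the models behind each stage, the parameters that
matter, what the synthetic generator does and does not emulate, and the
choices made where the procedure was genuinely open.

## From slopes to masses

Each single ion arrives as an (m/z, STORI slope, scan, line) record. The
slope is proportional to charge, with the proportionality constant
(`calib_slope`) coming from an instrument calibration. A point estimate
`round(slope / calib_slope)` is correct with probability
`2Φ(0.5 / (z·cv)) − 1` under multiplicative Gaussian slope noise with
coefficient of variation `cv` — about 98.8% at z = 10 and cv = 0.02, but
dropping fast with charge (about 68% at z = 30). `assign_charge()` therefore
votes: `n_votes` (default 25) resampled slopes, each perturbed by the
estimated relative slope uncertainty, each voting for its rounded charge; an
ion is kept only when the modal vote reaches `vote_agreement` (default 0.8).
This trades completeness for accuracy — ions whose slope falls between two
charges are dropped rather than mis-assigned, which protects every downstream
mass. The slope uncertainty is estimated robustly from the deviations of
`slope/calib_slope` from the nearest integer (a MAD across all ions) unless
supplied. With cv = 0.02 the assigned set is ≥ 95% correct across charges
5–30 while the unassigned fraction is reported per ion via `vote_share`.

Assigned ions get neutral masses by `mass = mz·z − z·M_proton` with
`M_proton = 1.007276466` Da. The round trip mass → (m/z, z) → mass is exact
to better than 1e−9 relative over 1–70 kDa and z = 1–60 (it is pure
floating-point arithmetic), which the tests assert.

## The mass-domain spectrum and feature picking

Neutral masses are converted to a profile spectrum by a Gaussian kernel
density estimate on a uniform grid; each ion contributes exactly unit area
(the kernel is renormalised on the grid), so the spectrum integral equals the
assigned-ion count for any bandwidth — a conservation law the tests check.
The default bandwidth is `max(0.2 Da, 5 ppm × median mass)`: below roughly
30 kDa this resolves the 1.00235 Da isotopologue spacing, above it the
isotopes blur into an envelope, which is the intended behaviour since
per-isotope information stops being meaningful there anyway. The grid step is
`bandwidth / 4`, and peak positions are refined by three-point parabolic
interpolation so grid quantisation (±step/2 ≈ 2.5 ppm at 10 kDa) does not eat
into the ±10 ppm matching budget.

Features are picked iteratively: take the global density maximum, record it,
mask ± `mask_halfwidth`, repeat until the remaining maximum falls below
`rel_abundance_threshold` times the *first* maximum. The automatic mask is
`max(2.5 Da, 2 × isotope-envelope FWHM at the apex mass)`. The envelope FWHM
grows like the square root of mass (about 6 Da at 10 kDa, 13 Da at 40 kDa),
and a mask that does not cover the whole envelope leaves shoulder isotopes at
20–60% of the apex height, which would be re-picked as spurious "features";
masking two FWHM suppresses them below a 1% threshold. The cost is that two
proteoforms closer than the mask (≈ 11 Da at 8.5 kDa) merge into one feature
— a genuine resolution limit of this design, acceptable because common PTM
spacings (14, 42, 80 Da) stay resolvable.

Each apex is converted to a monoisotopic mass using the averagine model: the
standard average-residue composition (C₄.₉₃₈₄H₇.₇₅₈₃N₁.₃₅₇₇O₁.₄₇₇₃S₀.₀₄₁₇
per 111.1254 Da) scaled to the apex mass, hydrogen-adjusted, with the
aggregated isotope distribution computed by exact convolution of the
elemental isotope patterns. The apex is nominally the most abundant isotope,
but sampling noise can shift the observed apex by one isotope near
theoretical ties; a cross-correlation between observed per-isotope ion counts
and the theoretical pattern over ±2 whole-isotope shifts picks the phase, so
the reported monoisotopic mass does not jump by ±1.00235 Da. Reported masses
are monoisotopic by convention (recorded in the feature-table header); the
most-abundant-isotope centroid is available as `apex_mass`.

A feature's member ions are those within ±10 ppm of any of its 5–11 major
isotope masses (5 below 10 kDa scaling linearly to 11 at 40 kDa), and its
`isotope_fit_score` is the cosine between observed per-isotope counts and the
averagine intensities — a simplified isotope-distribution confirmation: 1 for
a perfectly proportional envelope, near 0 for ions piled on an isotope the
model says should be empty. On synthetic surveys with 113 proteoforms spread
over 5–50 kDa at ion budgets 500–20 000, ≥ 95% of true masses are recovered
within ±10 ppm at a 1% picking threshold; the misses are the smallest budgets
at the highest masses, where 500 ions spread over a ~30-isotope envelope drop
below the threshold.

## Target selection

In-silico purification assigns every charge-assigned ion to the feature whose
nearest isotope mass is closest, within ± `inclusion_halfwidth` (default
2 Da — wide enough to absorb envelope drift at survey statistics, narrow
enough not to swallow a neighbouring proteoform; exposed in the config). Ties
break to the lower feature mass. Isolation windows are scored on a candidate
grid (default width 4 Th, step width/8, typical quadrupole settings for
intact proteins) by `target_count × purity^γ` with γ = 1: the product is the
simplest monotone combination of the two stated criteria (abundance and
purity) and γ is exposed for users who want purity to dominate. Ties break to
higher purity, then lower centre m/z, making the choice deterministic; on
small instances the top window provably equals an exhaustive enumeration
(tested). Unassigned ions — noise, charge-voting dropouts — count against
purity, which is honest: they will be co-isolated regardless of why they
lack a label. Every window carries the identity and count of co-isolating
features so fragment spectra can be interpreted with known contaminants.

## Spatial bin allocation

For tissue, a target should be fragmented where it is abundant. The line is
divided into equal bins (one per target by default; 150–300 µm bins with up
to two bins per target in multi-bin mode, 200 µm default as the midpoint of
that range) and per-target spatial profiles are summed per bin. Allocation
then iterates: every unassigned target claims its best remaining bin;
uniquely claimed bins are granted; a contested bin goes to the claimant with
the *lowest* total ion count — the weakest target, which has the most to lose
— and losers re-enter the pool. Each round grants at least one bin, so the
iteration count is bounded by the number of targets; empirically it stays
within ten at the 100-target scale (asserted over 50 seeded instances).

Two readings of "lowest absolute ion count" are defensible: the target's
line-total count, or its count inside the contested bin. The line-total
reading matches the algorithm's purpose (protecting globally weak targets)
and is the default; `contest_rule = "in_bin"` gives the other. Ties the
procedure leaves open are fixed deterministically: equal counts across bins
go to the lower bin index, equal totals in a contest to the lower target
mass, then id. In multi-bin mode a second pass hands one extra bin to each
target in ascending order of total abundance, using the same best-remaining
logic, so low-abundance heavy proteoforms (which need the most MS² scans in
single-ion detection) are prioritised.

## Method export

Bin edges divide by the probe rate to give chronological MS² events. Targets
below 17 kDa are acquired in ensemble mode (default NCE 30, range 25–50
sensible), heavier ones in individual-ion mode (default 9–12 eV, 10 eV
chosen); both the threshold and energies are config keys. The CSV schema is
deliberately neutral (vendor method formats are proprietary):
2-decimal minutes, 4-decimal m/z, RFC-4180 quoting, byte-stable output — a
golden-file test freezes it. A ~20 µm offset between the survey and MS² lines
is physical probe positioning, recorded as metadata only.

## Label-free quantitation

Sampled regions are 45–50 adjacent scans (≈ 80 µm at 4 µm/s and 2 spectra/s).
Counting uses only the major-isotope windows of each proteoform (±10 ppm),
which suppresses interference from overlapping neighbours. Regions with fewer
than 1000 total ions are discarded as empty-probe events before statistics.

Per proteoform, a two-sample T-test compares the classes — Welch by default
(region count ~237/class makes the normal approximation of NB count means
comfortable; Welch is robust to the variance inequality that fold changes
imply), Student behind `var_equal = TRUE`. Proteoforms are ranked by
−log10(p) descending and filtered at FDR `Q` by the critical value
`−log10(i·Q/m)`. Two decisions here:

* **m** defaults to the number of *tests*. Using the number of sampled
  regions (an alternative reading of the procedure) does not control FDR in
  general — it is supported behind `m_convention = "regions"` but not
  default.
* The rule is applied as the classical **step-up** procedure: every rank up
  to the largest rank whose −log10(p) clears its critical value is
  significant. Pointwise thresholding can produce non-contiguous decision
  sets that the Benjamini–Hochberg procedure never produces; the tests verify
  decision-set equality with `p.adjust(, "BH")` on a thousand random
  p-vectors, and the empirical FDR of the whole pipeline stays below Q under
  a 70% null / 30% signal mixture at the study's scale (the acceptance
  script recomputes this).

Fold change is the mean count in the first class over the second
(alphabetically, e.g. stroma/tumor; both overridable). When a class mean is
zero the ratio is undefined; a 0.5 pseudocount is applied to both means and
the row flagged (`fc_pseudo`) rather than dropped. Zero variance in both
classes yields p = 1 with a `degenerate` flag. The differential list keeps
significant proteoforms with |log2 FC| strictly above 0.5. PCA normalises
each region by its total ion count, mean-centres, and returns the first two
score columns with explained-variance fractions; two-class simulations at
effect |log2 FC| = 1 separate with ≥ 95% 2-means agreement.

## Imaging and intact-mass annotation

Ion images accumulate raw counts of ±10 ppm isotope-window matches on a grid
of line index × along-track pixel (default 20 µm along-track, matching the
probe's effective resolution; across-track pixel is the strip step — 80 µm
for imaging, 100 µm for LFQ rasters). No smoothing or interpolation is
applied by default so that pixel sums remain auditable ion counts; overlays
normalise each channel by its own maximum and never mix counts.

The intact-mass-tag search expands each database protein into 11 candidates:
unmodified, four single modifications (initiator-Met loss −131.040485, water
loss −18.010565, acetylation +42.010565, phosphorylation +79.966331 Da), and
their six unordered pairs. The Met-loss delta is offered to every entry
because the search operates on a mass database; when sequences are supplied
(FASTA input) masses are computed from standard monoisotopic residue masses
but the candidate set is unchanged. Matching is ±1.5 ppm on the candidate
scale, served from a sorted index that is test-equivalent to a linear scan;
all matches within tolerance are returned (no arbitration between ambiguous
candidates — that is the caller's decision). Systematic drift is removed
first by a linear ppm-vs-mass least-squares fit to anchor identifications;
anchor residuals are attached to the output so a nonlinear drift shows up
rather than being silently absorbed.

## The synthetic generator

`simulate_line_scan()` emulates what the downstream algorithms consume: per
proteoform, Poisson ion counts per scan proportional to a spatial profile;
integer charges from a rounded Gaussian envelope (clamped at 1); isotopes
sampled from the averagine distribution; exact m/z from mass and charge;
multiplicative Gaussian slope noise; uniform noise ions in m/z, scan and
slope. Defaults mirror the experimental regime the package addresses: probe
rates 4–5 µm/s, 2 spectra/s, 80–100 µm strip steps, charge envelopes typical
of denatured proteins (mean ≈ mass/1100–2200), slope noise cv = 0.02,
region sizes of 45–50 scans, and LFQ simulations at 1000 proteoforms over
237 + 235 regions with negative-binomial dispersion 0.1 (mild biological
overdispersion; dispersion → 0 recovers Poisson). Baseline abundances are
log-normal (median 5 ions/region/proteoform, sd-log 1), giving region totals
in the few-thousands, consistent with a 1000-ion QC floor.

What it deliberately does not model: time-domain transients and STORI
physics, ion decay in the trap, detector artefacts, chimeric/harmonic ions,
carryover between adjacent regions, and any structured (non-uniform) noise
background — the noise model is a stand-in, not an inference about the
instrument. Passing tests therefore demonstrate algorithmic correctness and
statistical calibration on idealised single-ion data, not robustness to
instrument pathologies.

## Numerical choices and problem sizes

Isotopologue spacing is fixed at 1.00235 Da (adequate at ±10 ppm tolerances);
the aggregated averagine distribution is computed by truncated
exponentiation-by-squaring convolution, identical to brute-force polynomial
convolution to 1e−12 (tested). The KDE is evaluated by FFT convolution on a
padded composite length. All allocator and selector tie-breaks are
deterministic, and simulators restore the caller's RNG state, deriving
everything from an explicit seed.

The test suite runs the full chain at deliberately moderate sizes — a
113-feature survey over 5–50 kDa (~400k ions), 20-replicate LFQ simulations
at 1000 proteoforms × 472 regions, 50-seed allocator runs at 100 targets —
so the complete suite finishes in a few minutes on one CPU while still
exercising the study-scale regime.

## Known limitations

Features closer than the picking mask merge; charge voting discards a
substantial ion fraction at high charge (by design — accuracy over
completeness); quantitation offers no normalisation beyond total ion count
and supports exactly two classes; images are not registered to microscopy;
and the intact-mass search neither scores nor arbitrates ambiguous matches.
MS² fragment-level identification and instrument control are out of scope.
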