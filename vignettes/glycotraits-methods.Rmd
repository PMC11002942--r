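---
title: "Methods: composition assignment and derived-trait analysis of MALDI-TOF N-glycomics spectra"
author: "glycotraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition assignment and derived-trait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotraits)
```

## Scope and model

`glycotraits` analyses MALDI-TOF reflectron spectra of PNGase-F-released,
ethyl-esterified, sodiated N-glycans at the *composition* level. A glycan is
represented by five residue-class counts — hexose (H), N-acetylhexosamine
(N), deoxyhexose/fucose (F), ethyl-esterified NeuAc (E) and lactonized NeuAc
(L) — written canonically as, e.g., `H5N4F1E1`. The derivatization chemistry
makes sialic acid linkage mass-distinguishable: an α(2,6)-linked NeuAc is
ethyl-esterified (residue C13H21NO8, 319.127 Da), an α(2,3)-linked NeuAc
lactonizes (C11H15NO7, 273.085 Da). Topology (branch position, linkage
isomers, bisecting GlcNAc) is out of scope: everything downstream is a pure
function of the residue counts.

The observed ion is the singly sodiated species of the free-reducing-end
glycan, so

$$m/z = \sum_r c_r \, m_r + m_{\mathrm{H_2O}} + (m_{\mathrm{Na}} - m_e),$$

with dehydrated residue masses $m_r$ computed from elemental formulas and
IUPAC monoisotopic atomic masses. Isotope patterns come from exact
convolution of per-element isotopologue distributions of the full elemental
formula, aggregated by nominal mass shift; the per-bin abundance-weighted
mean mass provides the isotopologue m/z. For glycans above roughly 2 kDa the
A+1 peak overtakes the monoisotopic peak, which the scoring and the
simulator both reproduce since they share the same pattern computation.

## Composition assignment

Candidates for an observed m/z are enumerated over bounded count ranges
(defaults H 0–12, N 2–10, F 0–5, E 0–4, L 0–4) subject to a biosynthetic
plausibility filter: at least the two core HexNAc (`N >= 2`), sialic acids
limited by antenna capacity (`E + L <= max(N - 2, 0)`), and `F <= N`. A
candidate matches when its theoretical m/z lies within the ±20 ppm window.
Candidates are reported ordered by absolute ppm error, ties broken by fewer
total residues, so the head of the list is the single "most probable"
assignment while the full set records nonunivocal peaks. The enumeration is
implemented as a binary search into a cached, mass-sorted table of all
in-bounds compositions; the test suite checks it against an exhaustive
nested-loop oracle.

A deliberately recorded oddity of the composition space: `H5N4E2` and
`H6N5L1` differ by only 0.036 Da (≈16 ppm at m/z 2300, since
2 × ENeuAc ≈ Hex + HexNAc + LNeuAc), one of the few genuine ambiguities
within the default bounds. The simulation presets avoid it so that
ground-truth checks stay univocal; real peaks at that mass are reported with
both candidates.

## Spectrum processing

Processing one spectrum follows the usual internal-calibration workflow:

1. **Apex picking.** A coarse running-median baseline (window ≈ 10 Da, wide
   relative to the 0.05 Da peak width) and a running-MAD noise estimate
   nominate local maxima more than 3 noise-SD above baseline. Each apex is
   refined by three-point log-parabolic interpolation, exact for a Gaussian
   peak, which removes the m/z-grid quantization (half a 0.02 Da step is
   ±7.5 ppm at m/z 1300 — larger than the calibration tolerance itself).
   Apexes one isotope spacing (1.00336 Da) above a taller apex are treated
   as isotopologues and suppressed.
2. **Internal recalibration.** Calibrant glycans of univocal composition are
   matched within a coarse 50 ppm pre-tolerance; at least three matches are
   required. The default drift model is a constant ppm offset (fitted as the
   mean ppm residual); a linear-in-m/z model is available. Corrected m/z
   are used for candidate assignment.
3. **Integration and QC.** For each candidate-bearing apex the local
   baseline is the median intensity in a ±5 Da annulus (peak windows
   excluded) and the noise its MAD; S/N is apex height above baseline over
   noise. The peak area is the trapezoidal integral, summed over the first
   four isotopologue windows (±0.15 Da each) so that areas are comparable
   across masses despite the mass-dependent envelope shape. The
   isotopic-fit score is the cosine similarity between the observed
   envelope areas and the theoretical pattern, both normalized to sum 1 —
   the score metric itself is a documented package choice (the reference
   workflow names a 0.95 score but not its functional form); cosine is
   symmetric, bounded in [0, 1], and equals 1 exactly on identical shapes.
   A peak is kept iff score ≥ 0.95 **and** S/N > 2 (strict, per the
   "greater than 2" convention) **and** |ppm| ≤ 20 (inclusive window).
   Every rejection records each failed criterion.
4. **Normalization.** Kept areas are expressed as percentages of their sum
   (TIC normalization), per spectrum, after QC.

## Derived-trait calculus

Classification is a pure function of the composition and a rule set carried
as data (`trait_rules()`), so alternative conventions are testable without
code changes:

* **Type.** paucimannosidic: `N == 2`, `H <= 3`, asialo; high-mannose:
  `N == 2`, `5 <= H <= 9`, no fucose, asialo; hybrid: `N == 3`, `H >= 5`;
  complex: `N >= 4` or (`N == 3`, `H <= 4`); anything else is
  `unclassified` and logged rather than forced.
* **Fucosylation.** mono (`F == 1`) vs multi (`F >= 2`); total = mono +
  multi.
* **Sialylation.** α(2,3) ⇔ `L >= 1`, α(2,6) ⇔ `E >= 1`, mixed ⇔ both;
  the three groups are non-exclusive. The sialyl-Lewis-x candidate flag is
  the co-occurrence `F >= 1 & L >= 1` — a compositional proxy, not a
  structural call.
* **H/N ratio.** Raw count comparison: `H > N`, `H = N`, `H < N`.
* **Antennarity.** Base antenna count `A = min(N - 2, 4)` maps to
  mono/di/tri/tetra. The polyantennary flag is exactly `H > 7 & N > 6`
  (probable poly-LacNAc elongation) and is exclusive at composition level.
  A composition with `A >= 3` whose hexose count also fits `A - 1` antennas
  plus one LacNAc repeat (`H >= A + 2`) carries the adjacent-lower label
  too: H6N5 is genuinely consistent with a triantennary glycan *or* a
  diantennary glycan with a LacNAc repeat, whereas H4N5 (too few hexoses)
  is strictly triantennary and H5N4 strictly diantennary. We restricted the
  adjacent-lower rule to `A >= 3` deliberately: the trait table has no
  mono-/di- intermediate group, and H5N4 is the canonical diantennary
  anchor sequence, so extending the ambiguity to `A = 2` would contradict
  both.

Aggregation sums the normalized percentage of each kept peak into every
trait group that at least one of its candidate compositions belongs to. A
nonunivocal peak therefore contributes fully to several groups — this is
why trait-group totals can exceed 100%, and the four type groups plus
`unclassified` sum to exactly 100% only when every peak is univocal. For
antennarity, the union of labels across a peak's candidates is mapped to
the exact group or, when it spans exactly two adjacent classes, to the
intermediate group (di-/tri-, tri-/tetra-, tetra-/poly-).

## Synthetic cohorts and what they do (and do not) show

The generator emulates the replicated two-group design used for cell-line
comparisons: 3 biological extracts × 4 technical spots per group. Each
species contributes a Gaussian isotopic envelope (σ = 0.05 Da) on a uniform
0.02 Da grid over the 1000–5000 m/z acquisition window; the baseline is a
slowly varying offset plus white noise; every spectrum carries a constant
ppm calibration drift (default 8 ppm ± 2 ppm per spot). Species abundances
are perturbed log-normally **per biological extract only**; technical
replicates share the biological draw and differ in noise and drift, so
technical averaging and biological-unit statistics can be exercised
separately. All randomness derives from a master seed through deterministic
31-bit sub-seeds per (group, extract, spot), so any single spectrum is
reproducible in isolation.

The two presets encode a control-like ("ntc_like") and a
core-fucosyltransferase-knockdown-like ("knockdown_like") glycome. Their
programmed differences are +10 percentage points complex type (at the
expense of high-mannose), −8 monofucosylation, +5 multifucosylation and +6
α(2,6)-sialylation — the direction and order of magnitude of the changes
reported for the real knockdown model. The biological log-normal sigma
(0.15) was calibrated once so the dominant traits show a within-group SD
of ≈ 2 percentage points with smaller traits proportionally tighter,
matching the replicate SDs printed for the real cohorts (complex ≈ 1.5–2.8,
multifucosylation ≈ 1–2, α(2,6) ≈ 1 point). The paucimannosidic preset
species is H3N2F1 because unfucosylated H3N2 (933 m/z) falls below the
acquisition window.

What the simulator does **not** model: matrix cluster peaks, detector
saturation, mass-dependent resolution, chemical derivatization
side-products, or correlated species variation (co-regulation). Passing the
end-to-end tests therefore demonstrates that the *processing and statistics
are correct and unbiased under the stated noise model*, not that the
pipeline is robust to every artifact of real MALDI data.

## Replicate statistics

Technical replicates are averaged within biological extracts; the
biological extract (n = 3 per group) is the statistical unit, which avoids
technical pseudo-replication. Outlier screening is a mean-centered PCA of
the per-spectrum normalized signal matrix with Hotelling's T² on the first
two components, performed within each group (between-group separation is
signal, not an outlier). The critical value is the in-model form
$\frac{k(n-1)}{n-k} F_{1-\alpha}(k, n-k)$ with $k = 2$ — appropriate for
screening the samples the model was built on; the prediction-form ellipse
is so close to the algebraic maximum of in-sample T² at small n that even a
gross outlier could never be flagged. Group differences per trait use the
two-sided pooled-variance Student's t-test (Welch available as an option),
flagged `*` at p ≤ 0.05 and `**` at p ≤ 0.01, with no multiple-testing
correction by default (per-trait p-values are reported individually; a
Benjamini–Hochberg adjustment can be applied by the user via `p.adjust`).

## SILAC utilities

Label incorporation is $(1 - 1/(\bar r + 1)) \times 100$ from the mean
heavy:light ratio of a fully labeled reference. Observed peptide ratios are
corrected for arginine→proline interconversion as
$r_c = r_o / (1 - p)^n$ (default $p = 0.077$, i.e. 7.7%), *before*
aggregation; the protein ratio is the median of its corrected peptide
ratios (all quantified peptides of the protein, not only unique ones);
proteins require ≥ 2 unique peptides to count as identified; selection is
$|\log_2 r| > 1$, strict, on both the up- and down-regulated side. The
module flags but never tests: the design it serves has no replicates, so
p-values would be meaningless.

## Numerical choices and degenerate inputs

* Residue masses agree with their elemental formulas to < 1e-4 Da by
  construction; isotope abundances are renormalized to sum to 1 ± 1e-9.
* Candidate ordering (|ppm|, then residue count) is deterministic, so
  reported "most probable" assignments cannot depend on enumeration order.
* `recalibrate()` refuses fewer than 3 matched calibrants; a flat spectrum
  integrates to area 0 and S/N 0; an all-zero envelope is rejected rather
  than scored; zero-variance group comparisons return p = 1 (`ns`), not an
  error; empty candidate sets are a valid enumeration result.
* QC comparisons follow the stated wording exactly: score ≥ 0.95, S/N
  strictly > 2, |ppm| ≤ 20 inclusive.
* Problem sizes in the shipped tests: cohorts of 24 spectra (2 × 3 × 4) at
  0.02 Da over 1000–5000 m/z, 100-seed recovery experiments, 100-probe
  enumeration cross-checks, 1000-peptide median-recovery simulations —
  chosen to keep the full suite comfortably reproducible on a laptop.

## Known limitations

* Composition-level classification cannot separate bisecting GlcNAc from a
  third antenna, nor LacNAc repeats from extra antennas except through the
  documented adjacent-label convention; the sLex flag is a proxy.
* The constant-ppm drift model is the default; strongly mass-dependent
  miscalibration requires the linear model.
* Trait-rule defaults follow standard N-glycan conventions; unusual
  glycomes (e.g. heavy LacdiNAc) may need a modified `trait_rules()`.
* The end-to-end guarantees are relative to the synthetic noise model
  described above.
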