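# glycotraits

Composition-centric analysis of MALDI-TOF mass spectra of ethyl-esterified,
sodiated N-glycans, for glycomics work that compares derived glycan traits
between cell populations (e.g. a gene-knockdown model against its
non-targeting control), plus the SILAC ratio arithmetic used alongside such
experiments.

## What it computes

A glycan composition counts residue classes — hexose (H), N-acetylhexosamine
(N), fucose (F), ethyl-esterified NeuAc (E, marking α2,6-sialylation) and
lactonized NeuAc (L, marking α2,3-sialylation) — written `H5N4F1E1`. The
singly sodiated ion mass is

    m/z = Σ counts × residue mass + H2O + (Na − e)

from monoisotopic elemental masses (Hex C6H10O5, HexNAc C8H13NO5, Fuc
C6H10O4, ENeuAc C13H21NO8, LNeuAc C11H15NO7). On top of this mass engine the
package provides:

* **Composition assignment**: enumeration of all biosynthetically plausible
  compositions within a ppm tolerance of an observed peak, ranked by mass
  error (checked against a brute-force oracle in the tests);
* **Spectrum processing**: apex picking, internal recalibration against
  univocal calibrant glycans, background-subtracted envelope integration,
  isotopic-fit scoring, QC filtering (score ≥ 0.95, S/N > 2, |ppm| ≤ 20)
  and TIC normalization to percentages;
* **Derived-trait calculus**: glycan type (paucimannosidic / high-mannose /
  hybrid / complex), mono- vs multifucosylation, linkage-specific
  sialylation, a sialyl-Lewis-x candidate flag, Hex/HexNAc ratio classes and
  antennarity (mono … poly, with intermediate groups for nonunivocal
  assignments); trait sums above 100% signal nonunivocal peaks by design;
* **Cohort statistics**: technical→biological replicate averaging,
  PCA/Hotelling-T² outlier screening, pooled-variance Student's t-tests with
  `*` (p ≤ 0.05) / `**` (p ≤ 0.01) flags;
* **Synthetic cohorts**: a seeded generator of MALDI-TOF-like spectra
  (isotopic envelopes, baseline noise, ppm drift, log-normal biological
  variability, 3 × 4 replicate design) with known ground truth, so the whole
  pipeline is testable end to end;
* **SILAC utilities**: incorporation rate, arginine→proline interconversion
  correction `r_c = r_o/(1−p)^n`, median protein ratios, |log2 FC| > 1
  selection, ≥2-unique-peptides identification filter.

## Worked example

```r
library(glycotraits)

theoretical_mz("H3N4")
#> [1] 1339.476
enumerate_compositions(1809.639, tol_ppm = 20)$composition[1]
#> [1] "H5N4F1"

# simulate a control-like vs knockdown-like cohort (3 biological x 4
# technical replicates per group), process every spectrum, compare traits
res <- run_cohort_pipeline(make_profile("ntc_like"),
                           make_profile("knockdown_like"), seed = 1)
subset(res$comparison, trait %in% c("complex", "high_mannose", "hybrid",
                                    "monofucosylation", "multifucosylation",
                                    "a26_sialylation"))
#>               trait mean_ref sd_ref mean_test sd_test     t       p flag
#> 1           complex    46.29  0.371      55.4   2.034  7.62 0.00160   **
#> 2      high_mannose    33.60  0.219      23.5   3.215 -5.43 0.00560   **
#> 3            hybrid    19.05  0.218      20.0   1.612  1.02 0.36582   ns
#> 4  monofucosylation    25.32  2.734      17.3   0.907 -4.83 0.00843   **
#> 5 multifucosylation    14.31  1.277      19.2   1.122  4.93 0.00787   **
#> 6   a26_sialylation     8.85  1.034      14.8   1.864  4.87 0.00822   **
```

Each row is one derived trait: group means ± SD of the normalized signal
percentage over the three biological replicates per group, the pooled
t statistic, and the significance flag. The simulated knockdown shifts —
more complex-type and α2,6-sialylated glycans, fewer high-mannose and
monofucosylated ones, more multifucosylated ones — are recovered with the
programmed signs; hybrid glycans were not shifted and come out `ns`.

```r
# SILAC side: correct a ratio for Arg->Pro interconversion and quantify
correct_ratio(2.0, p = 0.077, n = 2)
#> [1] 2.346238
```

A thin command-line wrapper with subcommands `simulate`, `process`,
`traits`, `compare` and `silac` ships in `inst/cli/glycotraits.R`.

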