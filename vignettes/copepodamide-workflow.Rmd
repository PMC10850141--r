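---
title: "Targeted copepodamide analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted copepodamide analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copepodamides)
```

## The analytical problem

Copepodamides are taurine-conjugated lipids that copepods release into the
water and that phytoplankton read as a grazer alarm cue. Chemically the
class is a family of homologs: a common scaffold -- either copepodamide
(CA, methylene at C3) or dihydro-copepodamide (dhCA, methyl at C3, exactly
two hydrogens heavier) -- esterified with a variable fatty acyl chain
("C:D", C carbons and D double bonds). Collision-induced dissociation of
the protonated molecule cleaves the acyl as a neutral free fatty acid,
leaving a charged diagnostic fragment shared by every member of a scaffold:
m/z 430.26 for CA (C22H40NO5S) and 432.28 for dhCA (C22H42NO5S), with
taurine (m/z 124.0) and sulfonate (m/z 80) as secondary confirmations.

This structure makes the whole class detectable with two precursor-ion
scans on a triple quadrupole -- one per diagnostic channel -- and makes the
acyl identifiable from the neutral loss alone. The package implements that
logic end to end:

1. **chemistry**: monoisotopic formula arithmetic, homolog library
   enumeration, neutral-loss annotation, MRM transition design;
2. **screening**: windowed precursor-scan annotation, cumulative-abundance
   MRM target selection, habitat occurrence classification;
3. **quantification**: single-point calibration, prosome length to dry
   mass, pmol/ng/ppt content metrics, the content-mass allometry;
4. **statistics**: Bray-Curtis, PERMANOVA, PERMDISP, nMDS, ANCOVA with
   partial eta squared;
5. **synthetic data**: a fully seeded generator of bulk scans, MRM tables
   and metadata with known ground truth.

## Chemistry conventions

A deliberate subtlety: the diagnostic fragment formulas are the *charged*
fragment compositions. Their monoisotopic masses minus one electron
reproduce the observed m/z 432.28 / 430.26 directly; protonating a neutral
of the same composition would land one proton too high. `monoisotopic_mass()`
therefore has an explicit `cation` mode that subtracts the electron mass,
and the precursor m/z of a species is the charged fragment mass plus the
neutral free fatty acid mass -- identically the protonated intact molecule.

The default library spans chains of 12-24 carbons with 0-6 double bonds on
both scaffolds (178 species). That covers every reported copepodamide with
margin, including the odd-chain C15/C17 species typical of freshwater
samples; no biological plausibility filter is applied, because odd and
polyunsaturated acyls are real observations, not noise. Within this
library the minimum spacing between same-channel precursors is ~1.9 Da, so
the default 0.3 Da matching tolerance (unit-resolution triple-quadrupole
data) cannot produce annotation collisions; `assign_acyl()` still returns
every candidate in tolerance, sorted by absolute mass error, so a
collision in a user-configured library is reported rather than dropped.

The packaged reference table stores *reported* precursor m/z values next
to theoretical ones. Reported values are instrument readings: most agree
with theory to 0.12 Da or better, and three entries (17:0 dhCA at 702.7,
20:3 dhCA at 738.7, 22:6 CA at 758.7) deviate by 0.16-0.20 Da. The
validation helper flags entries against a configurable tolerance rather
than asserting exact equality, and m/z is carried at 4 decimals
internally with 1-decimal rounding only at the display/CSV boundary.

## Screening rules

The scan window is applied half-open, [600, 1000), a convention chosen
once and documented because the inclusive/exclusive choice at the
boundaries is otherwise invisible in results. "Detection" means annotation
in at least one sample; no minimum-intensity filter is layered on top.

MRM targets are chosen by the cumulative-abundance rule: annotated hits
are ranked by intensity (ties broken by ascending m/z, so the selection is
deterministic), and the minimal prefix reaching 80% of the total annotated
intensity is kept, then unioned with the previously known compounds. Two
readings of that rule exist when several bulk samples are screened --
apply it per sample and union the selections, or pool samples first. Both
are implemented (`per_sample`), with per-sample as the default: it is the
conservative choice, since a compound dominant in any one sample is
guaranteed a transition. The rule is monotone in the threshold (lowering
the threshold never adds compounds); it is *not* exactly idempotent in
pathological intensity configurations where the dropped tail holds just
under the skipped share, which is why re-selection on a selected subset is
only guaranteed to be stable for typical, strongly-ranked spectra.

## Quantification conventions

Calibration is single-point through the origin against an authentic
standard, with one response factor applied to every compound -- the
equal-ionisation-efficiency assumption that the shared taurine head group
makes defensible. Amounts convert to mass via the *monoisotopic* neutral
species mass (precursor minus one proton); for these ~660-760 Da species
the monoisotopic/average difference is below 0.1%, far inside calibration
error. The headline content metric is mass fraction in parts per thousand:
ppt = total ng / (dry mass ug x 1000) x 1000, so 10 ng in a 100 ug
individual is 0.1 ppt.

Dry mass comes from prosome length through a power law W = a L^b (L in
mm, W in ug). The packaged defaults a = 100, b = 2.5 make a 1 mm prosome
correspond to 100 ug -- a placeholder consistent with the headline metric
above, **not** fitted coefficients; real analyses must supply
taxon-specific regressions, and the applied model is stamped on every
output for provenance.

## Statistics

The multivariate workflow is implemented from first principles rather than
wrapped, so every numerical choice is explicit:

* **Bray-Curtis** on sample x compound abundances, optionally row-normalised
  to relative composition (the default in the pipeline, since individuals
  differ hugely in total content). Symmetry, zero diagonal and the [0, 1]
  range are guaranteed; the triangle inequality is not asserted because
  Bray-Curtis does not satisfy it in general.
* **PERMANOVA** (one-way): pseudo-F from the partition of summed squared
  interpoint distances, p by free permutation of labels with the observed
  statistic included in numerator and denominator -- p is never 0 and never
  below 1/(n_perm+1). For small n an exact mode enumerates all distinct
  label assignments. An infinite F (perfect separation) is ranked, not
  rejected; an undefined F (all distances zero) returns an explicit
  degenerate status.
* **PERMDISP**: principal-coordinates embedding with negative eigenvalues
  truncated at zero (the count is reported), distances to the group
  *mean* -- means rather than spatial medians, matching the centroid
  construction used throughout -- and a permutation test on those
  distances.
* **nMDS**: stress majorisation (Guttman transform) alternating with
  monotone regression of configuration distances on dissimilarity ranks by
  pool-adjacent-violators; tied dissimilarity blocks share one disparity.
  Goodness of fit is Kruskal stress-1. The first restart starts from the
  principal-coordinates embedding (which solves exactly embeddable inputs
  immediately); the remaining restarts are random, and the best solution
  is returned with a convergence flag. Stress-1 is invariant to rotation,
  translation and uniform scaling of the configuration, which the tests
  verify directly.
* **ANCOVA**: base `lm()` fits with a hand-assembled Type-II decomposition;
  partial eta squared is SS_term / (SS_term + SS_residual). Slope
  homogeneity is the p-value of the group x covariate interaction from the
  augmented model, and conditional normality is checked with Shapiro-Wilk
  on the residuals. Sums of squares at rounding-noise level are snapped to
  zero so that degenerate inputs (zero residual, fully explained terms)
  yield exact 0/1 effect sizes instead of noise ratios.
* **Centroid ellipses**: Hotelling confidence regions for the group mean,
  c^2 = 2(n-1)/(n(n-2)) F(level; 2, n-2), drawn on the ordination.

Defaults follow the field: 9999 permutations and alpha = 0.05 (the test
suite and acceptance checks use fewer permutations purely as a problem
size, stated below).

## What the synthetic data emulate -- and what they do not

The generator reproduces the statistical structure the analysis assumes:
a 6 freshwater + 4 marine site design; freshwater composition profiles
that are >= 98% dhCA by default (with a 1% CA trace, matching the trace
CAs seen in some lakes) versus marine profiles mixing CA/dhCA 40/60;
per-taxon signatures obtained by blending the habitat profile with a
fixed, seeded taxon perturbation (blend fraction 0.3 by default);
ln-ln content allometry with slope 0.296, intercept 0.25 and lognormal
scatter sigma = 0.5; multiplicative lognormal noise on peak areas and
intensities (sigma 0.5) and additive Gaussian m/z error (sd 0.02 Da);
and uniform background peaks (2 per 100 Da) kept at least twice the
matching tolerance away from any library mass. Noise magnitudes are
engineering choices -- instrument noise levels are not published for this
workflow -- and are all config, not claims. One master seed determines
everything; per-site and per-individual sub-streams are derived
deterministically so partial regeneration is stable.

The generator does **not** emulate chromatographic peak shapes, retention
time, isotope patterns, adducts other than [M+H]+, matrix effects, or
compound-specific response factors. Consequently, passing the end-to-end
recovery tests shows the *pipeline logic* is correct (annotation,
bookkeeping, calibration arithmetic, statistics), not that real spectra of
this quality will be annotated perfectly: real data add exactly the
effects listed above, and the background-exclusion guarantee in the
simulator (no background peak within 2x tolerance of a library mass) has
no counterpart in nature.

## Problem sizes and numerical tolerances

The validation suite uses problem sizes chosen to make each property
measurable with comfortable margin: 1000 null simulations at 199
permutations for the PERMANOVA type-I rate (expected 0.05 +/- 0.02); 200
simulated 5+5-site studies for habitat-detection power (observed 1.0);
100 seeds of 200 individuals for allometric slope recovery within +/-0.1
(sigma = 0.5 scatter gives a slope standard error near 0.05, so ~95% of
seeds recover); exact permutation enumeration up to n = 8. nMDS uses a
stress-decrease tolerance of 1e-7 and up to 200 majorisation iterations;
exactly embeddable configurations must reach stress below 1e-4 (they
reach ~0 from the principal-coordinates start).

## Known limitations

* One-way designs only in PERMANOVA/PERMDISP; no strata, no multi-factor
  partitioning.
* Single-point calibration: no curve, no LOD/LOQ model, no internal
  standards.
* The reference table's occurrence classes are carried as published; the
  per-sample detail behind the "found in only one sample" flag is not
  reconstructable from the table and is exposed as a column, not a filter.
* The length-weight defaults are placeholders (see above).
* Negative-eigenvalue truncation in the principal-coordinates step biases
  PERMDISP dispersions slightly downward for strongly non-Euclidean
  dissimilarities; the number of truncated axes is reported so users can
  judge exposure.
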