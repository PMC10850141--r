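# copepodamides

Targeted mass-spectrometric screening, annotation and quantification of
**copepodamides** — the taurine-conjugated lipid alarm cues of copepods —
plus the compositional statistics used to compare them across habitats.

Copepodamides share two scaffolds, CA and dhCA (methylene vs methyl at C3,
exactly 2 H apart), carrying a variable fatty acyl "C:D" at C5. Collision-
induced dissociation of [M+H]⁺ loses the acyl as the free fatty acid
CₙH₂ₙ₋₂dO₂ and leaves a charged scaffold fragment: m/z 430.26 (CA,
C22H40NO5S) or 432.28 (dhCA, C22H42NO5S), confirmed by taurine (124.0) and
sulfonate (80) fragments. Precursor-ion scans on those two channels detect
the whole class in the 600–1000 m/z window; the neutral loss
(precursor − product) identifies the acyl. The package is aimed at
analytical and chemical-ecology labs running this workflow on
triple-quadrupole data, and at anyone needing its statistical machinery
standalone.

What it provides:

- **Chemistry** — monoisotopic formula arithmetic (`monoisotopic_mass`),
  homolog library enumeration (`enumerate_library`; chains 12–24, 0–6
  double bonds by default), neutral-loss annotation (`assign_acyl`), MRM
  transition design/export (`build_transitions`, `write_transitions`), and
  the packaged reference table of 35 reported species
  (`copepodamide_reference`).
- **Screening** — `screen_sample` (half-open [600, 1000) window, 0.3 Da
  tolerance), MRM target selection by the ≥ 80 % cumulative-abundance rule
  (`select_transitions`), habitat occurrence classification
  (`classify_presence`), novelty counts (`count_novel`).
- **Quantification** — single-point calibration (`quantify`), pmol↔ng via
  monoisotopic species mass (`pmol_to_ng`), prosome length→dry mass
  power laws (`dry_mass`), content metrics in pmol/ng/ppt
  (`content_metrics`), and the ln–ln content/mass allometry
  (`allometric_regression`).
- **Statistics, from first principles** — `bray_curtis`, one-way
  `permanova` (pseudo-F, permutation p = (count ≥ obs + 1)/(n_perm + 1),
  exact enumeration for small n), `permdisp`, `nmds` (stress majorisation
  with pool-adjacent-violators monotone regression, Kruskal stress-1),
  `ancova` with partial η², `centroid_ellipses`.
- **Synthetic data** — `sim_config`/`simulate_dataset`: seeded bulk scans,
  MRM tables, metadata and ground truth emulating the 6-freshwater +
  4-marine study design with dhCA-dominated freshwater vs mixed marine
  profiles.
- **Orchestration** — `run_pipeline` wires screen → quantify → stats and
  `write_report` serialises JSON/Markdown/CSV outputs; `export_library`,
  `write_dataset`, `write_mgf`/`read_mgf` handle the file formats.

## Worked example

```r
library(copepodamides)

# what is the peak at 760.5 producing the 432.3 product?
assign_acyl(760.5, 432.3)
#>        name scaffold acyl carbons double_bonds precursor_mz product_mz
#> 1 22:6 dhCA     dhCA 22:6      22            6     760.5181   432.2778
#>   fatty_acid_mass  mass_error
#> 1        328.2402 -0.04023027

# a full synthetic study and analysis run
ds  <- simulate_dataset(sim_config(seed = 42))
rep <- run_pipeline(ds, n_perm = 999, seed = 42)
rep
#> Copepodamide pipeline report
#>   hits: 300 (224 annotated); MRM targets: 33
#>   compounds: 35 (F = 6, M = 17, B = 12)
#>   permanova_bulk: F = 17.4, p = 0.007
#>   permdisp_bulk: F = 0.969, p = 0.351
#>   nmds_bulk: stress = 0.000592
#>   permanova_individuals: F = 246, p = 0.001
#>   allometry: slope = 0.080, R^2 = 0.010
```

Reading the output: the annotation at 760.5 is docosahexaenoyl
dihydro-copepodamide, 0.04 Da from theory. In the synthetic run, 35
compounds pass screening and are classed by occurrence (freshwater-only /
marine-only / both); bulk composition differs between habitats
(PERMANOVA p = 0.007) while dispersions are homogeneous (PERMDISP
p = 0.35), so the location effect is real; the near-zero nMDS stress says
two dimensions embed the 10 bulk samples essentially perfectly; and the
individual-level allometry is shallow with low R² — total content grows
much more slowly than dry mass, as expected for a surface-active cue.

```r
rep$stats$ancova_content
#> ANCOVA (Type II)
#>   group      df = 1, 117  F = 2.198  p = 0.1409  partial eta^2 = 0.018
#>   covariate  df = 1, 117  F = 0.3787  p = 0.5395  partial eta^2 = 0.003
#>   slope homogeneity (interaction) p = 0.9196
#>   Shapiro-Wilk on residuals: W = 0.9919, p = 0.7143
```

Size-adjusted content does not differ between habitats in this simulated
study (group p = 0.14, partial η² = 0.018) — the generator's default is
one shared allometry for both habitats, and the test correctly fails to
reject it.

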