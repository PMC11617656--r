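# pinyonDefense

Drought constrains the induced terpene defense of pinyon pine
(*Pinus edulis*). When bark beetles and their blue-stain fungi attack,
trees accumulate mono- and sesquiterpenes (MST) in the inner bark — but
that response costs carbon, and it happens in living cells whose turgor
collapses under severe drought. `pinyonDefense` implements the analysis
pipeline for glasshouse experiments that separate the two candidate
constraints — carbohydrate substrate versus cell turgor — and a
synthetic-cohort generator that emulates the experimental design so every
stage is testable end to end. It is written for plant ecophysiologists
and chemical ecologists working with tree-level defense, carbohydrate and
water-relations data.

## What it computes

**Girdle resin-loss correction.** Girdling (severing phloem to isolate
the local carbohydrate pool) mechanically leaks resin. The relative loss
is estimated from girdled-only trees, regressed on predawn water
potential (ψ_pd, MPa; watered trees lose more), and predicted corrections
(clipped to [−1, 0]) adjust the induced change in inoculated + girdled
trees:

    ΔT_corrected = ΔT_raw + ΔT_raw × Correction

with an alternative `add_back_absolute` convention
(`ΔT_raw − Correction × MST_pre`) one flag away.

**Stoichiometric cost ledger.** An itemized account of synthesizing
terpene from glucose via the MEP pathway — carbon skeleton (1 glucose per
C5 unit), ATP/CTP and reductant demands, glycolytic co-product credits —
converted to glucose equivalents (ATP 32 per glucose, NADPH 12 per
glucose, P/O 2.5, CTP = 2 ATP). Defaults price 1 g of MST at **3.35 g
glucose**.

**De novo synthesis budget.** For inoculated + girdled trees:
`NSC_available = NSC_pre × (100 − maintenance)/100` (maintenance = mean %
NSC depletion of girdled-only trees), maximum potential synthesis
`10 × NSC_available / cost` (mg g⁻¹), and the percent of observed
induction that de novo synthesis could support.

**Inner-bark water relations.**
`ψ_solute = −mOsm kg⁻¹ × 8.3144598e−6 × K` from vapor-pressure
osmometry, and `ψ_pressure = ψ − ψ_solute`, classifying trees into
turgid (ψ_pressure > 0) and turgor-lost groups.

**Statistical layer.** Linear models with type-II ANOVA and Tukey-HSD
contrasts; Bray–Curtis dissimilarities of 43-compound relative terpene
profiles; PERMANOVA (distance-based trace partition, raw-label
permutations, seeded); principal-coordinate projection for
visualization.

## Worked example

```r
library(pinyonDefense)

co <- simulateCohort(generatorParams(), seed = 7)
co
#> DefenseCohort: 46 trees, 43 terpene compounds
#>   watered 14 / drought 32; girdled 23; inoculated 22
#>   psi_pd range: [-3.55, -0.32] MPa; 4 trees lack post tissue

glucoseCost("monoterpene", "MEP")
#> CostLedger: monoterpene via MEP pathway
#>   glucose (carbon skeleton): 2.0000 mol
#>   ATP demand 6.00, CTP demand 2.00, NADPH demand 6.00 mol
#>   ATP credit 4.00, NADH credit 2.00 mol
#>   glucose equivalents: 2.5312 mol mol^-1
#>   mass cost: 3.347 g glucose per g terpene

rep <- runPipeline(pipelineConfig(seed = 7, nPerm = 999))
print(headlineSummary(rep), digits = 3)
#>                                     quantity     value
#> 1     potential_percent_induction_watered_ig  4.40e+01
#> 2  potential_percent_induction_watered_ig_se  9.15e+00
#> 3                      induction_mean_turgid  2.04e+01
#> 4                 induction_mean_turgor_lost  1.85e-01
#> 5             induction_ratio_turgid_vs_lost  1.11e+02
#> 6            r_squared_induction_vs_pressure  5.22e-01
#> 7                    p_induction_vs_pressure  2.18e-04
#> 8                         p_induction_vs_nsc  9.90e-01
#> 9                    induction_slope_per_mpa  1.46e+01
#> 10                        induction_slope_se  3.40e+00
#> 11                  maintenance_fraction_pct  5.61e+01
#> 12                      glucose_cost_g_per_g  3.35e+00
#> 13                      loss_model_intercept -4.54e-01
#> 14                          loss_model_slope -1.22e-01
```

Reading the headline table: on this synthetic cohort, local NSC could
support only part of the observed induction in watered
inoculated + girdled trees (44 ± 9 % here; the exact value depends on the
simulated noise); induction declines by ~14.6 ± 3.4 mg g⁻¹ per MPa of
ψ_pd (the generator's true slope is 15.9); estimated turgor explains 52 %
of induction variance (p = 2 × 10⁻⁴) while pre-inoculation NSC explains
none (p = 0.99) — the qualitative contrast the experiment was designed to
expose. The compositional PERMANOVA on the same run:

```r
print(permanovaTable(rep$permanova), digits = 3)
#>                 term df    ss pseudoF     p
#> 1            drought  1 0.206    2.69 0.001
#> 2         inoculated  1 0.183    2.38 0.003
#> 3 drought:inoculated  1 0.340    4.44 0.001
#> 4           Residual 38 2.912      NA    NA
#> 5              Total 41 3.641      NA    NA
```

`runPipeline()` also accepts `mode = "file"` with `cohort.csv` /
`terpenes_pre.csv` / `terpenes_post.csv` (see `?readCohort` for the
schema) and writes per-tree tables, model summaries and a checksum
manifest when given `outDir`.

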