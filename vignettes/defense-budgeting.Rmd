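---
title: "Budgeting induced terpene defense under drought"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Budgeting induced terpene defense under drought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinyonDefense)
```

## The scientific problem

Conifers such as pinyon pine (*Pinus edulis*) defend against bark beetles
and their fungal symbionts with resin rich in mono- and sesquiterpenes
(MST). Attack induces additional terpene accumulation on top of the
constitutive pool, and the induced response is carbon-hungry: the
precursors, ATP and reducing equivalents all trace back to nonstructural
carbohydrates (NSC: starch, sucrose, glucose, fructose). Drought is
suspected to throttle this response, but the mechanism is contested —
substrate limitation (not enough NSC) versus a water-relations constraint
(loss of cell turgor in the inner bark, where resin is synthesized and
pressurized).

This package implements the analysis layer of a glasshouse experiment
designed to separate these hypotheses, and a synthetic-cohort generator
that emulates the experiment so the whole pipeline is testable without the
original field data. The experimental units are trees dried to a gradient
of predawn shoot water potential ($\psi_{pd}$, MPa), factorially assigned
to stem girdling (G: severs phloem, isolating the local NSC pool) and
fungal inoculation (I), with inner-bark MST and NSC measured before and
two weeks after inoculation.

## Girdle resin-loss correction

Girdling alone causes mechanical resin loss, which contaminates the
induced change $\Delta T_{raw} = \mathrm{MST}_{post} - \mathrm{MST}_{pre}$
in inoculated + girdled (IG) trees. The correction uses the girdled-only
(G) cells, where no induction occurs: for each G tree the relative change
$(\mathrm{MST}_{post} - \mathrm{MST}_{pre})/\mathrm{MST}_{pre}$ estimates
relative resin loss, and an ordinary least-squares line on $\psi_{pd}$
captures the observation that well-watered trees lose more resin than
drought-stressed ones (resin is pressurized by turgor). The fitted line
predicts a per-tree correction for IG trees, clipped to $[-1, 0]$: a
relative loss below $-1$ is physically impossible, and a predicted gain is
treated as "no loss".

Two application conventions are provided because the field's verbal
description ("adding back the lost resin") and the published arithmetic
($\Delta T_{corr} = \Delta T_{raw} + \Delta T_{raw}\times Correction$,
with $Correction \le 0$) point in opposite directions for positive
$\Delta T_{raw}$. The `printed` convention (default) follows the
arithmetic; `add_back_absolute` computes
$\Delta T_{raw} - Correction \times \mathrm{MST}_{pre}$, restoring the
absolute concentration lost. Every output records which convention was
used, and downstream regressions are qualitatively similar under either.
The correction applies *only* to IG trees; all other trees pass through
with correction 0.

One consequence worth knowing: the generator applies resin loss
multiplicatively to the whole post-inoculation pool, and neither
convention is an exact algebraic inverse of that process. Corrected IG
inductions are therefore attenuated relative to the generator's
configured induction line. For this reason parameter-recovery tests and
the headline slope estimate use inoculated, *non-girdled* trees, where
the raw change sits exactly on the configured line in expectation.

## Stoichiometric cost of terpene synthesis

`glucoseCost()` builds an itemized ledger for one mole of terpene
(monoterpene C10H16, two C5 isoprenoid units; sesquiterpene C15H24,
three), synthesized from glucose:

* **Carbon skeleton.** Via the plastidic MEP route, each C5 unit consumes
  one glucose: glycolysis supplies pyruvate plus glyceraldehyde
  3-phosphate, which condense (losing one CO2) into the C5 precursor.
* **Energy and reductant.** Per C5 unit the route spends 1 NADPH (DXR),
  1 CTP (MCT), 1 ATP (CMK) and two further two-electron reductions
  (HDS/HDR), i.e. 3 reductant equivalents in total; glycolysis costs
  2 ATP of priming but returns 2 ATP and 1 NADH from the triose carried
  through to pyruvate.
* **Conversion to glucose equivalents.** Net ATP (counting CTP at 2 ATP
  and crediting NADH at a P/O ratio of 2.5) is divided by 32 ATP per
  glucose respired; NADPH demand is divided by 12 NADPH per glucose via
  the oxidative pentose-phosphate route. These conventions are explicit,
  positive parameters of `energyConventions()`; changing any of them
  propagates transparently through the ledger.

Under the defaults the cost is 2.53 mol glucose per mol monoterpene, i.e.
**3.35 g glucose per g terpene**, and identical (to < 1%) for
sesquiterpenes since both classes are (C5H8)$_n$ by composition. A
carbon-skeleton-only floor of $2 \times 180.156 / 136.234 = 2.645$ g/g is
enforced: co-product credits may offset energy costs but never the
skeleton glucose. Without that floor, extreme (but individually
plausible) convention choices could price a terpene below its own carbon
content, which we regard as an accounting artifact rather than a
biochemical possibility. The cytosolic MVA route (1.5 glucose per C5,
2 NADPH, 3 ATP, large NADH credits) is implemented for comparison but is
not the default, because a single blended MEP-based cost is applied to
the total MST pool.

## De novo synthesis budget

For IG trees — whose isolated stem section can only draw on local NSC —
the budget chain is:

$$\mathrm{NSC}_{avail} = \mathrm{NSC}_{pre} \times \frac{100 - m}{100},
\qquad
\mathrm{MST}_{max} = \frac{10 \times \mathrm{NSC}_{avail}}{c},
\qquad
\%_{denovo} = 100 \times \frac{\mathrm{MST}_{max}}{\Delta T_{corr}}$$

where $m$ is the maintenance fraction (the mean percent NSC depletion of
girdled-only trees, i.e. the share consumed by baseline metabolism; the
cohort mean is used, not per-tree values), $c$ the glucose cost (g/g),
and the factor 10 converts % DW to mg g$^{-1}$ (centralized in
`pctToMgPerG()`, the only place that conversion exists). Trees whose
corrected change is not positive did not induce; they are flagged
excluded rather than given a meaningless ratio. Setting $m = 0$ is the
documented sensitivity mode (the whole pre-inoculation pool assumed
available) and can only increase every budget. The maintenance fraction
may be computed on total NSC (default) or on soluble sugars only
(`pool = "sugar"`); sugars are ~98% of the inner-bark pool, so the two
differ little in practice.

## Inner-bark water relations

Solute potential follows the van't Hoff relation used with vapor-pressure
osmometry, $\psi_{solute} = -\mathrm{mOsm\,kg^{-1}} \times 8.3144598
\times 10^{-6} \times T$ (MPa, with $T$ in K; chamber default 305.0 K),
and pressure potential is the difference
$\psi_{pressure} = \psi - \psi_{solute}$, taking predawn shoot water
potential as the inner-bark water potential. That substitution is the
standard field approximation and is propagated here without a gradient
correction; the resulting turgor values are estimates, and the package
makes no claim of accuracy beyond the sign and ordering used by the
group contrast ($\psi_{pressure} > 0$ versus $\le 0$).

## Statistical layer

`fitLinearModel()` wraps least squares with a type-II ANOVA table and
Shapiro-Wilk residual diagnostics (reported, never used to auto-switch
methods); `tukeyContrasts()` gives family-wise pairwise comparisons.
Compositional analysis works on the 43-compound relative-abundance
profiles: `brayCurtis()` builds the dissimilarity matrix and
`compositionPermanova()` partitions it in the McArdle-Anderson
trace form with raw-label permutations,
$p = (1 + \#\{F_{perm} \ge F_{obs}\})/(n_{perm} + 1)$, under a fixed
seed. When a term separates samples perfectly the residual sum of squares
is zero; the observed pseudo-F is treated as infinite and $p$ attains its
floor $1/(n_{perm}+1)$, since any label permutation breaks the
separation. Whether permutations should be of raw labels or of residuals
under a reduced model is a known open choice for multi-factor designs;
raw-label permutation is implemented and stated. The default is 999
permutations; the visualization layer is a principal-coordinate
projection (classical metric scaling) rather than NMDS — deterministic,
with no stress-minimization convergence ambiguity — while all inference
about composition runs through the PERMANOVA. In all treatment models the
drought factor is binary (watered versus drought), with the mild and
moderate strata combined.

## What the synthetic cohort emulates — and what it does not

`simulateCohort()` reproduces the *statistical structure* of the
experiment under its documented study conditions:

* 14 watered / 16 mild / 16 moderate trees; $\psi_{pd}$ uniform within
  $[-0.91, -0.31]$, $[-2.85, -1.66]$ and $[-3.61, -2.86]$ MPa (uniform is
  the least-committal choice consistent with reported ranges and means);
  four treatments allocated evenly (3-4 per cell) within each stratum.
* Induced MST linear in $\psi_{pd}$: slope 15.9 mg g$^{-1}$ MPa$^{-1}$,
  anchored at 49.3 mg g$^{-1}$ for the watered-stratum mean $\psi_{pd}$,
  plus truncated additive Gaussian noise (sd 15 mg g$^{-1}$, consistent
  with group standard errors of 6-7 mg g$^{-1}$ at $n \approx 7$;
  reported uncertainties imply a noise scale, not a noise model, so
  Gaussian is a choice).
* Girdle resin loss linear through the anchors $(-0.31, -0.43)$ and
  $(-3.61, 0)$, truncated to $[-1, 0]$, applied multiplicatively to the
  post pool of girdled trees.
* Soluble sugars 5.4 ± 1.4 % DW with starch 0.3 (watered) or 0.03
  (drought) % DW; NSC depletion by treatment cell 0/52/76/89 % (sd
  5/11/10/10), truncated so pools stay non-negative.
* An osmolality regime with solute potential $-2.0$ MPa at the watered
  anchor and partial osmotic adjustment of 0.25 MPa per MPa of
  $\psi_{pd}$ (noise 40 mmol kg$^{-1}$). No published osmolality values
  exist to copy; this regime was chosen once so that essentially all
  watered trees have positive estimated turgor and most moderate-drought
  trees negative, the sign structure the group contrast requires.
* Constitutive MST 30 ± 8 mg g$^{-1}$ — a placeholder (no published
  tree-level value), never used as ground truth by any test.
* Dirichlet compound profiles (concentration 60) whose mean blend shifts
  (mixing weight 0.5) only for watered inoculated trees, emulating the
  finding that drought overrides induced compositional shifts.
* Four drought trees with missing post-inoculation tissue, mirroring the
  desiccated-bark exclusions; missing means missing, never zero.

It does **not** simulate resin-duct pressure dynamics, phloem transport,
within-tree spatial structure, compound-level biochemistry, or
measurement error models beyond the Gaussians above. Passing
recovery tests therefore demonstrates that the pipeline's estimators are
correct and calibrated under this generative structure — not that the
biological conclusions would survive data with different error structure.

## Numerical choices and problem sizes

Predictions of the loss model are clipped, never extrapolated; budgets
divide only by positive observed inductions; relative compositions are
undefined (an error, not NaN) for empty profiles; CSV round trips use
full-precision formatting so floats survive to $10^{-9}$ relative. The
test suite runs its heavier checks at sizes chosen to balance power and
runtime: parameter recovery uses 100 replicate cohorts of 500 trees
(strata scaled 152/174/174), and the PERMANOVA null calibration uses 200
simulations of 30 samples with 199 permutations each. The package's own
PERMANOVA engine is cross-checked against vegan's `adonis2` on
non-degenerate designs.

## Known limitations

* The girdle correction is a statistical adjustment, not a mechanistic
  resin-flow model; its two conventions bracket the intended behavior.
* The energy conventions behind the 3.35 g/g cost are textbook-level
  defaults (ATP 32/glucose, NADPH 12/glucose, P/O 2.5, CTP = 2 ATP);
  they are exposed precisely because reasonable alternatives exist, and
  the ledger makes every line item auditable. Diterpenes are not costed;
  including them would only lower any de novo share.
* The maintenance fraction borrows the girdled-only cohort mean for all
  IG trees; per-tree maintenance is not identifiable from this design.
* Estimated turgor inherits the shoot-to-bark water-potential
  approximation; treat $\psi_{pressure}$ as an index, not a measurement.
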