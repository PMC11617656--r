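#' Default energy conventions
#'
#' @param atpPerGlucose ATP per glucose fully respired (default 32)
#' @param nadphPerGlucose NADPH per glucose via the oxidative
#'   pentose-phosphate route (default 12)
#' @param poRatioNADH ATP credited per NADH (default 2.5)
#' @param ctpATPEquiv ATP equivalents per CTP (default 2)
#' @param reductantPer2eStep NADPH equivalents per two-electron reduction
#'   (default 1)
#' @return an [EnergyConventions-class]
#' @export
energyConventions <- function(atpPerGlucose = 32, nadphPerGlucose = 12,
                              poRatioNADH = 2.5, ctpATPEquiv = 2,
                              reductantPer2eStep = 1) {
  methods::new("EnergyConventions", atpPerGlucose = atpPerGlucose,
               nadphPerGlucose = nadphPerGlucose, poRatioNADH = poRatioNADH,
               ctpATPEquiv = ctpATPEquiv,
               reductantPer2eStep = reductantPer2eStep)
}

## Per-IPP line items for each pathway (mol per mol IPP).
##
## MEP (plastidic): one glucose supplies pyruvate + glyceraldehyde
## 3-phosphate (DXS condenses them, losing one CO2). Getting there by
## glycolysis costs 2 ATP (hexokinase, PFK) and returns 2 ATP + 1 NADH from
## the one triose carried through to pyruvate. The pathway proper spends
## 1 NADPH (DXR), 1 CTP (MCT), 1 ATP (CMK) and two further two-electron
## reductions (HDS, HDR ferredoxin steps), i.e. 3 reductant equivalents.
##
## MVA (cytosolic): 3 acetyl-CoA per IPP, i.e. 1.5 glucose; glycolysis
## returns 2 ATP + 2 NADH per glucose and pyruvate dehydrogenase 1 NADH per
## acetyl-CoA (one CO2 each); the pathway spends 2 NADPH (HMG-CoA
## reductase) and 3 ATP (MVK, PMK, MVD).
.ipp_items <- function(pathway, conv) {
  switch(pathway,
    MEP = c(glucose_skeleton = 1,
            atp_demand = 2 + 1,      # glycolytic priming + CMK
            ctp_demand = 1,
            nadph_demand = 3 * conv@reductantPer2eStep,
            atp_credit = 2,          # substrate-level, triose -> pyruvate
            nadh_credit = 1),
    MVA = c(glucose_skeleton = 1.5,
            atp_demand = 1.5 * 2 + 3,  # glycolytic priming + MVK/PMK/MVD
            ctp_demand = 0,
            nadph_demand = 2 * conv@reductantPer2eStep,
            atp_credit = 1.5 * 4,      # substrate-level, both trioses
            nadh_credit = 1.5 * 2 + 3),# glycolysis + pyruvate dehydrogenase
    stop("unknown pathway: ", pathway))
}

#' Stoichiometric glucose cost of terpene biosynthesis
#'
#' Builds the itemized cost ledger for one mole of terpene synthesized from
#' glucose: carbon-skeleton glucose (one glucose per C5 isoprenoid unit via
#' MEP; 1.5 via MVA), ATP/CTP and reductant demands of the pathway, and
#' glycolytic co-product credits. Net ATP (including CTP as ATP equivalents
#' and NADH credits at the P/O ratio) and NADPH are converted to glucose
#' equivalents with the supplied conventions. Energy credits can offset
#' energy costs but never the carbon skeleton, so the total is floored at
#' the skeleton requirement. Under the default conventions the mass cost is
#' 3.35 g glucose per g terpene for either compound class.
#'
#' @param compoundClass `"monoterpene"` (C10H16, 2 IPP) or
#'   `"sesquiterpene"` (C15H24, 3 IPP)
#' @param pathway `"MEP"` (default; plastidic route used for conifer resin
#'   mono-/sesquiterpene costing here) or `"MVA"`
#' @param conventions an [EnergyConventions-class]
#' @return a [CostLedger-class]
#' @export
glucoseCost <- function(compoundClass = c("monoterpene", "sesquiterpene"),
                        pathway = c("MEP", "MVA"),
                        conventions = energyConventions()) {
  compoundClass <- match.arg(compoundClass)
  pathway <- match.arg(pathway)
  methods::validObject(conventions)
  nIPP <- if (compoundClass == "monoterpene") 2 else 3
  mm <- if (compoundClass == "monoterpene") .MM_MONOTERPENE else .MM_SESQUITERPENE
  items <- .ipp_items(pathway, conventions) * nIPP
  netATP <- items[["atp_demand"]] +
    items[["ctp_demand"]] * conventions@ctpATPEquiv -
    items[["atp_credit"]] -
    items[["nadh_credit"]] * conventions@poRatioNADH
  energyGlucose <- netATP / conventions@atpPerGlucose +
    items[["nadph_demand"]] / conventions@nadphPerGlucose
  total <- items[["glucose_skeleton"]] + max(energyGlucose, 0)
  methods::new("CostLedger",
               compoundClass = compoundClass, pathway = pathway,
               items = items, conventions = conventions,
               glucoseEquivalents = total,
               massCost = total * .MM_GLUCOSE / mm,
               molarMass = mm)
}

#' Maintenance fraction of the pre-inoculation NSC pool
#'
#' Mean percent reduction in local NSC across girdled, non-inoculated
#' trees: the share of the isolated pool consumed by baseline metabolism
#' (maintenance respiration) rather than available for defense synthesis.
#'
#' @param cohort a [DefenseCohort-class] or tree-level data.frame
#' @param pool `"total"` NSC or soluble `"sugar"` only
#' @return percent (0-100)
#' @export
maintenanceFraction <- function(cohort, pool = c("total", "sugar")) {
  pool <- match.arg(pool)
  td <- if (methods::is(cohort, "DefenseCohort")) treeData(cohort) else cohort
  pre <- nscPool(td, "pre", pool)
  post <- nscPool(td, "post", pool)
  use <- td$girdled & !td$inoculated & !is.na(post)
  zero <- use & pre == 0
  if (any(zero)) {
    warning("excluding tree(s) with zero pre-inoculation NSC: ",
            paste(td$tree_id[zero], collapse = ", "))
    use <- use & !zero
  }
  if (!any(use))
    stop("insufficient data: no girdled, non-inoculated trees with NSC ",
         "measurements")
  mean(100 * (pre[use] - post[use]) / pre[use])
}

#' NSC available for defense synthesis
#'
#' The pre-inoculation pool minus the maintenance share:
#' `nscPre * (100 - maintenance) / 100`.
#'
#' @param nscPre pre-inoculation NSC, % DW (>= 0)
#' @param maintenance maintenance fraction, percent in [0, 100]
#' @return available NSC, % DW
#' @export
nscAvailable <- function(nscPre, maintenance) {
  if (any(maintenance < 0 | maintenance > 100))
    stop("parameter error: maintenance fraction must lie in [0, 100]")
  if (any(nscPre < 0, na.rm = TRUE))
    stop("nscPre must be non-negative")
  nscPre * (100 - maintenance) / 100
}

#' Maximum potential de novo MST synthesis
#'
#' Converts available NSC (% DW) to mg g^-1 (factor 10) and divides by the
#' glucose cost of synthesis.
#'
#' @param nscAvail available NSC, % DW (>= 0)
#' @param cost g glucose per g MST (> 0); a number or a [CostLedger-class]
#' @return maximum potential MST synthesis, mg g^-1 DW
#' @export
maxPotentialMST <- function(nscAvail, cost) {
  if (methods::is(cost, "CostLedger")) cost <- massCost(cost)
  if (any(cost <= 0)) stop("parameter error: glucose cost must be positive")
  if (any(nscAvail < 0, na.rm = TRUE)) stop("nscAvail must be non-negative")
  pctToMgPerG(nscAvail) / cost
}

#' Potential percent of the observed induction
#'
#' 100 x maximum potential synthesis / observed induction, defined only for
#' trees that induced (observed change > 0). Trees with non-positive
#' observed induction are excluded: the return carries NA there and an
#' `"excluded"` attribute marking them.
#'
#' @param maxPotential mg g^-1 (>= 0)
#' @param observedDeltaT observed (corrected) MST change, mg g^-1
#' @return percent, with attribute `excluded` (logical, TRUE where the tree
#'   showed no induction)
#' @export
potentialPercentInduction <- function(maxPotential, observedDeltaT) {
  if (any(maxPotential < 0, na.rm = TRUE))
    stop("maxPotential must be non-negative")
  excluded <- !is.na(observedDeltaT) & observedDeltaT <= 0
  out <- ifelse(!excluded & !is.na(observedDeltaT),
                100 * maxPotential / observedDeltaT, NA_real_)
  attr(out, "excluded") <- excluded
  out
}

#' De novo synthesis budget for inoculated+girdled trees
#'
#' Chains [nscAvailable()], [maxPotentialMST()] and
#' [potentialPercentInduction()] per tree, recording every intermediate.
#' The budget is defined only for inoculated+girdled trees, whose isolated
#' stem section restricts synthesis to local NSC; applying it elsewhere
#' requires `allowAllTrees = TRUE` (exploratory use; scope is recorded in
#' the output).
#'
#' @param cohort a [DefenseCohort-class]
#' @param induction per-tree induction table from [correctInduction()]
#' @param cost g glucose per g MST or a [CostLedger-class]
#' @param maintenance percent in [0, 100]; `"auto"` estimates it from the
#'   cohort's girdled-only trees via [maintenanceFraction()]
#' @param pool NSC pool used for both the budget and an automatic
#'   maintenance estimate (`"total"` or `"sugar"`)
#' @param allowAllTrees include trees outside the I+G cell (logged in the
#'   `scope` column)
#' @return data.frame: tree_id, treatment, nsc_pre, maintenance_pct,
#'   nsc_available, glucose_cost, max_potential_mst, observed_delta_t,
#'   potential_percent_induction, excluded, scope
#' @export
deNovoBudget <- function(cohort, induction, cost = glucoseCost(),
                         maintenance = "auto", pool = c("total", "sugar"),
                         allowAllTrees = FALSE) {
  pool <- match.arg(pool)
  td <- treeData(cohort)
  if (identical(maintenance, "auto"))
    maintenance <- maintenanceFraction(cohort, pool)
  if (methods::is(cost, "CostLedger")) cost <- massCost(cost)
  keep <- if (allowAllTrees) rep(TRUE, nrow(td)) else treatmentCell(td) == "IG"
  if (!allowAllTrees && !any(keep))
    stop("scope error: no inoculated+girdled trees in the cohort")
  td <- td[keep, , drop = FALSE]
  ind <- induction[match(td$tree_id, induction$tree_id), , drop = FALSE]
  nscPre <- nscPool(td, "pre", pool)
  avail <- nscAvailable(nscPre, maintenance)
  maxPot <- maxPotentialMST(avail, cost)
  pct <- potentialPercentInduction(maxPot, ind$delta_t_corrected)
  data.frame(tree_id = td$tree_id,
             treatment = as.character(treatmentCell(td)),
             nsc_pre = unname(nscPre),
             maintenance_pct = maintenance,
             nsc_available = unname(avail),
             glucose_cost = cost,
             max_potential_mst = unname(maxPot),
             observed_delta_t = ind$delta_t_corrected,
             potential_percent_induction = as.numeric(pct),
             excluded = attr(pct, "excluded") | is.na(ind$delta_t_corrected),
             scope = if (allowAllTrees) "all_trees" else "ig_only",
             stringsAsFactors = FALSE)
}
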