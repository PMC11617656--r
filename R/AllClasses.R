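#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @import SummarizedExperiment
NULL

## MPa per (mmol kg^-1 * K): the van't Hoff gas-constant factor used by
## vapor-pressure osmometry (R = 8.3144598 J mol^-1 K^-1, expressed so that
## osmolality in mmol kg^-1 times temperature in K gives MPa).
.VANT_HOFF_MPA <- 8.3144598e-6

## Molar masses (g mol^-1)
.MM_GLUCOSE <- 180.156
.MM_MONOTERPENE <- 136.234   # C10H16
.MM_SESQUITERPENE <- 204.351 # C15H24

#' Experimental cohort of trees with terpene profiles
#'
#' `DefenseCohort` extends [SummarizedExperiment::SummarizedExperiment] to
#' hold one glasshouse cohort: per-compound terpene concentration matrices
#' (compounds x trees, mg per g dry weight) in the assays `terpenes_pre` and
#' `terpenes_post`, and all tree-level measurements in `colData`.
#'
#' Required `colData` columns:
#' \describe{
#'   \item{tree_id}{unique identifier}
#'   \item{water_group}{`"watered"` or `"drought"`}
#'   \item{drought_stratum}{`"well_watered"`, `"mild"` or `"moderate"`}
#'   \item{girdled, inoculated}{logical treatment flags}
#'   \item{psi_pd}{predawn shoot water potential, MPa (non-positive)}
#'   \item{osmolality}{inner-bark osmolality, mmol kg^-1 (optional, NA allowed)}
#'   \item{chamber_temp}{osmometer chamber temperature, K}
#'   \item{mst_pre, mst_post}{total mono+sesquiterpene concentration,
#'     mg g^-1 DW; `mst_post` may be NA (trees whose post-inoculation inner
#'     bark could not be sampled)}
#'   \item{starch_pre, sucrose_pre, glucose_pre, fructose_pre}{NSC fractions
#'     pre-inoculation, percent of dry weight}
#'   \item{starch_post, sucrose_post, glucose_post, fructose_post}{same,
#'     post-inoculation (NA allowed)}
#' }
#'
#' @export
setClass("DefenseCohort", contains = "SummarizedExperiment")

.REQUIRED_TREE_COLS <- c(
  "tree_id", "water_group", "drought_stratum", "girdled", "inoculated",
  "psi_pd", "osmolality", "chamber_temp", "mst_pre", "mst_post",
  "starch_pre", "sucrose_pre", "glucose_pre", "fructose_pre",
  "starch_post", "sucrose_post", "glucose_post", "fructose_post")

setValidity("DefenseCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.REQUIRED_TREE_COLS, colnames(cd))
  if (length(miss))
    return(sprintf("missing colData column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(cd$tree_id))
    return("tree_id values must be unique")
  if (!all(cd$water_group %in% c("watered", "drought")))
    return("water_group must be 'watered' or 'drought'")
  if (!all(cd$drought_stratum %in% c("well_watered", "mild", "moderate")))
    return("drought_stratum must be 'well_watered', 'mild' or 'moderate'")
  if (any((cd$drought_stratum == "well_watered") != (cd$water_group == "watered")))
    return("drought_stratum 'well_watered' must coincide with water_group 'watered'")
  if (any(cd$psi_pd > 0, na.rm = TRUE))
    return(sprintf("psi_pd must be non-positive (tree %s)",
                   cd$tree_id[which(cd$psi_pd > 0)[1]]))
  for (col in c("osmolality", "mst_pre", "mst_post")) {
    bad <- which(cd[[col]] < 0)
    if (length(bad))
      return(sprintf("%s must be non-negative (tree %s)", col, cd$tree_id[bad[1]]))
  }
  for (col in grep("^(starch|sucrose|glucose|fructose)_", .REQUIRED_TREE_COLS,
                   value = TRUE)) {
    bad <- which(cd[[col]] < 0 | cd[[col]] > 100)
    if (length(bad))
      return(sprintf("%s must lie in [0, 100] %% DW (tree %s)",
                     col, cd$tree_id[bad[1]]))
  }
  for (a in SummarizedExperiment::assayNames(object)) {
    m <- SummarizedExperiment::assay(object, a)
    if (any(m < 0, na.rm = TRUE))
      return(sprintf("assay '%s' contains negative concentrations", a))
  }
  TRUE
})

#' Parameters of the synthetic-cohort generator
#'
#' Holds the experimental-design constants and effect sizes used by
#' [simulateCohort()]. Defaults reproduce the study conditions: 14 watered /
#' 16 mild-drought / 16 moderate-drought trees with predawn water potential
#' (psi_pd) drawn uniformly within the stratum ranges, fungal-induction
#' magnitude declining by `inductionSlope` mg g^-1 per MPa of psi_pd and
#' anchored to `wateredInductionMean` at the watered-stratum mean psi_pd,
#' treatment-specific NSC depletion, and a girdle resin-loss line through the
#' two `girdleLoss*` anchors.
#'
#' @slot nWatered,nMild,nModerate tree counts per drought stratum
#' @slot psiWatered,psiMild,psiModerate psi_pd ranges (MPa, length-2)
#' @slot inductionSlope induced MST decline, mg g^-1 per MPa
#' @slot wateredInductionMean,constrainedInductionMean reference induction
#'   means (mg g^-1) for turgid and turgor-lost groups
#' @slot constitutiveMean,constitutiveSD pre-inoculation total MST (mg g^-1)
#' @slot inductionSD additive noise on induced MST (mg g^-1)
#' @slot relativeSD multiplicative measurement noise on post/pre MST ratio
#' @slot sugarPreMean,sugarPreSD soluble-sugar pool pre-inoculation (% DW)
#' @slot starchPreWatered,starchPreDrought starch pool by water group (% DW)
#' @slot depletionMean,depletionSD percent NSC depletion by treatment
#'   (named C/G/I/IG)
#' @slot girdleLossPsi,girdleLossValue two psi_pd anchors (MPa) and the
#'   relative MST losses there (dimensionless, in [-1, 0])
#' @slot soluteAtAnchor solute potential (MPa) at the watered-mean psi_pd
#' @slot osmoticAdjustment change in solute potential per MPa of psi_pd
#' @slot osmolalitySD osmolality noise (mmol kg^-1)
#' @slot chamberTempMean,chamberTempSD osmometer chamber temperature (K)
#' @slot nCompounds number of quantified terpene compounds
#' @slot dirichletConcentration concentration of the compositional sampler
#' @slot compositionShift mixing weight toward the induced composition for
#'   watered inoculated trees (0 = no shift)
#' @slot nMissingPost number of drought trees with unsampleable post tissue
#' @slot seed default RNG seed
#' @export
setClass("GeneratorParams", representation(
  nWatered = "numeric", nMild = "numeric", nModerate = "numeric",
  psiWatered = "numeric", psiMild = "numeric", psiModerate = "numeric",
  inductionSlope = "numeric",
  wateredInductionMean = "numeric", constrainedInductionMean = "numeric",
  constitutiveMean = "numeric", constitutiveSD = "numeric",
  inductionSD = "numeric", relativeSD = "numeric",
  sugarPreMean = "numeric", sugarPreSD = "numeric",
  starchPreWatered = "numeric", starchPreDrought = "numeric",
  depletionMean = "numeric", depletionSD = "numeric",
  girdleLossPsi = "numeric", girdleLossValue = "numeric",
  soluteAtAnchor = "numeric", osmoticAdjustment = "numeric",
  osmolalitySD = "numeric",
  chamberTempMean = "numeric", chamberTempSD = "numeric",
  nCompounds = "numeric", dirichletConcentration = "numeric",
  compositionShift = "numeric",
  nMissingPost = "numeric", seed = "numeric"))

setValidity("GeneratorParams", function(object) {
  counts <- c(object@nWatered, object@nMild, object@nModerate,
              object@nCompounds, object@nMissingPost)
  if (any(counts < 0)) return("counts must be non-negative")
  sds <- c(object@constitutiveSD, object@inductionSD, object@relativeSD,
           object@sugarPreSD, object@depletionSD, object@osmolalitySD,
           object@chamberTempSD)
  if (any(sds < 0)) return("standard deviations must be non-negative")
  for (r in list(object@psiWatered, object@psiMild, object@psiModerate)) {
    if (length(r) != 2 || r[1] > r[2]) return("psi ranges must be sorted length-2")
    if (r[1] < -4 || r[2] > 0) return("psi ranges must lie within [-4, 0] MPa")
  }
  if (!identical(names(object@depletionMean), c("C", "G", "I", "IG")) ||
      !identical(names(object@depletionSD), c("C", "G", "I", "IG")))
    return("depletionMean/depletionSD must be named C, G, I, IG")
  if (length(object@girdleLossPsi) != 2 || length(object@girdleLossValue) != 2)
    return("girdle-loss anchors must have two points")
  if (any(object@girdleLossValue < -1 | object@girdleLossValue > 0))
    return("girdle-loss anchor values must lie in [-1, 0]")
  if (object@chamberTempMean <= 0) return("chamberTempMean must be positive (K)")
  TRUE
})

#' Energy conventions for stoichiometric costing
#'
#' Conversion factors used to express ATP, CTP and reductant demands of
#' terpene biosynthesis as glucose equivalents.
#'
#' @slot atpPerGlucose mol ATP recovered per mol glucose fully respired
#' @slot nadphPerGlucose mol NADPH per mol glucose through the oxidative
#'   pentose-phosphate route
#' @slot poRatioNADH ATP credited per NADH reoxidized (P/O ratio)
#' @slot ctpATPEquiv ATP equivalents per CTP regenerated
#' @slot reductantPer2eStep NADPH equivalents charged per two-electron
#'   reduction step
#' @export
setClass("EnergyConventions", representation(
  atpPerGlucose = "numeric", nadphPerGlucose = "numeric",
  poRatioNADH = "numeric", ctpATPEquiv = "numeric",
  reductantPer2eStep = "numeric"))

setValidity("EnergyConventions", function(object) {
  v <- c(object@atpPerGlucose, object@nadphPerGlucose, object@poRatioNADH,
         object@ctpATPEquiv, object@reductantPer2eStep)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all energy conventions must be positive and finite")
  TRUE
})

#' Itemized glucose cost of terpene biosynthesis
#'
#' Produced by [glucoseCost()]. `items` holds the per-mole-terpene demands
#' and credits (mol): `glucose_skeleton`, `atp_demand`, `ctp_demand`,
#' `nadph_demand`, `atp_credit`, `nadh_credit`.
#'
#' @slot compoundClass "monoterpene" (C10H16) or "sesquiterpene" (C15H24)
#' @slot pathway "MEP" or "MVA"
#' @slot items named numeric vector of ledger line items (mol per mol terpene)
#' @slot conventions the [EnergyConventions-class] used
#' @slot glucoseEquivalents mol glucose per mol terpene (skeleton + net energy)
#' @slot massCost g glucose per g terpene
#' @slot molarMass g mol^-1 of the terpene
#' @export
setClass("CostLedger", representation(
  compoundClass = "character", pathway = "character",
  items = "numeric", conventions = "EnergyConventions",
  glucoseEquivalents = "numeric", massCost = "numeric",
  molarMass = "numeric"))

setValidity("CostLedger", function(object) {
  need <- c("glucose_skeleton", "atp_demand", "ctp_demand", "nadph_demand",
            "atp_credit", "nadh_credit")
  if (!all(need %in% names(object@items)))
    return(sprintf("items must contain: %s", paste(need, collapse = ", ")))
  skeleton_bound <- object@items[["glucose_skeleton"]] * .MM_GLUCOSE /
    object@molarMass
  if (object@massCost < skeleton_bound - 1e-9)
    return("massCost fell below the carbon-skeleton bound")
  TRUE
})

#' Girdle resin-loss correction model
#'
#' Ordinary least-squares relation between predawn water potential and the
#' relative girdle-induced loss of mono+sesquiterpenes, fitted on girdled,
#' non-inoculated trees; predictions are clipped to `clipBounds`.
#'
#' @slot intercept,slope regression coefficients (loss is dimensionless;
#'   slope per MPa of psi_pd)
#' @slot intercept_se,slope_se coefficient standard errors
#' @slot n number of trees used
#' @slot sigma residual standard deviation
#' @slot rSquared coefficient of determination
#' @slot clipBounds admissible range of a relative loss, default c(-1, 0)
#' @export
setClass("CorrectionModel", representation(
  intercept = "numeric", slope = "numeric",
  intercept_se = "numeric", slope_se = "numeric",
  n = "numeric", sigma = "numeric", rSquared = "numeric",
  clipBounds = "numeric"))

setValidity("CorrectionModel", function(object) {
  if (length(object@clipBounds) != 2 || object@clipBounds[1] > object@clipBounds[2])
    return("clipBounds must be sorted length-2")
  TRUE
})

#' Linear-model result with type-II ANOVA
#'
#' Wrapper produced by [fitLinearModel()]: the least-squares fit, a type-II
#' ANOVA table, and residual diagnostics.
#'
#' @slot fit the underlying [stats::lm] object
#' @slot coefficients data.frame of estimates, SEs, t and p values
#' @slot anovaTable data.frame with term, sum of squares, df, F, p (type II)
#' @slot rSquared,adjRSquared coefficients of determination
#' @slot residualSD residual standard deviation
#' @slot shapiroP Shapiro-Wilk p-value of the residuals
#' @export
setClass("LinearModelResult", representation(
  fit = "lm", coefficients = "data.frame", anovaTable = "data.frame",
  rSquared = "numeric", adjRSquared = "numeric",
  residualSD = "numeric", shapiroP = "numeric"))

#' PERMANOVA result
#'
#' @slot table data.frame with term, df, sums of squares, pseudo-F and
#'   permutation p per term
#' @slot nPerm number of permutations
#' @slot seed RNG seed used for the permutation stream
#' @export
setClass("PermanovaResult", representation(
  table = "data.frame", nPerm = "numeric", seed = "numeric"))

setValidity("PermanovaResult", function(object) {
  p <- object@table$p
  p <- p[!is.na(p)]
  if (length(p) && (any(p < 1 / (object@nPerm + 1) - 1e-12) || any(p > 1)))
    return("permutation p-values must lie in [1/(nPerm+1), 1]")
  TRUE
})
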