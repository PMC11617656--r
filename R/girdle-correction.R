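#' Raw change in MST concentration
#'
#' Post- minus pre-inoculation total mono+sesquiterpene concentration
#' (delta-T raw, mg g^-1 DW). May be negative. A missing post value yields
#' `NA`, signalling that the tree is excluded from post-tissue analyses
#' rather than zero-filled.
#'
#' @param mstPre,mstPost totals, mg g^-1 DW (>= 0)
#' @return mstPost - mstPre (mg g^-1), NA where mstPost is missing
#' @export
deltaMST <- function(mstPre, mstPost) {
  if (any(mstPre < 0, na.rm = TRUE) || any(mstPost < 0, na.rm = TRUE))
    stop("MST concentrations must be non-negative")
  mstPost - mstPre
}

#' Relative change in MST concentration
#'
#' (post - pre) / pre: the dimensionless change used to quantify
#' girdle-induced resin loss on girdled-only trees.
#'
#' @param mstPre,mstPost totals, mg g^-1 DW; `mstPre` must be positive
#' @param treeId optional identifier(s) used in error messages
#' @return dimensionless relative change
#' @export
relativeMSTChange <- function(mstPre, mstPost, treeId = NULL) {
  bad <- which(mstPre <= 0)
  if (length(bad)) {
    id <- if (is.null(treeId)) as.character(bad[1]) else treeId[bad[1]]
    stop("undefined relative change: pre-inoculation MST is zero (tree ", id, ")")
  }
  deltaMST(mstPre, mstPost) / mstPre
}

#' Fit the girdle resin-loss model
#'
#' Ordinary least squares of the relative MST change on predawn water
#' potential, using girdled, non-inoculated trees only (the girdle-alone
#' cells isolate resin loss from fungal induction). Watered trees lose more
#' resin than drought-stressed trees, so the fitted slope on psi_pd is
#' typically negative.
#'
#' @param cohort a [DefenseCohort-class] (the girdled-only subset is taken
#'   internally), or a data.frame with `psi_pd`, `mst_pre`, `mst_post`,
#'   `girdled`, `inoculated`, `tree_id`
#' @param clipBounds admissible prediction range, default `c(-1, 0)`
#' @return a [CorrectionModel-class]
#' @export
fitLossModel <- function(cohort, clipBounds = c(-1, 0)) {
  td <- if (methods::is(cohort, "DefenseCohort")) treeData(cohort) else cohort
  sub <- td[td$girdled & !td$inoculated & !is.na(td$mst_post) &
              !is.na(td$psi_pd) & td$mst_pre > 0, , drop = FALSE]
  if (nrow(sub) < 3)
    stop("insufficient data: need >= 3 girdled, non-inoculated trees with ",
         "pre/post MST (have ", nrow(sub), ")")
  if (stats::var(sub$psi_pd) == 0)
    stop("singular fit: psi_pd has zero variance among girdled trees")
  relLoss <- relativeMSTChange(sub$mst_pre, sub$mst_post, sub$tree_id)
  fit <- stats::lm(relLoss ~ psi_pd, data = data.frame(psi_pd = sub$psi_pd,
                                                       relLoss = relLoss))
  sm <- summary(fit)
  methods::new("CorrectionModel",
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               intercept_se = unname(sm$coefficients[1, 2]),
               slope_se = unname(sm$coefficients[2, 2]),
               n = nrow(sub), sigma = sm$sigma,
               rSquared = sm$r.squared, clipBounds = clipBounds)
}

#' Predict the girdle-loss correction for a tree
#'
#' Linear prediction of relative resin loss at the tree's psi_pd, clipped
#' to the model's bounds (default [-1, 0]): a predicted relative gain is
#' treated as "no loss", and a loss cannot exceed the whole pool.
#'
#' @param model a [CorrectionModel-class]
#' @param psi_pd predawn water potential, MPa (vectorized)
#' @return dimensionless correction in `model@clipBounds`
#' @export
predictCorrection <- function(model, psi_pd) {
  raw <- model@intercept + model@slope * psi_pd
  pmin(pmax(raw, model@clipBounds[1]), model@clipBounds[2])
}

#' Apply the girdle-loss correction to a raw MST change
#'
#' Two conventions are provided. `"printed"` (the default) follows the
#' published equation delta-T corrected = delta-T raw + delta-T raw x
#' Correction. `"add_back_absolute"` instead adds back the absolute
#' concentration lost, delta-T raw - Correction x mst_pre; it is provided
#' because the verbal description of the correction ("adding back the
#' relative concentration of MST lost") points the opposite way from the
#' printed equation when Correction < 0. Outputs always record which
#' convention was used.
#'
#' @param deltaTRaw raw MST change, mg g^-1 (vectorized)
#' @param correction dimensionless correction in [-1, 0]
#' @param convention `"printed"` or `"add_back_absolute"`
#' @param mstPre pre-inoculation total, required for `"add_back_absolute"`
#' @return corrected MST change, mg g^-1
#' @export
applyCorrection <- function(deltaTRaw, correction,
                            convention = c("printed", "add_back_absolute"),
                            mstPre = NULL) {
  convention <- match.arg(convention)
  if (any(correction < -1 | correction > 0, na.rm = TRUE))
    stop("parameter error: correction must lie in [-1, 0]")
  if (convention == "printed") {
    deltaTRaw * (1 + correction)
  } else {
    if (is.null(mstPre))
      stop("mstPre is required for the add_back_absolute convention")
    deltaTRaw - correction * mstPre
  }
}

#' Per-tree induction table with girdle correction
#'
#' Computes delta-T raw for every tree, fits (or takes) the resin-loss
#' model, predicts the correction for inoculated+girdled trees only (all
#' other trees pass through with correction 0), and applies the chosen
#' convention. Trees without post-inoculation tissue carry NA and an
#' exclusion reason.
#'
#' @param cohort a [DefenseCohort-class]
#' @param model optional pre-fitted [CorrectionModel-class]; fitted from
#'   the cohort's girdled-only trees when NULL
#' @param convention passed to [applyCorrection()]
#' @return data.frame: tree_id, treatment, psi_pd, mst_pre, mst_post,
#'   delta_t_raw, correction, delta_t_corrected, convention, excluded_reason
#' @export
correctInduction <- function(cohort, model = NULL,
                             convention = c("printed", "add_back_absolute")) {
  convention <- match.arg(convention)
  td <- treeData(cohort)
  if (is.null(model)) model <- fitLossModel(cohort)
  out <- data.frame(tree_id = td$tree_id,
                    treatment = as.character(treatmentCell(td)),
                    psi_pd = td$psi_pd,
                    mst_pre = td$mst_pre, mst_post = td$mst_post,
                    stringsAsFactors = FALSE)
  out$delta_t_raw <- deltaMST(td$mst_pre, td$mst_post)
  out$correction <- ifelse(out$treatment == "IG",
                           predictCorrection(model, td$psi_pd), 0)
  out$delta_t_corrected <- applyCorrection(out$delta_t_raw, out$correction,
                                           convention, mstPre = td$mst_pre)
  out$convention <- convention
  out$excluded_reason <- ifelse(is.na(td$mst_post), "missing_post_tissue", "")
  out
}
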