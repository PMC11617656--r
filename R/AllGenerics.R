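#' @rdname DefenseCohort-class
#' @param x a `DefenseCohort`
#' @export
setGeneric("treeData", function(x) standardGeneric("treeData"))

#' @rdname DefenseCohort-class
#' @param when `"pre"` or `"post"` inoculation
#' @export
setGeneric("terpenes", function(x, when = c("pre", "post"))
  standardGeneric("terpenes"))

#' @rdname CostLedger-class
#' @param x a `CostLedger`
#' @export
setGeneric("massCost", function(x) standardGeneric("massCost"))

#' @rdname CostLedger-class
#' @export
setGeneric("glucoseEquivalents", function(x) standardGeneric("glucoseEquivalents"))

#' @rdname CostLedger-class
#' @export
setGeneric("ledgerItems", function(x) standardGeneric("ledgerItems"))

#' @rdname LinearModelResult-class
#' @param x a `LinearModelResult`
#' @export
setGeneric("anovaTable", function(x) standardGeneric("anovaTable"))

#' @rdname PermanovaResult-class
#' @param x a `PermanovaResult`
#' @export
setGeneric("permanovaTable", function(x) standardGeneric("permanovaTable"))

#' @rdname DefenseCohort-class
#' @export
setMethod("treeData", "DefenseCohort", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname DefenseCohort-class
#' @export
setMethod("terpenes", "DefenseCohort", function(x, when = c("pre", "post")) {
  when <- match.arg(when)
  SummarizedExperiment::assay(x, paste0("terpenes_", when))
})

#' @rdname CostLedger-class
#' @export
setMethod("massCost", "CostLedger", function(x) x@massCost)

#' @rdname CostLedger-class
#' @export
setMethod("glucoseEquivalents", "CostLedger", function(x) x@glucoseEquivalents)

#' @rdname CostLedger-class
#' @export
setMethod("ledgerItems", "CostLedger", function(x) x@items)

#' @rdname LinearModelResult-class
#' @export
setMethod("anovaTable", "LinearModelResult", function(x) x@anovaTable)

#' @rdname PermanovaResult-class
#' @export
setMethod("permanovaTable", "PermanovaResult", function(x) x@table)

setMethod("show", "DefenseCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("DefenseCohort: %d trees, %d terpene compounds\n",
              ncol(object), nrow(object)))
  cat(sprintf("  watered %d / drought %d; girdled %d; inoculated %d\n",
              sum(cd$water_group == "watered"),
              sum(cd$water_group == "drought"),
              sum(cd$girdled), sum(cd$inoculated)))
  cat(sprintf("  psi_pd range: [%.2f, %.2f] MPa; %d trees lack post tissue\n",
              min(cd$psi_pd), max(cd$psi_pd), sum(is.na(cd$mst_post))))
})

setMethod("show", "CostLedger", function(object) {
  cat(sprintf("CostLedger: %s via %s pathway\n",
              object@compoundClass, object@pathway))
  it <- object@items
  cat(sprintf("  glucose (carbon skeleton): %.4f mol\n", it[["glucose_skeleton"]]))
  cat(sprintf("  ATP demand %.2f, CTP demand %.2f, NADPH demand %.2f mol\n",
              it[["atp_demand"]], it[["ctp_demand"]], it[["nadph_demand"]]))
  cat(sprintf("  ATP credit %.2f, NADH credit %.2f mol\n",
              it[["atp_credit"]], it[["nadh_credit"]]))
  cat(sprintf("  glucose equivalents: %.4f mol mol^-1\n",
              object@glucoseEquivalents))
  cat(sprintf("  mass cost: %.3f g glucose per g terpene\n", object@massCost))
})

setMethod("show", "CorrectionModel", function(object) {
  cat(sprintf(
    "CorrectionModel: loss = %.4f + %.4f * psi_pd (n = %d, R^2 = %.3f)\n",
    object@intercept, object@slope, object@n, object@rSquared))
  cat(sprintf("  predictions clipped to [%g, %g]\n",
              object@clipBounds[1], object@clipBounds[2]))
})

setMethod("show", "LinearModelResult", function(object) {
  cat("LinearModelResult:", deparse(formula(object@fit)), "\n")
  cat(sprintf("  R^2 = %.3f (adj %.3f), residual SD = %.3f, Shapiro-Wilk p = %.3f\n",
              object@rSquared, object@adjRSquared, object@residualSD,
              object@shapiroP))
  print(object@anovaTable, digits = 4)
})

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PermanovaResult (%d permutations, seed %d):\n",
              object@nPerm, object@seed))
  print(object@table, digits = 4)
})
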