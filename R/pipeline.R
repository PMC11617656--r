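#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]: input
#' mode (synthetic cohort or CSV files), girdle-correction convention,
#' energy conventions, maintenance mode, permutation count and seeds.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"file"` (read CSVs)
#' @param params [GeneratorParams-class] for synthetic mode
#' @param cohortPath,terpenesPrePath,terpenesPostPath input CSVs for file
#'   mode (`cohortPath` required; terpene matrices required for the
#'   compositional analysis)
#' @param convention girdle-correction convention, see [applyCorrection()]
#' @param conventions an [EnergyConventions-class]
#' @param maintenance `"auto"` or a fixed percent in [0, 100]
#' @param pool NSC pool for the budget, `"total"` or `"sugar"`
#' @param nPerm PERMANOVA permutations
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it
#' @param outDir optional output directory for CSV/JSON artifacts
#' @return a `PipelineConfig` (list)
#' @export
pipelineConfig <- function(mode = c("synthetic", "file"),
                           params = generatorParams(),
                           cohortPath = NULL, terpenesPrePath = NULL,
                           terpenesPostPath = NULL,
                           convention = c("printed", "add_back_absolute"),
                           conventions = energyConventions(),
                           maintenance = "auto", pool = "total",
                           nPerm = 999, seed = 1, outDir = NULL) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  if (mode == "file") {
    if (is.null(cohortPath))
      stop("file mode requires cohortPath")
    for (p in c(cohortPath, terpenesPrePath, terpenesPostPath))
      if (!is.null(p) && !file.exists(p))
        stop("input file not found: ", p)
  }
  if (!identical(maintenance, "auto") &&
      (!is.numeric(maintenance) || maintenance < 0 || maintenance > 100))
    stop("maintenance must be 'auto' or a percent in [0, 100]")
  structure(list(mode = mode, params = params, cohortPath = cohortPath,
                 terpenesPrePath = terpenesPrePath,
                 terpenesPostPath = terpenesPostPath,
                 convention = convention, conventions = conventions,
                 maintenance = maintenance, pool = pool,
                 nPerm = nPerm, seed = seed, outDir = outDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [pipelineConfig()];
#' `params` and `conventions` are nested maps of [generatorParams()] /
#' [energyConventions()] arguments.
#'
#' @param path YAML file
#' @return a `PipelineConfig`
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$params)) args$params <- do.call(generatorParams, y$params)
  if (!is.null(y$conventions))
    args$conventions <- do.call(energyConventions, y$conventions)
  do.call(pipelineConfig, args)
}

.lm_summary <- function(res) {
  list(coefficients = cbind(term = rownames(res@coefficients),
                            res@coefficients),
       anova = res@anovaTable, r_squared = res@rSquared,
       adj_r_squared = res@adjRSquared, residual_sd = res@residualSD,
       shapiro_p = res@shapiroP)
}

.mean_se <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, se = NA_real_, n = 0))
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)), n = length(x))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in experimental order: obtain the cohort
#' (generate or read), estimate the inner-bark water state, fit the girdle
#' resin-loss model and correct induction, estimate the maintenance
#' fraction and stoichiometric cost, build the de novo budget for
#' inoculated+girdled trees, and fit the statistical layer (induction
#' linear models, compositional PERMANOVA, principal-coordinate
#' projection). Identical configuration and seed give identical output,
#' byte-for-byte when written via `outDir`.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] or
#'   [readPipelineConfig()]
#' @return a `DefenseReport` (list): `cohort`, per-tree tables
#'   (`induction`, `budget`, `water_state`), `models`, `headline`,
#'   `provenance`
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  cohort <- switch(config$mode,
    synthetic = simulateCohort(config$params, seed = config$seed),
    file = readCohort(config$cohortPath, config$terpenesPrePath,
                      config$terpenesPostPath))
  td <- treeData(cohort)
  water <- waterState(cohort)

  lossModel <- fitLossModel(cohort)
  induction <- correctInduction(cohort, lossModel, config$convention)

  maintenance <- if (identical(config$maintenance, "auto"))
    maintenanceFraction(cohort, config$pool) else config$maintenance
  ledger <- glucoseCost("monoterpene", "MEP", config$conventions)
  budget <- deNovoBudget(cohort, induction, ledger, maintenance,
                         pool = config$pool)

  ## statistical layer
  dat <- data.frame(td, treatment = treatmentCell(td),
                    delta_t = induction$delta_t_corrected,
                    psi_pressure = water$psi_pressure,
                    nsc_pre = nscPool(td, "pre", config$pool))
  datPost <- dat[!is.na(dat$delta_t), , drop = FALSE]
  inoc <- datPost[datPost$inoculated, , drop = FALSE]
  models <- list(
    delta_vs_psi_by_inoculation = fitLinearModel(
      delta_t ~ psi_pd * inoculated, datPost),
    induction_vs_pressure = fitLinearModel(delta_t ~ psi_pressure, inoc),
    induction_vs_nsc = fitLinearModel(delta_t ~ nsc_pre, inoc),
    induction_slope_recovery = fitLinearModel(
      delta_t ~ psi_pd, inoc[!inoc$girdled, , drop = FALSE]))
  permanova <- NULL
  pcoa <- NULL
  if (nrow(cohort) > 0) {
    hasPost <- !is.na(td$mst_post) & td$mst_post > 0
    comp <- t(terpenes(cohort, "post")[, hasPost, drop = FALSE])
    d <- brayCurtis(comp, relative = TRUE)
    permanova <- compositionPermanova(
      d, data.frame(drought = td$water_group[hasPost],
                    inoculated = td$inoculated[hasPost]),
      nPerm = config$nPerm, seed = config$seed)
    pcoa <- pcoaProjection(d, k = 2)
  }

  ## headline quantities
  wateredIG <- budget[budget$treatment == "IG" & !budget$excluded &
                        budget$tree_id %in% td$tree_id[td$water_group == "watered"],
                      , drop = FALSE]
  pctStats <- .mean_se(wateredIG$potential_percent_induction)
  turgid <- water$psi_pressure > 0
  indTurgid <- .mean_se(dat$delta_t[dat$inoculated & turgid])
  indLost <- .mean_se(dat$delta_t[dat$inoculated & !turgid])
  recov <- models$induction_slope_recovery
  headline <- list(
    potential_percent_induction_watered_ig = pctStats[["mean"]],
    potential_percent_induction_watered_ig_se = pctStats[["se"]],
    induction_mean_turgid = indTurgid[["mean"]],
    induction_mean_turgor_lost = indLost[["mean"]],
    induction_ratio_turgid_vs_lost =
      if (is.na(indLost[["mean"]]) || indLost[["mean"]] == 0) NA_real_
      else indTurgid[["mean"]] / indLost[["mean"]],
    r_squared_induction_vs_pressure = models$induction_vs_pressure@rSquared,
    p_induction_vs_pressure =
      models$induction_vs_pressure@anovaTable$p[1],
    p_induction_vs_nsc = models$induction_vs_nsc@anovaTable$p[1],
    induction_slope_per_mpa = recov@coefficients["psi_pd", "estimate"],
    induction_slope_se = recov@coefficients["psi_pd", "se"],
    maintenance_fraction_pct = maintenance,
    glucose_cost_g_per_g = massCost(ledger),
    loss_model_intercept = lossModel@intercept,
    loss_model_slope = lossModel@slope)

  report <- list(
    cohort = cohort, induction = induction, budget = budget,
    water_state = water, loss_model = lossModel, cost_ledger = ledger,
    models = models, permanova = permanova, pcoa = pcoa,
    headline = headline,
    provenance = list(
      mode = config$mode, seed = config$seed, n_perm = config$nPerm,
      convention = config$convention, maintenance = maintenance,
      pool = config$pool,
      energy_conventions = list(
        atp_per_glucose = config$conventions@atpPerGlucose,
        nadph_per_glucose = config$conventions@nadphPerGlucose,
        po_ratio_nadh = config$conventions@poRatioNADH,
        ctp_atp_equiv = config$conventions@ctpATPEquiv),
      package_version = as.character(utils::packageVersion("pinyonDefense"))))
  class(report) <- c("DefenseReport", "list")

  if (!is.null(config$outDir)) {
    modelJson <- lapply(models, .lm_summary)
    modelJson$permanova <- if (is.null(permanova)) NULL else
      list(table = permanova@table, n_perm = permanova@nPerm,
           seed = permanova@seed)
    modelJson$headline <- headline
    modelJson$provenance <- report$provenance
    writeResults(list(induction = induction, stoichiometry = budget,
                      water_state = water, models = modelJson),
                 config$outDir)
  }
  report
}

#' Headline quantities of a pipeline report
#'
#' Key-value table of the report's summary quantities: mean and SE of the
#' potential percent induction for watered inoculated+girdled trees that
#' induced, induction means and ratio for the turgid (psi_pressure > 0) vs
#' turgor-lost groups, R-squared and p of induction against pressure
#' potential, p of induction against pre-inoculation NSC, the recovered
#' induction slope (from inoculated, non-girdled trees) with its SE, the
#' maintenance fraction and the glucose cost. Fields that cannot be
#' computed (e.g. an empty group) are NA, never fabricated.
#'
#' @param report a `DefenseReport` from [runPipeline()]
#' @return data.frame with columns `quantity`, `value`
#' @export
headlineSummary <- function(report) {
  stopifnot(inherits(report, "DefenseReport"))
  h <- report$headline
  data.frame(quantity = names(h),
             value = vapply(h, function(v) as.numeric(v)[1], numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
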