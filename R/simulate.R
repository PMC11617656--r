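#' Default generator parameters
#'
#' Builds a [GeneratorParams-class] object. Defaults emulate the glasshouse
#' study: 14 watered / 16 mild / 16 moderate-drought trees; psi_pd uniform
#' within [-0.91, -0.31], [-2.85, -1.66] and [-3.61, -2.86] MPa; induced
#' MST declining 15.9 mg g^-1 per MPa, anchored at 49.3 mg g^-1 for the
#' watered-stratum mean psi_pd; mean NSC depletion 52/76/89 % for girdled,
#' inoculated and inoculated+girdled trees; a girdle resin-loss line from
#' -0.43 at psi_pd = -0.31 MPa to 0 at -3.61 MPa; soluble sugars
#' 5.4 +/- 1.4 % DW; chamber temperature 305.0 +/- 0.2 K.
#'
#' @param ... named overrides of any slot of `GeneratorParams`
#' @return a validated `GeneratorParams`
#' @export
generatorParams <- function(...) {
  defaults <- list(
    nWatered = 14, nMild = 16, nModerate = 16,
    psiWatered = c(-0.91, -0.31), psiMild = c(-2.85, -1.66),
    psiModerate = c(-3.61, -2.86),
    inductionSlope = 15.9,
    wateredInductionMean = 49.3, constrainedInductionMean = 11.9,
    constitutiveMean = 30, constitutiveSD = 8,
    inductionSD = 15, relativeSD = 0.05,
    sugarPreMean = 5.4, sugarPreSD = 1.4,
    starchPreWatered = 0.3, starchPreDrought = 0.03,
    depletionMean = c(C = 0, G = 52, I = 76, IG = 89),
    depletionSD = c(C = 5, G = 11, I = 10, IG = 10),
    girdleLossPsi = c(-0.31, -3.61), girdleLossValue = c(-0.43, 0),
    soluteAtAnchor = -2.0, osmoticAdjustment = 0.25, osmolalitySD = 40,
    chamberTempMean = 305.0, chamberTempSD = 0.2,
    nCompounds = 43, dirichletConcentration = 60, compositionShift = 0.5,
    nMissingPost = 4, seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown generator parameter(s): ",
                        paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  do.call(methods::new, c(list(Class = "GeneratorParams"), defaults))
}

## Linear girdle-loss line through the two anchors: loss(psi) = a + b*psi,
## clipped to [-1, 0] when evaluated.
.loss_line <- function(params) {
  x <- params@girdleLossPsi
  y <- params@girdleLossValue
  if (x[1] == x[2]) stop("girdle-loss anchors need distinct psi values")
  b <- (y[2] - y[1]) / (x[2] - x[1])
  c(intercept = y[1] - b * x[1], slope = b)
}

.psi_anchor <- function(params) mean(params@psiWatered)

## Expected induction (mg g^-1) for an inoculated tree at psi_pd, before any
## girdle loss: linear in psi with the configured slope, anchored to the
## watered mean.
.induction_mean <- function(params, psi)
  params@wateredInductionMean +
    params@inductionSlope * (psi - .psi_anchor(params))

## Base and induced mean compositions over nCompounds compounds. The base
## blend decays geometrically (a few dominant compounds, a long tail, as in
## conifer resin); the induced blend mixes toward the reversed ranking.
.composition_means <- function(params) {
  k <- params@nCompounds
  w <- exp(-3 * seq(0, 1, length.out = max(k, 1)))
  base <- w / sum(w)
  induced <- (1 - params@compositionShift) * base +
    params@compositionShift * rev(base)
  list(base = base, induced = induced)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              ncol = n)
  sweep(g, 2, colSums(g), "/")  # compounds x samples
}

#' Simulate a synthetic experimental cohort
#'
#' Generates a [DefenseCohort-class] with the structure of the glasshouse
#' experiment: three psi_pd strata, the four treatment cells (C/G/I/IG)
#' allocated evenly within each stratum, induced MST linear in psi_pd for
#' inoculated trees, girdle resin loss following the configured loss line,
#' treatment-specific NSC depletion, an osmolality regime giving positive
#' pressure potential for watered and negative for most moderate-drought
#' trees, and Dirichlet compound profiles whose mean shifts only for
#' watered inoculated trees. A configurable number of drought trees have
#' missing post-inoculation tissue.
#'
#' @param params a [GeneratorParams-class], e.g. [generatorParams()]
#' @param seed integer RNG seed; defaults to `params@seed`
#' @return a `DefenseCohort`; `metadata()` records seed and parameters
#' @export
simulateCohort <- function(params = generatorParams(), seed = params@seed) {
  methods::validObject(params)
  set.seed(seed)
  strata <- list(well_watered = list(n = params@nWatered, r = params@psiWatered),
                 mild = list(n = params@nMild, r = params@psiMild),
                 moderate = list(n = params@nModerate, r = params@psiModerate))
  rows <- lapply(names(strata), function(s) {
    n <- strata[[s]]$n
    if (n == 0) return(NULL)
    data.frame(
      drought_stratum = s,
      psi_pd = stats::runif(n, strata[[s]]$r[1], strata[[s]]$r[2]),
      treatment = sample(rep_len(c("C", "G", "I", "IG"), n)),
      stringsAsFactors = FALSE)
  })
  trees <- do.call(rbind, rows)
  n <- nrow(trees)
  if (n == 0) stop("parameter error: zero trees requested")
  trees$tree_id <- sprintf("T%03d", seq_len(n))
  trees$water_group <- ifelse(trees$drought_stratum == "well_watered",
                              "watered", "drought")
  trees$girdled <- trees$treatment %in% c("G", "IG")
  trees$inoculated <- trees$treatment %in% c("I", "IG")

  ## total MST, mg g^-1
  trees$mst_pre <- pmax(stats::rnorm(n, params@constitutiveMean,
                                     params@constitutiveSD), 0.5)
  loss <- .loss_line(params)
  lossAt <- pmin(pmax(loss["intercept"] + loss["slope"] * trees$psi_pd, -1), 0)
  lossAt[!trees$girdled] <- 0
  ind <- .induction_mean(params, trees$psi_pd) +
    stats::rnorm(n, 0, params@inductionSD)
  postBase <- ifelse(trees$inoculated,
                     pmax(trees$mst_pre + ind, 0),
                     trees$mst_pre *
                       (1 + stats::rnorm(n, 0, params@relativeSD)))
  trees$mst_post <- pmax(postBase * (1 + lossAt), 0)

  ## NSC pools, % DW
  sugar <- pmax(stats::rnorm(n, params@sugarPreMean, params@sugarPreSD), 0.2)
  split <- .rdirichlet(n, c(10, 5, 5))  # sucrose : glucose : fructose
  trees$sucrose_pre <- sugar * split[1, ]
  trees$glucose_pre <- sugar * split[2, ]
  trees$fructose_pre <- sugar * split[3, ]
  starchMean <- ifelse(trees$water_group == "watered",
                       params@starchPreWatered, params@starchPreDrought)
  trees$starch_pre <- pmax(stats::rnorm(n, starchMean, starchMean / 3), 0)
  depl <- pmin(pmax(stats::rnorm(
    n, params@depletionMean[trees$treatment],
    params@depletionSD[trees$treatment]) / 100, 0), 1)
  for (comp in c("starch", "sucrose", "glucose", "fructose"))
    trees[[paste0(comp, "_post")]] <- trees[[paste0(comp, "_pre")]] * (1 - depl)

  ## osmometry: solute potential tracks psi_pd with partial osmotic adjustment
  trees$chamber_temp <- stats::rnorm(n, params@chamberTempMean,
                                     params@chamberTempSD)
  soluteTarget <- params@soluteAtAnchor +
    params@osmoticAdjustment * (trees$psi_pd - .psi_anchor(params))
  osmMean <- -soluteTarget / (.VANT_HOFF_MPA * params@chamberTempMean)
  trees$osmolality <- pmax(osmMean + stats::rnorm(n, 0, params@osmolalitySD), 0)

  ## compound profiles (compounds x trees), scaled to the totals
  cm <- .composition_means(params)
  conc <- params@dirichletConcentration
  k <- params@nCompounds
  shifted <- trees$water_group == "watered" & trees$inoculated
  pre <- .rdirichlet(n, conc * cm$base)
  post <- matrix(NA_real_, k, n)
  if (any(shifted))
    post[, shifted] <- .rdirichlet(sum(shifted), conc * cm$induced)
  if (any(!shifted))
    post[, !shifted] <- .rdirichlet(sum(!shifted), conc * cm$base)
  pre <- sweep(pre, 2, trees$mst_pre, "*")
  post <- sweep(post, 2, trees$mst_post, "*")
  rownames(pre) <- rownames(post) <- sprintf("compound_%02d", seq_len(k))
  colnames(pre) <- colnames(post) <- trees$tree_id

  ## unsampleable post tissue: drought trees only, mirrors the desiccated bark
  nMiss <- min(params@nMissingPost, sum(trees$water_group == "drought"))
  if (nMiss > 0) {
    missIdx <- sample(which(trees$water_group == "drought"), nMiss)
    trees$mst_post[missIdx] <- NA_real_
    for (comp in c("starch", "sucrose", "glucose", "fructose"))
      trees[[paste0(comp, "_post")]][missIdx] <- NA_real_
    post[, missIdx] <- NA_real_
  }

  cols <- c(.REQUIRED_TREE_COLS, "treatment")
  DefenseCohort(trees[, cols], pre, post,
                metadata = list(seed = seed, params = params))
}

#' Noise-free expectations of the generator
#'
#' Returns the expected values the generator targets: per tree when a
#' generated cohort is supplied (at its realized psi_pd and treatments),
#' otherwise per stratum x treatment cell at the stratum mean psi_pd.
#' Columns: expected induction before girdle loss (`e_induction`), the true
#' girdle-loss correction (`true_correction`), expected raw MST change
#' (`e_delta_mst`), and expected relative NSC depletion in percent
#' (`e_depletion_pct`). Used by parameter-recovery tests.
#'
#' @param params a `GeneratorParams`
#' @param cohort optional `DefenseCohort` produced by [simulateCohort()]
#' @return data.frame of expectations
#' @export
truthTable <- function(params = generatorParams(), cohort = NULL) {
  if (is.null(cohort)) {
    grid <- expand.grid(
      drought_stratum = c("well_watered", "mild", "moderate"),
      treatment = c("C", "G", "I", "IG"), stringsAsFactors = FALSE)
    ranges <- list(well_watered = params@psiWatered, mild = params@psiMild,
                   moderate = params@psiModerate)
    grid$psi_pd <- vapply(grid$drought_stratum,
                          function(s) mean(ranges[[s]]), numeric(1))
    df <- grid
  } else {
    td <- treeData(cohort)
    df <- data.frame(tree_id = td$tree_id, psi_pd = td$psi_pd,
                     treatment = as.character(treatmentCell(td)),
                     stringsAsFactors = FALSE)
  }
  inoculated <- df$treatment %in% c("I", "IG")
  girdled <- df$treatment %in% c("G", "IG")
  loss <- .loss_line(params)
  df$e_induction <- ifelse(inoculated, .induction_mean(params, df$psi_pd), 0)
  df$true_correction <- ifelse(
    girdled, pmin(pmax(loss["intercept"] + loss["slope"] * df$psi_pd, -1), 0), 0)
  preMean <- params@constitutiveMean
  df$e_delta_mst <- (preMean + df$e_induction) * (1 + df$true_correction) -
    preMean
  df$e_depletion_pct <- params@depletionMean[df$treatment]
  df
}

#' True parameters of the girdle-loss line implied by the anchors
#'
#' @param params a `GeneratorParams`
#' @return named numeric: `intercept`, `slope` (per MPa)
#' @export
trueLossLine <- function(params = generatorParams()) .loss_line(params)
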