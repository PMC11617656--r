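test_that("the MEP monoterpene ledger matches a hand-computed oracle", {
  ## Independent hand computation for one C10H16 monoterpene (2 IPP, MEP):
  ## skeleton: 2 glucose (one per C5 unit; pyruvate + GAP -> DXP, CO2 lost).
  ## per glucose routed to pyruvate + GAP: 2 ATP invested, 2 ATP + 1 NADH
  ## returned from the triose carried to pyruvate. Pathway per IPP: 1 NADPH
  ## (DXR), 1 CTP (MCT), 1 ATP (CMK), 2 further 2e- reductions (HDS, HDR).
  atp_demand  <- 2 * (2 + 1)            # priming + CMK
  ctp_demand  <- 2 * 1
  nadph       <- 2 * 3
  atp_credit  <- 2 * 2
  nadh_credit <- 2 * 1
  net_atp <- atp_demand + 2 * ctp_demand - atp_credit - 2.5 * nadh_credit
  glucose_eq <- 2 + nadph / 12 + net_atp / 32
  oracle_mass <- glucose_eq * 180.156 / 136.234

  led <- glucoseCost("monoterpene", "MEP")
  expect_equal(glucoseEquivalents(led), glucose_eq, tolerance = 1e-12)
  expect_equal(massCost(led), oracle_mass, tolerance = 1e-12)
  ## and the oracle itself reproduces the published rounded cost
  expect_equal(oracle_mass, 3.34, tolerance = 0.05)
  ## every line item is reported, never just the scalar
  expect_named(ledgerItems(led),
               c("glucose_skeleton", "atp_demand", "ctp_demand",
                 "nadph_demand", "atp_credit", "nadh_credit"),
               ignore.order = TRUE)
  expect_equal(ledgerItems(led)[["glucose_skeleton"]], 2)
})

test_that("carbon-skeleton-only costing reduces to molar-mass arithmetic", {
  ## with energy terms made negligible the cost collapses to the skeleton
  conv <- energyConventions(atpPerGlucose = 1e12, nadphPerGlucose = 1e12)
  led <- glucoseCost("monoterpene", "MEP", conv)
  expect_equal(massCost(led), 2 * 180.156 / 136.234, tolerance = 1e-9)
  expect_equal(massCost(led), 2.645, tolerance = 1e-3)
})

test_that("mono- and sesquiterpene mass costs coincide, per-mole costs scale", {
  mono <- glucoseCost("monoterpene", "MEP")
  sesq <- glucoseCost("sesquiterpene", "MEP")
  expect_lt(abs(massCost(mono) - massCost(sesq)) / massCost(mono), 0.01)
  expect_equal(glucoseEquivalents(sesq) / glucoseEquivalents(mono), 3 / 2,
               tolerance = 1e-12)
})

test_that("mass cost never falls below the skeleton bound", {
  set.seed(8)
  bound <- 2 * 180.156 / 136.234
  for (i in 1:25) {
    conv <- energyConventions(atpPerGlucose = runif(1, 20, 40),
                              nadphPerGlucose = runif(1, 6, 14),
                              poRatioNADH = runif(1, 1, 3),
                              ctpATPEquiv = runif(1, 1, 3))
    for (pw in c("MEP", "MVA"))
      expect_gte(massCost(glucoseCost("monoterpene", pw, conv)),
                 bound - 1e-9)
  }
  expect_error(energyConventions(atpPerGlucose = -1), "positive")
})

test_that("maintenance fraction is the mean relative NSC reduction", {
  trees <- makeTrees(2, girdled = TRUE,
                     starch_pre = 0, sucrose_pre = c(4, 4),
                     glucose_pre = 0, fructose_pre = 0,
                     starch_post = 0, sucrose_post = c(2.4, 1.6),
                     glucose_post = 0, fructose_post = 0)
  expect_equal(maintenanceFraction(DefenseCohort(trees)), 50)
  ## unchanged pools give zero
  expect_equal(maintenanceFraction(DefenseCohort(makeTrees(3, girdled = TRUE))),
               0)
  expect_error(maintenanceFraction(DefenseCohort(makeTrees(3))),
               "insufficient data")
})

test_that("a large default cohort recovers the embedded 52% depletion", {
  p <- generatorParams(nWatered = 152, nMild = 174, nModerate = 174,
                       nMissingPost = 0)
  co <- simulateCohort(p, seed = 500)
  expect_equal(maintenanceFraction(co), 52, tolerance = 3 / 52)
})

test_that("the de novo budget chain reproduces its arithmetic", {
  expect_equal(nscAvailable(5.0, 52), 2.4)
  expect_equal(nscAvailable(5.0, 100), 0)
  expect_equal(nscAvailable(5.4, 52), 2.592)
  expect_error(nscAvailable(5, 120), "\\[0, 100\\]")

  expect_equal(maxPotentialMST(2.592, 3.34), 25.92 / 3.34)
  expect_equal(maxPotentialMST(2.592, 3.34), 7.76, tolerance = 1e-2)
  expect_equal(maxPotentialMST(2.4, 3.34), 7.19, tolerance = 1e-2)
  expect_equal(maxPotentialMST(0, 3.34), 0)
  expect_error(maxPotentialMST(2, -1), "positive")

  p1 <- potentialPercentInduction(7.76, 49.3)
  expect_equal(as.numeric(p1), 15.7, tolerance = 1e-2)
  expect_false(attr(p1, "excluded"))
  expect_equal(as.numeric(potentialPercentInduction(10, 10)), 100)
  p3 <- potentialPercentInduction(5, -2)
  expect_true(attr(p3, "excluded"))
  expect_true(is.na(as.numeric(p3)))
})

test_that("maxPotentialMST is monotone in pool size and cost", {
  pools <- seq(0, 6, by = 0.5)
  out <- maxPotentialMST(pools, 3.34)
  expect_true(all(diff(out) > 0))
  expect_equal(out, 10 * pools / 3.34)          # linear in the pool
  costs <- seq(2.7, 5, by = 0.1)
  expect_true(all(diff(maxPotentialMST(2.5, costs)) < 0))
})

test_that("per-tree budgets are scoped to inoculated+girdled trees", {
  co <- simulateCohort(generatorParams(), seed = 3)
  ind <- correctInduction(co)
  b <- deNovoBudget(co, ind, cost = 3.34, maintenance = 52)
  expect_true(all(b$treatment == "IG"))
  expect_equal(b$nsc_available, b$nsc_pre * 0.48)
  expect_equal(b$max_potential_mst, 10 * b$nsc_available / 3.34)
  expect_true(all(b$excluded[!is.na(b$observed_delta_t) &
                               b$observed_delta_t <= 0]))
  ## the worked mean-level example flows through the budget chain
  trees <- makeTrees(1, girdled = TRUE, inoculated = TRUE,
                     starch_pre = 0, sucrose_pre = 5.4,
                     glucose_pre = 0, fructose_pre = 0)
  one <- DefenseCohort(trees)
  indOne <- data.frame(tree_id = "T001", delta_t_corrected = 49.3)
  bOne <- deNovoBudget(one, indOne, cost = 3.34, maintenance = 52)
  expect_equal(bOne$potential_percent_induction, 15.7, tolerance = 1e-2)
  ## sensitivity mode: maintenance 0 leaves the whole pool available
  b0 <- deNovoBudget(one, indOne, cost = 3.34, maintenance = 0)
  expect_equal(b0$nsc_available, 5.4)
  ## scope error outside I+G unless overridden
  noIG <- DefenseCohort(makeTrees(3, girdled = TRUE))
  indNo <- data.frame(tree_id = sprintf("T%03d", 1:3), delta_t_corrected = 1)
  expect_error(deNovoBudget(noIG, indNo, cost = 3.34, maintenance = 52),
               "scope error")
  bAll <- deNovoBudget(noIG, indNo, cost = 3.34, maintenance = 52,
                       allowAllTrees = TRUE)
  expect_equal(nrow(bAll), 3)
  expect_true(all(bAll$scope == "all_trees"))
})

test_that("dropping maintenance to zero never lowers potential induction", {
  co <- simulateCohort(generatorParams(), seed = 19)
  ind <- correctInduction(co)
  b52 <- deNovoBudget(co, ind, cost = 3.34, maintenance = 52)
  b0 <- deNovoBudget(co, ind, cost = 3.34, maintenance = 0)
  ok <- !b52$excluded
  expect_true(all(b0$potential_percent_induction[ok] >=
                    b52$potential_percent_induction[ok]))
})
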