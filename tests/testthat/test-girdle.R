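test_that("raw and relative MST changes follow their definitions", {
  expect_equal(deltaMST(20, 35), 15)
  expect_equal(deltaMST(20, 20), 0)
  expect_equal(deltaMST(20, 10), -10)
  expect_true(is.na(deltaMST(20, NA)))
  expect_error(deltaMST(-1, 5), "non-negative")

  expect_equal(relativeMSTChange(20, 10), -0.5)
  expect_equal(relativeMSTChange(20, 20), 0)
  expect_error(relativeMSTChange(0, 5, treeId = "T007"), "T007")
})

test_that("the loss model matches closed-form OLS on collinear points", {
  co <- makeLossCohort(psi = c(-1, -2, -3), relLoss = c(-0.4, -0.2, 0))
  m <- suppressWarnings(fitLossModel(co))
  expect_equal(m@slope, -0.2, tolerance = 1e-12)
  expect_equal(m@intercept, -0.6, tolerance = 1e-12)
  expect_equal(m@rSquared, 1, tolerance = 1e-12)

  flat <- makeLossCohort(psi = c(-1, -2, -3, -0.5), relLoss = rep(-0.3, 4))
  mf <- suppressWarnings(fitLossModel(flat))
  expect_equal(mf@slope, 0, tolerance = 1e-12)
  expect_equal(mf@intercept, -0.3, tolerance = 1e-12)
})

test_that("loss-model coefficients agree with a normal-equations oracle", {
  set.seed(31)
  psi <- runif(20, -3.6, -0.3)
  rel <- -0.45 - 0.13 * psi + rnorm(20, 0, 0.05)
  m <- fitLossModel(makeLossCohort(psi, rel))
  X <- cbind(1, psi)
  beta <- solve(t(X) %*% X, t(X) %*% rel)
  expect_equal(m@intercept, beta[1], tolerance = 1e-10)
  expect_equal(m@slope, beta[2], tolerance = 1e-10)
})

test_that("degenerate loss-model inputs raise informative errors", {
  expect_error(fitLossModel(makeLossCohort(c(-1, -2), c(-0.3, -0.2))),
               "insufficient data")
  expect_error(fitLossModel(makeLossCohort(rep(-2, 4), rep(-0.3, 4))),
               "zero variance")
  ## inoculated trees never enter the fit
  trees <- makeTrees(6, girdled = TRUE,
                     inoculated = c(rep(FALSE, 3), rep(TRUE, 3)),
                     psi_pd = c(-1, -2, -3, -1, -2, -3),
                     mst_post = c(12, 16, 20, 50, 50, 50), mst_pre = 20)
  m <- suppressWarnings(fitLossModel(DefenseCohort(trees)))
  expect_equal(m@n, 3)
  expect_equal(m@intercept, -0.6, tolerance = 1e-12)
})

test_that("predicted corrections are linear then clipped to [-1, 0]", {
  m <- new("CorrectionModel", intercept = -0.6, slope = -0.2,
           intercept_se = 0, slope_se = 0, n = 3, sigma = 0, rSquared = 1,
           clipBounds = c(-1, 0))
  expect_equal(predictCorrection(m, -2), -0.2)
  expect_equal(predictCorrection(m, -4), 0)   # raw +0.2, clipped: no gain
  expect_equal(predictCorrection(m, 0), -0.6)
  psi <- seq(-8, 2, by = 0.25)
  expect_true(all(predictCorrection(m, psi) >= -1 &
                    predictCorrection(m, psi) <= 0))
})

test_that("both correction conventions compute their arithmetic", {
  expect_equal(applyCorrection(10, 0, "printed"), 10)
  expect_equal(applyCorrection(10, -0.43, "printed"), 5.7)
  expect_equal(applyCorrection(10, -0.43, "add_back_absolute", mstPre = 20),
               18.6)
  expect_error(applyCorrection(10, 0.2), "\\[-1, 0\\]")
  expect_error(applyCorrection(10, -1.5), "\\[-1, 0\\]")
  expect_error(applyCorrection(10, -0.4, "add_back_absolute"), "mstPre")
})

test_that("correction identities and bounds hold across random inputs", {
  set.seed(77)
  for (i in 1:50) {
    draw <- rnorm(1, 0, 30)
    corr <- runif(1, -1, 0)
    pre <- runif(1, 1, 60)
    ## identity at zero correction, both conventions
    expect_equal(applyCorrection(draw, 0, "printed"), draw)
    expect_equal(applyCorrection(draw, 0, "add_back_absolute", mstPre = pre),
                 draw)
    ## printed convention shrinks and preserves sign
    out <- applyCorrection(draw, corr, "printed")
    expect_lte(abs(out), abs(draw))
    expect_gte(sign(out) * sign(draw), 0)
  }
})

test_that("the correction applies only to inoculated+girdled trees", {
  co <- simulateCohort(generatorParams(), seed = 13)
  ind <- correctInduction(co)
  ig <- ind$treatment == "IG"
  expect_true(all(ind$correction[!ig] == 0))
  expect_identical(ind$delta_t_corrected[!ig], ind$delta_t_raw[!ig])
  expect_true(all(ind$correction >= -1 & ind$correction <= 0))
  expect_true(all(ind$convention == "printed"))
  miss <- is.na(treeData(co)$mst_post)
  expect_true(all(ind$excluded_reason[miss] == "missing_post_tissue"))
  expect_true(all(is.na(ind$delta_t_corrected[miss])))
  ## alternative convention flows through and is reported
  ind2 <- correctInduction(co, convention = "add_back_absolute")
  expect_true(all(ind2$convention == "add_back_absolute"))
  expect_true(all(ind2$delta_t_corrected[ig & !miss] >=
                    ind2$delta_t_raw[ig & !miss]))
})

test_that("the loss model recovers the generator's loss line without noise", {
  p <- generatorParams(constitutiveSD = 0, inductionSD = 0, relativeSD = 0,
                       nMissingPost = 0)
  co <- simulateCohort(p, seed = 21)
  m <- suppressWarnings(fitLossModel(co))
  line <- trueLossLine(p)
  expect_equal(m@slope, unname(line["slope"]), tolerance = 1e-9)
  expect_equal(m@intercept, unname(line["intercept"]), tolerance = 1e-9)
  expect_equal(m@rSquared, 1, tolerance = 1e-9)
})
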