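test_that("exact linear data are fit exactly", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  r <- suppressWarnings(fitLinearModel(y ~ x, d))
  expect_equal(unname(coef(r@fit)), c(0, 2), tolerance = 1e-12)
  expect_equal(r@rSquared, 1, tolerance = 1e-12)
})

test_that("coefficients agree with a normal-equations oracle", {
  set.seed(14)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40),
                  g = factor(sample(c("a", "b"), 40, TRUE)))
  d$y <- 1 + 2 * d$x1 - 0.5 * d$x2 + (d$g == "b") + rnorm(40)
  r <- fitLinearModel(y ~ x1 + x2 + g, d)
  X <- cbind(1, d$x1, d$x2, as.numeric(d$g == "b"))
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(coef(r@fit)), as.numeric(beta), tolerance = 1e-10)
  ## ANOVA degrees of freedom sum to n - 1
  expect_equal(sum(anovaTable(r)$df), nrow(d) - 1)
  ## fitted decomposition reproduces the response
  expect_equal(fitted(r@fit) + residuals(r@fit), d$y,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("rank-deficient designs raise an error naming aliased terms", {
  d <- data.frame(x = 1:10, y = rnorm(10))
  d$z <- d$x
  expect_error(fitLinearModel(y ~ x + z, d), "aliased.*z")
})

test_that("the interaction structure of the design is detected", {
  p <- generatorParams(nWatered = 152, nMild = 174, nModerate = 174)
  co <- simulateCohort(p, seed = 42)
  td <- treeData(co)
  d <- data.frame(delta = td$mst_post - td$mst_pre, psi_pd = td$psi_pd,
                  inoculated = td$inoculated)
  d <- d[!is.na(d$delta), ]
  r <- fitLinearModel(delta ~ psi_pd * inoculated, d)
  an <- anovaTable(r)
  expect_lt(an$p[an$term == "psi_pd:inoculated"], 0.05)
})

test_that("Tukey contrasts control the family-wise error direction", {
  set.seed(9)
  d <- data.frame(g = factor(rep(c("a", "b", "c"), each = 30)))
  d$y <- rnorm(90, sd = 1) + ifelse(d$g == "c", 10, 0)
  r <- fitLinearModel(y ~ g, d)
  tk <- tukeyContrasts(r, "g")
  expect_equal(nrow(tk), 3)
  shifted <- grepl("c", tk$contrast)
  expect_true(all(tk$p_adjusted[shifted] < 0.05))
  expect_gt(tk$p_adjusted[!shifted], 0.05)
  ## adjusted p never undercuts unadjusted p
  expect_true(all(tk$p_adjusted >= tk$p_unadjusted - 1e-12))
  ## identical groups: difference ~0, adjusted p ~1
  d2 <- data.frame(g = factor(rep(c("a", "b"), each = 25)),
                   y = rep(rnorm(25), 2))
  tk2 <- tukeyContrasts(fitLinearModel(y ~ g, d2), "g")
  expect_equal(tk2$estimate, 0, tolerance = 1e-12)
  expect_gt(tk2$p_adjusted, 0.999)
  expect_error(tukeyContrasts(r, "nope"), "term error")
})

test_that("Bray-Curtis dissimilarities match hand-computed values", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(0, 0, 5))
  d <- as.matrix(brayCurtis(m, relative = FALSE))
  expect_equal(d["a", "b"], 0)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))
  ## disjoint supports
  dd <- as.matrix(brayCurtis(rbind(c(2, 0), c(0, 7)), relative = FALSE))
  expect_equal(dd[1, 2], 1)
  ## hand computation: |2-1| + |1-3| over (2+1) + (1+3) = 3/7
  d2 <- as.matrix(brayCurtis(rbind(c(2, 1), c(1, 3)), relative = FALSE))
  expect_equal(d2[1, 2], 3 / 7, tolerance = 1e-12)
  ## random matrix against a double-loop oracle
  set.seed(4)
  x <- matrix(runif(6 * 5), 6, 5)
  got <- as.matrix(brayCurtis(x, relative = FALSE))
  for (i in 1:6) for (j in 1:6)
    expect_equal(got[i, j], sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ]),
                 tolerance = 1e-12)
  ## relative mode normalizes rows first, and rejects empty samples
  rel <- as.matrix(brayCurtis(rbind(c(2, 2), c(5, 5)), relative = TRUE))
  expect_equal(rel[1, 2], 0, tolerance = 1e-12)
  expect_error(brayCurtis(rbind(c(1, 1), c(0, 0)), relative = TRUE),
               "zero total")
  expect_error(brayCurtis(rbind(c(-1, 1), c(0, 2))), "non-negative")
  expect_true(all(got >= 0 & got <= 1))
})

test_that("PERMANOVA detects perfect separation and is seed-stable", {
  profA <- c(5, 1, 0, 0); profB <- c(0, 0, 1, 5)
  m <- rbind(matrix(profA, 10, 4, byrow = TRUE),
             matrix(profB, 10, 4, byrow = TRUE))
  rownames(m) <- sprintf("s%02d", 1:20)
  d <- brayCurtis(m, relative = TRUE)
  des <- data.frame(group = rep(c("A", "B"), each = 10))
  r <- compositionPermanova(d, des, nPerm = 199, seed = 5)
  tab <- permanovaTable(r)
  expect_equal(tab$p[tab$term == "group"], 1 / 200)
  ## identical seed gives identical p; p respects its bounds
  r2 <- compositionPermanova(d, des, nPerm = 199, seed = 5)
  expect_identical(permanovaTable(r2), tab)
  expect_true(all(tab$p >= 1 / 200 & tab$p <= 1, na.rm = TRUE))
  ## observed pseudo-F is invariant to sample reordering
  ord <- sample(1:20)
  dOrd <- brayCurtis(m[ord, ], relative = TRUE)
  rOrd <- compositionPermanova(dOrd, data.frame(group = des$group[ord]),
                               nPerm = 199, seed = 5)
  expect_equal(permanovaTable(rOrd)$pseudoF, tab$pseudoF, tolerance = 1e-10)
  expect_error(compositionPermanova(d, data.frame(group = rep("A", 20)),
                                    nPerm = 199),
               "degenerate design")
  expect_error(compositionPermanova(d, des, nPerm = 9), "at least 99")
})

test_that("PERMANOVA partition agrees with an independent implementation", {
  set.seed(55)
  m <- matrix(rgamma(24 * 8, 2), 24, 8)
  rownames(m) <- sprintf("s%02d", 1:24)
  des <- data.frame(drought = rep(c("watered", "drought"), each = 12),
                    inoculated = rep(c(TRUE, FALSE), 12))
  d <- brayCurtis(m, relative = TRUE)
  r <- compositionPermanova(d, des, nPerm = 199, seed = 3)
  tab <- permanovaTable(r)
  ref <- vegan::adonis2(d ~ drought * inoculated, data = des,
                        permutations = 199, by = "terms")
  expect_equal(tab$ss, ref$SumOfSqs, tolerance = 1e-8)
  expect_equal(tab$df, ref$Df)
  expect_equal(tab$pseudoF[1:3], ref$F[1:3], tolerance = 1e-8)
})

test_that("principal-coordinate projection preserves distances", {
  ## three equidistant samples form an equilateral triangle
  d3 <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  pc <- pcoaProjection(d3, k = 2)
  got <- as.matrix(stats::dist(pc$points))
  expect_equal(got[lower.tri(got)], rep(1, 3), tolerance = 1e-8)
  ## duplicate samples land on coincident coordinates
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(4, 0))
  pcd <- suppressWarnings(pcoaProjection(stats::dist(m), k = 2))
  expect_equal(unname(pcd$points["a", ]), unname(pcd$points["b", ]),
               tolerance = 1e-8)
  ## full-rank Euclidean round trip to 1e-8
  set.seed(6)
  pts <- matrix(rnorm(5 * 4), 5, 4)
  dE <- stats::dist(pts)
  pcE <- pcoaProjection(dE, k = 4)
  expect_equal(as.numeric(stats::dist(pcE$points)), as.numeric(dE),
               tolerance = 1e-8)
  ## k beyond the positive spectrum truncates with a warning
  expect_warning(pcoaProjection(stats::dist(m), k = 3), "truncating")
})
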