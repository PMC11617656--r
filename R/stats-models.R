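#' Fit a linear model with type-II ANOVA and residual diagnostics
#'
#' Least-squares fit of the supplied formula, a type-II ANOVA table
#' (partial sums of squares via [car::Anova]), and residual diagnostics
#' (Shapiro-Wilk p-value, residual SD). The diagnostics are reported, never
#' used to switch methods automatically.
#'
#' @param formula model formula (factors, covariates, interactions)
#' @param data data.frame of per-tree values
#' @return a [LinearModelResult-class]
#' @export
fitLinearModel <- function(formula, data) {
  data <- stats::model.frame(formula, data)
  fit <- stats::lm(formula, data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular design: aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)
  coefTab <- as.data.frame(sm$coefficients)
  names(coefTab) <- c("estimate", "se", "t", "p")
  an <- if (length(attr(stats::terms(fit), "term.labels"))) {
    ## car::Anova refuses saturated/perfect fits; fall back to a direct
    ## type-II computation there (p-values are degenerate in that case)
    tryCatch({
      a2 <- car::Anova(fit, type = 2)
      data.frame(term = rownames(a2), ss = a2[["Sum Sq"]], df = a2[["Df"]],
                 F = a2[["F value"]], p = a2[["Pr(>F)"]],
                 stringsAsFactors = FALSE)
    }, error = function(e) .anova_type2(fit))
  } else {
    data.frame(term = "Residuals", ss = sum(stats::residuals(fit)^2),
               df = stats::df.residual(fit), F = NA_real_, p = NA_real_,
               stringsAsFactors = FALSE)
  }
  res <- stats::residuals(fit)
  shp <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
    stats::shapiro.test(res)$p.value else NA_real_
  methods::new("LinearModelResult", fit = fit, coefficients = coefTab,
               anovaTable = an, rSquared = sm$r.squared,
               adjRSquared = sm$adj.r.squared, residualSD = sm$sigma,
               shapiroP = shp)
}

## Direct type-II sums of squares: each term is tested against the model
## holding all terms except itself and anything containing it.
.anova_type2 <- function(fit) {
  X <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  asgn <- attr(X, "assign")
  tl <- attr(stats::terms(fit), "term.labels")
  rssFull <- sum(stats::residuals(fit)^2)
  dfRes <- stats::df.residual(fit)
  rss <- function(cols) {
    if (!length(cols)) return(sum((y - mean(y))^2))
    sum(qr.resid(qr(X[, cols, drop = FALSE]), y)^2)
  }
  rows <- lapply(seq_along(tl), function(i) {
    vars <- strsplit(tl[i], ":", fixed = TRUE)[[1]]
    keep <- which(vapply(seq_along(tl), function(j)
      !all(vars %in% strsplit(tl[j], ":", fixed = TRUE)[[1]]), logical(1)))
    base <- which(asgn %in% c(0, keep))
    with <- which(asgn %in% c(0, keep, i))
    ss <- rss(base) - rss(with)
    df <- sum(asgn == i)
    Fv <- (ss / df) / (rssFull / dfRes)
    data.frame(term = tl[i], ss = ss, df = df, F = Fv,
               p = stats::pf(Fv, df, dfRes, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rbind(do.call(rbind, rows),
        data.frame(term = "Residuals", ss = rssFull, df = dfRes,
                   F = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
}

#' Tukey-HSD pairwise contrasts for one factor
#'
#' All pairwise differences of estimated marginal means for `factor`, with
#' family-wise p-values from the studentized-range (Tukey) adjustment;
#' unadjusted p-values are reported alongside.
#'
#' @param result a [LinearModelResult-class]
#' @param factor name of a factor term in the model
#' @return data.frame: contrast, estimate, se, df, p_adjusted, p_unadjusted
#' @export
tukeyContrasts <- function(result, factor) {
  fit <- result@fit
  if (!factor %in% all.vars(stats::formula(fit)))
    stop("term error: '", factor, "' is not in the model")
  em <- emmeans::emmeans(fit, specs = factor)
  adj <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "tukey"))
  raw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "none"))
  data.frame(contrast = adj$contrast, estimate = adj$estimate, se = adj$SE,
             df = adj$df, p_adjusted = adj$p.value,
             p_unadjusted = raw$p.value, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = sum|x_i - x_j| / sum(x_i + x_j) over compounds, computed on
#' rows of a samples x compounds abundance matrix. With `relative = TRUE`
#' (the default, matching analysis of relative terpene composition) rows
#' are first normalized to sum to one.
#'
#' @param abundance samples x compounds matrix, non-negative
#' @param relative normalize rows to relative abundances first
#' @return a [stats::dist] object with sample labels
#' @export
brayCurtis <- function(abundance, relative = TRUE) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  if (anyNA(abundance)) stop("abundance matrix contains NA")
  if (relative) {
    tot <- rowSums(abundance)
    if (any(tot == 0)) {
      bad <- rownames(abundance)[tot == 0]
      if (is.null(bad)) bad <- which(tot == 0)
      stop("undefined sample(s) with zero total abundance: ",
           paste(bad, collapse = ", "))
    }
    abundance <- sweep(abundance, 1, tot, "/")
  }
  vegan::vegdist(abundance, method = "bray")
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate ANOVA in the distance-based
#' McArdle-Anderson form: the Gower-centered matrix of squared
#' dissimilarities is partitioned over the design terms (added
#' sequentially) via projection traces, giving sequential sums of squares
#' and pseudo-F statistics. Significance comes from raw-label
#' permutations: p = (1 + number of permuted pseudo-F >= observed) /
#' (nPerm + 1). When a term separates samples perfectly the residual sum
#' of squares is zero and the observed pseudo-F is infinite; label
#' permutations then break the separation, so p attains its floor
#' 1/(nPerm+1). The permutation stream is fixed by `seed`. Factors with a
#' single level are dropped with a warning; a design with no informative
#' factor is an error.
#'
#' @param dist a [stats::dist] (e.g. from [brayCurtis()])
#' @param design data.frame of factors, rows aligned with `dist` labels
#' @param formula right-hand-side formula over `design` columns, default
#'   all main effects and interactions of the supplied columns
#' @param nPerm number of permutations (>= 99)
#' @param seed integer seed for the permutation stream
#' @return a [PermanovaResult-class]
#' @export
compositionPermanova <- function(dist, design, formula = NULL, nPerm = 999,
                                 seed = 1) {
  if (nPerm < 99) stop("nPerm must be at least 99")
  design <- as.data.frame(design)
  n <- attr(dist, "Size")
  if (nrow(design) != n)
    stop("design rows must align with the dissimilarity matrix")
  nlev <- vapply(design, function(v) length(unique(v)), integer(1))
  if (all(nlev < 2))
    stop("degenerate design: every factor has a single level")
  if (any(nlev < 2)) {
    warning("dropping single-level factor(s): ",
            paste(colnames(design)[nlev < 2], collapse = ", "))
    design <- design[, nlev >= 2, drop = FALSE]
  }
  rhs <- if (is.null(formula))
    paste(colnames(design), collapse = " * ")
  else
    paste(deparse(formula[[2]]), collapse = "")
  tt <- stats::terms(stats::as.formula(paste("~", rhs)), data = design)
  X <- stats::model.matrix(tt, design)
  asgn <- attr(X, "assign")
  labels <- attr(tt, "term.labels")

  ## Gower-centered inner-product matrix of the squared dissimilarities
  A <- -0.5 * as.matrix(dist)^2
  G <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A)

  ## projection (hat) matrices of the cumulative sequential models
  hats <- lapply(seq_along(labels), function(i) {
    Q <- qr.Q(qr(X[, asgn <= i, drop = FALSE]))
    tcrossprod(Q)
  })
  dfTerm <- vapply(seq_along(labels), function(i) {
    qr(X[, asgn <= i, drop = FALSE])$rank -
      qr(X[, asgn <= i - 1, drop = FALSE])$rank
  }, numeric(1))
  dfRes <- n - 1 - sum(dfTerm)
  if (dfRes < 1) stop("no residual degrees of freedom for the permutation test")

  ssTotal <- sum(diag(G))
  stats_for <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ssSeq <- diff(c(0, tr))
    ssRes <- sum(diag(Gp)) - tr[length(tr)]
    Fv <- (ssSeq / dfTerm) / (ssRes / dfRes)
    ## perfect separation: zero residual (to rounding) means infinite F
    if (ssRes <= max(ssTotal, 1) * 1e-12) Fv <- rep(Inf, length(ssSeq))
    list(ss = ssSeq, ssRes = ssRes, F = Fv)
  }
  obs <- stats_for(G)
  exceed <- numeric(length(labels))
  set.seed(seed)
  for (b in seq_len(nPerm)) {
    p <- sample.int(n)
    Fp <- stats_for(G[p, p])$F
    exceed <- exceed + (Fp >= obs$F - 1e-12)
  }
  pvals <- (1 + exceed) / (nPerm + 1)
  tab <- data.frame(
    term = c(labels, "Residual", "Total"),
    df = c(dfTerm, dfRes, n - 1),
    ss = c(obs$ss, obs$ssRes, ssTotal),
    pseudoF = c(obs$F, NA_real_, NA_real_),
    p = c(pvals, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  methods::new("PermanovaResult", table = tab, nPerm = nPerm, seed = seed)
}

#' Principal-coordinate projection of a dissimilarity matrix
#'
#' Classical metric scaling ([stats::cmdscale]) used as the deterministic
#' visualization layer for compositional differences (no stress
#' optimization). When fewer positive eigenvalues than `k` are available
#' the projection is truncated with a warning.
#'
#' @param dist a [stats::dist]
#' @param k number of dimensions (>= 1)
#' @return list with `points` (samples x k coordinates) and `eigenvalues`
#' @export
pcoaProjection <- function(dist, k = 2) {
  if (k < 1) stop("k must be >= 1")
  n <- attr(dist, "Size")
  sc <- stats::cmdscale(dist, k = min(k, n - 1), eig = TRUE)
  eig <- sc$eig
  nPos <- sum(eig > max(eig) * 1e-8)
  if (k > nPos) {
    warning("only ", nPos, " positive eigenvalue(s); truncating to ", nPos,
            " dimension(s)")
    k <- nPos
  }
  pts <- sc$points[, seq_len(min(k, ncol(sc$points))), drop = FALSE]
  list(points = pts, eigenvalues = eig)
}
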