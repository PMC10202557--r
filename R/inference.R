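oneWayF <- function(y, g) {
  # vectorized one-way F for a feature matrix y (subjects x features)
  y <- as.matrix(y)
  g <- as.factor(g)
  n <- nrow(y)
  kg <- nlevels(g)
  gm <- rowsum(y, g) / as.vector(table(g))
  grand <- colMeans(y)
  ssb <- colSums(as.vector(table(g)) * sweep(gm, 2, grand)^2)
  sst <- colSums(sweep(y, 2, grand)^2)
  ssw <- sst - ssb
  dfb <- kg - 1
  dfw <- n - kg
  list(F = (ssb / dfb) / (ssw / dfw), ssb = ssb, ssw = ssw, sst = sst,
       dfb = dfb, dfw = dfw)
}

#' Eta-squared effect size
#'
#' One-way ANOVA effect size: between-group sum of squares over the total.
#'
#' @param y numeric response.
#' @param g group factor.
#' @return Scalar eta squared.
#' @export
etaSquared <- function(y, g) {
  r <- oneWayF(matrix(y, ncol = 1), g)
  as.numeric(r$ssb / r$sst)
}

#' Voxelwise (featurewise) log-F map
#'
#' Per feature, the one-way ANOVA F between groups on (log relative power)
#' values, stored as the natural log of the F ratio.
#'
#' @param features subjects x features numeric matrix.
#' @param groups group labels (length = subjects), >= 2 groups with >= 2
#'   subjects each.
#' @return List with logF (per feature), F, df.
#' @export
voxelwiseLogF <- function(features, groups) {
  features <- as.matrix(features)
  g <- as.factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 subjects each")
  r <- oneWayF(features, g)
  if (any(r$ssw <= 0))
    stop("zero within-group variance: F ratio degenerate")
  list(logF = log(r$F), F = r$F, df = c(r$dfb, r$dfw))
}

#' Permutation max-statistic correction
#'
#' Estimates, by randomization of the group labels, the null distribution of
#' the maximum statistic across ALL features (voxels/ROIs and bands jointly),
#' and corrects each feature's p-value against it:
#' p_corr = (1 + #\{perm max >= observed\}) / (n_perm + 1). This controls the
#' familywise error over the whole collection of tests without Gaussian
#' assumptions.
#'
#' @param features subjects x features matrix (stack bands as extra columns).
#' @param groups group labels.
#' @param n_perm number of permutations (default 5000).
#' @param alpha level for the corrected threshold (default 0.05).
#' @param seed RNG seed.
#' @param statistic function(features, groups) returning a per-feature
#'   statistic vector; default the log-F map.
#' @return List: observed, maxNull, threshold, pCorr, n_perm, seed.
#' @export
permutationMaxstat <- function(features, groups, n_perm = 5000, alpha = 0.05,
                               seed = 1, statistic = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  features <- as.matrix(features)
  g <- as.factor(groups)
  if (is.null(statistic))
    statistic <- function(y, gg) voxelwiseLogF(y, gg)$logF
  obs <- statistic(features, g)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  maxNull <- vapply(seq_len(n_perm), function(i) {
    max(statistic(features, g[sample.int(length(g))]))
  }, 0.0)
  pCorr <- vapply(obs, function(o) (1 + sum(maxNull >= o)) / (n_perm + 1), 0.0)
  list(observed = obs, maxNull = maxNull,
       threshold = stats::quantile(maxNull, 1 - alpha, names = FALSE),
       pCorr = pCorr, n_perm = n_perm, seed = seed)
}

#' Patient-minus-control contrast as a Z map
#'
#' Two-group contrast converted to Z through the permutation null of the
#' two-group F statistic: per feature, z = qnorm(1 - p_perm) signed by the
#' direction of the group-mean difference (group2 - group1). p is floored at
#' 1 / (n_perm + 1).
#'
#' @param features subjects x features matrix.
#' @param groups two-level labels; the FIRST level is the reference
#'   (control) group.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return Numeric vector of signed Z values.
#' @export
contrastZ <- function(features, groups, n_perm = 1000, seed = 1) {
  features <- as.matrix(features)
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("contrastZ needs exactly two groups")
  obs <- oneWayF(features, g)$F
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  exceed <- numeric(ncol(features))
  for (i in seq_len(n_perm)) {
    Fp <- oneWayF(features, g[sample.int(length(g))])$F
    exceed <- exceed + (Fp >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  dir <- sign(colMeans(features[g == levels(g)[2], , drop = FALSE]) -
                colMeans(features[g == levels(g)[1], , drop = FALSE]))
  dir * stats::qnorm(1 - p)
}

#' Minimum-statistic conjunction of two contrast maps
#'
#' The conjunction statistic is the elementwise minimum of the two Z maps;
#' a feature shows a shared processing component when min(Z1, Z2) exceeds the
#' threshold (default 1.96, the two-sided 5 percent normal cutoff), i.e. both
#' contrasts are active.
#'
#' @param z1,z2 numeric Z maps on the same feature grid.
#' @param z_thresh threshold (default 1.96).
#' @return List: minZ, significant (logical), z_thresh.
#' @export
conjunctionMin <- function(z1, z2, z_thresh = 1.96) {
  if (length(z1) != length(z2)) stop("feature grids differ")
  mz <- pmin(z1, z2)
  list(minZ = mz, significant = mz > z_thresh, z_thresh = z_thresh)
}

#' Holm-Bonferroni step-down adjusted p-values
#'
#' Classic step-down adjustment: sort ascending, adjusted p at rank k is the
#' running maximum of (m - k + 1) p_(k), capped at 1, returned in the
#' original order (delegates to \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holmBonferroni(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holmBonferroni <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

# ---- MANOVA -> ANOVA -> pairwise step-down ----------------------------------

pillaiTest <- function(Y, g) {
  g <- droplevels(as.factor(g))
  if (ncol(Y) == 1) {
    r <- oneWayF(Y, g)
    p <- stats::pf(r$F, r$dfb, r$dfw, lower.tail = FALSE)
    return(list(statistic = NA_real_, F = as.numeric(r$F),
                df1 = r$dfb, df2 = r$dfw, p = as.numeric(p),
                eta2 = as.numeric(r$ssb / r$sst)))
  }
  fit <- stats::manova(as.matrix(Y) ~ g)
  s <- summary(fit, test = "Pillai")$stats
  V <- s[1, "Pillai"]
  ns <- min(nlevels(g) - 1, ncol(Y))
  list(statistic = V, F = s[1, "approx F"], df1 = s[1, "num Df"],
       df2 = s[1, "den Df"], p = s[1, "Pr(>F)"], eta2 = V / ns)
}

#' Declarative family specification for the step-down scheme
#'
#' Helper building one node of the nested family tree used by
#' \code{manovaStepdown}: a named family of features with optional
#' subfamilies (e.g. the 12-link pgACC family with per-pair 2-link
#' subfamilies).
#'
#' @param name family name.
#' @param features character vector of feature (column) names.
#' @param children optional list of \code{familySpec} nodes partitioning the
#'   features.
#' @return A list of class \code{"familySpec"}.
#' @export
familySpec <- function(name, features, children = NULL) {
  structure(list(name = name, features = features, children = children),
            class = "familySpec")
}

#' MANOVA -> ANOVA -> pairwise step-down with Holm-Bonferroni correction
#'
#' For each family: a multivariate test (Pillai's trace with its F
#' approximation; Wilks' lambda behind \code{test}); if significant at
#' \code{alpha}, either recurse into declared subfamilies or run univariate
#' one-way ANOVAs per feature with Holm-Bonferroni correction across the
#' family; for features surviving correction, all three pairwise two-group
#' contrasts (F with 1, n-2 df) with eta-squared effect sizes.
#'
#' @param featureTable subjects x features data.frame or matrix with column
#'   names.
#' @param groups group labels.
#' @param families list of \code{familySpec} nodes (or a single node).
#' @param alpha gate level for descending the hierarchy (default 0.05).
#' @param test "pillai" (default) or "wilks".
#' @return List of class \code{"stepdownReport"} with data.frames
#'   \code{multivariate}, \code{univariate}, \code{pairwise}.
#' @export
manovaStepdown <- function(featureTable, groups, families, alpha = 0.05,
                           test = c("pillai", "wilks")) {
  test <- match.arg(test)
  Y <- as.data.frame(featureTable)
  g <- droplevels(as.factor(groups))
  if (inherits(families, "familySpec")) families <- list(families)
  multi <- list(); uni <- list(); pair <- list()

  runPairwise <- function(feature) {
    levs <- levels(g)
    cmb <- utils::combn(levs, 2)
    lapply(seq_len(ncol(cmb)), function(k) {
      sel <- g %in% cmb[, k]
      y <- Y[sel, feature]; gg <- droplevels(g[sel])
      r <- oneWayF(matrix(y, ncol = 1), gg)
      data.frame(feature = feature, group1 = cmb[1, k], group2 = cmb[2, k],
                 F = as.numeric(r$F),
                 p = stats::pf(r$F, r$dfb, r$dfw, lower.tail = FALSE),
                 eta2 = as.numeric(r$ssb / r$sst),
                 mean1 = mean(y[gg == cmb[1, k]]),
                 mean2 = mean(y[gg == cmb[2, k]]))
    })
  }

  runNode <- function(node) {
    feats <- node$features
    miss <- setdiff(feats, names(Y))
    if (length(miss))
      stop("family '", node$name, "' references unknown features: ",
           paste(miss, collapse = ", "))
    if (length(feats) > 1 && min(table(g)) <= length(feats))
      stop("family '", node$name, "' has more features than per-group ",
           "subjects; declare smaller subfamilies")
    mv <- if (test == "pillai" || length(feats) == 1) {
      pillaiTest(Y[, feats, drop = FALSE], g)
    } else {
      fit <- stats::manova(as.matrix(Y[, feats, drop = FALSE]) ~ g)
      s <- summary(fit, test = "Wilks")$stats
      list(statistic = s[1, "Wilks"], F = s[1, "approx F"],
           df1 = s[1, "num Df"], df2 = s[1, "den Df"], p = s[1, "Pr(>F)"],
           eta2 = 1 - s[1, "Wilks"]^(1 / min(nlevels(g) - 1, length(feats))))
    }
    multi[[length(multi) + 1]] <<- data.frame(
      family = node$name, n_features = length(feats),
      statistic = mv$statistic, F = mv$F, df1 = mv$df1, df2 = mv$df2,
      p = mv$p, eta2 = mv$eta2, significant = mv$p < alpha)
    if (mv$p >= alpha) return(invisible())
    if (!is.null(node$children)) {
      for (ch in node$children) runNode(ch)
      return(invisible())
    }
    r <- oneWayF(as.matrix(Y[, feats, drop = FALSE]), g)
    praw <- stats::pf(r$F, r$dfb, r$dfw, lower.tail = FALSE)
    padj <- holmBonferroni(praw)
    uniTab <- data.frame(family = node$name, feature = feats,
                         F = as.numeric(r$F), p = as.numeric(praw),
                         p_holm = as.numeric(padj),
                         eta2 = as.numeric(r$ssb / r$sst),
                         significant = padj < alpha)
    uni[[length(uni) + 1]] <<- uniTab
    for (f in feats[uniTab$significant])
      pair <<- c(pair, runPairwise(f))
    invisible()
  }
  for (node in families) runNode(node)
  structure(list(
    multivariate = if (length(multi)) do.call(rbind, multi) else data.frame(),
    univariate = if (length(uni)) do.call(rbind, uni) else data.frame(),
    pairwise = if (length(pair)) do.call(rbind, pair) else data.frame(),
    alpha = alpha, test = test, groups = levels(g)),
    class = "stepdownReport")
}

#' @export
print.stepdownReport <- function(x, ...) {
  cat("Step-down report (", x$test, ", alpha = ", x$alpha, ")\n", sep = "")
  cat("Multivariate tests:\n")
  print(x$multivariate, row.names = FALSE)
  if (nrow(x$univariate)) {
    cat("Univariate ANOVAs (Holm-corrected):\n")
    print(x$univariate, row.names = FALSE)
  }
  if (nrow(x$pairwise)) {
    cat("Pairwise contrasts:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
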