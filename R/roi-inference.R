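# ROI summarization and scalar statistics: sphere ROIs, ROI means, Bayesian
# Pearson correlations (stretched-beta prior), ANCOVA with a Levene check,
# and the basic two-group tests (t, chi-squared, Mann-Whitney z).

#' Spherical ROI around a peak coordinate
#'
#' Includes every voxel whose center lies within `radius_mm` of `center_mm`
#' (center-to-center Euclidean distance in mm via the affine).
#'
#' @param center_mm Length-3 mm coordinate (e.g. a cluster peak).
#' @param radius_mm Sphere radius in mm; 0 selects exactly the center voxel.
#' @param dim Spatial grid dimensions.
#' @param affine 4x4 voxel-to-mm affine.
#' @return Logical 3D array.
#' @export
sphere_roi <- function(center_mm, radius_mm, dim, affine) {
  stopifnot_msg(radius_mm >= 0, "radius must be >= 0")
  ijk <- as.matrix(expand.grid(seq_len(dim[1]), seq_len(dim[2]),
                               seq_len(dim[3])))
  mm <- voxel_to_mm(ijk, affine)
  d2 <- colSums((t(mm) - as.numeric(center_mm))^2)
  if (radius_mm == 0) {
    sel <- rep(FALSE, nrow(ijk))
    sel[which.min(d2)] <- TRUE
  } else {
    sel <- d2 <= radius_mm^2 + 1e-9
  }
  stopifnot_msg(any(sel), "sphere contains no voxel center (outside grid?)")
  array(sel, dim)
}

#' Mean of a map over an ROI
#'
#' Arithmetic mean over the finite in-ROI voxels.
#'
#' @param map Numeric 3D array (or vector).
#' @param roi Logical array/vector of the same length.
#' @return Scalar mean.
#' @export
extract_roi_mean <- function(map, roi) {
  stopifnot_msg(length(map) == length(roi), "map and roi shapes differ")
  v <- as.vector(map)[as.vector(roi)]
  v <- v[is.finite(v)]
  stopifnot_msg(length(v) > 0, "ROI has no finite voxels in the map")
  mean(v)
}

# Gauss hypergeometric 2F1 by series; converges for |z| < 1 and, when
# c - a - b > 0, also at z = 1. Used with a = b = 1/2, c = n - 1/2.
hyp2f1 <- function(a, b, c, z, tol = 1e-13, maxit = 500000L) {
  term <- 1
  s <- 1
  for (k in 0:maxit) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
    s <- s + term
    if (abs(term) < tol * abs(s)) return(s)
  }
  s
}

# likelihood of rho given observed r at sample size n, relative to rho = 0
# (rho-free factors cancel): exact sampling density of the Pearson r.
pearson_lik_ratio <- function(rho, r, n) {
  exp((n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r)) *
    vapply(rho, function(p) hyp2f1(0.5, 0.5, n - 0.5, (1 + p * r) / 2), 0) /
    hyp2f1(0.5, 0.5, n - 0.5, 0.5)
}

#' Bayesian Pearson correlation
#'
#' Sample Pearson correlation with the Bayes factor BF10 for a nonzero
#' population correlation, under a two-sided stretched-beta prior on rho
#' with width `kappa` (width 1, the default of common Bayesian software, is
#' uniform on (-1, 1)). BF10 is the prior-weighted integral of the exact
#' sampling-density likelihood ratio, evaluated by adaptive quadrature;
#' BF01 = 1/BF10. BF10 between 1 and 3 is conventionally read as anecdotal
#' evidence for a correlation, 3-10 moderate, > 10 strong.
#'
#' @param x,y Numeric vectors, n >= 4, finite, non-degenerate.
#' @param kappa Prior width in (0, 2\]; 1 = uniform prior.
#' @return A list of class `bayes_cor`: `r`, `n`, `bf10`, `bf01`, `kappa`.
#' @export
bayes_pearson <- function(x, y, kappa = 1) {
  stopifnot_msg(length(x) == length(y), "x and y lengths differ")
  stopifnot_msg(length(x) >= 4, "need n >= 4")
  stopifnot_msg(all(is.finite(x)) && all(is.finite(y)), "non-finite values")
  stopifnot_msg(stats::sd(x) > 0 && stats::sd(y) > 0,
                "zero variance in x or y")
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    bf10 <- Inf
  } else {
    a <- 1 / kappa
    bf10 <- stats::integrate(function(p)
      stats::dbeta((p + 1) / 2, a, a) / 2 * pearson_lik_ratio(p, r, n),
      -1, 1, rel.tol = 1e-9, subdivisions = 500L)$value
  }
  structure(list(r = r, n = n, bf10 = bf10, bf01 = 1 / bf10, kappa = kappa),
            class = "bayes_cor")
}

#' @export
print.bayes_cor <- function(x, ...) {
  cat(sprintf("Bayesian Pearson correlation: r = %.3f (n = %d), BF10 = %.3f, BF01 = %.3f\n",
              x$r, x$n, x$bf10, x$bf01))
  invisible(x)
}

#' ANCOVA group effect with a Levene check
#'
#' F-test for a group factor adjusting for covariates (type III; with a
#' single two-level factor and no interactions this equals the
#' model-comparison F of dropping the group term), plus Levene's test on the
#' model residuals as an equal-variance check.
#'
#' @param y Numeric response.
#' @param group Two-or-more-level factor.
#' @param covariates Optional data frame / named list of numeric covariates.
#' @return A list: `F`, `df` (c(df1, df2)), `p`, `levene` (list with `F`,
#'   `df`, `p`), `covariate_F` (per-covariate type-III F table).
#' @export
ancova_group_effect <- function(y, group, covariates = NULL) {
  group <- factor(group)
  stopifnot_msg(all(table(group) >= 2), "need n >= 2 per group")
  dat <- data.frame(y = y, group = group)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  full_fml <- stats::reformulate(c("group", cov_names), response = "y")
  fit_full <- stats::lm(full_fml, data = dat)
  X <- stats::model.matrix(fit_full)
  if (qr(X)$rank < ncol(X))
    stop("collinear covariates in the ANCOVA design", call. = FALSE)
  drop_term <- function(term) {
    keep <- setdiff(c("group", cov_names), term)
    fml <- if (length(keep)) stats::reformulate(keep, response = "y")
    else y ~ 1
    fit0 <- stats::lm(fml, data = dat)
    a <- stats::anova(fit0, fit_full)
    list(F = a$F[2], df = c(a$Df[2], a$Res.Df[2]), p = a$`Pr(>F)`[2])
  }
  grp_test <- drop_term("group")
  cov_tests <- lapply(cov_names, drop_term)
  names(cov_tests) <- cov_names

  # Levene (Brown-Forsythe uses medians; the classical check uses means) on
  # the residuals, by group
  res <- stats::residuals(fit_full)
  z <- abs(res - stats::ave(res, group))
  lv <- stats::anova(stats::lm(z ~ group))
  levene <- list(F = lv$`F value`[1], df = c(lv$Df[1], lv$Df[2]),
                 p = lv$`Pr(>F)`[1])
  list(F = grp_test$F, df = grp_test$df, p = grp_test$p, levene = levene,
       covariate_F = cov_tests)
}

#' Basic two-group tests
#'
#' The demographic-table statistics: two-sample t-test (Student by default,
#' Welch optional), Pearson chi-squared on a contingency table (no
#' continuity correction, matching common reporting), and the
#' normal-approximation Mann-Whitney z with tie correction.
#'
#' @param y Numeric outcome (t-test / Mann-Whitney) or a contingency table /
#'   matrix (chi-squared).
#' @param group Two-level factor (ignored for a contingency table).
#' @param test `"t"`, `"chisq"`, or `"mannwhitney"`.
#' @param welch Use the Welch t-test instead of the pooled-variance Student
#'   test.
#' @return A list with the statistic (`t`/`chisq`/`z`), `df` where defined,
#'   `p`, and `method`.
#' @export
basic_tests <- function(y, group = NULL, test = c("t", "chisq", "mannwhitney"),
                        welch = FALSE) {
  test <- match.arg(test)
  if (test == "chisq") {
    tab <- as.matrix(y)
    stopifnot_msg(all(dim(tab) >= 2), "need at least a 2x2 table")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      stop("degenerate contingency table", call. = FALSE)
    ct <- stats::chisq.test(tab, correct = FALSE)
    return(list(chisq = unname(ct$statistic), df = unname(ct$parameter),
                p = ct$p.value, method = "Pearson chi-squared"))
  }
  group <- factor(group)
  stopifnot_msg(nlevels(group) == 2, "group must have exactly 2 levels")
  g1 <- y[group == levels(group)[1]]
  g2 <- y[group == levels(group)[2]]
  if (test == "t") {
    tt <- stats::t.test(g1, g2, var.equal = !welch)
    return(list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value,
                method = if (welch) "Welch t" else "Student t"))
  }
  # Mann-Whitney z, normal approximation with tie correction
  n1 <- length(g1)
  n2 <- length(g2)
  rk <- rank(c(g1, g2))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(g1, g2))
  nn <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0) stop("degenerate data for the Mann-Whitney test",
                        call. = FALSE)
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(z = z, U = U, p = 2 * stats::pnorm(-abs(z)),
       method = "Mann-Whitney z (normal approximation, tie-corrected)")
}
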