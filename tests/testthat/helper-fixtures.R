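# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

tiny_geom <- function(dim = c(6L, 6L, 6L), n_vol = 60L, tr = 2) {
  bold_geometry(dim = dim, voxel_mm = 3, tr = tr, n_vol = n_vol)
}

# independent AUC oracle: tie-corrected Mann-Whitney P(old > new)
mw_auc_oracle <- function(rt) {
  old <- rt$rating[rt$status == "old"]
  new <- rt$rating[rt$status == "new"]
  cmp <- outer(old, new, ">") + 0.5 * outer(old, new, "==")
  mean(cmp)
}

# independent 2F1 oracle via the Euler integral representation
# 2F1(a, b; c; z) = Gamma(c)/(Gamma(b) Gamma(c-b)) *
#                   int_0^1 t^(b-1) (1-t)^(c-b-1) (1-z t)^(-a) dt
hyp2f1_euler <- function(a, b, c, z) {
  f <- function(t) t^(b - 1) * (1 - t)^(c - b - 1) * (1 - z * t)^(-a)
  exp(lgamma(c) - lgamma(b) - lgamma(c - b)) *
    stats::integrate(f, 0, 1, rel.tol = 1e-11)$value
}

# independent Bayes-factor oracle: trapezoidal quadrature over a fine rho
# grid, likelihood via the Euler-integral 2F1
bf10_oracle <- function(r, n, kappa = 1, n_grid = 2001L) {
  a <- 1 / kappa
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = n_grid)
  lik <- vapply(rho, function(p) {
    exp((n - 1) / 2 * log1p(-p^2) - (n - 1.5) * log1p(-p * r)) *
      hyp2f1_euler(0.5, 0.5, n - 0.5, (1 + p * r) / 2)
  }, 0) / hyp2f1_euler(0.5, 0.5, n - 0.5, 0.5)
  w <- stats::dbeta((rho + 1) / 2, a, a) / 2
  h <- diff(rho[1:2])
  sum((w * lik)[-1] + (w * lik)[-n_grid]) / 2 * h
}

# toy single-voxel BOLD series wrapped as a bold_series
series_as_bold <- function(y, tr = 2.58) {
  bold_series(array(y, dim = c(1, 1, 1, length(y))), tr = tr)
}

# small two-group cohort without random draws, for design tests
fixed_cohort <- function(n_per_cell = 3L) {
  cells <- expand.grid(age_group = c("young", "old"),
                       scanner = c("Verio", "Skyra"),
                       stringsAsFactors = FALSE)
  co <- cells[rep(seq_len(4), each = n_per_cell), ]
  n <- nrow(co)
  co$subject_id <- sprintf("sub-%03d", seq_len(n))
  co$sex <- rep(c("m", "f"), length.out = n)
  co$age <- ifelse(co$age_group == "young", 24, 67) + seq_len(n) %% 5
  co$hc_vol <- ifelse(co$age_group == "young", 6900, 6450) + 100 * (seq_len(n) %% 7)
  co$tiv <- 1.5e6 + 1e4 * seq_len(n)
  co$wmlv <- 500 + 100 * seq_len(n)
  rownames(co) <- NULL
  co
}
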