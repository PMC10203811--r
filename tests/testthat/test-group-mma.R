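# Voxel-wise multi-modal group GLM: masks, designs, fits, contrasts,
# permutation FWE, and overlap maps.

test_that("inclusive mask is the finite-and-nonzero intersection", {
  full <- matrix(1, 4, 10)
  expect_equal(build_inclusive_mask(full, full), rep(TRUE, 10))
  one0 <- full
  one0[2, 3] <- 0
  expect_equal(which(!build_inclusive_mask(full, one0)), 3L)
  set.seed(5)
  a <- matrix(rnorm(40), 4, 10)
  b <- matrix(rnorm(40), 4, 10)
  a[sample(40, 6)] <- 0
  b[sample(40, 5)] <- NA
  oracle <- apply(is.finite(a) & a != 0 & is.finite(b) & b != 0, 2, all)
  expect_equal(build_inclusive_mask(a, b), oracle)
  expect_error(build_inclusive_mask(matrix(0, 2, 3)), "empty")
})

test_that("the amplitude model has exactly the documented 15 columns", {
  co <- fixed_cohort(3)
  g <- tiny_geom(dim = c(4, 4, 4))
  gmv <- matrix(rlnorm(nrow(co) * 64), nrow(co))
  spec <- default_model("amplitude", analysis_mask = array(TRUE, g$dim))
  des <- assemble_designs(spec, co, maps = list(gmv = gmv))
  expect_identical(des$col_names,
                   c("young_Skyra", "young_Verio", "older_Skyra",
                     "older_Verio", "HCvol_young", "HCvol_old", "TIV_young",
                     "TIV_old", "WMLV_young", "WMLV_old", "age",
                     "GMV_young_Skyra", "GMV_young_Verio", "GMV_old_Skyra",
                     "GMV_old_Verio"))
  # group-wise centering: each group's centered covariate sums to zero
  X <- des$X0
  for (cn in c("HCvol_young", "HCvol_old", "age"))
    for (grp in c("young", "old"))
      expect_equal(sum(X[co$age_group == grp, cn]), 0, tolerance = 1e-9)
  # voxelwise columns are centered within their cell at every voxel
  vx <- des$vox[["GMV_young_Skyra"]]
  expect_equal(max(abs(colSums(vx$mat))), 0, tolerance = 1e-9)
  # missing map errors name the covariate
  expect_error(assemble_designs(spec, co), "gmv")
})

test_that("constant voxelwise covariate reduces to the scalar design", {
  co <- fixed_cohort(4)
  n <- nrow(co)
  V <- 20
  const_map <- matrix(rep(rnorm(n), V), n, V)
  spec <- group_model_spec("y", scalar_covariates = list(
    age = list(center = "groupwise_mean_center", split = FALSE)),
    voxelwise_covariates = list(cov = list(split = "none")),
    analysis_mask = rep(TRUE, V))
  des <- assemble_designs(spec, co, maps = list(cov = const_map))
  X1 <- dmnsme:::design_at(des, 1)
  X7 <- dmnsme:::design_at(des, 7)
  expect_equal(X1, X7)
  # and equals appending the centered scalar column to the base design
  expect_equal(unname(X1[, ncol(X1)]), const_map[, 1] - mean(const_map[, 1]))
})

test_that("voxelwise fit equals the per-voxel normal-equations oracle", {
  set.seed(21)
  co <- fixed_cohort(5)
  n <- nrow(co)
  V <- 100
  gmv <- matrix(rlnorm(n * V), n, V)
  Y <- matrix(rnorm(n * V), n, V)
  spec <- group_model_spec("y",
    scalar_covariates = list(age = list(center = "groupwise_mean_center",
                                        split = FALSE)),
    voxelwise_covariates = list(gmv = list(split = "cell", label = "GMV")),
    analysis_mask = rep(TRUE, V))
  des <- assemble_designs(spec, co, maps = list(gmv = gmv))
  fit <- fit_voxelwise(des, Y)
  for (v in c(1, 17, 50, 100)) {
    X <- dmnsme:::design_at(des, v)
    b <- solve(crossprod(X), crossprod(X, Y[, v]))
    expect_equal(fit$betas[, v], drop(b), tolerance = 1e-10,
                 ignore_attr = TRUE)
    r <- Y[, v] - X %*% b
    expect_equal(fit$sigma2[v], sum(r^2) / (n - ncol(X)), tolerance = 1e-10)
  }
  # t contrast at a single voxel matches the textbook formula
  st <- t_contrast(fit, c(GMV_young_Skyra = 1))
  v <- 17
  X <- dmnsme:::design_at(des, v)
  cv <- as.numeric(colnames(X) == "GMV_young_Skyra")
  tv <- sum(cv * fit$betas[, v]) /
    sqrt(fit$sigma2[v] * drop(t(cv) %*% solve(crossprod(X)) %*% cv))
  expect_equal(st$t[v], tv, tolerance = 1e-12)
})

test_that("without voxelwise covariates the fit is the standard group GLM", {
  set.seed(22)
  co <- fixed_cohort(5)
  n <- nrow(co)
  V <- 50
  Y <- matrix(rnorm(n * V), n, V)
  spec <- group_model_spec("y", scalar_covariates = list(
    hc_vol = list(center = "groupwise_mean_center", split = TRUE,
                  label = "HCvol")),
    analysis_mask = rep(TRUE, V))
  des <- assemble_designs(spec, co)
  fit <- fit_voxelwise(des, Y)
  # bit-identical to the one-shot standard GLM on the same design
  B <- qr.coef(qr(des$X0), Y)
  expect_identical(unname(fit$betas), unname(B))
})

test_that("t contrasts: antisymmetry and null calibration", {
  set.seed(23)
  co <- fixed_cohort(5)
  n <- nrow(co)
  V <- 5000
  Y <- matrix(rnorm(n * V), n, V)
  spec <- group_model_spec("y", analysis_mask = rep(TRUE, V))
  des <- assemble_designs(spec, co)
  fit <- fit_voxelwise(des, Y)
  cw <- c(young_Skyra = 0.5, young_Verio = 0.5,
          older_Skyra = -0.5, older_Verio = -0.5)
  tp <- t_contrast(fit, cw)
  tm <- t_contrast(fit, -cw)
  expect_equal(tp$t, -tm$t, tolerance = 1e-12)
  expect_equal(tp$df, n - 4)
  # null t-values follow Student t(df)
  ks <- ks.test(tp$t, "pt", df = tp$df)
  expect_gt(ks$p.value, 0.01)
  expect_error(t_contrast(fit, c(nonexistent = 1)), "unknown contrast")
  expect_error(t_contrast(fit, rep(0, 4)), "all zero")
})

test_that("permutation FWE: trivial cases, extent threshold, determinism", {
  set.seed(24)
  dims <- c(6, 6, 6)
  V <- prod(dims)
  co <- fixed_cohort(6)
  n <- nrow(co)
  spec <- group_model_spec("y", cell_factors = "age_group",
                           analysis_mask = array(TRUE, dims))
  des <- assemble_designs(spec, co)
  cw <- c(young = 1, old = -1)
  # pure noise: no supra-threshold clusters expected (checked over one run)
  Y0 <- matrix(rnorm(n * V), n, V)
  fw0 <- fwe_threshold(fit_voxelwise(des, Y0), cw, n_perm = 199, seed = 1,
                       k = 10)
  expect_equal(nrow(fw0$clusters), 0)
  # strong 5-voxel blob is removed by the k = 10 extent threshold,
  # found with k = 5
  blob <- 1:5  # contiguous along x
  Yb <- Y0
  Yb[co$age_group == "young", blob] <- Yb[co$age_group == "young", blob] + 8
  fitb <- fit_voxelwise(des, Yb)
  fw_k10 <- fwe_threshold(fitb, cw, n_perm = 199, seed = 2, k = 10)
  expect_equal(nrow(fw_k10$clusters), 0)
  expect_false(any(fw_k10$supra))
  fw_k5 <- fwe_threshold(fitb, cw, n_perm = 199, seed = 2, k = 5)
  expect_equal(nrow(fw_k5$clusters), 1)
  expect_equal(fw_k5$clusters$size, 5)
  expect_true(all(which(fw_k5$supra) %in% blob))
  # determinism under a fixed permutation seed
  fw_a <- fwe_threshold(fitb, cw, n_perm = 99, seed = 7, k = 5)
  fw_b <- fwe_threshold(fitb, cw, n_perm = 99, seed = 7, k = 5)
  expect_identical(fw_a$maxT, fw_b$maxT)
  expect_identical(fw_a$fwe_p, fw_b$fwe_p)
  # bonferroni fallback agrees on the blob
  fw_bf <- fwe_threshold(fitb, cw, method = "bonferroni", k = 5)
  expect_true(all(which(fw_bf$supra) %in% blob))
  expect_error(fwe_threshold(fit_voxelwise(
    assemble_designs(group_model_spec("y", cell_factors = "age_group",
                                      analysis_mask = rep(TRUE, 4)),
                     fixed_cohort(2)[1:8, ]), matrix(rnorm(32), 8, 4)),
    c(young = 1, old = -1)), "too few")
})

test_that("FWER is controlled under heavy-tailed (t3) null data", {
  dims <- c(5, 5, 5)
  V <- prod(dims)
  co <- fixed_cohort(5)
  n <- nrow(co)
  spec <- group_model_spec("y", cell_factors = "age_group",
                           analysis_mask = array(TRUE, dims))
  des <- assemble_designs(spec, co)
  cw <- c(young = 1, old = -1)
  set.seed(31)
  rej <- vapply(1:150, function(i) {
    Y <- matrix(rt(n * V, df = 3), n, V)
    fw <- fwe_threshold(fit_voxelwise(des, Y), cw, n_perm = 99,
                        seed = sample.int(1e6, 1), k = 1)
    any(fw$supra)
  }, NA)
  # binomial 2 SE band around 0.05 at 150 reps
  expect_lt(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 150) + 1e-9)
})

test_that("overlap maps are exact set intersections", {
  dims <- c(4, 4, 4)
  set.seed(26)
  a <- array(runif(prod(dims)) < 0.4, dims)
  b <- array(runif(prod(dims)) < 0.4, dims)
  ov <- overlap_maps(a, b, dim = dims)
  expect_equal(as.vector(ov$overlap), as.vector(a) & as.vector(b))
  expect_equal(as.vector(overlap_maps(a, a, dim = dims)$overlap),
               as.vector(a))
  disj <- overlap_maps(a, array(FALSE, dims), dim = dims)
  expect_false(any(disj$overlap))
  expect_equal(nrow(disj$clusters), 0)
  expect_error(overlap_maps(a, array(TRUE, c(2, 2, 2))), "mismatch")
})

test_that("cluster peaks are reported in mm via the affine", {
  dims <- c(6, 6, 6)
  co <- fixed_cohort(6)
  n <- nrow(co)
  spec <- group_model_spec("y", cell_factors = "age_group",
                           analysis_mask = array(TRUE, dims))
  des <- assemble_designs(spec, co)
  set.seed(27)
  Y <- matrix(rnorm(n * prod(dims)), n)
  idx <- which(array(seq_len(prod(dims)), dims) %in%
                 which(sphere_roi(c(0, 0, 0), 5, dims, ras_affine(3, dims))))
  Y[co$age_group == "young", idx] <- Y[co$age_group == "young", idx] + 6
  fw <- fwe_threshold(fit_voxelwise(des, Y), c(young = 1, old = -1),
                      n_perm = 199, seed = 3, k = 3,
                      affine = ras_affine(3, dims))
  expect_gt(nrow(fw$clusters), 0)
  peak_mm <- c(fw$clusters$peak_x[1], fw$clusters$peak_y[1],
               fw$clusters$peak_z[1])
  expect_lt(sqrt(sum(peak_mm^2)), 5 + 1e-9)
})
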