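# Synthetic cohort, ratings, and image generators.

test_that("cohorts are deterministic under a seed and validate their spec", {
  s <- cohort_spec(n_young = 20, n_old = 20, seed = 5)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$manifest$subject_seeds, b$manifest$subject_seeds)
  c2 <- generate_cohort(cohort_spec(n_young = 20, n_old = 20, seed = 6))
  expect_false(identical(a$cohort$hc_vol, c2$cohort$hc_vol))
  expect_error(cohort_spec(n_young = 0), "counts")
  expect_error(cohort_spec(auc_sd = -1), "SDs")
  expect_error(cohort_spec(age_range_young = c(18, 65)), "overlap")
})

test_that("cohort covariate moments converge to the spec (n = 2000, 2 SE)", {
  s <- cohort_spec(n_young = 2000, n_old = 2000, seed = 10)
  co <- generate_cohort(s)$cohort
  y <- co[co$age_group == "young", ]
  o <- co[co$age_group == "old", ]
  expect_lt(abs(mean(y$hc_vol) - s$hc_mean_young),
            2 * s$hc_sd_young / sqrt(2000))
  expect_lt(abs(mean(o$hc_vol) - s$hc_mean_old),
            2 * s$hc_sd_old / sqrt(2000))
  expect_lt(abs(mean(y$scanner == "Verio") - s$p_verio_young),
            2 * sqrt(0.25 / 2000))
  # degenerate SD pins the value exactly
  s0 <- cohort_spec(n_young = 50, n_old = 2, hc_sd_young = 0, seed = 2)
  co0 <- generate_cohort(s0)$cohort
  expect_true(all(co0$hc_vol[co0$age_group == "young"] == s0$hc_mean_young))
  # ages stay inside their group ranges
  expect_true(all(y$age >= 18 & y$age <= 35))
  expect_true(all(o$age >= 60 & o$age <= 80))
})

test_that("rating generator is calibrated to its target AUC", {
  rt <- generate_ratings(0.82, 88, 44, seed = 1)
  expect_equal(nrow(rt), 132)
  expect_true(all(rt$rating %in% 1:5))
  # null separation: expected AUC 0.5 over 10,000 items
  big0 <- generate_ratings(0.5, 10000, 10000, seed = 2)
  expect_equal(compute_auc(big0), 0.5, tolerance = 0.02)
  # calibrated separation: empirical AUC within ~2 SE of 0.82 at n = 10,000;
  # SE estimated by replication
  aucs <- vapply(1:12, function(i)
    compute_auc(generate_ratings(0.82, 10000, 10000, seed = 100 + i)), 0)
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.82), 2 * se + 1e-4)
  # continuous-model inversion is a lower bound on the calibrated separation
  d_binned <- dmnsme:::calibrate_dprime(0.82)
  expect_gte(d_binned, sqrt(2) * qnorm(0.82) - 1e-9)
  expect_error(generate_ratings(0.8, 0, 10), "counts")
})

test_that("rest generator: determinism, band limits, amplitude contract", {
  g <- tiny_geom(dim = c(6, 6, 6), n_vol = 96, tr = 2.5)
  roi <- synthetic_roi_set(g)
  subj <- list(true_rest_amplitude_dmn = 3.0)
  a <- generate_rest_bold(subj, g, roi$dmn_mask, seed = 3, white_sd = 0.5)
  b <- generate_rest_bold(subj, g, roi$dmn_mask, seed = 3, white_sd = 0.5)
  expect_identical(a$data, b$data)
  expect_error(generate_rest_bold(subj, g, array(FALSE, g$dim), seed = 1),
               "empty")
  # >= 95% of spectral power inside the band when white noise is off
  clean <- generate_rest_bold(subj, g, roi$dmn_mask, seed = 4, white_sd = 0)
  y <- clean$data[1, 1, 1, ] - mean(clean$data[1, 1, 1, ])
  pw <- Mod(fft(y))^2
  freq <- (seq_along(y) - 1) / (length(y) * g$tr)
  freq <- pmin(freq, 1 / g$tr - freq)
  inband <- freq >= 0.01 - 1e-12 & freq <= 0.08 + 1e-12
  expect_gte(sum(pw[inband]) / sum(pw), 0.95)
  # zero amplitude + zero noise -> constant image, PerAF all zero
  z <- generate_rest_bold(list(true_rest_amplitude_dmn = 0), g, roi$dmn_mask,
                          seed = 5, background_amp = 0, white_sd = 0)
  expect_equal(max(z$data) - min(z$data), 0)
  expect_true(all(compute_peraf(z)$data == 0))
})

test_that("task generator: event contract and null SME", {
  g <- tiny_geom(dim = c(4, 4, 4), n_vol = 60, tr = 2.58)
  roi <- synthetic_roi_set(g)
  subj <- list(true_sme_beta_dmn = -1, auc_target = 0.8)
  tk <- generate_task_run(subj, g, roi$dmn_mask, seed = 7, n_scans = 206)
  expect_equal(nrow(tk$events), 132)
  expect_true(all(tk$events$duration == 2.5))
  expect_equal(sum(tk$events$trial_type == "novel"), 88)
  expect_true(all(diff(tk$events$onset) > 0))
  expect_true(all(tk$events$rating[tk$events$trial_type == "novel"] %in% 1:5))
  expect_true(all(is.na(tk$events$rating[tk$events$trial_type == "master"])))
  expect_error(generate_task_run(subj, g, roi$dmn_mask, seed = 7,
                                 n_scans = 60),
               "too short")
  # null effect: SME estimates centered on zero across simulations
  subj0 <- list(true_sme_beta_dmn = 0, auc_target = 0.8)
  ev <- event_spec(n_novel = 20, n_master = 10)
  est <- vapply(1:100, function(i) {
    tk <- generate_task_run(subj0, g, roi$dmn_mask, seed = 1000 + i,
                            events = ev, n_scans = 60, noise_sd = 1)
    mean(fit_first_level(tk$bold, tk$design)$sme[roi$dmn_mask])
  }, 0)
  expect_lt(abs(mean(est)), 2 * sd(est) / sqrt(length(est)))
})

test_that("covariate maps: determinism, positivity, null group contrast", {
  g <- tiny_geom(dim = c(5, 5, 5))
  co <- generate_cohort(cohort_spec(n_young = 12, n_old = 12, seed = 3))$cohort
  m1 <- generate_covariate_maps(co, g, seed = 11)
  m2 <- generate_covariate_maps(co, g, seed = 11)
  expect_identical(m1, m2)
  expect_true(all(m1 > 0))
  expect_equal(rownames(m1), co$subject_id)
  # ROI labels partition their voxels
  roi <- synthetic_roi_set(g)
  expect_true(all(roi$labels %in% 0:3))
  expect_equal(sum(roi$dmn_mask), sum(roi$labels > 0))
  # with zero injected group difference, a group contrast on GMV maps is
  # null at alpha = .05 FWE in most runs (checked over 20 runs)
  spec <- group_model_spec("gmv", cell_factors = "age_group",
                           analysis_mask = array(TRUE, g$dim))
  hits <- vapply(1:20, function(i) {
    coi <- generate_cohort(cohort_spec(n_young = 12, n_old = 12,
                                       seed = 20 + i))$cohort
    M <- generate_covariate_maps(coi, g, seed = 40 + i)
    fit <- fit_voxelwise(assemble_designs(spec, coi), M)
    fw <- fwe_threshold(fit, c(old = 1, young = -1), n_perm = 99,
                        seed = 60 + i, k = 1)
    any(fw$supra)
  }, NA)
  expect_lte(mean(hits), 0.2)
})

test_that("per-subject seeds are stable hashes", {
  expect_identical(subject_seed(1, "sub-001"), subject_seed(1L, "sub-001"))
  expect_false(subject_seed(1, "sub-001") == subject_seed(2, "sub-001"))
  expect_false(subject_seed(1, "sub-001") == subject_seed(1, "sub-002"))
})
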