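# Synthetic cohort, behavior, and image generator.
#
# Emulates the stated world of a two-scanner, two-age-group incidental
# encoding study: cohort covariates calibrated to the published group
# summaries, 5-point recognition-confidence ratings from an equal-variance
# Gaussian signal-detection model, band-limited resting-state BOLD whose DMN
# amplitude differs by age group, and task runs whose DMN response scales
# with the subsequent-memory modulator. Everything is reproducible from a
# master seed; per-subject seeds are derived by stable hashing.

#' Acquisition geometry for synthetic images
#'
#' @param dim Spatial grid (length 3); default 24^3, a desk-scale stand-in
#'   for the 3 mm EPI grid.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param tr Repetition time in seconds (default 2.58, as acquired).
#' @param n_vol Number of volumes (default 184, a 7:54 min rest run).
#' @return A list of class `bold_geometry` with an RAS affine.
#' @export
bold_geometry <- function(dim = c(24L, 24L, 24L), voxel_mm = 3, tr = 2.58,
                          n_vol = 184L) {
  stopifnot_msg(length(dim) == 3 && all(dim >= 2), "dim must be length 3, >= 2")
  structure(list(dim = as.integer(dim), voxel_mm = voxel_mm, tr = tr,
                 n_vol = as.integer(n_vol),
                 affine = ras_affine(voxel_mm, dim)),
            class = "bold_geometry")
}

#' Cohort specification
#'
#' Defaults are calibrated to the published demographics and group summaries:
#' 106 young / 111 older participants, scanner split 58/48 (young) and 64/47
#' (older) between Verio and Skyra, recognition AUC 0.82 (young) vs 0.77
#' (older) with SD 0.07, total hippocampal volume 6890.91 +/- 638.65 mm^3
#' (young) vs 6453.07 +/- 593.21 mm^3 (older), ages 24.12 +/- 4.00 in 18-35
#' and 67.28 +/- 4.65 in 60-80 years. TIV and white-matter lesion volume
#' (log-normal, right-skewed) defaults are field-realistic choices; see the
#' methods vignette.
#'
#' @param n_young,n_old Group sizes.
#' @param p_verio_young,p_verio_old Proportion scanned on the Verio.
#' @param p_female_young,p_female_old Proportion female.
#' @param auc_mean_young,auc_mean_old,auc_sd Target recognition AUC
#'   distribution per group (truncated to (0.5, 0.99)).
#' @param hc_mean_young,hc_mean_old,hc_sd_young,hc_sd_old Total hippocampal
#'   volume, mm^3.
#' @param tiv_mean,tiv_sd Total intracranial volume, mm^3.
#' @param wmlv_meanlog_young,wmlv_sdlog_young,wmlv_meanlog_old,wmlv_sdlog_old
#'   Log-normal white-matter lesion volume parameters per group (mm^3).
#' @param age_range_young,age_range_old,age_mean_young,age_sd_young,
#'   age_mean_old,age_sd_old Truncated-normal age model per group, years.
#' @param rest_amp_mean_young,rest_amp_mean_old,rest_amp_sd True DMN
#'   resting fluctuation amplitude (PerAF %), per group.
#' @param rest_amp_background Background (non-DMN) amplitude, PerAF %.
#' @param sme_beta_mean_young,sme_beta_mean_old,sme_beta_sd True DMN SME
#'   effect (signal units per PM unit); negative = deactivation predicts
#'   remembering.
#' @param coupling_slope_young,coupling_slope_old Slope of the true DMN SME
#'   beta on the subject's DMN rest amplitude (young-only coupling by
#'   default), mirroring the negative rest-encoding relationship observed in
#'   young adults.
#' @param scanner_effect Multiplicative scanner (Skyra) factor on rest
#'   amplitude, to exercise scanner-confound models; default 1 (off).
#' @param seed Master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 106L, n_old = 111L,
                        p_verio_young = 58 / 106, p_verio_old = 64 / 111,
                        p_female_young = 59 / 106, p_female_old = 65 / 111,
                        auc_mean_young = 0.82, auc_mean_old = 0.77,
                        auc_sd = 0.07,
                        hc_mean_young = 6890.91, hc_mean_old = 6453.07,
                        hc_sd_young = 638.65, hc_sd_old = 593.21,
                        tiv_mean = 1.5e6, tiv_sd = 1.5e5,
                        wmlv_meanlog_young = log(500), wmlv_sdlog_young = 0.8,
                        wmlv_meanlog_old = log(3000), wmlv_sdlog_old = 1.0,
                        age_range_young = c(18, 35), age_range_old = c(60, 80),
                        age_mean_young = 24.12, age_sd_young = 4.00,
                        age_mean_old = 67.28, age_sd_old = 4.65,
                        rest_amp_mean_young = 3.0, rest_amp_mean_old = 2.4,
                        rest_amp_sd = 0.5, rest_amp_background = 2.0,
                        sme_beta_mean_young = -1.0, sme_beta_mean_old = -0.4,
                        sme_beta_sd = 0.25,
                        coupling_slope_young = -0.8, coupling_slope_old = 0,
                        scanner_effect = 1, seed = 1L) {
  spec <- as.list(environment())
  stopifnot_msg(n_young > 0 && n_old > 0, "group counts must be > 0")
  stopifnot_msg(auc_mean_young >= 0 && auc_mean_young <= 1 &&
                  auc_mean_old >= 0 && auc_mean_old <= 1,
                "AUC means must lie in [0, 1]")
  stopifnot_msg(all(c(auc_sd, hc_sd_young, hc_sd_old, tiv_sd, rest_amp_sd,
                      sme_beta_sd, age_sd_young, age_sd_old) >= 0),
                "SDs must be >= 0")
  stopifnot_msg(age_range_young[2] < age_range_old[1] ||
                  age_range_old[2] < age_range_young[1],
                "age ranges must not overlap between groups")
  structure(spec, class = "cohort_spec")
}

# truncated-normal draw by rejection (cheap at these bounds)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort
#'
#' Draws per-subject demographics, structural covariates, target memory
#' performance, and ground-truth imaging effect sizes from a [cohort_spec].
#' Identical seeds yield identical cohorts; per-subject seeds (in the
#' manifest) are derived by stable hashing of (master seed, subject_id).
#'
#' @param spec A [cohort_spec].
#' @return A list with `cohort` (data frame, one row per subject) and
#'   `manifest` (ground-truth bookkeeping: master seed, per-subject seeds,
#'   generator parameters).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot_msg(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  n <- spec$n_young + spec$n_old
  ids <- sprintf("sub-%03d", seq_len(n))
  grp <- rep(c("young", "old"), c(spec$n_young, spec$n_old))
  with_seed(spec$seed, {
    scanner <- ifelse(stats::runif(n) < ifelse(grp == "young",
                                               spec$p_verio_young,
                                               spec$p_verio_old),
                      "Verio", "Skyra")
    sex <- ifelse(stats::runif(n) < ifelse(grp == "young",
                                           spec$p_female_young,
                                           spec$p_female_old), "f", "m")
    age <- numeric(n)
    age[grp == "young"] <- rtrunc_norm(spec$n_young, spec$age_mean_young,
                                       spec$age_sd_young,
                                       spec$age_range_young[1],
                                       spec$age_range_young[2])
    age[grp == "old"] <- rtrunc_norm(spec$n_old, spec$age_mean_old,
                                     spec$age_sd_old,
                                     spec$age_range_old[1],
                                     spec$age_range_old[2])
    hc <- ifelse(grp == "young",
                 stats::rnorm(n, spec$hc_mean_young, spec$hc_sd_young),
                 stats::rnorm(n, spec$hc_mean_old, spec$hc_sd_old))
    tiv <- stats::rnorm(n, spec$tiv_mean, spec$tiv_sd)
    wmlv <- ifelse(grp == "young",
                   stats::rlnorm(n, spec$wmlv_meanlog_young,
                                 spec$wmlv_sdlog_young),
                   stats::rlnorm(n, spec$wmlv_meanlog_old,
                                 spec$wmlv_sdlog_old))
    auc <- numeric(n)
    auc[grp == "young"] <- rtrunc_norm(spec$n_young, spec$auc_mean_young,
                                       spec$auc_sd, 0.5, 0.99)
    auc[grp == "old"] <- rtrunc_norm(spec$n_old, spec$auc_mean_old,
                                     spec$auc_sd, 0.5, 0.99)
    amp <- ifelse(grp == "young",
                  stats::rnorm(n, spec$rest_amp_mean_young, spec$rest_amp_sd),
                  stats::rnorm(n, spec$rest_amp_mean_old, spec$rest_amp_sd))
    amp <- pmax(amp, 0.2)
    amp <- amp * ifelse(scanner == "Skyra", spec$scanner_effect, 1)
    slope <- ifelse(grp == "young", spec$coupling_slope_young,
                    spec$coupling_slope_old)
    amp_ref <- ifelse(grp == "young", spec$rest_amp_mean_young,
                      spec$rest_amp_mean_old)
    sme <- ifelse(grp == "young", spec$sme_beta_mean_young,
                  spec$sme_beta_mean_old) +
      slope * (amp - amp_ref) + stats::rnorm(n, 0, spec$sme_beta_sd)
    cohort <- data.frame(
      subject_id = ids, age_group = grp, scanner = scanner, sex = sex,
      age = age, hc_vol = hc, tiv = tiv, wmlv = wmlv,
      auc_target = auc, true_rest_amplitude_dmn = amp,
      true_sme_beta_dmn = sme, stringsAsFactors = FALSE)
  })
  stopifnot_msg(all(cohort$hc_vol > 0) && all(cohort$tiv > 0) &&
                  all(cohort$wmlv > 0), "non-positive structural volume drawn")
  manifest <- list(
    master_seed = spec$seed,
    subject_seeds = stats::setNames(
      vapply(ids, function(i) subject_seed(spec$seed, i), 1L), ids),
    spec = unclass(spec))
  list(cohort = cohort, manifest = manifest)
}

# Expected trapezoidal AUC of ratings binned by `criteria`, for an
# equal-variance Gaussian SDT model with separation dprime. Equals the
# tie-corrected P(old > new) of the binned categories.
binned_auc_expected <- function(dprime, criteria) {
  p_new <- diff(c(0, stats::pnorm(criteria), 1))
  p_old <- diff(c(0, stats::pnorm(criteria, mean = dprime), 1))
  F_new <- c(0, cumsum(p_new))
  sum(p_old * (F_new[seq_along(p_old)] + p_new / 2))
}

# Invert the expected binned AUC for a target, with criteria centered on
# dprime/2 at unit spacing.
calibrate_dprime <- function(target_auc, spacing = 1) {
  stopifnot_msg(target_auc >= 0.5 && target_auc < 0.995,
                "target AUC must lie in [0.5, 0.995)")
  if (target_auc == 0.5) return(0)
  f <- function(d) binned_auc_expected(d, d / 2 + spacing * c(-1.5, -0.5, 0.5, 1.5)) -
    target_auc
  stats::uniroot(f, c(0, 8), tol = 1e-10)$root
}

#' Generate a recognition rating table for one subject
#'
#' Equal-variance Gaussian signal-detection model: new-item evidence
#' N(0, 1), old-item evidence N(d', 1), binned into 5 confidence ratings by
#' four equally spaced criteria centered on d'/2. The separation d' is
#' calibrated numerically so the *expected* trapezoidal AUC of the binned
#' table equals `auc_target`.
#'
#' @param auc_target Target AUC in \[0.5, 0.995); typically
#'   `cohort$auc_target`.
#' @param n_old_items,n_new_items Item counts (default 88 previously novel
#'   old items and 44 new items; the two pre-familiarized master images are
#'   excluded from memory scoring).
#' @param seed RNG seed.
#' @return A [rating_table] with `n_old_items + n_new_items` rows.
#' @export
generate_ratings <- function(auc_target, n_old_items = 88L, n_new_items = 44L,
                             seed = 1L) {
  stopifnot_msg(n_old_items > 0 && n_new_items > 0, "item counts must be > 0")
  d <- calibrate_dprime(auc_target)
  crit <- d / 2 + c(-1.5, -0.5, 0.5, 1.5)
  with_seed(seed, {
    ev <- c(stats::rnorm(n_old_items, d, 1), stats::rnorm(n_new_items, 0, 1))
    rating_table(
      item_id = sprintf("item-%03d", seq_len(n_old_items + n_new_items)),
      status = rep(c("old", "new"), c(n_old_items, n_new_items)),
      rating = 1L + findInterval(ev, crit))
  })
}

# band-limited unit-variance Gaussian-process series, time x voxel:
# random phases, flat in-band power, synthesized in the frequency domain
# (exactly band-limited).
bandlimited_series <- function(n, tr, n_voxel, low = 0.01, high = 0.08) {
  freq <- (seq_len(n) - 1) / (n * tr)
  half <- seq(2L, floor(n / 2) + 1L)
  inband <- half[freq[half] >= low - 1e-12 & freq[half] <= high + 1e-12]
  stopifnot_msg(length(inband) > 0, "no FFT bins inside the requested band")
  co <- matrix(0 + 0i, n, n_voxel)
  z <- matrix(stats::rnorm(length(inband) * n_voxel) +
                1i * stats::rnorm(length(inband) * n_voxel),
              length(inband), n_voxel)
  co[inband, ] <- z
  mirror <- n - inband + 2L
  ok <- mirror >= 1 & mirror <= n & mirror != inband
  co[mirror[ok], ] <- Conj(z[ok, , drop = FALSE])
  x <- Re(stats::mvfft(co, inverse = TRUE)) / n
  # standardize columns to exact unit SD
  s <- sqrt(colSums(sweep(x, 2L, colMeans(x))^2) / (n - 1))
  sweep(x, 2L, ifelse(s > 0, s, 1), `/`)
}

#' Generate a resting-state BOLD series for one subject
#'
#' Each voxel's series is baseline plus a band-limited (default
#' 0.01-0.08 Hz) Gaussian-process fluctuation plus white noise. The
#' fluctuation SD is scaled so that the voxel's expected PerAF equals the
#' subject's true DMN amplitude inside `dmn_mask` and the background
#' amplitude elsewhere (PerAF of a Gaussian fluctuation with SD s about mean
#' mu is s*sqrt(2/pi)/mu*100).
#'
#' @param subject One row of a generated cohort (needs
#'   `true_rest_amplitude_dmn`).
#' @param geometry A [bold_geometry].
#' @param dmn_mask Logical 3D array marking the DMN compartment.
#' @param seed RNG seed (use the manifest's per-subject seed).
#' @param background_amp Background PerAF amplitude, percent.
#' @param baseline Mean BOLD intensity, scanner units.
#' @param white_sd White-noise SD, scanner units.
#' @param band Fluctuation band in Hz.
#' @return A [bold_series] with an all-TRUE brain mask.
#' @export
generate_rest_bold <- function(subject, geometry, dmn_mask, seed,
                               background_amp = 2.0, baseline = 1000,
                               white_sd = 1.0, band = c(0.01, 0.08)) {
  stopifnot_msg(inherits(geometry, "bold_geometry"), "need a bold_geometry")
  stopifnot_msg(any(dmn_mask), "dmn_mask is empty")
  stopifnot_msg(identical(dim(dmn_mask), geometry$dim),
                "dmn_mask shape must match the geometry")
  V <- prod(geometry$dim)
  n <- geometry$n_vol
  amp <- ifelse(as.vector(dmn_mask), subject$true_rest_amplitude_dmn,
                background_amp)
  sd_target <- amp / 100 * baseline * sqrt(pi / 2)
  with_seed(seed, {
    x <- bandlimited_series(n, geometry$tr, V, band[1], band[2])
    x <- sweep(x, 2L, sd_target, `*`)
    if (white_sd > 0)
      x <- x + matrix(stats::rnorm(n * V, 0, white_sd), n, V)
  })
  data <- array(aperm(array(x, c(n, geometry$dim)), c(2, 3, 4, 1)) + baseline,
                dim = c(geometry$dim, n))
  bold_series(data, tr = geometry$tr, affine = geometry$affine,
              mask = array(TRUE, geometry$dim))
}

#' Generate an event table for one encoding run
#'
#' Trial order is randomized; each trial is a fixation jitter followed by a
#' 2.5 s scene presentation. Jitters are drawn from 0.70 s plus an
#' exponential (mean `jitter_mean - 0.70`) truncated at 2.65 s -- a
#' short-biased distribution so the default 132 trials fit a 206-scan run.
#'
#' @param n_novel,n_master Trial counts (default 88 + 44).
#' @param duration Stimulus duration, seconds.
#' @param jitter Jitter bounds, seconds.
#' @param jitter_mean Mean jitter, seconds.
#' @return Event-spec list used by [generate_task_run()].
#' @export
event_spec <- function(n_novel = 88L, n_master = 44L, duration = 2.5,
                       jitter = c(0.70, 2.65), jitter_mean = 1.26) {
  list(n_novel = as.integer(n_novel), n_master = as.integer(n_master),
       duration = duration, jitter = jitter, jitter_mean = jitter_mean)
}

#' Generate a task (encoding) BOLD run with ground-truth effects
#'
#' BOLD = constant baseline + true design (novelty and master boxcars
#' convolved with the canonical HRF) + the parametric subsequent-memory
#' regressor scaled by the subject's true DMN SME beta inside `dmn_mask`,
#' plus white noise. Ratings for the novel items are drawn from the
#' subject's calibrated signal-detection model unless supplied.
#'
#' @inheritParams generate_rest_bold
#' @param events An [event_spec()].
#' @param n_scans Number of volumes (default 206).
#' @param ratings Optional integer ratings (1-5) for the novel events.
#' @param novelty_beta,master_beta True responses (signal units) shared by
#'   all brain voxels.
#' @param noise_sd White-noise SD, scanner units.
#' @return A list with `bold` (a [bold_series]) and `events` (data frame:
#'   onset, duration, trial_type, rating).
#' @export
generate_task_run <- function(subject, geometry, dmn_mask, seed,
                              events = event_spec(), n_scans = 206L,
                              ratings = NULL, baseline = 1000,
                              novelty_beta = 1, master_beta = 0.5,
                              noise_sd = 2.0) {
  stopifnot_msg(inherits(geometry, "bold_geometry"), "need a bold_geometry")
  stopifnot_msg(identical(dim(dmn_mask), geometry$dim),
                "dmn_mask shape must match the geometry")
  tr <- geometry$tr
  n_trial <- events$n_novel + events$n_master
  with_seed(seed, {
    jit <- pmin(events$jitter[2],
                events$jitter[1] +
                  stats::rexp(n_trial, 1 / (events$jitter_mean - events$jitter[1])))
    type <- sample(rep(c("novel", "master"),
                       c(events$n_novel, events$n_master)))
    onset <- cumsum(jit + events$duration) - events$duration
    if (is.null(ratings)) {
      d <- calibrate_dprime(min(subject$auc_target, 0.99))
      crit <- d / 2 + c(-1.5, -0.5, 0.5, 1.5)
      ratings <- 1L + findInterval(stats::rnorm(events$n_novel, d, 1), crit)
    }
    noise_draw <- stats::rnorm(prod(geometry$dim) * n_scans, 0, noise_sd)
  })
  if (max(onset) + events$duration > n_scans * tr)
    stop(sprintf("run too short: %d trials need %.1f s but the run is %.1f s",
                 n_trial, max(onset) + events$duration, n_scans * tr),
         call. = FALSE)
  ev <- data.frame(onset = onset, duration = events$duration,
                   trial_type = type,
                   rating = NA_integer_, stringsAsFactors = FALSE)
  ev$rating[ev$trial_type == "novel"] <- ratings

  des <- build_design(ev, n_scans = n_scans, tr = tr)
  V <- prod(geometry$dim)
  B <- matrix(0, ncol(des$values), V)
  rownames(B) <- des$names
  B["novelty", ] <- novelty_beta
  B["master", ] <- master_beta
  B["novelty_x_pm", as.vector(dmn_mask)] <- subject$true_sme_beta_dmn
  B["constant", ] <- baseline
  Y <- des$values %*% B
  if (noise_sd > 0) Y <- Y + matrix(noise_draw, n_scans, V)
  data <- array(aperm(array(Y, c(n_scans, geometry$dim)), c(2, 3, 4, 1)),
                dim = c(geometry$dim, n_scans))
  bold <- bold_series(data, tr = tr, affine = geometry$affine,
                      mask = array(TRUE, geometry$dim))
  list(bold = bold, events = ev, design = des)
}

#' Geometric stand-in ROI set (DMN midline regions)
#'
#' Non-overlapping box ROIs on the synthetic grid standing in for
#' functionally defined DMN regions: mPFC/ACC (anterior midline), PCC
#' (posterior midline), and precuneus (posterior-superior midline). The
#' composite DMN is their union.
#'
#' @param geometry A [bold_geometry].
#' @return A list of class `roi_set`: `labels` (3D integer array, 0 =
#'   background), `names` (label lookup), `dmn_mask` (composite union),
#'   `affine`.
#' @export
synthetic_roi_set <- function(geometry) {
  d <- geometry$dim
  lab <- array(0L, d)
  mid <- round(d[1] / 2) + (-1:1)
  mid <- mid[mid >= 1 & mid <= d[1]]
  thirds <- function(k, lo, hi) pmax(1, round(lo * k)):pmin(k, round(hi * k))
  lab[mid, thirds(d[2], 0.70, 0.90), thirds(d[3], 0.35, 0.55)] <- 1L  # mPFC/ACC
  lab[mid, thirds(d[2], 0.15, 0.32), thirds(d[3], 0.35, 0.52)] <- 2L  # PCC
  lab[mid, thirds(d[2], 0.15, 0.32), thirds(d[3], 0.60, 0.80)] <- 3L  # precuneus
  structure(list(labels = lab,
                 names = c(mpfc_acc = 1L, pcc = 2L, precuneus = 3L),
                 dmn_mask = lab > 0L, affine = geometry$affine),
            class = "roi_set")
}

#' Generate per-subject grey-matter volume covariate maps
#'
#' Smooth positive 3D maps with a configurable between-group mean difference
#' in a given region, for use as a voxel-wise imaging covariate.
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param geometry A [bold_geometry].
#' @param seed RNG seed.
#' @param group_diff Additive GMV difference (old minus young) inside
#'   `effect_mask`; default 0 (no group difference).
#' @param effect_mask Logical 3D array; default the composite DMN of
#'   [synthetic_roi_set()].
#' @param base Mean GMV level (arbitrary tissue-fraction-like units).
#' @param noise_sd Subject-level spatial noise SD before smoothing.
#' @return A subjects x voxels matrix of GMV values (rownames =
#'   subject_id), with the smoothing performed by local 3D box averaging.
#' @export
generate_covariate_maps <- function(cohort, geometry, seed = 1L,
                                    group_diff = 0, effect_mask = NULL,
                                    base = 0.5, noise_sd = 0.1) {
  if (is.null(effect_mask)) effect_mask <- synthetic_roi_set(geometry)$dmn_mask
  d <- geometry$dim
  V <- prod(d)
  n <- nrow(cohort)
  smooth3d <- function(x) {
    a <- array(x, d)
    # separable 3-point box smoother per axis
    for (ax in 1:3) {
      a2 <- a
      idx_lo <- c(1, seq_len(d[ax] - 1))
      idx_hi <- c(seq_len(d[ax] - 1) + 1, d[ax])
      if (ax == 1) a2 <- (a[idx_lo, , , drop = FALSE] + a +
                            a[idx_hi, , , drop = FALSE]) / 3
      if (ax == 2) a2 <- (a[, idx_lo, , drop = FALSE] + a +
                            a[, idx_hi, , drop = FALSE]) / 3
      if (ax == 3) a2 <- (a[, , idx_lo, drop = FALSE] + a +
                            a[, , idx_hi, drop = FALSE]) / 3
      a <- a2
    }
    as.vector(a)
  }
  with_seed(seed, {
    out <- matrix(0, n, V, dimnames = list(cohort$subject_id, NULL))
    for (i in seq_len(n)) {
      g <- base + smooth3d(stats::rnorm(V, 0, noise_sd))
      if (cohort$age_group[i] == "old")
        g <- g + group_diff * as.vector(effect_mask)
      out[i, ] <- pmax(g, 0.01)
    }
    out
  })
}
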