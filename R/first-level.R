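# Single-subject task GLM: canonical HRF, design construction on a microtime
# grid, and per-voxel least squares yielding the subsequent memory effect
# (SME) map -- the contrast estimate of the arcsine parametric modulator.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with response peak at 6 s, undershoot
#' peak at 16 s, unit dispersions, undershoot ratio 1/6, 32 s support;
#' peak-normalized to maximum 1.
#'
#' @param dt Sampling interval in seconds.
#' @param peak,upeak Response and undershoot peak times (gamma modes), s.
#' @param disp,udisp Dispersions (gamma scale parameters), s.
#' @param ratio Undershoot amplitude ratio.
#' @param length_s Kernel support in seconds.
#' @return Numeric kernel sampled at `0, dt, 2 dt, ...`.
#' @export
canonical_hrf <- function(dt, peak = 6, upeak = 16, disp = 1, udisp = 1,
                          ratio = 1 / 6, length_s = 32) {
  stopifnot_msg(dt > 0, "dt must be > 0")
  t <- seq(0, length_s, by = dt)
  # gamma density with mode = peak: shape = peak/scale + 1
  h <- stats::dgamma(t, shape = peak / disp + 1, scale = disp) -
    ratio * stats::dgamma(t, shape = upeak / udisp + 1, scale = udisp)
  h / max(h)
}

#' Build a first-level design matrix
#'
#' Boxcar stimulus functions are laid out on a microtime grid (`microtime`
#' bins per TR), convolved with [canonical_hrf()], and sampled at the
#' reference bin of each scan. Columns: novelty, novelty x PM (the boxcar
#' weighted by the mean-centered parametric modulator before convolution),
#' master, six motion parameters, constant.
#'
#' @param events Data frame with `onset`, `duration` (seconds) and
#'   `trial_type` (`"novel"` or `"master"`); novel events also need `rating`
#'   (1-5) unless `pm` is supplied.
#' @param n_scans Number of volumes.
#' @param tr Repetition time, seconds.
#' @param motion Numeric n_scans x 6 matrix of rigid-body parameters, or
#'   `NULL` to omit.
#' @param pm Optional parametric-modulator values for the novel events (in
#'   event order); default `parametric_modulator(rating)`.
#' @param microtime Microtime bins per TR (default 16).
#' @param ref_bin Reference bin sampled per scan (default 8).
#' @return A list of class `design_matrix`: `values` (n_scans x p), `names`,
#'   `tr`, plus the convolution settings.
#' @export
build_design <- function(events, n_scans, tr, motion = NULL, pm = NULL,
                         microtime = 16L, ref_bin = 8L) {
  stopifnot_msg(all(events$duration > 0), "durations must be > 0")
  stopifnot_msg(!is.unsorted(events$onset), "onsets must be non-decreasing")
  run_end <- n_scans * tr
  if (nrow(events) > 0 && any(events$onset + events$duration > run_end))
    stop(sprintf("events extend beyond the run end (%g s)", run_end),
         call. = FALSE)
  dt <- tr / microtime
  n_bins <- n_scans * microtime
  hrf <- canonical_hrf(dt)

  conv_boxcar <- function(onsets, durations, heights) {
    u <- numeric(n_bins)
    for (i in seq_along(onsets)) {
      a <- floor(onsets[i] / dt) + 1
      b <- min(n_bins, ceiling((onsets[i] + durations[i]) / dt))
      u[a:b] <- u[a:b] + heights[i]
    }
    x <- stats::convolve(u, rev(hrf), type = "open")[seq_len(n_bins)]
    x[(seq_len(n_scans) - 1L) * microtime + ref_bin]
  }

  nov <- events$trial_type == "novel"
  mas <- events$trial_type == "master"
  col_nov <- if (any(nov))
    conv_boxcar(events$onset[nov], events$duration[nov], rep(1, sum(nov)))
  else NULL
  if (any(nov)) {
    if (is.null(pm)) pm <- parametric_modulator(events$rating[nov])
    stopifnot_msg(length(pm) == sum(nov),
                  "pm length must match the number of novel events")
    pmc <- pm - mean(pm)
    col_pm <- conv_boxcar(events$onset[nov], events$duration[nov], pmc)
  } else col_pm <- NULL
  col_mas <- if (any(mas))
    conv_boxcar(events$onset[mas], events$duration[mas], rep(1, sum(mas)))
  else NULL

  X <- cbind(col_nov, col_pm, col_mas)
  nms <- c("novelty", "novelty_x_pm", "master")[c(any(nov), any(nov), any(mas))]
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot_msg(nrow(motion) == n_scans, "motion must have n_scans rows")
    X <- cbind(X, motion)
    nms <- c(nms, paste0("motion", seq_len(ncol(motion))))
  }
  X <- cbind(X, 1)
  nms <- c(nms, "constant")
  colnames(X) <- nms
  structure(list(values = X, names = nms, tr = tr, microtime = microtime,
                 ref_bin = ref_bin),
            class = "design_matrix")
}

# DCT high-pass basis (SPM-style): k = 1 .. floor(2 n tr / cutoff) cosines.
dct_highpass_basis <- function(n, tr, cutoff_s = 128) {
  K <- floor(2 * n * tr / cutoff_s)
  if (K < 1) return(NULL)
  t <- seq_len(n) - 0.5
  sapply(seq_len(K), function(k) cos(pi * k * t / n))
}

#' Fit a first-level GLM and extract the SME map
#'
#' Ordinary least squares per voxel after appending a discrete-cosine
#' high-pass basis (128 s cutoff by default) to the design. The SME map is
#' the estimate of the `novelty_x_pm` regressor: positive where stronger
#' responses predict later remembering, negative where they predict
#' forgetting.
#'
#' @param bold A [bold_series].
#' @param design A `design_matrix` from [build_design()].
#' @param hpf_cutoff_s High-pass cutoff in seconds; `Inf` disables.
#' @return A list of class `first_level_fit`: `betas` (named list of 3D
#'   maps for the task regressors), `sme` (3D SME map), `sme_se` (its
#'   standard error map), `df`, `design`.
#' @export
fit_first_level <- function(bold, design, hpf_cutoff_s = 128) {
  stopifnot_msg(inherits(bold, "bold_series"), "bold must be a bold_series")
  d <- dim(bold$data)
  n <- d[4]
  stopifnot_msg(nrow(design$values) == n,
                "design rows must match the number of scans")
  X <- design$values
  H <- if (is.finite(hpf_cutoff_s)) dct_highpass_basis(n, design$tr, hpf_cutoff_s)
  if (!is.null(H)) {
    colnames(H) <- paste0("dct", seq_len(ncol(H)))
    X <- cbind(X, H)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("design is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  Y <- matrix(aperm(bold$data, c(4, 1, 2, 3)), nrow = n)
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- solve(crossprod(X))
  task_cols <- design$names
  betas <- lapply(task_cols, function(nm) array(B[match(nm, colnames(X)), ], d[1:3]))
  names(betas) <- task_cols
  sme <- if ("novelty_x_pm" %in% task_cols) betas[["novelty_x_pm"]] else NULL
  sme_se <- if (!is.null(sme)) {
    j <- match("novelty_x_pm", colnames(X))
    array(sqrt(sigma2 * XtXinv[j, j]), d[1:3])
  }
  structure(list(betas = betas, sme = sme, sme_se = sme_se, df = df,
                 design = design, mask = bold$mask, affine = bold$affine),
            class = "first_level_fit")
}
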