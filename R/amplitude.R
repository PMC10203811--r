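# PerAF / mPerAF: percent amplitude of fluctuation of band-limited
# resting-state BOLD, and its global-mean-normalized variant.

#' Detrend and band-pass filter a BOLD series
#'
#' Removes the per-voxel linear trend, suppresses frequency content outside
#' `[low, high]` with an ideal (rectangular) FFT-domain filter (in-band edge
#' bins inclusive), and re-adds the original series mean so that the mean
#' BOLD intensity -- the denominator of PerAF -- remains defined.
#'
#' @param bold A [bold_series].
#' @param low,high Pass-band edges in Hz; `0 <= low < high <= ` Nyquist
#'   (`1/(2 tr)`). Defaults 0.01-0.08 Hz, the conventional low-frequency
#'   fluctuation band.
#' @return A [bold_series] with filtered data.
#' @export
detrend_bandpass <- function(bold, low = 0.01, high = 0.08) {
  stopifnot_msg(inherits(bold, "bold_series"), "bold must be a bold_series")
  nyq <- 1 / (2 * bold$tr)
  stopifnot_msg(low >= 0 && low < high, "need 0 <= low < high")
  if (high > nyq + 1e-12)
    stop(sprintf("high edge %g Hz exceeds the Nyquist frequency %g Hz (tr = %g s)",
                 high, nyq, bold$tr), call. = FALSE)
  d <- dim(bold$data)
  n <- d[4]
  Y <- matrix(aperm(bold$data, c(4, 1, 2, 3)), nrow = n)  # time x voxel
  mu <- colMeans(Y)

  # linear detrend, mean preserved
  tt <- seq_len(n) - (n + 1) / 2
  slope <- crossprod(tt, Y) / sum(tt^2)
  Y <- Y - outer(tt, drop(slope))

  # ideal band-pass on the mean-removed series
  Yc <- sweep(Y, 2L, colMeans(Y))
  f <- stats::mvfft(Yc)
  freq <- (seq_len(n) - 1) / (n * bold$tr)
  freq <- pmin(freq, 1 / bold$tr - freq)      # fold to [0, Nyquist]
  keep <- freq >= low - 1e-12 & freq <= high + 1e-12
  f[!keep, ] <- 0
  Yf <- Re(stats::mvfft(f, inverse = TRUE)) / n
  Yf <- sweep(Yf, 2L, mu, `+`)

  out <- bold
  out$data <- aperm(array(Yf, dim = c(n, d[1:3])), c(2, 3, 4, 1))
  out
}

#' Compute the percent amplitude of fluctuation (PerAF)
#'
#' For each masked voxel with time series \eqn{y_1..y_n} and mean \eqn{\mu},
#' \deqn{PerAF = \frac{1}{n}\sum_{i=1}^n \frac{|y_i - \mu|}{\mu} \cdot 100.}
#' PerAF is scale-independent (invariant to multiplying the series by any
#' positive constant) and sign-free. Voxels with non-positive mean or zero
#' variance are set to 0 and recorded in the returned QC table instead of
#' propagating NaN.
#'
#' Apply [detrend_bandpass()] first to restrict the measure to the
#' low-frequency band; that filter re-centers on the raw series mean, so the
#' \eqn{\mu} used here is the mean raw BOLD intensity.
#'
#' @param bold A [bold_series] (typically already filtered).
#' @param band Provenance band edges recorded in the output map.
#' @return An [amplitude_map] of kind `"peraf"`; component `qc` lists
#'   flagged voxels.
#' @export
compute_peraf <- function(bold, band = c(NA_real_, NA_real_)) {
  stopifnot_msg(inherits(bold, "bold_series"), "bold must be a bold_series")
  d <- dim(bold$data)
  n <- d[4]
  Y <- matrix(aperm(bold$data, c(4, 1, 2, 3)), nrow = n)
  mu <- colMeans(Y)
  mad_ <- colMeans(abs(sweep(Y, 2L, mu)))
  bad <- (mu <= 0 | mad_ == 0) & as.vector(bold$mask)
  val <- ifelse(mu > 0, mad_ / mu * 100, 0)
  val[mu <= 0] <- 0
  val[!as.vector(bold$mask)] <- 0
  qc_idx <- which(bad & mu <= 0)
  qc <- data.frame(voxel = which(bad),
                   reason = ifelse(mu[which(bad)] <= 0,
                                   "non-positive mean", "zero variance"))
  amplitude_map(array(val, d[1:3]), kind = "peraf", mask = bold$mask,
                affine = bold$affine, band = band, qc = qc)
}

#' Normalize a PerAF map by its global mean (mPerAF)
#'
#' Divides each voxel's PerAF by the mean PerAF over the normalization mask,
#' yielding a unitless map whose mean over that mask is exactly 1.
#'
#' @param peraf An [amplitude_map] of kind `"peraf"`.
#' @param mask Normalization mask; default is the map's brain mask
#'   intersected with voxels of nonzero PerAF (i.e. nonzero variance), the
#'   "inclusive mask of active voxels".
#' @return An [amplitude_map] of kind `"mperaf"`.
#' @export
normalize_global_mean <- function(peraf, mask = NULL) {
  stopifnot_msg(inherits(peraf, "amplitude_map") && peraf$kind == "peraf",
                "peraf must be an amplitude_map of kind 'peraf'")
  if (is.null(mask)) mask <- peraf$mask & is.finite(peraf$data) & peraf$data > 0
  stopifnot_msg(any(mask), "normalization mask is empty")
  g <- mean(peraf$data[mask])
  if (!is.finite(g) || g <= 0)
    stop("global mean PerAF over the normalization mask is not positive",
         call. = FALSE)
  amplitude_map(peraf$data / g, kind = "mperaf", mask = peraf$mask,
                affine = peraf$affine, band = peraf$band, norm_mask = mask,
                qc = peraf$qc)
}

#' One-call PerAF/mPerAF pipeline
#'
#' Detrend, band-pass, compute PerAF, and normalize to mPerAF.
#'
#' @inheritParams detrend_bandpass
#' @return A list with `peraf` and `mperaf` [amplitude_map]s.
#' @export
peraf_pipeline <- function(bold, low = 0.01, high = 0.08) {
  filt <- detrend_bandpass(bold, low, high)
  p <- compute_peraf(filt, band = c(low, high))
  list(peraf = p, mperaf = normalize_global_mean(p))
}
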