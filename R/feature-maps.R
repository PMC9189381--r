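# Linear detrend of each row of a voxels x T matrix (removes mean and slope).
detrend_rows <- function(x) {
  Tn <- ncol(x)
  tt <- seq_len(Tn) - (Tn + 1) / 2
  xc <- x - rowMeans(x)
  beta <- drop(xc %*% tt) / sum(tt^2)
  xc - outer(beta, tt)
}

#' Band-pass filter a time series in the frequency domain
#'
#' Linear detrend followed by a hard FFT mask: Fourier bins whose frequency
#' falls outside `[low_hz, high_hz]` (including DC) are zeroed and the series
#' inverse-transformed. The mask is zero-phase, so the retained band is not
#' shifted in time. Output series are zero-mean.
#'
#' @param series Numeric vector (one time course) or 4-D array (X, Y, Z, T).
#' @param low_hz,high_hz Pass band in Hz; requires 0 <= low < high < Nyquist.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @return Filtered data, same shape as the input.
#' @export
bandpass_filter <- function(series, low_hz, high_hz, tr_seconds) {
  nyq <- 1 / (2 * tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz) stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyq)
    stop("high_hz (", high_hz, ") must be below the Nyquist frequency ", nyq)
  vec <- is.null(dim(series))
  if (vec) {
    x <- matrix(series, nrow = 1)
  } else {
    stopifnot(length(dim(series)) == 4)
    d <- dim(series)
    x <- matrix(series, nrow = prod(d[1:3]))
  }
  Tn <- ncol(x)
  x <- detrend_rows(x)
  freqs <- (seq_len(Tn) - 1) / (Tn * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs)  # mirror bins share a frequency
  keep <- freqs >= low_hz & freqs <= high_hz
  keep[1] <- FALSE  # DC always excluded
  xf <- t(stats::mvfft(t(x)))
  xf[, !keep] <- 0
  out <- Re(t(stats::mvfft(t(xf), inverse = TRUE))) / Tn
  if (vec) drop(out) else array(out, dim = dim(series))
}

neighbourhood_offsets <- function(neighborhood) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  switch(as.character(neighborhood),
         "7"  = offs[nz <= 1, , drop = FALSE],
         "19" = offs[nz <= 2, , drop = FALSE],
         "27" = offs,
         stop("neighborhood must be one of 7, 19, 27"))
}

#' Regional homogeneity (Kendall's coefficient of concordance)
#'
#' For every in-mask voxel, ReHo is Kendall's W of the time-course ranks over
#' the voxel and its neighbours (6, 18 or 26 of them): with R_t the sum of the
#' K ranks at time t, W = 12 * sum_t (R_t - K(T+1)/2)^2 / (K^2 (T^3 - T)).
#' Neighbourhoods are clipped to the brain mask, so boundary voxels use only
#' their in-mask neighbours.
#'
#' @param volume 4-D array, already band-pass filtered.
#' @param brain_mask 3-D logical array.
#' @param neighborhood Cube size including the centre: 7, 19 or 27 (default).
#' @param subject_id Optional identifier carried into the result.
#' @return A `feature_map` (list with `values`, `brain_mask`, `kind`,
#'   `subject_id`); values lie in [0, 1] inside the mask, 0 outside.
#' @export
compute_reho <- function(volume, brain_mask, neighborhood = 27,
                         subject_id = NULL) {
  stopifnot(length(dim(volume)) == 4)
  d <- dim(volume)[1:3]
  Tn <- dim(volume)[4]
  if (Tn < 3) stop("need at least 3 time points")
  offs <- neighbourhood_offsets(neighborhood)
  flat <- matrix(volume, nrow = prod(d))
  midx <- which(brain_mask)
  ranks <- matrix(0, nrow = prod(d), ncol = Tn)
  ranks[midx, ] <- t(apply(flat[midx, , drop = FALSE], 1, rank))
  rank4 <- array(ranks, dim = c(d, Tn))
  inmask <- array(as.numeric(brain_mask), dim = d)
  ssum <- array(0, dim = c(d, Tn))
  kcount <- array(0, dim = d)
  for (o in seq_len(nrow(offs))) {
    dx <- offs[o, 1]; dy <- offs[o, 2]; dz <- offs[o, 3]
    tx <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ty <- max(1, 1 - dy):min(d[2], d[2] - dy)
    tz <- max(1, 1 - dz):min(d[3], d[3] - dz)
    ssum[tx, ty, tz, ] <- ssum[tx, ty, tz, ] +
      rank4[tx + dx, ty + dy, tz + dz, , drop = FALSE]
    kcount[tx, ty, tz] <- kcount[tx, ty, tz] + inmask[tx + dx, ty + dy, tz + dz]
  }
  k <- kcount[midx]
  s <- matrix(ssum, nrow = prod(d))[midx, , drop = FALSE]
  dev2 <- rowSums((s - k * (Tn + 1) / 2)^2)
  w <- 12 * dev2 / (k^2 * (Tn^3 - Tn))
  values <- array(0, dim = d)
  values[midx] <- pmin(pmax(w, 0), 1)
  structure(list(values = values, brain_mask = brain_mask, kind = "ReHo",
                 subject_id = subject_id), class = "feature_map")
}

#' Amplitude of low-frequency fluctuation
#'
#' The per-voxel mean of the Fourier amplitude spectrum over the analysis band
#' (default 0.01-0.08 Hz), computed on the linearly detrended but otherwise
#' unfiltered time series. Amplitude of bin k is 2 |X_k| / T, so a pure
#' sinusoid of amplitude a contributes a at its own bin.
#'
#' @param volume 4-D array (X, Y, Z, T), T >= 16.
#' @param brain_mask 3-D logical array.
#' @param band Length-2 pass band in Hz, inside (0, Nyquist).
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id Optional identifier carried into the result.
#' @return A `feature_map` with nonnegative values (`kind = "ALFF"`).
#' @export
compute_alff <- function(volume, brain_mask, band = c(0.01, 0.08),
                         tr_seconds, subject_id = NULL) {
  stopifnot(length(dim(volume)) == 4)
  Tn <- dim(volume)[4]
  if (Tn < 16) stop("need at least 16 time points")
  nyq <- 1 / (2 * tr_seconds)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq)
    stop("band must lie inside (0, Nyquist = ", nyq, ")")
  d <- dim(volume)[1:3]
  midx <- which(brain_mask)
  x <- detrend_rows(matrix(volume, nrow = prod(d))[midx, , drop = FALSE])
  xf <- stats::mvfft(t(x))
  nb <- floor(Tn / 2)
  freqs <- seq_len(nb) / (Tn * tr_seconds)
  inband <- which(freqs >= band[1] & freqs <= band[2])
  if (length(inband) == 0) stop("no Fourier bins fall inside the band")
  amp <- 2 * Mod(xf[1 + inband, , drop = FALSE]) / Tn
  values <- array(0, dim = d)
  values[midx] <- colMeans(amp)
  structure(list(values = values, brain_mask = brain_mask, kind = "ALFF",
                 subject_id = subject_id), class = "feature_map")
}

#' Mean time series of each atlas region
#'
#' @param volume 4-D array.
#' @param atlas 3-D integer array with labels 1..90 (0 = background); every
#'   label must be present.
#' @param tr_seconds Repetition time carried along for later spectral steps.
#' @return A `region_timeseries`: list with `matrix` (90 x T), `region_labels`
#'   and `tr_seconds`.
#' @export
extract_region_timeseries <- function(volume, atlas, tr_seconds = NA_real_) {
  stopifnot(length(dim(volume)) == 4)
  d <- dim(volume)[1:3]
  stopifnot(all(dim(atlas) == d))
  labs <- sort(unique(atlas[atlas > 0]))
  missing <- setdiff(1:90, labs)
  if (length(missing) > 0)
    stop("atlas is missing region labels: ", paste(missing, collapse = ", "))
  flat <- matrix(volume, nrow = prod(d))
  mat <- matrix(0, nrow = 90, ncol = dim(volume)[4])
  av <- as.integer(atlas)
  for (g in 1:90) {
    vi <- which(av == g)
    mat[g, ] <- colMeans(flat[vi, , drop = FALSE])
  }
  structure(list(matrix = mat, region_labels = 1:90, tr_seconds = tr_seconds),
            class = "region_timeseries")
}

#' Pearson connectivity matrix of the region time series
#'
#' Signed Pearson correlation between every pair of the 90 regional mean time
#' series. The absolute value required by the network graph is taken later,
#' when the graph is built; the signed matrix is what edge-level feature
#' selection consumes.
#'
#' @param rts A `region_timeseries`.
#' @param subject_id Optional identifier carried into the result.
#' @return A `connectivity_matrix`: list with `r` (90 x 90, symmetric, unit
#'   diagonal) and `subject_id`.
#' @export
compute_connectivity <- function(rts, subject_id = NULL) {
  stopifnot(inherits(rts, "region_timeseries"))
  m <- rts$matrix
  if (ncol(m) < 3) stop("need at least 3 time points")
  v <- apply(m, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance region(s): ", paste(which(v == 0), collapse = ", "))
  r <- stats::cor(t(m))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(r = r, subject_id = subject_id), class = "connectivity_matrix")
}
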