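#' Nuisance regressor set
#'
#' A named design matrix sampled at volume times. Columns that are constant
#' (other than an explicit intercept) are flagged degenerate rather than
#' rejected, so callers can decide whether to drop them.
#'
#' @param matrix Numeric matrix, volumes x regressors.
#' @param names Column labels.
#' @param volume_times Volume onsets in seconds.
#' @return An object of class `regressor_set`.
#' @export
regressor_set <- function(matrix, names = colnames(matrix), volume_times) {
  matrix <- as.matrix(matrix)
  if (is.null(names)) names <- paste0("reg", seq_len(ncol(matrix)))
  if (length(volume_times) != nrow(matrix)) {
    stop("volume_times must match the number of rows")
  }
  colnames(matrix) <- names
  degen <- apply(matrix, 2, function(x) stats::sd(x) == 0) &
    names != "intercept"
  structure(
    list(matrix = matrix, names = names, volume_times = volume_times,
         degenerate = names[degen]),
    class = "regressor_set"
  )
}

#' Combine regressor sets column-wise
#' @param ... `regressor_set` objects on the same volume grid.
#' @return A merged `regressor_set`.
#' @export
cbind_regressors <- function(...) {
  sets <- list(...)
  vt <- sets[[1]]$volume_times
  for (s in sets) {
    if (!isTRUE(all.equal(s$volume_times, vt))) {
      stop("regressor sets are on different volume grids")
    }
  }
  regressor_set(do.call(cbind, lapply(sets, `[[`, "matrix")),
                unlist(lapply(sets, `[[`, "names")), vt)
}

#' Respiratory phase at volume times
#'
#' Assigns each volume a phase in (-pi, pi] encoding its position within the
#' respiratory cycle: 0 at an inspiratory maximum, advancing linearly to the
#' next maximum. This is the simple linear-phase variant of retrospective
#' respiratory correction; it depends only on peak times, so it is invariant
#' to amplitude scaling of the trace. Volumes outside the span covered by
#' detected maxima are assigned the nearest cycle's phase with a warning.
#'
#' @param extrema A [detect_resp_extrema()] result.
#' @param volume_times Volume onsets in seconds.
#' @return Numeric vector of phases in (-pi, pi].
#' @export
respiratory_phase <- function(extrema, volume_times) {
  pk <- extrema$peak_times
  if (length(pk) < 2L) stop("need at least 2 respiratory maxima")
  outside <- volume_times < pk[1] | volume_times > pk[length(pk)]
  if (any(outside)) {
    warning(sum(outside), " volumes outside the covered respiratory span; ",
            "assigned nearest-cycle phase")
  }
  # cycle index: interval [pk[i], pk[i+1]) ; clamp to the covered span
  idx <- findInterval(volume_times, pk, rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), length(pk) - 1L)
  frac <- (volume_times - pk[idx]) / (pk[idx + 1L] - pk[idx])
  frac <- pmin(pmax(frac, 0), 1)
  phi <- 2 * pi * frac
  ((phi + pi) %% (2 * pi)) - pi
}

#' Fourier expansion of respiratory phase
#'
#' Builds `sin(k*phi)` and `cos(k*phi)` columns for `k = 1..order`; the
#' default order 2 yields the four low-order respiratory Fourier regressors.
#'
#' @param phase Per-volume phase (radians).
#' @param volume_times Volume onsets in seconds.
#' @param order Harmonic order (default 2).
#' @return A [regressor_set()] with `2 * order` columns.
#' @export
fourier_regressors <- function(phase, volume_times, order = 2L) {
  if (order < 1L) stop("order must be at least 1")
  cols <- lapply(seq_len(order), function(k) {
    cbind(sin(k * phase), cos(k * phase))
  })
  m <- do.call(cbind, cols)
  nm <- as.vector(vapply(seq_len(order), function(k) {
    c(sprintf("resp_sin%d", k), sprintf("resp_cos%d", k))
  }, character(2)))
  regressor_set(m, nm, volume_times)
}

#' Respiration volume per time (RVT)
#'
#' For each breath, RVT is the peak-to-adjacent-trough amplitude difference
#' divided by the breath period (peak-to-peak interval), a slow regressor
#' tracking blood-oxygenation fluctuations driven by breathing depth and
#' rate. Breath-wise values at peak times are linearly interpolated to the
#' volume grid, with constant extrapolation beyond the first/last breath.
#'
#' @param extrema A [detect_resp_extrema()] result.
#' @param volume_times Volume onsets in seconds.
#' @return A list of class `rvt_series` with `values` (amplitude/s at
#'   volume times), `volume_times` and `delays_applied` (0).
#' @export
compute_rvt <- function(extrema, volume_times) {
  pk <- extrema$peak_times
  if (length(pk) < 2L || length(extrema$trough_times) < 1L) {
    stop("cannot compute RVT: insufficient extrema")
  }
  period <- diff(pk)
  # amplitude of breath i: peak i minus the trough between peaks i and i+1
  amp <- extrema$peak_amps[-length(pk)] - extrema$trough_amps
  rvt_breath <- amp / period
  at_peak <- pk[-length(pk)]
  vals <- stats::approx(at_peak, rvt_breath, xout = volume_times,
                        rule = 2)$y
  structure(list(values = vals, volume_times = volume_times,
                 delays_applied = 0),
            class = "rvt_series")
}

#' Delayed RVT regressor bank
#'
#' Evaluates the RVT series at `t - d` for each delay `d`, modelling the
#' lagged hemodynamic response to respiration changes; the default delays
#' 0, 5, 10, 15 and 20 s give five columns. Samples before the recording
#' start are edge-padded with the first defined value.
#'
#' @param rvt An `rvt_series` from [compute_rvt()].
#' @param delays Delays in seconds (default `c(0, 5, 10, 15, 20)`).
#' @return A [regressor_set()] with one column per delay.
#' @export
rvt_regressors <- function(rvt, delays = c(0, 5, 10, 15, 20)) {
  if (any(delays < 0)) stop("delays must be non-negative")
  vt <- rvt$volume_times
  m <- vapply(delays, function(d) {
    stats::approx(vt, rvt$values, xout = vt - d, rule = 2)$y
  }, numeric(length(vt)))
  regressor_set(m, sprintf("rvt_d%g", delays), vt)
}

#' Remove trends and nuisance variance from BOLD
#'
#' Per voxel, ordinary least squares on an intercept, linear and quadratic
#' trends (when `add_trends`) plus the supplied regressors; the residual
#' image is returned. Residuals are exactly orthogonal to every retained
#' design column and have zero mean. Collinear columns are dropped with a
#' warning naming them.
#'
#' @param bold A [bold_image()].
#' @param regressors A [regressor_set()] aligned to the retained volumes,
#'   or NULL for trend removal only.
#' @param add_trends Include intercept + linear + quadratic trends
#'   (default TRUE).
#' @return A [bold_image()] of residuals.
#' @export
regress_nuisance <- function(bold, regressors = NULL, add_trends = TRUE) {
  nt <- dim(bold$data)[4]
  X <- NULL
  if (add_trends) {
    tt <- seq_len(nt)
    X <- cbind(intercept = rep(1, nt),
               trend_lin = scale(tt, scale = FALSE)[, 1],
               trend_quad = scale(tt^2, scale = FALSE)[, 1])
  }
  if (!is.null(regressors)) {
    if (nrow(regressors$matrix) != nt) {
      stop("regressor rows (", nrow(regressors$matrix),
           ") != volumes (", nt, ")")
    }
    keep <- !(regressors$names %in% regressors$degenerate)
    if (any(!keep)) {
      warning("dropping degenerate regressors: ",
              paste(regressors$names[!keep], collapse = ", "))
    }
    X <- cbind(X, regressors$matrix[, keep, drop = FALSE])
  }
  if (is.null(X)) stop("nothing to regress: no trends and no regressors")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning("rank-deficient design; dropping collinear columns: ",
            paste(dropped, collapse = ", "))
  }
  Y <- t(mask_matrix(bold))           # t x nvox
  resid <- qr.resid(qrX, Y)
  out <- bold
  out$data <- unmask_matrix(t(resid), bold)
  attr(out, "design") <- X
  out
}

#' Temporal band-pass filter
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass applied to
#' every masked voxel, retaining the low-frequency fluctuation band
#' (default 0.01-0.1 Hz).
#'
#' @param bold A [bold_image()].
#' @param low,high Band edges in Hz.
#' @return A filtered [bold_image()].
#' @export
bandpass <- function(bold, low = 0.01, high = 0.1) {
  fs <- 1 / bold$tr
  nyq <- fs / 2
  if (high >= nyq) stop("high edge ", high, " Hz >= Nyquist ", nyq, " Hz")
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  Y <- mask_matrix(bold)
  # demean first: the mean (0 Hz) is outside the pass band, and removing it
  # up front avoids large forward-backward edge transients
  filt <- t(apply(Y - rowMeans(Y), 1,
                  function(v) signal::filtfilt(bf, v)))
  out <- bold
  out$data <- unmask_matrix(filt, bold)
  out
}

# 1-D Gaussian kernel, unit sum
gauss_kernel <- function(sigma_vox) {
  h <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-h):h)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# separable 1-D convolution along the first margin of a 3-D array
conv_axis <- function(a, kern, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, dp[1], dp[2] * dp[3])
  h <- (length(kern) - 1L) %/% 2L
  pad <- rbind(matrix(0, h, ncol(m)), m, matrix(0, h, ncol(m)))
  out <- apply(pad, 2, function(v) {
    stats::convolve(v, rev(kern), type = "filter")
  })
  aperm(array(out, dp), order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Per-volume separable 3-D Gaussian convolution with
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis, scaled by the voxel
#' size from the affine. Zero padding at the grid edge; kernels are
#' normalized so total intensity is conserved away from edges.
#'
#' @param bold A [bold_image()].
#' @param fwhm Full width at half maximum in mm (default 6; 0 is identity).
#' @return A smoothed [bold_image()].
#' @export
spatial_smooth <- function(bold, fwhm = 6) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (fwhm == 0) return(bold)
  vs <- sqrt(colSums(bold$affine[1:3, 1:3]^2))
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / vs
  kerns <- lapply(sigma_vox, gauss_kernel)
  d <- dim(bold$data)
  out <- bold
  for (t in seq_len(d[4])) {
    v <- bold$data[, , , t]
    for (ax in 1:3) if (d[ax] > 1L) v <- conv_axis(v, kerns[[ax]], ax)
    out$data[, , , t] <- v
  }
  out
}
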