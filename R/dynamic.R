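#' Sliding-window scheme
#'
#' Rectangular windows of `length` volumes advancing by `step` volumes; the
#' defaults (90-TR windows, 45-TR step) give 50% overlap. With TR 0.484 s a
#' 90-TR window spans about 44 s. Trailing volumes that do not fill a
#' window are dropped.
#'
#' @param n_volumes Number of retained volumes.
#' @param length Window length in volumes (default 90).
#' @param step Step between window starts in volumes (default 45).
#' @param tr Repetition time in seconds (default 0.484).
#' @param start_time Onset of the first volume in seconds.
#' @return A list of class `window_scheme` with `starts`/`ends` (1-based
#'   inclusive volume indices), `length`, `step`, `tr`, `n_windows`.
#' @export
make_windows <- function(n_volumes, length = 90L, step = 45L, tr = 0.484,
                         start_time = 0) {
  if (n_volumes < length) {
    stop("recording too short: ", n_volumes, " volumes < window length ",
         length)
  }
  n_win <- as.integer((n_volumes - length) %/% step + 1)
  length <- as.integer(length); step <- as.integer(step)
  starts <- (seq_len(n_win) - 1L) * step + 1L
  structure(
    list(starts = starts, ends = starts + length - 1L, length = length,
         step = step, tr = tr, start_time = start_time, n_windows = n_win),
    class = "window_scheme"
  )
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("<window_scheme> %d windows of %d volumes (%.1f s), step %d\n",
              x$n_windows, x$length, x$length * x$tr, x$step))
  invisible(x)
}

# [t0, t1) spans in seconds for each window
window_spans <- function(scheme) {
  cbind(scheme$start_time + (scheme$starts - 1L) * scheme$tr,
        scheme$start_time + scheme$ends * scheme$tr)
}

#' Windowed SDNN regressor
#'
#' SDNN of the inter-beat intervals falling in each sliding window. An
#' interval belongs to the window containing its closing (later) beat; beat
#' times and volume times must share one clock. Windows with fewer than
#' `min_beats` intervals are flagged missing (NA), guarding against
#' degenerate SDNN estimates.
#'
#' @param ibi An [ibi_series()].
#' @param scheme A [make_windows()] scheme.
#' @param min_beats Minimum intervals per window (default 10).
#' @return A list of class `windowed_hrv` with `sdnn` (ms, NA when
#'   missing), `n_beats` per window and the scheme.
#' @export
windowed_sdnn <- function(ibi, scheme, min_beats = 10L) {
  spans <- window_spans(scheme)
  closing <- ibi$beat_times[-1L]
  sdnn <- numeric(scheme$n_windows)
  nb <- integer(scheme$n_windows)
  for (w in seq_len(scheme$n_windows)) {
    sel <- closing >= spans[w, 1] & closing < spans[w, 2]
    nb[w] <- sum(sel)
    sdnn[w] <- if (nb[w] >= min_beats) stats::sd(ibi$intervals[sel]) else NA_real_
  }
  if (all(is.na(sdnn))) stop("all windows missing: too few beats per window")
  structure(list(sdnn = sdnn, n_beats = nb, scheme = scheme),
            class = "windowed_hrv")
}

#' Windowed seed connectivity maps
#'
#' One Fisher-z seed map per sliding window, each computed on that window's
#' volumes only. Windows whose seed series has zero variance are returned
#' as NULL (missing) rather than failing the whole subject.
#'
#' @param bold A cleaned [bold_image()].
#' @param seed A [sphere_roi()].
#' @param scheme A [make_windows()] scheme.
#' @return List of [seed_fc_map()] results (NULL for missing windows).
#' @export
windowed_seed_fc <- function(bold, seed, scheme) {
  lapply(seq_len(scheme$n_windows), function(w) {
    vols <- scheme$starts[w]:scheme$ends[w]
    tryCatch(seed_fc_map(bold, seed, volumes = vols),
             error = function(e) NULL)
  })
}

#' Subject-level HRV-connectivity coupling regression
#'
#' Per voxel, the ordinary-least-squares slope of windowed seed z on the
#' standardized (z-scored) windowed SDNN, with intercept. Standardizing the
#' regressor makes slopes comparable across subjects regardless of each
#' subject's HRV scale. Windows missing in either input are dropped
#' pairwise.
#'
#' @param window_maps List of [seed_fc_map()] results (NULL = missing).
#' @param hrv A [windowed_sdnn()] result aligned to the same scheme.
#' @param min_windows Minimum usable windows (default 8).
#' @return A list of class `coupling_map` with `values` (slope per voxel)
#'   and `n_windows` used.
#' @export
coupling_regression <- function(window_maps, hrv, min_windows = 8L) {
  if (length(window_maps) != length(hrv$sdnn)) {
    stop("window counts differ between maps and HRV")
  }
  usable <- !vapply(window_maps, is.null, logical(1)) & !is.na(hrv$sdnn)
  if (sum(usable) < min_windows) {
    stop("only ", sum(usable), " usable windows; need ", min_windows)
  }
  x <- hrv$sdnn[usable]
  if (stats::sd(x) == 0) stop("SDNN regressor is constant")
  x <- (x - mean(x)) / stats::sd(x)
  zs <- vapply(window_maps[usable], function(m) as.vector(m$values),
               numeric(length(window_maps[usable][[1]]$values)))
  xc <- x - mean(x)
  beta <- as.vector(zs %*% xc) / sum(xc^2)
  d <- dim(window_maps[usable][[1]]$values)
  structure(list(values = array(beta, d), n_windows = sum(usable)),
            class = "coupling_map")
}

#' Group test of HRV-connectivity coupling
#'
#' One-sample t-test of subject coupling maps against zero, followed by
#' permutation cluster-extent thresholding.
#'
#' @param maps List of [coupling_regression()] results (>= 3 subjects).
#' @param voxel_p,cluster_alpha,n_perm,seed Passed to [cluster_threshold()].
#' @return A thresholded [group_ttest()] `stat_map`.
#' @export
group_coupling_test <- function(maps, voxel_p = 0.005, cluster_alpha = 0.05,
                                n_perm = 2000L, seed = 1L) {
  stat <- group_ttest(maps, design = "one_sample")
  cluster_threshold(stat, voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                    n_perm = n_perm, seed = seed)
}

#' Write windowed HRV as a TSV table
#'
#' @param hrv A [windowed_sdnn()] result.
#' @param path Output TSV path.
#' @export
write_windowed_hrv <- function(hrv, path) {
  spans <- window_spans(hrv$scheme)
  tab <- data.frame(window_index = seq_along(hrv$sdnn),
                    t_start_s = spans[, 1], sdnn_ms = hrv$sdnn,
                    n_beats = hrv$n_beats)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
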