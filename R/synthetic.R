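#' Simulation configuration
#'
#' All generators are deterministic functions of one configuration,
#' including its mandatory seed. The defaults emulate the physiology of a
#' healthy resting adult (heart rate near 70 bpm, SDNN near 54 ms,
#' breathing near 16 breaths/min) scanned with a fast-TR protocol
#' (TR 0.484 s).
#'
#' @param seed RNG seed (mandatory; no silent nondeterminism).
#' @param duration Recording length in seconds.
#' @param tr Repetition time in seconds (default 0.484).
#' @param fs_physio Physiological sampling rate in Hz (default 100).
#' @param mean_ibi Mean inter-beat interval in ms (default 856, ~70 bpm).
#' @param target_sdnn Target SDNN in ms (default 54.4).
#' @param rsa_amplitude Respiratory sinus arrhythmia amplitude in ms
#'   (default 25).
#' @param resp_rate Breathing rate in breaths/min (default 16).
#' @param noise_sd AR(1) IBI noise standard deviation in ms (default 20).
#' @param coupling Dimensionless HRV-coupling strength kappa (default 0).
#' @param static_coupling Baseline shared-signal amplitude for coupled
#'   nodes (default 0.5).
#' @param effect_size Planted connectome effect size d (default 0).
#' @param n_subjects,n_nodes Cohort and graph sizes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, duration = 300, tr = 0.484, fs_physio = 100,
                       mean_ibi = 856, target_sdnn = 54.4,
                       rsa_amplitude = 25, resp_rate = 16, noise_sd = 20,
                       coupling = 0, static_coupling = 0.5,
                       effect_size = 0, n_subjects = 15L, n_nodes = 60L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(duration > 0, tr > 0, fs_physio > 0, mean_ibi > 0,
            resp_rate > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate an inter-beat-interval series
#'
#' IBI fluctuations are the sum of respiratory sinus arrhythmia (a
#' sinusoid at the breathing frequency), a slow 0.1 Hz oscillation (the
#' Mayer-wave band that paced breathing entrains) and AR(1) noise; the
#' fluctuation is rescaled so the sample SDNN equals `target_sdnn`. Beat
#' times are the cumulative sum of the intervals.
#'
#' @param cfg A [sim_config()]; `duration` must be at least 60 s.
#' @return An [ibi_series()] with attribute `sdnn_envelope`, the local
#'   fluctuation scale used by windowed analyses as ground truth.
#' @export
gen_ibi_series <- function(cfg) {
  if (cfg$duration < 60) stop("duration must be at least 60 s")
  if (cfg$target_sdnn == 0 && (cfg$rsa_amplitude > 0 || cfg$noise_sd > 0)) {
    stop("infeasible targets: target_sdnn 0 with nonzero fluctuations")
  }
  set.seed(cfg$seed)
  n <- ceiling(cfg$duration * 1000 / cfg$mean_ibi) + 2L
  tt <- (seq_len(n) - 1L) * cfg$mean_ibi / 1000   # provisional beat times
  f_resp <- cfg$resp_rate / 60
  fluct <- cfg$rsa_amplitude * sin(2 * pi * f_resp * tt) +
    0.6 * cfg$rsa_amplitude * sin(2 * pi * 0.1 * tt)
  if (cfg$noise_sd > 0) {
    ar <- stats::filter(stats::rnorm(n, sd = cfg$noise_sd), 0.7,
                        method = "recursive")
    fluct <- fluct + as.numeric(ar)
  }
  s <- stats::sd(fluct)
  if (s > 0 && cfg$target_sdnn > 0) {
    fluct <- fluct * cfg$target_sdnn / s
  } else if (cfg$target_sdnn == 0) {
    fluct <- fluct * 0
  }
  intervals <- cfg$mean_ibi + fluct
  intervals <- pmax(intervals, 250)   # physiological floor
  beat_times <- cumsum(c(0, intervals)) / 1000
  keep <- beat_times <= cfg$duration
  if (sum(keep) < 3L) stop("duration too short for mean_ibi")
  out <- ibi_series(beat_times[keep])
  attr(out, "config") <- cfg
  out
}

# integrated-amplitude pulse template: derivative is a narrow Gaussian
# upstroke at lag 0 minus a slow decay that returns the waveform to
# baseline, so the maximum first derivative sits exactly at the beat time
pulse_template <- function(fs, pre = 0.1, post = 0.6, rise_sd = 0.015,
                           decay_tau = 0.18) {
  tt <- seq(-pre, post, by = 1 / fs)
  up <- exp(-tt^2 / (2 * rise_sd^2))
  dec <- ifelse(tt > 0, exp(-tt / decay_tau), 0)
  dec <- dec * sum(up) / sum(dec)     # equal area: waveform returns to 0
  d <- up - dec
  h <- cumsum(d) / fs
  list(h = h, offset = round(pre * fs))   # index of the beat fiducial
}

#' Synthesize a pulse waveform from beat times
#'
#' Superposes a fixed asymmetric pulse template (fast upstroke, slow decay)
#' at each beat time; the template's maximum first derivative falls within
#' one sample of the beat time, matching the fiducial used by
#' [detect_pulse_peaks()]. Optional additive white noise.
#'
#' @param ibi An [ibi_series()].
#' @param fs Sampling rate in Hz (>= 50).
#' @param noise_sd White-noise standard deviation relative to unit pulse
#'   amplitude (default 0).
#' @param seed Seed for the noise draw (default 1).
#' @return A [raw_signal()] on the pulse channel.
#' @export
gen_pulse_waveform <- function(ibi, fs = 100, noise_sd = 0, seed = 1L) {
  if (fs < 50) stop("fs too low to resolve the upstroke (need >= 50 Hz)")
  tmpl <- pulse_template(fs)
  t_end <- max(ibi$beat_times) + 1
  n <- ceiling(t_end * fs) + length(tmpl$h)
  x <- numeric(n)
  for (bt in ibi$beat_times) {
    i0 <- round(bt * fs) + 1L - tmpl$offset
    idx <- seq_along(tmpl$h) + i0 - 1L
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tmpl$h[ok]
  }
  x <- x / max(x)
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  raw_signal(x, fs, start_time = 0, channel = "pulse")
}

#' Synthesize a respiration trace
#'
#' A sinusoid at `resp_rate`/60 Hz with optional slow frequency drift and
#' amplitude jitter, generated through an explicit phase integral so the
#' true extrema times are known exactly and returned as ground truth.
#'
#' @param cfg A [sim_config()]; `resp_rate` must lie in [6, 30].
#' @param freq_drift Fractional peak-to-peak frequency drift (default 0.1).
#' @param amp_jitter Fractional amplitude jitter (default 0.1).
#' @return A [raw_signal()] on the respiration channel with attributes
#'   `true_peak_times` and `true_trough_times`.
#' @export
gen_respiration <- function(cfg, freq_drift = 0.1, amp_jitter = 0.1) {
  if (cfg$resp_rate < 6 || cfg$resp_rate > 30) {
    stop("resp_rate must lie in [6, 30] breaths/min")
  }
  set.seed(cfg$seed + 1L)
  fs <- cfg$fs_physio
  tt <- seq(0, cfg$duration, by = 1 / fs)
  f0 <- cfg$resp_rate / 60
  f_inst <- f0 * (1 + freq_drift * sin(2 * pi * tt / cfg$duration))
  phase <- 2 * pi * cumsum(f_inst) / fs
  amp <- 1 + amp_jitter * sin(2 * pi * 0.01 * tt + stats::runif(1, 0, 2 * pi))
  x <- amp * sin(phase)
  # true extrema where the phase crosses pi/2 (peaks) and 3pi/2 (troughs)
  peaks <- extrema_from_phase(phase, tt, pi / 2)
  troughs <- extrema_from_phase(phase, tt, 3 * pi / 2)
  out <- raw_signal(x, fs, start_time = 0, channel = "respiration")
  attr(out, "true_peak_times") <- peaks
  attr(out, "true_trough_times") <- troughs
  out
}

extrema_from_phase <- function(phase, tt, target) {
  ph <- (phase - target) %/% (2 * pi)
  cross <- which(diff(ph) > 0)
  # linear interpolation of the crossing time
  frac <- ((ph[cross] + 1) * 2 * pi + target - phase[cross]) /
    (phase[cross + 1L] - phase[cross])
  tt[cross] + frac * (tt[cross + 1L] - tt[cross])
}

# band-limited (0.01-0.1 Hz) unit-variance noise via random-phase Fourier
# synthesis; deterministic given the current RNG state
bandlimited_noise <- function(n_t, tr, n_series = 1L,
                              band = c(0.01, 0.1)) {
  freqs <- seq_len(n_t %/% 2) / (n_t * tr)
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(sel)) sel <- which.min(abs(freqs - mean(band)))
  tt <- seq_len(n_t)
  out <- matrix(0, n_series, n_t)
  for (s in seq_len(n_series)) {
    ph <- stats::runif(length(sel), 0, 2 * pi)
    amp <- stats::rnorm(length(sel), 1, 0.2)
    x <- rep(0, n_t)
    for (k in seq_along(sel)) {
      x <- x + amp[k] * sin(2 * pi * freqs[sel[k]] * tt * tr + ph[k])
    }
    out[s, ] <- x / stats::sd(x)
  }
  out
}

#' Generate node BOLD series with HRV-coupled connectivity
#'
#' A latent in-band seed signal `s(t)` drives the seed node and a set of
#' coupled nodes. Coupled nodes follow
#' `x_i(t) = (a + kappa * S(t)) * s(t) + noise`, where `S(t)` is the
#' standardized windowed-SDNN envelope of the supplied beat series
#' interpolated to volume times: when `kappa > 0` the instantaneous
#' connectivity to the seed co-varies with HRV, which is the coupling the
#' sliding-window analysis is built to detect. Uncoupled nodes are pure
#' in-band noise. All noise is band-limited to 0.01-0.1 Hz.
#'
#' @param cfg A [sim_config()] (uses `coupling`, `static_coupling`,
#'   `n_nodes`, `tr`, `seed`).
#' @param ibi An [ibi_series()] on the same clock.
#' @param scheme A [make_windows()] scheme defining the SDNN envelope.
#' @param n_coupled Number of coupled nodes (default 6).
#' @param noise_sd Node noise standard deviation (default 1).
#' @return A list: `node_ts` (node x time, row 1 is the seed),
#'   `coupled` (logical per node), `sdnn_envelope` (per volume),
#'   `scheme`.
#' @export
gen_coupled_bold <- function(cfg, ibi, scheme, n_coupled = 6L,
                             noise_sd = 1) {
  if (cfg$coupling != 0 && n_coupled == 0L) {
    stop("coupling requested with an empty coupled set")
  }
  set.seed(cfg$seed + 2L)
  n_t <- scheme$ends[scheme$n_windows]
  hrv <- windowed_sdnn(ibi, scheme, min_beats = 5L)
  centers <- (scheme$starts + scheme$ends) / 2 * scheme$tr
  sd_w <- hrv$sdnn
  if (any(is.na(sd_w))) sd_w[is.na(sd_w)] <- mean(sd_w, na.rm = TRUE)
  envelope <- stats::approx(centers, sd_w, xout = seq_len(n_t) * scheme$tr,
                            rule = 2)$y
  envelope <- (envelope - mean(envelope)) / stats::sd(envelope)
  s <- bandlimited_noise(n_t, scheme$tr)[1, ]
  n_nodes <- cfg$n_nodes
  coupled <- c(FALSE, seq_len(n_nodes - 1L) <= n_coupled)
  noise <- bandlimited_noise(n_t, scheme$tr, n_nodes) * noise_sd
  node_ts <- noise
  node_ts[1, ] <- s + 0.1 * noise[1, ]          # seed node: mostly latent
  gain <- cfg$static_coupling + cfg$coupling * envelope
  for (i in which(coupled)) {
    node_ts[i, ] <- gain * s + noise[i, ]
  }
  list(node_ts = node_ts, coupled = coupled, sdnn_envelope = envelope,
       scheme = scheme, hrv = hrv)
}

#' Embed node time series in a small 4-D BOLD grid
#'
#' Lays the nodes out on a compact 3-D grid (one node per voxel, coupled
#' nodes first and therefore spatially contiguous) so voxel-based group
#' statistics and cluster thresholding can run on node-level simulations.
#'
#' @param node_ts Node x time matrix (row 1 = seed).
#' @param tr Repetition time in seconds.
#' @param voxel_size Voxel size in mm (default 2.5).
#' @return A list: `bold` (a [bold_image()]), `seed` (a [sphere_roi()]
#'   covering the seed voxel), `node_voxels` (linear voxel index per node).
#' @export
nodes_to_bold <- function(node_ts, tr, voxel_size = 2.5) {
  n_nodes <- nrow(node_ts)
  nx <- ceiling(sqrt(n_nodes))
  ny <- ceiling(n_nodes / nx)
  d <- c(nx, ny, 1L)
  data <- array(0, c(d, ncol(node_ts)))
  flat <- matrix(data, prod(d), ncol(node_ts))
  flat[seq_len(n_nodes), ] <- node_ts
  data <- array(flat, c(d, ncol(node_ts)))
  mask <- array(FALSE, d)
  mask[seq_len(n_nodes)] <- TRUE
  bold <- bold_image(data, tr = tr, mask = mask, voxel_size = voxel_size)
  seed_center <- voxel_coords_mm(d, bold$affine)[1, ]
  seed <- sphere_roi(seed_center, voxel_size / 2, bold)
  list(bold = bold, seed = seed, node_voxels = seq_len(n_nodes))
}

#' Generate paired connectome cohorts with a planted effect
#'
#' Subject-level symmetric Fisher-z matrices are a shared baseline plus a
#' subject random effect plus edge noise; the T2 set adds
#' `effect_size * edge_noise_sd` on the effect edges. With
#' `effect_edges = NULL` and `effect_size > 0` a random spanning tree over
#' `effect_nodes` nodes is planted, mirroring the connected-subnetwork
#' alternative the network-based statistic targets.
#'
#' @param cfg A [sim_config()] (uses `n_subjects`, `n_nodes`,
#'   `effect_size`, `seed`).
#' @param effect_edges Optional 2-column node-pair matrix.
#' @param effect_nodes Number of nodes in the random planted tree
#'   (default 21, giving 20 edges).
#' @param baseline_sd,subject_sd,edge_noise_sd Standard deviations of the
#'   shared baseline, subject random effect and edge noise (Fisher-z
#'   units).
#' @return A list: `t1`, `t2` (lists of [connectivity_matrix()] objects),
#'   `effect_edges`, `parcellation` (synthetic coordinates obeying 10 mm
#'   spacing).
#' @export
gen_paired_connectomes <- function(cfg, effect_edges = NULL,
                                   effect_nodes = 21L, baseline_sd = 0.2,
                                   subject_sd = 0.05, edge_noise_sd = 0.1) {
  set.seed(cfg$seed + 3L)
  n <- cfg$n_nodes
  ns <- cfg$n_subjects
  parc <- synthetic_coordinates(n, min_spacing = 10)
  if (!is.null(effect_edges)) {
    effect_edges <- as.matrix(effect_edges)
    if (any(effect_edges < 1L | effect_edges > n)) {
      stop("effect edge references an unknown node")
    }
  } else if (cfg$effect_size != 0) {
    # plant the tree only across edges that survive the distance mask
    effect_edges <- random_spanning_tree(sample.int(n, effect_nodes),
                                         allowed = parc$distance >= 20)
  }
  idx <- edge_index(n)
  ne <- length(idx)
  baseline <- stats::rnorm(ne, 0.1, baseline_sd)
  eff_vec <- logical(ne)
  if (!is.null(effect_edges)) {
    eff_vec <- apply_edge_ids(effect_edges, n)
  }
  make_mat <- function(evec) {
    z <- matrix(NA_real_, n, n)
    z[idx] <- evec
    z[lower.tri(z)] <- t(z)[lower.tri(z)]
    diag(z) <- NA_real_
    valid <- parc$distance >= 20
    diag(valid) <- FALSE
    structure(list(z = z, valid = valid, labels = parc$labels),
              class = "connectivity_matrix")
  }
  t1 <- vector("list", ns); t2 <- vector("list", ns)
  for (s in seq_len(ns)) {
    subj <- stats::rnorm(1, 0, subject_sd)
    e1 <- baseline + subj + stats::rnorm(ne, 0, edge_noise_sd)
    e2 <- baseline + subj + stats::rnorm(ne, 0, edge_noise_sd)
    # effect_size is the paired Cohen's d: the shift is d times the
    # standard deviation of the within-subject difference T2 - T1
    e2[eff_vec] <- e2[eff_vec] + cfg$effect_size * sqrt(2) * edge_noise_sd
    t1[[s]] <- make_mat(e1)
    t2[[s]] <- make_mat(e2)
  }
  list(t1 = t1, t2 = t2, effect_edges = effect_edges,
       parcellation = parc)
}

# random spanning tree over the given node ids (random parent attachment);
# `allowed` optionally restricts which node pairs may carry a tree edge.
# Nodes with no allowed partner among those already attached are deferred
# and retried once more have joined.
random_spanning_tree <- function(nodes, allowed = NULL) {
  k <- length(nodes)
  if (k < 2L) stop("need at least 2 nodes for a tree")
  pending <- sample(nodes)
  added <- pending[1L]
  pending <- pending[-1L]
  edges <- matrix(integer(0), 0, 2)
  stall <- 0L
  while (length(pending)) {
    v <- pending[1L]
    pending <- pending[-1L]
    cand <- if (is.null(allowed)) added else added[allowed[added, v]]
    if (length(cand)) {
      p <- cand[sample.int(length(cand), 1L)]
      edges <- rbind(edges, c(p, v))
      added <- c(added, v)
      stall <- 0L
    } else {
      pending <- c(pending, v)
      stall <- stall + 1L
      if (stall > length(pending)) {
        stop("cannot build a connected effect under the edge constraints")
      }
    }
  }
  edges
}

#' Synthetic node coordinates obeying a minimum spacing
#'
#' Places nodes on a jittered 3-D lattice so all center distances respect
#' the spacing rule; a stand-in for real parcellation coordinates.
#'
#' @param n Number of nodes.
#' @param min_spacing Minimum center distance in mm (default 10).
#' @param radius Sphere radius in mm (default 5).
#' @return A [parcellation()].
#' @export
synthetic_coordinates <- function(n, min_spacing = 10, radius = 5) {
  pitch <- min_spacing + 4
  k <- ceiling(n^(1 / 3))
  g <- as.matrix(expand.grid(x = seq_len(k + 1), y = seq_len(k + 1),
                             z = seq_len(k + 1)))[seq_len(n), ] * pitch
  jit <- matrix(stats::runif(3 * n, -1.5, 1.5), n, 3)
  centers <- sweep(g + jit, 2, colMeans(g))
  parcellation(centers, radius = radius, min_spacing = min_spacing)
}
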