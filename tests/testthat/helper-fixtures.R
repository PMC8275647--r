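# shared fixture builders; everything is generated in code at test time

# pulse train with identical templates at fixed spacing (s)
pulse_train <- function(spacing = 0.8, duration = 60, fs = 100,
                        drop_beat = NULL) {
  beats <- seq(spacing / 2, duration, by = spacing)
  if (!is.null(drop_beat)) beats <- beats[-drop_beat]
  gen_pulse_waveform(ibi_series(beats), fs = fs)
}

# single-voxel-line bold image holding given series in voxel (1,1,1)
series_bold <- function(..., tr = 0.484) {
  series <- list(...)
  n <- length(series[[1]])
  arr <- array(0, c(length(series), 1, 1, n))
  for (i in seq_along(series)) arr[i, 1, 1, ] <- series[[i]]
  bold_image(arr, tr)
}

# centered isotropic grid spec for sphere_roi
grid_spec <- function(n = 21L, voxel = 2.5) {
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- -voxel * (n - 1) / 2
  list(dim = rep(as.integer(n), 3), affine = aff)
}

# independent flood-fill cluster labeler (recursive BFS), oracle for
# label_clusters
flood_fill_labels <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask)
  strides <- c(1L, d[1], d[1] * d[2])
  for (start in idx) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      pos <- arrayInd(v, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        p <- pos[ax] + s
        if (p >= 1L && p <= d[ax]) {
          nb <- v + s * strides[ax]
          if (mask[nb] && lab[nb] == 0L) {
            lab[nb] <- nxt
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  lab
}

# one simulated dFC subject: coupling maps plus ground truth
simulate_dfc_subject <- function(seed, kappa, duration = 320,
                                 n_nodes = 20L, static_coupling = 0.4) {
  cfg <- sim_config(seed = seed, duration = duration, coupling = kappa,
                    static_coupling = static_coupling, n_nodes = n_nodes)
  ibi <- gen_ibi_series(cfg)
  nvol <- floor(cfg$duration / cfg$tr)
  sch <- make_windows(nvol)
  gb <- gen_coupled_bold(cfg, ibi, sch)
  emb <- nodes_to_bold(gb$node_ts, cfg$tr)
  wm <- windowed_seed_fc(emb$bold, emb$seed, sch)
  hrv <- windowed_sdnn(ibi, sch)
  list(map = coupling_regression(wm, hrv), coupled = gb$coupled,
       node_voxels = emb$node_voxels)
}

edge_mask <- function(pairs, n) neurocardiac:::apply_edge_ids(pairs, n)
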