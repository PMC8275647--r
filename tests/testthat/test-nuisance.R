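test_that("initial volumes are discarded with a shifted clock", {
  b <- bold_image(array(rnorm(2 * 2 * 2 * 50), c(2, 2, 2, 50)), tr = 0.5)
  out <- discard_initial_volumes(b, 20)
  expect_equal(dim(out$data)[4], 30)
  expect_equal(out$start_time, 10)
  expect_equal(out$data[, , , 1], b$data[, , , 21])
  expect_error(discard_initial_volumes(
    bold_image(array(0, c(1, 1, 1, 20)) + rnorm(20), tr = 0.5), 20),
    "too short")
  # the study's retained volume counts
  expect_equal(1900 - 20, 1880)
  b2 <- bold_image(array(rnorm(1250), c(1, 1, 1, 1250)), tr = 0.484)
  expect_equal(dim(discard_initial_volumes(b2)$data)[4], 1230)
})

test_that("respiratory phase advances linearly and is amplitude-invariant", {
  tt <- seq(0, 60, by = 0.01)
  mk <- function(a) raw_signal(a * sin(2 * pi * 0.25 * tt), 100,
                               channel = "respiration")
  ex <- detect_resp_extrema(mk(1))
  vt <- seq(2, 56, by = 0.484)
  ph <- suppressWarnings(respiratory_phase(ex, vt))
  expect_true(all(ph > -pi - 1e-9 & ph <= pi + 1e-9))
  # phase at a peak is 0
  expect_equal(respiratory_phase(ex, ex$peak_times[3]), 0)
  # linear advance: unwrapped phase increments match 2*pi*f*dt
  inc <- diff(ph) %% (2 * pi)
  expect_equal(inc, rep(2 * pi * 0.25 * 0.484, length(inc)),
               tolerance = 0.02)
  ex2 <- detect_resp_extrema(mk(5))
  expect_equal(suppressWarnings(respiratory_phase(ex2, vt)), ph,
               tolerance = 1e-6)
})

test_that("Fourier expansion yields four bounded low-order columns", {
  set.seed(2)
  ph <- runif(200, -pi, pi)
  fr <- fourier_regressors(ph, seq_along(ph))
  expect_equal(ncol(fr$matrix), 4)
  expect_true(all(abs(fr$matrix) <= 1))
  expect_equal(fr$matrix[, 1], sin(ph))
  expect_equal(fr$matrix[, 4], cos(2 * ph))
  degen <- fourier_regressors(rep(0, 100), 1:100)
  expect_setequal(degen$degenerate,
                  c("resp_sin1", "resp_cos1", "resp_sin2", "resp_cos2"))
})

test_that("RVT is amplitude-over-period with expected scaling", {
  mk_ex <- function(amp, period) {
    np <- floor(58 / period)
    structure(list(peak_times = seq(1, by = period, length.out = np),
                   trough_times = seq(1 + period / 2, by = period,
                                      length.out = np - 1),
                   peak_amps = rep(amp, np),
                   trough_amps = rep(-amp, np - 1)),
              class = "resp_extrema")
  }
  vt <- seq(5, 50, by = 0.484)
  base <- compute_rvt(mk_ex(1, 4), vt)
  expect_equal(base$values, rep(0.5, length(vt)))
  expect_equal(compute_rvt(mk_ex(2, 4), vt)$values, base$values * 2)
  expect_equal(compute_rvt(mk_ex(1, 8), vt)$values, base$values / 2,
               tolerance = 1e-9)
  expect_error(compute_rvt(structure(list(peak_times = 1,
                                          trough_times = numeric(0)),
                                     class = "resp_extrema"), vt),
               "insufficient extrema")
})

test_that("delayed RVT columns are shifted copies with edge padding", {
  vt <- seq(0, 200, by = 0.484)
  # slowly varying series so sub-sample interpolation error is negligible
  vals <- sin(2 * pi * 0.01 * vt) + 0.5 * cos(2 * pi * 0.017 * vt)
  rvt <- structure(list(values = vals, volume_times = vt,
                        delays_applied = 0), class = "rvt_series")
  rr <- rvt_regressors(rvt)
  expect_equal(ncol(rr$matrix), 5)
  k <- round(5 / 0.484)
  inner <- (k + 5):length(vt)
  expect_equal(rr$matrix[inner, 2], rr$matrix[inner - k, 1],
               tolerance = 0.05)
  # delay 0 on constant RVT flags the degenerate column
  cr <- rvt_regressors(structure(list(values = rep(2, length(vt)),
                                      volume_times = vt),
                                 class = "rvt_series"), delays = 0)
  expect_equal(cr$degenerate, "rvt_d0")
})

test_that("nuisance regression removes fitted variance exactly", {
  set.seed(1)
  nt <- 300
  motion <- matrix(rnorm(nt * 6), nt, 6,
                   dimnames = list(NULL, paste0("mot", 1:6)))
  planted <- 0.7 * motion[, 1] + rnorm(nt, sd = 0.3)
  ramp <- seq_len(nt) * 0.5 + 3
  ortho <- rnorm(nt)
  b <- series_bold(planted, ramp, ortho)
  rs <- regressor_set(motion, volume_times = volume_times(b))
  res <- regress_nuisance(b, rs)
  # ramp voxel: trends fit it perfectly
  expect_lt(max(abs(res$data[2, 1, 1, ])), 1e-8)
  # planted voxel: variance shrinks, residual orthogonal to motion
  expect_lt(var(res$data[1, 1, 1, ]), var(planted))
  expect_lt(abs(cor(res$data[1, 1, 1, ], motion[, 1])), 1e-10)
  # residuals orthogonal to every design column at machine precision
  X <- attr(res, "design")
  expect_lt(max(abs(t(X) %*% res$data[1, 1, 1, ])), 1e-8)
  expect_lt(abs(mean(res$data[1, 1, 1, ])), 1e-10)
  # residual operator matches the textbook projection for any voxel
  expect_equal(res$data[3, 1, 1, ], qr.resid(qr(X), ortho),
               tolerance = 1e-8)
})

test_that("collinear design columns are dropped with a warning", {
  set.seed(2)
  nt <- 100
  m <- cbind(a = rnorm(nt), b = rnorm(nt))
  m <- cbind(m, c = m[, 1] + m[, 2])
  b <- series_bold(rnorm(nt))
  rs <- regressor_set(m, volume_times = volume_times(b))
  expect_warning(regress_nuisance(b, rs), "collinear")
})

test_that("band-pass keeps in-band power and rejects out-of-band power", {
  tr <- 0.484
  n <- 1200
  tt <- (seq_len(n) - 1) * tr
  bp1 <- function(v) as.vector(bandpass(series_bold(v, tr = tr))$data)
  mid <- 200:1000
  inband <- bp1(sin(2 * pi * 0.05 * tt))
  expect_gt(max(abs(inband[mid])), 0.95)
  outband <- bp1(sin(2 * pi * 0.3 * tt))
  expect_lt(max(abs(outband[mid])), 0.1)
  dc <- bp1(rep(7, n))
  expect_lt(max(abs(dc)), 1e-8)
  expect_error(bandpass(series_bold(rnorm(50), tr = tr), high = 2),
               "Nyquist")
})

test_that("Gaussian smoothing matches the analytic kernel and conserves mass", {
  a <- array(0, c(15, 15, 15, 2))
  a[8, 8, 8, ] <- 1
  b <- bold_image(a, tr = 0.5, voxel_size = 2.5)
  sm <- spatial_smooth(b, fwhm = 6)
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  expect_equal(sm$data[8, 8, 8, 1], (2.5 / (sqrt(2 * pi) * sigma))^3,
               tolerance = 0.01)
  expect_equal(sum(sm$data[, , , 1]), 1, tolerance = 1e-3)
  # identity and constant-image cases
  expect_identical(spatial_smooth(b, 0), b)
  cst <- bold_image(array(3, c(9, 9, 9, 2)), tr = 0.5)
  smc <- spatial_smooth(cst, 6)
  expect_equal(smc$data[5, 5, 5, 1], 3, tolerance = 1e-6)
})

test_that("cleaning chain removes respiratory artifact, keeps coupling", {
  tr <- 0.484
  nvol <- 1000
  cfg <- sim_config(seed = 21, duration = (nvol + 5) * tr)
  resp <- gen_respiration(cfg)
  ex <- detect_resp_extrema(resp)
  vt <- seq(ex$peak_times[1] + 1, by = tr, length.out = nvol)
  ph <- suppressWarnings(respiratory_phase(ex, vt))

  set.seed(22)
  # both the shared signal and the voxel noise live in the retained band,
  # so cleaning should leave their correlation essentially untouched
  shared <- neurocardiac:::bandlimited_noise(nvol, tr)[1, ]
  vn <- neurocardiac:::bandlimited_noise(nvol, tr, 2)
  v1 <- shared + 0.6 * vn[1, ]
  v2 <- shared + 0.6 * vn[2, ]
  artifact <- 2 * sin(ph) + rnorm(nvol, sd = 0.2)
  b <- series_bold(v1, v2, artifact, tr = tr)

  design <- cbind_regressors(fourier_regressors(ph, vt),
                             rvt_regressors(compute_rvt(ex, vt)))
  clean <- bandpass(regress_nuisance(b, design))

  r_before <- cor(v1, v2)
  r_after <- cor(clean$data[1, 1, 1, ], clean$data[2, 1, 1, ])
  expect_lt(abs(r_after - r_before), 0.05)
  expect_lt(abs(cor(clean$data[3, 1, 1, ], sin(ph))), 0.1)
})
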