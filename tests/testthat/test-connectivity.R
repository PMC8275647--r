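test_that("sphere ROIs contain the lattice-enumeration voxel counts", {
  g <- grid_spec(21, 2.5)
  # brute-force oracle: integer lattice points with i^2+j^2+k^2 <= (r/vs)^2
  lattice_count <- function(r_vox) {
    gr <- expand.grid(i = -10:10, j = -10:10, k = -10:10)
    sum(gr$i^2 + gr$j^2 + gr$k^2 <= r_vox^2)
  }
  expect_equal(length(sphere_roi(c(0, 0, 0), 10, g)$voxels),
               lattice_count(4))
  expect_equal(length(sphere_roi(c(0, 0, 0), 10, g)$voxels), 257)
  expect_equal(length(sphere_roi(c(0, 0, 0), 5, g)$voxels),
               lattice_count(2))
  expect_equal(length(sphere_roi(c(0, 0, 0), 5, g)$voxels), 33)
  expect_equal(length(sphere_roi(c(0, 0, 0), 1, g)$voxels), 1)
  expect_error(sphere_roi(c(500, 0, 0), 1, g), "empty sphere")
})

test_that("Fisher z is atanh with clamping at |r| = 1", {
  expect_equal(as.numeric(fisher_z(0)), 0)
  expect_equal(as.numeric(fisher_z(0.5)), 0.5493, tolerance = 1e-4)
  expect_equal(as.numeric(fisher_z(-0.5)), -as.numeric(fisher_z(0.5)))
  z1 <- fisher_z(1)
  expect_equal(as.numeric(z1), atanh(1 - 1e-6))
  expect_true(attr(z1, "clamped"))
  expect_error(fisher_z(1.2), "> 1")
  # round trip on (-8, 8)
  z <- seq(-7.9, 7.9, by = 0.37)
  expect_equal(as.numeric(fisher_z(tanh(z))), z, tolerance = 1e-9)
})

test_that("seed maps recover planted correlations", {
  set.seed(31)
  n <- 500
  s <- as.vector(neurocardiac:::bandlimited_noise(n, 0.484))
  # voxel with planted r = 0.5: x = s + noise with matched variance
  planted <- 0.5 * s + sqrt(1 - 0.25) * rnorm(n, sd = sd(s))
  noisevox <- rnorm(n)
  b <- series_bold(s, planted, noisevox, s)
  seed <- sphere_roi(voxel_coords_mm(dim(b$data)[1:3], b$affine)[1, ],
                     1, b)
  zm <- seed_fc_map(b, seed)
  # self-correlation clamps
  expect_equal(zm$values[1, 1, 1], atanh(1 - 1e-6))
  expect_equal(zm$values[4, 1, 1], atanh(1 - 1e-6))
  expect_equal(zm$values[2, 1, 1], atanh(0.5), tolerance = 0.15)
  expect_lt(abs(zm$values[3, 1, 1]), 0.15)
  # constant seed errors
  cb <- series_bold(rep(1, 100), rnorm(100))
  cseed <- sphere_roi(voxel_coords_mm(dim(cb$data)[1:3], cb$affine)[1, ],
                      1, cb)
  expect_error(seed_fc_map(cb, cseed), "constant")
})

test_that("group t-tests match hand calculations and design identities", {
  maps1 <- lapply(c(1, 2, 3, 4), function(v) array(v, c(2, 2, 1)))
  st <- group_ttest(maps1, "one_sample")
  expect_equal(st$t[1, 1, 1], 3.872983, tolerance = 1e-6)
  expect_equal(st$df, 3)

  # paired with identical lists: t = 0 everywhere
  same <- group_ttest(maps1, "paired", maps2 = maps1)
  expect_true(all(same$t == 0 | is.na(same$t)))

  # paired equals one-sample on differences, exactly
  set.seed(32)
  t1m <- lapply(1:6, function(i) array(rnorm(8), c(2, 2, 2)))
  t2m <- lapply(1:6, function(i) array(rnorm(8), c(2, 2, 2)))
  paired <- group_ttest(t2m, "paired", maps2 = t1m)
  diffs <- Map(function(a, b) a - b, t2m, t1m)
  onesam <- group_ttest(diffs, "one_sample")
  expect_identical(paired$t, onesam$t)

  # degenerate two-sample: zero within-group variance flagged
  g1 <- lapply(1:4, function(i) array(1, c(2, 1, 1)))
  g2 <- lapply(1:4, function(i) array(3, c(2, 1, 1)))
  ts <- group_ttest(g1, "two_sample", maps2 = g2)
  expect_true(all(ts$degenerate))
  expect_true(all(is.na(ts$t)))
  expect_error(group_ttest(g1[1:2], "two_sample", maps2 = g2), "at least 3")
})

test_that("cluster labeling agrees with a flood-fill oracle", {
  set.seed(33)
  for (i in 1:8) {
    d <- sample(3:20, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < 0.3, d)
    got <- label_clusters(mask)
    want <- flood_fill_labels(mask)
    # same partition up to label renaming
    expect_equal(got > 0, want > 0)
    tab <- table(got[got > 0], want[want > 0])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("single suprathreshold voxels get near-unity FWE p", {
  set.seed(34)
  n <- 15
  maps <- lapply(seq_len(n), function(i) array(rnorm(64), c(4, 4, 4)))
  st <- group_ttest(maps, "one_sample")
  # force at least one suprathreshold voxel by planting a strong voxel
  maps2 <- lapply(maps, function(m) { m[1, 1, 1] <- m[1, 1, 1] + 3; m })
  st2 <- cluster_threshold(group_ttest(maps2, "one_sample"),
                           n_perm = 500, seed = 1)
  one_vox <- Filter(function(cl) cl$extent == 1, st2$clusters)
  if (length(one_vox)) {
    expect_true(all(vapply(one_vox, `[[`, numeric(1), "p_fwe") > 0.2))
  }
  succeed()
})

test_that("permutation cluster correction is calibrated under the null", {
  fp <- 0
  for (r in 1:20) {
    set.seed(400 + r)
    maps <- lapply(1:15, function(i) array(rnorm(200), c(10, 10, 2)))
    st <- cluster_threshold(group_ttest(maps, "one_sample"),
                            n_perm = 200, seed = r)
    if (any(vapply(st$clusters, `[[`, logical(1), "significant"))) {
      fp <- fp + 1
    }
  }
  # 95% binomial bound for 20 runs at alpha 0.05
  expect_lte(fp, qbinom(0.975, 20, 0.05))
})

test_that("a planted cube of effect d = 1.5 is detected with high power", {
  hits <- 0
  cube <- as.matrix(expand.grid(4:6, 4:6, 1:2))
  for (r in 1:10) {
    set.seed(500 + r)
    maps <- lapply(1:15, function(i) {
      m <- array(rnorm(200), c(10, 10, 2))
      m[cube] <- m[cube] + 1.5
      m
    })
    st <- cluster_threshold(group_ttest(maps, "one_sample"),
                            n_perm = 200, seed = r)
    sig <- Filter(function(cl) cl$significant && cl$sign > 0, st$clusters)
    vox <- unlist(lapply(sig, `[[`, "voxels"))
    cube_lin <- cube[, 1] + (cube[, 2] - 1) * 10 + (cube[, 3] - 1) * 100
    if (length(intersect(vox, cube_lin)) >= 0.5 * nrow(cube)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("cluster tables report extent-sorted clusters with peaks", {
  set.seed(36)
  maps <- lapply(1:12, function(i) {
    m <- array(rnorm(125), c(5, 5, 5))
    m[1:2, 1:2, 1] <- m[1:2, 1:2, 1] + 2
    m
  })
  st <- cluster_threshold(group_ttest(maps, "one_sample"),
                          n_perm = 200, seed = 2)
  tab <- cluster_table(st)
  if (nrow(tab) > 1) {
    expect_true(all(diff(tab$extent) <= 0))
  }
  expect_named(tab, c("region", "extent", "peak_t", "x", "y", "z",
                      "p_fwe", "p_fdr"))
})
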