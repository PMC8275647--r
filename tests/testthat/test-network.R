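test_that("parcellations validate coordinates and spacing", {
  set.seed(50)
  parc <- synthetic_coordinates(40)
  expect_s3_class(parc, "parcellation")
  d <- parc$distance
  expect_true(all(d[upper.tri(d)] >= 10))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_warning(parcellation(rbind(c(0, 0, 0), c(0, 0, 5))), "closer")
  # TSV round trip
  path <- file.path(tempdir(), "coords.tsv")
  write_parcellation(parc, path)
  back <- read_parcellation(path)
  expect_equal(back$centers, parc$centers, ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("parcel time series average sphere voxels", {
  set.seed(51)
  n_t <- 60
  arr <- array(rnorm(10 * 10 * 4 * n_t), c(10, 10, 4, n_t))
  b <- bold_image(arr, tr = 0.5, voxel_size = 2.5)
  mm <- voxel_coords_mm(dim(arr)[1:3], b$affine)
  parc <- parcellation(rbind(mm[1, ], mm[250, ]), radius = 1)
  ts <- parcel_timeseries(b, parc)
  expect_equal(ts[1, ], arr[1, 1, 1, ])
  # uniform image: every node series is the constant
  bu <- bold_image(array(3, c(10, 10, 4, 5)), tr = 0.5, voxel_size = 2.5)
  tsu <- parcel_timeseries(bu, parc)
  expect_true(all(tsu == 3))
})

test_that("connectivity matrices are symmetric with distance masking", {
  set.seed(52)
  centers <- rbind(c(0, 0, 0), c(0, 0, 15), c(0, 0, 40), c(30, 0, 0))
  parc <- suppressWarnings(parcellation(centers, min_spacing = 10))
  ts <- matrix(rnorm(4 * 100), 4, 100)
  cm <- connectivity_matrix(ts, parc)
  expect_equal(cm$z, t(cm$z))
  expect_true(all(is.na(diag(cm$z))))
  expect_false(cm$valid[1, 2])   # 15 mm < 20 mm
  expect_true(cm$valid[1, 3])    # 40 mm
  expect_true(cm$valid[1, 4])
  # edge count before masking: n(n-1)/2
  expect_equal(length(neurocardiac:::edge_index(260)), 33670)
  expect_error(connectivity_matrix(ts[, 1:20], parc), "30 time points")
})

test_that("edgewise paired t matches hand calculation and antisymmetry", {
  set.seed(53)
  n_nodes <- 6
  parc <- synthetic_coordinates(n_nodes)
  mk <- function(evec) {
    z <- matrix(0, n_nodes, n_nodes)
    z[upper.tri(z)] <- evec
    z <- z + t(z); diag(z) <- NA
    valid <- matrix(TRUE, n_nodes, n_nodes); diag(valid) <- FALSE
    structure(list(z = z, valid = valid, labels = parc$labels),
              class = "connectivity_matrix")
  }
  ne <- n_nodes * (n_nodes - 1) / 2
  base <- lapply(1:4, function(i) mk(rnorm(ne, 0, 1e-8)))
  # one edge with paired differences 1,2,3,4
  shifted <- lapply(1:4, function(i) {
    e <- base[[i]]$z[upper.tri(base[[i]]$z)]
    e[1] <- e[1] + i
    mk(e)
  })
  tm <- edgewise_ttest(shifted, base, design = "paired")
  expect_equal(tm[1, 2], 3.872983, tolerance = 1e-5)
  expect_equal(attr(tm, "df"), 3)
  # identical inputs give t = 0; swapping negates
  same <- edgewise_ttest(base, base, design = "paired")
  expect_true(all(same[upper.tri(same)] == 0 | is.na(same[upper.tri(same)])))
  swapped <- edgewise_ttest(base, shifted, design = "paired")
  expect_equal(swapped, -tm, ignore_attr = TRUE)
})

test_that("suprathreshold components match inspection and igraph", {
  n <- 6
  tm <- matrix(0, n, n)
  for (e in list(c(1, 2), c(2, 3), c(4, 5))) {
    tm[e[1], e[2]] <- tm[e[2], e[1]] <- 5
  }
  comps <- suprathreshold_components(tm, threshold = 4.17,
                                     direction = "A>B")
  expect_equal(length(comps), 2)
  ext <- sort(vapply(comps, `[[`, integer(1), "extent"))
  expect_equal(ext, c(1L, 2L))
  sizes <- sort(vapply(comps, function(c) length(c$nodes), integer(1)))
  expect_equal(sizes, c(2L, 3L))
  # threshold above max t: empty
  expect_equal(length(suprathreshold_components(tm, 10)), 0)
  # a connected component with k nodes and k-1 edges is a tree (acyclic)
  for (cp in comps) expect_equal(cp$extent, length(cp$nodes) - 1L)
})

test_that("component extraction agrees with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(54)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    tm <- matrix(0, n, n)
    ne <- sample(1:min(60, n * (n - 1) / 2), 1)
    idx <- sample(neurocardiac:::edge_index(n), ne)
    tm[idx] <- 5
    tm[lower.tri(tm)] <- t(tm)[lower.tri(tm)]
    comps <- suprathreshold_components(tm, 4.17)
    g <- igraph::graph_from_adjacency_matrix(tm > 4.17, mode = "undirected")
    memb <- igraph::components(g)$membership
    sizes <- table(memb)
    got_nodes <- sort(vapply(comps, function(c) length(c$nodes), integer(1)))
    want_nodes <- sort(as.integer(sizes[sizes > 1]))
    expect_equal(got_nodes, want_nodes)
    expect_equal(sum(vapply(comps, `[[`, integer(1), "extent")), ne)
  }
})

test_that("NBS Monte-Carlo equals exhaustive enumeration on 8 pairs", {
  set.seed(55)
  n_nodes <- 6
  ns <- 8
  cfg <- sim_config(seed = 55, n_subjects = ns, n_nodes = n_nodes,
                    effect_size = 2)
  pc <- gen_paired_connectomes(cfg, effect_edges = rbind(c(1, 2), c(2, 3)))
  res <- nbs(pc$t2, pc$t1, design = "paired", threshold = 2.5,
             exhaustive = TRUE)
  expect_equal(res$n_perm, 256L)

  # independent oracle: loop over all 256 sign patterns with textbook
  # formulas and flood-fill components
  s2 <- lapply(pc$t2, function(m) m$z[upper.tri(m$z)])
  s1 <- lapply(pc$t1, function(m) m$z[upper.tri(m$z)])
  valid <- pc$t1[[1]]$valid[upper.tri(pc$t1[[1]]$valid)]
  D <- do.call(cbind, Map(`-`, s2, s1))
  max_ext <- function(tv) {
    tm <- matrix(0, n_nodes, n_nodes)
    tm[upper.tri(tm)] <- ifelse(valid, tv, NA)
    tm[lower.tri(tm)] <- t(tm)[lower.tri(tm)]
    cc <- suprathreshold_components(tm, 2.5, "A>B")
    if (!length(cc)) 0L else max(vapply(cc, `[[`, integer(1), "extent"))
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), ns)))
  null_oracle <- apply(signs, 1, function(sg) {
    Df <- sweep(D, 2, sg, `*`)
    tv <- apply(Df, 1, function(x) mean(x) / (sd(x) / sqrt(ns)))
    max_ext(tv)
  })
  obs <- max_ext(apply(D, 1, function(x) mean(x) / (sd(x) / sqrt(ns))))
  for (cp in res$components) {
    p_oracle <- (1 + sum(null_oracle >= cp$extent)) / (1 + 256)
    expect_equal(cp$fwe_p, p_oracle)
  }
  expect_equal(sort(res$null_max_extent), sort(null_oracle))
})

test_that("FWE p decreases with observed extent for a fixed null", {
  null_max <- c(0, 0, 1, 1, 2, 3, 5, 8)
  p_of <- function(e) (1 + sum(null_max >= e)) / (1 + length(null_max))
  p <- vapply(1:9, p_of, numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("NBS runs per group independently on the paired study design", {
  cfg_a <- sim_config(seed = 57, n_subjects = 8, n_nodes = 20,
                      effect_size = 2.5)
  cfg_b <- sim_config(seed = 58, n_subjects = 8, n_nodes = 20,
                      effect_size = 0)
  pa <- gen_paired_connectomes(cfg_a, effect_nodes = 8)
  pb <- gen_paired_connectomes(cfg_b)
  ra <- nbs(pa$t2, pa$t1, design = "paired", threshold = 3,
            n_perm = 200, seed = 1)
  rb <- nbs(pb$t2, pb$t1, design = "paired", threshold = 3,
            n_perm = 200, seed = 1)
  expect_gt(length(ra$components), 0)
  sig_b <- vapply(rb$components, `[[`, logical(1), "significant")
  expect_true(length(sig_b) == 0 || mean(sig_b) < 0.5)
  # determinism: same seed, same result
  ra2 <- nbs(pa$t2, pa$t1, design = "paired", threshold = 3,
             n_perm = 200, seed = 1)
  expect_equal(ra2$null_max_extent, ra$null_max_extent)
})

test_that("NBS results serialize to JSON with component records", {
  cfg <- sim_config(seed = 59, n_subjects = 10, n_nodes = 20,
                    effect_size = 3)
  pc <- gen_paired_connectomes(cfg, effect_nodes = 6)
  res <- nbs(pc$t2, pc$t1, design = "paired", threshold = 3.5,
             n_perm = 200, seed = 2)
  path <- file.path(tempdir(), "nbs.json")
  write_nbs_json(res, path, labels = pc$parcellation$labels)
  got <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(got$threshold, 3.5)
  expect_equal(got$n_perm, 200)
  expect_true(all(vapply(got$components, function(cp) {
    all(c("nodes", "extent", "fwe_p", "significant") %in% names(cp))
  }, logical(1))))
})
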