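#' Spherical region of interest on an image grid
#'
#' Collects all voxels whose centers lie within `radius` mm of `center`
#' (inclusive boundary), using the image affine to map grid indices to MNI
#' millimetres.
#'
#' @param center MNI coordinates in mm, length 3.
#' @param radius Sphere radius in mm.
#' @param grid A [bold_image()] or a list with `dim` (length-3 integer) and
#'   `affine` (4x4 voxel-to-mm matrix).
#' @return A list of class `sphere_roi` with `center`, `radius`, `voxels`
#'   (linear indices into the 3-D grid) and `ijk` (index triplets).
#' @export
sphere_roi <- function(center, radius, grid) {
  if (inherits(grid, "bold_image")) {
    d <- dim(grid$data)[1:3]; affine <- grid$affine
  } else {
    d <- grid$dim; affine <- grid$affine
  }
  mm <- voxel_coords_mm(d, affine)
  dist2 <- rowSums(sweep(mm, 2, center)^2)
  vox <- which(dist2 <= radius^2 + 1e-9)
  if (!length(vox)) stop("empty sphere: no voxel center within ", radius,
                         " mm of (", paste(center, collapse = ", "), ")")
  structure(
    list(center = center, radius = radius, voxels = vox,
         ijk = arrayInd(vox, d), grid_dim = d),
    class = "sphere_roi"
  )
}

#' @export
print.sphere_roi <- function(x, ...) {
  cat(sprintf("<sphere_roi> r=%g mm at (%g, %g, %g): %d voxels\n",
              x$radius, x$center[1], x$center[2], x$center[3],
              length(x$voxels)))
  invisible(x)
}

#' Fisher z transform of a correlation
#'
#' `z = atanh(r)`, variance-stabilizing and approximately normal.
#' Correlations of exactly +/-1 (self-correlation, degenerate series) are
#' clamped to `1 - 1e-6` in magnitude and flagged via the `"clamped"`
#' attribute.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Fisher z value(s); attribute `clamped` marks clamped entries.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1")
  # clamp only essentially-perfect correlations (|z| beyond ~8.4), so the
  # transform stays invertible over the working range |z| < 8
  clamp <- !is.na(r) & abs(r) > 1 - 1e-7
  r[clamp] <- sign(r[clamp]) * (1 - 1e-6)
  z <- atanh(r)
  attr(z, "clamped") <- clamp
  z
}

#' Seed-based functional connectivity map
#'
#' Averages the (cleaned) BOLD signal over the seed sphere and correlates
#' that series against every in-mask voxel; Pearson correlations are
#' converted to Fisher z. Zero-variance voxels are returned as NA and
#' flagged undefined.
#'
#' @param bold A cleaned [bold_image()].
#' @param seed A [sphere_roi()] on the same grid.
#' @param volumes Optional volume index subset (used by windowed analyses).
#' @return A list of class `seed_zmap` with `values` (3-D array of z, NA
#'   off-mask/undefined), `seed`, and `undefined` (logical 3-D array).
#' @export
seed_fc_map <- function(bold, seed, volumes = NULL) {
  d <- dim(bold$data)
  if (!identical(seed$grid_dim, d[1:3])) stop("seed grid does not match bold")
  Y <- matrix(bold$data, prod(d[1:3]), d[4])
  if (!is.null(volumes)) Y <- Y[, volumes, drop = FALSE]
  s <- colMeans(Y[seed$voxels, , drop = FALSE])
  if (stats::sd(s) == 0) stop("seed time series is constant")
  midx <- which(bold$mask)
  Ym <- Y[midx, , drop = FALSE]
  sds <- apply(Ym, 1, stats::sd)
  r <- rep(NA_real_, length(midx))
  ok <- sds > 0
  r[ok] <- as.vector(stats::cor(t(Ym[ok, , drop = FALSE]), s))
  z <- fisher_z(r)
  vals <- array(NA_real_, d[1:3])
  vals[midx] <- z
  undef <- array(FALSE, d[1:3])
  undef[midx[!ok]] <- TRUE
  structure(list(values = vals, seed = seed, undefined = undef),
            class = "seed_zmap")
}

# stack a list of maps (seed_zmap / coupling_map / arrays / vectors) into a
# voxel x subject matrix plus the spatial dim
stack_maps <- function(maps) {
  get_vals <- function(m) {
    if (inherits(m, c("seed_zmap", "coupling_map"))) m$values else m
  }
  v1 <- get_vals(maps[[1]])
  d <- dim(v1)
  if (is.null(d)) d <- c(length(v1), 1L, 1L)
  if (length(d) == 2L) d <- c(d, 1L)
  mat <- vapply(maps, function(m) as.vector(get_vals(m)),
                numeric(prod(d)))
  list(mat = mat, dim = d)
}

#' Group-level voxelwise t-test on z maps
#'
#' One-sample, paired or two-sample (pooled variance; Welch by flag)
#' t-statistics per voxel. A paired design is computed as a one-sample test
#' on within-subject differences, so the two are exactly equivalent.
#'
#' @param maps For `one_sample`: list of maps. For `paired`: list of T2
#'   maps; supply the matched T1 maps in `maps2`. For `two_sample`: group-1
#'   maps, with group-2 maps in `maps2` (typically per-subject difference
#'   maps).
#' @param design One of `"one_sample"`, `"paired"`, `"two_sample"`.
#' @param maps2 Second list of maps for paired/two-sample designs.
#' @param welch Use Welch's unequal-variance t for two-sample designs.
#' @return A list of class `stat_map` with `t`, `df`, `p_voxel` (two-sided),
#'   plus the stacked data needed for permutation thresholding.
#' @export
group_ttest <- function(maps, design = c("one_sample", "paired",
                                         "two_sample"),
                        maps2 = NULL, welch = FALSE) {
  design <- match.arg(design)
  s1 <- stack_maps(maps)
  if (design == "paired") {
    if (is.null(maps2) || length(maps2) != length(maps)) {
      stop("paired design needs matched maps2 of equal length")
    }
    s2 <- stack_maps(maps2)
    diff <- s1$mat - s2$mat
    return(one_sample_stat(diff, s1$dim, design = "paired"))
  }
  if (design == "one_sample") {
    return(one_sample_stat(s1$mat, s1$dim, design = "one_sample"))
  }
  if (is.null(maps2)) stop("two_sample design needs maps2")
  s2 <- stack_maps(maps2)
  n1 <- ncol(s1$mat); n2 <- ncol(s2$mat)
  if (n1 < 3L || n2 < 3L) stop("need at least 3 subjects per group")
  m1 <- rowMeans(s1$mat); m2 <- rowMeans(s2$mat)
  v1 <- rowSums((s1$mat - m1)^2) / (n1 - 1)
  v2 <- rowSums((s2$mat - m2)^2) / (n2 - 1)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tval <- (m1 - m2) / se
  degenerate <- !is.na(se) & se == 0
  tval[degenerate] <- NA_real_
  p <- 2 * stats::pt(-abs(tval), df)
  structure(
    list(t = array(tval, s1$dim), df = df,
         p_voxel = array(p, s1$dim), dim = s1$dim,
         design = "two_sample", welch = welch,
         data = list(s1$mat, s2$mat), degenerate = array(degenerate, s1$dim)),
    class = "stat_map"
  )
}

one_sample_stat <- function(mat, d, design) {
  n <- ncol(mat)
  if (n < 3L) stop("need at least 3 subjects")
  m <- rowMeans(mat)
  se <- sqrt(rowSums((mat - m)^2) / (n - 1) / n)
  tval <- m / se
  degenerate <- !is.na(se) & se == 0
  tval[degenerate] <- NA_real_
  p <- 2 * stats::pt(-abs(tval), n - 1)
  structure(
    list(t = array(tval, d), df = n - 1, p_voxel = array(p, d), dim = d,
         design = design, data = list(mat),
         degenerate = array(degenerate, d)),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s design, df %s, %d voxels, max |t| %.2f\n",
              x$design, format(x$df[1], digits = 4), prod(x$dim),
              max(abs(x$t), na.rm = TRUE)))
  if (!is.null(x$clusters)) {
    cat(sprintf("  %d suprathreshold clusters (voxel p < %g)\n",
                length(x$clusters), x$voxel_p))
  }
  invisible(x)
}

# t statistics for one-sample data under a sign-flip matrix (n x P)
flip_tstats <- function(mat, flips) {
  n <- ncol(mat)
  mean_p <- (mat %*% flips) / n                 # V x P
  ssq <- rowSums(mat^2)                         # flip-invariant
  var_p <- (ssq - n * mean_p^2) / (n - 1)
  var_p[var_p < 0] <- 0
  mean_p / sqrt(var_p / n)
}

max_cluster_extent <- function(tvec, d, t_thr) {
  mx <- 0L
  for (sgn in c(1, -1)) {
    m <- array(!is.na(tvec) & sgn * tvec > t_thr, d)
    if (any(m)) {
      lab <- label_clusters(m)
      mx <- max(mx, max(tabulate(lab[lab > 0L])))
    }
  }
  mx
}

#' Permutation cluster-extent thresholding
#'
#' Thresholds the voxelwise map at an uncorrected `voxel_p`, labels
#' face-connected clusters of same-signed suprathreshold voxels, and
#' assigns each cluster a family-wise-error-corrected p value from the
#' permutation distribution of the maximum cluster extent (sign flips for
#' one-sample/paired designs, group-label shuffles for two-sample). An
#' optional cluster-level FDR (Benjamini-Hochberg across the uncorrected
#' cluster p values) is reported alongside.
#'
#' @param stat A [group_ttest()] result.
#' @param voxel_p Uncorrected voxel threshold (default 0.005, two-sided).
#' @param cluster_alpha FWE significance level (default 0.05).
#' @param n_perm Number of permutations (default 2000, minimum 500 advised).
#' @param seed RNG seed for the permutation draw.
#' @return The `stat_map` with `clusters`: a list of records
#'   (`voxels`, `extent`, `sign`, `peak_t`, `p_fwe`, `p_fdr`, `significant`)
#'   and `null_max_extent`, the permutation distribution.
#' @export
cluster_threshold <- function(stat, voxel_p = 0.005, cluster_alpha = 0.05,
                              n_perm = 2000L, seed = 1L) {
  if (!inherits(stat, "stat_map")) stop("stat must come from group_ttest")
  d <- stat$dim
  t_thr <- stats::qt(1 - voxel_p / 2, stat$df[1])
  clusters <- list()
  for (sgn in c(1, -1)) {
    m <- array(!is.na(stat$t) & sgn * stat$t > t_thr, d)
    if (any(m)) {
      lab <- label_clusters(m)
      for (id in seq_len(max(lab))) {
        vox <- which(lab == id)
        clusters[[length(clusters) + 1L]] <- list(
          voxels = vox, extent = length(vox), sign = sgn,
          peak_t = sgn * max(sgn * stat$t[vox]))
      }
    }
  }
  # permutation null of the maximum cluster extent
  set.seed(seed)
  null_max <- integer(n_perm)
  if (stat$design %in% c("one_sample", "paired")) {
    mat <- stat$data[[1]]
    n <- ncol(mat)
    flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    tp <- flip_tstats(mat, flips)
    for (p in seq_len(n_perm)) {
      null_max[p] <- max_cluster_extent(tp[, p], d, t_thr)
    }
  } else {
    m1 <- stat$data[[1]]; m2 <- stat$data[[2]]
    all <- cbind(m1, m2)
    n1 <- ncol(m1); ntot <- ncol(all)
    for (p in seq_len(n_perm)) {
      pick <- sample.int(ntot, n1)
      perm_stat <- group_ttest(
        split_cols(all[, pick, drop = FALSE]), design = "two_sample",
        maps2 = split_cols(all[, -pick, drop = FALSE]), welch = stat$welch)
      null_max[p] <- max_cluster_extent(as.vector(perm_stat$t), d, t_thr)
    }
  }
  if (length(clusters)) {
    ext <- vapply(clusters, `[[`, integer(1), "extent")
    p_fwe <- vapply(ext, function(e) {
      (1 + sum(null_max >= e)) / (1 + n_perm)
    }, numeric(1))
    p_fdr <- stats::p.adjust(p_fwe, method = "BH")
    for (i in seq_along(clusters)) {
      clusters[[i]]$p_fwe <- p_fwe[i]
      clusters[[i]]$p_fdr <- p_fdr[i]
      clusters[[i]]$significant <- p_fwe[i] < cluster_alpha
    }
  }
  stat$clusters <- clusters
  stat$null_max_extent <- null_max
  stat$voxel_p <- voxel_p
  stat$cluster_alpha <- cluster_alpha
  stat$n_perm <- n_perm
  stat$perm_seed <- seed
  stat
}

split_cols <- function(m) lapply(seq_len(ncol(m)), function(j) m[, j])

#' Cluster table of a thresholded stat map
#'
#' One row per cluster with extent, peak t, peak location (mm when an
#' affine is supplied, grid indices otherwise) and corrected p values,
#' sorted by extent. Region labels are left blank (no atlas lookup).
#'
#' @param stat A [cluster_threshold()] result.
#' @param affine Optional 4x4 voxel-to-mm matrix for peak coordinates.
#' @return A data.frame.
#' @export
cluster_table <- function(stat, affine = NULL) {
  if (is.null(stat$clusters)) stop("run cluster_threshold first")
  if (!length(stat$clusters)) {
    return(data.frame(region = character(0), extent = integer(0),
                      peak_t = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), p_fwe = numeric(0),
                      p_fdr = numeric(0)))
  }
  rows <- lapply(stat$clusters, function(cl) {
    pk <- cl$voxels[which.max(cl$sign * stat$t[cl$voxels])]
    ijk <- arrayInd(pk, stat$dim)[1, ]
    xyz <- if (!is.null(affine)) {
      as.vector(affine[1:3, 1:3] %*% (ijk - 1) + affine[1:3, 4])
    } else ijk
    data.frame(region = "", extent = cl$extent, peak_t = cl$peak_t,
               x = xyz[1], y = xyz[2], z = xyz[3],
               p_fwe = cl$p_fwe, p_fdr = cl$p_fdr)
  })
  out <- do.call(rbind, rows)
  out[order(-out$extent), , drop = FALSE]
}
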