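#' Spherical parcellation from node coordinates
#'
#' Nodes are spheres (default 5 mm radius, i.e. 10 mm diameter) at MNI
#' coordinates. Centers closer than `min_spacing` (10 mm, so spheres never
#' overlap) trigger a warning, not an error.
#'
#' @param centers Numeric n x 3 matrix of MNI mm coordinates.
#' @param labels Node labels (default `node_1..n`).
#' @param radius Sphere radius in mm (default 5).
#' @param min_spacing Minimum allowed center spacing in mm (default 10).
#' @return A list of class `parcellation` with `labels`, `centers`,
#'   `radius`, `distance` (pairwise center distances, mm).
#' @export
parcellation <- function(centers, labels = NULL, radius = 5,
                         min_spacing = 10) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L) stop("centers must be n x 3 (x, y, z in mm)")
  n <- nrow(centers)
  if (n < 2L) stop("need at least 2 nodes")
  if (is.null(labels)) labels <- paste0("node_", seq_len(n))
  dist <- as.matrix(stats::dist(centers))
  close <- dist < min_spacing & upper.tri(dist)
  if (any(close)) {
    warning(sum(close), " node pairs closer than ", min_spacing, " mm")
  }
  structure(
    list(labels = labels, centers = centers, radius = radius,
         distance = dist),
    class = "parcellation"
  )
}

#' Read a node-coordinate TSV (label, x, y, z in MNI mm)
#' @param path TSV path with a header.
#' @inheritParams parcellation
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path, radius = 5, min_spacing = 10) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("coordinates TSV needs columns: ", paste(need, collapse = ", "))
  }
  parcellation(as.matrix(tab[, c("x", "y", "z")]), tab$label,
               radius = radius, min_spacing = min_spacing)
}

#' Write a parcellation as a coordinates TSV
#' @param parc A [parcellation()].
#' @param path Output TSV path.
#' @export
write_parcellation <- function(parc, path) {
  tab <- data.frame(label = parc$labels, x = parc$centers[, 1],
                    y = parc$centers[, 2], z = parc$centers[, 3])
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean parcel time series
#'
#' Averages the BOLD signal over each node's sphere per volume. Nodes whose
#' spheres contain no in-mask voxel are returned as NA rows and flagged.
#'
#' @param bold A [bold_image()].
#' @param parc A [parcellation()].
#' @return Node x time matrix with attribute `empty` flagging empty nodes.
#' @export
parcel_timeseries <- function(bold, parc) {
  d <- dim(bold$data)
  Y <- matrix(bold$data, prod(d[1:3]), d[4])
  midx <- which(bold$mask)
  out <- matrix(NA_real_, nrow(parc$centers), d[4])
  empty <- logical(nrow(parc$centers))
  for (i in seq_len(nrow(parc$centers))) {
    roi <- tryCatch(
      sphere_roi(parc$centers[i, ], parc$radius,
                 list(dim = d[1:3], affine = bold$affine)),
      error = function(e) NULL)
    vox <- if (is.null(roi)) integer(0) else intersect(roi$voxels, midx)
    if (length(vox)) {
      out[i, ] <- colMeans(Y[vox, , drop = FALSE])
    } else {
      empty[i] <- TRUE
    }
  }
  if (all(empty)) stop("all parcels are empty on this grid")
  rownames(out) <- parc$labels
  attr(out, "empty") <- empty
  out
}

#' Node-by-node Fisher-z connectivity matrix
#'
#' Pearson correlations between all node pairs, Fisher-z transformed.
#' Edges between nodes whose sphere centers are closer than `min_distance`
#' (default 20 mm) are marked invalid, since short-range correlations are
#' inflated by spatial smoothing; so are edges touching a constant or
#' missing node series. The diagonal is undefined.
#'
#' @param node_ts Node x time matrix from [parcel_timeseries()].
#' @param parc The matching [parcellation()].
#' @param min_distance Shortest valid edge length in mm (default 20).
#' @return A list of class `connectivity_matrix` with `z` (symmetric, NA
#'   diagonal) and `valid` (logical edge mask).
#' @export
connectivity_matrix <- function(node_ts, parc, min_distance = 20) {
  n <- nrow(node_ts)
  if (n != nrow(parc$centers)) stop("node count does not match parcellation")
  if (ncol(node_ts) < 30L) stop("need at least 30 time points")
  sds <- apply(node_ts, 1, stats::sd)
  ok <- !is.na(sds) & sds > 0
  z <- matrix(NA_real_, n, n)
  if (sum(ok) >= 2L) {
    r <- stats::cor(t(node_ts[ok, , drop = FALSE]))
    z[ok, ok] <- fisher_z(r)
  }
  diag(z) <- NA_real_
  valid <- outer(ok, ok, `&`) & parc$distance >= min_distance
  diag(valid) <- FALSE
  dimnames(z) <- list(parc$labels, parc$labels)
  structure(list(z = z, valid = valid, labels = parc$labels),
            class = "connectivity_matrix")
}

# upper-triangle edge index helpers: edges enumerated column-major over
# upper.tri of an n x n matrix
edge_index <- function(n) which(upper.tri(matrix(0, n, n)))

edge_endpoints <- function(n) {
  idx <- edge_index(n)
  cbind((idx - 1L) %/% n + 1L, (idx - 1L) %% n + 1L)[, 2:1, drop = FALSE]
}

# stack a list of connectivity matrices into edges x subjects, with the
# jointly valid edge mask
stack_connectomes <- function(mats) {
  n <- nrow(mats[[1]]$z)
  idx <- edge_index(n)
  E <- vapply(mats, function(m) m$z[idx], numeric(length(idx)))
  valid <- Reduce(`&`, lapply(mats, function(m) m$valid[idx]))
  list(E = E, valid = valid, n_nodes = n, idx = idx)
}

#' Edgewise paired or two-sample t statistics
#'
#' Per valid edge, the t statistic comparing condition A to condition B.
#' Paired designs test the within-subject difference A - B; edges invalid
#' in any subject are excluded from the whole analysis (complete case).
#'
#' @param matrices_A,matrices_B Lists of [connectivity_matrix()] objects
#'   (paired: matched order; for the study design A = T2, B = T1).
#' @param design `"paired"` or `"two_sample"`.
#' @param direction `"A>B"` (default), `"B>A"`, or `"two_sided"`; only
#'   stored for downstream thresholding, the t sign convention is A - B.
#' @return A symmetric node x node t matrix (NA on invalid edges) with
#'   attributes `df`, `direction`, `design`.
#' @export
edgewise_ttest <- function(matrices_A, matrices_B,
                           design = c("paired", "two_sample"),
                           direction = c("A>B", "B>A", "two_sided")) {
  design <- match.arg(design)
  direction <- match.arg(direction)
  sA <- stack_connectomes(matrices_A)
  sB <- stack_connectomes(matrices_B)
  if (sA$n_nodes != sB$n_nodes) stop("node counts differ")
  valid <- sA$valid & sB$valid
  n <- sA$n_nodes
  if (design == "paired") {
    if (ncol(sA$E) != ncol(sB$E)) stop("paired design needs matched lists")
    ns <- ncol(sA$E)
    if (ns < 3L) stop("need at least 3 pairs")
    D <- sA$E - sB$E
    m <- rowMeans(D)
    se <- sqrt(rowSums((D - m)^2) / (ns - 1) / ns)
    tval <- m / se
    df <- ns - 1
  } else {
    n1 <- ncol(sA$E); n2 <- ncol(sB$E)
    if (n1 < 3L || n2 < 3L) stop("need at least 3 subjects per group")
    m1 <- rowMeans(sA$E); m2 <- rowMeans(sB$E)
    v1 <- rowSums((sA$E - m1)^2) / (n1 - 1)
    v2 <- rowSums((sB$E - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tval[!valid] <- NA_real_
  tm <- matrix(NA_real_, n, n)
  tm[sA$idx] <- tval
  tm[lower.tri(tm)] <- t(tm)[lower.tri(tm)]
  structure(tm, df = df, direction = direction, design = design)
}

# component extraction on an edge vector (upper-tri enumeration):
# returns list of (nodes, edges (indices into the upper-tri edge vector),
# extent)
components_from_edges <- function(sup_edges, n_nodes) {
  if (!length(sup_edges)) return(list())
  ep <- edge_endpoints(n_nodes)[sup_edges, , drop = FALSE]
  nodes <- sort(unique(as.vector(ep)))
  compact <- match(ep, nodes)
  dim(compact) <- dim(ep)
  parent <- uf_union_pairs(length(nodes), compact[, 1], compact[, 2])
  roots <- uf_roots(parent)
  comp_of_edge <- roots[compact[, 1]]
  split_ids <- unname(split(seq_along(sup_edges), comp_of_edge))
  lapply(split_ids, function(eids) {
    list(nodes = nodes[sort(unique(as.vector(compact[eids, ])))],
         edges = sup_edges[eids], extent = length(eids))
  })
}

#' Connected components of suprathreshold edges
#'
#' Builds the graph whose edges exceed the component-forming threshold and
#' returns its connected components; singleton nodes are ignored and a
#' component's extent is its edge count.
#'
#' @param t_matrix Symmetric node x node t matrix (from [edgewise_ttest()]).
#' @param threshold Component-forming threshold (default 4.17); edges with
#'   `t > threshold` enter the graph (`|t|` for two-sided direction).
#' @param direction `"A>B"`, `"B>A"` or `"two_sided"`; defaults to the
#'   matrix's own attribute.
#' @return List of components, each with `nodes`, `edges` (node-pair
#'   matrix), `extent`.
#' @export
suprathreshold_components <- function(t_matrix, threshold = 4.17,
                                      direction = NULL) {
  n <- nrow(t_matrix)
  if (is.null(direction)) direction <- attr(t_matrix, "direction") %||% "A>B"
  tv <- t_matrix[edge_index(n)]
  sup <- which(edge_exceeds(tv, threshold, direction))
  comps <- components_from_edges(sup, n)
  ep <- edge_endpoints(n)
  lapply(comps, function(cp) {
    list(nodes = cp$nodes, edges = ep[cp$edges, , drop = FALSE],
         extent = cp$extent)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

edge_exceeds <- function(tv, threshold, direction) {
  v <- switch(direction, `A>B` = tv, `B>A` = -tv, two_sided = abs(tv))
  !is.na(v) & v > threshold
}

max_component_extent <- function(tv, threshold, direction, n_nodes) {
  sup <- which(edge_exceeds(tv, threshold, direction))
  if (!length(sup)) return(0L)
  comps <- components_from_edges(sup, n_nodes)
  max(vapply(comps, `[[`, integer(1), "extent"))
}

#' Network-based statistic with permutation FWE
#'
#' Mass-univariate edgewise t-tests, a component-forming threshold
#' (`t > threshold` in the tested direction), and family-wise-error
#' corrected p values for each observed connected component from the
#' permutation distribution of the maximum component extent (edge count).
#' Paired permutation flips each subject's within-pair difference
#' independently; two-sample permutation shuffles group labels. p values
#' use the add-one correction `(1 + #{null >= obs}) / (1 + n_perm)`.
#'
#' @param matrices_A,matrices_B Lists of [connectivity_matrix()] objects
#'   (for the study design A = T2, B = T1).
#' @param design `"paired"` or `"two_sample"`.
#' @param threshold Component-forming t threshold (default 4.17).
#' @param n_perm Number of permutations (default 10000).
#' @param alpha Significance level on the corrected p (default 0.05).
#' @param seed RNG seed for the permutation draw.
#' @param direction Tail: `"A>B"` (default), `"B>A"`, `"two_sided"`.
#' @param exhaustive For paired designs with few subjects, enumerate all
#'   `2^n` sign-flip patterns instead of sampling (forces
#'   `n_perm = 2^n`).
#' @param statistic Component statistic: `"extent"` (edge count, default)
#'   or `"intensity"` (sum of suprathreshold `t - threshold`).
#' @return A list of class `nbs_result`: `components` (with `fwe_p` and
#'   `significant`), `t_matrix`, `threshold`, `n_perm`, `seed`,
#'   `null_max_extent`.
#' @export
nbs <- function(matrices_A, matrices_B, design = c("paired", "two_sample"),
                threshold = 4.17, n_perm = 10000L, alpha = 0.05,
                seed = 1L, direction = c("A>B", "B>A", "two_sided"),
                exhaustive = FALSE, statistic = c("extent", "intensity")) {
  design <- match.arg(design)
  direction <- match.arg(direction)
  statistic <- match.arg(statistic)
  if (!exhaustive && n_perm < 100L) stop("n_perm must be at least 100")
  tm <- edgewise_ttest(matrices_A, matrices_B, design = design,
                       direction = direction)
  n_nodes <- nrow(tm)
  comps <- suprathreshold_components(tm, threshold, direction)
  comp_stat <- function(tv, eids) {
    if (statistic == "extent") length(eids)
    else sum(abs(tv[eids]) - threshold)
  }
  # permutation null of the maximum component statistic
  if (design == "paired") {
    sA <- stack_connectomes(matrices_A)
    sB <- stack_connectomes(matrices_B)
    valid <- sA$valid & sB$valid
    D <- (sA$E - sB$E)[valid, , drop = FALSE]
    ns <- ncol(D)
    if (exhaustive) {
      n_perm <- as.integer(2^ns)
      flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), ns)))
      flips <- t(flips)
    } else {
      set.seed(seed)
      flips <- matrix(sample(c(-1, 1), ns * n_perm, replace = TRUE),
                      ns, n_perm)
    }
    tp <- flip_tstats(D, flips)
    valid_idx <- which(valid)
    null_max <- vapply(seq_len(ncol(tp)), function(p) {
      tv_full <- rep(NA_real_, length(valid))
      tv_full[valid_idx] <- tp[, p]
      null_max_stat(tv_full, threshold, direction, n_nodes, statistic)
    }, numeric(1))
  } else {
    sA <- stack_connectomes(matrices_A)
    sB <- stack_connectomes(matrices_B)
    valid <- sA$valid & sB$valid
    all_E <- cbind(sA$E, sB$E)[valid, , drop = FALSE]
    n1 <- ncol(sA$E); ntot <- ncol(all_E)
    valid_idx <- which(valid)
    set.seed(seed)
    null_max <- vapply(seq_len(n_perm), function(p) {
      pick <- sample.int(ntot, n1)
      tv <- two_sample_t(all_E[, pick, drop = FALSE],
                         all_E[, -pick, drop = FALSE])
      tv_full <- rep(NA_real_, length(valid))
      tv_full[valid_idx] <- tv
      null_max_stat(tv_full, threshold, direction, n_nodes, statistic)
    }, numeric(1))
  }
  ep <- edge_endpoints(n_nodes)
  tv_obs <- tm[edge_index(n_nodes)]
  components <- lapply(comps, function(cp) {
    eids <- which(apply_edge_ids(cp$edges, n_nodes))
    stat_obs <- comp_stat(tv_obs, eids)
    p <- (1 + sum(null_max >= stat_obs)) / (1 + n_perm)
    c(cp, list(stat = stat_obs, fwe_p = p, significant = p < alpha))
  })
  structure(
    list(components = components, t_matrix = tm, threshold = threshold,
         n_perm = n_perm, alpha = alpha, seed = seed,
         direction = direction, statistic = statistic,
         null_max_extent = null_max),
    class = "nbs_result"
  )
}

# logical edge mask (upper-tri enumeration) for a node-pair matrix
apply_edge_ids <- function(pairs, n) {
  sel <- logical(n * (n - 1) / 2)
  idx <- edge_index(n)
  lin <- (pmax(pairs[, 1], pairs[, 2]) - 1L) * n +
    pmin(pairs[, 1], pairs[, 2])
  sel[match(lin, idx)] <- TRUE
  sel
}

two_sample_t <- function(E1, E2) {
  n1 <- ncol(E1); n2 <- ncol(E2)
  m1 <- rowMeans(E1); m2 <- rowMeans(E2)
  v1 <- rowSums((E1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((E2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

null_max_stat <- function(tv, threshold, direction, n_nodes, statistic) {
  sup <- which(edge_exceeds(tv, threshold, direction))
  if (!length(sup)) return(0)
  comps <- components_from_edges(sup, n_nodes)
  if (statistic == "extent") {
    max(vapply(comps, `[[`, integer(1), "extent"))
  } else {
    max(vapply(comps, function(cp) sum(abs(tv[cp$edges]) - threshold),
               numeric(1)))
  }
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> t > %g, %d permutations (%s tail)\n",
              x$threshold, x$n_perm, x$direction))
  if (!length(x$components)) {
    cat("  no suprathreshold components\n")
  } else {
    for (cp in x$components) {
      cat(sprintf("  component: %d nodes, %d edges, FWE p = %.4f%s\n",
                  length(cp$nodes), cp$extent, cp$fwe_p,
                  if (cp$significant) " *" else ""))
    }
  }
  invisible(x)
}

#' Write an NBS result as JSON (plus edge lists for significant components)
#'
#' @param res An [nbs()] result.
#' @param path Output JSON path.
#' @param labels Optional node labels for the edge lists.
#' @return Invisibly, the JSON path.
#' @export
write_nbs_json <- function(res, path, labels = NULL) {
  comp <- lapply(res$components, function(cp) {
    list(nodes = cp$nodes, n_nodes = length(cp$nodes), extent = cp$extent,
         fwe_p = cp$fwe_p, significant = cp$significant)
  })
  jsonlite::write_json(
    list(threshold = res$threshold, n_perm = res$n_perm, seed = res$seed,
         direction = res$direction, statistic = res$statistic,
         components = comp),
    path, auto_unbox = TRUE, digits = NA)
  sig <- Filter(function(cp) cp$significant, res$components)
  for (k in seq_along(sig)) {
    ep <- sig[[k]]$edges
    tab <- data.frame(
      node_a = if (is.null(labels)) ep[, 1] else labels[ep[, 1]],
      node_b = if (is.null(labels)) ep[, 2] else labels[ep[, 2]],
      t = res$t_matrix[ep])
    utils::write.table(tab, sub("\\.json$",
                                sprintf("_component%d_edges.tsv", k), path),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
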