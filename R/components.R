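# Union-find (disjoint set) with path halving; shared by cluster labeling
# on voxel grids and suprathreshold-edge components on connectomes.

uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# union all pairs (a[k], b[k]); returns the parent vector
uf_union_pairs <- function(n, a, b) {
  parent <- uf_new(n)
  for (k in seq_along(a)) {
    ra <- uf_find(parent, a[k])
    rb <- uf_find(parent, b[k])
    if (ra != rb) parent[rb] <- ra
  }
  parent
}

# final root per element
uf_roots <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

#' Label face-connected clusters on a 3-D mask
#'
#' Connected-component labeling of TRUE voxels under 6-connectivity
#' (shared faces only), via union-find over adjacent voxel pairs.
#'
#' @param mask Logical 3-D array.
#' @return Integer array of the same shape: 0 outside, cluster id (1-based,
#'   ordered by first voxel) inside.
#' @export
label_clusters <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3-D array")
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  pos <- arrayInd(idx, d)
  key <- integer(prod(d))
  key[idx] <- seq_along(idx)      # voxel linear index -> compact id
  pairs_a <- integer(0); pairs_b <- integer(0)
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    both <- key[nb] > 0L
    pairs_a <- c(pairs_a, key[idx[ok]][both])
    pairs_b <- c(pairs_b, key[nb[both]])
  }
  parent <- uf_union_pairs(length(idx), pairs_a, pairs_b)
  roots <- uf_roots(parent)
  lab[idx] <- match(roots, unique(roots))
  lab
}
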