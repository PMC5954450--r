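# Independent oracles used across the suite. Each reimplements the checked
# quantity by direct enumeration or closed form, sharing no code with the
# package internals.

# Brute-force maximal-sphere local thickness (same discrete convention as
# the package documents: sphere radius = distance to the nearest
# opposite-phase voxel centre, open-ball coverage). O(n^2); small grids only.
oracle_thickness_map <- function(mask) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  stopifnot(nrow(fg) > 0, nrow(bg) > 0)
  r2 <- apply(fg, 1, function(v)
    min((bg[, 1] - v[1])^2 + (bg[, 2] - v[2])^2 + (bg[, 3] - v[3])^2))
  th2 <- numeric(nrow(fg))
  for (k in seq_len(nrow(fg))) {
    d2 <- (fg[, 1] - fg[k, 1])^2 + (fg[, 2] - fg[k, 2])^2 +
      (fg[, 3] - fg[k, 3])^2
    cover <- d2 < r2[k] - 0.5
    th2[cover] <- pmax(th2[cover], r2[k])
  }
  out <- array(0, d)
  out[mask] <- 2 * sqrt(th2)
  out
}

# Cycle rank (first Betti number) of the L x L x L rod-lattice skeleton,
# built explicitly as a graph: beta1 = E - V + components.
oracle_lattice_cycle_rank <- function(L) {
  id <- function(i, j, k) (k - 1) * L^2 + (j - 1) * L + i
  edges <- integer(0)
  for (k in seq_len(L)) for (j in seq_len(L)) for (i in seq_len(L)) {
    if (i < L) edges <- c(edges, id(i, j, k), id(i + 1, j, k))
    if (j < L) edges <- c(edges, id(i, j, k), id(i, j + 1, k))
    if (k < L) edges <- c(edges, id(i, j, k), id(i, j, k + 1))
  }
  g <- igraph::make_graph(edges, n = L^3, directed = FALSE)
  as.integer(igraph::ecount(g) - igraph::vcount(g) +
               igraph::count_components(g))
}

# Hand evaluation of the Benjamini-Hochberg step-up formula:
# q_(i) = min_{j >= i} m p_(j) / j, clipped at 1, returned in input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive search for the largest odd-edge cube centred (in z) on the
# central slice and contained in the mask; returns edge and all optimal
# centres. Small grids only.
oracle_max_cube <- function(trab, central) {
  d <- dim(trab)
  hmax <- min(central - 1, d[3] - central, (min(d[1], d[2]) - 1) %/% 2)
  for (h in seq(hmax, 0)) {
    hits <- NULL
    for (cx in (1 + h):(d[1] - h)) for (cy in (1 + h):(d[2] - h)) {
      if (all(trab[(cx - h):(cx + h), (cy - h):(cy + h),
                   (central - h):(central + h)]))
        hits <- rbind(hits, c(cx, cy))
    }
    if (!is.null(hits)) return(list(edge = 2 * h + 1, centers = hits))
  }
  NULL
}

# A small solid torus for topology checks: one handle, Euler characteristic 0.
make_torus <- function(d = c(32L, 32L, 16L), R = 9, r = 3.5) {
  ix <- list(x = slice.index(array(0, d), 1),
             y = slice.index(array(0, d), 2),
             z = slice.index(array(0, d), 3))
  cx <- (d + 1) / 2
  rad <- sqrt((ix$x - cx[1])^2 + (ix$y - cx[2])^2)
  (rad - R)^2 + (ix$z - cx[3])^2 <= r^2
}

make_ball_mask <- function(d, centre, radius) {
  ix <- list(x = slice.index(array(0, d), 1),
             y = slice.index(array(0, d), 2),
             z = slice.index(array(0, d), 3))
  (ix$x - centre[1])^2 + (ix$y - centre[2])^2 + (ix$z - centre[3])^2 <=
    radius^2
}
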