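#' Quasi-uniform directions on the unit sphere
#'
#' Fibonacci lattice on the upper hemisphere (mean intercept lengths are
#' antipodally symmetric), optionally rotated by a random rotation drawn
#' from the seed so the direction set carries no lattice alignment with the
#' image axes.
#'
#' @param n number of directions (>= 100 for fabric work).
#' @param seed integer seed for the random rotation; `NULL` for none.
#' @return An `n x 3` matrix of unit vectors.
#' @export
fibonacci_directions <- function(n, seed = NULL) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n           # hemisphere: z in (0, 1)
  r <- sqrt(1 - z^2)
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(seed)) {
    R <- withr::with_seed(seed, random_rotation())
    dirs <- dirs %*% t(R)
  }
  dirs
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed, det +1
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Mean-intercept-length fabric tensor
#'
#' Casts parallel ray bundles through the volume along quasi-uniformly
#' sampled directions; for each direction the mean intercept length is the
#' total in-volume ray length divided by the number of bone/marrow phase
#' crossings. An ellipsoid (quadratic form) is fit by least squares to the
#' direction-scaled MIL point cloud. The degree of anisotropy is
#' 1 - (shortest / longest ellipsoid radius), ranging from 0 (isotropic) to
#' 1 (fully anisotropic); the main direction of trabeculae is the unit
#' major-axis vector (eigenvector of the lowest eigenvalue of the quadratic
#' form), sign-normalized to a non-negative z component.
#'
#' @param vol a [bin_volume()] with both phases present.
#' @param n_directions number of sampled directions (>= 100).
#' @param seed seed for the random rotation of the direction lattice.
#' @param spacing ray spacing within each bundle, voxels.
#' @param step marching step along each ray, voxels.
#' @return An object of class `mil_fabric`: list with `mil` (per-direction
#'   table), `eigenvalues` (ascending), `eigenvectors`, `da`, `mdt`,
#'   `n_dropped`.
#' @export
mil_fabric <- function(vol, n_directions = 512L, seed = 1L, spacing = 1,
                       step = 0.5) {
  stopifnot(inherits(vol, "bin_volume"))
  if (n_directions < 100L) stop("n_directions must be >= 100")
  if (!any(vol$data) || all(vol$data))
    stop("structure too coarse for MIL: a phase is empty")
  d <- dim(vol$data)
  dirs <- fibonacci_directions(n_directions, seed)
  raw <- mil_cpp(as.vector(vol$data), d, dirs, spacing, step)
  mil <- raw$mil
  ok <- is.finite(mil)
  if (mean(!ok) > 0.2)
    stop("structure too coarse for MIL: ",
         sum(!ok), " of ", n_directions, " directions have no crossings")
  dirs_ok <- dirs[ok, , drop = FALSE]
  mil_ok <- mil[ok]

  # least-squares quadratic form: d' A d = 1 / MIL(d)^2
  D <- cbind(dirs_ok[, 1]^2, dirs_ok[, 2]^2, dirs_ok[, 3]^2,
             2 * dirs_ok[, 1] * dirs_ok[, 2],
             2 * dirs_ok[, 1] * dirs_ok[, 3],
             2 * dirs_ok[, 2] * dirs_ok[, 3])
  b <- 1 / mil_ok^2
  a <- lm.fit(D, b)$coefficients
  A <- matrix(c(a[1], a[4], a[5],
                a[4], a[2], a[6],
                a[5], a[6], a[3]), 3, 3)
  eg <- eigen(A, symmetric = TRUE)  # values descending
  ev <- rev(eg$values)              # ascending
  vecs <- eg$vectors[, 3:1, drop = FALSE]
  ev_pos <- pmax(ev, 0)
  da <- if (ev_pos[3] <= 0) NA_real_ else 1 - sqrt(ev_pos[1] / ev_pos[3])
  mdt <- vecs[, 1]                  # lowest eigenvalue = longest radius
  mdt <- mdt / sqrt(sum(mdt^2))
  if (mdt[3] < 0 || (mdt[3] == 0 && mdt[1] < 0)) mdt <- -mdt
  structure(list(mil = data.frame(dx = dirs_ok[, 1], dy = dirs_ok[, 2],
                                  dz = dirs_ok[, 3],
                                  mil = mil_ok * vol$voxel_size),
                 eigenvalues = ev, eigenvectors = vecs,
                 da = da, mdt = mdt, n_dropped = sum(!ok)),
            class = "mil_fabric")
}

#' @export
print.mil_fabric <- function(x, ...) {
  cat(sprintf("MIL fabric: %d directions (%d dropped), DA = %.3f\n",
              nrow(x$mil) + x$n_dropped, x$n_dropped, x$da))
  cat(sprintf("  MDT = (%.3f, %.3f, %.3f)\n", x$mdt[1], x$mdt[2], x$mdt[3]))
  invisible(x)
}

#' Mirror and project a main trabecular direction
#'
#' Right-femur vectors are mirrored mediolaterally to the left side
#' (x negated), then every vector is projected onto the proximal hemisphere
#' (antipodal negation if z < 0). Mirroring precedes projection.
#'
#' @param mdt unit 3-vector (x mediolateral, y anteroposterior,
#'   z proximodistal).
#' @param side `"left"` or `"right"`.
#' @return A unit 3-vector with non-negative z.
#' @export
project_mdt <- function(mdt, side = c("left", "right")) {
  side <- match.arg(side)
  if (length(mdt) != 3L || !all(is.finite(mdt)))
    stop("mdt must be a finite 3-vector")
  nrm <- sqrt(sum(mdt^2))
  if (nrm == 0) stop("zero vector has no direction")
  if (abs(nrm - 1) > 1e-3) stop("mdt must be a unit vector")
  v <- mdt
  if (side == "right") v[1] <- -v[1]
  if (v[3] < 0) v <- -v
  v
}
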