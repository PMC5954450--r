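#' Binarize a grayscale volume
#'
#' Foreground (bone) = voxels strictly above the selected threshold. The
#' default criterion is Otsu's between-class variance maximum, computed on
#' the full 3D gray-level histogram; the chosen method and threshold are
#' recorded in the provenance of the result.
#'
#' @param vol a [gray_volume()] (a `bin_volume` is passed through untouched).
#' @param method `"otsu"`, `"mean"`, or `"fixed"`.
#' @param value threshold for `method = "fixed"`.
#' @return A [bin_volume()].
#' @export
binarize <- function(vol, method = c("otsu", "mean", "fixed"), value = NULL) {
  if (inherits(vol, "bin_volume")) return(vol)
  stopifnot(inherits(vol, "gray_volume"))
  method <- match.arg(method)
  x <- vol$data
  if (length(unique(as.vector(x))) < 2L)
    stop("no threshold separates phases: constant image")
  thr <- switch(method,
                otsu = threshold_otsu(x),
                mean = mean(x),
                fixed = {
                  if (is.null(value)) stop("method 'fixed' needs `value`")
                  value
                })
  bin_volume(x > thr, vol$voxel_size,
             provenance = list(threshold_method = method,
                               threshold = thr))
}

# Otsu's criterion on the integer gray-level histogram.
threshold_otsu <- function(x) {
  v <- as.integer(round(as.vector(x)))
  lo <- min(v)
  counts <- as.numeric(tabulate(v - lo + 1L))
  levels <- as.numeric(seq_along(counts) - 1L + lo)
  n <- sum(counts)
  w <- cumsum(counts)
  mu <- cumsum(counts * levels)
  mu_t <- mu[length(mu)]
  # between-class variance for threshold after level k
  wb <- w[-length(w)]
  wf <- n - wb
  valid <- wb > 0 & wf > 0
  sigma_b <- rep(-Inf, length(wb))
  sigma_b[valid] <- (mu_t * wb[valid] / n - mu[-length(mu)][valid])^2 /
    (wb[valid] / n * wf[valid] / n) / n
  # midpoint of the plateau of maxima (well separated modes leave a wide
  # plateau; the centre is the stable choice)
  ks <- which(sigma_b >= max(sigma_b) * (1 - 1e-12))
  mean(levels[ks])
}

#' Keep the main trabecular structure and fill internal cavities
#'
#' Retains only the largest 26-connected foreground component and fills
#' every enclosed background cavity (6-connected background components that
#' do not touch the stack boundary), so the Euler characteristic of the
#' result is interpretable as 1 - (number of handles).
#'
#' @param vol a [bin_volume()].
#' @return A purified [bin_volume()].
#' @export
purify <- function(vol) {
  stopifnot(inherits(vol, "bin_volume"))
  mask <- vol$data
  if (!any(mask)) stop("empty foreground")
  d <- dim(mask)
  lab <- label_components_cpp(as.vector(mask), d, 26L)
  sizes <- tabulate(lab)
  keep <- which.max(sizes)
  fg <- array(lab == keep, d)

  bg <- !fg
  labb <- array(label_components_cpp(as.vector(bg), d, 6L), d)
  boundary_labels <- unique(c(labb[1, , ], labb[d[1], , ],
                              labb[, 1, ], labb[, d[2], ],
                              labb[, , 1], labb[, , d[3]]))
  boundary_labels <- boundary_labels[boundary_labels != 0L]
  cavity <- labb != 0L & !(labb %in% boundary_labels)
  fg[cavity] <- TRUE
  bin_volume(fg, vol$voxel_size,
             provenance = c(vol$provenance, list(purified = TRUE)))
}

#' Bone volume fraction (BV/TV)
#'
#' Ratio of foreground voxels to total voxels.
#'
#' @param vol a [bin_volume()].
#' @return A number in \[0, 1\].
#' @export
bone_volume_fraction <- function(vol) {
  stopifnot(inherits(vol, "bin_volume"))
  mean(vol$data)
}

#' Euler characteristic and connectivity density
#'
#' The Euler characteristic of the structure is computed as
#' V - E + F - C of the union-of-closed-cubes complex (vertices, edges and
#' faces belonging to at least one foreground voxel), which realizes the
#' 26-connected-foreground / 6-connected-background convention and is
#' algebraically identical to summing 2x2x2 octant contributions over the
#' zero-padded volume. Absolute connectivity Conn = 1 - Euler characteristic
#' equals the number of independent loops (handles) for a purified volume;
#' ConnD normalizes by the physical stack volume.
#'
#' @param vol a [bin_volume()].
#' @return A list with `delta_chi`, `conn`, and `conn_density` (mm^-3).
#' @export
euler_connectivity <- function(vol) {
  stopifnot(inherits(vol, "bin_volume"))
  chi <- euler_characteristic(vol$data)
  conn <- 1L - chi
  structure(list(delta_chi = chi, conn = conn,
                 conn_density = conn / (length(vol$data) * vol$voxel_size^3)),
            class = "euler_result")
}

euler_characteristic <- function(A) {
  d <- dim(A)
  P <- array(FALSE, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- A
  blk <- function(ox, oy, oz, lx, ly, lz)
    P[(1 + ox):(lx + ox), (1 + oy):(ly + oy), (1 + oz):(lz + oz)]
  # vertices: any of the 8 voxels around each lattice corner
  Vocc <- array(FALSE, d + 1L)
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1)
    Vocc <- Vocc | blk(ox, oy, oz, d[1] + 1, d[2] + 1, d[3] + 1)
  nV <- sum(Vocc)
  # edges parallel to each axis: any of the 4 voxels sharing the edge
  nE <- 0
  Eo <- array(FALSE, c(d[1], d[2] + 1, d[3] + 1))
  for (oy in 0:1) for (oz in 0:1)
    Eo <- Eo | blk(1, oy, oz, d[1], d[2] + 1, d[3] + 1)
  nE <- nE + sum(Eo)
  Eo <- array(FALSE, c(d[1] + 1, d[2], d[3] + 1))
  for (ox in 0:1) for (oz in 0:1)
    Eo <- Eo | blk(ox, 1, oz, d[1] + 1, d[2], d[3] + 1)
  nE <- nE + sum(Eo)
  Eo <- array(FALSE, c(d[1] + 1, d[2] + 1, d[3]))
  for (ox in 0:1) for (oy in 0:1)
    Eo <- Eo | blk(ox, oy, 1, d[1] + 1, d[2] + 1, d[3])
  nE <- nE + sum(Eo)
  # faces normal to each axis: either of the 2 voxels sharing the face
  nF <- sum(blk(0, 1, 1, d[1] + 1, d[2], d[3]) |
              blk(1, 1, 1, d[1] + 1, d[2], d[3])) +
    sum(blk(1, 0, 1, d[1], d[2] + 1, d[3]) |
          blk(1, 1, 1, d[1], d[2] + 1, d[3])) +
    sum(blk(1, 1, 0, d[1], d[2], d[3] + 1) |
          blk(1, 1, 1, d[1], d[2], d[3] + 1))
  nC <- sum(A)
  as.integer(nV - nE + nF - nC)
}

#' Local thickness of a phase by maximal inscribed spheres
#'
#' The thickness at a voxel is the diameter of the greatest sphere that fits
#' entirely within the selected phase and contains the voxel; the sphere
#' radius at a centre voxel is its Euclidean distance to the nearest
#' opposite-phase voxel centre. Voxels beyond the grid are treated as phase
#' continuation (no artificial padding). The mean is volume-weighted over
#' all phase voxels. Computing on the background yields trabecular
#' separation.
#'
#' @param vol a [bin_volume()].
#' @param phase `"foreground"` (TbTh) or `"background"` (TbSp).
#' @param keep_map keep the per-voxel thickness map (mm)?
#' @return A list with `mean` (mm), `phase`, and optionally `map`.
#' @export
local_thickness <- function(vol, phase = c("foreground", "background"),
                            keep_map = FALSE) {
  stopifnot(inherits(vol, "bin_volume"))
  phase <- match.arg(phase)
  mask <- if (phase == "foreground") vol$data else !vol$data
  if (!any(mask)) stop("selected phase is empty")
  if (all(mask)) stop("opposite phase is empty: thickness is unbounded")
  d <- dim(mask)
  th2 <- local_thickness_cpp(as.vector(mask), d)
  thick <- 2 * sqrt(th2) * vol$voxel_size
  res <- list(mean = mean(thick[as.vector(mask)]), phase = phase)
  if (keep_map) res$map <- array(thick, d)
  res
}

#' Bone surface density (BS/BV)
#'
#' Surface area from a marching-tetrahedra triangulation of the binary
#' volume at iso-level 0.5, divided by the bone volume (foreground voxel
#' count times voxel volume). The volume is zero-padded before meshing so
#' structures touching the stack boundary are closed, and the binary
#' indicator is lightly Gaussian-smoothed (default 0.7 voxels) before
#' triangulation: smoothing trades the upward staircase bias of meshing raw
#' voxel data against a small downward edge-rounding bias.
#'
#' @param vol a [bin_volume()].
#' @param smooth_sigma pre-meshing smoothing in voxels; 0 disables.
#' @return A list with `bs_bv` (mm^-1), `area` (mm^2) and `bone_volume`
#'   (mm^3).
#' @export
surface_density <- function(vol, smooth_sigma = 0.7) {
  stopifnot(inherits(vol, "bin_volume"))
  mask <- vol$data
  if (!any(mask)) stop("empty foreground")
  d <- dim(mask)
  pad <- as.integer(ceiling(3.5 * max(smooth_sigma, 0)) + 1L)
  dp <- d + 2L * pad
  field <- array(0, dp)
  field[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]),
        (pad + 1):(pad + d[3])] <- mask * 1.0
  if (smooth_sigma > 0)
    field <- smooth3d_cpp(as.vector(field), dp, rep(smooth_sigma, 3))
  area_vox2 <- mesh_area_cpp(as.vector(field), dp, 0.5)
  area <- area_vox2 * vol$voxel_size^2
  bv <- sum(mask) * vol$voxel_size^3
  list(bs_bv = area / bv, area = area, bone_volume = bv)
}

#' Full morphometric summary of a binary volume of interest
#'
#' Runs all trabecular parameters on a (purified) binary VOI: BV/TV,
#' Euler-characteristic connectivity, local thickness and separation,
#' surface density, and the mean-intercept-length fabric (degree of
#' anisotropy and main trabecular direction, mirrored/projected according to
#' `side`). If the fabric analysis is impossible (degenerate phase or too
#' coarse a structure) DA and MDT are reported as `NA` with the failure
#' recorded in `flags`.
#'
#' @param vol a [bin_volume()], ideally after [purify()].
#' @param side `"left"` or `"right"`: right-side main directions are
#'   mirrored mediolaterally onto the left side.
#' @param n_directions number of MIL sampling directions.
#' @param mil_seed seed for the random rotation of the direction set.
#' @return An object of class `trab_summary`: a list with fields `bv_tv`,
#'   `delta_chi`, `conn`, `conn_density`, `tb_th`, `tb_sp`, `bs_bv`, `da`,
#'   `mdt`, `relative_resolution`, `voxel_size`, `side`, `flags`.
#' @export
summarize_morphometry <- function(vol, side = c("left", "right"),
                                  n_directions = 512L, mil_seed = 1L) {
  stopifnot(inherits(vol, "bin_volume"))
  side <- match.arg(side)
  eu <- euler_connectivity(vol)
  bvtv <- bone_volume_fraction(vol)
  flags <- character(0)

  tb_th <- tb_sp <- NA_real_
  if (any(vol$data) && !all(vol$data)) {
    tb_th <- local_thickness(vol, "foreground")$mean
    tb_sp <- local_thickness(vol, "background")$mean
  } else {
    flags <- c(flags, "thickness: one phase empty")
  }
  bs <- if (any(vol$data)) surface_density(vol)$bs_bv else NA_real_

  da <- NA_real_
  mdt <- rep(NA_real_, 3)
  fab <- tryCatch(mil_fabric(vol, n_directions = n_directions,
                             seed = mil_seed),
                  error = function(e) e)
  if (inherits(fab, "error")) {
    flags <- c(flags, paste("fabric:", conditionMessage(fab)))
  } else {
    da <- fab$da
    mdt <- project_mdt(fab$mdt, side)
  }

  structure(list(bv_tv = bvtv,
                 delta_chi = eu$delta_chi,
                 conn = eu$conn,
                 conn_density = eu$conn_density,
                 tb_th = tb_th,
                 tb_sp = tb_sp,
                 bs_bv = bs,
                 da = da,
                 mdt = mdt,
                 relative_resolution = tb_th / vol$voxel_size,
                 voxel_size = vol$voxel_size,
                 side = side,
                 flags = flags),
            class = "trab_summary")
}

#' @export
print.trab_summary <- function(x, ...) {
  cat("Trabecular morphometry summary\n")
  cat(sprintf("  BV/TV   %.4f    Conn  %d (ConnD %.2f mm^-3)\n",
              x$bv_tv, x$conn, x$conn_density))
  cat(sprintf("  TbTh    %.4f mm  TbSp  %.4f mm  BS/BV %.2f mm^-1\n",
              x$tb_th, x$tb_sp, x$bs_bv))
  if (is.na(x$da)) {
    cat("  DA / MDT: not available\n")
  } else {
    cat(sprintf("  DA      %.3f     MDT   (%.3f, %.3f, %.3f)\n",
                x$da, x$mdt[1], x$mdt[2], x$mdt[3]))
  }
  cat(sprintf("  relative resolution %.2f (TbTh / voxel)\n",
              x$relative_resolution))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' One-row data frame from a morphometry summary
#'
#' @param x a `trab_summary`.
#' @param ... unused.
#' @return A one-row `data.frame` with the seven trabecular parameters, the
#'   MDT components and QC fields.
#' @export
as.data.frame.trab_summary <- function(x, ...) {
  data.frame(BVTV = x$bv_tv, ConnD = x$conn_density, Conn = x$conn,
             TbTh = x$tb_th, TbSp = x$tb_sp, BSBV = x$bs_bv, DA = x$da,
             MDT_x = x$mdt[1], MDT_y = x$mdt[2], MDT_z = x$mdt[3],
             relative_resolution = x$relative_resolution,
             voxel_size = x$voxel_size, side = x$side,
             stringsAsFactors = FALSE)
}
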