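#' Central slice of a femoral-head mask
#'
#' Returns the z index of the plane dividing the head mask into a distal
#' (lower z) and a proximal (upper z) half: the slice minimizing the
#' absolute difference between the voxel counts below and above it. Ties
#' are broken toward the distal (lower-index) side.
#'
#' @param head 3D logical array (or [bin_volume()]) marking the femoral
#'   head.
#' @return Integer slice index.
#' @export
central_slice <- function(head) {
  mask <- if (inherits(head, "bin_volume")) head$data else head
  if (!any(mask)) stop("empty head mask")
  counts <- apply(mask, 3, sum)
  nz <- length(counts)
  total <- sum(counts)
  below <- cumsum(counts) - counts      # strictly below each slice
  above <- total - below - counts       # strictly above
  which.min(abs(below - above))         # first minimum = distal tie-break
}

#' Largest cortex-free cubic VOI centred on the central slice
#'
#' Finds the largest axis-aligned cube with odd edge length whose z extent
#' is centred on the central slice and which lies entirely within the
#' trabecular region (head mask minus cortical mask). Among the largest
#' cubes, the one whose centre is closest to the trabecular centroid of the
#' central slice is returned (lowest x, then y, on exact ties).
#'
#' @param head 3D logical array or [bin_volume()]: the femoral head
#'   (trabecular + cortical).
#' @param cortex 3D logical array or [bin_volume()] marking cortical bone,
#'   or `NULL` for none.
#' @param central central slice index from [central_slice()]; computed from
#'   `head` when missing.
#' @param voxel_size voxel edge length in mm (taken from `head` when it is
#'   a `bin_volume`).
#' @param min_edge smallest acceptable edge length in voxels.
#' @return A list of class `voi_spec`: `center` (x, y, z), `edge` (voxels),
#'   `vl` (mm), `central_slice`.
#' @export
fit_max_cube <- function(head, cortex = NULL, central = NULL,
                         voxel_size = NULL, min_edge = 16L) {
  if (inherits(head, "bin_volume")) {
    if (is.null(voxel_size)) voxel_size <- head$voxel_size
    head <- head$data
  }
  if (is.null(voxel_size))
    stop("voxel_size is required (never guessed)")
  if (inherits(cortex, "bin_volume")) cortex <- cortex$data
  trab <- if (is.null(cortex)) head else (head & !cortex)
  if (is.null(central)) central <- central_slice(head)
  d <- dim(trab)
  if (!any(trab[, , central]))
    stop("VOI too small: no trabecular voxels on the central slice")

  # integral image for O(1) cube-occupancy queries
  S <- array(as.numeric(trab), d)
  S <- apply(S, c(2, 3), cumsum)
  S <- aperm(apply(S, c(1, 3), cumsum), c(2, 1, 3))
  S <- apply(S, c(1, 2), cumsum)
  S <- aperm(S, c(2, 3, 1))
  Sp <- array(0, d + 1L)
  Sp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- S
  box_sum <- function(x0, x1, y0, y1, z0, z1)
    Sp[x1 + 1, y1 + 1, z1 + 1] - Sp[x0, y1 + 1, z1 + 1] -
    Sp[x1 + 1, y0, z1 + 1] - Sp[x1 + 1, y1 + 1, z0] +
    Sp[x0, y0, z1 + 1] + Sp[x0, y1 + 1, z0] + Sp[x1 + 1, y0, z0] -
    Sp[x0, y0, z0]

  hmax_z <- min(central - 1L, d[3] - central)
  hmax <- min(hmax_z, (min(d[1], d[2]) - 1L) %/% 2L)
  best <- NULL
  for (h in seq(hmax, 0L)) {
    edge <- 2L * h + 1L
    z0 <- central - h; z1 <- central + h
    cx_range <- seq(1L + h, d[1] - h)
    cy_range <- seq(1L + h, d[2] - h)
    full <- as.numeric(edge)^3
    hits <- NULL
    for (cy in cy_range) {
      for (cx in cx_range) {
        if (box_sum(cx - h, cx + h, cy - h, cy + h, z0, z1) == full)
          hits <- rbind(hits, c(cx, cy))
      }
    }
    if (!is.null(hits)) {
      # centroid of the trabecular region on the central slice
      sl <- which(trab[, , central], arr.ind = TRUE)
      cen <- colMeans(sl)
      d2 <- (hits[, 1] - cen[1])^2 + (hits[, 2] - cen[2])^2
      ord <- order(d2, hits[, 1], hits[, 2])
      pick <- hits[ord[1], ]
      best <- list(center = c(pick[1], pick[2], central), edge = edge)
      break
    }
  }
  if (is.null(best) || best$edge < min_edge)
    stop("VOI too small: no cube of edge >= ", min_edge, " voxels fits")
  structure(list(center = as.integer(best$center),
                 edge = as.integer(best$edge),
                 vl = best$edge * voxel_size,
                 central_slice = as.integer(central)),
            class = "voi_spec")
}

#' Extract the VOI subvolume
#'
#' @param vol a [bin_volume()] or [gray_volume()].
#' @param voi a `voi_spec` from [fit_max_cube()].
#' @return A volume of the same class restricted to the cube.
#' @export
extract_voi <- function(vol, voi) {
  h <- (voi$edge - 1L) %/% 2L
  c_ <- voi$center
  sub <- vol$data[(c_[1] - h):(c_[1] + h),
                  (c_[2] - h):(c_[2] + h),
                  (c_[3] - h):(c_[3] + h)]
  if (inherits(vol, "bin_volume"))
    bin_volume(sub, vol$voxel_size, provenance = c(vol$provenance,
                                                   list(voi = TRUE)))
  else gray_volume(sub, vol$voxel_size)
}

#' Specimen quality filter
#'
#' A specimen passes when its relative resolution (TbTh / voxel size) is at
#' least `min_resolution` and its absolute connectivity is at least
#' `min_conn`; scans below either threshold are flagged (not deleted) with
#' the failing reasons.
#'
#' @param summary a `trab_summary` from [summarize_morphometry()], or a list
#'   with `relative_resolution` and `conn`.
#' @param min_resolution minimum relative resolution (default 5).
#' @param min_conn minimum absolute connectivity (default 50; exactly 50
#'   passes).
#' @return A list of class `qc_record`: `relative_resolution`, `conn`,
#'   `passed`, `reasons`.
#' @export
qc_filter <- function(summary, min_resolution = 5, min_conn = 50) {
  rel <- summary$relative_resolution
  conn <- summary$conn
  reasons <- character(0)
  if (!is.finite(rel) || rel < min_resolution)
    reasons <- c(reasons,
                 sprintf("relative resolution %.3g below %g", rel,
                         min_resolution))
  if (!is.finite(conn) || conn < min_conn)
    reasons <- c(reasons,
                 sprintf("absolute connectivity %s below %g",
                         format(conn), min_conn))
  structure(list(relative_resolution = rel, conn = conn,
                 passed = length(reasons) == 0L, reasons = reasons),
            class = "qc_record")
}

#' @export
print.qc_record <- function(x, ...) {
  cat(sprintf("QC: %s (relative resolution %.2f, Conn %s)\n",
              if (x$passed) "passed" else "FAILED",
              x$relative_resolution, format(x$conn)))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}
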