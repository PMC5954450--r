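#' Binary voxel volume
#'
#' The unit of morphometric measurement: a 3D logical grid with an isotropic
#' physical voxel size. Axis convention: the first array dimension is
#' mediolateral (x), the second anteroposterior (y), the third proximodistal
#' (z).
#'
#' @param data 3D logical (or coercible) array, `TRUE` = bone.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param provenance named list recording how the volume was produced
#'   (thresholding method and value, purified flag, ...).
#' @return An object of class `bin_volume`.
#' @export
bin_volume <- function(data, voxel_size, provenance = list()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.logical(data)) {
    storage.mode(data) <- "logical"
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (mm)")
  structure(list(data = data, voxel_size = voxel_size,
                 provenance = provenance),
            class = "bin_volume")
}

#' Grayscale voxel volume
#'
#' @param data 3D numeric array of integer gray values (8- or 16-bit range).
#' @param voxel_size isotropic voxel edge length in mm.
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(data, voxel_size) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (mm)")
  structure(list(data = data, voxel_size = voxel_size),
            class = "gray_volume")
}

#' @export
print.bin_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Binary volume %d x %d x %d, voxel %.4g mm, BV/TV = %.3f\n",
              d[1], d[2], d[3], x$voxel_size,
              mean(x$data)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, function(v)
                                 paste(format(v), collapse = ","), ""),
                               sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Gray volume %d x %d x %d, voxel %.4g mm, range [%g, %g]\n",
              d[1], d[2], d[3], x$voxel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Write a volume as a multi-page TIFF stack
#'
#' Pages are z slices; binary volumes are written 8-bit as 0/255. A JSON
#' sidecar (same path with extension `.json`) records the voxel size and any
#' extra metadata.
#'
#' @param vol a `bin_volume` or `gray_volume`.
#' @param path output TIFF path.
#' @param bits bits per sample (8 or 16) for grayscale data.
#' @param sidecar named list of extra metadata for the JSON sidecar, or
#'   `NULL` to skip the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path, bits = 8L, sidecar = list()) {
  d <- dim(vol$data)
  maxval <- 2^bits - 1
  # writeTIFF expects values in [0, 1]; pages are z slices, rows = y, cols = x
  slices <- lapply(seq_len(d[3]), function(k) {
    m <- t(vol$data[, , k]) * 1.0
    if (!is.logical(vol$data)) m <- m / maxval
    m
  })
  tiff::writeTIFF(slices, path, bits.per.sample = as.integer(bits))
  if (!is.null(sidecar)) {
    meta <- c(list(voxel_size_mm = vol$voxel_size,
                   dim = d,
                   binary = is.logical(vol$data)),
              sidecar)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path,
                                   ignore.case = TRUE)

#' Read a multi-page TIFF stack
#'
#' The voxel size is taken from `voxel_size` if given, otherwise from the
#' JSON sidecar next to the file; it is an error to have neither (the voxel
#' size is never guessed).
#'
#' @param path TIFF path.
#' @param voxel_size voxel edge length in mm, or `NULL` to read the sidecar.
#' @param bits bits per sample used when the file was written (for rescaling
#'   gray values back to integers).
#' @return A `bin_volume` if the stack holds only two gray levels that are 0
#'   and the maximum, otherwise a `gray_volume`.
#' @export
read_stack <- function(path, voxel_size = NULL, bits = 8L) {
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp))
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(voxel_size)) {
    if (is.null(meta) || is.null(meta$voxel_size_mm))
      stop("voxel size not given and no JSON sidecar found for ", path)
    voxel_size <- meta$voxel_size_mm
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  arr <- array(0, d)
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  vals <- sort(unique(as.vector(arr)))
  if (length(vals) <= 2L && all(vals %in% c(0, 1))) {
    bin_volume(arr > 0, voxel_size, provenance = list(source = basename(path)))
  } else {
    gray_volume(round(arr * (2^bits - 1)), voxel_size)
  }
}
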