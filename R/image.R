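#' Raster image with physical spacing
#'
#' The working image container: a 2D (`[x, y]`) or 3D (`[x, y, z]`) numeric
#' array plus per-axis physical spacing in mm and an orientation tag.
#'
#' Coordinate convention (stored with every image and used by all spatial
#' reasoning): indices are 1-based and physical position is
#' `(index - 1) * spacing` mm. In 3D, axis 3 (z) is the craniocaudal axis and
#' "above" means larger z (superior); in 2D, axis 2 (y) is vertical and
#' "above" means smaller y (row convention of radiograph rasters). Axis 1 (x)
#' is lateral with "patient-left" at larger x (radiological display
#' orientation).
#'
#' @param data numeric 2D or 3D array.
#' @param spacing numeric vector, mm per axis (length = number of dims).
#' @param orientation orientation tag, default `"radiological"`.
#' @return an object of class `sm_image`.
#' @export
sm_image <- function(data, spacing, orientation = "radiological") {
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("image data must be a 2D or 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, length(d))
  if (length(spacing) != length(d) || any(spacing <= 0))
    stop("spacing must give a positive mm value per image axis")
  structure(list(data = data, spacing = spacing, orientation = orientation),
            class = "sm_image")
}

#' @export
print.sm_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sm_image> %s voxels, spacing %s mm (%s)\n",
              paste(d, collapse = "x"),
              paste(format(x$spacing), collapse = "x"), x$orientation))
  invisible(x)
}

n_axes <- function(image) length(dim(image$data))

# Axis bookkeeping: which array axis is vertical / lateral and which index
# direction is "above" / "patient-left" under the stored convention.
axis_info <- function(image) {
  nd <- n_axes(image)
  if (nd == 3L) {
    list(vertical = 3L, above_sign = +1, lateral = 1L, left_sign = +1)
  } else {
    list(vertical = 2L, above_sign = -1, lateral = 1L, left_sign = +1)
  }
}

#' Physical coordinates (mm) of voxel indices
#'
#' @param idx integer vector of linear indices into the raster.
#' @param dim raster dimensions.
#' @param spacing mm per axis.
#' @return matrix, one row per index, columns = axes, in mm.
#' @export
coords_mm <- function(idx, dim, spacing) {
  ai <- arrayInd(idx, .dim = dim)
  sweep(ai - 1, 2L, spacing, "*")
}

centroid_mm <- function(idx, dim, spacing) {
  if (length(idx) == 0L) return(rep(NA_real_, length(dim)))
  colMeans(coords_mm(idx, dim, spacing))
}

mask_from_idx <- function(idx, dim) {
  m <- array(FALSE, dim = dim)
  m[idx] <- TRUE
  m
}

## ---- file formats -------------------------------------------------------

#' Read a raster image from disk
#'
#' NIfTI (`.nii`, `.nii.gz`) for 3D volumes, ASCII PGM (`.pgm`, with a
#' `<file>.json` spacing sidecar) for 2D images, PNG for 2D binary masks.
#'
#' @param path file path.
#' @param spacing optional mm spacing overriding file metadata (required for
#'   PGM/PNG when no sidecar is present).
#' @return an [sm_image()].
#' @export
read_image <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    vol <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(vol)
    arr <- array(as.numeric(vol), dim = dim(vol))
    return(sm_image(arr, sp[seq_along(dim(arr))]))
  }
  if (grepl("\\.pgm$", low)) {
    img <- read_pgm(path)
    side <- paste0(path, ".json")
    if (is.null(spacing) && file.exists(side))
      spacing <- jsonlite::fromJSON(side)$spacing
    if (is.null(spacing)) stop("no spacing for PGM image: ", path)
    return(sm_image(img, spacing))
  }
  if (grepl("\\.png$", low)) {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
    arr <- t(arr)  # png is [row=y, col=x]; store [x, y]
    if (is.null(spacing)) spacing <- c(1, 1)
    return(sm_image(arr, spacing))
  }
  stop("unsupported image format: ", path)
}

#' Write a raster image to disk
#'
#' Format chosen by extension; see [read_image()].
#'
#' @param image an [sm_image()] (or a logical mask array for masks).
#' @param path destination path.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "sm_image"))
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) {
    vol <- RNifti::asNifti(image$data)
    RNifti::pixdim(vol) <- image$spacing
    RNifti::writeNifti(vol, path)
  } else if (grepl("\\.pgm$", low)) {
    write_pgm(image$data, path)
    jsonlite::write_json(list(spacing = image$spacing), paste0(path, ".json"),
                         auto_unbox = FALSE, digits = NA)
  } else if (grepl("\\.png$", low)) {
    arr <- t(image$data)  # back to [row=y, col=x]
    arr <- pmin(pmax(arr, 0), 1)
    png::writePNG(arr, path)
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' Write / read a binary mask
#'
#' 3D masks go to NIfTI, 2D masks to PNG (values 0/1).
#'
#' @param mask logical array.
#' @param spacing mm per axis.
#' @param path destination (`.nii.gz` or `.png`).
#' @export
write_mask <- function(mask, spacing, path) {
  write_image(sm_image(array(as.numeric(mask), dim = dim(mask)), spacing), path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, spacing = NULL) {
  img <- read_image(path, spacing)
  img$data > 0.5
}

# ASCII (P2) PGM; no installed R package reads this classic format.
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1L] != "P2") stop("only ASCII (P2) PGM supported: ", path)
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch in ", path)
  # file is row-major (y rows of x); store [x, y]
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  t(m)
}

write_pgm <- function(data, path, maxval = NULL) {
  v <- round(data)
  if (min(v) < 0) stop("PGM requires non-negative intensities")
  if (is.null(maxval)) maxval <- max(v, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(data), ncol(data)), format(maxval)), con)
  # row-major: one image row (fixed y) per line
  write.table(t(v), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
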