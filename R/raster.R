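# Low-level binary raster algorithms shared by the segmentation and reasoning
# agents: connected-component labeling, spacing-aware binary morphology, hole
# filling, boundaries and Hausdorff distance. Dimension-generic over 2D/3D
# logical arrays; all algorithms work on a zero-padded copy so neighbour
# offsets never wrap across array edges.

pad_array <- function(a, width, fill) {
  d <- dim(a)
  nd <- length(d)
  if (length(width) == 1L) width <- rep(width, nd)
  dp <- d + 2L * width
  out <- array(fill, dim = dp)
  idx <- lapply(seq_len(nd), function(k) seq_len(d[k]) + width[k])
  if (nd == 2L) out[idx[[1L]], idx[[2L]]] <- a
  else out[idx[[1L]], idx[[2L]], idx[[3L]]] <- a
  out
}

unpad_array <- function(a, width, dim_orig) {
  nd <- length(dim_orig)
  if (length(width) == 1L) width <- rep(width, nd)
  idx <- lapply(seq_len(nd), function(k) seq_len(dim_orig[k]) + width[k])
  if (nd == 2L) a[idx[[1L]], idx[[2L]]] else a[idx[[1L]], idx[[2L]], idx[[3L]]]
}

# linear-index offsets for unit-neighbourhood deltas within padded dims
neighbour_offsets <- function(dimp, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  nd <- length(dimp)
  deltas <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  deltas <- deltas[rowSums(abs(deltas)) > 0L, , drop = FALSE]
  if (connectivity == "face")
    deltas <- deltas[rowSums(abs(deltas)) == 1L, , drop = FALSE]
  mult <- cumprod(c(1, dimp[-nd]))
  as.integer(deltas %*% mult)
}

# ellipsoidal (physical-radius) structuring-element offsets, origin included
ball_deltas <- function(radius_mm, spacing) {
  rvox <- pmax(0L, floor(radius_mm / spacing))
  nd <- length(spacing)
  ranges <- lapply(seq_len(nd), function(k) -rvox[k]:rvox[k])
  g <- as.matrix(expand.grid(ranges))
  d2 <- as.numeric((g^2) %*% (spacing^2))
  g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

#' Label connected components of a binary raster
#'
#' Default connectivity is the full neighbourhood (8 in 2D, 26 in 3D);
#' `"face"` gives 4/6-connectivity.
#'
#' @param mask logical 2D/3D array.
#' @param connectivity `"full"` (default) or `"face"`.
#' @return integer array of the same shape: 0 background, components numbered
#'   `1..k` in raster (first-voxel) order.
#' @export
label_components <- function(mask, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  d <- dim(mask)
  mp <- pad_array(mask, 1L, FALSE)
  dimp <- dim(mp)
  off <- neighbour_offsets(dimp, connectivity)
  lab <- integer(length(mp))
  fg <- which(mp)
  nextlab <- 0L
  for (seed in fg) {
    if (lab[seed] > 0L) next
    nextlab <- nextlab + 1L
    lab[seed] <- nextlab
    frontier <- seed
    while (length(frontier) > 0L) {
      nb <- rep(frontier, each = length(off)) + off
      nb <- nb[mp[nb] & lab[nb] == 0L]
      if (length(nb) == 0L) break
      lab[nb] <- nextlab
      frontier <- unique(nb)
    }
  }
  unpad_array(array(lab, dim = dimp), 1L, d)
}

dilate_mask <- function(mask, radius_mm, spacing) {
  if (radius_mm <= 0) return(mask)
  d <- dim(mask)
  deltas <- ball_deltas(radius_mm, spacing)
  w <- apply(abs(deltas), 2L, max)
  mp <- pad_array(mask, w, FALSE)
  dimp <- dim(mp)
  mult <- cumprod(c(1, dimp[-length(dimp)]))
  off <- as.integer(deltas %*% mult)
  fg <- which(mp)
  out <- logical(length(mp))
  for (o in off) out[fg + o] <- TRUE
  unpad_array(array(out, dim = dimp), w, d)
}

erode_mask <- function(mask, radius_mm, spacing) {
  if (radius_mm <= 0) return(mask)
  # erosion as complement-dilation; beyond the image edge counts as background
  !dilate_mask(!mask, radius_mm, spacing)
}

open_mask <- function(mask, radius_mm, spacing)
  dilate_mask(erode_mask(mask, radius_mm, spacing), radius_mm, spacing)

close_mask <- function(mask, radius_mm, spacing)
  erode_mask(dilate_mask(mask, radius_mm, spacing), radius_mm, spacing)

#' Fill interior holes of a binary mask
#'
#' Background components (face connectivity) not connected to the raster
#' border are filled.
#'
#' @param mask logical 2D/3D array.
#' @return logical array, superset of `mask`.
#' @export
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = "face")
  d <- dim(bg)
  nd <- length(d)
  border <- integer(0)
  for (k in seq_len(nd)) {
    idx <- lapply(d, seq_len)
    for (side in c(1L, d[k])) {
      idx_k <- idx; idx_k[[k]] <- side
      sl <- if (nd == 2L) bg[idx_k[[1L]], idx_k[[2L]]]
            else bg[idx_k[[1L]], idx_k[[2L]], idx_k[[3L]]]
      border <- c(border, sl)
    }
  }
  outside <- unique(border[border > 0L])
  mask | (bg > 0L & !(bg %in% outside))
}

mask_boundary <- function(mask) {
  d <- dim(mask)
  mp <- pad_array(mask, 1L, FALSE)
  off <- neighbour_offsets(dim(mp), "face")
  fg <- which(mp)
  interior <- fg
  for (o in off) interior <- interior[mp[interior + o]]
  bnd <- logical(length(mp))
  bnd[setdiff(fg, interior)] <- TRUE
  unpad_array(array(bnd, dim = dim(mp)), 1L, d)
}

directed_hd <- function(A, B, chunk = 512L) {
  # max over rows of A of the min Euclidean distance to rows of B
  worst <- 0
  nb <- nrow(B)
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    d2 <- matrix(0, e - s + 1L, nb)
    for (k in seq_len(ncol(A)))
      d2 <- d2 + outer(A[s:e, k], B[, k], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1L, min))))
  }
  worst
}

#' Hausdorff distance between two masks (mm)
#'
#' Symmetric Hausdorff distance between mask boundaries, in physical mm.
#' Sensitive to stray disconnected regions, which is why it is the metric of
#' interest for candidate-rejection behaviour.
#'
#' @param a,b logical arrays of identical shape.
#' @param spacing mm per axis.
#' @return distance in mm (0 if both empty, `Inf` if exactly one is empty).
#' @export
hausdorff_mm <- function(a, b, spacing) {
  ia <- which(mask_boundary(a)); ib <- which(mask_boundary(b))
  if (length(ia) == 0L && length(ib) == 0L) return(0)
  if (length(ia) == 0L || length(ib) == 0L) return(Inf)
  A <- coords_mm(ia, dim(a), spacing)
  B <- coords_mm(ib, dim(b), spacing)
  max(directed_hd(A, B), directed_hd(B, A))
}
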