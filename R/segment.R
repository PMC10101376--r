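# Candidate-generating segmentation primitives: intensity thresholding,
# connected components -> candidate regions, morphological refinement,
# derived box regions, preprocessing channels, and the external-predictor
# hook (the seam where a trained model, e.g. a DNN, plugs in).

#' Threshold an image into labeled candidate components
#'
#' Voxels with `low <= value <= high`, optionally intersected with a search
#' area, labeled by connected component (full connectivity: 26 in 3D, 8 in
#' 2D). An empty result is not an error; it simply yields no candidates.
#'
#' @param image an [sm_image()].
#' @param low,high intensity window (inclusive; native units, e.g. HU).
#' @param search_area optional logical mask restricting the segmentation.
#' @return integer label array.
#' @export
threshold_segment <- function(image, low, high, search_area = NULL) {
  stopifnot(inherits(image, "sm_image"), low <= high)
  m <- image$data >= low & image$data <= high
  if (!is.null(search_area)) m <- m & search_area
  label_components(m, "full")
}

new_candidate <- function(idx, dim, spacing, point = NULL) {
  structure(list(idx = as.integer(idx), dim = dim, npix = length(idx),
                 volume_mm = length(idx) * prod(spacing), point = point,
                 features = list(), memberships = list(), score = NA_real_),
            class = "candidate_region")
}

#' @export
print.candidate_region <- function(x, ...) {
  cat(sprintf("<candidate_region> %d voxels (%.1f mm^%d)%s, score %s\n",
              x$npix, x$volume_mm, length(x$dim),
              if (!is.null(x$point)) " [landmark]" else "",
              ifelse(is.na(x$score), "unscored", format(x$score))))
  invisible(x)
}

#' Extract candidate regions from a label raster
#'
#' One candidate per connected component with at least `min_size` voxels.
#'
#' @param labels integer label array (0 = background).
#' @param spacing mm per axis.
#' @param min_size minimum component size in voxels (default 1).
#' @return list of `candidate_region` objects, in label order.
#' @export
extract_candidates <- function(labels, spacing, min_size = 1) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L) return(list())
  lab <- labels[idx]
  split_idx <- split(idx, lab)
  split_idx <- unname(split_idx[lengths(split_idx) >= min_size])
  lapply(split_idx, function(ix) new_candidate(ix, dim(labels), spacing))
}

#' Morphological refinement of a region mask
#'
#' Applies hole filling and/or spacing-aware opening/closing in the given
#' order. Opening never adds voxels; closing and hole filling never remove
#' them.
#'
#' @param mask logical array.
#' @param ops list of operations: each `list(op = "fill_holes")` or
#'   `list(op = "open"|"close", radius = <mm>)`.
#' @param spacing mm per axis.
#' @return refined logical array.
#' @export
refine_region <- function(mask, ops, spacing) {
  extent <- dim(mask) * spacing
  for (o in ops) {
    if (o$op %in% c("open", "close")) {
      if (is.null(o$radius) || o$radius < 0)
        stop("morphological op needs a non-negative radius")
      if (o$radius > min(extent))
        stop("structuring radius ", o$radius,
             " mm exceeds the image extent")
    }
    mask <- switch(o$op,
                   fill_holes = fill_holes(mask),
                   open = open_mask(mask, o$radius, spacing),
                   close = close_mask(mask, o$radius, spacing),
                   stop("unknown refinement op: ", o$op))
  }
  mask
}

#' Axis-aligned box derived from a recognized reference
#'
#' The box is centered laterally on the reference centroid, spans the stated
#' in-plane size, and covers the slab `offset_range` mm above (or below) the
#' reference's center slice along the vertical axis.
#'
#' @param center_mm reference centroid, mm (length = image dims).
#' @param in_plane `c(width, height)` mm (in 2D only the width is used).
#' @param offset_range `c(d_low, d_high)` mm from the reference center slice.
#' @param direction `"above"` or `"below"`.
#' @param image the [sm_image()] supplying shape/spacing/orientation.
#' @return logical mask.
#' @export
derive_box <- function(center_mm, in_plane, offset_range, direction, image) {
  direction <- match.arg(direction, c("above", "below"))
  ax <- axis_info(image)
  d <- dim(image$data)
  sp <- image$spacing
  sign <- if (direction == "above") ax$above_sign else -ax$above_sign
  vlo <- center_mm[ax$vertical] + sort(sign * offset_range)[1L]
  vhi <- center_mm[ax$vertical] + sort(sign * offset_range)[2L]
  within <- lapply(seq_along(d), function(k) {
    xs <- coord_axis(d[k], sp[k])
    if (k == ax$vertical) return(xs >= vlo & xs <= vhi)
    half <- in_plane[min(k, length(in_plane))] / 2
    abs(xs - center_mm[k]) <= half
  })
  if (length(d) == 2L) outer(within[[1L]], within[[2L]], "&")
  else outer(outer(within[[1L]], within[[2L]], "&"), within[[3L]], "&")
}

## ---- preprocessing ------------------------------------------------------

#' Build preprocessed input channels
#'
#' Each channel is an ordered pipeline of steps from {`biasfield`, `minmax`,
#' `centile_clip`, `clip_histeq`}; normalization statistics are computed over
#' the histogram-source region only (default: the whole image). The
#' bias-field step delegates to a registered hook named `"biasfield"` and is
#' the identity when none is registered.
#'
#' @param image an [sm_image()].
#' @param channels list of channels, each a list of steps
#'   `list(step = <name>, args = <numeric>)`.
#' @param histogram_source optional logical mask supplying the statistics.
#' @return list of [sm_image()] channels (1--3), values in `[0, 1]` after a
#'   `minmax`/`clip_histeq` step.
#' @export
preprocess_channels <- function(image, channels, histogram_source = NULL) {
  if (length(channels) < 1L || length(channels) > 3L)
    stop("between 1 and 3 preprocessing channels are supported")
  src <- histogram_source
  lapply(channels, function(steps) {
    x <- image$data
    for (s in steps) {
      region <- if (is.null(src)) x else x[src]
      x <- switch(s$step,
        biasfield = {
          hook <- get_predictor("biasfield", optional = TRUE)
          if (is.null(hook)) x else hook(sm_image(x, image$spacing))$data
        },
        minmax = {
          r <- range(region)
          if (diff(r) == 0) array(0, dim = dim(x))
          else pmin(pmax((x - r[1L]) / diff(r), 0), 1)
        },
        centile_clip = {
          p <- if (length(s$args) >= 2L) s$args[1:2] else c(2, 98)
          q <- stats::quantile(region, p / 100, names = FALSE)
          pmin(pmax(x, q[1L]), q[2L])
        },
        clip_histeq = {
          p <- if (length(s$args) >= 2L) s$args[1:2] else c(2, 98)
          q <- stats::quantile(region, p / 100, names = FALSE)
          xc <- pmin(pmax(x, q[1L]), q[2L])
          rc <- pmin(pmax(region, q[1L]), q[2L])
          e <- stats::ecdf(rc)
          array(e(xc), dim = dim(x))
        },
        stop("unknown preprocessing step: ", s$step))
      dim(x) <- dim(image$data)
    }
    sm_image(x, image$spacing, image$orientation)
  })
}

## ---- external predictor hooks -------------------------------------------

the_hooks <- new.env(parent = emptyenv())

#' Register / fetch an external predictor hook
#'
#' Hooks are named callables taking an [sm_image()] (or a list of channel
#' images) and returning a logical mask or label array of identical spatial
#' shape. They are the integration point for trained segmenters; a node
#' whose hook is absent at run time is simply `not_found` and dependents
#' still run.
#'
#' @param name hook name (as referenced from `ExternalPredictor` attributes).
#' @param fun the callable, or `NULL` to unregister.
#' @export
register_predictor <- function(name, fun) {
  if (is.null(fun)) {
    if (exists(name, envir = the_hooks)) rm(list = name, envir = the_hooks)
  } else {
    stopifnot(is.function(fun))
    assign(name, fun, envir = the_hooks)
  }
  invisible(name)
}

#' @rdname register_predictor
#' @param optional if `TRUE`, return `NULL` for an unregistered name instead
#'   of erroring.
#' @export
get_predictor <- function(name, optional = FALSE) {
  if (exists(name, envir = the_hooks)) get(name, envir = the_hooks)
  else if (optional) NULL
  else stop("no predictor hook registered under name '", name, "'")
}

#' Run an external predictor hook
#'
#' @param image an [sm_image()] or list of channel images.
#' @param hook a callable (see [register_predictor()]).
#' @return integer label array (hook output relabeled by connected
#'   component, exactly like threshold output).
#' @export
external_predict <- function(image, hook) {
  out <- hook(image)
  ref <- if (inherits(image, "sm_image")) image else image[[1L]]
  if (is.null(dim(out)) || !identical(dim(out), dim(ref$data)))
    stop("predictor hook returned shape ",
         paste(dim(out), collapse = "x"), " but the image is ",
         paste(dim(ref$data), collapse = "x"))
  label_components(out > 0, "full")
}
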