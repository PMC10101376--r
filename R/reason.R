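# Machine-reasoning primitives: spatial search-area inference, candidate
# feature computation, fuzzy scoring, best-candidate selection with
# rejection, decision rules and cross-estimate consistency checks.

# mask of one axis-aligned physical band
axis_band_mask <- function(image, axis, lo, hi) {
  d <- dim(image$data)
  within <- lapply(seq_along(d), function(k) {
    xs <- coord_axis(d[k], image$spacing[k])
    if (k == axis) xs >= lo & xs <= hi else rep(TRUE, d[k])
  })
  if (length(d) == 2L) outer(within[[1L]], within[[2L]], "&")
  else outer(outer(within[[1L]], within[[2L]], "&"), within[[3L]], "&")
}

se_selected_idx <- function(se) if (is.null(se$selected)) integer(0) else se$selected$idx

se_candidate_union_idx <- function(se) {
  if (length(se$candidates) == 0L) return(integer(0))
  unique(unlist(lapply(se$candidates, `[[`, "idx")))
}

se_ref_position <- function(se, image) {
  if (!is.null(se$selected$point)) return(se$selected$point)
  centroid_mm(se_selected_idx(se), dim(image$data), image$spacing)
}

ref_is_recognized <- function(bb, ref) {
  !is.null(bb$elements[[ref]]) && bb$elements[[ref]]$status == "recognized"
}

#' Derive the spatial search area for a Solution Element
#'
#' Intersects the admissible bands implied by the element's spatial
#' relations to already-recognized references, each widened by the
#' element's soft-shoulder margin (relative shoulder `shoulder`, so a
#' "50--100 mm" relation with shoulder 0.2 admits 40--110 mm). Relations
#' whose reference is not recognized contribute nothing; an element without
#' usable relations searches the whole image. An empty intersection is a
#' legal (empty) search area.
#'
#' @param se a Solution Element of a [build_blackboard()] blackboard.
#' @param bb the blackboard.
#' @return logical mask over the image.
#' @export
derive_search_area <- function(se, bb) {
  image <- bb$image
  ax <- axis_info(image)
  mask <- array(TRUE, dim = dim(image$data))
  s <- se$shoulder
  for (rel in se$relations) {
    if (!ref_is_recognized(bb, rel$ref)) next
    refpos <- se_ref_position(bb$elements[[rel$ref]], image)
    band <- switch(rel$kind,
      LeftOf = , RightOf = {
        sgn <- if (rel$kind == "LeftOf") ax$left_sign else -ax$left_sign
        w <- s * diff(rel$range)
        b <- sort(refpos[ax$lateral] + sgn * (rel$range + c(-w, w)))
        axis_band_mask(image, ax$lateral, b[1L], b[2L])
      },
      Above = , Below = {
        sgn <- if (rel$kind == "Above") ax$above_sign else -ax$above_sign
        w <- s * diff(rel$range)
        b <- sort(refpos[ax$vertical] + sgn * (rel$range + c(-w, w)))
        axis_band_mask(image, ax$vertical, b[1L], b[2L])
      },
      SameLevelAs = {
        tol <- rel$range[1L] * (1 + s)
        axis_band_mask(image, ax$vertical, refpos[ax$vertical] - tol,
                       refpos[ax$vertical] + tol)
      },
      InsideOf = mask_from_idx(se_selected_idx(bb$elements[[rel$ref]]),
                               dim(image$data)),
      NULL)
    if (!is.null(band)) mask <- mask & band
  }
  mask
}

#' Compute feature values for a candidate region
#'
#' Unary features: size (`volume_mm3` in 3D / `area_mm2` in 2D), mean
#' per-slice cross-sectional area (`csa_mm2`), centroid (mm) and mean
#' intensity. Relational features (per expectation): signed lateral /
#' vertical centroid offsets to the reference in mm, absolute craniocaudal
#' offset, and overlap fractions with reference regions. Features of
#' expectations whose reference is not recognized are `NA`
#' (non-informative).
#'
#' @param cand a `candidate_region`.
#' @param se the owning Solution Element.
#' @param bb the blackboard.
#' @return the candidate with its `features` list populated.
#' @export
compute_features <- function(cand, se, bb) {
  image <- bb$image
  d <- dim(image$data)
  sp <- image$spacing
  ax <- axis_info(image)
  f <- list()
  ctr <- if (!is.null(cand$point)) cand$point else centroid_mm(cand$idx, d, sp)
  if (length(d) == 3L) {
    f$volume_mm3 <- cand$npix * prod(sp)
    z <- arrayInd(cand$idx, d)[, 3L]
    f$csa_mm2 <- mean(tabulate(z, nbins = d[3L])[unique(z)]) * sp[1L] * sp[2L]
  } else {
    f$area_mm2 <- cand$npix * prod(sp)
    f$csa_mm2 <- f$area_mm2
  }
  f$mean_intensity <- mean(image$data[cand$idx])
  f$centroid <- ctr
  for (e in se$expectations) {
    if (e$kind != "relational") next
    refse <- bb$elements[[e$ref]]
    if (!ref_is_recognized(bb, e$ref)) { f[[e$feature]] <- NA_real_; next }
    f[[e$feature]] <- switch(e$relation,
      LeftOf = (ctr[ax$lateral] - se_ref_position(refse, image)[ax$lateral]) *
        ax$left_sign,
      RightOf = -(ctr[ax$lateral] - se_ref_position(refse, image)[ax$lateral]) *
        ax$left_sign,
      Above = (ctr[ax$vertical] - se_ref_position(refse, image)[ax$vertical]) *
        ax$above_sign,
      Below = -(ctr[ax$vertical] - se_ref_position(refse, image)[ax$vertical]) *
        ax$above_sign,
      SameLevelAs = abs(ctr[ax$vertical] -
                          se_ref_position(refse, image)[ax$vertical]),
      PartOf = {
        ref_idx <- se_candidate_union_idx(refse)
        length(intersect(cand$idx, ref_idx)) / cand$npix
      },
      NotPartOf = , InsideOf = {
        length(intersect(cand$idx, se_selected_idx(refse))) / cand$npix
      },
      NA_real_)
  }
  cand$features <- f
  cand
}

#' Score a candidate against an element's expectations
#'
#' Per-expectation membership comes from the fuzzy function evaluated at the
#' candidate's feature value (overlap expectations use the overlap fraction
#' directly; `NotPartOf` contributes `1 - overlap`). Non-informative
#' expectations (unresolved reference) contribute 1. The aggregate score is
#' the product of memberships.
#'
#' @param cand a `candidate_region` with features computed.
#' @param se the owning Solution Element.
#' @return the candidate with `memberships` and `score` set.
#' @export
score_candidate <- function(cand, se) {
  mem <- list()
  for (e in se$expectations) {
    if (!e$kind %in% c("unary", "relational")) next
    v <- cand$features[[e$feature]]
    mem[[e$feature]] <-
      if (is.null(v) || is.na(v)) 1
      else if (!is.null(e$fuzzy)) eval_fuzzy(e$fuzzy, v)
      else if (identical(e$relation, "NotPartOf")) 1 - v
      else if (e$relation %in% c("PartOf", "InsideOf")) v
      else 1
  }
  cand$memberships <- mem
  cand$score <- if (length(mem) == 0L) 1 else prod(unlist(mem))
  cand
}

#' Select the best-scoring candidate for an element
#'
#' Argmax of the aggregate score when it exceeds the element's acceptance
#' threshold (default 0, i.e. any strictly positive score); ties broken by
#' larger volume, then first-found. With no acceptable candidate the element
#' is `not_found` and outputs nothing.
#'
#' @param se a Solution Element with scored candidates.
#' @return the updated element (status `recognized` or `not_found`).
#' @export
select_best <- function(se) {
  scores <- vapply(se$candidates, `[[`, numeric(1), "score")
  if (length(scores) == 0L || max(scores) <= se$accept_threshold) {
    se$status <- "not_found"
    se["selected"] <- list(NULL)  # keep the slot: `$selected` stays NULL
    se$score <- NA_real_
    return(se)
  }
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    sizes <- vapply(se$candidates[best], `[[`, numeric(1), "npix")
    best <- best[sizes == max(sizes)]
  }
  se$selected_index <- best[1L]
  se$selected <- se$candidates[[best[1L]]]
  se$score <- se$selected$score
  se$status <- "recognized"
  se
}

## ---- decisions ----------------------------------------------------------

point_to_idx <- function(point, dim, spacing) {
  ix <- pmin(pmax(round(point / spacing) + 1, 1), dim)
  ixm <- matrix(as.integer(ix), nrow = 1L)
  mult <- cumprod(c(1, dim[-length(dim)]))
  as.integer(1 + sum((ixm - 1L) * mult))
}

#' Evaluate a decision rule on the blackboard
#'
#' Rule kinds: `inside_zone` (a landmark/tip must fall inside a zone
#' region), `path_within` (a fraction of a path's voxels must lie inside a
#' reference region), `conjunction` (logical AND over operand decisions).
#' Any operand that is `not_found` or `unreliable` makes the decision
#' indeterminate (`NA`) rather than failing; the explanation names every
#' operand outcome.
#'
#' @param rule list with `kind`, `operands` (node names) and, for
#'   `path_within`, `threshold` (containment fraction, default 0.9).
#' @param bb the blackboard.
#' @return list with `decision` (`TRUE`/`FALSE`/`NA`) and `explanation`.
#' @export
evaluate_decision <- function(rule, bb) {
  els <- lapply(rule$operands, function(nm) bb$elements[[nm]])
  names(els) <- rule$operands
  bad <- rule$operands[vapply(els, function(e)
    is.null(e) || e$status %in% c("not_found", "unreliable"), logical(1))]
  if (rule$kind != "conjunction" && length(bad) > 0L)
    return(list(decision = NA,
                explanation = paste0("indeterminate: operand(s) ",
                                     paste(bad, collapse = ", "),
                                     " not reliably identified")))
  switch(rule$kind,
    inside_zone = {
      tip <- els[[1L]]; zone <- els[[2L]]
      d <- dim(bb$image$data)
      pt <- se_ref_position(tip, bb$image)
      zmask <- mask_from_idx(se_selected_idx(zone), d)
      inside <- zmask[point_to_idx(pt, d, bb$image$spacing)]
      if (inside)
        return(list(decision = TRUE,
                    explanation = sprintf("%s is inside %s", rule$operands[1L],
                                          rule$operands[2L])))
      ax <- axis_info(bb$image)
      zc <- coords_mm(se_selected_idx(zone), d, bb$image$spacing)[, ax$vertical]
      vt <- pt[ax$vertical] * ax$above_sign
      zlo <- min(zc * ax$above_sign); zhi <- max(zc * ax$above_sign)
      why <- if (vt < zlo) "tip too low" else if (vt > zhi) "tip too high"
             else "tip laterally outside"
      list(decision = FALSE,
           explanation = sprintf("%s is outside %s (%s relative to the zone)",
                                 rule$operands[1L], rule$operands[2L], why))
    },
    path_within = {
      thr <- rule$threshold %||% 0.9
      path <- se_selected_idx(els[[1L]])
      region <- se_selected_idx(els[[2L]])
      frac <- if (length(path) == 0L) 0
              else length(intersect(path, region)) / length(path)
      ok <- frac >= thr
      list(decision = ok,
           explanation = sprintf(
             "%.0f%% of %s lies within %s (threshold %.0f%%): %s",
             100 * frac, rule$operands[1L], rule$operands[2L], 100 * thr,
             if (ok) "contained" else "not contained"))
    },
    conjunction = {
      vals <- lapply(els, function(e) if (is.null(e)) NA else e$decision)
      vals[rule$operands %in% bad] <- NA
      txt <- paste(sprintf("%s=%s", rule$operands,
                           vapply(vals, function(v)
                             if (is.null(v) || is.na(v)) "indeterminate"
                             else if (isTRUE(v)) "met" else "violated",
                             character(1))),
                   collapse = ", ")
      dec <- if (any(vapply(vals, isFALSE, logical(1)))) FALSE
             else if (any(vapply(vals, function(v) is.null(v) || is.na(v),
                                 logical(1)))) NA
             else TRUE
      list(decision = dec, explanation = paste0("criteria: ", txt))
    },
    stop("unknown decision rule kind: ", rule$kind))
}

#' Cross-check two estimates of the same structure
#'
#' Two point or region estimates agree when their (centroid) distance is
#' within `tolerance` mm; the fused estimate is then the point midpoint (or
#' the region intersection, falling back to the centroid midpoint when the
#' intersection is empty). Disagreement, or a missing estimate, yields
#' `consistent = FALSE`: the caller should report that the structure cannot
#' be reliably identified rather than output a guess.
#'
#' @param a,b point coordinates (mm) or logical masks.
#' @param tolerance mm.
#' @param spacing mm per axis (needed when masks are supplied).
#' @return list with `consistent`, `distance` (mm), and `refined` (point or
#'   mask, `NULL` when inconsistent).
#' @export
consistency_check <- function(a, b, tolerance, spacing = NULL) {
  if (is.null(a) || is.null(b))
    return(list(consistent = FALSE, distance = NA_real_, refined = NULL,
                explanation = "an estimate is missing"))
  pos <- function(x) {
    if (is.array(x) || !is.null(dim(x))) centroid_mm(which(x), dim(x), spacing)
    else as.numeric(x)
  }
  pa <- pos(a); pb <- pos(b)
  d <- sqrt(sum((pa - pb)^2))
  if (is.na(d) || d > tolerance)
    return(list(consistent = FALSE, distance = d, refined = NULL,
                explanation = sprintf(
                  "estimates %.1f mm apart exceed the %.1f mm tolerance",
                  d, tolerance)))
  refined <- if (is.array(a) && is.array(b)) {
    ix <- a & b
    if (any(ix)) ix else (pa + pb) / 2
  } else (pa + pb) / 2
  list(consistent = TRUE, distance = d, refined = refined,
       explanation = sprintf("estimates agree (%.1f mm apart)", d))
}
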