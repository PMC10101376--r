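# The blackboard: shared working memory of the multi-agent engine. One
# Solution Element per semantic-network node holds the element's prior
# expectations (translated from KB attributes), its spatial relations and
# segmentation recipe, the candidate regions, the selected result and a
# terminal status. The blackboard is an environment: agents mutate it in
# place and the activation history records every contribution.

SEG_DRIVERS <- c("IntensityRange", "ExternalPredictor", "Box", "BottomOf")
DECISION_ATTRS <- c("InsideZone", "PathWithin", "DecisionAnd")
CONTROL_ATTRS <- c("SearchShoulder", "AcceptThreshold", "MinSize")

# translate one SN node into a pending Solution Element
translate_node <- function(node, net, image) {
  se <- list(node = node$name, kind = "region", expectations = list(),
             relations = list(), seg = NULL, morph_ops = list(),
             preproc = list(), histogram_source = NULL,
             min_size = 1, accept_threshold = 0, shoulder = 0.2,
             search_area = NULL, search_derived = FALSE,
             candidates = list(), candidates_generated = FALSE,
             selected = NULL, selected_index = NA_integer_,
             status = "pending", score = NA_real_,
             decision = NULL, decision_rule = NULL, explanation = NULL)
  add_exp <- function(feature, kind, ref = NA_character_, fuzzy = NULL,
                      relation = NA_character_) {
    se$expectations[[length(se$expectations) + 1L]] <<-
      list(feature = feature, kind = kind, ref = ref, fuzzy = fuzzy,
           relation = relation)
  }
  unary_feature <- c(Area = "area_mm2", Volume = "volume_mm3",
                     CrossSectionalArea = "csa_mm2",
                     MeanIntensity = "mean_intensity")
  for (a in node$attributes) {
    v <- attr_values(a)
    switch(a$name,
      IntensityRange = {
        se$seg <- list(type = "threshold", low = v[[1L]], high = v[[2L]])
      },
      ExternalPredictor = {
        se$seg <- list(type = "hook", hook = v[[1L]])
      },
      Box = {
        se$seg <- list(type = "box", ref = v[[1L]],
                       in_plane = c(v[[2L]], v[[3L]]),
                       offset_range = c(v[[4L]], v[[5L]]),
                       direction = v[[6L]])
        add_exp(paste0("box_ref(", v[[1L]], ")"), "source", ref = v[[1L]])
      },
      BottomOf = {
        se$kind <- "landmark"
        se$seg <- list(type = "bottom", ref = v[[1L]])
        add_exp(paste0("bottom_ref(", v[[1L]], ")"), "source", ref = v[[1L]])
      },
      MinSize = se$min_size <- v[[1L]],
      AcceptThreshold = se$accept_threshold <- v[[1L]],
      SearchShoulder = se$shoulder <- v[[1L]],
      FillHoles = se$morph_ops <- c(se$morph_ops, list(list(op = "fill_holes"))),
      MorphOpen = se$morph_ops <- c(se$morph_ops,
                                    list(list(op = "open", radius = v[[1L]]))),
      MorphClose = se$morph_ops <- c(se$morph_ops,
                                     list(list(op = "close", radius = v[[1L]]))),
      PartOf = {
        add_exp(paste0("overlap(", v[[1L]], ")"), "relational", ref = v[[1L]],
                relation = "PartOf")
        se$partof_ref <- c(se$partof_ref, v[[1L]])
      },
      NotPartOf = add_exp(paste0("non_overlap(", v[[1L]], ")"), "relational",
                          ref = v[[1L]], relation = "NotPartOf"),
      InsideOf = {
        add_exp(paste0("inside(", v[[1L]], ")"), "relational", ref = v[[1L]],
                relation = "InsideOf")
        se$relations[[length(se$relations) + 1L]] <-
          list(kind = "InsideOf", ref = v[[1L]])
      },
      LeftOf = , RightOf = , Above = , Below = {
        rng <- c(v[[2L]], v[[3L]])
        add_exp(sprintf("offset_%s(%s)", tolower(a$name), v[[1L]]),
                "relational", ref = v[[1L]],
                fuzzy = fuzzy_from_range(rng[1L], rng[2L]),
                relation = a$name)
        se$relations[[length(se$relations) + 1L]] <-
          list(kind = a$name, ref = v[[1L]], range = rng)
      },
      SameLevelAs = {
        add_exp(sprintf("level_offset(%s)", v[[1L]]), "relational",
                ref = v[[1L]], fuzzy = fuzzy_within(v[[2L]]),
                relation = "SameLevelAs")
        se$relations[[length(se$relations) + 1L]] <-
          list(kind = "SameLevelAs", ref = v[[1L]], range = v[[2L]])
      },
      Area = , Volume = , CrossSectionalArea = , MeanIntensity =
        add_exp(unary_feature[[a$name]], "unary", fuzzy = attr_fuzzy(a)),
      InsideZone = {
        se$kind <- "decision"
        se$decision_rule <- list(kind = "inside_zone",
                                 operands = c(v[[1L]], v[[2L]]))
        for (r in se$decision_rule$operands)
          add_exp(paste0("operand(", r, ")"), "operand", ref = r)
      },
      PathWithin = {
        se$kind <- "decision"
        se$decision_rule <- list(kind = "path_within",
                                 operands = c(v[[1L]], v[[2L]]),
                                 threshold = if (length(v) >= 3L) v[[3L]])
        for (r in se$decision_rule$operands)
          add_exp(paste0("operand(", r, ")"), "operand", ref = r)
      },
      DecisionAnd = {
        se$kind <- "decision"
        se$decision_rule <- list(kind = "conjunction",
                                 operands = unlist(v))
        for (r in se$decision_rule$operands)
          add_exp(paste0("operand(", r, ")"), "operand", ref = r)
      },
      ConsistentWith = {
        se$kind <- "consistency"
        se$consistency <- list(a = v[[1L]], b = v[[2L]], tolerance = v[[3L]])
        for (r in c(v[[1L]], v[[2L]]))
          add_exp(paste0("operand(", r, ")"), "operand", ref = r)
      },
      HistogramSource = {
        se$histogram_source <- v[[1L]]
        add_exp(paste0("hist_source(", v[[1L]], ")"), "source", ref = v[[1L]])
      },
      PreprocChannel = {
        ch <- as.integer(v[[1L]])
        step <- list(step = v[[2L]],
                     args = if (length(v) > 2L) unlist(v[-(1:2)]))
        if (length(se$preproc) < ch) se$preproc[[ch]] <- list()
        se$preproc[[ch]] <- c(se$preproc[[ch]], list(step))
      },
      NULL)  # learning attributes have no runtime agent
  }
  # a node fed purely by another node's candidates (no intrinsic driver):
  if (is.null(se$seg) && se$kind == "region" && !is.null(se$partof_ref)) {
    se$seg <- if (length(se$morph_ops) > 0L)
      list(type = "refine", ref = se$partof_ref[[1L]])
    else list(type = "partof", ref = se$partof_ref[[1L]])
  }
  se
}

#' Build a blackboard from a network and an image
#'
#' Creates one pending Solution Element per node (the Knowledge Agent's
#' mapping step): attributes are translated into feature expectations with
#' fuzzy priors, spatial relations, segmentation recipes and decision rules.
#'
#' @param net a `semantic_network`.
#' @param image an [sm_image()].
#' @return a `blackboard` (environment).
#' @export
build_blackboard <- function(net, image) {
  stopifnot(inherits(net, "semantic_network"), inherits(image, "sm_image"))
  bb <- new.env(parent = emptyenv())
  bb$net <- net
  bb$image <- image
  bb$node_order <- net$node_order
  bb$elements <- lapply(net$nodes, translate_node, net = net, image = image)
  names(bb$elements) <- net$node_order
  bb$history <- list()
  bb$current <- NULL
  bb$initialized <- TRUE
  class(bb) <- "blackboard"
  bb
}

record_activation <- function(bb, agent, family, score) {
  bb$history[[length(bb$history) + 1L]] <-
    data.frame(step = length(bb$history) + 1L, agent = agent,
               family = family,
               element = bb$current_label %||% NA_character_,
               score = score, stringsAsFactors = FALSE)
  invisible(bb)
}

bb_history <- function(bb) {
  if (length(bb$history) == 0L)
    return(data.frame(step = integer(0), agent = character(0),
                      family = character(0), element = character(0),
                      score = numeric(0)))
  do.call(rbind, bb$history)
}

#' @export
print.blackboard <- function(x, ...) {
  cat("<blackboard>", length(x$elements), "solution elements,",
      length(x$history), "agent activations\n")
  for (nm in x$node_order) {
    se <- x$elements[[nm]]
    extra <- if (se$kind %in% c("decision", "consistency") &&
                 !is.null(se$explanation)) paste0(" - ", se$explanation)
             else if (!is.null(se$selected))
               sprintf(" (%d voxels, score %.3f)", se$selected$npix, se$score)
             else ""
    cat(sprintf("  %-24s %-11s%s\n", nm, se$status, extra))
  }
  invisible(x)
}

#' @export
summary.blackboard <- function(object, ...) {
  summary_report(list(object))
}

#' Tabular report over one or more blackboards
#'
#' One row per case per node: status, aggregate score, decision and
#' explanation, selected-region size and centroid. Deterministic ordering
#' (case order, then node-list order).
#'
#' @param bbs list of `blackboard` objects.
#' @param case_ids optional case labels (default `case_1`, ...).
#' @return data.frame.
#' @export
summary_report <- function(bbs, case_ids = NULL) {
  if (inherits(bbs, "blackboard")) bbs <- list(bbs)
  stopifnot(length(bbs) >= 1L)
  if (is.null(case_ids)) case_ids <- paste0("case_", seq_along(bbs))
  rows <- list()
  for (i in seq_along(bbs)) {
    bb <- bbs[[i]]
    for (nm in bb$node_order) {
      se <- bb$elements[[nm]]
      ctr <- if (!is.null(se$selected))
        paste(sprintf("%.2f", se$selected$features$centroid %||%
                        centroid_mm(se$selected$idx, dim(bb$image$data),
                                    bb$image$spacing)), collapse = ";")
      else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        case = case_ids[i], node = nm, status = se$status,
        score = se$score,
        decision = if (is.null(se$decision)) NA else se$decision,
        explanation = se$explanation %||% NA_character_,
        n_candidates = length(se$candidates),
        selected_voxels = if (is.null(se$selected)) NA_integer_
                          else se$selected$npix,
        centroid_mm = ctr, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- serialization ------------------------------------------------------

serialize_candidate <- function(cand, keep_idx = FALSE) {
  list(npix = cand$npix, volume_mm = cand$volume_mm, point = cand$point,
       features = cand$features, memberships = cand$memberships,
       score = cand$score)
}

#' Write a blackboard to an output directory
#'
#' Emits `blackboard.json` (elements with statuses, scores, features,
#' memberships, decisions and explanations, plus the activation history)
#' and one mask file per recognized element's selected region (NIfTI in 3D,
#' PNG in 2D). `not_found` elements output nothing but keep their status in
#' the index.
#'
#' @param bb a `blackboard`.
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
serialize_blackboard <- function(bb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(bb$image$data)
  nd <- length(d)
  index <- list(dim = d, spacing = bb$image$spacing,
                orientation = bb$image$orientation,
                node_order = bb$node_order, elements = list(),
                history = bb_history(bb))
  for (nm in bb$node_order) {
    se <- bb$elements[[nm]]
    el <- list(node = nm, kind = se$kind, status = se$status,
               score = se$score, decision = se$decision,
               explanation = se$explanation,
               n_candidates = length(se$candidates),
               candidates = lapply(se$candidates, serialize_candidate),
               selected_index = se$selected_index)
    if (!is.null(se$selected) && se$status == "recognized") {
      mf <- paste0(nm, if (nd == 3L) ".nii.gz" else ".png")
      write_mask(mask_from_idx(se$selected$idx, d), bb$image$spacing,
                 file.path(dir, mf))
      el$mask_file <- mf
      el$selected <- serialize_candidate(se$selected)
      el$selected$point <- se$selected$point
    }
    index$elements[[nm]] <- el
  }
  jsonlite::write_json(index, file.path(dir, "blackboard.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Read a serialized blackboard back
#'
#' Reconstructs element statuses, scores, features, decisions and selected
#' masks (voxel-exact); the knowledge network and the input image voxel data
#' are not part of the serialized state.
#'
#' @param dir directory written by [serialize_blackboard()].
#' @return a `blackboard`.
#' @export
deserialize_blackboard <- function(dir) {
  path <- file.path(dir, "blackboard.json")
  if (!file.exists(path)) stop("no blackboard.json in ", dir)
  index <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                              simplifyVector = TRUE, simplifyMatrix = FALSE)
  d <- as.integer(unlist(index$dim))
  sp <- as.numeric(unlist(index$spacing))
  bb <- new.env(parent = emptyenv())
  bb$image <- sm_image(array(0, dim = d), sp, index$orientation)
  bb$node_order <- unlist(index$node_order)
  bb$net <- NULL
  bb$history <- lapply(index$history, function(r)
    data.frame(step = as.integer(r$step), agent = r$agent,
               family = r$family,
               element = r$element %||% NA_character_,
               score = as.numeric(r$score), stringsAsFactors = FALSE))
  bb$current <- NULL
  bb$initialized <- TRUE
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  bb$elements <- lapply(index$elements, function(el) {
    se <- list(node = el$node, kind = el$kind, status = el$status,
               score = as.numeric(el$score %||% NA_real_),
               decision = el$decision,
               explanation = el$explanation,
               candidates = lapply(el$candidates, function(cd) {
                 cd$idx <- integer(0); cd$dim <- d
                 cd$score <- num(cd$score)
                 cd$features <- lapply(cd$features, num)
                 cd$memberships <- lapply(cd$memberships, num)
                 structure(cd, class = "candidate_region")
               }),
               selected = NULL, selected_index = el$selected_index %||% NA,
               expectations = list(), relations = list())
    if (!is.null(el$mask_file)) {
      m <- read_mask(file.path(dir, el$mask_file), sp)
      sel <- new_candidate(which(m), d, sp,
                           point = if (!is.null(el$selected$point))
                             as.numeric(unlist(el$selected$point)))
      sel$features <- lapply(el$selected$features, num)
      sel$memberships <- lapply(el$selected$memberships, num)
      sel$score <- num(el$selected$score)
      se$selected <- sel
    }
    se
  })
  names(bb$elements) <- bb$node_order
  class(bb) <- "blackboard"
  bb
}
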