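# The agent activation loop. At each iteration every registered agent
# computes an activation score from the blackboard contents; the single
# highest-scoring agent activates (ties by priority rank, then agent id) and
# contributes to the solution. The process repeats until all scores are
# zero. Scheduling is opportunistic: the Scheduling Agent always picks the
# pending Solution Element with the highest fraction of computable features,
# so a missing object changes the processing order without hard-coded
# exception rules.

#' Fraction of an element's features that can be computed now
#'
#' An expectation counts as computable when it is unary or when its
#' reference element has reached a terminal status (`recognized`,
#' `not_found` or `unreliable` all count as resolved: an absent object does
#' not block dependents). An element with no expectations is fully
#' computable (1.0).
#'
#' @param se a Solution Element.
#' @param bb the blackboard.
#' @return fraction in `[0, 1]`.
#' @export
computable_fraction <- function(se, bb) {
  exps <- se$expectations
  if (length(exps) == 0L) return(1.0)
  ok <- vapply(exps, function(e) {
    if (is.na(e$ref)) return(TRUE)
    ref <- bb$elements[[e$ref]]
    !is.null(ref) && ref$status != "pending"
  }, logical(1))
  mean(ok)
}

#' Pick the next Solution Element to process
#'
#' The pending element with the highest [computable_fraction()]; ties are
#' broken by node-list order. `NULL` when nothing is pending.
#'
#' @param bb the blackboard.
#' @return a node name or `NULL`.
#' @export
next_solution_element <- function(bb) {
  pending <- bb$node_order[vapply(bb$elements[bb$node_order],
                                  function(se) se$status == "pending",
                                  logical(1))]
  if (length(pending) == 0L) return(NULL)
  fr <- vapply(bb$elements[pending], computable_fraction, numeric(1), bb = bb)
  pending[which.max(fr)]  # which.max takes the first maximum: list order
}

# resolve the hook for a node: run-time `hooks` map (function, or registry
# name) first, then the registry under the KB-declared hook name
resolve_hook <- function(se, hooks) {
  h <- hooks[[se$node]]
  if (is.function(h)) return(h)
  if (is.character(h)) return(get_predictor(h, optional = TRUE))
  get_predictor(se$seg$hook, optional = TRUE)
}

segment_element <- function(se, bb, hooks) {
  image <- bb$image
  d <- dim(image$data)
  sp <- image$spacing
  sa <- se$search_area %||% array(TRUE, dim = d)
  cands <- list()
  ref_se <- function(ref) bb$elements[[ref]]
  type <- se$seg$type %||% "none"
  # mask-producing sources share a pipeline: foreground mask -> morphology
  # (applied before labeling, so e.g. a closing can reconnect a region split
  # by an overlying structure) -> connected components -> candidates
  m <- NULL
  if (type == "threshold") {
    m <- image$data >= se$seg$low & image$data <= se$seg$high & sa
  } else if (type == "hook") {
    hook <- resolve_hook(se, hooks)
    if (!is.null(hook)) {
      input <- image
      if (length(se$preproc) > 0L) {
        src <- NULL
        if (!is.null(se$histogram_source)) {
          hs <- ref_se(se$histogram_source)
          if (is.null(hs$selected))
            stop("histogram source node '", se$histogram_source,
                 "' has no selected region")
          src <- mask_from_idx(se_selected_idx(hs), d)
        }
        input <- preprocess_channels(image, se$preproc, src)
      }
      m <- external_predict(input, hook) > 0L & sa
    }
  } else if (type == "partof") {
    ref <- ref_se(se$seg$ref)
    idx <- se_candidate_union_idx(ref)
    if (length(idx) > 0L) m <- mask_from_idx(idx, d) & sa
  } else if (type == "box") {
    ref <- ref_se(se$seg$ref)
    if (ref$status == "recognized") {
      ctr <- se_ref_position(ref, image)
      m <- derive_box(ctr, se$seg$in_plane, se$seg$offset_range,
                      se$seg$direction, image)
    }
  } else if (type == "refine") {
    ref <- ref_se(se$seg$ref)
    if (ref$status == "recognized") {
      m <- refine_region(mask_from_idx(se_selected_idx(ref), d),
                         se$morph_ops, sp)
    }
  } else if (type == "bottom") {
    ref <- ref_se(se$seg$ref)
    if (ref$status == "recognized") {
      co <- coords_mm(se_selected_idx(ref), d, sp)
      ax <- axis_info(image)
      v <- co[, ax$vertical] * ax$above_sign
      pt <- colMeans(co[v == min(v), , drop = FALSE])
      cands <- list(new_candidate(point_to_idx(pt, d, sp), d, sp, point = pt))
    }
  }
  if (!is.null(m)) {
    if (type != "refine" && length(se$morph_ops) > 0L)
      m <- refine_region(m, se$morph_ops, sp)
    cands <- extract_candidates(label_components(m, "full"), sp, se$min_size)
  }
  se$candidates <- cands
  se$candidates_generated <- TRUE
  se
}

evaluate_element <- function(se, bb) {
  se$candidates <- lapply(se$candidates, function(cd)
    score_candidate(compute_features(cd, se, bb), se))
  select_best(se)
}

decide_element <- function(se, bb) {
  if (se$kind == "consistency") {
    d <- dim(bb$image$data)
    get_est <- function(nm) {
      ref <- bb$elements[[nm]]
      if (ref$status != "recognized" || is.null(ref$selected)) return(NULL)
      if (!is.null(ref$selected$point)) ref$selected$point
      else mask_from_idx(ref$selected$idx, d)
    }
    chk <- consistency_check(get_est(se$consistency$a),
                             get_est(se$consistency$b),
                             se$consistency$tolerance, bb$image$spacing)
    se$explanation <- chk$explanation
    if (chk$consistent) {
      sel <- if (is.array(chk$refined))
        new_candidate(which(chk$refined), d, bb$image$spacing)
      else new_candidate(point_to_idx(chk$refined, d, bb$image$spacing), d,
                         bb$image$spacing, point = chk$refined)
      se$selected <- sel
      se$candidates <- list(sel)
      se$selected_index <- 1L
      se$score <- 1
      se$status <- "recognized"
    } else {
      se$status <- "unreliable"
    }
  } else {
    res <- evaluate_decision(se$decision_rule, bb)
    se$decision <- res$decision
    se$explanation <- res$explanation
    se$status <- "recognized"
  }
  se
}

make_agents <- function(hooks) {
  cur <- function(bb) if (is.null(bb$current)) NULL else bb$elements[[bb$current]]
  list(
    list(id = "knowledge_mapper", family = "knowledge", priority = 1L,
         score = function(bb) if (!isTRUE(bb$mapped)) 1.0 else 0,
         act = function(bb) bb$mapped <- TRUE),
    list(id = "scheduler", family = "scheduling", priority = 2L,
         score = function(bb) {
           if (isTRUE(bb$mapped) && is.null(bb$current) &&
               !is.null(next_solution_element(bb))) 0.9 else 0
         },
         act = function(bb) bb$current <- next_solution_element(bb)),
    list(id = "search_area_reasoner", family = "reasoning", priority = 3L,
         score = function(bb) {
           se <- cur(bb)
           if (!is.null(se) && !se$kind %in% c("decision", "consistency") &&
               !se$search_derived) 0.8 else 0
         },
         act = function(bb) {
           se <- cur(bb)
           se$search_area <- derive_search_area(se, bb)
           se$search_derived <- TRUE
           bb$elements[[bb$current]] <- se
         }),
    list(id = "segmenter", family = "segmentation", priority = 4L,
         score = function(bb) {
           se <- cur(bb)
           if (!is.null(se) && !se$kind %in% c("decision", "consistency") &&
               se$search_derived && !se$candidates_generated) 0.7 else 0
         },
         act = function(bb) {
           bb$elements[[bb$current]] <- segment_element(cur(bb), bb, hooks)
         }),
    list(id = "candidate_evaluator", family = "reasoning", priority = 5L,
         score = function(bb) {
           se <- cur(bb)
           if (!is.null(se) && !se$kind %in% c("decision", "consistency") &&
               se$candidates_generated && se$status == "pending") 0.6 else 0
         },
         act = function(bb) {
           bb$elements[[bb$current]] <- evaluate_element(cur(bb), bb)
           bb$current <- NULL
         }),
    list(id = "decision_reasoner", family = "reasoning", priority = 5L,
         score = function(bb) {
           se <- cur(bb)
           if (!is.null(se) && se$kind %in% c("decision", "consistency") &&
               se$status == "pending") 0.6 else 0
         },
         act = function(bb) {
           bb$elements[[bb$current]] <- decide_element(cur(bb), bb)
           bb$current <- NULL
         }))
}

#' Run the thinking loop: apply a knowledge base to an image
#'
#' Builds a blackboard from the (optionally chromosome-specified) network,
#' then iterates the activation loop until every agent's activation score is
#' zero. Exactly one agent activates per iteration; every activation is
#' recorded in the blackboard history. The run is deterministic for
#' identical inputs.
#'
#' @param net a `semantic_network`.
#' @param image an [sm_image()].
#' @param chromosome optional 0/1 string specifying all tunable parameters.
#' @param hooks named list mapping node names to predictor callables (or
#'   registered hook names); nodes with an `ExternalPredictor` attribute and
#'   no available hook end `not_found`.
#' @param max_activations safety cap, default `100 * number of nodes`.
#' @return the completed `blackboard` (every element in a terminal status).
#' @export
run_think <- function(net, image, chromosome = NULL, hooks = list(),
                      max_activations = NULL) {
  if (!is.null(chromosome))
    net <- apply_chromosome(net, chromosome)$network
  bb <- build_blackboard(net, image)
  bb$mapped <- FALSE
  agents <- make_agents(hooks)
  if (is.null(max_activations))
    max_activations <- 100L * (length(net$nodes) + 1L)
  for (iter in seq_len(max_activations + 1L)) {
    scores <- vapply(agents, function(a) a$score(bb), numeric(1))
    if (all(scores <= 0)) {
      stuck <- bb$node_order[vapply(bb$elements[bb$node_order],
                                    function(se) se$status == "pending",
                                    logical(1))]
      if (length(stuck) > 0L)
        stop("thinking loop stalled with pending element(s): ",
             paste(stuck, collapse = ", "))
      return(bb)
    }
    if (iter > max_activations)
      stop("thinking loop exceeded ", max_activations,
           " activations; stuck element: ", bb$current %||% "<none>")
    best <- which(scores == max(scores))
    if (length(best) > 1L) {
      pr <- vapply(agents[best], `[[`, integer(1), "priority")
      best <- best[order(pr, vapply(agents[best], `[[`, character(1),
                                    "id"))][1L]
    }
    a <- agents[[best]]
    el_before <- bb$current
    a$act(bb)
    bb$current_label <- bb$current %||% el_before
    record_activation(bb, a$id, a$family, max(scores))
  }
  bb
}
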