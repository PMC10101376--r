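# Knowledge-network learning and optimization: a seeded genetic algorithm
# over the chromosome of tunable knowledge-base parameters. The optimizer
# proposes chromosomes; the distributor evaluates (chromosome, case) jobs --
# sequentially by default, order-independently by contract -- and the
# weighted per-node performance over the tuning set is the fitness.

#' A tuning case: an image with reference results
#'
#' @param image an [sm_image()] (or a path readable by [read_image()]).
#' @param references named list mapping node names to a reference: a logical
#'   mask (segmentation nodes) or a numeric point in mm (landmark nodes).
#' @return list of class `tuning_case`.
#' @export
tuning_case <- function(image, references) {
  if (is.character(image)) image <- read_image(image)
  stopifnot(inherits(image, "sm_image"), length(references) >= 1L,
            !is.null(names(references)))
  structure(list(image = image, references = references),
            class = "tuning_case")
}

#' Fitness specification
#'
#' @param metrics named character vector mapping node names to a metric in
#'   `dice`, `sensitivity`, `specificity`, `precision`, `recall`,
#'   `landmark`.
#' @param weights optional non-negative per-node weights (default equal);
#'   normalized to sum to 1.
#' @return list of class `fitness_spec`.
#' @export
fitness_spec <- function(metrics, weights = NULL) {
  known <- c("dice", "sensitivity", "specificity", "precision", "recall",
             "landmark")
  stopifnot(all(metrics %in% known), !is.null(names(metrics)))
  if (is.null(weights)) weights <- rep(1, length(metrics))
  if (is.null(names(weights))) names(weights) <- names(metrics)
  stopifnot(all(weights >= 0), sum(weights) > 0)
  structure(list(metrics = metrics,
                 weights = weights[names(metrics)] / sum(weights)),
            class = "fitness_spec")
}

metric_fun <- function(name) {
  switch(name,
         dice = dice_coefficient,
         sensitivity = , recall = sensitivity_metric,
         specificity = specificity_metric,
         precision = precision_metric,
         stop("unknown metric: ", name))
}

#' Evaluate the fitness of a chromosome over a tuning set
#'
#' Runs the thinking loop on every case with the chromosome-specified
#' network, compares each weighted node's selected result against the
#' case's reference, and averages the weighted node performance over cases.
#' A `not_found`/`unreliable` node scores 0 for that case; a failed run
#' scores 0 for the whole case (optimization must tolerate degenerate
#' parameter sets).
#'
#' @param chromosome 0/1 string.
#' @param net a `semantic_network`.
#' @param cases list of [tuning_case()] objects.
#' @param spec a [fitness_spec()].
#' @param hooks optional predictor hooks passed to [run_think()].
#' @return fitness in `[0, 1]`.
#' @export
evaluate_fitness <- function(chromosome, net, cases, spec, hooks = list()) {
  per_case <- vapply(cases, function(cs) {
    for (nm in names(spec$metrics))
      if (is.null(cs$references[[nm]]))
        stop("tuning case lacks a reference for node '", nm, "'")
    bb <- tryCatch(run_think(net, cs$image, chromosome = chromosome,
                             hooks = hooks),
                   error = function(e) NULL)
    if (is.null(bb)) return(0)
    tot <- 0
    for (nm in names(spec$metrics)) {
      se <- bb$elements[[nm]]
      ref <- cs$references[[nm]]
      val <- if (is.null(se) || se$status != "recognized" ||
                 is.null(se$selected)) 0
      else if (spec$metrics[[nm]] == "landmark") {
        pred <- se$selected$point %||%
          centroid_mm(se$selected$idx, dim(cs$image$data), cs$image$spacing)
        landmark_fitness(pred, ref)
      } else {
        metric_fun(spec$metrics[[nm]])(
          mask_from_idx(se$selected$idx, dim(cs$image$data)), ref)
      }
      tot <- tot + spec$weights[[nm]] * val
    }
    tot
  }, numeric(1))
  mean(per_case)
}

#' Genetic-algorithm configuration
#'
#' Defaults: population 30, 10 generations, elitism 2, tournament selection
#' (size 2), single-point crossover with probability 0.8, per-bit mutation
#' probability `1 / chromosome length`.
#'
#' @param population_size,generations,elitism_count,tournament_size counts.
#' @param crossover_prob,mutation_prob_per_bit probabilities (`NULL`
#'   mutation = `1/length`).
#' @param seed integer seed; fixes the whole trajectory.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(population_size = 30L, generations = 10L,
                      elitism_count = 2L, tournament_size = 2L,
                      crossover_prob = 0.8, mutation_prob_per_bit = NULL,
                      seed = 1L) {
  stopifnot(population_size > 0, generations > 0,
            elitism_count < population_size)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 crossover_prob = crossover_prob,
                 mutation_prob_per_bit = mutation_prob_per_bit,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Distribute evaluation jobs over a backend
#'
#' The sequential reference backend is always available; any backend must
#' yield results keyed by job id so aggregation is independent of
#' completion order. A failing job is retried once and then recorded as
#' fitness 0 with a diagnostic.
#'
#' @param jobs named list of zero-argument closures.
#' @param backend function `(jobs) -> named list of results`; default
#'   [backend_sequential()].
#' @return named list of results in the jobs' key order.
#' @export
distribute <- function(jobs, backend = backend_sequential) {
  if (length(jobs) == 0L) return(list())
  if (is.null(names(jobs))) names(jobs) <- as.character(seq_along(jobs))
  res <- backend(jobs)
  res[names(jobs)]
}

#' @rdname distribute
#' @export
backend_sequential <- function(jobs) {
  lapply(jobs, function(j) {
    r <- tryCatch(j(), error = function(e) tryCatch(j(), error = function(e2) {
      warning("job failed twice (", conditionMessage(e2),
              "); recording fitness 0", call. = FALSE)
      0
    }))
    r
  })
}

#' @rdname distribute
#' @param cores worker count for the local process-pool backend.
#' @export
backend_multicore <- function(cores = 2L) {
  force(cores)
  function(jobs) {
    res <- parallel::mclapply(jobs, function(j)
      tryCatch(j(), error = function(e) tryCatch(j(), error = function(e2) 0)),
      mc.cores = cores)
    res
  }
}

mutate_bits <- function(bits, p) {
  v <- strsplit(bits, "")[[1L]]
  flip <- stats::runif(length(v)) < p
  v[flip] <- ifelse(v[flip] == "0", "1", "0")
  paste(v, collapse = "")
}

crossover_single_point <- function(a, b) {
  n <- nchar(a)
  if (n < 2L) return(c(a, b))
  cut <- sample.int(n - 1L, 1L)
  c(paste0(substr(a, 1L, cut), substr(b, cut + 1L, n)),
    paste0(substr(b, 1L, cut), substr(a, cut + 1L, n)))
}

#' Co-optimize the tunable knowledge-base parameters
#'
#' Seeded genetic algorithm: random initial population, per-generation
#' evaluation of every chromosome through the distributor, elitism, binary
#' tournament selection, single-point crossover and per-bit mutation.
#' Fitness evaluations are memoized per chromosome (the fitness is
#' deterministic), and the best-so-far fitness is non-decreasing by
#' construction.
#'
#' @param net a `semantic_network` with at least one tunable parameter.
#' @param cases list of [tuning_case()] objects.
#' @param config a [ga_config()].
#' @param spec a [fitness_spec()].
#' @param backend distribution backend, default [backend_sequential()].
#' @param hooks optional predictor hooks.
#' @param baseline optional reference fitness (e.g. hand-tuned performance)
#'   annotated in the status summary.
#' @param initial_population optional explicit start population
#'   (`population_size` bit strings) replacing the random initialization.
#' @return object of class `ga_fit`: best chromosome and fitness, the
#'   specified network, decoded best parameters and the per-generation
#'   fitness trajectory.
#' @export
ga_optimize <- function(net, cases, config = ga_config(), spec,
                        backend = backend_sequential, hooks = list(),
                        baseline = NULL, initial_population = NULL) {
  tun <- list_tunable_parameters(net)
  if (nrow(tun) == 0L)
    stop("nothing to optimize: the network has no tunable parameters")
  span <- attr(tun, "span")
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  fit_of <- function(bits_vec) {
    todo <- unique(bits_vec[!vapply(bits_vec, function(b)
      exists(b, envir = cache), logical(1))])
    if (length(todo) > 0L) {
      jobs <- lapply(todo, function(b) {
        force(b)
        function() evaluate_fitness(b, net, cases, spec, hooks)
      })
      names(jobs) <- todo
      res <- distribute(jobs, backend)
      for (b in todo) assign(b, as.numeric(res[[b]]), envir = cache)
      n_evals <<- n_evals + length(todo)
    }
    unname(vapply(bits_vec, function(b) get(b, envir = cache), numeric(1)))
  }
  traj <- list()
  with_seed(config$seed, {
    pop <- if (!is.null(initial_population)) {
      stopifnot(length(initial_population) == config$population_size)
      initial_population
    } else vapply(seq_len(config$population_size), function(i)
      paste(sample(c("0", "1"), span, replace = TRUE), collapse = ""),
      character(1))
    pmut <- config$mutation_prob_per_bit %||% (1 / span)
    best_bits <- NULL
    best_fit <- -Inf
    for (gen in seq_len(config$generations)) {
      fits <- fit_of(pop)
      gi <- which.max(fits)
      if (fits[gi] > best_fit) {
        best_fit <- fits[gi]
        best_bits <- pop[gi]
      }
      traj[[gen]] <- data.frame(generation = gen, fit_min = min(fits),
                                fit_median = stats::median(fits),
                                fit_max = max(fits), best_so_far = best_fit,
                                best_bits = best_bits,
                                stringsAsFactors = FALSE)
      if (gen == config$generations) break
      ord <- order(fits, decreasing = TRUE)
      elites <- pop[ord[seq_len(config$elitism_count)]]
      tournament <- function() {
        k <- sample.int(length(pop), config$tournament_size, replace = TRUE)
        pop[k[which.max(fits[k])]]
      }
      children <- character(0)
      while (length(children) < config$population_size -
             config$elitism_count) {
        pa <- tournament(); pb <- tournament()
        pair <- if (stats::runif(1) < config$crossover_prob)
          crossover_single_point(pa, pb) else c(pa, pb)
        children <- c(children, vapply(pair, mutate_bits, character(1),
                                       p = pmut))
      }
      pop <- c(elites,
               children[seq_len(config$population_size -
                                  config$elitism_count)])
    }
  })
  trajectory <- do.call(rbind, traj)
  rownames(trajectory) <- NULL
  specified <- apply_chromosome(net, best_bits)
  structure(list(best_chromosome = best_bits, best_fitness = best_fit,
                 network = specified$network,
                 parameters = specified$parameters,
                 trajectory = trajectory, config = config,
                 baseline = baseline, n_evaluations = n_evals),
            class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat("<ga_fit> genetic optimization of",
      nrow(x$parameters), "tunable parameter(s)\n")
  cat(sprintf("  best fitness %.4f after %d generation(s) (%d evaluations)\n",
              x$best_fitness, nrow(x$trajectory), x$n_evaluations))
  cat("  best chromosome:", x$best_chromosome, "\n")
  invisible(x)
}

#' @export
summary.ga_fit <- function(object, ...) {
  cat("Decoded best parameter set:\n")
  print(object$parameters[, c("node", "attribute", "param_index", "lower",
                              "upper", "value")])
  cat("\nFitness trajectory:\n")
  print(object$trajectory[, c("generation", "fit_min", "fit_median",
                              "fit_max", "best_so_far")])
  invisible(object)
}

#' @export
plot.ga_fit <- function(x, ...) {
  tr <- x$trajectory
  graphics::plot(tr$generation, tr$fit_max, type = "b", pch = 19,
                 ylim = range(c(tr$fit_min, tr$fit_max, x$baseline)),
                 xlab = "generation", ylab = "fitness", ...)
  graphics::lines(tr$generation, tr$fit_median, lty = 2)
  graphics::lines(tr$generation, tr$fit_min, lty = 3)
  graphics::lines(tr$generation, tr$best_so_far, col = "forestgreen")
  if (!is.null(x$baseline))
    graphics::abline(h = x$baseline, col = "red", lty = 2)
  graphics::legend("bottomright",
                   c("max", "median", "min", "best so far"),
                   lty = c(1, 2, 3, 1),
                   col = c("black", "black", "black", "forestgreen"),
                   bty = "n")
  invisible(x)
}

#' Per-generation status summary of a GA run
#'
#' @param fit a `ga_fit` (or its trajectory data.frame).
#' @param baseline optional baseline fitness; the summary marks the first
#'   generation whose best-so-far fitness exceeds it.
#' @param csv_path optional path; when given the table is written as CSV.
#' @return the summary data.frame (invisibly when written to disk).
#' @export
status_summary <- function(fit, baseline = NULL, csv_path = NULL) {
  tr <- if (inherits(fit, "ga_fit")) fit$trajectory else fit
  if (is.null(baseline) && inherits(fit, "ga_fit"))
    baseline <- fit$baseline
  out <- tr[, c("generation", "fit_min", "fit_median", "fit_max",
                "best_so_far", "best_bits")]
  if (!is.null(baseline)) {
    out$exceeds_baseline <- out$best_so_far > baseline
    first <- which(out$exceeds_baseline)[1L]
    attr(out, "first_exceeding_generation") <-
      if (is.na(first)) NA_integer_ else out$generation[first]
  }
  if (!is.null(csv_path)) {
    utils::write.csv(out, csv_path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
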