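test_that("overlap metrics follow their definitions", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE     # 100 voxels
  b <- matrix(FALSE, 20, 20); b[6:10, 1:20] <- TRUE     # 100 voxels, 50 shared
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 0.5)   # 2*50 / (100+100)
  expect_equal(sensitivity_metric(a, b), 0.5)
  expect_equal(precision_metric(a, b), 0.5)
  expect_equal(specificity_metric(a, b), 250 / 300)
  expect_equal(landmark_fitness(c(0, 0), c(0, 0)), 1)
  expect_equal(landmark_fitness(c(0, 0), c(10, 0)), 0.5)
})

test_that("fitness is the weighted node average over cases", {
  img <- sm_image(array(c(rep(0, 500), rep(50, 524)), dim = c(8, 8, 16)),
                  c(1, 1, 1))
  net <- make_kb(list(blob = "IntensityRange 40 60",
                      ghost = "IntensityRange 5000 6000"))
  ref <- img$data > 40
  cs <- tuning_case(img, list(blob = ref, ghost = ref))
  # blob matches exactly (dice 1); ghost is not_found (scores 0)
  spec <- fitness_spec(c(blob = "dice", ghost = "dice"),
                       weights = c(blob = 3, ghost = 1))
  expect_equal(evaluate_fitness("", net, list(cs), spec), 0.75)
  spec2 <- fitness_spec(c(blob = "dice"))
  expect_equal(evaluate_fitness("", net, list(cs), spec2), 1)
  expect_error(
    evaluate_fitness("", net, list(tuning_case(img, list(blob = ref))),
                     spec),
    "lacks a reference for node 'ghost'")
})

test_that("a 1-bit space is searched exhaustively in two generations", {
  net <- make_kb(list(blob = "IntensityRange 40 {0, 0, 40, 500} 60"))
  img <- sm_image(array(c(rep(0, 500), rep(50, 524)), dim = c(8, 8, 16)),
                  c(1, 1, 1))
  cs <- tuning_case(img, list(blob = img$data > 40))
  spec <- fitness_spec(c(blob = "dice"))
  fit <- ga_optimize(net, cs_list <- list(cs),
                     ga_config(population_size = 4, generations = 2,
                               elitism_count = 1, seed = 3), spec)
  expect_equal(fit$best_chromosome, "0")  # low=40 keeps the blob; 500 loses it
  expect_equal(fit$best_fitness, 1)
  expect_equal(fit$parameters$value, 40)
})

test_that("with variation off, the GA equals exhaustive search over a 2-bit space", {
  net <- ga_recovery_net()
  # narrow the gene to 2 bits for the exhaustive comparison
  net$nodes$kidney$attributes[[1L]]$params[[1L]]$enc <-
    list(bit_start = 0L, bit_end = 1L, lower = 200, upper = 500)
  case <- ga_recovery_case(17)
  spec <- fitness_spec(c(kidney = "dice"))
  all4 <- c("00", "01", "10", "11")
  exhaustive <- vapply(all4, evaluate_fitness, numeric(1), net = net,
                       cases = list(case), spec = spec)
  fit <- ga_optimize(net, list(case),
                     ga_config(population_size = 4, generations = 3,
                               elitism_count = 1, crossover_prob = 0,
                               mutation_prob_per_bit = 0, seed = 2),
                     spec, initial_population = all4)
  expect_equal(fit$best_fitness, max(exhaustive))
  expect_equal(fit$best_chromosome, names(which.max(exhaustive)))
})

test_that("GA runs are seed-reproducible with non-decreasing best fitness", {
  net <- ga_recovery_net()
  case <- ga_recovery_case(23)
  spec <- fitness_spec(c(kidney = "dice"))
  cfg <- ga_config(population_size = 10, generations = 5, seed = 11)
  f1 <- ga_optimize(net, list(case), cfg, spec)
  f2 <- ga_optimize(net, list(case), cfg, spec)
  expect_identical(f1$trajectory, f2$trajectory)
  expect_true(all(diff(f1$trajectory$best_so_far) >= 0))
  f3 <- ga_optimize(net, list(case), ga_config(population_size = 10,
                                               generations = 5, seed = 12),
                    spec)
  expect_false(identical(f1$trajectory$fit_median, f3$trajectory$fit_median))
})

test_that("the distributor is order-invariant and survives failing jobs", {
  expect_identical(distribute(list()), list())
  jobs <- lapply(1:20, function(i) { force(i); function() i^2 })
  names(jobs) <- paste0("j", 1:20)
  shuffled_backend <- function(jobs) {
    set.seed(99)
    jobs <- jobs[sample(names(jobs))]
    lapply(jobs, function(j) j())
  }
  r1 <- distribute(jobs, backend_sequential)
  r2 <- distribute(jobs, shuffled_backend)
  expect_identical(r1, r2)
  boom <- list(ok = function() 5, bad = function() stop("nope"))
  expect_warning(res <- distribute(boom, backend_sequential),
                 "failed twice")
  expect_equal(res$ok, 5)
  expect_equal(res$bad, 0)
  # a flaky job succeeds on its single retry
  env <- new.env(); env$n <- 0L
  flaky <- list(f = function() {
    env$n <- env$n + 1L
    if (env$n < 2L) stop("first attempt fails")
    42
  })
  expect_equal(distribute(flaky, backend_sequential)$f, 42)
})

test_that("status summaries report per-generation statistics and baselines", {
  net <- ga_recovery_net()
  case <- ga_recovery_case(29)
  spec <- fitness_spec(c(kidney = "dice"))
  fit <- ga_optimize(net, list(case),
                     ga_config(population_size = 8, generations = 4,
                               seed = 7), spec)
  s <- status_summary(fit, baseline = 0.9)
  expect_equal(nrow(s), 4L)
  expect_true(all(diff(s$best_so_far) >= 0))
  expect_true(all(s$fit_min <= s$fit_median & s$fit_median <= s$fit_max))
  first <- attr(s, "first_exceeding_generation")
  expect_false(is.na(first))
  expect_true(all(s$best_so_far[s$generation >= first] > 0.9))
  csv <- tempfile(fileext = ".csv")
  status_summary(fit, baseline = 0.9, csv_path = csv)
  expect_true(file.exists(csv))
  expect_equal(nrow(utils::read.csv(csv)), 4L)
})
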