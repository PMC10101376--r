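test_that("derived boxes match closed-form extent arithmetic", {
  img <- sm_image(array(0, dim = c(40, 40, 30)), c(2, 2, 3))
  # degenerate box: zero offset range, one-voxel in-plane size
  b0 <- derive_box(c(40, 40, 45), c(1, 1), c(0, 0), "above", img)
  idx <- which(b0, arr.ind = TRUE)
  expect_equal(nrow(idx), 1L)
  expect_equal(as.integer(idx), c(21L, 21L, 16L))
  # 100x100 mm in plane, 5-25 mm above the reference center slice
  b <- derive_box(c(40, 40, 45), c(100, 100), c(5, 25), "above", img)
  rng <- apply(which(b, arr.ind = TRUE), 2, range)
  # lateral: |x-40| <= 50 -> x in [0,90] -> voxels 1..46 capped at 40
  expect_equal(rng[, 1], c(1L, 40L))
  # vertical: z in [50, 70] mm -> voxel coords (i-1)*3 in [50,70] -> 18..24
  expect_equal(rng[, 3], c(18L, 24L))
  below <- derive_box(c(40, 40, 45), c(100, 100), c(5, 25), "below", img)
  expect_equal(apply(which(below, arr.ind = TRUE), 2, range)[, 3], c(8L, 14L))
  # in 2D, "above" means smaller y
  img2 <- sm_image(matrix(0, 50, 50), c(1, 1))
  b2 <- derive_box(c(25, 30), c(10, 10), c(5, 15), "above", img2)
  expect_equal(range(which(b2, arr.ind = TRUE)[, 2]), c(16L, 26L))
})

test_that("preprocessing steps normalize, clip and equalize as specified", {
  img <- sm_image(matrix(5, 4, 4), c(1, 1))
  ch <- preprocess_channels(img, list(list(list(step = "minmax"))))
  expect_equal(ch[[1L]]$data, matrix(0, 4, 4))  # degenerate range -> 0

  g <- sm_image(matrix(as.numeric(1:9), 3, 3), c(1, 1))
  ch <- preprocess_channels(g, list(list(list(step = "centile_clip",
                                              args = c(10, 90)),
                                         list(step = "minmax"))))
  # brute-force percentile oracle (type-7 interpolation on sorted values)
  v <- sort(as.numeric(1:9))
  q10 <- v[1] + (v[2] - v[1]) * 0.8   # h = 1 + 0.10 * 8 = 1.8
  q90 <- v[8] + (v[9] - v[8]) * 0.2   # h = 1 + 0.90 * 8 = 8.2
  clipped <- pmin(pmax(1:9, q10), q90)
  expect_equal(as.numeric(ch[[1L]]$data),
               (clipped - min(clipped)) / diff(range(clipped)))
  expect_true(all(ch[[1L]]$data >= 0 & ch[[1L]]$data <= 1))

  # two channels, second clipping + histogram-equalizing
  two <- preprocess_channels(g, list(
    list(list(step = "biasfield"), list(step = "minmax")),
    list(list(step = "clip_histeq", args = c(2, 98)))))
  expect_length(two, 2L)
  expect_true(all(two[[2L]]$data >= 0 & two[[2L]]$data <= 1))
  expect_error(preprocess_channels(g, rep(list(list(list(step = "minmax"))),
                                          4)), "1 and 3")
})

test_that("a local histogram source raises in-region contrast", {
  # dim structure inside a bright field: whole-image normalization squashes
  # the structure's dynamic range; box-local normalization spreads it
  set.seed(42)
  img <- matrix(1000, 60, 60) + rnorm(3600, 0, 5)
  img[20:40, 20:40] <- seq(0, 100, length.out = 441)
  im <- sm_image(img, c(1, 1))
  box <- array(FALSE, dim(img)); box[15:45, 15:45] <- TRUE
  whole <- preprocess_channels(im, list(list(list(step = "minmax"))))[[1L]]
  local <- preprocess_channels(im, list(list(list(step = "minmax"))),
                               histogram_source = box)[[1L]]
  contrast <- function(ch) diff(range(ch$data[20:40, 20:40]))
  expect_gt(contrast(local), contrast(whole))
})

test_that("external predictor hooks behave like any other segmentation source", {
  ph <- abdominal_phantom(seed = 4)
  truth_hook <- function(img) ph$truth$kidney_left | ph$truth$kidney_right |
    ph$truth$stray
  lab <- external_predict(ph$image, truth_hook)
  cands <- extract_candidates(lab, ph$image$spacing)
  expect_length(cands, 3L)
  bad_hook <- function(img) matrix(TRUE, 2, 2)
  expect_error(external_predict(ph$image, bad_hook), "shape")
  register_predictor("tmp_hook", truth_hook)
  expect_identical(get_predictor("tmp_hook"), truth_hook)
  register_predictor("tmp_hook", NULL)
  expect_null(get_predictor("tmp_hook", optional = TRUE))
  expect_error(get_predictor("tmp_hook"), "no predictor hook")
})

test_that("reasoning rejects a stray region a predictor hallucinated", {
  ph <- abdominal_phantom(seed = 6)
  net <- make_kb(list(
    dense_bone = "IntensityRange 1200 3000",
    spine = "IntensityRange 1200 3000",
    kidney_cnn = "ExternalPredictor kidney_model",
    kidney_left = c("PartOf kidney_cnn", "NotPartOf dense_bone",
                    "LeftOf spine 50 100")))
  hook <- function(img) ph$truth$kidney_left | ph$truth$kidney_right |
    ph$truth$stray
  bb <- run_think(net, ph$image, hooks = list(kidney_cnn = hook))
  sel <- bb$elements$kidney_left$selected$idx
  expect_gt(length(sel), 0L)
  expect_length(intersect(sel, which(ph$truth$stray)), 0L)
  expect_length(intersect(sel, which(ph$truth$kidney_right)), 0L)
  # without the hook the node is not_found but dependents still run
  bb2 <- run_think(net, ph$image)
  expect_equal(bb2$elements$kidney_cnn$status, "not_found")
  expect_equal(bb2$elements$kidney_left$status, "not_found")
  expect_true(all(vapply(bb2$elements, function(se) se$status != "pending",
                         logical(1))))
})
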