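make_point_se <- function(pt, dim, spacing, status = "recognized") {
  se <- fake_se(status = status)
  if (status == "recognized")
    se$selected <- knowseg:::new_candidate(
      knowseg:::point_to_idx(pt, dim, spacing), dim, spacing, point = pt)
  se
}

make_mask_se <- function(idx, dim, spacing, status = "recognized") {
  se <- fake_se(status = status)
  if (status == "recognized") {
    se$selected <- knowseg:::new_candidate(idx, dim, spacing)
    se$candidates <- list(se$selected)
  }
  se
}

test_that("search areas follow closed-form band arithmetic", {
  img <- sm_image(array(0, dim = c(100, 20, 20)), c(2, 2, 2))
  d <- dim(img$data)
  ref <- make_point_se(c(100, 20, 20), d, img$spacing)
  se <- fake_se()
  se$relations <- list(list(kind = "LeftOf", ref = "spine",
                            range = c(50, 100)))
  bb <- fake_bb(list(spine = ref, x = se), img)
  sa <- derive_search_area(se, bb)
  xs <- sort(unique((which(sa, arr.ind = TRUE)[, 1] - 1) * 2))
  # patient-left band: x in [100+40, 100+120] with the 20% shoulder
  expect_equal(range(xs), c(140, 198))  # image ends at 198 mm
  expect_true(all(xs >= 140))
  # no usable relations -> whole image
  se2 <- fake_se()
  expect_true(all(derive_search_area(se2, bb)))
  # unresolved reference contributes nothing
  bb2 <- fake_bb(list(spine = fake_se(status = "not_found"), x = se), img)
  expect_true(all(derive_search_area(se, bb2)))
})

test_that("candidate features follow centroid and overlap arithmetic", {
  img <- sm_image(array(0, dim = c(10, 10, 10)), c(1, 1, 1))
  d <- dim(img$data)
  # 1-voxel mask at index (3,4,5): volume 1 mm^3, centroid (2,3,4) mm
  idx <- 3L + (4L - 1L) * 10L + (5L - 1L) * 100L
  cand <- knowseg:::new_candidate(idx, d, img$spacing)
  se <- fake_se()
  bb <- fake_bb(list(x = se), img)
  cand <- compute_features(cand, se, bb)
  expect_equal(cand$features$volume_mm3, 1)
  expect_equal(cand$features$centroid, c(2, 3, 4))
  expect_equal(cand$features$csa_mm2, 1)

  # two bars offset 30 mm vertically: |dz| = 30
  bar1 <- array(FALSE, d); bar1[3:7, 5, 2] <- TRUE
  bar2 <- array(FALSE, d); bar2[3:7, 5, 5] <- TRUE
  img2 <- sm_image(array(0, dim = d), c(1, 1, 10))
  ref <- make_mask_se(which(bar2), d, img2$spacing)
  se <- fake_se(refs = "other")
  se$expectations <- list(list(feature = "level_offset(other)",
                               kind = "relational", ref = "other",
                               fuzzy = NULL, relation = "SameLevelAs"))
  bb2 <- fake_bb(list(other = ref, x = se), img2)
  c2 <- compute_features(knowseg:::new_candidate(which(bar1), d,
                                                 img2$spacing), se, bb2)
  expect_equal(c2$features$`level_offset(other)`, 30)

  # candidate fully inside the parent's components: overlap fraction 1
  se3 <- fake_se(refs = "parent")
  parent <- make_mask_se(which(bar1 | bar2), d, img2$spacing)
  bb3 <- fake_bb(list(parent = parent, x = se3), img2)
  c3 <- compute_features(knowseg:::new_candidate(which(bar1), d,
                                                 img2$spacing), se3, bb3)
  expect_equal(c3$features$`overlap(parent)`, 1)
})

test_that("scores multiply fuzzy memberships and empty expectations score 1", {
  cand <- structure(list(idx = 1L, npix = 1L, features =
                           list(csa_mm2 = 30000), memberships = list(),
                         score = NA_real_), class = "candidate_region")
  se <- fake_se()
  expect_equal(score_candidate(cand, se)$score, 1)  # empty product
  se$expectations <- list(list(feature = "csa_mm2", kind = "unary",
                               ref = NA_character_,
                               fuzzy = fuzzy_function(c(10000, 50000),
                                                      c(0, 1)),
                               relation = NA_character_))
  expect_equal(score_candidate(cand, se)$score, 0.5)
  # a second, violated expectation zeroes the product
  se$expectations <- c(se$expectations,
                       list(list(feature = "offset_leftof(spine)",
                                 kind = "relational", ref = "spine",
                                 fuzzy = fuzzy_from_range(50, 100),
                                 relation = "LeftOf")))
  cand$features$`offset_leftof(spine)` <- 200
  expect_equal(score_candidate(cand, se)$score, 0)
  # non-informative relational expectation contributes 1
  cand$features$`offset_leftof(spine)` <- NA_real_
  expect_equal(score_candidate(cand, se)$score, 0.5)
})

test_that("shrinking a fuzzy support never increases a score", {
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 0, 50); b <- a + runif(1, 10, 60)
    shrink <- runif(1, 0.05, 0.45) * (b - a)
    wide <- fuzzy_from_range(a, b)
    narrow <- fuzzy_from_range(a + shrink, b - shrink)
    x <- runif(40, a - 30, b + 30)
    expect_true(all(eval_fuzzy(narrow, x) <= eval_fuzzy(wide, x) + 1e-12))
  }
})

test_that("selection is a pure argmax with volume tie-break and rejection", {
  mk <- function(score, npix) structure(
    list(idx = seq_len(npix), npix = npix, score = score,
         features = list(), memberships = list()),
    class = "candidate_region")
  se <- fake_se()
  se$candidates <- list(mk(0.8, 10))
  out <- select_best(se)
  expect_equal(out$status, "recognized")
  expect_equal(out$score, 0.8)
  se$candidates <- list(mk(0.5, 10), mk(0.9, 4), mk(0.9, 20))
  out <- select_best(se)
  expect_equal(out$selected_index, 3L)  # tie broken by larger volume
  se$candidates <- list(mk(0, 10), mk(0, 99))
  out <- select_best(se)
  expect_equal(out$status, "not_found")  # all scores zero -> output nothing
  expect_null(out$selected)
  # ordering invariance
  se$candidates <- list(mk(0.3, 5), mk(0.7, 8), mk(0.2, 9))
  s1 <- select_best(se)
  se$candidates <- rev(se$candidates)
  s2 <- select_best(se)
  expect_equal(s1$selected$score, s2$selected$score)
  expect_equal(s1$selected$npix, s2$selected$npix)
})

test_that("decision rules explain tip position and tolerate missing operands", {
  img <- sm_image(matrix(0, 100, 200), c(1, 1))
  d <- dim(img$data)
  zone <- array(FALSE, d); zone[40:60, 80:120] <- TRUE  # y in [79,119] mm
  mkbb <- function(tip_y, zone_status = "recognized") {
    fake_bb(list(tip = make_point_se(c(50, tip_y), d, img$spacing),
                 zone = make_mask_se(which(zone), d, img$spacing,
                                     status = zone_status)), img)
  }
  rule <- list(kind = "inside_zone", operands = c("tip", "zone"))
  r <- evaluate_decision(rule, mkbb(100))
  expect_true(r$decision)
  r <- evaluate_decision(rule, mkbb(140))  # below the zone (2D: larger y)
  expect_false(r$decision)
  expect_match(r$explanation, "too low")
  r <- evaluate_decision(rule, mkbb(60))
  expect_false(r$decision)
  expect_match(r$explanation, "too high")
  r <- evaluate_decision(rule, mkbb(100, zone_status = "not_found"))
  expect_true(is.na(r$decision))
  expect_match(r$explanation, "indeterminate")
})

test_that("path containment and conjunctions combine operand outcomes", {
  img <- sm_image(matrix(0, 50, 50), c(1, 1))
  d <- dim(img$data)
  region <- array(FALSE, d); region[20:30, 5:45] <- TRUE
  path_in <- array(FALSE, d); path_in[25, 6:40] <- TRUE
  path_out <- array(FALSE, d); path_out[25, 6:40] <- TRUE
  path_out[40:45, 10] <- TRUE  # 6 of 41 voxels outside
  bb <- fake_bb(list(region = make_mask_se(which(region), d, img$spacing),
                     good = make_mask_se(which(path_in), d, img$spacing),
                     bad = make_mask_se(which(path_out), d, img$spacing)),
                img)
  rule <- list(kind = "path_within", operands = c("good", "region"),
               threshold = 0.9)
  expect_true(evaluate_decision(rule, bb)$decision)
  rule$operands <- c("bad", "region")
  expect_false(evaluate_decision(rule, bb)$decision)

  dec <- function(v) { se <- fake_se(status = "recognized"); se$decision <- v; se }
  bb2 <- fake_bb(list(a = dec(TRUE), b = dec(TRUE), c = dec(FALSE),
                      d = dec(NA)))
  conj <- function(ops) evaluate_decision(list(kind = "conjunction",
                                               operands = ops), bb2)
  expect_true(conj(c("a", "b"))$decision)
  expect_false(conj(c("a", "c"))$decision)
  expect_true(is.na(conj(c("a", "d"))$decision))
  expect_match(conj(c("a", "c"))$explanation, "a=met, c=violated")
})

test_that("consistency checks fuse close estimates and flag distant ones", {
  p <- c(10, 20)
  r <- consistency_check(p, p, 10)
  expect_true(r$consistent)
  expect_equal(r$refined, p)
  r <- consistency_check(c(0, 0), c(0, 25), 10)
  expect_false(r$consistent)
  expect_equal(r$distance, 25)
  r <- consistency_check(c(0, 0), c(0, 6), 10)
  expect_true(r$consistent)
  expect_equal(r$refined, c(0, 3))  # midpoint
  expect_false(consistency_check(NULL, p, 10)$consistent)
  # overlapping region estimates fuse to their intersection
  a <- matrix(FALSE, 10, 10); a[2:6, 2:6] <- TRUE
  b <- matrix(FALSE, 10, 10); b[4:8, 2:6] <- TRUE
  r <- consistency_check(a, b, 10, spacing = c(1, 1))
  expect_true(r$consistent)
  expect_equal(r$refined, a & b)
})
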