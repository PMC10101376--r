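test_that("a minimal two-node network parses with one derived edge", {
  net <- make_kb(list(image = "IntensityRange 0 100",
                      blob = "PartOf image"))
  expect_s3_class(net, "semantic_network")
  expect_equal(net$node_order, c("image", "blob"))
  e <- summarize_graph(net)$edges
  expect_equal(nrow(e), 1L)
  expect_equal(e$from, "blob")
  expect_equal(e$to, "image")
})

test_that("the learning-rate line with a value-encoding operator parses", {
  net <- make_kb(list(cnn = "NeuralNet_LearningRate 1.0 -2 {45, 46, -5, -2}"))
  a <- net$nodes$cnn$attributes[[1L]]
  expect_equal(vapply(a$params, `[[`, numeric(1), "value"), c(1.0, -2))
  enc <- a$params[[2L]]$enc
  expect_equal(enc, list(bit_start = 45L, bit_end = 46L, lower = -5,
                         upper = -2))
  expect_null(a$params[[1L]]$enc)
})

test_that("a kidney-style node file parses with resolved references", {
  net <- make_kb(list(
    kidney_cnn = "IntensityRange 300 2000",
    dense_bone = "IntensityRange 1200 3000",
    spine = "IntensityRange 1200 3000",
    kidney_right_init = "PartOf kidney_cnn",
    kidney_left_init = c(
      "MinSize 1",
      "SearchShoulder 0.2",
      "PartOf kidney_cnn",
      "NotPartOf dense_bone",
      "LeftOf spine 50 100",
      "SameLevelAs kidney_right_init 3cm")))
  nd <- net$nodes$kidney_left_init
  expect_length(nd$attributes, 6L)
  refs <- unique(unlist(lapply(nd$attributes, knowseg:::node_params)))
  expect_setequal(refs, c("kidney_cnn", "dense_bone", "spine",
                          "kidney_right_init"))
  # cm suffix converted to mm
  lvl <- nd$attributes[[6L]]
  expect_equal(lvl$params[[2L]]$value, 30)
})

test_that("parse errors name the offending node, file and token", {
  dir <- tempfile("kb"); dir.create(dir)
  writeLines(c("a", "b"), file.path(dir, "node_list"))
  writeLines("IntensityRange 0 1", file.path(dir, "a"))
  expect_error(parse_network(file.path(dir, "node_list")),
               "missing node file for node 'b'")
  writeLines("NoSuchAttribute 1", file.path(dir, "b"))
  expect_error(parse_network(file.path(dir, "node_list")),
               "unknown attribute name 'NoSuchAttribute'.*line 1")
  writeLines("IntensityRange 0 {3, 4 1", file.path(dir, "b"))
  expect_error(parse_network(file.path(dir, "node_list")),
               "malformed value-encoding")
  writeLines("PartOf nowhere", file.path(dir, "b"))
  expect_error(parse_network(file.path(dir, "node_list")),
               "references unknown node 'nowhere'")
  writeLines(c("a", "a"), file.path(dir, "node_list"))
  expect_error(parse_network(file.path(dir, "node_list")),
               "duplicate node name")
})

test_that("tunable-parameter listing sorts by bit, reports span and rejects overlap", {
  net0 <- make_kb(list(a = "IntensityRange 0 10"))
  t0 <- list_tunable_parameters(net0)
  expect_equal(nrow(t0), 0L)
  expect_equal(attr(t0, "span"), 0L)

  net1 <- make_kb(list(a = "NeuralNet_LearningRate 1.0 -2 {45, 46, -5, -2}"))
  t1 <- list_tunable_parameters(net1)
  expect_equal(nrow(t1), 1L)
  expect_equal(attr(t1, "span"), 47L)

  net3 <- make_kb(list(
    a = "IntensityRange 5 {2, 4, 0, 10} 100",
    b = c("IntensityRange 1 {0, 1, 0, 3} 50", "MorphClose 2 {5, 5, 1, 4}")))
  t3 <- list_tunable_parameters(net3)
  expect_equal(nrow(t3), 3L)
  expect_equal(t3$bit_start, c(0L, 2L, 5L))
  expect_equal(attr(t3, "span"), 6L)

  over <- make_kb(list(
    a = "IntensityRange 5 {0, 2, 0, 10} 100",
    b = "IntensityRange 1 {2, 3, 0, 3} 50"))
  expect_error(list_tunable_parameters(over), "overlapping chromosome bits")
})

test_that("parse-write-parse is the identity on knowledge bases", {
  for (kb in c("kidney", "ett")) {
    net <- parse_network(example_kb(kb))
    out <- tempfile(kb)
    write_network(net, out)
    net2 <- parse_network(file.path(out, "node_list"))
    net$dir <- net2$dir <- NULL
    for (nm in names(net$nodes))
      net$nodes[[nm]]$source_file <- net2$nodes[[nm]]$source_file <- NULL
    expect_identical(net$nodes, net2$nodes)
    expect_identical(net$node_order, net2$node_order)
  }
  # encodings are re-emitted verbatim
  net <- make_kb(list(cnn = "NeuralNet_LearningRate 1.0 -2 {45, 46, -5, -2}"))
  out <- tempfile("enc")
  write_network(net, out)
  expect_match(readLines(file.path(out, "cnn")),
               "NeuralNet_LearningRate 1 -2 {45, 46, -5, -2}", fixed = TRUE)
  # fuzzy vertex lists round-trip in order
  net <- make_kb(list(a = "CrossSectionalArea 100cm2 0.0 250cm2 0.5 500cm2 1.0"))
  net2 <- parse_network(file.path(write_network(net, tempfile("fz")) |>
                                    dirname(), "node_list"))
  f1 <- knowseg:::attr_fuzzy(net$nodes$a$attributes[[1L]])
  f2 <- knowseg:::attr_fuzzy(net2$nodes$a$attributes[[1L]])
  expect_identical(f1, f2)
  expect_equal(f1$values, c(10000, 25000, 50000))
})

test_that("graph summaries are deterministic and the shipped graphs are acyclic", {
  net <- parse_network(example_kb("kidney"))
  g <- summarize_graph(net)
  expect_true(any(g$edges$from == "kidney_left_init" &
                    g$edges$to == "spine"))
  expect_match(g$report[1L], "nodes: 8")
  expect_identical(g$edges, summarize_graph(net)$edges)
  skip_if_not_installed("igraph")
  for (kb in c("kidney", "ett")) {
    e <- summarize_graph(parse_network(example_kb(kb)))$edges
    gr <- igraph::graph_from_data_frame(e[, c("from", "to")])
    expect_true(igraph::is_dag(gr))
  }
})

test_that("nodes reject conflicting segmentation drivers", {
  expect_error(make_kb(list(a = c("IntensityRange 0 1",
                                  "ExternalPredictor h"))),
               "more than one segmentation-driving attribute")
})
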