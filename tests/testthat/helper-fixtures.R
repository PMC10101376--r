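# Shared fixtures and independent oracles for the test suite.

# write a knowledge base from a named list of node-file contents and parse it
make_kb <- function(nodes, dir = tempfile("kb")) {
  dir.create(dir, recursive = TRUE)
  writeLines(names(nodes), file.path(dir, "node_list"))
  for (nm in names(nodes)) writeLines(nodes[[nm]], file.path(dir, nm))
  parse_network(file.path(dir, "node_list"))
}

# independent connected-component oracle: naive union-find over all
# neighbouring foreground pairs (no shared code with the implementation)
oracle_label <- function(mask, connectivity = "full") {
  d <- dim(mask)
  nd <- length(d)
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, dim = d))
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pos <- arrayInd(idx, d)
  key <- function(p) paste(p, collapse = ",")
  lookup <- new.env()
  for (k in seq_along(idx)) assign(key(pos[k, ]), k, envir = lookup)
  deltas <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  deltas <- deltas[rowSums(abs(deltas)) > 0, , drop = FALSE]
  if (connectivity == "face")
    deltas <- deltas[rowSums(abs(deltas)) == 1, , drop = FALSE]
  for (k in seq_along(idx)) {
    for (r in seq_len(nrow(deltas))) {
      q <- pos[k, ] + deltas[r, ]
      if (any(q < 1) || any(q > d)) next
      j <- mget(key(q), envir = lookup, ifnotfound = list(NULL))[[1L]]
      if (!is.null(j)) {
        a <- find(k); b <- find(j)
        if (a != b) parent[b] <- a
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab <- array(0L, dim = d)
  lab[idx] <- as.integer(factor(roots, levels = unique(roots)))
  lab
}

# random blobby test mask
random_mask <- function(d, p = 0.4, seed = 1) {
  knowseg:::with_seed(seed, array(stats::runif(prod(d)) < p, dim = d))
}

# same-partition comparison: labelings are equal up to label renaming
expect_same_partition <- function(a, b) {
  expect_equal(a > 0, b > 0)
  fa <- a[a > 0]; fb <- b[b > 0]
  expect_true(all(tapply(fb, fa, function(v) length(unique(v)) == 1L)))
  expect_true(all(tapply(fa, fb, function(v) length(unique(v)) == 1L)))
}

# minimal synthetic Solution Element / blackboard builders for scheduler and
# reasoning tests that do not need a full engine run
fake_se <- function(refs = character(0), status = "pending") {
  exps <- lapply(refs, function(r)
    list(feature = paste0("overlap(", r, ")"), kind = "relational", ref = r,
         fuzzy = NULL, relation = "PartOf"))
  list(node = "x", kind = "region", status = status, expectations = exps,
       relations = list(), candidates = list(), selected = NULL,
       shoulder = 0.2, accept_threshold = 0)
}

fake_bb <- function(elements, image = NULL) {
  bb <- new.env(parent = emptyenv())
  bb$elements <- elements
  bb$node_order <- names(elements)
  bb$image <- image
  class(bb) <- "blackboard"
  bb
}

ga_recovery_net <- function() {
  make_kb(list(kidney = "IntensityRange 300 {0, 2, 100, 800} 2000"))
}

ga_recovery_case <- function(seed) {
  ph <- abdominal_phantom(dim = c(32, 32, 28), spacing = 3, body = FALSE,
                          spine = FALSE, stray = FALSE, bump = TRUE,
                          kidney_offsets = c(left = 0), seed = seed)
  net <- ga_recovery_net()
  bb <- run_think(net, ph$image)
  ref <- array(FALSE, dim(ph$image$data))
  ref[bb$elements$kidney$selected$idx] <- TRUE
  tuning_case(ph$image, list(kidney = ref))
}
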