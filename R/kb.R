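# Semantic-network knowledge-base dialect: parser, writer, tunable-parameter
# listing and graph summary.
#
# A knowledge base is a directory holding a "node list" text file (one node
# name per line, defining processing/reporting order) plus one attribute file
# per node, named exactly after the node. Attribute files contain one
# attribute per line: whitespace-separated tokens, first token the attribute
# name from the vocabulary, `#` starting a comment. Scalar tokens default to
# mm and accept `cm`/`cm2`/`cm3` suffixes (converted at parse time). A
# `{start, end, lower, upper}` group immediately after a numeric token is the
# value-encoding operator exposing that scalar to the optimizer over the
# stated chromosome bit range.

unit_multipliers <- c(mm = 1, cm = 10, cm2 = 100, cm3 = 1000)

parse_scalar_token <- function(tok, where) {
  m <- regmatches(tok, regexec("^([-+]?[0-9.]+(?:[eE][-+]?[0-9]+)?)(mm|cm2|cm3|cm)?$", tok))[[1L]]
  if (length(m) == 0L)
    stop("expected a numeric value but found '", tok, "' ", where, call. = FALSE)
  val <- suppressWarnings(as.numeric(m[2L]))
  if (is.na(val))
    stop("malformed number '", tok, "' ", where, call. = FALSE)
  mult <- if (m[3L] == "") 1 else unit_multipliers[[m[3L]]]
  val * mult
}

tokenize_kb_line <- function(line) {
  line <- sub("#.*$", "", line)
  line <- gsub("([{}])", " \\1 ", line)
  line <- gsub(",", " ", line)
  toks <- strsplit(trimws(line), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

# consume an optional {a, b, lo, hi} value-encoding group at position `i`
take_encoding <- function(toks, i, where) {
  if (i > length(toks) || toks[i] != "{") return(list(enc = NULL, i = i))
  if (i + 5L > length(toks) || toks[i + 5L] != "}")
    stop("malformed value-encoding braces near '",
         paste(toks[i:min(i + 5L, length(toks))], collapse = " "), "' ", where,
         call. = FALSE)
  nums <- suppressWarnings(as.numeric(toks[i + 1:4]))
  if (anyNA(nums))
    stop("malformed value-encoding token '", toks[i + 1:4][is.na(nums)][1L],
         "' ", where, call. = FALSE)
  enc <- list(bit_start = as.integer(nums[1L]), bit_end = as.integer(nums[2L]),
              lower = nums[3L], upper = nums[4L])
  if (enc$bit_end < enc$bit_start)
    stop("value encoding has bit_end < bit_start ", where, call. = FALSE)
  if (enc$lower > enc$upper)
    stop("value encoding has lower > upper ", where, call. = FALSE)
  list(enc = enc, i = i + 6L)
}

parse_attribute_line <- function(toks, vocabulary, where) {
  name <- toks[1L]
  def <- vocabulary[[name]]
  if (is.null(def))
    stop("unknown attribute name '", name, "' ", where, call. = FALSE)
  params <- list()
  i <- 2L
  push_scalar <- function(i, fuzzy_part = NA_character_) {
    val <- parse_scalar_token(toks[i], where)
    e <- take_encoding(toks, i + 1L, where)
    params[[length(params) + 1L]] <<- list(type = "scalar", value = val,
                                           fuzzy_part = fuzzy_part,
                                           enc = e$enc)
    e$i
  }
  for (ptype in def$params) {
    switch(ptype,
      node = , word = {
        if (i > length(toks))
          stop("attribute ", name, " is missing a ", ptype, " parameter ",
               where, call. = FALSE)
        params[[length(params) + 1L]] <- list(type = ptype, value = toks[i],
                                              fuzzy_part = NA_character_,
                                              enc = NULL)
        i <- i + 1L
      },
      scalar = {
        if (i > length(toks))
          stop("attribute ", name, " is missing a scalar parameter ", where,
               call. = FALSE)
        i <- push_scalar(i)
      },
      fuzzy = {
        n0 <- length(params)
        part <- "value"
        while (i <= length(toks)) {
          i <- push_scalar(i, part)
          part <- if (part == "value") "confidence" else "value"
        }
        nvert <- length(params) - n0
        if (nvert < 2L || nvert %% 2L != 0L)
          stop("attribute ", name,
               " needs alternating value/confidence vertex pairs ", where,
               call. = FALSE)
      },
      varscalar = {
        while (i <= length(toks)) i <- push_scalar(i)
      },
      varnode = {
        while (i <= length(toks)) {
          params[[length(params) + 1L]] <- list(type = "node", value = toks[i],
                                                fuzzy_part = NA_character_,
                                                enc = NULL)
          i <- i + 1L
        }
        if (length(params) < 2L)
          stop("attribute ", name, " needs at least two node operands ", where,
               call. = FALSE)
      })
  }
  if (i <= length(toks))
    stop("trailing token '", toks[i], "' after attribute ", name, " ", where,
         call. = FALSE)
  list(name = name, category = def$category, params = params)
}

# fuzzy_function from the fuzzy-part params of an attribute
attr_fuzzy <- function(a) {
  fp <- Filter(function(p) !is.na(p$fuzzy_part), a$params)
  vals <- vapply(fp, function(p) as.numeric(p$value), numeric(1))
  part <- vapply(fp, function(p) p$fuzzy_part, character(1))
  fuzzy_function(vals[part == "value"], vals[part == "confidence"])
}

attr_values <- function(a) {
  lapply(a$params, function(p) p$value)
}

node_params <- function(a) {
  unlist(lapply(a$params, function(p) if (p$type == "node") p$value))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

find_attr <- function(node, name) {
  hits <- Filter(function(a) a$name == name, node$attributes)
  if (length(hits) == 0L) NULL else hits[[1L]]
}

find_attrs <- function(node, names) {
  Filter(function(a) a$name %in% names, node$attributes)
}

#' Parse a semantic-network knowledge base
#'
#' Reads the node-list file and one attribute file per listed node (same
#' directory, file named after the node), validates attribute arity against
#' the vocabulary, resolves node references and attaches value-encoding
#' records.
#'
#' @param node_list_path path to the node-list text file.
#' @param vocabulary an `sn_vocabulary` or path to one; default the shipped
#'   vocabulary.
#' @return an object of class `semantic_network`.
#' @export
parse_network <- function(node_list_path, vocabulary = NULL) {
  if (!file.exists(node_list_path))
    stop("node list file not found: ", node_list_path)
  if (is.null(vocabulary)) vocabulary <- load_vocabulary()
  if (is.character(vocabulary)) vocabulary <- load_vocabulary(vocabulary)
  dir <- dirname(node_list_path)
  lines <- readLines(node_list_path, warn = FALSE)
  names_ <- trimws(sub("#.*$", "", lines))
  names_ <- names_[nzchar(names_)]
  if (anyDuplicated(names_))
    stop("duplicate node name in node list: ",
         names_[duplicated(names_)][1L])
  nodes <- list()
  for (nm in names_) {
    nf <- file.path(dir, nm)
    if (!file.exists(nf))
      stop("missing node file for node '", nm, "' (expected ", nf, ")")
    nlines <- readLines(nf, warn = FALSE)
    attributes <- list()
    for (li in seq_along(nlines)) {
      toks <- tokenize_kb_line(nlines[li])
      if (length(toks) == 0L) next
      where <- sprintf("(%s line %d)", nf, li)
      attributes[[length(attributes) + 1L]] <-
        parse_attribute_line(toks, vocabulary, where)
    }
    nodes[[nm]] <- list(name = nm, attributes = attributes, source_file = nf)
  }
  net <- structure(list(nodes = nodes, node_order = names_,
                        vocabulary = vocabulary, dir = dir),
                   class = "semantic_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  seg_drivers <- c("IntensityRange", "ExternalPredictor", "Box", "BottomOf")
  for (nd in net$nodes) {
    for (a in nd$attributes) {
      for (ref in node_params(a)) {
        if (!ref %in% net$node_order)
          stop("node '", nd$name, "' references unknown node '", ref,
               "' in attribute ", a$name)
      }
    }
    n_drivers <- length(find_attrs(nd, seg_drivers))
    if (n_drivers > 1L)
      stop("node '", nd$name,
           "' has more than one segmentation-driving attribute")
  }
  invisible(net)
}

#' @export
print.semantic_network <- function(x, ...) {
  e <- network_edges(x)
  cat("<semantic_network>", length(x$nodes), "nodes,", nrow(e), "edges\n")
  for (nm in x$node_order)
    cat(sprintf("  %-24s %d attributes\n", nm,
                length(x$nodes[[nm]]$attributes)))
  invisible(x)
}

network_edges <- function(net) {
  out <- list()
  for (nd in net$nodes)
    for (a in nd$attributes)
      for (ref in node_params(a))
        out[[length(out) + 1L]] <- data.frame(from = nd$name, to = ref,
                                              attribute = a$name,
                                              stringsAsFactors = FALSE)
  if (length(out) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      attribute = character(0)))
  do.call(rbind, out)
}

#' List the tunable (value-encoded) parameters of a network
#'
#' @param net a `semantic_network`.
#' @return data.frame sorted by `bit_start` with one row per encoded scalar
#'   (node, attribute, param_index, bit range, bounds, current value). The
#'   total chromosome bit span is attached as attribute `"span"`. Overlapping
#'   bit ranges are a validation error.
#' @export
list_tunable_parameters <- function(net) {
  rows <- list()
  for (nd in net$nodes) {
    for (ai in seq_along(nd$attributes)) {
      a <- nd$attributes[[ai]]
      for (pi in seq_along(a$params)) {
        enc <- a$params[[pi]]$enc
        if (!is.null(enc))
          rows[[length(rows) + 1L]] <- data.frame(
            node = nd$name, attribute = a$name, attr_index = ai,
            param_index = pi, bit_start = enc$bit_start,
            bit_end = enc$bit_end, lower = enc$lower, upper = enc$upper,
            default = a$params[[pi]]$value, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(node = character(0), attribute = character(0),
                      attr_index = integer(0), param_index = integer(0),
                      bit_start = integer(0), bit_end = integer(0),
                      lower = numeric(0), upper = numeric(0),
                      default = numeric(0))
    attr(out, "span") <- 0L
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$bit_start, out$bit_end), , drop = FALSE]
  rownames(out) <- NULL
  # reject overlapping bit claims
  if (nrow(out) > 1L) {
    for (k in 2:nrow(out)) {
      if (out$bit_start[k] <= out$bit_end[k - 1L])
        stop("overlapping chromosome bits: ",
             sprintf("%s/%s [%d..%d] and %s/%s [%d..%d]",
                     out$node[k - 1L], out$attribute[k - 1L],
                     out$bit_start[k - 1L], out$bit_end[k - 1L],
                     out$node[k], out$attribute[k],
                     out$bit_start[k], out$bit_end[k]))
    }
  }
  attr(out, "span") <- max(out$bit_end) + 1L
  out
}

# shortest decimal representation that round-trips the double exactly
fmt_num <- function(x) {
  vapply(x, function(v) {
    for (d in c(6L, 10L, 15L, 17L)) {
      s <- formatC(v, digits = d, format = "g", width = 1)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

format_attribute_line <- function(a) {
  toks <- a$name
  for (p in a$params) {
    toks <- c(toks, if (p$type == "scalar") fmt_num(p$value) else p$value)
    if (!is.null(p$enc))
      toks <- c(toks, sprintf("{%d, %d, %s, %s}", p$enc$bit_start,
                              p$enc$bit_end, fmt_num(p$enc$lower),
                              fmt_num(p$enc$upper)))
  }
  paste(toks, collapse = " ")
}

#' Write a semantic network back to knowledge-base text files
#'
#' Emits a `node_list` file plus one attribute file per node such that
#' `parse_network()` on the result reproduces the network field-for-field
#' (scalars are written with round-trip-exact precision, in mm).
#'
#' @param net a `semantic_network`.
#' @param dir destination directory (created if missing).
#' @return the path of the written node-list file, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create knowledge-base directory: ", dir)
  nl <- file.path(dir, "node_list")
  writeLines(net$node_order, nl)
  for (nd in net$nodes) {
    lines <- vapply(nd$attributes, format_attribute_line, character(1))
    writeLines(lines, file.path(dir, nd$name))
  }
  invisible(nl)
}

#' Summarize the relational structure of a network
#'
#' @param net a `semantic_network`.
#' @return list with `edges` (data.frame from/to/attribute, deterministic
#'   order) and `report` (character lines: node, edge and tunable-parameter
#'   counts), class `sn_graph_summary`.
#' @export
summarize_graph <- function(net) {
  edges <- network_edges(net)
  if (nrow(edges) > 0) {
    ord <- order(match(edges$from, net$node_order),
                 match(edges$to, net$node_order), edges$attribute)
    edges <- edges[ord, , drop = FALSE]
    rownames(edges) <- NULL
  }
  tun <- list_tunable_parameters(net)
  report <- c(sprintf("nodes: %d", length(net$nodes)),
              sprintf("edges: %d", nrow(edges)),
              sprintf("tunable parameters: %d (chromosome span %d bits)",
                      nrow(tun), attr(tun, "span")),
              sprintf("  %s -[%s]-> %s", edges$from, edges$attribute,
                      edges$to))
  structure(list(edges = edges, report = report), class = "sn_graph_summary")
}

#' @export
print.sn_graph_summary <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}
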