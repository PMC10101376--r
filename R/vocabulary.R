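#' Load an attribute vocabulary
#'
#' The vocabulary defines the attribute names usable in a knowledge base,
#' their parameter arity/types, and the agent-family category each belongs
#' to. The default vocabulary covers intensity/threshold segmentation,
#' morphology, spatial relations, fuzzy unary features, decision rules,
#' preprocessing and learning parameters; users may supply an extended file.
#'
#' @param path YAML vocabulary file; default is the vocabulary shipped with
#'   the package.
#' @return named list of attribute definitions (class `sn_vocabulary`).
#' @export
load_vocabulary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "vocabulary.yaml", package = "knowseg")
  entries <- yaml::read_yaml(path)
  defs <- list()
  for (e in entries) {
    if (is.null(e$params)) e$params <- character(0)
    e$params <- as.character(e$params)
    bad <- setdiff(e$params,
                   c("node", "scalar", "word", "fuzzy", "varscalar", "varnode"))
    if (length(bad) > 0)
      stop("unknown parameter type(s) in vocabulary entry ", e$name, ": ",
           paste(bad, collapse = ", "))
    variadic <- e$params %in% c("fuzzy", "varscalar", "varnode")
    if (any(variadic) && which(variadic)[1L] != length(e$params))
      stop("variadic parameter must be last in vocabulary entry ", e$name)
    if (!is.null(defs[[e$name]]))
      stop("duplicate vocabulary attribute name: ", e$name)
    defs[[e$name]] <- e
  }
  structure(defs, class = "sn_vocabulary")
}

#' @export
print.sn_vocabulary <- function(x, ...) {
  cat("<sn_vocabulary>", length(x), "attribute definitions\n")
  for (e in x)
    cat(sprintf("  %-22s %-13s (%s)\n", e$name, e$category,
                paste(e$params, collapse = ", ")))
  invisible(x)
}

# agent family owning each category (one family per category)
category_family <- c(segmentation = "segmentation",
                     unary        = "reasoning",
                     relational   = "reasoning",
                     decision     = "reasoning",
                     preprocessing = "segmentation",
                     learning     = "learning")
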