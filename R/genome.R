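# Chromosome encoding of tunable knowledge-base parameters.
#
# A chromosome is a plain 0/1 string. Each value-encoded scalar owns an
# inclusive bit range [bit_start, bit_end] (0-based positions into the
# chromosome); the n-bit pattern is read as an unsigned index into 2^n
# candidate values spaced equidistantly between the declared lower and upper
# bounds (all-zeros -> lower, all-ones -> upper). Unused bits between genes
# are permitted and ignored.

check_bits <- function(bits) {
  if (length(bits) != 1L || !is.character(bits) ||
      grepl("[^01]", bits) || nchar(bits) == 0L)
    stop("chromosome must be a non-empty string of 0s and 1s")
  invisible(bits)
}

#' Candidate value set of a value encoding
#'
#' @param enc a value-encoding record (`bit_start`, `bit_end`, `lower`,
#'   `upper`), as attached by [parse_network()].
#' @return numeric vector of `2^nbits` equidistant values from `lower` to
#'   `upper` inclusive.
#' @export
gene_values <- function(enc) {
  n <- enc$bit_end - enc$bit_start + 1L
  k <- 2^n
  if (enc$lower == enc$upper) return(rep(enc$lower, k))
  enc$lower + (0:(k - 1)) * (enc$upper - enc$lower) / (k - 1)
}

#' Decode one gene
#'
#' @param bits binary substring exactly covering the gene's bit range.
#' @param enc the gene's value encoding.
#' @return the decoded scalar.
#' @examples
#' enc <- list(bit_start = 45L, bit_end = 46L, lower = -5, upper = -2)
#' decode_gene("00", enc)  # -5
#' decode_gene("11", enc)  # -2
#' @export
decode_gene <- function(bits, enc) {
  check_bits(bits)
  n <- enc$bit_end - enc$bit_start + 1L
  if (nchar(bits) != n)
    stop("gene expects ", n, " bits, got ", nchar(bits))
  idx <- sum(as.integer(strsplit(bits, "")[[1L]]) * 2^((n - 1):0))
  gene_values(enc)[idx + 1L]
}

#' Generate a random chromosome
#'
#' Deterministic for a fixed seed; does not disturb the caller's RNG state.
#'
#' @param length number of bits (> 0).
#' @param seed integer seed.
#' @return 0/1 string of the requested length.
#' @export
random_chromosome <- function(length, seed) {
  if (length <= 0) stop("chromosome length must be positive")
  with_seed(seed, paste(sample(c("0", "1"), length, replace = TRUE),
                        collapse = ""))
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply a chromosome to a network
#'
#' Replaces every value-encoded scalar by its decoded value and clears the
#' encodings, yielding a fully specified network; non-tunable parameters are
#' untouched.
#'
#' @param net a `semantic_network`.
#' @param chromosome 0/1 string covering all encodings (ignored extra bits
#'   are allowed; an empty-string chromosome is valid for a network without
#'   encodings).
#' @return list with `network` (the specified network) and `parameters`
#'   (data.frame of node/attribute/param_index/decoded value).
#' @export
apply_chromosome <- function(net, chromosome) {
  tun <- list_tunable_parameters(net)
  span <- attr(tun, "span")
  if (nrow(tun) == 0L) {
    return(list(network = net,
                parameters = cbind(tun, value = numeric(0))))
  }
  check_bits(chromosome)
  if (nchar(chromosome) < span)
    stop("chromosome has ", nchar(chromosome), " bits but the network needs ",
         span)
  values <- numeric(nrow(tun))
  for (k in seq_len(nrow(tun))) {
    bits <- substr(chromosome, tun$bit_start[k] + 1L, tun$bit_end[k] + 1L)
    enc <- list(bit_start = tun$bit_start[k], bit_end = tun$bit_end[k],
                lower = tun$lower[k], upper = tun$upper[k])
    values[k] <- decode_gene(bits, enc)
    p <- net$nodes[[tun$node[k]]]$attributes[[tun$attr_index[k]]]$params[[tun$param_index[k]]]
    p$value <- values[k]
    p$enc <- NULL
    net$nodes[[tun$node[k]]]$attributes[[tun$attr_index[k]]]$params[[tun$param_index[k]]] <- p
  }
  out <- tun
  out$value <- values
  list(network = net, parameters = out)
}
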