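#' Build a configuration-model random multigraph from a degree sequence
#'
#' Each node `i` is split into `degrees[i]` stubs (edge halves); the stub
#' list is permuted uniformly at random and paired consecutively, which is
#' equivalent to repeatedly picking two uniform random stubs and joining
#' them. Self-loops and multi-links are kept: their share of edges vanishes
#' as the network grows, and erasing them would bias the degrees. A
#' self-loop contributes two edge-ends (degree 2) to its node.
#'
#' @param degrees integer degree sequence with even sum, all entries >= 1.
#'   Use [repair_graphical()] first if the sum may be odd.
#' @return An object of class `multinet`: list with `n_nodes`, `edges`
#'   (two-column integer matrix of 1-based node ids, one row per edge,
#'   loops as `c(i, i)`, multi-links as repeated rows) and `degrees`
#'   (realized degrees, equal to the input).
#' @examples
#' set.seed(1)
#' net <- build_network(rep(4L, 100))
#' net
#' @export
build_network <- function(degrees) {
  degrees <- as.integer(degrees)
  if (any(degrees < 1L)) stop("all degrees must be >= 1")
  if (sum(degrees) %% 2L != 0L)
    stop("odd degree sum: repair_graphical() the sequence first")
  n <- length(degrees)
  stubs <- rep.int(seq_len(n), degrees)
  stubs <- stubs[sample.int(length(stubs))] # uniform perfect matching
  edges <- matrix(stubs, ncol = 2L, byrow = TRUE)
  structure(list(n_nodes = n, edges = edges, degrees = degrees),
            class = "multinet")
}

#' @export
print.multinet <- function(x, ...) {
  art <- count_artifacts(x)
  cat("Configuration-model multigraph:", x$n_nodes, "nodes,",
      nrow(x$edges), "edges (", art[["self_loops"]], "self-loops,",
      art[["multi_links"]], "multi-links)\n")
  cat("  degrees: min", min(x$degrees), "/ mean",
      format(mean(x$degrees)), "/ max", max(x$degrees), "\n")
  invisible(x)
}

#' Count self-loops and multi-links of a multigraph
#'
#' @param net a `multinet`.
#' @return Named integer vector: `self_loops` (number of loop edges) and
#'   `multi_links` (edges beyond the first between each node pair,
#'   self-pairs included).
#' @export
count_artifacts <- function(net) {
  stopifnot(inherits(net, "multinet"))
  e <- net$edges
  loops <- sum(e[, 1L] == e[, 2L])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  multi <- nrow(e) - length(unique(key))
  c(self_loops = as.integer(loops), multi_links = as.integer(multi))
}

#' Realized node degrees of a multigraph
#'
#' Loops counted twice (two edge-ends).
#'
#' @param net a `multinet`.
#' @return Integer vector of length `n_nodes`.
#' @export
network_degrees <- function(net) {
  tabulate(c(net$edges[, 1L], net$edges[, 2L]), nbins = net$n_nodes)
}

# CSR adjacency-with-multiplicity in 0-based form for the C++ kernel.
# adj lists every edge-end's opposite node; a loop lists the node itself
# twice. ptr has length n_nodes + 1.
as_adjacency <- function(net) {
  ends <- c(net$edges[, 1L], net$edges[, 2L])
  nbrs <- c(net$edges[, 2L], net$edges[, 1L])
  ord <- order(ends)
  deg <- tabulate(ends, nbins = net$n_nodes)
  list(ptr = c(0L, cumsum(deg)), adj = nbrs[ord] - 1L)
}

#' Write or read a multigraph as a plain-text edge list
#'
#' One edge per line, two whitespace-separated 0-based node ids; a
#' self-loop is written `i i` and multi-links as repeated lines. Header
#' comment lines (`#`) carry the node count and, optionally, the
#' generating seed.
#'
#' @param net a `multinet`.
#' @param path file path.
#' @param seed optional integer recorded in the header.
#' @return `write_edgelist` returns `path` invisibly; `read_edgelist`
#'   returns a `multinet`.
#' @export
write_edgelist <- function(net, path, seed = NULL) {
  stopifnot(inherits(net, "multinet"))
  hdr <- paste0("# n_nodes=", net$n_nodes)
  if (!is.null(seed)) hdr <- c(hdr, paste0("# seed=", seed))
  lines <- paste(net$edges[, 1L] - 1L, net$edges[, 2L] - 1L)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  nn <- sub("^# *n_nodes=", "", grep("n_nodes=", hdr, value = TRUE))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  e <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE) + 1L
  n <- if (length(nn)) as.integer(nn[1L]) else max(e)
  net <- structure(list(n_nodes = n, edges = e, degrees = NULL),
                   class = "multinet")
  net$degrees <- network_degrees(net)
  net
}
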