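#' Enumerate controlled degree substitutions between degree types
#'
#' Starting from a sequence of `N` nodes that all carry the smallest degree
#' type, nodes are substituted one at a time by nodes of the other types
#' until every composition of `N` over the `m` types has been visited. A
#' substitution is represented by its *counts* (how many nodes of each
#' type), not by a literal position-wise sequence: node positions are
#' immaterial to the configuration model, so two sequences with the same
#' counts generate the same random-graph ensemble.
#'
#' The enumeration is ordered lexicographically by decreasing count of the
#' lower degree types, i.e. it starts at the homogeneous low-degree
#' sequence and ends at the homogeneous high-degree sequence. With
#' `stride > 1` the composition grid is thinned: only compositions whose
#' first `m - 1` counts are multiples of `stride` are kept (both
#' homogeneous endpoints always survive a stride that divides `N`). This
#' keeps three-type enumerations tractable, since the full grid grows as
#' `choose(N + m - 1, m - 1)`.
#'
#' @param N number of nodes (positive integer).
#' @param degree_types vector of `m` distinct positive integer degrees.
#' @param stride positive integer thinning factor for the count grid
#'   (default 1 = full enumeration).
#' @return An object of class `degree_mix_set`: a list with elements `N`,
#'   `degree_types` (sorted), `counts` (one row per mix, one column per
#'   type) and `stride`. Supports `length()`, `[[` (returns a single
#'   `degree_mix`) and `print()`.
#' @seealso [count_mixes()], [expand_mix()], [run_substitution_experiment()]
#' @examples
#' make_substitution_sequences(3, c(3, 4))
#' @export
make_substitution_sequences <- function(N, degree_types, stride = 1L) {
  stopifnot(length(N) == 1L, N >= 1, N == round(N))
  degree_types <- as.integer(degree_types)
  if (any(degree_types < 1)) stop("degree types must be positive integers")
  if (anyDuplicated(degree_types)) stop("degree types must be distinct")
  stopifnot(length(stride) == 1L, stride >= 1, stride == round(stride))
  degree_types <- sort(degree_types)
  m <- length(degree_types)
  counts <- compositions_desc(as.integer(N), m)
  if (stride > 1L && m > 1L) {
    keep <- rowSums(counts[, -m, drop = FALSE] %% as.integer(stride)) == 0L
    counts <- counts[keep, , drop = FALSE]
  }
  colnames(counts) <- paste0("k", degree_types)
  structure(list(N = as.integer(N), degree_types = degree_types,
                 counts = counts, stride = as.integer(stride)),
            class = "degree_mix_set")
}

# All compositions of N into m non-negative parts, lexicographically
# decreasing in the leading parts: (N,0,...,0), (N-1,1,0,...), ..., (0,...,N).
compositions_desc <- function(N, m) {
  if (m == 1L) return(matrix(N, 1L, 1L))
  blocks <- vector("list", N + 1L)
  for (c1 in N:0) {
    sub <- compositions_desc(N - c1, m - 1L)
    blocks[[N - c1 + 1L]] <- cbind(rep.int(c1, nrow(sub)), sub)
  }
  do.call(rbind, blocks)
}

#' Number of degree substitutions between m degree types
#'
#' The number of compositions of `N` nodes over `m` degree types is the
#' binomial coefficient `choose(N + m - 1, m - 1)`. This equals
#' `length(make_substitution_sequences(N, types))` at `stride = 1`.
#'
#' @param N number of nodes (positive integer).
#' @param m number of distinct degree types (positive integer).
#' @return The count, as a double (exact while below 2^53).
#' @examples
#' count_mixes(1000, 2) # 1001
#' @export
count_mixes <- function(N, m) {
  stopifnot(N >= 1, N == round(N), m >= 1, m == round(m))
  choose(N + m - 1, m - 1)
}

#' @export
length.degree_mix_set <- function(x) nrow(x$counts)

#' @export
`[[.degree_mix_set` <- function(x, i) {
  cnt <- x$counts[i, ]
  structure(list(degree_types = x$degree_types,
                 counts = as.integer(cnt), N = x$N),
            class = "degree_mix")
}

#' @export
print.degree_mix_set <- function(x, ...) {
  cat("Degree substitution set: N =", x$N, ", types = (",
      paste(x$degree_types, collapse = ", "), "), ",
      nrow(x$counts), "mixes")
  if (x$stride > 1L) cat(" (stride ", x$stride, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
print.degree_mix <- function(x, ...) {
  cat("Degree mix: ",
      paste(sprintf("%d x k=%d", x$counts, x$degree_types), collapse = " + "),
      "  <k> = ", format(mix_avg_degree(x)), "\n", sep = "")
  invisible(x)
}

#' Average degree of a degree mix or mix set
#'
#' @param x a `degree_mix` or `degree_mix_set`.
#' @return For a single mix, the scalar average degree
#'   `sum(type * count) / N`; for a set, the vector over all mixes.
#' @export
mix_avg_degree <- function(x) {
  if (inherits(x, "degree_mix_set"))
    return(as.numeric(x$counts %*% x$degree_types) / x$N)
  sum(x$degree_types * x$counts) / x$N
}

#' Expand a degree mix into a literal degree sequence
#'
#' @param mix a `degree_mix` (e.g. from `[[` on a `degree_mix_set`), or a
#'   vector of counts if `degree_types` is supplied.
#' @param degree_types degree types matching `mix` when `mix` is a plain
#'   count vector.
#' @return Integer vector of node degrees, ordered by type (order is
#'   irrelevant downstream).
#' @export
expand_mix <- function(mix, degree_types = NULL) {
  if (inherits(mix, "degree_mix")) {
    rep.int(mix$degree_types, mix$counts)
  } else {
    stopifnot(length(mix) == length(degree_types))
    rep.int(as.integer(degree_types), as.integer(mix))
  }
}

#' Repair a degree sequence to even (graphical-ready) sum
#'
#' The stub-pairing construction needs an even number of stubs. If the
#' degree sum is odd, one entry with an odd degree is chosen uniformly at
#' random and removed, shortening the sequence by one node; an even-sum
#' sequence is returned unchanged. An odd sum guarantees at least one odd
#' entry, so the removal always succeeds. Uses the current RNG state
#' (`set.seed()` for reproducibility).
#'
#' @param degrees integer vector of node degrees, all >= 1.
#' @return Integer degree sequence with even sum.
#' @examples
#' set.seed(1)
#' repair_graphical(c(3, 3, 3)) # one 3 removed
#' @export
repair_graphical <- function(degrees) {
  degrees <- as.integer(degrees)
  if (length(degrees) == 0L) stop("empty degree sequence")
  if (any(degrees < 1L)) stop("all degrees must be >= 1")
  if (sum(degrees) %% 2L == 0L) return(degrees)
  odd <- which(degrees %% 2L == 1L)
  stopifnot(length(odd) >= 1L) # odd sum implies an odd entry
  drop <- odd[sample.int(length(odd), 1L)]
  degrees[-drop]
}

#' Read or write a degree sequence as plain text
#'
#' One degree per line (single column, no header).
#'
#' @param degrees integer degree sequence.
#' @param path file path.
#' @return `read_degree_sequence` returns an integer vector;
#'   `write_degree_sequence` returns `path` invisibly.
#' @export
write_degree_sequence <- function(degrees, path) {
  writeLines(as.character(as.integer(degrees)), path)
  invisible(path)
}

#' @rdname write_degree_sequence
#' @export
read_degree_sequence <- function(path) {
  as.integer(readLines(path))
}
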