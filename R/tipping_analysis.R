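#' Fit a parabolic tipping-boundary curve for one degree pair
#'
#' Least-squares quadratic of the tipping point on the average degree,
#' `H_T ~ a <k>^2 + b <k> + c`, fitted over the substitution records of one
#' degree pair `(k1, k2)`. The fit is unconstrained (no sign or curvature
#' restriction) and is only meaningful inside its domain `[k1, k2]`. The
#' chord joining the two simulated homogeneous endpoints is stored with the
#' curve: the pair's *tipping region* is the area between the fitted curve
#' (below) and that chord (above).
#'
#' @param records a `tipping_table` (or data frame with `avg_degree`,
#'   `H_T`, `found`) from a single two-degree substitution experiment.
#' @param pair optional `c(k1, k2)`; inferred from `records$degree_types`
#'   when missing.
#' @return An object of class `boundary_curve`: coefficients (`a`, `b`,
#'   `c`), `domain`, `rms` residual, chord `endpoints` (H_T at the
#'   homogeneous ends, simulated where available, otherwise the fitted
#'   values), and the number of points used. Has `print`, `coef`,
#'   `predict` and `plot` methods.
#' @export
fit_boundary <- function(records, pair = NULL) {
  records <- as.data.frame(records)
  if (is.null(pair)) {
    tys <- unique(records$degree_types)
    if (length(tys) != 1L)
      stop("records mix several degree pairs; pass `pair` explicitly")
    pair <- as.integer(strsplit(tys, "+", fixed = TRUE)[[1L]])
  }
  if (length(pair) != 2L || pair[1L] >= pair[2L])
    stop("`pair` must be two increasing degrees")
  ok <- records$found & !is.na(records$H_T)
  if (sum(ok) == 0L) stop("no record has a found tipping point")
  if (sum(ok) < 3L) stop("need at least 3 usable points to fit a quadratic")
  k <- records$avg_degree[ok]
  y <- records$H_T[ok]
  fit <- stats::lm(y ~ k + I(k^2))
  cf <- stats::coef(fit)
  coefs <- c(a = unname(cf[3L]), b = unname(cf[2L]), c = unname(cf[1L]))
  rms <- sqrt(mean(stats::resid(fit)^2))
  ends <- vapply(pair, function(kk) {
    at <- ok & abs(records$avg_degree - kk) < 1e-9
    if (any(at)) mean(records$H_T[at])
    else coefs["a"] * kk^2 + coefs["b"] * kk + coefs["c"]
  }, numeric(1))
  structure(list(pair = as.integer(pair), coef = coefs,
                 domain = as.numeric(pair), rms = rms,
                 endpoints = unname(ends), n = sum(ok)),
            class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, digits = 4, ...) {
  cat(sprintf("Tipping boundary (%d, %d): H_T = %s<k>^2 + %s<k> + %s\n",
              x$pair[1L], x$pair[2L],
              format(x$coef["a"], digits = digits),
              format(x$coef["b"], digits = digits),
              format(x$coef["c"], digits = digits)))
  cat(sprintf("  domain [%d, %d], RMS residual %s, %d points; chord ends H_T = %s, %s\n",
              x$pair[1L], x$pair[2L], format(x$rms, digits = digits), x$n,
              format(x$endpoints[1L], digits = digits),
              format(x$endpoints[2L], digits = digits)))
  invisible(x)
}

#' @export
coef.boundary_curve <- function(object, ...) object$coef

#' Evaluate a boundary curve at average degrees inside its domain
#'
#' @param object a `boundary_curve`.
#' @param avg_degree average degree values; must lie inside the fit domain
#'   (small numerical slack allowed).
#' @param ... unused.
#' @return Predicted tipping points.
#' @export
predict.boundary_curve <- function(object, avg_degree, ...) {
  if (any(avg_degree < object$domain[1L] - 1e-9 |
          avg_degree > object$domain[2L] + 1e-9))
    stop("boundary curve evaluated outside its fit domain [",
         object$domain[1L], ", ", object$domain[2L], "]")
  unname(object$coef["a"] * avg_degree^2 + object$coef["b"] * avg_degree +
           object$coef["c"])
}

# Straight chord between the pair's homogeneous endpoints.
chord_value <- function(curve, avg_degree) {
  k1 <- curve$domain[1L]; k2 <- curve$domain[2L]
  w <- (avg_degree - k1) / (k2 - k1)
  (1 - w) * curve$endpoints[1L] + w * curve$endpoints[2L]
}

# Containment tolerance: generous enough to absorb fit noise and the field
# grid quantization (default grid step 20/999).
default_tolerance <- function(curve, grid_step = 20 / 999) {
  max(2 * curve$rms, grid_step)
}

#' Pairwise span relations between tipping-boundary curves
#'
#' A curve for the degree pair `(ki, kj)` is expected to *span over* every
#' curve whose degree interval it contains: evaluated on the inner pair's
#' domain, the outer curve should lie on or below the inner one everywhere.
#' Each ordered pair of curves with nested domains is checked on a shared
#' grid; pairs whose domains are not nested are reported as not comparable.
#'
#' @param curves list of `boundary_curve`s from the same simulation
#'   configuration.
#' @param grid_n grid points used on the inner domain (default 101).
#' @param tol span tolerance; defaults to the larger of the two curves'
#'   containment tolerances.
#' @return A data frame of class `nesting_report` with one row per ordered
#'   curve pair: `outer`, `inner`, `comparable`, `spans` (outer <= inner +
#'   tol everywhere on the inner domain), and `worst_gap` (max of outer -
#'   inner; negative means strictly below).
#' @export
check_nesting <- function(curves, grid_n = 101L, tol = NULL) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "boundary_curve")))
  lab <- vapply(curves, function(cu)
    sprintf("(%d,%d)", cu$pair[1L], cu$pair[2L]), character(1))
  rows <- list()
  for (i in seq_along(curves)) for (j in seq_along(curves)) {
    outer <- curves[[i]]; inner <- curves[[j]]
    nested <- outer$domain[1L] <= inner$domain[1L] &&
      inner$domain[2L] <= outer$domain[2L]
    if (!nested) {
      rows[[length(rows) + 1L]] <- data.frame(
        outer = lab[i], inner = lab[j], comparable = FALSE,
        spans = NA, worst_gap = NA_real_)
      next
    }
    grid <- seq(inner$domain[1L], inner$domain[2L], length.out = grid_n)
    gap <- predict(outer, grid) - predict(inner, grid)
    tl <- if (is.null(tol))
      max(default_tolerance(outer), default_tolerance(inner)) else tol
    rows[[length(rows) + 1L]] <- data.frame(
      outer = lab[i], inner = lab[j], comparable = TRUE,
      spans = max(gap) <= tl, worst_gap = max(gap))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("nesting_report", "data.frame")
  out
}

#' Classify a tipping point into degree-pair tipping regions
#'
#' A pair's tipping region lies between its fitted boundary curve (lower
#' bound) and the straight chord joining its homogeneous endpoints (upper
#' bound), boundaries inclusive up to a tolerance. A point contained in no
#' region lies in a *forbidden tipping region*: no substitution between the
#' supplied degree pairs can produce it.
#'
#' @param avg_degree average degree of the network.
#' @param H_T its tipping point.
#' @param curves list of `boundary_curve`s.
#' @param tol containment tolerance; default per curve via the larger of
#'   twice its RMS residual and one field-grid step.
#' @return Character vector of pair labels (e.g. `"(3,5)"`) whose region
#'   contains the point; `character(0)` means forbidden.
#' @export
classify_point <- function(avg_degree, H_T, curves, tol = NULL) {
  stopifnot(length(avg_degree) == 1L, length(H_T) == 1L)
  in_dom <- vapply(curves, function(cu)
    avg_degree >= cu$domain[1L] - 1e-9 &&
      avg_degree <= cu$domain[2L] + 1e-9, logical(1))
  if (!any(in_dom))
    stop("avg_degree ", avg_degree, " lies outside every curve's domain")
  hits <- character(0)
  for (cu in curves[in_dom]) {
    tl <- if (is.null(tol)) default_tolerance(cu) else tol
    lo <- predict(cu, avg_degree) - tl
    hi <- chord_value(cu, avg_degree) + tl
    if (H_T >= lo && H_T <= hi)
      hits <- c(hits, sprintf("(%d,%d)", cu$pair[1L], cu$pair[2L]))
  }
  hits
}

#' Tipping-point spread of three-degree mixes against the pairwise envelope
#'
#' Samples random compositions of `N` nodes over a triple of distinct
#' degrees (uniformly over the composition simplex), runs the hysteresis
#' protocol on each sampled mix, and classifies every `(<k>, H_T)` point
#' against the regions of the triple's three degree pairs. Tipping points
#' of three-degree mixes are expected to land inside the envelope spanned
#' by the pairwise curves; escaping it is statistically unlikely.
#'
#' @param degree_triple three distinct positive integer degrees.
#' @param n_samples number of random compositions to simulate.
#' @param cfg a [sweep_config()]; its `base_seed` also seeds the
#'   composition sampling.
#' @param curves optional list of the three pairwise `boundary_curve`s; if
#'   `NULL` they are fitted from fresh pairwise substitution experiments
#'   (`pair_mixes` mixes per pair) under the same configuration.
#' @param N nodes per network (default 1000).
#' @param pair_mixes substitution mixes per pair when fitting `curves`.
#' @return A list of class `triple_spread`: `samples` (data frame with
#'   counts, `avg_degree`, `H_T`, `found`, `inside`, `regions`),
#'   `fraction_inside` (of the samples with a found tipping point),
#'   `curves`, and the triple.
#' @export
triple_spread_experiment <- function(degree_triple, n_samples,
                                     cfg = sweep_config(), curves = NULL,
                                     N = 1000L, pair_mixes = 11L) {
  degree_triple <- sort(as.integer(degree_triple))
  stopifnot(length(degree_triple) == 3L,
            !anyDuplicated(degree_triple), n_samples >= 1L)
  pairs <- list(degree_triple[c(1L, 2L)], degree_triple[c(2L, 3L)],
                degree_triple[c(1L, 3L)])
  if (is.null(curves)) {
    curves <- lapply(seq_along(pairs), function(p) {
      mixes <- make_substitution_sequences(
        N, pairs[[p]],
        stride = max(1L, as.integer(ceiling(N / (pair_mixes - 1L)))))
      cfg_p <- cfg
      cfg_p$base_seed <- derive_seed(cfg$base_seed, 900000L + p, 1L)
      fit_boundary(run_substitution_experiment(mixes, cfg_p))
    })
  }
  set.seed(derive_seed(cfg$base_seed, 990000L, 1L))
  comp <- t(replicate(n_samples, {
    bars <- sort(sample.int(N + 2L, 2L))
    c(bars[1L] - 1L, bars[2L] - bars[1L] - 1L, N + 2L - bars[2L])
  }))
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    mix <- structure(list(degree_types = degree_triple,
                          counts = as.integer(comp[i, ]), N = N),
                     class = "degree_mix")
    cfg_i <- cfg
    cfg_i$base_seed <- derive_seed(cfg$base_seed, 991000L + i, 1L)
    rec <- run_substitution_experiment(list(mix), cfg_i)
    regions <- if (rec$found)
      classify_point(rec$avg_degree, rec$H_T, curves) else character(0)
    rows[[i]] <- data.frame(
      counts = paste(comp[i, ], collapse = "+"),
      avg_degree = rec$avg_degree, H_T = rec$H_T, found = rec$found,
      inside = rec$found && length(regions) > 0L,
      regions = paste(regions, collapse = " "))
  }
  samples <- do.call(rbind, rows)
  structure(list(degree_triple = degree_triple, samples = samples,
                 fraction_inside = mean(samples$inside[samples$found]),
                 curves = curves),
            class = "triple_spread")
}

#' @export
print.triple_spread <- function(x, ...) {
  cat(sprintf("Three-degree tipping spread (%s): %d samples, %.1f%% inside the pairwise envelope\n",
              paste(x$degree_triple, collapse = ","),
              nrow(x$samples), 100 * x$fraction_inside))
  invisible(x)
}

#' @export
plot.boundary_curve <- function(x, ..., add = FALSE, n_grid = 101L,
                                col = "steelblue") {
  grid <- seq(x$domain[1L], x$domain[2L], length.out = n_grid)
  y <- predict(x, grid)
  if (!add)
    graphics::plot(grid, y, type = "l", col = col,
                   xlab = "average degree <k>", ylab = expression(H[T]), ...)
  else graphics::lines(grid, y, col = col, ...)
  graphics::segments(x$domain[1L], x$endpoints[1L],
                     x$domain[2L], x$endpoints[2L], lty = 2, col = col)
  invisible(x)
}

#' Serialize boundary curves to JSON
#'
#' @param curves list of `boundary_curve`s.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_boundary_json <- function(curves, path) {
  payload <- lapply(curves, function(cu)
    list(pair = cu$pair, coef = as.list(cu$coef), domain = cu$domain,
         rms = cu$rms, endpoints = cu$endpoints, n = cu$n,
         tolerance = default_tolerance(cu)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
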