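#' Sweep configuration
#'
#' Bundles the protocol parameters for quasi-static field sweeps. Defaults
#' reproduce the reference protocol: temperature held at 1 while the
#' external field is stepped through 1000 equally spaced values over the
#' closed interval \[-10, 10\] (grid spacing 20/999), one full asynchronous
#' sweep per field value, spins carried over between steps.
#'
#' @param temperature temperature T > 0 (default 1).
#' @param field_range closed field interval swept (default `c(-10, 10)`).
#' @param n_steps number of field values, endpoints included (default 1000).
#' @param sweeps_per_step full update passes per field value (default 1).
#' @param direction `"increasing"` (spins start all -1) or `"decreasing"`
#'   (spins start all +1, field swept downward).
#' @param n_replicates Monte-Carlo replicates per degree mix (default 1).
#' @param replicate_mode `"fresh"` builds a new random network for every
#'   replicate (network disorder averaged with thermal noise);
#'   `"fixed"` reuses the first replicate's network and redraws only the
#'   thermal trajectory.
#' @param base_seed integer seed from which per-mix, per-replicate child
#'   seeds are derived (see [derive_seed()]).
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(temperature = 1, field_range = c(-10, 10),
                         n_steps = 1000L, sweeps_per_step = 1L,
                         direction = c("increasing", "decreasing"),
                         n_replicates = 1L,
                         replicate_mode = c("fresh", "fixed"),
                         base_seed = 1L) {
  direction <- match.arg(direction)
  replicate_mode <- match.arg(replicate_mode)
  stopifnot(temperature > 0, length(field_range) == 2L,
            field_range[1L] < field_range[2L], n_steps >= 2L,
            sweeps_per_step >= 1L, n_replicates >= 1L)
  structure(list(temperature = temperature, field_range = field_range,
                 n_steps = as.integer(n_steps),
                 sweeps_per_step = as.integer(sweeps_per_step),
                 direction = direction,
                 n_replicates = as.integer(n_replicates),
                 replicate_mode = replicate_mode,
                 base_seed = as.integer(base_seed)),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat("Sweep config: T =", x$temperature, ", H in [",
      x$field_range[1L], ",", x$field_range[2L], "] x", x$n_steps,
      "steps,", x$sweeps_per_step, "sweep(s)/step,", x$direction, "\n")
  cat("  replicates:", x$n_replicates, "(", x$replicate_mode,
      "network ), base seed", x$base_seed, "\n")
  invisible(x)
}

#' Deterministic child-seed derivation
#'
#' Child seed for replicate `replicate` of mix `mix` under `base` seed.
#' Pure integer arithmetic below 2^31, so runs are bit-reproducible. When
#' `mix` identifies the degree mix intrinsically (see [mix_fingerprint()]),
#' results are invariant to the order in which mixes are processed.
#'
#' @param base base seed (integer).
#' @param mix mix index or fingerprint (non-negative integer).
#' @param replicate replicate index (1-based).
#' @return A positive integer seed.
#' @export
derive_seed <- function(base, mix, replicate) {
  p <- 2147483587 # large prime < 2^31
  s <- ((base %% p) * 1000003 + mix * 7919 + replicate * 104729) %% p
  as.integer(s + 1)
}

#' Integer fingerprint of a degree mix
#'
#' Order-independent identifier of a mix (a polynomial hash of its degree
#' types and counts), used by [run_substitution_experiment()] to derive
#' per-mix child seeds that do not depend on the mix's position in a list.
#'
#' @param mix a `degree_mix`.
#' @return A non-negative integer below 2^31.
#' @export
mix_fingerprint <- function(mix) {
  stopifnot(inherits(mix, "degree_mix"))
  p <- 2147480009
  h <- 17
  for (v in c(length(mix$degree_types), rbind(mix$degree_types, mix$counts)))
    h <- (h * 8191 + v) %% p
  as.integer(h)
}

new_transition_curve <- function(control, M, direction, control_param,
                                 n_replicates = 1L) {
  structure(data.frame(control = control, M = M),
            direction = direction, control_param = control_param,
            n_replicates = n_replicates,
            class = c("transition_curve", "data.frame"))
}

#' Quasi-static hysteresis sweep of the external field
#'
#' Runs the asynchronous spin dynamic while the external field is stepped
#' across `cfg$field_range` in `cfg$n_steps` equally spaced values
#' (endpoints included). For an increasing sweep all spins start at -1 (the
#' deeply stable branch at strongly negative field); for a decreasing sweep
#' all start at +1 and the field is stepped downward. The spin state is
#' carried over between field values, so the system tracks a stable branch
#' until it tips — the mechanism behind the hysteresis loop.
#'
#' @param net a `multinet`.
#' @param cfg a [sweep_config()].
#' @return A `transition_curve`: data frame with columns `control` (field)
#'   and `M` (magnetization), plus direction metadata.
#' @export
run_hysteresis_sweep <- function(net, cfg = sweep_config()) {
  stopifnot(inherits(net, "multinet"), inherits(cfg, "sweep_config"))
  grid <- seq(cfg$field_range[1L], cfg$field_range[2L],
              length.out = cfg$n_steps)
  if (cfg$direction == "decreasing") grid <- rev(grid)
  init <- if (cfg$direction == "increasing") -1L else 1L
  spins <- rep.int(init, net$n_nodes)
  a <- as_adjacency(net)
  M <- sweep_curve_cpp(a$ptr, a$adj, spins,
                       rep.int(cfg$temperature, cfg$n_steps), grid,
                       cfg$sweeps_per_step)
  new_transition_curve(grid, M, cfg$direction, "H")
}

#' Temperature sweep across the pitchfork bifurcation
#'
#' Starts from the fully ordered state (all spins +1) and steps the
#' temperature upward along `temp_grid` at fixed field, recording the
#' magnetization at each value. The ensemble curve decays smoothly toward 0
#' at high temperature — a qualitatively different, non-abrupt transition
#' compared to the field-driven hysteresis case.
#'
#' @param net a `multinet`.
#' @param temp_grid increasing vector of temperatures, all > 0.
#' @param H fixed external field (default 0).
#' @param sweeps_per_step update passes per temperature value.
#' @return A `transition_curve` with `control` = temperature.
#' @export
run_pitchfork_sweep <- function(net, temp_grid, H = 0,
                                sweeps_per_step = 1L) {
  stopifnot(inherits(net, "multinet"), all(temp_grid > 0),
            !is.unsorted(temp_grid))
  spins <- rep.int(1L, net$n_nodes)
  a <- as_adjacency(net)
  M <- sweep_curve_cpp(a$ptr, a$adj, spins, as.numeric(temp_grid),
                       rep.int(as.numeric(H), length(temp_grid)),
                       as.integer(sweeps_per_step))
  new_transition_curve(as.numeric(temp_grid), M, "increasing", "T")
}

#' Pointwise mean of replicate transition curves
#'
#' @param curves list of `transition_curve`s sharing the same control grid
#'   and direction.
#' @return A `transition_curve` whose `M` is the pointwise arithmetic mean;
#'   `n_replicates` records the number averaged.
#' @export
aggregate_mean_curve <- function(curves) {
  stopifnot(length(curves) >= 1L)
  ref <- curves[[1L]]
  for (cu in curves) {
    if (!isTRUE(all.equal(cu$control, ref$control)) ||
        !identical(attr(cu, "direction"), attr(ref, "direction")))
      stop("curves must share an identical control grid and direction")
  }
  M <- rowMeans(vapply(curves, function(cu) cu$M, numeric(nrow(ref))))
  new_transition_curve(ref$control, M, attr(ref, "direction"),
                       attr(ref, "control_param"),
                       n_replicates = length(curves))
}

#' @export
print.transition_curve <- function(x, ...) {
  cat("Transition curve:", attr(x, "control_param"), "swept",
      attr(x, "direction"), "over [", format(min(x$control)), ",",
      format(max(x$control)), "] in", nrow(x), "steps; mean of",
      attr(x, "n_replicates"), "replicate(s)\n")
  invisible(x)
}

#' @export
plot.transition_curve <- function(x, ...,
                                  xlab = attr(x, "control_param"),
                                  ylab = "magnetization M", type = "l") {
  graphics::plot(x$control, x$M, xlab = xlab, ylab = ylab, type = type,
                 ylim = c(-1, 1), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Extract the tipping point from an increasing transition curve
#'
#' The tipping point `H_T` is the first control value at which the
#' magnetization has passed half of the whole state transition, i.e. the
#' first value with `M > 0`. It is reported as the grid value itself (no
#' interpolation); the grid spacing bounds the quantization error. A
#' decreasing curve is mirrored (`control -> -control`, `M -> -M`,
#' re-ordered) before extraction, so its reported value is the mirrored
#' tipping field.
#'
#' @param curve a `transition_curve` over the field.
#' @return A list of class `tipping_record`: `H_T` (`NA` when the curve
#'   never crosses), `found`, and the curve's replicate count.
#' @examples
#' cu <- spintip:::new_transition_curve(c(0, .5, 1, 1.5, 2),
#'                                      c(-1, -1, -.2, .4, .9),
#'                                      "increasing", "H")
#' extract_tipping(cu)$H_T # 1.5
#' @export
extract_tipping <- function(curve) {
  stopifnot(inherits(curve, "transition_curve"))
  if (identical(attr(curve, "direction"), "decreasing"))
    curve <- mirror_curve(curve)
  hit <- which(curve$M > 0)
  structure(list(H_T = if (length(hit)) curve$control[hit[1L]] else NA_real_,
                 found = length(hit) > 0L,
                 n_replicates = attr(curve, "n_replicates")),
            class = "tipping_record")
}

#' Mirror a transition curve under global spin-flip symmetry
#'
#' Applies `control -> -control`, `M -> -M` and restores increasing order;
#' under the spin-flip symmetry of the dynamics a decreasing sweep is
#' statistically equivalent to the mirror of an increasing one.
#'
#' @param curve a `transition_curve`.
#' @return The mirrored `transition_curve` (direction flag flipped).
#' @export
mirror_curve <- function(curve) {
  dir <- if (identical(attr(curve, "direction"), "increasing"))
    "decreasing" else "increasing"
  ctrl <- -curve$control
  ord <- order(ctrl)
  new_transition_curve(ctrl[ord], -curve$M[ord], dir,
                       attr(curve, "control_param"),
                       attr(curve, "n_replicates"))
}

#' @export
print.tipping_record <- function(x, ...) {
  if (x$found) cat("Tipping point H_T =", format(x$H_T), "( mean of",
                   x$n_replicates, "replicate(s) )\n")
  else cat("No tipping point found within the swept interval\n")
  invisible(x)
}

#' Tipping points across a set of degree substitutions
#'
#' For every degree mix: expand the mix to a degree sequence, repair it to
#' even sum, build configuration-model network(s), run replicate hysteresis
#' sweeps, average the curves, and extract the tipping point. Child seeds
#' are derived from `cfg$base_seed`, an integer fingerprint of the mix
#' (its degree types and counts) and the replicate index, so results are
#' bit-reproducible and invariant to the order of the mixes list.
#' Under `replicate_mode = "fresh"` every replicate gets a newly drawn
#' network; under `"fixed"` the first replicate's network is reused.
#'
#' @param mixes a `degree_mix_set`, or a list of `degree_mix` objects.
#' @param cfg a [sweep_config()]; `n_replicates` replicates per mix.
#' @param keep_curves if `TRUE`, the aggregated mean curve of each mix is
#'   attached as attribute `"curves"` (a list) on the result.
#' @param progress print one line per mix.
#' @return A `tipping_table`: data frame with one row per mix and columns
#'   `degree_types`, `counts`, `avg_degree`, `H_T`, `found`,
#'   `n_replicates`, `seed` (first child seed of the mix).
#' @export
run_substitution_experiment <- function(mixes, cfg = sweep_config(),
                                        keep_curves = FALSE,
                                        progress = FALSE) {
  if (inherits(mixes, "degree_mix_set"))
    mixes <- lapply(seq_len(length(mixes)), function(i) mixes[[i]])
  stopifnot(length(mixes) >= 1L,
            all(vapply(mixes, inherits, logical(1), "degree_mix")))
  n_mix <- length(mixes)
  rows <- vector("list", n_mix)
  curves <- if (keep_curves) vector("list", n_mix) else NULL
  for (i in seq_len(n_mix)) {
    mix <- mixes[[i]]
    fp <- mix_fingerprint(mix)
    reps <- vector("list", cfg$n_replicates)
    net_fixed <- NULL
    for (r in seq_len(cfg$n_replicates)) {
      set.seed(derive_seed(cfg$base_seed, fp, r))
      if (cfg$replicate_mode == "fixed" && !is.null(net_fixed)) {
        net <- net_fixed
      } else {
        net <- build_network(repair_graphical(expand_mix(mix)))
        if (cfg$replicate_mode == "fixed") net_fixed <- net
      }
      reps[[r]] <- run_hysteresis_sweep(net, cfg)
    }
    mean_curve <- aggregate_mean_curve(reps)
    tip <- extract_tipping(mean_curve)
    rows[[i]] <- data.frame(
      degree_types = paste(mix$degree_types, collapse = "+"),
      counts = paste(mix$counts, collapse = "+"),
      avg_degree = mix_avg_degree(mix),
      H_T = tip$H_T, found = tip$found,
      n_replicates = cfg$n_replicates,
      seed = derive_seed(cfg$base_seed, fp, 1L))
    if (keep_curves) curves[[i]] <- mean_curve
    if (progress)
      message(sprintf("mix %d/%d <k>=%.3f H_T=%s", i, n_mix,
                      rows[[i]]$avg_degree, format(tip$H_T)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tipping_table", "data.frame")
  if (keep_curves) attr(out, "curves") <- curves
  out
}

#' @export
plot.tipping_table <- function(x, ..., xlab = "average degree <k>",
                               ylab = expression(H[T]), pch = 16) {
  graphics::plot(x$avg_degree, x$H_T, xlab = xlab, ylab = ylab,
                 pch = pch, ...)
  invisible(x)
}

#' Write or read a tipping table as CSV
#'
#' @param table a `tipping_table`.
#' @param path file path.
#' @return `read_tipping_table` returns a `tipping_table`;
#'   `write_tipping_table` returns `path` invisibly.
#' @export
write_tipping_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tipping_table
#' @export
read_tipping_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("tipping_table", "data.frame")
  out
}

#' Write a transition curve as CSV
#'
#' Columns: `control_value`, `mean_spin`, `n_replicates`, `direction`.
#'
#' @param curve a `transition_curve`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_transition_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(control_value = curve$control, mean_spin = curve$M,
               n_replicates = attr(curve, "n_replicates"),
               direction = attr(curve, "direction")),
    path, row.names = FALSE)
  invisible(path)
}
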