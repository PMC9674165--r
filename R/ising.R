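#' Energy gain of flipping a spin
#'
#' The energy a spin `s` can gain by flipping, given the sum `G` of its
#' neighbourhood spins (counted with edge multiplicity) and the external
#' field `H`: `E = 2 s (G + H)`. Negative values mean the flip is
#' energetically favourable. Vectorized over all arguments.
#'
#' @param s spin value(s), each -1 or +1.
#' @param G neighbourhood spin sum(s).
#' @param H external field.
#' @return Numeric energy gain.
#' @examples
#' energy_gain(-1, -4, 0) # 8: a down spin in a down neighbourhood is stable
#' @export
energy_gain <- function(s, G, H) {
  if (!all(abs(s) == 1)) stop("spins must be -1 or +1")
  2 * s * (G + H)
}

#' Metropolis-style flip rule
#'
#' A spin flips if the energy gain `E` is non-positive, or with probability
#' `exp(-E / T)` otherwise. The uniform draw `u` (half-open `[0, 1)`) is
#' supplied by the caller, making the rule a pure deterministic function.
#' Vectorized.
#'
#' @param E energy gain(s) from [energy_gain()].
#' @param temp temperature, > 0.
#' @param u uniform draw(s) in `[0, 1)`.
#' @return Logical: flip or not.
#' @examples
#' flip_decision(-8, 1, 0.999) # TRUE: favourable flips always happen
#' flip_decision(2, 1, 0.10)   # TRUE: 0.10 < exp(-2)
#' @export
flip_decision <- function(E, temp, u) {
  stopifnot(temp > 0)
  E <= 0 | u < exp(-E / temp)
}

#' Neighbourhood spin sum of a node
#'
#' Sum of the spins at the other end of every edge-end incident to `node`,
#' counted with multiplicity: a double edge contributes its neighbour's
#' spin twice, and a self-loop contributes the node's own spin twice (both
#' ends of the loop). Hence `abs(G) <= degree(node)`.
#'
#' @param net a `multinet`.
#' @param spins integer vector of -1/+1 spins, one per node.
#' @param node node id (1-based).
#' @return Integer spin sum G.
#' @export
neighborhood_sum <- function(net, spins, node) {
  stopifnot(inherits(net, "multinet"), length(spins) == net$n_nodes)
  if (node < 1 || node > net$n_nodes) stop("unknown node id: ", node)
  e <- net$edges
  sum(spins[e[e[, 1L] == node, 2L]]) + sum(spins[e[e[, 2L] == node, 1L]])
}

#' One or more asynchronous update sweeps
#'
#' Performs `n_sweeps` full passes over the network. Each pass visits every
#' node exactly once in a fresh uniformly random order; at each visit the
#' neighbourhood sum is recomputed from the *current* state (asynchronous,
#' in-place updating), [energy_gain()] is evaluated and the flip accepted
#' per [flip_decision()] with a fresh uniform draw. Randomness comes from
#' R's RNG stream: `set.seed()` makes the trajectory bit-reproducible.
#'
#' @param net a `multinet`.
#' @param spins integer -1/+1 vector of length `n_nodes`.
#' @param temp temperature, > 0.
#' @param H external field.
#' @param n_sweeps number of full passes (default 1).
#' @return The updated spin vector.
#' @export
sweep_update <- function(net, spins, temp, H, n_sweeps = 1L) {
  stopifnot(inherits(net, "multinet"), length(spins) == net$n_nodes,
            all(abs(spins) == 1), temp > 0, n_sweeps >= 1)
  a <- as_adjacency(net)
  ising_sweeps_cpp(a$ptr, a$adj, as.integer(spins), temp, H,
                   as.integer(n_sweeps))
}

#' Mean-field magnetization: fixed point of M = tanh((M + H) / T)
#'
#' Damped fixed-point iteration on the mean-field self-consistency map.
#' Which fixed point is reached depends on `init`: below the pitchfork
#' temperature T = 1 (at H = 0) the map has two symmetric nonzero roots
#' reached from `init = +1` / `init = -1`, plus the unstable zero root;
#' above it only M = 0 remains. The iteration converges to a *stable* root
#' on the same side as `init`.
#'
#' @param temp temperature, > 0.
#' @param H external field (default 0).
#' @param init starting magnetization in `[-1, 1]`.
#' @param damping step fraction in (0, 1]; 0.5 is robust.
#' @param tol residual tolerance `|M - tanh((M+H)/T)|` (default 1e-12).
#' @param max_iter iteration cap.
#' @return The fixed-point magnetization.
#' @examples
#' mean_field_magnetization(2, 0, init = 0.5)    # 0: disordered
#' mean_field_magnetization(0.5, 0, init = 1)    # ~0.9575: ordered branch
#' @export
mean_field_magnetization <- function(temp, H = 0, init = 1, damping = 0.5,
                                     tol = 1e-12, max_iter = 500000L) {
  stopifnot(temp > 0, init >= -1, init <= 1, damping > 0, damping <= 1)
  M <- init
  for (i in seq_len(max_iter)) {
    tgt <- tanh((M + H) / temp)
    if (abs(M - tgt) < tol) return(M)
    M <- (1 - damping) * M + damping * tgt
  }
  stop("mean-field iteration did not converge; last residual ",
       format(abs(M - tanh((M + H) / temp))))
}
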