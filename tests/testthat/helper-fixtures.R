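# Small builders used across test files. All fixtures are constructed in
# code; no data files.

mk_mix <- function(types, counts, N = sum(counts)) {
  structure(list(degree_types = as.integer(types),
                 counts = as.integer(counts), N = as.integer(N)),
            class = "degree_mix")
}

# Hand-built multigraph from an explicit 1-based edge matrix.
mk_net <- function(n, edges) {
  net <- structure(list(n_nodes = as.integer(n),
                        edges = matrix(as.integer(edges), ncol = 2L,
                                       byrow = TRUE),
                        degrees = NULL),
                   class = "multinet")
  net$degrees <- network_degrees(net)
  net
}

mk_curve <- function(control, M, direction = "increasing",
                     control_param = "H") {
  structure(data.frame(control = control, M = M),
            direction = direction, control_param = control_param,
            n_replicates = 1L,
            class = c("transition_curve", "data.frame"))
}

# Independent pure-R replay of one asynchronous sweep, consuming R's RNG
# stream in exactly the same call order as the compiled kernel
# (Fisher-Yates permutation first, then one uniform per visit). Used to
# cross-check the C++ path bit-for-bit under a shared seed.
r_sweep_oracle <- function(net, spins, temp, H) {
  n <- net$n_nodes
  e <- net$edges
  ord <- seq_len(n)
  for (i in seq(n, 2L)) {
    j <- floor(runif(1) * i) + 1L
    if (j > i) j <- i
    tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
  }
  for (node in ord) {
    G <- sum(spins[e[e[, 1L] == node, 2L]]) +
      sum(spins[e[e[, 2L] == node, 1L]])
    E <- 2 * spins[node] * (G + H)
    u <- runif(1)
    if (E <= 0 || u < exp(-E / temp)) spins[node] <- -spins[node]
  }
  spins
}

# Brute-force enumeration of all compositions of N into m non-negative
# parts (independent of the package's recursive generator).
brute_compositions <- function(N, m) {
  grid <- do.call(expand.grid, rep(list(0:N), m))
  as.matrix(grid[rowSums(grid) == N, , drop = FALSE])
}

# Homogeneous-degree tipping estimate at reduced size, shared by tests.
homog_tip <- function(k, n_nodes, n_reps, seed, n_steps = 1000L) {
  cfg <- sweep_config(n_steps = n_steps, n_replicates = n_reps,
                      base_seed = seed)
  tab <- run_substitution_experiment(list(mk_mix(k, n_nodes)), cfg)
  tab$H_T
}
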