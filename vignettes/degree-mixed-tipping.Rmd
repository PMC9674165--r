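---
title: "Tipping points in degree-mixed networked spin systems: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tipping points in degree-mixed networked spin systems: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spintip)
```

## The model

`spintip` studies how the degree sequence of a network shapes the onset of
a critical transition in an Ising-type spin system.

**Networks.** A degree sequence $(k_1, \dots, k_N)$ is realized as a random
multigraph with the configuration model: every node contributes $k_i$
stubs, the stub list is permuted uniformly at random and paired
consecutively — equivalent to repeatedly joining two uniformly chosen free
stubs, but a single permutation. Sequences with odd degree sum cannot be
paired; one uniformly chosen odd-degree entry is removed first
(`repair_graphical()`), shortening the sequence by one node. Self-loops and
multi-links are *kept*: erasing or rewiring them would distort the degree
sequence, and their share of edges vanishes as $N$ grows (an explicit
stochastic test in the suite compares $N = 50$ against $N = 500$). No
connectivity is enforced; small disconnected components may tip on their
own, which is part of the degree-mixing effect rather than an artifact.

**Dynamics.** Spins $s_i = \pm 1$ live on the nodes. One *sweep* visits
every node exactly once in a fresh uniformly random order; at each visit
the neighbourhood sum $G$ (spins at the other end of every incident
edge-end, so a double edge counts its neighbour twice) is recomputed from
the current state, the energy gain of flipping is

$$E = 2 s (G + H),$$

and the spin flips if $E \le 0$, or with probability $e^{-E/T}$ otherwise.
Updates are asynchronous and in place; a synchronous scheme would let
neighbouring spins flip simultaneously and oscillate artificially. The
visit order is resampled every sweep rather than fixed once, so no node is
systematically early. The uniform draw is taken on every visit even when
$E \le 0$ makes it redundant, which keeps the RNG stream layout fixed;
$e^{-E/T}$ itself is only evaluated for $E > 0$ so tiny temperatures cannot
overflow the exponent.

**Self-loop convention.** A self-loop contributes $2 s_i$ to node $i$'s own
neighbourhood sum — both ends of the loop — consistent with loops adding 2
to the degree. Loops are rare at the default $N = 1000$ (a fraction of a
percent of edges), so this choice is immaterial to results, but it is fixed
and unit-tested.

**Mean-field reference.** The self-consistency map
$M = \tanh\!\big((M + H)/T\big)$ is solved by damped fixed-point iteration
($M \leftarrow (1-d)\,M + d \tanh((M+H)/T)$, default damping $d = 0.5$,
residual tolerance $10^{-12}$). The branch reached follows the
initialization: below the pitchfork temperature $T = 1$ (at $H = 0$) the
two stable ordered roots are reached from `init = +1` / `init = -1`. The
solver is validated against a bisection oracle (`uniroot`) to $10^{-8}$
across a $(T, H)$ grid. Exactly *at* $T = 1, H = 0$ convergence is
algebraic (the map is tangent to the identity) and the solver should not be
used there.

## The sweep protocol and its parameters

`sweep_config()` defaults encode the reference protocol:

| parameter | default | meaning |
|---|---|---|
| `temperature` | 1 | dimensionless $T$; low enough that the stability landscape is bistable for all degrees studied |
| `field_range` | $[-10, 10]$ | closed interval swept by $H$ |
| `n_steps` | 1000 | equally spaced field values, endpoints included (spacing $20/999 \approx 0.02$) |
| `sweeps_per_step` | 1 | full passes per field value |
| `n_replicates` | 1 | replicate networks/trajectories averaged per mix |
| `replicate_mode` | `"fresh"` | new random network per replicate |

An increasing sweep starts from all spins down — the deeply stable branch
at $H = -10$ — and carries the state from one field value to the next
(quasi-static driving; re-initializing at every step would destroy the
hysteresis that defines the transition). The tipping point $H_T$ is the
first grid value at which the replicate-averaged magnetization exceeds 0;
it is reported as the grid value itself, not an interpolated crossing, so
the grid spacing ($\approx 0.02$) bounds the quantization error — an
*approximate* tipping point by construction.

Two choices here were genuinely open:

* **Equilibration.** One sweep per field value is the default: with 1000
  field steps the driving is slow compared to the relaxation of the system,
  and the homogeneous degree-4 reference then tips at $H_T \approx 1.37$,
  matching the reference value 1.36 well within the grid resolution and
  replicate noise. `sweeps_per_step` stays configurable for sensitivity
  checks.
* **Replicates.** Whether replicate curves should share one network or each
  draw a fresh one is ambiguous when both network disorder and thermal
  noise matter. The default (`"fresh"`) averages over both; `"fixed"`
  isolates thermal noise. Both are exposed, and the tipping tables record
  which was used.

Child seeds are derived arithmetically from the base seed, an
order-independent fingerprint of the degree mix, and the replicate index
(`derive_seed()`, `mix_fingerprint()`), so a run is bit-reproducible and
unchanged by reordering the mix list.

## Degree substitution and its enumeration

Substitutions are represented by *counts per degree type*, not position-wise
sequences: the configuration model is exchangeable over node labels, so
only the multiset of degrees matters, and the count representation avoids
an astronomically redundant enumeration. The full grid over $m$ types has
$\binom{N+m-1}{m-1}$ mixes — 1001 for two types at $N = 1000$, but 501,501
for three. For $m \ge 3$ an optional `stride` thins the count grid (kept in
the output metadata); the three-degree experiments here instead *sample*
compositions uniformly (`triple_spread_experiment()`), which covers the
simplex without committing to a particular sub-grid.

## Boundary curves, regions, and their tolerances

For one degree pair $(k_1, k_2)$ the tipping points of its mixes are fitted
with an unconstrained least-squares quadratic in the average degree
$\langle k \rangle$ — "parabolic" is an empirical description, not a
constraint, and the RMS residual is kept with the curve so the fit quality
is auditable. The pair's *tipping region* is bounded below by the fitted
curve and above by the straight chord joining its simulated homogeneous
endpoints; homogeneous reference points are always simulated, never assumed
linear in $k$ (they are not). Containment and nesting verdicts use a
tolerance of $\max(2 \times \text{RMS residual}, \text{one grid step})$:
twice the fit scatter, but never tighter than the field quantization.
Nesting of two curves is decided on a shared evaluation grid over the inner
pair's domain (verdicts are checked to be stable under grid refinement);
curves whose degree intervals are not nested are reported "not comparable"
rather than forced into a verdict.

For three-degree mixes, a point counts as *inside the envelope* when at
least one of the triple's three pairwise regions contains it. The reference
observation is only that escaping the envelope is statistically unlikely,
with no printed rate; the $\ge 90\%$ bound asserted in the acceptance suite
is an implementer-chosen conservative stand-in.

## What the tests simulate, and at what size

The acceptance suite runs the full reference protocol ($N = 1000$, 1000
field steps, 50 replicates) for the three headline tipping points, 30
replicates per degree for the monotonicity check, and reduced substitution
experiments ($N = 500$, 11 mixes per pair, 20 replicates) for the
nesting/forbidden-region structure, plus 100 sampled three-degree mixes at
5 replicates for the envelope check. These sizes keep the whole suite
around a minute on one core while leaving the Monte-Carlo noise far below
the tolerances asserted; the compiled sweep kernel makes the full-size
protocol cheap (a 50-replicate headline estimate takes a couple of
seconds). The unit suite separately pins the kernel itself: the compiled
sweep is replayed bit-for-bit by an independent pure-R implementation under
a shared RNG stream.

## What the generator does and does not emulate

The synthetic networks are exactly the objects under study — there is no
external data. What the simulations therefore show is a property of
configuration-model ensembles with prescribed degree counts: conclusions
about real networks carry over only insofar as a real system resembles a
uniformly random multigraph with that degree sequence. Degree-degree
correlations, clustering, community structure, weighted couplings
($J \ne 1$), heterogeneous per-node fields, and mechanisms beyond the
single-spin-flip Metropolis rule (cluster updates, Glauber heat-bath rates)
are all out of scope. The mean-field solver describes the fully connected
limit and serves as an analytic reference for the bifurcation structure,
not as an approximation of the simulated networks.

## Known limitations

* $H_T$ inherits the field grid's quantization (one step
  $\approx 0.02$); comparisons finer than that need a denser grid.
* Near-degenerate sweeps (very small networks, temperatures far above 1)
  may never cross $M > 0$; records then carry a `found = FALSE` flag
  rather than a value, and downstream fits drop them.
* The pitchfork temperature sweep gives a smooth transition with no
  unambiguous tipping point; it is provided for comparison, and tipping
  extraction is deliberately not defined for it.
* Boundary curves are valid only on their fitted degree interval;
  extrapolation beyond it is refused rather than attempted.
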