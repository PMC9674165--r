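test_that("field grid covers the closed interval in equal steps", {
  cfg <- sweep_config()
  expect_equal(cfg$temperature, 1)
  expect_equal(cfg$field_range, c(-10, 10))
  expect_equal(cfg$n_steps, 1000L)
  set.seed(1)
  net <- build_network(rep(2L, 20))
  cu <- run_hysteresis_sweep(net, sweep_config(n_steps = 5,
                                               field_range = c(-1, 1)))
  expect_equal(cu$control, seq(-1, 1, length.out = 5))
  # default spacing 20/999
  grid <- seq(-10, 10, length.out = 1000)
  expect_equal(unique(round(diff(grid), 12)), 20 / 999)
  expect_error(sweep_config(field_range = c(2, 1)))
  expect_error(sweep_config(n_steps = 1))
})

test_that("increasing sweeps start deeply down and saturate up", {
  set.seed(2)
  net <- build_network(rep(4L, 200))
  cu <- run_hysteresis_sweep(net, sweep_config(n_steps = 300))
  expect_lte(cu$M[1], -0.99)     # all-down start at H = -10 is stable
  expect_gte(cu$M[nrow(cu)], 0.99) # H = +10 saturates every spin
  expect_true(all(abs(cu$M) <= 1))
  # decreasing sweep starts from the opposite branch
  cu_dn <- run_hysteresis_sweep(net, sweep_config(n_steps = 300,
                                                  direction = "decreasing"))
  expect_gte(cu_dn$M[1], 0.99)
  expect_equal(cu_dn$control, rev(cu$control))
})

test_that("pitchfork temperature sweep decays from order to disorder", {
  set.seed(3)
  net <- build_network(rep(4L, 1000))
  tgrid <- seq(0.01, 10, length.out = 250)
  cu <- run_pitchfork_sweep(net, tgrid, sweeps_per_step = 2)
  expect_gte(cu$M[1], 0.99)            # effectively zero temperature
  expect_lte(abs(cu$M[nrow(cu)]), 0.1) # disordered tail
  # ensemble mean, binned, is monotonically non-increasing (small slack)
  reps <- lapply(1:10, function(r) {
    set.seed(100 + r)
    run_pitchfork_sweep(build_network(rep(4L, 1000)), tgrid,
                        sweeps_per_step = 2)
  })
  m <- aggregate_mean_curve(reps)$M
  binned <- colMeans(matrix(m, nrow = 25)) # 10 bins of 25 steps
  expect_true(all(diff(binned) <= 0.02))
})

test_that("mean-curve aggregation is a pointwise arithmetic mean", {
  cu <- mk_curve(1:4, c(-1, -0.5, 0.5, 1))
  agg <- aggregate_mean_curve(list(cu, cu, cu))
  expect_equal(agg$M, cu$M)
  expect_equal(attr(agg, "n_replicates"), 3L)
  neg <- mk_curve(1:4, -cu$M)
  expect_equal(aggregate_mean_curve(list(cu, neg))$M, rep(0, 4))
  expect_error(aggregate_mean_curve(list(cu, mk_curve(2:5, cu$M))),
               "identical control grid")
})

test_that("replicate averaging shrinks the pointwise standard error ~ 1/sqrt(n)", {
  set.seed(44)
  net <- build_network(rep(4L, 100))
  cfg <- sweep_config(field_range = c(0, 3), n_steps = 40)
  one_curve <- function() run_hysteresis_sweep(net, cfg)
  batch_mean <- function(n) {
    agg <- aggregate_mean_curve(replicate(n, one_curve(), simplify = FALSE))
    agg$M[20] # mid-transition point, where replicate noise is largest
  }
  # quadrupling the replicate count should halve the standard error;
  # enough batches that the sd estimates themselves are stable
  sd4 <- sd(replicate(100, batch_mean(4)))
  sd16 <- sd(replicate(50, batch_mean(16)))
  ratio <- sd4 / sd16
  expect_gt(ratio, 1.4) # expected 2, with Monte-Carlo slack
  expect_lt(ratio, 2.8)
})

test_that("tipping extraction takes the first grid value with M > 0", {
  cu <- mk_curve(c(0, 0.5, 1, 1.5, 2), c(-1, -1, -0.2, 0.4, 0.9))
  tip <- extract_tipping(cu)
  expect_equal(tip$H_T, 1.5)
  expect_true(tip$found)
  flat <- extract_tipping(mk_curve(1:5, rep(-0.8, 5)))
  expect_false(flat$found)
  expect_true(is.na(flat$H_T))
  # decreasing curves are mirrored before extraction
  dn <- mk_curve(rev(-cu$control), rev(-cu$M), direction = "decreasing")
  expect_equal(extract_tipping(dn)$H_T, 1.5)
})

test_that("hysteresis loop has positive width and mirror symmetry", {
  mixes <- list(mk_mix(4, 300))
  up_cfg <- sweep_config(n_replicates = 20, base_seed = 50)
  up <- run_substitution_experiment(mixes, up_cfg, keep_curves = TRUE)
  expect_true(up$found)
  expect_gt(up$H_T, 0) # increasing branch tips at positive field
  dn_cfg <- sweep_config(n_replicates = 20, base_seed = 50,
                         direction = "decreasing")
  dn <- run_substitution_experiment(mixes, dn_cfg, keep_curves = TRUE)
  # mirrored decreasing tipping sits at ~ -H_T: the loop has width ~ 2 H_T
  expect_equal(dn$H_T, up$H_T, tolerance = 0.25)
})

test_that("substitution records are reproducible and order-invariant", {
  mixes <- list(mk_mix(c(3, 5), c(100, 100)), mk_mix(4, 200))
  cfg <- sweep_config(n_steps = 200, n_replicates = 3, base_seed = 9)
  a <- run_substitution_experiment(mixes, cfg)
  b <- run_substitution_experiment(rev(mixes), cfg)
  expect_equal(a[order(a$degree_types), ], b[order(b$degree_types), ],
               ignore_attr = TRUE)
  # bit-reproducible end to end
  expect_identical(run_substitution_experiment(mixes, cfg), a)
  # fixed-network mode redraws only the thermal trajectory
  cfg_fx <- sweep_config(n_steps = 200, n_replicates = 3, base_seed = 9,
                         replicate_mode = "fixed")
  fx <- run_substitution_experiment(mixes, cfg_fx)
  expect_equal(nrow(fx), 2)
  # a sweep that never reaches the tipping field flags not-found
  cfg_short <- sweep_config(field_range = c(-1, 1), n_steps = 100,
                            n_replicates = 2, base_seed = 9)
  short <- run_substitution_experiment(list(mk_mix(4, 200)), cfg_short)
  expect_false(short$found)
})
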