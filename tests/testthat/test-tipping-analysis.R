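# Noiseless records lying exactly on a known polynomial
exact_records <- function(ks, f, types = "3+5") {
  data.frame(degree_types = types, counts = NA, avg_degree = ks,
             H_T = f(ks), found = TRUE, n_replicates = 1, seed = 1)
}

test_that("quadratic fit recovers noiseless coefficients to machine precision", {
  cu <- fit_boundary(exact_records(c(3, 4, 5), function(k) k^2))
  expect_equal(unname(coef(cu)), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(cu$domain, c(3, 5))
  expect_lt(cu$rms, 1e-10)
  expect_equal(predict(cu, 3.5), 3.5^2, tolerance = 1e-9)
  # collinear points: the quadratic term vanishes
  lin <- fit_boundary(exact_records(c(3, 3.5, 4, 5), function(k) 2 * k - 1))
  expect_lt(abs(coef(lin)["a"]), 1e-8)
  # guard rails
  expect_error(fit_boundary(exact_records(c(3, 5), function(k) k)),
               "at least 3")
  none <- exact_records(c(3, 4, 5), function(k) k)
  none$found <- FALSE
  expect_error(fit_boundary(none), "no record")
  expect_error(predict(cu, 6), "outside its fit domain")
})

test_that("mixed (3,5) boundary bows below the homogeneous chord", {
  mixes <- make_substitution_sequences(300, c(3, 5), stride = 30) # 11 mixes
  cfg <- sweep_config(n_replicates = 5, base_seed = 60)
  tab <- run_substitution_experiment(mixes, cfg)
  cu <- fit_boundary(tab)
  # at <k> = 4 the fitted curve sits strictly below the straight chord
  # joining the homogeneous-3 and homogeneous-5 endpoints
  expect_lt(predict(cu, 4), spintip:::chord_value(cu, 4))
  # and almost every m=2 record classifies into its own pair's region
  ok <- tab[tab$found, ]
  inside <- vapply(seq_len(nrow(ok)), function(i)
    "(3,5)" %in% classify_point(ok$avg_degree[i], ok$H_T[i], list(cu)),
    logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("span verdicts follow domain nesting and survive grid refinement", {
  # synthetic curves with the expected geometry: outer pair bows lower
  f_out <- function(k) 0.34 * k - 0.25 * (k - 3) * (6 - k) # (3,6), deep bow
  f_in <- function(k) 0.34 * k - 0.10 * (k - 4) * (5 - k)  # (4,5), shallow
  out36 <- fit_boundary(exact_records(seq(3, 6, by = 0.5), f_out, "3+6"))
  in45 <- fit_boundary(exact_records(seq(4, 5, by = 0.25), f_in, "4+5"))
  rep1 <- check_nesting(list(out36, in45), grid_n = 51)
  rep2 <- check_nesting(list(out36, in45), grid_n = 101)
  row <- rep1[rep1$outer == "(3,6)" & rep1$inner == "(4,5)", ]
  expect_true(row$comparable && row$spans)
  # verdict stable when the evaluation grid is refined
  expect_equal(rep1$spans, rep2$spans)
  # a curve trivially spans itself with zero gap
  self <- rep1[rep1$outer == "(3,6)" & rep1$inner == "(3,6)", ]
  expect_true(self$spans)
  expect_equal(self$worst_gap, 0)
  # disjoint domains are not comparable
  in34 <- fit_boundary(exact_records(seq(3, 4, by = 0.25), f_out, "3+4"))
  in56 <- fit_boundary(exact_records(seq(5, 6, by = 0.25), f_out, "5+6"))
  rep3 <- check_nesting(list(in34, in56))
  cross <- rep3[rep3$outer == "(3,4)" & rep3$inner == "(5,6)", ]
  expect_false(cross$comparable)
})

test_that("points classify into regions between curve and chord", {
  cu <- structure(list(pair = c(3L, 5L), coef = c(a = 0.1, b = -0.4, c = 1),
                       domain = c(3, 5), rms = 0.005,
                       endpoints = c(0.1 * 9 - 0.4 * 3 + 1,
                                     0.1 * 25 - 0.4 * 5 + 1), n = 11L),
                  class = "boundary_curve")
  k <- 4
  on_curve <- predict(cu, k)
  mid <- (on_curve + spintip:::chord_value(cu, k)) / 2
  above <- spintip:::chord_value(cu, k) + 1
  expect_equal(classify_point(k, on_curve, list(cu)), "(3,5)") # inclusive
  expect_equal(classify_point(k, mid, list(cu)), "(3,5)")
  expect_identical(classify_point(k, above, list(cu)), character(0)) # forbidden
  expect_error(classify_point(10, 1, list(cu)), "outside every curve")
})

test_that("degenerate triple compositions reduce to pairs and endpoints", {
  set.seed(71)
  cfg <- sweep_config(n_replicates = 5, base_seed = 72)
  # two-degree composition of a triple lands on that pair's boundary curve
  mixes <- make_substitution_sequences(300, c(3, 5), stride = 30)
  cu <- fit_boundary(run_substitution_experiment(mixes, cfg))
  two_of_three <- run_substitution_experiment(
    list(mk_mix(c(3, 4, 5), c(150, 0, 150))), cfg)
  expect_equal(two_of_three$H_T, predict(cu, two_of_three$avg_degree),
               tolerance = 0.2)
  # single-degree composition is a homogeneous endpoint
  homog <- run_substitution_experiment(
    list(mk_mix(c(3, 4, 5), c(0, 0, 300))), cfg)
  expect_equal(homog$avg_degree, 5)
  expect_equal(homog$H_T, cu$endpoints[2], tolerance = 0.2)
})

test_that("triple-spread summary classifies sampled mixes against the envelope", {
  cfg <- sweep_config(n_replicates = 3, base_seed = 80)
  ts <- triple_spread_experiment(c(3, 4, 5), n_samples = 6, cfg = cfg,
                                 N = 300, pair_mixes = 6)
  expect_s3_class(ts, "triple_spread")
  expect_equal(nrow(ts$samples), 6)
  expect_length(ts$curves, 3)
  expect_true(all(ts$samples$found))
  expect_true(ts$fraction_inside >= 0 && ts$fraction_inside <= 1)
  # reproducible under the same configuration
  ts2 <- triple_spread_experiment(c(3, 4, 5), n_samples = 6, cfg = cfg,
                                  N = 300, pair_mixes = 6,
                                  curves = ts$curves)
  expect_equal(ts2$samples, ts$samples)
})
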