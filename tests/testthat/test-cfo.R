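test_that("population initialisation is uniform on [0,1] and reproducible", {
  p1 <- init_population(10, 20, seed = 3)
  p2 <- init_population(10, 20, seed = 3)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  big <- init_population(100, 100, seed = 4)
  # mean of 10^4 U(0,1) draws: SE = sqrt(1/12)/100
  expect_lt(abs(mean(big) - 0.5), 3 * sqrt(1 / 12) / 100)
})

test_that("sigmoid binarization follows the printed inverted rule", {
  s <- c(-2, 0, 0.5, 2)
  expect_equal(cfo_binarize(s, 0), rep(0L, 4))   # sigmoid > 0 always
  expect_equal(cfo_binarize(s, 1), rep(1L, 4))
  expect_equal(cfo_binarize(0, 0.6), 1L)         # sigmoid(0)=0.5 < 0.6
  expect_equal(cfo_binarize(s, 0.6, invert = TRUE), 1L - cfo_binarize(s, 0.6))
})

test_that("search moves honour their null cases and stay in the unit box", {
  s <- c(0.2, 0.8, 0.5)
  expect_equal(explore_step(s, c(1, 0, 1), 0, 0), s)
  expect_equal(explore_step(s, s, 1, 0), s)
  expect_equal(exploit_step(s, c(0, 0, 0), 0, 0, 1), s)
  set.seed(1)
  for (i in 1:50) {
    out <- explore_step(runif(5), runif(5), 2, 2)
    expect_true(all(out >= 0 & out <= 1))
    out <- exploit_step(runif(5), runif(5), 2, 5, 1)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("exploitation perturbation has the configured spread", {
  set.seed(2)
  s <- rep(0.5, 1e4)
  out <- exploit_step(s, s, alpha2 = 0, beta2 = 1, gauss_sigma = 0.1)
  # pre-clipping the displacement is N(0, 0.1^2); clipping is inactive at
  # 0.5 +- a few sigmas
  expect_lt(abs(sd(out - s) - 0.1), 3 * 0.1 / sqrt(2 * (1e4 - 1)))
})

test_that("fitness combines wrapper error and selected fraction as printed", {
  ft <- generate_feature_table(
    feature_table_spec(200, 20, 5, 0, effect_size = 6, n_classes = 2,
                       seed = 5))
  x <- scale(ft$features)
  cfg <- cfo_config(fit_alpha = 0.9, fit_beta = 0.1, seed = 5)
  # strongly separated classes: the wrapper is perfect on the informative
  # columns, so J reduces to the count penalty
  b <- rep(0, 20); b[ft$informative] <- 1
  j <- cfo_fitness(b, x, ft$labels, cfg)
  expect_equal(attr(j, "accuracy"), 1)
  expect_equal(as.numeric(j), 0.1 * 5 / 20)
  # degenerate all-zero selection scores at majority-class chance
  j0 <- cfo_fitness(rep(0, 20), x, ft$labels, cfg)
  expect_true(attr(j0, "degenerate"))
  expect_equal(attr(j0, "accuracy"), max(table(ft$labels)) / 200)
  expect_error(cfo_fitness(b, x, ft$labels[-1], cfg), "disagree")
})

test_that("informative subsets beat random equal-size subsets in fitness", {
  wins <- 0L
  for (s in 1:10) {
    ft <- generate_feature_table(
      feature_table_spec(150, 30, 5, 0, effect_size = 2, n_classes = 3,
                         seed = 600 + s))
    x <- scale(ft$features)
    cfg <- cfo_config(seed = s)
    b_inf <- rep(0, 30); b_inf[ft$informative] <- 1
    set.seed(s)
    b_rnd <- rep(0, 30); b_rnd[sample(setdiff(1:30, ft$informative), 5)] <- 1
    if (cfo_fitness(b_inf, x, ft$labels, cfg) <
          cfo_fitness(b_rnd, x, ft$labels, cfg)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 8L)
})

test_that("the optimizer degenerates gracefully and keeps an elitist trace", {
  ft <- generate_feature_table(
    feature_table_spec(90, 12, 3, 0, effect_size = 3, seed = 7))
  x <- scale(ft$features)
  # t_max = 0: result is the argmin of the initial population
  r0 <- run_cfo(x, ft$labels, cfo_config(pop_size = 6, t_max = 0, seed = 2))
  expect_length(r0$fitness_trace, 1)
  pop <- init_population(6, 12, seed = 2)
  # reproduce the initial population: run_cfo draws it with the same seed
  set.seed(2)
  invisible(sample(rep_len(1:4, 90)))  # the CV fold assignment draw
  pop2 <- matrix(runif(6 * 12), 6, 12)
  js <- apply(pop2, 1, function(s) {
    cfo_fitness(cfo_binarize(s, 0.6), x, ft$labels,
                cfo_config(pop_size = 6, t_max = 0, seed = 2))
  })
  expect_equal(r0$fitness_trace[1], min(js))

  r <- run_cfo(x, ft$labels, cfo_config(pop_size = 6, t_max = 8, seed = 3))
  expect_true(all(diff(r$fitness_trace) <= 1e-12))
  expect_false(r$degenerate)
  r2 <- run_cfo(x, ft$labels, cfo_config(pop_size = 6, t_max = 8, seed = 3))
  expect_identical(r$fitness_trace, r2$fitness_trace)
})

test_that("column selection restricts matrices consistently", {
  m <- matrix(1:12, 4, 3, dimnames = list(NULL, c("c0", "c1", "c2")))
  expect_equal(apply_selection(m, c(1, 1, 1)), m)
  sel <- apply_selection(m, c(1, 0, 1))
  expect_equal(colnames(sel), c("c0", "c2"))
  expect_equal(sel, m[, c(1, 3)])
  expect_error(apply_selection(m, c(0, 0, 0)), "empty")
  expect_error(apply_selection(m, c(1, 0)), "mismatch")
})
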