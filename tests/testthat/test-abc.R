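test_that("summary statistics cover the pattern and the distribution", {
  # perfectly heritable cycle lengths: all kin correlations 1
  dfs <- do.call(rbind, lapply(1:8, function(i) {
    make_binary_table(5, tau = 12 + i, tree_id = paste0("t", i))
  }))
  fo <- as_lineage_forest(dfs)
  st <- summary_stats(fo)
  expect_true(all(abs(st$kin - 1) < 1e-12, na.rm = TRUE))
  expect_equal(unname(st$quantiles[3]), median(cycle_length(fo)))
  expect_false(is.unsorted(st$quantiles))

  # degenerate: all cycle lengths equal -> correlations masked
  same <- as_lineage_forest(make_binary_table(5, tau = 18))
  st0 <- summary_stats(same)
  expect_true(all(is.na(st0$kin)))
  expect_true(all(st0$quantiles == 18))

  # cross-module agreement with correlation_pattern
  sim <- simulate_gp_trees(ref_gp(), n_trees = 25, n_gen = 6, seed = 1)
  st1 <- summary_stats(sim)
  cp <- suppressWarnings(correlation_pattern(sim, n_boot = 0))
  expect_equal(unname(st1$kin), cp$rho, tolerance = 1e-12)
  tau <- cycle_length(sim)
  expect_equal(unname(st1$quantiles),
               unname(quantile(tau, c(0.1, 0.25, 0.5, 0.75, 0.9))))
})

test_that("the ABC distance is a weighted metric on unmasked entries", {
  sim <- simulate_gp_trees(ref_gp(), n_trees = 20, n_gen = 6, seed = 2)
  sim2 <- simulate_gp_trees(ref_gp(), n_trees = 20, n_gen = 6, seed = 3)
  a <- summary_stats(sim)
  b <- summary_stats(sim2)
  expect_equal(ss_distance(a, a), 0)
  d_ab <- ss_distance(a, b)
  expect_equal(d_ab, ss_distance(b, a))
  expect_gt(d_ab, 0)
  w <- rep(2, 13)
  expect_equal(ss_distance(a, b, w), 2 * d_ab)

  # a simulation missing an observed statistic cannot be accepted
  b_masked <- b
  b_masked$kin[1] <- NA
  expect_equal(ss_distance(a, b_masked), Inf)
  a_empty <- a
  a_empty$kin[] <- NA
  b_empty <- b
  b_empty$quantiles[] <- NA
  b_empty$kin[] <- NA
  expect_error(ss_distance(a_empty, b_empty), class = "kc_incomparable")
})

test_that("rejection ABC respects its acceptance contract", {
  obs <- simulate_gp_trees(ref_gp(), n_trees = 12, n_gen = 5, seed = 4)
  fit <- fit_gp_abc(obs, n_sims = 1000, accept_fraction = 0.05,
                    n_trees = 12, n_gen = 5, seed = 5)
  expect_equal(nrow(fit$accepted), 50)
  expect_true(all(diff(fit$accepted$distance) >= 0))

  # same seed: identical accepted set
  fit2 <- fit_gp_abc(obs, n_sims = 1000, accept_fraction = 0.05,
                     n_trees = 12, n_gen = 5, seed = 5)
  expect_identical(fit$accepted, fit2$accepted)

  # config validation
  expect_error(fit_gp_abc(obs, n_sims = 500), class = "kc_invalid_parameter")
  expect_error(fit_gp_abc(obs, accept_fraction = 0.5),
               class = "kc_invalid_parameter")
})

test_that("accepting everything returns the prior", {
  obs <- simulate_gp_trees(ref_gp(), n_trees = 10, n_gen = 5, seed = 6)
  # accept_fraction capped at 0.1 by contract; at that fraction the
  # accepted marginals already span most of the prior range
  fit <- fit_gp_abc(obs, n_sims = 1000, accept_fraction = 0.1,
                    n_trees = 10, n_gen = 5, seed = 7, weights = NULL)
  pri <- gp_priors()
  for (j in seq_len(nrow(pri))) {
    x <- fit$accepted[[pri$parameter[j]]]
    expect_gte(min(x), pri$lower[j])
    expect_lte(max(x), pri$upper[j])
  }
  expect_equal(nrow(fit$accepted), 100)
})

test_that("posterior-predictive bands cover and widen with acceptance", {
  obs <- simulate_gp_trees(ref_gp(), n_trees = 15, n_gen = 5, seed = 8)
  fit <- fit_gp_abc(obs, n_sims = 1000, accept_fraction = 0.02,
                    mode = "logistic", n_trees = 15, n_gen = 5, seed = 9)
  pp <- posterior_predictive(fit, n_draws = 12, seed = 10)
  expect_equal(nrow(pp$kin), 8)
  expect_true(all(pp$kin$lo <= pp$kin$hi))
  expect_true(all(pp$quantiles$lo <= pp$quantiles$hi))

  # nestedness: a looser acceptance widens the parameter spread
  fit_loose <- fit_gp_abc(obs, n_sims = 1000, accept_fraction = 0.1,
                          mode = "logistic", n_trees = 15, n_gen = 5,
                          seed = 9)
  spread <- function(f) {
    mean((f$posterior$q97.5 - f$posterior$q2.5) /
           (gp_priors()$upper - gp_priors()$lower))
  }
  expect_gte(spread(fit_loose), spread(fit) - 0.05)
})

test_that("perturbing growth and progression moves the cousin ratio as predicted", {
  p <- ref_gp()
  ctrl <- predict_perturbation(p, n_trees = 600, seed = 11)
  expect_s3_class(ctrl, "gp_perturbation")
  expect_true(all(is.finite(ctrl$ratios)))

  slow_growth <- predict_perturbation(p, k_scale = 0.7, n_trees = 600,
                                      seed = 11)
  slow_prog <- predict_perturbation(p, mu_shift = 0.5, n_trees = 600,
                                    seed = 11)
  expect_gt(slow_growth$ratios["c1_md"], ctrl$ratios["c1_md"])
  expect_lt(slow_prog$ratios["c1_md"], ctrl$ratios["c1_md"])

  # a regime with no mother-daughter signal refuses to form ratios
  p0 <- gp_params(a = 0, gamma = 0, s_threshold = 0, mode = "exponential")
  expect_error(predict_perturbation(p0, n_trees = 100, seed = 12),
               class = "kc_degenerate")
})

test_that("ABC recovery: posterior intervals cover the generating parameters", {
  # compact recovery run (the full-size experiment lives in the acceptance
  # battery); intervals for k and mu must cover the truth
  p <- ref_gp()
  obs <- simulate_gp_trees(p, 30, 7, seed = 42)
  fit <- fit_gp_abc(obs, n_sims = 1200, accept_fraction = 0.05,
                    mode = "logistic", seed = 7)
  post <- fit$posterior
  for (par in c("k", "mu")) {
    row <- post[post$parameter == par, ]
    expect_within(p[[par]], row$q2.5, row$q97.5)
  }
  # mu estimate is informative, not just the prior midpoint
  expect_lt(abs(post$median[post$parameter == "mu"] - p$mu), 0.25)
})
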