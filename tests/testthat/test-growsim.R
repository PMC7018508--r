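test_that("progression_time and size_at follow their closed forms", {
  p <- gp_params(mode = "exponential")
  expect_equal(progression_time(0, p), exp(p$mu))
  p0 <- gp_params(sigma_p = 0, mode = "exponential")
  expect_equal(progression_time(c(-2, 0, 3), p0), rep(exp(p0$mu), 3))
  p2 <- gp_params(sigma_p = 0.2, mu = 2, mode = "exponential")
  expect_equal(progression_time(1, p2), exp(2.2))

  pe <- gp_params(k = log(2), mode = "exponential")
  expect_equal(size_at(0.5, 0, pe), 0.5)
  expect_equal(size_at(0.5, 1, pe), 1.0)

  # logistic with huge smax agrees with exponential, and with an RK4
  # integration of ds/dt = k s (1 - s/smax)
  pl <- gp_params(k = 0.1, mode = "logistic", smax = 1e6)
  ts <- seq(0, 50, by = 10)
  expect_equal(size_at(0.5, ts, pl),
               size_at(0.5, ts, gp_params(k = 0.1, mode = "exponential")),
               tolerance = 1e-4)
  pl2 <- gp_params(k = 0.1, mode = "logistic", smax = 5)
  rk4 <- function(s0, t, k, smax, h = 1e-3) {
    f <- function(s) k * s * (1 - s / smax)
    s <- s0
    for (i in seq_len(round(t / h))) {
      k1 <- f(s); k2 <- f(s + h * k1 / 2)
      k3 <- f(s + h * k2 / 2); k4 <- f(s + h * k3)
      s <- s + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    s
  }
  expect_equal(size_at(0.5, 20, pl2), rk4(0.5, 20, 0.1, 5),
               tolerance = 1e-8)
  expect_error(size_at(6, 1, pl2), class = "kc_invalid_state")
})

test_that("growth_time inverts size_at for both growth laws", {
  pe <- gp_params(k = log(2), mode = "exponential")
  expect_equal(growth_time(0.5, 1, pe), 1)
  expect_equal(growth_time(1.4, 1, pe), 0)  # born above threshold

  pl <- gp_params(k = log(2), mode = "logistic", smax = 20)
  tg <- growth_time(0.5, 1, pl)
  # bisection oracle on size_at
  lo <- 0; hi <- 50
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (size_at(0.5, mid, pl) >= 1) hi <- mid else lo <- mid
  }
  expect_equal(tg, hi, tolerance = 1e-8)
  expect_equal(size_at(0.5, tg, pl), 1, tolerance = 1e-10)
  expect_error(growth_time(0.5, 25, pl), class = "kc_unreachable_threshold")
})

test_that("gp_divide halves size and couples sisters as specified", {
  p <- gp_params(a = 0.6, gamma = 0.4, sigma_g = 0)
  d <- gp_divide(list(q = 0.5, s_div = 3), p, seed = 1)
  expect_equal(d[[1]]$s_birth, 1.5)
  expect_equal(d[[2]]$s_birth, 1.5)
  expect_equal(d[[1]]$sth, 1)  # sigma_g = 0: threshold exactly 1
  expect_equal(d[[1]]$tau, pmax(d[[1]]$tau_g, d[[1]]$tau_p))

  # sister correlation of q over many divisions: a^2 + gamma (1 - a^2)
  n <- 1e5
  dd <- gp_divide(list(q = rnorm(n), s_div = rep(2, n)), p, seed = 2)
  r <- cor(dd[[1]]$q, dd[[2]]$q)
  expect_lt(abs(r - 0.616), 3 * (1 - 0.616^2) / sqrt(n - 3) + 1e-3)

  # a = 0, gamma = 0: daughters are independent standard normal
  p0 <- gp_params(a = 0, gamma = 0)
  dd0 <- gp_divide(list(q = rnorm(n), s_div = rep(2, n)), p0, seed = 3)
  expect_lt(abs(cor(dd0[[1]]$q, dd0[[2]]$q)), 3 / sqrt(n))
  expect_lt(abs(sd(dd0[[1]]$q) - 1), 0.02)
})

test_that("simulate_gp_trees builds complete annotated binary forests", {
  p <- ref_gp()
  fo <- simulate_gp_trees(p, n_trees = 30, n_gen = 7, seed = 1)
  expect_equal(nrow(fo), 30 * (2^7 - 1))
  expect_true(all(fo$fate == "divided"))
  expect_equal(max(fo$generation), 6)

  # bit-identical under the same seed
  fo2 <- simulate_gp_trees(p, n_trees = 30, n_gen = 7, seed = 1)
  expect_identical(fo, fo2)

  # tau = max(tau_g, tau_p), limitation label consistent
  expect_equal(fo$tau, pmax(fo$tau_g, fo$tau_p))
  expect_identical(fo$limitation == "growth", fo$tau_g >= fo$tau_p)

  # mass bookkeeping: daughters split the mother's division size exactly
  pr <- kincycle:::forest_parent_row(fo)
  kids <- which(!is.na(pr))
  expect_equal(2 * fo$s_birth[kids], fo$s_div[pr[kids]], tolerance = 1e-12)

  # noise-free regime: every cell has the same cycle length
  pdet <- gp_params(sigma_p = 0, sigma_g = 0)
  fod <- simulate_gp_trees(pdet, n_trees = 5, n_gen = 5, seed = 2)
  expect_lt(diff(range(fod$tau)), 1e-6)
})

test_that("limitation fractions respond to the progression/growth balance", {
  # very slow progression: everything progression-limited
  pp <- gp_params(mu = 5, mode = "exponential")
  fo <- suppressWarnings(simulate_gp_trees(pp, n_trees = 10, n_gen = 5, seed = 3))
  expect_gt(limitation_fractions(fo)["progression"], 0.99)

  # very fast progression: everything growth-limited
  pg <- gp_params(mu = 0.5, mode = "exponential")
  fo2 <- suppressWarnings(simulate_gp_trees(pg, 10, 5, seed = 3))
  expect_gt(limitation_fractions(fo2)["growth"], 0.99)
  expect_equal(sum(limitation_fractions(fo)), 1)

  # reference set: fraction reproducible across repeated 30-tree designs
  # (tree-level correlation leaves ~0.03-0.04 s.d. on a fraction near 0.2)
  fr <- vapply(1:20, function(s) {
    limitation_fractions(simulate_gp_trees(ref_gp(), 30, 7, seed = s))["growth"]
  }, numeric(1))
  expect_lt(sd(fr), 0.05)
})

test_that("size distribution is stationary at the reference parameters", {
  drift <- vapply(1:40, function(s) {
    fo <- simulate_gp_trees(ref_gp(), 30, 7, seed = 600 + s)
    stats::median(log(fo$s_birth[fo$generation == 6])) -
      stats::median(log(fo$s_birth[fo$generation == 4]))
  }, numeric(1))
  expect_lt(abs(mean(drift)), 0.05)
})

test_that("ancestral statistics expose the negative growth-progression coupling", {
  fo <- simulate_gp_trees(ref_gp(), n_trees = 800, n_gen = 7, seed = 5)
  st <- ancestral_stats(fo, max_lag = 3)
  expect_equal(st$rho[st$lag == 0 & st$statistic == "tau"], 1)
  cross <- st[st$statistic == "cross_tp_tg" & st$lag >= 1, ]
  expect_true(all(cross$rho < 0))

  # uncoupled all-progression regime: tau autocorrelation ~ 0 at lags >= 1
  p0 <- gp_params(a = 0, gamma = 0, sigma_g = 0, mu = 5, mode = "exponential")
  fo0 <- suppressWarnings(simulate_gp_trees(p0, n_trees = 400, n_gen = 6, seed = 6))
  st0 <- suppressWarnings(ancestral_stats(fo0, variables = "tau", max_lag = 3))
  auto <- st0[st0$statistic == "tau" & st0$lag >= 1, ]
  expect_true(all(abs(auto$rho) < 3 / sqrt(auto$n)))
})

test_that("conditioned correlations isolate the inheritance channels", {
  fo <- simulate_gp_trees(ref_gp(), n_trees = 1500, n_gen = 7, seed = 7)

  # identity predicate equals the unconditioned correlation
  un <- conditioned_corr(fo, c(0, 1))
  pairs <- kin_pairs(fo, c(0, 1))
  expect_equal(un$rho, spearman_cor(pairs))
  expect_equal(un$share, 1)

  # mother and daughter both progression-limited in a regime where size
  # never binds: reduces to the q inheritance correlation a (on ranks)
  pp <- gp_params(mu = 6, mode = "exponential")
  fop <- suppressWarnings(simulate_gp_trees(pp, n_trees = 1500, n_gen = 6, seed = 8))
  both_p <- function(a, b, m) {
    a$limitation == "progression" & b$limitation == "progression"
  }
  cc <- conditioned_corr(fop, c(0, 1), both_p)
  expect_equal(cc$share, 1)
  # Spearman of a bivariate normal with correlation a
  rho_rank <- (6 / pi) * asin(pp$a / 2)
  expect_lt(abs(cc$rho - rho_rank), 0.02)

  # cousins from a progression-limited grandmother correlate more strongly
  # than cousins from a growth-limited grandmother
  gm_p <- function(a, b, m) m$limitation == "progression"
  gm_g <- function(a, b, m) m$limitation == "growth"
  c_p <- conditioned_corr(fo, c(2, 2), gm_p)
  c_g <- conditioned_corr(fo, c(2, 2), gm_g)
  expect_gt(c_p$rho, c_g$rho)
  expect_equal(c_p$share + c_g$share, 1)
})

test_that("disabling the size checkpoint reduces the model to a pure AR process", {
  p <- gp_params(s_threshold = 0, mode = "exponential")
  fo <- simulate_gp_trees(p, n_trees = 2000, n_gen = 6, seed = 9)
  expect_true(all(fo$tau == fo$tau_p))
  bar <- bar_params(matrix(p$a, 1, 1), gamma = p$gamma)
  # compare on Gaussian scores (the BAR analytics are Pearson on scores)
  sc <- kincycle:::forest_scores(fo)
  for (k in list(c(0, 1), c(1, 1), c(2, 2), c(0, 2))) {
    pr <- attr(kin_pairs(fo, k), "rows")
    r_emp <- cor(sc[pr$row_a], sc[pr$row_b])
    n_eff <- if (k[1] == k[2]) nrow(pr) / 2 else nrow(pr)
    se <- (1 - r_emp^2) / sqrt(n_eff - 3)
    expect_lt(abs(r_emp - kin_corr(bar, k)), 3 * se + 5e-3)
  }
})
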