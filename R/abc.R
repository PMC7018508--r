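#' Summary statistics for ABC fitting
#'
#' The growth-progression model is fitted to two facets of the data: the
#' kinship correlation pattern (eight Spearman correlations,
#' mother-daughter through second cousins) and the cycle-length
#' distribution (quantiles at probabilities 0.1, 0.25, 0.5, 0.75, 0.9, in
#' hours). Kinship entries with fewer than `min_pairs` pairs, or with
#' degenerate ranks, are masked (`NA`).
#'
#' @param forest A (truncated) lineage forest.
#' @param kinships Kinships to include (default [default_kinships]).
#' @param min_pairs Masking threshold on unordered pair counts (default 10).
#' @return Object of class `gp_summary`: numeric vectors `kin` (named
#'   `"u,v"`) and `quantiles`.
#' @export
summary_stats <- function(forest, kinships = default_kinships(),
                          min_pairs = 10) {
  maxd <- max(vapply(kinships, function(k) max(as_kinship(k)), integer(1)))
  cache <- forest_kin_cache(forest, maxd)
  tau <- forest$end_time_h - forest$birth_time_h
  kin <- vapply(kinships, function(k) {
    k <- as_kinship(k)
    pr <- kin_pair_rows(forest, k, cache = cache)
    np <- if (k[1] == k[2]) nrow(pr) / 2 else nrow(pr)
    if (np < min_pairs || nrow(pr) < 3L) return(NA_real_)
    ta <- tau[pr$row_a]; tb <- tau[pr$row_b]
    if (stats::sd(ta) == 0 || stats::sd(tb) == 0) return(NA_real_)
    stats::cor(ta, tb, method = "spearman")
  }, numeric(1))
  names(kin) <- vapply(kinships, function(k) {
    paste(as_kinship(k), collapse = ",")
  }, character(1))
  taus <- forest$end_time_h[forest$fate == "divided"] -
    forest$birth_time_h[forest$fate == "divided"]
  q <- stats::quantile(taus, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  structure(list(kin = kin, quantiles = q), class = "gp_summary")
}

#' @export
print.gp_summary <- function(x, digits = 3, ...) {
  cat("Summary statistics: kin correlations\n")
  print(round(x$kin, digits))
  cat("cycle-length quantiles (h) at p = 0.1, 0.25, 0.5, 0.75, 0.9:\n")
  print(round(x$quantiles, digits))
  invisible(x)
}

stat_vector <- function(s) c(s$kin, q = s$quantiles)

#' Weighted distance between summary statistics
#'
#' Weighted Euclidean distance over the entries unmasked in the observed
#' statistics. A simulation that masks an entry the observation provides
#' receives infinite distance (it failed to reproduce the statistic);
#' fully disjoint masks are an error.
#'
#' @param obs,sim `gp_summary` objects.
#' @param weights Per-statistic scale (default all 1); doubling all
#'   weights doubles every distance.
#' @return Nonnegative scalar; zero iff the unmasked entries coincide.
#' @export
ss_distance <- function(obs, sim, weights = NULL) {
  a <- stat_vector(obs)
  b <- stat_vector(sim)
  if (is.null(weights)) weights <- rep(1, length(a))
  use <- is.finite(a)
  if (!any(use & is.finite(b))) {
    stop_kc("kc_incomparable", "no jointly unmasked summary statistics")
  }
  d2 <- (weights[use] * (a[use] - b[use]))^2
  if (any(!is.finite(b[use]))) return(Inf)
  sqrt(sum(d2))
}

# Tree-level bootstrap standard errors of the summary statistics; the
# default ABC weights are their reciprocals.
ss_bootstrap_se <- function(forest, n_boot = 200, min_pairs = 10,
                            seed = NULL) {
  trees <- unique(forest$tree_id)
  with_seed(seed, {
    boot <- replicate(n_boot, {
      pick <- sample(trees, replace = TRUE)
      res <- lapply(seq_along(pick), function(i) {
        sub <- forest[forest$tree_id == pick[i], , drop = FALSE]
        sub$tree_id <- sprintf("b%03d", i)
        sub
      })
      reboot <- do.call(rbind, res)
      class(reboot) <- class(forest)
      stat_vector(summary_stats(reboot, min_pairs = min_pairs))
    })
    apply(boot, 1, stats::sd, na.rm = TRUE)
  })
}

#' Default growth-progression priors for ABC
#'
#' Independent uniform ranges spanning cycle lengths of roughly 10-80
#' hours: `k` in (0.005, 0.2) per hour, `mu` in (2, 4.5), `sigma_p` in
#' (0.05, 0.8), `a` in (0, 0.95), `gamma` in (-0.5, 0.95), `sigma_g` in
#' (0, 0.3).
#'
#' @return Data.frame with columns `parameter`, `lower`, `upper`.
#' @export
gp_priors <- function() {
  data.frame(
    parameter = c("k", "mu", "sigma_p", "a", "gamma", "sigma_g"),
    lower = c(0.005, 2, 0.05, 0, -0.5, 0),
    upper = c(0.2, 4.5, 0.8, 0.95, 0.95, 0.3)
  )
}

#' Fit the growth-progression model by rejection ABC
#'
#' Likelihood-free fit: `n_sims` parameter vectors are drawn from the
#' uniform priors, lineage forests are simulated at the observed design
#' (same number of trees and generations), and the draws whose summary
#' statistics lie closest to the observed ones (smallest
#' `accept_fraction`) form the approximate posterior.
#'
#' @param obs A (truncated) lineage forest, or a precomputed `gp_summary`
#'   (then `n_trees`/`n_gen` must be given).
#' @param priors Prior ranges as from [gp_priors].
#' @param n_sims Number of simulations (>= 1000).
#' @param accept_fraction Fraction of draws accepted (in (0, 0.1]).
#' @param weights Per-statistic weights: `"bootstrap"` (reciprocal
#'   tree-level bootstrap SEs of the observed statistics; needs a forest),
#'   a numeric vector, or `NULL` for unit weights.
#' @param mode Growth law passed to the simulator.
#' @param smax Maximum size (logistic mode).
#' @param n_trees,n_gen Simulated design; defaults read off the observed
#'   forest.
#' @param seed Optional integer seed.
#' @return Object of class `gp_abc`: accepted draws with distances,
#'   posterior medians and central 95% intervals, configuration, and the
#'   observed statistics. Flagged if more than 20% of simulations raised
#'   stationarity warnings.
#' @export
fit_gp_abc <- function(obs, priors = gp_priors(), n_sims = 5000,
                       accept_fraction = 0.02, weights = "bootstrap",
                       mode = "exponential", smax = 20, n_trees = NULL,
                       n_gen = NULL, seed = NULL) {
  if (accept_fraction <= 0 || accept_fraction > 0.1) {
    stop_kc("kc_invalid_parameter", "accept_fraction must be in (0, 0.1]")
  }
  if (n_sims < 1000) {
    stop_kc("kc_invalid_parameter", "n_sims must be at least 1000")
  }
  if (inherits(obs, "lineage_forest")) {
    if (is.null(n_trees)) n_trees <- length(unique(obs$tree_id))
    if (is.null(n_gen)) n_gen <- max(obs$generation) + 1L
    obs_stats <- summary_stats(obs)
    if (identical(weights, "bootstrap")) {
      se <- ss_bootstrap_se(obs, seed = seed)
      weights <- ifelse(is.finite(se) & se > 0, 1 / se, 0)
    }
  } else {
    obs_stats <- obs
    if (is.null(n_trees) || is.null(n_gen)) {
      stop_kc("kc_invalid_parameter",
              "n_trees and n_gen are required with precomputed statistics")
    }
    if (identical(weights, "bootstrap")) weights <- NULL
  }

  with_seed(seed, {
    theta <- vapply(seq_len(nrow(priors)), function(j) {
      stats::runif(n_sims, priors$lower[j], priors$upper[j])
    }, numeric(n_sims))
    colnames(theta) <- priors$parameter
    dist <- rep(Inf, n_sims)
    n_nonstat <- 0L
    for (i in seq_len(n_sims)) {
      pars <- do.call(gp_params, c(as.list(theta[i, ]),
                                   list(mode = mode, smax = smax)))
      sim <- withCallingHandlers(
        simulate_gp_trees(pars, n_trees = n_trees, n_gen = n_gen),
        kc_stationarity_warning = function(w) {
          n_nonstat <<- n_nonstat + 1L
          invokeRestart("muffleWarning")
        })
      dist[i] <- tryCatch(
        ss_distance(obs_stats, summary_stats(sim), weights = weights),
        kincycle_error = function(e) Inf)
    }
    n_accept <- round(accept_fraction * n_sims)
    ord <- order(dist)
    acc <- ord[seq_len(n_accept)]
    accepted <- data.frame(theta[acc, , drop = FALSE],
                           distance = dist[acc])
    post <- apply(theta[acc, , drop = FALSE], 2, function(x) {
      stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    })
    posterior <- data.frame(parameter = colnames(theta),
                            q2.5 = post[1, ], median = post[2, ],
                            q97.5 = post[3, ])
    structure(list(accepted = accepted, posterior = posterior,
                   obs_stats = obs_stats, weights = weights,
                   n_sims = n_sims, accept_fraction = accept_fraction,
                   mode = mode, smax = smax, n_trees = n_trees,
                   n_gen = n_gen,
                   frac_nonstationary = n_nonstat / n_sims,
                   flagged = n_nonstat / n_sims > 0.2),
              class = "gp_abc")
  })
}

#' @export
print.gp_abc <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Rejection-ABC fit of the growth-progression model (%s growth)\n  %d simulations at design %d trees x %d generations, %d accepted (%.1f%%)\n",
    x$mode, x$n_sims, x$n_trees, x$n_gen, nrow(x$accepted),
    100 * x$accept_fraction))
  if (isTRUE(x$flagged)) {
    cat(sprintf("  flagged: %.0f%% of simulations were non-stationary\n",
                100 * x$frac_nonstationary))
  }
  cat("posterior (median and central 95% interval):\n")
  print(format(x$posterior, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.gp_abc <- function(object, ...) object$posterior

#' @export
coef.gp_abc <- function(object, ...) {
  stats::setNames(object$posterior$median, object$posterior$parameter)
}

#' Posterior-predictive bands of an ABC fit
#'
#' Re-simulates at accepted parameter draws and reports, per summary
#' statistic, the min/max and the central 95% interval across
#' re-simulations.
#'
#' @param fit A `gp_abc` object.
#' @param n_draws Accepted draws to re-simulate (default all, capped).
#' @param seed Optional integer seed.
#' @return List with data.frames `kin` and `quantiles` (columns `lo`,
#'   `hi`, `q2.5`, `q97.5`) and the matrix of simulated statistics.
#' @export
posterior_predictive <- function(fit, n_draws = 100, seed = NULL) {
  acc <- fit$accepted
  if (!nrow(acc)) stop_kc("kc_insufficient_data", "no accepted draws")
  with_seed(seed, {
    take <- if (nrow(acc) <= n_draws) seq_len(nrow(acc)) else {
      sample.int(nrow(acc), n_draws)
    }
    sims <- vapply(take, function(i) {
      pars <- do.call(gp_params,
                      c(as.list(acc[i, setdiff(names(acc), "distance")]),
                        list(mode = fit$mode, smax = fit$smax)))
      stat_vector(summary_stats(
        simulate_gp_trees(pars, n_trees = fit$n_trees, n_gen = fit$n_gen)))
    }, stat_vector(fit$obs_stats))
    sims <- matrix(sims, nrow = length(stat_vector(fit$obs_stats)),
                   dimnames = list(names(stat_vector(fit$obs_stats)), NULL))
    band <- function(rows) {
      t(apply(sims[rows, , drop = FALSE], 1, function(x) {
        c(lo = min(x, na.rm = TRUE), hi = max(x, na.rm = TRUE),
          stats::quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
      }))
    }
    nk <- length(fit$obs_stats$kin)
    kin <- as.data.frame(band(seq_len(nk)))
    qs <- as.data.frame(band(nk + seq_along(fit$obs_stats$quantiles)))
    names(kin) <- names(qs) <- c("lo", "hi", "q2.5", "q97.5")
    list(kin = kin, quantiles = qs, sims = sims)
  })
}

#' Predicted effect of growth or progression perturbations
#'
#' Simulates the growth-progression model at perturbed parameters -
#' growth slowed by scaling `k`, cycle progression slowed by shifting
#' `mu` - and returns the cousin to mother-daughter correlation ratios
#' `rho_c1 / rho_md` and `rho_c2 / rho_md` with approximate simulation
#' standard errors. Slowing growth shifts cycles toward growth
#' limitation and raises cousin correlations relative to mother-daughter
#' ones; slowing progression does the opposite.
#'
#' @param params A [gp_params] object (e.g. a best fit).
#' @param k_scale Multiplicative perturbation of the growth rate.
#' @param mu_shift Additive perturbation of the mean log progression time.
#' @param n_trees,n_gen Simulated design (default 3000 trees x 7
#'   generations).
#' @param seed Optional integer seed.
#' @return Object of class `gp_perturbation`: `rho` (md, c1, c2), `se`,
#'   `ratios` (`c1_md`, `c2_md`), `ratio_se`, `n_pairs`.
#' @export
predict_perturbation <- function(params, k_scale = 1, mu_shift = 0,
                                 n_trees = 3000, n_gen = 7, seed = NULL) {
  pert <- params
  pert$k <- params$k * k_scale
  pert$mu <- params$mu + mu_shift
  forest <- simulate_gp_trees(pert, n_trees = n_trees, n_gen = n_gen,
                              seed = seed)
  ks <- list(md = kinship(0, 1), c1 = kinship(2, 2), c2 = kinship(3, 3))
  cache <- forest_kin_cache(forest, 3L)
  tau <- forest$end_time_h - forest$birth_time_h
  rho <- se <- n_pairs <- numeric(3)
  names(rho) <- names(se) <- names(n_pairs) <- names(ks)
  for (i in seq_along(ks)) {
    k <- ks[[i]]
    pr <- kin_pair_rows(forest, k, cache = cache)
    n <- if (k[1] == k[2]) nrow(pr) / 2 else nrow(pr)
    rho[i] <- spearman_cor(tau[pr$row_a], tau[pr$row_b])
    se[i] <- (1 - rho[i]^2) * sqrt(1.06 / (n - 3))
    n_pairs[i] <- n
  }
  if (abs(rho["md"]) < 2 * se["md"]) {
    stop_kc("kc_degenerate",
            "mother-daughter correlation indistinguishable from 0; ratios undefined")
  }
  ratios <- c(c1_md = unname(rho["c1"] / rho["md"]),
              c2_md = unname(rho["c2"] / rho["md"]))
  ratio_se <- c(
    c1_md = abs(ratios["c1_md"]) *
      sqrt((se["c1"] / rho["c1"])^2 + (se["md"] / rho["md"])^2),
    c2_md = abs(ratios["c2_md"]) *
      sqrt((se["c2"] / rho["c2"])^2 + (se["md"] / rho["md"])^2)
  )
  structure(list(rho = rho, se = se, ratios = ratios,
                 ratio_se = unname(ratio_se), n_pairs = n_pairs,
                 k_scale = k_scale, mu_shift = mu_shift),
            class = "gp_perturbation")
}

#' @export
print.gp_perturbation <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Perturbation prediction (k_scale = %.3g, mu_shift = %.3g)\n", x$k_scale,
    x$mu_shift))
  cat(sprintf("  rho_md = %.3f, rho_c1 = %.3f, rho_c2 = %.3f\n",
              x$rho["md"], x$rho["c1"], x$rho["c2"]))
  cat(sprintf("  rho_c1/rho_md = %.3f (se %.3f), rho_c2/rho_md = %.3f (se %.3f)\n",
              x$ratios["c1_md"], x$ratio_se[1], x$ratios["c2_md"],
              x$ratio_se[2]))
  invisible(x)
}
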