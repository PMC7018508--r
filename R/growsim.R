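#' Growth-progression model parameters
#'
#' A mechanistic realisation of coupled cell-cycle inheritance: each cell
#' carries a heritable progression state `q` (a centred Gaussian AR(1)
#' variable down the lineage, stationary variance 1) giving a log-normal
#' progression time `tau_p = exp(sigma_p * q + mu)`, and a size `s`
#' (threshold units) growing exponentially or logistically. A cell divides
#' only once it has both completed progression and grown past its division
#' threshold `sth = s_threshold * (1 + zeta)`, `zeta ~ N(0, sigma_g^2)`
#' independently per cell, so the cycle length is
#' `tau = max(tau_g, tau_p)` with `tau_g` the time to reach the threshold.
#' Size is split equally between daughters.
#'
#' @param k Growth rate per hour (> 0).
#' @param mu Mean log progression time (log-hours).
#' @param sigma_p Stationary s.d. of the log progression time.
#' @param a Mother-daughter inheritance coefficient of `q` (|a| < 1).
#' @param gamma Sister coupling of the intrinsic `q` noise: the two
#'   daughters' innovations have correlation `gamma`.
#' @param sigma_g S.d. of the relative division-threshold fluctuation.
#' @param mode Growth law: `"exponential"` or `"logistic"` (growth rate
#'   throttled as size approaches `smax`, used for conditions with
#'   feedback-stabilised size).
#' @param smax Maximum normalised size, logistic mode only (default 20
#'   threshold units).
#' @param s_threshold Mean division threshold in threshold units (default
#'   1; set to 0 to disable the size checkpoint, reducing the model to a
#'   single-variable AR process on log cycle time).
#' @return Object of class `gp_params`.
#' @export
gp_params <- function(k = 0.036, mu = 2.9, sigma_p = 0.55, a = 0.5,
                      gamma = 0.35, sigma_g = 0.05,
                      mode = c("logistic", "exponential"), smax = 20,
                      s_threshold = 1) {
  mode <- match.arg(mode)
  if (!is.finite(k) || k <= 0) {
    stop_kc("kc_invalid_parameter", "growth rate k must be > 0")
  }
  if (sigma_p < 0 || sigma_g < 0) {
    stop_kc("kc_invalid_parameter", "sigma_p and sigma_g must be >= 0")
  }
  if (abs(a) >= 1) stop_kc("kc_invalid_parameter", "|a| must be < 1")
  if (abs(gamma) >= 1) stop_kc("kc_invalid_parameter", "|gamma| must be < 1")
  if (mode == "logistic" && smax <= 1) {
    stop_kc("kc_invalid_parameter", "logistic mode needs smax > 1")
  }
  if (s_threshold < 0) {
    stop_kc("kc_invalid_parameter", "s_threshold must be >= 0")
  }
  structure(list(k = k, mu = mu, sigma_p = sigma_p, a = a, gamma = gamma,
                 sigma_g = sigma_g, mode = mode, smax = smax,
                 s_threshold = s_threshold),
            class = "gp_params")
}

#' @export
print.gp_params <- function(x, ...) {
  cat(sprintf(
    "Growth-progression parameters: k = %.4g /h, mu = %.3g, sigma_p = %.3g,\n  a = %.3g, gamma = %.3g, sigma_g = %.3g, %s growth%s\n",
    x$k, x$mu, x$sigma_p, x$a, x$gamma, x$sigma_g, x$mode,
    if (x$mode == "logistic") sprintf(" (smax = %g)", x$smax) else ""))
  invisible(x)
}

#' Elementary growth-progression kinetics
#'
#' `progression_time` is the log-normal progression duration
#' `exp(sigma_p * q + mu)`; `size_at` propagates size for `t` hours under
#' the growth law; `growth_time` is the earliest time at which size
#' reaches the division threshold (closed forms for both growth laws).
#'
#' @param q Latent progression state(s).
#' @param params A [gp_params] object.
#' @return Hours (`progression_time`, `growth_time`) or size (`size_at`);
#'   all vectorised.
#' @export
progression_time <- function(q, params) {
  exp(params$sigma_p * q + params$mu)
}

#' @rdname progression_time
#' @param s_birth Size(s) at birth (threshold units, > 0).
#' @param t Elapsed time(s) in hours (>= 0).
#' @export
size_at <- function(s_birth, t, params) {
  stopifnot(all(t >= 0), all(s_birth > 0))
  if (params$mode == "exponential") {
    s_birth * exp(params$k * t)
  } else {
    if (any(s_birth >= params$smax)) {
      stop_kc("kc_invalid_state", "logistic growth requires s_birth < smax")
    }
    g <- exp(params$k * t)
    params$smax * s_birth * g / (params$smax + s_birth * (g - 1))
  }
}

#' @rdname progression_time
#' @param sth Division threshold(s).
#' @export
growth_time <- function(s_birth, sth, params) {
  stopifnot(all(s_birth > 0))
  if (params$mode == "exponential") {
    return(pmax(0, log(sth / s_birth) / params$k))
  }
  if (any(sth >= params$smax)) {
    stop_kc("kc_unreachable_threshold",
            "logistic growth saturates below the division threshold")
  }
  if (any(s_birth >= params$smax)) {
    stop_kc("kc_invalid_state", "logistic growth requires s_birth < smax")
  }
  tg <- log(sth * (params$smax - s_birth) /
              (s_birth * (params$smax - sth))) / params$k
  pmax(0, tg)
}

# Complete a cohort of cells: given latent state and size at birth, draw
# the division threshold and compute all per-cell quantities.
gp_complete_cells <- function(q, s_birth, params) {
  n <- length(q)
  if (params$s_threshold > 0) {
    zeta <- stats::rnorm(n, 0, params$sigma_g)
    zeta <- pmax(zeta, -0.99)  # keep the threshold positive
    sth <- params$s_threshold * (1 + zeta)
  } else {
    sth <- rep(0, n)
  }
  tau_p <- progression_time(q, params)
  tau_g <- if (params$s_threshold > 0) growth_time(s_birth, sth, params)
           else rep(0, n)
  tau <- pmax(tau_g, tau_p)
  list(q = q, s_birth = s_birth, sth = sth, tau_g = tau_g, tau_p = tau_p,
       tau = tau, s_div = size_at(s_birth, tau, params),
       limitation = ifelse(tau_g >= tau_p, "growth", "progression"))
}

# Sister-coupled daughter latent states: q_i = a q_m + xi_i with
# Var(xi) = 1 - a^2 and Corr(xi_1, xi_2) = gamma, keeping Var(q) = 1.
gp_daughter_q <- function(qm, params) {
  n <- length(qm)
  sd_xi <- sqrt(1 - params$a^2)
  z1 <- stats::rnorm(n)
  z2 <- params$gamma * z1 + sqrt(1 - params$gamma^2) * stats::rnorm(n)
  list(q1 = params$a * qm + sd_xi * z1,
       q2 = params$a * qm + sd_xi * z2)
}

#' Divide a completed mother cell
#'
#' Produces the two daughters of one or more completed mothers: latent
#' states inherit with coefficient `a` and sister-coupled intrinsic noise,
#' size is split equally, and each daughter's threshold, growth time,
#' progression time, cycle length and limitation label are computed.
#'
#' @param mother List with numeric elements `q` and `s_div` (vectors allowed).
#' @param params A [gp_params] object.
#' @param seed Optional integer seed.
#' @return List of two daughter-state lists (elements as in the annotated
#'   simulator output).
#' @export
gp_divide <- function(mother, params, seed = NULL) {
  with_seed(seed, {
    dq <- gp_daughter_q(mother$q, params)
    s <- mother$s_div / 2
    list(gp_complete_cells(dq$q1, s, params),
         gp_complete_cells(dq$q2, s, params))
  })
}

#' Simulate annotated lineage trees from the growth-progression model
#'
#' Grows complete binary trees generation by generation. Each tree founder
#' is the endpoint of a discarded single-lineage burn-in chain (latent
#' state started from its stationary distribution, size at the threshold),
#' which removes founder transients. All fates are `divided`, so the
#' output drops straight into the correlation machinery.
#'
#' @param params A [gp_params] object.
#' @param n_trees Number of trees (default 30, matching typical
#'   experiment sizes).
#' @param n_gen Number of recorded generations (default 7; cells occupy
#'   generations `0 .. n_gen - 1`).
#' @param burn_in Discarded burn-in generations per founder (default 20).
#' @param seed Optional integer seed (bit-reproducible output).
#' @return A [lineage_forest][as_lineage_forest] with annotation columns
#'   `q`, `s_birth`, `sth`, `tau_g`, `tau_p`, `tau`, `s_div`,
#'   `limitation`. If the median log birth size drifts by more than one
#'   log unit between generation 3 and the last generation, a
#'   non-stationarity warning is attached.
#' @export
simulate_gp_trees <- function(params, n_trees = 30, n_gen = 7,
                              burn_in = 20, seed = NULL) {
  stopifnot(n_trees >= 1, n_gen >= 1)
  with_seed(seed, {
    # burn-in: single-lineage chain per founder
    q <- stats::rnorm(n_trees)
    s <- rep(max(params$s_threshold, 1e-12), n_trees)
    for (g in seq_len(burn_in)) {
      cells <- gp_complete_cells(q, s, params)
      q <- params$a * q + sqrt(1 - params$a^2) * stats::rnorm(n_trees)
      s <- cells$s_div / 2
    }

    per_gen <- vector("list", n_gen)
    tree <- seq_len(n_trees)
    idx <- rep(1L, n_trees)
    birth <- rep(0, n_trees)
    for (g in seq_len(n_gen) - 1L) {
      cells <- gp_complete_cells(q, s, params)
      parent <- as.character(idx %/% 2L)
      parent[idx == 1L] <- NA_character_
      per_gen[[g + 1L]] <- data.frame(
        tree_id = sprintf("t%03d", tree), cell_id = as.character(idx),
        parent_id = parent,
        birth_time_h = birth, end_time_h = birth + cells$tau,
        fate = "divided", q = cells$q, s_birth = cells$s_birth,
        sth = cells$sth, tau_g = cells$tau_g, tau_p = cells$tau_p,
        tau = cells$tau, s_div = cells$s_div,
        limitation = cells$limitation,
        stringsAsFactors = FALSE
      )
      if (g < n_gen - 1L) {
        dq <- gp_daughter_q(q, params)
        q <- c(dq$q1, dq$q2)
        s <- rep(cells$s_div / 2, 2)
        tree <- rep(tree, 2)
        birth <- rep(birth + cells$tau, 2)
        idx <- c(2L * idx, 2L * idx + 1L)
      }
    }
    df <- do.call(rbind, per_gen)
    forest <- as_lineage_forest(df, validate = FALSE)
    attr(forest, "gp_params") <- params

    if (n_gen >= 5L && params$s_threshold > 0) {
      m3 <- stats::median(log(forest$s_birth[forest$generation == 3L]))
      mL <- stats::median(log(forest$s_birth[forest$generation == n_gen - 1L]))
      if (abs(mL - m3) > 1) {
        warn_kc("kc_stationarity_warning",
                sprintf("median log birth size drifts %.2f between generations 3 and %d",
                        mL - m3, n_gen - 1L))
        attr(forest, "nonstationary") <- TRUE
      }
    }
    forest
  })
}

#' Share of growth- versus progression-limited cycles
#'
#' @param forest An annotated forest from [simulate_gp_trees].
#' @return Named proportions `c(growth = , progression = )` summing to 1.
#' @export
limitation_fractions <- function(forest) {
  stopifnot("limitation" %in% names(forest))
  f <- c(growth = mean(forest$limitation == "growth"),
         progression = mean(forest$limitation == "progression"))
  f
}

#' Ancestral auto- and cross-correlations of cycle components
#'
#' Spearman correlations between a cell and its direct ancestors at lags
#' `0..max_lag` for cycle length `tau`, growth time `tau_g` and
#' progression time `tau_p`, plus the `tau_p`(ancestor) vs
#' `tau_g`(descendant) cross-correlation that exposes the negative
#' growth-progression coupling.
#'
#' @param forest An annotated forest from [simulate_gp_trees].
#' @param variables Subset of `c("tau", "tau_g", "tau_p")`.
#' @param max_lag Maximum ancestral lag in generations (default 4).
#' @return Data.frame with columns `statistic`, `lag`, `rho`, `n`.
#' @export
ancestral_stats <- function(forest, variables = c("tau", "tau_g", "tau_p"),
                            max_lag = 4) {
  stopifnot(all(variables %in% names(forest)))
  cache <- forest_kin_cache(forest, max_lag)
  pair_rows <- lapply(seq_len(max_lag), function(L) {
    kin_pair_rows(forest, kinship(0, L), cache = cache)
  })
  rows <- list()
  for (v in variables) {
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = v, lag = 0L, rho = 1, n = nrow(forest))
    for (L in seq_len(max_lag)) {
      pr <- pair_rows[[L]]
      rho <- if (nrow(pr) >= 3L) {
        spearman_cor(forest[[v]][pr$row_a], forest[[v]][pr$row_b])
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = v, lag = L, rho = rho, n = nrow(pr))
    }
  }
  for (L in 0:max_lag) {
    if (L == 0L) {
      rho <- spearman_cor(forest$tau_p, forest$tau_g)
      n <- nrow(forest)
    } else {
      pr <- pair_rows[[L]]
      rho <- if (nrow(pr) >= 3L) {
        spearman_cor(forest$tau_p[pr$row_a], forest$tau_g[pr$row_b])
      } else NA_real_
      n <- nrow(pr)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      statistic = "cross_tp_tg", lag = L, rho = rho, n = n)
  }
  do.call(rbind, rows)
}

#' Kinship correlations conditioned on division limitation
#'
#' Spearman correlation within the subgroup of pairs selected by a
#' predicate on the two cells and their MRCA - e.g. mother and daughter
#' both progression-limited, or cousins whose shared grandmother was
#' growth-limited - together with the subgroup's share of all pairs.
#'
#' @param forest An annotated forest from [simulate_gp_trees].
#' @param k A [kinship].
#' @param condition Function `(cells_a, cells_b, cells_mrca) -> logical`,
#'   receiving the annotation rows of the two pair members and of their
#'   MRCA. Default keeps every pair.
#' @param min_pairs Subgroups with fewer (unordered) pairs are flagged.
#' @return List with `rho`, `n_pairs`, `share`, `reliable`.
#' @export
conditioned_corr <- function(forest, k, condition = NULL, min_pairs = 10) {
  k <- as_kinship(k)
  pr <- kin_pair_rows(forest, k)
  if (!nrow(pr)) {
    return(list(rho = NA_real_, n_pairs = 0, share = NA_real_,
                reliable = FALSE))
  }
  keep <- if (is.null(condition)) rep(TRUE, nrow(pr)) else {
    condition(forest[pr$row_a, , drop = FALSE],
              forest[pr$row_b, , drop = FALSE],
              forest[pr$mrca, , drop = FALSE])
  }
  sel <- which(keep)
  ordered_div <- if (k[1] == k[2]) 2 else 1
  n_pairs <- length(sel) / ordered_div
  share <- length(sel) / nrow(pr)
  rho <- if (length(sel) >= 3L) {
    tau_a <- forest$end_time_h[pr$row_a[sel]] - forest$birth_time_h[pr$row_a[sel]]
    tau_b <- forest$end_time_h[pr$row_b[sel]] - forest$birth_time_h[pr$row_b[sel]]
    if (stats::sd(tau_a) > 0 && stats::sd(tau_b) > 0) {
      stats::cor(tau_a, tau_b, method = "spearman")
    } else NA_real_
  } else NA_real_
  list(rho = rho, n_pairs = n_pairs, share = share,
       reliable = is.finite(rho) && n_pairs >= min_pairs)
}
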