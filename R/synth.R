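#' Observation model for synthetic lineage-tree datasets
#'
#' Emulates the imperfections of live-cell tracking: per cell, a single
#' draw decides whether it is lost from observation (probability
#' `loss_prob`) or dies (`death_prob`, mutually exclusive); lost and dead
#' cells terminate their subtree at a uniformly placed time within the
#' cycle. Cells whose cycle runs past the end of the movie are censored at
#' `movie_length` and leave no recorded daughters.
#'
#' @param loss_prob,death_prob Per-cell probabilities in `[0, 1]` with
#'   `loss_prob + death_prob <= 1`.
#' @param movie_length Movie duration in hours (may be `Inf`).
#' @return Object of class `observation_model`.
#' @export
observation_model <- function(loss_prob = 0.03, death_prob = 0.01,
                              movie_length = 150) {
  if (loss_prob < 0 || death_prob < 0 || loss_prob + death_prob > 1) {
    stop_kc("kc_invalid_parameter",
            "loss_prob and death_prob must be probabilities summing to <= 1")
  }
  if (!(movie_length > 0)) {
    stop_kc("kc_invalid_parameter", "movie_length must be positive")
  }
  structure(list(loss_prob = loss_prob, death_prob = death_prob,
                 movie_length = movie_length),
            class = "observation_model")
}

#' Forward-sample lineage forests from a BAR model
#'
#' Samples the latent vector process down complete binary trees: founders
#' from the stationary distribution, daughters with conditional mean
#' `A x_mother`, unit intrinsic noise and sister cross-covariance
#' `gamma I`. The observed score is the standardised weighted sum
#' `alpha' x`, converted to a cycle time by `tau_map` (default: a
#' log-normal marginal `exp(meanlog + sdlog * y)`).
#'
#' @param params A [bar_params] object.
#' @param n_trees,n_gen Design: complete binary trees with generations
#'   `0 .. n_gen - 1`.
#' @param meanlog,sdlog Log-normal marginal mapping scores to hours
#'   (defaults: median 18 h, s = 0.25, typical of fast-cycling cultured
#'   cells).
#' @param tau_map Optional monotone function `y -> tau` overriding the
#'   log-normal marginal (e.g. a fitted inverse rank-Gaussian map).
#' @param seed Optional integer seed.
#' @return A [lineage_forest][as_lineage_forest] with all fates `divided`
#'   and annotation columns `y` (standardised score) and `x1`..`xd`.
#' @export
bar_forward_sample <- function(params, n_trees = 30, n_gen = 7,
                               meanlog = log(18), sdlog = 0.25,
                               tau_map = NULL, seed = NULL) {
  stopifnot(inherits(params, "bar_params"))
  if (is.null(tau_map)) {
    tau_map <- function(y) exp(meanlog + sdlog * y)
  }
  C <- stationary_cov(params$A)
  sd_y <- sqrt(drop(t(params$alpha) %*% C %*% params$alpha))
  Croot <- chol(C)
  d <- params$d
  with_seed(seed, {
    per_gen <- vector("list", n_gen)
    x <- t(Croot) %*% matrix(stats::rnorm(d * n_trees), d, n_trees)
    tree <- seq_len(n_trees)
    idx <- rep(1L, n_trees)
    birth <- rep(0, n_trees)
    for (g in seq_len(n_gen) - 1L) {
      y <- drop(t(params$alpha) %*% x) / sd_y
      tau <- tau_map(y)
      per_gen[[g + 1L]] <- data.frame(
        tree_id = sprintf("t%03d", tree), cell_id = as.character(idx),
        parent_id = ifelse(idx == 1L, NA_character_,
                           as.character(idx %/% 2L)),
        birth_time_h = birth, end_time_h = birth + tau, fate = "divided",
        y = y, stringsAsFactors = FALSE
      )
      for (l in seq_len(d)) per_gen[[g + 1L]][[paste0("x", l)]] <- x[l, ]
      if (g < n_gen - 1L) {
        x <- bar_daughter_x(x, params)
        tree <- rep(tree, 2)
        birth <- rep(birth + tau, 2)
        idx <- c(2L * idx, 2L * idx + 1L)
      }
    }
    forest <- as_lineage_forest(do.call(rbind, per_gen), validate = FALSE)
    attr(forest, "bar_params") <- params
    forest
  })
}

# Sister-coupled daughter latent states, columns = mothers: xi_2 is
# correlated with xi_1 entrywise with correlation gamma.
bar_daughter_x <- function(x, params) {
  d <- nrow(x)
  n <- ncol(x)
  m <- params$A %*% x
  xi1 <- matrix(stats::rnorm(d * n), d, n)
  xi2 <- params$gamma * xi1 +
    sqrt(1 - params$gamma^2) * matrix(stats::rnorm(d * n), d, n)
  cbind(m + xi1, m + xi2)
}

#' Generate a synthetic lineage-tree dataset with censoring
#'
#' Emulates a time-lapse experiment end to end: trees are grown from
#' either generative model (growth-progression or BAR forward sampling)
#' and passed through the [observation_model] - per-cell loss and death
#' terminate subtrees, the movie end censors running cycles. Defaults (25
#' trees, 150 h movie, 3% loss, 1% death) yield datasets with 5-7 fully
#' observed generations, like typical fast-cycling culture experiments.
#'
#' @param generator `"gp"` (growth-progression) or `"bar"`.
#' @param params A [gp_params] or [bar_params] object, matching
#'   `generator`.
#' @param n_trees Number of trees (default 25).
#' @param obs An [observation_model].
#' @param max_gen Hard cap on generated generations (default 12).
#' @param meanlog,sdlog Log-normal marginal for the BAR generator.
#' @param burn_in Burn-in generations for the growth-progression
#'   generator.
#' @param seed Optional integer seed.
#' @return A [lineage_forest][as_lineage_forest] with fates assigned by
#'   the observation process and a `tau_true` annotation column holding
#'   each cell's underlying full cycle length.
#' @export
generate_dataset <- function(generator = c("gp", "bar"), params,
                             n_trees = 25, obs = observation_model(),
                             max_gen = 12, meanlog = log(18), sdlog = 0.25,
                             burn_in = 20, seed = NULL) {
  generator <- match.arg(generator)
  stopifnot(inherits(obs, "observation_model"))
  with_seed(seed, {
    if (generator == "gp") {
      stopifnot(inherits(params, "gp_params"))
      q <- stats::rnorm(n_trees)
      s <- rep(max(params$s_threshold, 1e-12), n_trees)
      for (g in seq_len(burn_in)) {
        cells <- gp_complete_cells(q, s, params)
        q <- params$a * q + sqrt(1 - params$a^2) * stats::rnorm(n_trees)
        s <- cells$s_div / 2
      }
      state <- list(q = q, s = s)
      step <- function(state) gp_complete_cells(state$q, state$s, params)
      offspring <- function(state, cells, alive) {
        dq <- gp_daughter_q(state$q[alive], params)
        list(q = c(dq$q1, dq$q2),
             s = rep(cells$s_div[alive] / 2, 2))
      }
    } else {
      stopifnot(inherits(params, "bar_params"))
      C <- stationary_cov(params$A)
      sd_y <- sqrt(drop(t(params$alpha) %*% C %*% params$alpha))
      x <- t(chol(C)) %*% matrix(stats::rnorm(params$d * n_trees),
                                 params$d, n_trees)
      state <- list(x = x)
      step <- function(state) {
        y <- drop(t(params$alpha) %*% state$x) / sd_y
        list(tau = exp(meanlog + sdlog * y))
      }
      offspring <- function(state, cells, alive) {
        list(x = bar_daughter_x(state$x[, alive, drop = FALSE], params))
      }
    }

    per_gen <- list()
    tree <- seq_len(n_trees)
    idx <- rep(1L, n_trees)
    birth <- rep(0, n_trees)
    for (g in 0:(max_gen - 1L)) {
      if (!length(tree)) break
      cells <- step(state)
      tau <- cells$tau
      n <- length(tau)
      udraw <- stats::runif(n)
      fate <- rep("divided", n)
      end <- birth + tau
      lost <- udraw < obs$loss_prob
      died <- !lost & udraw < obs$loss_prob + obs$death_prob
      fate[lost] <- "lost"
      fate[died] <- "died"
      end[lost | died] <- birth[lost | died] +
        stats::runif(sum(lost | died)) * tau[lost | died]
      over <- fate == "divided" & end > obs$movie_length
      fate[over] <- "censored"
      end[over] <- obs$movie_length
      # movie end can also cut short a loss/death event
      cut <- (lost | died) & end > obs$movie_length
      fate[cut] <- "censored"
      end[cut] <- obs$movie_length

      rec <- data.frame(
        tree_id = sprintf("t%03d", tree), cell_id = as.character(idx),
        parent_id = ifelse(idx == 1L, NA_character_,
                           as.character(idx %/% 2L)),
        birth_time_h = birth, end_time_h = end, fate = fate,
        tau_true = tau, stringsAsFactors = FALSE
      )
      if (generator == "gp") {
        rec$q <- cells$q; rec$s_birth <- cells$s_birth
        rec$tau_g <- cells$tau_g; rec$tau_p <- cells$tau_p
        rec$limitation <- cells$limitation
      }
      per_gen[[g + 1L]] <- rec

      alive <- which(fate == "divided" & g < max_gen - 1L)
      if (!length(alive)) break
      state <- offspring(state, cells, alive)
      tree <- rep(tree[alive], 2)
      birth <- rep(end[alive], 2)
      idx <- c(2L * idx[alive], 2L * idx[alive] + 1L)
    }
    forest <- as_lineage_forest(do.call(rbind, per_gen), validate = FALSE)
    attr(forest, "generator") <- generator
    forest
  })
}
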