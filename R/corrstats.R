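#' Spearman rank correlation of cycle-length pairs
#'
#' Pearson correlation of average-ranked values (ties get average ranks, as
#' produced by time-discretised imaging).
#'
#' @param x Either a numeric vector or a two-column pairs data.frame/matrix
#'   (as returned by [kin_pairs]).
#' @param y Second numeric vector when `x` is a vector.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x[, 1:2])
    y <- x[, 2]
    x <- x[, 1]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_kc("kc_insufficient_data",
            sprintf("need at least 3 pairs, got %d", length(x)))
  }
  stats::cor(x, y, method = "spearman")
}

#' Tree-level bootstrap confidence interval for a kinship correlation
#'
#' Cells within a tree are not independent, so resampling happens at the
#' level of whole lineage trees: trees are drawn with replacement, the
#' Spearman correlation of the pooled pairs recomputed, and a percentile
#' interval reported. Resamples with fewer than 3 usable pairs (or zero
#' variance) are skipped; if more than half are skipped the interval is
#' deemed unstable and an error is raised.
#'
#' @param forest A lineage forest.
#' @param k A [kinship].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed (the caller's RNG stream is preserved).
#' @return `c(ci_low, ci_high)` with attribute `n_skipped`.
#' @export
bootstrap_ci <- function(forest, k, n_boot = 1000, level = 0.95,
                         seed = NULL) {
  k <- as_kinship(k)
  trees <- unique(forest$tree_id)
  if (length(trees) < 2L) {
    stop_kc("kc_insufficient_data", "bootstrap needs at least 2 trees")
  }
  pairs <- kin_pairs(forest, k)
  rows <- attr(pairs, "rows")
  by_tree <- split(seq_len(nrow(pairs)),
                   factor(forest$tree_id[rows$mrca], levels = trees))
  with_seed(seed, {
    rho <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      pick <- sample.int(length(trees), replace = TRUE)
      idx <- unlist(by_tree[pick], use.names = FALSE)
      if (length(idx) < 3L) next
      ta <- pairs$tau_a[idx]; tb <- pairs$tau_b[idx]
      if (stats::sd(ta) == 0 || stats::sd(tb) == 0) next
      rho[b] <- stats::cor(ta, tb, method = "spearman")
    }
    skipped <- sum(is.na(rho))
    if (skipped > n_boot / 2) {
      stop_kc("kc_unstable_ci",
              sprintf("%d of %d bootstrap resamples unusable", skipped, n_boot))
    }
    ci <- stats::quantile(rho, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    structure(c(ci_low = ci[1], ci_high = ci[2]), n_skipped = skipped)
  })
}

#' Kinship-resolved correlation pattern of cycle lengths
#'
#' The correlation pattern - Spearman rank correlation per kinship with
#' tree-level bootstrap confidence bounds - is the summary statistic that
#' characterises inheritance: ancestral kinships `(0, v)` probe how fast
#' memory of the mother's cycle decays, intra-generational kinships
#' `(u, u)` (sisters, cousins) probe shared inherited state.
#'
#' @param forest A (truncated) lineage forest.
#' @param kinships List of kinships (default [default_kinships]).
#' @param n_boot,level,seed Passed to [bootstrap_ci].
#' @param min_pairs Kinships with fewer (unordered) pairs are flagged
#'   unreliable (default 10).
#' @return A data.frame of class `correlation_pattern` with columns `u`,
#'   `v`, `rho`, `ci_low`, `ci_high`, `n_pairs`, `reliable`. Kinships with
#'   too few pairs get `NA` estimates rather than failing.
#' @export
correlation_pattern <- function(forest, kinships = default_kinships(),
                                n_boot = 1000, level = 0.95, seed = NULL,
                                min_pairs = 10) {
  if (!isTRUE(attr(forest, "truncated"))) {
    warn_kc("kc_untruncated_warning",
            "forest not truncated; estimates may carry censoring bias")
  }
  n_trees <- length(unique(forest$tree_id))
  with_seed(seed, {
    rows <- lapply(kinships, function(k) {
      k <- as_kinship(k)
      pairs <- kin_pairs(forest, k)
      np <- if (k[1] == k[2]) nrow(pairs) / 2 else nrow(pairs)
      rho <- ci <- c(NA_real_, NA_real_)
      est <- NA_real_
      if (nrow(pairs) >= 3L && stats::sd(pairs$tau_a) > 0 &&
          stats::sd(pairs$tau_b) > 0) {
        est <- spearman_cor(pairs)
        if (n_boot <= 0) {
          ci <- c(NA_real_, NA_real_)
        } else if (n_trees >= 2L) {
          ci <- tryCatch(bootstrap_ci(forest, k, n_boot = n_boot,
                                      level = level),
                         kincycle_error = function(e) c(NA_real_, NA_real_))
        } else {
          ci <- c(est, est)
        }
      }
      data.frame(u = k[[1]], v = k[[2]], rho = est, ci_low = ci[[1]],
                 ci_high = ci[[2]], n_pairs = np,
                 reliable = is.finite(est) && np >= min_pairs)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("correlation_pattern", "data.frame")
    attr(out, "level") <- level
    attr(out, "min_pairs") <- min_pairs
    out
  })
}

#' @export
print.correlation_pattern <- function(x, digits = 3, ...) {
  cat("Cycle-length correlation pattern (Spearman, tree-level bootstrap CI)\n")
  df <- as.data.frame(x)
  df$kinship <- vapply(seq_len(nrow(df)), function(i) {
    kinship_label(c(df$u[i], df$v[i]))
  }, character(1))
  df <- df[, c("u", "v", "kinship", "rho", "ci_low", "ci_high", "n_pairs",
               "reliable")]
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}
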