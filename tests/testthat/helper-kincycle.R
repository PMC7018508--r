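# Fixture builders and independent oracles used across the suite.

# A complete binary tree as a raw cell table: generations 0..n_gen-1, fixed
# or supplied cycle lengths, all fates divided unless overridden.
make_binary_table <- function(n_gen = 3, tau = 18, tree_id = "t1") {
  idx <- seq_len(2^n_gen - 1L)
  gen <- floor(log2(idx))
  taus <- rep_len(tau, length(idx))
  birth <- numeric(length(idx))
  for (i in idx[-1]) birth[i] <- birth[i %/% 2L] + taus[i %/% 2L]
  data.frame(
    tree_id = tree_id, cell_id = as.character(idx),
    parent_id = ifelse(idx == 1L, NA_character_, as.character(idx %/% 2L)),
    birth_time_h = birth, end_time_h = birth + taus,
    fate = "divided", stringsAsFactors = FALSE
  )
}

# Brute-force kinship oracle: intersect full ancestor-path lists.
oracle_kinship <- function(df, a, b) {
  # assumes cell ids unique across the table (true for all fixtures here)
  path <- function(id) {
    out <- id
    repeat {
      p <- df$parent_id[match(id, df$cell_id)]
      if (is.na(p)) break
      out <- c(out, p)
      id <- p
    }
    out
  }
  pa <- path(a); pb <- path(b)
  common <- intersect(pa, pb)
  mrca <- common[which.min(match(common, pa))]
  sort(c(match(mrca, pa), match(mrca, pb)) - 1L)
}

# Brute-force pair enumeration: all ordered pairs of divided cells whose
# kinship (by the oracle) equals (u, v), with the elder first when u < v.
oracle_pair_count <- function(fo, u, v) {
  total <- 0L
  for (tid in unique(fo$tree_id)) {
    df <- as.data.frame(fo[fo$tree_id == tid, , drop = FALSE])
    div <- which(df$fate == "divided")
    for (i in div) for (j in div) {
      if (i == j) next
      k <- oracle_kinship(df, df$cell_id[i], df$cell_id[j])
      if (k[1] == u && k[2] == v) total <- total + 1L
    }
  }
  # the double loop counts both orderings; halve for asymmetric kinships
  # (kin_pairs lists those once) but keep both for symmetric ones
  if (u == v) total else total / 2L
}

# Per-generation completion fractions computed straight off the raw table.
oracle_completion <- function(fo) {
  sapply(sort(unique(fo$generation)), function(g) {
    mean(fo$fate[fo$generation == g] == "divided")
  })
}

# Forward-sample pairs of BAR relatives directly (independent of kin_cov):
# walk from the MRCA down both branches and return the two observed scores.
oracle_bar_pairs <- function(params, u, v, n) {
  d <- params$d
  C <- stationary_cov(params$A)
  A <- params$A
  x0 <- t(chol(C)) %*% matrix(rnorm(d * n), d, n)
  if (u == 0L) {
    xa <- x0
    xb <- x0
    for (i in seq_len(v)) {
      xb <- A %*% xb + matrix(rnorm(d * n), d, n)
    }
  } else {
    # first step off the MRCA carries the sister coupling
    xi1 <- matrix(rnorm(d * n), d, n)
    xi2 <- params$gamma * xi1 +
      sqrt(1 - params$gamma^2) * matrix(rnorm(d * n), d, n)
    xa <- A %*% x0 + xi1
    xb <- A %*% x0 + xi2
    for (i in seq_len(u - 1L)) xa <- A %*% xa + matrix(rnorm(d * n), d, n)
    for (i in seq_len(v - 1L)) xb <- A %*% xb + matrix(rnorm(d * n), d, n)
  }
  al <- params$alpha
  sdy <- sqrt(drop(t(al) %*% C %*% al))
  cbind(drop(t(al) %*% xa) / sdy, drop(t(al) %*% xb) / sdy)
}

ref_gp <- function(...) gp_params(...)

expect_within <- function(x, lo, hi) {
  expect_true(x >= lo && x <= hi,
              label = sprintf("%.4f in [%.4f, %.4f]", x, lo, hi))
}
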