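#' Kinship of two cells on a lineage tree
#'
#' The kinship of two distinct cells in the same tree is the ordered pair
#' `(u, v)`, `u <= v`, of their generation distances to their most recent
#' common ancestor (MRCA). `(0,1)` is mother-daughter, `(0,2)` grandmother,
#' `(1,1)` sisters, `(1,2)` aunt-niece, `(2,2)` first cousins, `(3,3)`
#' second cousins. In a stationary tree-autoregressive process the kinship
#' fully determines the covariance of the two cells.
#'
#' @param u,v Nonnegative integers, not both zero.
#' @return An integer vector `c(u, v)` of class `kinship` (sorted).
#' @export
kinship <- function(u, v) {
  u <- as.integer(u); v <- as.integer(v)
  if (length(u) != 1L || length(v) != 1L || is.na(u) || is.na(v) ||
      u < 0L || v < 0L || (u == 0L && v == 0L)) {
    stop_kc("kc_invalid_parameter",
            "kinship requires nonnegative integers (u, v) != (0, 0)")
  }
  structure(c(u = min(u, v), v = max(u, v)), class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("kinship (%d,%d) - %s\n", x[1], x[2], kinship_label(x)))
  invisible(x)
}

kinship_label <- function(k) {
  lbl <- c("0,1" = "mother-daughter", "0,2" = "grandmother",
           "0,3" = "great-grandmother", "1,1" = "sisters",
           "1,2" = "aunt-niece", "2,2" = "first cousins",
           "1,3" = "great-aunt", "3,3" = "second cousins")
  key <- paste(k[1], k[2], sep = ",")
  if (key %in% names(lbl)) lbl[[key]] else key
}

as_kinship <- function(k) {
  if (inherits(k, "kinship")) return(k)
  kinship(k[1], k[2])
}

#' The eight kinships used throughout: mother-daughter through second
#' cousins.
#' @return A list of [kinship] objects.
#' @export
default_kinships <- function() {
  lapply(list(c(0, 1), c(0, 2), c(0, 3), c(1, 1), c(1, 2), c(2, 2),
              c(1, 3), c(3, 3)), function(k) kinship(k[1], k[2]))
}

# Row index of each cell's ancestor at distance L (NA where the chain leaves
# the recorded tree). ancestor_rows(x, 0) is the identity.
ancestor_rows <- function(forest, L, pr = forest_parent_row(forest)) {
  a <- seq_len(nrow(forest))
  if (L == 0L) return(a)
  for (i in seq_len(L)) a <- pr[a]
  a
}

#' @rdname kinship
#' @param forest A lineage forest.
#' @param a,b Two distinct cells (row indices or `cell_id` values).
#' @export
kinship_of <- function(forest, a, b) {
  ra <- resolve_cells(forest, a)
  rb <- resolve_cells(forest, b)
  if (length(ra) != 1L || length(rb) != 1L || ra == rb) {
    stop_kc("kc_invalid_parameter", "kinship_of needs two distinct cells")
  }
  if (forest$tree_id[ra] != forest$tree_id[rb]) {
    stop_kc("kc_no_common_ancestor", "cells belong to different trees")
  }
  pr <- forest_parent_row(forest)
  anc_a <- ra
  r <- ra
  while (!is.na(pr[r])) { r <- pr[r]; anc_a <- c(anc_a, r) }
  r <- rb
  v <- 0L
  while (!(r %in% anc_a)) {
    r <- pr[r]
    v <- v + 1L
  }
  u <- which(anc_a == r) - 1L
  kinship(u, v)
}

#' Enumerate cycle-length pairs of a given kinship
#'
#' Collects all pairs of divided cells with kinship `k` across the forest.
#' For symmetric kinships (`u == v`) both orderings of every pair are
#' returned, so downstream correlation estimates are orientation-invariant;
#' for asymmetric kinships the elder cell (closer to the MRCA) is first.
#'
#' @param forest A lineage forest (normally truncated first, see
#'   [truncate_trees]).
#' @param k A [kinship] or integer pair `c(u, v)`.
#' @return A data.frame with columns `tau_a`, `tau_b` (hours); attribute
#'   `rows` holds the underlying row indices (`row_a`, `row_b`, `mrca`).
#' @export
kin_pairs <- function(forest, k) {
  k <- as_kinship(k)
  pr <- kin_pair_rows(forest, k)
  out <- data.frame(
    tau_a = forest$end_time_h[pr$row_a] - forest$birth_time_h[pr$row_a],
    tau_b = forest$end_time_h[pr$row_b] - forest$birth_time_h[pr$row_b]
  )
  attr(out, "rows") <- pr
  attr(out, "kinship") <- k
  out
}

# Ancestor-pointer cache shared by all kinship queries on one forest:
# anc[[L + 1]] holds each cell's ancestor row at distance L.
forest_kin_cache <- function(forest, max_depth) {
  pr <- forest_parent_row(forest)
  anc <- vector("list", max_depth + 1L)
  anc[[1]] <- seq_len(nrow(forest))
  for (L in seq_len(max_depth)) anc[[L + 1L]] <- pr[anc[[L]]]
  list(anc = anc, div = forest$fate == "divided")
}

# Vectorised pair enumeration via ancestor pointers; only fate == "divided"
# cells enter pairs.
kin_pair_rows <- function(forest, k, cache = NULL) {
  u <- k[[1]]; v <- k[[2]]
  if (is.null(cache) || length(cache$anc) <= max(u, v)) {
    cache <- forest_kin_cache(forest, max(u, v))
  }
  div <- cache$div

  if (u == 0L) {
    anc_v <- cache$anc[[v + 1L]]
    b <- which(div & !is.na(anc_v))
    a <- anc_v[b]
    keep <- div[a]
    return(data.frame(row_a = a[keep], row_b = b[keep], mrca = a[keep]))
  }

  anc_u <- cache$anc[[u + 1L]]
  anc_v <- cache$anc[[v + 1L]]
  anc_u1 <- cache$anc[[u]]
  anc_v1 <- cache$anc[[v]]

  ca <- which(div & !is.na(anc_u))
  cb <- which(div & !is.na(anc_v))
  if (!length(ca) || !length(cb)) {
    return(data.frame(row_a = integer(0), row_b = integer(0),
                      mrca = integer(0)))
  }
  jn <- cross_join_keys(anc_u[ca], anc_v[cb])
  row_a <- ca[jn$i]
  row_b <- cb[jn$j]
  # same first-step branch means the true MRCA is deeper than (u, v) claims
  keep <- anc_u1[row_a] != anc_v1[row_b]
  data.frame(row_a = row_a[keep], row_b = row_b[keep],
             mrca = anc_u[row_a[keep]])
}
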