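#' Lineage forests: tracked cells on lineage trees
#'
#' A *lineage forest* is the central data container: one row per tracked
#' cell, holding its tree membership, parentage, birth and end times (hours)
#' and its fate. Fates follow time-lapse tracking conventions: `divided`
#' (mitosis observed, so the cycle length is defined), `lost` (cell left the
#' field of view or tracking failed), `died`, or `censored` (still alive when
#' the movie ended). Generations are 0-based with the tree founder at
#' generation 0.
#'
#' @param x A data.frame with columns `tree_id`, `cell_id`, `parent_id`
#'   (`NA` or `""` for tree founders), `birth_time_h`, `end_time_h`, `fate`.
#'   Additional columns (e.g. simulator annotations) are carried along.
#' @param validate Check all structural invariants (default `TRUE`).
#' @param tol Tolerance (hours) for the parent-end / child-birth time match.
#' @return An object of class `lineage_forest` (a data.frame with a
#'   `generation` column added).
#' @examples
#' df <- data.frame(
#'   tree_id = "t1", cell_id = c("a", "b", "c"),
#'   parent_id = c(NA, "a", "a"),
#'   birth_time_h = c(0, 20, 20), end_time_h = c(20, 38, 41),
#'   fate = c("divided", "divided", "lost")
#' )
#' fo <- as_lineage_forest(df)
#' cycle_length(fo, "b")
#' @export
as_lineage_forest <- function(x, validate = TRUE, tol = 1e-6) {
  req <- c("tree_id", "cell_id", "parent_id", "birth_time_h", "end_time_h",
           "fate")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop_kc("kc_parse_error",
            paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$tree_id <- as.character(x$tree_id)
  x$cell_id <- as.character(x$cell_id)
  x$parent_id <- as.character(x$parent_id)
  x$parent_id[!is.na(x$parent_id) & x$parent_id == ""] <- NA_character_
  x$birth_time_h <- as.numeric(x$birth_time_h)
  x$end_time_h <- as.numeric(x$end_time_h)
  x$fate <- as.character(x$fate)

  pr <- forest_parent_row(x)
  if (validate) validate_forest(x, pr, tol = tol)
  x$generation <- assign_generations(x, pr)

  structure(x, class = c("lineage_forest", "data.frame"))
}

# Row index of each cell's mother (NA for founders). Recomputed on demand so
# that subsetting a forest cannot leave a stale index behind.
forest_parent_row <- function(x) {
  key <- paste(x$tree_id, x$cell_id, sep = "\r")
  pkey <- ifelse(is.na(x$parent_id), NA_character_,
                 paste(x$tree_id, x$parent_id, sep = "\r"))
  match(pkey, key)
}

validate_forest <- function(x, pr, tol = 1e-6) {
  n <- nrow(x)
  if (n == 0L) stop_kc("kc_parse_error", "empty cell table")

  key <- paste(x$tree_id, x$cell_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_kc("kc_parse_error",
            sprintf("duplicate cell_id '%s' in tree '%s' (row %d)",
                    x$cell_id[dup[1]], x$tree_id[dup[1]], dup[1]))
  }
  unresolved <- which(!is.na(x$parent_id) & is.na(pr))
  if (length(unresolved)) {
    stop_kc("kc_parse_error",
            sprintf("parent_id '%s' of cell '%s' (row %d) not found in tree '%s'",
                    x$parent_id[unresolved[1]], x$cell_id[unresolved[1]],
                    unresolved[1], x$tree_id[unresolved[1]]))
  }
  bad_fate <- which(!x$fate %in% c("divided", "lost", "died", "censored"))
  if (length(bad_fate)) {
    stop_kc("kc_parse_error",
            sprintf("unknown fate '%s' (row %d)", x$fate[bad_fate[1]],
                    bad_fate[1]))
  }
  bad_time <- which(!(x$end_time_h > x$birth_time_h))
  if (length(bad_time)) {
    stop_kc("kc_parse_error",
            sprintf("end_time_h <= birth_time_h for cell '%s' (row %d)",
                    x$cell_id[bad_time[1]], bad_time[1]))
  }
  roots_per_tree <- tapply(is.na(pr), x$tree_id, sum)
  multi <- names(roots_per_tree)[roots_per_tree > 1L]
  if (length(multi)) {
    stop_kc("kc_parse_error",
            sprintf("tree '%s' has %d founder cells (expected exactly 1)",
                    multi[1], roots_per_tree[[multi[1]]]))
  }
  none <- names(roots_per_tree)[roots_per_tree == 0L]
  if (length(none)) {
    stop_kc("kc_parse_error",
            sprintf("tree '%s' has no founder cell", none[1]))
  }

  kids <- which(!is.na(pr))
  if (length(kids)) {
    nk <- tabulate(pr[kids], n)
    too_many <- which(nk > 2L)
    if (length(too_many)) {
      stop_kc("kc_parse_error",
              sprintf("cell '%s' (row %d) has %d children (max 2)",
                      x$cell_id[too_many[1]], too_many[1], nk[too_many[1]]))
    }
    nondiv_parent <- kids[x$fate[pr[kids]] != "divided"]
    if (length(nondiv_parent)) {
      r <- nondiv_parent[1]
      stop_kc("kc_parse_error",
              sprintf("cell '%s' (row %d) has children but fate '%s'",
                      x$cell_id[pr[r]], pr[r], x$fate[pr[r]]))
    }
    off <- kids[abs(x$birth_time_h[kids] - x$end_time_h[pr[kids]]) > tol]
    if (length(off)) {
      stop_kc("kc_parse_error",
              sprintf("birth_time_h of cell '%s' (row %d) differs from parent end_time_h",
                      x$cell_id[off[1]], off[1]))
    }
  }
  invisible(TRUE)
}

assign_generations <- function(x, pr) {
  n <- nrow(x)
  gen <- rep(NA_integer_, n)
  gen[is.na(pr)] <- 0L
  repeat {
    todo <- which(is.na(gen) & !is.na(gen[pr]))
    if (!length(todo)) break
    gen[todo] <- gen[pr[todo]] + 1L
  }
  if (anyNA(gen)) {
    stop_kc("kc_parse_error",
            sprintf("parent pointers contain a cycle (cell '%s', row %d)",
                    x$cell_id[which(is.na(gen))[1]], which(is.na(gen))[1]))
  }
  gen
}

#' @export
print.lineage_forest <- function(x, ...) {
  nt <- length(unique(x$tree_id))
  cat(sprintf("Lineage forest: %d cells in %d tree(s), generations 0-%d\n",
              nrow(x), nt, max(x$generation)))
  ft <- table(x$fate)
  cat("  fates:", paste(sprintf("%s=%d", names(ft), ft), collapse = ", "), "\n")
  if (isTRUE(attr(x, "truncated"))) {
    cat(sprintf("  truncated at generation %d\n", attr(x, "truncation_depth")))
  }
  invisible(x)
}

#' @export
summary.lineage_forest <- function(object, ...) {
  div <- object$fate == "divided"
  tau <- object$end_time_h[div] - object$birth_time_h[div]
  out <- list(
    n_cells = nrow(object), n_trees = length(unique(object$tree_id)),
    max_generation = max(object$generation), fates = table(object$fate),
    cycle_length = if (length(tau)) summary(tau) else NULL
  )
  class(out) <- "summary.lineage_forest"
  out
}

#' @export
print.summary.lineage_forest <- function(x, ...) {
  cat(sprintf("Lineage forest: %d cells, %d trees, max generation %d\n",
              x$n_cells, x$n_trees, x$max_generation))
  print(x$fates)
  if (!is.null(x$cycle_length)) {
    cat("Cycle lengths (h) of divided cells:\n")
    print(x$cycle_length)
  }
  invisible(x)
}

#' Read and write lineage-tree tables
#'
#' Tab-separated tables with a header row and columns `tree_id`, `cell_id`,
#' `parent_id` (empty for tree founders), `birth_time_h`, `end_time_h`,
#' `fate`. Times are hours with a decimal point. Malformed tables (unresolved
#' parents, more than two children, parent/child time mismatch beyond `tol`,
#' duplicated ids) raise a parse error naming the offending row.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param tol Parent-end / child-birth tolerance in hours.
#' @return `read_tree_table` returns a [lineage_forest][as_lineage_forest];
#'   `write_tree_table` returns `path` invisibly.
#' @export
read_tree_table <- function(path, sep = "\t", tol = 1e-6) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = "",
                          stringsAsFactors = FALSE, check.names = TRUE)
  as_lineage_forest(df, validate = TRUE, tol = tol)
}

#' @rdname read_tree_table
#' @param forest A lineage forest.
#' @param extra Also write non-standard annotation columns (default `FALSE`).
#' @export
write_tree_table <- function(forest, path, sep = "\t", extra = FALSE) {
  std <- c("tree_id", "cell_id", "parent_id", "birth_time_h", "end_time_h",
           "fate")
  cols <- if (extra) union(std, names(forest)) else std
  out <- as.data.frame(forest)[, intersect(cols, names(forest)), drop = FALSE]
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Cell-cycle lengths
#'
#' The cycle length of a cell is `end_time_h - birth_time_h`, defined only
#' for cells whose division was observed (`fate == "divided"`).
#'
#' @param forest A lineage forest.
#' @param cells Cells to evaluate: row indices, a logical mask, or `cell_id`
#'   values (which must be unique across the forest). Default: all cells.
#' @return Numeric vector of cycle lengths in hours.
#' @export
cycle_length <- function(forest, cells = NULL) {
  rows <- resolve_cells(forest, cells)
  bad <- rows[forest$fate[rows] != "divided"]
  if (length(bad)) {
    stop_kc("kc_undefined_cycle",
            sprintf("cycle length undefined for cell '%s' (fate '%s')",
                    forest$cell_id[bad[1]], forest$fate[bad[1]]))
  }
  forest$end_time_h[rows] - forest$birth_time_h[rows]
}

resolve_cells <- function(forest, cells) {
  if (is.null(cells)) return(seq_len(nrow(forest)))
  if (is.logical(cells)) return(which(cells))
  if (is.numeric(cells)) return(as.integer(cells))
  idx <- match(cells, forest$cell_id)
  if (anyNA(idx)) {
    stop_kc("kc_parse_error",
            sprintf("cell_id '%s' not found", cells[which(is.na(idx))[1]]))
  }
  if (anyDuplicated(forest$cell_id)) {
    stop_kc("kc_parse_error",
            "cell_id values are not unique across trees; use row indices")
  }
  idx
}
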