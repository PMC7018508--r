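#' Truncate lineage trees to fully observed generations
#'
#' Finite observation time biases correlation estimates: cycles still
#' running at the end of the movie are preferentially long, so the deepest
#' generations over-represent short cycles. The remedy is to truncate all
#' trees after the last generation completed by the vast majority of cells.
#' Operationally, the truncation depth `G` is the largest generation index
#' such that every generation `0..G` has a dataset-wide fraction of divided
#' cells of at least `completion_fraction`. Cells of generation `> G` are
#' removed; cells of generation `G` with incomplete cycles (fate other than
#' `divided`) are retained but never enter correlation estimates.
#'
#' @param forest A lineage forest.
#' @param completion_fraction Minimum fraction of cells born in a generation
#'   that must have divided for the generation to count as complete
#'   (default 0.95).
#' @return The truncated forest, with attributes `truncated = TRUE`,
#'   `truncation_depth = G` and `completion` (per-generation fractions).
#'   If even generation 0 misses the threshold, `G = 0` with a warning.
#' @export
truncate_trees <- function(forest, completion_fraction = 0.95) {
  stopifnot(nrow(forest) > 0)
  gens <- sort(unique(forest$generation))
  comp <- vapply(gens, function(g) {
    mean(forest$fate[forest$generation == g] == "divided")
  }, numeric(1))
  ok <- comp >= completion_fraction
  if (!ok[1]) {
    warn_kc("kc_truncation_warning",
            sprintf("no generation reaches completion fraction %.2f; keeping generation 0 only",
                    completion_fraction))
    G <- 0L
  } else {
    run <- cumprod(ok) > 0  # TRUE while all generations so far are complete
    G <- gens[max(which(run))]
  }
  out <- forest[forest$generation <= G, , drop = FALSE]
  class(out) <- class(forest)
  attr(out, "truncated") <- TRUE
  attr(out, "truncation_depth") <- G
  attr(out, "completion") <- data.frame(generation = gens, fraction = comp)
  out
}
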