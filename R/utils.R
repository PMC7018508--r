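# Internal helpers shared across modules.

# Classed errors so callers can distinguish failure modes programmatically.
stop_kc <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "kincycle_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

warn_kc <- function(class, msg) {
  warning(structure(
    class = c(class, "kincycle_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL means: use the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# All-pairs equi-join: returns index pairs (i, j) into `key_a`, `key_b` with
# key_a[i] == key_b[j], fully vectorised (no per-group R loop).
cross_join_keys <- function(key_a, key_b) {
  keys <- unique(c(key_a, key_b))
  ga <- match(key_a, keys)
  gb <- match(key_b, keys)
  nk <- length(keys)
  cnt_a <- tabulate(ga, nk)
  cnt_b <- tabulate(gb, nk)
  ord_a <- order(ga)
  ord_b <- order(gb)
  start_a <- cumsum(c(0L, cnt_a))
  start_b <- cumsum(c(0L, cnt_b))
  total <- cnt_a * cnt_b
  if (sum(total) == 0L) {
    return(list(i = integer(0), j = integer(0)))
  }
  keyrep <- rep.int(seq_len(nk), total)
  pos <- sequence(total) - 1L
  i <- ord_a[start_a[keyrep] + pos %/% cnt_b[keyrep] + 1L]
  j <- ord_b[start_b[keyrep] + pos %% cnt_b[keyrep] + 1L]
  list(i = i, j = j)
}
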