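`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Allocate n integer counts proportional to non-negative weights p
# (largest-remainder rounding); every strictly positive weight keeps
# at least one count so no requested component vanishes.
largest_remainder <- function(p, n) {
  stopifnot(all(p >= 0), sum(p) > 0, n >= sum(p > 0))
  raw <- p / sum(p) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  for (i in which(p > 0 & base == 0)) {
    j <- which.max(base)
    base[j] <- base[j] - 1
    base[i] <- base[i] + 1
  }
  storage.mode(base) <- "integer"
  base
}

as_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != round(x))
    stop(sprintf("`%s` must be a single integer >= 1", name), call. = FALSE)
  as.integer(x)
}
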