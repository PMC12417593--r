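#' @importFrom methods as is
#' @importFrom stats rnorm sd pt t.test quantile
#' @importFrom utils head read.csv read.delim write.table
#' @importFrom data.table data.table rbindlist
NULL

.datatable.aware <- TRUE

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# 31-bit string hash (FNV-style polynomial roll), used by the hash embedding
# backend. Independent of R's RNG.
str_hash31 <- function(s, seed = 0L) {
  h <- (as.numeric(seed) %% 2147483647) + 2166136261 %% 2147483647
  cp <- utf8ToInt(s)
  for (c in cp) h <- (h * 127 + c + 1) %% 2147483647
  h
}

# Deterministic LCG stream in [-1, 1]; state is a 31-bit integer-valued double.
lcg_runif_sym <- function(state, n) {
  out <- numeric(n)
  for (k in seq_len(n)) {
    state <- (state * 48271) %% 2147483647
    out[k] <- 2 * (state / 2147483647) - 1
  }
  list(values = out, state = state)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Population standard deviation (n denominator); single value -> 0.
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Stratified allocation of `n_take` items across classes proportionally:
# floor of the ideal share per class, remainder to the largest fractional
# parts (ties: larger class first, then first-seen order).
stratified_counts <- function(class_sizes, n_take) {
  ideal <- class_sizes * n_take / sum(class_sizes)
  base <- floor(ideal)
  rem <- n_take - sum(base)
  if (rem > 0) {
    frac <- ideal - base
    ord <- order(-frac, -class_sizes, seq_along(class_sizes))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}
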