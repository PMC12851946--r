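# Internal helpers: seeded RNG plumbing, validation, small numeric utilities.

#' Derive a stage-specific seed from a global seed
#'
#' All stochastic stages draw their seed deterministically from the single
#' pipeline seed, so that re-running any stage in isolation reproduces the
#' values it saw inside a full run. Derived seeds stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage label (hashed into an offset).
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  off <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(seed)) * 69069 + off * 2654435 + 1) %% 2147483647)
}

#' Evaluate an expression under a local, restored RNG state
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# largest-remainder apportionment of n into round(n * p) with sum exactly n
apportion <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-6)
  raw <- n * p
  k <- floor(raw)
  rem <- raw - k
  short <- n - sum(k)
  if (short > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    k[idx] <- k[idx] + 1
  }
  as.integer(k)
}
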