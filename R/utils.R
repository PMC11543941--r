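# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state, so seeded operations do not
#' disturb the caller's random stream. `seed = NULL` uses the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a global seed
#'
#' Stable integer hash so one global seed fans out to reproducible,
#' distinct per-stage seeds.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 1) + 1)
}

# stopifnot-style check with a formatted message
.check <- function(ok, ...) if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)

# truncated-at-zero normal draws by inverse CDF; exact, no rejection loop
.rtnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, lo, 1)
  q <- stats::qnorm(u, mean, sd)
  pmax(q, 0)  # guard against u == lo rounding below the bound
}
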