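# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pr <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_pr(msg)
  invisible(TRUE)
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not perturb the caller's
#' random stream. `seed = NULL` leaves the RNG alone.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed (kept below 2^31) from a base seed.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 131 + as.numeric(index) * 7919) %% 2147483629)
}

# Normal draws truncated at a lower floor by resampling (physical floors such
# as CD45 >= 0 or cell counts >= 0); falls back to the floor when sd == 0 and
# the mean lies below it.
rnorm_floor <- function(n, mean, sd, floor = 0) {
  x <- rnorm(n, mean, sd)
  for (it in 1:100) {
    bad <- which(x < floor)
    if (!length(bad)) return(x)
    if (sd == 0) { x[bad] <- pmax(mean, floor); return(x) }
    x[bad] <- rnorm(length(bad), mean, sd)
  }
  x[x < floor] <- floor
  x
}

is_binary_array <- function(x) {
  is.array(x) && all(x %in% c(0, 1, TRUE, FALSE))
}
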