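#' @keywords internal
"_PACKAGE"

## Classed conditions so callers (and the CLI) can distinguish failure modes.
mr_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mrcore_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

format_error     <- function(msg, ...) mr_stop("mrcore_format_error", msg, ...)
data_error       <- function(msg, ...) mr_stop("mrcore_data_error", msg, ...)
parameter_error  <- function(msg, ...) mr_stop("mrcore_parameter_error", msg, ...)
estimation_error <- function(msg, ...) mr_stop("mrcore_estimation_error", msg, ...)
usage_error      <- function(msg, ...) mr_stop("mrcore_usage_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
## stream. All randomized operations in the package go through this, so
## results depend only on the seeds passed in, never on call order.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed from a master seed and context labels
#'
#' Hashes the master seed together with an arbitrary sequence of labels
#' (method name, group index, scope, replicate number, ...) into a
#' deterministic integer seed. Used throughout the package so that every
#' randomized step (tie-breaking, bootstrap resampling, simulation
#' replicates) receives its own seed that does not depend on the order in
#' which steps are executed.
#'
#' @param seed Integer master seed.
#' @param ... Further labels (coerced to character) identifying the context.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "weighted_median", 3, "cumulative")
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\x1f")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

## Weighted median by cumulative-weight interpolation: with sorted values
## b_(1) <= ... <= b_(J) and standardized weights s_j, the quantile position
## of b_(j) is p_j = sum_{i<=j} s_i - s_j / 2; the estimate interpolates the
## sorted values at p = 0.5.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  s <- w[o] / sum(w)
  p <- cumsum(s) - s / 2
  stats::approx(x = p, y = b, xout = 0.5, rule = 2, ties = "ordered")$y
}
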