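#' Derive a reproducible 31-bit seed from a base seed and stream labels
#'
#' Folds any number of non-negative integers into a single seed below
#' 2^31 - 1 with a multiplicative hash, so that independent random streams
#' (per subject, per frame, per training run) can all be derived from one
#' experiment base seed.
#'
#' @param base integer base seed (>= 0)
#' @param ... further non-negative integers identifying the stream
#' @return a single integer in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(base, ...) {
  parts <- c(base, ...)
  if (any(!is.finite(parts)) || any(parts < 0)) {
    stop("seed components must be finite and non-negative")
  }
  acc <- 0
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  for (p in parts) {
    acc <- (acc * 69069 + (p %% m) + 1) %% m
  }
  as.integer(acc)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

clamp01 <- function(x) {
  # index assignment (not pmin/pmax) so dim and other attributes survive
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
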