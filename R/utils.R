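#' Derive a reproducible child seed from a master seed and a stream name
#'
#' All randomness in the package flows from a single master seed through
#' named streams, so stages can be re-run independently without sharing
#' global RNG state.
#'
#' @param seed Integer master seed.
#' @param name Character stream name (e.g. `"counts"`, `"run17"`).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  s <- (abs(seed) %% m) * 48271 %% m
  as.integer((s + h) %% (m - 1) + 1)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so callers never perturb the global
#' RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# stop() with a consistent prefix for user-input validation failures
abort_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# key=value structured log line on stderr
log_line <- function(stage, ...) {
  kv <- list(...)
  msg <- paste0(
    "stage=", stage,
    if (length(kv)) paste0(" ", paste(names(kv), unlist(kv), sep = "=", collapse = " ")) else ""
  )
  message(msg)
  invisible(msg)
}

# row variances of a numeric matrix without matrixStats
row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}
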