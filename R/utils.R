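# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's `.Random.seed`, so
#' generators are bit-reproducible without clobbering the session RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# p-value floor used throughout: avoids -Inf on the log scale downstream.
P_FLOOR <- 1e-300

floor_p <- function(p) pmax(p, P_FLOOR)

# Two-sided normal p from a z score (large-sample convention used by the
# marginal scan and the association engine).
z_to_p <- function(z) floor_p(2 * pnorm(-abs(z)))

# Derive a stream-specific child seed from a user seed.  Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101L + offset) %% 2147483647)
}

# Mean-impute missing entries of a dosage matrix, column by column.
impute_mean <- function(X) {
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2L]]
  X[is.na(X)] <- 0  # columns that were entirely missing
  X
}
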