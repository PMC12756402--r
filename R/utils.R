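# Internal numeric helpers shared across modules.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed with a max shift.
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp for a matrix of log values (combos in rows,
# families in columns); fixed left-to-right summation for reproducibility.
logsumexp_cols <- function(x) {
  m <- apply(x, 2, max)
  finite <- is.finite(m)
  out <- m
  if (any(finite)) {
    sh <- sweep(x[, finite, drop = FALSE], 2, m[finite], "-")
    out[finite] <- m[finite] + log(colSums(exp(sh)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic seed stream: derive child seeds from a master seed without
# consuming the global RNG state. Keeps every derived seed below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483629) + 1L
}

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
  force(expr)
}
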