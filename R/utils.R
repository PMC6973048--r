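# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so that seeded package functions do not perturb the
#' caller's random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer scalar or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible sub-seed from a master seed and a character tag.
# Keeps results below 2^31 so the value is a valid R integer.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(paste0(tag, collapse = "/")) *
             (seq_along(utf8ToInt(paste0(tag, collapse = "/"))) %% 97L + 1L))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

#' Moment skewness
#'
#' Skewness as the third standardized central moment, \eqn{m_3 / m_2^{3/2}},
#' with moments computed with denominator `n` (no small-sample correction).
#'
#' @param x numeric vector.
#' @return skewness, or `NA` when fewer than 3 values or zero variance.
#' @examples
#' moment_skewness(c(3, 5, 5, 7))   # symmetric -> 0
#' @export
moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Moment kurtosis
#'
#' Kurtosis as the fourth standardized central moment, \eqn{m_4 / m_2^2}
#' (normal distribution = 3). Set `excess = TRUE` to subtract 3.
#'
#' @param x numeric vector.
#' @param excess subtract 3? Default `FALSE` (raw kurtosis).
#' @return kurtosis, or `NA` when fewer than 4 values or zero variance.
#' @export
moment_kurtosis <- function(x, excess = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  k <- mean((x - m)^4) / m2^2
  if (excess) k - 3 else k
}

# stop() with a consistent prefix-free message built by sprintf
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
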