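#' @keywords internal
#' @importFrom utils head tail modifyList
#' @importFrom stats approx dnorm dpois ppois rpois runif rnorm var t.test
"_PACKAGE"

# Shared validators and small numeric helpers.

stop_if <- function(cond, ..., call. = FALSE) {
  if (isTRUE(cond)) stop(..., call. = call.)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integer = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("'%s' must be a single finite number", name))
  stop_if(integer && x != round(x),
          sprintf("'%s' must be an integer", name))
  stop_if(x < lower || x > upper,
          sprintf("'%s' must be in [%s, %s]", name, lower, upper))
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Derive a reproducible substream seed
#'
#' Expands one global seed into independent per-unit seeds with a counter
#' scheme, so that the draws attached to unit `i` do not depend on how many
#' other units are simulated or on their order. The mixing constant is a
#' large odd multiplier; results are reduced modulo 2^31 - 1 to stay inside
#' R's integer range.
#'
#' @param seed Integer global seed.
#' @param index Nonnegative integer counter (e.g. gene index, sample index).
#' @param stream Small integer separating independent uses of the same index
#'   (parameters vs. noise, etc.).
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, index, stream = 0L) {
  assert_scalar_number(seed, "seed", integer = TRUE)
  assert_scalar_number(index, "index", lower = 0, integer = TRUE)
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) + 1
  s <- (s * 48271 + as.numeric(index) * 16807 + as.numeric(stream) * 69621) %% m
  as.integer(s)
}

# rowwise mean/var for matrices without extra dependencies
row_means <- function(m) .rowMeans(m, nrow(m), ncol(m))
row_vars <- function(m) {
  n <- ncol(m)
  mu <- row_means(m)
  .rowSums((m - mu)^2, nrow(m), ncol(m)) / (n - 1)
}
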