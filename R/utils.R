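#' @keywords internal
"_PACKAGE"

#' @importFrom stats acf approx cor kruskal.test median optim predict quantile
#'   rlogis rnorm runif sd setNames var dnorm pnorm
#' @importFrom utils combn head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible integer seed from a base seed and a label
#'
#' Streams of randomness (per subject, per visit, kinematics vs scores) are
#' split deterministically so that changing one stream never reshuffles
#' another. The derived seed is always in `[1, 2^31 - 2]`.
#'
#' @param seed integer base seed.
#' @param ... labels (character or numeric) identifying the substream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 104729
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h + 1L)
}

stop_arg <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_arg(...)
  invisible(TRUE)
}

#' Centered moving average with shrinking symmetric edge windows
#'
#' Interior samples use the full centered window; at distance `k` from either
#' edge the window shrinks symmetrically to `2k + 1` samples, so the output
#' has the same length as the input and no phase shift is introduced.
#'
#' @param x numeric vector.
#' @param window odd integer window size.
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window = 21L) {
  n <- length(x)
  assert_that(window >= 1 && window %% 2 == 1, "`window` must be an odd integer >= 1")
  assert_that(window <= n, "`window` (", window, ") exceeds the series length (", n, ")")
  if (window == 1L || n == 1L) return(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  k <- pmin(half, i - 1L, n - i)  # usable half-width at each sample
  (cs[i + k + 1] - cs[i - k]) / (2 * k + 1)
}

# logistic moment estimate of the scale: sqrt(3) * sd / pi
logistic_moment_scale <- function(x) sqrt(3) * sd(x) / pi

compact_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}
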