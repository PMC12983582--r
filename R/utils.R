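#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats fft quantile sd var cor lm coef prcomp approx splinefun
#'   rnorm runif median setNames mvfft optim predict IQR
#' @importFrom utils head tail modifyList
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# unwrap a wrapped phase sequence (radians) into a continuous one
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  d <- diff(p)
  jumps <- cumsum((d < -pi) - (d > pi))
  p + c(0, jumps) * 2 * pi
}

# centred first difference, one-sided at the ends (like a gradient)
grad1 <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  g <- numeric(n)
  g[1] <- x[2] - x[1]
  g[n] <- x[n] - x[n - 1]
  if (n > 2L) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  g
}

rms <- function(x) sqrt(mean(x^2))

# indices of strict local maxima of x
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # collapse flat tops by treating zero slopes as inheriting the previous sign
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  which(diff(s) < 0) + 1L
}

local_minima <- function(x) local_maxima(-x)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", name, format(lower), format(upper)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
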