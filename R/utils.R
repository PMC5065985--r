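#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor fft mvfft nextn quantile rnorm runif sd
#' @importFrom utils read.table write.table
NULL

# Wrap angles to the half-open interval (-pi, pi].
wrap_phase <- function(x) {
  y <- x %% (2 * pi)
  y - 2 * pi * (y > pi)
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# Smallest integers (n, m) with n * f_m == m * f_n. Frequencies are assumed to
# lie on a grid of multiples of `grid` Hz (default 1/8 Hz, the wavelet grid).
nm_ratio <- function(f_m, f_n, grid = 0.125) {
  a <- round(f_m / grid)
  b <- round(f_n / grid)
  if (a <= 0L || b <= 0L) stop("frequencies must be positive", call. = FALSE)
  if (abs(a * grid - f_m) > 1e-9 || abs(b * grid - f_n) > 1e-9) {
    stop("frequencies must lie on the ", grid, "-Hz grid", call. = FALSE)
  }
  g <- gcd_int(a, b)
  c(n = b / g, m = a / g)
}

# Cumulative phase from a wrapped series (inverse of wrap_phase up to constant).
unwrap_phase <- function(x) {
  if (length(x) < 2L) return(x)
  d <- wrap_phase(diff(x))
  cumsum(c(x[1L], d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
    stop("`", name, "` must be a single positive integer", call. = FALSE)
  }
  invisible(as.integer(x))
}
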