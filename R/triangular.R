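#' The triangular distribution
#'
#' Density and random generation for the triangular distribution on
#' `[min, max]` with peak at `mode`, used throughout the network-formation
#' simulator because only the range and a central value of the empirical
#' association indices are recoverable, not their full distribution.
#'
#' Sampling uses the closed-form inverse CDF applied to a uniform draw, so a
#' degenerate distribution (`min == mode == max`) returns the constant.
#'
#' @param n Number of draws.
#' @param x Vector of quantiles.
#' @param min,mode,max Distribution parameters, `min <= mode <= max`
#'   (vectors are recycled to the length of the draw).
#' @return `rtriangular`: numeric vector of draws in `[min, max]`;
#'   `dtriangular`: densities.
#' @examples
#' set.seed(1)
#' mean(rtriangular(1e4, 0, 0.2, 1)) # ~ (0 + 0.2 + 1) / 3
#' @export
rtriangular <- function(n, min, mode, max) {
  check_triangular(min, mode, max)
  min <- rep_len(min, n)
  mode <- rep_len(mode, n)
  max <- rep_len(max, n)
  u <- stats::runif(n)
  width <- max - min
  fc <- ifelse(width > 0, (mode - min) / width, 0)
  lower <- u < fc | width == 0
  out <- numeric(n)
  out[lower] <- min[lower] + sqrt(u[lower] * width[lower] * (mode[lower] - min[lower]))
  out[!lower] <- max[!lower] -
    sqrt((1 - u[!lower]) * width[!lower] * (max[!lower] - mode[!lower]))
  pmin(pmax(out, min), max)
}

#' @rdname rtriangular
#' @export
dtriangular <- function(x, min, mode, max) {
  check_triangular(min, mode, max)
  k <- length(x)
  min <- rep_len(min, k)
  mode <- rep_len(mode, k)
  max <- rep_len(max, k)
  out <- numeric(k)
  up <- x >= min & x < mode
  down <- x >= mode & x <= max
  out[up] <- 2 * (x[up] - min[up]) / ((max[up] - min[up]) * (mode[up] - min[up]))
  out[down] <- 2 * (max[down] - x[down]) /
    ((max[down] - min[down]) * (max[down] - mode[down]))
  out[x == mode & max == min] <- Inf
  out[is.nan(out)] <- 0
  out
}

check_triangular <- function(min, mode, max) {
  if (any(!(min <= mode & mode <= max))) {
    abort("Triangular parameters must satisfy min <= mode <= max.")
  }
  invisible(TRUE)
}
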