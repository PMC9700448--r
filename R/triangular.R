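#' Triangular duration distribution
#'
#' Three-parameter triangular distribution on `[lower, upper]` with mode
#' `mode`, in minutes.  Used as the duration law for every subprocess of the
#' admission pathway.
#'
#' @param lower Lower bound (minutes, >= 0).
#' @param mode  Mode (minutes), `lower <= mode <= upper`.
#' @param upper Upper bound (minutes).
#' @return An object of class `triangular_dist`.
#' @examples
#' d <- triangular_dist(9.3, 14, 18.7)
#' tri_mean(d); tri_sd(d)
#' @export
triangular_dist <- function(lower, mode, upper) {
  stopifnot(is.numeric(lower), is.numeric(mode), is.numeric(upper),
            length(lower) == 1L, length(mode) == 1L, length(upper) == 1L)
  if (lower < 0)
    stop("triangular_dist: lower bound must be >= 0 (durations in minutes)")
  if (!(lower <= mode && mode <= upper))
    stop("triangular_dist: need lower <= mode <= upper")
  structure(list(lower = lower, mode = mode, upper = upper),
            class = "triangular_dist")
}

#' @export
print.triangular_dist <- function(x, ...) {
  cat(sprintf("triangular(lower = %.4g, mode = %.4g, upper = %.4g)  mean = %.4g, sd = %.4g\n",
              x$lower, x$mode, x$upper, tri_mean(x), tri_sd(x)))
  invisible(x)
}

#' Analytic moments of a triangular distribution
#'
#' @param dist A [triangular_dist()].
#' @return Mean, variance or standard deviation in minutes (resp. minutes^2).
#' @export
tri_mean <- function(dist) (dist$lower + dist$mode + dist$upper) / 3

#' @rdname tri_mean
#' @export
tri_var <- function(dist) {
  a <- dist$lower; m <- dist$mode; b <- dist$upper
  (a^2 + m^2 + b^2 - a * m - a * b - m * b) / 18
}

#' @rdname tri_mean
#' @export
tri_sd <- function(dist) sqrt(tri_var(dist))

#' Fit a symmetric triangular distribution from a mean and SD
#'
#' Returns the unique symmetric triangular distribution matching the two
#' given moments: `mode = mean`, `lower = mean - sd * sqrt(6)`,
#' `upper = mean + sd * sqrt(6)`.  The admission model only ever sees a
#' duration's mean and SD, which do not identify skew, so the symmetric
#' member is used throughout.
#'
#' If the implied lower bound is negative it is clipped to 0 and the upper
#' bound reset to `3 * mean - mode - lower` so the mean is preserved; the
#' variance then undershoots the requested one and a warning is emitted.
#'
#' @param mean Target mean (minutes, > 0).
#' @param sd   Target standard deviation (minutes, >= 0).
#' @return A [triangular_dist()] whose analytic mean equals `mean` and,
#'   absent clipping, whose analytic SD equals `sd`.
#' @examples
#' fit_triangular_from_moments(525.5, 93.5)
#' @export
fit_triangular_from_moments <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("fit_triangular_from_moments: mean must be a positive number")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("fit_triangular_from_moments: sd must be a non-negative number")
  half <- sd * sqrt(6)
  lower <- mean - half
  upper <- mean + half
  mode <- mean
  if (lower < 0) {
    warning(sprintf(paste0(
      "fit_triangular_from_moments: implied lower bound %.3f < 0; ",
      "clipped to 0 (mean preserved, variance undershoots)"), lower))
    lower <- 0
    upper <- 3 * mean - mode - lower
  }
  triangular_dist(lower, mode, upper)
}

#' Triangular quantile function
#'
#' Inverse CDF of a triangular distribution, vectorised over `p`.  This is
#' the single entry point through which pre-drawn uniforms become service
#' durations, which keeps common random numbers synchronised across
#' scenarios (a scaled distribution maps the same uniform to a scaled
#' duration).
#'
#' @param p Probabilities in `[0, 1]`.
#' @param dist A [triangular_dist()].
#' @return Quantiles in minutes.
#' @export
qtri <- function(p, dist) {
  a <- dist$lower; m <- dist$mode; b <- dist$upper
  if (b == a) return(rep(a, length(p)))
  fc <- (m - a) / (b - a)
  out <- numeric(length(p))
  left <- p <= fc
  out[left] <- a + sqrt(p[left] * (b - a) * (m - a))
  out[!left] <- b - sqrt((1 - p[!left]) * (b - a) * (b - m))
  out
}

#' Exponential arrival process
#'
#' @param mean_interarrival Mean inter-arrival time in minutes (> 0).
#' @return An object of class `exponential_arrival`.
#' @export
exponential_arrival <- function(mean_interarrival) {
  stopifnot(is.numeric(mean_interarrival), length(mean_interarrival) == 1L)
  if (!is.finite(mean_interarrival) || mean_interarrival <= 0)
    stop("exponential_arrival: mean_interarrival must be > 0")
  structure(list(mean_interarrival = mean_interarrival),
            class = "exponential_arrival")
}

#' @export
print.exponential_arrival <- function(x, ...) {
  cat(sprintf("exponential arrivals, mean inter-arrival %.4g min (%.3g/day)\n",
              x$mean_interarrival, 1440 / x$mean_interarrival))
  invisible(x)
}
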