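#' Organ length under negative-exponential growth
#'
#' Organ elongation follows the negative-exponential law
#' \deqn{l(t) = l_{max} (1 - e^{-r t / l_{max}})}
#' where \code{r} is the initial elongation rate (the derivative at t = 0)
#' and \code{l_max} the asymptotic maximal organ length.
#'
#' @param t age of the organ since emergence (days); vectorized.
#' @param r initial elongation rate (cm d^-1), > 0.
#' @param l_max maximal organ length (cm), > 0.
#' @return organ length (cm), in [0, l_max).
#' @seealso [age_at_length()] for the inverse map.
#' @export
#' @examples
#' length_at_age(7, r = 4.627, l_max = 139)
length_at_age <- function(t, r, l_max) {
  if (any(r <= 0) || any(l_max <= 0)) stop("r and l_max must be positive")
  if (any(t < 0)) stop("t must be non-negative")
  l_max * (1 - exp(-r * t / l_max))
}

#' Age at which an organ reaches a given length
#'
#' Inverse of [length_at_age()]:
#' \deqn{t(l) = -\frac{l_{max}}{r} \log(1 - l / l_{max})}
#' Used to convert distance-from-base conductivity profiles into
#' age-dependent profiles, and to assign creation times to simulated
#' root segments.
#'
#' @param l length (cm), must satisfy 0 <= l < l_max (the age at l_max is
#'   infinite and is rejected).
#' @inheritParams length_at_age
#' @return age (days).
#' @export
age_at_length <- function(l, r, l_max) {
  if (any(r <= 0) || any(l_max <= 0)) stop("r and l_max must be positive")
  if (any(l < 0)) stop("l must be non-negative")
  if (any(l >= l_max)) {
    stop("l >= l_max: age undefined for lengths at or beyond the asymptote")
  }
  -l_max / r * log(1 - l / l_max)
}

#' Fit the initial elongation rate to a length time series
#'
#' Least-squares fit of the negative-exponential growth curve to a
#' (time, cumulative length) series with the maximal length held fixed,
#' estimating only the initial elongation rate r. The 1-D residual sum of
#' squares is minimized by bounded Brent search on r in (0, 50] cm d^-1.
#'
#' @param t observation times (days), strictly increasing, length >= 2.
#' @param len cumulative organ lengths (cm), non-decreasing, all < l_max.
#' @param l_max fixed maximal length (cm). Axial maize roots use 139 cm.
#' @return an object of class \code{growth_fit}: list with \code{r_hat},
#'   \code{l_max_fixed}, \code{rss} (cm^2) and \code{n_points}.
#' @export
fit_elongation <- function(t, len, l_max) {
  if (length(t) != length(len)) stop("t and len must have equal length")
  if (length(t) < 2) stop("at least 2 points are required")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (any(diff(len) < 0)) stop("lengths must be non-decreasing")
  if (any(len >= l_max)) stop("lengths must be below l_max")
  if (all(len == 0)) stop("all lengths are zero: elongation rate not identifiable")
  rss <- function(r) sum((len - length_at_age(t, r, l_max))^2)
  opt <- stats::optimize(rss, interval = c(1e-8, 50), tol = 1e-12)
  structure(
    list(r_hat = opt$minimum, l_max_fixed = l_max,
         rss = opt$objective, n_points = length(t)),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Elongation fit: r = %.4f cm/d (l_max fixed at %g cm, RSS %.4g, n = %d)\n",
              x$r_hat, x$l_max_fixed, x$rss, x$n_points))
  invisible(x)
}

#' Trim the declining-elongation phase from a leaf growth series
#'
#' Leaf elongation data are only informative for the initial rate while the
#' daily increment has not yet started to decline. Trailing points are
#' dropped once the finite-difference daily increment falls below a fraction
#' of the maximum observed increment.
#'
#' @inheritParams fit_elongation
#' @param frac cutoff as a fraction of the maximum observed daily increment
#'   (default 0.2).
#' @return list with trimmed \code{t} and \code{len}.
#' @export
trim_declining_phase <- function(t, len, frac = 0.2) {
  if (length(t) < 3) return(list(t = t, len = len))
  inc <- diff(len) / diff(t)
  cut <- which(inc < frac * max(inc))
  keep <- if (length(cut) == 0) length(t) else min(cut)
  list(t = t[seq_len(keep)], len = len[seq_len(keep)])
}

#' Convert a distance-from-base profile to an age profile
#'
#' Conductivity atlases tabulate hydraulic properties against distance from
#' the root base; the simulator needs them against segment age. Each
#' distance is mapped through [age_at_length()] using the root type's
#' elongation parameters; the profile values are unchanged.
#'
#' @param distance distances from the root base (cm), each in [0, l_max).
#' @param value profile values at those distances.
#' @inheritParams length_at_age
#' @return data.frame with columns \code{age} (days) and \code{value}.
#' @export
distance_profile_to_age_profile <- function(distance, value, r, l_max) {
  if (length(distance) != length(value)) {
    stop("distance and value must have equal length")
  }
  if (length(distance) == 0) {
    return(data.frame(age = numeric(0), value = numeric(0)))
  }
  bad <- which(distance >= l_max)
  if (length(bad) > 0) {
    stop(sprintf("distance entry %d (%.3f cm) is at or beyond l_max = %g cm",
                 bad[1], distance[bad[1]], l_max))
  }
  data.frame(age = age_at_length(distance, r, l_max), value = value)
}
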