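#' @name synthetic_data
#' @title Synthetic data generators with known ground truth
#'
#' @description
#' Every input the analysis pipeline consumes can be generated
#' synthetically with a machine-readable truth record: rhizotron-style
#' per-root length time series (negative-exponential growth plus
#' measurement noise), RSML time series of simulated root systems,
#' age-dependent hydraulic property profiles, and linear/capped-linear
#' dose-response datasets. All generators are deterministic under a fixed
#' seed. Default noise magnitudes emulate tracing error: root length
#' s.d. 0.5 cm, radii 10 % relative, response values 5 % relative.
NULL

#' Default rhizotron imaging days
#'
#' Daily imaging to day 21, then every other day to 28.
#'
#' @return numeric vector of days after sowing.
#' @export
default_imaging_days <- function() {
  c(1:21, seq(23, 27, by = 2), 28)
}

#' Generate a noisy root-length time series
#'
#' Lengths follow the negative-exponential growth law plus Gaussian
#' noise, clipped to be non-negative and non-decreasing (as a traced
#' cumulative root length is).
#'
#' @param r true initial elongation rate (cm d^-1).
#' @param l_max true maximal length (cm).
#' @param days observation days.
#' @param noise_sd measurement noise s.d. (cm).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return list with \code{data} (data.frame day, length) and
#'   \code{truth} (list r, l_max, noise_sd).
#' @export
gen_root_length_series <- function(r = 3, l_max = 139,
                                   days = default_imaging_days(),
                                   noise_sd = 0.5, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  len <- length_at_age(days, r, l_max)
  if (noise_sd > 0) {
    len <- len + stats::rnorm(length(days), 0, noise_sd)
    len <- cummax(pmax(len, 0))
  }
  list(data = data.frame(day = days, length = len),
       truth = list(r = r, l_max = l_max, noise_sd = noise_sd))
}

#' Generate a synthetic rhizotron RSML time series
#'
#' Simulates one plant and writes one RSML file per imaging day with the
#' root system as it stood that day, projected to the rhizotron (x-z)
#' plane (the y coordinate is written as zero), with root ids consistent
#' across days and the primary root first in every file. A truth record
#' (the generating parameters and seed) is written as JSON next to the
#' RSML files.
#'
#' @param params a \code{plant_params} object.
#' @param days imaging days.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return list with \code{files} (RSML paths by day), \code{truth_file},
#'   \code{network} (the full \code{plant_network}).
#' @export
gen_synthetic_rhizotron <- function(params, days = default_imaging_days(),
                                    seed = 1L, dir = tempfile("rhizotron")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- simulate_plant(params, t_end = max(days), seed = seed)
  files <- character(0)
  for (d in days) {
    sub <- network_at_time(net, d)
    roots <- network_to_rsml(sub, project_2d = TRUE)
    f <- file.path(dir, sprintf("day_%05.1f.rsml", d))
    write_rsml(roots, f)
    files <- c(files, f)
  }
  truth_file <- file.path(dir, "truth.json")
  truth <- list(treatment = params$treatment, seed = seed, days = days,
                root_means = lapply(params$roots, function(rt) {
                  list(a = unname(rt$a), r = unname(rt$r),
                       l_max = unname(rt$l_max))
                }))
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA)
  list(files = stats::setNames(files, days), truth_file = truth_file,
       network = net)
}

#' Generate a synthetic age-dependent hydraulic profile
#'
#' Per root type, the radial conductivity decreases monotonically with
#' segment age and the axial conductance increases, as piecewise-linear
#' knot tables. The default magnitudes are those of the packaged
#' synthetic stand-in profile, optionally rescaled.
#'
#' @param kr_scale multiplier on all radial conductivities.
#' @param kx_scale multiplier on all axial conductances.
#' @inheritParams hydraulic_profile
#' @return list with \code{profile} (a \code{hydraulic_profile}) and
#'   \code{truth} (the knot table actually used).
#' @export
gen_hydraulic_profile <- function(kr_scale = 1, kx_scale = 1,
                                  a_xyl_frac = 0.1) {
  if (kx_scale <= 0) stop("K_x scale must be positive")
  path <- system.file("extdata", "hydraulic_profile_synthetic.csv",
                      package = "rhizoconduct", mustWork = TRUE)
  knots <- utils::read.csv(path, stringsAsFactors = FALSE)
  knots$kr <- knots$kr * kr_scale
  knots$kx <- knots$kx * kx_scale
  list(profile = hydraulic_profile(knots, a_xyl_frac = a_xyl_frac),
       truth = knots)
}

#' Generate a dose-response dataset with known coefficients
#'
#' Draws axial radii (linear in P), crown elongation rates (capped-linear
#' in PB) and leaf elongation rates (linear in P) with multiplicative
#' Gaussian noise around the true response curves.
#'
#' @param P_levels soil P levels (>= 4 required for a meaningful fit).
#' @param DM plant dry matter per level (g), recycled.
#' @param alpha_a,a_P0 radius response slope and intercept.
#' @param alpha_rc,PB_max crown elongation slope and cap.
#' @param alpha_rl,r_P0 leaf elongation slope and intercept.
#' @param n_per_level replicate plants per P level.
#' @param noise_rel relative noise s.d. (default 5 %).
#' @param seed integer seed, or NULL.
#' @return list with \code{data} (data.frame P, PB, radius, rc, rl) and
#'   \code{truth}. When all generated PB values fall below PB_max the cap
#'   is unidentifiable and \code{truth$cap_identifiable} is FALSE.
#' @export
gen_response_dataset <- function(P_levels = unname(soil_p_levels()),
                                 DM = 0.36 * P_levels,
                                 alpha_a = 0.005, a_P0 = 0.045,
                                 alpha_rc = 1.6, PB_max = 2.4,
                                 alpha_rl = 0.45, r_P0 = 6.8,
                                 n_per_level = 5, noise_rel = 0.05,
                                 seed = NULL) {
  if (length(P_levels) < 4) stop("need at least 4 P levels")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  DM <- rep_len(DM, length(P_levels))
  P <- rep(P_levels, each = n_per_level)
  PB <- rep(P_levels / DM, each = n_per_level)
  noisy <- function(x) {
    if (noise_rel == 0) x else x * (1 + stats::rnorm(length(x), 0, noise_rel))
  }
  data <- data.frame(
    P = P, PB = PB,
    radius = noisy(alpha_a * P + a_P0),
    rc = noisy(alpha_rc * pmin(PB, PB_max)),
    rl = noisy(alpha_rl * P + r_P0))
  list(data = data,
       truth = list(alpha_a = alpha_a, a_P0 = a_P0, alpha_rc = alpha_rc,
                    PB_max = PB_max, alpha_rl = alpha_rl, r_P0 = r_P0,
                    noise_rel = noise_rel,
                    cap_identifiable = max(PB) > PB_max))
}
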