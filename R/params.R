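#' @name parameter_table
#' @title Architectural parameter tables
#'
#' @description
#' The package ships one delimited parameter file per soil-phosphorus
#' treatment (P0 severe deficiency, 1.8 mg P per 100 g soil, up to P3
#' sufficiency, 7.7 mg P per 100 g soil) plus a treatment-averaged
#' "general" set used as the base for the dose-response machinery. Each
#' file holds (organ, parameter, mean, s.d.) rows: plant-level scheduling
#' parameters (seminal and crown-root initiation), per-root-type
#' architectural parameters (radius a, basal zone l_b, apical unbranched
#' zone l_delay, inter-branch distance l_n, elongation rate r, maximal
#' length l_max, insertion angle theta) and shoot parameters (stem and
#' leaf). Values were measured on rhizotron-grown Zea mays cv. B73.
NULL

.treatments <- c("P0", "P1", "P2", "P3", "general")

#' Soil phosphorus levels of the four treatments
#'
#' Plant-available soil P (CAL extraction) of the four fertilization
#' treatments, in mg P per 100 g soil (equivalently mg P hg^-1).
#'
#' @return named numeric vector over P0..P3.
#' @export
soil_p_levels <- function() {
  c(P0 = 1.8, P1 = 3.3, P2 = 4.6, P3 = 7.7)
}

#' Load a packaged (or external) architectural parameter table
#'
#' @param treatment one of "P0", "P1", "P2", "P3" or "general".
#' @param path optional path to a CSV with columns
#'   organ, parameter, mean, sd; defaults to the packaged table for the
#'   treatment.
#' @return object of class \code{parameter_table}: list with
#'   \code{treatment} and \code{data} (data.frame).
#' @export
load_parameter_table <- function(treatment, path = NULL) {
  if (!treatment %in% .treatments) {
    stop(sprintf("unknown treatment '%s'; expected one of %s",
                 treatment, paste(.treatments, collapse = ", ")))
  }
  if (is.null(path)) {
    path <- system.file("extdata", sprintf("params_%s.csv", treatment),
                        package = "rhizoconduct", mustWork = TRUE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("organ", "parameter", "mean", "sd") %in% names(d)))
  d$sd[is.na(d$sd)] <- 0
  if (any(d$sd < 0)) stop("negative s.d. in parameter table")
  structure(list(treatment = treatment, data = d), class = "parameter_table")
}

#' Look up a (mean, s.d.) pair in a parameter table
#'
#' @param table a \code{parameter_table}.
#' @param organ organ type, e.g. "primary", "crown", "stem", "plant".
#' @param parameter parameter name, e.g. "a", "r", "first_SB".
#' @return numeric vector \code{c(mean, sd)}.
#' @export
param_value <- function(table, organ, parameter) {
  stopifnot(inherits(table, "parameter_table"))
  i <- which(table$data$organ == organ & table$data$parameter == parameter)
  if (length(i) != 1) {
    stop(sprintf("parameter '%s' for organ '%s' not found in %s table",
                 parameter, organ, table$treatment))
  }
  c(mean = table$data$mean[i], sd = table$data$sd[i])
}

# Defaults for parameters named in the catalogue but without printed
# per-treatment values. Chosen once, documented in the methods vignette:
# - axial l_max fixed at 139 cm (literature value used for the r fits);
# - axial insertion angles: primary vertical, seminal 0.9 rad, crown 1.2 rad;
# - tropism strength N: 1.5 candidate draws per step for axials, 1 for
#   laterals; heading noise sigma 0.2 rad per sqrt(cm);
# - maximal segment length dx 0.25 cm;
# - stem l_max 80 cm; first leaf at 5 d.
.param_defaults <- function() {
  list(
    axial_l_max = c(mean = 139, sd = 0),
    theta = list(primary = c(mean = 0, sd = 0),
                 seminal = c(mean = 0.9, sd = 0.2),
                 crown = c(mean = 1.2, sd = 0.2)),
    tropism_N = c(axial = 1.5, lateral = 1),
    tropism_sigma = 0.2,
    dx = 0.25,
    stem_l_max = c(mean = 80, sd = 0),
    first_leaf = 5,
    floor_frac = 1e-4
  )
}

.root_types <- c("primary", "seminal", "crown", "l-lateral", "s-lateral")
.axial_types <- c("primary", "seminal", "crown")

#' Assemble simulation-ready plant parameters from tables
#'
#' Merges a root parameter table with plant-level scheduling and shoot
#' rows (taken from \code{base} when the root table lacks them, as for the
#' "general" set) and fills in the documented defaults for parameters
#' without printed values.
#'
#' @param table \code{parameter_table} holding per-root-type rows.
#' @param base optional \code{parameter_table} supplying the plant-level
#'   (scheduling, seed position) and shoot rows when \code{table} does not.
#' @return object of class \code{plant_params}.
#' @export
plant_params <- function(table, base = NULL) {
  stopifnot(inherits(table, "parameter_table"))
  defs <- .param_defaults()
  src <- function(organ, parameter) {
    has <- any(table$data$organ == organ & table$data$parameter == parameter)
    from <- if (has) table else base
    if (is.null(from)) {
      stop(sprintf("no source for %s/%s: supply 'base'", organ, parameter))
    }
    param_value(from, organ, parameter)
  }
  plant <- list(
    first_B = src("plant", "first_B")[["mean"]],
    delay_B = src("plant", "delay_B")[["mean"]],
    max_B = src("plant", "max_B")[["mean"]],
    first_SB = src("plant", "first_SB")[["mean"]],
    delay_SB = src("plant", "delay_SB")[["mean"]],
    delay_RC = src("plant", "delay_RC")[["mean"]],
    n_C = src("plant", "n_C")[["mean"]],
    seed_pos = c(src("plant", "seed_x")[["mean"]],
                 src("plant", "seed_y")[["mean"]],
                 src("plant", "seed_z")[["mean"]]),
    simulation_time = src("plant", "simulation_time")[["mean"]],
    successors = c(`l-lateral` = src("plant", "succ_l_lateral")[["mean"]],
                   `s-lateral` = src("plant", "succ_s_lateral")[["mean"]])
  )
  roots <- list()
  for (ty in .root_types) {
    axial <- ty %in% .axial_types
    rt <- list(
      a = src(ty, "a"),
      r = src(ty, "r"),
      l_max = if (axial) defs$axial_l_max else src(ty, "l_max"),
      theta = if (axial) defs$theta[[ty]] else src(ty, "theta"),
      N = if (axial) defs$tropism_N[["axial"]] else defs$tropism_N[["lateral"]],
      sigma = defs$tropism_sigma,
      dx = defs$dx
    )
    if (ty != "s-lateral") {
      rt$l_b <- src(ty, "l_b")
      rt$l_delay <- src(ty, "l_delay")
      rt$l_n <- src(ty, "l_n")
      rt$successors <- if (axial) plant$successors else c(`s-lateral` = 1)
    }
    roots[[ty]] <- rt
  }
  shoot <- list(
    stem = list(a = src("stem", "a"), l_n = src("stem", "l_n"),
                r = src("stem", "r"), l_max = defs$stem_l_max,
                dx = defs$dx),
    leaf = list(r = src("leaf", "r"), l_max = src("leaf", "l_max"),
                theta = src("leaf", "theta"),
                delay_lat = src("leaf", "delay_lat")[["mean"]],
                width_blade = src("leaf", "width_blade")[["mean"]],
                area_max = src("leaf", "area_max")[["mean"]],
                rot_beta = src("leaf", "rot_beta")[["mean"]],
                first_leaf = defs$first_leaf)
  )
  structure(list(treatment = table$treatment, plant = plant, roots = roots,
                 shoot = shoot, floor_frac = defs$floor_frac),
            class = "plant_params")
}

#' Draw realized parameter values from a (mean, s.d.) pair
#'
#' Draws are normal(mean, sd) truncated below at a small positive floor
#' (1e-4 of the absolute mean by default) so that radii, rates and lengths
#' stay positive. With sd = 0 the mean is returned.
#'
#' @param n number of draws.
#' @param ms numeric \code{c(mean, sd)} pair (as from [param_value()]).
#' @param floor_frac floor, as a fraction of |mean|.
#' @return numeric vector of n realizations.
#' @export
draw_param <- function(n, ms, floor_frac = 1e-4) {
  m <- ms[[1]]; s <- ms[[2]]
  if (s < 0) stop("s.d. must be non-negative")
  if (s == 0) return(rep(m, n))
  pmax(stats::rnorm(n, m, s), floor_frac * abs(m))
}

# Stochastic rounding preserving the mean: 3.5 -> 3 or 4 with p = 0.5.
.round_stochastic <- function(x, n = 1) {
  floor(x) + stats::rbinom(n, 1, x - floor(x))
}

#' Realize one stochastic parameter set
#'
#' Draws one realization of every per-root-type architectural parameter
#' and of the integer-valued schedule counts (seminal count from max_B,
#' per-whorl crown count from n_C, both by mean-preserving stochastic
#' rounding). Identical seeds give identical realizations.
#'
#' @param params a \code{plant_params} object.
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used (as inside [simulate_plant()]).
#' @return list with \code{roots} (realized per-type values),
#'   \code{max_B}, \code{n_C_per_whorl}.
#' @export
sample_parameters <- function(params, seed = NULL) {
  stopifnot(inherits(params, "plant_params"))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  n_whorl <- .n_whorls(params)
  realized <- lapply(params$roots, function(rt) {
    out <- list()
    for (nm in intersect(names(rt), c("a", "r", "l_max", "theta",
                                      "l_b", "l_delay", "l_n"))) {
      out[[nm]] <- draw_param(1, rt[[nm]], params$floor_frac)
    }
    out
  })
  list(roots = realized,
       max_B = .round_stochastic(params$plant$max_B),
       n_C_per_whorl = .round_stochastic(rep(params$plant$n_C, n_whorl),
                                         n = n_whorl))
}

.n_whorls <- function(params) {
  p <- params$plant
  if (p$first_SB > p$simulation_time) return(0L)
  length(seq(p$first_SB, p$simulation_time, by = p$delay_RC))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.plant_params <- function(x, ...) {
  cat(sprintf("plant_params for treatment %s: %d root types, stem + leaves\n",
              x$treatment, length(x$roots)))
  cat(sprintf("  schedule: first_B %.1f d, first_SB %.1f d, delay_RC %.1f d, n_C %.1f\n",
              x$plant$first_B, x$plant$first_SB, x$plant$delay_RC, x$plant$n_C))
  invisible(x)
}
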