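#' @name p_response
#' @title Soil-phosphorus dose-response functions
#'
#' @description
#' Three response functions convert a base (treatment-averaged) parameter
#' set plus a soil-P level into a treatment-specific set:
#' \itemize{
#' \item axial root radius: linear in plant-available soil P,
#'   \eqn{a_{ax} = \alpha_a P + a_{P0}}, valid between the observed
#'   P bounds;
#' \item crown-root elongation rate: linear through the origin in the
#'   P-to-dry-matter ratio PB = P / DM_plant, capped at PB_max,
#'   \eqn{r_c = \alpha_{rc} \min(PB, PB_{max})};
#' \item leaf elongation rate: linear in soil P,
#'   \eqn{r_l = \alpha_{rl} P + r_{P0}}, valid between the observed
#'   P bounds.
#' }
NULL

#' Fit the linear axial-radius response to soil P
#'
#' Ordinary least squares of radius on soil P. The observed P range is
#' recorded as the validity bounds; no extrapolation is allowed when the
#' fit is applied.
#'
#' @param P plant-available soil P levels (mg P per 100 g soil).
#' @param radii axial root radii (cm), same length as P.
#' @return list with \code{slope} (cm per mg P hg^-1), \code{intercept}
#'   (cm), \code{P_min}, \code{P_max}, \code{P_ref} (centroid),
#'   \code{r_squared}, \code{residuals}.
#' @export
fit_axial_radius_response <- function(P, radii) {
  if (length(P) != length(radii)) stop("P and radii must have equal length")
  if (length(unique(P)) < 2) stop("need at least 2 distinct P levels")
  fit <- stats::lm(radii ~ P)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       P_min = min(P), P_max = max(P), P_ref = mean(P),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       residuals = unname(stats::residuals(fit)))
}

#' Fit the capped-linear crown elongation response to PB
#'
#' The model is linear through the origin below a changepoint PB_max and
#' constant above it. The slope is the origin-constrained least-squares
#' estimate; the changepoint is profiled over the observed PB values (the
#' simplest estimator consistent with a straight-line-plus-plateau
#' presentation). When the best changepoint is the largest observed PB
#' the cap is unidentifiable from the data and \code{cap_identified} is
#' FALSE.
#'
#' @param PB soil-P to plant-dry-matter ratios (mg P hg^-1 g^-1).
#' @param rc crown-root initial elongation rates (cm d^-1).
#' @return list with \code{alpha_rc}, \code{PB_max}, \code{rss},
#'   \code{cap_identified}.
#' @export
fit_crown_elongation_response <- function(PB, rc) {
  if (length(PB) != length(rc)) stop("PB and rc must have equal length")
  if (any(PB < 0)) stop("PB must be non-negative")
  cands <- sort(unique(PB))
  cands <- cands[cands > 0]
  best <- NULL
  for (cp in cands) {
    x <- pmin(PB, cp)
    alpha <- sum(x * rc) / sum(x^2)
    rss <- sum((rc - alpha * x)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(alpha_rc = alpha, PB_max = cp, rss = rss)
    }
  }
  best$cap_identified <- best$PB_max < max(PB)
  best
}

#' Crown-root elongation rate at a given PB
#'
#' @param PB soil-P to dry-matter ratio(s), >= 0.
#' @param model list with \code{alpha_rc} and \code{PB_max} (as from
#'   [fit_crown_elongation_response()]).
#' @return elongation rate(s), cm d^-1.
#' @export
crown_elongation_response <- function(PB, model) {
  if (any(PB < 0)) stop("PB must be non-negative")
  model$alpha_rc * pmin(PB, model$PB_max)
}

#' Fit the linear leaf elongation response to soil P
#'
#' @inheritParams fit_axial_radius_response
#' @param rl initial leaf elongation rates (cm d^-1).
#' @return list with \code{slope}, \code{intercept}, \code{P_min},
#'   \code{P_max}, \code{P_ref}, \code{r_squared}.
#' @export
fit_leaf_elongation_response <- function(P, rl) {
  if (length(P) != length(rl)) stop("P and rl must have equal length")
  if (length(unique(P)) < 2) stop("need at least 2 distinct P levels")
  fit <- stats::lm(rl ~ P)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       P_min = min(P), P_max = max(P), P_ref = mean(P),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Leaf elongation rate at a given soil P
#'
#' The validity bounds are part of the model: P outside [P_min, P_max]
#' is rejected rather than extrapolated.
#'
#' @param P soil P level(s) (mg P per 100 g soil).
#' @param model list from [fit_leaf_elongation_response()].
#' @return elongation rate(s), cm d^-1.
#' @export
leaf_elongation_response <- function(P, model) {
  if (any(P < model$P_min - 1e-9) || any(P > model$P_max + 1e-9)) {
    stop(sprintf("P outside the fitted validity bounds [%g, %g]",
                 model$P_min, model$P_max))
  }
  model$slope * P + model$intercept
}

#' Default plant dry matter per treatment
#'
#' Plant dry matter (g) at 28 d used to form the PB covariate. The
#' measured values are only published graphically, so these are synthetic
#' plausible stand-ins for young maize under increasing P supply
#' (documented in the methods vignette); override via the DM arguments of
#' the fitting and pipeline functions.
#'
#' @return named numeric vector over P0..P3 (g).
#' @export
default_dry_matter <- function() {
  c(P0 = 1.0, P1 = 1.8, P2 = 2.2, P3 = 2.8)
}

#' Fit the full P-response model from the packaged treatment tables
#'
#' Pools the tabulated per-treatment mean radii of the three axial root
#' types for the radius line, uses the tabulated crown-root elongation
#' means against PB for the capped-linear response, and the tabulated
#' leaf elongation means for the leaf line.
#'
#' @param DM named plant dry-matter vector (g) over P0..P3 used to form
#'   PB; defaults to the documented stand-in values.
#' @return object of class \code{p_response_model}: list with components
#'   \code{axial}, \code{crown}, \code{leaf}, \code{DM}, \code{P_levels}.
#' @export
fit_p_response <- function(DM = default_dry_matter()) {
  P <- soil_p_levels()
  tabs <- lapply(names(P), load_parameter_table)
  names(tabs) <- names(P)
  ax_P <- numeric(0); ax_r <- numeric(0)
  for (tr in names(P)) {
    for (ty in .axial_types) {
      ax_P <- c(ax_P, P[[tr]])
      ax_r <- c(ax_r, param_value(tabs[[tr]], ty, "a")[["mean"]])
    }
  }
  crown_r <- vapply(tabs, function(tb) param_value(tb, "crown", "r")[["mean"]],
                    numeric(1))
  leaf_r <- vapply(tabs, function(tb) param_value(tb, "leaf", "r")[["mean"]],
                   numeric(1))
  PB <- P / DM[names(P)]
  structure(list(axial = fit_axial_radius_response(ax_P, ax_r),
                 crown = fit_crown_elongation_response(PB, crown_r),
                 leaf = fit_leaf_elongation_response(P, leaf_r),
                 DM = DM, P_levels = P),
            class = "p_response_model")
}

#' Apply the P-response model to a base parameter table
#'
#' Returns a copy of the base table where only the identified response
#' parameters change: the mean radii of the three axial root types are
#' scaled by the fitted radius line's ratio at P versus at the fit
#' centroid (preserving the per-type offsets), the crown-root elongation
#' mean follows the capped-linear PB response, and the leaf elongation
#' mean follows the leaf line. All other parameters, and every s.d., are
#' untouched.
#'
#' @param base a \code{parameter_table} (normally the "general" set).
#' @param P soil P level (mg P per 100 g soil), within the fitted bounds.
#' @param DM_plant plant dry matter (g) used to form PB.
#' @param model a \code{p_response_model}.
#' @return a modified \code{parameter_table}.
#' @export
apply_response <- function(base, P, DM_plant, model) {
  stopifnot(inherits(base, "parameter_table"),
            inherits(model, "p_response_model"))
  if (P < model$axial$P_min - 1e-9 || P > model$axial$P_max + 1e-9) {
    stop(sprintf("P outside the fitted validity bounds [%g, %g]",
                 model$axial$P_min, model$axial$P_max))
  }
  out <- base
  d <- out$data
  line <- function(p) model$axial$slope * p + model$axial$intercept
  ratio <- line(P) / line(model$axial$P_ref)
  for (ty in .axial_types) {
    i <- which(d$organ == ty & d$parameter == "a")
    d$mean[i] <- d$mean[i] * ratio
  }
  i <- which(d$organ == "crown" & d$parameter == "r")
  d$mean[i] <- crown_elongation_response(P / DM_plant, model$crown)
  i <- which(d$organ == "leaf" & d$parameter == "r")
  if (length(i) == 1) {
    d$mean[i] <- leaf_elongation_response(P, model$leaf)
  }
  out$data <- d
  out
}

#' @export
print.p_response_model <- function(x, ...) {
  cat(sprintf("p_response_model:\n  axial radius: a = %.5f P + %.5f cm (P in [%g, %g])\n",
              x$axial$slope, x$axial$intercept, x$axial$P_min, x$axial$P_max))
  cat(sprintf("  crown elongation: r_c = %.4f * min(PB, %.3f) cm/d%s\n",
              x$crown$alpha_rc, x$crown$PB_max,
              if (x$crown$cap_identified) "" else " (cap at data boundary)"))
  cat(sprintf("  leaf elongation: r_l = %.4f P + %.4f cm/d\n",
              x$leaf$slope, x$leaf$intercept))
  invisible(x)
}
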