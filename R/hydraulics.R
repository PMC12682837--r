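#' @name hydraulics
#' @title Root-system hydraulic architecture
#'
#' @description
#' Steady-state water flow on a segmented plant network. Each root segment
#' exchanges water radially with the soil through its surface
#' (\eqn{K_r = 2\pi a\, dl\, k_r}, with the radial conductivity k_r a
#' function of segment age and root type) and conducts water axially
#' through its xylem (conductance K_x, also age- and type-dependent).
#' Stem segments take up no water (k_r = 0) and conduct axially with the
#' Hagen-Poiseuille conductance \eqn{K_x = \pi a_{xyl}^4 / (8 \mu)} of an
#' equivalent xylem cylinder. Potentials are expressed as water heads
#' (cm). Solving the flow-balance system for the xylem potentials yields
#' per-segment radial and axial flows, the actual transpiration T_act,
#' the standard uptake fraction SUF and the root system conductance
#' \eqn{K_{rs} = T_{act} / (\psi_{sr,eff} - \psi_{collar})}.
NULL

# Head-based dynamic viscosity of pure water at 20 C, in cm * day:
# mu_head = eta / (rho g) = 1.002e-3 Pa s / (98.1 Pa cm^-1) = 1.0214e-5 cm s
#         = 1.1822e-10 cm d. Then pi a^4 / (8 mu_head) has units cm^3 d^-1.
MU_HEAD_CM_DAY <- 1.002e-3 / 98.1 / 86400

#' Construct an age-dependent hydraulic property profile
#'
#' Per root type, the radial conductivity k_r (d^-1) and axial conductance
#' K_x (cm^3 d^-1) are piecewise-linear functions of segment age with
#' constant extrapolation beyond the outermost knots. Properties are
#' treatment-independent; treatment effects enter only through the
#' architecture (radii, lengths, ages).
#'
#' @param knots data.frame with columns \code{type}, \code{age} (d),
#'   \code{kr} (d^-1), \code{kx} (cm^3 d^-1).
#' @param a_xyl_frac equivalent stem xylem radius as a fraction of the
#'   stem radius (default 0.1, making the stem a negligible resistance).
#' @param mu head-based water viscosity (cm d), default water at 20 C.
#' @return object of class \code{hydraulic_profile}.
#' @export
hydraulic_profile <- function(knots, a_xyl_frac = 0.1, mu = MU_HEAD_CM_DAY) {
  stopifnot(all(c("type", "age", "kr", "kx") %in% names(knots)))
  if (any(knots$kr < 0)) stop("k_r must be non-negative")
  if (any(knots$kx <= 0)) stop("K_x must be positive")
  types <- split(knots[c("age", "kr", "kx")], knots$type)
  types <- lapply(types, function(d) d[order(d$age), , drop = FALSE])
  structure(list(types = types, a_xyl_frac = a_xyl_frac, mu = mu),
            class = "hydraulic_profile")
}

#' Load the packaged default hydraulic profile
#'
#' The packaged profile is a synthetic stand-in with magnitudes in the
#' range of published maize root hydraulic properties (radial
#' conductivity decreasing with segment age, axial conductance
#' increasing); it is not a transcription of any measured atlas. See the
#' methods vignette.
#'
#' @inheritParams hydraulic_profile
#' @return a \code{hydraulic_profile}.
#' @export
default_hydraulic_profile <- function(a_xyl_frac = 0.1) {
  path <- system.file("extdata", "hydraulic_profile_synthetic.csv",
                      package = "rhizoconduct", mustWork = TRUE)
  hydraulic_profile(utils::read.csv(path, stringsAsFactors = FALSE),
                    a_xyl_frac = a_xyl_frac)
}

#' Constant (age-independent) profile, mainly for closed-form checks
#'
#' @param kr radial conductivity (d^-1) applied to all root types.
#' @param kx axial conductance (cm^3 d^-1) applied to all root types.
#' @param types root types to cover.
#' @inheritParams hydraulic_profile
#' @return a \code{hydraulic_profile}.
#' @export
constant_hydraulic_profile <- function(kr, kx,
                                       types = c("primary", "seminal",
                                                 "crown", "l-lateral",
                                                 "s-lateral"),
                                       a_xyl_frac = 0.1) {
  hydraulic_profile(data.frame(type = rep(types, each = 2),
                               age = rep(c(0, 1), length(types)),
                               kr = kr, kx = kx),
                    a_xyl_frac = a_xyl_frac)
}

.profile_lookup <- function(profile, type, age, what) {
  d <- profile$types[[type]]
  if (is.null(d)) {
    stop(sprintf("hydraulic profile has no entry for root type '%s'", type))
  }
  if (nrow(d) == 1) return(rep(d[[what]], length(age)))
  stats::approx(d$age, d[[what]], xout = age, rule = 2)$y
}

#' Per-segment radial and axial conductances
#'
#' Evaluates, at time t, the radial conductance
#' \eqn{K_r = 2\pi a\, dl\, k_r(age)} and the axial conductance
#' \eqn{K_x(age)} of every segment. Stem segments get K_r = 0 and the
#' Hagen-Poiseuille K_x for an equivalent xylem radius
#' \code{a_xyl_frac * a}.
#'
#' @param net a \code{plant_network}.
#' @param profile a \code{hydraulic_profile}.
#' @param t evaluation time (days); all segments must exist at t.
#' @return data.frame with columns id, Kr (cm^2 d^-1), Kx (cm^3 d^-1).
#' @export
segment_conductances <- function(net, profile, t = net$t_end) {
  stopifnot(inherits(net, "plant_network"),
            inherits(profile, "hydraulic_profile"))
  s <- net$segments
  age <- t - s$creation_time
  if (any(age < -1e-9)) {
    stop("some segments are created after t; restrict with network_at_time first")
  }
  age <- pmax(age, 0)
  Kr <- numeric(nrow(s)); Kx <- numeric(nrow(s))
  is_stem <- s$type == "stem"
  if (any(is_stem)) {
    a_xyl <- profile$a_xyl_frac * s$a[is_stem]
    Kr[is_stem] <- 0
    Kx[is_stem] <- pi * a_xyl^4 / (8 * profile$mu)
  }
  for (ty in setdiff(unique(s$type), "stem")) {
    i <- which(s$type == ty)
    Kr[i] <- 2 * pi * s$a[i] * s$dl[i] * .profile_lookup(profile, ty, age[i], "kr")
    Kx[i] <- .profile_lookup(profile, ty, age[i], "kx")
  }
  data.frame(id = s$id, Kr = Kr, Kx = Kx)
}

# The collar is the node where the plant potential boundary condition is
# applied: the most distal stem node present, or the seed node (0) for
# root-only networks.
.collar_node <- function(net) {
  s <- net$segments
  stem <- s[s$type == "stem", , drop = FALSE]
  if (nrow(stem) == 0) return(0L)
  stem$id[which.max(stem$z1)]
}

#' Solve steady-state water flow on a plant network
#'
#' Discretizes the radial-uptake/axial-transport balance with nodal xylem
#' potentials at segment ends and the radial exchange attached at the
#' segment midpoint (the midpoint unknown is eliminated analytically via a
#' star-delta reduction, which keeps the system symmetric positive
#' definite and second-order accurate). The collar potential is a
#' Dirichlet condition; the sparse system is solved directly.
#'
#' @param net a \code{plant_network} (connected; segments present at the
#'   conductance evaluation time).
#' @param cond per-segment conductances from [segment_conductances()].
#' @param psi_sr soil water potential at the root-soil interface (cm
#'   head): a scalar (uniform) or a vector over segments (stem entries
#'   ignored).
#' @param psi_collar collar xylem potential (cm head).
#' @return object of class \code{hydraulic_solution}: list with
#'   \code{psi_node} (potential at node i = distal end of segment i;
#'   element "0" is the seed node), \code{Jr} and \code{Jx} (cm^3 d^-1,
#'   per segment; Jx positive toward the collar), \code{T_act},
#'   \code{psi_collar}, \code{collar_node}.
#' @export
solve_water_flow <- function(net, cond, psi_sr, psi_collar) {
  s <- net$segments
  n <- nrow(s)
  if (n == 0) stop("empty network")
  if (!all(cond$id == s$id)) cond <- cond[match(s$id, cond$id), ]
  if (length(psi_sr) == 1) psi_sr <- rep(psi_sr, n)
  if (length(psi_sr) != n) {
    stop("psi_sr must be scalar or one value per segment")
  }
  Kr <- cond$Kr; Kx <- cond$Kx
  if (all(Kr <= 0)) {
    stop("all radial conductances are zero: the flow system is degenerate")
  }
  if (any(Kx <= 0)) stop("axial conductances must be positive")
  c_ax <- Kx / s$dl
  denom <- 4 * c_ax + Kr
  g_pq <- 4 * c_ax^2 / denom          # effective proximal-distal conductance
  g_s <- 2 * c_ax * Kr / denom        # soil link to each end node
  # node i is the distal end of segment with id node_ids[i+1]; node_ids[1]
  # is the seed node (0). Ids need not be dense after network_at_time.
  node_ids <- c(0L, s$id)
  p <- match(s$parent, node_ids)
  q <- match(s$id, node_ids)
  if (anyNA(p)) stop("network is not connected: missing parent segments")
  nn <- n + 1L
  A <- Matrix::sparseMatrix(
    i = c(p, q, p, q), j = c(p, q, q, p),
    x = c(g_pq + g_s, g_pq + g_s, -g_pq, -g_pq),
    dims = c(nn, nn))
  b <- numeric(nn)
  bp <- rowsum(g_s * psi_sr, p); b[as.integer(rownames(bp))] <- bp
  bq <- rowsum(g_s * psi_sr, q)
  b[as.integer(rownames(bq))] <- b[as.integer(rownames(bq))] + bq
  collar <- .collar_node(net)
  k <- match(collar, node_ids)
  free <- setdiff(seq_len(nn), k)
  rhs <- b[free] - A[free, k] * psi_collar
  psi <- numeric(nn)
  psi[k] <- psi_collar
  psi[free] <- as.numeric(Matrix::solve(A[free, free, drop = FALSE], rhs))
  psi_m <- (2 * c_ax * (psi[p] + psi[q]) + Kr * psi_sr) / denom
  Jr <- Kr * (psi_sr - psi_m)
  Jx <- 2 * c_ax * (psi_m - psi[p])
  structure(list(psi_node = stats::setNames(psi, c(0, s$id)),
                 psi_mid = psi_m, Jr = Jr, Jx = Jx,
                 T_act = sum(Jr), psi_collar = psi_collar,
                 collar_node = collar, psi_sr = psi_sr),
            class = "hydraulic_solution")
}

#' Standard uptake fraction of each segment
#'
#' SUF_i is segment i's share of total water uptake under a uniform soil
#' potential; it is independent of the (uniform) soil and collar values,
#' sums to 1 and is non-negative. The SUF-weighted average of any soil
#' potential vector gives the effective soil-root interface potential.
#'
#' @inheritParams solve_water_flow
#' @return numeric SUF vector over segments (stem entries 0).
#' @export
compute_suf <- function(net, cond) {
  sol <- solve_water_flow(net, cond, psi_sr = -300, psi_collar = -1300)
  if (abs(sol$T_act) < 1e-300) {
    stop("total uptake is zero: SUF undefined")
  }
  sol$Jr / sol$T_act
}

#' Effective soil-root interface potential
#'
#' @param suf SUF vector from [compute_suf()].
#' @param psi_sr per-segment soil potentials (cm head), or a scalar.
#' @return SUF-weighted average potential (cm head).
#' @export
effective_soil_potential <- function(suf, psi_sr) {
  if (length(psi_sr) == 1) return(psi_sr * sum(suf))
  sum(suf * psi_sr)
}

#' Root system conductance K_rs
#'
#' \eqn{K_{rs} = T_{act} / (\psi_{sr,eff} - \psi_{collar})} (cm^2 d^-1).
#' By linearity of the flow system K_rs does not depend on the choice of
#' the collar potential nor on adding a constant to all potentials.
#'
#' @inheritParams solve_water_flow
#' @return K_rs (cm^2 d^-1), scalar.
#' @export
compute_krs <- function(net, cond, psi_sr = -300, psi_collar = -1000) {
  sol <- solve_water_flow(net, cond, psi_sr, psi_collar)
  if (length(unique(sol$psi_sr)) == 1) {
    eff <- sol$psi_sr[1]
  } else {
    eff <- effective_soil_potential(compute_suf(net, cond), sol$psi_sr)
  }
  if (abs(eff - psi_collar) < 1e-300) {
    stop("psi_sr_eff equals psi_collar: K_rs undefined")
  }
  sol$T_act / (eff - psi_collar)
}

#' K_rs of a growing plant over time
#'
#' Restricts the network to each query time, re-evaluates segment ages and
#' conductances there, and computes K_rs.
#'
#' @param net a \code{plant_network}.
#' @param profile a \code{hydraulic_profile}.
#' @param times query times (days), within [0, t_end].
#' @inheritParams solve_water_flow
#' @return data.frame with columns t, krs, t_act, n_segments.
#' @export
krs_time_series <- function(net, profile, times, psi_sr = -300,
                            psi_collar = -1000) {
  stopifnot(length(psi_sr) == 1)
  out <- lapply(times, function(t) {
    sub <- network_at_time(net, t)
    roots <- sub$segments$type != "stem"
    if (!any(roots)) {
      return(data.frame(t = t, krs = 0, t_act = 0,
                        n_segments = nrow(sub$segments)))
    }
    cond <- segment_conductances(sub, profile, t)
    sol <- solve_water_flow(sub, cond, psi_sr, psi_collar)
    data.frame(t = t, krs = sol$T_act / (psi_sr[1] - psi_collar),
               t_act = sol$T_act, n_segments = nrow(sub$segments))
  })
  do.call(rbind, out)
}

#' @export
print.hydraulic_solution <- function(x, ...) {
  cat(sprintf(
    "hydraulic_solution: %d segments, T_act = %.4g cm^3/d, psi_collar = %g cm\n",
    length(x$Jr), x$T_act, x$psi_collar))
  invisible(x)
}
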