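#' @name plant_network
#' @title Segmented plant network
#'
#' @description
#' A simulated plant is represented as a rooted tree of cylindrical
#' segments covering the root system and the stem. The \code{segments}
#' data.frame has one row per segment: \code{id}, \code{parent} (segment
#' id of the proximal neighbour, 0 for segments attached to the seed
#' node), \code{organ}, \code{type}, proximal (\code{x0,y0,z0}) and distal
#' (\code{x1,y1,z1}) coordinates in cm (z negative downward), segment
#' length \code{dl}, organ radius \code{a} and \code{creation_time} (days
#' after sowing). Node i is the distal end of segment i; node 0 is the
#' seed position. The \code{organs} data.frame records per-organ metadata
#' (type, parent organ, emergence day and the realized elongation
#' parameters), including leaves, which carry no hydraulic segments.
NULL

#' Emergence schedule of axial roots
#'
#' Builds the deterministic whorl/emergence-time scaffold of the axial
#' root system: the primary root at sowing, seminal (basal) roots from
#' \code{first_B} spaced \code{delay_B}, and crown-root whorls at
#' \code{first_SB + k * delay_RC} with the roots of a whorl spaced
#' \code{delay_SB}. The integer counts (seminal count from max_B, crown
#' roots per whorl from n_C) are realized by mean-preserving stochastic
#' rounding from the current RNG stream (or \code{seed}).
#'
#' @param params a \code{plant_params} object.
#' @param seed optional integer seed for the count realization.
#' @return data.frame with columns \code{type}, \code{emergence} (d) and
#'   \code{whorl} (crown whorl index from 0; NA otherwise).
#' @export
schedule_axial_roots <- function(params, seed = NULL) {
  stopifnot(inherits(params, "plant_params"))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  p <- params$plant
  tmax <- p$simulation_time
  out <- data.frame(type = "primary", emergence = 0, whorl = NA_integer_)
  n_sem <- .round_stochastic(p$max_B)
  if (n_sem > 0) {
    em <- p$first_B + (seq_len(n_sem) - 1) * p$delay_B
    em <- em[em <= tmax]
    if (length(em) > 0) {
      out <- rbind(out, data.frame(type = "seminal", emergence = em,
                                   whorl = NA_integer_))
    }
  }
  nw <- .n_whorls(params)
  if (nw > 0) {
    n_c <- .round_stochastic(rep(p$n_C, nw), n = nw)
    for (k in seq_len(nw)) {
      t0 <- p$first_SB + (k - 1) * p$delay_RC
      if (n_c[k] < 1) next
      em <- t0 + (seq_len(n_c[k]) - 1) * p$delay_SB
      em <- em[em <= tmax]
      if (length(em) > 0) {
        out <- rbind(out, data.frame(type = "crown", emergence = em,
                                     whorl = k - 1L))
      }
    }
  }
  rownames(out) <- NULL
  out
}

# Unit heading tilted by angle theta from straight down, random azimuth.
.tilted_heading <- function(theta) {
  phi <- stats::runif(1, 0, 2 * pi)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), -cos(theta))
}

# Heading tilted by theta away from a parent direction d, random azimuth.
.branch_heading <- function(d, theta) {
  # orthonormal basis around d
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  phi <- stats::runif(1, 0, 2 * pi)
  w <- cos(phi) * u + sin(phi) * v
  h <- cos(theta) * d + sin(theta) * w
  h / sqrt(sum(h^2))
}

# Gravitropism-biased random walk: per step of length dx, draw ncand
# candidate headings (heading + Gaussian 3-vector noise, renormalized) and
# keep the most downward one. sigma is in rad per sqrt(cm) (diffusive
# heading noise), so the per-step s.d. is sigma * sqrt(dx).
.grow_polyline <- function(start, h0, L, dx, N_mean, sigma) {
  nstep <- max(1L, as.integer(ceiling(L / dx - 1e-9)))
  steps <- rep(dx, nstep)
  steps[nstep] <- L - (nstep - 1) * dx
  pts <- matrix(0, nstep + 1, 3)
  pts[1, ] <- start
  h <- h0
  nfloor <- floor(N_mean)
  nfrac <- N_mean - nfloor
  ncand <- nfloor + stats::rbinom(nstep, 1, nfrac)
  ncand[ncand < 1] <- 1L
  sd_step <- sigma * sqrt(dx)
  noise <- stats::rnorm(3 * sum(ncand), 0, sd_step)
  off <- 0L
  for (i in seq_len(nstep)) {
    k <- ncand[i]
    cand <- matrix(noise[(off + 1):(off + 3 * k)], k, 3, byrow = TRUE)
    off <- off + 3L * k
    cand <- cand + rep(h, each = k)
    cand <- cand / sqrt(rowSums(cand^2))
    h <- cand[which.min(cand[, 3]), ]
    pts[i + 1, ] <- pts[i, ] + h * steps[i]
  }
  list(points = pts, steps = steps, cumlen = cumsum(steps))
}

# Creation time of the point at arc length cum on an organ emerging at
# t_e: inverse growth law, clamped so lengths at the numerical asymptote
# map to the age actually reached (age_end) rather than +Inf.
.ctime_at_length <- function(cum, r, l_max, t_e, age_end) {
  arg <- pmax(1 - cum / l_max, exp(-r * age_end / l_max))
  t_e + pmin(-l_max / r * log(arg), age_end)
}

# Environment-based accumulator for segment/organ rows (avoids repeated
# rbind during recursion).
.new_collector <- function() {
  e <- new.env(parent = emptyenv())
  e$segs <- list()
  e$organs <- list()
  e$next_seg <- 1L
  e$next_organ <- 1L
  e
}

# Build one root organ (recursively adding its laterals).
# parent_nodes/parent_pts/parent_ctimes describe the attachment candidates.
.build_root <- function(col, params, type, t_emerge, t_end,
                        base_node, base_pt, base_dir, parent_organ) {
  rt <- params$roots[[type]]
  ff <- params$floor_frac
  r <- draw_param(1, rt$r, ff)
  l_max <- draw_param(1, rt$l_max, ff)
  theta <- draw_param(1, rt$theta, ff)
  a <- draw_param(1, rt$a, ff)
  age_end <- t_end - t_emerge
  organ_id <- col$next_organ; col$next_organ <- organ_id + 1L
  col$organs[[organ_id]] <- list(
    v = c(organ_id, parent_organ, t_emerge, r, l_max, a, theta),
    type = type)
  if (age_end <= 0) return(invisible(NULL))
  L <- length_at_age(age_end, r, l_max)
  if (L < 1e-6) return(invisible(NULL))
  h0 <- if (is.null(base_dir)) .tilted_heading(theta) else
    .branch_heading(base_dir, theta)
  pl <- .grow_polyline(base_pt, h0, L, rt$dx, rt$N, rt$sigma)
  nstep <- length(pl$steps)
  ids <- col$next_seg + seq_len(nstep) - 1L
  col$next_seg <- col$next_seg + nstep
  ctime <- .ctime_at_length(pmin(pl$cumlen, L), r, l_max, t_emerge, age_end)
  ctime[nstep] <- t_end  # cumlen[nstep] == L by construction
  col$segs[[length(col$segs) + 1L]] <- list(
    m = cbind(ids, c(base_node, ids[-nstep]), organ_id,
              pl$points[-(nstep + 1), 1], pl$points[-(nstep + 1), 2],
              pl$points[-(nstep + 1), 3],
              pl$points[-1, 1], pl$points[-1, 2], pl$points[-1, 3],
              pl$steps, a, ctime),
    type = type)
  # laterals beyond the basal zone, spaced l_n, apical zone l_delay
  if (!is.null(rt$l_n)) {
    l_b <- draw_param(1, rt$l_b, ff)
    l_n <- max(draw_param(1, rt$l_n, ff), rt$dx / 2)
    l_delay <- draw_param(1, rt$l_delay, ff)
    pos <- l_b
    while (pos + l_delay <= L) {
      child_type <- sample(names(rt$successors), 1, prob = rt$successors)
      idx <- min(which(pl$cumlen >= pos - 1e-12))
      t_child <- .ctime_at_length(min(pos + l_delay, L), r, l_max,
                                  t_emerge, age_end)
      t_child <- max(t_child, ctime[idx])
      d <- pl$points[idx + 1, ] - pl$points[idx, ]
      d <- d / sqrt(sum(d^2))
      .build_root(col, params, child_type, t_child, t_end,
                  base_node = ids[idx], base_pt = pl$points[idx + 1, ],
                  base_dir = d, parent_organ = organ_id)
      pos <- pos + l_n
    }
  }
  invisible(NULL)
}

#' Simulate a growing maize plant
#'
#' Generates one stochastic plant realization: the vertical stem, the
#' axial root system following the emergence schedule, and lateral roots
#' branching beyond each axis' basal zone at the inter-branch distance,
#' with the apical zone unbranched. Every organ elongates along the
#' negative-exponential law with its own realized (r, l_max); segment
#' creation times are assigned by the exact inverse of that law, so the
#' architecture at any earlier time can be recovered exactly with
#' [network_at_time()]. Root headings follow a gravitropism-biased random
#' walk. The same (params, t_end, seed) triple reproduces the network
#' bit-for-bit.
#'
#' @param params a \code{plant_params} object.
#' @param t_end simulation horizon (days), at most
#'   \code{params$plant$simulation_time}.
#' @param seed integer seed.
#' @return object of class \code{plant_network}; see [plant_network].
#' @export
simulate_plant <- function(params, t_end = params$plant$simulation_time,
                           seed = 1L) {
  stopifnot(inherits(params, "plant_params"))
  if (t_end < 0) stop("t_end must be non-negative")
  if (t_end > params$plant$simulation_time) {
    stop("t_end exceeds the parameterized simulation time")
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ff <- params$floor_frac
  col <- .new_collector()
  seed_pos <- params$plant$seed_pos
  # --- stem: vertical from the seed upward --------------------------------
  st <- params$shoot$stem
  stem_r <- draw_param(1, st$r, ff)
  stem_lmax <- draw_param(1, st$l_max, ff)
  stem_a <- draw_param(1, st$a, ff)
  Ls <- if (t_end > 0) length_at_age(t_end, stem_r, stem_lmax) else 0
  stem_ids <- integer(0); stem_cum <- numeric(0); stem_ct <- numeric(0)
  col$organs[[1L]] <- list(v = c(1, NA, 0, stem_r, stem_lmax, stem_a, 0),
                           type = "stem")
  col$next_organ <- 2L
  if (Ls > 1e-6) {
    nstep <- max(1L, as.integer(ceiling(Ls / st$dx - 1e-9)))
    steps <- rep(st$dx, nstep); steps[nstep] <- Ls - (nstep - 1) * st$dx
    cum <- cumsum(steps)
    ct <- .ctime_at_length(pmin(cum, Ls), stem_r, stem_lmax, 0, t_end)
    ct[nstep] <- t_end
    ids <- seq_len(nstep)
    z0 <- seed_pos[3] + c(0, cum[-nstep]); z1 <- seed_pos[3] + cum
    col$segs[[1L]] <- list(
      m = cbind(ids, c(0L, ids[-nstep]), 1, seed_pos[1], seed_pos[2], z0,
                seed_pos[1], seed_pos[2], z1, steps, stem_a, ct),
      type = "stem")
    col$next_seg <- nstep + 1L
    stem_ids <- ids; stem_cum <- cum; stem_ct <- ct
  }
  # --- axial roots --------------------------------------------------------
  sched <- schedule_axial_roots(params)
  sched <- sched[sched$emergence <= t_end, , drop = FALSE]
  dz_S <- st$l_n[["mean"]]  # crown whorl spacing along the shoot
  for (i in seq_len(nrow(sched))) {
    ty <- sched$type[i]; tem <- sched$emergence[i]
    if (ty == "crown" && length(stem_ids) > 0) {
      target <- sched$whorl[i] * dz_S
      ok <- which(stem_ct <= tem + 1e-9)
      if (length(ok) > 0) {
        j <- ok[which.min(abs(stem_cum[ok] - target))]
        base_node <- stem_ids[j]
        base_pt <- c(seed_pos[1], seed_pos[2], seed_pos[3] + stem_cum[j])
      } else {
        base_node <- 0L; base_pt <- seed_pos
      }
    } else {
      base_node <- 0L; base_pt <- seed_pos
    }
    .build_root(col, params, ty, tem, t_end, base_node, base_pt,
                base_dir = NULL, parent_organ = 1L)
  }
  # --- leaves (metadata only; no hydraulic segments) ----------------------
  lf <- params$shoot$leaf
  t_leaf <- lf$first_leaf
  while (t_leaf <= t_end) {
    oid <- col$next_organ; col$next_organ <- oid + 1L
    col$organs[[oid]] <- list(
      v = c(oid, 1, t_leaf, draw_param(1, lf$r, ff),
            draw_param(1, lf$l_max, ff), NA, draw_param(1, lf$theta, ff)),
      type = "leaf")
    t_leaf <- t_leaf + lf$delay_lat
  }
  if (length(col$segs) > 0) {
    m <- do.call(rbind, lapply(col$segs, `[[`, "m"))
    seg_type <- rep(vapply(col$segs, `[[`, character(1), "type"),
                    vapply(col$segs, function(x) nrow(x$m), integer(1)))
    segments <- data.frame(
      id = as.integer(m[, 1]), parent = as.integer(m[, 2]),
      organ = as.integer(m[, 3]), type = seg_type,
      x0 = m[, 4], y0 = m[, 5], z0 = m[, 6],
      x1 = m[, 7], y1 = m[, 8], z1 = m[, 9],
      dl = m[, 10], a = m[, 11], creation_time = m[, 12])
  } else {
    segments <- data.frame(id = integer(0), parent = integer(0),
                           organ = integer(0), type = character(0),
                           x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
                           x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                           dl = numeric(0), a = numeric(0),
                           creation_time = numeric(0))
  }
  rownames(segments) <- NULL
  om <- do.call(rbind, lapply(col$organs, `[[`, "v"))
  organs <- data.frame(
    organ = as.integer(om[, 1]), type = vapply(col$organs, `[[`,
                                               character(1), "type"),
    parent_organ = as.integer(om[, 2]), emergence = om[, 3],
    r = om[, 4], l_max = om[, 5], a = om[, 6], theta = om[, 7])
  rownames(organs) <- NULL
  structure(list(segments = segments, organs = organs,
                 seed_pos = seed_pos, t_end = t_end, seed = seed,
                 treatment = params$treatment, schedule = sched),
            class = "plant_network")
}

#' Restrict a plant network to an earlier time
#'
#' Keeps the segments created up to time t; because creation times follow
#' the exact inverse growth law, this reproduces the architecture as it
#' stood at t. Segment sets are monotone in t.
#'
#' @param net a \code{plant_network}.
#' @param t query time (days), in [0, t_end].
#' @return a \code{plant_network} with \code{t_end = t}.
#' @export
network_at_time <- function(net, t) {
  stopifnot(inherits(net, "plant_network"))
  if (t < 0 || t > net$t_end) stop("t outside the simulated range")
  keep <- net$segments$creation_time <= t + 1e-12
  out <- net
  out$segments <- net$segments[keep, , drop = FALSE]
  out$organs <- net$organs[net$organs$emergence <= t, , drop = FALSE]
  out$t_end <- t
  out
}

#' Per-type totals of a plant network
#'
#' Exact sums over the cylindrical segments present at time t: total
#' length, surface (2 pi a dl) and volume (pi a^2 dl) per organ type,
#' plus organ counts.
#'
#' @param net a \code{plant_network}.
#' @param t time at which to evaluate (default: the network's horizon).
#' @param roots_only drop the stem row (default FALSE).
#' @return data.frame with columns type, n_organs, length, surface, volume.
#' @export
summarize_network <- function(net, t = net$t_end, roots_only = FALSE) {
  sub <- if (t == net$t_end) net else network_at_time(net, t)
  s <- sub$segments
  if (roots_only) s <- s[s$type != "stem", , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(type = character(0), n_organs = integer(0),
                      length = numeric(0), surface = numeric(0),
                      volume = numeric(0)))
  }
  agg <- function(x, f) tapply(x, s$type, f)
  types <- sort(unique(s$type))
  data.frame(
    type = types,
    n_organs = as.integer(tapply(s$organ, s$type,
                                 function(o) length(unique(o)))[types]),
    length = as.numeric(agg(s$dl, sum)[types]),
    surface = as.numeric(tapply(2 * pi * s$a * s$dl, s$type, sum)[types]),
    volume = as.numeric(tapply(pi * s$a^2 * s$dl, s$type, sum)[types]),
    row.names = NULL)
}

#' Total root volume of a network (cm^3)
#'
#' @inheritParams summarize_network
#' @return total root-system volume (stem excluded).
#' @export
total_root_volume <- function(net, t = net$t_end) {
  sm <- summarize_network(net, t, roots_only = TRUE)
  sum(sm$volume)
}

#' @export
print.plant_network <- function(x, ...) {
  cat(sprintf(
    "plant_network (%s, seed %s): %d segments, %d organs, t_end %.1f d\n",
    x$treatment, format(x$seed), nrow(x$segments), nrow(x$organs), x$t_end))
  invisible(x)
}
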