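# Hand-built networks and an independent dense-matrix flow oracle used to
# cross-check the production sparse solver.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal plant_network wrapper around a segment table.
fake_network <- function(segments, t_end = 0) {
  structure(list(segments = segments, organs = NULL, seed_pos = c(0, 0, 0),
                 t_end = t_end, seed = NA, treatment = "fixture",
                 schedule = NULL),
            class = "plant_network")
}

# Single unbranched vertical root of length L split into n segments.
single_root_network <- function(L, n, a = 0.05, type = "primary") {
  dl <- L / n
  z <- -seq(0, L, by = dl)
  fake_network(data.frame(
    id = seq_len(n), parent = 0:(n - 1), organ = 2L, type = type,
    x0 = 0, y0 = 0, z0 = z[-(n + 1)], x1 = 0, y1 = 0, z1 = z[-1],
    dl = dl, a = a, creation_time = 0))
}

# Two identical unbranched roots attached at the seed node.
twin_root_network <- function(L, n, a = 0.05) {
  one <- single_root_network(L, n, a)$segments
  two <- one
  two$id <- two$id + n
  two$parent <- c(0L, two$id[-n])
  two$x0 <- two$x0 + 1; two$x1 <- two$x1 + 1
  fake_network(rbind(one, two))
}

# Random tree network with n segments: each new segment attaches to a
# uniformly chosen earlier node (or the seed).
random_tree_network <- function(n, seed) {
  set.seed(seed)
  parent <- integer(n)
  for (i in seq_len(n)) parent[i] <- sample.int(i, 1) - 1L
  dl <- runif(n, 0.05, 0.5)
  fake_network(data.frame(
    id = seq_len(n), parent = parent, organ = 2L, type = "primary",
    x0 = 0, y0 = 0, z0 = 0, x1 = 0, y1 = 0, z1 = -dl,
    dl = dl, a = runif(n, 0.01, 0.1), creation_time = 0))
}

random_conductances <- function(net, seed) {
  set.seed(seed)
  n <- nrow(net$segments)
  data.frame(id = net$segments$id,
             Kr = runif(n, 1e-5, 1e-2),
             Kx = runif(n, 1e-3, 1))
}

# Independent oracle: assemble the full flow-balance system with explicit
# midpoint unknowns and solve it densely with base R. Unknowns are the
# nn node potentials followed by the n midpoint potentials.
dense_flow_oracle <- function(net, cond, psi_sr, psi_collar) {
  s <- net$segments
  n <- nrow(s)
  if (length(psi_sr) == 1) psi_sr <- rep(psi_sr, n)
  node_ids <- c(0L, s$id)
  p <- match(s$parent, node_ids)
  q <- match(s$id, node_ids)
  nn <- n + 1L
  c_ax <- cond$Kx / s$dl
  A <- matrix(0, nn + n, nn + n)
  b <- numeric(nn + n)
  for (i in seq_len(n)) {
    m <- nn + i
    # midpoint balance: 2c (psi_p - psi_m) + 2c (psi_q - psi_m) + Kr (psi_s - psi_m) = 0
    A[m, p[i]] <- A[m, p[i]] + 2 * c_ax[i]
    A[m, q[i]] <- A[m, q[i]] + 2 * c_ax[i]
    A[m, m] <- A[m, m] - 4 * c_ax[i] - cond$Kr[i]
    b[m] <- b[m] - cond$Kr[i] * psi_sr[i]
    # node balances: flow from the midpoint into each end node
    A[p[i], m] <- A[p[i], m] + 2 * c_ax[i]
    A[p[i], p[i]] <- A[p[i], p[i]] - 2 * c_ax[i]
    A[q[i], m] <- A[q[i], m] + 2 * c_ax[i]
    A[q[i], q[i]] <- A[q[i], q[i]] - 2 * c_ax[i]
  }
  stem <- net$segments[net$segments$type == "stem", , drop = FALSE]
  collar <- if (nrow(stem) == 0) 0L else stem$id[which.max(stem$z1)]
  k <- match(collar, node_ids)
  A[k, ] <- 0; A[k, k] <- 1; b[k] <- psi_collar
  x <- solve(A, b)
  psi <- x[seq_len(nn)]
  psi_m <- x[nn + seq_len(n)]
  Jr <- cond$Kr * (psi_sr - psi_m)
  list(psi_node = stats::setNames(psi, node_ids), psi_mid = psi_m,
       Jr = Jr, T_act = sum(Jr))
}

# Closed-form conductance of a single uniform root (hyperbolic solution
# of the continuous radial-uptake/axial-transport balance).
krs_uniform_root <- function(L, a, kr, kx) {
  tau <- sqrt(2 * pi * a * kr / kx)
  sqrt(2 * pi * a * kr * kx) * tanh(L * tau)
}
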