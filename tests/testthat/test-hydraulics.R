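test_that("segment conductances instantiate the radial and axial formulas", {
  net <- single_root_network(L = 0.25, n = 1, a = 0.05)
  prof <- constant_hydraulic_profile(kr = 1e-3, kx = 0.1)
  cond <- segment_conductances(net, prof, t = 0)
  expect_equal(cond$Kr, 2 * pi * 0.05 * 0.25 * 1e-3)
  expect_equal(cond$Kx, 0.1)
})

test_that("stem segments have zero radial and quartic axial conductance", {
  seg <- data.frame(id = 1L, parent = 0L, organ = 1L, type = "stem",
                    x0 = 0, y0 = 0, z0 = -3, x1 = 0, y1 = 0, z1 = -2,
                    dl = 1, a = 0.13, creation_time = 0)
  net <- fake_network(seg)
  c1 <- segment_conductances(net, constant_hydraulic_profile(1e-4, 0.1,
                                                             a_xyl_frac = 0.1))
  expect_equal(c1$Kr, 0)
  c2 <- segment_conductances(net, constant_hydraulic_profile(1e-4, 0.1,
                                                             a_xyl_frac = 0.2))
  expect_equal(c2$Kx / c1$Kx, 16, tolerance = 1e-12)
})

test_that("a missing profile type is reported by name", {
  net <- single_root_network(1, 4, type = "crown")
  prof <- constant_hydraulic_profile(1e-4, 0.1, types = "primary")
  expect_error(segment_conductances(net, prof), "crown")
})

test_that("no potential gradient means no flow", {
  net <- single_root_network(10, 40)
  cond <- data.frame(id = net$segments$id, Kr = 1e-4, Kx = 0.1)
  sol <- solve_water_flow(net, cond, psi_sr = -500, psi_collar = -500)
  expect_lt(max(abs(sol$Jr)), 1e-12)
  expect_lt(max(abs(sol$Jx)), 1e-12)
  expect_lt(abs(sol$T_act), 1e-12)
})

test_that("mirrored sibling roots carry identical flows", {
  net <- twin_root_network(10, 20)
  cond <- data.frame(id = net$segments$id, Kr = 1e-4, Kx = 0.05)
  sol <- solve_water_flow(net, cond, psi_sr = -300, psi_collar = -1000)
  expect_equal(sol$Jr[1:20], sol$Jr[21:40], tolerance = 1e-9)
})

test_that("the sparse solver matches the independent dense oracle", {
  for (seed in 1:12) {
    n <- sample(10:200, 1)
    net <- random_tree_network(n, seed)
    cond <- random_conductances(net, seed + 500)
    set.seed(seed + 900)
    psi_sr <- runif(n, -800, -100)
    sol <- solve_water_flow(net, cond, psi_sr, psi_collar = -2000)
    ora <- dense_flow_oracle(net, cond, psi_sr, psi_collar = -2000)
    rel <- max(abs(sol$psi_node - ora$psi_node) / pmax(abs(ora$psi_node), 1))
    expect_lt(rel, 1e-8)
    expect_equal(sol$T_act, ora$T_act, tolerance = 1e-8)
  }
})

test_that("flow is conserved at every junction and at the collar", {
  net <- random_tree_network(120, seed = 4)
  cond <- random_conductances(net, 77)
  sol <- solve_water_flow(net, cond, psi_sr = -300, psi_collar = -1500)
  s <- net$segments
  # at each internal node: outflow of the owning segment equals the sum of
  # the children's proximal inflows
  for (j in s$id) {
    children <- which(s$parent == j)
    own <- which(s$id == j)
    arriving <- sum(sol$Jx[children])
    leaving <- sol$Jx[own] - sol$Jr[own]
    expect_equal(leaving, arriving,
                 tolerance = 1e-10 * max(1, abs(sol$T_act)))
  }
  # collar: total transpiration equals the axial flow arriving there
  at_collar <- which(s$parent == 0)
  expect_equal(sum(sol$Jx[at_collar]), sol$T_act,
               tolerance = 1e-10 * max(1, abs(sol$T_act)))
})

test_that("a single uniform root reproduces the closed-form conductance", {
  L <- 50; a <- 0.05; kr <- 1e-4; kx <- 0.05
  net <- single_root_network(L, n = L / 0.1, a = a)
  cond <- data.frame(id = net$segments$id,
                     Kr = 2 * pi * a * net$segments$dl * kr, Kx = kx)
  krs <- compute_krs(net, cond)
  expect_equal(krs, krs_uniform_root(L, a, kr, kx), tolerance = 1e-3)
  # short nearly-all-radial root too
  L2 <- 2
  net2 <- single_root_network(L2, n = 20, a = a)
  cond2 <- data.frame(id = net2$segments$id,
                      Kr = 2 * pi * a * net2$segments$dl * kr, Kx = kx)
  expect_equal(compute_krs(net2, cond2), krs_uniform_root(L2, a, kr, kx),
               tolerance = 1e-3)
})

test_that("SUF is a probability vector and splits by symmetry", {
  one <- single_root_network(0.5, 1)
  suf1 <- compute_suf(one, data.frame(id = 1L, Kr = 1e-4, Kx = 0.1))
  expect_equal(suf1, 1)
  twin <- twin_root_network(10, 15)
  cond <- data.frame(id = twin$segments$id, Kr = 2e-4, Kx = 0.05)
  suf <- compute_suf(twin, cond)
  expect_equal(sum(suf), 1, tolerance = 1e-10)
  expect_true(all(suf >= 0))
  expect_equal(sum(suf[1:15]), 0.5, tolerance = 1e-10)
  # uniform soil: effective potential is the uniform value
  expect_equal(effective_soil_potential(suf, -432), -432, tolerance = 1e-9)
  net <- random_tree_network(80, 3)
  suf2 <- compute_suf(net, random_conductances(net, 8))
  expect_equal(sum(suf2), 1, tolerance = 1e-10)
  expect_true(all(suf2 >= -1e-14))
})

test_that("K_rs is invariant to the collar potential and scales linearly", {
  net <- random_tree_network(60, 21)
  cond <- random_conductances(net, 22)
  k1 <- compute_krs(net, cond, psi_collar = -1000)
  k2 <- compute_krs(net, cond, psi_collar = -5000)
  expect_equal(k1, k2, tolerance = 1e-10)
  # joint scaling of all conductances scales K_rs by the same factor
  cond_scaled <- transform(cond, Kr = 3 * Kr, Kx = 3 * Kx)
  expect_equal(compute_krs(net, cond_scaled), 3 * k1, tolerance = 1e-10)
  # vanishing radial conductivity kills K_rs
  cond_small <- transform(cond, Kr = 1e-12 * Kr)
  expect_lt(compute_krs(net, cond_small), 1e-10 * k1)
  # infinite axial transport: K_rs approaches the all-radial limit
  cond_inf <- transform(cond, Kx = 1e9)
  expect_equal(compute_krs(net, cond_inf), sum(cond$Kr), tolerance = 1e-4)
})

test_that("K_rs never decreases when a radial conductivity is raised", {
  for (seed in 1:5) {
    net <- random_tree_network(30, seed + 40)
    cond <- random_conductances(net, seed + 60)
    k0 <- compute_krs(net, cond)
    i <- sample.int(30, 1)
    cond$Kr[i] <- cond$Kr[i] * 2
    expect_gte(compute_krs(net, cond), k0 - 1e-14)
  }
})

test_that("degenerate systems are reported", {
  net <- single_root_network(1, 4)
  cond <- data.frame(id = net$segments$id, Kr = 0, Kx = 0.1)
  expect_error(solve_water_flow(net, cond, -300, -1000), "radial")
  expect_error(compute_krs(net, data.frame(id = net$segments$id,
                                           Kr = 1e-4, Kx = 0.1),
                           psi_sr = -300, psi_collar = -300), "undefined")
})

test_that("the K_rs time series is consistent and grows with the plant", {
  pp <- plant_params(load_parameter_table("P2"))
  net <- simulate_plant(pp, t_end = 14, seed = 2)
  prof <- constant_hydraulic_profile(kr = 5e-5, kx = 0.05)
  ts <- krs_time_series(net, prof, times = c(6, 10, 14))
  # age-constant properties on a growing network: K_rs non-decreasing
  expect_true(all(diff(ts$krs) > 0))
  # single-time evaluation equals the direct computation
  cond <- segment_conductances(net, prof, 14)
  expect_equal(ts$krs[3], compute_krs(net, cond), tolerance = 1e-12)
})
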