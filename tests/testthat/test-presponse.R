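# closed-form OLS used as the independent oracle throughout
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = b, intercept = mean(y) - b * mean(x))
}

test_that("the axial-radius line matches the closed-form OLS oracle", {
  P <- c(1.8, 3.3, 4.6, 7.7)
  radii <- c(0.054, 0.064, 0.067, 0.091)  # tabulated primary radii
  fit <- fit_axial_radius_response(P, radii)
  ora <- ols_oracle(P, radii)
  expect_equal(fit$slope, unname(ora["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(ora["intercept"]), tolerance = 1e-10)
  expect_equal(fit$P_min, 1.8)
  expect_equal(fit$P_max, 7.7)
  # perfectly collinear data are recovered exactly
  fit2 <- fit_axial_radius_response(c(1, 2, 4), 0.01 * c(1, 2, 4) + 0.03)
  expect_equal(fit2$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0.03, tolerance = 1e-12)
  # two points: the line through both
  fit3 <- fit_axial_radius_response(c(2, 6), c(0.05, 0.09))
  expect_equal(fit3$slope, 0.01, tolerance = 1e-12)
  expect_error(fit_axial_radius_response(c(3, 3), c(1, 2)), "distinct")
})

test_that("the crown elongation response is capped linear through zero", {
  m <- list(alpha_rc = 1.6, PB_max = 2.4)
  expect_equal(crown_elongation_response(0, m), 0)
  expect_equal(crown_elongation_response(2.4, m),
               crown_elongation_response(4.8, m))
  expect_equal(crown_elongation_response(1, m), 1.6)
  expect_error(crown_elongation_response(-0.1, m), "non-negative")
})

test_that("capped-linear fits recover the generating coefficients", {
  # zero noise: exact recovery (cap identifiable: PB values straddle it)
  d0 <- gen_response_dataset(P_levels = c(1, 2, 4, 6, 8), DM = 2,
                             alpha_rc = 1.6, PB_max = 2,
                             noise_rel = 0, n_per_level = 3)
  f0 <- fit_crown_elongation_response(d0$data$PB, d0$data$rc)
  expect_equal(f0$alpha_rc, 1.6, tolerance = 1e-10)
  expect_equal(f0$PB_max, 2)
  expect_true(f0$cap_identified)
  # all PB below the cap: flagged unidentifiable
  d1 <- gen_response_dataset(P_levels = c(1, 1.5, 2, 2.5), DM = 2,
                             alpha_rc = 1.6, PB_max = 9, noise_rel = 0)
  expect_false(d1$truth$cap_identifiable)
  f1 <- fit_crown_elongation_response(d1$data$PB, d1$data$rc)
  expect_false(f1$cap_identified)
})

test_that("the leaf elongation line honours its validity bounds", {
  P <- c(1.8, 3.3, 4.6, 7.7)
  rl <- c(7.921, 7.914, 8.8, 10.907)  # tabulated leaf elongation means
  fit <- fit_leaf_elongation_response(P, rl)
  ora <- ols_oracle(P, rl)
  expect_equal(fit$slope, unname(ora["slope"]), tolerance = 1e-10)
  expect_equal(leaf_elongation_response(7.7, fit),
               unname(ora["slope"]) * 7.7 + unname(ora["intercept"]),
               tolerance = 1e-10)
  # OLS passes through the centroid
  expect_equal(leaf_elongation_response(mean(P), fit), mean(rl),
               tolerance = 1e-10)
  # zero slope: constant
  fitc <- list(slope = 0, intercept = 6.5, P_min = 1, P_max = 9)
  expect_equal(leaf_elongation_response(c(2, 5), fitc), c(6.5, 6.5))
  expect_error(leaf_elongation_response(0.5, fit), "bounds")
  expect_error(leaf_elongation_response(9, fit), "bounds")
})

test_that("response application touches only the response parameters", {
  model <- fit_p_response()
  base <- load_parameter_table("general")
  out <- apply_response(base, P = 4.6, DM_plant = 2.2, model = model)
  d0 <- base$data; d1 <- out$data
  changed <- which(d0$mean != d1$mean)
  allowed <- which((d0$organ %in% c("primary", "seminal", "crown") &
                      d0$parameter == "a") |
                     (d0$organ == "crown" & d0$parameter == "r"))
  expect_true(all(changed %in% allowed))
  expect_identical(d0$sd, d1$sd)
  # e.g. lateral maximal lengths are bit-identical
  expect_identical(param_value(out, "l-lateral", "l_max"),
                   param_value(base, "l-lateral", "l_max"))
  # a flat radius line leaves radii untouched (ratio 1 at any P)
  flat <- model
  flat$axial$slope <- 0
  out2 <- apply_response(base, P = 4.6, DM_plant = 2.2, model = flat)
  for (ty in c("primary", "seminal", "crown")) {
    expect_identical(param_value(out2, ty, "a"), param_value(base, ty, "a"))
  }
  # applying twice at the same P from the same base is idempotent on
  # non-response parameters
  out3 <- apply_response(out, P = 4.6, DM_plant = 2.2, model = model)
  keep <- setdiff(seq_len(nrow(d0)), allowed)
  expect_identical(out3$data$mean[keep], out$data$mean[keep])
  expect_error(apply_response(base, P = 12, DM_plant = 2, model = model),
               "bounds")
})

test_that("the radius response scales axial radii by the fitted line ratio", {
  model <- fit_p_response()
  base <- load_parameter_table("general")
  line <- function(p) model$axial$slope * p + model$axial$intercept
  out <- apply_response(base, P = 7.7, DM_plant = 2.8, model = model)
  ratio <- line(7.7) / line(model$axial$P_ref)
  expect_equal(param_value(out, "primary", "a")[["mean"]],
               param_value(base, "primary", "a")[["mean"]] * ratio,
               tolerance = 1e-12)
})
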