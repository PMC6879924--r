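param_of <- function(tbl, name, col = "mean") {
  tbl[[col]][tbl$parameter == name]
}

test_that("aging tables reproduce the prescribed per-decade anchors exactly", {
  p75 <- aging_parameters(75)
  expect_identical(param_of(p75, "prox_aortic_length"), 112.0)
  expect_identical(param_of(p75, "pvc"), 17.3)
  p25 <- aging_parameters(25)
  expect_identical(param_of(p25, "prox_aortic_length"), 80.0)
  expect_identical(param_of(p25, "pvc"), 40.1)
  expect_identical(param_of(p25, "hr"), 73.0)
  expect_identical(param_of(aging_parameters(45), "hr"), 77.0)
  expect_error(aging_parameters(20), "between 25 and 75")
  expect_error(aging_parameters(80), "between 25 and 75")
})

test_that("interpolated means lie between their decade anchors", {
  p25 <- aging_parameters(25); p35 <- aging_parameters(35)
  p30 <- aging_parameters(30)
  for (par in p30$parameter) {
    lo <- min(param_of(p25, par), param_of(p35, par))
    hi <- max(param_of(p25, par), param_of(p35, par))
    expect_gte(param_of(p30, par), lo - 1e-9)
    expect_lte(param_of(p30, par), hi + 1e-9)
  }
})

test_that("exactly six varied factors are flagged", {
  p <- aging_parameters(50)
  expect_setequal(unique(stats::na.omit(p$varied_factor)), varied_factors())
  expect_length(varied_factors(), 6)
})

test_that("offsets apply with LVET coupling and asymmetric PWV SDs", {
  p <- aging_parameters(25)
  base <- apply_offsets(p)
  expect_equal(base$hr, 73.0)
  expect_equal(base$lvet, 282)
  expect_true(all(c(base$off_hr, base$off_sv, base$off_lvet, base$off_diameter,
                    base$off_pwv, base$off_map) == 0))

  ## +1 SD in HR (= +11 beats/min) shifts the LVET mean by -0.926 * 11
  hr_up <- apply_offsets(p, c(hr = 1))
  expect_equal(hr_up$hr, 84)
  expect_equal(hr_up$lvet, 282 - 0.926 * 11, tolerance = 1e-12)

  ## asymmetric SDs: +1 uses sd_plus, -1 uses sd_minus
  p35 <- aging_parameters(35)
  up <- apply_offsets(p35, c(pwv = 1))
  dn <- apply_offsets(p35, c(pwv = -1))
  sp <- param_of(p35, "pwv_aortic", "sd_plus")
  sm <- param_of(p35, "pwv_aortic", "sd_minus")
  expect_equal(up$pwv_aortic, param_of(p35, "pwv_aortic") + sp)
  expect_equal(dn$pwv_aortic, param_of(p35, "pwv_aortic") - sm)
  expect_gt(sp, sm)  # positive skewness of the PWV distribution

  ## absolute regression mode
  abs_mode <- suppressWarnings(apply_offsets(p, lvet_mode = "absolute"))
  expect_equal(abs_mode$lvet, 244 - 0.926 * 73 + 1.08 * 66.8, tolerance = 1e-12)

  expect_error(apply_offsets(p, c(hr = 2)), "-1, 0 or \\+1")
  expect_error(apply_offsets(p, c(pft = 1)), "varied factors")
})

test_that("stiffness calibration recovers known constants and its closed forms", {
  ## single anchor, k1 = 0: k3 = 3 rho c^2 / 2
  fit1 <- calibrate_stiffness(5, 0.01)
  expect_equal(fit1$k3, 1.5 * 1060 * 25)
  expect_equal(fit1$k1, 0)

  ## parameter recovery from synthetic targets (exponential-shaped truth)
  truth <- list(k1 = 2e5, k2 = -900, k3 = 5e4)
  radii <- c(0.01, 0.002, 0.004)
  targets <- wave_speed(wall_stiffness(radii, truth$k1, truth$k2, truth$k3), radii)
  fit <- calibrate_stiffness(targets, radii)
  expect_lt(fit$residual, 0.005)
  expect_equal(fit$achieved, targets, tolerance = 0.005)
  expect_equal(fit$k2, truth$k2, tolerance = 1e-4)

  ## deterministic: identical fit on a second call
  fit2 <- calibrate_stiffness(targets, radii)
  expect_identical(fit$k1, fit2$k1)

  td <- tidy(fit)
  expect_equal(td$term, c("k1", "k2", "k3"))
  expect_equal(glance(fit)$n_anchors, 3)
})

test_that("resistance calibration hits the target effective resistance", {
  net <- make_fixture_network("tiny")
  map <- 93.3; co <- 5
  net <- calibrate_resistances(net, map_target = map, co = co,
                               pvc_total = 4e-9)
  r_target <- map * 133.322 / (co / 1000 / 60)
  expect_equal(r_target, 1.49e8, tolerance = 0.01)   # unit arithmetic
  r_wk <- setNames(as.list(net$outlets$R1 + net$outlets$R2),
                   net$outlets$segment)
  eff <- pulsesim:::tree_effective_resistance(net, r_wk)
  expect_equal(eff, r_target, tolerance = 1e-8)
  ## symmetric outlets with equal areas get equal resistances
  expect_equal(net$outlets$R1[1], net$outlets$R1[2])
  expect_equal(net$outlets$R2[1], net$outlets$R2[2])
  ## compliances sum to the prescribed total, equal time constants per bed
  expect_equal(sum(net$outlets$C), 4e-9)
  expect_equal(net$outlets$R2[1] * net$outlets$C[1],
               net$outlets$R2[2] * net$outlets$C[2])
  expect_error(calibrate_resistances(net, map_target = 0, co = 5,
                                     pvc_total = 4e-9, p_out = 10),
               "parameter error")
})

test_that("the subject grid enumerates 3^k offset combinations deterministically", {
  g1 <- generate_grid(25)
  expect_equal(nrow(g1), 729)
  g6 <- generate_grid(seq(25, 75, by = 10))
  expect_equal(nrow(g6), 4374)
  expect_equal(nrow(generate_grid(25, factors = "hr")), 3)
  ## the baseline (all-zero) member is present once per age
  offs <- paste0("off_", varied_factors())
  expect_equal(sum(rowSums(abs(g1[offs])) == 0), 1)
  expect_identical(generate_grid(c(25, 75)), generate_grid(c(25, 75)))
})

test_that("plausibility filter uses closed 99% reference intervals", {
  ref <- bp_reference()
  at_mean <- setNames(as.list(ref$mean[ref$age == 25]),
                      ref$quantity[ref$age == 25])
  ok <- plausibility_filter(at_mean, 25)
  expect_true(ok$plausible)
  expect_length(ok$violations, 0)

  bad <- at_mean
  i <- which(ref$age == 25 & ref$quantity == "brachial_sbp")
  bad$brachial_sbp <- ref$mean[i] + 3 * ref$sd[i]
  res <- plausibility_filter(bad, 25)
  expect_false(res$plausible)
  expect_identical(res$violations, "brachial_sbp")

  ## exactly on the boundary: still plausible (closed interval)
  edge <- at_mean
  edge$brachial_sbp <- ref$mean[i] + 2.575 * ref$sd[i]
  expect_true(plausibility_filter(edge, 25)$plausible)

  expect_error(plausibility_filter(at_mean[-1], 25), "missing quantit")
})
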