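test_that("tube law reproduces its closed forms and the wave speed constraint", {
  Eh <- 400; Ad <- pi * 0.01^2; Pd <- 1e4
  expect_equal(tube_law_pressure(Ad, Ad, 0, Eh, 0, Pd), Pd)
  ## elastic closed form at A = 1.21 Ad (sqrt(A) = 1.1 sqrt(Ad))
  beta <- 4 / 3 * sqrt(pi) * Eh
  expect_equal(tube_law_pressure(1.21 * Ad, Ad, 0, Eh, 0, Pd) - Pd,
               0.1 * beta / sqrt(Ad), tolerance = 1e-12)
  ## numeric dP/dA at Ad times Ad/rho equals c_d^2 to < 0.1%
  h <- Ad * 1e-6
  dPdA <- (tube_law_pressure(Ad + h, Ad, 0, Eh, 0, Pd) -
           tube_law_pressure(Ad - h, Ad, 0, Eh, 0, Pd)) / (2 * h)
  cd2 <- wave_speed(Eh, 0.01, 1060)^2
  expect_equal(dPdA * Ad / 1060, cd2, tolerance = 1e-3)
  ## viscous term adds g * dA/dt with g = Gamma / (Ad sqrt(Ad))
  expect_equal(tube_law_pressure(Ad, Ad, 1e-4, Eh, 700, Pd) - Pd,
               0.7 / (Ad * sqrt(Ad)) * 1e-4, tolerance = 1e-12)
  expect_error(tube_law_pressure(-Ad, Ad, 0, Eh), "blow-up")
})

test_that("windkessel reaches its resistive steady state and decays with tau = R2 C", {
  R1 <- 2e8; R2 <- 8e8; C <- 1e-9; P_out <- 500
  q0 <- 1e-5; dt <- 1e-4
  pc <- 0
  for (i in 1:200000) pc <- windkessel_step(pc, q0, dt, R1, R2, C, P_out)$pc
  st <- windkessel_step(pc, q0, dt, R1, R2, C, P_out)
  expect_equal(st$P, q0 * (R1 + R2) + P_out, tolerance = 1e-6)
  expect_equal(st$V, C * (st$pc - P_out), tolerance = 1e-12)

  ## free decay from P_C0: fit the time constant within 1%
  tau <- R2 * C
  dt <- tau / 2000
  pc <- 5000; n <- 2000
  trace <- numeric(n)
  for (i in seq_len(n)) {
    pc <- windkessel_step(pc, 0, dt, R1, R2, C, 0)$pc
    trace[i] <- pc
  }
  tt <- dt * seq_len(n)
  tau_fit <- -1 / coef(lm(log(trace) ~ tt))[["tt"]]
  expect_equal(tau_fit, tau, tolerance = 0.01)
})

test_that("PPG synthesis normalises exactly to [0, 1] and is affine invariant", {
  t <- seq(0, 0.798, by = 0.002)
  v <- 2e-7 + 5e-8 * sin(2 * pi * t / 0.8) + 1e-8 * cos(4 * pi * t / 0.8)
  ppg <- synthesize_ppg(waveform(t, v, "PPG"))
  expect_identical(min(ppg$y), 0)
  expect_identical(max(ppg$y), 1)
  ppg2 <- synthesize_ppg(3.7 * v + 1e-6)
  expect_equal(ppg2, ppg$y, tolerance = 1e-12)
  expect_error(synthesize_ppg(rep(1, 100)), "degenerate")
})

test_that("a small pulse propagates at the theoretical diastolic wave speed", {
  c_d <- 8
  pws <- cached("pulse_tube", pulse_tube_sim())
  ptt <- foot_to_foot_ptt(get_wave(pws, "a", "P"), get_wave(pws, "b", "P"))
  pwv_measured <- pwv(ptt, 0.7 * 1.2)
  expect_equal(pwv_measured, c_d, tolerance = 0.02)
})

test_that("a matched windkessel absorbs the incident pulse (< 2% reflection)", {
  pws <- cached("pulse_tube", pulse_tube_sim())
  p <- get_wave(pws, "a", "P")
  peak <- max(p$y)
  ## after the incident pulse has passed site a (transit + pulse width),
  ## any secondary excursion is a reflection
  t_pass <- 0.05 + (0.15 * 1.2 + 0.012 * 8) / 8 + 6 * 0.012
  late <- p$y[p$t > t_pass & p$t < 0.75]
  expect_lt(max(abs(late)), 0.02 * peak)
})

test_that("an interposed junction between identical tubes is transparent", {
  k3 <- 1.5 * 1060 * 8^2
  seg <- tibble::tibble(id = c("t1", "t2"), length = 0.6, r_in = 0.005,
                        r_out = 0.005, k1 = 0, k2 = 0, k3 = k3, b0 = 0, b1 = 0,
                        diam_class = NA_character_, len_class = NA_character_)
  jn <- tibble::tibble(parent = "t1", daughter = "t2")
  a <- pi * 0.005^2
  out <- tibble::tibble(segment = "t2", R1 = 1060 * 8 / a, R2 = 5e5, C = 1e-9,
                        P_out = 0)
  sites <- tibble::tibble(site = "a", segment = "t1", fraction = 0.3,
                          ppg = NA_character_)
  net <- pw_network(seg, jn, out, "t1", sites,
                    blood = blood_properties(viscosity = 1e-6))
  pws <- simulate_subject(net, gaussian_inflow(), p_diastolic = 0,
                          options = solver_options(max_cycles = 3,
                                                   output_fs = 2000,
                                                   dx_max = 0.004))
  p <- get_wave(pws, "a", "P")
  peak <- max(p$y)
  t_pass <- 0.05 + (0.3 * 1.2) / 8 + 6 * 0.012
  late <- p$y[p$t > t_pass & p$t < 0.75]
  expect_lt(max(abs(late)), 0.01 * peak)
})

test_that("a symmetric bifurcation splits flow equally", {
  k3 <- 1.5 * 1060 * 8^2
  seg <- tibble::tibble(id = c("p", "d1", "d2"), length = c(0.3, 0.4, 0.4),
                        r_in = c(0.006, 0.004, 0.004),
                        r_out = c(0.006, 0.004, 0.004),
                        k1 = 0, k2 = 0, k3 = k3, b0 = 600, b1 = 150,
                        diam_class = NA_character_, len_class = NA_character_)
  jn <- tibble::tibble(parent = "p", daughter = c("d1", "d2"))
  out <- tibble::tibble(segment = c("d1", "d2"), R1 = 2e8, R2 = 8e8, C = 1e-9,
                        P_out = 0)
  sites <- tibble::tibble(site = c("e1", "e2"), segment = c("d1", "d2"),
                          fraction = 0.7, ppg = NA_character_)
  net <- pw_network(seg, jn, out, "p", sites)
  q <- generate_inflow(list(hr = 75, sv = 12, lvet = 282, pft = 79, rfv = 0.2))
  pws <- simulate_subject(net, q, p_diastolic = 20)
  q1 <- get_wave(pws, "e1", "Q")$y
  q2 <- get_wave(pws, "e2", "Q")$y
  expect_lt(max(abs(q1 - q2)), 1e-10 * max(abs(q1)))
})

test_that("steady flow through a tube reproduces the Poiseuille pressure gradient", {
  ## low outlet resistance keeps the tube near its diastolic area so the
  ## closed-form gradient at radius r applies
  r <- 0.004; L <- 0.5; mu <- 2.5e-3; q0 <- 5e-6
  net <- uniform_tube(length = L, radius = r, c_d = 8, R1 = 2e6, R2 = 8e6,
                      C = 1e-9,
                      sites = tibble::tibble(
                        site = c("a", "b"), segment = "tube",
                        fraction = c(0.1, 0.9), ppg = NA_character_))
  n <- 400
  infl <- waveform((0:(n - 1)) * 0.8 / n, rep(q0, n), "Q")
  pws <- suppressWarnings(simulate_subject(
    net, infl, p_diastolic = 0,
    options = solver_options(max_cycles = 20, periodicity_tol = 1e-6)))
  dp <- mean(get_wave(pws, "a", "P")$y) - mean(get_wave(pws, "b", "P")$y)
  dp_poiseuille <- 8 * mu * (0.8 * L) * q0 / (pi * r^4)
  expect_equal(dp, dp_poiseuille, tolerance = 0.02)
})

test_that("zero inflow leaves the diastolic equilibrium untouched", {
  net <- uniform_tube()
  n <- 200
  infl <- waveform((0:(n - 1)) * 0.4 / n, rep(0, n), "Q")
  pws <- suppressWarnings(simulate_subject(
    net, infl, p_diastolic = 0, options = solver_options(max_cycles = 2)))
  expect_lt(max(abs(get_wave(pws, "mid", "Q")$y)), 1e-15)
  a <- get_wave(pws, "mid", "A")$y
  expect_equal(a, rep(pi * 0.005^2, length(a)), tolerance = 1e-12)
})

test_that("simulated subjects conserve mass and satisfy Q = U A", {
  pws <- baseline_sim(25)
  expect_true(attr(pws, "meta")$converged)
  expect_lt(mass_balance(pws)$residual_frac, 0.005)
  for (site in c("aortic_root", "radial", "femoral")) {
    q <- get_wave(pws, site, "Q")$y
    u <- get_wave(pws, site, "U")$y
    a <- get_wave(pws, site, "A")$y
    expect_equal(q, u * a, tolerance = 1e-12)
  }
  ## cycle-averaged pressure audit: MAP ~ CO x R_effective + P_out
  cfg <- attr(pws, "config")
  map <- mean(pa_to_mmhg(get_wave(pws, "aortic_root", "P")$y))
  expect_equal(map, cfg$map, tolerance = 2 / cfg$map)  # within ~2 mmHg
})

test_that("wall viscosity produces pressure-area hysteresis, elastic walls do not", {
  loop_area <- function(b0, b1) {
    net <- uniform_tube(length = 0.6, c_d = 7, b0 = b0, b1 = b1, R1 = NULL)
    q <- generate_inflow(list(hr = 75, sv = 15, lvet = 282, pft = 79, rfv = 0))
    pws <- simulate_subject(net, q, p_diastolic = 40)
    p <- get_wave(pws, "mid", "P")$y
    a <- get_wave(pws, "mid", "A")$y
    sum(p * (dplyr::lead(a, default = a[1]) - dplyr::lag(a, default = a[length(a)]))) / 2
  }
  area_elastic <- loop_area(0, 0)
  area_visc <- loop_area(600, 150)
  expect_gt(area_visc, 0)
  expect_gt(area_visc, 10 * abs(area_elastic))
})

test_that("halving the grid spacing changes systolic pressure by < 0.5 mmHg", {
  sbp <- vapply(c(0.007, 0.0035), function(dx) {
    pws <- simulate_virtual_subject(25, options = solver_options(dx_max = dx))
    max(pa_to_mmhg(get_wave(pws, "aortic_root", "P")$y))
  }, numeric(1))
  expect_lt(abs(diff(sbp)), 0.5)
})
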