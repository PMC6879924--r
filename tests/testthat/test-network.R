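test_that("radius_at interpolates linearly and matches endpoints", {
  expect_equal(radius_at(0.01, 0.008, 0), 0.01)
  expect_equal(radius_at(0.01, 0.008, 1), 0.008)
  expect_equal(radius_at(0.01, 0.008, 0.5), 0.009)
  expect_equal(radius_at(0.01, 0.008, 0.25), 0.0095)
  x <- seq(0, 1, by = 0.05)
  r <- radius_at(0.012, 0.007, x)
  expect_true(all(diff(r) < 0))          # monotone along the taper
  expect_error(radius_at(0.01, 0.008, 1.2), "axial fraction")
  expect_error(radius_at(-0.01, 0.008, 0.5), "radii")
})

test_that("wall stiffness law matches a CGS hand computation after unit conversion", {
  ## exponential term switched off: Eh = Rd * k3
  expect_equal(wall_stiffness(0.01, 0, -5, 3e4), 0.01 * 3e4)
  ## CGS oracle: Rd = 0.75 cm, k in g s^-2 cm^-1 / cm^-1
  rd_cm <- 0.75
  k1_cgs <- 2e6; k2_cgs <- -2.253; k3_cgs <- 8.65e5
  eh_cgs <- rd_cm * (k1_cgs * exp(k2_cgs * rd_cm) + k3_cgs)  # dyn/cm
  eh_si_expected <- eh_cgs * 1e-3                            # N/m
  ks <- stiffness_constants_si(k1_cgs, k2_cgs, k3_cgs)
  expect_equal(wall_stiffness(0.0075, ks$k1, ks$k2, ks$k3), eh_si_expected,
               tolerance = 1e-12)
  expect_error(wall_stiffness(-1, 1, 1, 1), "Rd")
})

test_that("theoretical wave speed follows c_d = sqrt(2Eh/(3 rho Rd))", {
  rho <- 1060; rd <- 0.008
  expect_equal(wave_speed(1.5 * rho * rd, rd, rho), 1)        # algebraic identity
  expect_equal(wave_speed(400, 0.01, 1060), sqrt(800 / 31.8), tolerance = 1e-12)
  ## inverse use: Eh that yields the young aortic wave speed target
  eh <- 1.5 * 1060 * 0.012 * 5.9^2
  expect_equal(wave_speed(eh, 0.012, 1060), 5.9)
  expect_error(wave_speed(-1, 0.01), "> 0")
})

test_that("wall viscosity law and its limits", {
  expect_equal(wall_viscosity(0.0075), 150 / 1.5 + 600)  # 700 g/s
  expect_equal(wall_viscosity(10), 600, tolerance = 1e-3) # large-radius limit
  expect_equal(wall_viscosity(0.001, b1 = 0), 600)        # constant limit
  rd <- seq(5e-4, 0.02, length.out = 30)
  expect_true(all(wall_viscosity(rd) > 600))              # Gamma > b0 for b1 > 0
})

test_that("wave speed decreases with radius at fixed wall stiffness", {
  rd <- seq(0.001, 0.02, length.out = 40)
  cd <- wave_speed(400, rd, 1060)   # c_d proportional to 1/sqrt(Rd)
  expect_true(all(diff(cd) < 0))
  ## and through the radius-dependent law with k1 > 0, k2 < 0 the speed
  ## still falls monotonically over the arterial range
  cd2 <- wave_speed(wall_stiffness(rd, 2e5, -500, 5e4), rd)
  expect_true(all(diff(cd2) < 0))
})

test_that("network validation rejects malformed configs", {
  seg <- tibble::tibble(id = c("a", "b", "c"), length = 0.1, r_in = 0.01,
                        r_out = 0.009, k1 = 0, k2 = 0, k3 = 1e5, b0 = 0, b1 = 0)
  jn <- tibble::tibble(parent = "a", daughter = c("b", "c"))
  out <- tibble::tibble(segment = c("b", "c"), R1 = 1e8, R2 = 1e8, C = 1e-9,
                        P_out = 0)
  sites <- tibble::tibble(site = "root", segment = "a", fraction = 0)
  expect_s3_class(pw_network(seg, jn, out, "a", sites), "pw_network")

  expect_error(pw_network(seg[, -2], jn, out, "a", sites), "missing field")
  jn_bad <- tibble::tibble(parent = "a", daughter = c("b", "zz"))
  expect_error(pw_network(seg, jn_bad, out, "a", sites), "unknown segment")
  ## daughter removed -> disconnected segment
  expect_error(pw_network(seg, jn[1, ], out, "a", sites), "not connected|outlet")
  ## terminal without an outlet
  expect_error(pw_network(seg, jn, out[1, ], "a", sites), "windkessel outlet")
  ## cycle back into the inlet
  jn_cyc <- dplyr::bind_rows(jn, tibble::tibble(parent = "b", daughter = "a"))
  expect_error(pw_network(seg, jn_cyc, out, "a", sites), "daughter")
})

test_that("bundled 7-segment fixture loads and round-trips through save_network", {
  path <- system.file("extdata", "network_7seg.json", package = "pulsesim")
  net <- load_network(path)
  expect_equal(nrow(net$segments), 7)
  expect_equal(length(unique(net$junctions$parent)), 3)
  expect_equal(nrow(net$outlets), 4)

  tmp <- tempfile(fileext = ".json")
  save_network(net, tmp)
  net2 <- load_network(tmp)
  expect_equal(net2$segments$length, net$segments$length)
  expect_equal(net2$segments$r_in, net$segments$r_in)
  expect_equal(net2$outlets$R1, net$outlets$R1)
  expect_equal(sort(net2$junctions$daughter), sort(net$junctions$daughter))
  expect_equal(net2$sites$fraction, net$sites$fraction)
})

test_that("fixture generators produce the documented networks", {
  tiny <- make_fixture_network("tiny")
  expect_equal(nrow(tiny$segments), 3)
  expect_equal(length(unique(tiny$junctions$parent)), 1)
  expect_equal(nrow(tiny$outlets), 2)

  red <- make_fixture_network("reduced")
  expect_true(all(c("aortic_root", "carotid", "brachial", "radial", "femoral",
                    "finger", "iliac_bifurcation") %in% red$sites$site))
  expect_true("windkessel" %in% red$sites$ppg)
  expect_s3_class(red, "pw_network")  # construction implies validation
  ## calibrated wall law reproduces the aging targets along the paths
  fit <- attr(red, "stiffness_fit")
  expect_lt(fit$residual, 0.1)
})
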