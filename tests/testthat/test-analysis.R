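## constructed single-cycle waves with known features
gauss <- function(t, mu, sig) exp(-((t - mu) / sig)^2)

two_bump_wave <- function(a1 = 1, a2 = 0.8, t1 = 0.12, t2 = 0.3,
                          dbp = 80, fs = 500, period = 0.9) {
  n <- round(period * fs)
  t <- (seq_len(n) - 1L) / fs
  y <- dbp + 30 * (a1 * gauss(t, t1, 0.035) + a2 * gauss(t, t2, 0.05))
  waveform(t, y, "P")
}

test_that("pressure statistics match closed forms", {
  t <- seq(0, 0.998, by = 0.002)
  w <- waveform(t, rep(90, length(t)) + 0 * t, "P")
  s <- pressure_stats(w)
  expect_equal(unlist(s), c(sbp = 90, dbp = 90, map = 90, pp = 0))

  ## two full sine cycles: extrema and mean are exact
  t2 <- seq(0, 2 - 0.002, by = 0.002)
  w2 <- waveform(t2, 100 + 20 * sin(2 * pi * t2), "P")
  s2 <- pressure_stats(w2)
  expect_equal(s2$sbp, 120, tolerance = 1e-4)
  expect_equal(s2$dbp, 80, tolerance = 1e-4)
  expect_equal(s2$map, 100, tolerance = 1e-6)
  expect_equal(s2$pp, 40, tolerance = 1e-4)
})

test_that("pulse pressure amplification is the brachial/aortic PP ratio", {
  w <- two_bump_wave()
  expect_equal(pp_amplification(w, w), 1)
  a <- waveform(w$t, 80 + (w$y - 80), "P")
  b <- waveform(w$t, 80 + 1.6 * (w$y - 80), "P")
  expect_equal(pp_amplification(a, b), 1.6, tolerance = 1e-12)
  flat <- waveform(w$t, rep(80, nrow(w)), "P")
  expect_error(pp_amplification(flat, w), "undefined")
})

test_that("fiducial detection finds constructed P1/P2 and orders points", {
  ## C-type: early peak dominant; A-type: late peak dominant
  for (amps in list(c(1, 0.75), c(0.8, 1))) {
    w <- two_bump_wave(amps[1], amps[2])
    fid <- find_fiducials(w, "pressure")
    ## oracle: the two prominent interior local maxima of the constructed
    ## signal (ignore flat-diastole grid artefacts)
    y <- w$y
    locmax <- which(diff(sign(diff(y))) < 0) + 1L
    locmax <- locmax[y[locmax] > min(y) + 3]
    expect_length(locmax, 2)
    p1 <- fid[fid$point == "p1", ]
    p2 <- fid[fid$point == "p2", ]
    expect_equal(p1$t, w$t[locmax[1]], tolerance = 2 / 500)
    expect_equal(p2$t, w$t[locmax[2]], tolerance = 2 / 500)
    if (amps[2] > amps[1]) expect_gt(p2$y, p1$y) else expect_lt(p2$y, p1$y)
    ## ordering invariant: foot <= max slope <= systolic peak
    tf <- fid$t[fid$point == "foot"]
    expect_lte(tf, fid$t[fid$point == "max_slope"])
    expect_lte(fid$t[fid$point == "max_slope"], fid$t[fid$point == "sys_peak"])
  }
})

test_that("detectors never fabricate a diastolic peak", {
  ## smooth rise then featureless exponential decay
  fs <- 500
  t <- (0:449) / fs
  y <- 80 + 40 * ifelse(t < 0.1, 0.5 * (1 - cos(pi * t / 0.1)),
                        exp(-(t - 0.1) / 0.25))
  fid <- find_fiducials(waveform(t, y, "P"), "pressure")
  expect_true(is.na(fid$y[fid$point == "dia_peak"]))
  fid_ppg <- find_fiducials(waveform(t, (y - 80) / 40, "PPG"), "ppg")
  expect_true(is.na(fid_ppg$y[fid_ppg$point == "dia_peak"]))
  flat <- waveform(t, rep(1, length(t)), "P")
  expect_error(find_fiducials(flat, "pressure"), "degenerate|flat")
})

test_that("fiducial times are shift-equivariant and amplitudes affine", {
  w <- two_bump_wave()
  fid <- find_fiducials(w, "pressure")
  k <- 25L  # rotate right: every feature arrives k samples later
  y_shift <- c(w$y[(nrow(w) - k + 1):nrow(w)], w$y[1:(nrow(w) - k)])
  ws <- waveform(w$t, y_shift, "P")
  fid_s <- find_fiducials(ws, "pressure")
  dt <- w$t[2] - w$t[1]
  for (pt in c("p1", "p2", "sys_peak", "max_slope")) {
    expect_equal(fid_s$t[fid_s$point == pt], fid$t[fid$point == pt] + k * dt,
                 tolerance = 2 * dt)
    expect_equal(fid_s$y[fid_s$point == pt], fid$y[fid$point == pt],
                 tolerance = 1e-6)
  }
  ## positive affine rescaling: AIx unchanged, BP stats transform affinely
  wa <- waveform(w$t, 2 * w$y + 10, "P")
  fid_a <- find_fiducials(wa, "pressure")
  aug <- augmentation_indexes(fid, pressure_stats(w))
  aug_a <- augmentation_indexes(fid_a, pressure_stats(wa))
  expect_equal(aug_a$aix, aug$aix, tolerance = 1e-9)
  expect_equal(pressure_stats(wa)$map, 2 * pressure_stats(w)$map + 10)
})

test_that("augmentation indexes follow their definitions", {
  fid <- tibble::tibble(point = c("foot", "p1", "p2"),
                        t = c(0.02, 0.1, 0.25), y = c(80, 100, 110))
  stats <- tibble::tibble(sbp = 110, dbp = 80, map = 95, pp = 30)
  aug <- augmentation_indexes(fid, stats)
  expect_equal(aug$ap, 10)
  expect_equal(aug$aix, 100 * 10 / 30)
  expect_equal(aug$tr, 80)
  ## equal shoulders: zero augmentation
  fid0 <- fid; fid0$y[3] <- 100
  expect_equal(augmentation_indexes(fid0, stats)$ap, 0)
  ## missing P1: indexes reported missing
  fid_na <- fid; fid_na$t[2] <- NA; fid_na$y[2] <- NA
  expect_true(is.na(augmentation_indexes(fid_na, stats)$aix))
})

test_that("PPG stiffness indexes follow their definitions", {
  fid <- structure(
    tibble::tibble(point = c("foot", "sys_peak", "dia_peak",
                             "a", "b", "c", "d", "e"),
                   t = c(0, 0.15, 0.40, 0.05, 0.08, 0.1, 0.12, 0.14),
                   y = c(0, 1, 0.5, 1, -1, 0, 0, 0)),
    foot_y = 0)
  ix <- ppg_stiffness_indexes(fid, height = 1.75)
  expect_equal(ix$ri, 0.5)
  expect_equal(ix$si, 1.75 / 0.25)  # 7 m/s
  expect_equal(ix$agi_mod, -1)      # (b - c - d - e)/a with b = -a
  fid$t[fid$point == "dia_peak"] <- NA
  fid$y[fid$point == "dia_peak"] <- NA
  ix2 <- ppg_stiffness_indexes(fid)
  expect_true(is.na(ix2$ri) && is.na(ix2$si))
})

test_that("foot-to-foot transit time recovers a pure shift", {
  w <- two_bump_wave()
  n <- nrow(w); k <- 20L  # 40 ms at 500 Hz
  y2 <- c(w$y[(n - k + 1):n], w$y[1:(n - k)])
  w2 <- waveform(w$t, y2, "P")
  ptt <- foot_to_foot_ptt(w, w2)
  expect_equal(ptt, 40, tolerance = 2)
  expect_equal(pwv(ptt, 0.4), 0.4 / 0.040, tolerance = 0.5)
  expect_error(pwv(-1, 0.4), "> 0")
})

test_that("transit times are additive along one measurement path", {
  pws <- baseline_sim(25)
  root_fem <- foot_to_foot_ptt(get_wave(pws, "aortic_root", "P"),
                               get_wave(pws, "femoral", "P"))
  fem_ankle <- foot_to_foot_ptt(get_wave(pws, "femoral", "P"),
                                get_wave(pws, "ankle", "P"))
  root_ankle <- foot_to_foot_ptt(get_wave(pws, "aortic_root", "P"),
                                 get_wave(pws, "ankle", "P"))
  expect_equal(root_fem + fem_ankle, root_ankle, tolerance = 2)
})

test_that("flow-derived indexes integrate volumes and slopes correctly", {
  q <- generate_inflow(list(hr = 73, sv = 66.8, lvet = 282, pft = 79,
                            rfv = 0.73))
  t <- q$t
  p <- waveform(t, 80 + 30 * gauss(t, 0.18, 0.1), "P")
  ix <- flow_indexes(q, p)
  expect_equal(ix$sv, 66.8, tolerance = 0.4)
  expect_equal(ix$co, 73 * 66.8 / 1000, tolerance = 0.03)
  ## maximal slope of a Gaussian bump: 30 * sqrt(2)/ (0.1 e^{1/2}) / ... use
  ## numerical oracle from the constructed signal
  slope_true <- max(diff(p$y) / diff(p$t))
  expect_equal(ix$dpdt_max, slope_true, tolerance = slope_true * 0.05)
  ## cumulative volume at the end of the cycle equals SV
  cum <- cumsum(q$y) * (t[2] - t[1])
  expect_equal(cum[length(cum)] * 1e6, 66.8, tolerance = 0.1)
})

test_that("full subject report satisfies its internal identities", {
  ix <- baseline_index(25)
  expect_lte(ix$aortic_dbp, ix$aortic_map)
  expect_lte(ix$aortic_map, ix$aortic_sbp)
  expect_equal(ix$aortic_pp, ix$aortic_sbp - ix$aortic_dbp)
  expect_equal(ix$pp_amp, ix$brachial_pp / ix$aortic_pp)
  expect_equal(ix$aix, 100 * ix$ap / ix$carotid_pp, tolerance = 1e-6)
  expect_true(ix$plausible)
})
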