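## Pulse wave analysis: fiducial-point detection on pressure and PPG waves
## and their derivatives, and computation of the clinically used indexes.

## Savitzky-Golay derivative of a periodic single-cycle signal (circular
## padding avoids end transients); window scaled to the sampling rate
sg_derivative <- function(y, dt, order = 1L, fs = 1 / dt) {
  n_win <- max(5L, round(9 * fs / 500))
  if (n_win %% 2L == 0L) n_win <- n_win + 1L
  n_win <- min(n_win, if (length(y) %% 2L == 0L) length(y) - 1L else length(y))
  pad <- n_win
  yp <- c(utils::tail(y, pad), y, utils::head(y, pad))
  d <- signal::sgolayfilt(yp, p = 3, n = n_win, m = order)
  d[(pad + 1L):(pad + length(y))] / dt^order
}

local_maxima <- function(y, idx = seq_along(y)) {
  i <- idx[idx > 1L & idx < length(y)]
  i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
}

local_minima <- function(y, idx = seq_along(y)) {
  i <- idx[idx > 1L & idx < length(y)]
  i[y[i] < y[i - 1L] & y[i] <= y[i + 1L]]
}

## foot of a wave by intersecting tangents: horizontal tangent at the
## pre-upstroke minimum crossed with the tangent at the point of steepest
## systolic upstroke
wave_foot <- function(wave, d1 = NULL) {
  y <- wave$y
  dt <- wave_dt(wave)
  if (is.null(d1)) d1 <- sg_derivative(y, dt, 1L)
  ims <- which.max(d1)
  if (d1[ims] <= 0) abort(sprintf("foot undetectable on %s wave at site `%s`",
                                  attr(wave, "kind") %||% "?",
                                  attr(wave, "site") %||% "?"))
  before <- if (ims > 1L) min(y[1:ims]) else y[1L]
  y_min <- min(before, min(y))
  t_foot <- wave$t[ims] - (y[ims] - y_min) / d1[ims]
  list(t = t_foot, y = y_min, i_ms = ims)
}

#' Locate fiducial points on a pressure or PPG pulse wave
#'
#' Analyses the wave and its first and second derivatives
#' (Savitzky-Golay differentiation) to locate the foot (intersecting
#' tangents), point of steepest upstroke, systolic peak, dicrotic notch
#' and diastolic peak, plus the early (P1) and late (P2) systolic
#' shoulders on pressure waves and the second-derivative a-e waves on PPG
#' waves. Points that are genuinely absent from the wave shape (e.g. no
#' diastolic peak in stiff, elderly-type waves) are reported as missing,
#' never fabricated.
#'
#' @param wave A single-cycle [waveform()] with at least 50 samples.
#' @param kind `"pressure"` or `"ppg"`.
#' @return Tibble of class `pw_fiducials` with columns `point`, `t` (s),
#'   `y` (wave units; derivative units for a-e).
#' @export
find_fiducials <- function(wave, kind = c("pressure", "ppg")) {
  kind <- match.arg(kind)
  y <- wave$y
  n <- length(y)
  if (n < 50L) abort("fiducial detection needs at least 50 samples per cycle")
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1)) {
    abort("degenerate signal: flat wave")
  }
  dt <- wave_dt(wave)
  d1 <- sg_derivative(y, dt, 1L)
  d2 <- sg_derivative(y, dt, 2L)

  foot <- wave_foot(wave, d1)
  ims <- foot$i_ms
  ipk <- which.max(y)

  pt <- function(point, i) tibble(point = point, t = wave$t[i], y = y[i])
  na_pt <- function(point) tibble(point = point, t = NA_real_, y = NA_real_)

  ## dicrotic notch after index `from`: first local minimum of the wave
  ## within the plausible end-systolic window; fall back to the most
  ## prominent late-systolic inflection (local maximum of d2)
  find_notch <- function(from) {
    win_hi <- min(n - 1L, from + round(0.4 * n))
    if (win_hi <= from + 2L) return(NA_integer_)
    cand <- local_minima(y, (from + 2L):win_hi)
    if (length(cand)) return(cand[1L])
    cand2 <- local_maxima(d2, (from + 3L):win_hi)
    if (length(cand2)) cand2[which.max(d2[cand2])] else NA_integer_
  }
  ## diastolic peak after the notch; when the diastolic wave does not
  ## reverse the decay, fall back to the slope shoulder (an interior local
  ## maximum of d1 -- absent from a featureless monotone decay, so nothing
  ## is fabricated)
  find_dia <- function(notch_i) {
    if (is.na(notch_i)) return(NA_integer_)
    dia_win <- (notch_i + 1L):min(n - 1L, notch_i + round(0.45 * n))
    if (length(dia_win) < 3L) return(NA_integer_)
    cand <- local_maxima(y, dia_win)
    if (length(cand)) return(cand[which.max(y[cand])])
    cand <- local_maxima(d1, dia_win)
    cand <- cand[d1[cand] < 0]
    if (length(cand)) cand[which.max(d1[cand])] else NA_integer_
  }

  rows <- list(
    tibble(point = "foot", t = foot$t, y = foot$y),
    pt("max_slope", ims),
    pt("sys_peak", ipk)
  )

  if (kind == "pressure") {
    ## P1 / P2: early and late systolic peaks when both are distinct local
    ## maxima; otherwise shoulder search on the single smooth peak
    pk_hi <- min(n - 1L, ims + round(0.45 * n))
    peaks <- local_maxima(y, (ims + 1L):pk_hi)
    peaks <- peaks[y[peaks] > foot$y + 0.25 * (y[ipk] - foot$y)]
    if (length(peaks) >= 2L) {
      p1_i <- peaks[1L]
      p2_i <- peaks[2L]
      notch_i <- find_notch(p2_i)
    } else {
      notch_i <- find_notch(ipk)
      sys_end <- if (!is.na(notch_i)) notch_i else min(n, ipk + round(0.3 * n))
      ## single smooth systolic peak: a slope dip on the rising limb is the
      ## early shoulder (A-type); a slope bulge on the falling limb is the
      ## late shoulder (C-type)
      p1_i <- p2_i <- ipk
      rise <- if (ipk - ims > 2L) local_minima(d1, (ims + 1L):(ipk - 1L)) else integer(0)
      rise <- rise[d1[rise] > 0]
      if (length(rise)) {
        p1_i <- rise[which.min(d1[rise])]
      } else if (sys_end > ipk + 2L) {
        fall <- local_maxima(d1, (ipk + 2L):(sys_end - 1L))
        fall <- fall[d1[fall] < 0]
        if (length(fall)) p2_i <- fall[which.max(d1[fall])]
      }
    }
    dia_i <- find_dia(notch_i)
    rows <- c(rows, list(
      if (!is.na(notch_i)) pt("dicrotic_notch", notch_i) else na_pt("dicrotic_notch"),
      if (!is.na(dia_i)) pt("dia_peak", dia_i) else na_pt("dia_peak"),
      pt("p1", p1_i), pt("p2", p2_i)))
  } else {
    notch_i <- find_notch(ipk)
    dia_i <- find_dia(notch_i)
    rows <- c(rows, list(
      if (!is.na(notch_i)) pt("dicrotic_notch", notch_i) else na_pt("dicrotic_notch"),
      if (!is.na(dia_i)) pt("dia_peak", dia_i) else na_pt("dia_peak")))
    ## a-e waves of the second derivative: a is the dominant early
    ## acceleration maximum (up to the systolic peak), b the deceleration
    ## minimum after it, then alternating extrema up to late systole
    start <- max(2L, min(ims, ipk) - round(0.05 * n))
    stop_i <- min(n - 1L, start + round(0.6 * n))
    abcde <- rep(NA_integer_, 5L)
    a_hi <- max(start + 2L, ipk)
    a_reg <- start:min(a_hi, n - 1L)
    abcde[1L] <- a_reg[which.max(d2[a_reg])]
    b_reg <- (abcde[1L] + 1L):stop_i
    abcde[2L] <- b_reg[which.min(d2[b_reg])]
    i_from <- abcde[2L]
    for (k in 3:5) {
      finder <- if (k %% 2L == 0L) local_minima else local_maxima
      cand <- finder(d2, (i_from + 1L):stop_i)
      if (!length(cand)) break
      abcde[k] <- cand[1L]
      i_from <- cand[1L]
    }
    lab <- c("a", "b", "c", "d", "e")
    for (k in 1:5) {
      rows <- c(rows, list(
        if (!is.na(abcde[k])) {
          tibble(point = lab[k], t = wave$t[abcde[k]], y = d2[abcde[k]])
        } else na_pt(lab[k])
      ))
    }
  }
  out <- bind_rows(rows)
  attr(out, "kind") <- kind
  attr(out, "foot_y") <- foot$y
  attr(out, "wave_range") <- range(y)
  class(out) <- c("pw_fiducials", class(out))
  out
}

fid_val <- function(fid, point, what = "y") {
  i <- match(point, fid$point)
  if (is.na(i)) NA_real_ else fid[[what]][i]
}

#' Blood pressure statistics of a pressure wave
#'
#' @param wave Single-cycle pressure [waveform()] (any pressure unit;
#'   output in the same unit).
#' @return One-row tibble with `sbp` (max), `dbp` (min), `map` (time
#'   average) and `pp`.
#' @export
pressure_stats <- function(wave) {
  tibble(sbp = max(wave$y), dbp = min(wave$y), map = mean(wave$y),
         pp = max(wave$y) - min(wave$y))
}

#' Pulse pressure amplification
#'
#' Ratio of brachial to aortic pulse pressure.
#'
#' @param aortic,brachial Pressure waveforms from the same subject/cycle.
#' @return PP_amp (dimensionless).
#' @export
pp_amplification <- function(aortic, brachial) {
  ppa <- diff(range(aortic$y))
  if (ppa <= 0) abort("undefined: aortic pulse pressure is zero")
  diff(range(brachial$y)) / ppa
}

#' Augmentation pressure, augmentation index and time to reflected wave
#'
#' `AP = P(P2) - P(P1)`, `AIx = 100 AP / PP`, `Tr = t(P1) - t(foot)`,
#' computed from the fiducials of a central pressure wave.
#'
#' @param fid `pw_fiducials` of a pressure wave.
#' @param stats Output of [pressure_stats()] for the same wave (for PP).
#' @return One-row tibble with `ap` (wave units), `aix` (%), `tr` (ms);
#'   NA when P1/P2 are missing.
#' @export
augmentation_indexes <- function(fid, stats) {
  p1 <- fid_val(fid, "p1"); p2 <- fid_val(fid, "p2")
  if (is.na(p1) || is.na(p2)) {
    return(tibble(ap = NA_real_, aix = NA_real_, tr = NA_real_))
  }
  ap <- p2 - p1
  tibble(ap = ap,
         aix = if (stats$pp > 0) 100 * ap / stats$pp else NA_real_,
         tr = 1000 * (fid_val(fid, "p1", "t") - fid_val(fid, "foot", "t")))
}

#' PPG-derived stiffness indexes
#'
#' Reflection index `RI` (diastolic over systolic peak amplitude above the
#' foot), stiffness index `SI = height / (t_dia - t_sys)` and the modified
#' aging index `AGI_mod = (b - c - d - e)/a` from the second-derivative
#' wave amplitudes.
#'
#' @param fid `pw_fiducials` of a digital PPG wave.
#' @param height Subject height, m. The model carries no height; the
#'   default 1.75 m is used for all subjects so SI is proportional to the
#'   reciprocal peak-to-peak delay.
#' @return One-row tibble with `ri`, `si` (m/s), `agi_mod`; NA where the
#'   needed fiducials are missing.
#' @export
ppg_stiffness_indexes <- function(fid, height = 1.75) {
  base <- attr(fid, "foot_y") %||% 0
  y_sys <- fid_val(fid, "sys_peak") - base
  y_dia <- fid_val(fid, "dia_peak") - base
  t_sys <- fid_val(fid, "sys_peak", "t")
  t_dia <- fid_val(fid, "dia_peak", "t")
  ri <- if (is.na(y_dia) || y_sys <= 0) NA_real_ else y_dia / y_sys
  si <- if (is.na(t_dia) || t_dia <= t_sys) NA_real_ else height / (t_dia - t_sys)
  a <- fid_val(fid, "a"); b <- fid_val(fid, "b")
  cc <- fid_val(fid, "c"); d <- fid_val(fid, "d"); e <- fid_val(fid, "e")
  agi <- if (is.na(a) || a == 0 || is.na(b)) {
    NA_real_
  } else {
    (b - sum(cc, d, e, na.rm = TRUE)) / a
  }
  tibble(ri = ri, si = si, agi_mod = agi)
}

#' Foot-to-foot pulse transit time and pulse wave velocity
#'
#' The foot of each wave is located by intersecting tangents; the transit
#' time is the difference of foot times (wrapped into half a cycle).
#'
#' @param wave_a,wave_b Proximal and distal single-cycle waveforms on the
#'   same time base.
#' @return PTT in ms.
#' @export
foot_to_foot_ptt <- function(wave_a, wave_b) {
  fa <- wave_foot(wave_a)
  fb <- wave_foot(wave_b)
  period <- nrow(wave_a) * wave_dt(wave_a)
  ptt <- fb$t - fa$t
  if (ptt < -period / 2) ptt <- ptt + period
  ptt * 1000
}

#' @rdname foot_to_foot_ptt
#' @param ptt Pulse transit time, ms.
#' @param path_length Arterial path length, m.
#' @return `pwv()`: velocity in m/s.
#' @export
pwv <- function(ptt, path_length) {
  if (any(ptt <= 0)) abort("PTT must be > 0 to form a PWV")
  path_length / (ptt / 1000)
}

## distance from the aortic root to a named measurement site, m
site_distance <- function(network, site) {
  s <- network$sites[network$sites$site == site, ]
  if (!nrow(s)) abort(sprintf("unknown site `%s`", site))
  path <- path_to_segment(network, s$segment)
  segl <- network$segments$length[match(path, network$segments$id)]
  sum(segl[-length(segl)]) + s$fraction * segl[length(segl)]
}

#' Hemodynamic indexes from aortic-root flow and pressure
#'
#' Cardiac features via [measure_inflow_features()], the maximal pressure
#' upstroke slope, and the cumulative flow volumes and velocities at the
#' P1 and P2 times of the root pressure wave.
#'
#' @param q Aortic-root flow [waveform()] (m^3/s).
#' @param p Aortic-root pressure [waveform()] in mmHg.
#' @return One-row tibble.
#' @export
flow_indexes <- function(q, p) {
  feats <- measure_inflow_features(q)
  dt <- wave_dt(p)
  d1 <- sg_derivative(p$y, dt, 1L)
  fid <- find_fiducials(p, "pressure")
  cumv <- cumsum(q$y) * wave_dt(q)
  vol_at <- function(tx) {
    if (is.na(tx)) return(NA_real_)
    approx(q$t, cumv, xout = tx, rule = 2)$y * 1e6
  }
  u_at <- function(tx) {
    if (is.na(tx)) return(NA_real_)
    approx(q$t, q$y, xout = tx, rule = 2)$y
  }
  t1 <- fid_val(fid, "p1", "t"); t2 <- fid_val(fid, "p2", "t")
  bind_cols(feats,
            tibble(dpdt_max = max(d1),
                   vol_p1 = vol_at(t1), vol_p2 = vol_at(t2),
                   q_p1 = u_at(t1), q_p2 = u_at(t2)))
}

#' Full index report for one simulated subject
#'
#' Extracts the complete set of pulse wave indexes from a simulated pulse
#' wave set: aortic and brachial BP statistics, PP amplification, carotid
#' augmentation indexes, digital PPG stiffness indexes, foot-to-foot PTTs
#' and PWVs along the standard measurement paths, cardiac features from
#' the root flow wave, extremes of Q/U/A at the root, and the BP
#' plausibility flag.
#'
#' @param pws A `pw_pulse_set` from [simulate_virtual_subject()] (carries
#'   the subject config and network as attributes) or
#'   [simulate_subject()] (pass `network`/`config` explicitly).
#' @param network The network simulated (for path lengths).
#' @param config Optional subject config row (offsets and prescribed
#'   values are copied into the report; age enables the plausibility
#'   check).
#' @param height Subject height for SI, m.
#' @return One-row tibble (the subject's row of the database index).
#' @export
analyze_subject <- function(pws, network = attr(pws, "network"),
                            config = attr(pws, "config"), height = 1.75) {
  p_root <- get_wave(pws, "aortic_root", "P")
  p_root_mmhg <- waveform(p_root$t, pa_to_mmhg(p_root$y), "P", "aortic_root")
  q_root <- get_wave(pws, "aortic_root", "Q")

  stat_site <- function(site) {
    w <- get_wave(pws, site, "P")
    pressure_stats(waveform(w$t, pa_to_mmhg(w$y), "P", site))
  }
  sa <- stat_site("aortic_root")
  sb <- stat_site("brachial")

  p_car <- get_wave(pws, "carotid", "P")
  p_car <- waveform(p_car$t, pa_to_mmhg(p_car$y), "P", "carotid")
  fid_car <- find_fiducials(p_car, "pressure")
  aug <- augmentation_indexes(fid_car, pressure_stats(p_car))

  ppg_fin <- get_wave(pws, "finger", "PPG")
  fid_ppg <- find_fiducials(ppg_fin, "ppg")
  ppg_ix <- ppg_stiffness_indexes(fid_ppg, height = height)

  ptt_pair <- function(a, b) {
    foot_to_foot_ptt(get_wave(pws, a, "P"), get_wave(pws, b, "P"))
  }
  dist <- function(s) site_distance(network, s)
  ptt_aortic <- ptt_pair("aortic_root", "iliac_bifurcation")
  ptt_cf <- ptt_pair("carotid", "femoral")
  ptt_br <- ptt_pair("brachial", "radial")
  ptt_fa <- ptt_pair("femoral", "ankle")
  len_aortic <- dist("iliac_bifurcation") - dist("aortic_root")
  len_cf <- dist("femoral") - dist("carotid")
  len_br <- dist("radial") - dist("brachial")
  len_fa <- dist("ankle") - dist("femoral")

  flow <- flow_indexes(q_root, p_root_mmhg)
  u_root <- get_wave(pws, "aortic_root", "U")
  a_root <- get_wave(pws, "aortic_root", "A")

  out <- bind_cols(
    tibble(
      aortic_sbp = sa$sbp, aortic_dbp = sa$dbp, aortic_map = sa$map,
      aortic_pp = sa$pp,
      brachial_sbp = sb$sbp, brachial_dbp = sb$dbp, brachial_map = sb$map,
      brachial_pp = sb$pp,
      pp_amp = sb$pp / sa$pp,
      carotid_pp = max(p_car$y) - min(p_car$y),
      ap = aug$ap, aix = aug$aix, tr = aug$tr,
      ri = ppg_ix$ri, si = ppg_ix$si, agi_mod = ppg_ix$agi_mod,
      ptt_aortic = ptt_aortic, ptt_cf = ptt_cf, ptt_br = ptt_br,
      ptt_fa = ptt_fa,
      pwv_aortic_ff = pwv(ptt_aortic, len_aortic),
      pwv_cf_ff = pwv(ptt_cf, len_cf),
      pwv_br_ff = pwv(ptt_br, len_br),
      pwv_fa_ff = pwv(ptt_fa, len_fa),
      q_max = max(q_root$y), q_min = min(q_root$y), q_mean = mean(q_root$y),
      u_max = max(u_root$y), u_min = min(u_root$y),
      a_max = max(a_root$y), a_min = min(a_root$y)
    ),
    flow
  )
  if (!is.null(config)) {
    pl <- plausibility_filter(
      list(aortic_sbp = sa$sbp, aortic_dbp = sa$dbp, aortic_map = sa$map,
           aortic_pp = sa$pp, brachial_sbp = sb$sbp, brachial_dbp = sb$dbp,
           brachial_map = sb$map, brachial_pp = sb$pp,
           pp_amp = out$pp_amp),
      age = config$age)
    out <- bind_cols(
      config |> rename(hr_in = "hr", sv_in = "sv", lvet_in = "lvet",
                       pft_in = "pft", rfv_in = "rfv", map_in = "map"),
      out,
      tibble(plausible = pl$plausible,
             n_violations = length(pl$violations))
    )
  }
  out
}
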