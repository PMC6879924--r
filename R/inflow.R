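## Aortic-root inflow: construct the periodic volumetric flow waveform Q(t)
## from cardiac parameters, and measure cardiac features back from any flow
## waveform.

#' Left ventricular ejection time from heart rate and stroke volume
#'
#' Empirical regression `LVET = 244 - 0.926 HR + 1.08 SV` (ms, with HR in
#' beats/min and SV in ml).
#'
#' @param hr Heart rate, beats/min.
#' @param sv Stroke volume, ml.
#' @return LVET in ms.
#' @export
#' @examples
#' lvet_from_hr_sv(60, 80)
lvet_from_hr_sv <- function(hr, sv) {
  if (any(hr < 30) || any(hr > 200) || any(sv < 20) || any(sv > 150)) {
    warn("lvet_from_hr_sv(): HR or SV outside the physiological range of the regression")
  }
  244 - 0.926 * hr + 1.08 * sv
}

#' Archetype aortic flow waveform
#'
#' A piecewise-smooth analytic single-cycle flow shape: a raised-cosine
#' systolic lobe peaking early in systole, a brief reverse-flow lobe at
#' end-systole, and zero flow in diastole. Used as the default template for
#' [generate_inflow()], which time-warps and rescales it to meet a
#' subject's cardiac parameters; the shape characteristics not pinned by
#' those parameters are held fixed across subjects.
#'
#' @param pft,lvet,t_rev Peak-flow time, ejection time and reverse-lobe
#'   duration of the archetype, s.
#' @param period Cycle duration, s.
#' @param fs Sampling rate, Hz.
#' @return A flow [waveform()].
#' @export
inflow_template <- function(pft = 0.079, lvet = 0.282, t_rev = 0.06,
                            period = 0.82, fs = 1000) {
  n <- round(period * fs)
  t <- (seq_len(n) - 1L) / fs
  y <- numeric(n)
  ris <- t < pft
  y[ris] <- 0.5 * (1 - cos(pi * t[ris] / pft))
  fal <- t >= pft & t < lvet
  y[fal] <- 0.5 * (1 + cos(pi * (t[fal] - pft) / (lvet - pft)))
  rev <- t >= lvet & t < (lvet + t_rev)
  y[rev] <- -0.25 * sin(pi * (t[rev] - lvet) / t_rev)
  waveform(t, y, kind = "Q", site = "aortic_root")
}

## characteristic times of a single-cycle flow template: peak, end of the
## systolic forward lobe, end of the reverse lobe
template_times <- function(tmpl) {
  ipk <- which.max(tmpl$y)
  tol <- 1e-9 * max(tmpl$y)
  after <- which(tmpl$y[(ipk + 1L):nrow(tmpl)] <= tol)
  if (!length(after)) abort("template has no end-systolic zero crossing")
  iz <- ipk + after[1L]
  irev <- iz
  while (irev < nrow(tmpl) && tmpl$y[irev + 1L] < -tol) irev <- irev + 1L
  list(t_peak = tmpl$t[ipk], t_zero = tmpl$t[iz], t_rev_end = tmpl$t[irev],
       has_reverse = any(tmpl$y < -tol))
}

#' Generate an aortic-root inflow waveform
#'
#' Time-warps the template so the flow peak falls at `pft` and the
#' end-systolic zero crossing at `lvet`, scales the reverse lobe so its
#' volume equals `rfv`, and scales the forward lobe so the net integral
#' over the cycle equals `sv` (forward volume minus reverse volume).
#'
#' @param params List or one-row tibble with `hr` (beats/min), `sv` (ml),
#'   `lvet` (ms), `pft` (ms), `rfv` (ml).
#' @param template Single-cycle template flow shape; default
#'   [inflow_template()].
#' @param fs Nominal sampling rate, Hz. The actual grid spacing is
#'   `T / round(T * fs)` so a whole number of samples spans the cycle.
#' @return A flow [waveform()] in m^3/s over one cycle `[0, T)`.
#' @export
#' @examples
#' q <- generate_inflow(list(hr = 73, sv = 66.8, lvet = 282, pft = 79, rfv = 0.73))
#' measure_inflow_features(q)
generate_inflow <- function(params, template = inflow_template(), fs = 500) {
  p <- as.list(params)
  for (f in c("hr", "sv", "lvet", "pft", "rfv")) {
    if (is.null(p[[f]]) || !is.finite(p[[f]])) {
      abort(sprintf("parameter error: missing or non-finite `%s`", f))
    }
  }
  period <- 60 / p$hr
  pft <- p$pft / 1000
  lvet <- p$lvet / 1000
  if (p$sv <= 0) abort("parameter error: `sv` must be > 0")
  if (p$rfv < 0) abort("parameter error: `rfv` must be >= 0")
  if (pft <= 0 || pft >= lvet || lvet >= period) {
    abort("parameter error: need 0 < PFT < LVET < T")
  }
  tt <- template_times(template)
  t_rev <- min((tt$t_rev_end - tt$t_zero) * lvet / tt$t_zero,
               0.8 * (period - lvet))

  n <- round(period * fs)
  dt <- period / n
  t <- (seq_len(n) - 1L) * dt
  ## inverse time warp: subject time -> template time
  u <- rep(NA_real_, n)
  i1 <- t < pft
  u[i1] <- t[i1] * tt$t_peak / pft
  i2 <- t >= pft & t < lvet
  u[i2] <- tt$t_peak + (t[i2] - pft) * (tt$t_zero - tt$t_peak) / (lvet - pft)
  i3 <- t >= lvet & t < lvet + t_rev & t_rev > 0
  if (any(i3)) {
    u[i3] <- tt$t_zero + (t[i3] - lvet) * (tt$t_rev_end - tt$t_zero) / t_rev
  }
  y <- numeric(n)
  ok <- !is.na(u)
  y[ok] <- approx(template$t, template$y, xout = u[ok], rule = 2)$y

  ypos <- pmax(y, 0)
  yneg <- pmin(y, 0)
  sv_si <- p$sv * 1e-6
  rfv_si <- p$rfv * 1e-6
  i_fwd <- sum(ypos) * dt
  i_rev <- -sum(yneg) * dt
  amp_rev <- if (rfv_si > 0 && i_rev > 0) rfv_si / i_rev else 0
  amp_fwd <- (sv_si + if (amp_rev > 0) rfv_si else 0) / i_fwd
  q <- amp_fwd * ypos + amp_rev * yneg
  out <- waveform(t, q, kind = "Q", site = "aortic_root")
  attr(out, "params") <- p
  out
}

#' Measure cardiac features from a flow waveform
#'
#' Inverse of [generate_inflow()]: heart rate from the cycle duration,
#' stroke volume as the net integral, peak flow time as the argmax, LVET as
#' the downward zero crossing ending the systolic forward lobe, and reverse
#' flow volume as the magnitude of the integral over the negative-flow
#' phase.
#'
#' @param q Single-cycle flow [waveform()] in m^3/s over `[0, T)`.
#' @return Tibble with `hr` (beats/min), `sv` (ml), `lvet` (ms),
#'   `pft` (ms), `rfv` (ml), `co` (l/min).
#' @export
measure_inflow_features <- function(q) {
  if (all(abs(q$y) < .Machine$double.eps)) {
    abort("degenerate signal: flow waveform is identically zero")
  }
  dt <- wave_dt(q)
  period <- nrow(q) * dt
  sv_si <- sum(q$y) * dt
  rfv_si <- -sum(pmin(q$y, 0)) * dt
  ipk <- which.max(q$y)
  pft <- q$t[ipk]
  tol <- 1e-9 * max(q$y)
  after <- which(q$y[(ipk + 1L):nrow(q)] <= tol)
  if (!length(after)) abort("degenerate signal: no end of systolic forward flow")
  iz <- ipk + after[1L]
  ## linear interpolation of the zero crossing between samples iz-1 and iz
  y0 <- q$y[iz - 1L]; y1 <- q$y[iz]
  lvet <- if (y0 > tol && y1 < y0) q$t[iz - 1L] + dt * (y0 - 0) / (y0 - y1) else q$t[iz]
  lvet <- min(lvet, q$t[iz])
  hr <- 60 / period
  tibble(hr = hr, sv = sv_si * 1e6, lvet = lvet * 1000, pft = pft * 1000,
         rfv = rfv_si * 1e6, co = hr * sv_si * 1e6 / 1000)
}
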