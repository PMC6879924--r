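## Scripted case-study analyses over a generated virtual-subject database:
## (1) decomposition of pulse pressure amplification into early systolic
## amplification and late systolic augmentation, (2) correlation of
## PPG-derived indexes with aortic stiffness plus one-at-a-time parameter
## sensitivities, (3) in silico assessment of pulse contour cardiac output
## algorithms.

#' Decompose pulse pressure amplification
#'
#' Besides the usual `PP_amp = PP_b / PP_a`, computes the amplification of
#' the early systolic portion, `PP_b / (P1_a - DBP_a)`, and of the fully
#' augmented late systolic portion, `PP_b / (P2_a - DBP_a)`.
#'
#' @param aortic,brachial Single-cycle pressure waveforms (same units).
#' @return One-row tibble with `pp_amp`, `pp_amp_p1`, `pp_amp_p2`.
#' @export
ppamp_decomposition <- function(aortic, brachial) {
  fid <- find_fiducials(aortic, "pressure")
  dbp_a <- min(aortic$y)
  pp_a <- max(aortic$y) - dbp_a
  pp_b <- max(brachial$y) - min(brachial$y)
  p1 <- fid_val(fid, "p1")
  p2 <- fid_val(fid, "p2")
  tibble(
    pp_amp = pp_b / pp_a,
    pp_amp_p1 = if (!is.na(p1) && p1 > dbp_a) pp_b / (p1 - dbp_a) else NA_real_,
    pp_amp_p2 = if (!is.na(p2) && p2 > dbp_a) pp_b / (p2 - dbp_a) else NA_real_
  )
}

#' Relative sensitivity index
#'
#' Percent change of a pulse wave index caused by moving one model input
#' parameter +1 SD from the age-matched baseline while holding everything
#' else at baseline: `I = 100 (index(+1 SD) - index(baseline)) /
#' index(baseline)`.
#'
#' @param db Index table (rows from [analyze_subject()] with `off_*`
#'   columns).
#' @param parameter One of [varied_factors()].
#' @param index_name Column of `db` holding the index.
#' @param age Age of the baseline, years.
#' @return One-row tibble with `index`, `parameter`, `age`, `I`.
#' @export
sensitivity_index <- function(db, parameter, index_name, age) {
  offs <- paste0("off_", varied_factors())
  offs <- intersect(offs, names(db))
  this <- paste0("off_", parameter)
  if (!this %in% names(db)) abort(sprintf("no offset column for `%s`", parameter))
  at_age <- db[db$age == age, ]
  is_base <- rowSums(abs(at_age[offs])) == 0
  is_plus <- at_age[[this]] == 1 &
    rowSums(abs(at_age[setdiff(offs, this)])) == 0
  if (!any(is_base) || !any(is_plus)) {
    abort("database must contain the baseline and the single-parameter +1 SD subject")
  }
  i0 <- at_age[[index_name]][which(is_base)[1L]]
  i1 <- at_age[[index_name]][which(is_plus)[1L]]
  if (!is.finite(i0) || i0 == 0) abort("undefined: baseline index is zero or missing")
  tibble(index = index_name, parameter = parameter, age = age,
         I = 100 * (i1 - i0) / i0)
}

#' Coefficient of determination of an index against aortic PWV
#'
#' R^2 (squared Pearson correlation) between a pulse wave index and the
#' foot-to-foot aortic PWV over the plausible subjects of a database,
#' optionally restricted to one age.
#'
#' @param db Index table.
#' @param index_name Column of `db`.
#' @param ages Optional ages to restrict to (default: all).
#' @param plausible_only Restrict to BP-plausible subjects (default TRUE
#'   when the column is present).
#' @param pwv_col Reference PWV column (foot-to-foot aortic by default).
#' @return R^2.
#' @export
correlate_index_with_pwv <- function(db, index_name, ages = NULL,
                                     plausible_only = TRUE,
                                     pwv_col = "pwv_aortic_ff") {
  d <- db
  if (!is.null(ages)) d <- d[d$age %in% ages, ]
  if (plausible_only && "plausible" %in% names(d)) d <- d[d$plausible, ]
  x <- d[[pwv_col]]
  y <- d[[index_name]]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) abort("need at least 3 subjects with defined index and PWV")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) abort("undefined: zero variance")
  cor(x[ok], y[ok])^2
}

## ---------------------------------------------------------------------------
## Case study 3: pulse contour cardiac output

#' Estimate cardiac output from a radial pressure wave
#'
#' Two pulse-contour algorithms built on the two-element windkessel
#' picture: `"RMS"` assumes CO proportional to the root mean square of the
#' radial pressure wave; `"PP"` assumes CO proportional to pulse pressure
#' over compliance, approximated as `PP / (T (SBP + DBP))`. Both need a
#' calibration constant `k`, normally fixed on the age-matched baseline
#' subject via [co_calibrate()].
#'
#' @param radial_p Single-cycle radial pressure [waveform()] in mmHg.
#' @param algorithm `"RMS"` or `"PP"`.
#' @param k Calibration constant.
#' @param mean_subtract For `"RMS"`: use the raw RMS of the pressure wave
#'   (default) or the RMS of the mean-subtracted (pulsatile) pressure.
#'   The raw RMS carries the mean-pressure information that lets the
#'   algorithm track CO when the vasculature is unchanged.
#' @return Estimated CO, l/min.
#' @export
co_estimate <- function(radial_p, algorithm = c("RMS", "PP"), k,
                        mean_subtract = FALSE) {
  algorithm <- match.arg(algorithm)
  if (missing(k) || is.null(k) || !is.finite(k)) {
    abort("uncalibrated call: supply the calibration constant `k`")
  }
  k * co_feature(radial_p, algorithm, mean_subtract)
}

co_feature <- function(radial_p, algorithm, mean_subtract = TRUE) {
  y <- radial_p$y
  if (algorithm == "RMS") {
    if (mean_subtract) y <- y - mean(y)
    sqrt(mean(y^2))
  } else {
    period <- nrow(radial_p) * wave_dt(radial_p)
    s <- pressure_stats(radial_p)
    s$pp / (period * (s$sbp + s$dbp))
  }
}

#' @rdname co_estimate
#' @param co_ref Reference CO of the calibration subject, l/min.
#' @return `co_calibrate()`: the constant `k`.
#' @export
co_calibrate <- function(radial_p, algorithm = c("RMS", "PP"), co_ref,
                         mean_subtract = FALSE) {
  algorithm <- match.arg(algorithm)
  co_ref / co_feature(radial_p, algorithm, mean_subtract)
}

#' Mean absolute percentage error
#'
#' @param estimate,reference Numeric vectors (same length).
#' @return MAPE in percent.
#' @export
mape <- function(estimate, reference) {
  mean(100 * abs(estimate - reference) / reference)
}

#' Run the cardiac output monitoring case study
#'
#' For each age, simulates the baseline subject plus the six
#' single-parameter subjects in which either CO (HR +/-1 SD, SV +/-1 SD)
#' or MAP (+/-1 SD) is varied while everything else is held at baseline.
#' Both CO algorithms are calibrated on the age-matched baseline and
#' assessed by mean absolute percentage error against the reference CO
#' (HR x SV of the prescribed inflow), overall and within the CO-varied
#' and MAP-varied subgroups.
#'
#' @param ages Ages to include, default the six decades 25-75.
#' @param base_network Base network (default reduced fixture).
#' @param options [solver_options()].
#' @param mean_subtract Passed to [co_estimate()].
#' @return Object of class `pw_co_assessment`: list with `estimates`
#'   (per-subject tibble) and `mape` (per algorithm x subgroup).
#' @export
run_co_case_study <- function(ages = seq(25, 75, by = 10),
                              base_network = default_base_network(),
                              options = solver_options(),
                              mean_subtract = FALSE) {
  variations <- list(
    list(off = NULL, group = "baseline"),
    list(off = c(hr = 1), group = "co"), list(off = c(hr = -1), group = "co"),
    list(off = c(sv = 1), group = "co"), list(off = c(sv = -1), group = "co"),
    list(off = c(map = 1), group = "map"), list(off = c(map = -1), group = "map")
  )
  rows <- list()
  for (age in ages) {
    k_rms <- k_pp <- NULL
    base_outlets <- NULL
    for (v in variations) {
      pws <- simulate_virtual_subject(
        age, v$off, base_network = base_network, options = options,
        hold_outlets = if (v$group == "co") base_outlets)
      cfg <- attr(pws, "config")
      w <- get_wave(pws, "radial", "P")
      radial <- waveform(w$t, pa_to_mmhg(w$y), "P", "radial")
      co_ref <- cfg$hr * cfg$sv / 1000
      if (v$group == "baseline") {
        k_rms <- co_calibrate(radial, "RMS", co_ref, mean_subtract)
        k_pp <- co_calibrate(radial, "PP", co_ref, mean_subtract)
        base_outlets <- attr(pws, "network")$outlets
      }
      rows[[length(rows) + 1L]] <- tibble(
        age = age, group = v$group,
        varied = if (is.null(v$off)) "none" else names(v$off),
        offset = if (is.null(v$off)) 0 else unname(v$off),
        co_ref = co_ref,
        co_rms = co_estimate(radial, "RMS", k_rms, mean_subtract),
        co_pp = co_estimate(radial, "PP", k_pp, mean_subtract)
      )
    }
  }
  est <- bind_rows(rows)
  varied <- est[est$group != "baseline", ]
  mape_tbl <- bind_rows(lapply(c("overall", "co", "map"), function(g) {
    d <- if (g == "overall") varied else varied[varied$group == g, ]
    tibble(subgroup = g,
           mape_rms = mape(d$co_rms, d$co_ref),
           mape_pp = mape(d$co_pp, d$co_ref),
           n = nrow(d))
  }))
  structure(list(estimates = est, mape = mape_tbl),
            class = "pw_co_assessment")
}

#' @export
print.pw_co_assessment <- function(x, ...) {
  cat("<pw_co_assessment>\n")
  print(x$mape)
  invisible(x)
}

#' @export
tidy.pw_co_assessment <- function(x, ...) {
  tidyr::pivot_longer(x$mape, cols = c("mape_rms", "mape_pp"),
                      names_to = "algorithm", values_to = "mape") |>
    mutate(algorithm = toupper(sub("mape_", "", .data$algorithm)))
}

#' @export
glance.pw_co_assessment <- function(x, ...) {
  ov <- x$mape[x$mape$subgroup == "overall", ]
  tibble(mape_rms = ov$mape_rms, mape_pp = ov$mape_pp,
         n_subjects = nrow(x$estimates))
}

#' Run the PP-amplification case study
#'
#' Simulates the baseline subject at each age and decomposes the
#' aortic-to-brachial pulse pressure amplification into its early
#' (P1-referenced) and late (P2-referenced) systolic components.
#'
#' @inheritParams run_co_case_study
#' @return Tibble with one row per age.
#' @export
run_ppamp_case_study <- function(ages = seq(25, 75, by = 10),
                                 base_network = default_base_network(),
                                 options = solver_options()) {
  bind_rows(lapply(ages, function(age) {
    pws <- simulate_virtual_subject(age, base_network = base_network,
                                    options = options)
    pa <- get_wave(pws, "aortic_root", "P")
    pb <- get_wave(pws, "brachial", "P")
    bind_cols(tibble(age = age),
              ppamp_decomposition(
                waveform(pa$t, pa_to_mmhg(pa$y), "P", "aortic_root"),
                waveform(pb$t, pa_to_mmhg(pb$y), "P", "brachial")))
  }))
}
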