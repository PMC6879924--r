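## Aging model: literature-derived per-decade parameter anchors, subject
## construction on a +/-1 SD offset grid, calibration of wall stiffness to
## target pulse wave velocities and of outlet resistances/compliances to a
## target mean pressure, and the blood-pressure plausibility filter.

the <- new.env(parent = emptyenv())

## Table-1 compliance values are converted to SI with this factor; see the
## methods vignette for the unit interpretation adopted here.
PVC_UNIT <- 1e-10

## cohort SD of a parameter applied linearly over a {-1, 0, +1} offset grid
GRID_SD_FACTOR <- sqrt(2 / 3)

#' Literature-derived aging parameter tables
#'
#' Per-decade anchors (mean, upper and lower SD) for each model input
#' parameter, shipped as a CSV so transcribed values can be swapped without
#' touching code. The six parameters found to strongly influence pulse
#' waves carry a `varied_factor` label (hr, sv, lvet, diameter, pwv, map).
#'
#' @return A tibble with columns `parameter`, `age`, `mean`, `sd_plus`,
#'   `sd_minus`, `varied_factor`, `interp`, `units`.
#' @export
aging_tables <- function() {
  if (is.null(the$aging_tables)) {
    path <- system.file("extdata", "aging_tables.csv", package = "pulsesim")
    tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
    tbl$varied_factor[tbl$varied_factor == ""] <- NA_character_
    the$aging_tables <- as_tibble(tbl)
  }
  the$aging_tables
}

#' Age-specific healthy blood pressure reference ranges
#'
#' Reference means and SDs for aortic and brachial SBP/DBP/MAP/PP and pulse
#' pressure amplification at each age decade, used by the plausibility
#' filter.
#'
#' @return A tibble with columns `age`, `quantity`, `mean`, `sd`.
#' @export
bp_reference <- function() {
  if (is.null(the$bp_reference)) {
    path <- system.file("extdata", "bp_reference.csv", package = "pulsesim")
    the$bp_reference <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  the$bp_reference
}

interp_one <- function(ages, values, age, method) {
  switch(method,
    linear = approx(ages, values, xout = age, rule = 1)$y,
    monoH  = splinefun(ages, values, method = "monoH.FC")(age),
    spline = splinefun(ages, values, method = "natural")(age),
    abort(sprintf("unknown interpolation method `%s`", method))
  )
}

#' Model input parameters for a given age
#'
#' Interpolates the per-decade anchor tables to an arbitrary age in
#' 25-75 yr. Decade anchors are reproduced exactly. Heart rate uses
#' shape-preserving piecewise-cubic interpolation and the MAP mean a
#' natural cubic spline (SDs are interpolated linearly), matching how the
#' anchors were derived; all other parameters are interpolated linearly.
#'
#' @param age Age in years, between 25 and 75.
#' @param tables Anchor tables, defaulting to [aging_tables()].
#' @return A tibble with one row per parameter: `parameter`, `mean`,
#'   `sd_plus`, `sd_minus`, `varied_factor`, `units`, plus an `age`
#'   attribute column.
#' @export
#' @examples
#' aging_parameters(50)
aging_parameters <- function(age, tables = aging_tables()) {
  if (!is.numeric(age) || length(age) != 1L || age < 25 || age > 75) {
    abort("`age` must be a single value between 25 and 75 years")
  }
  out <- tables |>
    group_by(.data$parameter) |>
    summarise(
      mean = interp_one(.data$age, .data$mean, .env$age, .data$interp[1L]),
      sd_plus = interp_one(.data$age, .data$sd_plus, .env$age, "linear"),
      sd_minus = interp_one(.data$age, .data$sd_minus, .env$age, "linear"),
      varied_factor = .data$varied_factor[1L],
      units = .data$units[1L],
      .groups = "drop"
    )
  out$age <- age
  out
}

#' The six varied cardiovascular factors
#' @return Character vector of factor names.
#' @export
varied_factors <- function() c("hr", "sv", "lvet", "diameter", "pwv", "map")

#' Apply +/-1 SD offsets to age-specific means
#'
#' Builds the absolute parameter values of one virtual subject from the
#' age-specific means and a set of offsets (in SD units) on the six varied
#' factors. Coupling rules: the LVET mean is first shifted according to the
#' subject's HR and SV deviations (slope -0.926 ms per beat/min and
#' +1.08 ms per ml) before LVET's own offset is applied; the asymmetric
#' upper/lower SDs are honoured for the PWV targets.
#'
#' @param params Output of [aging_parameters()].
#' @param offsets Named numeric vector/list with elements from
#'   [varied_factors()], each in \{-1, 0, 1\}. Missing factors default to 0.
#' @param lvet_mode `"deviation"` (default) applies the HR/SV regression as
#'   a shift about the age mean; `"absolute"` evaluates the regression
#'   `244 - 0.926 HR + 1.08 SV` directly.
#' @return One-row tibble with the subject's absolute parameter values and
#'   the offsets used (`off_*` columns).
#' @export
apply_offsets <- function(params, offsets = NULL,
                          lvet_mode = c("deviation", "absolute")) {
  lvet_mode <- match.arg(lvet_mode)
  off <- setNames(rep(0, 6L), varied_factors())
  if (!is.null(offsets)) {
    offsets <- unlist(offsets)
    bad <- setdiff(names(offsets), varied_factors())
    if (length(bad)) {
      abort(sprintf("offsets only allowed on the varied factors (got: %s)",
                    paste(bad, collapse = ", ")))
    }
    if (any(!offsets %in% c(-1, 0, 1))) abort("offsets must be -1, 0 or +1")
    off[names(offsets)] <- offsets
  }
  p <- setNames(params$mean, params$parameter)
  sp <- setNames(params$sd_plus, params$parameter)
  sm <- setNames(params$sd_minus, params$parameter)
  shift <- function(name, o) {
    o <- unname(o)
    p[[name]] + (if (o >= 0) sp[[name]] else sm[[name]]) * o
  }

  hr <- shift("hr", off["hr"])
  sv <- shift("sv", off["sv"])
  lvet_base <- if (lvet_mode == "deviation") {
    p[["lvet"]] - 0.926 * (hr - p[["hr"]]) + 1.08 * (sv - p[["sv"]])
  } else {
    lvet_from_hr_sv(hr, sv)
  }
  lvet <- unname(lvet_base + sp[["lvet"]] * off[["lvet"]])

  tibble(
    age = params$age[1L],
    hr = hr, sv = sv, lvet = lvet,
    pft = p[["pft"]], rfv = p[["rfv"]],
    map = shift("map", off["map"]),
    dbp = p[["dbp"]],
    prox_aortic_length = p[["prox_aortic_length"]],
    asc_aorta_diam = shift("asc_aorta_diam", off["diameter"]),
    desc_thor_diam = shift("desc_thor_diam", off["diameter"]),
    abd_aorta_diam = shift("abd_aorta_diam", off["diameter"]),
    carotid_diam = shift("carotid_diam", off["diameter"]),
    pwv_aortic = shift("pwv_aortic", off["pwv"]),
    pwv_arm = shift("pwv_arm", off["pwv"]),
    pwv_leg = shift("pwv_leg", off["pwv"]),
    pvc = p[["pvc"]],
    off_hr = off[["hr"]], off_sv = off[["sv"]], off_lvet = off[["lvet"]],
    off_diameter = off[["diameter"]], off_pwv = off[["pwv"]],
    off_map = off[["map"]]
  )
}

#' MAP adjustment of the aortic PWV target
#'
#' Reference carotid-femoral PWV values depend on both age and blood
#' pressure; the stiffness target is therefore evaluated at the subject's
#' MAP. Implemented as a multiplicative adjustment linear in the MAP
#' deviation from the age mean (default slope 1 %/mmHg, the magnitude
#' implied by population reference tables of PWV by age and BP category).
#'
#' @param pwv Age-specific PWV target(s), m/s.
#' @param map Subject MAP, mmHg.
#' @param map_mean Age-specific mean MAP, mmHg.
#' @param slope Relative change per mmHg.
#' @return Adjusted PWV target(s).
#' @export
pwv_at_map <- function(pwv, map, map_mean, slope = 0.01) {
  pwv * (1 + slope * (map - map_mean))
}

## ---------------------------------------------------------------------------
## Stiffness calibration

#' Calibrate the wall stiffness law to target wave speeds
#'
#' Finds constants (k1, k2, k3) of the stiffness law
#' `Eh = Rd (k1 exp(k2 Rd) + k3)` such that the theoretical diastolic wave
#' speed at each anchor radius equals its target. With three anchors the
#' system is solved exactly (k1 and k3 eliminated analytically, k2 by a
#' deterministic 1-D root search); a least-squares fall-back from a fixed
#' initial guess covers degenerate anchor sets. A single anchor fixes
#' `k1 = 0` and gives the closed form `k3 = 3 rho c^2 / 2`.
#'
#' @param targets Target wave speeds, m/s (typically aortic, arm, leg).
#' @param anchor_radii Representative diastolic radii, m, same length.
#' @param rho Blood density, kg/m^3.
#' @param weights Optional anchor weights for the least-squares path
#'   (defaults to equal weights). Ignored when an exact interpolating fit
#'   exists.
#' @return Object of class `pw_stiffness_fit`: list with `k1`, `k2`, `k3`
#'   (SI), `achieved` speeds at the anchors and `residual` (max relative
#'   anchor error).
#' @export
#' @examples
#' fit <- calibrate_stiffness(c(5.9, 8.9, 8.7), c(0.012, 0.0027, 0.0037))
#' fit$residual
calibrate_stiffness <- function(targets, anchor_radii, rho = 1060,
                                weights = NULL) {
  if (length(targets) != length(anchor_radii)) {
    abort("`targets` and `anchor_radii` must have equal length")
  }
  if (any(targets <= 0) || any(anchor_radii <= 0)) {
    abort("targets and anchor radii must be > 0")
  }
  y <- 1.5 * rho * targets^2   # Eh/Rd needed at each anchor
  r <- anchor_radii
  ## the law must stay positive over the radius range it will be applied to
  r_chk <- seq(0.3 * min(r), 2 * max(r), length.out = 50L)
  valid <- function(ks) {
    yy <- ks$k1 * exp(ks$k2 * r_chk) + ks$k3
    all(is.finite(yy)) && all(yy > 0)
  }
  ks <- NULL
  if (length(r) == 1L) {
    ks <- list(k1 = 0, k2 = 0, k3 = y)
  } else if (length(r) == 3L && length(unique(r)) == 3L) {
    ## exact interpolation: eliminate k1, k3; 1-D root search for k2 < 0
    f <- function(k2) {
      e <- exp(k2 * r)
      (e[1L] - e[2L]) * (y[2L] - y[3L]) - (e[2L] - e[3L]) * (y[1L] - y[2L])
    }
    grid <- -exp(seq(log(1), log(5e4), length.out = 300L))
    fv <- vapply(grid, f, numeric(1L))
    ix <- which(diff(sign(fv)) != 0)
    for (i in ix) {
      root <- uniroot(f, sort(c(grid[i], grid[i + 1L])), tol = 1e-12)$root
      e <- exp(root * r)
      k1 <- (y[1L] - y[2L]) / (e[1L] - e[2L])
      k3 <- y[1L] - k1 * e[1L]
      cand <- list(k1 = k1, k2 = root, k3 = k3)
      res <- max(abs(cand$k1 * e + cand$k3 - y) / y)
      if (is.finite(k1) && is.finite(k3) && res < 1e-8 && valid(cand)) {
        ks <- cand
        break
      }
    }
  }
  if (is.null(ks)) {
    ks <- calibrate_stiffness_ls(y, r, weights %||% rep(1, length(r)), valid)
    if (!valid(ks)) {
      ks <- list(k1 = 0, k2 = 0,
                 k3 = stats::weighted.mean(y, weights %||% rep(1, length(r))))
    }
  }
  achieved <- wave_speed(wall_stiffness(r, ks$k1, ks$k2, ks$k3), r, rho)
  structure(
    list(k1 = ks$k1, k2 = ks$k2, k3 = ks$k3,
         targets = targets, anchor_radii = r, rho = rho,
         achieved = achieved,
         residual = max(abs(achieved - targets) / targets)),
    class = "pw_stiffness_fit"
  )
}

## deterministic weighted least squares over the valid (positive-stiffness)
## region: linear solve for (k1, k3) at fixed k2, grid + local search on k2
calibrate_stiffness_ls <- function(y, r, w, valid = function(ks) TRUE) {
  fit_k2 <- function(k2) {
    e <- exp(k2 * r)
    X <- cbind(e, 1)
    A <- crossprod(X * sqrt(w))
    b <- crossprod(X, w * y)
    k13 <- tryCatch(as.numeric(solve(A, b)), error = function(e2) c(0, mean(y)))
    ks <- list(k1 = k13[1L], k2 = k2, k3 = k13[2L])
    ks$obj <- if (valid(ks)) sum(w * (X %*% k13 - y)^2) else 1e300
    ks
  }
  grid <- -exp(seq(log(10), log(3000), length.out = 250L))
  objs <- vapply(grid, function(k2) fit_k2(k2)$obj, numeric(1L))
  if (all(objs >= 1e300)) return(list(k1 = 0, k2 = 0, k3 = -1))
  i <- which.min(objs)
  lo <- grid[min(length(grid), i + 1L)]
  hi <- grid[max(1L, i - 1L)]
  opt <- optimize(function(k2) fit_k2(k2)$obj, interval = sort(c(lo, hi)),
                  tol = 1e-8)
  best <- fit_k2(opt$minimum)
  if (best$obj >= 1e300) best <- fit_k2(grid[i])
  list(k1 = best$k1, k2 = best$k2, k3 = best$k3)
}

#' @export
print.pw_stiffness_fit <- function(x, ...) {
  cat(sprintf("<pw_stiffness_fit> k1 = %.4g Pa, k2 = %.4g 1/m, k3 = %.4g Pa\n",
              x$k1, x$k2, x$k3))
  cat(sprintf("  anchor residual (max rel.): %.3g\n", x$residual))
  invisible(x)
}

#' @export
tidy.pw_stiffness_fit <- function(x, ...) {
  tibble(term = c("k1", "k2", "k3"),
         estimate = c(x$k1, x$k2, x$k3),
         units = c("Pa", "1/m", "Pa"))
}

#' @export
glance.pw_stiffness_fit <- function(x, ...) {
  tibble(n_anchors = length(x$anchor_radii), residual = x$residual)
}

## Apply a stiffness fit to every segment of a network, with a fixed-point
## refinement so the *path-integrated* theoretical transit times match the
## target PWVs (the anchor radii alone only match pointwise wave speeds).
calibrate_network_stiffness <- function(network, targets, paths, rho = NULL,
                                        n_refine = 4L,
                                        weights = c(10, 1, 1)) {
  rho <- rho %||% network$blood$density
  radii <- vapply(paths, function(p) effective_path_radius(network, p), numeric(1L))
  weights <- weights[seq_along(radii)]
  tgt <- targets
  fit <- calibrate_stiffness(tgt, radii, rho, weights = weights)
  for (i in seq_len(n_refine)) {
    ach <- vapply(paths, function(p) {
      theoretical_path_pwv(network, p, fit, rho)
    }, numeric(1L))
    tgt <- tgt * targets / ach
    fit <- calibrate_stiffness(tgt, radii, rho, weights = weights)
  }
  network$segments$k1 <- fit$k1
  network$segments$k2 <- fit$k2
  network$segments$k3 <- fit$k3
  attr(network, "stiffness_fit") <- fit
  network
}

## path length / integral of dx / c_d(Rd(x)) along a chain of segments
theoretical_path_pwv <- function(network, segment_ids, fit, rho = NULL,
                                 n_sub = 50L) {
  rho <- rho %||% network$blood$density
  seg <- network$segments[match(segment_ids, network$segments$id), ]
  tt <- 0
  for (i in seq_len(nrow(seg))) {
    x <- (seq_len(n_sub) - 0.5) / n_sub
    rd <- radius_at(seg$r_in[i], seg$r_out[i], x)
    cd <- wave_speed(wall_stiffness(rd, fit$k1, fit$k2, fit$k3), rd, rho)
    tt <- tt + sum(seg$length[i] / n_sub / cd)
  }
  sum(seg$length) / tt
}

## ---------------------------------------------------------------------------
## Vascular bed calibration

## Poiseuille resistance of a linearly tapered segment, Pa s m^-3
segment_poiseuille_resistance <- function(length, r_in, r_out, mu,
                                          n_sub = 50L) {
  x <- (seq_len(n_sub) - 0.5) / n_sub
  r <- r_in + (r_out - r_in) * x
  sum(8 * mu / (pi * r^4) * length / n_sub)
}

## effective resistance from the root to the venous side of a resistive
## tree: series Poiseuille segment resistances, parallel combination at
## junctions, outlet windkessel totals at the terminals
tree_effective_resistance <- function(network, r_wk) {
  seg <- network$segments
  mu <- network$blood$viscosity
  r_seg <- vapply(seq_len(nrow(seg)), function(i) {
    segment_poiseuille_resistance(seg$length[i], seg$r_in[i], seg$r_out[i], mu)
  }, numeric(1L))
  names(r_seg) <- seg$id
  jn <- network$junctions
  downstream <- function(id) {
    dtr <- jn$daughter[jn$parent == id]
    if (!length(dtr)) {
      r_wk[[id]] + r_seg[[id]]
    } else {
      r_seg[[id]] + 1 / sum(vapply(dtr, function(d) 1 / downstream(d), numeric(1L)))
    }
  }
  downstream(network$inlet)
}

#' Calibrate windkessel resistances and compliances
#'
#' Sets the total peripheral resistance so the subject's mean arterial
#' pressure matches its target: the tree of conduit (Poiseuille)
#' resistances in series with the outlet windkessels must satisfy
#' `R_effective = (MAP_target - P_out) / CO`. The windkessel totals are
#' split between vascular beds by their baseline fractions of cardiac
#' output and within a bed between outlets in inverse proportion to the
#' luminal area of the feeding branch, then scaled by a common factor
#' solved so the tree-effective resistance hits the target. The proximal
#' resistance R1 is matched to the characteristic impedance of the
#' terminal segment (capped at 90% of the outlet total) to minimise
#' non-physiological outlet reflections; compliances are distributed so
#' every bed has the same RC time constant and their sum equals the
#' prescribed total peripheral compliance.
#'
#' @param network A `pw_network` whose outlets carry `bed` and
#'   `bed_fraction` columns (fractions of cardiac output at baseline).
#' @param map_target Target mean arterial pressure, mmHg.
#' @param co Cardiac output, l/min.
#' @param pvc_total Total peripheral compliance, m^3/Pa.
#' @param p_out Outflow (venous) pressure, mmHg; default 0.
#' @return The network with recalibrated outlet `R1`, `R2`, `C`, `P_out`.
#' @export
calibrate_resistances <- function(network, map_target, co, pvc_total,
                                  p_out = 0) {
  if (co <= 0) abort("`co` must be > 0")
  if (map_target <= p_out) abort("parameter error: MAP target must exceed P_out")
  co_si <- co / 1000 / 60                      # l/min -> m^3/s
  r_target <- (map_target - p_out) * MMHG / co_si
  out <- network$outlets
  if (!"bed" %in% names(out)) out$bed <- out$segment
  if (!"bed_fraction" %in% names(out)) {
    abort("calibrate_resistances() needs a `bed_fraction` column on outlets")
  }
  seg <- network$segments[match(out$segment, network$segments$id), ]
  a_out <- pi * seg$r_out^2
  ## per-outlet share of flow: bed fraction split within bed by 1/A rule
  ## (resistance inversely proportional to luminal area <=> flow prop. to A)
  share <- numeric(nrow(out))
  for (b in unique(out$bed)) {
    i <- out$bed == b
    ## the bed's CO fraction is stored identically on each member row
    bed_frac <- out$bed_fraction[i][1L]
    share[i] <- bed_frac * a_out[i] / sum(a_out[i])
  }
  share <- share / sum(share)
  base_r <- r_target / share
  ## common scale on the windkessel totals so that the conduit + windkessel
  ## tree gives the target effective resistance
  eff <- function(s) {
    r_wk <- setNames(s * base_r, out$segment)
    tree_effective_resistance(network, as.list(r_wk)) - r_target
  }
  s <- tryCatch(uniroot(eff, c(0.05, 1.2), tol = 1e-10)$root,
                error = function(e) {
                  abort("parameter error: conduit resistance alone exceeds the MAP target")
                })
  r_out_total <- s * base_r
  ## characteristic impedance of the terminal segment end
  rd <- seg$r_out
  eh <- wall_stiffness(rd, seg$k1, seg$k2, seg$k3)
  cd <- wave_speed(eh, rd, network$blood$density)
  z0 <- network$blood$density * cd / a_out
  r1 <- pmin(z0, 0.9 * r_out_total)
  r2 <- r_out_total - r1
  cc <- pvc_total * (1 / r2) / sum(1 / r2)
  out$R1 <- r1
  out$R2 <- r2
  out$C <- cc
  out$P_out <- p_out * MMHG
  network$outlets <- out
  network
}

## ---------------------------------------------------------------------------
## Subject grid and plausibility filter

#' Enumerate the virtual-subject offset grid
#'
#' Deterministically enumerates all 3^k combinations of \{-1, 0, +1\}
#' offsets of the varied factors at each age (729 subjects per age for the
#' six standard factors; the all-zero row is the baseline subject). Rows
#' are ordered by age, then by offsets with the last factor varying
#' fastest.
#'
#' @param ages Ages in years.
#' @param factors Varied factors; default all six.
#' @return Tibble with columns `age`, `subject` (1-based within age) and
#'   one `off_<factor>` column per factor.
#' @export
#' @examples
#' nrow(generate_grid(25))          # 729
#' nrow(generate_grid(c(25, 75), factors = "hr")) # 6
generate_grid <- function(ages, factors = varied_factors()) {
  stopifnot(length(factors) >= 1L)
  offs <- rep(list(c(-1, 0, 1)), length(factors))
  names(offs) <- paste0("off_", factors)
  grid <- rev(do.call(tidyr::crossing, rev(offs)))[, paste0("off_", factors)]
  out <- tidyr::crossing(age = ages) |>
    dplyr::reframe(grid, .by = "age") |>
    group_by(.data$age) |>
    mutate(subject = dplyr::row_number(), .after = "age") |>
    ungroup()
  out
}

#' Blood-pressure plausibility filter
#'
#' A virtual subject is physiologically plausible iff each of the nine BP
#' summaries (aortic and brachial SBP, DBP, MAP, PP, and PP amplification)
#' lies inside the age-specific 99% reference interval
#' `mean +/- 2.575 SD`. The interval is closed: a value exactly on the
#' boundary is plausible.
#'
#' @param bp Named list/vector or one-row tibble with elements
#'   `aortic_sbp`, `aortic_dbp`, `aortic_map`, `aortic_pp`, `brachial_sbp`,
#'   `brachial_dbp`, `brachial_map`, `brachial_pp`, `pp_amp` (mmHg, ratio).
#' @param age Subject age (matched against the reference table).
#' @param reference Reference table, default [bp_reference()].
#' @param n_sd Width of the interval in SDs (2.575 for 99% coverage).
#' @return List with `plausible` (logical) and `violations` (character
#'   vector naming offending quantities).
#' @export
plausibility_filter <- function(bp, age, reference = bp_reference(),
                                n_sd = 2.575) {
  bp <- as.list(bp)
  ref <- reference[reference$age == age, ]
  if (!nrow(ref)) abort(sprintf("no reference BP values for age %s", age))
  missing_q <- setdiff(ref$quantity, names(bp))
  if (length(missing_q)) {
    abort(sprintf("plausibility input error: missing quantit%s: %s",
                  if (length(missing_q) > 1) "ies" else "y",
                  paste(missing_q, collapse = ", ")))
  }
  viol <- character(0)
  for (i in seq_len(nrow(ref))) {
    q <- ref$quantity[i]
    v <- bp[[q]]
    lo <- ref$mean[i] - n_sd * ref$sd[i]
    hi <- ref$mean[i] + n_sd * ref$sd[i]
    if (!is.finite(v) || v < lo || v > hi) viol <- c(viol, q)
  }
  list(plausible = length(viol) == 0L, violations = viol)
}
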