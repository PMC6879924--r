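## R surface of the 1D haemodynamics solver: constitutive helpers that are
## useful (and testable) on their own, solver options, and the subject
## simulation wrapper around the compiled core.

#' Voigt-type viscoelastic tube law
#'
#' Transmural pressure as a function of luminal area and its rate of
#' change: `P = Pd + (beta/Ad) (sqrt(A) - sqrt(Ad)) + g dA/dt` with
#' `beta = (4/3) sqrt(pi) Eh` and `g = Gamma / (Ad sqrt(Ad))` (Gamma in
#' kg/s). The elastic part is constrained so the linearised wave speed at
#' `A = Ad` equals [wave_speed()] exactly.
#'
#' @param A Luminal area, m^2.
#' @param Ad Diastolic area, m^2.
#' @param dA_dt Area rate of change, m^2/s.
#' @param Eh Wall stiffness, N/m.
#' @param gamma Wall viscosity in g/s (as returned by [wall_viscosity()]).
#' @param Pd Diastolic reference pressure, Pa.
#' @return Pressure in Pa.
#' @export
tube_law_pressure <- function(A, Ad, dA_dt = 0, Eh, gamma = 0, Pd = 0) {
  if (any(A <= 0) || any(Ad <= 0)) {
    abort("solver blow-up: tube law evaluated at non-positive area")
  }
  beta <- 4 / 3 * sqrt(pi) * Eh
  g <- (gamma * 1e-3) / (Ad * sqrt(Ad))
  Pd + beta / Ad * (sqrt(A) - sqrt(Ad)) + g * dA_dt
}

#' One step of a three-element (RCR) windkessel
#'
#' Advances the compliant pressure of an RCR vascular bed model by `dt`
#' under inflow `q_in` (implicit Euler on the RC state, unconditionally
#' stable). At sustained constant inflow the interface pressure tends to
#' `q_in (R1 + R2) + P_out`; with zero inflow the compliant pressure
#' relaxes to `P_out` with time constant `R2 C`.
#'
#' @param pc Current compliant (capacitor) pressure, Pa.
#' @param q_in Inflow, m^3/s.
#' @param dt Time step, s.
#' @param R1,R2 Proximal and distal resistances, Pa s m^-3.
#' @param C Compliance, m^3/Pa.
#' @param P_out Outflow pressure, Pa.
#' @return List with `P` (interface pressure, Pa), `pc` (updated compliant
#'   pressure) and `V` (stored compliant volume, m^3).
#' @export
windkessel_step <- function(pc, q_in, dt, R1, R2, C, P_out = 0) {
  if (dt <= 0) abort("`dt` must be > 0")
  pc_new <- (pc + dt / C * (q_in + P_out / R2)) / (1 + dt / (R2 * C))
  list(P = pc_new + q_in * R1, pc = pc_new, V = C * (pc_new - P_out))
}

#' Synthesize a PPG from a blood-volume series
#'
#' The photoplethysmogram is modelled as the pulsatile arterial blood
#' volume normalised to occupy the range 0 to 1 exactly. The volume can be
#' the blood stored in a terminal windkessel or the integrated luminal
#' volume of an arterial segment; any positive affine transformation of
#' the volume gives the same PPG.
#'
#' @param volume A [waveform()] or numeric vector of blood volume over one
#'   cycle.
#' @return Same shape as the input, normalised to \[0, 1\].
#' @export
synthesize_ppg <- function(volume) {
  y <- if (is.data.frame(volume)) volume$y else volume
  rng <- range(y)
  if (!all(is.finite(rng)) || diff(rng) <= 0) {
    abort("degenerate signal: blood volume has no pulsatile variation")
  }
  ppg <- (y - rng[1L]) / diff(rng)
  if (is.data.frame(volume)) {
    out <- waveform(volume$t, ppg, kind = "PPG", site = attr(volume, "site"))
    out
  } else {
    ppg
  }
}

#' Solver options
#'
#' @param cfl CFL safety factor in (0, 1].
#' @param max_cycles Maximum number of cardiac cycles before giving up on
#'   periodicity.
#' @param periodicity_tol Relative L-infinity change of the aortic-root
#'   pressure between consecutive cycles (normalised by the cycle's pulse
#'   pressure) below which the solution is deemed periodic.
#' @param output_fs Output sampling rate, Hz.
#' @param friction_model `"parabolic"` (momentum correction alpha = 4/3,
#'   wall friction -8 pi mu Q / (rho A)) or `"flat"` (alpha = 1, friction
#'   coefficient 22 pi).
#' @param dx_max Maximum node spacing, m (each segment has at least 3
#'   nodes); the default resolves the taper of the shortest segments
#'   finely enough to keep the per-cycle mass residual well below 0.5% of
#'   stroke volume.
#' @return List of class `pw_solver_options`.
#' @export
solver_options <- function(cfl = 0.5, max_cycles = 20, periodicity_tol = 1e-3,
                           output_fs = 500,
                           friction_model = c("parabolic", "flat"),
                           dx_max = 0.007) {
  friction_model <- match.arg(friction_model)
  if (cfl <= 0 || cfl > 1) abort("`cfl` must be in (0, 1]")
  if (periodicity_tol <= 0) abort("`periodicity_tol` must be > 0")
  structure(list(cfl = cfl, max_cycles = as.integer(max_cycles),
                 periodicity_tol = periodicity_tol, output_fs = output_fs,
                 friction_model = friction_model, dx_max = dx_max),
            class = "pw_solver_options")
}

## node-level discretisation of a network
discretize_network <- function(network, dx_max = 0.007) {
  seg <- network$segments
  n <- if ("n_nodes" %in% names(seg) && !all(is.na(seg$n_nodes))) {
    ifelse(is.na(seg$n_nodes), segment_nodes(seg$length, dx_max), seg$n_nodes)
  } else {
    segment_nodes(seg$length, dx_max)
  }
  n <- pmax(3L, as.integer(n))
  Ad <- beta <- gvis <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    x <- seq(0, 1, length.out = n[i])
    rd <- radius_at(seg$r_in[i], seg$r_out[i], x)
    eh <- wall_stiffness(rd, seg$k1[i], seg$k2[i], seg$k3[i])
    gam <- wall_viscosity(rd, seg$b0[i], seg$b1[i]) * 1e-3  # g/s -> kg/s
    a <- pi * rd^2
    Ad[[i]] <- a
    beta[[i]] <- 4 / 3 * sqrt(pi) * eh
    gvis[[i]] <- gam / (a * sqrt(a))
  }
  list(n = n, dx = seg$length / (n - 1),
       Ad = unlist(Ad), beta = unlist(beta), gvis = unlist(gvis))
}

#' Simulate the pulse waves of one subject
#'
#' Runs the 1D model to cycle-to-cycle periodicity and returns one
#' converged cardiac cycle of pressure (P, Pa), flow velocity (U, m/s),
#' luminal area (A, m^2), flow rate (Q, m^3/s) and synthesized PPG waves
#' at the network's measurement sites.
#'
#' @param network A `pw_network` (calibrated: wall constants and outlet
#'   windkessels set).
#' @param inflow Periodic aortic-root inflow [waveform()] (kind Q).
#' @param options [solver_options()].
#' @param p_diastolic Diastolic reference pressure of the tube law, mmHg
#'   (the pressure at which the diastolic geometry is prescribed).
#' @return A `pw_pulse_set`: long tibble with columns `site`, `kind`, `t`,
#'   `y`, carrying simulation metadata in `attr(, "meta")`. `Q = U * A`
#'   holds pointwise at every site and sample.
#' @export
simulate_subject <- function(network, inflow, options = solver_options(),
                             p_diastolic = 75) {
  stopifnot(inherits(network, "pw_network"))
  disc <- discretize_network(network, options$dx_max)
  seg <- network$segments
  ids <- seg$id
  seg_index <- function(x) match(x, ids) - 1L

  jn <- network$junctions
  parents <- unique(jn$parent)
  jn_daughters <- lapply(parents, function(p) seg_index(jn$daughter[jn$parent == p]))

  out <- network$outlets
  period <- nrow(inflow) * wave_dt(inflow)
  q_mean <- sum(inflow$y) * wave_dt(inflow) / period
  r_parallel <- 1 / sum(1 / (out$R1 + out$R2))
  pc0 <- out$P_out + q_mean * r_parallel * (out$R2 / (out$R1 + out$R2))

  alpha <- if (options$friction_model == "parabolic") 4 / 3 else 1
  fric <- if (options$friction_model == "parabolic") 8 * pi else 22 * pi

  sites <- network$sites
  ppg_wk <- which(!is.na(sites$ppg) & sites$ppg == "windkessel")
  ppg_seg <- which(!is.na(sites$ppg) & sites$ppg == "segment")
  vol_seg <- seg_index(sites$segment[ppg_seg])

  res <- .pw_solve(
    disc$n, disc$dx, disc$Ad, disc$beta, disc$gvis,
    network$blood$density, network$blood$viscosity, alpha, fric,
    mmhg_to_pa(p_diastolic),
    seg_index(network$inlet),
    seg_index(parents), jn_daughters,
    seg_index(out$segment), out$R1, out$R2, out$C, out$P_out, pc0,
    inflow$t, inflow$y, period,
    options$cfl, options$max_cycles, options$periodicity_tol,
    seg_index(sites$segment), sites$fraction, as.integer(vol_seg)
  )
  if (!res$converged) {
    warn(sprintf("simulation did not reach periodicity in %d cycles (last residual %.3g)",
                 res$n_cycles, utils::tail(res$residuals, 1L)))
  }

  ## periodic resample of the recording cycle onto the output grid
  fs <- options$output_fs
  n_out <- round(period * fs)
  t_out <- (seq_len(n_out) - 1L) * period / n_out
  resample <- function(v) {
    ns <- length(v)
    tg <- c(0, res$t[-ns])
    vg <- c(v[ns], v[-ns])
    approx(tg, vg, xout = t_out, rule = 2)$y
  }

  rows <- list()
  for (s in seq_len(nrow(sites))) {
    a_out <- resample(res$A[, s])
    q_out <- resample(res$Q[, s])
    vals <- list(P = resample(res$P[, s]), U = q_out / a_out, A = a_out,
                 Q = q_out)
    for (kind in names(vals)) {
      yv <- vals[[kind]]
      rows[[length(rows) + 1L]] <- tibble(
        site = sites$site[s], kind = kind, t = t_out, y = yv)
    }
  }
  out_idx <- function(segment) {
    i <- match(segment, out$segment)
    if (is.na(i)) {
      abort(sprintf("PPG site on segment `%s` has no terminal windkessel", segment))
    }
    i
  }
  for (s in ppg_wk) {
    v <- resample(res$wk_V[, out_idx(sites$segment[s])])
    rows[[length(rows) + 1L]] <- tibble(
      site = sites$site[s], kind = "PPG", t = t_out, y = synthesize_ppg(v))
  }
  for (j in seq_along(ppg_seg)) {
    v <- resample(res$seg_vol[, j])
    rows[[length(rows) + 1L]] <- tibble(
      site = sites$site[ppg_seg[j]], kind = "PPG", t = t_out, y = synthesize_ppg(v))
  }
  pws <- bind_rows(rows)
  meta <- list(
    converged = res$converged, n_cycles = res$n_cycles,
    residuals = res$residuals, dt = res$dt,
    steps_per_cycle = res$steps_per_cycle, period = period, fs = fs,
    mass = res$mass,
    wk_V_end = res$wk_V[nrow(res$wk_V), ], p_diastolic = p_diastolic
  )
  attr(pws, "meta") <- meta
  class(pws) <- c("pw_pulse_set", class(pws))
  pws
}

#' Extract one waveform from a pulse-wave set
#'
#' @param pws A `pw_pulse_set`.
#' @param site Site name.
#' @param kind Signal kind ("P", "U", "A", "Q", "PPG").
#' @return A [waveform()].
#' @export
get_wave <- function(pws, site, kind) {
  w <- pws[pws$site == site & pws$kind == kind, ]
  if (!nrow(w)) abort(sprintf("no %s wave at site `%s`", kind, site))
  waveform(w$t, w$y, kind = kind, site = site)
}

#' Per-cycle mass balance of a simulation
#'
#' Compares the inflow volume over the recorded cycle with the summed
#' outlet outflow and the change in stored volume (conduit plus
#' windkessel).
#'
#' @param pws A `pw_pulse_set`.
#' @return One-row tibble with volumes (m^3), the residual and the
#'   residual as a fraction of stroke volume.
#' @export
mass_balance <- function(pws) {
  m <- attr(pws, "meta")$mass
  sv <- m$v_in
  ## the outlet volumes are measured at the conduit/windkessel interface,
  ## so conduit storage is the only storage term of the conduit domain
  resid <- m$v_in - sum(m$v_out) - m$d_conduit
  tibble(v_in = m$v_in, v_out = sum(m$v_out),
         d_storage = m$d_conduit + sum(m$d_windkessel),
         residual = resid, residual_frac = abs(resid) / sv)
}

#' @export
print.pw_pulse_set <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<pw_pulse_set> %d sites, %.0f Hz, period %.3f s (%s after %d cycles)\n",
              length(unique(x$site)), meta$fs, meta$period,
              if (meta$converged) "periodic" else "NOT converged", meta$n_cycles))
  NextMethod()
}

#' @export
glance.pw_pulse_set <- function(x, ...) {
  meta <- attr(x, "meta")
  mb <- mass_balance(x)
  tibble(converged = meta$converged, n_cycles = meta$n_cycles,
         residual = utils::tail(meta$residuals, 1L) %||% NA_real_,
         dt = meta$dt, period = meta$period,
         mass_residual_frac = mb$residual_frac)
}
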