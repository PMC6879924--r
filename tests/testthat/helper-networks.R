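# Small deterministic networks and cached simulations shared across tests.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# single uniform tube with prescribed wave speed and a windkessel outlet
uniform_tube <- function(length = 1, radius = 0.005, c_d = 8, rho = 1060,
                         b0 = 0, b1 = 0, R1 = NULL, R2 = 8e8, C = 1e-9,
                         sites = NULL, viscosity = 2.5e-3) {
  k3 <- 1.5 * rho * c_d^2
  a <- pi * radius^2
  z0 <- rho * c_d / a
  seg <- tibble::tibble(id = "tube", length = length, r_in = radius,
                        r_out = radius, k1 = 0, k2 = 0, k3 = k3,
                        b0 = b0, b1 = b1,
                        diam_class = NA_character_, len_class = NA_character_)
  jn <- tibble::tibble(parent = character(), daughter = character())
  out <- tibble::tibble(segment = "tube", R1 = R1 %||% z0, R2 = R2, C = C,
                        P_out = 0)
  if (is.null(sites)) {
    sites <- tibble::tibble(site = c("prox", "mid", "dist"), segment = "tube",
                            fraction = c(0.1, 0.5, 0.9), ppg = NA_character_)
  }
  pw_network(seg, jn, out, "tube", sites,
             blood = blood_properties(rho, viscosity))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# short gaussian flow pulse as a periodic inflow (small amplitude)
gaussian_inflow <- function(q_peak = 2e-6, t0 = 0.05, width = 0.012,
                            period = 0.8, fs = 2000) {
  n <- round(period * fs)
  t <- (seq_len(n) - 1L) / fs
  waveform(t, q_peak * exp(-((t - t0) / width)^2), kind = "Q")
}

## rebound of a decaying tail: zero for a monotone decay, positive when a
## secondary (reflected) wave interrupts it
rebound <- function(y) max(y - cummin(y))

## uniform frictionless tube with an impedance-matched, fast-draining
## outlet (R2 << Z0 so even the pulse low-frequency content is absorbed),
## excited by a compact gaussian flow pulse
pulse_tube_sim <- function() {
  net <- uniform_tube(length = 1.2, c_d = 8, viscosity = 1e-6,
                      R2 = 2e6, C = 1e-9,
                      sites = tibble::tibble(
                        site = c("a", "b"), segment = "tube",
                        fraction = c(0.15, 0.85), ppg = NA_character_))
  suppressWarnings(simulate_subject(
    net, gaussian_inflow(), p_diastolic = 0,
    options = solver_options(max_cycles = 3, output_fs = 2000,
                             dx_max = 0.004)))
}

baseline_sim <- function(age) {
  cached(paste0("baseline", age), simulate_virtual_subject(age))
}

baseline_index <- function(age) {
  cached(paste0("index", age), analyze_subject(baseline_sim(age)))
}
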