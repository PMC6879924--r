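## Arterial network: segments, junctions, terminal windkessels, and the
## constitutive laws tying diastolic geometry to wall mechanics.
##
## All computation is in SI units. The empirical wall-law constants are
## conventionally quoted in CGS in the haemodynamics literature;
## stiffness_constants_si() performs the conversion at the config boundary.

#' Diastolic radius along a linearly tapered segment
#'
#' Segments taper linearly in diameter between their inlet and outlet.
#'
#' @param r_in,r_out Inlet and outlet diastolic radii, m.
#' @param x Axial fraction(s) in \[0, 1\].
#' @return Radius in m, vectorised over `x`.
#' @export
#' @examples
#' radius_at(0.01, 0.008, 0.5) # 0.009
radius_at <- function(r_in, r_out, x) {
  if (any(x < 0 | x > 1)) abort("axial fraction `x` must lie in [0, 1]")
  if (any(r_in <= 0) || any(r_out <= 0)) abort("radii must be > 0")
  r_in + (r_out - r_in) * x
}

#' Wall stiffness law Eh(Rd)
#'
#' The product of Young's modulus and wall thickness is modelled as an
#' empirical function of diastolic radius,
#' `Eh = Rd * (k1 * exp(k2 * Rd) + k3)`, shared by all segments of a
#' network. With SI constants (`k1`, `k3` in Pa; `k2` in 1/m) the result is
#' in N/m.
#'
#' @param Rd Diastolic radius, m.
#' @param k1,k2,k3 Empirical constants (SI units).
#' @return Eh in N/m.
#' @export
wall_stiffness <- function(Rd, k1, k2, k3) {
  if (any(Rd <= 0)) abort("`Rd` must be > 0")
  Rd * (k1 * exp(k2 * Rd) + k3)
}

#' Convert CGS wall-law constants to SI
#'
#' Literature values of the stiffness constants are quoted in CGS
#' (`k1`, `k3` in g s^-2 cm^-1, i.e. dyn/cm^2; `k2` in cm^-1). This converts
#' them to the SI units used internally (Pa, 1/m).
#'
#' @param k1,k2,k3 Constants in CGS units.
#' @return Named list with SI `k1`, `k2`, `k3`.
#' @export
#' @examples
#' stiffness_constants_si(k1 = 2e6, k2 = -22.53, k3 = 8.65e5)
stiffness_constants_si <- function(k1, k2, k3) {
  ## 1 dyn/cm^2 = 0.1 Pa; 1 cm^-1 = 100 m^-1
  list(k1 = k1 * 0.1, k2 = k2 * 100, k3 = k3 * 0.1)
}

#' Theoretical diastolic wave speed
#'
#' Speed of small pressure disturbances about the diastolic state,
#' `c_d = sqrt(2 * Eh / (3 * rho * Rd))`.
#'
#' @param Eh Wall stiffness, N/m.
#' @param Rd Diastolic radius, m.
#' @param rho Blood density, kg/m^3.
#' @return Wave speed, m/s.
#' @export
#' @examples
#' wave_speed(400, 0.01, 1060)
wave_speed <- function(Eh, Rd, rho = 1060) {
  if (any(Eh <= 0) || any(Rd <= 0) || any(rho <= 0)) {
    abort("all arguments of wave_speed() must be > 0")
  }
  sqrt(2 * Eh / (3 * rho * Rd))
}

#' Wall viscosity law
#'
#' Voigt-type wall viscosity coefficient as a function of diastolic radius,
#' `Gamma = b1 / (2 * Rd\[cm\]) + b0`, returned in g/s as conventionally
#' quoted. Defaults `b1 = 150` g cm/s and `b0 = 600` g/s give realistic
#' hysteresis in peripheral pressure-area loops.
#'
#' @param Rd Diastolic radius, m.
#' @param b0 Constant term, g/s.
#' @param b1 Radius-dependent term, g cm/s.
#' @return Gamma in g/s.
#' @export
#' @examples
#' wall_viscosity(0.0075) # 700 g/s
wall_viscosity <- function(Rd, b0 = 600, b1 = 150) {
  if (any(Rd <= 0)) abort("`Rd` must be > 0")
  b1 / (2 * (Rd * 100)) + b0
}

## ---------------------------------------------------------------------------
## Network container

#' Assemble and validate an arterial network
#'
#' @param segments Tibble with columns `id`, `length` (m), `r_in`, `r_out`
#'   (diastolic radii, m), the wall-law constants `k1`, `k2`, `k3` (SI),
#'   `b0`, `b1`, and optionally `diam_class` / `len_class` (which aging
#'   factor scales the segment) and `n_nodes`.
#' @param junctions Tibble with columns `parent`, `daughter` (one row per
#'   parent-daughter edge).
#' @param outlets Tibble with columns `segment`, `R1`, `R2` (Pa s m^-3),
#'   `C` (m^3/Pa), `P_out` (Pa), and optionally `bed` and `bed_fraction`.
#' @param inlet Id of the inlet (aortic root) segment.
#' @param sites Tibble with columns `site`, `segment`, `fraction`, and
#'   optionally `ppg` ("windkessel" or "segment") marking sites where a PPG
#'   is synthesised.
#' @param blood A [blood_properties()] object.
#' @return A validated object of class `pw_network`.
#' @export
pw_network <- function(segments, junctions, outlets, inlet, sites,
                       blood = blood_properties()) {
  segments <- as_tibble(segments)
  junctions <- as_tibble(junctions)
  outlets <- as_tibble(outlets)
  sites <- as_tibble(sites)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(sprintf("network config error: %s missing field(s): %s",
                    what, paste(miss, collapse = ", ")))
    }
  }
  need(segments, c("id", "length", "r_in", "r_out", "k1", "k2", "k3", "b0", "b1"),
       "segments")
  need(junctions, c("parent", "daughter"), "junctions")
  need(outlets, c("segment", "R1", "R2", "C", "P_out"), "outlets")
  need(sites, c("site", "segment", "fraction"), "sites")
  if (!"ppg" %in% names(sites)) sites$ppg <- NA_character_
  if (!"diam_class" %in% names(segments)) segments$diam_class <- NA_character_
  if (!"len_class" %in% names(segments)) segments$len_class <- NA_character_

  if (anyDuplicated(segments$id)) abort("network config error: duplicate segment ids")
  if (any(segments$length <= 0)) abort("network config error: segment lengths must be > 0")
  if (any(segments$r_in <= 0) || any(segments$r_out <= 0)) {
    abort("network config error: segment radii must be > 0")
  }
  if (any(outlets$R1 <= 0) || any(outlets$R2 <= 0) || any(outlets$C <= 0)) {
    abort("network config error: windkessel R1, R2, C must be > 0")
  }

  ids <- segments$id
  bad <- setdiff(unique(c(junctions$parent, junctions$daughter)), ids)
  if (length(bad)) {
    abort(sprintf("network topology error: junction references unknown segment(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!inlet %in% ids) abort("network topology error: inlet segment not found")
  if (!all(outlets$segment %in% ids)) abort("network topology error: outlet on unknown segment")
  if (!all(sites$segment %in% ids)) abort("network config error: site on unknown segment")
  if (any(sites$fraction < 0 | sites$fraction > 1)) {
    abort("network config error: site fractions must lie in [0, 1]")
  }

  ## rooted-tree checks: each daughter appears once, inlet is nobody's daughter
  if (anyDuplicated(junctions$daughter)) {
    abort("network topology error: a segment is daughter of two junctions")
  }
  if (inlet %in% junctions$daughter) {
    abort("network topology error: inlet segment cannot be a junction daughter")
  }
  reached <- inlet
  frontier <- inlet
  while (length(frontier)) {
    nxt <- junctions$daughter[junctions$parent %in% frontier]
    nxt <- setdiff(nxt, reached)
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  if (!setequal(reached, ids)) {
    abort(sprintf("network topology error: segment(s) not connected to inlet: %s",
                  paste(setdiff(ids, reached), collapse = ", ")))
  }
  terminals <- setdiff(ids, unique(junctions$parent))
  if (!setequal(terminals, outlets$segment)) {
    abort(paste0("network topology error: every terminal segment needs exactly one ",
                 "windkessel outlet (terminals: ", paste(terminals, collapse = ", "),
                 "; outlets: ", paste(outlets$segment, collapse = ", "), ")"))
  }
  if (anyDuplicated(outlets$segment)) {
    abort("network topology error: multiple outlets on one segment")
  }

  structure(
    list(segments = segments, junctions = junctions, outlets = outlets,
         inlet = inlet, sites = sites, blood = blood),
    class = "pw_network"
  )
}

#' @export
print.pw_network <- function(x, ...) {
  cat(sprintf(
    "<pw_network> %d segments, %d junctions, %d outlets, %d sites (inlet: %s)\n",
    nrow(x$segments), length(unique(x$junctions$parent)), nrow(x$outlets),
    nrow(x$sites), x$inlet))
  invisible(x)
}

#' Load / save an arterial network as JSON
#'
#' The JSON schema has tables `segments`, `junctions` (parent with a
#' `daughters` array), `outlets` and `sites`, plus a `units` header
#' declaring the SI unit system; [save_network()] writes the same schema so
#' load/save round-trips.
#'
#' @param path Path of a JSON network config.
#' @return A `pw_network`.
#' @export
load_network <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (f in c("segments", "junctions", "outlets", "sites", "inlet")) {
    if (is.null(cfg[[f]])) abort(sprintf("network config error: missing field `%s`", f))
  }
  jn <- as_tibble(cfg$junctions)
  junctions <- tidyr::unnest(
    tibble(parent = jn$parent, daughter = jn$daughters), "daughter")
  blood <- if (!is.null(cfg$blood)) {
    blood_properties(cfg$blood$density, cfg$blood$viscosity)
  } else {
    blood_properties()
  }
  pw_network(as_tibble(cfg$segments), junctions, as_tibble(cfg$outlets),
             cfg$inlet, as_tibble(cfg$sites), blood)
}

#' @rdname load_network
#' @param network A `pw_network`.
#' @export
save_network <- function(network, path) {
  jn <- network$junctions
  parents <- unique(jn$parent)
  junctions <- lapply(parents, function(p) {
    list(parent = p, daughters = jn$daughter[jn$parent == p])
  })
  cfg <- list(
    units = list(length = "m", radius = "m", stiffness = "Pa (k1,k3), 1/m (k2)",
                 wall_viscosity = "g/s (b0), g.cm/s (b1)",
                 resistance = "Pa.s.m-3", compliance = "m3.Pa-1", pressure = "Pa"),
    inlet = network$inlet,
    segments = network$segments,
    junctions = junctions,
    outlets = network$outlets,
    sites = network$sites,
    blood = list(density = network$blood$density,
                 viscosity = network$blood$viscosity)
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## number of nodes for a segment: spacing <= dx_max, at least 3 nodes
segment_nodes <- function(length, dx_max = 0.025) {
  pmax(3L, as.integer(ceiling(length / dx_max)) + 1L)
}

## effective (length-weighted mean) diastolic radius along a path of segments
effective_path_radius <- function(network, segment_ids) {
  seg <- network$segments[match(segment_ids, network$segments$id), ]
  sum(seg$length * (seg$r_in + seg$r_out) / 2) / sum(seg$length)
}

path_length <- function(network, segment_ids) {
  sum(network$segments$length[match(segment_ids, network$segments$id)])
}

## segment ids along the root->terminal path containing `segment`
path_to_segment <- function(network, segment) {
  path <- segment
  jn <- network$junctions
  while (path[1L] != network$inlet) {
    up <- jn$parent[jn$daughter == path[1L]]
    if (!length(up)) abort("segment is not connected to the inlet")
    path <- c(up, path)
  }
  path
}
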