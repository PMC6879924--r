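## Deterministic anatomically shaped fixture networks. The reduced network
## covers the main measurement paths (aorta in four tapering segments, one
## arm path, one leg path, one carotid-temporal path) so every downstream
## analysis runs on it; the tiny network is a minimal bifurcation for fast
## solver checks. Geometry is the 25-yr baseline; build_subject() rescales
## it per age and offset.

reduced_geometry <- function() {
  tibble(
    id = c("ascending_aorta", "aortic_arch", "thoracic_aorta",
           "abdominal_aorta", "visceral", "arm", "leg", "contra_iliac",
           "carotid", "tibial", "radial", "ulnar", "temporal"),
    length = c(0.040, 0.040, 0.160, 0.150, 0.060, 0.400, 0.400, 0.080,
               0.150, 0.350, 0.250, 0.250, 0.100),
    r_in  = c(0.01835, 0.01750, 0.01350, 0.01000, 0.00950, 0.00400,
              0.00520, 0.00520, 0.00305, 0.00300, 0.00170, 0.00170,
              0.00290),
    r_out = c(0.01750, 0.01350, 0.01220, 0.00725, 0.00850, 0.00280,
              0.00390, 0.00500, 0.00305, 0.00250, 0.00150, 0.00150,
              0.00240),
    diam_class = c("asc_aorta_diam", "asc_aorta_diam", "desc_thor_diam",
                   "abd_aorta_diam", NA, NA, NA, NA, "carotid_diam",
                   NA, NA, NA, NA),
    len_class = c("prox_aortic_length", "prox_aortic_length",
                  NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA)
  )
}

reduced_junctions <- function() {
  tibble(
    parent = c("ascending_aorta", "ascending_aorta", "aortic_arch",
               "aortic_arch", "thoracic_aorta", "thoracic_aorta",
               "abdominal_aorta", "abdominal_aorta", "arm", "arm", "leg",
               "carotid"),
    daughter = c("aortic_arch", "carotid", "thoracic_aorta", "arm",
                 "abdominal_aorta", "visceral", "leg", "contra_iliac",
                 "radial", "ulnar", "tibial", "temporal")
  )
}

reduced_sites <- function() {
  tibble(
    site = c("aortic_root", "carotid", "brachial", "radial", "femoral",
             "ankle", "iliac_bifurcation", "finger", "toe", "temporal"),
    segment = c("ascending_aorta", "carotid", "arm", "radial", "leg",
                "tibial", "abdominal_aorta", "radial", "tibial", "temporal"),
    fraction = c(0, 0.5, 0.9, 0.8, 0.9, 0.95, 1, 1, 1, 0.9),
    ppg = c(NA, NA, NA, NA, NA, NA, NA, "windkessel", "windkessel",
            "windkessel")
  )
}

## baseline fractions of cardiac output taken by each vascular bed; the
## contralateral-iliac outlet stands in for all abdominal/contralateral
## beds absent from the reduced network
reduced_outlets <- function() {
  tibble(
    segment = c("visceral", "contra_iliac", "tibial", "radial", "ulnar",
                "temporal"),
    bed = c("visceral", "contra_leg", "leg", "arm", "arm", "head"),
    bed_fraction = c(0.55, 0.17, 0.08, 0.04, 0.04, 0.12),
    R1 = 1, R2 = 1, C = 1, P_out = 0
  )
}

#' Measurement paths of a fixture network
#'
#' Chains of segment ids along which path-averaged wave speeds are
#' calibrated and foot-to-foot transit times measured.
#'
#' @param network A fixture `pw_network`.
#' @return Named list of character vectors (`aortic`, `arm`, `leg`).
#' @export
network_paths <- function(network) {
  attr(network, "paths") %||%
    abort("network carries no measurement path metadata")
}

#' Build a deterministic fixture arterial network
#'
#' `"tiny"` is a single bifurcation (3 segments, 1 junction, 2 outlets)
#' for solver unit checks. `"reduced"` is a 12-segment anatomically shaped
#' network: aorta in four tapering segments (root to iliac bifurcation)
#' with a large visceral bed off the distal thoracic aorta,
#' subclavian-brachial-radial arm path with an ulnar branch,
#' iliac-femoral-tibial leg path plus the contralateral iliac,
#' carotid-temporal head path, with named measurement sites including
#' peripheral PPG sites. Wall stiffness is calibrated to the 25-yr
#' baseline PWV targets and the windkessels to the 25-yr baseline MAP.
#'
#' @param scale `"tiny"` or `"reduced"`.
#' @return A calibrated `pw_network` (25-yr baseline) with a `paths`
#'   attribute.
#' @export
#' @examples
#' net <- make_fixture_network("tiny")
make_fixture_network <- function(scale = c("reduced", "tiny")) {
  scale <- match.arg(scale)
  base <- aging_parameters(25)
  cfg <- apply_offsets(base)
  if (scale == "tiny") {
    segments <- tibble(
      id = c("aorta", "branch_a", "branch_b"),
      length = c(0.20, 0.40, 0.40),
      r_in = c(0.0120, 0.0040, 0.0040),
      r_out = c(0.0100, 0.0025, 0.0025),
      diam_class = NA_character_, len_class = NA_character_
    )
    junctions <- tibble(parent = "aorta", daughter = c("branch_a", "branch_b"))
    outlets <- tibble(segment = c("branch_a", "branch_b"),
                      bed = c("a", "b"), bed_fraction = c(0.5, 0.5),
                      R1 = 1, R2 = 1, C = 1, P_out = 0)
    sites <- tibble(site = c("aortic_root", "branch_a_end"),
                    segment = c("aorta", "branch_a"),
                    fraction = c(0, 0.9), ppg = NA_character_)
    paths <- list(aortic = "aorta", arm = "branch_a", leg = "branch_b")
  } else {
    segments <- reduced_geometry()
    junctions <- reduced_junctions()
    outlets <- reduced_outlets()
    sites <- reduced_sites()
    paths <- list(
      aortic = c("ascending_aorta", "aortic_arch", "thoracic_aorta",
                 "abdominal_aorta"),
      arm = c("arm", "radial"),
      leg = c("leg", "tibial")
    )
  }
  segments$k1 <- 0; segments$k2 <- 0; segments$k3 <- 1e5  # placeholder
  segments$b0 <- 600; segments$b1 <- 150
  net <- pw_network(segments, junctions, outlets, segments$id[1L], sites)
  attr(net, "paths") <- paths
  net <- calibrate_network_stiffness(
    net, targets = c(cfg$pwv_aortic, cfg$pwv_arm, cfg$pwv_leg),
    paths = paths)
  net <- calibrate_resistances(
    net, map_target = cfg$map, co = cfg$hr * cfg$sv / 1000,
    pvc_total = cfg$pvc * PVC_UNIT)
  attr(net, "paths") <- paths
  net
}

## ---------------------------------------------------------------------------
## Subject construction

#' Build one virtual subject
#'
#' Applies the aging model to the base (25-yr baseline) network: scales the
#' age-varying diameters (aorta and carotid) and the proximal aortic
#' length, shifts the six varied parameters by their offsets, evaluates
#' the aortic PWV target at the subject's MAP, recalibrates wall stiffness
#' to the subject's PWV targets and the windkessel outlets to the
#' subject's MAP and cardiac output, and generates the matching aortic
#' inflow waveform.
#'
#' @param age Age, years (25-75).
#' @param offsets Named offsets in \{-1, 0, 1\} on [varied_factors()];
#'   `NULL` for the baseline subject.
#' @param base_network Base network at the 25-yr baseline geometry;
#'   default [make_fixture_network()] (cached).
#' @param lvet_mode See [apply_offsets()].
#' @param pwv_map_slope Relative PWV-target change per mmHg of MAP
#'   deviation, see [pwv_at_map()].
#' @param hold_outlets Optional outlet table (from the age-matched
#'   baseline network) to impose instead of recalibrating the windkessels
#'   to the subject's MAP and CO. Database subjects control MAP as its own
#'   factor (default NULL = recalibrate); acute perturbation studies that
#'   let MAP respond passively to cardiac changes pass the baseline
#'   outlets.
#' @return List of class `pw_subject`: `config` (one-row tibble of
#'   absolute parameter values), `network` (calibrated), `inflow`
#'   (waveform), `paths`.
#' @export
#' @examples
#' \donttest{
#' subj <- build_subject(25)
#' }
build_subject <- function(age, offsets = NULL,
                          base_network = default_base_network(),
                          lvet_mode = "deviation", pwv_map_slope = 0.01,
                          hold_outlets = NULL) {
  params <- aging_parameters(age)
  cfg <- apply_offsets(params, offsets, lvet_mode = lvet_mode)
  base25 <- apply_offsets(aging_parameters(25))
  net <- base_network
  seg <- net$segments

  ## geometry scaling relative to the 25-yr baseline the fixture encodes
  diam_scale <- c(
    asc_aorta_diam = cfg$asc_aorta_diam / base25$asc_aorta_diam,
    desc_thor_diam = cfg$desc_thor_diam / base25$desc_thor_diam,
    abd_aorta_diam = cfg$abd_aorta_diam / base25$abd_aorta_diam,
    carotid_diam = cfg$carotid_diam / base25$carotid_diam
  )
  len_scale <- c(prox_aortic_length = cfg$prox_aortic_length / base25$prox_aortic_length)
  for (i in seq_len(nrow(seg))) {
    dc <- seg$diam_class[i]
    if (!is.na(dc) && dc %in% names(diam_scale)) {
      seg$r_in[i] <- seg$r_in[i] * diam_scale[[dc]]
      seg$r_out[i] <- seg$r_out[i] * diam_scale[[dc]]
    }
    lc <- seg$len_class[i]
    if (!is.na(lc) && lc %in% names(len_scale)) {
      seg$length[i] <- seg$length[i] * len_scale[[lc]]
    }
  }
  net$segments <- seg

  paths <- network_paths(base_network)
  map_factor <- pwv_at_map(1, cfg$map, params$mean[params$parameter == "map"],
                           slope = pwv_map_slope)
  targets <- c(cfg$pwv_aortic, cfg$pwv_arm, cfg$pwv_leg) * map_factor
  net <- calibrate_network_stiffness(net, targets, paths)
  if (!is.null(hold_outlets)) {
    ## acute-perturbation mode: the vascular beds keep their age-baseline
    ## calibration, so mean pressure responds passively to the cardiac
    ## change (used by the CO-tracking case study)
    net$outlets <- hold_outlets
  } else {
    net <- calibrate_resistances(net, map_target = cfg$map,
                                 co = cfg$hr * cfg$sv / 1000,
                                 pvc_total = cfg$pvc * PVC_UNIT)
  }
  attr(net, "paths") <- paths

  inflow <- generate_inflow(cfg)
  structure(list(config = cfg, network = net, inflow = inflow, paths = paths),
            class = "pw_subject")
}

#' @export
print.pw_subject <- function(x, ...) {
  cat(sprintf("<pw_subject> age %g yr; HR %.1f, SV %.1f ml, LVET %.0f ms, MAP %.1f mmHg\n",
              x$config$age, x$config$hr, x$config$sv, x$config$lvet,
              x$config$map))
  invisible(x)
}

## base network cache (geometry construction + calibration is deterministic)
default_base_network <- function() {
  if (is.null(the$base_network)) the$base_network <- make_fixture_network("reduced")
  the$base_network
}

#' Simulate one virtual subject end to end
#'
#' Convenience wrapper: [build_subject()] then [simulate_subject()] with
#' the subject's diastolic pressure as tube-law reference.
#'
#' @inheritParams build_subject
#' @param options [solver_options()].
#' @return A `pw_pulse_set` with the subject `config` attached as
#'   attribute.
#' @export
simulate_virtual_subject <- function(age, offsets = NULL,
                                     base_network = default_base_network(),
                                     options = solver_options(), ...) {
  subj <- build_subject(age, offsets, base_network = base_network, ...)
  pws <- simulate_subject(subj$network, subj$inflow, options = options,
                          p_diastolic = subj$config$dbp)
  attr(pws, "config") <- subj$config
  attr(pws, "paths") <- subj$paths
  attr(pws, "network") <- subj$network
  pws
}
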