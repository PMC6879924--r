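## ggplot2 visualisations of simulation results.

#' Plot a simulated pulse wave set
#'
#' Facets the P/U/A/Q/PPG waves by signal kind and site. Pressures are
#' shown in mmHg.
#'
#' @param object A `pw_pulse_set`.
#' @param sites Sites to show (default all).
#' @param kinds Signal kinds to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pw_pulse_set <- function(object, sites = NULL,
                                  kinds = c("P", "U", "Q", "PPG"), ...) {
  d <- as_tibble(object)
  if (!is.null(sites)) d <- d[d$site %in% sites, ]
  d <- d[d$kind %in% kinds, ]
  d$y[d$kind == "P"] <- pa_to_mmhg(d$y[d$kind == "P"])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$y, colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Simulated pulse waves (one converged cycle)") +
    ggplot2::theme_minimal()
}

#' Plot a waveform with its fiducial points
#'
#' @param object A `pw_fiducials` tibble.
#' @param wave The waveform it was computed from.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pw_fiducials <- function(object, wave, ...) {
  fid <- as_tibble(object)
  fid <- fid[!is.na(fid$t) & !fid$point %in% c("a", "b", "c", "d", "e"), ]
  ggplot2::ggplot(wave, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = fid, colour = "red") +
    ggplot2::geom_text(data = fid, ggplot2::aes(label = .data$point),
                       vjust = -0.7, size = 3) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot estimated versus reference cardiac output
#'
#' @param object A `pw_co_assessment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pw_co_assessment <- function(object, ...) {
  est <- object$estimates[object$estimates$group != "baseline", ]
  d <- tidyr::pivot_longer(est, cols = c("co_rms", "co_pp"),
                           names_to = "algorithm", values_to = "co_est")
  d$algorithm <- toupper(sub("co_", "", d$algorithm))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$co_ref, y = .data$co_est,
                                  colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$algorithm)) +
    ggplot2::labs(x = "reference CO (l/min)", y = "estimated CO (l/min)",
                  colour = "varied") +
    ggplot2::theme_minimal()
}

#' Plot an index across age from a database index table
#'
#' @param index_tbl Index table (e.g. `db$index`).
#' @param index_name Column to plot.
#' @return A ggplot of per-age means +/- SD.
#' @export
plot_index_by_age <- function(index_tbl, index_name) {
  d <- index_tbl |>
    group_by(.data$age) |>
    summarise(m = mean(.data[[index_name]], na.rm = TRUE),
              s = sd(.data[[index_name]], na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "age (yr)", y = index_name) +
    ggplot2::theme_minimal()
}
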