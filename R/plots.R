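# Tidiers and ggplot2 visualisations for simulation results.

#' Tidy a simulated trajectory
#'
#' `tidy()` returns one row per (time, compartment) with volume, pressure
#' and osmolarity; `tidy_fluxes()` one row per (time, arc).
#'
#' @param x A `csf_trajectory` from [csf_integrate()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy csf_trajectory
#' @export
tidy.csf_trajectory <- function(x, ...) {
  m <- x$model
  S <- nrow(m$species)
  phi_n <- m$species$osmotic_coeff_phi * m$species$dissociation_n
  rows <- lapply(seq_along(.csf_compartments), function(i) {
    comp <- .csf_compartments[i]
    V <- x$states[, paste0("V_", comp)]
    A <- x$states[, paste0("A_", comp, "_", m$species$name), drop = FALSE]
    osm <- as.vector((1000 * A / V) %*% phi_n)
    tibble::tibble(time = x$times, compartment = comp, volume = V,
                   pressure = x$aux[, paste0("P_", comp)], osmolarity = osm)
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.csf_trajectory
#' @export
tidy_fluxes <- function(x, ...) {
  stopifnot(inherits(x, "csf_trajectory"))
  arc_ids <- names(x$model$arcs)
  dplyr::bind_rows(lapply(arc_ids, function(a) {
    tibble::tibble(time = x$times, arc = a, flux = x$aux[, paste0("flux_", a)])
  }))
}

#' Tidy a per-species concentration table from a trajectory
#'
#' @param x A `csf_trajectory`.
#' @param compartments Compartments to include (default all).
#' @return A tibble with time, compartment, species, concentration (mmol/L).
#' @export
tidy_concentrations <- function(x, compartments = .csf_compartments) {
  m <- x$model
  dplyr::bind_rows(lapply(compartments, function(comp) {
    V <- x$states[, paste0("V_", comp)]
    dplyr::bind_rows(lapply(m$species$name, function(s) {
      tibble::tibble(time = x$times, compartment = comp, species = s,
                     concentration = 1000 * x$states[, paste0("A_", comp, "_", s)] / V)
    }))
  }))
}

#' Plot methods
#'
#' `autoplot()` methods give quick-look figures: compartment state
#' trajectories, osmotic dose-response curves, chronic ventricular volume
#' time courses, and tracer accumulation curves.
#'
#' @param object A result object (`csf_trajectory`, `csf_dose_response`,
#'   `csf_chronic`, `csf_tracer_study`).
#' @param vars For trajectories: which panel variable to draw
#'   (`"volume"`, `"pressure"` or `"osmolarity"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @name autoplot.csfnet
NULL

#' @rdname autoplot.csfnet
#' @method autoplot csf_trajectory
#' @export
autoplot.csf_trajectory <- function(object,
                                    vars = c("volume", "pressure",
                                             "osmolarity"), ...) {
  vars <- match.arg(vars)
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data[[vars]],
                                  colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [min]",
                  y = switch(vars, volume = "volume [µL]",
                             pressure = "pressure [mmHg]",
                             osmolarity = "osmolarity [mOsm]")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.csfnet
#' @method autoplot csf_dose_response
#' @export
autoplot.csf_dose_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$osmolarity, y = .data$Q_f)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = paste(object$site[1], "osmolarity [mOsm]"),
                  y = "nascent flow [µL/min]") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.csfnet
#' @method autoplot csf_chronic
#' @export
autoplot.csf_chronic <- function(object, ...) {
  ggplot2::ggplot(object$timecourse,
                  ggplot2::aes(x = .data$time_day, y = .data$pct_increase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [days]", y = "ventricular volume increase [%]") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.csfnet
#' @method autoplot csf_tracer_study
#' @export
autoplot.csf_tracer_study <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$tracer_ventricles,
                               colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [min]", y = "ventricular tracer amount") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL

#' Tidy a perfusion record
#'
#' One-row tibble with the perfusion inputs, the measured outflow record,
#' and the estimator outputs.
#'
#' @param x A `csf_vcp` from [run_vcp()].
#' @param ... Unused.
#' @method tidy csf_vcp
#' @export
tidy.csf_vcp <- function(x, ...) {
  tibble::tibble(perfusate_osm = x$perfusate_osm, serum_osm = x$serum_osm,
                 Q_inj = x$Q_inj, C_inj = x$C_inj, Q_out = x$Q_out,
                 C_out = x$C_out, Q_f = x$Q_f, Q_SAS = x$Q_SAS,
                 Q_nascent_true = x$Q_nascent_true)
}
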