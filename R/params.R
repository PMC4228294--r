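# Flat parameter access on model configurations.
#
# Calibration addresses scalar parameters by path strings:
#   "<arc>.LpA"              hydraulic conductivity of a starling arc
#   "<arc>.alpha"            resistance of a luminal/darcy/boundary arc
#   "<arc>.sigma.<species>"  reflection coefficient
#   "<arc>.pump.<species>"   active-transport rate, µmol/min
#   "<compartment>.kappa"    compliance, µL/mmHg
#   "metabolic.G"            direct metabolic water override, µL/min
#   "metabolic.k_gluc"       glucose destruction constant, 1/min
#   "boundary.<species>"     arterial boundary concentration, mmol/L

.find_arc <- function(config, id) {
  for (i in seq_along(config$arcs)) if (config$arcs[[i]]$id == id) return(i)
  stop("unknown arc '", id, "' in parameter path")
}

.find_comp <- function(config, id) {
  for (i in seq_along(config$compartments)) {
    if (config$compartments[[i]]$id == id) return(i)
  }
  stop("unknown compartment '", id, "' in parameter path")
}

#' Read scalar parameters from a configuration by path
#'
#' @param config A configuration list (or `csf_model`, whose configuration
#'   is used).
#' @param paths Character vector of parameter paths (see Details in
#'   [csf_update_params()]).
#' @return Named numeric vector of parameter values.
#' @export
csf_get_params <- function(config, paths) {
  if (inherits(config, "csf_model")) config <- config$config
  out <- vapply(paths, function(p) {
    parts <- strsplit(p, ".", fixed = TRUE)[[1]]
    if (parts[1] == "metabolic") {
      return(switch(parts[2],
                    G = config$metabolic$direct_G_override %||% NA_real_,
                    k_gluc = config$metabolic$k_gluc %||% 0,
                    nu = config$metabolic$nu_water_per_glucose %||% 0,
                    stop("unknown metabolic field '", parts[2], "'")))
    }
    if (parts[1] == "boundary") {
      v <- config$boundaries$arterial_concentrations[[parts[2]]]
      if (is.null(v)) stop("no boundary concentration for '", parts[2], "'")
      return(v)
    }
    if (length(parts) >= 2 && parts[2] == "kappa") {
      return(config$compartments[[.find_comp(config, parts[1])]]$compliance_kappa)
    }
    a <- config$arcs[[.find_arc(config, parts[1])]]
    switch(parts[2],
           LpA = a$LpA,
           alpha = a$resistance_alpha,
           sigma = a$sigma[[parts[3]]] %||% 1,
           pump = a$pump[[parts[3]]] %||% 0,
           stop("unknown arc field '", parts[2], "'"))
  }, 0)
  stats::setNames(out, paths)
}

#' Update scalar parameters of a configuration by path
#'
#' Paths take the forms `"<arc>.LpA"`, `"<arc>.alpha"`,
#' `"<arc>.sigma.<species>"`, `"<arc>.pump.<species>"`,
#' `"<compartment>.kappa"`, `"metabolic.G"`, `"metabolic.k_gluc"`, and
#' `"boundary.<species>"`.
#'
#' @param config A configuration list or `csf_model`.
#' @param values Named numeric vector; names are parameter paths.
#' @param as_model If `TRUE`, return the rebuilt `csf_model`.
#' @return Updated configuration list or `csf_model`.
#' @export
csf_update_params <- function(config, values, as_model = inherits(config, "csf_model")) {
  force(as_model)
  if (inherits(config, "csf_model")) config <- config$config
  for (p in names(values)) {
    v <- unname(values[[p]])
    parts <- strsplit(p, ".", fixed = TRUE)[[1]]
    if (parts[1] == "metabolic") {
      config$metabolic[[switch(parts[2], G = "direct_G_override",
                               k_gluc = "k_gluc", nu = "nu_water_per_glucose",
                               stop("unknown metabolic field"))]] <- v
    } else if (parts[1] == "boundary") {
      config$boundaries$arterial_concentrations[[parts[2]]] <- v
    } else if (length(parts) >= 2 && parts[2] == "kappa") {
      config$compartments[[.find_comp(config, parts[1])]]$compliance_kappa <- v
    } else {
      i <- .find_arc(config, parts[1])
      config$arcs[[i]][[switch(parts[2],
                               LpA = "LpA", alpha = "resistance_alpha",
                               sigma = "sigma", pump = "pump",
                               stop("unknown arc field '", parts[2], "'"))]] <-
        if (parts[2] %in% c("sigma", "pump")) {
          lst <- config$arcs[[i]][[parts[2]]] %||% list()
          lst[[parts[3]]] <- v
          lst
        } else v
    }
  }
  if (as_model) build_canonical_network(config) else config
}
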