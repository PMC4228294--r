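# Network topology: 8 compartments, 12 arcs.
#
# Canonical arc map (fixed reference topology; alternatives loadable via
# config):
#   Q1  inlet   -> arteries     boundary (pressure-driven)
#   Q2  arteries -> arterioles  luminal
#   Q3  arterioles -> capillaries luminal
#   Q4  capillaries -> veins    luminal
#   Q5  veins   -> outlet       boundary
#   Q6  PVS     -> SAS          luminal
#   J7  arterioles -> ventricles  Starling (choroid plexus epithelium)
#   J8  capillaries -> PVS      Starling (blood-brain barrier)
#   Q9  PVS     -> ECS          Darcy (porous parenchymal interface)
#   J10 ECS     -> ventricles   Starling (ventricular ependyma)
#   Q11 ventricles -> SAS       luminal (aqueducts)
#   J12 SAS     -> veins        Starling, one-way (arachnoid granulations)

.csf_canonical_arcs <- data.frame(
  id   = c("Q1", "Q2", "Q3", "Q4", "Q5", "Q6",
           "J7", "J8", "Q9", "J10", "Q11", "J12"),
  kind = c("boundary", "luminal", "luminal", "luminal", "boundary", "luminal",
           "starling", "starling", "darcy", "starling", "luminal", "starling"),
  from = c("inlet", "arteries", "arterioles", "capillaries", "veins", "PVS",
           "arterioles", "capillaries", "PVS", "ECS", "ventricles", "SAS"),
  to   = c("arteries", "arterioles", "capillaries", "veins", "outlet", "SAS",
           "ventricles", "PVS", "ECS", "ventricles", "SAS", "veins"),
  stringsAsFactors = FALSE
)

#' Species table
#'
#' Canonical solute set.  `dissociation_n` is the number of particles per
#' formula unit (the ionic species are listed post-dissociation, so their
#' `n` is 1); `osmotic_coeff_phi` is the osmotic coefficient entering the
#' osmolarity sum.  The `tracer` species is the inert marker used by the
#' perfusion experiments.  Two inert loading solutes are distinguished
#' because the experiments use different agents at different sites and
#' their fitted reflection coefficients differ: `sucrose` (intraventricular
#' osmotic loading) and `mannitol` (intravenous loading; also the stand-in
#' for background impermeant plasma osmolytes).
#'
#' @param extra Optional data.frame with columns `name`, `dissociation_n`,
#'   `osmotic_coeff_phi` appended to the canonical set.
#' @return A data.frame with one row per species.
#' @export
csf_species <- function(extra = NULL) {
  base <- data.frame(
    name = c("albumin", "Na", "K", "Cl", "HCO3", "glucose", "sucrose",
             "mannitol", "tracer"),
    dissociation_n = 1,
    osmotic_coeff_phi = 1,
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) base <- rbind(base, extra)
  if (anyDuplicated(base$name)) stop("csf_species(): duplicate species name")
  if (any(base$dissociation_n < 1)) stop("csf_species(): dissociation_n must be >= 1")
  if (any(base$osmotic_coeff_phi <= 0 | base$osmotic_coeff_phi > 1.2)) {
    stop("csf_species(): osmotic_coeff_phi must lie in (0, 1.2]")
  }
  base
}

.known_config_keys <- c("name", "constants", "species", "compartments",
                        "arcs", "boundaries", "metabolic", "initial")

#' Build the canonical eight-compartment model from a configuration
#'
#' Validates a configuration list (typically read from YAML via
#' [read_csf_config()]) and assembles the simulation-ready model object:
#' resolved hydraulic resistances, per-species reflection coefficient and
#' active-transport (pump) vectors for every arc, compartment rest states,
#' and boundary conditions.
#'
#' @param config A configuration list with sections `constants`,
#'   `compartments`, `arcs`, `boundaries`, and optionally `species`,
#'   `metabolic`, `initial`, `name`.  Unknown top-level keys are rejected.
#' @return An object of class `csf_model`.
#' @export
build_canonical_network <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown)) {
    stop("build_canonical_network(): unknown config section(s): ",
         paste(unknown, collapse = ", "))
  }
  cst <- do.call(csf_constants, config$constants %||% list())

  species <- if (is.null(config$species)) csf_species() else {
    sp <- do.call(rbind, lapply(config$species, function(s) {
      data.frame(name = s$name,
                 dissociation_n = s$dissociation_n %||% 1,
                 osmotic_coeff_phi = s$osmotic_coeff_phi %||% 1,
                 stringsAsFactors = FALSE)
    }))
    if (any(sp$dissociation_n < 1) || any(sp$osmotic_coeff_phi <= 0)) {
      stop("build_canonical_network(): invalid species table ",
           "(dissociation_n >= 1, osmotic_coeff_phi > 0 required)")
    }
    sp
  }
  S <- nrow(species)

  ## --- compartments ----------------------------------------------------
  if (is.null(config$compartments)) stop("config lacks 'compartments'")
  comp_list <- config$compartments
  ids <- vapply(comp_list, function(x) x$id, "")
  missing_comp <- setdiff(.csf_compartments, ids)
  if (length(missing_comp)) {
    stop("build_canonical_network(): missing compartment(s): ",
         paste(missing_comp, collapse = ", "))
  }
  if (anyDuplicated(ids)) stop("duplicate compartment id")
  ord <- match(.csf_compartments, ids)
  comp_list <- comp_list[ord]
  comp <- data.frame(
    id = .csf_compartments,
    V0 = vapply(comp_list, function(x) as.numeric(x$rest_volume_V0), 0),
    P0 = vapply(comp_list, function(x) as.numeric(x$rest_pressure_P0), 0),
    kappa = vapply(comp_list, function(x) {
      if (isTRUE(x$rigid)) NA_real_ else as.numeric(x$compliance_kappa)
    }, 0),
    rigid = vapply(comp_list, function(x) isTRUE(x$rigid), TRUE),
    stringsAsFactors = FALSE
  )
  if (any(comp$V0 <= 0)) stop("rest_volume_V0 must be positive for every compartment")
  bad_kappa <- !comp$rigid & (is.na(comp$kappa) | comp$kappa <= 0)
  if (any(bad_kappa)) {
    stop("compliance_kappa must be positive for non-rigid compartment(s): ",
         paste(comp$id[bad_kappa], collapse = ", "))
  }

  ## --- arcs -------------------------------------------------------------
  if (is.null(config$arcs)) stop("config lacks 'arcs'")
  arc_ids <- vapply(config$arcs, function(a) a$id, "")
  if (anyDuplicated(arc_ids)) {
    stop("build_canonical_network(): duplicate arc id: ",
         paste(unique(arc_ids[duplicated(arc_ids)]), collapse = ", "))
  }
  arcs <- lapply(config$arcs, function(a) .resolve_arc(a, species))
  names(arcs) <- arc_ids

  node_of <- function(x) {
    if (x %in% c("inlet", "outlet")) return(0L)
    i <- match(x, .csf_compartments)
    if (is.na(i)) stop("build_canonical_network(): unknown compartment '", x,
                       "' referenced by an arc")
    i
  }
  for (a in seq_along(arcs)) {
    arcs[[a]]$from_idx <- node_of(arcs[[a]]$from)
    arcs[[a]]$to_idx <- node_of(arcs[[a]]$to)
  }

  ## --- boundaries -------------------------------------------------------
  b <- config$boundaries
  if (is.null(b)) stop("config lacks 'boundaries'")
  if (is.null(b$inlet_pressure) || is.null(b$outlet_pressure)) {
    stop("boundaries must provide inlet_pressure and outlet_pressure")
  }
  if (b$inlet_pressure <= b$outlet_pressure) {
    stop("boundaries: inlet_pressure must exceed outlet_pressure at baseline")
  }
  cart <- unlist(b$arterial_concentrations)
  conc_art <- stats::setNames(rep(0, S), species$name)
  if (length(cart)) {
    unk <- setdiff(names(cart), species$name)
    if (length(unk)) stop("boundaries: unknown species in arterial_concentrations: ",
                          paste(unk, collapse = ", "))
    conc_art[names(cart)] <- cart
  }
  boundaries <- list(inlet_pressure = as.numeric(b$inlet_pressure),
                     outlet_pressure = as.numeric(b$outlet_pressure),
                     arterial_concentrations = conc_art,
                     provided_species = names(cart))

  metabolic <- do.call(metabolic_params, config$metabolic %||% list())

  model <- structure(
    list(name = config$name %||% "unnamed",
         constants = cst, species = species, comp = comp, arcs = arcs,
         boundaries = boundaries, metabolic = metabolic,
         initial = config$initial, config = config),
    class = "csf_model"
  )
  rep <- validate_degrees_of_freedom(model)
  if (!rep$closed) {
    stop("build_canonical_network(): system not closed:\n  ",
         paste(rep$problems, collapse = "\n  "))
  }
  model
}

.resolve_arc <- function(a, species) {
  S <- nrow(species)
  kind <- match.arg(a$kind, c("luminal", "starling", "darcy", "boundary"))
  out <- list(id = a$id, kind = kind, from = a$from, to = a$to,
              one_way = isTRUE(a$one_way))
  sig <- stats::setNames(rep(1, S), species$name)
  pump <- stats::setNames(rep(0, S), species$name)
  if (kind %in% c("luminal", "boundary")) {
    if (!is.null(a$resistance_alpha)) {
      alpha <- as.numeric(a$resistance_alpha)
    } else if (!is.null(a$lumen_radius_R)) {
      alpha <- poiseuille_resistance(a$lumen_radius_R, a$lumen_length_L,
                                     a$viscosity_mu %||% 0.7)
    } else {
      stop("arc ", a$id, ": luminal arcs need resistance_alpha or lumen geometry")
    }
    if (alpha <= 0) stop("arc ", a$id, ": resistance_alpha must be positive")
    out$alpha <- alpha
    out$g <- 1 / alpha
  } else if (kind == "darcy") {
    if (!is.null(a$resistance_alpha)) {
      alpha <- as.numeric(a$resistance_alpha)
    } else if (!is.null(a$permeability_k)) {
      alpha <- darcy_resistance(a$permeability_k, a$area_A,
                                a$viscosity_mu %||% 0.7, a$path_length_L)
    } else {
      stop("arc ", a$id, ": darcy arcs need resistance_alpha or (permeability_k, area_A, path_length_L)")
    }
    if (alpha <= 0) stop("arc ", a$id, ": darcy resistance must be positive")
    out$alpha <- alpha
    out$g <- 1 / alpha
  } else { # starling
    if (is.null(a$LpA)) stop("arc ", a$id, ": starling arcs need LpA")
    if (a$LpA < 0) stop("arc ", a$id, ": LpA must be >= 0")
    out$LpA <- as.numeric(a$LpA)
    svals <- unlist(a$sigma)
    if (length(svals)) {
      unk <- setdiff(names(svals), species$name)
      if (length(unk)) stop("arc ", a$id, ": sigma given for unknown species ",
                            paste(unk, collapse = ", "))
      if (any(svals < 0 | svals > 1)) {
        stop("arc ", a$id, ": sigma for species '",
             paste(names(svals)[svals < 0 | svals > 1], collapse = ", "),
             "' outside [0, 1]")
      }
      sig[names(svals)] <- svals
    }
  }
  pvals <- unlist(a$pump)
  if (length(pvals)) {
    unk <- setdiff(names(pvals), species$name)
    if (length(unk)) stop("arc ", a$id, ": pump given for unknown species ",
                          paste(unk, collapse = ", "))
    pump[names(pvals)] <- pvals
  }
  out$sigma <- sig
  out$pump <- pump
  out
}

#' Check that the assembled ODE system is closed
#'
#' Confirms that every compartment has at least one inflow and one outflow
#' arc, that every arc is fully parameterized, and that the boundary
#' conditions (inlet/outlet pressures, arterial concentration for every
#' species) are present, so that each state variable has exactly one balance
#' equation.
#'
#' @param model A `csf_model`.
#' @return A list with elements `closed` (logical) and `problems`
#'   (character vector of findings, empty when closed).
#' @export
validate_degrees_of_freedom <- function(model) {
  problems <- character()
  comp <- model$comp
  n_in <- n_out <- stats::setNames(integer(nrow(comp)), comp$id)
  for (a in model$arcs) {
    if (a$from_idx > 0) n_out[a$from_idx] <- n_out[a$from_idx] + 1L
    if (a$to_idx > 0) n_in[a$to_idx] <- n_in[a$to_idx] + 1L
    ok <- switch(a$kind,
                 luminal = , boundary = , darcy = !is.null(a$g) && a$g >= 0,
                 starling = !is.null(a$LpA) && a$LpA >= 0)
    if (!ok) problems <- c(problems, paste0("arc ", a$id, " lacks a fully parameterized law"))
  }
  no_in <- comp$id[n_in == 0]
  no_out <- comp$id[n_out == 0]
  if (length(no_in)) {
    problems <- c(problems, paste0("compartment ", no_in,
                                   " volume balance has no inflow arc"))
  }
  if (length(no_out)) {
    problems <- c(problems, paste0("compartment ", no_out,
                                   " volume balance has no outflow arc"))
  }
  b <- model$boundaries
  if (is.null(b$inlet_pressure)) problems <- c(problems, "missing inlet_pressure boundary")
  if (is.null(b$outlet_pressure)) problems <- c(problems, "missing outlet_pressure boundary")
  missing_conc <- setdiff(model$species$name, b$provided_species %||% character())
  if (length(missing_conc)) {
    problems <- c(problems, paste0("missing arterial boundary concentration for ",
                                   missing_conc))
  }
  list(closed = length(problems) == 0, problems = problems)
}

#' @export
print.csf_model <- function(x, ...) {
  cat("<csf_model> '", x$name, "': ", nrow(x$comp), " compartments, ",
      length(x$arcs), " arcs, ", nrow(x$species), " species\n", sep = "")
  invisible(x)
}

#' Serialize a model back to its configuration list
#'
#' The inverse of [build_canonical_network()]: `build_canonical_network(
#' as_csf_config(model))` reproduces the model field-by-field.
#'
#' @param model A `csf_model`.
#' @return A configuration list suitable for [write_csf_config()].
#' @export
as_csf_config <- function(model) {
  model$config
}

#' Read / write model configurations
#'
#' Configurations are stored as YAML (JSON, a YAML subset, is also
#' accepted).  [read_csf_config()] returns the configuration list;
#' pass it to [build_canonical_network()] to obtain a runnable model.
#'
#' @param path File path.
#' @param config Configuration list.
#' @return The configuration list (`read_csf_config`) or `path`, invisibly
#'   (`write_csf_config`).
#' @export
read_csf_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown)) {
    stop("read_csf_config(): unknown config section(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  cfg
}

#' @rdname read_csf_config
#' @export
write_csf_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Load one of the shipped model configurations
#'
#' Four parameter sets ship with the package: `"human_baseline"`
#' (calibrated to the adult human operating point: 580 mL/day CSF
#' production, 150 mL CSF of which 25 mL ventricular, 34 µL/min metabolic
#' water), `"feline_vcp"` (calibrated to the feline ventriculo-cisternal
#' perfusion operating points), `"canine_bolus"` (intravenous-tracer bolus
#' scenario), and `"chronic_infusion"` (chronic intraventricular osmotic
#' loading).
#'
#' @param name Configuration name.
#' @param as_model If `TRUE` (default) return the built `csf_model`,
#'   otherwise the raw configuration list.
#' @return A `csf_model` or configuration list.
#' @export
csf_config <- function(name = c("human_baseline", "feline_vcp",
                                "canine_bolus", "chronic_infusion"),
                       as_model = TRUE) {
  name <- match.arg(name)
  path <- system.file("extdata", "configs", paste0(name, ".yaml"),
                      package = "csfnet")
  if (!nzchar(path)) stop("shipped configuration not found: ", name)
  cfg <- read_csf_config(path)
  if (as_model) build_canonical_network(cfg) else cfg
}
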