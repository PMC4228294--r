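# Virtual experiments: ventriculo-cisternal perfusion (VCP), osmotic
# dose-response, intravenous tracer bolus, chronic intraventricular
# osmotic loading.

#' Nascent-flow estimate from tracer dilution
#'
#' During VCP an impermeant tracer is perfused into the lateral ventricle at
#' rate `Q_inj` and concentration `C_inj`, and collected fluid is sampled at
#' the cisternal outflow at concentration `C_out`.  Nascent fluid entering
#' the ventricle dilutes the tracer; the water balance
#' `Q_inj + Q_f = Q_out + Q_SAS` and tracer balance
#' `Q_inj C_inj = (Q_out + Q_SAS) C_out` give the unique solution
#' `Q_f = Q_inj (C_inj - C_out) / C_out`.
#'
#' @param Q_inj Perfusion inflow rate, µL/min (> 0).
#' @param C_inj Tracer concentration of the perfusate (> 0, any units).
#' @param C_out Tracer concentration of the collected fluid (same units).
#' @return Nascent flow `Q_f` in µL/min.  Negative values (concentration
#'   rather than dilution, `C_out > C_inj`) are returned with a warning.
#' @export
nascent_flow_estimate <- function(Q_inj, C_inj, C_out) {
  if (any(Q_inj <= 0)) stop("nascent_flow_estimate(): Q_inj must be positive")
  if (any(C_inj <= 0)) stop("nascent_flow_estimate(): C_inj must be positive")
  if (any(C_out <= 0)) stop("nascent_flow_estimate(): C_out must be positive")
  if (any(C_out > C_inj)) {
    warning("nascent_flow_estimate(): C_out exceeds C_inj; ",
            "tracer was concentrated, returning negative nascent flow")
  }
  Q_inj * (C_inj - C_out) / C_out
}

#' Subarachnoid bulk-flow estimate from the combined balances
#'
#' Solves the same two balances as [nascent_flow_estimate()] for the
#' subarachnoid bulk flow: `Q_SAS = (Q_inj C_inj - Q_out C_out) / C_out`.
#' The identity `Q_f = Q_out + Q_SAS - Q_inj` holds by construction.
#'
#' @inheritParams nascent_flow_estimate
#' @param Q_out Measured collection outflow rate, µL/min (>= 0).
#' @return `Q_SAS` in µL/min; negative values (measured outflow exceeding
#'   the tracer-consistent total) are returned with a warning.
#' @export
sas_flow_estimate <- function(Q_inj, C_inj, Q_out, C_out) {
  if (any(Q_inj <= 0)) stop("sas_flow_estimate(): Q_inj must be positive")
  if (any(C_out <= 0)) stop("sas_flow_estimate(): C_out must be positive")
  if (any(Q_out < 0)) stop("sas_flow_estimate(): Q_out must be >= 0")
  q <- (Q_inj * C_inj - Q_out * C_out) / C_out
  if (any(q < 0)) {
    warning("sas_flow_estimate(): measured outflow exceeds the ",
            "tracer-consistent total; negative Q_SAS")
  }
  q
}

# Perfusate composition for a target osmolarity (mOsm).  An ionic mock-CSF
# base carries up to `ion_base` mOsm; the surplus is carried by sucrose
# (the intraventricular loading agent of the perfusion experiments); below
# the base the ionic solution is diluted, emulating dilute perfusates.
.perfusate_composition <- function(osm, ion_base = 250, tracer_conc = 1e-3) {
  half <- min(osm, ion_base) / 2
  comp <- c(Na = half, Cl = half, sucrose = max(0, osm - ion_base))
  c(comp, tracer = tracer_conc)
}

# Serum osmotic loading: returns a model whose arterial boundary reaches
# `serum_osm` mOsm, by adding impermeant mannitol (hyperosmolar loading) or
# by proportional dilution of all boundary solutes (hypo-osmolar loading).
.with_serum_osm <- function(model, serum_osm) {
  if (is.null(serum_osm)) return(model)
  conc <- model$boundaries$arterial_concentrations
  phi_n <- model$species$osmotic_coeff_phi * model$species$dissociation_n
  base <- sum(phi_n * conc)
  if (serum_osm >= base) {
    i <- match("mannitol", model$species$name)
    if (is.na(i)) stop("serum loading requires a 'mannitol' species")
    conc[i] <- conc[i] + (serum_osm - base) / phi_n[i]
  } else {
    conc <- conc * serum_osm / base
  }
  model$boundaries$arterial_concentrations <- conc
  model$config$boundaries$arterial_concentrations <- as.list(conc)
  model
}

#' Baseline serum osmolarity of a model
#'
#' Osmolarity of the arterial boundary composition, mOsm.
#' @param model A `csf_model`.
#' @export
serum_osmolarity <- function(model) {
  osmolarity(model$boundaries$arterial_concentrations, model$species)
}

#' Simulate a ventriculo-cisternal perfusion experiment
#'
#' Adds a continuous intraventricular infusion of tracer-laden perfusate
#' and an open cisternal collection drain at the subarachnoid node, runs
#' the model to steady state, and applies the tracer-dilution estimator to
#' the simulated record.  The collected concentration `C_out` is sampled
#' from the aqueduct effluent (the stream arriving at the cisternal
#' collection site, before mixing into the wider subarachnoid space), as in
#' the experimental preparation.
#'
#' @param model A calibrated `csf_model`.
#' @param perfusate_osm Perfusate osmolarity, mOsm.
#' @param perfusion_rate Infusion rate `Q_inj`, µL/min.
#' @param serum_osm Optional arterial (serum) osmolarity override, mOsm.
#' @param ion_base Osmolarity carried by the ionic mock-CSF base of the
#'   perfusate; the surplus above it is carried by sucrose.
#' @param state0 Optional warm-start state (e.g. the previous grid point of
#'   a dose-response sweep).
#' @param method `"newton"` solves directly for the steady state;
#'   `"sampled"` integrates in 15-min sampling intervals until successive
#'   simulated collection samples differ by less than `sample_tol`
#'   (the experimental steady-state criterion).
#' @param sample_tol Relative successive-sample tolerance for
#'   `method = "sampled"`.
#' @param max_duration Maximum simulated perfusion time for the sampled
#'   method, min.
#' @param drain_pressure,drain_resistance Collection cannula reference
#'   pressure (mmHg) and hydraulic resistance (mmHg·min·µL^-1).
#' @param pre_integrate Minutes of transient integration before the direct
#'   steady-state solve (shorten when warm-starting from a nearby state).
#' @param max_horizon Longest fallback integration horizon for the
#'   steady-state solver, min.
#' @return A list of class `csf_vcp` with the perfusion record (`Q_inj`,
#'   `C_inj`, `Q_out`, `C_out`), estimator outputs (`Q_f`, `Q_SAS`), the
#'   directly recorded nascent ventricular inflow `Q_nascent_true`
#'   (choroidal + ependymal Starling flux), and the steady state.
#' @export
run_vcp <- function(model, perfusate_osm, perfusion_rate = 77,
                    serum_osm = NULL, ion_base = 250, state0 = NULL,
                    method = c("newton", "sampled"), sample_tol = 0.02,
                    max_duration = 5000, drain_pressure = 0,
                    drain_resistance = 0.05, pre_integrate = 240,
                    max_horizon = 2e5) {
  method <- match.arg(method)
  model <- .with_serum_osm(model, serum_osm)
  comp <- .perfusate_composition(perfusate_osm, ion_base)
  C_inj <- comp[["tracer"]]
  protocol <- csf_protocol(
    list(kind = "continuous_infusion", site = "ventricles", start = 0,
         rate = perfusion_rate, composition = comp),
    list(kind = "drain", site = "SAS", start = 0,
         ref_pressure = drain_pressure, resistance = drain_resistance)
  )
  if (method == "newton") {
    ss <- csf_steady_state(model, protocol, state0 = state0, t_eval = 1,
                           pre_integrate = pre_integrate,
                           max_horizon = max_horizon)
  } else {
    y <- if (is.null(state0)) csf_state(model) else state0
    i_tr <- match("tracer", model$species$name)
    pos <- 8 + (i_tr - 1) * 8 + 5          # ventricular tracer amount
    c_prev <- NA_real_
    t <- 0
    converged <- FALSE
    while (t < max_duration) {
      tr <- csf_integrate(model, protocol, c(t, t + 15), state0 = y, n_save = 3)
      y <- as.numeric(tr$states[nrow(tr$states), ])
      t <- t + 15
      c_now <- 1000 * y[pos] / y[5]
      if (!is.na(c_prev) && c_prev > 0 &&
          abs(c_now - c_prev) / c_prev < sample_tol) {
        converged <- TRUE
        break
      }
      c_prev <- c_now
    }
    if (!converged) {
      stop("run_vcp(): no steady state within max_duration = ", max_duration,
           " min (successive-sample criterion)")
    }
    ss <- csf_steady_state(model, protocol, state0 = y, t_eval = 1,
                           pre_integrate = 0)
  }
  aux <- attr(ss, "aux")
  i_tr <- match("tracer", model$species$name)
  C_out <- 1000 * ss[8 + (i_tr - 1) * 8 + 5] / ss[5]   # aqueduct effluent
  Q_out <- aux[["Q_drain"]]
  Q_f <- suppressWarnings(nascent_flow_estimate(perfusion_rate, C_inj, C_out))
  structure(list(
    Q_inj = perfusion_rate, C_inj = C_inj, Q_out = unname(Q_out),
    C_out = unname(C_out), Q_f = unname(Q_f),
    Q_SAS = unname(suppressWarnings(
      sas_flow_estimate(perfusion_rate, C_inj, Q_out, C_out))),
    Q_nascent_true = unname(aux[["Q_nascent"]]),
    perfusate_osm = perfusate_osm,
    serum_osm = serum_osm %||% serum_osmolarity(model),
    state = ss, model_name = model$name
  ), class = "csf_vcp")
}

#' @export
print.csf_vcp <- function(x, ...) {
  cat(sprintf(
    "<csf_vcp> Q_inj %.3g uL/min at %.4g mOsm (serum %.4g): Q_f = %.4g uL/min (true nascent %.4g)\n",
    x$Q_inj, x$perfusate_osm, x$serum_osm, x$Q_f, x$Q_nascent_true))
  invisible(x)
}

#' Osmotic dose-response of nascent flow
#'
#' Runs [run_vcp()] across a grid of osmolarities at either the ventricular
#' site (perfusate osmolarity varied) or the serum site (arterial boundary
#' osmolarity varied, perfusate held at the control), and computes the local
#' sensitivity of nascent flow to osmolarity by central finite difference
#' (plus/minus `h` mOsm) around the control point.
#'
#' @param model A calibrated `csf_model`.
#' @param site `"ventricle"` or `"serum"`.
#' @param osm_grid Osmolarities to sweep, mOsm (strictly increasing).
#' @param control Control osmolarity at which the sensitivity is evaluated;
#'   defaults to 320 (ventricular site) or the model's baseline serum
#'   osmolarity.
#' @param h Finite-difference half-step, mOsm.
#' @param perfusion_rate Perfusion rate, µL/min.
#' @param state0 Optional warm-start state for the first grid point
#'   (subsequent points chain automatically).
#' @param ... Passed to [run_vcp()].
#' @return A tibble of class `csf_dose_response` with columns `site`,
#'   `osmolarity`, `Q_f` (estimator) and `Q_nascent` (recorded), and
#'   attributes `local_sensitivity` (µL/min per mOsm) and `control`.
#' @export
dose_response <- function(model, site = c("ventricle", "serum"), osm_grid,
                          control = NULL, h = 10, perfusion_rate = 77,
                          state0 = NULL, ...) {
  site <- match.arg(site)
  if (is.unsorted(osm_grid, strictly = TRUE)) {
    stop("dose_response(): osm_grid must be strictly increasing")
  }
  if (is.null(control)) {
    control <- if (site == "ventricle") 320 else serum_osmolarity(model)
  }
  one <- function(osm, state0 = NULL) {
    if (site == "ventricle") {
      run_vcp(model, perfusate_osm = osm, perfusion_rate = perfusion_rate,
              state0 = state0, ...)
    } else {
      run_vcp(model, perfusate_osm = 320, perfusion_rate = perfusion_rate,
              serum_osm = osm, state0 = state0, ...)
    }
  }
  rows <- vector("list", length(osm_grid))
  st <- state0
  for (i in seq_along(osm_grid)) {
    v <- one(osm_grid[i], state0 = st)
    st <- v$state
    rows[[i]] <- tibble::tibble(site = site, osmolarity = osm_grid[i],
                                Q_f = v$Q_f, Q_nascent = v$Q_nascent_true)
  }
  out <- dplyr::bind_rows(rows)
  lo <- one(control - h, state0 = st)
  hi <- one(control + h, state0 = lo$state)
  sens <- (hi$Q_f - lo$Q_f) / (2 * h)
  structure(out, local_sensitivity = sens, control = control,
            class = c("csf_dose_response", class(out)))
}

#' Intravenous tracer study with ventricular osmotic challenge
#'
#' Emulates the radiolabeled-water experiments: an inert, freely permeating
#' tracer appears in the arterial blood from `t = 0`, and a hyperosmolar
#' bolus is injected into a ventricle.  Two arms are simulated (bolus vs
#' isomolar control) and the tracer accumulation in the ventricular and
#' subarachnoid CSF is recorded, together with the nascent-flow time course.
#'
#' @param model A calibrated `csf_model` whose membrane arcs assign the
#'   tracer a reflection coefficient of 0 (tritiated water follows bulk
#'   water).
#' @param bolus_osm Osmolarity of the ventricular bolus, mOsm.
#' @param bolus_site Compartment receiving the bolus.
#' @param bolus_volume Bolus volume, µL.
#' @param t_bolus Bolus time, min.
#' @param duration Total simulated time, min.
#' @param isomolar_osm Osmolarity of the control arm's bolus (the CSF-
#'   isotonic reference).
#' @param plateau_window Post-bolus window (min, relative to the bolus) over
#'   which the plateau nascent flow is averaged.
#' @param arms `"both"` simulates the hyperosmolar and isomolar-control
#'   arms; `"bolus"` only the hyperosmolar arm (faster; no comparison
#'   curves).
#' @param base_state Optional pre-computed baseline steady state.
#' @return A list of class `csf_tracer_study`: `curves` (tibble: time, arm,
#'   ventricular and subarachnoid tracer amounts, nascent flow),
#'   `plateau_nascent` (bolus arm), `control_nascent` (pre-bolus steady
#'   flow).
#' @export
run_tracer_bolus <- function(model, bolus_osm, bolus_site = "ventricles",
                             bolus_volume = 250, t_bolus = 30, duration = 120,
                             isomolar_osm = 320,
                             plateau_window = c(2, 12),
                             arms = c("both", "bolus"), base_state = NULL) {
  arms <- match.arg(arms)
  i_tr <- match("tracer", model$species$name)
  if (is.na(i_tr)) stop("model lacks a tracer species")
  base <- if (is.null(base_state)) csf_steady_state(model, NULL) else base_state
  # tracer enters the arterial boundary from t = 0
  m_tr <- model
  m_tr$boundaries$arterial_concentrations[i_tr] <- 1e-3
  arm <- function(osm) {
    protocol <- csf_protocol(list(
      kind = "bolus", site = bolus_site, start = t_bolus,
      volume = bolus_volume,
      composition = .perfusate_composition(osm, tracer_conc = 0)
    ))
    csf_integrate(m_tr, protocol, c(0, duration), state0 = as.numeric(base),
                  n_save = 2 * duration, rtol = 1e-7, atol = 1e-9)
  }
  tr_b <- arm(bolus_osm)
  curve_of <- function(tr, label) {
    tibble::tibble(
      time = tr$times, arm = label,
      tracer_ventricles = tr$states[, paste0("A_ventricles_",
                                             model$species$name[i_tr])],
      tracer_SAS = tr$states[, paste0("A_SAS_", model$species$name[i_tr])],
      Q_nascent = tr$aux[, "Q_nascent"]
    )
  }
  curves <- curve_of(tr_b, "hyperosmolar")
  if (arms == "both") {
    curves <- dplyr::bind_rows(curves, curve_of(arm(isomolar_osm), "isomolar"))
  }
  win <- t_bolus + plateau_window
  sel <- tr_b$times >= win[1] & tr_b$times <= win[2]
  ctrl <- attr(base, "aux")
  if (is.null(ctrl)) ctrl <- csf_balance(model, base)$aux
  structure(list(
    curves = curves,
    plateau_nascent = mean(tr_b$aux[sel, "Q_nascent"]),
    control_nascent = unname(ctrl[["Q_nascent"]]),
    bolus_osm = bolus_osm
  ), class = "csf_tracer_study")
}

#' Chronic intraventricular osmotic loading
#'
#' Continuous infusion of an (an)isotonic solution into the ventricles over
#' days, tracking the ventricular volume.  The infusate is modeled as an
#' isotonic vehicle plus an impermeant osmolyte carrying the surplus
#' osmolarity.
#'
#' @param model A calibrated `csf_model` with a compliant ventricular
#'   compartment.
#' @param osm Infusate osmolarity, mOsm.
#' @param days Infusion duration, days.
#' @param rate Infusion rate, µL/min.
#' @param vehicle_osm Osmolarity of the isotonic vehicle.
#' @param agent Loading agent carrying the surplus osmolarity: `"dextran"`
#'   (an impermeant macromolecule, mapped to the mannitol-class species) or
#'   `"fgf2"` (a distinct species whose ependymal reflection coefficient is
#'   fitted separately; requires an `fgf2` species in the configuration).
#' @param n_save Saved time points.
#' @param base_state Optional pre-computed baseline steady state.
#' @return A list of class `csf_chronic`: `timecourse` (tibble: time_day,
#'   V_ventricles, pct_increase), `pct_increase` (final), `V0`.
#' @export
run_chronic_infusion <- function(model, osm, days, rate = 0.2,
                                 vehicle_osm = NULL,
                                 agent = c("dextran", "fgf2"), n_save = 120,
                                 base_state = NULL) {
  agent <- match.arg(agent)
  if (model$comp$rigid[5]) stop("run_chronic_infusion(): ventricles must be compliant")
  if (is.null(vehicle_osm)) vehicle_osm <- serum_osmolarity(model)
  half <- vehicle_osm / 2
  species <- if (agent == "dextran") "mannitol" else "fgf2"
  if (!species %in% model$species$name) {
    stop("run_chronic_infusion(): model lacks a '", species, "' species")
  }
  comp <- c(Na = half, Cl = half)
  comp[species] <- max(0, osm - vehicle_osm)
  if (osm < vehicle_osm) comp[c("Na", "Cl")] <- half * osm / vehicle_osm
  base <- if (is.null(base_state)) csf_steady_state(model, NULL) else base_state
  V0 <- unname(base[5])
  protocol <- csf_protocol(list(
    kind = "continuous_infusion", site = "ventricles", start = 0,
    rate = rate, composition = comp
  ))
  tr <- csf_integrate(model, protocol, c(0, days * 1440),
                      state0 = as.numeric(base), n_save = n_save,
                      rtol = 1e-7, atol = 1e-8)
  tc <- tibble::tibble(
    time_day = tr$times / 1440,
    V_ventricles = tr$states[, "V_ventricles"],
    pct_increase = 100 * (tr$states[, "V_ventricles"] - V0) / V0
  )
  structure(list(timecourse = tc,
                 pct_increase = tc$pct_increase[nrow(tc)],
                 V0 = V0, osm = osm, days = days, rate = rate),
            class = "csf_chronic")
}
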