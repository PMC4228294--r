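# Coupled water + solute balances and their integration.
#
# State vector layout: 8 compartment volumes (µL) followed by the 8 x S
# matrix of species amounts (µmol), column-major by species.
#
# Pressure closure: compliant compartments follow P = P0 + (V - V0)/kappa;
# rigid compartments (the vascular tree by default) hold their volume and
# take the quasi-steady pressure that balances their instantaneous flows.
# Because every flux law is affine in pressure at fixed composition, the
# rigid pressures solve a small linear system; one-way arcs are handled by
# an active-set iteration.

# Precompute flat arrays and incidence structures for fast repeated RHS
# evaluation.
.csf_runtime <- function(model) {
  arcs <- model$arcs
  n_a <- length(arcs)
  S <- nrow(model$species)
  rt <- list(
    n_a = n_a, S = S,
    arc_ids = names(arcs),
    from = vapply(arcs, `[[`, 0L, "from_idx"),
    to = vapply(arcs, `[[`, 0L, "to_idx"),
    kind = vapply(arcs, `[[`, "", "kind"),
    one_way = vapply(arcs, `[[`, TRUE, "one_way"),
    gcoef = vapply(arcs, function(a) {
      if (a$kind == "starling") a$LpA else a$g
    }, 0),
    is_starling = vapply(arcs, function(a) a$kind == "starling", TRUE),
    sigma = t(vapply(arcs, `[[`, numeric(S), "sigma")),   # n_a x S
    pump = t(vapply(arcs, `[[`, numeric(S), "pump")),
    phi_n = model$species$osmotic_coeff_phi * model$species$dissociation_n,
    RT = model$constants$gas_constant * model$constants$temperature,
    V0 = model$comp$V0,
    P0 = model$comp$P0,
    kappa = model$comp$kappa,
    rigid = model$comp$rigid,
    P_in = model$boundaries$inlet_pressure,
    P_out = model$boundaries$outlet_pressure,
    C_art = model$boundaries$arterial_concentrations,
    metabolic = model$metabolic,
    species_names = model$species$name,
    i_gluc = match("glucose", model$species$name)
  )
  rt$rigid_idx <- which(rt$rigid)
  rt$n_r <- length(rt$rigid_idx)
  rt$rigid_pos <- integer(8)
  rt$rigid_pos[rt$rigid_idx] <- seq_len(rt$n_r)
  # starling precomputations
  rt$star <- which(rt$is_starling)
  if (any(rt$from[rt$star] == 0L) || any(rt$to[rt$star] == 0L)) {
    stop("starling arcs must connect two compartments")
  }
  PN <- matrix(rt$phi_n, n_a, S, byrow = TRUE)
  rt$SW_star <- (rt$sigma * PN)[rt$star, , drop = FALSE]
  rt$oms_star <- 1 - rt$sigma[rt$star, , drop = FALSE]
  rt$pump_star <- rt$pump[rt$star, , drop = FALSE]
  # pressure-vector index maps: positions 9/10 hold inlet/outlet pressures
  rt$from_p <- ifelse(rt$from == 0L, 9L, rt$from)
  rt$to_p <- ifelse(rt$to == 0L, 10L, rt$to)
  # concentration index maps into rbind(C, C_art): row 9 = arterial boundary;
  # outflow to the outlet boundary uses the from-node as donor either way
  rt$from_c <- ifelse(rt$from == 0L, 9L, rt$from)
  rt$to_c <- ifelse(rt$to == 0L, rt$from, rt$to)
  rt$one_idx <- which(rt$one_way)
  # signed incidence (8 x n_a): +1 into, -1 out of each compartment
  inc <- matrix(0, 8, n_a)
  for (a in seq_len(n_a)) {
    if (rt$from[a] > 0L) inc[rt$from[a], a] <- -1
    if (rt$to[a] > 0L) inc[rt$to[a], a] <- 1
  }
  rt$inc <- inc
  rt$nasc_idx <- which(rt$is_starling & rt$to == 5L)
  # compliant pressure law P = Pb + V/kappa (rigid rows overwritten later)
  kinv <- ifelse(rt$rigid, 0, 1 / rt$kappa)
  rt$kinv <- kinv
  rt$Pbase <- rt$P0 - rt$V0 * kinv
  rt
}

# Solve quasi-steady pressures of rigid nodes given compliant pressures and
# the osmotic forcing.  `extra` is a length-8 vector of non-arc source flows
# (protocol, metabolic water) entering each node.  Returns the full length-8
# pressure vector (rigid entries overwritten).  One-way arcs are handled by
# an active-set iteration.
.solve_pressures <- function(rt, P, d_osm, extra) {
  if (rt$n_r == 0) return(P)
  open <- rep(TRUE, rt$n_a)
  rpos_from <- integer(rt$n_a)
  rpos_to <- integer(rt$n_a)
  for (a in seq_len(rt$n_a)) {
    f <- rt$from[a]; to <- rt$to[a]
    rpos_from[a] <- if (f != 0L && rt$rigid[f]) rt$rigid_pos[f] else 0L
    rpos_to[a] <- if (to != 0L && rt$rigid[to]) rt$rigid_pos[to] else 0L
  }
  for (iter in 1:6) {
    # Row n:  sum_incident g * P_n - sum g * P_other
    #           = extra_n + sum_out d_a - sum_in d_a
    M <- matrix(0, rt$n_r, rt$n_r)
    b <- extra[rt$rigid_idx]
    for (a in seq_len(rt$n_a)) {
      if (!open[a]) next
      g <- rt$gcoef[a]
      rf <- rpos_from[a]; rtt <- rpos_to[a]
      if (rf == 0L && rtt == 0L) next
      if (rf > 0L) {
        M[rf, rf] <- M[rf, rf] + g
        if (rtt > 0L) M[rf, rtt] <- M[rf, rtt] - g
        else {
          pt_known <- if (rt$to[a] == 0L) rt$P_out else P[rt$to[a]]
          b[rf] <- b[rf] + g * pt_known
        }
        b[rf] <- b[rf] + d_osm[a]
      }
      if (rtt > 0L) {
        M[rtt, rtt] <- M[rtt, rtt] + g
        if (rf > 0L) M[rtt, rf] <- M[rtt, rf] - g
        else {
          pf_known <- if (rt$from[a] == 0L) rt$P_in else P[rt$from[a]]
          b[rtt] <- b[rtt] + g * pf_known
        }
        b[rtt] <- b[rtt] - d_osm[a]
      }
    }
    P[rt$rigid_idx] <- solve(M, b)
    # active set check for one-way arcs incident to rigid nodes
    changed <- FALSE
    for (a in rt$one_idx) {
      if (rpos_from[a] == 0L && rpos_to[a] == 0L) next
      pf <- if (rt$from[a] == 0L) rt$P_in else P[rt$from[a]]
      pt <- if (rt$to[a] == 0L) rt$P_out else P[rt$to[a]]
      J <- rt$gcoef[a] * (pf - pt) - d_osm[a]
      if (open[a] && J < 0) { open[a] <- FALSE; changed <- TRUE }
      else if (!open[a] && J > 0) { open[a] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  P
}

# Continuous protocol terms active at time t.  Returns list(Q = length-8
# net volumetric source µL/min split into Qin/ Qout, molar_in = 8 x S µmol/min,
# withdraw_rate = length-8 µL/min removed at compartment concentration,
# drains = list of (site, ref, res)).
.protocol_terms <- function(protocol, t, S, species_names) {
  Qin <- numeric(8)
  molar_in <- matrix(0, 8, S)
  withdraw <- numeric(8)
  drains <- list()
  if (!is.null(protocol)) {
    for (ev in protocol$events) {
      if (ev$kind == "bolus") next
      if (t < ev$start || t >= ev$stop) next
      site <- ev$site_idx
      if (ev$kind == "continuous_infusion") {
        Qin[site] <- Qin[site] + ev$rate
        if (!is.null(ev$composition)) {
          comp <- numeric(S)
          comp[match(names(ev$composition), species_names)] <- ev$composition
          molar_in[site, ] <- molar_in[site, ] + ev$rate * comp / 1000
        }
      } else if (ev$kind == "withdrawal") {
        withdraw[site] <- withdraw[site] + ev$rate
      } else if (ev$kind == "drain") {
        drains[[length(drains) + 1]] <- ev
      }
    }
  }
  list(Qin = Qin, molar_in = molar_in, withdraw = withdraw, drains = drains)
}

# The combined RHS.  Returns list(dy, aux) in deSolve convention.
.csf_rhs <- function(t, y, parms) {
  rt <- parms$rt
  S <- rt$S
  V <- y[1:8]
  A <- matrix(y[-(1:8)], 8, S)
  C <- (1000 * A) / V

  pro <- .protocol_terms(parms$protocol, t, S, rt$species_names)

  # metabolic water and glucose destruction at the ECS node
  met <- rt$metabolic
  iE <- 6L
  if (!is.na(met$direct_G_override)) {
    G <- met$direct_G_override
    D_gluc <- 0
  } else {
    cg <- if (!is.na(rt$i_gluc)) max(C[iE, rt$i_gluc], 0) else 0
    D_gluc <- met$k_gluc * cg * V[iE] / 1000            # µmol/min
    G <- met$nu_water_per_glucose * D_gluc              # µL/min
  }

  # osmotic forcing of the starling arcs
  d_osm <- numeric(rt$n_a)
  sf <- rt$from[rt$star]; st <- rt$to[rt$star]
  d_osm[rt$star] <- rt$gcoef[rt$star] * rt$RT *
    rowSums(rt$SW_star * (C[sf, , drop = FALSE] - C[st, , drop = FALSE]))

  # pressures: compliant law, rigid quasi-steady solve
  P <- rt$Pbase + V * rt$kinv
  extra <- pro$Qin - pro$withdraw
  extra[iE] <- extra[iE] + G
  # (drains are restricted to compliant compartments; they would otherwise
  # have to enter the rigid linear solve)
  P <- .solve_pressures(rt, P, d_osm, extra)

  # arc water fluxes
  Px <- c(P, rt$P_in, rt$P_out)
  Jarc <- rt$gcoef * (Px[rt$from_p] - Px[rt$to_p]) - d_osm
  if (length(rt$one_idx)) {
    # smoothed one-way clamp: nonnegative, C1, and within 5e-7 uL/min of
    # max(J, 0); the kink of a hard clamp collapses stiff-solver steps
    J1 <- Jarc[rt$one_idx]
    Jarc[rt$one_idx] <- 0.5 * (J1 + sqrt(J1 * J1 + 1e-12))
  }
  if (!all(is.finite(Jarc))) {
    stop("non-finite flux on arc ",
         paste(rt$arc_ids[!is.finite(Jarc)], collapse = ", "), " at t = ", t)
  }

  # drains (free outflow at a reference pressure)
  Qdrain <- numeric(8)
  for (ev in pro$drains) {
    site <- ev$site_idx
    Qdrain[site] <- Qdrain[site] +
      max(0, (P[site] - ev$ref_pressure) / ev$resistance)
  }

  # water balances
  dV <- drop(rt$inc %*% Jarc) + pro$Qin - pro$withdraw - Qdrain
  dV[iE] <- dV[iE] + G
  dV[rt$rigid] <- 0

  # species balances: upwind convection; solvent drag + pumps on membranes
  Cx <- rbind(C, rt$C_art)
  donor <- rt$from_c
  neg <- Jarc < 0
  donor[neg] <- rt$to_c[neg]
  Fm <- (Jarc / 1000) * Cx[donor, , drop = FALSE]
  Fm[rt$star, ] <- Fm[rt$star, , drop = FALSE] * rt$oms_star + rt$pump_star
  dA <- pro$molar_in + rt$inc %*% Fm
  # withdrawals and drains remove fluid at the site composition
  rem <- pro$withdraw + Qdrain
  ir <- which(rem > 0)
  if (length(ir)) {
    dA[ir, ] <- dA[ir, , drop = FALSE] - (rem[ir] / 1000) * C[ir, , drop = FALSE]
  }
  if (D_gluc > 0) dA[iE, rt$i_gluc] <- dA[iE, rt$i_gluc] - D_gluc

  aux <- c(Jarc, P, Qdrain[8], G, sum(Jarc[rt$nasc_idx]))
  list(c(dV, dA), aux)
}

.aux_names <- function(rt) {
  c(paste0("flux_", rt$arc_ids), paste0("P_", .csf_compartments),
    "Q_drain", "G", "Q_nascent")
}

#' Initial model state
#'
#' Builds the packed state vector (volumes and species amounts) from the
#' model's rest volumes and initial concentrations.  Initial concentrations
#' come from the configuration's `initial$concentrations` section: a
#' `default` entry applied to every compartment, overridden per compartment
#' by name; compartments default to the arterial boundary composition when
#' nothing is given.
#'
#' @param model A `csf_model`.
#' @param concentrations Optional named list overriding the configuration:
#'   each element a named vector of mmol/L keyed by species, list names
#'   being compartment ids (or `default`).
#' @return A named numeric state vector of class `csf_state`.
#' @export
csf_state <- function(model, concentrations = NULL) {
  S <- nrow(model$species)
  sp <- model$species$name
  conc_cfg <- model$initial$concentrations
  base <- model$boundaries$arterial_concentrations
  # per-compartment overrides replace the full vector; order of specificity:
  # argument per-comp > config per-comp > argument default > config default
  # > arterial boundary composition
  get_conc <- function(comp_id) {
    pick <- NULL
    for (src in list(concentrations[[comp_id]], conc_cfg[[comp_id]],
                     concentrations$default, conc_cfg$default)) {
      if (is.null(pick) && !is.null(src)) pick <- unlist(src)
    }
    out <- stats::setNames(rep(0, S), sp)
    if (is.null(pick)) return(base)
    unk <- setdiff(names(pick), sp)
    if (length(unk)) stop("csf_state(): unknown species ", paste(unk, collapse = ", "))
    out[names(pick)] <- pick
    out
  }
  V <- model$comp$V0
  A <- matrix(0, 8, S)
  for (i in 1:8) A[i, ] <- get_conc(model$comp$id[i]) * V[i] / 1000
  y <- c(V, as.vector(A))
  names(y) <- .state_names(model)
  class(y) <- c("csf_state", "numeric")
  y
}

.state_names <- function(model) {
  c(paste0("V_", .csf_compartments),
    as.vector(outer(.csf_compartments, model$species$name,
                    function(a, b) paste0("A_", a, "_", b))))
}

#' Experiment protocol
#'
#' A protocol is a list of timed events applied to the model:
#' \describe{
#'   \item{continuous_infusion}{`rate` µL/min of fluid with the given
#'     `composition` (mmol/L per species) into `site`, between `start` and
#'     `stop`.}
#'   \item{bolus}{instantaneous addition of `volume` µL with the given
#'     `composition` at time `start`.}
#'   \item{withdrawal}{fluid removal at a fixed `rate` µL/min, at the site's
#'     current composition.}
#'   \item{drain}{free outflow through a cannula: `max(0, (P_site -
#'     ref_pressure)/resistance)` µL/min, emulating open collection at a
#'     reference (atmospheric) pressure.  Only allowed at compliant
#'     compartments.}
#' }
#'
#' @param ... Events, each a list with fields `kind`, `site`, `start`,
#'   `stop` (not for bolus), and the kind-specific fields above.
#' @return An object of class `csf_protocol`.
#' @export
csf_protocol <- function(...) {
  events <- list(...)
  if (length(events) == 1 && is.null(events[[1]]$kind) &&
      is.list(events[[1]]) && length(events[[1]]) && !is.null(events[[1]][[1]]$kind)) {
    events <- events[[1]]
  }
  events <- lapply(events, function(ev) {
    ev$kind <- match.arg(ev$kind,
                         c("continuous_infusion", "bolus", "withdrawal", "drain"))
    ev$site_idx <- match(ev$site, .csf_compartments)
    if (is.na(ev$site_idx)) stop("csf_protocol(): unknown site '", ev$site, "'")
    if (ev$kind == "bolus") {
      if (is.null(ev$volume) || ev$volume < 0) stop("bolus event needs volume >= 0")
      ev$stop <- ev$start
    } else {
      ev$start <- ev$start %||% 0
      ev$stop <- ev$stop %||% Inf
      if (ev$start >= ev$stop) stop("csf_protocol(): event start must precede stop")
      if (ev$kind %in% c("continuous_infusion", "withdrawal")) {
        if (is.null(ev$rate) || ev$rate < 0) stop("event needs rate >= 0")
      }
      if (ev$kind == "drain") {
        ev$ref_pressure <- ev$ref_pressure %||% 0
        ev$resistance <- ev$resistance %||% 1e-2
      }
    }
    if (!is.null(ev$composition)) ev$composition <- unlist(ev$composition)
    ev
  })
  structure(list(events = events), class = "csf_protocol")
}

.apply_bolus <- function(y, ev, model) {
  S <- nrow(model$species)
  site <- ev$site_idx
  y[site] <- y[site] + ev$volume
  if (!is.null(ev$composition)) {
    idx <- match(names(ev$composition), model$species$name)
    for (k in seq_along(idx)) {
      pos <- 8 + (idx[k] - 1) * 8 + site
      y[pos] <- y[pos] + ev$volume * ev$composition[k] / 1000
    }
  }
  y
}

#' Integrate the model through time
#'
#' Stiff implicit integration (via [deSolve::lsoda()]) of the coupled water
#' and solute balances.  Bolus events are applied as discontinuous state
#' increments; integration is stopped and restarted at each event time.
#'
#' @param model A `csf_model`.
#' @param protocol A [csf_protocol()] or `NULL`.
#' @param t_span Length-2 numeric, minutes.
#' @param state0 Initial state; defaults to [csf_state()] of the model.
#' @param n_save Number of saved time points (approximately, across the
#'   span).
#' @param rtol,atol Integrator tolerances.
#' @return A `csf_trajectory`: list with `times`, `states` (matrix), `aux`
#'   (matrix of per-arc fluxes, pressures, and derived quantities), and the
#'   model.
#' @export
csf_integrate <- function(model, protocol = NULL, t_span, state0 = NULL,
                          n_save = 200, rtol = 1e-8, atol = 1e-10) {
  rt <- .csf_runtime(model)
  y <- if (is.null(state0)) csf_state(model) else as.numeric(state0)
  t0 <- t_span[1]; t1 <- t_span[2]
  stopifnot(is.finite(t0), is.finite(t1), t1 > t0)
  bolus_times <- numeric()
  if (!is.null(protocol)) {
    bolus_times <- sort(unique(vapply(
      Filter(function(e) e$kind == "bolus", protocol$events),
      `[[`, 0, "start")))
    bolus_times <- bolus_times[bolus_times >= t0 & bolus_times <= t1]
  }
  breaks <- unique(c(t0, bolus_times, t1))
  out_all <- NULL
  parms <- list(rt = rt, protocol = protocol)
  for (seg in seq_len(length(breaks) - 1)) {
    a <- breaks[seg]; b <- breaks[seg + 1]
    if (!is.null(protocol) && a %in% bolus_times) {
      for (ev in protocol$events) {
        if (ev$kind == "bolus" && ev$start == a) {
          y <- .apply_bolus(y, ev, model)
        }
      }
    }
    if (b <= a) next
    n_seg <- max(2L, ceiling(n_save * (b - a) / (t1 - t0)))
    times <- seq(a, b, length.out = n_seg)
    sol <- deSolve::lsoda(y = y, times = times, func = .csf_rhs,
                          parms = parms, rtol = rtol, atol = atol,
                          maxsteps = 200000)
    if (attr(sol, "istate")[1] < 0) {
      stop("csf_integrate(): solver failed near t = ",
           signif(max(sol[, 1]), 6), " min")
    }
    y <- as.numeric(sol[nrow(sol), 1 + seq_along(y)])
    keep <- if (is.null(out_all)) seq_len(nrow(sol)) else 2:nrow(sol)
    out_all <- rbind(out_all, sol[keep, , drop = FALSE])
  }
  sn <- .state_names(model)
  traj <- list(times = out_all[, 1],
               states = `colnames<-`(out_all[, 1 + seq_along(sn), drop = FALSE], sn),
               aux = `colnames<-`(out_all[, -(seq_len(1 + length(sn))), drop = FALSE],
                                  .aux_names(rt)),
               model = model, protocol = protocol)
  class(traj) <- "csf_trajectory"
  traj
}

#' Evaluate the instantaneous balance of a state
#'
#' Returns the time-derivative of the state plus the auxiliary quantities
#' (per-arc fluxes, pressures, metabolic water, nascent ventricular inflow)
#' at time `t`.
#'
#' @param model A `csf_model`.
#' @param state State vector.
#' @param protocol Optional protocol.
#' @param t Evaluation time, min.
#' @return List with `dstate` and named `aux`.
#' @export
csf_balance <- function(model, state, protocol = NULL, t = 0) {
  rt <- .csf_runtime(model)
  out <- .csf_rhs(t, as.numeric(state), list(rt = rt, protocol = protocol))
  list(dstate = stats::setNames(out[[1]], .state_names(model)),
       aux = stats::setNames(out[[2]], .aux_names(rt)))
}

#' Compartment pressures for a given state
#'
#' Compliant compartments follow the linear compliance law
#' `P = P0 + (V - V0)/kappa`; rigid compartments take the quasi-steady
#' pressure balancing their instantaneous flows.
#'
#' @inheritParams csf_balance
#' @return Named pressure vector, mmHg.
#' @export
pressure_closure <- function(model, state, protocol = NULL, t = 0) {
  aux <- csf_balance(model, state, protocol, t)$aux
  stats::setNames(aux[paste0("P_", .csf_compartments)], .csf_compartments)
}

#' Solve for a steady state
#'
#' Damped Newton iteration on the combined right-hand side (numerical
#' Jacobian over the free coordinates: compliant volumes and all species
#' amounts), started from `state0` and preceded/interleaved with transient
#' integration to enter the basin of attraction.  The result is verified by
#' requiring a small residual norm and, optionally, by a confirmation
#' integration over 100 min.
#'
#' @param model A `csf_model`.
#' @param protocol Constant (or absent) forcing; bolus events are not
#'   allowed.
#' @param state0 Starting state; defaults to [csf_state()].
#' @param t_eval Time at which the (constant) protocol is evaluated.
#' @param pre_integrate Minutes of transient integration before the first
#'   Newton attempt.
#' @param max_horizon Longest fallback transient-integration horizon (min)
#'   tried when Newton fails; shorten to fail fast inside optimization
#'   loops.
#' @param tol Residual tolerance: max |dy| per unit state scale.
#' @param confirm If `TRUE`, integrate 100 min from the root and require the
#'   state to change by less than 0.01% (relative, with an absolute floor).
#' @return A `csf_state` with attributes `aux` (fluxes and pressures) and
#'   `converged`.
#' @export
csf_steady_state <- function(model, protocol = NULL, state0 = NULL,
                             t_eval = NULL, pre_integrate = 240,
                             max_horizon = 2e5, tol = 1e-8,
                             confirm = FALSE) {
  if (!is.null(protocol)) {
    if (any(vapply(protocol$events, function(e) e$kind == "bolus", TRUE))) {
      stop("csf_steady_state(): protocol must be constant (no bolus events)")
    }
  }
  rt <- .csf_runtime(model)
  if (is.null(t_eval)) {
    t_eval <- 1
    if (!is.null(protocol) && length(protocol$events)) {
      t_eval <- max(vapply(protocol$events, `[[`, 0, "start")) + 1
    }
  }
  y <- if (is.null(state0)) as.numeric(csf_state(model)) else as.numeric(state0)
  parms <- list(rt = rt, protocol = protocol)
  n <- length(y)
  free <- c(which(!rt$rigid), 9:n)     # compliant volumes + all amounts
  scale <- pmax(abs(y), c(rep(1, 8), rep(1e-3, n - 8)))

  ffun <- function(yy) .csf_rhs(t_eval, yy, parms)[[1]]

  resnorm <- function(yy) max(abs(ffun(yy)[free]) / scale[free])

  newton <- function(y) {
    mu <- 0
    for (it in 1:40) {
      f0 <- ffun(y)
      r0 <- max(abs(f0[free]) / scale[free])
      if (r0 < tol) return(list(y = y, ok = TRUE))
      nf <- length(free)
      Jm <- matrix(0, nf, nf)
      h <- 1e-6 * pmax(abs(y[free]), scale[free])
      for (k in seq_len(nf)) {
        yk <- y
        yk[free[k]] <- yk[free[k]] + h[k]
        Jm[, k] <- (ffun(yk)[free] - f0[free]) / h[k]
      }
      try_step <- function(step) {
        if (is.null(step) || any(!is.finite(step))) return(NULL)
        lambda <- 1
        for (ls in 1:10) {
          yn <- y
          yn[free] <- y[free] + lambda * step
          # keep volumes positive
          if (all(yn[1:8] > 0)) {
            rn <- tryCatch(resnorm(yn), error = function(e) Inf)
            if (is.finite(rn) && rn < r0) return(yn)
          }
          lambda <- lambda / 2
        }
        NULL
      }
      step <- tryCatch(-solve(Jm, f0[free]), error = function(e) NULL)
      yn <- try_step(step)
      if (is.null(yn)) {
        # Levenberg-Marquardt retries for singular or overshooting Jacobians
        JtJ <- crossprod(Jm)
        Jtf <- crossprod(Jm, f0[free])
        mu <- max(mu, 1e-8 * max(abs(diag(JtJ)), 1))
        for (lmt in 1:6) {
          step <- tryCatch(-solve(JtJ + mu * diag(nf), Jtf),
                           error = function(e) NULL)
          yn <- try_step(step)
          if (!is.null(yn)) break
          mu <- mu * 30
        }
      }
      if (is.null(yn)) return(list(y = y, ok = resnorm(y) < tol))
      y <- yn
    }
    list(y = y, ok = resnorm(y) < tol)
  }

  # pre-integration, then Newton; repeat with longer integration on failure
  horizons <- c(pre_integrate, 2000, 20000, 2e5)
  horizons <- horizons[horizons <= max(max_horizon, pre_integrate)]
  ok <- FALSE
  for (h in horizons) {
    if (h > 0) {
      tr <- csf_integrate(model, protocol, c(0, h) + t_eval - 1, state0 = y,
                          n_save = 8, rtol = 1e-8, atol = 1e-9)
      y <- as.numeric(tr$states[nrow(tr$states), ])
    }
    res <- newton(y)
    y <- res$y
    if (res$ok) { ok <- TRUE; break }
  }
  if (!ok && resnorm(y) > 1e-4) {
    stop("csf_steady_state(): no convergence (residual ",
         signif(resnorm(y), 3), "); try transient integration")
  }
  if (confirm) {
    tr <- csf_integrate(model, protocol, c(t_eval, t_eval + 100), state0 = y,
                        n_save = 4)
    yend <- as.numeric(tr$states[nrow(tr$states), ])
    drift <- max(abs(yend - y) / pmax(abs(y), scale))
    if (drift > 1e-4) {
      warning("csf_steady_state(): confirmation integration drifted by ",
              signif(drift * 100, 3), "% over 100 min")
    }
  }
  out <- .csf_rhs(t_eval, y, parms)
  names(y) <- .state_names(model)
  class(y) <- c("csf_state", "numeric")
  attr(y, "aux") <- stats::setNames(out[[2]], .aux_names(rt))
  attr(y, "converged") <- ok
  y
}
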