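# Small test network used across the suite.  Round parameter values, fast
# to solve.  `sealed = TRUE` closes the vascular boundaries (infinite
# resistance) so that water and solutes are exactly conserved; `uniform =
# TRUE` puts every compartment at the same pressure and composition, which
# is a global equilibrium when pumps and metabolic water are off.
test_config <- function(sealed = FALSE, uniform = FALSE, pumps = TRUE,
                        G = 0, sigma_ep = 0, one_way_cp = FALSE,
                        kappa_vent = 10) {
  conc <- list(Na = 150, Cl = 150)
  sig1 <- list(albumin = 1, Na = 1, K = 1, Cl = 1, HCO3 = 1, glucose = 1,
               sucrose = 1, mannitol = 1, tracer = 1)
  sig_ep <- list(albumin = 1, Na = sigma_ep, K = sigma_ep, Cl = sigma_ep,
                 HCO3 = sigma_ep, glucose = sigma_ep, sucrose = sigma_ep,
                 mannitol = sigma_ep, tracer = 1)
  sig0 <- list(albumin = 0, Na = 0, K = 0, Cl = 0, HCO3 = 0, glucose = 0,
               sucrose = 0, mannitol = 0, tracer = 0)
  ba <- if (sealed) Inf else 1e-3
  P0 <- if (uniform) rep(10, 8) else c(90, 70, 30, 8, 10, 10, 10, 10)
  list(
    name = "test_net",
    compartments = list(
      list(id = "arteries", rest_volume_V0 = 500, rest_pressure_P0 = P0[1], rigid = TRUE),
      list(id = "arterioles", rest_volume_V0 = 200, rest_pressure_P0 = P0[2], rigid = TRUE),
      list(id = "capillaries", rest_volume_V0 = 200, rest_pressure_P0 = P0[3], rigid = TRUE),
      list(id = "veins", rest_volume_V0 = 600, rest_pressure_P0 = P0[4], rigid = TRUE),
      list(id = "ventricles", rest_volume_V0 = 400, rest_pressure_P0 = P0[5],
           compliance_kappa = kappa_vent),
      list(id = "ECS", rest_volume_V0 = 1500, rest_pressure_P0 = P0[6], compliance_kappa = 5),
      list(id = "PVS", rest_volume_V0 = 100, rest_pressure_P0 = P0[7], compliance_kappa = 1),
      list(id = "SAS", rest_volume_V0 = 800, rest_pressure_P0 = P0[8], compliance_kappa = 20)
    ),
    arcs = list(
      list(id = "Q1", kind = "boundary", from = "inlet", to = "arteries",
           resistance_alpha = ba),
      list(id = "Q2", kind = "luminal", from = "arteries", to = "arterioles",
           resistance_alpha = 2e-3),
      list(id = "Q3", kind = "luminal", from = "arterioles", to = "capillaries",
           resistance_alpha = 4e-3),
      list(id = "Q4", kind = "luminal", from = "capillaries", to = "veins",
           resistance_alpha = 2e-3),
      list(id = "Q5", kind = "boundary", from = "veins", to = "outlet",
           resistance_alpha = ba),
      list(id = "Q6", kind = "luminal", from = "PVS", to = "SAS",
           resistance_alpha = 10),
      list(id = "J7", kind = "starling", from = "arterioles", to = "ventricles",
           LpA = 0.05, one_way = one_way_cp, sigma = sig1,
           pump = if (pumps) list(Na = 1, Cl = 1) else list()),
      list(id = "J8", kind = "starling", from = "capillaries", to = "PVS",
           LpA = 0.02, sigma = sig1,
           pump = if (pumps) list(Na = 0.05, Cl = 0.05) else list()),
      list(id = "Q9", kind = "darcy", from = "PVS", to = "ECS",
           resistance_alpha = 5),
      list(id = "J10", kind = "starling", from = "ECS", to = "ventricles",
           LpA = 0.1, sigma = sig_ep),
      list(id = "Q11", kind = "luminal", from = "ventricles", to = "SAS",
           resistance_alpha = 0.1),
      list(id = "J12", kind = "starling", from = "SAS", to = "veins",
           LpA = 2, one_way = TRUE, sigma = sig0)
    ),
    boundaries = list(
      # sealed/uniform networks have zero boundary conductance, so the
      # boundary pressures are inert; they still must satisfy the invariant
      inlet_pressure = if (uniform) 10 + 1e-9 else 100,
      outlet_pressure = if (uniform) 10 else 5,
      arterial_concentrations = list(albumin = 0, Na = 150, K = 0, Cl = 150,
                                     HCO3 = 0, glucose = 0, sucrose = 0,
                                     mannitol = 0, tracer = 0)
    ),
    metabolic = list(k_gluc = 0, nu_water_per_glucose = 0.10809,
                     direct_G_override = G),
    initial = list(concentrations = list(default = conc))
  )
}

test_model <- function(...) build_canonical_network(test_config(...))

# total water and per-species totals of a packed state
state_totals <- function(model, y) {
  y <- as.numeric(y)
  A <- matrix(y[-(1:8)], 8)
  list(water = sum(y[1:8]),
       species = stats::setNames(colSums(A), model$species$name))
}
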