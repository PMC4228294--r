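# Closed-form constitutive laws against independent oracles.

test_that("Hagen-Poiseuille resistance matches the direct formula", {
  # oracle: Q = pi R^4 dP / (8 mu L), evaluated in SI and converted
  R_um <- 100; L_mm <- 10; mu <- 0.7; dP <- 1
  Q_si <- pi * (R_um * 1e-6)^4 * (dP * 133.322) / (8 * mu * 1e-3 * L_mm * 1e-3)
  Q_model_units <- Q_si * 1e9 * 60   # m^3/s -> uL/min
  alpha <- poiseuille_resistance(R_um, L_mm, mu)
  expect_equal(luminal_flow(dP, alpha), Q_model_units, tolerance = 1e-12)
  # R^4 scaling, linearity in L
  expect_equal(poiseuille_resistance(2 * R_um, L_mm, mu), alpha / 16,
               tolerance = 1e-12)
  expect_equal(poiseuille_resistance(R_um, 2 * L_mm, mu), 2 * alpha,
               tolerance = 1e-12)
  expect_error(poiseuille_resistance(-1, L_mm, mu), "positive")
})

test_that("luminal flow is linear and antisymmetric in the pressure drop", {
  expect_identical(luminal_flow(0, 2), 0)
  expect_equal(luminal_flow(10, 2), 5)
  expect_equal(luminal_flow(-10, 2), -luminal_flow(10, 2))
  expect_error(luminal_flow(1, 0), "positive")
})

test_that("osmolarity sums phi * n * C across species", {
  expect_identical(osmolarity(c(Na = 0, Cl = 0)), 0)
  sp <- csf_species(extra = data.frame(name = "NaCl", dissociation_n = 2,
                                       osmotic_coeff_phi = 1))
  expect_equal(osmolarity(c(NaCl = 1), sp), 2)
  # the mock-CSF perfusate: 320 mOsm of a nondissociating sugar
  expect_equal(osmolarity(c(sucrose = 320), csf_species()), 320)
  expect_error(osmolarity(c(Na = -1)), "negative")
})

test_that("van't Hoff pressure is RT per osmole", {
  cst <- csf_constants()
  expect_identical(osmotic_pressure(0, cst), 0)
  # oracle: R = 62.3637 L mmHg / (mol K) at 310.15 K
  expect_equal(osmotic_pressure(1, cst), 62.3637e-3 * 310.15, tolerance = 1e-12)
  expect_equal(osmotic_pressure(1, cst), 19.34, tolerance = 1e-3)
  expect_equal(osmotic_pressure(2 * 7, cst), 2 * osmotic_pressure(7, cst))
})

test_that("amended Starling flux balances hydrostatic and osmotic terms", {
  expect_identical(starling_flux(1, 0), 0)
  expect_equal(starling_flux(1, 10, c(s = 10), c(s = 1)), 0)
  expect_equal(starling_flux(0.5, 10, c(s = 123), c(s = 0)), 5)
  # one-way arcs clamp reversed gradients
  expect_equal(starling_flux(1, -5, one_way = TRUE), 0)
  expect_equal(starling_flux(1, -5, one_way = FALSE), -5)
  expect_error(starling_flux(1, 0, c(s = 1), c(s = 1.3)), "\\[0, 1\\]")
})

test_that("starling and luminal laws agree when sigma = 1 and dPi = dP", {
  # with every sigma = 1 and the osmotic difference re-expressed as a
  # hydrostatic one, J = LpA * (dP - dPi) is the luminal law with
  # alpha = 1/LpA
  LpA <- 0.37
  for (dP in c(-12, 0, 3, 25)) {
    expect_equal(starling_flux(LpA, 2 * dP, c(x = dP), c(x = 1)),
                 luminal_flow(dP, 1 / LpA), tolerance = 1e-12)
  }
})

test_that("Darcy flow equals the equivalent-resistance luminal flow", {
  k <- 1.3; A <- 2.5; mu <- 0.8; L <- 4; dP <- 7.5
  expect_equal(darcy_flow(k, A, dP, mu, L),
               luminal_flow(dP, darcy_resistance(k, A, mu, L)),
               tolerance = 1e-12)
  expect_identical(darcy_flow(k, A, 0, mu, L), 0)
  expect_equal(darcy_flow(k, 2 * A, dP, mu, L), 2 * darcy_flow(k, A, dP, mu, L))
  expect_equal(darcy_flow(k, A, -dP, mu, L), -darcy_flow(k, A, dP, mu, L))
  expect_error(darcy_flow(-1, A, dP, mu, L), "positive")
})

test_that("bicarbonate inverts Henderson-Hasselbalch", {
  cst <- csf_constants()
  # at pH = pKa the ratio term is 1
  expect_equal(bicarbonate_from_gas(6.1, 40, cst), 0.03 * 40)
  # oracle: 0.03 * 40 * 10^(7.4 - 6.1)
  expect_equal(bicarbonate_from_gas(7.4, 40, cst), 0.03 * 40 * 10^1.3,
               tolerance = 1e-12)
  expect_equal(bicarbonate_from_gas(7.4, 40, cst), 23.94, tolerance = 1e-3)
  expect_equal(bicarbonate_from_gas(8.4, 40, cst),
               10 * bicarbonate_from_gas(7.4, 40, cst))
  expect_error(bicarbonate_from_gas(7.4, 0), "positive")
})

test_that("metabolic water follows glucose-oxidation stoichiometry", {
  # oracle: 6 waters x 18.015 uL/mmol per glucose = 0.10809 uL/umol
  expect_equal(metabolic_params()$nu_water_per_glucose, 6 * 18.015 / 1000,
               tolerance = 1e-9)
  p <- metabolic_params(k_gluc = 0.01)
  # k C V / 1000 umol/min destroyed, times nu
  expect_equal(metabolic_water_rate(3, 6000, p),
               0.10809 * 0.01 * 3 * 6000 / 1000, tolerance = 1e-9)
  expect_identical(metabolic_water_rate(3, 6000, metabolic_params(k_gluc = 0)), 0)
  # direct override (the adult-human operating value)
  p34 <- metabolic_params(direct_G_override = 34)
  expect_identical(metabolic_water_rate(0, 0, p34), 34)
  both <- metabolic_params(k_gluc = 0.01, direct_G_override = 34)
  expect_error(metabolic_water_rate(3, 6000, both), "not both")
})

test_that("solvent drag is upwind and unit-consistent", {
  # 10 uL/min of water dragging 2 mmol/L = 2 umol/mL at sigma 0
  expect_equal(solvent_drag_molar_flux(10, 0, 2), 0.02)
  expect_identical(solvent_drag_molar_flux(10, 1, 2), 0)
  # reversed flux takes the downstream side as donor
  expect_equal(solvent_drag_molar_flux(-10, 0, 2, C_to = 5), -0.05)
  expect_error(solvent_drag_molar_flux(1, 1.5, 1), "\\[0, 1\\]")
})

test_that("osmotic pressure of mixtures superposes across species", {
  set.seed(42)
  cst <- csf_constants()
  sp <- csf_species()
  for (i in 1:20) {
    conc <- stats::setNames(stats::runif(nrow(sp), 0, 300), sp$name)
    total <- osmotic_pressure(osmolarity(conc, sp), cst)
    parts <- vapply(sp$name, function(s) {
      osmotic_pressure(osmolarity(conc[s], sp), cst)
    }, 0)
    expect_equal(total, sum(parts), tolerance = 1e-10)
  }
})
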