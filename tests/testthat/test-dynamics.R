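# Balance assembly, conservation, pressure closure, integration, and the
# steady-state solver.

test_that("uniform pressures and compositions are a global equilibrium", {
  m <- test_model(sealed = TRUE, uniform = TRUE, pumps = FALSE, G = 0)
  y <- csf_state(m)
  bal <- csf_balance(m, y)
  # fixed point up to the valve-smoothing leak (~5e-7 uL/min at zero drive)
  expect_lt(max(abs(bal$dstate)), 2e-6)
  # and the fixed point is attracting: moving water between compartments
  # (conserving every total) relaxes back to the same equilibrium
  y2 <- as.numeric(y)
  y2[5] <- y2[5] + 20
  y2[8] <- y2[8] - 20
  tr <- csf_integrate(m, NULL, c(0, 2000), state0 = y2, n_save = 5)
  yend <- tr$states[nrow(tr$states), ]
  expect_lt(max(abs(yend[5:8] - as.numeric(y)[5:8]) / as.numeric(y)[5:8]), 1e-3)
})

test_that("compartment balances telescope to boundary flows plus sources", {
  m <- test_model(G = 0.7)
  protocol <- csf_protocol(list(kind = "continuous_infusion",
                                site = "ventricles", start = 0, rate = 3,
                                composition = c(Na = 160, Cl = 160)))
  y <- as.numeric(csf_state(m))
  set.seed(11)
  y[5:8] <- y[5:8] * (1 + stats::runif(4, -0.1, 0.1))
  bal <- csf_balance(m, y, protocol, t = 1)
  total_dV <- sum(bal$dstate[1:8])
  expect_equal(total_dV,
               unname(bal$aux[["flux_Q1"]] - bal$aux[["flux_Q5"]] +
                        bal$aux[["G"]] + 3),
               tolerance = 1e-9)
})

test_that("sealed systems conserve water and every species along trajectories", {
  m <- test_model(sealed = TRUE, pumps = TRUE, G = 0)
  y0 <- as.numeric(csf_state(m))
  set.seed(3)
  y0[5:8] <- y0[5:8] * (1 + stats::runif(4, -0.1, 0.1))
  tr <- csf_integrate(m, NULL, c(0, 300), state0 = y0, n_save = 10)
  t0 <- state_totals(m, y0)
  for (i in seq_along(tr$times)) {
    ti <- state_totals(m, tr$states[i, ])
    expect_lt(abs(ti$water - t0$water) / t0$water, 1e-7)
    nz <- t0$species > 0
    expect_lt(max(abs(ti$species[nz] - t0$species[nz]) / t0$species[nz]), 1e-7)
  }
})

test_that("fully reflecting membranes carry water but no solute", {
  # sigma = 1 on every membrane arc, no pumps, uniform pressures: raise the
  # ventricular sodium and inspect the instantaneous balances
  m <- test_model(sealed = TRUE, uniform = TRUE, pumps = FALSE, sigma_ep = 1)
  y <- as.numeric(csf_state(m))
  i_na <- 8 + (which(m$species$name == "Na") - 1) * 8 + 5
  y[i_na] <- y[i_na] * 1.5
  bal <- csf_balance(m, y)
  J7 <- bal$aux[["flux_J7"]]
  expect_gt(J7, 0)                       # water drawn toward the ventricle
  # the ventricle gains water but no sodium (aqueduct flow is still zero,
  # and the membranes reflect the solute completely)
  expect_equal(unname(bal$aux[["flux_Q11"]]), 0, tolerance = 1e-12)
  expect_equal(unname(bal$dstate[["A_ventricles_Na"]]), 0, tolerance = 1e-12)
  # the arterioles lose pure water through the choroidal membrane, so their
  # luminal throughflow leaves them a solute surplus of C * J7
  C_na <- 150
  expect_equal(unname(bal$dstate[["A_arterioles_Na"]]), C_na * J7 / 1000,
               tolerance = 1e-9)
})

test_that("raising ventricular osmolarity above the ECS drives trans-ependymal inflow", {
  m <- test_model(sealed = TRUE, uniform = TRUE, pumps = FALSE, sigma_ep = 1)
  y <- as.numeric(csf_state(m))
  i_na <- 8 + (which(m$species$name == "Na") - 1) * 8 + 5
  y[i_na] <- y[i_na] * 1.2
  bal <- csf_balance(m, y)
  expect_gt(bal$aux[["flux_J10"]], 0)
})

test_that("pressure closure follows the compliance law and rigid nodes balance", {
  m <- test_model()
  y <- csf_state(m)
  P <- pressure_closure(m, y)
  # compliant nodes at rest volume sit at rest pressure
  expect_equal(unname(P["ventricles"]), 10, tolerance = 1e-12)
  expect_equal(unname(P["SAS"]), 10, tolerance = 1e-12)
  # rigid nodes: the quasi-steady pressures make their net flux vanish
  bal <- csf_balance(m, y)
  expect_lt(max(abs(bal$dstate[1:4])), 1e-12)
  # a very large compliance approximates constant pressure
  m2 <- csf_update_params(m, c("ventricles.kappa" = 1e9))
  y2 <- as.numeric(csf_state(m2))
  y2[5] <- y2[5] * 1.5
  P2 <- pressure_closure(m2, y2)
  expect_lt(abs(P2[["ventricles"]] - 10), 1e-5)
})

test_that("integration reproduces the global water balance by quadrature", {
  m <- test_model(G = 0.4)
  y0 <- as.numeric(csf_state(m))
  tr <- csf_integrate(m, NULL, c(0, 400), state0 = y0, n_save = 400)
  v_tot <- rowSums(tr$states[, 1:8])
  net <- tr$aux[, "flux_Q1"] - tr$aux[, "flux_Q5"] + tr$aux[, "G"]
  dt <- diff(tr$times)
  integral <- sum((net[-1] + net[-length(net)]) / 2 * dt)
  change <- v_tot[length(v_tot)] - v_tot[1]
  scale <- max(abs(change), sum(abs(net)) * mean(dt), 1)
  expect_lt(abs(change - integral) / scale, 1e-3)
})

test_that("halving the tolerances barely moves the endpoint", {
  m <- test_model()
  y0 <- as.numeric(csf_state(m))
  y0[5] <- y0[5] * 1.1
  e1 <- csf_integrate(m, NULL, c(0, 200), state0 = y0, rtol = 1e-8,
                      atol = 1e-10, n_save = 3)
  e2 <- csf_integrate(m, NULL, c(0, 200), state0 = y0, rtol = 5e-9,
                      atol = 5e-11, n_save = 3)
  d <- abs(e1$states[3, ] - e2$states[3, ])
  expect_lt(max(d / pmax(abs(e1$states[3, ]), 1e-3)), 1e-6)
})

test_that("the steady-state solver fixes equilibria and agrees with long integration", {
  m <- test_model(sealed = TRUE, uniform = TRUE, pumps = FALSE, G = 0)
  y <- csf_state(m)
  ss <- csf_steady_state(m, NULL, state0 = y, pre_integrate = 0)
  expect_lt(max(abs(as.numeric(ss) - as.numeric(y)) /
                  pmax(abs(as.numeric(y)), 1e-3)), 1e-8)

  # open boundaries: steady state balances inflow against outflow net of G
  # (a large metabolic source keeps every washout time constant well under
  # the integration horizon)
  m2 <- test_model(G = 5)
  ss2 <- csf_steady_state(m2, NULL, confirm = TRUE)
  aux <- attr(ss2, "aux")
  expect_equal(unname(aux[["flux_Q1"]] - aux[["flux_Q5"]] + aux[["G"]]), 0,
               tolerance = 1e-6)
  # long-time limit of the transient integration lands on the same state
  tr <- csf_integrate(m2, NULL, c(0, 1e4), n_save = 4)
  yend <- as.numeric(tr$states[nrow(tr$states), ])
  expect_lt(max(abs(yend - as.numeric(ss2)) /
                  pmax(abs(as.numeric(ss2)), 1e-3)), 1e-3)
})

test_that("bolus events are conservative state jumps that reach downstream", {
  m <- test_model(sealed = TRUE, pumps = FALSE)
  y0 <- as.numeric(csf_state(m))
  protocol <- csf_protocol(list(kind = "bolus", site = "ventricles",
                                start = 10, volume = 20,
                                composition = c(tracer = 1)))
  tr <- csf_integrate(m, protocol, c(0, 120), state0 = y0, n_save = 60)
  t0 <- state_totals(m, y0)
  tend <- state_totals(m, tr$states[nrow(tr$states), ])
  expect_equal(tend$water, t0$water + 20, tolerance = 1e-6)
  expect_equal(unname(tend$species["tracer"]), 20 * 1 / 1000,
               tolerance = 1e-8)
  # tracer appears downstream in the SAS
  expect_gt(tr$states[nrow(tr$states), "A_SAS_tracer"], 0)
})

test_that("one-way arcs never carry reverse flux along trajectories", {
  m <- test_model(one_way_cp = TRUE)
  y0 <- as.numeric(csf_state(m))
  set.seed(5)
  y0[5:8] <- y0[5:8] * (1 + stats::runif(4, -0.15, 0.15))
  tr <- csf_integrate(m, NULL, c(0, 500), state0 = y0, n_save = 100)
  expect_true(all(tr$aux[, "flux_J12"] >= 0))
  expect_true(all(tr$aux[, "flux_J7"] >= 0))
})
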