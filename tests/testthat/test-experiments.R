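# Virtual experiments on the shipped configurations.

feline <- csf_config("feline_vcp")
feline_base <- csf_steady_state(feline, NULL)

test_that("disabling every membrane stops nascent flow and tracer dilution", {
  m0 <- csf_update_params(feline, c("J7.LpA" = 0, "J8.LpA" = 0,
                                    "J10.LpA" = 0, "J12.LpA" = 0))
  v <- run_vcp(m0, 320)
  expect_equal(v$C_out, v$C_inj, tolerance = 1e-6)
  expect_lt(abs(v$Q_f), 1e-3)
  # zero up to the one-way smoothing leak
  expect_lt(abs(v$Q_nascent_true), 1e-5)
})

test_that("the sampled steady-state criterion agrees with the direct solve", {
  v1 <- run_vcp(feline, 320, state0 = feline_base)
  v2 <- run_vcp(feline, 320, state0 = feline_base, method = "sampled")
  expect_lt(abs(v1$Q_f - v2$Q_f) / max(abs(v1$Q_f), 2), 0.02)
})

test_that("nascent flow responds monotonically to osmotic loading", {
  dv <- dose_response(feline, "ventricle", osm_grid = c(6, 150, 320, 500, 780),
                      state0 = feline_base)
  expect_true(all(diff(dv$Q_f) >= -1e-6))
  expect_gt(attr(dv, "local_sensitivity"), 0)

  base_s <- serum_osmolarity(feline)
  ds <- dose_response(feline, "serum",
                      osm_grid = sort(c(290, base_s, 340, 360)),
                      state0 = feline_base)
  expect_true(all(diff(ds$Q_f) <= 1e-6))
  expect_lt(attr(ds, "local_sensitivity"), 0)
})

test_that("serum loading helpers hit the requested osmolarity", {
  m <- csfnet:::.with_serum_osm(feline, 360)
  expect_equal(serum_osmolarity(m), 360, tolerance = 1e-9)
  m2 <- csfnet:::.with_serum_osm(feline, 290)
  expect_equal(serum_osmolarity(m2), 290, tolerance = 1e-9)
})

test_that("an intravenous tracer accumulates faster under ventricular hyperosmolarity", {
  canine <- csf_config("canine_bolus")
  tb <- run_tracer_bolus(canine, bolus_osm = 950, arms = "both",
                         t_bolus = 30, duration = 90)
  hyper <- tb$curves[tb$curves$arm == "hyperosmolar", ]
  iso <- tb$curves[tb$curves$arm == "isomolar", ]
  post <- hyper$time > 35 & hyper$time < 80
  expect_true(all(hyper$tracer_ventricles[post] >=
                    iso$tracer_ventricles[post] - 1e-12))
  expect_gt(mean(hyper$tracer_ventricles[post] - iso$tracer_ventricles[post]),
            0)
  # the hyperosmolar bolus raises nascent flow above the pre-bolus level
  expect_gt(tb$plateau_nascent, tb$control_nascent)
  # an isomolar bolus leaves the accumulation curve essentially unchanged
  tb_iso <- run_tracer_bolus(canine, bolus_osm = 320, arms = "both",
                             t_bolus = 30, duration = 90)
  h2 <- tb_iso$curves[tb_iso$curves$arm == "hyperosmolar", ]
  i2 <- tb_iso$curves[tb_iso$curves$arm == "isomolar", ]
  expect_lt(max(abs(h2$tracer_ventricles - i2$tracer_ventricles)) /
              max(i2$tracer_ventricles), 1e-6)
})

test_that("chronic intraventricular loading grows the ventricle monotonically", {
  chronic <- csf_config("chronic_infusion")
  base <- csf_steady_state(chronic, NULL)
  iso <- run_chronic_infusion(chronic, osm = 307, days = 4, base_state = base,
                              n_save = 30)
  hyper <- run_chronic_infusion(chronic, osm = 337, days = 4,
                                base_state = base, n_save = 30)
  expect_gt(hyper$pct_increase, iso$pct_increase)
  # loading never shrinks the ventricle over time (up to integrator ripple
  # on the plateau, well below 0.001 percentage points)
  expect_true(all(diff(hyper$timecourse$pct_increase) > -1e-3))
  # longer loading at fixed osmolarity is nondecreasing
  hyper8 <- run_chronic_infusion(chronic, osm = 337, days = 8,
                                 base_state = base, n_save = 30)
  expect_gte(hyper8$pct_increase, hyper$pct_increase - 1e-3)
})

test_that("trajectory tidiers and plots expose the run", {
  tr <- csf_integrate(test_model(), NULL, c(0, 30), n_save = 10)
  td <- tidy(tr)
  expect_true(all(c("time", "compartment", "volume", "pressure",
                    "osmolarity") %in% names(td)))
  expect_equal(nrow(td), 8 * length(tr$times))
  tf <- tidy_fluxes(tr)
  expect_setequal(unique(tf$arc), names(test_model()$arcs))
  p <- ggplot2::autoplot(tr)
  expect_s3_class(p, "ggplot")
  stem <- withr::local_tempfile()
  files <- write_trajectory_csv(tr, stem)
  expect_true(all(file.exists(files)))
  back <- utils::read.csv(files[1])
  expect_true("C_Na" %in% names(back))
})
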