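# Anchor sets, least-squares calibration, recovery, determinism.

test_that("anchor sets transcribe the packaged fixtures", {
  sets <- csf_anchor_sets()
  expect_setequal(names(sets),
                  c("human_baseline", "feline_vcp", "canine_bolus",
                    "chronic_infusion"))
  fel <- sets$feline_vcp
  expect_equal(sum(fel$observable == "nascent_flow"), 8)
  expect_equal(sum(fel$observable == "sensitivity"), 2)
  expect_equal(fel$target_value[fel$name == "E1_320"], 24.9)
  expect_equal(fel$target_value[fel$name == "E1_780"], 88.0)
  expect_equal(fel$target_value[fel$name == "sens_ventricle"], 0.231)
  expect_equal(fel$target_value[fel$name == "sens_serum"], 0.835)
  # every anchor value equals the fixture cell it cites
  t2 <- read.csv(system.file("extdata", "table2_vcp.csv", package = "csfnet"))
  for (e in c("E1", "E3", "E5")) {
    rows <- t2[t2$experiment == e, ]
    for (i in seq_len(nrow(rows))) {
      nm <- paste0(e, "_", rows$injection_mOsm[i])
      expect_equal(fel$target_value[fel$name == nm],
                   rows$bulk_flow_uL_min[i])
    }
  }
  chr <- sets$chronic_infusion
  expect_true(any(chr$osm == 307 & chr$target_value == 0))  # isotonic row
  expect_equal(chr$target_value[chr$osm == 337 & chr$duration_days == 15], 125)
  expect_equal(sets$human_baseline$target_value[
    sets$human_baseline$observable == "production_per_day"], 580)
  expect_true(all(unlist(lapply(sets, function(s) s$weight)) > 0))
})

test_that("calibration is self-consistent at the generating parameters", {
  m <- csf_config("canine_bolus")
  anchors <- csf_anchor_sets("canine_bolus")
  cache <- new.env()
  anchors$target_value <- csfnet:::.eval_anchors(m, anchors, cache)
  cal <- calibrate(m, anchors, c("J7.LpA", "J7.sigma.sucrose"),
                   seed = 1, n_starts = 1, maxiter = 3)
  expect_lt(max(abs(cal$residuals$residual) /
                  pmax(abs(cal$residuals$target), 1)), 0.01)
  expect_lt(max(abs(cal$params$fitted / cal$params$start - 1)), 0.05)
})

test_that("perturbed parameters are recovered from synthetic anchors", {
  m <- csf_config("canine_bolus")
  truth <- c("J7.LpA" = unname(csf_get_params(m, "J7.LpA")) * 1.35,
             "J7.sigma.sucrose" =
               unname(csf_get_params(m, "J7.sigma.sucrose")) * 0.75)
  m_true <- csf_update_params(m, truth)
  anchors <- csf_anchor_sets("canine_bolus")
  anchors$target_value <- csfnet:::.eval_anchors(m_true, anchors, new.env())
  cal <- calibrate(m, anchors, names(truth), seed = 1, n_starts = 1,
                   maxiter = 12)
  expect_lt(max(abs(cal$params$fitted / unname(truth) - 1)), 0.05)
})

test_that("identical seeds give bit-identical fits", {
  m <- csf_config("canine_bolus")
  anchors <- csf_anchor_sets("canine_bolus")
  cal1 <- calibrate(m, anchors, c("J7.LpA", "J7.sigma.sucrose"),
                    seed = 7, n_starts = 2, maxiter = 3, eval_timeout = 20)
  cal2 <- calibrate(m, anchors, c("J7.LpA", "J7.sigma.sucrose"),
                    seed = 7, n_starts = 2, maxiter = 3, eval_timeout = 20)
  expect_identical(cal1$params$fitted, cal2$params$fitted)
  expect_identical(cal1$objective, cal2$objective)
})

test_that("parameters without leverage on the anchors are flagged non-identifiable", {
  m <- csf_config("human_baseline")
  anchors <- csf_anchor_sets("human_baseline")
  # these anchors are all steady-state quantities; a compartment compliance
  # moves none of them (rest pressures sit at the solved baseline)
  cal <- calibrate(m, anchors, c("J7.pump.mannitol", "ECS.kappa"),
                   lower = c("ECS.kappa" = 0.5), upper = c("ECS.kappa" = 2),
                   seed = 1, n_starts = 1, maxiter = 2, eval_timeout = 60)
  p <- cal$params
  expect_true(p$identifiable[p$path == "J7.pump.mannitol"])
  expect_false(p$identifiable[p$path == "ECS.kappa"])
})

test_that("tidy and glance summarize a calibration", {
  m <- csf_config("canine_bolus")
  anchors <- csf_anchor_sets("canine_bolus")
  cal <- calibrate(m, anchors, "J7.LpA", seed = 1, n_starts = 1, maxiter = 2)
  td <- tidy(cal)
  expect_true(all(c("path", "start", "fitted", "identifiable") %in% names(td)))
  g <- glance(cal)
  expect_equal(g$n_anchors, nrow(anchors))
  expect_equal(g$n_params, 1)
})
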