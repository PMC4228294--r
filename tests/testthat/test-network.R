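# Topology construction, validation, and configuration round-trips.

test_that("canonical network builds with 8 compartments and 12 arcs", {
  m <- test_model()
  expect_s3_class(m, "csf_model")
  expect_equal(nrow(m$comp), 8)
  expect_length(m$arcs, 12)
  expect_true(m$arcs$J12$one_way)
  expect_false(m$arcs$J7$one_way)
  expect_identical(m$arcs$J7$from, "arterioles")
  expect_identical(m$arcs$J7$to, "ventricles")
  expect_identical(m$arcs$Q9$kind, "darcy")
  rep <- validate_degrees_of_freedom(m)
  expect_true(rep$closed)
  expect_length(rep$problems, 0)
})

test_that("invalid configurations are rejected with the offending field named", {
  cfg <- test_config()
  cfg$arcs[[8]]$sigma$albumin <- 1.3     # J8
  expect_error(build_canonical_network(cfg), "albumin")

  cfg <- test_config()
  cfg$compartments <- cfg$compartments[-7]   # drop PVS
  expect_error(build_canonical_network(cfg), "PVS")

  cfg <- test_config()
  cfg$arcs[[2]]$id <- "Q1"
  expect_error(build_canonical_network(cfg), "duplicate arc id.*Q1")

  cfg <- test_config()
  cfg$unexpected_section <- list(1)
  expect_error(build_canonical_network(cfg), "unexpected_section")

  cfg <- test_config()
  cfg$boundaries$inlet_pressure <- 1   # below outlet
  expect_error(build_canonical_network(cfg), "inlet_pressure")
})

test_that("degree-of-freedom analysis names unhoused unknowns", {
  cfg <- test_config()
  cfg$boundaries$arterial_concentrations$glucose <- NULL
  expect_error(build_canonical_network(cfg), "glucose")

  # removing the aqueduct leaves the ventricles without an outflow path
  cfg <- test_config()
  cfg$arcs <- Filter(function(a) a$id != "Q11", cfg$arcs)
  expect_error(build_canonical_network(cfg), "ventricles.*no outflow")
})

test_that("configuration round-trips through serialization and YAML", {
  cfg <- test_config()
  m1 <- build_canonical_network(cfg)
  m2 <- build_canonical_network(as_csf_config(m1))
  expect_equal(m1$comp, m2$comp)
  expect_equal(m1$species, m2$species)
  expect_equal(m1$boundaries, m2$boundaries)
  for (a in names(m1$arcs)) expect_equal(m1$arcs[[a]], m2$arcs[[a]])

  path <- withr::local_tempfile(fileext = ".yaml")
  write_csf_config(cfg, path)
  m3 <- build_canonical_network(read_csf_config(path))
  expect_equal(m1$comp, m3$comp)
  for (a in names(m1$arcs)) expect_equal(m1$arcs[[a]], m3$arcs[[a]])
})

test_that("every non-boundary compartment of the shipped configs has in- and outflow", {
  for (nm in c("feline_vcp", "canine_bolus", "chronic_infusion",
               "human_baseline")) {
    m <- csf_config(nm)
    rep <- validate_degrees_of_freedom(m)
    expect_true(rep$closed, info = nm)
  }
})

test_that("parameter paths read and write configuration scalars", {
  m <- test_model()
  v <- csf_get_params(m, c("J7.LpA", "J10.sigma.Na", "Q9.alpha",
                           "ventricles.kappa", "boundary.Na"))
  expect_equal(unname(v), c(0.05, 0, 5, 10, 150))
  m2 <- csf_update_params(m, c("J7.LpA" = 0.08, "J10.sigma.Na" = 0.5,
                               "ventricles.kappa" = 22))
  v2 <- csf_get_params(m2, c("J7.LpA", "J10.sigma.Na", "ventricles.kappa"))
  expect_equal(unname(v2), c(0.08, 0.5, 22))
  expect_error(csf_get_params(m, "Q99.alpha"), "unknown arc")
})
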