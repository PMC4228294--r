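# Run-level interface: trajectory export, run manifests, and the
# reproduction of the published operating points.

#' Export a trajectory to tidy CSV files
#'
#' Writes two files: `<stem>_states.csv` (time, compartment, volume,
#' pressure, osmolarity, one column per species concentration) and
#' `<stem>_fluxes.csv` (time, arc, flux).
#'
#' @param traj A `csf_trajectory`.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_trajectory_csv <- function(traj, stem) {
  st <- tidy(traj)
  conc <- tidy_concentrations(traj)
  wide <- tidyr::pivot_wider(conc, names_from = "species",
                             values_from = "concentration",
                             names_prefix = "C_")
  st <- dplyr::left_join(st, wide, by = c("time", "compartment"))
  f1 <- paste0(stem, "_states.csv")
  f2 <- paste0(stem, "_fluxes.csv")
  utils::write.csv(st, f1, row.names = FALSE)
  utils::write.csv(tidy_fluxes(traj), f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Run manifest
#'
#' A reproducibility record emitted alongside simulation output: hashes of
#' the configuration and protocol, the seed, package version and timestamp.
#' Hashes are plain FNV-1a over the serialized objects, so identical inputs
#' give identical manifests.
#'
#' @param config Configuration list.
#' @param protocol Protocol (or `NULL`).
#' @param seed Seed used for the run (or `NA`).
#' @return A list of class `csf_manifest`.
#' @export
csf_manifest <- function(config, protocol = NULL, seed = NA) {
  structure(list(
    config_hash = .fnv1a(config),
    protocol_hash = .fnv1a(protocol),
    seed = seed,
    package_version = as.character(utils::packageVersion("csfnet")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), class = "csf_manifest")
}

.fnv1a <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # drop the serialization header (platform-invariant payload only)
  bytes <- bytes[-(1:14)]
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor acts on the low byte only (b < 256); keep h as a double
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # h * 16777619 mod 2^32, exactly representable in double arithmetic
    h <- (h * 403 + (h * 16384) %% 4294967296 * 1024) %% 4294967296
  }
  # format the 32-bit value as hex from two 16-bit halves (h is a double)
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' @export
print.csf_manifest <- function(x, ...) {
  cat("<csf_manifest>\n")
  for (f in names(unclass(x))) cat(" ", f, ": ", as.character(x[[f]]), "\n", sep = "")
  invisible(x)
}

#' Write a manifest as JSON
#'
#' @param manifest A `csf_manifest`.
#' @param path Output file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------

.reproduce_targets <- function() {
  tibble::tibble(
    name = c("human_production_mL_day",
             "feline_sensitivity_ventricle",
             "feline_sensitivity_serum",
             "feline_control_nascent_flow",
             "feline_nascent_flow_780",
             "canine_bolus_response",
             "chronic_volume_increase_pct"),
    expected = c(580, 0.231, 0.835, 24.9, 88.0, 24.8, 125),
    tolerance = c(0.02, 0.10, 0.10, 0.05, 0.10, 0.10, NA),
    tol_abs = c(NA, NA, NA, NA, NA, NA, 10),
    units = c("mL/day", "uL/min/mOsm", "uL/min/mOsm", "uL/min", "uL/min",
              "uL/min", "%")
  )
}

#' Recompute the published operating points from scratch
#'
#' Runs the shipped calibrations and virtual experiments and reports the
#' model's value for each documented operating point: daily CSF production
#' of the human baseline; the feline perfusion control flow, its 780 mOsm
#' response, and the two local osmotic sensitivities; the canine
#' ventricular-bolus response; and the chronic-infusion ventricular volume
#' increase.  Everything is computed at call time by calibrating the
#' shipped configurations (deterministically, from `seed`) and running the
#' corresponding experiment operations.
#'
#' @param targets Character vector of target names (see the `name` column
#'   of the result), or `"all"`.
#' @param seed Integer seed passed to every calibration.
#' @param verbose Print progress.
#' @return A tibble with columns `name`, `value`, `expected`, `units`,
#'   `within_tolerance`, and `n` (the number of anchors behind the
#'   calibration that produced the value).
#' @export
csf_reproduce <- function(targets = "all", seed = 1, verbose = interactive()) {
  tt <- .reproduce_targets()
  if (!identical(targets, "all")) {
    unknown <- setdiff(targets, tt$name)
    if (length(unknown)) stop("unknown target(s): ", paste(unknown, collapse = ", "))
    tt <- tt[tt$name %in% targets, ]
  }
  say <- function(...) if (verbose) message(...)
  vals <- stats::setNames(rep(NA_real_, nrow(tt)), tt$name)
  ns <- stats::setNames(rep(NA_real_, nrow(tt)), tt$name)

  need <- function(x) any(grepl(x, tt$name))
  if (need("^human")) {
    say("calibrating human baseline ...")
    cal <- csf_calibrate_shipped("human_baseline", seed = seed)
    ss <- csf_steady_state(cal$model, NULL)
    vals["human_production_mL_day"] <- 1.44 * unname(attr(ss, "aux")[["Q_nascent"]])
    ns["human_production_mL_day"] <- nrow(cal$residuals)
  }
  if (need("^feline")) {
    say("calibrating feline perfusion model ...")
    cal <- csf_calibrate_shipped("feline_vcp", seed = seed)
    m <- cal$model
    say("running ventricular dose-response ...")
    dv <- dose_response(m, "ventricle", osm_grid = c(6, 320, 780))
    say("running serum dose-response ...")
    ds <- dose_response(m, "serum",
                        osm_grid = sort(c(290, serum_osmolarity(m), 360)))
    n <- nrow(cal$residuals)
    if ("feline_sensitivity_ventricle" %in% tt$name) {
      vals["feline_sensitivity_ventricle"] <- attr(dv, "local_sensitivity")
      ns["feline_sensitivity_ventricle"] <- n
    }
    if ("feline_sensitivity_serum" %in% tt$name) {
      vals["feline_sensitivity_serum"] <- abs(attr(ds, "local_sensitivity"))
      ns["feline_sensitivity_serum"] <- n
    }
    if ("feline_control_nascent_flow" %in% tt$name) {
      vals["feline_control_nascent_flow"] <- dv$Q_f[dv$osmolarity == 320]
      ns["feline_control_nascent_flow"] <- n
    }
    if ("feline_nascent_flow_780" %in% tt$name) {
      vals["feline_nascent_flow_780"] <- dv$Q_f[dv$osmolarity == 780]
      ns["feline_nascent_flow_780"] <- n
    }
  }
  if (need("^canine")) {
    say("calibrating canine bolus model ...")
    cal <- csf_calibrate_shipped("canine_bolus", seed = seed)
    tb <- run_tracer_bolus(cal$model, bolus_osm = 950, arms = "bolus")
    vals["canine_bolus_response"] <- tb$plateau_nascent
    ns["canine_bolus_response"] <- nrow(cal$residuals)
  }
  if (need("^chronic")) {
    say("calibrating chronic infusion model ...")
    cal <- csf_calibrate_shipped("chronic_infusion", seed = seed)
    rc <- run_chronic_infusion(cal$model, osm = 337, days = 15)
    vals["chronic_volume_increase_pct"] <- rc$pct_increase
    ns["chronic_volume_increase_pct"] <- nrow(cal$residuals)
  }

  out <- tt
  out$value <- unname(vals[out$name])
  out$n <- unname(ns[out$name])
  ok_rel <- abs(out$value - out$expected) <= out$tolerance * abs(out$expected)
  ok_abs <- abs(out$value - out$expected) <= out$tol_abs
  out$within_tolerance <- ifelse(is.na(out$tolerance), ok_abs, ok_rel)
  dplyr::select(out, "name", "value", "expected", "units",
                "within_tolerance", "n")
}
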