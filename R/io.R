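# On-disk schemas (comma-separated, UTF-8, mandatory header, ISO-8601 UTC):
#   deployments.csv  carcass_id,site_id,town,latitude,longitude,start_utc,
#                    end_utc,initial_mass_g,final_mass_g,removed,access_class,
#                    is_control
#   detections.csv   carcass_id,timestamp_utc,species,behavior
#   observations.csv carcass_id,species,behavior,start_utc,end_utc,duration_min
#   suntimes.csv     site_id,date,sunrise_utc,sunset_utc   (optional override)

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    abort_validation(sprintf("%s file not found: %s", what, path))
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    abort_validation(sprintf("%s is missing column(s): %s",
                             what, paste(missing, collapse = ", ")))
  }
  d
}

parse_time_column <- function(x, what, column) {
  out <- parse_utc(x)
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    abort_validation(sprintf("%s: unparseable %s at line %d (value '%s')",
                             what, column, bad[1] + 1L, x[bad[1]]))
  }
  out
}

#' Read a deployments table
#' @param path CSV path in the deployments schema.
#' @return Data frame with POSIXct `start`/`end` and logical flags.
#' @export
read_deployments <- function(path) {
  d <- read_csv_checked(path, c("carcass_id", "site_id", "town", "latitude",
                                "longitude", "start_utc", "end_utc",
                                "initial_mass_g", "final_mass_g", "removed",
                                "access_class", "is_control"), "deployments")
  out <- data.frame(
    carcass_id = as.character(d$carcass_id),
    site_id = as.character(d$site_id),
    town = as.character(d$town),
    latitude = as.numeric(d$latitude),
    longitude = as.numeric(d$longitude),
    start = parse_time_column(d$start_utc, "deployments", "start_utc"),
    end = parse_time_column(d$end_utc, "deployments", "end_utc"),
    initial_mass_g = as.numeric(d$initial_mass_g),
    final_mass_g = as.numeric(d$final_mass_g),
    removed = as.logical(d$removed == 1 | d$removed == "TRUE"),
    access_class = as.character(d$access_class),
    is_control = as.logical(d$is_control == 1 | d$is_control == "TRUE")
  )
  bad <- which(!out$access_class %in% c("ALL", "AVIAN_ONLY"))
  if (length(bad)) {
    abort_validation(sprintf(
      "deployments: unknown access_class '%s' at line %d",
      out$access_class[bad[1]], bad[1] + 1L))
  }
  bad <- which(out$end <= out$start)
  if (length(bad)) {
    abort_integrity(sprintf("deployments: end <= start for carcass %s (line %d)",
                            out$carcass_id[bad[1]], bad[1] + 1L))
  }
  validate_deployments(out)
  out
}

#' Read a detections table
#' @param path CSV path in the detections schema.
#' @return Data frame with POSIXct `timestamp`.
#' @export
read_detections <- function(path) {
  d <- read_csv_checked(path, c("carcass_id", "timestamp_utc", "species",
                                "behavior"), "detections")
  data.frame(
    carcass_id = as.character(d$carcass_id),
    timestamp = parse_time_column(d$timestamp_utc, "detections",
                                  "timestamp_utc"),
    species = as.character(d$species),
    behavior = as.character(d$behavior)
  )
}

#' Read an observations table
#' @param path CSV path in the observations schema.
#' @return Observation data frame.
#' @export
read_observations <- function(path) {
  d <- read_csv_checked(path, c("carcass_id", "species", "behavior",
                                "start_utc", "end_utc", "duration_min"),
                        "observations")
  data.frame(
    carcass_id = as.character(d$carcass_id),
    species = as.character(d$species),
    behavior = as.character(d$behavior),
    start = parse_time_column(d$start_utc, "observations", "start_utc"),
    end = parse_time_column(d$end_utc, "observations", "end_utc"),
    duration_min = as.numeric(d$duration_min)
  )
}

#' Read a sunrise/sunset override table
#' @param path CSV path in the suntimes schema.
#' @return Data frame `site_id`, `date`, `sunrise_utc`, `sunset_utc`.
#' @export
read_suntimes <- function(path) {
  d <- read_csv_checked(path, c("site_id", "date", "sunrise_utc",
                                "sunset_utc"), "suntimes")
  d$date <- as.Date(d$date)
  d
}

#' Assemble and validate a study bundle from CSV files
#'
#' Reads the deployment table plus a detection stream and/or a pre-extracted
#' observation table (at least one must be given; when observations are
#' supplied, frame-level extraction is skipped), with an optional
#' sunrise/sunset override. Cross-table referential integrity is enforced:
#' every detection and observation must reference a deployed carcass, and
#' timestamps must lie within the deployment window.
#'
#' @param deployments Path to `deployments.csv`.
#' @param detections Optional path to `detections.csv`.
#' @param observations Optional path to `observations.csv`.
#' @param suntimes Optional path to `suntimes.csv`.
#' @param config Named list of options (currently `gap_threshold_s`,
#'   `utc_offset_h`) merged over defaults.
#' @return An object of class `study_bundle`.
#' @export
read_study <- function(deployments, detections = NULL, observations = NULL,
                       suntimes = NULL, config = list()) {
  dep <- read_deployments(deployments)
  det <- if (!is.null(detections)) read_detections(detections)
  obs <- if (!is.null(observations)) read_observations(observations)
  sun <- if (!is.null(suntimes)) read_suntimes(suntimes)
  if (is.null(det) && is.null(obs)) {
    abort_validation("a study bundle needs a detections or an observations file")
  }
  for (nm in c("detections", "observations")) {
    t <- if (nm == "detections") det else obs
    if (is.null(t) || !nrow(t)) next
    bad <- which(!t$carcass_id %in% dep$carcass_id)
    if (length(bad)) {
      abort_integrity(sprintf("%s: unknown carcass id '%s' at line %d",
                              nm, t$carcass_id[bad[1]], bad[1] + 1L))
    }
    ts <- if (nm == "detections") t$timestamp else t$start
    idx <- match(t$carcass_id, dep$carcass_id)
    bad <- which(ts < dep$start[idx] | ts > dep$end[idx])
    if (length(bad)) {
      abort_integrity(sprintf(
        "%s: timestamp outside deployment window at line %d (carcass %s)",
        nm, bad[1] + 1L, t$carcass_id[bad[1]]))
    }
  }
  defaults <- list(gap_threshold_s = 60, utc_offset_h = 0)
  config <- utils::modifyList(defaults, config)
  structure(list(deployments = dep, detections = det, observations = obs,
                 suntimes = sun, config = config,
                 metadata = list(package_version =
                                   as.character(utils::packageVersion("carrionfate")))),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d deployments; %s detection frames; %s observations\n",
              nrow(x$deployments),
              if (is.null(x$detections)) "no" else nrow(x$detections),
              if (is.null(x$observations)) "no" else nrow(x$observations)))
  invisible(x)
}

#' Write study tables to CSV
#'
#' Writes `deployments.csv` and `detections.csv` in the standard schemas,
#' and, for simulated studies, the ground-truth ledger
#' (`truth_consumption.csv`, `truth_carcass.csv`, `truth_arrivals.csv`) and
#' a `metadata.yaml` recording the seed and package version. Output is
#' deterministic: identical studies produce byte-identical files.
#'
#' @param study A `carrion_study` from [simulate_study()] or a
#'   `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dep <- study$deployments
  out <- data.frame(
    carcass_id = dep$carcass_id, site_id = dep$site_id, town = dep$town,
    latitude = dep$latitude, longitude = dep$longitude,
    start_utc = format_utc(dep$start), end_utc = format_utc(dep$end),
    initial_mass_g = dep$initial_mass_g, final_mass_g = dep$final_mass_g,
    removed = as.integer(dep$removed), access_class = dep$access_class,
    is_control = as.integer(dep$is_control))
  utils::write.csv(out, file.path(dir, "deployments.csv"), row.names = FALSE)
  det <- study$detections
  if (!is.null(det)) {
    utils::write.csv(
      data.frame(carcass_id = det$carcass_id,
                 timestamp_utc = format_utc(det$timestamp),
                 species = det$species, behavior = det$behavior),
      file.path(dir, "detections.csv"), row.names = FALSE)
  }
  if (!is.null(study$truth)) {
    utils::write.csv(study$truth$consumption,
                     file.path(dir, "truth_consumption.csv"), row.names = FALSE)
    utils::write.csv(study$truth$carcass,
                     file.path(dir, "truth_carcass.csv"), row.names = FALSE)
    utils::write.csv(study$truth$arrivals,
                     file.path(dir, "truth_arrivals.csv"), row.names = FALSE)
    seed <- study$config$seed
    yaml::write_yaml(list(seed = if (is.null(seed)) NA else seed,
                          package_version =
                            as.character(utils::packageVersion("carrionfate"))),
                     file.path(dir, "metadata.yaml"))
  }
  invisible(dir)
}

#' Write an observations table
#' @param observations Observation data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(
    data.frame(carcass_id = observations$carcass_id,
               species = observations$species,
               behavior = observations$behavior,
               start_utc = format_utc(observations$start),
               end_utc = format_utc(observations$end),
               duration_min = observations$duration_min),
    path, row.names = FALSE)
  invisible(path)
}

#' Build a simulation configuration from a YAML file
#'
#' The YAML mirrors [simulation_config()] arguments; `species_profiles` is a
#' list of mappings passed to [species_profile()], and `season` a pair of
#' dates.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  profs <- lapply(y$species_profiles, function(p) do.call(species_profile, p))
  y$species_profiles <- profs
  if (!is.null(y$season)) y$season <- as.Date(unlist(y$season))
  if (!is.null(y$initial_mass_range_g)) {
    y$initial_mass_range_g <- as.numeric(unlist(y$initial_mass_range_g))
  }
  if (!is.null(y$deployment_duration_range_h)) {
    y$deployment_duration_range_h <-
      as.numeric(unlist(y$deployment_duration_range_h))
  }
  do.call(simulation_config, y)
}

#' Run the full analysis pipeline on a study bundle
#'
#' Extract observations (if not supplied), classify their diel timing,
#' attribute biomass loss among species, and compute the descriptive
#' summaries, optionally writing all output tables and a human-readable
#' report. The run is deterministic given its inputs.
#'
#' @param bundle A `study_bundle` from [read_study()], or a `carrion_study`
#'   from [simulate_study()] (converted internally).
#' @param body_masses Named scavenger body masses, grams.
#' @param out_dir Optional directory for output CSVs and `report.txt`.
#' @param ... Passed to [attribute_study()] (e.g. `method`, `fraction`).
#' @return An object of class `study_report`: list with `observations`
#'   (diel-classified), `attribution`, `attendance`, `detection`,
#'   `mass_loss`, `diel`, and `conservation` (max per-carcass residual, g).
#' @export
run_pipeline <- function(bundle, body_masses = default_body_masses(),
                         out_dir = NULL, ...) {
  if (inherits(bundle, "carrion_study")) {
    bundle <- structure(list(deployments = bundle$deployments,
                             detections = bundle$detections,
                             observations = NULL, suntimes = NULL,
                             config = list(gap_threshold_s = 60,
                                           utc_offset_h = 0),
                             metadata = list()),
                        class = "study_bundle")
  }
  obs <- bundle$observations
  if (is.null(obs)) {
    obs <- extract_observations(bundle$detections,
                                gap_threshold_s = bundle$config$gap_threshold_s)
  }
  obs <- classify_observations(obs, bundle$deployments, bundle$suntimes)
  att <- attribute_study(bundle$deployments, obs, body_masses = body_masses, ...)
  report <- structure(list(
    observations = obs,
    attribution = att,
    attendance = attendance_summary(bundle$deployments, obs,
                                    species = names(body_masses)),
    detection = scavenging_detection_summary(bundle$deployments, obs),
    mass_loss = mass_loss_comparison(bundle$deployments, obs),
    diel = diel_fraction(obs, bundle$deployments, bundle$suntimes),
    conservation = with(att$carcass,
                        max(abs(allocated_g + unattributed_g +
                                  nonvertebrate_g - loss_g), 0)),
    metadata = bundle$metadata
  ), class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_observations(obs, file.path(out_dir, "observations.csv"))
    utils::write.csv(att$carcass, file.path(out_dir, "attribution_carcass.csv"),
                     row.names = FALSE)
    utils::write.csv(att$allocations,
                     file.path(out_dir, "attribution_allocations.csv"),
                     row.names = FALSE)
    utils::write.csv(att$summary, file.path(out_dir, "study_summary.csv"),
                     row.names = FALSE)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  d <- x$detection
  cat("== Carcass-fate study report ==\n")
  cat(sprintf("Experimental carcasses: %d; attended by vertebrates: %d (%s%%); scavenged: %d (%s%%)\n",
              d$n_experimental, d$n_attended,
              format(round_half_up(d$attended_pct)),
              d$n_scavenged, format(round_half_up(d$scavenged_pct))))
  cat(sprintf("Observations: %d, of which scavenging behaviour: %d (%s%%)\n",
              d$n_observations, d$n_scavenging_observations,
              format(round_half_up(d$scavenging_obs_pct))))
  cat("\nPer-species activity:\n")
  print(x$attendance, row.names = FALSE, digits = 3)
  cat("\nDiel activity (% of observations in daylight):\n")
  print(x$diel, row.names = FALSE, digits = 3)
  cat("\nMass loss by scavenger presence:\n")
  print(x$mass_loss, row.names = FALSE, digits = 3)
  cat("\nBiomass attribution:\n")
  print(summary(x$attribution))
  cat(sprintf("Max conservation residual: %.2e g\n", x$conservation))
  invisible(x)
}
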