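#' Collapse per-image detections into behavioural observations
#'
#' An observation is the unit of replication: a contiguous interval during
#' which one species displays one behaviour at one carcass. Consecutive
#' frames of the same species at the same carcass whose inter-frame gaps do
#' not exceed `gap_threshold_s` form a single presence run; a run is split
#' into separate observations wherever the behaviour label changes. Each
#' observation's duration is the time from its first to its last frame, so a
#' single-frame observation has duration zero (it still counts toward
#' observation tallies, but contributes nothing to feeding time).
#'
#' Frames with species `NONE` (empty triggers) yield no observations.
#' Different species present simultaneously form independent runs.
#'
#' @param frames Detection frame table with columns `carcass_id`,
#'   `timestamp` (POSIXct, UTC), `species`, `behavior`, sorted by
#'   `(carcass_id, timestamp)`.
#' @param gap_threshold_s Maximum gap in seconds between frames of one run
#'   (> 0). The default of 60 s separates genuine revisits from camera reset
#'   gaps, which are well under a second.
#' @return Data frame of observations: `carcass_id`, `species`, `behavior`,
#'   `start`, `end` (POSIXct UTC), `duration_min`, ordered by
#'   `(carcass_id, start, species)`.
#' @examples
#' f <- data.frame(
#'   carcass_id = "C1",
#'   timestamp = as.POSIXct("2014-06-01 10:00:00", tz = "UTC") + 0:7,
#'   species = "CROW",
#'   behavior = rep(c("EATING", "EXAMINING"), c(5, 3)))
#' extract_observations(f)  # EATING 4 s, then EXAMINING 2 s
#' @export
extract_observations <- function(frames, gap_threshold_s = 60) {
  check_number(gap_threshold_s, "gap_threshold_s", lower = 1e-9)
  frames <- validate_frames(frames)
  frames <- frames[frames$species != SPECIES_NONE, , drop = FALSE]
  if (nrow(frames) == 0L) {
    return(empty_observations())
  }
  o <- order(frames$carcass_id, frames$species, frames$timestamp)
  f <- frames[o, , drop = FALSE]
  key <- paste(f$carcass_id, f$species)
  n <- nrow(f)
  new_key <- c(TRUE, key[-1] != key[-n])
  gap <- c(0, as.numeric(difftime(f$timestamp[-1], f$timestamp[-n],
                                  units = "secs")))
  new_run <- new_key | gap > gap_threshold_s
  new_obs <- new_run | c(TRUE, f$behavior[-1] != f$behavior[-n])
  id <- cumsum(new_obs)
  first <- which(new_obs)
  last <- c(first[-1] - 1L, n)
  out <- data.frame(
    carcass_id = f$carcass_id[first],
    species = f$species[first],
    behavior = f$behavior[first],
    start = f$timestamp[first],
    end = f$timestamp[last],
    duration_min = as.numeric(difftime(f$timestamp[last], f$timestamp[first],
                                       units = "mins")),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$carcass_id, out$start, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_observations <- function() {
  data.frame(carcass_id = character(0), species = character(0),
              behavior = character(0),
              start = as.POSIXct(character(0), tz = "UTC"),
              end = as.POSIXct(character(0), tz = "UTC"),
              duration_min = numeric(0))
}

validate_frames <- function(frames) {
  required <- c("carcass_id", "timestamp", "species", "behavior")
  missing <- setdiff(required, names(frames))
  if (length(missing)) {
    abort_validation(paste("detection frames lack column(s):",
                           paste(missing, collapse = ", ")))
  }
  if (nrow(frames) == 0L) return(frames)
  bad <- !frames$behavior %in% BEHAVIORS
  if (any(bad)) {
    abort_validation(sprintf(
      "unknown behavior code(s): %s (row %d first)",
      paste(unique(frames$behavior[bad]), collapse = ", "), which(bad)[1]))
  }
  none_mismatch <- xor(frames$species == SPECIES_NONE,
                       frames$behavior == "NONE")
  if (any(none_mismatch)) {
    abort_validation(sprintf(
      "behavior must be NONE exactly when species is NONE (row %d)",
      which(none_mismatch)[1]))
  }
  o <- order(frames$carcass_id, frames$timestamp)
  if (!identical(o, seq_len(nrow(frames)))) {
    abort_ordering("detection frames must be sorted by (carcass_id, timestamp)")
  }
  frames
}

#' Total eating time per carcass and species
#'
#' Sums observation durations over behaviour `EATING`, grouped by carcass and
#' species. Species from `species` (and carcasses from `carcasses`) with no
#' eating are zero-filled so downstream joins see an explicit zero rather
#' than a missing row.
#'
#' @param observations Observation table from [extract_observations()].
#' @param species Optional character vector of species codes to zero-fill.
#' @param carcasses Optional character vector of carcass ids to zero-fill.
#' @return Data frame `carcass_id`, `species`, `eating_min`.
#' @export
eating_time_by_species <- function(observations, species = NULL,
                                   carcasses = NULL) {
  eat <- observations[observations$behavior == "EATING", , drop = FALSE]
  species <- sort(unique(c(species, eat$species)))
  carcasses <- sort(unique(c(carcasses, observations$carcass_id)))
  out <- expand.grid(carcass_id = carcasses, species = species,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$carcass_id, out$species), , drop = FALSE]
  out$eating_min <- rep(0, nrow(out))
  if (nrow(eat) && nrow(out)) {
    agg <- stats::aggregate(duration_min ~ carcass_id + species, data = eat,
                            FUN = sum)
    idx <- match(paste(agg$carcass_id, agg$species),
                 paste(out$carcass_id, out$species))
    out$eating_min[idx] <- agg$duration_min
  }
  rownames(out) <- NULL
  out
}

#' Minutes from deployment to each species' first observation
#'
#' For every (carcass, species) pair that was observed, the latency in
#' minutes from the carcass being deployed to the start of the species'
#' first observation of any behaviour. Pairs never observed produce no row.
#'
#' @param deployments Deployment table with `carcass_id` and `start`.
#' @param observations Observation table.
#' @return Data frame `carcass_id`, `species`, `latency_min` (>= 0).
#' @export
first_arrival_latency <- function(deployments, observations) {
  if (nrow(observations) == 0L) {
    return(data.frame(carcass_id = character(0), species = character(0),
                      latency_min = numeric(0)))
  }
  idx <- match(observations$carcass_id, deployments$carcass_id)
  if (anyNA(idx)) {
    abort_integrity(sprintf(
      "observations reference unknown carcass id(s): %s",
      paste(unique(observations$carcass_id[is.na(idx)]), collapse = ", ")))
  }
  key <- paste(observations$carcass_id, observations$species)
  firsts <- tapply(as.numeric(observations$start), key, min)
  carcass <- sub(" .*", "", names(firsts))
  species <- sub("^[^ ]+ ", "", names(firsts))
  dep_start <- deployments$start[match(carcass, deployments$carcass_id)]
  out <- data.frame(
    carcass_id = carcass,
    species = species,
    latency_min = (as.numeric(firsts) - as.numeric(dep_start)) / 60,
    row.names = NULL
  )
  if (any(out$latency_min < 0)) {
    abort_integrity("observation precedes its deployment start")
  }
  out[order(out$carcass_id, out$species), , drop = FALSE]
}

#' Re-encode observations as a regular detection-frame stream
#'
#' Inverse of [extract_observations()] up to frame-interval resolution:
#' every observation is expanded into frames every `interval_s` seconds from
#' its start to its end. Useful for round-trip checks and for feeding
#' observation-level data to frame-level tools.
#'
#' @param observations Observation table.
#' @param interval_s Frame spacing in seconds.
#' @return A detection frame table sorted by `(carcass_id, timestamp)`.
#' @export
observations_to_frames <- function(observations, interval_s = 1) {
  if (nrow(observations) == 0L) {
    return(data.frame(carcass_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      species = character(0), behavior = character(0)))
  }
  n_frames <- pmax(1L, floor(observations$duration_min * 60 / interval_s) + 1L)
  idx <- rep(seq_len(nrow(observations)), n_frames)
  offset <- unlist(lapply(n_frames, function(k) seq_len(k) - 1L)) * interval_s
  out <- data.frame(
    carcass_id = observations$carcass_id[idx],
    timestamp = observations$start[idx] + offset,
    species = observations$species[idx],
    behavior = observations$behavior[idx]
  )
  out <- out[order(out$carcass_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
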