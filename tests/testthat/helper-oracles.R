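# Independent oracles, deliberately implemented differently from the package.

# Naive observation grouping: per frame, scan for the most recent frame of the
# same carcass+species and start a new observation on a large gap or a
# behaviour change. O(n^2)-style reference for extract_observations().
naive_extract <- function(frames, gap_threshold_s = 60) {
  frames <- frames[frames$species != "NONE", , drop = FALSE]
  if (!nrow(frames)) {
    return(data.frame(carcass_id = character(0), species = character(0),
                      behavior = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      duration_min = numeric(0)))
  }
  obs <- list()
  open <- list()   # key -> index into obs of the open observation
  for (i in seq_len(nrow(frames))) {
    key <- paste(frames$carcass_id[i], frames$species[i])
    t <- frames$timestamp[i]
    b <- frames$behavior[i]
    j <- open[[key]]
    extend <- !is.null(j) &&
      as.numeric(t) - as.numeric(obs[[j]]$end) <= gap_threshold_s &&
      obs[[j]]$behavior == b
    if (extend) {
      obs[[j]]$end <- t
    } else {
      # same run but behaviour changed, or a brand new run
      obs[[length(obs) + 1L]] <- list(carcass_id = frames$carcass_id[i],
                                      species = frames$species[i],
                                      behavior = b, start = t, end = t)
      open[[key]] <- length(obs)
    }
  }
  out <- do.call(rbind, lapply(obs, function(o) {
    data.frame(carcass_id = o$carcass_id, species = o$species,
               behavior = o$behavior, start = o$start, end = o$end,
               duration_min = as.numeric(difftime(o$end, o$start,
                                                  units = "mins")))
  }))
  out <- out[order(out$carcass_id, out$start, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Solar altitude (degrees) from the Meeus low-accuracy ephemeris -- a
# different formulation from the package's NOAA fractional-year equations.
solar_altitude_deg <- function(time, lat, lon) {
  rad <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + 36000.76983 * T) %% 360
  M <- 357.52911 + 35999.05029 * T
  C <- (1.914602 - 0.004817 * T) * sin(M * rad) +
    (0.019993 - 0.000101 * T) * sin(2 * M * rad) + 0.000289 * sin(3 * M * rad)
  lambda <- (L0 + C - 0.00569 -
               0.00478 * sin((125.04 - 1934.136 * T) * rad)) * rad
  eps <- (23.439291 - 0.0130042 * T +
            0.00256 * cos((125.04 - 1934.136 * T) * rad)) * rad
  decl <- asin(sin(eps) * sin(lambda))
  ra <- atan2(cos(eps) * sin(lambda), cos(lambda))
  gmst <- (280.46061837 + 360.98564736629 * (jd - 2451545)) %% 360
  H <- ((gmst + lon) * rad - ra)
  asin(sin(lat * rad) * sin(decl) +
         cos(lat * rad) * cos(decl) * cos(H)) / rad
}

# Minute-wise scan for the crossings of solar altitude through -0.833 deg
# (zenith 90.833): first upward crossing is sunrise, last downward crossing
# sunset. Returns POSIXct times (UTC) or NA when no crossing occurs.
oracle_sun_times <- function(lat, lon, date) {
  midnight <- as.POSIXct(paste0(format(as.Date(date)), " 00:00:00"),
                         tz = "UTC")
  grid <- midnight + seq(0, 86400, by = 60)
  alt <- solar_altitude_deg(grid, lat, lon)
  up <- alt >= -0.833
  rise <- which(!up[-length(up)] & up[-1])
  set <- which(up[-length(up)] & !up[-1])
  cross <- function(i) {
    # linear interpolation of the crossing inside the bracketing minute
    grid[i] + 60 * (-0.833 - alt[i]) / (alt[i + 1L] - alt[i])
  }
  list(sunrise = if (length(rise)) cross(rise[1]) else NA,
       sunset = if (length(set)) cross(set[length(set)]) else NA)
}

# Independent ledger summation: total accounted mass per carcass from the
# simulator's truth tables.
ledger_totals <- function(truth) {
  cons <- truth$consumption
  per <- tapply(cons$in_situ_g + cons$removed_g, cons$carcass_id, sum)
  tot <- truth$carcass$nonvertebrate_g + truth$carcass$remaining_g
  extra <- per[truth$carcass$carcass_id]
  tot + ifelse(is.na(extra), 0, extra)
}
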