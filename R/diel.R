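#' Compute sunrise and sunset for a site and date
#'
#' Sunrise and sunset (UTC) from the standard NOAA closed-form solar position
#' equations: fractional year, equation of time, solar declination, and the
#' hour angle at a zenith of 90.833 degrees (official sunrise, accounting for
#' atmospheric refraction and the solar disc radius). The hour angle is
#' refined once by re-evaluating the fractional year at the provisional event
#' time, which keeps results within about a minute of a minute-wise solar
#' altitude scan at temperate latitudes.
#'
#' @param latitude Degrees north (positive) or south (negative); must satisfy
#'   `abs(latitude) < 66.5` — polar day/night is not handled.
#' @param longitude Degrees east (positive) or west (negative).
#' @param date A `Date` (or anything coercible), possibly vectorised.
#' @return A data frame with one row per date: `date`, `latitude`,
#'   `longitude`, `sunrise`, `sunset` (POSIXct, UTC).
#' @examples
#' sun_times(52.04, -0.75, as.Date("2014-06-21"))
#' @export
sun_times <- function(latitude, longitude, date) {
  check_number(latitude, "latitude", lower = -90, upper = 90)
  check_number(longitude, "longitude", lower = -180, upper = 180)
  if (abs(latitude) >= 66.5) {
    abort_validation(sprintf(
      "unsupported latitude %.2f: polar day/night (|lat| >= 66.5) not handled",
      latitude))
  }
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))

  event_minutes <- function(rise) {
    # one fixed-point refinement of the fractional year at the event hour
    minutes <- rep(720, length(doy))
    for (pass in 1:3) {
      sol <- solar_parameters(doy, minutes / 60)
      ha <- hour_angle_deg(latitude, sol$decl)
      sign <- if (rise) 1 else -1
      minutes <- 720 - 4 * (longitude + sign * ha) - sol$eqtime
    }
    minutes
  }

  sunrise_min <- event_minutes(TRUE)
  sunset_min <- event_minutes(FALSE)
  midnight <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  data.frame(
    date = date,
    latitude = latitude,
    longitude = longitude,
    sunrise = midnight + sunrise_min * 60,
    sunset = midnight + sunset_min * 60
  )
}

# NOAA fractional-year quantities: equation of time (minutes) and solar
# declination (radians), evaluated at a given UTC decimal hour.
solar_parameters <- function(doy, hour) {
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime = eqtime, decl = decl)
}

# Hour angle (degrees) at official sunrise/sunset zenith 90.833 deg.
hour_angle_deg <- function(latitude_deg, decl_rad) {
  phi <- latitude_deg * pi / 180
  zen <- 90.833 * pi / 180
  cosha <- cos(zen) / (cos(phi) * cos(decl_rad)) - tan(phi) * tan(decl_rad)
  cosha <- pmin(1, pmax(-1, cosha))
  acos(cosha) * 180 / pi
}

#' Classify times of day as DAY or NIGHT
#'
#' A time is `DAY` when it falls in the half-open interval
#' `[sunrise, sunset)` — closed at sunrise, open at sunset — and `NIGHT`
#' otherwise. For observations, the start time decides the class; bouts that
#' span sunset are not split.
#'
#' @param time POSIXct vector (UTC).
#' @param sunrise,sunset POSIXct vectors (recycled) bracketing daylight for
#'   the relevant date and site.
#' @return Character vector of `"DAY"`/`"NIGHT"`.
#' @examples
#' st <- sun_times(52.04, -0.75, as.Date("2014-06-21"))
#' classify_diel(st$sunrise + 3600, st$sunrise, st$sunset)
#' @export
classify_diel <- function(time, sunrise, sunset) {
  ifelse(time >= sunrise & time < sunset, "DAY", "NIGHT")
}

# Sunrise/sunset for a vector of (lat, lon, date) rows, honouring a
# user-supplied override table (site_id, date, sunrise_utc, sunset_utc).
site_sun_times <- function(latitude, longitude, date, site_id = NULL,
                           suntimes = NULL) {
  date <- as.Date(date)
  n <- length(date)
  sunrise <- rep(as.POSIXct(NA, tz = "UTC"), n)
  sunset <- sunrise
  if (!is.null(suntimes) && !is.null(site_id)) {
    key <- paste(site_id, format(date))
    tab_key <- paste(suntimes$site_id, format(as.Date(suntimes$date)))
    hit <- match(key, tab_key)
    found <- !is.na(hit)
    sunrise[found] <- parse_utc(suntimes$sunrise_utc[hit[found]])
    sunset[found] <- parse_utc(suntimes$sunset_utc[hit[found]])
  }
  todo <- which(is.na(sunrise))
  if (length(todo)) {
    # group by (lat, lon) so sun_times is called once per site
    grp <- paste(latitude[todo], longitude[todo])
    for (g in unique(grp)) {
      idx <- todo[grp == g]
      st <- sun_times(latitude[idx[1]], longitude[idx[1]], date[idx])
      sunrise[idx] <- st$sunrise
      sunset[idx] <- st$sunset
    }
  }
  data.frame(sunrise = sunrise, sunset = sunset)
}

#' Attach a DAY/NIGHT class to each observation
#'
#' Looks up each observation's deployment for site coordinates, computes
#' sunrise and sunset for the observation's start date (or takes them from an
#' optional override table), and classifies the start time.
#'
#' @param observations Observation table (see [extract_observations()]).
#' @param deployments Deployment table with `carcass_id`, `site_id`,
#'   `latitude`, `longitude`.
#' @param suntimes Optional override table with columns `site_id`, `date`,
#'   `sunrise_utc`, `sunset_utc`, used for exact replication of an external
#'   sunrise/sunset source.
#' @return `observations` with added columns `diel` (`"DAY"`/`"NIGHT"`),
#'   `sunrise` and `sunset`.
#' @export
classify_observations <- function(observations, deployments, suntimes = NULL) {
  if (nrow(observations) == 0L) {
    observations$diel <- character(0)
    return(observations)
  }
  idx <- match(observations$carcass_id, deployments$carcass_id)
  if (anyNA(idx)) {
    abort_integrity(sprintf(
      "observations reference unknown carcass id(s): %s",
      paste(unique(observations$carcass_id[is.na(idx)]), collapse = ", ")))
  }
  st <- site_sun_times(deployments$latitude[idx], deployments$longitude[idx],
                       as.Date(observations$start, tz = "UTC"),
                       deployments$site_id[idx], suntimes)
  observations$diel <- classify_diel(observations$start, st$sunrise, st$sunset)
  observations$sunrise <- st$sunrise
  observations$sunset <- st$sunset
  observations
}

#' Per-species percentage of observations made during the day
#'
#' The denominator for each species is all of its observations; species with
#' no observations do not appear in the result (an empty denominator is
#' reported as missing, not as zero).
#'
#' @inheritParams classify_observations
#' @return Data frame with one row per observed species: `species`,
#'   `n_observations`, `n_day`, `day_pct` (0–100).
#' @export
diel_fraction <- function(observations, deployments, suntimes = NULL) {
  obs <- classify_observations(observations, deployments, suntimes)
  if (nrow(obs) == 0L) {
    return(data.frame(species = character(0), n_observations = integer(0),
                      n_day = integer(0), day_pct = numeric(0)))
  }
  n <- tapply(obs$diel, obs$species, length)
  nd <- tapply(obs$diel == "DAY", obs$species, sum)
  out <- data.frame(
    species = names(n),
    n_observations = as.integer(n),
    n_day = as.integer(nd),
    day_pct = 100 * as.integer(nd) / as.integer(n),
    row.names = NULL
  )
  out[order(out$species), , drop = FALSE]
}

#' Kernel density of activity time of day
#'
#' Estimates a species' activity curve over the 24-h clock from observation
#' start times. The default estimator is a circular (wrapped) Gaussian kernel
#' density on `[0, 24)`: each kernel contribution is wrapped modulo 24 h so
#' the curve has no artificial boundary at midnight and integrates to one
#' over the day. A plain linear estimate on `[0, 24]` (renormalised to unit
#' mass) is available with `wrap = FALSE` for replicating analyses done with
#' non-circular density software.
#'
#' @param times_of_day Numeric vector of times in decimal hours; values are
#'   folded into `[0, 24)`. At least two points are required.
#' @param bandwidth Kernel standard deviation in hours, or `"auto"` for the
#'   normal reference rule ([stats::bw.nrd0()]) on the linearised sample.
#' @param n_grid Number of grid intervals over the 24-h day (the grid has
#'   `n_grid + 1` points including both endpoints).
#' @param wrap Use the circular estimator (default) or the linear one.
#' @param species Optional species code carried in the result for labelling.
#' @return An object of class `activity_density`: list with `grid` (hours),
#'   `density` (per hour), `bandwidth`, `wrapped`, `n`, `species`.
#' @examples
#' ad <- activity_density(c(10, 11, 12.5, 13, 14), bandwidth = 1)
#' trapezoid_integral(ad$grid, ad$density)  # ~1
#' @export
activity_density <- function(times_of_day, bandwidth = "auto", n_grid = 512,
                             wrap = TRUE, species = NULL) {
  x <- as.numeric(times_of_day)
  if (length(x) < 2L || anyNA(x)) {
    abort_data("activity_density needs at least 2 non-missing time points")
  }
  x <- x %% 24
  if (identical(bandwidth, "auto")) {
    bandwidth <- stats::bw.nrd0(x)
  }
  h <- check_number(bandwidth, "bandwidth", lower = 1e-9)
  grid <- seq(0, 24, length.out = n_grid + 1)
  if (wrap) {
    dens <- numeric(length(grid))
    shifts <- -max(1, ceiling(4 * h / 24)):max(1, ceiling(4 * h / 24))
    # chunk the sample so the grid-by-sample kernel matrix stays small
    chunks <- split(x, ceiling(seq_along(x) / 2000))
    for (xc in chunks) {
      for (k in shifts) {
        dens <- dens + rowSums(stats::dnorm(outer(grid, xc + 24 * k, "-"),
                                            sd = h))
      }
    }
    dens <- dens / length(x)
  } else {
    d <- stats::density(x, bw = h, from = 0, to = 24, n = n_grid + 1)
    dens <- d$y / trapezoid_integral(d$x, d$y)
  }
  structure(list(grid = grid, density = dens, bandwidth = h,
                 wrapped = wrap, n = length(x), species = species),
            class = "activity_density")
}

#' Trapezoid-rule integral
#'
#' @param x Ordered abscissae.
#' @param y Values at `x`.
#' @return The trapezoid approximation of the integral of `y` over `x`.
#' @export
trapezoid_integral <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.activity_density <- function(x, ...) {
  cat(sprintf(
    "<activity_density>%s n = %d, bandwidth = %.3f h, %s, peak at %.2f h\n",
    if (is.null(x$species)) "" else paste0(" ", x$species),
    x$n, x$bandwidth, if (x$wrapped) "circular" else "linear",
    x$grid[which.max(x$density)]))
  invisible(x)
}

#' @export
plot.activity_density <- function(x, ...,
                                  xlab = "Time of day (h)",
                                  ylab = "Activity density (1/h)",
                                  main = x$species) {
  graphics::plot(x$grid, x$density, type = "l", xlab = xlab, ylab = ylab,
                 main = main %||% "", xaxs = "i", ...)
  invisible(x)
}
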