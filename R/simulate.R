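#' Configuration for a synthetic carcass-fate study
#'
#' Bundles every tunable of the study generator: how many experimental and
#' caged control carcasses are deployed, over which sites, the carcass mass
#' and deployment-duration ranges, the scavenger community
#' ([species_profile()] list), the non-vertebrate (invertebrate/microbial)
#' mass-loss fraction per deployment, and the camera frame cadence.
#'
#' @param n_carcasses Number of experimental carcasses (>= 1).
#' @param n_controls Number of caged control carcasses (vertebrates excluded;
#'   background loss only).
#' @param n_sites Number of sites; ignored if `sites` is supplied.
#' @param avian_only_sites Site ids (e.g. rooftops) inaccessible to mammals.
#' @param initial_mass_range_g Carcass mass range `(min, max)` in grams;
#'   masses are drawn uniformly and rounded to 1 g (field weighing
#'   precision).
#' @param deployment_duration_range_h Deployment duration range in hours.
#' @param species_profiles List of [species_profile()] objects.
#' @param background_loss_fraction_per_deployment Mean fraction of initial
#'   mass lost to non-vertebrate causes over a full deployment, in `[0, 1]`.
#' @param background_loss_sd Between-carcass SD of that fraction (truncated
#'   to `[0, 1]`).
#' @param frame_interval_s Spacing of emitted camera frames while an animal
#'   is present, seconds. The real camera's 0.2 s trigger / 0.5 s reset is
#'   emulated as a regular 1 s stream.
#' @param season `(first, last)` possible deployment dates (`Date`).
#' @param deploy_hour_range_utc Deployment start hour range (UTC); carcasses
#'   are always put out in the daytime.
#' @param sites Optional site table (`site_id`, `town`, `latitude`,
#'   `longitude`); defaults to [default_site_table()].
#' @param seed Optional integer seed recorded in the config and applied by
#'   [simulate_study()].
#' @return An object of class `simulation_config`.
#' @seealso [default_paperlike_config()] for the standard 63-carcass design.
#' @export
simulation_config <- function(n_carcasses,
                              n_controls = 0,
                              n_sites = 9,
                              avian_only_sites = character(0),
                              initial_mass_range_g = c(250, 300),
                              deployment_duration_range_h = c(48, 96),
                              species_profiles = list(),
                              background_loss_fraction_per_deployment = 0.096,
                              background_loss_sd = 0.03,
                              frame_interval_s = 1,
                              season = as.Date(c("2014-05-12", "2014-09-01")),
                              deploy_hour_range_utc = c(9, 15),
                              sites = NULL,
                              seed = NULL) {
  cfg <- list(
    n_carcasses = check_count(n_carcasses, "n_carcasses", lower = 1L),
    n_controls = check_count(n_controls, "n_controls", lower = 0L),
    initial_mass_range_g = check_range(initial_mass_range_g,
                                       "initial_mass_range_g"),
    deployment_duration_range_h = check_range(deployment_duration_range_h,
                                              "deployment_duration_range_h"),
    background_loss_fraction_per_deployment =
      check_fraction(background_loss_fraction_per_deployment,
                     "background_loss_fraction_per_deployment"),
    background_loss_sd = check_number(background_loss_sd,
                                      "background_loss_sd", lower = 0),
    frame_interval_s = check_number(frame_interval_s, "frame_interval_s",
                                    lower = 1e-3),
    deploy_hour_range_utc = check_range(deploy_hour_range_utc,
                                        "deploy_hour_range_utc"),
    season = as.Date(season),
    seed = if (is.null(seed)) NULL else check_count(seed, "seed")
  )
  if (length(cfg$season) != 2L || cfg$season[1] > cfg$season[2]) {
    abort_validation("field 'season' must be an ordered pair of dates")
  }
  if (!length(species_profiles)) {
    abort_validation("field 'species_profiles' must contain at least one profile")
  }
  ok <- vapply(species_profiles, inherits, logical(1), "species_profile")
  if (!all(ok)) {
    abort_validation("field 'species_profiles' must be a list of species_profile objects")
  }
  codes <- vapply(species_profiles, `[[`, character(1), "code")
  if (anyDuplicated(codes)) {
    abort_validation("field 'species_profiles' has duplicated species codes")
  }
  names(species_profiles) <- codes
  cfg$species_profiles <- species_profiles
  cfg$sites <- sites %||% default_site_table(check_count(n_sites, "n_sites",
                                                         lower = 1L))
  needed <- c("site_id", "town", "latitude", "longitude")
  if (!all(needed %in% names(cfg$sites))) {
    abort_validation("field 'sites' must have columns site_id, town, latitude, longitude")
  }
  cfg$n_sites <- nrow(cfg$sites)
  avian_only_sites <- as.character(avian_only_sites)
  if (!all(avian_only_sites %in% cfg$sites$site_id)) {
    abort_validation("field 'avian_only_sites' contains unknown site id(s)")
  }
  cfg$avian_only_sites <- avian_only_sites
  structure(cfg, class = "simulation_config")
}

#' Default site table for the simulated towns
#'
#' Nine (by default) non-woodland urban green-space sites spread over three
#' adjacent UK towns — five in Milton Keynes (52.04 N, 0.75 W), three in
#' Bedford (52.14 N, 0.47 W) and one in Luton (51.88 N, 0.42 W) — with small
#' deterministic coordinate offsets separating sites within a town.
#'
#' @param n_sites Number of sites to generate (towns are filled in the
#'   5:3:1 proportion).
#' @return Data frame `site_id`, `town`, `latitude`, `longitude`.
#' @export
default_site_table <- function(n_sites = 9) {
  towns <- data.frame(
    town = c("MiltonKeynes", "Bedford", "Luton"),
    latitude = c(52.04, 52.135, 51.88),
    longitude = c(-0.75, -0.47, -0.42)
  )
  counts <- diff(round(n_sites * c(0, 5, 8, 9) / 9))
  idx <- rep(seq_len(3), counts)
  data.frame(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    town = towns$town[idx],
    latitude = towns$latitude[idx] + 0.004 * (seq_len(n_sites) - 1),
    longitude = towns$longitude[idx] + 0.004 * (seq_len(n_sites) - 1)
  )
}

#' Standard configuration of the urban scavenging experiment
#'
#' The design emulated by default: 63 experimental rat carcasses of
#' 250–300 g and 10 caged controls, deployed in the daytime for 2–4 days
#' across nine sites in three towns (three sites accessible to birds only),
#' with about 9.6% of initial mass lost per deployment to non-vertebrate
#' causes. The scavenger community is carrion crow, Eurasian magpie and red
#' fox with gamma first-arrival latencies of mean 683 (SD 460), 504 (SD 436)
#' and 755 (SD 278) minutes respectively; the corvids are almost entirely
#' diurnal (day-activity probabilities 0.98 and 0.996) while the fox is
#' largely nocturnal (0.092). The fox never eats in situ (rate 0) but
#' removes whole carcasses with high per-visit probability; the corvids eat
#' in place and rarely remove. Remaining parameters (attendance
#' probabilities, revisit rates, bout lengths) are realistic defaults chosen
#' for the simulator, not field measurements; see the package vignette.
#'
#' @param seed Optional integer seed stored in the config.
#' @return A [simulation_config()] object.
#' @examples
#' cfg <- default_paperlike_config(seed = 1)
#' cfg$n_carcasses
#' @export
default_paperlike_config <- function(seed = NULL) {
  profiles <- list(
    species_profile("CROW", body_mass_g = 570,
                    mean_arrival_latency_min = 683,
                    sd_arrival_latency_min = 460,
                    day_activity_prob = 0.98,
                    eat_rate_g_per_kg_min = 2,
                    bout_duration_mean_min = 10,
                    removal_prob_per_visit = 0.01,
                    guild = "avian", attendance_prob = 0.45,
                    revisit_rate_per_h = 0.12,
                    examine_duration_mean_min = 1.5),
    species_profile("MAGPIE", body_mass_g = 230,
                    mean_arrival_latency_min = 504,
                    sd_arrival_latency_min = 436,
                    day_activity_prob = 0.996,
                    eat_rate_g_per_kg_min = 2,
                    bout_duration_mean_min = 8,
                    removal_prob_per_visit = 0.008,
                    guild = "avian", attendance_prob = 0.35,
                    revisit_rate_per_h = 0.2,
                    examine_duration_mean_min = 1),
    species_profile("FOX", body_mass_g = 6500,
                    mean_arrival_latency_min = 755,
                    sd_arrival_latency_min = 278,
                    day_activity_prob = 0.092,
                    eat_rate_g_per_kg_min = 0,
                    bout_duration_mean_min = 0,
                    removal_prob_per_visit = 0.15,
                    guild = "mammal", attendance_prob = 0.6,
                    revisit_rate_per_h = 0.05,
                    examine_duration_mean_min = 2)
  )
  simulation_config(
    n_carcasses = 63, n_controls = 10, n_sites = 9,
    avian_only_sites = c("S05", "S08", "S09"),
    initial_mass_range_g = c(250, 300),
    deployment_duration_range_h = c(48, 96),
    species_profiles = profiles,
    background_loss_fraction_per_deployment = 0.096,
    background_loss_sd = 0.03,
    frame_interval_s = 1,
    seed = seed
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d carcasses + %d controls over %d sites (%d avian-only)\n",
    x$n_carcasses, x$n_controls, x$n_sites, length(x$avian_only_sites)))
  cat(sprintf("  mass %g-%g g, duration %g-%g h, background loss %.3f +/- %.3f\n",
              x$initial_mass_range_g[1], x$initial_mass_range_g[2],
              x$deployment_duration_range_h[1], x$deployment_duration_range_h[2],
              x$background_loss_fraction_per_deployment, x$background_loss_sd))
  cat("  species:", paste(names(x$species_profiles), collapse = ", "), "\n")
  invisible(x)
}

# Chronological day/night windows covering [from, to] at a site. Windows are
# half-open [start, end) in the package's diel convention; here they are
# returned clipped to the deployment.
diel_windows <- function(latitude, longitude, from, to) {
  dates <- seq(as.Date(from, tz = "UTC") - 1, as.Date(to, tz = "UTC") + 1,
               by = "day")
  st <- sun_times(latitude, longitude, dates)
  k <- nrow(st)
  w <- data.frame(
    class = c(rep("DAY", k), rep("NIGHT", k - 1)),
    start = c(as.numeric(st$sunrise), as.numeric(st$sunset[-k])),
    end = c(as.numeric(st$sunset), as.numeric(st$sunrise[-1]))
  )
  w <- w[order(w$start), , drop = FALSE]
  w$start <- pmax(w$start, as.numeric(from))
  w$end <- pmin(w$end, as.numeric(to))
  w <- w[w$end - w$start > 0, , drop = FALSE]
  rownames(w) <- NULL
  w
}

# Round a duration in seconds onto the frame grid (at least one interval).
discretize_s <- function(x, interval) {
  pmax(interval, round(x / interval) * interval)
}

#' Generate a complete synthetic carcass-fate study
#'
#' Simulates deployments, the camera-trap detection stream, and a hidden
#' ground-truth consumption ledger. For each experimental carcass, each
#' species in the community may discover it (attendance probability), arrives
#' after a gamma-distributed latency, and returns as a homogeneous Poisson
#' process; every visit is placed in a daylight or night window according to
#' the species' `day_activity_prob`. Visits consist of optional looking, an
#' examining prelude, an eating bout that depletes carcass mass at
#' `eat_rate_g_per_kg_min` times body mass, and possibly a whole-carcass
#' removal, which sets remaining mass to zero and ends that carcass's
#' detection stream. Non-vertebrate background loss accrues linearly over the
#' deployment; caged controls receive only background loss and produce no
#' frames.
#'
#' The ledger satisfies, for every carcass, the accounting identity
#' `in-situ + removed + non-vertebrate + remaining = initial mass` exactly.
#'
#' @param config A [simulation_config()].
#' @return An object of class `carrion_study`: a list with
#'   \describe{
#'     \item{deployments}{one row per carcass (experimental and control) in
#'       the standard deployment schema;}
#'     \item{detections}{the frame stream (`carcass_id`, `timestamp`,
#'       `species`, `behavior`) sorted by carcass and time;}
#'     \item{truth}{the ground-truth ledger: `consumption` (per carcass and
#'       species, grams eaten in situ and removed), `carcass` (background
#'       loss, remaining mass, realised background fraction) and `arrivals`
#'       (realised and drawn first-arrival latencies, visit counts);}
#'     \item{config}{the configuration used (seed included).}
#'   }
#' @examples
#' cfg <- default_paperlike_config(seed = 42)
#' cfg$n_carcasses <- 4; cfg$n_controls <- 2
#' study <- simulate_study(cfg)
#' head(study$deployments)
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort_validation("config must be a simulation_config object")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  sites <- config$sites
  profs <- config$species_profiles
  interval <- config$frame_interval_s

  n_exp <- config$n_carcasses
  n_all <- n_exp + config$n_controls
  is_control <- c(rep(FALSE, n_exp), rep(TRUE, config$n_controls))
  ids <- c(sprintf("C%03d", seq_len(n_exp)),
           if (config$n_controls) sprintf("K%02d", seq_len(config$n_controls)))

  site_idx <- sample.int(nrow(sites), n_all, replace = TRUE)
  days <- seq(config$season[1], config$season[2], by = "day")
  start_day <- days[sample.int(length(days), n_all, replace = TRUE)]
  start_hour <- stats::runif(n_all, config$deploy_hour_range_utc[1],
                             config$deploy_hour_range_utc[2])
  start <- as.POSIXct(paste0(format(start_day), " 00:00:00"), tz = "UTC") +
    round(start_hour * 3600)
  duration_h <- stats::runif(n_all, config$deployment_duration_range_h[1],
                             config$deployment_duration_range_h[2])
  end <- start + round(duration_h * 3600)
  initial <- round(stats::runif(n_all, config$initial_mass_range_g[1],
                                config$initial_mass_range_g[2]))
  bg_frac <- pmin(1, pmax(0, stats::rnorm(
    n_all, config$background_loss_fraction_per_deployment,
    config$background_loss_sd)))

  access <- ifelse(sites$site_id[site_idx] %in% config$avian_only_sites,
                   "AVIAN_ONLY", "ALL")

  frames_acc <- vector("list", n_all)
  cons_acc <- vector("list", n_all)
  arr_acc <- vector("list", n_all)
  final_mass <- numeric(n_all)
  removed <- logical(n_all)
  nonvert_g <- numeric(n_all)
  remaining_g <- numeric(n_all)

  for (i in seq_len(n_all)) {
    init <- initial[i]
    if (is_control[i]) {
      nonvert_g[i] <- bg_frac[i] * init
      remaining_g[i] <- init - nonvert_g[i]
      final_mass[i] <- remaining_g[i]
      next
    }
    lat <- sites$latitude[site_idx[i]]
    lon <- sites$longitude[site_idx[i]]
    win <- diel_windows(lat, lon, start[i], end[i])
    visits <- list()
    arrivals <- list()
    for (p in profs) {
      if (access[i] == "AVIAN_ONLY" && p$guild == "mammal") next
      if (stats::runif(1) > p$attendance_prob) next
      sh <- (p$mean_arrival_latency_min / p$sd_arrival_latency_min)^2
      ra <- p$mean_arrival_latency_min / p$sd_arrival_latency_min^2
      drawn <- stats::rgamma(1, shape = sh, rate = ra)
      t_arr <- as.numeric(start[i]) + drawn * 60
      want_day <- stats::runif(1) < p$day_activity_prob
      cls <- if (want_day) "DAY" else "NIGHT"
      t_arr <- place_in_class(t_arr, cls, win)
      if (is.na(t_arr) || t_arr >= as.numeric(end[i])) next
      remain_h <- (as.numeric(end[i]) - t_arr) / 3600
      n_rev <- stats::rpois(1, p$revisit_rate_per_h * remain_h)
      times <- t_arr
      if (n_rev > 0) {
        rev_day <- stats::runif(n_rev) < p$day_activity_prob
        for (j in seq_len(n_rev)) {
          tj <- sample_window_time(if (rev_day[j]) "DAY" else "NIGHT",
                                   win, t_arr, as.numeric(end[i]))
          if (!is.na(tj)) times <- c(times, tj)
        }
      }
      times <- sort(times)
      # enforce non-overlapping same-species visits
      keep <- rep(TRUE, length(times))
      last_end <- -Inf
      spans <- numeric(length(times))
      nv <- length(times)
      looking <- stats::runif(nv) < p$looking_prob
      look_s <- discretize_s(stats::rexp(nv, rate = 1 / 30), interval)
      exam_s <- discretize_s(stats::rexp(
        nv, rate = 1 / max(1, p$examine_duration_mean_min * 60)), interval)
      eat_s <- if (p$bout_duration_mean_min > 0) {
        discretize_s(stats::rexp(nv, rate = 1 / (p$bout_duration_mean_min * 60)),
                     interval)
      } else rep(0, nv)
      rem_flag <- stats::runif(nv) < p$removal_prob_per_visit
      for (j in seq_len(nv)) {
        span <- looking[j] * look_s[j] + exam_s[j] + eat_s[j] +
          rem_flag[j] * 60 + 5 * interval
        if (times[j] < last_end + 90) { keep[j] <- FALSE; next }
        last_end <- times[j] + span
        spans[j] <- span
      }
      visits[[length(visits) + 1L]] <- data.frame(
        species = p$code, time = times[keep],
        looking = looking[keep], look_s = look_s[keep],
        exam_s = exam_s[keep], eat_s = eat_s[keep],
        removal = rem_flag[keep])
      arrivals[[length(arrivals) + 1L]] <- data.frame(
        carcass_id = ids[i], species = p$code,
        latency_min = (times[1] - as.numeric(start[i])) / 60,
        drawn_latency_min = drawn, n_visits = sum(keep))
    }
    res <- process_carcass(ids[i], init, bg_frac[i], as.numeric(start[i]),
                           as.numeric(end[i]), win, visits, profs, interval)
    frames_acc[[i]] <- res$frames
    cons_acc[[i]] <- res$consumption
    arr_acc[[i]] <- if (length(arrivals)) do.call(rbind, arrivals) else NULL
    removed[i] <- res$removed
    nonvert_g[i] <- res$nonvert_g
    remaining_g[i] <- res$remaining_g
    final_mass[i] <- if (res$removed) 0 else res$remaining_g
  }

  deployments <- data.frame(
    carcass_id = ids,
    site_id = sites$site_id[site_idx],
    town = sites$town[site_idx],
    latitude = sites$latitude[site_idx],
    longitude = sites$longitude[site_idx],
    start = start,
    end = end,
    initial_mass_g = initial,
    final_mass_g = final_mass,
    removed = removed,
    access_class = access,
    is_control = is_control
  )
  detections <- do.call(rbind, Filter(Negate(is.null), frames_acc))
  if (is.null(detections) || nrow(detections) == 0L) {
    detections <- data.frame(carcass_id = character(0),
                             timestamp = as.POSIXct(character(0), tz = "UTC"),
                             species = character(0), behavior = character(0))
  } else {
    detections <- detections[order(detections$carcass_id,
                                   detections$timestamp), , drop = FALSE]
    rownames(detections) <- NULL
  }
  consumption <- do.call(rbind, Filter(Negate(is.null), cons_acc))
  if (is.null(consumption)) {
    consumption <- data.frame(carcass_id = character(0), species = character(0),
                              in_situ_g = numeric(0), removed_g = numeric(0))
  }
  arrivals <- do.call(rbind, Filter(Negate(is.null), arr_acc))
  if (is.null(arrivals)) {
    arrivals <- data.frame(carcass_id = character(0), species = character(0),
                           latency_min = numeric(0),
                           drawn_latency_min = numeric(0),
                           n_visits = integer(0))
  }
  truth <- list(
    consumption = consumption,
    carcass = data.frame(carcass_id = ids, initial_g = initial,
                         nonvertebrate_g = nonvert_g,
                         remaining_g = remaining_g, removed = removed,
                         background_fraction = bg_frac,
                         is_control = is_control),
    arrivals = arrivals
  )
  rownames(truth$carcass) <- NULL
  structure(list(deployments = deployments, detections = detections,
                 truth = truth, config = config),
            class = "carrion_study")
}

# Move a candidate time into the requested diel class: keep it if its window
# already matches, otherwise advance to the start of the next matching
# window. Returns NA when no matching window remains.
place_in_class <- function(t, class, win) {
  k <- findInterval(t, win$start)
  if (k >= 1 && t < win$end[k] && win$class[k] == class) {
    t2 <- min(ceiling(t), floor(win$end[k]) - 1)
    return(if (t2 >= win$start[k]) t2 else NA_real_)
  }
  nxt <- which(win$class == class & win$start > t)
  if (!length(nxt)) return(NA_real_)
  ceiling(win$start[nxt[1]])
}

# Uniform time inside the union of windows of a diel class intersected with
# (lo, hi), chosen proportionally to window length.
sample_window_time <- function(class, win, lo, hi) {
  w <- win[win$class == class, , drop = FALSE]
  w$start <- pmax(w$start, lo)
  w$end <- pmin(w$end, hi)
  w <- w[w$end > w$start, , drop = FALSE]
  if (!nrow(w)) return(NA_real_)
  len <- w$end - w$start
  k <- sample.int(nrow(w), 1, prob = len)
  t <- min(ceiling(stats::runif(1, w$start[k], w$end[k])),
           floor(w$end[k]) - 1)
  if (t >= w$start[k]) t else NA_real_
}

# Chronological bookkeeping for one carcass: emit frames, deplete mass, and
# settle the ground-truth ledger. All random draws were made upstream, so the
# arithmetic here is deterministic given the visit list.
process_carcass <- function(id, init, bg_frac, t_start, t_end, win, visits,
                            profs, interval) {
  total_s <- t_end - t_start
  bg_rate <- bg_frac * init / total_s   # g per second
  m <- init
  bg <- 0
  consumed <- stats::setNames(numeric(length(profs)), names(profs))
  removed_by <- stats::setNames(numeric(length(profs)), names(profs))
  t_last <- t_start
  removal_done <- FALSE
  frames <- list()

  vis <- if (length(visits)) do.call(rbind, visits) else NULL
  if (!is.null(vis)) vis <- vis[order(vis$time), , drop = FALSE]

  emit <- function(species, behavior, t0, dur_s) {
    n <- floor(dur_s / interval) + 1L
    list(species = species, behavior = behavior,
         time = t0 + (seq_len(n) - 1L) * interval)
  }

  if (!is.null(vis)) for (j in seq_len(nrow(vis))) {
    if (removal_done) break
    v <- vis[j, ]
    p <- profs[[v$species]]
    # window containing the visit; segments stay strictly inside it so a
    # day-placed visit never spills past sunset (and vice versa)
    k <- findInterval(v$time, win$start)
    w_end <- if (k >= 1 && v$time < win$end[k]) win$end[k] else t_end
    limit <- min(w_end - interval, t_end - interval)
    cursor <- v$time
    segs <- list()
    add_seg <- function(behavior, dur_s) {
      avail <- limit - cursor
      dur_s <- min(dur_s, floor(avail / interval) * interval)
      if (dur_s < interval) return(FALSE)
      segs[[length(segs) + 1L]] <<- list(behavior = behavior, t0 = cursor,
                                         dur = dur_s)
      cursor <<- cursor + dur_s + interval
      TRUE
    }
    if (v$looking) add_seg("LOOKING", v$look_s)
    add_seg("EXAMINING", v$exam_s)
    eat_done <- if (v$eat_s > 0) add_seg("EATING", v$eat_s) else FALSE
    if (eat_done) {
      eseg <- segs[[length(segs)]]
      dt <- max(0, eseg$t0 - t_last)
      db <- min(bg_rate * dt, m)
      bg <- bg + db; m <- m - db
      c_g <- min(p$eat_rate_g_per_kg_min * (p$body_mass_g / 1000) *
                   (eseg$dur / 60), m)
      consumed[v$species] <- consumed[v$species] + c_g
      m <- m - c_g
      t_last <- eseg$t0 + eseg$dur
    }
    if (v$removal) {
      rem_t0 <- cursor
      dt <- max(0, rem_t0 - t_last)
      db <- min(bg_rate * dt, m)
      if (m - db > 1e-12 && add_seg("REMOVING", 60)) {
        bg <- bg + db; m <- m - db
        t_last <- rem_t0
        removed_by[v$species] <- removed_by[v$species] + m
        m <- 0
        removal_done <- TRUE
      }
    }
    for (s in segs) {
      frames[[length(frames) + 1L]] <- emit(v$species, s$behavior, s$t0, s$dur)
    }
  }

  if (!removal_done) {
    db <- min(bg_rate * max(0, t_end - t_last), m)
    bg <- bg + db; m <- m - db
  }

  fr <- NULL
  if (length(frames)) {
    fr <- data.frame(
      carcass_id = id,
      timestamp = as.POSIXct(unlist(lapply(frames, `[[`, "time")),
                             origin = "1970-01-01", tz = "UTC"),
      species = rep(vapply(frames, `[[`, character(1), "species"),
                    vapply(frames, function(f) length(f$time), integer(1))),
      behavior = rep(vapply(frames, `[[`, character(1), "behavior"),
                     vapply(frames, function(f) length(f$time), integer(1)))
    )
  }
  cons <- NULL
  active <- consumed > 0 | removed_by > 0
  if (any(active)) {
    cons <- data.frame(carcass_id = id, species = names(consumed)[active],
                       in_situ_g = unname(consumed[active]),
                       removed_g = unname(removed_by[active]))
  }
  list(frames = fr, consumption = cons, removed = removal_done,
       nonvert_g = bg, remaining_g = m)
}

#' @export
print.carrion_study <- function(x, ...) {
  d <- x$deployments
  cat(sprintf(
    "<carrion_study> %d experimental + %d control carcasses, %d detection frames\n",
    sum(!d$is_control), sum(d$is_control), nrow(x$detections)))
  cat(sprintf("  %d carcasses removed whole; %.0f g deployed (experimental)\n",
              sum(d$removed), sum(d$initial_mass_g[!d$is_control])))
  invisible(x)
}

#' Simulate a study from a configuration object
#'
#' Method for the [stats::simulate()] generic: draws `nsim` studies from a
#' [simulation_config()], optionally re-seeded.
#'
#' @param object A `simulation_config`.
#' @param nsim Number of studies.
#' @param seed Optional seed overriding the config's.
#' @param ... Ignored.
#' @return A single `carrion_study` when `nsim = 1`, else a list of them.
#' @export
simulate.simulation_config <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) object$seed <- seed
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    if (k > 1 && !is.null(object$seed)) object$seed <- object$seed + 1L
    out[[k]] <- simulate_study(object)
  }
  if (nsim == 1) out[[1]] else out
}
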