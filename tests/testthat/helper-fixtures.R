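# Programmatic fixtures shared across test files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

make_deployments <- function(n, initial = 275, final = initial * 0.9,
                             removed = FALSE, access = "ALL",
                             is_control = FALSE, prefix = "C",
                             start = utc("2014-06-10 12:00:00"),
                             duration_h = 72) {
  data.frame(
    carcass_id = sprintf("%s%03d", prefix, seq_len(n)),
    site_id = "S01", town = "MiltonKeynes",
    latitude = 52.04, longitude = -0.75,
    start = rep(start, n), end = rep(start, n) + duration_h * 3600,
    initial_mass_g = rep_len(initial, n),
    final_mass_g = rep_len(final, n),
    removed = rep_len(removed, n),
    access_class = rep_len(access, n),
    is_control = rep_len(is_control, n)
  )
}

make_obs <- function(carcass_id, species, behavior,
                     start = utc("2014-06-10 14:00:00"), duration_min = 10) {
  n <- max(length(carcass_id), length(species), length(behavior),
           length(start), length(duration_min))
  start <- rep_len(start, n)
  duration_min <- rep_len(duration_min, n)
  data.frame(
    carcass_id = rep_len(carcass_id, n),
    species = rep_len(species, n),
    behavior = rep_len(behavior, n),
    start = start,
    end = start + duration_min * 60,
    duration_min = duration_min
  )
}

# A small fast paper-like configuration for tests that only need structure,
# not the full 63-carcass study.
small_config <- function(seed, n_carcasses = 8, n_controls = 2) {
  cfg <- default_paperlike_config(seed = seed)
  cfg$n_carcasses <- n_carcasses
  cfg$n_controls <- n_controls
  cfg
}

# One species with many short visits, sparse enough that visits rarely
# overlap (each visit then yields exactly one observation, as the binomial
# day/night check assumes); used by the diel tests.
diel_probe_config <- function(seed, p_day, n_carcasses = 12) {
  prof <- species_profile("FOX", body_mass_g = 6500,
                          mean_arrival_latency_min = 300,
                          sd_arrival_latency_min = 200,
                          day_activity_prob = p_day,
                          eat_rate_g_per_kg_min = 0,
                          bout_duration_mean_min = 0,
                          removal_prob_per_visit = 0,
                          guild = "mammal", attendance_prob = 1,
                          revisit_rate_per_h = 0.6,
                          examine_duration_mean_min = 0.5,
                          looking_prob = 0)
  simulation_config(n_carcasses = n_carcasses, n_controls = 0, n_sites = 3,
                    deployment_duration_range_h = c(90, 96),
                    species_profiles = list(prof), seed = seed)
}
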