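test_that("configuration validation names the offending field", {
  expect_error(simulation_config(n_carcasses = 0,
                                 species_profiles = list(species_profile(
                                   "X", 100, 10, 5, 1, 1, 1, 0))),
               "n_carcasses", class = "carrionfate_validation_error")
  expect_error(default_paperlike_config()$species_profiles$CROW$code, NA)
  expect_error(
    simulation_config(n_carcasses = 5, initial_mass_range_g = c(300, 250),
                      species_profiles = list(species_profile(
                        "X", 100, 10, 5, 1, 1, 1, 0))),
    "initial_mass_range_g", class = "carrionfate_validation_error")
  expect_error(species_profile("X", 100, 10, 5, day_activity_prob = 1.4,
                               eat_rate_g_per_kg_min = 1,
                               bout_duration_mean_min = 1,
                               removal_prob_per_visit = 0),
               "day_activity_prob", class = "carrionfate_validation_error")
  expect_error(
    simulation_config(n_carcasses = 5, avian_only_sites = "NOPE",
                      species_profiles = list(species_profile(
                        "X", 100, 10, 5, 1, 1, 1, 0))),
    "avian_only_sites", class = "carrionfate_validation_error")
})

test_that("the default study design matches the emulated experiment", {
  cfg <- default_paperlike_config()
  expect_equal(cfg$n_carcasses, 63)
  expect_equal(cfg$n_controls, 10)
  expect_equal(cfg$initial_mass_range_g, c(250, 300))
  expect_equal(cfg$deployment_duration_range_h, c(48, 96))
  expect_equal(cfg$background_loss_fraction_per_deployment, 0.096)
  expect_equal(length(cfg$avian_only_sites), 3L)
  p <- cfg$species_profiles
  expect_setequal(names(p), c("CROW", "MAGPIE", "FOX"))
  expect_equal(p$FOX$mean_arrival_latency_min, 755)
  expect_equal(p$FOX$sd_arrival_latency_min, 278)
  expect_equal(p$CROW$mean_arrival_latency_min, 683)
  expect_equal(p$MAGPIE$mean_arrival_latency_min, 504)
  expect_equal(p$FOX$eat_rate_g_per_kg_min, 0)
  expect_gt(p$CROW$day_activity_prob, 0.9)
  expect_lt(p$FOX$day_activity_prob, 0.1)
})

test_that("with effectively infinite latency no scavenger ever arrives", {
  cfg <- small_config(2, n_carcasses = 6, n_controls = 2)
  cfg$species_profiles <- lapply(cfg$species_profiles, function(p) {
    p$mean_arrival_latency_min <- 1e9
    p$sd_arrival_latency_min <- 1e6
    p
  })
  class(cfg) <- "simulation_config"
  study <- simulate_study(cfg)
  expect_equal(nrow(study$detections), 0L)
  d <- study$deployments
  tr <- study$truth$carcass
  expect_equal(d$initial_mass_g - d$final_mass_g,
               tr$nonvertebrate_g, tolerance = 1e-9)
  expect_false(any(d$removed))
})

test_that("the ledger accounting identity holds on every seeded run", {
  for (seed in c(1, 7, 101)) {
    study <- simulate_study(small_config(seed))
    tot <- ledger_totals(study$truth)
    expect_lt(max(abs(tot - study$truth$carcass$initial_g)), 1e-6)
    expect_true(all(study$truth$consumption$in_situ_g >= 0))
    expect_true(all(study$truth$consumption$removed_g >= 0))
    expect_true(all(study$truth$carcass$remaining_g >= -1e-9))
  }
})

test_that("identical seeds reproduce identical tables", {
  a <- simulate_study(small_config(13))
  b <- simulate_study(small_config(13))
  expect_identical(a$deployments, b$deployments)
  expect_identical(a$detections, b$detections)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_study(small_config(14))
  expect_false(identical(a$detections, c2$detections))
})

test_that("frame timestamps stay within their deployment window", {
  study <- simulate_study(small_config(19))
  idx <- match(study$detections$carcass_id, study$deployments$carcass_id)
  expect_true(all(study$detections$timestamp >= study$deployments$start[idx]))
  expect_true(all(study$detections$timestamp <= study$deployments$end[idx]))
})

test_that("degenerate diel preferences confine all frames to one diel class", {
  nocturnal <- simulate_study(diel_probe_config(5, p_day = 0, n_carcasses = 4))
  obs <- extract_observations(nocturnal$detections)
  frames_cls <- classify_observations(
    data.frame(carcass_id = nocturnal$detections$carcass_id,
               species = nocturnal$detections$species,
               behavior = nocturnal$detections$behavior,
               start = nocturnal$detections$timestamp,
               end = nocturnal$detections$timestamp,
               duration_min = 0),
    nocturnal$deployments)
  expect_gt(nrow(frames_cls), 0)
  expect_true(all(frames_cls$diel == "NIGHT"))

  diurnal <- simulate_study(diel_probe_config(6, p_day = 1, n_carcasses = 4))
  fr <- diurnal$detections
  cls <- classify_observations(
    data.frame(carcass_id = fr$carcass_id, species = fr$species,
               behavior = fr$behavior, start = fr$timestamp,
               end = fr$timestamp, duration_min = 0),
    diurnal$deployments)
  expect_gt(nrow(cls), 0)
  expect_true(all(cls$diel == "DAY"))
})

test_that("raising the eat rate never lowers total consumption (same seed)", {
  base <- small_config(29, n_carcasses = 10)
  rates <- c(0.5, 1, 2, 4)
  totals <- vapply(rates, function(r) {
    cfg <- base
    cfg$species_profiles <- lapply(cfg$species_profiles, function(p) {
      if (p$eat_rate_g_per_kg_min > 0) p$eat_rate_g_per_kg_min <- r
      p
    })
    class(cfg) <- "simulation_config"
    st <- simulate_study(cfg)
    sum(st$truth$consumption$in_situ_g + st$truth$consumption$removed_g)
  }, numeric(1))
  expect_true(all(diff(totals) >= -1e-9))
})

test_that("controls receive background loss only and emit no frames", {
  study <- simulate_study(small_config(37, n_carcasses = 5, n_controls = 4))
  ctl <- study$deployments[study$deployments$is_control, ]
  expect_equal(nrow(ctl), 4L)
  expect_false(any(study$detections$carcass_id %in% ctl$carcass_id))
  tr <- study$truth$carcass[study$truth$carcass$is_control, ]
  expect_equal(ctl$initial_mass_g - ctl$final_mass_g, tr$nonvertebrate_g,
               tolerance = 1e-9)
})

test_that("mammals never appear at avian-only sites", {
  cfg <- default_paperlike_config(seed = 55)
  cfg$n_carcasses <- 25
  study <- simulate_study(cfg)
  avian_only <- study$deployments$carcass_id[
    study$deployments$access_class == "AVIAN_ONLY"]
  expect_gt(length(avian_only), 0)
  fox_frames <- study$detections[study$detections$species == "FOX", ]
  expect_false(any(fox_frames$carcass_id %in% avian_only))
})
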