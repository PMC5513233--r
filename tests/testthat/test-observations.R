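test_that("empty frame list yields an empty observation table", {
  f <- data.frame(carcass_id = character(0),
                  timestamp = as.POSIXct(character(0), tz = "UTC"),
                  species = character(0), behavior = character(0))
  out <- extract_observations(f)
  expect_equal(nrow(out), 0L)
  expect_named(out, c("carcass_id", "species", "behavior", "start", "end",
                      "duration_min"))
})

test_that("a behaviour change splits one presence run into two observations", {
  t0 <- utc("2014-06-10 10:00:00")
  f <- data.frame(carcass_id = "C1", timestamp = t0 + 0:7,
                  species = "CROW",
                  behavior = rep(c("EATING", "EXAMINING"), c(5, 3)))
  out <- extract_observations(f)
  expect_equal(out$behavior, c("EATING", "EXAMINING"))
  expect_equal(out$duration_min * 60, c(4, 2))
  expect_equal(out$start, c(t0, t0 + 5))
})

test_that("gaps above the threshold split runs; at/below do not", {
  t0 <- utc("2014-06-10 10:00:00")
  f <- data.frame(carcass_id = "C1",
                  timestamp = t0 + c(0:4, 604:608),
                  species = "CROW", behavior = "EXAMINING")
  out <- extract_observations(f, gap_threshold_s = 60)
  expect_equal(nrow(out), 2L)
  expect_equal(out$duration_min * 60, c(4, 4))
  merged <- extract_observations(f, gap_threshold_s = 600)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$duration_min * 60, 608)
})

test_that("invalid frame input raises classed errors", {
  t0 <- utc("2014-06-10 10:00:00")
  unsorted <- data.frame(carcass_id = "C1", timestamp = t0 + c(3, 1, 2),
                         species = "CROW", behavior = "EATING")
  expect_error(extract_observations(unsorted),
               class = "carrionfate_ordering_error")
  badcode <- data.frame(carcass_id = "C1", timestamp = t0 + 0:1,
                        species = "CROW", behavior = c("EATING", "GRAZING"))
  expect_error(extract_observations(badcode),
               class = "carrionfate_validation_error")
  mismatch <- data.frame(carcass_id = "C1", timestamp = t0,
                         species = "NONE", behavior = "EATING")
  expect_error(extract_observations(mismatch),
               class = "carrionfate_validation_error")
})

test_that("extraction matches the naive quadratic grouping oracle exactly", {
  set.seed(11)
  t0 <- utc("2014-06-10 06:00:00")
  # irregular stream over two carcasses and three species, with NONE frames,
  # behaviour switches, and gaps straddling the threshold
  n <- 1000
  f <- data.frame(
    carcass_id = sample(c("C1", "C2"), n, TRUE),
    timestamp = t0 + sort(cumsum(sample(c(1, 1, 2, 30, 61, 400), n, TRUE))),
    species = sample(c("CROW", "MAGPIE", "FOX", "NONE"), n, TRUE,
                     prob = c(.4, .3, .2, .1)),
    behavior = NA_character_)
  f$behavior <- ifelse(f$species == "NONE", "NONE",
                       sample(c("LOOKING", "EXAMINING", "EATING", "REMOVING"),
                              n, TRUE))
  f <- f[order(f$carcass_id, f$timestamp), ]
  got <- extract_observations(f, gap_threshold_s = 60)
  want <- naive_extract(f, gap_threshold_s = 60)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("re-encoding observations as frames and re-extracting is idempotent", {
  set.seed(3)
  study <- simulate_study(small_config(3))
  obs <- extract_observations(study$detections)
  back <- extract_observations(observations_to_frames(obs, interval_s = 1))
  expect_equal(nrow(back), nrow(obs))
  expect_true(all(abs(back$duration_min - obs$duration_min) <= 1 / 60))
})

test_that("eating time sums durations and zero-fills known species", {
  obs <- rbind(
    make_obs("C001", "CROW", "EATING", duration_min = 10),
    make_obs("C001", "CROW", "EATING", duration_min = 5),
    make_obs("C001", "MAGPIE", "EXAMINING", duration_min = 7))
  tab <- eating_time_by_species(obs, species = c("CROW", "MAGPIE", "FOX"))
  expect_equal(tab$eating_min[tab$species == "CROW"], 15)
  expect_equal(tab$eating_min[tab$species == "MAGPIE"], 0)
  expect_equal(tab$eating_min[tab$species == "FOX"], 0)
  none <- eating_time_by_species(make_obs("C001", "CROW", "LOOKING"))
  expect_true(all(none$eating_min == 0))
})

test_that("eating totals equal an independent re-summation on simulated data", {
  study <- simulate_study(small_config(17))
  obs <- extract_observations(study$detections)
  tab <- eating_time_by_species(obs)
  for (k in sample(nrow(tab), min(20, nrow(tab)))) {
    manual <- sum(obs$duration_min[obs$carcass_id == tab$carcass_id[k] &
                                     obs$species == tab$species[k] &
                                     obs$behavior == "EATING"])
    expect_equal(tab$eating_min[k], manual)
  }
})

test_that("duration per (carcass, species) is conserved across behaviour splits", {
  study <- simulate_study(small_config(23))
  obs <- extract_observations(study$detections)
  # merging contiguous observations back into runs must reproduce total span
  key <- paste(obs$carcass_id, obs$species)
  for (k in unique(key)[1:min(10, length(unique(key)))]) {
    o <- obs[key == k, ]
    o <- o[order(o$start), ]
    gap <- as.numeric(o$start[-1]) - as.numeric(o$end[-nrow(o)])
    run_id <- cumsum(c(TRUE, gap > 60))
    span <- tapply(as.numeric(o$end), run_id, max) -
      tapply(as.numeric(o$start), run_id, min)
    dur <- tapply(o$duration_min * 60, run_id, sum)
    n_obs <- tapply(run_id, run_id, length)
    # observations within a run abut within the gap threshold
    expect_true(all(span - dur >= -1e-9 & span - dur <= (n_obs - 1) * 60 + 1e-9))
  }
})

test_that("first-arrival latency reproduces simple clock arithmetic", {
  dep <- make_deployments(1, start = utc("2014-06-10 12:00:00"))
  obs <- make_obs("C001", "MAGPIE", "EXAMINING",
                  start = utc("2014-06-10 20:24:00"))
  lat <- first_arrival_latency(dep, obs)
  expect_equal(lat$latency_min, 504)
  # never-observed pairs yield no row
  expect_false("CROW" %in% lat$species)
  orphan <- make_obs("C999", "CROW", "EATING")
  expect_error(first_arrival_latency(dep, orphan),
               class = "carrionfate_integrity_error")
})

test_that("latencies recovered from the stream equal the simulator's ledger", {
  study <- simulate_study(small_config(31, n_carcasses = 12))
  obs <- extract_observations(study$detections)
  lat <- first_arrival_latency(study$deployments, obs)
  tr <- study$truth$arrivals
  m <- merge(lat, tr, by = c("carcass_id", "species"))
  expect_equal(nrow(m), nrow(tr))
  expect_true(all(abs(m$latency_min.x - m$latency_min.y) < 1 / 60 + 1e-9))
})
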