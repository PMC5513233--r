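test_that("pooled non-vertebrate fraction is total loss over total mass", {
  zero <- make_deployments(3, initial = 250, final = 250, is_control = TRUE)
  expect_equal(nonvertebrate_loss_fraction(zero), 0)
  two <- make_deployments(2, initial = c(250, 300), final = c(240, 280),
                          is_control = TRUE)
  expect_equal(nonvertebrate_loss_fraction(two), 30 / 550)
  expect_error(nonvertebrate_loss_fraction(two[0, ]),
               class = "carrionfate_insufficient_data_error")
  rem <- make_deployments(1, final = 0, removed = TRUE)
  expect_error(nonvertebrate_loss_fraction(rem),
               class = "carrionfate_validation_error")
})

test_that("loss adjustment floors at zero and treats removals as total loss", {
  d <- make_deployments(1, initial = 300, final = 200)
  expect_equal(adjust_loss(d, 0), 100)
  exact <- make_deployments(1, initial = 250, final = 250 * (1 - 0.096))
  expect_equal(adjust_loss(exact, 0.096), 0, tolerance = 1e-9)
  removed <- make_deployments(1, initial = 280, final = 0, removed = TRUE)
  expect_equal(adjust_loss(removed, 0.096), 280 * 0.904)
})

test_that("kappa calibration is least squares through the origin", {
  expect_equal(calibrate_kappa(90, 11.4), 90 / 11.4)
  expect_equal(calibrate_kappa(c(90, 50), c(11.4, 5)),
               (90 * 11.4 + 50 * 5) / (11.4^2 + 5^2))
  expect_equal(calibrate_kappa(c(0, 0), c(3, 8)), 0)
  expect_error(calibrate_kappa(c(10, 10), c(0, 0)),
               class = "carrionfate_calibration_error")
  # cross-check against lm() with a through-origin formula
  set.seed(4)
  S <- runif(20, 1, 30)
  L <- 8 * S + rnorm(20, sd = 3)
  L <- pmax(0, L)
  expect_equal(calibrate_kappa(L, S),
               unname(coef(lm(L ~ 0 + S))), tolerance = 1e-10)
})

test_that("non-removed allocation follows mass-time weights", {
  bm <- default_body_masses()
  one <- allocate_carcass(100, c(CROW = 30), NULL, bm)
  expect_equal(unname(one$grams["CROW"]), 100)
  expect_equal(one$unattributed_g, 0)

  two <- allocate_carcass(100, c(CROW = 30, MAGPIE = 30), NULL, bm)
  expect_equal(unname(two$grams["CROW"]), 71.25)
  expect_equal(unname(two$grams["MAGPIE"]), 28.75)

  none <- allocate_carcass(80, c(CROW = 0), NULL, bm)
  expect_equal(none$unattributed_g, 80)
})

test_that("removal credit: remover takes the post-kappa remainder", {
  bm <- default_body_masses()
  # fox removes with zero prior eating: full adjusted loss to the fox
  fox <- allocate_carcass(280 * 0.904, c(FOX = 0), "FOX", bm, kappa = 8)
  expect_equal(unname(fox$grams["FOX"]), 253.12)
  # prior crow eating splits off kappa * m * t
  mix <- allocate_carcass(200, c(CROW = 20), "FOX", bm, kappa = 5)
  expect_equal(unname(mix$grams["CROW"]), 5 * 0.57 * 20)
  expect_equal(unname(mix$grams["FOX"]), 200 - 5 * 0.57 * 20)
  # rescale when kappa over-explains the adjusted loss
  cap <- allocate_carcass(50, c(CROW = 100, MAGPIE = 100), "FOX", bm,
                          kappa = 5)
  expect_equal(sum(cap$grams), 50)
  expect_equal(unname(cap$grams["FOX"]), 0)
  expect_equal(unname(cap$grams["CROW"]) / unname(cap$grams["MAGPIE"]),
               570 / 230)
  # proportional fallback: remover treated as sole consumer
  prop <- allocate_carcass(200, c(CROW = 20), "FOX", bm, kappa = 5,
                           method = "proportional")
  expect_equal(unname(prop$grams["FOX"]), 200)
  expect_error(allocate_carcass(10, c(BADGER = 5), NULL, bm),
               class = "carrionfate_validation_error")
})

test_that("allocation conserves mass and responds monotonically to effort", {
  bm <- default_body_masses()
  set.seed(12)
  for (k in 1:25) {
    adj <- runif(1, 0, 260)
    mins <- setNames(runif(3, 0, 120) * rbinom(3, 1, 0.7),
                     c("CROW", "MAGPIE", "FOX"))
    rem <- if (runif(1) < 0.4) "FOX" else NULL
    a <- allocate_carcass(adj, mins, rem, bm, kappa = runif(1, 0, 4))
    expect_lt(abs(sum(a$grams) + a$unattributed_g - adj), 1e-9)
    expect_true(all(a$grams >= -1e-12))
  }
  # more eating time never lowers a species' share (non-removed)
  shares <- vapply(seq(10, 120, by = 10), function(t) {
    unname(allocate_carcass(100, c(CROW = t, MAGPIE = 30), NULL,
                            bm)$grams["CROW"])
  }, numeric(1))
  expect_true(all(diff(shares) >= -1e-12))
})

test_that("non-removed allocations are invariant to body-mass rescaling", {
  bm <- default_body_masses()
  a <- allocate_carcass(150, c(CROW = 42, MAGPIE = 17), NULL, bm)
  b <- allocate_carcass(150, c(CROW = 42, MAGPIE = 17), NULL, bm * 7)
  expect_equal(a$grams, b$grams, tolerance = 1e-12)
})

test_that("percentage ledgers reproduce share arithmetic with half-up display", {
  led <- biomass_ledger(c(CROW = 3586, MAGPIE = 1416, FOX = 3018), 18610)
  expect_equal(led$pct_display[led$species != "TOTAL"], c(19, 8, 16))
  expect_equal(led$pct_display[led$species == "TOTAL"], 43)
  expect_equal(led$grams[led$species == "TOTAL"], 8020)
  empty <- biomass_ledger(c(CROW = 0), 0)
  expect_true(all(is.na(empty$pct)))
  expect_equal(round_half_up(c(0.5, 1.5, 2.45, -0.5), 0), c(1, 2, 2, -1))
  expect_equal(round_half_up(9.6024, 1), 9.6)
})

test_that("study attribution conserves mass per carcass and study-wide", {
  study <- simulate_study(small_config(41, n_carcasses = 20, n_controls = 4))
  obs <- extract_observations(study$detections)
  att <- attribute_study(study$deployments, obs)
  cc <- att$carcass
  expect_lt(max(abs(cc$allocated_g + cc$unattributed_g +
                      cc$nonvertebrate_g - cc$loss_g)), 1e-9)
  all_row <- att$summary[att$summary$scope == "ALL" &
                           att$summary$species == "TOTAL", ]
  expect_equal(all_row$grams, sum(att$allocations$grams), tolerance = 1e-9)
  # species + unconsumed + non-vertebrate pools tile the deployed biomass
  deployed <- sum(cc$initial_mass_g)
  unconsumed <- sum(cc$final_mass_g[!cc$removed]) + sum(cc$unattributed_g)
  expect_equal(all_row$grams + unconsumed + sum(cc$nonvertebrate_g),
               deployed, tolerance = 1e-6)
})

test_that("an unscavenged study attributes nothing and flags empty scopes", {
  dep <- rbind(make_deployments(4, initial = 260, final = 240),
               make_deployments(2, initial = 260, final = 240,
                                is_control = TRUE, prefix = "K"))
  obs <- make_obs("C001", "CROW", "LOOKING")
  att <- attribute_study(dep, obs)
  expect_equal(nrow(att$allocations), 0L)
  sc <- att$summary[att$summary$scope == "SCAVENGED_ONLY", ]
  expect_true(all(is.na(sc$pct)))
  expect_true(is.na(att$kappa))
})

test_that("estimated fraction and kappa recover simulator ground truth", {
  cfg <- default_paperlike_config(seed = 77)
  study <- simulate_study(cfg)
  obs <- extract_observations(study$detections)
  att <- attribute_study(study$deployments, obs)
  expect_lt(abs(att$fraction - 0.096), 0.02)
  expect_lt(abs(att$kappa - 2), 0.5)
  expect_equal(unname(coef(att)["nonvertebrate_fraction"]), att$fraction)
})

test_that("deployment table integrity violations are rejected by name", {
  bad <- make_deployments(2)
  bad$final_mass_g[2] <- bad$initial_mass_g[2] + 5
  expect_error(attribute_study(bad, make_obs("C001", "CROW", "EATING")),
               "C002", class = "carrionfate_integrity_error")
  dup <- make_deployments(2)
  dup$carcass_id <- "C001"
  expect_error(attribute_study(dup, make_obs("C001", "CROW", "EATING")),
               class = "carrionfate_integrity_error")
})
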