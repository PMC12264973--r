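test_that("template observer matches templates to themselves and tie-breaks fixed", {
  # letter sized to the array footprint so every template has content the
  # implant can render under central fixation
  cfg <- desk_cfg(stimulus = list(size_deg = 12))
  bank <- template_bank(cfg, desk_sim())
  expect_named(bank, optotype_letters())
  # every template matched against the bank returns itself
  for (L in optotype_letters())
    expect_equal(template_observer(bank[[L]], bank), L)
  # all-zero percept: deterministic first-alternative choice
  expect_equal(template_observer(bank[["E"]] * 0, bank), "C")
  # empty clip errors
  empty <- structure(list(frames = array(0, c(2, 2, 0))),
                     class = "percept_clip")
  expect_error(template_observer(empty, bank), "empty")
})

test_that("letters are read perfectly in the near-veridical limit", {
  # no raster, no temporal model, tight spread (rho = 100 um, lam -> 0),
  # letters sized into the array footprint: the percept is an almost
  # undistorted subsampled letter and the observer must read all 8
  sim <- desk_sim_with_params(rho = 100, lam = 1)
  cfg <- desk_cfg("no_raster", duration_s = 0.1, seed = 2,
                  params = list(rho = 100, lam = 1),
                  temporal = list(on = FALSE),
                  stimulus = list(size_deg = 12))
  bank <- template_bank(cfg, sim)
  correct <- vapply(optotype_letters(), function(L) {
    stim <- render_optotype(L, size_deg = 12, duration_s = 0.1)
    clip <- run_simulation(stim, NULL, cfg, sim = sim)
    template_observer(clip, bank) == L
  }, logical(1))
  expect_equal(sum(correct), 8)
})

test_that("random observer sits at the 1/8 chance level", {
  # analytic chance level for an 8AFC task
  expect_equal(1 / 8, 0.125)
  # 1e5 seeded draws against a uniform target: within a 3-sigma binomial band
  n <- 1e5
  ch <- random_observer(8, n, seed = 123)
  expect_true(all(ch %in% 1:8))
  target <- random_observer(8, n, seed = 321)
  acc <- mean(ch == target)
  expect_lt(abs(acc - 1 / 8), 3 * sqrt(0.125 * 0.875 / n))
  expect_identical(ch, random_observer(8, n, seed = 123))
})

test_that("motion energy reports zero for static clips and true drift for bars", {
  sim <- desk_sim()
  # static percept: no drift, no wobble
  cfg0 <- desk_cfg("no_raster", duration_s = 0.5)
  clip0 <- run_simulation(render_optotype("E", duration_s = 0.5), NULL, cfg0,
                          sim = sim)
  me0 <- motion_energy(clip0)
  expect_equal(unname(me0$drift_dps), c(0, 0), tolerance = 1e-6)

  # rightward bar under no-raster: positive x drift
  clipR <- run_simulation(render_moving_bar("right", duration_s = 2), NULL,
                          cfg0, sim = sim)
  expect_gt(motion_energy(clipR)$drift_dps[["x"]], 0)

  expect_error(motion_energy(structure(list(frames = array(0, c(2, 2, 1))),
                                       class = "percept_clip")), "2 frames")
})

test_that("drift direction is within 45 degrees of truth for all 8 bar directions", {
  sim <- desk_sim()
  cfg <- desk_cfg("no_raster", duration_s = 2)
  for (d in motion_directions()) {
    clip <- run_simulation(render_moving_bar(d, duration_s = 2), NULL, cfg,
                           sim = sim)
    v <- motion_energy(clip)$drift_dps
    u <- switch(d, "up" = c(0, 1), "down" = c(0, -1), "left" = c(-1, 0),
                "right" = c(1, 0), "up-right" = c(1, 1), "up-left" = c(-1, 1),
                "down-right" = c(1, -1), "down-left" = c(-1, -1))
    cosang <- sum(v * u) / sqrt(sum(v^2)) / sqrt(sum(u^2))
    expect_gt(cosang, cos(pi / 4))
  }
})

test_that("static-percept wobble is lower under checkerboard than band rasters", {
  sim <- desk_sim()
  wob <- vapply(c("horizontal", "vertical", "checkerboard"), function(p) {
    cfg <- desk_cfg("main", p, duration_s = 1)
    clip <- run_simulation(render_optotype("E", duration_s = 1), NULL, cfg,
                           sim = sim)
    motion_energy(clip)$wobble_dps
  }, numeric(1))
  expect_lt(wob[["checkerboard"]], min(wob[["horizontal"]], wob[["vertical"]]))
})

test_that("confusion matrices conserve trials and expose response bias", {
  # perfect observer: identity-pattern matrix, NA bias (no errors)
  rec <- data.frame(task = "letter",
                    stimulus = rep(optotype_letters(), each = 6),
                    choice = rep(optotype_letters(), each = 6),
                    correct = TRUE)
  cb <- confusion_and_bias(rec)
  expect_equal(unname(diag(cb$confusion)), rep(6, 8))
  expect_equal(sum(cb$confusion), 48)
  expect_equal(unname(rowSums(cb$confusion)), rep(6, 8))
  expect_true(all(is.na(cb$bias)))
  expect_equal(cb$accuracy, 1)

  # uniform random responder: bias indices near 1/8
  set.seed(5)
  n <- 16000
  rec2 <- data.frame(task = "letter",
                     stimulus = sample(optotype_letters(), n, TRUE),
                     choice = sample(optotype_letters(), n, TRUE))
  rec2$correct <- rec2$stimulus == rec2$choice
  cb2 <- confusion_and_bias(rec2)
  expect_equal(sum(cb2$confusion), n)
  expect_true(all(abs(cb2$bias - 1 / 8) < 0.02))
  expect_equal(sum(cb2$bias), 1)

  expect_error(confusion_and_bias(data.frame()), "empty")
  rec3 <- rbind(rec, transform(rec, task = "motion"))
  expect_error(confusion_and_bias(rec3), "mixes tasks")
})
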