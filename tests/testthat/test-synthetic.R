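test_that("scene configuration validates its invariants", {
  expect_error(scene_config("Nature", "Low", composition = c(trees = 0.5)),
               "sum to 1")
  expect_error(scene_config("Nature", "Low",
                            composition = c(trees = 1.5, grass = -0.5)),
               "non-negative|sum to 1")
  expect_error(scene_config("Nature", "Low",
                            composition = c(bricks = 1)), "vocabulary")
  expect_error(scene_config("Nature", "Low", target_sky_fraction = 1.2),
               "0, 1")
  # default calibration: more sky the lower the horizon
  fr <- vapply(c("Low", "Medium", "High"), function(h)
    scene_config("Nature", h)$target_sky_fraction, numeric(1))
  expect_true(fr["Low"] > fr["Medium"] && fr["Medium"] > fr["High"])
})

test_that("generated scenes honour the sky band and composition", {
  cfg0 <- scene_config("Urban", "Low", target_sky_fraction = 0,
                       width = 40, height = 30)
  sc0 <- generate_scene(cfg0, seed = 1)
  expect_equal(sc0$record$pct_sky, 0)

  cfg1 <- scene_config("Urban", "Low", target_sky_fraction = 1,
                       composition = numeric(), width = 40, height = 30)
  sc1 <- generate_scene(cfg1, seed = 1)
  expect_equal(sc1$record$pct_sky, 100)

  expect_error(generate_scene(
    scene_config("Urban", "Low", target_sky_fraction = 0.5,
                 composition = numeric(), width = 40, height = 30), seed = 1),
    "incompatible")

  # realized sky within one row of the configured fraction
  for (h in c("Low", "Medium", "High")) {
    cfg <- scene_config("Nature", h, width = 120, height = 80)
    sc <- generate_scene(cfg, seed = 7)
    expect_lt(abs(sc$record$pct_sky - 100 * cfg$target_sky_fraction),
              100 / 80 + 1e-9)
    expect_equal(sum(quantify_labels(sc$mask)), 100, tolerance = 1e-12)
  }

  # record percentages come from the emitted mask, not the targets
  cfg <- scene_config("Nature", "Low", width = 60, height = 40)
  sc <- generate_scene(cfg, seed = 11)
  expect_equal(unname(sc$record$pct_trees),
               unname(quantify_labels(sc$mask)["trees"]))

  # seed determinism
  expect_identical(generate_scene(cfg, seed = 5)$mask,
                   generate_scene(cfg, seed = 5)$mask)
})

test_that("simulated trials follow the profile and rating model", {
  m <- patch_mask(40, 20, list(
    list(rows = 11:20, cols = 1:40, label = "trees"),
    list(rows = 1:10, cols = 1:40, label = "sky")))
  rec <- scene_record("img1", "Nature", "Low", "front", "blue",
                      "spring_summer", quantify_labels(m))
  rm0 <- default_rating_model()
  prof <- make_participant_profiles(
    1, rm0, label_affinity = c(trees = 1),
    click_rate = c(Nature = 8), seed = 2)[[1]]

  tr <- simulate_trial(m, rec, prof, rm0, seed = 3)
  if (nrow(tr$clicks) > 0) {
    labs <- unclass(m)[cbind(floor(tr$clicks$y) + 1, floor(tr$clicks$x) + 1)]
    expect_true(all(labs == match("trees", vocab)))
  }
  expect_true(all(names(tr$ratings) ==
                    c("preference", "familiarity", "emotion", "openness",
                      "naturalness")))
  expect_true(all(tr$ratings[c("preference", "familiarity", "emotion",
                               "openness")] >= -50 &
                  tr$ratings[c("preference", "familiarity", "emotion",
                               "openness")] <= 50))
  expect_true(tr$ratings["naturalness"] >= 0 && tr$ratings["naturalness"] <= 100)

  # zero click rate for the environment -> zero clicks
  prof0 <- make_participant_profiles(1, rm0, click_rate = c(Nature = 0),
                                     seed = 4)[[1]]
  expect_equal(nrow(simulate_trial(m, rec, prof0, rm0, seed = 5)$clicks), 0)

  # zero noise, zero intercepts -> rating equals the clipped linear predictor
  rm_det <- default_rating_model(sd_participant = 0, sd_image = 0,
                                 sd_resid = 0)
  profd <- make_participant_profiles(1, rm_det, click_rate = c(Nature = 1),
                                     seed = 6)[[1]]
  trd <- simulate_trial(m, rec, profd, rm_det, seed = 7)
  expected <- min(100, max(0, 15 + 0.65 * rec$pct_nature))
  expect_equal(unname(trd$ratings["naturalness"]), expected)
})

test_that("click counts are capped at 20 by the truncated Poisson", {
  m <- patch_mask(10, 10, list(list(rows = 1:10, cols = 1:10,
                                    label = "trees")))
  rec <- scene_record("i", "Nature", "Low", "front", "blue", "winter",
                      quantify_labels(m))
  prof <- make_participant_profiles(1, click_rate = c(Nature = 30),
                                    seed = 1)[[1]]
  counts <- vapply(1:200, function(s)
    nrow(simulate_trial(m, rec, prof, seed = s)$clicks), numeric(1))
  expect_true(all(counts <= 20))
  expect_gt(mean(counts), 15)  # high-rate profile still clicks a lot
})

test_that("raising a label's affinity does not decrease its click share", {
  m <- patch_mask(40, 20, list(
    list(rows = 1:20, cols = 1:20, label = "trees"),
    list(rows = 1:20, cols = 21:40, label = "grass")))
  rec <- scene_record("i", "Nature", "Low", "front", "blue", "winter",
                      quantify_labels(m))
  share_trees <- function(affinity, seed) {
    prof <- make_participant_profiles(
      1, label_affinity = affinity, click_rate = c(Nature = 5),
      seed = 1000 + seed)[[1]]
    clicks <- do.call(rbind, lapply(seq_len(250), function(s)
      simulate_trial(m, rec, prof, seed = s)$clicks))
    labs <- unclass(m)[cbind(floor(clicks$y) + 1, floor(clicks$x) + 1)]
    mean(labs == match("trees", vocab))
  }
  low <- share_trees(c(trees = 1, grass = 1), 1)
  high <- share_trees(c(trees = 3, grass = 1), 1)
  expect_gte(high, low)
  expect_gt(high, 0.6)  # 3:1 affinity on a 50/50 scene
})

test_that("generate_dataset is deterministic and has the right shape", {
  g <- build_design_grid(4, 2, 2, 2)
  b <- generate_dataset(3, g, seed = 21, width = 48, height = 24,
                        n_patches = 12)
  expect_length(b$trials, 3 * g$schedule_length)
  expect_length(b$scenes$masks, g$n_images)
  expect_equal(nrow(b$scenes$catalog), g$n_images)
  # every trial references an existing scene and participant
  pids <- vapply(b$profiles, `[[`, "", "participant_id")
  for (t in b$trials) {
    expect_true(t$image_id %in% names(b$scenes$masks))
    expect_true(t$participant_id %in% pids)
  }
  b2 <- generate_dataset(3, g, seed = 21, width = 48, height = 24,
                         n_patches = 12)
  expect_identical(b, b2)
  b3 <- generate_dataset(3, g, seed = 22, width = 48, height = 24,
                         n_patches = 12)
  expect_false(identical(b, b3))

  # degenerate grid: one scheduled presentation per participant
  g1 <- build_design_grid(1, 1, 1, 1)
  b1 <- generate_dataset(2, g1, seed = 1, width = 30, height = 20)
  expect_length(b1$trials, 2)

  # the full default design: 96 scheduled trials x 105 participants
  expect_equal(105 * build_design_grid()$schedule_length, 10080)
})

test_that("flat tables carry one row per trial and per click", {
  g <- build_design_grid(2, 2, 2, 2)
  b <- generate_dataset(2, g, seed = 33, width = 40, height = 20,
                        n_patches = 8)
  rt <- ratings_table(b)
  expect_equal(nrow(rt), length(b$trials))
  expect_true(all(c("participant_id", "image_id", "horizon", "weather",
                    "season", "pct_sky", "naturalness") %in% names(rt)))
  ct <- clicks_table(b)
  expect_equal(nrow(ct), sum(vapply(b$trials, function(t) nrow(t$clicks), 0)))
  expect_true(all(c("click_index", "x", "y", "radius") %in% names(ct)))
})
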