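# Synthetic-data generator: label-mask scenes with the factorial structure,
# participant click streams biased toward nature labels, and subjective
# ratings from a linear model with crossed random intercepts.  Ground truth
# is retained so downstream stages can be tested by parameter recovery.

# Default below-horizon compositions per environment type.  Proportions are
# of the below-horizon surface and sum to 1.
DEFAULT_COMPOSITIONS <- list(
  Urban      = c(manmade = 0.85, trees = 0.05, grass = 0.03, vegetation = 0.02,
                 rocks = 0.02, background = 0.03),
  SomeUrban  = c(manmade = 0.55, trees = 0.18, grass = 0.12, vegetation = 0.08,
                 water = 0.04, background = 0.03),
  SomeNature = c(manmade = 0.20, trees = 0.35, grass = 0.20, vegetation = 0.12,
                 water = 0.08, rocks = 0.03, background = 0.02),
  Nature     = c(trees = 0.40, grass = 0.20, vegetation = 0.15, water = 0.10,
                 rocks = 0.07, sand = 0.05, snow = 0.02, background = 0.01))

# Default sky-fraction targets per horizon level, calibrated to the stimulus
# set's reported per-horizon sky means (Low ~41%, Medium ~19%, High ~4%).
# Configuration, not ground truth.
DEFAULT_SKY_FRACTIONS <- c(Low = 0.41, Medium = 0.19, High = 0.04)

# Between-image spread of the sky fraction within a horizon level,
# calibrated to the stimulus set's reported per-horizon SDs (~23/13/4.4%).
DEFAULT_SKY_FRACTION_SD <- c(Low = 0.23, Medium = 0.13, High = 0.044)

# Default expected clicks per trial by environment type (reported sample
# means of the selection task).
DEFAULT_CLICK_RATES <- c(Urban = 2, SomeUrban = 4, SomeNature = 5, Nature = 6)

# Default propensity to select a label as "nature"; manmade and background
# are never deliberately selected.
DEFAULT_AFFINITY <- c(trees = 1, grass = 1, vegetation = 1, water = 1,
                      sky = 0.6, rocks = 0.3, sand = 0.3, snow = 0.5,
                      manmade = 0, background = 0)

RATING_SCALES <- c("preference", "familiarity", "emotion", "openness",
                   "naturalness")

#' Scene configuration for the synthetic generator
#'
#' @param environment,horizon,vantage,weather,season Factor levels
#'   (normalized; see [factor_levels()]).
#' @param width,height Canvas size in pixels (default 1500 x 750, the
#'   stimulus format).
#' @param target_sky_fraction Proportion of the image occupied by the sky
#'   band; defaults per horizon level to Low 0.41, Medium 0.19, High 0.04.
#' @param composition Named proportions (summing to 1 within 1e-9) of the
#'   below-horizon surface per label; defaults per environment type.
#' @param n_patches Number of Voronoi patch seeds used to texture the
#'   below-horizon region.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(environment, horizon, vantage = "front",
                         weather = "blue", season = "spring_summer",
                         width = 1500, height = 750,
                         target_sky_fraction = NULL, composition = NULL,
                         n_patches = 40) {
  environment <- normalize_environment(environment)
  horizon <- normalize_horizon(horizon)
  target_sky_fraction <- target_sky_fraction %||%
    unname(DEFAULT_SKY_FRACTIONS[horizon])
  if (is.na(target_sky_fraction) || target_sky_fraction < 0 ||
      target_sky_fraction > 1)
    stop("`target_sky_fraction` must lie in [0, 1]", call. = FALSE)
  composition <- composition %||% DEFAULT_COMPOSITIONS[[environment]]
  if (length(composition)) {
    if (is.null(names(composition)) ||
        !all(names(composition) %in% SKY_LABELS))
      stop("composition names must be vocabulary labels", call. = FALSE)
    if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
      stop("composition proportions must be non-negative and sum to 1",
           call. = FALSE)
  }
  structure(list(environment = environment, horizon = horizon,
                 vantage = normalize_vantage(vantage),
                 weather = normalize_weather(weather),
                 season = normalize_season(season),
                 width = as_count(width, "width"),
                 height = as_count(height, "height"),
                 target_sky_fraction = target_sky_fraction,
                 composition = composition,
                 n_patches = as_count(n_patches, "n_patches")),
            class = "scene_config")
}

#' Generate one synthetic scene
#'
#' The top band of the mask is sky, occupying `target_sky_fraction` of the
#' pixels up to row rounding; the below-horizon region is tiled with
#' contiguous label patches grown from random Voronoi seeds whose label
#' shares follow the configured composition.  The returned scene record's
#' percentages are quantified from the emitted mask itself, not from the
#' targets.
#'
#' @param config A [scene_config()].
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @param image_id Identifier stored in the scene record.
#' @return List with `mask` (a [label_mask()]) and `record` (a one-row
#'   [scene_record()] data frame).
#' @export
generate_scene <- function(config, seed = NULL, image_id = "scene") {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(seed))
    return(with_seed(seed, generate_scene(config, image_id = image_id)))
  w <- config$width; h <- config$height
  n_sky <- round(config$target_sky_fraction * h)
  below <- h - n_sky
  if (below > 0 && (length(config$composition) == 0 ||
                    sum(config$composition) == 0))
    stop("composition incompatible with requested sky fraction: ",
         "the below-horizon region needs a non-empty composition",
         call. = FALSE)
  codes <- matrix(match("background", SKY_LABELS), nrow = h, ncol = w)
  if (n_sky > 0) codes[seq_len(n_sky), ] <- match("sky", SKY_LABELS)
  if (below > 0) {
    comp <- config$composition[config$composition > 0]
    n_seeds <- max(config$n_patches, length(comp))
    counts <- largest_remainder(comp, n_seeds)
    seed_lab <- match(rep(names(comp), counts), SKY_LABELS)
    sx <- runif(n_seeds, 0, w)
    sy <- runif(n_seeds, n_sky, h)
    xs <- seq_len(w) - 0.5
    chunk <- max(1L, floor(2e6 / n_seeds / w))
    for (start in seq(1L, below, by = chunk)) {
      rows <- start:min(start + chunk - 1L, below)
      ys <- (n_sky + rows) - 0.5
      px <- rep(xs, each = length(rows))
      py <- rep(ys, times = w)
      d <- outer(px, sx, function(a, b) (a - b)^2) +
        outer(py, sy, function(a, b) (a - b)^2)
      nearest <- max.col(-d, ties.method = "first")
      codes[cbind(rep(n_sky + rows, times = w),
                  rep(seq_len(w), each = length(rows)))] <- seed_lab[nearest]
    }
  }
  mask <- label_mask(codes)
  record <- scene_record(image_id, config$environment, config$horizon,
                         config$vantage, config$weather, config$season,
                         quantify_labels(mask))
  list(mask = mask, record = record)
}

#' Participant profiles for the simulator
#'
#' Each profile carries the participant's label-selection affinities, the
#' expected clicks per trial by environment type, per-scale random
#' intercepts (drawn from the rating model's participant SD) and the
#' residual rating noise SD.
#'
#' @param n_participants Number of profiles.
#' @param rating_model A [default_rating_model()]-style list supplying the
#'   participant intercept SD and residual SD.
#' @param label_affinity Named non-negative selection weights per label; at
#'   least one must be positive.
#' @param click_rate Named expected clicks per trial by environment type
#'   (values >= 0).
#' @param seed Optional seed (`NULL` uses the current stream).
#' @return List of `participant_profile` objects.
#' @export
make_participant_profiles <- function(n_participants,
                                      rating_model = default_rating_model(),
                                      label_affinity = DEFAULT_AFFINITY,
                                      click_rate = DEFAULT_CLICK_RATES,
                                      seed = NULL) {
  if (!is.null(seed))
    return(with_seed(seed, make_participant_profiles(
      n_participants, rating_model, label_affinity, click_rate)))
  n_participants <- as_count(n_participants, "n_participants")
  if (any(label_affinity < 0) || all(label_affinity == 0))
    stop("label_affinity needs non-negative weights, at least one > 0",
         call. = FALSE)
  if (is.null(names(label_affinity)) ||
      !all(names(label_affinity) %in% SKY_LABELS))
    stop("label_affinity names must be vocabulary labels", call. = FALSE)
  if (any(click_rate < 0)) stop("click_rate values must be >= 0", call. = FALSE)
  lapply(seq_len(n_participants), function(i) {
    structure(list(
      participant_id = sprintf("p%03d", i),
      label_affinity = label_affinity,
      click_rate = click_rate,
      rating_noise_sd = rating_model$sd_resid,
      random_intercepts = setNames(
        rnorm(length(RATING_SCALES), 0, rating_model$sd_participant),
        RATING_SCALES)),
      class = "participant_profile")
  })
}

#' Default rating-generating model
#'
#' Linear fixed effects of scene covariates per scale, crossed random
#' intercepts for participant and image, Gaussian residual noise, and
#' truncation to the scale bounds (naturalness 0..100, all other scales
#' -50..50).  Coefficient names are either `"(Intercept)"`, a numeric
#' catalog column (e.g. `pct_nature`), or `"column=level"` for a factor
#' indicator (e.g. `"horizon=High"`).
#'
#' @param sd_participant,sd_image,sd_resid Standard deviations (>= 0) of the
#'   participant intercepts, image intercepts and residual noise, in scale
#'   units.
#' @param scales Optional replacement list of per-scale `coef` / `bounds`.
#' @return List of class `rating_model`.
#' @export
default_rating_model <- function(sd_participant = 10, sd_image = 8,
                                 sd_resid = 12, scales = NULL) {
  if (any(c(sd_participant, sd_image, sd_resid) < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  scales <- scales %||% list(
    naturalness = list(coef = c("(Intercept)" = 15, pct_nature = 0.65),
                       bounds = c(0, 100)),
    preference  = list(coef = c("(Intercept)" = -12, pct_nature = 0.35),
                       bounds = c(-50, 50)),
    emotion     = list(coef = c("(Intercept)" = -10, pct_nature = 0.30),
                       bounds = c(-50, 50)),
    openness    = list(coef = c("(Intercept)" = -5, pct_sky = 0.45),
                       bounds = c(-50, 50)),
    familiarity = list(coef = c("(Intercept)" = 0, pct_nature = 0.10),
                       bounds = c(-50, 50)))
  structure(list(scales = scales, sd_participant = sd_participant,
                 sd_image = sd_image, sd_resid = sd_resid),
            class = "rating_model")
}

# Linear predictor of one scale over catalog rows.
rating_linpred <- function(coefs, data) {
  lp <- numeric(nrow(data))
  for (nm in names(coefs)) {
    if (nm == "(Intercept)") {
      lp <- lp + coefs[[nm]]
    } else if (grepl("=", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1]]
      if (!parts[1] %in% names(data))
        stop("rating model references unknown column: ", parts[1],
             call. = FALSE)
      lp <- lp + coefs[[nm]] * (data[[parts[1]]] == parts[2])
    } else {
      if (!nm %in% names(data))
        stop("rating model references unknown column: ", nm, call. = FALSE)
      lp <- lp + coefs[[nm]] * data[[nm]]
    }
  }
  lp
}

clip_to <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

#' Simulate one trial
#'
#' The click count is drawn from a Poisson distribution with mean
#' `click_rate[environment]`, truncated to 0..20.  Each click targets a
#' label drawn with probability proportional to `affinity x availability`
#' (label pixel count); a uniformly chosen pixel of that label becomes the
#' click centre.  If every available label has zero affinity the sampler
#' falls back to a uniform choice over available labels.  Ratings are the
#' rating model's linear predictor plus participant intercept, image effect
#' and residual noise, truncated to the scale bounds.
#'
#' @param mask A [label_mask()] of the presented image.
#' @param record The image's one-row [scene_record()].
#' @param profile A participant profile ([make_participant_profiles()]).
#' @param rating_model A [default_rating_model()]-style model.
#' @param image_effects Optional named numeric vector of the image's
#'   per-scale random effects (default zero).
#' @param seed Optional seed (`NULL` uses the current stream).
#' @param radius Click disc radius in pixels.
#' @return A `trial_record`: list with `participant_id`, `image_id`, the
#'   design factors, a `clicks` data frame (`click_index`, `x`, `y`,
#'   `radius`) and a named `ratings` vector over all five scales.
#' @export
simulate_trial <- function(mask, record, profile,
                           rating_model = default_rating_model(),
                           image_effects = NULL, seed = NULL, radius = 150) {
  if (!is.null(seed))
    return(with_seed(seed, simulate_trial(mask, record, profile,
                                          rating_model, image_effects,
                                          radius = radius)))
  stopifnot(inherits(mask, "label_mask"))
  cr <- profile$click_rate
  lambda <- if (record$environment %in% names(cr)) cr[[record$environment]] else 0
  n_clicks <- if (lambda <= 0) 0L else {
    u <- runif(1, 0, ppois(20, lambda))
    qpois(u, lambda)
  }
  B <- tabulate(mask, nbins = length(SKY_LABELS))
  avail <- which(B > 0)
  aff <- setNames(numeric(length(SKY_LABELS)), SKY_LABELS)
  aff[names(profile$label_affinity)] <- profile$label_affinity
  w <- aff[avail] * B[avail]
  if (sum(w) <= 0) w <- rep(1, length(avail))
  clicks <- data.frame(click_index = integer(0), x = numeric(0),
                       y = numeric(0), radius = numeric(0))
  if (n_clicks > 0) {
    labs <- avail[sample.int(length(avail), n_clicks, replace = TRUE,
                             prob = w)]
    xy <- t(vapply(labs, function(code) {
      px <- sample(which(mask == code), 1L)
      iy <- (px - 1L) %% nrow(mask) + 1L
      ix <- (px - 1L) %/% nrow(mask) + 1L
      c(ix - 0.5, iy - 0.5)
    }, numeric(2)))
    clicks <- data.frame(click_index = seq_len(n_clicks),
                         x = xy[, 1], y = xy[, 2], radius = radius)
  }
  if (is.null(image_effects))
    image_effects <- setNames(numeric(length(RATING_SCALES)), RATING_SCALES)
  ratings <- vapply(RATING_SCALES, function(sc) {
    sm <- rating_model$scales[[sc]]
    y <- rating_linpred(sm$coef, record) +
      profile$random_intercepts[[sc]] + image_effects[[sc]] +
      rnorm(1, 0, profile$rating_noise_sd %||% rating_model$sd_resid)
    clip_to(y, sm$bounds)
  }, numeric(1))
  structure(list(participant_id = profile$participant_id,
                 image_id = record$image_id,
                 environment = record$environment, horizon = record$horizon,
                 vantage = record$vantage, weather = record$weather,
                 season = record$season, clicks = clicks, ratings = ratings),
            class = "trial_record")
}

#' Simulate subjective ratings over a scene catalog
#'
#' Lightweight ratings-only generator (no masks or clicks needed): every
#' participant rates every catalog row (or the rows of a supplied schedule),
#' with outcome = fixed linear predictor + participant intercept + image
#' intercept + residual noise, truncated to the scale bounds.  Used for
#' mixed-model parameter-recovery checks where the generating model must be
#' known exactly.
#'
#' @param catalog Data frame with `image_id` and every column the rating
#'   model references.
#' @param n_participants Number of simulated raters.
#' @param rating_model A [default_rating_model()]-style model.
#' @param seed Optional seed.
#' @param scales Subset of scales to emit (default all in the model).
#' @return Data frame: `participant_id`, `image_id`, one column per scale.
#' @export
simulate_ratings <- function(catalog, n_participants,
                             rating_model = default_rating_model(),
                             seed = NULL, scales = names(rating_model$scales)) {
  if (!is.null(seed))
    return(with_seed(seed, simulate_ratings(catalog, n_participants,
                                            rating_model, scales = scales)))
  n_participants <- as_count(n_participants, "n_participants")
  n_img <- nrow(catalog)
  out <- data.frame(
    participant_id = rep(sprintf("p%03d", seq_len(n_participants)),
                         each = n_img),
    image_id = rep(catalog$image_id, n_participants),
    stringsAsFactors = FALSE)
  for (cc in setdiff(names(catalog), c("image_id", "participant_id")))
    out[[cc]] <- rep(catalog[[cc]], n_participants)
  for (sc in scales) {
    sm <- rating_model$scales[[sc]]
    lp <- rating_linpred(sm$coef, catalog)
    b_part <- rnorm(n_participants, 0, rating_model$sd_participant)
    b_img <- rnorm(n_img, 0, rating_model$sd_image)
    y <- rep(lp, n_participants) + rep(b_part, each = n_img) +
      rep(b_img, n_participants) +
      rnorm(n_participants * n_img, 0, rating_model$sd_resid)
    out[[sc]] <- clip_to(y, sm$bounds)
  }
  out
}

#' Generate a full synthetic dataset
#'
#' Draws weather and season per environment, generates one label-mask scene
#' per design-grid image, draws participant profiles and per-image rating
#' effects, and simulates every scheduled presentation.  The same seed
#' reproduces the bundle exactly.
#'
#' @param n_participants Number of participants (the study analysed 105;
#'   any smaller number is allowed for faster runs).
#' @param grid A [build_design_grid()] object.
#' @param rating_model A [default_rating_model()]-style model.
#' @param seed Integer seed for the whole bundle.
#' @param width,height Scene canvas size in pixels.
#' @param label_affinity,click_rate Passed to
#'   [make_participant_profiles()].
#' @param n_patches Passed to [scene_config()].
#' @param sky_fraction_sd Named per-horizon SD of the per-image sky
#'   fraction around its horizon target (default calibrated to the
#'   stimulus set's reported spread); draws are truncated to `[0, 1]`.
#' @param click_radius Selection-circle radius in pixels (the experiment
#'   used 150 px on a 1500 x 750 canvas; scale it with `width`/`height`
#'   when simulating on a smaller canvas).
#' @return Object of class `simulation_bundle`: `scenes` (list with `masks`
#'   keyed by image id and the `catalog` data frame), `trials` (list of
#'   trial records), `profiles`, `rating_model`, `image_effects`, `grid`,
#'   `seed`.
#' @export
generate_dataset <- function(n_participants, grid = build_design_grid(),
                             rating_model = default_rating_model(),
                             seed = 1, width = 1500, height = 750,
                             label_affinity = DEFAULT_AFFINITY,
                             click_rate = DEFAULT_CLICK_RATES,
                             n_patches = 40,
                             sky_fraction_sd = DEFAULT_SKY_FRACTION_SD,
                             click_radius = 150) {
  n_participants <- as_count(n_participants, "n_participants")
  with_seed(seed, {
    envs <- grid$environments
    envs$weather <- sample(WEATHER_LEVELS, nrow(envs), replace = TRUE)
    envs$season <- sample(SEASON_LEVELS, nrow(envs), replace = TRUE)

    masks <- vector("list", grid$n_images)
    names(masks) <- grid$images$image_id
    records <- vector("list", grid$n_images)
    for (i in seq_len(grid$n_images)) {
      img <- grid$images[i, ]
      e <- envs[match(img$env_id, envs$env_id), ]
      h_canon <- if (img$horizon %in% HORIZON_LEVELS) img$horizon else "Low"
      sd_h <- if (h_canon %in% names(sky_fraction_sd))
        sky_fraction_sd[[h_canon]] else 0
      tsf <- min(1, max(0, rnorm(1, DEFAULT_SKY_FRACTIONS[[h_canon]], sd_h)))
      cfg <- scene_config(
        environment = if (img$environment %in% ENV_LEVELS) img$environment
                      else "Nature",
        horizon = h_canon,
        vantage = if (img$vantage %in% VANTAGE_LEVELS) img$vantage
                  else "front",
        weather = e$weather, season = e$season,
        width = width, height = height,
        target_sky_fraction = tsf, n_patches = n_patches)
      sc <- generate_scene(cfg, image_id = img$image_id)
      # keep the grid's own (possibly non-canonical) level names
      sc$record$environment <- img$environment
      sc$record$horizon <- img$horizon
      sc$record$vantage <- img$vantage
      masks[[img$image_id]] <- sc$mask
      records[[i]] <- sc$record
    }
    catalog <- do.call(rbind, records)

    profiles <- make_participant_profiles(
      n_participants, rating_model,
      label_affinity = label_affinity,
      click_rate = if (all(grid$env_levels %in% names(click_rate)))
        click_rate else setNames(rep(mean(click_rate), length(grid$env_levels)),
                                 grid$env_levels))
    image_effects <- matrix(rnorm(grid$n_images * length(RATING_SCALES),
                                  0, rating_model$sd_image),
                            nrow = grid$n_images,
                            dimnames = list(grid$images$image_id,
                                            RATING_SCALES))
    trials <- vector("list", n_participants * grid$schedule_length)
    k <- 0L
    for (p in seq_len(n_participants)) {
      sched <- participant_schedule(grid)
      for (t in seq_len(nrow(sched))) {
        img_id <- sched$image_id[t]
        k <- k + 1L
        trials[[k]] <- simulate_trial(
          masks[[img_id]], catalog[match(img_id, catalog$image_id), ],
          profiles[[p]], rating_model,
          image_effects = image_effects[img_id, ], radius = click_radius)
      }
    }
    structure(list(scenes = list(masks = masks, catalog = catalog),
                   trials = trials, profiles = profiles,
                   rating_model = rating_model,
                   image_effects = image_effects, grid = grid, seed = seed),
              class = "simulation_bundle")
  })
}

#' @export
print.simulation_bundle <- function(x, ...) {
  cat(sprintf("<simulation_bundle: %d scene(s), %d participant(s), %d trial(s), seed %s>\n",
              length(x$scenes$masks), length(x$profiles), length(x$trials),
              format(x$seed)))
  invisible(x)
}

#' Flat trial tables from a simulation bundle
#'
#' `ratings_table()` returns one row per trial with the design factors, the
#' scene covariates and the five ratings; `clicks_table()` returns one row
#' per click (`participant_id`, `image_id`, `click_index`, `x`, `y`,
#' `radius`).
#'
#' @param bundle A [generate_dataset()] bundle.
#' @return A data frame.
#' @export
ratings_table <- function(bundle) {
  stopifnot(inherits(bundle, "simulation_bundle"))
  cat_cols <- c("pct_sky", "pct_greenery", "pct_nature", "pct_trees",
                "pct_water")
  catalog <- bundle$scenes$catalog
  rows <- lapply(bundle$trials, function(t) {
    row <- data.frame(participant_id = t$participant_id,
                      image_id = t$image_id, environment = t$environment,
                      horizon = t$horizon, vantage = t$vantage,
                      weather = t$weather, season = t$season,
                      n_clicks = nrow(t$clicks), stringsAsFactors = FALSE)
    row[cat_cols] <- catalog[match(t$image_id, catalog$image_id), cat_cols]
    row[names(t$ratings)] <- as.list(unname(t$ratings))
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname ratings_table
#' @export
clicks_table <- function(bundle) {
  stopifnot(inherits(bundle, "simulation_bundle"))
  rows <- lapply(bundle$trials, function(t) {
    if (nrow(t$clicks) == 0) return(NULL)
    cbind(data.frame(participant_id = t$participant_id,
                     image_id = t$image_id, stringsAsFactors = FALSE),
          t$clicks)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(participant_id = character(), image_id = character(),
                      click_index = integer(), x = numeric(), y = numeric(),
                      radius = numeric())
  rownames(out) <- NULL
  out
}
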