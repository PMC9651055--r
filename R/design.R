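# Factorial stimulus design: environments x vantage points x horizon levels,
# and the per-participant presentation schedule in which each environment is
# seen at both vantage points but under only one horizon condition per image.

#' Build the factorial stimulus design grid
#'
#' Enumerates the full image grid — every environment trimmed at every
#' vantage point and horizon level — and fixes the per-participant schedule
#' length (one trial per environment x vantage, with the horizon condition
#' varying between participants).  With the default counts (48 environments
#' in 4 categories, 2 vantage points, 3 horizon levels) this yields 288
#' images and 96 trials per participant, 8 from each of the 12
#' (category x horizon) cells.
#'
#' @param n_environments Number of source environments (default 48).
#' @param vantages Number of vantage points per environment (default 2).
#' @param horizons Number of horizon levels (default 3).
#' @param categories Number of environment-type categories; must divide
#'   `n_environments` evenly (default 4).
#' @return Object of class `design_grid` with elements `environments`
#'   (data frame: `env_id`, `environment`), `images` (data frame: `image_id`,
#'   `env_id`, `environment`, `vantage`, `horizon`), `n_images`,
#'   `schedule_length` and the level sets used.
#' @export
#' @examples
#' g <- build_design_grid()
#' g$n_images          # 288
#' g$schedule_length   # 96
build_design_grid <- function(n_environments = 48, vantages = 2,
                              horizons = 3, categories = 4) {
  n_environments <- as_count(n_environments, "n_environments")
  vantages <- as_count(vantages, "vantages")
  horizons <- as_count(horizons, "horizons")
  categories <- as_count(categories, "categories")
  if (n_environments %% categories != 0)
    stop("`n_environments` must be divisible by `categories` ",
         "so every environment type has the same number of scenes",
         call. = FALSE)
  env_levels <- if (categories <= length(ENV_LEVELS))
    ENV_LEVELS[seq_len(categories)] else paste0("Env", seq_len(categories))
  van_levels <- if (vantages <= length(VANTAGE_LEVELS))
    VANTAGE_LEVELS[seq_len(vantages)] else paste0("v", seq_len(vantages))
  hor_levels <- if (horizons <= length(HORIZON_LEVELS))
    HORIZON_LEVELS[seq_len(horizons)] else paste0("H", seq_len(horizons))

  environments <- data.frame(
    env_id = sprintf("env%03d", seq_len(n_environments)),
    environment = rep(env_levels, each = n_environments / categories),
    stringsAsFactors = FALSE)
  images <- expand.grid(env_id = environments$env_id,
                        vantage = van_levels, horizon = hor_levels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  images$environment <- environments$environment[match(images$env_id,
                                                       environments$env_id)]
  images$image_id <- sprintf("%s_%s_%s", images$env_id, images$vantage,
                             images$horizon)
  images <- images[order(images$env_id, images$vantage, images$horizon),
                   c("image_id", "env_id", "environment", "vantage", "horizon")]
  rownames(images) <- NULL
  structure(list(environments = environments, images = images,
                 n_images = nrow(images),
                 schedule_length = n_environments * vantages,
                 env_levels = env_levels, vantage_levels = van_levels,
                 horizon_levels = hor_levels),
            class = "design_grid")
}

#' @export
print.design_grid <- function(x, ...) {
  cat(sprintf(paste0("<design_grid: %d environments x %d vantage(s) x %d ",
                     "horizon(s) = %d images; %d trials/participant>\n"),
              nrow(x$environments), length(x$vantage_levels),
              length(x$horizon_levels), x$n_images, x$schedule_length))
  invisible(x)
}

#' Draw one participant's presentation schedule
#'
#' Each environment appears at both vantage points; for each environment x
#' vantage slot exactly one horizon condition is shown.  Horizon assignments
#' are balanced within every (category, vantage) block (each horizon gets an
#' equal share when the block size divides evenly, e.g. 8 trials per
#' (category x horizon) cell on the default grid), and the trial order is
#' randomized.
#'
#' @param grid A [build_design_grid()] object.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as [generate_dataset()] does).
#' @return Data frame with one row per trial: `trial_index`, `image_id`,
#'   `env_id`, `environment`, `vantage`, `horizon`.
#' @export
participant_schedule <- function(grid, seed = NULL) {
  stopifnot(inherits(grid, "design_grid"))
  if (!is.null(seed)) return(with_seed(seed, participant_schedule(grid)))
  hor <- grid$horizon_levels
  slots <- expand.grid(env_id = grid$environments$env_id,
                       vantage = grid$vantage_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  slots$environment <- grid$environments$environment[
    match(slots$env_id, grid$environments$env_id)]
  slots$horizon <- NA_character_
  for (cat in grid$env_levels) {
    for (v in grid$vantage_levels) {
      i <- which(slots$environment == cat & slots$vantage == v)
      assign_h <- rep(hor, length.out = length(i))
      slots$horizon[i] <- sample(assign_h, length(i))
    }
  }
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  slots$trial_index <- seq_len(nrow(slots))
  slots$image_id <- sprintf("%s_%s_%s", slots$env_id, slots$vantage,
                            slots$horizon)
  rownames(slots) <- NULL
  slots[, c("trial_index", "image_id", "env_id", "environment", "vantage",
            "horizon")]
}
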