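# Closed label vocabulary and canonical factor levels shared by all modules.
# The vocabulary is the 10 segmentation categories used for the stimuli;
# "background" holds unclassified or blurred pixels.

SKY_LABELS <- c("trees", "sky", "grass", "water", "rocks", "sand",
                "vegetation", "snow", "manmade", "background")

GREENERY_LABELS <- c("grass", "trees", "vegetation")

ENV_LEVELS     <- c("Urban", "SomeUrban", "SomeNature", "Nature")
HORIZON_LEVELS <- c("Low", "Medium", "High")
VANTAGE_LEVELS <- c("front", "back")
WEATHER_LEVELS <- c("blue", "grey", "cloudy")
SEASON_LEVELS  <- c("spring_summer", "autumn", "winter")

# Normalization tables.  "clear" is the stimulus-annotation wording for a
# blue sky; spring and summer are collapsed into one modelled level.
WEATHER_ALIASES <- c(blue = "blue", clear = "blue", grey = "grey",
                     gray = "grey", cloudy = "cloudy")
SEASON_ALIASES <- c(spring_summer = "spring_summer", spring = "spring_summer",
                    summer = "spring_summer", "spring/summer" = "spring_summer",
                    autumn = "autumn", fall = "autumn", winter = "winter")
ENV_ALIASES <- c(Urban = "Urban", U = "Urban",
                 SomeUrban = "SomeUrban", "Some Urban" = "SomeUrban",
                 SU = "SomeUrban",
                 SomeNature = "SomeNature", "Some Nature" = "SomeNature",
                 SN = "SomeNature",
                 Nature = "Nature", N = "Nature")
HORIZON_ALIASES <- c(Low = "Low", low = "Low",
                     Medium = "Medium", medium = "Medium",
                     Middle = "Medium", middle = "Medium",
                     High = "High", high = "High")
VANTAGE_ALIASES <- c(front = "front", Front = "front",
                     back = "back", Back = "back")

#' Semantic label vocabulary
#'
#' The closed set of per-pixel semantic labels used throughout the package.
#' Unknown label names are rejected at parse time; an alias map argument on
#' the parsers allows user data with other spellings to be mapped onto this
#' vocabulary.
#'
#' @return Character vector of the 10 label names.
#' @export
#' @examples
#' label_vocabulary()
label_vocabulary <- function() SKY_LABELS

#' Canonical factor levels for scene metadata
#'
#' @param factor_name One of `"environment"`, `"horizon"`, `"vantage"`,
#'   `"weather"`, `"season"`.
#' @return Character vector of accepted canonical levels, in reference-level
#'   order (the first level is the modelling reference: Urban, Low, front,
#'   blue, spring_summer).
#' @export
factor_levels <- function(factor_name = c("environment", "horizon", "vantage",
                                          "weather", "season")) {
  switch(match.arg(factor_name),
         environment = ENV_LEVELS,
         horizon     = HORIZON_LEVELS,
         vantage     = VANTAGE_LEVELS,
         weather     = WEATHER_LEVELS,
         season      = SEASON_LEVELS)
}

# Map raw level names onto the canonical levels via an alias table;
# unknown values raise an error that lists what is accepted.
normalize_level <- function(x, aliases, what) {
  x <- as.character(x)
  out <- unname(aliases[x])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop(sprintf("unknown %s level(s): %s (accepted: %s)", what,
                 paste(bad, collapse = ", "),
                 paste(unique(names(aliases)), collapse = ", ")),
         call. = FALSE)
  }
  out
}

normalize_weather <- function(x) normalize_level(x, WEATHER_ALIASES, "weather")
normalize_season  <- function(x) normalize_level(x, SEASON_ALIASES, "season")
normalize_environment <- function(x) normalize_level(x, ENV_ALIASES, "environment")
normalize_horizon <- function(x) normalize_level(x, HORIZON_ALIASES, "horizon")
normalize_vantage <- function(x) normalize_level(x, VANTAGE_ALIASES, "vantage")
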