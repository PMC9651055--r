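#' Per-pixel semantic label mask
#'
#' A `label_mask` is an integer matrix (rows = image rows, columns = image
#' columns) whose entries index the closed label vocabulary
#' ([label_vocabulary()]).  Pixel coordinates are 0-based with the origin at
#' the top-left corner, x rightward and y downward; the pixel with index
#' `(ix, iy)` has its centre at `(ix + 0.5, iy + 0.5)`.
#'
#' @param codes Integer matrix of vocabulary indices (1..10), or a character
#'   matrix of label names.
#' @return An object of class `label_mask`.
#' @export
#' @examples
#' m <- label_mask(matrix("sky", 4, 6))
#' quantify_labels(m)
label_mask <- function(codes) {
  if (is.character(codes)) {
    idx <- match(codes, SKY_LABELS)
    if (anyNA(idx))
      stop("unknown label name(s): ",
           paste(unique(codes[is.na(idx)]), collapse = ", "), call. = FALSE)
    codes <- matrix(idx, nrow = nrow(codes), ncol = ncol(codes))
  }
  if (!is.matrix(codes) || !is.numeric(codes))
    stop("`codes` must be an integer or character matrix", call. = FALSE)
  if (anyNA(codes) || any(codes < 1L | codes > length(SKY_LABELS)) ||
      any(codes != round(codes)))
    stop("mask codes must index the label vocabulary (1..",
         length(SKY_LABELS), ")", call. = FALSE)
  storage.mode(codes) <- "integer"
  structure(codes, class = c("label_mask", "matrix"), labels = SKY_LABELS)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask %d x %d px>\n", ncol(x), nrow(x)))
  pct <- quantify_labels(x)
  pct <- pct[pct > 0]
  cat(paste(sprintf("  %s: %.1f%%", names(pct), pct), collapse = "\n"), "\n")
  invisible(x)
}

mask_width  <- function(mask) ncol(mask)
mask_height <- function(mask) nrow(mask)

#' Quantify the surface of each semantic label
#'
#' Converts a label mask into the scene's semantic vector: the percentage of
#' the image surface covered by each label.  All vocabulary labels are
#' reported (0 when absent) and the denominator is the total pixel count,
#' background included, so the percentages always sum to 100.
#'
#' @param mask A [label_mask()].
#' @return Named numeric vector of percentages, one entry per vocabulary
#'   label, summing to 100.
#' @export
quantify_labels <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  counts <- tabulate(mask, nbins = length(SKY_LABELS))
  setNames(100 * counts / length(mask), SKY_LABELS)
}

#' Derive the scene covariates from label percentages
#'
#' Computes the three composite covariates used in the analysis:
#' * `pct_sky` — the sky percentage itself;
#' * `pct_greenery` — grass + trees + vegetation, exactly;
#' * `pct_nature` — the summed percentage of the configured natural-label
#'   set.  By default every label except `manmade` and `background` counts
#'   as nature; whether sky itself is included is a flag, since "natural"
#'   label sets differ between studies.
#'
#' @param label_pct Named percentage vector as returned by
#'   [quantify_labels()].
#' @param nature_labels Labels counted as nature before the sky flag is
#'   applied.
#' @param include_sky Should sky count towards `pct_nature`?
#' @return Named list with `pct_sky`, `pct_greenery`, `pct_nature`.
#' @export
#' @examples
#' pct <- setNames(numeric(10), label_vocabulary())
#' pct[c("grass", "trees", "vegetation")] <- c(10, 20, 5)
#' pct["background"] <- 65
#' derive_covariates(pct)$pct_greenery  # 35
derive_covariates <- function(label_pct,
                              nature_labels = setdiff(SKY_LABELS,
                                                      c("manmade", "background")),
                              include_sky = TRUE) {
  stopifnot(all(nature_labels %in% SKY_LABELS))
  label_pct <- label_pct[SKY_LABELS]
  label_pct[is.na(label_pct)] <- 0
  names(label_pct) <- SKY_LABELS
  if (!include_sky) nature_labels <- setdiff(nature_labels, "sky")
  list(pct_sky = unname(label_pct["sky"]),
       pct_greenery = unname(sum(label_pct[GREENERY_LABELS])),
       pct_nature = unname(sum(label_pct[nature_labels])))
}

#' Assemble a scene record
#'
#' Joins normalized design factors and annotations to the quantified label
#' percentages of one scene, producing the one-row data frame used by the
#' catalog, the QC rules and the models.
#'
#' @param image_id Scene identifier.
#' @param environment,horizon,vantage,weather,season Factor levels; raw
#'   spellings are normalized (e.g. weather `"clear"` is stored as `"blue"`,
#'   season `"spring"` as `"spring_summer"`).
#' @param label_pct Named percentage vector from [quantify_labels()].
#' @param include_sky Passed to [derive_covariates()].
#' @return One-row data frame with factor columns, `pct_<label>` columns and
#'   the derived covariates `pct_greenery`, `pct_nature` (`pct_sky` is the
#'   sky label column).
#' @export
scene_record <- function(image_id, environment, horizon, vantage,
                         weather, season, label_pct, include_sky = TRUE) {
  cov <- derive_covariates(label_pct, include_sky = include_sky)
  pct <- as.list(setNames(as.numeric(label_pct[SKY_LABELS]),
                          paste0("pct_", SKY_LABELS)))
  out <- data.frame(image_id = as.character(image_id),
                    environment = normalize_environment(environment),
                    horizon = normalize_horizon(horizon),
                    vantage = normalize_vantage(vantage),
                    weather = normalize_weather(weather),
                    season = normalize_season(season),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pct),
        data.frame(pct_greenery = cov$pct_greenery,
                   pct_nature = cov$pct_nature))
}

#' Join quantified percentages to a scene metadata row
#'
#' Catalog-building step: takes the label percentages of a rasterized mask
#' and the image's metadata (environment, horizon, vantage, weather, season)
#' and returns the normalized [scene_record()].  Unknown factor levels raise
#' an error listing the accepted levels.
#'
#' @param image_id Scene identifier.
#' @param metadata_row Named list or one-row data frame supplying
#'   `environment`, `horizon`, `vantage`, `weather`, `season`.
#' @param label_pct Named percentage vector from [quantify_labels()].
#' @param ... Passed on to [scene_record()].
#' @return One-row scene record data frame.
#' @export
annotate_factors <- function(image_id, metadata_row, label_pct, ...) {
  need <- c("environment", "horizon", "vantage", "weather", "season")
  missing <- setdiff(need, names(metadata_row))
  if (length(missing))
    stop("metadata row lacks: ", paste(missing, collapse = ", "), call. = FALSE)
  scene_record(image_id,
               environment = metadata_row[["environment"]],
               horizon = metadata_row[["horizon"]],
               vantage = metadata_row[["vantage"]],
               weather = metadata_row[["weather"]],
               season = metadata_row[["season"]],
               label_pct = label_pct, ...)
}

#' Read and write a scene catalog as tab-separated text
#'
#' @param catalog Data frame of scene records.
#' @param path File path.
#' @return `read_catalog()` returns the catalog data frame;
#'   `write_catalog()` returns `path` invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
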