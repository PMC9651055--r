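# Data-quality rules applied to the CBSV table, in a fixed documented
# order: click-count outliers, flagged images, then the sky-score filter.
# Rules only remove rows, never modify them, so the pipeline is idempotent
# and its report conserves counts.

new_qc_report <- function(n_in, n_out, removed_click_outliers = 0L,
                          removed_images = character(),
                          removed_image_rows = 0L,
                          removed_sky_over100 = 0L, removed_sky_zero = 0L,
                          log = NULL) {
  log <- log %||% data.frame(rule = character(), participant_id = character(),
                             image_id = character(), detail = character(),
                             stringsAsFactors = FALSE)
  structure(list(n_rows_in = as.integer(n_in), n_rows_out = as.integer(n_out),
                 removed_click_outliers = as.integer(removed_click_outliers),
                 removed_images = removed_images,
                 removed_image_rows = as.integer(removed_image_rows),
                 removed_sky_over100 = as.integer(removed_sky_over100),
                 removed_sky_zero = as.integer(removed_sky_zero),
                 log = log),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  rows in / out:        %d / %d\n", x$n_rows_in, x$n_rows_out))
  cat(sprintf("  click-count outliers: %d\n", x$removed_click_outliers))
  cat(sprintf("  flagged-image rows:   %d (%d image(s))\n",
              x$removed_image_rows, length(x$removed_images)))
  cat(sprintf("  sky score > 100:      %d\n", x$removed_sky_over100))
  cat(sprintf("  sky absolute zeros:   %d\n", x$removed_sky_zero))
  invisible(x)
}

qc_log_rows <- function(rule, tab, detail) {
  if (nrow(tab) == 0)
    return(data.frame(rule = character(), participant_id = character(),
                      image_id = character(), detail = character(),
                      stringsAsFactors = FALSE))
  data.frame(rule = rule,
             participant_id = as.character(tab$participant_id),
             image_id = as.character(tab$image_id),
             detail = detail, stringsAsFactors = FALSE)
}

#' Remove click-count outliers
#'
#' Rows whose click count exceeds `max_clicks` are removed; rows exactly at
#' the cap are retained ("above 20" is read strictly).
#'
#' @param cbsv Data frame with an `n_clicks` column (see [build_cbsv()]).
#' @param max_clicks Cap on clicks per trial (default 20).
#' @return List with the filtered `table` and a `report` (`qc_report`).
#' @export
filter_click_outliers <- function(cbsv, max_clicks = 20) {
  stopifnot("n_clicks" %in% names(cbsv))
  drop <- cbsv$n_clicks > max_clicks
  list(table = cbsv[!drop, , drop = FALSE],
       report = new_qc_report(nrow(cbsv), sum(!drop),
                              removed_click_outliers = sum(drop),
                              log = qc_log_rows("click_outlier", cbsv[drop, ],
                                                sprintf("n_clicks=%d",
                                                        cbsv$n_clicks[drop]))))
}

#' Remove rows of flagged images
#'
#' Image-level anomalies (e.g. serial clicking concentrated on particular
#' stimuli) are supplied as an explicit id list by configuration; all rows
#' of flagged images are removed.  Ids not present in the table produce a
#' warning, not an error.
#'
#' @param cbsv CBSV data frame.
#' @param flagged_image_ids Character vector of image ids to drop.
#' @return List with `table` and `report`.
#' @export
drop_flagged_images <- function(cbsv, flagged_image_ids = character()) {
  unknown <- setdiff(flagged_image_ids, unique(cbsv$image_id))
  if (length(unknown))
    warning("flagged image id(s) not present in the table: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  drop <- cbsv$image_id %in% flagged_image_ids
  list(table = cbsv[!drop, , drop = FALSE],
       report = new_qc_report(nrow(cbsv), sum(!drop),
                              removed_images = intersect(flagged_image_ids,
                                                         unique(cbsv$image_id)),
                              removed_image_rows = sum(drop),
                              log = qc_log_rows("flagged_image", cbsv[drop, ],
                                                "image flagged")))
}

#' Filter the sky selection scores
#'
#' For the sky analysis stream only: rows with a sky EDB score strictly
#' above 100 (overlapping serial clicking) and rows with an absolute-zero
#' sky score are removed.  Each removed zero is logged with its rationale —
#' `absent_sky` when the scene's sky coverage is below `min_sky_pct`
#' (absence or very minimal presence of sky), `true_zero_selection`
#' otherwise.  Scores of every other label are untouched; the zero rule is
#' applied to no other stream.
#'
#' @param cbsv CBSV data frame with an `edb_sky` column.
#' @param catalog Optional scene catalog with `image_id` and `pct_sky`,
#'   used only to attribute the zero-removal rationale.
#' @param min_sky_pct Sky-coverage threshold (percent) below which a zero is
#'   attributed to absence of sky (default 2).
#' @return List with `table` and `report`.
#' @export
filter_sky_scores <- function(cbsv, catalog = NULL, min_sky_pct = 2) {
  stopifnot("edb_sky" %in% names(cbsv))
  over <- cbsv$edb_sky > 100
  zero <- cbsv$edb_sky == 0
  reason <- rep("true_zero_selection", nrow(cbsv))
  if (!is.null(catalog) && all(c("image_id", "pct_sky") %in% names(catalog))) {
    pct <- catalog$pct_sky[match(cbsv$image_id, catalog$image_id)]
    reason[!is.na(pct) & pct < min_sky_pct] <- "absent_sky"
  }
  keep <- !(over | zero)
  log <- rbind(qc_log_rows("sky_over_100", cbsv[over, ],
                           sprintf("edb_sky=%.2f", cbsv$edb_sky[over])),
               qc_log_rows("sky_zero", cbsv[zero, ], reason[zero]))
  list(table = cbsv[keep, , drop = FALSE],
       report = new_qc_report(nrow(cbsv), sum(keep),
                              removed_sky_over100 = sum(over),
                              removed_sky_zero = sum(zero), log = log))
}

#' Full QC pipeline
#'
#' Applies the three rules in documented order — click-count outliers,
#' flagged images, sky-score filter — and returns the analysis-ready table
#' with a consolidated report.  A row violating several rules is counted
#' once, under the first rule that removes it.
#'
#' @param cbsv CBSV data frame.
#' @param catalog Optional scene catalog (for the zero-removal rationale).
#' @param config List with optional entries `max_clicks` (default 20),
#'   `flagged_images` (default none) and `min_sky_pct` (default 2).
#' @return List with `table` and `report`.
#' @export
#' @examples
#' tab <- data.frame(participant_id = "p1", image_id = paste0("i", 1:3),
#'                   n_clicks = c(2, 25, 3),
#'                   edb_sky = c(40, 50, 120))
#' qc_pipeline(tab)$report
qc_pipeline <- function(cbsv, catalog = NULL, config = list()) {
  max_clicks <- config$max_clicks %||% 20
  flagged <- config$flagged_images %||% character()
  min_sky <- config$min_sky_pct %||% 2
  s1 <- filter_click_outliers(cbsv, max_clicks)
  s2 <- drop_flagged_images(s1$table, flagged)
  s3 <- filter_sky_scores(s2$table, catalog, min_sky)
  report <- new_qc_report(
    nrow(cbsv), nrow(s3$table),
    removed_click_outliers = s1$report$removed_click_outliers,
    removed_images = s2$report$removed_images,
    removed_image_rows = s2$report$removed_image_rows,
    removed_sky_over100 = s3$report$removed_sky_over100,
    removed_sky_zero = s3$report$removed_sky_zero,
    log = rbind(s1$report$log, s2$report$log, s3$report$log))
  stopifnot(report$n_rows_out ==
              report$n_rows_in - report$removed_click_outliers -
              report$removed_image_rows - report$removed_sky_over100 -
              report$removed_sky_zero)
  list(table = s3$table, report = report)
}
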