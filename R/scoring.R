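# Click-based selection scoring: disc geometry, per-click label counts,
# the EDB score and the content-based semantic vector (CBSV).
#
# The EDB score of label x over the clicks of one (participant, image)
# presentation is
#
#     Score_EDB_x = sum_n (D_x(n) / B_x) * 100
#
# where D_x(n) is the number of pixels of label x inside click n's disc and
# B_x the number of pixels of label x in the whole image.  Clicks are summed
# without pixel de-duplication, so overlapping discs can push a score above
# 100 — which is exactly the behaviour the downstream QC rule screens for.

#' Boolean disc mask for one click
#'
#' Pixel `(ix, iy)` belongs to the disc iff the Euclidean distance from its
#' centre `(ix + 0.5, iy + 0.5)` to the click centre is at most `radius`.
#' Discs are clipped at the image edges.
#'
#' @param centre Numeric length-2 vector `(x, y)` in pixel coordinates; must
#'   lie within `[0, width] x [0, height]`.
#' @param radius Disc radius in pixels (> 0; the experimental selection
#'   circle is 150 px).
#' @param width,height Image dimensions in pixels.
#' @return Logical `height` x `width` matrix.
#' @export
#' @examples
#' sum(disc_mask(c(10, 10), 5, 20, 20))
disc_mask <- function(centre, radius, width, height) {
  cx <- centre[[1]]; cy <- centre[[2]]
  if (is.na(cx) || is.na(cy) || cx < 0 || cx > width || cy < 0 || cy > height)
    stop(sprintf("click centre (%.1f, %.1f) lies outside [0,%d] x [0,%d]",
                 cx, cy, width, height), call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  dx2 <- ((seq_len(width) - 0.5) - cx)^2
  dy2 <- ((seq_len(height) - 0.5) - cy)^2
  outer(dy2, dx2, `+`) <= radius^2
}

#' Per-label pixel counts for one click
#'
#' For every vocabulary label x, counts `D_x` (pixels of x inside the
#' click's disc) and `B_x` (pixels of x in the whole image).
#'
#' @param click List or one-row data frame with `x`, `y` and `radius`.
#' @param mask A [label_mask()] of the clicked image.
#' @return Data frame with columns `label`, `D`, `B`; `0 <= D <= B` always.
#' @export
score_click <- function(click, mask) {
  stopifnot(inherits(mask, "label_mask"))
  disc <- disc_mask(c(click$x, click$y), click$radius %||% 150,
                    mask_width(mask), mask_height(mask))
  data.frame(label = SKY_LABELS,
             D = tabulate(mask[disc], nbins = length(SKY_LABELS)),
             B = tabulate(mask, nbins = length(SKY_LABELS)),
             stringsAsFactors = FALSE)
}

#' EDB selection score per label
#'
#' Sums `D_x / B_x * 100` over all clicks of one presentation.  A label
#' absent from the image (`B_x = 0`) scores 0 and is flagged in the
#' `"absent"` attribute so that a true zero-selection remains
#' distinguishable from structural absence downstream.
#'
#' @param clicks Data frame with columns `x`, `y` and optionally `radius`
#'   (default 150), one row per click; zero rows mean no selection.
#' @param mask A [label_mask()].
#' @param radius Default radius for clicks lacking a `radius` column.
#' @return Named numeric vector of scores over the vocabulary, with a
#'   logical `"absent"` attribute marking labels with `B_x = 0`.
#' @export
edb_score <- function(clicks, mask, radius = 150) {
  stopifnot(inherits(mask, "label_mask"))
  B <- tabulate(mask, nbins = length(SKY_LABELS))
  score <- numeric(length(SKY_LABELS))
  if (!is.null(clicks) && nrow(clicks) > 0) {
    r <- clicks$radius %||% rep(radius, nrow(clicks))
    for (i in seq_len(nrow(clicks))) {
      disc <- disc_mask(c(clicks$x[i], clicks$y[i]), r[i],
                        mask_width(mask), mask_height(mask))
      D <- tabulate(mask[disc], nbins = length(SKY_LABELS))
      score <- score + ifelse(B > 0, D / pmax(B, 1L) * 100, 0)
    }
  }
  structure(setNames(score, SKY_LABELS),
            absent = setNames(B == 0L, SKY_LABELS))
}

#' Build the content-based semantic vector (CBSV) table
#'
#' One row per (participant, image) presentation, holding the EDB score of
#' every vocabulary label (`edb_<label>`), the click count, and presence
#' flags (`present_<label>`, i.e. `B_x > 0`).  Rows are ordered by
#' participant then image.  Trials referencing an image with no mask raise
#' an error listing the missing ids.
#'
#' @param trials List of trial records (as produced by [simulate_trial()] /
#'   [generate_dataset()]: each a list with `participant_id`, `image_id` and
#'   a `clicks` data frame), or a [generate_dataset()] bundle.
#' @param masks Named list of [label_mask()] objects keyed by `image_id`;
#'   taken from the bundle when `trials` is one.
#' @return Data frame of CBSV rows.
#' @export
build_cbsv <- function(trials, masks = NULL) {
  if (inherits(trials, "simulation_bundle")) {
    masks <- masks %||% trials$scenes$masks
    trials <- trials$trials
  }
  edb_cols <- paste0("edb_", SKY_LABELS)
  pres_cols <- paste0("present_", SKY_LABELS)
  if (length(trials) == 0) {
    out <- data.frame(participant_id = character(), image_id = character(),
                      n_clicks = integer())
    for (cc in edb_cols) out[[cc]] <- numeric(0)
    for (cc in pres_cols) out[[cc]] <- logical(0)
    return(out)
  }
  ids <- vapply(trials, function(t) t$image_id, "")
  orphans <- setdiff(unique(ids), names(masks))
  if (length(orphans))
    stop("trials reference images missing from the catalog: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  rows <- lapply(trials, function(t) {
    sc <- edb_score(t$clicks, masks[[t$image_id]])
    row <- data.frame(participant_id = t$participant_id,
                      image_id = t$image_id,
                      n_clicks = if (is.null(t$clicks)) 0L else nrow(t$clicks),
                      stringsAsFactors = FALSE)
    row[edb_cols] <- as.list(unname(sc))
    row[pres_cols] <- as.list(!attr(sc, "absent"))
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$image_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
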