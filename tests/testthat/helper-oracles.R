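# Independent oracles and small fixture builders.  Each oracle is coded
# from the defining formula or by exhaustive enumeration, on a different
# code path from the implementation it checks.

vocab <- skyselect::label_vocabulary()

# Classic even-odd ray-cast, one pixel at a time (Franklin's crossing loop).
oracle_point_in_poly <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

# Per-pixel rasterization of a single polygon: logical height x width.
oracle_rasterize <- function(pts, width, height) {
  out <- matrix(FALSE, height, width)
  for (iy in seq_len(height)) {
    for (ix in seq_len(width)) {
      out[iy, ix] <- oracle_point_in_poly(ix - 0.5, iy - 0.5,
                                          pts[, 1], pts[, 2])
    }
  }
  out
}

# Exhaustive per-pixel disc membership via a flat distance enumeration.
oracle_disc <- function(centre, radius, width, height) {
  grid <- expand.grid(x = seq_len(width) - 0.5, y = seq_len(height) - 0.5)
  ok <- (grid$x - centre[1])^2 + (grid$y - centre[2])^2 <= radius^2
  matrix(ok, nrow = height, byrow = TRUE)
}

# Brute-force EDB: enumerate every pixel of every disc, sum D/B * 100.
oracle_edb <- function(clicks, mask) {
  w <- ncol(mask); h <- nrow(mask)
  B <- sapply(seq_along(vocab), function(code) sum(mask == code))
  score <- numeric(length(vocab))
  for (i in seq_len(nrow(clicks))) {
    grid <- expand.grid(ix = seq_len(w), iy = seq_len(h))
    d2 <- (grid$ix - 0.5 - clicks$x[i])^2 + (grid$iy - 0.5 - clicks$y[i])^2
    inside <- grid[d2 <= clicks$radius[i]^2, , drop = FALSE]
    if (nrow(inside) == 0) next
    labs <- mask[cbind(inside$iy, inside$ix)]
    D <- sapply(seq_along(vocab), function(code) sum(labs == code))
    score <- score + ifelse(B > 0, D / pmax(B, 1) * 100, 0)
  }
  setNames(score, vocab)
}

# Star-shaped random polygon (vertices sorted by angle -> simple polygon).
random_polygon <- function(n_vertices, width, height) {
  cx <- runif(1, width * 0.25, width * 0.75)
  cy <- runif(1, height * 0.25, height * 0.75)
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 2, min(width, height) / 2)
  pts <- cbind(pmin(pmax(cx + rad * cos(ang), 0), width),
               pmin(pmax(cy + rad * sin(ang), 0), height))
  pts
}

random_mask <- function(width, height, n_labels = length(vocab)) {
  skyselect::label_mask(matrix(sample.int(n_labels, width * height,
                                          replace = TRUE),
                               nrow = height, ncol = width))
}

# Mask that is all background except explicit label patches.
patch_mask <- function(width, height, patches = list()) {
  m <- matrix("background", height, width)
  for (p in patches) m[p$rows, p$cols] <- p$label
  skyselect::label_mask(m)
}

# A LabelMe JSON string with the given shapes.
labelme_json <- function(shapes, width = 64, height = 64) {
  doc <- list(imageWidth = width, imageHeight = height,
              shapes = lapply(shapes, function(sh) {
                list(label = sh$label, shape_type = "polygon",
                     points = lapply(seq_len(nrow(sh$points)),
                                     function(i) as.numeric(sh$points[i, ])))
              }))
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
}

# Minimal trial record for scoring tests.
make_trial <- function(participant_id, image_id, clicks) {
  list(participant_id = participant_id, image_id = image_id, clicks = clicks)
}

# Ten-row CBSV-style toy table: 2 click-count outliers, 1 sky score > 100,
# 1 sky absolute zero, 6 clean rows.
toy_cbsv <- function() {
  data.frame(
    participant_id = rep(c("p1", "p2"), each = 5),
    image_id = rep(paste0("img", 1:5), 2),
    n_clicks = c(3, 21, 5, 2, 4, 25, 1, 6, 2, 3),
    edb_sky = c(40, 50, 104, 0, 30, 20, 60, 15, 75, 10),
    edb_trees = runif(10, 0, 80),
    stringsAsFactors = FALSE)
}
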