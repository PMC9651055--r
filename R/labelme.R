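# LabelMe-style polygon annotations: parsing, validation and rasterization.
#
# Geometry conventions (fixed package-wide): 0-based pixel indices, origin
# top-left, x rightward, y downward; a pixel belongs to a polygon iff its
# centre (ix + 0.5, iy + 0.5) is inside under the even-odd rule; overlapping
# shapes are painted in file order (later shapes win).

#' Construct a polygon annotation
#'
#' @param image_id Identifier of the annotated image.
#' @param shapes List of shapes, each a list with `label` (a vocabulary name)
#'   and `points` (an n x 2 numeric matrix of x, y vertices in pixel
#'   coordinates, n >= 3).
#' @param width,height Image dimensions in pixels.
#' @return Object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(image_id, shapes, width, height) {
  width <- as_count(width, "width"); height <- as_count(height, "height")
  for (k in seq_along(shapes)) {
    sh <- shapes[[k]]
    if (is.null(sh$label) || !sh$label %in% SKY_LABELS)
      stop(sprintf("shape %d: label '%s' is not in the vocabulary", k,
                   sh$label %||% "<missing>"), call. = FALSE)
    pts <- sh$points
    if (!is.matrix(pts) || ncol(pts) != 2 || nrow(pts) < 3)
      stop(sprintf("shape %d ('%s'): a closed polygon needs >= 3 vertices",
                   k, sh$label), call. = FALSE)
    if (anyNA(pts) || any(pts[, 1] < 0 | pts[, 1] > width |
                          pts[, 2] < 0 | pts[, 2] > height))
      stop(sprintf("shape %d ('%s'): vertices must lie within [0,%d] x [0,%d]",
                   k, sh$label, width, height), call. = FALSE)
    shapes[[k]] <- list(label = sh$label, points = unname(pts))
  }
  structure(list(image_id = as.character(image_id), shapes = shapes,
                 width = width, height = height),
            class = "polygon_annotation")
}

#' @export
print.polygon_annotation <- function(x, ...) {
  cat(sprintf("<polygon_annotation '%s' %d x %d px, %d shape(s)>\n",
              x$image_id, x$width, x$height, length(x$shapes)))
  invisible(x)
}

#' Parse a LabelMe JSON document
#'
#' Reads the LabelMe dialect (`shapes: [{label, points: [[x, y], ...]}]`,
#' `imageWidth`, `imageHeight`).  Shapes are retained in file order; labels
#' are normalized to the closed vocabulary through `aliases`.  Missing
#' dimensions, non-polygon shape types, open polygons (< 3 vertices) or
#' unmappable labels raise a parse error naming the offending shape.
#'
#' @param x Path to a `.json` file, or a JSON string.
#' @param image_id Identifier for the annotation; defaults to the file name
#'   without extension (or `"scene"` for inline JSON).
#' @param aliases Named character vector mapping raw label names to
#'   vocabulary names, applied before vocabulary validation.  Vocabulary
#'   names always map to themselves.
#' @return A [polygon_annotation()].
#' @export
parse_labelme <- function(x, image_id = NULL, aliases = character()) {
  if (length(x) == 1 && !grepl("[{]", x) && file.exists(x)) {
    if (is.null(image_id)) image_id <- sub("\\.[^.]*$", "", basename(x))
    txt <- paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    txt <- paste(x, collapse = "\n")
    image_id <- image_id %||% "scene"
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (is.null(doc$imageWidth) || is.null(doc$imageHeight))
    stop("LabelMe document lacks imageWidth/imageHeight", call. = FALSE)
  amap <- c(setNames(SKY_LABELS, SKY_LABELS), aliases)
  shapes <- lapply(seq_along(doc$shapes), function(k) {
    sh <- doc$shapes[[k]]
    if (!is.null(sh$shape_type) && !identical(sh$shape_type, "polygon"))
      stop(sprintf("shape %d: shape_type '%s' is not a closed polygon",
                   k, sh$shape_type), call. = FALSE)
    lab <- unname(amap[sh$label %||% ""])[1]
    if (is.na(lab))
      stop(sprintf("shape %d: label '%s' cannot be mapped to the vocabulary",
                   k, sh$label %||% "<missing>"), call. = FALSE)
    pts <- sh$points
    if (is.null(pts) || length(pts) < 3)
      stop(sprintf("shape %d ('%s'): open polygon (fewer than 3 vertices)",
                   k, lab), call. = FALSE)
    list(label = lab,
         points = do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2]))))
  })
  polygon_annotation(image_id, shapes,
                     width = doc$imageWidth, height = doc$imageHeight)
}

#' Serialize a polygon annotation back to LabelMe JSON
#'
#' @param annotation A [polygon_annotation()].
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_labelme <- function(annotation, path = NULL) {
  stopifnot(inherits(annotation, "polygon_annotation"))
  doc <- list(
    imageWidth = annotation$width,
    imageHeight = annotation$height,
    shapes = lapply(annotation$shapes, function(sh) {
      list(label = sh$label, shape_type = "polygon",
           points = lapply(seq_len(nrow(sh$points)),
                           function(i) as.numeric(sh$points[i, ])))
    }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# Linear indices (into a height x width matrix) of pixels whose centre lies
# inside the polygon under the even-odd rule.  Scanline fill: for each pixel
# row, horizontal crossings are collected with a half-open vertex rule and a
# pixel centre is inside iff the number of crossings left of it is odd.
polygon_pixels <- function(pts, width, height) {
  xs <- pts[, 1]; ys <- pts[, 2]
  n <- length(xs)
  x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
  xc <- seq_len(width) - 0.5
  out <- vector("list", height)
  ymin <- max(1L, floor(min(ys) + 0.5) + 1L)
  ymax <- min(height, ceiling(max(ys) + 0.5))
  for (iy in seq.int(ymin, length.out = max(0L, ymax - ymin + 1L))) {
    ycen <- iy - 0.5
    cr <- (ys <= ycen) != (y2 <= ycen)
    if (!any(cr)) next
    xint <- sort(xs[cr] + (ycen - ys[cr]) * (x2[cr] - xs[cr]) / (y2[cr] - ys[cr]))
    inside <- (findInterval(xc, xint) %% 2L) == 1L
    if (any(inside))
      out[[iy]] <- iy + (which(inside) - 1L) * height
  }
  unlist(out) %||% integer(0)
}

#' Rasterize a polygon annotation into a label mask
#'
#' Pixels covered by later shapes overwrite earlier ones (painter's order);
#' pixels covered by no shape are `background`.  A pixel is covered iff its
#' centre `(ix + 0.5, iy + 0.5)` lies inside the polygon under the even-odd
#' rule.
#'
#' @param annotation A [polygon_annotation()].
#' @return A [label_mask()] of the annotated image's dimensions.
#' @export
rasterize <- function(annotation) {
  stopifnot(inherits(annotation, "polygon_annotation"))
  h <- annotation$height; w <- annotation$width
  codes <- matrix(match("background", SKY_LABELS), nrow = h, ncol = w)
  for (sh in annotation$shapes)
    codes[polygon_pixels(sh$points, w, h)] <- match(sh$label, SKY_LABELS)
  label_mask(codes)
}

#' Read and write indexed raster label masks
#'
#' Masks are stored as single-channel grayscale PNGs whose pixel value is
#' `palette_index / 255`, with a sidecar legend mapping label names to
#' palette indices.  Indices present in the image but absent from the legend
#' are a parse error.
#'
#' @param path PNG file path.
#' @param legend Named integer vector `label -> palette index`, or a path to
#'   a JSON file containing that mapping.
#' @return `read_label_mask_png()` returns a [label_mask()];
#'   `write_label_mask_png()` returns `path` invisibly.
#' @export
read_label_mask_png <- function(path, legend) {
  if (is.character(legend) && length(legend) == 1 && file.exists(legend))
    legend <- unlist(jsonlite::fromJSON(legend))
  if (is.null(names(legend)) || !all(names(legend) %in% SKY_LABELS))
    stop("legend must map vocabulary label names to palette indices",
         call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  idx <- round(img * 255)
  back <- match(names(legend), SKY_LABELS)
  codes <- matrix(back[match(idx, legend)], nrow = nrow(idx))
  if (anyNA(codes))
    stop("mask contains palette indices missing from the legend: ",
         paste(setdiff(unique(as.vector(idx)), legend), collapse = ", "),
         call. = FALSE)
  label_mask(codes)
}

#' @rdname read_label_mask_png
#' @param mask A [label_mask()] to write.
#' @export
write_label_mask_png <- function(mask, path,
                                 legend = setNames(seq_along(SKY_LABELS),
                                                   SKY_LABELS)) {
  stopifnot(inherits(mask, "label_mask"))
  idx <- matrix(legend[SKY_LABELS[mask]], nrow = nrow(mask))
  png::writePNG(idx / 255, path)
  invisible(path)
}
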