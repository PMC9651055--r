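test_that("parse_labelme keeps shapes in order and normalizes labels", {
  sq <- function(x0, y0, x1, y1)
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  js <- labelme_json(list(list(label = "sky", points = sq(0, 0, 64, 32)),
                          list(label = "trees", points = sq(0, 32, 32, 64)),
                          list(label = "grass", points = sq(32, 32, 64, 64))))
  ann <- parse_labelme(js)
  expect_s3_class(ann, "polygon_annotation")
  expect_length(ann$shapes, 3)
  expect_equal(vapply(ann$shapes, `[[`, "", "label"),
               c("sky", "trees", "grass"))

  # alias mapping onto the closed vocabulary
  js2 <- labelme_json(list(list(label = "building", points = sq(0, 0, 10, 10))))
  expect_error(parse_labelme(js2), "cannot be mapped")
  ann2 <- parse_labelme(js2, aliases = c(building = "manmade"))
  expect_equal(ann2$shapes[[1]]$label, "manmade")

  # zero shapes rasterizes to all background
  empty <- parse_labelme(labelme_json(list(), 8, 8))
  pct <- quantify_labels(rasterize(empty))
  expect_equal(unname(pct["background"]), 100)
})

test_that("malformed LabelMe documents raise parse errors naming the shape", {
  expect_error(parse_labelme('{"shapes": []}'), "imageWidth")
  open_poly <- labelme_json(list(list(label = "sky",
                                      points = cbind(c(0, 5), c(0, 5)))))
  expect_error(parse_labelme(open_poly), "shape 1.*open polygon")
  js <- '{"imageWidth": 8, "imageHeight": 8,
          "shapes": [{"label": "sky", "shape_type": "line",
                      "points": [[0,0],[5,5],[3,1]]}]}'
  expect_error(parse_labelme(js), "shape 1.*line")
})

test_that("rasterization follows painter's order and covers the canvas", {
  full <- cbind(c(0, 16, 16, 0), c(0, 0, 16, 16))
  ann <- polygon_annotation("a", list(list(label = "water", points = full)),
                            16, 16)
  expect_true(all(rasterize(ann) == match("water", vocab)))

  # overlap: the later shape wins on the shared pixels
  left <- cbind(c(0, 10, 10, 0), c(0, 0, 16, 16))
  right <- cbind(c(6, 16, 16, 6), c(0, 0, 16, 16))
  ann2 <- polygon_annotation("b", list(list(label = "grass", points = left),
                                       list(label = "snow", points = right)),
                             16, 16)
  m <- rasterize(ann2)
  expect_true(all(m[, 7:10] == match("snow", vocab)))
  expect_true(all(m[, 1:6] == match("grass", vocab)))
})

test_that("rasterization matches the per-pixel point-in-polygon oracle", {
  set.seed(42)
  for (i in 1:25) {
    pts <- random_polygon(sample(3:9, 1), 64, 64)
    ann <- polygon_annotation("x", list(list(label = "sky", points = pts)),
                              64, 64)
    got <- rasterize(ann) == match("sky", vocab)
    expect_identical(unname(got), oracle_rasterize(pts, 64, 64),
                     label = sprintf("polygon %d", i))
  }
})

test_that("quantify_labels counts surface percentages exactly", {
  allsky <- label_mask(matrix("sky", 10, 10))
  pct <- quantify_labels(allsky)
  expect_equal(unname(pct["sky"]), 100)
  expect_equal(sum(pct), 100)

  # half of a 1500 x 750 canvas is exactly 562,500 sky pixels -> 50%
  codes <- matrix(match("manmade", vocab), 750, 1500)
  codes[1:375, ] <- match("sky", vocab)
  expect_equal(unname(quantify_labels(label_mask(codes))["sky"]), 50)

  # random mask agrees with an independent per-pixel tally
  set.seed(7)
  m <- random_mask(37, 23)
  tally <- sapply(seq_along(vocab), function(code) sum(m == code))
  expect_equal(unname(quantify_labels(m)), 100 * tally / (37 * 23))
})

test_that("label percentages are conserved and permutation-invariant", {
  set.seed(11)
  for (i in 1:20) {
    m <- random_mask(sample(5:40, 1), sample(5:40, 1), sample(2:10, 1))
    expect_equal(sum(quantify_labels(m)), 100, tolerance = 1e-12)
    shuffled <- label_mask(matrix(sample(as.vector(unclass(m))),
                                  nrow = nrow(m)))
    expect_equal(quantify_labels(shuffled), quantify_labels(m))
  }
})

test_that("derived covariates follow the printed composites", {
  pct <- setNames(numeric(length(vocab)), vocab)
  pct[c("grass", "trees", "vegetation")] <- c(10, 20, 5)
  pct["background"] <- 65
  cov <- derive_covariates(pct)
  expect_equal(cov$pct_greenery, 35)
  expect_equal(cov$pct_sky, 0)

  manmade <- setNames(numeric(length(vocab)), vocab)
  manmade["manmade"] <- 100
  expect_equal(derive_covariates(manmade)$pct_nature, 0)

  empty <- setNames(numeric(length(vocab)), vocab)
  empty["background"] <- 100
  cov0 <- derive_covariates(empty)
  expect_equal(unlist(cov0, use.names = FALSE), c(0, 0, 0))

  # sky counts toward nature by default; the flag removes it
  sky <- setNames(numeric(length(vocab)), vocab)
  sky["sky"] <- 40; sky["manmade"] <- 60
  expect_equal(derive_covariates(sky)$pct_nature, 40)
  expect_equal(derive_covariates(sky, include_sky = FALSE)$pct_nature, 0)
})

test_that("annotate_factors normalizes metadata levels", {
  pct <- quantify_labels(label_mask(matrix("sky", 4, 4)))
  meta <- list(environment = "Some Urban", horizon = "Low", vantage = "front",
               weather = "clear", season = "spring")
  rec <- annotate_factors("img1", meta, pct)
  expect_equal(rec$weather, "blue")
  expect_equal(rec$season, "spring_summer")
  expect_equal(rec$horizon, "Low")
  expect_equal(rec$environment, "SomeUrban")
  expect_equal(rec$pct_sky, 100)

  meta$weather <- "sunny"
  expect_error(annotate_factors("img1", meta, pct), "accepted")
  expect_error(annotate_factors("img1", meta[-1], pct), "lacks")
})

test_that("annotation survives a JSON re-serialization round trip", {
  set.seed(3)
  shapes <- lapply(c("sky", "trees", "manmade"), function(lab)
    list(label = lab, points = random_polygon(6, 32, 32)))
  ann <- polygon_annotation("rt", shapes, 32, 32)
  reparsed <- parse_labelme(write_labelme(ann), image_id = "rt")
  expect_identical(rasterize(reparsed), rasterize(ann))
  reparsed2 <- parse_labelme(write_labelme(reparsed), image_id = "rt")
  expect_identical(rasterize(reparsed2), rasterize(ann))
})

test_that("indexed PNG masks round-trip through the legend", {
  set.seed(5)
  m <- random_mask(20, 12)
  path <- tempfile(fileext = ".png")
  write_label_mask_png(m, path)
  back <- read_label_mask_png(path, setNames(seq_along(vocab), vocab))
  expect_identical(unclass(back), unclass(m))
  expect_error(read_label_mask_png(path, c(sky = 2)), "legend|palette")
})
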