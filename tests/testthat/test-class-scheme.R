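test_that("scheme has 11 foreground classes with contiguous unique codes", {
  sc <- oct_class_scheme()
  expect_length(sc$classes, 11)
  expect_equal(unname(sc$codes), 0:11)
  expect_equal(sc$codes[[sc$background_label]], 0)
  expect_equal(class_code(sc, c("SRF", "Choroid")), c(5L, 10L))
  expect_error(class_code(sc, "NotAClass"), "NotAClass")
})

test_that("rasterization follows the even-odd inside test and painter's rule", {
  sc <- oct_class_scheme()
  # empty shape list: all background
  m0 <- rasterize_polygons(polygon_annotation(list(), 8, 8), sc)
  expect_true(all(m0$codes == 0))

  # axis-aligned 10x10 square: pixel count matches the brute-force oracle
  doc <- polygon_annotation(list(list(label = "SRF",
                                      points = square_poly(5, 7, 10))), 32, 32)
  m <- rasterize_polygons(doc, sc)
  oracle <- 0L
  for (r in 1:32) for (c in 1:32)
    if (oracle_point_in_polygon(c - 0.5, r - 0.5, square_poly(5, 7, 10)))
      oracle <- oracle + 1L
  expect_equal(sum(m$codes == class_code(sc, "SRF")), oracle)
  expect_equal(oracle, 100L)  # interior centres of a 10x10 square

  # painter's rule: later shape wins on the overlap
  doc2 <- polygon_annotation(list(
    list(label = "NR", points = square_poly(2, 2, 10)),
    list(label = "IRF", points = square_poly(8, 8, 10))), 24, 24)
  m2 <- rasterize_polygons(doc2, sc)
  expect_equal(m2$codes[12, 12], class_code(sc, "IRF"))  # overlap pixel
  expect_equal(m2$codes[4, 4], class_code(sc, "NR"))

  # errors: unknown label named; degenerate polygon indexed
  bad <- polygon_annotation(list(list(label = "Vitreous",
                                      points = square_poly(1, 1, 4))), 8, 8)
  expect_error(rasterize_polygons(bad, sc), "Vitreous")
  dg <- polygon_annotation(list(list(label = "NR", points = cbind(1:2, 1:2))), 8, 8)
  expect_error(rasterize_polygons(dg, sc), "shape 1")
})

test_that("rasterization agrees with the per-pixel oracle on random triangles", {
  sc <- oct_class_scheme()
  for (seed in 1:5) {
    poly <- with_seed2(seed, matrix(runif(6, 0, 16), 3, 2))
    doc <- polygon_annotation(list(list(label = "NR", points = poly)), 16, 16)
    m <- rasterize_polygons(doc, sc)
    want <- matrix(0L, 16, 16)
    for (r in 1:16) for (c in 1:16)
      if (oracle_point_in_polygon(c - 0.5, r - 0.5, poly))
        want[r, c] <- class_code(sc, "NR")
    expect_equal(m$codes, want, info = paste("seed", seed))
  }
})

test_that("rasterization order matters only on overlap pixels", {
  sc <- oct_class_scheme()
  for (seed in 1:5) {
    p1 <- with_seed2(seed, square_poly(runif(1, 0, 8), runif(1, 0, 8), 6))
    p2 <- with_seed2(seed + 100, square_poly(runif(1, 0, 8), runif(1, 0, 8), 6))
    a <- rasterize_polygons(polygon_annotation(list(
      list(label = "NR", points = p1), list(label = "IRF", points = p2)), 16, 16), sc)
    b <- rasterize_polygons(polygon_annotation(list(
      list(label = "IRF", points = p2), list(label = "NR", points = p1)), 16, 16), sc)
    differs <- a$codes != b$codes
    overlap <- a$codes != 0 & b$codes != 0 & (a$codes != b$codes)
    expect_true(all(differs == overlap))
  }
})

test_that("image resize is bilinear with rescaled physical units", {
  img <- bscan_image(matrix(runif(512 * 512), 512, 512),
                     axial_um_per_px = 3.87, lateral_um_per_px = 11.3)
  half <- resize_image(img, 256)
  expect_equal(dim(half$pixels), c(256, 256))
  expect_equal(half$axial_um_per_px, 2 * 3.87)
  expect_equal(half$lateral_um_per_px, 2 * 11.3)

  const <- resize_image(bscan_image(matrix(0.7, 64, 64)), 16)
  expect_true(all(abs(const$pixels - 0.7) < 1e-12))

  same <- resize_image(img, 512)
  expect_identical(same$pixels, img$pixels)
  expect_error(resize_image(img, 0), "positive")
})

test_that("mask resize is nearest-neighbour and never invents classes", {
  sc <- oct_class_scheme()
  allsrf <- label_mask(matrix(class_code(sc, "SRF"), 8, 8), sc)
  expect_true(all(resize_mask(allsrf, 4)$codes == class_code(sc, "SRF")))
  expect_identical(resize_mask(allsrf, 8)$codes, allsrf$codes)

  chk <- label_mask(matrix(c(1L, 2L), 4, 4), sc)
  small <- resize_mask(chk, 2)
  expect_true(all(small$codes %in% c(1L, 2L)))

  for (seed in 1:5) {
    m <- label_mask(random_mask(9, 9, 0:11, seed), sc)
    r <- resize_mask(m, 5)
    expect_true(all(unique(as.vector(r$codes)) %in% unique(as.vector(m$codes))))
  }
})

test_that("mask PNG round trip is lossless and palette mismatch errors", {
  sc <- oct_class_scheme()
  m <- label_mask(random_mask(16, 12, 0:11, 1), sc)
  f <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, f)
  back <- read_mask_png(f, sc)
  expect_identical(back$codes, m$codes)

  # foreign colours are rejected
  png::writePNG(array(runif(16 * 16 * 3), c(16, 16, 3)), f)
  expect_error(read_mask_png(f, sc), "palette mismatch")
  expect_error(label_mask(matrix(99L, 2, 2), sc), "outside the scheme")
})

test_that("rasterize -> write -> read round trip preserves every pixel", {
  sc <- oct_class_scheme()
  doc <- polygon_annotation(list(
    list(label = "NR", points = square_poly(2, 2, 12)),
    list(label = "IRF", points = square_poly(6, 6, 5))), 20, 20)
  m <- rasterize_polygons(doc, sc)
  f <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, f)
  expect_identical(read_mask_png(f, sc)$codes, m$codes)
})

test_that("grayscale images round trip through PNG and read from TIFF", {
  img <- bscan_image(matrix(round(runif(64) * 255) / 255, 8, 8),
                     axial_um_per_px = 7, lateral_um_per_px = 23)
  f <- withr::local_tempfile(fileext = ".png")
  write_image_png(img, f)
  back <- read_image_png(f)
  expect_equal(back$pixels, img$pixels, tolerance = 1e-7)
  expect_equal(back$axial_um_per_px, 7)   # sidecar carries the scales
  ft <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(img$pixels, ft)
  expect_equal(read_image_png(ft)$pixels, img$pixels, tolerance = 1e-4)
})

test_that("LabelMe JSON documents and scheme sidecars round trip", {
  sc <- oct_class_scheme()
  doc <- list(imageHeight = 10, imageWidth = 12,
              shapes = list(list(label = "SRF", shape_type = "polygon",
                                 points = list(list(1, 1), list(8, 1), list(8, 6), list(1, 6)))))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  ann <- read_labelme(f)
  expect_s3_class(ann, "polygon_annotation")
  expect_equal(ann$image_height, 10L)
  expect_equal(ann$shapes[[1]]$label, "SRF")
  expect_equal(dim(ann$shapes[[1]]$points), c(4, 2))

  y <- withr::local_tempfile(fileext = ".yml")
  write_scheme_yaml(sc, y)
  sc2 <- read_scheme_yaml(y)
  expect_equal(sc2$codes, sc$codes)
})
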