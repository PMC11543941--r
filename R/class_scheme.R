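# Label taxonomy and image/mask/annotation I/O.

#' The 11-class OCT annotation scheme
#'
#' Ordered label taxonomy for neovascular AMD B-scan segmentation following
#' the AAO consensus nomenclature: epiretinal membrane (ERM), neurosensory
#' retina (NR), retinal pigment epithelium (RPE), intraretinal fluid (IRF),
#' subretinal fluid (SRF), subretinal hyperreflective material (SHRM),
#' drusenoid and fibrovascular pigment epithelial detachment (dPED, fPED),
#' fibrosis, choroid and posterior hyaloid membrane (PHM). A 12th background
#' class (code 0) covers not-evaluated pixels (vitreous, image crop); it is
#' predicted and trained like any other class but excluded from reported F1.
#'
#' @param classes Character vector of foreground class labels (default: the
#'   11 canonical labels above, in their canonical order, codes 1..11).
#' @param background_label Label used for not-evaluated pixels (code 0).
#' @return An object of class `oct_scheme` with elements `classes`,
#'   `background_label`, `labels` (background + foreground), `codes`
#'   (named integer vector) and `palette` (hex colours, one per code).
#' @examples
#' sc <- oct_class_scheme()
#' sc$codes[["SRF"]]
#' @export
oct_class_scheme <- function(classes = c("ERM", "NR", "RPE", "IRF", "SRF",
                                         "SHRM", "dPED", "fPED", "Fibrosis",
                                         "Choroid", "PHM"),
                             background_label = "background") {
  .check(!anyDuplicated(c(background_label, classes)),
         "class labels must be unique")
  labels <- c(background_label, classes)
  codes <- stats::setNames(seq_along(labels) - 1L, labels)
  palette <- grDevices::hcl.colors(length(labels), "Spectral")
  palette[1] <- "#FFFFE0"  # background: pale yellow (not-evaluated)
  structure(list(classes = classes, background_label = background_label,
                 labels = labels, codes = codes,
                 palette = toupper(palette)),
            class = "oct_scheme")
}

#' @export
print.oct_scheme <- function(x, ...) {
  cat("OCT class scheme:", length(x$classes), "foreground classes +",
      x$background_label, "(code 0)\n")
  print(x$codes)
  invisible(x)
}

#' Look up integer codes for class labels
#'
#' @param scheme An `oct_scheme`.
#' @param labels Character vector of labels.
#' @return Integer codes.
#' @export
class_code <- function(scheme, labels) {
  miss <- setdiff(labels, scheme$labels)
  .check(length(miss) == 0, "unknown class label(s): %s",
         paste(miss, collapse = ", "))
  unname(scheme$codes[labels])
}

#' Construct a B-scan image
#'
#' @param pixels Numeric matrix of intensities (rows = axial, columns =
#'   lateral; origin top-left).
#' @param axial_um_per_px,lateral_um_per_px Physical scale in micrometres per
#'   pixel.
#' @return An object of class `bscan_image`.
#' @export
bscan_image <- function(pixels, axial_um_per_px = 3.87,
                        lateral_um_per_px = 11.3) {
  .check(is.matrix(pixels) && is.numeric(pixels), "pixels must be a numeric matrix")
  .check(all(is.finite(pixels)), "pixel intensities must be finite")
  .check(nrow(pixels) > 0 && ncol(pixels) > 0, "image dimensions must be positive")
  .check(axial_um_per_px > 0 && lateral_um_per_px > 0, "physical scales must be positive")
  structure(list(pixels = pixels,
                 height_px = nrow(pixels), width_px = ncol(pixels),
                 axial_um_per_px = axial_um_per_px,
                 lateral_um_per_px = lateral_um_per_px),
            class = "bscan_image")
}

#' Construct a label mask
#'
#' @param codes Integer matrix of per-pixel class codes.
#' @param scheme The `oct_scheme` the codes refer to.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(codes, scheme) {
  .check(is.matrix(codes), "codes must be a matrix")
  storage.mode(codes) <- "integer"
  bad <- setdiff(unique(as.vector(codes)), unname(scheme$codes))
  .check(length(bad) == 0, "mask contains codes outside the scheme: %s",
         paste(bad, collapse = ", "))
  structure(list(codes = codes, scheme = scheme), class = "label_mask")
}

#' Construct a polygon annotation document
#'
#' LabelMe-style: a list of labelled polygons in pixel coordinates
#' (x = column, y = row, 0-based, origin top-left).
#'
#' @param shapes List of `list(label = <chr>, points = <n x 2 matrix>)`.
#' @param image_height,image_width Canvas size in pixels.
#' @return An object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(shapes, image_height, image_width) {
  .check(image_height > 0 && image_width > 0, "canvas dimensions must be positive")
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    .check(is.character(s$label), "shape %d has no label", i)
    s$points <- as.matrix(s$points)
    .check(ncol(s$points) == 2, "shape %d: points must be an n x 2 matrix", i)
    shapes[[i]] <- s
  }
  structure(list(shapes = shapes, image_height = as.integer(image_height),
                 image_width = as.integer(image_width)),
            class = "polygon_annotation")
}

#' Read a LabelMe JSON annotation document
#'
#' @param path Path to a LabelMe-format JSON file.
#' @return A `polygon_annotation`.
#' @export
read_labelme <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  shapes <- lapply(doc$shapes, function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    list(label = s$label, points = pts)
  })
  polygon_annotation(shapes, doc$imageHeight, doc$imageWidth)
}

# Even-odd inside test for pixel centres against one polygon.
# Pixel (r, c) (1-based matrix indices) has centre (x, y) = (c - 0.5, r - 0.5)
# in the 0-based corner-origin coordinate system LabelMe uses. Points exactly
# on an edge count as inside.
.points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xin <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- px[crosses] < xin
      inside[crosses] <- xor(inside[crosses], flip)
    }
    # boundary: point within eps of the segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x1) * dx + (py - y1) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      on_edge <- on_edge | d2 < eps
    }
    j <- i
  }
  inside | on_edge
}

#' Rasterize a polygon annotation to a label mask
#'
#' Pixels inside any polygon receive that polygon's class code; pixels in no
#' polygon receive the background code. Where polygons overlap, the later
#' shape in document order wins (painter's rule). The inside test is the
#' even-odd rule applied to pixel centres at half-integer coordinates;
#' pixels whose centre lies exactly on a polygon edge count as inside.
#'
#' @param doc A `polygon_annotation`.
#' @param scheme An `oct_scheme`; every shape label must be in it.
#' @return A `label_mask` of size `image_height` x `image_width`.
#' @export
rasterize_polygons <- function(doc, scheme) {
  stopifnot(inherits(doc, "polygon_annotation"), inherits(scheme, "oct_scheme"))
  h <- doc$image_height; w <- doc$image_width
  codes <- matrix(0L, h, w)
  if (length(doc$shapes)) {
    px <- rep(seq_len(w) - 0.5, each = h)   # column-major order
    py <- rep(seq_len(h) - 0.5, times = w)
    for (i in seq_along(doc$shapes)) {
      s <- doc$shapes[[i]]
      .check(s$label %in% scheme$labels, "unknown label '%s' in shape %d",
             s$label, i)
      .check(nrow(s$points) >= 3, "degenerate polygon (<3 vertices) at shape %d", i)
      inside <- .points_in_polygon(px, py, s$points)
      codes[inside] <- class_code(scheme, s$label)
    }
  }
  label_mask(codes, scheme)
}

#' Resize a B-scan image by bilinear interpolation
#'
#' Physical scales are updated by the resize factor, e.g. 512 to 256 pixels
#' doubles the micrometres per pixel.
#'
#' @param img A `bscan_image`.
#' @param target Target size in pixels; a single integer (square) or
#'   `c(height, width)`.
#' @return A resized `bscan_image`.
#' @export
resize_image <- function(img, target) {
  stopifnot(inherits(img, "bscan_image"))
  target <- as.integer(rep(target, length.out = 2))
  .check(all(target > 0), "target size must be positive")
  if (target[1] == img$height_px && target[2] == img$width_px) return(img)
  # EBImage dimension order: first array dim = w argument
  out <- EBImage::resize(img$pixels, w = target[1], h = target[2])
  bscan_image(matrix(as.numeric(out), target[1], target[2]),
              axial_um_per_px = img$axial_um_per_px * img$height_px / target[1],
              lateral_um_per_px = img$lateral_um_per_px * img$width_px / target[2])
}

#' Resize a label mask by nearest-neighbour interpolation
#'
#' Nearest-neighbour keeps codes categorical: the output codes are always a
#' subset of the input codes.
#'
#' @param mask A `label_mask`.
#' @param target Target size in pixels; single integer or `c(height, width)`.
#' @return A resized `label_mask`.
#' @export
resize_mask <- function(mask, target) {
  stopifnot(inherits(mask, "label_mask"))
  target <- as.integer(rep(target, length.out = 2))
  .check(all(target > 0), "target size must be positive")
  d <- dim(mask$codes)
  if (all(target == d)) return(mask)
  out <- EBImage::resize(mask$codes, w = target[1], h = target[2], filter = "none")
  label_mask(matrix(as.integer(round(out)), target[1], target[2]), mask$scheme)
}

.palette_rgb <- function(scheme) t(grDevices::col2rgb(scheme$palette))

#' Write a label mask as a palette-coded PNG
#'
#' Each class code is stored as its fixed scheme colour, so the file is
#' human-viewable and the write/read round trip is lossless.
#'
#' @param mask A `label_mask`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  pal <- .palette_rgb(mask$scheme) / 255
  d <- dim(mask$codes)
  arr <- array(0, c(d, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(pal[mask$codes + 1L, ch], d[1], d[2])
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a palette-coded PNG mask
#'
#' @param path PNG file written by [write_mask_png()] (or any PNG whose
#'   colours all belong to the scheme palette).
#' @param scheme The `oct_scheme` declaring the palette.
#' @return A `label_mask`.
#' @export
read_mask_png <- function(path, scheme) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  pal <- .palette_rgb(scheme)
  key <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
  v <- round(arr[, , 1] * 255) * 65536 + round(arr[, , 2] * 255) * 256 +
    round(arr[, , 3] * 255)
  idx <- match(as.vector(v), key)
  .check(!anyNA(idx), "palette mismatch: %d pixel(s) have colours outside the scheme palette",
         sum(is.na(idx)))
  label_mask(matrix(as.integer(idx - 1L), nrow(v), ncol(v)), scheme)
}

#' Write / read a grayscale B-scan image
#'
#' Writes PNG; reads PNG or TIFF (by file extension). Intensities are
#' clipped to `[0, 1]` on write; physical scales travel in a YAML sidecar
#' written next to the image.
#'
#' @param img A `bscan_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  stopifnot(inherits(img, "bscan_image"))
  png::writePNG(pmin(pmax(img$pixels, 0), 1), path)
  yaml::write_yaml(list(axial_um_per_px = img$axial_um_per_px,
                        lateral_um_per_px = img$lateral_um_per_px),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  arr <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  side <- paste0(path, ".yml")
  sc <- if (file.exists(side)) yaml::read_yaml(side) else
    list(axial_um_per_px = 3.87, lateral_um_per_px = 11.3)
  bscan_image(arr, sc$axial_um_per_px, sc$lateral_um_per_px)
}

#' Write / read a class scheme YAML sidecar
#'
#' @param scheme An `oct_scheme`.
#' @param path File path.
#' @return `path` (write) or an `oct_scheme` (read).
#' @export
write_scheme_yaml <- function(scheme, path) {
  yaml::write_yaml(list(classes = scheme$classes,
                        background_label = scheme$background_label), path)
  invisible(path)
}

#' @rdname write_scheme_yaml
#' @export
read_scheme_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  oct_class_scheme(classes = unlist(x$classes),
                   background_label = x$background_label)
}
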