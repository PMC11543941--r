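# Independent brute-force oracles used to cross-check the implementation.

# even-odd point-in-polygon, one point at a time (crossing-number loop,
# written independently of the package's vectorised rasterizer)
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    x1 <- poly[j, 1]; y1 <- poly[j, 2]
    x2 <- poly[i, 1]; y2 <- poly[i, 2]
    # on-edge counts as inside
    if (abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)) < 1e-9 &&
        x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
        y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9) return(TRUE)
    if ((y1 > y) != (y2 > y)) {
      xi <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
      if (x < xi) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# per-class F1 by explicit pixel loops over a confusion matrix
oracle_f1 <- function(pred, truth, n_classes) {
  conf <- matrix(0, n_classes, n_classes)
  for (i in seq_along(pred))
    conf[pred[i] + 1, truth[i] + 1] <- conf[pred[i] + 1, truth[i] + 1] + 1
  sapply(seq_len(n_classes - 1), function(k) {
    tp <- conf[k + 1, k + 1]
    fp <- sum(conf[k + 1, ]) - tp
    fn <- sum(conf[, k + 1]) - tp
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  })
}

# textbook t statistics and p-values
oracle_t_pooled <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}

oracle_t_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x) / n1; v2 <- var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# small fixture builders
square_poly <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
}

tiny_scheme <- oct_class_scheme()

random_mask <- function(h, w, codes, seed) {
  with_seed2(seed, matrix(sample(codes, h * w, replace = TRUE), h, w))
}

with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# small fully-deterministic phantom parameter set for fast tests
fast_phantom <- function(size = 64, ...) phantom_params(image_size = size, ...)
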