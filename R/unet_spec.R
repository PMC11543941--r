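# Declarative U-net architecture: spec object and realized layer list.

#' U-net model specification
#'
#' Declarative description of the segmentation network: a U-net style
#' encoder-decoder with two 3x3 conv-BN-ReLU layers per encoder block, a max
#' pooling after each block, a single conv-BN-ReLU bottleneck, dropout
#' between encoder and decoder, and a decoder of transposed convolutions
#' with skip concatenations. Filters start at `base_filters`, double after
#' every pooling up to `filter_cap`, and halve after every transposed
#' convolution. With the defaults (256 px input, 64 base filters, 5
#' poolings, cap 1024) the contracting path holds 11 convolution layers and
#' the bottleneck has 1024 filters at 8x8 spatial resolution.
#'
#' @param input_size Input side length in pixels; must be divisible by
#'   `2^n_poolings`.
#' @param base_filters Filters of the first convolution layer.
#' @param n_poolings Number of 2x2 max poolings (encoder depth).
#' @param filter_cap Upper bound on the filter count.
#' @param dropout_rate Dropout probability between encoder and decoder.
#' @param n_classes Output classes (11 foreground + background = 12).
#' @param kernel_size Convolution kernel size (3 throughout).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (gradient accumulation over images).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation loss, in epochs.
#' @param seed Integer seed for weight initialization and shuffling.
#' @return An object of class `unet_spec`.
#' @export
model_spec <- function(input_size = 256, base_filters = 64, n_poolings = 5,
                       filter_cap = 1024, dropout_rate = 0.2, n_classes = 12,
                       kernel_size = 3, learning_rate = 0.001, batch_size = 8,
                       max_epochs = 100, patience = 10, seed = NULL) {
  .check(kernel_size == 3, "kernel size is 3 throughout the network")
  .check(base_filters >= 1, "base_filters must be >= 1")
  .check(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate must be in [0, 1)")
  .check(input_size %% 2^n_poolings == 0,
         "input_size %d is not divisible by 2^%d", input_size, n_poolings)
  structure(list(input_size = as.integer(input_size),
                 base_filters = as.integer(base_filters),
                 n_poolings = as.integer(n_poolings),
                 filter_cap = as.integer(filter_cap),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 kernel_size = 3L,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = seed),
            class = "unet_spec")
}

# filter/size schedule shared by build_network() and the realized engine
.unet_structure <- function(spec) {
  P <- spec$n_poolings
  enc <- pmin(spec$base_filters * 2^(seq_len(P) - 1), spec$filter_cap)
  bott <- min(spec$base_filters * 2^P, spec$filter_cap)
  dec <- pmax(bott %/% 2^seq_len(P), 1)
  sizes <- spec$input_size / 2^(0:P)  # size at encoder block i input; bottleneck = last
  list(enc_filters = as.integer(enc), bottleneck_filters = as.integer(bott),
       dec_filters = as.integer(dec), sizes = as.integer(sizes))
}

#' Realize the layer list of a U-net specification
#'
#' Pure function: the same spec always yields the identical layer table.
#'
#' @param spec A `unet_spec`.
#' @return A `data.frame` (class `network_description`) with one row per
#'   layer: `stage` (encoder / bottleneck / decoder / head), `kind` (conv,
#'   batch-norm, relu, max-pool, dropout, transposed-conv, softmax-head),
#'   `filters` and `out_size` (spatial side length of the layer output).
#' @examples
#' net <- build_network(model_spec())
#' subset(net, stage == "bottleneck" & kind == "conv")
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  st <- .unet_structure(spec)
  P <- spec$n_poolings
  rows <- list()
  add <- function(stage, kind, filters, out_size)
    rows[[length(rows) + 1]] <<- data.frame(stage = stage, kind = kind,
                                            filters = filters, out_size = out_size)
  for (i in seq_len(P)) {
    s <- st$sizes[i]; f <- st$enc_filters[i]
    for (k in 1:2) {
      add("encoder", "conv", f, s)
      add("encoder", "batch-norm", f, s)
      add("encoder", "relu", f, s)
    }
    add("encoder", "max-pool", f, st$sizes[i + 1])
  }
  sb <- st$sizes[P + 1]
  add("bottleneck", "conv", st$bottleneck_filters, sb)
  add("bottleneck", "batch-norm", st$bottleneck_filters, sb)
  add("bottleneck", "relu", st$bottleneck_filters, sb)
  add("bottleneck", "dropout", st$bottleneck_filters, sb)
  for (j in seq_len(P)) {
    s <- st$sizes[P + 1 - j]; f <- st$dec_filters[j]
    add("decoder", "transposed-conv", f, s)
    for (k in 1:2) {
      add("decoder", "conv", f, s)
      add("decoder", "batch-norm", f, s)
      add("decoder", "relu", f, s)
    }
  }
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(stage = "head", kind = "softmax-head",
                               filters = spec$n_classes,
                               out_size = spec$input_size))
  out$layer <- seq_len(nrow(out))
  class(out) <- c("network_description", "data.frame")
  out[, c("layer", "stage", "kind", "filters", "out_size")]
}
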