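test_that("default architecture realizes the published geometry", {
  net <- build_network(model_spec())
  bott <- subset(net, stage == "bottleneck" & kind == "conv")
  expect_equal(bott$filters, 1024)
  expect_equal(bott$out_size, 8)
  contracting <- subset(net, stage %in% c("encoder", "bottleneck") & kind == "conv")
  expect_equal(nrow(contracting), 11)
  expect_equal(sum(net$kind == "max-pool"), 5)
  # decoder halving schedule 512, 256, 128, 64, 32
  dec <- subset(net, stage == "decoder" & kind == "transposed-conv")
  expect_equal(dec$filters, c(512, 256, 128, 64, 32))
  head_ <- subset(net, stage == "head")
  expect_equal(head_$filters, 12)
  expect_equal(head_$out_size, 256)
})

test_that("toy architecture enumerates the expected layer list", {
  sp <- model_spec(input_size = 16, base_filters = 4, n_poolings = 1,
                   filter_cap = 8, n_classes = 3)
  net <- build_network(sp)
  enc_conv <- subset(net, stage == "encoder" & kind == "conv")
  expect_equal(enc_conv$filters, c(4, 4))
  expect_equal(enc_conv$out_size, c(16, 16))
  expect_equal(subset(net, kind == "max-pool")$out_size, 8)
  bott <- subset(net, stage == "bottleneck" & kind == "conv")
  expect_equal(bott$filters, 8)
  expect_equal(bott$out_size, 8)
  dec <- subset(net, stage == "decoder")
  expect_equal(subset(dec, kind == "transposed-conv")$out_size, 16)
  expect_equal(subset(dec, kind == "conv")$filters, c(4, 4))
})

test_that("build_network is pure and every output size matches its stage", {
  sp <- model_spec(input_size = 64, base_filters = 8, n_poolings = 3)
  expect_identical(build_network(sp), build_network(sp))
  net <- build_network(sp)
  expect_equal(net$out_size[nrow(net)], 64)  # padding contract
  # filter schedule: filters after pooling k = min(base * 2^k, cap)
  for (spx in list(model_spec(), model_spec(input_size = 64, base_filters = 8,
                                            n_poolings = 5, filter_cap = 64))) {
    st <- octseg:::.unet_structure(spx)
    expect_equal(st$enc_filters,
                 pmin(spx$base_filters * 2^(0:(spx$n_poolings - 1)), spx$filter_cap))
    expect_equal(st$bottleneck_filters,
                 min(spx$base_filters * 2^spx$n_poolings, spx$filter_cap))
  }
  expect_error(model_spec(input_size = 100, n_poolings = 3), "divisible")
})

test_that("softmax predictions are normalized probabilities", {
  sp <- model_spec(input_size = 16, base_filters = 2, n_poolings = 2,
                   n_classes = 4, max_epochs = 1, batch_size = 2, seed = 1)
  img <- matrix(runif(256), 16, 16)
  msk <- matrix(sample(0:3, 256, TRUE), 16, 16)
  m <- train_unet(list(list(image = img, mask = msk)),
                  list(list(image = img, mask = msk)), sp)
  p <- predict_softmax(m, img)
  expect_equal(dim(p), c(16, 16, 4))
  expect_true(all(p >= 0 & p <= 1))
  sums <- apply(unclass(p), c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  # inference is deterministic (dropout off)
  expect_identical(unclass(predict_softmax(m, img)), unclass(p))
})

test_that("the degenerate single-class problem is learned exactly", {
  # one image = one Adam step per epoch, so the toy run uses a larger
  # learning rate than the 0.001 default to reach the optimum quickly
  sp <- model_spec(input_size = 16, base_filters = 2, n_poolings = 1,
                   n_classes = 4, max_epochs = 150, patience = 150,
                   batch_size = 1, learning_rate = 0.02, seed = 2)
  img <- matrix(runif(256, 0.4, 0.6), 16, 16)
  msk <- matrix(2L, 16, 16)
  m <- train_unet(list(list(image = img, mask = msk)),
                  list(list(image = img, mask = msk)), sp)
  pred <- probs_to_mask(predict_softmax(m, img))
  expect_true(all(pred$codes == 2L))
  expect_equal(m$validation_score, 1.0)
  # training loss is essentially non-increasing and collapses overall
  tl <- m$history$train_loss
  expect_true(all(diff(tl) < 0.01))
  expect_lt(tl[length(tl)], tl[1] / 50)
})

test_that("analytic gradients match central finite differences", {
  sp <- model_spec(input_size = 8, base_filters = 2, n_poolings = 1,
                   filter_cap = 4, dropout_rate = 0, n_classes = 3, seed = 7)
  ini <- octseg:::.init_unet_params(sp)
  params <- ini$params; bn_state <- ini$bn_state
  x <- with_seed2(1, matrix(runif(64), 64, 1))
  y <- with_seed2(2, sample(0:2, 64, replace = TRUE))
  loss_of <- function(p) {
    fw <- octseg:::.unet_forward(p, bn_state, sp, x, training = TRUE)
    -mean(log(pmax(fw$probs[cbind(1:64, y + 1)], 1e-12)))
  }
  fw <- octseg:::.unet_forward(params, bn_state, sp, x, training = TRUE)
  dZ <- fw$probs
  dZ[cbind(1:64, y + 1)] <- dZ[cbind(1:64, y + 1)] - 1
  grads <- octseg:::.unet_backward(params, sp, fw, dZ / 64)
  eps <- 1e-5
  set.seed(3)
  for (nm in names(grads)) for (cn in names(grads[[nm]])) {
    g <- grads[[nm]][[cn]]
    for (i in sample(length(g), min(3, length(g)))) {
      p2 <- params; p2[[nm]][[cn]][i] <- p2[[nm]][[cn]][i] + eps
      p3 <- params; p3[[nm]][[cn]][i] <- p3[[nm]][[cn]][i] - eps
      num <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-3)
    }
  }
})

test_that("training is reproducible under a fixed seed", {
  sp <- model_spec(input_size = 16, base_filters = 2, n_poolings = 1,
                   n_classes = 3, max_epochs = 2, batch_size = 2, seed = 31)
  pairs <- lapply(1:3, function(i) with_seed2(i, list(
    image = matrix(runif(256), 16, 16),
    mask = matrix(sample(0:2, 256, TRUE), 16, 16))))
  m1 <- train_unet(pairs[1:2], pairs[3], sp)
  m2 <- train_unet(pairs[1:2], pairs[3], sp)
  expect_identical(m1$history$train_loss[1], m2$history$train_loss[1])
  expect_identical(m1$history, m2$history)
})

test_that("shape and code violations are rejected with labeled errors", {
  sp <- model_spec(input_size = 16, base_filters = 2, n_poolings = 1,
                   n_classes = 3, max_epochs = 1, seed = 1)
  img <- matrix(runif(256), 16, 16)
  good <- list(image = img, mask = matrix(0L, 16, 16))
  expect_error(train_unet(list(good), list(), sp), "validation")
  bad_code <- list(image = img, mask = matrix(7L, 16, 16))
  expect_error(train_unet(list(bad_code), list(good), sp), "n_classes")
  small <- list(image = matrix(0, 8, 8), mask = matrix(0L, 8, 8))
  expect_error(train_unet(list(small), list(good), sp), "input_size")
})

test_that("model checkpoints round trip with their YAML sidecar", {
  sp <- model_spec(input_size = 16, base_filters = 2, n_poolings = 1,
                   n_classes = 3, max_epochs = 1, seed = 4)
  img <- matrix(runif(256), 16, 16)
  msk <- matrix(sample(0:2, 256, TRUE), 16, 16)
  m <- train_unet(list(list(image = img, mask = msk)),
                  list(list(image = img, mask = msk)), sp)
  f <- withr::local_tempfile(fileext = ".rds")
  save_unet(m, f)
  expect_true(file.exists(paste0(f, ".yml")))
  m2 <- load_unet(f)
  expect_identical(unclass(predict_softmax(m2, img)),
                   unclass(predict_softmax(m, img)))
  side <- yaml::read_yaml(paste0(f, ".yml"))
  expect_equal(side$validation_score, m$validation_score, tolerance = 1e-6)
})
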