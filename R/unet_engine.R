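# Self-contained CNN engine realizing the U-net specification.
#
# Feature maps are stored as (H*W) x C matrices in R's column-major pixel
# order; convolutions are im2col + BLAS GEMM, so the whole engine is
# vectorised base R. Batch normalization uses per-image spatial statistics
# (each sample normalised over its own H*W pixels per channel) with running
# moments for inference; minibatches accumulate gradients over images.

.im2col_cache <- new.env(parent = emptyenv())

# index tables for a given (H, W): im2col gather indices into the padded
# image, the padded positions of the core pixels, 2x2 pool gather indices,
# and 2x2 transposed-conv scatter indices
.geom_tables <- function(H, W) {
  key <- paste(H, W, sep = "x")
  tab <- .im2col_cache[[key]]
  if (!is.null(tab)) return(tab)
  HW <- H * W
  p <- seq_len(HW)
  r <- ((p - 1L) %% H) + 1L
  cc <- ((p - 1L) %/% H) + 1L
  core <- cc * (H + 2L) + r + 1L
  idx <- matrix(0L, HW, 9L)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {  # dr fastest: k = dr + 3*dc + 1
    k <- k + 1L
    idx[, k] <- (cc + dc - 1L) * (H + 2L) + (r + dr)
  }
  Ho <- H %/% 2L; Wo <- W %/% 2L
  po <- seq_len(Ho * Wo)
  ro <- ((po - 1L) %% Ho) + 1L
  co <- ((po - 1L) %/% Ho) + 1L
  pool <- lapply(1:4, function(k) {
    a <- (k - 1L) %% 2L; b <- (k - 1L) %/% 2L
    (2L * co - 2L + b) * H + (2L * ro - 1L + a)
  })
  up <- lapply(1:4, function(k) {
    a <- (k - 1L) %% 2L; b <- (k - 1L) %/% 2L
    (2L * cc - 2L + b) * (2L * H) + (2L * r - 1L + a)
  })
  tab <- list(idx = idx, core = core, pool = pool, up = up)
  .im2col_cache[[key]] <- tab
  tab
}

.he_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# ---- layer primitives -------------------------------------------------------

.conv_fwd <- function(X, H, W, prm) {
  g <- .geom_tables(H, W)
  Cin <- ncol(X); HW <- H * W
  xpad <- matrix(0, (H + 2L) * (W + 2L), Cin)
  xpad[g$core, ] <- X
  patches <- xpad[as.vector(g$idx), , drop = FALSE]
  dim(patches) <- c(HW, 9L * Cin)
  Y <- patches %*% prm$W
  Y <- Y + rep(prm$b, each = HW)
  list(Y = Y, cache = list(patches = patches, H = H, W = W, Cin = Cin))
}

# permutation turning W (9*Cin x Cout) into the backward kernel
# (9*Cout x Cin): kernel rotated 180 degrees, channels swapped
.wflip_cache <- new.env(parent = emptyenv())
.wflip_idx <- function(Cin, Cout) {
  key <- paste(Cin, Cout, sep = "x")
  v <- .wflip_cache[[key]]
  if (!is.null(v)) return(v)
  # element (k' + 9(co-1), ci) of the backward kernel is element
  # ((10-k') + 9(ci-1), co) of W; build the linear gather index
  kk <- rep(1:9, times = Cout)
  co <- rep(seq_len(Cout), each = 9)
  v <- matrix(0L, 9L * Cout, Cin)
  for (ci in seq_len(Cin))
    v[, ci] <- (10L - kk) + 9L * (ci - 1L) + (co - 1L) * (9L * Cin)
  v <- as.vector(v)  # plain linear index (a 2-column matrix would be
                     # treated as coordinate pairs by `[`)
  .wflip_cache[[key]] <- v
  v
}

.conv_bwd <- function(dY, prm, cache) {
  g <- .geom_tables(cache$H, cache$W)
  HW <- cache$H * cache$W
  dW <- crossprod(cache$patches, dY)
  db <- colSums(dY)
  # dX = correlation of dY with the rotated, channel-swapped kernel
  Cout <- ncol(dY)
  Wb <- matrix(prm$W[.wflip_idx(cache$Cin, Cout)], 9L * Cout, cache$Cin)
  ypad <- matrix(0, (cache$H + 2L) * (cache$W + 2L), Cout)
  ypad[g$core, ] <- dY
  dpat <- ypad[as.vector(g$idx), , drop = FALSE]
  dim(dpat) <- c(HW, 9L * Cout)
  list(dX = dpat %*% Wb, grads = list(W = dW, b = db))
}

# spatial normalization over the sample's own H*W pixels per channel, in
# both training and inference; `state` keeps running moments for reporting
.bn_fwd <- function(X, prm, state, training, momentum = 0.1, eps = 1e-5) {
  HW <- nrow(X)
  mu <- colMeans(X)
  xc <- X - rep(mu, each = HW)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = HW)
  if (training) {
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  }
  Y <- xhat * rep(prm$gamma, each = HW) + rep(prm$beta, each = HW)
  list(Y = Y, state = state, cache = list(xhat = xhat, istd = istd))
}

.bn_bwd <- function(dY, prm, cache) {
  HW <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(prm$gamma, each = HW)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- (dxhat - rep(s1 / HW, each = HW) -
           cache$xhat * rep(s2 / HW, each = HW)) * rep(cache$istd, each = HW)
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

.pool_fwd <- function(X, H, W) {
  g <- .geom_tables(H, W)
  s <- lapply(g$pool, function(i) X[i, , drop = FALSE])
  M <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  used <- matrix(FALSE, nrow(M), ncol(M))
  sel <- vector("list", 4)
  for (k in 1:4) {
    sk <- (s[[k]] == M) & !used
    used <- used | sk
    sel[[k]] <- sk
  }
  list(Y = M, cache = list(sel = sel, H = H, W = W, C = ncol(X)))
}

.pool_bwd <- function(dY, cache) {
  g <- .geom_tables(cache$H, cache$W)
  dX <- matrix(0, cache$H * cache$W, cache$C)
  for (k in 1:4) {
    tmp <- matrix(0, nrow(dY), ncol(dY))
    tmp[cache$sel[[k]]] <- dY[cache$sel[[k]]]
    dX[g$pool[[k]], ] <- tmp
  }
  dX
}

# 2x2 stride-2 transposed convolution: blocks of prm$W are (Cin x Cout),
# one per output sub-position; non-overlapping so each is one GEMM
.up_fwd <- function(X, H, W, prm, Cout) {
  g <- .geom_tables(H, W)
  HW <- H * W
  Y <- matrix(0, 4L * HW, Cout)
  for (k in 1:4) {
    blk <- ((k - 1L) * Cout + 1L):(k * Cout)
    Y[g$up[[k]], ] <- X %*% prm$W[, blk, drop = FALSE]
  }
  Y <- Y + rep(prm$b, each = 4L * HW)
  list(Y = Y, cache = list(X = X, H = H, W = W))
}

.up_bwd <- function(dY, prm, cache, Cout) {
  g <- .geom_tables(cache$H, cache$W)
  dW <- matrix(0, nrow(prm$W), ncol(prm$W))
  dX <- matrix(0, nrow(cache$X), ncol(cache$X))
  for (k in 1:4) {
    blk <- ((k - 1L) * Cout + 1L):(k * Cout)
    dYk <- dY[g$up[[k]], , drop = FALSE]
    dW[, blk] <- crossprod(cache$X, dYk)
    dX <- dX + tcrossprod(dYk, prm$W[, blk, drop = FALSE])
  }
  list(dX = dX, grads = list(W = dW, b = colSums(dY)))
}

.softmax_rows <- function(Z) {
  j <- max.col(Z, ties.method = "first")
  m <- Z[cbind(seq_len(nrow(Z)), j)]
  E <- exp(Z - m)
  E / rowSums(E)
}

# ---- parameter initialisation ----------------------------------------------

.init_unet_params <- function(spec) {
  st <- .unet_structure(spec)
  P <- spec$n_poolings
  params <- list()
  bn_state <- list()
  conv <- function(Cin, F) list(W = .he_mat(9 * Cin, F, 9 * Cin), b = numeric(F))
  bn <- function(F) list(gamma = rep(1, F), beta = numeric(F))
  bn0 <- function(F) list(mean = numeric(F), var = rep(1, F))
  Cin <- 1L
  for (i in seq_len(P)) {
    F <- st$enc_filters[i]
    params[[paste0("enc", i, "_conv1")]] <- conv(Cin, F)
    params[[paste0("enc", i, "_conv2")]] <- conv(F, F)
    params[[paste0("enc", i, "_bn1")]] <- bn(F)
    params[[paste0("enc", i, "_bn2")]] <- bn(F)
    bn_state[[paste0("enc", i, "_bn1")]] <- bn0(F)
    bn_state[[paste0("enc", i, "_bn2")]] <- bn0(F)
    Cin <- F
  }
  Fb <- st$bottleneck_filters
  params$bott_conv <- conv(Cin, Fb)
  params$bott_bn <- bn(Fb)
  bn_state$bott_bn <- bn0(Fb)
  Cin <- Fb
  for (j in seq_len(P)) {
    F <- st$dec_filters[j]
    skipF <- st$enc_filters[P + 1 - j]
    params[[paste0("dec", j, "_up")]] <-
      list(W = .he_mat(Cin, 4 * F, Cin), b = numeric(F))
    params[[paste0("dec", j, "_conv1")]] <- conv(F + skipF, F)
    params[[paste0("dec", j, "_conv2")]] <- conv(F, F)
    params[[paste0("dec", j, "_bn1")]] <- bn(F)
    params[[paste0("dec", j, "_bn2")]] <- bn(F)
    bn_state[[paste0("dec", j, "_bn1")]] <- bn0(F)
    bn_state[[paste0("dec", j, "_bn2")]] <- bn0(F)
    Cin <- F
  }
  params$head <- list(W = .he_mat(Cin, spec$n_classes, Cin),
                      b = numeric(spec$n_classes))
  list(params = params, bn_state = bn_state)
}

# ---- forward / backward -----------------------------------------------------

# x: (H*W) x 1 matrix. Returns probs and (if training) caches + updated
# bn_state + the dropout mask.
.unet_forward <- function(params, bn_state, spec, x, training = FALSE) {
  st <- .unet_structure(spec)
  P <- spec$n_poolings
  caches <- list()
  H <- spec$input_size; W <- spec$input_size
  X <- x
  skips <- vector("list", P)
  cb_block <- function(X, H, W, nm1, nm2, bn1, bn2) {
    c1 <- .conv_fwd(X, H, W, params[[nm1]])
    b1 <- .bn_fwd(c1$Y, params[[bn1]], bn_state[[bn1]], training)
    bn_state[[bn1]] <<- b1$state
    r1 <- pmax(b1$Y, 0)
    c2 <- .conv_fwd(r1, H, W, params[[nm2]])
    b2 <- .bn_fwd(c2$Y, params[[bn2]], bn_state[[bn2]], training)
    bn_state[[bn2]] <<- b2$state
    r2 <- pmax(b2$Y, 0)
    list(Y = r2, cache = list(c1 = c1$cache, bn1 = b1$cache, m1 = b1$Y > 0,
                              c2 = c2$cache, bn2 = b2$cache, m2 = b2$Y > 0))
  }
  for (i in seq_len(P)) {
    blk <- cb_block(X, H, W, paste0("enc", i, "_conv1"), paste0("enc", i, "_conv2"),
                    paste0("enc", i, "_bn1"), paste0("enc", i, "_bn2"))
    skips[[i]] <- blk$Y
    pl <- .pool_fwd(blk$Y, H, W)
    caches[[paste0("enc", i)]] <- list(block = blk$cache, pool = pl$cache)
    X <- pl$Y
    H <- H %/% 2L; W <- W %/% 2L
  }
  cb <- .conv_fwd(X, H, W, params$bott_conv)
  bb <- .bn_fwd(cb$Y, params$bott_bn, bn_state$bott_bn, training)
  bn_state$bott_bn <- bb$state
  rb <- pmax(bb$Y, 0)
  drop_mask <- NULL
  if (training && spec$dropout_rate > 0) {
    drop_mask <- (matrix(stats::runif(length(rb)), nrow(rb), ncol(rb)) >=
                    spec$dropout_rate) / (1 - spec$dropout_rate)
    rb <- rb * drop_mask
  }
  caches$bott <- list(conv = cb$cache, bn = bb$cache, mask = bb$Y > 0,
                      drop = drop_mask)
  X <- rb
  for (j in seq_len(P)) {
    F <- st$dec_filters[j]
    upn <- paste0("dec", j, "_up")
    up <- .up_fwd(X, H, W, params[[upn]], F)
    H <- H * 2L; W <- W * 2L
    skip <- skips[[P + 1 - j]]
    Xc <- cbind(up$Y, skip)
    blk <- cb_block(Xc, H, W, paste0("dec", j, "_conv1"), paste0("dec", j, "_conv2"),
                    paste0("dec", j, "_bn1"), paste0("dec", j, "_bn2"))
    caches[[paste0("dec", j)]] <- list(up = up$cache, upF = F,
                                       splitF = ncol(up$Y), block = blk$cache)
    X <- blk$Y
  }
  logits <- X %*% params$head$W + rep(params$head$b, each = nrow(X))
  probs <- .softmax_rows(logits)
  caches$head <- list(X = X)
  list(probs = probs, caches = caches, bn_state = bn_state)
}

# dZ: gradient at the logits ((H*W) x K). Returns named grads list.
.unet_backward <- function(params, spec, fw, dZ) {
  st <- .unet_structure(spec)
  P <- spec$n_poolings
  caches <- fw$caches
  grads <- list()
  grads$head <- list(W = crossprod(caches$head$X, dZ), b = colSums(dZ))
  dX <- tcrossprod(dZ, params$head$W)
  cb_block_bwd <- function(dY, cache, nm1, nm2, bn1, bn2) {
    dY <- dY * cache$m2
    b2 <- .bn_bwd(dY, params[[bn2]], cache$bn2)
    grads[[bn2]] <<- b2$grads
    c2 <- .conv_bwd(b2$dX, params[[nm2]], cache$c2)
    grads[[nm2]] <<- c2$grads
    dY <- c2$dX * cache$m1
    b1 <- .bn_bwd(dY, params[[bn1]], cache$bn1)
    grads[[bn1]] <<- b1$grads
    c1 <- .conv_bwd(b1$dX, params[[nm1]], cache$c1)
    grads[[nm1]] <<- c1$grads
    c1$dX
  }
  for (j in rev(seq_len(P))) {
    cj <- caches[[paste0("dec", j)]]
    dXc <- cb_block_bwd(dX, cj$block, paste0("dec", j, "_conv1"),
                        paste0("dec", j, "_conv2"),
                        paste0("dec", j, "_bn1"), paste0("dec", j, "_bn2"))
    dUp <- dXc[, seq_len(cj$splitF), drop = FALSE]
    # skip-connection gradient flows back to the matching encoder block
    dSkip <- dXc[, -seq_len(cj$splitF), drop = FALSE]
    upn <- paste0("dec", j, "_up")
    ub <- .up_bwd(dUp, params[[upn]], cj$up, cj$upF)
    grads[[upn]] <- ub$grads
    dX <- ub$dX
    caches[[paste0("enc", P + 1 - j)]]$dskip <- dSkip
  }
  dY <- dX
  if (!is.null(caches$bott$drop)) dY <- dY * caches$bott$drop
  dY <- dY * caches$bott$mask
  bb <- .bn_bwd(dY, params$bott_bn, caches$bott$bn)
  grads$bott_bn <- bb$grads
  cb <- .conv_bwd(bb$dX, params$bott_conv, caches$bott$conv)
  grads$bott_conv <- cb$grads
  dX <- cb$dX
  for (i in rev(seq_len(P))) {
    ci <- caches[[paste0("enc", i)]]
    dPool <- .pool_bwd(dX, ci$pool)
    dY <- dPool + ci$dskip
    dX <- cb_block_bwd(dY, ci$block, paste0("enc", i, "_conv1"),
                       paste0("enc", i, "_conv2"),
                       paste0("enc", i, "_bn1"), paste0("enc", i, "_bn2"))
  }
  grads
}

# ---- optimiser --------------------------------------------------------------

.adam_init <- function(params) {
  lapply(params, function(p) lapply(p, function(w) {
    list(m = array(0, dim = if (is.null(dim(w))) length(w) else dim(w)),
         v = array(0, dim = if (is.null(dim(w))) length(w) else dim(w)))
  }))
}

.adam_step <- function(params, grads, opt, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
  for (nm in names(grads)) {
    for (cn in names(grads[[nm]])) {
      g <- grads[[nm]][[cn]]
      o <- opt[[nm]][[cn]]
      o$m <- b1 * o$m + (1 - b1) * g
      o$v <- b2 * o$v + (1 - b2) * g * g
      opt[[nm]][[cn]] <- o
      params[[nm]][[cn]] <- params[[nm]][[cn]] -
        lr * (o$m / bc1) / (sqrt(o$v / bc2) + eps)
    }
  }
  list(params = params, opt = opt)
}

.acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) for (cn in names(g[[nm]]))
    acc[[nm]][[cn]] <- acc[[nm]][[cn]] + g[[nm]][[cn]]
  acc
}

.scale_grads <- function(g, s) {
  for (nm in names(g)) for (cn in names(g[[nm]]))
    g[[nm]][[cn]] <- g[[nm]][[cn]] * s
  g
}

# ---- training ---------------------------------------------------------------

.as_pixel_matrix <- function(img) {
  m <- if (inherits(img, "bscan_image")) img$pixels else img
  matrix(as.vector(m), length(m), 1)
}

.as_code_vector <- function(mask) {
  m <- if (inherits(mask, "label_mask")) mask$codes else mask
  as.integer(as.vector(m))
}

# macro-averaged F1 over foreground classes present in truth or prediction
.macro_f1 <- function(pred, truth, n_classes) {
  f1 <- numeric(0)
  for (k in seq_len(n_classes - 1)) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    if (tp + fp + fn > 0) f1 <- c(f1, 2 * tp / (2 * tp + fp + fn))
  }
  if (length(f1) == 0) NA_real_ else mean(f1)
}

#' Train a U-net segmentation model
#'
#' Optimizes the categorical cross-entropy over all pixels with Adam at the
#' configured learning rate. Each epoch records training loss, validation
#' loss and validation macro-F1 (mean per-class F1 over foreground classes,
#' pixels concatenated across the validation images). The weights from the
#' epoch with the lowest validation loss are kept; `validation_score` is the
#' validation macro-F1 at that epoch. Training stops early when validation
#' loss has not improved for `spec$patience` epochs. Fixed-seed runs are
#' reproducible on a given machine/BLAS configuration.
#'
#' @param train_pairs,val_pairs Lists of `list(image = , mask = )` pairs
#'   (`bscan_image`/`label_mask` or plain matrices) at the spec input size.
#' @param spec A `unet_spec`.
#' @param verbose Print per-epoch progress.
#' @return An object of class `trained_unet` with elements `spec`, `params`,
#'   `bn_state`, `history` (data.frame epoch/train_loss/val_loss/val_macro_f1)
#'   and `validation_score`.
#' @export
train_unet <- function(train_pairs, val_pairs, spec, verbose = FALSE) {
  stopifnot(inherits(spec, "unet_spec"))
  .check(length(train_pairs) >= 1, "need at least one training pair")
  .check(length(val_pairs) >= 1,
         "empty validation set: validation_score would be undefined")
  prep <- function(pairs) lapply(pairs, function(p) {
    x <- .as_pixel_matrix(p$image)
    y <- .as_code_vector(p$mask)
    .check(nrow(x) == spec$input_size^2,
           "image size does not match spec input_size %d", spec$input_size)
    .check(length(y) == nrow(x), "image/mask shape mismatch")
    .check(max(y) < spec$n_classes && min(y) >= 0,
           "mask contains class code >= n_classes (%d)", spec$n_classes)
    list(x = x, y = y)
  })
  tr <- prep(train_pairs)
  va <- prep(val_pairs)
  with_seed(spec$seed, {
    ini <- .init_unet_params(spec)
    params <- ini$params; bn_state <- ini$bn_state
    opt <- .adam_init(params)
    t_step <- 0L
    HW <- spec$input_size^2
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric(), val_macro_f1 = numeric())
    best <- list(val_loss = Inf, params = params, bn_state = bn_state,
                 score = NA_real_, epoch = 0L)
    wait <- 0L
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(length(tr))
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1, length(ord), by = spec$batch_size)) {
        ids <- ord[start:min(start + spec$batch_size - 1, length(ord))]
        acc <- NULL
        bloss <- 0
        for (id in ids) {
          fw <- .unet_forward(params, bn_state, spec, tr[[id]]$x, training = TRUE)
          bn_state <- fw$bn_state
          y1 <- tr[[id]]$y + 1L
          ii <- cbind(seq_len(HW), y1)
          bloss <- bloss - mean(log(pmax(fw$probs[ii], 1e-12)))
          dZ <- fw$probs
          dZ[ii] <- dZ[ii] - 1
          dZ <- dZ / HW
          acc <- .acc_grads(acc, .unet_backward(params, spec, fw, dZ))
        }
        acc <- .scale_grads(acc, 1 / length(ids))
        t_step <- t_step + 1L
        st <- .adam_step(params, acc, opt, spec$learning_rate, t_step)
        params <- st$params; opt <- st$opt
        ep_loss <- ep_loss + bloss / length(ids)
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      vl <- 0; preds <- integer(0); truths <- integer(0)
      for (v in va) {
        fw <- .unet_forward(params, bn_state, spec, v$x, training = FALSE)
        ii <- cbind(seq_len(HW), v$y + 1L)
        vl <- vl - mean(log(pmax(fw$probs[ii], 1e-12)))
        preds <- c(preds, max.col(fw$probs, ties.method = "first") - 1L)
        truths <- c(truths, v$y)
      }
      vl <- vl / length(va)
      vf1 <- .macro_f1(preds, truths, spec$n_classes)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                     val_loss = vl, val_macro_f1 = vf1))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  macroF1 %.4f",
                        epoch, ep_loss, vl, vf1))
      if (vl < best$val_loss - 1e-6) {
        best <- list(val_loss = vl, params = params, bn_state = bn_state,
                     score = vf1, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
    structure(list(spec = spec, params = best$params, bn_state = best$bn_state,
                   history = hist, validation_score = best$score,
                   best_epoch = best$epoch),
              class = "trained_unet")
  })
}

#' @export
print.trained_unet <- function(x, ...) {
  cat(sprintf("trained U-net: input %d, %d classes, %d epochs, validation macro-F1 %.3f\n",
              x$spec$input_size, x$spec$n_classes, nrow(x$history),
              x$validation_score))
  invisible(x)
}

#' Per-pixel class probabilities for an image
#'
#' Runs the trained network in inference mode (dropout off, batch-norm
#' running statistics); prediction is deterministic for a fixed model. If
#' the image is not at the spec input size it is bilinearly resized first.
#'
#' @param model A `trained_unet`.
#' @param img A `bscan_image` or plain intensity matrix.
#' @return An H x W x K array of class probabilities (class
#'   `softmax_prediction`); each pixel's probabilities sum to 1.
#' @export
predict_softmax <- function(model, img) {
  stopifnot(inherits(model, "trained_unet"))
  S <- model$spec$input_size
  m <- if (inherits(img, "bscan_image")) img$pixels else img
  if (!all(dim(m) == c(S, S))) {
    .check(inherits(img, "bscan_image") || is.matrix(m),
           "image size does not match spec input_size")
    m <- resize_image(bscan_image(m), S)$pixels
  }
  fw <- .unet_forward(model$params, model$bn_state, model$spec,
                      matrix(as.vector(m), length(m), 1), training = FALSE)
  structure(array(fw$probs, c(S, S, model$spec$n_classes)),
            class = "softmax_prediction")
}

#' Hard segmentation from a probability stack
#'
#' Argmax per pixel with ties broken toward the lowest class code.
#'
#' @param probs An H x W x K probability array ([predict_softmax()] output).
#' @param scheme An `oct_scheme` for the resulting mask.
#' @return A `label_mask`.
#' @export
probs_to_mask <- function(probs, scheme = oct_class_scheme()) {
  d <- dim(probs)
  P <- matrix(probs, d[1] * d[2], d[3])
  codes <- matrix(max.col(P, ties.method = "first") - 1L, d[1], d[2])
  label_mask(codes, scheme)
}

#' Save / load a trained model
#'
#' Weights are stored with `saveRDS`; a portable YAML sidecar carries the
#' model spec and validation score.
#'
#' @param model A `trained_unet`.
#' @param path File path (`.rds`).
#' @return `path` (save) or a `trained_unet` (load).
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "trained_unet"))
  saveRDS(model, path)
  sp <- model$spec
  yaml::write_yaml(list(spec = sp[setdiff(names(sp), "seed")],
                        validation_score = model$validation_score),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "trained_unet"))
  m
}
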