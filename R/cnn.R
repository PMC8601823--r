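## cnn_classifier: the two-class patch CNN, implemented directly on BLAS
## (im2col + GEMM); conv blocks are 5x5 convolution -> batch normalization
## -> leaky ReLU -> 2x2 max pooling, followed by three fully connected
## layers (fc1, fc2, 2) with dropout on the FC activations and a softmax.
##
## Activation arrays use layout (H, W, N, C); the im2col matrix has one row
## per (output pixel, example) and one column per (kernel offset, input
## channel), so batch normalization acts directly on its GEMM product.

cnnFlattenSize <- function(inputSize, s2, d2) {
  h1 <- inputSize %/% 2L                         # conv1 same + pool
  h2 <- as.integer(ceiling(h1 / s2)) %/% 2L      # conv2 + pool
  h2 * h2 * d2
}

#' Define the CNN architecture
#'
#' The default: 5x5 convolutions of depth 16 and 25, 2x2 max pooling after
#' each block, fully connected layers of 1600 and 500 units, two softmax
#' outputs.  With depth 25 the flattened block-2 output is exactly 1600,
#' so the first fully connected layer consumes the flattened features
#' one-to-one; both depths are configurable.
#'
#' @param d1,d2 convolution depths.
#' @param s2 stride of the second convolution.
#' @param fc1,fc2 fully connected layer sizes.
#' @param input_size patch side length.
#' @param alpha leaky-ReLU negative slope.
#' @param flatten flattened size feeding fc1; normally left to the computed
#'   value, and validated against it.
#' @return a [CNNSpec].
#' @export
cnnSpec <- function(d1 = 16L, d2 = 25L, s2 = 1L, fc1 = 1600L, fc2 = 500L,
                    input_size = 32L, alpha = 0.01, flatten = NULL) {
  if (is.null(flatten)) flatten <- cnnFlattenSize(input_size, s2, d2)
  new("CNNSpec", inputSize = as.integer(input_size), d1 = as.integer(d1),
      d2 = as.integer(d2), s2 = as.integer(s2), fc1 = as.integer(fc1),
      fc2 = as.integer(fc2), alpha = alpha, flatten = as.integer(flatten))
}

#' Default training configuration
#'
#' Batch 32, plain SGD, moving-average decay 0.9997 for both the shadow
#' weights and the BN statistics (with the usual `(1 + t) / (10 + t)`
#' warm-up so early averages track the raw weights), learning rate decayed
#' exponentially by the same factor at every 10000-step boundary, dropout
#' keep probability 0.6 on the FC activations, L2 coefficient `eta = 1`,
#' truncated-Gaussian weight initialization with sd 0.1.
#'
#' The default `initial_lr` is 3e-4.  With `eta = 1` the L2 term shrinks
#' every weight by the factor `(1 - lr * eta)` per step, so the rate doubles
#' as a weight-decay rate: large rates reach high accuracy quickly but
#' shrink the logits until the softmax saturates near 0.5/0.5, which is
#' fatal for the downstream `|p1 - p2|` margin rule.  3e-4 keeps the
#' cumulative shrink over 3000 steps near 0.4 while training the network to
#' sharp, well-separated probabilities.
#'
#' @param max_steps SGD steps.
#' @param initial_lr starting learning rate.
#' @param batch_size minibatch size.
#' @param lr_decay,lr_decay_every exponential LR schedule.
#' @param ma_decay moving-average decay for shadow weights and BN stats.
#' @param keep_prob dropout keep probability on FC activations.
#' @param eta L2 regularization coefficient.
#' @param val_fraction held-out validation fraction (stratified).
#' @param log_every log cadence in steps.
#' @param seed integer seed.
#' @return a plain list of training settings.
#' @export
trainingConfig <- function(max_steps = 3000L, initial_lr = 3e-4,
                           batch_size = 32L, lr_decay = 0.9997,
                           lr_decay_every = 10000L, ma_decay = 0.9997,
                           keep_prob = 0.6, eta = 1.0, val_fraction = 0.1,
                           log_every = 100L, seed = 1L) {
  stopifnot(keep_prob > 0, keep_prob <= 1, ma_decay > 0, ma_decay < 1)
  list(max_steps = as.integer(max_steps), initial_lr = initial_lr,
       batch_size = as.integer(batch_size), lr_decay = lr_decay,
       lr_decay_every = as.integer(lr_decay_every), ma_decay = ma_decay,
       keep_prob = keep_prob, eta = eta, val_fraction = val_fraction,
       log_every = as.integer(log_every), seed = as.integer(seed))
}

## Truncated Gaussian (resample beyond 2 sd), the TF-style initializer.
rtruncGauss <- function(n, sd = 0.1) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

#' Build (initialize) a patch CNN
#'
#' Weights from a truncated Gaussian (sd 0.1), biases 0, BN scale 1 /
#' shift 0; deterministic given the seed.  Shadow weights start equal to
#' the raw weights.
#'
#' @param spec a [CNNSpec].
#' @param seed integer seed.
#' @return an (untrained) [PatchCNN].
#' @export
buildCNN <- function(spec = cnnSpec(), seed = 1L) {
  validObject(spec)
  withSeed(seed, {
    w <- list(
      W1 = matrix(rtruncGauss(25L * spec@d1), 25L, spec@d1),
      b1 = numeric(spec@d1), g1 = rep(1, spec@d1), be1 = numeric(spec@d1),
      W2 = matrix(rtruncGauss(25L * spec@d1 * spec@d2), 25L * spec@d1,
                  spec@d2),
      b2 = numeric(spec@d2), g2 = rep(1, spec@d2), be2 = numeric(spec@d2),
      Wf1 = matrix(rtruncGauss(spec@flatten * spec@fc1), spec@flatten,
                   spec@fc1),
      bf1 = numeric(spec@fc1),
      Wf2 = matrix(rtruncGauss(spec@fc1 * spec@fc2), spec@fc1, spec@fc2),
      bf2 = numeric(spec@fc2),
      Wf3 = matrix(rtruncGauss(spec@fc2 * 2L), spec@fc2, 2L),
      bf3 = numeric(2L))
    bn <- list(rm1 = numeric(spec@d1), rv1 = rep(1, spec@d1),
               rm2 = numeric(spec@d2), rv2 = rep(1, spec@d2))
    new("PatchCNN", spec = spec, weights = w, shadow = w, bn = bn,
        step = 0L, trained = FALSE, classes = c("boundary", "lesion"))
  })
}

## ---- im2col machinery -----------------------------------------------------
## Gather/scatter and pooling are compiled (src/fastops.cpp); layout
## (H, W, N, C), rows of the im2col matrix ordered (out_i, out_j, n) and
## columns (di, dj, c).

.im2col <- function(A, stride = 1L) {
  d <- dim(A)
  cpp_im2col(A, d[1], d[2], d[3], d[4], as.integer(stride))
}

## ---- layers ---------------------------------------------------------------

.lrelu <- function(x, alpha) pmax(x, 0) + alpha * pmin(x, 0)
.lreluGrad <- function(x, alpha) alpha + (1 - alpha) * (x > 0)

## column-wise scale/shift without sweep() copies
.colScale <- function(Z, s) Z * rep(s, each = nrow(Z))
.colShift <- function(Z, s) Z + rep(s, each = nrow(Z))

## Fused batch-norm + leaky-ReLU (compiled); training mode uses batch
## statistics, inference the running ones.
.bnFused <- function(Z, gamma, beta, training, rm, rv, alpha, eps = 1e-5) {
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(Z * Z) - mu^2
  } else {
    mu <- rm; v <- rv
  }
  istd <- 1 / sqrt(v + eps)
  r <- cpp_bnrelu_fwd(Z, mu, istd, gamma, beta, alpha)
  list(out = r$out, xhat = r$xhat, pos = r$pos, istd = istd,
       mu = mu, v = v)
}

## ---- forward / backward ---------------------------------------------------

## X: (32, 32, N, 1) array.  Returns logits and (optionally) all caches.
.cnnForward <- function(model, X, training = FALSE, keepProb = 1,
                        dropoutMasks = NULL, keepCache = FALSE) {
  sp <- model@spec
  w <- if (training) model@weights else model@shadow
  bn <- model@bn
  N <- dim(X)[3]
  a <- sp@alpha
  cache <- list(X = X)

  C1 <- .im2col(X, 1L)
  Z1 <- .colShift(C1 %*% w$W1, w$b1)
  B1 <- .bnFused(Z1, w$g1, w$be1, training, bn$rm1, bn$rv1, a)
  h1 <- sp@inputSize %/% 2L
  P1 <- cpp_pool2(B1$out, sp@inputSize, sp@inputSize, N, sp@d1)
  P1out <- P1$out; dim(P1out) <- c(h1, h1, N, sp@d1)

  C2 <- .im2col(P1out, sp@s2)
  Z2 <- .colShift(C2 %*% w$W2, w$b2)
  B2 <- .bnFused(Z2, w$g2, w$be2, training, bn$rm2, bn$rv2, a)
  h2 <- h1 %/% sp@s2
  P2 <- cpp_pool2(B2$out, h2, h2, N, sp@d2)
  h2o <- h2 %/% 2L
  Fl <- P2$out; dim(Fl) <- c(h2o, h2o, N, sp@d2)
  Fl <- aperm(Fl, c(1, 2, 4, 3))
  dim(Fl) <- c(sp@flatten, N)
  Xf <- t(Fl)

  H1 <- .colShift(Xf %*% w$Wf1, w$bf1)
  A3 <- .lrelu(H1, a)
  dm1 <- dm2 <- NULL
  D1 <- if (training && keepProb < 1) {
    dm1 <- if (!is.null(dropoutMasks)) dropoutMasks[[1]]
           else (matrix(runif(length(A3)), nrow(A3)) < keepProb) / keepProb
    A3 * dm1
  } else A3
  H2 <- .colShift(D1 %*% w$Wf2, w$bf2)
  A4 <- .lrelu(H2, a)
  D2 <- if (training && keepProb < 1) {
    dm2 <- if (!is.null(dropoutMasks)) dropoutMasks[[2]]
           else (matrix(runif(length(A4)), nrow(A4)) < keepProb) / keepProb
    A4 * dm2
  } else A4
  logits <- .colShift(D2 %*% w$Wf3, w$bf3)

  if (keepCache)
    cache <- list(X = X, C1 = C1, B1 = B1, P1which = P1$which,
                  P1out = P1out, C2 = C2, B2 = B2, P2which = P2$which,
                  Xf = Xf, H1 = H1, A3 = A3, D1 = D1, H2 = H2, A4 = A4,
                  D2 = D2, dm1 = dm1, dm2 = dm2, h1 = h1, h2 = h2,
                  h2o = h2o)
  list(logits = logits, cache = if (keepCache) cache else NULL,
       batchStats = if (training) list(m1 = B1$mu, v1 = B1$v,
                                       m2 = B2$mu, v2 = B2$v) else NULL)
}

## Cross-entropy + L2 loss and gradients for one batch.
## targets: integer vector in {1, 2} (boundary, lesion).
.cnnLossGrad <- function(model, X, targets, eta, keepProb = 1,
                         dropoutMasks = NULL, wantGrads = TRUE) {
  sp <- model@spec
  w <- model@weights
  a <- sp@alpha
  N <- dim(X)[3]
  fw <- .cnnForward(model, X, training = TRUE, keepProb = keepProb,
                    dropoutMasks = dropoutMasks, keepCache = wantGrads)
  logits <- fw$logits
  P <- softmax2(logits)
  Tm <- matrix(0, N, 2); Tm[cbind(seq_len(N), targets)] <- 1
  ce <- -mean(log(pmax(P[cbind(seq_len(N), targets)], 1e-12)))
  l2 <- sum(w$W1^2) + sum(w$W2^2) + sum(w$Wf1^2) + sum(w$Wf2^2) +
    sum(w$Wf3^2)
  loss <- ce + eta / 2 * l2
  if (!wantGrads)
    return(list(loss = loss, ce = ce, P = P, batchStats = fw$batchStats))

  cc <- fw$cache
  gLogits <- (P - Tm) / N
  gWf3 <- crossprod(cc$D2, gLogits) + eta * w$Wf3
  gbf3 <- colSums(gLogits)
  gD2 <- tcrossprod(gLogits, w$Wf3)
  gA4 <- if (keepProb < 1) gD2 * cc$dm2 else gD2
  gH2 <- gA4 * .lreluGrad(cc$H2, a)
  gWf2 <- crossprod(cc$D1, gH2) + eta * w$Wf2
  gbf2 <- colSums(gH2)
  gD1 <- tcrossprod(gH2, w$Wf2)
  gA3 <- if (keepProb < 1) gD1 * cc$dm1 else gD1
  gH1 <- gA3 * .lreluGrad(cc$H1, a)
  gWf1 <- crossprod(cc$Xf, gH1) + eta * w$Wf1
  gbf1 <- colSums(gH1)
  gXf <- tcrossprod(gH1, w$Wf1)

  gFl <- t(gXf)
  dim(gFl) <- c(cc$h2o, cc$h2o, sp@d2, N)
  gP2 <- aperm(gFl, c(1, 2, 4, 3))
  gR2 <- cpp_pool2_back(gP2, cc$P2which, cc$h2, cc$h2, N, sp@d2)
  dim(gR2) <- c(cc$h2 * cc$h2 * N, sp@d2)
  bn2 <- cpp_bnrelu_bwd(gR2, cc$B2$xhat, cc$B2$pos, w$g2, cc$B2$istd, a)
  gW2 <- crossprod(cc$C2, bn2$gZ) + eta * w$W2
  gb2 <- colSums(bn2$gZ)
  ## scatter back through im2col of conv2
  gC2 <- tcrossprod(bn2$gZ, w$W2)          # (rows) x (25*d1)
  gP1 <- cpp_col2im(gC2, cc$h1, cc$h1, N, sp@d1, sp@s2)
  gR1 <- cpp_pool2_back(gP1, cc$P1which, sp@inputSize, sp@inputSize, N,
                        sp@d1)
  dim(gR1) <- c(sp@inputSize^2 * N, sp@d1)
  bn1 <- cpp_bnrelu_bwd(gR1, cc$B1$xhat, cc$B1$pos, w$g1, cc$B1$istd, a)
  gW1 <- crossprod(cc$C1, bn1$gZ) + eta * w$W1
  gb1 <- colSums(bn1$gZ)

  grads <- list(W1 = gW1, b1 = gb1, g1 = bn1$gGamma, be1 = bn1$gBeta,
                W2 = gW2, b2 = gb2, g2 = bn2$gGamma, be2 = bn2$gBeta,
                Wf1 = gWf1, bf1 = gbf1, Wf2 = gWf2, bf2 = gbf2,
                Wf3 = gWf3, bf3 = gbf3)
  list(loss = loss, ce = ce, P = P, grads = grads,
       batchStats = fw$batchStats)
}

#' Loss of the classifier on a batch
#'
#' Mean cross-entropy over the batch plus `eta/2` times the sum of squared
#' convolution and fully-connected weight matrices (biases and BN
#' scale/shift excluded).  Evaluated with training-mode batch normalization
#' and without dropout.
#'
#' @param model a [PatchCNN].
#' @param patches 32x32xN array (or a [PatchSet]).
#' @param labels character vector of `"boundary"` / `"lesion"` (taken from
#'   the [PatchSet] when omitted).
#' @param eta L2 coefficient.
#' @return scalar loss.
#' @export
cnnLoss <- function(model, patches, labels = NULL, eta = 1.0) {
  if (is(patches, "PatchSet")) {
    labels <- patchLabels(patches)
    patches <- patchArray(patches)
  }
  if (length(dim(patches)) == 2L) dim(patches) <- c(dim(patches), 1L)
  if (is.null(labels) || length(labels) != dim(patches)[3])
    stop("cnnLoss needs one label per patch")
  X <- patches; dim(X) <- c(dim(patches), 1L)
  targets <- match(labels, model@classes)
  .cnnLossGrad(model, X, targets, eta, keepProb = 1,
               wantGrads = FALSE)$loss
}

#' Train the patch classifier
#'
#' Minibatch SGD with the exponential learning-rate schedule, dropout on the
#' FC activations, and moving-average (shadow) weights and BN statistics;
#' a stratified validation split is held out and accuracy on it is logged
#' every `log_every` steps.  Fully reproducible given the seed.
#'
#' @param model a [PatchCNN] from [buildCNN()].
#' @param data a [PatchSet] containing both classes.
#' @param cfg a list from [trainingConfig()].
#' @return list with `model` (trained) and `log` (data.frame of step, lr,
#'   loss, validation accuracy).
#' @export
trainCNN <- function(model, data, cfg = trainingConfig()) {
  labs <- patchLabels(data)
  if (length(unique(labs)) < 2L)
    stop("training data must contain both classes")
  arr <- patchArray(data)
  n <- length(labs)
  withSeed(cfg$seed, {
    ## stratified validation split
    vIdx <- unlist(lapply(model@classes, function(cl) {
      ix <- which(labs == cl)
      sample(ix, max(1L, round(cfg$val_fraction * length(ix))))
    }))
    tIdx <- setdiff(seq_len(n), vIdx)
    targets <- match(labs, model@classes)
    Xval <- arr[, , vIdx, drop = FALSE]
    tval <- targets[vIdx]

    ## deep-copy the tensors: the training loop updates them in place
    w <- lapply(model@weights, function(x) x + 0)
    shadow <- lapply(model@shadow, function(x) x + 0)
    bn <- model@bn
    l2names <- c("W1", "W2", "Wf1", "Wf2", "Wf3")
    logRows <- vector("list", cfg$max_steps %/% cfg$log_every + 1L)
    nlog <- 0L
    pool <- integer(0)
    step0 <- model@step
    for (s in seq_len(cfg$max_steps)) {
      if (length(pool) < cfg$batch_size)
        pool <- c(pool, tIdx[sample.int(length(tIdx))])
      take <- pool[seq_len(cfg$batch_size)]
      pool <- pool[-seq_len(cfg$batch_size)]
      X <- arr[, , take, drop = FALSE]
      dim(X) <- c(dim(X), 1L)
      model@weights <- w; model@bn <- bn
      res <- .cnnLossGrad(model, X, targets[take], cfg$eta,
                          keepProb = cfg$keep_prob)
      step <- step0 + s
      lr <- cfg$initial_lr * cfg$lr_decay^(step %/% cfg$lr_decay_every)
      dec <- min(cfg$ma_decay, (1 + step) / (10 + step))
      for (nm in names(w))
        cpp_sgd_shadow(w[[nm]], res$grads[[nm]], shadow[[nm]], lr, dec)
      bs <- res$batchStats
      bn$rm1 <- dec * bn$rm1 + (1 - dec) * bs$m1
      bn$rv1 <- dec * bn$rv1 + (1 - dec) * bs$v1
      bn$rm2 <- dec * bn$rm2 + (1 - dec) * bs$m2
      bn$rv2 <- dec * bn$rv2 + (1 - dec) * bs$v2

      if (s %% cfg$log_every == 0L || s == cfg$max_steps) {
        model@weights <- w; model@shadow <- shadow; model@bn <- bn
        model@trained <- TRUE
        acc <- .cnnAccuracy(model, Xval, tval)
        nlog <- nlog + 1L
        logRows[[nlog]] <- data.frame(step = step, lr = lr,
                                      loss = res$loss, ce = res$ce,
                                      val_accuracy = acc)
      }
    }
    model@weights <- w; model@shadow <- shadow; model@bn <- bn
    model@step <- step0 + cfg$max_steps
    model@trained <- TRUE
    list(model = model,
         log = do.call(rbind, logRows[seq_len(nlog)]))
  })
}

.cnnAccuracy <- function(model, X, targets, chunk = 256L) {
  n <- dim(X)[3]
  correct <- 0L
  at <- 1L
  while (at <= n) {
    hi <- min(n, at + chunk - 1L)
    Xb <- X[, , at:hi, drop = FALSE]
    dim(Xb) <- c(dim(Xb), 1L)
    P <- softmax2(.cnnForward(model, Xb)$logits)
    correct <- correct + sum((P[, 2] > P[, 1]) + 1L == targets[at:hi])
    at <- hi + 1L
  }
  correct / n
}

#' Classify patches
#'
#' Inference uses the shadow (moving-average) weights and the frozen BN
#' running statistics, with dropout off: duplicate calls give identical
#' output.
#'
#' @param model a trained [PatchCNN].
#' @param patches a 32x32 matrix, 32x32xN array, or [PatchSet].
#' @return for a single patch a named vector `(boundary, lesion)`; for many,
#'   an N x 2 matrix of class probabilities (rows sum to 1).
#' @export
predictCNN <- function(model, patches) {
  if (!model@trained) stop("predictCNN requires a trained model")
  if (is(patches, "PatchSet")) patches <- patchArray(patches)
  single <- length(dim(patches)) == 2L
  if (single) dim(patches) <- c(dim(patches), 1L)
  X <- patches; dim(X) <- c(dim(patches), 1L)
  P <- softmax2(.cnnForward(model, X)$logits)
  colnames(P) <- model@classes
  if (single) P[1, ] else P
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is the serialized weight set plus a JSON sidecar recording
#' the architecture hyperparameters, the class label order and a format
#' version; `loadCheckpoint(saveCheckpoint(m))` reproduces predictions
#' bitwise.
#'
#' @param model a [PatchCNN].
#' @param path checkpoint path (`.rds`); the sidecar is `paste0(path,
#'   ".json")`.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns the [PatchCNN].
#' @export
saveCheckpoint <- function(model, path) {
  sp <- model@spec
  sidecar <- list(format_version = 1L,
                  classes = model@classes,
                  step = model@step, trained = model@trained,
                  spec = list(input_size = sp@inputSize, d1 = sp@d1,
                              d2 = sp@d2, s2 = sp@s2, fc1 = sp@fc1,
                              fc2 = sp@fc2, alpha = sp@alpha,
                              flatten = sp@flatten),
                  preprocessing = list(patch = 10L, upsampled = 32L,
                                       clahe_clip = 0.02,
                                       clahe_tiles = c(4L, 4L)))
  saveRDS(list(weights = model@weights, shadow = model@shadow,
               bn = model@bn), path)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  sidecarPath <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecarPath))
    stop("checkpoint or sidecar missing at: ", path)
  sc <- tryCatch(jsonlite::read_json(sidecarPath, simplifyVector = TRUE),
                 error = function(e) stop("unreadable sidecar: ",
                                          conditionMessage(e)))
  if (is.null(sc$format_version) || sc$format_version != 1L)
    stop("checkpoint format version mismatch: found ",
         sc$format_version %||% "<none>", ", expected 1")
  blob <- tryCatch(readRDS(path),
                   error = function(e) stop("corrupt checkpoint: ",
                                            conditionMessage(e)))
  spec <- cnnSpec(d1 = sc$spec$d1, d2 = sc$spec$d2, s2 = sc$spec$s2,
                  fc1 = sc$spec$fc1, fc2 = sc$spec$fc2,
                  input_size = sc$spec$input_size, alpha = sc$spec$alpha)
  if (spec@flatten != sc$spec$flatten)
    stop("sidecar spec inconsistent: flatten ", sc$spec$flatten,
         " vs computed ", spec@flatten)
  if (nrow(blob$weights$Wf1) != spec@flatten)
    stop("weights do not match the sidecar architecture")
  new("PatchCNN", spec = spec, weights = blob$weights,
      shadow = blob$shadow, bn = blob$bn,
      step = as.integer(sc$step), trained = isTRUE(sc$trained),
      classes = sc$classes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "PatchCNN", function(object) {
  sp <- object@spec
  cat(sprintf(
    "PatchCNN %dx%d -> conv5x5(%d) -> conv5x5(%d) -> fc %d/%d/2; step %d%s\n",
    sp@inputSize, sp@inputSize, sp@d1, sp@d2, sp@fc1, sp@fc2, object@step,
    if (object@trained) "" else " (untrained)"))
})
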