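## The slice-quality network: a residual convolutional regressor ending in a
## single sigmoid unit, trained with mean-square error by Adagrad.
##
## Three backbones are available. "mini" (stem + four residual blocks,
## channels 8/16/32) is the desk-scale default that trains in minutes on one
## CPU at 128-px input; "18-layer" and "101-layer" follow the classic
## basic-block and bottleneck residual layouts for full-scale use. The
## network is normalization-free: He initialization plus small-scale
## initialization of each block's last convolution keeps the residual
## stream well-conditioned without batch statistics, so inference is
## exactly deterministic.

#' Network and training configuration
#'
#' Defaults mirror the reference full-scale training recipe: learning rate
#' 5e-7, 200 epochs, minibatch size 8, MSE loss under Adagrad. For the
#' desk-scale "mini" backbone use [miniNetConfig()], whose learning rate and
#' epoch count are sized for from-scratch training at 128-px input.
#'
#' @param backboneDepth `"mini"`, `"18-layer"` or `"101-layer"`.
#' @param inputSize network input edge length in pixels.
#' @param usePretrainedBackbone if `TRUE`, a warning notes that no weight
#'   file is bundled and initialization falls back to random.
#' @param learningRate Adagrad learning rate.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed integer seed governing initialization and shuffling.
#' @return A named list of settings.
#' @export
netConfig <- function(backboneDepth = c("mini", "18-layer", "101-layer"),
                      inputSize = 128L, usePretrainedBackbone = FALSE,
                      learningRate = 5e-7, epochs = 200L, batchSize = 8L,
                      noiseAug = 0, seed = 1L) {
  backboneDepth <- match.arg(backboneDepth)
  list(backboneDepth = backboneDepth, inputSize = as.integer(inputSize),
       usePretrainedBackbone = isTRUE(usePretrainedBackbone),
       learningRate = learningRate, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), noiseAug = noiseAug,
       seed = as.integer(seed))
}

#' @rdname netConfig
#' @param noiseAug upper bound of the per-slice training noise
#'   augmentation: each epoch every standardized slice receives fresh
#'   Gaussian noise of sd `u ~ U(0, noiseAug)` and is rescaled by
#'   `1/sqrt(1 + u^2)` — exactly the effect a lower acquisition dose has on
#'   a standardized slice — teaching the regressor noise-level robustness.
#'   0 disables augmentation.
#' @export
miniNetConfig <- function(seed = 1L, inputSize = 128L, epochs = 10L,
                          learningRate = 0.01, batchSize = 8L,
                          noiseAug = 0.5) {
  netConfig("mini", inputSize = inputSize, learningRate = learningRate,
            epochs = epochs, batchSize = batchSize, noiseAug = noiseAug,
            seed = seed)
}

.archLayers <- function(depth) {
  conv <- function(k, s, p, cin, cout, act = TRUE)
    list(type = "conv", k = k, s = s, p = p, cin = cin, cout = cout, act = act)
  res <- function(ch) list(type = "res", ch = ch)
  down <- function(cin, cout) list(type = "down", cin = cin, cout = cout)
  bneck <- function(cin, mid, cout, stride, project)
    list(type = "bneck", cin = cin, mid = mid, cout = cout, stride = stride,
         project = project)
  ## the pooled feature vector is RMS-normalized per sample before the
  ## head: without batch statistics the raw pooled features are large and
  ## all-positive, and a few coordinated optimizer steps on the head can
  ## then saturate the sigmoid irrecoverably (MSE gradients vanish there)
  head <- function(nin) list(list(type = "gap"), list(type = "rmsnorm"),
                             list(type = "fc", nin = nin, nout = 1L))
  if (depth == "mini") {
    c(list(conv(5L, 4L, 2L, 1L, 8L)),
      list(res(8L), down(8L, 16L), res(16L), down(16L, 32L),
           res(32L), res(32L)),
      head(32L))
  } else if (depth == "18-layer") {
    c(list(conv(7L, 2L, 3L, 1L, 64L)),
      list(res(64L), res(64L), down(64L, 128L), res(128L),
           down(128L, 256L), res(256L), down(256L, 512L), res(512L)),
      head(512L))
  } else if (depth == "101-layer") {
    stage <- function(cin, mid, cout, n, stride) {
      c(list(bneck(cin, mid, cout, stride, TRUE)),
        replicate(n - 1L, bneck(cout, mid, cout, 1L, FALSE),
                  simplify = FALSE))
    }
    c(list(conv(7L, 2L, 3L, 1L, 64L)),
      stage(64L, 64L, 256L, 3L, 1L),
      stage(256L, 128L, 512L, 4L, 2L),
      stage(512L, 256L, 1024L, 23L, 2L),
      stage(1024L, 512L, 2048L, 3L, 2L),
      head(2048L))
  } else stop(sprintf("unsupported backbone depth '%s'", depth))
}

.heW <- function(k, cin, cout, scale = 1)
  array(stats::rnorm(k * k * cin * cout,
                     sd = scale * sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))

.initParams <- function(layers, seed) {
  withSeed(seed, lapply(layers, function(ly) {
    switch(ly$type,
      conv = list(w = .heW(ly$k, ly$cin, ly$cout), b = numeric(ly$cout)),
      res = list(w1 = .heW(3L, ly$ch, ly$ch), b1 = numeric(ly$ch),
                 w2 = .heW(3L, ly$ch, ly$ch, scale = 0.1),
                 b2 = numeric(ly$ch)),
      down = list(w1 = .heW(3L, ly$cin, ly$cout), b1 = numeric(ly$cout),
                  ws = .heW(1L, ly$cin, ly$cout), bs = numeric(ly$cout)),
      bneck = c(list(w1 = .heW(1L, ly$cin, ly$mid), b1 = numeric(ly$mid),
                     w2 = .heW(3L, ly$mid, ly$mid), b2 = numeric(ly$mid),
                     w3 = .heW(1L, ly$mid, ly$cout, scale = 0.1),
                     b3 = numeric(ly$cout)),
                if (ly$project)
                  list(ws = .heW(1L, ly$cin, ly$cout), bs = numeric(ly$cout))),
      gap = NULL,
      rmsnorm = NULL,
      ## unit-RMS features keep initial logits ~ N(0, 1) under this init:
      ## the sigmoid starts well inside its responsive range and the
      ## backbone receives a nonzero gradient from the first step
      fc = list(w = matrix(stats::rnorm(ly$nin * ly$nout,
                                        sd = 1 / sqrt(ly$nin)),
                           ly$nin, ly$nout),
                b = numeric(ly$nout)))
  }))
}

#' Build an (untrained) slice-quality network
#'
#' @param config a configuration from [netConfig()] or [miniNetConfig()].
#' @return An untrained [QualityModel-class]; identical configs and seeds
#'   yield identical initial weights.
#' @export
buildNetwork <- function(config) {
  layers <- .archLayers(config$backboneDepth)
  if (isTRUE(config$usePretrainedBackbone))
    warning("no pretrained backbone weights are bundled; using random init")
  new("QualityModel", config = config, layers = layers,
      params = .initParams(layers, config$seed), lossHistory = numeric(0))
}

.relu <- function(z) { z[z < 0] <- 0; z }

.forwardNet <- function(layers, params, x, keepCache = FALSE) {
  caches <- if (keepCache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]; pp <- params[[i]]
    if (ly$type == "conv") {
      z <- .conv2dForward(x, pp$w, pp$b, ly$s, ly$p)
      if (keepCache) caches[[i]] <- list(x = x, z = z)
      x <- if (isTRUE(ly$act)) .relu(z) else z
    } else if (ly$type == "res") {
      z1 <- .conv2dForward(x, pp$w1, pp$b1, 1L, 1L)
      a1 <- .relu(z1)
      s <- .conv2dForward(a1, pp$w2, pp$b2, 1L, 1L) + x
      if (keepCache) caches[[i]] <- list(x = x, z1 = z1, a1 = a1, s = s)
      x <- .relu(s)
    } else if (ly$type == "down") {
      s <- .conv2dForward(x, pp$w1, pp$b1, 2L, 1L) +
        .conv2dForward(x, pp$ws, pp$bs, 2L, 0L)
      if (keepCache) caches[[i]] <- list(x = x, s = s)
      x <- .relu(s)
    } else if (ly$type == "bneck") {
      z1 <- .conv2dForward(x, pp$w1, pp$b1, ly$stride, 0L)
      a1 <- .relu(z1)
      z2 <- .conv2dForward(a1, pp$w2, pp$b2, 1L, 1L)
      a2 <- .relu(z2)
      z3 <- .conv2dForward(a2, pp$w3, pp$b3, 1L, 0L)
      sc <- if (ly$project) .conv2dForward(x, pp$ws, pp$bs, ly$stride, 0L)
            else x
      s <- z3 + sc
      if (keepCache)
        caches[[i]] <- list(x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2, s = s)
      x <- .relu(s)
    } else if (ly$type == "gap") {
      d <- dim(x)
      if (keepCache) caches[[i]] <- list(dim = d)
      x <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
    } else if (ly$type == "rmsnorm") {
      r <- sqrt(colMeans(x^2) + 1e-8)
      out <- sweep(x, 2L, r, "/")
      if (keepCache) caches[[i]] <- list(r = r, out = out)
      x <- out
    } else if (ly$type == "fc") {
      if (keepCache) caches[[i]] <- list(x = x)
      x <- t(pp$w) %*% x + pp$b
    }
  }
  list(logits = as.numeric(x), caches = caches)
}

.backwardNet <- function(layers, params, caches, dlogit) {
  grads <- vector("list", length(layers))
  d <- dlogit                             # (nout, N)
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; pp <- params[[i]]; ca <- caches[[i]]
    if (ly$type == "fc") {
      grads[[i]] <- list(w = ca$x %*% t(d), b = rowSums(d))
      d <- pp$w %*% d
    } else if (ly$type == "rmsnorm") {
      ## f_hat = f / r with r = sqrt(mean f^2 + eps):
      ## df = (dfh - f_hat * mean(f_hat * dfh)) / r
      proj <- colSums(ca$out * d) / nrow(ca$out)
      d <- sweep(d - sweep(ca$out, 2L, proj, "*"), 2L, ca$r, "/")
    } else if (ly$type == "gap") {
      dd <- ca$dim
      d <- array(rep(as.vector(d) / (dd[1] * dd[2]), each = dd[1] * dd[2]),
                 dim = dd)
    } else if (ly$type == "conv") {
      dz <- if (isTRUE(ly$act)) d * (ca$z > 0) else d
      bk <- .conv2dBackward(ca$x, pp$w, dz, ly$s, ly$p)
      grads[[i]] <- list(w = bk$dw, b = bk$db)
      d <- bk$dx
    } else if (ly$type == "res") {
      ds <- d * (ca$s > 0)
      bk2 <- .conv2dBackward(ca$a1, pp$w2, ds, 1L, 1L)
      da1 <- bk2$dx * (ca$z1 > 0)
      bk1 <- .conv2dBackward(ca$x, pp$w1, da1, 1L, 1L)
      grads[[i]] <- list(w1 = bk1$dw, b1 = bk1$db, w2 = bk2$dw, b2 = bk2$db)
      d <- bk1$dx + ds
    } else if (ly$type == "down") {
      ds <- d * (ca$s > 0)
      bk1 <- .conv2dBackward(ca$x, pp$w1, ds, 2L, 1L)
      bks <- .conv2dBackward(ca$x, pp$ws, ds, 2L, 0L)
      grads[[i]] <- list(w1 = bk1$dw, b1 = bk1$db, ws = bks$dw, bs = bks$db)
      d <- bk1$dx + bks$dx
    } else if (ly$type == "bneck") {
      ds <- d * (ca$s > 0)
      bk3 <- .conv2dBackward(ca$a2, pp$w3, ds, 1L, 0L)
      da2 <- bk3$dx * (ca$z2 > 0)
      bk2 <- .conv2dBackward(ca$a1, pp$w2, da2, 1L, 1L)
      da1 <- bk2$dx * (ca$z1 > 0)
      bk1 <- .conv2dBackward(ca$x, pp$w1, da1, ly$stride, 0L)
      g <- list(w1 = bk1$dw, b1 = bk1$db, w2 = bk2$dw, b2 = bk2$db,
                w3 = bk3$dw, b3 = bk3$db)
      d <- bk1$dx
      if (ly$project) {
        bks <- .conv2dBackward(ca$x, pp$ws, ds, ly$stride, 0L)
        g$ws <- bks$dw; g$bs <- bks$db
        d <- d + bks$dx
      } else d <- d + ds
      grads[[i]] <- g
    }
  }
  grads
}

.adagrad <- function(params, state, grads, lr, layers, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    ## the head sees 1/sqrt(nin)-scale normalized features; scaling its
    ## step by sqrt(nin) equalizes logit-space step sizes with the body
    lri <- if (layers[[i]]$type == "fc") lr * sqrt(layers[[i]]$nin) else lr
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      state[[i]][[nm]] <- state[[i]][[nm]] + g * g
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lri * g / (sqrt(state[[i]][[nm]]) + eps)
    }
  }
  list(params = params, state = state)
}

## crop-then-standardize preprocessing shared by training and inference
.prepSlice <- function(slice, inputSize) {
  d <- dim(pixels(slice))
  if (any(d > inputSize)) slice <- cropCenter(slice, inputSize)
  d <- dim(pixels(slice))
  if (!all(d == inputSize))
    stop(sprintf("slice is %dx%d px but the network input size is %d",
                 d[1], d[2], inputSize))
  pixels(normalizeSlice(slice))
}

.datasetTensor <- function(dataset, inputSize) {
  n <- length(dataset)
  x <- array(0, dim = c(inputSize, inputSize, 1L, n))
  y <- numeric(n)
  for (i in seq_len(n)) {
    ls <- dataset[[i]]
    x[, , 1L, i] <- .prepSlice(ls@slice, inputSize)
    y[i] <- ls@target
  }
  list(x = x, y = y)
}

#' Train the slice-quality network
#'
#' Minimizes mean-square error between the sigmoid output and the
#' continuous quality targets with Adagrad, shuffling minibatches each
#' epoch. All randomness is governed by `config$seed`, so the same data,
#' config and seed reproduce the loss history exactly.
#'
#' @param model an untrained (or previously trained) [QualityModel-class].
#' @param dataset non-empty list of [LabeledSlice-class]; slices are
#'   center-cropped and standardized to the configured input size.
#' @param config training configuration (defaults to the model's).
#' @return The trained [QualityModel-class] with per-epoch training MSE
#'   appended to `lossHistory`.
#' @export
trainModel <- function(model, dataset, config = model@config) {
  if (length(dataset) == 0L) stop("dataset must be non-empty")
  dt <- .datasetTensor(dataset, config$inputSize)
  n <- length(dt$y)
  layers <- model@layers
  params <- model@params
  state <- rapply(params, function(a) a * 0, how = "replace")
  hist <- numeric(config$epochs)
  lr <- config$learningRate
  B <- config$batchSize
  withSeed(config$seed + 1L, {
    for (e in seq_len(config$epochs)) {
      perm <- sample.int(n)
      sse <- 0
      for (b0 in seq(1L, n, by = B)) {
        idx <- perm[b0:min(b0 + B - 1L, n)]
        xb <- dt$x[, , , idx, drop = FALSE]
        yb <- dt$y[idx]
        na <- config$noiseAug
        if (!is.null(na) && na > 0) {
          npix <- prod(dim(xb)[1:3])
          u <- stats::runif(length(idx), 0, na)
          xb <- (xb + array(stats::rnorm(length(xb)), dim(xb)) *
                   rep(u, each = npix)) / rep(sqrt(1 + u^2), each = npix)
        }
        fw <- .forwardNet(layers, params, xb, keepCache = TRUE)
        s <- stats::plogis(fw$logits)
        sse <- sse + sum((s - yb)^2)
        dlogit <- matrix(2 * (s - yb) * s * (1 - s) / length(idx), 1L)
        gr <- .backwardNet(layers, params, fw$caches, dlogit)
        upd <- .adagrad(params, state, gr, lr, layers)
        params <- upd$params
        state <- upd$state
      }
      hist[e] <- sse / n
    }
  })
  initialize(model, params = params,
             lossHistory = c(model@lossHistory, hist))
}

.predictMatrixBatch <- function(model, mats) {
  sz <- model@config$inputSize
  x <- array(0, dim = c(sz, sz, 1L, length(mats)))
  for (i in seq_along(mats)) x[, , 1L, i] <- mats[[i]]
  stats::plogis(.forwardNet(model@layers, model@params, x)$logits)
}

#' Predict the quality score of one preprocessed slice
#'
#' The slice must already match the network input size (crop and
#' standardization are applied automatically by [predictVolume()] and
#' [trainModel()]; here only standardization is applied if needed).
#'
#' @param model a [QualityModel-class].
#' @param slice a [SliceImage-class] or numeric matrix of the configured
#'   input size.
#' @return A single score strictly within (0, 1).
#' @export
predictSlice <- function(model, slice) {
  if (is.matrix(slice)) slice <- new("SliceImage", pixels = slice)
  d <- dim(pixels(slice))
  sz <- model@config$inputSize
  if (!all(d == sz))
    stop(sprintf("slice is %dx%d px but the network input size is %d",
                 d[1], d[2], sz))
  .predictMatrixBatch(model, list(pixels(normalizeSlice(slice))))
}

#' @rdname predictSlice
#' @param slices list of slices; scores are returned in order and agree
#'   with per-slice calls exactly.
#' @export
predictSlices <- function(model, slices) {
  vapply(slices, function(s) predictSlice(model, s), numeric(1))
}

#' Score every z-slice of a tomogram
#'
#' Applies the training-time preprocessing (centered crop to the input
#' size, zero-mean/unit-variance standardization) to each z-slice and
#' returns one score per slice in z order.
#'
#' @param model a trained [QualityModel-class].
#' @param volume a [TomoVolume-class]; slices must be at least the input
#'   size.
#' @param tomogramId id recorded on the profile.
#' @param chunkSize slices scored per forward pass.
#' @return A [QualityProfile-class].
#' @export
predictVolume <- function(model, volume, tomogramId = "", chunkSize = 16L) {
  stopifnot(is(volume, "TomoVolume"))
  nz <- nSlices(volume)
  sz <- model@config$inputSize
  mats <- lapply(seq_len(nz) - 1L, function(z)
    .prepSlice(getSlice(volume, z), sz))
  sc <- numeric(nz)
  for (b0 in seq(1L, nz, by = chunkSize)) {
    idx <- b0:min(b0 + chunkSize - 1L, nz)
    sc[idx] <- .predictMatrixBatch(model, mats[idx])
  }
  new("QualityProfile", scores = sc, tomogramId = tomogramId,
      apix = apix(volume))
}

#' Save / load a quality model checkpoint
#'
#' The checkpoint embeds the full configuration, weights and loss history.
#'
#' @param model a [QualityModel-class].
#' @param path checkpoint path (RDS).
#' @return `saveModel`: `path` invisibly; `loadModel`: the
#'   [QualityModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "QualityModel")) stop(sprintf("'%s' is not a model checkpoint", path))
  m
}
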