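#' Model configuration for the 1-D residual segment classifier
#'
#' A compact residual convolutional network over raw 0.4-s segments:
#' a stem convolution into the first channel width, `nBlocks` residual
#' blocks (two same-padding convolutions plus an identity or 1x1-projected
#' skip), average pooling between stages, global average pooling, and a
#' linear 3-way head with softmax. The contract is behavioural -- a
#' probability simplex per segment and desk-scale trainability -- not a
#' reproduction of any specific published architecture.
#'
#' @param nBlocks Number of residual blocks (default 2).
#' @param channels Channel width per block (length `nBlocks`).
#' @param kernel Odd convolution kernel size.
#' @param inputPool Average-pool stride applied to the raw input before
#'   the stem convolution (decimation; 1 disables). Useful for small,
#'   fast configurations where amplitude/energy structure matters more
#'   than fine temporal detail.
#' @param stemPool Average-pool stride after the stem convolution.
#' @param blockPool Average-pool stride after each residual block.
#' @param inputLength Segment length in samples (0.4 s at 10 kHz = 4000).
#' @param nClasses Number of diagnosis classes.
#' @return Configuration list of class `emgNetConfig`.
#' @export
emgNetConfig <- function(nBlocks = 2, channels = c(16, 32), kernel = 9,
                         inputPool = 1, stemPool = 4, blockPool = 4,
                         inputLength = 4000, nClasses = 3) {
  if (length(channels) != nBlocks)
    stop("channels must have one entry per block", call. = FALSE)
  if (kernel %% 2 == 0) stop("kernel must be odd", call. = FALSE)
  stopifnot(nBlocks >= 1, all(channels >= 1), inputPool >= 1,
            stemPool >= 1, blockPool >= 1, inputLength >= kernel,
            nClasses >= 2)
  structure(list(nBlocks = as.integer(nBlocks),
                 channels = as.integer(channels),
                 kernel = as.integer(kernel),
                 inputPool = as.integer(inputPool),
                 stemPool = as.integer(stemPool),
                 blockPool = as.integer(blockPool),
                 inputLength = as.integer(inputLength),
                 nClasses = as.integer(nClasses)),
            class = "emgNetConfig")
}

#' Training configuration
#'
#' @param learningRate Adam learning rate (default 1e-3).
#' @param batchSize Minibatch size (default 32).
#' @param evalEvery Validation-accuracy evaluation period in gradient
#'   updates (default 30).
#' @param patience Early stopping: number of consecutive evaluations
#'   without improvement after which training stops (default 100).
#' @param maxUpdates Hard cap on gradient updates so training terminates
#'   even if patience never triggers (default 20000).
#' @param seed Seed for batch order (and any other training randomness).
#' @return Configuration list of class `emgTrainConfig`.
#' @export
emgTrainConfig <- function(learningRate = 1e-3, batchSize = 32,
                           evalEvery = 30, patience = 100,
                           maxUpdates = 20000, seed = 1) {
  stopifnot(learningRate > 0, batchSize >= 1, evalEvery >= 1,
            patience >= 1, maxUpdates >= 1)
  structure(list(learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 evalEvery = as.integer(evalEvery),
                 patience = as.integer(patience),
                 maxUpdates = as.integer(maxUpdates),
                 seed = as.integer(seed)),
            class = "emgTrainConfig")
}

#' Inverse-frequency class weights
#'
#' Weights inversely proportional to the number of training segments per
#' class, normalised so the mean weight is 1.
#'
#' @param counts Vector of 3 per-class segment counts.
#' @return Numeric weight vector of the same length.
#' @export
#' @examples
#' classWeights(c(122, 160, 94))
classWeights <- function(counts) {
  if (any(counts <= 0))
    stop("every class must be present in the training set", call. = FALSE)
  w <- 1 / counts
  w / mean(w)
}

# ---- parameter initialisation -------------------------------------------

.initParams <- function(cfg) {
  K <- cfg$kernel
  he <- function(nOut, nIn) {
    matrix(rnorm(nOut * nIn, sd = sqrt(2 / nIn)), nOut, nIn)
  }
  p <- list()
  p[["conv0.W"]] <- he(cfg$channels[1], K * 1)
  p[["conv0.b"]] <- numeric(cfg$channels[1])
  cin <- cfg$channels[1]
  for (i in seq_len(cfg$nBlocks)) {
    ci <- cfg$channels[i]
    p[[sprintf("b%d.Wa", i)]] <- he(ci, K * cin)
    p[[sprintf("b%d.ba", i)]] <- numeric(ci)
    p[[sprintf("b%d.Wb", i)]] <- he(ci, K * ci)
    p[[sprintf("b%d.bb", i)]] <- numeric(ci)
    if (ci != cin) {
      p[[sprintf("b%d.Wp", i)]] <- he(ci, 1 * cin)
      p[[sprintf("b%d.bp", i)]] <- numeric(ci)
    }
    cin <- ci
  }
  p[["head.W"]] <- matrix(rnorm(cin * cfg$nClasses, sd = sqrt(1 / cin)),
                          cin, cfg$nClasses)
  p[["head.b"]] <- numeric(cfg$nClasses)
  p
}

#' Build an (untrained) segment classifier
#'
#' @param config An [emgNetConfig()].
#' @param seed Initialisation seed.
#' @return An [EMGNet-class], untrained.
#' @export
buildModel <- function(config = emgNetConfig(), seed = 1) {
  stopifnot(inherits(config, "emgNetConfig"))
  params <- withSeed(seed, .initParams(config))
  new("EMGNet", config = unclass(config), params = params)
}

# ---- forward / backward --------------------------------------------------

.softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# X: inputLength x B matrix. Returns probs (B x nClasses), logits, and a
# cache for the backward pass.
.forward <- function(params, cfg, X) {
  B <- ncol(X)
  cache <- list(layers = vector("list", cfg$nBlocks))
  X3 <- array(X, c(nrow(X), 1L, B))
  cache$Lraw <- nrow(X)
  inPool <- if (is.null(cfg$inputPool)) 1L else cfg$inputPool
  if (inPool > 1L) X3 <- .avgPoolForward(X3, inPool)
  Z0 <- .conv1dForward(X3, params[["conv0.W"]], params[["conv0.b"]])
  A0 <- Z0 * (Z0 > 0)
  cur <- .avgPoolForward(A0, cfg$stemPool)
  cache$X3 <- X3; cache$Z0 <- Z0; cache$L0 <- dim(A0)[1]
  for (i in seq_len(cfg$nBlocks)) {
    inCube <- cur
    Za <- .conv1dForward(inCube, params[[sprintf("b%d.Wa", i)]],
                         params[[sprintf("b%d.ba", i)]])
    Aa <- Za * (Za > 0)
    Zb <- .conv1dForward(Aa, params[[sprintf("b%d.Wb", i)]],
                         params[[sprintf("b%d.bb", i)]])
    hasProj <- !is.null(params[[sprintf("b%d.Wp", i)]])
    skip <- if (hasProj)
      .conv1dForward(inCube, params[[sprintf("b%d.Wp", i)]],
                     params[[sprintf("b%d.bp", i)]])
    else inCube
    S <- Zb + skip
    Ab <- S * (S > 0)
    cur <- .avgPoolForward(Ab, cfg$blockPool)
    cache$layers[[i]] <- list(inCube = inCube, Za = Za, Aa = Aa, S = S,
                              hasProj = hasProj, Lpre = dim(Ab)[1])
  }
  Fmat <- colMeans(cur)                       # channels x B
  if (is.null(dim(Fmat))) Fmat <- matrix(Fmat, ncol = B)
  logits <- t(Fmat) %*% params[["head.W"]] +
    matrix(params[["head.b"]], B, cfg$nClasses, byrow = TRUE)
  cache$Fmat <- Fmat; cache$Lgap <- dim(cur)[1]
  list(probs = .softmaxRows(logits), logits = logits, cache = cache)
}

# dlogits: B x nClasses. Returns gradients for every parameter plus the
# gradient with respect to the input matrix.
.backward <- function(params, cfg, cache, dlogits) {
  g <- list()
  B <- nrow(dlogits)
  g[["head.W"]] <- cache$Fmat %*% dlogits
  g[["head.b"]] <- colSums(dlogits)
  dF <- params[["head.W"]] %*% t(dlogits)     # channels x B
  Lg <- cache$Lgap
  dcur <- array(rep(dF / Lg, each = Lg), c(Lg, nrow(dF), B))
  for (i in rev(seq_len(cfg$nBlocks))) {
    ly <- cache$layers[[i]]
    dAb <- .avgPoolBackward(dcur, cfg$blockPool, ly$Lpre)
    dS <- dAb * (ly$S > 0)
    bb <- .conv1dBackward(ly$Aa, params[[sprintf("b%d.Wb", i)]], dS)
    g[[sprintf("b%d.Wb", i)]] <- bb$dW
    g[[sprintf("b%d.bb", i)]] <- bb$db
    dZa <- bb$dX * (ly$Za > 0)
    ba <- .conv1dBackward(ly$inCube, params[[sprintf("b%d.Wa", i)]], dZa)
    g[[sprintf("b%d.Wa", i)]] <- ba$dW
    g[[sprintf("b%d.ba", i)]] <- ba$db
    if (ly$hasProj) {
      bp <- .conv1dBackward(ly$inCube, params[[sprintf("b%d.Wp", i)]], dS)
      g[[sprintf("b%d.Wp", i)]] <- bp$dW
      g[[sprintf("b%d.bp", i)]] <- bp$db
      dcur <- ba$dX + bp$dX
    } else {
      dcur <- ba$dX + dS
    }
  }
  dA0 <- .avgPoolBackward(dcur, cfg$stemPool, cache$L0)
  dZ0 <- dA0 * (cache$Z0 > 0)
  b0 <- .conv1dBackward(cache$X3, params[["conv0.W"]], dZ0)
  g[["conv0.W"]] <- b0$dW
  g[["conv0.b"]] <- b0$db
  dX <- b0$dX
  inPool <- if (is.null(cfg$inputPool)) 1L else cfg$inputPool
  if (inPool > 1L) dX <- .avgPoolBackward(dX, inPool, cache$Lraw)
  dim(dX) <- c(dim(dX)[1], dim(dX)[3])
  list(grads = g, dInput = dX)
}

#' Weighted cross-entropy loss
#'
#' `sum(w[y] * -log p[y]) / sum(w[y])`; with unit weights this is the
#' plain mean cross-entropy.
#'
#' @param probs n x 3 matrix of class probabilities.
#' @param labels Diagnosis labels (factor/character) or integer codes 1..3.
#' @param weights Per-class weights (order M, N, NL).
#' @return Scalar loss.
#' @export
crossEntropyLoss <- function(probs, labels, weights = c(1, 1, 1)) {
  y <- .labelCodes(labels)
  w <- weights[y]
  py <- probs[cbind(seq_along(y), y)]
  sum(w * -log(pmax(py, 1e-12))) / sum(w)
}

.labelCodes <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% 1:3))
    as.integer(labels)
  } else {
    as.integer(diagnosisFactor(labels))
  }
}

.lossGrad <- function(probs, y, w) {
  B <- nrow(probs)
  d <- probs
  d[cbind(seq_len(B), y)] <- d[cbind(seq_len(B), y)] - 1
  d * (w[y] / sum(w[y]))
}

.adamStep <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.segMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "segments")
  else as.matrix(x)
}

.segLabels <- function(x, labels = NULL) {
  if (!is.null(labels)) return(.labelCodes(labels))
  if (is(x, "SummarizedExperiment"))
    return(.labelCodes(SummarizedExperiment::colData(x)$diagnosis))
  stop("labels are required when segments are a plain matrix",
       call. = FALSE)
}

#' Train the segment classifier
#'
#' Minibatch Adam on class-weighted cross-entropy (weights inversely
#' proportional to the per-class training segment counts), with early
#' stopping on validation segment accuracy evaluated every
#' `trainConfig$evalEvery` updates: training stops after
#' `trainConfig$patience` consecutive evaluations without improvement and
#' the best-validation checkpoint is restored.
#'
#' @param model An [EMGNet-class] from [buildModel()].
#' @param train,val Segment containers: `inputLength x n` matrices or
#'   `SummarizedExperiment`s from [segmentCohort()].
#' @param trainLabels,valLabels Labels, required for plain matrices.
#' @param trainConfig An [emgTrainConfig()].
#' @return The trained [EMGNet-class] with its training history.
#' @export
trainModel <- function(model, train, val, trainLabels = NULL,
                       valLabels = NULL, trainConfig = emgTrainConfig()) {
  stopifnot(is(model, "EMGNet"), inherits(trainConfig, "emgTrainConfig"))
  if (is(train, "SummarizedExperiment") && is(val, "SummarizedExperiment")) {
    shared <- intersect(SummarizedExperiment::colData(train)$patient_id,
                        SummarizedExperiment::colData(val)$patient_id)
    if (length(shared))
      stop("train and validation sets share patient(s): ",
           paste(head(shared, 3), collapse = ", "), call. = FALSE)
  }
  Xtr <- .segMatrix(train); ytr <- .segLabels(train, trainLabels)
  Xva <- .segMatrix(val); yva <- .segLabels(val, valLabels)
  if (ncol(Xtr) == 0 || ncol(Xva) == 0)
    stop("train and validation sets must be non-empty", call. = FALSE)
  if (length(unique(ytr)) < 2)
    stop("single-class training set", call. = FALSE)
  cfg <- model@config
  if (nrow(Xtr) != cfg$inputLength)
    stop("segment length ", nrow(Xtr), " does not match model input length ",
         cfg$inputLength, call. = FALSE)
  w <- numeric(cfg$nClasses)
  cnt <- tabulate(ytr, nbins = cfg$nClasses)
  if (any(cnt == 0))
    stop("every class must be present in the training set", call. = FALSE)
  w <- classWeights(cnt)

  params <- model@params
  state <- list(m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  best <- list(acc = -Inf, params = params, update = 0L)
  sinceBest <- 0L
  hist <- list()
  lossAcc <- 0; lossN <- 0L

  withSeed(trainConfig$seed, {
    queue <- sample(ncol(Xtr))
    qpos <- 1L
    nextBatch <- function() {
      bs <- min(trainConfig$batchSize, ncol(Xtr))
      if (qpos + bs - 1L > length(queue)) {
        queue <<- sample(ncol(Xtr))
        qpos <<- 1L
      }
      idx <- queue[qpos:(qpos + bs - 1L)]
      qpos <<- qpos + bs
      idx
    }
    for (upd in seq_len(trainConfig$maxUpdates)) {
      idx <- nextBatch()
      fw <- .forward(params, cfg, Xtr[, idx, drop = FALSE])
      y <- ytr[idx]
      lossAcc <- lossAcc + crossEntropyLoss(fw$probs, y, w)
      lossN <- lossN + 1L
      bw <- .backward(params, cfg, fw$cache, .lossGrad(fw$probs, y, w))
      st <- .adamStep(params, bw$grads, state, trainConfig$learningRate, upd)
      params <- st$params; state <- st$state
      if (upd %% trainConfig$evalEvery == 0L) {
        acc <- .segmentAccuracy(params, cfg, Xva, yva)
        hist[[length(hist) + 1L]] <-
          data.frame(update = upd, train_loss = lossAcc / lossN,
                     val_accuracy = acc)
        lossAcc <- 0; lossN <- 0L
        if (acc > best$acc) {
          best <- list(acc = acc, params = params, update = upd)
          sinceBest <- 0L
        } else {
          # a tie is not an improvement (it counts toward patience), but
          # among equally accurate checkpoints keep the most trained one
          if (acc == best$acc)
            best <- list(acc = acc, params = params, update = upd)
          sinceBest <- sinceBest + 1L
          if (sinceBest >= trainConfig$patience) break
        }
      }
    }
  })
  model@params <- best$params
  model@history <- if (length(hist)) do.call(rbind, hist) else data.frame()
  model@bestUpdate <- as.integer(best$update)
  model@trained <- TRUE
  model
}

.segmentAccuracy <- function(params, cfg, X, y, batchSize = 512L) {
  n <- ncol(X)
  correct <- 0L
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1L)
    p <- .forward(params, cfg, X[, idx, drop = FALSE])$probs
    correct <- correct + sum(max.col(p, ties.method = "first") == y[idx])
  }
  correct / n
}

#' Segment-level class probabilities
#'
#' Deterministic given the weights and independent of batching.
#'
#' @param model A trained [EMGNet-class].
#' @param segments `inputLength x n` matrix or `SummarizedExperiment`.
#' @param batchSize Forward batch size.
#' @return n x 3 matrix of class probabilities (columns M, N, NL).
#' @export
predictSegments <- function(model, segments, batchSize = 256L) {
  stopifnot(is(model, "EMGNet"))
  X <- .segMatrix(segments)
  cfg <- model@config
  if (nrow(X) != cfg$inputLength)
    stop("segment length ", nrow(X), " does not match model input length ",
         cfg$inputLength, call. = FALSE)
  n <- ncol(X)
  out <- matrix(NA_real_, n, cfg$nClasses,
                dimnames = list(colnames(X), diagnosisLevels()))
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1L)
    out[idx, ] <- .forward(model@params, cfg, X[, idx, drop = FALSE])$probs
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing serialised object holding the
#' configuration, weights and training history.
#'
#' @param model An [EMGNet-class].
#' @param path Checkpoint file path.
#' @return `saveModel`: the path, invisibly. `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "EMGNet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "EMGNet")) stop("not an EMGNet checkpoint: ", path,
                                 call. = FALSE)
  model
}
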