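# A small (bi)LSTM sequence classifier written with plain matrix
# algebra: forward pass, backpropagation through time, Adam updates.
# Sequences are short (3 time bins of 8 band ratios), so an explicit
# R implementation is fast enough for the full experiment grid.

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' LSTM classifier configuration
#'
#' @param hiddenUnits memory cells per LSTM direction (HU; swept over
#'   20-200, default 200).
#' @param layers 1 (default) or 2 stacked LSTM layers.
#' @param bidirectional process the 3-bin sequence in both directions
#'   (default `TRUE`).
#' @param dropout dropout probability after each LSTM layer during
#'   training (0 or 0.2 in the architecture variants; default 0).
#' @param nIterations optimizer steps (mini-batch updates, NI; swept
#'   over 200-2000, default 1000).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param batchSize mini-batch size (default 128).
#' @param clipNorm global gradient-norm clip (default 1).
#' @param transform feature transform before the network: `"log1p"`
#'   (default; compresses the 1-50x ratio dynamic range) or `"raw"`.
#' @param seed RNG seed for weight initialisation and batch shuffling.
#' @return list with class `"LstmConfig"`.
#' @export
lstmConfig <- function(hiddenUnits = 200L, layers = 1L,
                       bidirectional = TRUE, dropout = 0,
                       nIterations = 1000L, learningRate = 1e-3,
                       batchSize = 128L, clipNorm = 1,
                       transform = c("log1p", "raw"), seed = 1L) {
  stopifnot(hiddenUnits >= 1L, nIterations >= 0L,
            dropout >= 0, dropout < 1, layers %in% c(1L, 2L))
  structure(list(
    hiddenUnits = as.integer(hiddenUnits), layers = as.integer(layers),
    bidirectional = isTRUE(bidirectional), dropout = dropout,
    nIterations = as.integer(nIterations), learningRate = learningRate,
    batchSize = as.integer(batchSize), clipNorm = clipNorm,
    transform = match.arg(transform), seed = as.integer(seed)
  ), class = "LstmConfig")
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.initDir <- function(D, H) {
  b <- rep(0, 4L * H)
  b[(H + 1L):(2L * H)] <- 1          # forget-gate bias
  list(Wx = .glorot(4L * H, D), Wh = .glorot(4L * H, H), b = b)
}

#' Build an (untrained) LSTM classifier
#'
#' Architecture: sequence input (8 features x 3 time steps) ->
#' (bi)LSTM layer(s) with `hiddenUnits` cells per direction, optional
#' dropout after each LSTM layer -> fully connected layer -> softmax
#' over the four event classes. Weights are Glorot-uniform with a
#' forget-gate bias of 1, seeded from the config.
#'
#' @param config an [lstmConfig()].
#' @param inputDim features per time step (default 8).
#' @return An [LstmClassifier-class].
#' @export
buildLstm <- function(config = lstmConfig(), inputDim = 8L) {
  set.seed(config$seed)
  H <- config$hiddenUnits
  dirs <- if (config$bidirectional) c("f", "b") else "f"
  params <- list()
  D <- inputDim
  for (l in seq_len(config$layers)) {
    for (d in dirs) {
      p <- .initDir(D, H)
      params[[paste0("L", l, d, "_Wx")]] <- p$Wx
      params[[paste0("L", l, d, "_Wh")]] <- p$Wh
      params[[paste0("L", l, d, "_b")]] <- p$b
    }
    D <- H * length(dirs)            # next layer consumes the sequence output
  }
  params[["FC_W"]] <- .glorot(4L, D)
  params[["FC_b"]] <- rep(0, 4L)
  new("LstmClassifier", config = unclass(config), params = params,
      classes = eventClasses(), trained = FALSE, history = numeric(),
      manifest = list())
}

#' Number of learnable parameters
#'
#' @param model an [LstmClassifier-class].
#' @return Integer parameter count.
#' @export
nParams <- function(model) sum(vapply(model@params, length, 1L))

# ---- single-direction forward/backward over a D x T x B input -------

.dirForward <- function(X, Wx, Wh, b) {
  d <- dim(X); D <- d[1]; Tn <- d[2]; B <- d[3]
  H <- ncol(Wh)
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  Hs <- array(0, c(H, Tn, B))
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[, t, ], D, B)
    Z <- Wx %*% xt + Wh %*% h + b
    i <- .sigmoid(Z[1:H, , drop = FALSE])
    f <- .sigmoid(Z[(H + 1):(2 * H), , drop = FALSE])
    g <- tanh(Z[(2 * H + 1):(3 * H), , drop = FALSE])
    o <- .sigmoid(Z[(3 * H + 1):(4 * H), , drop = FALSE])
    cPrev <- cc
    cc <- f * cPrev + i * g
    tc <- tanh(cc)
    h <- o * tc
    Hs[, t, ] <- h
    cache[[t]] <- list(i = i, f = f, g = g, o = o, cPrev = cPrev, tc = tc,
                       xt = xt)
  }
  list(Hs = Hs, cache = cache)
}

.dirBackward <- function(dHs, fwd, Wx, Wh) {
  Hs <- fwd$Hs; cache <- fwd$cache
  H <- dim(Hs)[1]; Tn <- dim(Hs)[2]; B <- dim(Hs)[3]
  D <- ncol(Wx)
  dWx <- matrix(0, nrow(Wx), D); dWh <- matrix(0, nrow(Wh), H)
  db <- rep(0, 4L * H)
  dX <- array(0, c(D, Tn, B))
  dh <- matrix(0, H, B); dc <- matrix(0, H, B)
  for (t in rev(seq_len(Tn))) {
    k <- cache[[t]]
    dhT <- matrix(dHs[, t, ], H, B) + dh
    do <- dhT * k$tc * k$o * (1 - k$o)
    dc <- dc + dhT * k$o * (1 - k$tc^2)
    di <- dc * k$g * k$i * (1 - k$i)
    df <- dc * k$cPrev * k$f * (1 - k$f)
    dg <- dc * k$i * (1 - k$g^2)
    dZ <- rbind(di, df, dg, do)
    hPrev <- if (t > 1L) matrix(Hs[, t - 1L, ], H, B) else matrix(0, H, B)
    dWx <- dWx + tcrossprod(dZ, k$xt)
    dWh <- dWh + tcrossprod(dZ, hPrev)
    db <- db + rowSums(dZ)
    dX[, t, ] <- crossprod(Wx, dZ)
    dh <- crossprod(Wh, dZ)
    dc <- dc * k$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

.revTime <- function(A) A[, rev(seq_len(dim(A)[2])), , drop = FALSE]

# Full-model forward. Returns logits/probs plus everything the
# backward pass needs. Dropout masks are sampled here when training.
.modelForward <- function(params, X, config, training = FALSE) {
  layers <- config$layers
  bi <- config$bidirectional
  H <- config$hiddenUnits
  caches <- vector("list", layers)
  masks <- vector("list", layers)
  inp <- X
  for (l in seq_len(layers)) {
    fwd <- .dirForward(inp, params[[paste0("L", l, "f_Wx")]],
                       params[[paste0("L", l, "f_Wh")]],
                       params[[paste0("L", l, "f_b")]])
    if (bi) {
      bwd <- .dirForward(.revTime(inp), params[[paste0("L", l, "b_Wx")]],
                         params[[paste0("L", l, "b_Wh")]],
                         params[[paste0("L", l, "b_b")]])
      Y <- array(0, c(2L * H, dim(inp)[2], dim(inp)[3]))
      Y[1:H, , ] <- fwd$Hs
      Y[(H + 1):(2 * H), , ] <- .revTime(bwd$Hs)
    } else {
      bwd <- NULL
      Y <- fwd$Hs
    }
    if (training && config$dropout > 0) {
      keep <- 1 - config$dropout
      m <- array(stats::rbinom(length(Y), 1L, keep) / keep, dim(Y))
      Y <- Y * m
      masks[[l]] <- m
    }
    caches[[l]] <- list(fwd = fwd, bwd = bwd, input = inp, Y = Y)
    inp <- Y
  }
  Tn <- dim(X)[2]
  top <- caches[[layers]]$Y
  feat <- if (bi)
    rbind(matrix(top[1:H, Tn, ], H), matrix(top[(H + 1):(2 * H), 1L, ], H))
  else matrix(top[, Tn, ], H)
  logits <- params$FC_W %*% feat + params$FC_b
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  ez <- exp(z)
  probs <- sweep(ez, 2L, colSums(ez), "/")
  list(logits = logits, probs = probs, feat = feat, caches = caches,
       masks = masks)
}

# Backward pass: cross-entropy gradient through FC and all LSTM layers.
.modelBackward <- function(params, fw, Yhot, config) {
  layers <- config$layers; bi <- config$bidirectional
  H <- config$hiddenUnits
  B <- ncol(Yhot)
  grads <- list()
  dlogits <- (fw$probs - Yhot) / B
  grads$FC_W <- tcrossprod(dlogits, fw$feat)
  grads$FC_b <- rowSums(dlogits)
  dfeat <- crossprod(params$FC_W, dlogits)

  Tn <- dim(fw$caches[[1]]$input)[2]
  dY <- NULL
  for (l in rev(seq_len(layers))) {
    cl <- fw$caches[[l]]
    outDim <- if (bi) 2L * H else H
    if (l == layers) {
      dY <- array(0, c(outDim, Tn, B))
      if (bi) {
        dY[1:H, Tn, ] <- dfeat[1:H, , drop = FALSE]
        dY[(H + 1):(2 * H), 1L, ] <- dfeat[(H + 1):(2 * H), , drop = FALSE]
      } else dY[, Tn, ] <- dfeat
    }
    if (!is.null(fw$masks[[l]])) dY <- dY * fw$masks[[l]]
    gF <- .dirBackward(dY[1:H, , , drop = FALSE], cl$fwd,
                       params[[paste0("L", l, "f_Wx")]],
                       params[[paste0("L", l, "f_Wh")]])
    grads[[paste0("L", l, "f_Wx")]] <- gF$dWx
    grads[[paste0("L", l, "f_Wh")]] <- gF$dWh
    grads[[paste0("L", l, "f_b")]] <- gF$db
    dInp <- gF$dX
    if (bi) {
      gB <- .dirBackward(.revTime(dY[(H + 1):(2 * H), , , drop = FALSE]),
                         cl$bwd,
                         params[[paste0("L", l, "b_Wx")]],
                         params[[paste0("L", l, "b_Wh")]])
      grads[[paste0("L", l, "b_Wx")]] <- gB$dWx
      grads[[paste0("L", l, "b_Wh")]] <- gB$dWh
      grads[[paste0("L", l, "b_b")]] <- gB$db
      dInp <- dInp + .revTime(gB$dX)
    }
    dY <- dInp
  }
  grads
}

.applyTransform <- function(x, transform) {
  if (transform == "log1p") log1p(x) else x
}

.oneHot <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) stop("labels outside the four event classes")
  Y <- matrix(0, length(classes), length(idx))
  Y[cbind(idx, seq_along(idx))] <- 1
  Y
}

#' Train the classifier
#'
#' Runs `nIterations` Adam mini-batch steps of categorical
#' cross-entropy on the (transformed) 8 x 3 feature matrices. Batches
#' walk shuffled epochs; shuffling, initialisation and dropout all
#' derive from `seed`, so the same data and seed reproduce the same
#' model exactly. `nIterations = 0` returns the model unchanged.
#'
#' @param model an [LstmClassifier-class] from [buildLstm()].
#' @param features numeric array 8 x 3 x N of relative powers (or a
#'   [GroundTruthSet-class], in which case `labels` defaults to its
#'   labels).
#' @param labels event class per feature (character or factor).
#' @param nIterations optimizer steps; default from the model config.
#' @param seed RNG seed for shuffling/dropout; default model config
#'   seed.
#' @return The trained [LstmClassifier-class] with loss `history` and
#'   a training `manifest`.
#' @export
trainLstm <- function(model, features, labels = NULL,
                      nIterations = NULL, seed = NULL) {
  if (is(features, "GroundTruthSet")) {
    if (is.null(labels)) labels <- eventInfo(features)$label
    features <- eventFeatures(features)
  }
  config <- model@config
  if (is.null(nIterations)) nIterations <- config$nIterations
  if (is.null(seed)) seed <- config$seed
  N <- dim(features)[3]
  stopifnot(N == length(labels), N >= 1L)
  if (length(unique(as.character(labels))) < 2L)
    stop("degenerate-data error: training set has a single class")
  if (nIterations == 0L) return(model)

  X <- .applyTransform(features, config$transform)
  Yhot <- .oneHot(labels, model@classes)
  params <- model@params
  mAdam <- lapply(params, function(p) p * 0)
  vAdam <- mAdam
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learningRate
  B <- min(config$batchSize, N)

  set.seed(seed)
  order <- sample.int(N)
  pos <- 1L
  history <- numeric(nIterations)
  for (it in seq_len(nIterations)) {
    if (pos + B - 1L > N) { order <- sample.int(N); pos <- 1L }
    idx <- order[pos:(pos + B - 1L)]
    pos <- pos + B
    fw <- .modelForward(params, X[, , idx, drop = FALSE], config,
                        training = TRUE)
    history[it] <- -mean(log(pmax(
      fw$probs[cbind(match(as.character(labels[idx]), model@classes),
                     seq_along(idx))], 1e-12)))
    grads <- .modelBackward(params, fw, Yhot[, idx, drop = FALSE], config)

    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
    if (is.finite(gn) && gn > config$clipNorm) {
      sc <- config$clipNorm / gn
      grads <- lapply(grads, function(g) g * sc)
    }
    for (nm in names(params)) {
      g <- grads[[nm]]
      mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g
      vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * g^2
      mh <- mAdam[[nm]] / (1 - beta1^it)
      vh <- vAdam[[nm]] / (1 - beta2^it)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  model@params <- params
  model@trained <- TRUE
  model@history <- history
  model@manifest <- list(
    seed = seed, nIterations = nIterations, nEvents = N,
    dataHash = dataHash(features), classCounts = table(as.character(labels))
  )
  model
}

#' Predict event classes
#'
#' Softmax class probabilities and argmax labels for 8 x 3 feature
#' matrices. Ties are broken toward the first class in the fixed
#' class order. Batch prediction equals event-by-event prediction.
#'
#' @param object an [LstmClassifier-class].
#' @param features numeric array 8 x 3 x N (or a single 8 x 3 matrix,
#'   or a [GroundTruthSet-class]).
#' @return list: `label` (factor over the class order) and `prob`
#'   (4 x N matrix of class probabilities, columns summing to 1).
#' @export
setMethod("predict", "LstmClassifier", function(object, features) {
  if (is(features, "GroundTruthSet")) features <- eventFeatures(features)
  if (length(dim(features)) == 2L)
    features <- array(features, c(dim(features), 1L))
  if (dim(features)[1] != 8L || dim(features)[2] != 3L)
    stop("input error: features must be 8 x 3 (x N)")
  X <- .applyTransform(features, object@config$transform)
  fw <- .modelForward(object@params, X, object@config, training = FALSE)
  win <- apply(fw$probs, 2L, function(p) which(p >= max(p) - 1e-12)[1L])
  list(label = factor(object@classes[win], levels = object@classes),
       prob = fw$probs)
})

#' Hash of a numeric dataset
#'
#' MD5 of the serialised array, used in training manifests to tie a
#' model to the exact data it saw.
#'
#' @param x any R object.
#' @return hex string.
#' @export
dataHash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2L)
  unname(tools::md5sum(tf))
}

#' Save / load a classifier with its manifest
#'
#' Checkpoints are plain RDS files holding the weights, config,
#' classes and manifest.
#'
#' @param model an [LstmClassifier-class].
#' @param path file path.
#' @return `path` (save) or the restored model (load).
#' @export
saveLstm <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               classes = model@classes, trained = model@trained,
               history = model@history, manifest = model@manifest),
          path)
  invisible(path)
}

#' @rdname saveLstm
#' @export
loadLstm <- function(path) {
  x <- readRDS(path)
  new("LstmClassifier", config = x$config, params = x$params,
      classes = x$classes, trained = x$trained, history = x$history,
      manifest = x$manifest)
}
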