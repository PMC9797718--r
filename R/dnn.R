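## Feed-forward network engine: plain matrix backpropagation.
## Layout: widths = c(inputDim, hiddenUnits, 1). W[[l]] is widths[l+1] x
## widths[l]; forward activations are ReLU on hidden layers and a linear or
## sigmoid scalar head. Dropout is inverted (masked activations scaled by
## 1/(1-p)) and active only during training.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.relu <- function(x) pmax(x, 0)

.dnn_widths <- function(spec) c(spec@inputDim, spec@hiddenUnits, 1L)

#' Number of trainable parameters of a layer-width sequence
#'
#' For consecutive widths `w_i -> w_{i+1}` each dense layer contributes
#' `w_i * w_{i+1}` weights plus `w_{i+1}` biases.
#'
#' @param widths integer vector of layer widths including input and output.
#' @return integer parameter count.
#' @examples
#' countParameters(c(1308, 200, 100, 1))  # 282001
#' @export
countParameters <- function(widths) {
  if (any(widths < 1)) stop("all layer widths must be >= 1")
  sum(widths[-length(widths)] * widths[-1]) + sum(widths[-1])
}

#' @rdname nParameters
#' @export
setMethod("nParameters", "NetworkSpec",
  function(x) countParameters(.dnn_widths(x)))

#' @rdname nParameters
#' @export
setMethod("nParameters", "DNNModel", function(x) nParameters(x@spec))

#' Build an untrained feed-forward network
#'
#' Weights use seeded Glorot-style uniform initialization,
#' `U(-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out)))`; biases start
#' at zero.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer seed for the initialization draw.
#' @param featureNames optional character vector recorded as the schema
#'   fingerprint; `predict` rejects inputs whose columns do not match.
#' @return an untrained [DNNModel-class].
#' @export
buildDNN <- function(spec, seed = 1L, featureNames = character()) {
  validObject(spec)
  widths <- .dnn_widths(spec)
  params <- .with_seed(seed, {
    lapply(seq_len(length(widths) - 1L), function(l) {
      fan_in <- widths[l]; fan_out <- widths[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_out, fan_in)
    })
  })
  biases <- lapply(widths[-1], function(w) numeric(w))
  new("DNNModel", spec = spec, weights = params, biases = biases,
      history = data.frame(epoch = integer(), loss = numeric()),
      featureNames = as.character(featureNames), trained = FALSE)
}

## Forward pass. Returns activations per layer; drop masks when training.
.dnn_forward <- function(W, b, X, task, dropout = 0, training = FALSE) {
  L <- length(W)
  A <- vector("list", L + 1L); A[[1L]] <- X
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- tcrossprod(A[[l]], W[[l]])
    Z <- sweep(Z, 2L, b[[l]], "+")
    if (l < L) {
      H <- .relu(Z)
      if (training && dropout > 0) {
        mask <- matrix(stats::rbinom(length(H), 1L, 1 - dropout) / (1 - dropout),
                       nrow(H), ncol(H))
        H <- H * mask
        masks[[l]] <- mask
      }
      A[[l + 1L]] <- H
    } else {
      A[[l + 1L]] <- if (task == "classification") .sigmoid(Z) else Z
    }
  }
  list(A = A, masks = masks)
}

## Mean loss over a batch: MSE or binary cross-entropy.
.dnn_loss <- function(pred, y, task) {
  if (task == "classification") {
    p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else mean((pred - y)^2)
}

## Backward pass; returns per-layer gradients of the mean batch loss.
.dnn_backward <- function(W, fwd, y, task, dropout) {
  A <- fwd$A; L <- length(W); n <- nrow(A[[1L]])
  pred <- A[[L + 1L]]
  ## For MSE: dL/dz = 2(z - y)/n. For BCE through the sigmoid: (z - y)/n.
  delta <- if (task == "classification") (pred - y) / n else 2 * (pred - y) / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(delta, A[[l]])
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% W[[l]]
      if (dropout > 0 && !is.null(fwd$masks[[l - 1L]]))
        delta <- delta * fwd$masks[[l - 1L]]
      delta <- delta * (A[[l]] > 0)  # ReLU gate
    }
  }
  list(W = gW, b = gb)
}

.opt_state <- function(W, b) {
  zeros <- function(p) lapply(p, function(x) x * 0)
  list(mW = zeros(W), vW = zeros(W), mb = zeros(b), vb = zeros(b), t = 0L)
}

.opt_step <- function(params, grads, state, optimizer, lr) {
  eps <- 1e-8
  state$t <- state$t + 1L
  upd <- function(p, g, m, v, mkey, vkey) {
    for (l in seq_along(p)) {
      if (optimizer == "adam") {
        m[[l]] <- 0.9 * m[[l]] + 0.1 * g[[l]]
        v[[l]] <- 0.999 * v[[l]] + 0.001 * g[[l]]^2
        mhat <- m[[l]] / (1 - 0.9^state$t)
        vhat <- v[[l]] / (1 - 0.999^state$t)
        p[[l]] <- p[[l]] - lr * mhat / (sqrt(vhat) + eps)
      } else if (optimizer == "rmsprop") {
        v[[l]] <- 0.9 * v[[l]] + 0.1 * g[[l]]^2
        p[[l]] <- p[[l]] - lr * g[[l]] / (sqrt(v[[l]]) + eps)
      } else {
        p[[l]] <- p[[l]] - lr * g[[l]]
      }
    }
    list(p = p, m = m, v = v)
  }
  rw <- upd(params$W, grads$W, state$mW, state$vW)
  rb <- upd(params$b, grads$b, state$mb, state$vb)
  state$mW <- rw$m; state$vW <- rw$v; state$mb <- rb$m; state$vb <- rb$v
  list(W = rw$p, b = rb$p, state = state)
}

#' Train a feed-forward network
#'
#' Mini-batch training of the network with the configured loss (MSE for
#' regression, mean binary cross-entropy for classification) and optimizer
#' (Adam, RMSprop or plain SGD). All randomness (shuffling, dropout masks)
#' flows through `config@seed`, so a fixed seed reproduces the loss history
#' bit for bit.
#'
#' @param model an untrained [DNNModel-class] from [buildDNN()], or a
#'   [NetworkSpec-class] (a model is then built with the config seed).
#' @param x samples-in-rows feature matrix, or a [SampleSet-class]
#'   (standardize first).
#' @param y numeric labels; taken from the SampleSet when `x` is one.
#' @param config a [TrainingConfig-class].
#' @return the trained [DNNModel-class] with per-epoch loss history.
#' @export
trainDNN <- function(model, x, y = NULL, config = trainingConfig()) {
  validObject(config)
  if (is(model, "NetworkSpec"))
    model <- buildDNN(model, seed = config@seed,
                      featureNames = if (is(x, "SampleSet"))
                        rownames(SummarizedExperiment::assay(x)) else colnames(x))
  if (is(x, "SampleSet")) {
    if (is.null(y)) y <- sampleLabels(x, config@task)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x); y <- as.numeric(y)
  .check_predict_input(model@featureNames, x)
  if (ncol(x) != model@spec@inputDim)
    stop("input dimension ", ncol(x), " does not match spec ", model@spec@inputDim)
  if (length(y) != nrow(x)) stop("label length does not match sample count")
  if (model@spec@task == "classification" && !all(y %in% c(0, 1)))
    stop("classification labels must be 0/1")

  W <- model@weights; b <- model@biases
  task <- model@spec@task; p <- model@spec@dropoutRate
  n <- nrow(x); bs <- min(config@batchSize, n)
  state <- .opt_state(W, b)
  losses <- numeric(config@epochs)

  .with_seed(config@seed + 1L, {
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1L, n)]
        Xb <- x[idx, , drop = FALSE]; yb <- y[idx]
        fwd <- .dnn_forward(W, b, Xb, task, p, training = TRUE)
        loss <- .dnn_loss(fwd$A[[length(fwd$A)]], yb, task)
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (learning rate ", config@learningRate, ")")
        epoch_loss <- epoch_loss + loss * length(idx)
        grads <- .dnn_backward(W, fwd, yb, task, p)
        step <- .opt_step(list(W = W, b = b), grads, state,
                          config@optimizer, config@learningRate)
        W <- step$W; b <- step$b; state <- step$state
      }
      losses[epoch] <- epoch_loss / n
    }
  })
  model@weights <- W
  model@biases <- b
  model@history <- data.frame(epoch = seq_len(config@epochs), loss = losses)
  model@trained <- TRUE
  model
}

.check_predict_input <- function(featureNames, x) {
  if (length(featureNames) && !is.null(colnames(x)) &&
      !identical(colnames(x), featureNames))
    stop("feature columns do not match the model's schema fingerprint ",
         "(expected ", length(featureNames), " features starting ",
         featureNames[1L], ")")
  invisible(TRUE)
}

#' Predict scores from a trained network
#'
#' Dropout is disabled at inference. Regression returns unbounded real
#' scores (pseudo-log-IC50); classification returns sigmoid scores in
#' `[0, 1]`.
#'
#' @param object a trained [DNNModel-class].
#' @param newdata samples-in-rows matrix or [SampleSet-class] standardized
#'   with the training statistics.
#' @param ... ignored.
#' @return numeric score vector.
#' @export
setMethod("predict", "DNNModel", function(object, newdata, ...) {
  x <- if (is(newdata, "SampleSet")) featureMatrix(newdata) else as.matrix(newdata)
  if (ncol(x) != object@spec@inputDim)
    stop("dimension mismatch: model expects ", object@spec@inputDim,
         " features, got ", ncol(x))
  .check_predict_input(object@featureNames, x)
  fwd <- .dnn_forward(object@weights, object@biases, x, object@spec@task,
                      dropout = 0, training = FALSE)
  as.numeric(fwd$A[[length(fwd$A)]])
})

#' Save / load a network model
#'
#' The model is written as a directory holding `spec.json` (architecture,
#' task, history, schema fingerprint) and `parameters.bin`, a flat
#' little-endian double archive of all weights and biases in layer order.
#'
#' @param model a [DNNModel-class].
#' @param path directory to create/read.
#' @return `loadDNNModel` returns the restored [DNNModel-class].
#' @export
saveDNNModel <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  spec <- list(inputDim = model@spec@inputDim,
               hiddenUnits = model@spec@hiddenUnits,
               dropoutRate = model@spec@dropoutRate,
               task = model@spec@task,
               featureNames = model@featureNames,
               trained = model@trained,
               history = model@history)
  jsonlite::write_json(spec, file.path(path, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- c(unlist(lapply(model@weights, as.numeric)),
            unlist(model@biases))
  writeBin(flat, file.path(path, "parameters.bin"), size = 8L,
           endian = "little")
  invisible(path)
}

#' @rdname saveDNNModel
#' @export
loadDNNModel <- function(path) {
  spec <- jsonlite::read_json(file.path(path, "spec.json"),
                              simplifyVector = TRUE)
  ns <- networkSpec(spec$inputDim, spec$hiddenUnits, spec$dropoutRate, spec$task)
  model <- buildDNN(ns, seed = 0L, featureNames = spec$featureNames)
  widths <- .dnn_widths(ns)
  nflat <- countParameters(widths)
  flat <- readBin(file.path(path, "parameters.bin"), "double", n = nflat,
                  size = 8L, endian = "little")
  pos <- 0L
  for (l in seq_along(model@weights)) {
    k <- widths[l] * widths[l + 1L]
    model@weights[[l]] <- matrix(flat[pos + seq_len(k)], widths[l + 1L], widths[l])
    pos <- pos + k
  }
  for (l in seq_along(model@biases)) {
    k <- widths[l + 1L]
    model@biases[[l]] <- flat[pos + seq_len(k)]
    pos <- pos + k
  }
  model@trained <- isTRUE(spec$trained)
  if (!is.null(spec$history) && length(spec$history))
    model@history <- as.data.frame(spec$history)
  model
}
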