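# Training and evaluation: SGD with momentum and weight decay on softmax
# cross-entropy, per-epoch history, confusion-matrix evaluation. Defaults
# follow the study protocol: learning rate 0.001, momentum 0.9, weight
# decay 0.01, batch size 8, 50 epochs, no schedule, final-epoch model.

#' TrainConfig: optimisation hyperparameters
#'
#' @slot learningRate SGD learning rate (default 0.001).
#' @slot momentum Momentum coefficient (default 0.9).
#' @slot weightDecay L2 weight-decay coefficient (default 0.01).
#' @slot batchSize Minibatch size (default 8).
#' @slot epochs Number of full passes (default 50).
#' @slot rngSeed Integer seed driving shuffling (and, via [buildModel()],
#'   initialisation).
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", momentum = "numeric",
                 weightDecay = "numeric", batchSize = "numeric",
                 epochs = "numeric", rngSeed = "numeric"),
  validity = function(object) {
    if (object@learningRate <= 0 || object@momentum < 0 ||
        object@weightDecay < 0 || object@batchSize < 1)
      return("hyperparameters must be positive")
    if (object@epochs < 1) return("epochs must be >= 1")
    TRUE
  })

#' @describeIn TrainConfig-class Constructor with the study defaults.
#' @param learningRate,momentum,weightDecay,batchSize,epochs,rngSeed
#'   See slots.
#' @export
trainConfig <- function(learningRate = 0.001, momentum = 0.9,
                        weightDecay = 0.01, batchSize = 8, epochs = 50,
                        rngSeed = 1L)
  new("TrainConfig", learningRate = learningRate, momentum = momentum,
      weightDecay = weightDecay, batchSize = batchSize, epochs = epochs,
      rngSeed = rngSeed)

# softmax cross-entropy loss and logit gradient for one batch
softmaxLoss <- function(logits, yIdx) {
  p <- softmaxCols(logits)
  n <- ncol(p)
  loss <- -mean(log(pmax(p[cbind(yIdx, seq_len(n))], 1e-12)))
  dlogits <- p
  dlogits[cbind(yIdx, seq_len(n))] <- dlogits[cbind(yIdx, seq_len(n))] - 1
  list(loss = loss, dlogits = dlogits / n)
}

#' Train a SeedNet classifier
#'
#' Runs exactly `config@epochs` passes of momentum SGD (velocity
#' `v <- momentum v + grad + weightDecay * w`; `w <- w - lr v`) on softmax
#' cross-entropy, recording training loss and, when validation data are
#' given, validation loss/accuracy per epoch. All shuffling derives from
#' `config@rngSeed`; two runs with identical data and seeds are identical.
#' The final-epoch model is returned (no early stopping).
#'
#' @param model A [SeedNet-class] (initialisation fixes its own seed via
#'   [buildModel()]).
#' @param x H x W x 3 x N training inputs on the \[0, 1\] scale.
#' @param y Training labels (must all be in `modelClasses(model)`).
#' @param valX,valY Optional validation data.
#' @param config A [TrainConfig-class].
#' @return List with `model` (trained [SeedNet-class]) and `history`
#'   (data frame: epoch, train_loss, val_loss, val_acc).
#' @export
trainModel <- function(model, x, y, valX = NULL, valY = NULL,
                       config = trainConfig()) {
  stopIfNot(length(dim(x)) == 4 && dim(x)[4] >= 1,
            "invalid argument: empty training data")
  y <- as.character(y)
  stopIfNot(length(y) == dim(x)[4],
            "invalid argument: labels must match sample count")
  stopIfNot(all(y %in% model@classes),
            "invalid argument: labels outside the model's class set")
  yIdx <- match(y, model@classes)
  N <- dim(x)[4]
  params <- lapply(model@params, function(p) p + 0)  # unshare for in-place SGD
  state <- model@state
  vel <- lapply(params, function(p) p * 0)
  lr <- config@learningRate; mom <- config@momentum; wd <- config@weightDecay
  bs <- as.integer(config@batchSize)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))
  for (ep in seq_len(config@epochs)) {
    ord <- withSeed(childSeed(config@rngSeed, ep), sample(N))
    losses <- numeric(0)
    for (b0 in seq(1, N, by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1, N)]
      xb <- x[, , , idx, drop = FALSE]
      fw <- netForward(model@arch, params, state, xb, train = TRUE)
      state <- fw$state
      sl <- softmaxLoss(fw$y, yIdx[idx])
      losses <- c(losses, sl$loss)
      gacc <- new.env()
      gacc$g <- list()
      netBackward(model@arch, params, fw$caches, sl$dlogits, gacc)
      for (nm in names(gacc$g))
        cpp_sgd_step(params[[nm]], vel[[nm]], gacc$g[[nm]], lr, mom, wd)
    }
    vl <- NA_real_; va <- NA_real_
    if (!is.null(valX)) {
      ev <- evalPass(model@arch, params, state, valX,
                     match(as.character(valY), model@classes))
      vl <- ev$loss; va <- ev$acc
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = vl, val_acc = va))
  }
  trained <- model
  trained@params <- params
  trained@state <- state
  list(model = trained, history = hist)
}

# inference pass in batches; returns loss, accuracy and predicted indices
evalPass <- function(arch, params, state, x, yIdx, batch = 32L) {
  N <- dim(x)[4]
  pred <- integer(N)
  loss <- 0
  for (b0 in seq(1, N, by = batch)) {
    idx <- b0:min(b0 + batch - 1, N)
    fw <- netForward(arch, params, state, x[, , , idx, drop = FALSE],
                     train = FALSE)
    p <- softmaxCols(fw$y)
    pred[idx] <- apply(p, 2, which.max)
    if (!is.null(yIdx))
      loss <- loss - sum(log(pmax(p[cbind(yIdx[idx], seq_along(idx))], 1e-12)))
  }
  list(pred = pred, loss = if (is.null(yIdx)) NA_real_ else loss / N,
       acc = if (is.null(yIdx)) NA_real_ else mean(pred == yIdx))
}

#' Build a confusion matrix from true and predicted labels
#'
#' Rows are true classes, columns predicted classes, in the order of
#' `classes`.
#'
#' @param true,pred Label vectors of equal length.
#' @param classes Class label order (default: sorted union).
#' @return K x K integer matrix with dimnames.
#' @export
confusionMatrix <- function(true, pred, classes = sort(unique(c(true, pred)))) {
  true <- factor(as.character(true), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  stopIfNot(!anyNA(true) && !anyNA(pred),
            "invalid argument: labels outside the class set")
  tab <- table(true = true, pred = pred)
  matrix(as.integer(tab), nrow(tab), ncol(tab),
         dimnames = list(classes, classes))
}

#' Evaluate a model on test data
#'
#' Argmax prediction per sample, accumulated into a confusion matrix by
#' (true, predicted) class.
#'
#' @param model A [SeedNet-class].
#' @param x H x W x 3 x N inputs.
#' @param y True labels.
#' @param batchSize Inference batch size (default 32).
#' @return K x K confusion matrix (rows true, columns predicted).
#' @export
evaluateModel <- function(model, x, y, batchSize = 32L) {
  stopIfNot(length(dim(x)) == 4 && dim(x)[4] >= 1,
            "invalid argument: empty test data")
  y <- as.character(y)
  stopIfNot(all(y %in% model@classes),
            "invalid argument: labels outside the model's class set")
  ev <- evalPass(model@arch, model@params, model@state, x, NULL, batchSize)
  confusionMatrix(y, model@classes[ev$pred], model@classes)
}
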