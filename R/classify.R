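# Train/validation splitting, one-vs-rest SVM, a small MLP baseline,
# and the precision/sensitivity/specificity report suite.

#' Random train/validation split
#'
#' Deterministic under \code{seed}. With stratification the training
#' share is rounded per class; otherwise over the whole set (a 100-sample
#' set at fraction 0.7 yields exactly 70/30).
#'
#' @param labels class token per sample.
#' @param trainFraction proportion assigned to training, in (0, 1).
#' @param seed integer seed.
#' @param stratified sample within classes (default); every class then
#'   needs at least 2 samples.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
splitData <- function(labels, trainFraction = 0.7, seed = 1L,
                      stratified = TRUE) {
  if (trainFraction <= 0 || trainFraction >= 1)
    .stopf("trainFraction must be in (0, 1)")
  n <- length(labels)
  .withSeed(seed, {
    if (stratified) {
      cl <- split(seq_len(n), labels)
      small <- names(cl)[lengths(cl) < 2L]
      if (length(small))
        .stopf("stratified split needs >= 2 samples per class; offending: %s",
               paste(small, collapse = ", "))
      train <- unlist(lapply(cl, function(idx)
        sample(idx, round(trainFraction * length(idx)))), use.names = FALSE)
    } else {
      train <- sample(seq_len(n), round(trainFraction * n))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

.standardize <- function(x, center = NULL, scl = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scl)) {
    scl <- apply(x, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
  }
  list(x = sweep(sweep(x, 2L, center), 2L, scl, `/`), center = center,
       scale = scl)
}

#' Train a one-vs-rest support vector machine
#'
#' Fits one binary max-margin machine per class (\pkg{e1071} backend)
#' on standardized features; prediction takes the class with the largest
#' decision value. The default RBF kernel width follows
#' \code{gamma = 1 / (d * mean feature variance)}.
#'
#' @param x numeric feature matrix, one sample per row.
#' @param y class tokens (at least two distinct).
#' @param kernel \code{"radial"} (default) or \code{"linear"}.
#' @param cost soft-margin cost C.
#' @param gamma RBF width; default as above.
#' @param seed integer seed (fixes any backend tie-breaking).
#' @return an \linkS4class{SVMEnsemble}.
#' @export
trainSVM <- function(x, y, kernel = "radial", cost = 1, gamma = NULL,
                     seed = 1L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) .stopf("training set contains a single class")
  st <- .standardize(as.matrix(x))
  if (is.null(gamma)) {
    v <- mean(apply(st$x, 2L, stats::var))
    gamma <- 1 / (ncol(x) * max(v, 1e-12))
  }
  models <- .withSeed(seed, lapply(classes, function(cl) {
    yk <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(st$x, yk, kernel = kernel, cost = cost, gamma = gamma,
               scale = FALSE)
  }))
  names(models) <- classes
  new("SVMEnsemble", models = models, classes = classes,
      center = st$center, scale = st$scale, kernel = kernel,
      cost = cost, gamma = gamma)
}

#' @describeIn trainSVM predict class tokens; ties go to the first class
#'   in sorted order.
#' @param object fitted ensemble.
#' @param newdata feature matrix.
#' @param ... unused.
#' @export
setMethod("predict", "SVMEnsemble", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  xs <- .standardize(newdata, object@center, object@scale)$x
  dec <- vapply(object@classes, function(cl) {
    p <- stats::predict(object@models[[cl]], xs, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    # orient so positive means "this class"
    if (grepl("^pos/", colnames(dv)[1L])) dv[, 1L] else -dv[, 1L]
  }, numeric(nrow(xs)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1L)
  object@classes[max.col(dec, ties.method = "first")]
})

setMethod("show", "SVMEnsemble", function(object) {
  cat(sprintf("SVMEnsemble: %d one-vs-rest %s machines (C %.3g, gamma %.3g), classes: %s\n",
              length(object@models), object@kernel, object@cost,
              object@gamma, paste(object@classes, collapse = ", ")))
})

#' Support vector counts of the ensemble
#'
#' @param model an \linkS4class{SVMEnsemble}.
#' @return named integer vector, one entry per class machine.
#' @export
supportVectorCounts <- function(model) {
  vapply(model@models, function(m) nrow(m$SV), integer(1L))
}

#' Train the single-hidden-layer network baseline
#'
#' One hidden layer with ReLU activation, softmax output, cross-entropy
#' loss, plain per-sample stochastic gradient descent with a fixed
#' learning rate (default 0.001). Provided as a secondary baseline; the
#' SVM is the primary model.
#'
#' @param x feature matrix; \code{y} class tokens.
#' @param y class tokens.
#' @param hidden hidden units.
#' @param lr learning rate.
#' @param epochs passes over the training set.
#' @param seed integer seed (weight init and sample order).
#' @return an \linkS4class{MLPModel}.
#' @export
trainMLP <- function(x, y, hidden = 16L, lr = 0.001, epochs = 300L,
                     seed = 1L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) .stopf("training set contains a single class")
  st <- .standardize(as.matrix(x))
  X <- st$x
  n <- nrow(X); d <- ncol(X); K <- length(classes)
  yIdx <- match(y, classes)
  .withSeed(seed, {
    W1 <- matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden * K, sd = sqrt(2 / hidden)), hidden, K)
    b2 <- numeric(K)
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        xi <- X[i, ]
        h <- pmax(drop(xi %*% W1) + b1, 0)
        o <- drop(h %*% W2) + b2
        p <- exp(o - max(o)); p <- p / sum(p)
        dO <- p
        dO[yIdx[i]] <- dO[yIdx[i]] - 1
        dW2 <- outer(h, dO)
        dH <- drop(W2 %*% dO) * (h > 0)
        W2 <- W2 - lr * dW2
        b2 <- b2 - lr * dO
        W1 <- W1 - lr * outer(xi, dH)
        b1 <- b1 - lr * dH
      }
    }
    new("MLPModel", W1 = W1, b1 = b1, W2 = W2, b2 = b2, classes = classes,
        center = st$center, scale = st$scale)
  })
}

#' @describeIn trainMLP predict class tokens.
#' @param object fitted network.
#' @param newdata feature matrix.
#' @param ... unused.
#' @export
setMethod("predict", "MLPModel", function(object, newdata, ...) {
  X <- .standardize(as.matrix(newdata), object@center, object@scale)$x
  H <- pmax(X %*% object@W1 + matrix(object@b1, nrow(X), length(object@b1),
                                     byrow = TRUE), 0)
  O <- H %*% object@W2 + matrix(object@b2, nrow(X), length(object@b2),
                                byrow = TRUE)
  object@classes[max.col(O, ties.method = "first")]
})

#' Metric report from a confusion matrix
#'
#' One-vs-rest reading per class c: \code{precision = TP/(TP+FP)},
#' \code{sensitivity = TP/(TP+FN)}, \code{specificity = TN/(TN+FP)}, all
#' in percent. Rows of \code{confusion} are true classes, columns
#' predicted. A metric with a zero denominator is \code{NA} and excluded
#' from the macro average.
#'
#' @param confusion square count matrix with matching row/column names
#'   (unnamed matrices get classes \code{c1, c2, ...}).
#' @return a \linkS4class{ClassifierReport}.
#' @export
reportFromConfusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (is.null(rownames(confusion))) {
    cls <- paste0("c", seq_len(nrow(confusion)))
    dimnames(confusion) <- list(cls, cls)
  }
  cls <- rownames(confusion)
  tot <- sum(confusion)
  pc <- do.call(rbind, lapply(seq_along(cls), function(k) {
    tp <- confusion[k, k]
    fn <- sum(confusion[k, ]) - tp
    fp <- sum(confusion[, k]) - tp
    tn <- tot - tp - fn - fp
    data.frame(class = cls[k], tp = tp, fp = fp, fn = fn, tn = tn,
               precision   = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
               sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
  }))
  rownames(pc) <- NULL
  macro <- c(precision = mean(pc$precision, na.rm = TRUE),
             sensitivity = mean(pc$sensitivity, na.rm = TRUE),
             specificity = mean(pc$specificity, na.rm = TRUE))
  new("ClassifierReport", confusion = confusion, perClass = pc,
      macro = macro, accuracy = 100 * sum(diag(confusion)) / tot)
}

#' Evaluate a classifier on a validation set
#'
#' Predicts, tabulates the class-by-class confusion matrix over the
#' union of true and trained classes, and derives the metric suite with
#' \code{\link{reportFromConfusion}}.
#'
#' @param model an \linkS4class{SVMEnsemble} or \linkS4class{MLPModel}.
#' @param x validation features; \code{y} true tokens.
#' @param y true class tokens.
#' @return a \linkS4class{ClassifierReport}.
#' @export
evaluateClassifier <- function(model, x, y) {
  if (length(y) == 0L) .stopf("empty validation set")
  y <- as.character(y)
  unknown <- setdiff(unique(y), model@classes)
  if (length(unknown))
    .stopf("validation set contains unknown class(es): %s",
           paste(unknown, collapse = ", "))
  pred <- predict(model, x)
  cls <- model@classes
  conf <- table(factor(y, levels = cls), factor(pred, levels = cls))
  conf <- matrix(conf, nrow = length(cls), dimnames = list(cls, cls))
  reportFromConfusion(conf)
}

#' @rdname ClassifierReport-class
#' @aliases confusionCounts perClassMetrics macroMetrics overallAccuracy
#' @export
setMethod("confusionCounts", "ClassifierReport", function(x) x@confusion)

#' @rdname ClassifierReport-class
#' @export
setMethod("perClassMetrics", "ClassifierReport", function(x) x@perClass)

#' @rdname ClassifierReport-class
#' @export
setMethod("macroMetrics", "ClassifierReport", function(x) x@macro)

#' @rdname ClassifierReport-class
#' @export
setMethod("overallAccuracy", "ClassifierReport", function(x) x@accuracy)

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport: accuracy %.2f%% over %d samples\n",
              object@accuracy, sum(object@confusion)))
  cat(sprintf("  macro precision %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              object@macro["precision"], object@macro["sensitivity"],
              object@macro["specificity"]))
  print(object@confusion)
})
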