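#' Fit a small rectifier multi-layer perceptron classifier
#'
#' One hidden layer of rectified linear units, a sigmoid output, binary
#' cross-entropy loss with an L2 weight penalty, trained full-batch with
#' Adam. Features are standardized internally using training-set statistics
#' (stored for prediction). The positive class is `poor` prognosis.
#'
#' @param x samples x features numeric matrix.
#' @param y factor with levels `good`/`poor` (or coercible).
#' @param hidden hidden layer width.
#' @param l2 L2 penalty coefficient on the weight matrices.
#' @param epochs full-batch Adam steps.
#' @param learning_rate Adam step size.
#' @param seed integer seed for weight initialization.
#' @return object of class `omnirank_mlp`.
#' @export
mlp_fit <- function(x, y, hidden = 64L, l2 = 1e-3, epochs = 300L,
                    learning_rate = 1e-2, seed = 1L) {
  y <- factor(as.character(y), levels = c("good", "poor"))
  if (anyNA(y) || nlevels(droplevels(y)) < 2L)
    stop_validation("y must contain both good and poor samples")
  yb <- as.numeric(y == "poor")
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  n <- ncol(xs)
  set.seed(seed)
  W1 <- matrix(rnorm(n * hidden, sd = sqrt(2 / n)), n, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
  b2 <- 0
  adam <- function(p) list(m = p * 0, v = p * 0, t = 0L)
  st <- list(W1 = adam(W1), b1 = adam(b1), W2 = adam(W2), b2 = adam(b2))
  step <- function(p, g, s) {
    s$t <- s$t + 1L
    s$m <- 0.9 * s$m + 0.1 * g
    s$v <- 0.999 * s$v + 0.001 * g * g
    list(p = p - learning_rate * (s$m / (1 - 0.9^s$t)) /
           (sqrt(s$v / (1 - 0.999^s$t)) + 1e-8), s = s)
  }
  m <- nrow(xs)
  for (ep in seq_len(epochs)) {
    a1 <- sweep(xs %*% W1, 2, b1, "+")
    h1 <- a1; h1[h1 < 0] <- 0
    o <- 1 / (1 + exp(-(h1 %*% W2 + b2)))
    d2 <- (o - yb) / m
    gW2 <- t(h1) %*% d2 + l2 * W2
    gb2 <- sum(d2)
    da1 <- (d2 %*% t(W2)) * (a1 > 0)
    gW1 <- t(xs) %*% da1 + l2 * W1
    gb1 <- colSums(da1)
    u <- step(W1, gW1, st$W1); W1 <- u$p; st$W1 <- u$s
    u <- step(b1, gb1, st$b1); b1 <- u$p; st$b1 <- u$s
    u <- step(W2, gW2, st$W2); W2 <- u$p; st$W2 <- u$s
    u <- step(b2, gb2, st$b2); b2 <- u$p; st$b2 <- u$s
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = mu,
                 scale = sg, features = colnames(x)),
            class = "omnirank_mlp")
}

#' @rdname mlp_fit
#' @param object fitted `omnirank_mlp`.
#' @param newdata samples x features matrix (columns matched by name when
#'   both are named).
#' @param ... unused.
#' @return `predict()` returns the per-sample probability of poor prognosis.
#' @export
predict.omnirank_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) && !is.null(object$features)) {
    if (!all(object$features %in% colnames(x)))
      stop_validation("newdata lacks features: ",
                      paste(head(setdiff(object$features, colnames(x)), 5),
                            collapse = ", "))
    x <- x[, object$features, drop = FALSE]
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  a1 <- sweep(xs %*% object$W1, 2, object$b1, "+")
  a1[a1 < 0] <- 0
  as.vector(1 / (1 + exp(-(a1 %*% object$W2 + object$b2))))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation: the probability that a random `poor` sample
#' scores above a random `good` sample, with ties counted half.
#'
#' @param scores numeric predictions (higher = more poor-like).
#' @param y labels with levels `good`/`poor`.
#' @return AUC in `[0,1]`, or NA if a class is absent.
#' @export
auc_rank <- function(scores, y) {
  y <- factor(as.character(y), levels = c("good", "poor"))
  pos <- y == "poor"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# seeded stratified fold assignment; reduces k (with a warning) when the
# rarer class cannot reach every fold
stratified_folds <- function(y, k, seed) {
  y <- factor(as.character(y), levels = c("good", "poor"))
  minc <- min(table(y))
  if (minc < k) {
    warning("reducing folds from ", k, " to ", minc,
            " so both classes reach every fold")
    k <- minc
  }
  if (k < 2L) stop_validation("cannot form 2 stratified folds")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated prognosis AUC
#'
#' Stratified k-fold cross-validation of the rectifier MLP on a feature
#' table: per fold the classifier is trained on the remaining folds and
#' scored on the held-out samples; reported are the per-fold AUCs, their
#' mean (headline figure) and the AUC of the pooled out-of-fold predictions.
#'
#' @param table a [assemble_dataset()] result (or a list with `x`, `y`).
#' @param n_folds number of folds (default 10).
#' @param hidden,l2,epochs,learning_rate MLP settings, see [mlp_fit()].
#' @param seed controls fold assignment and per-fold initialization.
#' @return list with `fold_auc`, `mean_auc`, `pooled_auc`, `predictions`
#'   (out-of-fold scores in sample order) and `folds`.
#' @export
crossval_auc <- function(table, n_folds = 10L, hidden = 64L, l2 = 1e-3,
                         epochs = 300L, learning_rate = 1e-2, seed = 1L) {
  x <- table$x
  y <- table$y
  fold <- withCallingHandlers(
    stratified_folds(y, n_folds, seed),
    warning = function(w) {
      # fold reduction is reported once at this level
      invokeRestart("muffleWarning")
    })
  k <- max(fold)
  if (k < n_folds)
    warning("folds reduced to ", k, " (class too small for ", n_folds, ")")
  preds <- rep(NA_real_, length(y))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- mlp_fit(x[tr, , drop = FALSE], y[tr], hidden = hidden, l2 = l2,
                   epochs = epochs, learning_rate = learning_rate,
                   seed = seed + f)
    p <- predict(fit, x[!tr, , drop = FALSE])
    preds[!tr] <- p
    fold_auc[f] <- auc_rank(p, y[!tr])
  }
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc, na.rm = TRUE),
       pooled_auc = auc_rank(preds, y), predictions = preds, folds = fold)
}
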