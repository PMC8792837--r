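#' Declarative classifier configuration
#'
#' The four classifier families evaluated by the pipeline, with the
#' standard hyperparameters: KNN with K = 3, an ANN with two hidden
#' layers of 16 and 6 units, an RBF-kernel SVM decomposed one-vs-one, and
#' LDA (pooled within-class covariance, ridge-regularised if singular).
#'
#' @param kind One of "LDA", "KNN", "ANN", "SVM".
#' @param knn_k Odd neighbour count for KNN (default 3).
#' @param ann_hidden Hidden layer sizes for the ANN (default c(16, 6)).
#' @param ann_maxit Optimiser iteration cap for the ANN (default 500).
#' @param svm_gamma RBF kernel width; `NULL` (default) uses the median
#'   heuristic, 1 / median pairwise squared distance of the (standardised)
#'   training rows.
#' @param standardize Z-score features using training-fold statistics
#'   before fitting (default TRUE; KNN and the RBF kernel are otherwise
#'   dominated by the largest-scale features).
#' @param seed Seed for the ANN weight initialisation.
#' @return An `rsc_classifier_spec`.
#' @export
#' @examples
#' classifier_spec("KNN", knn_k = 3)
classifier_spec <- function(kind = c("KNN", "LDA", "ANN", "SVM"), knn_k = 3,
                            ann_hidden = c(16, 6), ann_maxit = 500,
                            svm_gamma = NULL, standardize = TRUE, seed = 1) {
  kind <- match.arg(kind)
  if (knn_k < 1 || knn_k %% 2 != 1)
    stop("`knn_k` must be odd and >= 1", call. = FALSE)
  if (any(ann_hidden < 1))
    stop("`ann_hidden` sizes must all be >= 1", call. = FALSE)
  structure(list(kind = kind, knn_k = as.integer(knn_k),
                 ann_hidden = as.integer(ann_hidden),
                 ann_maxit = as.integer(ann_maxit),
                 svm_gamma = svm_gamma, standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "rsc_classifier_spec")
}

#' @export
print.rsc_classifier_spec <- function(x, ...) {
  extra <- switch(x$kind,
    KNN = sprintf("K = %d", x$knn_k),
    ANN = sprintf("hidden layers [%s], maxit %d, seed %d",
                  paste(x$ann_hidden, collapse = ", "), x$ann_maxit, x$seed),
    SVM = sprintf("RBF kernel, gamma = %s, one-vs-one",
                  if (is.null(x$svm_gamma)) "median heuristic"
                  else format(x$svm_gamma)),
    LDA = "pooled covariance, ridge if singular")
  cat(sprintf("Classifier spec: %s (%s), standardize = %s\n", x$kind, extra,
              x$standardize))
  invisible(x)
}

fit_standardizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  if (any(scale == 0)) {
    warning("constant feature column(s): ",
            paste(colnames(X)[scale == 0], collapse = ", "),
            "; scale set to 1", call. = FALSE)
    scale[scale == 0] <- 1
  }
  list(center = center, scale = scale)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center, `-`), 2, std$scale, `/`)
}

# Gaussian LDA on the pooled within-class covariance; a small ridge
# (1e-6 x mean diagonal) is added when the pooled covariance is singular.
lda_train <- function(X, y) {
  k <- nlevels(y)
  p <- ncol(X)
  means <- t(vapply(levels(y),
                    function(cl) colMeans(X[y == cl, , drop = FALSE]),
                    numeric(p)))
  Sw <- matrix(0, p, p)
  for (cl in levels(y)) {
    Xc <- sweep(X[y == cl, , drop = FALSE], 2, means[cl, ], `-`)
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (nrow(X) - k)
  Sinv <- tryCatch(solve(Sw), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    ridge <- 1e-6 * mean(diag(Sw)) + 1e-12
    Sinv <- solve(Sw + diag(ridge, p))
  }
  priors <- as.numeric(table(y)) / length(y)
  list(means = means, Sinv = Sinv, log_priors = log(priors),
       levels = levels(y))
}

lda_predict <- function(model, X) {
  # linear discriminant: x' Sinv mu_k - mu_k' Sinv mu_k / 2 + log pi_k
  A <- model$means %*% model$Sinv           # k x p
  const <- -rowSums(A * model$means) / 2 + model$log_priors
  scores <- X %*% t(A)
  scores <- sweep(scores, 2, const, `+`)
  factor(model$levels[max.col(scores, ties.method = "first")],
         levels = model$levels)
}

knn_predict_one <- function(d, y_train, k) {
  ord <- order(d)
  nn <- ord[seq_len(k)]
  votes <- table(y_train[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) top else as.character(y_train[ord[1L]])
}

median_heuristic_gamma <- function(X) {
  n <- nrow(X)
  idx <- if (n > 400) round(seq(1, n, length.out = 400)) else seq_len(n)
  d2 <- as.vector(stats::dist(X[idx, , drop = FALSE]))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med == 0) 1 else 1 / med
}

#' Fit a classifier to feature rows
#'
#' Standardisation parameters are estimated from the training rows only
#' and stored in the model; the SVM trains one binary classifier per
#' unordered class pair (N(N-1)/2 for N classes) and predicts by majority
#' vote over the pairwise decisions.
#'
#' @param spec An `rsc_classifier_spec`.
#' @param X Numeric feature matrix (rows = windows) or an `rsc_features`
#'   object (its labels are then used when `y` is missing).
#' @param y Class labels (coerced to factor).
#' @return An `rsc_model` usable with [predict()].
#' @export
fit_classifier <- function(spec, X, y = NULL) {
  stopifnot(inherits(spec, "rsc_classifier_spec"))
  if (inherits(X, "rsc_features")) {
    if (is.null(y)) y <- X$labels
    X <- X$values
  }
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("feature matrix contains non-finite values",
                               call. = FALSE)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("need >= 2 classes in `y`", call. = FALSE)
  if (nrow(X) != length(y)) stop("row/label length mismatch", call. = FALSE)
  std <- if (spec$standardize) fit_standardizer(X) else NULL
  Xs <- if (is.null(std)) X else apply_standardizer(std, X)
  internal <- switch(spec$kind,
    LDA = lda_train(Xs, y),
    KNN = list(X = Xs, y = y),
    ANN = mlp_train(Xs, y, spec$ann_hidden, seed = spec$seed,
                    maxit = spec$ann_maxit),
    SVM = {
      gamma <- if (is.null(spec$svm_gamma)) median_heuristic_gamma(Xs)
               else spec$svm_gamma
      list(gamma = gamma,
           model = e1071::svm(Xs, y, kernel = "radial", gamma = gamma,
                              scale = FALSE))
    })
  structure(list(spec = spec, class_ids = levels(y), standardization = std,
                 n_features = ncol(X), feature_names = colnames(X),
                 internal = internal),
            class = "rsc_model")
}

#' Predict motion classes for new feature rows
#'
#' KNN takes the majority among the K nearest training rows by Euclidean
#' distance on standardised features, breaking vote ties with the single
#' nearest neighbour's class. The SVM aggregates its one-vs-one decisions
#' by vote; vote ties go to the class with the largest summed decision
#' margin, then the lowest class index. LDA and the ANN take the argmax
#' discriminant / output activation.
#'
#' @param object An `rsc_model`.
#' @param newdata Feature matrix with the training column count, or an
#'   `rsc_features` object.
#' @param ... Unused.
#' @return Factor of predicted labels, levels = the training classes.
#' @export
predict.rsc_model <- function(object, newdata, ...) {
  if (inherits(newdata, "rsc_features")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("`newdata` has ", ncol(newdata), " columns but the model was ",
         "trained on ", object$n_features, call. = FALSE)
  Xs <- if (is.null(object$standardization)) newdata
        else apply_standardizer(object$standardization, newdata)
  lv <- object$class_ids
  out <- switch(object$spec$kind,
    LDA = lda_predict(object$internal, Xs),
    ANN = mlp_predict(object$internal, Xs),
    KNN = {
      tr <- object$internal$X
      d2 <- outer(rowSums(Xs^2), rowSums(tr^2), `+`) - 2 * Xs %*% t(tr)
      labs <- vapply(seq_len(nrow(Xs)),
                     function(i) knn_predict_one(d2[i, ], object$internal$y,
                                                 object$spec$knn_k),
                     character(1))
      factor(labs, levels = lv)
    },
    SVM = {
      pr <- predict(object$internal$model, Xs, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      pair <- strsplit(colnames(dv), "/", fixed = TRUE)
      labs <- character(nrow(Xs))
      for (i in seq_len(nrow(Xs))) {
        votes <- stats::setNames(numeric(length(lv)), lv)
        margin <- votes
        for (j in seq_along(pair)) {
          a <- pair[[j]][1]; b <- pair[[j]][2]
          if (dv[i, j] > 0) votes[a] <- votes[a] + 1
          else votes[b] <- votes[b] + 1
          margin[a] <- margin[a] + dv[i, j]
          margin[b] <- margin[b] - dv[i, j]
        }
        top <- lv[votes == max(votes)]
        if (length(top) > 1L) top <- top[margin[top] == max(margin[top])]
        labs[i] <- top[1L]  # lowest class index on residual ties
      }
      factor(labs, levels = lv)
    })
  out
}

#' @export
print.rsc_model <- function(x, ...) {
  cat(sprintf("Fitted %s classifier: %d features, classes %s\n",
              x$spec$kind, x$n_features, paste(x$class_ids, collapse = ", ")))
  invisible(x)
}
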