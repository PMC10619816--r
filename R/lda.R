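# Interpretable linear discriminant analysis ----------------------------------
#
# Supervised separation of labeled repertoires in the parsed biophysical
# space. The point is interpretability: a univariate pre-selection caps the
# feature count against overfitting, and the fitted linear weights decode
# back to (alignment position, property) pairs.

#' Univariate feature pre-selection for discriminant analysis
#'
#' Ranks retained columns by a univariate class-separation score and keeps
#' the top k. The default score is the one-way ANOVA F statistic; the
#' mutual-information option discretizes each column into quantile bins.
#' Ties break deterministically by column index.
#'
#' @param parsed A \code{parsed_matrix} (or numeric matrix).
#' @param labels Class label per sequence (>= 2 classes).
#' @param k Number of columns to keep.
#' @param method \code{"f_stat"} (default) or \code{"mutual_info"}.
#' @return Integer vector of selected column indices (ranked best first).
#' @export
select_features <- function(parsed, labels, k,
                            method = c("f_stat", "mutual_info")) {
  method <- match.arg(method)
  X <- if (inherits(parsed, "parsed_matrix")) parsed$data else as.matrix(parsed)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("feature selection needs >= 2 classes")
  if (k > ncol(X)) stop("k exceeds the retained column count")
  score <- if (method == "f_stat") f_scores(X, labels)
           else mi_scores(X, labels)
  score[!is.finite(score)] <- -Inf
  order(score, decreasing = TRUE)[seq_len(k)]
}

# vectorized one-way ANOVA F statistic per column
f_scores <- function(X, g) {
  n <- nrow(X); k <- nlevels(g)
  gm <- colMeans(X)
  ssb <- numeric(ncol(X)); ssw <- numeric(ncol(X))
  for (lev in levels(g)) {
    rows <- g == lev
    m <- colMeans(X[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (m - gm)^2
    ssw <- ssw + colSums(sweep(X[rows, , drop = FALSE], 2, m)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# plug-in mutual information between quantile-binned columns and the labels
mi_scores <- function(X, g, bins = 8) {
  apply(X, 2, function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2) return(0)
    xb <- cut(v, breaks = br, include.lowest = TRUE)
    joint <- table(xb, g) / length(v)
    entropy_bits(rowSums(joint)) + entropy_bits(colSums(joint)) -
      entropy_bits(as.vector(joint))
  })
}

#' Fit a linear discriminant model on the parsed biophysical matrix
#'
#' Selects \code{k} columns (\code{\link{select_features}}), fits linear
#' discriminant axes that minimize within-class scatter while maximizing
#' between-class separation, and records the training accuracy. A singular
#' within-class scatter falls back to a ridge-regularized fit (logged via
#' message).
#'
#' @param parsed A \code{parsed_matrix} (or numeric matrix).
#' @param labels Class label per sequence; every class needs >= 2 members.
#' @param k Number of pre-selected columns; default
#'   \code{min(50, floor(n/10))} to limit overfitting, and never more than
#'   n - 2.
#' @param select_method Passed to \code{\link{select_features}}.
#' @return Object of class \code{"discriminant_model"}:
#'   \code{selected_columns}, \code{weights} (columns = discriminant axes),
#'   \code{class_labels}, \code{training_accuracy}, \code{column_index}
#'   rows for the selected columns (when available), and the underlying
#'   fit.
#' @export
fit_lda <- function(parsed, labels, k = NULL,
                    select_method = c("f_stat", "mutual_info")) {
  X <- if (inherits(parsed, "parsed_matrix")) parsed$data else as.matrix(parsed)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("LDA needs >= 2 classes")
  if (any(table(labels) < 2)) stop("every class needs >= 2 sequences")
  n <- nrow(X)
  if (is.null(k)) k <- max(2L, min(50L, n %/% 10L))
  k <- min(k, ncol(X), n - 2L)
  sel <- select_features(X, labels, k, method = select_method)
  Xs <- X[, sel, drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(MASS::lda(Xs, grouping = labels)),
    error = function(e) NULL)
  if (is.null(fit)) {
    message("within-class scatter singular; applying ridge regularization")
    fit <- ridge_lda(Xs, labels)
  }
  pred <- predict_labels(fit, Xs)
  acc <- mean(pred == labels)
  ci <- if (inherits(parsed, "parsed_matrix"))
    parsed$column_index[sel, ] else NULL
  structure(list(selected_columns = sel, weights = lda_weights(fit),
                 class_labels = levels(labels), training_accuracy = acc,
                 column_index = ci, fit = fit),
            class = "discriminant_model")
}

lda_weights <- function(fit) {
  if (inherits(fit, "lda")) fit$scaling else fit$scaling
}

predict_labels <- function(fit, X) {
  if (inherits(fit, "lda")) return(stats::predict(fit, X)$class)
  # ridge fallback: nearest class centroid in discriminant space
  Z <- X %*% fit$scaling
  cz <- fit$centroids %*% fit$scaling
  d2 <- outer(rowSums(Z^2), rowSums(cz^2), "+") - 2 * Z %*% t(cz)
  factor(rownames(cz)[apply(d2, 1, which.min)], levels = rownames(cz))
}

# regularized discriminant axes: eigen-decomposition of
# solve(Sw + lambda I) %*% Sb
ridge_lda <- function(X, g, lambda = 1e-6) {
  p <- ncol(X)
  gm <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  cents <- matrix(0, nlevels(g), p, dimnames = list(levels(g), NULL))
  for (lev in levels(g)) {
    rows <- g == lev
    m <- colMeans(X[rows, , drop = FALSE])
    cents[lev, ] <- m
    Xc <- sweep(X[rows, , drop = FALSE], 2, m)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + sum(rows) * tcrossprod(m - gm)
  }
  lam <- lambda * mean(diag(Sw) + 1e-30)
  ev <- eigen(solve(Sw + diag(lam, p), Sb))
  d <- min(nlevels(g) - 1, p)
  scaling <- Re(ev$vectors[, seq_len(d), drop = FALSE])
  colnames(scaling) <- paste0("LD", seq_len(d))
  list(scaling = scaling, centroids = cents)
}

#' @export
#' @method print discriminant_model
print.discriminant_model <- function(x, ...) {
  cat(sprintf(
    "Discriminant model: %d classes, %d selected columns, training accuracy %.3f\n",
    length(x$class_labels), length(x$selected_columns),
    x$training_accuracy))
  invisible(x)
}

#' Classify sequences with a fitted discriminant model
#'
#' @param model A \code{discriminant_model}.
#' @param parsed A \code{parsed_matrix} (or matrix) parsed identically to
#'   the training data.
#' @return Factor of predicted class labels.
#' @export
classify <- function(model, parsed) {
  X <- if (inherits(parsed, "parsed_matrix")) parsed$data else as.matrix(parsed)
  predict_labels(model$fit, X[, model$selected_columns, drop = FALSE])
}

#' Top discriminating features by weight magnitude
#'
#' Decodes the largest-magnitude linear weights (first discriminant axis)
#' back to alignment position and property name.
#'
#' @param model A \code{discriminant_model} fitted on a
#'   \code{parsed_matrix}.
#' @param m Number of features to report (default 10).
#' @return data.frame: rank, column, position, property, feature, weight.
#' @export
top_features <- function(model, m = 10) {
  w <- model$weights[, 1]
  ord <- order(abs(w), decreasing = TRUE)[seq_len(min(m, length(w)))]
  out <- data.frame(rank = seq_along(ord),
                    column = model$selected_columns[ord],
                    weight = w[ord], row.names = NULL)
  if (!is.null(model$column_index)) {
    out$position <- model$column_index$position[ord]
    out$property <- model$column_index$property[ord]
    out$feature <- model$column_index$feature[ord]
  }
  out
}
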