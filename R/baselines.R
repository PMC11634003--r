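# Baseline classifiers: DAPC (PCA -> LDA) and chi-square-distance KNN.
#
# CLBP feature matrices have many more descriptors than samples and highly
# correlated columns, so ordinary LDA cannot be applied directly; DAPC first
# projects onto a reduced set of principal components, chosen by
# cross-validation, and runs the discriminant analysis in that space.

#' Select the number of principal components for DAPC by cross-validation
#'
#' For each candidate number of components, a k-fold cross-validation
#' estimates the assignment success of PCA + LDA with that many retained
#' components; the smallest candidate attaining the maximal mean success is
#' returned (preferring parsimony on ties, which guards against the
#' overfitting that large retained spaces invite).
#'
#' @param x numeric feature matrix.
#' @param y class labels.
#' @param candidates integer vector of candidate component counts. When
#'   `NULL`, `1 .. cap` is used, where the cap is `floor(2n/3)` by default or
#'   `max(1, floor(0.1 n))` with `cap = "ten_percent"` — both capped at the
#'   feature count.
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed for the fold partition (deterministic result).
#' @param cap `"two_thirds"` (default) or `"ten_percent"`, used only when
#'   `candidates` is `NULL`.
#' @return the selected number of components, with the per-candidate mean
#'   success attached as attribute `"success"`.
#' @export
select_components <- function(x, y, candidates = NULL, folds = 5L, seed = 1L,
                              cap = c("two_thirds", "ten_percent")) {
  cap <- match.arg(cap)
  x <- as.matrix(x); y <- factor(y)
  n <- nrow(x)
  max_train <- n - ceiling(n / folds) # smallest training-fold size
  admissible <- min(max_train - 1L, ncol(x))
  if (is.null(candidates)) {
    lim <- if (cap == "two_thirds") floor(2 * n / 3) else max(1L, floor(0.1 * n))
    candidates <- seq_len(max(1L, min(lim, admissible)))
  }
  assert_that(length(candidates) > 0, "candidate grid is empty")
  assert_that(all(candidates >= 1) && max(candidates) <= admissible,
              sprintf("candidates must lie in [1, %d] for %d samples in %d folds",
                      admissible, n, folds))
  folds_idx <- with_seed(seed, stratified_folds(y, folds))
  success <- vapply(candidates, function(q) {
    acc <- vapply(seq_len(folds), function(f) {
      tr <- folds_idx != f
      fit <- dapc(x[tr, , drop = FALSE], y[tr], n_retained = q)
      pred <- predict(fit, x[!tr, , drop = FALSE], type = "class")
      mean(pred == y[!tr])
    }, numeric(1))
    mean(acc)
  }, numeric(1))
  best <- max(success)
  sel <- min(candidates[success >= best - 1e-12])
  structure(sel, success = stats::setNames(success, candidates))
}

#' Fit a Discriminant Analysis of Principal Components
#'
#' PCA (SVD of the centred, unscaled feature matrix — CLBP histograms share
#' a common scale) followed by linear discriminant analysis with pooled
#' within-class covariance on the retained principal-component scores.
#'
#' @param x numeric feature matrix; singular inputs (duplicated or
#'   correlated columns) are handled by the PCA reduction.
#' @param y class labels; >= 2 classes with >= 2 samples each.
#' @param n_retained number of principal components to keep
#'   (`<= min(n - 1, p)`); see [select_components()].
#' @param prior `"proportional"` (training class frequencies, default) or
#'   `"uniform"`.
#' @return an object of class `dapc`: `center`, `rotation`, `sdev`,
#'   `n_retained`, class `means` in PC space, pooled covariance `W` (after
#'   any ridge regularisation), `prior`, `classes`, discriminant axes `disc`
#'   (at most K - 1 columns) and the training discriminant `scores`.
#' @export
dapc <- function(x, y, n_retained, prior = c("proportional", "uniform")) {
  prior <- match.arg(prior)
  x <- as.matrix(x); y <- factor(y)
  counts <- table(y)
  assert_that(length(counts) >= 2, "need >= 2 classes")
  if (any(counts < 2)) {
    ct_stop("every class needs >= 2 samples", "coraltex_validation_error")
  }
  n <- nrow(x)
  assert_that(n_retained >= 1 && n_retained <= min(n - 1L, ncol(x)),
              "n_retained out of admissible range")
  centre <- colMeans(x)
  xc <- sweep(x, 2, centre)
  sv <- svd(xc, nu = 0, nv = n_retained)
  rot <- sv$v
  Z <- xc %*% rot
  K <- nlevels(y)
  M <- do.call(rbind, lapply(levels(y), function(cl) {
    colMeans(Z[y == cl, , drop = FALSE])
  }))
  rownames(M) <- levels(y)
  Wc <- matrix(0, n_retained, n_retained)
  for (cl in levels(y)) {
    zz <- sweep(Z[y == cl, , drop = FALSE], 2, M[cl, ])
    Wc <- Wc + crossprod(zz)
  }
  Wc <- Wc / (n - K)
  ok <- tryCatch({ chol(Wc); TRUE }, error = function(e) FALSE)
  if (!ok) {
    warning("singular pooled within-class covariance; adding ridge 1e-8")
    Wc <- Wc + diag(1e-8, n_retained)
  }
  Winv <- chol2inv(chol(Wc))
  pr <- if (prior == "proportional") as.numeric(counts) / n else rep(1 / K, K)
  names(pr) <- levels(y)
  # discriminant axes: eigenvectors of W^-1 B, at most K - 1 of them
  gm <- colMeans(Z)
  B <- matrix(0, n_retained, n_retained)
  for (cl in levels(y)) {
    dmu <- M[cl, ] - gm
    B <- B + as.numeric(counts[cl]) * tcrossprod(dmu)
  }
  B <- B / n
  ev <- eigen(Winv %*% B)
  ndisc <- min(K - 1L, n_retained)
  disc <- Re(ev$vectors[, seq_len(ndisc), drop = FALSE])
  structure(list(center = centre, rotation = rot, sdev = sv$d / sqrt(max(1, n - 1)),
                 n_retained = as.integer(n_retained), means = M, W = Wc,
                 Winv = Winv, prior = pr, classes = levels(y), disc = disc,
                 scores = Z %*% disc, grouping = y),
            class = "dapc")
}

#' Posterior class membership probabilities from a DAPC model
#'
#' Gaussian class-conditional densities with the shared pooled covariance in
#' the retained principal-component space; posteriors are proportional to
#' prior times density and sum to one for every sample.
#'
#' @param object a fitted [dapc()] model.
#' @param newdata matrix (or vector) of raw features in the training
#'   dimension.
#' @param type `"posterior"` (default) or `"class"` for the argmax label.
#' @param ... unused.
#' @return matrix samples x classes of posteriors, or a factor.
#' @export
predict.dapc <- function(object, newdata, type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  assert_that(ncol(newdata) == length(object$center),
              "feature dimension does not match the fitted model")
  Z <- sweep(newdata, 2, object$center) %*% object$rotation
  K <- length(object$classes)
  logd <- vapply(seq_len(K), function(k) {
    dz <- sweep(Z, 2, object$means[k, ])
    -0.5 * rowSums((dz %*% object$Winv) * dz) + log(object$prior[k])
  }, numeric(nrow(Z)))
  logd <- matrix(logd, nrow = nrow(Z), ncol = K,
                 dimnames = list(NULL, object$classes))
  post <- exp(logd - apply(logd, 1, max))
  post <- post / rowSums(post)
  if (type == "class") {
    factor(object$classes[apply(post, 1, which.max)], levels = object$classes)
  } else {
    post
  }
}

#' @export
print.dapc <- function(x, ...) {
  cat("Discriminant analysis of principal components\n")
  cat(sprintf("  %d retained components, %d classes (%s), %d discriminant axes\n",
              x$n_retained, length(x$classes),
              paste(x$classes, collapse = ", "), ncol(x$disc)))
  invisible(x)
}

#' Scatter of the first two discriminant axes
#'
#' @param x a fitted [dapc()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dapc <- function(x, ...) {
  s <- x$scores
  if (ncol(s) == 1) s <- cbind(s, 0)
  graphics::plot(s[, 1], s[, 2], col = as.integer(x$grouping), pch = 19,
                 xlab = "Discriminant axis 1", ylab = "Discriminant axis 2",
                 ...)
  graphics::legend("topright", legend = x$classes,
                   col = seq_along(x$classes), pch = 19, bty = "n")
}

#' Chi-square distance between two histograms
#'
#' `d = sum((h1 - h2)^2 / (h1 + h2))`, with zero-denominator terms
#' contributing 0. Symmetric, non-negative, zero iff the histograms are
#' equal.
#'
#' @param h1,h2 non-negative numeric vectors of equal length.
#' @return the distance (>= 0).
#' @export
#' @examples
#' chi2_distance(c(1, 0), c(0, 1)) # 2
chi2_distance <- function(h1, h2) {
  assert_that(length(h1) == length(h2), "histograms must have equal length")
  assert_that(all(h1 >= 0) && all(h2 >= 0), "histogram entries must be >= 0")
  s <- h1 + h2
  keep <- s > 0
  sum((h1[keep] - h2[keep])^2 / s[keep])
}

# All chi-square distances between rows of X (queries) and rows of A
# (training); returns an n x m matrix.
chi2_cross_distance <- function(X, A) {
  t(apply(X, 1, function(q) {
    s <- sweep(A, 2, q, "+")
    d <- sweep(A, 2, q, "-")
    rowSums(ifelse(s > 0, d^2 / s, 0))
  }))
}

#' K-nearest-neighbour classification with chi-square distances
#'
#' Majority vote among the k training histograms nearest by
#' [chi2_distance()]. Vote ties are broken by the summed inverse distance of
#' each tied class's voters, then by class order.
#'
#' @param x training histogram matrix (rows = samples, entries >= 0).
#' @param y training class labels.
#' @param query query histogram matrix (or single vector).
#' @param k neighbour count (default 5; `k <= nrow(x)`).
#' @return list with `class` (factor of predicted labels) and `votes`
#'   (matrix of per-class vote fractions in `[0, 1]`).
#' @export
knn_chi2 <- function(x, y, query, k = 5L) {
  x <- as.matrix(x); y <- factor(y)
  assert_that(nrow(x) > 0, "empty training set")
  assert_that(k >= 1 && k <= nrow(x), "k must lie in [1, n_train]")
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  query <- as.matrix(query)
  D <- chi2_cross_distance(query, x)
  D <- matrix(D, nrow = nrow(query))
  classes <- levels(y)
  votes <- matrix(0, nrow(query), length(classes),
                  dimnames = list(NULL, classes))
  pred <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    ord <- order(D[i, ])[seq_len(k)]
    tally <- table(factor(y[ord], levels = classes))
    votes[i, ] <- as.numeric(tally) / k
    top <- which(tally == max(tally))
    if (length(top) > 1) {
      invd <- vapply(names(tally)[top], function(cl) {
        sum(1 / pmax(D[i, ord][y[ord] == cl], 1e-12))
      }, numeric(1))
      top <- top[which.max(invd)] # which.max keeps class order on exact tie
    }
    pred[i] <- classes[top]
  }
  list(class = factor(pred, levels = classes), votes = votes)
}
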