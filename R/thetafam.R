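# Fuzzy associative memory classifier (Theta-FAM / E-FAM).
#
# The model stores every training exemplar as a "fundamental memory" a_i with
# a non-negative weight v_i. A hidden layer computes an equivalence measure
# theta(x, a_i) in [0, 1] between the (min-max scaled) input and each memory;
# the competitive output layer returns, per class c, the pertinence
#   y_c(x) = max over memories i of class c of v_i * theta(x, a_i),
# clipped to [0, 1]. Pertinences are fuzzy memberships: they need not sum to
# one across classes, and a sample may be equally pertinent to two species.
# Weights are trained by stochastic subgradient descent on a multiclass
# hinge loss over the margin between the true class and its best rival.

#' Equivalence measure between two vectors in the unit hypercube
#'
#' Two measures are offered. `l1_complement` is
#' `1 - mean(|x - a|)`, the complement of the normalised L1 distance;
#' `fuzzy_jaccard` is `sum(min(x, a)) / max(sum(max(x, a)), epsilon)`, which
#' weighs coordinates by their mass and suits histogram inputs. Both equal 1
#' iff `x == a` (up to the epsilon floor) and lie in `[0, 1]` for inputs in
#' `[0, 1]^n`.
#'
#' @param x,a numeric vectors of equal length with entries in `[0, 1]`.
#' @param cfg an [equivalence_config()].
#' @return equivalence score in `[0, 1]`.
#' @export
#' @examples
#' equivalence(c(0, 1), c(1, 1)) # 0.5
equivalence <- function(x, a, cfg = equivalence_config()) {
  assert_that(length(x) == length(a),
              "x and a must have the same length")
  assert_that(all(is.finite(x)) && all(is.finite(a)) &&
                all(x >= 0 & x <= 1) && all(a >= 0 & a <= 1),
              "entries must lie in [0, 1]")
  if (cfg$measure == "l1_complement") {
    1 - mean(abs(x - a))
  } else {
    sum(pmin(x, a)) / max(sum(pmax(x, a)), cfg$epsilon)
  }
}

#' Equivalence-measure configuration
#'
#' @param measure `"l1_complement"` (default) or `"fuzzy_jaccard"`.
#' @param epsilon numerical floor guarding the fuzzy-Jaccard denominator.
#' @return an object of class `equivalence_config`.
#' @export
equivalence_config <- function(measure = c("l1_complement", "fuzzy_jaccard"),
                               epsilon = 1e-12) {
  measure <- match.arg(measure)
  assert_that(epsilon > 0, "epsilon must be > 0")
  structure(list(measure = measure, epsilon = epsilon),
            class = "equivalence_config")
}

# Equivalence of every row of X against every row of A (both already scaled
# to [0,1]). Uses stats::dist for the heavy manhattan pass; for the fuzzy
# Jaccard, sum(min) and sum(max) are recovered from the L1 distance via
# min(x,a) = (x + a - |x - a|)/2.
equivalence_matrix <- function(X, A, cfg = equivalence_config()) {
  n <- nrow(X); m <- nrow(A); d <- ncol(X)
  l1 <- as.matrix(stats::dist(rbind(X, A), method = "manhattan"))
  l1 <- l1[seq_len(n), n + seq_len(m), drop = FALSE]
  if (cfg$measure == "l1_complement") {
    1 - l1 / d
  } else {
    sx <- rowSums(X); sa <- rowSums(A)
    s <- outer(sx, sa, `+`)
    num <- (s - l1) / 2
    den <- pmax((s + l1) / 2, cfg$epsilon)
    num / den
  }
}

# Min-max feature scaler fitted on training data; transform clips into [0,1]
# so out-of-range validation features remain scorable.
fit_scaler <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1 # constant columns map to 0
  list(lo = lo, rng = rng)
}

apply_scaler <- function(scaler, x) {
  z <- sweep(sweep(x, 2, scaler$lo), 2, scaler$rng, "/")
  z[z < 0] <- 0
  z[z > 1] <- 1
  z
}

#' Fit a Theta-FAM fuzzy associative memory classifier
#'
#' All training exemplars become fundamental memories with initial weight 1.
#' Features are min-max scaled into the unit hypercube (the scaling is part
#' of the model; validation vectors outside the training range are clipped).
#' Weights are then refined by stochastic subgradient descent on the hinge
#' loss `max(0, margin - (y_true(x) - max_{c != true} y_c(x)))`: when the
#' margin is violated, the weight of the true class's best memory is
#' increased and the rival class's best memory decreased, with weights kept
#' inside `[0, 1]` so scores retain their equivalence interpretation (the
#' upper cap makes the pertinence clip a no-op; learning then acts chiefly
#' by suppressing the memories that confuse rival classes).
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y class labels (factor or character/integer vector); every class
#'   needs at least 2 samples.
#' @param cfg an [equivalence_config()]. The L1 complement suits min-max
#'   scaled measurement vectors; the fuzzy Jaccard suits histogram inputs,
#'   whose mass-weighted comparison it preserves.
#' @param epochs number of passes over the training data (default 200).
#' @param learning_rate subgradient step size (default 0.05).
#' @param margin hinge margin on the pertinence scale (default 0.1).
#' @param seed RNG seed controlling the sample presentation order;
#'   the fit is deterministic given the seed.
#' @param scale when `TRUE` (default) fit a min-max scaler on the training
#'   features; when `FALSE` the features must already lie in `[0, 1]` (e.g.
#'   normalised histograms) and are used as-is, preserving relative bin
#'   masses for the fuzzy-Jaccard measure.
#' @return an object of class `theta_fam`: `memories` (scaled training
#'   matrix), `labels` (factor), `weights`, `scaler`, `equivalence` config,
#'   `classes`, and `trace` (mean hinge loss per epoch, plus the seed).
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 4), 10))
#' fit <- theta_fam(x, rep(c("a", "b"), each = 10), seed = 1)
#' predict(fit, x[1, , drop = FALSE])
theta_fam <- function(x, y, cfg = equivalence_config(), epochs = 200L,
                      learning_rate = 0.05, margin = 0.1, seed = 1L,
                      scale = TRUE) {
  x <- as.matrix(x)
  assert_that(all(is.finite(x)), "features must be finite")
  if (!scale) {
    assert_that(all(x >= 0 & x <= 1),
                "with scale = FALSE features must lie in [0, 1]")
  }
  y <- factor(y)
  counts <- table(y)
  if (length(counts) < 2 || any(counts < 2)) {
    ct_stop("need >= 2 classes with >= 2 samples each",
            "coraltex_training_error")
  }
  assert_that(nrow(x) == length(y), "x and y sizes differ")
  scaler <- if (scale) {
    fit_scaler(x)
  } else {
    list(lo = rep(0, ncol(x)), rng = rep(1, ncol(x)))
  }
  A <- apply_scaler(scaler, x)
  m <- nrow(A)
  K <- nlevels(y)
  class_idx <- split(seq_len(m), y)
  TH <- equivalence_matrix(A, A, cfg)
  v <- rep(1, m)
  trace <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      total <- 0
      for (i in sample.int(m)) {
        s <- v * TH[i, ]
        best_s <- numeric(K); best_j <- integer(K)
        for (k in seq_len(K)) {
          jj <- class_idx[[k]]
          w <- which.max(s[jj])
          best_s[k] <- s[jj[w]]; best_j[k] <- jj[w]
        }
        yt <- as.integer(y[i])
        rivals <- setdiff(seq_len(K), yt)
        r <- rivals[which.max(best_s[rivals])]
        loss <- margin - (best_s[yt] - best_s[r])
        if (loss > 0) {
          total <- total + loss
          jt <- best_j[yt]; jr <- best_j[r]
          v[jt] <- min(1, v[jt] + learning_rate * TH[i, jt])
          v[jr] <- max(0, v[jr] - learning_rate * TH[i, jr])
        }
      }
      trace[ep] <- total / m
      if (!is.finite(trace[ep])) {
        ct_stop("non-finite training loss", "coraltex_numerical_error")
      }
    }
  })
  structure(list(memories = A, labels = y, weights = v, scaler = scaler,
                 equivalence = cfg, classes = levels(y),
                 trace = list(loss = trace, seed = seed,
                              epochs = epochs, learning_rate = learning_rate,
                              margin = margin)),
            class = "theta_fam")
}

#' Per-class pertinence of new samples
#'
#' Inputs are scaled by the model's training scaler (clipping out-of-range
#' values into `[0, 1]`), then scored as
#' `y_c = max over memories i in class c of v_i * theta(x, a_i)`,
#' clipped to `[0, 1]`.
#'
#' @param object a fitted [theta_fam()] model.
#' @param newdata numeric matrix (or single vector) of raw features.
#' @param type `"pertinence"` (default) for the score matrix, `"class"` for
#'   the argmax label (ties broken by the declared class order).
#' @param ... unused.
#' @return a numeric matrix samples x classes of pertinences in `[0, 1]`, or
#'   a factor of predicted classes.
#' @export
predict.theta_fam <- function(object, newdata,
                              type = c("pertinence", "class"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  assert_that(ncol(newdata) == ncol(object$memories),
              sprintf("feature dimension %d does not match model dimension %d",
                      ncol(newdata), ncol(object$memories)))
  Z <- apply_scaler(object$scaler, newdata)
  TH <- equivalence_matrix(Z, object$memories, object$equivalence)
  TH <- sweep(TH, 2, object$weights, "*")
  K <- length(object$classes)
  scores <- matrix(0, nrow(Z), K, dimnames = list(NULL, object$classes))
  for (k in seq_len(K)) {
    jj <- which(object$labels == object$classes[k])
    scores[, k] <- apply(TH[, jj, drop = FALSE], 1, max)
  }
  scores[scores < 0] <- 0
  scores[scores > 1] <- 1
  if (type == "class") {
    factor(object$classes[apply(scores, 1, which.max)],
           levels = object$classes)
  } else {
    scores
  }
}

#' Classify one sample, returning the argmax class and its pertinences
#'
#' @param model a fitted [theta_fam()] model with at least one memory.
#' @param x raw feature vector.
#' @return list with `class` (factor level, ties broken by class order) and
#'   `pertinence` (named vector).
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "theta_fam"))
  assert_that(nrow(model$memories) > 0, "model has no memories")
  p <- predict(model, x)[1, ]
  list(class = factor(model$classes[which.max(p)], levels = model$classes),
       pertinence = p)
}

#' @export
print.theta_fam <- function(x, ...) {
  cat("Theta-FAM fuzzy associative memory\n")
  cat(sprintf("  %d fundamental memories, %d features, %d classes (%s)\n",
              nrow(x$memories), ncol(x$memories), length(x$classes),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  equivalence: %s; final epoch mean hinge loss %.4g\n",
              x$equivalence$measure, utils::tail(x$trace$loss, 1)))
  invisible(x)
}

#' Serialize a Theta-FAM model to a portable text file
#'
#' The file is versioned plain text (dput of the model's fields) and
#' round-trips exactly: scaler, memories, weights, equivalence config and
#' training trace included.
#'
#' @param model a fitted [theta_fam()] model.
#' @param path output file.
#' @export
write_theta_fam <- function(model, path) {
  stopifnot(inherits(model, "theta_fam"))
  payload <- unclass(model)
  payload$labels <- as.character(payload$labels)
  payload$equivalence <- unclass(payload$equivalence)
  payload$.format_version <- 1L
  dput(payload, file = path,
       control = c("keepNA", "keepInteger", "niceNames", "showAttributes",
                   "hexNumeric"))
  invisible(path)
}

#' @rdname write_theta_fam
#' @return the restored `theta_fam` model.
#' @export
read_theta_fam <- function(path) {
  payload <- dget(path)
  assert_that(identical(payload$.format_version, 1L),
              "unrecognised model file version")
  payload$.format_version <- NULL
  payload$labels <- factor(payload$labels, levels = payload$classes)
  payload$equivalence <- structure(payload$equivalence,
                                   class = "equivalence_config")
  structure(payload, class = "theta_fam")
}
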