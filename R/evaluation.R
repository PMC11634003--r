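# Classifier evaluation machinery: replicated stratified cross-validation,
# one-vs-rest True Skill Statistic threshold sweeps on class-balanced
# subsamples, max-TSS binarization of the outcomes, and a meta-learning
# assessment in which a logistic regression of binarized success on the
# classification score is itself cross-validated and summarised by the area
# under its precision-recall curve.
#
# Terminology: sensitivity is the true positive rate and specificity the
# true negative rate (the standard definitions). TSS = sensitivity +
# specificity - 1 is symmetric in the two rates, prevalence-insensitive,
# 1 for a perfect classifier and <= 0 for one no better than random.

# ---- score matrices ---------------------------------------------------------

#' Assemble a score matrix
#'
#' One row per evaluated sample: identifiers, the true label, one score
#' column per class (pertinences in `[0, 1]` or posteriors summing to 1) and
#' the source classifier tag.
#'
#' @param sample_id,colony_id identifiers (recycled if length 1).
#' @param true true class labels.
#' @param scores numeric matrix samples x classes with column names; entries
#'   in `[0, 1]`.
#' @param classifier tag recording the score source (e.g. `"thetafam"`).
#' @param replicate replicate id.
#' @return data frame of class `score_matrix` with attribute `"classes"`.
#' @export
score_matrix <- function(sample_id, colony_id, true, scores,
                         classifier = "unknown", replicate = 1L) {
  scores <- as.matrix(scores)
  assert_that(!is.null(colnames(scores)), "scores needs class column names")
  assert_that(all(scores >= -1e-9 & scores <= 1 + 1e-9),
              "scores must lie in [0, 1]")
  scores[] <- pmin(pmax(scores, 0), 1)
  df <- data.frame(sample_id = as.character(sample_id),
                   colony_id = as.character(colony_id),
                   true = as.character(true),
                   classifier = classifier,
                   replicate = replicate,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(scores))
  structure(df, classes = colnames(scores),
            class = c("score_matrix", "data.frame"))
}

score_classes <- function(sm) {
  cl <- attr(sm, "classes")
  if (is.null(cl)) {
    cl <- setdiff(names(sm), c("sample_id", "colony_id", "true",
                               "classifier", "replicate"))
  }
  cl
}

# ---- cross-validation -------------------------------------------------------

# Random equitable stratified partition: within each class the (shuffled)
# samples are dealt round-robin to folds, so fold sizes differ by at most
# the number of classes. With group ids, whole groups are dealt instead so
# no group ever spans two folds. Uses the current RNG state.
stratified_folds <- function(y, folds, groups = NULL) {
  y <- factor(y)
  fold_of <- integer(length(y))
  if (is.null(groups)) {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < folds) {
        ct_stop(sprintf("class '%s' has %d samples, fewer than %d folds",
                        cl, length(idx), folds),
                "coraltex_stratification_error")
      }
      idx <- sample(idx)
      fold_of[idx] <- rep(sample.int(folds), length.out = length(idx))
    }
  } else {
    groups <- as.character(groups)
    glab <- tapply(as.character(y), groups, function(v) v[1])
    gcls <- factor(glab, levels = levels(y))
    gf <- integer(length(glab))
    names(gf) <- names(glab)
    for (cl in levels(y)) {
      g <- names(glab)[which(gcls == cl)]
      if (length(g) < folds) {
        ct_stop(sprintf("class '%s' has %d colonies, fewer than %d folds",
                        cl, length(g), folds),
                "coraltex_stratification_error")
      }
      g <- sample(g)
      gf[g] <- rep(sample.int(folds), length.out = length(g))
    }
    fold_of <- gf[groups]
  }
  as.integer(fold_of)
}

#' Classifier specification for cross-validation experiments
#'
#' @param type `"thetafam"`, `"dapc"` or `"knn"`.
#' @param ... parameters forwarded to the fit ([theta_fam()] arguments,
#'   `n_retained`/`prior` for [dapc()], `k` for [knn_chi2()]).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(type = c("thetafam", "dapc", "knn"), ...) {
  type <- match.arg(type)
  structure(list(type = type, params = list(...)), class = "classifier_spec")
}

# Fit the specified classifier on (x, y) and score the rows of xv,
# returning a samples x classes matrix in [0, 1].
fit_and_score <- function(spec, x, y, xv, seed) {
  p <- spec$params
  switch(spec$type,
    thetafam = {
      args <- c(list(x = x, y = y, seed = seed), p)
      predict(do.call(theta_fam, args), xv)
    },
    dapc = {
      q <- p$n_retained
      if (is.null(q)) {
        q <- min(10L, nrow(x) - ceiling(nrow(x) / 5) - 1L, ncol(x))
      }
      args <- list(x = x, y = y, n_retained = q)
      if (!is.null(p$prior)) args$prior <- p$prior
      predict(do.call(dapc, args), xv)
    },
    knn = {
      k <- p$k %||% 5L
      knn_chi2(x, y, xv, k = k)$votes
    })
}

#' Replicated stratified cross-validation of a classifier
#'
#' Per replicate, samples (or whole colonies with `group_by = "colony"`) are
#' randomly and equitably partitioned into `folds` sets; each fold is scored
#' by a model trained on the remaining folds, so every sample is scored
#' exactly once per replicate. Deterministic given `seed`; per-replicate
#' seeds are derived with [seed_stream()] and recorded.
#'
#' @param x feature matrix.
#' @param labels true class labels.
#' @param spec a [classifier_spec()].
#' @param folds number of folds (default 5).
#' @param replicates number of repetitions of the whole partition (the
#'   full-scale design uses 100; desk-scale experiments use 10).
#' @param seed master seed.
#' @param group_by `"image"` (partition samples) or `"colony"` (no colony
#'   spans two folds).
#' @param sample_id,colony_id identifiers carried into the score matrices.
#' @return list of `score_matrix`, one per replicate, with the replicate
#'   seed attached as attribute `"seed"`.
#' @export
run_cv_experiment <- function(x, labels, spec, folds = 5L, replicates = 1L,
                              seed = 1L, group_by = c("image", "colony"),
                              sample_id = NULL, colony_id = NULL) {
  group_by <- match.arg(group_by)
  x <- as.matrix(x)
  y <- factor(labels)
  n <- nrow(x)
  if (is.null(sample_id)) sample_id <- sprintf("s%04d", seq_len(n))
  if (is.null(colony_id)) colony_id <- sample_id
  assert_that(length(y) == n && length(colony_id) == n,
              "labels/ids must match the number of rows")
  groups <- if (group_by == "colony") colony_id else NULL
  lapply(seq_len(replicates), function(r) {
    rseed <- seed_stream(seed, 101L, r)
    fold_of <- with_seed(rseed, stratified_folds(y, folds, groups))
    scores <- matrix(NA_real_, n, nlevels(y),
                     dimnames = list(NULL, levels(y)))
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      if (!any(!tr)) next
      scores[!tr, ] <- fit_and_score(spec, x[tr, , drop = FALSE], y[tr],
                                     x[!tr, , drop = FALSE],
                                     seed = seed_stream(rseed, 7L, f))
    }
    sm <- score_matrix(sample_id, colony_id, as.character(y), scores,
                       classifier = spec$type, replicate = r)
    attr(sm, "seed") <- rseed
    sm
  })
}

# ---- balanced subsampling and TSS ------------------------------------------

#' Class-balanced subsample of a score matrix
#'
#' Draws, without replacement, `n` rows per true class where `n` is the
#' minority-class count, preventing class imbalance from distorting the TSS
#' sweep. Deterministic given `seed`.
#'
#' @param sm a `score_matrix`.
#' @param seed RNG seed.
#' @return a `score_matrix` with exactly `n` rows per class, plus attributes
#'   `"n"` (the minority count) and `"seed"`.
#' @export
balanced_subsample <- function(sm, seed = 1L) {
  counts <- table(sm$true)
  assert_that(length(counts) >= 1 && all(counts >= 1),
              "need >= 1 sample per class")
  n <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(sm$true == cl)
      if (length(idx) == 1) idx else sample(idx, n)
    }), use.names = FALSE)
  })
  out <- sm[sort(keep), , drop = FALSE]
  attr(out, "classes") <- score_classes(sm)
  attr(out, "n") <- as.integer(n)
  attr(out, "seed") <- seed
  class(out) <- class(sm)
  out
}

#' True Skill Statistic
#'
#' `TSS = sensitivity + specificity - 1`; 1 for a perfect classifier, 0 at
#' chance, -1 when every assignment is wrong.
#'
#' @param sensitivity true positive rate in `[0, 1]`.
#' @param specificity true negative rate in `[0, 1]`.
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(sensitivity, specificity) {
  assert_that(all(sensitivity >= 0 & sensitivity <= 1) &&
                all(specificity >= 0 & specificity <= 1),
              "rates must lie in [0, 1]")
  sensitivity + specificity - 1
}

#' One-vs-rest TSS threshold sweep for one class
#'
#' Response: `true == class`; predictor: the score for that class. For every
#' threshold `t` a sample is predicted positive iff its score `>= t`, and
#' sensitivity, specificity and TSS are computed from the resulting 2x2
#' table — the same construction as an ROC curve. The default threshold grid
#' is every distinct observed score plus 0 and 1 (an exact sweep).
#'
#' @param sm a `score_matrix` containing both positives and negatives for
#'   `class`.
#' @param class the class whose one-vs-rest curve is computed.
#' @param thresholds optional numeric grid in `[0, 1]`.
#' @return object of class `tss_curve`: data frame `curve` (threshold,
#'   sensitivity, specificity, tss), `max_tss`, and `tau` (the smallest
#'   threshold attaining `max_tss`).
#' @export
tss_curve <- function(sm, class, thresholds = NULL) {
  cls <- score_classes(sm)
  assert_that(class %in% cls, sprintf("unknown class '%s'", class))
  s <- sm[[class]]
  pos <- sm$true == class
  if (!any(pos) || all(pos)) {
    ct_stop(sprintf("class '%s' needs both positives and negatives", class),
            "coraltex_undefined_rate_error")
  }
  if (is.null(thresholds)) thresholds <- sort(unique(c(0, s, 1)))
  assert_that(all(thresholds >= 0 & thresholds <= 1),
              "thresholds must lie in [0, 1]")
  np <- sum(pos); nn <- sum(!pos)
  sens <- vapply(thresholds, function(t) sum(s >= t & pos) / np, numeric(1))
  spec <- vapply(thresholds, function(t) sum(s < t & !pos) / nn, numeric(1))
  tv <- sens + spec - 1
  mx <- max(tv)
  structure(list(curve = data.frame(threshold = thresholds,
                                    sensitivity = sens,
                                    specificity = spec, tss = tv),
                 max_tss = mx,
                 tau = min(thresholds[tv >= mx - 1e-12]),
                 class = class),
            class = "tss_curve")
}

#' @export
print.tss_curve <- function(x, ...) {
  cat(sprintf("TSS sweep for class '%s': max TSS %.3f at threshold %.3f (%d thresholds)\n",
              x$class, x$max_tss, x$tau, nrow(x$curve)))
  invisible(x)
}

#' Multiclass confusion bookkeeping
#'
#' Each sample is assigned to its argmax class (ties resolved by the fixed
#' class order and counted in attribute `"ties"`). A correct assignment is a
#' true positive for its class and a true negative for every other class; a
#' wrong assignment is a false negative for the true class, a false positive
#' for the predicted class, and a true negative for all remaining classes.
#'
#' @param sm a `score_matrix` with >= 2 classes.
#' @return data frame with one row per class: `TP`, `FP`, `TN`, `FN`
#'   (each row sums to the sample total).
#' @export
multiclass_confusion <- function(sm) {
  cls <- score_classes(sm)
  assert_that(length(cls) >= 2, "need >= 2 classes")
  s <- as.matrix(sm[, cls, drop = FALSE])
  pred_i <- apply(s, 1, which.max)
  ties <- sum(apply(s, 1, function(r) sum(r == max(r)) > 1))
  pred <- cls[pred_i]
  out <- do.call(rbind, lapply(cls, function(cl) {
    data.frame(class = cl,
               TP = sum(pred == cl & sm$true == cl),
               FP = sum(pred == cl & sm$true != cl),
               TN = sum(pred != cl & sm$true != cl),
               FN = sum(pred != cl & sm$true == cl))
  }))
  structure(out, ties = ties)
}

#' Binarize classification outcomes at max-TSS thresholds
#'
#' A sample scores 1 ("success") only when the classifier and the human
#' label agree (argmax class equals the true class) and the winning score is
#' at or above that class's binarization threshold; every other outcome
#' scores 0.
#'
#' @param sm a `score_matrix`.
#' @param tau per-class named vector of thresholds in `[0, 1]` (one value is
#'   recycled as a pooled threshold).
#' @return data frame: `sample_id`, `true`, `predicted`, `top_score`,
#'   `success`.
#' @export
binarize_outcomes <- function(sm, tau) {
  cls <- score_classes(sm)
  if (length(tau) == 1 && is.null(names(tau))) {
    tau <- stats::setNames(rep(tau, length(cls)), cls)
  }
  assert_that(all(cls %in% names(tau)), "tau must name every class")
  assert_that(all(tau >= 0 & tau <= 1), "tau must lie in [0, 1]")
  s <- as.matrix(sm[, cls, drop = FALSE])
  pred_i <- apply(s, 1, which.max)
  top <- s[cbind(seq_len(nrow(s)), pred_i)]
  pred <- cls[pred_i]
  data.frame(sample_id = sm$sample_id, true = sm$true, predicted = pred,
             top_score = top,
             success = as.integer(pred == sm$true & top >= tau[pred]),
             stringsAsFactors = FALSE)
}

# ---- meta-learning ----------------------------------------------------------

#' Area under the precision-recall curve
#'
#' Precision-recall points are taken at every distinct score, descending,
#' with tied scores handled as one group; the area is the step integral
#' `sum((R_i - R_{i-1}) * P_i)` with `R_0 = 0`.
#'
#' @param labels 0/1 outcomes (>= 1 positive).
#' @param scores numeric scores, higher = more positive.
#' @return area in `[0, 1]`.
#' @export
#' @examples
#' prc_auc(c(0, 0, 1, 1), c(.1, .2, .8, .9)) # 1
prc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  assert_that(all(labels %in% c(0L, 1L)), "labels must be 0/1")
  assert_that(length(labels) == length(scores), "length mismatch")
  P <- sum(labels)
  if (P == 0) ct_stop("no positive outcomes; PRC AUC undefined",
                      "coraltex_undefined_auc_error")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  cut <- which(!duplicated(sc, fromLast = TRUE)) # last index of each tie group
  tp <- cumsum(lab)[cut]
  nseen <- cut
  recall <- tp / P
  precision <- tp / nseen
  sum(diff(c(0, recall)) * precision)
}

# Ridge-penalized logistic fit (intercept + single slope, penalty on the
# slope only), used when the ordinary ML fit separates completely.
ridge_logit <- function(x, y, lambda = 1e-6) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    sum(log1p(exp(eta))) - sum(y * eta) + lambda * b[2]^2
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS")
  fit$par
}

#' Meta-learning assessment: cross-validated logistic regression of success
#' on score, summarised by PRC AUC
#'
#' A binary logistic regression `P(success = 1 | top score)` describes how
#' well the underlying classifier's scores predict its own binarized
#' successes. One round of stratified `folds`-fold cross-validation fits the
#' regression on 4/5 of the outcomes and predicts the held-out fifth;
#' pooled held-out predictions are scored by the area under the
#' precision-recall curve with success = 1 as the positive class. Complete
#' separation triggers a ridge-penalized fall-back fit (penalty 1e-6 on the
#' slope), recorded in attribute `"penalized_folds"`.
#'
#' @param outcomes data frame from [binarize_outcomes()] (needs `success`
#'   and `top_score`); both outcome values must be present.
#' @param folds CV folds (default 5).
#' @param seed RNG seed for the fold partition.
#' @return the PRC AUC in `[0, 1]`, with the pooled held-out predictions as
#'   attribute `"predictions"`.
#' @export
meta_logistic_cv <- function(outcomes, folds = 5L, seed = 1L) {
  y <- outcomes$success
  x <- outcomes$top_score
  if (length(unique(y)) < 2) {
    ct_stop("outcomes contain a single class; PRC AUC undefined",
            "coraltex_undefined_auc_error")
  }
  folds <- min(folds, min(table(y)))
  fold_of <- with_seed(seed, stratified_folds(factor(y), folds))
  pred <- numeric(length(y))
  penal <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    fit <- withCallingHandlers(
      stats::glm(y[tr] ~ x[tr], family = stats::binomial()),
      warning = function(w) invokeRestart("muffleWarning"))
    co <- stats::coef(fit)
    separated <- !fit$converged || !all(is.finite(co)) ||
      any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
    if (separated) {
      co <- ridge_logit(x[tr], y[tr])
      penal <- penal + 1L
    }
    eta <- co[1] + co[2] * x[!tr]
    pred[!tr] <- 1 / (1 + exp(-eta))
  }
  structure(prc_auc(y, pred), predictions = pred, penalized_folds = penal)
}

# ---- replicate summaries ----------------------------------------------------

#' Evaluate one cross-validation replicate
#'
#' Balanced subsampling, per-class TSS sweeps, max-TSS binarization and the
#' meta-learning PRC AUC, in the order the evaluation design prescribes.
#' When the binarized outcomes contain a single value (e.g. a perfect
#' replicate) the PRC AUC is reported as `NA`.
#'
#' @param sm a `score_matrix` for one replicate.
#' @param seed seed for the balanced subsample and the meta-CV partition.
#' @param descriptor descriptor-set tag carried into the summary
#'   (e.g. `"clbp"` or `"morpho"`).
#' @return data frame with one row per class: `replicate`, `classifier`,
#'   `descriptor`, `class`, `max_tss`, `tau`, `prc_auc`, `n_balanced`,
#'   `subsample_seed`.
#' @export
evaluate_replicate <- function(sm, seed = 1L, descriptor = "clbp") {
  sub_seed <- seed_stream(seed, 11L)
  bal <- balanced_subsample(sm, seed = sub_seed)
  cls <- score_classes(bal)
  curves <- lapply(cls, function(cl) tss_curve(bal, cl))
  tau <- stats::setNames(vapply(curves, `[[`, numeric(1), "tau"), cls)
  outcomes <- binarize_outcomes(bal, tau)
  auc <- tryCatch(as.numeric(meta_logistic_cv(outcomes, seed = seed_stream(seed, 13L))),
                  coraltex_undefined_auc_error = function(e) NA_real_)
  data.frame(replicate = sm$replicate[1],
             classifier = sm$classifier[1],
             descriptor = descriptor,
             class = cls,
             max_tss = vapply(curves, `[[`, numeric(1), "max_tss"),
             tau = tau,
             prc_auc = auc,
             n_balanced = attr(bal, "n"),
             subsample_seed = sub_seed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarise replicate results
#'
#' Stacks per-replicate evaluations into one long table and attaches
#' per-(classifier, descriptor, class) distribution summaries (median and
#' interquartile range of max TSS, threshold and PRC AUC), the quantities
#' a downstream mixed-model analysis of classifier performance consumes.
#'
#' @param replicate_tables list of data frames from [evaluate_replicate()].
#' @return data frame of all rows, with the summary table as attribute
#'   `"summary"`.
#' @export
summarize_replicates <- function(replicate_tables) {
  assert_that(length(replicate_tables) >= 1, "no replicates supplied")
  long <- do.call(rbind, replicate_tables)
  key <- interaction(long$classifier, long$descriptor, long$class, drop = TRUE)
  summ <- do.call(rbind, lapply(levels(key), function(k) {
    d <- long[key == k, ]
    data.frame(classifier = d$classifier[1], descriptor = d$descriptor[1],
               class = d$class[1],
               median_max_tss = stats::median(d$max_tss),
               iqr_max_tss = stats::IQR(d$max_tss),
               median_tau = stats::median(d$tau),
               iqr_tau = stats::IQR(d$tau),
               median_prc_auc = stats::median(d$prc_auc, na.rm = TRUE),
               iqr_prc_auc = stats::IQR(d$prc_auc, na.rm = TRUE),
               n_replicates = length(unique(d$replicate)),
               stringsAsFactors = FALSE)
  }))
  structure(long, summary = summ)
}
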