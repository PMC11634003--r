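make_scores <- function(true, scores, classes = colnames(scores), ...) {
  score_matrix(sample_id = sprintf("s%03d", seq_along(true)),
               colony_id = sprintf("c%03d", seq_along(true)),
               true = true, scores = scores, ...)
}

perfect_scores <- function(n_per = 20, classes = c("spA", "spB", "spC")) {
  true <- rep(classes, each = n_per)
  s <- matrix(0, length(true), length(classes),
              dimnames = list(NULL, classes))
  s[cbind(seq_along(true), match(true, classes))] <- 1
  make_scores(true, s)
}

test_that("cross-validation partitions are equitable, exhaustive and seeded", {
  set.seed(1)
  x <- matrix(rnorm(60 * 3), 60)
  y <- rep(c("a", "b", "c"), each = 20)
  sms <- run_cv_experiment(x, y, classifier_spec("knn", k = 3), folds = 5,
                           replicates = 2, seed = 9)
  expect_length(sms, 2)
  expect_identical(sort(sms[[1]]$sample_id), sprintf("s%04d", 1:60))
  expect_false(anyNA(as.matrix(sms[[1]][, c("a", "b", "c")])))
  # same master seed reproduces partitions and scores exactly
  sms2 <- run_cv_experiment(x, y, classifier_spec("knn", k = 3), folds = 5,
                            replicates = 2, seed = 9)
  expect_identical(as.data.frame(sms[[1]]), as.data.frame(sms2[[1]]))
  # different seeds give different partitions (checked via scores)
  sms3 <- run_cv_experiment(x, y, classifier_spec("knn", k = 3), folds = 5,
                            replicates = 1, seed = 10)
  expect_false(identical(as.data.frame(sms[[1]]), as.data.frame(sms3[[1]])))
  # fold sizes are equitable within each class
  fold_of <- withr::with_seed(4, coraltex:::stratified_folds(y, 5))
  expect_true(all(table(fold_of) == 12))
  expect_true(all(table(fold_of, y) == 4))
  expect_error(withr::with_seed(4, coraltex:::stratified_folds(rep(c("a", "b"),
                                                                   c(3, 57)), 5)),
               class = "coraltex_stratification_error")
})

test_that("colony grouping keeps colonies inside one fold", {
  y <- rep(c("a", "b"), each = 30)
  colony <- paste0(y, rep(1:10, each = 3))
  fold_of <- withr::with_seed(2, coraltex:::stratified_folds(y, 5, colony))
  spans <- tapply(fold_of, colony, function(f) length(unique(f)))
  expect_true(all(spans == 1))
})

test_that("balanced subsampling draws the minority count per class, seeded", {
  set.seed(3)
  true <- rep(c("radians", "siderea", "stellata"), times = c(16, 12, 35))
  s <- matrix(runif(length(true) * 3), ncol = 3,
              dimnames = list(NULL, c("radians", "siderea", "stellata")))
  sm <- make_scores(true, s)
  bal <- balanced_subsample(sm, seed = 11)
  expect_identical(nrow(bal), 36L)
  expect_true(all(table(bal$true) == 12))
  expect_identical(attr(bal, "n"), 12L)
  expect_identical(balanced_subsample(sm, seed = 11)$sample_id, bal$sample_id)
  # already balanced input: counts preserved (a permutation)
  sm2 <- perfect_scores(10)
  bal2 <- balanced_subsample(sm2, seed = 4)
  expect_true(all(table(bal2$true) == 10))
})

test_that("TSS arithmetic and bounds hold", {
  expect_identical(tss(1, 1), 1)
  expect_identical(tss(0.5, 0.5), 0)
  expect_identical(tss(0, 0), -1)
  expect_error(tss(1.2, 0.5), class = "coraltex_validation_error")
})

test_that("TSS sweeps recover perfect separation and degenerate flatness", {
  sm <- perfect_scores(20)
  for (cl in c("spA", "spB", "spC")) {
    cur <- tss_curve(sm, cl)
    expect_identical(cur$max_tss, 1)
    expect_true(cur$tau > 0 && cur$tau <= 1)
  }
  # identically scored samples: every threshold yields TSS 0
  true <- rep(c("a", "b"), each = 5)
  s <- matrix(0.5, 10, 2, dimnames = list(NULL, c("a", "b")))
  flat <- tss_curve(make_scores(true, s), "a")
  expect_true(all(flat$curve$tss == 0))
  # single-class input is undefined
  sm1 <- make_scores(rep("a", 4), matrix(runif(8), 4,
                                         dimnames = list(NULL, c("a", "b"))))
  expect_error(tss_curve(sm1, "a"), class = "coraltex_undefined_rate_error")
  # every computed TSS lies in [-1, 1] on random scores
  set.seed(6)
  smr <- make_scores(sample(c("a", "b"), 40, TRUE),
                     matrix(runif(80), 40, dimnames = list(NULL, c("a", "b"))))
  cur <- tss_curve(smr, "a")
  expect_true(all(cur$curve$tss >= -1 & cur$curve$tss <= 1))
})

test_that("label-independent scores give expected TSS near zero at a fixed
           threshold", {
  set.seed(8)
  reps <- 400
  vals <- vapply(seq_len(reps), function(i) {
    pos <- runif(60) < 1 / 3
    s <- runif(60)
    sens <- sum(s >= 0.5 & pos) / sum(pos)
    spec <- sum(s < 0.5 & !pos) / sum(!pos)
    sens + spec - 1
  }, numeric(1))
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals)), 3 * se + 1e-3)
})

test_that("the TSS sweep agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  true <- sample(c("a", "b"), 50, TRUE, prob = c(0.4, 0.6))
  s <- matrix(runif(100), 50, dimnames = list(NULL, c("a", "b")))
  s[true == "a", "a"] <- s[true == "a", "a"] + 0.3
  sm <- make_scores(true, pmin(s, 1))
  cur <- tss_curve(sm, "a")
  roc <- pROC::roc(response = sm$true == "a", predictor = sm$a,
                   quiet = TRUE)
  want <- max(roc$sensitivities + roc$specificities - 1)
  expect_equal(cur$max_tss, want, tolerance = 1e-12)
})

test_that("multiclass confusion distributes outcomes per class", {
  sm <- perfect_scores(10)
  conf <- multiclass_confusion(sm)
  expect_true(all(conf$TP == 10 & conf$TN == 20 & conf$FP == 0 & conf$FN == 0))
  # one spA sample assigned to spB: FN for A, FP for B, TN for C
  s <- as.matrix(sm[, c("spA", "spB", "spC")])
  s[1, ] <- c(0.1, 0.9, 0)
  sm2 <- make_scores(sm$true, s)
  conf2 <- multiclass_confusion(sm2)
  rownames(conf2) <- conf2$class
  expect_identical(conf2["spA", "FN"], 1L + 0L)
  expect_identical(conf2["spB", "FP"], 1L + 0L)
  expect_identical(conf2["spC", "TN"], 20L)
  # conservation: each class's counts sum to the sample total
  expect_true(all(rowSums(conf2[, c("TP", "FP", "TN", "FN")]) == nrow(sm2)))
})

test_that("binarization requires agreement and threshold exceedance", {
  true <- c("a", "a", "b")
  s <- matrix(c(0.9, 0.6, 0.2,
                0.1, 0.4, 0.9), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  sm <- make_scores(true, s)
  out <- binarize_outcomes(sm, c(a = 0.7, b = 0.7))
  expect_identical(out$success, c(1L, 0L, 1L))   # 0.6 < tau -> 0
  out2 <- binarize_outcomes(sm, c(a = 0.7, b = 0.95))
  expect_identical(out2$success, c(1L, 0L, 0L))
  # wrong argmax scores 0 regardless of score
  s[3, ] <- c(0.99, 0.98)
  out3 <- binarize_outcomes(make_scores(true, s), c(a = 0.5, b = 0.5))
  expect_identical(out3$success[3], 0L)
})

test_that("PRC AUC matches hand counts and the exhaustive oracle", {
  expect_identical(prc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  # single positive ranked last among 9 negatives: one step at recall 1
  expect_equal(prc_auc(c(rep(0, 9), 1), c(seq(0.9, 0.1, length.out = 9), 0.05)),
               0.1)
  set.seed(10)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    lab <- sample(c(0, 1), n, TRUE)
    if (sum(lab) == 0) lab[1] <- 1
    sc <- sample(seq(0, 1, by = 0.25), n, TRUE) # force ties
    expect_equal(prc_auc(lab, sc), brute_prc_auc(lab, sc), tolerance = 1e-12)
  }
  expect_error(prc_auc(c(0, 0), c(0.1, 0.2)),
               class = "coraltex_undefined_auc_error")
})

test_that("PRC AUC of random scores concentrates on prevalence", {
  set.seed(12)
  reps <- 1000
  prev <- 0.3
  vals <- vapply(seq_len(reps), function(i) {
    lab <- rbinom(200, 1, prev)
    if (sum(lab) == 0) lab[1] <- 1
    prc_auc(lab, runif(200))
  }, numeric(1))
  expect_lt(abs(mean(vals) - prev), 0.02)
})

test_that("meta-learning logistic CV scores ordered, random and degenerate
           outcomes correctly", {
  set.seed(14)
  # perfectly ordered outcomes -> AUC 1
  sc <- runif(60)
  ord <- data.frame(success = as.integer(sc > stats::median(sc)),
                    top_score = sc)
  # pooling held-out predictions across folds can introduce hairline rank
  # inversions at the class boundary, so allow a sliver below 1
  expect_gte(as.numeric(meta_logistic_cv(ord, seed = 2)), 0.99)
  # outcomes independent of scores -> AUC near prevalence
  vals <- vapply(1:40, function(i) {
    o <- data.frame(success = rbinom(80, 1, 0.4), top_score = runif(80))
    if (length(unique(o$success)) < 2) o$success[1:2] <- c(0L, 1L)
    as.numeric(meta_logistic_cv(o, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.4), 0.06)
  # identical scores: constant prediction, AUC ~ prevalence
  o <- data.frame(success = rep(c(1L, 0L), c(12, 28)), top_score = 0.5)
  expect_lt(abs(as.numeric(suppressWarnings(meta_logistic_cv(o, seed = 3))) -
                  12 / 40), 0.06)
  # single-value outcomes are undefined
  o1 <- data.frame(success = rep(1L, 10), top_score = runif(10))
  expect_error(meta_logistic_cv(o1), class = "coraltex_undefined_auc_error")
})

test_that("replicate summaries stack long tables and round-trip via CSV", {
  set.seed(15)
  x <- matrix(rnorm(90 * 4), 90)
  x[31:60, 1] <- x[31:60, 1] + 3
  x[61:90, 2] <- x[61:90, 2] + 3
  y <- rep(c("a", "b", "c"), each = 30)
  sms <- run_cv_experiment(x, y, classifier_spec("thetafam", epochs = 30L),
                           replicates = 3, seed = 20)
  reps <- lapply(sms, function(s) evaluate_replicate(s, seed = attr(s, "seed"),
                                                     descriptor = "morpho"))
  long <- summarize_replicates(reps)
  expect_identical(nrow(long), 9L) # 3 replicates x 3 classes
  s <- attr(long, "summary")
  expect_true(all(s$median_max_tss >= min(long$max_tss) &
                    s$median_max_tss <= max(long$max_tss)))
  expect_true(all(is.finite(s$iqr_tau)))
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(long, p, row.names = FALSE)
  back <- utils::read.csv(p, stringsAsFactors = FALSE)
  expect_equal(back$max_tss, long$max_tss, tolerance = 1e-12)
  expect_equal(back$prc_auc, long$prc_auc, tolerance = 1e-12)
})
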