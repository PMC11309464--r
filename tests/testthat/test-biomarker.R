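toy_features <- function(n = 40, p = 2, sep = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  labels <- rep(c("HC", "MCI"), each = n / 2)
  x[labels == "MCI", 1] <- x[labels == "MCI", 1] + sep
  list(x = as.data.frame(x), labels = labels)
}

test_that("a separable toy problem is fit perfectly with MCI scores positive", {
  toy <- toy_features(sep = 6)
  m <- train_svm(toy$x, toy$labels)
  s <- predict_scores(m, toy$x)
  expect_true(all(s[toy$labels == "MCI"] > 0))
  expect_true(all(s[toy$labels == "HC"] < 0))
  expect_equal(evaluate(s, toy$labels)$accuracy_pct, 100)
  # duplicating every row leaves the decision function unchanged (in the
  # hard-margin regime; with a binding box constraint duplication doubles the
  # effective per-point budget)
  mh <- train_svm(toy$x, toy$labels, cost = 1000)
  m2 <- train_svm(rbind(toy$x, toy$x), c(toy$labels, toy$labels), cost = 1000)
  # compare the decision functions (the standardization moments differ by the
  # n-1 denominator, so weights agree only up to that scale)
  expect_equal(predict_scores(m2, toy$x), predict_scores(mh, toy$x),
               tolerance = 1e-2)
})

test_that("training fails loudly on single-class input and mismatched columns", {
  toy <- toy_features()
  expect_error(train_svm(toy$x, rep("MCI", 40)), "single class")
  m <- train_svm(toy$x, toy$labels)
  bad <- toy$x
  names(bad) <- c("f1", "other")
  expect_error(predict_scores(m, bad), "match")
})

test_that("test scores use training standardization, not a refit", {
  toy <- toy_features(sep = 3)
  m <- train_svm(toy$x, toy$labels)
  shifted <- toy$x + 10  # a distribution-shifted test set
  s_correct <- predict_scores(m, shifted)
  # deliberately leaky reference: re-standardize on the test moments
  leaky <- scale(as.matrix(shifted))
  s_leaky <- drop(leaky[, m$predictors] %*% m$weights) + m$bias
  expect_false(isTRUE(all.equal(s_correct, unname(s_leaky))))
  # the honest path shifts all scores by the same amount
  expect_equal(s_correct - predict_scores(m, toy$x),
               rep(sum(m$weights * 10 / m$scale), 40), tolerance = 1e-9)
})

test_that("evaluation reproduces AUC conventions and confusion arithmetic", {
  expect_equal(evaluate(c(1, 2, 3, 4), c("HC", "HC", "MCI", "MCI"))$auc, 1.0)
  expect_equal(evaluate(rep(0.5, 6), rep(c("HC", "MCI"), 3))$auc, 0.5)
  # 2 TP, 1 FN, 3 TN, 1 FP -> sens 2/3, spec 3/4, BAC 70.8333%
  scores <- c(1, 1, -1, -1, -1, -1, 1)
  labels <- c("MCI", "MCI", "MCI", "HC", "HC", "HC", "HC")
  ev <- evaluate(scores, labels)
  expect_equal(ev$sensitivity, 2 / 3)
  expect_equal(ev$specificity, 3 / 4)
  expect_equal(ev$balanced_accuracy_pct, 100 * 17 / 24, tolerance = 1e-9)
})

test_that("the rank-statistic AUC matches the pROC oracle including ties", {
  skip_if_not_installed("pROC")
  set.seed(60)
  for (r in 1:25) {
    n <- sample(10:40, 1)
    labels <- sample(c("HC", "MCI"), n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    got <- evaluate(scores, labels)$auc
    want <- as.numeric(pROC::auc(pROC::roc(
      labels, scores, levels = c("HC", "MCI"), direction = "<", quiet = TRUE)))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(61)
  scores <- rnorm(30)
  labels <- rep(c("HC", "MCI"), 15)
  a0 <- evaluate(scores, labels)$auc
  expect_equal(evaluate(exp(scores), labels)$auc, a0)
  expect_equal(evaluate(3 * scores + 7, labels)$auc, a0)
})

test_that("cross-validation is stratified, leak-free and deterministic", {
  ft <- simulate_feature_table(30, 24, seed = 5)
  f <- ft$visits[[1]]
  cv1 <- cross_validate(f, f$label, k = 5, seed = 9)
  cv2 <- cross_validate(f, f$label, k = 5, seed = 9)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$report$auc, cv2$report$auc)
  # each fold contains both classes
  for (fold in 1:5) {
    expect_equal(sort(unique(as.character(f$label[cv1$folds == fold]))),
                 c("HC", "MCI"))
  }
  expect_gte(cv1$report$auc, 0.8)  # calibrated cohort separates well
})

test_that("label shuffling drives cross-validated AUC to chance", {
  ft <- simulate_feature_table(30, 24, seed = 6)
  f <- ft$visits[[1]]
  set.seed(62)
  aucs <- vapply(1:20, function(i) {
    cross_validate(f, sample(as.character(f$label)), k = 5, seed = i)$report$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("split validation rejects subject overlap and honours per-visit labels", {
  ft <- simulate_feature_table(16, 16, n_visits = 2, seed = 7)
  f1 <- ft$visits[[1]]; f2 <- ft$visits[[2]]
  tr_i <- c(1:8, 17:24)   # 8 HC + 8 MCI for training
  te_i <- c(9:16, 25:32)
  tr <- list(features = f1[tr_i, ], labels = f1$label[tr_i],
             subjects = f1$subject[tr_i])
  te <- list(features = f1[te_i, ], labels = f1$label[te_i],
             subjects = f1$subject[te_i])
  expect_error(split_validation(tr, list(a = tr)), "overlap")
  te2 <- list(features = f2[te_i, ], labels = f2$label[te_i],
              subjects = f2$subject[te_i])
  sv <- split_validation(tr, list(baseline = te, followup = te2))
  expect_named(sv$reports, c("baseline", "followup"))
  expect_equal(nrow(sv$retest), 16)
  # relabeling a test subject changes the follow-up evaluation only
  te3 <- te2
  te3$labels[1] <- if (te3$labels[1] == "MCI") "HC" else "MCI"
  sv2 <- split_validation(tr, list(baseline = te, followup = te3))
  expect_equal(sv2$reports$baseline$auc, sv$reports$baseline$auc)
  expect_false(isTRUE(all.equal(sv2$reports$followup$auc,
                                sv$reports$followup$auc)))
})

test_that("weight importance normalizes absolute weights", {
  m <- structure(list(weights = c(a = 3, b = -1), bias = 0,
                      center = c(a = 0, b = 0), scale = c(a = 1, b = 1),
                      predictors = c("a", "b")), class = "linear_svm")
  wi <- weight_importance(m)
  expect_equal(wi$weight_pct, c(75, 25))
  expect_equal(wi$predictor, c("a", "b"))
  expect_equal(sum(wi$weight_pct), 100, tolerance = 1e-9)
})

test_that("permutation importance isolates informative predictors", {
  toy <- toy_features(n = 60, p = 3, sep = 4, seed = 8)
  m <- train_svm(toy$x, toy$labels)
  # force a zero weight on the last predictor
  m$weights["f3"] <- 0
  imp <- permutation_importance(m, toy$x, toy$labels, n_rep = 50, seed = 3)
  expect_lt(abs(imp$d_auc[imp$predictor == "f3"]), 0.01)
  expect_equal(imp$predictor[1], "f1")  # the separating feature drops most
  # the two rankings agree on the toy problem
  wi <- weight_importance(m)
  r1 <- match(c("f1", "f2", "f3"), wi$predictor)
  r2 <- match(c("f1", "f2", "f3"), imp$predictor)
  expect_gt(cor(r1, r2, method = "spearman"), 0)
})

test_that("the SVM model serializes to JSON and back", {
  toy <- toy_features()
  m <- train_svm(toy$x, toy$labels)
  path <- tempfile(fileext = ".json")
  write_svm_json(m, path)
  m2 <- read_svm_json(path)
  expect_equal(predict_scores(m2, toy$x), predict_scores(m, toy$x),
               tolerance = 1e-12)
})

test_that("feature assembly yields the 12 canonical predictors with fallback", {
  gc_rel <- simulate_stat_grids(20, 18, "channel_frequency", seed = 90)
  gc_abs <- simulate_stat_grids(20, 18, "channel_frequency",
                                effects = resting_grid_effects(0.2, -0.2),
                                seed = 91)
  gc_cvt <- simulate_stat_grids(20, 18, "channel_time",
                                effects = erp_grid_effects("cvt"), seed = 92)
  gc_sir <- simulate_stat_grids(20, 18, "channel_time",
                                effects = erp_grid_effects("sir"), seed = 93)
  ids <- sprintf("S%03d", 1:38)
  modal <- lapply(list(psd_rel = gc_rel, psd_abs = gc_abs,
                       erp_cvt = gc_cvt, erp_sir = gc_sir), function(gc) {
    # reduced-size fixture: scale the minimum channel-time cluster size down
    ms <- if (gc$space == "channel_time") 5 else 2
    ct <- cluster_permutation_test(gc$visits[[1]], gc$labels, n_perm = 100,
                                   min_size = ms, seed = 9)
    grids <- gc$visits[[1]]
    dimnames(grids)[[1]] <- ids
    list(grids = grids, clusters = ct$clusters)
  })
  latency <- data.frame(subject = rep(ids, 2),
                        task = rep(c("cvt", "sir"), each = 38),
                        latency_s = runif(76, 0.1, 0.3))
  behavior <- data.frame(subject = rep(ids, 2),
                         task = rep(c("cvt", "sir"), each = 38),
                         rt_s = runif(76, 0.4, 0.9),
                         accuracy_pct = runif(76, 60, 100))
  labels <- stats::setNames(as.character(gc_rel$labels), ids)
  ft <- suppressMessages(assemble_features(modal, latency, behavior, labels))
  expect_s3_class(ft, "feature_table")
  expect_identical(setdiff(names(ft), c("subject", "label")),
                   c("EEG-PSDrel", "EEG-PSDabs",
                     "3CVT-cluster-1", "3CVT-cluster-2", "3CVT-Latency",
                     "SIR-cluster-1", "SIR-cluster-2", "SIR-Latency",
                     "RT-3CVT", "PC-3CVT", "RT-SIR", "PC-SIR"))
  expect_equal(nrow(ft), 38)
  # a subject missing one modality is dropped
  behavior2 <- behavior[!(behavior$subject == "S001" & behavior$task == "sir"), ]
  ft2 <- suppressMessages(assemble_features(modal, latency, behavior2, labels))
  expect_false("S001" %in% ft2$subject)
  # a modality without clusters is a hard error naming the modality
  modal_bad <- modal
  modal_bad$psd_abs$clusters <- list()
  expect_error(suppressMessages(
    assemble_features(modal_bad, latency, behavior, labels)), "psd_abs")
})
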