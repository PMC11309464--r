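# The 12-predictor composite MCI biomarker: feature assembly from cluster
# results and behaviour, a standardized linear SVM, evaluation (AUC, accuracy,
# balanced accuracy), cross-validation, split-sample validation, and two
# feature-importance rankings.

# pick n clusters for a modality: significant ones first (by percentile, then
# |tsize|), topped up with the highest-percentile non-significant clusters
select_clusters <- function(clusters, n, modality) {
  if (length(clusters) == 0) {
    stopf("modality '%s' produced no clusters at any percentile", modality)
  }
  ord <- order(-vapply(clusters, function(x) isTRUE(x$significant), logical(1)),
               -vapply(clusters, `[[`, 0, "percentile"),
               -abs(vapply(clusters, `[[`, 0, "tsize")))
  clusters <- clusters[ord]
  if (!any(vapply(clusters, function(x) isTRUE(x$significant), logical(1)))) {
    message(sprintf(
      "modality '%s': no significant cluster; falling back to the highest-percentile cluster",
      modality))
  }
  if (length(clusters) < n) {
    stopf("modality '%s' produced %d cluster(s); %d needed", modality,
          length(clusters), n)
  }
  clusters[seq_len(n)]
}

#' Assemble the 12-predictor feature table
#'
#' Builds one row per subject with the canonical predictors: the CBA of the
#' significant cluster of the relative and absolute resting PSD analyses (one
#' each), the CBAs of the top two clusters of each ERP task, the
#' early-component peak latency at the configured channel per task, and mean
#' reaction time and accuracy per task. When a modality has no significant
#' cluster, the cluster with the highest percentile is used instead. Subjects
#' missing any modality are dropped (listwise completeness).
#'
#' @param modalities named list with entries `psd_rel`, `psd_abs`, `erp_cvt`,
#'   `erp_sir`; each a list with `grids` (`[subject, channel, bin]` array with
#'   subject ids in `dimnames(grids)[[1]]`) and `clusters` (assessed cluster
#'   list from [cluster_permutation_test()] or [assess_significance()]).
#' @param latency data.frame `subject`, `task` (`"cvt"`/`"sir"`), `latency_s`.
#' @param behavior data.frame `subject`, `task`, `rt_s`, `accuracy_pct`.
#' @param labels optional named vector/factor of diagnosis per subject,
#'   attached as a `label` column.
#' @return data.frame of class `feature_table`: `subject`, optional `label`,
#'   then exactly the 12 named predictors.
#' @export
assemble_features <- function(modalities, latency, behavior, labels = NULL) {
  req <- c("psd_rel", "psd_abs", "erp_cvt", "erp_sir")
  if (!all(req %in% names(modalities))) {
    stopf("modalities must contain: %s", paste(req, collapse = ", "))
  }
  n_per <- c(psd_rel = 1, psd_abs = 1, erp_cvt = 2, erp_sir = 2)
  cba <- list()
  for (m in req) {
    mod <- modalities[[m]]
    subj <- dimnames(mod$grids)[[1]]
    if (is.null(subj)) stopf("modality '%s': grids need subject dimnames", m)
    sel <- select_clusters(mod$clusters, n_per[[m]], m)
    for (i in seq_along(sel)) {
      cba[[paste0(m, "_", i)]] <-
        stats::setNames(cba_by_subject(mod$grids, sel[[i]]), subj)
    }
  }
  lat_of <- function(task) {
    d <- latency[latency$task == task, ]
    stats::setNames(d$latency_s, d$subject)
  }
  beh_of <- function(task, col) {
    d <- behavior[behavior$task == task, ]
    stats::setNames(d[[col]], d$subject)
  }
  cols <- list(
    "EEG-PSDrel" = cba$psd_rel_1, "EEG-PSDabs" = cba$psd_abs_1,
    "3CVT-cluster-1" = cba$erp_cvt_1, "3CVT-cluster-2" = cba$erp_cvt_2,
    "3CVT-Latency" = lat_of("cvt"),
    "SIR-cluster-1" = cba$erp_sir_1, "SIR-cluster-2" = cba$erp_sir_2,
    "SIR-Latency" = lat_of("sir"),
    "RT-3CVT" = beh_of("cvt", "rt_s"), "PC-3CVT" = beh_of("cvt", "accuracy_pct"),
    "RT-SIR" = beh_of("sir", "rt_s"), "PC-SIR" = beh_of("sir", "accuracy_pct")
  )
  subjects <- Reduce(intersect, lapply(cols, names))
  keep <- subjects[vapply(subjects, function(s)
    all(vapply(cols, function(cl) is.finite(cl[[s]]), logical(1))), logical(1))]
  out <- data.frame(subject = keep, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(labels)) out$label <- labels[keep]
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]][keep])
  class(out) <- c("feature_table", "data.frame")
  out
}

predictor_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  drop_cols <- intersect(c("subject", "visit", "label"), names(features))
  as.matrix(features[, setdiff(names(features), drop_cols), drop = FALSE])
}

#' Train the linear SVM MCI classifier
#'
#' Standardizes each predictor by its training mean and SD, then fits a
#' soft-margin linear-kernel SVM (box constraint C = 1). Scores are oriented
#' so that positive values indicate MCI; classification is MCI when the score
#' exceeds 0.
#'
#' @param features a `feature_table` or numeric matrix/data.frame of predictors.
#' @param labels factor/character with levels HC and MCI.
#' @param cost SVM box constraint.
#' @return object of class `linear_svm`: `weights`, `bias`, `center`, `scale`,
#'   `predictors`.
#' @export
train_svm <- function(features, labels, cost = 1) {
  x <- predictor_matrix(features)
  y <- factor(as.character(labels), levels = c("HC", "MCI"))
  if (nlevels(droplevels(y)) < 2) stopf("training labels contain a single class")
  if (any(table(y) < 2)) stopf("need at least 2 subjects per class")
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center, scl)
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients decision values toward the first encountered label
  if (fit$levels[fit$labels[1]] != "MCI") {
    w <- -w
    b <- -b
  }
  structure(list(weights = stats::setNames(w, colnames(x)), bias = b,
                 center = center, scale = scl, predictors = colnames(x)),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d predictors, bias %.3f (score > 0 => MCI)\n",
              length(x$weights), x$bias))
  invisible(x)
}

#' Signed decision scores of the linear SVM
#'
#' Applies the training standardization (never refit on test data) and the
#' linear decision function `w . x + b`; positive scores indicate MCI.
#'
#' @param model a `linear_svm`.
#' @param features predictors with columns matching the model.
#' @return numeric score vector.
#' @export
predict_scores <- function(model, features) {
  x <- predictor_matrix(features)
  if (!setequal(colnames(x), model$predictors)) {
    stopf("feature columns do not match the model's predictors")
  }
  x <- x[, model$predictors, drop = FALSE]
  xs <- scale(x, model$center[model$predictors], model$scale[model$predictors])
  drop(xs %*% model$weights[model$predictors]) + model$bias
}

# rank-statistic AUC with midranks for ties (internal)
auc_midrank <- function(scores, labels, positive = "MCI") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate classifier scores
#'
#' AUC by the rank statistic (ties midranked), accuracy and balanced accuracy
#' at the fixed score > 0 operating point, and the Hedges' g separation of the
#' score distributions.
#'
#' @param scores numeric decision scores (positive = MCI).
#' @param labels factor/character with levels HC and MCI.
#' @return object of class `eval_report`: `auc`, `accuracy_pct`,
#'   `balanced_accuracy_pct`, `sensitivity`, `specificity`, `effect_size_g`,
#'   `n_mci`, `n_hc`.
#' @export
evaluate <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "MCI"
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  pred_mci <- scores > 0
  sens <- sum(pred_mci & pos) / sum(pos)
  spec <- sum(!pred_mci & !pos) / sum(!pos)
  g <- if (sum(pos) >= 2 && sum(!pos) >= 2 &&
           (stats::sd(scores[pos]) > 0 || stats::sd(scores[!pos]) > 0)) {
    hedges_g(scores[pos], scores[!pos])
  } else NA_real_
  structure(list(
    auc = auc_midrank(scores, labels),
    accuracy_pct = 100 * mean(pred_mci == pos),
    balanced_accuracy_pct = 100 * (sens + spec) / 2,
    sensitivity = sens, specificity = spec,
    effect_size_g = g, n_mci = sum(pos), n_hc = sum(!pos)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> AUC %.3f | accuracy %.1f%% | BAC %.1f%% (n = %d MCI / %d HC)\n",
              x$auc, x$accuracy_pct, x$balanced_accuracy_pct, x$n_mci, x$n_hc))
  invisible(x)
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Folds are stratified by class; standardization and the SVM fit happen
#' inside each training fold only (no leakage), and the pooled out-of-fold
#' scores are evaluated once.
#'
#' @inheritParams train_svm
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @return list with `report` (an `eval_report` on pooled out-of-fold scores),
#'   `scores`, `folds`.
#' @export
cross_validate <- function(features, labels, k = 5, seed = 1L, cost = 1) {
  y <- factor(as.character(labels), levels = c("HC", "MCI"))
  n <- length(y)
  if (n < k) stopf("n < k")
  folds <- integer(n)
  with_seed(derive_seed(seed, "cv"), {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  scores <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- train_svm(features[tr, , drop = FALSE], y[tr], cost = cost)
    scores[!tr] <- predict_scores(model, features[!tr, , drop = FALSE])
  }
  list(report = evaluate(scores, y), scores = scores, folds = folds)
}

#' Split-sample validation across visits
#'
#' Fits the classifier on the training set and evaluates it on each test
#' visit separately (subjects must be disjoint from training). Diagnosis
#' labels are taken per visit, so status changes between visits are honoured.
#' When two test visits share subjects, their paired scores are returned for
#' reliability analysis.
#'
#' @param train list with `features`, `labels`, `subjects`.
#' @param test_visits named list of visits, each a list with `features`,
#'   `labels`, `subjects`.
#' @param cost SVM box constraint.
#' @return list with `model`, `reports` (one `eval_report` per visit),
#'   `scores` (per visit), `retest` (data.frame `subject`, `score_1`,
#'   `score_2` for subjects present in the first two visits; NULL otherwise).
#' @export
split_validation <- function(train, test_visits, cost = 1) {
  for (v in test_visits) {
    if (length(intersect(train$subjects, v$subjects)) > 0) {
      stopf("training and testing subjects overlap")
    }
  }
  model <- train_svm(train$features, train$labels, cost = cost)
  reports <- list()
  scores <- list()
  for (nm in names(test_visits)) {
    v <- test_visits[[nm]]
    s <- predict_scores(model, v$features)
    names(s) <- v$subjects
    scores[[nm]] <- s
    reports[[nm]] <- evaluate(s, v$labels)
  }
  retest <- NULL
  if (length(test_visits) >= 2) {
    common <- intersect(names(scores[[1]]), names(scores[[2]]))
    retest <- data.frame(subject = common,
                         score_1 = unname(scores[[1]][common]),
                         score_2 = unname(scores[[2]][common]),
                         stringsAsFactors = FALSE)
  }
  list(model = model, reports = reports, scores = scores, retest = retest)
}

#' Predictor importance from SVM weights
#'
#' Relative importance of each predictor: its absolute weight as a percentage
#' of the sum of absolute weights, sorted descending.
#'
#' @param model a `linear_svm`.
#' @return data.frame `predictor`, `weight_pct`.
#' @export
weight_importance <- function(model) {
  w <- abs(model$weights)
  out <- data.frame(predictor = names(w), weight_pct = 100 * w / sum(w),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$weight_pct), ]
}

#' Permutation feature importance
#'
#' For each predictor, shuffles that column across all data points (without
#' refitting), re-evaluates, and averages the performance change over `n_rep`
#' shuffles. Larger drops indicate more predictive features.
#'
#' @param model a fitted `linear_svm`.
#' @param features,labels evaluation set.
#' @param n_rep number of shuffles per predictor.
#' @param seed integer seed.
#' @return data.frame `predictor`, `d_auc`, `d_accuracy_pct`, `d_bac_pct`
#'   (mean change vs the unshuffled evaluation), sorted by increasing `d_auc`
#'   (most important first).
#' @export
permutation_importance <- function(model, features, labels, n_rep = 100,
                                   seed = 1L) {
  x <- predictor_matrix(features)[, model$predictors, drop = FALSE]
  base <- evaluate(predict_scores(model, x), labels)
  out <- lapply(model$predictors, function(p) {
    d <- matrix(0, n_rep, 3)
    with_seed(derive_seed(seed, "permimp", p), {
      for (r in seq_len(n_rep)) {
        xp <- x
        xp[, p] <- sample(xp[, p])
        ev <- evaluate(predict_scores(model, xp), labels)
        d[r, ] <- c(ev$auc - base$auc,
                    ev$accuracy_pct - base$accuracy_pct,
                    ev$balanced_accuracy_pct - base$balanced_accuracy_pct)
      }
    })
    data.frame(predictor = p, d_auc = mean(d[, 1]), d_accuracy_pct = mean(d[, 2]),
               d_bac_pct = mean(d[, 3]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$d_auc), ]
}

#' Serialize a linear SVM model to JSON
#'
#' @param model a `linear_svm`; @param path output path.
#' @return `path`, invisibly.
#' @export
write_svm_json <- function(model, path) {
  jsonlite::write_json(list(
    weights = as.list(model$weights), bias = model$bias,
    center = as.list(model$center), scale = as.list(model$scale),
    predictors = model$predictors), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a linear SVM model from JSON
#'
#' @param path JSON path written by [write_svm_json()].
#' @return a `linear_svm`.
#' @export
read_svm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = unlist(j$weights), bias = j$bias,
                 center = unlist(j$center), scale = unlist(j$scale),
                 predictors = j$predictors), class = "linear_svm")
}
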