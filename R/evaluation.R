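# Performance metrics (Sn, Sp, Acc, MCC, F-score, AUROC, AUPRC) and
# leakage-free evaluation protocols: stratified k-fold cross-validation and
# the jackknife, both refitting the NPPS encoder and re-running the grid
# search inside every training fold.

#' Confusion counts
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  structure(list(TP = counts[1L], TN = counts[2L], FP = counts[3L],
                 FN = counts[4L]),
            class = "confusion_counts")
}

confusion_from_predictions <- function(truth, predicted) {
  truth <- as_signed_labels(truth)
  predicted <- as_signed_labels(predicted)
  confusion_counts(TP = sum(truth == 1L & predicted == 1L),
                   TN = sum(truth == -1L & predicted == -1L),
                   FP = sum(truth == -1L & predicted == 1L),
                   FN = sum(truth == 1L & predicted == -1L))
}

#' Compute Sn, Sp, Acc, MCC and F-score from confusion counts
#'
#' Standard definitions: `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `Acc = (TP+TN)/n` and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with a
#' zero factor in the MCC denominator giving `MCC = 0`. `Sn` or `Sp` is
#' reported as `NA` when its class is absent from the evaluation set
#' (undefined, not zero).
#'
#' @param confusion a [confusion_counts()] object (or a list with
#'   `TP`/`TN`/`FP`/`FN`).
#' @return object of class `metrics_report`: proportions `Sn`, `Sp`, `Acc`,
#'   `precision`, `recall`, `F1` plus `MCC` and the counts.
#' @export
compute_metrics <- function(confusion) {
  TP <- confusion$TP; TN <- confusion$TN
  FP <- confusion$FP; FN <- confusion$FN
  n <- TP + TN + FP + FN
  if (n == 0L) stop("no evaluated samples (all counts zero)", call. = FALSE)
  sn <- if (TP + FN > 0L) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0L) TN / (TN + FP) else NA_real_
  acc <- (TP + TN) / n
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  prec <- if (TP + FP > 0L) TP / (TP + FP) else NA_real_
  rec <- sn
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else if (TP + FN > 0L) 0 else NA_real_
  structure(
    list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc,
         precision = prec, recall = rec, F1 = f1,
         AUROC = NA_real_, AUPRC = NA_real_,
         counts = confusion_counts(TP, TN, FP, FN)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.*f%%", digits,
                                                     100 * v)
  cat("Sn = ", pct(x$Sn), "  Sp = ", pct(x$Sp), "  Acc = ", pct(x$Acc),
      "  MCC = ", ifelse(is.na(x$MCC), "NA", sprintf("%.4f", x$MCC)),
      "\n", sep = "")
  if (!is.na(x$AUROC)) {
    cat("AUROC = ", sprintf("%.4f", x$AUROC), "  AUPRC = ",
        sprintf("%.4f", x$AUPRC), "\n", sep = "")
  }
  invisible(x)
}

#' Threshold-free ranking metrics
#'
#' AUROC via the Mann-Whitney pair-counting formulation (a tied
#' positive/negative score pair counts 1/2), computed from mid-ranks.
#' AUPRC as the step-wise integral of precision over recall across the
#' distinct score thresholds, descending.
#'
#' @param labels +1/-1 (or `"positive"`/`"negative"`) truth labels.
#' @param scores finite real decision scores, higher = more positive.
#' @return list with `AUROC` and `AUPRC`, both in `[0, 1]`.
#' @export
ranking_metrics <- function(labels, scores) {
  y <- as_signed_labels(labels)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(y) != length(scores)) stop("labels and scores differ in length",
                                        call. = FALSE)
  np <- sum(y == 1L); nn <- sum(y == -1L)
  if (np == 0L || nn == 0L) {
    stop("ranking metrics need both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)

  # PR curve over distinct thresholds, highest first
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # last index of each run of tied scores = one point per distinct threshold
  keep <- which(ss != c(ss[-1L], NA) | seq_along(ss) == length(ss))
  tp <- cumsum(ys == 1L)[keep]
  fp <- cumsum(ys == -1L)[keep]
  recall <- tp / np
  precision <- tp / (tp + fp)
  prev_rec <- c(0, recall[-length(recall)])
  auprc <- sum((recall - prev_rec) * precision)
  list(AUROC = auroc, AUPRC = auprc)
}

#' Stratified k-fold cross-validation with per-fold encoder refitting
#'
#' The dataset is partitioned into `k` stratified folds with a seeded
#' shuffle (plain leave-one-out when `k` equals the number of records).
#' Within each fold the NPPS profiles are fitted only on the training
#' portion, the SVM grid search and training run only on training-portion
#' data, and the held-out portion is encoded with the training-fold
#' profiles — no information flows from validation to training. The nested
#' grid search applies the same discipline one level down: the encoder is
#' refitted inside every inner fold, so the inner F-score is an honest
#' generalization estimate. Each record is validated exactly once.
#'
#' Metrics are reported both pooled (confusion counts summed over folds —
#' the primary report, including AUROC/AUPRC over the pooled scores) and as
#' per-fold reports with their mean accuracy.
#'
#' @param dataset an [npps_dataset()] of positive and negative windows.
#' @param k number of folds (>= 2; `k = n` gives the jackknife).
#' @param intervals,pseudocount encoder configuration passed to
#'   [fit_npps_profiles()].
#' @param config an [svm_config()]; a 1x1 grid skips the inner search.
#' @param seed integer controlling the fold shuffle (and, offset per fold,
#'   the inner grid-search shuffles).
#' @return object of class `npps_cv` with `pooled` (a `metrics_report`),
#'   `folds` (per-fold reports), `fold_mean_acc`, `assignments` (fold id
#'   per record), `params` (chosen `C`/`gamma` per fold), `scores`,
#'   `labels`, and a `config` echo.
#' @export
kfold_cv <- function(dataset, k = 10L, intervals = 0:6, pseudocount = 0,
                     config = svm_config(), seed = 1L) {
  stopifnot(inherits(dataset, "npps_dataset"))
  n <- n_records(dataset)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must be between 2 and n", call. = FALSE)
  y <- as_signed_labels(dataset$labels)
  if (k < n && min(sum(y == 1L), sum(y == -1L)) < k) {
    stop("each class needs at least k members for stratified folds",
         call. = FALSE)
  }
  folds <- stratified_folds(y, k, seed)

  # Inner grid search with the encoder refitted per inner fold: encoding
  # inner-validation samples with profiles that saw them inflates the inner
  # F-score and biases the search toward over-regularized fits, so the
  # same leakage discipline applied to the outer folds is applied here.
  nested_search <- function(train_ds, y_tr, config, seed) {
    folds <- stratified_folds(y_tr, config$inner_folds, seed)
    grid <- expand.grid(gamma = config$gamma_grid, C = config$C_grid,
                        KEEP.OUT.ATTRS = FALSE)
    scores <- matrix(NA_real_, nrow(grid), config$inner_folds)
    for (f in seq_len(config$inner_folds)) {
      val_i <- which(folds == f)
      fit_ds <- subset_records(train_ds, -val_i)
      prof <- fit_npps_profiles(fit_ds, intervals = intervals,
                                pseudocount = pseudocount)
      x_fit <- as.matrix(encode_dataset(prof, fit_ds))
      x_val <- as.matrix(encode_dataset(prof,
                                        subset_records(train_ds, val_i)))
      for (g in seq_len(nrow(grid))) {
        fit <- svm_train(x_fit, y_tr[-val_i], C = grid$C[g],
                         gamma = grid$gamma[g])
        scores[g, f] <- f1_score(y_tr[val_i],
                                 predict(fit, x_val)$labels)
      }
    }
    grid$f_score <- rowMeans(scores)
    ord <- order(-grid$f_score, grid$C, grid$gamma)
    list(C = grid$C[ord[1L]], gamma = grid$gamma[ord[1L]],
         f_score = grid$f_score[ord[1L]])
  }

  fold_reports <- vector("list", k)
  params <- data.frame(fold = seq_len(k), C = NA_real_, gamma = NA_real_,
                       f_score = NA_real_)
  scores <- numeric(n)
  predicted <- integer(n)
  for (f in seq_len(k)) {
    test_i <- which(folds == f)
    train_ds <- subset_records(dataset, -test_i)
    profiles <- fit_npps_profiles(train_ds, intervals = intervals,
                                  pseudocount = pseudocount)
    x_tr <- as.matrix(encode_dataset(profiles, train_ds))
    y_tr <- y[-test_i]
    single_point <- length(config$C_grid) == 1L &&
      length(config$gamma_grid) == 1L
    if (single_point) {
      best <- list(C = config$C_grid, gamma = config$gamma_grid,
                   f_score = NA_real_)
    } else {
      best <- nested_search(train_ds, y_tr, config, config$seed + f)
    }
    model <- svm_train(x_tr, y_tr, C = best$C, gamma = best$gamma,
                       f_score = best$f_score)
    test_ds <- subset_records(dataset, test_i)
    x_te <- as.matrix(encode_dataset(profiles, test_ds))
    pr <- predict(model, x_te)
    scores[test_i] <- pr$scores
    predicted[test_i] <- pr$labels
    fold_reports[[f]] <- compute_metrics(
      confusion_from_predictions(y[test_i], pr$labels))
    params$C[f] <- best$C
    params$gamma[f] <- best$gamma
    params$f_score[f] <- best$f_score
  }

  pooled <- compute_metrics(confusion_from_predictions(y, predicted))
  rk <- ranking_metrics(y, scores)
  pooled$AUROC <- rk$AUROC
  pooled$AUPRC <- rk$AUPRC
  structure(
    list(pooled = pooled, folds = fold_reports,
         fold_mean_acc = mean(vapply(fold_reports, `[[`, numeric(1L),
                                     "Acc")),
         assignments = folds, params = params,
         scores = scores, labels = y,
         config = list(k = k, intervals = intervals,
                       pseudocount = pseudocount, seed = seed,
                       C_grid = config$C_grid,
                       gamma_grid = config$gamma_grid,
                       inner_folds = config$inner_folds)),
    class = "npps_cv"
  )
}

#' @export
print.npps_cv <- function(x, ...) {
  cat(x$config$k, "-fold cross-validation (pooled):\n", sep = "")
  print(x$pooled)
  cat("per-fold mean Acc = ", sprintf("%.2f%%", 100 * x$fold_mean_acc),
      "\n", sep = "")
  invisible(x)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Leave-one-out over all records with per-iteration refitting of the NPPS
#' profiles (and grid search, when the grid has more than one point); the
#' aggregated confusion counts give the metrics. Fully deterministic — no
#' randomness remains once each singleton is its own validation fold.
#'
#' @inheritParams kfold_cv
#' @return an `npps_cv` object (see [kfold_cv()]) with `k = n`.
#' @export
jackknife <- function(dataset, intervals = 0:6, pseudocount = 0,
                      config = svm_config()) {
  n <- n_records(dataset)
  if (n < 3L) stop("jackknife needs at least 3 records", call. = FALSE)
  kfold_cv(dataset, k = n, intervals = intervals,
           pseudocount = pseudocount, config = config, seed = 0L)
}

#' Write a cross-validation report to JSON and TSV
#'
#' @param cv an `npps_cv` result.
#' @param json_path,tsv_path output paths (`NULL` to skip either).
#' @return invisibly, the report list written to JSON.
#' @export
write_cv_report <- function(cv, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(cv, "npps_cv"))
  fold_rows <- do.call(rbind, lapply(seq_along(cv$folds), function(f) {
    m <- cv$folds[[f]]
    data.frame(fold = f, Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, MCC = m$MCC,
               F1 = m$F1, C = cv$params$C[f], gamma = cv$params$gamma[f])
  }))
  p <- cv$pooled
  pooled_row <- data.frame(fold = NA_integer_, Sn = p$Sn, Sp = p$Sp,
                           Acc = p$Acc, MCC = p$MCC, F1 = p$F1,
                           C = NA_real_, gamma = NA_real_)
  report <- list(
    tool = "nppsvm", version = as.character(utils::packageVersion("nppsvm")),
    config = cv$config,
    pooled = p[c("Sn", "Sp", "Acc", "MCC", "precision", "recall", "F1",
                 "AUROC", "AUPRC")],
    pooled_counts = unclass(p$counts),
    fold_mean_acc = cv$fold_mean_acc,
    folds = fold_rows,
    assignments = cv$assignments
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(rbind(fold_rows, pooled_row), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
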