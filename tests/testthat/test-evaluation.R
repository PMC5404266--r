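test_that("metrics follow their standard definitions", {
  perfect <- compute_metrics(confusion_counts(5, 5, 0, 0))
  expect_equal(perfect$Sn, 1)
  expect_equal(perfect$Sp, 1)
  expect_equal(perfect$Acc, 1)
  expect_equal(perfect$MCC, 1)

  # TP*TN - FP*FN = 6 - 6 = 0
  coin <- compute_metrics(confusion_counts(3, 2, 2, 3))
  expect_equal(coin$Acc, 0.5)
  expect_equal(coin$MCC, 0)

  # balanced 10,000-per-class benchmark identity: Acc = (Sn + Sp) / 2
  bench <- compute_metrics(confusion_counts(TP = 7842, TN = 8087,
                                            FP = 1913, FN = 2158))
  expect_equal(100 * bench$Sn, 78.42)
  expect_equal(100 * bench$Sp, 80.87)
  expect_equal(100 * bench$Acc, 79.645)
  expect_lt(abs(100 * bench$Acc - 79.65), 0.005 + 1e-9)  # printed as 79.65%
  expect_equal(bench$Acc, (bench$Sn + bench$Sp) / 2)
  expect_equal(round(bench$MCC, 2), 0.59)
})

test_that("degenerate confusion tables are handled as documented", {
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "zero")
  # empty positive class: Sn undefined (NA), not 0; zero MCC factor -> 0
  m <- compute_metrics(confusion_counts(0, 4, 1, 0))
  expect_true(is.na(m$Sn))
  expect_equal(m$Sp, 0.8)
  expect_equal(m$MCC, 0)
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("MCC is invariant under the simultaneous TP/TN and FP/FN swap", {
  set.seed(3)
  for (i in 1:20) {
    cnt <- as.list(rpois(4, 20) + 1L)
    a <- compute_metrics(confusion_counts(cnt[[1]], cnt[[2]], cnt[[3]],
                                          cnt[[4]]))
    b <- compute_metrics(confusion_counts(cnt[[2]], cnt[[1]], cnt[[4]],
                                          cnt[[3]]))
    expect_equal(a$MCC, b$MCC)
  }
})

test_that("AUROC matches exhaustive pair counting with ties at 1/2", {
  expect_equal(ranking_metrics(c(1, 1, -1, -1), c(3, 2, 1, 0))$AUROC, 1)
  expect_equal(ranking_metrics(c(1, 1, -1, -1), rep(0.7, 4))$AUROC, 0.5)

  pair_count_auroc <- function(y, s) {
    ps <- s[y == 1]; ns <- s[y == -1]
    tot <- 0
    for (p in ps) for (n in ns) tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(ps) * length(ns))
  }
  set.seed(17)
  for (i in 1:25) {
    y <- sample(c(1, -1), 6, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.25), 6, replace = TRUE)  # forces ties
    expect_equal(ranking_metrics(y, s)$AUROC, pair_count_auroc(y, s))
  }
  expect_error(ranking_metrics(c(1, 1), c(0.1, 0.2)), "both classes")
  expect_error(ranking_metrics(c(1, -1), c(Inf, 0)), "finite")
})

test_that("AUPRC agrees with the step integral on a worked case", {
  # scores descending: labels +,-,+,+,-  ->  steps at recall 1/3, 2/3, 1
  y <- c(1, -1, 1, 1, -1)
  s <- c(5, 4, 3, 2, 1)
  expected <- (1 / 3) * 1 + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 4)
  expect_equal(ranking_metrics(y, s)$AUPRC, expected)
  expect_equal(ranking_metrics(c(1, 1, -1), c(2, 1, 0))$AUPRC, 1)
})

test_that("cross-validation folds partition the data and stay stratified", {
  spec <- synthetic_spec(n_pos = 25, n_neg = 20, window_length = 11,
                         seed = 9)
  ds <- generate_dataset(spec)
  cfg <- svm_config(C_grid = 2, gamma_grid = 0.05)
  cv <- kfold_cv(ds, k = 5, intervals = 0:1, config = cfg, seed = 4)
  folds <- cv$assignments
  expect_setequal(folds, 1:5)
  expect_length(folds, 45L)
  y <- ifelse(ds$labels == "positive", 1, -1)
  for (f in 1:5) {
    expect_equal(sum(folds == f & y == 1), 5)
    expect_equal(sum(folds == f & y == -1), 4)
  }
  # pooled counts cover every sample exactly once
  cnt <- cv$pooled$counts
  expect_equal(cnt$TP + cnt$TN + cnt$FP + cnt$FN, 45L)

  # determinism: same data + seed reruns identically
  cv2 <- kfold_cv(ds, k = 5, intervals = 0:1, config = cfg, seed = 4)
  expect_identical(cv$assignments, cv2$assignments)
  expect_identical(cv$scores, cv2$scores)
  expect_identical(cv$pooled$Acc, cv2$pooled$Acc)

  expect_error(kfold_cv(ds, k = 21, intervals = 0:1, config = cfg),
               "at least k members")
})

test_that("jackknife is leave-one-out and equals k = n cross-validation", {
  spec <- synthetic_spec(n_pos = 6, n_neg = 6, window_length = 9,
                         seed = 10)
  ds <- generate_dataset(spec)
  cfg <- svm_config(C_grid = 4, gamma_grid = 0.1)
  jk <- jackknife(ds, intervals = 0:1, config = cfg)
  expect_length(jk$folds, 12L)
  expect_equal(sort(unique(jk$assignments)), 1:12)
  cnt <- jk$pooled$counts
  expect_equal(cnt$TP + cnt$TN + cnt$FP + cnt$FN, 12L)
  kn <- kfold_cv(ds, k = 12, intervals = 0:1, config = cfg, seed = 123)
  expect_equal(jk$pooled$Acc, kn$pooled$Acc)
  expect_equal(sort(jk$scores), sort(kn$scores))
})

test_that("a sequence present in both classes is scored once per record", {
  set.seed(19)
  shared <- "ACGUACGUA"
  pos <- c(shared, random_windows(4, 9))
  neg <- c(shared, random_windows(4, 9))
  ds <- make_labeled_dataset(pos, neg)
  jk <- jackknife(ds, intervals = 0, config = svm_config(C_grid = 1,
                                                         gamma_grid = 0.1))
  cnt <- jk$pooled$counts
  expect_equal(cnt$TP + cnt$FN, 5L)  # one verdict per positive record
  expect_equal(cnt$TN + cnt$FP, 5L)
})

test_that("cv reports serialize to JSON and TSV", {
  spec <- synthetic_spec(n_pos = 10, n_neg = 10, window_length = 9,
                         seed = 2)
  ds <- generate_dataset(spec)
  cv <- kfold_cv(ds, k = 2, intervals = 0:1,
                 config = svm_config(C_grid = 2, gamma_grid = 0.1),
                 seed = 6)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_cv_report(cv, json_path = jp, tsv_path = tp)
  doc <- jsonlite::read_json(jp)
  expect_equal(doc$config$k, 2L)
  expect_equal(doc$config$seed, 6L)
  expect_equal(doc$pooled$Acc, cv$pooled$Acc)
  tsv <- utils::read.delim(tp)
  expect_equal(nrow(tsv), 3L)  # 2 folds + pooled row
})
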