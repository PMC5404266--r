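# RBF-kernel SVM on NPPS features, hyperparameters chosen by grid search
# maximizing the F-score (F1 of the positive class) under stratified inner
# cross-validation. Training and prediction go through e1071, the R binding
# of LibSVM.

#' Grid-search configuration for the RBF SVM
#'
#' The default grids follow the exponential LibSVM convention:
#' `C = 2^-5, 2^-3, ..., 2^15` and `gamma = 2^-15, 2^-13, ..., 2^3`
#' (`fine_gamma = TRUE` halves the gamma step to `x2`). NPPS features are
#' bounded in `[-1, 1]`, so no feature scaling is applied anywhere.
#'
#' @param C_grid strictly increasing positive penalty constants.
#' @param gamma_grid strictly increasing positive RBF widths.
#' @param inner_folds number of stratified folds for the inner
#'   cross-validation of the grid search (>= 2).
#' @param seed integer seed controlling the inner fold shuffling.
#' @param fine_gamma use the finer `x2`-stepped gamma grid.
#' @return an object of class `svm_config`.
#' @export
svm_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = if (fine_gamma) 2^seq(-15, 3, by = 1)
                                    else 2^seq(-15, 3, by = 2),
                       inner_folds = 5L, seed = 1L, fine_gamma = FALSE) {
  check_grid <- function(g, what) {
    if (!length(g) || any(!is.finite(g)) || any(g <= 0) ||
        is.unsorted(g, strictly = TRUE)) {
      stop(what, " must be a non-empty, strictly increasing, positive grid",
           call. = FALSE)
    }
  }
  check_grid(C_grid, "C_grid")
  check_grid(gamma_grid, "gamma_grid")
  inner_folds <- as.integer(inner_folds)
  if (inner_folds < 2L) stop("inner_folds must be >= 2", call. = FALSE)
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid,
                 inner_folds = inner_folds, seed = as.integer(seed)),
            class = "svm_config")
}

# run expr with a private RNG state so library code never perturbs (or
# depends on) the caller's random stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

as_signed_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    labels <- ifelse(labels %in% c("positive", "1", "+1"), 1L,
                     ifelse(labels %in% c("negative", "-1"), -1L,
                            NA_integer_))
  }
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(-1L, 1L))) {
    stop("labels must be +1/-1 (or positive/negative)", call. = FALSE)
  }
  labels
}

# stratified fold ids 1..k, shuffled within class; k == n degenerates to
# plain leave-one-out
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k == n) return(seq_len(n))
  folds <- integer(n)
  with_seed(seed, {
    for (cls in unique(labels)) {
      i <- which(labels == cls)
      if (length(i) < k) {
        stop("class ", cls, " has fewer members (", length(i),
             ") than folds (", k, ")", call. = FALSE)
      }
      folds[i[sample.int(length(i))]] <- rep_len(seq_len(k), length(i))
    }
  })
  folds
}

f1_score <- function(truth, predicted) {
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == -1L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == -1L)
  if (tp == 0L && (fp > 0L || fn > 0L)) return(0)
  if (tp + fp == 0L || tp + fn == 0L) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Choose (C, gamma) by F-score-driven grid search
#'
#' Evaluates every grid point by mean F1 of the positive class over
#' stratified `inner_folds`-fold cross-validation and returns the maximizer.
#' Ties are broken toward smaller `C`, then smaller `gamma`, so the result
#' is deterministic given the data and `config$seed`.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels +1/-1 (or `"positive"`/`"negative"`) class labels.
#' @param config an [svm_config()].
#' @return list with `C`, `gamma`, `f_score` (the best mean F1) and the
#'   full `grid` data frame of all evaluated points.
#' @export
grid_search <- function(features, labels, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  x <- as.matrix(features)
  y <- as_signed_labels(labels)
  if (length(y) != nrow(x)) stop("labels must match feature rows",
                                 call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("grid search needs both classes present", call. = FALSE)
  }
  if (length(y) < 2L * config$inner_folds) {
    stop("need at least 2 * inner_folds samples", call. = FALSE)
  }
  grid <- expand.grid(gamma = config$gamma_grid, C = config$C_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 1L) {
    return(list(C = grid$C[1L], gamma = grid$gamma[1L], f_score = NA_real_,
                grid = cbind(grid, f_score = NA_real_)))
  }
  folds <- stratified_folds(y, config$inner_folds, config$seed)
  grid$f_score <- vapply(seq_len(nrow(grid)), function(g) {
    fs <- vapply(seq_len(config$inner_folds), function(f) {
      tr <- folds != f
      fit <- svm_train(x[tr, , drop = FALSE], y[tr],
                       C = grid$C[g], gamma = grid$gamma[g])
      f1_score(y[!tr], predict(fit, x[!tr, , drop = FALSE])$labels)
    }, numeric(1L))
    mean(fs)
  }, numeric(1L))
  # maximize F1; ties -> smaller C, then smaller gamma
  ord <- order(-grid$f_score, grid$C, grid$gamma)
  best <- grid[ord[1L], ]
  list(C = best$C, gamma = best$gamma, f_score = best$f_score,
       grid = grid[, c("C", "gamma", "f_score")])
}

#' Train the RBF-kernel SVM
#'
#' @param features numeric matrix, one row per sample; must be finite.
#' @param labels +1/-1 (or `"positive"`/`"negative"`) labels, both classes
#'   present.
#' @param C penalty constant.
#' @param gamma RBF kernel width.
#' @param f_score optional grid-search F1 recorded in the model metadata.
#' @return an object of class `npps_model` wrapping the fitted LibSVM
#'   decision function plus `C`, `gamma`, `n`, `D` metadata. Deterministic:
#'   identical inputs give identical models.
#' @export
svm_train <- function(features, labels, C, gamma, f_score = NA_real_) {
  x <- as.matrix(features)
  if (!all(is.finite(x))) stop("features contain non-finite values",
                               call. = FALSE)
  y <- as_signed_labels(labels)
  if (length(y) != nrow(x)) stop("labels must match feature rows",
                                 call. = FALSE)
  if (length(unique(y)) < 2L) stop("training needs both classes present",
                                   call. = FALSE)
  stopifnot(is.numeric(C), C > 0, is.numeric(gamma), gamma > 0)
  fit <- e1071::svm(x, factor(y, levels = c(1L, -1L)), scale = FALSE,
                    type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma)
  structure(
    list(kernel = "RBF", C = C, gamma = gamma, fit = fit,
         n = nrow(x), D = ncol(x), grid_f_score = f_score,
         encoder_checksum = NA_character_, version = 1L),
    class = "npps_model"
  )
}

#' @export
print.npps_model <- function(x, ...) {
  cat("npps_model: RBF SVM, C=", format(x$C), ", gamma=", format(x$gamma),
      ", trained on n=", x$n, ", D=", x$D, "\n", sep = "")
  if (!is.na(x$encoder_checksum)) {
    cat("  encoder checksum: ", x$encoder_checksum, "\n", sep = "")
  }
  invisible(x)
}

#' Predict labels and decision scores
#'
#' @param object a trained [svm_train()] model.
#' @param features numeric matrix with `model$D` columns.
#' @param ... unused.
#' @return list with integer `labels` in `{+1, -1}` and numeric `scores`;
#'   a positive score favors the positive class and `label = sign(score)`
#'   with a score of exactly 0 mapped to +1.
#' @export
predict.npps_model <- function(object, features, ...) {
  x <- as.matrix(features)
  if (nrow(x) == 0L) return(list(labels = integer(0), scores = numeric(0)))
  if (ncol(x) != object$D) {
    stop("feature dimension ", ncol(x), " does not match model dimension ",
         object$D, call. = FALSE)
  }
  pred <- stats::predict(object$fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # orient so that positive scores favor class +1, whatever order LibSVM
  # stored the two classes in
  lab_pair <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]]
  scores <- if (lab_pair[1L] == "1") dv[, 1L] else -dv[, 1L]
  scores <- unname(scores)
  list(labels = ifelse(scores >= 0, 1L, -1L), scores = scores)
}

#' Save / load a trained model
#'
#' The model file is a self-describing archive (RDS) holding the kernel
#' parameters, the LibSVM support data, the checksum of the NPPS encoder it
#' was trained with, and a format version tag. A round trip preserves
#' predictions bit-identically.
#'
#' @param model an `npps_model`, typically with `encoder_checksum` set (see
#'   [attach_encoder()]).
#' @param path file path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "npps_model"))
  saveRDS(list(format = "npps_model", payload = model), path, version = 2L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file '", path,
                                           "': not an RDS archive",
                                           call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "npps_model") ||
      !inherits(obj$payload, "npps_model")) {
    stop("'", path, "' is not a saved npps_model", call. = FALSE)
  }
  obj$payload
}

#' Bind a model to the encoder it was trained with
#'
#' Stores the [profile_checksum()] of `profiles` in the model so that
#' [check_model_encoder()] (called by the prediction pipeline) can refuse a
#' mismatched encoder/model pair.
#'
#' @param model an `npps_model`.
#' @param profiles the `npps_profile_set` used to encode its training data.
#' @return the model with `encoder_checksum` set.
#' @export
attach_encoder <- function(model, profiles) {
  stopifnot(inherits(model, "npps_model"))
  model$encoder_checksum <- profile_checksum(profiles)
  model
}

#' @rdname attach_encoder
#' @export
check_model_encoder <- function(model, profiles) {
  stopifnot(inherits(model, "npps_model"))
  if (is.na(model$encoder_checksum)) return(invisible(TRUE))
  cs <- profile_checksum(profiles)
  if (!identical(cs, model$encoder_checksum)) {
    stop("encoder checksum mismatch: the model was trained with a ",
         "different NPPS profile set (model ", model$encoder_checksum,
         ", supplied ", cs, "); refusing to predict", call. = FALSE)
  }
  invisible(TRUE)
}
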