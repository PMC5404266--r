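# Nucleotide pair position specificity (NPPS) encoding.
#
# For a class of training windows of length l and an interval xi, two
# positional frequency matrices are tallied:
#   T_s (4 x l):          f[i, k]  — probability of nucleotide i at position k
#   T_d (16 x (l-xi-1)):  F[j, k]  — probability of the ordered pair
#                                    (s_k, s_{k+xi+1}) being pair j
# xi counts the nucleotides *between* the two pair members, so xi = 0 is the
# contiguous dinucleotide and a window of length l yields l - xi - 1 pairs.
# A query position k is scored with the conditional probability of the first
# pair member given the second, F[j, k] / f[i, k+xi+1], under the positive
# and the negative profile; the feature is their difference.

#' Fit a per-class positional frequency profile
#'
#' Tallies the single-nucleotide matrix `T_s` (rows `A,C,G,U` by position)
#' and the gapped-pair matrix `T_d` (rows `AA,AC,...,UU` in lexicographic
#' order by pair start position) from all sequences of one class, with
#' optional additive smoothing: counts become `(count + alpha) / (n + 4*alpha)`
#' for single nucleotides and `(count + alpha) / (n + 16*alpha)` for pairs.
#'
#' @param dataset an [npps_dataset()]; every record is used, whatever its
#'   label (restrict with [subset_records()] first).
#' @param interval non-negative integer `xi`, the number of nucleotides
#'   between the two pair members; must satisfy `xi <= l - 2`.
#' @param pseudocount non-negative smoothing weight `alpha` (default 0).
#' @return an object of class `npps_profile` with fields `interval`,
#'   `window_length`, `single_freq` (4 x l), `pair_freq`
#'   (16 x (l - xi - 1)), `n_sequences`, `pseudocount`.
#' @export
#' @examples
#' ds <- npps_dataset(c("ACGU", "ACGA"), label = "positive")
#' pr <- fit_class_profile(ds, interval = 0)
#' pr$single_freq[, 4]   # A and U each seen once at position 4
fit_class_profile <- function(dataset, interval, pseudocount = 0) {
  stopifnot(inherits(dataset, "npps_dataset"))
  n <- n_records(dataset)
  if (n == 0L) stop("cannot fit a profile on an empty dataset", call. = FALSE)
  l <- dataset$window_length
  xi <- as.integer(interval)
  if (xi < 0L || xi > l - 2L) {
    stop("interval must satisfy 0 <= xi <= window_length - 2 (got xi = ",
         xi, ", l = ", l, ")", call. = FALSE)
  }
  alpha <- pseudocount
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("pseudocount must be a single non-negative number", call. = FALSE)
  }

  idx <- sequence_index_matrix(dataset$sequences, l)  # n x l in 1..4
  single_counts <- vapply(seq_len(l), function(k)
    tabulate(idx[, k], nbins = 4L), integer(4L))      # 4 x l
  n_pairs <- l - xi - 1L
  pair_counts <- vapply(seq_len(n_pairs), function(k)
    tabulate(4L * (idx[, k] - 1L) + idx[, k + xi + 1L], nbins = 16L),
    integer(16L))                                     # 16 x (l-xi-1)
  dim(pair_counts) <- c(16L, n_pairs)

  single_freq <- (single_counts + alpha) / (n + 4 * alpha)
  pair_freq <- (pair_counts + alpha) / (n + 16 * alpha)
  dimnames(single_freq) <- list(RNA_BASES, paste0("pos_", seq_len(l)))
  dimnames(pair_freq) <- list(RNA_PAIRS, paste0("pos_", seq_len(n_pairs)))

  structure(
    list(interval = xi, window_length = l, single_freq = single_freq,
         pair_freq = pair_freq, n_sequences = n, pseudocount = alpha),
    class = "npps_profile"
  )
}

# n x l matrix of base indices (A=1, C=2, G=3, U=4)
sequence_index_matrix <- function(sequences, l) {
  chars <- matrix(unlist(strsplit(sequences, "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = length(sequences), ncol = l, byrow = TRUE)
  m <- match(chars, RNA_BASES)
  dim(m) <- dim(chars)
  m
}

#' Fit the paired positive/negative NPPS encoder
#'
#' Fits one [fit_class_profile()] per interval on the positive records and
#' one on the negative records of `dataset`. The result is the trained
#' encoder: four matrix families `T_s+`, `T_d+`, `T_s-`, `T_d-` generalized
#' over the interval set.
#'
#' @param dataset an [npps_dataset()] containing both positive and negative
#'   records.
#' @param intervals ordered set of intervals `xi` (default `0:6`, giving the
#'   329-dimensional joined encoding for 51-nt windows).
#' @param pseudocount additive smoothing `alpha` shared by all profiles.
#' @return an object of class `npps_profile_set` with fields
#'   `positive_profiles`, `negative_profiles` (lists keyed `xi_<value>`),
#'   `intervals`, `window_length`, `pseudocount`.
#' @export
fit_npps_profiles <- function(dataset, intervals = 0:6, pseudocount = 0) {
  stopifnot(inherits(dataset, "npps_dataset"))
  intervals <- sort(unique(as.integer(intervals)))
  pos <- subset_records(dataset, dataset$labels == "positive")
  neg <- subset_records(dataset, dataset$labels == "negative")
  if (n_records(pos) == 0L || n_records(neg) == 0L) {
    stop("both positive and negative records are required to fit the ",
         "encoder", call. = FALSE)
  }
  fit_set <- function(ds) {
    prof <- lapply(intervals, fit_class_profile, dataset = ds,
                   pseudocount = pseudocount)
    names(prof) <- paste0("xi_", intervals)
    prof
  }
  structure(
    list(positive_profiles = fit_set(pos), negative_profiles = fit_set(neg),
         intervals = intervals, window_length = dataset$window_length,
         pseudocount = pseudocount),
    class = "npps_profile_set"
  )
}

#' @export
print.npps_profile_set <- function(x, ...) {
  cat("npps_profile_set: window_length=", x$window_length,
      ", intervals={", paste(x$intervals, collapse = ","),
      "}, joined dimension=", joined_dimension(x),
      ", alpha=", x$pseudocount, "\n", sep = "")
  cat("  fitted on ", x$positive_profiles[[1L]]$n_sequences, " positive / ",
      x$negative_profiles[[1L]]$n_sequences, " negative sequences\n",
      sep = "")
  invisible(x)
}

#' Joined feature dimension of an encoder or interval set
#'
#' `sum(l - xi - 1)` over the intervals: 329 for `l = 51` and
#' `intervals = 0:6`.
#'
#' @param x an `npps_profile_set`, or a vector of intervals.
#' @param window_length required when `x` is a plain interval vector.
#' @return integer dimension.
#' @export
joined_dimension <- function(x, window_length = NULL) {
  if (inherits(x, "npps_profile_set")) {
    intervals <- x$intervals
    window_length <- x$window_length
  } else {
    intervals <- as.integer(x)
    if (is.null(window_length)) stop("window_length required", call. = FALSE)
  }
  sum(as.integer(window_length) - intervals - 1L)
}

# conditional probabilities p_k for one class over all rows at once;
# idx: n x l base-index matrix. Returns n x (l-xi-1).
class_conditionals <- function(profile, idx) {
  xi <- profile$interval
  l <- profile$window_length
  n_pairs <- l - xi - 1L
  ks <- seq_len(n_pairs)
  first <- idx[, ks, drop = FALSE]
  second <- idx[, ks + xi + 1L, drop = FALSE]
  j <- 4L * (first - 1L) + second
  kk <- matrix(rep(ks, each = nrow(idx)), nrow = nrow(idx))
  num <- profile$pair_freq[cbind(as.vector(j), as.vector(kk))]
  den <- profile$single_freq[cbind(as.vector(second), as.vector(kk + xi + 1L))]
  p <- ifelse(den == 0, 0, num / den)   # unseen conditioning base => 0
  matrix(p, nrow = nrow(idx), ncol = n_pairs)
}

#' Encode a sequence with a single-interval NPPS feature vector
#'
#' Position `k` of the output is `p_k = p_k_plus - p_k_minus`, where
#' `p_k_plus` is the conditional probability, under the positive profile, of
#' the first member of the pair `(s_k, s_{k+xi+1})` given its second member
#' (`F[j,k] / f[i,k+xi+1]`), and `p_k_minus` is the same under the negative
#' profile. A zero denominator (conditioning base never seen at that
#' position in a class) yields 0 for that class, keeping every conditional
#' in `[0, 1]` and every feature in `[-1, 1]`.
#'
#' @param profiles a fitted [fit_npps_profiles()] encoder.
#' @param sequence a single window (character string) or an
#'   [npps_dataset()] with exactly one record.
#' @param interval one of `profiles$intervals`.
#' @return numeric vector of length `window_length - interval - 1`.
#' @export
encode_single <- function(profiles, sequence, interval) {
  stopifnot(inherits(profiles, "npps_profile_set"))
  xi <- as.integer(interval)
  key <- paste0("xi_", xi)
  if (!key %in% names(profiles$positive_profiles)) {
    stop("interval ", xi, " not in the fitted set {",
         paste(profiles$intervals, collapse = ","), "}", call. = FALSE)
  }
  ds <- as_single_record(sequence, profiles$window_length)
  idx <- sequence_index_matrix(ds$sequences, profiles$window_length)
  p_pos <- class_conditionals(profiles$positive_profiles[[key]], idx)
  p_neg <- class_conditionals(profiles$negative_profiles[[key]], idx)
  as.numeric(p_pos - p_neg)
}

as_single_record <- function(sequence, window_length) {
  if (inherits(sequence, "npps_dataset")) {
    if (n_records(sequence) != 1L) {
      stop("expected a single sequence", call. = FALSE)
    }
    ds <- sequence
  } else {
    ds <- npps_dataset(as.character(sequence))
  }
  if (ds$window_length != window_length) {
    stop("sequence length ", ds$window_length,
         " does not match encoder window length ", window_length,
         call. = FALSE)
  }
  ds
}

#' Encode a sequence with the joined multi-interval NPPS vector
#'
#' Concatenates the [encode_single()] blocks over the fitted intervals in
#' ascending `xi` order (ascending position within each block). For 51-nt
#' windows and intervals `0:6` the joined vector has 329 dimensions.
#'
#' @inheritParams encode_single
#' @return numeric vector of length [joined_dimension()].
#' @export
encode_joined <- function(profiles, sequence) {
  stopifnot(inherits(profiles, "npps_profile_set"))
  unlist(lapply(profiles$intervals, function(xi)
    encode_single(profiles, sequence, xi)), use.names = FALSE)
}

#' Encode every record of a dataset
#'
#' @param profiles a fitted [fit_npps_profiles()] encoder.
#' @param dataset an [npps_dataset()] with the encoder's window length.
#' @return an `npps_features` object: the numeric `n x D` matrix `values`
#'   (rows named by record id), with attributes `interval_layout` (data
#'   frame of `interval` and `dimension` per block) and `ids`, `labels`.
#' @export
encode_dataset <- function(profiles, dataset) {
  stopifnot(inherits(profiles, "npps_profile_set"),
            inherits(dataset, "npps_dataset"))
  n <- n_records(dataset)
  if (n && dataset$window_length != profiles$window_length) {
    stop("dataset window length ", dataset$window_length,
         " does not match encoder window length ", profiles$window_length,
         call. = FALSE)
  }
  layout <- data.frame(
    interval = profiles$intervals,
    dimension = profiles$window_length - profiles$intervals - 1L
  )
  d_total <- sum(layout$dimension)
  if (n == 0L) {
    values <- matrix(numeric(0), nrow = 0L, ncol = d_total)
  } else {
    idx <- sequence_index_matrix(dataset$sequences, profiles$window_length)
    blocks <- lapply(seq_along(profiles$intervals), function(b) {
      key <- paste0("xi_", profiles$intervals[b])
      class_conditionals(profiles$positive_profiles[[key]], idx) -
        class_conditionals(profiles$negative_profiles[[key]], idx)
    })
    values <- do.call(cbind, blocks)
    rownames(values) <- dataset$ids
  }
  colnames(values) <- feature_names(layout)
  structure(values, class = c("npps_features", class(values)),
            interval_layout = layout, ids = dataset$ids,
            labels = dataset$labels)
}

feature_names <- function(layout) {
  unlist(mapply(function(xi, d) sprintf("xi%d_p%d", xi, seq_len(d)),
                layout$interval, layout$dimension, SIMPLIFY = FALSE),
         use.names = FALSE)
}

#' @export
print.npps_features <- function(x, ...) {
  layout <- attr(x, "interval_layout")
  cat("npps_features: ", nrow(x), " x ", ncol(x), " (intervals ",
      paste(layout$interval, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Serialize a fitted encoder to JSON
#'
#' Writes a single self-describing JSON document holding the window length,
#' intervals, pseudocount and the four matrix families with explicit
#' row/column labels. [load_profiles()] re-validates all invariants.
#'
#' @param profiles a fitted [fit_npps_profiles()] encoder.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "npps_profile_set"))
  pack <- function(prof) {
    list(interval = prof$interval, n_sequences = prof$n_sequences,
         single_freq = mat_to_json(prof$single_freq),
         pair_freq = mat_to_json(prof$pair_freq))
  }
  doc <- list(
    format = "npps_profile_set", version = 1L,
    window_length = profiles$window_length,
    intervals = profiles$intervals,
    pseudocount = profiles$pseudocount,
    checksum = profile_checksum(profiles),
    positive_profiles = lapply(profiles$positive_profiles, pack),
    negative_profiles = lapply(profiles$negative_profiles, pack)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

mat_to_json <- function(m) {
  list(rows = rownames(m), cols = colnames(m), values = unname(m))
}

mat_from_json <- function(x) {
  m <- do.call(rbind, lapply(x$values, as.numeric))
  dimnames(m) <- list(unlist(x$rows), unlist(x$cols))
  m
}

#' Load an encoder saved by [save_profiles()]
#'
#' @param path JSON file path.
#' @return an `npps_profile_set`; fails if the document is malformed or any
#'   profile invariant (column sums, value range, matching intervals) is
#'   violated.
#' @export
load_profiles <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse profile JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, "npps_profile_set")) {
    stop("'", path, "' is not an NPPS profile document", call. = FALSE)
  }
  l <- as.integer(doc$window_length)
  alpha <- as.numeric(doc$pseudocount)
  unpack <- function(x) {
    structure(
      list(interval = as.integer(x$interval), window_length = l,
           single_freq = mat_from_json(x$single_freq),
           pair_freq = mat_from_json(x$pair_freq),
           n_sequences = as.integer(x$n_sequences), pseudocount = alpha),
      class = "npps_profile"
    )
  }
  profiles <- structure(
    list(positive_profiles = lapply(doc$positive_profiles, unpack),
         negative_profiles = lapply(doc$negative_profiles, unpack),
         intervals = as.integer(unlist(doc$intervals)),
         window_length = l, pseudocount = alpha),
    class = "npps_profile_set"
  )
  validate_profile_set(profiles)
  profiles
}

validate_profile_set <- function(profiles, tol = 1e-9) {
  keys <- paste0("xi_", profiles$intervals)
  if (!identical(sort(names(profiles$positive_profiles)), sort(keys)) ||
      !identical(sort(names(profiles$negative_profiles)), sort(keys))) {
    stop("positive and negative profiles must cover exactly the declared ",
         "intervals", call. = FALSE)
  }
  for (side in c("positive_profiles", "negative_profiles")) {
    for (prof in profiles[[side]]) {
      if (prof$window_length != profiles$window_length) {
        stop("profile window length mismatch", call. = FALSE)
      }
      for (m in list(prof$single_freq, prof$pair_freq)) {
        if (any(m < -tol | m > 1 + tol)) {
          stop("profile entries outside [0, 1]", call. = FALSE)
        }
        if (any(abs(colSums(m) - 1) > tol)) {
          stop("profile columns do not sum to 1", call. = FALSE)
        }
      }
      if (ncol(prof$pair_freq) !=
          profiles$window_length - prof$interval - 1L) {
        stop("pair matrix has wrong number of positions for its interval",
             call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' MD5 checksum of a fitted encoder
#'
#' A canonical fingerprint of the four matrix families (values rounded to 12
#' significant digits) plus window length, intervals and pseudocount. Models
#' embed it so that predicting through a different encoder than the one the
#' model was trained with is refused.
#'
#' @param profiles an `npps_profile_set`.
#' @return 32-character hex string.
#' @export
profile_checksum <- function(profiles) {
  stopifnot(inherits(profiles, "npps_profile_set"))
  canon <- list(
    window_length = profiles$window_length,
    intervals = profiles$intervals,
    pseudocount = profiles$pseudocount,
    pos = lapply(profiles$positive_profiles, function(p)
      c(signif(p$single_freq, 12), signif(p$pair_freq, 12))),
    neg = lapply(profiles$negative_profiles, function(p)
      c(signif(p$single_freq, 12), signif(p$pair_freq, 12)))
  )
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf))
  writeBin(serialize(canon, NULL, version = 2L), tf)
  unname(tools::md5sum(tf))
}
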