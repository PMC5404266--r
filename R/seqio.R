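# Fixed-length labeled RNA window datasets: construction, FASTA input,
# feature-table output.

RNA_BASES <- c("A", "C", "G", "U")
RNA_PAIRS <- as.vector(t(outer(RNA_BASES, RNA_BASES, paste0)))

#' Build a labeled dataset of fixed-length RNA windows
#'
#' The basic container for m6A-candidate sequence windows. Sequences are
#' normalized to uppercase RNA (`T` is mapped to `U`) and validated against
#' the `A/C/G/U` alphabet and a common window length.
#'
#' @param sequences character vector of RNA (or DNA) windows.
#' @param label class label recycled across records, or a vector with one
#'   label per record; one of `"positive"`, `"negative"`, `"unknown"`.
#' @param ids optional record identifiers; defaults to `seq_1 ... seq_n`.
#' @param window_length expected window length in nucleotides. If `NULL`,
#'   taken from the first record.
#' @param require_center_a if `TRUE`, require the central position of every
#'   window to be `A` (the m6A candidate). Off by default: it is a property
#'   of how windows were extracted, not of the encoding.
#'
#' @return An object of class `npps_dataset`: a list with `ids`,
#'   `sequences`, `labels` and `window_length`.
#' @export
#' @examples
#' ds <- npps_dataset(c("ACGUA", "AAGUU"), label = "positive")
#' n_records(ds)
npps_dataset <- function(sequences, label = "unknown", ids = NULL,
                         window_length = NULL, require_center_a = FALSE) {
  sequences <- as.character(sequences)
  n <- length(sequences)
  if (is.null(ids)) ids <- if (n) paste0("seq_", seq_len(n)) else character(0)
  ids <- as.character(ids)
  if (length(ids) != n) {
    stop("`ids` must have one entry per sequence (", n, " expected, got ",
         length(ids), ")", call. = FALSE)
  }
  labels <- normalize_labels(label, n)
  sequences <- toupper(sequences)
  sequences <- chartr("T", "U", sequences)

  if (n == 0L) {
    if (is.null(window_length)) window_length <- 0L
  } else {
    lens <- nchar(sequences)
    if (is.null(window_length)) window_length <- lens[1L]
    bad <- which(lens != window_length)
    if (length(bad)) {
      stop("record '", ids[bad[1L]], "' has length ", lens[bad[1L]],
           ", expected window length ", window_length, call. = FALSE)
    }
    check_alphabet(sequences, ids)
    if (require_center_a) {
      center <- (window_length + 1L) %/% 2L
      cb <- substr(sequences, center, center)
      bad <- which(cb != "A")
      if (length(bad)) {
        stop("record '", ids[bad[1L]], "' has '", cb[bad[1L]],
             "' at center position ", center, "; expected 'A'",
             call. = FALSE)
      }
    }
  }

  structure(
    list(ids = ids, sequences = sequences, labels = labels,
         window_length = as.integer(window_length)),
    class = "npps_dataset"
  )
}

normalize_labels <- function(label, n) {
  allowed <- c("positive", "negative", "unknown")
  label <- as.character(label)
  if (!length(label)) label <- "unknown"
  if (length(label) == 1L) label <- rep(label, n)
  if (length(label) != n) {
    stop("`label` must be length 1 or one per record", call. = FALSE)
  }
  bad <- setdiff(unique(label), allowed)
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (use positive/negative/unknown)", call. = FALSE)
  }
  factor(label, levels = allowed)
}

check_alphabet <- function(sequences, ids) {
  bad_pos <- regexpr("[^ACGU]", sequences)
  bad <- which(bad_pos > 0L)
  if (length(bad)) {
    i <- bad[1L]
    sym <- substr(sequences[i], bad_pos[i], bad_pos[i])
    stop("record '", ids[i], "' contains ambiguous base '", sym,
         "' at position ", bad_pos[i],
         " (only A/C/G/U are allowed after normalization)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.npps_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat("npps_dataset: ", length(x$sequences), " windows of ",
      x$window_length, " nt (", tab[["positive"]], " positive, ",
      tab[["negative"]], " negative, ", tab[["unknown"]], " unknown)\n",
      sep = "")
  invisible(x)
}

#' Number of records in a dataset
#'
#' @param dataset an [npps_dataset()].
#' @param label optional class label; if given, counts only that class.
#' @return integer count.
#' @export
n_records <- function(dataset, label = NULL) {
  stopifnot(inherits(dataset, "npps_dataset"))
  if (is.null(label)) return(length(dataset$sequences))
  sum(dataset$labels == label)
}

#' Subset a dataset by index or class
#'
#' @param dataset an [npps_dataset()].
#' @param i integer or logical index over records.
#' @return an [npps_dataset()] with the selected records.
#' @export
subset_records <- function(dataset, i) {
  stopifnot(inherits(dataset, "npps_dataset"))
  npps_dataset(dataset$sequences[i],
               label = as.character(dataset$labels[i]),
               ids = dataset$ids[i],
               window_length = dataset$window_length)
}

#' Concatenate two datasets with a common window length
#'
#' @param a,b [npps_dataset()] objects of equal `window_length`.
#' @return combined [npps_dataset()]; record order is `a` then `b`.
#' @export
bind_datasets <- function(a, b) {
  stopifnot(inherits(a, "npps_dataset"), inherits(b, "npps_dataset"))
  if (n_records(a) && n_records(b) && a$window_length != b$window_length) {
    stop("window lengths differ (", a$window_length, " vs ",
         b$window_length, ")", call. = FALSE)
  }
  wl <- if (n_records(a)) a$window_length else b$window_length
  npps_dataset(c(a$sequences, b$sequences),
               label = c(as.character(a$labels), as.character(b$labels)),
               ids = c(a$ids, b$ids), window_length = wl)
}

#' Read fixed-length RNA windows from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file, normalizes the
#' sequences to uppercase RNA (`T` becomes `U`) and attaches a class label.
#' Ambiguous bases (`N`, `R`, ...) are hard errors unless
#' `skip_ambiguous = TRUE`, in which case offending records are dropped with
#' a warning naming them.
#'
#' @param path FASTA file path.
#' @param label class label for every record: `"positive"`, `"negative"` or
#'   `"unknown"` (labels live in separate files, not in FASTA headers).
#' @param window_length if given, every record must have exactly this
#'   length; otherwise the first record sets it.
#' @param skip_ambiguous drop records with non-ACGU symbols instead of
#'   raising an error.
#' @param require_center_a require the central base to be `A`; see
#'   [npps_dataset()].
#' @return an [npps_dataset()]; record order follows the file.
#' @export
read_fasta <- function(path, label = "unknown", window_length = NULL,
                       skip_ambiguous = FALSE, require_center_a = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  seqs <- as.character(set)
  ids <- names(set)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  # first whitespace-delimited token of the header is the id
  ids <- sub("\\s.*$", "", ids)
  if (skip_ambiguous && length(seqs)) {
    norm <- chartr("T", "U", toupper(seqs))
    bad <- grepl("[^ACGU]", norm)
    if (any(bad)) {
      warning("skipping ", sum(bad), " record(s) with ambiguous bases: ",
              paste(utils::head(ids[bad], 5L), collapse = ", "),
              if (sum(bad) > 5L) ", ..." else "", call. = FALSE)
      seqs <- seqs[!bad]
      ids <- ids[!bad]
    }
  }
  npps_dataset(seqs, label = label, ids = ids,
               window_length = window_length,
               require_center_a = require_center_a)
}

#' Write a dataset to FASTA
#'
#' @param dataset an [npps_dataset()].
#' @param path output file path.
#' @param width line-wrap width; `Inf` keeps each sequence on one line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path, width = Inf) {
  stopifnot(inherits(dataset, "npps_dataset"))
  set <- Biostrings::BStringSet(dataset$sequences)
  names(set) <- dataset$ids
  w <- if (is.finite(width)) as.integer(width) else 20001L
  Biostrings::writeXStringSet(set, path, format = "fasta", width = w)
  invisible(path)
}

label_to_sign <- function(labels) {
  ifelse(as.character(labels) == "positive", 1L,
         ifelse(as.character(labels) == "negative", -1L, NA_integer_))
}

#' Write an encoded feature table
#'
#' Writes one row per sequence in either a TSV layout (`id`, `label`, then
#' `f_1 ... f_D` in the canonical joined-feature order) or the sparse
#' LibSVM text format (`label index:value` with 1-based feature indices).
#' Values are printed with 15 significant digits so a TSV round trip
#' reproduces them to full precision.
#'
#' @param features numeric matrix (or `npps_features` object), one row per
#'   sequence.
#' @param ids character identifiers, one per row.
#' @param labels class labels, one per row (written as `+1`/`-1`/`0` in
#'   libsvm format, verbatim in TSV).
#' @param path output file path.
#' @param format `"tsv"` or `"libsvm"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, ids, labels, path,
                                format = c("tsv", "libsvm")) {
  format <- match.arg(format)
  values <- as.matrix(features)
  n <- nrow(values)
  if (length(ids) != n || length(labels) != n) {
    stop("row count (", n, ") must match ids (", length(ids),
         ") and labels (", length(labels), ")", call. = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "tsv") {
    d <- ncol(values)
    writeLines(paste(c("id", "label", if (d) paste0("f_", seq_len(d))),
                     collapse = "\t"), con)
    if (n) {
      body <- apply(values, 1L, function(r)
        paste(sprintf("%.15g", r), collapse = "\t"))
      if (ncol(values) == 0L) body <- rep("", n)
      lines <- paste(ids, as.character(labels),
                     body, sep = "\t")
      lines <- sub("\t$", "", lines)  # zero-column case
      writeLines(lines, con)
    }
  } else {
    sign <- label_to_sign(labels)
    sign[is.na(sign)] <- 0L
    for (r in seq_len(n)) {
      v <- values[r, ]
      nz <- which(v != 0)
      writeLines(paste(c(sprintf("%+d", sign[r]),
                         sprintf("%d:%.15g", nz, v[nz])),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a TSV feature table written by [write_feature_table()]
#'
#' @param path TSV file path.
#' @return list with `ids`, `labels` and numeric matrix `values`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = NA, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df)[1:2])) {
    stop("not a feature table: expected 'id' and 'label' columns",
         call. = FALSE)
  }
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(values) <- "double"
  list(ids = as.character(df$id), labels = as.character(df$label),
       values = values)
}
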