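# Synthetic fixed-length RNA window generator. Positive windows carry a
# position-specific motif enrichment around the candidate site (by default a
# 5-position DRACH-like consensus centered on the window); negatives are
# i.i.d. background. This emulates the structure of m6A benchmark sets —
# fixed-length windows, a centered consensus — without transcriptome
# context, conservation or secondary structure.

#' Default DRACH-like motif block
#'
#' Five degenerate position-weight columns, D-R-A-C-H, with
#' D = A/G/U, R = A/G and H = A/C/U uniform over their allowed bases and
#' the central column fixed to `A` (the methylation candidate).
#'
#' @return 4 x 5 column-stochastic matrix, rows `A,C,G,U`.
#' @export
drach_motif <- function() {
  cols <- list(
    D = c(A = 1 / 3, C = 0, G = 1 / 3, U = 1 / 3),
    R = c(A = 1 / 2, C = 0, G = 1 / 2, U = 0),
    A = c(A = 1, C = 0, G = 0, U = 0),
    C = c(A = 0, C = 1, G = 0, U = 0),
    H = c(A = 1 / 3, C = 1 / 3, G = 0, U = 1 / 3)
  )
  m <- do.call(cbind, cols)
  rownames(m) <- RNA_BASES
  m
}

#' Specification for a synthetic window dataset
#'
#' Positive windows draw each motif-covered position from
#' `motif_strength * motif + (1 - motif_strength) * background` and every
#' other position from `background`; negative windows are background
#' everywhere. With `center_a = TRUE` (default) the central base of every
#' window, positive or negative, is forced to `A`, as in real m6A benchmark
#' sets where both classes are adenosine-centered.
#'
#' @param n_pos,n_neg numbers of positive and negative windows.
#' @param window_length window length in nt (default 51: the candidate A
#'   with 25 nt of flank on each side).
#' @param background length-4 nucleotide distribution (A,C,G,U), default
#'   uniform.
#' @param motif 4 x w column-stochastic matrix; default [drach_motif()].
#' @param motif_offset 1-based window position of the motif's first column;
#'   default centers the motif on the window.
#' @param motif_strength mixing weight in `[0, 1]`; 1 (default) makes the
#'   consensus fully penetrant in positives, 0 makes the classes
#'   exchangeable.
#' @param center_a force the central base to `A` in both classes.
#' @param seed integer seed; the same spec generates byte-identical data.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 300L, n_neg = 300L, window_length = 51L,
                           background = rep(0.25, 4), motif = drach_motif(),
                           motif_offset = NULL, motif_strength = 1,
                           center_a = TRUE, seed = 1L) {
  window_length <- as.integer(window_length)
  background <- as.numeric(background)
  motif <- as.matrix(motif)
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("background must be a length-4 probability vector", call. = FALSE)
  }
  if (nrow(motif) != 4L || any(motif < 0) ||
      any(abs(colSums(motif) - 1) > 1e-9)) {
    stop("every motif column must be a probability vector over A,C,G,U",
         call. = FALSE)
  }
  if (is.null(motif_offset)) {
    motif_offset <- (window_length + 1L) %/% 2L - (ncol(motif) %/% 2L)
  }
  motif_offset <- as.integer(motif_offset)
  if (motif_offset < 1L ||
      motif_offset + ncol(motif) - 1L > window_length) {
    stop("motif does not fit inside the window", call. = FALSE)
  }
  if (motif_strength < 0 || motif_strength > 1) {
    stop("motif_strength must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         window_length = window_length, background = background,
         motif = motif, motif_offset = motif_offset,
         motif_strength = motif_strength, center_a = isTRUE(center_a),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# per-class 4 x l position distribution matrices implied by a spec
spec_position_distributions <- function(spec) {
  l <- spec$window_length
  bg <- matrix(spec$background, nrow = 4L, ncol = l,
               dimnames = list(RNA_BASES, NULL))
  pos <- bg
  span <- spec$motif_offset + seq_len(ncol(spec$motif)) - 1L
  pos[, span] <- spec$motif_strength * spec$motif +
    (1 - spec$motif_strength) * bg[, span]
  neg <- bg
  if (spec$center_a) {
    center <- (l + 1L) %/% 2L
    pos[, center] <- c(1, 0, 0, 0)
    neg[, center] <- c(1, 0, 0, 0)
  }
  list(positive = pos, negative = neg)
}

#' Generate a labeled synthetic window dataset
#'
#' @param spec a [synthetic_spec()].
#' @return an [npps_dataset()] with `n_pos` positives (ids `pos_1, ...`)
#'   followed by `n_neg` negatives (ids `neg_1, ...`); deterministic given
#'   `spec$seed`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dists <- spec_position_distributions(spec)
  with_seed(spec$seed, {
    pos <- sample_windows(spec$n_pos, dists$positive)
    neg <- sample_windows(spec$n_neg, dists$negative)
  })
  ids <- c(if (spec$n_pos) paste0("pos_", seq_len(spec$n_pos)),
           if (spec$n_neg) paste0("neg_", seq_len(spec$n_neg)))
  npps_dataset(c(pos, neg),
               label = rep(c("positive", "negative"),
                           c(spec$n_pos, spec$n_neg)),
               ids = ids, window_length = spec$window_length)
}

# draw n windows, position k from the 4-distribution dist[, k]
sample_windows <- function(n, dist) {
  if (n == 0L) return(character(0))
  l <- ncol(dist)
  m <- vapply(seq_len(l), function(k)
    sample.int(4L, n, replace = TRUE, prob = dist[, k]), integer(n))
  dim(m) <- c(n, l)
  apply(m, 1L, function(r) paste(RNA_BASES[r], collapse = ""))
}

#' Write a synthetic dataset as FASTA files plus a JSON sidecar
#'
#' Emits `<prefix>_pos.fasta` and `<prefix>_neg.fasta` along with
#' `<prefix>_spec.json` recording the full generating spec (including the
#' seed), so the files are reconstructible.
#'
#' @param spec a [synthetic_spec()].
#' @param prefix output path prefix.
#' @return character vector of the three paths written, invisibly.
#' @export
write_synthetic_fasta <- function(spec, prefix) {
  ds <- generate_dataset(spec)
  paths <- paste0(prefix, c("_pos.fasta", "_neg.fasta", "_spec.json"))
  write_fasta(subset_records(ds, ds$labels == "positive"), paths[1L])
  write_fasta(subset_records(ds, ds$labels == "negative"), paths[2L])
  side <- spec
  side$motif <- mat_to_json(side$motif)
  class(side) <- NULL
  jsonlite::write_json(side, paths[3L], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
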