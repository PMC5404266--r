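test_that("class profiles tally positional frequencies exactly", {
  # degenerate single-sequence case
  ds1 <- npps_dataset("AAAA", label = "positive")
  pr1 <- fit_class_profile(ds1, interval = 0)
  expect_equal(unname(pr1$single_freq), matrix(c(1, 0, 0, 0), 4, 4))
  expect_true(all(pr1$pair_freq["AA", ] == 1))

  # hand-counted two-sequence case
  ds2 <- npps_dataset(c("ACGU", "ACGA"), label = "positive")
  pr2 <- fit_class_profile(ds2, interval = 0)
  expect_equal(unname(pr2$single_freq[, 4]), c(0.5, 0, 0, 0.5))
  expect_equal(pr2$pair_freq["GU", 3], 0.5, ignore_attr = TRUE)
  expect_equal(pr2$pair_freq["GA", 3], 0.5, ignore_attr = TRUE)
  expect_equal(ncol(pr2$pair_freq), 3L)  # l - xi - 1

  # 51-nt windows at xi = 0 give 50 pair positions
  set.seed(41)
  ds3 <- npps_dataset(random_windows(5, 51), label = "negative")
  expect_equal(ncol(fit_class_profile(ds3, 0)$pair_freq), 50L)
})

test_that("profile columns are distributions for any pseudocount", {
  set.seed(11)
  for (alpha in c(0, 0.5, 1, 5)) {
    ds <- npps_dataset(random_windows(7, 9))
    pr <- fit_class_profile(ds, interval = 2, pseudocount = alpha)
    expect_true(all(abs(colSums(pr$single_freq) - 1) < 1e-9))
    expect_true(all(abs(colSums(pr$pair_freq) - 1) < 1e-9))
    expect_true(all(pr$single_freq >= 0 & pr$single_freq <= 1))
    expect_true(all(pr$pair_freq >= 0 & pr$pair_freq <= 1))
  }
})

test_that("profile fitting is invariant to record order", {
  set.seed(12)
  seqs <- random_windows(9, 8)
  a <- fit_class_profile(npps_dataset(seqs), 1)
  b <- fit_class_profile(npps_dataset(rev(seqs)), 1)
  expect_identical(a$single_freq, b$single_freq)
  expect_identical(a$pair_freq, b$pair_freq)
})

test_that("profile preconditions are enforced", {
  ds <- npps_dataset(c("ACGU"))
  expect_error(fit_class_profile(subset_records(ds, integer(0)), 0),
               "empty")
  expect_error(fit_class_profile(ds, interval = 3), "interval")
  expect_error(fit_class_profile(ds, interval = 0, pseudocount = -1),
               "pseudocount")
})

test_that("worked toy encoding matches hand-derived conditionals", {
  # All positive-class conditionals of the query are 1 by counting; every
  # negative-class one hits the zero-denominator rule and contributes 0.
  full <- make_labeled_dataset(c("ACGU", "ACGA"), c("UGCA", "UGCC"))
  ps <- fit_npps_profiles(full, intervals = 0)
  expect_equal(encode_single(ps, "ACGU", 0), c(1, 1, 1))
})

test_that("encode_single matches the brute-force recount oracle", {
  set.seed(99)
  for (case in seq_len(60)) {
    l <- sample(4:10, 1)
    xi <- sample(0:min(3, l - 2), 1)
    alpha <- sample(c(0, 0, 0.5, 1), 1)
    pos <- random_windows(sample(1:8, 1), l)
    neg <- random_windows(sample(1:8, 1), l)
    query <- random_windows(1, l)
    ps <- fit_npps_profiles(make_labeled_dataset(pos, neg),
                            intervals = xi, pseudocount = alpha)
    expect_equal(encode_single(ps, query, xi),
                 brute_force_encode(pos, neg, query, xi, alpha),
                 tolerance = 1e-12)
  }
})

test_that("identical positive and negative training sets encode to zero", {
  set.seed(5)
  seqs <- random_windows(6, 12)
  ps <- fit_npps_profiles(make_labeled_dataset(seqs, seqs), intervals = 0:4)
  for (q in random_windows(5, 12)) {
    expect_identical(encode_joined(ps, q),
                     rep(0, joined_dimension(ps)))
  }
})

test_that("joined encoding concatenates single-interval blocks in order", {
  set.seed(21)
  ds <- make_labeled_dataset(random_windows(4, 4), random_windows(4, 4))
  ps <- fit_npps_profiles(ds, intervals = 0:1)
  q <- "AGCU"
  joined <- encode_joined(ps, q)
  expect_length(joined, 5L)  # (4-1) + (4-2)
  expect_equal(joined[1:3], encode_single(ps, q, 0))
  expect_equal(joined[4:5], encode_single(ps, q, 1))
})

test_that("joined dimension follows sum(l - xi - 1)", {
  expect_equal(joined_dimension(0:6, 51), 329L)
  expect_equal(joined_dimension(0, 51), 50L)
  expect_equal(joined_dimension(5, 51), 45L)
  expect_equal(joined_dimension(6, 51), 44L)
  set.seed(31)
  ds <- make_labeled_dataset(random_windows(3, 51), random_windows(3, 51))
  ps <- fit_npps_profiles(ds, intervals = 0:6)
  expect_length(encode_joined(ps, random_windows(1, 51)), 329L)
})

test_that("encode_dataset is row-wise encode_joined with bounded entries", {
  set.seed(42)
  ds <- make_labeled_dataset(random_windows(10, 9), random_windows(10, 9))
  ps <- fit_npps_profiles(ds, intervals = 0:3)
  feats <- encode_dataset(ps, ds)
  expect_equal(dim(feats), c(20L, joined_dimension(ps)))
  expect_true(all(feats >= -1 & feats <= 1))
  expect_equal(unname(as.matrix(feats)[7, ]),
               encode_joined(ps, ds$sequences[7]))
  layout <- attr(feats, "interval_layout")
  expect_equal(layout$interval, 0:3)
  expect_equal(layout$dimension, c(8L, 7L, 6L, 5L))

  # empty dataset keeps the layout metadata
  empty <- encode_dataset(ps, subset_records(ds, integer(0)))
  expect_equal(dim(empty), c(0L, joined_dimension(ps)))
  expect_equal(attr(empty, "interval_layout")$dimension, layout$dimension)

  # identical sequences encode identically
  dup <- npps_dataset(rep(ds$sequences[1], 2), label = "unknown",
                      window_length = 9)
  fd <- encode_dataset(ps, dup)
  expect_identical(as.matrix(fd)[1, ], as.matrix(fd)[2, ])
})

test_that("encoding rejects unknown intervals and length mismatches", {
  ds <- make_labeled_dataset(c("ACGU"), c("UGCA"))
  ps <- fit_npps_profiles(ds, intervals = 0:1)
  expect_error(encode_single(ps, "ACGU", 2), "interval 2")
  expect_error(encode_single(ps, "ACGUA", 0), "length")
  expect_error(encode_dataset(ps, npps_dataset("ACGUA")), "window length")
})

test_that("profiles survive a JSON round trip and are validated on load", {
  set.seed(8)
  ds <- make_labeled_dataset(random_windows(5, 8), random_windows(4, 8))
  ps <- fit_npps_profiles(ds, intervals = 0:2, pseudocount = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  save_profiles(ps, path)
  back <- load_profiles(path)
  expect_equal(back$intervals, ps$intervals)
  expect_equal(back$pseudocount, ps$pseudocount)
  q <- random_windows(1, 8)
  expect_equal(encode_joined(back, q), encode_joined(ps, q),
               tolerance = 1e-14)
  expect_identical(profile_checksum(back), profile_checksum(ps))

  # corrupting a stored frequency must be caught on load
  doc <- jsonlite::read_json(path)
  doc$positive_profiles$xi_0$single_freq$values[[1]][[1]] <- 0.9
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_profiles(path), "sum to 1")
  writeLines("not json", path)
  expect_error(load_profiles(path), "parse")
})

test_that("the encoder checksum is sensitive to the training data", {
  set.seed(77)
  ds1 <- make_labeled_dataset(random_windows(4, 7), random_windows(4, 7))
  ds2 <- make_labeled_dataset(random_windows(4, 7), random_windows(4, 7))
  ps1 <- fit_npps_profiles(ds1, intervals = 0:1)
  ps2 <- fit_npps_profiles(ds2, intervals = 0:1)
  expect_false(identical(profile_checksum(ps1), profile_checksum(ps2)))
})
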