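test_that("scanning scores consensus at 1 and matches a brute-force oracle", {
  m <- toy_model()
  tr <- scan_affinity(model_consensus(m), m)
  expect_equal(tr$affinity, 1)
  expect_equal(tr$pos, 0L)

  # exhaustive enumeration over all offsets and both strands, 4-bp toy model
  m4 <- toy_model("t4", "ACGT")
  s8 <- "TTACGTAA"
  tr4 <- scan_affinity(s8, m4)
  expect_equal(nrow(tr4), 5L)
  expect_equal(tr4$affinity, brute_scan(s8, m4), tolerance = 1e-12)

  # and on random sequences with a second model
  for (s in withr::with_seed(3, random_dna(5, 25))) {
    trb <- scan_affinity(s, toy_model_b())
    expect_equal(trb$affinity, brute_scan(s, toy_model_b()), tolerance = 1e-12)
  }

  expect_error(scan_affinity("ACG", m), "shorter")
})

test_that("palindromic models score both strands equally", {
  m <- palindromic_model()
  s <- withr::with_seed(11, random_dna(1, 40))
  k <- m$k
  W <- m$weights
  score <- function(km) {
    prod(vapply(seq_len(k), function(j) W[j, substr(km, j, j)], numeric(1)))
  }
  for (i in seq_len(nchar(s) - k + 1)) {
    km <- substr(s, i, i + k - 1)
    expect_equal(score(km), score(revcomp(km)), tolerance = 1e-12)
  }
  # with equal strands the scanner reports the forward orientation
  expect_true(all(scan_affinity(s, m)$strand == "+"))
})

test_that("scan is strand-consistent under reverse complement", {
  m <- toy_model_b()
  s <- withr::with_seed(5, random_dna(1, 60))
  t1 <- scan_affinity(s, m)
  t2 <- scan_affinity(revcomp(s), m)
  expect_equal(rev(t2$affinity), t1$affinity, tolerance = 1e-12)
  # strands flip wherever the two orientations are not tied
  k <- m$k
  W <- m$weights
  fwd_score <- function(seq, i) {
    prod(vapply(seq_len(k),
                function(j) W[j, substr(seq, i + j - 1, i + j - 1)],
                numeric(1)))
  }
  fwd <- vapply(seq_len(nchar(s) - k + 1), function(i) fwd_score(s, i),
                numeric(1)) / m$norm_constant
  rc_score <- vapply(seq_len(nchar(s) - k + 1), function(i) {
    km <- substr(s, i, i + k - 1)
    prod(vapply(seq_len(k),
                function(j) W[j, substr(revcomp(km), j, j)], numeric(1)))
  }, numeric(1)) / m$norm_constant
  not_tied <- abs(fwd - rc_score) > 1e-12
  expect_equal(rev(ifelse(t2$strand == "+", "-", "+"))[not_tied],
               t1$strand[not_tied])
})

test_that("norm-constant calibration is a seeded empirical quantile", {
  flat <- binding_model("flat", matrix(1, 6, 4))
  expect_equal(calibrate_norm_constant(flat, 1e4, seed = 1), 1.0)
  m <- toy_model()
  c1 <- calibrate_norm_constant(m, 5e4, seed = 42)
  c2 <- calibrate_norm_constant(m, 5e4, seed = 42)
  expect_identical(c1, c2)
  c3 <- calibrate_norm_constant(m, 5e4, seed = 43)
  expect_lt(abs(log(c3 / c1)), 0.5)  # smooth toy model: resampling stability
  expect_error(calibrate_norm_constant(m, 100, seed = 1), "10,000")
})

test_that("normalized affinity is invariant to per-position rescaling after recalibration", {
  m <- toy_model()
  w2 <- m$weights
  w2[3, ] <- w2[3, ] * 7.5
  m2 <- binding_model(m$tf_name, w2,
                      norm_constant = calibrate_norm_constant(
                        binding_model(m$tf_name, w2), 2e4, seed = 9))
  m1 <- binding_model(m$tf_name, m$weights,
                      norm_constant = calibrate_norm_constant(m, 2e4, seed = 9))
  s <- withr::with_seed(2, random_dna(1, 50))
  expect_equal(scan_affinity(s, m1)$affinity, scan_affinity(s, m2)$affinity,
               tolerance = 1e-12)
})

test_that("TFBS calling suppresses non-maxima and recovers planted sites", {
  m <- toy_model()
  low <- scan_affinity(withr::with_seed(8, random_dna(1, 50)), m)
  low$affinity <- rep(0.01, nrow(low))
  expect_equal(nrow(call_tfbs(low, 0.05)), 0L)

  s <- paste0(strrep("T", 13), model_consensus(m), strrep("T", 11))
  sites <- call_tfbs(scan_affinity(s, m), 0.05)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 13L)
  expect_equal(sites$end, 13L + m$k)
  expect_equal(sites$affinity, 1)
})

test_that("max-merge keeps the winning model's affinity and orientation", {
  m <- toy_model()
  s <- withr::with_seed(21, random_dna(1, 40))
  ta <- scan_affinity(s, m)
  tb <- scan_affinity(s, toy_model("tfA2", "CCGGTA", off = 0.04))
  mg <- max_merge_tracks(ta, tb, tf_name = "tfA/2")
  expect_equal(mg$affinity, pmax(ta$affinity, tb$affinity))
  win_a <- ta$affinity >= tb$affinity
  expect_equal(mg$strand, ifelse(win_a, ta$strand, tb$strand))
  mg_flip <- max_merge_tracks(ta, tb, flip_b_strand = TRUE)
  lost <- !win_a
  expect_equal(mg_flip$strand[lost],
               ifelse(tb$strand[lost] == "+", "-", "+"))
})

test_that("anchor building merges overlapping sites and tiles the CRE", {
  m <- toy_model()
  # two overlapping planted motifs: consensus then a shifted copy sharing 2 bp
  s <- paste0("TT", "ACGTACGTAC", strrep("T", 20))  # consensus at 2 and at 6
  a <- build_anchors(tibble::tibble(id = "c", seq = s), list(m),
                     threshold = 0.04)
  anchors <- a[a$type == "anchor", ]
  gaps <- a[a$type == "gap", ]
  # sweep-line oracle: anchor cover equals the union of called intervals
  tr <- scan_affinity(s, m)
  called <- call_tfbs(tr, 0.04)
  covered <- sort(unique(unlist(Map(function(s0, e0) s0:(e0 - 1),
                                    called$start, called$end))))
  anchor_cover <- sort(unlist(Map(function(s0, e0) s0:(e0 - 1),
                                  anchors$start, anchors$end)))
  expect_true(all(covered %in% anchor_cover))
  # anchors are disjoint and, with gaps, tile [0, L)
  allv <- c(anchor_cover, unlist(Map(function(s0, e0) s0:(e0 - 1),
                                     gaps$start, gaps$end)))
  expect_equal(sort(allv), 0:(nchar(s) - 1))
  expect_equal(anyDuplicated(allv), 0L)

  # disjoint sites stay unchanged
  s2 <- paste0("TT", model_consensus(m), strrep("A", 10), model_consensus(m),
               strrep("T", 8))
  a2 <- build_anchors(s2, list(m), threshold = 0.05)
  expect_equal(nrow(a2[a2$type == "anchor", ]), 2L)
  expect_warning(build_anchors(strrep("T", 40), list(m), threshold = 0.5),
                 "empty")
})

test_that("binding models round-trip through their TSV format", {
  m <- toy_model(norm_constant = 0.123)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_binding_model(m, f)
  back <- read_binding_model(f)
  expect_equal(back$tf_name, m$tf_name)
  expect_equal(back$weights, m$weights)
  expect_equal(back$norm_constant, m$norm_constant)
})
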