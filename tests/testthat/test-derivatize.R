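test_that("dinucleotide shuffling preserves transition counts exactly", {
  expect_equal(dinucleotide_shuffle("AAAA", 1), "AAAA")
  set.seed(5)
  for (i in 1:25) {
    s <- random_dna(1, sample(20:200, 1), gc = runif(1, 0.3, 0.7))
    sh <- dinucleotide_shuffle(s, seed = i)
    expect_equal(dinucleotide_counts(sh), dinucleotide_counts(s))
    expect_equal(nchar(sh), nchar(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
  # determinism
  s <- random_dna(1, 80)
  expect_identical(dinucleotide_shuffle(s, 42), dinucleotide_shuffle(s, 42))
})

test_that("dinucleotide shuffling samples all Eulerian arrangements roughly uniformly", {
  s <- "AATATGATT"
  # oracle: exhaustive enumeration of sequences with identical transition
  # counts, same first and last base, by brute-force permutation of the
  # middle characters
  chars <- strsplit(s, "")[[1]]
  mid <- chars[2:(length(chars) - 1)]
  perms <- unique(combinat_perms(mid))
  valid <- unique(vapply(perms, function(p) {
    paste(c(chars[1], p, chars[length(chars)]), collapse = "")
  }, character(1)))
  valid <- valid[vapply(valid, function(v) {
    identical(dinucleotide_counts(v), dinucleotide_counts(s))
  }, logical(1))]
  draws <- vapply(1:1500, function(i) dinucleotide_shuffle(s, i), character(1))
  expect_true(all(draws %in% valid))
  expect_setequal(unique(draws), valid)  # full support reached
  tab <- table(factor(draws, levels = valid))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("background panels pair each sequence with a composition-matched shuffle", {
  bg <- make_backgrounds(n = 10, length = 60, seed = 3)
  expect_equal(nrow(bg), 20L)
  expect_equal(sum(bg$origin == "genomic_inaccessible"), 10L)
  shufs <- bg[bg$origin == "dinucleotide_shuffle", ]
  for (i in seq_len(nrow(shufs))) {
    parent <- bg$seq[bg$id == shufs$parent_id[i]]
    expect_equal(dinucleotide_counts(shufs$seq[i]),
                 dinucleotide_counts(parent))
  }
})

test_that("reconstitution splices anchors at exact positions", {
  anchors <- tibble::tibble(start = 2L, end = 5L, seq = "CGT")
  out <- reconstitute(anchors, "AAAAAAAA")
  expect_equal(out$seq, "AACGTAAA")

  # flank trim writes the central bases at [start+1, end-1)
  a5 <- tibble::tibble(start = 2L, end = 7L, seq = "CGTGC")
  tr <- reconstitute(a5, "AAAAAAAAAA", flank_trim = 1)
  expect_equal(tr$seq, paste0("AAA", "GTG", "AAAA"))

  # native positions preserve inter-anchor spacing exactly
  cre <- "TTCGTAAGGAATT"
  aset <- tibble::tibble(start = c(2L, 8L), end = c(5L, 11L),
                         seq = c("CGT", "GAA"))
  rec <- reconstitute(aset, strrep("C", 13))
  expect_equal(substr(rec$seq, 3, 5), "CGT")
  expect_equal(substr(rec$seq, 9, 11), "GAA")

  expect_error(
    reconstitute(tibble::tibble(start = c(0L, 2L), end = c(3L, 5L),
                                seq = c("AAA", "CCC")), "GGGGGG"),
    "overlap")
})

test_that("random deposition is uniform, non-overlapping and seed-deterministic", {
  a <- tibble::tibble(start = 0L, end = 10L, seq = strrep("G", 10))
  forced <- random_deposit(a, strrep("A", 10), seed = 1)
  expect_equal(forced$layout$start, 0L)

  d1 <- random_deposit(a, strrep("A", 40), seed = 9)
  d2 <- random_deposit(a, strrep("A", 40), seed = 9)
  expect_identical(d1$seq, d2$seq)

  # empirical placement frequency of a short anchor is uniform
  a2 <- tibble::tibble(start = 0L, end = 2L, seq = "GG")
  starts <- vapply(1:4000, function(i) {
    random_deposit(a2, strrep("A", 10), seed = i)$layout$start
  }, integer(1))
  expect_setequal(unique(starts), 0:8)
  expect_gt(stats::chisq.test(table(factor(starts, levels = 0:8)))$p.value,
            0.01)

  # several anchors never overlap
  many <- tibble::tibble(start = c(0L, 0L, 0L), end = c(8L, 6L, 4L),
                         seq = c(strrep("G", 8), strrep("C", 6), strrep("T", 4)))
  dep <- random_deposit(many, strrep("A", 30), seed = 2)
  lay <- dplyr::arrange(dep$layout, start)
  expect_true(all(lay$start[-1] >= lay$end[-nrow(lay)]))
})

test_that("thripsis conserves fragment content and keeps anchors intact", {
  m <- toy_model()
  cre <- generate_cre(150, list(m), n_sites = 3, seed = 21)
  s <- cre$record$seq[[1]]
  aset <- build_anchors(cre$record, list(m), threshold = 0.05)

  # no cuts: identity
  expect_equal(thripsis(s, aset, 0, seed = 1)$seq, s)

  th <- thripsis(s, aset, 5, seed = 2)
  expect_equal(nrow(th$layout), 6L)  # N + 1 fragments
  expect_equal(nchar(th$seq), nchar(s))
  # multiset of fragment strings conserved
  frags_orig <- substring(s, th$layout$orig_start + 1, th$layout$orig_end)
  frags_new <- substring(th$seq, th$layout$new_start + 1, th$layout$new_end)
  expect_equal(sort(frags_new), sort(frags_orig))
  # anchors intact in the derived sequence
  for (a in anchor_seqs(aset, s)$seq) {
    expect_true(grepl(a, th$seq, fixed = TRUE))
  }
  expect_error(thripsis(s, aset, 10000, seed = 1), "gap positions")
})

test_that("fragment reconstruction inverts a known permutation", {
  expect_equal(nrow(reconstruct_fragments("ACGTACGT", "ACGTACGT")), 1L)

  # three fragments with unique content, permuted so that no two fragments
  # stay adjacent (adjacent fragments would legitimately merge into one)
  f1 <- "AAAACCC"; f2 <- "GGGTTTA"; f3 <- "CATCATG"
  orig <- paste0(f1, f2, f3)
  deriv <- paste0(f2, f1, f3)
  rec <- reconstruct_fragments(orig, deriv)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$orig_start, c(0L, 7L, 14L))
  expect_equal(rec$new_start, c(7L, 0L, 14L))
  # every original position covered exactly once
  cov <- unlist(Map(function(s0, e0) s0:(e0 - 1), rec$orig_start, rec$orig_end))
  expect_equal(sort(cov), 0:(nchar(orig) - 1))
  expect_error(reconstruct_fragments("ACGT", "ACG"), "equal length")
})

test_that("thripsis layouts are recovered by reconstruction on random cases", {
  m <- toy_model()
  set.seed(33)
  for (i in 1:5) {
    cre <- generate_cre(120, list(m), n_sites = 2, seed = 100 + i)
    s <- cre$record$seq[[1]]
    aset <- build_anchors(cre$record, list(m), threshold = 0.05)
    th <- thripsis(s, aset, 4, seed = 200 + i)
    rec <- reconstruct_fragments(s, th$seq)
    # reconstruction covers both sequences completely
    expect_equal(sum(rec$orig_end - rec$orig_start), nchar(s))
    # each recovered piece really matches between the two sequences
    for (j in seq_len(nrow(rec))) {
      expect_equal(substring(s, rec$orig_start[j] + 1, rec$orig_end[j]),
                   substring(th$seq, rec$new_start[j] + 1, rec$new_end[j]))
    }
  }
})

test_that("a scaled-down derivative library has the configured structure and reproduces", {
  m <- toy_model()
  cres <- dplyr::bind_rows(lapply(1:2, function(i) {
    generate_cre(120, list(m), n_sites = 3, seed = i)$record
  }))
  asets <- lapply(seq_len(nrow(cres)), function(i) {
    build_anchors(cres[i, ], list(m), threshold = 0.05)
  })
  names(asets) <- cres$id
  bg <- make_backgrounds(n = 4, length = 120, seed = 2)
  cfg <- derivative_config(seed = 3, n_deposition_seeds = 3,
                           n_deposition_backgrounds = 2,
                           thripsis_breakpoints = c(2L, 4L),
                           n_thripsis_seeds = 3, n_negative = 10L)
  lib <- design_library(cres, asets, bg, cfg)
  counts <- dplyr::count(lib, class, cre_id)
  # reconstitution: (3 trims + 2 random sets) x 8 backgrounds
  expect_equal(counts$n[counts$class == "reconstitution"], c(40L, 40L))
  expect_equal(counts$n[counts$class == "deposition"], c(6L, 6L))
  expect_equal(counts$n[counts$class == "thripsis"], c(6L, 6L))
  expect_equal(sum(counts$n[counts$class == "negative_control"]), 10L)
  expect_equal(sum(counts$n[counts$class == "wt"]), 2L)

  # anchor integrity audit passes for all CRE-derived designs
  audited <- audit_anchor_integrity(lib, asets, cres)
  expect_true(all(audited$anchors_intact[!is.na(audited$anchors_intact)]))

  # byte-identical regeneration from the same configuration
  lib2 <- design_library(cres, asets, bg, cfg)
  expect_identical(lib$seq, lib2$seq)
  expect_equal(attr(lib, "manifest")$counts, attr(lib2, "manifest")$counts)
})

test_that("variance explained matches planted shares and degenerate rules", {
  df <- tibble::tibble(g = rep(c("a", "b"), each = 4),
                       y = rep(c(1, 3), each = 4))
  expect_equal(variance_explained(df, y, g), 1)

  set.seed(50)
  n <- 5000
  bgs <- sprintf("bg%02d", sample.int(20, n, replace = TRUE))
  pos <- sprintf("ps%02d", sample.int(20, n, replace = TRUE))
  bg_eff <- stats::setNames(rnorm(20, 0, sqrt(0.5)), sprintf("bg%02d", 1:20))
  ps_eff <- stats::setNames(rnorm(20, 0, sqrt(0.3)), sprintf("ps%02d", 1:20))
  y <- bg_eff[bgs] + ps_eff[pos] + rnorm(n, 0, sqrt(0.2))
  df2 <- tibble::tibble(bg = bgs, ps = pos, y = y)
  expect_lt(abs(variance_explained(df2, y, bg) - 0.5), 0.05)
  expect_lt(abs(variance_explained(df2, y, ps) - 0.3), 0.05)

  # factor independent of activity: expectation (k-1)/(n-1)
  yr <- rnorm(200)
  gr <- rep(sprintf("g%d", 1:10), each = 20)
  ve_null <- replicate(30, variance_explained(
    tibble::tibble(y = sample(yr), g = gr), y, g))
  expect_equal(mean(ve_null), (10 - 1) / (200 - 1), tolerance = 0.02)

  expect_error(variance_explained(tibble::tibble(y = 1:3, g = "a"), y, g),
               "two factor levels")
})

test_that("wild-type position rank uses mid-ranks for ties", {
  r <- runif(100)
  expect_equal(wt_position_rank(min(r) - 1, r), 0)
  expect_equal(wt_position_rank(max(r) + 1, r), 1)
  expect_equal(wt_position_rank(0.5, rep(0.5, 50)), 0.5)
  expect_error(wt_position_rank(1, runif(5)), "at least 10")
})
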