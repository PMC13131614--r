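# Shared small simulated mutagenesis dataset (kept small; deeper recovery
# checks live in the acceptance suite).
satmut_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(replicates = 2)
      cre <- generate_cre(80, list(toy_model()), n_sites = 3, seed = 5,
                          config = cfg)
      dict <- generate_satmut_dictionary(cre, cfg, n_barcodes = 15000, seed = 2)
      counts <- generate_counts(dict, cre$truth, cfg, seed = 3)
      cache <<- list(cfg = cfg, cre = cre, dict = dict, counts = counts,
                     effects = variant_effects(dict, counts))
    }
    cache
  }
})

test_that("variant effects recover the planted effect spectrum", {
  fx <- satmut_fixture()
  eff <- fx$effects
  sub <- eff[!eff$is_deletion & !is.na(eff$log2fc), ]
  truth <- fx$cre$truth$variant_lfc[sub$variant]
  expect_gte(cor(sub$log2fc, truth, method = "spearman"), 0.9)
  # planted-site substitutions are strongly LoF
  sites <- fx$cre$truth$sites
  in_site <- purrr::map_lgl(sub$position, function(p) {
    any(p >= sites$start & p < sites$end)
  })
  expect_lt(median(sub$log2fc[in_site]), -1)
})

test_that("effects of exchangeable barcodes are null and calls permutation-invariant", {
  # all-neutral generator: no planted sites, zero-effect mutations
  cfg <- generator_config(replicates = 2, nonsite_lfc_mean = 0,
                          nonsite_lfc_sd = 0)
  cre <- generate_cre(40, list(toy_model()), n_sites = 0, seed = 9,
                      config = cfg)
  dict <- generate_satmut_dictionary(cre, cfg, n_barcodes = 6000, seed = 10)
  counts <- generate_counts(dict, cre$truth, cfg, seed = 11)
  eff <- variant_effects(dict, counts)
  expect_lt(median(abs(eff$log2fc), na.rm = TRUE), 0.1)
  expect_equal(sum(eff$class %in% c("LoF", "GoF")), 0)

  # permuting dictionary rows changes nothing
  perm <- withr::with_seed(3, dict[sample.int(nrow(dict)), ])
  eff2 <- variant_effects(perm, counts)
  expect_equal(tidy(eff2), tidy(eff))

  # BH is rank-monotone in p
  ord <- order(eff$p_value)
  expect_true(all(diff(eff$fdr[ord]) >= -1e-12))
})

test_that("barcode support below the minimum yields missing effects", {
  fx <- satmut_fixture()
  eff <- variant_effects(fx$dict, fx$counts, min_barcodes = 1e6)
  expect_true(all(is.na(eff$log2fc)))
})

test_that("the self-consistent reference minimizes significant calls and is scale-equivariant", {
  set.seed(12)
  acts <- 2^rnorm(200, 0, 0.05) * 5  # all-null around a true value of 5
  chosen <- choose_wt_reference(acts, designed_wt = 5)
  grid_step <- 2 / 40  # log2 span 2 over 40 intervals
  expect_lt(abs(log2(chosen / 5)), grid_step + 1e-9)

  expect_equal(choose_wt_reference(acts, designed_wt = 5, grid_n = 1), 5)
  # doubling all activities doubles the chosen reference
  expect_equal(choose_wt_reference(acts * 2, designed_wt = 10), chosen * 2)
})

test_that("single- and multi-mutation strata give concordant effects with a downward offset", {
  fx <- satmut_fixture()
  conc <- single_vs_multi_concordance(fx$dict, fx$counts)
  expect_gte(conc$r_squared, 0.7)
  # extra mutation load is LoF-biased at generator defaults
  expect_lt(conc$median_offset_log2, 0.05)
  expect_gt(conc$n_variants, 50)
})

test_that("singleton-functional calls reproduce exact regressions", {
  # graded model: substitutions at different positions/bases lose different
  # amounts of affinity, so the affinity fold-change spans a range
  w <- withr::with_seed(44, matrix(runif(24, 0.02, 0.6), 6, 4))
  b <- match(strsplit("ACGTAC", "")[[1]], c("A", "C", "G", "T"))
  w[cbind(1:6, b)] <- 1
  m <- binding_model("tfA", w)
  s <- paste0(strrep("T", 10), model_consensus(m), strrep("T", 10))
  tfbs <- tibble::tibble(tfbs_id = "site1", start = 10L, end = 10L + m$k)
  se <- tfbs_substitution_effects(s, m, tfbs)
  expect_equal(nrow(se), 3 * m$k)

  # noiseless linear relation with slope 1 -> R^2 = 1, slope 1
  eff <- tibble::tibble(
    variant = se$variant, is_deletion = FALSE,
    log2fc = log2(se$mut_affinity / se$wt_affinity)
  )
  call <- call_singleton_functional(eff, se)
  expect_equal(call$r_squared, 1)
  expect_equal(call$slope, 1)
  expect_true(call$singleton_functional)

  # constant activity -> R^2 = 0, not functional
  eff0 <- dplyr::mutate(eff, log2fc = 0.7)
  call0 <- call_singleton_functional(eff0, se)
  expect_equal(call0$r_squared, 0)
  expect_false(call0$singleton_functional)

  # degenerate affinity fold-changes are skipped with a flag
  se_deg <- dplyr::mutate(se, mut_affinity = wt_affinity)
  cd <- call_singleton_functional(eff, se_deg)
  expect_true(cd$degenerate)
  expect_false(cd$singleton_functional)
})

test_that("necessity scores interpolate between baseline and wild type", {
  m <- toy_model()
  s <- paste0(strrep("T", 10), model_consensus(m), strrep("T", 10))
  se <- tfbs_substitution_effects(
    s, m, tibble::tibble(tfbs_id = "site1", start = 10L, end = 10L + m$k))
  strong <- (se$wt_affinity - se$mut_affinity) > 0.075
  expect_gt(sum(strong), 0)
  mkeff <- function(a) tibble::tibble(variant = se$variant,
                                      is_deletion = FALSE, activity = a)
  # disrupted activity equal to minP -> necessity 1
  n1 <- necessity_scores(mkeff(1), se, wt_activity = 9, minP = 1)
  expect_equal(n1$necessity, 1)
  expect_true(n1$high_lof)
  # disrupted activity equal to WT -> necessity 0
  n0 <- necessity_scores(mkeff(9), se, wt_activity = 9, minP = 1)
  expect_equal(n0$necessity, 0)
  # below-baseline disruption exceeds 1 and is flagged
  nx <- necessity_scores(mkeff(0.5), se, wt_activity = 9, minP = 1)
  expect_gt(nx$necessity, 1)
  expect_true(nx$above_one)
  expect_error(necessity_scores(mkeff(1), se, wt_activity = 0.5, minP = 1),
               "exceed")
})

test_that("GoF classification matches an independent rule-table oracle", {
  set.seed(20)
  n <- 60
  eff <- tibble::tibble(
    variant = paste0(1:n, ":A"), position = 1:n, alt = "A",
    is_deletion = FALSE,
    activity = 2^runif(n, 0.6, 2) * 5,
    log2fc = runif(n, 0.55, 2), p_value = 1e-5, fdr = 1e-4,
    n_barcodes = 50L, class = "GoF"
  )
  class(eff) <- c("variant_effects", class(eff))
  ae <- tibble::tibble(
    variant = rep(eff$variant, each = 2),
    position = rep(eff$position, each = 2),
    alt = "A",
    tf = rep(c("tfA", "tfB"), n),
    start_affinity = runif(2 * n, 0, 0.4),
    mut_affinity = NA_real_,
    affinity_delta = runif(2 * n, -0.1, 0.4) *
      sample(c(0, 1), 2 * n, replace = TRUE, prob = c(0.3, 0.7))
  )
  sc <- tibble::tibble(tfbs_id = "s1", tf = "tfA", start = 1L, end = 30L,
                       singleton_functional = TRUE)
  got <- classify_gof(eff, ae, sc)
  oracle <- vapply(eff$variant, function(v) {
    rows <- ae[ae$variant == v, ]
    if (max(abs(rows$affinity_delta)) < 0.02) return("unrelated")
    best <- rows[which.max(rows$affinity_delta), ]
    if (best$start_affinity < 0.05) return("create_new_site")
    pos <- eff$position[eff$variant == v]
    if (best$tf == "tfA" && pos >= 1 && pos < 30) "strengthen_functional"
    else "strengthen_subfunctional"
  }, character(1))
  expect_equal(got$category, unname(oracle[got$variant]))
})

test_that("strong affinity-disrupting variants are enriched among LoF calls", {
  fx <- satmut_fixture()
  eff <- fx$effects
  # affinity drops predicted from the planted model over every planted site
  sites <- fx$cre$truth$sites
  se <- dplyr::bind_rows(lapply(seq_len(nrow(sites)), function(i) {
    tfbs_substitution_effects(
      fx$cre$record$seq[[1]], toy_model(),
      tibble::tibble(tfbs_id = paste0("s", i),
                     start = sites$start[i], end = sites$end[i]))
  }))
  drop_big <- se$variant[(se$wt_affinity - se$mut_affinity) > 0.075]
  sub <- eff[!eff$is_deletion & !is.na(eff$log2fc), ]
  grp <- sub$variant %in% drop_big
  expect_gt(sum(grp), 10)
  wt <- stats::wilcox.test(sub$log2fc[grp], sub$log2fc[!grp],
                           alternative = "less")
  expect_lt(wt$p.value, 0.01)
})
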