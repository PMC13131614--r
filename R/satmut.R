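# Variant tokens are "pos:alt" with 0-based position and alt in
# {A, C, G, T, del}. A barcode's `variants` field joins its tokens with ";".

# Long (barcode, variant) map from a dictionary; empty variant sets drop out.
variant_map <- function(dict) {
  has <- !is.na(dict$variants) & dict$variants != ""
  d <- dict[has, c("barcode", "variants")]
  tidyr::separate_rows(d, "variants", sep = ";") %>%
    rename(variant = "variants")
}

variant_position <- function(v) as.integer(sub(":.*$", "", v))
variant_alt <- function(v) sub("^.*:", "", v)

#' Barcodes of the unmutagenized (wild-type) element
#'
#' @param dict Barcode dictionary.
#' @return Character vector of barcodes with an empty variant set.
#' @export
wt_barcodes <- function(dict) {
  dict$barcode[is.na(dict$variants) | dict$variants == ""]
}

#' Estimate single-variant effects from multi-hit barcode ensembles
#'
#' Each variant's activity is computed over *all* barcodes carrying that
#' variant — possibly alongside other mutations, whose effects average out
#' across the ensemble (and at worst shift all estimates by a common
#' factor, which the self-consistent wild-type reference absorbs). The
#' p-value comes from a two-sided rank-sum (Mann-Whitney) test of
#' per-barcode normalized RNA/DNA ratios against wild-type barcodes, pooled
#' across replicates; Benjamini-Hochberg correction is applied across the
#' full variant set.
#'
#' @param dict Filtered barcode dictionary (variant rows plus, ideally,
#'   wild-type rows with empty variant sets).
#' @param counts Count tibble.
#' @param wt_activity Wild-type reference activity. `NULL` (default) uses
#'   the activity of the wild-type barcodes if present, refined
#'   self-consistently via [choose_wt_reference()].
#' @param min_barcodes Minimum barcodes per variant (default 5); variants
#'   below it are reported with missing effect estimates.
#' @param winsor_frac Winsorization fraction passed to the activity
#'   computation.
#' @param lfc_threshold,fdr_threshold Significance thresholds used for the
#'   LoF/GoF/neutral classification (defaults `|log2FC| > 0.32`,
#'   `FDR < 0.006`).
#' @param self_consistent_wt Refine the reference on a grid to minimize the
#'   number of significant calls (default TRUE when `wt_activity` is NULL).
#' @return A `variant_effects` tibble: `variant`, `position`, `alt`,
#'   `is_deletion`, `activity`, `log2fc`, `p_value`, `fdr`, `n_barcodes`,
#'   `class`; the reference activity is attached as attribute
#'   `wt_activity`.
#' @export
variant_effects <- function(dict, counts, wt_activity = NULL,
                            min_barcodes = 5, winsor_frac = 0.01,
                            lfc_threshold = 0.32, fdr_threshold = 0.006,
                            self_consistent_wt = is.null(wt_activity)) {
  vm <- variant_map(dict)
  counts_full <- complete_counts(dict, counts)
  act <- activity_core(
    tibble(group_id = vm$variant, barcode = vm$barcode),
    counts_full, winsor_frac
  ) %>%
    group_by(.data$group_id) %>%
    summarise(activity = geometric_mean(.data$activity[!is.na(.data$activity)]),
              .groups = "drop") %>%
    rename(variant = "group_id")
  nbc <- vm %>% group_by(.data$variant) %>%
    summarise(n_barcodes = dplyr::n_distinct(.data$barcode), .groups = "drop")

  ratios <- barcode_ratios(dict, counts)
  wtb <- wt_barcodes(dict)
  wt_ratios <- ratios$ratio[ratios$barcode %in% wtb]
  ratio_by_bc <- split(ratios$ratio, ratios$barcode)
  pvals <- vapply(split(vm$barcode, vm$variant), function(bcs) {
    v <- unlist(ratio_by_bc[bcs], use.names = FALSE)
    if (length(v) < 2 || length(wt_ratios) < 2) return(NA_real_)
    suppressWarnings(wilcox.test(v, wt_ratios, exact = FALSE)$p.value)
  }, numeric(1))

  out <- act %>%
    left_join(nbc, by = "variant") %>%
    mutate(p_value = unname(pvals[.data$variant]))
  low <- out$n_barcodes < min_barcodes
  out$activity[low] <- NA_real_
  out$p_value[low] <- NA_real_
  out$fdr <- p.adjust(out$p_value, method = "BH")

  wt_est <- wt_activity
  if (is.null(wt_est)) {
    if (length(wt_ratios) >= 2) {
      wt_est <- element_activity(
        dict[dict$barcode %in% wtb, ], counts, winsor_frac = winsor_frac
      )$activity[1]
    } else {
      wt_est <- median(out$activity, na.rm = TRUE)
    }
  }
  if (self_consistent_wt) {
    wt_est <- choose_wt_reference(
      out$activity, designed_wt = wt_est, fdr = out$fdr,
      lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold
    )
  }

  out <- out %>%
    mutate(
      position = variant_position(.data$variant),
      alt = variant_alt(.data$variant),
      is_deletion = .data$alt == "del",
      log2fc = log2(.data$activity / wt_est),
      class = case_when(
        is.na(.data$log2fc) | is.na(.data$fdr) ~ NA_character_,
        .data$log2fc < -lfc_threshold & .data$fdr < fdr_threshold ~ "LoF",
        .data$log2fc > lfc_threshold & .data$fdr < fdr_threshold ~ "GoF",
        TRUE ~ "neutral"
      )
    ) %>%
    select("variant", "position", "alt", "is_deletion", "activity", "log2fc",
           "p_value", "fdr", "n_barcodes", "class") %>%
    arrange(.data$position, .data$alt)
  attr(out, "wt_activity") <- wt_est
  class(out) <- c("variant_effects", class(out))
  out
}

#' Choose the wild-type reference activity self-consistently
#'
#' Evaluates candidate reference activities on a log-spaced grid spanning
#' `[0.5, 2] x designed_wt` and returns the candidate minimizing the number
#' of variants called significantly non-zero (`|log2FC| > lfc_threshold`
#' and, when FDRs are supplied, `FDR < fdr_threshold`). Ties break toward
#' the designed wild-type value. This is the most conservative fold-change
#' baseline: it absorbs any global shift induced by the background mutation
#' load of multi-hit barcodes.
#'
#' @param activities Numeric vector of per-variant activities.
#' @param designed_wt Activity of the designed wild-type sequence (grid
#'   center).
#' @param fdr Optional vector of per-variant FDRs aligned with
#'   `activities`.
#' @param grid_n Number of candidates (default 41).
#' @param grid_span Multiplicative span of the grid (default `c(0.5, 2)`).
#' @param lfc_threshold,fdr_threshold Significance thresholds.
#' @return The chosen reference activity (scalar).
#' @export
choose_wt_reference <- function(activities, designed_wt, fdr = NULL,
                                grid_n = 41, grid_span = c(0.5, 2),
                                lfc_threshold = 0.32, fdr_threshold = 0.006) {
  stopifnot(grid_n >= 1, designed_wt > 0)
  grid <- if (grid_n == 1) designed_wt else
    designed_wt * 2^seq(log2(grid_span[1]), log2(grid_span[2]),
                        length.out = grid_n)
  ok <- !is.na(activities) & activities > 0
  sig_fdr <- if (is.null(fdr)) rep(TRUE, length(activities)) else
    !is.na(fdr) & fdr < fdr_threshold
  n_sig <- vapply(grid, function(cand) {
    sum(abs(log2(activities[ok] / cand)) > lfc_threshold & sig_fdr[ok])
  }, numeric(1))
  best <- which(n_sig == min(n_sig))
  grid[best[which.min(abs(log2(grid[best] / designed_wt)))]]
}

#' Concordance of effects from single- vs multi-mutation barcodes
#'
#' Splits each variant's barcodes into those carrying only the programmed
#' mutation and those carrying two or more mutations, estimates the variant
#' activity separately in each stratum, and reports the log-scale R-squared
#' and the systematic offset (median log2 difference, multi minus single) —
#' expected to be slightly negative when the extra mutation load is
#' LoF-biased.
#'
#' @inheritParams variant_effects
#' @return One-row tibble: `r_squared`, `median_offset_log2`, `n_variants`.
#' @export
single_vs_multi_concordance <- function(dict, counts, min_barcodes = 5,
                                        winsor_frac = 0.01) {
  vm <- variant_map(dict)
  nmut <- vm %>% group_by(.data$barcode) %>%
    summarise(n_mut = dplyr::n(), .groups = "drop")
  vm <- left_join(vm, nmut, by = "barcode")
  counts_full <- complete_counts(dict, counts)
  est <- function(sub) {
    activity_core(tibble(group_id = sub$variant, barcode = sub$barcode),
                  counts_full, winsor_frac) %>%
      group_by(.data$group_id) %>%
      summarise(activity = geometric_mean(.data$activity[!is.na(.data$activity)]),
                n_bc = max(.data$n_barcodes), .groups = "drop")
  }
  single <- est(vm[vm$n_mut == 1, ])
  multi <- est(vm[vm$n_mut >= 2, ])
  both <- inner_join(single, multi, by = "group_id", suffix = c("_s", "_m")) %>%
    filter(.data$n_bc_s >= min_barcodes, .data$n_bc_m >= min_barcodes,
           .data$activity_s > 0, .data$activity_m > 0)
  if (nrow(both) < 3) abort("too few variants with both barcode strata")
  tibble(
    r_squared = cor(log2(both$activity_s), log2(both$activity_m))^2,
    median_offset_log2 = median(log2(both$activity_m) - log2(both$activity_s)),
    n_variants = nrow(both)
  )
}

#' Predicted affinity effects of substitutions within a TFBS
#'
#' For every substitution inside a called site, recomputes the site's
#' affinity (the maximum normalized affinity over k-mer windows overlapping
#' the site interval) on the mutated sequence.
#'
#' @param seq Parent CRE sequence string.
#' @param model [binding_model()] for the site's factor.
#' @param tfbs One-row tibble or list with `start`, `end` (0-based
#'   half-open) and optionally `tfbs_id`.
#' @return Tibble per substitution: `tfbs_id`, `tf`, `position`, `alt`,
#'   `variant`, `wt_affinity`, `mut_affinity`, `affinity_delta`.
#' @export
tfbs_substitution_effects <- function(seq, model, tfbs) {
  x <- seq_to_int(seq)
  k <- model$k
  L <- length(x)
  site_affinity <- function(xv, s, e) {
    lo <- max(0L, s - k + 1L)
    hi <- min(L - k, e - 1L)
    if (hi < lo) return(NA_real_)
    sc <- scan_core(xv[(lo + 1L):(hi + k)], model$weights)
    max(pmax(sc$fwd, sc$rev)) / model$norm_constant
  }
  s <- tfbs$start[[1]]; e <- tfbs$end[[1]]
  id <- tfbs$tfbs_id[[1]] %||% paste0(model$tf_name, "_", s)
  wt_aff <- site_affinity(x, s, e)
  rows <- list()
  for (p in s:(e - 1L)) {
    ref <- x[p + 1L]
    for (alt_i in setdiff(1:4, ref)) {
      xm <- x
      xm[p + 1L] <- alt_i
      ma <- site_affinity(xm, s, e)
      alt_chr <- DNA_BASES[alt_i]
      rows[[length(rows) + 1]] <- tibble(
        tfbs_id = id, tf = model$tf_name,
        position = p, alt = alt_chr,
        variant = paste0(p, ":", alt_chr),
        wt_affinity = wt_aff, mut_affinity = ma,
        affinity_delta = ma - wt_aff
      )
    }
  }
  bind_rows(rows)
}

#' Local affinity change of arbitrary substitutions, per model
#'
#' For each variant and model, computes the maximum normalized affinity over
#' the k-mer windows covering the mutated base, before and after the
#' substitution. Used for gain-of-function classification, where a variant
#' may strengthen an existing site or create a site where none was called.
#'
#' @param seq Parent CRE sequence string.
#' @param models List of [binding_model()]s.
#' @param variants Character vector of `pos:alt` substitution tokens
#'   (deletions are skipped).
#' @return Tibble: `variant`, `position`, `alt`, `tf`, `start_affinity`,
#'   `mut_affinity`, `affinity_delta`.
#' @export
variant_affinity_effects <- function(seq, models, variants) {
  x <- seq_to_int(seq)
  L <- length(x)
  variants <- unique(variants[variant_alt(variants) != "del"])
  rows <- list()
  for (m in models) {
    k <- m$k
    local_max <- function(xv, p) {
      lo <- max(0L, p - k + 1L)
      hi <- min(L - k, p)
      sc <- scan_core(xv[(lo + 1L):(hi + k)], m$weights)
      max(pmax(sc$fwd, sc$rev)) / m$norm_constant
    }
    for (v in variants) {
      p <- variant_position(v)
      alt <- match(variant_alt(v), DNA_BASES)
      before <- local_max(x, p)
      xm <- x
      xm[p + 1L] <- alt
      after <- local_max(xm, p)
      rows[[length(rows) + 1]] <- tibble(
        variant = v, position = p, alt = DNA_BASES[alt], tf = m$tf_name,
        start_affinity = before, mut_affinity = after,
        affinity_delta = after - before
      )
    }
  }
  bind_rows(rows)
}

#' Call singleton-functional TFBSs
#'
#' A site is singleton-functional when the activity changes of its
#' substitutions track their predicted affinity changes: per TFBS, log2
#' activity fold-change is regressed on log2 predicted-affinity fold-change
#' across substitutions, and sites with R-squared above the threshold are
#' flagged. Deletions are excluded from the regression.
#'
#' @param effects [variant_effects()] tibble.
#' @param site_effects Row-bound [tfbs_substitution_effects()] tables for
#'   the sites to test.
#' @param r2_threshold R-squared threshold (default 0.195).
#' @return Tibble per site: `tfbs_id`, `tf`, `n`, `r_squared`, `slope`,
#'   `singleton_functional`, `degenerate`.
#' @export
call_singleton_functional <- function(effects, site_effects,
                                      r2_threshold = 0.195) {
  df <- inner_join(
    site_effects,
    effects[!effects$is_deletion, c("variant", "log2fc")],
    by = "variant"
  ) %>% filter(!is.na(.data$log2fc), .data$wt_affinity > 0, .data$mut_affinity > 0)
  df %>%
    group_by(.data$tfbs_id, .data$tf) %>%
    dplyr::group_modify(function(g, key) {
      x <- log2(g$mut_affinity / g$wt_affinity)
      y <- g$log2fc
      degen <- var(x) == 0
      if (degen || nrow(g) < 3) {
        tibble(n = nrow(g), degenerate = degen,
               r_squared = NA_real_, slope = NA_real_)
      } else {
        tibble(
          n = nrow(g), degenerate = FALSE,
          r_squared = if (var(y) == 0) 0 else cor(x, y)^2,
          slope = unname(coef(lm(y ~ x))[2])
        )
      }
    }) %>%
    ungroup() %>%
    mutate(singleton_functional = !is.na(.data$r_squared) &
             .data$r_squared > r2_threshold)
}

#' Necessity score of TFBSs
#'
#' The fraction of baseline-subtracted wild-type activity lost when a site
#' is disrupted: `1 - (A_disrupted - minP) / (A_WT - minP)`, where
#' `A_disrupted` is the median activity over the site's strong
#' affinity-disrupting substitutions (predicted affinity drop greater than
#' `min_affinity_drop`). Values above 1 (activity pushed below baseline)
#' are allowed and flagged.
#'
#' @param effects [variant_effects()] tibble.
#' @param site_effects Row-bound [tfbs_substitution_effects()] tables.
#' @param wt_activity Wild-type activity.
#' @param minP Basal minimal-promoter-only activity.
#' @param min_affinity_drop Normalized-affinity drop defining a strong
#'   disruption (default 0.075).
#' @param summary Aggregator over disrupting substitutions: `"median"`
#'   (default), `"mean"`, or `"min"`.
#' @param lof_flag_threshold Necessity above which a site is flagged as
#'   high-LoF (default 0.75).
#' @return Tibble per site: `tfbs_id`, `tf`, `n_disrupting`,
#'   `a_disrupted`, `necessity`, `above_one`, `high_lof`.
#' @export
necessity_scores <- function(effects, site_effects, wt_activity, minP,
                             min_affinity_drop = 0.075, summary = "median",
                             lof_flag_threshold = 0.75) {
  if (wt_activity <= minP) abort("wild-type activity must exceed minP baseline")
  agg <- switch(summary, median = median, mean = mean, min = min,
                abort("summary must be median, mean or min"))
  df <- inner_join(
    site_effects,
    effects[!effects$is_deletion, c("variant", "activity")],
    by = "variant"
  ) %>%
    filter((.data$wt_affinity - .data$mut_affinity) > min_affinity_drop,
           !is.na(.data$activity))
  df %>%
    group_by(.data$tfbs_id, .data$tf) %>%
    summarise(
      n_disrupting = dplyr::n(),
      a_disrupted = agg(.data$activity),
      .groups = "drop"
    ) %>%
    mutate(
      necessity = 1 - (.data$a_disrupted - minP) / (wt_activity - minP),
      above_one = .data$necessity > 1,
      high_lof = .data$necessity > lof_flag_threshold
    )
}

#' Classify gain-of-function substitutions by mechanism
#'
#' Large-effect GoF variants (`log2fc > lfc_gof`) are assigned to one of
#' four mechanistic categories from their predicted local affinity changes
#' across the module's TFs: `unrelated` (no TF's local affinity changes by
#' more than `unrelated_delta`), `create_new_site` (the most-strengthened
#' site starts below `new_site_affinity`), `strengthen_functional` /
#' `strengthen_subfunctional` (starting affinity at or above
#' `new_site_affinity`, split by whether the variant falls in a
#' singleton-functional site for that TF).
#'
#' @param effects [variant_effects()] tibble.
#' @param affinity_effects Output of [variant_affinity_effects()] covering
#'   the GoF variants.
#' @param singleton_calls Output of [call_singleton_functional()], joined
#'   with site coordinates (`tfbs_id`, `tf`, `start`, `end`,
#'   `singleton_functional`). May be NULL, in which case no site is treated
#'   as singleton-functional.
#' @param lfc_gof GoF effect threshold (default 0.5).
#' @param unrelated_delta Maximum absolute affinity change for the
#'   `unrelated` class (default 0.02).
#' @param new_site_affinity Starting-affinity boundary between
#'   strengthening and site creation (default 0.05).
#' @return Tibble per GoF variant: `variant`, `position`, `alt`, `log2fc`,
#'   `tf`, `start_affinity`, `affinity_delta`, `category`.
#' @export
classify_gof <- function(effects, affinity_effects, singleton_calls = NULL,
                         lfc_gof = 0.5, unrelated_delta = 0.02,
                         new_site_affinity = 0.05) {
  gof <- effects %>%
    filter(!is.na(.data$log2fc), .data$log2fc > lfc_gof, !.data$is_deletion)
  if (nrow(gof) == 0) {
    return(tibble(variant = character(0), position = integer(0),
                  alt = character(0), log2fc = numeric(0), tf = character(0),
                  start_affinity = numeric(0), affinity_delta = numeric(0),
                  category = character(0)))
  }
  ae <- affinity_effects[affinity_effects$variant %in% gof$variant, ]
  best <- ae %>%
    group_by(.data$variant) %>%
    summarise(
      max_abs_delta = max(abs(.data$affinity_delta)),
      tf = .data$tf[which.max(.data$affinity_delta)],
      start_affinity = .data$start_affinity[which.max(.data$affinity_delta)],
      affinity_delta = max(.data$affinity_delta),
      .groups = "drop"
    )
  in_singleton <- function(pos, tf) {
    if (is.null(singleton_calls) || nrow(singleton_calls) == 0) return(FALSE)
    sc <- singleton_calls[singleton_calls$singleton_functional &
                            singleton_calls$tf == tf, , drop = FALSE]
    any(pos >= sc$start & pos < sc$end)
  }
  out <- inner_join(gof[, c("variant", "position", "alt", "log2fc")],
                    best, by = "variant")
  out$category <- purrr::pmap_chr(
    list(out$max_abs_delta, out$start_affinity, out$position, out$tf),
    function(mad, sa, pos, tf) {
      if (mad < unrelated_delta) return("unrelated")
      if (sa < new_site_affinity) return("create_new_site")
      if (in_singleton(pos, tf)) "strengthen_functional" else "strengthen_subfunctional"
    }
  )
  select(out, "variant", "position", "alt", "log2fc", "tf",
         "start_affinity", "affinity_delta", "category")
}
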