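#' Select the disrupting mutation set for a TFBS
#'
#' Two-stage selection giving confidence in both binding disruption and
#' functional impact: rank the site's substitutions by predicted affinity
#' loss and keep the top `n_affinity`; among those, keep the `n_activity`
#' with the lowest measured activity.
#'
#' @param effects [variant_effects()] tibble.
#' @param site_effects [tfbs_substitution_effects()] table for one site.
#' @param n_affinity Size of the affinity-loss shortlist (default 15).
#' @param n_activity Final number of activity-disrupting mutations
#'   (default 10).
#' @return Tibble of selected variants with `variant`, `affinity_delta`,
#'   `activity`; fewer than `n_activity` rows (flagged via attribute
#'   `short_set`) when candidates run out.
#' @export
select_disrupting_mutations <- function(effects, site_effects,
                                        n_affinity = 15, n_activity = 10) {
  df <- inner_join(site_effects,
                   effects[, c("variant", "activity")], by = "variant") %>%
    filter(!is.na(.data$activity))
  shortlist <- df %>%
    arrange(.data$affinity_delta) %>%   # most negative = largest affinity loss
    head(n_affinity)
  out <- shortlist %>%
    arrange(.data$activity) %>%
    head(n_activity) %>%
    select("variant", "affinity_delta", "activity")
  attr(out, "short_set") <- nrow(out) < n_activity
  out
}

#' Pairwise TFBS epistasis against a multiplicative null
#'
#' For each pair of sites, barcodes carrying at least one selected
#' disrupting mutation from *both* constituents estimate the observed
#' double-disruption activity; single-constituent barcode sets estimate the
#' marginals. The score is `log2(observed_fc / (fc_i * fc_j))`: zero under
#' multiplicative (independent) action, positive for buffering, negative
#' for synergy. A nominal p-value comes from a rank-sum test of the
#' double-hit barcodes' per-barcode normalized ratios against a composite
#' null set resampled under multiplicativity
#' (`r_i + r_j - r_wt` on the log scale). Barcodes hitting three or more
#' selected sites are excluded to isolate second-order effects; pairs where
#' the multiplicative expectation falls below the minP baseline are
#' flagged, since observed activity cannot fall below basal.
#'
#' @param dict Filtered barcode dictionary.
#' @param counts Count tibble.
#' @param disrupting_sets Named list (one element per TFBS) of variant
#'   character vectors, e.g. from [select_disrupting_mutations()].
#' @param wt_activity Wild-type reference activity.
#' @param minP Basal minP-only activity.
#' @param min_barcodes Minimum double-hit barcodes per pair (default 10);
#'   pairs below it are reported with missing estimates.
#' @param n_null Size of the resampled multiplicative composite (default
#'   200).
#' @param winsor_frac Winsorization fraction for activity estimates.
#' @param seed Seed for the composite resampling.
#' @return An `epistasis_result` tibble: one row per unordered pair with
#'   `tfbs_i`, `tfbs_j`, `n_double`, `fc_i`, `fc_j`, `observed_fc`,
#'   `expected_fc`, `score`, `p_value`, `below_minP`.
#' @export
pairwise_epistasis <- function(dict, counts, disrupting_sets, wt_activity,
                               minP, min_barcodes = 10, n_null = 200,
                               winsor_frac = 0.01, seed = 1) {
  stopifnot(length(disrupting_sets) >= 2, !is.null(names(disrupting_sets)))
  sites <- names(disrupting_sets)
  vm <- variant_map(dict)
  # barcode -> which selected sites it hits
  hit <- lapply(disrupting_sets, function(vs) unique(vm$barcode[vm$variant %in% vs]))
  n_hits <- table(unlist(hit))
  excluded <- names(n_hits)[n_hits >= 3]

  counts_full <- complete_counts(dict, counts)
  ratios <- barcode_ratios(dict, counts)
  ratio_by_bc <- split(ratios$ratio, ratios$barcode)
  wtb <- wt_barcodes(dict)
  wt_log <- log(unlist(ratio_by_bc[wtb], use.names = FALSE))

  act_of <- function(bcs) {
    if (length(bcs) == 0) return(NA_real_)
    a <- activity_core(tibble(group_id = "g", barcode = bcs),
                       counts_full, winsor_frac)
    geometric_mean(a$activity[!is.na(a$activity)])
  }
  logr_of <- function(bcs) log(unlist(ratio_by_bc[bcs], use.names = FALSE))

  single_bc <- lapply(sites, function(s) {
    others <- unique(unlist(hit[setdiff(sites, s)]))
    setdiff(setdiff(hit[[s]], others), excluded)
  })
  names(single_bc) <- sites
  fc_single <- vapply(single_bc, function(b) act_of(b) / wt_activity, numeric(1))

  pairs <- utils::combn(sites, 2, simplify = FALSE)
  rows <- with_seed(seed, lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    dbl <- setdiff(intersect(hit[[i]], hit[[j]]), excluded)
    base <- tibble(tfbs_i = i, tfbs_j = j, n_double = length(dbl),
                   fc_i = fc_single[[i]], fc_j = fc_single[[j]])
    if (length(dbl) < min_barcodes || is.na(base$fc_i) || is.na(base$fc_j)) {
      return(mutate(base, observed_fc = NA_real_, expected_fc = NA_real_,
                    score = NA_real_, p_value = NA_real_, below_minP = NA))
    }
    obs_fc <- act_of(dbl) / wt_activity
    exp_fc <- base$fc_i * base$fc_j
    ri <- logr_of(single_bc[[i]]); rj <- logr_of(single_bc[[j]])
    rd <- logr_of(dbl)
    p <- NA_real_
    if (length(rd) >= 2 && length(ri) >= 2 && length(rj) >= 2 &&
        length(wt_log) >= 2) {
      comp <- sample(ri, n_null, replace = TRUE) +
        sample(rj, n_null, replace = TRUE) -
        sample(wt_log, n_null, replace = TRUE)
      p <- suppressWarnings(wilcox.test(rd, comp, exact = FALSE)$p.value)
    }
    mutate(base, observed_fc = obs_fc, expected_fc = exp_fc,
           score = log2(obs_fc / exp_fc), p_value = p,
           below_minP = exp_fc * wt_activity < minP)
  }))
  out <- bind_rows(rows)
  attr(out, "wt_activity") <- wt_activity
  attr(out, "minP") <- minP
  class(out) <- c("epistasis_result", class(out))
  out
}
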