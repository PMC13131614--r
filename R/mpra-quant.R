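#' Filter a barcode dictionary
#'
#' Keeps barcodes with enough read support, a large-enough fraction of their
#' reads attributable to a single element (barcodes split across elements
#' are likely chimeric or non-uniquely paired), and — for variant
#' dictionaries — sufficient read support for the called variant set.
#'
#' @param dict Barcode dictionary tibble (see [read_barcode_dict()]).
#' @param min_reads Minimum reads per barcode (library-specific; see
#'   [suggest_min_reads()]).
#' @param min_fraction Minimum fraction of a barcode's reads mapping to its
#'   element (default 0.95).
#' @param min_variant_support Variant rows must have
#'   `frac_variant > min_variant_support` (default 0.90); ignored for rows
#'   with an empty variant set.
#' @return The filtered dictionary.
#' @export
filter_dictionary <- function(dict, min_reads = 10, min_fraction = 0.95,
                              min_variant_support = 0.90) {
  if (min_fraction <= 0.5 || min_fraction > 1) {
    abort("min_fraction must be in (0.5, 1]")
  }
  has_variants <- !is.na(dict$variants) & dict$variants != ""
  keep <- dict$reads >= min_reads &
    dict$frac_element >= min_fraction &
    (!has_variants | dict$frac_variant > min_variant_support)
  out <- dict[keep, ]
  if (nrow(out) == 0) warn("no barcodes survive dictionary filtering")
  if (anyDuplicated(out$barcode)) abort("barcodes must be unique after filtering")
  out
}

#' Suggest a read-count threshold from coverage bimodality
#'
#' Real barcode-coverage distributions are bimodal: a low mode of sequencing
#' errors / PCR chimeras and a high mode of genuine barcodes. This fits a
#' kernel-smoothed density to log10 read counts, locates the two largest
#' modes, and returns the count at the density minimum between them. If the
#' distribution is unimodal the configured fallback is returned and flagged.
#'
#' @param read_counts Positive numeric vector of per-barcode read counts
#'   (at least 100 barcodes).
#' @param fallback Threshold returned when no clear second mode exists.
#' @param bw Density bandwidth on the log10 scale.
#' @return One-row tibble: `threshold`, `bimodal` (logical), `mode_low`,
#'   `mode_high` (NA when unimodal).
#' @export
suggest_min_reads <- function(read_counts, fallback = 10, bw = 0.15) {
  stopifnot(length(read_counts) >= 100, all(read_counts > 0))
  lx <- log10(read_counts)
  d <- stats::density(lx, bw = bw, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2) {
    return(tibble(threshold = fallback, bimodal = FALSE,
                  mode_low = NA_real_, mode_high = NA_real_))
  }
  top2 <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  tibble(
    threshold = 10^d$x[valley],
    bimodal = TRUE,
    mode_low = 10^d$x[lo],
    mode_high = 10^d$x[hi]
  )
}

# Per-(element, replicate) activity from normalized, winsorized UMI sums.
# `groups` maps barcode -> group id (element or variant); barcodes may appear
# in several groups (multi-hit variant estimation), so the join is many-to-many.
activity_core <- function(group_map, counts, winsor_frac = 0.01) {
  totals <- counts %>%
    group_by(.data$replicate) %>%
    summarise(tot_rna = sum(.data$rna_umi), tot_dna = sum(.data$dna_umi),
              .groups = "drop")
  df <- inner_join(group_map, counts, by = "barcode",
                   relationship = "many-to-many") %>%
    inner_join(totals, by = "replicate") %>%
    mutate(
      # a replicate whose library total is zero has all-zero counts; its
      # normalized values are zero rather than 0/0
      rna_norm = ifelse(.data$tot_rna > 0, .data$rna_umi / .data$tot_rna, 0),
      dna_norm = ifelse(.data$tot_dna > 0, .data$dna_umi / .data$tot_dna, 0)
    )
  df %>%
    group_by(.data$group_id, .data$replicate) %>%
    summarise(
      activity = {
        r <- winsorize(.data$rna_norm, winsor_frac)
        d <- winsorize(.data$dna_norm, winsor_frac)
        if (sum(d) == 0) NA_real_ else sum(r) / sum(d)
      },
      n_barcodes = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-replicate element activities
#'
#' For each replicate, each barcode's RNA and DNA UMI counts are normalized
#' by the replicate's library totals (over all dictionary barcodes), the
#' element's per-barcode normalized values are winsorized two-sided at
#' `winsor_frac`, and activity is the ratio of the winsorized-normalized RNA
#' sum to the winsorized-normalized DNA sum.
#'
#' @param dict Filtered barcode dictionary.
#' @param counts Count tibble (`barcode`, `replicate`, `rna_umi`, `dna_umi`).
#'   Barcodes absent from a replicate contribute zero counts.
#' @param winsor_frac Two-sided winsorization fraction (default 0.01; 0
#'   reproduces the plain ratio exactly).
#' @return Tibble: `element_id`, `replicate`, `activity`, `n_barcodes`.
#' @export
activity_by_replicate <- function(dict, counts, winsor_frac = 0.01) {
  counts <- complete_counts(dict, counts)
  group_map <- tibble(group_id = dict$element_id, barcode = dict$barcode)
  activity_core(group_map, counts, winsor_frac) %>%
    rename(element_id = "group_id")
}

# Ensure every (dictionary barcode, replicate) pair exists, with zeros for
# missing pairs: missingness is informative for DNA representation.
complete_counts <- function(dict, counts) {
  reps <- unique(counts$replicate)
  full <- tidyr::expand_grid(barcode = unique(dict$barcode), replicate = reps)
  out <- left_join(full, counts, by = c("barcode", "replicate"))
  out$rna_umi[is.na(out$rna_umi)] <- 0L
  out$dna_umi[is.na(out$dna_umi)] <- 0L
  out
}

#' Cross-replicate element activities
#'
#' Summarises [activity_by_replicate()] with a geometric mean across
#' replicates (log-scale averaging, matching the log-scale statistics used
#' throughout the analyses).
#'
#' @inheritParams activity_by_replicate
#' @param element_id Optional single element to compute; default all.
#' @return Tibble: `element_id`, `activity`, `n_barcodes`, `n_replicates`.
#' @export
element_activity <- function(dict, counts, element_id = NULL, winsor_frac = 0.01) {
  # Library totals are always taken over the full dictionary, so subsetting
  # to an element happens after the per-replicate computation.
  per_rep <- activity_by_replicate(dict, counts, winsor_frac)
  if (!is.null(element_id)) {
    per_rep <- per_rep[per_rep$element_id %in% element_id, ]
    if (nrow(per_rep) == 0) abort("element_id not found in dictionary")
  }
  bad <- per_rep %>% group_by(.data$element_id) %>%
    summarise(all_na = all(is.na(.data$activity)), .groups = "drop")
  if (any(bad$all_na)) {
    abort(paste0("element(s) with zero DNA in all replicates: ",
                 paste(head(bad$element_id[bad$all_na], 3), collapse = ", ")))
  }
  per_rep %>%
    group_by(.data$element_id) %>%
    summarise(
      n_replicates = sum(!is.na(.data$activity)),
      activity = geometric_mean(.data$activity),
      n_barcodes = max(.data$n_barcodes),
      .groups = "drop"
    ) %>%
    select("element_id", "activity", "n_barcodes", "n_replicates")
}

#' Replicate concordance of log activities
#'
#' Squared Pearson correlation of log-transformed activities for every
#' replicate pair, over elements with positive activity in both members of
#' the pair.
#'
#' @param per_rep Output of [activity_by_replicate()].
#' @return Tibble: `rep_a`, `rep_b`, `r_squared`, `n_elements`.
#' @export
replicate_concordance <- function(per_rep) {
  reps <- sort(unique(per_rep$replicate))
  if (length(reps) < 2) abort("need at least two replicates")
  wide <- tidyr::pivot_wider(per_rep[, c("element_id", "replicate", "activity")],
                             names_from = "replicate", values_from = "activity")
  pairs <- utils::combn(reps, 2, simplify = FALSE)
  bind_rows(lapply(pairs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
    if (sum(ok) < 3) abort("fewer than 3 shared positive elements for a replicate pair")
    tibble(rep_a = pr[1], rep_b = pr[2],
           r_squared = cor(log(a[ok]), log(b[ok]))^2,
           n_elements = sum(ok))
  }))
}

# Per-barcode, per-replicate normalized RNA/DNA ratios; the unit of the
# rank-sum tests in the mutagenesis and epistasis modules. Barcodes with
# zero DNA in a replicate are dropped (ratio undefined).
barcode_ratios <- function(dict, counts) {
  counts <- complete_counts(dict, counts)
  totals <- counts %>%
    group_by(.data$replicate) %>%
    summarise(tot_rna = sum(.data$rna_umi), tot_dna = sum(.data$dna_umi),
              .groups = "drop")
  counts %>%
    inner_join(totals, by = "replicate") %>%
    filter(.data$dna_umi > 0) %>%
    mutate(ratio = (.data$rna_umi / .data$tot_rna) / (.data$dna_umi / .data$tot_dna)) %>%
    select("barcode", "replicate", "ratio")
}
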