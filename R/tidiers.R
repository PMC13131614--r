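#' Tidy a variant-effects table
#'
#' Returns the effects as a plain tibble (one row per variant); `glance()`
#' summarises the scan: class counts, the wild-type reference used, and
#' the fraction of mutation-sensitive positions.
#'
#' @param x A [variant_effects()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.variant_effects <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "variant_effects")
  as_tibble(out)
}

#' @rdname tidy.variant_effects
#' @export
glance.variant_effects <- function(x, ...) {
  by_pos <- x %>%
    filter(!is.na(.data$class)) %>%
    group_by(.data$position) %>%
    summarise(sensitive = any(.data$class != "neutral"), .groups = "drop")
  tibble(
    n_variants = nrow(x),
    n_lof = sum(x$class == "LoF", na.rm = TRUE),
    n_gof = sum(x$class == "GoF", na.rm = TRUE),
    n_missing = sum(is.na(x$class)),
    frac_sensitive_positions = mean(by_pos$sensitive),
    wt_activity = attr(x, "wt_activity")
  )
}

#' Tidy a compaction trajectory
#'
#' One row per recorded step; `glance()` reports the endpoints and the
#' best-scoring step.
#'
#' @param x A [greedy_compact()] trajectory.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.compaction_trajectory <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "compaction_trajectory")
  as_tibble(out)
}

#' @rdname tidy.compaction_trajectory
#' @export
glance.compaction_trajectory <- function(x, ...) {
  best <- which.max(x$score)
  tibble(
    start_length = x$length[1],
    stop_length = x$length[nrow(x)],
    n_steps = nrow(x) - 1L,
    best_length = x$length[best],
    best_score = x$score[best]
  )
}

#' Tidy an epistasis result
#'
#' One row per TFBS pair; `glance()` counts scored pairs and those with
#' nominally significant deviation from the multiplicative null.
#'
#' @param x A [pairwise_epistasis()] result.
#' @param ... Unused.
#' @param p_cutoff Significance cutoff used by `glance()` (default 0.01).
#' @return A tibble.
#' @export
tidy.epistasis_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "epistasis_result")
  as_tibble(out)
}

#' @rdname tidy.epistasis_result
#' @export
glance.epistasis_result <- function(x, p_cutoff = 0.01, ...) {
  scored <- !is.na(x$score)
  tibble(
    n_pairs = nrow(x),
    n_scored = sum(scored),
    n_significant = sum(scored & x$p_value < p_cutoff, na.rm = TRUE),
    median_score = median(x$score[scored]),
    n_below_minP = sum(x$below_minP, na.rm = TRUE)
  )
}
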