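#' Affinity-content sequence scorer
#'
#' The default pluggable scorer for compaction experiments: the sum over
#' models and positions of the normalized affinity wherever it exceeds
#' `threshold`. Deterministic and strictly increased by adding binding
#' sites, which makes greedy compaction preserve planted motifs. Any other
#' scorer — including wrappers around external accessibility models — can
#' be supplied wherever a scorer is accepted; the contract is simply
#' `function(seq) -> scalar`, higher meaning better.
#'
#' @param models List of [binding_model()]s.
#' @param threshold Normalized-affinity floor below which positions do not
#'   contribute (default 0.05).
#' @return A function mapping a sequence string to a numeric score.
#' @export
affinity_scorer <- function(models, threshold = 0.05) {
  force(models); force(threshold)
  function(seq) {
    x <- seq_to_int(seq)
    total <- 0
    for (m in models) {
      if (length(x) < m$k) next
      sc <- scan_core(x, m$weights)
      a <- pmax(sc$fwd, sc$rev) / m$norm_constant
      total <- total + sum(a[a >= threshold])
    }
    total
  }
}

#' Greedy single-base-deletion compaction
#'
#' At each step, all `L` single-base deletions of the current sequence are
#' scored; the deletion with the highest score is applied (ties broken
#' leftmost, for determinism) and recorded. Iteration stops when the
#' sequence reaches `stop_length`. A 300 bp start therefore yields 261
#' recorded sequences (lengths 300 down to 40, inclusive).
#'
#' @param seq Starting sequence string (longer than `stop_length`).
#' @param scorer A `function(seq) -> scalar` (see [affinity_scorer()]).
#' @param stop_length Final length (default 40).
#' @return A `compaction_trajectory`: tibble with one row per recorded
#'   sequence (`step`, `length`, `deleted_position` — 0-based position in
#'   the previous step's sequence, NA for the start — `score`, `seq`).
#' @export
greedy_compact <- function(seq, scorer, stop_length = 40L) {
  L0 <- nchar(seq)
  if (L0 <= stop_length) abort("sequence must be longer than stop_length")
  cur <- seq
  steps <- vector("list", L0 - stop_length + 1L)
  steps[[1]] <- tibble(step = 0L, length = L0,
                       deleted_position = NA_integer_,
                       score = scorer(cur), seq = cur)
  for (i in seq_len(L0 - stop_length)) {
    L <- nchar(cur)
    cand_scores <- vapply(seq_len(L), function(p) {
      scorer(paste0(substr(cur, 1, p - 1), substr(cur, p + 1, L)))
    }, numeric(1))
    best <- which.max(cand_scores)  # which.max takes the leftmost maximum
    cur <- paste0(substr(cur, 1, best - 1), substr(cur, best + 1, L))
    steps[[i + 1L]] <- tibble(step = i, length = L - 1L,
                              deleted_position = as.integer(best - 1L),
                              score = cand_scores[best], seq = cur)
  }
  out <- bind_rows(steps)
  attr(out, "start_seq") <- seq
  class(out) <- c("compaction_trajectory", class(out))
  out
}

#' Marginal embedding score
#'
#' Scores a sequence by writing it at the center of each of `n` background
#' sequences, averaging the scorer over the embedded backgrounds, and
#' normalizing by the mean score of the backgrounds alone (the null value).
#' A ratio of 1 means the insert adds nothing beyond background.
#'
#' @param seq Sequence string to embed.
#' @param scorer A `function(seq) -> scalar`.
#' @param backgrounds Tibble with a `seq` column; all backgrounds must be
#'   at least as long as `seq`.
#' @param n Number of backgrounds to use (default 1000).
#' @return Scalar marginal score ratio.
#' @export
marginal_embed_score <- function(seq, scorer, backgrounds, n = 1000) {
  if (n > nrow(backgrounds)) abort("n exceeds the number of available backgrounds")
  bg <- backgrounds$seq[seq_len(n)]
  if (any(nchar(bg) < nchar(seq))) abort("backgrounds must be at least as long as seq")
  w <- nchar(seq)
  embed_one <- function(b) {
    off <- (nchar(b) - w) %/% 2
    paste0(substr(b, 1, off), seq, substr(b, off + w + 1, nchar(b)))
  }
  scores_emb <- vapply(bg, function(b) scorer(embed_one(b)), numeric(1))
  scores_null <- vapply(bg, scorer, numeric(1))
  mean(scores_emb) / mean(scores_null)
}

#' Activity-size Pareto front
#'
#' A point is dominated when another point has activity at least as high
#' and length at least as short, with at least one strict inequality. The
#' front is the set of non-dominated points, sorted by length. With
#' `by_source = TRUE`, per-source fronts are computed instead of the global
#' one.
#'
#' @param points Tibble with `length`, `activity` and optionally `source`.
#' @param by_source Compute one front per `source` level.
#' @return The subset of `points` on the front (plus all input columns),
#'   sorted by length.
#' @export
pareto_front <- function(points, by_source = FALSE) {
  stopifnot(nrow(points) >= 1)
  # Sweep lengths in increasing order: a point survives iff it has the
  # maximal activity at its length and that activity strictly exceeds every
  # activity achievable at a shorter length.
  front_of <- function(df) {
    d <- df[order(df$length, -df$activity), ]
    keep <- logical(nrow(d))
    best <- -Inf
    for (L in unique(d$length)) {
      idx <- which(d$length == L)
      amax <- max(d$activity[idx])
      if (amax > best) keep[idx[d$activity[idx] == amax]] <- TRUE
      best <- max(best, amax)
    }
    arrange(d[keep, ], .data$length)
  }
  if (by_source) {
    if (!"source" %in% names(points)) abort("by_source requires a 'source' column")
    points %>% group_by(.data$source) %>%
      dplyr::group_modify(function(g, key) front_of(g)) %>% ungroup()
  } else {
    front_of(points)
  }
}
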