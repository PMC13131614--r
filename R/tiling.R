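#' Design a multi-size sub-tile library
#'
#' For each tile size `w`, left-aligned tiles at stride `s` cover the parent
#' with `floor((L - w) / s) + 1` tiles per orientation.
#'
#' @param parent One-row tibble (`id`, `seq`) or a bare sequence string; only
#'   the length is used if `length` is given.
#' @param sizes Tile sizes in bases (default the seven canonical sizes
#'   40-300 bp).
#' @param stride Offset between consecutive same-size tiles (default 5).
#' @param orientations Orientations to design (default both).
#' @param length Parent length override (design without a sequence).
#' @return Tile design tibble: `parent_id`, `tile_id`, `start`, `end`,
#'   `size`, `orientation`.
#' @export
design_tiles <- function(parent = NULL,
                         sizes = c(40L, 70L, 120L, 170L, 220L, 270L, 300L),
                         stride = 5L, orientations = c("+", "-"),
                         length = NULL) {
  if (is.character(parent)) parent <- tibble(id = "parent", seq = parent)
  L <- length %||% nchar(parent$seq[[1]])
  pid <- if (is.null(parent)) "parent" else parent$id[[1]]
  if (any(sizes > L)) abort("tile size exceeds parent length")
  out <- tidyr::expand_grid(size = as.integer(sizes),
                            orientation = orientations) %>%
    mutate(starts = purrr::map(.data$size, function(w) {
      as.integer(seq(0L, L - w, by = stride))
    })) %>%
    tidyr::unnest("starts") %>%
    mutate(parent_id = pid,
           start = .data$starts,
           end = .data$starts + .data$size,
           tile_id = paste0(pid, "_w", .data$size, "_s", .data$starts,
                            "_", ifelse(.data$orientation == "+", "fwd", "rev"))) %>%
    select("parent_id", "tile_id", "start", "end", "size", "orientation")
  out
}

#' Extract tile sequences as cloned
#'
#' Minus-orientation tiles are reverse-complemented.
#' @param tiles Tile design tibble from [design_tiles()].
#' @param parent One-row tibble (`id`, `seq`).
#' @return `tiles` with a `seq` column.
#' @export
tile_sequences <- function(tiles, parent) {
  iv <- tibble(seq_id = tiles$parent_id, start = tiles$start, end = tiles$end,
               strand = tiles$orientation)
  ex <- extract_sequences(iv, tibble(id = parent$id[[1]], seq = parent$seq[[1]]))
  mutate(tiles, seq = ex$seq)
}

#' Smooth a positional activity profile with a sliding median
#'
#' Median over `window` consecutive tile positions (the profile's native
#' resolution, i.e. one point per stride); edge positions use truncated
#' windows.
#'
#' @param profile Tibble with `position` (sorted) and `activity`.
#' @param window Odd window size in tile positions (default 3).
#' @return `profile` with `activity` replaced by the smoothed values and the
#'   raw values kept in `activity_raw`.
#' @export
smooth_profile <- function(profile, window = 3L) {
  stopifnot(window %% 2 == 1)
  if (is.unsorted(profile$position)) abort("positions must be sorted")
  x <- profile$activity
  h <- (window - 1L) %/% 2L
  n <- length(x)
  sm <- vapply(seq_len(n), function(i) {
    median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
  mutate(profile, activity_raw = x, activity = sm)
}

#' Scan for sub-tile synergy between short and long tiles
#'
#' For each long tile `L`, the two short tiles `S1`, `S2` whose outer
#' boundaries match `L`'s are located (they overlap centrally by
#' `2 * s_size - l_size` bases, wider than a single TFBS), and the synergy
#' ratio `A(L) / max(A(S1) + A(S2) - minP, eps)` is computed. Ratios above 1
#' indicate super-additive (synergistic) activity of the long tile.
#'
#' @param activities Tibble of tile activities with columns `start`, `end`,
#'   `size`, `activity` (one orientation, or orientation-averaged).
#' @param minP Basal minimal-promoter-only activity, subtracted once from
#'   the short-tile sum so the baseline is not counted twice.
#' @param s_size,l_size Short and long tile sizes (defaults 70 and 120).
#' @param eps Denominator floor (default `minP / 10`); rows that hit the
#'   floor are flagged and should be excluded from ranking.
#' @param subtract_minP Set `FALSE` to compare against the raw short-tile
#'   sum.
#' @return Tibble of synergy triples sorted by decreasing ratio: `start`,
#'   `end`, `a_long`, `a_s1`, `a_s2`, `expected`, `synergy_ratio`,
#'   `floored`.
#' @export
synergy_scan <- function(activities, minP, s_size = 70L, l_size = 120L,
                         eps = minP / 10, subtract_minP = TRUE) {
  stopifnot(2L * s_size > l_size)
  longs <- activities[activities$size == l_size, ]
  shorts <- activities[activities$size == s_size, ]
  if (nrow(longs) == 0 || nrow(shorts) == 0) {
    abort("activities must contain both short and long tile sizes")
  }
  s_by_start <- setNames(shorts$activity, shorts$start)
  s_by_end <- setNames(shorts$activity, shorts$end)
  out <- longs %>%
    mutate(
      a_s1 = unname(s_by_start[as.character(.data$start)]),
      a_s2 = unname(s_by_end[as.character(.data$end)])
    )
  miss <- is.na(out$a_s1) | is.na(out$a_s2)
  if (any(miss)) {
    warn(paste0(sum(miss), " long tile(s) lack boundary-matched short tiles; skipped"))
    out <- out[!miss, ]
  }
  base <- if (subtract_minP) minP else 0
  out %>%
    mutate(
      a_long = .data$activity,
      expected = .data$a_s1 + .data$a_s2 - base,
      floored = .data$expected <= eps,
      synergy_ratio = .data$a_long / pmax(.data$expected, eps)
    ) %>%
    select("start", "end", "a_long", "a_s1", "a_s2", "expected",
           "synergy_ratio", "floored") %>%
    arrange(dplyr::desc(.data$synergy_ratio))
}

#' Collapse tile activities onto promoter-distance coordinates
#'
#' For each tile, computes the distance (delta x) from the tile's
#' minP-proximal end — the 3' end of the tile as cloned in its orientation,
#' i.e. the right edge in parent coordinates for `+` tiles and the left edge
#' for `-` tiles — to the nearest edge of an active subregion. Plotting
#' activity against delta x overlays forward and reverse profiles when
#' activity is governed by subregion-to-promoter distance.
#'
#' @param activities Tile activity tibble with `start`, `end`,
#'   `orientation`, `activity`.
#' @param active_subregion Length-2 numeric `c(start, end)` of the active
#'   subregion in parent coordinates.
#' @return `activities` with columns `proximal_end` and `delta_x` added,
#'   restricted to tiles that fully contain the subregion's nearest edge.
#' @export
distance_collapse <- function(activities, active_subregion) {
  stopifnot(length(active_subregion) == 2)
  sub_s <- active_subregion[1]; sub_e <- active_subregion[2]
  covering <- activities$start <= sub_s & activities$end >= sub_e
  if (!any(covering)) abort("active subregion not covered by any tile")
  out <- activities[covering, ]
  p <- ifelse(out$orientation == "+", out$end, out$start)
  dx <- pmin(abs(p - sub_s), abs(p - sub_e))
  mutate(out, proximal_end = p, delta_x = dx)
}

#' Fit an exponential distance-decay model to collapsed activities
#'
#' Fits `activity = minP + A0 * exp(-delta_x / tau)` by least squares on
#' `log(activity - minP)` and returns the decay constant.
#'
#' @param collapsed Output of [distance_collapse()].
#' @param minP Basal activity to subtract.
#' @return One-row tibble: `a0`, `tau`, `r_squared`, `n`.
#' @export
fit_distance_decay <- function(collapsed, minP = 0) {
  y <- collapsed$activity - minP
  ok <- y > 0
  fit <- lm(log(y[ok]) ~ collapsed$delta_x[ok])
  tibble(
    a0 = exp(unname(coef(fit)[1])),
    tau = -1 / unname(coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    n = sum(ok)
  )
}
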