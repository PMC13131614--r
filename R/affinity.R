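#' Construct a position-specific binding model
#'
#' A binding model is a k x 4 matrix of per-base relative-affinity
#' multipliers (columns A, C, G, T; all strictly positive) plus a
#' normalization constant. The unnormalized affinity of a k-mer is the
#' product of one multiplier per position; normalized affinity divides by
#' `norm_constant`, conventionally calibrated as the 99.99th percentile of
#' affinities over random k-mers (see [calibrate_norm_constant()]) so that
#' exceptionally strong sequences can score slightly above 1.
#'
#' @param tf_name Transcription factor label.
#' @param weights k x 4 numeric matrix, columns in A, C, G, T order.
#' @param norm_constant Positive scalar; defaults to the model's maximum
#'   unnormalized affinity so the consensus scores exactly 1.
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(tf_name, weights, norm_constant = NULL) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 4) abort("weights must have 4 columns (A, C, G, T)")
  if (nrow(weights) < 4) abort("binding models must have width k >= 4")
  if (any(weights <= 0)) abort("all weights must be strictly positive")
  colnames(weights) <- DNA_BASES
  if (is.null(norm_constant)) norm_constant <- prod(apply(weights, 1, max))
  if (norm_constant <= 0) abort("norm_constant must be positive")
  structure(
    list(tf_name = tf_name, k = nrow(weights), weights = weights,
         norm_constant = norm_constant),
    class = "binding_model"
  )
}

#' @export
print.binding_model <- function(x, ...) {
  cat("<binding_model> ", x$tf_name, ": k = ", x$k,
      ", norm_constant = ", signif(x$norm_constant, 4), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a binding model
#'
#' @param model A [binding_model()].
#' @return The maximum-affinity k-mer as a string.
#' @export
model_consensus <- function(model) {
  paste(DNA_BASES[apply(model$weights, 1, which.max)], collapse = "")
}

#' Read / write binding models as TSV matrices
#'
#' The on-disk format is a TSV with comment lines `#tf_name=` and
#' `#norm_constant=` followed by a header row `A C G T` and one row of
#' multipliers per model position.
#'
#' @param path File path.
#' @return A `binding_model`.
#' @export
read_binding_model <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key, default = NULL) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit) == 0) return(default)
    sub(paste0("^#", key, "="), "", hit[1])
  }
  df <- readr::read_tsv(I(paste(body, collapse = "\n")),
                        show_col_types = FALSE, progress = FALSE)
  nc <- get_meta("norm_constant")
  binding_model(
    tf_name = get_meta("tf_name", "unknown"),
    weights = as.matrix(df[, DNA_BASES]),
    norm_constant = if (is.null(nc)) NULL else as.numeric(nc)
  )
}

#' @rdname read_binding_model
#' @param model A `binding_model`.
#' @export
write_binding_model <- function(model, path) {
  header <- c(paste0("#tf_name=", model$tf_name),
              paste0("#norm_constant=", format(model$norm_constant, digits = 17)))
  readr::write_lines(header, path)
  readr::write_tsv(as_tibble(as.data.frame(model$weights)), path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

# Numeric core of the scanner: forward and reverse-complement affinities for
# all k-mer offsets of an integer-encoded sequence. Returns a list of two
# vectors of length L - k + 1.
scan_core <- function(x, W) {
  k <- nrow(W)
  n <- length(x) - k + 1L
  # Reverse-complement scan reuses the same loop with the row-reversed,
  # column-complemented weight matrix.
  Wrc <- W[k:1, 4:1, drop = FALSE]
  fwd <- rep(1, n)
  rev <- rep(1, n)
  for (j in seq_len(k)) {
    b <- x[j:(j + n - 1L)]
    fwd <- fwd * W[j, b]
    rev <- rev * Wrc[j, b]
  }
  list(fwd = unname(fwd), rev = unname(rev))
}

#' Scan a sequence with a binding model
#'
#' Computes, for every k-mer offset, the maximum over the two orientations of
#' the product of per-position multipliers, divided by the model's
#' normalization constant. The best-scoring orientation is recorded. Edges
#' are scored only where a full k-mer fits.
#'
#' @param record A one-row tibble with `id` and `seq` (or a bare string).
#' @param model A [binding_model()].
#' @return An affinity track: tibble with `seq_id`, `tf`, `pos` (0-based
#'   k-mer offset), `affinity`, `strand`, carrying the model width as
#'   attribute `k`.
#' @export
scan_affinity <- function(record, model) {
  if (is.character(record)) record <- tibble(id = "seq", seq = record)
  stopifnot(nrow(record) == 1)
  s <- record$seq[[1]]
  if (nchar(s) < model$k) abort("sequence shorter than model width k")
  x <- seq_to_int(s)
  sc <- scan_core(x, model$weights)
  out <- tibble(
    seq_id = record$id[[1]],
    tf = model$tf_name,
    pos = seq_along(sc$fwd) - 1L,
    affinity = pmax(sc$fwd, sc$rev) / model$norm_constant,
    strand = ifelse(sc$fwd >= sc$rev, "+", "-")
  )
  attr(out, "k") <- model$k
  out
}

#' Calibrate a model's normalization constant from random k-mers
#'
#' Draws `n_kmers` uniform random k-mers and returns the empirical 99.99th
#' percentile (linear-interpolation order statistic) of their unnormalized
#' affinities. Deterministic given `seed`.
#'
#' @param model A [binding_model()].
#' @param n_kmers Number of random k-mers (default one million; at least
#'   10,000 so the tail quantile is estimable).
#' @param seed Integer seed.
#' @param quantile_level Tail quantile (default 0.9999).
#' @return Positive scalar normalization constant.
#' @export
calibrate_norm_constant <- function(model, n_kmers = 1e6, seed = 1,
                                    quantile_level = 0.9999) {
  if (n_kmers < 1e4) abort("n_kmers must be >= 10,000 to estimate the 99.99th percentile")
  W <- model$weights
  with_seed(seed, {
    a <- rep(1, n_kmers)
    for (j in seq_len(nrow(W))) {
      a <- a * W[j, sample.int(4L, n_kmers, replace = TRUE)]
    }
    quantile(a, quantile_level, names = FALSE, type = 7)
  })
}

#' Merge two affinity tracks position-wise by maximum
#'
#' Used to treat near-redundant factors (e.g. two GATA family models) as one
#' composite track: each position keeps the larger normalized affinity and
#' the orientation of the winning model. Set `flip_b_strand = TRUE` when the
#' second model's consensus is stored in the opposite orientation to the
#' first, so reported orientations are comparable.
#'
#' @param track_a,track_b Affinity tracks from [scan_affinity()] over the
#'   same sequence with equal-width models.
#' @param tf_name Label for the merged track.
#' @param flip_b_strand Flip the strand reported for positions won by
#'   `track_b`.
#' @return A merged affinity track.
#' @export
max_merge_tracks <- function(track_a, track_b, tf_name = NULL,
                             flip_b_strand = FALSE) {
  if (nrow(track_a) != nrow(track_b) || !all(track_a$pos == track_b$pos)) {
    abort("tracks must cover identical positions")
  }
  b_strand <- track_b$strand
  if (flip_b_strand) b_strand <- ifelse(b_strand == "+", "-", "+")
  win_a <- track_a$affinity >= track_b$affinity
  out <- tibble(
    seq_id = track_a$seq_id,
    tf = tf_name %||% paste0(track_a$tf[1], "/", track_b$tf[1]),
    pos = track_a$pos,
    affinity = pmax(track_a$affinity, track_b$affinity),
    strand = ifelse(win_a, track_a$strand, b_strand)
  )
  attr(out, "k") <- attr(track_a, "k")
  out
}

#' Call discrete TFBSs from an affinity track
#'
#' Greedy non-maximum suppression: positions are visited in decreasing
#' affinity order and accepted unless within `k` of an already-accepted
#' site, yielding one site per local optimum. Sites below `threshold` are
#' not called. Each called site spans `[pos, pos + k)` and reports the site
#' maximum affinity and its orientation.
#'
#' @param track Affinity track from [scan_affinity()].
#' @param threshold Normalized-affinity cutoff in (0, 1]; 0.05 is the
#'   conventional putative-site cutoff, 0.1 the stricter anchor-definition
#'   cutoff.
#' @param k Site width; defaults to the track's model width.
#' @return Tibble of called sites: `seq_id`, `tf`, `start`, `end`, `strand`,
#'   `affinity`, sorted by `start`.
#' @export
call_tfbs <- function(track, threshold = 0.05, k = attr(track, "k")) {
  stopifnot(threshold > 0, threshold <= 1, !is.null(k))
  cand <- track[track$affinity >= threshold, ]
  cand <- cand[order(-cand$affinity, cand$pos), ]
  accepted <- integer(0)
  for (p in cand$pos) {
    if (length(accepted) == 0 || all(abs(p - accepted) >= k)) {
      accepted <- c(accepted, p)
    }
  }
  out <- cand[match(accepted, cand$pos), ]
  out <- out[order(out$pos), ]
  tibble(
    seq_id = out$seq_id, tf = out$tf,
    start = out$pos, end = out$pos + as.integer(k),
    strand = out$strand, affinity = out$affinity
  )
}

# Merge possibly-overlapping intervals into maximal disjoint intervals,
# concatenating member annotations.
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$start, df$end), ]
  starts <- df$start; ends <- df$end
  tfs <- if ("tf" %in% names(df)) df$tf else rep(NA_character_, nrow(df))
  res_start <- starts[1]; res_end <- ends[1]; res_tfs <- tfs[1]
  acc <- list()
  for (i in seq_len(nrow(df))[-1]) {
    if (starts[i] < res_end) {  # overlap (half-open: touching intervals stay separate)
      res_end <- max(res_end, ends[i])
      res_tfs <- paste(unique(c(strsplit(res_tfs, ",")[[1]], tfs[i])), collapse = ",")
    } else {
      acc[[length(acc) + 1]] <- tibble(start = res_start, end = res_end, tfs = res_tfs)
      res_start <- starts[i]; res_end <- ends[i]; res_tfs <- tfs[i]
    }
  }
  acc[[length(acc) + 1]] <- tibble(start = res_start, end = res_end, tfs = res_tfs)
  bind_rows(acc)
}

#' Build a TFBS anchor set for a CRE
#'
#' Calls sites for each supplied model at `threshold`, takes the union of
#' the called intervals, merges overlaps into maximal non-overlapping
#' "anchor" intervals, and computes the complementary gap intervals. Anchors
#' and gaps together tile `[0, L)`.
#'
#' @param record One-row tibble (`id`, `seq`) or bare sequence string.
#' @param models List of [binding_model()]s (pre-merged composite tracks can
#'   be passed via `tracks`).
#' @param threshold Normalized-affinity cutoff for anchor definition
#'   (default 0.1).
#' @param tracks Optional list of precomputed affinity tracks, used instead
#'   of scanning `models`.
#' @return An anchor set: tibble with `cre_id`, `start`, `end`, `type`
#'   (`"anchor"` or `"gap"`), `tfs`; attribute `cre_length`.
#' @export
build_anchors <- function(record, models = NULL, threshold = 0.1, tracks = NULL) {
  if (is.character(record)) record <- tibble(id = "cre", seq = record)
  L <- nchar(record$seq[[1]])
  if (is.null(tracks)) {
    if (is.null(models) || length(models) == 0) abort("supply models or tracks")
    tracks <- lapply(models, function(m) scan_affinity(record, m))
  }
  sites <- bind_rows(lapply(tracks, function(tr) {
    call_tfbs(tr, threshold = threshold, k = attr(tr, "k"))
  }))
  if (nrow(sites) == 0) {
    warn("no TFBS called; anchor set is empty")
    anchors <- tibble(start = integer(0), end = integer(0), tfs = character(0))
  } else {
    anchors <- merge_intervals(sites[, c("start", "end", "tf")])
  }
  gaps <- interval_complement(anchors, L)
  out <- bind_rows(
    mutate(anchors, type = "anchor"),
    mutate(gaps, type = "gap", tfs = NA_character_)
  )
  out <- arrange(mutate(out, cre_id = record$id[[1]]), .data$start)
  out <- out[, c("cre_id", "start", "end", "type", "tfs")]
  attr(out, "cre_length") <- L
  out
}

# Complement of disjoint sorted intervals within [0, L).
interval_complement <- function(df, L) {
  if (nrow(df) == 0) return(tibble(start = 0L, end = as.integer(L)))
  df <- df[order(df$start), ]
  starts <- c(0L, df$end)
  ends <- c(df$start, as.integer(L))
  keep <- starts < ends
  tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Anchor intervals of an anchor set, with sequences
#'
#' @param anchor_set Output of [build_anchors()].
#' @param seq The parent CRE sequence string.
#' @return Tibble of anchor rows with a `seq` column (native orientation).
#' @export
anchor_seqs <- function(anchor_set, seq) {
  a <- anchor_set[anchor_set$type == "anchor", ]
  mutate(a, seq = substr(rep(seq, nrow(a)), .data$start + 1, .data$end))
}
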