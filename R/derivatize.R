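#' Dinucleotide shuffle of a DNA sequence
#'
#' Uniform random Eulerian-path shuffle (Altschul-Erickson): the output
#' preserves the exact dinucleotide transition counts of the input, its
#' first and last base, and its length. Deterministic given `seed`.
#' Sequences whose dinucleotide graph admits only the identity arrangement
#' (e.g. homopolymers) are returned unchanged.
#'
#' @param seq DNA string of length at least 3.
#' @param seed Integer seed.
#' @return The shuffled sequence string.
#' @export
dinucleotide_shuffle <- function(seq, seed) {
  x <- seq_to_int(seq)
  n <- length(x)
  if (n < 3) abort("sequence must have length >= 3")
  with_seed(seed, {
    adj <- vector("list", 4)
    for (v in 1:4) adj[[v]] <- x[-1][x[-n] == v]
    verts <- sort(unique(x))
    last <- x[n]
    # Sample a random "last edge" per non-terminal vertex until these edges
    # form an arborescence into the terminal vertex (rejection sampling;
    # guaranteed to succeed since the input itself is an Eulerian path).
    found <- FALSE
    last_edge <- rep(NA_integer_, 4)
    for (attempt in seq_len(10000)) {
      for (v in verts) {
        if (v == last) next
        succs <- adj[[v]]
        last_edge[v] <- succs[sample.int(length(succs), 1L)]
      }
      ok <- TRUE
      for (v in setdiff(verts, last)) {
        cur <- v
        for (hop in 1:4) {
          cur <- last_edge[cur]
          if (is.na(cur) || cur == last) break
        }
        if (is.na(cur) || cur != last) { ok <- FALSE; break }
      }
      if (ok) { found <- TRUE; break }
    }
    if (!found) return(seq)
    adj2 <- vector("list", 4)
    for (v in verts) {
      succs <- adj[[v]]
      if (length(succs) == 0) next
      if (v == last) {
        adj2[[v]] <- succs[sample.int(length(succs))]
      } else {
        i <- match(last_edge[v], succs)
        rest <- succs[-i]
        if (length(rest) > 1) rest <- rest[sample.int(length(rest))]
        adj2[[v]] <- c(rest, last_edge[v])
      }
    }
    out <- integer(n)
    ptr <- rep(1L, 4)
    out[1] <- x[1]
    cur <- x[1]
    for (i in 2:n) {
      nxt <- adj2[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    int_to_seq(out)
  })
}

#' Generate a background DNA panel
#'
#' Synthetic stand-ins for inaccessible genomic background sequences:
#' `n` random sequences at the given GC content, plus one dinucleotide
#' shuffle of each, for `2n` backgrounds total. Mirrors the convention of
#' pairing each genomic background with its composition-matched shuffle.
#'
#' @param n Number of primary backgrounds (default 200, giving 400 total).
#' @param length Background length in bases (default 300, matched to the
#'   CREs they host).
#' @param gc GC content of the primary backgrounds (default 0.42,
#'   genome-typical).
#' @param seed Integer seed.
#' @return Tibble: `id`, `seq`, `origin`
#'   (`"genomic_inaccessible"`/`"dinucleotide_shuffle"`), `parent_id`.
#' @export
make_backgrounds <- function(n = 200, length = 300, gc = 0.42, seed = 1) {
  prim <- with_seed(seed, random_dna(n, length, gc))
  prim_ids <- sprintf("bg%03d", seq_len(n))
  shuf <- vapply(seq_len(n), function(i) {
    dinucleotide_shuffle(prim[i], derive_seed(seed, i))
  }, character(1))
  bind_rows(
    tibble(id = prim_ids, seq = prim, origin = "genomic_inaccessible",
           parent_id = NA_character_),
    tibble(id = paste0(prim_ids, "_shuf"), seq = shuf,
           origin = "dinucleotide_shuffle", parent_id = prim_ids)
  )
}

# Trim anchors by `flank_trim` bases on each flank; anchors must stay
# non-empty after trimming.
trim_anchors <- function(anchors, flank_trim) {
  if (flank_trim == 0) return(anchors)
  if (any(anchors$end - anchors$start <= 2 * flank_trim)) {
    abort("anchor too short for requested flank trimming")
  }
  mutate(anchors,
         start = .data$start + flank_trim,
         end = .data$end - flank_trim,
         seq = substr(.data$seq, flank_trim + 1,
                      nchar(.data$seq) - flank_trim))
}

#' Reconstitute TFBS anchors onto a background sequence
#'
#' Writes each (optionally flank-trimmed) anchor substring over the
#' background at the given target positions — by default the exact
#' positions the anchors occupy in the native CRE, preserving inter-motif
#' spacing while replacing all non-anchor sequence with background.
#'
#' @param anchors Anchor tibble with `start`, `end`, `seq` (native
#'   orientation), e.g. from [anchor_seqs()].
#' @param background Background sequence string, at least as long as the
#'   CRE.
#' @param positions Optional integer vector of target start positions for
#'   the (trimmed) anchors; default native (trimmed) starts.
#' @param flank_trim Bases trimmed from each anchor flank (0, 1 or 2).
#' @return List with `seq` (the derived sequence) and `layout` (tibble of
#'   written intervals).
#' @export
reconstitute <- function(anchors, background, positions = NULL,
                         flank_trim = 0) {
  a <- trim_anchors(anchors, flank_trim)
  widths <- a$end - a$start
  starts <- positions %||% a$start
  stopifnot(length(starts) == nrow(a))
  ends <- starts + widths
  L <- nchar(background)
  ord <- order(starts)
  if (any(ends > L) || any(starts < 0)) abort("anchor placement outside background")
  if (any(starts[ord][-1] < ends[ord][-length(ord)])) {
    abort("target anchor intervals overlap")
  }
  out <- background
  for (i in seq_along(starts)) {
    substr(out, starts[i] + 1, ends[i]) <- a$seq[i]
  }
  list(seq = out,
       layout = tibble(anchor = seq_len(nrow(a)), start = starts,
                       end = ends, seq = a$seq))
}

# Draw non-overlapping uniform start positions for anchors of the given
# widths on a background of length L (longest anchor placed first,
# bounded rejection sampling). Returns starts in the input anchor order.
sample_anchor_positions <- function(widths, L, seed, max_tries = 1000,
                                    max_restarts = 20) {
  if (sum(widths) > L) abort("total anchor length exceeds background length")
  for (restart in seq_len(max_restarts)) {
    res <- with_seed(derive_seed(seed, restart - 1), {
      ord <- order(widths, decreasing = TRUE)
      placed_s <- integer(0); placed_e <- integer(0)
      starts <- rep(NA_integer_, length(widths))
      ok <- TRUE
      for (i in ord) {
        w <- widths[i]
        hit <- FALSE
        for (t in seq_len(max_tries)) {
          s <- sample.int(L - w + 1L, 1L) - 1L
          if (!any(s < placed_e & (s + w) > placed_s)) {
            starts[i] <- s
            placed_s <- c(placed_s, s); placed_e <- c(placed_e, s + w)
            hit <- TRUE
            break
          }
        }
        if (!hit) { ok <- FALSE; break }
      }
      if (ok) starts else NULL
    })
    if (!is.null(res)) return(res)
  }
  abort("anchor placement failed after bounded retries")
}

#' Randomly deposit TFBS anchors into a background
#'
#' Places the anchors (wild-type orientation, untrimmed) at uniformly drawn
#' non-overlapping positions: candidates are drawn uniformly over all valid
#' start positions and accepted only if they do not overlap any previously
#' placed anchor (longest anchor first). Deterministic given `seed`.
#'
#' @inheritParams reconstitute
#' @param seed Integer seed.
#' @return List with `seq` and `layout`, as [reconstitute()].
#' @export
random_deposit <- function(anchors, background, seed) {
  widths <- anchors$end - anchors$start
  starts <- sample_anchor_positions(widths, nchar(background), seed)
  reconstitute(anchors, background, positions = starts, flank_trim = 0)
}

#' Synthetic thripsis: shatter and reassemble a CRE
#'
#' Selects `n_breakpoints` cut sites uniformly without replacement from gap
#' (non-anchor) positions, partitioning the sequence into
#' `n_breakpoints + 1` fragments, then concatenates the fragments in a
#' uniformly random order with orientation preserved. Anchor substrings are
#' never split and the sequence composition is conserved up to junction
#' effects.
#'
#' @param seq CRE sequence string.
#' @param anchor_set Anchor set from [build_anchors()].
#' @param n_breakpoints Number of cuts (conventionally 5, 10 or 20).
#' @param seed Integer seed.
#' @return List with `seq` (the thripsized sequence) and `layout` (tibble:
#'   `fragment`, `orig_start`, `orig_end`, `new_order`, `new_start`,
#'   `new_end`).
#' @export
thripsis <- function(seq, anchor_set, n_breakpoints, seed) {
  L <- nchar(seq)
  gaps <- anchor_set[anchor_set$type == "gap", ]
  gap_pos <- unlist(purrr::map2(gaps$start, gaps$end, function(s, e) s:(e - 1L)))
  gap_pos <- setdiff(gap_pos, 0L)  # a cut before position 0 is a no-op
  if (length(gap_pos) < n_breakpoints) abort("not enough gap positions for cuts")
  with_seed(seed, {
    cuts <- if (n_breakpoints == 0) integer(0) else
      sort(sample(gap_pos, n_breakpoints))
    bounds <- c(0L, cuts, L)
    frags <- substring(seq, bounds[-length(bounds)] + 1L, bounds[-1])
    perm <- if (length(frags) == 1) 1L else sample.int(length(frags))
    new_seq <- paste(frags[perm], collapse = "")
    new_ends <- cumsum(nchar(frags[perm]))
    new_starts <- c(0L, head(new_ends, -1))
    layout <- tibble(
      fragment = perm,
      orig_start = bounds[-length(bounds)][perm],
      orig_end = bounds[-1][perm],
      new_order = seq_along(perm),
      new_start = as.integer(new_starts),
      new_end = as.integer(new_ends)
    )
    list(seq = new_seq, layout = layout)
  })
}

# Longest common substring among unmasked positions of integer-encoded a, b.
# Ties: longest, then leftmost in a, then leftmost in b. Returns
# c(len, i, j) with 1-based starts, or len = 0 when nothing matches.
lcs_unmasked <- function(a, b, mask_a, mask_b) {
  n <- length(a); m <- length(b)
  best_len <- 0L; best_i <- 0L; best_j <- 0L
  for (d in (-(n - 1L)):(m - 1L)) {
    i0 <- max(1L, 1L - d)
    j0 <- i0 + d
    len <- min(n - i0, m - j0) + 1L
    ii <- i0:(i0 + len - 1L)
    jj <- j0:(j0 + len - 1L)
    eq <- (a[ii] == b[jj]) & !mask_a[ii] & !mask_b[jj]
    r <- rle(eq)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      l <- r$lengths[k]
      i <- ii[starts[k]]; j <- jj[starts[k]]
      if (l > best_len ||
          (l == best_len && (i < best_i || (i == best_i && j < best_j)))) {
        best_len <- l; best_i <- i; best_j <- j
      }
    }
  }
  c(best_len, best_i, best_j)
}

#' Reconstruct thriptic fragments by iterated longest-common-substring
#'
#' Compares an original sequence with its rearranged derivative: the
#' longest common substring over still-unmatched positions is recorded and
#' masked in both sequences, and the process repeats until the original is
#' fully covered. Residual single-base matches are reported as singleton
#' fragments. Total masked length strictly increases every iteration, so
#' termination is guaranteed.
#'
#' @param original,derived Equal-length sequence strings.
#' @return Tibble of fragments sorted by position in the original:
#'   `fragment` (discovery rank, 1 = longest), `orig_start`, `orig_end`,
#'   `new_start`, `new_end` (0-based half-open).
#' @export
reconstruct_fragments <- function(original, derived) {
  if (nchar(original) != nchar(derived)) abort("sequences must have equal length")
  a <- seq_to_int(original); b <- seq_to_int(derived)
  mask_a <- rep(FALSE, length(a)); mask_b <- rep(FALSE, length(b))
  rows <- list()
  rank <- 0L
  while (!all(mask_a)) {
    hit <- lcs_unmasked(a, b, mask_a, mask_b)
    if (hit[1] == 0) break  # unmatchable residue (cannot occur for permuted content)
    rank <- rank + 1L
    i <- hit[2]; j <- hit[3]; l <- hit[1]
    rows[[rank]] <- tibble(
      fragment = rank,
      orig_start = i - 1L, orig_end = i - 1L + l,
      new_start = j - 1L, new_end = j - 1L + l
    )
    mask_a[i:(i + l - 1L)] <- TRUE
    mask_b[j:(j + l - 1L)] <- TRUE
  }
  arrange(bind_rows(rows), .data$orig_start)
}

#' Default derivative-library configuration
#'
#' @param seed Master seed from which every per-design seed is derived.
#' @param flank_trims Flank trims of the endogenous-position reconstitution
#'   sets.
#' @param n_random_position_sets Randomized-position reconstitution sets
#'   per CRE.
#' @param n_deposition_seeds Random deposition position sets per
#'   background.
#' @param n_deposition_backgrounds Designated backgrounds for deposition.
#' @param thripsis_breakpoints Breakage densities.
#' @param n_thripsis_seeds Random configurations per breakage density.
#' @param n_negative Total negative controls (the background panel plus
#'   additional independent shuffles up to this count).
#' @return Named list of configuration values.
#' @export
derivative_config <- function(seed = 1,
                              flank_trims = c(0L, 1L, 2L),
                              n_random_position_sets = 2L,
                              n_deposition_seeds = 100L,
                              n_deposition_backgrounds = 6L,
                              thripsis_breakpoints = c(5L, 10L, 20L),
                              n_thripsis_seeds = 200L,
                              n_negative = 2400L) {
  as.list(environment())
}

#' Design the full TFBS-anchored derivative library
#'
#' Per CRE: reconstitution = (endogenous position sets at each flank trim +
#' randomized position sets, wild-type orientation) x all backgrounds;
#' random deposition = `n_deposition_seeds` position sets x the designated
#' backgrounds; synthetic thripsis = each breakage density x
#' `n_thripsis_seeds` configurations. Plus the wild-type sequences and a
#' negative-control panel (the backgrounds themselves, extended with
#' further independent dinucleotide shuffles up to `n_negative`). With the
#' defaults and a 400-sequence background panel this yields 2,000
#' reconstitutions, 600 depositions and 600 thripsis derivatives per CRE.
#' Fully reproducible: every row records the derived seed used to build it.
#'
#' @param cres Tibble of CREs (`id`, `seq`).
#' @param anchor_sets Named list of [build_anchors()] outputs, one per CRE
#'   id.
#' @param backgrounds Background panel from [make_backgrounds()].
#' @param config Configuration from [derivative_config()].
#' @return Tibble of designs (`id`, `class`, `cre_id`, `background_id`,
#'   `position_set_id`, `flank_trim`, `n_breakpoints`, `seed`, `seq`) with
#'   a `manifest` attribute summarising class counts and the configuration.
#' @export
design_library <- function(cres, anchor_sets, backgrounds,
                           config = derivative_config()) {
  stopifnot(all(cres$id %in% names(anchor_sets)))
  rows <- list()
  push <- function(df) rows[[length(rows) + 1L]] <<- df
  for (ci in seq_len(nrow(cres))) {
    cre_id <- cres$id[ci]
    cre_seq <- cres$seq[ci]
    anchors <- anchor_seqs(anchor_sets[[cre_id]], cre_seq)
    cre_base <- derive_seed(config$seed, ci * 1000L)

    # --- reconstitution: position sets x all backgrounds
    pos_sets <- list()
    for (tr in config$flank_trims) {
      pos_sets[[paste0("endo_trim", tr)]] <-
        list(positions = NULL, flank_trim = tr)
    }
    for (r in seq_len(config$n_random_position_sets)) {
      w <- anchors$end - anchors$start
      ps_seed <- derive_seed(cre_base, r)
      pos_sets[[paste0("random", r)]] <- list(
        positions = sample_anchor_positions(w, nchar(cre_seq), ps_seed),
        flank_trim = 0L, seed = ps_seed
      )
    }
    for (ps_name in names(pos_sets)) {
      ps <- pos_sets[[ps_name]]
      seqs <- vapply(backgrounds$seq, function(bg) {
        reconstitute(anchors, bg, positions = ps$positions,
                     flank_trim = ps$flank_trim)$seq
      }, character(1), USE.NAMES = FALSE)
      push(tibble(
        class = "reconstitution", cre_id = cre_id,
        background_id = backgrounds$id, position_set_id = ps_name,
        flank_trim = ps$flank_trim, n_breakpoints = NA_integer_,
        seed = ps$seed %||% NA_integer_, seq = seqs
      ))
    }

    # --- random deposition: seeds x designated backgrounds
    depo_bg <- backgrounds[seq_len(config$n_deposition_backgrounds), ]
    for (bi in seq_len(nrow(depo_bg))) {
      for (s in seq_len(config$n_deposition_seeds)) {
        dseed <- derive_seed(cre_base, 100000L + bi * 1000L + s)
        dep <- random_deposit(anchors, depo_bg$seq[bi], dseed)
        push(tibble(
          class = "deposition", cre_id = cre_id,
          background_id = depo_bg$id[bi],
          position_set_id = paste0("depo", s),
          flank_trim = 0L, n_breakpoints = NA_integer_,
          seed = dseed, seq = dep$seq
        ))
      }
    }

    # --- synthetic thripsis: breakage densities x seeds
    for (nb in config$thripsis_breakpoints) {
      for (s in seq_len(config$n_thripsis_seeds)) {
        tseed <- derive_seed(cre_base, 200000L + nb * 1000L + s)
        th <- thripsis(cre_seq, anchor_sets[[cre_id]], nb, tseed)
        push(tibble(
          class = "thripsis", cre_id = cre_id,
          background_id = NA_character_,
          position_set_id = NA_character_,
          flank_trim = NA_integer_, n_breakpoints = as.integer(nb),
          seed = tseed, seq = th$seq
        ))
      }
    }

    # --- wild type
    push(tibble(
      class = "wt", cre_id = cre_id, background_id = NA_character_,
      position_set_id = NA_character_, flank_trim = NA_integer_,
      n_breakpoints = NA_integer_, seed = NA_integer_, seq = cre_seq
    ))
  }

  # --- negative controls: the background panel plus extra shuffles
  n_bg <- nrow(backgrounds)
  push(tibble(
    class = "negative_control", cre_id = NA_character_,
    background_id = backgrounds$id, position_set_id = NA_character_,
    flank_trim = NA_integer_, n_breakpoints = NA_integer_,
    seed = NA_integer_, seq = backgrounds$seq
  ))
  n_extra <- config$n_negative - n_bg
  if (n_extra > 0) {
    extra <- vapply(seq_len(n_extra), function(i) {
      src <- (i - 1L) %% n_bg + 1L
      dinucleotide_shuffle(backgrounds$seq[src],
                           derive_seed(config$seed, 900000L + i))
    }, character(1))
    push(tibble(
      class = "negative_control", cre_id = NA_character_,
      background_id = paste0(backgrounds$id[((seq_len(n_extra) - 1L) %% n_bg) + 1L],
                             "_neg", seq_len(n_extra)),
      position_set_id = NA_character_, flank_trim = NA_integer_,
      n_breakpoints = NA_integer_,
      seed = vapply(seq_len(n_extra), function(i)
        derive_seed(config$seed, 900000L + i), integer(1)),
      seq = extra
    ))
  }

  out <- bind_rows(rows)
  out <- mutate(out, id = sprintf("d%05d", row_number()), .before = 1)
  counts <- out %>% group_by(.data$class, .data$cre_id) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  attr(out, "manifest") <- list(config = config, counts = counts,
                                n_backgrounds = n_bg)
  out
}

#' Fraction of variance explained by a grouping factor
#'
#' Between-group sum of squares over total sum of squares, the one-way
#' ANOVA eta-squared. Activities should be supplied on the log scale.
#'
#' @param data Data frame.
#' @param value Column of (log) activities (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return Scalar fraction in `[0, 1]`.
#' @export
variance_explained <- function(data, value, group) {
  v <- eval_tidy(enquo(value), data)
  g <- as.factor(eval_tidy(enquo(group), data))
  if (nlevels(droplevels(g)) < 2) abort("need at least two factor levels")
  if (any(table(g) < 2)) abort("need at least two observations per level")
  mu <- mean(v)
  means <- tapply(v, g, mean)
  ss_between <- sum(table(g) * (means - mu)^2)
  ss_total <- sum((v - mu)^2)
  if (ss_total == 0) return(0)
  unname(ss_between / ss_total)
}

#' Quantile rank of the wild-type position set among randomized sets
#'
#' Fraction of randomized-position activities strictly below the wild-type
#' activity, counting ties as half (mid-rank).
#'
#' @param wt_activity Scalar wild-type-position activity.
#' @param random_activities Activities of at least 10 randomized position
#'   sets.
#' @return Quantile in `[0, 1]`.
#' @export
wt_position_rank <- function(wt_activity, random_activities) {
  if (length(random_activities) < 10) abort("need at least 10 random activities")
  (sum(random_activities < wt_activity) +
     0.5 * sum(random_activities == wt_activity)) / length(random_activities)
}

#' Audit anchor integrity of derivative designs
#'
#' Checks that every anchor substring occurs intact (in its recorded native
#' orientation) in each derived sequence.
#'
#' @param designs Design tibble with `cre_id` and `seq` (classes based on a
#'   CRE).
#' @param anchor_sets Named list of anchor sets.
#' @param cres CRE tibble (`id`, `seq`).
#' @return `designs` with a logical `anchors_intact` column.
#' @export
audit_anchor_integrity <- function(designs, anchor_sets, cres) {
  per_cre <- lapply(setNames(cres$id, cres$id), function(cid) {
    anchor_seqs(anchor_sets[[cid]], cres$seq[cres$id == cid])$seq
  })
  trims <- designs$flank_trim
  trims[is.na(trims)] <- 0L
  ok <- purrr::pmap_lgl(
    list(designs$cre_id, designs$seq, trims),
    function(cid, s, tr) {
      if (is.na(cid)) return(NA)
      a <- per_cre[[cid]]
      # designs built from trimmed anchors must contain the trimmed substrings
      if (tr > 0) a <- substr(a, tr + 1, nchar(a) - tr)
      all(vapply(a, function(x) grepl(x, s, fixed = TRUE), logical(1)))
    }
  )
  mutate(designs, anchors_intact = ok)
}
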