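#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are uppercased on ingest. Records with duplicate ids, empty
#' sequences, or characters outside A/C/G/T (including IUPAC ambiguity codes
#' and N) are rejected with an informative error: every sequence handled by
#' this package is a fully specified designed or assayed DNA molecule.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence for id: ", ids[nchar(seqs) == 0][1]))
  }
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    abort(paste0("non-ACGT characters in sequence '", ids[bad][1],
                 "'; ambiguity codes are not supported"))
  }
  tibble(id = unname(ids), seq = unname(seqs), length = unname(nchar(seqs)))
}

#' Write sequence records to FASTA
#'
#' @param records Data frame with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a BED6 file of intervals
#'
#' BED uses 0-based half-open coordinates, which is also the package-wide
#' internal convention, so no coordinate shift is applied anywhere.
#'
#' @param path Path to a BED file (3-6 columns, no header).
#' @return A tibble with columns `seq_id`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("seq_id", "start", "end", "name", "score", "strand")
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  names(df) <- cols[seq_len(ncol(df))]
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "+"
  validate_intervals(df)
  as_tibble(df[cols])
}

#' Write intervals to BED6
#'
#' @param intervals Data frame with at least `seq_id`, `start`, `end`;
#'   optional `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  df <- tibble(
    seq_id = intervals$seq_id,
    start = intervals$start,
    end = intervals$end,
    name = intervals$name %||% ".",
    score = intervals$score %||% 0,
    strand = intervals$strand %||% "+"
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# Shared interval sanity checks (0-based half-open).
validate_intervals <- function(df, parent_length = NULL) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(df)))
  if (any(df$start < 0)) abort("interval start must be >= 0")
  if (any(df$end <= df$start)) abort("interval end must exceed start (half-open)")
  if (!is.null(parent_length) && any(df$end > parent_length)) {
    abort("interval end exceeds parent sequence length")
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  invisible(df)
}

#' Extract interval sequences from parent records
#'
#' Minus-strand intervals are returned reverse-complemented, matching how a
#' fragment cloned in the reverse orientation presents to the promoter.
#'
#' @param intervals Interval tibble (`seq_id`, `start`, `end`, `strand`).
#' @param records Sequence record tibble from [read_fasta()].
#' @return `intervals` with a `seq` column added.
#' @export
extract_sequences <- function(intervals, records) {
  validate_intervals(intervals)
  idx <- match(intervals$seq_id, records$id)
  if (anyNA(idx)) abort("interval seq_id not found among records")
  parent <- records$seq[idx]
  if (any(intervals$end > nchar(parent))) {
    abort("interval end exceeds parent sequence length")
  }
  out <- substr(parent, intervals$start + 1, intervals$end)
  strand <- intervals$strand %||% rep("+", nrow(intervals))
  flip <- strand == "-"
  if (any(flip)) out[flip] <- revcomp(out[flip])
  dplyr::mutate(as_tibble(intervals), seq = out)
}

#' Read / write a barcode dictionary
#'
#' Dictionary TSVs have columns `barcode`, `element_id`, `variants`
#' (semicolon-joined `pos:alt` tokens, empty for unmutagenized inserts),
#' `reads`, `frac_element`, `frac_variant`.
#'
#' @param path File path.
#' @return A barcode dictionary tibble.
#' @export
read_barcode_dict <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          barcode = "c", element_id = "c", variants = "c",
                          reads = "d", frac_element = "d", frac_variant = "d"
                        ))
  df$variants[is.na(df$variants)] <- ""
  as_tibble(df)
}

#' @rdname read_barcode_dict
#' @param dict Barcode dictionary tibble.
#' @export
write_barcode_dict <- function(dict, path) {
  readr::write_tsv(dict, path, progress = FALSE)
  invisible(path)
}

#' Read / write a per-barcode UMI count table
#'
#' Count TSVs have columns `barcode`, `replicate`, `rna_umi`, `dna_umi`.
#'
#' @param path File path.
#' @return A count tibble.
#' @export
read_count_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          barcode = "c", replicate = "c",
                          rna_umi = "i", dna_umi = "i"
                        ))
  if (any(df$rna_umi < 0 | df$dna_umi < 0)) abort("UMI counts must be non-negative")
  as_tibble(df)
}

#' @rdname read_count_table
#' @param counts Count tibble.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}
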