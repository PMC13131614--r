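# Shared fixtures: all built in code, no files.

# A sharply specific binding model whose consensus is given explicitly;
# off-consensus bases carry a small common multiplier.
toy_model <- function(tf = "tfA", consensus = "ACGTAC", off = 0.05,
                      norm_constant = NULL) {
  b <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  w <- matrix(off, length(b), 4)
  w[cbind(seq_along(b), b)] <- 1
  binding_model(tf, w, norm_constant)
}

# A second model with a different consensus, for multi-TF scenarios.
toy_model_b <- function() toy_model("tfB", "TGACTC", off = 0.07)

# Palindromic model: the consensus GGATCC is its own reverse complement.
palindromic_model <- function() toy_model("pal", "GGATCC", off = 0.1)

# Independent brute-force scanner used as an oracle: scores every k-mer of
# both orientations by direct substring arithmetic, sharing no code with
# scan_affinity().
brute_scan <- function(seq, model) {
  k <- model$k
  W <- model$weights
  score_kmer <- function(km) {
    b <- strsplit(km, "")[[1]]
    prod(vapply(seq_len(k), function(j) W[j, b[j]], numeric(1)))
  }
  n <- nchar(seq) - k + 1
  vapply(seq_len(n), function(i) {
    km <- substr(seq, i, i + k - 1)
    max(score_kmer(km), score_kmer(revcomp(km))) / model$norm_constant
  }, numeric(1))
}

# Deterministic count table where estimated activities equal the supplied
# per-barcode activity exactly: DNA constant, RNA = DNA * activity * scale.
exact_counts <- function(barcodes, activities, replicates = c("rep1", "rep2"),
                         dna = 1000L) {
  dplyr::bind_rows(lapply(replicates, function(r) {
    tibble::tibble(barcode = barcodes, replicate = r,
                   rna_umi = as.integer(round(dna * activities)),
                   dna_umi = dna)
  }))
}

variant_position_of <- function(v) as.integer(sub(":.*$", "", v))

# All permutations of a short vector (duplicates allowed; callers unique()).
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}

simple_dict <- function(barcodes, element_ids, variants = "") {
  tibble::tibble(
    barcode = barcodes, element_id = element_ids,
    variants = rep(variants, length.out = length(barcodes)),
    reads = 100, frac_element = 1, frac_variant = 1
  )
}
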