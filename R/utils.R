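DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a temporary, isolated RNG seed
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that results are reproducible given a seed and the caller's
#' RNG state is never disturbed.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a parent seed and an index, staying inside the
# signed 32-bit range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((abs(as.double(seed)) * 48271 + as.double(index) * 16807) %% 2147483647)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Integer encoding A=1, C=2, G=3, T=4 used by the affinity scanner.
seq_to_int <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
}

int_to_seq <- function(x) {
  paste(DNA_BASES[x], collapse = "")
}

# Complement in integer encoding (A<->T, C<->G).
int_complement <- function(x) 5L - x

#' Geometric mean
#'
#' Zeros propagate to zero (an element with no RNA signal in one replicate has
#' zero cross-replicate activity rather than an undefined one).
#' @param x Non-negative numeric vector.
#' @param na.rm Drop missing values first.
#' @return Scalar geometric mean.
#' @export
geometric_mean <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (any(x < 0)) abort("geometric_mean() requires non-negative values")
  if (any(x == 0)) return(0)
  exp(mean(log(x)))
}

#' Two-sided winsorization by quantiles
#'
#' Clips `x` at its empirical `frac` and `1 - frac` quantiles. With
#' `frac = 0` the input is returned unchanged.
#' @param x Numeric vector.
#' @param frac Clipping fraction in `[0, 0.5)`.
#' @return Clipped numeric vector.
#' @export
winsorize <- function(x, frac = 0.01) {
  stopifnot(frac >= 0, frac < 0.5)
  if (frac == 0 || length(x) < 2) return(x)
  q <- quantile(x, c(frac, 1 - frac), names = FALSE, type = 7)
  pmin(pmax(x, q[1]), q[2])
}

# Random DNA of a given length (optionally GC-biased); vectorized over n.
random_dna <- function(n, length, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(
    seq_len(n),
    function(i) paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = ""),
    character(1)
  )
}

# Dinucleotide transition counts of a sequence as a 4x4 matrix.
dinucleotide_counts <- function(s) {
  x <- seq_to_int(s)
  n <- length(x)
  m <- matrix(0L, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  if (n < 2) return(m)
  idx <- cbind(x[-n], x[-1])
  for (i in seq_len(nrow(idx))) m[idx[i, 1], idx[i, 2]] <- m[idx[i, 1], idx[i, 2]] + 1L
  m
}
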