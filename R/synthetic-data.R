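#' Synthetic MPRA generator configuration
#'
#' Defaults emulate the barcode-count structure of a deeply sequenced
#' episomal MPRA: a median of 492 barcodes per element, saturation
#' mutagenesis inserts carrying one programmed mutation plus a
#' Poisson(1.3) number of additional PCR-induced mutations (about 20% of
#' them 1-bp deletions), two or more transfection replicates, log-normal
#' per-barcode DNA abundances, and negative-binomial UMI noise (the
#' overdispersion real libraries show over Poisson). Activity is
#' multiplicative across a barcode's mutations under the default model,
#' matching the multiplicative null used for epistasis.
#'
#' @param seed Master seed.
#' @param barcodes_per_element Barcode depth per plain element.
#' @param barcodes_per_variant Barcode depth per programmed variant.
#' @param wt_barcodes Barcodes of the co-assayed unmutagenized element.
#' @param poisson_lambda Mean of the extra-mutation Poisson (default 1.3).
#' @param deletion_frac Fraction of extra mutations that are deletions.
#' @param replicates Number of replicates (default 2).
#' @param dna_mean Mean DNA UMI count per barcode.
#' @param rna_per_dna RNA UMIs per DNA UMI at unit activity.
#' @param abundance_sdlog Log-sd of per-barcode abundances.
#' @param dna_size,rna_size Negative-binomial size (inverse-dispersion)
#'   parameters; the `preset` scales depth for shallow/deep libraries.
#' @param wt_activity Ground-truth wild-type activity (8x over basal, mid
#'   of the observed 2-36x range).
#' @param minP_baseline Basal minP-only activity (activity unit).
#' @param site_within_sd Log2-sd of per-substitution effects around their
#'   site's effect.
#' @param nonsite_lfc_mean,nonsite_lfc_sd Log2 effect distribution of
#'   mutations outside planted sites (slightly LoF-biased by default:
#'   most positions of a strong developmental enhancer are
#'   mutation-sensitive).
#' @param activity_model Ground-truth activity model label
#'   (`additive_affinity`, `thresholded_synergy`, `distance_decay`).
#' @param preset Depth preset: `"shallow"`, `"default"` or `"deep"`.
#' @return Named list of generator settings.
#' @export
generator_config <- function(seed = 1,
                             barcodes_per_element = 492L,
                             barcodes_per_variant = 100L,
                             wt_barcodes = 500L,
                             poisson_lambda = 1.3,
                             deletion_frac = 0.2,
                             replicates = 2L,
                             dna_mean = 50,
                             rna_per_dna = 1,
                             abundance_sdlog = 1,
                             dna_size = 10,
                             rna_size = 4,
                             wt_activity = 8,
                             minP_baseline = 1,
                             site_within_sd = 0.2,
                             nonsite_lfc_mean = -0.1,
                             nonsite_lfc_sd = 0.4,
                             activity_model = "additive_affinity",
                             preset = "default") {
  cfg <- as.list(environment())
  stopifnot(poisson_lambda >= 0, dna_size > 0, rna_size > 0)
  depth_scale <- switch(preset, shallow = 0.2, default = 1, deep = 5,
                        abort("preset must be shallow, default or deep"))
  cfg$dna_mean <- cfg$dna_mean * depth_scale
  cfg
}

#' Generate a synthetic CRE with planted TFBSs and recorded ground truth
#'
#' A random background sequence with `n_sites` model-consensus motifs
#' planted at non-overlapping random positions (random orientation). The
#' ground truth records the planted sites, a disruption-effect multiplier
#' per site, and a log2 effect for every possible substitution and 1-bp
#' deletion: mutations inside a planted site carry the site effect (plus
#' `site_within_sd` jitter), mutations elsewhere draw from the non-site
#' effect distribution.
#'
#' @param length CRE length (default 300).
#' @param models List of [binding_model()]s to plant (cycled over sites).
#' @param n_sites Number of planted sites.
#' @param seed Integer seed.
#' @param config [generator_config()].
#' @param site_effects Disruption multipliers per site (default drawn
#'   uniformly from 0.1-0.5: disrupting a site keeps 10-50% of activity).
#' @return List with `record` (tibble `id`, `seq`, `length`) and `truth`
#'   (list: `sites`, `wt_activity`, `minP`, `variant_lfc` named vector,
#'   `site_effects`).
#' @export
generate_cre <- function(length = 300L, models, n_sites = 8L, seed = 1,
                         config = generator_config(),
                         site_effects = NULL) {
  ks <- vapply(models, function(m) m$k, integer(1))
  widths <- ks[((seq_len(n_sites) - 1L) %% length(models)) + 1L]
  if (n_sites > 0 && sum(widths) >= length) abort("sites do not fit in the CRE")
  with_seed(seed, {
    bg <- random_dna(1, length)
    s <- bg
    sites <- tibble(tf = character(0), start = integer(0), end = integer(0),
                    strand = character(0), effect = numeric(0))
    if (n_sites > 0) {
      starts <- sample_anchor_positions(widths, length, derive_seed(seed, 17L))
      if (is.null(site_effects)) site_effects <- runif(n_sites, 0.1, 0.5)
      stopifnot(length(site_effects) == n_sites)
      strands <- sample(c("+", "-"), n_sites, replace = TRUE)
      for (i in seq_len(n_sites)) {
        m <- models[[((i - 1L) %% length(models)) + 1L]]
        motif <- model_consensus(m)
        if (strands[i] == "-") motif <- revcomp(motif)
        substr(s, starts[i] + 1L, starts[i] + m$k) <- motif
        sites <- bind_rows(sites, tibble(
          tf = m$tf_name, start = starts[i], end = starts[i] + m$k,
          strand = strands[i], effect = site_effects[i]
        ))
      }
    }
    # Ground-truth log2 effect for every possible point mutation.
    x <- seq_to_int(s)
    alts <- c(DNA_BASES, "del")
    grid <- tidyr::expand_grid(position = 0:(length - 1L), alt = alts)
    ref <- DNA_BASES[x[grid$position + 1L]]
    grid <- grid[grid$alt != ref, ]
    in_site <- rep(NA_integer_, nrow(grid))
    if (nrow(sites) > 0) {
      for (i in seq_len(nrow(sites))) {
        hit <- grid$position >= sites$start[i] & grid$position < sites$end[i]
        in_site[hit] <- i
      }
    }
    lfc <- ifelse(
      is.na(in_site),
      rnorm(nrow(grid), config$nonsite_lfc_mean, config$nonsite_lfc_sd),
      log2(sites$effect[ifelse(is.na(in_site), 1L, in_site)]) +
        rnorm(nrow(grid), 0, config$site_within_sd)
    )
    variant_lfc <- setNames(lfc, paste0(grid$position, ":", grid$alt))
    list(
      record = tibble(id = paste0("cre_", seed), seq = s, length = length),
      truth = list(
        sites = sites,
        wt_activity = config$wt_activity,
        minP = config$minP_baseline,
        variant_lfc = variant_lfc,
        site_effects = sites$effect
      )
    )
  })
}

# Draw per-barcode extra mutations: Poisson(lambda) count, each a uniform
# substitution (or deletion with prob deletion_frac) distinct from the
# programmed mutation and from one another.
sample_extra_mutations <- function(n_extra, L, ref_bases, deletion_frac) {
  if (n_extra == 0) return(character(0))
  pos <- sample.int(L, n_extra, replace = TRUE) - 1L
  is_del <- runif(n_extra) < deletion_frac
  alt <- character(n_extra)
  alt[is_del] <- "del"
  if (any(!is_del)) {
    alt[!is_del] <- vapply(pos[!is_del], function(p) {
      sample(setdiff(DNA_BASES, ref_bases[p + 1L]), 1L)
    }, character(1))
  }
  paste0(pos, ":", alt)
}

#' Generate a saturation-mutagenesis barcode dictionary
#'
#' Every possible single-base substitution of the CRE is represented as a
#' programmed mutation; each barcode carries its programmed mutation plus
#' a Poisson(`poisson_lambda`) number of additional uniform-random
#' mutations (substitutions and 1-bp deletions), emulating the extra
#' mutation load PCR mutagenesis superimposes during cloning. With the
#' default rate of 1.3 the mean total mutation count per insert is 2.3.
#' Unmutagenized wild-type barcodes are appended for use as the reference
#' set.
#'
#' @param cre Output of [generate_cre()] (or a one-row tibble with `seq`).
#' @param config [generator_config()].
#' @param n_barcodes Optional total number of variant barcodes; overrides
#'   `config$barcodes_per_variant` (each programmed variant is represented
#'   at least once, the remainder assigned uniformly).
#' @param seed Integer seed (default `config$seed`).
#' @param include_wt Append `config$wt_barcodes` wild-type barcodes.
#' @return A barcode dictionary tibble (see [read_barcode_dict()]).
#' @export
generate_satmut_dictionary <- function(cre, config = generator_config(),
                                       n_barcodes = NULL,
                                       seed = config$seed,
                                       include_wt = TRUE) {
  s <- if (is.list(cre) && !is.data.frame(cre)) cre$record$seq[[1]] else cre$seq[[1]]
  L <- nchar(s)
  ref <- strsplit(s, "")[[1]]
  programmed <- unlist(lapply(0:(L - 1L), function(p) {
    paste0(p, ":", setdiff(DNA_BASES, ref[p + 1L]))
  }))
  with_seed(seed, {
    n_var <- length(programmed)
    if (is.null(n_barcodes)) {
      per_var <- pmax(1L, rpois(n_var, config$barcodes_per_variant))
    } else {
      stopifnot(n_barcodes >= n_var)
      extra <- tabulate(sample.int(n_var, n_barcodes - n_var, replace = TRUE),
                        nbins = n_var)
      per_var <- 1L + extra
    }
    prog_of_bc <- rep(programmed, per_var)
    n_bc <- length(prog_of_bc)
    n_extras <- rpois(n_bc, config$poisson_lambda)
    variants <- vapply(seq_len(n_bc), function(i) {
      ex <- sample_extra_mutations(n_extras[i], L, ref, config$deletion_frac)
      paste(unique(c(prog_of_bc[i], ex)), collapse = ";")
    }, character(1))
    element_id <- if (is.list(cre) && !is.data.frame(cre))
      cre$record$id[[1]] else (cre$id[[1]] %||% "cre")
    dict <- tibble(
      barcode = sprintf("bc%07d", seq_len(n_bc)),
      element_id = element_id,
      variants = variants,
      reads = pmax(1, rnbinom(n_bc, mu = 60, size = 5)),
      frac_element = 1 - runif(n_bc, 0, 0.03),
      frac_variant = 1 - runif(n_bc, 0, 0.05)
    )
    if (include_wt && config$wt_barcodes > 0) {
      dict <- bind_rows(dict, tibble(
        barcode = sprintf("wtbc%06d", seq_len(config$wt_barcodes)),
        element_id = "wt",
        variants = "",
        reads = pmax(1, rnbinom(config$wt_barcodes, mu = 60, size = 5)),
        frac_element = 1 - runif(config$wt_barcodes, 0, 0.03),
        frac_variant = 1
      ))
    }
    dict
  })
}

#' Generate a barcode dictionary for plain (unmutagenized) elements
#'
#' @param element_ids Character vector of element ids.
#' @param config [generator_config()].
#' @param n_barcodes Barcodes per element (default
#'   `config$barcodes_per_element`, the median depth a deeply cloned
#'   library reaches).
#' @param seed Integer seed.
#' @return A barcode dictionary tibble with empty variant sets.
#' @export
generate_element_dictionary <- function(element_ids,
                                        config = generator_config(),
                                        n_barcodes = config$barcodes_per_element,
                                        seed = config$seed) {
  n_barcodes <- rep(n_barcodes, length.out = length(element_ids))
  with_seed(seed, {
    n <- sum(n_barcodes)
    tibble(
      barcode = sprintf("bc%07d", seq_len(n)),
      element_id = rep(element_ids, n_barcodes),
      variants = "",
      reads = pmax(1, rnbinom(n, mu = 60, size = 5)),
      frac_element = 1 - runif(n, 0, 0.03),
      frac_variant = 1
    )
  })
}

#' Generate RNA/DNA UMI count tables from a dictionary and ground truth
#'
#' Per barcode and replicate: DNA UMIs are negative-binomial around a
#' log-normal barcode abundance; RNA UMIs are negative-binomial with mean
#' proportional to abundance times the barcode's ground-truth activity.
#' A barcode's activity is the element's base activity times the product
#' of the effects of all mutations it carries (multiplicative composite
#' genotypes); planted epistasis can be injected via
#' `truth$interaction_fn`, a hook receiving the variant set and returning
#' an extra multiplier.
#'
#' @param dict Barcode dictionary.
#' @param truth Truth list from [generate_cre()], optionally extended with
#'   `element_activities` (named vector of base activities per
#'   element_id; elements absent default to `wt_activity`, the element
#'   `"minP"` to the basal activity).
#' @param config [generator_config()].
#' @param seed Integer seed.
#' @return A count tibble (`barcode`, `replicate`, `rna_umi`, `dna_umi`).
#' @export
generate_counts <- function(dict, truth, config = generator_config(),
                            seed = config$seed) {
  base_act <- rep(truth$wt_activity %||% 1, nrow(dict))
  ea <- truth$element_activities
  if (!is.null(ea)) {
    hit <- dict$element_id %in% names(ea)
    base_act[hit] <- ea[dict$element_id[hit]]
  }
  base_act[dict$element_id == "minP"] <- truth$minP %||% config$minP_baseline
  lfc <- rep(0, nrow(dict))
  has_var <- !is.na(dict$variants) & dict$variants != ""
  if (any(has_var) && !is.null(truth$variant_lfc)) {
    vl <- truth$variant_lfc
    lfc[has_var] <- vapply(strsplit(dict$variants[has_var], ";", fixed = TRUE),
                           function(vs) {
                             e <- vl[vs]
                             sum(e, na.rm = TRUE)
                           }, numeric(1))
  }
  act <- base_act * 2^lfc
  if (!is.null(truth$interaction_fn)) {
    act <- act * vapply(strsplit(dict$variants, ";", fixed = TRUE),
                        truth$interaction_fn, numeric(1))
  }
  n <- nrow(dict)
  reps <- paste0("rep", seq_len(config$replicates))
  with_seed(seed, {
    abundance <- rlnorm(n, meanlog = log(config$dna_mean) -
                          config$abundance_sdlog^2 / 2,
                        sdlog = config$abundance_sdlog)
    bind_rows(lapply(reps, function(r) {
      tibble(
        barcode = dict$barcode,
        replicate = r,
        rna_umi = rnbinom(n, mu = abundance * act * config$rna_per_dna,
                          size = config$rna_size),
        dna_umi = rnbinom(n, mu = abundance, size = config$dna_size)
      )
    }))
  })
}

#' Maximum-likelihood estimate of the extra-mutation Poisson rate
#'
#' For a Poisson count the MLE of the rate is the sample mean; the extra
#' (non-programmed) mutation count of a saturation-mutagenesis insert is
#' its total mutation count minus one.
#'
#' @param dict Barcode dictionary (wild-type rows are ignored).
#' @return One-row tibble: `mean_mutations` (per insert), `lambda_hat`,
#'   `n_inserts`.
#' @export
estimate_mutation_load <- function(dict) {
  has <- !is.na(dict$variants) & dict$variants != ""
  counts <- lengths(strsplit(dict$variants[has], ";", fixed = TRUE))
  tibble(
    mean_mutations = mean(counts),
    lambda_hat = mean(counts - 1L),
    n_inserts = length(counts)
  )
}
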