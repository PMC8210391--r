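#' Configuration for the synthetic two-class sequence generator
#'
#' The generator emulates the shape of a curated secretion training set —
#' two balanced classes of protein-like sequences with a tunable amount of
#' compositional signal — so that every pipeline stage can be exercised
#' without downloading real data. It does not emulate real exosome cargo
#' biology (motifs, domains, homology structure).
#'
#' Two signal modes:
#' \describe{
#'   \item{`aa_bias`}{classes draw residues i.i.d. from two distributions
#'     obtained by mixing a Dirichlet-drawn base distribution with
#'     class-specific preferred alphabets (first vs last ten residues);
#'     the total-variation distance between the class distributions equals
#'     `bias_strength` (0 = identical, 1 = disjoint alphabets).}
#'   \item{`dipeptide_bias`}{classes are first-order Markov chains with the
#'     same uniform stationary distribution but different transition
#'     structure (mixtures of the uniform kernel with class-specific
#'     residue-cycle permutations), so single-residue composition carries no
#'     class signal while dipeptide composition does.}
#' }
#'
#' @param n_pos,n_neg Class sizes.
#' @param length_range Integer interval of sequence lengths; minimum 30 so
#'   dipeptide vectors are well populated. Default 50-400, roughly
#'   protein-like.
#' @param bias_strength Signal strength in \[0, 1\].
#' @param signal_mode `"aa_bias"` or `"dipeptide_bias"`.
#' @param annotation_noise Fraction of records flagged with a disqualifying
#'   annotation (signal peptide, transmembrane region, or non-vertebrate),
#'   assigned at random.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list of class `exocargo_synth_config`.
#' @export
synthetic_config <- function(n_pos = 200, n_neg = 200,
                             length_range = c(50, 400), bias_strength = 0.5,
                             signal_mode = c("aa_bias", "dipeptide_bias"),
                             annotation_noise = 0, seed = 1) {
  signal_mode <- match.arg(signal_mode)
  if (n_pos < 1 || n_neg < 1) abort("n_pos and n_neg must be >= 1")
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 30) {
    abort("length_range must be an increasing interval with minimum >= 30")
  }
  if (bias_strength < 0 || bias_strength > 1) abort("bias_strength must be in [0, 1]")
  if (annotation_noise < 0 || annotation_noise > 1) {
    abort("annotation_noise must be in [0, 1]")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 bias_strength = bias_strength, signal_mode = signal_mode,
                 annotation_noise = annotation_noise, seed = as.integer(seed)),
            class = "exocargo_synth_config")
}

#' Generate a labeled synthetic dataset with annotations
#'
#' @param config `exocargo_synth_config` from [synthetic_config()].
#' @return List with `records` (tibble `id`, `description`, `sequence`,
#'   `label`) and `annotations` (annotation tibble in the
#'   [read_annotations()] layout).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  if (!inherits(config, "exocargo_synth_config")) {
    abort("config must come from synthetic_config()")
  }
  withr_seed(config$seed, {
    if (config$signal_mode == "aa_bias") {
      base <- rdirichlet1(rep(10, 20))
      pref_pos <- c(rep(0.1, 10), rep(0, 10))
      pref_neg <- c(rep(0, 10), rep(0.1, 10))
      b <- config$bias_strength
      p_pos <- (1 - b) * base + b * pref_pos
      p_neg <- (1 - b) * base + b * pref_neg
      draw <- function(n, positive) {
        p <- if (positive) p_pos else p_neg
        paste(sample(AA_ALPHABET, n, replace = TRUE, prob = p), collapse = "")
      }
    } else {
      t_pos <- markov_kernel(config$bias_strength, shift = 1L)
      t_neg <- markov_kernel(config$bias_strength, shift = 3L)
      draw <- function(n, positive) {
        tm <- if (positive) t_pos else t_neg
        idx <- integer(n)
        idx[1] <- sample.int(20, 1)
        for (k in 2:n) idx[k] <- sample.int(20, 1, prob = tm[idx[k - 1], ])
        paste(AA_ALPHABET[idx], collapse = "")
      }
    }
    n_tot <- config$n_pos + config$n_neg
    lens <- sample(seq(config$length_range[1], config$length_range[2]),
                   n_tot, replace = TRUE)
    positive <- c(rep(TRUE, config$n_pos), rep(FALSE, config$n_neg))
    seqs <- vapply(seq_len(n_tot), function(i) draw(lens[i], positive[i]), "")
    records <- tibble(
      id = sprintf("%s_%04d", ifelse(positive, "pos", "neg"),
                   c(seq_len(config$n_pos), seq_len(config$n_neg))),
      description = ifelse(positive, "synthetic exosome-class",
                           "synthetic non-exosome-class"),
      sequence = seqs,
      label = ifelse(positive, "positive", "negative")
    )

    n_noise <- round(config$annotation_noise * n_tot)
    noisy <- sample.int(n_tot, n_noise)
    flag_kind <- sample(c("sp", "tm", "nonvert"), n_noise, replace = TRUE)
    is_vert <- rep(TRUE, n_tot)
    has_sp <- rep(FALSE, n_tot); has_tm <- rep(FALSE, n_tot)
    is_vert[noisy[flag_kind == "nonvert"]] <- FALSE
    has_sp[noisy[flag_kind == "sp"]] <- TRUE
    has_tm[noisy[flag_kind == "tm"]] <- TRUE
    loc_pool <- c("nucleus", "cytosol", "ER", "GA", "mitochondrion", "other")
    n_loc <- sample(0:2, n_tot, replace = TRUE, prob = c(0.15, 0.6, 0.25))
    annotations <- tibble(
      id = records$id,
      is_vertebrate = is_vert,
      has_signal_peptide = has_sp,
      has_transmembrane = has_tm,
      locations = lapply(n_loc, function(k) sample(loc_pool, k)),
      uniprot_id = sprintf("SYN%05d", seq_len(n_tot))
    )
    list(records = records, annotations = annotations)
  })
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Mixture of the uniform kernel with a residue-cycle permutation; stationary
# distribution is uniform for any mixing weight, so marginal composition is
# class-independent while transitions are not.
markov_kernel <- function(bias, shift) {
  uniform <- matrix(1 / 20, 20, 20)
  cycle <- matrix(0, 20, 20)
  for (i in 1:20) cycle[i, ((i - 1L + shift) %% 20L) + 1L] <- 1
  (1 - bias) * uniform + bias * cycle
}

#' Tiny hand-checkable sequences with golden feature vectors
#'
#' A fixed set of micro-sequences whose amino-acid and dipeptide
#' compositions can be verified by eye; the expected non-zero components
#' are embedded as golden data. Used as ground truth for the feature
#' encoders and the feature TSV round-trip.
#'
#' @return Tibble `id`, `sequence`, `aa_golden` (list of named non-zero
#'   expected amino-acid components), `dp_golden` (same for dipeptides;
#'   `NULL` where the sequence is too short).
#' @export
worked_example_set <- function() {
  tibble(
    id = c("ex_homo4", "ex_homo3", "ex_alt", "ex_uniform", "ex_pair", "ex_av",
           "ex_single"),
    sequence = c("AAAA", "AAA", "ACAC", "ACDEFGHIKLMNPQRSTVWY", "AC", "AV", "W"),
    aa_golden = list(
      c(AA_A = 1),
      c(AA_A = 1),
      c(AA_A = 0.5, AA_C = 0.5),
      setNames(rep(0.05, 20), paste0("AA_", AA_ALPHABET)),
      c(AA_A = 0.5, AA_C = 0.5),
      c(AA_A = 0.5, AA_V = 0.5),
      c(AA_W = 1)
    ),
    dp_golden = list(
      c(DP_AA = 1),
      c(DP_AA = 1),
      c(DP_AC = 2 / 3, DP_CA = 1 / 3),
      setNames(rep(1 / 19, 19),
               paste0("DP_", paste0(AA_ALPHABET[-20], AA_ALPHABET[-1]))),
      c(DP_AC = 1),
      c(DP_AV = 1),
      NULL
    )
  )
}
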