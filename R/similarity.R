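#' Global-alignment percent identity between two sequences
#'
#' Needleman-Wunsch global alignment (terminal gaps penalized) with affine
#' gap costs: a gap of length L costs `gap_open + gap_extend * L`, the
#' convention of the EMBOSS needle tool whose defaults (BLOSUM62, 10, 0.5)
#' are adopted here. Identity is the percentage of identical aligned columns
#' over the full alignment length, gap columns included.
#'
#' @param a,b Sequences: either plain strings or one-row record tibbles with
#'   `id` and `sequence`.
#' @param gap_open,gap_extend Affine gap parameters.
#' @param matrix_name Substitution matrix name understood by Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @return One-row tibble: `query_id`, `subject_id`, `identity_percent`,
#'   `aligned_length`, `score`.
#' @export
#' @examples
#' global_identity("PAWHEAE", "HEAGAWGHEE")
global_identity <- function(a, b, gap_open = 10, gap_extend = 0.5,
                            matrix_name = "BLOSUM62") {
  qa <- as_seq(a, "a"); qb <- as_seq(b, "b")
  aln <- tryCatch(
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(qa$sequence), Biostrings::AAString(qb$sequence),
      substitutionMatrix = matrix_name,
      gapOpening = gap_open, gapExtension = gap_extend, type = "global"),
    error = function(e) abort(paste0("alignment failed: ", conditionMessage(e))))
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  tibble(
    query_id = qa$id, subject_id = qb$id,
    identity_percent = 100 * sum(p == s & p != "-") / length(p),
    aligned_length = length(p),
    score = Biostrings::score(aln)
  )
}

as_seq <- function(x, what) {
  if (is.character(x) && length(x) == 1) {
    if (!nzchar(x)) abort(paste0("sequence '", what, "' is empty"))
    return(list(id = what, sequence = x))
  }
  if (is.data.frame(x) && nrow(x) == 1) {
    if (!nzchar(x$sequence)) abort(paste0("sequence '", x$id, "' is empty"))
    return(list(id = x$id, sequence = x$sequence))
  }
  abort("expected a single sequence string or a one-row record tibble")
}

#' Identity statistics over a dataset
#'
#' Aligns sequences pairwise (never with themselves) and summarises percent
#' identity. Within one set all ordered non-self pairs are counted, so a set
#' of N sequences yields N*(N-1) alignments; identity is symmetric, so each
#' unordered pair is aligned once and counted twice. Between two subsets all
#' |A| x |B| cross pairs are used.
#'
#' Full summaries are quadratic in N; above `max_n` sequences an explicit
#' `allow_large = TRUE` or a seeded `sample_pairs` is required.
#'
#' @param records Record tibble.
#' @param subset_a,subset_b Optional id vectors. With only `subset_a`, the
#'   summary is within that subset; with both, between the two.
#' @param sample_pairs If non-`NULL`, summarise this many uniformly sampled
#'   pairs instead of all pairs (requires `seed`).
#' @param seed Seed for pair sampling.
#' @param max_n Guard on full enumeration.
#' @param allow_large Set `TRUE` to force full enumeration past `max_n`.
#' @inheritParams global_identity
#' @return One-row tibble: `n_sequences`, `n_alignments`, `mean_identity`,
#'   `sd_identity`, plus a `histogram` list column (5-point identity bins)
#'   and the per-pair identities in attribute `identities`.
#' @export
dataset_identity_summary <- function(records, subset_a = NULL, subset_b = NULL,
                                     sample_pairs = NULL, seed = 1,
                                     max_n = 2000, allow_large = FALSE,
                                     gap_open = 10, gap_extend = 0.5,
                                     matrix_name = "BLOSUM62") {
  between <- !is.null(subset_b)
  if (!is.null(subset_a)) {
    a_rec <- records[records$id %in% subset_a, , drop = FALSE]
  } else {
    a_rec <- records
  }
  if (between) {
    b_rec <- records[records$id %in% subset_b, , drop = FALSE]
    if (nrow(a_rec) == 0 || nrow(b_rec) == 0) abort("empty subset")
    pairs <- expand.grid(i = seq_len(nrow(a_rec)), j = seq_len(nrow(b_rec)))
    n_seq <- nrow(a_rec) + nrow(b_rec)
    n_aln <- nrow(pairs)
  } else {
    if (nrow(a_rec) < 2) abort("need at least 2 sequences to summarise identity")
    pairs <- t(utils::combn(nrow(a_rec), 2))
    pairs <- data.frame(i = pairs[, 1], j = pairs[, 2])
    b_rec <- a_rec
    n_seq <- nrow(a_rec)
    n_aln <- n_seq * (n_seq - 1)
  }
  if (!is.null(sample_pairs)) {
    withr_seed(seed, {
      pairs <- pairs[sample.int(nrow(pairs), min(sample_pairs, nrow(pairs))), ,
                     drop = FALSE]
    })
  } else if (max(nrow(a_rec), nrow(b_rec)) > max_n && !allow_large) {
    abort(paste0("more than ", max_n, " sequences: a full summary needs ",
                 "allow_large = TRUE or a sample_pairs budget"))
  }
  ids <- purrr::map2_dfr(pairs$i, pairs$j, function(i, j) {
    global_identity(a_rec[i, ], b_rec[j, ], gap_open, gap_extend, matrix_name)
  })
  # within-set: each unordered pair stands for two ordered alignments
  vals <- ids$identity_percent
  if (!between) vals <- rep(vals, each = 2)
  if (!is.null(sample_pairs)) n_aln <- length(vals)
  br <- seq(0, 100, by = 5)
  h <- hist(vals, breaks = br, plot = FALSE)
  out <- tibble(
    n_sequences = n_seq, n_alignments = n_aln,
    mean_identity = mean(vals), sd_identity = sd(vals),
    histogram = list(tibble(bin_low = br[-length(br)], bin_high = br[-1],
                            count = h$counts))
  )
  attr(out, "identities") <- ids
  out
}

# run code under a temporary RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Identity-threshold redundancy reduction
#'
#' Greedy longest-first clustering in the style of CD-HIT, but using true
#' global-alignment identity for every comparison rather than k-mer
#' pre-filters: records are visited in order of decreasing sequence length
#' (ties by input order), each joins the first existing cluster whose
#' representative it exceeds the identity threshold with, otherwise it
#' founds a new cluster. Representatives (the retained set) therefore never
#' share more than `identity_threshold` percent identity.
#'
#' @param records Record tibble.
#' @param identity_threshold Percent identity in (0, 100]; pairs strictly
#'   above it are considered redundant. Dataset curation uses 80.
#' @inheritParams global_identity
#' @return List with `retained` (record tibble of representatives, in
#'   founding order) and `clusters` (tibble `member_id`,
#'   `representative_id`, `identity_percent`; representatives map to
#'   themselves at 100).
#' @export
reduce_redundancy <- function(records, identity_threshold = 80,
                              gap_open = 10, gap_extend = 0.5,
                              matrix_name = "BLOSUM62") {
  if (nrow(records) == 0) abort("no records to reduce")
  if (identity_threshold <= 0 || identity_threshold > 100) {
    abort("identity_threshold must be in (0, 100]")
  }
  ord <- order(-nchar(records$sequence))
  sorted <- records[ord, , drop = FALSE]
  rep_idx <- integer(0)
  members <- list()
  for (k in seq_len(nrow(sorted))) {
    placed <- FALSE
    for (r in rep_idx) {
      res <- global_identity(sorted[k, ], sorted[r, ],
                             gap_open, gap_extend, matrix_name)
      if (res$identity_percent > identity_threshold) {
        members[[length(members) + 1]] <- tibble(
          member_id = sorted$id[k], representative_id = sorted$id[r],
          identity_percent = res$identity_percent)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, k)
      members[[length(members) + 1]] <- tibble(
        member_id = sorted$id[k], representative_id = sorted$id[k],
        identity_percent = 100)
    }
  }
  list(
    retained = sorted[rep_idx, , drop = FALSE],
    clusters = bind_rows(members)
  )
}
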