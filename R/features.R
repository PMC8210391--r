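#' Amino-acid composition of a sequence
#'
#' Twenty values: the proportion of each canonical residue in the sequence,
#' in fixed alphabetical order (ACDEFGHIKLMNPQRSTVWY). Components sum to 1.
#'
#' @param sequence A single canonical-alphabet residue string.
#' @return Named numeric vector of length 20 (`AA_<residue>`).
#' @export
#' @examples
#' aa_composition("ACAC")
aa_composition <- function(sequence) {
  ch <- check_sequence(sequence, min_len = 1)
  counts <- tabulate(factor(ch, levels = AA_ALPHABET), nbins = 20)
  setNames(counts / length(ch), paste0("AA_", AA_ALPHABET))
}

#' Dipeptide composition of a sequence
#'
#' Four hundred values: the proportion of each ordered residue pair among
#' the N-1 overlapping windows of the sequence, in row-major order over the
#' canonical residue order (AA, AC, ..., YY). Components sum to 1 for any
#' sequence of length >= 2.
#'
#' @param sequence A single canonical-alphabet residue string, length >= 2.
#' @return Named numeric vector of length 400 (`DP_<pair>`).
#' @export
#' @examples
#' head(sort(dipeptide_composition("ACAC"), decreasing = TRUE))
dipeptide_composition <- function(sequence) {
  ch <- check_sequence(sequence, min_len = 2)
  n <- length(ch)
  pairs <- paste0(ch[-n], ch[-1])
  counts <- tabulate(factor(pairs, levels = DIPEPTIDES), nbins = 400)
  setNames(counts / (n - 1), paste0("DP_", DIPEPTIDES))
}

#' Physico-chemical property features of a sequence
#'
#' For each of the 11 property scales, the mean of the normalized per-residue
#' value over all positions of the sequence. With min-max-normalized scales
#' every component lies in \[0, 1\].
#'
#' @param sequence A single canonical-alphabet residue string.
#' @param scale_set Scale-set tibble, default [aa_scale_set()].
#' @return Named numeric vector of length 11 (`PCP_<scale>`).
#' @export
pcp_features <- function(sequence, scale_set = aa_scale_set()) {
  ch <- check_sequence(sequence, min_len = 1)
  m <- scale_matrix(scale_set)
  means <- colMeans(m[ch, , drop = FALSE])
  setNames(means, paste0("PCP_", colnames(m)))
}

#' Encode a sequence under a named feature scheme
#'
#' The five schemes are `PCP` (11 values), `AA` (20), `DP` (400) and the
#' combinations `PCP_AA` and `PCP_AA_DP`. Combined schemes are the exact
#' concatenation of their standalone blocks — physico-chemical block first,
#' then amino-acid composition, then dipeptide composition — so their
#' lengths are the sums of the block lengths, 31 and 431.
#'
#' @param sequence A single canonical-alphabet residue string.
#' @param scheme One of `"PCP"`, `"AA"`, `"PCP_AA"`, `"DP"`, `"PCP_AA_DP"`.
#' @param scale_set Scale-set tibble; only consulted for schemes with a
#'   physico-chemical block.
#' @return Named numeric vector of the scheme's fixed length.
#' @export
encode <- function(sequence, scheme, scale_set = aa_scale_set()) {
  scheme <- match_scheme(scheme)
  blocks <- list()
  if (grepl("PCP", scheme)) blocks <- c(blocks, list(pcp_features(sequence, scale_set)))
  if (grepl("AA", scheme)) blocks <- c(blocks, list(aa_composition(sequence)))
  if (grepl("DP", scheme)) blocks <- c(blocks, list(dipeptide_composition(sequence)))
  do.call(c, blocks)
}

#' Encode a dataset of records into a feature tibble
#'
#' Applies [encode()] to every record and returns one wide tibble: `id`,
#' `label` (if present in `records`), then one column per feature. Row order
#' matches record order and column names are stable across calls, so the
#' result can be written to TSV and reused.
#'
#' @param records Record tibble with `id`, `sequence` and optionally `label`.
#' @param scheme Feature scheme name.
#' @param scale_set Scale-set tibble.
#' @return Wide tibble of features; attribute `scheme` records the scheme.
#' @export
encode_dataset <- function(records, scheme, scale_set = aa_scale_set()) {
  scheme <- match_scheme(scheme)
  if (nrow(records) == 0) abort("no records to encode")
  if (anyDuplicated(records$id)) abort("duplicate record ids in dataset")
  mat <- matrix(NA_real_, nrow = nrow(records), ncol = scheme_length(scheme))
  for (i in seq_len(nrow(records))) {
    v <- tryCatch(encode(records$sequence[i], scheme, scale_set),
                  error = function(e) {
                    abort(paste0("record '", records$id[i],
                                 "' cannot be encoded: ", conditionMessage(e)))
                  })
    if (i == 1) colnames(mat) <- names(v)
    mat[i, ] <- v
  }
  out <- tibble(id = records$id)
  if ("label" %in% names(records)) out$label <- records$label
  out <- bind_cols_matrix(out, mat, colnames(mat))
  attr(out, "scheme") <- scheme
  out
}

#' Write / read a feature tibble as TSV
#'
#' @param features Wide feature tibble from [encode_dataset()].
#' @param path File path.
#' @return `path` invisibly (write); the feature tibble (read).
#' @export
write_features <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       check.names = FALSE))
}

check_sequence <- function(sequence, min_len) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence)) {
    abort("sequence must be a single non-empty string")
  }
  ch <- strsplit(sequence, "")[[1]]
  if (length(ch) < min_len) {
    abort(paste0("sequence must have at least ", min_len, " residues"))
  }
  bad <- which(!(ch %in% AA_ALPHABET))
  if (length(bad) > 0) {
    abort(paste0("non-canonical residue ", ch[bad[1]], " at position ", bad[1]))
  }
  ch
}

# Split a wide feature tibble into the numeric matrix + metadata columns.
feature_matrix <- function(features) {
  meta <- intersect(c("id", "label"), names(features))
  m <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
  rownames(m) <- features$id
  m
}
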