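#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-record, arbitrarily wrapped) FASTA file into a tibble of
#' protein records. Sequences are uppercased and checked against the 20
#' canonical one-letter residue codes; how non-canonical residues are handled
#' is controlled by `sanitize`.
#'
#' The three policies are:
#' \describe{
#'   \item{`strict`}{any non-canonical residue is an error naming the record,
#'     residue and position.}
#'   \item{`drop_ambiguous`}{records containing any of B, J, O, U, X, Z are
#'     excluded; the number dropped is reported in the `n_dropped` attribute
#'     and a message. Recommended when building training datasets.}
#'   \item{`map_ambiguous`}{U (selenocysteine) is mapped to C, O (pyrrolysine)
#'     to K, and B/Z/J/X are deleted from the sequence, so no query record is
#'     refused. Recommended at prediction time.}
#' }
#' Stop codons (`*`) are always stripped before checking. Characters outside
#' the canonical and ambiguous sets are an error under every policy.
#'
#' @param path Path to a FASTA file.
#' @param sanitize Sanitization policy; one of `"strict"`,
#'   `"drop_ambiguous"`, `"map_ambiguous"`.
#' @return A tibble with columns `id` (header token up to first whitespace),
#'   `description` (remainder of the header) and `sequence`, one row per
#'   surviving record; attribute `n_dropped` counts records removed under
#'   `drop_ambiguous`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "ACDE", ">p2", "MKLV"), fa)
#' read_fasta(fa)
read_fasta <- function(path,
                       sanitize = c("drop_ambiguous", "strict", "map_ambiguous")) {
  sanitize <- match.arg(sanitize)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    abort(paste0("duplicate record ids in ", path, ": ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  records <- tibble(id = id, description = description,
                    sequence = unname(as.character(set)))
  sanitize_records(records, policy = sanitize)
}

AMBIGUOUS_RESIDUES <- c("B", "J", "O", "U", "X", "Z")

#' Sanitize a record table's sequences under a named policy
#'
#' Workhorse behind [read_fasta()]; exported so record tibbles built in
#' memory (e.g. by the synthetic generator or user code) can be passed
#' through the identical policy. Idempotent: applying the same policy twice
#' changes nothing.
#'
#' @param records Tibble with at least `id` and `sequence` columns.
#' @param policy One of `"strict"`, `"drop_ambiguous"`, `"map_ambiguous"`.
#' @return The records tibble with sanitized sequences; possibly fewer rows
#'   under `drop_ambiguous` (count in attribute `n_dropped`).
#' @export
sanitize_records <- function(records,
                             policy = c("drop_ambiguous", "strict", "map_ambiguous")) {
  policy <- match.arg(policy)
  seqs <- toupper(gsub("[*[:space:]]", "", records$sequence))
  bad <- lapply(strsplit(seqs, ""), function(ch) {
    setdiff(unique(ch), c(AA_ALPHABET, AMBIGUOUS_RESIDUES))
  })
  offender <- which(lengths(bad) > 0)
  if (length(offender) > 0) {
    abort(paste0("record '", records$id[offender[1]],
                 "' contains unrecognized character(s): ",
                 paste(bad[[offender[1]]], collapse = ", ")))
  }
  n_dropped <- 0L
  if (policy == "strict") {
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[i], "")[[1]]
      hit <- which(ch %in% AMBIGUOUS_RESIDUES)
      if (length(hit) > 0) {
        abort(paste0("record '", records$id[i], "' contains non-canonical residue ",
                     ch[hit[1]], " at position ", hit[1]))
      }
    }
  } else if (policy == "drop_ambiguous") {
    keep <- !grepl(paste0("[", paste(AMBIGUOUS_RESIDUES, collapse = ""), "]"), seqs)
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      message(n_dropped, " record(s) dropped for ambiguous residues")
    }
    records <- records[keep, , drop = FALSE]
    seqs <- seqs[keep]
  } else { # map_ambiguous
    seqs <- chartr("UO", "CK", seqs)
    seqs <- gsub("[BZJX]", "", seqs)
  }
  if (any(nchar(seqs) == 0) || nrow(records) == 0) {
    abort("no records with non-empty canonical sequences survive sanitization")
  }
  out <- records
  out$sequence <- seqs
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write protein records to a FASTA file
#'
#' @param records Tibble with `id`, `sequence` and optionally `description`.
#' @param path Output path.
#' @param width Line-wrap width (columns); 60 by convention.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  set <- Biostrings::AAStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else
    rep("", nrow(records))
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
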