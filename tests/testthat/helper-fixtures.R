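# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files these helpers write to tempdir().

tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# small record tibble straight from sequences
records_from <- function(seqs, ids = NULL, labels = NULL) {
  ids <- ids %||% sprintf("r%02d", seq_along(seqs))
  out <- tibble::tibble(id = ids, description = "", sequence = seqs)
  if (!is.null(labels)) out$label <- labels
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_protein <- function(n, seed = NULL) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# annotation tibble in the package layout
make_annotations <- function(ids, vert = TRUE, sp = FALSE, tm = FALSE,
                             locations = NULL, uniprot = NA_character_) {
  n <- length(ids)
  tibble::tibble(
    id = ids,
    is_vertebrate = rep_len(vert, n),
    has_signal_peptide = rep_len(sp, n),
    has_transmembrane = rep_len(tm, n),
    locations = locations %||% replicate(n, character(0), simplify = FALSE),
    uniprot_id = rep_len(uniprot, n)
  )
}

# a constant-value scale set (bypasses min-max normalization on purpose):
# with every residue mapped to the same value c, the property average of any
# sequence is exactly c.
constant_scale_set <- function(values) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- lapply(seq_along(values), function(i) {
    row <- c(list(scale = paste0("const_", i), source = "test"),
             as.list(stats::setNames(rep(values[i], 20), aa)))
    tibble::as_tibble(row)
  })
  dplyr::bind_rows(rows)
}
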