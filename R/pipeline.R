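#' Curate a labeled dataset for training
#'
#' Applies the dataset-building filter chain, in order: (1) drop
#' non-vertebrate proteins, (2) drop proteins with a signal peptide, (3)
#' drop proteins with transmembrane regions, (4) reduce redundancy within
#' each class so that no two retained proteins of a class share more than
#' `identity_threshold` percent identity. Records whose filter fields are
#' unknown are dropped (dataset building is conservative) and counted
#' separately from definite removals.
#'
#' @param records Labeled record tibble.
#' @param annotations Annotation tibble covering the filter fields.
#' @param identity_threshold Redundancy threshold (percent); 80 by default.
#' @param drop_unknown Drop records with unknown vertebrate/SP/TM status
#'   (default `TRUE`; set `FALSE` to keep them, at your own risk).
#' @return List with `records` (curated tibble), `clusters` (per-class
#'   redundancy maps) and `log` (tibble of counts removed at each step).
#' @export
curate_dataset <- function(records, annotations, identity_threshold = 80,
                           drop_unknown = TRUE) {
  ann <- annotation_lookup(annotations, records$id)
  log_rows <- list()
  note <- function(step, removed) {
    log_rows[[length(log_rows) + 1]] <<- tibble(step = step, removed = removed)
  }

  unknown <- is.na(ann$is_vertebrate) | is.na(ann$has_signal_peptide) |
    is.na(ann$has_transmembrane)
  if (drop_unknown) {
    note("unknown_annotation", sum(unknown))
    keep <- !unknown
    records <- records[keep, , drop = FALSE]; ann <- ann[keep, , drop = FALSE]
  } else {
    note("unknown_annotation", 0L)
  }

  steps <- list(
    non_vertebrate = !is.na(ann$is_vertebrate) & !ann$is_vertebrate,
    signal_peptide = !is.na(ann$has_signal_peptide) & ann$has_signal_peptide,
    transmembrane = !is.na(ann$has_transmembrane) & ann$has_transmembrane
  )
  for (nm in names(steps)) {
    drop <- steps[[nm]]
    note(nm, sum(drop))
    records <- records[!drop, , drop = FALSE]
    ann <- ann[!drop, , drop = FALSE]
    for (snm in names(steps)) steps[[snm]] <- steps[[snm]][!drop]
  }

  labels <- as_binary_labels(records$label)
  clusters <- list()
  kept <- list()
  for (cls in c(TRUE, FALSE)) {
    sub <- records[labels == cls, , drop = FALSE]
    if (nrow(sub) == 0) {
      abort(paste0("curation emptied the ",
                   if (cls) "positive" else "negative", " class"))
    }
    red <- reduce_redundancy(sub, identity_threshold)
    note(paste0("redundancy_", if (cls) "positive" else "negative"),
         nrow(sub) - nrow(red$retained))
    clusters[[if (cls) "positive" else "negative"]] <- red$clusters
    kept[[length(kept) + 1]] <- red$retained
  }
  out <- bind_rows(kept)
  list(records = out, clusters = clusters, log = bind_rows(log_rows))
}

#' Gated exosome-secretion prediction report
#'
#' The secretion model is only executed for proteins that are from a
#' vertebrate and have neither a signal peptide nor transmembrane regions;
#' all other proteins receive `NA` in the `exosome_secretion` column and no
#' score. Prediction mode is permissive about missing external evidence: a
#' protein with unknown vertebrate status (e.g. no UniProt equivalent) is
#' still scored, with `is_vertebrate` reported as `unknown` and
#' `uniprot_id` as `not found`; unknown SP/TM status resolves via
#' `unknown_is` (default `"no"`, i.e. scored).
#'
#' @param records Record tibble of query proteins.
#' @param annotations Annotation tibble (may be `NULL`).
#' @param bundle Trained `exocargo_model`.
#' @param unknown_is How to resolve unknown SP/TM flags: `"no"` (score the
#'   protein) or `"na"` (gate it out).
#' @param threshold Decision threshold for the Y/N call.
#' @return Tibble with one row per record, columns in report order:
#'   `index`, `sequence_name`, `is_vertebrate` (Y/N/unknown), `uniprot_id`,
#'   `signal_peptide` (Y/N), `transmembrane` (Y/N), `location_annotated`,
#'   `exosome_secretion` (Y/N/NA) and `score`.
#' @export
gate_and_predict <- function(records, annotations, bundle,
                             unknown_is = c("no", "na"), threshold = NULL) {
  unknown_is <- match.arg(unknown_is)
  ann <- annotation_lookup(annotations, records$id)
  sp <- ann$has_signal_peptide
  tm <- ann$has_transmembrane
  if (unknown_is == "no") {
    sp[is.na(sp)] <- FALSE
    tm[is.na(tm)] <- FALSE
  } else {
    sp[is.na(sp)] <- TRUE
    tm[is.na(tm)] <- TRUE
  }
  gated_out <- (!is.na(ann$is_vertebrate) & !ann$is_vertebrate) | sp | tm

  score <- rep(NA_real_, nrow(records))
  call <- rep(NA_character_, nrow(records))
  if (any(!gated_out)) {
    preds <- predict_scores(bundle, records[!gated_out, , drop = FALSE],
                            threshold = threshold)
    score[!gated_out] <- preds$score
    call[!gated_out] <- preds$call
  }
  tibble(
    index = seq_len(nrow(records)),
    sequence_name = records$id,
    is_vertebrate = tri_to_yn(ann$is_vertebrate),
    uniprot_id = ifelse(is.na(ann$uniprot_id), "not found", ann$uniprot_id),
    signal_peptide = ifelse(sp, "Y", "N"),
    transmembrane = ifelse(tm, "Y", "N"),
    location_annotated = vapply(ann$locations, function(l) {
      if (length(l) == 0) "not found" else paste(l, collapse = ";")
    }, ""),
    exosome_secretion = call,
    score = score
  )
}

tri_to_yn <- function(x) ifelse(is.na(x), "unknown", ifelse(x, "Y", "N"))

#' Tally exclusive sub-cellular locations
#'
#' Counts, over a record set, how many proteins are annotated with exactly
#' one sub-cellular location (one row per location), how many carry several
#' locations, and how many have none.
#'
#' @param records Record tibble.
#' @param annotations Annotation tibble.
#' @return Tibble `category`, `count`; exclusive locations first, then
#'   `multi_location` and `unannotated`. Counts sum to `nrow(records)`.
#' @export
location_tally <- function(records, annotations) {
  ann <- annotation_lookup(annotations, records$id)
  nloc <- lengths(ann$locations)
  exclusive <- unlist(ann$locations[nloc == 1])
  excl_counts <- if (length(exclusive) > 0) {
    tibble(category = names(table(exclusive)),
           count = as.integer(table(exclusive)))
  } else tibble(category = character(0), count = integer(0))
  bind_rows(
    excl_counts,
    tibble(category = c("multi_location", "unannotated"),
           count = c(sum(nloc > 1), sum(nloc == 0)))
  )
}
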