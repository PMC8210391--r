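#' Read a per-protein annotation table
#'
#' The annotation table stands in for the external lookups a curator would
#' normally run (taxonomy from UniProt, signal peptides from SignalP,
#' transmembrane regions from TMHMM, locations from UniProt/PSORT): the
#' package consumes their results, it never shells out to them. Format:
#' tab-separated with a header row and columns `id`, `is_vertebrate`,
#' `has_signal_peptide`, `has_transmembrane`, `locations`
#' (semicolon-separated), `uniprot_id`.
#'
#' Boolean columns are tri-state: `yes`/`no`/`unknown` (also accepted:
#' `y`/`n`, `true`/`false`, empty or `NA` for unknown). Unknown is
#' deliberately distinct from `no` — downstream filters treat the two
#' differently.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `is_vertebrate`,
#'   `has_signal_peptide`, `has_transmembrane` (logical, `NA` = unknown),
#'   `locations` (list column of character vectors) and `uniprot_id`
#'   (character, `NA` = not found).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("annotation table not found: ", path))
  }
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL)
  needed <- c("id", "is_vertebrate", "has_signal_peptide", "has_transmembrane")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("annotation table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  parse_tri <- function(x, column) {
    x <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[x %in% c("yes", "y", "true", "1")] <- TRUE
    out[x %in% c("no", "n", "false", "0")] <- FALSE
    bad <- !(x %in% c("yes", "y", "true", "1", "no", "n", "false", "0",
                      "unknown", "na", ""))
    if (any(bad)) {
      abort(paste0("unrecognized value '", x[which(bad)[1]], "' in column '",
                   column, "', row ", which(bad)[1]))
    }
    as.logical(out)
  }
  locs <- raw$locations %||% rep("", nrow(raw))
  uid <- raw$uniprot_id %||% rep("", nrow(raw))
  tibble(
    id = raw$id,
    is_vertebrate = parse_tri(raw$is_vertebrate, "is_vertebrate"),
    has_signal_peptide = parse_tri(raw$has_signal_peptide, "has_signal_peptide"),
    has_transmembrane = parse_tri(raw$has_transmembrane, "has_transmembrane"),
    locations = lapply(locs, function(s) {
      parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
      parts[nzchar(parts)]
    }),
    uniprot_id = ifelse(nzchar(trimws(uid)) & !tolower(trimws(uid)) %in% c("na", "not found"),
                        trimws(uid), NA_character_)
  )
}

#' Write an annotation table to TSV
#'
#' Inverse of [read_annotations()]; logical `NA` serializes as `unknown`.
#'
#' @param annotations Annotation tibble as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  fmt_tri <- function(x) ifelse(is.na(x), "unknown", ifelse(x, "yes", "no"))
  out <- data.frame(
    id = annotations$id,
    is_vertebrate = fmt_tri(annotations$is_vertebrate),
    has_signal_peptide = fmt_tri(annotations$has_signal_peptide),
    has_transmembrane = fmt_tri(annotations$has_transmembrane),
    locations = vapply(annotations$locations, paste, "", collapse = ";"),
    uniprot_id = ifelse(is.na(annotations$uniprot_id), "",
                        annotations$uniprot_id),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up annotations for a set of ids
#'
#' Ids absent from the table resolve to an all-unknown entry rather than an
#' error, mirroring how a query protein without any external hit is still
#' processed.
#'
#' @param annotations Annotation tibble (may be `NULL` for "no table").
#' @param ids Character vector of record ids, in the order wanted.
#' @return Annotation tibble with one row per id, in `ids` order.
#' @export
annotation_lookup <- function(annotations, ids) {
  blank <- tibble(
    id = ids,
    is_vertebrate = NA, has_signal_peptide = NA, has_transmembrane = NA,
    locations = replicate(length(ids), character(0), simplify = FALSE),
    uniprot_id = NA_character_
  )
  if (is.null(annotations) || nrow(annotations) == 0) {
    return(blank)
  }
  hit <- match(ids, annotations$id)
  out <- blank
  found <- !is.na(hit)
  for (col in c("is_vertebrate", "has_signal_peptide", "has_transmembrane",
                "uniprot_id")) {
    out[[col]][found] <- annotations[[col]][hit[found]]
  }
  out$locations[found] <- annotations$locations[hit[found]]
  out
}
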