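#' Amino-acid physico-chemical property scales
#'
#' Builds the ordered set of 11 per-residue property scales used by the
#' physico-chemical feature encoding: average flexibility, residue volume,
#' relative mutability, net charge, optimized side-chain interaction
#' parameter, polarity, alpha-helix propensity from designed sequences,
#' beta-sheet propensity from designed sequences, amphiphilicity index, the
#' modified Kyte-Doolittle hydrophobicity scale, and aromaticity. The first
#' ten are taken from the AAindex database as shipped with the seqinr
#' package (accessions in the `source` column); aromaticity, which has no
#' published AAindex scale, is a binary indicator (1 for F, W, Y; 0
#' otherwise — histidine is not counted as aromatic here).
#'
#' Each scale is min-max normalized to \[0, 1\] across the 20 residues, so
#' the per-sequence property average is itself bounded in \[0, 1\]. The row
#' order of the returned tibble is fixed and defines the order of the 11
#' physico-chemical features.
#'
#' @return A tibble with columns `scale` (name), `source` (AAindex
#'   accession or `"indicator"`), one numeric column per residue in
#'   canonical order holding the normalized values, and list columns are
#'   avoided so it round-trips through TSV.
#' @seealso [read_scale_set()] to supply custom raw values.
#' @export
aa_scale_set <- function() {
  accessions <- c(
    average_flexibility       = "BHAR880101",
    residue_volume            = "GOLD730102",
    relative_mutability       = "JOND920102",
    net_charge                = "KLEP840101",
    side_chain_interaction    = "OOBM850105",
    polarity                  = "GRAR740102",
    alpha_helix_propensity    = "KOEP990101",
    beta_sheet_propensity     = "KOEP990102",
    amphiphilicity            = "MITS020101",
    hydrophobicity_kd_mod     = "JURD980101"
  )
  aaidx <- get_aaindex()
  rows <- purrr::imap(accessions, function(acc, nm) {
    raw <- aaidx[[acc]]$I
    names(raw) <- aa3to1(names(raw))
    c(list(scale = nm, source = acc), as.list(normalize_scale(raw[AA_ALPHABET])))
  })
  aromatic <- setNames(as.numeric(AA_ALPHABET %in% c("F", "W", "Y")), AA_ALPHABET)
  rows <- c(rows, list(c(list(scale = "aromaticity", source = "indicator"),
                         as.list(aromatic))))
  bind_rows(lapply(rows, as_tibble))
}

get_aaindex <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  env$aaindex
}

aa3to1 <- function(x) {
  map <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
           Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
           Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
           Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  unname(map[x])
}

#' Min-max normalize a 20-residue scale to \[0, 1\]
#'
#' @param raw Named numeric vector over the 20 canonical residues.
#' @return Named numeric vector in \[0, 1\]; the minimum maps to 0 and the
#'   maximum to 1. A constant scale is an error (it carries no information
#'   and has no normalization).
#' @export
normalize_scale <- function(raw) {
  if (length(raw) != 20 || !setequal(names(raw), AA_ALPHABET)) {
    abort("a property scale must cover exactly the 20 canonical residues")
  }
  raw <- raw[AA_ALPHABET]
  if (anyNA(raw)) abort("property scale contains missing values")
  rng <- range(raw)
  if (rng[1] == rng[2]) abort("property scale is constant; cannot normalize")
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Read a custom property-scale set from TSV
#'
#' Expects columns `scale`, optionally `source`, and the 20 residue columns
#' with *raw* values; each scale is min-max normalized on read. The file's
#' row order defines feature order.
#'
#' @param path Path to the TSV file.
#' @return Scale-set tibble in the same layout as [aa_scale_set()].
#' @export
read_scale_set <- function(path) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("scale", AA_ALPHABET), names(raw))
  if (length(missing) > 0) {
    abort(paste0("scale table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(raw$scale)) abort("duplicate scale names in scale table")
  norm <- t(apply(as.matrix(raw[, AA_ALPHABET]), 1, function(v) {
    normalize_scale(setNames(v, AA_ALPHABET))
  }))
  out <- tibble(scale = raw$scale,
                source = raw$source %||% rep("custom", nrow(raw)))
  bind_cols_matrix(out, norm, AA_ALPHABET)
}

bind_cols_matrix <- function(tbl, mat, colnames) {
  m <- as_tibble(as.data.frame(mat))
  names(m) <- colnames
  dplyr::bind_cols(tbl, m)
}

# Internal: scale set as a residues x scales numeric matrix for fast lookup.
scale_matrix <- function(scale_set) {
  m <- t(as.matrix(scale_set[, AA_ALPHABET]))
  colnames(m) <- scale_set$scale
  m
}
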