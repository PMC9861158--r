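#' Candidate-substrate peptide repertoires
#'
#' A repertoire table is a plain `data.frame` (class `repertoire_table`)
#' with one row per candidate peptide window and columns:
#' \describe{
#'   \item{peptide}{window sequence, one-letter upper case}
#'   \item{protein_id}{source protein identifier}
#'   \item{k_position}{1-based position of the central lysine in the source}
#'   \item{site_label}{site name such as `"H3K5"` (may be `NA`)}
#'   \item{methyl_state}{`"Kme0"`, `"Kme1"` or `"Kme2"`; default `"Kme0"`}
#'   \item{binding_energy}{optional binding free energy, kcal/mol
#'     (more negative = stronger binding)}
#'   \item{sources}{`;`-separated `protein_id:k_position` annotations,
#'     populated by [dedupe_repertoire()] when duplicates are merged}
#' }
#' The attribute `provenance` records where the table came from.
#'
#' @name repertoire_table
NULL

new_repertoire <- function(df, provenance = NA_character_) {
  cols <- c("peptide", "protein_id", "k_position", "site_label",
            "methyl_state", "binding_energy", "sources")
  for (cn in setdiff(cols, names(df))) {
    fill <- if (cn == "k_position") NA_integer_
      else if (cn == "binding_energy") NA_real_
      else if (cn == "methyl_state") "Kme0"
      else NA_character_
    df[[cn]] <- rep(fill, nrow(df))
  }
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("repertoire_table", "data.frame"))
}

#' Extract lysine-centered peptide windows from protein sequences
#'
#' Scans each sequence with the pattern xxxKxxx (x = any residue): every
#' lysine with at least `center_index - 1` residues before it and
#' `window_length - center_index` after it yields one window. Windows that
#' would run off either terminus are skipped, as are windows containing
#' non-standard residue codes (X, U, B, Z, ...), the latter with a warning.
#'
#' @param sequences A named character vector of amino-acid sequences, a
#'   `Biostrings::AAStringSet`, or the path to a FASTA file.
#' @param window_length Odd window length (default 7).
#' @param center_index 1-based index of the central lysine within the
#'   window (default 4).
#' @return A [repertoire_table] in source order.
#' @examples
#' extract_windows(c(pep = "AAAKAAA"))
#' @export
extract_windows <- function(sequences, window_length = 7L, center_index = 4L) {
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  if (methods::is(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  window_length <- as.integer(window_length)
  center_index <- as.integer(center_index)
  if (window_length %% 2L != 1L) stop("window_length must be odd")
  if (center_index < 1L || center_index > window_length) {
    stop("center_index must lie within the window")
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }

  before <- center_index - 1L
  after <- window_length - center_index
  rows <- vector("list", length(sequences))
  n_skipped <- 0L
  for (i in seq_along(sequences)) {
    s <- toupper(sequences[[i]])
    len <- nchar(s)
    chars <- strsplit(s, "")[[1]]
    kpos <- which(chars == "K")
    kpos <- kpos[kpos > before & kpos <= len - after]
    if (!length(kpos)) next
    win <- substring(s, kpos - before, kpos + after)
    ok <- !grepl(paste0("[^", paste(STANDARD_AA, collapse = ""), "]"), win)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    rows[[i]] <- data.frame(peptide = win[ok],
                            protein_id = names(sequences)[i],
                            k_position = as.integer(kpos[ok]),
                            stringsAsFactors = FALSE)
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d window(s) skipped: non-standard residue codes",
                    n_skipped))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(), protein_id = character(),
               k_position = integer(), stringsAsFactors = FALSE)
  new_repertoire(df, provenance = "extract_windows")
}

#' Deduplicate a repertoire on exact peptide identity
#'
#' The first occurrence of each peptide sequence is kept as canonical; the
#' `protein_id:k_position` annotations of all merged duplicates are
#' retained in its `sources` column.
#'
#' @param table A [repertoire_table].
#' @return A deduplicated [repertoire_table] (idempotent).
#' @export
dedupe_repertoire <- function(table) {
  stopifnot(inherits(table, "repertoire_table") || is.data.frame(table))
  if (!nrow(table)) return(table)
  src <- ifelse(is.na(table$sources) | table$sources == "",
                paste0(table$protein_id, ":", table$k_position),
                table$sources)
  keep <- !duplicated(table$peptide)
  merged <- vapply(table$peptide[keep], function(p) {
    paste(unique(src[table$peptide == p]), collapse = ";")
  }, character(1))
  out <- table[keep, , drop = FALSE]
  out$sources <- unname(merged)
  new_repertoire(out, provenance = attr(table, "provenance"))
}

#' Build a site label from a protein name and lysine position
#'
#' Two labelling conventions are in common use: counting from the
#' initiator methionine (`"with_initiator_met"`, giving e.g. `"H3K5"` for
#' source position 5) and classical histone nomenclature that drops the
#' initiator Met (`"histone_nomenclature"`, giving `"H3K4"` for the same
#' residue). Both are supported because published site names mix them.
#'
#' @param protein_name Protein name prefix, e.g. `"H3"`.
#' @param k_position 1-based lysine position counting the initiator Met.
#' @param convention `"with_initiator_met"` or `"histone_nomenclature"`.
#' @return The site label string.
#' @examples
#' label_site("H3", 5, "with_initiator_met")   # "H3K5"
#' label_site("H3", 5, "histone_nomenclature") # "H3K4"
#' @export
label_site <- function(protein_name, k_position,
                       convention = c("with_initiator_met",
                                      "histone_nomenclature")) {
  convention <- match.arg(convention)
  k_position <- as.integer(k_position)
  stopifnot(k_position >= 1L)
  if (convention == "histone_nomenclature") {
    if (k_position < 2L) {
      stop("histone nomenclature needs k_position >= 2 (no initiator Met to drop)")
    }
    k_position <- k_position - 1L
  }
  paste0(protein_name, "K", k_position)
}

#' Load the packaged 64-peptide histone repertoire with binding energies
#'
#' Returns the packaged repertoire of 64 unique lysine-centered
#' heptapeptides derived from histones H1.2, H2B, H3.1 and H4, each with a
#' precomputed binding free energy (kcal/mol) against the PRDM15 PR
#' domain. Site labels are attached for the six strongest binders.
#'
#' @return A [repertoire_table] with 64 rows.
#' @seealso [prdm9_reference()] for the PRDM9 positive-control energy.
#' @export
load_fixture_table1 <- function() {
  path <- system.file("extdata", "table1_repertoire.csv",
                      package = "metscreen", mustWork = FALSE)
  if (path == "" || !file.exists(path)) {
    stop("packaged fixture 'extdata/table1_repertoire.csv' not found")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "character",
                                       "character", "character"))
  if (nrow(df) != 64L || anyDuplicated(df$peptide) ||
      any(nchar(df$peptide) != 7L)) {
    stop("fixture 'table1_repertoire.csv' is corrupt")
  }
  df$binding_energy <- as.numeric(normalize_minus(df$binding_energy))
  df$site_label[df$site_label == ""] <- NA_character_
  out <- data.frame(peptide = df$peptide,
                    protein_id = sub("K[0-9]+$", "", df$site_label),
                    k_position = suppressWarnings(
                      as.integer(sub("^.*K([0-9]+)$", "\\1", df$site_label))),
                    site_label = df$site_label,
                    binding_energy = df$binding_energy,
                    stringsAsFactors = FALSE)
  new_repertoire(out, provenance = "packaged 64-peptide fixture")
}

#' PRDM9 positive-control substrate and binding energy
#'
#' The H3 N-terminal peptide ARTKQTA bound to PRDM9, with the reference
#' binding free energy used to benchmark candidate rankings.
#'
#' @return A list with `peptide`, `site_label` and `binding_energy`
#'   (kcal/mol).
#' @export
prdm9_reference <- function() {
  list(peptide = "ARTKQTA", site_label = "H3K4", binding_energy = -2.73)
}

# Normalize typographic minus signs (U+2212, en-dash) to ASCII "-".
normalize_minus <- function(x) {
  gsub("−|–", "-", x)
}

#' Read a multi-record FASTA file
#'
#' @param path Path to a FASTA file (wrapped lines allowed).
#' @return A named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(aa))
  # keep only the first word of each header, as alignment tools do
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Write / read a repertoire CSV
#'
#' The on-disk dialect has columns
#' `peptide,protein_id,k_position,site_label,methyl_state,binding_energy,sources`
#' in UTF-8; typographic minus signs in the energy column are normalized
#' to ASCII on read, so tables transcribed from typeset sources load
#' cleanly.
#'
#' @param table A [repertoire_table].
#' @param path Output/input CSV path.
#' @return `write_repertoire()` returns `path` invisibly;
#'   `read_repertoire()` returns a [repertoire_table].
#' @export
write_repertoire <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_repertoire
#' @export
read_repertoire <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$k_position <- suppressWarnings(as.integer(df$k_position))
  df$binding_energy <- suppressWarnings(
    as.numeric(normalize_minus(df$binding_energy)))
  for (cn in c("protein_id", "site_label", "methyl_state", "sources")) {
    if (cn %in% names(df)) df[[cn]][df[[cn]] == ""] <- NA_character_
  }
  df$methyl_state[is.na(df$methyl_state)] <- "Kme0"
  new_repertoire(df, provenance = path)
}
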