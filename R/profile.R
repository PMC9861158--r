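#' Annotated reference methyltransferase
#'
#' Bundles a reference catalytic-domain sequence with the 1-based
#' positions of its active-site catalytic tyrosines and optional labelled
#' motif regions (e.g. the cofactor-binding stretch). The canonical
#' example is murine PRDM9, whose three active-site tyrosines
#' (276, 341, 357) support its mono-, di- and tri-methylation activity.
#'
#' @param sequence Reference amino-acid sequence (one-letter upper case).
#' @param tyr_positions Strictly increasing 1-based positions, each
#'   indexing a `Y` in `sequence`.
#' @param motif_regions Optional named list of `list(start =, text =)`.
#' @return An object of class `reference_annotation`.
#' @export
reference_annotation <- function(sequence, tyr_positions,
                                 motif_regions = NULL) {
  sequence <- toupper(sequence)
  tyr_positions <- as.integer(tyr_positions)
  stopifnot(nchar(sequence) > 0, length(tyr_positions) >= 1L,
            all(diff(tyr_positions) > 0),
            all(tyr_positions >= 1L), all(tyr_positions <= nchar(sequence)))
  res <- substring(sequence, tyr_positions, tyr_positions)
  if (any(res != "Y")) {
    stop(sprintf("position(s) %s do not index a tyrosine",
                 paste(tyr_positions[res != "Y"], collapse = ", ")))
  }
  structure(list(sequence = sequence, catalytic_tyr_positions = tyr_positions,
                 motif_regions = motif_regions),
            class = "reference_annotation")
}

#' Global pairwise alignment with per-position correspondence map
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gap penalties,
#' computed with \pkg{Biostrings}. Returns the alignment score and a map
#' giving, for every reference position, the aligned query residue and
#' its 1-based query position (`NA` for a gap).
#'
#' @param query,reference Amino-acid sequences (standard residues).
#' @param substitution_matrix Scoring matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs;
#'   defaults 10 and 0.5).
#' @return A list with `score`, `aligned_query`, `aligned_reference`
#'   (gapped strings) and `map` (`data.frame(ref_pos, ref_res, query_pos,
#'   query_res)`).
#' @export
global_align <- function(query, reference, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  query <- toupper(query); reference <- toupper(reference)
  if (!nchar(query) || !nchar(reference)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- cumsum(qa != "-")
  rpos <- cumsum(ra != "-")
  ref_cols <- which(ra != "-")
  map <- data.frame(
    ref_pos = rpos[ref_cols],
    ref_res = ra[ref_cols],
    query_pos = ifelse(qa[ref_cols] == "-", NA_integer_, qpos[ref_cols]),
    query_res = ifelse(qa[ref_cols] == "-", NA_character_, qa[ref_cols]),
    stringsAsFactors = FALSE)
  list(score = Biostrings::score(aln),
       aligned_query = paste(qa, collapse = ""),
       aligned_reference = paste(ra, collapse = ""),
       map = map)
}

# Admissible methylation-state transitions given n conserved catalytic
# tyrosines: each conserved tyrosine supports one deprotonation, hence one
# methyl-transfer step. All three conserved -> the full me0->me3 cascade;
# two -> either pair of consecutive steps; one -> one of the three single
# steps; zero -> none. Returned as a list of alternative transition sets.
capacity_hypotheses <- function(n) {
  steps <- c("me0->me1", "me1->me2", "me2->me3")
  switch(as.character(n),
         "3" = list(steps),
         "2" = list(steps[1:2], steps[2:3]),
         "1" = list(steps[1], steps[2], steps[3]),
         "0" = list())
}

#' Profile catalytic tyrosine conservation of a query methyltransferase
#'
#' Globally aligns the query against an annotated reference and counts how
#' many of the reference's active-site catalytic tyrosines align to a
#' tyrosine in the query. The predicted methylation capacity equals that
#' count (each conserved tyrosine supports one lysine-deprotonation /
#' methyl-transfer step), and `capacity_hypotheses` enumerates the
#' admissible substrate methylation-state transitions as alternative sets.
#'
#' @param query Query amino-acid sequence.
#' @param reference A [reference_annotation()].
#' @param query_id Identifier recorded in the profile.
#' @param ... Alignment parameters passed to [global_align()].
#' @return An object of class `catalytic_profile` with `query_id`,
#'   `aligned_residues` (one row per reference catalytic position),
#'   `n_conserved_tyr`, `predicted_capacity` and `capacity_hypotheses`.
#' @export
profile_query <- function(query, reference, query_id = "query", ...) {
  stopifnot(inherits(reference, "reference_annotation"))
  aln <- global_align(query, reference$sequence, ...)
  pos <- reference$catalytic_tyr_positions
  rows <- aln$map[match(pos, aln$map$ref_pos), , drop = FALSE]
  n_cons <- sum(!is.na(rows$query_res) & rows$query_res == "Y")
  structure(list(query_id = query_id,
                 aligned_residues = data.frame(
                   ref_pos = pos, ref_res = rows$ref_res,
                   query_pos = rows$query_pos, query_res = rows$query_res,
                   conserved = !is.na(rows$query_res) & rows$query_res == "Y",
                   stringsAsFactors = FALSE),
                 n_conserved_tyr = n_cons,
                 predicted_capacity = n_cons,
                 capacity_hypotheses = capacity_hypotheses(n_cons),
                 alignment_score = aln$score),
            class = "catalytic_profile")
}

#' Scan a sequence for SET-domain signature motifs
#'
#' Two signature motifs of SET-domain methyltransferase substrates/
#' cofactor binding are searched (x = any standard residue):
#' \itemize{
#'   \item `ELxF/YDY`: `E-L-x-(F|Y)-D-Y` (the slash marks alternatives at
#'     the fourth symbol);
#'   \item `NHS/CxxPN`: `N-H-(S|C)-x-x-P-N` (alternatives at the third).
#' }
#' All occurrences, including overlapping ones, are reported with 1-based
#' start positions.
#'
#' @param query Amino-acid sequence.
#' @return A `data.frame(motif_id, start, matched_text)`, zero rows if no
#'   hit.
#' @export
scan_motifs <- function(query) {
  query <- toupper(query)
  x <- paste0("[", paste(STANDARD_AA, collapse = ""), "]")
  motifs <- list(
    "ELxF/YDY" = list(pattern = paste0("EL", x, "[FY]DY"), width = 6L),
    "NHS/CxxPN" = list(pattern = paste0("NH[SC]", x, x, "PN"), width = 7L))
  hits <- lapply(names(motifs), function(id) {
    m <- motifs[[id]]
    # lookahead so overlapping occurrences are all found
    starts <- gregexpr(paste0("(?=", m$pattern, ")"), query, perl = TRUE)[[1]]
    if (starts[1] == -1) return(NULL)
    data.frame(motif_id = id, start = as.integer(starts),
               matched_text = substring(query, starts, starts + m$width - 1L),
               stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(motif_id = character(), start = integer(),
                      matched_text = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$motif_id), , drop = FALSE]
}
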