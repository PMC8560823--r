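# Epitope conservation across receptor orthologs and paralogs.
#
# Global pairwise alignment is delegated to Biostrings; identity is reported
# over aligned columns where neither sequence has a gap (the documented
# denominator convention).

#' Alignment scoring scheme
#'
#' Either a named substitution matrix (default BLOSUM62) or a simple
#' match/mismatch scheme, with affine gap costs (both given as non-negative
#' penalties).
#'
#' @param matrix name of a packaged substitution matrix (e.g. "BLOSUM62"), or
#'   `NULL` to use `match`/`mismatch`.
#' @param match,mismatch simple scoring used when `matrix` is `NULL`.
#' @param gap_open,gap_extend affine gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(matrix = "BLOSUM62", match = 1, mismatch = -1,
                          gap_open = 10, gap_extend = 0.5) {
  structure(list(matrix = matrix, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' @keywords internal
scoring_matrix <- function(scoring) {
  if (!is.null(scoring$matrix)) {
    e <- new.env()
    utils::data(list = scoring$matrix, package = "Biostrings", envir = e)
    return(get(scoring$matrix, envir = e))
  }
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V", "X")
  m <- matrix(scoring$mismatch, length(aa), length(aa),
              dimnames = list(aa, aa))
  diag(m) <- scoring$match
  m
}

#' Optimal global pairwise alignment
#'
#' End-to-end (Needleman-Wunsch) alignment with affine gaps. Identity is the
#' percentage of identical residues over aligned columns where neither
#' sequence is gapped.
#'
#' @param a,b [seq_record()]s or plain character sequences (non-empty).
#' @param scoring an [align_scoring()].
#' @return list of class `pairwise_alignment`: ids, gapped `aligned_a` /
#'   `aligned_b`, `score`, `identity_pct` and `column_map` (data.frame of
#'   matched columns with 1-based positions `pos_a`, `pos_b` into the ungapped
#'   sequences).
#' @export
align_pair <- function(a, b, scoring = align_scoring()) {
  as_rec <- function(s, id) if (inherits(s, "seq_record")) s
    else seq_record(id, s)
  a <- as_rec(a, "seq_a"); b <- as_rec(b, "seq_b")
  if (!nchar(a$residues) || !nchar(b$residues))
    stop("empty sequence: both inputs must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    a$residues, b$residues, type = "global",
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  pos_a <- cumsum(ca != "-")
  pos_b <- cumsum(cb != "-")
  both <- ca != "-" & cb != "-"
  identity <- if (any(both)) 100 * mean(ca[both] == cb[both]) else 0
  structure(list(
    seq_a_id = a$id, seq_b_id = b$id, aligned_a = al_a, aligned_b = al_b,
    score = Biostrings::score(pa), identity_pct = identity,
    column_map = data.frame(column = which(both), pos_a = pos_a[both],
                            pos_b = pos_b[both]),
    seq_a = a, seq_b = b), class = "pairwise_alignment")
}

#' @keywords internal
resno_to_index <- function(rec, positions) {
  idx <- match(positions, rec$numbering$resno)
  names(idx) <- positions
  idx
}

#' Epitope conservation across species
#'
#' For each aligned species, splits the reference epitope positions into
#' conserved and substituted sets; cross-reactivity is predicted iff every
#' epitope position is strictly conserved (positions outside alignment
#' coverage are reported uncovered and count against the prediction, never
#' silently conserved).
#'
#' @param ref reference [seq_record()] (numbering carries the epitope residue
#'   numbers).
#' @param epitope_positions reference residue numbers of the epitope.
#' @param alignments named list of [align_pair()] results with the reference
#'   as `seq_a`.
#' @return list of class `conservation_report`: `epitope_positions` and
#'   `per_species` (each with `conserved`, `substituted` data.frame,
#'   `uncovered`, `predicted_cross_reactive`).
#' @export
epitope_conservation <- function(ref, epitope_positions, alignments) {
  if (!length(epitope_positions)) {
    warning("empty epitope list: prediction is vacuously cross-reactive")
    per <- lapply(alignments, function(al) list(
      conserved = integer(), substituted = data.frame(
        position = integer(), ref_aa = character(), other_aa = character()),
      uncovered = integer(), predicted_cross_reactive = TRUE))
    return(structure(list(epitope_positions = epitope_positions,
                          per_species = per),
                     class = "conservation_report"))
  }
  idx <- resno_to_index(ref, epitope_positions)
  if (anyNA(idx))
    stop("epitope position(s) not in reference numbering: ",
         paste(epitope_positions[is.na(idx)], collapse = ", "))
  per <- lapply(alignments, function(al) {
    map <- al$column_map
    ra <- strsplit(gsub("-", "", al$aligned_a), "")[[1]]
    rb <- strsplit(gsub("-", "", al$aligned_b), "")[[1]]
    cons <- integer(); unc <- integer()
    sub <- data.frame(position = integer(), ref_aa = character(),
                      other_aa = character(), stringsAsFactors = FALSE)
    for (k in seq_along(epitope_positions)) {
      p <- epitope_positions[k]
      row <- map[map$pos_a == idx[k], , drop = FALSE]
      if (!nrow(row)) { unc <- c(unc, p); next }
      aa_ref <- ra[row$pos_a[1]]; aa_oth <- rb[row$pos_b[1]]
      if (aa_ref == aa_oth) cons <- c(cons, p)
      else sub <- rbind(sub, data.frame(position = p, ref_aa = aa_ref,
                                        other_aa = aa_oth,
                                        stringsAsFactors = FALSE))
    }
    list(conserved = cons, substituted = sub, uncovered = unc,
         predicted_cross_reactive = !nrow(sub) && !length(unc))
  })
  structure(list(epitope_positions = epitope_positions, per_species = per),
            class = "conservation_report")
}

#' Overall and epitope-restricted identity to a paralog
#'
#' Aligns the two sequences and reports the identity over all aligned columns
#' and over the epitope columns only.
#'
#' @param a reference [seq_record()] (carries the epitope numbering).
#' @param b paralog [seq_record()] or character sequence.
#' @param epitope_positions residue numbers (reference numbering).
#' @param scoring an [align_scoring()].
#' @return list with `overall_identity_pct` and `epitope_identity_pct`.
#' @export
paralog_similarity <- function(a, b, epitope_positions,
                               scoring = align_scoring()) {
  al <- align_pair(a, b, scoring)
  idx <- resno_to_index(al$seq_a, epitope_positions)
  ra <- strsplit(gsub("-", "", al$aligned_a), "")[[1]]
  rb <- strsplit(gsub("-", "", al$aligned_b), "")[[1]]
  map <- al$column_map
  rows <- map[map$pos_a %in% idx, , drop = FALSE]
  epi <- if (length(epitope_positions))
    100 * sum(ra[rows$pos_a] == rb[rows$pos_b]) / length(epitope_positions)
  else NA_real_
  list(overall_identity_pct = al$identity_pct, epitope_identity_pct = epi)
}
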