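# IMGT-style Fv numbering, CDR grafting and structure-guided back-mutation
# flagging.
#
# The V-region frame is the IMGT unique numbering: FR1 1-26, CDR1 27-38,
# FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 105-117 (insertions 111.x/112.x for
# long loops), FR4 118-128. Numbering is obtained by aligning a query to the
# best-matching gapped germline and inheriting its frame; loops whose length
# differs from the germline's are renumbered by the IMGT symmetric fill
# (positions taken from both ends of the span toward the middle).

IMGT_REGIONS <- list(FR1 = c(1, 26), CDR1 = c(27, 38), FR2 = c(39, 55),
                     CDR2 = c(56, 65), FR3 = c(66, 104), CDR3 = c(105, 117),
                     FR4 = c(118, 128))

#' Region of an IMGT position label
#' @param label character position label(s), e.g. "34" or "111.1".
#' @return character region name(s) (FR1..FR4, CDR1..CDR3).
#' @export
imgt_region <- function(label) {
  v <- suppressWarnings(as.numeric(label))
  out <- rep(NA_character_, length(v))
  for (nm in names(IMGT_REGIONS)) {
    r <- IMGT_REGIONS[[nm]]
    out[!is.na(v) & v >= r[1] & v < r[2] + 1] <- nm
  }
  out
}

#' @keywords internal
imgt_fill <- function(region, len) {
  span <- IMGT_REGIONS[[region]]
  width <- span[2] - span[1] + 1
  if (len <= width) {
    nf <- ceiling(len / 2); nb <- len - nf
    return(as.character(c(seq(span[1], length.out = nf),
                          if (nb) seq(span[2] - nb + 1, span[2]))))
  }
  if (region != "CDR3")
    stop(region, " longer than its numbering span (", len, " > ", width, ")")
  extra <- len - width
  n111 <- ceiling(extra / 2); n112 <- extra - n111
  c(as.character(105:111), paste0("111.", seq_len(n111)),
    if (n112) rev(paste0("112.", seq_len(n112))), as.character(112:117))
}

#' Germline V-gene record on the gapped IMGT frame
#'
#' @param gene_name gene and allele, e.g. `"SYNGHV1-1*01"`.
#' @param species species label.
#' @param gapped_sequence one-letter string of length 104 covering IMGT
#'   positions 1-104, with `.` (or `-`) at unoccupied positions.
#' @return list of class `germline_record`.
#' @export
germline_record <- function(gene_name, species, gapped_sequence) {
  gapped_sequence <- toupper(gsub("-", ".", gapped_sequence))
  if (nchar(gapped_sequence) != 104)
    stop("gapped germline must cover IMGT positions 1-104 (length 104), got ",
         nchar(gapped_sequence))
  structure(list(gene_name = gene_name, species = species,
                 gapped_sequence = gapped_sequence),
            class = "germline_record")
}

#' @keywords internal
germline_slots <- function(g) which(strsplit(g$gapped_sequence, "")[[1]] != ".")

#' Ungapped sequence of a germline record
#' @param g a [germline_record()].
#' @return the one-letter sequence without frame gaps.
#' @export
germline_ungapped <- function(g) gsub("\\.", "", g$gapped_sequence)

#' Residues of a germline record keyed by IMGT position
#' @param g a [germline_record()].
#' @return named character vector (names: occupied IMGT positions).
#' @export
germline_letters <- function(g) {
  ch <- strsplit(g$gapped_sequence, "")[[1]]
  stats::setNames(ch[ch != "."], as.character(which(ch != ".")))
}

#' Number an antibody variable domain on the IMGT frame
#'
#' Aligns the query to each reference germline, inherits the frame of the
#' best-matching one, renumbers loops of non-germline length by the IMGT
#' symmetric fill, and numbers any post-FR3 tail as CDR3 (+ an 11-residue FR4
#' when present). Deterministic. Queries matching no reference at >= 40%
#' identity are rejected.
#'
#' @param fv a [seq_record()] or character sequence (80-140 residues).
#' @param chain_type `"heavy"` or `"light"`.
#' @param reference_set list of [germline_record()]s.
#' @param scoring an [align_scoring()].
#' @return list of class `numbered_fv`: `chain_type`, `sequence`, `positions`
#'   (character IMGT labels, parallel to the sequence), `regions`,
#'   `cdr_spans` (per CDR, the labels it occupies), `germline` (gene name of
#'   the inherited frame) and `germline_identity_pct`.
#' @export
imgt_number <- function(fv, chain_type = c("heavy", "light"), reference_set,
                        scoring = align_scoring()) {
  chain_type <- match.arg(chain_type)
  if (inherits(fv, "seq_record")) fv <- fv$residues
  n <- nchar(fv)
  if (n < 80 || n > 140)
    stop("not a plausible V region: length ", n, " outside 80-140")
  stopifnot(length(reference_set) >= 1)
  als <- lapply(reference_set, function(g)
    align_pair(fv, germline_ungapped(g), scoring))
  ids <- vapply(als, function(a) a$identity_pct, numeric(1))
  if (max(ids) < 40)
    stop("not an antibody V region: best germline identity ",
         round(max(ids), 1), "% < 40%")
  best <- which.max(ids)
  g <- reference_set[[best]]
  al <- als[[best]]
  slots <- germline_slots(g)               # germline index -> frame position
  ca <- strsplit(al$aligned_a, "")[[1]]
  cb <- strsplit(al$aligned_b, "")[[1]]
  ia <- cumsum(ca != "-"); ib <- cumsum(cb != "-")
  prov <- rep(NA_real_, n)                 # provisional frame slot per residue
  for (k in seq_along(ca))
    if (ca[k] != "-" && cb[k] != "-") prov[ia[k]] <- slots[ib[k]]
  covered <- which(!is.na(prov))
  if (!length(covered)) stop("alignment covers no frame positions")
  last_cov <- max(covered)
  # insertions inside the frame: admissible only within a CDR
  ins_region <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.na(prov[i]) || i > last_cov) next
    left <- if (any(covered < i)) prov[max(covered[covered < i])] else NA
    right <- prov[min(covered[covered > i])]
    reg_l <- if (is.na(left)) NA else imgt_region(left)
    reg_r <- imgt_region(right)
    reg <- if (!is.na(reg_l) && grepl("CDR", reg_l)) reg_l
    else if (grepl("CDR", reg_r)) reg_r
    else stop("insertion relative to the germline frame inside a framework ",
              "region (near position ", right, "): unsupported")
    ins_region[i] <- reg
  }
  labels <- as.character(prov)
  # renumber CDR1/2 segments that gained or lost residues vs the germline
  for (reg in c("CDR1", "CDR2")) {
    span <- IMGT_REGIONS[[reg]]
    seg <- which((!is.na(prov) & prov >= span[1] & prov <= span[2] &
                    seq_len(n) <= last_cov) |
                   (!is.na(ins_region) & ins_region == reg))
    if (!length(seg)) next
    if (any(diff(seg) != 1)) stop("non-contiguous ", reg, " segment")
    g_len <- sum(slots >= span[1] & slots <= span[2])
    if (length(seg) != g_len || anyNA(prov[seg]))
      labels[seg] <- imgt_fill(reg, length(seg))
  }
  # tail beyond the germline frame: CDR3 (+ FR4 when long enough)
  tail_idx <- if (last_cov < n) (last_cov + 1):n else integer()
  if (length(tail_idx)) {
    tl <- length(tail_idx)
    if (tl >= 13) {
      cdr3 <- tail_idx[seq_len(tl - 11)]
      fr4 <- tail_idx[(tl - 10):tl]
      labels[cdr3] <- imgt_fill("CDR3", length(cdr3))
      labels[fr4] <- as.character(118:128)
    } else {
      labels[tail_idx] <- imgt_fill("CDR3", tl)
    }
  }
  if (anyNA(labels)) stop("unnumbered residues remain (frame gap)")
  regions <- imgt_region(labels)
  structure(list(
    chain_type = chain_type, sequence = fv, positions = labels,
    regions = regions,
    cdr_spans = lapply(c(CDR1 = "CDR1", CDR2 = "CDR2", CDR3 = "CDR3"),
                       function(r) labels[regions == r]),
    germline = g$gene_name, germline_identity_pct = ids[best]),
    class = "numbered_fv")
}

#' @export
print.numbered_fv <- function(x, ...) {
  cat("Numbered", x$chain_type, "V region (", nchar(x$sequence), "aa,",
      "frame:", x$germline, ")\n")
  cat(x$sequence, "\n")
  for (r in names(x$cdr_spans))
    cat(r, ": ", paste(strsplit(x$sequence, "")[[1]][x$regions == r],
                       collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Sequence identity between a numbered Fv and a germline
#'
#' Identity over shared numbered positions (frame positions occupied in both;
#' gaps excluded from the denominator). Reported for all shared positions and,
#' as the alternative convention, over framework positions only.
#'
#' @param fv a `numbered_fv`.
#' @param germline a [germline_record()] on the same frame.
#' @return list with `identity_pct`, `identity_fr_pct`, `n_shared`,
#'   `n_matches`.
#' @export
germline_identity <- function(fv, germline) {
  stopifnot(inherits(fv, "numbered_fv"), inherits(germline, "germline_record"))
  gl <- germline_letters(germline)
  shared <- intersect(fv$positions, names(gl))
  if (!length(shared)) stop("frame mismatch: no shared numbered positions")
  fchr <- strsplit(fv$sequence, "")[[1]]
  fv_at <- stats::setNames(fchr, fv$positions)[shared]
  match_v <- fv_at == gl[shared]
  fr <- grepl("^FR", imgt_region(shared))
  list(identity_pct = 100 * mean(match_v),
       identity_fr_pct = if (any(fr)) 100 * mean(match_v[fr]) else NA_real_,
       n_shared = length(shared), n_matches = sum(match_v))
}

#' Select the framework donor germline by highest identity
#'
#' @param fv a [seq_record()] or character V-region sequence.
#' @param candidates list of [germline_record()]s (non-empty).
#' @param scoring an [align_scoring()].
#' @return the winning [germline_record()], with the identity attached as
#'   attribute `identity_pct`. Exact ties go to the lexicographically first
#'   gene name, with a warning.
#' @export
select_germline <- function(fv, candidates, scoring = align_scoring()) {
  if (!length(candidates)) stop("empty candidate set")
  if (inherits(fv, "seq_record")) fv <- fv$residues
  ids <- vapply(candidates, function(g)
    align_pair(fv, germline_ungapped(g), scoring)$identity_pct, numeric(1))
  top <- which(ids == max(ids))
  if (length(top) > 1) {
    nms <- vapply(candidates[top], function(g) g$gene_name, "")
    warning("identity tie between ", paste(nms, collapse = ", "),
            ": keeping the lexicographically first")
    top <- top[order(nms)][1]
  }
  out <- candidates[[top]]
  attr(out, "identity_pct") <- ids[top]
  out
}

#' Graft parental CDRs onto a germline framework donor
#'
#' Framework positions come from the donor, CDR1/CDR2 (and the whole
#' CDR3/FR4 tail, which germline V genes do not cover) from the parent.
#' Configured flank positions are forced to the parental residue after
#' grafting and recorded when that changes a donor framework letter.
#'
#' @param parent a `numbered_fv` (from [imgt_number()]).
#' @param donor a [germline_record()].
#' @param flank_rules integer/character vector of IMGT positions where the
#'   parental residue is retained (default none).
#' @return list of class `graft_result`: `grafted` (`numbered_fv`), `donor`,
#'   `source_cdrs`, `flank_substitutions` (data.frame position/donor_aa/
#'   parent_aa).
#' @export
graft_cdrs <- function(parent, donor, flank_rules = NULL) {
  stopifnot(inherits(parent, "numbered_fv"), inherits(donor, "germline_record"))
  gl <- germline_letters(donor)
  gl_fr <- gl[grepl("^FR", imgt_region(names(gl)))]
  if (!length(gl_fr)) stop("donor frame incompatible: no framework positions")
  pchr <- stats::setNames(strsplit(parent$sequence, "")[[1]], parent$positions)
  keep_cdr <- parent$positions[grepl("CDR", parent$regions) |
                                 parent$regions == "FR4"]
  low <- c(stats::setNames(unname(gl_fr), names(gl_fr)),
           pchr[keep_cdr[as.numeric(keep_cdr) <= 104]])
  low <- low[order(as.numeric(names(low)))]
  tail_lab <- parent$positions[as.numeric(parent$positions) >= 105]
  seq_chr <- c(low, pchr[tail_lab])
  labels <- names(seq_chr)
  flank_sub <- data.frame(position = character(), donor_aa = character(),
                          parent_aa = character(), stringsAsFactors = FALSE)
  for (p in as.character(flank_rules)) {
    if (!p %in% labels || !p %in% names(pchr)) next
    if (seq_chr[p] != pchr[p]) {
      flank_sub <- rbind(flank_sub, data.frame(
        position = p, donor_aa = unname(seq_chr[p]),
        parent_aa = unname(pchr[p]), stringsAsFactors = FALSE))
      seq_chr[p] <- pchr[p]
    }
  }
  regions <- imgt_region(labels)
  grafted <- structure(list(
    chain_type = parent$chain_type,
    sequence = paste(seq_chr, collapse = ""),
    positions = labels, regions = regions,
    cdr_spans = lapply(c(CDR1 = "CDR1", CDR2 = "CDR2", CDR3 = "CDR3"),
                       function(r) labels[regions == r]),
    germline = donor$gene_name, germline_identity_pct = NA_real_),
    class = "numbered_fv")
  structure(list(grafted = grafted, donor = donor,
                 source_cdrs = lapply(parent$cdr_spans, function(sp)
                   paste(pchr[sp], collapse = "")),
                 flank_substitutions = flank_sub),
            class = "graft_result")
}

#' @keywords internal
min_dist_to <- function(from, to) {
  if (!nrow(from) || !nrow(to)) return(Inf)
  min(atom_distances(from, to))
}

#' Flag framework positions for back mutation on a structural template
#'
#' For every framework position where the graft differs from the parent, the
#' parental residue's side chain is inspected in the template: it is flagged
#' when within `antigen` of the antigen chain (rationale `antigen_contact`),
#' within `pairing` of the partner V domain (`vh_vl_interface`), or within
#' `cdr` of any CDR atom of either chain (`cdr_support`). All triggered
#' rationales are reported; the primary one is the first in that order.
#'
#' @param graft a `graft_result` (or `numbered_fv` of the grafted chain).
#' @param parent the parental `numbered_fv`.
#' @param template a `tie2ab_structure` containing the parental Fv (and
#'   antigen, when bound).
#' @param chain_map list with `fv_chain`, `partner_chain`, `antigen_chain`
#'   (may be `NA`), `position_map` (data.frame `imgt` label -> template
#'   `resno`) and `cdr_resnos` (named list: template residue numbers of the
#'   CDRs for `fv` and `partner`).
#' @param cutoffs heavy-atom distance cutoffs in Angstrom
#'   (default 4.5/4.5/4.5).
#' @return data.frame with `chain_type`, `imgt_position`, `from_aa`
#'   (humanized), `to_aa` (parental), `rationale` (primary), `rationales`.
#' @export
flag_back_mutations <- function(graft, parent, template, chain_map,
                                cutoffs = list(antigen = 4.5, pairing = 4.5,
                                               cdr = 4.5)) {
  g <- if (inherits(graft, "graft_result")) graft$grafted else graft
  stopifnot(inherits(g, "numbered_fv"), inherits(parent, "numbered_fv"),
            inherits(template, "tie2ab_structure"))
  need <- c("fv_chain", "partner_chain", "antigen_chain", "position_map",
            "cdr_resnos")
  if (!all(need %in% names(chain_map)))
    stop("chain_map incomplete: needs ", paste(need, collapse = ", "))
  gchr <- stats::setNames(strsplit(g$sequence, "")[[1]], g$positions)
  pchr <- stats::setNames(strsplit(parent$sequence, "")[[1]],
                          parent$positions)
  fr_pos <- intersect(names(gchr)[grepl("^FR", imgt_region(names(gchr)))],
                      names(pchr))
  diff_pos <- fr_pos[gchr[fr_pos] != pchr[fr_pos]]
  tmpl_fv <- template[template$chain == chain_map$fv_chain, , drop = FALSE]
  partner <- template[template$chain == chain_map$partner_chain, ,
                      drop = FALSE]
  antigen <- if (!is.na(chain_map$antigen_chain))
    template[template$chain == chain_map$antigen_chain, , drop = FALSE]
  else template[0, , drop = FALSE]
  cdr_atoms <- rbind(
    tmpl_fv[tmpl_fv$resno %in% chain_map$cdr_resnos$fv, , drop = FALSE],
    partner[partner$resno %in% chain_map$cdr_resnos$partner, , drop = FALSE])
  rows <- list()
  for (p in diff_pos) {
    resno <- chain_map$position_map$resno[chain_map$position_map$imgt == p]
    if (!length(resno))
      stop("chain_map incomplete: no template residue for position ", p)
    res_atoms <- tmpl_fv[tmpl_fv$resno == resno, , drop = FALSE]
    sc <- res_atoms[!(res_atoms$elety %in% MAINCHAIN_ATOMS), , drop = FALSE]
    if (!nrow(sc)) sc <- res_atoms
    hits <- c(
      antigen_contact = min_dist_to(sc, antigen) <= cutoffs$antigen,
      vh_vl_interface = min_dist_to(sc, partner) <= cutoffs$pairing,
      cdr_support = min_dist_to(
        sc, cdr_atoms[!(cdr_atoms$chain == chain_map$fv_chain &
                          cdr_atoms$resno == resno), , drop = FALSE]) <=
        cutoffs$cdr)
    if (!any(hits)) next
    rows[[p]] <- data.frame(
      chain_type = g$chain_type, imgt_position = p,
      from_aa = unname(gchr[p]), to_aa = unname(pchr[p]),
      rationale = names(hits)[hits][1],
      rationales = paste(names(hits)[hits], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chain_type = character(), imgt_position = character(),
                      from_aa = character(), to_aa = character(),
                      rationale = character(), rationales = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply back mutations to a grafted variable domain
#'
#' Mutations are given on IMGT positions (e.g. `"G34N"`: G at position 34
#' becomes N); the current letter must match, otherwise the position is named
#' in the error.
#'
#' @param graft a `graft_result` or `numbered_fv`.
#' @param mutations character vector like `c("G34N", "Y36L")`, or the
#'   data.frame returned by [flag_back_mutations()].
#' @return the mutated `numbered_fv`.
#' @export
build_variant <- function(graft, mutations) {
  g <- if (inherits(graft, "graft_result")) graft$grafted else graft
  stopifnot(inherits(g, "numbered_fv"))
  if (is.data.frame(mutations) && nrow(mutations))
    mutations <- paste0(mutations$from_aa, mutations$imgt_position,
                        mutations$to_aa)
  if (!length(mutations) ||
      (is.data.frame(mutations) && !nrow(mutations))) return(g)
  mut <- parse_mutations(mutations)
  chr <- strsplit(g$sequence, "")[[1]]
  for (i in seq_len(nrow(mut))) {
    idx <- which(g$positions == as.character(mut$pos[i]))
    if (length(idx) != 1)
      stop("IMGT position ", mut$pos[i], " not present in the graft")
    if (chr[idx] != mut$wild[i])
      stop("mismatch at IMGT position ", mut$pos[i], ": expected ",
           mut$wild[i], ", observed ", chr[idx])
    chr[idx] <- mut$new[i]
  }
  g$sequence <- paste(chr, collapse = "")
  g
}
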