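# Coordinate data model and PDB I/O.
#
# A structure is a plain data.frame of atoms (one row per atom) carrying the
# columns chain, resno, ins, resid, elety, element, x, y, z, o, b. Residue
# numbering is always the author numbering of the source file; no renumbering
# is ever performed implicitly. Insertion codes are carried but never used for
# arithmetic.

STRUCTURE_COLS <- c("chain", "resno", "ins", "resid", "elety", "element",
                    "x", "y", "z", "o", "b")

#' Construct an atomic structure table
#'
#' Validates and normalises a data.frame of atom records into the structure
#' container used throughout the package.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid` (3-letter
#'   residue code), `elety` (atom name), `x`, `y`, `z`; optional `ins`
#'   (insertion code, default `""`), `element` (derived from `elety` when
#'   absent), `o` (occupancy, default 1) and `b` (B-factor, default 0).
#' @return data.frame of class `tie2ab_structure`.
#' @export
structure_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("missing atom columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("empty structure: no atoms")
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$element) || any(is.na(atoms$element)) ||
      any(!nzchar(atoms$element)))
    atoms$element <- guess_element(atoms$elety, atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  atoms <- atoms[, STRUCTURE_COLS]
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, resno, ins, atom name): ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  class(atoms) <- c("tie2ab_structure", "data.frame")
  atoms
}

#' @keywords internal
guess_element <- function(elety, element = NULL) {
  out <- if (is.null(element)) rep(NA_character_, length(elety)) else element
  fix <- is.na(out) | !nzchar(out)
  nm <- toupper(trimws(elety[fix]))
  # strip leading digits (hydrogens such as 1HB), then take the leading
  # letters; two-letter elements in proteins are rare (SE of MSE handled)
  nm <- sub("^[0-9]+", "", nm)
  first <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el <- ifelse(two == "SE", "SE", first)
  out[fix] <- el
  out
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM (and optionally HETATM) records via \pkg{bio3d}. Alternate
#' locations are resolved to the highest-occupancy conformer (ties broken by
#' the alphabetically first altloc identifier). Waters and heteroatoms are
#' excluded by default. Multi-model (NMR-style) files are rejected.
#'
#' @param path path to a PDB-format file.
#' @param keep_hetero keep HETATM records (default `FALSE`).
#' @param keep_waters keep water molecules (default `FALSE`).
#' @return a `tie2ab_structure`.
#' @export
read_structure <- function(path, keep_hetero = FALSE, keep_waters = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (sum(grepl("^MODEL", lines)) > 1)
    stop("multi-model PDB file: this reader handles single-model entries; ",
         "split the models and supply one")
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec)) stop("empty model: no ATOM/HETATM records in ", path)
  for (i in rec) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))))
      stop("malformed fixed-width record at line ", i)
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!keep_waters)
    at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!nrow(at)) stop("empty model: no atoms after filtering")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: keep highest occupancy, ties -> alphabetically first altloc id
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
             drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  structure_atoms(data.frame(
    chain = at$chain, resno = at$resno, ins = at$insert, resid = at$resid,
    elety = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                     NA_character_, toupper(trimws(at$elesy))),
    x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
    stringsAsFactors = FALSE))
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM records (coordinates at the format's 3-decimal
#' precision) followed by END.
#'
#' @param x a `tie2ab_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "tie2ab_structure"))
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(x)),
    ifelse(nchar(x$elety) >= 4, x$elety, paste0(" ", x$elety)),
    " ", x$resid, x$chain, x$resno, ifelse(nzchar(x$ins), x$ins, " "),
    x$x, x$y, x$z, x$o, x$b, x$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Atom selection specification
#'
#' @param chains character vector of chain identifiers, or `NULL` for all.
#' @param residue_ranges list of length-2 numeric vectors `c(start, end)`
#'   (inclusive, author residue numbers), or `NULL` for all.
#' @param atom_class one of `"all"`, `"heavy"`, `"mainchain"`, `"sidechain"`.
#' @return a list of class `selection`.
#' @export
selection <- function(chains = NULL, residue_ranges = NULL,
                      atom_class = c("all", "heavy", "mainchain",
                                     "sidechain")) {
  atom_class <- match.arg(atom_class)
  if (!is.null(residue_ranges)) {
    if (!is.list(residue_ranges)) residue_ranges <- list(residue_ranges)
    for (r in residue_ranges) {
      if (length(r) != 2 || r[1] > r[2])
        stop("residue range must be c(start, end) with start <= end")
    }
  }
  structure(list(chains = chains, residue_ranges = residue_ranges,
                 atom_class = atom_class), class = "selection")
}

MAINCHAIN_ATOMS <- c("N", "CA", "C", "O")

#' Select a sub-structure
#'
#' Applies a [selection()] to a structure. Selection is idempotent; requesting
#' an absent chain yields an empty selection with a warning, not an error.
#'
#' @param x a `tie2ab_structure`.
#' @param spec a [selection()], or `NULL` for the identity selection.
#' @return the selected `tie2ab_structure` (possibly zero rows).
#' @export
select_atoms <- function(x, spec = selection()) {
  stopifnot(inherits(x, "tie2ab_structure"))
  if (is.null(spec)) return(x)
  keep <- rep(TRUE, nrow(x))
  if (!is.null(spec$chains)) {
    absent <- setdiff(spec$chains, unique(x$chain))
    if (length(absent))
      warning("chain(s) not present: ", paste(absent, collapse = ", "))
    keep <- keep & x$chain %in% spec$chains
  }
  if (!is.null(spec$residue_ranges)) {
    inr <- rep(FALSE, nrow(x))
    for (r in spec$residue_ranges) inr <- inr | (x$resno >= r[1] & x$resno <= r[2])
    keep <- keep & inr
  }
  keep <- keep & switch(spec$atom_class,
    all = TRUE,
    heavy = x$element != "H",
    mainchain = x$elety %in% MAINCHAIN_ATOMS,
    sidechain = !(x$elety %in% MAINCHAIN_ATOMS) & x$element != "H")
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tie2ab_structure", "data.frame")
  out
}

# 3-letter -> 1-letter residue codes; anything else is X
AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Sequence record with explicit numbering
#'
#' @param id record identifier.
#' @param residues one-letter amino-acid string (unknowns as `X`).
#' @param numbering data.frame with columns `resno` and `ins` parallel to the
#'   sequence; defaults to 1..n with empty insertion codes.
#' @return list of class `seq_record`.
#' @export
seq_record <- function(id, residues, numbering = NULL) {
  residues <- toupper(residues)
  n <- nchar(residues)
  if (is.null(numbering))
    numbering <- data.frame(resno = seq_len(n), ins = rep("", n),
                            stringsAsFactors = FALSE)
  if (nrow(numbering) != n)
    stop("numbering length (", nrow(numbering),
         ") must equal sequence length (", n, ")")
  structure(list(id = id, residues = residues, numbering = numbering),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(">", x$id, " (", nchar(x$residues), " aa)\n", sep = "")
  cat(x$residues, "\n")
  invisible(x)
}

#' Extract the one-letter sequence of a chain
#'
#' Residues are emitted in residue-number order (insertion codes preserved in
#' the numbering); non-standard residues map to `X`.
#'
#' @param x a `tie2ab_structure`.
#' @param chain chain identifier.
#' @param id record id; defaults to the chain id.
#' @return a [seq_record()].
#' @export
extract_sequence <- function(x, chain, id = chain) {
  stopifnot(inherits(x, "tie2ab_structure"))
  if (!chain %in% x$chain) stop("chain not present: ", chain)
  xs <- x[x$chain == chain, , drop = FALSE]
  xs <- xs[order(xs$resno, xs$ins), , drop = FALSE]
  key <- paste(xs$resno, xs$ins)
  first <- !duplicated(key)
  res <- xs$resid[first]
  aa <- unname(AA_321[res])
  aa[is.na(aa)] <- "X"
  seq_record(id, paste(aa, collapse = ""),
             data.frame(resno = xs$resno[first], ins = xs$ins[first],
                        stringsAsFactors = FALSE))
}

#' @keywords internal
parse_mutations <- function(mutations) {
  if (is.data.frame(mutations)) return(mutations)
  m <- regmatches(mutations,
                  regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", mutations))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed mutation spec: ", mutations[bad][1])
  data.frame(wild = toupper(vapply(m, `[`, "", 2)),
             pos = as.integer(vapply(m, `[`, "", 3)),
             new = toupper(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Apply point mutations to a sequence record
#'
#' Each mutation states the expected wild-type residue; a mismatch aborts with
#' the position and the observed letter, guarding against numbering offsets.
#'
#' @param seq a [seq_record()].
#' @param mutations character vector like `c("D682C", "N691C")`, or a
#'   data.frame with columns `wild`, `pos`, `new`. Positions are residue
#'   numbers of the record's own numbering.
#' @return the mutated [seq_record()] (the input is unchanged).
#' @export
apply_mutations <- function(seq, mutations) {
  stopifnot(inherits(seq, "seq_record"))
  if (!length(mutations)) return(seq)
  mut <- parse_mutations(mutations)
  res <- strsplit(seq$residues, "")[[1]]
  for (i in seq_len(nrow(mut))) {
    idx <- which(seq$numbering$resno == mut$pos[i])
    if (length(idx) != 1)
      stop("position ", mut$pos[i], " not present (or ambiguous) in ", seq$id)
    if (res[idx] != mut$wild[i])
      stop("wild-type mismatch at position ", mut$pos[i], ": expected ",
           mut$wild[i], ", observed ", res[idx])
    res[idx] <- mut$new[i]
  }
  seq_record(seq$id, paste(res, collapse = ""), seq$numbering)
}

#' Pairwise distances between two atom sets
#'
#' @param a,b `tie2ab_structure` tables.
#' @return matrix of Euclidean distances (rows: atoms of `a`).
#' @export
atom_distances <- function(a, b) {
  ma <- as.matrix(a[, c("x", "y", "z")])
  mb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ma^2), rep(1, nrow(mb))) +
    outer(rep(1, nrow(ma)), rowSums(mb^2)) - 2 * ma %*% t(mb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return list of [seq_record()]s.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  lapply(seq_along(ss), function(i)
    seq_record(names(ss)[i], as.character(ss[[i]])))
}

#' Write sequence records to a FASTA file
#' @param records list of [seq_record()]s (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  ss <- Biostrings::AAStringSet(vapply(records, function(r) r$residues, ""))
  names(ss) <- vapply(records, function(r) r$id, "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
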