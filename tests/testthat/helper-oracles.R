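# Independent oracles and small fixture builders shared across the suite.

# Exhaustive global-alignment score with affine gaps (gap of length L costs
# open + L * extend), enumerating every alignment path. Independent of the
# package's alignment route; tractable for sequences up to ~8 residues.
bf_align_score <- function(a, b, submat, gap_open, gap_extend) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(sa) && j > length(sb)) return(0)
    best <- -Inf
    if (i <= length(sa) && j <= length(sb))
      best <- max(best, submat[sa[i], sb[j]] + rec(i + 1, j + 1, "m"))
    if (i <= length(sa))
      best <- max(best, -(if (prev == "a") gap_extend else
        gap_open + gap_extend) + rec(i + 1, j, "a"))
    if (j <= length(sb))
      best <- max(best, -(if (prev == "b") gap_extend else
        gap_open + gap_extend) + rec(i, j + 1, "b"))
    best
  }
  rec(1, 1, "m")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Numerical 1:1-binding association curve by adaptive ODE integration
ode_association <- function(kon, koff, rmax, conc, times) {
  out <- deSolve::ode(
    c(R = 0), times,
    function(t, y, p) list(kon * conc * (rmax - y) - koff * y),
    parms = NULL, rtol = 1e-10, atol = 1e-12)
  unname(out[, "R"])
}

# One PDB ATOM line at the format's fixed columns
pdb_line <- function(serial, elety, alt, resid, chain, resno, x, y, z,
                     occ = 1, b = 0, element = substr(elety, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(elety) >= 4, elety, paste0(" ", elety)),
          alt, resid, chain, resno, " ", x, y, z, occ, b, element)
}

# data.frame row shortcut for structure_atoms()
atom_row <- function(chain, resno, elety, x, y, z, resid = "ALA",
                     element = substr(elety, 1, 1)) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# Hand-built numbered Fv from a named letter vector (names = IMGT labels)
mk_numbered_fv <- function(chain_type, letters_named) {
  labs <- names(letters_named)
  regions <- imgt_region(labs)
  structure(list(
    chain_type = chain_type,
    sequence = paste(letters_named, collapse = ""),
    positions = labs, regions = regions,
    cdr_spans = lapply(c(CDR1 = "CDR1", CDR2 = "CDR2", CDR3 = "CDR3"),
                       function(r) labs[regions == r]),
    germline = NA_character_, germline_identity_pct = NA_real_),
    class = "numbered_fv")
}

# Minimal Fv/antigen template for back-mutation flagging: chain L residues at
# template resno == IMGT position, each with mainchain + CB; partner chain H
# and antigen chain T atoms placed to trigger one rationale each.
mk_backmut_template <- function() {
  res <- function(chain, resno, x0, y0) {
    rbind(atom_row(chain, resno, "N", x0, y0, 0),
          atom_row(chain, resno, "CA", x0 + 1, y0, 0),
          atom_row(chain, resno, "C", x0 + 2, y0, 0),
          atom_row(chain, resno, "O", x0 + 2, y0 + 1, 0),
          atom_row(chain, resno, "CB", x0 + 1, y0 + 2, 0))
  }
  rows <- rbind(
    res("L", 27, 0, 0),      # own CDR1
    res("L", 40, 100, 0),    # FR2, near partner chain
    res("L", 45, 200, 0),    # FR2, isolated
    res("L", 56, 300, 0),    # own CDR2
    res("L", 66, 400, 0),    # FR3, near antigen
    res("L", 70, 500, 0),    # FR3, near own CDR3 residue
    res("L", 105, 501, 4),   # own CDR3, CB near CB of residue 70
    # partner chain H: one FR atom near L40, one CDR atom (resno 205) near L40
    atom_row("H", 201, "CB", 101, 5, 0),
    atom_row("H", 205, "CB", 101, -1, 0),
    # antigen chain T near L66 CB
    atom_row("T", 705, "CB", 401, 5, 0))
  structure_atoms(rows)
}
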