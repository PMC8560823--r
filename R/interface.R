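# Buried-surface decomposition, interface residues and typed contacts.
#
# BSA follows the standard convention BSA = (SASA_A + SASA_B - SASA_AB) / 2,
# computed over the atoms of the two sides only.

#' @keywords internal
atom_key <- function(x) paste(x$chain, x$resno, x$ins, x$elety)

#' @keywords internal
take_side <- function(complex, spec, what = "selection") {
  s <- select_atoms(complex, spec)
  if (!nrow(s)) stop(what, " selects no atoms")
  s
}

#' @keywords internal
bind_sides <- function(a, b) {
  ab <- rbind(as.data.frame(a), as.data.frame(b))
  class(ab) <- c("tie2ab_structure", "data.frame")
  ab
}

#' Buried surface area between two sides of a complex
#'
#' `(SASA_A + SASA_B - SASA_AB) / 2`, symmetric in the two sides and zero for
#' non-contacting partners (within sampling noise).
#'
#' @param complex a `tie2ab_structure` holding both sides.
#' @param side_a,side_b [selection()]s; must be disjoint.
#' @param params a [sasa_params()].
#' @return buried area in Angstrom^2.
#' @export
buried_surface_area <- function(complex, side_a, side_b,
                                params = sasa_params()) {
  a <- take_side(complex, side_a, "side_a")
  b <- take_side(complex, side_b, "side_b")
  if (length(intersect(atom_key(a), atom_key(b))))
    stop("side_a and side_b selections overlap")
  sa <- compute_sasa(a, params)$total
  sb <- compute_sasa(b, params)$total
  sab <- compute_sasa(bind_sides(a, b), params)$total
  (sa + sb - sab) / 2
}

#' Decompose one side's buried surface into parts
#'
#' Each part's contribution is the buried area of that part alone against
#' `side_b` (the remaining parts removed). When the parts bury disjoint
#' patches, contributions sum to the undivided buried area.
#'
#' @param complex a `tie2ab_structure`.
#' @param side_a_parts named list of [selection()]s partitioning side A.
#' @param side_b [selection()] for the partner side.
#' @param params a [sasa_params()].
#' @return data.frame with `part`, `bsa` and `fraction` (of the summed parts).
#' @export
bsa_decompose <- function(complex, side_a_parts, side_b,
                          params = sasa_params()) {
  stopifnot(is.list(side_a_parts), length(side_a_parts) >= 1)
  if (is.null(names(side_a_parts)))
    names(side_a_parts) <- paste0("part", seq_along(side_a_parts))
  keys <- lapply(side_a_parts, function(s) atom_key(take_side(complex, s)))
  all_keys <- unlist(keys)
  if (anyDuplicated(all_keys))
    stop("side_a parts are not a partition: overlapping selections")
  bsa <- vapply(side_a_parts, function(s)
    buried_surface_area(complex, s, side_b, params), numeric(1))
  data.frame(part = names(side_a_parts), bsa = unname(bsa),
             fraction = unname(bsa / sum(bsa)), stringsAsFactors = FALSE)
}

#' Interface residues by SASA loss on complexation
#'
#' A residue is listed iff its solvent-accessible area decreases by more than
#' `min_delta` when the partner side is added; lists are sorted by the loss,
#' descending.
#'
#' @inheritParams buried_surface_area
#' @param min_delta minimal SASA loss (Angstrom^2) to call a residue
#'   interfacial (default 0.1).
#' @return list with data.frames `side_a` and `side_b`
#'   (chain/resno/ins/resid/delta_sasa).
#' @export
interface_residues <- function(complex, side_a, side_b,
                               params = sasa_params(), min_delta = 0.1) {
  a <- take_side(complex, side_a, "side_a")
  b <- take_side(complex, side_b, "side_b")
  if (length(intersect(atom_key(a), atom_key(b))))
    stop("side_a and side_b selections overlap")
  ab <- compute_sasa(bind_sides(a, b), params)
  one_side <- function(side) {
    free <- compute_sasa(side, params)$per_residue
    key <- paste(free$chain, free$resno, free$ins)
    bound <- ab$per_residue
    bkey <- paste(bound$chain, bound$resno, bound$ins)
    free$delta_sasa <- free$area - bound$area[match(key, bkey)]
    out <- free[free$delta_sasa > min_delta,
                c("chain", "resno", "ins", "resid", "delta_sasa")]
    out <- out[order(-out$delta_sasa), ]
    rownames(out) <- NULL
    out
  }
  list(side_a = one_side(a), side_b = one_side(b))
}

# --- contact chemistry tables ------------------------------------------------

# formally charged side-chain heavy atoms
POS_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"))
NEG_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# hydrogen-bond donors (atom -> antecedent used for the heavy-atom angle
# proxy); mainchain N handled separately
SC_DONORS <- list(
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  LYS = c(NZ = "CE"), ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"),
  HIS = c(ND1 = "CG", NE2 = "CD2"), TRP = c(NE1 = "CD1"), CYS = c(SG = "CB"))

SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")

# polar carbons excluded from the hydrophobic rule: backbone carbonyl plus
# carboxylate/amide/guanidinium carbons
POLAR_CARBONS <- list("*" = "C", ASP = "CG", ASN = "CG", GLU = "CD",
                      GLN = "CD", ARG = "CZ")

#' @keywords internal
flag_atoms <- function(x, table) {
  hits <- rep(FALSE, nrow(x))
  for (res in names(table)) {
    if (res == "*") hits <- hits | x$elety %in% table[[res]]
    else hits <- hits | (x$resid == res & x$elety %in% table[[res]])
  }
  hits
}

#' Contact cutoffs
#' @param hbond donor-acceptor heavy-atom distance cutoff (default 3.5).
#' @param ionic opposing-charge heavy-atom cutoff (default 4.0).
#' @param hydrophobic apolar carbon-carbon cutoff (default 4.5).
#' @param hbond_angle minimal antecedent-donor-acceptor angle in degrees,
#'   applied when the antecedent atom is present (heavy-atom proxy for the
#'   D-H...A angle; default 90).
#' @return list of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond = 3.5, ionic = 4.0, hydrophobic = 4.5,
                             hbond_angle = 90) {
  structure(list(hbond = hbond, ionic = ionic, hydrophobic = hydrophobic,
                 hbond_angle = hbond_angle), class = "contact_criteria")
}

#' @keywords internal
angle_deg <- function(v1, v2) {
  cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

#' @keywords internal
donor_ok <- function(x, i, acceptor_xyz, min_angle) {
  # heavy-atom angle proxy: antecedent-donor-acceptor
  ante <- if (x$elety[i] == "N") "CA"
  else {
    tab <- SC_DONORS[[x$resid[i]]]
    if (is.null(tab)) NA_character_ else unname(tab[x$elety[i]])
  }
  if (is.na(ante) || !length(ante)) return(TRUE)
  j <- which(x$chain == x$chain[i] & x$resno == x$resno[i] &
               x$ins == x$ins[i] & x$elety == ante)
  if (!length(j)) return(TRUE)
  d <- c(x$x[i], x$y[i], x$z[i])
  a <- c(x$x[j[1]], x$y[j[1]], x$z[j[1]])
  angle_deg(a - d, acceptor_xyz - d) >= min_angle
}

#' Classify inter-molecular residue contacts
#'
#' Types every close residue pair by the first matching rule in the precedence
#' order ionic > hydrogen bond > hydrophobic; hydrogen bonds between mainchain
#' atoms of both partners are flagged `mainchain_hbond`.
#'
#' @inheritParams buried_surface_area
#' @param criteria a [contact_criteria()].
#' @return data.frame with one row per (residue pair, kind): chain/resno/resid
#'   for both partners, `kind`, minimal `distance` and the atom names realising
#'   it.
#' @export
classify_contacts <- function(complex, side_a, side_b,
                              criteria = contact_criteria()) {
  a <- take_side(complex, side_a, "side_a")
  b <- take_side(complex, side_b, "side_b")
  a <- a[a$element != "H", , drop = FALSE]
  b <- b[b$element != "H", , drop = FALSE]
  d <- atom_distances(a, b)
  maxcut <- max(criteria$hbond, criteria$ionic, criteria$hydrophobic)
  idx <- which(d <= maxcut, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      kind = character(), distance = numeric(),
                      atom_a = character(), atom_b = character(),
                      stringsAsFactors = FALSE))
  pos_a <- flag_atoms(a, POS_ATOMS); neg_a <- flag_atoms(a, NEG_ATOMS)
  pos_b <- flag_atoms(b, POS_ATOMS); neg_b <- flag_atoms(b, NEG_ATOMS)
  don_a <- a$elety == "N" | flag_atoms(a, lapply(SC_DONORS, names))
  don_b <- b$elety == "N" | flag_atoms(b, lapply(SC_DONORS, names))
  acc_a <- a$elety == "O" | flag_atoms(a, SC_ACCEPTORS)
  acc_b <- b$elety == "O" | flag_atoms(b, SC_ACCEPTORS)
  apo_a <- a$element == "C" & !flag_atoms(a, POLAR_CARBONS)
  apo_b <- b$element == "C" & !flag_atoms(b, POLAR_CARBONS)
  mc_a <- a$elety %in% MAINCHAIN_ATOMS
  mc_b <- b$elety %in% MAINCHAIN_ATOMS
  rows <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    dist <- d[i, j]
    kind <- NA_character_
    if (dist <= criteria$ionic &&
        ((pos_a[i] && neg_b[j]) || (neg_a[i] && pos_b[j]))) {
      kind <- "ionic"
    } else if (dist <= criteria$hbond &&
               ((don_a[i] && acc_b[j] &&
                 donor_ok(a, i, c(b$x[j], b$y[j], b$z[j]),
                          criteria$hbond_angle)) ||
                (don_b[j] && acc_a[i] &&
                 donor_ok(b, j, c(a$x[i], a$y[i], a$z[i]),
                          criteria$hbond_angle)))) {
      kind <- if (mc_a[i] && mc_b[j]) "mainchain_hbond" else "hydrogen_bond"
    } else if (dist <= criteria$hydrophobic && apo_a[i] && apo_b[j]) {
      kind <- "hydrophobic"
    }
    if (is.na(kind)) next
    rows[[k]] <- data.frame(
      chain_a = a$chain[i], resno_a = a$resno[i], resid_a = a$resid[i],
      chain_b = b$chain[j], resno_b = b$resno[j], resid_b = b$resid[j],
      kind = kind, distance = dist, atom_a = a$elety[i], atom_b = b$elety[j],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      kind = character(), distance = numeric(),
                      atom_a = character(), atom_b = character(),
                      stringsAsFactors = FALSE))
  # one row per residue pair and kind, keeping the closest atom pair
  key <- paste(out$chain_a, out$resno_a, out$chain_b, out$resno_b, out$kind)
  out <- out[order(key, out$distance), ]
  out <- out[!duplicated(paste(out$chain_a, out$resno_a, out$chain_b,
                               out$resno_b, out$kind)), ]
  rownames(out) <- NULL
  out
}

#' Epitope region table for the Tie2 Fn3 / antibody interface
#'
#' Packaged assignment of Tie2 epitope residues to the three interface regions
#' (A: polar contacts with the heavy-chain CDR1/CDR2; B: the central
#' hydrophobic patch; C: polar contacts with light-chain framework residues).
#' A residue may belong to two regions (I647 sits in both A and B).
#'
#' @return data.frame with columns `resno` and `region`.
#' @export
tie2_region_table <- function() {
  data.frame(
    resno = c(643, 644, 645, 646, 647, 727,      # A
              647, 650, 707, 730, 732,           # B
              677, 705, 728),                    # C
    region = c(rep("A", 6), rep("B", 5), rep("C", 3)),
    stringsAsFactors = FALSE)
}

#' Assign interface residues to named epitope regions
#'
#' Labels every epitope-side residue found in the region table; residues
#' absent from the table are `unassigned`. Assignment is a set: a residue can
#' carry several regions.
#'
#' @param report an interface report (list from [interface_report()]) or a
#'   residue data.frame as returned in `interface_residues()$side_a`.
#' @param region_table data.frame with `resno`, `region`
#'   (default [tie2_region_table()]); `NULL` yields all-unassigned with a
#'   warning.
#' @return the input with a `region_assignment` data.frame
#'   (`resno`, `region`) attached (reports) or returned (residue tables).
#' @export
assign_regions <- function(report, region_table = tie2_region_table()) {
  residues <- if (is.data.frame(report)) report
  else report$interface_residues$side_b
  if (is.null(region_table)) {
    warning("region table missing: all residues unassigned")
    asn <- data.frame(resno = residues$resno, region = "unassigned",
                      stringsAsFactors = FALSE)
  } else {
    hit <- region_table[region_table$resno %in% residues$resno, ,
                        drop = FALSE]
    rest <- setdiff(residues$resno, region_table$resno)
    asn <- rbind(hit, if (length(rest))
      data.frame(resno = rest, region = "unassigned",
                 stringsAsFactors = FALSE))
    rownames(asn) <- NULL
  }
  if (is.data.frame(report)) return(asn)
  report$region_assignment <- asn
  report
}

#' Full interface report for a two-sided complex
#'
#' Combines total buried surface, optional per-part decomposition, interface
#' residue lists and typed contacts into one object; regions can then be
#' attached with [assign_regions()].
#'
#' @inheritParams buried_surface_area
#' @param side_a_parts optional named list of selections partitioning side A
#'   (e.g. heavy and light chains of a Fab).
#' @param criteria a [contact_criteria()].
#' @param min_delta threshold for [interface_residues()].
#' @return list of class `interface_report` with elements `total_bsa`,
#'   `bsa_by_part` (or `NULL`), `interface_residues`, `contacts`.
#' @export
interface_report <- function(complex, side_a, side_b, params = sasa_params(),
                             side_a_parts = NULL,
                             criteria = contact_criteria(), min_delta = 0.1) {
  rep <- list(
    total_bsa = buried_surface_area(complex, side_a, side_b, params),
    bsa_by_part = if (!is.null(side_a_parts))
      bsa_decompose(complex, side_a_parts, side_b, params),
    interface_residues = interface_residues(complex, side_a, side_b, params,
                                            min_delta),
    contacts = classify_contacts(complex, side_a, side_b, criteria))
  class(rep) <- "interface_report"
  rep
}
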