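# Synthetic fixtures with analytic ground truth for every analysis stage.
# Each generator returns the input object(s) together with the exact expected
# result, so round-trip tests never re-derive expectations ad hoc.

#' Two-sphere fixture with analytic SASA ground truth
#'
#' Two atoms at a given separation, with the exact accessible area of the
#' union from the spherical-cap closed form.
#'
#' @param r1,r2 van der Waals radii in Angstrom (> 0).
#' @param separation centre-centre distance (>= 0).
#' @param probe_radius probe radius (default 1.4).
#' @param n_points sampling density for the matching [sasa_params()].
#' @return list with `structure`, `params` (radii keyed so each atom gets its
#'   radius) and `ground_truth` (from [two_sphere_sasa()]).
#' @export
make_sphere_pair <- function(r1 = 1.7, r2 = 1.7, separation = 2.0,
                             probe_radius = 1.4, n_points = 960) {
  stopifnot(r1 > 0, r2 > 0)
  if (separation < 0) stop("separation must be non-negative")
  s <- structure_atoms(data.frame(
    chain = c("A", "B"), resno = 1L, resid = "UNK",
    elety = c("C1", "N1"), element = c("C", "N"),
    x = c(0, separation), y = 0, z = 0, stringsAsFactors = FALSE))
  list(structure = s,
       params = sasa_params(probe_radius, n_points,
                            radii = c(C = r1, N = r2)),
       ground_truth = two_sphere_sasa(r1, r2, separation, probe_radius))
}

#' Slab complex with a designed interface decomposition
#'
#' Three chains: parts A and B sit above chain C in identical, well-separated
#' single-atom contacts, so each contact buries exactly the same area and the
#' per-part buried-surface fractions equal the atom-count split by
#' construction.
#'
#' @param contact_split length-2 fractions (sum 1) of contacts on parts A, B.
#' @param n_pairs total number of contacts (default 100).
#' @param spacing contact-to-contact spacing in Angstrom (default 20, far
#'   enough that contacts are independent).
#' @param contact_gap atom-atom distance within a contact (default 4).
#' @return list with `structure` and `ground_truth` (exact fractions and
#'   counts).
#' @export
make_slab_complex <- function(contact_split = c(0.57, 0.43), n_pairs = 100,
                              spacing = 20, contact_gap = 4.0) {
  if (length(contact_split) != 2 || any(contact_split < 0) ||
      abs(sum(contact_split) - 1) > 1e-9)
    stop("infeasible split: need two non-negative fractions summing to 1")
  k1 <- round(contact_split[1] * n_pairs)
  k2 <- n_pairs - k1
  x <- spacing * seq_len(n_pairs)
  top_chain <- c(rep("A", k1), rep("B", k2))
  s <- structure_atoms(data.frame(
    chain = c(top_chain, rep("C", n_pairs)),
    resno = c(seq_len(n_pairs), seq_len(n_pairs)),
    resid = "UNK", elety = "C1", element = "C",
    x = c(x, x), y = 0, z = c(rep(contact_gap, n_pairs), rep(0, n_pairs)),
    stringsAsFactors = FALSE))
  list(structure = s,
       ground_truth = list(fractions = c(A = k1 / n_pairs, B = k2 / n_pairs),
                           counts = c(A = k1, B = k2)))
}

#' Ideal antiparallel beta-ladder with a known mainchain H-bond registry
#'
#' Two strands of glycine mainchains built at idealised geometry: residue i of
#' strand A pairs with residue n+1-i of strand B, and odd-numbered pairs carry
#' the two reciprocal mainchain N-H...O=C bonds of a narrow rung (2.9 Angstrom
#' donor-acceptor), giving the alternating ladder of an antiparallel sheet.
#'
#' @param n_residues residues per strand (>= 4).
#' @param registry only `"antiparallel"` is supported.
#' @param offset_b rigid translation applied to strand B (3-vector; default
#'   none) to break the bonds deliberately.
#' @return list with `structure` and `hbonds` (data.frame `res_a` in chain A,
#'   `res_b` in chain B, the bonded pairs).
#' @export
make_beta_ladder <- function(n_residues, registry = "antiparallel",
                             offset_b = c(0, 0, 0)) {
  if (!identical(registry, "antiparallel"))
    stop("unsupported registry: ", registry)
  stopifnot(n_residues >= 4)
  rows <- list()
  add <- function(chain, resno, elety, x, y, z)
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, resid = "GLY", elety = elety,
      element = substr(elety, 1, 1), x = x, y = y, z = z,
      stringsAsFactors = FALSE)
  for (i in seq_len(n_residues)) {
    xi <- 7 * i
    bonded <- i %% 2 == 1
    yN <- if (bonded) 1.0 else 0.2
    yO <- if (bonded) 1.0 else 0.2
    add("A", i, "N", xi, yN, 0)
    add("A", i, "CA", xi + 0.8, -0.2, 0)
    add("A", i, "C", xi + 1.5, -0.3, 0)
    add("A", i, "O", xi + 1.5, yO, 0)
    j <- n_residues + 1 - i
    yOp <- if (bonded) 3.9 else 4.7
    yNp <- if (bonded) 3.9 else 4.7
    add("B", j, "O", xi + offset_b[1], yOp + offset_b[2], offset_b[3])
    add("B", j, "C", xi + offset_b[1], 5.1 + offset_b[2], offset_b[3])
    add("B", j, "CA", xi + 2.3 + offset_b[1], 5.1 + offset_b[2], offset_b[3])
    add("B", j, "N", xi + 1.5 + offset_b[1], yNp + offset_b[2], offset_b[3])
  }
  s <- structure_atoms(do.call(rbind, rows))
  odd <- seq(1, n_residues, by = 2)
  list(structure = s,
       hbonds = data.frame(res_a = odd, res_b = n_residues + 1 - odd))
}

FV_FR_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "H", "I", "L", "K",
                    "M", "P", "S", "T", "V")   # excludes W/Y/F/G (CDR marks)

#' Parent Fv / donor germline pair with exact known identity
#'
#' Builds a synthetic germline on the gapped IMGT frame (frameworks fully
#' occupied, loop lengths chosen to reach `n_positions`) and a parent sequence
#' occupying the same positions with exactly `identity_target` percent
#' matches. With `cdr_marks`, parental CDR residues are drawn from {W, Y, F}
#' and germline CDR positions are G, so grafted loops are recognisable at a
#' glance.
#'
#' @param identity_target percent identity (must give an integer match count).
#' @param n_positions total occupied positions (84-104; default 100).
#' @param cdr_marks use the distinguishable CDR composition (default `TRUE`).
#' @param seed RNG seed (same spec + seed reproduces the pair exactly).
#' @return list with `parent` ([seq_record()]), `donor` ([germline_record()]),
#'   `ground_truth` (identity, match count, CDR labels).
#' @export
make_fv_pair <- function(identity_target = 66, n_positions = 100,
                         cdr_marks = TRUE, seed = 1) {
  n_cdr <- n_positions - 82              # frameworks occupy 82 positions
  if (n_cdr < 2 || n_cdr > 22)
    stop("infeasible n_positions: must be 84-104")
  matches <- identity_target * n_positions / 100
  if (abs(matches - round(matches)) > 1e-9)
    stop("infeasible identity target: ", identity_target, "% of ",
         n_positions, " positions is not an integer")
  matches <- round(matches)
  set.seed(seed)
  cdr1_len <- min(12, max(1, round(n_cdr * 12 / 22)))
  cdr2_len <- n_cdr - cdr1_len
  if (cdr2_len < 1 || cdr2_len > 10) { cdr1_len <- n_cdr - 10; cdr2_len <- 10 }
  fr_slots <- unlist(lapply(c("FR1", "FR2", "FR3"), function(r)
    seq(IMGT_REGIONS[[r]][1], IMGT_REGIONS[[r]][2])))
  cdr_slots <- as.numeric(c(imgt_fill("CDR1", cdr1_len),
                            imgt_fill("CDR2", cdr2_len)))
  slots <- sort(c(fr_slots, cdr_slots))
  is_cdr <- slots %in% cdr_slots
  parent <- character(n_positions)
  parent[!is_cdr] <- sample(FV_FR_ALPHABET, sum(!is_cdr), replace = TRUE)
  parent[is_cdr] <- if (cdr_marks)
    sample(c("W", "Y", "F"), sum(is_cdr), replace = TRUE)
  else sample(FV_FR_ALPHABET, sum(is_cdr), replace = TRUE)
  donor <- parent
  n_mismatch <- n_positions - matches
  # mismatches live in the CDRs first (the grafting setting), then spill
  # into the frameworks
  cdr_idx <- which(is_cdr)
  mm_cdr <- cdr_idx[seq_len(min(length(cdr_idx), n_mismatch))]
  mm_fr <- if (n_mismatch > length(cdr_idx))
    sample(which(!is_cdr), n_mismatch - length(cdr_idx))
  else integer()
  for (i in mm_cdr)
    donor[i] <- if (cdr_marks) "G"
  else sample(setdiff(FV_FR_ALPHABET, donor[i]), 1)
  for (i in mm_fr) donor[i] <- sample(setdiff(FV_FR_ALPHABET, donor[i]), 1)
  gapped <- rep(".", 104)
  gapped[slots] <- donor
  list(parent = seq_record("synthetic_parent_fv",
                           paste(parent, collapse = "")),
       donor = germline_record("SYNGV1-1*01", "synthetic",
                               paste(gapped, collapse = "")),
       ground_truth = list(identity_pct = identity_target,
                           n_matches = matches, n_positions = n_positions,
                           cdr_labels = as.character(sort(cdr_slots))))
}

#' @keywords internal
ring_edges <- function(k, tag) {
  hubs <- sprintf("%s_h%d", tag, seq_len(k))
  dims <- sprintf("%s_d%d", tag, seq_len(k))
  data.frame(hub = c(hubs, hubs[c(2:k, 1)]), dimer = c(dims, dims),
             stringsAsFactors = FALSE)
}

#' @keywords internal
path_edges <- function(k, tag) {
  # k hubs chained by k-1 dimers plus one dangling dimer (acyclic, connected)
  hubs <- sprintf("%s_h%d", tag, seq_len(k))
  dims <- sprintf("%s_d%d", tag, seq_len(k))
  data.frame(hub = c(hubs, if (k > 1) hubs[2:k]),
             dimer = c(dims, if (k > 1) dims[seq_len(k - 1)]),
             stringsAsFactors = FALSE)
}

#' Assembly-graph set with specified category proportions
#'
#' Category counts are the rounded `n * proportion` with largest-remainder
#' correction so they sum exactly to `n`; graphs are constructed per the
#' category definitions (paths for linear, closed k-rings otherwise).
#'
#' @param proportions named numeric over (a subset of) the six categories,
#'   summing to 1.
#' @param n number of assemblies (>= 1).
#' @param seed RNG seed (sizes of linear and >hexagonal assemblies vary
#'   deterministically with it).
#' @return list with `graphs` (list of edge data.frames) and `labels` (the
#'   generated ground-truth categories, parallel to `graphs`).
#' @export
make_assembly_set <- function(proportions, n, seed = 1) {
  stopifnot(n >= 1)
  bad <- setdiff(names(proportions), ASSEMBLY_CATEGORIES)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must be non-negative and sum to 1")
  p <- stats::setNames(numeric(length(ASSEMBLY_CATEGORIES)),
                       ASSEMBLY_CATEGORIES)
  p[names(proportions)] <- proportions
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * p - base
    top <- order(-frac, seq_along(p))[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  set.seed(seed)
  graphs <- list(); labels <- character()
  kk <- 0
  for (cat in ASSEMBLY_CATEGORIES) {
    for (i in seq_len(base[[cat]])) {
      kk <- kk + 1
      tag <- sprintf("g%d", kk)
      g <- switch(cat,
        linear = path_edges(sample(1:3, 1), tag),
        lt_tetragonal = ring_edges(3, tag),
        tetragonal = ring_edges(4, tag),
        pentagonal = ring_edges(5, tag),
        hexagonal = ring_edges(6, tag),
        gt_hexagonal = ring_edges(sample(7:9, 1), tag))
      graphs[[kk]] <- g
      labels[kk] <- cat
    }
  }
  list(graphs = graphs, labels = labels)
}

#' Sensorgram fixture set at the study concentration ladder
#'
#' Thin wrapper over [simulate_series()] that carries the generating
#' parameters as ground truth.
#'
#' @param kon,koff,rmax generating parameters (defaults: the parental
#'   antibody rates, kon 1.4e5 M^-1 s^-1, koff 6.0e-4 s^-1, rmax 100 RU).
#' @param concs concentration ladder in M (default 0-64 nM doubling).
#' @param t_assoc,t_dissoc phase durations in s.
#' @param dt sampling interval in s.
#' @param noise_sd Gaussian noise SD in RU.
#' @param seed RNG seed.
#' @return list with `series` and `ground_truth` (the [kinetic_params()]).
#' @export
make_sensorgram_set <- function(kon = 1.4e5, koff = 6.0e-4, rmax = 100,
                                concs = c(0, 2, 4, 8, 16, 32, 64) * 1e-9,
                                t_assoc = 300, t_dissoc = 300, dt = 1,
                                noise_sd = 0, seed = 1) {
  pars <- kinetic_params(kon, koff, rmax)
  list(series = simulate_series(pars, concs, t_assoc, t_dissoc, dt,
                                noise_sd, seed),
       ground_truth = pars)
}
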