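test_that("buried surface is symmetric, zero for distant partners", {
  # two chains > 20 A apart at every atom pair
  s <- structure_atoms(rbind(atom_row("A", 1, "C1", 0, 0, 0),
                             atom_row("A", 2, "C1", 4, 0, 0),
                             atom_row("B", 1, "C1", 40, 0, 0),
                             atom_row("B", 2, "C1", 44, 0, 0)))
  ab <- buried_surface_area(s, selection("A"), selection("B"))
  ba <- buried_surface_area(s, selection("B"), selection("A"))
  expect_equal(ab, 0, tolerance = 1e-9)
  expect_equal(ab, ba)
  # contacting pair: positive and symmetric
  fx <- make_sphere_pair(separation = 2.0)
  v1 <- buried_surface_area(fx$structure, selection("A"), selection("B"),
                            fx$params)
  v2 <- buried_surface_area(fx$structure, selection("B"), selection("A"),
                            fx$params)
  expect_gt(v1, 0)
  expect_equal(v1, v2)
  expect_error(
    buried_surface_area(fx$structure, selection("A"), selection("A")),
    "overlap")
})

test_that("adding a distant third chain leaves the pair interface unchanged", {
  fx <- make_sphere_pair(separation = 2.0)
  base <- buried_surface_area(fx$structure, selection("A"), selection("B"),
                              fx$params)
  cols <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  bigger <- structure_atoms(rbind(as.data.frame(fx$structure)[, cols],
                                  atom_row("Z", 1, "C1", 500, 0, 0)))
  again <- buried_surface_area(bigger, selection("A"), selection("B"),
                               fx$params)
  expect_equal(base, again, tolerance = 1e-9)
})

test_that("slab decomposition recovers the designed contact split", {
  for (split in list(c(0.57, 0.43), c(2 / 3, 1 / 3), c(0.5, 0.5))) {
    fx <- make_slab_complex(split, n_pairs = 60)
    dec <- bsa_decompose(fx$structure,
                         list(A = selection("A"), B = selection("B")),
                         selection("C"))
    expect_equal(dec$fraction, unname(fx$ground_truth$fractions),
                 tolerance = 0.02)
    whole <- buried_surface_area(fx$structure, selection(c("A", "B")),
                                 selection("C"))
    expect_equal(sum(dec$bsa), whole, tolerance = 0.01 * whole)
  }
  # degenerate split: everything on one part
  fx <- make_slab_complex(c(1, 0), n_pairs = 10)
  suppressWarnings(expect_error(
    bsa_decompose(fx$structure, list(A = selection("A"), B = selection("B")),
                  selection("C")),
    "no atoms"))
  one <- bsa_decompose(fx$structure, list(A = selection("A")), selection("C"))
  expect_equal(one$fraction, 1)
  expect_error(
    bsa_decompose(fx$structure, list(A = selection("A"), A2 = selection("A")),
                  selection("C")),
    "not a partition")
})

test_that("interface residues require a SASA loss above the threshold", {
  far <- structure_atoms(rbind(atom_row("A", 1, "C1", 0, 0, 0),
                               atom_row("B", 1, "C1", 40, 0, 0)))
  res <- interface_residues(far, selection("A"), selection("B"))
  expect_equal(nrow(res$side_a), 0)
  expect_equal(nrow(res$side_b), 0)
  fx <- make_slab_complex(c(0.5, 0.5), n_pairs = 10)
  res <- interface_residues(fx$structure, selection(c("A", "B")),
                            selection("C"))
  expect_equal(nrow(res$side_a), 10)   # every contact atom buried
  expect_equal(nrow(res$side_b), 10)
  expect_true(all(diff(res$side_a$delta_sasa) <= 1e-9))  # sorted descending
})

test_that("beta-ladder mainchain hydrogen bonds are detected exactly", {
  fx <- make_beta_ladder(9)
  cc <- classify_contacts(fx$structure, selection("A"), selection("B"))
  expect_true(all(cc$kind == "mainchain_hbond"))
  got <- unique(cc[, c("resno_a", "resno_b")])
  got <- got[order(got$resno_a), ]
  expect_equal(got$resno_a, fx$hbonds$res_a)
  expect_equal(got$resno_b, fx$hbonds$res_b)
  # minimal ladder still carries at least two bonds
  cc4 <- classify_contacts(make_beta_ladder(4)$structure,
                           selection("A"), selection("B"))
  expect_gte(nrow(cc4), 2)
  # pushing one strand 5 A away removes every bond
  moved <- make_beta_ladder(9, offset_b = c(0, 5, 0))
  cc0 <- classify_contacts(moved$structure, selection("A"), selection("B"))
  expect_equal(nrow(cc0), 0)
})

test_that("contact typing follows the ionic > hbond > hydrophobic precedence", {
  # opposing charges at 3.4 A: ionic wins over the hbond rule
  ion <- structure_atoms(rbind(
    atom_row("A", 1, "NZ", 0, 0, 0, resid = "LYS", element = "N"),
    atom_row("A", 1, "CE", -1.2, 0.8, 0, resid = "LYS", element = "C"),
    atom_row("B", 1, "OE1", 3.4, 0, 0, resid = "GLU", element = "O")))
  cc <- classify_contacts(ion, selection("A"), selection("B"))
  expect_equal(cc$kind, "ionic")
  # two apolar carbons at 4.0 A, no polar atoms in range: hydrophobic
  apo <- structure_atoms(rbind(
    atom_row("A", 1, "CB", 0, 0, 0, resid = "VAL"),
    atom_row("B", 1, "CG1", 4.0, 0, 0, resid = "VAL")))
  cc <- classify_contacts(apo, selection("A"), selection("B"))
  expect_equal(cc$kind, "hydrophobic")
  expect_equal(cc$distance, 4.0)
  # sidechain donor to mainchain acceptor: plain hydrogen bond
  hb <- structure_atoms(rbind(
    atom_row("A", 1, "OG", 0, 0, 0, resid = "SER", element = "O"),
    atom_row("A", 1, "CB", -1.0, 1.0, 0, resid = "SER"),
    atom_row("B", 1, "O", 2.9, 0, 0, resid = "GLY", element = "O")))
  cc <- classify_contacts(hb, selection("A"), selection("B"))
  expect_equal(cc$kind, "hydrogen_bond")
  # beyond every cutoff: nothing
  none <- structure_atoms(rbind(atom_row("A", 1, "CB", 0, 0, 0),
                                atom_row("B", 1, "CB", 6, 0, 0)))
  expect_equal(nrow(classify_contacts(none, selection("A"), selection("B"))),
               0)
})

test_that("region assignment labels epitope residues, leaves others unassigned", {
  residues <- data.frame(chain = "T", resno = c(730, 705, 647, 999),
                         ins = "", resid = c("VAL", "GLU", "ILE", "ALA"),
                         delta_sasa = c(50, 30, 20, 10))
  asn <- assign_regions(residues)
  expect_true("B" %in% asn$region[asn$resno == 730])
  expect_true("C" %in% asn$region[asn$resno == 705])
  # I647 belongs to both A and B: assignment is a set
  expect_setequal(asn$region[asn$resno == 647], c("A", "B"))
  expect_equal(asn$region[asn$resno == 999], "unassigned")
  expect_warning(asn0 <- assign_regions(residues, region_table = NULL),
                 "missing")
  expect_true(all(asn0$region == "unassigned"))
})

test_that("interface report ties the pieces together", {
  fx <- make_slab_complex(c(0.5, 0.5), n_pairs = 10)
  rep <- interface_report(fx$structure, selection(c("A", "B")), selection("C"),
                          side_a_parts = list(A = selection("A"),
                                              B = selection("B")))
  expect_gt(rep$total_bsa, 0)
  expect_equal(sum(rep$bsa_by_part$bsa), rep$total_bsa,
               tolerance = 0.01 * rep$total_bsa)
  # every contact residue appears in the interface residue lists
  if (nrow(rep$contacts)) {
    expect_true(all(rep$contacts$resno_a %in% rep$interface_residues$side_a$resno))
    expect_true(all(rep$contacts$resno_b %in% rep$interface_residues$side_b$resno))
  }
})
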