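test_that("single-record PDB parses to a one-atom structure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "CA", " ", "ALA", "A", 1, 0, 0, 0), "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 1)
  expect_equal(s$chain, "A")
  expect_equal(s$resid, "ALA")
  expect_equal(c(s$x, s$y, s$z), c(0, 0, 0))
})

test_that("altlocs resolve to highest occupancy, ties to the first id", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "A", "ALA", "A", 1, 0, 0, 0, occ = 0.6),
    pdb_line(2, "CA", "B", "ALA", "A", 1, 1, 0, 0, occ = 0.4),
    pdb_line(3, "CB", "B", "ALA", "A", 1, 2, 0, 0, occ = 0.5),
    pdb_line(4, "CB", "A", "ALA", "A", 1, 3, 0, 0, occ = 0.5),
    pdb_line(5, "CG", "A", "ALA", "A", 1, 4, 0, 0, occ = 0.3),
    pdb_line(6, "CG", "B", "ALA", "A", 1, 5, 0, 0, occ = 0.7),
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 3)
  expect_equal(s$x[s$elety == "CA"], 0)   # occ 0.6 wins
  expect_equal(s$x[s$elety == "CB"], 3)   # tie -> altloc A
  expect_equal(s$x[s$elety == "CG"], 5)   # occ 0.7 wins even as altloc B
})

test_that("multi-model and malformed files are rejected with clear errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", pdb_line(1, "CA", " ", "ALA", "A", 1, 0, 0, 0),
               "ENDMDL", "MODEL     2",
               pdb_line(1, "CA", " ", "ALA", "A", 1, 1, 0, 0),
               "ENDMDL", "END"), f)
  expect_error(read_structure(f), "multi-model")
  writeLines(c("ATOM      1  CA  ALA A   1      bad"), f)
  expect_error(read_structure(f), "line 1")
  writeLines("END", f)
  expect_error(read_structure(f), "empty model")
})

test_that("write/read round trip preserves coordinates to 3 decimals", {
  s <- structure_atoms(rbind(
    atom_row("A", 1, "N", 1.1234, -2.5678, 3.999),
    atom_row("A", 1, "CA", 0.0004, 100.123, -50.5),
    atom_row("B", 7, "CA", 12.345, 0, 0)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2), 3)
  expect_equal(s2$x, round(s$x, 3), tolerance = 1e-9)
  expect_equal(s2$y, round(s$y, 3), tolerance = 1e-9)
  expect_equal(s2$chain, s$chain)
  expect_equal(s2$resno, s$resno)
})

test_that("selection filters chains, ranges and atom classes and is idempotent", {
  s <- structure_atoms(rbind(
    atom_row("A", 541, "N", 0, 0, 0), atom_row("A", 541, "CA", 1, 0, 0),
    atom_row("A", 541, "C", 2, 0, 0), atom_row("A", 541, "O", 3, 0, 0),
    atom_row("A", 541, "CB", 4, 0, 0), atom_row("A", 541, "CG", 5, 0, 0),
    atom_row("A", 541, "CD", 6, 0, 0), atom_row("A", 541, "CE", 7, 0, 0),
    atom_row("A", 800, "CA", 8, 0, 0),
    atom_row("B", 10, "CA", 9, 0, 0)))
  only_a <- select_atoms(s, selection(chains = "A"))
  expect_true(all(only_a$chain == "A"))
  expect_identical(select_atoms(only_a, selection(chains = "A")), only_a)
  # inclusive range bound: at most end - start + 1 distinct residues
  win <- select_atoms(s, selection(residue_ranges = c(541, 735)))
  expect_lte(length(unique(paste(win$chain, win$resno))), 195)
  expect_true(all(win$resno >= 541 & win$resno <= 735))
  # mainchain pick: 4 of the 8 atoms of residue 541
  mc <- select_atoms(s, selection(chains = "A", residue_ranges = c(541, 541),
                                  atom_class = "mainchain"))
  expect_equal(sort(mc$elety), sort(c("N", "CA", "C", "O")))
  # union over chains equals union of single-chain selections
  ab <- select_atoms(s, selection(chains = c("A", "B")))
  expect_equal(nrow(ab), nrow(only_a) + nrow(select_atoms(s, selection("B"))))
  expect_warning(empty <- select_atoms(s, selection(chains = "Z")),
                 "not present")
  expect_equal(nrow(empty), 0)
})

test_that("sequence extraction maps residues in order, non-standard to X", {
  s <- structure_atoms(rbind(
    atom_row("A", 1, "CA", 0, 0, 0, resid = "ALA"),
    atom_row("A", 2, "CA", 1, 0, 0, resid = "GLY"),
    atom_row("A", 3, "CA", 2, 0, 0, resid = "VAL"),
    atom_row("A", 4, "CA", 3, 0, 0, resid = "MSE")))
  rec <- extract_sequence(s, "A")
  expect_equal(rec$residues, "AGVX")
  expect_equal(rec$numbering$resno, 1:4)
  expect_error(extract_sequence(s, "Q"), "chain not present")
})

test_that("mutations validate the wild type and invert cleanly", {
  fn3 <- seq_record("tie2_fn3_window", "DQAVAVAAKNAAAAAYAAKAAEAE",
                    data.frame(resno = 682:705, ins = ""))
  # the disulfide-locking dimer design: both ends of the strand to cysteine
  mut <- apply_mutations(fn3, c("D682C", "N691C"))
  chr <- strsplit(mut$residues, "")[[1]]
  expect_equal(chr[mut$numbering$resno == 682], "C")
  expect_equal(chr[mut$numbering$resno == 691], "C")
  expect_equal(apply_mutations(fn3, character()), fn3)
  # involution: the monomerising triple and its inverse restore the input
  fwd <- apply_mutations(fn3, c("V685D", "V687D", "K700E"))
  back <- apply_mutations(fwd, c("D685V", "D687V", "E700K"))
  expect_equal(back$residues, fn3$residues)
  expect_error(apply_mutations(fn3, "D683C"), "position 683.*observed Q")
})

test_that("distances are symmetric and satisfy the triangle inequality", {
  s <- structure_atoms(rbind(atom_row("A", 1, "CA", 0, 0, 0),
                             atom_row("A", 2, "CA", 3, 4, 0),
                             atom_row("A", 3, "CA", -1, 2, 7)))
  d <- atom_distances(s, s)
  expect_equal(d, t(d))
  expect_equal(d[1, 2], 5)
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("fasta round trip preserves ids and residues", {
  recs <- list(seq_record("tie2_fn23", "ACDEFGHIKLMNPQRSTVWY"),
               seq_record("fab_vl", "DIQMTQSPSS"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(vapply(back, `[[`, "", "id"), c("tie2_fn23", "fab_vl"))
  expect_equal(back[[1]]$residues, recs[[1]]$residues)
})
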