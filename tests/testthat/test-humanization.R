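test_that("a germline sequence inherits its own IMGT frame", {
  fx <- make_fv_pair(identity_target = 100, n_positions = 100, seed = 11)
  expect_equal(fx$parent$residues, germline_ungapped(fx$donor))
  num <- imgt_number(fx$parent, "heavy", list(fx$donor))
  slots <- as.character(which(strsplit(fx$donor$gapped_sequence, "")[[1]] != "."))
  expect_equal(num$positions, slots)
  expect_equal(num$germline, fx$donor$gene_name)
  gi <- germline_identity(num, fx$donor)
  expect_equal(gi$identity_pct, 100)
})

test_that("an insertion inside CDR1 is renumbered within the loop frame", {
  fx <- make_fv_pair(identity_target = 100, n_positions = 98, seed = 5)
  chr <- strsplit(fx$parent$residues, "")[[1]]
  num0 <- imgt_number(fx$parent, "heavy", list(fx$donor))
  cdr1_idx <- which(num0$regions == "CDR1")
  # insert one residue mid-CDR1
  at <- cdr1_idx[ceiling(length(cdr1_idx) / 2)]
  longer <- paste(c(chr[1:at], "W", chr[(at + 1):length(chr)]), collapse = "")
  num1 <- imgt_number(longer, "heavy", list(fx$donor))
  # framework numbering is untouched
  expect_equal(num1$positions[num1$regions != "CDR1"],
               num0$positions[num0$regions != "CDR1"])
  # the extra residue lands inside the CDR1 span
  expect_equal(sum(num1$regions == "CDR1"), length(cdr1_idx) + 1)
  v <- as.numeric(num1$positions[num1$regions == "CDR1"])
  expect_true(all(v >= 27 & v <= 38))
  expect_false(any(duplicated(v)))
  # symmetric fill: front-loaded from 27, back-anchored at the span end
  expect_equal(v[1], 27)
  expect_equal(v[length(v)], max(v))
})

test_that("framework insertions and non-V-regions are rejected", {
  fx <- make_fv_pair(identity_target = 100, n_positions = 100, seed = 8)
  chr <- strsplit(fx$parent$residues, "")[[1]]
  with_fr_ins <- paste(c(chr[1:10], "WWW", chr[11:length(chr)]),
                       collapse = "")
  expect_error(imgt_number(with_fr_ins, "heavy", list(fx$donor)),
               "framework")
  junk <- paste(rep("PG", 50), collapse = "")
  expect_error(imgt_number(junk, "heavy", list(fx$donor)),
               "not an antibody V region")
  expect_error(imgt_number("ACD", "heavy", list(fx$donor)), "80-140")
})

test_that("germline identity counts matches over shared positions", {
  fx <- make_fv_pair(identity_target = 66, n_positions = 100, seed = 3)
  num <- imgt_number(fx$parent, "heavy", list(fx$donor))
  gi <- germline_identity(num, fx$donor)
  expect_equal(gi$identity_pct, 66)
  expect_equal(gi$n_matches, 66)
  expect_equal(gi$n_shared, 100)
  # a 50-position toy with 30 matches reads 60%
  fx2 <- make_fv_pair(identity_target = 60, n_positions = 90, seed = 4)
  gi2 <- germline_identity(imgt_number(fx2$parent, "light", list(fx2$donor)),
                           fx2$donor)
  expect_equal(gi2$identity_pct, 60)
})

test_that("germline selection takes the identity argmax, ties lexicographic", {
  fx66 <- make_fv_pair(identity_target = 66, n_positions = 100, seed = 3)
  fx60 <- make_fv_pair(identity_target = 60, n_positions = 100, seed = 31)
  # candidates: the true 66% donor plus two decoys with lower identity
  decoy1 <- germline_record("SYNGV2-1*01", "synthetic",
                            fx60$donor$gapped_sequence)
  sel <- select_germline(fx66$parent, list(decoy1, fx66$donor))
  expect_equal(sel$gene_name, fx66$donor$gene_name)
  expect_equal(attr(sel, "identity_pct"), 66, tolerance = 1e-9)
  # single candidate: that candidate
  expect_equal(select_germline(fx66$parent, list(decoy1))$gene_name,
               decoy1$gene_name)
  # exact tie: same sequence under two names -> lexicographically first
  dup_a <- germline_record("SYNGV1-1*01", "synthetic",
                           fx66$donor$gapped_sequence)
  dup_b <- germline_record("SYNGV0-1*01", "synthetic",
                           fx66$donor$gapped_sequence)
  expect_warning(tie <- select_germline(fx66$parent, list(dup_a, dup_b)),
                 "tie")
  expect_equal(tie$gene_name, "SYNGV0-1*01")
  expect_error(select_germline(fx66$parent, list()), "empty")
})

test_that("grafting puts donor frameworks around parental CDRs", {
  fx <- make_fv_pair(identity_target = 66, n_positions = 100, seed = 3)
  num <- imgt_number(fx$parent, "heavy", list(fx$donor))
  gr <- graft_cdrs(num, fx$donor)
  g <- gr$grafted
  gchr <- strsplit(g$sequence, "")[[1]]
  # marked parental CDR letters (W/Y/F) land exactly at CDR spans
  expect_true(all(gchr[grepl("CDR", g$regions)] %in% c("W", "Y", "F")))
  expect_false(any(gchr[grepl("^FR", g$regions)] %in% c("W", "Y", "F")))
  # frameworks equal the donor at every position
  expect_equal(germline_identity(g, fx$donor)$identity_fr_pct, 100)
  # identity graft: parent == donor everywhere gives back the donor V region
  fx100 <- make_fv_pair(identity_target = 100, n_positions = 100, seed = 12)
  id_graft <- graft_cdrs(imgt_number(fx100$parent, "heavy",
                                     list(fx100$donor)), fx100$donor)
  expect_equal(id_graft$grafted$sequence, germline_ungapped(fx100$donor))
  expect_equal(nrow(id_graft$flank_substitutions), 0)
  # re-grafting the parent CDRs onto the graft is idempotent
  regraft <- graft_cdrs(gr$grafted, fx$donor)
  expect_equal(regraft$grafted$sequence, gr$grafted$sequence)
})

test_that("flank rules retain the parental residue next to a grafted loop", {
  fx <- make_fv_pair(identity_target = 66, n_positions = 100, seed = 3)
  num <- imgt_number(fx$parent, "heavy", list(fx$donor))
  pchr <- stats::setNames(strsplit(num$sequence, "")[[1]], num$positions)
  dl <- germline_letters(fx$donor)
  # pick a framework position where parent and donor differ
  fr <- names(pchr)[grepl("^FR", imgt_region(names(pchr)))]
  diffp <- fr[pchr[fr] != dl[fr]][1]
  gr <- graft_cdrs(num, fx$donor, flank_rules = diffp)
  gchr <- stats::setNames(strsplit(gr$grafted$sequence, "")[[1]],
                          gr$grafted$positions)
  expect_equal(unname(gchr[diffp]), unname(pchr[diffp]))
  expect_equal(gr$flank_substitutions$position, diffp)
  expect_equal(gr$flank_substitutions$donor_aa, unname(dl[diffp]))
  expect_equal(gr$flank_substitutions$parent_aa, unname(pchr[diffp]))
})

test_that("back-mutation flagging applies the three structural rules in order", {
  parent <- mk_numbered_fv("light", c("27" = "W", "40" = "N", "45" = "Q",
                                      "56" = "Y", "66" = "R", "70" = "A",
                                      "105" = "F"))
  graft <- mk_numbered_fv("light", c("27" = "W", "40" = "G", "45" = "Q",
                                     "56" = "Y", "66" = "G", "70" = "S",
                                     "105" = "F"))
  tmpl <- mk_backmut_template()
  cm <- list(fv_chain = "L", partner_chain = "H", antigen_chain = "T",
             position_map = data.frame(
               imgt = c("27", "40", "45", "56", "66", "70", "105"),
               resno = c(27, 40, 45, 56, 66, 70, 105)),
             cdr_resnos = list(fv = c(27, 56, 105), partner = 205))
  bm <- flag_back_mutations(graft, parent, tmpl, cm)
  expect_setequal(bm$imgt_position, c("40", "66", "70"))
  expect_equal(bm$rationale[bm$imgt_position == "66"], "antigen_contact")
  expect_equal(bm$rationale[bm$imgt_position == "40"], "vh_vl_interface")
  expect_equal(bm$rationale[bm$imgt_position == "70"], "cdr_support")
  # the partner CDR atom near position 40 adds a secondary rationale
  expect_match(bm$rationales[bm$imgt_position == "40"], "cdr_support")
  expect_equal(bm$from_aa[bm$imgt_position == "66"], "G")
  expect_equal(bm$to_aa[bm$imgt_position == "66"], "R")
  # every emitted mutation satisfies its distance rule on recomputation
  for (i in seq_len(nrow(bm))) {
    resno <- cm$position_map$resno[cm$position_map$imgt ==
                                     bm$imgt_position[i]]
    sc <- tmpl[tmpl$chain == "L" & tmpl$resno == resno &
                 !(tmpl$elety %in% c("N", "CA", "C", "O")), ]
    class(sc) <- c("tie2ab_structure", "data.frame")
    other <- tmpl[tmpl$chain != "L" | tmpl$resno %in% c(27, 56, 105), ]
    class(other) <- c("tie2ab_structure", "data.frame")
    expect_lte(min(atom_distances(sc, other)), 4.5)
  }
  # identical graft: nothing to flag
  expect_equal(nrow(flag_back_mutations(parent, parent, tmpl, cm)), 0)
  expect_error(flag_back_mutations(graft, parent, tmpl,
                                   cm[c("fv_chain", "partner_chain")]),
               "chain_map incomplete")
})

test_that("build_variant applies the published-style mutation sets", {
  # light chain: the four back mutations restoring pairing, loop conformation
  # and the antigen salt bridge
  l1 <- mk_numbered_fv("light", c("30" = "S", "34" = "G", "36" = "Y",
                                  "50" = "A", "55" = "Q", "66" = "G",
                                  "90" = "T"))
  l2 <- build_variant(l1, c("G34N", "Y36L", "Q55D", "G66R"))
  chr <- stats::setNames(strsplit(l2$sequence, "")[[1]], l2$positions)
  expect_equal(unname(chr[c("34", "36", "55", "66")]), c("N", "L", "D", "R"))
  expect_equal(unname(chr[c("30", "50", "90")]), c("S", "A", "T"))
  # heavy chain: the two loop-stabilising framework reversions
  h1 <- mk_numbered_fv("heavy", c("20" = "V", "72" = "R", "74" = "T",
                                  "80" = "M"))
  h2 <- build_variant(h1, c("R72V", "T74K"))
  chr <- stats::setNames(strsplit(h2$sequence, "")[[1]], h2$positions)
  expect_equal(unname(chr[c("72", "74")]), c("V", "K"))
  # empty set: unchanged; mismatch: error naming the position
  expect_equal(build_variant(l1, character()), l1)
  expect_error(build_variant(l1, "N34G"), "position 34")
  # point mutations never change position labels
  expect_equal(l2$positions, l1$positions)
})
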