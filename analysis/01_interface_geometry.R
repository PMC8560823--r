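#!/usr/bin/env Rscript
# Interface geometry stage: verifies the solvent-accessible surface machinery
# against analytic ground truth, then reproduces the style of the
# antibody/receptor interface decomposition (heavy vs light chain) and the
# mainchain hydrogen-bond ladder of the receptor homodimer interface on
# synthetic fixtures.

suppressMessages(library(tie2ab))
dir.create("results", showWarnings = FALSE)

cat("== Sphere-pair oracle ==\n")
oracle <- do.call(rbind, lapply(c(2.0, 3.1, 4.4), function(sep) {
  fx <- make_sphere_pair(separation = sep)
  got <- compute_sasa(fx$structure, fx$params)$total
  data.frame(separation_A = sep, sampled_A2 = got,
             analytic_A2 = fx$ground_truth$total,
             rel_err_pct = 100 * abs(got - fx$ground_truth$total) /
               fx$ground_truth$total)
}))
print(oracle, row.names = FALSE)
write.table(oracle, "results/sasa_oracle.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("Sampled areas track the closed form to",
    sprintf("%.3f%%\n\n", max(oracle$rel_err_pct)))

cat("== Designed 57/43 interface decomposition ==\n")
slab <- make_slab_complex(c(0.57, 0.43), n_pairs = 100)
dec <- bsa_decompose(slab$structure,
                     list(heavy_like = selection("A"),
                          light_like = selection("B")), selection("C"))
dec$fraction_pct <- 100 * dec$fraction
print(dec, row.names = FALSE)
write.table(dec, "results/interface_decomposition.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
whole <- buried_surface_area(slab$structure, selection(c("A", "B")),
                             selection("C"))
cat(sprintf("Component sum %.1f vs undivided %.1f A^2 (conservation %.2f%%)\n\n",
            sum(dec$bsa), whole, 100 * sum(dec$bsa) / whole))

cat("== Antiparallel mainchain hydrogen-bond ladder ==\n")
bl <- make_beta_ladder(9)   # mirrors the 9-residue strand span of the dimer
cc <- classify_contacts(bl$structure, selection("A"), selection("B"))
print(cc[, c("resno_a", "resno_b", "kind", "distance")], row.names = FALSE)
write.table(cc, "results/beta_ladder_contacts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
stopifnot(identical(sort(unique(cc$resno_a)), bl$hbonds$res_a))
cat("Detected registry matches the constructed ground truth exactly.\n")
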