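#!/usr/bin/env Rscript
# Assembly stage: ring-feasibility of closed IgG/receptor-dimer polygons under
# the IgG1 hinge-angle range, and shape-category statistics of generated
# assembly sets at the published particle counts per IgG subclass.

suppressMessages(library(tie2ab))
dir.create("results", showWarnings = FALSE)

cat("== Ring feasibility under the 115-148 degree hinge range ==\n")
rf0 <- ring_feasibility(geometry_params(vertex_tolerance = 0), 3:14)
rf25 <- ring_feasibility(geometry_params(), 3:14)
tab <- data.frame(n = rf0$n, vertex_angle = rf0$vertex_angle,
                  feasible_strict = rf0$feasible,
                  feasible_tol25 = rf25$feasible)
print(tab, row.names = FALSE)
write.table(tab, "results/ring_feasibility.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Strict range admits n = 6..11; the vertex tolerance (Fab elbow, epitope",
    "tilt,\nout-of-plane pucker) opens the observed tetragonal and pentagonal",
    "rings.\n\n")

cat("== Category statistics at the published particle counts ==\n")
mixes <- list(
  IgG1 = list(n = 1381, prop = c(linear = 371 / 1381, tetragonal = 450 / 1381,
                                 pentagonal = 350 / 1381,
                                 hexagonal = 150 / 1381,
                                 gt_hexagonal = 60 / 1381)),
  IgG2 = list(n = 1162, prop = c(linear = 1031 / 1162, tetragonal = 60 / 1162,
                                 pentagonal = 40 / 1162,
                                 hexagonal = 31 / 1162)),
  IgG4 = list(n = 1277, prop = c(linear = 389 / 1277, tetragonal = 400 / 1277,
                                 pentagonal = 300 / 1277,
                                 hexagonal = 150 / 1277,
                                 gt_hexagonal = 38 / 1277)))
rows <- do.call(rbind, lapply(names(mixes), function(sub) {
  m <- mixes[[sub]]
  fx <- make_assembly_set(m$prop, m$n, seed = 7)
  labs <- vapply(fx$graphs, classify_assembly, "")
  stopifnot(identical(labs, fx$labels))   # classifier/generator round trip
  cp <- category_proportions(labs)
  data.frame(subclass = sub, t(cp$proportions_pct),
             polygonal_pct = cp$polygonal_fraction_pct, n = cp$total)
}))
print(rows, row.names = FALSE)
write.table(rows, "results/assembly_categories.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nPolygonal fractions by subclass:",
    paste(sprintf("%s %.1f%%", rows$subclass, rows$polygonal_pct),
          collapse = "; "),
    "\n(the flexible-hinge subclasses cluster into rings; the rigid one",
    "stays mostly linear).\n")
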