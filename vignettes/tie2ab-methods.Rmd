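---
title: "Methods: interface quantification, humanization, kinetics and ring geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface quantification, humanization, kinetics and ring geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tie2ab)
```

## Scientific setting

Tie2 is an endothelial receptor tyrosine kinase whose ectodomain ends in
three fibronectin-III domains (Fn1–3). The membrane-proximal Fn3 domain
mediates ligand-independent Tie2 homodimerization; an agonistic antibody that
binds Fn3 laterally can tether these preformed dimers into closed polygonal
rings, and that higher-order clustering — not mere binding — drives receptor
activation. `tie2ab` implements the computational analyses behind this
picture: quantifying the antibody–antigen and dimer interfaces from
coordinates, testing epitope conservation across species, humanizing the
antibody by CDR grafting with structure-guided back mutations, fitting 1:1
binding kinetics, and classifying assembly graphs into linear versus
polygonal categories.

## Coordinate model

A structure is a flat atom table (chain, author residue number, insertion
code, residue and atom names, element, coordinates in Å, occupancy,
B-factor). Author numbering is never altered: the literature cites epitope
residues such as V730 in author numbering, so any implicit renumbering would
corrupt every downstream residue reference. Alternate locations are resolved
to the highest-occupancy conformer, ties going to the alphabetically first
altloc identifier — the sources are silent on this, so the convention is
documented here and applied uniformly. Waters and heteroatoms are excluded
by default (the usual convention for interface areas; a switch retains
them). Multi-model files are rejected rather than silently truncated.
Insertion codes are carried but never used for arithmetic; residue ranges
select on the residue number alone.

## Solvent accessibility and buried surface

SASA uses sphere-point sampling (Shrake–Rupley): each atom's van der Waals
sphere is expanded by the probe radius (default 1.4 Å, water) and covered by
a deterministic golden-spiral lattice of 960 points; a point is accessible
if it lies outside every neighbouring expanded sphere. Radii are Bondi-type
(C 1.70, N 1.55, O 1.52, S 1.80 Å …); hydrogens are dropped before the
calculation (united-atom convention) and unknown elements fall back to
1.70 Å with a warning. The golden spiral makes results exactly reproducible;
960 points keep the two-sphere error well under 0.5 %, verified against the
spherical-cap closed form that `two_sphere_sasa()` provides as an
independent oracle. Points that fall exactly on a shared sphere boundary are
attributed to the earlier atom so that coincident atoms count their union
surface once.

Buried surface area follows the standard convention
BSA = (SASA~A~ + SASA~B~ − SASA~AB~)/2, computed over the atoms of the two
sides only, so it is exactly symmetric and unaffected by distant chains.
Published interface areas for this complex came from a different
implementation with unstated radii; percent-level differences between
algorithms are expected, which is why structure-level comparisons carry a
±5 % band rather than printed-digit agreement.

**Decomposition convention.** To split one side's buried surface into parts
(heavy versus light chain of a Fab), each part is scored against the partner
with the remaining parts removed. When parts bury disjoint patches — true
for an antibody's two chains on a compact epitope — contributions sum to the
undivided area within 1 %. The alternative (ΔSASA attribution inside the
full complex) needs an arbitrary rule for partner area shared between parts;
the isolation convention avoids that and is testable by construction.

Interface residues are those losing more than 0.1 Å² of SASA on
complexation (the threshold only suppresses sampling noise; any real contact
buries orders of magnitude more).

## Contact typing

Residue–residue contacts are typed by the first matching rule in the
precedence order ionic > hydrogen bond > hydrophobic, using
community-standard heavy-atom cutoffs: opposing formal charges within
4.0 Å; donor–acceptor pairs within 3.5 Å, with the donor-antecedent →
donor → acceptor angle ≥ 90° as a heavy-atom proxy for the D–H⋯A angle when
hydrogens are absent; apolar carbon pairs within 4.5 Å (backbone carbonyl
and carboxylate/amide/guanidinium carbons are excluded from "apolar").
Hydrogen bonds between mainchain atoms of both partners are flagged
separately (`mainchain_hbond`) because the receptor homodimer interface is
an antiparallel mainchain β-ladder and distinguishing it from side-chain
polar contacts is the scientifically interesting readout. The packaged
region table assigns the Tie2 epitope residues to the three published
interface regions (A: polar heavy-chain contacts; B: central hydrophobic
patch around V730; C: polar light-chain framework contacts); assignment is a
set, since one residue (I647) belongs to two regions.

## Conservation analysis

Ortholog comparison uses end-to-end global alignment with affine gaps
(BLOSUM62, open 10, extend 0.5) — orthologous domain windows are nearly
equal length, so local alignment would only hide real substitutions.
Identity is reported over aligned columns where neither sequence is gapped;
this denominator choice is stated because published percentages depend on
it, and `germline_identity()` reports an FR-only variant for the same
reason. Cross-reactivity prediction is deliberately strict: a species is
predicted cross-reactive only if **every** epitope position is identically
conserved. The underlying argument is exact-residue based (one
valine→arginine substitution abolishes binding), so a
conservative-substitution relaxation would be unfaithful to the logic being
reproduced; positions outside alignment coverage are reported as uncovered
and count against the prediction rather than being silently conserved.

## Humanization

The variable-domain frame is the IMGT unique numbering with CDR1 27–38,
CDR2 56–65, CDR3 105–117 and FR4 118–128. Numbering anchors a query to the
best-matching gapped germline (global alignment; identity < 40 % to every
reference is rejected as "not a V region") and inherits the germline's
frame. Loops whose length differs from the germline's are renumbered by the
IMGT symmetric fill — positions taken from both ends of the span toward the
middle, long CDR3 loops taking 111.x/112.x insertions. This
germline-anchored scheme is simpler and fully deterministic compared with a
profile-HMM numberer, and is adequate for sequences near a packaged
reference set; framework-length variants are out of its scope and are
rejected explicitly.

Grafting takes framework residues from the donor germline and the loops
(plus the whole CDR3/FR4 tail, which V genes do not cover) from the parent.
Flank rules are an explicit configured position list where the parental
residue is retained after grafting: the study applied exactly one such rule
(a serine→arginine reversion flanking the heavy CDR2), and a configurable
list reproduces that without promoting it to a general Vernier-zone policy
the data would not support. One numbering wrinkle is worth stating: the
published mutation positions (34, 36, 55, 59, 66, 72, 74) are treated here
as frame labels as given; under the fixed IMGT spans some of them fall
inside a CDR interval even though the original report places them on
framework strands, suggesting the published figure used sequential
numbering. The machinery is position-label agnostic, so this affects only
which positions the FR-difference scan visits, and the flank-rule mechanism
covers the boundary cases.

Back-mutation flagging scans framework positions where graft and parent
differ and inspects the parental residue's side chain in a structural
template. Three rules fire in fixed order: within 4.5 Å of the antigen
(`antigen_contact`), of the partner V domain (`vh_vl_interface`), or of any
CDR atom of either chain (`cdr_support`). All triggered rationales are
reported with the first as primary. The 4.5 Å heavy-atom cutoffs are the
conventional van der Waals contact shell; the original analysis was
qualitative, so the cutoffs are exposed as configuration. The parental
crystal Fv serves as the template — homology-model construction is out of
scope, and for back-mutation flagging the parental structure is exactly the
geometry whose preservation the rules test.

Registry germline sequences are not shipped: they are distributed by the
germline registry, not reproducible from the study text, and transcribing
them from memory would fabricate reference data. All grafting and flagging
tests therefore run on synthetic Fv/germline pairs from `make_fv_pair()`,
which control identity exactly and mark CDR composition so positional
bookkeeping errors are visible. Tests requiring the real registry and the
deposited coordinates read them from documented local paths and fail (not
skip) when absent.

## Binding kinetics

The 1:1 Langmuir model dR/dt = k~on~·C·(R~max~ − R) − k~off~·R has closed
forms for both phases; the package uses them for simulation and the fit
model, with an adaptive ODE integration as the independent oracle in tests
(agreement ≤ 10⁻⁶ relative). Global fitting shares one
(k~on~, k~off~, R~max~) across all non-blank traces, subtracts the blank
trace point-wise when present, and minimises least squares by
Levenberg–Marquardt on log-scale parameters — the rates span decades, and
the log transform makes the problem well-scaled and keeps iterates positive.
Initial values come from the dissociation tail log-slope (k~off~), the
observed-rate relation k~obs~ = k~on~C + k~off~ on the top trace (k~on~) and
1.2× the maximal response (R~max~); bounds are k~on~ ∈ [10², 10⁹] M⁻¹s⁻¹,
k~off~ ∈ [10⁻⁶, 1] s⁻¹. Mass-transport limitation and baseline drift are
deliberately not modelled: the reference analysis used a plain 1:1 model,
and adding transport terms to simulated 1:1 data would only soak up noise.
The association/dissociation boundary is supplied explicitly (300 s/300 s
for the SPR ladder of 0, 2, 4, 8, 16, 32, 64 nM), not detected.

K~D~ = k~off~/k~on~ is reported exactly and at two significant figures, the
precision of printed kinetic tables. One internal inconsistency in the
published numbers is handled explicitly: the parental row's printed K~D~
(4.2×10⁻⁹ M) differs from the two-significant-figure quotient of its printed
rates (4.3×10⁻⁹ M), presumably because unrounded rates were used for the
printed K~D~. Consistency checks therefore use the humanized-variant rows,
whose printed triples are self-consistent.

## Assembly geometry

The hinge-angle argument is made quantitative by identifying the angle
between the two Fab arms of an IgG at a ring vertex with the interior angle
of a regular n-gon, 180(n−2)/n. The IgG1 hinge range 115–148° then admits
n = 6…11 exactly; the observed tetragonal (90°) and pentagonal (108°) rings
require the unmodelled flexibility — Fab elbow bending, the ~15° epitope
tilt, out-of-plane pucker, non-regular rings — which is absorbed into a
single vertex tolerance, default 25°, rather than a multi-parameter model
the images could not constrain. Feasibility is monotone in the tolerance by
construction. A companion check compares the receptor-dimer
epitope-to-epitope span (~120 Å) with the optimal paratope separation of an
IgG (~130 Å) under a 20 Å slack.

Assembly graphs are bipartite (IgG hubs versus receptor dimers, degree ≤ 2
on both sides, one Fab per epitope). A connected acyclic graph is linear; a
single cycle is categorised by its hub count (3 → below-tetragonal,
4/5/6 → tetragonal/pentagonal/hexagonal, ≥ 7 → above-hexagonal; a 2-hub
closed dimer also falls below tetragonal). Disconnected inputs are an error
so that callers classify components individually and no particle is silently
double-counted. Category statistics report exact counts, proportions to one
decimal and the polygonal fraction (tetragonal and larger).

## Synthetic data: what it does and does not show

Every stage has a generator whose ground truth is exact by construction:
two-sphere fixtures (closed-form SASA), slab complexes whose contact split
is an atom-count ratio, ideal β-ladders with a known bond registry,
Fv/germline pairs with exact identity and marked CDRs, noiseless or
Gaussian-noise sensorgrams from known rates, and assembly sets with
largest-remainder exact category counts. Passing the round-trip suite shows
the algorithms are correct on inputs satisfying their assumptions; it does
not show robustness to real-data pathologies — crystallographic disorder,
non-ideal hydrogen-bond geometry, analyte rebinding and drift in
sensorgrams, or ambiguous particle shapes — which the generators
deliberately do not emulate.

Problem sizes used by the test suite and the acceptance script are chosen
to exercise the mathematics at the study's scale while staying desk-sized:
SASA fixtures ≤ 300 atoms at 960 points/atom, the 7-concentration ladder at
1–2 s sampling, 100 noise seeds for the recovery study, and 1381 assemblies
(the published IgG1 particle count) for the classification round trip.

## Degenerate inputs and tie-breaks

Empty selections warn (absent chain) or error (empty side of an interface);
zero-atom SASA is an error. Coincident spheres resolve by the
earlier-atom rule above. Germline selection breaks exact identity ties by
lexicographic gene name, with a warning. The alignment backend resolves
equal-scoring alignments deterministically, so all derived quantities are
reproducible. An empty epitope list yields a vacuously true cross-reactivity
prediction, flagged with a warning rather than hidden. Largest-remainder
rounding breaks remainder ties by category order.

## Known limitations

SASA is O(n²) in atoms with dense sampling — appropriate for domain-scale
interfaces, not whole ribosomes. The numbering scheme rejects framework
indels rather than modelling them. The kinetics module fits only the 1:1
model (no bivalent-analyte or heterogeneous-ligand variants, no proprietary
instrument formats). Ring geometry is a planar regular-polygon
idealisation; 3-D ring reconstruction and image processing are out of
scope. Structure-level reproduction of the crystallographic interface
numbers requires the deposited entry as a local file, since coordinate
archives cannot be redistributed inside the package.
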