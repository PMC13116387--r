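---
title: "GradeScreen: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GradeScreen: models, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it
implements: the scoring model and its assumptions, the conventions that
were genuinely open and how they were fixed, what the synthetic-data
generators do and do not emulate, and the numerical choices that keep
the test suite deterministic.

## The seven-criterion drug-likeness score

A compound's total score is a weighted linear combination of seven
component scores, each normalized to [0, 1]:
S_total = 0.15·S_Lipinski + 0.10·S_Veber + 0.10·S_Ghose + 0.20·S_QED +
0.15·S_SA + 0.20·S_ADMET + 0.10·S_PAINS. QED and the ADMET rule block
carry the largest weights as the strongest attrition predictors;
Veber, Ghose and the structural-alert score act as supplementary
filters. Letter grades are assigned on fixed left-closed bands
(A ≥ 0.85, B ≥ 0.70, C ≥ 0.55, D ≥ 0.40, F below), so a score exactly
at a boundary takes the better grade.

**Normalization of rule-based criteria.** Lipinski, Veber, Ghose and
ADMET are scored as the *fraction of their sub-rules passed* rather
than as pass/fail bits. This is a deliberate design choice: fractions
give a graded, monotone signal (a compound violating one Lipinski rule
is less damaged than one violating three), make the aggregation
continuous enough to spread a screening library across all five
grades, and are testable against hand counts. The ADMET block is a
fixed six-bound rule list (150 ≤ MW ≤ 500 Da, −0.7 ≤ logP ≤ 5.0,
TPSA ≤ 140 Å², rotatable bonds ≤ 10, H-bond donors ≤ 5, aromatic
rings ≤ 4) — property ranges associated with acceptable absorption and
safety windows, not an ML predictor.

**Alert penalty.** S_PAINS = max(0, 1 − 0.5·n_alerts), where n_alerts
counts distinct matched alert classes across both catalogs. This is
the simplest monotone map that scores a clean compound 1, a one-alert
compound 0.5 and anything with two or more alerts 0.

## Descriptor backend and its consequences

All structure perception runs through OpenBabel (ChemmineR/ChemmineOB).
Before any descriptor is computed a molecule is normalized to its
canonical *isomeric* SMILES, which is also the deduplication key: two
encodings of one molecule (atom order, Kekulé vs aromatic, explicit
hydrogens) collapse to one key, while stereoisomers stay distinct.
Duplicate filtering keeps the first occurrence, and rejection reasons
have a fixed precedence (missing SMILES, then unparseable, then
duplicate), so the kept/rejected split always partitions the input
deterministically.

Particular estimator choices, all fixed and documented because the
score depends on them:

- **logP** is OpenBabel's atom-contribution (Wildman–Crippen-type)
  estimate.
- **Rotatable bonds** are counted by the standard SMARTS
  `[!$(*#*)&!D1]-!@[!$(*#*)&!D1]` (acyclic single bonds between
  non-terminal atoms; amide C–N bonds are counted).
- **Aromatic rings** are unique 5- and 6-membered aromatic cycles.
- **QED** is implemented in-package as the published
  desirability-function composite: eight properties, each mapped
  through an asymmetric double sigmoid with the published fitted
  parameters, combined as a weighted geometric mean. The ALERTS
  property counts hits in the package's BRENK-style catalog. Because
  property inputs come from OpenBabel rather than other toolkits'
  perception rules, absolute QED values can differ by a few hundredths
  from other implementations; where alert and acceptor counts agree,
  values agree to three decimals.
- **Synthetic accessibility** is a deterministic complexity-based
  estimate on the conventional 1 (easy) to 10 (hard) scale, built from
  molecule size, ring-fusion atoms, declared stereocenters, macrocycle
  presence, total ring count and unusual elements. The classical
  fragment-contribution formulation needs a multi-megabyte fragment
  frequency table; the complexity terms used here are the part of that
  method that is self-contained, and the component score only consumes
  the affine map (10 − SA)/9, so ranking behavior — small rigid
  drug-like molecules near the easy end, stereo-rich polycycles near
  the hard end — is what matters.
- **Alert catalogs** ship as versioned plain-text SMARTS tables:
  a curated PAINS subset covering the high-frequency interference
  families (catechols, quinones, rhodanines, hydroxyphenyl hydrazones,
  azo dyes, alkylidene barbiturates, Mannich phenols, cross-conjugated
  enones) and a BRENK-style unwanted-functionality set (reactive,
  toxic and unstable groups). They are data, not code: rows can be
  audited or extended without touching the scorer.

## Docking geometry conventions

The docking box is the axis-aligned bounding box of the co-crystal
ligand plus padding: center = per-axis midpoint of min/max, size =
per-axis extent + 2δ, δ = 4.0 Å by default. A single-atom ligand
therefore produces an 8 Å cube — the degenerate case is well-defined.

Structure screening accepts a complex only if all four criteria hold:
human origin, X-ray method with resolution strictly below 3.0 Å, a
single protein chain, and a co-crystal ligand of at least 100 Da
(heavy-atom mass estimate when only coordinates are available).
Unknown metadata fails closed. The resolution bound is strict and the
ligand-weight bound inclusive, exactly as stated.

RMSD is the raw coordinate deviation sqrt(mean ‖r_i − r'_i‖²) with
correspondence by atom order and **no superposition**: redocked and
reference poses share the docking frame, so a uniform translation
contributes its full magnitude. There is no symmetry correction — for
symmetric ligands this can overestimate deviation, a known limitation.
The redock verdict is inclusive at the 2.0 Å threshold. Alternate
locations in PDB input are resolved by keeping the blank or
highest-occupancy altloc (ties to the earlier letter), and multi-copy
ligands resolve to the first chain/residue instance in file order.

## Interaction typing

Contacts are typed by distance only, on heavy atoms: hydrogen bonds
(donor↔acceptor ≤ 3.5 Å), salt bridges (cation↔anion ≤ 5.5 Å),
hydrophobic contacts (apolar carbon pairs ≤ 4.0 Å) and π interactions
(ring-centroid↔ring-centroid or centroid↔cation ≤ 5.5 Å; stacking and
cation–π are reported under one kind). Full interaction-profiler
geometry (donor–H–acceptor angles, ring-plane angles, halogen bonds,
water bridges, metal coordination) is intentionally out of scope;
distance-only criteria overcall contacts relative to angle-filtered
profilers, and summaries should be read accordingly.

Protein atom roles come from a residue/atom-name template table
shipped as data (backbone N/O, Ser/Thr/Tyr hydroxyls, Asp/Glu
carboxylates, Lys/Arg cations, apolar side-chain carbons,
Phe/Tyr/Trp/His rings). Ligand roles are perceived from element
identity and distance-based connectivity (bond within 1.75 Å, 1.95 Å
when S/P is involved): N/O acceptors, hydroxyl-like O and low-degree N
donors, carboxylate O anions, terminal amine N cations, carbons
without N/O neighbors hydrophobic, and planar 5/6-cycles of C/N as
aromatic rings. These rules are deliberately simple, deterministic and
auditable; they are not a protonation model.

## Network ranking conventions

The PPI graph is undirected, simple and unweighted after thresholding:
confidence scores only gate edges (kept iff ≥ 400, inclusive;
duplicate undirected edges keep the maximum score; self-loops are
dropped). The five centralities follow fixed conventions, since the
composite depends on them: normalized betweenness; closeness computed
per connected component as (n_c − 1)/Σd; degree over N − 1;
eigenvector centrality by power iteration scaled to max 1; PageRank at
damping 0.85. The power iteration runs on A + I — the same principal
eigenvector, but the spectral shift prevents oscillation on bipartite
graphs — with a successive-change tolerance of 1e-13, chosen well
below the 1e-9 accuracy the composite is validated to because the
per-step change underestimates distance to the limit.

Z-scores use the sample (n − 1) standard deviation over **all** nodes
of the network, and a column that is constant up to floating noise
(sd below 1e-12 relative) maps to all zeros, so fully symmetric graphs
get all-zero composites instead of amplified rounding noise. Composite
ties break lexicographically by gene symbol for reproducibility. The
default composite weights are betweenness 0.25, closeness 0.25, degree
0.20, eigenvector 0.15, PageRank 0.15, with the top 30 flagged.

## What the synthetic generators emulate

**Compound libraries** are sampled from an embedded ~95-structure
SMILES panel stratified by the grade each structure receives under the
default scorer; the default mix (A 25/171, B 92/171, C 37/171,
D 10/171, F 7/171) emulates a screening library dominated by good but
not excellent compounds. Library size is apportioned across grades by
largest remainder and strata are sampled with replacement, so the
generated library reproduces the target mix up to apportionment — by
construction, not approximately. The panel is sampled rather than
generating random SMILES because random strings rarely parse. What
this does *not* emulate: the chemical diversity of a real enrichment
hit list (the panel repeats structures), assay-driven composition, or
name/identifier noise.

**Toy complexes** place each planted contact in its own spatial motif
(motif centers 16 Å apart): hydroxyl-O→Ser OG for hydrogen bonds,
carboxylate-O→Lys NZ for salt bridges, lone carbon→Leu CD1 for
hydrophobic contacts, benzene↔Phe ring coaxial for π. Contact
distances are sampled at least 0.1 Å inside their cutoff and every
non-planted pair sits at least 0.5 Å outside every cutoff, so
floating-point boundary flakiness cannot change the contact set; a
zero-contact specification still emits a single inert carbon ligand.
Filler atoms and waters sit on a distant shell. These are geometric
benchmarks, not protein folds: passing recovery tests shows the
typing/cutoff machinery is exact, not that role perception is complete
for arbitrary chemistry.

**Networks** use preferential attachment (m = 2) over 311 genes by
default, edge scores from a two-component mixture (40% below the 400
threshold), and an optional planted hub wired to 30% of genes. Degree
distributions are scale-free-like but not degree-sequence-exact
replicas of any real STRING subnetwork.

All generators are pure functions of their arguments including the
seed (R's Mersenne-Twister stream, seeded locally and restored), so
identical calls give byte-identical artifacts.

## Validation design and problem sizes

The suite validates each stage against independent oracles: docking
boxes against a per-axis brute-force min/max scan on 1000 random
coordinate sets; contacts against an all-pairs double-loop scan and
against planted ground truth on 50 seeded complexes; centralities and
the composite against hand-written brute force (simple-path
enumeration for betweenness/closeness, dense eigendecomposition for
eigenvector, a direct linear solve for PageRank) on the exhaustive
catalog of labeled connected graphs with up to 4 nodes plus 100 seeded
random connected graphs on 5–8 nodes, to 1e-9. The exhaustive catalog
stops at 4 nodes because the labeled catalog grows astronomically
beyond that; random graphs cover the larger sizes. Planted-hub
recovery uses 20 seeded 311-gene networks and requires the hub ranked
first in at least 19. Aggregation boundedness/monotonicity run over
10^4 random component vectors. These sizes keep the default test run
fast while exercising every code path at the scale the defaults
target.

## Known limitations

- Descriptor values are OpenBabel's; other toolkits' perception (HBA
  definitions, aromaticity models) shifts component scores by small
  amounts, so absolute S_total values are backend-specific even though
  the framework's arithmetic is exact.
- The SA estimate ranks complexity sensibly but is not calibrated to
  the fragment-contribution scale's absolute values.
- The PAINS subset trades recall for auditability and size; a clean
  scan here does not guarantee a clean scan against the full
  published catalogs.
- Interaction typing is distance-only and protonation-blind.
- Docking execution itself (engine runs, protonation, PDBQT
  conversion) is outside the package: it prepares inputs for and
  validates outputs of any engine.
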