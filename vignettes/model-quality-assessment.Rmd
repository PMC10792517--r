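---
title: "Assessing predicted protein structures with modelcritic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing predicted protein structures with modelcritic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modelcritic)
```

## Overview

modelcritic implements the model-quality-assessment machinery used in
community experiments on protein tertiary structure prediction: a panel of
complementary structural metrics, a two-round z-score tournament that
aggregates them into a group ranking, and a set of downstream analyses that
ask where models deviate from experiment and whether those deviations
matter for applications such as molecular replacement (MR) and functional
annotation. This vignette explains the models and procedures, the tunable
parameters and their defaults, the numerical choices made where the
published procedures leave latitude, and what the synthetic-data generator
can and cannot tell you about behaviour on real data.

## Structures and correspondence

Structures are parsed from PDB or mmCIF via bio3d with the assessment's
conventions applied at the door: hydrogens dropped (every metric here is
heavy-atom), alternate locations resolved to the highest-occupancy
conformer (ties favour altloc "A"), and non-standard/HETATM residues
discarded. Crystal targets carry their cell and space group; predictions
carry per-atom confidence (pLDDT, 0–100) in the B-factor column, taken at
face value — off-scale values are passed through with a warning, never
rescaled, mirroring how wrong-scale submissions are treated in practice.

Target and model residues are matched primarily by author numbering
(chain, residue number, insertion code). When fewer than half of the
target residues match — renumbered submissions — the matcher falls back to
a per-chain global sequence alignment (match +1, mismatch −1, gap −2),
which is deterministic and dependency-free. Pairs whose residue type
differs stay in the map for backbone metrics but are excluded from
side-chain metrics. Evaluation units (EUs) — the sub-chain segments over
which scoring happens — are consumed as input tables
(`target_id eu_id selection difficulty taxonomy`, selection syntax
`A:1-120+A:180-210`); constructing EUs and classifying difficulty are out
of scope.

## The metric panel

**GDT_TS / GDT_HA.** For each distance threshold ({1,2,4,8} Å for TS,
{0.5,1,2,4} Å for HA) the score needs the maximal fraction of Cα pairs
simultaneously superposable within the threshold. This is a non-convex
search; the exact parameterisation used by the reference LGA program is
not public, so the package uses a seeded iterative search: superpositions
seeded from every contiguous window of lengths 3, 5 and 7 (plus the whole
chain), each iterated fit-inliers → refit to a fixed point, best inlier
count kept, ties broken by lower inlier RMSD. On chains of ≤ 12 residues
the search additionally seeds from every residue triple, making the
small-chain behaviour exact with respect to triple seeding — this is what
the oracle-equivalence tests compare against. Unmatched target residues
count as failures (a coverage penalty), so a model of half the target can
score at most 50. The superposition found at the shared 4 Å threshold is
kept as the *final* superposition; its per-residue Cα distances feed all
local-error analyses, making them independent of the TS/HA mode.

**LDDT.** Superposition-free: reference distances are all heavy-atom pairs
in the target between distinct residues within 15 Å; a pair is preserved
at a threshold if the model reproduces it within that threshold; the
per-residue score averages preserved fractions over {0.5,1,2,4} Å. Pairs
involving atoms the model does not have count as violated, and residues
entirely absent from the model score 0. No stereochemistry gate is
applied.

**Sphere-Grinder.** Local-environment accuracy: all matched heavy atoms
within 6 Å of a residue's Cα are locally superposed; the score is the
percentage of residues with local RMSD ≤ 2 Å. Residues with fewer than 3
local atoms pass trivially.

**CAD (all-atom surrogate).** The published score uses Voronoi
tessellation of atomic volumes; re-implementing that was deliberately
avoided. Instead, residue–residue contact areas are estimated by sampling
each atom's solvent-extended sphere (golden-spiral points, deterministic;
default 256/atom, 64 in bulk scoring) and assigning each point to the
nearest other atom whose extended sphere contains it. The score is
`1 − Σ min(|A_model − A_target|, A_target) / Σ A_target` over target
contacts. It is exact at the identity and clamps to 0 when all contacts
are lost; doubling the sample count moves scores by < 0.02 on fixtures.

**DipDiff.** The cited description is verbal, so the concrete form here
is: for each consecutive residue pair, compare the four distances
{Cαi–Cαi+1, Cαi–Oi+1, Oi–Cαi+1, Oi–Oi+1}; each pair scores
max(0, 1 − meanΔ/1 Å); the mean is scaled to 0–100. Identity gives 100;
the tolerance is an argument.

**Clash surrogate.** MolProbity's clashscore requires hydrogen placement;
the package instead counts heavy-atom pairs with van der Waals overlap
≥ 0.4 Å (radii C 1.70, N 1.55, O 1.52, S 1.80 Å), per 1000 atoms. Pairs
within three bonds (bonded, 1-3, 1-4) by standard residue topology and
peptide links are excluded: 1-4 backbone contacts such as O(i)–CA(i+1)
sit inside the raw overlap cut in perfectly ideal geometry, so counting
them would flag flawless structures.

**Torsion metrics.** φ/ψ and χ1–χ4 come from the canonical atom
quadruples. Backbone deviation is the mean over residues of the RMS
circular (φ, ψ) difference; side-chain deviation the analogous χ quantity;
AAA is the percentage of χ angles within 40°. For the terminal dihedrals
of Asp, Glu, Phe and Tyr the difference is minimised over the 180°
chemical-equivalence flip. (The published equivalence list says "Asp, Gly,
and Tyr"; Gly has no side chain, so this is treated as a typo for the
standard four-residue set — the list is an argument, so other choices are
one keyword away.)

**ASE.** Self-assessment accuracy: `100·(1 − mean |pLDDT/100 − LDDT|)`
per residue. Whether the original applied a sigmoid to the differences is
unknown; the linear form is documented and swappable.

**Solvent accessibility.** Shrake–Rupley with a 1.4 Å probe over heavy
atoms; relative accessibility against theoretical Gly-X-Gly maxima (Tien
et al. values); a residue is *surface* when relative SASA exceeds 20%
(strictly). Surface classification is always computed on the full target
chain before EU restriction, so a residue buried in the full structure
stays "buried" even if its EU exposes it.

**Secondary-structure composition.** DSSP is out of scope; a φ/ψ-box
assignment stands in (helix: φ∈[−100,−30], ψ∈[−80,−5]; strand:
φ∈[−180,−45], ψ∈[90,180]∪[−180,−170]; runs ≥ 3 required). Labels follow
the helix fraction among regular residues: all-α (100%), mostly-α (>65%),
mixed, and symmetrically for β.

**MSA depth.** Neff/length is imported data in the original study without
a published formula; the stand-in clusters aligned sequences at 80%
pairwise identity (each sequence contributes 1/cluster-size) and divides
by the ungapped query length.

## Ranking

Per EU and metric, group values (model-1 submissions by default) are
z-scored twice: values below z = −2 in round 1 are excluded as outliers,
the mean and standard deviation are recomputed over survivors, and final
z-scores are assigned to everyone from the recomputed statistics. The
standard deviation is the population form (ddof 0) — the convention in
these tournaments and deterministic on tiny fixtures. Outlier exclusion is
applied per metric (whether the original applied it per metric or per
composite is unstated). Lower-is-better metrics (clash, backbone and
side-chain deviation) are negated first.

The composite weights are 1/16 on {LDDT, CAD, SG, side-chain}, 1/12 on
{clash, backbone, DipDiff}, and 1/4 on {GDT_HA, ASE, reLLG}. With all ten
z-scores at 1 the composite is 1.25; the printed formula was interpreted
as retaining these group weights un-renormalised after the reLLG term was
added. reLLG is an external input column; when absent, the composite runs
in 9-metric mode (total weight 1) rather than silently renormalising.
Group totals sum max(S, 0) over EUs — only positive contributions count,
so a few disastrous models cannot erase consistent performance — and
groups attempting fewer than 10 EUs are dropped. Ties share the better
rank; best-model counts give strict maxima full credit and split ties
1/k. Fisher's exact test (two-sided, by hypergeometric enumeration) backs
enrichment statements; heatmap layouts come from Ward clustering
(`ward.D2`) on Euclidean distances with column-mean imputation of missing
entries (imputed values are used for distances only).

## Local error and structural context

Per-residue error is the Cα distance under the 4 Å GDT superposition.
Error regions are maximal runs of ≥ 3 consecutive residues whose 5-residue
centred rolling mean (truncated at termini; absent residues break runs) is
≥ 3 Å. Residues are at a lattice/chain/domain interface when they have ≥ 3
Cα contacts within 10 Å in symmetry mates / other chains / other domains;
regions are labelled by a mean of ≥ 0.5 such neighbours per residue.
Where a residue or region qualifies for several classes the label follows
the precedence lattice > chain > domain, because the headline contrast in
the analyses is lattice versus the rest. Symmetry mates come from
tabulated space-group operators (P 1 and a few common monoclinic /
orthorhombic groups; unknown symbols fall back to identity with a warning
— no external symmetry library exists in this stack, and the synthetic
lattices are P1). B-factor binning z-normalises B per target ("normalised"
is not further specified; the z-score is the package's reading), pools
residues of model-1 submissions with GDT_TS > 80, and splits them into 10
equal-count bins.

## MR preparation and functional sites

`trim_by_plddt` removes residues whose *first* atom scores below 70 —
deliberately the first atom, not the residue mean, reproducing the
documented behaviour of the preparation tool on atomic-level pLDDTs.
`slice_rigid` splits a model into 2–4 pieces by incremental (BIRCH-style)
leaf clustering of Cα coordinates: the threshold starts at a quarter of
the radius of gyration and tightens until at least k leaves exist, nearest
centroids merge down to exactly k, and sequence segments shorter than 3
residues join their flanking piece. PAE-based decomposition is explicitly
not implemented. `llg_points` consumes an external LLG table: x = number
of groups attempting ≥ 1 target; per target the best model earns x points,
the next x−1, and so on; LLG < 60 earns nothing; ties share the higher
value (the original is silent on ties).

`site_rmsd` fits the model's catalytic-site heavy atoms (2–6 residues)
onto the target's by least squares and reports the RMSD minimised over
every combination of equivalence flips of the site residues (His ring
flips behind a flag); models with GDT_HA ≤ 30 are excluded. A single joint
fit over all site atoms is used (per-residue independent fits would hide
relative-geometry errors, which are the point of the analysis).

## The synthetic-data generator

`build_peptide` constructs full heavy-atom peptides from internal
coordinates (N–Cα 1.458, Cα–C 1.525, C–N 1.329 Å, trans ω) over a
10-residue alphabet (Ala, Gly, Leu, Asp, Glu, Phe, Tyr, Arg, Ser, His —
enough to exercise every χ and equivalence rule). Side chains take the
first clash-free candidate from a small rotamer set, deterministically, so
ideal structures always have clash score 0. `perturb` applies segment
rigid transforms, per-residue Gaussian noise (optionally coupled to the
target's normalised B-factor), and uniform χ re-sampling. `emulate_plddt`
writes clipped noisy copies of the actual per-residue LDDT into the B
column. `make_ensemble` plants group skills: noise σ = 4 Å × (1 − skill),
jittered ±30% per model, with model 1 drawn from the same distribution so
self-ranking is uninformative by construction; targets are 16-residue
helix–loop–strand peptides with gamma-distributed B-factors, which keeps
the full 10-metric panel over 10 groups × 20 EUs within minutes on one
CPU. Those sizes are the package's study conditions throughout the tests
and the acceptance script.

What passing these simulations shows: the metrics order models correctly
by controlled error, the tournament recovers planted skill (Spearman ≥
0.9), injected ≥ 5-residue displacements are found by the region detector,
and B-coupled noise produces monotone error bins. What they cannot show:
behaviour on real experimental artefacts (missing density, alternate
conformations, oligomeric context), realistic side-chain packing, or
metric calibration against the reference implementations' exact outputs —
the CAD, DipDiff, Sphere-Grinder and clash implementations are documented
surrogates with their own constants, all overridable.

## Numerical choices and degenerate inputs

Kabsch superposition refuses fewer than 3 pairs and collinear point sets;
the GDT search falls back to the seed fit when an inlier set is collinear.
Circular angle differences live in [0, 180]; dihedrals are undefined (and
warn) for collinear quadruples. Zero-variance z-scores return 0 for
everyone. The round-1 outlier rule is *strictly below* −2, so a value at
exactly −2 survives; trimming keeps first-atom pLDDT exactly 70;
surface classification requires relative SASA strictly above 0.20. Fisher
enumeration treats probabilities within a 1e−7 relative tolerance of the
observed table as "as extreme", matching the convention of the reference
implementation in stats.

## Limitations

Single-model-per-file PDB input (no multi-MODEL ensembles); no mmCIF
writing; no cryo-EM maps or diffraction data (LLG and reLLG are consumed,
never computed); space-group coverage is the tabulated set; the sequence
alignment fallback is global and ungapped-scored, adequate for renumbered
submissions but not for heavily split chains.
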