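---
title: "Network-based prediction of mutation-induced stability changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based prediction of mutation-induced stability changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinstab)
```

## The model

`rinstab` predicts the folding free-energy change of a single amino-acid
substitution, ΔΔG = ΔG~wt~ − ΔG~mut~ in kcal/mol, from the wild-type
structure alone — no mutant model is built. The default sign convention
is *positive = destabilizing*; it is a configuration flag
(`sign_convention`) because stability datasets in the literature are
inconsistent about the sign, and the curation filter
(`apply_curation_filters()`) applies its 5 kcal/mol destabilization
bound on whichever side the convention marks as destabilizing.

The central representation is the residue interaction network. Nodes
are residues; a generic contact edge (IAC) connects every residue pair
whose closest heavy atoms are within 5 Å, and typed edges are added when
their geometric rule fires:

| edge type  | rule                                                 | default |
|------------|------------------------------------------------------|--------:|
| IAC        | closest heavy-atom distance                          |   5.0 Å |
| HBOND      | N/O heavy-atom pair                                  |   3.5 Å |
| IONIC      | charged-group atoms of Arg/Lys/His vs Asp/Glu        |   4.0 Å |
| PIPISTACK  | aromatic ring centroids (Phe/Tyr/Trp/His)            |   6.5 Å |
| PICATION   | ring centroid to Lys NZ / Arg CZ                     |   6.0 Å |

Only the 5 Å closest-atom rule is fixed by the network definition; the
typed thresholds are standard literature values and are configurable
(`default_rin_params()`). Edges require a sequence separation of at
least 2 on author numbering, so covalently adjacent backbones do not
dominate the topology; hydrogens are ignored because most crystal
structures lack them. Centralities (degree, local clustering,
closeness, betweenness; unweighted paths) are computed on six
subnetworks — one per edge type plus ALL — for the mutation site and its
two sequence neighbours. Conventions for sparse graphs are explicit:
clustering is 0 below degree 2, closeness is (n~c~ − 1)/Σd within the
node's component and 0 for isolated nodes, betweenness is normalised by
(n − 1)(n − 2)/2 over the full node set.

The descriptor has 184 named slots (see the README table). The total
and the feature families are fixed; the exact slot-by-slot decomposition
2 + 80 + 4 + 3 + 2 + 72 + 20 + 1 is this package's design, chosen so
that one-hot sequence information occupies 80 slots (close to half),
network topology uses 3 positions × 6 subnetworks × 4 measures, and the
layout is serialised in a machine-readable manifest
(`default_manifest()`, `write_manifest()`) so alternatives remain
testable. Two ablations mirror common practice of measuring the
contribution of network features: `"no_topology"` (drops centralities,
composition and size; 91 slots) and `"minimal"` (environment, one-hot,
local context, conservation, the potential terms, network size; 90
slots). pH and temperature pass through unnormalised — the model scales
all inputs internally.

## Structure annotation

Secondary structure is assigned in simplified 3-state form rather than
by shelling out to an external program. A backbone hydrogen bond
between CO(i) and NH(j) is scored with the classic electrostatic model
E = 0.084·332·(1/d(ON) + 1/d(CH) − 1/d(OH) − 1/d(CN)) kcal/mol and
accepted below −0.5 kcal/mol; the amide hydrogen, when absent from the
file, is placed 1 Å from N along the previous residue's O→C direction.
Helices are residues covered by two consecutive i→i+4 turns; strands
are members of parallel/antiparallel bridge patterns (|i−j| ≥ 3); helix
wins ties; everything else, including residues with incomplete
backbones and chains shorter than five residues, is coil. A
pre-computed DSSP output file can override the internal assignment
(`read_dssp()`/`apply_dssp()`).

Accessibility uses Shrake–Rupley sampling (92 spiral points per atom,
probe 1.4 Å, element van der Waals radii) summed per residue and
normalised by the Rost & Sander (1994) maximum-ASA table, clipped to
[0, 1]. The buried/exposed split is RSA ≤ 25 %. The maximum-ASA table
is a genuine degree of freedom — different reference tables shift RSA by
several percent near the threshold — which is why the table is shipped
as data and the threshold is a parameter.

## Evolutionary features and potentials

The alignment is a user input; the package never runs a homology
search. Conservation of a column is 1 − H/log₂20 with gaps excluded
(an all-gap column scores 0). Mutual information between two columns
is the plug-in estimate over co-ungapped rows (0 below two rows), and
the average cluster purity of a position is the mean, over its network
partners, of the frequency of the partner column's majority residue
among rows that carry the query's residue at the position. These
definitions are fixed here and unit-tested; they are deliberately the
simplest members of their families, and the provider interface accepts
alternatives. Without an MSA the features default to conservation 1,
MI 0, ACP 1 with a warning, so prediction degrades gracefully.

The two potential slots are a simplified stand-in for full
statistical-potential suites (each of which is its own body of work and
out of scope): `pairwise(i) = Σ_j −log(f_obs/f_exp)` over the residue's
IAC neighbours using a 20×20 observed/expected contact table, and
`solvation(i) = −log(P(state|aa)/P(state))` for the residue's burial
state. The default reference statistics are computed once per session
from a small deterministic ensemble of **synthetic** seeded
random-sequence helices and hairpins (12 structures) — they make the
terms well-defined and reproducible but carry no real-protein
information; users with genuine potential outputs should inject them
via `load_external_scores()`, which bypasses the built-in provider
entirely. A torsion-angle term is omitted from the default manifest to
respect the 184-slot budget.

## The regressor

A single hidden layer of 5 tanh units with a linear output. Five
units suffice for this descriptor family; the width is a parameter.
Inputs and the target are min–max scaled to [−1, 1] using
training-split statistics (the convention of the classic MLP tools this
design follows); predictions are mapped back to kcal/mol. Weights
start from seeded uniform(−0.5, 0.5). Training is *online*
backpropagation with momentum: one update per instance, instance order
reshuffled every epoch. Early stopping holds out the last 15 % of a
seeded shuffle as a validation set and stops once validation RMSE has
not set a new minimum (tolerance 10⁻⁶) for 5 consecutive epochs,
returning the best-validation-epoch parameters. Ten-fold
cross-validation uses a seeded random partition with per-fold derived
seeds, so the whole procedure is reproducible from one integer.

Defaults: momentum 0.2, at most 500 epochs, learning rate **0.1**. The
classic online-backpropagation default of 0.3 was tried first and
rejected: on this 184-wide scaled descriptor the per-instance updates
overshoot — training RMSE oscillates between ~0.4 and ~1.5 across
epochs and never converges, on every seed tried — while 0.1 converges
smoothly. 0.3 remains one flag away. The `activation = "identity"`
option turns the network into a linear model, used in tests to verify
the closed-form limit: with zero noise and a small step size, training
on an exactly linear target recovers it to held-out RMSE below
0.05 kcal/mol (observed ~10⁻⁵).

## Evaluation statistics

Pearson *r* on raw values; Spearman ρ as Pearson on average ranks;
Kendall τ = (CP − DP)/(n(n−1)/2) with pairs tied in either vector
counting in neither CP nor DP; and σ = √(Σ(ŷ−y)²/(n−1)), the root
residual spread in kcal/mol (denominator configurable to n — the
literature rarely states which is used). Outlier trimming fits OLS
ŷ ~ y and drops the ⌈f·n⌉ largest absolute residuals (default f = 0.10;
note ⌈·⌉ can remove slightly more than f·n). Stratified reports split
by secondary-structure state and by the 25 % burial threshold, skipping
strata below n = 3. `common_mutations()` intersects prediction tables
on the (structure, chain, position, wt, mut) key, the protocol used when
different predictors fail on different subsets of a benchmark.

## Synthetic data: what it does and does not show

`make_fixture_structure()` builds ideal-geometry structures from
internal coordinates: α-helix (φ = −57°, ψ = −47°), two-stranded
antiparallel hairpin (φ = −139°, ψ = 135°, type-II′ turn), extended
chains, and a "cage" (a residue enclosed by an occluding shell) for
burial tests. Backbones carry N, CA, C, O and an ideal CB; sequences
are poly-Ala or seeded random draws (proline excluded so torsions stay
ideal). Coordinates are rounded to PDB precision so objects round-trip
exactly through `write_pdb()`/`parse_pdb()`.

The parameter-recovery experiment plants a sparse linear signal on the
encoded descriptor: coefficients are drawn once (seeded), scaled so the
signal spread is 1.5 kcal/mol — a realistic spread for single-mutation
stability data — and Gaussian noise of 0.3 kcal/mol is added. With
these conditions the noise ceiling on held-out Pearson r is ≈ 0.98, and
the default training protocol reaches r ≈ 0.93–0.97 on 200 held-out
mutations (seeds vary). This demonstrates that the encoder exposes the
information and the optimizer recovers it; it does **not** demonstrate
accuracy on real proteins, where the mapping from descriptor to ΔΔG is
neither linear nor noise-free, side chains beyond CB exist, and real
contact statistics differ from the synthetic reference ensemble.
Benchmarks on experimental mutation sets require curated
thermodynamic data and real structures, which are inputs, not package
contents.

## Comparative (mesophile/thermophile) scan

`needleman_wunsch()` produces a global alignment with affine gaps (a
gap of length L costs open + extend·L; defaults BLOSUM62, 10, 0.5, the
defaults of the classic alignment suite). Identity is counted over the
full alignment length including gap columns. `bidirectional_scan()`
then predicts, for every aligned gap-free substituted column, the ΔΔG
of mutating structure A's residue into B's on structure A under A's
pH/temperature, and the reverse on B — gapped columns are excluded
because insertions/deletions have no single-site interpretation. Each
site is classed as a predicted stability increase (ΔΔG ≤ 0) or decrease,
and tallied by the burial class *of the structure being mutated* (the
natural choice; the alternative — using the partner's exposure — is a
one-line change). `hypothesis_report()` aggregates per-pair counts,
energy sums and the percentage of thermophile→mesophile substitutions
predicted destabilizing, overall and by burial class; empty directions
report NA rather than 0.

## Numerical and interface choices

* Alternate locations resolve per atom to the highest occupancy, ties
  to file order; the first MODEL is used unless another is requested.
* Residue identity follows author numbering (resSeq + insertion code);
  sequence separation for network edges is measured on author numbering
  so numbering gaps (chain breaks) suppress spurious "adjacent" edges.
* The network betweenness/closeness conventions for disconnected graphs
  are stated above and tested against brute-force oracles.
* Ties in Spearman use average ranks; tied pairs are excluded from
  Kendall CP/DP.
* Model serialization is plain JSON carrying a manifest hash; loading
  refuses a model whose hash disagrees with the requested feature
  layout.
* Problem sizes in tests and in `scripts/acceptance.R` (30-residue
  fixtures, 1000 synthetic mutations, 100 random graphs, 1000 random
  vectors) were chosen as the smallest sizes at which the checked
  properties are stable; all run in about a minute.

## Known limitations

* Single chains only; no mmCIF; 3-state secondary structure only.
* Typed-edge geometry is distance-only; no angular filters for π
  systems, no energy-weighted edges.
* The built-in potential terms are intentionally minimal stand-ins;
  real statistical-potential outputs should be supplied by file.
* MSA quality is the user's responsibility; no row weighting for
  redundant alignments.
* The regressor is deliberately small; no hyperparameter search or
  deep variants.
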