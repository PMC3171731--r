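---
title: "Predicting protein binding sites from Voronoi residue environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein binding sites from Voronoi residue environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vorsite)
```

## The problem and the model

Residues that form protein-protein interfaces differ from other exposed
residues: interfaces are enriched in hydrophobic and aromatic side chains,
tend to be evolutionarily conserved, and show lower crystallographic
B-factors than the rest of the surface. None of these signals is strong on
its own, and all of them are properties of surface *patches* rather than of
single residues. `vorsite` therefore scores every exposed residue with a
two-step random-forest classifier whose inputs combine per-residue features
with descriptors of the residue's structural neighbourhood.

The neighbourhood is the distinctive ingredient. Instead of a Euclidean
distance cutoff or a sequence window, the default environment is read off a
three-dimensional Voronoi tessellation of all heavy-atom centres: residues
$a_i$ and $a_j$ are in contact when at least one pair of heavy atoms, one
from each residue, share a Voronoi facet. With $N_{ij}$ the number of such
facet-sharing atom pairs and $N_i = \sum_j N_{ij}$, the contact strength

$$c_{ij} = N_{ij} / N_i$$

weights neighbour $j$'s influence on residue $i$. Note that $N_{ij}$ is
symmetric but $c_{ij}$ is not, and that $\sum_j c_{ij} = 1$ for every
residue with at least one neighbour, so every environment descriptor below
is a convex combination. Contact is defined by *visibility* (shared
facets), not by a distance threshold, so no cutoff parameter exists in this
mode — a practical advantage over sphere and window definitions, which the
package also implements for comparison (`env_config()` modes `"sphere"`,
`"window"`, `"none"`).

Three descriptor families are computed on the contact graph:

* **EF** — for each feature $k$, $ef_{ik} = \sum_j c_{ij} f_{jk}$, the
  strength-weighted average of the neighbours' features;
* **CDV** — a 20-vector, component $l$ being $\sum_{a_j \equiv type_l}
  c_{ij}$: the composition of the environment by residue type;
* **EDM** — a symmetric $20 \times 20$ matrix of contacts *among* the
  neighbours themselves (central residue excluded), normalised by the total
  internal contact count $M_i$; the classifier sees its upper triangle
  (210 columns), since the full 400 would duplicate every symmetric entry.

The first random forest scores each exposed residue from its own features
plus EF, CDV and EDM. Because true interfaces are contiguous patches, a
residue's score carries information about its neighbours' labels; the
second forest exploits this by adding four score-feedback features computed
from the first-step scores $s_j$ through the same graph: the environmental
score $es_i = \sum_j c_{ij} s_j$, its by-type decomposition CSV (which sums
exactly to $es_i$), and the max/min summaries
$(\max_j c_{ij} s_j,\ \min_j c_{ij} s_j,\ \max_j s_j,\ \min_j s_j)$. The
published description of the max/min tuple is typographically corrupted;
this four-component reading is the package's interpretation and is isolated
in `max_min_scores()` so an alternative can be swapped in without touching
anything else.

## Feature groups and their defaults

The classifier consumes four feature groups, selected by the letters
`s`, `e`, `c`, `b`. The original feature inventory is not public, so each
group is a self-contained default provider behind a stable registry (the
design-matrix column names); alternatives can replace a provider without
affecting the environment formulas.

* **s (structure)**: relative solvent accessibility (Shrake–Rupley areas
  over heavy atoms divided by Tien et al. (2013) theoretical Gly-X-Gly
  maxima, clipped to $[0,1]$); a 3-state secondary structure one-hot from an
  internal Kabsch–Sander-style hydrogen-bond assignment (reconstructed
  amide hydrogens, electrostatic bond energy with a $-0.5$ kcal/mol
  threshold, $i{+}4 \to i$ bonds mark helix, mutual long-range bonds mark
  strand); and the residue-type one-hot (20 columns).
* **e (energy)**: a desolvation proxy (Kyte–Doolittle hydropathy times
  rSASA) and a residue-contact pseudo-energy summing a $20 \times 20$ pair
  potential over residues whose heavy-atom centroids lie within 8 Å. The
  embedded potential is a transparent rank-one "hydrophobic force"
  construction from the Kyte–Doolittle scale ($e_{lk} \propto -h_l h_k$),
  chosen over transcribing a published knowledge-based table; any symmetric
  matrix with amino-acid dimnames can be dropped in.
* **c (conservation)**: per-column Shannon entropy and relative entropy
  against Swiss-Prot background frequencies, from an aligned-FASTA MSA
  whose first row must match the chain sequence (ungapped). With no MSA the
  group is absent — never zero-imputed — mirroring feature-subset
  experiments in which conservation is simply left out.
* **b (B-factors)**: mean heavy-atom B-factor, z-scored within each chain
  (zero when the chain has no B-factor variance).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| exposure threshold | rSASA ≥ 0.05 | defines the prediction universe |
| interface cutoff | 5 Å heavy-atom | labels training residues from the bound complex |
| sphere radius | 15 Å | sphere-mode environment |
| window length | 9 | window-mode environment (4 residues either side) |
| trees / mtry | 500 / $\sqrt{p}$ | forest size; class-balanced sampling on |
| threshold | 0.5 | score cutoff for count-based metrics |

The exposure threshold and the 5 Å heavy-atom interface definition are
standard conventions adopted because the original choices are not public;
both are configurable. Class-balanced per-tree sampling addresses the
strong label imbalance (most exposed residues are not interface). All
random-forest fits take a mandatory seed, and predictions are bit-identical
across runs and across save/load round-trips.

Two training subtleties are deliberate:

* **Folds split by structure, never by residue.** Residues of one protein
  are heavily dependent; residue-level folds would leak.
* **Out-of-fold feedback.** The second forest must not learn from
  resubstitution-inflated first-step scores, so the feedback features for
  training are built from inner structure-wise out-of-fold predictions
  (5 inner folds by default). How the original implementation handled this
  is not described; this choice is conservative.

## Numerical choices

The tessellation is an incremental Bowyer–Watson Delaunay construction
(compiled code) whose edge set — pairs of sites with facet-sharing Voronoi
cells — is all the package needs. Two guards make it robust and bounded:

* **Degenerate inputs** (lattices, cospherical points) are joggled by a
  deterministic quasi-random perturbation of $10^{-4}$ Å, in the spirit of
  Qhull's joggle option; the perturbation is chemically negligible and
  reproducible.
* **Unbounded surface cells** are closed by a pseudo-solvent shell of 256
  sites on a sphere 10 Å beyond the structure's extent. Facets against
  shell sites are discarded, so the shell never creates residue contacts —
  but it does *suppress* spurious long contacts that would otherwise span
  surface clefts and the convex hull. Consequently the residue graph is
  the Delaunay adjacency of atoms-plus-shell restricted to atoms, a strict
  subset (typically by a few percent) of the bare-cloud Delaunay adjacency;
  the tests verify the bare tessellation exactly against a brute-force
  empty-circumsphere oracle and sandwich the shelled graph between the two
  references.

Residue-level degenerate cases all have explicit conventions: a residue
with no neighbours gets its own features as EF (the convex-combination
limit), zero CDV/EDM, its own score as $es$ and Mms, and a binary
`isolated` indicator column so the forest can tell fallbacks from real
environments. MCC is 0 when a confusion-matrix marginal vanishes;
precision is reported as 0 (flagged) when nothing is predicted positive.
AUC uses midrank ties and equals the trapezoidal area under the step ROC.
Solvent-accessible areas use 960 golden-spiral sample points per atom, at
which per-residue areas change by under 2% when the density is doubled.
Reported metrics are displayed truncated (not rounded) to two decimals,
matching how the reference operating points reproduce their printed F1
values; full precision is always stored.

For comparing two AUCs over the same residues the package uses a paired
bootstrap (2000 replicates, seed-deterministic): residues are resampled
with replacement, both AUCs recomputed per replicate, and the two-sided
p-value and percentile interval read from the $\Delta$AUC distribution.
This replaces an external ROC-comparison program with an assumption-light,
self-contained test; a DeLong-variance variant could be added later.

## What the synthetic generator emulates — and what it does not

`generate_complex()` builds two ideal α-helices (φ = −57°, ψ = −47°,
standard backbone geometry via internal-coordinate chain construction, one
Cβ-like pseudo-atom per side chain) and docks them at the separation that
brings the requested fraction of residues (default 0.2) within 5 Å of the
partner. Interface labels are therefore *geometric* and re-derivable from
the emitted PDB. Signal is planted per group, in directions real
interfaces show: interface residue types are tilted towards hydrophobics
(feeding the s and e groups and the environment composition descriptors),
interface B-factors are lowered (default one population SD per unit effect
size), and interface MSA columns mutate less often across the 50 synthetic
homologs. Effect-size 1 per group was fixed once as "clearly detectable at
desk scale"; zero effect sizes give a null complex whose features carry no
label information.

The generator emulates the *statistical* structure of the problem —
contiguous surface patches, heterogeneous weak signals, strong class
imbalance — not protein physics: helices are ideal, side chains are single
pseudo-atoms, docking is rigid translation, and MSA columns evolve
independently. Passing tests on these fixtures therefore demonstrate that
the pipeline recovers planted multi-group signal, that the environment and
feedback machinery help as designed, and that everything is deterministic;
they say nothing quantitative about accuracy on real complexes, which would
require the external benchmark datasets that are out of scope here.

Desk-scale study conditions used by the tests and the acceptance script:
four complexes of 36–40 residues per chain, forests of 120–150 trees,
3 outer / 2 inner structure-wise folds. These sizes were chosen as the
smallest at which the planted/null contrast is unambiguous.

## Known limitations

* Single-model PDB input only; no mmCIF, no assembly reconstruction, no
  hydrogen placement.
* The secondary-structure assignment is a simplified two-state-pattern
  reading of hydrogen bonds, adequate as a feature, not as a DSSP
  replacement; an external DSSP could back the same provider.
* The contact pseudo-energy is a rank-one surrogate, not a fitted
  statistical potential.
* Window-mode feedback restricts neighbourhoods to scored (exposed)
  residues, since buried window members have no first-step score;
  strengths are renormalised over the scored set.
* Probability calibration is out of scope; scores order residues well but
  are not calibrated probabilities.
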