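---
title: "Quantifying RNA pocket flexibility on NMR ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA pocket flexibility on NMR ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpflex)
```

## The problem and the model

A multi-model NMR deposition is the closest thing crystallography-era
structural biology has to an experimental sample of an RNA's conformational
ensemble. `rpflex` treats the set of models as exactly that: it detects the
binding pockets of every model on one shared lattice, asks how much the
*same* pocket moves and deforms across models, and condenses the answer into
a per-pocket-group flexibility score Q, cross-checked by ensemble RMSF,
contact-network variability and interaction profiles.

The pipeline assumes:

* the deposited models are pre-superimposed (true of essentially all NMR
  depositions), so coordinates are compared as deposited and no additional
  least-squares fitting is applied;
* one RNA chain per entry, optionally with one protein chain or bound
  ligands;
* an entry with a single model carries no flexibility information and is
  flagged on reading.

## Pocket detection

The two-probe discrete-volume method rasterizes atom occupancy (per-element
van der Waals radii: C 1.70, N 1.55, O 1.52, P 1.80, S 1.80, otherwise
1.60 Å) on a cubic lattice and computes, for a probe radius r, the
solvent-excluded region as the morphological closing of the occupancy by a
ball of radius r minus the occupancy. Pockets are the 6-connected components
of the difference between the large-probe (10 Å) and small-probe (3 Å)
regions. The closing is evaluated with two exact Euclidean distance
transforms per probe, with no connectivity restriction on the probe
positions: a cavity that is sealed against the small probe but large enough
to hold it is therefore reported as a pocket, which is the behaviour the
synthetic sealed-cavity fixtures assert, while the unbounded far field
cancels in the large/small difference.

Numerical points worth knowing:

* **Grid spacing** defaults to 1.0 Å, the same voxel size used for overlap
  counting; one shared lattice (anchored at the floor of the ensemble
  bounding box) makes pocket cells from different models directly
  comparable integer triples.
* **Surface area** is counted from exposed 6-neighbour faces. Face counting
  overestimates the area of smooth shapes by a staircase factor (≈ 1.5× for
  spheres); it is deterministic and exactly checkable against closed forms
  (a digitized cube gives the analytic sphericity (π/6)^(1/3) to machine
  precision). An optional 2/3 correction factor exists and is off by
  default, so sphericities of smooth pockets sit below their continuum
  values — consistently so, which is what a *comparative* score needs.
* **min_volume = 100 Å³** discards grid-noise components; set it to 0 to
  keep everything.
* **Ligand atoms are excluded from occupancy** by default so that
  ligand-filled sites are detected as pockets rather than walled off.
* Pockets within a model are indexed by decreasing volume, ties broken on
  the lexicographically smallest cell, so labels are deterministic.
* Because the discretized balls of two different radii are not exactly
  nested sets of cells, total pocket volume under a shrinking large probe
  is monotone only up to single-voxel boundary jitter; the tests allow for
  that jitter explicitly.

## Similarity, grouping and the score

`P_ij = n_ij / N_i` is deliberately asymmetric: it is the fraction of
*reference* pocket i's voxels recovered in pocket j. Grouping uses the
pockets of the first structural model as references with a strict
`P_ij > 0.25` cutoff; a pocket similar to several references joins the best
match, ties to the lowest reference index. Pockets matching no reference
become leftover singleton groups, kept in the report but never scored
(a group needs m ≥ 3 members).

For a valid group the spatial terms are the population (÷ m) standard
deviation of each row of the m × m sub-matrix (`sigma_i`), their mean S and
the grand mean P̄. The topology term

Γ = (1/m) Σ_i | ψ_i − π^(1/3) (6 |V_i − V̄|)^(2/3) / (A_i − Ā) |

subtracts from each pocket's sphericity the "sphericity of its difference
pocket". Three conventions make Γ total: the volume deviation enters as a
magnitude before the 2/3 power (fractional powers of negative numbers are
avoided), the area deviation keeps its sign, and terms with
|A_i − Ā| < 10⁻⁹ Å² contribute |ψ_i|. A variant that drops the sphericity
constant (`gamma_form = "literal"`) is retained for comparison.

**Why Q = (S/P̄) · Γ.** The score's definition can be typeset two ways — a
quotient of S/P̄ by Γ, or their product. The expanded form of the
definition, in which each summand is S/P̄ multiplied by one pocket's
|ψ_i − …| term, and the stated reading of Γ as *the* measure of topological
change (more change ⇒ more flexible) both point to the product, so the
product is the default; `q_form = "quotient"` selects the other reading.
Identical pockets give S = 0 and hence Q = 0 in both forms. Classes follow
the fixed boundaries: rigidity Q < 0.30, intermediate 0.30 ≤ Q < 0.60,
flexibility Q ≥ 0.60; the boundary values belong to the upper class.
`Vg = V̄ × P̄` stratifies groups into small (0, 500], medium (500, 1500] and
large (1500, 7200] Å³ bins with inclusive upper bounds; a value beyond 7200
warns and stays "large".

## RMSF, networks, interactions

*RMSF.* Each overlapping nucleotide (lining more than half of the group's
pockets; "lining" = any heavy atom within 4.0 Å of a pocket cell center,
about the small-probe radius plus a heavy-atom van der Waals radius) is
reduced to one representative point per model — the heavy-atom center of
mass by default, the C1' atom optionally, because the fluctuation formula is
written per nucleotide rather than per atom. The reference positions come
from the model of the group's first pocket; per-nucleotide RMSF is the root
mean square displacement over the group's m member models and the group
value averages over the nucleotides. Whole-structure RMSF uses all
nucleotides and all models against a stated reference model.

*Networks.* Nodes default to the nucleotides lining the group's *reference*
pocket so all m networks share one node set and metric differences reflect
interaction changes, not node-set churn (`node_set = "per_model"` is the
alternative). An edge joins residues at sequence separation ≥ 2 — covalent
neighbours are excluded, which is also why shortest paths skip along
every-other-residue chains — whose closest heavy atoms approach within 8 Å
(strict). Average degree uses the handshake identity 2L/N; local clustering
contributes 0 for nodes of degree < 2; diameter and mean path length are
computed on the largest connected component (infinite distances would
otherwise poison the cross-model SDs), with a message when a network is
disconnected. Cross-model population SDs of the four metrics, times Q, give
the combined scores.

*Interactions.* Only the distance criteria are enforced (H–A < 2.7 Å with
an explicit donor-bound hydrogen, D–A < 3.35 Å always, vdW < 3.9 Å for
non-H-bonded heavy-atom pairs, all strict), with no angular terms — a
documented divergence from full HBPLUS behaviour. The donor/acceptor
dictionary ships as an editable CSV (`inst/extdata/`); ligand N/O/S atoms
are generically allowed to donate and accept. Covalent inter-residue
linkages (O3'–P, peptide C–N, and any pair under 1.8 Å) are excluded, and an
atom pair is never both hydrogen bond and vdW contact. RNA–RNA contacts map
onto the five group-pair categories (BB, RB, PB, PR, RR);
phosphate–phosphate pairs, which fall outside the five, are labelled
separately and excluded from the five-category percentages. Contacts are
counted per structural model and both the pooled summary and the per-model
summaries are reported, since aggregation order is a genuine choice.

## The synthetic generator and what the tests show

`make_cavity_shell()` builds a sealed spherical cavity of known analytic
volume inside a densely packed pseudo-atom shell whose atoms are grouped
into pseudo-nucleotide residues by angular sector, and
`make_perturbed_ensemble()` displaces each residue rigidly by a zero-mean
Gaussian 3-vector of scale s per model. The standard-normal draws depend
only on the seed and the problem size, so two ensembles built at different
s from one seed share displacement directions exactly — monotonicity tests
compare like with like. Per-residue rigid displacement (rather than
per-atom noise) gives nucleotide-level RMSF a closed-form expectation
(mean squared RMSF ≈ 3s²(n−1)/n over n models) that the tests verify.

The study conditions used by the test-suite and the acceptance script are
fixed choices: a rigid condition of s = 0.3 Å (per-nucleotide RMSF around
0.5 Å, matching the rigid end of deposited NMR ensembles) and a flexible
condition of s = 1.2 Å (RMSF around 2 Å, the regime where a substantial
fraction of nucleotides exceed 2 Å), both with 10 models and a 7 Å cavity —
s = 1.2 Å is about the strongest perturbation at which the pocket group
itself reliably survives, which is the defining property of a *flexible
pocket group* as opposed to no group at all. Smaller 4–5 Å cavities with
3–6 models keep the unit tests fast.

What passing tests do and do not show: the generator produces isotropic,
residue-rigid, harmonic-like displacements around one template. Real NMR
ensembles have anisotropic, sequence-correlated motions, partial unfolding,
and restraint artefacts; chemically, the shell's pseudo-nucleotides carry
no donors/acceptors, so the hydrogen-bond machinery is exercised on
idealized base-pair geometry instead. The tests therefore validate the
*computational* contract of every stage — geometry, counting rules,
invariances, closed forms and monotone responses — not the biological
calibration of the class boundaries, which comes from the corpus the method
was built on.

## Degenerate inputs and edge cases

* Structures with fewer than 4 heavy atoms or thinner than one grid cell
  warn and return no pockets.
* A first model without pockets leaves every pocket a leftover group, with
  a warning.
* Groups whose overlapping-nucleotide set is empty warn and are unusable
  for RMSF; missing representative atoms skip the residue with a warning.
* Entries with one model are flagged on reading.
* The pipeline records per-group stage errors in the report instead of
  aborting the entry.

## Known limitations

* The pocket detector is a discrete re-formulation of rolling-probe cavity
  detection; absolute volumes carry O(spacing) digitization error (the
  sealed-cavity fixture recovers its analytic volume to ~13% at 1 Å and
  ~1% at 0.5 Å), and face-counted areas are staircase-biased, so ψ and
  r_eff are comparative rather than absolute quantities.
* Grouping keys on first-model references only; a pocket present in models
  2..n but absent from model 1 can only form leftover groups.
* No angular hydrogen-bond criteria, no water-mediated bonds, no
  π-stacking.
* Path metrics on disconnected networks describe the largest component
  only.
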