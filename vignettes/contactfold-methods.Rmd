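---
title: "Contact-guided coarse-grained folding and confidence estimation with contactfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-guided coarse-grained folding and confidence estimation with contactfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactfold)
```

## The problem

Template-free protein structure prediction became practical once predicted
residue-residue contact maps grew accurate enough to restrain a folding
simulation. The accuracy of those contact maps in turn depends on the
coevolution signal in the family's multiple sequence alignment (MSA), which
metagenomic sequence collections can deepen dramatically. `contactfold`
implements the quantitative machinery of such a pipeline in a form that is
fully exercisable on synthetic data:

1. **Alignment statistics** — the effective sequence count Nf, the
   metagenome contribution fraction Nff, and family triage;
2. **Consensus contact selection** from several ranked predictors grouped
   in accuracy tiers;
3. **A contact-restraint potential** with a smooth, length-adaptive well;
4. **Replica-exchange Monte Carlo fragment assembly** of a coarse-grained
   chain (Cα trace plus virtual Cβ);
5. **Decoy clustering** and first-model selection;
6. **Confidence estimation** — a C-score combining alignment depth,
   contact satisfaction and simulation convergence, linearly calibrated to
   an expected TM-score.

## Models and statistics

### Effective sequence count

For an MSA with $n_{seq}$ rows and query length $L$,

$$\mathrm{Nf} = \frac{1}{\sqrt{L}} \sum_{i=1}^{n_{seq}}
  \frac{1}{1 + \sum_{j \ne i} I(S_{ij} \ge 0.8)},$$

where $S_{ij}$ is the pairwise sequence identity and $I$ the Iverson
bracket. Each cluster of mutually similar rows contributes roughly one
effective sequence; the $\sqrt{L}$ normalization makes depths comparable
across family lengths. The identity denominator is the number of columns
where both rows are non-gap (the local-alignment convention used by common
MSA filtering tools); the formula's source does not fix the convention, so
this is a documented package choice, as is computing Nf after the
gap-row (≥ 75% gaps) and redundancy (identity ≥ 0.90, coverage < 0.75)
filters, mirroring the order of the MSA construction workflow this models.

Families with Nf above 64 are considered deep enough for contact-guided
folding; among those, families whose augmenting (metagenomic) set
contributes more than half of Nf, i.e.
$\mathrm{Nff} = (\mathrm{Nf}_{combined} - \mathrm{Nf}_{base}) /
\mathrm{Nf}_{combined} > 0.5$, are labelled metagenome-driven.

### Consensus contacts

Predictors are grouped in four accuracy tiers; the top $L$, $L/2$,
$L/4.5$ and $L/7.5$ pairs (rounded half-up, floored at one) of the
very-high, high, medium and low tiers are unioned. A pair reported by
several predictors gets the *mean* of their confidences as its restraint
weight $U_{ij}$; the mean (rather than sum) keeps $U_{ij}$ on the
confidence scale regardless of how many predictors run. The source
describes both branches of its alignment-depth switch (Nf below/above 50)
with the same fraction list — almost certainly a typo whose intended
asymmetry is unknown — so both branches default to that list and are
configurable separately rather than guessed.

### Contact-restraint potential

Each consensus contact contributes a piecewise well on the Cβ–Cβ distance
$d$: $-U$ for $d \le 8$ Å, a half-sine rise to zero at $d_2$, a half-sine
rise to $+U$ at 80 Å and flat beyond. $d_2$ controls the gradient of the
well and is length-dependent within 14–24 Å; the mapping itself is not
published, so the package uses the simplest monotone rule spanning the
printed range, $d_2 = 14 + 10\,\mathrm{clamp}((L-50)/300, 0, 1)$,
configurable. Branch boundaries are assigned to the closed side as
printed; continuity makes the choice value-neutral (verified to 1e-9 in
the tests).

### The folding engine and its stand-in force field

The full knowledge-based force field of the modelling program this
emulates is inherited opaque machinery, not a published algorithm, so it
is replaced by a *documented minimal stand-in*:

* harmonic pseudo-bond term about 3.8 Å;
* soft-sphere excluded volume below 4.5 Å (the hard geometric invariant —
  no non-bonded Cα pair under 3.4 Å — is enforced at move time);
* an optional fragment-derived distance-profile term: for residue pairs
  covered by a library fragment, $-w\,\ln(p(d) + \varepsilon)$ with $p$
  the normalized histogram of Cβ distances across the covering fragments
  (bin 0.5 Å, $\varepsilon = 10^{-3}$), summed over profiled pairs.

The profile term matters: with noisy contact lists the restraint term
alone is minimized by an indiscriminately collapsed globule that satisfies
false contacts as happily as true ones. The profile term anchors
local-range geometry to fragment statistics and restores the native as the
energy optimum; its per-pair weight (default 0.05) was set so that profile
differences between native-like and collapsed states dominate the few
energy units separating their restraint terms.

Sampling is replica-exchange Metropolis Monte Carlo: 8 replicas on a
geometric temperature ladder (0.15–15 in energy units), fragment
substitution in internal coordinates (pseudo-bond lengths, angles,
torsions; downstream atoms rebuilt by the standard NeRF construction),
pivot and crankshaft rotations, with move amplitudes scaled by
$\sqrt{T/T_{max}}$ so cold, compact replicas take small steps. Adjacent
replicas attempt swaps every 50 steps with the standard exchange
criterion, alternating even/odd pairing. Decoys are harvested from the two
coldest slots after a 40% burn-in, and each cold replica ends with a
greedy quench (1500 downhill moves, default) whose snapshots populate the
decoy ensemble with basin-floor structures — the cheap stand-in for the
long trajectories a production pipeline would run. Temperature range,
replica count, move mix and weights are engine choices the source does not
specify; all live in `simulation_config()` and were fixed on desk-scale
helix-bundle experiments before the acceptance harness was frozen.

A known degeneracy: contact maps and distance profiles are invariant under
mirror reflection, so a simulation can converge to the mirror topology
with high contact satisfaction and mediocre TM-score. Production systems
break chirality with backbone physics the stand-in omits; the acceptance
property therefore checks contact satisfaction plus superiority over a
random-coil TM baseline, not absolute TM.

### Clustering and confidence

Decoys are clustered by iterative neighbor counting on pairwise
optimal-superposition RMSD: the decoy with most neighbors within the
cutoff seeds cluster one (ties to the lower index), members are removed,
and the process repeats up to five clusters. With `cutoff = "auto"` the
cutoff is the smallest value on a 0.5 Å grid in [3.5, 12] whose top
cluster holds 10–70% of decoys. The published clustering program's
internals are not part of this source, so this faithful simplified variant
is used. Refinement of the centroid is an identity step here, so the
first model *is* the largest cluster's centroid.

Confidence combines three signals:

$$\mathrm{C\text{-}score} = 0.2\,\ln(\mathrm{Nf}) +
  \ln(S_r \times D_c), \qquad
  \widehat{\mathrm{TM}} = 0.0659\,\mathrm{C\text{-}score} + 0.477,$$

with $S_r = \frac{1}{n_L}\sum \delta_i w_i^2$ the weighted satisfaction of
the top-$L$ long-range (separation > 24) contacts in the first model
($\delta_i$: Cβ distance ≤ 8 Å; $w_i = U_{ij}$, already in (0,1]), and
$D_c = (M/M_{tot})/\langle R \rangle$ the convergence density of the top
cluster. $\langle R \rangle$ is floored at 0.5 Å so degenerate
single-point clusters cannot blow up $D_c$; zero $S_r$ or $D_c$ is floored
at $10^{-6}$ with a warning so failed runs stay finite. The TM estimate is
clamped to [0, 1] (the linear form is unbounded) and reported with the
calibration's residual RMSD, 0.084.

## The synthetic world

`toygen` generates everything the pipeline consumes, deterministically per
seed:

* **Toy folds** (20–120 residues): ideal-geometry helix bundles (2.3 Å
  helix radius, 1.5 Å rise, 100°/residue), pleated two-strand hairpins
  (5 Å sheet separation) and a mixed strand/helix topology, joined by
  equal-chord circular-arc loops chosen to respect the bond-length
  ([3.6, 4.0] Å) and clash (≥ 3.4 Å) invariants, plus 0.03 Å seeded
  jitter.
* **True contact maps**: all Cβ pairs within 8 Å at separation ≥ 6 (the
  floor keeps trivial local pairs from dominating).
* **Corrupted predictor lists**: tier-length ranked lists whose true-pair
  fraction equals the requested precision to rounding, false pairs drawn
  uniformly from non-contacts, true pairs biased toward the top,
  confidences decreasing with rank. Default tier precisions (0.8 / 0.65 /
  0.5 / 0.35) are plausible stand-ins for the four accuracy categories,
  which the source names but does not quantify.
* **Alignments with controlled Nf**: descendants of a random ancestor with
  a 30% row-duplication rate; the point-mutation rate is tuned by
  bisection against frozen per-seed randomness until Nf lands within 10%
  of target.
* **Fragment libraries**: native-derived segments (default lengths 3–12 of
  the allowed 1–20 — shorter pieces carry no internal geometry, longer
  ones add little on toy chains) with seeded jitter, pseudo-bond lengths
  re-clamped after jittering.

What a green test does **not** establish: the generator emulates none of
the hard parts of real data — alignment errors, domain boundaries,
non-uniform predictor error structure (real false positives cluster near
true contacts; ours are uniform, which is *harder* for the energy
function), or real backbone physics. Synthetic results validate the
machinery, not biological accuracy.

### The desk-scale calibration benchmark

The acceptance property for the confidence score folds 30 toy targets
whose alignment depth spans the Nf range of the families the source
models (about 15–736) and whose contact precision increases with ln(Nf)
plus noise — the depth-drives-accuracy premise of the whole approach. The
Pearson correlation between C-score and true TM-score on this benchmark is
required to exceed 0.5, a desk-scale analogue (not a reproduction) of the
published benchmark correlation.

## Numerical choices and degenerate inputs

* Pairwise identity over zero co-aligned columns is 0; an MSA consisting
  of copies of one sequence has Nf exactly $1/\sqrt{L}$.
* `read_rr` tie-breaks equal confidences by ascending (i, j); duplicate
  pairs within one predictor keep the highest-confidence record.
* Proposals that violate chain geometry are resampled up to 20 times, then
  the identity move is returned; a zero-step run returns the initial
  conformations.
* The running MC energy is accumulated from per-move differences and
  cross-checked against full recomputation every 1000 accepted moves
  (tested drift < 1e-6).
* Virtual Cβ placement uses a fixed 1.53 Å offset built from the two
  flanking pseudo-bonds; termini copy their neighbor's offset and
  collinear triples fall back to a deterministic perpendicular.
* TM-score uses $d_0 = \max(0.5,\ 1.24\,(L-15)^{1/3} - 1.8)$ and seeds
  its superposition search from sliding windows of several lengths,
  iterating membership until fixed point; the tests compare it against a
  dense-seed oracle within 0.02.

## Known limitations

* The folding engine is a desk-scale sampler; 40–60 residue toys fold in
  one to three minutes, real-protein scales would not be reachable.
* Mirror-image topologies are not penalized (see above).
* The consensus scheme's intended Nf-branch asymmetry is unknown and left
  configurable rather than guessed.
* Stockholm parsing accepts the single-block dialect Biostrings reads;
  A3M support drops insertion states, which is the standard match-state
  reduction.
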