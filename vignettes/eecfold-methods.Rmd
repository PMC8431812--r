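---
title: "eecfold: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eecfold: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eecfold)
```

## The compensation picture

The package implements an entropy–enthalpy-compensation account of
protein folding. Its core quantitative claim is local: forming one
backbone N–H···O=C hydrogen bond in water is enthalpically uphill,
because the chain must first break one N–H···water and one C=O···water
bond, while the two released waters recover only one water–water bond:

$$\Delta H = E_{NH\cdot w} + E_{CO\cdot w} - E_{NH\cdot OC} - E_{w\cdot w}$$

At the package defaults this is $7.65 + 4.7 - 3.47 - 6.18 = 2.70$
kcal/mol. The compensating term is entropic: hydration-shell water
around nonpolar surface is ordered, with a molar entropy close to that
of ice (≈45 J mol⁻¹K⁻¹) rather than bulk liquid (≈70 J mol⁻¹K⁻¹), so
expelling $n$ shell waters releases $\Delta S = n \cdot 25$ J mol⁻¹K⁻¹.
For the ~12 waters of a lateral leucine–leucine side-chain collapse,
$-T\Delta S \approx -21.4$ kcal/mol at 298 K — an order of magnitude
more than the 2.70 kcal/mol bond cost. Folding proceeds where sequence
geometry lets a hydrophobic collapse and a backbone hydrogen bond occur
together.

```{r}
compensation(hbond_swap_enthalpy(), collapse_entropy_gain(12))
```

### Parameter provenance

Three of the four bond-energy magnitudes (3.47, 7.65, 4.7 kcal/mol) and
both molar entropies (70, 45 J mol⁻¹K⁻¹) are literature values. The
water–water term, 6.18 kcal/mol, is **calibrated**: it is chosen so the
default swap enthalpy is exactly 2.70 kcal/mol, the value the bond
bookkeeping is quoted to produce. It is exposed in `thermo_params()`
and documented as calibrated rather than sourced. Note an arithmetic
tension we deliberately do not paper over: the often-quoted total of
about −23 kcal/mol for the 12-water collapse does not follow from
12 × 25 J mol⁻¹K⁻¹ × 298 K ≈ 21.4 kcal/mol; the package therefore
treats the claim as an inequality ($|-T\Delta S| \in [20, 24]$
kcal/mol, exceeding 2.70) and never asserts the point value.

## Residue classes and the attraction table

Side-chains are classified by their *hydrophobic portion*: the eight
fully hydrophobic residues (C, I, L, M, W, F, Y, V); the long
amphipathic residues (R, H, K, E, Q) whose nonpolar stalk packs
laterally even though the terminus is polar; the limited-polar pair
(D, N); alanine, whose methyl is short enough to reach a long
side-chain's stalk without clashing with its polar head; glycine
(negligible side-chain); proline (no backbone N–H); and the short-polar
pair (S, T), of which only threonine carries an extra methyl.

No pairwise interaction matrix is tabulated anywhere authoritative, so
the 20×20 verdict table is *derived* from per-class participation
statements: any pair touching G, D/N, or P is non-attracting; serine
never attracts (it is in the blocking group); threonine attracts only
fully hydrophobic partners or alanine; alanine attracts fully
hydrophobic, long amphipathic, alanine and threonine; all remaining
pairs (full×full, full×long, long×long) attract. Two judgment calls are
flagged rather than inferred: threonine is a weak attractor despite
sharing a figure panel with serine (it is absent from the blocking
list), and alanine does *not* attract D/N. The table is snapshot-tested
so any rule change is deliberate, and a user can supply a replacement
matrix file.

D, N, S, P and G form the **RB (hydrophobic-blocking) group**: runs of
two or more of them block lateral attraction on both sides and nucleate
turns. A single RB residue does not force a turn — observed turn
composition is a statement about turns containing RB residues, not a
sufficiency rule.

## The secondary-structure decision rules

An *interval* is the number of residues strictly between two positions.
Interval 1 (separation 2) is the same-face contact of an extended
strand; intervals 2 and 3 (separations 3–4) are the i±3/i±4 contacts of
a helix turn. `build_attraction_graph()` keeps a candidate edge when
the verdict table attracts and the span crosses neither a proline nor
an RB run of length ≥ 2.

Prediction proceeds by marking RB runs as turns, splitting the rest at
turns and prolines, and scoring each stretch by attraction-edge
densities (edges present over edges geometrically possible):

* **helix** when the interval-2 *and* interval-3 densities each
  strictly exceed `helix_density_min` and the stretch is at least
  `min_helix_len`;
* else **strand** when the interval-1 density reaches
  `strand_density_min` (default 0.5) at length ≥ `min_strand_len`;
* else coil. Helix is tested first: a fragment satisfying both folds
  helix, since the extra i±3/i±4 collapse is the deeper compensation.

### Why `helix_density_min` defaults to 0.7, strictly

This was the one genuinely open design point. A perfectly alternating
hydrophobic/polar pattern — the canonical strand face, e.g. `VTVTVTVT` —
is *not* helix-poor under the verdict table: its cross-parity
separation-3 pairs (V–T) all attract, so its interval-2 density is 1.
Discrimination rests entirely on the interval-3 (separation-4,
same-parity) density, which for the alternating family is at most 2/3
(hydrophobic termini, odd length) and exactly 1/2 for even lengths.
A period-4 amphipathic helix pattern such as `LAEE` repeats scores 1 at
both intervals. Any strict threshold in (2/3, 1) therefore separates
the two families identically; 0.7 is the smallest round value above the
analytic ceiling. A threshold at 0.5 — the superficially natural
"majority" choice — misreads alternating strands as helices. In
addition, each helix interval must offer at least two geometrically
possible pairs before its density counts as evidence: a stretch of
length 5 has a single separation-4 pair, i.e. one helical turn's worth
of contact, which cannot witness periodicity. Consequently stretches
shorter than 6 are never called H.

The strand criterion pools both faces; the per-face split (even/odd
left endpoints) is reported by `explain_prediction()`.

## What the synthetic generator emulates — and what it does not

`generate_sequence()` plants motifs whose true labels follow the rules
by construction: strands are alternating fully-hydrophobic/threonine;
helices are L-A-E-E repeats; turn linkers are RB runs (GG/PG/NG-like);
coils interleave threonine with D/N/S so they are RB-rich without ever
forming a blocking run. `generate_corpus()` always separates structured
motifs with turn linkers, as turns separate real secondary-structure
elements. Mutated variants keep the clean labels.

A green planted-motif test therefore establishes that the
implementation applies its own rules correctly and robustly — it does
**not** establish predictive accuracy on real proteins, whose strands
and helices are noisier than any rule family here, and whose reference
annotations (DSSP/STRIDE) encode hydrogen-bond geometry the sequence
rules only approximate. The survey statistics (coverage, success rate,
turn composition, involvement) are implemented as procedures and
exercised on synthetic corpora; reproducing published percentages would
require the original structure samples, which are not packaged.

## The Gibbs functional on union-of-balls models

A conformation is a union of van der Waals balls. The functional is

$$G(X) = \omega_e V(\Omega_X) + \omega_e d_w A(\Sigma_X)
  + \sum_{i=1}^{l} \omega_i A(\Sigma_{X,i})
  + k \sum_{a<b} \frac{Z_a Z_b}{|x_a - x_b|}$$

with the boundary partitioned into hydrophobicity-class surfaces by the
nearest-class rule. None of $\omega_e$, $\omega_i$, $k$ is tabulated
anywhere; the defaults ($\omega_e = 0.01$, $\omega = \pm 0.05$,
$k = 0$) are toy values that respect the required ordering
$\omega_1 > \dots > \omega_k > 0 > \dots > \omega_l$, which
`validate_omega_order()` checks rather than assumes.

Numerical choices:

* **Area** by deterministic Fibonacci-lattice sampling (default 960
  points per sphere): a point on a sphere is boundary iff outside every
  other ball. Each boundary point is assigned to exactly one class, so
  the class areas partition the total *exactly*.
* **Volume** by voxel-center counting (default edge 0.2 Å) with an
  irrational grid offset; aligning the grid with an atom center
  produces a lattice-count bias of several percent, the offset brings
  the single-sphere error under 0.5 %.
* **Forces** are central finite differences of each term group
  (default step 0.01 Å). Computing *all three* groups by the same
  differencing makes total = packing + aqueous + expansion an exact
  identity rather than an approximation. The price is quantization: the
  sampled area is piecewise constant in the coordinates, so forces on
  small models are noisy at the sample resolution.
* **Relaxation** is plain gradient descent with a backtracking line
  search; only energy-decreasing steps are accepted, so the recorded G
  sequence is nonincreasing by construction, and quantization noise in
  the force direction cannot cause divergence. Coincident charged
  centers are a reported singularity. The Coulomb sum runs over
  unordered distinct pairs. When the boundary has several connected
  components the whole boundary is used and the component count is
  reported.

A limitation worth stating plainly: the functional's geometry is
*local*. Two balls whose surfaces do not touch exert no
surface-mediated force on each other, so "hydrophobic attraction at a
distance" is outside this model; tests of the shrinking-surface claim
use overlapping configurations.

## 2D patch docking

Subunit surfaces are projected along a user-chosen axis into labeled
grids (empty / hydrophobic / donor / acceptor / hydrophilic, PGM or CSV
on disk). `dock_images()` mirrors the second patch (facing surfaces
meet), then searches rotations × an extra mirror × all integer
translations, scoring hydrophobic pixel overlap (rule 1) and requiring
at least `min_hb` donor–acceptor pairs within a Chebyshev pixel radius
(rule 2, defaults 3 and 1 — "several, close together" made concrete and
config-exposed). Ties are broken lexicographically so the search is
deterministic; rotations that are not multiples of 90° use
nearest-neighbour resampling and are exact only at multiples of 90°.
Rule-2 infeasibility is reported distinctly from a feasible placement
with zero overlap. The planted-pair generator hides a perfectly
complementary patch behind a recorded transform; tests require the
search to match an independent brute-force re-scorer and recover the
planted placement.

## Degenerate inputs and conventions

Unknown residue letters are positioned errors, never coerced — silent
coercion corrupts survey statistics. Undefined ratios are `NA`, never 0
or 1. Intervals are 0-based half-open internally and 1-based inclusive
in every user-facing report. Annotation letters G/I fold into H, B into
E, anything else into C on ingest. The entropy conversion constant is
fixed at 4184 J/kcal.

## Known limitations

* The attraction table is binary; no partial scores, no continuous
  hydrophobicity scale, no rotamer geometry.
* The predictor assigns no β-sheet pairing topology and no confidence.
* The Gibbs functional contains no hydrogen-bond term; the dielectric
  is a constant folded into `coulomb_k`.
* Docking is strictly 2D, with a user-supplied projection axis.
* Published survey percentages are not reproducible without the
  original structure samples; every statistic is computed on whatever
  corpus the user supplies.
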