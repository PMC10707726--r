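---
title: "Methods: quantifying loop flexibility and conformer states in crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying loop flexibility and conformer states in crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscape)
```

`loopscape` quantifies the conformational behaviour of active-site loops
across an ensemble of related crystal structures. Its reference use case
is the four loops (L1–L4) above the substrate-binding pocket of a
family-1 β-glucosidase, where one loop (L3) populates two discrete
conformers — *folded*, toward the pocket, and *straight*, toward solvent —
while the others stay put. This vignette explains the models and
conventions behind each stage, the parameters that matter, what the
synthetic generator does and does not emulate, and the design choices
made where more than one defensible option existed.

## Coordinate model and residue numbering

Everything operates on author residue numbering — the numbers assigned by
depositors — because that is the coordinate system in which loop
definitions are communicated (e.g. "Gln300"). Sequential indexing is never
used for addressing. `tsabgl_loops()` ships the reference spans: L1
39–54, L2 175–183, L3 300–325, L4 398–416.

Two span conventions circulate for L3 in the TsaBgl literature: a header
form ending at Tyr326 and an explicit 26-residue count ending at Ile325.
Similarly the structural L1 span 39–54 holds 16 residues while
sequence-level comparisons count a 14-residue L1. We default to the
explicit counts (L3 = 300–325) and keep the variants expressible
(`tsabgl_loops(l3_variant = "326")`) rather than silently resolving the
discrepancy.

Alternate locations are *kept* at parse time (file fidelity) and
*collapsed* at selection time (deterministic geometry): the
highest-occupancy altloc wins, ties broken by altloc letter. Heteroatoms
(bound ligands, waters) are parsed but excluded from protein geometry
unless explicitly included.

## Superposition and displacement

`kabsch_fit()` computes the closed-form least-squares proper rotation via
SVD of the cross-covariance matrix, with the determinant sign correction
that forbids reflections; a mirror-image point set therefore fits with a
non-zero r.m.s.d., which is correct behaviour for chiral molecules.
Degenerate (collinear or < 3-point) inputs are refused.

`refine_superposition()` adds iterative outlier rejection: fit, drop kept
pairs whose residual exceeds `reject_sigma` × the r.m.s. residual of the
kept set, repeat until stable or `max_cycles` (default 5) is reached. Two
numerical details matter. First, the threshold scale is the *r.m.s.*
residual, not the standard deviation of residual norms: residual norms of
well-fitted pairs follow a Maxwell distribution whose standard deviation
(≈ 0.45 σ) lies *below* its mean, so a ±2 s.d. rule would reject roughly
half the kept set on every cycle and erode to nothing — we verified this
failure mode empirically before settling the definition. Second,
rejection stops once the kept r.m.s. residual falls below 10⁻⁶ Å;
beyond that the cycles would chase floating-point noise. The default
multiplier 2.0 mirrors common structural-alignment practice; both
parameters are exposed. This is the route by which a whole-molecule fit
between a folded- and a straight-loop conformer reports the sub-0.2 Å
agreement of the rigid body instead of being inflated by the swung loop.

`displacement_profile()` fits only on a *core* region set (typically
everything minus the loops), applies the transform to the whole chain and
reports per-residue Cα distances. Residues are paired strictly by author
number; no sequence alignment happens in this module (non-identical
sequences belong to the family stage). Unpaired residues are reported,
not fatal.

Per-loop r.m.s.d. (`per_loop_rmsd()`) is computed in two declared modes,
because published per-loop figures rarely state which was used and the
two measure different things: `"loop-local"` (fit on the loop itself —
internal shape) and `"core-frame"` (fit on the core, measure the loop —
placement relative to the fold). The mode is recorded in every output.

## Conformer classification

`classify_conformer()` thresholds the *maximum* displacement over a
sub-region. Defaults: region 301–311 (the N-terminal part of L3, where
the two-state behaviour of the reference system is localized) and 3.0 Å.
The threshold sits between the two scales the decision must separate:
coordinate noise plus core-fit leakage (≲ 0.5 Å) and genuine conformer
swings (≈ 5–9 Å). The maximum (not the mean) is used because a swing
confined to a few residues is still a conformer change. Labels are always
relative to a *named* reference conformer — "folded" is a convention of
the reference choice, never an absolute property. Classification is
monotone in the threshold by construction.

## B-factor normalization

Flexibility profiling uses the Cα B-factor per residue (not the residue
mean over atoms), converted to a z-score with the *population* standard
deviation, `z = (B − ⟨B⟩)/σ_B`. Normalization defaults to per-chain
populations: overall protein B varies by a factor of ~2 between crystal
forms of the same protein, so raw B is not comparable across datasets
while "x σ above this molecule's average" is. If σ_B = 0 (degenerate
input) all z are defined as 0. The min–max alternative was rejected
because it is dominated by the two extreme residues. Region labels use
|mean z| > 0.5 (half a population σ) for flexible/rigid — a documented
labelling convention, not a fitted constant; the mean z itself is the
quantitative output.

## Contact criteria

Crystal structures at 1.5–2 Å resolution carry no hydrogens, so hydrogen
bonds are called on heavy-atom geometry alone: any N/O pair (optionally
S) at ≤ 3.5 Å, no angle term. Pairs within one residue are excluded, and
mainchain–mainchain pairs require a sequence separation ≥ 2 because the
N(i)⋯O(i−1) peptide-plane geometry (~2.2 Å) is covalent neighbourhood,
not bonding. Hydrophobic contacts are side-chain carbon pairs at ≤ 4.5 Å
among \{Ala, Val, Leu, Ile, Met, Phe, Trp, Pro, Cys, Tyr\}, with Tyr
contributing ring carbons only (its hydroxyl end is polar); each residue
pair is reported once at its minimum C–C distance. Both cutoffs are
conventional values for this resolution regime and are exposed as
parameters. Contact sets are stored in a canonical residue-key order, so
outputs are byte-identical regardless of atom order, and are invariant
under rigid motion and monotone in the cutoff (both property-tested).

Published interaction lists for a specific structure are treated as
*membership* checks (is pair X–Y detected?), not exhaustive set equality:
the software and criteria behind such lists are typically unstated.

## Pocket geometry and charge

`pocket_geometry()` reports the minimum heavy-atom distance between the
two gap-forming loops (L2–L3) and an entrance-width metric. Width has no
canonical definition; the default is the maximum Cα–Cα distance between
an L1+L2 rim set and an L3+L4 rim set, an explicit residue-pair list can
replace it, and the definition actually used is embedded in the output.
Width figures should be compared as orderings (folded narrower than
straight), not absolute values. Loop charge is the discrete formal count
(Asp/Glu −1, Lys/Arg +1, His 0) — a deliberate, coarse stand-in for
continuous surface electrostatics, which is out of scope.

## Sequence-level family comparison

Loop mapping across homologs is strictly pairwise (reference → target),
so the aligner is a plain Needleman–Wunsch with affine gaps rather than a
multiple-alignment engine. A gap of length *L* costs
`gap_open + L × gap_extend` (defaults 10 and 0.5, BLOSUM62); traceback
ties break deterministically diagonal > up > left. The aligner is checked
two independent ways: against exhaustive enumeration of every gapped
alignment for short sequences, and against `Biostrings::pairwiseAlignment`
(same penalty convention) on random pairs. `map_loops()` projects the
reference loop's aligned column interval onto the target and counts
non-gap target positions; a loop falling entirely into a target gap is
flagged unmappable with length 0. The L4 signature
`WxxxDNxEWxxGxxxxFG` fixes 8 of 18 positions; `motif_scan()` counts a
match only if every fixed position agrees in some window, and reports the
mismatching positions of the best window otherwise. Conservation is the
fraction of sequences carrying the most common non-gap residue per
column, with the full set size as denominator.

## The synthetic generator, and what passing tests mean

`generate_structure()` lays residues on a helical curve with the
canonical ~3.8 Å Cα spacing and plants, in order: the conformer swing (a
sine-window arc over the flexible span, peak = `swing_amplitude`),
outlier displacements, per-axis Gaussian noise, per-residue B-factors
(background Normal(20, 5) Å², +10 Å² — two background σ — inside the
flexible span), and an optional rigid transform. All randomness comes
from one seeded stream per call; the caller's RNG state is restored, and
identical specifications yield byte-identical files.
`generate_conformer_pair()` shares one noise draw between the twins, so
they differ *exactly* by the planted arc — which makes every downstream
statistic predictable in closed form (e.g. the core-frame L3 r.m.s.d. of
a 6 Å swing over 26 residues is 6·√(mean sin²) ≈ 4.32 Å).

Defaults mirror the reference study system: 420 residues, the four
TsaBgl loop spans, flexible L3, 6 Å swing, 0.1 Å coordinate noise
(typical positional uncertainty of a well-refined 1.5–2 Å structure).

What the generator does **not** emulate: real secondary-structure
topology (the scaffold is a single smooth curve, not a TIM barrel),
side-chain rotamers and packing, crystal contacts, anisotropic or
TLS-modelled B-factors, and correlated noise along the chain. Passing
the planted-truth tests therefore demonstrates that the *estimators*
recover known signals of realistic magnitude under realistic noise — it
does not validate crystallographic model quality, and contact lists on
synthetic structures are meaningful only for planted pairs.

## Test and simulation sizes

The test suite checks the Kabsch fit against a 10⁵-sample random-rotation
grid on 50 small instances; the √3·σ noise law over 200 seeded replicates
at σ = 0.5 Å (mean unfitted r.m.s.d. must fall within ±10% of σ√3);
conformer classification on 50 seeded twin pairs (all must classify
correctly at swing 6 Å / threshold 3 Å); flexible-loop identification by
argmax mean-z and argmax per-loop r.m.s.d. over 100 seeds (≥ 95%); and
aligner-vs-enumeration equality over every pair of length ≤ 2 on a
4-letter alphabet plus several hundred random pairs of length ≤ 4. The
enumeration set is capped at those lengths because the number of gapped
alignments grows super-exponentially (321 paths already at 4×4) while the
property being checked does not change with length.

## Known limitations

- Residue pairing across structures is by author number; renumbered or
  insertion-code-heavy pairs of structures should be mapped through the
  family stage first.
- The hydrogen-bond criterion is distance-only; it will overcount
  N/O pairs in unusual geometries that an angle-aware criterion would
  reject.
- Entrance width is definition-dependent by design; compare widths only
  within one definition.
- `run_analysis()` pairs chains all-vs-all within the declared chain
  list; crystallographic symmetry mates are not generated.
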