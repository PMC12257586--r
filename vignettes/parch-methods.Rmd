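---
title: "PARCH hydropathy for nucleic acids: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PARCH hydropathy for nucleic acids: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

PARCH scores the hydropathy of a residue region from its *dynamics of
hydration* rather than from a fixed chemical lookup. The observable is the
water-count series $\eta_{i\alpha}(t)$: the number of water molecules whose
oxygen lies within a cutoff of any atom of region $\alpha$ of residue $i$
at recorded frame $t$. Nucleotides contribute two regions — the
sugar–phosphate backbone (BB: P, OP1, OP2, OP3, O5', C5', C4', O4', C3',
O3', C2', O2', C1', plus their hydrogens) and the nitrogenous base (NB:
everything else) — amino acids one (AA). The score is

$$C_{i\alpha}(\tau) = \langle \eta_{i\alpha}(t)\,\eta_{i\alpha}(t+\tau)\rangle,
\qquad
\bar C_{i\alpha} = \frac{1}{\tau_{max}}\int_0^{\tau_{max}} C_{i\alpha}(\tau)\,d\tau,
\qquad
PV_{i\alpha} = 10\,\frac{\bar C_{i\alpha}}{\bar C_{ref}},$$

with $\bar C_{ref}$ the identical quantity for a zwitterionic-lysine
reference run. Two modelling commitments follow directly from this
definition and drive the implementation:

* **No mean subtraction.** $C$ is the raw second moment of the counts, not
  the autocovariance of fluctuations. A region that never contacts water
  has $\eta \equiv 0$, hence $\bar C = 0$ and $PV = 0$ *exactly* — the
  zero-exposure rule. Subtracting the mean would destroy this property and
  change the meaning of the scale. A consequence worth knowing: $C(0) \ge
  C(\tau)$ is *not* guaranteed, and $PV$ grows quadratically if counts are
  scaled ($\eta \to k\eta$ gives $PV \to k^2 PV$).
* **One reference for everything.** Because amino acids and nucleotides are
  normalized by the same $\bar C_{ref}$, their values are directly
  comparable. The numeric value of $\bar C_{ref}$ under the original
  protocol is not published, so this package never hard-codes it: every
  `parch_table` records the calibration (value + provenance) that produced
  it, and `calibrate_reference()` runs the reference series through the
  *identical* code path as any target, which makes $PV = 10$ for a series
  referenced against itself a machine-precision identity rather than a
  convention.

The counting window is the annealing production run of the protocol: the
structure is stripped of bulk solvent, rehydrated with a 4.5 Å shell
(4.15 Å for proteins; the thickness comes from the first-shell extent of
the backbone-phosphorus/water-oxygen radial distribution function),
neutralized with counterions at least 3 Å from the molecular surface and
from each other, boxed 3 Å beyond the shell, and heated 300 → 800 K at
1 K/10 ps (5 ns) with the solute position-restrained, in triplicate. The
ramp progressively strips loosely bound water; regions that hold their
hydration shell longer integrate to larger $\bar C$.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| nucleic-acid cutoff | 4.5 | Å | first hydration shell of the backbone (RDF-derived) |
| amino-acid cutoff | 3.15 | Å | protein first shell; used for the lysine reference |
| shell thickness | 4.5 (NA) / 4.15 (protein) | Å | same RDF argument as the cutoff |
| ion clearance | 3.0 | Å | protocol's minimum ion–surface and ion–ion distance |
| box margin | 3.0 | Å | boundary beyond the shell's outer edge |
| ramp | 300→800 K, 0.1 K/ps, 5000 ps | | recording window |
| restraint | 10000 | kJ mol⁻¹ nm⁻² | solute/ion position restraints |
| replicates | 3 | | triplicate annealing runs |
| recording stride | 10 | ps | matches the 1 K/10 ps ramp granularity (500 samples / 5 ns); the original stride is unstated, so this is configurable |
| $\tau_{max}$ | half the series span | ps | unstated in the protocol; long lags rest on few pairs and are noise-dominated, so the horizon excludes them. Configurable via `parch_config()` |
| $\eta$ mapping | identity | | the count-to-$\eta$ map is named but not specified; any fixed linear map cancels in the $\bar C / \bar C_{ref}$ ratio, so identity is the minimal faithful choice. A registry (`register_eta_mapping()`) accepts alternatives, which are applied identically to target and reference |
| replicate combination | mean of $\bar C$ | | also unstated; averaging the integrated quantity avoids any lag-wise alignment assumption between replicates |

## Numerical choices

* **Estimator.** $\hat C(k\,dt) = \frac{1}{N-k}\sum_t \eta_t\eta_{t+k}$,
  dividing by the number of available pairs at each lag. Computed via FFT
  ($O(N\log N)$); the test suite pins it to a direct-summation oracle at
  $10^{-10}$ relative on series up to $N = 2000$ and to the analytic AR(1)
  autocovariance at $N \in \{500, 5000, 50000\}$.
* **Quadrature.** Trapezoid on the uniform lag grid — exact for the
  piecewise-linear interpolant, and therefore the natural definition of
  the integral of a sampled curve.
* **Counting boundary.** Closed ($d \le$ cutoff). The choice at the
  boundary is arbitrary but must be fixed and identical across code paths;
  the acceptance tests include a water at *exactly* the cutoff distance.
* **Cell list.** Water counting uses a cell list whose cells are at least
  one cutoff wide; it only *prunes* candidate pairs, and the surviving
  pairs go through the same squared-distance expression (same operation
  order, same minimum-image convention) as the brute-force path, so the
  two agree exactly, not just statistically. With a periodic box whose
  edge supports fewer than three cells the code falls back to brute force,
  since the 27-neighbour enumeration is only valid from three cells up.
* **Double counting.** A water may count simultaneously for BB and NB of
  the same residue; the two regions are scored independently. The sum of
  region counts is therefore never below the whole-solute count.
* **Region membership** is a pure function of atom names: primed
  hydrogens and terminal hydroxyl/phosphate hydrogens follow the backbone,
  unprimed base hydrogens follow the base; OP3 (5'-terminal phosphate) is
  backbone. O2' makes the RNA backbone one atom larger than DNA's.
  Alternate locations keep the highest-occupancy conformer. A 5'-terminal
  residue without a phosphate still has a (sugar-only) BB region; a
  nucleotide with no sugar atoms is rejected as malformed; unrecognized
  solute residues are excluded with a warning rather than guessed at.
  Modified nucleotides that keep a standard residue name are partitioned
  by the same table — substituted constructs get no special casing.
* **Degenerate inputs.** Series shorter than two samples, single-point lag
  grids, all-zero reference series, empty shells, and infeasible ion
  placements are hard errors with classed conditions; a PV above the PDB
  B-factor field width is clamped to 999.99 with a warning.

## The synthetic generators: what they emulate, what they do not

The toy layer exists so that every stage of the pipeline — classification,
shell construction, counting, estimation, normalization, annotation,
statistics — can be validated end to end with no MD engine and no
downloads. All generators are seed-deterministic.

* `generate_duplex()` builds a schematic cylindrical helix: rigid
  per-residue templates with correct PDB v3 atom names, backbone at
  7–10 Å radius, base walking inward, placed by the declared twist/rise
  (36°/3.38 Å B-form for DNA with an auto-generated complementary
  antiparallel strand; 32.7°/2.81 Å single-strand A-form for RNA, matching
  the mostly single-stranded character of folded RNA). The declared
  twist/rise are exactly recoverable from the C1' coordinates, which the
  tests verify. It is *not* a refined nucleic-acid geometry: bond lengths,
  grooves, and base pairing are only sketched.
* `simulate_shell_dynamics()` moves waters as overdamped random walks
  confined to the shell (step variance $2D(T)\,dt$ per axis, $D(T)$ linear
  in the instantaneous ramp temperature, hard-wall rejection at the shell
  boundaries, which preserves a uniform stationary distribution over the
  accessible volume — verified against the geometric volume fraction).
  The solute is frozen, mimicking the position restraints. There are no
  forces, no water–water interactions, and no energetics: the generator
  reproduces the *statistical shape* of count series (positive, bounded,
  autocorrelated, temperature-thinned), not water structure.
* `generate_ar1()` supplies series whose raw autocorrelation is known in
  closed form ($\mu^2 + \phi^{|k|}\sigma^2/(1-\phi^2)$), the analytic
  oracle for the estimator chain.
* `buried_vs_exposed_fixture()` makes the zero-exposure rule *provable*
  rather than probable: a 1.6 Å-spaced atom ball of radius 6 Å has no
  interior voids beyond the 1.5 Å steric floor, so no accessible point
  exists within the amino-acid cutoff of its central residue, and that
  residue's count series is identically zero by geometry.

Consequently, a passing test suite demonstrates that the *mathematics and
plumbing* of the scale are correct and that the qualitative backbone >
base ordering emerges from exposure geometry alone. It does not reproduce
the dataset-level magnitudes of production runs (e.g. backbone means near
4.3 under the full protocol), which require force-field MD on curated PDB
sets; with the toy simulator's small shells and frozen solute, absolute
PV values run higher and are meaningful only relative to one another and
to their recorded calibration.

## Statistics layer

Densities default to Freedman–Diaconis histograms (figure bandwidths in
published distributions are rarely stated; FD is robust for the skewed,
bounded-below PV distributions), renormalized to unit area; constant
input degenerates to an explicit point mass. Group comparisons use the
tie-corrected Kruskal–Wallis omnibus (`stats::kruskal.test`), with an
optional seeded permutation null — the pooled ranks and tie correction are
permutation-invariant, so the null reduces to rank-sum reshuffles — and a
Dunn post hoc with Holm correction to localize pairwise differences
(the omnibus test alone cannot support claims like "dA differs from dT").
Complex-versus-component deltas report $PV_{component} - PV_{complex}$
per matched region, stratified by interface contact; a contact is any
region atom within 4.5 Å of the partner molecule (the same first-shell
distance as the counting cutoff, since published contact lists rarely
state a criterion).

## Problem sizes

The shipped validation runs at deliberate desk scale: toy duplexes of 4–8
residues (150–300 shell waters), 40–151 recorded frames per replicate,
AR(1) series up to $N = 5\times10^4$, 100-fold randomized counting
fixtures, and $10^5$-draw permutation nulls. These sizes were chosen so
the full suite completes in about a minute while every statistical
assertion retains a ≥3-standard-error margin.

## Known limitations

* The toy simulator's hydration numbers are not transferable to real
  systems; only production MD following the full protocol yields
  comparable magnitudes. The package's own calibration is honest about
  this by carrying provenance everywhere.
* $\bar C_{ref}$, $\tau_{max}$, the recording stride, the $\eta$ map, and
  the replicate-combination rule are declared defaults, not published
  constants; changing them rescales PV values (the tables record the
  configuration used).
* mmCIF input is not implemented; structures arrive as PDB (v3 atom
  naming). Structure repair, protonation, and topology generation are out
  of scope.
* The RDF normalization assumes an orthorhombic box and uniform partner
  density; triclinic cells are not supported.
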