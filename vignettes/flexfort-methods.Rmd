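---
title: "Flexibility-guided thermostabilization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexibility-guided thermostabilization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexfort)
```

# The engineering model

Thermophilic enzymes are, on average, more rigid than their
mesophilic relatives. flexfort operationalizes the two-step strategy
that follows from this observation: (1) locate sites of elevated
flexibility in the target enzyme, and (2) replace them with residues
the protein family prefers — in practice often serine or threonine,
which are associated with rigidity in thermophiles.

## Step 1: normalized B-factor comparison

Crystallographic B-factors measure mean-square atomic displacement
but depend strongly on resolution and refinement protocol, so two
structures' raw B-values live on different scales. Within each chain
we therefore z-score the Cα B-factors,
$$B' = \frac{B - \langle B \rangle}{\sigma(B)},$$
using the **sample** (n − 1) standard deviation. The choice of
divisor is immaterial at typical chain lengths (n ≈ 200 changes B'
by 0.25%) but must be pinned for exact tests; we use the sample
convention throughout. Normalization is applied to the extracted Cα
profile of one chain, not to all atoms: main-chain flexibility is
what the comparison is about, and mixing chains would blur
per-protomer differences.

The two sequences are aligned globally (Needleman–Wunsch via
Biostrings) under BLOSUM62 with gap opening 10 and extension 0.5 —a
gap of length $L$ costs $10 + 0.5L$. A global alignment fits the
use case (two homologous single-domain enzymes compared end to end);
the scoring parameters are conventional defaults and exposed as
arguments. Where several alignments tie, the alignment engine's
deterministic tie-breaking is accepted as is; determinism, not a
specific tie, is what downstream code relies on.

The paired profile assigns to every alignment column the residue
numbers and B' values present, and on *match columns* the difference
$\Delta B' = B'_{target} - B'_{homolog}$. Segment calling then scans
target positions for maximal runs with $\Delta B' \ge \delta_{min}$.
Two parameters govern the call:

* `deltaMin` (default **0.5**, dimensionless): half a standard
  deviation of excess mobility. Small enough to catch moderately
  flexible loops, large enough that, with per-position noise of
  z-score scale ~0.1, a spurious 3-run has negligible probability.
* `minRun` (default **3** residues): a mutation-worthy segment
  should be a structural element, not a single noisy position.

Target residues facing alignment gaps in the homolog have no
$\Delta B'$; they are reported as segments of kind `gap-opposite`
(insertions the homolog simply lacks — themselves candidate
flexibility hotspots). These defaults recover planted segments of
the sizes seen in practice (4–6 residues) essentially perfectly on
the synthetic fixtures; both are configuration, not constants.

## Step 2: conservation-guided proposal

Column frequencies are counted over **all** records of the family
MSA, gaps included in the denominator — a residue conserved in 31% of
the family means 31% of sequences, not 31% of non-gap rows. Gaps are
never reported as consensus. No sequence weighting or redundancy
filtering is applied by default: the intended input is a
representative family set, and plain counting keeps the reported
percentages interpretable. Information content is the standard logo
quantity $\log_2 20 + \sum_a g_a \log_2 g_a$ with $g$ the non-gap
renormalized frequencies; no small-sample correction is applied.

A substitution is proposed at a flexible-segment position when three
predicates hold: the consensus differs from the wild type, the
consensus frequency is at least `minConsensus` (default **0.25** — a
quarter of a diverse family agreeing on one residue at a surface
position is strong preference), and the consensus is more frequent
than the wild-type residue. An optional `serThrBonus` lowers the
floor to 0.20 when the consensus is Ser/Thr, encoding the
rigidity-by-hydroxyl prior; it is off by default so that the base
policy is purely frequency-driven. With the frequency configuration
typical of the motivating GH11 C-terminus case (consensus S/S/G/S at
31/31/48/31% against wild type N/G/G/A at 7/4/48/11%), the policy
yields exactly the three substitutions N207S, G208S, A210S and leaves
the already-consensus glycine alone.

Codon edits minimize Hamming distance to the wild-type codon among
all codons of the target residue (NCBI genetic-code tables via
Biostrings; table 1 default). Ties break lexicographically
(A < C < G < T) rather than by codon usage — for the cases this
package targets the minimal edit is unique, and a deterministic rule
keeps primer output reproducible. Full primer design (flanks, Tm) is
out of scope.

# Trajectory analytics

All metrics are deterministic functions of the trajectory file; no
randomness enters this module.

**Superposition and RMSF.** Each frame is rigid-body fitted to a
reference frame on selected Cα atoms, with the optimal rotation from
the SVD (Kabsch) construction. RMSF is
$\sqrt{\langle |x_i - \bar x_i|^2 \rangle}$ about the time-average
position, with the $n$ (not $n-1$) divisor. Note a small-system
caveat: fitting to a noisy reference absorbs six rigid-body degrees
of freedom, deflating RMSF by about $\sqrt{1 - 6/3N}$ for $N$ fitted
atoms. The harmonic synthetic fixtures are generated in a common
frame, so their closed-form truth $\sigma\sqrt{3}$ applies to the
unrefitted trajectory; real trajectories should be superposed on a
large, rigid selection.

**Minimal distance.** Per frame, the minimum pairwise atom distance
between two residues; heavy atoms only by default, because hydrogen
positions are force-field constructs where present at all. The
histogram is density-normalized. Output in Å or nm via a units flag
(areas likewise in Å² or nm²).

**SASA.** Shrake–Rupley: each atom inflated by the probe radius
(default 1.4 Å) carries a deterministic golden-spiral mesh (default
960 points); the accessible area is the unoccluded fraction times
the sphere area. Radii are the Bondi set, looked up by element; an
unknown element is an error rather than a silent default. 960 points
give ≤ 1% error against the two-sphere closed form and ≤ 1%
drift against a 4000-point mesh; the count is configurable where
tighter convergence is needed. Trajectory mode reports per-residue
mean ± sd over frames.

**Hydrogen bonds.** Geometric criteria: donor–acceptor distance
≤ 3.5 Å and H–donor–acceptor angle ≤ 30°, the conventional defaults
of trajectory H-bond tools, both configurable. Donors are N/O atoms
with a covalently attached hydrogen (attachment inferred at
< 1.25 Å), acceptors are N/O atoms. Occupancy is the bonded fraction
of frames; a window series (default window span/100) and a block
standard error (default block span/5, one standard error of
per-block means) summarize the time structure. Both windows scale
with the trajectory span so short fixtures remain analyzable.

**Secondary structure.** A simplified Kabsch–Sander assignment:
backbone H-bond energy
$E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol, bond when $E < -0.5$. Missing amide hydrogens are placed
1.0 Å from N opposite the bisector of the C(i−1)–N and CA–N bonds;
prolines and chain-initial residues donate nothing. Two consecutive
i→i+4 bonds label the four bracketed residues H; parallel or
antiparallel bridge patterns label both partners E (helix wins on
overlap); everything else is C, including residues with missing
backbone atoms (warned). The 8-class DSSP alphabet is deliberately
collapsed — the analyses this supports need only helix/strand/coil
propensities. Labels on ideal geometries are stable to ≥ 0.05 Å
coordinate jitter.

# Kinetics

Lineweaver–Burk is ordinary least squares on $(1/S, 1/v)$, after
which $V_{max} = 1/\text{intercept}$ and $K_m =
\text{slope}/\text{intercept}$. The fit is unweighted: that is what
the classical double-reciprocal analysis does, and matching it is
the point; the well-known variance distortion of the transform is
why a direct nonlinear `michaelisMentenFit` (via `nls`, started from
the LB estimates, with a scale offset so zero-residual data
converge) is provided for comparison. A non-positive intercept
flags the estimates as meaningless rather than erroring. Reported
tables round half-up to 2 decimals. `kcatConsistency` audits units:
for $V_{max}$ in µmol·min⁻¹·mg⁻¹ and mass in kDa,
$V_{max} \cdot m_w / 60$ is an implied $k_{cat}$ in s⁻¹, and the
relative deviation from the quoted $k_{cat}$ should be within a few
percent for a coherent table. The catalytic-efficiency column is
stored as the plain quotient $k_{cat}/K_m$ with an explicit unit tag
(1/s/µM), so re-derived values match a table's printed numbers
without reinterpreting its unit label.

# Synthetic data: what it emulates, and what not

Each generator takes a seed, uses a private RNG stream (global RNG
state is saved and restored), and emits machine-readable truth, so
identical calls are byte-identical and downstream tests score
against planted truth rather than copied constants.

* `genStructurePair` plants a smooth AR(1) baseline B-profile in the
  homolog and adds prescribed $\Delta B'$ bumps and insertion blocks
  in the target, on an idealized extended backbone. Because
  z-scoring is affine-invariant, the planted contrast survives the
  raw-B encoding up to a small attenuation
  ($\approx \delta \cdot \ell / n$ mean shift and a ~2% variance
  inflation for one planted segment of length $\ell$), which the
  default margins absorb. Letters flanking an insertion are
  resampled to differ from the letters across the junction so the
  gap's alignment placement is score-unique. Defaults (220 residues,
  one 4-residue planted segment at 1.2, one 6-residue insertion,
  noise sd 0.1) mirror the motivating use case's geometry.
* `genMsa` plants exact residue counts at chosen columns (31% means
  exactly 31 of 100 sequences) against i.i.d. uniform background
  columns, optionally around a given full reference sequence.
* `genTrajectory` provides (i) harmonic Cα jitter with truth RMSF
  $\sigma\sqrt3$, (ii) an H-bond pair toggled on/off by an explicit
  schedule, and (iii) ideal-geometry frames: a φ/ψ = (−57°, −47°)
  helix, a (−139°, 135°) extended strand, and an antiparallel
  two-strand pair built from a canonicalized strand and its
  180°-rotated copy, with the rigid offset chosen so cross-strand
  Kabsch–Sander energies clear the −0.5 kcal/mol threshold with
  ≥ 0.13 kcal/mol margin on both sides.
* `genKinetics` draws $v = V_{max}S/(K_m+S)\,(1+\varepsilon)$,
  $\varepsilon \sim N(0, cv)$, at eight substrate concentrations
  spanning 0.5–5.

None of these generators emulate real physics: no force field, no
correlated dynamics, no phylogenetic structure in the MSA, no
crystallographic error model. Passing the recovery tests therefore
demonstrates that the *analytics* are correct on inputs with known
truth — not that the engineering strategy will succeed on any given
real enzyme, which remains an experimental question.

# Numerical conventions and degenerate inputs

* Coordinates are Å internally (PDB native); distances and areas
  offer nm/nm² output flags.
* Author residue numbering is the only public coordinate system.
* Altloc collapse keeps the highest occupancy, ties to the
  alphabetically first altloc.
* Constant B-profiles (σ = 0) and profiles of < 3 residues are
  errors, not NaNs; zero velocities cannot be reciprocated; a
  single distinct substrate concentration is a singular design.
* PDB round trips preserve coordinates to 3 decimals and B to 2
  (the format's own precision); trajectory frames must agree in
  atom count and identity, checked with the offending frame named.
* Problem sizes used by the default test run and the acceptance
  script (200 alignment pairs of length ≤ 8 against an independent
  affine-gap dynamic program — itself validated against exhaustive
  enumeration at lengths ≤ 5 —, 50 segment-recovery fixtures of 220
  residues, 5000-frame harmonic trajectories of 10 residues, 200
  noisy kinetics replicates) were chosen to make sampling error
  negligible relative to the tested tolerances while completing in
  minutes on one CPU.

# Known limitations

* PDB dialect only (no mmCIF); single-conformer models after altloc
  collapse; no assembly generation.
* Sequence-based pairing only: a structure-based (3D) alignment
  would map flexibility more faithfully where sequences have
  diverged badly.
* The H/E/C assignment omits 3₁₀/π helices, turns and bends; bridge
  detection has no ladder-merging beyond the bridge patterns
  themselves.
* SASA has no per-frame neighbor-list acceleration and is intended
  for selections and fixture-scale systems, not thousands of frames
  of large proteins.
* The proposal policy is frequency-only; it does not model
  structural context (packing, strain, disulfides) and will happily
  propose substitutions a structure-aware method would veto.
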