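# flexfort

Flexibility-guided thermostabilization of enzymes: find the floppy
segments of a mesophilic target by comparing normalized crystal
B-factors against a thermophilic homolog, then rigidify them with
family-consensus substitutions — plus the trajectory analytics and
kinetics arithmetic used to characterize the resulting mutant.

The package is aimed at protein engineers and structural
bioinformaticians who have (i) crystal structures of a target enzyme
and a thermostable relative, (ii) a family multiple sequence
alignment, and optionally (iii) MD trajectories and steady-state rate
measurements of designed variants.

## The method

**Flexible-site detection.** Crystallographic B-factors are
proportional to atomic mean-square displacement, but refinement
protocols differ between structures, so raw values are not
comparable. Each structure's Cα B-factors are therefore reduced to
per-structure z-scores

    B' = (B − ⟨B⟩) / σ(B)

with ⟨B⟩ the mean and σ(B) the sample standard deviation within that
chain. After a global Needleman–Wunsch alignment of the two sequences
(BLOSUM62, affine gaps), the profiles are paired column by column and
the excess flexibility ΔB' = B'_target − B'_homolog is scanned for
maximal runs with ΔB' ≥ δ_min (default 0.5, ≥ 3 residues). Target
insertions facing alignment gaps in the homolog are reported as their
own segment kind, since they have no counterpart to compare against.

**Substitution proposal.** For each position in a flexible segment,
the family MSA's column frequencies are computed (gaps count in the
denominator, never as consensus). A mutation to the consensus residue
is proposed when the consensus differs from the wild type, reaches a
frequency floor (default 25%), and is more frequent than the wild
type. Minimal-Hamming codon edits (ties broken lexicographically)
translate each proposal into the single-nucleotide change a
mutagenesis primer would carry.

**Mutant characterization.** Self-contained trajectory analytics:
Kabsch superposition and per-residue RMSF, minimal inter-residue
distance distributions (e.g. the thumb–finger gate of a GH11
xylanase cleft), Shrake–Rupley SASA (Bondi radii, 1.4 Å probe, 960
golden-spiral points), geometric hydrogen-bond occupancy (donor–
acceptor ≤ 3.5 Å, H-donor-acceptor angle ≤ 30°) with block standard
errors, and a simplified Kabsch–Sander H/E/C secondary-structure
assignment. Kinetics: Lineweaver–Burk estimation of (Vmax, Km),
catalytic efficiency kcat/Km, fold changes, and a Vmax·mw/60 ↔ kcat
unit audit.

Seeded generators (`genStructurePair`, `genMsa`, `genTrajectory`,
`genKinetics`) produce synthetic inputs with machine-readable planted
truth for every one of these analyses.

## Worked example

```r
library(flexfort)

## a synthetic target/homolog pair with a planted flexible C-terminal
## segment (207-210, ΔB' = 1.2) and a 6-residue insertion (86-91)
pair <- genStructurePair(nRes = 220,
                         plantedSegments = list(c(207, 210, 1.2)),
                         gapBlocks = list(c(86, 6)),
                         noiseSd = 0.1, seed = 7)
cmp <- compareFlexibility(pair$target, pair$homolog)
cmp$segments
#>   start end length meanDelta         kind
#> 1    86  91      6        NA gap-opposite
#> 2   207 210      4   1.11162      matched
```

Both planted regions are recovered: the matched segment with mean
normalized-B excess ≈ 1.1 (planted 1.2, attenuated slightly by
re-standardization), and the insertion as a gap-opposite segment.

```r
## catalytic efficiencies of a mutant (kcat 125 /s, Km 0.22 uM) and
## its template (204 /s, 0.59 uM), and their ratio
eff <- c(mut = catalyticEfficiency(125, 0.22),
         wt  = catalyticEfficiency(204, 0.59))
round(eff, 2)                       #   mut     wt
#>    568.18 345.76
round(foldChange(eff["mut"], eff["wt"]), 2)
#> 1.64

## Lineweaver-Burk on noisy synthetic rate data (true Vmax 278, Km 1.5)
g <- genKinetics(Vmax = 278, Km = 1.5, noiseCv = 0.02, seed = 5)
f <- lineweaverBurkFit(g$data$S, g$data$v)
c(Vmax = round(f$Vmax, 1), Km = round(f$Km, 3), R2 = round(f$r2, 4))
#>     Vmax       Km       R2
#> 281.2000   1.5460   0.9981
```

The efficiency of the mutant is 1.64-fold that of the template, and
the double-reciprocal fit recovers the generating parameters within a
few percent at 2% multiplicative noise.

A command-line wrapper is provided in `inst/scripts/flexfort`
(`design`, `kinetics`, `synth` subcommands); `runDesignPipeline()` is
the same pipeline as a function and writes a deterministic report
bundle (paired profile, segments, conservation, proposals, mutant
FASTA, config with input hashes).

## Documentation

The methods vignette (`vignettes/flexfort-methods.Rmd`) describes the
model, parameter choices, numerical conventions, what the synthetic
generators do and do not emulate, and known limitations.
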