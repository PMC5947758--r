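---
title: "Preparing molecular-replacement search models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing molecular-replacement search models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrprep)
```

# The problem

Molecular replacement (MR) phases a crystallographic data set by placing a
related structure — the *search model* — in the target unit cell. Success
is acutely sensitive to how closely the model resembles the target, so the
preparation step matters as much as the MR search itself: the parts of a
homologue that are conserved should be kept, the parts likely to differ
should be pruned or removed, and a set of homologues can be combined into
a statistically weighted *ensemble*. `mrprep` implements that preparation
as a library: from sequence-search hits and homologue coordinates to
truncated, r.m.s.d.-annotated ensemble search models, plus copy-number
estimation and triage of MR results.

# The pipeline and its assumptions

## Hit handling

A sequence search of a database of known structures returns hits with
bit-like scores and a multiple sequence alignment (MSA). The pipeline

1. filters hits at a score cutoff (default 20, inclusive); the default
   removes unrelated proteins while keeping distant but usable homologues;
2. strips terminal polyhistidine purification tags and discards sequences
   shorter than ten residues, both of which otherwise attract
   false-positive matches;
3. collapses redundancy by greedy single-linkage clustering of sequences
   whose pairwise identity exceeds the chosen level (100 = no removal, 95,
   90, 70, 50%; default 95), keeping per cluster the entry with the best
   (numerically smallest) resolution, then the lowest *R* value, then the
   lexicographically first identifier. The 95% default samples
   structurally distinct models rather than ten ligand variants of one
   deposition.

Identity between two sequences is computed from an end-gap-free affine
global alignment (match +1, mismatch 0, gap open −10, extend −0.5 per
position) as identical aligned pairs divided by the length of the
*shorter* sequence. The short-side denominator makes a fragment collapse
onto its parent chain, which is the behaviour redundancy reduction needs.
One score column is carried per hit; the hit table is treated as the
search program's full-sequence score, the field its tabular output ranks
on.

## Domain clustering

Hits may match different parts of the target. Each hit's aligned region is
summarised by its *midpoint* and *extent* in target numbering (midpoint
rounded half-up), and hits are grouped by a seeded rule: the
highest-scoring unassigned hit (ties by identifier) seeds a cluster, and
every unassigned hit within ±10 residues of the seed's midpoint *and* ±25
residues of its extent joins. Tolerances are measured to the seed, not
chained transitively: chaining could merge drifting spans into one
cluster, while the seed-relative rule is deterministic and bounds every
member's deviation from its seed. Clusters are numbered in creation
order; these "domains" are grouping labels, not necessarily structural
domains.

## Model editing

Editing works through the pairwise target–hit alignment extracted from the
MSA (columns gapped in both rows removed). The i-th residue of the
single-chain model corresponds to the i-th hit-sequence position; aligned
residues are renumbered to their target positions (original numbers kept
as `source_resno`), and insertions relative to the target are deleted.
Three protocols are offered:

- **mixed (C^γ) models**: residues whose type matches the aligned target
  residue keep all atoms; others are pruned to {N, CA, C, O, CB} plus one
  γ-position atom. The γ atom per residue type is enumerated explicitly —
  OG for Ser, OG1 for Thr, SG for Cys, CG1 for Ile/Val, CG otherwise — so
  behaviour is deterministic across all twenty types.
- **polyalanine**: backbone plus existing Cβ, renamed ALA; no Cβ is ever
  fabricated for glycine.
- **unmodified**: renumbering only.

Pruned residues keep their homologue names, with the aligned target type
recorded as an annotation: renaming without rebuilding side-chain
coordinates would misdescribe the atoms present, and the package never
invents coordinates. B factors pass through unchanged — the conservative
reading of "use the original B factors" — and editing never adds atoms or
moves retained ones.

## Superposition and per-position variance

Members of a domain are superposed by iterative least squares: the frame
is anchored on the first member; each member is rigidly fitted (Kabsch SVD
with reflection correction) onto the current centroid over the *core* —
the target-numbered positions carrying a C^α in every member; the centroid
is recomputed as the per-position mean; iteration stops when the largest
centroid shift is below 10⁻⁶ Å or after 100 iterations (typical families
converge in < 10). Correspondence comes from target renumbering rather
than sequence-independent structural search: models are edited first, so
their numbering is already common, and replicating a full structural
aligner is out of scope here.

The result carries the per-position variance — the population mean squared
deviation of member C^α positions from the centroid (divisor *n*) — and
each member's core r.m.s.d. The decomposition is exact:
Σ_j σ²(j) · n_members = Σ_m rmsd_m² · N_core, which the tests assert to
10⁻⁹.

## Ensemble truncation

Derived ensembles retain the least-variable core positions in steps of 5%
(20 derived levels by default): level *p* keeps the ⌈p/100 · N_core⌉
positions of lowest variance. Ceiling rounding makes a 184-position core
keep 19 positions at the 10% level. Variance ties break by ascending
residue number, which both fixes the selection and guarantees that
retained sets nest across levels. The *base* ensemble (labelled "110%" in
interactive interfaces) additionally keeps each member's residues outside
the common core.

Members of each truncated ensemble are re-superposed onto the centroid
restricted to the retained positions before their r.m.s.d. is computed, so
the annotation describes the model actually written; with fewer than three
retained positions the fit is skipped and only the r.m.s.d. is
recomputed in the base frame. Annotations are written as
`REMARK PHASER ENSEMBLE MODEL i RMS r.mmm` cards, the form MR programs
read as per-member coordinate-error estimates.

When no superposition is available, an initial r.m.s.d. can be estimated
from sequence identity as 0.4·exp(1.87·(1 − identity)) Å — the
exponential identity-to-deviation calibration familiar from the MR
likelihood literature. The constants are fixed in code and documented
here; at identity 1 the estimate floors at 0.40 Å, at 25% it reaches
≈ 1.6 Å.

## Copy number and solution triage

The Matthews coefficient V_M = V/(Z·M) (Å³/Da; V from the standard
triclinic volume formula, Z = asymmetric units per cell × copies, M from
residue count × 110 Da by default) gives solvent fraction 1 − 1.23/V_M.
The copy-number estimate scans n = 1, 2, … while solvent stays ≥ 25% and
picks the n closest to 50% solvent (ties to the larger n): protein
crystals cluster around half solvent, and the resolution-dependent prior
refinements of that criterion are deliberately out of scope.

Triage of refined MR trials uses R_free categories — GOOD < 0.35,
MARGINAL up to 0.5, POOR above — plus flags: log-likelihood gain ≥ 60,
translation-function peak > 8σ, and density-modification tracing success
(CC > 25% *and* mean traced chain length ≥ 10 residues). Boundary
semantics the thresholds' sources leave open are fixed as printed here:
GOOD is strict, R_free = 0.5 is MARGINAL, the LLG flag is inclusive, CC
strict, chain length inclusive. Ranking sorts ascending R_free with ties
by model identifier; rows with no R_free keep input order at the bottom.

# The synthetic generator

`make_target()` builds a self-avoiding chain of alternating idealized
helical segments (radius 2.3 Å, rise 1.5 Å, 100°/residue) and smooth
connecting turns, laid out as a serpentine bundle; C^α atoms are placed by
marching along the smooth path at an exact 3.8 Å chord, and N, C, O, Cβ
and one γ atom are added from an idealized local frame. `make_family()`
adds per-residue isotropic Gaussian displacements in two tiers — a
conserved core (default σ 0.2 Å) and one contiguous variable block
(default σ 2.0 Å) — optional random rigid motions, and sequence mutations
placed to land on a requested identity. `make_hits()` fabricates
multi-domain hit tables and Stockholm MSAs with spans jittered within the
clustering tolerances.

What this emulates: the conserved-core/variable-loop statistics that
variance-ranked truncation exploits, controlled sequence identity, rigid
displacement of input models, and multi-domain hit layouts. What it does
not: real side-chain packing, correlated (hinge or domain) motions,
alignment errors, experimental B-factor structure, or crystallographic
data. Passing tests therefore demonstrate that the algorithms recover
engineered signal under the stated noise model — not that any particular
real target will solve.

Two calibration facts the tests rely on, derived before testing:

- For n members with per-axis noise σ, the r.m.s. deviation about the
  sample mean has expectation σ√3·√(1 − 1/n); the suite checks the
  10-member case within 10%.
- When estimated variance is rank-correlated against a *two-valued*
  reference (core σ² vs loop σ²), ties in the reference cap the attainable
  Spearman at √(3·p(1−p)) for loop fraction p — 0.75 at p = 0.25 and 0.866
  for balanced tiers — even for perfect recovery. The rank-correlation
  check is therefore run at a 50% loop fraction, where the 0.8 bar can
  discriminate (measured: 0.866, i.e. essentially perfect), and the
  tier-separation check (≥ 95% of the top-variance positions belong to the
  loop tier) at a 25% block.

# Numerical and degenerate-input choices

- Kabsch requires ≥ 3 points and rejects collinear sets (second singular
  value < 10⁻⁸ of the largest): the rotation about the line is undefined.
- Alt-loc resolution on PDB input keeps the highest-occupancy conformer,
  ties to the alphabetically first alt-loc; waters, HETATM records and
  hydrogens are dropped — search models never need them.
- Stockholm `.` and `-` are both gaps, normalised to `-`; FASTA wraps at
  60 columns and uppercases on read, so writers are byte-deterministic.
- Insertion codes order alphabetically after their parent residue number.
- The score cutoff is inclusive (≥ 20); an empty result from any filter is
  valid and propagates as an empty (not failed) stage.
- All generators are seeded; two runs with the same inputs produce
  byte-identical output trees.

# Problem sizes in the test suite

The suite exercises targets of 30–200 residues, families of 2–10 members,
50-hit clustering instances, and exhaustive-subset checks for cores of up
to 15 positions; the acceptance script uses a 120-residue single-domain
family of 8 members, a 184-core family for the ceiling-truncation count,
and a 200-residue 10-member family for variance recovery. These sizes give
every statistic headroom above its threshold while keeping a full run in
seconds.

# Known limitations

- Correspondence-by-renumbering stands in for sequence-independent
  structural alignment; homologues whose alignment to the target is wrong
  will superpose wrongly (garbage in, garbage out).
- Maximum-likelihood superposition can down-weight variable regions and
  give a lower core variance than least squares; only the least-squares
  scheme is provided, and no criterion for choosing between the two is
  offered.
- The per-member r.m.s.d. is not guaranteed monotone per member across
  truncation levels (the per-level *mean* is, on tiered families, and that
  is what the suite asserts).
- Copy-number estimation ignores resolution-dependent priors and
  non-protein content; the 110 Da mean residue mass is configurable but
  crude for unusual compositions.
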