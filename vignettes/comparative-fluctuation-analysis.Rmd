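---
title: "Comparative residue-fluctuation analysis of MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative residue-fluctuation analysis of MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdfluct)
```

## The scientific question

When a hyperthermophilic enzyme and its mesophilic homolog share a fold,
the difference in thermal tolerance often shows up in molecular dynamics as
a difference in *local* flexibility: the thermostable protein is rigid where
the mesophilic one fluctuates. mdfluct implements the comparative analysis
used to localise that difference. Given one trajectory per homolog it

1. superposes every frame onto a reference and reports per-frame RMSD
   (global drift) and per-residue RMSF (local flexibility),
2. aligns the homolog sequences and assigns a *common residue numbering*
   so per-residue quantities can be compared across proteins of different
   lengths,
3. computes the per-column difference
   $\Delta_i = \mathrm{RMSF}^{\text{meso}}_i -
   \overline{\mathrm{RMSF}^{\text{thermo}}_i}$ and calls contiguous
   *regions* where $\Delta_i$ exceeds the average difference
   $\bar\Delta$, and
4. measures salt-bridge and hydrogen-bond distance series and their
   occupancies, classifying each candidate interaction per homolog as
   SB, HB or NI (no corresponding interaction).

Because production MD trajectories of real enzymes are rarely
distributable, the package also contains a synthetic-trajectory generator with
*planted* ground truth. It is first-class, tested code: every downstream
quantity (fluctuation amplitude, region boundaries, contact occupancy,
residue correspondence) can be checked against what was planted.

## Models and procedures

### Superposition, RMSD, RMSF

Rigid superposition is the closed-form Kabsch solution: SVD of the
weighted covariance of the centred point sets, with the reflection branch
suppressed so the returned rotation is proper. A deliberately slow
quaternion-grid search (`rmsd_quaternion_grid`) is kept in the package as
an independent brute-force reference; tests require agreement to 1e-4 Å.

RMSF uses a two-pass iterated-mean procedure: frames are superposed onto
frame 1 and averaged; all frames are then re-superposed onto that mean and
averaged again; RMSF is the root mean squared deviation about the second
mean. Two fixed passes (no convergence loop) keep the procedure
deterministic. A consequence worth knowing: the result depends weakly on
which frame seeds the first pass, so frame-order invariance holds only to
$O(\sigma/F)$, and the tests assert it at that level rather than exactly.

Two finite-size factors appear in the closed-form expectations the tests
use. Fitting a noisy frame removes six rigid degrees of freedom, shrinking
the expected mean-square deviation by $(3N-6)/3N$ for $N$ fitted atoms, and
estimating the mean structure from $F$ frames contributes $(F-1)/F$. The
expected RMSF under isotropic per-axis noise $\sigma$ is therefore
$\sigma\sqrt{3}\sqrt{(3N-6)/3N}\sqrt{(F-1)/F}$, with per-residue sampling
error $\approx \sigma/\sqrt{2F}$. Both factors were validated against
repeated simulation before the tolerances were frozen.

The atom selection for both RMSD and RMSF defaults to the CA trace and is
config-exposed; the selection used is recorded in the outputs. RMSF
requires the selection to resolve to exactly one atom per residue.

### Common numbering and region calling

Pairwise alignment is global (Needleman–Wunsch) with affine gaps via the
Gotoh three-state recurrence; a gap of length $L$ costs
$\text{open} + L\cdot\text{extend}$ (defaults 10 and 1, BLOSUM62). Ties are
broken deterministically: residue pairing, then gap in the first sequence,
then gap in the second. Multiple alignment is progressive: the closest pair
by percent identity is aligned first and the remaining sequences are added
against the growing profile, scored by the column-average substitution
score, with lexicographic-id tie breaks. This is adequate for the intended
use (full-length homologs at moderate divergence); it is not a replacement
for a production MSA tool at high divergence. Percent identity counts
identical columns over gap-free columns only; the convention matters when
comparing against published "homology" percentages, whose conventions are
frequently unstated, so the package reports its own convention and does not
claim to reproduce any specific published figure.

The common numbering is simply the alignment column index. The delta
profile drops any column gapped in *any* contributing protein, and the
threshold $\bar\Delta$ is the mean of the retained deltas. Columns with
$\Delta_i > \bar\Delta$ (strict, so a flat profile yields no regions) are
merged into runs, tolerating up to `gap_tolerance = 2` unflagged columns
inside a run; runs spanning fewer than `min_length = 3` columns are
discarded. The merging defaults were chosen once so that single-residue
noise spikes cannot form a region while broad multi-residue regions
survive; both are config-exposed. When several thermophiles are supplied
their RMSF is averaged before subtraction (per-thermophile deltas can be
obtained by calling `delta_profile` per pair).

### Interactions

Interaction criteria are distance-only. Salt bridges pair a basic
side-chain group (Lys NZ; Arg NH1/NH2/NE; His ND1/NE2 — His is treated as
potentially basic, protonation being out of scope) with an acidic one
(Asp OD1/OD2; Glu OE1/OE2); hydrogen bonds pair N/O heavy atoms. The
per-frame distance is the minimum over the listed equivalent atoms, which
makes the measure robust to side-chain symmetry. Candidates are searched on
the reference geometry within 6 Å; contact cutoffs are 4.0 Å (salt bridge)
and 3.5 Å (hydrogen bond) — standard heavy-atom literature values, both
config-exposed. No donor–H–acceptor angle is applied: the coarse topology
carries no hydrogens, and occupancy comparisons across homologs are the
point, not absolute bond assignment.

Occupancy is the fraction of frames at or below the cutoff. In the
cross-homolog table an interaction is called formed (SB/HB) at occupancy
≥ 0.1 — a deliberately permissive default for "formed at reasonable
frequency", config-exposed — and NI otherwise. NI is also assigned, with a
note, when the aligned residue cannot chemically form the interaction
(e.g. the basic partner replaced by a methionine) or when the residues fall
in gap columns (flagged, not dropped).

## The synthetic generator

`make_reference_structure` builds a coarse two-atoms-per-residue model: CA
atoms on a wide helix with exact 3.8 Å consecutive spacing (self-avoiding
by construction) and one named side-chain tip atom per residue placed
radially at an approximate side-chain extent. Glycine is excluded from the
synthetic alphabet because the model needs a side-chain heavy atom per
residue. `make_trajectory` adds, per frame, independent Gaussian
displacements with per-residue amplitudes (the planted fluctuation
profile), then overrides planted contact distances by a two-state Bernoulli
draw (moving only the partner atom, so the anchor residue's CA — and hence
its RMSF — is untouched), and finally applies a random rigid-body
rotation/translation so that superposition has real work to do. The
rigid-noise draws are consumed even when disabled, so paired runs with the
same seed share identical thermal noise and differ only by the rigid
motion — the superposition-invariance tests exploit this.

Temperature is metadata only: amplitudes are specified directly as σ rather
than derived from a force constant and kT, because no force-field
parameters are being emulated. Frames are scheduled at
$t = i\cdot\Delta t$, $i = 1..N$ with $N = \text{duration}/\Delta t$, so a
400 ns run saved every 400 ps yields exactly 1,000 frames.

The default study conditions (`default_generator_config`) emulate a
three-homolog comparison: a 130-residue base sequence, one thermophile
identical to it, a second thermophile at substitution rate 0.12, a
mesophile at substitution rate 0.2 with sparse single-residue indels, four
planted high-fluctuation regions in the mesophile (σ = 0.9 Å vs baseline
0.4 Å, a ratio comfortably above the detection floor), planted bridges and
bonds with distinct occupancies — including a Lys→Met replacement in the
mesophile that makes one bridge chemically impossible — 1,000 frames at
400 ps, and rigid-body noise of up to 5° and 1 Å per frame. These values
were fixed once as representative of the emulated study design and are not
tuned per run.

What the generator does **not** emulate: correlated motions, anisotropic
fluctuations, solvent and ions, real side-chain geometry, oligomeric
assemblies. Passing tests therefore demonstrate that the *analysis
machinery* recovers planted structure under realistic noise — not that any
biological conclusion about a particular enzyme follows.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear points; collinearity is detected
  from the singular values of the centred sets (threshold 1e-8 relative).
* Region calling uses strict inequality at the threshold; ties are never
  flagged, so an exactly flat profile yields zero regions.
* PDB coordinates are written at the format's 3-decimal precision; round
  trips are exact in atom identities and to 5e-4 Å in coordinates.
  Alternate locations and insertion codes are rejected rather than
  silently dropped; HETATM records are ignored.
* Multi-model files must have congruent atom counts; the offending model
  index is named in the error.
* The trajectory frame interval is not representable in PDB and is
  supplied via config (default 400 ps).
* A structure whose residues disagree with its FASTA record is a hard
  error before any analysis runs.

## Problem sizes in the shipped checks

The test suite and the acceptance script regenerate everything they
measure. Representative sizes, chosen to give the statistical assertions
adequate power: 300 residues × 5,000 frames for the RMSF closed form;
110 residues × 1,000 frames × 3 proteins × 5 seeds for region recovery;
1,000 frames for occupancy recovery (binomial 3·SE ≈ 0.043 at p = 0.7);
50 random pairs of length ≤ 6 against the exhaustive alignment
enumeration; a 60-residue, 120-frame three-protein set for the end-to-end
determinism check.

## Known limitations

* Progressive profile alignment degrades at high divergence (< ~40%
  identity); the ground-truth recovery guarantee in the tests is for
  substitution rates ≤ 0.3 with sparse indels.
* RMSF is unweighted (no mass weighting) and no B-factor conversion is
  offered.
* Interaction detection has no angular term and no disulfide, π-stacking
  or cation-π categories.
* Secondary-structure annotation of regions is accepted as user input, not
  computed.
* The region-calling threshold (the mean delta) is global; a profile that
  is elevated everywhere yields few regions by construction, since the
  threshold rises with the profile.
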