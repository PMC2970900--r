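---
title: "Coordinate-based re-referencing of protein chemical shifts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based re-referencing of protein chemical shifts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftref)
```

## The problem

A protein NMR chemical shift is a relative quantity: it is computed from an
absolute resonance frequency against a reference frequency. When the
reference is set incorrectly — a non-standard referencing compound, a
spectrometer default carbon base frequency instead of the recommended
gyromagnetic-ratio-derived one — every shift of the affected nucleus in that
entry is offset by one constant. Such systematic offsets are invisible
locally but corrupt any downstream use of archived shift data (secondary
structure and dihedral prediction, shift-based structure determination,
random-coil reference construction).

shiftref estimates that constant per entry and per *nucleus group*, using
the entry's own 3D coordinates, and validates individual shifts with
Z-scores against coordinate-conditional reference distributions.

## The model

Shifts are partitioned into five nucleus groups
g ∈ {H, N, C_ali, C_aro, C_noH}. Carbons are split three ways — aliphatic,
aromatic, proton-less — because different carbon spectra (aliphatic-,
aromatic-optimized, carbonyl) may be referenced independently within one
study; each group carries its own offset.

Each measured shift δᵢ is modeled as

δᵢ = s_α(i) + c_g(i) + εᵢ,  εᵢ ~ N(0, 1/k_α(i))

where α(i) is the shift's *class*: the combination of atom type (residue +
atom name), the parent residue's secondary structure state (α-helix, 3₁₀
helix, π-helix, β-strand, turn, coil), and a solvent-accessibility bin.
The class reference distribution has mean s_α and precision (inverse
variance) k_α, estimated from a large reference population. Conditioning on
solvent accessibility matters because buried atoms have systematically
wider shift distributions than solvent-exposed ones; binning by the
ASA fraction, conditional on secondary structure and atom type, captures
this without an explicit functional model.

With shifts independent within an entry and a flat prior on c_g, the
posterior is Gaussian with precision K = Σ_α n_α k_α:

c̄_g = (Σ_α n_α k_α (δ̄_α − s_α)) / K,  σ_g = K^(−1/2),

where n_α and δ̄_α are the count and mean of the entry's class-α shifts.
Two consequences follow directly from this form and are enforced by tests:
adding a constant Δ to a group's shifts moves c̄_g by exactly Δ and leaves
σ_g untouched; adding zero-mean scatter leaves the expected correction
unchanged and only inflates the error margin (through wider class
variances when the reference is refit).

**Retention.** A correction is *applied* only when |c̄_g| ≥ 3σ_g; the
comparison is `>=`, so a correction sitting exactly at three uncertainties
is retained. Below the threshold the entry's shifts are left unchanged and
the correction is reported as informational. Groups with fewer than 5
shifts are additionally flagged low-confidence (non-destructively): tiny
samples make the Gaussian machinery formally correct but practically
fragile.

**Sign convention.** c_g is the offset *contained in* the measured shifts,
so the corrected value is δᵢ − c̄_g. Reports state both the correction
factor and the applied subtraction to remove any ambiguity.

**Z-scores.** After applying retained corrections,
z = (δ_corr − s_α)·√k_α per shift. Z-scores are computed on applied values
only: when a correction is computed but not retained, the original shift is
standardized, since that is the value a consumer of the entry would use.

## Reference statistics

Within each (atom type, secondary structure) stratum, observations at
exactly zero ASA form their own bin (it may be arbitrarily large: buried
atoms are plentiful); the remaining observations, sorted by ASA, are cut
into consecutive runs of 200; the highest-ASA bin keeps the remainder.
Observations sharing one discretized ASA value are never split across bins
— a class must be a function of the (atom type, SS, ASA) triple or lookup
is ill-defined — so bin sizes can exceed 200 where ties straddle a
boundary; "exactly 200" is the generic distinct-value case. Classes with
fewer than 200 observations, including any undersized final bin, are
excluded from inference entirely.

Class statistics are the sample mean and the inverse *unbiased* (n−1)
variance; at n ≥ 200 the distinction from the maximum-likelihood variance
is negligible, and the unbiased form is the conventional choice.
Zero-variance classes are rejected.

**Iterative build.** Incorrectly referenced entries inflate the reference
variances. The build is therefore self-consistent: pass 1 fits classes from
raw shifts; each later pass computes per-entry corrections against the
current statistics, subtracts the *retained* ones, and refits. Two passes
are the default; the acceptance suite verifies that a zero-offset
population is a fixed point of the second pass and that a third pass moves
corrections by well under their own posterior uncertainty.

**Class granularity.** Classes are per (residue, atom name) by default,
matching the statistics the method was designed around. A coarser
per-atom-name mode exists for synthetic populations, where per-residue
strata would never reach 200 observations; bin-count thresholds are
configurable for the same reason (desk-scale tests use 150 or less where
noted, always stated in the test).

## Structure annotation

**ASA.** Shrake–Rupley quadrature: each heavy atom's sphere (Chothia-style
van der Waals radius + 1.4 Å probe) is sampled at 960 deterministic
golden-spiral points; the reported fraction is unoccluded points / total,
i.e. the exposed fraction of the in-vacuum sphere surface, then discretized
to multiples of 0.43 % (configurable; the granularity mimics the service
the original reference statistics were computed with, but numerical
equivalence with that service is *not* claimed). Quadrature resolution is
~1/960 per point; tests of symmetry and rigid-motion invariance use
tolerances at that scale rather than exact equality. Protons are excluded
from the calculation and inherit the ASA of their bonded heavy atom — NMR
ensembles vary too much in proton placement for per-proton areas to be
meaningful. For multi-model files the first model is the default.

**Secondary structure.** The builtin assigner places amide protons from the
preceding peptide C=O direction, computes the classic electrostatic
hydrogen-bond energy (bond when E < −0.5 kcal/mol), and applies pattern
rules: two consecutive i→i+4 turns → α-helix, i→i+3 → 3₁₀, i→i+5 → π;
bridge patterns → strand; residues covered by an isolated hydrogen-bonded
turn → turn ("turn (any)"); else coil. This is a documented approximation
of the STRIDE/DSSP family, adequate for clean synthetic geometry; for
fidelity to an external assignment the precomputed backend ingests
whitespace-separated (chain, position, letter) rows with H/G/I/E/B/T/C
mapped onto the six states. Residues with incomplete backbone are coil.

**Sequence mapping.** Shift-list numbering and structure numbering are
independent author numberings, reconciled only by global Needleman–Wunsch
alignment (match +1, mismatch −1, linear gap −2 — the classical defaults;
the method's description fixes none). Only identically typed aligned
positions enter the mapping; mismatches and gaps are excluded, so the
mapping is one-to-one and strictly increasing. An aligned identity below
0.8 rejects the pairing outright ("sequences do not correspond"). The DP
implementation is checked against plain-recursion exhaustive enumeration
(≤ 8 residues) and against an independent alignment library at the same
scoring scheme.

## Synthetic data

The generator states a small world and the tests live in it:

* `default_refdb_layout()`: seven atom types (amide/alpha protons, amide
  nitrogen, CA/CB, an aromatic ring carbon, carbonyl), three secondary
  structure states, two ASA bins, 200 observations per class. Means and
  widths are round numbers in the ranges seen for folded proteins (e.g.
  amide proton 8.3 ± 0.65 ppm, CA 56 ± 2.2 ppm, amide nitrogen 119 ± 4
  ppm); exposed-bin widths are 0.8× the buried ones, reflecting the
  narrower distributions of exposed atoms.
* `make_entry()` simulates the model forward: class mean + group offset +
  N(0, (noise_scale/√k)²). `noise_scale = 1` is the model-matched case used
  for calibration tests; 0 gives exact recovery; > 1 emulates the
  random-scatter robustness scenario. The characteristic test offset is
  2 ppm on aliphatic carbons — the magnitude of the well-known
  spectrometer-default carbon referencing discrepancy.
* Stability experiments delete 10–90 % of shifts at random and count
  spuriously retained corrections; at desk scale 1000 samples per fraction
  (not the archive-scale 10,000) keep the suite inside its time budget,
  stated in the test.

What a green suite does **not** establish: agreement with archive-scale
statistics, behaviour on real (ring-current-shifted, paramagnetic,
exchange-broadened) data, or equivalence with the external ASA/SS programs.
The synthetic world has no assignment errors, no missing heavy atoms and
Gaussian classes by construction.

## Numerical choices and degenerate inputs

* The closed-form posterior is the only runtime path; trapezoidal
  integration of the likelihood product exists solely as a test oracle
  (agreement to 1e−6 relative on ~200 random inputs).
* Empty groups report c̄ = 0, infinite uncertainty, `retained = FALSE`.
* Bin lookup: half-open [low, high) intervals, last bin closed; exact ASA 0
  goes to the zero bin when one exists; out-of-range values clamp to the
  nearest bin (a discretized value can otherwise fall below the first
  build-set value).
* Duplicate (chain, position, atom) shift rows are rejected by default
  (`last`-wins is opt-in); altloc ties resolve to the first-encountered
  highest occupancy.
* Reference databases serialize with C99 hex floats and round-trip
  bit-exactly.

## Open design points decided here

* Proton-less aromatic ring carbons (PHE/TYR/TRP CG, TYR CZ, TRP CD2/CE2)
  are grouped as aromatic, not proton-less: the group exists because
  referencing errors track spectrum type, and ring carbons appear in
  aromatic-optimized spectra. Histidine ring carbons are treated as
  aromatic for the same reason. Both choices are table-driven
  (`inst/extdata/residue_topology.tsv`) and changeable without code edits.
* Whether Z-scores should use unapplied corrections was open; here they use
  applied values only (see above).
* ASA bins are built globally per stratum across the pooled population, and
  ties are kept within one bin, as discussed.

## Limitations

Single-chain mapping only (the residue mapping keys on sequence position);
non-standard residues and nucleic acids are skipped at parse time;
the builtin secondary-structure assigner is an approximation; archive-scale
reference statistics are out of scope — the package builds real reference
databases from user-supplied annotated populations, but ships none.
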