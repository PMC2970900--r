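# shiftref

Coordinate-based correction ("re-referencing") and validation of protein
NMR chemical shifts.

## Why

Chemical shifts are measured relative to a reference frequency. When that
reference is set incorrectly — a common deposition problem, e.g. the ~2 ppm
discrepancy between a spectrometer's default carbon base frequency and the
recommended γ-ratio-derived one — *every* shift of the affected nucleus in
the entry is offset by one constant. shiftref is for people who consume
archived shift data (shift-based structure/dihedral prediction, random-coil
references, validation pipelines) and need entries on a common reference,
with an honest error bar on each correction.

## The method

Shifts are split into five nucleus groups g ∈ {H, N, C_ali, C_aro, C_noH}
(carbons three ways, because aliphatic-, aromatic- and carbonyl-optimized
spectra may be referenced independently). Each shift is modeled against a
class-conditional Gaussian reference,

δᵢ = s_α(i) + c_g(i) + εᵢ,  εᵢ ~ N(0, k_α(i)⁻¹),

where the class α = (atom type, secondary-structure state, solvent-
accessibility bin) has mean s_α and precision k_α estimated from a large
reference population (interior ASA bins hold 200 observations; smaller
classes are excluded). Under a flat prior the posterior for the group
offset is Gaussian:

c̄_g = (Σ_α n_α k_α (δ̄_α − s_α)) / K,  σ_g = K^(−1/2),  K = Σ_α n_α k_α.

A correction is applied only when |c̄_g| ≥ 3σ_g (corrected = original −
c̄_g); each shift then gets a Z-score z = (δ_corr − s_α)√k_α to flag
individual outliers. Structure annotation is built in: Shrake–Rupley ASA
fractions (960-point quadrature, 1.4 Å probe, discretized to 0.43 % steps),
hydrogen-bond-pattern secondary structure (six states), and
Needleman–Wunsch mapping of shift-list numbering onto structure numbering.

## Worked example

Simulate an entry carrying a +2 ppm aliphatic-carbon referencing error and
recover it:

```r
library(shiftref)
db <- make_refdb()                                   # synthetic reference
e  <- make_entry(db, n_shifts = 300,
                 offsets = c(C_ali = 2), seed = 42)  # +2 ppm on C_ali
corr <- group_corrections(e$classified)
print(corr, digits = 3)
#>   group mean_ppm uncertainty_ppm total_precision n_shifts_used retained
#> 1     H -0.03766          0.0447          500.99           106    FALSE
#> 2     N -1.00980          0.5453            3.36            42    FALSE
#> 3 C_ali  1.61643          0.1970           25.76            75     TRUE
#> 4 C_aro  0.00759          0.1912           27.36            39    FALSE
#> 5 C_noH  0.05910          0.1885           28.14            38    FALSE
```

Only the aliphatic-carbon correction clears the 3σ retention rule
(1.62 ≥ 3 × 0.20); the injected offset lies within two uncertainties of the
estimate, and the other groups — including the noisy nitrogen at 1.9σ —
are correctly left alone. Applying the correction and standardizing:

```r
zs <- zscore_shifts(e$classified, corr)
head(zs[, c("seq_pos", "residue_type", "atom_name", "group",
            "value_ppm", "corrected_ppm", "z")], 4)
#>   seq_pos residue_type atom_name group value_ppm corrected_ppm       z
#> 1       1          ALA         N     N   118.554       118.554 -0.2615
#> 2       2          ALA         C C_noH   178.634       178.634  0.4106
#> 3       3          ALA         H     H     8.572         8.572 -0.5046
#> 4       4          ALA        CA C_ali    58.287        56.670  0.6650
```

C_ali shifts are reduced by the retained correction; Z-scores are ~N(0, 1)
for in-class shifts (here 1 of 300 exceeds |z| > 3).

Real data go through `run_entry(shifts, structure, refdb, out = ...)`
(TSV or NMR-STAR shift lists, PDB coordinates, a reference-database file
built with `iterative_build()`), or the command line:

```sh
shiftref run --shifts entry.tsv --structure entry.pdb \
             --refdb refdb.tsv --model 0 --out report.txt
shiftref stability --entry entry.tsv --structure entry.pdb --refdb refdb.tsv \
                   --fractions 0.1:0.9:0.1 --samples 1000 --seed 42
shiftref synth refdb|entry|structure ...
```

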