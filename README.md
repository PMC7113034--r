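# densamp

Per-atom amplitude analysis of time-resolved crystallographic
difference electron-density maps.

## The problem

Time-resolved serial crystallography (TR-SFX and Laue methods) yields,
for each pump-probe delay Δt, a difference Fourier map
FT[(F<sub>obs</sub><sup>light</sup> − F<sub>obs</sub><sup>dark</sup>)·exp(iΦ)]:
positive density marks atoms arriving, negative density marks atoms
leaving. When the photo-response spreads through the whole protein —
photocycle intermediates in a light-driven pump, or quake-like
sub-picosecond motions radiating from a chromophore — a stack of 3D
maps is hard to grasp, and manually reading peak heights residue by
residue is subjective and does not scale. `densamp` is for
crystallographers who need an objective, whole-protein, time-resolved
summary of such map series and a quantitative bridge between maps and
refined models.

## The method

The central reduction maps each 3D difference map to a dual-valued
per-atom amplitude function. For every atom *a<sub>i</sub>* of the
resting model:

1. interpolate the map (trilinear, periodic in the unit cell) on a
   0.5 Å lattice restricted to a sphere of radius 2.0 Å about the
   atom (257 points at the defaults; both parameters tunable);
2. zero every sample with |ρ| below a floor, by default 3σ, where σ is
   the root-mean-square density of the cell;
3. average surviving positive and surviving negative samples
   separately:

   A(a<sub>i</sub>) = ( mean ρ<sup>+</sup>, mean ρ<sup>−</sup> ).

Plotting A(a<sub>i</sub>) against atom number gives a 1D fingerprint
of the map. On top of this reduction the package provides

- **Pearson correlation matrices** ρ(A<sub>j</sub>(a), A<sub>k</sub>(a))
  between time points (on the concatenated 2N vector of both
  branches), and greedy segmentation into **highly correlated blocks**
  (mean pairwise ρ ≥ threshold) that delimit structural intermediates;
- **linear decomposition** M ≈ W·P of a profile series into k signed
  density patterns with nonnegative population curves (ALS with NNLS,
  separability-based initialization);
- **concentric-shell amplitudes** around an epicentre, computed as
  conserving differences of sphere sums, to follow perturbations
  propagating outward;
- **theoretical difference maps** from a resting/photo-activated
  structure pair (Cromer–Mann structure factors, FFT synthesis) with
  **dummy-water relative scaling** across a series, and rectangular
  experiment-vs-model cross-correlation matrices;
- seeded **synthetic generators** (Gaussian-blob maps, sequential
  A→B→C kinetics, toy poly-alanine structures) with known ground
  truth.

I/O: CCP4/MRC (MRC2014) volumes, PDB coordinate files (altloc,
occupancy and B-factor aware), CSV/JSON exports.

## Worked example

A synthetic 13-point photocycle (sequential A→B→C kinetics, rates
2×10⁶ and 2×10³ s⁻¹, delays 16 ns – 1.725 ms, 5% voxel noise),
profiled at the planted feature sites:

```r
library(densamp)
comps <- list(
  list(blobSpec(c(10, 10, 10), 5, 1.2), blobSpec(c(12, 10, 10), -4, 1.0)),
  list(blobSpec(c(20, 20, 20), 4, 1.3), blobSpec(c(22, 20, 20), -5, 1.1)),
  list(blobSpec(c(30, 28, 12), 6, 1.2), blobSpec(c(28, 28, 12), -3, 1.2)))
times <- 10^seq(log10(16e-9), log10(1.725e-3), length.out = 13)
tr  <- kineticTruth(comps, rates = c(2e6, 2e3), times = times,
                    noiseSd = 0.25, seed = 5)
ser <- makeKineticSeries(tr)

ctrs  <- do.call(rbind, lapply(comps, function(cl)
  t(vapply(cl, `[[`, numeric(3), "center"))))
atoms <- data.frame(serial = 1:6, name = "C", element = "C", altloc = "",
                    resname = "ALA", chain = "A", resno = 1:6,
                    occupancy = 1, b = 20, x = ctrs[, 1], y = ctrs[, 2],
                    z = ctrs[, 3], hetero = FALSE, dummy = FALSE)
profs <- lapply(seq_along(ser$maps), function(j)
  amplitudeProfile(ser$maps[[j]], atoms, extractionParams(nSigma = 0),
                   delay = ser$delays[j], label = ser$labels[j]))

profs[[5]]
#> AmplitudeProfile [761.5 ns]: 6 atoms, sigma 0.2545, max pos 1.309, min neg -1.194
#> ExtractionParams: radius 2.00 A, mesh 0.50 A, floor 0.0 sigma

cm <- correlationMatrix(profs)
round(corValues(cm)[1:4, 1:4], 3)
#>          16 ns 42.03 ns 110.4 ns 289.9 ns
#> 16 ns    1.000    0.999    0.989    0.874
#> 42.03 ns 0.999    1.000    0.991    0.883
#> 110.4 ns 0.989    0.991    1.000    0.934
#> 289.9 ns 0.874    0.883    0.934    1.000

findBlocks(cm, threshold = 0.85)
#> BlockPartition: 3 blocks, threshold 0.85
#>   [1..4] (4)
#>   [5..12] (8)
#>   [13..13] (1)

decomposeProfiles(profs, k = 3, seed = 1)
#> DecompositionResult: k=3, residual 0.0376, seed 1
```

Early and late delays fall into separate high-correlation blocks — the
fingerprint of distinct intermediates — and the three-component
decomposition reconstructs the series to within the injected noise
(relative residual 0.038), with population curves matching the planted
kinetics (correlation > 0.99 after permutation matching; asserted in
the test suite).

A thin command-line wrapper over the same functions ships at
`system.file("scripts", "densamp.R", package = "densamp")` with
subcommands `simulate`, `profile`, `sweep`, `correlate`, `decompose`,
`theomap` and `compare`.

## The methods vignette

`vignettes/densamp-methods.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the
conventions (σ definition, strict floor, dual-value reductions,
block-search and exclusion semantics, decomposition identifiability),
what the synthetic generator does and does not emulate, and known
limitations (P1 only, no bulk solvent, isotropic B).
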