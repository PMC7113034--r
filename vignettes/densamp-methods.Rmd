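---
title: "Methods: per-atom amplitude analysis of difference density maps"
author: "densamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-atom amplitude analysis of difference density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densamp)
```

## The problem

Time-resolved serial crystallography delivers, per pump-probe delay, a
three-dimensional difference Fourier electron-density map: positive
features mark density gained relative to the resting state, negative
features mark density lost. When structural changes are not confined to
one active site — photocycle intermediates spreading through a proton
pump, or quake-like sub-picosecond motions radiating from a chromophore
— inspecting a stack of 3D maps by eye does not scale. `densamp`
reduces each map to a one-dimensional, per-atom summary that can be
plotted, correlated across a time series, segmented into intermediates
and compared against refined structural models.

## The dual-valued amplitude A(a_i)

For every atom $a_i$ of the resting-state model (in file order, which
is the canonical x axis of all profiles):

1. sample the map on a cubic lattice of spacing `mesh` restricted to a
   sphere of radius `radius` centred on the atom (boundary inclusive,
   origin included; at the defaults 2.0 Å / 0.5 Å this is 257 points),
   using trilinear interpolation with periodic unit-cell wrapping;
2. set every sample with $|\rho| <$ `floor` to zero (strictly below:
   a sample exactly at the floor survives);
3. average the surviving positive and the surviving negative samples
   *separately*.

The result is the dual-valued amplitude
$A(a_i) = (A^+_i, A^-_i)$ with $A^+_i \ge 0$ and $A^-_i \le 0$; an
empty surviving set yields 0 for that branch. Storing the negative
branch signed keeps plots mirror-symmetric about zero.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `radius` | 2.0 Å | sphere radius; roughly the map resolution. Too small loses positive features displaced from the atom; too large overlaps neighbouring spheres and raises the baseline. |
| `mesh` | 0.5 Å | sampling spacing inside the sphere. |
| `nSigma` | 3.0 | floor in units of the map σ. Lower floors admit noise into the baseline; higher floors discard signal. |
| `floorAbs` | `NA` | absolute floor override; required for theoretical maps (below). |
| `faithful` | `FALSE` | resample the map onto a 0.25 Å Cartesian grid before sphere interpolation, reproducing the classical two-step CCP4 workflow. |

σ is the *literal root-mean-square* density of the full cell,
`sqrt(mean(v^2))`, with no mean subtraction: difference maps have
near-zero mean, so the distinction from the centred convention
(`mapSd`) is negligible in practice, but both are exposed because the
choice is a convention, not a fact of the data. Sigma is a cell
property: maps that do not cover exactly one full unit cell are
refused rather than silently wrapped, and symmetry expansion (e.g. with
CCP4 `mapmask`) is expected upstream — only P1 periodic semantics are
implemented.

The default extraction interpolates straight off the native map grid.
The historical workflow regridded to a fine Cartesian mesh first; the
`faithful` flag reproduces it, at the cost of one extra interpolation
(which only smooths — the difference is bounded by the interpolation
error, below 1% of peak for features wider than ~1.8 Å sampled at
0.3 Å or finer).

### Atom universe

Profiles default to every non-hydrogen `ATOM` and `HETATM` record —
cofactors, structured waters and lipids included, because density
changes on a chromophore or an internal water are exactly what the
method should surface. Hydrogens are excluded (deposited models lack
them). When a deposition carries alternate conformers, the resting
conformer "A" defines the profile centres. All of this is overridable
in `selectAtoms()`.

## Time-series analyses

**Correlation.** Two profiles are compared by the Pearson correlation
of their concatenated $2N$ vectors $[A^+; A^-]$. The paper-style
dual-valued function does not dictate how the two branches enter the
correlation; concatenation uses all information and keeps signs
meaningful, and single-channel modes (`channel = "pos"/"neg"`) exist
for sensitivity checks. Note that a profile derived from the negated
map has its channels *swapped* ($A^+ \leftrightarrow -A^-$), an exact
symmetry the tests assert; because the dual value is sign-constrained,
elementwise negation of a valid profile is not itself a valid profile.

**Blocks.** A square correlation matrix over a (log-spaced) time
series is segmented into contiguous runs whose mean off-diagonal
pairwise correlation meets a threshold (0.85–0.90 in typical use),
interpreted as the reign of one structural intermediate. The search is
greedy left-to-right and maximal: from each start the farthest
admissible end is taken. A noisy time point can be listed as
`excluded`; it is ignored in the means, and — because the physical
reading is that the intermediate persists across it — an excluded
index interior to a block's span is absorbed into that block
(`absorbExcluded = FALSE` makes it a singleton instead).

**Decomposition.** The $2N \times T$ profile matrix is factorized as
$M \approx W P$ with $k$ unconstrained signed density patterns $W$
(unit Euclidean norm) and nonnegative populations $P$, by alternating
least squares (nonnegative step via Lawson–Hanson NNLS, max 500
iterations, convergence at relative residual change $< 10^{-8}$).
This factorization is *not unique*: any nonnegative remixing of the
population rows achieves the same residual. Physical series, however,
pass close to each pure state ("smoothly varying populations"), so the
primary initialization picks the $k$ most mutually novel time columns
by successive projection — a separability argument standard in
spectral unmixing — and ALS then settles at that vertex of the
zero-residual set. An SVD start and 10 seeded random restarts guard
against poor local minima; a restart replaces the incumbent only when
it improves the residual by more than `max(1e-9, 1e-6 * residual)`, so
that numerically tied zero-residual solutions do not displace the
separability-anchored one. Fitting explicit kinetic schemes to the
recovered populations is out of scope.

**Shells.** Propagation away from an epicentre (e.g. the Schiff-base
nitrogen of a retinal protein) is followed through concentric shells:
the shell amplitude between radii $r_\mathrm{in} < r_\mathrm{out}$ is
computed as a *difference of sphere sums* (positive sum and count at
the outer radius minus the inner, after flooring) and then averaged.
Membership is $r_\mathrm{in} < \lVert o\rVert \le r_\mathrm{out}$,
with the origin sample assigned to the innermost shell, so
$r_\mathrm{in} = 0$ reduces exactly to the sphere amplitude and shell
sums over any partition of $[0, R]$ reproduce the full-sphere sums.
The alternative reading — averaging per-shell atom values — is not the
implemented semantics; difference-of-sums is, because only it
conserves.

**Region averages.** For Figs-style region time courses the dual value
is reduced per atom to $(A^+ + |A^-|)/2$ (flag `reduce = "concat"`
averages over the $2N$ absolute values instead — the reduction of a
dual value to a scalar $|A|$ is a convention), averaged over the
region's atoms, and normalized either at a single reference time point
(unity at the last delay) or by the mean over a reference window.

## Theoretical difference maps

Given a resting model and a photo-activated conformer rewritten to
full occupancy (`extractConformer`), structure factors are computed by
direct summation with Cromer–Mann 4-Gaussian form factors, isotropic
Debye–Waller factors $\exp(-Bs^2/4)$ and occupancy weights, over the
full Friedel sphere to `dmin`; the difference density is synthesized
by FFT on a grid of spacing `dmin/3` by default. No bulk-solvent model
is applied, and anisotropic displacement records are ignored. Only P1
cells are accepted — models in other space groups must be expanded to
P1 upstream; general Hermann–Mauguin operator expansion is a known
limitation, acceptable because the synthetic pipeline is P1
throughout.

Theoretical maps are noise-free, so their σ has a different physical
meaning (it scales with how much of the model moved) and the default
3σ floor would be wrong; the floor is therefore a required explicit
parameter (`floorAbs`, typically 0) when profiling them.

**Dummy-water scaling.** To put a *series* of theoretical maps on one
scale, a handful of dummy water oxygens (occupancy 1, B = 30 Å²,
≥ 3.5 Å from any protein atom — "outside the protein" is enforced) are
added to the excited models only. Each map is then rescaled so the
mean sphere amplitude (radius 2 Å, floor 0) at the dummy sites matches
the reference map's. Because rescaling is a single global factor per
map, Pearson correlations between profiles are unchanged — asserted as
a test.

## The synthetic generator

Tests and the acceptance script run on seeded synthetic data with
known ground truth, emulating the study conditions at desk scale:

- **Maps:** full-cell P1 grids (default 40 Å cube, 0.5 Å spacing) of
  isotropic Gaussian blobs with signed amplitudes — the paired
  positive/negative features of real difference maps — summed over
  periodic images within $4w$, plus i.i.d. Gaussian voxel noise.
- **Kinetics:** a sequential three-state first-order scheme
  A → B → C (closed-form two-exponential populations, verified against
  numerical integration of the rate equations) with rates
  $2\times10^6$ and $2\times10^3\,\mathrm{s}^{-1}$ over 13 log-spaced
  delays from 16 ns to 1.725 ms — the sampling regime of a
  nanosecond-to-millisecond pump-probe series. The 5%-of-peak noise
  level (sd 0.25 against blob amplitudes 4–6) represents a
  well-measured difference map.
- **Structures:** ideal poly-alanine helices (100°/1.5 Å per residue)
  placed in the cell with ≥ 5 Å boundary clearance.

What the generator does *not* emulate: spatially correlated map noise,
solvent contributions, symmetry-related clutter, anisotropic features,
and model error. Passing tests therefore demonstrate the correctness
of the reduction and analyses, not detector-level realism.

## Numerical choices

- Sphere membership is boundary-inclusive ($\lVert o\rVert \le r$,
  with a $10^{-12}$ lattice-unit guard against float droop); the count
  257 at (2.0, 0.5) follows from this choice.
- The floor comparison is strict (`|v| < floor` is zeroed; equality
  survives).
- Map values are stored as 32-bit floats on disk (the format's
  precision); the first write quantizes, after which round trips are
  bit-exact. In memory everything is double precision, and the profile
  code reduces each atom through the identical code path as the
  single-atom call, so the two agree bit-for-bit.
- Shell/sphere conservation holds to the last floating-point ulp
  (asserted at $10^{-12}$ relative); counts are integer-exact.
- Degenerate inputs error early and explicitly: non-full-cell maps,
  empty selections, zero-variance profiles, zero normalization
  references, $k > T$, reflection-set mismatches, dummy waters inside
  the protein.
- Problem sizes in the test-suite and acceptance runs: 40³–80³ voxel
  grids, 6–60 atoms, 13 time points, resolution limits 1.5–2 Å —
  chosen so every stage (including the 50-map brute-force oracle
  comparison) completes in seconds while exercising the same code
  paths as protein-scale inputs.

## Worked example

```{r example}
# a 13-point synthetic photocycle and its planted truth
comps <- list(
  list(blobSpec(c(10, 10, 10), 5, 1.2), blobSpec(c(12, 10, 10), -4, 1.0)),
  list(blobSpec(c(20, 20, 20), 4, 1.3), blobSpec(c(22, 20, 20), -5, 1.1)),
  list(blobSpec(c(30, 28, 12), 6, 1.2), blobSpec(c(28, 28, 12), -3, 1.2)))
times <- 10^seq(log10(16e-9), log10(1.725e-3), length.out = 13)
tr <- kineticTruth(comps, rates = c(2e6, 2e3), times = times,
                   noiseSd = 0.25, seed = 5)
ser <- makeKineticSeries(tr)

# profile every map at the planted feature sites
ctrs <- do.call(rbind, lapply(comps, function(cl)
  t(vapply(cl, `[[`, numeric(3), "center"))))
atoms <- data.frame(serial = seq_len(nrow(ctrs)), name = "C",
                    element = "C", altloc = "", resname = "ALA",
                    chain = "A", resno = seq_len(nrow(ctrs)),
                    occupancy = 1, b = 20, x = ctrs[, 1], y = ctrs[, 2],
                    z = ctrs[, 3], hetero = FALSE, dummy = FALSE)
profs <- lapply(seq_along(ser$maps), function(j)
  amplitudeProfile(ser$maps[[j]], atoms, extractionParams(nSigma = 0),
                   delay = ser$delays[j], label = ser$labels[j]))

cm <- correlationMatrix(profs)
findBlocks(cm, threshold = 0.85)
decomposeProfiles(profs, k = 3, seed = 1)
```

## Known limitations

- P1 only, for both map periodicity and structure factors; other space
  groups require upstream expansion.
- No bulk-solvent or anisotropic-B modelling in theoretical maps.
- The decomposition's identifiability rests on near-pure time points;
  series that never approach a pure state can return a remixed but
  equally well-fitting solution (the residual is still meaningful).
- Region reduction of the dual value to a scalar is a convention with
  two offered variants; results near zero amplitude depend on it.
```
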