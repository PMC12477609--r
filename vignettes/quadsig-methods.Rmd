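---
title: "Methods: G-quadruplex folding signatures from single UV spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: G-quadruplex folding signatures from single UV spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadsig)
```

## The problem

G-rich DNA folds into G-quadruplexes (G4s): stacks of G-tetrads coordinating
K^+^ or Na^+^. A single sequence can adopt many conformers — parallel,
antiparallel, hybrid, even left-handed (Z) topologies — and telling them
apart normally requires circular dichroism (CD), NMR, or difference
spectroscopy that needs a measured unfolded reference (thermal or isothermal
difference spectra). Obtaining a genuinely unfolded reference is the weak
point: stable G4s retain cations through desalting, so the "unfolded"
spectrum is contaminated by residual folding and the difference signature
is attenuated.

quadsig implements the *Eps2Fold* idea: replace the measured unfolded
reference with an unfolded-state spectrum **calculated from sequence**, so a
single folded-state UV absorbance measurement suffices. The signature

$$\Delta\varepsilon(\lambda) \;=\; \varepsilon^{\mathrm{calc}}_{\mathrm{unfolded}}(\lambda) \;-\; \varepsilon^{\mathrm{meas}}_{\mathrm{folded}}(\lambda)$$

is conformation-dependent and, after principal component analysis against a
reference panel, supports topology assignment comparable to CD.

## The nearest-neighbor extinction model

Unfolded single-strand extinction at 260 nm uses the classic
nearest-neighbor formula: the sum of the 16 dinucleotide coefficients along
the sequence minus the sum of the interior monomer coefficients
(`eps260_classic()`). The equivalent pure doublet-sum form
(`eps260_nn()`) writes

$$\varepsilon_{260} = \sum_{i,j \in \{A,C,G,T,E\}} N_{ij}\,\varepsilon_{ij},$$

where `E` marks the sequence termini: a sequence of $N_b$ bases contributes
$N_b-1$ internal doublets plus one 5′ `E`-doublet and one 3′ `E`-doublet,
$N_b+1$ in total. `build_table_from_classic()` bridges the two
parameterizations with
$\varepsilon'_{ij} = \varepsilon_{ij} - (\varepsilon_i+\varepsilon_j)/2$
for internal doublets and $\varepsilon'_{E i} = \varepsilon'_{iE} =
\varepsilon_i/2$ for terminal ones; the identity is algebraic and the test
suite checks it exactly on 1000 random sequences of length 2–50.

The full spectrum scales $\varepsilon_{260}$ by doublet-specific,
dimensionless ratio curves $R_{ij}(\lambda)$, weighted by doublet fractions:

$$\varepsilon_\lambda = \varepsilon_{260} \sum_{i,j}
  \frac{N_{ij}}{N_b+1}\, R_{ij}(\lambda).$$

Because every $R_{ij}(260) = 1$ and $\sum_{ij} N_{ij} = N_b+1$, the value
at 260 nm reduces to $\varepsilon_{260}$. The implementation preserves this
identity *exactly* in floating point by summing the integer-weighted ratios
first and dividing by $N_b+1$ once.

### The packaged parameter table

`default_nn_table()` ships a self-contained table
(`inst/extdata/nn_table_synthetic.tsv`, one row per doublet: label,
$\varepsilon_{260}$, then one column per nm from 220–350). Its 260 nm
values are the published classic monomer/doublet coefficients
(`classic_dna_extinctions()`). Its ratio curves are **synthetic**: Gaussian
band models of the four deoxynucleotide absorption spectra (main maxima at
258 nm for A, 270 nm for C, 253 nm with a 275 nm shoulder for G, 266 nm for
T), averaged per doublet and normalized to 1 at 260 nm. They reproduce the
qualitative shape of single-strand DNA spectra and keep every calculated
spectrum strictly positive, but they are a constructed stand-in, not fitted
experimental curves. Any experimentally derived table in the same layout
drops in via `read_nn_table()`; validation renormalizes each curve so
$R(260)=1$ (warning above 1 % deviation), which guarantees the 260 nm
identity for arbitrary input tables.

## Spectrum handling

Spectra are tibbles (`wavelength`, `value`) with a unit tag and metadata
(pathlength $l$ in cm, strand concentration $C$ in M, analyte, salt).
Conversions are the standard ones: $\varepsilon = A/(lC)$ for absorbance
and $\Delta\varepsilon = \theta/(32980\,l\,C)$ for CD ellipticities, with
$\theta$ in millidegrees (the constant corresponds to standard
spectropolarimeter output). Unit tags are checked on every conversion and
subtraction; mismatched grids must be `resample()`d explicitly (linear,
node-exact, no extrapolation) — this matters in practice because CD is
typically acquired at 0.5 nm pitch and UV at 1 nm.

Baseline correction subtracts the mean over 320–350 nm, a region where
nucleic acids do not absorb. The window is a convention of this package
(configurable), not a published prescription. Strand concentration should
be measured on cation-free samples; `estimate_concentration()` offers
$C = A_{260}/(\varepsilon_{260} l)$ with the nearest-neighbor
$\varepsilon_{260}$ as a clearly-flagged convenience estimate.

Signatures stay in molar units with **no further normalization by
default**; `normalize_signature()` ([−1, 1] or unit variance) exists but is
off everywhere, since molar units already remove concentration and
pathlength effects and additional normalization does not improve class
resolution. Analysis restricts to 220–310 nm by default (the chemometrics
range); the full 220–350 nm data are retained when `range = NULL`.

## Structural descriptors and the reference panel

`load_reference_panel()` returns the bundled 30-entry panel of G4-forming
oligonucleotides of known structure. Each entry carries seven descriptors:
topology, conformer, groove widths (4 characters over w/n/m), tetrad–loop
progression, groove-type combination group (I–VIII, Z), tetrad handedness,
the per-guanine glycosidic (GBA) string (s = syn, a = anti, 5′→3′ per
tract, brackets for capping guanines), and the GBA-stack composition
(counts of `aa`, `as`, `sa`, `ss` core stacks and annotated interface
stacks such as `aa^5/6r`).

`stacks_from_gba()` derives stack counts from a GBA string: within each
tract every adjacent letter pair is one stack, the first letter being the
5′ partner. Two deliberate policies:

* **Ambiguity refuses rather than guesses.** A bracketed capping guanine
  attaches to the adjacent tract end only when that attachment is
  unambiguous (single letter, one adjacent tract). Multi-letter or dashed
  groups, or groups flanked by two adjacent tracts, raise an error that
  points to the explicit stack string — which the panel stores verbatim
  and which is authoritative (the one bracketed panel entry, 6GZN, is
  handled this way).
* **Unit interfaces are first-class.** The left-handed Z-G4's four-tetrad
  core is two stacked 2-tetrad units; the step between tetrads 2 and 3 of
  each tract is a unit-interface stack with opposite tetrad polarity, not
  a core stack. `interface_after = 2` marks it, turning the naive 12
  `aa` derivation into the correct `8aa·4aa^5/6r`. On load, the panel
  checks that derivation reproduces the printed stack string for all 29
  bracket-free entries.

Tetrad handedness, loop progression and groove combination are validated
annotations, not quantities computed from coordinates — deriving them from
structure is out of scope.

## Stacking geometry

`chi_torsion()` computes the glycosidic dihedral O4′–C1′–N9–C4;
`classify_gba()` assigns syn for $\chi \in (-90°, +90°]$ and anti
otherwise. The boundary value −90° is assigned anti by the open interval —
an arbitrary but deterministic choice at a physically unpopulated boundary.

`twist_angle()` defines the apparent inter-guanine twist as follows: the
stacking axis is the unit normal of the least-squares plane through the
lower guanine's nine ring atoms, oriented toward the upper guanine's ring
centroid; the twist is the signed angle (right-hand rule about that axis)
between the projections of the two C1′→N9 vectors onto the plane
perpendicular to the axis. Right-handed parallel cores give positive
twists, left-handed (Z) cores negative ones. Published structure archives
do not fix a unique convention for this quantity, so the definition above
is validated two ways: synthetically constructed stacked pairs
(`generate_stack_fixture()`) recover their prescribed rotation to 10⁻⁶
degrees, and the sign convention matches the published per-class values
(core `sa` near +48°, Z-core `aa` near −23°) when run on deposited
coordinates. One consequence of the axis re-orientation rule is that the
apparent twist is *symmetric* under swapping the two residues — the axis
sign flip compensates the reversed vector order — as expected for an
apparent helical twist viewed from either end.

Overlap classes are assigned by lookup from the GBA pair and context
(`aa`/`ss` same-direction → "same 5/6-ring", `sa` → "5-ring", `as` →
"partial 6-ring"; opposite-direction interface `aa` carries an explicit
annotation among 5/6r, 6r, 5r, p6r), not by integrating projected ring
areas. `ensemble_twist_summary()` uses **all** deposited models of an NMR
ensemble, unweighted, with sample (n−1) standard deviations; single-model
structures report sd as absent rather than zero.

## Chemometrics

`fit_pca()` centers and, by default, standardizes wavelengths
(unit-variance scaling, the default of the common PCA front-ends in this
field); covariance PCA is one switch away because published
explained-variance figures do not always state which mode was used, and
the reproduction script reports both. Component signs are arbitrary in
PCA, so they are fixed deterministically (largest-magnitude loading made
positive) to make scores and plots reproducible. Constant wavelengths with
scaling on raise an error naming the wavelength rather than producing
NaNs.

Conformation prediction is defined in this package as k-nearest-neighbor
voting on PC scores: project the query (`project()`), vote among the `k`
(default 3) nearest reference samples in the first `n_pc` (default 2)
score dimensions with Euclidean distance, break ties by smallest mean
neighbor distance and then lexicographically, and return the full ranked
distance table. The defaults reflect that only PC1/PC2 are interpreted;
both are tunable.

## The synthetic generator

`default_templates()` encodes the class-dependent band structure of the
folding signatures as Gaussian mixtures: every class has a positive band
at 245 nm and a negative band at 295 nm; the parallel template adds the
class-specific negative band at 265 nm (absent — near zero — in the
antiparallel template); the hybrid template sits between the two with a
shallow negative shoulder near 275 nm. Band *positions and signs* emulate
the observed signatures. Band *amplitudes* are free generator parameters:
the defaults give extrema of about 4×10⁴ M⁻¹cm⁻¹, the Δε scale expected
for ~20-mer oligonucleotides whose ε₂₆₀ is of order 2×10⁵ M⁻¹cm⁻¹. The
default noise sd is 2000 M⁻¹cm⁻¹ (5 % of the dominant band amplitude).
These choices were fixed once, before the downstream classification tests
were run, and are not tuned.

`generate_folded_uv()` inverts the signature definition (folded =
calculated unfolded − signature), guaranteeing the end-to-end round trip:
at zero noise `eps2fold()` returns the template bit-for-bit; with noise
the residual equals the injected noise realization exactly. Oversized
amplitudes that would imply negative extinction raise an error against the
noise-free template (measurement-like noise may still produce small
negative folded values at long wavelengths where absorption vanishes, as
real baseline-subtracted data do).

What the generator does **not** emulate: exciton coupling and the true
quantum-mechanical dependence of absorption on stacking geometry,
correlated (non-white) instrument noise, baseline drift, conformer
mixtures, and the real amplitude differences between conformers within a
topology class. Passing the synthetic classification tests therefore
demonstrates that the pipeline (signature → PCA → k-NN) is correct and
deterministic, not that real conformers are separable at any given noise
level — that evidence comes from the reproduction suite on deposited
spectra (`scripts/reference-repro.R`), which requires externally obtained
data.

## Numerical choices, sizes, determinism

* Ratio interpolation is linear; the packaged grid is 1 nm, where
  higher-order interpolation is immaterial.
* All generators take explicit seeds and restore the caller's RNG state;
  identical seeds give bit-identical output.
* Group summaries use sample (n−1) standard deviations (group sizes are
  small); singleton groups report sd = 0 with a warning.
* Test problem sizes: 1000 random sequences (length 2–50) for the
  nearest-neighbor identity; the 30-sequence panel for spectrum
  consistency; a 15-sample (3 × 5), fixed-seed synthetic panel for
  leave-one-out classification (expected: 100 % recovery, mean silhouette
  > 0.5 in PC1/PC2); random 6×4 matrices against a dense
  eigendecomposition for the PCA oracle (tolerance 10⁻⁸); constructed
  stacks at 0°, ±30°, +48°, −23° for twist recovery (tolerance 10⁻⁶ °).
  These sizes are the package's chosen verification conditions.

## Known limitations

* The packaged ratio curves are synthetic; quantitative signature work on
  real spectra needs an experimentally derived drop-in table.
* Like all bulk methods, the signature of a conformer mixture is the
  abundance-weighted mixture of signatures (`eps2fold()` is linear in the
  folded spectrum); interpretation of mixed samples needs orthogonal
  purity evidence.
* DNA only: U and IUPAC ambiguity codes are rejected because the
  parameter tables are DNA-specific. No RNA parameters, no
  temperature-dependent hypochromicity corrections, no duplex/hairpin
  models.
* PDB input only (no mmCIF); residues with insertion codes are rejected
  rather than silently renumbered.
* Overlap classes are assigned by lookup, not computed from ring-overlap
  geometry; tetrad handedness and groove geometry are annotations, not
  derived quantities.
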