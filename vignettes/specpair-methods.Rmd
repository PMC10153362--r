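---
title: "Models and methods behind specpair"
author: "specpair authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind specpair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specpair)
```

# The problem

Photosynthetic reaction centers position a "special pair" of (bacterio)chlorophylls
so that their Qy transition dipoles couple excitonically: the two
near-degenerate site states mix into delocalized exciton states split by
twice the coupling, giving the red-shifted absorbance and conservative
circular-dichroism couplet that are the spectroscopic fingerprints of the
pair. Designing a water-soluble protein that reproduces this arrangement
means solving three coupled problems: (i) place a *chlorin dimer* — not a
single ligand — with defined geometry inside a protein; (ii) verify the
placement structurally; (iii) predict and fit the spectroscopy and binding
behavior that the geometry implies. `specpair` implements the computational
machinery for all three, plus the symmetry bookkeeping needed to assemble
the dimer proteins into a two-component octahedral nanocage.

The central simplification is symmetry. A C2-symmetric homodimeric protein
whose two-fold axis coincides with that of the chromophore dimer guarantees
equivalent binding sites and near-degenerate site energies. It also
collapses the search: instead of docking a ligand with six free rigid-body
degrees of freedom against every pocket, one enumerates C2-symmetric
His–chlorin dimer *motifs* once, indexes them by the 6-D rigid transform
between the two ligating histidines' backbone frames, and then asks of any
candidate scaffold only whether some cross-chain residue pair realizes one
of the indexed transforms — a constant-time hash lookup per position.

# Motif model

A motif half is built by NeRF (natural extension reference frame) from an
idealized histidine backbone outward: N, CA, C, O, CB placed with standard
bond geometry, the imidazole ring closed with planar internal coordinates,
and the side-chain conformation set by the χ1 (N-CA-CB-CG) and χ2
(CA-CB-CG-ND1) dihedrals. The metal sits on the ligating nitrogen's
lone-pair bisector at `metal_his_distance` (default 2.1 Å; the paperless
default for an axial His–Zn/Mg bond), and the chlorin is attached with its
ring plane perpendicular to the metal–N bond, spun about that bond by the
*ligation dihedral*. The metal is displaced 0.3 Å out of the ring plane
toward the histidine, the pentacoordinate geometry typical of
His-ligated (B)Chls. Both Nε ("epsilon") and Nδ ("delta") ligation modes are
enumerated.

The chlorin template is an idealized, exactly planar, four-fold symmetric
macrocycle: pyrrole nitrogens at 2.05 Å from the metal on 90° azimuths,
pyrrole rings as outward pentagons of side 1.40 Å, methine bridge carbons
on the diagonals at 3.45 Å. No experimental template coordinates are
assumed; every computation in the package that compares chlorins uses the
same self-consistent template and the fixed 24-atom naming/ordering
convention (`tetrapyrrole_atom_names()`), so only relative geometry
matters. The Qy transition dipole axis is taken through the NA–NC nitrogen
pair (configurable to NB–ND); the literature states no universal
convention, and all downstream quantities depend only on consistent use.

The *dimer geometry* is parameterized by four numbers: `stack` (separation
along the shared ring normal), `slip` (lateral offset), `tilt` (opening
angle between ring planes) and `azimuth` (spin of each chlorin about its
own normal). The C2 axis is the global z axis and the second half is an
exact 180° rotation of the first, so emitted motifs are C2-symmetric to
machine precision. Defaults (`stack = 3.6`, `slip = 6.7` Å) give a
metal–metal distance of 7.6 Å, bracketing the native special pair; closer
slips emulate the more tightly coupled designed geometry. Motifs whose two
halves approach within the clash cutoff (default 2.8 Å heavy-atom; no
number is published for this step) are filtered out.

# Transform hashing and scaffold matching

Backbone frames are built deterministically from N, CA, C (origin at CA,
x along CA→N, z along (CA→N)×(CA→C)). The relative transform between two
frames is expressed in the first frame's local coordinates, making it
invariant under any joint rigid motion — the property that lets one motif
library serve every scaffold orientation. Hash keys discretize the
translation componentwise (half-open 1.0 Å cells over ±32 Å) and the
rotation via intrinsic ZYX Euler angles (15° cells; the gimbal-locked
pitch = ±90° case deterministically zeroes the roll). The six bin indices
pack into one integer-valued double (< 2^53 by construction); out-of-range
translations return an `NA` sentinel rather than wrapping. Binning is
half-open, so transforms near a cell face can fall on either side: exact-key
retrieval at the insertion transform always succeeds, and an optional
27-cell neighborhood query (off by default, matching single-cell lookup)
mitigates boundary false negatives when perturbed queries matter.

Matching a scaffold hashes the cross-chain transform of every index-paired
residue (i ↔ i, the natural pairing for C2 homodimers) and rebuilds each
hit from its record — ligation mode, χ angles, ligation dihedral, dimer
geometry — anchored on the chain-A residue frame. A placement is accepted
when no chlorin heavy atom is within the clash cutoff of a non-exempt
backbone atom; ligand burial (the DSasa fraction) is computed with the
package's deterministic golden-spiral Shrake–Rupley SASA and used for
ranking, not acceptance.

The test fixture (`make_planted_scaffold`) grafts a motif-compatible
residue pair into a synthetic two-chain scaffold: a short ideal α-helical
segment (φ = −57°, ψ = −47°) is placed so the plant residue's frame equals
the motif's first His frame *exactly*, chain B is the image of chain A
under the motif's His-pair transform (hence an exact C2 homodimer), and the
remaining residues form a distal decoy helix whose placement — and a small
coordinate jitter on decoy residues — varies with the seed without touching
the planted pair. Flanks are trimmed (down to ±1 residue) until the
backbone clears the chlorin footprint; conformers that fold the chlorin
back over their own backbone cannot be grafted into any α-helical host and
raise an error rather than producing a clashing "scaffold". Because the
planted transform is exact, recovery through the hash table is exact as
well; the recovery property test measures this over 100 random plantable
motifs.

This fixture emulates the one feature of real scaffolds that the matching
stage actually consumes — a cross-chain backbone frame pair realizing a
stored transform amid decoy pairs — and nothing else: no side chains, no
pocket shape, no sequence designability. Passing tests therefore validate
the indexing and rebuilding machinery, not the discovery rate on real
scaffold libraries (scaffold inputs of the original design campaign are
not deposited, so design counts are not reproducible quantities).

# Structural comparison

Special pairs are compared over the 48-atom tetrapyrrole correspondence:
per chlorin the 4 pyrrole N, 16 pyrrole C and 4 methine C in fixed name
order; metals excluded (sidestepping Mg vs Zn differences), peripheral
substituents excluded (their rotamers are conformational noise). Kabsch
superposition uses proper rotations only; the two possible monomer
pairings are both tried and the minimum RMSD reported. In-plane
pseudo-four-fold ambiguity is resolved chemically, by atom identity, never
by geometric search.

# Exciton model

The package deliberately replaces quantum-chemical coupling calculations
with the transparent coupled-oscillator model. Each chromophore is a point
transition dipole at its metal center: magnitude 4.6 D for the chlorin Qy
(a standard literature-scale value, configurable), direction along the
template's Qy axis, site energy from a band position (default 669 nm, the
protein-bound monomer maximum). The coupling is the screened point-dipole
interaction

V = 5.04 · s · κ · μ₁μ₂ / R³  (cm⁻¹, μ in Debye, R in nm),

with κ = û₁·û₂ − 3(û₁·R̂)(û₂·R̂) and the constant fixed by SI constants
(1 D² nm⁻³ / 4πε₀hc = 5.04 cm⁻¹). Screening defaults to 1. The
site Hamiltonian is diagonalized exactly; for a degenerate dimer the states
sit at E ± |V| with (1, ±1)/√2 coefficients, which is what licenses reading
the experimental Qy splitting of a dimer as 2V. Dipole strengths conserve
the total μ² sum; rotatory strengths use the exciton-chirality length form
R_k = −(π ν̄ / 2) Σ_{i<j} c_ki c_kj R_ij·(μ_i × μ_j) with ν̄ the mean site
energy as the common prefactor, which makes the couplet of an
identical-site dimer exactly conservative (sum zero) by coefficient
orthonormality. Intrinsic monomer CD is not added by default.

Spectra are sums of Gaussians, one per state, with band-class FWHM
350 cm⁻¹ (Q) / 1150 cm⁻¹ (Soret, above 20 000 cm⁻¹ by default) and a
global −0.25 eV shift that calibrates the computed Qy position onto the
experimental band; band areas are proportional to dipole (absorbance) or
rotatory (CD) strength. Grids may be specified in wavelength or wavenumber;
integral checks should use a uniform wavenumber grid, where Riemann
summation of Gaussians is accurate to machine precision, since non-uniform
nm-grid weights contribute ~1e-4 relative quadrature error that has nothing
to do with the physics.

What this model does *not* capture: transition-density effects at
sub-nanometer separations (point dipoles systematically misestimate
close-contact couplings), interband Qx/Soret mixing, vibronic structure,
and environmental site-energy shifts. Computed couplings for specific
crystal-structure geometries are therefore indicative, not reproductions of
published quantum-chemistry values; the experimentally anchored arithmetic
(splitting ↔ coupling) is exact.

# Binding model

Titrations are modeled with stepwise macroscopic constants on the protein
dimer: P + L ⇌ PL (K_D1), PL + L ⇌ PL₂ (K_D2). Free ligand is the root of
a strictly increasing conservation function on [0, L_T]; the curve solver
is a bracketed Newton iteration with analytic derivative, vectorized over
the titration series, converged to better than 1e-10 relative mass balance
(the scalar entry point cross-checks uniroot plus Newton polish against a
brute-force grid in the tests). CD signal is s_PL·[PL] + s_PL2·[PL₂];
absorbance is per-chromophore, ε_free·[L] + ε_PL·[PL] + 2ε_PL2·[PL₂], so
the doubly loaded dimer contributes per bound chlorin.

The synthetic generator's defaults are the study conditions used
throughout: 5 µM protein dimer, 25 ligand points spanning 0–5 equivalents,
Gaussian noise at 2% of the maximum signal, 50 seeded replicates. Where the
source experiments leave a coefficient unstated, it was fixed once:
s_PL = −0.1, s_PL2 = +1.0 signal units per µM of complex (a
dimer-dominated doublet, with a weak monomer-like contribution of opposite
sign), and ε_free = 30 000 M⁻¹cm⁻¹ at the dimer Qy maximum (a realistic
red-tail value for unbound chlorin in aqueous buffer). These were chosen
before the recovery experiments and are not tuned.

Fitting is Levenberg–Marquardt (`minpack.lm`) on log-K_D with the
coefficients free; log-parameterization enforces positivity without
constraints. The five-parameter absorbance surface supports local optima,
so the fitter multistarts from six deterministic K_D pairs with
data-driven coefficient starts (terminal slope → ε_free, initial slope →
ε_PL) and keeps the lowest residual. One statistical property deserves
note: at these conditions the first constant is in the tight-binding regime
(K_D1 ≪ P_T) and its least-squares estimator is strongly right-skewed —
across 500 replicates the 5–95% quantiles span roughly 0.3×–3× the truth,
and the estimator's median overshoots by ~9%. The median over 50
replicates is the reported summary; a dense-restart audit of the
high-K_D1 fits confirms they are global optima, i.e. this is sampling
skew inherent to the protocol, not an optimization failure. The second
constant and the extinction coefficients are well identified (medians
within a few percent).

Lifetime arithmetic uses the amplitude-weighted mean, τ_av = Σaᵢτᵢ/Σaᵢ,
and transfer efficiency E = 1 − τ_DA/τ_D; no instrument-response
deconvolution is attempted.

# Nanocage assembly

The octahedral rotation group (24 elements) is generated from two 90°
rotations and verified closed; a two-component cage places an internally
C2-symmetric component on the edge two-fold axis (1,1,0)/√2 and a
C3-symmetric component on the vertex three-fold axis (1,1,1)/√3, each with
an axial spin and radial translation, and expands by coset representatives
of the component's cyclic stabilizer — 12 dimer copies and 8 trimer
copies, 48 chains, and 24 chromophores when the dimer carries one per
protomer. Scoring replaces hierarchical docking with an exhaustive axial
grid: per unique C2–C3 interface (symmetry copies are equivalent by group
action) it reports clash count, contact count and buried
solvent-accessible area, with pass bounds defaulting to clashes < 3 and
1000–1600 Å² buried area. Shape complementarity, binding-energy and
hydrogen-bond filters are out of scope here, as they require a full-atom
energy function.

# Numerical choices and problem sizes

* Dihedral signs follow the right-hand (IUPAC) rule; NeRF placement is
  verified against the independent dihedral routine and round-trips
  internal↔Cartesian coordinates to < 1e-6 Å.
* Superpositions use SVD with the determinant correction (proper rotations
  only); an independently implemented rotation-matrix oracle and a
  20 000-sample random-rotation brute force bound it in the tests.
* SASA uses a deterministic golden-spiral point set (default 960 points;
  120 in bulk placement scoring), accurate to ~2% on the analytic sphere.
* Bin-boundary behavior of the hash is half-open and deterministic; the
  hashing invariants are tested against a linear-scan oracle on
  1000-record random tables.
* The test suite and acceptance script size their simulations to run on a
  single CPU in minutes: 100 planted-recovery motifs, 50-replicate
  titration ensembles, 10-residue-per-chain toy cage components. These
  sizes were chosen as the smallest that exercise the contracts they test.

# Known limitations

* The ideal chlorin is a geometric abstraction: no ring-V, no asymmetric
  substituents, exact planarity. Comparisons of real structures depend on
  the deposited ligand's atom naming (a configurable name map is provided).
* Hash matching has boundary false negatives by construction; real
  scaffold scans near cell faces should enable the neighbor-cell query.
* The point-dipole exciton model degrades below ~1 nm separations exactly
  where special pairs live; treat absolute couplings as order-of-magnitude
  and rely on the degenerate-splitting arithmetic for experiment-anchored
  numbers.
* The sequential binding model uses macroscopic constants; microscopic
  site constants and cooperativity mechanisms are not identifiable from a
  single-wavelength titration and are not modeled.
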