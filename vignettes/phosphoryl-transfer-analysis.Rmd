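---
title: "Methods: geometry and kinetics of alpha-phosphate attack"
author: "phosnap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry and kinetics of alpha-phosphate attack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosnap)
```

# Scope and model

`phosnap` quantifies the geometry of nucleophilic substitution at a
phosphorus centre across a series of structural snapshots, and fits the
accompanying reaction progress measured by quantitative ³¹P-NMR. The
reference system is trimeric dUTPase: a catalytic water, oriented by the
Val93 main-chain carbonyl and the Asp95 carboxylate, attacks the
alpha-phosphorus of the bound nucleotide in line with the scissile bond,
inverting the configuration at phosphorus through a trigonal-bipyramidal
(TBP) transition state; the nascent product then relaxes by rotation of
its phosphate about the O5′–αP bond. Every quantity the package reports is
a plain geometric or least-squares measurement; no energies are computed
(quantum-chemical reaction-path work is explicitly out of scope, as are
crystallographic refinement, density interpretation and symmetry-mate
generation).

# Structures, bonds and radii

Structures are parsed from PDB files (via `bio3d`) into a plain
chain/residue/atom table per model. Coordinates are used exactly as
deposited, in orthogonal Angstrom; crystal structures carry no hydrogens,
so every geometric operation works without them, and the proton-transfer
coordinate Q2 only applies to modelled or synthetic input that supplies an
explicit hydrogen position.

Alternate conformers are collapsed with the *highest-occupancy* policy by
default (ties resolve towards altloc "A"). Occupancy-weighted averaging
was rejected because averaged positions are not positions of any physical
conformer and would bias measured distances.

Bonds are always perceived geometrically — deposited CONECT records are
ignored as unreliable: pair $(i,j)$ is bonded iff
$d_{ij} \le r_{cov}(i) + r_{cov}(j) + t$ with Cordero covalent radii and
tolerance $t = 0.4$ Å, a slack wide enough for stretched ground-state
bonds but below the shortest non-bonded contacts of interest (the 2.52 Å
pre-catalytic P–O contact is comfortably above the 2.13 Å P–O bonding
threshold). Coincident atoms (below 0.01 Å) are flagged as clashes, never
bonded. Van der Waals radii are the Bondi (1964) values, chosen because
they give the exact P+O sum of 3.32 Å used as the short-contact threshold
throughout. Both tables can be overridden from a key-value file.

# Near-attack conformations

For each phosphorus, candidate nucleophiles are non-bonded oxygens within
`max_attack_distance` (default **3.6 Å**, the upper end of the
pre-catalytic P–O range observed across dUTPase complexes; the lower end
is bounded by bond perception itself). The leaving atom is the bonded
bridging O/N that maximizes the nucleophile–P–leaving angle, and a site is
accepted when that angle reaches `min_inline_angle` (default **150°**; the
literature says "in-line" without a number, and 150° separates genuinely
backside approaches from adjacent-oxygen artefacts) and when each required
coordination contact of the nucleophile is present (default contacts for
the dUTPase water: Val93 O and Asp95 OD1/OD2 within 3.5 Å, an ordinary
hydrogen-bond ceiling). Bonded oxygens of the phosphorus are classified by
onward connectivity: bridging oxygens (e.g. O5′) bond a further heavy
atom, non-bridging ones do not.

The reaction coordinates are
$q_1 = d_{break} - d_{form}$ and
$q_2 = q_1 + \tfrac12\,[d(H_w{-}O_w) - d(H_w{-}O_{Asp})]$;
the two hydrogen distances must be supplied together or not at all.

# The non-bonded P–O survey

Over a corpus of structures, every unordered P–O pair that is not bonded
and lies within `max_distance` (default **4.5 Å**, the upper edge of the
reference band, so the band fraction is a fraction of all surveyed pairs)
contributes one count. Bins and the reference band (default 3.3–4.5 Å,
bin width 0.1 Å) are **half-open** `[lo, hi)` — a documented convention,
since a survey quoted only as "3.3–4.5" does not fix its boundaries. An
empty survey reports `band_fraction = NA` with an explicit `undefined`
flag rather than a guess. Whether the corpus-wide fraction near 0.9 holds
for any particular structure collection is a property of that collection;
the package only guarantees exact bookkeeping, which the tests verify on
planted corpora.

# Superposition and motion metrics

Superposition is least-squares (Kabsch via SVD) restricted to proper
rotations: the smallest singular direction is sign-corrected so that
reflections are never returned and mirror-related sets retain a positive
RMSD. Fewer than three or collinear pairs are rejected. The default frame
for snapshot comparisons pairs shared main-chain N/CA/C/O atoms of
standard residues; an explicit atom-descriptor frame (e.g. ligand atoms)
and the identity frame are available, because the frame is part of the
measurement definition and published displacement values rarely state it.

Per-atom displacement is the Euclidean distance after frame superposition.
Side-chain motion reports (i) the change in the terminal chi dihedral (for
aspartate CA–CB–CG–OD1), wrapped to [0°, 180°], and (ii) the maximum
side-chain atom displacement. The carboxylate-plane alternative for
"rotation" was considered and set aside: the terminal dihedral is defined
for every side-chain type in the table and degrades gracefully with
missing atoms.

**Rotation about a bond axis** is measured from torsion azimuths: for each
rotating atom, the dihedral reference–axis1–axis2–atom is evaluated in
each structure separately, and the rotation is the least-squares common
shift of these azimuths (a circular mean). Dihedrals are invariant to
rigid motion, so no prior superposition is needed — and, decisively, the
measurement stays well-defined when the axis itself translates between
conformers, as the alpha-phosphorus does (1.57 Å) during product
relaxation. Projecting displacements about a fixed frame axis, the more
obvious construction, silently breaks in exactly that case. The azimuth
reference atom is auto-selected among atoms bonded to the first axis atom
(preferring carbon, e.g. C5′ on O5′) or can be given explicitly.

# Chirality and inversion

Handedness at a tetrahedral phosphorus is the signed volume
$V = (s_2 - P) \cdot [(s_3 - P) \times (s_4 - P)]$ over substituents in
the fixed order O5′ > O1A > O2A > leaving/incoming — bridging-to-nucleoside
first, non-bridging by name, the exchanging atom last, so that
substitution with inversion flips the sign. $|V|$ below **0.1 Å³**
(roughly the volume noise from 0.1 Å-scale coordinate uncertainty on
1.5 Å bonds) raises a planarity flag and the sign is treated as 0;
inversion calls involving a planar descriptor are returned as `NA`, not
forced to a boolean. The substituent mapping between snapshots is always
explicit, and the water-oxygen-for-leaving-atom substitution must be named
in it — this is what makes "inversion" well-posed when the atom identities
change across the chemical step.

# TBP assignment and deviation

At a 5-coordinate phosphorus the axial pair is the ligand pair with the
largest ligand–P–ligand angle; ties resolve towards the larger mean
P–ligand distance (axial bonds are the stretched ones), then by ligand
label. This heuristic is provably equivalent to the exhaustive 10-pair
search, which the tests assert on jittered geometries. Deviations from the
ideal associative-mechanism reference (equatorial 1.60 Å, axial 1.91 Å,
angles 180°/120°/90°) are reported per feature and aggregated as separate
RMS values over angles (10 of them) and bond lengths (5) — a single
mixed-unit score would be meaningless. Bond perception for 5-coordinate
sites uses a wider 0.6 Å tolerance, since transition-state axial bonds are
elongated past the ground-state threshold.

# ³¹P-NMR simulation, integration and the global fit

Multiplets are first-order: $n$ scalar couplings expand into $2^n$
Lorentzian lines of equal area at all sign combinations of $\pm J_i/2$
(in Hz; divided by the spectrometer frequency, default 101.25 MHz, for
ppm). Strong-coupling (second-order) distortions and any FID-level
processing are out of scope. Simulation is linear by construction, and the
full-grid integral equals the summed multiplet intensities up to
truncation.

Integration windows default to the multiplet centre ±(ΣJ/2 + 25
linewidths). The margin matters: a Lorentzian truncated at $k$ linewidths
captures only $(2/\pi)\arctan(2k)$ of its area — 92.1 % at $k = 4$,
98.7 % at $k = 25$ — and the captured fraction differs between singlets
and multiplets, so narrow margins bias area *ratios* (a 4-linewidth margin
distorts an equimolar three-peak ratio by about 3 %, more than the 2 %
fidelity the quantitative chain targets). The default linewidth of 0.5 Hz
keeps these wide relative margins narrow in absolute ppm, so the
neighbouring 3.27/3.48 ppm product multiplets remain essentially disjoint.

The kinetic model is a shared first-order rate over all peaks: decays
$a_0 e^{-kt}$, rises $b_0(1 - e^{-kt})$. Amplitudes enter linearly and are
profiled out analytically (variable projection), reducing the fit to a 1-D
bounded search over $k > 0$ on the log scale, multi-started from 0.1×, 1×
and 10× of a half-life heuristic (three half-lives per sampled span) —
deterministic, with no randomized restarts. The standard error of $k$
comes from the Gauss–Newton covariance of the full parameter vector at the
optimum. All-constant series raise a non-identifiability error; a rate at
the search bound raises a warning flag. Rate units are the inverse of the
caller's time unit and are never converted; published rate constants for
slow hydrolyses are not always dimensionally self-consistent across
experiments, and the package deliberately takes no position. The fit
returns a classed model object (`rate_fit`) with the usual
`print`/`summary`/`coef`/`predict`/`fitted`/`residuals`/`plot`/`simulate`
methods.

# Morph trajectories

Morphing is linear Cartesian interpolation between consecutive snapshots
after superposing each onto the first (on the shared-atom set by default);
endpoints reproduce the superposed snapshots exactly, junction frames are
shared, and the model count is $(n-1)f + 1$. No clash relaxation or
internal-coordinate interpolation is attempted — the trajectory is an
illustration of the pathway ordering supplied by the caller, never an
inference of it. Atoms missing from any snapshot are dropped with a
warning.

# The synthetic-data generators

Every analysis has a generator that plants its ground truth: attack sites
with exact distance/angle and optional coordination atoms; tetrahedral
phosphates of chosen handedness with their Walden images; jittered TBP
sites; survey corpora with planted distance lists; first-order time
courses with seeded Gaussian noise; and a four-stage snapshot series
(apo → ES → EpiP → EP) in which the attack geometry (2.52 Å, 175°), the
Asp95 rotation (15.8°) and OD2 shift (0.61 Å, obtained by composing a
terminal-dihedral rotation with a chi-1 rotation solved by root-finding —
chi-1 leaves the terminal dihedral invariant, so both plants hold
simultaneously), the Asp42 CG shift (1.2 Å), the inversion at αP, and the
product relaxation (1.57 Å shift, 40° rotation) are all planted exactly.
Generator defaults are the study conditions; all randomness is seeded and
byte-reproducible.

These structures use a minimal atom vocabulary with legal PDB names, so
the I/O and bond-perception layers treat them like real deposits. They are
synthetic stand-ins with known ground truth, **not** models of any
deposited coordinates: passing tests demonstrate that the measurements
recover planted values through the full file-based pipeline, not that any
particular deposited structure exhibits those values. What the generator
does not emulate: crystallographic noise and anisotropy, partial
occupancies and static disorder, solvent networks, lattice contacts, and
realistic force-field geometry away from the planted features.

# Test and problem sizes

The suite validates each operation round-trip and property-style under
fixed seeds: 100 random rigid transforms for chirality invariance, 100
jittered TBP geometries against the exhaustive axial-pair oracle,
brute-force rotational superposition on up-to-8-point instances, planted
survey corpora of 10–100 pairs, and 50 replicate kinetic fits at 5 %
noise with 20 time points over three half-lives (median relative error
required below 5 %; noiseless recovery below $10^{-6}$). These sizes were
chosen to exercise the estimators well into their asymptotic behaviour
while keeping the full suite fast on a single CPU.

# Known limitations

- No symmetry expansion: measurements across crystallographic interfaces
  require the caller to supply reconstructed coordinates.
- Q2 requires explicit hydrogen positions; deposited crystal structures
  do not provide them.
- The TBP reference describes a single idealized associative transition
  state; dissociative or exploded geometries are not scored.
- First-order multiplet simulation only; strong coupling between nearby
  ³¹P shifts is ignored.
- The shared-rate model assumes one global exponential; multi-phase
  kinetics are detectable only as structured residuals.
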