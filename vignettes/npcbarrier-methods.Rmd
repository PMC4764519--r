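---
title: "Coarse-grained energetics of nuclear pore transport: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained energetics of nuclear pore transport: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The nuclear pore complex (NPC) gates all traffic between cytoplasm and
nucleus. Its central channel is lined by intrinsically disordered
FG-nucleoporins (FG-Nups) that let small molecules diffuse through while
blocking inert cargoes larger than roughly 5 nm; transport factors
(karyopherins) carrying hydrophobic FG-binding spots pass even at 10 nm and
beyond. `npcbarrier` implements a one-bead-per-amino-acid model of this
system and the analysis chain that turns it into a single number per cargo:
the equilibrium energy barrier $G$ that the pore presents, measured by
umbrella sampling and WHAM, plus a closed-form transport model
$G(D, n)$ fitted to those barriers.

Everything is equilibrium energetics. Translocation rates, first-passage
times and any kinetic quantity are out of scope by design: the underlying
force field is parameterised against equilibrium properties of FG-Nup
segments and carries no kinetic calibration.

# The model

## Beads and interactions

Each amino acid is one bead of mass 120 Da and radius $r_b$ = 0.3 nm.
Consecutive beads are bonded at 0.38 nm by a stiff harmonic spring
(default 8000 kJ mol$^{-1}$ nm$^{-2}$; this constant is not a printed model
value — it is chosen so RMS bond fluctuations stay below 0.02 nm at 300 K,
and the test suite enforces exactly that). Backbone stiffness enters through
tabulated bending (3-bead pseudo-angle) and torsion (4-bead dihedral)
potentials. The canonical tables derived from Ramachandran statistics of
coil regions are not public data; the package ships smooth default tables
peaked at extended conformations (editable two-column text files in
`inst/extdata/`), interpolated with a C1 cubic-Hermite scheme so forces are
the exact gradient of the interpolant. Angles outside the bending table are
clamped.

Nonbonded terms:

* **Hydrophobic attraction.** A split Lennard-Jones pair potential: a fixed
  repulsive core of strength $\varepsilon_{\max}$ and an attractive well of
  depth $\varepsilon_{ij} = \varepsilon_{\max} h_i h_j$, where $h$ is a
  normalised hydrophobicity in $[0, 1]$ with phenylalanine at the maximum.
  $\varepsilon_{\max}$ = 5.2 kJ/mol, so an F–F contact (or a binding-spot–F
  contact) sits in a well of exactly −5.2 kJ/mol ≈ 2.1 $k_BT$. The energy is
  shifted to vanish at the 2.5 nm cutoff. With $\varepsilon_{ij} = 0$ the
  interaction is purely repulsive and exactly zero beyond
  $2^{1/6}\sigma$ — hydrophilic beads only exclude volume. The
  hydrophobicity scale shipped with the package is a normalised composite of
  standard octanol scales with F forced to the maximum; it is a declared,
  editable substitute, not a reconstruction of any published
  calibration.
* **Electrostatics.** Debye–Hückel screening,
  $U = C q_i q_j e^{-r/\lambda_D} / (\epsilon_r r)$, with
  $\lambda_D$ = 0.8 nm, $\epsilon_r$ = 80, shifted to zero at 5.0 nm. D/E
  carry −1, K/R +1, H is neutral.
* **Excluded volume.** Scaffold beads and inert cargo surfaces interact with
  everything through a purely repulsive WCA term that is zero at and beyond
  the contact distance. Both LJ forms linearise their inner core below
  0.8 σ: a finite, continuous force when umbrella windows warm-start with
  slight overlaps. Equilibrium averages are unaffected — configurations that
  deep in the core are never thermally sampled.

Units are nm, ps, Da, kJ/mol throughout; PDB export converts to Å at the
boundary, nowhere else.

## Geometry, cargoes, binding spots

The scaffold is a rigid, eightfold-symmetric hourglass wall of 5-nm
hard-sphere beads (no attraction to FG-Nups), capped by nuclear-envelope
discs at $z = \pm$ half-height. The discs matter: without them grafted
chains drift over the pore mouth and push an approaching cargo *into* the
channel, a depletion artefact that inverts the barrier sign at fixture
scale. The pore axis is $z$, the central plane $z = 0$, cytoplasm at
$z > 0$.

Inert cargoes up to 5 nm are a single bead with contact
$\sigma_c = D/2 + r_b$. Larger cargoes are rigid composites of beads with
$\sigma_c$ = 2.5 nm centred at $r_c = D/2 - (\sigma_c - r_b)$; sub-bead
directions are a Fibonacci-sphere set grown adaptively until the effective
repulsive surface is spherical to better than 3.5% (the documented
icosahedron-plus-face-centres placement fails the 5% sphericity bound for
$D \gtrsim 10$ nm, so the package deviates there). A Kap–cargo complex adds
$n$ Phe-like binding-spot beads (diameter $a$ = 0.6 nm) on the surface,
spaced at arc length $d$ along a great circle on the cargo equator — the
"stripe" is taken as that single great circle, the narrowest reading
consistent with the geometry. With $n = 0$ the complex is bit-identical in
its energy terms to the inert cargo.

## Dynamics

BAOAB-split Langevin dynamics at 300 K, time step 0.02 ps. The physical
friction is 50 ps$^{-1}$ (water-like collision rate) and that value is the
package default and the one used for thermostat validation. Umbrella
campaigns, however, default to much lower friction: equilibrium
distributions are rigorously independent of the friction coefficient and of
all masses, and lowering both (cargo `mass_scale`, $\gamma \sim$
0.1–0.5 ps$^{-1}$) shortens correlation times by an order of magnitude at
desk scale. This is a sampling-efficiency device, not a physical claim.

The cargo is one rigid body: net force and torque propagate its center and
quaternion (spherical inertia $\tfrac{2}{5} M (D/2)^2$, rotational friction
Stokes-scaled as $\gamma_r = \tfrac{10}{3}\gamma$). Whether the original
simulations let the cargo rotate during umbrella sampling is not stated;
here it rotates by default and `free_rotate = FALSE` freezes it. Grafted
chains hang from one extra fixed anchor bead per chain; anchored and
scaffold beads never move. A Verlet neighbour list (0.5–1 nm skin,
displacement-triggered rebuilds, per-pair cutoffs) makes forces exact with
respect to the all-pairs sum, and the RNG is a counter-seeded
xoshiro256++ stream so a run is bit-reproducible from its seed.

# Umbrella sampling and WHAM

The reaction coordinate is the cargo-center $z$ (axial) or its signed
radial projection at fixed $z$ and direction $\theta$ (radial). Windows at
spacing $dz$ carry a harmonic bias; the default stiffness
$k = 4 k_BT/dz^2$ makes the ideal-spring SD $dz/2$ so neighbouring
histograms overlap generously. A stiff lateral restraint (default
100 kJ mol$^{-1}$ nm$^{-2}$) keeps axial scans on the axis; radial scans
swap the roles and add an angular restraint at
$\theta \in \{0°, 90°, 180°, 270°\}$. Campaigns run from the cytoplasmic
end inward, warm-starting each window from the last — the 20–30%
equilibration segment that every window discards then absorbs the cargo
translation.

WHAM iterates the standard self-consistent equations on a shared bin grid
until the window constants move less than `tol`; non-overlap between
adjacent windows and non-convergence are hard errors that name the gap or
the residual. Profiles are reported up to an additive constant fixed by a
reference region (the cytoplasmic interval for barrier work, $r = 0$ for
radial profiles). Per-bin uncertainties come from a block bootstrap
(50 blocks per window, 20 replicates by default) re-solved warm-started at
a relaxed tolerance, which the replicate noise dominates anyway.

Numerical choices worth knowing: very stiff windows amplify window-mean
noise into profile noise (the error in a window's mean enters multiplied by
$k$), so wide-and-soft beats narrow-and-stiff whenever the landscape
allows; and the binning bias of WHAM is second order in bin width, so the
default 0.25–0.4 nm bins with SD-matched windows are safe. Both effects are
exercised by the analytic double-well oracle in the acceptance suite.

# The barrier statistic and analyses

The energy barrier is
$G = \langle G(z)\rangle_{z \in \text{core}} - \langle G(z)\rangle_{z \in \text{ref}}$,
with core $-5 < z < 5$ nm and reference $20 < z < 27$ nm at full scale
(both scale linearly with fixture size). Bins are weighted uniformly — the
source does not say whether its interval means weight by sample count, and
uniform weighting keeps the statistic independent of the sampling design.
The dispersion attached to $G$ is the root mean square of the PMF standard
deviations over the two intervals, matching the error bars of the
barrier-versus-diameter analysis. The $k_BT$ crossing of the interpolated
$G(D)$ curve defines the size-selectivity threshold $D^*$; multiple
crossings are all reported.

Density maps bin mobile FG-Nup bead mass into annular $(r, z)$ voxels
(volume $2\pi r\,\Delta r\,\Delta z$, defaults 0.5 nm), with an overflow
accumulator so total mass is conserved to machine precision.

# The transport model

$$G(D, n) = a_1 (D/L)^2 - \left(b_2 X^2 + b_1 X + b_0\right),
\qquad X = \frac{n a}{\pi D}$$

$f = a_1 D'^2$ is fitted by least squares to inert barriers (surface-area
scaling of brush insertion at low grafting density), $g(X)$ to the
spot-count series at fixed $D$ = 10 nm. The published constants live in
supplementary material that is not available, so the package never ships
numeric model constants: it always derives them by fitting its own barrier
tables and stores them in a key-value parameter file with a provenance
header. $b_0$ is unconstrained by default (`constrain_b0_zero` flips that);
an $n = 0$ point in the $g$ data drives $b_0$ to zero on its own. Whether
the trapped high-$n$ point belongs in the $g$ fit domain is genuinely open;
the package fits whatever table it is given and reports residuals, leaving
the domain choice to the caller. Regimes: $G > +k_BT$ expelled,
$|G| \le k_BT$ transported, $G < -k_BT$ trapped.

# The synthetic fixture, and what a green test establishes

Real Nup sequences and anchor coordinates are external inputs the package
reads from FASTA and a delimited anchor table. For desk-scale work the
fixture generator builds a stated world: a pore scaled to 1/3 (L = 20 nm,
half-height 5.1 nm), 16 chains in two eightfold rings near the central
plane, and FG-like sequences of 80 residues — FSFG motifs every 20 residues
(FG-dimer residue fraction 10%, the dilute end of the declared 10–15% band)
with S/T/N/Q/G/A spacers and one balanced K/D pair per two units (net
charge 0). Chain length sits in the stated 50–100 band. Two fixture choices
came from physics rather than aesthetics: anchor rings sit near the central
plane (mouth-adjacent rings let chains spill toward the cytoplasmic
reference region and produce a depletion artefact), and the FG fraction
sits at the dilute end of the band because at higher fractions the 16-chain
brush collapses into wall clumps whose quenched arrangement varies from
realization to realization and washes out the size-selectivity signal.
These are declared properties of the synthetic world; the residual
realization-to-realization spread of fixture barriers (of order a few
kJ/mol for large cargoes) is the main known limitation of the desk-scale
acceptance surface, and it bears hardest on the spotted-versus-inert
comparison, whose true effect size is comparable to that spread.

The fixture emulates: a grafted, cohesive FG-brush in an eightfold pore;
entropic size exclusion growing with cargo diameter; hydrophobic
binding-spot attraction. It does not emulate: the real sequence diversity
and lengths (up to ~700 residues), the anchor map of a real NPC, absolute
barrier heights, or wildtype-scale PMFs (those need the cluster-tier
campaign, which is deliberately outside CI). A green fixture test therefore
establishes qualitative physics — monotone size selectivity, barrier
lowering by binding spots, estimator correctness — and nothing quantitative
about the yeast pore.

# Known limitations

* Implicit solvent, no hydrodynamic interactions; kinetics are meaningless.
* Hydrophobicity scale and angle tables are declared substitutes for
  unavailable calibrations; both are user-replaceable data files.
* The fixture's 16-chain brush is noisy: window-mean fluctuations of the
  slowly relaxing brush dominate the PMF uncertainty, so fixture barriers
  carry dispersions of order 1 kJ/mol even with low-friction sampling.
* WHAM only; MBAR or transition-based estimators are future extensions.
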