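---
title: "Dual binding modes of cohesin-dockerin complexes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual binding modes of cohesin-dockerin complexes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualbind)
```

## The scientific problem

Dockerin domains of cellulosomal enzymes carry an internal sequence
duplication: two loop-helix segments, each with a calcium-binding motif
and a near-identical set of cohesin-contacting residues. As a
consequence a dockerin can bind its cohesin in two orientations related
by a rotation of roughly 180 degrees -- *dual binding*. Crystal
structures capture one orientation each (the wild type in one, a
surface mutant designed to disfavour that orientation in the other), so
the equilibrium balance between the two modes must be inferred
computationally. This package implements that inference in three
layers:

1. **binding geometry** -- derive, from a structure pair exemplifying
   the two modes, the symmetry axis (the *Z*-axis) such that a rotation
   of the dockerin about *Z* by an angle $\varphi$ carries mode I into
   mode II, and generate rigid poses of the dockerin on a
   $(Z, \varphi)$ grid with steric masking;
2. **landscape statistics** -- aggregate per-pose free energies
   $\Delta G_k(Z, \varphi)$, supplied by any external energy backend
   for one or more input structure replicas $k$, into binding-mode free
   energies and mode probabilities;
3. **coarse-grained mechanics** -- a structure-based (Go-type)
   C$\alpha$ model with native contacts from an atomic overlap
   criterion, used for thermal stability, thermal unfolding, and
   AFM-like constant-speed stretching.

A synthetic-data layer generates every input class -- two-basin
landscapes with analytic ground truth, toy helical proteins with heavy
atoms, and structure pairs related by a known rotation -- so the whole
pipeline is testable without external data.

## Deriving the symmetry axis

With the cohesins of the two complexes superposed (Kabsch
least-squares on shared C$\alpha$ atoms), the displacement vectors
between equivalent C$\alpha$ atoms of the two dockerins -- taken over
the first and third dockerin helices (residues 11-23 and 45-56), the
two that couple to the cohesin -- lie nearly in a plane. The plane
normal is the symmetry axis. `find_symmetry_axis()` implements the
iterative prescription: starting from the laboratory frame, each
iteration solves in closed form for the small rotation about the two
in-plane frame axes that minimizes the linearized sum of squared
*Z*-components of the vectors, applies it (with step damping if the
linearization overshoots), and stops when the residual improves by
less than $10^{-9}\,\mathrm{\AA}^2$ (500 iterations is an error). The
residual is non-increasing by construction, and on synthetic pairs
built with a known rotation the axis is recovered to well under a
degree.

Two quantities are deliberately separated:

* the **axis** comes from the planarity condition alone;
* the **mode-switch angle** is then a centered two-dimensional
  Procrustes fit of the in-plane C$\alpha$ coordinates. Centering
  matters: the frame origin (set to the centroid of the paired helix
  atoms of both modes, the midpoint of the two orientations) need not
  lie exactly on the true rotation axis, and an uncentered fit would
  absorb that offset into an angle bias of a few tenths of a degree.

The sign of a derived axis is arbitrary; `orient_frame()` fixes the
convention that $+Z$ points from the dockerin toward the cohesin, so
positive *Z*-shifts bring the molecules closer. Poses are composed as
rotation about *Z* first, then translation along $+Z$; `apply_pose()`
documents this order and the tests pin the composition property. Poses
whose inter-molecular heavy-atom minimum distance falls below 2 A (a
clearly sub-bonded separation) are marked sterically forbidden in the
pose grid. The default grid is $Z \in [-10, 4]$ A in 0.5 A steps and
$\varphi \in [-180, 180)$ degrees in 2 degree steps, fine enough to
resolve minima that sit a few degrees off the mode centers.

## Mode free energies and probabilities

For a set of landscapes $\Delta G_k(Z, \varphi)$ in kcal/mol the mode
free energies are discrete Boltzmann aggregates,

$$F_{I} = -k_B T \,\ln \sum_k \sum_Z \sum_{-\pi/2 < \varphi < \pi/2}
  e^{-\Delta G_k(Z,\varphi)/k_B T}\;\theta(E_c - \Delta G_k),$$

and likewise $F_{II}$ over $\pi/2 < \varphi < 3\pi/2$; the step
function $\theta$ excludes cells at or above the cutoff $E_c$, and the
$\varphi = \pm\pi/2$ boundary belongs to neither mode (strict
inequalities). The ratio of mode probabilities is
$p_I/p_{II} = \exp[-(F_I - F_{II})/k_B T]$ with $p_I + p_{II} = 1$.
Throughout, $k_B = 1.9872 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and
$T$ is in kelvin (298 K default, 308 K the second supported analysis
temperature).

Numerical choices:

* Sums are evaluated in shifted (log-sum-exp) form, so cells with
  $\Delta G / k_B T \approx -65$ (e.g. $-38.5$ kcal/mol at 298 K)
  cannot overflow; the unit tests pin agreement with a direct
  fixed-shift summation to $10^{-9}$ relative.
* The sums are unweighted grid sums, matching the discrete definition;
  no cell-area weighting is applied (the grids are uniform).
* An empty state set under the cutoff is an error, never a silent
  zero.
* The cutoff scan (`saturation_scan()`) reports the plateau onset as
  the smallest $E_c$ from which $F$ stays within 0.05 kcal/mol over a
  5 kcal/mol window *and* within 0.05 kcal/mol of the saturation value
  ($F$ at the largest cutoff). A consequence worth stating: a state
  far above the global minimum (say 14 kcal/mol up) carries Boltzmann
  weight $e^{-23.6}$ at 298 K, so admitting it does not move $F$ and
  the plateau genuinely begins just above the *low* level, not at the
  high one. The plateau is about free-energy stability, not about when
  states enter the sum.

The saturation values of $F_I$ and $F_{II}$ are the binding free
energies used for mode probabilities. For the reference
cohesin-dockerin systems the literature-reported saturation values are
shipped as data (`reported_free_energies()`); applying the probability
relation at 298 K to them gives ratios of about 222 (wild type without
tails: strong mode-I preference), about 25 (mutant without tails), and
about 0.009 (mutant with tails: mode II dominates), i.e. the
one-significant-figure values 200, 20 and 0.01.

## The coarse-grained model

Each residue is one bead at its C$\alpha$; bound calcium ions are
additional beads. The Hamiltonian has four terms (reduced units:
energy $\varepsilon$, length A, time $\tau$, mass $m = 1$,
$k_B = 1$):

| term | form | parameters |
|---|---|---|
| bonds | $\tfrac{1}{2} k_b (r - r_0^{ij})^2$ over sequence neighbors | $k_b = 100\ \varepsilon/\mathrm{\AA}^2$, native lengths |
| native contacts | $4\varepsilon[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6]$ | $\sigma_{ij} = r^{\mathrm{nat}}_{ij}/2^{1/6}$ |
| non-native pairs | truncated-shifted repulsion, zero beyond $r_0$ | $r_0 = 4$ A |
| chirality | $\tfrac{\kappa}{2}(C_i - C_i^{\mathrm{nat}})^2$ | $\kappa = 1\ \varepsilon$ |

with $C_i = [(\vec v_i \times \vec v_{i+1}) \cdot \vec v_{i+2}]/d_0^3$
over successive bond vectors and $d_0$ the chain's mean native bond
length. The chirality form is a modeling choice (the harmonic
local-chirality term standard in this model family); its strength is
configurable. The physical scale of $\varepsilon$ is
$110 \pm 30$ pN A (about 1.58 kcal/mol), used only by the
`force_to_pN()` / `energy_to_kcal()` converters; $\tau$ is of order
1 ns in the overdamped regime.

**Native contacts** come from the atomic overlap criterion: residues
are in contact if any heavy-atom pair overlaps once van der Waals radii
are inflated by 1.24 (the inflection point of the 12-6 potential).
Radii follow a Tsai/Taylor/Chothia-style atom-class table (sp3 carbon
1.88, sp2 carbon 1.76, nitrogen 1.64, carbonyl-type oxygen 1.42,
hydroxyl/carboxylate oxygen 1.46, sulfur 1.77 A), overridable through a
radii file; the exact class granularity of the literature radii set is
not recoverable from the source, so contact counts on real structures
can shift by a few contacts with the oxygen classification -- the
radii-sensitivity hook (`native_contacts(radii = ...)`) exists for
exactly that reason. Same-chain pairs at sequence separation 1 or 2 are
excluded; inter-chain pairs never are. Calcium ions are single spheres
of radius 1.53 A whose contacts are never sequence-excluded; ion beads
are held only by their native contacts (no bonds, no chirality).

A useful consistency property follows from the criterion itself: two
C$\alpha$ atoms closer than $1.24 \times 2 \times 1.88 = 4.66$ A
always overlap, so any non-native pair is farther than that at native
coordinates -- beyond the 4 A repulsion range. The native configuration
is therefore an exact stationary point of the full Hamiltonian, which
the tests assert at $10^{-8}\ \varepsilon$/A.

**Dynamics** follow the Langevin equation
$m \ddot{\vec r} = \vec F - \gamma \dot{\vec r} + \vec\Gamma$ with
$\gamma = 2 m/\tau$ (overdamped), integrated by the fifth-order Gear
predictor-corrector with $\Delta t = 0.005\,\tau$ and the corrector
coefficients appropriate for velocity-dependent forces ($c_0 = 3/16$).
The quoted noise dispersion $\sqrt{2\gamma k_B T}$ is discretized in
the standard way as a per-step random force of standard deviation
$\sqrt{2\gamma k_B T/\Delta t}$; the equipartition tests (positional
variance $k_B T/k$ in a harmonic well, kinetic energy
$k_B T/2$ per degree of freedom) validate the combination of
discretization and integrator, and an undamped zero-temperature run
conserves energy to $10^{-4}\ \varepsilon$ over $10^4$ steps. All
randomness flows through R's RNG, so trajectories are bit-reproducible
for a fixed seed.

### Protocols

* **Thermal stability**: $P_0$ is the fraction of sampled frames
  (pooled over time and independent trajectories) in which *every*
  native contact is present, $Q$ the mean fraction of present
  contacts; a contact is *present* when $r_{ij} < 1.5\,\sigma_{ij}$ --
  the same cutoff the pulling protocol uses for breaking, chosen for
  internal consistency. $P_0 \le Q$ always; $T_0$ is where $P_0$
  crosses one half (linear interpolation).
* **Thermal unfolding**: a trajectory unfolds when all *nonlocal*
  contacts (sequence separation $|i-j| > 4$; ion contacts count as
  nonlocal) are simultaneously broken; $t_u$ is the median over
  trajectories with censored runs entering as $+\infty$, so the median
  is finite only when more than half the runs unfold, and the
  unfolded fraction is reported alongside.
* **Pulling**: harmonic springs of stiffness $K = 0.12\
  \varepsilon/\mathrm{\AA}^2$ attach to the N-terminal beads of the
  two chains; one is fixed, the other moves at constant speed (the
  reference speed is $v_p = 5\times10^{-5}$ A/$\tau$, about 5 nm/ms)
  along the line joining the attachment points, at $T = 0.3\
  \varepsilon/k_B$. The spring force is averaged over 0.5 A windows of
  spring displacement $d = v_p t$; $F_{\max}$ is the largest windowed
  peak. Contacts may break and re-form; the *last* break displacement
  per contact is what the scenario analysis uses. Dissociation is
  declared when all interface contacts have stayed broken over 1 A of
  further displacement. Note the stated correspondence of $K$ to
  "about 1 pN/nm" is dimensionally inconsistent with
  $\varepsilon = 110$ pN A (which makes $0.12\ \varepsilon/\mathrm{\AA}^2
  \approx 13$ pN/A); the $\varepsilon$-unit value is authoritative
  here, and conversions go through `force_to_pN()`.
* **Long/short classification**: stretching ensembles split into
  trajectories that dissociate early (short) or extend far before
  dissociating (long). No classifier threshold is inherited from the
  source analysis, so by default `scenario_report()` places it midway
  between the two modes of the dissociation-displacement distribution
  (univariate 2-means, with a min-max midpoint fallback for degenerate
  ensembles); it is user-overridable, and the class fractions carry a
  Wilson binomial confidence interval.

## What the synthetic generators emulate

* `make_landscape()` builds $\Delta G(Z, \varphi)$ surfaces as a
  baseline plus Gaussian basins with circular angle handling; the
  defaults plant the two binding-mode basins at $\varphi = 3$ and
  $173$ degrees with depths $-38.2$ and $-28.7$ kcal/mol, the
  reference mode-I/mode-II minima of the wild-type system. Replicas
  $k$ receive independent Gaussian jitter (default amplitude when
  enabled: 1 kcal/mol, the scale of the reported spread of per-replica
  minima). The manifest stores analytic ground truth, including the
  mode-probability ratio by dense quadrature, against which the
  aggregation pipeline must agree to 1%.
* `make_helix()` builds poly-alanine helices from ideal peptide
  geometry (NeRF internal-coordinate construction, $\phi = -57$,
  $\psi = -47$), giving genuinely helical heavy-atom arrangements:
  3.80 A virtual bonds, carbonyl-to-amide O(i)-N(i+4) distances near
  3.1 A, and the (i, i+3)/(i, i+4) overlap-contact pattern.
* `make_two_body_complex()` and `make_hairpin()` pack two helices
  antiparallel at an 8.5 A axis separation with a 90 degree azimuthal
  twist of the second helix. The twist interdigitates the side chains
  so the closest interatomic approach (~2.9 A) is that of a packed
  interface rather than a clash; 8.5 A is a typical helix-packing
  distance. The hairpin's loop is a geometric arch tall enough that no
  (i, i+2) pair enters the 4 A repulsion range, preserving exact
  native-state stationarity.

What the toys do **not** emulate: side-chain diversity (alanine-only
decoration), sequence-dependent contact energetics, the real
dockerin's calcium-loop architecture, and crystallographic detail such
as alternate conformations. Passing the property suites on these
fixtures validates the machinery -- contact detection, Hamiltonian,
integrator, protocols, estimators -- not any biological claim about a
particular protein; analyses of real systems require the user to
supply the crystal structures (they are not redistributed with the
package) and an external per-pose energy backend for the landscapes.

## Problem sizes and determinism

The shipped tests and the acceptance script run deliberately small
ensembles chosen as the package's own test conditions: toy systems of
20-30 beads, thermal sampling of order $10^4$-$10^5$ steps over a
handful of trajectories, 50 unfolding runs per temperature, and
pulling speeds of $5\times10^{-3}$-$5\times10^{-4}$ A/$\tau$ on toys
(the reference speed applies to production runs on real complexes).
Production-scale counts (hundreds of trajectories, $10^5\,\tau$
trajectories) are reachable through the same interfaces by raising the
respective arguments. Every stochastic stage takes an explicit seed,
and composite runs derive per-stage seeds from a single root seed
recorded in the run manifest, so identical configurations reproduce
identical outputs byte for byte.

## Known limitations

* Per-pose energies are an external input: the empirical energy
  function that produced the reference landscapes (and its printed
  minima tables) is out of scope, as are all-atom MM/PBSA binding
  energies. The landscape interface is a plain TSV grid, so any
  backend can feed it.
* The long/short fractions of the reference stretching study require
  tail-modeled structures and ensembles of ~100 long trajectories;
  here the classifier and its estimators are validated on synthetic
  bimodal ensembles instead.
* Pose generation is rigid-body; no backbone or side-chain
  flexibility.
* Contact counts on real crystal structures are sensitive at the
  margin (a few contacts) to the oxygen-class radii; the radii table
  is explicit and swappable rather than hidden.
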