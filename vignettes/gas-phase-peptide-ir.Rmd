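---
title: "Methods: gas-phase peptide conformers from IR action spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gas-phase peptide conformers from IR action spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformIR)
```

## Scope

Neutral peptides in a cold molecular beam can be interrogated by infrared
multiple-photon dissociation combined with vacuum-ultraviolet single-photon
ionisation (IRMPD--VUV): tuning a free-electron laser across the mid-IR and
recording the fragmentation yield gives a conformer-averaged IR action
spectrum without requiring a UV chromophore. Assigning structure then rests
on comparing that spectrum against predictions for candidate conformers and
on characterising those conformers geometrically. `conformIR` implements
the full computational side of such a study for free (NH2/COOH-terminated)
polyalanine-like peptides:

* extraction of the IR cross-section from raw parent/fragment ion counts
  (`cross_section_point()`, `build_action_spectrum()`);
* prediction of IR spectra from harmonic stick spectra
  (`scale_frequencies()`, `broaden()`, `composite()`) and from molecular
  dynamics dipole trajectories (`psd()`, `cross_section()`,
  `average_runs()`, `makeup_broaden()`);
* calibration and inversion of the integrator-induced frequency blue shift
  of finite-time-step dynamics (`fit_shift_law()`, `predict_shift()`,
  `correct_frequency()`);
* conformer structural analysis: backbone torsions and C/G/A/T
  classification (`compute_torsions()`, `classify_angle()`,
  `descriptive_name()`), hydrogen bonds from electron-density grids or
  geometry (`detect_hbonds_nci()`, `detect_hbonds_geometric()`),
  pseudo-ring orders (`ring_order()`), MRSSAD conformer distances and
  threshold graphs (`mrssad()`, `build_graph()`), and Boltzmann abundances
  (`rank_and_weight()`).

Electronic-structure computation itself (geometry optimisation, Hessians,
ab-initio MD forces) is out of scope; the package consumes its columnar
exports and replaces it, for testing, with analytic model potentials.

## The IRMPD detection model

During the IR macropulse each ground-state molecule is excited with rate
$\Phi\sigma$; once excited it absorbs further photons and dissociates, so
the intact fraction after exposure time $\tau$ is $e^{-\Phi\sigma\tau}$.
The VUV pulse ionises parents and fragments with equal total probability,
and an unknown, IR-independent fraction of the parent ions dissociates
during or after ionisation. Recording parent ($P$) and summed-fragment
($F$) counts with the IR on and off therefore gives

$$\sigma(\nu) \;=\; \frac{1}{\Phi\tau}\left[
  \ln\frac{P_\mathrm{off}}{P_\mathrm{off}+F_\mathrm{off}} -
  \ln\frac{P_\mathrm{on}}{P_\mathrm{on}+F_\mathrm{on}}\right],$$

where the off-term cancels the post-ionisation fragmentation exactly
because it does not involve the IR beam. Negative values (noise below
baseline) are flagged but never clamped: clamping would bias the noise
statistics of weak bands. The fluence measure $\Phi\tau$ is proportional
to pulse energy divided by photon energy, i.e. to $E/\nu$
(`fluence()`); only linear fluence normalisation is implemented. The
generative twin of this model (`gen_ion_counts()`) draws binomial counts
from exactly these assumptions, which is what makes the estimator
testable: recovery of a known $\sigma(\nu)$ within binomial standard
errors, and invariance of the expectation to the fragmentation fraction.

## Harmonic spectra

Calculated harmonic bands are corrected in two ways, each with one tunable
constant:

* **Frequency scaling**, default `0.98` -- the empirical hybrid-functional
  correction for systematic overestimation of harmonic frequencies.
  Applied before broadening.
* **Broadening**, default $\sigma(\nu) = 0.01\,\nu$ -- each band $(\nu, I)$
  becomes a Gaussian of mean $\nu$ and integrated area $I$ whose width
  matches the free-electron-laser line width, evaluated at the *scaled*
  frequency since the width is an instrument property at the observed
  position.

The default grid is 0.5 cm$^{-1}$ spacing over 300--1900 cm$^{-1}$,
covering the 340--1820 cm$^{-1}$ experimental window with margin; on this
grid every band's trapezoid integral retains its stick intensity to 0.1%.
Composites over conformers are pointwise abundance-weighted sums.
`similarity()` (cosine similarity of mean-subtracted curves, i.e. Pearson
correlation) is provided as a convenience score; no claim is made about
intensity normalisation between predicted and measured spectra, which is
why assignment remains a judgement call rather than an argmax.

## Dynamic spectra from dipole trajectories

Via the Fermi golden rule and the Wiener--Khintchine theorem, the
absorbance is proportional to the power spectral density of the electric
dipole. `psd()` subtracts the mean per Cartesian component, applies a Hann
window (to curb spectral leakage), zero-pads (default factor 4, sharpening
the frequency grid to $1/(c\,N_\mathrm{pad}\Delta t)$), transforms, and
sums squared magnitudes over components. Normalisation is by the padded
length, so without a window the total one-sided power equals the
time-domain variance times the sample count (Parseval), which the tests
assert to $10^{-6}$.

Three absorbance prefactors are available in `cross_section()` --
`psd-only`, `nu-squared` (default) and `quantum-harmonic` -- because the
literature differs on the harmonic quantum correction; none is asserted as
canonical, and all downstream checks rely only on peak positions, which
the prefactor does not move.

The reference protocol is mirrored exactly: initial velocities are
Maxwell--Boltzmann at **twice** the target temperature (so each mode ends
up with average energy $k_BT$ after equipartition), linear and angular
momenta are removed by projection, trajectories run 2--3 ps at 0.5 fs, and
spectra are averaged over 30 runs (`psd_options(runs = 30)`), since a
single run's peak heights depend on the random velocity draw.

A trajectory of length $\tau$ is already broadened by its finite length,
with an intrinsic width of order $1/(c\tau)$. `makeup_broaden()` therefore
convolves with a Gaussian of variance
$\sigma_\mathrm{target}^2(\nu) - \sigma_\tau^2$, with
$\sigma_\tau = \kappa/(c\tau)$, skipping any grid point where the
difference is non-positive. The constant $\kappa$ defaults to 0.5
($\sigma_\tau = 1/(2c\tau)$) and is configurable; every test relies only
on the variance-composition contract (output variance equals target
variance minus intrinsic variance), not on a particular $\kappa$. Because
$\sigma_\mathrm{target}$ depends on $\nu$, the convolution kernel is
evaluated per grid point -- slower than an FFT convolution but faithful to
$\sigma = 0.01\nu$. Dynamic spectra are frequency-scaled by the same 0.98
factor, after the transform.

## The time-step blue shift

A symplectic integrator does not oscillate at the physical frequency: on a
harmonic mode of angular frequency $\omega$, velocity Verlet produces an
exactly periodic sequence at
$\omega_D = (2/\Delta t)\,\mathrm{asin}(\omega\Delta t/2)$
(`analytic_vv_frequency()`), always blue-shifted. In the dimensionless
variable $x = \nu c \Delta t$ (non-angular convention;
`dimensionless_frequency()`) the shift is molecule-independent and well
described by a power law $\Delta x = a\,x^b$. `fit_shift_law()` fits
$(a, b)$ by least squares in log--log space, excluding non-positive shifts
with a warning, and returns a classed model object with `print`, `coef`,
`summary` and `predict` methods. Two named profiles ship:

* `"admp-b3lyp-n07d"`: $a = 2.95$, $b = 3.25$, the calibration obtained
  with an extended-Lagrangian DFT propagator. Evaluated at 1900 cm$^{-1}$
  and 0.5 fs it predicts a shift of about 1.87 cm$^{-1}$ -- under the
  2 cm$^{-1}$ level below which the shift is negligible for assignment.
  Reproducing these two constants themselves requires the original
  electronic-structure propagator and is a non-goal.
* `"velocity-verlet"`: $a = (2\pi)^2/24 \approx 1.645$, $b = 3$, the
  leading-order Taylor expansion of the closed form above. This is the
  law the package's own model dynamics must reproduce, and does: fitting
  simulated shifts at $\Delta t \le 0.5$ fs recovers both constants (the
  exponent within 0.05, the constant within 2%). At longer steps
  ($\Delta t \gtrsim 1$ fs at mid-IR frequencies) the $O(x^2)$ correction
  to the leading term is no longer negligible -- at
  $x \approx 0.14$ it contributes $\sim$9% of the shift -- so a log--log
  fit over such a range returns an effective constant visibly above
  $(2\pi)^2/24$ even with error-free inputs. This is a property of the
  integrator, not a fitting artefact, and the test suite documents it.

`correct_frequency()` inverts the forward map
$\nu_H \mapsto \nu_H + \Delta\nu(\nu_H)$ by Newton iteration (tolerance
$10^{-8}$ cm$^{-1}$, at most 100 iterations), enabling the
long-time-step-then-correct workflow; forward and inverse round-trip to
$10^{-6}$ cm$^{-1}$ across $\nu \in [100, 1900]$ cm$^{-1}$,
$\Delta t \in [0.25, 3]$ fs.

`width_match_temperature()` answers when a *classical* trajectory
distribution is as wide as the quantum ground-state density of a mode: we
equate the classical thermal energy with the vibrational quantum,
$k_BT = hc\nu$, giving $T = 1439$ K at 1000 cm$^{-1}$ ("around 1500 K").
An alternative convention -- equating classical and quantum ground-state
*position variances* -- gives about half that; the energy-matching choice
is the package's decision and is documented rather than asserted as
unique. Either way the conclusion stands: the required temperature is far
above what a floppy peptide survives, which is why low-temperature
dynamic spectra underestimate anharmonic widths.

## Conformer structural analysis

**Torsions and names.** A free peptide of $n$ residues has $2n$
informative backbone angles: $\varphi_N$ (defined by extending the
backbone to the centre of the amino group, implemented as the midpoint of
the two amine hydrogens), the interior $\varphi/\psi$ pairs, and $\psi_C$
(to the hydroxyl oxygen of the COOH). Peptide $\omega$ angles are locked
trans and side-chain $\chi$ angles are retained only as metadata. Each
informative angle is classified into the conventional symmetric sectors --
cis $|\theta| < 30°$, gauche $30° \le |\theta| < 90°$, anticlinal
$90° \le |\theta| < 150°$, trans $|\theta| \ge 150°$ -- and concatenated
N-terminus leftmost. Signs are not marked (G$^+$ and G$^-$ both read G);
the classification is even in $\theta$ by construction. Where a detected
hydrogen bond closes a pseudo-ring, the letters of exactly those torsions
whose rotatable bond lies on the covalent ring path are replaced by one
bracketed token `[b]`, `[g]` or `[C5]`, keeping the string unambiguous: a
gamma-turn consumes two letters ($\varphi/\psi$ of the bridged residue), a
beta-turn four, the N-terminal C5 ring the $\varphi_N\psi_1$ pair.

**Ring orders.** The order of the pseudo-ring closed by a hydrogen bond is
the number of atoms on the shortest covalent path from the donor hydrogen
to the acceptor, inclusive of both endpoints: 5 for the intra-unit
NH···O=C contact (C5), 7 for a gamma-turn ($i \to i+2$), 10 for a
beta-turn ($i \to i+3$). Two adjacent $i \to i+3$ rings are the signature
of a short 3$_{10}$-helix. Intermolecular contacts have undefined (NA)
order.

**Hydrogen bonds.** The primary assignment is NCI-style, on an
electron-density grid: a candidate donor-H···acceptor pair is an H-bond
iff at some grid point in the corridor between H and acceptor the density
exceeds 18 nm$^{-3}$ with reduced density gradient
$s = |\nabla\rho| / (2(3\pi^2)^{1/3}\rho^{4/3}) \le 0.5$ (evaluated in
atomic units) and a negative second Hessian eigenvalue; 15--18 nm$^{-3}$
grades as a weak interaction, and the reported strength is the maximum
qualifying density. The 18 nm$^{-3}$ threshold is deliberately not set
higher -- C5 and C7 ring densities sit just above it. Derivatives come
from central finite differences at one grid spacing; the corridor default
excludes the 20% of the segment nearest each nucleus, where the density is
nuclear rather than interactional, and spans a 0.5 A radius. Densities are
held internally in nm$^{-3}$ (the unit of the thresholds); atomic-unit
cube files are converted on input (1 a.u. = 6748.33 nm$^{-3}$). When no
grid is available, a geometric fallback (H···A $\le$ 2.5 A, donor-H···A
angle $\ge 120°$ -- common literature cutoffs) gives the same pair set on
the synthetic fixtures, with strength left undefined.

**MRSSAD.** Conformer distance is the minimal root-sum-square of atom
displacements over proper rigid motions and atom reindexings,
$\sqrt{N}\times$RMSD at the optimum, with equal weight for every atom. Two
choices matter. Reflections are excluded: the peptide is chiral, and its
enantiomer must not collapse to distance zero. Reindexing is restricted to
orbits of the covalent-graph automorphism structure refined by element
(computed by iterative neighbourhood-signature refinement) -- in practice
methyl hydrogens and NH2 hydrogens -- because the full permutation group
is both chemically wrong and intractable. The minimum is found by
alternating optimal superposition (Kabsch with the determinant sign
constrained) and optimal within-orbit assignment until a fixed point, over
10 orbit-respecting random starts (seed 0 by default); exhaustive
enumeration is used for assignment within orbits of up to six atoms and
maximum-weight bipartite matching (igraph) beyond. On instances small
enough for brute force the result equals the exhaustive minimum, and
identity, symmetry and the triangle inequality hold on sampled triples.

**Graphs and abundances.** `build_graph()` draws edges between conformers
closer than 10 A and computes the minimal spanning forest by Kruskal's
algorithm with lexicographic tie-breaking (so output is deterministic);
`rank_and_weight()` assigns Boltzmann abundances
$e^{-G_i/k_BT}/\sum_j e^{-G_j/k_BT}$ at 400 K (the laser-desorption
temperature estimate), subtracting the minimum energy before
exponentiation, and short names `A<rank>` by ascending Gibbs energy.

## The synthetic-data engine

`model_system()` + `simulate_md()` integrate site-harmonic, pairwise
spring, or Morse potentials with velocity Verlet in amu/A/fs units,
recording the point-charge dipole each step and aborting if the total
energy exceeds ten times its initial value. What this emulates is the
*protocol and numerics* of ab-initio dynamics -- velocity initialisation
at $2T$, momentum projection, integration, dipole spectra, the integrator
blue shift -- at desk scale. What it does not emulate is the physics of a
real peptide's potential surface: anharmonic mode coupling, conformational
transitions and dissociation are absent, so passing tests validate the
estimators and the processing chain, not the accuracy of any dynamical
prediction for a real molecule. The other generators
(`gen_toy_peptide()`, `gen_density_grid()`, `gen_dipole_signal()`,
`gen_ion_counts()`) are first-class tested code and provide ground-truth
fixtures: ideal-geometry peptides realising prescribed torsions to better
than a degree (built atom-by-atom from internal coordinates), density
grids with controllable hydrogen-bond bridges, cosine dipole signals with
known mode content, and ion counts from a known cross-section. All are
seed-deterministic.

## Numerical choices and degenerate inputs

* Bond perception: distance $\le 1.15 \times$ sum of covalent radii;
  atoms closer than 0.4 A are an error. Only ring-path topology depends
  on this heuristic.
* Dipole files must be uniformly sampled; non-uniform timestamps are an
  error, never silently interpolated (interpolation biases the PSD).
* Collinear four-point sets have no dihedral and raise a
  degenerate-geometry error; classification requires angles in
  $(-180°, 180°]$.
* PSD peak positions can be refined off-grid
  (`psd_peak_frequency(refine = TRUE)`) by maximising the windowed DTFT
  magnitude around the strongest bin -- used wherever sub-bin accuracy is
  needed, e.g. measuring integrator shifts of order 0.01 cm$^{-1}$.
* Newton inversion of the shift law starts at $\nu_D$ and converges in a
  handful of iterations over the entire working range; non-convergence
  raises rather than returning a best guess.
* Spanning-forest ties are broken lexicographically; duplicate action-
  spectrum frequencies are averaged with a warning; empty conformer sets,
  zero-variance spectra and mismatched grids are errors.
* Problem sizes in the test suite are chosen for a desk machine: 21
  harmonic-oscillator simulations of a few thousand steps for the
  integrator law, $10^5$--$10^7$ counts per frequency for the IRMPD
  estimator, 6-atom structures for exhaustive MRSSAD enumeration, and up
  to 200 sampled triples for the metric properties. The full suite runs
  in well under a minute.

## Known limitations

* The NCI implementation evaluates criteria at grid nodes in the contact
  corridor; very coarse grids can miss a narrow density ridge (a coverage
  error is raised only when the corridor contains no nodes at all).
* `annotate_backbone()` walks free linear peptides with NH2 and COOH
  termini; capped, cyclic or branched peptides are rejected. How backbone
  atoms are identified is not prescribed by the problem; any consistent
  annotation is acceptable, and this one is the simplest that covers the
  target molecules.
* The alternating MRSSAD solver is exact on all brute-force-checkable
  instances but carries no global-optimality proof for large molecules;
  raising `n_starts` tightens it at linear cost.
* Fitting conformer weights to an experimental spectrum, mode-assignment
  labelling, and graph layout are out of scope.
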