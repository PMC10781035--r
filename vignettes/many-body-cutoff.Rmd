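---
title: "Truncating the many-body term of a polarizable water model at a coordination shell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Truncating the many-body term of a polarizable water model at a coordination shell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`dcwater` implements a rigid, polarizable, 4-site water potential of the
Dang--Chang (DC) type.  Each molecule is a rigid body with an oxygen, two
hydrogens, and a massless M site on the H-O-H bisector.  The interaction
energy of a cluster is

$$
E \;=\; \underbrace{\sum_{i<j} 4\varepsilon\!\left[\Big(\tfrac{\sigma}{d_{ij}}\Big)^{12}
      - \Big(\tfrac{\sigma}{d_{ij}}\Big)^{6}\right]}_{E_\mathrm{LJ},\ \text{O--O}}
\;+\; \underbrace{\sum_{i<j}\sum_{a,b} \frac{k\, q_a q_b}{r_{ab}}}_{E_\mathrm{Coul},\ \text{H and M sites}}
\;+\; E_\mathrm{pol},
$$

with the polarization (induction) energy
$E_\mathrm{pol} = -\tfrac{k}{2}\sum_i \boldsymbol\mu_i \cdot \mathbf E_i^0$,
where the induced point dipoles on the M sites solve the self-consistency
equation

$$
\boldsymbol\mu_i \;=\; \alpha\Big(\mathbf E_i^0 +
  \sum_{j \ne i} \mathbf T_{ij}\, \boldsymbol\mu_j\Big),
$$

$\mathbf E_i^0$ being the field of the fixed charges of the other
molecules at the M site of molecule $i$ and $\mathbf T_{ij}$ the
point-dipole interaction tensor.  $E_\mathrm{pol}$ is the *many-body*
(nonadditive) part of the model: the dipoles respond to all molecules at
once, so it cannot be written as a pair sum.

The package's question is how much of this many-body term is carried by
the near neighborhood of each molecule.  To that end a **cutoff radius**
$r$ truncates the polarization term -- and *only* the polarization term:
molecule pairs whose O--O distance exceeds $r$ contribute neither to
$\mathbf E_i^0$ nor to the dipole--dipole couplings $\mathbf T_{ij}$.
The Lennard-Jones and Coulomb sums are never truncated.  For $r$ below
the closest O--O contact the model degenerates to the pure pair
potential; for $r \ge d_\mathrm{max}$ (the largest O--O distance in the
cluster) it is exactly the full polarizable model.

### Parameters

The default parameter set is the Dang--Chang model, transcribed from
Dang & Chang, *J. Chem. Phys.* **106**, 8149 (1997), since the
first-principles constants are what the analysis is defined on:
$\varepsilon = 0.1825$ kcal/mol, $\sigma = 3.234$ Å (O--O),
$q_\mathrm{H} = +0.519\,e$, $q_\mathrm{M} = -1.038\,e$,
$\alpha = 1.444$ Å$^3$, with the gas-phase monomer geometry
($r_\mathrm{OH} = 0.9572$ Å, $\theta_\mathrm{HOH} = 104.5^\circ$,
$r_\mathrm{OM} = 0.215$ Å).  These reproduce the monomer dipole of
1.85 D.  Everything is configurable through `dc_params()` or a YAML file
(`read_water_params()`); the packaged defaults live in
`inst/extdata/dc_params.yaml`.  The Coulomb constant
$k = 332.0637$ kcal mol$^{-1}$ Å $e^{-2}$ is an explicit parameter so no
unit convention is hidden.

Two formulation choices deserve note:

* **Mutual induction.** By default the self-consistency includes the
  dipole--dipole coupling (full linear response), the standard DC
  formulation.  A charges-only mode (`mutual = FALSE`, i.e.
  $\boldsymbol\mu_i = \alpha \mathbf E_i^0$) is available for
  sensitivity analysis.
* **Cutoff semantics.** The truncation is a *hard* cutoff on the
  symmetric O--O distance relation (closed ball: ties count), applied
  identically to the static field and to the dipole couplings.  This
  makes "the number of molecules interacting via the polarization term"
  well defined and produces the step-like coordination counts described
  below.

### Numerical treatment of the induction

The dipole equations are solved either by a direct solve of the
$3N \times 3N$ linear system (default) or by fixed-point iteration; the
two agree to $10^{-10}$ whenever the iteration converges, which the test
suite asserts.  The system matrix $I - \alpha T$ is symmetric and is
factorized by Cholesky: **positive definiteness is required** for the
linear-response energy to be bounded, and a failed factorization is
reported as a polarization catastrophe rather than silently "solved".
The model carries no Thole-style damping (faithful to the DC
formulation), so close contacts genuinely diverge; evaluations are
additionally rejected as degenerate when any intermolecular charged-site
pair comes below 0.7 Å or any O--O pair below 0.1 Å -- far inside any
physical geometry (the shortest H$\cdots$M contact in bound clusters is
about 1.5 Å), but enough to keep the optimizer out of the unphysical
region.  Induced dipoles above 2 $e$Å (an order of magnitude beyond
physical values) are likewise treated as a catastrophe.

### Gradients

Local minimization uses analytic derivatives with respect to the
rigid-body coordinates: position of the O atom plus an angle-axis
rotation vector per molecule (gimbal-lock-free and smooth, which is why
no canonical reduction of the rotation vector is applied during
optimization -- only when comparing poses).  The polarization gradient
uses the variational property of the converged dipoles: at the SCF
solution the energy is stationary in $\boldsymbol\mu$, so only the
explicit coordinate dependence of $\mathbf E^0$ and $\mathbf T$
contributes.  The test suite checks the gradient against central finite
differences to $10^{-5}$ relative error.

## Global optimization

`basin_hopping()` implements the standard protocol for rigid molecular
clusters: from a random start, perturb *all* molecules, quench with
L-BFGS, and accept or reject the quenched energy by a Metropolis rule at
$k_BT = 3$ kcal/mol.  Moves alternate in blocks of 100 translational and
200 angular (rotation-vector) perturbations, both uniform-in-cube; after
each block the step size is multiplied by 1.05 if the measured
acceptance exceeded the 20% target and by 0.95 otherwise.  Four
independent trajectories (per-trajectory seeds derived from the main
seed) are run by default and the best quenched minimum is re-polished at
a tight gradient tolerance ($10^{-6}$).

Choices made where the protocol is genuinely open:

* Moves perturb every molecule simultaneously (standard practice for
  clusters of this size; single-molecule moves mix more slowly).
* Initial step sizes are large (1.2 Å and 1.2 rad).  Starting small and
  letting the $\times 1.05$ adaptation grow the steps wastes the early
  part of short runs; starting large and adapting *down* toward the 20%
  target reaches the productive large-step regime immediately.  With
  these settings the putative global minima of the hexamer and octamer
  are found reliably within a few thousand steps.
* Quenches during the search use a loose gradient tolerance
  ($10^{-2}$ kcal/mol/Å, iteration cap 200): basins are already
  distinguished at that accuracy and the final answer is re-polished.
  The quench line search caps the per-coordinate displacement at 0.5
  per iteration, which prevents early overlap-driven steps from
  scattering the cluster.
* Quenched configurations whose O--O graph at 5 Å is disconnected (an
  evaporated molecule) are rejected: the object of study is the bound
  cluster.
* The dissociation guard, the Metropolis rule and the step adaptation
  operate on quenched energies only, so the search is a Markov chain on
  the set of local minima, as in standard basin hopping.

Reproducibility is exact: identical `(seed, settings, params, N)` give
bit-identical trajectories (the move stream runs on R's RNG).

## Structural observables

* `oo_distances()`: the multiset of the $P = N(N-1)/2$ O--O distances.
* `permutation_rmsd()`: the structural deviation between two clusters,
  $\min_\pi \sqrt{\sum_i (R_i - r_{\pi(i)})^2 / P}$ over pairings $\pi$
  of the distance multisets.  Sorting both multisets and pairing in
  order attains the minimum for squared loss (rearrangement inequality);
  an exhaustive $P!$ search is kept as a test oracle for small clusters.
  Normalizing by the number of distances $P$ makes the result a
  per-distance RMS in Å, commensurate with thresholds like 0.05 Å; a
  divide-by-$N$ variant is exposed for sensitivity checks.  The metric is
  invariant under relabeling and rigid motions, and deliberately
  hydrogen-blind: clusters with the same oxygen frame but different
  hydrogen-bond orientation ordering compare equal at the O--O level.
* `avg_interacting()`: $\langle N_i \rangle$, the mean over molecules of
  the number of molecules (the molecule itself included) within O--O
  distance $r$ -- the average number coupled by the truncated
  polarization term.  It is a non-decreasing step function of $r$ with
  $\langle N_i\rangle(0^+) = 1$ and $\langle N_i\rangle(\infty) = N$;
  plateaus mark complete coordination shells (4 for the cubic octamer's
  first shell, 5 for tetrahedral bulk-like coordination).
* `d_max()` and `shell_radii()` (plateau radii detected as midpoints of
  gaps in the distance multiset).

## The cutoff-scan pipeline

`scan_cutoffs()` re-optimizes a cluster size at each radius of a grid
(default 1--8 Å in 0.5 Å steps plus a 20 Å reference radius, which
resolves the first-shell region near 3 Å and the inter-shell region near
4 Å) and tabulates, per radius: the energy breakdown of the best minimum
found, its permutation RMSD to the full-potential reference, $\langle
N_i\rangle$, the percent energy deviation
$100\,|E - E_\mathrm{ref}|/|E_\mathrm{ref}|$, and $d_\mathrm{max}$.
The reference is always the basin-hopping minimum of the *same*
parameter set at the reference radius (`reference_minimum()`, which also
verifies that the reference radius exceeds $d_\mathrm{max}$ and that the
energy equals the untruncated evaluation exactly).  Per-radius searches
are independently seeded (seeds derived from the scan seed and the
radius), so records are reproducible and independent of execution order.

Two behaviors of the scan are worth knowing in advance.  The truncated
model can relax into *artificial* minima with energies below the full
polarizable model -- the truncation is not a variational approximation
-- and the location of the lowest such minimum (near 4 Å for the
octamer, between the first and second shells) is itself a result.  And
although only the polarization term is truncated, the Lennard-Jones and
Coulomb terms vary with $r$ too, as an indirect effect of the changing
minimum-energy structure.

## Problem sizes and what the tests show

The package's standard analysis runs at desk scale: reference searches
use 4 trajectories $\times\ 10^4$ steps (raise to $10^5$ per trajectory
for production work on larger clusters), per-radius scan searches use 2
trajectories $\times$ 1500 steps, and the shipped analysis covers
$N \in \{6, 8\}$.  At these budgets the hexamer and octamer searches
find the same best minimum from every trajectory and reproduce the
model's known structures: the hexamer trigonal prism with
$d_\mathrm{max} = 4.16$ Å and the distorted-cube octamer with
$d_\mathrm{max} \approx 4.85$ Å.  Larger sizes ($N = 10, 16, 20$) run
with the same functions but need the larger budget; nothing in the
test suite asserts about them.

The random-cluster generator used for starting configurations samples O
positions uniformly in a sphere of radius $1.5\,N^{1/3}$ Å with a 2.2 Å
minimum O--O separation and Haar-uniform orientations: dense enough to
quench into bound minima, separated enough that the first SCF solve is
well inside the positive-definite region.  It emulates nothing about
real water beyond these constraints -- starting-point quality only
affects how fast the search converges, not what the minima are, which is
why passing tests on these synthetic starts say something about the
potential and the optimizer rather than about real-water sampling.

## Limitations

* No Ewald/periodic electrostatics: clusters in vacuum only.
* Rigid monomers; no Thole damping (faithful to the DC model, but it
  means the potential is undefined at unphysically close contacts).
* The basin-hopping minimum is *putative*: global optimality is not
  provable, only made likely by trajectory consensus.
* The O--O distance metric cannot distinguish clusters that differ only
  in hydrogen-bond ordering on the same oxygen frame; that is a property
  of the chosen (distance-multiset) metric, not a bug, but it means a
  small RMSD does not imply identical hydrogen networks.
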