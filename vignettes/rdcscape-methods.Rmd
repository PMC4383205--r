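---
title: "Determining low-population interdomain states from replica-averaged RDC restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining low-population interdomain states from replica-averaged RDC restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcscape)
```

## The problem

Enzymes with two domains joined by a hinge often populate, besides their
ground state, minor conformational states with populations of a few
percent that are invisible to conventional structure determination but
functionally decisive — for example as intermediates in product release.
Residual dipolar couplings (RDCs) measured in weakly aligning media are
sensitive reporters of such states: the coupling of an internuclear
vector is an average over the whole conformational distribution, so a 13%
subpopulation with a different interdomain geometry leaves a measurable
imprint on the data even though no single structure shows it.

`rdcscape` implements the computational machinery for turning such data
into a conformational ensemble and a free-energy landscape:

1. **RDC back-calculation.** For a conformation with alignment tensor
   $A$ and a unit bond vector with direction cosines $\cos\varphi_i$,
   $D = D_{\max}\sum_{ij} A_{ij}\cos\varphi_i\cos\varphi_j$.
2. **Replica-averaged restraints.** $M$ replicas are simulated together
   and the restraint penalises the *mean* calculated coupling,
   $E_{\mathrm{RDC}} = \alpha\sum_i (D^{\mathrm{exp}}_i -
   \bar D^{\mathrm{calc}}_i)^2$ with
   $\bar D^{\mathrm{calc}} = \tfrac1M\sum_m D_m$, added to the
   conformational energy, $E_{\mathrm{Tot}} = E_{\mathrm{Pot}} +
   E_{\mathrm{RDC}}$.  Restraining the mean rather than each copy yields
   an ensemble consistent with the data in the maximum-entropy sense: the
   replicas are free to split between states so long as their average
   matches the measurement.
3. **Tensor prediction from shape and charge.**  During sampling the
   alignment tensor of each replica is computed from its own structure
   (not fitted to the data), so that conformational changes feed back
   into the predicted couplings.  An SVD fit is provided as a separate
   validation mode.
4. **Landscape analysis.**  Collected frames are histogrammed over a
   breathing angle $\theta$ (the angle between the centres of mass of an
   $\alpha$-domain region, a hinge region and a $\beta$-domain region)
   and the RMSD to a reference, and converted to free energies as
   $F = -k_B T\ln H(\theta, \mathrm{RMSD})$; basin populations, basin
   centres (mean and mode) and contact occupancies are computed from the
   same frames.
5. **Independent validation.**  Q factors against RDCs, $^3J_{HN-H\alpha}$
   couplings extracted from HNHA intensity ratios
   ($I_X/I_D = -\tan^2(2\pi\xi\,^3J)$, $\xi = 13.05$ ms) compared with
   Karplus back-calculation, and per-structure NOE satisfaction.

Because experimental data of this kind are rarely redistributable, the
package ships a synthetic-data generator with stored ground truth, which
is also how the package tests itself end to end.

## The toy system and what it emulates

`make_toy_protein()` builds a coarse-grained two-domain protein: two
helical domains of 12 residues at 10 Å from a 4-residue hinge, each
residue carrying an `N` particle and an `H` particle at 1.02 Å in a
deterministic, orientationally diverse direction (a pseudo N–H bond
vector), plus a deterministic partial-charge pattern on the `N`
particles for electrostatic alignment media.  The reference pose sits at
the ground-state breathing angle (58°); the minor state differs by an
in-plane swing of the β-domain about its hinge attachment to 49°.

`make_two_state_ensemble()` draws frames from the two poses with
probabilities $(1-p, p)$, default $p = 0.13$, and applies isotropic
Gaussian jitter (0.25 Å) per residue with the H riding its N rigidly, so
bond orientations remain state-defined.  `make_rdc_tables()` then
back-calculates couplings frame by frame — each frame with its own
shape/charge-predicted tensor in a steric and an electrostatic medium —
averages them (the population-weighted mean), and adds Gaussian noise at
5% of the per-medium RMS coupling.  The true labels, basin centres and
the midpoint basin boundary are stored alongside.

What the toy does **not** emulate: real side-chain packing and force-field
energetics, ligand chemistry, anisotropic domain shapes beyond a helix,
spin relaxation, or medium imperfections.  Passing tests therefore
demonstrate that the *inference machinery* is correct — that
population-averaged couplings plus replica-averaged restraints recover a
known minor-state population — not that any particular force field or
experimental setup would do so on a real protein.

## The conformational potential

`toy_potential()` stands in for a molecular-mechanics force field at desk
scale: harmonic chain bonds, harmonic restraints on all intra-domain
residue–residue distances (domain rigidity), cross restraints between the
α-domain and the hinge, and a double well in $\theta$ built as
$-k_BT_0\log$ of a two-Gaussian mixture with centres 58°/49°, widths
0.8° and configurable depths ($T_0 = 310$ K), plus an explicit Gaussian
barrier (12 kJ/mol, 1.5° wide) at the midpoint between the centres.
Three deliberate consequences:

* At $T_0$ the basin widths and weights of the $\theta$ marginal follow
  from the construction in closed form, so unrestrained sampler
  occupancies can be checked against quadrature (the Boltzmann sanity
  test).
* The system is genuinely two-state.  The barrier makes intermediate
  hinge angles rare, and the narrow wells bound the within-basin
  heterogeneity.  Both matter for *population* inference: couplings are
  locally linear in $\theta$, so if replicas could park between the
  basins, or drift far within them, small coordinated $\theta$ shifts
  across replicas could mimic a change in basin populations at almost no
  energetic cost, and the replica-averaged restraint would leave the
  basin count under-determined (the entropy of replica compositions then
  biases it upward — we observed exactly this with 2° wells and no
  barrier).  Spreading the required 9° of mean-angle shift over $n$
  replicas costs $k_BT_0\,(9°)^2/(2w^2 n)$ of hinge strain; with 0.8°
  wells and 15 compensating replicas that is about 10 kJ/mol per
  mimicked flip, well above the composition entropy scale, so the data
  pin the composition itself.
* The α-domain/hinge cross restraints make the β-domain swing the single
  soft mode.  The Monte Carlo move set matches: residue translations
  (rigid N–H pairs) relax local structure, and rigid β-domain swings
  about the breathing-plane normal through the hinge-attachment pivot
  move the system along the hinge mode.  Unconstrained 3D domain
  rotations are deliberately absent: they add rotational degrees of
  freedom that the potential does not restrain, and with replica-averaged
  restraints each individual replica is only $1/M$-coupled to the data,
  so unrestrained co-rotation decoheres the per-replica couplings and
  destroys population recovery.  A real force field would resist such
  twisting; the hinge-mode move set encodes the same physics directly.

Swing proposals mix two widths (70% at 2°, 30% at 12°): the small steps
relax within a basin, the large ones hop between basins in one step
(over the barrier), which keeps replica compositions equilibrated across
annealing cycles.  Both are symmetric, so detailed balance is preserved.

## Tensors during sampling

The alignment tensor is predicted from molecular shape and charge: the
director dyadic $\langle nn^\top\rangle - I/3$ is averaged over a
deterministic spherical Fibonacci grid of orientations, each weighted by
the accessible placement length between two parallel obstructions
(hard-sphere exclusion with a 2 Å probe radius and 120 Å spacing), and —
for charged media — by a Boltzmann factor from a Debye–Hückel screened
wall potential (15 Å screening length) acting on the particle charges.
The absolute degree of alignment is not separable from $D_{\max}$, so
each medium carries one dimensionless scale calibrated once on the
reference structure (8 Hz RMS coupling) and held fixed.

Two numerical choices matter and are worth stating plainly:

* **Tensors are recomputed exactly inside every swing proposal.**  On
  this system the locked/unlocked coupling contrast is carried almost
  entirely by the shape-driven tensor change (≈ 2.2 Hz rms) rather than
  by bond-vector rotation (≈ 0.3 Hz rms).  A cached tensor updated every
  $k$ accepted moves therefore blinds the restraint to exactly the
  signal it must feel, and the periodic cache refresh injects
  non-Metropolis energy jumps.  With exact per-proposal recomputation
  the restraint energy is a deterministic function of the coordinates
  and detailed balance holds exactly for swing moves.  Residue
  translations change the molecular shape by well under 0.1% of the
  coupling scale and leave tensors untouched; this is the one
  (quantified) approximation in the move set.  A cached projection
  matrix (orientations × atoms) per replica makes the exact scheme
  affordable.
* **The orientation grid is part of the forward model.**  Back-calculated
  couplings differ between Fibonacci grids of different size by ~0.6 Hz
  rms on this system — more than the 5% noise.  Synthesis and refinement
  must therefore use the same grid; the shipped pipeline uses 144
  orientations everywhere.  (For standalone tensor prediction the
  default is 256, and at least 100 is enforced.)

## The annealing protocol

`annealing_schedule()` keeps the full protocol bookkeeping — cycles
between 310 and 500 K, 250 ps per cycle at a nominal 2 fs time step
(125,000 integrator steps), frames collected at 1/ps in the final 50 ps
of the final 30 cycles of each replica, 24,000 frames at $M = 16$ — while
the desk-scale dynamics realises each cycle as Metropolis sweeps
(stepwise temperature switching; one sweep is one attempted move per
residue per replica).  The restraint weight is ramped geometrically
(×1.6 per stage) during an initial 310 K equilibration, halting early if
move acceptance falls below 20%, echoing the practice of raising α to
the largest stable value.

Two protocol parameters deserve their rationale:

* **Target weight α = 60 kJ/mol/Hz².**  At this weight the restraint
  energy separates neighbouring replica compositions by many $k_BT$, so
  the number of replicas in the minor basin is pinned near the
  data-optimal value; acceptance stays near 45%.
* **Ramp start α = 5 kJ/mol/Hz².**  The ramp must not pass through a
  nearly unrestrained regime: under the symmetric double-well prior half
  the replicas would drift into the minor basin early and the annealing
  then purges the excess only slowly, leaving a hysteresis bias in the
  collected populations.  Starting the ramp where compositions are
  already ordered removes the bias without affecting the maximum-entropy
  logic (the final weight, not the path, defines the restrained
  ensemble).  Raising the start much further is counterproductive: the
  stronger the restraint during the very first flips, the more the run
  freezes whatever composition it first reaches.

## Problem sizes

The shipped study conditions are chosen so every stage runs on a desk:
28-residue toy protein (56 particles), 56 restrained couplings over two
media, $M = 16$ replicas, 200-frame data synthesis, and an annealing run
of 16 cycles × (20 hot + 40 annealed) sweeps with a 60-sweep ramp,
collecting the final 12 sweeps of the final 12 cycles (2,304 frames) —
the same retained-to-total cycle ratio and end-of-cycle collection
window structure as the full-scale protocol.
Parameter recovery with these sizes returns the generator's 13% minor
population to within a few percentage points per seed; the test suite
asserts the 5-seed mean within ±5 points and a < 2% background when the
data contain no minor state.  The Boltzmann check uses 8 independent
unrestrained replicas (600 sweeps after 150 burn-in) against a
quadrature reference over the swing angle, with the between-chain spread
providing the standard error.

## Degenerate inputs and numerical conventions

Units are Å, kJ/mol, K, Hz throughout, with
$k_B = 0.0083145$ kJ/mol/K.  Free energies are undefined (NA), never
zero, on empty histogram bins.  Table readers reject rather than drop:
duplicate keys, non-positive uncertainties and unknown media are errors
naming the offending row, and an experimental coupling without a
matching bond vector is a hard mapping error (silent mismatch being the
classic RDC-pipeline bug).  Basin partitions are θ thresholds; a
polygonal partition in $(\theta, \mathrm{RMSD})$ is not implemented
because the toy basins — like the paper-style boundary θ < 50° — are
separable in θ.  HNHA extraction uses the principal branch
($2\pi\xi J < \pi/2$), discards glycines and zero diagonal intensities,
flags cross peaks below the noise, and propagates intensity errors to
first order with a 5% relative floor.  The Karplus coefficients
(A = 7.09, B = −1.42, C = 1.55 Hz, on $\varphi - 60°$) are explicit
arguments, and coarse-grained chains without full backbones fall back to
a four-particle pseudo-torsion so the validation path stays exercisable
on the toy system.

## Known limitations

* The sampler's move set is specialised to the two-domain hinge
  architecture the generator builds; it is not a general-purpose
  conformational sampler.
* Jitter moves hold tensors fixed (quantified above as negligible here);
  systems whose alignment is sensitive to sub-Å local moves would need
  exact recomputation for translations too.
* The steric/electrostatic medium model is a planar-obstruction
  caricature adequate for generating and refining self-consistent
  synthetic data; absolute tensor magnitudes are calibrated, not
  predicted.
* NOE satisfaction is per-structure (matching ensemble-validation
  practice), not $r^{-6}$-averaged.

## A minimal run

```{r example, eval = FALSE}
toy   <- make_toy_protein(generator_spec(minor_population = 0.13))
media <- calibrate_default_media(toy, n_orient = 144)
two   <- make_two_state_ensemble(toy, 200, seed = 1)
rdc   <- make_rdc_tables(two$ensemble, toy, media, seed = 1001,
                         n_orient = 144)

sys   <- build_system(toy, toy_potential(), rdc, media, M = 16)
sched <- annealing_schedule(cycles = 16, sweeps_high = 20, sweeps_low = 40,
                            collect_ps = 12, cycles_retained = 12,
                            equil_sweeps = 60)
run   <- run_annealing(sys, sched, seed = 1)

basin_population(run$ensemble, toy$regions,
                 basin_partition(two$truth$boundary))
```
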