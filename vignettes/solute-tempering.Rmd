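---
title: "Solute tempering on toy molecular systems: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solute tempering on toy molecular systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The sampling problem

Flexible loops — the CDR-H3 loop of antibodies and nanobodies being the
canonical case — relax on timescales far beyond what plain constant-
temperature simulation reaches: a start model trapped on the wrong side of
an isomerisation barrier (for instance a proline peptide bond built cis
instead of trans) simply stays there.  Replica exchange with solute
tempering attacks this by running M replicas at one common bath
temperature while scaling ("tempering") only the energy terms of a chosen
region, and letting neighbouring replicas swap their scaling parameters.

`grest` implements the generalized form of this algorithm at desk scale,
over toy bead systems, together with the surrounding protocol: ladder
optimization to a target exchange acceptance, trajectory demultiplexing,
loop RMSD, distance-matrix PCA, and the energy–RMSD diagnostic.

## The model

A replica holding scaling parameter $\beta_m$ (its solute "temperature" is
$T_m = 1/\beta_m$; reduced units with $k_B = 1$ throughout, bath
temperature $T_0 = 1$ playing the role of 300 K) runs on the potential

$$E_m = \frac{\beta_m}{\beta_0} E_{uu}
 + \sum_i \left(\frac{\beta_m}{\beta_0}\right)^{k_i/l_i} E_{uv,i}
 + E_{vv},$$

where each potential-energy term is classified against the solute
selection: $E_{uu}$ collects tempered-category terms whose atoms all lie
in the solute region, $E_{uv,i}$ are the cross terms ($k_i$ of their $l_i$
atoms inside), and $E_{vv}$ everything else.  Only dihedral, van der Waals
and electrostatic terms are ever tempered; bond and angle terms always stay
at the bath temperature.  A proposed swap of $\beta_m$ (replica a) and
$\beta_n$ (replica b) is accepted with probability $\min(1, e^{-\Delta})$,

$$\Delta = (\beta_n - \beta_m)\,\bigl(E_{uu}(x_a) - E_{uu}(x_b)\bigr)
 + \sum_i \beta_0^{1 - k_i/l_i} \bigl(\beta_n^{k_i/l_i} -
   \beta_m^{k_i/l_i}\bigr) \bigl(E_{uv,i}(x_a) - E_{uv,i}(x_b)\bigr),$$

which satisfies detailed balance in the extended ensemble.  Two limits are
built into the same formula and are asserted exactly in the test suite:
with every cross exponent $k_i/l_i = 1/2$ it is the REST2 delta, and with
the whole system tempered it is the plain temperature-replica-exchange
(T-REMD) delta, in which the solvent energy has cancelled out entirely.
That cancellation is the reason solute tempering needs far fewer replicas:
T-REMD acceptance at fixed spacing decays with the total degrees of
freedom $f$ (ladder spacing at fixed acceptance shrinks as $f^{-1/2}$, a
law the package exposes analytically on harmonic baths), whereas the
solute-tempering delta never sees the solvent.

## What is computed, and how

**Force field.**  Harmonic bonds $\tfrac{k}{2}(r - r_0)^2$ and angles
$\tfrac{k}{2}(\theta - \theta_0)^2$, cosine dihedrals
$K(1 + \cos(n\phi - \delta))$ with the IUPAC sign convention, plain
(non-periodic, cutoff-free) Lennard-Jones 12-6 and Coulomb $q_iq_j/r$
pairs with Lorentz–Berthelot combination, and harmonic positional
restraints.  1-2 and 1-3 pairs are excluded from the nonbonded list; 1-4
pairs are kept at full strength.  The additional `restraint` term category
(a single-atom tether, $l = 1$) exists so that systems of independent
oscillators have scalable terms at all; it must be selected explicitly and
is never part of `"all"`.

**Samplers.**  Two propagators run each replica at the bath temperature
under its scaled potential: single-particle Gaussian-displacement
Metropolis sweeps (`mode = "mc"`, the default) and BAOAB Langevin
dynamics (`mode = "langevin"`, time step 0.01, friction 2 by default).
MC is the default deliberately: a converged solute-tempering ladder
legitimately visits rungs where the vdW terms are scaled down by many
orders of magnitude, so replicas sample configurations with overlapping
LJ cores; when such a replica later swaps toward the bath rung, the
unscaled forces at those configurations are arbitrarily large and any
fixed-timestep integrator can diverge, while Metropolis sampling remains
exact and robust at every scaling.  Langevin is the right tool for
dynamics-flavoured runs on smooth fixtures, and both samplers are held to
the same distributional tests (harmonic variance, bottom-rung marginal).

**Exchange schedule.**  Exchanges are attempted every
`exchange_interval` sampler steps (default 1000), alternating between the
even pair set (1,2),(3,4),… and the odd set (2,3),(4,5),…; accepted swaps
exchange the parameter indices and leave coordinates (and velocities)
with their replicas.  All randomness derives from one seed: R's RNG
drives exchange decisions, and every propagation chunk gets its own
counter-based stream keyed by (seed, replica, chunk), so runs are
bit-reproducible in MC mode regardless of how chunks are scheduled.

**Ladder optimization.**  Starting from a ladder geometric in solute
temperature between $T_0$ and `T_max` (default $5\,T_0$), short trial
runs measure per-pair acceptance $p_m$ and the log-temperature gaps are
updated multiplicatively, $\ln(T_{m+1}/T_m) \mathrel{*}= \ln p^\ast /
\ln p_m$, until all pairs sit within `tolerance` (default 0.05) of the
target $p^\ast$ (default 0.3).  The exact update rule is a package
choice; the measured $p_m$ is a noisy binomial estimate, so $p_m$ is
clamped to $[0.02, 0.95]$ and per-round factors to $[0.5, 2]$, and rung
temperatures are capped at $10^6\,T_0$ — the effectively decoupled-solute
ceiling — so that a rung pair passing through a low-susceptibility band
cannot push the ladder to numerical overflow.  Trial rounds default to
32\,000 sweeps with exchanges every 160 steps — short enough to gather
acceptance statistics quickly, long enough between attempts that the
measured acceptance is close to its fully-relaxed production value (very
frequent exchanges systematically inflate it) — and at most 15 rounds.  $\beta_1$
is pinned to $\beta_0$ throughout, so the bottom rung always samples the
physical ensemble.

**Analysis.**  `sort_by_parameter()` demultiplexes replica trajectories
into constant-parameter streams (the bottom-rung stream is the analysis
trajectory), `rmsd_traj()` computes Kabsch-superposed RMSD with
independent fit and RMSD selections (superposition delegated to
`bio3d::fit.xyz`; the default sets both selections equal because the
choice of superposition frame is a genuine ambiguity best made
explicit), `distance_matrix_pca()` runs PCA on the flattened upper
triangle of the per-frame pairwise-distance matrix (superposition-free by
construction; each component is oriented so its largest-magnitude loading
is positive), and `energy_rmsd_correlation()` emits the (RMSD, $E_m$)
scatter at the bottom rung with its Pearson correlation — the diagnostic
that distinguishes a tempering choice that merely explores from one that
also ranks the native basin as the stable state.

## The synthetic fixtures

**Harmonic baths** (`make_harmonic_bath`): independent isotropic 3-D
oscillators tethered to the origin, the first `n_solute` beads forming
the solute.  Per-rung energies are Gamma distributed, so exchange
acceptance has the closed form $2\,I_{\beta_{\min}/(\beta_a+\beta_b)}
(f/2, f/2)$, cross-checked in the tests against blind numerical
quadrature.  These baths carry the analytic side of the theory: the
$f^{-1/2}$ spacing law (asymptotic in $f$, hence measured on the grid
$f = 16 \dots 512$), the solvent-size invariance of solute-tempering
acceptance, and the Kolmogorov–Smirnov check of the bottom-rung marginal.

**The mini-loop** (`make_mini_loop`): the deliberately hard fixture.  Two
restrained six-bead framework strands form a hairpin; an eight-bead loop
bridges a 1.2-unit gap with nine bonds of slack, so it must bulge out and
pack, the way a long CDR-type loop protrudes from the immunoglobulin
framework.  The central loop dihedral is bistable, $K(1 - \cos 2\phi)$
with wells at $\phi = 0$ (cis) and $\pi$ (trans) and barrier $2K = 8$
reduced units; the emitted `start` structure sits in the cis well and the
`reference` in the trans well, emulating a start model built on the wrong
side of a proline-type isomerisation.  The two angles flanking the
bistable dihedral are stiffened (proline-ring-like) so the barrier cannot
be bypassed through a collinear chain geometry.  Interaction strengths
(alternating charges $\pm 1.8$, LJ $\epsilon = 1.0$, $\sigma = 0.9$,
loop angles $k_\theta = 6$, and CHARMM-style multi-multiplicity
background dihedrals whose stiffnesses are graded geometrically from
$K = 0.8$ — floppy, side-chain-like — to $K = 100$ — stiff,
omega-bond-like) were fixed once, by design, so that the fixture has the
three properties the whole protocol needs: (i) unbiased sampling at
$T_0$ stays trapped in the cis well on desk timescales; (ii) the
tempered energy retains exchange susceptibility across the entire rung
band, because some graded dihedral scale softens in every
solute-temperature decade — bounded energy terms of a single scale
otherwise stop responding and no eight-rung ladder can realize a 0.3
neighbour acceptance at every pair; and (iii) tempering the dihedral
category alone suffices to cross the isomerisation barrier, because the
electrostatic packing cage is deliberately modest.  Structures are built
by biased minimisation (a strong temporary dihedral restraint toward the
desired well, then released), validated for well membership and absence
of clashes, retrying with a fresh symmetry-breaking jitter — still
deterministic in the seed — when the minimiser lands in a bad basin.

**Discrete systems** (`make_discrete`): finite state spaces with per-state
energy decompositions.  The full extended-ensemble transition matrix of
the propagate-plus-exchange cycle is built explicitly
(`discrete_extended_chain`), and its stationary law is compared with the
product of scaled Boltzmann weights to total-variation distance below
$10^{-8}$ — detailed balance as a theorem-grade assertion rather than a
statistical one.

What the fixtures do *not* emulate: real force-field chemistry,
explicit solvent, hydrodynamics, or the entropic fine structure of real
loop ensembles.  Passing tests demonstrate the correctness of the
algorithmic machinery and the qualitative phenomenology (trapping,
melting, two-state behaviour), not quantitative transfer to proteins.

## Worked protocol

```r
library(grest)
ml  <- make_mini_loop()                       # fixture, seed 1
lad <- optimize_ladder(ml$system, ml$sel, M = 8, seed = 1)
run <- run_grest(ml$system, ml$sel, lad, n_sweeps = 2e5,
                 exchange_interval = 1000, seed = 2)
st  <- exchange_statistics(run)
mean(st$pairs$ratio)                          # ~0.3 by construction
b1  <- sort_by_parameter(run)[[1]]
r   <- rmsd_traj(b1$coords, ml$reference,
                 fit_selection  = ml$framework_atoms,
                 rmsd_selection = ml$loop_atoms)
co  <- energy_rmsd_correlation(sort_by_parameter(run), ml$reference,
                               ml$framework_atoms, ml$loop_atoms)
```

The same protocol is scripted in `scripts/acceptance.R` and the README.

## Numerical choices and degenerate inputs

* Dihedral angles use `atan2` of the standard triple products; angle
  gradients clamp $\sin\theta$ away from zero, and LJ/Coulomb kernels
  clamp $r$ away from zero, so forces stay finite on degenerate geometry
  (the finite-difference tests cover the generic case).
* Minimisation is plain L-BFGS-B on the scaled potential.
* MC proposals are isotropic Gaussians (default s.d. 0.12 reduced
  lengths, chosen for healthy move acceptance on the mini-loop; harmonic-
  bath tests pass larger steps explicitly).
* `metropolis_accept` consumes no random draw when $\Delta \le 0$ and
  exactly one otherwise, which keeps run replay byte-stable.
* Empty solute selections, single-replica ladders, zero-attempt exchange
  pairs and zero-variance PCA inputs are all defined, tested cases rather
  than errors; truly invalid input (indices out of range, non-finite
  coordinates, non-positive temperatures, too-short loops) fails fast
  with a message naming the constraint.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely from generated
fixtures: the mini-loop protocol optimizes 8 replicas (32\,000-sweep
trials) and measures production acceptance over $2\times 10^5$ sweeps;
distributional checks use 20 seeded runs of $3\times 10^4$ sweeps on
harmonic baths; the discrete detailed-balance matrices have 18–48
extended states.  These sizes were picked so the full protocol completes
in minutes on a single core while keeping every statistical tolerance at
the 3–4$\sigma$ level of its own sampling error.

## Known limitations

* The exchange-delta bookkeeping assumes both decompositions come from
  the same solute selection; mixing selections raises an alignment error
  rather than attempting a reinterpretation.
* The ladder optimizer assumes acceptance responds monotonically to the
  local gap; fixtures with genuinely zero tempered susceptibility in some
  temperature band will push rungs to the $10^6\,T_0$ ceiling and return
  a non-convergence warning instead of failing silently.
* No pressure coupling, constraints, periodic boundaries or PME — the
  package targets the algorithm, not condensed-phase realism.
* CMAP-style coupled-dihedral corrections are out of scope entirely; the
  tempered categories are exactly dihedral, vdW, electrostatic (and the
  fixture-only restraint class).
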