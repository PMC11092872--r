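---
title: "Coupled polymer collapse and bulk condensation: model, methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled polymer collapse and bulk condensation: model, methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prewetting)
```

## The physical problem

A long, compressible polymer (think of a chromosome) sits in a solution of
proteins that are themselves prone to liquid–liquid phase separation.  Two
transitions can then interact: the polymer's coil–globule *collapse*
transition, controlled by the effective monomer–monomer interaction, and the
bulk's *condensation* transition, controlled by its chemical potential and
interaction strength.  When polymer and bulk bind each other, a new,
*generalized prewetting* phase appears: a locally condensed droplet of bulk
molecules stabilized on a collapsed polymer, at parameter values where
neither the isolated polymer would collapse nor the isolated bulk would
condense.  This package implements both sides of that story: a lattice
Monte-Carlo model whose three Hamiltonian pieces couple a single pinned
self-avoiding chain to a phase-separating bulk, and the matching two-order-
parameter mean-field theory.

## Lattice model

All energies are in units of $k_BT$.  On a periodic cubic lattice, site $i$
carries polymer indicators $s_i^p$ (by monomer type) and bulk indicators
$s_i^1$, $s_i^2$.  The three energy pieces are

* polymer: $-(\mu_p + v_p)\sum_i s_i^p + v_p \sum_{\langle ij\rangle} s_i^p s_j^p$,
  so $v_p > 0$ is a repulsive contact energy and the per-monomer shift
  offsets the contacts between sequential monomers up to an $O(1)$ end
  effect;
* bulk (two-species molecular fluid): $-\mu_b (n_1 + n_2)
  - J_{bulk}\sum_i s_i^1 s_i^2 - J_{nn}\sum_{\langle ij\rangle} (s_i^1+s_i^2)(s_j^1+s_j^2)$,
  with molecules of fixed length $N_b$ (default 20), self-avoiding within a
  species while different species may share a site;
* coupling: $-\sum_t J_{int,t} \sum_i s_i^1 s_i^{p,t}$ — only species 1
  binds the polymer, per monomer type $t$; a non-interacting segment type
  simply has $J_{int,t} = 0$.

A *minimal* variant replaces the molecular bulk by a single-species lattice
gas, $-\mu_b \sum_i s_i - J_{bulk} \sum_{\langle ij \rangle} s_i s_j$,
updated by spin flips; it is the workhorse for scans because it reproduces
the coupled phenomenology at a fraction of the cost.

Three conventions deserve a note, because they are choices the model text
leaves open:

* **Chemical potential per molecule.**  The molecular bulk's $\mu_b$
  multiplies the molecule count, not the monomer count; exchange moves act
  on whole molecules and this makes the grand-canonical bookkeeping clean.
* **Symmetrized nearest-neighbour coupling.**  The weak $J_{nn}$ term acts
  on total bulk density $(s^1+s^2)$ per unordered pair, i.e. the
  cross-species term appears symmetrically in both orderings; an asymmetric
  cross term would make the two species physically inequivalent for no
  stated reason.
* **Coupling sign.**  $J_{int,t} \ge 0$ always means attraction; "inert"
  segments are realized by a zero coupling rather than a sign flip.

### The pinned, box-spanning chain

The production chain is pinned at $(L/2, L/2, 0)$ and at $(L/2, L/2, L)$ —
the periodic image of the first pin.  We store the chain in *unwrapped*
coordinates with winding number 1 in $z$: the two terminal monomers are
periodic images sharing one wrapped lattice site, counted once in occupancy
and energy, so the straight spanning chain has exactly $N_p = L$ occupied
sites, consistent with the length window $L \le N_p < N_{max}$.  Because
every move translates one bond, the terminal monomers can never be
displaced: kinks relocate only interior monomers, removals need both
contour flanks, and additions insert new monomers without moving the bond.
Endpoint pinning is therefore structural rather than enforced by rejection,
and the winding number — a homotopy invariant under bond translation — is
conserved exactly.

### Move set and detailed balance

A polymer attempt draws a move class from the schedule
$P_{add} = \frac{N_p+2}{2(1+N_p)}(1-P_{kink})$,
$P_{rem} = \frac{N_p}{2(1+N_p)}(1-P_{kink})$, $P_{kink}$ constant, then a
bond and one of its four orthogonal directions uniformly.  The translated
bond's intersections with the two flanking monomers fully determine the
geometric move class (neither flank: addition; both: removal; exactly one:
kink); a mismatch between drawn and geometric class is a rejection.  These
class weights do **not** satisfy $P_{add}(N_p) = P_{rem}(N_p+2)$ exactly,
so acceptance multiplies the Metropolis factor by the exact
reverse-to-forward proposal ratio,
$H = \frac{P_{rev}(N_p')\,/\,n'_{bonds}}{P_{fwd}(N_p)\,/\,n_{bonds}}$,
which guarantees detailed balance for any $P_{kink} \in [0, 1)$ and any
proposal schedule.  $P_{kink}$ defaults to 0.2 — an efficiency dial with no
effect on the sampled distribution, which the oracle tests confirm.

Bulk molecules move by the same kink geometry (length-preserving class
only) and by reptation, whose Hastings factor is the ratio of free target
sites at the two growing ends.  Reservoir exchange inserts or removes whole
molecules at the rates $\lambda_+ = N_r/(N_r+N_s+1)$ and
$\lambda_- = (N_s+1)/(N_r+N_s+1)$; inserted configurations are ideal random
walks (the reservoir is non-interacting) at a uniform anchor, rejected on
same-species overlap and otherwise accepted by Metropolis on the bulk
energy.  Internal configurations are resampled at each insertion — for
ideal reservoir chains this leaves the equilibrium distribution untouched.

One Monte-Carlo sweep is $N_p$ polymer attempts, plus one spin-flip attempt
per site (minimal bulk) or one kink-or-reptation attempt per bulk monomer
and one exchange attempt (molecular bulk).  Each run uses one seeded
generator (PCG32 in the compiled kernel), and the seed is echoed into every
output header.

## Exact oracles

Because samplers fail silently, the package carries two exhaustive
references sharing the engine's energy code: a depth-first enumeration of
all pinned self-avoiding walks below a length cap, and a $2^V$ sum over
lattice-gas states on up to 24 sites.  The walk enumeration runs in
unwrapped coordinates with wrapped-site self-avoidance, so it counts
exactly the fixed-winding homotopy sector the sampler explores — enumerating
wrapped configurations would silently include winding sectors the dynamics
cannot reach.  The test suite requires Monte-Carlo means of energy and
contact count on a $3{\times}3{\times}4$ spanning system to agree with
enumeration within three batch-means standard errors over $10^6$ sweeps,
and lattice-gas occupancy on $2^3$ sites to match the exact average; with
$J_{bulk}=0$ the occupancy must also hit the independent-site closed form
$e^{\mu_b}/(1+e^{\mu_b})$.

## Mean-field theory

The coupled free energy is
$F_{sys}(R_g, \phi) = F^0_{poly}(R_g) - h\phi N_p + R_g^3\,\Delta f_{bulk}(\phi)$,
with $F^0_{poly}$ the single-chain free energy (Gaussian elasticity plus
two- and three-body terms), $f_{bulk}(\phi) = \frac{t_b}{2}\phi^2 +
\frac{u}{4!}\phi^4 - \mu_b\phi$, and $\Delta f_{bulk}$ measured from the
global minimizer $\phi_\infty$.  Numerical choices:

* minimization runs in $(\log\rho, \phi)$ so $R_g > 0$ is implicit, with
  Nelder-Mead restarted from a $12 \times 12$ grid (densities log-spaced
  over $[10^{-4}, 3]$, $\phi$ spanning the bulk minima widened by one unit)
  and a second polish from each converged point; minima closer than 0.05 in
  $\log\rho$ and 0.02 in $\phi$ are merged;
* $\phi_\infty$ comes from the real roots of the cubic
  $f'_{bulk}(\phi) = 0$; exact ties (the symmetric well at $\mu_b = 0$) are
  broken toward the lower-$\phi$ branch and flagged, for determinism;
* a continuous collapse is located where the minimizing density crosses
  0.01 (reported at the bracket midpoint), a first-order one where the
  global minimum jumps between branches by more than 0.2 in $\rho$ with two
  coexisting minima; both thresholds are configurable;
* when the bulk free energy is expanded to second order around each of its
  minima, minimizing $\phi$ analytically yields, per branch, an effective
  excluded volume $v_{eff} = v_p - h^2/t_m$ with $t_m$ the local curvature
  (the in-text linear coefficient $-h^2/t_b\,N_p\rho$ is inconsistent with
  this $v_{eff}$ by a factor two; we implement
  $-\frac{h^2}{2 t_m} N_p \rho$, the version consistent with the quoted
  $v_{eff}$ and with the two-body term's $\frac{v_p}{2} N_p \rho$
  normalization);
* confinement-entropy and higher-order corrections to $F^0_{poly}$ are
  omitted, as in the source theory.

Two analytic facts anchor the scans and are recomputed by
`scripts/acceptance.R`: the isolated polymer's sharp continuous collapse at
$v_p = 0$ (at $N_p = 10^6$, scanning $v_p$ in steps of 0.01, the density
first exceeds 0.01 at grid midpoint $-0.005$), and the uncoupled
subcritical bulk's branch switch at $\mu_b = 0$ (grid step 0.005, reported
midpoint 0.0025).  A worked check of the induced shift: for supercritical
bulks the continuous transition moves to $v_p = h^2/t_b$, verified
numerically to within two scan steps over $t_b \in \{0.5, 1, 2\}$,
$h \in \{0.5, 1\}$.

One detail worth recording: at $v_p = 0$ the full single-chain free energy
is minimized at $x \equiv R_g^2/(N_p a^2) = 1$ exactly (the three-body term
contributes $x^{-3}/6$ independently of $N_p$), whereas the non-interacting
part alone would give $x = 2/3$; the tests pin both facts.

## Scaled-down simulation studies

Running the published geometry ($L = 64$, $N_{max} = 1500$, multi-million
sweep schedules) is not a job for a test suite, so the package's automated
studies use deliberately reduced conditions, chosen once on physical
grounds:

* **Prewetting scan (minimal bulk).**  $L = 16$, $N_{max} = 150$,
  $v_p = 0$, $J_{int} = 1.5$, $J_{bulk} \in \{0.5, 1.5\}$, scanning
  $\mu_b$ in steps of 0.05 below each gas's symmetric coexistence point
  $\mu_b^* = -3 J_{bulk}$ ($8000 + 4000$ sweeps per point).  The scan runs
  quasi-statically in both directions, each point inheriting the previous
  state — the standard protocol for exposing the hysteresis of a
  first-order transition.  At $J_{bulk} = 1.5$ (subcritical gas: the 3-d
  lattice-gas critical coupling is $J_c \approx 0.89$) the on-polymer
  density difference jumps discontinuously, the pooled order-parameter
  histogram at the jump is bimodal, and the condensed branch carries a
  collapsed chain; at $J_{bulk} = 0.5$ (supercritical) the rise is steep
  but continuous and unimodal everywhere.
* **Multi-component polymer (molecular bulk).**  $L = 16$, an
  untyped chain first equilibrated to working length and then labeled
  yellow/green/yellow with nominal counts $35/35/35$ and $\Delta = 12$
  (the segment-window default used throughout), $J_{int} = (2, 0)$,
  $N_b = 20$, $\mu_b = -1$, reservoir of 400 molecules.  With
  $J_{bulk} = 1$ the direct binder coats the yellow segments while green
  stays at the far-field density and the indirect binder co-enriches; with
  $J_{bulk} = 0$ the indirect binder's enrichment vanishes.  $J_{nn}$ is
  set to 0 in this study so the direct/indirect pathways are not confounded
  by the weak density-density attraction, which by itself draws indirect
  binders to any coated region.

What these reduced studies demonstrate is the *mechanism* — phase
identities, discontinuity versus continuity, segment selectivity — not the
published phase boundaries: finite-size effects blunt discontinuities, the
spanning chain's $R_g$ is bounded below by the box span, and a $16^3$ box
cannot resolve wetting-layer structure.  They say nothing about real
chromatin beyond the model's own assumptions (a single chain, structureless
monomers, strictly on-site binding, no loop extrusion or other activity).

## Known limitations

* The molecular-bulk reservoir is finite, so very dense phases can deplete
  it; studies here keep $N_s \ll N_r + N_s$.
* Enumeration oracles cap at $\sim 10^7$ walk states and 24 gas sites;
  validation therefore lives on small lattices, and correctness at scale
  rests on the locality of the energy deltas (tested exactly) plus detailed
  balance by construction.
* Near a strong first-order point the quasi-static scan shows hysteresis by
  design; locating the equal-weight point precisely would need reweighting
  machinery that is out of scope here.
* `v_eff` and the quadratic-branch analysis require a locally quadratic
  bulk; both refuse parameter regimes (spinodal crossings, single wells)
  where that approximation is meaningless rather than extrapolating.
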