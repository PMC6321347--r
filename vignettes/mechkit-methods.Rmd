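---
title: "Graph-spectral reaction discovery and statistical-rate kinetics with mechkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-spectral reaction discovery and statistical-rate kinetics with mechkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechkit)
library(ggplot2)
```

mechkit implements the analysis core of trajectory-based reaction mechanism
discovery: given molecular geometries or dynamics trajectories it detects
bonds and bond-change events, screens and deduplicates transition-state (TS)
candidate structures with spectral graph descriptors, evaluates canonical
(TST) and microcanonical (RRKM) rate constants on a reaction network, and
solves the resulting chemical master equation by kinetic Monte Carlo (KMC).
The expensive steps that normally surround this core — electronic-structure
calculations, molecular dynamics propagation, TS optimization, IRC
integration — are deliberately out of scope: mechkit consumes their outputs
(XYZ frames, a network of wells and transition states with ZPE-inclusive
energies and harmonic frequencies) and produces the kinetics.

## Molecular graphs from geometry

Bonding is purely geometric. Atoms $i, j$ at distance $r_{ij}$ are bonded
when $r_{ij} < r^{\mathrm{ref}}_{ij}$, the reference being 20% more than the
sum of their covalent radii (a bundled Cordero-type table; H 0.31 Å, C
0.76 Å, N 0.71 Å, O 0.66 Å, ...). This gives the binary adjacency matrix
$A$. A smooth companion,

$$a^w_{ij} = \frac{1 - (r_{ij}/r^{\mathrm{ref}}_{ij})^n}
                  {1 - (r_{ij}/r^{\mathrm{ref}}_{ij})^m},
\qquad (n, m) = (6, 12),$$

interpolates bond order between 1 (coincident) and 0 (far). For the default
exponents the expression collapses to $1/(1 + x^6)$, which is how it is
evaluated everywhere — the removable singularity at $r = r^{\mathrm{ref}}$
(value exactly 1/2) needs no special casing, and monotonicity in $r$ is
manifest. For other exponent pairs the singular point is filled with the
algebraic limit $n/m$.

The graph Laplacian $L = D - A$ (degree matrix minus adjacency) counts
molecular fragments: the multiplicity of its zero eigenvalue equals the
number of connected components. For the weighted graph no entry is ever
exactly zero, so eigenvalues below a configurable upper threshold
($10^{-4}$ by default) are counted as fragmentation modes; the unweighted
zero tolerance is $10^{-6}$. The smallest eigenvalue above the threshold —
the spectral gap — measures how weakly the structure is held together: van
der Waals contacts at $\gtrsim 1.7\, r^{\mathrm{ref}}$ contribute pair
weights $\lesssim 0.05$ whereas covalent bonds contribute $\gtrsim 0.5$,
which is why the prescreening filter's default minimum gap is 0.1.

```{r}
h2o <- geometry(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(0.76, 0.59, 0), c(-0.76, 0.59, 0)))
glance(laplacian_spectrum(build_connectivity(h2o)))
```

Two per-atom spectral descriptors serve different jobs. SPRINT coordinates,
$s_i = \sqrt{N}\,\lambda_{\max} v_i$ with $(\lambda_{\max}, v)$ the principal
eigenpair of $A^w$, are invariant under rotation, translation and *any* atom
permutation — ideal for spotting recurring structures along scrambling
trajectories. The exact normalization is a convention (the literature admits
several); mechkit reports values sorted within element groups, and computes
the eigenpair per connected component, where the Perron–Frobenius theorem
guarantees a positive principal eigenvector (components are split at a small
weight cutoff, $10^{-4}$, because at $r = r^{\mathrm{ref}}$ exactly the
binary criterion already counts the pair as non-bonded while the weight is
still 0.5). Because SPRINT forgets atom identity, it cannot distinguish two
structures in which non-equivalent atoms trade places; the deduplication
descriptor therefore decorates the weighted adjacency with element labels,
$a_{Z,ii} = 1 + Z_i/10$, making the sorted eigenvalue spectrum invariant
*only* under like-atom permutation. The diagonal scaling keeps label and
bond-order entries comparable in magnitude.

## Bond-event detection along trajectories

The adjacency matrix is recomputed for every frame and monitored
element-wise. A flip that persists for at least `debounce` frames (default
5) is an event; shorter excursions are vibrational chatter and are ignored,
except that a flip surviving to the final frame is always kept, since it
never reverts. Events closer than `gap` frames (default 10) are grouped into
one reaction window, so concerted multi-bond processes count once. The
defaults were chosen on synthetic fixtures and are exposed as arguments; the
fixtures' jitter margin analysis (below) shows when they are safe.

Each group yields one TS candidate: the geometry at the temporal midpoint of
the window — the simplest realization of "a structure with partly
formed/broken bonds", documented as replaceable — together with the
connectivity just before and after the window and the set of active atoms.
Groups whose flips cancel (reactant and product graphs identical) are
dropped as null reactions; windows touching the trajectory boundary are
flagged rather than dropped. Downstream TS refinement (partial optimization
with frozen active atoms, saddle-point search) is out of scope by design;
candidates carry everything an external optimizer needs.

## Screening and clustering

Candidates from many trajectories are redundant: trajectories revisit the
kinetically relevant regions. Deduplication buckets candidates whose labeled
weighted-adjacency spectra agree element-wise within $10^{-3}$ per
eigenvalue (no value is prescribed by theory; this default separates genuine
structural differences from numerical noise on the fixtures used in the test
suite) and keeps the first representative in trajectory order.
Prescreening removes fragmented structures (more than one fragment by the
weighted Laplacian count) and van der Waals assemblies (spectral gap below
0.1). Finally, candidates are clustered by the sorted spectrum of the
labeled average $(A_\mathrm{reactant} + A_\mathrm{product})/2$ — a TS
connectivity fingerprint in which forming/breaking bonds contribute 1/2 —
and each cluster's representative is the member closest to the cluster mean
in signature space (ties to the earliest candidate). Bucketing with a
tolerance, rather than k-means, keeps the partition deterministic and
order-independent up to representative ties. The payoff is the usual
$M \to N$ reduction in downstream saddle-point optimizations.

## Rate constants

Canonical rates follow Eyring TST,

$$k(T) = \sigma\,\frac{k_B T}{h}\left(\frac{RT}{p_0}\right)^{\Delta n}
          e^{-\Delta G^\ddagger / RT},$$

with $p_0 = 1$ bar and $\Delta n = 1$ for bimolecular, 0 for unimolecular
steps; bimolecular rates are reported in cm$^3$ molecule$^{-1}$ s$^{-1}$.
The reaction path degeneracy is the optical-isomer ratio
$\sigma = m_{TS}/m$; a product convention would grow with reactant
chirality, which contradicts standard usage, so the ratio reading is
adopted, with optional rotational symmetry numbers defaulting to 1. When a
network supplies no explicit $\Delta G^\ddagger$, it is estimated from the
ZPE-inclusive energy difference plus the harmonic vibrational entropy
$-RT \ln(q^{vib}_{TS}/q^{vib}_{well})$; rotations are not included because
the network schema carries no geometries.

Microcanonical rates follow RRKM theory, $k(E) = \sigma W_{TS}(E) / (h
\rho(E))$, with the sum of states at the TS and the density of states at the
well both obtained by Beyer–Swinehart direct count on an energy grain
(default 10 cm$^{-1}$; frequencies are rounded to the nearest grain
multiple, the standard formulation). All bookkeeping is ZPE-inclusive:
well and TS energies are relative to a declared reference species, and each
species' state count starts at its own zero-point level — so the TS sum of
states is counted from the TS ZPE, not the classical barrier top. The single
conversion constant 1 kcal/mol = 349.755 cm$^{-1}$ and the CODATA values of
$k_B$, $h$, $R$, $c$ live in one exported table (`mech_constants`) and are
used everywhere.

```{r}
tst_rate(0, 298.15)                            # the universal kB*T/h
state_count_W(beyer_swinehart(100, 400, 10), 350)  # 4 levels under 350/cm
```

An optional Eckart tunneling correction multiplies canonical rates: the
closed-form transmission probability through an asymmetric Eckart barrier
matched to the forward barrier, reverse barrier and imaginary-frequency
magnitude, thermally averaged over a Boltzmann distribution by adaptive
quadrature (relative tolerance $10^{-6}$, integral split at the barrier top
where the integrand kinks, hyperbolic functions evaluated in log space
because $\cosh$ overflows for realistic barriers). The correction tends to 1
as the imaginary frequency vanishes or the temperature grows, and its
small-$u$ behaviour reproduces the Wigner limit $1 + u^2/24$,
$u = h c \nu^\ddagger / k_B T$.

## Kinetic Monte Carlo and its oracle

The master equation is solved by Gillespie's direct method: waiting time
$\tau = -\ln u / k_{tot}$, channel chosen proportionally to its propensity
(rate × source population, × partner population for pseudo-first-order
bimolecular channels). Replicas terminate at sink species — declared in the
network, with undeclared dead-ends warned about and absorbed — or at the
time horizon. Reproducibility is exact: one master seed generates one
sub-seed per replica, so a fixed seed gives bit-identical populations,
branching counts and event totals on any platform; scans over an energy or
temperature grid give each grid point an independent seeded stream derived
from the master seed. Microcanonical mode holds the total energy fixed (no
collisional relaxation — the isolated-molecule regime of photodissociation
studies); every outgoing $k(E)$ is determined by the current well's depth.

The deterministic oracle `ode_reference()` integrates $\dot p = K p$ with
deSolve for any (pseudo-)first-order network; the test suite holds KMC means
to within three binomial standard errors of the ODE solution on
six-species cascades at $10^4$ replicas, and two-channel branching to the
same band around the analytic $k_1/(k_1+k_2)$.

```{r, fig.width = 6, fig.height = 3.5}
net <- make_toy_network("sequential", k1 = 1, k2 = 1)
rates <- network_rates(net, T = 300)
res <- run_kmc(net, rates,
               kmc_config(replicas = 2000, t_max = 6, seed = 1,
                          initial = c(A = 1)))
autoplot(res)
```

## Empirical reaction orders

`fit_reaction_orders()` rediscovers a rate law stochastically: scale one
species' initial amount across a factor grid (default 0.25–4), estimate the
initial product-formation rate at each point, and regress $\ln(\text{rate})$
on $\ln(\text{concentration})$. The measurement window closes at 5% of the
limiting species converted or a configurable event budget, whichever comes
first. When the window closes exactly on the $n$-th product event the rate
estimate is $(n-1)/t$ — the unbiased estimator for a stopped Poisson
process; the naive $n/t$ overestimates by $n/(n-1)$, which varies along the
factor grid and visibly distorts fitted orders. Elementary steps come out at
order 1 per reactant and spectators at 0 (both within ±0.1 at the test
suite's replica counts); the bundled catalytic-cycle toy, in which CO
sequesters the catalyst in a dead-end complex, yields the negative CO order
characteristic of inhibition.

## The synthetic fixture generator

`event_script()`/`make_trajectory()` produce trajectories in which selected
pair distances follow a linear interpolation across a frame window —
crossing the bond threshold at a frame computable in closed form from the
interpolation arithmetic — while all unscripted atoms receive seeded uniform
jitter. The script validator rejects jitter large enough
($2\sqrt{3}\,a$ exceeding any unscripted pair's threshold margin) to flip a
non-event bond, so every detection failure in testing is a real failure.
What the generator does *not* emulate: real vibrational spectra (jitter is
white, not modal), curvilinear reactive paths, recrossing dynamics, and
multi-atom concerted motions; passing its tests therefore demonstrates
correct event bookkeeping, not chemical realism. Toy networks with known
kinetics (analytic two-channel branching, closed-form sequential decay, a
catalytic cycle with known orders, and a 3-TS/2-intermediate chain for
microcanonical exercises) play the same role on the kinetics side; the
first three carry explicit rates so their analytic solutions hold at any
temperature.

## Numerical choices and problem sizes

Tolerances: Laplacian zero count $10^{-6}$ (unweighted) / $10^{-4}$
(weighted, user-configurable); dedup and clustering $10^{-3}$ per
eigenvalue; prescreen gap 0.1; Eckart quadrature $10^{-6}$ relative;
Beyer–Swinehart grain 10 cm$^{-1}$. Ties in cluster representatives go to
the lowest candidate index. Degenerate inputs: single atoms give the 1×1
zero Laplacian (one fragment, no gap); empty event lists give empty
groupings; dead networks (all rates zero) leave populations untouched and
report no branching.

The test suite runs at sizes chosen for thorough coverage at interactive
speed: 1000 random structures for the fragment-count cross-check, 100 random
event scripts, $10^4$ KMC replicas for branching and ODE comparisons, 16
replicas × 5 factors per fitted order. Larger sizes change nothing
qualitatively; the stochastic tolerances (3 binomial standard errors) scale
accordingly.

## Known limitations

Connectivity is geometric only — no bond orders, valence rules or
aromaticity. No periodic systems. Barrierless (variational) channels have no
TS record and cannot be represented; pressure dependence, collisional energy
transfer and multipath torsional anharmonicity are out of scope. The
canonical $\Delta G^\ddagger$ estimate omits rotational entropy unless the
caller supplies explicit activation free energies. Microcanonical mode
assumes statistical (RRKM) intramolecular energy redistribution.
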