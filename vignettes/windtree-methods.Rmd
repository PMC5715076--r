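---
title: "Model and methods behind windtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind windtree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windtree)
```

# The model

`windtree` simulates forests of virtual trees built from cylindrical
*segments* of common length $L$ and varying diameter $d$. Each segment
holds a unit axis vector $\mathbf t$ and a unit branching-plane normal
$\mathbf b$; it has one parent (except the trunk) and at most two
children. Childless segments — *twigs* — carry a spherical *foliage* of
diameter $L$ at their distal end. Trees also hold a carbon reserve and a
34-gene genome. Everything is non-dimensional: lengths in $L$, wind
speeds in the average yearly maximum $U_0$, stresses in the wood strength
$\sigma_0$. The only mechanical constant left is the Cauchy number
$C_Y = \rho U_0^2/\sigma_0$, the ratio of dynamic wind pressure to
material strength ($2\times10^{-5}$ for $U_0 \approx 40$ m/s and
$\sigma_0 \approx 100$ MPa).

Each simulated year runs, in order:

1. **Light.** The upper hemisphere is split into 32 equal solid angles
   (4 cos-zenith bands × 8 azimuths). For each mean direction the forest
   is rotated so that direction maps to $+z$; foliage centers are binned
   into an $L\times L$ ground grid and sorted by descending height per
   column; the $k$-th foliage of a column receives
   $\alpha_{fol}^k/32$ of light ($\alpha_{fol} = 0.5$ is the foliage
   transparency). Segments cast no shadow. An unshaded foliage receives
   exactly $l = 1$.
2. **Sensed stress.** Drag forces (coefficient 1) act on foliages
   ($\tfrac12 C_Y U^2 S_{fol}$, sail area $S_{fol} = L^2/4$) and on
   segments ($\tfrac12 C_Y U^2 dL \sin^2\theta$ at midpoints). Forces
   and moments fold leaf-to-root; the surface bending stress at a
   segment base is $\sigma = (32/\pi)\,\lVert\mathbf M\times\mathbf
   t\rVert/d^3$. The sensed stress $\sigma_{max}$ is the maximum over 8
   azimuths at $U = U_0$.
3. **Secondary growth.** A per-species neural network maps
   $(\sigma_{max}/\sigma_0,\ N_{fol,above})$ to a safety factor $S$.
   Each segment's sink is the volume gap to $S$ times its fracture
   volume (the volume at which $\sigma_{max} = \sigma_0$) plus a
   maintenance volume $\pi L d e$ ($e = 0.02L$, a bark-like renewal
   layer). Sinks are requested in equal shares from all foliages above;
   a foliage producing $4 V_0 l$ pays requests in full when it can
   (surplus to the reserve) and pro rata otherwise. Received carbon pays
   maintenance first, then thickens the segment. A fully paid segment
   reaches exactly $\sigma_{max}/\sigma_0 = S^{-3/2}$ at the load that
   drove the demand. Under-maintained segments lose strength
   geometrically and are shed once their strength factor falls below
   0.05.
4. **Storm.** One storm per year: azimuth uniform, speed exponential
   with $P(U > 1.5\,U_0) = 1/100$ (hundred-year return period for winds
   50% above the yearly maximum). Each segment fractures independently
   with the Weibull probability
   $P = 1 - \exp[-(V/V_0)(\sigma/\sigma_0 f)^{10}]$, where $f$ is its
   strength factor; root-most fractures remove whole subtrees.
5. **Death.** Trees die past age 1000, or past age 6 with fewer than 10
   segments, or when the trunk breaks.
6. **Primary growth.** A second network maps (reserve, foliage count) to
   allocation fractions $P_{seg}, P_{seed}$ (their sum at most 1) and a
   photosensitivity $p$. The reserve funds
   $\lfloor P_{seg} V_{res}/V_0\rfloor$ new segments (in pairs per
   selected twig) and $\lfloor P_{seed} V_{res}/5V_0\rfloor$ seeds; at
   $p = 1$ the best-lit twigs are chosen, at $p = 0$ uniformly random
   ones.
7. **Reproduction.** Seeds fall at 45° — landing a horizontal distance
   equal to the release height away, at a uniform azimuth — and
   germinate as single-segment seedlings with a mutated copy of the
   parent genome ($p_{mut} = 0.05$ per gene, amplitude 0.005, clamped to
   $[0,1]$). Seeds leaving the island are lost.

# Genome and growth-policy networks

The 34 genes (all in $[0,1]$) comprise 3 branching-angle genes, 18
primary-network weights, 10 secondary-network weights and 3 neutral
markers used only for display. Both networks have one hidden tanh layer
of gain 5 plus a constant-signal bias neuron.

Several encodings are deliberate design choices where only qualitative
behaviour is constrained by the biology:

- **Gene-to-weight map**: affine, $w = 2g - 1$, a bijection of $[0,1]$
  onto $[-1,1]$.
- **Branching-angle ranges**: $\theta_1 \in [0°, 90°]$,
  $\theta_2 \in [-90°, 0°]$, $\gamma \in [0°, 180°]$, so the two
  children always fork to opposite sides of the parent axis. Rotations
  are right-handed about the given axis, everywhere.
- **Input scalings** (inputs should be of order 1):
  $\log_{10}(1 + V_{res}/V_0)/3$ and $\log_{10}(1 + N_{fol})/3$ for the
  primary network; $\min(\sigma_{max}/\sigma_0, 2)$ and
  $\log_{10}(1 + N_{fol,above})/3$ for the secondary one. These are
  bounded and order-1 across realistic states.
- **Output squashings**: with $u = (1 + \tanh z)/2$, the primary outputs
  are $P_{seg} = u_1(1 - u_2)$, $P_{seed} = u_1 u_2$, $p = u_3$, which
  enforces $P_{seg} + P_{seed} \le 1$ by construction; the safety factor
  is $S = 1 + 5(1+\tanh z)/2 \in [1, 6]$, bracketing realistic wind
  safety factors with midpoint 3.5.

# Numerical choices

- Segment arrays stay in topological order (parents before children);
  all tree traversals are single passes in compiled code, cross-checked
  in the tests against recursive and brute-force R oracles.
- Light grid columns are anchored at a fixed origin (no jitter); height
  ties are broken by foliage index, making runs bit-reproducible.
- Stresses use the 8-azimuth maximum. The bending stress is close to the
  square root of a quadratic form in the wind direction, so 45° sampling
  can undershoot a dense sweep by at most about $\cos 22.5° = 0.924$ in
  the degenerate single-load case; for real multi-load trees the typical
  undershoot is well under 2%.
- Within one storm, stresses are evaluated once; fracture draws are
  independent per segment and the root-most break wins. No load
  redistribution happens mid-storm.
- The maintenance-weakening law is a one-state surrogate: strength
  multiplies by $0.5 + 0.5\,m$ (maintenance fraction $m < 1$) and
  recovers by 1.25 (capped at 1) when fully maintained; segments below
  0.05 fall in the next storm regardless of load. Five fully
  unmaintained years push a healthy branch below the threshold.
- A twig branches at most once per year; one standard-normal draw
  perturbs each rotated angle per branching event
  ($\delta\theta = 10°$).
- All randomness flows through R's session RNG in a documented order
  (storm, then per-tree fracture draws, then growth placement and
  dispersal in tree list order), so a single `set.seed()` reproduces a
  run exactly.

# Emergent-structure statistics

`strahler_orders()` ranks segments (twigs rank 1; two equal-rank
children promote the parent) and groups equal-rank runs into branches.
`self_similar_ratios()` fits geometric progressions over the first 7
ranks, giving the branching, length, diameter and area ratios and the
fractal dimension $D = \ln R_n/\ln R_l$, with an 80% CI from
independent-normal propagation of the two slope errors. Crown radius is
$\sqrt{\mathrm{var}_x + \mathrm{var}_y}$ of the ground-projected foliage
centers. Stand density uses the effective number
$\bar N = (\sum B)^2/\sum B^2$ and effective biomass
$\bar M = \sum B^2/\sum B$, which are insensitive to seedling swarms.
Allometric exponents come from weighted reduced-major-axis fits on
$\log_{10}$ data, with foliage count as weight and trees restricted to
the central 90% of the island radius (edge trees grow large and would
bias pooled fits); the self-thinning exponent is the $\bar N$-weighted
least-squares slope of $\log\bar M$ vs $\log\bar N$.

# The analytical scaling model

The closed-form companion model assumes the three emergent regularities
the simulator produces: self-similar skeletons ($R_l = R_n^{1/D}$),
fractal dimension $D$, and constant wind safety ($\sigma_k/\sigma_0 =
S^{-3/2}$ at every rank). The constant-safety condition fixes
$R_d = R_n^{(D+1)/(3D)}$ and the rank-1 diameter

$$d_1^3 = \frac{16\,\alpha_1\alpha_2 S^{3/2}}{\pi}\,C_Y S_{fol}
\frac{R_l L}{R_l - 1},$$

with geometry factors $\alpha_1 = \alpha_2 = 1/2$ (foliage lever arm and
wind projection). The always-vertical trunk is $\alpha_2^{-1/3}$ thicker
($d_1' \approx 0.0552\,L$ at the defaults). Allometric exponents depend
on $D$ alone: $\beta_H = 3/(D+1)$, $\beta_N = 3D/(D+1)$,
$\beta_B = (2D+5)/(D+1)$, $\beta_{ML} = 3D/(2D+5)$.

Two subtleties, resolved as follows:

- **Reference diameter.** Written with the trunk-corrected $d_1'$, the
  height prefactor evaluates to about 30.4; the familiar printed
  coefficients (37.1, ~814, ~33.9 in units of $L$) require the plain
  rank-1 diameter $d_1$ as reference. `asm_prefactors()` exposes the
  choice (`reference = "d1"` by default) rather than hiding it.
- **Biomass closed form.** The rank sum for stem volume is a finite
  geometric series; the power-law form keeps its dominant term only and
  overstates the sum by the relative amount $(R_n/(R_d^2R_l))^K =
  R_n^{K(D-5)/(3D)}$ (about 0.7% at $K = 12$ with the defaults).
  `asm_biomass()` returns the explicit sum, the closed form, and the
  gap; the tests assert the exact series identity.

Similarly, the SI leaf-mass/stem-mass coefficient obtained by
eliminating the trunk diameter from the closed forms is about 0.15 at
the default constants; `asm_si()` reports it as computed.

Elasticities of the constants to the Cauchy number and foliage
transparency (`asm_sensitivities()`) take $D = 2 + \alpha_{fol}$,
reflecting that opaque canopies shed their interior foliage ($D \to 2$)
while transparent ones fill space ($D \to 3$): exponents then respond
to transparency only, and prefactors to $C_Y$ through $d_1 \propto
C_Y^{1/3}$.

```{r asm}
asm_exponents(2.5)
asm_ratios(3.5, 2.5)
signif(asm_prefactors(), 3)
```

# Study conditions and what the tests show

The simulator is its own data generator; tests run at desk scale chosen
once:

- unit oracles on randomized trees of up to ~100 segments;
- a 50-tree, 30-year island for the exact carbon-conservation ledger
  (production = maintenance + growth + reserve gain, to $10^{-12}V_0$);
- a 2,000-tree random-genome island of radius $40L$ run for 1,000 years
  for the emergent statistics (self-thinning trajectory, self-similar
  ratios, area conservation, safety factors). A thousand years gives
  individual trees time to grow old — juvenile trees are not yet
  self-similar, and their statistics are known to be noisy;
- synthetic allometric cohorts drawn from the closed forms for
  parameter-recovery checks of the fitting code: a latent size, log-
  uniform over trunk diameters $[0.1, 10]\,L$ (the range where the
  closed forms are compared to data), with multiplicative log-normal
  scatter on *every* measured axis whose log-sd is proportional to the
  exponent (0.1 on the diameter axis). That is the errors-in-variables
  setting for which reduced-major-axis regression is the consistent
  symmetric estimator — the reason allometry uses RMA in the first
  place; scatter on the responses alone would bias any symmetric fit.

These island runs are one to two orders of magnitude smaller than
publication-scale experiments (32 forests of 20,000 trees on $R = 200L$
islands, tournaments over $10^5$ years). At desk scale the population
has not been distilled to a single fit species, so emergent statistics
are broader: band checks on such runs demonstrate that the mechanisms
(thinning under light competition, wind-shaped diameters, self-similar
crowns) operate, not that the asymptotic published values are
recovered. Functions `tournament()` and the CLI expose the full
protocol for users with the patience for larger runs.

# Known limitations

No hydraulics (by design: the point of the model family is that light
plus wind suffice for realistic allometry), no gravity loads or
reorientation, no curved segments, no root system, no within-canopy wind
profile or dynamic (resonant) loading, single-process execution. Species
identity is operationalised as founding lineage; the neutral marker
genes exist only for colouring.
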