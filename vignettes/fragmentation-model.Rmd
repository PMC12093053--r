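---
title: "Modelling cancer evolution under asexual fragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cancer evolution under asexual fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragevo)
```

## The problem

Some animals — planarians, *Hydra*, certain starfish, annelids and sea
anemones — reproduce asexually by fragmentation: a detached body fragment or
bud regenerates into a complete organism. Unlike a zygote, a fragment is a
multicellular sample of the parent's body, so parental tumour cells can ride
along into the offspring. At the same time a fragment needs far fewer cell
replications to reach the mature cell number than a zygote does, and
replications are the primary engine of oncogenic mutation. Fragmentation
therefore carries two opposing cancer effects: vertical tumour transmission
(bad) and a shortened mutational history (good). `fragevo` implements a
deterministic model of this trade-off and asks when natural selection should
favour fragmentation over unitary (sexual) development, and what cancer
prevalence results.

## Within-organism dynamics

Each organism carries two cell compartments: the germline pool (primordial
germ cells, or adult primordial stem cells — APSCs — in species that have
them) and the soma. Within a compartment, cells progress irreversibly
through three states — normal, defective, cancerous — following the two-hit
picture of carcinogenesis. Writing $(\Pi_t, \Psi_t, \Gamma_t)$ for the
germline state proportions after $t$ replications,

$$\dot\Pi = -\mu_1 \Pi, \qquad
  \dot\Psi = \mu_1 \Pi - \mu_2 \Psi, \qquad
  \dot\Gamma = \mu_2 \Psi,$$

with the closed-form solution implemented in `propagate()`:
$\Pi_t = \Pi_0 e^{-\mu_1 t}$,
$\Psi_t = \Psi_0 e^{-\mu_2 t} + \mu_1 \Pi_0 (e^{-\mu_1 t} - e^{-\mu_2 t})/(\mu_2 - \mu_1)$,
and $\Gamma_t$ as the simplex remainder. The somatic compartment obeys the
same chain with rates $(k_1, k_2)$. `t` is treated as a continuous
non-negative quantity — a replication count, or equivalently age under a
constant replication rate. When $\mu_2 = \mu_1$ the solution's removable
singularity is replaced by its analytic limit
$\Psi_t = (\Psi_0 + \mu_1 t \Pi_0) e^{-\mu_1 t}$; the branch switch happens
at relative rate differences below $10^{-12}$ and is continuous to well
below $10^{-8}$ (tested).

Rates derive from three strategy parameters via `make_rates()`: the combined
cancer-suppression capability $I \in (0,1)$ sets a baseline rate $\eta(I)$;
the fidelity bias $s \in (0,2)$ shifts protection between compartments
($k_1 = s\,\eta$, germline factor $2-s$); the APSC proliferability
$\theta \in [0,1)$ adds a germline surcharge
($\mu_1 = (1+\theta)(2-s)\,\eta$). Second hits are 1.5 times faster than
first hits, reflecting genomic instability after the first
tumour-suppressor loss. The functional form of $\eta$ is not pinned down by
the model description, only its requirements (strictly positive, strictly
decreasing in $I$); we use $\eta(I) = \eta_0 e^{-\lambda I}$ with defaults
$\eta_0 = 0.05$, $\lambda = 3$ — at mid-range suppression this gives a
per-replication transition rate of about 1%, so an organism maturing over
35 replications keeps a predominantly normal soma, which is the regime the
scenario analyses inhabit. Both constants live in the scenario config
files, the single source of truth for all such choices.

In APSC-bearing organisms part of the mature soma is APSC-derived:
`couple_somatic()` blends the somatic composition as
$\theta \cdot \text{APSC} + (1-\theta) \cdot \text{soma}$. Whether this
blending reapplies at fragment maturity is genuinely open in the model
description, which defines it for unitary development; we apply it to every
APSC-bearing organism (fragments included) by default, with
`apsc_coupling_fragments = FALSE` available to disable it, because the
biological reading — APSCs continuously provision the soma — does not
distinguish how the organism was born.

## Fragmentation and the purging/accumulation dichotomy

A fragment inherits the parent's maturity composition reweighted by
transmission propensities $f_1, f_2, f_3$ (`fragment_inherit()`): mobile
tumour cells mean $f_3$ near $f_1$; tumour-free budding zones mean small
$f_3$. One fragmentation generation is therefore the normalized linear map
$x \mapsto M x / \lVert M x \rVert_1$ with
$M = T(\mu_1, \mu_2, T_F)\,\mathrm{diag}(f)$, where $T$ is the
lower-triangular transfer operator of the two-hit chain and $T_F$ the
replications to maturity after fragmentation. Because $M$ is triangular its
eigenvalues sit on the diagonal,

$$d = \bigl(f_1 e^{-\mu_1 T_F},\; f_2 e^{-\mu_2 T_F},\; f_3\bigr),$$

and the limit of consecutive fragmentations is the normalized dominant
eigenvector, computed in closed form by back-substitution
(`limit_composition()`); power iteration is kept only as a test oracle.
`classify_regime()` reads off the dichotomy: if $f_3$ strictly dominates,
cancer accumulates every generation towards $(0,0,1)$ and purging is
impossible — binary fission ($f_1 = f_2 = f_3$) always lands here since
$e^{-\mu t} < 1$; if $f_1 e^{-\mu_1 T_F}$ dominates, lineages converge to a
limit with a positive normal share (fragmentational purging); the middle
case governs lineages that lack normal cells. Exact ties are reported as
`indeterminate` rather than resolved arbitrarily: the strict inequalities
are what the analysis rests on, and a tie has no unique limit.

## Fitness and population dynamics

Organism fitness (`organism_fitness()`) is
$\omega = \omega_0 + \alpha_N N^\varepsilon + \alpha_D D^\varepsilon +
\alpha_C C^\varepsilon - \tau\delta(1-\theta^2) - c_0 I^2$
with $\alpha_N \ge \alpha_D \ge \alpha_C$: a baseline plus the somatic
composition term (the exponent $\varepsilon \in [1,2]$ encodes cancer
aggressiveness), minus expected trauma damage discounted by regeneration,
minus the physiological cost of cancer suppression. The extracted forms of
the regeneration discount and the diversity curve are typographically
ambiguous; we default to $1-\theta^2$ and
$H = b_0 + (1-b_0)(1-\rho)^{1/4}$ (matching the rendering of $c_0 I^2$, and
the only reading of $H$ that is concave as stated), with the alternatives
$(1-\theta)^2$ and $b_0 + (1-b_0)(1-\rho^4)$ selectable per config. Fitness
is clamped at zero because it multiplies subpopulation sizes in the
recursion and negative reproductive output is meaningless.

The population is tracked per lineage class: `NU`/`DU` organisms developed
from a normal/defective zygote, and `NF`$_i$/`DF`$_i$ organisms produced by
$i$ consecutive fragmentations from such an ancestor. Defective lineages
never regain normal cells and can only produce defective zygotes. Each
generation (`run_pedigree()`), sexual inflows weight parents by fitness,
zygote-success probabilities (`zygote_probabilities()`; a cancerous gamete
that fertilizes is a failed embryo) and juvenile survival
$\Delta_V, \Delta_W$; fragmentation inflows shift depth by one and multiply
by the offspring count (2 for binary fission); every clone contribution
carries the diversity coefficient $H(\rho)$ of the current clone proportion
$\rho$. Generation 1 is all-`NU` with size 1: sizes are relative, the
recursion being homogeneous of degree 1, so the absolute scale is
unidentifiable and immaterial.

Total growth is regulated by a generalized logistic
$\Theta$ (`theta_transform()`) with the stated bounds $[0.9391, 1.08]$,
anchored so $\Theta(1) = 1$. The published description fixes only the
bounds, not the shape; steepness is configurable (`regulation: k`) and the
shipped scenarios use $k = 20$, making the bounds effectively attained for
any strategy whose raw output is clearly above or below replacement. This
choice matters: with a soft logistic the regulated growth still increases
appreciably in raw output, so a strategy with more offspring compounds a
size advantage over 29 generations and the optimizer degenerates to "most
offspring wins"; with a steep logistic all viable strategies grow at the
cap and optima are decided by organism quality, diversity costs and
survival terms — the trade-off structure the model exists to study. The
scaling rule is also stated ambiguously; by default the realized total is
$P_{j+1} = \Theta(P^*_{j+1}/P_j)\,P_j$ with subpopulations taking their
untransformed shares, which makes the printed ratio bounds hold exactly
(`regulation: rule: literal` selects the verbatim per-subpopulation
multiplication instead). The strategy-ranking index is the population
fitness sum at generation 30, with clone fitness carrying $H$ exactly as it
does in every reproduction equation (excludable via
`include_H_in_index = FALSE`). Depth classes below $10^{-12}$ of the total
are pruned each generation; at sweep scales this changes nothing above
test tolerance and keeps the state compact.

## Scenarios and sweeps

Seven shipped configs (`load_scenario()`) cover the published model
families: purging (`FRPG-*`), accumulation (`FRAC-*`) and binary fission
(`BINF-*`), each with a variant where fragmentation (`-FR`) or unitary
development (`-UD`) is fitness-maximizing. `sweep_fitness()` evaluates the
strategy grid $\phi \times I$ (fragmentation prevalence × cancer
suppression, default 21 × 21 with $I \in [0.025, 0.975]$) at fixed
$(\theta, s)$, forcing $\theta = 0$ wherever $\phi = 0$ (no fragmentation
implies no APSCs); `global_optimum()` sweeps
$\theta \in \{0.1, \dots, 0.7\}$ and $s \in \{0.5, 0.75, 1, 1.25, 1.5\}$
and breaks exact ties lexicographically. Everything is deterministic:
repeated sweeps are bit-identical. Cancer prevalence of a population state
is the size-weighted mean somatic cancerous proportion, reported at the
final generation.

The scenario files distinguish `printed` constants (stated in the model
description: e.g. FRPG-FR's $f = (5, 1, 0.5)$, $T_U/T_F = 35/15$,
$\Delta_V/\Delta_W = 0.7/0.5$; FRPG-UD's $\varepsilon = 1.1$,
$\tau\delta = 0.3 \times 0.1$, $b_0 = 0.1$; BINF's equal $f$, two offspring
and $b_0 = 0.7$ for FRa) from `reconstructed` ones, which are this
package's choices selected so each scenario realizes its documented regime
and optimum structure: FRPG-FR favours frequent fragmentation with maximal
APSC proliferability and germline-protective fidelity
($\theta = 0.7, s = 1.5, \phi > 0.5$), with the per-$\phi$ optimal
suppression relaxing as fragmentation intensifies and prevalence falling
along $\phi$; FRPG-UD shows that purging alone does not select for
fragmentation when cancer is benign, damage mild and diversity loss harsh;
FRAC-FR shows the converse — accumulation does not preclude fragmentation
when juvenile mortality is severe — with prevalence rising along $\phi$.
Absolute surface heights depend on these reconstructions and are not
claimed to reproduce anything; only the qualitative structure above is
asserted (and tested).

One reconstruction limit is worth stating plainly: in `BINF-UD`, binary
fission's two offspring per event mean that among strategies sustaining
population growth, a small admixture of fission always adds net
reproductive output, so no explored parameterization makes exclusive
unitary development optimal in a thriving population. The shipped `BINF-UD`
(weak baseline suppression, low baseline fitness) realizes the documented
optimum — no fragmentation, soma-protective fidelity — in a
resource-limited population below replacement, where quality competition
rather than output competition decides the ranking.

## Numerical choices and testing

Compositions are validated to the simplex with renormalization tolerance
$10^{-9}$ (drift is absorbed, construction bugs are not). The closed-form
propagation is cross-checked against adaptive ODE integration (`deSolve`,
tolerances $10^{-12}/10^{-14}$) to $10^{-9}$ over 200 random draws with
$t \le 100$ and rates $\le 0.2$; the eigen-limit against $10^4$-step
lineage iteration to $10^{-8}$ over 200 strict-dominance draws. The
property suite fuzzes randomly generated valid configs
(`generate_fixture()`, deterministic in its seed, with optional
regime-forcing solved from the dominance inequality with a 1.5 margin) for
simplex conservation, bound obedience of realized growth ratios, the
purging corollaries, and the exact reduction of the full recursion to a
two-type system when fragmentation is off. Problem sizes throughout
(21 × 21 grids, 30 generations, 100–200 fuzz draws) are desk-scale choices
that keep the full suite in minutes while leaving the conclusions
insensitive to further refinement.

## Worked example

```{r example, eval = FALSE}
cfg <- load_scenario("FRPG-FR")
classify_regime_config(cfg)
run_pedigree(cfg, 30)
sw <- sweep_fitness(cfg, theta = 0.7, s = 1.5)
sw$global      # optimal (phi, I) cell for this strategy surface
sw$per_phi     # optimal suppression per fragmentation level
```

## Known limitations

The model is deterministic and infinite-population: no demographic noise,
no finite-cell-count effects within organisms, no spatial tumour structure
(anterior/posterior localization is representable only through the
inheritance weights), no overlapping generations, and no evolutionary
dynamics on the strategy parameters themselves — optima come from
exhaustive sweeps, not mutation–selection. Reconstructed constants are
exactly that; the scenario files are the single place to revise them, and
every conclusion shipped with the package is qualitative structure, not
absolute numbers.
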