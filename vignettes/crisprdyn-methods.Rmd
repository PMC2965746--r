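---
title: "Models and methods: chemostat dynamics of CRISPR-mediated immunity"
author: "crisprdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: chemostat dynamics of CRISPR-mediated immunity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprdyn)
```

# The scientific question

CRISPR arrays give bacteria sequence-specific, acquired immunity against
lytic phage and conjugative plasmids. Whether that immunity is what
establishes and maintains CRISPR in bacterial populations is an ecological
question: immunity must pay for the intrinsic growth-rate (Malthusian
fitness) cost of carrying and expressing the system, and it competes with
cheaper defenses such as envelope resistance (loss of the phage receptor).
`crisprdyn` implements deterministic chemostat models of these dynamics and
the closed-form invasion/maintenance criteria they imply, so the conditions
favoring CRISPR can be explored quantitatively and turned into testable
predictions for chemostat experiments.

# Shared habitat model

Both models live in a 1 ml continuous-culture vessel. Medium with the
limiting resource at concentration $A$ (µg/ml) flows in at dilution rate $w$
(hr$^{-1}$); all populations and excess resource wash out at the same rate.
Cells grow by Monod kinetics, $\psi_i(R) = V_i R/(k + R)$, where $V_i$
(hr$^{-1}$) is the sole intrinsic fitness parameter of strain $i$ and $k$
(µg/ml) is the half-saturation constant. Resource is consumed as
$e \sum_i \psi_i X_i$ with conversion efficiency $e$ (µg per cell).

A lone population with $V > w$ equilibrates at
$R^* = kw/(V - w)$ and $N^* = (A - R^*)/e$
(`resource_equilibrium()`, `bacterial_equilibrium()`). With the reference
habitat ($A = 50$, $w = 0.2$, $k = 0.25$, $e = 5\times10^{-7}$) and $V = 1$,
$N^* \approx 10^8$ cells/ml. All times are hours; densities and counts
coincide because the vessel has unit volume.

# The lytic-phage model

Populations: sensitive non-CRISPR $N$, envelope-resistant $N_R$ (no
adsorption), sensitive CRISPR $C$, immune CRISPR $C_R$, free phage $P$.
Phage adsorb by mass action with rate constants $\delta_N$, $\delta_C$;
bursts are $\beta_N$, $\beta_C$, $\beta_{CR}$ (net of the adsorbed
particle). A fraction $m$ of infections of $C$ abort and immunize the cell
($C \to C_R$); immunity is lost at rate $v$; envelope resistance arises by
mutation at rate $\mu$ per division ($\mu \psi_N N$; a constant-rate variant
is available via `mu_growth_coupled = FALSE`).

Immunity is not absolute. The effective killing rate of phage on $C_R$
rises with the multiplicity of infection $M = P/C_R$:

$$\delta_{CR}(M) = \delta_{MIN} + x\,(\delta_{MAX} - \delta_{MIN})
  \frac{M^n}{q^n + M^n},$$

so immune cells are effectively resistant at low $M$ but can be overwhelmed
when phage vastly outnumber them ($x$ sets the magnitude of the effect, $q$
the half-effect MOI, $n$ the steepness). Independently of killing, phage
that adsorb to $C_R$ are always removed from the free pool at the full
$\delta_{MAX}$ — immune cells are a phage *sink*. The full right-hand side
is documented in `?phage_rhs` and checked term-by-term against independent
arithmetic in the test suite.

# The conjugative-plasmid model

Populations: plasmid-free/bearing non-CRISPR $N$, $N_P$; plasmid-free and
plasmid-bearing CRISPR $C$, $C_P$; and $C_X$, CRISPR cells whose array
carries plasmid-derived spacers making them immune to receipt. Transfer is
mass action with donor-recipient constants $\gamma_{NN}, \gamma_{NC},
\gamma_{CN}, \gamma_{CC}$; a fraction $m$ of transfers into $C$ abort and
immunize the recipient directly to $C_X$. Plasmids segregate at $\tau_N$,
$\tau_C$ (hr$^{-1}$); $C_X$ reverts to $C$ at rate $v$; the CRISPR element
itself is lost at rate $z$ ($C \to N$, $C_P \to N_P$). See `?plasmid_rhs`.

Three structural choices deserve note, each made once and surfaced as a
documented default:

* **$C_X$ donates nothing.** It is immune to receipt and carries spacer
  sequences, not a complete conjugative plasmid, so it contributes no
  $\gamma$ terms.
* **Immunization bypasses $C_P$.** New immune cells arise from the transfer
  flux into $C$, going directly to $C_X$.
* **$z$ does not touch $C_X$ by default** (it loses immunity only through
  $v$); the flag `z_includes_CX` extends CRISPR loss to $C_X$ if wanted.

# Closed-form criteria

* **Phage establishment** (`phage_establishment_threshold()`): phage invade
  a resident $N^*$ when production outruns washout,
  $\delta_N \beta_N N^* > w$, i.e. the critical product is $w/N^*$
  ($2\times10^{-9}$ ml/hr at the reference habitat).
* **Plasmid maintenance** (`critical_gamma()`): at the resident equilibrium
  the plasmid-free population grows at exactly $w$, so plasmid carriage
  costs $w(1 - V_{NP}/V_N)$; adding segregation, maintenance requires
  $$\gamma_{NN} > \frac{w\,(1 - V_{NP}/V_N) + \tau_N}{N^*},$$
  $1.1\times10^{-10}$ ml cell$^{-1}$ hr$^{-1}$ for a 5% plasmid cost with
  $\tau_N = 10^{-3}$. Segregation enters as a constant per-hour rate: that
  form reproduces the reference critical value exactly, whereas a
  growth-coupled variant would give $1.02\times10^{-10}$.
* **Immune-culture kill curve** (`immune_decline_curve()`): in batch
  culture, phage adsorbing at $\delta_{MAX}$ to an immune culture growing
  exponentially at $V_R$ decline as
  $P(t) = P_0 \exp[-\delta_{MAX} C_{R0} (e^{V_R t} - 1)/V_R]$,
  the predicted readout of an experiment testing that phage infecting
  immune cells are lost. The closed form is validated against direct
  quadrature of its defining ODE.

Both simulation brackets (0.5x/2x around each threshold) behave as
predicted; the test suite runs them routinely.

# Numerical methods

* **Integrator.** `deSolve::lsoda` (stiff-capable, variable step) with
  `rtol = 1e-8`, `atol = 1e-10`, reporting every 0.5 hr. Halving the
  tolerances moves final states of the oscillatory reference scenario by
  under $10^{-5}$ relative; `ode45` agrees within $3\times10^{-5}$.
* **Phage loss rule.** When free phage fall below $10^{-1}$/ml at a
  reported step they are set to exactly zero and a `phage_extinct` event is
  logged; with $P = 0$ every phage term vanishes, so the state stays zero.
  The solver works on raw densities (no log transform) precisely so this
  event semantics is exact; reported states are floored at zero.
* **Low-density refuge.** Hosts below `refuge_density` (default
  $10^2$ cells/ml) cannot be adsorbed; this bounds the predator-prey
  oscillations that otherwise grow without limit. A hard on/off switch
  makes the refuge boundary a *sliding surface* — trajectories chatter on
  it (killed just above, protected just below) and a variable-step solver
  stalls with step size collapsing to zero. The switch is therefore a steep
  smooth sigmoid, $(X/\rho)^4 / (1 + (X/\rho)^4)$, half-engaged at the
  refuge density itself. The refuge applies per host population, not to
  total bacterial density: the protected quantity is the density of each
  prey type the phage must find.
* **MOI guard.** $M = P/C_R$ is computed with the denominator floored at 1
  cell/ml, so the $C_R$ killing term goes to zero smoothly as $C_R \to 0$.

# Scenario presets and the outcome classifier

`preset()`/`run_preset()` expose twelve named invasion scenarios (see
`preset_names()`); their serialized configurations flag every value as
scenario-defining or default. Invasion initial conditions follow one
convention: residents at their analytic equilibrium, invading cells at
$10^3$/ml, phage at $10^4$/ml. Phage scenarios run 500 hr; plasmid
scenarios 2000 hr, because the immune-CRISPR invasion of an established
plasmid community is slow by construction. The `fig6c` scenario needs the
joint $N$-$N_P$ coexistence state, which has no simple closed form; it is
obtained by a deterministic 3000 hr burn-in of the plasmid model without
CRISPR classes.

`classify_outcome()` reduces a trajectory to an ecological verdict over the
final 20% of the run (means over a window, not instantaneous values,
because the predator-prey oscillations persist): persisting populations
(mean above 1 cell/ml and, for phage, no extinction event), the dominant
*bacterial* population (free phage are particles, not cells, and are
reported separately as `phage_persisted`), and the limitation regime —
phage-limited when the mean resource exceeds half the reservoir
concentration (cells scarce while food is abundant means predation, not
resources, limits the community), resource-limited otherwise, washout if no
bacteria persist.

# Calibration of unprinted parameters

The scenario-defining growth rates, adsorption constants, MOI parameters,
transfer/segregation/loss rates above are fixed by the scenarios
themselves. Four quantities are not, and were set once as package defaults:

* $m = 0.1$ (phage), $v = 10^{-3}$/hr, $\mu = 10^{-8}$: plausible
  laboratory-scale values; the scenario regime structure is insensitive to
  $m$ across $[0.01, 0.3]$ (tested).
* **Burst sizes** $\beta_N = \beta_C = \beta_{CR} = 150$. The scenarios
  state only that the bursts are equal and that parameters sit in the
  *E. coli*/T-phage range. The burst size controls peak phage pressure and
  with it whether strong-MOI immunity override can hold the immune
  population down: at $\beta \lesssim 100$ the strong-MOI scenario
  (`fig4c`) collapses to resource-limited immune dominance during the first
  phage trough, while $\beta = 150$ (well within the empirical T-phage
  range) yields the full reference regime structure — including the
  phage-limited coexistence state. This is an explicit calibration against
  the reference regimes, not an independently measured value.
* **MOI magnitude in the envelope-resistance scenarios.** The `fig5`
  scenarios inherit the shared phage parameters, but the MOI magnitude
  differs between the source panels ($x$ = 0, 0.5, 0.2). Only the modest
  effect $x = 0.2$ reproduces both reference outcomes — with $x = 0$ the
  phage survive on a sensitive-host niche instead of being eliminated in
  `fig5a`; with $x = 0.5$ periodic override killing keeps the immune
  population below the resistant one in `fig5b`. The presets use
  $x = 0.2$.

# What the deterministic models do and do not capture

These are mass-action, infinite-population caricatures. They omit latent
periods, spatial structure, stochastic loss of rare invaders (an invader at
$10^3$/ml in 1 ml is 1000 cells; real invasions can fail by drift),
host-range coevolution and spacer-sequence evolution, repressed conjugative
pili, and multi-phage communities. Passing regime checks therefore show
that the deterministic skeleton reproduces the reference dynamics, not that
real chemostats will match them quantitatively — the models' role is to
generate qualitative, testable predictions and to make the invasion
criteria explicit.

# A worked example

```{r example, eval = FALSE}
env <- chemostat_env()
bacterial_equilibrium(env, V = 1.0)        # 99875000 cells/ml
phage_establishment_threshold(0.2, 1e8)    # 2e-09 ml/hr
critical_gamma(1.0, 0.95, 0.2, 1e-3, 1e8)  # 1.1e-10 ml/cell/hr

res <- run_preset("fig4b")
res$outcome
# regime: resource-limited; dominant: C_R; persisting: N, C, C_R, P
```
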