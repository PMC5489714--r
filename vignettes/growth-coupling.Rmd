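---
title: "Deciding strong growth coupling with constrained minimal cut sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding strong growth coupling with constrained minimal cut sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcs)
```

## The decision problem

Growth-coupled strain design seeks knockouts that make product synthesis an
obligatory by-product of metabolism. *Strong* coupling is the demanding
variant: after the knockouts, **every** steady-state flux distribution that
serves the maintenance demand must reach at least the demanded product
yield — production is enforced even at zero growth. This package decides,
per metabolite and demanded yield level, whether such a knockout set exists.

With stoichiometric matrix $N$, bounds $\alpha \le r \le \beta$, substrate
uptake $r_S$, product export $r_P$ and growth rate $\mu$, the *undesired*
region is the single inequality $r_P - Y^{P/S}_{\min} r_S \le 0$ (yield at
or below threshold) and the *desired* region is the pair
$-r_P + Y^{P/S}_{\min} r_S \le 0$, $-\mu + Y^{BM}_{\min} r_S \le 0$. A
knockout set $K$ induces strong coupling iff
$\{ r : Nr=0,\ \alpha \le r \le \beta,\ T r \le t,\ r_i = 0 \ \forall i \in K \}$
is empty while the analogous desired region is not. Because the
inequalities are non-strict, fluxes whose yield equals the threshold count
as undesired; surviving desired solutions therefore have yield strictly
above it.

The demanded yield $Y^{P/S}_{\min}$ is a fraction (default 10/30/50 %) of
the metabolite's maximum yield, computed by maximizing the product export
flux under the substrate uptake limit and maintenance demand and dividing
by the realized uptake at the optimum. We interpret "divided by the
substrate uptake" as the realized uptake because it is well defined whether
or not the uptake limit binds (they coincide when it binds, which is the
generic case).

## The certificate MILP

Emptiness of a polyhedron is certified by Farkas duality. For each
candidate knockout pattern, encoded by binary indicators $zp_i$ (and
$zn_i$ for reversible reactions), the MILP demands

* a dual certificate of the knocked-out undesired region: per-reaction
  stationarity $N_i^\top u + \lambda^{ub}_i - \lambda^{lb}_i + T_i^\top w +
  vp_i - vn_i = 0$ and the normalization
  $\beta^\top \lambda^{ub} - \alpha^\top \lambda^{lb} + t^\top w \le -1$,
  where $vp_i, vn_i \ge 0$ are the knockout duals, allowed to be nonzero
  only when the reaction is cut ($vp_i \le M\,zp_i$, $vn_i \le M\,zn_i$,
  $zp_i + zn_i \le 1$); $vn_i$ exists only for reversible reactions, since
  an irreversible reaction is already bounded below by zero;
* a primal witness of the desired region that respects the knockouts:
  $N r^{des} = 0$, $D r^{des} \le d$ and
  $\alpha_i (1 - zp_i - zn_i) \le r^{des}_i \le \beta_i (1 - zp_i - zn_i)$;
* the objective $\min \sum zp_i + \sum zn_i$.

Indicators of irrepressible reactions are fixed to zero, so exchange,
transport, spontaneous and pseudo reactions (and optionally gene-less
reactions) can never be cut. The certificate's right-hand side $-1$ is an
arbitrary normalization (any negative constant is equivalent by scaling),
and $M = 10 \times \max(1, \max|\text{bound}|)$.

The dual side needs **finite** bounds for every reaction; they come from a
flux variability analysis run with the substrate limit, maintenance demand
and the minimum-biomass-yield row, with unbounded directions capped at
±2000 mmol gDW⁻¹ h⁻¹. Two consequences are handled explicitly. First, if
that FVA is itself infeasible, the network cannot grow at the demanded
biomass yield at all and coupling is immediately refuted. Second, because
the biomass-yield row tightens bounds that then describe the undesired
region in the dual, the MILP may admit *unsound* candidates. Every
candidate is therefore re-verified with two plain LPs on the original
network with its original (possibly infinite) bounds, and a verdict is
FEASIBLE only for a verified cut set. Infeasibility verdicts stay sound
under the tightening: any truly valid cut set's undesired region is empty
with the original bounds, hence also with tighter ones, so it would admit
a certificate — if the MILP is infeasible, no valid cut set exists. The
same argument makes MILP infeasibility under the smaller-support constraint
a proof of size-optimality in `shrink_cmcs()`.

An accepted incumbent need not be optimal: the solver stops at a relative
gap of 0.98, since any cut set — however large — proves feasibility, and is
afterwards reduced to an inclusion-minimal cMCS by dropping knockouts whose
removal keeps the undesired region infeasible (only one LP per candidate
removal is needed, as desired-region feasibility is monotone under removing
cuts). Reduction visits knockouts in descending network order; other orders
may yield different, equally valid cMCS.

## Pipeline around the MILP

Per candidate metabolite: add a temporary export-only exchange if none
exists; compute the maximum yield (zero ⇒ not producible, unbounded ⇒ not
substrate-limited; both excluded); process the yield levels in ascending
order, re-verifying a lower level's cut set at the next level and skipping
the MILP when it still applies; otherwise compress the network, run FVA,
assemble and solve the MILP with up to 10 seeded attempts, verify, reduce.
After all levels, a smaller cut set found at a higher level replaces larger
lower-level records (sound by threshold monotonicity: regions are nested in
the yield level, so validity transfers downward). The batch screen
classifies every substrate-producible organic metabolite — organic meaning
a carbon-containing formula outside an explicit inorganic-carbon list
(CO₂, CO, carbonate, bicarbonate), since bicarbonate contains carbon but
should not count — excluding all compartmental instances of the substrate
compound, and considering only the excreted instance of compounds wired to
an open standard outflow.

Compression merges fully coupled reaction sets (rows of a kernel basis of
$N$ proportional within $10^{-9}$; bounds deliberately ignored, since
bound-aware coupling is condition-dependent while kernel coupling is
lossless) and removes linearly dependent mass-balance rows. Blocked
reactions — identically zero in the kernel — are pruned first; they can
carry no steady-state flux and thus affect no verdict. Cutting one member
of a fully coupled set forces the whole set to zero, so a compressed cut
expands to a single repressible member, with the remaining repressible
members reported as interchangeable alternatives. Candidate cut sets are
always expanded and verified on the original, uncompressed network.

Gene-level designs integrate the gene–protein–reaction logic structurally:
each associated reaction consumes an auxiliary catalysis metabolite,
produced by one enzyme pseudo-reaction per DNF term of the association;
enzymes consume gene-product metabolites made by translation
pseudo-reactions, and only translation reactions are repressible.
Reversible associated reactions are split into two irreversible halves
sharing the auxiliary metabolite, because otherwise backward flux would
*produce* it. Genes occurring in the association of any irrepressible (or
DNF-capped, see below) reaction are protected from knockout. The DNF
expansion is capped at 64 terms per reaction; beyond the cap the reaction
is left unextended with a warning, i.e. treated as gene-irrepressible —
genome models rarely exceed this.

## Numerical and design choices

* **Solver.** No LP/MILP solver exists in the R dependency stack, so all
  programs are solved by HiGHS through a persistent Python/SciPy worker
  subprocess (JSON-line protocol, `inst/python/lp_worker.py`); round-trip
  overhead is a few milliseconds per LP. Feasibility and zero tolerances
  are $10^{-6}$ on the natural flux scale, the standard practice for
  constraint-based models.
* **Solver seeds.** SciPy's MILP interface exposes no random seed, so the
  "different seed per attempt" retry is emulated by a seed-determined
  permutation of the variable order, which deterministically changes the
  solver's search path. Retries matter only when attempts time out, which
  does not occur at fixture scale.
* **Zero-flux exclusion.** The undesired region must not contain the zero
  vector, or no knockout set could ever empty it. A maintenance reaction
  with positive lower bound achieves this; for models without one, a
  minimum substrate uptake of $0.001 \times$ the uptake limit is imposed on
  the undesired region instead (configurable; documented rather than
  silent, since the choice is not derivable from first principles).
* **Uptake orientation.** Internally exchanges are export-positive; the
  substrate uptake rate is the configured orientation times the exchange
  flux, so yield rows are written identically for SBML-style negative
  uptake fluxes and for fixtures with forward uptake reactions.

## What the fixtures emulate — and what a green test does not establish

The bundled fixtures mimic the architecture that makes genome-scale models
decidable: a limited substrate uptake, a maintenance reaction with positive
lower bound, a biomass sink, and product/waste branches whose energy
stoichiometry controls whether coupling is enforceable. `TOY3` couples ATP
supply to product formation (unique cMCS `{CAT2}`), `TOY1` decouples them
(provably infeasible at every level). The random generator draws one of the
two archetypes per seed plus decorations — coefficients in $\{1,2\}$, an
optional ADP/ATP conserved moiety (a planted rank deficiency), an optional
fully coupled two-step product chain, duplicate branches, per-branch
repressibility — keeping at most 12 reactions and 6 repressible reactions
so that an exhaustive oracle (every knockout subset, two LPs each, on the
original network, free of FVA tightening and big-M) defines ground truth.
Green tests therefore establish correctness of the decision logic, not
genome-scale performance: fixtures have no thousands-of-reactions MILPs, no
degenerate near-parallel constraints stressing big-M numerics, no
multi-compartment transport chains, and no time-limit-bound UNDECIDED
outcomes. Genome-scale behaviour (model parsing aside) is exercised only
through the same code paths, not measured.

## Known limitations

* Weak coupling (yield guaranteed only near maximal growth) and
  enumeration of *all* smallest cMCS are out of scope.
* Co-utilization of multiple substrates is not supported; yield rows
  reference a single configured substrate exchange.
* The big-M formulation can in principle leak with extreme bound ratios;
  leaked candidates are caught by verification (never silently returned),
  costing retries rather than correctness.
* SBML support covers the Level 3 core + fbc subset used by BiGG-style
  models; kinetic laws, annotations and SBML writing are not supported.
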