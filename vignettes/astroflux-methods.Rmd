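---
title: "Methods: constraint-based astrocyte stress modeling and proteomics integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based astrocyte stress modeling and proteomics integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroflux)
```

# The model and its assumptions

`astroflux` implements flux balance analysis (FBA) for astrocyte metabolic
networks: given a stoichiometric matrix $S$ (metabolites × reactions), the
feasible flux vectors $v$ satisfy the steady-state mass balance $S v = 0$
together with per-reaction bounds $lb \le v \le ub$ (µmol/g/min throughout;
for exchange reactions negative flux is uptake, positive is release).
Within this polytope a linear objective is optimized. FBA predicts
*capability*, not kinetics: the returned fluxes are an optimal routing under
the declared objective and constraints, not measurements of in vivo rates.

## The multi-tier objective

Astrocyte energetics are encoded as a *lexicographic* two-tier objective:

1. **ATP maintenance** — maximize flux through the cytosolic ATP hydrolysis
   sink (ATP~c~ + H~2~O~c~ → ADP~c~ + P~i,c~), representing the cell's
   energetic demand.
2. **Glutamate–glutamine cycling** — maximize conversion of imported
   glutamate to exported glutamine, the astrocyte's neurotransmitter
   recycling role.

"Multi-objective" admits several combination rules; we use lexicographic
order (energy first) because it is deterministic and matches the stated
priority of ATP maintenance. After tier $k$ is solved, the constraint
$c_k^\top v \ge z_k - \delta |z_k|$ is added before tier $k+1$ is
optimized; the relative retention tolerance $\delta$ defaults to $10^{-6}$.

## Unique flux representatives: pFBA and FVA

Optimal flux vectors are generally non-unique. So that downstream percent
changes are well defined and reproducible, `solve_lexicographic()` finishes
with a parsimonious step: among vectors retaining all tier optima within
$\delta$, it returns one minimizing total absolute flux
$\sum_i |v_i|$ (the standard split into nonnegative parts). Because the
parsimonious step may spend the $\delta$ slack, returned fluxes can sit up
to $\delta |z|$ below a tier optimum; the reported `objective_values` are
the exact tier optima. `run_fva()` quantifies how much any conclusion
depends on the representative: it brackets each reaction's flux over the
near-optimal set at a chosen objective-retention fraction.

## The LP engine

The linear programs are solved by a dense bounded-variable two-phase primal
simplex written for this package (`R/lp_simplex.R`), with Bland's rule
throughout (guaranteed termination on degenerate problems) and a final
clean re-solve of the basic system for accuracy. At the package's problem
sizes (tens of reactions; ~60 reactions and ~50 metabolites for the toy
network, twice that many variables in the parsimonious step) dense
refactorization per iteration is well inside interactive speed, and the
test suite holds its optima to $10^{-9}$ against an independent
vertex-enumeration oracle. Tolerances: primal feasibility and reduced-cost
thresholds $10^{-9}$; accepted solutions must satisfy
$\max|Sv| \le 10^{-8}\max(1, \|v\|_\infty)$ (`verify_solution()`).

# Conditions

Perturbations are encoded as bound-override sets (`make_condition()`),
applied to a copy of the model; scale overrides multiply both bounds by a
factor in $[0,1]$, so a condition can only shrink the feasible region —
hence any condition optimum is bounded by the steady-state optimum, a
property the tests assert.

* **Steady state.** Physiological uptake/release rates from the bundled
  astrocyte rate table (glucose 0.19, oxygen 0.530, CO~2~ release 0.515,
  glutamate 0.232, glutamine release 0.5 µmol/g/min, and further
  metabolites) are applied to matching exchange reactions; entries with no
  exchange in the model are reported unmatched. The table does not print
  directions, so the package reads glutamine and CO~2~ as release and the
  rest as uptake.
* **Hypoxia.** The oxygen-exchange bound is scaled by `o2_fraction`
  (default 0.02): 2 % of physiological oxygen uptake is admitted.
* **Acidosis.** Reduced buffering capacity: the Na⁺/H⁺ exchanger and the
  CO~2~/bicarbonate system (bicarbonate importer and CO~2~ exchange) are
  scaled by `buffer_fraction` (default 0.5). The magnitude of the reduction
  is not a measured quantity; 0.5 is an explicit package assumption,
  exposed in the configuration so it can be swept. The reaction ids of the
  acid-handling block are likewise configuration, since they differ between
  reconstructions.
* **Combined.** The union of both override sets.

# The toy astrocyte network

`generate_toy_astrocyte_model()` builds a deterministic ~60-reaction lumped
network covering glycolysis (with lactate dehydrogenase as the proton
source of the network's acid load), glycogen synthesis/phosphorolysis, the
oxidative pentose phosphate branch with a phosphoglucomutase-2 shunt,
pyruvate dehydrogenase and a lumped TCA cycle, NADH- and FADH~2~-oxidizing
oxidative phosphorylation (P/O ratios 2.5 and 1.5, textbook consensus,
configurable), a malate–aspartate NADH shuttle, ketone-body handling,
carnitine-shuttled β-oxidation of linoleate, the glutamate–glutamine cycle,
glycosphingolipid degradation, and the Na⁺/H⁺ / CO~2~-bicarbonate
acid-handling block. GPR rules carry the enzyme symbols used by the
integration stage (PYGB, PKM, PDHA1, NDUFA11, COX4I1, SDHA, CPT2, G6PD,
PGM2, HEXA, …).

Three design choices deserve explanation:

* **ATP-neutral glutamine synthesis.** Lumped glutamine synthesis is
  written glu~c~ → gln~c~. With a literal ATP cost, holding tier 1 at its
  optimum would leave no ATP for tier 2 and force the glutamate cycle to
  zero; the lumping keeps the energy and nitrogen tiers separable, so
  tier 2 saturates the glutamate uptake bound (0.232) as intended.
* **Forced turnover variant.** Parsimonious FBA silences futile cycles by
  construction, so the glycogen-turnover variant
  (`include_glycogen_turnover = TRUE`) forces 0.001 µmol/g/min lower
  bounds on glycogen synthase, glycogen phosphorylase, the
  fructose-2,6-bisphosphate-forming reaction and lactate dehydrogenase.
  This is a fixture device that makes the steady-state physiology checks
  (active glycogen turnover, F2,6BP formation, lactate production, NAD⁺/NADH
  turnover) visible at the optimum — not a claim about regulation.
* **Demand-driven default comparisons.** At this lumped scale, maximizing
  ATP under restricted bounds mostly lowers the optimum rather than
  rerouting flux. The pipeline therefore pins the ATP-maintenance demand at
  the anaerobic-feasible level (0.38 µmol/g/min, the glycolytic
  substrate-level yield of the full glucose uptake) by default, so every
  condition can still meet demand and the comparison isolates *route
  choice*: hypoxia then shifts ATP production from oxidative
  phosphorylation into glycolysis, the signature of interest.
  Capacity-driven comparisons remain available
  (`config$toy$atp_demand = NULL`).

## Closed-form optima

The lumped yields make the ATP-maintenance optimum analytic
(`analytic_toy_fluxes()`), and the test suite holds the LP to these values
at $10^{-9}$:

* anaerobic (no oxygen): $2 \times 0.19 = 0.38$, all glycolytic, with
  lactate release forced to 0.38;
* hypoxia (2 % oxygen): every marginal oxygen use — shuttled cytosolic
  NADH, pyruvate dehydrogenase, or the full TCA package — yields 5 ATP per
  O~2~ at the default P/O ratios, giving
  $0.38 + 5 \times (0.02 \times 0.530) = 0.433$;
* aerobic: carbon can leave as pyruvate or ketone bodies while its
  electrons are retained, so CO~2~ release stays slack and the optimum is
  oxygen-limited at $0.38 + 5 \times 0.530 = 3.03$.

At the fixed default yields the NADH route and the TCA package tie exactly
at 5 ATP/O~2~ (since $3 \times 2.5 + 1.5 + 1 = 4 \times 2.5$); with other
yields the marginal route changes, so `analytic_toy_fluxes()` refuses
non-default yields rather than report a stale formula.

# Flux comparison

`compute_percent_changes()` reports the signed percent change
$100\,(v_{cond} - v_{steady})/|v_{steady}|$ per reaction. The signed form
(rather than magnitude-based) preserves direction for reversible reactions;
the alternative reading is recorded in the configuration key
`change_metric`. Fluxes below $\varepsilon = 10^{-9}$ (the LP tolerance)
count as zero; a reaction switching on or off gets a qualitative sentinel
(`newly_active` / `silenced`) instead of an undefined percentage. A change
is **robust** when it *strictly exceeds* the 10 % threshold (a change of
exactly 10 % is not robust; a $10^{-9}$ guard keeps the decision stable
against floating-point residue), and sentinel records are always robust —
switching on or off is a larger qualitative change than any percentage.
Subsystem summaries report the mean, median and sum of the finite percent
changes (all three, since a headline aggregate could be any of them) with
sentinels counted in `n_robust` but excluded from the averages.

# Proteomics

The differential test is a two-sided Welch $t$ on log2 abundances with
log2 fold changes computed from linear-scale group means; the choice of
test is a stand-in recorded in the configuration, as no specific test is
mandated for normalized label-free intensities. Benjamini–Hochberg
adjustment uses the standard step-up (via `stats::p.adjust`; the test suite
compares it to a direct implementation of the definition on 1,000 random
vectors). The DEP filter applies three criteria conjunctively — linear
$|FC| \ge 1.2$ (boundary inclusive), $p < 0.10$ (strict) and
$q \le 0.05$ (inclusive) — and reports per-criterion rejection counts,
because "adjusted p-value" and "FDR" bounds can be read as referring to
different adjustments; surfacing the counts lets a user reproduce either
reading without the package guessing intent.

## The synthetic generator

`generate_synthetic_proteomics()` emulates a normalized 3-vs-3 label-free
LC-MS/MS comparison: per-gene log-normal baselines (log2 mean 20, sd 1.5),
shared log2-scale noise (sd 0.2), 200 genes, and planted log2 fold changes
in the injured group — a large glycogen-phosphorylase effect (PYGB,
log2FC 5.581) plus effects of |log2FC| 2.6–3.2 on the toy network's other
flux-relevant enzymes, signed to agree with the direction of the
corresponding flux shifts under oxygen/buffering stress. The non-PYGB
magnitudes are a package choice, set by a power argument: with $n = 3$,
noise 0.2 and 200 genes, clearing $q \le 0.05$ requires roughly
$p < \alpha k/m \approx 0.0025$, which an effect only clears reliably when
$|log2FC|$ is an order of magnitude above the noise. What the generator
does **not** emulate: peptide-level missingness, intensity-dependent
variance, correlated proteins, or contamination — so green tests here show
the *pipeline logic* is correct, not that the thresholds are well-powered
for real tissue proteomics.

# Integration

Passing DEP symbols are paired with every reaction whose GPR mentions them
(one row per enzyme–reaction pair; multi-subunit complexes are not rolled
up, so subunits appear as separate rows). Each row carries the proteomic
log2FC next to the per-condition percent flux changes; a cell is
*concordant* when the signs agree, and not applicable when either side is
zero (within $10^{-6}$ percent, guarding against LP residue) or the flux
change is a sentinel. The concordance summary reports fractions over
applicable cells only — an empty applicable set yields an undefined
fraction, never zero — overall and per subsystem. Concordance is sign-only
by design: the flux and abundance scales are incommensurable, and the
qualitative direction is the claim being checked.

# Determinism and numerical choices

Given a configuration and seed, `run_pipeline()` output is byte-identical
across runs: the toy model is deterministic, the simplex uses Bland's rule
(no random pivoting), the proteomics generator is seeded, and the run log
contains no timestamps. Numerical-zero is $10^{-9}$ µmol/g/min everywhere
a flux is compared to zero, matching the LP tolerance; GPR complexes are
de-duplicated sorted sets (C-locale ordering, so results do not depend on
the session locale); ties among optimal vertices are broken by the
parsimonious step and, below that, deterministically by Bland's rule.

# Problem sizes

The shipped analyses and tests run at desk scale by design: the ~60-reaction
toy network (LPs with ≤ ~120 variables in the parsimonious step), 20
random ≤ 8-reaction networks for the oracle comparison, 200-gene
proteomics tables, 1,000 random vectors for the BH comparison and 500
replicates for the empirical-FDR check. The loaders accept genome-scale
SBML/JSON reconstructions; the simplex is dense, so networks beyond a few
hundred reactions will be slow and a sparse/revised backend would be the
natural extension point (`solver` is a configuration key for this reason).

# Known limitations

* FBA optimality is an assumption about the cell; injured tissue may
  operate suboptimally, and the demand-driven default is one specific
  resolution of that ambiguity.
* The acidosis encoding is purely a bound reduction on acid-handling
  capacity; there is no explicit pH, proton-motive force or membrane
  potential.
* The toy network's acidosis response is scale-dependent: at the default
  demand level the halved buffering capacity does not bind, so
  acidosis-alone changes are essentially nil in the shipped configuration —
  visible honestly in the outputs as zero robust changes — while
  capacity-driven runs show the expected oxidative restriction.
* Enzyme attribution is by GPR symbol membership; isozyme redundancy (OR
  branches) and complex stoichiometry are not weighted.
* The proteomic and flux layers come from different organisms/scales in
  the motivating use case (bulk cortical tissue vs an astrocyte network);
  concordance is a qualitative alignment screen, not causal evidence.
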