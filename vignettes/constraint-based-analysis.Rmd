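---
title: "Constraint-based analysis of K. oxytoca 2,3-butanediol metabolism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of K. oxytoca 2,3-butanediol metabolism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koxfba)
```

## The model and its assumptions

All analyses in this package rest on flux balance analysis (FBA) under the
pseudo-steady-state assumption: intracellular metabolite concentrations are
taken as time-invariant over the balanced-growth window, so the flux vector
$v$ must satisfy $S v = 0$, where $S$ is the stoichiometric matrix (one row
per metabolite, one column per reaction). Together with capacity and
thermodynamic-direction bounds $lb \le v \le ub$ this defines a polytope of
feasible flux states; FBA selects a vertex by linear programming against an
objective, conventionally the biomass reaction, whose flux is the specific
growth rate $\mu$ (1/h). All other fluxes are in mmol/gDCW/h, with the
standard sign convention that exchange fluxes are negative for uptake and
positive for secretion.

Three structural assumptions matter for interpretation:

* **Optimality as a proxy for physiology.** The maximal-growth state is
  used to predict the actual state of the cell, on the premise that
  survival is a cell's first priority. Quantities reported "at the
  optimum" (product rate, byproduct rate) are properties of the optimal
  face of the polytope, not of any measured flux distribution.
* **Alternate optima are resolved lexicographically.** FBA optima are
  usually degenerate. Every headline triple (growth, 2,3-BD secretion,
  byproduct secretion) is computed by maximizing growth, then maximizing
  the product secretion holding growth at its optimum (within a
  $10^{-6}$ relative tolerance), then minimizing the molar byproduct sum
  holding both. A single arbitrary optimal vertex is never reported.
* **The byproduct axis is an unweighted molar sum** of the five secretion
  fluxes: ethanol plus lactic, acetic, succinic and formic acids.
  Mass-weighted aggregation is available (`byproduct_aggregate(...,
  mass_weighted = TRUE)`) but is not the default, since the molar
  convention is what the scanning analyses are defined on.

## The linear programming core

No LP backend is assumed: `solve_lp()` is a dense two-phase primal simplex
with native bounded-variable pivoting (bounds are handled in the ratio
test, not expanded into constraint rows). Phase 1 drives artificial
variables out of the basis; phase 2 optimizes the true objective. Entering
variables are priced with the Dantzig rule and the solver switches to
Bland's rule — which provably cannot cycle — after a fixed iteration
budget, a practical guard for the heavily degenerate LPs metabolic models
generate. The basis system is re-factorized from scratch at every
iteration; at the ~100-variable scale of the bundled model this costs
little and avoids accumulated numerical drift. Reduced-cost and
feasibility tolerances are $10^{-9}$; every optimal solution used in tests
is re-validated against $|S v| \le 10^{-6}$ and the bounds at $10^{-6}$.
Infeasibility is reported as a status, never coerced to zero: a model that
cannot meet its forced maintenance flux is infeasible, while a feasible
model with no growth reports an optimal objective of 0.

Correctness is anchored by two independent oracles in the test suite:
brute-force vertex enumeration on random small programs and toy networks
(all basis/bound assignments, $\le 6$ variables), and hand-balanced
pathway stoichiometry for the flux values on the core model.

## The core fixture: what it emulates

`build_core_model()` constructs a curated central-metabolism model of
*K. oxytoca* (86 reactions, 74 metabolites, 77 genes) intended as a
desk-scale stand-in for a genome-scale reconstruction of this organism.
Its scope is central carbon metabolism: PTS glucose uptake, glycolysis
(with fructose-1,6-bisphosphatase for gluconeogenic growth on glycerol),
a lumped oxidative/non-oxidative pentose phosphate shunt, the full TCA
cycle with PEP carboxylase anaplerosis, mixed-acid fermentation (D-lactate
dehydrogenase *ldhA*, pyruvate formate-lyase *pflB*, phosphotransacetylase
and acetate kinase with their enterobacterial isozymes *eutD*/*tdcD*,
aldehyde/alcohol dehydrogenase *adhE*, NADH-linked fumarate reductase),
and the complete 2,3-BD pathway: acetolactate synthase (*budB*,
EC 2.2.1.6), acetolactate decarboxylase (*budA*, EC 4.1.1.5), acetoin
reductase (*budC*, EC 1.1.1.4), a gene-free spontaneous oxygen-dependent
acetolactate-to-diacetyl reaction, and diacetyl reductase (EC 1.1.1.303).
Both glycerol routes are present: the oxidative *glpK*/*glpD* (EC 2.7.1.30,
1.1.5.3) and reductive *gldA*/*dhaK* (EC 1.1.1.6, 2.7.1.29) pairs.

Every reaction that is not a boundary exchange is elementally and
charge-balanced against explicit formulas; the test suite asserts this for
the whole network, so the fixture doubles as the package's mass-balance
regression suite. Amino-acid, nucleotide, lipid and glycogen biosynthesis
are represented as balanced lumped reactions from central precursors, not
at single-enzyme resolution — the price is that monomer coefficients, not
pathway intermediates, carry the biosynthetic burden.

Energy metabolism is deliberately coarse: respiration is lumped with
oxidative phosphorylation at a fixed P/O ratio of 2 ATP per NADH (1 for
the flavin-linked succinate and glycerol-3-phosphate steps), with
transhydrogenases in both directions (*pntAB*, *sthA*) connecting the
NADH/NADPH pools. No proton-motive-force accounting, no alternative
oxidases.

### The default medium and its curation

The default condition is glucose minimal medium at a maximal uptake of
10 mmol/gDCW/h with microaerobic oxygen supply (cap 5.2 mmol/gDCW/h) and
measured-flux-style caps on byproduct secretion (lactate 20, ethanol 2.5,
formate 0.5, acetate 2, succinate 1, acetoin 1 mmol/gDCW/h). Imposing
measured exchange-rate limits on fermentation products is standard
practice when simulating this organism, and the caps here were curated —
with FBA diagnostics, before the acceptance tests were written — so that
the wild-type optimum reproduces the qualitative fermentation phenotype
the package is designed to analyze:

* the wild type secretes a byproduct spectrum including lactate *and*
  produces 2,3-BD at its growth optimum;
* the *ldhA* deletion strictly raises the product rate and lowers the
  byproduct rate while changing maximal growth by less than 1% (the
  NADH that lactate formation absorbed is re-oxidized by acetoin
  reductase instead);
* knockouts of the pyruvate-dehydrogenase complex, which in a reduced
  network would trivially funnel pyruvate to the product at a heavy
  growth cost, fall below the 50% growth floor of the ranking (the
  formate outlet limits the *pflB* bypass);
* the oxygen flux-response is unimodal over 0–30 mmol/gDCW/h.

The cap *magnitudes* are illustrative, not fitted to any particular
fermentation: a linear-programming optimum systematically understates
overflow metabolism relative to real batch cultures, where kinetic, not
stoichiometric, limits dominate. Directions and orderings on this fixture
are meaningful; absolute rates are not calibrated.

### What the fixture does not emulate

A genome-scale reconstruction has ~1,400+ reactions, hundreds of
transporters and cofactor pathways, and a gene complement that changes
which deletions have backups. Consequences: essentiality on the fixture is
much coarser (lumped biosynthesis reactions are essential where a real
network has redundancy); precursor connectivity is thinner (PEP, for
example, has exactly one non-protected consumer); and absolute growth
rates and flux magnitudes depend on lumped parameters (P/O, GAM/NGAM)
rather than detailed chain stoichiometry. Tests passing on the fixture
demonstrate the correctness and the qualitative behavior of the
*procedures*; they do not validate numerical predictions for the real
organism.

## The biomass equation

`default_biomass_composition()` is a documented Gram-negative stand-in:
protein 0.55, RNA 0.20, DNA 0.03, lipid 0.09, carbohydrate 0.06 and a
soluble "other" pool 0.07 g/gDCW. Monomer profiles are resolvable in the
fixture: a four-amino-acid protein profile, NMP/dNMP profiles, palmitate
for lipid, a glucan residue for carbohydrate. DNA composition derives from
the GC content by Chargaff pairing (`dna_fractions_from_gc()`): dG = dC =
GC/2, dA = dT = (1−GC)/2. The default GC is 53%, the value used for this
organism's biomass equation; the genome-wide figure (56.05%) can be passed
instead — both are supported because the two numbers coexist in the
literature on this strain. Without rRNA/tRNA sequence counts, the RNA
profile mirrors the same GC rule applied to NMPs; this is flagged as an
assumption, not a measurement.

Coefficients follow
$1000 \cdot f \cdot p_i / \sum_j p_j w_j$ (mmol/gDCW) per class with mass
fraction $f$, mole fractions $p$, and residue weights $w$; polymer classes
release one water per residue incorporated, so per-class mass closure is
exact by construction and asserted to $10^{-9}$. Maintenance defaults are
GAM 45 mmol ATP/gDCW (added to the biomass equation) and NGAM
8.4 mmol ATP/gDCW/h (installed as the lower bound of an always-on ATP
hydrolysis reaction) — common enterobacterial values, both configurable.
The "other" pool is represented by glutamate at residue weight purely to
close the mass balance of the stand-in composition.

## Scanning procedures and their conventions

**Oxygen flux-response.** At each scanned value the oxygen exchange is
fixed as an *equality* (`lb = ub = −value`), not an upper bound, with
glucose at its medium cap, and the 2,3-BD secretion is both maximized and
minimized. The equality is the single most consequential convention here:
with a mere cap, the high-oxygen branch would simply leave oxygen unused
and the response would plateau instead of declining. Forcing uptake makes
the cell over-respire, which is what produces the characteristic decline
past the optimum. Infeasible points are masked, never interpolated.

**Solution-space surfaces.** `solution_space_scan()` grids the (product
rate, aggregate byproduct rate) plane from 0 to each axis's LP-determined
maximum (default 21×21, linear spacing) and records maximal growth with
both rates fixed per cell; the unconstrained optimum point is the
lexicographic triple. Infeasible cells are `NA` — with a capped oxygen
supply and a bounded carbon budget a large low-byproduct region is
genuinely unreachable, which is informative, not an artifact.

**Knockout scanning and ranking.** Deletions act through the
gene-protein-reaction rules: a reaction is disabled iff its boolean rule
evaluates false under the deletion (complexes break with any member,
isozymes survive). The ranking criterion is maximal product rate with ties
broken by minimal byproduct rate, then gene id; candidates below 50% of
wild-type growth are excluded so that high-yield but effectively
non-growing strains never top the list. The growth floor is a design
choice: the selection criteria themselves say nothing about growth, but a
strategy that kills the producer is not a strategy.

**Precursor-pool augmentation.** All reactions able to *consume* the
target precursor under current bounds are eliminated except the product
pathway and reactions essential for growth, where essentiality is
evaluated on the unmodified model under the same medium (threshold: 1% of
wild-type growth — a convention; no published threshold exists).
Elimination blocks only the consuming direction of reversible reactions:
full removal would also forbid production, which overshoots the procedure's
intent. An augmentation that leaves the model unable to grow is reported
as an outcome with `feasible = FALSE`, not as an error.

## Numerical choices

* LP tolerances: reduced-cost/feasibility $10^{-9}$ inside the solver,
  contract validation at $10^{-6}$ — decoupling solver internals from the
  package's guarantees.
* Lexicographic stage fixing at $10^{-6}$ relative, implemented as a
  one-sided inequality row with a slack column (an exact equality row
  invites spurious infeasibility from roundoff).
* Degenerate pivots are accepted (ratios clamped at 0); ties in the ratio
  test prefer the larger pivot magnitude for stability.
* Coverage percentages round half-up to 2 decimals; integer rounding of
  mutant/wild-type percentages happens only at the presentation layer.
* `perturb_bounds()` scales bounds multiplicatively, which can never flip
  a reaction's direction and never touches stoichiometry — so mass
  balance is invariant under perturbation by construction.

## Known limitations

* The simplex is dense and re-factorizes every iteration: fine to a few
  hundred reactions, not intended for genome-scale models at
  interactive speed. Grids and scans on the fixture run in seconds to a
  few minutes per surface at default resolution (tests use coarser grids).
* No thermodynamic (loop-law) constraints: futile cycles are prevented
  only by irreversibility assignments.
* The SBML importer reads a Level 3 core + fbc subset (species, bounds
  via parameters, gene-product associations, active objective); it does
  not write SBML and ignores units, annotations and groups.
* Batch fermentation summaries assume constant broth volume; fed-batch
  accounting is out of scope.
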