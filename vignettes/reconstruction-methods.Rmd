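---
title: "Methods: metabolic network reconstruction and nutrient-requirement simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic network reconstruction and nutrient-requirement simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and numerical choices
behind `fluxforge`, in the spirit of a methods section: what is computed,
under which assumptions, with which defaults, and what the synthetic
benchmarks do and do not establish.

## The constraint-based model

A metabolic network is represented as a stoichiometric matrix $S$
(metabolites × reactions) with per-reaction flux bounds
$l \le v \le u$ in mmol·gDW⁻¹·h⁻¹. Flux balance analysis (FBA) assumes
steady state, $S v = 0$, and solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

where $c$ indicates a single objective reaction — usually the biomass
pseudo-reaction, whose flux is the growth rate (h⁻¹). Exchange reactions
(`EX_<compound>`, one extracellular species, coefficient −1) connect the
system to the environment; negative exchange flux is uptake. Transport
reactions move species between the extracellular `(e)` and cytosolic
`(c)` compartments; the same compound in different compartments is a
distinct metabolite. These are the standard assumptions of
constraint-based modelling: no kinetics, no regulation, fluxes limited
only by stoichiometry and bounds.

### Bounds policy

Defaults (all mmol·gDW⁻¹·h⁻¹, `bounds_policy()`):

| reaction class | bounds |
|---|---|
| reversible metabolic / transport | (−1000, 1000) |
| irreversible metabolic | (0, 1000) |
| exchange, synthesizable nutrient | (0, 1000) |
| exchange, feed nutrient | (−5, 1000) |
| exchange, trace element | (−1, 1000) |

Exchange classification precedence is trace element > synthesizable >
feed nutrient; an exchange whose compound is in no declared class falls
back to feed nutrient with a warning, the conservative choice for a
nutrition-focused model. The ±1000 values are the conventional "effectively
unbounded" caps; −5 and −1 encode that feed nutrients and trace elements
are available but not unlimited.

## Draft reconstruction and GPR semantics

EC numbers bridge genes to reactions: a reaction enters the draft iff at
least one of its EC numbers is carried by an annotated gene. GPR rules are
built per reaction from the (gene, EC) pairs that justified it: genes
annotated to the *same* EC are treated as subunits of one enzyme complex
and joined with AND; genes reaching the reaction through *different* ECs
are alternative catalysts and joined with OR. This is deliberately
literal — the inputs carry no isozyme-versus-subunit evidence, so the
same-enzyme⇒AND reading is applied uniformly. Because a gene count and an
EC count answer different questions, `summary()` of a draft reports
distinct genes and distinct EC numbers separately rather than conflating
them into one "enzymes" figure. GPRs are stored and exported (including
to SBML/fbc) but not enforced during FBA: no gene-deletion simulation is
in scope.

## Refinement

**Balancing.** `check_balance()` computes per-element and charge deficits
(products minus substrates). `balance_reaction()` searches integer
multiples (|coefficient| ≤ 10) of an ordered filler list — H₂O, H⁺, e⁻,
CH₄, ethylene by default — that zero every deficit, minimizing the total
number of filler molecules, ties resolved deterministically in filler
order via a depth-first search with reachability pruning. The search
tracks *all* elements any filler touches, so a filler can never fix
hydrogen while silently unbalancing carbon. Reactions containing a
species of unknown formula are flagged uncomputable and left untouched
(an empty formula cell means "unknown"; a `.` cell means "known to have
no atoms", which is how the electron is represented). If no filler
combination within the bound balances a reaction it is flagged
`unbalanceable`, never modified.

**Chiral standardization.** An alias policy (data file) maps chirally
ambiguous accessions to a canonical form; the shipped default maps
D-glucose and beta-D-glucose to alpha-D-glucose, the anomeric form
favoured in animal cells. The policy must be idempotent (no chains or
cycles — fatal validation error otherwise), which also makes the
substitution itself idempotent. Reactions whose two sides become
identical collapse to an empty equation and are flagged for removal.

**Redundancy removal**, in fixed order with disjoint attribution:
step chains (a two-reaction chain whose net stoichiometry equals an
existing total reaction and whose intermediate occurs nowhere else),
generic reactions (touching a curated list of class compounds, or flagged
in the source), incomplete or symbolic-coefficient reactions, and
duplicates created by chiral standardization (the lexicographically first
twin is kept — an arbitrary but deterministic rule). Step-collapse is
restricted to chains of length two: longer chains would require deciding
which interior branches are "real", which the inputs cannot support.

**Metadata supplementation.** Missing pathway sets inherit from the
reference record, or failing that from the intersection of the reaction's
metabolites' pathway sets (a metabolite's pathways being the union over
reference reactions it occurs in); subsystems resolve through the
pathway→subsystem mapping. Un-inferable fields stay empty and are
counted, not guessed.

## Gap filling

The network is viewed as an undirected bipartite graph, reactions versus
their metabolites, and decomposed into weakly connected components
(WCCs, via `igraph`). Currency metabolites (H₂O, H⁺, ATP, ADP, NAD(H),
NADP(H), phosphate, CO₂, O₂, e⁻; configurable data file) carry no
connectivity edges — with them included the partition provably collapses
to one blob (asserted in the test-suite), which would make component
counts meaningless. A *gap candidate* is a reference reaction absent from
the network whose metabolites touch ≥ 2 components. Filling is greedy:
repeatedly add the candidate merging the most components (ties by
reaction id, for determinism), first restricted to candidates sharing a
pathway with *every* component they touch ("pathway scale" — the stricter
of the possible readings, chosen because it only proposes additions with
pathway-level support), then unrestricted ("global scale"). Each
iteration strictly reduces the component count, so termination is
guaranteed. Gap reactions are added without gene association and tagged
`gapfilled`. Optimization-based (MILP) gap filling against a growth
objective is deliberately out of scope.

## Biomass construction

Measured contents convert to mmol per gram dry weight:
g/100 g (and `%`) give $10\,c/M$; mg/kg give $c/(1000\,M)$
($M$ = molar mass, g/mol). For biomass coefficients the conversion is on
a dry basis — divided by $1-\text{moisture}$, since dry weight is total
mass minus water — so that all coefficients rescale by one factor if the
moisture estimate changes. Literature-requirement comparisons use the
wet-basis values, matching how such requirements are conventionally
printed; two decimals with half-up rounding for display, full precision
internally. Some printed requirement tables contain cells inconsistent
with this arithmetic (e.g. macro-mineral rows rounded down to 0.00);
such cells are excluded from the package's verification set rather than
"fixed".

The biomass reaction consumes each precursor at its coefficient, carries
an energy-maintenance term — ATP + H₂O consumed, ADP + phosphate + H⁺
produced, all at 29.8303 mmol/gDW by default, a coefficient adopted from
a curated mammalian-cell model in the absence of crustacean maintenance
measurements — and produces one unit of a biomass pseudo-metabolite
drained by a dedicated sink. NADPH is sometimes listed among maintenance
substances; the default excludes it (the operational cofactor set above
is the better-supported one) with `include_nadph = TRUE` adding
NADPH/NADP⁺ at the same coefficient. Time enters only through the
biomass flux: coefficients are mmol/gDW, flux is h⁻¹.

## The LP solver

No general-purpose LP package is available to depend on, so the package
implements a bounded-variable two-phase primal simplex (`lp_solve()`):
artificial variables with a phase-1 objective, implicit handling of
variable bounds (nonbasic-at-lower/upper states and bound flips), Dantzig
pricing with a Bland's-rule fallback when the objective stalls (cycling
protection), eta-updates of the basis inverse with periodic
refactorization. Tolerances: pivot/feasibility 1e-9, reduced-cost 1e-8;
optimal solutions satisfy $\max|Sv| \le 10^{-8}$ (asserted). The
test-suite checks ≥ 100 random systems against an exhaustive
basic-solution enumeration oracle and a second solver, and the SBML
export against an independent constraint-based implementation; agreement
is at 1e-6 or better.

**Alternate optima.** A single FBA flux vector at a degenerate optimum is
an arbitrary vertex and not reproducible across solvers. Requirement
profiles therefore report the *parsimonious* solution (minimize
$\sum|v|$ at fixed biomass flux, via variable splitting) together with
per-exchange FVA ranges (min/max at fixed biomass), making degeneracy
visible instead of hiding it. Individual degenerate flux values from
other implementations are expected to differ; bound compliance and the
FVA envelope are the reproducible statements.

## Blocked-precursor repair

A precursor with zero maximal synthesis flux marks a broken route.
`diagnose_and_repair()` searches edit sets of increasing size (default
cap 3): additions drawn from reference reactions within a few
reaction-layers of the target in the compound graph (default depth 4,
currency excluded), plus direction reversals of irreversible reactions in
that neighbourhood — wrong-direction annotations are a real failure mode.
First success at the smallest size wins, with lexicographic order within
a size, so the result is deterministic and minimal. The cap keeps the
combinatorial search bounded; targets needing larger repairs are reported
as unrepaired rather than searched open-endedly.

## Synthetic data: what it emulates, and what it does not

`generate_dataset()` emits the whole input suite (flat files, gene
annotations, composition tables, class/currency/alias sidecars) with
planted ground truth. The chemistry is token-level: pathway modules are
chains of isomerase-like reactions over same-formula compounds, balanced
by construction, with defects planted on top — withheld gap reactions
between module pairs (half annotated to both pathways, half pathway-less,
so both filling phases are exercised), equations missing one H₂O or one
H⁺, chiral alias pairs that create duplicates, two-step chains shadowing
a total reaction, generic/symbolic/incomplete reactions, and three
blocked synthesizable-precursor routes (one missing reaction, a missing
three-reaction stretch, one wrong-direction reaction).

Growth is made analytically computable: every biomass precursor is fed by
an independent route (direct feed uptake at −5, a trace element at −1, a
synthesizable route from a feed substrate, ATP from an energy substrate
at a fixed yield), so the maximum growth rate is exactly the tightest
capacity/coefficient ratio, recorded per variety as ground truth. Default
conditions: 20 pathway modules × 6 reactions, 5 withheld gaps, full
annotation coverage, five varieties whose compositions perturb a common
base by 0–20 % at moisture fractions near 0.75, energy yield 40 ATP per
substrate. The defaults keep the model at ~180 reactions so the complete
pipeline (including per-variety pFBA and FVA) runs in well under a
minute; these sizes are the package's chosen desk-scale study conditions.

What passing on synthetic data shows: the bookkeeping, graph, balancing
and LP machinery are correct, and planted signals are recovered exactly.
What it does not show: anything about real biochemistry — thermodynamic
plausibility, realistic pathway topology, protonation states, or the
biological adequacy of a measured composition table. Conclusions about a
real organism require real inputs and curation; the package's role there
is to make every automatic step deterministic, auditable and repeatable
(stage reports with counts, content-hashed inputs/outputs, seeds).

## Known limitations

* Direction information defaults to reversible when absent; no
  thermodynamic direction inference.
* Step-chain collapse handles length-2 chains only.
* Gap filling is connectivity-based, not growth-objective-based; it can
  add reactions a curator would reject.
* The repair search is capped (edit sets ≤ 3 by default) and its
  candidate pool is a graph neighbourhood, not the full reference set.
* Protonation states are not normalized to a reference pH; charge
  balancing relies on the annotations as given.
* The simplex is dense; models beyond a few thousand reactions would
  need a sparse factorized implementation.
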