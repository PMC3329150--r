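---
title: "Constraint-based analysis of photon-resolved cyanobacterial metabolism"
author: "cyanoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of photon-resolved cyanobacterial metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoflux)
```

# The model

`cyanoflux` analyzes genome-scale stoichiometric models of oxygenic
phototrophs under the steady-state constraint-based formalism. A model is
a stoichiometric matrix **S** (metabolites by reactions) together with
per-reaction capacity and directionality bounds. A flux distribution
**v** (mmol per g ash-free dry weight per hour; biomass flux in 1/h) is
feasible when

* **S v = 0** — every internal metabolite is produced as fast as it is
  consumed, and
* lower bound ≤ v ≤ upper bound per reaction — enzyme capacity and
  thermodynamic directionality.

Flux balance analysis (FBA) maximizes an objective flux, usually the
biomass equation, over this polytope; flux variability analysis (FVA)
minimizes and maximizes each flux individually under fixed measurements,
yielding a per-reaction feasible range whose width (the *flux span*)
measures how well the constraints resolve that flux.

What makes phototrophs special is that light enters through two distinct
photon-consuming reactions — photosystem II, which splits water and
reduces the plastoquinone pool, and photosystem I, which re-energizes
electrons towards ferredoxin and NADPH. The photosynthetic and
respiratory electron transport chains share carriers (plastoquinone,
plastocyanin/cytochrome c6), so cyclic electron flow, terminal oxidases
and flavodiiron (Mehler) reactions all compete for the same pools. The
package therefore treats the two photon uptakes as first-class,
independently controllable exchange fluxes.

# Analyses

**Photon-resolved FBA and phase planes.** `computePhpp()` grids the two
photon uptakes and records the optimal growth rate per cell. Regions of
the phase plane are delineated by which photon constraint has positive
marginal value: only PSII (region 1), only PSI (region 3), or both
(region 2). Because the LP value function is piecewise linear in the
uptakes, marginals are computed as forward finite differences with a
fixed probe of 0.25 mmol/g/h; this returns exact right-derivatives, and
the labelling is therefore stable under grid refinement. Simplex duals
are available but systematically degenerate at phase-plane vertices,
which is why the probe is the primary mechanism. Cells whose regime is
infeasible or supports no growth are labelled region 0. Boundary points
take the label their own marginals imply (right-derivatives make this
deterministic).

**Limitation diagnosis.** `diagnoseLimitation()` adds, separately, an
artificial ATP-generating reaction (ADP + Pi + H → ATP + H2O) and an
artificial NADPH-generating reaction (NADP + H → NADPH), each capped at
0.1 mmol/g/h, and reports which addition raises optimal growth by more
than 1e-8 1/h: energy-limited, reductant-limited, mixed (both), or
neither (e.g. carbon-limited). On the toy network the dual-limited
region reports *mixed*: its respiratory chain can convert surplus
reductant into ATP at the margin, so both artificial supplies help. This
is a property of the toy's tight coupling, not of the method.

**Region-wise FVA.** `phppFva()` fixes growth to its maximum at sampled
points of a region and aggregates FVA outcomes: a reaction is *active*
in the region if its range excludes zero with a consistent sign at every
sampled point, *blocked* if the range is [0,0] everywhere, *optional*
otherwise. Aggregation can only move labels toward *optional*, so
sampling more points never produces a contradiction. The default sample
is up to 25 points per region.

**Electron-transport scenarios.** `scenarioScan()` deletes named
reaction sets (cyclic routes; alternative reductant sinks), fixes the
PSII photon uptake and scans PSI uptake, reporting growth and secreted
products at a flux-norm-minimal optimum.

**Dark nitrogen fixation.** `darkN2Fixation()` closes both photon
exchanges and the ammonium exchange, supplies glycogen through a bounded
demand-style source (default cap 0.171 mmol/g/h), and maximizes
cyanophycin production. Yields are reported per glycogen from the
nitrogenase flux (with the nitrogen stored in cyanophycin attached as an
attribute for comparison), the net H2 exchange, and O2 uptake. The three
hydrogenase reactions are removed by default so that the obligate H2
co-product of nitrogenase is not silently recycled.

**ATP requirements (GAR/NGAR).** `estimateAtpRequirements()` fixes each
batch's growth rate and photon uptakes and maximizes the maintenance
ATP-hydrolysis flux by LP; ordinary least squares of that maximum
against growth gives the growth-associated requirement (slope, GAR) and
the non-growth-associated requirement (intercept, NGAR). The regression
is unweighted. Identifiability requires the batches to sit where growth
is energy-sensitive: in reductant-limited regimes the maximal ATP
hydrolysis contains slack unrelated to the growth cost and the line
breaks down. `toyBatchGrid()` therefore places synthetic batches in the
dual-limited band of the toy phase plane (PSI = 0.7 × PSII), mirroring
how real batch experiments under mixed-wavelength illumination behave.
The estimation model must carry polymerization-only ATP costs in its
biomass equation; `applyEnergyParameters()` then folds the fitted GAR
into the biomass ATP term and installs NGAR as the maintenance lower
bound (apply once).

**Evidence integration (transcriptome/proteome data, TPD).**
`buildReactionSets()` maps gene-level evidence to reactions through the
GPR rules: reactions whose rule evaluates true over detected proteins
form the high set R_H; reactions all of whose genes are undetected and
below the log2-mRNA threshold (default 8; a data-driven mode uses the
lowest mRNA level among detected proteins) form the low set R_L;
measured-rate reactions R_E are excluded from both. `fitTpdFlux()`
solves the mixed-integer program that maximizes the number of satisfied
evidence statements — flux magnitude at least ε for R_H, zero flux for
R_L — and then, lexicographically with the score fixed, minimizes the
sum of squared fluxes so alternate optima do not route flux through
futile cycles. Binary indicators of the first score-optimal solution are
then frozen for `tpdConstrainedFva()`, whose ranges can only shrink
relative to unconstrained FVA.

The indicator semantics are hard: an R_H reaction with both indicators
zero is constrained to exactly zero flux. A consequence worth knowing is
that when measured rates force a flux into the open interval (0, ε) the
program is infeasible for *every* binary assignment; the fit then stops
with an explicit error suggesting a smaller ε. The default ε is 0.1
mmol/g/h; on the toy network the smallest growth-coupled flux
(cyanophycin synthesis, about 0.4 × growth rate) lies below that, so the
packaged toy analyses use ε = 0.01. `epsilonSensitivity()` tabulates the
classification counts over ε ∈ {0.01, 0.1, 1} and flags infeasible
thresholds, since published classification counts depend on this
unreported constant.

**Deletion scans.** `deletionSpanScan()` knocks out candidate reactions
(bounds fixed to [0,0], which keeps matrix indices stable across the
scan) and recomputes mean central-metabolic flux spans, ranking
deletions by how much they sharpen the flux picture. Candidates default
to the reactions classified *optional* at baseline; pair scans prune
pairs whose singles are both below an effect floor (0.5 mmol/g/h,
disableable). Deletions that make the measured rates unattainable are
retained with `feasible = FALSE`.

# The synthetic generator

`makeToyNetwork()` builds a ~34-reaction phototroph with the canonical
electron-transport topology: PSII → plastoquinone → cytochrome b6f →
plastocyanin → PSI → ferredoxin → FNR → NADPH; ferredoxin-dependent
cyclic flow; pumping (NDH-1) and non-pumping (NDH-2) NADH
dehydrogenases; cytochrome c oxidase (pumping) and quinol oxidase
(non-pumping); NADPH- and ferredoxin-dependent Mehler reactions; ATP
synthase; lumped CO2 fixation (1 CO2 + 3 ATP + 2 NADPH per fixed-carbon
unit); glycogen and cyanophycin storage; nitrogenase with its obligate
1:1 H2 co-product; and bidirectional plus uptake hydrogenases. Default
proton stoichiometries per two electrons are textbook-like integers —
PSII 2, b6f 4, NDH-1 4, COX 2, ATP synthase 4 H+/ATP — chosen so that
the energetic ordering COX/NDH-1 over QOX/NDH-2 holds and the phase
plane over 0–60 mmol photons/g/h has three regions. Every internal
reaction is elementally and charge balanced over pseudo-element carrier
formulas, which `checkMassBalance()` audits; photons are massless and
exempt.

The generator's energy parameters default to GAR = 544 mmol ATP/g and
NGAR = 2.8 mmol/g/h — the published values for the organism modelled —
which places toy growth rates in the realistic 0.02–0.12 1/h range.
The biomass equation is assembled by `buildBiomassEquation()` from a
light-limited composition (55% protein, 3% cyanophycin) or an
ammonium-limited one (48% carbohydrate, no cyanophycin); coefficients
are linear in the mass fractions and the closure invariant (sum within
[0.95, 1.05]) tolerates measurement error.

Two useful closed forms follow from the toy's stoichiometry and are used
as independent oracles in the test suite. Respiring one NADH yields
(4+4+2)/4 = 2.5 ATP and one NADPH (via reverse FNR, FdPq, b6f, COX)
(4+2)/4 = 1.5 ATP; a fully catabolized glycogen unit yields
4 + 6×2.5 + 6×1.5 = 28 ATP; fixing one N2 into cyanophycin costs 20 ATP
plus 4 NADPH and 2/3 of a hydrolyzed glycogen's carbon. Equating the
carbon and ATP budgets gives the maximal dark N2 yield 42/67 ≈ 0.627
mol N2 per mol glycogen at zero maintenance, declining with NGAR — the
numbers `darkN2Fixation()` reproduces to solver precision.

What the toy deliberately does *not* emulate: fermentative
(organic-secretion) ATP routes, so the scenario with neither cyclic flow
nor reductant sinks is infeasible at every PSI uptake rather than
growing at a single point with organic secretion as a full genome-scale
model does; quantitative agreement with any published model's numbers;
state transitions and photoinhibition; diurnal dynamics. One emergent
artifact worth knowing: the two bidirectional hydrogenases running in
opposite directions act as a stoichiometric transhydrogenase (NADPH →
H2 → NADH). This is allowed by mass balance, mirrors a known class of
loops in genome-scale reconstructions, and is the reason hydrogenase
deletions collapse central flux spans in the deletion scan. Passing
toy-network tests therefore demonstrates correctness of the optimization
machinery and the analysis logic, not biological fidelity of any
particular flux prediction.

Expression evidence is simulated gene-wise from a known flux state
(detection probability 0.9 for genes of active reactions, 0.05
otherwise; log2 mRNA normals at 10 vs 5 with unit standard deviation,
threshold 8), and batch series apply multiplicative Gaussian noise to
FBA growth rates; all generators are bit-reproducible under their seeds.

# Numerical choices

* **LP engine.** A dense bounded-variable two-phase simplex
  (`R/solvers.R`) with Dantzig pricing, Bland's rule engaged after 500
  iterations to preclude cycling, feasibility tolerance 1e-7 and
  optimality tolerance 1e-9. Problems in this package have tens of
  variables, so the basis system is solved directly each iteration.
* **Quadratic norm stage.** Equality constraints are eliminated by a
  null-space parametrization (orthonormal basis from the QR of t(S)),
  leaving an identity-Hessian QP over bound constraints for `quadprog`.
  Degenerate vertices can still make `quadprog` declare a feasible
  problem inconsistent; the solver retries with bound relaxations of
  1e-9 then 1e-7 and clips the solution back into the bounds. An L1
  fallback (`norm = "L1"`, solved as an LP on split variables) is
  selectable wherever the quadratic norm is used.
* **MIQP.** Depth-first branch-and-bound over the binary indicators with
  LP relaxations, big-M rows built from the reaction bounds, integer
  tolerance 1e-6, most-fractional branching with first-index
  tie-breaks, and the satisfied-evidence branch explored first. The
  deterministic ordering makes alternate-optima selection reproducible.
* **Tolerances.** `zeroTol = 1e-9` separates solver noise from zero flux
  in classification; the evidence-activity threshold ε is a distinct,
  biological scale (default 0.1). Elemental balance is audited to 1e-6
  per element.
* **Problem sizes.** The packaged analyses run the toy network (34
  reactions): 7×7 phase-plane grids with step 10, up to 25 FVA sample
  points per region, batch series of 8–20, and evidence sets of about
  20 reactions. All are configurable upward.

# Known limitations

* Loop suppression is by norm minimization only; there are no
  thermodynamic (loop-law) constraints, so stoichiometrically balanced
  cycles such as the hydrogenase transhydrogenase loop remain feasible
  at the FVA stage and are only excluded from representative flux
  distributions.
* The weighted (non-lexicographic) evidence objective is exploratory:
  it evaluates candidate binary assignments found by the score-driven
  search rather than solving the weighted MIQP globally.
* `readSBML()` covers the two dialects used in practice for published
  genome-scale models (Level 2 with kinetic-law bounds and notes-based
  gene rules; Level 3 with the fbc extension); it is not a general SBML
  toolkit — kinetics, events and units are ignored.
* GAR/NGAR estimation assumes measurements lie in an energy-sensitive
  regime; the estimator reports the regression but cannot detect by
  itself that a batch sits in a reductant-limited region.
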