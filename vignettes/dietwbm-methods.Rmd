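---
title: "Methods: diet-constrained parsimonious FBA on whole-body models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet-constrained parsimonious FBA on whole-body models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietwbm)
```

## The model and the simulation protocol

An organ-resolved whole-body metabolic model (WBM) couples organ
sub-networks through shared biofluid compartments — here a systemic blood
compartment tagged `[bc]` and a gastrointestinal lumen tagged `[d]`. Its
state is a flux vector $v$ (mmol/day/person) over all reactions,
constrained by steady-state mass balance and flux bounds:

$$S\,v = 0, \qquad lb \le v \le ub,$$

where $S$ is the stoichiometric matrix (metabolites × reactions). Diets
enter exclusively through the bounds of *diet exchange reactions*
(identifiers prefixed `Diet_EX_`): an average daily intake of $a$
mmol/day of a nutrient constrains the corresponding exchange flux, with
uptake negative by convention.

A flux state is selected by parsimonious flux balance analysis in its
Euclidean (L2) form: the *whole-body maintenance reaction* — a composite
demand representing weight-stable physiological upkeep — is pinned to
flux 1 by setting both of its bounds, and among all feasible states the
one minimizing $\sum_i v_i^2$ over **all** reactions is returned
(exchange and maintenance reactions included; the pinned maintenance
contributes a constant). Because the objective is strictly convex on a
convex set, this optimum is unique, which makes every downstream readout
deterministic — a property the tests lean on heavily. No reaction
weighting or scaling is applied to the objective; the plain sum of
squares is the protocol.

Organ–blood exchange fluxes follow a package-wide sign convention:
*positive flux = secretion into blood*. Readers re-orient reactions
written the other way and record the flip, so all biomarker arithmetic
can assume the convention.

## Diet application semantics

The mapping from a daily amount $a$ to bounds is genuinely ambiguous in
practice, and the two interpretations differ materially, so both are
exposed in `diet_policy()`:

* `optional_uptake` (constructor default): bounds $[-a, 0]$ — the diet is
  an *upper* limit on supply; the model consumes what the optimum needs.
* `forced_uptake`: bounds $[-a, -f\,a]$ with force fraction $f = 0.8$
  (the convention used with VMH whole-body models) — at least 80% of the
  stated intake is actually absorbed.

The study pipeline defaults to `forced_uptake`. The reason is mechanistic:
under a minimum-norm objective, optional uptake collapses every diet onto
"the cheapest way to satisfy maintenance", so diet composition barely
propagates into the flux state. Forcing intake makes the organism
metabolize what it eats — surplus fat must be esterified or oxidized,
surplus cholesterol must be packaged — which is exactly the phenomenon
the biomarker readouts measure. Diet entries that match no diet exchange
in the model warn rather than fail, because real diet formulations
routinely include compounds absent from a given model version;
`close_unlisted = TRUE` zeroes the uptake of every unlisted exchange.

Energy accounting uses Atwater-style factors (4/9/4 kcal/g for
carbohydrate/fat/protein, 7 for alcohol, 2 for fermentable fiber, 0 for
micronutrients) through a nutrient classification table that also carries
grams-per-mmol conversions; all of it is overridable per nutrient.

## Biomarker readouts

Five metabolic-syndrome-relevant readouts are computed from each solved
flux state, each over a reaction panel resolved either from explicit
identifier lists (the route for real WBMs, whose panels come from
supplementary material) or from structural patterns (the route for
synthetic models):

* **Glucose**: per-organ glucose–blood exchange fluxes; totals use
  positive-part sums (total secretion $= \sum \max(v, 0)$, total uptake
  $= \sum \max(-v, 0)$) because organs secreting and organs taking up are
  tallied separately; the signed net is reported alongside. Organ roles
  (`secretor` / `uptaker` / `mixed` / `inactive`) are classified against a
  threshold $\tau = 10^{-6}$ mmol/day/person, which operationalizes
  "consistent" activity across diets; no principled value exists, and any
  threshold well below physiological flux scales gives the same labels.
* **TAG**: the signed sum over the three adipocyte triacylglycerol
  esterification reactions (one per fatty-acid class), read as storage
  flux — a proxy, not a serum concentration.
* **LDL-C/HDL-C**: the ratio of total LDL-C to total HDL-C secretion into
  blood, with a division guard (an HDL-C total below $10^{-9}$ raises an
  undefined-ratio error rather than returning infinity).
* **Fatty-acid β-oxidation**: the summed flux of the thiolase step
  (butyryl-CoA → acetyl-CoA) in skeletal muscle and heart — deliberately
  only that step, as a pathway-activity surrogate, with no attempt to
  integrate full β-oxidation spirals.

## The synthetic generator: what is emulated, what is planted

Real WBMs are multi-gigabyte, unversioned downloads; nothing in this
package's test surface depends on them. Instead `make_toy_wbm()` builds
~95-reaction (male) / ~110-reaction (female) models that are structurally
faithful to WBM conventions — organ-prefixed namespaces, one shared blood
compartment, lumen-side diet exchanges, a single maintenance reaction with
organ-weight coefficients (equal weights by default; the real models'
physiological weighting is out of scope) — and *mechanistically* faithful
on the pathways the readouts touch:

* liver gluconeogenesis from amino acids (plus a small fatty-acid-derived
  term) is the sole net glucose source, so the liver is a glucose
  secretor under every diet by construction;
* the three adipocyte esterification reactions absorb fatty-acid surplus;
  the essential fatty-acid species has no oxidative fate, so some TAG
  flux is unavoidable whenever fat is eaten;
* HDL-C synthesis is capacity-capped (0.4 mmol/day hepatic, 0.05 in
  muscle and adipocytes) while the hepatic LDL-C route (via VLDL) is
  uncapped: cholesterol overflow beyond ~0.5 mmol/day necessarily raises
  the LDL-C/HDL-C ratio;
* the muscle/heart thiolase step is fed both by fatty-acid β-oxidation
  and by fiber-derived butyrate from colonic fermentation.

The twelve toy diets span unhealthy/balanced/ketogenic/plant-based
macronutrient mixes with energy targets chosen once at design time (the
unhealthy pattern carries 1.5× the energy of the balanced one; the
ketogenic pattern derives ~74% of energy from fat; plant-based patterns
carry high fiber and near-zero cholesterol). Every structural fact and
expected ordering is stamped into a manifest, and the test suite checks
that the *pipeline recovers the planted facts* — forced chain fluxes,
symmetric splits, infeasibility deficits, biomarker orderings
(unhealthy > balanced TAG, unhealthy > vegan LDL-C/HDL-C,
keto > balanced β-oxidation, liver secretor everywhere).

What passing these tests shows is that the machinery — parsing, bound
application, the QP, the panel resolution, the summaries — is correct on
models whose ground truth is known exactly. What it does **not** show is
quantitative fidelity to human physiology: toy flux magnitudes are
arbitrary, organ coverage is lumped, and there is no hormonal regulation,
no transcriptional adaptation, and no concentration prediction (fluxes
only). Directions of planted mechanisms, not magnitudes, are the test
currency.

One emergent behavior of the L2 objective deserves a note: fat-poor diets
can show exactly zero β-oxidation flux, because at the optimum the
esterification route absorbs the entire (small) fat stream; the KKT
multiplier on the oxidation route's zero bound is strictly positive. This
is the honest optimum — both independent solvers agree to near machine
precision — not a solver artifact.

## Numerical design

**Quadratic programs.** The primary backend is the Goldfarb–Idnani dual
active-set method (`quadprog::solve.QP`), which is exact for strictly
convex QPs. Its pivoting, however, is sensitive to the mix of unit-scale
stoichiometry, tight physiological bounds, and the finite big-M sentinel
(±10⁶) used for unbounded reactions, and can falsely report inconsistent
constraints. The solver therefore tries four formulations (raw and
row-normalized equality rows, full and sub-sentinel bound sets), verifying
each candidate against the full constraint set. A second, independently
written backend — dual ascent on the mass-balance multipliers with
L-BFGS-B followed by a primal-dual active-set polish solved through the
SVD of the free block — serves both as the cross-check demanded by the
two-backend agreement invariant (they agree to ~10⁻¹⁴ on the toy suite)
and as a deterministic fallback when every Goldfarb–Idnani attempt fails.
Each returned solution is validated against tolerances: mass-balance
residual ≤ 10⁻⁶ (relative to the flux scale), bound violation ≤ 10⁻⁸,
maintenance deviation ≤ 10⁻⁹.

**Linear programs** (FBA probes, infeasibility diagnosis, L1 mode) are
solved through the quadratic regularization path: the minimizer of
$\tfrac12\lVert x\rVert^2 + t\,c^\top x$ over the flux polytope is
piecewise linear in $t$ and, beyond a finite threshold, equals the
least-norm point of the LP optimal face. The substitution $x = t z$ keeps
every solve on the unit scale, and $t$ walks a ladder ($10^3 \ldots
10^{11}$) until the objective stabilizes to a relative $10^{-9}$. This
reuses the hardened QP machinery instead of introducing a separate
simplex code path, at the cost of a handful of QP solves per LP — cheap
at the model sizes this package targets (hundreds of reactions). General
inequality rows are converted to equalities with bounded slack variables.
A consequence worth knowing: on a degenerate LP face the returned point
is the least-norm optimum, not an arbitrary vertex.

**Infeasibility diagnosis** minimizes total slack added to diet-exchange
and maintenance bounds. The maintenance slack is weighted 100× so that
diagnoses localize on dietary supply whenever relaxing a diet bound can
restore feasibility — the maintenance pin is the protocol constant and
relaxing it is the explanation of last resort.

**The exhaustive oracle** (`qp_oracle`) enumerates every assignment of
bound-activity states (free / at lower / at upper) over at most 12
reactions, solves each equality-restricted least-norm problem by SVD, and
returns the feasible candidate of least objective. Bounds at the big-M
sentinel are not enumerated as active states; since the candidate's
primal feasibility is verified, the oracle is exact whenever the optimum
touches no sentinel bound — true by construction for all generated oracle
models. It shares no code with either production backend.

**Embeddings.** PCA is computed by SVD of the centered (and by default
unit-scaled — macro fractions and mmol/day amounts live on very different
scales) feature matrix, with a deterministic sign convention: each
component is flipped so its largest-magnitude loading is positive.
Constant columns are dropped with a warning. t-SNE uses an exact dense
implementation (perplexity-calibrated input affinities, early
exaggeration, momentum gradient descent, seeded Gaussian initialization) —
entirely adequate for embedding a dozen diets — and is deterministic for
a fixed seed, which the pipeline makes mandatory. Embedding coordinates
carry no tested semantics beyond shape, finiteness, and same-seed
reproducibility: cluster reading in this kind of analysis is a visual,
manual act, and the package makes no cluster assertions.

## Problem sizes

The default test and acceptance surface uses: the 2-sex × 12-diet
synthetic study (24 pFBA solves on ~100-reaction models, about three
seconds in total), 50 random ≤12-reaction models for oracle equivalence,
and 12-sample embedding matrices. These sizes were chosen so the entire
ground-truth-verifiable surface runs comfortably on a laptop while still
exercising every code path; nothing in the implementation is specific to
them, and the same functions run unchanged on models read from SBML or
the package dialect.

## Known limitations

* Flux predictions only — no serum concentrations, no kinetics.
* No insulin or other hormonal regulation; no transcriptional adaptation;
  static (non-dynamic) FBA.
* Real-WBM reproduction requires the original model and diet snapshots,
  which are unversioned upstream; any such run should record download
  dates and checksums in its provenance.
* The SBML reader is minimal (Level 3 core + fbc flux bounds); models
  using other packages' extensions should be converted to the JSON/TSV
  dialect first.
* `fba()` and the LP-based diagnosis target toy-to-moderate model sizes;
  genome-scale LPs deserve a dedicated industrial solver.
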