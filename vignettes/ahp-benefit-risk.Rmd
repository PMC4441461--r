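---
title: "Benefit–risk decision analysis with the Analytic Hierarchy Process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benefit–risk decision analysis with the Analytic Hierarchy Process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahpbr)
```

## The decision model

The Analytic Hierarchy Process (AHP) decomposes a decision into a
hierarchy: a single goal, a tree of objectives (criteria) beneath it,
and a set of alternatives compared under every leaf objective. In
medication benefit–risk assessment the objectives are typically framed
positively — maximize benefit, minimize each harm — and the
alternatives are candidate treatments. `ahpbr` represents this as a
`decision_hierarchy`; every non-leaf node defines a *comparison group*
of its children, and every leaf objective defines a comparison group of
the alternatives.

Two structural conventions matter:

* **Single-child nodes carry weight 1.** A group with one member cannot
  be compared against anything, and normalization forces its local
  weight to 1, so no judgments are elicited for it. In the built-in
  diabetes model the benefits branch has a single outcome (HbA1c
  reduction), which therefore inherits the full benefits weight.
* **Groups larger than seven items warn but stay legal.** Keeping seven
  or fewer items per level bounds the number of pairwise questions
  (`n(n-1)/2` per group) and is associated with better judgment
  consistency; the validator flags larger groups without rejecting
  them, since the engine itself is size-agnostic.

Hierarchy depth is unrestricted, labels are matched case-insensitively
after whitespace trimming, and model files round-trip through YAML or
JSON against a JSON Schema shipped in `inst/extdata/`.

## From judgments to priorities

Each expert fills one positive reciprocal matrix per multi-item group:
entry $a_{ij}$ states how many times item $i$ is preferred to item
$j$, with $a_{ji} = 1/a_{ij}$ and unit diagonal. Judgments elicited on
the verbal 1–9 scale live in $[1/9, 9]$ (`scale_mode = "saaty"`); the
engine also accepts free positive ratios, which arise when directly
elicited weights $w$ are transformed into the equivalent consistent
matrix $a_{ij} = w_i / w_j$ (`matrix_from_weights()`). Whether such
derived ratios should additionally be clamped into $[1/9, 9]$ is a
genuine design choice — clamping keeps the matrix on the conventional
scale but sacrifices perfect consistency when a ratio exceeds 9 — so it
sits behind an explicit flag, default off. Direct weights of exactly
zero are rejected rather than smoothed: the ratio transformation is
undefined at zero, and eigenvector weights from positive reciprocal
matrices are strictly positive anyway.

Local priorities are the normalized principal right eigenvector of the
judgment matrix, computed by power iteration (repeated matrix
multiplication with normalization): starting from the uniform vector,
$w \leftarrow Mw / \lVert Mw \rVert_1$ until the max-abs change falls
below `tol`. Defaults are `tol = 1e-12` and `max_iter = 10000`; the
iteration is deterministic, and non-convergence is an error that
reports the last residual rather than a silent result. The dominant
eigenvalue is estimated as $\lambda_{\max} = \mathrm{mean}_i\,
[(Mw)_i / w_i]$ — averaging the component-wise Rayleigh ratios is more
stable than reading off a single component. The test suite checks the
whole pipeline against an independent LAPACK eigen-decomposition to
$10^{-8}$ on a thousand random reciprocal matrices of orders 3–8, and
against the 3×3 closed form
$\lambda_{\max} = 1 + t + 1/t$, $t = (a_{12}a_{23}/a_{13})^{1/3}$.

### Consistency

Perfect transitivity ($a_{ik} = a_{ij}a_{jk}$) gives
$\lambda_{\max} = n$; any intransitivity inflates it. The consistency
index is
$$CI = \frac{\lambda_{\max} - n}{n - 1},$$
zero for perfect consistency, and the consistency ratio $CR = CI/RI_n$
rescales it by the expected $CI$ of random matrices (Saaty's random
index table: 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49 for
$n = 3..10$; the $n=10$ value is reused beyond the table). Matrices of
order ≤ 2 are consistent by construction. Conventions in applied work
variously place an acceptability cutoff of 0.10–0.15 on "the
consistency index", sometimes meaning CI and sometimes CR; `ahpbr`
applies its verdict to **CR at 0.15** — CR is the quantity the random
index exists to normalize — but always reports both CI and CR so either
reading can be checked, and the threshold is an argument.

## Synthesis: ideal and distributive modes

Global objective weights multiply down the tree
(`global(child) = global(parent) × local(child)`, goal = 100%), so each
sibling partition's globals sum to its parent's global to machine
precision. Overall alternative scores combine the leaf globals
$g_\ell$ with each leaf's local alternative vector $p_{\ell\cdot}$:

* **distributive**: $s_k = \sum_\ell g_\ell \, p_{\ell k}$ — scores are
  proportional shares, appropriate for apportioning priority among
  alternatives, but sensitive to the composition of the alternative
  set;
* **ideal**: each leaf vector is first divided by its maximum, so the
  leaf-best alternative gets 1, then weighted and summed — designed to
  identify the single best alternative. Because existing alternatives'
  idealized values are untouched by an entrant that is nowhere the leaf
  maximum, their relative ranks are preserved under addition or removal
  of such an "irrelevant" alternative; the suite property-tests this on
  500 random instances, and includes a constructed two-criterion
  instance (performances A = (8, 1), B = (3, 3), entrant C = (1, 6),
  found by grid search) where distributive mode does reverse A vs B.

Ideal-mode raw scores are renormalized to sum 1 for reporting: the
relative-difference ratios reported downstream are
normalization-invariant, and a common scale eases comparison across
modes. Display output rounds globals and scores to 2 decimals and
ratios to 2 decimals; internal computation is never rounded. Tied
scores share the better rank, with label order used only to make the
printed layout deterministic.

Differences between priorities are summarized as ratios of the larger
score to the smaller; a ratio of at least 1.1 (a 10% multiplicative
difference) is flagged significant, the conventional AHP yardstick.
The printed table places each ratio in the row of the larger item,
leaving the mirror cell blank — the full symmetric matrix remains
available programmatically.

## Group aggregation

Group priorities are the element-wise geometric mean of the individual
experts' priority vectors, renormalized to sum 1 (AIP — aggregation of
individual priorities). The geometric mean is the aggregation rule
consistent with ratio-scale judgments: in the log domain the
unnormalized group weight is exactly the mean of the individual log
weights, which makes the rule invariant to per-expert positive
rescaling. Note the renormalized group weight is *not* guaranteed to
lie within the range of the individual weights, so the suite asserts
the log-domain mean property instead. Aggregation is applied to local
priority vectors before a single synthesis; aggregating each expert's
final scores instead is available behind `aggregate = "scores"` as a
sensitivity check on the aggregation level, since with unpublished
elicitation protocols either level is defensible. Disagreement is
summarized per item as the sample standard deviation (n−1 denominator —
panels are small) of expert weights, in percentage points. Zero
weights are an error in aggregation rather than epsilon-smoothed:
eigenvector priorities are strictly positive, so a zero indicates an
upstream bug, and silently smoothing would mask it.

## Sensitivity scenarios

`apply_scenario()` forces chosen objectives' local shares (for
example, benefits = 100%) and rescales the non-overridden siblings
proportionally to fill the remainder — the standard redistribution
rule, and the only one offered. A scenario that forces a node to 1
zeroes its siblings but leaves the internal weights of every subtree
untouched, so the analysis varies exactly one split at a time. Two
numerical choices are deliberate: the rescaling factor is snapped to 1
when within `1e-12`, so a scenario equal to the baseline reproduces it
bit-for-bit; and overriding a single-child group is an error, since its
weight is structurally fixed at 1.

One caution on the monotonicity folklore: raising an objective's
weight does *not* always raise the absolute score of that objective's
best alternative (its score elsewhere may be far higher, and scores
renormalize). What does hold — because distributive scores are linear
in the forced share — is that the leaf-best alternative's *rank* never
worsens as the share grows; that is the property the suite tests.

## The synthetic expert cohort

No raw expert-by-expert judgments accompany the built-in case study,
so the package ships a generator that emulates the study design: a
panel of `n_experts` (default 9, a typical in-person expert panel)
whose judgments are noisy perturbations of latent true priorities.

For every comparison group a true weight vector is drawn from a
symmetric Dirichlet distribution; the single `concentration` knob
(default 1, uniform on the simplex) controls how skewed true
priorities are, emulating "varying perspectives" without committing to
any particular elicited values. Each expert's matrix multiplies the
consistent ratio matrix by log-normal noise,
$a_{ij} = (w_i/w_j)\exp(\sigma z_{ij})$ with $z_{ji} = -z_{ij}$, which
preserves reciprocity exactly and maps $\sigma$ monotonically to the
measured consistency ratio. The default $\sigma = 0.3$ yields panels
whose CRs mostly fall below the 0.15 verdict line — a
mostly-consistent panel, the regime the method assumes. Optional
snapping moves each upper-triangle entry to the nearest of the 17
Saaty values $\{1/9,\dots,1/2,1,2,\dots,9\}$ in log space (symmetric
treatment of a ratio and its reciprocal) before the reciprocal is
refilled. All randomness derives from one root seed via deterministic
label hashing per expert and group, so output is reproducible and
independent of generation order. Because the published per-item
standard deviations cannot identify $\sigma$ without the raw
judgments, $\sigma$ is a free simulation parameter, not an estimate of
the real panel.

What the generator does **not** emulate: systematic expert bias
clusters, correlated noise across groups, round-number preference, or
the cognitive anchoring of real elicitation. Passing recovery tests
therefore shows the *pipeline* is correct and well-conditioned under
the assumed noise model, not that real panels behave this way.

Parameter recovery is quantified by `recovery_error()` (mean absolute
error, max-abs error, and the fraction of concordantly ordered item
pairs). The suite verifies MAE is zero without noise, increases with
$\sigma$ over $\{0, 0.05, 0.2, 0.5\}$, and decreases with panel size
over $\{1, 3, 9, 27\}$ at fixed $\sigma$ — the geometric mean pools
log-symmetric noise away. Simulation sizes in the shipped tests (100
replicates per noise level, 200 per panel size, on a two-criterion
model; 1,000 matrices for the eigen-oracle comparison) were chosen so
the Monte-Carlo orderings are stable across seeds while the whole
suite stays quick on a laptop.

## The built-in diabetes case

`diabetes_case()` ships the worked example: choosing an add-on
pharmacotherapy to metformin for type 2 diabetes, with benefits
(HbA1c reduction) against non-serious harms (fracture, weight gain, GI
symptoms) and serious harms (severe hypoglycemia, CHF, acute
pancreatitis, bladder cancer), over five alternatives. The published
group-level global priorities of the objectives are embedded as
reference data; `reference_locals()` inverts them into per-group local
weights via `global = parent × local`, and re-synthesis reproduces the
published table to display precision:

```{r}
fx <- diabetes_case()
g <- global_priorities(fx$hierarchy, reference_locals(fx))
round(g, 2)
```

The alternative-level judgments behind the published treatment ranking
were never released, so overall alternative scores are *not*
reproducible and are deliberately not embedded; alternative-level
functionality is exercised against synthetic cohorts instead, and the
ratio/reporting machinery is regression-tested against the published
objective-level table (for example severe hypoglycemia vs fracture,
$14.01/2.57 = 5.45$).

```{r}
rd <- relative_differences(g[c("Risk of fracture", "Weight gain",
                               "GI symptoms", "Severe hypoglycemia",
                               "CHF risk", "Acute pancreatitis",
                               "Risk of bladder cancer")])
rd$display[4, 1:4]
```

## Degenerate inputs and edge cases

* 1×1 groups: weight 1, $\lambda_{\max} = 1$, CI = 0, no elicitation.
* 2×2 reciprocal matrices: always consistent
  ($\lambda_{\max} = 2$, CI and CR identically 0).
* Incomplete or reciprocal-conflicting judgment files: errors naming
  the expert, group, and item pair — the long CSV format stores only
  the strict upper triangle precisely so a conflicting reciprocal
  cannot be expressed silently.
* Zero scores in ratio tables and zero weights in aggregation: errors,
  not smoothing.

## Known limitations

* Only eigenvector prioritization is implemented (no row geometric
  mean / LLSM variant); the eigenvector is the method the reference
  software implements, and cross-method agreement is out of scope.
* No probabilistic sensitivity analysis (weight sampling) or
  criterion-removal analysis; scenarios are deterministic overrides.
* No consensus-feedback iteration between rounds of judgment.
* The independence assumption of additive synthesis — objective
  weights do not depend on alternative performance — is inherited from
  AHP itself; rank reversal under the distributive mode is the visible
  symptom, demonstrated rather than hidden.
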