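---
title: "Quantitative epistasis analysis: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative epistasis analysis: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistinfer)
```

## Scope and assumptions

`epistinfer` analyzes one gene pair at a time from a factorial deletion
experiment: wildtype, two single deletions and the double deletion, each
measured in two states of an external signal, with replication. The method
assumes:

* the trait is strictly positive and analyzed on the log2 scale, so that
  multiplicative fitness neutrality becomes additivity;
* each gene's activity is controlled by a *single* upstream factor
  (the signal for the upstream gene, the upstream gene for the downstream
  gene) and is Boolean — present or absent. Redundant regulation,
  feedback loops, gain-of-function and partial-function alleles are out of
  scope, and cyclic inputs to the network reduction step are rejected
  rather than silently resolved;
* a deletion's basal (signal-independent) effect is not larger in
  magnitude than its combined basal-plus-signal effect. This is the
  validity domain of the basal-correction step discussed below.

## The forward model

A hypothetical pathway S → X → Y → T is parameterized by the sign of each
step (activation/repression) and an orientation (which observed gene plays
X): 16 architectures plus a null model. Boolean activities propagate as
"present and not switched off by the factor directly upstream"
(`signal_activities()`), and the theoretical log2 trait is

θ = θ0 + s·σS + x_S·σX + y_S·σY + x·αX + y·αY + x·y·αI.

All units are log2 trait units throughout (a σY of 3 means the pathway
output changes the raw trait 8-fold between its active and inactive
states). Every predicted parameter table in the package is *derived at run
time* by forward-evaluating this model over the 8 conditions and applying
the regression contrasts (`predicted_betas()`, `zero_pattern()`). Nothing
is transcribed per architecture, which guarantees internal consistency
between the generator, the predicted patterns and the influence solver.

## Estimation

The design is saturated: eight cell means, eight coefficients. We
estimate every β and δ as a cell-mean contrast with deletion-indicator
coding (`d = 1` means deleted), e.g.
`betaX_on = T(X deleted, ON) − T(wildtype, ON)` and
`deltaI = betaI_off − betaI_on`. This coding reproduces the standard
identities on log2 fitness: `betaX_on = log2(W_X_on / W_wt_on)` and
`deltaI = log2[(S_XY·S_wt)/(S_X·S_Y)]` where `S = W_off/W_on` is the
sensitivity (both identities are verified in the test suite by computing
the two routes independently).

Standard errors propagate per-condition standard errors of the mean in
quadrature; two-sided t-tests use Welch–Satterthwaite degrees of freedom.
We chose Welch-style propagation over pooling the replicate variance
across conditions because replicate counts differ by genotype class in the
target design (8 for wildtype and singles, 4 for doubles) and because
severe-phenotype genotypes often have inflated variance; pooling is a
sensitivity-analysis variant, not the default. With noise-free input
(all cell SEs zero but replication present) p-values degenerate to 0 for
nonzero contrasts and 1 for zero contrasts, with a `noise_free` flag; a
contrast counts as zero below `1e-8 · max(1, max |cell mean|)`. With no
replication at all the interaction test is undefined and the pair is
reported as undetectable, with a warning, rather than guessed.

## The four inference steps and their edge cases

**Step 1 (interaction).** `deltaI ≠ 0` at significance level `alpha`
(default 0.05, the conventional per-pair threshold; no multiple-testing
correction is applied by default since the method's downstream
consistency requirements already suppress false inferences — a correction
can be applied by lowering `alpha`).

**Gene-effect precondition.** Each gene must have a significant
single-deletion effect in at least one signal state; otherwise the pair is
classed `non_epistatic`. "At least one state per gene" (rather than both
states) was chosen because, under the model, genes without basal function
genuinely affect only one state.

**Step 2 (order).** `eps_i = |delta_i + deltaI| / max(|delta_i|, |deltaI|)`
for each gene, compared with `eps_thr`. The default threshold is the mean
relative standard error of all significant interaction terms in the
dataset (`epsilon_threshold()`), i.e. the data's own precision; it can be
overridden for threshold sweeps. When `delta_i` and `deltaI` are both
exactly zero the score is undefined and set to 0 with a warning (a
degenerate, perfectly masked case). Raising the threshold can only move
pairs between directed/coequivalent/none categories, never reverse a
direction — a property the tests check explicitly.

**Step 3 (architecture).** For each of βX, βY, βI, the signal state with
the smaller |β| is declared basal and subtracted from the other state.
Magnitude ties are broken toward OFF as basal, with a warning (the choice
is arbitrary; the data cannot distinguish the two). The corrected nonzero
value equals ± the corresponding δ, so its significance is the δ test —
"zero" is statistical indistinguishability from zero at `alpha`, not a
magnitude cutoff. The signal states of the significant corrected effects
form a triple that is unique to one architecture family; the Y→T sign
follows from the sign of the nonzero interaction term through the
model-predicted relation. Profiles matching no family (e.g. a gene acting
as activator in one state and repressor in the other) are reported
`inconsistent` — deliberately not forced into the nearest family.
Coequivalent pairs (σX = 0) are ordered anyway if the single-gene effects
sit in opposite signal states (negative-regulation families); otherwise
they are reported as a `cohesive_unit` with only the family identified.

**Step 4 (influences).** For the matched architecture the 8 cell means are
an over-determined linear system in the 7 influences. We solve by least
squares and report the residual norm as a model-fit diagnostic (zero on
model-consistent data; the solution is then exact). This generalizes
closed-form per-family definitions and averages over their redundancy
automatically. Confidence intervals propagate cell SEs through the linear
solution operator with Welch–Satterthwaite degrees of freedom.

## Network assembly

Each inferred pair contributes one signed directed edge
(upstream → downstream, sign of the X→Y step). Transitive reduction
removes edges implied by longer paths, which is justified here because
every retained interaction conforms to a single-upstream-regulator model.
We reduce *within sign-consistent reachability*: an edge is removed only
when an alternative path composes (by sign product) to the same sign. On a
single-sign DAG this coincides with the classical reachability-minimal
reduction, which the tests verify against a brute-force oracle on random
DAGs. Removed edges are kept with an `indirect` flag rather than deleted.
When networks from two traits are merged, sign conflicts exclude the edge
and are reported — silent override would hide errors; no-conflict merging
keeps combined provenance.

## What the synthetic generator does and does not emulate

`simulate_pair()` draws replicate log2 values around the forward-model
cell means with i.i.d. Gaussian noise (multiplicative on the raw scale)
and exponentiates, using the factorial design above. `simulate_cascade()`
evaluates a full multi-gene Boolean chain per condition — other genes stay
intact while a pair is deleted — so indirect relations arise in the data
itself, not by composing pairwise models.

Defaults encode the targeted study conditions: 8 replicates for wildtype
and singles, 4 for doubles; noise sd 0.1 log2 units for benchmark-scale
simulations. `random_influences()` draws |σS| in [0.5, 1.5], |σX| in
[2.5, 3.5], |σY| in [1, 1.5] and basal effects in ±0.2 — magnitudes on the
scale seen in log2 fitness analyses of strongly signal-responsive
pathways, chosen once so that (i) every generically nonzero effect is
bounded away from zero, (ii) |σX ± σY| cannot vanish by coincidence, and
(iii) basal effects stay inside the basal-correction validity domain.

The generator does **not** emulate: growth-curve or flow-cytometry
measurement processes (traits enter as per-replicate scalars),
condition-dependent variance heterogeneity, correlated replicates (batch
effects), feedback loops, or zero-trait (dead) genotypes — raw traits must
be strictly positive, so lethal phenotypes must be floored upstream.
Passing tests therefore demonstrate correctness of the estimation and
inference machinery under the model's own assumptions, not robustness to
the full messiness of experimental data.

## Problem sizes used in the checks

The bundled verification uses: 100 influence draws per architecture for
the ordering rule; 5 draws per architecture for the influence round trip;
all 16 architectures noise-free end-to-end; 200 noisy pairs
(noise sd 0.1, 4 replicates everywhere) for recovery and CI coverage,
with a masking threshold of 0.2 — the value at which sweep TPR plateaus on
simulated cascades and a typical magnitude for the data-derived threshold
at this noise level; a 4-gene all-activation cascade (per-gene σ = 3, 1.5,
0.75, 0.4 so that every pair's feedforward score stays well above the
sweep range) for benchmarking; and 100 random DAGs of up to 10 nodes for
the reduction oracle. These sizes were chosen as the smallest that
exercise every architecture and give stable rates.

## Known limitations

* Only loss-of-function perturbations; feedback is invisible by design.
* One upstream regulator per gene; branched *inputs* are not modeled
  (branched outputs are, via σX).
* The basal correction can mis-assign the basal state when basal and
  signal-specific effects nearly cancel; such profiles usually surface as
  `inconsistent` rather than as wrong architectures, but close cancellation
  plus noise can produce either.
* `epsilon_threshold()` requires at least one significant interaction in
  the dataset; otherwise the threshold must be supplied.
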