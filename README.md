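# epistinfer

Quantitative epistasis analysis and pathway inference for signal-responsive
gene networks.

## The problem

Classical epistasis analysis orders two genes in a pathway by asking which
deletion *masks* the phenotypic effect of the other, using Boolean
reasoning about single and double mutants in the presence and absence of a
signal. Those rules break down as soon as genes have both signal-specific
and signal-independent (basal) functions, and they discard the quantitative
information in modern trait measurements (growth rates, reporter
expression). `epistinfer` implements a quantitative generalization: from
replicate trait measurements of wildtype, single- and double-deletion
genotypes in two signal states, it infers which gene is upstream, how the
pathway is wired (activation vs repression at each step), and how strongly
the signal, the upstream gene and the downstream gene each influence the
trait. It is aimed at experimentalists and systems biologists who quantify
combinatorial loss-of-function phenotypes — the canonical example being the
yeast galactose-utilization (*GAL*) network with fitness and
reporter-expression traits.

## The model in brief

For one gene pair (X upstream of Y) there are 8 factorial conditions:
delete X or not, delete Y or not, signal ON or OFF. On the log2 scale the
eight cell means are exactly described by the saturated regression

    T = β0 + s·βS + x·βX^s + y·βY^s + x·y·βI^s + ε,

with deletion indicators `x`, `y` and signal state `s ∈ {OFF, ON}`. On log2
fitness, `βI = 0` is multiplicative neutrality
(`W_XY·W_wt = W_X·W_Y`), and `βI = −βX` or `−βY` is epistasis (masking).

The forward model generating these parameters is a Boolean chain
S → X → Y → T where each arrow may activate or repress (8 wirings × 2
orientations = 16 architectures, plus a null model). Gene activities follow

    x_S = x present AND (s, or NOT s for repression),
    y_S = y present AND (x_S, or NOT x_S),

and the trait is a sum of influences

    θ = θ0 + s·σS + x_S·σX + y_S·σY + x·αX + y·αY + x·y·αI,

where `σS` is the signal effect bypassing both genes, `σX` the feedforward
effect of the upstream gene bypassing the downstream one, `σY` the effect
routed through the downstream gene, and the `α`s are basal
(signal-independent) effects.

Differencing each β between signal states eliminates every basal term,
yielding `δi = βi^OFF − βi^ON`. The model predicts `δY = −δI` for **every**
architecture: *the gene whose signal-dependent deletion effect is negated
by the interaction term is downstream, whatever the wiring.* The inference
algorithm is therefore:

1. **Interaction** — require `δI ≠ 0` (t-test).
2. **Order** — compute `εi = |δi + δI| / max(|δi|, |δI|)`; the gene with
   `ε ≤ ε_thr` is downstream. `ε_thr` defaults to the mean relative
   standard error of all significant interaction terms.
3. **Architecture** — subtract the basal effect of each β pair (the
   smaller-magnitude state), then match the signal states of the remaining
   nonzero effects to the family patterns predicted by the forward model;
   the sign of the nonzero `βI` fixes the last arrow.
4. **Influences** — invert the forward model (least squares on the 8 cell
   means) for `θ0, σS, σX, σY, αX, αY, αI` with 95% confidence intervals.

Pairwise results are assembled into a signed directed graph, simplified by
sign-aware transitive reduction, and can be benchmarked against a gold
standard by TPR/FPR threshold sweeps. A synthetic-data module simulates
single pairs and multi-gene cascades under the same factorial design
(log-normal replicate noise; 8 replicates for wildtype/singles, 4 for
doubles, by default).

## Worked example

Simulate one gene pair from an all-activation pathway
(θ0 = 10, σS = 1, σX = 2, σY = 3, αX = 0.5, αY = 0.25, noise sd 0.1 log2
units) and run the full inference:

```r
library(epistinfer)

arch <- pathway_architecture(s_to_x = +1, x_to_y = +1, y_to_t = +1, upstream = "a")
infl <- influence_set(theta0 = 10, sigmaS = 1, sigmaX = 2, sigmaY = 3,
                      alphaX = 0.5, alphaY = 0.25)
tab <- simulate_pair(arch, infl, noise_sd = 0.1, seed = 7,
                     gene_a = "GAL1", gene_b = "GAL10", trait_name = "fitness")

res <- infer_pair(tab, alpha = 0.05, eps_thr = 0.2)
print(res)
#> Pair GAL1 / GAL10 ( fitness ): inferred
#>   architecture: S+X+Y+T, upstream gene: GAL1
#>   influences: theta0=10.1, sigmaS=1.01, sigmaX=1.85, sigmaY=3.13,
#>               alphaX=0.559, alphaY=0.194, alphaI=-0.0898

print(res$diagnostics$masking)
#> Masking: eps_a = 0.371, eps_b = 0.00116 (threshold 0.2) -> b_downstream
```

The masking score of GAL10 (`eps_b`) is essentially zero — its
signal-dependent deletion effect (`deltaY = 3.13`) is negated by the
interaction term (`deltaI = -3.13`) — so GAL10 is placed downstream of
GAL1. The corrected deletion effects are all confined to the signal-ON
state with a positive interaction term, which matches the all-activation
family, and the recovered influences sit within sampling error of the
generating values (e.g. `sigmaY = 3.13 [2.99, 3.27]` vs truth 3).

Dataset-level analysis, network assembly and benchmarking:

```r
sim <- simulate_cascade(c("A", "B", "C", "D"), signs = rep(1, 4),
                        influences = list(theta0 = 10, sigmaS = 0.5,
                                          sigma = c(3, 1.5, 0.75, 0.4),
                                          alpha = c(0.1, -0.1, 0.05, 0.15)),
                        noise_sd = 0, n_replicates = 4, seed = 5)
res <- lapply(sim$tables, infer_pair, eps_thr = 0.2)
net <- transitive_reduction(build_network(res))
print(net)
#> Network model: 4 nodes, 3 direct edge(s), 3 indirect
#>   A -> B  [trait]
#>   B -> C  [trait]
#>   C -> D  [trait]
score(res, sim$gold)  # tpr = 1, fpr = 0
```

A thin command-line wrapper with `simulate`, `infer` and `benchmark`
subcommands is installed at `inst/scripts/epistinfer`.

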