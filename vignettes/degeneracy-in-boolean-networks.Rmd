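---
title: "Measuring degeneracy in random Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring degeneracy in random Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Degeneracy is the capacity of structurally different parts of a network to
contribute to the same function, so that damage to one part can be
compensated by others. `rbndegen` quantifies degeneracy in random Boolean
networks (RBNs) — the classical discrete model of gene regulatory
networks — and in their continuous stochastic-differential-equation
counterparts, and studies how the measure responds to systematic edge
lesioning and node perturbation.

```{r setup}
library(rbndegen)
```

## The model

An RBN has $n$ binary nodes (genes), each driven by a Boolean function of
1–2 randomly chosen inputs, updated synchronously. The package generates
networks by drawing, for every node, an in-degree uniformly from $\{1,2\}$,
the input nodes uniformly without replacement from all $n$ nodes
(self-inputs allowed), and the operator uniformly within the arity class:
unary rules are COPY or NOT; binary rules are AND, OR, XOR in the discrete
regime and OR or AND NOT in the continuous regime. Out-degrees are left
emergent, so hub genes and unread genes both occur. Rulesets serialize to
a plain-text equation dialect (`G1 = (G2 OR G3)`).

Two lesioning schemes model damage in increments of 10% of the nodes:
type 1 cuts all incoming edges of the selected nodes (outgoing preserved);
type 2 additionally deletes the nodes from every surviving rule, a binary
rule collapsing onto its remaining operand with its sign preserved. A
lesion-isolated node carries a zero-input constant rule: its update
restores its randomly drawn initial state, so its activity is constant
over the run and an injected bit-flip is visible for exactly one recorded
step. (The alternative — letting flips persist on isolated nodes — turns
every isolated gene into a random walk holding a full bit of entropy; we
found this drowns the lesioning effects in estimator noise and
contradicts the constancy of isolated-node activity that motivates the
varying-activity condition in the first place.)

### Dynamics

Discrete runs start from a uniformly random state and iterate the
synchronous update for 1000 steps, discarding the first 10 as burn-in
(990 kept samples). Perturbation is uncorrelated bit-flip noise applied
after each update and included in the recorded state: each node of the
perturbed subset flips with probability 0.25, and — in the
*varying-activity* regime — every node flips with probability 0.05 per
step, ensuring no trajectory is frozen. Classical RBNs set the baseline
rate to 0.

Continuous networks are compiled to one SDE per gene,
$$dx_i = \big(m\,R_i(x) - \lambda x_i\big)\,dt + \sigma\,dW_i,$$
where $R_i \in [0,1]$ is the soft-logic value of the gene's rule over
Hill activations $a_j = x_j^h/(\theta^h + x_j^h)$: NOT is $1-a$, OR is
the probabilistic sum $a + b - ab$, AND NOT is $a(1-b)$, and a frozen
gene keeps $R_i$ fixed at the activation of its initial level. Defaults
are $m = 20$, $\lambda = 10$ (ON level $m/\lambda = 2$ expression units),
$\theta = m/2\lambda = 1$, $h = 10$ (switch-like), $\sigma = 0.05$, and
Euler–Maruyama step $dt = 0.01$; all are exposed through
`kinetic_params()`. Perturbed genes additionally receive additive
$N(0, 0.01)$ noise per recorded step; expression is clamped at zero.
Initial levels are drawn uniformly on $[0, m/\lambda]$, spanning the
OFF–ON range. Expression is binarized per gene by its median over the
kept window (strictly above the median maps to 1), which makes the
binary series invariant to positive rescaling.

### The degeneracy measure

All information quantities are plug-in estimates on the 990 kept binary
samples, in bits: the joint entropy $H(S)$ of a node subset is Shannon
entropy of the empirical joint-state distribution, and
$MI(A;B) = H(A) + H(B) - H(A \cup B)$. Perturbation gives the measure its
causal direction: a random *output sheet* $O$ of $n/2$ nodes stands for
the system's macroscopic behavior, and a subset $X^k_j$ of $k$ nodes is
injected with noise. Degeneracy sums, over $k = 1..n$, the excess of the
average perturbed-subset MI over a linear null:
$$D_N(X;O) \;=\; \sum_{k=1}^{n}\Big[\big\langle MI^P(X^k_j;O)\big\rangle
\;-\; \tfrac{k}{n}\,MI^P(X;O)\Big].$$
*Partial degeneracy* estimates one term from a single random subset per
random network: two companion runs of the same lesioned network are
simulated (the subset perturbed; all $n$ nodes perturbed, which supplies
$MI^P(X;O)$ and makes the $k=n$ term vanish in expectation), and the
replicate's value is $MI(X^k;O) - (k/n)\,MI(X;O)$. Individual values may
be negative; condition averages are expected non-negative. Subsets and
output sheets are redrawn per replicate and drawn from all $n$ nodes, so
subset/output overlap occurs (it must, whenever $k > n/2$).

## The factorial study

`run_grid()` crosses lesion type (2) × cut percent (0–100 by 10) × subset
size (1–10) and replicates each cell with a fresh random network. Every
replicate's randomness descends from a Lehmer-style hash of the master
seed and the cell coordinates, so any row is reproducible in isolation.
`condition_degeneracy()` sums condition-mean partial degeneracy over $k$;
`summarize_peaks()` locates maxima (ties break to the smallest
coordinate); and `anova_lesion_types()` compares the two lesion types
with a two-factor ANOVA *without replication* on the 2 × 11 matrix of
condition means, the interaction mean square serving as the error term
(df = 1, 10). Desk-scale runs default to 200 replicates per cell;
`replicates = 1000` reproduces the full-scale design. The package's own
acceptance runs use 200 (test suite) and 400 (acceptance script)
replicates, sizes at which a full grid takes a few minutes on one core.

```{r quick-example, eval = FALSE}
cfg <- experiment_config(replicates = 200, master_seed = 1)
tab <- run_grid(cfg)
condition_degeneracy(tab)
summarize_peaks(tab)
anova_lesion_types(tab)
```

## What the generator does and does not emulate

The generator reproduces the wiring statistics of small Kauffman-style
N-K models: 10 nodes, in-degree 1–2, operator menus as above, no bias
constraint on the truth-value density. It does not attempt scale-free or
curated biological topologies, two-species (mRNA + protein) kinetics,
cell-to-cell parameter variation, or asynchronous update schemes. Results
on these synthetic ensembles therefore speak to the behavior of the
degeneracy measure on random binary wiring, not to any particular
organism's regulatory network.

## Numerical choices

* **Estimator.** Plug-in (maximum-likelihood) entropies with no bias
  correction, log base 2; `0 log 0 = 0`; the empty subset has entropy 0
  by convention. All comparisons are within-estimator.
* **Ties.** Median binarization sends ties (and constant genes) to 0;
  peak reports resolve ties to the smallest coordinate.
* **Degenerate inputs.** A rule losing all inputs becomes the constant
  rule; `steps <= burn_in`, invalid cut percentages, and out-of-range
  subsets raise errors; SDE blow-up (non-finite state) aborts with the
  failing step.
* **Flip order.** Subset flips are applied before baseline flips, both
  after the synchronous update; a subset node can flip twice in a step
  (the flips compose). The recorded state is post-flip, so the
  perturbation is part of the observed activity.
* **Seeds.** Generation and both simulators accept explicit seeds and
  restore the caller's RNG state; the grid's seed tree keeps all derived
  seeds below $2^{31}$.

## Known limitations

The plug-in estimator is the binding constraint at the study's scale.
With 990 samples, the joint entropy of a union of more than ~9 active
binary columns saturates near $\log_2 990 \approx 9.95$ bits, which
inflates mutual information — and hence the per-$k$ degeneracy terms —
most strongly around $k \approx 7\text{–}8$ of the $k + n/2$-column
union. Two consequences are visible in the package's own runs. First,
condition-averaged partial degeneracy tends to peak at $k = 7$–$8$
rather than at half the nodes: the genuine network-mediated signal at
these sample sizes is small (of order 0.1 bits per cell) relative to the
estimator's saturation profile. Second, fully lesioned networks retain a
positive degeneracy floor (~0.4 bits summed over $k$ in the discrete
regime) even though their true degeneracy is zero, because perturbed
isolated nodes still carry blink entropy; the floor is larger in the
continuous regime, where median binarization forces a full bit per gene
and sample autocorrelation at $dt = 0.01$ shrinks the effective sample
count further. The lesioning trend (degeneracy declining as cuts deepen)
and the null lesion-type comparison are robust to all of this; exact
peak locations at 990 samples are not, and should be read with the
estimator's bias profile in mind. Entropy-bias corrections
(Miller–Madow, NSB) or longer runs would sharpen the profiles but are
deliberately out of scope: the measure is defined here, as in the
studies it follows, by the uncorrected plug-in estimator.

Negative partial degeneracy in single replicates is expected and
reported as computed — never clamped; its biological interpretation is
an open question in the literature the measure comes from.
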