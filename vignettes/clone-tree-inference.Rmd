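---
title: "Inferring subclonal lineage trees from SNV read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring subclonal lineage trees from SNV read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetree)
```

## The model

A tumor sample is a mixture of subclonal lineages related by a rooted tree.
Each lineage carries the SNVs first appearing along its ancestral path (its
*genotype*), and the population frequency of an SNV is the summed frequency
of the lineage it arose in plus all descendants. Under the infinite sites
assumption this forces `phi_parent >= sum(phi_children)` in every sample.

`clonetree` couples three ingredients:

**Observation model.** For SNV $i$ in sample $t$ with variant reads
$b_i^t$ of depth $d_i^t$, a read is a reference allele with probability
$(1-\phi)\mu^r + \phi\,\mu^{v:g}$, where $\mu^r = 1 - \text{error rate}$
and $\mu^{v:g}$ depends on the variant-population genotype $g$ (0.5 for a
heterozygous diploid variant). The genotype is unobserved; with Dirichlet
pseudo-counts $\delta$ over candidate genotypes, integrating the genotype
out turns the likelihood into a mixture with weights
$\delta_g / \sum_{g'} \delta_{g'}$ (the single-draw Dirichlet-compound
multinomial). We parameterize with variant counts and success probability
$1 - p_{\mathrm{ref}}$, which is algebraically identical to the
reference-count form but matches how count tables are printed, and clamp
success probabilities to $(10^{-10}, 1-10^{-10})$ so log-likelihoods stay
finite even for $\mu^{v:g} \in \{0, 1\}$.

**Tree prior.** A tree-structured stick-breaking process: node
$\varepsilon$ keeps a fraction $\nu_\varepsilon \sim
\mathrm{Beta}(1, \lambda^{|\varepsilon|}\alpha_0)$ of the mass reaching it,
and the remainder is split over children by sticks $\psi \sim
\mathrm{Beta}(1, \gamma)$. Data may sit at internal nodes, the number of
lineages is unbounded, and the depth-decaying concentration
$\alpha(j) = \lambda^j \alpha_0$ shortens trees when $\lambda < 1$.
Hyperparameters get continuous uniform priors on $\alpha_0 \in [1, 50]$,
$\gamma \in [1, 8]$, $\lambda \in [0.25, 1]$ (the hull of the calibration
grid), resampled by Metropolis steps each sweep, so inference integrates
over tree-shape preferences instead of fixing them.

**Constrained frequencies.** Each node carries a per-sample auxiliary
weight $\eta_v \ge 0$ with $\sum_v \eta_v = 1$, and
$\phi_v = \eta_v + \sum_{w \in \mathrm{children}(v)} \phi_w$. *Any* point
of the weight simplex satisfies the clonal constraint, which turns the
awkward constrained sampling problem into an unconstrained one on the
simplex. The generative scheme (breadth-first: each child draws
$\mathrm{Uniform}(0, \eta_{\mathrm{parent}})$ and decrements the parent)
has an exact density — a product of $1/\text{available mass}$ terms — which
we include in the Metropolis-Hastings target so that with flat likelihood
the chain provably recovers the generative prior (a tested oracle). The MH
proposal is $\mathrm{Dirichlet}(\sigma \eta + 10^{-4})$ with $\sigma = 100$;
the pseudo-count floor keeps the proposal proper near the simplex boundary
and is accounted for exactly in the acceptance ratio. With multiple
samples, per-sample proposals are accepted jointly on the product of
per-sample posteriors, sharing one tree.

The root node represents the non-tumor cell fraction: its frequency is
pinned at 1 by construction and it normally holds no SNVs (a truly clonal
cluster, present in every cell, is the exception). Following the model's
single-founding-clone assumption, the root has at most one child lineage by
default (`single_clone = TRUE`); disable it to allow multicentral tumors.

## The sampler

Each Gibbs sweep runs, in order: an auxiliary-candidate assignment scan, a
slice-retrospective assignment scan, subtree-relocation moves,
parent-insertion moves at the root, conjugate stick updates plus
hyperparameter Metropolis steps, culling of unoccupied branches, and the
global MH weight move (default 5,000 inner iterations). Defaults follow the
published settings: 5,000 sweeps, burn-in 100, no thinning.

Design choices that mattered, found the hard way on simulated data:

* **Initialization.** All SNVs start at the root holding the full unit
  weight; the first sweep updates SNVs in decreasing allele-fraction order.
  High-frequency clusters then claim weight while it is still available and
  lower clusters nest beneath them. Hyperparameters start at the parsimony
  corner ($\alpha_0 = 1, \gamma = 1, \lambda = 1$) — large initial
  $\alpha_0$ makes new-node stopping probabilities so small that clusters
  cannot be carved out before the weight is spent.
* **Fresh candidates are tentative.** During candidate search, transient
  nodes get sticks but no weight; a candidate draws a tentative
  $\mathrm{Uniform}(0, \eta_{\mathrm{parent}})$ weight that is committed
  only if selected. Eagerly committing weight to rejected candidates bleeds
  the parent dry within a single sweep and freezes the tree.
* **Auxiliary-candidate scan.** Besides the slice sampler, each SNV chooses
  among all instantiated nodes plus three fresh would-be children per node
  with probability proportional to stick weight times likelihood
  (Neal's algorithm-8 pattern). A slice sampler alone ends as soon as it
  re-draws the current node, which at deep coverage means a trapped SNV
  gets only a couple of escape lottery tickets per sweep.
* **Structure moves at fixed frequencies.** Whether a cluster at 0.23
  hangs beside or beneath a cluster at 0.27 is invisible to the likelihood
  but not to the prior. A subtree relocation that compensates weights so
  every $\phi$ is unchanged (accepted on the prior ratio alone), and a
  reversible parent-insertion/deletion pair at the root (the only move that
  can create a lineage *above* the current founding clone when the
  single-clone constraint is active), let the chain traverse these
  likelihood-flat ridges. Without the latter, a founding cluster that
  accidentally fuses two SNV groups in the first sweep can never unfuse —
  a failure mode worth ~500 log-likelihood units on the SU048 data.
* **Restarts.** `infer_clone_tree(..., n_restarts = k)` runs independent
  chains and keeps the one with the highest complete-data log-likelihood,
  the published remedy for chains caught in a poor mode.

## What the simulator emulates — and what it does not

`simulate_reads()` draws per-SNV depths $\mathrm{Poisson}(\text{depth})$
(the depth distribution is unstated in the validation designs; Poisson is
the natural minimal choice) and variant reads binomially under the
heterozygous normal-copy-number observation model at the cluster's
frequency. The presets encode the published designs: six clusters at
frequencies $\{1.0, 0.85, 0.6, 0.35, 0.2, 0.08\}$ with nine SNVs each at
depths 10,000/1,000/200; a five-node chain $0.9 \to 0.75 \to 0.55 \to 0.4
\to 0.25$ (only consistent with a chain, by the sum rule); and a two-sample
crossing design. The simulator does *not* model overdispersion
(negative-binomial noise), mapping bias, copy-number change, or
contamination by miscalled sites — a green recovery test establishes
correctness of the inference machinery under its own observation model,
not robustness to real-data artifacts.

## Numerical choices

* Stick draws are clamped to $(10^{-10}, 1-10^{-10})$; Beta densities in
  Metropolis ratios stay finite.
* Mixture likelihoods use log-sum-exp; binomial coefficients are
  precomputed once per dataset.
* Zero-depth observations contribute zero log-likelihood, so a dataset
  with no reads exercises the pure prior (used by the oracle tests).
* Proposed Dirichlet weights are floored at $10^{-12}$ and renormalized.
* At very deep coverage (hundreds of thousands of reads) the posterior over
  the weights is far narrower than the $\sigma = 100$ Dirichlet proposal,
  so the reported MH acceptance rate can be tiny at equilibrium. This is a
  property of the published proposal scale, not a defect: the weights are
  positioned by the assignment and structure moves and the rare accepted
  weight moves fine-tune them (the posterior means are unaffected; see the
  acceptance-rate column of `glance()`).
* Ties in `best_tree()` break toward the earliest recorded sweep; sibling
  order carries no model meaning and is by instantiation index.
* Depth and width of the lazily instantiated tree are capped (30 and 60);
  at the calibrated hyperparameter ranges the caps are effectively never
  reached.
* The complete-data log-likelihood records both the read-count term and
  the assignment-prior term $\sum_i \log \omega_{z_i}$, and the two are
  exposed separately, so either convention for "best tree" selection can be
  reproduced.

## Open design points, resolved

* **Correlation clustering** (for coloring the partial order plot) is
  NP-hard; we use greedy agglomeration with single-move local search and
  ten seeded restarts, ties toward the lowest SNV index. Tests verify
  exact optimality against exhaustive partition enumeration up to eight
  SNVs. The coloring is a visualization aid, not a posterior summary.
* **Triplet classification tolerance** defaults to 0 (exact frequencies);
  noisy estimates can pass a positive `tol`. The brute-force enumerator of
  consistent trees doubles as its oracle, including the mock wildtype
  ancestor (frequency 1) that covers multicentral configurations.
* **Genotype defaults**: a locus with unknown zygosity at copy number $n$
  enumerates $k = 1..n$ variant copies with reference-allele probabilities
  $(n-k)/n$ (clamped by the error rate) and uniform pseudo-counts
  $\delta = 1$. The sequencer error rate is not printed in the source
  material for the leukemia data; the default is 0.001 and it is
  configurable everywhere.

## Known limitations

* Lineage-genotype posterior probabilities on real single-sample data are
  dominated by the *prior* whenever several placements of a low-frequency
  cluster fit the read counts equally well; they are therefore sensitive
  to the exact prior bookkeeping and to the genotype states supplied per
  SNV (heterozygous-only versus a zygosity mixture), and published values
  of such probabilities should be compared qualitatively. With
  heterozygous-only inputs, the founding-lineage genotype of the SU048
  sample is recovered with posterior probability 1 — the read depths leave
  no ambiguity about the top of the tree — while the deeper branch-versus-
  chain arrangement of the three mid-frequency SNVs keeps substantial
  posterior spread.
* The binomial observation model underestimates read-count variance on
  real data (no overdispersion); a negative-binomial variant is out of
  scope.
* Copy number and zygosity are inputs, not inferred.
* At several hundred SNVs the R-level assignment scans become the
  bottleneck; the weight updates are compiled, the scans are not.

## A small end-to-end run

```{r example, eval = FALSE}
sim <- simulate_reads(preset_scenarios(seed = 11)$chain5)
fit <- infer_clone_tree(sim$counts, n_iters = 500, burn_in = 100,
                        mh_iters = 400, seed = 1)
glance(fit)
posterior_structures(fit)[1, ]   # modal tree: the five-node chain
autoplot(fit)                    # likelihood trace
trace_diagnostics(fit)           # autocorrelation of the trace
plot_partial_order(partial_order(fit))
```
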