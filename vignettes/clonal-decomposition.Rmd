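---
title: "Clonal decomposition of multi-section tumor counts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal decomposition of multi-section tumor counts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesect)
```

## The inference problem

A solid tumor is a mixture of clonal cell populations. When one tumor is
physically cut into subsections and each subsection — plus a matched normal
sample — is deep-sequenced at a common set of somatic loci, two integer
matrices result: `N[i, j]`, the coverage at locus `i` in subsection `j`,
and `X[i, j]`, the number of reads supporting the variant allele.
`clonesect` decomposes these counts into

* a binary genotype matrix `W` (`M` loci by `C` clones; `W[i, c] = 1` means
  clone `c` carries the heterozygous somatic variant at locus `i`; the
  first clone is the normal population and its column is all zero), and
* a clone frequency matrix `P` (`C` by `S`; column `j` is the mixture of
  clones in subsection `j` and sums to one).

Only loci that are somatically mutated somewhere in the tumor enter the
panel: positions homozygous normal in every tumor subsection carry no
information about the decomposition and are excluded upstream.

## The generative model

Three assumptions make the decomposition identifiable from count data:

1. every subsection contains some normal contamination (`P[1, j] > 0`);
2. subsections are independent given the parameters;
3. loci are independent given the parameters, and each variant is
   heterozygous with copy number one in the clones that carry it.

Under assumption 3, a clone carrying the variant contributes half of its
cell fraction to the chance that a random read shows the variant allele, so
the variant-read probability at locus `i` in subsection `j` is

    B[i, j] = sum_c W[i, c] * P[c, j] / 2,

always in `[0, 1/2]`. The observed counts are then independent binomial
draws, `X[i, j] ~ Binomial(N[i, j], B[i, j])`, and the latent genotype bits
have independent Bernoulli priors `W[i, c] ~ Bernoulli(theta[c])` for tumor
clones, with `theta[1] = 0` fixed for the normal clone. The number of
clones `C` is a hyperparameter; because the frequencies are otherwise
unconstrained, `C` may not exceed the number of subsections or the
optimization is under-constrained (`clonal_fit()` enforces this, with an
explicit override).

## EM inference

The genotype matrix is discrete, so the likelihood is maximized by an EM
algorithm that treats `W` as the latent variable:

* **E step** (`e_step()`): for each locus, Bayes' theorem over all
  `2^(C-1)` admissible genotype vectors, computed in log space; per-clone
  marginal mutation probabilities are sums of posterior mass over the
  vectors carrying the mutation. The enumeration is capped at `C = 12`
  (2048 vectors per locus), far beyond the model's practical regime where
  `C` cannot exceed the number of subsections.
* **M step for `theta`** (`m_step_theta()`): closed form — the mean of each
  tumor clone's posterior marginals.
* **M step for `P`** (`m_step_P()`): the expected binomial log-likelihood
  is maximized over the tumor-clone entries of `P` by L-BFGS-B with an
  analytic chain-rule gradient. The simplex and contamination constraints
  are enforced with pure box constraints: only tumor entries are free in
  `[0, 1 - delta_normal]`, the normal fraction is defined as one minus
  their column sum, a smooth quadratic penalty activates only when a
  column sum exceeds `1 - delta_normal`, and the result is projected back
  onto the feasible set. A literal logarithmic barrier is undefined on the
  infeasible side, which is why the exterior penalty was chosen; the
  penalty weight scales with the total read count so violations stay below
  solver tolerance. A monotonicity guard keeps the previous `P` (with a
  warning) if the solver fails to improve the objective, so the EM ascent
  property survives optimizer hiccups.

Convergence is declared when the relative change in `Q*`, the expected
complete-data log-likelihood assembled from the posterior table, falls
below `epsilon`. Genotypes are called by thresholding the converged
marginals at 0.5 (ties round to 1 — an arbitrary documented choice that is
immaterial in practice because converged marginals are numerically 0 or 1
on separated data).

**A note on monotonicity.** EM guarantees ascent of the *marginal*
log-likelihood (equivalently of the entropy-augmented surrogate), not of
`Q*` itself: `Q*` equals the marginal log-likelihood minus the posterior
entropy, and on ambiguous data the entropy can rise, producing
entropy-sized dips in the `Q*` trace while the fit is still ascending.
`clone_fit` objects therefore carry both traces: `loglik_trace` (`Q*`,
used for convergence and BIC) and `observed_trace` (the marginal
log-likelihood, guaranteed non-decreasing). The test suite asserts
monotonicity of the marginal trace on every run and documents the `Q*`
caveat where it checks the surrogate.

Because the M step is non-convex, `clonal_fit()` restarts the EM from
multiple seeded random initializations (frequencies uniform then
column-normalized; tumor priors uniform) and keeps the run with the best
`Q*`; restart `r` derives its seed as `seed + r` so every restart is
individually reproducible. All restarts' final `Q*` values are retained
for restart-sufficiency diagnostics.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | `1e-6` | relative `Q*` change that stops the EM. A much looser threshold (say `1e-3` relative) stops after very few iterations once counts are large, because `|Q*|` scales with the data; `1e-6` is ordinary EM practice and costs little since the posterior sharpens quickly. |
| `max_iter` | 1000 | iteration cap. |
| `restarts` | 10 | random initializations per fit; sufficient for small clone numbers, more are advisable as `C` grows. |
| `delta_normal` | `1e-3` | lower bound on the normal fraction per subsection (the contamination assumption is strict positivity; the numeric floor is a package choice). |
| genotype call threshold | 0.5 | marginal-probability cutoff for calling a mutation; ties round to 1. |

Reported log-likelihoods (`Q_star`, `observed_loglik`, the traces) include
the binomial coefficient terms so values are comparable across software;
inside the optimization the coefficients are dropped as constants.
Probabilities are clipped to machine-safe ranges only inside the
optimizer's objective and gradient, never in reported likelihoods — an
impossible observation yields `-Inf`, not a clipped number.

## Model selection by BIC

`BIC(fit)` computes `-2 Q* + K log(n)` with `n` the total read count and
`K = (C - 1)(M + S)` free parameters: one genotype bit per locus and one
frequency per subsection for each tumor clone. The normal clone is fully
determined and each column's simplex constraint removes the remaining
degree of freedom. This counting is isolated in `free_param_count()` so an
alternative convention can be swapped in. `select_clones()` reports the
BIC table together with percentage improvements between consecutive clone
numbers and deliberately applies no automatic cutoff: a small relative
improvement warns that added clones may over-fit, and that judgement is
left to the analyst.

## The simulator

`simulate_panel()` draws a study from the generative model itself:
coverage columns from `Multinomial(M * coverage, uniform)` so each
subsection totals exactly `M * coverage` reads; tumor genotype bits
`Bernoulli(genotype_p)` (default 0.3, exposed as a parameter); frequency
columns uniform-then-normalized with the normal subsection's column set to
the pure-normal vector; counts binomial. `inject_noise()` adds per-read
flip errors (`X' = X - Binomial(X, e) + Binomial(N - X, e)`).

Two emulation choices deserve emphasis:

* **Only mutated loci, by default.** Real panels are assembled by variant
  calling, so a locus enters only if it is somatically mutated somewhere in
  the tumor. Unconditioned Bernoulli genotypes instead leave a
  `(1 - genotype_p)^(C-1)` fraction of loci mutated in no clone; such loci
  are harmless in noise-free data but become structurally impossible under
  read-flip noise (their only admissible genotype has variant-read
  probability exactly zero), which forces genotype errors that the real
  pipeline can never see. `simulate_panel()` therefore conditions each
  locus on carrying at least one tumor mutation (`only_mutated = TRUE`);
  unconditioned draws remain available.
* **What is not emulated:** copy-number variation (the model fixes copy
  number one at variant loci), overdispersion beyond binomial sampling,
  spatial correlation between neighboring subsections, and mapping or
  base-calling artifacts beyond symmetric read flips. Passing simulation
  tests therefore demonstrates correct inference *under the model's own
  assumptions*, not robustness to these real-data violations.

## Error metrics

`match_and_score()` compares an estimate to the truth after resolving
label switching: estimated tumor-clone columns are matched to true ones by
the permutation minimizing the genotype error, found exactly (exhaustive
search up to nine tumor clones, a Hungarian assignment solver — equivalent
for this additive cost — above). The genotype error is the mean absolute
difference over tumor-clone genotype entries; the frequency error is the
mean absolute difference over *all* frequency entries, normal row
included, using the genotype-selected permutation. These denominators are
a documented package choice; any fixed convention leaves comparisons
across conditions meaningful up to a constant.

## Phylogeny analysis

A clonal tree in which every mutation arises exactly once and is never
lost exists if and only if the carrier sets of all mutations are pairwise
nested or disjoint (`is_valid_phylogeny()`, which returns a witness pair
of conflicting mutations on failure). `build_tree()` constructs the tree
over the laminar family of distinct carrier sets — one edge per carrier
set, with implied trunk nodes where sibling clones share mutations — and
attaches each clone at its deepest containing set; clones with identical
genotypes share a node. This reproduces, for example, a two-tumor-clone
solution with shared trunk mutations as root → trunk → two leaves, and
`tree_genotypes()` inverts it exactly.

When an inferred genotype matrix narrowly fails the test,
`nearby_variants()` enumerates all matrices differing in exactly one bit
among the *distinct row patterns* (the flip applies to every locus sharing
the pattern) that do admit a tree, and `score_genotype()` rescores each
candidate by maximizing the likelihood with the genotype held fixed — a
degenerate-posterior M step, restarted 200 times by default since this
one-shot optimization is far easier than a full EM fit. Because the
reporting convention for a fixed-genotype likelihood is ambiguous (with or
without binomial coefficients and Bernoulli prior terms), all variants are
returned; rankings agree across them on all data we have examined, and the
tests rely on the ranking, not the absolute values. `leave_one_out()`
refits with each tumor subsection held out and reports genotype bit
differences (after permutation matching) and whether the repaired trees
coincide.

## Variant screening

`screen_variants()` implements the two-stage multi-sample screen on
six-outcome allele-count tables (A, C, G, T, deletion, unknown). Stage 1
compares normal versus each tumor subsection with a 2x6 Fisher exact test
(`stats::fisher.test`'s exact network algorithm; for totals above
`mc_total` a seeded Monte-Carlo p-value with `1e5` draws is used), then
converts all p-values to q-values with Storey's procedure — implemented
in-package: `pi0` from a spline over a lambda grid, `q = pi0` times the
step-up adjusted p-values, falling back to plain Benjamini-Hochberg
(`pi0 = 1`) for small batches. A locus is accepted if any comparison has
`q` below the threshold (default 0.05, configurable — the original cutoff
is not stated). Stage 2 runs six 2x2 exact tests per accepted locus and
subsection (each allele against the other five), calling alleles
increased, decreased, or unchanged at `p < 0.01`, and flags
increased-with-zero-normal-count calls as tumor-specific.
`deep_locus_filter()` applies the deep-sequencing locus criteria: normal
coverage at least 3 and at most a few variant reads in the normal (default
2, configurable); the third customary criterion, visual review for
clustered mutations, is inherently manual and is not automated.

## Problem sizes used by the test suite

The acceptance tests replicate the method's validation experiments at the
following sizes, chosen to make each check statistically meaningful while
keeping the whole suite in the minutes range: parameter recovery on the
full grid `C ∈ {2,3,4}` x `S ∈ {4,8,12}` with `M = 100`, coverage 1000,
10 restarts and 100 simulations per grid point; noise robustness at
`C = 3, S = 8` with 20 replicates, comparing read-flip error 0.01 against
noise-free; BIC recovery with true `C = 3, S = 6, M = 30` over 20
replicates; EM monotonicity on 50 random panels; phylogeny round trips on
100 random trees. `scripts/acceptance.R` recomputes the headline
quantities at 25 replicates per condition.

## Known limitations

* Copy number is fixed at one for variant loci; amplified or deleted
  regions violate the halving in the variant-read probability. Extending
  the denominator with a per-locus hidden variable was considered and
  rejected as badly under-determined without aggressive regularization.
* Sequencing error is not part of the likelihood; robustness to moderate
  read-flip noise is empirical (and relies on panels containing only
  truly mutated loci), not structural.
* The decomposition requires at least as many subsections as clones, and
  the number of restarts needed grows quickly with the clone number.
* The phylogeny stage is a consistency analysis over the called genotype
  matrix, not joint inference of tree and genotypes; repairs explore only
  one-bit neighborhoods of the distinct row patterns.
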