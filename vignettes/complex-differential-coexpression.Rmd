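---
title: "Complex-centric differential co-expression and TF influence: models and design"
author: "CoCoDiff authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex-centric differential co-expression and TF influence: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoCoDiff)
```

## The scientific question

Protein complexes, not single genes, carry out most cellular processes.
When two biological conditions — a matched normal/tumour cohort, or two
tumour subtypes — rewire the cell, the signature is often a coordinated
loss (or compensatory gain) of co-expression among a complex's members
rather than a large fold-change in any one gene. CoCoDiff implements a
pipeline that (i) builds condition-specific co-expression-weighted PPI
networks, (ii) extracts complexes from each, (iii) matches them across
conditions and quantifies their co-expression change, and (iv) attributes
those changes to transcription factors through a log-linear influence
model.

## Models and procedures

### Reliability scoring

PPI edge lists pool experiments of very different quality, so edges are
first scored by topology: the iterated, degree-adjusted Czekanowski–Dice
neighbourhood similarity. With closed neighbourhoods $N_u$ (a node
belongs to its own neighbourhood), round $k$ computes

$$ w_k(u,v) \;=\; \frac{\sum_{x \in N_u \cap N_v}\big(w_{k-1}(u,x) + w_{k-1}(v,x)\big)}
   {\lambda_u + S_u + \lambda_v + S_v}, \qquad
   S_u = \sum_{x \in N_u} w_{k-1}(u,x), $$

where $\lambda_u = \max(0, \bar S - S_u)$ penalizes poorly connected
nodes ($\bar S$ is the network mean of $S$). Round 1 is the classical
adjusted CD score; 40 rounds and a cutoff of 0.20 (edges strictly below
are dropped, the boundary kept) are the conventional settings exposed as
defaults in `iterativeCDScore()` and `filterByReliability()`.

### The correlation transform

Per-condition edge weights are Pearson correlations passed through
$z = \tfrac{1}{2}\log\frac{1+\rho}{1-\rho}$. The default uses the
**base-10** logarithm: the tool this pipeline follows reports transformed
values on that scale (0.10 maps to 0.043 and 0.99 to 1.149), and all
downstream scores inherit it. `transformBase = "e"` switches to the
natural-log variant (`atanh`) for users who prefer the classical
variance-stabilized scale; the two differ only by the constant
$\ln 10$, so orderings, signs, and all threshold-free statistics are
unaffected — but thresholds such as $\delta$ and the rewiring cutoff are
scale-dependent and belong to the base-10 convention. Correlations at
$\pm 1$ are clamped to $\pm 0.999999$; correlations that are undefined
(zero variance, or fewer than three complete sample pairs) are set to 0
and flagged rather than dropped, so the edge stays visible. Correlations
below $10^{-12}$ in magnitude are treated as exactly zero: the Markov
clustering below column-normalizes weights, which would otherwise
amplify floating-point dust into real attachments.

### Clustering weight

The conditional "presence" score of an edge is
`reliability * max(rho, 0)`: negative co-expression is treated as
absence of the interaction in that condition. This is a convention — the
alternative `abs(rho)` (interpret strong anti-correlation as evidence of
a regulated interaction) is available via `negativeMode = "abs"` — but
the positive-part form matches the interpretation of complexes as
co-expressed units and keeps anti-correlated pairs from gluing clusters
together.

### Complex extraction

`mclCluster()` is a deterministic Markov Cluster implementation: the
symmetric weight matrix gets self-loops equal to each node's maximum
incident weight (standard MCL practice; it stabilizes small cliques),
is column-normalized, and then alternates expansion (matrix square, by
default) with inflation (entrywise power 2.3, the conventional setting
for PPI networks, then renormalization), pruning entries below $10^{-5}$,
until the iteration moves less than $10^{-6}$ in max-norm or 100 rounds
pass (the latter returns the current state with a warning). Attractor
rows define clusters; overlapping attractor systems are merged, so the
output is a partition of every node incident to a positive-weight edge.
Clusters with at least 4 members (the conventional minimum complex size)
become complexes.

### Co-expression of a complex

For a complex $S$ the score $C(S)$ aggregates the transformed pairwise
correlations of its members. The printed form of this statistic divides
by $|S|^2$, which is ambiguous about ordered pairs and self-pairs; the
package's default (`mode = "pairs"`) is the mean over unordered distinct
member pairs, which is scale-free across complex sizes and reads as an
average association. The literal form (`mode = "literal"`: ordered-pair
sum over $|S|^2$, self-pairs excluded) differs only by the factor
$(|S|-1)/|S|$, so the two modes agree in sign and ordering at any fixed
size; the tests assert this. Transformation happens per pair, before
averaging. Members without expression data are excluded and counted;
fewer than two measured members gives a flagged `NA` rather than a
number.

### Matching and partition

Complexes are paired across conditions when Jaccard similarity is at
least $t_J = 0.67$ and co-expression change at least $\delta = 0.10$.
Nothing in the source convention pins the matching cardinality; CoCoDiff
uses greedy one-to-one matching in order of descending Jaccard (ties:
larger $\Delta C$, then lexicographic ids), which is deterministic and
reproduces dedup-style counts. The matched set splits into M′
(co-expression higher in the first condition; direction `"decrease"`)
and M″ (lower; `"increase"`), summarized by size, maximum and mean
$\Delta C$.

Distribution-level statistics use (i) a two-sample KS comparison that
reports the *scaled* statistic $D\sqrt{nm/(n+m)}$ against the
large-sample critical value $c(0.05) = 1.36$ — the convention under
which reported statistics can exceed 1 — and (ii) a random-complex null:
size-matched uniformly drawn node sets, scored exactly like real
complexes, with the empirical p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + \text{reps})$, which is
never zero and is uniform when the observed value is itself a null draw.

### Differential network

On the shared edges of the two conditional networks, the per-edge change
is $\Delta = z_A - z_B$ (first condition minus second, so positive means
a drop toward the second condition). Edges with $|\Delta| \ge 0.50$ form
the rewired view; its Markov clusters (weight $|\Delta|$) are labelled
`decrease` when at least two-thirds of their rewired edges have positive
$\Delta$, `increase` when at least two-thirds are negative, `mixed`
otherwise. Exactly two-thirds counts as directional.

### TF influence

A TF $F$ regulates complex $S$ only if it physically interacts with at
least one member in the PPI network; its regulation score $R(S, F)$ is
the mean *untransformed* correlation with those interacting members
(the TF never counts as its own interactor). For matched pairs the
differential regulation is $\Delta R = |R(S,F) - R(T,F)|$, defined only
when both sides are.

The log-linear model
$\Delta C(S,T) = \prod_f \Delta R(S,T,F_f)^{\gamma_f}$ becomes, in
base-10 logs, a linear system solved by SVD least squares
(`solveInfluence()`; singular values below $10^{-10}$ of the largest are
treated as zero, giving the minimum-norm solution on rank-deficient
systems and the exact solution on square full-rank ones, such as the
two-complex demonstration system). Zero or undefined entries cannot be
logged; the `"drop"` policy removes such pairs (mirroring the
"non-zero $\Delta C$ and $\Delta R$" convention) and `"floor"` replaces
them with $10^{-6}$ so a joint solve keeps all pairs. A system with
fewer usable pairs than TFs is refused with counts.

Significance is a permutation test of the package's own construction
(none is prescribed by the source convention): the $\log \Delta C$
vector is permuted across matched pairs — preserving the regulation
design while severing its relation to the response — the system is
re-solved, and $p_f = (1 + \#\{|\gamma^{perm}_f| \ge
|\gamma^{obs}_f|\})/(1+n_{perm})$. Normalized influences divide by the
largest magnitude, so the top TF scores $\pm 1$. Subset solves
(`subsetInfluence()`) restrict to the pairs where every chosen TF has
defined nonzero $\Delta R$ — their shared complexes — which is how
pairs of TFs with opposite roles are compared.

## The synthetic-data generator

`generateExpressionPair()` emulates the statistical structure of a
two-cohort microarray study: two conditions with cohort-sized sample
counts (default 39 + 39, matching a matched normal/tumour design),
modules of genes drawn from a multivariate normal with exchangeable
(compound-symmetry) within-module correlation — one scalar per module
per condition, which maps directly onto the complex-level co-expression
scale — and independent background genes. Exchangeability is a deliberate
simplification: one parameter per module per condition is exactly what
the pipeline estimates, and it keeps positive-definiteness conditions
transparent ($\rho > -1/(m-1)$).

What it does **not** emulate: platform artifacts, batch effects,
heavy-tailed intensity distributions, probe-level noise, or overlapping
complexes. Passing tests therefore demonstrate the pipeline's algebra
and statistical behaviour under a clean generative model, not robustness
to real microarray pathology.

`generateInfluenceSystem()` simulates the influence model directly:
$\Delta R$ log-uniform, $\Delta C = \prod \Delta R^{\gamma} \cdot
10^{\varepsilon}$ with $\varepsilon \sim N(0, \sigma)$. Multiplicative
lognormal noise makes the log-linear model exactly the generating
family, so noiseless recovery must be exact and estimator behaviour
under noise is interpretable.

### The recovery preset

`generateRecoveryStudy()` plants ground truth for *every* stage at once:
eight complexes embedded as cliques (four shifted down, four up between
conditions), three TFs with influence coefficients $(+2, -1, 0)$, and
per-pair $\Delta R$ values drawn log-uniformly in $[0.08, 0.28]$ with
rejection so the implied $\Delta C$ stays in $[0.125, 0.38]$ — the range
a correlation difference can realize above a baseline of $z = 0.25$.

Two design choices matter here:

* **Exact colouring.** Expression is generated so the *sample*
  correlation matrix equals its target exactly (whitening the latent
  draws before colouring; this needs more samples than genes, hence the
  preset's 120 samples per condition). Planting influence coefficients
  through finite-sample correlations is otherwise hopeless at realistic
  scales: the measurement noise of a correlation difference enters the
  log-linear design matrix directly, and a variance analysis shows the
  null TF's estimated coefficient would have a standard deviation of
  several tenths even at thousands of samples — swamping the planted
  $\sigma = 0.02$. Exact colouring separates concerns: the recovery
  property tests the pipeline's clustering, matching, assembly and
  algebra; the cohort-sized, population-sampled presets test estimation
  noise behaviour separately.
* **TF anchors.** Each TF gets three dedicated partner proteins forming
  a stable module (correlation 0.45 in both conditions, so its own
  co-expression change is exactly zero and it can never enter the
  matched set). Without an anchor, a TF hub touching every planted
  clique gets absorbed into one of them by the clustering, perturbing
  that complex's co-expression score; with it, TFs cluster with their
  partners and the planted cliques are recovered verbatim. The TF
  attachment edges carry low reliability (0.15) for the same reason.

The per-TF high-correlation side is balanced across conditions and
across the decrease/increase halves so no condition concentrates a TF's
correlation budget (a unit-variance TF cannot be strongly correlated
with many independent module factors at once; the generator refuses
parameterizations whose summed squared loadings approach 1).

## Numerical choices and degenerate inputs

* Duplicate expression rows collapse by per-cell mean; identifiers are
  uppercased gene symbols throughout, and all files join on that key.
* Duplicate PPI edges merge keeping the maximum score; self-loops are
  dropped at parse time.
* Missing expression values are excluded pairwise from correlations,
  never imputed.
* Complex ids derive from a hash of the sorted member list, so they are
  stable under any input ordering.
* `ksCompare()` evaluates both empirical CDFs on the pooled support, so
  ties are handled exactly; the tests pin it to the reference
  implementation at $10^{-9}$.
* All stochastic functions take explicit seeds and are bitwise
  reproducible under them.

## Problem sizes in the test-suite

The suite generates everything programmatically at run time: studies of
10–100 genes, networks of tens to a few hundred edges, 39–120 samples
per condition, 50-seed Monte Carlo loops for the recovery and RMSE
properties, and 200-replicate permutation/null loops. These sizes were
chosen so each property is measured with enough replication to be
stable, while a full run stays in the tens of seconds.

## Known limitations

* Extraction is a hard partition: overlapping complexes (shared
  subunits) cannot be represented, and a protein belongs to exactly one
  cluster per condition.
* The influence model is linear in log space and attributes changes only
  to TFs that physically interact with complex members; indirect
  regulation is invisible to it, and regulation is correlation-based, so
  it cannot distinguish causation from co-variation.
* The `"drop"` policy can bias the solved system toward complexes every
  TF touches; the `"floor"` policy keeps all pairs but injects an
  arbitrary small constant. Results should be reported per policy, never
  mixed.
* The two matching thresholds ($t_J$, $\delta$) are inherited
  conventions; sensitivity to them is the user's responsibility to
  explore.
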