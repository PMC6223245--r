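---
title: "Graph-regularized NMF for microbe-disease link prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-regularized NMF for microbe-disease link prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnmflink)
```

## The problem

Curated microbe-disease association catalogues record which microbes
have literature support for involvement in which diseases. Such a
catalogue is a sparse bipartite network: an $m \times n$ binary
adjacency matrix $Y$ with $Y_{ij} = 1$ when microbe $i$ and disease $j$
have a known association. The catalogue is radically incomplete -- the
motivating scale is a few hundred known pairs over hundreds of microbes
and tens of diseases -- and the task is link prediction: score every
unknown pair so that true-but-unrecorded associations rank high.

`grnmflink` implements a matrix-factorization approach to this problem.
Because no confirmed *negative* pairs exist, the zeros of $Y$ mix true
negatives with undiscovered positives; the pipeline therefore (i)
derives entity similarities from the network itself, (ii) softens the
zeros with similarity-weighted neighbour profiles before factorizing,
and (iii) constrains the factorization with graph regularizers so that
similar entities receive similar latent representations.

## Model and procedure

### Gaussian interaction profile (GIP) kernel similarity

The interaction profile of microbe $m_i$ is the $i$-th row
$Y(m_i)$ of $Y$; of disease $d_j$, the $j$-th column. The GIP kernel
similarity between microbes is

$$S^m(m_i, m_j) = \exp\left(-\gamma_m \lVert Y(m_i) - Y(m_j)\rVert^2\right),
\qquad
\gamma_m = \gamma'_m \Big/ \frac{1}{m}\sum_{i=1}^m \lVert Y(m_i)\rVert^2,$$

and symmetrically on columns for diseases ($\gamma_d$, $\gamma'_d$).
The bandwidth is normalized by the mean squared profile norm, so the
kernel adapts to the overall density of the network. Entities with
empty profiles contribute $0$ to the normalization sum, per the literal
formula; only a fully zero matrix is rejected. We default
$\gamma'_m = \gamma'_d = 1$, the convention of the kernel-similarity
literature this construction comes from; both are exposed in
`run_config()`.

When an external disease similarity matrix is available (the motivating
use case is a symptom-co-occurrence-based similarity), it is averaged
entrywise with the GIP disease kernel, $S^d = (S^{d'} + \mathrm{SDM})/2$,
after aligning by label. External matrices are cleaned defensively:
clipped to $[0,1]$, symmetrized by transpose-averaging, unit diagonal;
changes beyond $10^{-9}$ raise a warning. Diseases missing from the
external matrix get external similarity 0 (with a warning) rather than
an error, because partial coverage is the common real-world case; a
`strict` flag turns this into an error.

### WKNN profile smoothing

Before factorization, each zero of $Y$ is replaced by an
interaction-likelihood score built from the $K$ nearest *known*
neighbours (entities with at least one association in the original
binary matrix). For entity $q$, with neighbours sorted by descending
similarity,

$$\tilde Y(q) = \frac{1}{Q}\sum_{i=1}^{K} \alpha^{i-1} S(i,q)\, Y(i,\cdot),
\qquad Q = \sum_{i=1}^{K} S(i,q).$$

Note the asymmetry: the weights carry the decay $\alpha^{i-1}$ but the
normalizer $Q$ sums plain similarities. This matches the formulation
this stage follows (and its antecedents) and is implemented literally;
since it makes $\tilde Y$ a *sub*-convex combination of binary
profiles, outputs stay in $[0,1]$. A `normalize_with_decay` flag offers
the fully normalized alternative for comparison.

Choices where the formulation is silent:

* **Defaults $K = 5$, $\alpha = 0.9$.** Small enough that neighbours
  remain genuinely similar at the motivating network scale (tens of
  known entities per axis), a mild decay that still distinguishes the
  first from the fifth neighbour. Both are config-exposed and recorded
  in run metadata.
* **Self-exclusion.** Entity $q$ is never its own neighbour, even when
  it has known associations. Anything else would let a held-out test
  label leak back into its own smoothed profile during cross-validation.
* **Ties** in neighbour selection break lexicographically by label, so
  runs are deterministic.
* **$Q = 0$** (all neighbour similarities zero) yields an all-zero
  profile, not NaN.

The microbe-wise and disease-wise smoothed matrices are combined as
$Y_{md} = (a_1 Y_m + a_2 Y_d)/(a_1 + a_2)$ with $a_1 = a_2 = 1$, and
the adjacency matrix is updated once as
$Y \leftarrow \max(Y, Y_{md})$, so known associations are never
downgraded. No iterative refinement is performed.

### Neighbourhood graphs and Laplacians

The graph regularizers act on sparse graphs derived from the
similarity matrices, combining $p$-nearest-neighbour structure with
clustering information:

$$X_{ij} = \begin{cases}
1 & i \in N(j) \wedge j \in N(i) \wedge \text{$i,j$ share a cluster}\\
0 & i \notin N(j) \wedge j \notin N(i) \wedge \text{no shared cluster}\\
0.5 & \text{otherwise,}
\end{cases}$$

where $N(\cdot)$ is the set of $p$ most-similar other entities. The
masked graph is $S^*_{ij} = X_{ij} S_{ij}$, with degree matrix
$D = \mathrm{diag}(\text{row sums})$ and Laplacian $L = D - S^*$
(symmetric, PSD, zero row sums -- all verified by the test suite via
the quadratic-form identity
$x^\top L x = \tfrac12 \sum_{ij} S^*_{ij}(x_i - x_j)^2$).

The cluster condition is read as *co-membership*: the middle branch
requires that the pair shares no cluster. (Reading it as membership of
one endpoint alone would make the condition asymmetric and
ill-defined; co-membership is the only reading that yields a symmetric
$X$.) The diagonal of $X$ is set to 1 so $S^*$ retains self-similarity;
this does not affect the off-diagonal structure of $L$ because $D$
subtracts the diagonal back out.

Clusters come from a deliberately simplified greedy cohesiveness
algorithm in the ClusterONE family: seeds are unassigned
maximum-degree vertices; a cluster greedily adds the outside vertex
that most increases cohesiveness $w_{in}/(w_{in} + w_{bound})$ until no
addition improves it; grown clusters with weighted density
$2 w_{in}/(|V|(|V|-1)) < 0.5$ are discarded; cluster pairs with Jaccard
overlap $\ge 0.8$ merge; uncovered vertices become singletons. The
published algorithm's penalty term and overlap scoring are intentionally
out of scope -- only the cohesive core needed to instantiate the weight
matrix is required -- and an externally computed cluster file can be
supplied instead (`read_cluster_file()`). The graph neighbourhood size
defaults to $p = 5$, independent of the WKNN $K$; both thresholds are
config-exposed.

### GRNMF: objective and multiplicative updates

The factorization seeks non-negative $W \in \mathbb{R}^{m \times k}$,
$H \in \mathbb{R}^{n \times k}$ with $Y \approx W H^\top$ by minimizing

$$\min_{W, H \ge 0}\;
\lVert Y - W H^\top\rVert_F^2
+ \lambda_l\left(\lVert W\rVert_F^2 + \lVert H\rVert_F^2\right)
+ \lambda_m \operatorname{Tr}(W^\top L_m W)
+ \lambda_d \operatorname{Tr}(H^\top L_d H).$$

The Tikhonov term smooths the factors; the trace terms pull the latent
rows of $W$ (resp. $H$) together along the edges of the masked
similarity graphs. (The pairwise form
$\sum_{i,p} \lVert w_i - w_p\rVert^2 S^{m*}_{ip}$ equals
$2\operatorname{Tr}(W^\top L_m W)$; we take the trace form as *the*
objective, because the update rules below are exactly its
majorization-minimization steps.)

Deriving the KKT stationarity conditions with multipliers for the
non-negativity constraints and turning each into a fixed-point ratio
gives the multiplicative updates

$$w_{ik} \leftarrow w_{ik}
\frac{(Y H + \lambda_m S^{m*} W)_{ik}}
     {(W H^\top H + \lambda_l W + \lambda_m D_m W)_{ik}},
\qquad
h_{jk} \leftarrow h_{jk}
\frac{(Y^\top W + \lambda_d S^{d*} H)_{jk}}
     {(H W^\top W + \lambda_l H + \lambda_d D_d H)_{jk}},$$

applied $W$ first, then $H$ with the updated $W$ (matching the
sequential derivation). The Lagrange multipliers are derivation
intermediates only; they have no runtime representation, and
stationarity is checked through `kkt_residual()` -- the max-norm of
$\min(W, |\nabla_W|)$ and $\min(H, |\nabla_H|)$ -- instead.

Numerical choices:

* **Initialization**: seeded uniform$(0,1)$ draws for both factors; the
  seed is part of `solver_config()` and recorded in run metadata, and
  the session RNG state is left untouched.
* **Denominator floor** `eps = 1e-12` guards the ratio. Flooring the
  denominator (rather than additively smoothing the numerator)
  preserves the zero-locking property: an entry at exactly 0 stays 0.
* **Convergence**: relative objective change
  $|f_t - f_{t-1}| / \max(f_{t-1}, \varepsilon) < \texttt{tol}$,
  default `tol = 1e-6`, `max_iter = 1000`.
* **Defaults** $k = 10$, $\lambda_l = \lambda_m = \lambda_d = 0.01$.
  The method's formulation leaves all of these open ("optimal
  parameters worth studying"); these are conventional middle-ground
  values for networks of the motivating scale, and `grnmf_grid()`
  sweeps alternatives. Multiplicative updates converge linearly, so
  tight stationarity (KKT residual $<10^{-3}$) needs a much smaller
  `tol` (the solver tests use `1e-11` with up to $10^4$ iterations on
  small instances); the production default trades that precision for
  speed, which is appropriate because prediction uses only the ranking
  of $Y^* = W H^\top$.

The matrix entering the factorization is the WKNN-updated $Y$, not the
raw binary one: the preprocessing exists precisely to feed the
factorization a better-conditioned target, and the pipeline stage order
reflects that.

## Evaluation: LOOCV and the AUC engine

`loocv()` holds out each known association in turn, zeroes its cell,
and re-runs the *entire* pipeline on the reduced matrix -- GIP kernels,
similarity integration, WKNN smoothing, graph construction, and the
fit. Anything less re-uses information derived from the held-out label
(the kernels and the smoothed profiles both depend on it) and inflates
the estimate; a `fast_mode` flag provides exactly that optimistic
shortcut (similarities and graphs computed once from the full matrix)
for exploratory runs, clearly so named. A hook (`score_fn`) lets tests
substitute oracle scorers; a leakage test asserts the held-out cell is
zero in every matrix the scorer sees.

The held-out pair's score is ranked (mid-ranks under ties) against the
candidate pairs: all unknown pairs of the original matrix in global
mode, the unknown pairs of the same disease in local mode. Each fold
thus yields a mid-rank $r_f$ among $c_f$ candidates; its individual ROC
curve is a unit step at false-positive rate $(r_f - 1)/c_f$, and the
reported ROC is the average of the per-fold step curves with AUC its
exact integral,
$\mathrm{AUC} = \frac{1}{F}\sum_f (c_f + 1 - r_f)/c_f$. With ties
mid-ranked this is exactly the Mann-Whitney U normalization (the test
suite checks the identity to $10^{-12}$, and against an independent ROC
package on pooled instances); when all folds share one candidate count
-- as in global mode -- it coincides with the pooled threshold sweep.
In local mode, where candidate counts differ by disease, folds are
weighted equally (per-disease normalization first, then pooling).

## The synthetic generator

`generate_fixture()` builds the study conditions every stage is tested
on, emulating a curated catalogue without any download:

* each microbe and disease belongs to one of $r$ latent groups;
  within-group factor loadings are uniform$(0.8, 1.2)$, off-group
  uniform$(0, 0.1)$. Block-structured factors (rather than i.i.d.
  draws) are deliberate: they create the cluster structure the
  graph-construction stage is supposed to detect, so that stage is
  exercised non-trivially;
* the ground-truth score matrix $P = W_0 H_0^\top$ is rescaled to
  $[0,1]$ by its global maximum, keeping threshold semantics simple;
* the binary matrix sets the top `density` fraction of cells of $P$ to
  1, then flips each cell independently with `noise_flip_prob`;
* the disease similarity is the cosine similarity of the rows of $H_0$
  plus Gaussian noise (`sdm_noise_sd`), clipped, symmetrized, unit
  diagonal;
* labels are synthetic (`M0001...`, `D001...`); `duplicate_some()`
  injects redundant records with fresh evidence ids to exercise the
  deduplication path.

The reference condition is $60 \times 25$, $r = 4$, density $0.10$,
flip probability $0.02$, SDM noise sd $0.1$ -- a scaled-down analogue
of the motivating catalogue (hundreds of microbes, tens of diseases,
$\sim$3% fill) that keeps a full leave-one-out sweep of the entire
pipeline at a few minutes on one core. The catalogue-scale shape
($292 \times 39$, 450 pairs, 483 raw records with 33 duplicates) is
generated where the data-handling path itself is under test. What the
generator does *not* emulate: real taxon/disease vocabularies, the
long-tailed degree distributions of literature-curated catalogues
(well-studied diseases accumulate many more associations), and any
biological correlation between the external similarity and disease
semantics beyond the planted factors. Passing tests therefore
demonstrate algorithmic correctness and recoverability of planted
structure, not clinical validity of predictions on real catalogues.

## Degenerate inputs and edge behaviour

* An all-zero adjacency matrix is rejected at the kernel stage
  (bandwidth undefined).
* A fold that leaves a microbe or disease with an empty profile still
  runs: the GIP kernel handles zero profiles, and WKNN simply finds no
  known-neighbour contribution.
* Entities never observed in an association list do not exist in the
  network it defines; rankings are complete over the network's own
  labels.
* `K` or `p` larger than the available neighbour pool are truncated
  with a warning; `rank_k > min(m, n)` is a configuration error.
* Duplicate records collapse silently into the binary matrix, with the
  collapsed count reported.

## Problem sizes used by the shipped checks

The test suite runs the solver checks on 50 random instances up to
$20 \times 10$ with $k \le 4$, the solver-vs-projected-gradient
comparison on ten $8 \times 5$ instances at a 200-iteration budget, and
the full-pipeline leave-one-out recovery on five replicates of the
reference $60 \times 25$ condition with the iteration cap at 300. The
acceptance script reruns the same reference condition (five replicates
for the global AUC, one for local and for a shuffled-association
control) plus the catalogue-scale deduplication path. These sizes are
the package's chosen reference conditions; `fixture_spec()` scales all
of them.

## Known limitations

* Prediction quality degrades for diseases and microbes with very few
  associations; the WKNN stage and the external similarity mitigate but
  do not remove the bias toward well-connected entities.
* Hyperparameters ($k$, the three $\lambda$s, $K$, $\alpha$, $p$) are
  not auto-tuned; `grnmf_grid()` is a helper, not a selection
  procedure.
* The simplified cohesiveness clustering is not a drop-in replacement
  for the published ClusterONE implementation; externally computed
  clusters can be supplied where fidelity matters.
* Multiplicative updates stall near zero entries; if exact stationarity
  matters, tighten `tol` and raise `max_iter`.
* LOOCV with full per-fold recomputation costs one pipeline run per
  known association; use `fast_mode` only for exploration, never for
  reported numbers.
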