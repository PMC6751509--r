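---
title: "Ranking candidate disease-related circRNAs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate disease-related circRNAs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precda)
```

## The problem

Circular RNAs (circRNAs) are covalently closed noncoding RNAs whose
dysregulation is implicated in many human diseases, but curated
circRNA–disease associations are sparse: most circRNAs have one or two
known diseases, and most diseases a handful of known circRNAs. `precda`
ranks *candidate* circRNAs for a target disease by propagating the sparse
curated evidence through a weighted circRNA–disease network that fuses two
complementary similarity channels:

1. **Expression similarity** — circRNAs with correlated expression across
   cell types and tissues are more likely to act in the same processes.
2. **Functional similarity** — circRNAs associated with similar diseases
   are more likely to share function.

A personalised random walk (PersonalRank, a single-target personalised
PageRank) started at the disease node then scores every circRNA by how much
walker mass reaches it.

## Expression similarity

For each expression source the similarity between two circRNAs is the
Spearman rank correlation of their expression profiles across that source's
conditions. We compute it as the Pearson correlation of average-rank
vectors, which coincides with the classical rank-difference form
$\rho = 1 - 6\sum_i d_i^2 / (n(n^2-1))$ whenever no ties occur; expression
matrices contain repeated values (notably zeros), so average ranks make the
result deterministic where the no-ties formula is undefined.

Missing measurements are removed pairwise per circRNA pair. A pair with
fewer than 3 shared non-missing conditions, or a profile with zero rank
variance, has *undefined* similarity — signalled as `NA`, not as 0, so
"no evidence" is never confused with "evidence of no correlation" at the
raw stage.

Two sources (emulating two public expression compendia) are combined by
taking, for every pair, the **maximum** of the two raw correlations, kept
only if it reaches the threshold $\tau$ (default 0.7) and set to 0
otherwise. Sparsifying at $\tau$ removes the many weak, noisy correlations
that would otherwise blanket the network with low-information edges.
Negative correlations can never pass $\tau \in (0, 1]$, so no separate
sign rule is needed, and undefined similarities are indistinguishable from
filtered-out pairs after thresholding — both read as "no expression edge".

Pairs measured in only one source are thresholded on that source's value
alone by default: discarding a measured correlation because the *other*
compendium did not profile the circRNA would throw away evidence. The
strict both-sources-only reading is available via
`combine_expression_similarity(..., both_sources_only = TRUE)`.

## Functional similarity

Each circRNA $c$ is embedded as a vector over $D$, the set of all
circRNA-related diseases in the association database (not the full
ontology — dimensions a walk can never reach add nothing but noise). The
entry for disease $dis$ is

$$\mathrm{Score}(dis, c) = \begin{cases}
1 & dis \in \mathrm{DisSet}(c) \\
\max_{dis_i \in \mathrm{DisSet}(c)} \mathrm{dsim}(dis, dis_i) & \text{otherwise,}
\end{cases}$$

where $\mathrm{DisSet}(c)$ is the set of diseases curated for $c$ and
`dsim` is an externally supplied disease–disease similarity matrix
(symmetric, unit diagonal, entries in $[0,1]$; any ontology-based disease
similarity method can produce it — the matrix is a pluggable input, and
computing it is outside this package's scope). Functional similarity
between two circRNAs is the cosine of their score vectors. Score rows are
nonnegative and always contain a 1, so the cosine is defined and lies in
$[0, 1]$ (clamped against floating-point rounding). No threshold is applied
to functional similarity: sparsification belongs to the noisy expression
channel only.

A circRNA with no curated disease has no score vector; the operations
raise an error rather than invent a default, because such a circRNA is
outside the disease-related set the model is defined on.

## The heterogeneous network

circRNA–circRNA edge weights fuse the two channels:

$$w(i,j) = \begin{cases}
(\mathrm{FnSim}(i,j) + \mathrm{ExSim}(i,j))/2 & \mathrm{ExSim}(i,j) > 0 \\
\mathrm{FnSim}(i,j) & \text{otherwise.}
\end{cases}$$

Every curated circRNA–disease association becomes an edge of weight exactly
1; there are no disease–disease edges (disease similarity influences the
model only through the score vectors) and no self-loops. Zero-weight pairs
produce no edge — under the walk a zero-weight edge is indistinguishable
from no edge. Isolated nodes are retained: they can still be ranked (at
score zero unless they share a component with the target).

## PersonalRank

With transition matrix $P$ (row-normalised) and restart vector $r$ (1 at
the target disease, 0 elsewhere), the walk iterates

$$PR = (1 - d)\, r + d\, P^{\mathsf T} PR,$$

initialised at $PR = r$, with transfer probability $d = 0.85$ by default.
The network is explicitly weighted, so each node's outgoing mass is split
in proportion to incident edge weights; this reduces to the classical
uniform out-degree split on unweighted graphs, and
`personal_rank(..., weighted = FALSE)` restores the literal out-degree
reading. Iteration stops when the largest componentwise change falls below
`tol` (default `1e-10`, well below any score gap that could affect a
ranking) or after `max_iter` (default 1000) iterations — non-convergence is
flagged on the result, not thrown, since a truncated fixed point may still
rank usefully. Since the contraction factor is $d$, the defaults converge
in at most a few hundred iterations on any input.

Scores are not normalised: comparisons happen only within a single
target's ranking, where scale is irrelevant. Candidates are the circRNA
nodes not curated for the target, ordered by score with lexicographic ID
tie-break, so identical inputs always produce bit-identical rankings. The
test suite checks the iterated solution against a dense linear solve of
$(I - d P^{\mathsf T})\,PR = (1-d)\,r$ on random graphs of up to 50 nodes.

## Cross-database validation

Curated databases overlap only partially, which yields a natural hold-out
scheme: build the network from database A, and for every disease present in
both databases treat the circRNAs that are network nodes, lack the
association in A, but carry it in reference database B as held-out
positives. Each test-case disease is scored by the AUC of its candidate
ranking over all its positives jointly, using the rank-sum (Mann–Whitney)
estimator with ties counted 1/2 — the estimator is verified against
brute-force pair enumeration in the tests. The headline summary is the
macro-average (unweighted mean over diseases); a positive-weighted pooled
mean is reported alongside because the two readings of "average AUC"
differ when diseases contribute unequal numbers of positives.

`threshold_sweep()` re-runs the pipeline over a grid of $\tau$ values
(retained-pair counts are non-increasing in $\tau$ by construction), and
`ablation_cosine_only()` forces all expression similarities to zero,
isolating the contribution of the expression channel.

## The synthetic-data generator

Real association databases and expression compendia cannot be bundled, so
`simulate_bundle()` plants the statistical structure the model assumes and
the validation scheme needs:

- **Modules.** Each of `n_modules` modules owns `circ_per_module` circRNAs
  and `dis_per_module` diseases. A circRNA associates with each of its
  module's diseases with probability `assoc_density` (at least one
  association is forced, since the model is defined on circRNAs with
  curated evidence).
- **Expression.** A latent-factor Gaussian model: circRNA $c$ in module $m$
  has $x_{ct} = \sqrt{\rho}\, f_{mt} + \sqrt{1-\rho}\,\sigma\,
  \varepsilon_{ct}$ per condition $t$. Spearman similarity depends only on
  rank structure, so this is the simplest model with a tunable rank
  correlation; the realised within-module correlation is
  $\rho / (\rho + (1-\rho)\sigma^2)$, i.e. exactly
  `within_module_expr_corr` at the default `noise_sd = 1`. Two
  pseudo-sources observe overlapping subsets (60% shared by default),
  exercising the single-source combination branch.
- **Disease similarity** is generated directly as a block matrix
  (`within_module_dsim` inside modules, `between_module_dsim` outside,
  unit diagonal) — the model consumes only the matrix, so simulating an
  ontology behind it would add nothing testable.
- **Hold-out.** A `holdout_fraction` of true associations is moved to the
  reference database only, with one association per circRNA protected so
  every circRNA stays attached to the network.

Three presets define the study conditions used throughout the tests and
the acceptance script, each at 5 modules × 10 circRNAs, 3 diseases per
module and 20 conditions per source (small enough that the full pipeline
runs in well under a second per bundle, large enough for stable AUCs):

- `sim_config_strong()` — the defaults (correlation 0.9, disease-similarity
  block 0.9/0.1, density 0.8, 20% hold-out): held-out associations should
  be clearly recoverable (macro-AUC well above 0.75 over seeds).
- `sim_config_expression_informative()` — weakens the disease-similarity
  contrast to 0.4/0.3 and the density to 0.5 while keeping expression
  correlation at 0.9. Under the strong preset both the full model and the
  cosine-only ablation saturate near the AUC ceiling and their paired
  difference is dominated by seed noise; in this regime the functional
  channel alone is less discriminative, leaving the expression channel
  measurable headroom, and the full model beats the ablation on average
  over paired seeds.
- `sim_config_null()` — uncorrelated expression, a flat disease-similarity
  matrix and uniformly random associations (the `random_assoc` flag exists
  precisely because module-consistent associations alone would still carry
  signal through shared disease sets even with flat similarities): rankings
  are uninformative and AUC centres on 1/2.

What the generator does **not** emulate: read-count noise models, the
heavy-tailed and zero-inflated intensity distributions of real expression
compendia, ontology DAG structure behind the disease similarity, database
curation biases, or identifier noise beyond what the synonym-mapping tests
construct explicitly. Passing tests therefore demonstrate that the
implementation recovers planted structure faithfully — not that the method
attains any particular performance on real databases.

## Numerical and interface choices

- Thresholds and probabilities are validated at entry (`tau` in $(0,1]$,
  `d` in $(0,1)$); violations raise errors rather than silently clamp.
- Undefined Spearman similarities propagate as `NA` through the raw stage
  and become 0 (absent) only at combination, mirroring the filter's intent.
- All file formats are plain TSV with `#` comments; association tables,
  expression matrices, similarity matrices and networks round-trip through
  their readers and writers exactly.
- Disease-name matching against an ontology is case-insensitive *exact*
  matching over names and synonyms — fuzzy matching would invent
  behaviour; ambiguous synonyms (claimed by two terms) and unmappable rows
  are surfaced (error and rejects report respectively), never guessed or
  dropped.
- Pipeline outputs carry a header with the package version, a configuration
  hash and input checksums, so any result file can be traced to its inputs.

## Limitations

- Published performance numbers for this class of method depend on
  specific database snapshots and a specific external disease-similarity
  matrix; they are not reproducible from synthetic data, and the package
  makes no claim about them. The synthetic conditions are analogues, at
  desk scale, of the qualitative claims (recovery well above chance;
  expression adds information when the functional channel does not already
  saturate).
- The walk treats the network as static and undirected; edge weights are
  heuristic fusions of similarities, not calibrated probabilities.
- Diseases enter the candidate pool only as restart targets; the method
  does not rank diseases for a circRNA (the transpose problem).
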