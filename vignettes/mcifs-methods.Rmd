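---
title: "Monte-Carlo and incremental feature selection for paired-tissue cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte-Carlo and incremental feature selection for paired-tissue cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcifs)
```

## The statistical problem

A cohort of patients is profiled in two tissues — tumor and adjacent
non-tumor tissue — and labelled with a binary phenotype such as perineural
invasion. With tens of thousands of probes per tissue and only tens of
patients, any classifier fitted to all features overfits immediately. The
package's strategy is the classic two-stage one: first rank all features by
a score that is cheap per feature but aggregates over many weak models, then
walk down the ranking with a cross-validated classifier to decide how many
top features a final predictor actually needs.

Both tissue blocks enter one combined matrix, one row per patient, because
the adjacent tissue reflects the tumor microenvironment and may carry
discriminative signal of its own; keeping tissue tags on the feature IDs
lets every downstream table report how many selected features came from
each block.

## Monte-Carlo feature selection

`run_mcfs()` draws `s` random subspaces of `m` features, grows `t` binary
classification trees per subspace, and scores feature $g$ as

$$\mathrm{RI}_g=\sum_{\tau=1}^{st}(\mathrm{wAcc}_\tau)^u
\sum_{n_g(\tau)}\mathrm{IG}\!\left(n_g(\tau)\right)
\left(\frac{\mathrm{no.in}\; n_g(\tau)}{\mathrm{no.in}\;\tau}\right)^{v},$$

where the inner sum runs over the nodes of tree $\tau$ that split on $g$,
$\mathrm{IG}$ is the node's information gain in bits, the coverage ratio is
the fraction of the tree's training samples reaching the node, and
$\mathrm{wAcc}$ is the tree's weighted accuracy on its held-out split — the
mean per-class recall

$$\mathrm{wAcc}=\frac{1}{c}\sum_{i=1}^{c}
\frac{n_{ii}}{n_{i1}+n_{i2}+\dots+n_{ic}}.$$

A feature scores highly when it is repeatedly chosen by trees that
generalize, at nodes that are both informative and close to the root. A
feature never used by any node scores exactly zero.

### Tree growing and its parameters

Trees are CART-style with the information-gain criterion, grown without
pruning until nodes are pure or no admissible split leaves `min_leaf = 2`
samples in each child. Deeper trees yield more recorded nodes and hence a
smoother RI distribution; with no pruning the procedure stays
hyperparameter-light. The per-tree train/test split is stratified by class
(`train_fraction = 0.66`): with cohorts of ~50 patients an unstratified
split can lose a class entirely, which would make the held-out weighted
accuracy undefined. If the tiny held-out split still misses a class, that
class is simply dropped from the wAcc average (the average runs over
observed classes), which avoids 0/0 without biasing larger splits.

Defaults are `s = 1000`, `t = 5`, `m = ⌈0.05·d⌉`, `u = v = 1`. The
exponents' neutral value 1 weights trees linearly by generalization and
nodes linearly by coverage; raising `u` sharpens the preference for
generalizing trees, `v = 0` ignores node depth. `s·t` should be large
enough that each feature is expected to appear in many subspaces
(`s·m/d ≈ 50` at the defaults). The desk-scale pipeline configuration in
`run_config()` uses `s = 200` on cohorts of 2000 combined features — an
expected 10 subspace appearances per feature, which is already stable for
rank recovery — and the package's own validation runs use that scale;
production analyses at `d ≈ 50{,}000` should keep `s` in the thousands.

Determinism: all subspace draws and splits derive from one seed, subsets are
processed in a fixed order, and rank ties (notably the shared zeros) are
broken by feature ID in C-locale order, so a rerun reproduces the ranking
byte for byte. Information gain is computed in bits throughout; the base
cancels in rankings but fixing it keeps recorded node statistics
reproducible.

## Incremental feature selection

`ifs_scan()` evaluates the nested top-$k$ sets $F_k$ of the ranking for
$k = 1,\dots,K$ with leave-one-out cross-validation: each patient in turn is
held out, the classifier is fitted on the rest, and accuracy is the fraction
of held-out patients predicted correctly. The default classifier is an RBF
SVM with cost 1 and $\gamma = 1/p$, features standardized per training fold
(centering and scaling estimated on the $n-1$ training samples only) — the
defaults of the standard R SVM implementation. Decision tree, 1-nearest
neighbor and Gaussian naive Bayes are available under the same protocol, and
a majority-class dummy provides the baseline: its LOOCV accuracy equals the
majority prior exactly.

One protocol subtlety is deliberate: the ranking is computed **once on the
full data set** and reused inside every LOOCV fold. This mirrors the
original two-stage workflow, but it means the held-out sample influenced the
feature ranking, so IFS accuracies are optimistically biased estimates of
generalization — they are model-selection scores, not validation-set
accuracies. Any external claim about the final predictor needs an
independent cohort.

`select_key_set()` formalizes the parsimony trade-off: `k_peak` is the
smallest set size attaining the maximum accuracy and `k_final` the smallest
size within `delta` of it. The default `delta = 0.02` equals one
misclassified patient at $n = 50$ and reproduces the canonical choice of a
26-feature set at accuracy 0.94 over a 175-feature set at 0.96.

## The comparator filter bank

Seven classical single-feature rankers are implemented natively so their
behavior is fully specified and testable, each interpreted at the
conventional default settings of the Weka attribute evaluators they
correspond to:

* Entropy-family scores (information gain, gain ratio, symmetrical
  uncertainty) and the Pearson chi-squared statistic operate on a
  bin-by-class contingency table after supervised Fayyad–Irani MDL
  discretization: recursive binary cuts maximizing class information gain,
  accepted only when the gain clears the MDL coding cost
  $(\log_2(n-1) + \log_2(3^k-2) - kH(S) + k_1H(S_1) + k_2H(S_2))/n$. A
  feature whose best cut fails the criterion collapses to a single bin and
  scores zero — undefined ratios ($H(X)=0$) are mapped to 0 rather than NaN
  so every ranking is total.
* Correlation is the absolute Pearson correlation with the 0/1 class coding.
* OneR merges adjacent discretization bins left to right until every bucket
  holds at least `min_bucket = 6` samples (a trailing undersized bucket
  joins its predecessor) and scores the training accuracy of the
  majority-class-per-bucket rule.
* ReliefF uses every sample as an anchor, `k_neighbors = 10` nearest hits
  and misses under Manhattan distance on range-normalized features, and
  neighbor ties broken by sample index. Classes smaller than
  `k_neighbors + 1` get a reduced neighbor count rather than an error.

All seven share the Monte-Carlo tie-break (score descending, then feature
ID), so cross-method rank tables are well defined. `compare_ranks()`
tabulates where each key feature lands in every comparator ranking;
`hypergeom_overlap()` scores top-list agreement as the exact upper-tail
hypergeometric probability of the observed overlap given the feature
universe, computed from log binomial coefficients with a max-shifted sum
(stable for universes far beyond the $5\times10^4$ features of a full
cohort), plus the fold enrichment $x/(ab/N)$. The universe defaults to the
combined feature count: both lists were selected from all features, so that
is the correct background. Only the pairwise test is provided; multi-list
generalizations add nothing for pairwise reporting.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a paired-tissue
microarray study of a 50-patient cohort: 28 phenotype-positive and 22
negative patients, both tissues profiled, log-scale intensities. Log
expression is modeled as Gaussian — per-probe baselines $N(8, 1)$, residual
noise $\sigma = 1$ — which matches the approximate normality of microarray
log2 intensities; the baselines are arbitrary and cancel out of every
rank-based stage. A chosen number of planted probes per tissue receive a
location shift of `effect`·$\sigma$ in positive patients (no variance
effects — the mean-shift structure is exactly what the rankers assume), and
planted probes within a tissue share pairwise correlation `block_rho`
through a latent factor ($x=\sqrt{\rho}\,z_{\mathrm{common}} +
\sqrt{1-\rho}\,z_{\mathrm{private}}$), giving the exact target correlation.
Defaults: `d = 1000` probes per tissue (a deliberate scale-down from the
~25,000 of a real array, keeping validation runs at desk scale), 15 tumor +
11 adjacent planted probes, `effect = 2`, `block_rho = 0.3` — a typical
co-expression correlation for co-regulated probes.

What the generator does **not** emulate: batch effects, missing values,
intensity-dependent variance, heavy-tailed outliers, and the pervasive weak
correlation structure of real transcriptomes. Passing recovery tests on
these cohorts therefore demonstrates that the machinery ranks, selects and
scores correctly under its own model assumptions — not that the biological
findings of any real cohort would be reproduced.

## Behavior under strong signal: parsimony versus recovery

One consequence of the delta rule deserves emphasis. When planted effects
are strong (around two standard deviations per probe), a handful of
top-ranked features already classify a 50-patient cohort almost perfectly,
so the IFS curve saturates by $k \approx 5{-}10$ and `select_key_set()`
correctly returns a very small `k_final`. The selected key set is then a
*minimal predictor*, not an inventory of all discriminative features: its
recall of the full planted set is low by construction, even though the
ranking itself recovers essentially all planted features in its top
$2\times$-truth-size stretch (the package's validation checks recovery
there). With weak, realistically diffuse effects the curve rises slowly, the
delta rule selects tens of features, and key-set recall and parsimony
coincide more closely. When the goal is an inventory rather than a
predictor, read the ranking depth directly instead of the key set.

## Validation scales and determinism

The test suite validates every numerical kernel against an independent
oracle: weighted accuracy against a per-class-recall loop, RI aggregation
against a literal transcription of its defining sum, LOOCV against explicit
fold enumeration for all four classifiers, the hypergeometric tail against
the reference distribution function over the full $N \le 60$ grid at
$10^{-12}$ relative tolerance, entropy scorers against closed-form
contingency arithmetic, and ReliefF against exhaustive neighbor
enumeration. End-to-end recovery runs use cohorts of 1000 probes per tissue
with `s = 200`, `t = 5` over seed grids — sizes chosen so the full suite
stays comfortably inside a coffee break while keeping per-feature subspace
coverage at production density. Every stage derives its seed from the global
one by stage-name hashing, so stages can be rerun independently and a full
pipeline rerun is byte-identical.

## Known limitations

* The IFS accuracies inherit selection bias from reusing the full-data
  ranking inside LOOCV (see above); the package reports them as such.
* The filter implementations follow the conventional defaults of their Weka
  counterparts but do not chase bit-compatibility with Weka.
* Only binary phenotypes are exercised, although weighted accuracy and the
  tree machinery support more classes.
* `run_mcfs()` is single-threaded; at full production scale
  (`d ≈ 5\times10^4`, `s` in the thousands) expect minutes to hours, and
  note the aggregation is defined to be reduction-order-independent so a
  parallel map over subsets is safe if added.
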