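---
title: "The signature-discovery funnel: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The signature-discovery funnel: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigfunnel)
```

# The problem

Given a genes x samples expression matrix and a class label per sample
(for example definite bacterial infection, definite viral infection,
healthy control, and Kawasaki disease in a pediatric blood-transcriptome
study), we want a compact gene signature that discriminates all classes at
once. Genome-scale matrices have tens of thousands of genes and a few
hundred samples, so a single selection step is either too permissive or too
greedy. `sigfunnel` stages the selection as a funnel that narrows the gene
set step by step:

1. **Quantile normalization** makes samples from different array platforms
   comparable.
2. **Boruta all-relevant filtering** discards genes that carry no
   detectable class information.
3. **Monte-Carlo Feature Selection (MCFS)** ranks the survivors by relative
   importance over an ensemble of projection trees.
4. **Incremental Feature Selection (IFS)** sweeps nested top-k prefixes of
   the ranking, scores each by SVM leave-one-out cross-validation (LOOCV),
   and takes the prefix at the accuracy peak as the signature.
5. **Hypergeometric enrichment** interprets the signature against
   user-supplied gene-set collections (GMT format).

Each stage only removes genes, so the funnel is monotone; `run_pipeline()`
chains the stages, writes every intermediate artifact as plain TSV/JSON
with a checksummed manifest, and derives each stage's seed from one root
seed so any stage reproduces standalone.

# Stage models and assumptions

## Quantile normalization

All columns are forced onto one reference distribution, the row-wise mean
of the column-sorted matrix. Each value is replaced by the reference value
at its within-column rank; **ties** receive the mean of the reference
values at the tied positions. Consequences we rely on elsewhere: all
columns share a single value multiset afterwards; within-column order is
preserved (modulo ties); the map is idempotent. An additive platform shift
applied to a subset of samples is removed *between* columns, but the shared
reference itself moves by `shift x batch_fraction`, so the normalized
matrix equals the normalization of the unshifted matrix only up to one
global additive constant. That is the strongest recovery statement that
holds, and it is what the tests assert.

Normalization is applied **jointly to the merged matrix** (after
`intersect_genes()`), not per platform: making batches comparable is the
purpose of the step, and per-platform normalization would leave the
between-platform offset in place. Merging keeps the lexicographically
sorted intersection of gene IDs, for determinism.

## Boruta all-relevant filtering

Each iteration permutes **every input gene** across samples into a fresh
"shadow" copy, fits a random forest (impurity importance, `ranger`) on the
still-undecided real genes plus all shadows, and scores a *hit* for a real
gene whose importance **strictly exceeds the maximum shadow importance**
of that iteration. Cumulative hits are tested against
Binomial(iterations, 1/2), two-sided: a significant excess confirms the
gene, a significant deficit rejects it (and it leaves the real side of the
forest), and the tests are Bonferroni-corrected across the genes still in
play (`correct = FALSE` disables this). Genes undecided after `max_iter`
iterations stay `tentative` and are **excluded** from the confirmed set —
the conservative reading, since downstream stages should only see genes
with positive evidence.

Keeping the *full* shadow ensemble for the whole run — rather than
shadowing only the surviving genes, as some implementations do — is a
deliberate choice. Shadows exist to estimate the importance an irrelevant
gene can reach by chance; if the pool shrinks with the field, the shadow
maximum is eventually taken over a handful of permutations, the bar drops,
and the luckiest chance-correlated noise genes clear it persistently
enough to be confirmed. With the full pool the bar stays "the maximum of
G fresh permutations" at every iteration, so a gene exchangeable with
noise hits with probability well below 1/2 throughout and the filter
confirms essentially nothing on label-independent data, which is exactly
the calibration an all-relevant filter should have.

Defaults `n_estimators = 100`, `max_iter = 100`, `alpha = 0.05` follow the
common reference implementations of the algorithm. "Relevant" still means
relevant *in this finite sample*: a gene whose association with the labels
is strong enough to out-rank every one of G permuted copies, iteration
after iteration, is confirmed whether or not that association would
replicate — the later stages exist to prune such survivors.

## MCFS ranking

For d candidate genes, draw `s` random subsets of `m` genes, grow `t`
entropy-criterion classification trees per subset (s*t trees total), each
trained on a stratified `split_fraction` draw of the samples and scored on
the held-out remainder. A gene's relative importance is

RI(g) = sum over trees tau of wAcc(tau)^u * sum over nodes n_g(tau)
splitting on g of IG(n_g(tau)) * (no. in n_g(tau) / no. in tau)^v

- **wAcc** is defined here as the mean per-class recall (balanced
  accuracy) on the held-out draw. With class sizes as unbalanced as
  75/122/71/311 a plain accuracy would reward majority-class trees; a
  class-weighted accuracy is the only reading under which the weighting
  does anything useful.
- **IG** is the entropy (base-2) information gain of the node's split.
  Trees use entropy splits, unlimited depth, minimum 2 samples to split,
  and deterministic tie-breaks (equal gain keeps the lowest feature index;
  leaf ties take the smallest class index). The tree inducer is compiled
  code (`src/tree.cpp`) because it must expose per-node gain and sample
  counts, which off-the-shelf tree fitters do not report in this form.
- **u = v = 1** by default, the convention of reference MCFS
  implementations; `u = v = 0` reduces RI to a plain sum of information
  gains, which the tests exploit as an oracle check.
- Defaults `m = max(ceiling(0.05 d), 5)`, `s = ceiling(15 d / m)` (each
  gene expected in at least 15 subsets), `t = 5`, `split_fraction = 0.66`.
  Reducing `s` below this degrades rank stability noticeably: with only ~5
  expected appearances per gene, an unlucky planted gene can fall far down
  the list.
- Ranking ties break lexicographically by gene ID, RI = 0 for genes never
  split on, so the ranking is a deterministic function of the seed.

**Top-ranking cutoff.** Published analyses often keep a fixed number of
top genes without stating a rule. `top_ranking_cutoff()` offers a
principled default — re-run the ranking on label-permuted data `n_perm`
times, take a quantile (default 0.95) of the permutation *maximum* RI as
the null threshold, and keep the leading run of genes above it — plus a
`fixed_k` override for exact replication of a published list length. On
pure noise the observed maximum RI is drawn from the same distribution as
the permutation maxima, so the cutoff concentrates near 0 by construction.

## IFS signature selection

For each k on the sweep grid, the top-k genes feed an SVM evaluated by
LOOCV; `select_signature()` takes the smallest k attaining the maximum
accuracy (parsimony tie-break). Choices the method literature leaves open:

- **Linear kernel, cost 1.0, one-vs-rest** multiclass. At p >> n a linear
  machine is the robust default; one-vs-rest is assembled from binary
  `e1071` machines via decision-value argmax because the library's native
  multiclass scheme is one-vs-one.
- **Per-fold standardization.** Genes are z-scored using the training
  fold's mean/SD and the held-out sample is transformed with those same
  parameters, so no information leaks from the left-out sample. A gene
  constant within a fold is centered only.
- Display rounding of accuracies is 3 decimals; computations keep full
  precision.

A class with a single sample is rejected (its LOOCV fold would have no
same-class training example).

## Enrichment

One-sided (upper-tail) hypergeometric over-representation of the signature
against each set of a collection, with Benjamini-Hochberg FDR within the
collection. The universe defaults to all genes that entered the filter
stage, the standard over-representation background; set members outside
the universe are excluded from the set size so the 2x2 margins stay
consistent. Collections that should be corrected separately (e.g. KEGG vs
each GO namespace) are passed in separate calls.

# The synthetic-data generator

`generate_dataset()` emulates the study design the funnel targets: a
4-class cohort with unequal class sizes (default 75/122/71/311), a small
set of planted class-discriminating genes inside a large irrelevant
background, two-platform additive batch structure, and Gaussian
measurement noise.

- Background model: each gene draws a baseline intensity from N(7, 1.5) —
  a log-intensity scale typical of expression arrays — and every
  measurement adds i.i.d. N(0, `noise_sd`) noise. This is the simplest
  model with the structure the funnel assumes.
- Each planted gene designates one **elevated class**, cycling over the
  classes so every class owns discriminating genes; its mean rises by
  `effect_size x noise_sd` in that class.
- Batch assignment is drawn **within each class** (crossed with class), so
  platform never proxies for class and normalization remains testable.
- One root seed determines everything; stages of the pipeline derive their
  own seeds by hashing the stage name (`derive_seed()`).

What the generator does **not** emulate: probe-level artifacts,
missingness, gene-gene correlation, heavy-tailed or sample-level variance
structure, or platform-specific probe sets beyond a shared-gene scenario.
Passing tests on this generator therefore demonstrate that the machinery
is correct and calibrated, not that real cohorts will reach any particular
accuracy.

# What the checks compute, and one known tension

The package's acceptance-level checks run at these problem sizes, chosen
to exercise study-scale behavior while staying desk-runnable: null
calibration on 20 noise datasets of 500 genes x 120 samples
(`alpha = 0.01`), with the permutation cutoff checked at a reduced
ensemble (`s = 60`, `t = 2`, 10 permutations — the cutoff property does
not depend on ensemble size); signal recovery on three replicates of 2,000
genes x 160 samples with 20 planted genes at effect size 3; and oracle
equivalence of RI, the hypergeometric tail (exhaustive up to universe size
30) and BH-FDR against brute-force reimplementations.

One tension is worth stating plainly. Under the signal-recovery
conditions, the filter recovers all planted genes and the ranking places
them at the very top, but LOOCV accuracy reaches exactly 1.0 (160/160)
once roughly two planted genes per class have entered the prefix — around
k = 8–10 — and the parsimony tie-break then stops there. The selected
signature is pure signal (every selected gene is planted) but contains
only about half of the planted set. Whenever classes are perfectly
separable, *any* peak-accuracy criterion with a smallest-k tie-break
truncates an all-relevant signature to a minimal-optimal one; recovering
the full planted set would require either a harder dataset (weaker
effects, correlated noise) or a different tie-break (largest k at the
peak), which would in turn inflate signatures on real, non-separable data.
We keep the parsimony rule and document the truncation rather than tune
the generator around it.

# Limitations

- Boruta confirmation probabilities depend on forest size; very small
  `n_estimators` makes importance estimates noisy and decisions slow.
- The MCFS permutation cutoff re-runs the full ranking `n_perm` times;
  for large d prefer modest `n_perm` (10–20) or the `fixed_k` override.
- LOOCV cost grows as n^2 in the number of samples times the sweep length;
  `step` trades resolution for time on long rankings.
- The enrichment stage tests over-representation only; it does not model
  directionality, gene length, or expression-level bias.
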