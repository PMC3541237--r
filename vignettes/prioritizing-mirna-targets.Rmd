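---
title: "Prioritizing candidate miRNA targets with functional genomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate miRNA targets with functional genomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtarrank)
```

## The problem

Sequence-based miRNA target predictors (seed matching, duplex
thermodynamics) emit candidate lists with false-positive rates on the
order of 70%. Genes that are genuinely regulated by the same miRNA,
however, tend to form functional modules: they share specific Gene
Ontology (GO) annotations and sit close together in protein–protein
interaction (PPI) networks. `mirtarrank` turns that coherence into a
re-ranking of a predictor's candidate list, using a miRNA's
experimentally validated targets as the reference group. The method
therefore applies only to miRNAs that already have validated targets; it
re-orders existing candidates and never proposes new ones.

## The model

For a candidate gene $c$ and the validated target group
$G = \{g_1, \dots, g_k\}$, two scores are computed.

**Functional similarity.** Each term $t$ of one GO namespace carries an
information content $IC(t) = -\log\!\big(n(t)/N\big)$, where $n(t)$ is
the number of genes annotated to $t$ *after* propagating annotations up
the ontology (true-path rule) and $N$ is the size of the annotation
corpus. The Resnik similarity of two genes is the IC of the most
informative common ancestor of their term sets,
$FS(g_1, g_2) = \max_{t \in A(g_1) \cap A(g_2)} IC(t)$,
where $A(g)$ is the ancestor-closed annotation set — after propagation,
the intersection of the two sets *is* the common-ancestor set. The
candidate's first score is the average over the group,
$AFS(c, G) = \tfrac{1}{k}\sum_i FS(c, g_i)$.

**Network closeness.** On the cleaned PPI graph (self-loops removed,
reciprocal duplicate rows collapsed; all edges weight 1) the closeness
of two gene products is the reciprocal shortest-path distance,
$NC(g_1, g_2) = 1 / DIS(g_1, g_2)$: 1 for interacting pairs, 0.5 for
distance two. The second score is the group average
$ANC(c, G) = \tfrac{1}{k}\sum_i NC(c, g_i)$. On a unit-weight graph
Dijkstra's algorithm reduces to breadth-first search, which is what
runs underneath.

**Rank fusion.** Scores from different sources live on incomparable
scales, so only their *ranks* are fused. Within each source, candidates
get mid-ranks (ties share the average of tied positions) and rank
ratios $r = \text{rank} / n_\text{ranked} \in (0, 1]$. The fused
statistic is the joint uniform order-statistic probability
$$Q(r_1, \dots, r_S) = P\big(U_{(1)} \le r_{(1)}, \dots,
U_{(S)} \le r_{(S)}\big),$$
computed by the standard $O(S^2)$ recursion ($Q = S!\,V_S$ with
$V_k = \sum_{i=1}^{k} (-1)^{i-1} V_{k-i}\, r_{(S-k+1)}^{\,i} / i!$ on
ascending ratios). $Q$ satisfies $Q(r) = r$, $Q(r,\dots,r) = r^S$, is
permutation-invariant and monotone in every ratio; smaller $Q$ means
consistently high ranks across sources. The final list is ascending in
$Q$ with lexicographic gene-id tie-breaks, so output is reproducible.

## Conventions and parameters

* **Log base for IC** (`log_base`, default natural log). The base is a
  monotone rescaling of all IC values, so every rank — and therefore the
  final list — is invariant to it; it only changes the printed scores.
* **Corpus size `N`** defaults to the number of annotated genes in the
  active namespace, which keeps $n(t)/N \le 1$ and $IC(\text{root}) = 0$
  on propagated counts. A fixed genome-wide `N` can be supplied when
  scores must be comparable across namespaces.
* **Propagated counts.** $n(t)$ is always taken on ancestor-closed
  annotation sets; on direct counts the most-informative-common-ancestor
  similarity is ill-defined (an ancestor could be rarer than its child).
* **Edges and evidence.** Only `is_a` ontology edges are used; GAF rows
  with a `NOT` qualifier are always dropped; all evidence codes are kept
  unless an exclusion list is given.
* **Disconnected pairs** score $NC = 0$, the limit of $1/DIS$; the
  convention is included in group averages. Distances are computed on
  the full cleaned graph, not a largest-component restriction.
* **Missing data** is a signal, not a zero. A gene with no annotation
  (or absent from the network) gets `NA` from that source, and the
  fusion policy decides: `"worst"` (default) substitutes rank ratio 1.0,
  `"available"` fuses over present sources only, `"drop"` refuses to
  fuse incomplete candidates. A candidate missing in *every* source goes
  to the bottom, flagged. The `"worst"` default is deliberately
  conservative: lack of annotation is not treated as evidence of
  targeting.
* **Self-exclusion.** A candidate that is itself a validated target is
  scored against the group minus itself, both for AFS and ANC, so known
  targets can sit in candidate lists without self-similarity inflation.

## Evaluation machinery

`loocv()` holds out each validated target of each miRNA in turn, removes
it from the training group, mixes it with 99 decoys drawn from the gene
universe (annotated genes plus network nodes by default; never from the
miRNA's own validated targets) and records its rank among the 100.
miRNAs with a single validated target cannot be evaluated this way and
are skipped and counted. All held-out positions are pooled into one ROC
sweep over rank cutoffs; the AUC reduces, for a single position $p$ in a
list of $n$, to $(n - p)/(n - 1)$ — 1 when every test gene ranks first,
0.5 for random placement. Positions may be fractional (mid-ranks from
ties). The per-run enrichment-fold score is $ES = (n/2)/\text{rank}$:
50 at the top of a 100-gene list, 1 in the middle, 0.5 at the bottom.

`random_group_analysis()` compares the mean pairwise FS (or NC) of
observed gene groups against 1000 random same-size groups per observed
group, reporting the fold change of means and a Mann–Whitney U test of
observed versus random group means (two-sided by default, since a
direction should be a finding rather than an assumption; a one-sided
option exists).

## What the synthetic generator emulates — and what it does not

`make_study()` builds a self-contained study: a rooted single-namespace
ontology (levels grow geometrically with depth; some terms get two
parents so common-ancestor logic is exercised beyond trees), background
annotations (each gene draws $1 + \text{Poisson}(2)$ random non-root
terms), a planted-partition PPI network, and a set of miRNAs whose
validated targets share a distinct deep leaf term and a home network
community. The signal is planted *imperfectly* on purpose: each target
carries the shared-term annotation, and joins its home community, with
probability `coverage = 0.8`, chosen a priori to mirror the fraction of
validated targets that real interactomes typically cover (roughly
75–80%). That makes the two sources individually informative but fallible,
which is exactly the regime where rank fusion should — and in the
package's cross-validation does — beat either source alone.

The default scale uses a 150-term ontology, 600 genes, 10 miRNAs with 5
validated targets each and a 12-block network with within/between edge
probabilities 0.4/0.01; these sizes keep a full leave-one-out experiment
(hundreds of 100-gene prioritizations) comfortably interactive while
leaving enough decoy diversity for stable AUCs. What the generator does
*not* emulate: the real GO's scale and shape (tens of thousands of
terms, heavy multi-parenting, namespace cross-links), scale-free PPI
degree distributions, annotation bias toward well-studied genes, and
literature-driven correlations between annotation and interaction
evidence. Green tests on fixtures therefore demonstrate that the
machinery is correct and recovers planted signal of a realistic
magnitude — not that any particular AUC will be attained on a given
real corpus.

Every stochastic routine takes an explicit integer seed, and
regeneration of a bundle from the same seed is byte-identical. The
bundle's component generators derive their internal seeds from the
user's seed through a Lehmer (minstd) step so that their RNG streams
cannot collide with streams a user later opens with nearby seeds — with
naive `seed + k` derivation, a "random" control drawn with an adjacent
seed can silently replay the draws that planted the signal.

## Numerical and degenerate-input choices

* Floating-point guard: $Q$ is clipped to $[0, 1]$ after the recursion.
* Ties everywhere use mid-ranks; the final ordering breaks remaining
  ties lexicographically on gene id.
* Empty intersections of propagated sets (possible only across
  namespaces) score $FS = 0$; a pair sharing only the root also scores 0
  because $IC(\text{root}) = 0$.
* A validated group that is empty after self-exclusion, an all-missing
  score vector, a network with no edges after cleaning, and an ontology
  with an `is_a` cycle each raise an informative error rather than a
  silent default.
* ROC false-positive rates at cutoff $c$ count $c - \mathbb{1}[p \le c]$
  of the $n - 1$ decoys at or above the cutoff; with fractional
  positions this is the mid-rank approximation.

## Known limitations

The method presupposes validated targets: cold-start miRNAs cannot be
ranked. Identifier matching is exact string equality (an optional
mapping table is supported); no fuzzy symbol resolution is attempted.
Only Resnik similarity is implemented — Lin, Jiang–Conrath or Wang
variants are out of scope, as are confidence-weighted networks and
diffusion-based closeness. The evaluation reports pooled ROC curves;
per-miRNA curves can be derived from the returned position table if
needed.
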