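# mirtarrank

Re-ranks a miRNA's candidate target genes — typically the long,
false-positive-heavy output of sequence-based predictors — by their
functional coherence with that miRNA's experimentally validated
targets.

Two signals are scored per candidate `c` against the validated group
`G = {g1, …, gk}`:

* **AFS**, average Resnik functional similarity over Gene Ontology
  annotations: `FS(g, h)` is the information content
  `IC(t) = −log(n(t)/N)` of the most informative common ancestor of the
  two genes' (ancestor-propagated) term sets, and
  `AFS(c, G) = mean_i FS(c, gi)`.
* **ANC**, average network closeness on a protein–protein interaction
  graph: `NC(g, h) = 1 / DIS(g, h)` with `DIS` the unweighted
  shortest-path distance, and `ANC(c, G) = mean_i NC(c, gi)`.

Candidates are ranked within each source (mid-ranks for ties, rank
ratios `r = rank/n`), and the per-source ratios are fused with the
uniform order-statistic
`Q(r1,…,rS) = P(U(1) ≤ r(1), …, U(S) ≤ r(S))` — smaller `Q` means
consistently high ranks across sources. The final list is ascending in
`Q`. Leave-one-out cross-validation against 99 random decoys, ROC/AUC,
enrichment-fold scores (`ES = (n/2)/rank`), random-group control
analyses, and a fully synthetic study-fixture generator are included.

## Worked example

Everything below is generated by the package itself — no downloads:

```r
library(mirtarrank)

d  <- file.path(tempdir(), "demo")
make_study(d, seed = 42, scale = "small")   # synthetic study bundle
st <- load_study(d)
st$dag
#> <ontology_dag> 80 terms, 96 is_a edges, namespace: biological_process, root(s): T:0001
st$net
#> <ppi_graph> 250 nodes, 2456 edges (removed: 0 self-loops, 0 duplicate/reciprocal rows)

ts     <- st$target_sets[["miR-01"]]        # 5 validated targets, 50 candidates
ranked <- prioritize(ts, st$ann, st$dag, st$net)
head(as.data.frame(ranked)[, c("gene_id", "afs_score", "afs_ratio",
                               "anc_score", "anc_ratio", "q_value",
                               "final_rank")], 5)
#>   gene_id afs_score afs_ratio anc_score anc_ratio q_value final_rank
#> 1   G0068      2.13      0.04     0.800      0.08  0.0048          1
#> 2   G0236      1.65      0.16     0.600      0.15  0.0255          2
#> 3   G0224      1.19      0.48     0.900      0.03  0.0279          3
#> 4   G0086      1.51      0.22     0.800      0.08  0.0288          4
#> 5   G0137      2.47      0.02     0.333      0.94  0.0372          5
```

`G0068` ranks first because it is both functionally similar (AFS 2.13,
4th percentile of the list) and network-close (ANC 0.8, 8th percentile)
to the validated group; fusing the two rank ratios gives
`Q = 0.0048`. The one known target hidden in this candidate list,
`G0095`, comes out 8th of 50 — top 16% — despite the generator's
deliberately incomplete (80%) annotation/interactome coverage.

Cross-validation of the whole study:

```r
res <- loocv(st$pairs, st$ann, st$dag, st$net, n_decoys = 99,
             seed = 42, universe = st$universe)
res
#> <loocv_result> 30 held-out runs (list size 100), AUC = 0.933 [afs 0.853, anc 0.819],
#>   0 single-target miRNA(s) skipped
mean(res$es)   # mean enrichment-fold score of held-out targets
#> [1] 25.7
```

The fused AUC (0.933) beats either source alone (0.853 / 0.819) — the
point of the rank fusion. An AUC of 1 would mean every held-out target
ranked first among its 100; 0.5 is random placement.

A thin command-line wrapper over the same functions ships in
`inst/scripts/mirtarrank` (subcommands `prioritize`, `batch`,
`evaluate`, `make-fixture`; see `?mtr_cli`).

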