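#' Leave-one-out cross-validation of the prioritization pipeline
#'
#' For each miRNA with at least two validated targets, each target in
#' turn is held out, removed from the training (validated) set, and mixed
#' with `n_decoys` genes drawn without replacement from the gene universe
#' (excluding that miRNA's validated targets). The pipeline ranks the
#' resulting list and the held-out target's rank position is recorded —
#' for the fused ranking and for each single source alone (mid-ranks of
#' the source's rank ratio, missing sources placed at ratio 1). miRNAs
#' with a single validated target cannot be evaluated this way and are
#' skipped and counted.
#'
#' @param target_sets List of [target_set()] objects (their `candidates`
#'   are ignored here) or a data frame with columns `mirna`, `gene` of
#'   validated pairs.
#' @param ann,dag,net,config See [prioritize()].
#' @param n_decoys Number of random decoy genes per run (default 99, so
#'   each ranked list has 100 genes).
#' @param n_repeats Number of independent decoy redraws per held-out
#'   target; repeats are pooled, which stabilizes AUC estimates on small
#'   fixtures.
#' @param seed Integer seed; identical seeds give identical position
#'   vectors.
#' @param universe Character vector of genes decoys are drawn from.
#'   Defaults to the union of annotated genes and network nodes.
#' @return An `loocv_result` list: `positions` (data frame with `mirna`,
#'   `gene`, `rep`, `pos_fused`, `pos_afs`, `pos_anc`), `list_size`,
#'   `auc` (fused), `auc_by_source`, `roc` (fused curve), `es` (per-run
#'   enrichment-fold scores), `n_skipped_mirnas`, and a config echo.
#' @export
loocv <- function(target_sets, ann = NULL, dag = NULL, net = NULL,
                  n_decoys = 99L, n_repeats = 1L, seed = 1L,
                  universe = NULL, config = prioritize_config()) {
  if (is.data.frame(target_sets)) {
    df <- read_two_col(target_sets, c("mirna", "gene"))
    target_sets <- lapply(split(df$gene, df$mirna), function(v)
      list(validated = unique(v)))
    for (m in names(target_sets)) target_sets[[m]]$mirna_id <- m
  }
  if (is.null(universe)) {
    universe <- sort(unique(c(names(ann$propagated),
                              if (!is.null(net)) net$nodes)))
  } else {
    universe <- sort(unique(universe))
  }
  list_size <- n_decoys + 1L

  use_go <- isTRUE(config$use_ontology) && !is.null(ann)
  use_net <- isTRUE(config$use_network) && !is.null(net)

  set.seed(as.integer(seed))
  rows <- list()
  n_skipped <- 0L
  for (ts in target_sets) {
    valid <- unique(ts$validated)
    if (length(valid) < 2L) {              # single-target miRNAs: skipped
      n_skipped <- n_skipped + 1L
      next
    }
    pool <- setdiff(universe, valid)
    if (length(pool) < n_decoys) {
      stop("gene universe too small to draw ", n_decoys,
           " decoys for ", ts$mirna_id)
    }
    for (held in valid) {
      train <- setdiff(valid, held)
      for (rep_i in seq_len(n_repeats)) {
        decoys <- sample(pool, n_decoys)
        cands <- c(held, decoys)
        ranked <- prioritize(target_set(ts$mirna_id, train, cands),
                             ann = ann, dag = dag, net = net, config = config)
        i <- match(held, ranked$gene_id)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = ts$mirna_id, gene = held, rep = rep_i,
          pos_fused = ranked$final_rank[i],
          pos_afs = if (use_go) source_position(ranked$afs_ratio, i)
                    else NA_real_,
          pos_anc = if (use_net) source_position(ranked$anc_ratio, i)
                    else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no miRNA with >= 2 validated targets to evaluate")
  positions <- do.call(rbind, rows)

  fused <- roc_auc(positions$pos_fused, list_size)
  by_source <- c(
    afs = if (use_go) roc_auc(positions$pos_afs, list_size)$auc else NA_real_,
    anc = if (use_net) roc_auc(positions$pos_anc, list_size)$auc else NA_real_
  )
  structure(list(
    positions = positions,
    list_size = list_size,
    auc = fused$auc,
    auc_by_source = by_source,
    roc = fused$roc,
    es = enrichment_score(positions$pos_fused, list_size),
    n_skipped_mirnas = n_skipped,
    config = c(config, list(n_decoys = n_decoys, n_repeats = n_repeats,
                            seed = as.integer(seed)))
  ), class = "loocv_result")
}

# Position of candidate i when ranking by a single source's rank ratio
# alone; unscored candidates are put at the worst ratio (1) before
# mid-ranking, mirroring the "worst" fusion policy.
source_position <- function(ratio, i) {
  r <- ifelse(is.na(ratio), 1, ratio)
  rank(r, ties.method = "average")[i]
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("<loocv_result> ", nrow(x$positions), " held-out runs (list size ",
      x$list_size, "), AUC = ", sprintf("%.3f", x$auc),
      " [afs ", sprintf("%.3f", x$auc_by_source[["afs"]]),
      ", anc ", sprintf("%.3f", x$auc_by_source[["anc"]]), "], ",
      x$n_skipped_mirnas, " single-target miRNA(s) skipped\n", sep = "")
  invisible(x)
}

#' ROC curve and AUC from held-out rank positions
#'
#' Pools all held-out positions into one sweep over rank cutoffs `c = 0,
#' 1, ..., list_size`. Sensitivity at `c` is the fraction of test genes
#' ranked at or above the cutoff; the false-positive rate is the fraction
#' of the `list_size - 1` decoys ranked at or above it. The area under
#' the curve is computed by the trapezoid rule; for a single position `p`
#' it reduces to `(list_size - p) / (list_size - 1)`, so 1 means every
#' test gene ranked first and 0.5 matches random placement. Mid-ranks
#' from ties (fractional positions) are accepted.
#'
#' @param positions Numeric vector of rank positions in `[1, list_size]`.
#' @param list_size Length of each ranked list (held-out + decoys).
#' @return A list with `roc` (data frame `cutoff`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(positions, list_size) {
  positions <- as.numeric(positions)
  if (!length(positions)) stop("no rank positions supplied")
  if (any(is.na(positions)) || any(positions < 1 | positions > list_size)) {
    stop("positions must lie within [1, list_size]")
  }
  cutoffs <- 0:list_size
  tpr <- vapply(cutoffs, function(cc) mean(positions <= cc), numeric(1))
  fpr <- vapply(cutoffs, function(cc)
    mean((cc - (positions <= cc)) / (list_size - 1)), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(cutoff = cutoffs, fpr = fpr, tpr = tpr), auc = auc)
}

#' Enrichment-fold score of a rank position
#'
#' `ES = (n / 2) / rank` for a ranked list of `n` genes: 50 for the top
#' of a 100-gene list, 0.5 for the bottom, and 1 exactly at the middle.
#' Strictly decreasing in rank and linear in `n`; fractional mid-ranks
#' are accepted.
#'
#' @param rank Rank position(s), each in `[1, n]`.
#' @param n Length of the ranked list.
#' @return Positive numeric vector of enrichment-fold scores.
#' @examples
#' enrichment_score(1, 100)    # 50
#' enrichment_score(100, 100)  # 0.5
#' enrichment_score(50, 100)   # 1
#' @export
enrichment_score <- function(rank, n) {
  rank <- as.numeric(rank)
  if (any(is.na(rank)) || any(rank < 1 | rank > n)) {
    stop("rank must lie within [1, n]")
  }
  (n / 2) / rank
}

#' Random-group control analysis of group coherence
#'
#' For each observed gene group (e.g. the validated targets of one
#' miRNA), computes the mean pairwise score — functional similarity
#' (`scorer = "FS"`) or network closeness (`scorer = "NC"`) — and
#' compares the observed per-group means against the means of `n_rand`
#' random same-size groups drawn from the gene universe: fold change of
#' means and a Mann-Whitney U test (two-sided by default) of observed
#' vs random group means.
#'
#' @param groups Named list of character vectors (one gene group each).
#' @param universe Character vector to draw random groups from.
#' @param n_rand Number of random groups per observed group (default
#'   1000).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @param scorer `"FS"` (requires `ann`) or `"NC"` (requires `net`).
#' @param ann,dag,net Data sources for the chosen scorer.
#' @param alternative Passed to [stats::wilcox.test()]; `"two.sided"`
#'   default, `"greater"` for a one-sided coherence test.
#' @return A list with `observed` (data frame `group`, `n_genes`,
#'   `mean_score`; groups with < 2 scoreable genes are dropped and listed
#'   in `skipped`), `random_means`, `fold_change`
#'   (mean observed / mean random), `p_value`, and `skipped`.
#' @export
random_group_analysis <- function(groups, universe, n_rand = 1000L, seed = 1L,
                                  scorer = c("FS", "NC"),
                                  ann = NULL, dag = NULL, net = NULL,
                                  alternative = "two.sided") {
  scorer <- match.arg(scorer)
  if (scorer == "FS") {
    assert_propagated(ann)
    score_group <- function(genes) {
      tryCatch(group_pairwise_fs(genes, ann, dag)$mean,
               error = function(e) NA_real_)
    }
  } else {
    stopifnot(inherits(net, "ppi_graph"))
    score_group <- function(genes) {
      tryCatch(group_pairwise_nc(genes, net)$mean,
               error = function(e) NA_real_)
    }
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  universe <- sort(unique(universe))

  obs <- vapply(groups, score_group, numeric(1))
  keep <- !is.na(obs)
  skipped <- names(groups)[!keep]

  set.seed(as.integer(seed))
  rand_means <- list()
  for (g in names(groups)[keep]) {
    k <- length(unique(groups[[g]]))
    m <- vapply(seq_len(n_rand), function(i) {
      score_group(sample(universe, k))
    }, numeric(1))
    rand_means[[g]] <- m[!is.na(m)]
  }
  random_means <- unlist(rand_means, use.names = FALSE)
  if (!sum(keep) || !length(random_means)) {
    stop("no group with >= 2 scoreable genes")
  }

  p <- stats::wilcox.test(obs[keep], random_means,
                          alternative = alternative, exact = FALSE)$p.value
  list(
    observed = data.frame(group = names(groups)[keep],
                          n_genes = vapply(groups[keep], function(x)
                            length(unique(x)), integer(1)),
                          mean_score = unname(obs[keep]),
                          stringsAsFactors = FALSE),
    random_means = random_means,
    fold_change = mean(obs[keep]) / mean(random_means),
    p_value = p,
    skipped = skipped
  )
}
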