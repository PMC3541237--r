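#' Rank scores and compute rank ratios
#'
#' Assigns ranks over the non-missing scores of one data source (rank 1 =
#' best; ties share the mid-rank, i.e. the average of the tied positions)
#' and rank ratios `r = rank / n_ranked`, so `r` lies in `(0, 1]`.
#' Missing scores are flagged, not ranked.
#'
#' @param scores Named numeric vector; `NA` marks a gene the source could
#'   not score (e.g. unannotated gene, node absent from the network).
#' @param higher_better Logical; if `TRUE` (default) larger scores get
#'   smaller (better) ranks.
#' @return A data frame with columns `gene`, `score`, `rank`, `ratio`
#'   (`NA` rank/ratio for missing scores) in the input gene order.
#' @export
rank_scores <- function(scores, higher_better = TRUE) {
  if (is.null(names(scores))) stop("scores must be a named vector")
  n_ranked <- sum(!is.na(scores))
  if (n_ranked == 0L) stop("all scores are missing; nothing to rank")
  x <- if (higher_better) -scores else scores
  rk <- rank(x, ties.method = "average", na.last = "keep")
  data.frame(gene = names(scores), score = unname(scores),
             rank = unname(rk), ratio = unname(rk) / n_ranked,
             stringsAsFactors = FALSE)
}

#' Order-statistic Q value for a vector of rank ratios
#'
#' Combines rank ratios from up to 10 data sources into one number: the
#' probability that `N` independent Uniform(0,1) order statistics all fall
#' below the sorted observed ratios,
#' `Q = P(U_(1) <= r_(1), ..., U_(N) <= r_(N))`,
#' computed with the O(N^2) recursion `Q = N! * V_N`,
#' `V_k = sum_{i=1..k} (-1)^(i-1) V_{k-i} r_(N-k+1)^i / i!` (ratios sorted
#' ascending, `V_0 = 1`), as used in uniform-order-statistic rank fusion.
#' Smaller Q means the candidate ranks consistently high across sources.
#' Identities: `Q(r) = r` for a single source and `Q(r, ..., r) = r^N`.
#'
#' @param ratios Numeric vector of rank ratios, each in `(0, 1]`,
#'   length 1 to 10. Order is irrelevant.
#' @return A single number in `[0, 1]`, nondecreasing in every ratio.
#' @examples
#' q_statistic(0.3)           # 0.3
#' q_statistic(c(0.2, 0.5))   # 2*r1*r2 - r1^2 = 0.16
#' @export
q_statistic <- function(ratios) {
  ratios <- as.numeric(ratios)
  n <- length(ratios)
  if (n < 1L || n > 10L) stop("between 1 and 10 rank ratios are required")
  if (any(is.na(ratios)) || any(ratios <= 0) || any(ratios > 1)) {
    stop("rank ratios must lie in (0, 1]")
  }
  r <- sort(ratios)
  v <- numeric(n + 1L)
  v[1L] <- 1                               # V_0
  for (k in seq_len(n)) {
    i <- seq_len(k)
    v[k + 1L] <- sum((-1)^(i - 1L) * v[k - i + 1L] *
                       r[n - k + 1L]^i / factorial(i))
  }
  q <- factorial(n) * v[n + 1L]
  min(max(q, 0), 1)                        # guard fp round-off at the edges
}

#' Fuse per-source rank ratios into a single ranking
#'
#' Computes a Q value per candidate from its available rank ratios under a
#' missing-data policy, then assigns the final rank by ascending Q
#' (smaller Q = stronger candidate). Ties in Q are broken
#' lexicographically on the gene identifier so output is reproducible.
#' Candidates missing in every source cannot be fused: they are placed at
#' the bottom of the list (in lexicographic order) and flagged.
#'
#' @param ratios Data frame or matrix of rank ratios (rows = candidates,
#'   one column per source, `NA` = source could not score the gene), with
#'   row names or a `gene` column giving identifiers.
#' @param policy Missing-source policy: `"worst"` (default) substitutes
#'   ratio 1.0 — the bottom of the list — for a missing source;
#'   `"available"` computes Q over the present sources only; `"drop"`
#'   refuses to fuse candidates with any missing source (they join the
#'   flagged bottom block).
#' @return A data frame with columns `gene`, `q_value`, `final_rank`,
#'   `flags` (comma-separated names of missing sources, `""` if none),
#'   ordered by `final_rank`.
#' @export
fuse_ranks <- function(ratios, policy = c("worst", "available", "drop")) {
  policy <- match.arg(policy)
  if (is.data.frame(ratios) && "gene" %in% names(ratios)) {
    genes <- as.character(ratios$gene)
    rmat <- as.matrix(ratios[setdiff(names(ratios), "gene")])
  } else {
    rmat <- as.matrix(ratios)
    genes <- rownames(rmat)
  }
  if (is.null(genes)) stop("candidate identifiers are required")
  if (is.null(colnames(rmat))) {
    colnames(rmat) <- paste0("source", seq_len(ncol(rmat)))
  }
  storage.mode(rmat) <- "double"

  q <- rep(NA_real_, nrow(rmat))
  flags <- character(nrow(rmat))
  for (i in seq_len(nrow(rmat))) {
    r <- rmat[i, ]
    miss <- is.na(r)
    flags[i] <- paste(colnames(rmat)[miss], collapse = ",")
    if (all(miss)) next                    # unfusable: stays NA, bottom
    q[i] <- switch(policy,
      worst = q_statistic(ifelse(miss, 1, r)),
      available = q_statistic(r[!miss]),
      drop = if (any(miss)) NA_real_ else q_statistic(r)
    )
  }

  ord <- order(is.na(q), q, genes)
  out <- data.frame(gene = genes, q_value = q, flags = flags,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("gene", "q_value", "final_rank", "flags")]
}
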