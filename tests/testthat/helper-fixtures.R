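# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

# ---- tiny hand-written OBO files -------------------------------------------

write_obo <- function(stanzas, header = c("format-version: 1.2", "")) {
  path <- tempfile(fileext = ".obo")
  writeLines(c(header, stanzas), path)
  path
}

# leaf is_a mid is_a root, one namespace
chain_obo <- function() {
  write_obo(c(
    "[Term]", "id: T:root", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: T:mid", "name: mid",
    "namespace: biological_process", "is_a: T:root ! root", "",
    "[Term]", "id: T:leaf", "name: leaf",
    "namespace: biological_process", "is_a: T:mid ! mid"
  ))
}

write_tsv_ann <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

write_edges <- function(a, b) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(a, b, sep = "\t"), path)
  path
}

# ---- brute-force ontology oracles ------------------------------------------

# ancestor closure of a term set (including the terms themselves) by naive
# repeated parent expansion over an explicit parent map
brute_closure <- function(terms, parents) {
  out <- unique(terms)
  repeat {
    nxt <- unique(c(out, unlist(parents[out], use.names = FALSE)))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}

# n(t) for every term by scanning all genes' closed annotation sets
brute_counts <- function(direct, parents, terms) {
  closed <- lapply(direct, brute_closure, parents = parents)
  sapply(stats::setNames(terms, terms), function(t)
    sum(vapply(closed, function(s) t %in% s, logical(1))))
}

# max-IC common ancestor similarity by explicit enumeration
brute_fs <- function(g1, g2, direct, parents, terms) {
  c1 <- brute_closure(direct[[g1]], parents)
  c2 <- brute_closure(direct[[g2]], parents)
  common <- intersect(c1, c2)
  if (!length(common)) return(0)
  cnt <- brute_counts(direct, parents, terms)
  N <- length(direct)
  max(-log(cnt[common] / N))
}

# ---- brute-force all-pairs shortest paths (Floyd-Warshall) -----------------

brute_distances <- function(nodes, edges_a, edges_b) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  ia <- match(edges_a, nodes); ib <- match(edges_b, nodes)
  for (k in seq_along(ia)) {
    D[ia[k], ib[k]] <- 1
    D[ib[k], ia[k]] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# ---- Monte-Carlo oracle for the order-statistic Q --------------------------

# vectorized row sort for up to 4 columns (sorting networks)
row_sort <- function(m) {
  swap <- function(m, i, j) {
    lo <- pmin(m[, i], m[, j]); hi <- pmax(m[, i], m[, j])
    m[, i] <- lo; m[, j] <- hi; m
  }
  nets <- list(NULL,
               list(c(1, 2)),
               list(c(1, 2), c(2, 3), c(1, 2)),
               list(c(1, 2), c(3, 4), c(1, 3), c(2, 4), c(2, 3)))
  for (p in nets[[ncol(m)]]) m <- swap(m, p[1L], p[2L])
  m
}

# empirical P(U_(1) <= r_(1), ..., U_(N) <= r_(N)) from n_draws uniform
# N-vectors
mc_q <- function(ratios, n_draws = 1e5) {
  n <- length(ratios)
  rs <- sort(ratios)
  m <- matrix(stats::runif(n_draws * n), ncol = n)
  if (n > 1L) m <- row_sort(m)
  ok <- rep(TRUE, n_draws)
  for (j in seq_len(n)) ok <- ok & (m[, j] <= rs[j])
  mean(ok)
}
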