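#' Generate a synthetic single-namespace ontology
#'
#' Builds a rooted is_a DAG with `n_terms` terms: one root, a guaranteed
#' chain down to `max_depth` (so every level is populated), remaining
#' terms assigned to levels with probability proportional to
#' `branching^level` (deeper levels are larger, as in a branching
#' hierarchy), and each term's parent(s) drawn from the level above. A
#' fraction of terms receive a second parent so that common-ancestor
#' logic is exercised beyond trees; at least one multi-parent term is
#' guaranteed. The result is written as a standard OBO file.
#'
#' @param n_terms Total number of terms (>= 3).
#' @param max_depth Depth of the deepest level below the root.
#' @param branching Level-size growth factor.
#' @param prob_multi Probability that a term gets a second parent.
#' @param seed Integer seed; regeneration is byte-identical.
#' @param path Output OBO path (default: a file in `tempdir()`).
#' @param namespace Namespace string written into each stanza.
#' @return A manifest list: `path`, `seed`, `namespace`, `terms`, `level`
#'   (named integer, assigned depth), `parents` (named list), `n_edges`,
#'   `leaves` (terms with no children), `multi_parent` (terms with >= 2
#'   parents).
#' @export
make_ontology <- function(n_terms = 50L, max_depth = 5L, branching = 3,
                          prob_multi = 0.2, seed = 1L,
                          path = tempfile(fileext = ".obo"),
                          namespace = "biological_process") {
  stopifnot(n_terms >= max_depth + 1L, max_depth >= 2L)
  set.seed(as.integer(seed))
  ids <- sprintf("T:%04d", seq_len(n_terms))
  level <- integer(n_terms)
  level[1L] <- 0L
  level[2:(max_depth + 1L)] <- seq_len(max_depth)      # backbone chain
  n_rest <- n_terms - max_depth - 1L
  if (n_rest > 0L) {
    level[(max_depth + 2L):n_terms] <-
      sample(seq_len(max_depth), n_rest, replace = TRUE,
             prob = branching^seq_len(max_depth))
  }

  parents <- vector("list", n_terms)
  names(parents) <- ids
  parents[[1L]] <- character(0)
  for (i in 2:n_terms) {
    cand <- ids[level == level[i] - 1L]
    p <- cand[sample.int(length(cand), 1L)]
    if (length(cand) >= 2L && stats::runif(1) < prob_multi) {
      rest <- setdiff(cand, p)
      p <- c(p, rest[sample.int(length(rest), 1L)])
    }
    parents[[i]] <- p
  }
  n_par <- vapply(parents, length, integer(1))
  if (!any(n_par >= 2L)) {           # guarantee at least one multi-parent term
    ok <- which(level >= 1L &
                  vapply(seq_len(n_terms), function(i)
                    sum(level == level[i] - 1L) >= 2L, logical(1)))
    if (length(ok)) {                # impossible for pure chains
      i <- ok[length(ok)]
      cand <- setdiff(ids[level == level[i] - 1L], parents[[i]])
      parents[[i]] <- c(parents[[i]], cand[sample.int(length(cand), 1L)])
    }
  }

  has_child <- unique(unlist(parents, use.names = FALSE))
  lines <- c("format-version: 1.2",
             paste0("default-namespace: ", namespace), "")
  for (i in seq_len(n_terms)) {
    lines <- c(lines, "[Term]",
               paste0("id: ", ids[i]),
               paste0("name: synthetic term ", i),
               paste0("namespace: ", namespace),
               paste0("is_a: ", parents[[i]],
                      " ! synthetic")[seq_along(parents[[i]])],
               "")
  }
  writeLines(lines, path)

  list(path = path, seed = as.integer(seed), namespace = namespace,
       terms = ids, level = stats::setNames(level, ids), parents = parents,
       n_edges = sum(vapply(parents, length, integer(1))),
       leaves = setdiff(ids, has_child),
       multi_parent = ids[vapply(parents, length, integer(1)) >= 2L])
}

#' Generate a synthetic annotation table with planted coherence
#'
#' Every gene receives `1 + Poisson(background_mean)` direct annotations
#' to random non-root terms. On top of that background, each planted
#' miRNA's target genes are directly annotated to that miRNA's shared
#' "deep" term(s) with probability `coverage` per target — emulating
#' validated target groups that map to a common specific term, with
#' realistic incomplete annotation coverage. Output is a two-column
#' gene/term TSV.
#'
#' @param dag_manifest Manifest from [make_ontology()] (or an
#'   `ontology_dag`; only term ids and the root are used).
#' @param genes Character vector of gene identifiers, or a single integer
#'   (number of genes, named `G0001`, ...).
#' @param planted Named list (one entry per miRNA):
#'   `list(targets = <genes>, shared_terms = <term ids>)`.
#' @param background_mean Mean of the Poisson background annotation count
#'   (each gene gets at least one term).
#' @param coverage Probability that a planted target actually carries a
#'   shared-term annotation.
#' @param seed Integer seed.
#' @param path Output TSV path.
#' @return A manifest list: `path`, `seed`, `genes`, `direct` (named list
#'   of the emitted direct annotations), `planted_hits` (per miRNA, the
#'   targets that received the shared term).
#' @export
make_annotations <- function(dag_manifest, genes, planted = list(),
                             background_mean = 2, coverage = 0.8,
                             seed = 1L, path = tempfile(fileext = ".tsv")) {
  terms <- dag_manifest$terms
  root <- if (!is.null(dag_manifest$roots)) dag_manifest$roots else
    names(dag_manifest$level)[dag_manifest$level == 0L]
  pool <- setdiff(terms, root)
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- sprintf("G%04d", seq_len(genes))
  }
  set.seed(as.integer(seed))
  direct <- lapply(stats::setNames(genes, genes), function(g) {
    k <- 1L + stats::rpois(1L, background_mean)
    sort(pool[sample.int(length(pool), min(k, length(pool)))])
  })
  planted_hits <- list()
  for (m in names(planted)) {
    hits <- character(0)
    for (g in planted[[m]]$targets) {
      got <- planted[[m]]$shared_terms[
        stats::runif(length(planted[[m]]$shared_terms)) < coverage]
      if (length(got)) {
        direct[[g]] <- sort(unique(c(direct[[g]], got)))
        hits <- c(hits, g)
      }
    }
    planted_hits[[m]] <- hits
  }
  df <- data.frame(
    gene = rep(names(direct), vapply(direct, length, integer(1))),
    term = unlist(direct, use.names = FALSE), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(path = path, seed = as.integer(seed), genes = genes,
       direct = direct, planted_hits = planted_hits)
}

#' Generate a planted-partition interaction network
#'
#' Assigns every gene to one of `n_communities` blocks and draws each
#' within-block edge with probability `p_in` and each between-block edge
#' with probability `p_out` (`p_in >> p_out` plants closeness signal).
#' Each planted miRNA is given a home community and each of its targets
#' joins it with probability `coverage` (otherwise a random community),
#' emulating validated target groups that cluster in the network with
#' imperfect interactome coverage. Output is a two-column edge TSV.
#'
#' @param genes Character vector of node identifiers.
#' @param n_communities Number of blocks.
#' @param p_in,p_out Within-/between-block edge probabilities.
#' @param planted Named list miRNA -> character vector of target genes.
#' @param coverage Probability a planted target lands in its miRNA's home
#'   community.
#' @param seed Integer seed.
#' @param path Output edge-list TSV path.
#' @return A manifest list: `path`, `seed`, `membership` (named integer),
#'   `home_community` (named, per planted miRNA), `in_home` (per miRNA,
#'   targets placed in the home community), `n_edges`.
#' @export
make_network <- function(genes, n_communities = 8L, p_in = 0.4, p_out = 0.01,
                         planted = list(), coverage = 0.8, seed = 1L,
                         path = tempfile(fileext = ".tsv")) {
  n <- length(genes)
  set.seed(as.integer(seed))
  membership <- stats::setNames(
    sample.int(n_communities, n, replace = TRUE), genes)
  home <- stats::setNames(integer(0), character(0))
  in_home <- list()
  ms <- names(planted)
  for (i in seq_along(ms)) {
    m <- ms[i]
    home[m] <- ((i - 1L) %% n_communities) + 1L
    placed <- character(0)
    for (g in planted[[m]]) {
      if (stats::runif(1) < coverage) {
        membership[g] <- home[m]
        placed <- c(placed, g)
      } else {
        membership[g] <- sample.int(n_communities, 1L)
      }
    }
    in_home[[m]] <- placed
  }

  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- membership[idx[, 1L]] == membership[idx[, 2L]]
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(nrow(idx)) < p
  df <- data.frame(a = genes[idx[keep, 1L]], b = genes[idx[keep, 2L]],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(path = path, seed = as.integer(seed), membership = membership,
       home_community = home, in_home = in_home, n_edges = nrow(df))
}

# Derive decorrelated sub-seeds for the bundle's component generators from
# the user-facing seed (Lehmer/minstd step). Keeps the generators' RNG
# streams separated from streams a caller may later open with nearby seeds.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483647)
}

study_scales <- function(scale) {
  switch(scale,
    tiny = list(n_terms = 30L, max_depth = 4L, branching = 3, n_genes = 80L,
                n_mirnas = 3L, targets_per = 4L, n_communities = 5L,
                p_in = 0.7, p_out = 0.03, background_mean = 2, coverage = 0.8,
                n_candidates = 20L),
    small = list(n_terms = 80L, max_depth = 5L, branching = 3, n_genes = 250L,
                 n_mirnas = 6L, targets_per = 5L, n_communities = 8L,
                 p_in = 0.5, p_out = 0.02, background_mean = 2, coverage = 0.8,
                 n_candidates = 50L),
    default = list(n_terms = 150L, max_depth = 6L, branching = 3,
                   n_genes = 600L, n_mirnas = 10L, targets_per = 5L,
                   n_communities = 12L, p_in = 0.4, p_out = 0.01,
                   background_mean = 2, coverage = 0.8, n_candidates = 50L),
    stop("unknown scale: ", scale)
  )
}

#' Generate a complete synthetic study bundle
#'
#' One call emits everything the pipeline consumes — ontology (OBO),
#' gene annotations (TSV), interaction network (edge TSV), validated
#' miRNA-target pairs (TSV), demonstration candidate lists (TSV: each
#' miRNA gets one known target mixed among random non-target genes) — plus
#' a JSON manifest recording every planted choice. Each miRNA's validated
#' targets share a distinct deep (leaf) ontology term and a home network
#' community, so functional-similarity and closeness signal are both
#' planted and independently verifiable from the emitted files.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer seed; regeneration from the same seed and scale is
#'   byte-identical.
#' @param scale `"tiny"` (smoke tests), `"small"`, or `"default"` (study
#'   conditions: 150-term ontology, 600 genes, 10 miRNAs with 5 validated
#'   targets each, 12-block network).
#' @param overrides Named list overriding single scale parameters (used
#'   to dial effect sizes, e.g. `coverage` or `p_in`, in calibration
#'   experiments).
#' @return The manifest list (also written to `manifest.json`): paths,
#'   scale parameters, per-miRNA planted targets / shared term / home
#'   community, and the sub-manifests of the three generators.
#' @export
make_study <- function(dir = tempfile("study"), seed = 1L,
                       scale = c("default", "small", "tiny"),
                       overrides = list()) {
  scale <- match.arg(scale)
  p <- utils::modifyList(study_scales(scale), overrides)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  ont <- make_ontology(p$n_terms, p$max_depth, p$branching,
                       seed = seed, path = file.path(dir, "ontology.obo"))
  genes <- sprintf("G%04d", seq_len(p$n_genes))

  # each miRNA: disjoint target block + its own deep leaf term
  deep <- ont$leaves[ont$level[ont$leaves] == max(ont$level[ont$leaves])]
  set.seed(derive_seed(seed, 1L))
  if (length(deep) < p$n_mirnas) {
    deep <- ont$leaves                     # fall back to any leaf
  }
  shared <- deep[sample.int(length(deep), p$n_mirnas)]
  target_pool <- sample(genes, p$n_mirnas * p$targets_per)
  mirnas <- sprintf("miR-%02d", seq_len(p$n_mirnas))
  planted_ann <- list()
  planted_net <- list()
  for (i in seq_len(p$n_mirnas)) {
    tg <- target_pool[((i - 1L) * p$targets_per + 1L):(i * p$targets_per)]
    planted_ann[[mirnas[i]]] <- list(targets = tg, shared_terms = shared[i])
    planted_net[[mirnas[i]]] <- tg
  }

  ann <- make_annotations(ont, genes, planted_ann,
                          background_mean = p$background_mean,
                          coverage = p$coverage, seed = derive_seed(seed, 2L),
                          path = file.path(dir, "annotations.tsv"))
  net <- make_network(genes, p$n_communities, p$p_in, p$p_out,
                      planted_net, coverage = p$coverage,
                      seed = derive_seed(seed, 3L),
                      path = file.path(dir, "ppi.tsv"))

  pairs <- data.frame(
    mirna = rep(mirnas, each = p$targets_per),
    gene = target_pool, stringsAsFactors = FALSE)
  utils::write.table(pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  set.seed(derive_seed(seed, 4L))
  cand_rows <- list()
  for (i in seq_len(p$n_mirnas)) {
    m <- mirnas[i]
    non_targets <- setdiff(genes, target_pool)
    decoys <- sample(non_targets, p$n_candidates - 1L)
    cand_rows[[m]] <- data.frame(
      mirna = m, gene = c(planted_net[[m]][1L], decoys),
      stringsAsFactors = FALSE)
  }
  cands <- do.call(rbind, cand_rows)
  utils::write.table(cands, file.path(dir, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  manifest <- list(
    seed = seed, scale = scale, params = p, dir = dir,
    files = list(obo = ont$path, annotations = ann$path, ppi = net$path,
                 pairs = file.path(dir, "pairs.tsv"),
                 candidates = file.path(dir, "candidates.tsv")),
    mirnas = mirnas,
    planted = lapply(stats::setNames(seq_len(p$n_mirnas), mirnas), function(i)
      list(targets = planted_net[[mirnas[i]]], shared_term = shared[i],
           home_community = unname(net$home_community[mirnas[i]]))),
    ontology = ont[c("seed", "n_edges", "leaves", "multi_parent")],
    ontology_level = as.list(ont$level),
    annotations = ann[c("seed", "planted_hits")],
    network = list(seed = net$seed, n_edges = net$n_edges,
                   in_home = net$in_home,
                   membership = as.list(net$membership))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a study bundle emitted by [make_study()]
#'
#' @param dir Bundle directory.
#' @param namespace Passed to [load_obo()].
#' @return A list with `dag`, `ann` (propagated), `net`, `pairs`,
#'   `candidates`, `target_sets` (one [target_set()] per miRNA),
#'   `universe` (annotated genes plus network nodes), and the parsed
#'   `manifest`.
#' @export
load_study <- function(dir, namespace = "BP") {
  dag <- load_obo(file.path(dir, "ontology.obo"), namespace)
  ann <- propagate_annotations(
    load_annotations(file.path(dir, "annotations.tsv"), dag), dag)
  net <- load_network(file.path(dir, "ppi.tsv"))
  pairs <- read_two_col(file.path(dir, "pairs.tsv"), c("mirna", "gene"))
  cands <- read_two_col(file.path(dir, "candidates.tsv"), c("mirna", "gene"))
  tsets <- lapply(split(pairs$gene, pairs$mirna), identity)
  tsets <- lapply(names(tsets), function(m)
    target_set(m, tsets[[m]], cands$gene[cands$mirna == m]))
  names(tsets) <- vapply(tsets, `[[`, character(1), "mirna_id")
  list(dag = dag, ann = ann, net = net, pairs = pairs, candidates = cands,
       target_sets = tsets,
       universe = sort(unique(c(names(ann$propagated), net$nodes))),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
}

#' Randomize validated-target labels (null fixture)
#'
#' Replaces each miRNA's validated target set with a random same-size
#' draw from the gene universe, destroying any planted coherence while
#' preserving group sizes — the null condition for calibration of the
#' evaluation machinery.
#'
#' @param pairs Data frame with columns `mirna`, `gene`.
#' @param universe Character vector to draw replacement genes from.
#' @param seed Integer seed.
#' @return A data frame of the same shape with shuffled target labels.
#' @export
shuffle_target_labels <- function(pairs, universe, seed = 1L) {
  pairs <- read_two_col(pairs, c("mirna", "gene"))
  set.seed(as.integer(seed))
  out <- lapply(split(pairs$gene, pairs$mirna), function(v)
    sample(universe, length(unique(v))))
  data.frame(
    mirna = rep(names(out), vapply(out, length, integer(1))),
    gene = unlist(out, use.names = FALSE),
    stringsAsFactors = FALSE)
}
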