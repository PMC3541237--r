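#' @importFrom stats setNames
NULL

GO_NAMESPACES <- c(
  BP = "biological_process",
  MF = "molecular_function",
  CC = "cellular_component"
)

#' Parse an OBO ontology into a single-namespace is_a DAG
#'
#' Reads an OBO 1.2/1.4 file and returns the directed acyclic graph of
#' `is_a` relationships restricted to one Gene Ontology namespace.
#' Obsolete terms are dropped and `alt_id`s are recorded so that
#' annotations using a secondary identifier resolve to the canonical term.
#' Only `is_a` edges are used; other relationship types (e.g. `part_of`)
#' are ignored.
#'
#' @param path Path to an OBO file.
#' @param namespace One of `"BP"`, `"MF"`, `"CC"`, or a full namespace
#'   string such as `"biological_process"`. Terms whose stanza carries no
#'   `namespace:` line are assigned the file's `default-namespace`, if any.
#' @return An object of class `ontology_dag` with components
#'   `terms` (character), `parents` (named list, direct `is_a` parents),
#'   `ancestors` (named list, full ancestor closure excluding the term
#'   itself), `depth` (named integer, shortest hop count from a root),
#'   `roots` (terms with no parent), `namespace`, and `alt_id`
#'   (named character, alternative id -> canonical id).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: T:1", "name: root", "namespace: biological_process", "",
#'   "[Term]", "id: T:2", "name: mid", "namespace: biological_process",
#'   "is_a: T:1 ! root", "",
#'   "[Term]", "id: T:3", "name: leaf", "namespace: biological_process",
#'   "is_a: T:2 ! mid"
#' ), obo)
#' dag <- load_obo(obo, "BP")
#' dag$ancestors[["T:3"]]
#' @export
load_obo <- function(path, namespace = "BP") {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  ns <- if (namespace %in% names(GO_NAMESPACES)) GO_NAMESPACES[[namespace]] else namespace
  lines <- readLines(path, warn = FALSE)

  default_ns <- NA_character_
  header_end <- match("[Term]", lines, nomatch = length(lines) + 1L) - 1L
  if (header_end >= 1L) {
    dn <- grep("^default-namespace:", lines[seq_len(header_end)], value = TRUE)
    if (length(dn)) default_ns <- trimws(sub("^default-namespace:", "", dn[1L]))
  }

  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanza found in ", path)
  # any stanza header ([Term], [Typedef], ...) or EOF closes the block
  block_bounds <- c(grep("^\\[.*\\]$", lines), length(lines) + 1L)

  ids <- character(0)
  names_ <- character(0)
  nss <- character(0)
  obsolete <- logical(0)
  parent_of <- list()
  alt_pairs <- list()

  for (s in starts) {
    e <- block_bounds[block_bounds > s][1L] - 1L
    block <- lines[s:e]
    id_line <- grep("^id:", block, value = TRUE)
    if (!length(id_line)) {
      stop("malformed [Term] stanza starting at line ", s, ": missing id")
    }
    id <- trimws(sub("^id:", "", id_line[1L]))
    if (!nzchar(id)) {
      stop("malformed [Term] stanza starting at line ", s, ": empty id")
    }
    nm <- grep("^name:", block, value = TRUE)
    nsl <- grep("^namespace:", block, value = TRUE)
    obs <- any(grepl("^is_obsolete:\\s*true", block))
    isa <- sub("\\s*!.*$", "", sub("^is_a:", "", grep("^is_a:", block, value = TRUE)))
    alt <- trimws(sub("^alt_id:", "", grep("^alt_id:", block, value = TRUE)))

    ids <- c(ids, id)
    names_ <- c(names_, if (length(nm)) trimws(sub("^name:", "", nm[1L])) else id)
    nss <- c(nss, if (length(nsl)) trimws(sub("^namespace:", "", nsl[1L])) else default_ns)
    obsolete <- c(obsolete, obs)
    parent_of[[id]] <- trimws(isa)
    if (length(alt)) alt_pairs[[id]] <- alt
  }

  keep <- !obsolete & (is.na(nss) | nss == ns)
  # if the file carries namespaces at all, unknown-namespace terms are dropped
  if (all(is.na(nss))) keep <- !obsolete
  terms <- ids[keep]
  if (!length(terms)) stop("namespace '", ns, "' has no terms in ", path)
  term_names <- setNames(names_[keep], terms)

  parents <- lapply(setNames(terms, terms), function(t) {
    p <- parent_of[[t]]
    p[p %in% terms]
  })

  alt_id <- character(0)
  for (id in names(alt_pairs)) {
    if (id %in% terms) {
      alt_id[alt_pairs[[id]]] <- id
    }
  }

  dag <- build_dag(terms, parents, ns, alt_id = alt_id, term_names = term_names)
  dag
}

# Assemble an ontology_dag from a parent map; checks acyclicity and computes
# the ancestor closure and depths via a topological order.
build_dag <- function(terms, parents, namespace,
                      alt_id = character(0), term_names = NULL) {
  n <- length(terms)
  idx <- setNames(seq_len(n), terms)

  # Kahn's algorithm on child -> parent edges (processed parents-first)
  n_unmet <- vapply(parents, length, integer(1))
  children <- vector("list", n)
  for (t in terms) {
    for (p in parents[[t]]) {
      pi <- idx[[p]]
      children[[pi]] <- c(children[[pi]], t)
    }
  }
  queue <- terms[n_unmet == 0L]
  topo <- character(0)
  unmet <- n_unmet
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, t)
    for (ch in children[[idx[[t]]]]) {
      unmet[[ch]] <- unmet[[ch]] - 1L
      if (unmet[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != n) {
    stop("cycle detected among is_a relationships: ontology is not a DAG")
  }

  ancestors <- vector("list", n)
  names(ancestors) <- terms
  depth <- setNames(rep(NA_integer_, n), terms)
  for (t in topo) {
    ps <- parents[[t]]
    if (!length(ps)) {
      ancestors[[t]] <- character(0)
      depth[[t]] <- 0L
    } else {
      ancestors[[t]] <- unique(c(ps, unlist(ancestors[ps], use.names = FALSE)))
      depth[[t]] <- min(depth[ps]) + 1L
    }
  }

  structure(list(
    terms = terms,
    parents = parents,
    ancestors = ancestors,
    depth = depth,
    roots = terms[vapply(parents, length, integer(1)) == 0L],
    namespace = namespace,
    alt_id = alt_id,
    term_names = term_names
  ), class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, integer(1)))
  cat("<ontology_dag> ", length(x$terms), " terms, ", n_edges,
      " is_a edges, namespace: ", x$namespace,
      ", root(s): ", paste(x$roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load gene-to-term annotations
#'
#' Reads either a GAF 2.x association file or a plain two-column TSV
#' (gene identifier, term identifier). Rows naming terms absent from the
#' DAG are skipped (a count is kept); GAF rows carrying a `NOT` qualifier
#' are always excluded; `alt_id`s are mapped to canonical term ids.
#' Identifiers are opaque, case-sensitive strings.
#'
#' @param path Path to a GAF or 2-column TSV file.
#' @param dag An [load_obo()] `ontology_dag`; only its terms are retained.
#' @param exclude_evidence Optional character vector of GAF evidence codes
#'   (column 7) to drop, e.g. `"IEA"`. All codes are kept by default.
#' @return An `annotation_table` with components `direct` (named list
#'   gene -> character vector of term ids), `propagated` (`NULL` until
#'   [propagate_annotations()] is called), `n_term`, `corpus_size`, and
#'   `namespace`. The number of skipped rows is in attribute `"n_skipped"`.
#' @export
load_annotations <- function(path, dag, exclude_evidence = character(0)) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) stop("no usable annotation rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1L]])

  if (ncol1 >= 15L) {                       # GAF 2.x
    gene <- vapply(fields, `[[`, character(1), 3L)
    qualifier <- vapply(fields, `[[`, character(1), 4L)
    term <- vapply(fields, `[[`, character(1), 5L)
    evidence <- vapply(fields, `[[`, character(1), 7L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
    if (length(exclude_evidence)) keep <- keep & !(evidence %in% exclude_evidence)
    gene <- gene[keep]; term <- term[keep]
  } else if (ncol1 >= 2L) {                 # plain gene<TAB>term
    gene <- vapply(fields, `[[`, character(1), 1L)
    term <- vapply(fields, `[[`, character(1), 2L)
  } else {
    stop("annotation file must be GAF 2.x or a 2-column TSV: ", path)
  }

  # secondary ids -> canonical
  is_alt <- term %in% names(dag$alt_id)
  term[is_alt] <- dag$alt_id[term[is_alt]]

  known <- term %in% dag$terms
  n_skipped <- sum(!known)
  gene <- gene[known]; term <- term[known]
  if (!length(gene)) stop("no annotation rows match terms of the loaded ontology")

  direct <- lapply(split(term, gene), function(v) sort(unique(v)))
  direct <- direct[order(names(direct))]

  structure(list(
    direct = direct,
    propagated = NULL,
    n_term = NULL,
    corpus_size = NULL,
    namespace = dag$namespace
  ), class = "annotation_table", n_skipped = n_skipped)
}

#' Build an annotation table directly from a gene/term data frame
#'
#' Programmatic equivalent of [load_annotations()] for in-memory data.
#'
#' @param df Data frame with columns `gene` and `term`.
#' @param dag An `ontology_dag`; rows naming unknown terms are skipped.
#' @return An `annotation_table` (unpropagated).
#' @export
annotations_from_frame <- function(df, dag) {
  stopifnot(all(c("gene", "term") %in% names(df)))
  known <- df$term %in% dag$terms
  direct <- lapply(split(df$term[known], df$gene[known]),
                   function(v) sort(unique(v)))
  direct <- direct[order(names(direct))]
  if (!length(direct)) stop("no annotation rows match terms of the loaded ontology")
  structure(list(direct = direct, propagated = NULL, n_term = NULL,
                 corpus_size = NULL, namespace = dag$namespace),
            class = "annotation_table", n_skipped = sum(!known))
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Extends each gene's direct term set with all ancestors of those terms,
#' then recomputes per-term gene counts `n(t)` and the corpus size `N` on
#' the propagated sets. Propagation makes the most-informative-common-
#' ancestor similarity well defined: after it, the intersection of two
#' genes' term sets *is* their common-ancestor set.
#'
#' @param ann An `annotation_table` from [load_annotations()].
#' @param dag The matching `ontology_dag`.
#' @return The `annotation_table` with `propagated`, `n_term` (named
#'   integer, genes per term) and `corpus_size` filled in.
#' @export
propagate_annotations <- function(ann, dag) {
  stopifnot(inherits(ann, "annotation_table"), inherits(dag, "ontology_dag"))
  if (!length(ann$direct)) stop("direct annotation map is empty")
  prop <- lapply(ann$direct, function(ts) {
    sort(unique(c(ts, unlist(dag$ancestors[ts], use.names = FALSE))))
  })
  cnt <- table(unlist(prop, use.names = FALSE))
  ann$propagated <- prop
  ann$n_term <- setNames(as.integer(cnt), names(cnt))
  ann$corpus_size <- length(prop)
  ann
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("<annotation_table> ", length(x$direct), " genes (",
      if (is.null(x$propagated)) "direct only" else
        paste0("propagated; N = ", x$corpus_size),
      "), namespace: ", x$namespace, "\n", sep = "")
  invisible(x)
}

assert_propagated <- function(ann) {
  if (is.null(ann$propagated)) {
    stop("annotations must be propagated first; call propagate_annotations()")
  }
}

#' Information content of an ontology term
#'
#' `IC(t) = -log(n(t) / N)` where `n(t)` is the number of genes annotated
#' (after propagation) to term `t` and `N` is the annotation corpus size.
#' Larger values mean more specific terms; a term covering the whole
#' corpus (the namespace root, on propagated counts) has `IC = 0`.
#'
#' @param term Term identifier(s).
#' @param ann A propagated `annotation_table`.
#' @param log_base Base of the logarithm (default natural log). The base
#'   is a pure monotone rescaling: rankings built on IC are invariant to it.
#' @param N Corpus size override, e.g. a fixed genome-wide gene count.
#'   Defaults to the number of annotated genes in the active namespace.
#' @return Numeric vector of non-negative information contents.
#' @export
information_content <- function(term, ann, log_base = exp(1), N = NULL) {
  assert_propagated(ann)
  if (is.null(N)) N <- ann$corpus_size
  n_t <- ann$n_term[term]
  if (any(is.na(n_t) | n_t < 1L)) {
    bad <- term[is.na(n_t) | n_t < 1L]
    stop("IC undefined: no gene annotated to term(s) ",
         paste(bad, collapse = ", "))
  }
  if (any(n_t > N)) stop("n(t) exceeds corpus size N")
  unname(-log(as.numeric(n_t) / N) / log(log_base))
}

# Max IC over the common propagated terms of two genes, in natural log
# units. Returns NA_real_ (missing signal) if either gene is unannotated;
# 0 if the genes share no term at all.
fs_nat <- function(p1, p2, n_term, N) {
  if (is.null(p1) || is.null(p2) || !length(p1) || !length(p2)) return(NA_real_)
  common <- p1[match(p2, p1, 0L)]
  if (!length(common)) return(0)
  max(-log(as.numeric(n_term[common]) / N))
}

#' Resnik functional similarity between two genes
#'
#' The information content of the most informative common ancestor of the
#' two genes' annotation sets. Because [propagate_annotations()] closes
#' each gene's term set under ancestry, the common-ancestor set is simply
#' the intersection of the two propagated sets. Symmetric in its gene
#' arguments. A pair sharing only the namespace root scores 0.
#'
#' @param g1,g2 Gene identifiers.
#' @param ann A propagated `annotation_table`.
#' @param dag The matching `ontology_dag` (kept for interface symmetry;
#'   the propagated sets already encode the ancestry).
#' @param log_base Logarithm base for IC (default natural log).
#' @param N Corpus size override (see [information_content()]).
#' @return A single non-negative number, or `NA` if either gene carries no
#'   annotation in the active namespace (a missing-data signal distinct
#'   from a true similarity of 0; downstream rank fusion decides its fate).
#' @export
functional_similarity <- function(g1, g2, ann, dag = NULL,
                                  log_base = exp(1), N = NULL) {
  assert_propagated(ann)
  if (is.null(N)) N <- ann$corpus_size
  v <- fs_nat(ann$propagated[[g1]], ann$propagated[[g2]], ann$n_term, N)
  v / log(log_base)
}

#' Average functional similarity of a candidate against a validated set
#'
#' Arithmetic mean of [functional_similarity()] between `candidate` and
#' each member of `validated`. The candidate itself is excluded from the
#' validated group (self-pairs would inflate the score), and unannotated
#' members are skipped and counted.
#'
#' @param candidate Gene identifier.
#' @param validated Character vector of validated target genes.
#' @param ann A propagated `annotation_table`.
#' @param dag The matching `ontology_dag`.
#' @param log_base,N See [functional_similarity()].
#' @return The AFS score, with attributes `n_used` and `n_skipped`; `NA`
#'   if the candidate or every validated member is unannotated.
#' @export
average_functional_similarity <- function(candidate, validated, ann, dag = NULL,
                                          log_base = exp(1), N = NULL) {
  assert_propagated(ann)
  validated <- setdiff(validated, candidate)
  if (!length(validated)) stop("validated set is empty after self-exclusion")
  if (is.null(N)) N <- ann$corpus_size
  pc <- ann$propagated[[candidate]]
  fs <- vapply(validated, function(v)
    fs_nat(pc, ann$propagated[[v]], ann$n_term, N), numeric(1))
  used <- !is.na(fs)
  out <- if (any(used)) mean(fs[used]) / log(log_base) else NA_real_
  structure(out, n_used = sum(used), n_skipped = sum(!used))
}

#' Pairwise functional similarity within a gene group
#'
#' Computes [functional_similarity()] for every unordered pair of
#' annotated genes in `genes`, as used when asking whether genes targeted
#' by the same miRNA are functionally more coherent than random gene sets.
#'
#' @param genes Character vector (>= 2 annotated members required).
#' @param ann A propagated `annotation_table`.
#' @param dag The matching `ontology_dag`.
#' @param log_base,N See [functional_similarity()].
#' @return A list with `pairs` (data frame `g1`, `g2`, `score`), `mean`,
#'   `n_used` (annotated genes) and `n_skipped` (unannotated, dropped).
#' @export
group_pairwise_fs <- function(genes, ann, dag = NULL,
                              log_base = exp(1), N = NULL) {
  assert_propagated(ann)
  genes <- unique(genes)
  ok <- genes[vapply(genes, function(g)
    length(ann$propagated[[g]]) > 0L, logical(1))]
  if (length(ok) < 2L) {
    stop("group too small: fewer than 2 annotated genes")
  }
  if (is.null(N)) N <- ann$corpus_size
  pr <- utils::combn(ok, 2L)
  score <- apply(pr, 2L, function(p)
    fs_nat(ann$propagated[[p[1L]]], ann$propagated[[p[2L]]], ann$n_term, N))
  score <- score / log(log_base)
  list(pairs = data.frame(g1 = pr[1L, ], g2 = pr[2L, ], score = score,
                          stringsAsFactors = FALSE),
       mean = mean(score),
       n_used = length(ok), n_skipped = length(genes) - length(ok))
}
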