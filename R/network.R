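#' Build a cleaned protein-protein interaction graph
#'
#' Constructs a simple undirected graph from an edge data frame:
#' self-loops are removed and duplicate or reciprocal pairs ("round
#' trips" a-b / b-a) are collapsed to a single interaction.
#'
#' @param edges Data frame or 2-column matrix; the first two columns are
#'   interactor identifiers.
#' @param nodes Optional character vector of nodes to declare even when
#'   isolated (no surviving edge).
#' @return A `ppi_graph`: list with `graph` (an undirected
#'   \pkg{igraph} object), `nodes`, `n_edges`, and cleanup counters
#'   `n_self_loops`, `n_duplicates`.
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  n_in <- length(a)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  # orientation-independent key collapses duplicates and round trips
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  if (!length(a)) stop("empty network: no edges remain after cleaning")
  verts <- sort(unique(c(a, b, nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = verts
  )
  structure(list(
    graph = g,
    nodes = verts,
    n_edges = length(a),
    n_self_loops = sum(self),
    n_duplicates = sum(dup)
  ), class = "ppi_graph")
}

#' Load a protein-protein interaction network from an edge list
#'
#' Reads a 2-column tab-separated edge list (`#`-prefixed comment lines
#' skipped). Files with more than two columns — e.g. PSI-MI TAB — are
#' accepted by taking the first two identifier columns. Identifier
#' namespaces (gene symbol vs protein accession) are the caller's
#' responsibility; an optional 2-column mapping table (`from`, `to`)
#' translates identifiers before the graph is built.
#'
#' @param path Path to the edge-list file.
#' @param mapping Optional data frame; column 1 identifiers are replaced
#'   by column 2. Unmapped identifiers pass through unchanged.
#' @return A `ppi_graph`; see [ppi_graph()] for the cleaning rule.
#' @export
load_network <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty network: no edge rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 2L
  if (any(short)) stop("edge list row with fewer than 2 columns in ", path)
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  if (!is.null(mapping)) {
    from <- as.character(mapping[[1L]]); to <- as.character(mapping[[2L]])
    ia <- match(a, from); ib <- match(b, from)
    a[!is.na(ia)] <- to[ia[!is.na(ia)]]
    b[!is.na(ib)] <- to[ib[!is.na(ib)]]
  }
  ppi_graph(data.frame(a = a, b = b, stringsAsFactors = FALSE))
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("<ppi_graph> ", length(x$nodes), " nodes, ", x$n_edges, " edges",
      " (removed: ", x$n_self_loops, " self-loops, ", x$n_duplicates,
      " duplicate/reciprocal rows)\n", sep = "")
  invisible(x)
}

#' Shortest-path distance between two gene products
#'
#' Minimum hop count on the unweighted interaction graph. With unit edge
#' weights Dijkstra's algorithm reduces to breadth-first search, which is
#' what is run here. Disconnected pairs have infinite distance.
#'
#' @param g1,g2 Node identifiers.
#' @param net A `ppi_graph`.
#' @return A non-negative number (`Inf` if no path); `NA` if either node
#'   is absent from the network (a missing-data signal, distinct from
#'   being unreachable).
#' @export
shortest_distance <- function(g1, g2, net) {
  stopifnot(inherits(net, "ppi_graph"))
  if (!(g1 %in% net$nodes) || !(g2 %in% net$nodes)) return(NA_real_)
  as.numeric(igraph::distances(net$graph, v = g1, to = g2))
}

#' Network closeness of two gene products
#'
#' `NC = 1 / DIS`, the reciprocal shortest-path distance: 1 for an
#' interacting pair, 0.5 for a common neighbour, and 0 for a disconnected
#' pair (the limiting value as distance grows).
#'
#' @inheritParams shortest_distance
#' @return A number in `[0, 1]`, or `NA` when a node is absent.
#' @export
network_closeness <- function(g1, g2, net) {
  d <- shortest_distance(g1, g2, net)
  if (is.na(d)) return(NA_real_)
  if (is.infinite(d)) 0 else 1 / d
}

#' Average network closeness of a candidate against a validated set
#'
#' Mean of [network_closeness()] between `candidate` and each validated
#' target present in the network; the candidate itself is excluded from
#' the group, absent members are skipped and counted, and unreachable
#' members contribute 0.
#'
#' @param candidate Node identifier.
#' @param validated Character vector of validated target genes.
#' @param net A `ppi_graph`.
#' @return The ANC score in `[0, 1]` with attributes `n_used` and
#'   `n_skipped`; `NA` if the candidate or every validated member is
#'   absent from the network.
#' @export
average_network_closeness <- function(candidate, validated, net) {
  stopifnot(inherits(net, "ppi_graph"))
  validated <- setdiff(validated, candidate)
  if (!length(validated)) stop("validated set is empty after self-exclusion")
  present <- validated[validated %in% net$nodes]
  if (!(candidate %in% net$nodes) || !length(present)) {
    return(structure(NA_real_, n_used = 0L,
                     n_skipped = length(validated) - length(present)))
  }
  d <- as.numeric(igraph::distances(net$graph, v = candidate, to = present))
  nc <- ifelse(is.infinite(d), 0, 1 / d)
  structure(mean(nc), n_used = length(present),
            n_skipped = length(validated) - length(present))
}

#' Pairwise network closeness within a gene group
#'
#' [network_closeness()] for every unordered pair of group members
#' present in the network, used to ask whether targets of the same miRNA
#' sit closer together than random gene sets.
#'
#' @param genes Character vector (>= 2 members in the network required).
#' @param net A `ppi_graph`.
#' @return A list with `pairs` (data frame `g1`, `g2`, `score`), `mean`,
#'   `n_used`, and `n_skipped` (members absent from the network).
#' @export
group_pairwise_nc <- function(genes, net) {
  stopifnot(inherits(net, "ppi_graph"))
  genes <- unique(genes)
  ok <- genes[genes %in% net$nodes]
  if (length(ok) < 2L) stop("group too small: fewer than 2 genes in network")
  d <- igraph::distances(net$graph, v = ok, to = ok)
  nc <- ifelse(is.infinite(d), 0, 1 / d)
  ut <- which(upper.tri(nc), arr.ind = TRUE)
  score <- nc[ut]
  list(pairs = data.frame(g1 = ok[ut[, 1L]], g2 = ok[ut[, 2L]],
                          score = score, stringsAsFactors = FALSE),
       mean = mean(score),
       n_used = length(ok), n_skipped = length(genes) - length(ok))
}
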