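#' Bundle a miRNA's validated targets and candidate list
#'
#' @param mirna_id miRNA identifier string.
#' @param validated Character vector of experimentally validated target
#'   genes (non-empty; the method needs known targets to score against).
#' @param candidates Character vector of candidate target genes to rank.
#' @return A `target_set` list.
#' @export
target_set <- function(mirna_id, validated, candidates) {
  validated <- unique(as.character(validated))
  candidates <- unique(as.character(candidates))
  if (!length(validated)) {
    stop("validated target set is empty: the method requires known targets")
  }
  if (!length(candidates)) stop("candidate list is empty")
  structure(list(mirna_id = as.character(mirna_id)[1L],
                 validated = validated, candidates = candidates),
            class = "target_set")
}

#' Default pipeline configuration
#'
#' @param missing_policy Missing-source policy passed to [fuse_ranks()].
#' @param log_base Logarithm base for information content.
#' @param use_ontology,use_network Which data sources to score; at least
#'   one must be `TRUE`.
#' @param N Annotation corpus-size override (see [information_content()]).
#' @return A named list of settings.
#' @export
prioritize_config <- function(missing_policy = "worst", log_base = exp(1),
                              use_ontology = TRUE, use_network = TRUE,
                              N = NULL) {
  if (!use_ontology && !use_network) {
    stop("at least one data source must be enabled")
  }
  list(missing_policy = missing_policy, log_base = log_base,
       use_ontology = use_ontology, use_network = use_network, N = N)
}

# AFS for every candidate against a (possibly self-excluded) validated set.
afs_scores <- function(candidates, validated, ann, log_base, N) {
  if (is.null(N)) N <- ann$corpus_size
  props <- ann$propagated
  vapply(candidates, function(g) {
    grp <- setdiff(validated, g)
    if (!length(grp)) return(NA_real_)
    pc <- props[[g]]
    if (is.null(pc) || !length(pc)) return(NA_real_)
    fs <- vapply(grp, function(v) fs_nat(pc, props[[v]], ann$n_term, N),
                 numeric(1))
    if (all(is.na(fs))) NA_real_ else mean(fs, na.rm = TRUE) / log(log_base)
  }, numeric(1))
}

# ANC for every candidate against a (possibly self-excluded) validated set;
# one igraph distance matrix call for the whole candidate list.
anc_scores <- function(candidates, validated, net) {
  out <- setNames(rep(NA_real_, length(candidates)), candidates)
  pres_c <- candidates[candidates %in% net$nodes]
  pres_v <- validated[validated %in% net$nodes]
  if (!length(pres_c) || !length(pres_v)) return(out)
  d <- igraph::distances(net$graph, v = pres_c, to = pres_v)
  nc <- ifelse(is.infinite(d), 0, 1 / d)
  for (g in pres_c) {
    keep <- pres_v != g                    # self-exclusion
    if (any(keep)) out[[g]] <- mean(nc[g, keep])
  }
  out
}

#' Prioritize a miRNA's candidate targets
#'
#' Runs the three-step pipeline: (1) each candidate is scored by average
#' functional similarity (AFS) to the validated target group and the list
#' is ranked by AFS; (2) each candidate is scored by average network
#' closeness (ANC) to the same group and ranked; (3) the per-source rank
#' ratios are fused into a single Q value and final rank with
#' [fuse_ranks()]. A candidate that is itself a validated target is
#' scored against the validated set *excluding itself*, so known targets
#' can sit in the candidate list without self-similarity leakage.
#'
#' @param ts A [target_set()].
#' @param ann A propagated `annotation_table` (or `NULL` when the
#'   ontology source is disabled).
#' @param dag The matching `ontology_dag` (interface completeness).
#' @param net A `ppi_graph` (or `NULL` when the network source is
#'   disabled).
#' @param config A [prioritize_config()] list.
#' @return A `ranked_candidates` data frame, ordered by `final_rank`,
#'   with columns `gene_id`, `afs_score`, `afs_rank`, `afs_ratio`,
#'   `anc_score`, `anc_rank`, `anc_ratio`, `q_value`, `final_rank`,
#'   `final_percentile` (final rank / list length * 100), and `flags`.
#' @export
prioritize <- function(ts, ann = NULL, dag = NULL, net = NULL,
                       config = prioritize_config()) {
  stopifnot(inherits(ts, "target_set"))
  cands <- ts$candidates
  use_go <- isTRUE(config$use_ontology) && !is.null(ann)
  use_net <- isTRUE(config$use_network) && !is.null(net)
  if (!use_go && !use_net) stop("no data source loaded")

  out <- data.frame(gene_id = cands, stringsAsFactors = FALSE)
  ratio_cols <- list()

  if (use_go) {
    assert_propagated(ann)
    afs <- afs_scores(cands, ts$validated, ann, config$log_base, config$N)
    if (all(is.na(afs))) {
      rk <- data.frame(rank = rep(NA_real_, length(cands)),
                       ratio = rep(NA_real_, length(cands)))
    } else {
      rk <- rank_scores(setNames(afs, cands))[, c("rank", "ratio")]
    }
    out$afs_score <- unname(afs)
    out$afs_rank <- rk$rank
    out$afs_ratio <- rk$ratio
    ratio_cols$afs <- rk$ratio
  }
  if (use_net) {
    anc <- anc_scores(cands, ts$validated, net)
    if (all(is.na(anc))) {
      rk <- data.frame(rank = rep(NA_real_, length(cands)),
                       ratio = rep(NA_real_, length(cands)))
    } else {
      rk <- rank_scores(setNames(anc, cands))[, c("rank", "ratio")]
    }
    out$anc_score <- unname(anc)
    out$anc_rank <- rk$rank
    out$anc_ratio <- rk$ratio
    ratio_cols$anc <- rk$ratio
  }

  rmat <- do.call(cbind, ratio_cols)
  rownames(rmat) <- cands
  if (all(is.na(rmat))) stop("no source could score any candidate")
  fused <- fuse_ranks(rmat, policy = config$missing_policy)

  out <- merge(out, fused, by.x = "gene_id", by.y = "gene", sort = FALSE)
  out <- out[order(out$final_rank), , drop = FALSE]
  out$final_percentile <- 100 * out$final_rank / nrow(out)
  rownames(out) <- NULL
  structure(out, class = c("ranked_candidates", "data.frame"),
            mirna_id = ts$mirna_id, config = config)
}

#' Write a ranked candidate table as TSV
#'
#' Deterministic plain-text serialization (fixed column order, no
#' quoting): identical inputs yield byte-identical files.
#'
#' @param x A `ranked_candidates` data frame from [prioritize()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranked <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Batch prioritization over a miRNA-target pairs table
#'
#' Iterates [prioritize()] over every miRNA in `candidates`, writing one
#' TSV per miRNA plus a `skipped.tsv` log of miRNAs that lacked validated
#' targets. Re-running with identical inputs and configuration produces
#' byte-identical output files.
#'
#' @param pairs Data frame (or TSV path) with columns miRNA id, validated
#'   target gene.
#' @param candidates Data frame (or TSV path) with columns miRNA id,
#'   candidate gene.
#' @param out_dir Output directory (created if absent).
#' @param ann,dag,net,config See [prioritize()].
#' @return Invisibly, a list with `written` (named vector of output
#'   paths) and `skipped` (miRNA ids without validated targets).
#' @export
run_batch <- function(pairs, candidates, out_dir,
                      ann = NULL, dag = NULL, net = NULL,
                      config = prioritize_config()) {
  pairs <- read_two_col(pairs, c("mirna", "gene"))
  candidates <- read_two_col(candidates, c("mirna", "gene"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  validated_by <- split(pairs$gene, pairs$mirna)
  mirnas <- sort(unique(candidates$mirna))
  written <- character(0)
  skipped <- character(0)
  for (m in mirnas) {
    valid <- validated_by[[m]]
    if (is.null(valid) || !length(valid)) {
      skipped <- c(skipped, m)
      next
    }
    ts <- target_set(m, valid, candidates$gene[candidates$mirna == m])
    ranked <- prioritize(ts, ann = ann, dag = dag, net = net, config = config)
    f <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", m), ".tsv"))
    write_ranked(ranked, f)
    written[m] <- f
  }
  utils::write.table(
    data.frame(mirna = skipped, reason = rep("no validated targets",
                                             length(skipped))),
    file.path(out_dir, "skipped.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(written = written, skipped = skipped))
}

# Accept a 2+-column data frame or TSV path; returns the first two columns
# renamed.
read_two_col <- function(x, nm) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.table(x, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  }
  if (ncol(x) < 2L) stop("expected at least 2 columns")
  out <- data.frame(a = as.character(x[[1L]]), b = as.character(x[[2L]]),
                    stringsAsFactors = FALSE)
  names(out) <- nm
  out
}
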