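test_that("load_obo builds the is_a DAG, drops obsolete terms, maps alt_ids", {
  dag <- load_obo(chain_obo(), "BP")
  expect_s3_class(dag, "ontology_dag")
  expect_setequal(dag$terms, c("T:root", "T:mid", "T:leaf"))
  expect_equal(sum(lengths(dag$parents)), 2L)          # 2 is_a edges
  expect_equal(dag$roots, "T:root")
  expect_setequal(dag$ancestors[["T:leaf"]], c("T:mid", "T:root"))

  # obsolete term absent; alt_id resolves to canonical id
  p <- write_obo(c(
    "[Term]", "id: T:r", "namespace: biological_process", "",
    "[Term]", "id: T:a", "alt_id: T:old", "namespace: biological_process",
    "is_a: T:r", "",
    "[Term]", "id: T:dead", "namespace: biological_process",
    "is_a: T:r", "is_obsolete: true"
  ))
  dag2 <- load_obo(p, "BP")
  expect_false("T:dead" %in% dag2$terms)
  expect_equal(unname(dag2$alt_id["T:old"]), "T:a")

  # namespace restriction
  p3 <- write_obo(c(
    "[Term]", "id: T:b", "namespace: biological_process", "",
    "[Term]", "id: T:m", "namespace: molecular_function"
  ))
  expect_false("T:m" %in% load_obo(p3, "BP")$terms)
  expect_equal(load_obo(p3, "MF")$terms, "T:m")
})

test_that("load_obo rejects malformed stanzas and cyclic ontologies", {
  bad <- write_obo(c("[Term]", "name: no id here"))
  expect_error(load_obo(bad, "BP"), "missing id")
  cyc <- write_obo(c(
    "[Term]", "id: T:x", "namespace: biological_process", "is_a: T:y", "",
    "[Term]", "id: T:y", "namespace: biological_process", "is_a: T:x"
  ))
  expect_error(load_obo(cyc, "BP"), "cycle")
})

test_that("annotation loading handles TSV, GAF NOT qualifiers, unknown terms", {
  dag <- load_obo(chain_obo(), "BP")
  ann <- load_annotations(
    write_tsv_ann(data.frame(g = c("g1", "g2"), t = c("T:leaf", "T:nope"))),
    dag)
  expect_equal(ann$direct[["g1"]], "T:leaf")
  expect_null(ann$direct[["g2"]])
  expect_equal(attr(ann, "n_skipped"), 1L)

  gaf_row <- function(gene, qual, term) {
    paste(c("DB", gene, gene, qual, term, "REF", "IDA", "", "P",
            "", "", "protein", "taxon:9606", "20120101", "DB", "", ""),
          collapse = "\t")
  }
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               gaf_row("g1", "", "T:leaf"),
               gaf_row("g2", "NOT", "T:leaf"),
               gaf_row("g3", "involved_in", "T:mid")), gaf)
  ann2 <- load_annotations(gaf, dag)
  expect_setequal(names(ann2$direct), c("g1", "g3"))   # NOT row excluded
  expect_error(load_annotations(write_tsv_ann(
    data.frame(g = "g1", t = "T:unknown")), dag), "no annotation rows match")
})

test_that("propagation obeys the true-path rule and brute-force counts", {
  dag <- load_obo(chain_obo(), "BP")
  ann <- propagate_annotations(annotations_from_frame(
    data.frame(gene = "g1", term = "T:leaf"), dag), dag)
  expect_setequal(ann$propagated[["g1"]], c("T:leaf", "T:mid", "T:root"))

  # two genes on disjoint leaves under one root: n(root) = 2
  p <- write_obo(c(
    "[Term]", "id: T:r", "namespace: biological_process", "",
    "[Term]", "id: T:l1", "namespace: biological_process", "is_a: T:r", "",
    "[Term]", "id: T:l2", "namespace: biological_process", "is_a: T:r"
  ))
  dag2 <- load_obo(p, "BP")
  ann2 <- propagate_annotations(annotations_from_frame(
    data.frame(gene = c("a", "b"), term = c("T:l1", "T:l2")), dag2), dag2)
  expect_equal(unname(ann2$n_term["T:r"]), 2L)
  expect_equal(ann2$corpus_size, 2L)

  # 50-term synthetic fixture: n(t) matches the brute-force gene scan
  ont <- make_ontology(n_terms = 50, seed = 42)
  dag3 <- load_obo(ont$path, "BP")
  am <- make_annotations(ont, 30, seed = 43)
  ann3 <- propagate_annotations(
    load_annotations(am$path, dag3), dag3)
  cnt <- brute_counts(am$direct, dag3$parents, dag3$terms)
  cnt <- cnt[cnt > 0]
  expect_equal(ann3$n_term[names(cnt)], cnt)
  # propagated supersets + ancestor closure invariants
  for (g in names(ann3$direct)) {
    expect_true(all(ann3$direct[[g]] %in% ann3$propagated[[g]]))
    expect_setequal(ann3$propagated[[g]],
                    brute_closure(am$direct[[g]], dag3$parents))
  }
})

test_that("information content matches hand-computed values and bases", {
  p <- write_obo(c(
    "[Term]", "id: T:r", "namespace: biological_process", "",
    "[Term]", "id: T:l", "namespace: biological_process", "is_a: T:r"
  ))
  dag <- load_obo(p, "BP")
  genes <- paste0("g", 1:100)
  df <- data.frame(gene = genes,
                   term = c("T:l", rep("T:r", 99)))
  ann <- propagate_annotations(annotations_from_frame(df, dag), dag)
  expect_equal(information_content("T:r", ann), 0)          # n = N
  expect_equal(information_content("T:l", ann), 4.6052, tolerance = 1e-4)
  # base 2, n(t)=50, N=100 via override
  expect_equal(information_content("T:l", ann, log_base = 2, N = 2), 1.0)
  expect_error(information_content("T:absent", ann), "IC undefined")
})

test_that("IC is monotone nonincreasing from child to parent", {
  ont <- make_ontology(n_terms = 60, seed = 5)
  dag <- load_obo(ont$path, "BP")
  am <- make_annotations(ont, 40, seed = 6)
  ann <- propagate_annotations(load_annotations(am$path, dag), dag)
  for (t in names(ann$n_term)) {
    for (p in dag$parents[[t]]) {
      if (p %in% names(ann$n_term)) {
        expect_lte(information_content(p, ann),
                   information_content(t, ann) + 1e-12)
      }
    }
  }
})

test_that("functional similarity: conventions, symmetry, self-dominance", {
  dag <- load_obo(chain_obo(), "BP")
  df <- data.frame(gene = c("a", "b", "c", "d"),
                   term = c("T:leaf", "T:leaf", "T:mid", "T:root"))
  ann <- propagate_annotations(annotations_from_frame(df, dag), dag)
  # both genes on the same leaf: FS = IC(leaf)
  expect_equal(functional_similarity("a", "b", ann),
               information_content("T:leaf", ann))
  # pair sharing only the root scores 0 (IC(root) = 0 on propagated counts)
  expect_equal(functional_similarity("a", "d", ann), 0)
  # missing-annotation signal is NA, not 0
  expect_true(is.na(functional_similarity("a", "zz", ann)))
  # log base rescales, ranks invariant
  expect_equal(functional_similarity("a", "b", ann, log_base = 2),
               functional_similarity("a", "b", ann) / log(2))
})

test_that("FS equals brute-force common-ancestor max-IC on a 100-term DAG", {
  ont <- make_ontology(n_terms = 100, max_depth = 6, seed = 9)
  dag <- load_obo(ont$path, "BP")
  am <- make_annotations(ont, 50, seed = 10)
  ann <- propagate_annotations(load_annotations(am$path, dag), dag)
  genes <- names(ann$direct)
  set.seed(11)
  for (i in 1:25) {
    pr <- sample(genes, 2)
    got <- functional_similarity(pr[1], pr[2], ann)
    want <- brute_fs(pr[1], pr[2], am$direct, dag$parents, dag$terms)
    expect_equal(got, unname(want), tolerance = 1e-12)
    # symmetry and self-dominance
    expect_equal(got, functional_similarity(pr[2], pr[1], ann))
    expect_lte(got, functional_similarity(pr[1], pr[1], ann) + 1e-12)
  }
})

test_that("AFS averages over annotated members and excludes the candidate", {
  dag <- load_obo(chain_obo(), "BP")
  df <- data.frame(gene = c("c", "v1", "v2"),
                   term = c("T:leaf", "T:leaf", "T:mid"))
  ann <- propagate_annotations(annotations_from_frame(df, dag), dag)
  fs1 <- functional_similarity("c", "v1", ann)
  fs2 <- functional_similarity("c", "v2", ann)
  expect_equal(as.numeric(
    average_functional_similarity("c", c("v1", "v2"), ann)),
    mean(c(fs1, fs2)))
  # singleton mean
  expect_equal(as.numeric(average_functional_similarity("c", "v1", ann)), fs1)
  # candidate inside the validated set: mean over the others only
  expect_equal(as.numeric(
    average_functional_similarity("c", c("c", "v1", "v2"), ann)),
    mean(c(fs1, fs2)))
  # unannotated members skipped and counted
  afs <- average_functional_similarity("c", c("v1", "ghost"), ann)
  expect_equal(as.numeric(afs), fs1)
  expect_equal(attr(afs, "n_skipped"), 1L)
  # all members unannotated: missing signal
  expect_true(is.na(average_functional_similarity("c", "ghost", ann)))
})

test_that("group pairwise FS enumerates C(k,2) pairs and flags small groups", {
  ont <- make_ontology(n_terms = 40, seed = 2)
  dag <- load_obo(ont$path, "BP")
  am <- make_annotations(ont, 20, seed = 3)
  ann <- propagate_annotations(load_annotations(am$path, dag), dag)
  genes <- names(ann$direct)
  expect_equal(nrow(group_pairwise_fs(genes[1:2], ann)$pairs), 1L)
  expect_equal(nrow(group_pairwise_fs(genes[1:5], ann)$pairs), 10L)
  expect_error(group_pairwise_fs(c(genes[1], "ghost"), ann), "too small")
})
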