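test_that("make_ontology emits a reparsable DAG matching its manifest", {
  ont <- make_ontology(n_terms = 50, max_depth = 5, seed = 77)
  dag <- load_obo(ont$path, "BP")
  expect_setequal(dag$terms, ont$terms)
  expect_equal(sum(lengths(dag$parents)), ont$n_edges)
  expect_equal(dag$roots, "T:0001")
  # parent map round-trips through the OBO file
  for (t in ont$terms) {
    expect_setequal(dag$parents[[t]], ont$parents[[t]])
  }
  # at least one multi-parent term; acyclicity already proven by load_obo
  expect_gte(length(ont$multi_parent), 1L)
  expect_gte(max(lengths(dag$parents)), 2L)
  # 3-term degenerate case: a chain with 2 edges
  tiny <- make_ontology(n_terms = 3, max_depth = 2, seed = 1)
  expect_equal(tiny$n_edges, 2L)
})

test_that("make_annotations plants shared deep terms at the stated coverage", {
  ont <- make_ontology(n_terms = 60, seed = 88)
  leaf <- ont$leaves[which.max(ont$level[ont$leaves])]
  targets <- sprintf("G%04d", 1:6)
  am <- make_annotations(
    ont, 40, planted = list(m1 = list(targets = targets, shared_terms = leaf)),
    coverage = 1.0, seed = 89)
  # full coverage: every target directly annotated to the shared term,
  # and the manifest's direct map equals the emitted file
  dag <- load_obo(ont$path, "BP")
  ann <- load_annotations(am$path, dag)
  expect_identical(ann$direct, am$direct[order(names(am$direct))])
  for (g in targets) expect_true(leaf %in% ann$direct[[g]])
  expect_setequal(am$planted_hits$m1, targets)
  # planted group's pairwise FS is at least IC(shared term)
  annp <- propagate_annotations(ann, dag)
  ic_leaf <- information_content(leaf, annp)
  fs <- group_pairwise_fs(targets, annp)
  expect_true(all(fs$pairs$score >= ic_leaf - 1e-12))
})

test_that("make_network plants communities and matches its manifest", {
  genes <- sprintf("G%03d", 1:60)
  targets <- genes[1:5]
  man <- make_network(genes, n_communities = 6, p_in = 1, p_out = 0.02,
                      planted = list(m1 = targets), coverage = 1,
                      seed = 90)
  net <- load_network(man$path)
  expect_equal(net$n_edges, man$n_edges)
  # p_in = 1, coverage 1: planted targets form a clique (all DIS = 1)
  for (pr in utils::combn(targets, 2, simplify = FALSE)) {
    expect_equal(shortest_distance(pr[1], pr[2], net), 1)
  }
  # intra-community closeness exceeds inter-community closeness
  memb <- unlist(man$membership)
  same <- group_pairwise_nc(names(memb)[memb == memb[[targets[1]]]], net)$mean
  set.seed(91)
  other <- sample(names(memb)[memb != memb[[targets[1]]]], 8)
  cross <- mean(vapply(other, function(g)
    network_closeness(targets[1], g, net), numeric(1)))
  expect_gt(same, cross)
})

test_that("study bundles regenerate byte-identically from the same seed", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  make_study(d1, seed = 404, scale = "tiny")
  make_study(d2, seed = 404, scale = "tiny")
  for (f in c("ontology.obo", "annotations.tsv", "ppi.tsv", "pairs.tsv",
              "candidates.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  d3 <- file.path(tempdir(), "det3")
  make_study(d3, seed = 405, scale = "tiny")
  expect_false(identical(readBin(file.path(d1, "ppi.tsv"), "raw", 1e7),
                         readBin(file.path(d3, "ppi.tsv"), "raw", 1e7)))
})

test_that("manifest claims are verifiable from the emitted files", {
  d <- file.path(tempdir(), "mtr-manifest-study")
  make_study(d, seed = 505, scale = "tiny")
  st <- load_study(d)
  man <- st$manifest
  expect_setequal(st$dag$terms, names(man$ontology_level))
  expect_equal(length(st$dag$terms), man$params$n_terms)
  expect_equal(st$net$n_edges, man$network$n_edges)
  # pairs file carries exactly the planted targets
  for (m in man$mirnas) {
    expect_setequal(st$pairs$gene[st$pairs$mirna == m],
                    unlist(man$planted[[m]]$targets))
  }
  # targets reported as annotated to the shared term really are
  for (m in man$mirnas) {
    shared <- man$planted[[m]]$shared_term
    for (g in unlist(man$annotations$planted_hits[[m]])) {
      expect_true(shared %in% st$ann$direct[[g]])
    }
  }
  # network membership recorded for every node
  expect_setequal(names(man$network$membership), sprintf("G%04d",
    seq_len(man$params$n_genes)))
})

test_that("tiny bundle runs the full pipeline end to end", {
  d <- file.path(tempdir(), "mtr-smoke-study")
  make_study(d, seed = 606, scale = "tiny")
  st <- load_study(d)
  r <- prioritize(st$target_sets[[1]], st$ann, st$dag, st$net)
  expect_equal(nrow(r), length(st$target_sets[[1]]$candidates))
  expect_true(all(diff(order(r$final_rank)) == 1))
})

test_that("stronger planted effects give larger cross-validation AUC", {
  # effect-size dial: annotation/community coverage of planted targets
  aucs <- vapply(c(0.15, 0.55, 0.95), function(cov) {
    mean(vapply(1:2, function(rep) {
      d <- tempfile("dial")
      make_study(d, seed = 700 + rep, scale = "tiny",
                 overrides = list(coverage = cov))
      st <- load_study(d)
      loocv(st$pairs, st$ann, st$dag, st$net, n_decoys = 30,
            seed = rep, universe = st$universe)$auc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
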