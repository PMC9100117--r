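test_that("score tiers follow the published boundaries", {
  expect_equal(categorize_score(c(92, 85, 75, 38)),
               c("very_strong", "strong", "medium_strong", "weak"))
  # boundary sweep forced by the printed interval notation
  expect_equal(categorize_score(c(40, 76, 91)),
               c("medium_strong", "medium_strong", "strong"))
  expect_equal(categorize_score(c(0, 100)), c("weak", "very_strong"))
  expect_equal(categorize_score(c(39.999, 76.5, 91.0001)),
               c("weak", "strong", "very_strong"))
  expect_error(categorize_score(101), "\\[0, 100\\]")
  expect_error(categorize_score(-1), "\\[0, 100\\]")
  # reproduces every packaged score's printed tier
  t5 <- load_fixture("table5_scores_interactors")
  expect_equal(categorize_score(t5$score), t5$category)
})

test_that("interactome loader collapses duplicates and drops self-loops", {
  path <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "B\tpp\tA", "A\tpp\tA"), path)
  expect_message(g <- load_interactome(path), "1 self-loop")
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::graph_attr(g, "n_self_loops"), 1L)

  # empty file gives a valid empty graph
  writeLines(character(0), path)
  g <- load_interactome(path)
  expect_equal(igraph::vcount(g), 0)

  # two-column TSV and multi-target SIF lines are both accepted
  writeLines(c("a\tb", "b\tc"), path)
  expect_equal(igraph::ecount(load_interactome(path)), 2)
  writeLines("A\tpp\tB\tC\tD", path)
  expect_equal(igraph::ecount(load_interactome(path)), 3)
})

test_that("packaged interactome covers candidates plus listed effectors", {
  g <- load_interactome(fixture_path("interactome_table5.sif"))
  t5 <- load_fixture("table5_scores_interactors")
  expected_nodes <- toupper(unique(c(t5$gene, unlist(t5$interactors))))
  expect_setequal(igraph::V(g)$name, expected_nodes)
  # undirected edge count equals the deduplicated listed pairs
  listed <- do.call(rbind, lapply(seq_len(nrow(t5)), function(i) {
    ints <- t5$interactors[[i]]
    if (!length(ints)) return(NULL)
    t(vapply(ints, function(x) sort(c(toupper(t5$gene[i]), toupper(x))),
             character(2)))
  }))
  expect_equal(igraph::ecount(g), nrow(unique(listed)))
})

test_that("direct interactors restrict to the disease neighborhood", {
  g <- load_interactome(fixture_path("interactome_table5.sif"))
  eff <- load_fixture("effector_sets")
  t5 <- load_fixture("table5_scores_interactors")
  di <- direct_interactors(g, t5$gene, eff)
  expect_true(all(c("TNNT3", "TPM1") %in% di$TNNI2))
  # a candidate absent from the graph yields an empty set and a warning
  expect_warning(di2 <- direct_interactors(g, "NOTAGENE", eff),
                 "NOTAGENE")
  expect_identical(di2$NOTAGENE, character(0))
  # star graph: candidate at the center of three effectors sees all three
  star <- igraph::make_graph(~ HUB - E1, HUB - E2, HUB - E3)
  di3 <- direct_interactors(star, "HUB",
                            list(m = c("E1", "E2", "E3")))
  expect_setequal(di3$HUB, c("E1", "E2", "E3"))
})

test_that("isolation partitions the candidate set and shrinks under new edges", {
  g <- load_interactome(fixture_path("interactome_table5.sif"))
  eff <- load_fixture("effector_sets")
  cands <- load_fixture("table5_scores_interactors")$gene
  iso <- isolated_candidates(g, cands, eff)
  di <- suppressWarnings(direct_interactors(g, cands, eff))
  nonempty <- names(di)[vapply(di, length, integer(1)) > 0]
  expect_setequal(c(iso, nonempty), toupper(cands))
  expect_length(intersect(iso, nonempty), 0)

  # fully connected candidate clique: nobody is isolated
  clique <- igraph::make_full_graph(3)
  igraph::V(clique)$name <- c("X", "Y", "Z")
  expect_length(isolated_candidates(clique, c("X", "Y", "Z"),
                                    list(m = "Q")), 0)
  # single candidate in an empty graph is isolated
  empty <- igraph::make_empty_graph(directed = FALSE)
  expect_equal(suppressWarnings(
    isolated_candidates(empty, "SOLO", list(m = "Q"))), "SOLO")

  # anti-monotonicity: adding edges never grows the isolated set
  withr::with_seed(3, {
    g2 <- g
    nodes <- igraph::V(g)$name
    for (i in 1:20) {
      pair <- sample(nodes, 2)
      g2 <- igraph::add_edges(g2, match(pair, igraph::V(g2)$name))
      expect_true(all(isolated_candidates(g2, cands, eff) %in% iso))
      iso <- isolated_candidates(g2, cands, eff)
    }
  })
})

test_that("motif assignment distinguishes containment from adjacency", {
  g <- load_interactome(fixture_path("interactome_table5.sif"))
  eff <- load_fixture("effector_sets")
  pygm <- motif_assignment("PYGM", eff, g)
  glyc <- pygm[pygm$motif == "glycogenolysis blockade", ]
  expect_equal(nrow(glyc), 1)
  expect_true(glyc$containment)  # PYGM is itself a glycogenolysis effector
  expect_true(glyc$adjacency)
  # MYLPF touches the glucose-uptake effector without being one
  mylpf <- motif_assignment("MYLPF", eff, g)
  glu <- mylpf[mylpf$motif == "increased glucose uptake", ]
  expect_false(glu$containment)
  expect_true(glu$adjacency)
  # isolated candidate has no motifs
  expect_equal(nrow(motif_assignment("CMBL", eff, g)), 0)
})

test_that("subnetwork export respects the hop radius", {
  star <- igraph::make_graph(~ HUB - E1, HUB - E2, HUB - E3)
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")

  sub0 <- export_subnetwork(star, "HUB", 0, sif)
  expect_equal(igraph::vcount(sub0), 1)
  expect_equal(readLines(sif), "HUB")  # isolated seed as a node line

  sub1 <- export_subnetwork(star, "HUB", 1, sif, graphml_path = gml,
                            node_attrs = data.frame(gene = "HUB",
                                                    cp_ratio = 2.1))
  expect_equal(igraph::vcount(sub1), 4)
  expect_equal(length(readLines(sif)), 3)
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(reread), 4)

  # a large radius returns the seeds' full connected component
  g <- load_interactome(fixture_path("interactome_table5.sif"))
  comp <- igraph::components(g)
  seed <- "TPM1"
  full <- export_subnetwork(g, seed, igraph::vcount(g), sif)
  expect_equal(igraph::vcount(full),
               comp$csize[comp$membership[[seed]]])
  expect_error(export_subnetwork(g, seed, -1, sif), "nonnegative")
})

test_that("effector-set reader accepts TSV and YAML", {
  eff <- load_fixture("effector_sets")
  expect_true("glycogenolysis blockade" %in% names(eff))
  expect_true("PYGM" %in% eff[["glycogenolysis blockade"]])
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("calcium:", "  - a1", "  - b1", "other:", "  - c1"), yml)
  sets <- read_effector_sets(yml)
  expect_equal(sets$calcium, c("A1", "B1"))
})
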