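test_that("repeated extraction of a triple accumulates weight and unions pmids", {
  g <- hetero_graph()
  rec <- function(pmid) list(subject_cui = "C0000001", subject_name = "a",
                             subject_semtype = "aapp", predicate = "TREATS",
                             object_cui = "C0000002", object_name = "b",
                             object_semtype = "dsyn", pmid = pmid)
  add_predication_record(g, rec("11"))
  add_predication_record(g, rec("12"))
  ed <- graph_edges(g)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$weight, 2L)
  expect_equal(ed$pmids, "11;12")

  g2 <- hetero_graph()
  add_predication_record(g2, rec("11"))
  add_predication_record(g2, rec("11"))
  ed2 <- graph_edges(g2)
  expect_equal(ed2$weight, 2L)   # weight counts records
  expect_equal(ed2$pmids, "11")  # pmids is a set
})

test_that("vocabulary and CUI validation reject bad records", {
  g <- hetero_graph(predicates = c("TREATS"), semtypes = c("aapp", "dsyn"))
  ok <- list(subject_cui = "C0000001", subject_name = "a",
             subject_semtype = "aapp", predicate = "TREATS",
             object_cui = "C0000002", object_name = "b",
             object_semtype = "dsyn", pmid = "1")
  bad_pred <- ok; bad_pred$predicate <- "FOO"
  expect_error(add_predication_record(g, bad_pred), class = "lbd_vocab_error")
  bad_type <- ok; bad_type$object_semtype <- "zzzz"
  expect_error(add_predication_record(g, bad_type), class = "lbd_vocab_error")
  bad_cui <- ok; bad_cui$subject_cui <- "X123"
  expect_error(add_predication_record(g, bad_cui), class = "lbd_parse_error")
  expect_equal(node_count(g), 0L) # nothing partially applied
})

test_that("primary type is the most common type, ties broken by first sight", {
  mk <- function(counts, first) {
    list(type_counts = counts, type_first_seen = first)
  }
  expect_equal(resolve_primary_type(mk(c(orch = 5L, hops = 2L),
                                       c("orch", "hops"))), "orch")
  expect_equal(resolve_primary_type(mk(c(hops = 3L, orch = 3L),
                                       c("hops", "orch"))), "hops")
  expect_equal(resolve_primary_type(mk(c(menp = 1L), "menp")), "menp")
  expect_error(resolve_primary_type(list(type_counts = integer(),
                                         type_first_seen = character())),
               class = "lbd_internal_error")

  # through the record stream: tie resolved by first-observed type
  g <- hetero_graph()
  for (st in c("hops", "orch", "orch", "hops")) {
    add_predication_record(g, list(
      subject_cui = "C0000009", subject_name = "x", subject_semtype = st,
      predicate = "AFFECTS", object_cui = "C0000010", object_name = "y",
      object_semtype = "menp", pmid = "1"))
  }
  expect_equal(graph_node(g, "C0000009")$primary_type, "hops")
})

test_that("neighbor queries agree with exhaustive edge scans on random graphs", {
  for (seed in 1:8) {
    rg <- random_graph(seed, n_nodes = sample(10:30, 1),
                       n_edges = sample(30:120, 1))
    g <- rg$graph
    nd <- graph_nodes(g)
    preds <- c(list(NULL), as.list(unique(graph_edges(g)$predicate)[1]))
    types <- c(list(NULL), as.list(unique(nd$primary_type)[1]))
    for (cui in sample(nd$cui, min(6, nrow(nd)))) {
      for (orient in c("forward", "reverse")) {
        for (p in preds) {
          for (ty in types) {
            expect_identical(
              node_neighbors(g, cui, p, orient, ty),
              oracle_neighbors(g, cui, p, orient, ty))
          }
        }
      }
    }
  }
  expect_error(node_neighbors(random_graph(1)$graph, "C9999999"),
               class = "lbd_missing_node_error")
})

test_that("toy-graph neighbor/degree reads match the adjacency by hand", {
  g <- fixture_toy_graph()
  expect_equal(node_neighbors(g, "C0000001", "R1", "forward"),
               c("C0000002", "C0000003"))
  expect_equal(node_neighbors(g, "C0000001", "R1", "reverse"), character())
  expect_equal(metaedge_degree(g, "C0000001", c("A", "R1", "B"), "source"), 2)
  expect_equal(metaedge_degree(g, "C0000004", c("A", "R1", "B"), "source"), 0)
  expect_equal(metaedge_degree(g, "C0000004", c("B", "R2", "C"), "target"), 2)
})

test_that("metaedge degrees agree with exhaustive scans on random graphs", {
  for (seed in 11:16) {
    rg <- random_graph(seed, n_nodes = 25, n_edges = 100)
    g <- rg$graph
    mg <- derive_metagraph(g)
    me_df <- mg$metaedges[sample(nrow(mg$metaedges), min(5, nrow(mg$metaedges))), ]
    for (cui in sample(graph_nodes(g)$cui, 5)) {
      for (r in seq_len(nrow(me_df))) {
        me <- unlist(me_df[r, ], use.names = FALSE)
        for (side in c("source", "target")) {
          expect_equal(metaedge_degree(g, cui, me, side),
                       oracle_degree(g, cui, me, side))
        }
      }
    }
  }
})

test_that("loading records in any order preserves edges, weights, pmid sets", {
  rg <- random_graph(21, n_nodes = 15, n_edges = 50)
  df <- rg$records
  set.seed(99)
  df2 <- df[sample(nrow(df)), , drop = FALSE]
  g1 <- load_predications(write_records(df))
  g2 <- load_predications(write_records(df2))
  expect_identical(graph_edges(g1), graph_edges(g2))
  n1 <- graph_nodes(g1); n2 <- graph_nodes(g2)
  expect_identical(n1$cui, n2$cui)
  # type count multisets match even where first-seen order differs
  canon <- function(tc) {
    lapply(strsplit(tc, ";", fixed = TRUE), sort)
  }
  expect_identical(canon(n1$type_counts), canon(n2$type_counts))
})

test_that("edge weights conserve the input record count", {
  for (seed in c(31, 32)) {
    rg <- random_graph(seed, n_nodes = 12, n_edges = 60, dup_frac = 0.3)
    ed <- graph_edges(rg$graph)
    expect_equal(sum(ed$weight), nrow(rg$records))
    n_pmids <- sum(lengths(strsplit(ed$pmids, ";", fixed = TRUE)))
    expect_lte(n_pmids, nrow(rg$records))
  }
})

test_that("the derived metagraph lists exactly the realized metaedges", {
  g <- fixture_toy_graph()
  mg <- derive_metagraph(g)
  expect_equal(mg$node_types, c("A", "B", "C"))
  expect_equal(mg$predicates, c("R1", "R2"))
  expect_equal(mg$metaedges,
               data.frame(source_type = c("A", "B"), predicate = c("R1", "R2"),
                          target_type = c("B", "C"), stringsAsFactors = FALSE))
})
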