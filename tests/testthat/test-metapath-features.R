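toy <- fixture_toy_graph()
toy_mp <- metapath(c("A", "B"), c("R1", "R2"), c("B", "C"))

test_that("metapath strings round-trip through the canonical grammar", {
  mps <- list(
    toy_mp,
    metapath("A", "R1", "B"),
    metapath(c("A", "B"), c("R1", "R1"), c("B", "A"), rev = c(FALSE, TRUE)),
    metapath(c("X", "Y", "Z"), c("P_1", "P_2", "P_3"), c("Y", "Z", "W"),
             rev = c(TRUE, FALSE, TRUE)))
  for (mp in mps) {
    expect_equal(parse_metapath(format(mp)), mp)
  }
  expect_equal(format(mps[[3]]), "A-R1>B<R1-A")
  expect_error(parse_metapath("A-R1"), class = "lbd_parse_error")
  expect_error(metapath(c("A", "C"), c("R1", "R2"), c("B", "D")),
               class = "lbd_parse_error")
})

test_that("source discovery evaluates boolean neighborhood rules", {
  # neighborhoods: N(L)={a,b}, N(M)={b,c}, N(Nic)={b,d}
  g <- hetero_graph()
  lk <- c(L = "C0000100", M = "C0000200", Nic = "C0000300",
          a = "C0000001", b = "C0000002", c = "C0000003", d = "C0000004")
  link <- function(x, y) {
    add_predication_record(g, list(
      subject_cui = lk[[x]], subject_name = x, subject_semtype = "tt",
      predicate = "REL", object_cui = lk[[y]], object_name = y,
      object_semtype = "tt", pmid = "1"))
  }
  link("L", "a"); link("L", "b"); link("M", "b"); link("c", "M")
  link("b", "Nic"); link("Nic", "d")
  expect_equal(find_sources(g, "(C0000100 OR C0000200) AND C0000300"),
               lk[["b"]])
  expect_equal(find_sources(g, "C0000100"), sort(unname(lk[c("a", "b")])))
  expect_error(find_sources(g, "C0099999"), class = "lbd_missing_node_error")
  expect_error(find_sources(g, "(C0000100 OR"), "position",
               class = "lbd_parse_error")
  expect_error(find_sources(g, "C0000100 banana C0000200"),
               class = "lbd_parse_error")
})

test_that("random source rules match brute-force set algebra", {
  for (seed in 41:45) {
    rg <- random_graph(seed, n_nodes = 20, n_edges = 80)
    g <- rg$graph
    cuis <- sample(graph_nodes(g)$cui, 3)
    nb <- lapply(cuis, function(cu) {
      sort(unique(c(oracle_neighbors(g, cu, orientation = "forward"),
                    oracle_neighbors(g, cu, orientation = "reverse"))))
    })
    rule <- sprintf("(%s OR %s) AND %s", cuis[1], cuis[2], cuis[3])
    expect_equal(find_sources(g, rule),
                 sort(intersect(union(nb[[1]], nb[[2]]), nb[[3]])))
    rule2 <- sprintf("%s AND %s OR %s", cuis[1], cuis[2], cuis[3])
    expect_equal(find_sources(g, rule2),
                 sort(union(intersect(nb[[1]], nb[[2]]), nb[[3]])))
  }
})

test_that("toy-graph path enumeration finds exactly the two-step paths", {
  ep <- enumerate_paths(toy, "C0000001", "C0000004", 2, forward_only = TRUE)
  expect_equal(names(ep), "A-R1>B-R2>C")
  expect_equal(ep[[1]]$paths,
               list(c("C0000001", "C0000002", "C0000004"),
                    c("C0000001", "C0000003", "C0000004")))
  expect_equal(length(enumerate_paths(toy, "C0000001", "C0000004", 1)), 0L)
})

test_that("path enumeration equals the exhaustive DFS oracle on random graphs", {
  for (seed in 51:58) {
    rg <- random_graph(seed, n_nodes = sample(8:20, 1),
                       n_edges = sample(20:60, 1))
    g <- rg$graph
    cuis <- graph_nodes(g)$cui
    ml <- sample(2:3, 1)
    for (rep in 1:2) {
      st <- sample(cuis, 2, replace = (rep == 2)) # includes s == t case
      got <- enumerate_paths(g, st[1], st[2], ml)
      want <- oracle_enumerate(g, st[1], st[2], ml)
      expect_equal(names(got), names(want))
      expect_equal(lapply(got, `[[`, "paths"), want,
                   ignore_attr = TRUE)
      # forward-only mode agrees too
      gotf <- enumerate_paths(g, st[1], st[2], ml, forward_only = TRUE)
      wantf <- oracle_enumerate(g, st[1], st[2], ml, forward_only = TRUE)
      expect_equal(lapply(gotf, `[[`, "paths"), wantf, ignore_attr = TRUE)
    }
  }
})

test_that("DWPC down-weights by metaedge-specific degrees", {
  ep <- enumerate_paths(toy, "C0000001", "C0000004", 2)
  paths <- ep[["A-R1>B-R2>C"]]$paths
  # each path's degree product is 2*1*1*2 = 4
  expect_equal(dwpc(toy, toy_mp, paths, 0.4), 2 * 4^(-0.4), tolerance = 1e-12)
  expect_identical(dwpc(toy, toy_mp, paths, 0), 2) # w = 0 is the plain count
  # single path with all incident degrees 1
  g1 <- hetero_graph()
  for (e in list(c("C0000011", "C0000012"), c("C0000012", "C0000013"))) {
    add_predication_record(g1, list(
      subject_cui = e[1], subject_name = e[1],
      subject_semtype = substr(e[1], 7, 8), predicate = "P",
      object_cui = e[2], object_name = e[2],
      object_semtype = substr(e[2], 7, 8), pmid = "1"))
  }
  mp1 <- metapath(c("11", "12"), c("P", "P"), c("12", "13"))
  for (w in c(0, 0.4, 1, 3)) {
    expect_equal(dwpc(g1, mp1, list(c("C0000011", "C0000012", "C0000013")), w),
                 1.0)
  }
  # non-increasing in w
  expect_true(dwpc(toy, toy_mp, paths, 0.8) <= dwpc(toy, toy_mp, paths, 0.4))
})

test_that("HeteSim follows the pairwise-mean recursion with delta base case", {
  expect_equal(hetesim(toy, "C0000001", "C0000004", toy_mp), 0.5)
  # empty path: delta(s, t)
  expect_equal(lbdgraph:::hs_rec(toy, "C0000001", "C0000001", NULL), 1)
  expect_equal(lbdgraph:::hs_rec(toy, "C0000001", "C0000004", NULL), 0)
  # length-1 metapath: edge indicator over the product of metaedge degrees
  mp_1 <- metapath("A", "R1", "B")
  expect_equal(hetesim(toy, "C0000001", "C0000002", mp_1), 1 / (2 * 1))
  # disjoint neighbor sets -> 0
  g <- hetero_graph()
  for (e in list(c("C0000021", "C0000022"), c("C0000023", "C0000024"))) {
    add_predication_record(g, list(
      subject_cui = e[1], subject_name = "s", subject_semtype = "A",
      predicate = "R", object_cui = e[2], object_name = "o",
      object_semtype = "B", pmid = "1"))
  }
  # s=C0000021 reaches {22}, t=C0000023 emits {24}: no meeting node
  mp3 <- metapath(c("A", "B"), c("R", "R"), c("B", "A"),
                  rev = c(FALSE, TRUE))
  expect_equal(hetesim(g, "C0000021", "C0000023", mp3), 0)
  # type mismatch is rejected
  expect_error(hetesim(toy, "C0000002", "C0000004", toy_mp),
               class = "lbd_applicability_error")
})

test_that("the feature tensor matches component values on the toy graph", {
  X <- build_feature_tensor(toy, "C0000001", "C0000004")
  expect_equal(dim(X), c(1, 1, 1, 3))
  expect_equal(dimnames(X)[[3]], "A-R1>B-R2>C")
  expect_equal(unname(X[1, 1, 1, ]), c(2, 2 * 4^(-0.4), 0.5),
               tolerance = 1e-12)
  # self-target run includes the out-and-back metapath with 2 closed walks
  Xs <- build_feature_tensor(toy, "C0000001", "C0000001")
  expect_true("A-R1>B<R1-A" %in% dimnames(Xs)[[3]])
  expect_equal(Xs[1, 1, "A-R1>B<R1-A", "count"], 2)
  # a disconnected source contributes an all-zero row
  g2 <- fixture_toy_graph()
  add_predication_record(g2, list(
    subject_cui = "C0000005", subject_name = "x", subject_semtype = "A",
    predicate = "R1", object_cui = "C0000006", object_name = "y",
    object_semtype = "B", pmid = "9"))
  Xd <- build_feature_tensor(g2, c("C0000001", "C0000005"), "C0000004")
  expect_true(all(Xd["C0000005", , , ] == 0))
  expect_gt(sum(Xd["C0000001", , , ]), 0)
})

test_that("tensor cells are zero or positive across all three features together", {
  for (seed in 61:64) {
    rg <- random_graph(seed, n_nodes = 15, n_edges = 50)
    g <- rg$graph
    cuis <- sample(graph_nodes(g)$cui, 4)
    X <- build_feature_tensor(g, cuis[1:2], cuis[3:4])
    pos <- X > 0
    expect_identical(pos[, , , "count"], pos[, , , "dwpc"])
    expect_identical(pos[, , , "count"], pos[, , , "hetesim"])
    expect_true(all(X[, , , "hetesim"] <= 1 + 1e-12))
    expect_true(all(X >= 0))
    # w = 0 collapses dwpc onto count exactly
    X0 <- build_feature_tensor(g, cuis[1:2], cuis[3:4], w = 0)
    expect_identical(X0[, , , "dwpc"], X0[, , , "count"])
  }
})

test_that("the length-2 closed form |O∩I|/(|O||I|) equals the recursion", {
  set.seed(71)
  checked <- 0L
  for (seed in 71:75) {
    rg <- random_graph(seed, n_nodes = 15, n_edges = 60)
    g <- rg$graph
    cuis <- graph_nodes(g)$cui
    for (rep in 1:6) {
      st <- sample(cuis, 2)
      ep <- enumerate_paths(g, st[1], st[2], 2)
      for (k in names(ep)) {
        mp <- ep[[k]]$metapath
        if (nrow(mp) != 2L) next
        O <- lbdgraph:::step_out_set(g, st[1], mp[1, ])
        I <- lbdgraph:::step_in_set(g, st[2], mp[2, ])
        closed <- length(intersect(O, I)) / (length(O) * length(I))
        expect_equal(hetesim(g, st[1], st[2], mp), closed, tolerance = 1e-15)
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 10L)
})

test_that("adding a path instance never decreases count or DWPC for its cell", {
  rg <- random_graph(81, n_nodes = 12, n_edges = 40)
  g <- load_predications(write_records(rg$records)) # open vocabulary copy
  nd <- graph_nodes(g)
  s <- nd$cui[1]; t <- nd$cui[2]
  before <- build_feature_tensor(g, s, t)
  # create a fresh two-step path via a new intermediate node
  mid <- "C0009999"
  ty_s <- nd$primary_type[1]; ty_t <- nd$primary_type[2]
  add_predication_record(g, list(
    subject_cui = s, subject_name = s, subject_semtype = ty_s,
    predicate = "P1", object_cui = mid, object_name = mid,
    object_semtype = "tyX", pmid = "1"))
  add_predication_record(g, list(
    subject_cui = mid, subject_name = mid, subject_semtype = "tyX",
    predicate = "P1", object_cui = t, object_name = t,
    object_semtype = ty_t, pmid = "1"))
  after <- build_feature_tensor(g, s, t)
  key <- sprintf("%s-P1>tyX-P1>%s", ty_s, ty_t)
  expect_true(key %in% dimnames(after)[[3]])
  for (m in intersect(dimnames(before)[[3]], dimnames(after)[[3]])) {
    expect_gte(after[1, 1, m, "count"], before[1, 1, m, "count"])
  }
  expect_gte(after[1, 1, key, "count"], 1)
  expect_gt(after[1, 1, key, "dwpc"], 0)
})
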