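#' Configuration for the synthetic predication-graph generator
#'
#' Describes a desk-scale SemMedDB-like heterogeneous graph: a node-type
#' vocabulary with per-type node counts, a predicate vocabulary with the
#' allowed metaedges and per-metaedge edge budgets, an endpoint-degree model
#' (uniform, or heavy-tailed with Pareto-distributed propensities so some
#' concepts become literature hubs), an optional multi-type observation
#' probability, a PMID pool, and an optional record duplication rate (which
#' produces edges of weight above 1). A seed is mandatory: generation is a
#' pure function of the configuration.
#'
#' @param node_types named positive integer vector: nodes per semantic type.
#' @param metaedges data frame with columns `from_type`, `predicate`,
#'   `to_type`, `n_edges`.
#' @param degree_model `"uniform"` or `"heavy_tailed"`.
#' @param alpha Pareto tail exponent for the heavy-tailed model (must be
#'   `> 1`; default 2.5).
#' @param multi_type_prob probability that a node is also observed under a
#'   second semantic type (default 0).
#' @param pmid_pool number of distinct article identifiers to draw from.
#' @param duplicate_rate fraction of records re-emitted with a fresh PMID
#'   (creates weight-2 edges; default 0).
#' @param seed integer RNG seed (required).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(node_types, metaedges,
                         degree_model = c("uniform", "heavy_tailed"),
                         alpha = 2.5, multi_type_prob = 0,
                         pmid_pool = 10000L, duplicate_rate = 0, seed) {
  degree_model <- match.arg(degree_model)
  if (missing(seed)) lbd_stop("lbd_schema_error", "a seed is required")
  stopifnot(is.numeric(node_types), all(node_types >= 1),
            !is.null(names(node_types)),
            is.data.frame(metaedges),
            all(c("from_type", "predicate", "to_type", "n_edges") %in%
                  names(metaedges)),
            alpha > 1, multi_type_prob >= 0, multi_type_prob <= 1,
            pmid_pool >= 1, duplicate_rate >= 0, duplicate_rate <= 1)
  bad <- setdiff(c(metaedges$from_type, metaedges$to_type), names(node_types))
  if (length(bad)) {
    lbd_stop("lbd_vocab_error", "metaedge uses unknown node type: %s", bad[1])
  }
  structure(list(node_types = node_types, metaedges = metaedges,
                 degree_model = degree_model, alpha = alpha,
                 multi_type_prob = multi_type_prob,
                 pmid_pool = as.integer(pmid_pool),
                 duplicate_rate = duplicate_rate, seed = as.integer(seed)),
            class = "synth_config")
}

## deterministic node roster for a config: cui, name, type
synth_nodes <- function(config) {
  types <- names(config$node_types)
  counts <- as.integer(config$node_types)
  cui_id <- 0L
  rows <- list()
  for (j in seq_along(types)) {
    ids <- cui_id + seq_len(counts[j])
    cui_id <- cui_id + counts[j]
    rows[[j]] <- data.frame(cui = sprintf("C%07d", ids),
                            name = sprintf("%s_%d", types[j],
                                           seq_len(counts[j])),
                            type = types[j], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic predication record table
#'
#' Produces a SemMedDB-style record table (default schema columns) honoring
#' the configuration's vocabularies and metaedge budgets. Under the
#' heavy-tailed degree model, endpoint propensities are Pareto draws, so a
#' few concepts accumulate many edges (the literature's bias toward highly
#' referenced concepts); the uniform model picks endpoints uniformly.
#' Multi-typed nodes are emulated by relabeling a strict minority of a
#' node's mentions to a secondary type, so the primary (most common) type is
#' never flipped. Fully reproducible from the config seed.
#'
#' @param config a [synth_config()].
#' @return data frame with columns `PMID`, `PREDICATE`, `SUBJECT_CUI`,
#'   `SUBJECT_NAME`, `SUBJECT_SEMTYPE`, `OBJECT_CUI`, `OBJECT_NAME`,
#'   `OBJECT_SEMTYPE`.
#' @export
generate_predications <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  roster <- synth_nodes(config)
  with_seed(config$seed, {
    prop <- if (config$degree_model == "heavy_tailed") {
      stats::runif(nrow(roster))^(-1 / (config$alpha - 1))
    } else {
      rep(1, nrow(roster))
    }
    names(prop) <- roster$cui
    recs <- list()
    for (i in seq_len(nrow(config$metaedges))) {
      me <- config$metaedges[i, ]
      if (me$n_edges < 1L) next
      from_nodes <- roster[roster$type == me$from_type, , drop = FALSE]
      to_nodes <- roster[roster$type == me$to_type, , drop = FALSE]
      n_pairs <- nrow(from_nodes) * nrow(to_nodes) -
        if (me$from_type == me$to_type) nrow(from_nodes) else 0L
      if (me$n_edges > n_pairs) {
        lbd_stop("lbd_capacity_error",
                 "metaedge %s-%s>%s: %d edges requested, only %d pairs exist",
                 me$from_type, me$predicate, me$to_type, me$n_edges, n_pairs)
      }
      seen <- new.env(parent = emptyenv())
      got <- 0L
      subj <- character(me$n_edges); obj <- character(me$n_edges)
      guard <- 0L
      while (got < me$n_edges) {
        guard <- guard + 1L
        if (guard > 200L * me$n_edges + 1000L) {
          lbd_stop("lbd_capacity_error",
                   "could not place %d distinct edges for %s-%s>%s",
                   me$n_edges, me$from_type, me$predicate, me$to_type)
        }
        s <- sample(from_nodes$cui, 1L, prob = prop[from_nodes$cui])
        o <- sample(to_nodes$cui, 1L, prob = prop[to_nodes$cui])
        if (s == o) next
        key <- paste(s, o, sep = "\r")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        got <- got + 1L
        subj[got] <- s; obj[got] <- o
      }
      recs[[i]] <- data.frame(PREDICATE = me$predicate, SUBJECT_CUI = subj,
                              OBJECT_CUI = obj, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, recs)
    if (!is.null(df) && nrow(df)) {
      if (config$duplicate_rate > 0) {
        dup <- which(stats::runif(nrow(df)) < config$duplicate_rate)
        if (length(dup)) df <- rbind(df, df[dup, , drop = FALSE])
      }
      df$PMID <- as.character(sample.int(config$pmid_pool, nrow(df),
                                         replace = TRUE))
    } else {
      df <- data.frame(PREDICATE = character(), SUBJECT_CUI = character(),
                       OBJECT_CUI = character(), PMID = character(),
                       stringsAsFactors = FALSE)
    }
    name_of <- stats::setNames(roster$name, roster$cui)
    type_of <- stats::setNames(roster$type, roster$cui)
    df$SUBJECT_NAME <- unname(name_of[df$SUBJECT_CUI])
    df$SUBJECT_SEMTYPE <- unname(type_of[df$SUBJECT_CUI])
    df$OBJECT_NAME <- unname(name_of[df$OBJECT_CUI])
    df$OBJECT_SEMTYPE <- unname(type_of[df$OBJECT_CUI])
    ## multi-typed nodes: relabel a strict minority of a node's mentions
    if (config$multi_type_prob > 0 && nrow(df) &&
        length(config$node_types) >= 2L) {
      multi <- roster$cui[stats::runif(nrow(roster)) < config$multi_type_prob]
      all_types <- names(config$node_types)
      for (cu in multi) {
        second <- sample(setdiff(all_types, type_of[[cu]]), 1L)
        s_rows <- which(df$SUBJECT_CUI == cu)
        o_rows <- which(df$OBJECT_CUI == cu)
        total <- length(s_rows) + length(o_rows)
        n_flip <- (total - 1L) %/% 2L
        if (n_flip < 1L) next
        flip <- sample(total, n_flip)
        for (fidx in flip) {
          if (fidx <= length(s_rows)) {
            df$SUBJECT_SEMTYPE[s_rows[fidx]] <- second
          } else {
            df$OBJECT_SEMTYPE[o_rows[fidx - length(s_rows)]] <- second
          }
        }
      }
    }
    rownames(df) <- NULL
    df[, c("PMID", "PREDICATE", "SUBJECT_CUI", "SUBJECT_NAME",
           "SUBJECT_SEMTYPE", "OBJECT_CUI", "OBJECT_NAME", "OBJECT_SEMTYPE")]
  })
}

#' Generate a synthetic heterogeneous concept graph
#'
#' Builds the graph by streaming the records of [generate_predications()]
#' through [add_predication_record()], so all graph invariants hold by
#' construction. Roster nodes that no sampled record mentions are added as
#' isolated nodes (observed once under their declared type), so the graph
#' always carries the configured node census.
#'
#' @param config a [synth_config()].
#' @return a [hetero_graph()].
#' @export
generate_graph <- function(config) {
  df <- generate_predications(config)
  g <- hetero_graph(predicates = unique(config$metaedges$predicate),
                    semtypes = names(config$node_types))
  for (i in seq_len(nrow(df))) {
    add_predication_record(g, list(
      subject_cui = df$SUBJECT_CUI[i], subject_name = df$SUBJECT_NAME[i],
      subject_semtype = df$SUBJECT_SEMTYPE[i], predicate = df$PREDICATE[i],
      object_cui = df$OBJECT_CUI[i], object_name = df$OBJECT_NAME[i],
      object_semtype = df$OBJECT_SEMTYPE[i], pmid = df$PMID[i]))
  }
  roster <- synth_nodes(config)
  for (i in seq_len(nrow(roster))) {
    if (!has_node(g, roster$cui[i])) {
      upsert_node(g, roster$cui[i], roster$name[i], roster$type[i])
      invalidate_index(g)
    }
  }
  g
}

#' Plant node-disjoint metapath instances between a source and a target
#'
#' Adds `n_paths` node-disjoint instances of a (currently length-2) metapath
#' between `source` and `target`, choosing intermediate nodes of the middle
#' type whose step edges do not yet exist, so the count feature for the
#' planted cell increases by exactly `n_paths`. The planted truth is recorded
#' on the graph (`graph$planted`).
#'
#' @param graph a [hetero_graph()] (mutated in place).
#' @param source,target CUIs present in the graph.
#' @param mp a forward two-step [metapath()] whose end types match the nodes.
#' @param n_paths number of disjoint instances to add.
#' @return the graph, invisibly.
#' @export
plant_association <- function(graph, source, target, mp, n_paths) {
  stopifnot(inherits(mp, "metapath"), n_paths >= 1)
  if (nrow(mp) != 2L || any(mp$rev)) {
    lbd_stop("lbd_schema_error",
             "only forward length-2 metapaths can be planted")
  }
  idx <- graph_index(graph)
  mid_type <- mp$to_type[1]
  candidates <- names(idx$ptype)[idx$ptype == mid_type]
  candidates <- setdiff(candidates, c(source, target))
  usable <- candidates[vapply(candidates, function(m) {
    is.null(graph$edges[[edge_key(source, mp$predicate[1], m)]]) &&
      is.null(graph$edges[[edge_key(m, mp$predicate[2], target)]])
  }, logical(1))]
  if (length(usable) < n_paths) {
    lbd_stop("lbd_capacity_error",
             "need %d spare intermediate nodes of type %s, found %d",
             n_paths, mid_type, length(usable))
  }
  mids <- sort(usable)[seq_len(n_paths)]
  k <- 0L
  for (m in mids) {
    k <- k + 1L
    add_predication_record(graph, list(
      subject_cui = source, subject_name = graph_node(graph, source)$name,
      subject_semtype = mp$from_type[1], predicate = mp$predicate[1],
      object_cui = m, object_name = graph_node(graph, m)$name,
      object_semtype = mid_type, pmid = sprintf("planted%d_1", k)))
    add_predication_record(graph, list(
      subject_cui = m, subject_name = graph_node(graph, m)$name,
      subject_semtype = mid_type, predicate = mp$predicate[2],
      object_cui = target, object_name = graph_node(graph, target)$name,
      object_semtype = mp$to_type[2], pmid = sprintf("planted%d_2", k)))
  }
  graph$planted <- rbind(graph$planted,
                         data.frame(source = source, target = target,
                                    metapath = format(mp), n_paths = n_paths,
                                    stringsAsFactors = FALSE))
  invisible(graph)
}

#' The documented toy fixture graph
#'
#' Four nodes — a source `s` of type `A`, two intermediates `m1`, `m2` of
#' type `B`, a target `t` of type `C` — and four unit-weight edges
#' `s-[R1]->m1`, `s-[R1]->m2`, `m1-[R2]->t`, `m2-[R2]->t`. Along the
#' metapath `A-R1>B-R2>C` it has exactly two paths, DWPC
#' `2 * 4^(-w)` and HeteSim `0.5`, which makes it a convenient hand-checkable
#' fixture.
#'
#' @return a [hetero_graph()] with nodes `C0000001` (s), `C0000002` (m1),
#'   `C0000003` (m2), `C0000004` (t).
#' @export
fixture_toy_graph <- function() {
  g <- hetero_graph(predicates = c("R1", "R2"), semtypes = c("A", "B", "C"))
  rec <- function(s, st, p, o, ot, pm) {
    names_ <- c(C0000001 = "s", C0000002 = "m1", C0000003 = "m2",
                C0000004 = "t")
    add_predication_record(g, list(
      subject_cui = s, subject_name = unname(names_[s]), subject_semtype = st,
      predicate = p, object_cui = o, object_name = unname(names_[o]),
      object_semtype = ot, pmid = pm))
  }
  rec("C0000001", "A", "R1", "C0000002", "B", "1")
  rec("C0000001", "A", "R1", "C0000003", "B", "2")
  rec("C0000002", "B", "R2", "C0000004", "C", "3")
  rec("C0000003", "B", "R2", "C0000004", "C", "4")
  g
}

#' Default synthetic study conditions for planted-association recovery
#'
#' A desk-scale SemMedDB-like background: 100 source-type nodes (`srce`), 80
#' intermediates (`inte`), 20 target-type nodes (`trgt`), 2000 edges split
#' 1200 `srce-REL1>inte`, 500 `inte-REL2>trgt`, 300 `srce-REL3>trgt`, with
#' heavy-tailed (alpha = 2.5) endpoint propensities — sparse enough that
#' spare intermediates remain available for planting associations.
#'
#' @param seed integer seed.
#' @return a [synth_config()].
#' @export
planted_recovery_config <- function(seed) {
  synth_config(
    node_types = c(srce = 100L, inte = 80L, trgt = 20L),
    metaedges = data.frame(
      from_type = c("srce", "inte", "srce"),
      predicate = c("REL1", "REL2", "REL3"),
      to_type = c("inte", "trgt", "trgt"),
      n_edges = c(1200L, 500L, 300L),
      stringsAsFactors = FALSE),
    degree_model = "heavy_tailed", alpha = 2.5, seed = seed)
}

#' End-to-end planted-association recovery simulation
#'
#' For each trial: generate a background graph under
#' [planted_recovery_config()], plant `n_paths` node-disjoint length-2
#' metapath instances from one randomly chosen source-type node to one
#' target-type node, compute the HeteSim feature tensor for all source-type
#' nodes against that target, aggregate the HeteSim rankers with ULARA, and
#' record whether the planted source's aggregate rank beats the median
#' unplanted source.
#'
#' @param n_trials number of independent trials.
#' @param seed base seed; trial `i` uses `seed * 1000 + i`.
#' @param n_paths planted path instances per trial (default 5).
#' @return data frame with one row per trial: `seed`, `planted_rank`,
#'   `median_unplanted_rank`, `success`.
#' @export
simulate_planted_recovery <- function(n_trials = 50, seed = 1, n_paths = 5) {
  res <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    trial_seed <- seed * 1000L + i
    cfg <- planted_recovery_config(trial_seed)
    g <- generate_graph(cfg)
    roster <- synth_nodes(cfg)
    ## only nodes observed in at least one predication exist in the graph
    present <- vapply(roster$cui, function(cu) has_node(g, cu), logical(1))
    sources <- roster$cui[roster$type == "srce" & present]
    target <- roster$cui[roster$type == "trgt" & present][1]
    planted <- with_seed(trial_seed + 500000L, sample(sources, 1L))
    mp <- metapath(c("srce", "inte"), c("REL1", "REL2"), c("inte", "trgt"))
    plant_association(g, planted, target, mp, n_paths)
    X <- build_feature_tensor(g, sources, target, max_len = 2,
                              features = "hetesim")
    R <- build_rank_matrix(X, features = "hetesim")
    agg <- ulara_aggregate(R)
    ranks <- aggregate_ranks(agg)
    pr <- ranks[[planted]]
    med <- stats::median(ranks[names(ranks) != planted])
    res[[i]] <- data.frame(seed = trial_seed, planted_rank = pr,
                           median_unplanted_rank = med,
                           success = pr < med)
  }
  do.call(rbind, res)
}
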