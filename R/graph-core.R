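#' Create an empty heterogeneous concept graph
#'
#' A concept graph holds one node per UMLS concept (CUI) and one directed,
#' typed edge per unique (subject, predicate, object) triple. Loading the same
#' triple again increments the edge weight and unions the article identifier
#' (PMID) set; a concept observed under several semantic types keeps per-type
#' observation counts, and its *primary* type is the most commonly observed
#' one, with ties broken by first observation order.
#'
#' The graph is environment-backed: functions that add records mutate it in
#' place and return it invisibly (reference semantics, as in `data.table` or
#' `igraph` handles). Query functions never mutate.
#'
#' @param predicates optional character vector: the allowed predicate
#'   vocabulary. `NULL` accepts any predicate code.
#' @param semtypes optional character vector: the allowed semantic-type
#'   vocabulary. `NULL` accepts any type code.
#' @return an object of class `hetero_graph`.
#' @export
hetero_graph <- function(predicates = NULL, semtypes = NULL) {
  g <- new.env(parent = emptyenv())
  g$nodes <- new.env(parent = emptyenv()) # cui -> node list
  g$edges <- new.env(parent = emptyenv()) # "s|p|o" -> edge list
  g$out <- new.env(parent = emptyenv())   # cui -> character vector of edge keys
  g$inn <- new.env(parent = emptyenv())
  g$vocab <- list(predicates = predicates, semtypes = semtypes)
  g$n_records <- 0L
  g$index <- NULL
  class(g) <- "hetero_graph"
  g
}

edge_key <- function(s, p, o) paste(s, p, o, sep = "\r")

invalidate_index <- function(g) {
  g$index <- NULL
  invisible(g)
}

#' Add one raw predication record to a graph
#'
#' Upserts both endpoint nodes (incrementing their semantic-type observation
#' counts and re-deriving the primary type) and the edge (weight `+1`, PMID
#' unioned into the edge's article set).
#'
#' @param graph a [hetero_graph()].
#' @param record named list or one-row data frame with fields `subject_cui`,
#'   `subject_name`, `subject_semtype`, `predicate`, `object_cui`,
#'   `object_name`, `object_semtype`, `pmid`.
#' @return the graph, invisibly (mutated in place).
#' @export
add_predication_record <- function(graph, record) {
  stopifnot(inherits(graph, "hetero_graph"))
  need <- c("subject_cui", "subject_name", "subject_semtype", "predicate",
            "object_cui", "object_name", "object_semtype", "pmid")
  missing_f <- setdiff(need, names(record))
  if (length(missing_f)) {
    lbd_stop("lbd_schema_error", "record is missing field(s): %s",
             paste(missing_f, collapse = ", "))
  }
  rec <- lapply(record[need], function(x) as.character(x)[1])
  assert_cui(rec$subject_cui, "subject")
  assert_cui(rec$object_cui, "object")
  voc <- graph$vocab
  if (!is.null(voc$predicates) && !(rec$predicate %in% voc$predicates)) {
    lbd_stop("lbd_vocab_error", "unknown predicate code: %s", rec$predicate)
  }
  for (st in c(rec$subject_semtype, rec$object_semtype)) {
    if (!is.null(voc$semtypes) && !(st %in% voc$semtypes)) {
      lbd_stop("lbd_vocab_error", "unknown semantic-type code: %s", st)
    }
  }
  upsert_node(graph, rec$subject_cui, rec$subject_name, rec$subject_semtype)
  upsert_node(graph, rec$object_cui, rec$object_name, rec$object_semtype)

  key <- edge_key(rec$subject_cui, rec$predicate, rec$object_cui)
  e <- graph$edges[[key]]
  if (is.null(e)) {
    e <- list(subject_cui = rec$subject_cui, predicate = rec$predicate,
              object_cui = rec$object_cui, weight = 1L, pmids = rec$pmid)
    graph$out[[rec$subject_cui]] <- c(graph$out[[rec$subject_cui]], key)
    graph$inn[[rec$object_cui]] <- c(graph$inn[[rec$object_cui]], key)
  } else {
    e$weight <- e$weight + 1L
    e$pmids <- sort(unique(c(e$pmids, rec$pmid)))
  }
  graph$edges[[key]] <- e
  graph$n_records <- graph$n_records + 1L
  invalidate_index(graph)
  invisible(graph)
}

upsert_node <- function(g, cui, name, semtype) {
  n <- g$nodes[[cui]]
  if (is.null(n)) {
    n <- list(cui = cui, name = name,
              type_counts = stats::setNames(1L, semtype),
              type_first_seen = semtype,
              primary_type = semtype)
  } else {
    if (semtype %in% names(n$type_counts)) {
      n$type_counts[[semtype]] <- n$type_counts[[semtype]] + 1L
    } else {
      n$type_counts <- c(n$type_counts, stats::setNames(1L, semtype))
      n$type_first_seen <- c(n$type_first_seen, semtype)
    }
    n$primary_type <- resolve_primary_type(n)
  }
  g$nodes[[cui]] <- n
  invisible(n)
}

#' Resolve the primary semantic type of a concept node
#'
#' The primary type is the most commonly observed type; ties are broken in
#' favour of the type observed first in the input stream.
#'
#' @param node a concept-node list with `type_counts` (named positive integer
#'   vector) and `type_first_seen` (character vector in first-observation
#'   order).
#' @return a single semantic-type code.
#' @export
resolve_primary_type <- function(node) {
  tc <- node$type_counts
  if (is.null(tc) || length(tc) == 0L) {
    lbd_stop("lbd_internal_error", "node has empty type_counts")
  }
  best <- names(tc)[tc == max(tc)]
  if (length(best) == 1L) return(best)
  fs <- node$type_first_seen
  fs[fs %in% best][1]
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("<hetero_graph> %d nodes, %d edges, %d records loaded\n",
              node_count(x), edge_count(x), x$n_records))
  invisible(x)
}

#' Number of nodes / edges in a graph
#' @param graph a [hetero_graph()].
#' @return integer count.
#' @export
node_count <- function(graph) length(ls(graph$nodes))

#' @rdname node_count
#' @export
edge_count <- function(graph) length(ls(graph$edges))

#' Retrieve one concept node
#' @param graph a [hetero_graph()].
#' @param cui concept identifier.
#' @return the node list (`cui`, `name`, `type_counts`, `type_first_seen`,
#'   `primary_type`), or an error for an unknown CUI.
#' @export
graph_node <- function(graph, cui) {
  n <- graph$nodes[[cui]]
  if (is.null(n)) lbd_stop("lbd_missing_node_error", "unknown node: %s", cui)
  n
}

has_node <- function(graph, cui) !is.null(graph$nodes[[cui]])

#' Node and edge tables of a graph
#'
#' Deterministic data-frame views (sorted by CUI / edge key). `type_counts`
#' and `type_first_seen` are serialized as `"type:count"` pairs joined by
#' `";"` in first-seen order; `pmids` as a sorted `";"`-joined list.
#'
#' @param graph a [hetero_graph()].
#' @return a data frame.
#' @export
graph_nodes <- function(graph) {
  cuis <- sort(ls(graph$nodes))
  rows <- lapply(cuis, function(cu) {
    n <- graph$nodes[[cu]]
    data.frame(cui = n$cui, name = n$name,
               primary_type = n$primary_type,
               type_counts = paste(sprintf("%s:%d",
                                           n$type_first_seen,
                                           n$type_counts[n$type_first_seen]),
                                   collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(cui = character(), name = character(),
                      primary_type = character(), type_counts = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @rdname graph_nodes
#' @export
graph_edges <- function(graph) {
  keys <- sort(ls(graph$edges))
  rows <- lapply(keys, function(k) {
    e <- graph$edges[[k]]
    data.frame(subject_cui = e$subject_cui, predicate = e$predicate,
               object_cui = e$object_cui, weight = e$weight,
               pmids = paste(e$pmids, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(subject_cui = character(), predicate = character(),
                      object_cui = character(), weight = integer(),
                      pmids = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

## Lazily built flat index over edges for fast neighbor/degree queries.
## Invalidated on any mutation.
graph_index <- function(g) {
  if (!is.null(g$index)) return(g$index)
  keys <- sort(ls(g$edges))
  n <- length(keys)
  subj <- character(n); pred <- character(n); obj <- character(n)
  for (i in seq_len(n)) {
    e <- g$edges[[keys[i]]]
    subj[i] <- e$subject_cui; pred[i] <- e$predicate; obj[i] <- e$object_cui
  }
  cuis <- sort(ls(g$nodes))
  ptype <- vapply(cuis, function(cu) g$nodes[[cu]]$primary_type, character(1))
  names(ptype) <- cuis
  idx <- list(
    subject = subj, predicate = pred, object = obj,
    stype = unname(ptype[subj]), otype = unname(ptype[obj]),
    ptype = ptype,
    out_rows = split(seq_len(n), factor(subj, levels = cuis)),
    in_rows = split(seq_len(n), factor(obj, levels = cuis))
  )
  g$index <- idx
  idx
}

#' Direction/type-aware neighbor query
#'
#' Forward returns the objects of edges whose subject is `cui`; reverse
#' returns the subjects of edges whose object is `cui`. Optional filters on
#' the predicate and on the neighbor's primary semantic type. The result is a
#' sorted set (no multiplicity).
#'
#' @param graph a [hetero_graph()].
#' @param cui concept identifier (must be in the graph).
#' @param predicate optional predicate code filter.
#' @param orientation `"forward"` (outgoing) or `"reverse"` (incoming).
#' @param neighbor_type optional primary-type filter on the neighbors.
#' @return sorted character vector of neighbor CUIs.
#' @export
node_neighbors <- function(graph, cui, predicate = NULL,
                           orientation = c("forward", "reverse"),
                           neighbor_type = NULL) {
  orientation <- match.arg(orientation)
  if (!has_node(graph, cui)) {
    lbd_stop("lbd_missing_node_error", "unknown node: %s", cui)
  }
  idx <- graph_index(graph)
  rows <- if (orientation == "forward") idx$out_rows[[cui]] else idx$in_rows[[cui]]
  if (!length(rows)) return(character())
  if (!is.null(predicate)) rows <- rows[idx$predicate[rows] == predicate]
  nb <- if (orientation == "forward") idx$object[rows] else idx$subject[rows]
  if (!is.null(neighbor_type)) nb <- nb[idx$ptype[nb] == neighbor_type]
  sort(unique(nb))
}

#' Undirected 1-hop neighborhood of a concept
#' @inheritParams node_neighbors
#' @return sorted character vector of CUIs adjacent to `cui` in either
#'   direction (not including `cui` itself unless it has a self-loop edge).
#' @export
node_neighborhood <- function(graph, cui) {
  sort(unique(c(node_neighbors(graph, cui, orientation = "forward"),
                node_neighbors(graph, cui, orientation = "reverse"))))
}

#' Metaedge-specific degree of a node
#'
#' Counts edges of a given metaedge (source type, predicate, target type)
#' incident to `cui` on the stated side. An unrealized metaedge yields 0.
#'
#' @param graph a [hetero_graph()].
#' @param cui concept identifier (must be in the graph).
#' @param metaedge character vector `c(source_type, predicate, target_type)`.
#' @param side `"source"` (edges whose subject is `cui`) or `"target"`.
#' @return non-negative integer.
#' @export
metaedge_degree <- function(graph, cui, metaedge,
                            side = c("source", "target")) {
  side <- match.arg(side)
  if (!has_node(graph, cui)) {
    lbd_stop("lbd_missing_node_error", "unknown node: %s", cui)
  }
  stopifnot(length(metaedge) == 3L)
  idx <- graph_index(graph)
  rows <- if (side == "source") idx$out_rows[[cui]] else idx$in_rows[[cui]]
  if (!length(rows)) return(0L)
  sum(idx$stype[rows] == metaedge[1] &
      idx$predicate[rows] == metaedge[2] &
      idx$otype[rows] == metaedge[3])
}

#' Derive the metagraph realized by a graph
#'
#' Lists the node types, predicates, and (source type, predicate, target
#' type) metaedge triples realized by at least one edge, using primary types.
#'
#' @param graph a [hetero_graph()].
#' @return list with `node_types`, `predicates`, and a `metaedges` data frame.
#' @export
derive_metagraph <- function(graph) {
  idx <- graph_index(graph)
  me <- unique(data.frame(source_type = idx$stype, predicate = idx$predicate,
                          target_type = idx$otype, stringsAsFactors = FALSE))
  me <- me[order(me$source_type, me$predicate, me$target_type), , drop = FALSE]
  rownames(me) <- NULL
  list(node_types = sort(unique(unname(idx$ptype))),
       predicates = sort(unique(idx$predicate)),
       metaedges = me)
}

#' Compare two graphs for equality
#'
#' Compares the node map (names, type counts, first-seen order, primary
#' types) and the edge map (weights, PMID sets). Vocabulary configuration is
#' not compared.
#'
#' @param a,b [hetero_graph()] objects.
#' @return logical.
#' @export
graph_identical <- function(a, b) {
  identical(graph_nodes(a), graph_nodes(b)) &&
    identical(graph_edges(a), graph_edges(b))
}
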