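#' Predication table schema
#'
#' Maps the eight record roles onto column names of a predication TSV. The
#' defaults mirror the SemMedDB PREDICATION table columns, so real extracts
#' load without configuration; any other tabular layout can be described by
#' overriding the names.
#'
#' @param pmid,predicate,subject_cui,subject_name,subject_semtype,object_cui,object_name,object_semtype
#'   column names for the eight roles.
#' @param sep field delimiter (default tab).
#' @param header does the file carry a header row?
#' @return an object of class `predication_schema`.
#' @export
predication_schema <- function(pmid = "PMID", predicate = "PREDICATE",
                               subject_cui = "SUBJECT_CUI",
                               subject_name = "SUBJECT_NAME",
                               subject_semtype = "SUBJECT_SEMTYPE",
                               object_cui = "OBJECT_CUI",
                               object_name = "OBJECT_NAME",
                               object_semtype = "OBJECT_SEMTYPE",
                               sep = "\t", header = TRUE) {
  cols <- c(pmid = pmid, predicate = predicate,
            subject_cui = subject_cui, subject_name = subject_name,
            subject_semtype = subject_semtype, object_cui = object_cui,
            object_name = object_name, object_semtype = object_semtype)
  if (anyDuplicated(cols)) {
    lbd_stop("lbd_schema_error",
             "schema maps two roles onto the same column: %s",
             cols[duplicated(cols)][1])
  }
  structure(list(columns = cols, sep = sep, header = header),
            class = "predication_schema")
}

#' Load a predication table into a concept graph
#'
#' Streams the rows of a SemMedDB-style TSV through
#' [add_predication_record()] in file order.
#'
#' @param path path to the delimited predication table.
#' @param schema a [predication_schema()].
#' @param predicates,semtypes optional vocabularies passed to
#'   [hetero_graph()]; `NULL` accepts any code.
#' @param lenient if `TRUE`, malformed rows are skipped with a warning and
#'   counted (attribute `n_skipped` on the result); if `FALSE` (default) the
#'   first bad row aborts the load with its line number.
#' @return a [hetero_graph()].
#' @export
load_predications <- function(path, schema = predication_schema(),
                              predicates = NULL, semtypes = NULL,
                              lenient = FALSE) {
  if (!file.exists(path)) lbd_stop("lbd_io_error", "no such file: %s", path)
  stopifnot(inherits(schema, "predication_schema"))
  tab <- utils::read.delim(path, sep = schema$sep, header = schema$header,
                           colClasses = "character", check.names = FALSE,
                           quote = "", fill = TRUE, blank.lines.skip = FALSE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(schema$columns), names(tab))
  if (length(missing_cols)) {
    lbd_stop("lbd_schema_error", "missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  ## detect ragged rows before building anything
  nf <- tryCatch(utils::count.fields(path, sep = schema$sep, quote = "",
                                     blank.lines.skip = FALSE),
                 error = function(e) NULL)
  bad_lines <- integer()
  if (!is.null(nf)) {
    expected <- nf[1]
    bad_lines <- which(nf != expected & !is.na(nf))
  }
  header_off <- if (schema$header) 1L else 0L
  if (length(bad_lines) && !lenient) {
    lbd_stop("lbd_schema_error", "malformed row at line %d (field count)",
             bad_lines[1])
  }
  g <- hetero_graph(predicates = predicates, semtypes = semtypes)
  n_skipped <- 0L
  bad_data_rows <- bad_lines - header_off
  for (i in seq_len(nrow(tab))) {
    if (i %in% bad_data_rows) {
      n_skipped <- n_skipped + 1L
      next
    }
    rec <- as.list(tab[i, unname(schema$columns)])
    names(rec) <- names(schema$columns)
    ok <- tryCatch({ add_predication_record(g, rec); TRUE },
                   lbd_error = function(e) e)
    if (!isTRUE(ok)) {
      if (lenient) {
        n_skipped <- n_skipped + 1L
      } else {
        lbd_stop(class(ok)[1], "row at line %d: %s",
                 i + header_off, conditionMessage(ok))
      }
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d malformed row(s)", n_skipped))
    attr(g, "n_skipped") <- n_skipped
  }
  g
}

#' Write / read a graph as paired node and edge TSV files
#'
#' Produces `<prefix>_nodes.tsv` and `<prefix>_edges.tsv` in the layout of
#' [graph_nodes()] / [graph_edges()], suitable for common graph-database bulk
#' importers. `read_graph_tables()` restores an identical graph.
#'
#' @param graph a [hetero_graph()].
#' @param prefix path prefix for the two files.
#' @param header_lines optional provenance lines written as `#` comments.
#' @return `write_graph_tables`: the two paths, invisibly.
#' @export
write_graph_tables <- function(graph, prefix, header_lines = character()) {
  np <- paste0(prefix, "_nodes.tsv")
  ep <- paste0(prefix, "_edges.tsv")
  write_tsv(graph_nodes(graph), np, header_lines)
  write_tsv(graph_edges(graph), ep, header_lines)
  invisible(c(nodes = np, edges = ep))
}

#' @rdname write_graph_tables
#' @return `read_graph_tables`: a [hetero_graph()].
#' @export
read_graph_tables <- function(prefix) {
  np <- paste0(prefix, "_nodes.tsv")
  ep <- paste0(prefix, "_edges.tsv")
  for (p in c(np, ep)) {
    if (!file.exists(p)) lbd_stop("lbd_io_error", "no such file: %s", p)
  }
  nodes <- read_tsv(np)
  edges <- read_tsv(ep)
  graph_from_tables(nodes, edges)
}

## rebuild a graph from its serialized node/edge tables
graph_from_tables <- function(nodes, edges) {
  g <- hetero_graph()
  for (i in seq_len(nrow(nodes))) {
    tc_pairs <- strsplit(nodes$type_counts[i], ";", fixed = TRUE)[[1]]
    parts <- strsplit(tc_pairs, ":", fixed = TRUE)
    tfs <- vapply(parts, `[`, character(1), 1)
    cnt <- as.integer(vapply(parts, `[`, character(1), 2))
    n <- list(cui = nodes$cui[i], name = nodes$name[i],
              type_counts = stats::setNames(cnt, tfs),
              type_first_seen = tfs)
    n$primary_type <- resolve_primary_type(n)
    g$nodes[[n$cui]] <- n
  }
  for (i in seq_len(nrow(edges))) {
    key <- edge_key(edges$subject_cui[i], edges$predicate[i],
                    edges$object_cui[i])
    e <- list(subject_cui = edges$subject_cui[i],
              predicate = edges$predicate[i],
              object_cui = edges$object_cui[i],
              weight = as.integer(edges$weight[i]),
              pmids = sort(strsplit(edges$pmids[i], ";", fixed = TRUE)[[1]]))
    g$edges[[key]] <- e
    g$out[[e$subject_cui]] <- c(g$out[[e$subject_cui]], key)
    g$inn[[e$object_cui]] <- c(g$inn[[e$object_cui]], key)
    g$n_records <- g$n_records + e$weight
  }
  invalidate_index(g)
  g
}

#' GraphML export / import
#'
#' Serializes the graph through `igraph`'s GraphML writer. Node attributes:
#' `name` (the CUI), `label`, `primary_type`, `type_counts` (first-seen-order
#' `"type:count"` pairs joined by `";"`). Edge attributes: `predicate`,
#' `weight`, `pmids` (sorted, `";"`-joined).
#'
#' @param graph a [hetero_graph()].
#' @param path output (input) file path.
#' @return `write_graphml`: `path` invisibly; `read_graphml`: a
#'   [hetero_graph()].
#' @export
write_graphml <- function(graph, path) {
  nodes <- graph_nodes(graph)
  edges <- graph_edges(graph)
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$subject_cui, to = edges$object_cui,
                   predicate = edges$predicate, weight = edges$weight,
                   pmids = edges$pmids, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes$cui, label = nodes$name,
                          primary_type = nodes$primary_type,
                          type_counts = nodes$type_counts,
                          stringsAsFactors = FALSE))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) lbd_stop("lbd_io_error", "no such file: %s", path)
  ig <- igraph::read_graph(path, format = "graphml")
  vdf <- igraph::as_data_frame(ig, what = "vertices")
  edf <- igraph::as_data_frame(ig, what = "edges")
  nodes <- data.frame(cui = vdf$name, name = vdf$label,
                      primary_type = vdf$primary_type,
                      type_counts = vdf$type_counts, stringsAsFactors = FALSE)
  edges <- data.frame(subject_cui = edf$from, predicate = edf$predicate,
                      object_cui = edf$to, weight = edf$weight,
                      pmids = edf$pmids, stringsAsFactors = FALSE)
  graph_from_tables(nodes, edges)
}

#' Write a feature tensor as a long-format TSV
#'
#' One row per non-zero `(source, target, metapath, feature)` cell. The full
#' axis labels are stored in `#`-comment header lines so the file round-trips
#' losslessly (zero cells are implicit).
#'
#' @param X a [build_feature_tensor()] result.
#' @param path output path.
#' @param header_lines additional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(X, path, header_lines = character()) {
  stopifnot(inherits(X, "feature_tensor"))
  dn <- dimnames(X)
  hdr <- c(header_lines,
           paste0("axis sources: ", paste(dn[[1]], collapse = ",")),
           paste0("axis targets: ", paste(dn[[2]], collapse = ",")),
           paste0("axis metapaths: ", paste(dn[[3]], collapse = ",")),
           paste0("axis features: ", paste(dn[[4]], collapse = ",")))
  nz <- which(X != 0, arr.ind = TRUE)
  df <- data.frame(source = dn[[1]][nz[, 1]], target = dn[[2]][nz[, 2]],
                   metapath = dn[[3]][nz[, 3]], feature = dn[[4]][nz[, 4]],
                   value = num_chr(X[nz]), stringsAsFactors = FALSE)
  df <- df[order(df$source, df$target, df$metapath, df$feature), , drop = FALSE]
  write_tsv(df, path, hdr)
}

#' Read a long-format feature TSV back into a tensor
#' @param path a file written by [write_feature_table()].
#' @return a `feature_tensor` (dense array with the stored axis labels).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) lbd_stop("lbd_io_error", "no such file: %s", path)
  lines <- readLines(path)
  ax <- list()
  for (nm in c("sources", "targets", "metapaths", "features")) {
    pat <- paste0("^# axis ", nm, ": ")
    hit <- grep(pat, lines, value = TRUE)
    if (!length(hit)) {
      lbd_stop("lbd_schema_error", "missing axis header '%s' in %s", nm, path)
    }
    ax[[nm]] <- strsplit(sub(pat, "", hit[1]), ",", fixed = TRUE)[[1]]
  }
  df <- read_tsv(path)
  X <- array(0, dim = lengths(ax), dimnames = unname(ax))
  if (nrow(df)) {
    X[cbind(match(df$source, ax$sources), match(df$target, ax$targets),
            match(df$metapath, ax$metapaths),
            match(df$feature, ax$features))] <- as.numeric(df$value)
  }
  class(X) <- c("feature_tensor", class(X))
  X
}
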