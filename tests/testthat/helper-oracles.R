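# Independent brute-force oracles. All of them work off the flat edge table
# (graph_edges()) and a cui -> primary type lookup, never off the package's
# adjacency index or recursion, so they exercise a genuinely separate path.

oracle_ptype <- function(g) {
  nd <- graph_nodes(g)
  stats::setNames(nd$primary_type, nd$cui)
}

# flat tables are expensive to rebuild; cache them per graph state
oracle_ctx <- function(g) {
  if (!is.null(g$oracle_cache) && g$oracle_cache$n == g$n_records) {
    return(g$oracle_cache)
  }
  ctx <- list(n = g$n_records, ed = graph_edges(g), pt = oracle_ptype(g))
  g$oracle_cache <- ctx
  ctx
}

oracle_neighbors <- function(g, cui, predicate = NULL,
                             orientation = "forward", neighbor_type = NULL) {
  ctx <- oracle_ctx(g)
  ed <- ctx$ed
  pt <- ctx$pt
  keep <- if (orientation == "forward") ed$subject_cui == cui else ed$object_cui == cui
  if (!is.null(predicate)) keep <- keep & ed$predicate == predicate
  nb <- if (orientation == "forward") ed$object_cui[keep] else ed$subject_cui[keep]
  if (!is.null(neighbor_type)) nb <- nb[pt[nb] == neighbor_type]
  sort(unique(nb))
}

oracle_degree <- function(g, cui, metaedge, side = "source") {
  ctx <- oracle_ctx(g)
  ed <- ctx$ed
  pt <- ctx$pt
  keep <- pt[ed$subject_cui] == metaedge[1] &
    ed$predicate == metaedge[2] &
    pt[ed$object_cui] == metaedge[3]
  keep <- keep & if (side == "source") ed$subject_cui == cui else ed$object_cui == cui
  sum(keep)
}

# exhaustive DFS over the edge table; returns list keyed by canonical
# metapath string -> lexicographically sorted list of cui vectors
oracle_enumerate <- function(g, s, t, max_len, forward_only = FALSE) {
  ctx <- oracle_ctx(g)
  ed <- ctx$ed
  pt <- ctx$pt
  found_keys <- character()
  found_paths <- list()
  rec <- function(path, mstr) {
    u <- path[length(path)]
    if (length(path) - 1L >= max_len) return(invisible())
    # exhaustive scan of the whole edge table at every step
    fwd <- which(ed$subject_cui == u)
    rev_ <- if (forward_only) integer() else which(ed$object_cui == u)
    vs <- c(ed$object_cui[fwd], ed$subject_cui[rev_])
    pieces <- c(
      if (length(fwd)) paste0("-", ed$predicate[fwd], ">",
                              pt[ed$object_cui[fwd]]) else character(),
      if (length(rev_)) paste0("<", ed$predicate[rev_], "-",
                               pt[ed$subject_cui[rev_]]) else character())
    for (j in seq_along(vs)) {
      v <- vs[j]
      m2 <- paste0(mstr, pieces[j])
      if (v == t) {
        found_keys[[length(found_keys) + 1L]] <<- m2
        found_paths[[length(found_paths) + 1L]] <<- c(path, v)
        if (t == s) next
      }
      if (v != t && !(v %in% path)) rec(c(path, v), m2)
    }
    invisible()
  }
  rec(s, pt[[s]])
  out <- structure(list(), names = character())
  for (k in sort(unique(found_keys))) {
    ps <- found_paths[found_keys == k]
    out[[k]] <- ps[order(vapply(ps, paste, character(1), collapse = "\r"))]
  }
  out
}

# per-path degree products from the edge table
oracle_dwpc <- function(g, mp_string, paths, w) {
  steps <- oracle_parse_metapath(mp_string)
  total <- 0
  for (p in paths) {
    prodd <- 1
    for (i in seq_len(nrow(steps))) {
      st <- steps[i, ]
      if (st$rev) {
        me <- c(st$to, st$pred, st$from)
        d1 <- oracle_degree(g, p[i], me, "target")
        d2 <- oracle_degree(g, p[i + 1], me, "source")
      } else {
        me <- c(st$from, st$pred, st$to)
        d1 <- oracle_degree(g, p[i], me, "source")
        d2 <- oracle_degree(g, p[i + 1], me, "target")
      }
      prodd <- prodd * d1 * d2
    }
    total <- total + prodd^(-w)
  }
  total
}

# independent metapath-string parser (same canonical grammar)
oracle_parse_metapath <- function(s) {
  toks <- regmatches(s, gregexpr("[^-<>]+|[-<>]", s))[[1]]
  k <- (length(toks) - 1L) %/% 4L
  steps <- data.frame(from = character(k), pred = character(k),
                      to = character(k), rev = logical(k),
                      stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    j <- (i - 1L) * 4L + 1L
    steps$from[i] <- toks[j]
    steps$pred[i] <- toks[j + 2L]
    steps$to[i] <- toks[j + 4L]
    steps$rev[i] <- toks[j + 1L] == "<"
  }
  steps
}

# direct evaluation of the pairwise arithmetic-mean recursion off the table
oracle_hetesim <- function(g, s, t, mp_string) {
  ctx <- oracle_ctx(g)
  ed <- ctx$ed
  pt <- ctx$pt
  steps <- oracle_parse_metapath(mp_string)
  out_set <- function(u, st) {
    if (st$rev) {
      sort(unique(ed$subject_cui[ed$object_cui == u &
                                   ed$predicate == st$pred &
                                   pt[ed$subject_cui] == st$to]))
    } else {
      sort(unique(ed$object_cui[ed$subject_cui == u &
                                  ed$predicate == st$pred &
                                  pt[ed$object_cui] == st$to]))
    }
  }
  in_set <- function(v, st) {
    if (st$rev) {
      sort(unique(ed$object_cui[ed$subject_cui == v &
                                  ed$predicate == st$pred &
                                  pt[ed$object_cui] == st$from]))
    } else {
      sort(unique(ed$subject_cui[ed$object_cui == v &
                                   ed$predicate == st$pred &
                                   pt[ed$subject_cui] == st$from]))
    }
  }
  rec <- function(a, b, stp) {
    l <- nrow(stp)
    if (l == 0L) return(as.numeric(a == b))
    if (l == 1L) {
      st <- stp[1, ]
      if (st$rev) {
        num <- sum(ed$subject_cui == b & ed$predicate == st$pred &
                     ed$object_cui == a)
        me <- c(st$to, st$pred, st$from)
        d1 <- oracle_degree(g, a, me, "target")
        d2 <- oracle_degree(g, b, me, "source")
      } else {
        num <- sum(ed$subject_cui == a & ed$predicate == st$pred &
                     ed$object_cui == b)
        me <- c(st$from, st$pred, st$to)
        d1 <- oracle_degree(g, a, me, "source")
        d2 <- oracle_degree(g, b, me, "target")
      }
      if (d1 == 0 || d2 == 0) return(0)
      return(min(num, 1) / (d1 * d2))
    }
    O <- out_set(a, stp[1, ])
    I <- in_set(b, stp[l, ])
    if (!length(O) || !length(I)) return(0)
    inner <- if (l > 2L) stp[2:(l - 1L), , drop = FALSE] else stp[0, , drop = FALSE]
    tot <- 0
    for (o in O) for (ii in I) tot <- tot + rec(o, ii, inner)
    tot / (length(O) * length(I))
  }
  rec(s, t, steps)
}

oracle_dense_rank <- function(values, descending = TRUE) {
  u <- sort(unique(values))
  if (descending) u <- rev(u)
  vapply(values, function(v) which(u == v), integer(1))
}

# O(n^2) concordant/discordant pair counting, tau-b
oracle_kendall <- function(a, b) {
  n <- length(a)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- a[i] - a[j]; dy <- b[i] - b[j]
      if (dx == 0 && dy == 0) next
      if (dx == 0) { tx <- tx + 1; next }
      if (dy == 0) { ty <- ty + 1; next }
      if (sign(dx) == sign(dy)) C <- C + 1 else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tiepairs <- function(v) { tt <- table(v); sum(tt * (tt - 1) / 2) }
  (C - D) / sqrt((n0 - tiepairs(a)) * (n0 - tiepairs(b)))
}

# random heterogeneous graph fixture: returns graph + its record table
random_graph <- function(seed, n_nodes = 20, n_edges = 60, n_types = 4,
                         n_preds = 3, dup_frac = 0.1) {
  set.seed(seed)
  types <- paste0("ty", seq_len(n_types))
  preds <- paste0("P", seq_len(n_preds))
  cuis <- sprintf("C%04d", seq_len(n_nodes))
  node_type <- sample(types, n_nodes, replace = TRUE)
  names(node_type) <- cuis
  subj <- sample(cuis, n_edges, replace = TRUE)
  obj <- sample(cuis, n_edges, replace = TRUE)
  keep <- subj != obj
  subj <- subj[keep]; obj <- obj[keep]
  pred <- sample(preds, length(subj), replace = TRUE)
  df <- data.frame(
    PMID = as.character(sample(1000, length(subj), replace = TRUE)),
    PREDICATE = pred,
    SUBJECT_CUI = subj, SUBJECT_NAME = subj,
    SUBJECT_SEMTYPE = unname(node_type[subj]),
    OBJECT_CUI = obj, OBJECT_NAME = obj,
    OBJECT_SEMTYPE = unname(node_type[obj]),
    stringsAsFactors = FALSE)
  ndup <- floor(nrow(df) * dup_frac)
  if (ndup > 0) {
    df <- rbind(df, df[sample(nrow(df), ndup), , drop = FALSE])
    rownames(df) <- NULL
  }
  g <- hetero_graph(predicates = preds, semtypes = types)
  for (i in seq_len(nrow(df))) {
    add_predication_record(g, list(
      subject_cui = df$SUBJECT_CUI[i], subject_name = df$SUBJECT_NAME[i],
      subject_semtype = df$SUBJECT_SEMTYPE[i], predicate = df$PREDICATE[i],
      object_cui = df$OBJECT_CUI[i], object_name = df$OBJECT_NAME[i],
      object_semtype = df$OBJECT_SEMTYPE[i], pmid = df$PMID[i]))
  }
  list(graph = g, records = df)
}

# write a record data frame as a predication TSV
write_records <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# read the data rows of a commented TSV
read_tsv_rows <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", quote = "",
                    stringsAsFactors = FALSE)
}
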