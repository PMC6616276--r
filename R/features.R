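#' Discover source nodes from a boolean rule over target neighborhoods
#'
#' Each CUI in the rule stands for its undirected 1-hop neighborhood;
#' `OR` is set union, `AND` set intersection, with parentheses for grouping
#' (`AND` binds tighter than `OR` when parentheses are omitted). Target CUIs
#' that land in the evaluated set are retained, so self-connections are
#' possible when targets neighbor each other.
#'
#' @param graph a [hetero_graph()].
#' @param rule a string such as `"(C0023185 OR C0025260) AND C0028040"`.
#' @return sorted character vector of source CUIs.
#' @export
find_sources <- function(graph, rule) {
  stopifnot(is.character(rule), length(rule) == 1L)
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", rule)[[1]]
  toks <- regmatches(rule, list(m))[[1]]
  pos <- as.integer(m)
  if (!length(toks)) lbd_stop("lbd_parse_error", "empty source rule")
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  fail <- function(why) {
    at <- if (i <= length(toks)) pos[i] else nchar(rule) + 1L
    lbd_stop("lbd_parse_error", "source rule: %s at position %d", why, at)
  }
  parse_expr <- function() {
    x <- parse_term()
    while (!is.na(peek()) && toupper(peek()) == "OR") {
      i <<- i + 1L
      x <- union(x, parse_term())
    }
    x
  }
  parse_term <- function() {
    x <- parse_factor()
    while (!is.na(peek()) && toupper(peek()) == "AND") {
      i <<- i + 1L
      x <- intersect(x, parse_factor())
    }
    x
  }
  parse_factor <- function() {
    tk <- peek()
    if (is.na(tk)) fail("unexpected end of rule")
    if (tk == "(") {
      i <<- i + 1L
      x <- parse_expr()
      if (is.na(peek()) || peek() != ")") fail("expected ')'")
      i <<- i + 1L
      return(x)
    }
    if (tk == ")" || toupper(tk) %in% c("AND", "OR")) fail("unexpected token")
    if (!is_cui(tk)) fail(sprintf("'%s' is not a CUI", tk))
    i <<- i + 1L
    node_neighborhood(graph, tk)
  }
  out <- parse_expr()
  if (!is.na(peek())) fail("trailing input")
  sort(out)
}

#' Enumerate node-simple paths between a source and a target, grouped by
#' metapath
#'
#' Finds every node-simple path of at most `max_len` edges from `source` to
#' `target`; each edge can be traversed in either orientation (reverse steps
#' are recorded in the metapath) unless `forward_only = TRUE`. Endpoints may
#' coincide only when `source == target` (self-connection analyses);
#' otherwise the target never appears as an interior node.
#'
#' @param graph a [hetero_graph()].
#' @param source,target CUIs present in the graph.
#' @param max_len maximum number of edges per path (default 2).
#' @param forward_only disallow reverse-orientation steps?
#' @return named list, one element per realized metapath (keys are canonical
#'   metapath strings in lexicographic order); each element has `$metapath`
#'   (a [metapath()]) and `$paths` (list of CUI vectors, lexicographically
#'   ordered).
#' @export
enumerate_paths <- function(graph, source, target, max_len = 2,
                            forward_only = FALSE) {
  stopifnot(max_len >= 1)
  for (cu in c(source, target)) {
    if (!has_node(graph, cu)) {
      lbd_stop("lbd_missing_node_error", "unknown node: %s", cu)
    }
  }
  idx <- graph_index(graph)
  acc <- new.env(parent = emptyenv())
  moves <- function(u) {
    out <- idx$out_rows[[u]]
    inn <- if (forward_only) integer() else idx$in_rows[[u]]
    list(rows = c(out, inn),
         rev = c(rep(FALSE, length(out)), rep(TRUE, length(inn))))
  }
  record <- function(cuis, from, pred, to, rv) {
    key <- format(metapath(from, pred, to, rv))
    hit <- acc[[key]]
    if (is.null(hit)) hit <- list(steps = list(from, pred, to, rv), paths = list())
    hit$paths[[length(hit$paths) + 1L]] <- cuis
    acc[[key]] <- hit
  }
  walk <- function(u, visited, cuis, from, pred, to, rv) {
    depth <- length(pred)
    if (depth >= max_len) return(invisible())
    mv <- moves(u)
    for (j in seq_along(mv$rows)) {
      r <- mv$rows[j]
      rvj <- mv$rev[j]
      v <- if (rvj) idx$subject[r] else idx$object[r]
      f2 <- c(from, idx$ptype[[u]])
      p2 <- c(pred, idx$predicate[r])
      t2 <- c(to, idx$ptype[[v]])
      r2 <- c(rv, rvj)
      if (v == target) {
        record(c(cuis, v), f2, p2, t2, r2)
        if (target == source) next # closed walk: stop here
      }
      if (v != target && !(v %in% visited)) {
        walk(v, c(visited, v), c(cuis, v), f2, p2, t2, r2)
      }
    }
    invisible()
  }
  walk(source, source, source, character(), character(), character(), logical())
  keys <- sort(ls(acc))
  out <- lapply(keys, function(k) {
    hit <- acc[[k]]
    mp <- metapath(hit$steps[[1]], hit$steps[[2]], hit$steps[[3]],
                   hit$steps[[4]])
    ord <- order(vapply(hit$paths, paste, character(1), collapse = "\r"))
    list(metapath = mp, paths = hit$paths[ord])
  })
  names(out) <- keys
  out
}

#' Path count feature
#' @param paths list of path-instance CUI vectors (one metapath group).
#' @return integer count.
#' @export
path_count <- function(paths) length(paths)

#' Degree-weighted path count (DWPC)
#'
#' Down-weights paths through highly connected nodes: each path contributes
#' the product, over its 2k node-metaedge incidences (both endpoints of each
#' of the k steps), of that node's metaedge-specific degree raised to `-w`.
#' With `w = 0` the DWPC equals the plain path count.
#'
#' @param graph a [hetero_graph()].
#' @param mp the shared [metapath()] of the paths.
#' @param paths list of CUI vectors conforming to `mp`.
#' @param w damping exponent (default 0.4).
#' @return non-negative numeric.
#' @export
dwpc <- function(graph, mp, paths, w = 0.4) {
  stopifnot(inherits(mp, "metapath"), w >= 0)
  if (!length(paths)) return(0)
  k <- nrow(mp)
  cache <- new.env(parent = emptyenv())
  deg <- function(cui, me, side) {
    key <- paste(cui, side, me[1], me[2], me[3], sep = "\r")
    d <- cache[[key]]
    if (is.null(d)) {
      d <- metaedge_degree(graph, cui, me, side)
      cache[[key]] <- d
    }
    d
  }
  total <- 0
  for (p in paths) {
    prodd <- 1
    for (i in seq_len(k)) {
      sm <- step_metaedge(mp[i, ])
      d1 <- deg(p[i], sm$me, sm$u_side)
      d2 <- deg(p[i + 1L], sm$me, sm$v_side)
      if (d1 == 0 || d2 == 0) {
        lbd_stop("lbd_internal_error",
                 "zero degree on a realized path incidence")
      }
      prodd <- prodd * d1 * d2
    }
    total <- total + prodd^(-w)
  }
  total
}

## neighbor set when leaving node u along a step (respecting orientation)
step_out_set <- function(graph, u, step) {
  if (step$rev) {
    node_neighbors(graph, u, step$predicate, "reverse", step$to_type)
  } else {
    node_neighbors(graph, u, step$predicate, "forward", step$to_type)
  }
}

## neighbor set when entering node t along a step (against its orientation)
step_in_set <- function(graph, t, step) {
  if (step$rev) {
    node_neighbors(graph, t, step$predicate, "forward", step$from_type)
  } else {
    node_neighbors(graph, t, step$predicate, "reverse", step$from_type)
  }
}

#' HeteSim relevance of a source-target pair along a metapath
#'
#' Path-constrained relevance on heterogeneous networks: the probability-like
#' score that `s`, walking along the metapath, and `t`, walking against it,
#' meet at the same node. Computed by the pairwise arithmetic-mean recursion:
#' strip the first relation from `s`'s side (out-neighbor set `O`) and the
#' last from `t`'s side (in-neighbor set `I`), average the recursion over all
#' pairs and normalize by `|O| * |I|`. The empty path has the Kronecker-delta
#' base case `HeteSim(s, t | I) = d(s, t)`. Odd-length paths bottom out at a
#' single relation, where the intermediate objects are the edge instances
#' themselves, giving `[s->t edge exists] / (out-degree of s x in-degree of t
#' for that metaedge)`. Returns 0 whenever either neighbor set is empty;
#' values always lie in `[0, 1]`.
#'
#' @param graph a [hetero_graph()].
#' @param s,t source and target CUIs; their primary types must match the
#'   metapath's end types.
#' @param mp a [metapath()].
#' @return numeric in `[0, 1]`.
#' @export
hetesim <- function(graph, s, t, mp) {
  stopifnot(inherits(mp, "metapath"))
  idx <- graph_index(graph)
  for (cu in c(s, t)) {
    if (!has_node(graph, cu)) {
      lbd_stop("lbd_missing_node_error", "unknown node: %s", cu)
    }
  }
  if (idx$ptype[[s]] != mp$from_type[1] ||
      idx$ptype[[t]] != mp$to_type[nrow(mp)]) {
    lbd_stop("lbd_applicability_error",
             "metapath end types (%s, %s) do not match node types (%s, %s)",
             mp$from_type[1], mp$to_type[nrow(mp)],
             idx$ptype[[s]], idx$ptype[[t]])
  }
  hs_rec(graph, s, t, mp)
}

hs_rec <- function(graph, s, t, mp) {
  l <- if (is.null(mp)) 0L else nrow(mp)
  if (l == 0L) return(as.numeric(s == t))
  if (l == 1L) {
    st <- mp[1, ]
    sm <- step_metaedge(st)
    key <- if (st$rev) edge_key(t, st$predicate, s) else edge_key(s, st$predicate, t)
    num <- as.numeric(!is.null(graph$edges[[key]]))
    d1 <- metaedge_degree(graph, s, sm$me, sm$u_side)
    d2 <- metaedge_degree(graph, t, sm$me, sm$v_side)
    if (d1 == 0 || d2 == 0) return(0)
    return(num / (d1 * d2))
  }
  O <- step_out_set(graph, s, mp[1, ])
  I <- step_in_set(graph, t, mp[l, ])
  if (!length(O) || !length(I)) return(0)
  inner <- if (l > 2L) mp[2:(l - 1L), , drop = FALSE] else NULL
  total <- 0
  for (o in O) for (ii in I) total <- total + hs_rec(graph, o, ii, inner)
  total / (length(O) * length(I))
}

#' Compute the labeled source x target x metapath x feature tensor
#'
#' Enumerates all metapaths of at most `max_len` edges realized between any
#' selected (source, target) pair and fills the three features per cell:
#' `count` (number of path instances), `dwpc` (degree-weighted path count at
#' damping `w`), and `hetesim`. Unrealized cells are 0, so per cell the three
#' features are simultaneously zero or simultaneously positive. The metapath
#' axis is canonically ordered (lexicographic on metapath strings).
#'
#' @param graph a [hetero_graph()].
#' @param sources,targets non-empty CUI vectors, all present in the graph.
#' @param max_len maximum metapath length in edges (default 2).
#' @param w DWPC damping exponent (default 0.4).
#' @param forward_only disallow reverse-orientation steps?
#' @param features which of `c("count", "dwpc", "hetesim")` to compute
#'   (others are left 0; the default computes all three).
#' @return a 4-d array of class `feature_tensor` with dimnames
#'   `(source, target, metapath, feature)` and attributes `max_len`, `w`.
#' @export
build_feature_tensor <- function(graph, sources, targets, max_len = 2,
                                 w = 0.4, forward_only = FALSE,
                                 features = c("count", "dwpc", "hetesim")) {
  stopifnot(length(sources) >= 1L, length(targets) >= 1L)
  features <- match.arg(features, several.ok = TRUE)
  sources <- unique(sources)
  targets <- unique(targets)
  for (cu in unique(c(sources, targets))) {
    if (!has_node(graph, cu)) {
      lbd_stop("lbd_missing_node_error", "unknown node: %s", cu)
    }
  }
  per_pair <- vector("list", length(sources) * length(targets))
  dim(per_pair) <- c(length(sources), length(targets))
  mp_keys <- character()
  for (si in seq_along(sources)) {
    for (ti in seq_along(targets)) {
      grp <- enumerate_paths(graph, sources[si], targets[ti], max_len,
                             forward_only)
      per_pair[[si, ti]] <- grp
      mp_keys <- unique(c(mp_keys, names(grp)))
    }
  }
  mp_keys <- sort(mp_keys)
  feats <- c("count", "dwpc", "hetesim")
  X <- array(0, dim = c(length(sources), length(targets),
                        length(mp_keys), length(feats)),
             dimnames = list(sources, targets, mp_keys, feats))
  for (si in seq_along(sources)) {
    for (ti in seq_along(targets)) {
      grp <- per_pair[[si, ti]]
      for (k in names(grp)) {
        mp <- grp[[k]]$metapath
        paths <- grp[[k]]$paths
        if ("count" %in% features) {
          X[si, ti, k, "count"] <- path_count(paths)
        }
        if ("dwpc" %in% features) {
          X[si, ti, k, "dwpc"] <- dwpc(graph, mp, paths, w)
        }
        if ("hetesim" %in% features) {
          X[si, ti, k, "hetesim"] <- hetesim(graph, sources[si], targets[ti],
                                             mp)
        }
      }
    }
  }
  structure(X, class = c("feature_tensor", class(X)),
            max_len = max_len, w = w)
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<feature_tensor> %d sources x %d targets x %d metapaths x %d features (%d non-zero cells)\n",
    d[1], d[2], d[3], d[4], sum(x != 0)))
  invisible(x)
}
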