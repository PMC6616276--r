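#' Cosine similarity matrix of per-source feature vectors
#'
#' Given a matrix whose rows are the metapath feature vectors of the sources
#' for one target and one feature, returns the s x s matrix of pairwise
#' cosine similarities. Non-negative features put entries in `[0, 1]`. An
#' all-zero row is defined to have similarity 0 to everything and 1 to
#' itself.
#'
#' @param M numeric matrix, sources in rows (rownames kept), metapaths in
#'   columns; at least 2 rows.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
cosine_similarity_matrix <- function(M) {
  M <- as.matrix(M)
  stopifnot(nrow(M) >= 2L)
  nrm <- sqrt(rowSums(M^2))
  safe <- ifelse(nrm == 0, 1, nrm)
  S <- tcrossprod(M / safe)
  S[nrm == 0, ] <- 0
  S[, nrm == 0] <- 0
  diag(S) <- 1
  dimnames(S) <- list(rownames(M), rownames(M))
  S
}

#' Hierarchical leaf order of a similarity matrix
#'
#' Average-linkage agglomerative clustering on distance `1 - similarity`;
#' returns the dendrogram leaf order so similar sources sit next to each
#' other in heatmaps. Deterministic given the input.
#'
#' @param S symmetric similarity matrix (e.g. from
#'   [cosine_similarity_matrix()]).
#' @return character vector of row labels in leaf order (or integer indices
#'   if `S` has no dimnames).
#' @export
hierarchical_order <- function(S) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == ncol(S), nrow(S) >= 2L)
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  labs <- rownames(S) %||% as.character(seq_len(nrow(S)))
  labs[hc$order]
}

#' Kendall rank correlation (tau-b) by Knight's algorithm
#'
#' Tie-adjusted tau-b, appropriate for dense rankings where ties are common.
#' Discordant pairs are counted in O(n log n) by merge-sort inversion
#' counting after sorting by the first ranking (ties broken by the second),
#' following Knight's algorithm. `+1`/`-1` for perfectly concordant /
#' discordant tie-free rankings.
#'
#' @param rank_a,rank_b numeric vectors over the same items; if both are
#'   named, `rank_b` is aligned to `rank_a` by name.
#' @return numeric in `[-1, 1]`.
#' @export
kendall_tau <- function(rank_a, rank_b) {
  if (!is.null(names(rank_a)) && !is.null(names(rank_b))) {
    shared <- intersect(names(rank_a), names(rank_b))
    if (!length(shared)) {
      lbd_stop("lbd_degenerate_error", "rankings share no items")
    }
    rank_a <- rank_a[shared]
    rank_b <- rank_b[shared]
  }
  n <- length(rank_a)
  stopifnot(n == length(rank_b), n >= 2L)
  x <- as.numeric(rank_a)
  y <- as.numeric(rank_b)
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_pairs(x)
  n2 <- tie_pairs(y)
  if (n1 == n0 || n2 == n0) {
    lbd_stop("lbd_degenerate_error",
             "correlation undefined: one ranking is all ties")
  }
  n3 <- tie_pairs(paste(x, y, sep = "\r"))
  ord <- order(x, y)
  D <- count_inversions(y[ord])
  S <- (n0 - n1 - n2 + n3) - 2 * D
  S / sqrt((n0 - n1) * (n0 - n2))
}

## strict inversions (y_i > y_j for i < j) via merge sort
count_inversions <- function(y) {
  n <- length(y)
  if (n < 2L) return(0)
  counter <- 0
  rec <- function(v) {
    m <- length(v)
    if (m < 2L) return(v)
    half <- m %/% 2L
    left <- rec(v[seq_len(half)])
    right <- rec(v[(half + 1L):m])
    merged <- numeric(m)
    i <- 1L; j <- 1L; k <- 1L
    nl <- length(left); nr <- length(right)
    while (i <= nl && j <= nr) {
      if (left[i] <= right[j]) {
        merged[k] <- left[i]; i <- i + 1L
      } else {
        merged[k] <- right[j]; j <- j + 1L
        counter <<- counter + (nl - i + 1L)
      }
      k <- k + 1L
    }
    if (i <= nl) merged[k:m] <- left[i:nl]
    if (j <= nr) merged[k:m] <- right[j:nr]
    merged
  }
  rec(y)
  counter
}

#' Pairwise Kendall tau-b matrix of a collection of rankings
#'
#' @param rankings a named list of rank vectors over a shared item set, or a
#'   matrix with items in rows and rankings in columns.
#' @return symmetric matrix of tau-b values with unit diagonal.
#' @export
tau_matrix <- function(rankings) {
  if (is.matrix(rankings)) {
    rankings <- stats::setNames(
      lapply(seq_len(ncol(rankings)), function(j) {
        stats::setNames(rankings[, j], rownames(rankings))
      }),
      colnames(rankings) %||% as.character(seq_len(ncol(rankings))))
  }
  k <- length(rankings)
  stopifnot(k >= 2L)
  labs <- names(rankings) %||% as.character(seq_len(k))
  M <- diag(1, k)
  dimnames(M) <- list(labs, labs)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      M[i, j] <- M[j, i] <- kendall_tau(rankings[[i]], rankings[[j]])
    }
  }
  M
}

#' Metapath diversity summaries
#'
#' Counts, per (source, target) pair, the number of metapaths with a non-zero
#' count feature (how diverse the literature connections are), and — when
#' there are at least two targets — the Pearson correlation matrix between
#' targets' per-source metapath-count vectors.
#'
#' @param X a [build_feature_tensor()] result.
#' @return list with `counts` (sources x targets integer matrix) and
#'   `correlation` (targets x targets matrix, `NULL` for a single target;
#'   entries involving a zero-variance count vector are `NA`).
#' @export
metapath_diversity <- function(X) {
  stopifnot(inherits(X, "feature_tensor"))
  cnt <- X[, , , "count", drop = FALSE]
  counts <- apply(cnt > 0, c(1, 2), sum)
  correlation <- NULL
  if (ncol(counts) >= 2L) {
    ## zero-variance columns have no defined correlation: NA, not a warning
    correlation <- suppressWarnings(stats::cor(counts, method = "pearson"))
  }
  list(counts = counts, correlation = correlation)
}

#' High-residual comparison of two aggregate rankings
#'
#' The residual of a shared item is its rank under ranking A minus its rank
#' under ranking B; large positive residuals mean the item fares much better
#' in B, large negative much better in A. The report partitions the top of
#' the comparison the way a Venn diagram is read: `overlap` holds the top-`k`
#' shared items by smallest mean rank (excluding items already claimed by a
#' side), `side_a` the top-`k` most negative residuals, `side_b` the top-`k`
#' most positive. Ties are broken lexicographically by CUI; the three lists
#' are disjoint.
#'
#' @param rank_a,rank_b named rank vectors (1 = best) over overlapping item
#'   sets.
#' @param k list length (default 10).
#' @return an object of class `residual_report`: `table` (per shared item:
#'   `rank_a`, `rank_b`, `residual`, `mean_rank`), `overlap`, `side_a`,
#'   `side_b`, `k`.
#' @export
residual_report <- function(rank_a, rank_b, k = 10) {
  stopifnot(k >= 1)
  shared <- intersect(names(rank_a), names(rank_b))
  if (!length(shared)) {
    lbd_stop("lbd_degenerate_error", "rankings share no items")
  }
  shared <- sort(shared)
  a <- as.numeric(rank_a[shared])
  b <- as.numeric(rank_b[shared])
  tab <- data.frame(cui = shared, rank_a = a, rank_b = b,
                    residual = a - b, mean_rank = (a + b) / 2,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$residual), tab$cui), , drop = FALSE]
  rownames(tab) <- NULL
  neg <- tab[tab$residual < 0, , drop = FALSE]
  posi <- tab[tab$residual > 0, , drop = FALSE]
  side_a <- utils::head(neg[order(neg$residual, neg$cui), "cui"], k)
  side_b <- utils::head(posi[order(-posi$residual, posi$cui), "cui"], k)
  rest <- tab[!(tab$cui %in% c(side_a, side_b)), , drop = FALSE]
  overlap <- utils::head(rest[order(rest$mean_rank, rest$cui), "cui"], k)
  structure(list(table = tab, overlap = overlap, side_a = side_a,
                 side_b = side_b, k = k),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual_report> %d shared items (k = %d)\n",
              nrow(x$table), x$k))
  cat("overlap:", paste(x$overlap, collapse = ", "), "\n")
  cat("side A :", paste(x$side_a, collapse = ", "), "\n")
  cat("side B :", paste(x$side_b, collapse = ", "), "\n")
  invisible(x)
}
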