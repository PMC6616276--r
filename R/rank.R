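#' Dense ranking of a numeric vector
#'
#' Tied values share a rank and the next distinct value receives the next
#' integer, so ranks always form `1..k` with no gaps. By default higher
#' values rank better (rank 1 = largest value), matching "higher feature
#' score means a higher rank".
#'
#' @param values non-empty numeric vector.
#' @param descending rank largest value first? (default `TRUE`)
#' @return integer vector of dense ranks.
#' @export
dense_rank <- function(values, descending = TRUE) {
  stopifnot(length(values) >= 1L, is.numeric(values))
  match(values, sort(unique(values), decreasing = descending))
}

#' Convert a feature tensor into a ranker matrix
#'
#' One ranker (column) per kept (target, metapath, feature) combination:
#' multi-target runs concatenate rankers along the metapath dimension.
#' Columns that are all-zero across items carry no ordering information and
#' are dropped; the rest are dense-ranked descending, so items with zero
#' feature value receive the column's worst rank (they stay ranked, keeping
#' every column a total ranking).
#'
#' @param X a [build_feature_tensor()] result.
#' @param targets target CUIs to keep (default: all in `X`).
#' @param features feature names to keep (default: all in `X`).
#' @return an object of class `rank_matrix`: list with `items` (source CUIs),
#'   `rankers` (labels `"target|metapath|feature"`), and `ranks` (integer
#'   matrix, items x rankers, rank 1 = best).
#' @export
build_rank_matrix <- function(X, targets = NULL, features = NULL) {
  stopifnot(inherits(X, "feature_tensor"))
  dn <- dimnames(X)
  targets <- targets %||% dn[[2]]
  features <- features %||% dn[[4]]
  stopifnot(all(targets %in% dn[[2]]), all(features %in% dn[[4]]))
  items <- dn[[1]]
  cols <- list()
  labels <- character()
  for (tg in targets) {
    for (f in features) {
      for (m in dn[[3]]) {
        v <- X[, tg, m, f]
        if (all(v == 0)) next
        cols[[length(cols) + 1L]] <- dense_rank(v, descending = TRUE)
        labels <- c(labels, paste(tg, m, f, sep = "|"))
      }
    }
  }
  if (!length(cols)) {
    lbd_stop("lbd_degenerate_error",
             "no informative ranker columns after dropping all-zero ones")
  }
  ranks <- do.call(cbind, cols)
  dimnames(ranks) <- list(items, labels)
  structure(list(items = items, rankers = labels, ranks = ranks),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %d items x %d rankers\n",
              length(x$items), length(x$rankers)))
  invisible(x)
}

#' Unsupervised rank aggregation (ULARA)
#'
#' Learns one non-negative weight per ranker, guided by the principle that a
#' ranker's contribution is determined by its tendency to agree with the rest
#' of the pool. Starting from uniform weights, each iteration computes the
#' weighted consensus rank per item, `mu(x) = sum_i w_i r_i(x)`, measures each
#' ranker's squared disagreement `D_i = sum_x (r_i(x) - mu(x))^2`, takes the
#' additive gradient step `w_i <- w_i - eta * D_i / sum_j D_j`, and projects
#' back onto the probability simplex (clip at zero, renormalize). Iteration
#' stops when the largest weight change falls below `tol` (in particular
#' immediately at the uniform fixed point when all rankers agree) or after
#' `max_iters`. The procedure is deterministic. Items are finally scored by
#' `sum_i w_i r_i(x)` and ordered by ascending score, ties broken
#' lexicographically by CUI.
#'
#' @param R a [build_rank_matrix()] result (or a bare integer matrix with
#'   item rownames).
#' @param learning_rate step size `eta` (default 0.01).
#' @param max_iters iteration cap (default 500).
#' @param tol convergence threshold on `max |delta w|` (default 1e-8).
#' @return an object of class `ulara_result`: `weights` (named, on the
#'   simplex), `aggregate_score` (named, per item), `ordering` (items best
#'   first), `iterations`, `converged`.
#' @export
ulara_aggregate <- function(R, learning_rate = 0.01, max_iters = 500,
                            tol = 1e-8) {
  ranks <- if (inherits(R, "rank_matrix")) R$ranks else as.matrix(R)
  items <- rownames(ranks) %||% as.character(seq_len(nrow(ranks)))
  if (nrow(ranks) < 2L) {
    lbd_stop("lbd_degenerate_error", "need at least 2 items to aggregate")
  }
  n_rankers <- ncol(ranks)
  if (n_rankers < 1L) lbd_stop("lbd_degenerate_error", "need >= 1 ranker")
  w <- rep(1 / n_rankers, n_rankers)
  iters <- 0L
  converged <- FALSE
  while (iters < max_iters) {
    iters <- iters + 1L
    mu <- as.vector(ranks %*% w)
    D <- colSums((ranks - mu)^2)
    sD <- sum(D)
    if (sD == 0) { # all rankers agree with the consensus: fixed point
      converged <- TRUE
      break
    }
    w_new <- w - learning_rate * D / sD
    w_new[w_new < 0] <- 0
    w_new <- w_new / sum(w_new)
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  names(w) <- colnames(ranks)
  score <- as.vector(ranks %*% w)
  names(score) <- items
  ordering <- items[order(score, items)]
  structure(list(weights = w, aggregate_score = score, ordering = ordering,
                 iterations = iters, converged = converged),
            class = "ulara_result")
}

#' @export
print.ulara_result <- function(x, ...) {
  cat(sprintf("<ulara_result> %d items, %d rankers, %d iterations (%s)\n",
              length(x$ordering), length(x$weights), x$iterations,
              if (x$converged) "converged" else "max_iters reached"))
  cat("top items:", paste(utils::head(x$ordering, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Final aggregate ranks from a ULARA result
#'
#' Dense position of each item in the aggregate ordering (1 = best).
#'
#' @param res a [ulara_aggregate()] result.
#' @return named integer vector of ranks.
#' @export
aggregate_ranks <- function(res) {
  stopifnot(inherits(res, "ulara_result"))
  stats::setNames(match(names(res$aggregate_score), res$ordering),
                  names(res$aggregate_score))
}
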