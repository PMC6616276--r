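#' Construct a metapath
#'
#' A metapath is an orientation-aware sequence of (node type, predicate, node
#' type) steps at the type level; each concrete path instance in the graph
#' conforms to one metapath. A step may be traversed against edge direction
#' (`rev = TRUE`), which the canonical string marks with `<`:
#' `"A-R1>B"` is a forward step, `"B<R1-A"` a reverse one, so e.g.
#' `"A-R1>B<R1-A"` is the out-and-back two-step metapath.
#'
#' @param from_type,predicate,to_type character vectors (one element per
#'   step); consecutive steps must chain (`to_type[i] == from_type[i+1]`).
#' @param rev logical vector: is each step traversed against edge direction?
#' @return an object of class `metapath` (a data frame of steps).
#' @export
metapath <- function(from_type, predicate, to_type,
                     rev = rep(FALSE, length(predicate))) {
  k <- length(predicate)
  stopifnot(k >= 1L, length(from_type) == k, length(to_type) == k,
            length(rev) == k)
  if (k > 1L && any(to_type[-k] != from_type[-1])) {
    lbd_stop("lbd_parse_error", "metapath steps do not chain")
  }
  structure(data.frame(from_type = from_type, predicate = predicate,
                       to_type = to_type, rev = rev,
                       stringsAsFactors = FALSE),
            class = c("metapath", "data.frame"))
}

#' Canonical string form of a metapath
#' @param x a [metapath()].
#' @param ... unused.
#' @return string like `"A-R1>B-R2>C"` (with `<` marking reverse steps).
#' @export
format.metapath <- function(x, ...) {
  out <- x$from_type[1]
  for (i in seq_len(nrow(x))) {
    out <- if (x$rev[i]) {
      paste0(out, "<", x$predicate[i], "-", x$to_type[i])
    } else {
      paste0(out, "-", x$predicate[i], ">", x$to_type[i])
    }
  }
  out
}

#' @export
print.metapath <- function(x, ...) {
  cat("<metapath>", format(x), "\n")
  invisible(x)
}

#' Parse a canonical metapath string
#' @param s a string produced by [format.metapath()].
#' @return a [metapath()].
#' @export
parse_metapath <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- gregexpr("[^-<>]+|[-<>]", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (length(toks) < 4L || length(toks) %% 4L != 1L) {
    lbd_stop("lbd_parse_error", "malformed metapath string: %s", s)
  }
  k <- (length(toks) - 1L) %/% 4L
  from <- character(k); pred <- character(k); to <- character(k)
  rv <- logical(k)
  for (i in seq_len(k)) {
    j <- (i - 1L) * 4L + 1L
    from[i] <- toks[j]
    open <- toks[j + 1L]; pred[i] <- toks[j + 2L]; close <- toks[j + 3L]
    to[i] <- toks[j + 4L]
    if (open == "-" && close == ">") {
      rv[i] <- FALSE
    } else if (open == "<" && close == "-") {
      rv[i] <- TRUE
    } else {
      lbd_stop("lbd_parse_error", "malformed step %d in metapath: %s", i, s)
    }
  }
  metapath(from, pred, to, rv)
}

## For a step traversed from node u to node v, resolve the underlying
## directed metaedge and which side each endpoint occupies.
step_metaedge <- function(step) {
  if (step$rev) {
    list(me = c(step$to_type, step$predicate, step$from_type),
         u_side = "target", v_side = "source")
  } else {
    list(me = c(step$from_type, step$predicate, step$to_type),
         u_side = "source", v_side = "target")
  }
}
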