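`%||%` <- function(a, b) if (is.null(a)) b else a

## classed conditions so callers/tests can distinguish failure modes
lbd_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lbd_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_cui <- function(x) {
  is.character(x) & grepl("^C[0-9]+$", x)
}

assert_cui <- function(x, what = "cui") {
  if (length(x) != 1L || is.na(x) || !is_cui(x)) {
    lbd_stop("lbd_parse_error", "malformed CUI for %s: %s", what,
             paste(utils::head(x, 3), collapse = ", "))
  }
  invisible(x)
}

## Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
## random state afterwards. No global random state leaks out.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## 32-bit FNV-1a over a string, returned as 8 hex chars. Done in doubles with
## a 16/16 bit split so the multiply never exceeds 2^53.
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31)) # sign-safe; top bit folded
}

## deterministic TSV writer with "# "-prefixed provenance header lines
write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste0("# ", header_lines), con, sep = "\n")
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    quote = "", stringsAsFactors = FALSE)
}

## format numbers so that write -> read is lossless for doubles
num_chr <- function(x) {
  ifelse(x == round(x) & abs(x) < 2^53, sprintf("%.0f", x),
         sprintf("%.17g", x))
}
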