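# Library-call trace parsing and line-by-line difference classification.
#
# Two executions that produce identical results are assumed to perform the
# same calls to libmath, in the same order, so paired traces are compared
# line by line and each pair of lines falls in exactly one class:
#   identical - same function, arguments and return value
#   type1     - different arguments, identical return (non-injective
#               functions such as floor()/ceil())
#   type2     - different arguments, different return (cascading drift)
#   type3     - identical arguments, different return (implementation
#               change in the library itself; the root cause class)
#   mismatch  - different functions called (diverged control flow)

DIFF_CLASSES <- c("identical", "type1", "type2", "type3", "mismatch")

TRACE_LINE_RE <- paste0(
  "^\\s*(?:\\[pid\\s+([0-9]+)\\]\\s+)?",   # optional "[pid N] " prefix
  "([A-Za-z_][A-Za-z0-9_]*)",              # function name
  "\\((.*)\\)",                            # argument list
  "\\s*=\\s*",
  "(\\S+)\\s*$")                           # return token ("void" reserved)

#' Parse a library-call trace log
#'
#' One call per line in the dialect `[pid N] func(arg1, arg2) = ret`, where
#' the pid prefix is optional (present when the tracer follows children
#' created by `fork()`/`clone()`). Lines starting with `#` are comments.
#' Argument and return tokens are kept verbatim as printed (decimal
#' strings), trimmed of surrounding whitespace.
#'
#' @param x Path to a log file, or a character vector of lines.
#' @param strict If `TRUE`, any line that does not match the grammar is an
#'   error naming the line number and text; if `FALSE` (default) such lines
#'   are skipped with a warning and do not consume an index.
#' @return A data frame of class `call_trace` with one row per call:
#'   `index` (0-based position), `pid` (integer or `NA`), `func`,
#'   `args` (list column of trimmed argument token vectors), `args_key`
#'   (the tokens re-joined with `","`, used for comparison), `ret`, `raw`.
#' @export
parse_trace <- function(x, strict = FALSE) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE) else x
  parse_trace_lines(lines, strict = strict, offset = 0L)
}

parse_trace_lines <- function(lines, strict = FALSE, offset = 0L) {
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  cand <- lines[keep]
  cand_lineno <- which(keep) + offset
  m <- regmatches(cand, regexec(TRACE_LINE_RE, cand))
  ok <- lengths(m) == 5L
  if (any(!ok)) {
    bad <- which(!ok)[1]
    msg <- sprintf("unparseable trace line %d: %s",
                   cand_lineno[bad], sQuote(cand[bad]))
    if (strict) stop(msg)
    warning(sprintf("%d unparseable line(s) skipped; first: %s",
                    sum(!ok), msg))
    m <- m[ok]; cand <- cand[ok]
  }
  n <- length(m)
  pid <- func <- ret <- character(n)
  argstr <- character(n)
  for (i in seq_len(n)) {
    pid[i] <- m[[i]][2]; func[i] <- m[[i]][3]
    argstr[i] <- m[[i]][4]; ret[i] <- m[[i]][5]
  }
  args <- lapply(argstr, function(s) {
    if (!nzchar(trimws(s))) character(0)
    else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  })
  out <- data.frame(index = seq_len(n) - 1L,
                    pid = ifelse(pid == "", NA_integer_,
                                 suppressWarnings(as.integer(pid))),
                    func = func,
                    args_key = vapply(args, paste, "", collapse = ","),
                    ret = trimws(ret),
                    raw = cand,
                    stringsAsFactors = FALSE)
  out$args <- args
  class(out) <- c("call_trace", "data.frame")
  out
}

#' Classify one pair of trace records
#'
#' Records at the same index in two traces are compared by exact string
#' equality of their trimmed tokens. Different function names take
#' precedence (`mismatch`: comparing arguments across different functions
#' is meaningless); otherwise the argument-list and return-value equalities
#' select among `type1` (args differ, return equal), `type2` (both differ),
#' `type3` (args equal, return differs) and `identical`.
#'
#' @param a,b Single records: one-row `call_trace` data frames, or lists
#'   with `func`, `args` (character vector) and `ret`.
#' @return One of `"identical"`, `"type1"`, `"type2"`, `"type3"`,
#'   `"mismatch"`.
#' @export
classify_pair <- function(a, b) {
  key <- function(r) {
    if (is.data.frame(r)) {
      stopifnot(nrow(r) == 1L)
      list(func = r$func, args = r$args_key, ret = r$ret)
    } else {
      list(func = r$func, args = paste(trimws(r$args), collapse = ","),
           ret = trimws(r$ret))
    }
  }
  ka <- key(a); kb <- key(b)
  classify_keys(ka$func, ka$args, ka$ret, kb$func, kb$args, kb$ret)
}

# vectorized classification over token keys
classify_keys <- function(func_a, args_a, ret_a, func_b, args_b, ret_b) {
  cls <- rep("identical", length(func_a))
  args_eq <- args_a == args_b
  ret_eq <- ret_a == ret_b
  cls[!args_eq & ret_eq] <- "type1"
  cls[!args_eq & !ret_eq] <- "type2"
  cls[args_eq & !ret_eq] <- "type3"
  cls[func_a != func_b] <- "mismatch"  # evaluated last: takes precedence
  cls
}

#' Compare two parsed traces line by line
#'
#' Classifies every shared index, counts per-(function, class) totals,
#' records the first differing index and builds cumulative difference
#' series sampled at checkpoint indices (the series plotted as "cumulative
#' differences vs. call number" in trace audits). If the traces have
#' different lengths, each unpaired trailing line counts as a `mismatch`
#' attributed to its own function — diverged control flow lengthens the
#' mismatch series rather than aborting the comparison.
#'
#' @param a,b `call_trace` objects from [parse_trace()], or objects
#'   coercible by it.
#' @param checkpoint Interval (in compared lines) at which the cumulative
#'   series are sampled; the final index is always included.
#' @param per_pid If `TRUE`, split both traces into per-pid streams and
#'   compare each stream independently, returning a named list of results.
#'   Default compares in file order ignoring pids.
#' @param keep_records If `FALSE`, drop the per-index classification table
#'   from the result (summaries are kept); useful for very long traces.
#' @return A `trace_diff` object: list with `records` (index, func_a,
#'   func_b, class), `totals` (function x class count table as a data
#'   frame), `class_totals` (named vector over the five classes),
#'   `first_difference` (list(index, class) or NULL), `cumulative`
#'   (data frame index/func/class/count at checkpoints), `n_compared`.
#' @export
diff_traces <- function(a, b, checkpoint = 10000L, per_pid = FALSE,
                        keep_records = TRUE) {
  if (!inherits(a, "call_trace")) a <- parse_trace(a)
  if (!inherits(b, "call_trace")) b <- parse_trace(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("cannot diff an empty trace")
  if (per_pid) {
    pids <- sort(unique(c(a$pid, b$pid)), na.last = TRUE)
    out <- lapply(pids, function(p) {
      sel <- function(tr) {
        sub <- tr[if (is.na(p)) is.na(tr$pid) else !is.na(tr$pid) & tr$pid == p, ]
        sub$index <- seq_len(nrow(sub)) - 1L
        sub
      }
      sa <- sel(a); sb <- sel(b)
      if (nrow(sa) == 0L && nrow(sb) == 0L) return(NULL)
      if (nrow(sa) == 0L || nrow(sb) == 0L)
        stop("pid ", p, " present in only one trace")
      diff_traces(sa, sb, checkpoint = checkpoint, keep_records = keep_records)
    })
    names(out) <- ifelse(is.na(pids), "<no pid>", as.character(pids))
    return(out[!vapply(out, is.null, logical(1))])
  }

  n <- max(nrow(a), nrow(b))
  pad <- function(v, fill = NA) c(v, rep(fill, n - length(v)))
  func_a <- pad(a$func); func_b <- pad(b$func)
  shared <- seq_len(min(nrow(a), nrow(b)))
  cls <- rep("mismatch", n)  # unpaired tail defaults to mismatch
  cls[shared] <- classify_keys(a$func[shared], a$args_key[shared],
                               a$ret[shared], b$func[shared],
                               b$args_key[shared], b$ret[shared])
  records <- data.frame(index = seq_len(n) - 1L, func_a = func_a,
                        func_b = func_b, class = cls,
                        stringsAsFactors = FALSE)
  build_trace_diff(records, n, checkpoint, keep_records)
}

build_trace_diff <- function(records, n, checkpoint, keep_records) {
  cls <- records$class
  diff_rows <- records[cls != "identical", , drop = FALSE]
  # attribute a difference to the function observed in A, or B for A-tails
  diff_func <- ifelse(is.na(diff_rows$func_a), diff_rows$func_b,
                      diff_rows$func_a)
  totals <- if (nrow(diff_rows) > 0L)
    as.data.frame(table(func = diff_func, class = diff_rows$class),
                  responseName = "count", stringsAsFactors = FALSE)
  else data.frame(func = character(0), class = character(0),
                  count = integer(0))
  totals <- totals[totals$count > 0L, , drop = FALSE]
  rownames(totals) <- NULL
  class_totals <- vapply(DIFF_CLASSES, function(k) sum(cls == k), integer(1))
  first_difference <- if (nrow(diff_rows) > 0L) {
    i <- which.min(diff_rows$index)
    list(index = diff_rows$index[i], class = diff_rows$class[i])
  } else NULL

  checkpoints <- unique(c(
    if (checkpoint <= n) seq.int(checkpoint, n, by = checkpoint), n))
  cum <- if (nrow(totals) > 0L) {
    do.call(rbind, lapply(seq_len(nrow(totals)), function(r) {
      idx <- sort(diff_rows$index[diff_func == totals$func[r] &
                                    diff_rows$class == totals$class[r]])
      data.frame(index = checkpoints - 1L, func = totals$func[r],
                 class = totals$class[r],
                 count = findInterval(checkpoints - 1L, idx),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(index = integer(0), func = character(0),
                    class = character(0), count = integer(0))
  structure(list(records = if (keep_records) records else NULL,
                 totals = totals, class_totals = class_totals,
                 first_difference = first_difference,
                 cumulative = cum, n_compared = n),
            class = "trace_diff")
}

#' Streaming trace comparison for very long logs
#'
#' Reads the two log files in chunks, classifying and accumulating as it
#' goes, so memory stays proportional to the chunk size rather than the
#' trace length (traces can run to tens of millions of calls). Produces the
#' same summaries as [diff_traces()]; the per-index classification table is
#' optionally streamed to a TSV sink instead of being kept in memory.
#'
#' @param path_a,path_b Paths to the two log files.
#' @param checkpoint Chunk size and cumulative-series sampling interval.
#' @param strict Passed to the parser.
#' @param records_tsv Optional path: per-index classifications are appended
#'   here (columns index, func_a, func_b, class) instead of kept in memory.
#' @return A `trace_diff` object with `records = NULL`.
#' @export
diff_trace_files <- function(path_a, path_b, checkpoint = 10000L,
                             strict = FALSE, records_tsv = NULL) {
  con_a <- file(path_a, "r"); on.exit(close(con_a), add = TRUE)
  con_b <- file(path_b, "r"); on.exit(close(con_b), add = TRUE)
  sink_con <- NULL
  if (!is.null(records_tsv)) {
    sink_con <- file(records_tsv, "w"); on.exit(close(sink_con), add = TRUE)
    writeLines("index\tfunc_a\tfunc_b\tclass", sink_con)
  }
  n <- 0L
  chunks <- list()
  lineno_a <- 0L; lineno_b <- 0L
  repeat {
    la <- readLines(con_a, n = checkpoint, warn = FALSE)
    lb <- readLines(con_b, n = checkpoint, warn = FALSE)
    if (length(la) == 0L && length(lb) == 0L) break
    pa <- parse_trace_lines(la, strict = strict, offset = lineno_a)
    pb <- parse_trace_lines(lb, strict = strict, offset = lineno_b)
    lineno_a <- lineno_a + length(la); lineno_b <- lineno_b + length(lb)
    m <- max(nrow(pa), nrow(pb))
    if (m == 0L) next
    pad <- function(v) c(v, rep(NA, m - length(v)))
    shared <- seq_len(min(nrow(pa), nrow(pb)))
    cls <- rep("mismatch", m)
    cls[shared] <- classify_keys(pa$func[shared], pa$args_key[shared],
                                 pa$ret[shared], pb$func[shared],
                                 pb$args_key[shared], pb$ret[shared])
    rec <- data.frame(index = n + seq_len(m) - 1L, func_a = pad(pa$func),
                      func_b = pad(pb$func), class = cls,
                      stringsAsFactors = FALSE)
    # chunked reading only pairs lines within a chunk; a length difference
    # inside one chunk shifts pairing for later chunks exactly as the
    # in-memory rule does only when it is a trailing tail, so unequal
    # chunk fills before EOF are an error
    if (nrow(pa) != nrow(pb) &&
        (length(la) == checkpoint && length(lb) == checkpoint))
      stop("traces fell out of step mid-file (unequal parseable lines in a ",
           "full chunk); re-run with diff_traces() on parsed traces")
    n <- n + m
    if (!is.null(sink_con)) {
      utils::write.table(rec, sink_con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE, na = "")
    }
    chunks[[length(chunks) + 1L]] <-
      rec[rec$class != "identical", , drop = FALSE]
  }
  if (n == 0L) stop("cannot diff an empty trace")
  diff_rows <- do.call(rbind, c(chunks,
                                list(data.frame(index = integer(0),
                                                func_a = character(0),
                                                func_b = character(0),
                                                class = character(0)))))
  # rebuild the summary object from the (sparse) difference rows
  records <- data.frame(index = seq_len(n) - 1L,
                        func_a = NA_character_, func_b = NA_character_,
                        class = "identical", stringsAsFactors = FALSE)
  if (nrow(diff_rows) > 0L) {
    records$func_a[diff_rows$index + 1L] <- diff_rows$func_a
    records$func_b[diff_rows$index + 1L] <- diff_rows$func_b
    records$class[diff_rows$index + 1L] <- diff_rows$class
  }
  out <- build_trace_diff(records, n, checkpoint, keep_records = FALSE)
  out
}

#' Per-function difference summary
#'
#' Tabulates how many differences of each class were attributed to each
#' function, omitting functions with no differences. The counts partition
#' the non-identical compared lines.
#'
#' @param result A `trace_diff` object.
#' @return Data frame with columns `func`, `class`, `count`.
#' @export
summarize_functions <- function(result) {
  stopifnot(inherits(result, "trace_diff"))
  result$totals
}

#' @export
print.trace_diff <- function(x, ...) {
  cat(sprintf("Trace comparison over %d line pairs\n", x$n_compared))
  nd <- sum(x$class_totals[setdiff(DIFF_CLASSES, "identical")])
  if (nd == 0L) {
    cat("  traces are identical\n")
  } else {
    cat(sprintf("  first difference: index %d (%s)\n",
                x$first_difference$index, x$first_difference$class))
    for (k in setdiff(DIFF_CLASSES, "identical"))
      if (x$class_totals[[k]] > 0)
        cat(sprintf("  %-9s %d\n", k, x$class_totals[[k]]))
  }
  invisible(x)
}

#' Write trace-diff outputs to a directory
#'
#' Writes the per-index classification TSV (when records were kept), the
#' cumulative-series TSV and a JSON summary of totals and the first
#' difference.
#'
#' @param result A `trace_diff` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trace_diff <- function(result, dir) {
  stopifnot(inherits(result, "trace_diff"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(result$records)) {
    p <- file.path(dir, "classifications.tsv")
    utils::write.table(result$records, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "cumulative.tsv")
  utils::write.table(result$cumulative, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(n_compared = result$n_compared,
         class_totals = as.list(result$class_totals),
         first_difference = result$first_difference,
         per_function = result$totals),
    p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
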