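# Vertex-wise cortical-thickness difference statistics. Thickness is sampled
# per subject at each vertex of a common surface template (mm); comparing
# two processing conditions reduces, per vertex, to a one-sample test on the
# paired difference scores (an intercept-only GLM, Y = 1, on d = A - B).

#' Assemble a subjects x vertices thickness matrix
#'
#' @param values Numeric matrix, rows = subjects, columns = vertices (mm).
#' @param subjects Optional subject identifiers (rownames used if present).
#' @return A `thickness_matrix` (the matrix with subject ids as rownames).
#' @export
thickness_matrix <- function(values, subjects = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("thickness values must be finite numbers")
  if (any(values < 0)) stop("thickness values must be non-negative (mm)")
  if (!is.null(subjects)) {
    stopifnot(length(subjects) == nrow(values))
    rownames(values) <- as.character(subjects)
  } else if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  }
  structure(values, class = c("thickness_matrix", class(values)))
}

#' Read a thickness matrix from delimited text
#'
#' Rows are subjects, columns vertices; an optional first column named
#' `subject` carries ids, and a header row is optional.
#'
#' @param path TSV/CSV file path.
#' @param sep Field separator (default tab).
#' @param header Whether the file has a header row.
#' @return A `thickness_matrix`.
#' @export
read_thickness <- function(path, sep = "\t", header = TRUE) {
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE)
  subjects <- NULL
  if (ncol(df) > 1 && (is.character(df[[1]]) ||
                       identical(tolower(names(df)[1]), "subject"))) {
    subjects <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  thickness_matrix(as.matrix(df), subjects = subjects)
}

#' Write a thickness matrix as TSV
#'
#' @param x A `thickness_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_thickness <- function(x, path) {
  df <- data.frame(subject = rownames(x), unclass(x), check.names = FALSE)
  names(df)[-1] <- sprintf("v%d", seq_len(ncol(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-subject, per-vertex difference scores between two conditions
#'
#' @param a,b `thickness_matrix` objects with identical shape and subject
#'   order (mismatched ids are an error — a silent reorder could pair the
#'   wrong subjects).
#' @return A plain subjects x vertices matrix of `a - b` (mm).
#' @export
difference_scores <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("condition matrices have different shapes")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("subject identifiers differ between conditions")
  unclass(a) - unclass(b)
}

#' Vertex-wise one-sample t statistics on difference scores
#'
#' For each vertex: `t = mean(d) / (sd(d) / sqrt(n))` with the n-1
#' denominator in sd, plus the mean and sd of the absolute differences
#' (the quantities usually mapped onto the surface). Vertices where every
#' subject differs identically (zero variance) get `defined = FALSE` and an
#' `NA` t value rather than an infinity, so downstream summaries stay
#' finite.
#'
#' @param d Subjects x vertices difference matrix (from
#'   [difference_scores()]).
#' @return A `vertex_stats` data frame (`vertex`, `mean_diff`, `sd_diff`,
#'   `mean_abs_diff`, `sd_abs_diff`, `t`, `defined`) with `n` and
#'   `df = n - 1` as attributes.
#' @export
vertex_ttest <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 subjects for a t statistic")
  mu <- colMeans(d)
  sdv <- sqrt(colSums(sweep(d, 2, mu)^2) / (n - 1))
  defined <- sdv > 0
  tval <- ifelse(defined, mu / (sdv / sqrt(n)), NA_real_)
  ad <- abs(d)
  mu_a <- colMeans(ad)
  sd_a <- sqrt(colSums(sweep(ad, 2, mu_a)^2) / (n - 1))
  out <- data.frame(vertex = seq_len(ncol(d)), mean_diff = mu, sd_diff = sdv,
                    mean_abs_diff = mu_a, sd_abs_diff = sd_a, t = tval,
                    defined = defined, row.names = NULL)
  structure(out, n = n, df = n - 1L,
            class = c("vertex_stats", "data.frame"))
}

#' @export
print.vertex_stats <- function(x, ...) {
  cat(sprintf("Vertex-wise difference statistics: %d vertices, n = %d (df = %d)\n",
              nrow(x), attr(x, "n"), attr(x, "df")))
  def <- x$t[x$defined]
  if (length(def) > 0)
    cat(sprintf("  |t| range over defined vertices: %.4g .. %.4g\n",
                min(abs(def)), max(abs(def))))
  cat(sprintf("  mean absolute difference: %.4g mm (max %.4g)\n",
              mean(x$mean_abs_diff), max(x$mean_abs_diff)))
  invisible(x)
}

#' Threshold a vertex t map at an uncorrected significance level
#'
#' Two-sided p values under the t distribution with `df` degrees of freedom;
#' undefined (zero-variance) vertices are never selected. No multiple-
#' comparison correction is applied.
#'
#' @param stats A `vertex_stats` object.
#' @param alpha Two-sided significance level.
#' @return A logical vector over vertices.
#' @export
threshold_tmap <- function(stats, alpha) {
  stopifnot(inherits(stats, "vertex_stats"), alpha > 0, alpha <= 1)
  df <- attr(stats, "df")
  p <- 2 * stats::pt(-abs(stats$t), df = df)
  out <- !is.na(p) & p < alpha
  if (alpha >= 1) out <- stats$defined  # every defined vertex
  out
}

#' Write vertex statistics as TSV
#'
#' @param stats A `vertex_stats` object.
#' @param path Output path.
#' @param alpha Optional significance level; adds a `selected` column from
#'   [threshold_tmap()].
#' @return Invisibly, `path`.
#' @export
write_vertex_stats <- function(stats, path, alpha = NULL) {
  tab <- as.data.frame(stats)
  if (!is.null(alpha)) tab$selected <- threshold_tmap(stats, alpha)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
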