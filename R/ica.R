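# ICA spatial component matching. Component order (and sign) is arbitrary
# between two ICA runs, so each component in one set is matched to the
# maximally correlated component in the other, and agreement is quantified
# by Dice overlap of the thresholded positive and negative parts separately.
# The matching is done per component with no one-to-one constraint; since it
# is not symmetric, both directions are reported.

#' Bundle ICA spatial maps into a component set
#'
#' @param maps A list of 3D statistic maps on one common grid, or a 4D array
#'   (one component per last-dimension volume).
#' @param mask Optional binary mask on the same spatial grid.
#' @param threshold Statistic cutoff (>= 0) used when binarizing the
#'   positive/negative parts; 0 means any non-zero activation.
#' @return A `component_set` (list with `maps`, `mask`, `threshold`).
#' @export
component_set <- function(maps, mask = NULL, threshold = 0) {
  if (is.array(maps) && length(dim(maps)) == 4L) {
    nd <- dim(maps)
    maps <- lapply(seq_len(nd[4]), function(i)
      array(maps[, , , i], dim = nd[1:3]))
  }
  stopifnot(is.list(maps), length(maps) >= 1L, threshold >= 0)
  ref <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), ref))
    stop("all component maps must share one grid")
  if (!is.null(mask)) check_same_shape(mask, maps[[1]])
  structure(list(maps = maps, mask = mask, threshold = threshold),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component set: %d maps on %s grid, threshold %g%s>\n",
              length(x$maps), paste(dim(x$maps[[1]]), collapse = "x"),
              x$threshold, if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

#' Spatial correlation of two maps
#'
#' Sample Pearson correlation over (in-mask) voxels.
#'
#' @param a,b Arrays on the same grid.
#' @param mask Optional binary mask.
#' @return Correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(a, b, mask = NULL) {
  check_same_shape(a, b)
  va <- as.vector(a); vb <- as.vector(b)
  if (!is.null(mask)) {
    check_same_shape(mask, a)
    keep <- as.logical(mask)
    va <- va[keep]; vb <- vb[keep]
  }
  if (length(va) < 2L) stop("need at least 2 in-mask voxels")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance in a map; correlation undefined")
  stats::cor(va, vb)
}

#' Dice overlap of thresholded positive and negative parts
#'
#' `dice_pos` compares the supra-threshold positive supports
#' (`a > threshold` vs `b > threshold`), `dice_neg` the negative ones
#' (`a < -threshold` vs `b < -threshold`). A sign-flipped copy therefore
#' scores `dice_pos = 0` against its original: positive support against a
#' disjoint one. Empty-vs-empty parts count as agreement (1);
#' empty-vs-non-empty as 0.
#'
#' @param a,b Maps on the same grid.
#' @param threshold Non-negative cutoff.
#' @return Named numeric vector `c(dice_pos, dice_neg)`.
#' @export
thresholded_dice <- function(a, b, threshold = 0) {
  stopifnot(threshold >= 0)
  check_same_shape(a, b)
  dpart <- function(ma, mb) {
    if (sum(ma) + sum(mb) == 0) 1 else 2 * sum(ma & mb) / (sum(ma) + sum(mb))
  }
  c(dice_pos = dpart(a > threshold, b > threshold),
    dice_neg = dpart(a < -threshold, b < -threshold))
}

#' Match each component in A to the maximally correlated component in B
#'
#' Per-component matching with no bipartite constraint: several A components
#' may select the same B component. Signed matching (default) maximizes the
#' correlation itself, so a sign-flipped component matches elsewhere or
#' poorly — which is exactly how inverted positive/negative parts surface as
#' a Dice = 0 mode in agreement histograms. Absolute matching maximizes
#' `|r|` instead.
#'
#' @param a,b `component_set`s on the same grid.
#' @param signed If `TRUE` maximize r; if `FALSE` maximize `|r|`.
#' @param threshold Cutoff for the part-wise Dice; defaults to `a$threshold`.
#' @return Data frame (`index_a`, `index_b`, `correlation`, `dice_pos`,
#'   `dice_neg`), one row per component of `a`.
#' @export
match_components <- function(a, b, signed = TRUE, threshold = NULL) {
  stopifnot(inherits(a, "component_set"), inherits(b, "component_set"))
  check_same_shape(a$maps[[1]], b$maps[[1]])
  if (is.null(threshold)) threshold <- a$threshold
  mask <- a$mask
  rows <- lapply(seq_along(a$maps), function(i) {
    r <- vapply(b$maps, function(m)
      spatial_correlation(a$maps[[i]], m, mask = mask), numeric(1))
    j <- if (signed) which.max(r) else which.max(abs(r))
    dd <- thresholded_dice(a$maps[[i]], b$maps[[j]], threshold = threshold)
    data.frame(index_a = i, index_b = j, correlation = r[j],
               dice_pos = dd[["dice_pos"]], dice_neg = dd[["dice_neg"]])
  })
  do.call(rbind, rows)
}

#' Two-direction component-set comparison with pooled Dice histograms
#'
#' Runs [match_components()] A-to-B and B-to-A (the matching is not
#' symmetric), reports whether the two runs even found the same number of
#' components, and summarizes the pooled positive- and negative-part Dice
#' values as histograms with 0.1-wide bins.
#'
#' @param a,b `component_set`s.
#' @param threshold Binarization cutoff.
#' @param signed Matching mode, see [match_components()].
#' @param bin_width Histogram bin width.
#' @return A `component_comparison`: list with `ab` and `ba` match tables,
#'   `dimensions` (n_a, n_b, equal), `hist_pos`, `hist_neg`.
#' @export
compare_sets <- function(a, b, threshold = 0, signed = TRUE,
                         bin_width = 0.1) {
  ab <- match_components(a, b, signed = signed, threshold = threshold)
  ba <- match_components(b, a, signed = signed, threshold = threshold)
  structure(list(
    ab = ab, ba = ba,
    dimensions = list(n_a = length(a$maps), n_b = length(b$maps),
                      equal = length(a$maps) == length(b$maps)),
    hist_pos = histogram_summary(c(ab$dice_pos, ba$dice_pos),
                                 bin_width = bin_width),
    hist_neg = histogram_summary(c(ab$dice_neg, ba$dice_neg),
                                 bin_width = bin_width)),
    class = "component_comparison")
}

#' @export
print.component_comparison <- function(x, ...) {
  d <- x$dimensions
  cat(sprintf("Component comparison: %d vs %d components (%s)\n",
              d$n_a, d$n_b, if (d$equal) "equal" else "differ"))
  cat(sprintf("  positive parts: min %.3g, mean %.3g, sd %.3g, mode %.3g\n",
              x$hist_pos$min, x$hist_pos$mean, x$hist_pos$sd, x$hist_pos$mode))
  cat(sprintf("  negative parts: min %.3g, mean %.3g, sd %.3g, mode %.3g\n",
              x$hist_neg$min, x$hist_neg$mean, x$hist_neg$sd, x$hist_neg$mode))
  invisible(x)
}

#' Fixed-bin histogram summary (min / mean / sd / mode)
#'
#' Bins are `[k*w, (k+1)*w)` anchored at 0. For values in `[0, 1]` (Dice
#' coefficients) the final bin is closed, `[1-w, 1]`, so a perfect score of
#' 1 is countable. The mode is the center of the most populated bin, ties
#' broken toward the lowest bin; min, mean and sd are over the raw values
#' (sd with the n-1 denominator).
#'
#' @param values Non-empty numeric vector.
#' @param bin_width Bin width (default 0.1).
#' @return A `histogram_summary` list: `min`, `mean`, `sd`, `mode`,
#'   `bin_width`, `counts` (named by bin center).
#' @export
histogram_summary <- function(values, bin_width = 0.1) {
  stopifnot(length(values) >= 1L, all(is.finite(values)), bin_width > 0)
  # tolerance absorbs 0.9/0.1 = 8.9999... style representation error
  idx <- floor(values / bin_width + 1e-9)
  if (all(values >= 0 & values <= 1)) {
    top <- ceiling(1 / bin_width) - 1L
    idx <- pmin(idx, top)  # closed last bin
  }
  tab <- table(idx)
  mode_idx <- as.numeric(names(tab)[which.max(tab)])  # ties: lowest bin
  counts <- as.integer(tab)
  names(counts) <- sprintf("%g", (as.numeric(names(tab)) + 0.5) * bin_width)
  structure(list(min = min(values), mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 mode = (mode_idx + 0.5) * bin_width,
                 bin_width = bin_width, counts = counts),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf("histogram (bin %g): min %.4g, mean %.4g, sd %.4g, mode %.4g\n",
              x$bin_width, x$min, x$mean, x$sd, x$mode))
  invisible(x)
}

#' Write component-match tables as TSV
#'
#' @param comparison A `component_comparison`.
#' @param path Output TSV path (columns: direction, index_a, index_b,
#'   correlation, dice_pos, dice_neg).
#' @return Invisibly, `path`.
#' @export
write_match_table <- function(comparison, path) {
  stopifnot(inherits(comparison, "component_comparison"))
  tab <- rbind(cbind(direction = "A->B", comparison$ab),
               cbind(direction = "B->A", comparison$ba))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
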