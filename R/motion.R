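# Residual rigid-transform metrics and stage-wise mean-absolute-difference
# attribution. Motion correction estimates one rigid transform (rotation +
# translation, 6 dof) per fMRI timepoint; two runs of the same correction
# agree exactly when the residual T1 o T2^-1 is the identity, so the norm of
# its translation vector (mm) and its rotation angle (degrees) measure how
# far apart the runs are at each timepoint.

RIGID_TOL <- 1e-6

#' Construct and validate a rigid transform
#'
#' @param m A 4x4 homogeneous matrix. The last row must be `(0,0,0,1)`, the
#'   upper-left 3x3 block orthonormal (`R'R = I` within `tol`) with
#'   determinant +1 within `tol`. Matrices violating rigidity are rejected,
#'   never re-orthogonalized: a silent repair would mask exactly the kind of
#'   difference this package exists to measure.
#' @param tol Tolerance on the rigidity invariants.
#' @return A `rigid_transform` (the matrix, classed).
#' @export
rigid_transform <- function(m, tol = RIGID_TOL) {
  m <- unclass(m)
  if (!is.matrix(m) || !identical(dim(m), c(4L, 4L)))
    stop("a rigid transform must be a 4x4 matrix")
  err_row <- max(abs(m[4, ] - c(0, 0, 0, 1)))
  if (err_row > tol)
    stop(sprintf("last row is not (0,0,0,1): max deviation %.3g", err_row))
  r <- m[1:3, 1:3]
  err_orth <- max(abs(crossprod(r) - diag(3)))
  if (err_orth > tol)
    stop(sprintf("rotation block is not orthonormal: max |R'R - I| = %.3g",
                 err_orth))
  err_det <- abs(det(r) - 1)
  if (err_det > tol)
    stop(sprintf("rotation block is not proper (det R = 1): |det - 1| = %.3g",
                 err_det))
  structure(m, class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid transform: rotation %.4g deg, translation %.4g mm>\n",
              rotation_angle(x), translation_norm(x)))
  print(unclass(x))
  invisible(x)
}

#' Read a 4x4 ASCII transform file (FLIRT .mat convention)
#'
#' @param path Path to a text file of 4 lines x 4 whitespace-separated
#'   numbers.
#' @param tol Rigidity tolerance passed to [rigid_transform()].
#' @return A validated `rigid_transform`.
#' @export
load_flirt_matrix <- function(path, tol = RIGID_TOL) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != 16L)
    stop("expected 16 numbers (4x4) in ", path, ", got ", length(vals))
  rigid_transform(matrix(vals, 4, 4, byrow = TRUE), tol = tol)
}

#' Write a transform as a FLIRT-style ASCII .mat file
#'
#' Values are written with 17 significant digits so the matrix round-trips
#' bit-identically through text.
#'
#' @param x A `rigid_transform` (or 4x4 matrix).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_flirt_matrix <- function(x, path) {
  m <- unclass(x)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = "  ")), path)
  invisible(path)
}

#' Load an ordered series of transform files from a directory
#'
#' @param dir Directory containing one `.mat`-style ASCII file per
#'   timepoint, named with a zero-padded index (`MAT_0000`, `MAT_0001`, ...)
#'   so lexicographic order is temporal order.
#' @param pattern Filename regexp.
#' @return A list of `rigid_transform`s in timepoint order.
#' @export
load_flirt_series <- function(dir, pattern = "^MAT_[0-9]+") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop("no transform files matching ", sQuote(pattern),
                                " in ", dir)
  lapply(files, load_flirt_matrix)
}

#' Residual transform between two runs: T1 composed with the inverse of T2
#'
#' Matrices act on column vectors, so the residual is `T1 %*% solve(T2)`
#' (read right-to-left): undo run 2's estimate, then apply run 1's. The
#' identity iff the runs agree.
#'
#' @param t1,t2 `rigid_transform`s (4x4 matrices are validated on the fly).
#' @return A `rigid_transform`.
#' @export
residual <- function(t1, t2) {
  if (!inherits(t1, "rigid_transform")) t1 <- rigid_transform(t1)
  if (!inherits(t2, "rigid_transform")) t2 <- rigid_transform(t2)
  m <- unclass(t1) %*% solve(unclass(t2))
  m[4, ] <- c(0, 0, 0, 1)  # clear rounding dust in the homogeneous row
  rigid_transform(m, tol = 10 * RIGID_TOL)
}

#' Rotation angle of a rigid transform, in degrees
#'
#' `theta = acos((trace(R) - 1) / 2)`, with the argument clamped to
#' `[-1, 1]` to absorb rounding for angles near 0 or 180 degrees. Depends
#' only on the trace, hence invariant to conjugation by any rotation.
#'
#' @param x A `rigid_transform`.
#' @return Angle in `[0, 180]` degrees.
#' @export
rotation_angle <- function(x) {
  r <- unclass(x)[1:3, 1:3]
  arg <- (sum(diag(r)) - 1) / 2
  acos(min(1, max(-1, arg))) * 180 / pi
}

#' Euclidean norm of the translation component, in mm
#'
#' @param x A `rigid_transform`.
#' @return Non-negative translation norm.
#' @export
translation_norm <- function(x) {
  sqrt(sum(unclass(x)[1:3, 4]^2))
}

#' Per-timepoint residual metrics between two motion-correction runs
#'
#' @param series1,series2 Equal-length lists of `rigid_transform`s, one per
#'   timepoint (see [load_flirt_series()]).
#' @return A `residual_series` data frame (`timepoint`, `translation_mm`,
#'   `rotation_deg`) with the maxima in `attr(, "max_translation_mm")` and
#'   `attr(, "max_rotation_deg")` — the summary numbers one reports
#'   ("all residuals below x mm and y degrees").
#' @export
series_residuals <- function(series1, series2) {
  if (length(series1) != length(series2))
    stop("series have different lengths: ", length(series1), " vs ",
         length(series2))
  if (length(series1) == 0L) stop("empty transform series")
  rows <- lapply(seq_along(series1), function(i) {
    res <- residual(series1[[i]], series2[[i]])
    data.frame(timepoint = i - 1L,
               translation_mm = translation_norm(res),
               rotation_deg = rotation_angle(res))
  })
  out <- do.call(rbind, rows)
  structure(out,
            max_translation_mm = max(out$translation_mm),
            max_rotation_deg = max(out$rotation_deg),
            class = c("residual_series", "data.frame"))
}

#' @export
print.residual_series <- function(x, ...) {
  cat(sprintf(
    "Residual rigid transforms over %d timepoints\n", nrow(x)))
  cat(sprintf("  max translation norm: %.6g mm\n",
              attr(x, "max_translation_mm")))
  cat(sprintf("  max rotation angle:   %.6g deg\n",
              attr(x, "max_rotation_deg")))
  invisible(x)
}

#' Mean absolute difference between two images
#'
#' Mean over voxels (and timepoints, for 4D series — pooled) of `|A - B|`,
#' optionally restricted to a spatial mask. The workhorse for attributing
#' divergence to pipeline stages.
#'
#' @param a,b Arrays of identical shape (3D volumes or 4D series).
#' @param mask Optional binary mask matching the spatial dimensions; for 4D
#'   input the mask is applied to every timepoint.
#' @return Mean absolute difference (same units as the images).
#' @export
mean_abs_diff <- function(a, b, mask = NULL) {
  check_same_shape(a, b)
  d <- abs(a - b)
  if (is.null(mask)) return(mean(d))
  md <- dim(mask); dd <- dim(d)
  if (length(dd) == length(md) + 1L) {
    if (!identical(dd[-length(dd)], md))
      stop("mask does not match the spatial grid")
    keep <- as.logical(mask)
    nt <- dd[length(dd)]
    dmat <- matrix(d, ncol = nt)
    return(mean(dmat[keep, , drop = FALSE]))
  }
  check_same_shape(mask, a)
  mean(d[as.logical(mask)])
}

#' Stage-wise difference attribution across pre-processing steps
#'
#' Computes the mean absolute difference between the two runs' images after
#' each pre-processing stage and normalizes by the reference stage (usually
#' the final one), giving a profile that shows which step introduced or
#' amplified the divergence. The reference stage normalizes to exactly 1.
#'
#' @param stages Ordered named list; each element a list with images `a` and
#'   `b` (and optionally `mask`).
#' @param reference Name of the reference stage; default the last.
#' @return A `stage_mad_profile` data frame (`stage`, `raw_mad`,
#'   `normalized_mad`) with the reference name in `attr(, "reference")`.
#' @export
stage_mad_profile <- function(stages, reference = NULL) {
  stopifnot(is.list(stages), length(stages) >= 1L, !is.null(names(stages)))
  if (is.null(reference)) reference <- names(stages)[length(stages)]
  if (!reference %in% names(stages))
    stop("reference stage ", sQuote(reference), " not present")
  raw <- vapply(stages, function(s)
    mean_abs_diff(s$a, s$b, mask = s$mask), numeric(1))
  ref_mad <- raw[[reference]]
  if (ref_mad == 0)
    stop("reference stage has zero mean absolute difference: ",
         "no difference to attribute")
  out <- data.frame(stage = names(stages), raw_mad = unname(raw),
                    normalized_mad = unname(raw) / ref_mad,
                    stringsAsFactors = FALSE)
  out$normalized_mad[out$stage == reference] <- 1.0
  structure(out, reference = reference,
            class = c("stage_mad_profile", "data.frame"))
}

#' @export
print.stage_mad_profile <- function(x, ...) {
  cat(sprintf("Stage-wise MAD profile (reference: %s)\n",
              attr(x, "reference")))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
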