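# Dice overlap, binarized difference maps and checksum screening for
# segmentation label volumes. Volumes are plain integer arrays voxel-aligned
# on a common grid; comparisons never resample (grid alignment is the
# caller's responsibility, and a silent resample could mask real
# differences).

#' Dice similarity index of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`: 1 for identical non-empty masks, 0 for disjoint
#' ones. Masks may be logical or 0/1 numeric arrays of identical shape.
#'
#' @param a,b Binary masks (logical or 0/1 arrays) of the same shape.
#' @param both_empty What to return when both masks are empty: `"one"`
#'   (default; perfect agreement on absence, with a warning), `"zero"`, or
#'   `"error"`.
#' @return A value in `[0, 1]`.
#' @export
dice <- function(a, b, both_empty = c("one", "zero", "error")) {
  both_empty <- match.arg(both_empty)
  check_same_shape(a, b)
  a <- as.logical(a); b <- as.logical(b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    return(switch(both_empty,
                  one = { warning("both masks empty; Dice defined as 1"); 1 },
                  zero = 0,
                  error = stop("both masks are empty")))
  }
  2 * sum(a & b) / (na + nb)
}

check_same_shape <- function(a, b) {
  da <- if (is.null(dim(a))) length(a) else dim(a)
  db <- if (is.null(dim(b))) length(b) else dim(b)
  if (!identical(da, db))
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}

#' Per-label and global Dice overlap of two label volumes
#'
#' For each label the Dice index of the masks `A == l` and `B == l`, plus a
#' generalized (label-summed) global Dice over all non-zero labels:
#' `2 * sum_l |A_l n B_l| / sum_l (|A_l| + |B_l|)`. Label 0 is background
#' and never compared. A requested label absent from both volumes is
#' reported with `dice = NA` (absent, not disagreement).
#'
#' @param a,b Integer label volumes on the same grid.
#' @param labels Labels to compare; default is the union of non-zero labels
#'   present in either volume.
#' @return A `dice_report`: data frame (`label`, `size_a`, `size_b`,
#'   `overlap`, `dice`) with the generalized global Dice in
#'   `attr(, "global_dice")`.
#' @export
per_label_dice <- function(a, b, labels = NULL) {
  check_same_shape(a, b)
  if (is.null(labels)) {
    labels <- sort(unique(c(a[a != 0], b[b != 0])))
  }
  rows <- lapply(labels, function(l) {
    ma <- a == l; mb <- b == l
    sa <- sum(ma); sb <- sum(mb)
    ov <- sum(ma & mb)
    data.frame(label = l, size_a = sa, size_b = sb, overlap = ov,
               dice = if (sa + sb == 0) NA_real_ else 2 * ov / (sa + sb))
  })
  report <- do.call(rbind, rows)
  present <- report[!is.na(report$dice), , drop = FALSE]
  global <- if (nrow(present) == 0) NA_real_ else
    2 * sum(present$overlap) / sum(present$size_a + present$size_b)
  structure(report, global_dice = global,
            class = c("dice_report", "data.frame"))
}

#' @export
print.dice_report <- function(x, ...) {
  cat("Per-label Dice overlap\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  cat(sprintf("global (generalized) Dice: %.6g\n", attr(x, "global_dice")))
  invisible(x)
}

#' Binarized difference map of two label volumes
#'
#' @param a,b Label volumes on the same grid.
#' @return An integer 0/1 array of the same shape, 1 where the labels
#'   disagree. Summed across subjects these maps localize where a pipeline's
#'   classifications diverge.
#' @export
binarized_diff <- function(a, b) {
  check_same_shape(a, b)
  out <- array(as.integer(a != b), dim = dim(a))
  out
}

#' Voxelwise sum of binary difference masks
#'
#' @param masks A list of 0/1 arrays on one common grid (pre-aligned; no
#'   resampling is performed).
#' @return An integer count array; the value at a voxel is the number of
#'   subjects whose comparison differed there (at most `length(masks)`).
#' @export
diff_sum <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  ref <- dim(masks[[1]])
  for (m in masks) {
    if (!identical(dim(m), ref)) stop("masks are on different grids")
  }
  out <- array(0L, dim = ref)
  for (m in masks) out <- out + as.integer(m != 0)
  out
}

#' Checksum screening of two result files
#'
#' The cheap first step of a reproducibility audit: identical checksums mean
#' identical outputs and no metric needs to run. Default hashes the raw file
#' bytes with SHA-256; payload mode hashes only the voxel data of a NIfTI
#' file, so volumes that differ only in header free-text (descriptions,
#' timestamps) still screen as equal.
#'
#' @param path_a,path_b Readable files.
#' @param payload If `TRUE`, read both files as NIfTI and hash the voxel
#'   array only.
#' @return A list with `equal`, `digest_a`, `digest_b`, `algorithm`, `mode`.
#' @export
checksum_compare <- function(path_a, path_b, payload = FALSE) {
  for (p in c(path_a, path_b))
    if (!file.exists(p)) stop("cannot read file: ", p)
  h <- if (payload) {
    function(p) {
      img <- RNifti::readNifti(p)
      digest::digest(as.vector(unclass(img)), algo = "sha256")
    }
  } else {
    function(p) digest::digest(file = p, algo = "sha256")
  }
  da <- h(path_a); db <- h(path_b)
  list(equal = identical(da, db), digest_a = da, digest_b = db,
       algorithm = "sha256", mode = if (payload) "nifti-payload" else "raw")
}

#' Read a volume from a NIfTI-1 file as a plain array
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A numeric/integer array with a `voxel_size` attribute (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.vector(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)
  out
}

#' Write an array as a NIfTI-1 volume
#'
#' @param x An array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel dimensions in mm (recycled to the array rank).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(x, dim = dim(x)))
  RNifti::pixdim(img) <- rep_len(voxel_size, length(dim(x)))
  RNifti::writeNifti(img, path)
  invisible(path)
}
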