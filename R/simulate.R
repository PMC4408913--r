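# Seeded synthetic-data generators. Each generator produces a PAIR of inputs
# for one comparison module together with the ground truth planted in it, so
# recovery can be verified exactly (or within a stated tolerance) without any
# clinical MRI data. Identical seeds reproduce identical outputs; the seed is
# recorded in the ground-truth block, mirroring the fixed-vs-variable-seed
# distinction that matters for ICA runs.

TRACE_VOCAB <- c("expf", "logf", "cosf", "sinf", "ceilf", "floorf")
TRACE_FUNS <- list(expf = exp, logf = log, cosf = cos, sinf = sin,
                   ceilf = ceiling, floorf = floor)

# bump the last printed digit of a fixed-point token without carrying
bump_last_digit <- function(s) {
  last <- substr(s, nchar(s), nchar(s))
  repl <- if (last == "9") "8" else as.character(as.integer(last) + 1L)
  paste0(substr(s, 1, nchar(s) - 1L), repl)
}

#' Generate a paired pair of library-call traces with planted differences
#'
#' Builds `n_calls` identical trace lines over a small libm vocabulary, then
#' plants differences of each class at known positions:
#' * `type3`: same argument, return value perturbed in its last printed
#'   digit (an implementation change in the library);
#' * `type2`: both the argument and the return perturbed;
#' * `type1`: a `floorf` call whose two arguments differ but floor to the
#'   same integer (non-injective function);
#' * `mismatch`: the function name replaced (diverged control flow).
#'
#' Perturbations act on the final printed digit so string-mode and
#' numeric-mode comparison agree on every planted difference.
#'
#' @param n_calls Number of trace lines (>= 1).
#' @param spec Injection spec: a list with any of `type1`, `type2`, `type3`,
#'   `mismatch`, each either a vector of explicit 0-based positions or a
#'   single rate in `[0, 1)` (count = `round(rate * n_calls)`, positions
#'   drawn without replacement). At most one injection per position.
#' @param seed Integer seed; identical seeds give byte-identical traces.
#' @param vocab Function-name vocabulary for the baseline lines.
#' @return A list `a` (lines), `b` (lines), `truth` (list with `positions`
#'   per class — sorted 0-based integer vectors — plus `n_calls` and
#'   `seed`).
#' @export
gen_trace_pair <- function(n_calls, spec = list(), seed = 1L,
                           vocab = TRACE_VOCAB) {
  stopifnot(n_calls >= 1L)
  set.seed(seed)
  classes <- c("type1", "type2", "type3", "mismatch")
  stopifnot(all(names(spec) %in% classes))

  # resolve explicit positions first, then sample rate-based ones
  taken <- integer(0)
  positions <- stats::setNames(vector("list", length(classes)), classes)
  for (k in classes) {
    v <- spec[[k]]
    if (is.null(v) || (length(v) == 1L && v >= 0 && v < 1 && v != trunc(v)))
      next
    if (any(v != trunc(v)) || any(v < 0) || any(v >= n_calls))
      stop("explicit positions for ", k, " must be 0-based integers < n_calls")
    positions[[k]] <- as.integer(sort(v))
    taken <- c(taken, positions[[k]])
  }
  for (k in classes) {
    v <- spec[[k]]
    if (is.null(v) || !(length(v) == 1L && v >= 0 && v < 1 && v != trunc(v)))
      next
    count <- round(v * n_calls)
    free <- setdiff(0:(n_calls - 1L), taken)
    if (count > length(free))
      stop("injection spec does not fit in ", n_calls, " lines")
    positions[[k]] <- sort(free[sample.int(length(free), count)])
    taken <- c(taken, positions[[k]])
  }
  if (anyDuplicated(taken))
    stop("injection positions overlap between classes")

  funcs <- sample(vocab, n_calls, replace = TRUE)
  args <- stats::runif(n_calls, 0.1, 3)
  fmt <- function(x) sprintf("%.6f", x)
  line_of <- function(fn, argtok, rettok) sprintf("%s(%s) = %s",
                                                  fn, argtok, rettok)
  arg_a <- arg_b <- fmt(args)
  ret_of <- function(fn, argtok) fmt(TRACE_FUNS[[fn]](as.numeric(argtok)))
  func_a <- func_b <- funcs

  # type1 needs a non-injective call: rewrite the line as floorf on k.3/k.6
  for (p in positions$type1) {
    i <- p + 1L
    k <- sample(0:9, 1L)
    func_a[i] <- func_b[i] <- "floorf"
    arg_a[i] <- fmt(k + 0.3); arg_b[i] <- fmt(k + 0.6)
  }
  ret_a <- vapply(seq_len(n_calls),
                  function(i) ret_of(func_a[i], arg_a[i]), "")
  ret_b <- vapply(seq_len(n_calls),
                  function(i) ret_of(func_b[i], arg_b[i]), "")
  for (p in positions$type3) {
    i <- p + 1L
    ret_b[i] <- bump_last_digit(ret_b[i])
  }
  for (p in positions$type2) {
    i <- p + 1L
    arg_b[i] <- bump_last_digit(arg_b[i])
    ret_b[i] <- bump_last_digit(ret_of(func_b[i], arg_b[i]))
    if (identical(ret_b[i], ret_a[i]))  # ensure the return really differs
      ret_b[i] <- bump_last_digit(ret_a[i])
  }
  for (p in positions$mismatch) {
    i <- p + 1L
    func_b[i] <- sample(setdiff(vocab, func_a[i]), 1L)
    ret_b[i] <- ret_of(func_b[i], arg_b[i])
  }
  list(a = line_of(func_a, arg_a, ret_a),
       b = line_of(func_b, arg_b, ret_b),
       truth = list(positions = lapply(positions, function(x)
         if (is.null(x)) integer(0) else x),
         n_calls = n_calls, seed = seed))
}

#' Generate a pair of label volumes with exact per-label Dice
#'
#' Each label occupies the same number of voxels `s` in both volumes, laid
#' out as runs in the flattened grid so that the overlap is exactly
#' `k = d * s` voxels, giving Dice `2k / 2s = d` exactly. Labels are
#' spatially disjoint within each volume. Realizable targets therefore need
#' `d * s` integral; anything else is rejected with the nearest realizable
#' value suggested.
#'
#' @param shape Grid dimensions, e.g. `c(64, 64, 64)`.
#' @param label_sizes Named vector: voxels per label (names are the integer
#'   labels).
#' @param target_dice Named vector of target Dice values in `[0, 1]`, same
#'   names.
#' @param seed Integer seed (randomizes the block placement order/offset).
#' @return List `a`, `b` (integer arrays), `truth` (per-label size, overlap,
#'   dice, seed).
#' @export
gen_label_volume_pair <- function(shape, label_sizes, target_dice, seed = 1L) {
  stopifnot(length(label_sizes) >= 1L,
            identical(sort(names(label_sizes)), sort(names(target_dice))))
  set.seed(seed)
  nvox <- prod(shape)
  labels <- names(label_sizes)
  overlaps <- stats::setNames(numeric(length(labels)), labels)
  for (l in labels) {
    s <- label_sizes[[l]]; d <- target_dice[[l]]
    stopifnot(s >= 1, d >= 0, d <= 1)
    k <- d * s
    if (abs(k - round(k)) > 1e-9) {
      stop(sprintf(
        "Dice %g is not realizable with size %d; nearest realizable value is %g",
        d, s, round(k) / s))
    }
    overlaps[[l]] <- round(k)
  }
  block_len <- 2 * label_sizes - overlaps
  if (sum(block_len) + length(labels) > nvox)
    stop("labels do not fit in the grid")
  a <- integer(nvox); b <- integer(nvox)
  order_l <- sample(labels)  # seeded placement order
  cursor <- 1L + sample.int(max(1L, nvox - sum(block_len) -
                                  length(labels)), 1L) - 1L
  for (l in order_l) {
    s <- label_sizes[[l]]; k <- overlaps[[l]]
    lab <- as.integer(l)
    a[cursor:(cursor + s - 1L)] <- lab
    b[(cursor + s - k):(cursor + 2L * s - k - 1L)] <- lab
    cursor <- cursor + 2L * s - k + 1L  # one-voxel gap between labels
  }
  truth <- data.frame(label = as.integer(labels),
                      size = as.integer(label_sizes),
                      overlap = as.integer(overlaps),
                      dice = as.numeric(target_dice))
  list(a = array(a, dim = shape), b = array(b, dim = shape),
       truth = list(per_label = truth, seed = seed))
}

# Rodrigues rotation matrix about a unit axis
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

make_rigid <- function(r, t) {
  m <- diag(4)
  m[1:3, 1:3] <- r
  m[1:3, 4] <- t
  rigid_transform(m)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a pair of rigid-transform runs with a known residual
#'
#' Draws a random rigid baseline `T1` and sets `T2 = G^-1 o T1`, where `G`
#' is the requested residual (rotation `angle_deg` about `axis`, translation
#' of norm `translation_mm` in a seeded random direction). Then
#' `residual(T1, T2) = G` exactly, so the residual metrics must recover the
#' requested angle and translation norm.
#'
#' @param axis Rotation axis (3-vector, any norm) for the residual.
#' @param angle_deg Residual rotation angle, `|angle| <= 180` degrees.
#' @param translation_mm Residual translation: a norm (scalar) or an
#'   explicit 3-vector in mm.
#' @param seed Integer seed.
#' @return List `t1`, `t2` (`rigid_transform`s), `truth` (G, `angle_deg`,
#'   `translation_norm_mm`, seed).
#' @export
gen_rigid_pair <- function(axis = c(0, 0, 1), angle_deg = 0,
                           translation_mm = 0, seed = 1L) {
  stopifnot(abs(angle_deg) <= 180)
  set.seed(seed)
  t_res <- if (length(translation_mm) == 3L) translation_mm
  else random_unit_vector() * translation_mm
  g <- make_rigid(rotation_about(axis, angle_deg), t_res)
  t1 <- make_rigid(rotation_about(random_unit_vector(),
                                  stats::runif(1, -30, 30)),
                   stats::rnorm(3, sd = 20))
  t2 <- rigid_transform(solve(unclass(g)) %*% unclass(t1))
  list(t1 = t1, t2 = t2,
       truth = list(g = g, angle_deg = abs(angle_deg),
                    translation_norm_mm = sqrt(sum(t_res^2)), seed = seed))
}

#' Generate paired ICA component sets with known permutation structure
#'
#' Set A holds `n_components` spatially disjoint smooth blobs of unit
#' amplitude (truncated Gaussians on a cell lattice). Set B is A reordered
#' by `permutation` (`B[[j]] = A[[permutation[j]]]`), with the listed B
#' components sign-flipped and independent Gaussian noise added. For noise
#' standard deviation below half the unit amplitude, signed matching
#' recovers the permutation exactly.
#'
#' @param n_components Number of components (must fit on the cell lattice).
#' @param shape Grid dimensions; default fits up to 50 components.
#' @param permutation Permutation of `1:n_components`; default identity.
#' @param sign_flips Indices (into B) whose maps are negated.
#' @param noise_sd Standard deviation of additive Gaussian noise on B.
#' @param seed Integer seed.
#' @return List `a`, `b` (`component_set`s), `truth` (permutation, its
#'   inverse `match_ab` mapping each A index to its B counterpart,
#'   sign_flips, noise_sd, seed).
#' @export
gen_component_sets <- function(n_components = 20L, shape = c(30, 30, 12),
                               permutation = NULL, sign_flips = integer(0),
                               noise_sd = 0, seed = 1L) {
  cell <- 6L
  ncell <- prod(shape %/% cell)
  if (n_components > ncell)
    stop("grid too small: ", ncell, " blob cells for ", n_components,
         " components")
  if (is.null(permutation)) permutation <- seq_len(n_components)
  permutation <- as.integer(permutation)
  stopifnot(identical(sort(permutation), seq_len(n_components)),
            all(sign_flips %in% seq_len(n_components)), noise_sd >= 0)
  set.seed(seed)
  dims <- shape %/% cell
  # blob template: truncated Gaussian within one cell
  ax <- seq_len(cell) - (cell + 1) / 2
  gg <- expand.grid(x = ax, y = ax, z = ax)
  blob <- exp(-(gg$x^2 + gg$y^2 + gg$z^2) / (2 * 1.2^2))
  blob[sqrt(gg$x^2 + gg$y^2 + gg$z^2) > cell / 2] <- 0
  blob <- blob / max(blob)  # unit amplitude
  cells <- sample(ncell, n_components)  # seeded distinct cells
  maps_a <- lapply(seq_len(n_components), function(i) {
    m <- array(0, dim = shape)
    ci <- cells[i] - 1L
    cx <- ci %% dims[1]; cy <- (ci %/% dims[1]) %% dims[2]
    cz <- ci %/% (dims[1] * dims[2])
    xs <- cx * cell + seq_len(cell); ys <- cy * cell + seq_len(cell)
    zs <- cz * cell + seq_len(cell)
    m[xs, ys, zs] <- array(blob, dim = rep(cell, 3))
    m
  })
  maps_b <- lapply(seq_len(n_components), function(j) {
    m <- maps_a[[permutation[j]]]
    if (j %in% sign_flips) m <- -m
    if (noise_sd > 0) m <- m + array(stats::rnorm(prod(shape), sd = noise_sd),
                                     dim = shape)
    m
  })
  match_ab <- order(permutation)  # A index i lives at B index match_ab[i]
  list(a = component_set(maps_a), b = component_set(maps_b),
       truth = list(permutation = permutation, match_ab = match_ab,
                    sign_flips = sign_flips, noise_sd = noise_sd,
                    seed = seed))
}

#' Generate paired image series with exact per-stage mean absolute difference
#'
#' For each named stage a 4D series A is drawn and B is set to
#' `A + sign * mad`, with a random +-1 sign per element and constant
#' magnitude, so the measured mean absolute difference equals the requested
#' value exactly (to machine precision).
#'
#' @param shape Spatial grid dimensions.
#' @param n_timepoints Number of timepoints.
#' @param stage_mads Named non-negative vector of target MADs in stage
#'   order; the final stage (the normalization reference) must be positive.
#' @param seed Integer seed.
#' @return List `stages` (named list of `list(a, b)` suitable for
#'   [stage_mad_profile()]), `truth` (stage_mads, seed).
#' @export
gen_stage_series <- function(shape = c(16, 16, 10), n_timepoints = 8L,
                             stage_mads, seed = 1L) {
  stopifnot(!is.null(names(stage_mads)), all(stage_mads >= 0))
  if (stage_mads[[length(stage_mads)]] == 0)
    stop("final (reference) stage MAD must be positive")
  set.seed(seed)
  dims <- c(shape, n_timepoints)
  stages <- lapply(stage_mads, function(mad) {
    a <- array(stats::runif(prod(dims), 0, 100), dim = dims)
    signs <- array(sample(c(-1, 1), prod(dims), replace = TRUE), dim = dims)
    list(a = a, b = a + signs * mad)
  })
  list(stages = stages, truth = list(stage_mads = stage_mads, seed = seed))
}

#' Generate paired cortical-thickness matrices with a planted effect
#'
#' Condition A is a realistic baseline (2.5 mm global mean plus per-subject
#' and per-vertex offsets); condition B adds `effect_mm` inside
#' `effect_region` plus independent Gaussian noise on every entry. With
#' `effect_mm = 0` the difference scores are pure iid noise, so the vertex
#' t map is exactly null-calibrated.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_vertices Number of template vertices.
#' @param effect_region Vertex indices carrying the planted effect.
#' @param effect_mm Planted thickness difference (mm).
#' @param noise_sd Per-entry noise standard deviation (mm).
#' @param seed Integer seed.
#' @return List `a`, `b` (`thickness_matrix` objects), `truth`
#'   (effect_region, effect_mm, noise_sd, seed).
#' @export
gen_thickness_pair <- function(n_subjects, n_vertices,
                               effect_region = integer(0), effect_mm = 0,
                               noise_sd = 0.1, seed = 1L) {
  stopifnot(n_subjects >= 2L, n_vertices >= 1L,
            all(effect_region %in% seq_len(n_vertices)))
  if (effect_mm != 0 && length(effect_region) == 0L)
    stop("non-zero effect requires a non-empty effect region")
  set.seed(seed)
  subj <- stats::rnorm(n_subjects, sd = 0.25)
  vert <- stats::rnorm(n_vertices, sd = 0.15)
  base <- 2.5 + outer(subj, rep(1, n_vertices)) +
    outer(rep(1, n_subjects), vert)
  base <- pmax(base, 0.5)  # thickness stays physically plausible
  a <- base
  b <- base
  if (length(effect_region) > 0L)
    b[, effect_region] <- b[, effect_region] + effect_mm
  if (noise_sd > 0)
    b <- b + matrix(stats::rnorm(length(base), sd = noise_sd),
                    nrow = n_subjects)
  subjects <- sprintf("S%03d", seq_len(n_subjects))
  list(a = thickness_matrix(a, subjects),
       b = thickness_matrix(pmax(b, 0), subjects),
       truth = list(effect_region = effect_region, effect_mm = effect_mm,
                    noise_sd = noise_sd, seed = seed))
}
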