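# rigid-transform residuals and stage-wise MAD attribution

test_that("rigid validation accepts rotations and rejects broken matrices", {
  expect_s3_class(rigid_transform(diag(4)), "rigid_transform")
  expect_s3_class(fixture_rigid(30, c(0, 0, 1), c(1, 2, 3)),
                  "rigid_transform")
  bad_row <- diag(4); bad_row[4, 4] <- 2
  expect_error(rigid_transform(bad_row), "last row")
  scaled <- diag(4); scaled[1, 1] <- 1.01
  expect_error(rigid_transform(scaled), "orthonormal")
  reflect <- diag(4); reflect[1, 1] <- -1       # orthogonal but det = -1
  expect_error(rigid_transform(reflect), "det")
})

test_that("FLIRT-style matrices round-trip bit-identically through text", {
  for (seed in 1:3) {
    rp <- gen_rigid_pair(c(1, 1, 0), 12.5, 3.7, seed = seed)
    p <- tempfile(fileext = ".mat")
    write_flirt_matrix(rp$t1, p)
    back <- load_flirt_matrix(p)
    expect_identical(unclass(back), unclass(rp$t1))
  }
})

test_that("malformed matrix files are rejected with the violated invariant", {
  p <- tempfile()
  writeLines(c("1 0 0 0", "0 1 0 0", "0 0 1 0", "0 0 0 2"), p)
  expect_error(load_flirt_matrix(p), "last row")
  writeLines(c("1 0 0 0", "0 1 0 0", "0 0 1 0"), p)
  expect_error(load_flirt_matrix(p), "16 numbers")
})

test_that("residual is T1 composed with the inverse of T2", {
  t1 <- fixture_rigid(17, c(1, 2, 2), c(5, -3, 1))
  expect_equal(unclass(residual(t1, t1)), diag(4), tolerance = 1e-12)
  id <- rigid_transform(diag(4))
  expect_equal(unclass(residual(t1, id)), unclass(t1), tolerance = 1e-12)
  # constructed pair recovers the planted residual within 1e-9 per entry
  rp <- gen_rigid_pair(c(2, -1, 3), 4.2, c(0.1, 0.2, -0.3), seed = 5)
  expect_equal(unclass(residual(rp$t1, rp$t2)), unclass(rp$truth$g),
               tolerance = 1e-9)
})

test_that("rotation angle matches axis-angle construction", {
  expect_equal(rotation_angle(rigid_transform(diag(4))), 0)
  expect_equal(rotation_angle(fixture_rigid(30)), 30, tolerance = 1e-12)
  # trace closed form: trace(R) = 1 + 2 cos(30 deg)
  r30 <- unclass(fixture_rigid(30))[1:3, 1:3]
  expect_equal(sum(diag(r30)), 1 + 2 * cos(pi / 6), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:10) {
    th <- runif(1, 0.01, 179.9)
    ax <- rnorm(3)
    expect_equal(rotation_angle(fixture_rigid(th, ax)), th,
                 tolerance = 1e-9)
    # invariant under conjugation by another rotation
    q <- fixture_rigid(runif(1, 0, 180), rnorm(3))
    conj <- rigid_transform(unclass(q) %*% unclass(fixture_rigid(th, ax)) %*%
                              solve(unclass(q)))
    expect_equal(rotation_angle(conj), th, tolerance = 1e-8)
  }
})

test_that("translation norm is the Euclidean norm of t", {
  expect_equal(translation_norm(rigid_transform(diag(4))), 0)
  expect_equal(translation_norm(fixture_rigid(0, t = c(3, 4, 0))), 5)
  set.seed(7)
  t <- rnorm(3, sd = 10)
  expect_equal(translation_norm(fixture_rigid(25, c(1, 0, 1), t)),
               sqrt(sum(t^2)), tolerance = 1e-12)
})

test_that("series residuals recover planted metrics and report maxima", {
  # identical series: all-zero metrics
  s <- lapply(1:5, function(i) fixture_rigid(i * 3, c(0, 0, 1), c(i, 0, 0)))
  res <- series_residuals(s, s)
  expect_equal(res$translation_mm, rep(0, 5))
  expect_equal(res$rotation_deg, rep(0, 5), tolerance = 1e-6)
  # one perturbed timepoint dominates the maxima
  rp <- gen_rigid_pair(c(1, 0, 0), 0.5, 0.02, seed = 8)
  s2 <- s; s2[[3]] <- rigid_transform(solve(unclass(rp$truth$g)) %*%
                                        unclass(s[[3]]))
  res2 <- series_residuals(s, s2)
  expect_equal(which.max(res2$rotation_deg), 3)
  expect_equal(attr(res2, "max_rotation_deg"), max(res2$rotation_deg))
  expect_equal(attr(res2, "max_translation_mm"), max(res2$translation_mm))
  expect_equal(attr(res2, "max_rotation_deg"), 0.5, tolerance = 1e-9)
  expect_error(series_residuals(s, s[1:3]), "different lengths")
})

test_that("mean absolute difference matches a brute-force loop", {
  a <- array(1:24, c(2, 3, 4)); b <- a + 2
  expect_equal(mean_abs_diff(a, a), 0)
  expect_equal(mean_abs_diff(a, b), 2)
  set.seed(9)
  ra <- array(rnorm(120), c(2, 3, 4, 5)); rb <- array(rnorm(120), c(2, 3, 4, 5))
  brute <- 0
  for (i in seq_along(ra)) brute <- brute + abs(ra[i] - rb[i])
  expect_equal(mean_abs_diff(ra, rb), brute / length(ra))
  # masked: mean over in-mask voxels only, all timepoints pooled
  mask <- array(0L, c(2, 3, 4)); mask[1:5] <- 1L
  keep <- which(as.logical(mask))
  brute_m <- mean(abs(matrix(ra, ncol = 5)[keep, ] - matrix(rb, ncol = 5)[keep, ]))
  expect_equal(mean_abs_diff(ra, rb, mask = mask), brute_m)
  expect_error(mean_abs_diff(a, array(0, c(2, 3, 5))), "shape mismatch")
})

test_that("stage MAD profile divides by the reference and is scale invariant", {
  ss <- gen_stage_series(shape = c(8, 8, 4), n_timepoints = 4,
                         stage_mads = c(mc = 0.2, thr = 0.1, smooth = 0.5,
                                        final = 1.0), seed = 10)
  prof <- stage_mad_profile(ss$stages)
  expect_equal(prof$raw_mad, c(0.2, 0.1, 0.5, 1.0), tolerance = 1e-12)
  expect_equal(prof$normalized_mad, c(0.2, 0.1, 0.5, 1.0), tolerance = 1e-12)
  expect_identical(prof$normalized_mad[4], 1.0)  # reference exactly 1
  # common positive scaling of all image pairs leaves the profile unchanged
  scaled <- lapply(ss$stages, function(s) list(a = 10 * s$a, b = 10 * s$b))
  prof10 <- stage_mad_profile(scaled)
  expect_equal(prof10$normalized_mad, prof$normalized_mad, tolerance = 1e-12)
  # all stages identical except the reference: zeros then 1
  z <- array(0, c(4, 4, 2))
  st <- list(mc = list(a = z, b = z),
             final = list(a = z, b = z + 0.3))
  expect_equal(stage_mad_profile(st)$normalized_mad, c(0, 1))
  expect_error(stage_mad_profile(list(mc = list(a = z, b = z))),
               "no difference to attribute")
})
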