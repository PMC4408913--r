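# shared fixture builders

trace_lines <- function(...) {
  parse_trace(c(...))
}

# a record list usable by classify_pair
rec <- function(func, args, ret) list(func = func, args = args, ret = ret)

# random rigid transform built from an axis-angle construction independent
# of the package's generator internals
fixture_rigid <- function(angle_deg, axis = c(0, 0, 1), t = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  r <- diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
  m <- diag(4)
  m[1:3, 1:3] <- r
  m[1:3, 4] <- t
  rigid_transform(m)
}

# write a minimal uncompressed NIfTI-1 volume and return its path
fixture_nifti <- function(x, path = tempfile(fileext = ".nii")) {
  write_volume(x, path)
  path
}
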