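# IEEE-754 binary32 forensics

test_that("little-endian hex decoding matches an independent IEEE-754 oracle", {
  # expected values computed with an independent decoder (Python struct)
  cases <- list(
    list(hex = "00 00 80 3f", pattern = 0x3f800000, value = 1),
    list(hex = "24 58 95 40", pattern = 0x40955824,
         value = 4.667009353637695),
    list(hex = "9a 0c 2d 3d", pattern = 0x3d2d0c9a,
         value = 0.04224834591150284),
    list(hex = "01 00 00 00", pattern = 1, value = 1.401298464324817e-45),
    list(hex = "ff ff 7f 7f", pattern = 0x7f7fffff,
         value = 3.4028234663852886e+38))
  for (cc in cases) {
    f <- float32_from_hex(cc$hex)
    expect_equal(f$pattern, cc$pattern)
    expect_identical(f$value, cc$value)
  }
  # dialect: compact, case-insensitive
  expect_equal(float32_from_hex("24589540")$pattern, 0x40955824)
  expect_equal(float32_from_hex("FF FF 7F 7F")$pattern, 0x7f7fffff)
  expect_error(float32_from_hex("24 58 95"), "4 hex bytes")
  expect_error(float32_from_hex("24 58 95 4g"), "4 hex bytes")
})

test_that("hex -> bits -> hex round-trips on edge and random patterns", {
  edge <- c(0, 0x80000000, 1, 0x7f7fffff, 0xff7fffff, 0x7f800000,
            0xff800000, 0x3f800000, 0x00800000)
  set.seed(42)
  random <- floor(runif(200) * 4294967296)
  for (p in c(edge, random)) {
    f <- float32_from_pattern(p)
    expect_equal(f$pattern, p)
    expect_equal(float32_from_hex(float32_to_hex(f))$pattern, p)
    # field decomposition recomposes the pattern
    expect_equal(f$sign * 2^31 + f$exponent * 2^23 + f$mantissa, p)
  }
})

test_that("ulp_distance is 1 for adjacent floats and behaves as a metric", {
  expect_equal(ulp_distance("24 58 95 40", "25 58 95 40"), 1)
  expect_equal(ulp_distance("d8 b3 5d 3f", "d7 b3 5d 3f"), 1)
  expect_equal(ulp_distance("9a 0c 2d 3d", "99 0c 2d 3d"), 1)
  set.seed(7)
  pats <- floor(runif(50) * 2139095039)  # finite positive range, below +Inf
  for (p in pats) {
    expect_equal(ulp_distance(p, p), 0)
    expect_equal(ulp_distance(p, p + 1), 1)  # adjacent same-sign floats
  }
  # symmetry and triangle inequality on random triples
  for (i in 1:25) {
    abc <- floor(runif(3) * 2139095039)
    expect_equal(ulp_distance(abc[1], abc[2]), ulp_distance(abc[2], abc[1]))
    expect_lte(ulp_distance(abc[1], abc[3]),
               ulp_distance(abc[1], abc[2]) + ulp_distance(abc[2], abc[3]))
  }
  # distance straddling zero counts representable values through zero
  expect_equal(ulp_distance(0x80000001, 0x00000001), 2)
})

test_that("signed zeros: equal in ULP, one bit apart in the pattern", {
  expect_equal(ulp_distance(0, 0x80000000), 0)
  expect_equal(hamming_bits(0, 0x80000000), 1)
})

test_that("NaN is rejected by ulp_distance, infinities are ranked", {
  expect_error(ulp_distance(0x7fc00000, 0), "NaN")
  expect_error(ulp_distance(0, 0xffc00000), "NaN")
  # +Inf is adjacent to the largest finite float
  expect_equal(ulp_distance(0x7f800000, 0x7f7fffff), 1)
})

test_that("hamming_bits counts XOR population, exposing ULP-vs-bit wording", {
  expect_equal(hamming_bits("24 58 95 40", "25 58 95 40"), 1)
  # one-ULP neighbours can differ in several pattern bits (carry)
  expect_equal(hamming_bits("d8 b3 5d 3f", "d7 b3 5d 3f"), 4)  # d8^d7 = 0x0f
  expect_equal(hamming_bits("9a 0c 2d 3d", "99 0c 2d 3d"), 2)  # 9a^99 = 0x03
  expect_equal(hamming_bits(0, 0xffffffff), 32)
  expect_equal(hamming_bits(5, 5), 0)
})

test_that("hamming_bits >= 1 whenever ulp_distance >= 1", {
  set.seed(11)
  for (i in 1:50) {
    a <- floor(runif(1) * 2139095039)
    b <- floor(runif(1) * 2139095039)
    if (ulp_distance(a, b) >= 1) expect_gte(hamming_bits(a, b), 1)
    else expect_equal(hamming_bits(a, b), 0)
  }
})

test_that("format_30dec prints the exact truncated decimal expansion", {
  expect_identical(format_30dec(0x3f800000),
                   "1.000000000000000000000000000000")
  expect_identical(format_30dec(0x3f000000),
                   "0.500000000000000000000000000000")
  # frozen from an arbitrary-precision decimal oracle
  expect_identical(format_30dec(0x3f800001),
                   "1.000000119209289550781250000000")
  expect_identical(format_30dec("24 58 95 40"),
                   "4.667009353637695312500000000000")
  expect_identical(format_30dec("d8 b3 5d 3f"),
                   "0.866025447845458984375000000000")
  expect_identical(format_30dec("9a 0c 2d 3d"),
                   "0.042248345911502838134765625000")
  # smallest subnormal truncates (not rounds) to zeros
  expect_identical(format_30dec(0x00000001),
                   "0.000000000000000000000000000000")
  # large integer part is exact too
  expect_identical(
    format_30dec(0x7f7fffff),
    "340282346638528859811704183484516925440.000000000000000000000000000000")
  expect_match(format_30dec(0xbf800000), "^-1\\.0{30}$")
  expect_error(format_30dec(0x7f800000), "finite")
  expect_error(format_30dec(0x7fc00000), "finite")
})

test_that("the built-in libm drift table reports one ULP for every pair", {
  tab <- libm_drift_examples()
  expect_equal(nrow(tab), 3)
  expect_equal(tab$func, c("expf", "cosf", "sinf"))
  expect_equal(tab$ulp, rep(1, 3))
  expect_equal(tab$bits_flipped, c(1, 4, 2))
  expect_true(all(abs(tab$value_a - tab$value_b) > 0))
})
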