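# IEEE-754 binary32 forensics: decoding little-endian hex dumps, ULP
# distances, flipped-bit counts and exact 30-decimal expansions.

TWO31 <- 2147483648  # 2^31; patterns are kept as doubles (exact below 2^53)
TWO23 <- 8388608     # 2^23

#' Decode a little-endian hexadecimal byte dump as an IEEE-754 binary32 value
#'
#' Debuggers and memory dumps on x86 print single-precision values as four
#' little-endian bytes (e.g. `"24 58 95 40"`). This reverses the bytes into
#' the big-endian bit pattern `0x40955824`, splits the sign / exponent /
#' mantissa fields and decodes the represented real number, including
#' subnormals, infinities and NaN.
#'
#' @param hex A string of exactly four two-digit hex bytes, least significant
#'   byte first. Bytes may be separated by spaces (`"24 58 95 40"`) or run
#'   together (`"24589540"`); case-insensitive.
#' @return A `float32` object: a list with elements `pattern` (the 32-bit
#'   pattern as a double in `[0, 2^32)`), `sign` (0/1), `exponent` (0..255),
#'   `mantissa` (0..2^23-1) and `value` (the decoded double).
#' @examples
#' f <- float32_from_hex("00 00 80 3f")
#' f$value        # 1
#' format(f)      # "0x3f800000"
#' @seealso [float32_from_pattern()], [ulp_distance()], [hamming_bits()]
#' @export
float32_from_hex <- function(hex) {
  stopifnot(is.character(hex), length(hex) == 1L, !is.na(hex))
  compact <- gsub("[[:space:]]+", "", hex)
  if (!grepl("^[0-9a-fA-F]{8}$", compact))
    stop("expected exactly 4 hex bytes (8 hex digits), got: ", sQuote(hex))
  bytes <- strtoi(substring(compact, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L)
  # little-endian: first byte is least significant
  pattern <- bytes[1] + bytes[2] * 256 + bytes[3] * 65536 + bytes[4] * 16777216
  float32_from_pattern(pattern)
}

#' Build a float32 object from its 32-bit pattern
#'
#' @param pattern Bit pattern as a non-negative number below 2^32 (doubles
#'   are exact in this range).
#' @return A `float32` object; see [float32_from_hex()].
#' @export
float32_from_pattern <- function(pattern) {
  stopifnot(is.numeric(pattern), length(pattern) == 1L, !is.na(pattern))
  if (pattern < 0 || pattern >= 4294967296 || pattern != trunc(pattern))
    stop("pattern must be an integer in [0, 2^32)")
  sign <- pattern %/% TWO31
  exponent <- (pattern %/% TWO23) %% 256
  mantissa <- pattern %% TWO23
  value <- readBin(float32_bytes(pattern), "numeric", size = 4L,
                   endian = "little")
  structure(
    list(pattern = pattern, sign = sign, exponent = exponent,
         mantissa = mantissa, value = value),
    class = "float32")
}

# little-endian raw bytes of a pattern
float32_bytes <- function(pattern) {
  as.raw(c(pattern %% 256,
           (pattern %/% 256) %% 256,
           (pattern %/% 65536) %% 256,
           (pattern %/% 16777216) %% 256))
}

as_float32 <- function(x) {
  if (inherits(x, "float32")) return(x)
  if (is.character(x)) return(float32_from_hex(x))
  if (is.numeric(x)) return(float32_from_pattern(x))
  stop("cannot interpret object of class ", class(x)[1], " as float32")
}

#' Re-encode a float32 as hexadecimal
#'
#' @param x A `float32` object (or hex string / pattern accepted by the
#'   constructors).
#' @param little_endian If `TRUE` (default) return the byte dump in memory
#'   order (`"24 58 95 40"`); otherwise the big-endian pattern (`"40955824"`).
#' @param sep Byte separator for the little-endian form.
#' @return A string.
#' @export
float32_to_hex <- function(x, little_endian = TRUE, sep = " ") {
  x <- as_float32(x)
  bytes <- as.integer(float32_bytes(x$pattern))
  if (little_endian) paste(sprintf("%02x", bytes), collapse = sep)
  else paste(sprintf("%02x", rev(bytes)), collapse = "")
}

#' @export
format.float32 <- function(x, ...) {
  sprintf("0x%s", float32_to_hex(x, little_endian = FALSE))
}

#' @export
print.float32 <- function(x, ...) {
  cat(sprintf("<float32 %s = %.9g (le: %s)>\n", format(x), x$value,
              float32_to_hex(x)))
  invisible(x)
}

is_nan_pattern <- function(x) x$exponent == 255 && x$mantissa != 0

# Monotone integer rank over ordered finite floats plus infinities:
# non-negative patterns map to themselves, negative ones to -(magnitude),
# so +0 and -0 share rank 0 and adjacent floats have adjacent ranks.
float32_rank <- function(x) {
  if (x$sign == 0) x$pattern else -(x$pattern - TWO31)
}

#' Distance between two binary32 values in units in the last place
#'
#' Counts how many representable single-precision values separate `a` and
#' `b`: 0 for identical values, 1 for adjacent floats. This is the right
#' ruler for "one bit flipped in the result" reports — a one-ULP step can
#' flip several bits of the pattern when it crosses a carry (compare
#' [hamming_bits()]).
#'
#' `+0` and `-0` are distance 0 apart (equal values); infinities rank
#' adjacent to the largest finite magnitudes; NaN is rejected.
#'
#' @param a,b `float32` objects, hex strings or bit patterns.
#' @return A non-negative count of representable values.
#' @examples
#' ulp_distance("24 58 95 40", "25 58 95 40")  # 1
#' @export
ulp_distance <- function(a, b) {
  a <- as_float32(a); b <- as_float32(b)
  if (is_nan_pattern(a) || is_nan_pattern(b))
    stop("ulp_distance is undefined for NaN")
  abs(float32_rank(a) - float32_rank(b))
}

#' Number of differing bits between two binary32 patterns
#'
#' Population count of the XOR of the two 32-bit patterns. Unlike
#' [ulp_distance()] this is a raw bit-level measure: values one ULP apart
#' can differ in up to 24 bits (carry propagation), and `+0`/`-0` differ in
#' exactly the sign bit.
#'
#' @inheritParams ulp_distance
#' @return Integer in `[0, 32]`.
#' @export
hamming_bits <- function(a, b) {
  a <- as_float32(a); b <- as_float32(b)
  xa <- as.integer(float32_bytes(a$pattern))
  xb <- as.integer(float32_bytes(b$pattern))
  sum(vapply(bitwXor(xa, xb), function(byte) {
    sum(as.integer(intToBits(byte)[1:8]))
  }, integer(1)))
}

#' Exact fixed-point expansion of a binary32 value to 30 decimals
#'
#' Every finite binary32 value has a terminating decimal expansion (at most
#' 149 fractional digits). This prints the integer part followed by the
#' first 30 fractional digits of that exact expansion, zero-padded —
#' the convention used when dumping single-precision results with
#' `printf("%.30f")` to expose differences invisible at default precision.
#' Digits beyond the 30th are truncated, never rounded, so the printed
#' string is a prefix of the exact value.
#'
#' @param x A `float32` object, hex string or bit pattern. Must be finite.
#' @return A string like `"4.667009353637695312500000000000"`.
#' @export
format_30dec <- function(x) {
  x <- as_float32(x)
  if (is_nan_pattern(x) || x$exponent == 255)
    stop("format_30dec requires a finite value")
  # decompose |x| = m * 2^e with integer m < 2^24
  if (x$exponent == 0) {             # subnormal (or zero)
    m <- x$mantissa; e <- -149
  } else {
    m <- x$mantissa + TWO23; e <- x$exponent - 150
  }
  int_digits <- as.integer(strsplit(sprintf("%.0f", m), "")[[1]])
  frac_digits <- integer(0)
  if (e >= 0) {
    for (i in seq_len(e)) int_digits <- digits_double(int_digits)
  } else {
    for (i in seq_len(-e)) {
      h <- digits_halve(int_digits, frac_digits)
      int_digits <- h$int; frac_digits <- h$frac
    }
  }
  frac30 <- c(frac_digits, integer(30))[1:30]
  sprintf("%s%s.%s",
          if (x$sign == 1) "-" else "",
          paste(int_digits, collapse = ""),
          paste(frac30, collapse = ""))
}

# double a base-10 digit vector (most significant first)
digits_double <- function(d) {
  d <- d * 2L
  carry <- 0L
  for (i in rev(seq_along(d))) {
    v <- d[i] + carry
    d[i] <- v %% 10L
    carry <- v %/% 10L
  }
  if (carry > 0L) d <- c(as.integer(strsplit(as.character(carry), "")[[1]]), d)
  # strip leading zeros beyond one digit
  while (length(d) > 1L && d[1] == 0L) d <- d[-1]
  d
}

# halve an (integer digits, fraction digits) pair in base 10
digits_halve <- function(int_d, frac_d) {
  all_d <- c(int_d, frac_d)
  out <- integer(length(all_d))
  r <- 0L
  for (i in seq_along(all_d)) {
    v <- r * 10L + all_d[i]
    out[i] <- v %/% 2L
    r <- v %% 2L
  }
  n_int <- length(int_d)
  frac <- out[-seq_len(n_int)]
  if (r > 0L) frac <- c(frac, 5L)  # remainder 1 -> trailing .5
  int <- out[seq_len(n_int)]
  while (length(int) > 1L && int[1] == 0L) int <- int[-1]
  list(int = int, frac = frac)
}

#' Worked examples of glibc single-precision drift
#'
#' Three libm results whose little-endian memory dumps changed between glibc
#' 2.5 and glibc 2.18 — `expf`, `cosf` and `sinf(0.042260922)` — decoded and
#' compared. Each pair is exactly one ULP apart, although the number of
#' flipped pattern bits varies from 1 to 4: "one bit flipped" in such
#' reports means one unit in the last place, not one bit of the pattern.
#'
#' @return A data frame with one row per function: the two hex encodings,
#'   both decoded values, `ulp` and `bits_flipped`.
#' @examples
#' libm_drift_examples()
#' @export
libm_drift_examples <- function() {
  cases <- list(
    list(func = "expf", hex_a = "24 58 95 40", hex_b = "25 58 95 40"),
    list(func = "cosf", hex_a = "d8 b3 5d 3f", hex_b = "d7 b3 5d 3f"),
    list(func = "sinf", hex_a = "9a 0c 2d 3d", hex_b = "99 0c 2d 3d"))
  rows <- lapply(cases, function(cc) {
    fa <- float32_from_hex(cc$hex_a)
    fb <- float32_from_hex(cc$hex_b)
    data.frame(func = cc$func, hex_a = cc$hex_a, hex_b = cc$hex_b,
               value_a = fa$value, value_b = fb$value,
               ulp = ulp_distance(fa, fb),
               bits_flipped = hamming_bits(fa, fb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
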