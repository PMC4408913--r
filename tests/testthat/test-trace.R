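# trace parsing and line-by-line difference classification

test_that("parser handles the dialect: plain calls, pid prefixes, comments", {
  tr <- trace_lines("expf(1.540630) = 4.667011",
                    "[pid 1234] floorf(2.700000) = 2.000000",
                    "# a comment",
                    "pow(2.000000, 3.000000) = 8.000000")
  expect_equal(nrow(tr), 3)
  expect_equal(tr$index, 0:2)
  expect_equal(tr$func, c("expf", "floorf", "pow"))
  expect_equal(tr$pid, c(NA, 1234L, NA))
  expect_equal(tr$args[[1]], "1.540630")
  expect_equal(tr$args[[3]], c("2.000000", "3.000000"))
  expect_equal(tr$ret[1], "4.667011")
})

test_that("malformed lines error in strict mode, skip with warning otherwise", {
  lines <- c("expf(1.0) = 2.718282", "garbage line", "cosf(0.0) = 1.000000")
  expect_error(parse_trace(lines, strict = TRUE), "line 2.*garbage")
  expect_warning(tr <- parse_trace(lines), "skipped")
  expect_equal(nrow(tr), 2)
  expect_equal(tr$index, 0:1)  # skipped lines do not consume an index
})

test_that("classify_pair applies the four-type taxonomy", {
  cases <- list(
    # different args, same return: non-injective floor
    list(a = rec("floorf", "2.300000", "2.000000"),
         b = rec("floorf", "2.600000", "2.000000"), want = "type1"),
    # different args, different return
    list(a = rec("expf", "1.540630", "4.667010"),
         b = rec("expf", "1.540631", "4.667015"), want = "type2"),
    # same args, different return: library implementation change
    list(a = rec("expf", "1.540630", "4.667010"),
         b = rec("expf", "1.540630", "4.667011"), want = "type3"),
    # different functions: control flow diverged (takes precedence)
    list(a = rec("cosf", "0.866000", "0.648000"),
         b = rec("sinf", "0.866000", "0.648000"), want = "mismatch"),
    list(a = rec("cosf", "0.866000", "0.648000"),
         b = rec("sinf", "0.866001", "0.762000"), want = "mismatch"),
    list(a = rec("expf", "1.540630", "4.667011"),
         b = rec("expf", "1.540630", "4.667011"), want = "identical"))
  for (cc in cases) {
    expect_equal(classify_pair(cc$a, cc$b), cc$want)
    # swapping the traces never changes the class
    expect_equal(classify_pair(cc$b, cc$a), cc$want)
  }
  # token equality trims whitespace
  expect_equal(classify_pair(rec("f", " 1.0 ", "2.0"), rec("f", "1.0", "2.0")),
               "identical")
})

test_that("identical traces diff to all-identical with no first difference", {
  tp <- gen_trace_pair(1000, list(), seed = 1)
  expect_identical(tp$a, tp$b)
  d <- diff_traces(parse_trace(tp$a), parse_trace(tp$b))
  expect_null(d$first_difference)
  expect_equal(d$class_totals[["identical"]], 1000)
  expect_equal(sum(d$class_totals) - d$class_totals[["identical"]], 0)
  expect_equal(nrow(summarize_functions(d)), 0)
})

test_that("a single planted type-3 is located exactly", {
  tp <- gen_trace_pair(1000, list(type3 = 500L), seed = 2)
  d <- diff_traces(parse_trace(tp$a), parse_trace(tp$b))
  expect_equal(d$first_difference, list(index = 500L, class = "type3"))
  expect_equal(d$class_totals[["type3"]], 1)
  expect_equal(sum(d$class_totals) - d$class_totals[["identical"]], 1)
})

test_that("unpaired trailing lines count as mismatches", {
  tp <- gen_trace_pair(10, list(), seed = 3)
  b <- c(tp$b, "expf(0.500000) = 1.648721", "expf(0.600000) = 1.822119")
  d <- diff_traces(parse_trace(tp$a), parse_trace(b))
  expect_equal(d$n_compared, 12)
  expect_equal(d$class_totals[["mismatch"]], 2)
  expect_equal(d$first_difference$index, 10L)
  # symmetric: extra lines in A count the same way
  d2 <- diff_traces(parse_trace(b), parse_trace(tp$a))
  expect_equal(d2$class_totals[["mismatch"]], 2)
})

test_that("planted classes and positions are recovered exactly across seeds", {
  for (seed in 1:4) {
    tp <- gen_trace_pair(2000, list(type1 = 0.01, type2 = 0.005,
                                    type3 = c(7L, 1999L), mismatch = 0.002),
                         seed = seed)
    d <- diff_traces(parse_trace(tp$a), parse_trace(tp$b))
    for (k in c("type1", "type2", "type3", "mismatch")) {
      got <- d$records$index[d$records$class == k]
      expect_equal(got, tp$truth$positions[[k]],
                       info = sprintf("seed %d class %s", seed, k))
    }
    planted <- sort(unname(unlist(tp$truth$positions)))
    expect_equal(d$first_difference$index, planted[1])
  }
})

test_that("cumulative series are monotone and end at the per-class totals", {
  tp <- gen_trace_pair(5000, list(type1 = 0.01, type3 = 0.01), seed = 9)
  d <- diff_traces(parse_trace(tp$a), parse_trace(tp$b), checkpoint = 500)
  cum <- d$cumulative
  expect_gt(nrow(cum), 0)
  for (key in unique(paste(cum$func, cum$class))) {
    series <- cum[paste(cum$func, cum$class) == key, ]
    expect_true(all(diff(series$count) >= 0))
    tot <- d$totals[paste(d$totals$func, d$totals$class) == key, "count"]
    expect_equal(series$count[nrow(series)], tot)
  }
  # per-function totals partition the non-identical lines
  expect_equal(sum(d$totals$count),
               sum(d$class_totals) - d$class_totals[["identical"]])
})

test_that("summary table matches the generator's per-function bookkeeping", {
  tp <- gen_trace_pair(500, list(type3 = c(10L, 20L, 30L), type1 = c(100L, 200L)),
                       seed = 5)
  d <- diff_traces(parse_trace(tp$a), parse_trace(tp$b))
  tab <- summarize_functions(d)
  expect_equal(sum(tab$count[tab$class == "type3"]), 3)
  expect_equal(sum(tab$count[tab$class == "type1"]), 2)
  expect_true(all(tab$func[tab$class == "type1"] == "floorf"))
})

test_that("empty traces are rejected", {
  tr <- trace_lines("expf(1.000000) = 2.718282")
  expect_error(diff_traces(tr[0, ], tr), "empty")
})

test_that("per-pid comparison splits interleaved child processes", {
  a <- c("[pid 1] expf(1.000000) = 2.718282",
         "[pid 2] cosf(0.000000) = 1.000000",
         "[pid 1] expf(2.000000) = 7.389056")
  # pid 2's line moved: file-order comparison sees mismatches, per-pid none
  b <- c("[pid 1] expf(1.000000) = 2.718282",
         "[pid 1] expf(2.000000) = 7.389056",
         "[pid 2] cosf(0.000000) = 1.000000")
  d_flat <- diff_traces(parse_trace(a), parse_trace(b))
  expect_gt(d_flat$class_totals[["mismatch"]], 0)
  d_pid <- diff_traces(parse_trace(a), parse_trace(b), per_pid = TRUE)
  expect_named(d_pid, c("1", "2"))
  for (p in d_pid) expect_null(p$first_difference)
})

test_that("streaming file comparison agrees with the in-memory result", {
  tp <- gen_trace_pair(3000, list(type1 = 0.01, type2 = 0.01,
                                  type3 = 0.01, mismatch = 0.01), seed = 8)
  fa <- tempfile(); fb <- tempfile()
  writeLines(tp$a, fa); writeLines(tp$b, fb)
  mem <- diff_traces(parse_trace(fa), parse_trace(fb), checkpoint = 250)
  tsv <- tempfile(fileext = ".tsv")
  stream <- diff_trace_files(fa, fb, checkpoint = 250, records_tsv = tsv)
  expect_equal(stream$class_totals, mem$class_totals)
  expect_equal(stream$first_difference, mem$first_difference)
  expect_equal(stream$n_compared, mem$n_compared)
  tot_s <- stream$totals[order(stream$totals$func, stream$totals$class), ]
  tot_m <- mem$totals[order(mem$totals$func, mem$totals$class), ]
  rownames(tot_s) <- rownames(tot_m) <- NULL
  expect_equal(tot_s, tot_m)
  # the streamed per-index sink matches the in-memory classifications
  rec <- utils::read.table(tsv, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_equal(rec$class, mem$records$class)
})

test_that("trace-diff outputs round-trip to disk", {
  tp <- gen_trace_pair(200, list(type3 = 50L), seed = 10)
  d <- diff_traces(parse_trace(tp$a), parse_trace(tp$b), checkpoint = 50)
  dir <- tempfile()
  paths <- write_trace_diff(d, dir)
  expect_true(all(file.exists(file.path(dir, c("classifications.tsv",
                                               "cumulative.tsv",
                                               "summary.json")))))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$first_difference$index, 50)
  expect_equal(js$class_totals$type3, 1)
})
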