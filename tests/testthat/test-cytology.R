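test_that("band parsing handles euchromatic and heterochromatic notation", {
  b <- parse_band("2C1")
  expect_equal(b$division, 2L)
  expect_equal(b$subdivision, "C")
  expect_equal(b$band, 1)
  expect_false(b$het)

  b <- parse_band("20F3")
  expect_equal(b$division, 20L)
  expect_equal(b$subdivision, "F")
  expect_equal(b$band, 3)

  h <- parse_band("h28")
  expect_true(h$het)
  expect_equal(h$division, 28L)

  # case-normalization
  expect_equal(format_band(parse_band("2c1")), "2C1")
  expect_equal(format_band(parse_band("H28")), "h28")

  # partial notation
  expect_true(is.na(parse_band("9C")$band))
  expect_true(is.na(parse_band("12")$subdivision))
})

test_that("malformed band strings fail naming the offending token", {
  expect_error(parse_band("21A1"), "21A1")
  expect_error(parse_band("0C1"), "0C1")
  expect_error(parse_band("h30"), "h30")
  expect_error(parse_band("2G1"), "2G1")
  expect_error(parse_band("xyz"), "xyz")
  expect_error(parse_band(""), "non-empty")
  expect_error(cyto_band(2, NA, 3), "subdivision")
  expect_error(cyto_band(28, "A", het = TRUE), "h-blocks")
})

test_that("parse/format round-trips on generated valid band strings", {
  set.seed(11)
  for (i in 1:200) {
    d <- sample(20, 1)
    s <- sample(c(NA, LETTERS[1:6]), 1)
    b <- if (is.na(s)) NA else sample(c(NA, 1:12), 1)
    text <- paste0(d, if (!is.na(s)) s, if (!is.na(s) && !is.na(b)) b)
    expect_identical(format_band(parse_band(text)), text)
  }
  for (h in 25:29) {
    text <- paste0("h", h)
    expect_identical(format_band(parse_band(text)), text)
  }
})

test_that("band_leq agrees with brute-force enumeration of the band order", {
  universe <- enumerate_band_universe(max_division = 6, max_band = 3)
  set.seed(7)
  pairs <- matrix(sample(length(universe), 400, replace = TRUE), ncol = 2)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    expect_identical(band_leq(universe[[i]], universe[[j]]), i <= j,
                     info = paste(format_band(universe[[i]]),
                                  format_band(universe[[j]])))
  }
})

test_that("band_leq is a total order", {
  universe <- enumerate_band_universe(max_division = 4, max_band = 2)
  set.seed(3)
  idx <- sample(length(universe), 30)
  for (i in idx) {
    a <- universe[[i]]
    expect_true(band_leq(a, a))  # reflexive
    for (j in sample(length(universe), 10)) {
      b <- universe[[j]]
      # totality + antisymmetry: exactly one of a<b, a=b, b<a
      lt <- band_leq(a, b) && !band_leq(b, a)
      gt <- band_leq(b, a) && !band_leq(a, b)
      eq <- band_leq(a, b) && band_leq(b, a)
      expect_equal(lt + gt + eq, 1L)
      expect_equal(eq, i == j)
    }
  }
  # h-blocks after all euchromatin, ordered among themselves
  expect_true(band_leq(parse_band("20F3"), parse_band("h25")))
  expect_true(band_leq(parse_band("h28"), parse_band("h29")))
  expect_false(band_leq(parse_band("h26"), parse_band("h25")))
})

test_that("interval parsing completes loose endpoints outward", {
  iv <- parse_interval("2C1-3E4")
  expect_equal(format_band(iv$start), "2C1")
  expect_equal(format_band(iv$end), "3E4")

  iv <- parse_interval("9C-10B")
  expect_equal(iv$start$band, 1)
  expect_equal(iv$start$subdivision, "C")
  expect_equal(iv$end$subdivision, "B")
  expect_true(is.infinite(iv$end$band))  # last band of 10B
  # the completed right end covers any concrete band of 10B ...
  expect_true(band_in_interval(parse_band("10B7"), iv))
  # ... but nothing in 10C
  expect_false(band_in_interval(parse_band("10C1"), iv))

  iv <- parse_interval("9-10")
  expect_equal(iv$start$subdivision, "A")
  expect_equal(iv$end$subdivision, "F")

  expect_error(parse_interval("3E4-2C1"), "reversed")
  expect_error(parse_interval("2C1"), "band")
  expect_error(parse_interval("2C1-3E4-5A1"), "interval")
})

test_that("overlap and intersection match the published example intervals", {
  a <- parse_interval("12C1-12F4")
  b <- parse_interval("12E9-13C5")
  expect_true(interval_overlaps(a, b))
  expect_true(interval_overlaps(b, a))  # symmetric
  inter <- interval_intersect(a, b)
  expect_equal(format(inter), "12E9-12F4")

  c1 <- parse_interval("11C2-11D1")
  c2 <- parse_interval("11D5-11E8")
  expect_false(interval_overlaps(c1, c2))
  expect_error(interval_intersect(c1, c2), "share no region")

  expect_true(interval_overlaps(a, a))  # self-overlap
  expect_equal(format(interval_intersect(a, a)), format(a))  # idempotence
})

test_that("overlap/intersect agree with an explicit band-set oracle", {
  axis <- band_axis_50()
  set.seed(19)
  for (rep in 1:150) {
    x <- random_axis_intervals(axis, 2)
    shared <- intersect(x[[1]]$idx, x[[2]]$idx)
    expect_identical(interval_overlaps(x[[1]]$interval, x[[2]]$interval),
                     length(shared) > 0)
    if (length(shared)) {
      inter <- interval_intersect(x[[1]]$interval, x[[2]]$interval)
      expect_identical(band_key(inter$start),
                       band_key(axis[[min(shared)]]))
      expect_identical(band_key(inter$end),
                       band_key(axis[[max(shared)]]))
      # containment in both inputs
      for (k in 1:2) {
        expect_true(band_leq(x[[k]]$interval$start, inter$start))
        expect_true(band_leq(inter$end, x[[k]]$interval$end))
      }
    }
  }
})

test_that("BED-like export uses 0-based half-open ordinal ranks", {
  ivs <- list(parse_interval("2C1-3E4"), parse_interval("11C2-11D1"),
              parse_interval("11D5-11E8"))
  bed <- cyto_bed(c("A", "B", "C"), ivs)
  expect_equal(bed$start, c(0L, 2L, 4L))
  expect_equal(bed$end, c(2L, 4L, 6L))
  expect_true(all(bed$end > bed$start))
  path <- withr::local_tempfile(fileext = ".bed")
  cyto_bed(c("A", "B", "C"), ivs, file = path)
  lines <- readLines(path)
  expect_match(lines[1], "^# ordinal")
  expect_equal(length(lines), 1 + 1 + 3)
})
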