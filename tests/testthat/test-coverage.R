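make_frags <- function(chrom, start, end, strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, name = ".",
             score = 0, strand = strand, stringsAsFactors = FALSE)
}

test_that("BED fragment reader validates the dialect", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrT\t0\t5\tfrag1\t0\t+",
               "chrT\t3\t9\tfrag2\t0\t-"), path)
  frags <- read_fragments(path, c(chrT = 10))
  expect_equal(nrow(frags), 2)
  expect_equal(frags$strand, c("+", "-"))
  expect_equal(frags$start, c(0, 3))

  writeLines("chrT\t0\t5", path)
  expect_warning(f3 <- read_fragments(path, c(chrT = 10)), "defaulting")
  expect_equal(f3$strand, "+")

  writeLines("chrT\t5\t5\tx\t0\t+", path)
  expect_error(read_fragments(path), "end <= start.*line 1")
  writeLines("chrT\t0\t5.5\tx\t0\t+", path)
  expect_error(read_fragments(path), "non-integer.*line 1")
  writeLines("chrT\t0\t50\tx\t0\t+", path)
  expect_error(read_fragments(path, c(chrT = 10)), "past end")
  writeLines("chrQ\t0\t5\tx\t0\t+", path)
  expect_error(read_fragments(path, c(chrT = 10)), "not in reference")
})

test_that("counting modes place signal as specified", {
  frags <- make_frags("chrT", 0, 5, "+")
  span <- compute_track(frags, c(chrT = 10), "span")
  expect_equal(span$values$chrT, c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))

  e3 <- compute_track(frags, c(chrT = 10), "end3")
  expect_equal(which(e3$values$chrT == 1), 5)  # base index 4, 0-based

  minus <- make_frags("chrT", 0, 5, "-")
  e3m <- compute_track(minus, c(chrT = 10), "end3")
  expect_equal(which(e3m$values$chrT == 1), 1)  # base index 0

  e5 <- compute_track(frags, c(chrT = 10), "end5")
  expect_equal(which(e5$values$chrT == 1), 1)
  e5m <- compute_track(minus, c(chrT = 10), "end5")
  expect_equal(which(e5m$values$chrT == 1), 5)

  empty <- compute_track(frags[0, ], c(chrT = 10), "span")
  expect_equal(empty$total_count, 0)
  expect_true(all(unlist(empty$values) == 0))
})

test_that("span counts match a naive per-base oracle on random fragments", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 200
    start <- sample(0:180, n, replace = TRUE)
    frags <- make_frags("chrT", start, start + sample(1:20, n, TRUE),
                        sample(c("+", "-"), n, TRUE))
    frags$end <- pmin(frags$end, 200)
    frags <- frags[frags$end > frags$start, ]
    tr <- compute_track(frags, c(chrT = 200), "span")
    expect_equal(tr$values$chrT, naive_span_coverage(frags, 200))
  }
})

test_that("raw-count conservation and strand partition hold", {
  set.seed(7)
  n <- 500
  start <- sample(0:900, n, replace = TRUE)
  frags <- make_frags(sample(c("c1", "c2"), n, TRUE), start,
                      start + sample(1:50, n, TRUE),
                      sample(c("+", "-"), n, TRUE))
  lens <- c(c1 = 1000, c2 = 1000)

  span <- compute_track(frags, lens, "span")
  expect_equal(span$total_count, sum(frags$end - frags$start))
  for (mode in c("end3", "end5")) {
    tr <- compute_track(frags, lens, mode)
    expect_equal(tr$total_count, nrow(frags))
  }
  for (mode in c("span", "end3", "end5")) {
    both <- compute_track(frags, lens, mode, "both")
    fwd <- compute_track(frags, lens, mode, "+")
    rev <- compute_track(frags, lens, mode, "-")
    expect_equal(both$values$c1, fwd$values$c1 + rev$values$c1)
    expect_equal(both$values$c2, fwd$values$c2 + rev$values$c2)
  }
})

test_that("fraction normalization gives mean one and scale invariance", {
  # uniform counts: every base exactly 1
  frags <- make_frags("chrT", (0:19) * 5, (0:19) * 5 + 5)
  tr <- fraction_normalize(compute_track(frags, c(chrT = 100), "span"))
  expect_equal(tr$values$chrT, rep(1, 100))

  # any nonempty input: genome-wide mean exactly 1 for every mode
  set.seed(13)
  n <- 300
  start <- sample(0:450, n, TRUE)
  rnd <- make_frags("chrA", start, start + sample(1:40, n, TRUE),
                    sample(c("+", "-"), n, TRUE))
  lens <- c(chrA = 500, chrB = 250)
  for (mode in c("span", "end3", "end5")) {
    norm <- fraction_normalize(compute_track(rnd, lens, mode))
    expect_equal(mean(unlist(norm$values)), 1, tolerance = 1e-9)
    expect_equal(sum(unlist(norm$values)), norm$genome_length)
  }

  # multiplying raw counts by 5 leaves the normalized track unchanged
  x5 <- rnd[rep(seq_len(nrow(rnd)), 5), ]
  n1 <- fraction_normalize(compute_track(rnd, lens, "span"))
  n5 <- fraction_normalize(compute_track(x5, lens, "span"))
  expect_equal(n1$values$chrA, n5$values$chrA)

  # all counts at one base of a 10-bp genome
  one <- make_frags("chrT", 3, 4)
  tr1 <- fraction_normalize(compute_track(one[rep(1, 7), ], c(chrT = 10),
                                          "span"))
  expect_equal(tr1$values$chrT, c(0, 0, 0, 10, 0, 0, 0, 0, 0, 0))

  empty <- compute_track(one[0, ], c(chrT = 10), "span")
  expect_error(fraction_normalize(empty), "empty track")
})

test_that("strand-pair normalization shares one sample-wide denominator", {
  set.seed(21)
  n <- 400
  start <- sample(0:900, n, TRUE)
  frags <- make_frags("c1", start, start + sample(1:30, n, TRUE),
                      sample(c("+", "-"), n, TRUE, prob = c(0.8, 0.2)))
  lens <- c(c1 = 1000)
  fwd <- compute_track(frags, lens, "span", "+")
  rev <- compute_track(frags, lens, "span", "-")
  pair <- normalize_strand_pair(fwd, rev)
  combined <- combine_tracks(pair$fwd, pair$rev)
  expect_equal(mean(unlist(combined$values)), 1, tolerance = 1e-9)
  # per-strand split preserved
  expect_equal(sum(unlist(pair$fwd$values)) / sum(unlist(combined$values)),
               fwd$total_count / (fwd$total_count + rev$total_count))
})

test_that("region_sum sums half-open intervals and checks bounds", {
  frags <- make_frags("chrT", 0, 5)
  raw <- compute_track(frags, c(chrT = 10), "span")
  expect_equal(region_sum(raw, "chrT", 0, 10), 5)  # fragment length
  expect_equal(region_sum(raw, "chrT", 0, 2), 2)
  expect_equal(region_sum(raw, "chrT", 5, 10), 0)

  uniform <- fraction_normalize(
    compute_track(make_frags("chrT", (0:19) * 5, (0:19) * 5 + 5),
                  c(chrT = 100), "span"))
  expect_equal(region_sum(uniform, "chrT", 10, 60), 50)

  expect_error(region_sum(raw, "chrT", 5, 20), "out of bounds")
  expect_error(region_sum(raw, "nope", 0, 5), "not in track")
})

test_that("bedGraph round trip is exact on values", {
  tr <- compute_track(make_frags("chrT", c(2, 2, 4), c(4, 4, 5)),
                      c(chrT = 5), "span")
  expect_equal(tr$values$chrT, c(0, 0, 2, 2, 1))
  path <- withr::local_tempfile(fileext = ".bg")
  write_bedgraph(tr, path)
  lines <- readLines(path)
  expect_equal(lines, c("chrT\t2\t4\t2", "chrT\t4\t5\t1"))
  back <- read_bedgraph(path, c(chrT = 5))
  expect_identical(back$values$chrT, tr$values$chrT)

  # fractional values round-trip bit-identically
  set.seed(31)
  n <- 200
  start <- sample(0:150, n, TRUE)
  norm <- fraction_normalize(
    compute_track(make_frags("chrT", start, start + sample(1:30, n, TRUE)),
                  c(chrT = 200), "span"))
  write_bedgraph(norm, path)
  back2 <- read_bedgraph(path, c(chrT = 200), normalized = TRUE)
  expect_identical(back2$values$chrT, norm$values$chrT)

  # empty track -> empty file -> all zeros
  empty <- compute_track(make_frags("chrT", 1, 2)[0, ], c(chrT = 5), "span")
  write_bedgraph(empty, path)
  expect_equal(length(readLines(path)), 0)
  back3 <- read_bedgraph(path, c(chrT = 5))
  expect_equal(back3$values$chrT, rep(0, 5))

  # overlapping runs rejected
  writeLines(c("chrT\t0\t3\t1", "chrT\t2\t5\t2"), path)
  expect_error(read_bedgraph(path, c(chrT = 5)), "overlapping")
})
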