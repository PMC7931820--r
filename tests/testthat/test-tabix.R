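test_that("line intervals follow the preset conventions", {
  expect_equal(lineInterval("chr1\t10\t20\tx", tabixConfig("bed")),
               list(seq = "chr1", beg = 10, end = 20))
  expect_equal(lineInterval("chr2\tsrc\texon\t100\t200\t.\t+\t.\tid",
                            tabixConfig("gff")),
               list(seq = "chr2", beg = 99, end = 200))
  expect_equal(lineInterval("chrX\t100\tid\tACG\tA\t50\tPASS\t.",
                            tabixConfig("vcf")),
               list(seq = "chrX", beg = 99, end = 102))
  expect_error(lineInterval("chr1\t10", tabixConfig("bed"), 7),
               "line 7", class = "tabix_parse")
  expect_error(lineInterval("chr1\tab\t20", tabixConfig("bed"), 9),
               "line 9", class = "tabix_parse")
})

test_that("a small sorted BED indexes and retrieves each line by interval", {
  bed <- c("chr1\t10\t20\ta", "chr1\t15\t30\tb", "chr2\t5\t8\tc")
  gz <- tempfile(fileext = ".bed.gz")
  bgzfWriteStream(bed, gz)
  idx <- tabixBuild(gz, tabixConfig("bed"))
  # point query at beg included, at end excluded (half-open)
  expect_identical(tabixQuery(gz, idx, list(seq = "chr1", beg = 10, end = 11)),
                   bed[1])
  expect_identical(tabixQuery(gz, idx, list(seq = "chr1", beg = 20, end = 21)),
                   bed[2])
  # whole-sequence query
  expect_identical(tabixQuery(gz, idx, "chr1"), bed[1:2])
  expect_identical(tabixQuery(gz, idx, "chr2"), bed[3])
  # unknown sequence: empty, not an error
  expect_identical(tabixQuery(gz, idx, "chr9"), character(0))
})

test_that("unsorted input is rejected with the offending line number", {
  bed <- c("chr1\t100\t200", "chr1\t50\t80")
  gz <- tempfile(fileext = ".bed.gz")
  bgzfWriteStream(bed, gz)
  expect_error(tabixBuild(gz, tabixConfig("bed")), "line 2",
               class = "not_sorted")
  # plain gzip input is refused
  pg <- tempfile()
  con <- gzfile(pg, "wb")
  writeBin(charToRaw("chr1\t1\t2\n"), con)
  close(con)
  expect_error(tabixBuild(pg, tabixConfig("bed")),
               class = "bgzf_plain_gzip")
})

test_that("comment handling: leading skipped, trailing rejected", {
  gz <- tempfile()
  bgzfWriteStream(c("#track", "chr1\t1\t5", "#oops", "chr1\t6\t9"), gz)
  expect_error(tabixBuild(gz, tabixConfig("bed")), class = "tabix_parse")
  gz2 <- tempfile()
  bgzfWriteStream(c("#track", "#another", "chr1\t1\t5"), gz2)
  idx <- tabixBuild(gz2, tabixConfig("bed"))
  expect_identical(tabixQuery(gz2, idx, "chr1"), "chr1\t1\t5")
})

test_that("tabix queries equal full-scan filtering on a generated BED", {
  lens <- c(chr1 = 100000, chr2 = 100000)
  bed <- genIntervals(lens, seed = 5, n = 3000)
  gz <- tempfile(fileext = ".bed.gz")
  bgzfWriteStream(bed, gz)
  conf <- tabixConfig("bed")
  idx <- tabixBuild(gz, conf)
  ivs <- lapply(seq_along(bed), function(i) lineInterval(bed[i], conf, i))
  seqs <- vapply(ivs, `[[`, "", "seq")
  begs <- vapply(ivs, `[[`, 0, "beg")
  ends <- vapply(ivs, `[[`, 0, "end")
  set.seed(405)
  for (i in 1:200) {
    sq <- sample(names(lens), 1)
    beg <- sample(0:99000, 1)
    end <- beg + sample(c(1, 10, 1000, 5000), 1)
    got <- tabixQuery(gz, idx, list(seq = sq, beg = beg, end = end))
    want <- bed[seqs == sq & begs < end & ends > beg]
    expect_identical(got, want)
  }
})

test_that("TBI round trip preserves config and name block byte-exactly", {
  bed <- genIntervals(c(chr1 = 50000, chr2 = 50000), seed = 6, n = 500)
  gz <- tempfile(fileext = ".bed.gz")
  bgzfWriteStream(bed, gz)
  idx <- tabixBuild(gz, tabixConfig("bed"))
  bytes <- writeIndex(idx)
  back <- readIndex(bytes)
  expect_identical(writeIndex(back), bytes)
  expect_equal(back@conf$names, idx@conf$names)
  expect_equal(back@conf$col_beg, 2L)
  expect_true(back@conf$zero_based)
  expect_identical(tabixQuery(gz, back, "chr1:1-5000"),
                   tabixQuery(gz, idx, "chr1:1-5000"))
})

test_that("our TBI agrees with the reference tabix tool", {
  bed <- genIntervals(c(chr1 = 50000), seed = 7, n = 400)
  dir <- tempfile(); dir.create(dir)
  gz <- file.path(dir, "x.bed.gz")
  bgzfWriteStream(bed, gz)
  idx <- tabixBuild(gz, tabixConfig("bed"))
  writeIndex(idx, paste0(gz, ".tbi"))
  for (rg in c("chr1:1-1000", "chr1:20000-21000", "chr1:49000-50000")) {
    theirs <- system2("tabix", c(gz, rg), stdout = TRUE)
    ours <- tabixQuery(gz, idx, rg)
    expect_identical(ours, as.character(theirs))
  }
  # and their index drives our queries
  file.remove(paste0(gz, ".tbi"))
  system2("tabix", c("-p", "bed", gz))
  theirs_idx <- readIndex(paste0(gz, ".tbi"))
  expect_identical(tabixQuery(gz, theirs_idx, "chr1:20000-21000"),
                   tabixQuery(gz, idx, "chr1:20000-21000"))
})

test_that("regidx matches a quadratic scan oracle and ignores insertion order", {
  expect_equal(regidxOverlap(regidxBuild(c("chr1\t0\t10", "chr1\t5\t15"),
                                         tabixConfig("bed")),
                             "chr1", 9, 11), c(1, 2))
  expect_equal(regidxOverlap(regidxBuild(c("chr1\t0\t10", "chr1\t5\t15"),
                                         tabixConfig("bed")),
                             "chr1", 10, 11), 2)
  set.seed(406)
  n <- 2000
  seqs <- sample(c("a", "b"), n, TRUE)
  begs <- sample(0:50000, n, TRUE)
  ends <- begs + sample(1:500, n, TRUE)
  lines <- sprintf("%s\t%d\t%d", seqs, begs, ends)
  rs <- regidxBuild(lines, tabixConfig("bed"))
  perm <- sample(n)
  rs_shuf <- regidxBuild(lines[perm], tabixConfig("bed"))
  for (i in 1:300) {
    sq <- sample(c("a", "b"), 1)
    qb <- sample(0:50000, 1); qe <- qb + sample(1:1000, 1)
    want <- sort(which(seqs == sq & begs < qe & ends > qb))
    expect_equal(sort(regidxOverlap(rs, sq, qb, qe)), want)
    # shuffled build returns the same intervals (payload = original line no.)
    expect_equal(sort(perm[regidxOverlap(rs_shuf, sq, qb, qe)]), want)
  }
})
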