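# independent oracle: enumerate every bin's interval from its number
oracle_bin_table <- function(scheme) {
  rows <- list()
  for (l in 0:scheme$depth) {
    off <- (8^l - 1) / 7
    size <- 2^(scheme$min_shift + 3 * (scheme$depth - l))
    k <- 0:(8^l - 1)
    rows[[l + 1]] <- data.frame(bin = off + k, beg = k * size,
                                end = (k + 1) * size, size = size)
  }
  do.call(rbind, rows)
}

oracle_reg2bin <- function(beg, end, tab) {
  containing <- tab[tab$beg <= beg & tab$end >= end, ]
  containing$bin[which.min(containing$size)]
}

oracle_reg2bins <- function(beg, end, tab) {
  sort(tab$bin[tab$beg < end & tab$end > beg])
}

test_that("reg2bin/reg2bins agree with exhaustive bin enumeration (small scheme)", {
  sch <- binningScheme(2L, 2L)         # 64 coordinates, 73 bins
  tab <- oracle_bin_table(sch)
  for (beg in seq(0, 60, by = 4)) for (end in seq(beg + 1, 64, by = 7)) {
    expect_equal(reg2bin(beg, end, sch), oracle_reg2bin(beg, end, tab))
    expect_equal(reg2bins(beg, end, sch), oracle_reg2bins(beg, end, tab))
  }
})

test_that("reg2bin/reg2bins match the oracle on the BAI scheme", {
  sch <- binningScheme(14L, 5L)
  tab <- oracle_bin_table(sch)
  expect_equal(reg2bin(0, 2^29, sch), 0)
  expect_equal(reg2bin(0, 16384, sch), 4681)
  expect_equal(reg2bin(0, 16385, sch), 585)
  expect_equal(reg2bins(0, 1, sch), c(0, 1, 9, 73, 585, 4681))
  expect_equal(length(reg2bins(0, 2^29, sch)), sum(8^(0:5)))  # all 37449 bins
  set.seed(401)
  for (i in 1:25) {
    beg <- sample(0:(2^29 - 2), 1)
    end <- beg + sample(1:10^6, 1)
    end <- min(end, 2^29)
    expect_equal(reg2bin(beg, end, sch), oracle_reg2bin(beg, end, tab))
    bins <- reg2bins(beg, end, sch)
    expect_equal(sort(bins), oracle_reg2bins(beg, end, tab))
    expect_true(reg2bin(beg, end, sch) %in% bins)
  }
  expect_error(reg2bin(0, 2^29 + 1, sch), class = "index_range")
})

test_that("maximum addressable coordinates reflect the scheme arithmetic", {
  expect_equal(maxCoordinate(binningScheme(14L, 5L)), 512 * 2^20)
  expect_equal(maxCoordinate(binningScheme(14L, 10L)), 2^44)
  expect_equal(maxCoordinate(binningScheme(0L, 0L)), 1)
})

test_that("single-record index places the chunk and linear anchor", {
  rec <- samRecord(qname = "one", ref_id = 0L, pos = 0,
                   cigar = cigarParse("100M"),
                   seq = strrep("A", 100), qual = rep(30L, 100))
  idx <- indexBuild(list(rec), vbeg = 123, vend = 456, n_ref = 1)
  rf <- idx@refs[[1]]
  expect_equal(names(rf$bins), "4681")
  expect_equal(unname(rf$bins[["4681"]]), matrix(c(123, 456), 1))
  expect_equal(rf$linear[1], 123)
  expect_equal(rf$pseudo$n_mapped, 1)
})

test_that("empty record stream still serializes a parseable index", {
  idx <- indexBuild(list(), numeric(0), numeric(0), n_ref = 1)
  bytes <- writeIndex(idx)
  back <- readIndex(bytes)
  expect_length(back@refs, 1)
  expect_equal(indexQuery(back, 0L, 0, 1000), matrix(numeric(0), 0, 2))
})

test_that("shuffled input is rejected", {
  recs <- list(
    samRecord(qname = "a", ref_id = 0L, pos = 500, cigar = cigarParse("4M"),
              seq = "ACGT"),
    samRecord(qname = "b", ref_id = 0L, pos = 100, cigar = cigarParse("4M"),
              seq = "ACGT"))
  expect_error(indexBuild(recs, c(0, 100), c(100, 200), n_ref = 1),
               class = "not_sorted")
})

test_that("abutting chunks merge into one", {
  m <- matrix(c(0, 100, 100, 250, 400, 500), ncol = 2, byrow = TRUE)
  merged <- mergeChunks(m)
  expect_equal(nrow(merged), 2)
  expect_equal(merged[1, ], c(0, 250))
})

test_that("index-driven retrieval equals brute-force scanning on random regions", {
  fx <- fix_small()
  dat <- readBam(fx$bam)
  bam <- bamOpen(fx$bam)
  refnames <- dat$header@refs$name
  ref_ids <- vapply(dat$records, `[[`, 0L, "ref_id")
  poss <- vapply(dat$records, `[[`, 0, "pos")
  ends <- pmax(vapply(dat$records, recordEndPos, 0), poss + 1)
  set.seed(402)
  for (i in 1:200) {
    rid <- sample(0:1, 1)
    beg <- sample(0:19000, 1)
    end <- beg + sample(c(1, 50, 500, 3000), 1)
    got <- bamQuery(bam, fx$index,
                    list(seq = refnames[rid + 1], ref_id = rid,
                         beg = beg, end = end))$records
    want <- dat$records[ref_ids == rid & poss < end & ends > beg & poss >= 0]
    expect_identical(vapply(got, `[[`, "", "qname"),
                     vapply(want, `[[`, "", "qname"))
  }
})

test_that("linear-index pruning keeps every overlapping record", {
  # dense low-coordinate records plus a query far to the right: pruning must
  # not drop the chunk that holds a long record spanning into the query
  recs <- c(
    list(samRecord(qname = "long", ref_id = 0L, pos = 10,
                   cigar = list(op = "M", len = 60000),
                   seq = "*", qual = NULL)),
    lapply(1:50, function(i)
      samRecord(qname = sprintf("s%02d", i), ref_id = 0L, pos = 100 + i,
                cigar = cigarParse("10M"), seq = strrep("A", 10))))
  wb <- writeBam(headerParse("@SQ\tSN:chr1\tLN:100000"), recs, index = TRUE)
  bam <- bamOpen(wb$bytes)
  got <- bamQuery(bam, wb$index, list(seq = "chr1", ref_id = 0L,
                                      beg = 59000, end = 59100))$records
  expect_equal(vapply(got, `[[`, "", "qname"), "long")
})

test_that("BAI serialization round-trips structurally", {
  fx <- fix_small()
  bytes <- writeIndex(fx$index)
  back <- readIndex(bytes)
  expect_equal(back@refs, fx$index@refs)
  expect_equal(back@n_no_coor, fx$index@n_no_coor)
  expect_identical(writeIndex(back), bytes)
  expect_error(readIndex(as.raw(c(0x42, 0x41, 0x49, 0x02))),
               class = "index_format")
})

test_that("CSI serialization round-trips at the byte level and in queries", {
  fx <- fix_small()
  dat <- readBam(fx$bam)
  csi <- indexBuild(dat$records, dat$vbeg, dat$vend, n_ref = 2,
                    ref_lengths = dat$header@refs$length, csi = TRUE)
  bytes <- writeIndex(csi)
  back <- readIndex(bytes)
  expect_identical(writeIndex(back), bytes)
  expect_equal(back@min_shift, 14L)
  expect_equal(back@depth, 5L)
  bam <- bamOpen(fx$bam)
  set.seed(403)
  for (i in 1:40) {
    beg <- sample(0:19000, 1); end <- beg + sample(1:2000, 1)
    a <- bamQuery(bam, csi, list(seq = "chr1", ref_id = 0L,
                                 beg = beg, end = end))$records
    b <- bamQuery(bam, back, list(seq = "chr1", ref_id = 0L,
                                  beg = beg, end = end))$records
    expect_identical(a, b)
  }
})

test_that("CSI depth auto-raises for long references", {
  rec <- samRecord(qname = "far", ref_id = 0L, pos = 2^30,
                   cigar = cigarParse("4M"), seq = "ACGT")
  idx <- indexBuild(list(rec), 0, 100, n_ref = 1,
                    ref_lengths = 2^31 - 2, csi = TRUE)
  expect_gt(idx@depth, 5L)
  expect_gte(maxCoordinate(binningScheme(idx@min_shift, idx@depth)), 2^31 - 2)
})

test_that("indexes interoperate with the reference implementation", {
  fx <- fix_small()
  # theirs -> ours: samtools-written BAI drives equivalent queries
  st_bai <- tempfile(fileext = ".bai")
  system2("samtools", c("index", "-o", st_bai, fx$bam))
  theirs <- readIndex(st_bai)
  bam <- bamOpen(fx$bam)
  set.seed(404)
  for (i in 1:40) {
    beg <- sample(0:19000, 1); end <- beg + sample(1:2000, 1)
    rg <- list(seq = "chr2", ref_id = 1L, beg = beg, end = end)
    expect_identical(bamQuery(bam, theirs, rg)$records,
                     bamQuery(bam, fx$index, rg)$records)
  }
  # ours -> theirs: samtools region queries through our BAI
  writeIndex(fx$index, paste0(fx$bam, ".bai"))
  cnt <- as.integer(system2("samtools",
                            c("view", "-c", fx$bam, "chr1:1000-3000"),
                            stdout = TRUE))
  dat <- readBam(fx$bam)
  want <- sum(vapply(dat$records, function(r)
    r$ref_id == 0 && r$pos >= 0 && recordOverlaps(r, 999, 3000), TRUE))
  expect_equal(cnt, want)
})
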