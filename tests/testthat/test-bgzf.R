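test_that("empty-payload block is the 28-byte EOF sentinel and gzip-decodable", {
  b <- bgzfCompressBlock(raw(0))
  expect_equal(b$bsize, 28L)
  expect_identical(b$bytes[1:4], as.raw(c(0x1f, 0x8b, 0x08, 0x04)))
  expect_identical(b$bytes, htslite:::BGZF_EOF)
  tf <- tempfile()
  writeBin(b$bytes, tf)
  con <- gzfile(tf, "rb")
  expect_identical(readBin(con, "raw", 10), raw(0))
  close(con)
})

test_that("block compress/decompress is the identity and respects size bounds", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(0:5000, 1)
    p <- if (i %% 2 == 0) as.raw(sample(0:255, n, TRUE))
         else as.raw(rep(sample(0:255, 1), n))
    for (lv in c(0L, 1L, 6L, 9L)) {
      blk <- bgzfCompressBlock(p, lv)
      expect_lte(blk$bsize, 65536)
      out <- bgzfDecompressBlock(blk$bytes)
      expect_identical(out$payload, p)
      expect_equal(out$bsize, blk$bsize)
    }
  }
  # worst case: incompressible payload at the full 65280-byte target
  p <- as.raw(sample(0:255, 65280, TRUE))
  expect_lte(bgzfCompressBlock(p, 6L)$bsize, 65536)
  expect_error(bgzfCompressBlock(as.raw(rep(0, 65281))),
               class = "bgzf_size_error")
})

test_that("any block can be decoded from only its own bytes", {
  set.seed(102)
  p1 <- as.raw(sample(0:255, 1000, TRUE))
  p2 <- as.raw(sample(0:255, 2000, TRUE))
  stream <- c(bgzfCompressBlock(p1)$bytes, bgzfCompressBlock(p2)$bytes)
  b1 <- bgzfDecompressBlock(stream, 1L)
  expect_identical(b1$payload, p1)
  lone <- stream[(b1$bsize + 1):length(stream)]
  expect_identical(bgzfDecompressBlock(lone, 1L)$payload, p2)
})

test_that("virtual offset packing round-trips and preserves ordering", {
  expect_equal(voffsetPack(0, 0), 0)
  expect_equal(voffsetPack(1, 0), 65536)
  expect_equal(voffsetPack(135, 4), 8847364)
  expect_identical(voffsetUnpack(8847364), list(coffset = 135, uoffset = 4))
  set.seed(103)
  co <- sort(sample(0:1e6, 50))
  uo <- sample(0:65535, 50, replace = TRUE)
  packed <- voffsetPack(co, uo)
  expect_identical(order(packed), order(co * 1e6 + uo))
  un <- voffsetUnpack(packed)
  expect_equal(un$coffset, co)
  expect_equal(un$uoffset, uo)
  expect_error(voffsetPack(2^48, 0), class = "voffset_range")
  expect_error(voffsetPack(0, 65536), class = "voffset_range")
})

test_that("stream writer chunks at 65280 bytes and appends the sentinel", {
  tf <- tempfile()
  bgzfWriteStream(raw(0), tf)
  expect_equal(file.size(tf), 28)
  expect_true(bgzfCheckEof(tf))
  set.seed(104)
  data <- as.raw(sample(0:255, 2^20, TRUE))
  tf2 <- tempfile()
  bgzfWriteStream(data, tf2)
  bf <- bgzfOpen(tf2)
  expect_equal(nrow(bf@state$blocks), ceiling(2^20 / 65280) + 1L)  # 17 + EOF
  expect_identical(bgzfRead(bf, 2^20 + 5), data)
  expect_true(bgzfCheckEof(tf2))
  # standard gzip tooling decodes the whole multi-member stream
  con <- gzfile(tf2, "rb")
  expect_identical(readBin(con, "raw", 2^21), data)
  close(con)
})

test_that("concatenated BGZF files form a valid stream", {
  a <- bgzfWriteStream(charToRaw("hello "))
  b <- bgzfWriteStream(charToRaw("world"))
  bf <- bgzfOpen(c(a, b))
  expect_identical(rawToChar(bgzfRead(bf, 100)), "hello world")
})

test_that("random access via recorded virtual offsets matches sequential reads", {
  set.seed(105)
  data <- as.raw(sample(0:255, 300000, TRUE))
  stream <- bgzfWriteStream(data)
  bf <- bgzfOpen(stream)
  # record (voffset, logical position) pairs during a sequential chunked read
  bgzfSeek(bf, 0)
  pos <- 0
  anchors <- list()
  repeat {
    v <- bgzfTell(bf)
    chunk <- bgzfRead(bf, 7777)
    if (length(chunk) == 0) break
    anchors[[length(anchors) + 1L]] <- list(v = v, pos = pos, n = length(chunk))
    pos <- pos + length(chunk)
  }
  for (a in anchors[sample(length(anchors), 10)]) {
    expect_identical(bgzfReadAt(bf, a$v, a$n),
                     data[(a$pos + 1):(a$pos + a$n)])
  }
  # reads spanning block boundaries are transparent
  expect_identical(bgzfReadAt(bf, 0, 70000), data[1:70000])
  # read at the EOF sentinel block yields end-of-stream
  eof_coff <- bf@state$blocks$coffset[nrow(bf@state$blocks)]
  expect_identical(bgzfReadAt(bf, voffsetPack(eof_coff, 0), 1), raw(0))
  # a coffset off the block grid is corruption
  expect_error(bgzfSeek(bf, voffsetPack(3, 0)), class = "bgzf_corrupt")
})

test_that("corruption and plain-gzip inputs are distinguished", {
  blk <- bgzfCompressBlock(charToRaw("payload"))$bytes
  # flip a payload byte: CRC failure
  bad <- blk
  bad[20] <- xor(bad[20], as.raw(0xff))
  expect_error(bgzfDecompressBlock(bad), class = "bgzf_corrupt")
  # plain gzip member: detectable, named distinctly
  tf <- tempfile()
  con <- gzfile(tf, "wb")
  writeBin(charToRaw("plain gzip data"), con)
  close(con)
  expect_error(bgzfDecompressBlock(readBin(tf, "raw", n = file.size(tf))),
               class = "bgzf_plain_gzip")
  # but sequential reading of plain gzip still works, flagged non-seekable
  bf <- bgzfOpen(tf)
  expect_false(bf@state$seekable)
  expect_identical(rawToChar(bgzfRead(bf, 100)), "plain gzip data")
  expect_error(bgzfReadAt(bf, 0, 5), class = "bgzf_plain_gzip")
  # not gzip at all
  expect_error(bgzfOpen(charToRaw("just text")), class = "bgzf_not_bgzf")
  # truncated final block
  stream <- bgzfWriteStream(as.raw((1:1000) %% 256))
  expect_error(bgzfOpen(stream[1:(length(stream) - 30)]),
               class = "bgzf_corrupt")
  # missing EOF sentinel: warning, not error
  noeof <- stream[1:(length(stream) - 28)]
  expect_warning(bgzfOpen(noeof), "EOF sentinel")
})
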