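test_that("frequency normalization totals 4096 with largest-remainder fixup", {
  one <- normalizeFreqs(c(A = 1))
  expect_equal(one$freq[utf8ToInt("A") + 1], 4096)
  expect_equal(sum(one$freq), 4096)
  two <- normalizeFreqs(c(A = 1, B = 1))
  expect_equal(two$freq[utf8ToInt("A") + 1], 2048)
  expect_equal(two$freq[utf8ToInt("B") + 1], 2048)
  skew <- normalizeFreqs(c(A = 3, B = 1))
  expect_equal(skew$freq[utf8ToInt("A") + 1], 3072)
  expect_equal(skew$freq[utf8ToInt("B") + 1], 1024)
  # every present symbol keeps freq >= 1 even under extreme skew
  counts <- numeric(256)
  counts[1] <- 1e6
  counts[2:101] <- 1
  nf <- normalizeFreqs(counts)
  expect_equal(sum(nf$freq), 4096)
  expect_true(all(nf$freq[2:101] >= 1))
})

test_that("round trips hold on arbitrary inputs including degenerate ones", {
  set.seed(701)
  cases <- c(list(raw(0), as.raw(0), as.raw(255), as.raw(rep(7, 1000))),
             lapply(c(1, 2, 3, 5, 100, 4096), function(n)
               as.raw(sample(0:255, n, TRUE))),
             list(charToRaw(strrep("abracadabra ", 100))))
  for (x in cases) for (k in 0:1) {
    enc <- ransEncode(x, k)
    expect_identical(ransDecode(enc), x)
    # deterministic: same input, same bytes
    expect_identical(ransEncode(x, k), enc)
  }
})

# Straight-line reference encoder written from the documented stream layout:
# single explicit loop per phase, flat vectors, no shared helpers.
oracle_rans0 <- function(data) {
  n <- length(data)
  syms <- as.integer(data)
  counts <- tabulate(syms + 1L, nbins = 256)
  # normalize to 4096, floor >= 1, largest remainders get the leftover
  total <- sum(counts)
  pres <- which(counts > 0)
  exact <- counts[pres] * 4096 / total
  f <- pmax(floor(exact), 1)
  short <- 4096 - sum(f)
  frac_order <- order(exact - floor(exact), decreasing = TRUE)
  i <- 0
  while (short > 0) {
    f[frac_order[(i %% length(pres)) + 1]] <-
      f[frac_order[(i %% length(pres)) + 1]] + 1
    short <- short - 1; i <- i + 1
  }
  while (short < 0) {
    k <- which.max(f); f[k] <- f[k] - min(f[k] - 1, -short)
    short <- 4096 - sum(f)
  }
  freq <- numeric(256); freq[pres] <- f
  cum <- cumsum(c(0, freq[-256]))
  # header: order byte, u32 n, freq table as runs
  le32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256,
                               x %/% 65536 %% 256, x %/% 16777216 %% 256))
  p0 <- pres - 1L
  runs <- split(p0, cumsum(c(1, diff(p0) != 1)))
  tab <- as.raw(c(length(runs) %% 256, length(runs) %/% 256))
  for (r in runs) {
    tab <- c(tab, as.raw(r[1]), as.raw(length(r)))
    for (s in r) {
      fv <- freq[s + 1]
      tab <- c(tab, if (fv < 128) as.raw(fv)
               else as.raw(c(128 + fv %/% 256, fv %% 256)))
    }
  }
  # payload: 4 interleaved states, renorm bytes reversed into decode order
  x <- rep(8388608, 4)
  emitted <- integer(0)
  for (i in seq(n, 1)) {
    lane <- ((i - 1) %% 4) + 1
    fv <- freq[syms[i] + 1]
    while (x[lane] >= 524288 * fv) {
      emitted <- c(emitted, x[lane] %% 256)
      x[lane] <- x[lane] %/% 256
    }
    x[lane] <- (x[lane] %/% fv) * 4096 + cum[syms[i] + 1] + x[lane] %% fv
  }
  c(as.raw(0), le32(n), tab,
    le32(x[1]), le32(x[2]), le32(x[3]), le32(x[4]),
    as.raw(rev(emitted)))
}

test_that("order-0 output is byte-exact against the straight-line oracle", {
  for (txt in c("abracadabra", "to be or not to be", "mississippi")) {
    x <- charToRaw(txt)
    expect_identical(ransEncode(x, 0L), oracle_rans0(x))
  }
  set.seed(702)
  for (i in 1:10) {
    x <- as.raw(sample(0:20, sample(10:500, 1), TRUE))
    expect_identical(ransEncode(x, 0L), oracle_rans0(x))
  }
})

test_that("order-0 payload approaches the Shannon bound on known-entropy input", {
  set.seed(703)
  # 4 equiprobable symbols: H0 = 2 bits/byte
  x <- as.raw(sample(0:3, 4096, TRUE))
  enc <- ransEncode(x, 0L)
  table_overhead <- 2 + 2 + 4 * 2          # run header + 4 two-byte freqs
  payload <- length(enc) - 5 - table_overhead - 16
  expect_gte(payload, 4096 * 2 / 8 * 0.98)   # cannot beat entropy (slack for
  expect_lte(payload, 4096 * 2 / 8 * 1.05)   # state flush amortization)
})

test_that("order-1 exploits bigram structure on English-like text", {
  x <- charToRaw(strrep("the quick brown fox jumps over the lazy dog. ", 60))
  e0 <- ransEncode(x, 0L)
  e1 <- ransEncode(x, 1L)
  expect_lte(length(e1), length(e0))
  expect_identical(ransDecode(e1), x)
})

test_that("codec selection returns the smallest candidate and decodes back", {
  set.seed(704)
  rnd <- as.raw(sample(0:255, 8192, TRUE))
  sel <- codecSelect(rnd)
  expect_equal(sel$codec, "raw")             # incompressible
  expect_identical(codecDecode(sel$bytes), rnd)
  const <- as.raw(rep(65, 65536))
  sel2 <- codecSelect(const)
  expect_false(sel2$codec == "raw")          # any entropy coder wins
  expect_identical(codecDecode(sel2$bytes), const)
  txt <- charToRaw(strrep("englishy text with structure. ", 200))
  sel3 <- codecSelect(txt)
  expect_identical(codecDecode(sel3$bytes), txt)
  expect_lte(length(sel3$bytes), length(txt) + 1)
  # never larger than raw + id byte, for any input
  for (x in list(raw(0), as.raw(1), rnd[1:100]))
    expect_lte(length(codecSelect(x)$bytes), length(x) + 1)
})
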