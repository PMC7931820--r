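# Little-endian byte packing helpers over raw vectors.
#
# Multi-byte integers are carried as R doubles (exact to 2^53), which covers
# every field in the formats handled here except the full 64-bit virtual
# offset range; see voffsetPack() for that bound.

uint8 <- function(x) as.raw(x)

uint16le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}

uint32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

int32le <- function(x) {
  x <- as.numeric(x)
  uint32le(ifelse(x < 0, x + 4294967296, x))
}

uint64le <- function(x) {
  x <- as.numeric(x)
  c(uint32le(x %% 4294967296), uint32le(x %/% 4294967296))
}

float32le <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")

# round a double through binary32 (what BAM float fields store)
float32snap <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}

# readers: `at` is the 1-based offset of the first byte
rd_uint8 <- function(r, at) as.integer(r[at])

rd_uint16 <- function(r, at) {
  as.integer(r[at]) + 256 * as.integer(r[at + 1])
}

rd_uint32 <- function(r, at) {
  as.numeric(as.integer(r[at])) + 256 * as.integer(r[at + 1]) +
    65536 * as.integer(r[at + 2]) + 16777216 * as.numeric(as.integer(r[at + 3]))
}

rd_int32 <- function(r, at) {
  v <- rd_uint32(r, at)
  ifelse(v >= 2147483648, v - 4294967296, v)
}

rd_uint64 <- function(r, at) {
  rd_uint32(r, at) + 4294967296 * rd_uint32(r, at + 4)
}

rd_float32 <- function(r, at) {
  readBin(r[at:(at + 3)], "double", n = 1L, size = 4L, endian = "little")
}

# vectorized u32 reads at several 1-based start offsets
rd_uint32v <- function(r, starts) {
  b <- as.integer(r)
  as.numeric(b[starts]) + 256 * b[starts + 1] + 65536 * b[starts + 2] +
    16777216 * as.numeric(b[starts + 3])
}

rawslice <- function(r, at, n) {
  if (n == 0) raw(0) else r[at:(at + n - 1)]
}

# NUL-terminated string starting at `at`, returns list(str, nbytes incl NUL)
rd_cstring <- function(r, at) {
  i <- at
  n <- length(r)
  while (i <= n && r[i] != as.raw(0)) i <- i + 1L
  if (i > n) stop("unterminated string in binary record")
  list(str = rawToChar(rawslice(r, at, i - at)), nbytes = i - at + 1L)
}
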