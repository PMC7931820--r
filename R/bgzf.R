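#' @useDynLib htslite, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# condition helper: all package errors carry a subclass so callers/tests can
# distinguish corruption from format-detection outcomes
hts_stop <- function(msg, class) {
  stop(structure(class = c(class, "htslite_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' BGZF constants
#'
#' `BGZF_EOF` is the bit-exact 28-byte empty-payload block appended to every
#' finished BGZF stream as an end-of-file sentinel.  `BGZF_BLOCK_SIZE` is the
#' target uncompressed payload per block (65280 bytes, leaving headroom so
#' that worst-case incompressible DEFLATE output still fits the 16-bit
#' on-disk block-size field).
#' @name bgzf-constants
#' @keywords internal
BGZF_BLOCK_SIZE <- 65280L

BGZF_EOF <- as.raw(c(
  0x1f, 0x8b, 0x08, 0x04, 0x00, 0x00, 0x00, 0x00, 0x00, 0xff,
  0x06, 0x00, 0x42, 0x43, 0x02, 0x00, 0x1b, 0x00, 0x03, 0x00,
  0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00))

#' Compress one BGZF block
#'
#' Wraps a payload of at most 65280 bytes into a single gzip member carrying
#' the BGZF `BC` extra subfield (total on-disk block length minus one, as a
#' 16-bit little-endian integer).  Any standard gzip decompressor recovers
#' the payload; the extra subfield is what makes the stream seekable.
#'
#' If the compressed block would overflow the 16-bit size field the payload
#' is re-compressed at decreasing levels and finally stored uncompressed
#' (DEFLATE stored blocks), which always fits at the 65280-byte target.
#'
#' @param payload raw vector, at most 65280 bytes
#' @param level DEFLATE level 0-9; 0 emits stored (uncompressed) blocks
#' @return a `BgzfBlock`: list with `bytes` (the framed block), `cdata`,
#'   `bsize`, `isize`, `crc32`
#' @export
bgzfCompressBlock <- function(payload, level = 6L) {
  stopifnot(is.raw(payload))
  if (length(payload) > BGZF_BLOCK_SIZE)
    hts_stop(sprintf("payload of %d bytes exceeds BGZF block capacity (%d)",
                     length(payload), BGZF_BLOCK_SIZE), "bgzf_size_error")
  cdata <- .zlib_deflate_raw(payload, as.integer(level))
  if (length(cdata) + 26L > 65536L) {
    for (lv in c(1L, 0L)) {
      cdata <- .zlib_deflate_raw(payload, lv)
      if (length(cdata) + 26L <= 65536L) break
    }
    if (length(cdata) + 26L > 65536L)
      hts_stop("compressed block exceeds 65536 bytes even when stored",
               "bgzf_size_error")
  }
  bsize <- length(cdata) + 26L
  crc <- .zlib_crc32(payload)
  bytes <- c(
    as.raw(c(0x1f, 0x8b, 0x08, 0x04,       # magic, CM=deflate, FLG=FEXTRA
             0x00, 0x00, 0x00, 0x00,       # MTIME
             0x00, 0xff,                   # XFL, OS=unknown
             0x06, 0x00,                   # XLEN=6
             0x42, 0x43, 0x02, 0x00)),     # 'B','C', SLEN=2
    uint16le(bsize - 1L),
    cdata,
    uint32le(crc),
    uint32le(length(payload)))
  structure(list(bytes = bytes, cdata = cdata, bsize = bsize,
                 isize = length(payload), crc32 = crc),
            class = "BgzfBlock")
}

# Parse the gzip member header at 1-based offset `at`; returns NULL fields on
# non-BGZF.  Internal: shared by the block decoder and the stream scanner.
.bgzf_member_info <- function(r, at) {
  n <- length(r)
  if (at + 1 > n || r[at] != as.raw(0x1f) || r[at + 1] != as.raw(0x8b))
    hts_stop("not a gzip stream (bad magic)", "bgzf_not_bgzf")
  if (at + 11 > n) hts_stop("truncated gzip member header", "bgzf_corrupt")
  flg <- as.integer(r[at + 3])
  if (bitwAnd(flg, 4L) == 0L)
    hts_stop("plain gzip, not seekable (no FEXTRA subfield)", "bgzf_plain_gzip")
  xlen <- rd_uint16(r, at + 10)
  if (at + 11 + xlen > n) hts_stop("truncated FEXTRA field", "bgzf_corrupt")
  # scan subfields for 'BC'
  p <- at + 12
  stop_at <- at + 12 + xlen
  bsize <- NA_integer_
  while (p < stop_at) {
    si1 <- r[p]; si2 <- r[p + 1]
    slen <- rd_uint16(r, p + 2)
    if (si1 == as.raw(0x42) && si2 == as.raw(0x43) && slen == 2L)
      bsize <- rd_uint16(r, p + 4) + 1L
    p <- p + 4 + slen
  }
  if (is.na(bsize))
    hts_stop("plain gzip, not seekable (no BC subfield)", "bgzf_plain_gzip")
  list(xlen = xlen, bsize = bsize, data_at = at + 12 + xlen)
}

#' Decompress one BGZF block
#'
#' Decodes the BGZF block starting at byte offset `at` (1-based) of `r`,
#' verifying the stored CRC32 and uncompressed size.
#'
#' @param r raw vector containing at least one whole block
#' @param at 1-based offset of the block start
#' @return list with `payload` (raw) and `bsize` (on-disk block length)
#' @export
bgzfDecompressBlock <- function(r, at = 1L) {
  info <- .bgzf_member_info(r, at)
  bsize <- info$bsize
  if (at + bsize - 1 > length(r))
    hts_stop("truncated BGZF block", "bgzf_corrupt")
  isize <- rd_uint32(r, at + bsize - 4)
  crc_stored <- rd_uint32(r, at + bsize - 8)
  cdata <- rawslice(r, info$data_at, bsize - (info$data_at - at) - 8)
  payload <- .zlib_inflate_raw(cdata, isize)
  if (.zlib_crc32(payload) != crc_stored)
    hts_stop("BGZF block CRC mismatch: stream is corrupt", "bgzf_corrupt")
  list(payload = payload, bsize = bsize)
}

#' Pack and unpack BGZF virtual offsets
#'
#' A virtual offset addresses a byte inside a BGZF stream as
#' `coffset * 2^16 + uoffset`: the upper 48 bits are the compressed-file
#' offset of a block start, the lower 16 bits the offset within that block's
#' uncompressed payload.  Packed values are doubles, exact for
#' `coffset < 2^37` (~137 GiB of compressed data); larger offsets are
#' rejected to avoid silent rounding.
#'
#' @param coffset compressed-file byte offset of a block start
#' @param uoffset within-block uncompressed offset, < 65536
#' @param v packed virtual offset
#' @return `voffsetPack`: packed numeric; `voffsetUnpack`: list with
#'   `coffset`, `uoffset`
#' @examples
#' voffsetPack(135, 4)          # 8847364
#' voffsetUnpack(65536)$coffset # 1
#' @export
voffsetPack <- function(coffset, uoffset) {
  coffset <- as.numeric(coffset); uoffset <- as.numeric(uoffset)
  if (any(coffset < 0) || any(coffset >= 2^48))
    hts_stop("coffset out of range [0, 2^48)", "voffset_range")
  if (any(coffset >= 2^37))
    hts_stop("coffset >= 2^37 not exactly representable as a double",
             "voffset_range")
  if (any(uoffset < 0) || any(uoffset >= 65536))
    hts_stop("uoffset out of range [0, 2^16)", "voffset_range")
  coffset * 65536 + uoffset
}

#' @rdname voffsetPack
#' @export
voffsetUnpack <- function(v) {
  v <- as.numeric(v)
  if (any(v < 0)) hts_stop("negative virtual offset", "voffset_range")
  list(coffset = v %/% 65536, uoffset = v %% 65536)
}

#' BGZF stream handle
#'
#' In-memory handle over a BGZF (or, read-only and non-seekable, plain gzip)
#' file.  Blocks are located up front; payloads are inflated lazily and
#' cached, and the handle counts how many blocks have actually been inflated
#' (`bgzfBlocksRead`), which the multi-region iterator tests use to measure
#' I/O.
#'
#' @slot path source path ("" for in-memory streams)
#' @slot state environment holding the block table, payload cache, cursor and
#'   inflation counter
#' @export
setClass("BgzfFile", representation(path = "character", state = "environment"))

setMethod("show", "BgzfFile", function(object) {
  st <- object@state
  cat(sprintf("BgzfFile: %s\n  %d block(s), %.0f compressed / %.0f uncompressed bytes%s%s\n",
              if (nzchar(object@path)) object@path else "<memory>",
              nrow(st$blocks), length(st$raw), sum(st$blocks$isize),
              if (st$seekable) "" else " [plain gzip, not seekable]",
              if (st$eof_present) "" else " [no EOF sentinel]"))
})

#' Open a BGZF stream
#'
#' Reads the whole file, scans the block table and positions a cursor at
#' logical offset 0.  A missing EOF sentinel raises a warning (truncation
#' cannot be proven); a truncated final block is an error.  Plain gzip input
#' (no `BC` subfield) is accepted for sequential reading but flagged
#' non-seekable.
#'
#' @param x path to a BGZF file, or a raw vector holding one
#' @return a [BgzfFile-class] handle
#' @export
bgzfOpen <- function(x) {
  if (is.raw(x)) {
    r <- x
    path <- ""
  } else {
    r <- readBin(x, "raw", n = file.size(x))
    path <- x
  }
  st <- new.env(parent = emptyenv())
  st$raw <- r
  st$cache <- vector("list", 0L)
  st$n_inflated <- 0L
  st$seekable <- TRUE
  plain <- FALSE
  coffs <- numeric(0); bsizes <- numeric(0); isizes <- numeric(0)
  off <- 0
  n <- length(r)
  if (n == 0) hts_stop("empty file is not BGZF", "bgzf_corrupt")
  while (off < n) {
    info <- tryCatch(.bgzf_member_info(r, off + 1),
                     bgzf_plain_gzip = function(e) e)
    if (inherits(info, "condition")) { plain <- TRUE; break }
    if (off + info$bsize > n)
      hts_stop("truncated final BGZF block", "bgzf_corrupt")
    isize <- rd_uint32(r, off + info$bsize - 3)
    coffs <- c(coffs, off); bsizes <- c(bsizes, info$bsize)
    isizes <- c(isizes, isize)
    off <- off + info$bsize
  }
  if (plain) {
    if (length(coffs) > 0)
      hts_stop("mixed BGZF and plain-gzip members", "bgzf_corrupt")
    payload <- memDecompress(r, type = "gzip")
    st$seekable <- FALSE
    st$plain_payload <- payload
    st$blocks <- data.frame(coffset = 0, bsize = n, isize = length(payload),
                            ustart = 0)
    st$cache <- list(payload)
    st$eof_present <- FALSE
  } else {
    st$blocks <- data.frame(coffset = coffs, bsize = bsizes, isize = isizes,
                            ustart = cumsum(c(0, isizes[-length(isizes)])))
    st$cache <- vector("list", length(coffs))
    st$eof_present <- n >= 28 && identical(r[(n - 27):n], BGZF_EOF)
    if (!st$eof_present)
      warning("BGZF stream has no EOF sentinel; file may be truncated")
  }
  st$cur_block <- 1L   # 1-based block index
  st$cur_uoff <- 0     # 0-based offset within block payload
  new("BgzfFile", path = path, state = st)
}

.bgzf_block_payload <- function(bf, i) {
  st <- bf@state
  p <- st$cache[[i]]
  if (is.null(p)) {
    b <- st$blocks[i, ]
    p <- bgzfDecompressBlock(st$raw, b$coffset + 1)$payload
    if (length(p) != b$isize)
      hts_stop("BGZF ISIZE mismatch", "bgzf_corrupt")
    st$cache[[i]] <- p
    st$n_inflated <- st$n_inflated + 1L
  }
  p
}

#' @rdname bgzfOpen
#' @param bf an open [BgzfFile-class]
#' @export
bgzfBlocksRead <- function(bf) bf@state$n_inflated

#' @rdname bgzfOpen
#' @export
bgzfResetCache <- function(bf) {
  st <- bf@state
  st$cache <- vector("list", nrow(st$blocks))
  st$n_inflated <- 0L
  invisible(bf)
}

# normalize cursor: an exhausted block advances to the next block's start
.bgzf_norm_cursor <- function(st) {
  while (st$cur_block < nrow(st$blocks) &&
         st$cur_uoff >= st$blocks$isize[st$cur_block]) {
    st$cur_uoff <- st$cur_uoff - st$blocks$isize[st$cur_block]
    st$cur_block <- st$cur_block + 1L
  }
  invisible(NULL)
}

#' Sequential and random-access reads from a BGZF stream
#'
#' `bgzfRead` returns up to `n` bytes from the cursor, transparently crossing
#' block boundaries; fewer bytes (possibly zero) signal end of stream.
#' `bgzfTell` reports the cursor as a packed virtual offset; `bgzfSeek`
#' repositions it (the compressed component must name a true block start).
#' `bgzfReadAt` is seek-then-read.
#'
#' @param bf an open [BgzfFile-class]
#' @param n number of bytes requested
#' @param voffset packed virtual offset
#' @return raw vector (`bgzfRead`/`bgzfReadAt`); numeric voffset (`bgzfTell`)
#' @export
bgzfRead <- function(bf, n) {
  st <- bf@state
  out <- vector("list", 0L)
  got <- 0
  while (got < n) {
    .bgzf_norm_cursor(st)
    i <- st$cur_block
    bl <- st$blocks[i, ]
    avail <- bl$isize - st$cur_uoff
    if (avail <= 0) break     # last block exhausted
    take <- min(avail, n - got)
    p <- .bgzf_block_payload(bf, i)
    out[[length(out) + 1L]] <- p[(st$cur_uoff + 1):(st$cur_uoff + take)]
    st$cur_uoff <- st$cur_uoff + take
    got <- got + take
  }
  if (length(out) == 0) raw(0) else do.call(c, out)
}

#' @rdname bgzfRead
#' @export
bgzfTell <- function(bf) {
  st <- bf@state
  .bgzf_norm_cursor(st)
  voffsetPack(st$blocks$coffset[st$cur_block], st$cur_uoff)
}

#' @rdname bgzfRead
#' @export
bgzfSeek <- function(bf, voffset) {
  st <- bf@state
  if (!st$seekable)
    hts_stop("plain gzip, not seekable", "bgzf_plain_gzip")
  vo <- voffsetUnpack(voffset)
  i <- match(vo$coffset, st$blocks$coffset)
  if (is.na(i))
    hts_stop(sprintf("virtual offset %.0f does not address a block boundary",
                     as.numeric(voffset)), "bgzf_corrupt")
  if (vo$uoffset > st$blocks$isize[i])
    hts_stop("within-block offset beyond block payload", "bgzf_corrupt")
  st$cur_block <- i
  st$cur_uoff <- vo$uoffset
  invisible(bf)
}

#' @rdname bgzfRead
#' @export
bgzfReadAt <- function(bf, voffset, n) {
  bgzfSeek(bf, voffset)
  bgzfRead(bf, n)
}

# logical (fully-uncompressed) offset <-> virtual offset
.bgzf_v2l <- function(bf, voffset) {
  st <- bf@state
  vo <- voffsetUnpack(voffset)
  i <- match(vo$coffset, st$blocks$coffset)
  if (is.na(i)) hts_stop("voffset not at a block boundary", "bgzf_corrupt")
  st$blocks$ustart[i] + vo$uoffset
}

.bgzf_l2v <- function(bf, off) {
  st <- bf@state
  i <- findInterval(off, st$blocks$ustart)
  i <- max(i, 1L)
  # skip empty blocks so offsets land in the block that holds the byte
  while (i < nrow(st$blocks) &&
         off >= st$blocks$ustart[i] + st$blocks$isize[i])
    i <- i + 1L
  voffsetPack(st$blocks$coffset[i], off - st$blocks$ustart[i])
}

#' Total uncompressed size of a BGZF stream
#' @param bf an open [BgzfFile-class]
#' @export
bgzfUncompressedSize <- function(bf) sum(bf@state$blocks$isize)

#' Streaming BGZF writer
#'
#' Accumulates bytes, flushing a block whenever 65280 payload bytes are
#' pending, and appends the EOF sentinel on close.  `$tell()` reports the
#' virtual offset at which the next appended byte will land, which is how
#' on-the-fly indexing records record-start anchors.
#'
#' @param path output path, or NULL to collect bytes in memory
#' @param level DEFLATE level
#' @return environment with `$append(raw)`, `$tell()`, `$close()` (returns
#'   the raw stream when `path` is NULL)
#' @export
bgzfWriter <- function(path = NULL, level = 6L) {
  pending <- raw(0)
  done <- list()
  coffset <- 0
  flush1 <- function(nbytes) {
    blk <- bgzfCompressBlock(pending[seq_len(nbytes)], level)
    pending <<- pending[-seq_len(nbytes)]
    done[[length(done) + 1L]] <<- blk$bytes
    coffset <<- coffset + blk$bsize
  }
  w <- new.env(parent = emptyenv())
  w$append <- function(data) {
    stopifnot(is.raw(data))
    pending <<- c(pending, data)
    while (length(pending) >= BGZF_BLOCK_SIZE) flush1(BGZF_BLOCK_SIZE)
    invisible(NULL)
  }
  w$tell <- function() voffsetPack(coffset, length(pending))
  w$close <- function() {
    if (length(pending) > 0) flush1(length(pending))
    done[[length(done) + 1L]] <- BGZF_EOF
    out <- do.call(c, done)
    if (!is.null(path)) {
      writeBin(out, path)
      invisible(NULL)
    } else out
  }
  w
}

#' Write data as a BGZF stream
#'
#' Chunks `data` into blocks of at most 65280 payload bytes and appends the
#' 28-byte EOF sentinel.
#'
#' @param data raw vector (or character, joined with newlines)
#' @param path output path, or NULL to return the stream as a raw vector
#' @param level DEFLATE level
#' @export
bgzfWriteStream <- function(data, path = NULL, level = 6L) {
  if (is.character(data))
    data <- charToRaw(paste0(paste(data, collapse = "\n"), "\n"))
  w <- bgzfWriter(path, level)
  w$append(data)
  w$close()
}

#' Check for the BGZF EOF sentinel
#' @param path file path
#' @return TRUE if the last 28 bytes equal the sentinel
#' @export
bgzfCheckEof <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 28) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, sz - 28)
  identical(readBin(con, "raw", 28), BGZF_EOF)
}
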