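# Byte-oriented rANS entropy coder, order 0 and order 1, of the family used
# for CRAM column compression: 12-bit normalized frequencies, four
# interleaved states, lower renormalization bound 2^23, byte-wise
# renormalization.  State arithmetic stays below 2^31 and is carried in
# doubles (exact), so the coder is deterministic and portable.
#
# Stream layout (self-contained; all integers little-endian):
#   byte 0      order (0 or 1)
#   bytes 1-4   n_in, the uncompressed length
#   frequency table:
#     order 0: one table (see below)
#     order 1: u16 number of contexts, then per context a context byte
#              followed by its table
#   payload: 4 x u32 final lane states, then the renormalization byte
#            stream in decode order
# A frequency table is serialized as a u16 run count followed by runs of
# consecutive present symbols: start byte, length byte, then that many
# frequencies, each either one byte (< 128) or two bytes (0x80|hi, lo).
# Symbols are assigned to the 4 lanes round-robin by position; order 1
# conditions each byte on its true predecessor (context 0 for the first).

RANS_TOTFREQ <- 4096       # 12-bit normalized frequencies
RANS_LOW <- 8388608        # 2^23 renormalization lower bound

#' Normalize symbol counts to a 12-bit frequency table
#'
#' Proportional scaling to a total of 4096 with largest-remainder
#' correction; every observed symbol keeps frequency >= 1.
#'
#' @param counts numeric vector of length 256 (counts per byte value), or a
#'   named vector of counts
#' @return list with `freq` (length-256 vector summing to 4096) and `cum`
#'   (exclusive cumulative frequencies)
#' @export
normalizeFreqs <- function(counts) {
  if (!is.null(names(counts)) && length(counts) != 256) {
    v <- numeric(256)
    v[vapply(names(counts), function(s) utf8ToInt(s), 0) + 1] <- counts
    counts <- v
  }
  stopifnot(length(counts) == 256)
  total <- sum(counts)
  if (total == 0) hts_stop("empty count vector", "rans_error")
  present <- counts > 0
  np <- sum(present)
  raw_f <- counts[present] * RANS_TOTFREQ / total
  f <- pmax(floor(raw_f), 1)
  excess <- sum(f) - RANS_TOTFREQ
  if (excess > 0) {
    # too many minimum-1 bumps: shave the largest frequencies
    for (k in order(f, decreasing = TRUE)) {
      cut <- min(excess, f[k] - 1)
      f[k] <- f[k] - cut
      excess <- excess - cut
      if (excess == 0) break
    }
  } else if (excess < 0) {
    rem <- raw_f - floor(raw_f)
    give <- order(rem, decreasing = TRUE)
    i <- 0
    while (excess < 0) {
      k <- give[(i %% np) + 1]
      f[k] <- f[k] + 1
      excess <- excess + 1
      i <- i + 1
    }
  }
  freq <- numeric(256)
  freq[present] <- f
  list(freq = freq, cum = cumsum(c(0, freq[-256])))
}

.freq_table_bytes <- function(freq) {
  present <- which(freq > 0) - 1L   # 0-based symbols
  runs <- split(present, cumsum(c(1, diff(present) != 1)))
  # run length is a single byte: split longer runs (256 symbols max anyway)
  runs <- do.call(c, lapply(runs, function(r)
    unname(split(r, (seq_along(r) - 1) %/% 255))))
  out <- list(uint16le(length(runs)))
  for (r in runs) {
    fr <- freq[r + 1]
    fb <- lapply(fr, function(x)
      if (x < 128) as.raw(x) else as.raw(c(128 + x %/% 256, x %% 256)))
    out[[length(out) + 1L]] <- c(uint8(r[1]), uint8(length(r)),
                                 do.call(c, fb))
  }
  do.call(c, out)
}

.freq_table_parse <- function(r, at) {
  n_runs <- rd_uint16(r, at); at <- at + 2
  freq <- numeric(256)
  for (k in seq_len(n_runs)) {
    start <- rd_uint8(r, at); len <- rd_uint8(r, at + 1); at <- at + 2
    for (j in seq_len(len)) {
      b <- rd_uint8(r, at)
      if (b < 128) { f <- b; at <- at + 1 }
      else { f <- (b - 128) * 256 + rd_uint8(r, at + 1); at <- at + 2 }
      freq[start + j] <- f
    }
  }
  if (sum(freq) != RANS_TOTFREQ)
    hts_stop("corrupt rANS frequency table", "rans_error")
  list(freq = freq, cum = cumsum(c(0, freq[-256])), at = at)
}

# encode one lane-interleaved symbol stream; syms 0-based, freq/cum from
# normalizeFreqs (per-symbol lookups prebuilt by caller); returns the
# renormalization bytes in DECODE order plus the 4 final states
.rans_core_encode <- function(fs, cs) {
  n <- length(fs)
  x <- rep(RANS_LOW, 4)
  buf <- numeric(2 * n + 64)   # renorm bytes, collected in encode order
  nb <- 0
  for (i in seq(n, 1L)) {      # encoder runs backwards
    lane <- ((i - 1) %% 4) + 1
    f <- fs[i]
    x_max <- 2048 * 256 * f    # ((2^23 >> 12) << 8) * f
    xi <- x[lane]
    while (xi >= x_max) {
      nb <- nb + 1
      buf[nb] <- xi %% 256
      xi <- xi %/% 256
    }
    x[lane] <- (xi %/% f) * RANS_TOTFREQ + cs[i] + (xi %% f)
  }
  list(states = x, bytes = if (nb > 0) as.raw(buf[nb:1]) else raw(0))
}

.rans_core_decode <- function(states, bytes, n, freq_of, sym_of, cum_of) {
  # freq_of/cum_of: per-context 256-vectors; sym_of: per-context 4096 lookup
  out <- integer(n)
  x <- states
  p <- 1
  nb <- length(bytes)
  ctx <- 1L
  for (i in seq_len(n)) {
    lane <- ((i - 1) %% 4) + 1
    m <- x[lane] %% RANS_TOTFREQ
    s <- sym_of[[ctx]][m + 1]
    out[i] <- s
    f <- freq_of[[ctx]][s + 1]
    xi <- f * (x[lane] %/% RANS_TOTFREQ) + m - cum_of[[ctx]][s + 1]
    while (xi < RANS_LOW) {
      if (p > nb) hts_stop("truncated rANS payload", "rans_error")
      xi <- xi * 256 + as.integer(bytes[p])
      p <- p + 1
    }
    x[lane] <- xi
    if (length(freq_of) > 1) ctx <- s + 1L
  }
  out
}

#' rANS encode / decode
#'
#' `ransEncode` compresses a raw vector with the order-0 (independent bytes)
#' or order-1 (conditioned on the previous byte) model; `ransDecode` is the
#' exact inverse and dispatches on the stored order flag.
#'
#' @param data raw vector (order 1 needs length >= 2 to be meaningful;
#'   shorter inputs fall back to order 0 internally)
#' @param order 0 or 1
#' @return raw vector
#' @export
ransEncode <- function(data, order = 0L) {
  stopifnot(is.raw(data))
  n <- length(data)
  if (n == 0) return(c(as.raw(order), uint32le(0)))
  syms <- as.integer(data)
  if (order == 0L || n < 2) {
    ft <- normalizeFreqs(tabulate(syms + 1L, nbins = 256))
    core <- .rans_core_encode(ft$freq[syms + 1], ft$cum[syms + 1])
    c(as.raw(order), uint32le(n), .freq_table_bytes(ft$freq),
      do.call(c, lapply(core$states, uint32le)), core$bytes)
  } else {
    prev <- c(0L, syms[-n])
    ctxs <- sort(unique(prev))
    fs <- numeric(n); cs <- numeric(n)
    tables <- list()
    for (cx in ctxs) {
      sel <- prev == cx
      ft <- normalizeFreqs(tabulate(syms[sel] + 1L, nbins = 256))
      tables[[as.character(cx)]] <- ft
      fs[sel] <- ft$freq[syms[sel] + 1]
      cs[sel] <- ft$cum[syms[sel] + 1]
    }
    core <- .rans_core_encode(fs, cs)
    tab_bytes <- do.call(c, lapply(ctxs, function(cx)
      c(uint8(cx), .freq_table_bytes(tables[[as.character(cx)]]$freq))))
    c(as.raw(1), uint32le(n), uint16le(length(ctxs)), tab_bytes,
      do.call(c, lapply(core$states, uint32le)), core$bytes)
  }
}

#' @rdname ransEncode
#' @param r raw vector produced by `ransEncode`
#' @export
ransDecode <- function(r) {
  if (length(r) < 5) hts_stop("truncated rANS header", "rans_error")
  order <- as.integer(r[1])
  n <- rd_uint32(r, 2)
  if (n == 0) return(raw(0))
  at <- 6
  sym_lookup <- function(freq) {
    s <- rep(0L, RANS_TOTFREQ)
    present <- which(freq > 0)
    cum <- cumsum(c(0, freq[-256]))
    for (k in present) s[(cum[k] + 1):(cum[k] + freq[k])] <- k - 1L
    s
  }
  if (order == 0L || n < 2) {
    ft <- .freq_table_parse(r, at); at <- ft$at
    freq_of <- list(ft$freq); cum_of <- list(ft$cum)
    sym_of <- list(sym_lookup(ft$freq))
  } else {
    n_ctx <- rd_uint16(r, at); at <- at + 2
    freq_of <- rep(list(numeric(256)), 256)
    cum_of <- rep(list(numeric(256)), 256)
    sym_of <- rep(list(integer(RANS_TOTFREQ)), 256)
    for (k in seq_len(n_ctx)) {
      cx <- rd_uint8(r, at); at <- at + 1
      ft <- .freq_table_parse(r, at); at <- ft$at
      freq_of[[cx + 1]] <- ft$freq
      cum_of[[cx + 1]] <- ft$cum
      sym_of[[cx + 1]] <- sym_lookup(ft$freq)
    }
  }
  if (at + 15 > length(r) + 1)
    hts_stop("truncated rANS payload", "rans_error")
  states <- rd_uint32v(r, at + 4 * (0:3))
  bytes <- if (at + 16 <= length(r)) r[(at + 16):length(r)] else raw(0)
  syms <- .rans_core_decode(states, bytes, n, freq_of, sym_of, cum_of)
  as.raw(syms)
}

#' Per-block codec selection by exhaustive size trial
#'
#' Encodes the block with every candidate codec and returns the smallest
#' result (ties resolved in candidate order), tagged with a one-byte codec
#' id so decoding can dispatch.  Candidates: "raw", "deflate" (gzip),
#' "rans0", "rans1".
#'
#' @param block raw vector
#' @param candidates subset of the codec names above
#' @return list with `codec`, `bytes` (id byte + encoded stream)
#' @export
codecSelect <- function(block,
                        candidates = c("raw", "deflate", "rans0", "rans1")) {
  ids <- c(raw = 0L, deflate = 1L, rans0 = 2L, rans1 = 3L)
  stopifnot(all(candidates %in% names(ids)))
  enc <- lapply(candidates, function(cd) switch(cd,
    raw = block,
    deflate = memCompress(block, "gzip"),
    rans0 = ransEncode(block, 0L),
    rans1 = ransEncode(block, 1L)))
  sizes <- lengths(enc)
  best <- which.min(sizes)   # first minimum = candidate order tie-break
  list(codec = candidates[best],
       bytes = c(as.raw(ids[[candidates[best]]]), enc[[best]]))
}

#' @rdname codecSelect
#' @param bytes output of `codecSelect`
#' @export
codecDecode <- function(bytes) {
  id <- as.integer(bytes[1])
  body <- bytes[-1]
  switch(as.character(id),
    "0" = body,
    "1" = memDecompress(body, "gzip"),
    "2" = ransDecode(body),
    "3" = ransDecode(body),
    hts_stop(sprintf("unknown codec id %d", id), "rans_error"))
}
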