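# BAM binary codec inside BGZF, plus content-based format detection.
# All on-disk integers are little-endian regardless of host.

BAM_MAGIC <- as.raw(c(0x42, 0x41, 0x4d, 0x01))  # "BAM\1"
SEQ_NIBBLE <- strsplit("=ACMGRSVTWYHKDBN", "")[[1]]
BAM_CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
BAM_POS_LIMIT <- 2147483648  # 2^31: the format's 2 Gb reference-length limit

.check_pos_limit <- function(x, what) {
  if (any(x >= BAM_POS_LIMIT, na.rm = TRUE))
    hts_stop(sprintf("%s exceeds format limit: BAM positions are 32-bit signed (max reference length 2 Gb)",
                     what), "bam_limit")
}

.seq_pack <- function(seq) {
  if (seq == "*") return(raw(0))
  codes <- match(strsplit(seq, "")[[1]], SEQ_NIBBLE)
  codes[is.na(codes)] <- 16L   # unknown bases encode as N
  codes <- codes - 1L
  n <- length(codes)
  if (n %% 2 == 1) codes <- c(codes, 0L)  # pad low nibble of last byte
  hi <- codes[seq(1, length(codes), 2)]
  lo <- codes[seq(2, length(codes), 2)]
  as.raw(hi * 16L + lo)
}

.seq_unpack <- function(r, n) {
  if (n == 0) return("*")
  b <- as.integer(r)
  codes <- c(rbind(b %/% 16L, b %% 16L))[seq_len(n)]
  paste(SEQ_NIBBLE[codes + 1L], collapse = "")
}

.tag_bytes <- function(t) {
  tagb <- charToRaw(t$tag)
  if (t$type == "i") {
    v <- t$value
    if (v >= -128 && v <= 127)      c(tagb, charToRaw("c"), as.raw(v %% 256))
    else if (v >= 0 && v <= 255)    c(tagb, charToRaw("C"), uint8(v))
    else if (v >= -32768 && v <= 32767) c(tagb, charToRaw("s"), uint16le(v %% 65536))
    else if (v >= 0 && v <= 65535)  c(tagb, charToRaw("S"), uint16le(v))
    else if (v >= -BAM_POS_LIMIT && v < BAM_POS_LIMIT) c(tagb, charToRaw("i"), int32le(v))
    else c(tagb, charToRaw("I"), uint32le(v))
  } else switch(t$type,
    A = c(tagb, charToRaw("A"), charToRaw(t$value)),
    f = c(tagb, charToRaw("f"), float32le(t$value)),
    Z = c(tagb, charToRaw("Z"), charToRaw(t$value), as.raw(0)),
    H = c(tagb, charToRaw("H"), charToRaw(t$value), as.raw(0)),
    B = {
      sub <- t$value$subtype
      vals <- t$value$values
      packed <- switch(sub,
        c = as.raw(vals %% 256), C = as.raw(vals),
        s = do.call(c, lapply(vals %% 65536, uint16le)),
        S = do.call(c, lapply(vals, uint16le)),
        i = do.call(c, lapply(vals, int32le)),
        I = do.call(c, lapply(vals, uint32le)),
        f = float32le(vals),
        hts_stop(sprintf("unknown B-array subtype '%s'", sub), "bam_codec"))
      c(tagb, charToRaw("B"), charToRaw(sub), uint32le(length(vals)), packed)
    },
    hts_stop(sprintf("unknown tag type '%s'", t$type), "bam_codec"))
}

#' Encode an alignment record as BAM bytes
#'
#' Serializes one record in the standard BAM layout (including the leading
#' 32-bit block size).  The bin field is always recomputed from the record's
#' reference span, never trusted from input.  Positions at or beyond 2^31 are
#' a hard error: the format stores signed 32-bit coordinates, limiting
#' references to 2 Gb.
#'
#' @param rec a record from [samRecord()]
#' @return raw vector
#' @export
encodeBamRecord <- function(rec) {
  validateRecord(rec)
  end_pos <- recordEndPos(rec)
  .check_pos_limit(c(rec$pos, end_pos, rec$mate_pos), sprintf("read %s", rec$qname))
  if (length(rec$cigar$op) > 65535)
    hts_stop(sprintf("read %s: %d CIGAR operations exceed the 16-bit field",
                     rec$qname, length(rec$cigar$op)), "bam_limit")
  l_seq <- if (rec$seq == "*") 0L else nchar(rec$seq)
  # the 16-bit bin field is defined for the fixed (14,5) scheme only; spans
  # beyond its 512 Mb limit store 0 (readers rely on the index, not the bin)
  bin <- if (rec$pos < 0) 4680
    else if (max(end_pos, rec$pos + 1) > 2^29) 0
    else reg2bin(rec$pos, max(end_pos, rec$pos + 1))
  cigar_words <- if (length(rec$cigar$op) == 0) raw(0) else
    do.call(c, lapply(seq_along(rec$cigar$op), function(i)
      uint32le(rec$cigar$len[i] * 16 +
               (match(rec$cigar$op[i], BAM_CIGAR_OPS) - 1))))
  qual_bytes <- if (l_seq == 0) raw(0)
    else if (is.null(rec$qual)) rep(as.raw(0xff), l_seq)
    else as.raw(rec$qual)
  body <- c(
    int32le(rec$ref_id), int32le(rec$pos),
    uint8(nchar(rec$qname) + 1L), uint8(rec$mapq), uint16le(bin),
    uint16le(length(rec$cigar$op)), uint16le(rec$flag), uint32le(l_seq),
    int32le(rec$mate_ref_id), int32le(rec$mate_pos), int32le(rec$tlen),
    charToRaw(rec$qname), as.raw(0),
    cigar_words, .seq_pack(rec$seq), qual_bytes,
    if (length(rec$tags)) do.call(c, lapply(rec$tags, .tag_bytes)) else raw(0))
  c(uint32le(length(body)), body)
}

.decode_tags <- function(r, at, stop_at) {
  tags <- list()
  while (at < stop_at) {
    if (at + 2 > stop_at)
      hts_stop("truncated tag block in BAM record", "bam_corrupt")
    tag <- rawToChar(r[at:(at + 1)])
    type <- rawToChar(r[at + 2])
    at <- at + 3
    t <- switch(type,
      A = { v <- list(tag = tag, type = "A", value = rawToChar(r[at])); at <- at + 1; v },
      c = { v <- rd_uint8(r, at); if (v > 127) v <- v - 256
            at <- at + 1; list(tag = tag, type = "i", value = as.numeric(v)) },
      C = { v <- rd_uint8(r, at); at <- at + 1
            list(tag = tag, type = "i", value = as.numeric(v)) },
      s = { v <- rd_uint16(r, at); if (v > 32767) v <- v - 65536
            at <- at + 2; list(tag = tag, type = "i", value = as.numeric(v)) },
      S = { v <- rd_uint16(r, at); at <- at + 2
            list(tag = tag, type = "i", value = as.numeric(v)) },
      i = { v <- rd_int32(r, at); at <- at + 4; list(tag = tag, type = "i", value = v) },
      I = { v <- rd_uint32(r, at); at <- at + 4; list(tag = tag, type = "i", value = v) },
      f = { v <- rd_float32(r, at); at <- at + 4; list(tag = tag, type = "f", value = v) },
      Z = { s <- rd_cstring(r, at); at <- at + s$nbytes
            list(tag = tag, type = "Z", value = s$str) },
      H = { s <- rd_cstring(r, at); at <- at + s$nbytes
            list(tag = tag, type = "H", value = s$str) },
      B = {
        sub <- rawToChar(r[at]); n <- rd_uint32(r, at + 1); at <- at + 5
        w <- c(c = 1, C = 1, s = 2, S = 2, i = 4, I = 4, f = 4)[[sub]]
        vals <- numeric(n)
        for (k in seq_len(n)) {
          vals[k] <- switch(sub,
            c = { v <- rd_uint8(r, at); if (v > 127) v - 256 else v },
            C = rd_uint8(r, at),
            s = { v <- rd_uint16(r, at); if (v > 32767) v - 65536 else v },
            S = rd_uint16(r, at),
            i = rd_int32(r, at), I = rd_uint32(r, at), f = rd_float32(r, at))
          at <- at + w
        }
        list(tag = tag, type = "B", value = list(subtype = sub, values = vals))
      },
      hts_stop(sprintf("unknown BAM tag type byte '%s'", type), "bam_corrupt"))
    tags[[length(tags) + 1L]] <- t
  }
  if (at != stop_at)
    hts_stop("BAM record tag block overruns record size", "bam_corrupt")
  tags
}

#' Decode one BAM record
#'
#' Inverse of [encodeBamRecord()].  `r` must start (at offset `at`) with the
#' record's 32-bit block size.  When `validate` is TRUE the stored bin field
#' is checked against the recomputed one.
#'
#' @param r raw vector
#' @param at 1-based offset of the record start
#' @param validate check stored bin vs recomputed bin
#' @return list with `rec` and `nbytes` consumed (block size + 4)
#' @export
decodeBamRecord <- function(r, at = 1L, validate = FALSE) {
  if (at + 3 > length(r))
    hts_stop("truncated BAM record (no block size)", "bam_corrupt")
  block_size <- rd_uint32(r, at)
  if (at + 3 + block_size > length(r))
    hts_stop("truncated BAM record", "bam_corrupt")
  if (block_size < 32)
    hts_stop("BAM record block size inconsistent with fixed fields",
             "bam_corrupt")
  p <- at + 4
  ref_id <- rd_int32(r, p); pos <- rd_int32(r, p + 4)
  l_read_name <- rd_uint8(r, p + 8); mapq <- rd_uint8(r, p + 9)
  bin <- rd_uint16(r, p + 10); n_cigar <- rd_uint16(r, p + 12)
  flag <- rd_uint16(r, p + 14); l_seq <- rd_uint32(r, p + 16)
  mate_ref_id <- rd_int32(r, p + 20); mate_pos <- rd_int32(r, p + 24)
  tlen <- rd_int32(r, p + 28)
  q <- p + 32
  need <- 32 + l_read_name + 4 * n_cigar + ((l_seq + 1) %/% 2) + l_seq
  if (block_size < need)
    hts_stop("BAM record block size inconsistent with contents", "bam_corrupt")
  qname <- rawToChar(rawslice(r, q, l_read_name - 1))
  q <- q + l_read_name
  cigar <- if (n_cigar == 0) list(op = character(0), len = numeric(0)) else {
    words <- rd_uint32v(r, q + 4 * (seq_len(n_cigar) - 1))
    list(op = BAM_CIGAR_OPS[(words %% 16) + 1], len = words %/% 16)
  }
  q <- q + 4 * n_cigar
  nseq_bytes <- (l_seq + 1) %/% 2
  seq <- .seq_unpack(rawslice(r, q, nseq_bytes), l_seq)
  q <- q + nseq_bytes
  qual <- if (l_seq == 0) NULL else {
    qb <- as.integer(rawslice(r, q, l_seq))
    if (all(qb == 255L)) NULL else qb
  }
  q <- q + l_seq
  tags <- .decode_tags(r, q, at + 4 + block_size)
  rec <- samRecord(qname = qname, flag = flag, ref_id = ref_id, pos = pos,
                   mapq = mapq, cigar = cigar, mate_ref_id = mate_ref_id,
                   mate_pos = mate_pos, tlen = tlen, seq = seq, qual = qual,
                   tags = tags)
  if (validate) {
    want <- if (pos < 0) 4680
      else if (max(recordEndPos(rec), pos + 1) > 2^29) 0
      else reg2bin(pos, max(recordEndPos(rec), pos + 1))
    if (bin != want)
      hts_stop(sprintf("read %s: stored bin %d != recomputed %d", qname, bin,
                       want), "bam_corrupt")
  }
  list(rec = rec, nbytes = block_size + 4)
}

#' Detect file format by content
#'
#' Inspects leading bytes: BGZF is recognized via the gzip magic plus `BC`
#' extra subfield and its first block re-sniffed (`BAM\1` payload = "BAM");
#' leading `@` header lines or >= 11 tab-separated columns = "SAM"; `>` =
#' "FASTA"; other tab-bearing text = "tab-text".
#'
#' @param x path or raw vector
#' @return one of "BAM", "SAM", "BGZF-other", "plain-gzip", "FASTA",
#'   "tab-text", "unknown"
#' @export
sniffFormat <- function(x) {
  r <- if (is.raw(x)) x else readBin(x, "raw", n = min(file.size(x), 65536))
  if (length(r) == 0) return("unknown")
  if (length(r) >= 2 && r[1] == as.raw(0x1f) && r[2] == as.raw(0x8b)) {
    info <- tryCatch(.bgzf_member_info(r, 1L), htslite_error = function(e) e)
    if (inherits(info, "condition")) return("plain-gzip")
    payload <- tryCatch(bgzfDecompressBlock(r, 1L)$payload,
                        error = function(e) raw(0))
    if (length(payload) >= 4 && identical(payload[1:4], BAM_MAGIC))
      return("BAM")
    return("BGZF-other")
  }
  txt <- tryCatch(rawToChar(r), error = function(e) NULL)
  if (is.null(txt)) return("unknown")
  first <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(first) == 0) return("unknown")
  if (startsWith(first[1], ">")) return("FASTA")
  ncols <- length(strsplit(first[1], "\t", fixed = TRUE)[[1]])
  if (startsWith(first[1], "@") && ncols >= 2) return("SAM")
  if (ncols >= 11) return("SAM")
  if (ncols >= 2) return("tab-text")
  "unknown"
}

#' BAM file handle
#'
#' Open handle pairing a [BgzfFile-class] with the parsed header and the
#' virtual offset of the first alignment record.
#'
#' @slot bgzf the underlying BGZF stream
#' @slot header the [SamHeader-class]
#' @slot data_voffset virtual offset where alignment records begin
#' @export
setClass("BamFile", representation(bgzf = "BgzfFile", header = "SamHeader",
                                   data_voffset = "numeric"))

setMethod("show", "BamFile", function(object) {
  cat(sprintf("BamFile: %s\n  %d reference(s)\n",
              if (nzchar(object@bgzf@path)) object@bgzf@path else "<memory>",
              nrow(object@header@refs)))
})

#' Open a BAM file (header only)
#'
#' Parses the BGZF-wrapped BAM header and reference dictionary, leaving the
#' cursor at the first alignment record.  The binary reference dictionary is
#' authoritative for the ref-id mapping; `@SQ` text lines are kept verbatim
#' when present and synthesized when absent.
#'
#' @param x path to a BAM file or raw vector of its bytes
#' @return a [BamFile-class]
#' @export
bamOpen <- function(x) {
  bf <- bgzfOpen(x)
  magic <- bgzfRead(bf, 4)
  if (!identical(magic, BAM_MAGIC))
    hts_stop("not a BAM file (bad magic)", "bam_corrupt")
  l_text <- rd_uint32(bgzfRead(bf, 4), 1)
  traw <- bgzfRead(bf, l_text)
  traw <- traw[traw != as.raw(0)]   # text block may be NUL-padded
  text <- rawToChar(traw)
  n_ref <- rd_uint32(bgzfRead(bf, 4), 1)
  names <- character(n_ref); lens <- numeric(n_ref)
  for (i in seq_len(n_ref)) {
    l_name <- rd_uint32(bgzfRead(bf, 4), 1)
    names[i] <- rawToChar(bgzfRead(bf, l_name)[seq_len(l_name - 1)])
    lens[i] <- rd_uint32(bgzfRead(bf, 4), 1)
  }
  header <- headerParse(text)
  refs <- data.frame(name = names, length = lens, stringsAsFactors = FALSE)
  if (nrow(header@refs) == 0 && n_ref > 0) {
    sq <- sprintf("@SQ\tSN:%s\tLN:%.0f", names, lens)
    header <- new("SamHeader", lines = c(header@lines, sq), refs = refs)
  } else {
    header <- new("SamHeader", lines = header@lines, refs = refs)
  }
  new("BamFile", bgzf = bf, header = header, data_voffset = bgzfTell(bf))
}

# scan records sequentially from voffset `from` while `while_lt` (exclusive
# voffset bound) is not reached; returns records with their spans and anchors
.bam_scan <- function(bam, from = bam@data_voffset, while_lt = Inf) {
  bf <- bam@bgzf
  bgzfSeek(bf, from)
  records <- list(); vbeg <- numeric(0); vend <- numeric(0)
  repeat {
    v0 <- bgzfTell(bf)
    if (v0 >= while_lt) break
    szb <- bgzfRead(bf, 4)
    if (length(szb) < 4) break
    block_size <- rd_uint32(szb, 1)
    body <- bgzfRead(bf, block_size)
    if (length(body) < block_size)
      hts_stop("truncated BAM record at end of file", "bam_corrupt")
    dec <- decodeBamRecord(c(szb, body), 1L)
    records[[length(records) + 1L]] <- dec$rec
    vbeg <- c(vbeg, v0); vend <- c(vend, bgzfTell(bf))
  }
  list(records = records, vbeg = vbeg, vend = vend)
}

#' Read a whole BAM file
#'
#' @param x path or raw vector
#' @return list with `header`, `records`, and per-record virtual-offset
#'   anchors `vbeg`/`vend`
#' @export
readBam <- function(x) {
  bam <- bamOpen(x)
  sc <- .bam_scan(bam)
  list(header = bam@header, records = sc$records, vbeg = sc$vbeg,
       vend = sc$vend, bam = bam)
}

# coordinate-sort check shared by the writer and the index builder
.check_sorted <- function(ref_ids, poss, qnames) {
  n <- length(ref_ids)
  if (n < 2) return(invisible(TRUE))
  key_ref <- ifelse(ref_ids < 0, .Machine$integer.max, ref_ids)
  bad <- which(diff(key_ref) < 0 |
               (diff(key_ref) == 0 & diff(poss) < 0))
  if (length(bad) > 0)
    hts_stop(sprintf("not coordinate sorted: read %s (record %d) out of order",
                     qnames[bad[1] + 1], bad[1] + 1), "not_sorted")
  invisible(TRUE)
}

#' Write a BAM file
#'
#' Serializes header and records into BGZF.  With `index = TRUE` the records
#' must arrive coordinate-sorted and the corresponding index is built from
#' the writer's own virtual offsets while writing, which by construction
#' equals the index built post hoc from the finished file.
#'
#' @param header a [SamHeader-class]
#' @param records list of records
#' @param path output path, or NULL for an in-memory stream
#' @param index build an index while writing
#' @param csi build a CSI (14,5) instead of a BAI index
#' @param level DEFLATE level
#' @return list with `bytes` (NULL when written to `path`) and `index` (an
#'   [HtsIndex-class] or NULL)
#' @export
writeBam <- function(header, records, path = NULL, index = FALSE,
                     csi = FALSE, level = 6L) {
  w <- bgzfWriter(NULL, level)
  text <- headerFormat(header)
  w$append(BAM_MAGIC)
  w$append(uint32le(nchar(text)))
  w$append(charToRaw(text))
  w$append(uint32le(nrow(header@refs)))
  for (i in seq_len(nrow(header@refs))) {
    nm <- header@refs$name[i]
    w$append(uint32le(nchar(nm) + 1))
    w$append(c(charToRaw(nm), as.raw(0)))
    w$append(uint32le(header@refs$length[i]))
  }
  if (index) {
    ref_ids <- vapply(records, `[[`, 0L, "ref_id")
    poss <- vapply(records, `[[`, 0, "pos")
    qnames <- vapply(records, `[[`, "", "qname")
    .check_sorted(ref_ids, poss, qnames)
  }
  vbeg <- numeric(length(records)); vend <- numeric(length(records))
  for (i in seq_along(records)) {
    vbeg[i] <- w$tell()
    w$append(encodeBamRecord(records[[i]]))
    vend[i] <- w$tell()
  }
  bytes <- w$close()
  if (!is.null(path)) writeBin(bytes, path)
  idx <- NULL
  if (index) {
    scheme <- if (csi) binningScheme(14L, 5L) else binningScheme(14L, 5L)
    idx <- indexBuild(records, vbeg, vend, n_ref = nrow(header@refs),
                      scheme = scheme,
                      ref_lengths = header@refs$length, csi = csi)
  }
  invisible(list(bytes = if (is.null(path)) bytes else NULL, index = idx))
}
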