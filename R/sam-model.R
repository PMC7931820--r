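# SAM data model: header, alignment records, CIGAR algebra, text dialect.
#
# Internal coordinates are 0-based half-open everywhere; the 1-based SAM
# convention is converted exactly once, at the text boundary.  Sentinels: an
# unmapped/absent reference is ref_id -1, an absent position is pos -1.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
CIGAR_CONSUMES_QUERY <- c(M = TRUE, I = TRUE, D = FALSE, N = FALSE, S = TRUE,
                          H = FALSE, P = FALSE, `=` = TRUE, X = TRUE)
CIGAR_CONSUMES_REF <- c(M = TRUE, I = FALSE, D = TRUE, N = TRUE, S = FALSE,
                        H = FALSE, P = FALSE, `=` = TRUE, X = TRUE)

FLAG_PAIRED <- 0x1; FLAG_UNMAP <- 0x4; FLAG_REVERSE <- 0x10
FLAG_SECONDARY <- 0x100; FLAG_QCFAIL <- 0x200; FLAG_DUP <- 0x400
FLAG_SUPPLEMENTARY <- 0x800

#' SAM header
#'
#' Ordered header lines (`@HD`, `@SQ`, `@RG`, `@PG`, `@CO`) kept verbatim for
#' lossless round-tripping, plus the reference dictionary (name, length in
#' declaration order) derived from the `@SQ` lines.
#'
#' @slot lines character vector of header lines, each starting with `@`
#' @slot refs data.frame with columns `name`, `length`
#' @export
setClass("SamHeader", representation(lines = "character", refs = "data.frame"))

setValidity("SamHeader", function(object) {
  if (anyDuplicated(object@refs$name))
    return("duplicate @SQ sequence names in header")
  TRUE
})

setMethod("show", "SamHeader", function(object) {
  cat(sprintf("SamHeader: %d line(s), %d reference(s)\n",
              length(object@lines), nrow(object@refs)))
  if (nrow(object@refs) > 0)
    cat(sprintf("  %s:%.0f\n", utils::head(object@refs$name, 3),
                utils::head(object@refs$length, 3)), sep = "")
})

.header_tag_value <- function(line, tag) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]][-1]
  hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
  if (length(hit) == 0) NA_character_ else sub("^..:", "", hit[1])
}

.refs_from_lines <- function(lines) {
  sq <- grep("^@SQ\t", lines, value = TRUE)
  if (length(sq) == 0)
    return(data.frame(name = character(0), length = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(
    name = vapply(sq, .header_tag_value, "", tag = "SN", USE.NAMES = FALSE),
    length = as.numeric(vapply(sq, .header_tag_value, "", tag = "LN",
                               USE.NAMES = FALSE)),
    stringsAsFactors = FALSE)
}

#' Parse and format SAM headers
#'
#' `headerParse` builds a [SamHeader-class] from header text (one string or a
#' vector of lines); `headerFormat` is its inverse and preserves unknown tags
#' and line order byte-for-byte.
#'
#' @param text header text: single string with embedded newlines, or a
#'   character vector of lines
#' @param header a [SamHeader-class]
#' @export
headerParse <- function(text) {
  lines <- if (length(text) == 1 && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && !all(startsWith(lines, "@")))
    hts_stop("header lines must start with '@'", "sam_parse")
  new("SamHeader", lines = lines, refs = .refs_from_lines(lines))
}

#' @rdname headerParse
#' @export
headerFormat <- function(header) {
  if (length(header@lines) == 0) return("")
  paste0(paste(header@lines, collapse = "\n"), "\n")
}

#' Reference dictionary accessors
#' @param header a [SamHeader-class]
#' @export
headerRefs <- function(header) header@refs

#' @rdname headerRefs
#' @param name reference name
#' @export
headerRefId <- function(header, name) {
  if (identical(name, "*")) return(-1L)
  i <- match(name, header@refs$name)
  if (is.na(i))
    hts_stop(sprintf("reference '%s' absent from header dictionary", name),
             "sam_parse")
  i - 1L
}

#' Localized header editing
#'
#' `headerUpdateTag` rewrites (or appends) one `TAG:value` field on the first
#' header line of `type` (optionally the `nth` such line), leaving every other
#' line byte-identical.  `headerAddLine` appends a line (duplicate `@SQ` SN is
#' an error); `headerRemoveLine` removes the first line equal to `line`
#' (missing line: no-op with a message).
#'
#' @param header a [SamHeader-class]
#' @param type two-letter line type, e.g. "HD"
#' @param tag two-letter tag
#' @param value replacement value
#' @param nth which line of that type to edit (default first)
#' @param line full header line text
#' @export
headerUpdateTag <- function(header, type, tag, value, nth = 1L) {
  idx <- grep(paste0("^@", type, "(\t|$)"), header@lines)
  if (length(idx) < nth)
    hts_stop(sprintf("no @%s line #%d in header", type, nth), "sam_parse")
  i <- idx[nth]
  fields <- strsplit(header@lines[i], "\t", fixed = TRUE)[[1]]
  hit <- grep(paste0("^", tag, ":"), fields[-1])
  if (length(hit) > 0) {
    fields[hit[1] + 1] <- paste0(tag, ":", value)
  } else {
    fields <- c(fields, paste0(tag, ":", value))
  }
  lines <- header@lines
  lines[i] <- paste(fields, collapse = "\t")
  new("SamHeader", lines = lines, refs = .refs_from_lines(lines))
}

#' @rdname headerUpdateTag
#' @export
headerAddLine <- function(header, line) {
  if (!startsWith(line, "@"))
    hts_stop("header lines must start with '@'", "sam_parse")
  if (startsWith(line, "@SQ")) {
    sn <- .header_tag_value(line, "SN")
    if (!is.na(sn) && sn %in% header@refs$name)
      hts_stop(sprintf("duplicate @SQ SN:%s", sn), "sam_parse")
  }
  lines <- c(header@lines, line)
  new("SamHeader", lines = lines, refs = .refs_from_lines(lines))
}

#' @rdname headerUpdateTag
#' @export
headerRemoveLine <- function(header, line) {
  i <- match(line, header@lines)
  if (is.na(i)) {
    message("headerRemoveLine: no such line; header unchanged")
    return(header)
  }
  lines <- header@lines[-i]
  new("SamHeader", lines = lines, refs = .refs_from_lines(lines))
}

# ---------------------------------------------------------------- CIGAR ----

#' CIGAR algebra
#'
#' A CIGAR is stored as parallel vectors of operators and lengths.
#' `cigarParse`/`cigarFormat` convert to and from text ("*" = empty);
#' `cigarSpans` returns the query-consuming (M/I/S/=/X) and
#' reference-consuming (M/D/N/=/X) lengths.
#'
#' @param text CIGAR string
#' @param cigar list with `op` (character) and `len` (numeric)
#' @return `cigarSpans`: list with `qlen` and `rlen`
#' @examples
#' cigarSpans(cigarParse("8M2I4M1D3M"))  # qlen 17, rlen 16
#' @export
cigarParse <- function(text) {
  if (identical(text, "*") || !nzchar(text))
    return(list(op = character(0), len = numeric(0)))
  m <- gregexpr("[0-9]+[MIDNSHP=X]", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    hts_stop(sprintf("malformed CIGAR '%s'", text), "sam_parse")
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.numeric(substring(toks, 1, nchar(toks) - 1)))
}

#' @rdname cigarParse
#' @export
cigarFormat <- function(cigar) {
  if (length(cigar$op) == 0) return("*")
  paste0(format(cigar$len, scientific = FALSE, trim = TRUE), cigar$op,
         collapse = "")
}

#' @rdname cigarParse
#' @export
cigarSpans <- function(cigar) {
  list(qlen = sum(cigar$len[CIGAR_CONSUMES_QUERY[cigar$op]]),
       rlen = sum(cigar$len[CIGAR_CONSUMES_REF[cigar$op]]))
}

# -------------------------------------------------------------- records ----

#' Construct an alignment record
#'
#' Plain-list record with the 11 mandatory SAM fields plus typed optional
#' tags.  Coordinates are 0-based half-open; `pos = -1` and `ref_id = -1`
#' are the "absent" sentinels ('*' / 0 in SAM text).
#'
#' @param qname read name (no tab, <= 254 bytes)
#' @param flag 16-bit SAM flag
#' @param ref_id 0-based index into the header reference dictionary, -1 if
#'   unmapped
#' @param pos 0-based leftmost reference position, -1 if absent
#' @param mapq mapping quality 0-255
#' @param cigar list(op=, len=) as from [cigarParse()]
#' @param mate_ref_id,mate_pos,tlen mate fields
#' @param seq base string over `=ACMGRSVTWYHKDBN` or "*"
#' @param qual integer phred vector, or NULL when absent ('*')
#' @param tags ordered list of `list(tag=, type=, value=)`; integer tags use
#'   type "i", arrays type "B" with `value = list(subtype=, values=)`
#' @export
samRecord <- function(qname = "r", flag = 0L, ref_id = -1L, pos = -1,
                      mapq = 0L, cigar = list(op = character(0), len = numeric(0)),
                      mate_ref_id = -1L, mate_pos = -1, tlen = 0,
                      seq = "*", qual = NULL, tags = list()) {
  cigar$len <- as.numeric(cigar$len)
  if (!is.null(qual)) qual <- as.integer(qual)
  list(qname = qname, flag = as.integer(flag), ref_id = as.integer(ref_id),
       pos = as.numeric(pos), mapq = as.integer(mapq), cigar = cigar,
       mate_ref_id = as.integer(mate_ref_id), mate_pos = as.numeric(mate_pos),
       tlen = as.numeric(tlen), seq = seq, qual = qual, tags = tags)
}

#' Validate record invariants
#' @param rec a record from [samRecord()]
#' @return invisibly TRUE; errors on violation
#' @export
validateRecord <- function(rec) {
  if (grepl("\t", rec$qname, fixed = TRUE) || nchar(rec$qname) > 254)
    hts_stop("invalid read name", "sam_invalid")
  if (rec$seq != "*" && length(rec$cigar$op) > 0) {
    if (cigarSpans(rec$cigar)$qlen != nchar(rec$seq))
      hts_stop(sprintf(
        "read %s: CIGAR query length %d != sequence length %d", rec$qname,
        cigarSpans(rec$cigar)$qlen, nchar(rec$seq)), "sam_invalid")
  }
  if (!is.null(rec$qual) && rec$seq != "*" &&
      length(rec$qual) != nchar(rec$seq))
    hts_stop(sprintf("read %s: quality length != sequence length", rec$qname),
             "sam_invalid")
  invisible(TRUE)
}

#' Reference span end of a record
#'
#' 0-based half-open end position (`pos` + reference-consuming CIGAR length).
#' @param rec a record
#' @export
recordEndPos <- function(rec) rec$pos + cigarSpans(rec$cigar)$rlen

.parse_tag_field <- function(field, colno) {
  parts <- strsplit(field, ":", fixed = TRUE)[[1]]
  if (length(parts) < 3 || nchar(parts[1]) != 2)
    hts_stop(sprintf("malformed optional tag in column %d: '%s'", colno, field),
             "sam_parse")
  tag <- parts[1]; type <- parts[2]
  valtxt <- paste(parts[-(1:2)], collapse = ":")
  value <- switch(type,
    A = valtxt,
    i = suppressWarnings(as.numeric(valtxt)),
    # float tags are binary32 on disk; snap at parse time so text round
    # trips are exact for canonically formatted input
    f = suppressWarnings(float32snap(as.numeric(valtxt))),
    Z = valtxt,
    H = valtxt,
    B = {
      items <- strsplit(valtxt, ",", fixed = TRUE)[[1]]
      vals <- suppressWarnings(as.numeric(items[-1]))
      if (items[1] == "f") vals <- float32snap(vals)
      list(subtype = items[1], values = vals)
    },
    hts_stop(sprintf("unknown tag type '%s' in column %d", type, colno),
             "sam_parse"))
  if (type %in% c("i", "f") && is.na(value))
    hts_stop(sprintf("non-numeric value for %s tag in column %d", type, colno),
             "sam_parse")
  list(tag = tag, type = type, value = value)
}

.format_tag_field <- function(t) {
  val <- switch(t$type,
    A = t$value,
    i = sprintf("%.0f", t$value),
    f = sprintf("%.9g", t$value),
    Z = t$value,
    H = t$value,
    B = paste(c(t$value$subtype,
                if (t$value$subtype == "f") sprintf("%.9g", t$value$values)
                else sprintf("%.0f", t$value$values)), collapse = ","))
  paste(t$tag, t$type, val, sep = ":")
}

#' Parse one SAM alignment line
#'
#' Converts the 1-based SAM POS to the internal 0-based convention, maps '*'
#' fields to sentinels, uppercases the sequence, and decodes optional tags by
#' type code.
#'
#' @param line one SAM line (no trailing newline)
#' @param header a [SamHeader-class]; RNAME/RNEXT must resolve in its
#'   dictionary
#' @export
parseSamRecord <- function(line, header) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11)
    hts_stop(sprintf("SAM record has %d column(s); 11 required", length(f)),
             "sam_parse")
  flag <- suppressWarnings(as.integer(f[2]))
  pos1 <- suppressWarnings(as.numeric(f[4]))
  if (is.na(flag) || is.na(pos1))
    hts_stop("non-numeric FLAG or POS column", "sam_parse")
  ref_id <- headerRefId(header, f[3])
  mate_ref_id <- if (f[7] == "=") ref_id else headerRefId(header, f[7])
  seq <- if (f[10] == "*") "*" else toupper(f[10])
  qual <- if (f[11] == "*") NULL else as.integer(utf8ToInt(f[11])) - 33L
  tags <- if (length(f) > 11)
    lapply(seq_along(f)[-(1:11)], function(i) .parse_tag_field(f[i], i))
  else list()
  rec <- samRecord(
    qname = f[1], flag = flag, ref_id = ref_id, pos = pos1 - 1,
    mapq = as.integer(f[5]), cigar = cigarParse(f[6]),
    mate_ref_id = mate_ref_id, mate_pos = suppressWarnings(as.numeric(f[8])) - 1,
    tlen = as.numeric(f[9]), seq = seq, qual = qual, tags = tags)
  validateRecord(rec)
  rec
}

#' Format one record as a SAM line
#'
#' Canonical inverse of [parseSamRecord()]: re-parsing the output reproduces
#' the record.
#'
#' @param rec a record
#' @param header a [SamHeader-class]
#' @export
formatSamRecord <- function(rec, header) {
  validateRecord(rec)
  refname <- function(id) if (id < 0) "*" else header@refs$name[id + 1]
  rnext <- if (rec$mate_ref_id >= 0 && rec$mate_ref_id == rec$ref_id)
    "=" else refname(rec$mate_ref_id)
  qualtxt <- if (is.null(rec$qual)) "*" else
    intToUtf8(rec$qual + 33L, multiple = FALSE)
  cols <- c(rec$qname, rec$flag, refname(rec$ref_id),
            sprintf("%.0f", rec$pos + 1), rec$mapq, cigarFormat(rec$cigar),
            rnext, sprintf("%.0f", rec$mate_pos + 1),
            sprintf("%.0f", rec$tlen), rec$seq, qualtxt,
            vapply(rec$tags, .format_tag_field, ""))
  paste(cols, collapse = "\t")
}

#' Read and write SAM text files
#'
#' `readSam` accepts a path or a character vector of lines and returns
#' `list(header=, records=)`; `writeSam` is its inverse (returns the lines
#' when `path` is NULL).
#'
#' @param x path to a SAM file, or character vector of SAM lines
#' @export
readSam <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  is_h <- startsWith(lines, "@")
  header <- headerParse(lines[is_h])
  records <- lapply(lines[!is_h & nzchar(lines)], parseSamRecord,
                    header = header)
  list(header = header, records = records)
}

#' @rdname readSam
#' @param header a [SamHeader-class]
#' @param records list of records
#' @param path output path or NULL
#' @export
writeSam <- function(header, records, path = NULL) {
  lines <- c(header@lines,
             vapply(records, formatSamRecord, "", header = header))
  if (is.null(path)) lines else writeLines(lines, path)
}
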