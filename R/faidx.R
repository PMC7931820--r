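# FASTA indexing (FAI) and random subsequence fetch.
#
# A FAI record stores (name, length, byte offset of first base, bases per
# line, bytes per line including terminator); the offset arithmetic then
# turns any [beg, end) base range into a byte range.  BGZF-compressed FASTA
# is supported by layering the same offsets over the BGZF logical stream.

# open a FASTA source with random byte access over its (logical) bytes
.fasta_source <- function(path) {
  r <- readBin(path, "raw", n = min(file.size(path), 4L))
  if (length(r) >= 2 && r[1] == as.raw(0x1f) && r[2] == as.raw(0x8b)) {
    bf <- bgzfOpen(path)
    list(type = "bgzf", bf = bf, size = bgzfUncompressedSize(bf), path = path)
  } else {
    list(type = "file", size = file.size(path), path = path)
  }
}

.fasta_bytes <- function(src, from, n) {
  # `from` 0-based logical byte offset
  if (n <= 0) return(raw(0))
  if (src$type == "bgzf") {
    bgzfReadAt(src$bf, .bgzf_l2v(src$bf, from), n)
  } else {
    con <- file(src$path, "rb")
    on.exit(close(con))
    seek(con, from)
    readBin(con, "raw", n = n)
  }
}

#' Build a FASTA index
#'
#' One record per sequence in file order.  All full lines of a sequence must
#' share the same length (the final line may be shorter); CRLF line endings
#' are supported.
#'
#' @param path FASTA file (plain or BGZF-compressed)
#' @return data.frame with columns `name`, `length`, `offset`, `line_bases`,
#'   `line_width`
#' @export
faiBuild <- function(path) {
  src <- .fasta_source(path)
  payload <- .fasta_bytes(src, 0, src$size)
  nl <- which(payload == as.raw(0x0a))
  if (length(nl) == 0 || nl[length(nl)] != length(payload))
    nl <- c(nl, length(payload) + 1L)
  lstart <- c(0, nl[-length(nl)])           # 0-based line start offsets
  lines <- strsplit(rawToChar(payload), "\n", fixed = TRUE)[[1]]
  crlf <- endsWith(lines, "\r")
  lines[crlf] <- substring(lines[crlf], 1, nchar(lines[crlf]) - 1)
  widths <- diff(c(lstart, length(payload)))  # bytes incl terminator
  recs <- list()
  cur <- NULL
  flush_rec <- function(cur) {
    if (is.null(cur)) return(invisible(NULL))
    if (cur$name %in% vapply(recs, `[[`, "", "name"))
      hts_stop(sprintf("duplicate sequence name '%s'", cur$name), "fai_parse")
    recs[[length(recs) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], ">")) {
      flush_rec(cur)
      nm <- sub("^>\\s*(\\S+).*$", "\\1", lines[i])
      cur <- list(name = nm, length = 0, offset = lstart[i] + widths[i],
                  line_bases = 0, line_width = 0, closed = FALSE)
    } else if (!is.null(cur)) {
      nb <- nchar(lines[i])
      if (nb == 0) { cur$closed <- TRUE; next }
      if (cur$closed)
        hts_stop(sprintf("line %d: sequence resumes after a break", i),
                 "fai_parse")
      if (cur$line_bases == 0) {
        cur$line_bases <- nb
        cur$line_width <- widths[i]
      } else if (nb > cur$line_bases ||
                 (cur$length %% cur$line_bases != 0)) {
        hts_stop(sprintf("line %d: different line length in sequence '%s'",
                         i, cur$name), "fai_parse")
      }
      if (nb < cur$line_bases) cur$closed <- TRUE  # short line must be last
      cur$length <- cur$length + nb
    } else if (nzchar(lines[i])) {
      hts_stop(sprintf("line %d: sequence data before first header", i),
               "fai_parse")
    }
  }
  flush_rec(cur)
  data.frame(
    name = vapply(recs, `[[`, "", "name"),
    length = vapply(recs, `[[`, 0, "length"),
    offset = vapply(recs, `[[`, 0, "offset"),
    line_bases = vapply(recs, `[[`, 0, "line_bases"),
    line_width = vapply(recs, `[[`, 0, "line_width"),
    stringsAsFactors = FALSE)
}

#' Serialize / parse the 5-column FAI text format
#' @param fai data.frame from [faiBuild()]
#' @export
faiFormat <- function(fai) {
  sprintf("%s\t%.0f\t%.0f\t%.0f\t%.0f", fai$name, fai$length, fai$offset,
          fai$line_bases, fai$line_width)
}

#' @rdname faiFormat
#' @param x path to a .fai file or character vector of its lines
#' @export
faiParse <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(name = f[, 1], length = as.numeric(f[, 2]),
             offset = as.numeric(f[, 3]), line_bases = as.numeric(f[, 4]),
             line_width = as.numeric(f[, 5]), stringsAsFactors = FALSE)
}

#' Fetch a subsequence from an indexed FASTA
#'
#' Equivalent to slicing the fully concatenated sequence at `[beg, end)`.
#' Regions beyond the sequence length are clamped with a message.
#'
#' @param path FASTA file (plain or BGZF)
#' @param fai index from [faiBuild()] (built on the fly when NULL)
#' @param region "name", "name:beg-end" (1-based inclusive), or
#'   `list(seq=, beg=, end=)` 0-based half-open
#' @return the sequence as a single string
#' @export
faiFetch <- function(path, region, fai = NULL) {
  if (is.null(fai)) fai <- faiBuild(path)
  if (is.character(region)) region <- .parse_region_generic(region)
  i <- match(region$seq, fai$name)
  if (is.na(i))
    hts_stop(sprintf("sequence '%s' not in FASTA index", region$seq),
             "fai_range")
  len <- fai$length[i]
  beg <- max(0, region$beg)
  end <- min(region$end, len)
  if (!is.infinite(region$end) && region$end > len)
    message(sprintf("region end %.0f clamped to sequence length %.0f",
                    region$end, len))
  if (beg >= end) return("")
  if (fai$line_bases[i] == 0) return("")
  src <- .fasta_source(path)
  b0 <- fai$offset[i] + (beg %/% fai$line_bases[i]) * fai$line_width[i] +
    beg %% fai$line_bases[i]
  b1 <- fai$offset[i] + ((end - 1) %/% fai$line_bases[i]) * fai$line_width[i] +
    (end - 1) %% fai$line_bases[i]
  bytes <- .fasta_bytes(src, b0, b1 - b0 + 1)
  bytes <- bytes[!(bytes == as.raw(0x0a) | bytes == as.raw(0x0d))]
  rawToChar(bytes)
}
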