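# Generic coordinate indexing of BGZF-compressed tab-delimited text (TBI)
# with BED/GFF/VCF/SAM presets, plus the in-memory regidx intersector.

#' Tabix column configuration
#'
#' Describes how to extract `(sequence, begin, end)` from a tab-delimited
#' line.  Columns are 1-based.  `zero_based` marks BED-style half-open
#' 0-based coordinates; otherwise the begin column is 1-based and converted.
#' A `col_end` of 0 derives the end: VCF uses the REF allele length, the
#' generic/GFF fallback is a single base.
#'
#' @slot preset one of "generic", "bed", "gff", "vcf", "sam"
#' @slot col_seq,col_beg,col_end 1-based column numbers
#' @slot zero_based BED-style coordinates
#' @slot comment_char comment/skip prefix character
#' @slot skip_lines leading lines to skip unconditionally
#' @export
setClass("TabixConfig", representation(
  preset = "character", col_seq = "integer", col_beg = "integer",
  col_end = "integer", zero_based = "logical", comment_char = "character",
  skip_lines = "integer"))

setValidity("TabixConfig", function(object) {
  if (object@col_seq < 1 || object@col_beg < 1)
    return("col_seq and col_beg must be >= 1")
  TRUE
})

#' @rdname TabixConfig-class
#' @param preset preset name; "generic" uses the explicit column arguments
#' @param col_seq,col_beg,col_end 1-based column numbers
#' @param zero_based BED-style 0-based half-open coordinates
#' @param comment_char comment prefix
#' @param skip_lines leading lines to skip
#' @export
tabixConfig <- function(preset = "generic", col_seq = 1L, col_beg = 2L,
                        col_end = 3L, zero_based = FALSE,
                        comment_char = "#", skip_lines = 0L) {
  if (preset == "bed") {
    col_seq <- 1L; col_beg <- 2L; col_end <- 3L; zero_based <- TRUE
  } else if (preset == "gff") {
    col_seq <- 1L; col_beg <- 4L; col_end <- 5L; zero_based <- FALSE
  } else if (preset == "vcf") {
    col_seq <- 1L; col_beg <- 2L; col_end <- 0L; zero_based <- FALSE
  } else if (preset == "sam") {
    col_seq <- 3L; col_beg <- 4L; col_end <- 0L; zero_based <- FALSE
  } else if (preset != "generic") {
    hts_stop(sprintf("unknown tabix preset '%s'", preset), "tabix_config")
  }
  new("TabixConfig", preset = preset, col_seq = as.integer(col_seq),
      col_beg = as.integer(col_beg), col_end = as.integer(col_end),
      zero_based = zero_based, comment_char = comment_char,
      skip_lines = as.integer(skip_lines))
}

#' Extract the genomic interval of one text line
#'
#' Returns the 0-based half-open interval `(seq, beg, end)` of a data line
#' under a [tabixConfig()].  BED columns are used as-is; GFF/generic 1-based
#' begins are decremented; VCF ends extend over the REF allele length (so
#' deletions remain findable by any covered base).
#'
#' @param line one data line
#' @param conf a [TabixConfig-class]
#' @param lineno line number used in error messages
#' @export
lineInterval <- function(line, conf, lineno = NA_integer_) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  needed <- max(conf@col_seq, conf@col_beg, conf@col_end,
                if (conf@preset == "vcf") 4L else 0L)
  if (length(f) < needed)
    hts_stop(sprintf("line %s: %d column(s), %d required",
                     ifelse(is.na(lineno), "?", lineno), length(f), needed),
             "tabix_parse")
  beg <- suppressWarnings(as.numeric(f[conf@col_beg]))
  if (is.na(beg))
    hts_stop(sprintf("line %s: non-numeric coordinate '%s'",
                     ifelse(is.na(lineno), "?", lineno), f[conf@col_beg]),
             "tabix_parse")
  if (conf@preset == "vcf") {
    beg <- beg - 1
    end <- beg + nchar(f[4])
  } else if (conf@preset == "sam") {
    beg <- beg - 1
    end <- beg + max(1, cigarSpans(cigarParse(f[6]))$rlen)
  } else if (conf@zero_based) {
    end <- suppressWarnings(as.numeric(f[conf@col_end]))
  } else {
    beg <- beg - 1
    end <- if (conf@col_end == 0L || conf@col_end == conf@col_beg) beg + 1
           else suppressWarnings(as.numeric(f[conf@col_end]))
  }
  if (is.na(end))
    hts_stop(sprintf("line %s: non-numeric end coordinate",
                     ifelse(is.na(lineno), "?", lineno)), "tabix_parse")
  list(seq = f[conf@col_seq], beg = beg, end = end)
}

# split a BGZF text payload into lines with their logical start offsets
.text_lines_offsets <- function(payload) {
  nl <- which(payload == as.raw(0x0a))
  if (length(nl) == 0 || nl[length(nl)] != length(payload))
    nl <- c(nl, length(payload) + 1L)  # tolerate missing final newline
  starts <- c(0, nl[-length(nl)])
  txt <- strsplit(rawToChar(payload), "\n", fixed = TRUE)[[1]]
  list(text = txt, lstart = starts, lend = nl)
}

#' Build a tabix (TBI) index over BGZF-compressed tab-delimited text
#'
#' Data lines must be grouped by sequence and sorted by begin coordinate;
#' sequence ids are assigned in first-appearance order.  Reuses the same
#' binning/linear machinery as the alignment indexes at the fixed (14,5)
#' scheme.
#'
#' @param path BGZF-compressed text file
#' @param conf a [TabixConfig-class]
#' @return an [HtsIndex-class] with format "TBI"
#' @export
tabixBuild <- function(path, conf = tabixConfig("bed")) {
  bf <- bgzfOpen(path)
  if (!bf@state$seekable)
    hts_stop("plain gzip, not BGZF: cannot index (re-compress with bgzip)",
             "bgzf_plain_gzip")
  payload <- bgzfReadAt(bf, 0, bgzfUncompressedSize(bf))
  lo <- .text_lines_offsets(payload)
  n <- length(lo$text)
  is_data <- rep(TRUE, n)
  if (conf@skip_lines > 0) is_data[seq_len(min(conf@skip_lines, n))] <- FALSE
  is_data[startsWith(lo$text, conf@comment_char)] <- FALSE
  is_data[!nzchar(lo$text)] <- FALSE
  di <- which(is_data)
  ci <- which(startsWith(lo$text, conf@comment_char))
  if (length(di) > 0 && any(ci > di[1]))
    hts_stop("comment line after first data line is not allowed",
             "tabix_parse")
  names_seen <- character(0)
  ref_ids <- integer(length(di)); begs <- numeric(length(di))
  ends <- numeric(length(di))
  for (k in seq_along(di)) {
    iv <- lineInterval(lo$text[di[k]], conf, lineno = di[k])
    id <- match(iv$seq, names_seen)
    if (is.na(id)) { names_seen <- c(names_seen, iv$seq); id <- length(names_seen) }
    ref_ids[k] <- id - 1L; begs[k] <- iv$beg; ends[k] <- iv$end
  }
  vbeg <- vapply(lo$lstart[di], function(o) .bgzf_l2v(bf, o), 0)
  vend <- vapply(lo$lend[di], function(o) .bgzf_l2v(bf, o), 0)
  scheme <- binningScheme(14L, 5L)
  core <- tryCatch(
    .index_build_core(ref_ids, begs, ends, vbeg, vend,
                      rep(TRUE, length(di)), length(names_seen), scheme),
    not_sorted = function(e) {
      k <- as.integer(sub(".*record ([0-9]+).*", "\\1", conditionMessage(e)))
      hts_stop(sprintf("file not sorted at line %d", di[k]), "not_sorted")
    })
  new("HtsIndex", min_shift = 14L, depth = 5L, refs = core$refs,
      n_no_coor = core$n_no_coor, format = "TBI",
      conf = list(preset = conf@preset, col_seq = conf@col_seq,
                  col_beg = conf@col_beg, col_end = conf@col_end,
                  zero_based = conf@zero_based,
                  comment_char = conf@comment_char,
                  skip_lines = conf@skip_lines, names = names_seen))
}

.tbi_format_code <- function(conf) {
  code <- switch(conf$preset, vcf = 2, sam = 1, 0)
  if (isTRUE(conf$zero_based)) code <- code + 65536
  code
}

.tbi_write_bytes <- function(idx) {
  conf <- idx@conf
  scheme <- binningScheme(idx@min_shift, idx@depth)
  nm <- conf$names
  nm_block <- if (length(nm))
    do.call(c, lapply(nm, function(s) c(charToRaw(s), as.raw(0)))) else raw(0)
  out <- list(charToRaw("TBI"), as.raw(1),
              int32le(length(idx@refs)),
              int32le(.tbi_format_code(conf)),
              int32le(conf$col_seq), int32le(conf$col_beg),
              int32le(conf$col_end),
              int32le(utf8ToInt(conf$comment_char)),
              int32le(conf$skip_lines),
              int32le(length(nm_block)), nm_block)
  for (rf in idx@refs) {
    out[[length(out) + 1L]] <- .ref_bins_bytes(rf, scheme, FALSE)
    out[[length(out) + 1L]] <- c(int32le(length(rf$linear)),
      if (length(rf$linear)) do.call(c, lapply(rf$linear, uint64le)) else raw(0))
  }
  out[[length(out) + 1L]] <- uint64le(idx@n_no_coor)
  bgzfWriteStream(do.call(c, out))
}

.tbi_parse_bytes <- function(r) {
  if (rawToChar(r[1:3]) != "TBI" || r[4] != as.raw(1))
    hts_stop("bad TBI magic", "index_format")
  scheme <- binningScheme(14L, 5L)
  pos <- 5
  n_ref <- rd_int32(r, pos)
  fmt <- rd_int32(r, pos + 4)
  col_seq <- rd_int32(r, pos + 8); col_beg <- rd_int32(r, pos + 12)
  col_end <- rd_int32(r, pos + 16)
  meta <- rd_int32(r, pos + 20); skip <- rd_int32(r, pos + 24)
  l_nm <- rd_int32(r, pos + 28)
  pos <- pos + 32
  nm <- character(0)
  p <- pos
  while (p < pos + l_nm) {
    s <- rd_cstring(r, p); nm <- c(nm, s$str); p <- p + s$nbytes
  }
  pos <- pos + l_nm
  refs <- vector("list", n_ref)
  for (i in seq_len(n_ref)) {
    rb <- .read_bins(r, pos, FALSE, .meta_bin(scheme)); pos <- rb$pos
    n_intv <- rd_int32(r, pos); pos <- pos + 4
    linear <- numeric(n_intv)
    for (k in seq_len(n_intv)) { linear[k] <- rd_uint64(r, pos); pos <- pos + 8 }
    refs[[i]] <- list(bins = rb$bins, linear = linear, pseudo = rb$pseudo)
  }
  n_no_coor <- if (pos + 7 <= length(r)) rd_uint64(r, pos) else 0
  zero_based <- fmt >= 65536
  base <- fmt %% 65536
  preset <- if (base == 2) "vcf" else if (base == 1) "sam"
            else if (zero_based && col_seq == 1 && col_beg == 2) "bed"
            else "generic"
  new("HtsIndex", min_shift = 14L, depth = 5L, refs = refs,
      n_no_coor = n_no_coor, format = "TBI",
      conf = list(preset = preset, col_seq = col_seq, col_beg = col_beg,
                  col_end = col_end, zero_based = zero_based,
                  comment_char = intToUtf8(meta), skip_lines = skip,
                  names = nm))
}

#' Query a tabix-indexed file for a region
#'
#' Yields exactly the data lines whose interval overlaps the region, in file
#' order.  A sequence name absent from the index gives an empty result.
#'
#' @param path BGZF-compressed text file
#' @param idx the [HtsIndex-class] from [tabixBuild()] (or [readIndex()])
#' @param region "seq", "seq:beg-end" (1-based inclusive) or
#'   `list(seq=, beg=, end=)` 0-based half-open
#' @return character vector of matching lines
#' @export
tabixQuery <- function(path, idx, region) {
  conf <- idx@conf
  if (is.character(region)) region <- .parse_region_generic(region)
  rid <- match(region$seq, conf$names)
  if (is.na(rid)) return(character(0))
  beg <- region$beg
  end <- min(region$end, maxCoordinate(binningScheme(idx@min_shift, idx@depth)))
  chunks <- indexQuery(idx, rid - 1L, beg, end)
  if (nrow(chunks) == 0) return(character(0))
  bf <- bgzfOpen(path)
  payload <- bgzfReadAt(bf, 0, bgzfUncompressedSize(bf))
  lo <- .text_lines_offsets(payload)
  lineconf <- new("TabixConfig", preset = conf$preset,
                  col_seq = as.integer(conf$col_seq),
                  col_beg = as.integer(conf$col_beg),
                  col_end = as.integer(conf$col_end),
                  zero_based = isTRUE(conf$zero_based),
                  comment_char = conf$comment_char,
                  skip_lines = as.integer(conf$skip_lines))
  hits <- character(0)
  for (ci in seq_len(nrow(chunks))) {
    lbeg <- .bgzf_v2l(bf, chunks[ci, 1]); lend <- .bgzf_v2l(bf, chunks[ci, 2])
    in_chunk <- which(lo$lstart >= lbeg & lo$lstart < lend)
    for (li in in_chunk) {
      txt <- lo$text[li]
      if (!nzchar(txt) || startsWith(txt, conf$comment_char)) next
      iv <- lineInterval(txt, lineconf, li)
      if (iv$seq == region$seq && iv$beg < end && iv$end > beg)
        hits <- c(hits, txt)
    }
  }
  hits
}

# "seq:B-E" (1-based inclusive, commas allowed) without a header dictionary
.parse_region_generic <- function(text) {
  m <- regmatches(text, regexec("^([^:]+)(:([0-9,]+)(-([0-9,]+))?)?$", text))[[1]]
  if (length(m) == 0 || !nzchar(m[1]))
    hts_stop(sprintf("cannot parse region '%s'", text), "region_parse")
  seq <- m[2]
  if (!nzchar(m[3])) return(list(seq = seq, beg = 0, end = Inf))
  b <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
  e <- if (nzchar(m[6])) as.numeric(gsub(",", "", m[6], fixed = TRUE)) else Inf
  if (is.na(b) || b < 1 || (!is.infinite(e) && e < b))
    hts_stop(sprintf("bad region bounds in '%s'", text), "region_parse")
  list(seq = seq, beg = b - 1, end = e)
}

# ------------------------------------------------------------- regidx ----

#' In-memory region index
#'
#' Per-sequence interval arrays (0-based half-open) with line-number
#' payloads, supporting overlap queries whose results are independent of
#' insertion order.
#'
#' @slot seqs named list: sequence -> 3-column matrix (beg, end, payload)
#' @export
setClass("RegionSet", representation(seqs = "list"))

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d sequence(s), %d interval(s)\n",
              length(object@seqs),
              sum(vapply(object@seqs, nrow, 0L))))
})

#' Build an in-memory region index from text lines
#'
#' Input need not be sorted; intervals are sorted internally.  Payloads are
#' the 1-based source line numbers.
#'
#' @param lines character vector of data lines (comments/blank skipped)
#' @param conf a [TabixConfig-class]
#' @return a [RegionSet-class]
#' @export
regidxBuild <- function(lines, conf = tabixConfig("bed")) {
  keep <- nzchar(lines) & !startsWith(lines, conf@comment_char)
  if (conf@skip_lines > 0) keep[seq_len(min(conf@skip_lines, length(keep)))] <- FALSE
  idx <- which(keep)
  seqs <- list()
  for (li in idx) {
    iv <- lineInterval(lines[li], conf, li)
    seqs[[iv$seq]] <- rbind(seqs[[iv$seq]], c(iv$beg, iv$end, li))
  }
  for (s in names(seqs)) {
    m <- seqs[[s]]
    seqs[[s]] <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  }
  new("RegionSet", seqs = seqs)
}

#' @rdname regidxBuild
#' @param rs a [RegionSet-class]
#' @param seq sequence name
#' @param beg,end query interval, 0-based half-open
#' @return payload vector (line numbers) of all stored intervals
#'   intersecting the query
#' @export
regidxOverlap <- function(rs, seq, beg, end) {
  m <- rs@seqs[[seq]]
  if (is.null(m)) return(numeric(0))
  m[m[, 1] < end & m[, 2] > beg, 3]
}
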