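# Hierarchical binning + linear indexes (BAI, CSI): build, serialize, query.
#
# A binning scheme (min_shift, depth) buckets intervals into a forest of
# bins of size 2^min_shift * 8^level; bin numbering offsets per level are
# (8^l - 1)/7.  BAI fixes (14, 5), giving a 512 Mb addressable span; CSI
# parameterizes both, (14, 10) reaching 2^44 bp.

#' Binning scheme
#'
#' @param min_shift log2 of the smallest bin interval (BAI: 14)
#' @param depth number of levels below the root (BAI: 5)
#' @export
binningScheme <- function(min_shift = 14L, depth = 5L) {
  stopifnot(min_shift >= 0, depth >= 0)
  structure(list(min_shift = as.integer(min_shift), depth = as.integer(depth)),
            class = "BinningScheme")
}

#' Maximum addressable coordinate of a binning scheme
#'
#' `2^(min_shift + 3*depth)`: 512 Mb for the BAI/TBI scheme (14,5), 2^44 bp
#' for CSI at (14,10), the bounds that motivated the BAI-to-CSI transition.
#'
#' @param scheme a [binningScheme()]
#' @examples
#' maxCoordinate(binningScheme(14, 5))  / 2^20  # 512 Mb
#' maxCoordinate(binningScheme(14, 10)) == 2^44
#' @export
maxCoordinate <- function(scheme) 2^(scheme$min_shift + 3 * scheme$depth)

.level_offset <- function(l) (8^l - 1) / 7

#' Map a region to its smallest containing bin
#'
#' Returns the number of the smallest bin wholly containing the 0-based
#' half-open interval `[beg, end)`.
#'
#' @param beg,end 0-based half-open interval
#' @param scheme a [binningScheme()]
#' @export
reg2bin <- function(beg, end, scheme = binningScheme()) {
  if (end > maxCoordinate(scheme))
    hts_stop(sprintf("region end %.0f exceeds the scheme's %0.f bp limit",
                     end, maxCoordinate(scheme)), "index_range")
  if (beg >= end) hts_stop("empty region", "index_range")
  end1 <- end - 1
  for (l in scheme$depth:0) {
    s <- scheme$min_shift + 3 * (scheme$depth - l)
    if (beg %/% 2^s == end1 %/% 2^s)
      return(.level_offset(l) + beg %/% 2^s)
  }
  0
}

#' Enumerate all bins overlapping a region
#'
#' Every bin, at every level, whose interval overlaps `[beg, end)`.
#'
#' @inheritParams reg2bin
#' @return numeric vector of bin numbers, ascending
#' @export
reg2bins <- function(beg, end, scheme = binningScheme()) {
  if (end > maxCoordinate(scheme))
    hts_stop(sprintf("region end %.0f exceeds the scheme's %.0f bp limit",
                     end, maxCoordinate(scheme)), "index_range")
  if (beg >= end) hts_stop("empty region", "index_range")
  end1 <- end - 1
  out <- numeric(0)
  for (l in 0:scheme$depth) {
    s <- scheme$min_shift + 3 * (scheme$depth - l)
    out <- c(out, .level_offset(l) + seq(beg %/% 2^s, end1 %/% 2^s))
  }
  out
}

#' Genomic index container
#'
#' Per-reference bin-to-chunk maps plus a linear index of minimum virtual
#' offsets per 2^min_shift window; optionally a metadata pseudo-bin with
#' record counts and the reference's overall file span.
#'
#' @slot min_shift,depth the binning scheme
#' @slot refs per-reference list: `bins` (named list, bin number ->
#'   two-column matrix of chunk `vbeg`/`vend`), `linear` (numeric), `pseudo`
#'   (list or NULL)
#' @slot n_no_coor count of placeless unmapped records
#' @slot format "BAI", "CSI" or "TBI"
#' @slot conf tabix configuration (TBI only) or empty list
#' @export
setClass("HtsIndex", representation(
  min_shift = "integer", depth = "integer", refs = "list",
  n_no_coor = "numeric", format = "character", conf = "list"))

setValidity("HtsIndex", function(object) {
  for (rf in object@refs) {
    if (length(rf$linear) > 1 && any(diff(rf$linear) < 0))
      return("linear index is not monotone non-decreasing")
    for (b in rf$bins) {
      if (any(b[, 1] >= b[, 2])) return("chunk with vbeg >= vend")
      if (nrow(b) > 1 && any(diff(b[, 1]) < 0)) return("unsorted chunks in bin")
    }
  }
  TRUE
})

setMethod("show", "HtsIndex", function(object) {
  nb <- sum(vapply(object@refs, function(r) length(r$bins), 0L))
  cat(sprintf("HtsIndex (%s, scheme %d/%d): %d reference(s), %d bin(s), %.0f placeless record(s)\n",
              object@format, object@min_shift, object@depth,
              length(object@refs), nb, object@n_no_coor))
})

.meta_bin <- function(scheme) .level_offset(scheme$depth + 1) + 1

# Core builder over intervals: used for BAM records and tabix lines alike.
# `mapped` marks records counted as mapped in the metadata pseudo-bin.
.index_build_core <- function(ref_ids, begs, ends, vbeg, vend, mapped,
                              n_ref, scheme) {
  ord_bad <- which(diff(ifelse(ref_ids < 0, Inf, ref_ids)) < 0 |
                   (diff(ref_ids) == 0 & ref_ids[-1] >= 0 & diff(begs) < 0))
  if (length(ord_bad) > 0)
    hts_stop(sprintf("not coordinate sorted at record %d", ord_bad[1] + 1),
             "not_sorted")
  ms <- 2^scheme$min_shift
  refs <- vector("list", n_ref)
  for (i in seq_len(n_ref))
    refs[[i]] <- list(bins = list(), linear = numeric(0), pseudo = NULL)
  n_no_coor <- 0
  for (k in seq_along(ref_ids)) {
    rid <- ref_ids[k]
    if (rid < 0 || begs[k] < 0) { n_no_coor <- n_no_coor + 1; next }
    rf <- refs[[rid + 1]]
    beg <- begs[k]
    end <- max(ends[k], beg + 1)  # zero-length spans indexed as [beg, beg+1)
    b <- as.character(reg2bin(beg, end, scheme))
    cur <- rf$bins[[b]]
    if (!is.null(cur) && cur[nrow(cur), 2] == vbeg[k]) {
      cur[nrow(cur), 2] <- vend[k]
    } else {
      cur <- rbind(cur, c(vbeg[k], vend[k]))
    }
    rf$bins[[b]] <- cur
    w <- (beg %/% ms):((end - 1) %/% ms) + 1
    if (length(rf$linear) < max(w))
      rf$linear <- c(rf$linear, rep(NA_real_, max(w) - length(rf$linear)))
    rf$linear[w] <- pmin(rf$linear[w], vbeg[k], na.rm = TRUE)
    if (is.null(rf$pseudo))
      rf$pseudo <- list(off_beg = vbeg[k], off_end = vend[k],
                        n_mapped = 0, n_unmapped = 0)
    rf$pseudo$off_end <- max(rf$pseudo$off_end, vend[k])
    if (mapped[k]) rf$pseudo$n_mapped <- rf$pseudo$n_mapped + 1
    else rf$pseudo$n_unmapped <- rf$pseudo$n_unmapped + 1
    refs[[rid + 1]] <- rf
  }
  # normalize: bins in ascending numeric order; linear made monotone by
  # filling empty windows with the preceding anchor (0 at the start)
  for (i in seq_len(n_ref)) {
    rf <- refs[[i]]
    if (length(rf$bins) > 0)
      rf$bins <- rf$bins[order(as.numeric(names(rf$bins)))]
    if (length(rf$linear) > 0) {
      last <- 0
      for (w in seq_along(rf$linear)) {
        if (is.na(rf$linear[w])) rf$linear[w] <- last
        else last <- rf$linear[w]
      }
    }
    refs[[i]] <- rf
  }
  list(refs = refs, n_no_coor = n_no_coor)
}

#' Build an index from coordinate-sorted alignment records
#'
#' Each mapped record's reference span `[pos, end)` (zero-length spans
#' widened to one base) lands in its smallest containing bin; adjacent
#' records in the same bin extend the open chunk; the linear index keeps the
#' minimum record anchor per 16 kb window.  For CSI the depth is raised
#' automatically if a reference exceeds the addressable span.
#'
#' @param records list of records (see [samRecord()])
#' @param vbeg,vend per-record virtual-offset anchors
#' @param n_ref number of references in the header dictionary
#' @param scheme a [binningScheme()]
#' @param ref_lengths reference lengths (used for the CSI depth auto-raise)
#' @param csi build a CSI-flavoured index
#' @return an [HtsIndex-class]
#' @export
indexBuild <- function(records, vbeg, vend, n_ref,
                       scheme = binningScheme(), ref_lengths = NULL,
                       csi = FALSE) {
  ref_ids <- vapply(records, `[[`, 0L, "ref_id")
  poss <- vapply(records, `[[`, 0, "pos")
  ends <- vapply(records, recordEndPos, 0)
  flags <- vapply(records, `[[`, 0L, "flag")
  unmapped <- bitwAnd(flags, FLAG_UNMAP) != 0L
  ends[unmapped] <- poss[unmapped] + 1
  if (csi && !is.null(ref_lengths) && length(ref_lengths) > 0) {
    while (max(ref_lengths) > maxCoordinate(scheme))
      scheme <- binningScheme(scheme$min_shift, scheme$depth + 1L)
  }
  core <- .index_build_core(ref_ids, poss, ends, vbeg, vend, !unmapped,
                            n_ref, scheme)
  new("HtsIndex", min_shift = scheme$min_shift, depth = scheme$depth,
      refs = core$refs, n_no_coor = core$n_no_coor,
      format = if (csi) "CSI" else "BAI", conf = list())
}

# minimum virtual offset relevant to a query starting at `beg`
.index_min_offset <- function(rf, beg, scheme) {
  if (length(rf$linear) > 0) {
    w <- beg %/% 2^scheme$min_shift + 1
    if (w > length(rf$linear)) w <- length(rf$linear)
    return(rf$linear[w])
  }
  # CSI-read path: walk the leaf bin containing beg up towards the root
  # until a bin with a recorded loffset is found
  if (!is.null(rf$loffset)) {
    for (l in scheme$depth:0) {
      s <- scheme$min_shift + 3 * (scheme$depth - l)
      b <- as.character(.level_offset(l) + beg %/% 2^s)
      lo <- rf$loffset[[b]]
      if (!is.null(lo)) return(lo)
    }
  }
  0
}

#' Query an index for a region
#'
#' Returns the merged chunk list covering all records possibly overlapping
#' `[beg, end)` on reference `ref_id`: the union of the chunks of every
#' overlapping bin, pruned by the linear index, merged where chunks overlap
#' or abut.  Reading those chunks yields a superset of the overlapping
#' records, and every overlapping record.
#'
#' @param idx an [HtsIndex-class]
#' @param ref_id 0-based reference id
#' @param beg,end 0-based half-open query interval
#' @return two-column matrix (`vbeg`, `vend`), possibly zero rows
#' @export
indexQuery <- function(idx, ref_id, beg, end) {
  if (ref_id < 0 || ref_id >= length(idx@refs))
    hts_stop(sprintf("reference id %d not in index", ref_id), "index_range")
  scheme <- binningScheme(idx@min_shift, idx@depth)
  rf <- idx@refs[[ref_id + 1]]
  if (length(rf$bins) == 0) return(matrix(numeric(0), 0, 2))
  bins <- as.character(reg2bins(beg, min(end, maxCoordinate(scheme)), scheme))
  chunks <- do.call(rbind, unname(rf$bins[intersect(bins, names(rf$bins))]))
  if (is.null(chunks) || nrow(chunks) == 0) return(matrix(numeric(0), 0, 2))
  min_off <- .index_min_offset(rf, beg, scheme)
  keep <- chunks[, 2] > min_off
  chunks <- chunks[keep, , drop = FALSE]
  if (nrow(chunks) == 0) return(matrix(numeric(0), 0, 2))
  chunks[, 1] <- pmax(chunks[, 1], min_off)
  chunks <- chunks[order(chunks[, 1], chunks[, 2]), , drop = FALSE]
  mergeChunks(chunks)
}

#' Merge sorted chunks that overlap or abut
#' @param chunks two-column matrix sorted by vbeg
#' @export
mergeChunks <- function(chunks) {
  if (nrow(chunks) < 2) return(chunks)
  out <- chunks[1, , drop = FALSE]
  for (i in 2:nrow(chunks)) {
    if (chunks[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], chunks[i, 2])
    } else {
      out <- rbind(out, chunks[i, , drop = FALSE])
    }
  }
  out
}

# ------------------------------------------------------- serialization ----

.chunks_bytes <- function(m) {
  if (nrow(m) == 0) return(raw(0))
  do.call(c, lapply(seq_len(nrow(m)), function(i)
    c(uint64le(m[i, 1]), uint64le(m[i, 2]))))
}

.ref_bins_bytes <- function(rf, scheme, with_loffset) {
  meta <- .meta_bin(scheme)
  n_bin <- length(rf$bins) + as.integer(!is.null(rf$pseudo))
  out <- list(int32le(n_bin))
  for (b in names(rf$bins)) {
    m <- rf$bins[[b]]
    lo <- if (with_loffset) {
      # loffset: linear-index anchor at the bin's first window
      binno <- as.numeric(b)
      l <- 0
      while (.level_offset(l + 1) <= binno) l <- l + 1
      first <- (binno - .level_offset(l)) * 2^(scheme$min_shift +
                                               3 * (scheme$depth - l))
      .index_min_offset(rf, first, scheme)
    } else NULL
    out[[length(out) + 1L]] <- c(
      uint32le(as.numeric(b)),
      if (with_loffset) uint64le(lo) else raw(0),
      int32le(nrow(m)), .chunks_bytes(m))
  }
  if (!is.null(rf$pseudo)) {
    ps <- rf$pseudo
    out[[length(out) + 1L]] <- c(
      uint32le(meta),
      if (with_loffset) uint64le(0) else raw(0),
      int32le(2L),
      uint64le(ps$off_beg), uint64le(ps$off_end),
      uint64le(ps$n_mapped), uint64le(ps$n_unmapped))
  }
  do.call(c, out)
}

#' Serialize an index
#'
#' BAI is written raw with magic `BAI\1` and the fixed (14,5) scheme; CSI is
#' BGZF-compressed with magic `CSI\1` and stores `min_shift` and `depth`
#' (and per-bin loffsets in place of the standalone linear index).  The
#' metadata pseudo-bin (37450 for depth 5) carries the reference's file span
#' and mapped/unmapped counts.
#'
#' @param idx an [HtsIndex-class]
#' @param path output path or NULL for raw bytes
#' @export
writeIndex <- function(idx, path = NULL) {
  scheme <- binningScheme(idx@min_shift, idx@depth)
  if (idx@format == "BAI") {
    out <- list(charToRaw("BAI"), as.raw(1), int32le(length(idx@refs)))
    for (rf in idx@refs) {
      out[[length(out) + 1L]] <- .ref_bins_bytes(rf, scheme, FALSE)
      out[[length(out) + 1L]] <- c(int32le(length(rf$linear)),
        if (length(rf$linear)) do.call(c, lapply(rf$linear, uint64le)) else raw(0))
    }
    out[[length(out) + 1L]] <- uint64le(idx@n_no_coor)
    bytes <- do.call(c, out)
  } else if (idx@format == "CSI") {
    out <- list(charToRaw("CSI"), as.raw(1),
                int32le(idx@min_shift), int32le(idx@depth), int32le(0L),
                int32le(length(idx@refs)))
    for (rf in idx@refs)
      out[[length(out) + 1L]] <- .ref_bins_bytes(rf, scheme, TRUE)
    out[[length(out) + 1L]] <- uint64le(idx@n_no_coor)
    bytes <- bgzfWriteStream(do.call(c, out))
  } else {
    bytes <- .tbi_write_bytes(idx)
  }
  if (is.null(path)) bytes else writeBin(bytes, path)
}

.read_bins <- function(r, pos, with_loffset, meta) {
  n_bin <- rd_int32(r, pos); pos <- pos + 4
  bins <- list(); loffset <- list(); pseudo <- NULL
  for (j in seq_len(n_bin)) {
    b <- rd_uint32(r, pos); pos <- pos + 4
    lo <- if (with_loffset) { v <- rd_uint64(r, pos); pos <- pos + 8; v } else NULL
    n_chunk <- rd_int32(r, pos); pos <- pos + 4
    m <- matrix(numeric(0), 0, 2)
    if (n_chunk > 0) {
      m <- matrix(0, n_chunk, 2)
      for (k in seq_len(n_chunk)) {
        m[k, 1] <- rd_uint64(r, pos); m[k, 2] <- rd_uint64(r, pos + 8)
        pos <- pos + 16
      }
    }
    if (b == meta) {
      pseudo <- list(off_beg = m[1, 1], off_end = m[1, 2],
                     n_mapped = m[2, 1], n_unmapped = m[2, 2])
    } else {
      bins[[as.character(b)]] <- m
      if (with_loffset) loffset[[as.character(b)]] <- lo
    }
  }
  list(bins = bins, loffset = loffset, pseudo = pseudo, pos = pos)
}

#' Read a serialized index
#'
#' Accepts BAI, CSI or TBI bytes (format detected from the magic).
#'
#' @param x path or raw vector
#' @return an [HtsIndex-class]
#' @export
readIndex <- function(x) {
  r <- if (is.raw(x)) x else readBin(x, "raw", n = file.size(x))
  if (length(r) >= 2 && r[1] == as.raw(0x1f) && r[2] == as.raw(0x8b)) {
    bf <- bgzfOpen(r)
    r <- bgzfRead(bf, bgzfUncompressedSize(bf))
  }
  magic <- rawToChar(r[1:3])
  if (magic == "TBI") return(.tbi_parse_bytes(r))
  if (!magic %in% c("BAI", "CSI") || r[4] != as.raw(1))
    hts_stop("unrecognized index magic", "index_format")
  if (magic == "BAI") {
    scheme <- binningScheme(14L, 5L)
    pos <- 5
    n_ref <- rd_int32(r, pos); pos <- pos + 4
    refs <- vector("list", n_ref)
    for (i in seq_len(n_ref)) {
      rb <- .read_bins(r, pos, FALSE, .meta_bin(scheme)); pos <- rb$pos
      n_intv <- rd_int32(r, pos); pos <- pos + 4
      linear <- numeric(n_intv)
      for (k in seq_len(n_intv)) { linear[k] <- rd_uint64(r, pos); pos <- pos + 8 }
      refs[[i]] <- list(bins = rb$bins, linear = linear, pseudo = rb$pseudo)
    }
    n_no_coor <- if (pos + 7 <= length(r)) rd_uint64(r, pos) else 0
    new("HtsIndex", min_shift = 14L, depth = 5L, refs = refs,
        n_no_coor = n_no_coor, format = "BAI", conf = list())
  } else {
    pos <- 5
    min_shift <- rd_int32(r, pos); depth <- rd_int32(r, pos + 4)
    l_aux <- rd_int32(r, pos + 8); pos <- pos + 12 + l_aux
    scheme <- binningScheme(min_shift, depth)
    n_ref <- rd_int32(r, pos); pos <- pos + 4
    refs <- vector("list", n_ref)
    for (i in seq_len(n_ref)) {
      rb <- .read_bins(r, pos, TRUE, .meta_bin(scheme)); pos <- rb$pos
      refs[[i]] <- list(bins = rb$bins, linear = numeric(0),
                        loffset = rb$loffset, pseudo = rb$pseudo)
    }
    n_no_coor <- if (pos + 7 <= length(r)) rd_uint64(r, pos) else 0
    new("HtsIndex", min_shift = as.integer(min_shift),
        depth = as.integer(depth), refs = refs, n_no_coor = n_no_coor,
        format = "CSI", conf = list())
  }
}
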