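# Region-string parsing and the single/multi-region record iterator with
# once-only emission semantics.

#' Parse a region string against a header dictionary
#'
#' `"name"` expands to the whole reference; `"name:B-E"` is 1-based
#' inclusive (commas permitted) and maps to the 0-based half-open
#' `[B-1, E)`; `"name:B"` runs to the reference end.
#'
#' @param text region string
#' @param header a [SamHeader-class] supplying names and lengths
#' @return list with `seq`, `ref_id`, `beg`, `end`
#' @export
parseRegion <- function(text, header) {
  r <- .parse_region_generic(text)
  i <- match(r$seq, header@refs$name)
  if (is.na(i))
    hts_stop(sprintf("unknown reference '%s' in region '%s'", r$seq, text),
             "region_parse")
  len <- header@refs$length[i]
  end <- if (is.infinite(r$end)) len else min(r$end, len)
  if (r$beg >= end)
    hts_stop(sprintf("empty region '%s' after bounds checking", text),
             "region_parse")
  list(seq = r$seq, ref_id = i - 1L, beg = r$beg, end = end)
}

#' Does a record overlap a region?
#'
#' True iff the record's reference span `[pos, pos + rlen)` intersects
#' `[beg, end)`; zero-reference-span records (e.g. unmapped with placement)
#' are treated as covering `[pos, pos + 1)`.
#'
#' @param rec a record
#' @param beg,end 0-based half-open region
#' @export
recordOverlaps <- function(rec, beg, end) {
  if (rec$pos < 0) return(FALSE)
  rend <- max(recordEndPos(rec), rec$pos + 1)
  rec$pos < end && rend > beg
}

# merge a set of [beg,end) intervals where overlapping or adjacent
.merge_intervals <- function(begs, ends) {
  o <- order(begs, ends)
  begs <- begs[o]; ends <- ends[o]
  mb <- begs[1]; me <- ends[1]
  ob <- numeric(0); oe <- numeric(0)
  for (i in seq_along(begs)[-1]) {
    if (begs[i] <= me) me <- max(me, ends[i])
    else { ob <- c(ob, mb); oe <- c(oe, me); mb <- begs[i]; me <- ends[i] }
  }
  cbind(c(ob, mb), c(oe, me))
}

# coalesce chunks further: also merge when the gap lies within one
# compressed block (same coffset), so a block is never visited twice
.coalesce_chunks <- function(chunks) {
  if (nrow(chunks) < 2) return(chunks)
  out <- chunks[1, , drop = FALSE]
  for (i in 2:nrow(chunks)) {
    prev_end_coff <- out[nrow(out), 2] %/% 65536
    beg_coff <- chunks[i, 1] %/% 65536
    if (chunks[i, 1] <= out[nrow(out), 2] || beg_coff <= prev_end_coff) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], chunks[i, 2])
    } else {
      out <- rbind(out, chunks[i, , drop = FALSE])
    }
  }
  out
}

#' Multi-region record iteration with once-only semantics
#'
#' Per reference, regions are sorted and merged (overlapping or adjacent),
#' chunk lists from the index are unioned and coalesced, and each chunk is
#' scanned once.  Every emitted record overlaps at least one input region,
#' appears exactly once, and appears in file order within each reference;
#' output follows reference-dictionary order.
#'
#' @param bam a [BamFile-class] from [bamOpen()]
#' @param idx the file's [HtsIndex-class]
#' @param regions list of regions from [parseRegion()] (or a character
#'   vector of region strings, parsed against the file header)
#' @return list with `records` and `blocks_read` (BGZF blocks inflated
#'   during the scan)
#' @export
multiRegionIter <- function(bam, idx, regions) {
  if (is.character(regions))
    regions <- lapply(regions, parseRegion, header = bam@header)
  bgzfResetCache(bam@bgzf)
  ref_ids <- vapply(regions, `[[`, 0L, "ref_id")
  records <- list()
  for (rid in sort(unique(ref_ids))) {
    sel <- regions[ref_ids == rid]
    merged <- .merge_intervals(vapply(sel, `[[`, 0, "beg"),
                               vapply(sel, `[[`, 0, "end"))
    chunks <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i)
      indexQuery(idx, rid, merged[i, 1], merged[i, 2])))
    if (is.null(chunks) || nrow(chunks) == 0) next
    chunks <- mergeChunks(chunks[order(chunks[, 1], chunks[, 2]), ,
                                 drop = FALSE])
    chunks <- .coalesce_chunks(chunks)
    for (ci in seq_len(nrow(chunks))) {
      sc <- .bam_scan(bam, from = chunks[ci, 1], while_lt = chunks[ci, 2])
      for (rec in sc$records) {
        if (rec$ref_id != rid) next
        if (rec$pos >= merged[nrow(merged), 2]) break
        hit <- any(rec$pos < merged[, 2] &
                   pmax(recordEndPos(rec), rec$pos + 1) > merged[, 1])
        if (hit) records[[length(records) + 1L]] <- rec
      }
    }
  }
  list(records = records, blocks_read = bgzfBlocksRead(bam@bgzf))
}

#' Single-region query against an indexed BAM
#'
#' @param bam a [BamFile-class]
#' @param idx an [HtsIndex-class]
#' @param region region string or parsed region
#' @return list with `records` and `blocks_read`
#' @export
bamQuery <- function(bam, idx, region) {
  if (is.character(region)) region <- parseRegion(region, bam@header)
  multiRegionIter(bam, idx, list(region))
}
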