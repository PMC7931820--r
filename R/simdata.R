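# Deterministic fixture generator: references, coordinate-sorted alignments
# and tab-delimited interval files exercising every code path.
#
# Identical seed + parameters give byte-identical outputs (integer-only
# sampling through R's RNG).  Desk-scale defaults: 2 references x 100 kb,
# 10k reads, 2k intervals.

BASES <- c("A", "C", "G", "T")

#' Generate a pseudo-random reference
#'
#' Optionally embeds tandem repeats at recorded coordinates (used to create
#' ambiguously placeable reads for alignment-quality tests).
#'
#' @param seed RNG seed
#' @param lengths named numeric vector of sequence lengths
#' @param line_width bases per FASTA line
#' @param repeats list of `list(seq=, at=, unit=, n=)`: paste `n` copies of
#'   `unit` starting at 0-based position `at`
#' @return list with `seqs` (named character), `fasta` (text lines),
#'   `repeats` (the recorded loci)
#' @export
genReference <- function(seed = 1L, lengths = c(chr1 = 100000, chr2 = 100000),
                         line_width = 60L, repeats = NULL) {
  set.seed(seed)
  seqs <- vapply(lengths, function(L)
    paste(BASES[sample.int(4L, L, replace = TRUE)], collapse = ""), "")
  names(seqs) <- names(lengths)
  for (rp in repeats) {
    tract <- strrep(rp$unit, rp$n)
    s <- seqs[[rp$seq]]
    stopifnot(rp$at + nchar(tract) <= nchar(s))
    seqs[[rp$seq]] <- paste0(substr(s, 1, rp$at), tract,
                             substr(s, rp$at + nchar(tract) + 1, nchar(s)))
  }
  fasta <- unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    starts <- seq(1, max(nchar(s), 1), by = line_width)
    c(paste0(">", nm),
      if (nchar(s) > 0) substring(s, starts, pmin(starts + line_width - 1,
                                                  nchar(s))))
  }))
  list(seqs = seqs, fasta = fasta, repeats = repeats)
}

.rev_comp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Generate coordinate-sorted alignments over a reference
#'
#' Reads are sampled uniformly from the reference with configurable
#' substitution and indel errors, soft clips and unmapped fractions; CIGARs
#' reflect the injected events and the `NM` tag counts them.  Output is
#' coordinate-sorted (placeless unmapped reads last) and a ground-truth
#' sidecar table records each read's origin.
#'
#' @param ref output of [genReference()]
#' @param seed RNG seed
#' @param n_reads number of reads
#' @param read_len min/max read length
#' @param sub_rate per-base substitution probability
#' @param indel_rate per-read probability of carrying one indel
#' @param indel_max maximum indel length
#' @param clip_rate per-read probability of a soft-clipped end
#' @param unmapped_rate fraction of reads emitted unmapped and placeless
#' @param placed_unmapped_rate fraction emitted unmapped but carrying a
#'   placement position (mate-anchored), exercising zero-span indexing
#' @return list with `header` ([SamHeader-class]), `records`, `truth`
#'   (data.frame)
#' @export
genAlignments <- function(ref, seed = 1L, n_reads = 10000L,
                          read_len = c(70L, 100L), sub_rate = 0.005,
                          indel_rate = 0.1, indel_max = 5L,
                          clip_rate = 0.1, unmapped_rate = 0.02,
                          placed_unmapped_rate = 0.01) {
  set.seed(seed + 1L)
  seqs <- ref$seqs
  refnames <- names(seqs)
  reflens <- nchar(seqs)
  header <- headerParse(c("@HD\tVN:1.6\tSO:coordinate",
                          sprintf("@SQ\tSN:%s\tLN:%d", refnames, reflens),
                          "@RG\tID:sim\tSM:sample1",
                          "@PG\tID:htslite\tPN:htslite"))
  recs <- vector("list", n_reads)
  truth <- data.frame(qname = character(n_reads), ref = character(n_reads),
                      pos = numeric(n_reads), cigar = character(n_reads),
                      nm = integer(n_reads), stringsAsFactors = FALSE)
  kind <- sample.int(1000L, n_reads, replace = TRUE)
  for (k in seq_len(n_reads)) {
    qname <- sprintf("read%06d", k)
    L <- sample(seq(read_len[1], read_len[2]), 1L)
    quals <- sample(20:40, L, replace = TRUE)
    if (kind[k] <= 1000 * unmapped_rate) {
      sq <- paste(BASES[sample.int(4L, L, replace = TRUE)], collapse = "")
      recs[[k]] <- samRecord(qname = qname, flag = FLAG_UNMAP, seq = sq,
                             qual = quals,
                             tags = list(list(tag = "RG", type = "Z",
                                              value = "sim")))
      truth[k, ] <- list(qname, "*", -1, "*", 0L)
      next
    }
    ri <- sample.int(length(seqs), 1L)
    nm <- 0L
    # optional single indel
    ins_len <- del_len <- 0L
    if (sample.int(1000L, 1L) <= 1000 * indel_rate) {
      if (sample.int(2L, 1L) == 1L) ins_len <- sample.int(indel_max, 1L)
      else del_len <- sample.int(indel_max, 1L)
    }
    span <- L - ins_len + del_len
    pos <- sample.int(max(reflens[ri] - span - 1L, 1L), 1L) - 1L
    tmpl <- substr(seqs[[ri]], pos + 1, pos + span)
    # soft clips
    c5 <- if (sample.int(1000L, 1L) <= 1000 * clip_rate) sample.int(10L, 1L) else 0L
    c3 <- if (sample.int(1000L, 1L) <= 1000 * clip_rate) sample.int(10L, 1L) else 0L
    core <- L  # aligned query length (incl. insertions)
    # assemble query from template
    if (ins_len > 0L) {
      cut <- sample(seq_len(core - ins_len - 1L), 1L)
      q <- paste0(substr(tmpl, 1, cut),
                  paste(BASES[sample.int(4L, ins_len, TRUE)], collapse = ""),
                  substr(tmpl, cut + 1, span))
      cig <- list(op = c("M", "I", "M"),
                  len = c(cut, ins_len, core - ins_len - cut))
      nm <- nm + ins_len
    } else if (del_len > 0L) {
      cut <- sample(seq_len(core - 1L), 1L)
      q <- paste0(substr(tmpl, 1, cut), substr(tmpl, cut + del_len + 1, span))
      cig <- list(op = c("M", "D", "M"),
                  len = c(cut, del_len, core - cut))
      nm <- nm + del_len
    } else {
      q <- tmpl
      cig <- list(op = "M", len = core)
    }
    # substitutions on aligned bases
    qb <- strsplit(q, "")[[1]]
    hit <- which(sample.int(1000L, length(qb), replace = TRUE) <=
                 1000 * sub_rate)
    for (i in hit) {
      qb[i] <- BASES[sample(setdiff(1:4, match(qb[i], BASES)), 1L)]
      nm <- nm + 1L
    }
    q <- paste(qb, collapse = "")
    if (c5 > 0L) {
      q <- paste0(paste(BASES[sample.int(4L, c5, TRUE)], collapse = ""), q)
      cig <- list(op = c("S", cig$op), len = c(c5, cig$len))
    }
    if (c3 > 0L) {
      q <- paste0(q, paste(BASES[sample.int(4L, c3, TRUE)], collapse = ""))
      cig <- list(op = c(cig$op, "S"), len = c(cig$len, c3))
    }
    qual_all <- sample(20:40, nchar(q), replace = TRUE)
    unmapped_placed <- kind[k] > 1000 * (1 - placed_unmapped_rate)
    flag <- if (unmapped_placed) FLAG_UNMAP
            else if (sample.int(2L, 1L) == 1L) FLAG_REVERSE else 0L
    recs[[k]] <- samRecord(
      qname = qname, flag = flag, ref_id = ri - 1L, pos = pos,
      mapq = if (unmapped_placed) 0L else sample(c(60L, 60L, 60L, 30L, 0L), 1L),
      cigar = if (unmapped_placed) list(op = character(0), len = numeric(0))
              else cig,
      seq = q, qual = qual_all,
      tags = list(list(tag = "RG", type = "Z", value = "sim"),
                  list(tag = "NM", type = "i", value = nm)))
    truth[k, ] <- list(qname, refnames[ri], pos,
                       if (unmapped_placed) "*" else cigarFormat(cig), nm)
  }
  # coordinate sort, placeless unmapped last
  rid <- vapply(recs, `[[`, 0L, "ref_id")
  pos <- vapply(recs, `[[`, 0, "pos")
  o <- order(ifelse(rid < 0, .Machine$integer.max, rid), pos)
  list(header = header, records = recs[o], truth = truth[o, ])
}

#' Generate BED or GFF interval fixtures
#'
#' @param ref_lengths named vector of sequence lengths
#' @param seed RNG seed
#' @param n number of intervals
#' @param format "bed" or "gff"
#' @param sorted emit sorted by (sequence, begin); FALSE guarantees at least
#'   one inversion (for error-path tests)
#' @param overlap_stress cluster intervals around hotspots so that a large
#'   fraction overlap a neighbour, mimicking exon-list iterator workloads
#' @return character vector of lines
#' @export
genIntervals <- function(ref_lengths, seed = 1L, n = 2000L, format = "bed",
                         sorted = TRUE, overlap_stress = FALSE) {
  set.seed(seed + 2L)
  nms <- names(ref_lengths)
  ri <- sample.int(length(ref_lengths), n, replace = TRUE)
  lens <- sample(50:2000, n, replace = TRUE)
  if (overlap_stress) {
    ncl <- max(1L, n %/% 20L)
    centers <- lapply(seq_along(ref_lengths), function(i)
      sample.int(max(ref_lengths[i] - 4000L, 1L), ncl, replace = TRUE))
    beg <- vapply(seq_len(n), function(k)
      centers[[ri[k]]][sample.int(ncl, 1L)] + sample.int(1500L, 1L), 0)
  } else {
    beg <- vapply(seq_len(n), function(k)
      sample.int(max(ref_lengths[ri[k]] - max(lens) - 1L, 1L), 1L), 0)
  }
  end <- pmin(beg + lens, ref_lengths[ri])
  o <- if (sorted) order(ri, beg) else seq_len(n)
  ri <- ri[o]; beg <- beg[o]; end <- end[o]
  if (!sorted && n >= 2 && !is.unsorted(order(ri, beg))) {
    tmp <- c(2L, 1L)
    ri[1:2] <- ri[tmp]; beg[1:2] <- beg[tmp]; end[1:2] <- end[tmp]
  }
  if (format == "bed") {
    sprintf("%s\t%.0f\t%.0f\tiv%05d", nms[ri], beg, end, seq_len(n))
  } else if (format == "gff") {
    sprintf("%s\tsim\tregion\t%.0f\t%.0f\t.\t+\t.\tID=iv%05d",
            nms[ri], beg + 1, end, seq_len(n))
  } else {
    hts_stop(sprintf("unknown interval format '%s'", format), "sim_config")
  }
}

#' Write a named fixture set to a directory
#'
#' Presets: `"default"` (reference, sorted SAM, BED, truth table), `"baq"`
#' (short tandem-repeat reference plus reads crossing the repeats),
#' `"stress"` (overlap-stress BED), `"unsorted"` (BED with an inversion).
#'
#' @param dir output directory (created if needed)
#' @param preset preset name
#' @param seed RNG seed
#' @return invisibly, the list of files written
#' @export
simdataWrite <- function(dir, preset = "default", seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(name, lines) {
    p <- file.path(dir, name)
    writeLines(lines, p)
    files <<- c(files, p)
  }
  if (preset == "default") {
    ref <- genReference(seed)
    al <- genAlignments(ref, seed)
    put("ref.fa", ref$fasta)
    put("reads.sam", writeSam(al$header, al$records))
    put("intervals.bed", genIntervals(nchar(ref$seqs), seed))
    put("truth.tsv", c(paste(colnames(al$truth), collapse = "\t"),
                       do.call(sprintf, c(list("%s\t%s\t%.0f\t%s\t%d"),
                                          al$truth))))
  } else if (preset == "baq") {
    ref <- genReference(seed, lengths = c(chr1 = 20000),
                        repeats = list(list(seq = "chr1", at = 5000,
                                            unit = "AC", n = 50),
                                       list(seq = "chr1", at = 12000,
                                            unit = "ACGT", n = 30)))
    al <- genAlignments(ref, seed, n_reads = 500L, sub_rate = 0.002,
                        indel_rate = 0.02, clip_rate = 0,
                        unmapped_rate = 0, placed_unmapped_rate = 0)
    put("ref.fa", ref$fasta)
    put("reads.sam", writeSam(al$header, al$records))
  } else if (preset == "stress") {
    ref_lengths <- c(chr1 = 100000, chr2 = 100000)
    put("stress.bed", genIntervals(ref_lengths, seed, n = 2000L,
                                   overlap_stress = TRUE))
  } else if (preset == "unsorted") {
    put("unsorted.bed", genIntervals(c(chr1 = 100000), seed, n = 100L,
                                     sorted = FALSE))
  } else {
    hts_stop(sprintf("unknown preset '%s'", preset), "sim_config")
  }
  invisible(files)
}
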