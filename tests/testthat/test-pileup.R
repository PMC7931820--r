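hdr_p <- headerParse("@SQ\tSN:chr1\tLN:100000")

test_that("a single read pivots into one column per reference position", {
  r <- parseSamRecord("r1\t0\tchr1\t1\t60\t4M\t*\t0\t0\tACGT\tIIII", hdr_p)
  pf <- pileupColumns(list(header = hdr_p, records = list(r)))
  expect_equal(nrow(pf), 4)
  expect_equal(pf$pos, 0:3)
  expect_equal(pf$base[pf$pos == 2], "G")
  expect_true(pf$is_start[1] && pf$is_end[4])
})

test_that("deletions produce marker entries and indel annotations", {
  r <- parseSamRecord("r\t0\tchr1\t11\t60\t2M1D2M\t*\t0\t0\tACGT\tIIII",
                      hdr_p)
  pf <- pileupColumns(list(header = hdr_p, records = list(r)))
  expect_equal(pf$pos, 10:14)
  expect_true(pf$is_del[pf$pos == 12])
  expect_true(is.na(pf$qual[pf$pos == 12]))
  expect_equal(pf$indel[pf$pos == 11], -1)
  ins <- parseSamRecord("i\t0\tchr1\t11\t60\t2M3I2M\t*\t0\t0\tACGTAGA\t*",
                        hdr_p)
  pfi <- pileupColumns(list(header = hdr_p, records = list(ins)))
  expect_equal(nrow(pfi), 4)              # insertions add no columns
  expect_equal(pfi$indel[pfi$pos == 11], 3)
  # query offsets strictly increase across non-deletion entries
  expect_true(all(diff(pf$qoff[!pf$is_del]) > 0))
})

test_that("default filters drop unmapped/secondary/qcfail/dup records", {
  mk <- function(flag) samRecord(qname = paste0("f", flag), flag = flag,
                                 ref_id = 0L, pos = 10,
                                 cigar = cigarParse("4M"), seq = "ACGT")
  pf <- pileupColumns(list(header = hdr_p,
                           records = list(mk(0L), mk(4L), mk(256L),
                                          mk(512L), mk(1024L))))
  expect_equal(unique(pf$rec), 1)
  expect_equal(nrow(pf), 4)
})

test_that("depth is conserved and each (record, position) appears exactly once", {
  ref <- genReference(41, lengths = c(chr1 = 10000))
  al <- genAlignments(ref, 41, n_reads = 600)
  pf <- pileupColumns(list(header = al$header, records = al$records))
  surviving <- Filter(function(r)
    bitwAnd(r$flag, htslite:::PILEUP_DROP_FLAGS) == 0L &&
      r$ref_id >= 0 && length(r$cigar$op) > 0, al$records)
  expect_equal(nrow(pf),
               sum(vapply(surviving, function(r) cigarSpans(r$cigar)$rlen, 0)))
  expect_false(anyDuplicated(pf[, c("input", "rec", "pos")]) > 0)
  # columns arrive in (ref, pos) order
  expect_false(is.unsorted(pf$pos))
})

test_that("two inputs merge with depth additivity and label preservation", {
  r1 <- samRecord(qname = "a", ref_id = 0L, pos = 40,
                  cigar = list(op = "M", len = 20), seq = strrep("A", 20))
  r2 <- samRecord(qname = "b", ref_id = 0L, pos = 50,
                  cigar = list(op = "M", len = 20), seq = strrep("C", 20))
  pf <- pileupColumns(list(list(header = hdr_p, records = list(r1)),
                           list(header = hdr_p, records = list(r2))))
  d <- pileupDepth(pf)
  expect_equal(d$depth[d$pos %in% 50:59], rep(2, 10))
  expect_equal(d$depth[d$pos %in% 40:49], rep(1, 10))
  expect_equal(d$depth[d$pos %in% 60:69], rep(1, 10))
  expect_equal(sort(unique(pf$input)), 1:2)
  # equals the pileup of concatenated inputs up to the input label
  both <- pileupColumns(list(header = hdr_p, records = list(r1, r2)))
  expect_equal(both$pos, pf$pos)
  expect_equal(both$base, pf$base)
})

test_that("depth cap truncates with a message", {
  recs <- lapply(1:30, function(i)
    samRecord(qname = sprintf("d%02d", i), ref_id = 0L, pos = 10,
              cigar = cigarParse("4M"), seq = "ACGT"))
  expect_message(pf <- pileupColumns(list(header = hdr_p, records = recs),
                                     max_depth = 10L), "truncated")
  expect_equal(max(pileupDepth(pf)$depth), 10)
})

# --- BAQ ---------------------------------------------------------------

test_that("banded BAQ equals the unbanded oracle on sub-band instances", {
  set.seed(601)
  for (rep in 1:20) {
    L <- sample(8:14, 1)
    m <- sample(4:(L - 2), 1)
    win <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    off <- sample(0:(L - m), 1)
    read <- substr(win, off + 1, off + m)
    # sprinkle mismatches
    rb <- strsplit(read, "")[[1]]
    if (sample(2, 1) == 1) {
      i <- sample(m, 1)
      rb[i] <- sample(setdiff(c("A", "C", "G", "T"), rb[i]), 1)
    }
    read <- paste(rb, collapse = "")
    quals <- sample(10:40, m, replace = TRUE)
    exp_col <- off + seq_len(m)
    post_band <- htslite:::.baq_posteriors(
      strsplit(read, "")[[1]], 10^(-quals / 10), exp_col,
      strsplit(win, "")[[1]], baqParams(band = 20L))
    post_oracle <- oracle_baq(read, quals, exp_col, win)
    expect_equal(post_band, post_oracle, tolerance = 1e-9)
  }
})

test_that("BAQ caps but never raises qualities", {
  set.seed(602)
  ref <- genReference(42, lengths = c(chr1 = 3000),
                      repeats = list(list(seq = "chr1", at = 1000,
                                          unit = "AT", n = 30)))
  al <- genAlignments(ref, 42, n_reads = 80, unmapped_rate = 0,
                      placed_unmapped_rate = 0, clip_rate = 0)
  tf <- tempfile(); writeLines(ref$fasta, tf)
  fai <- faiBuild(tf)
  for (rec in al$records[1:40]) {
    wbeg <- max(0, rec$pos - 10)
    wend <- min(3000, recordEndPos(rec) + 10)
    win <- faiFetch(tf, list(seq = "chr1", beg = wbeg, end = wend), fai = fai)
    adj <- baqAdjust(rec, win, wbeg)
    expect_true(all(adj <= rec$qual))
    expect_length(adj, length(rec$qual))
  }
})

test_that("ambiguous tandem-repeat placement lowers qualities, unique placement does not", {
  rep_ref <- strrep("AC", 20)
  rec <- samRecord(qname = "amb", flag = 0L, ref_id = 0L, pos = 10,
                   mapq = 60L, cigar = cigarParse("6M"), seq = "ACACAC",
                   qual = rep(40L, 6))
  adj <- baqAdjust(rec, rep_ref, 0)
  expect_true(all(adj < 40))
  # oracle agrees on this tiny instance
  post <- oracle_baq("ACACAC", rep(40, 6), 11:16, rep_ref)
  expect_true(all(pmin(floor(-10 * log10(1 - post)), 93) < 40))
  set.seed(603)
  u <- paste(sample(c("A", "C", "G", "T"), 260, TRUE), collapse = "")
  rec2 <- samRecord(qname = "uniq", flag = 0L, ref_id = 0L, pos = 30,
                    mapq = 60L, cigar = cigarParse("200M"),
                    seq = substr(u, 31, 230), qual = rep(40L, 200))
  adj2 <- baqAdjust(rec2, u, 0, baqParams(band = 25L))
  expect_gte(mean(adj2 == 40), 0.9)
})

test_that("unmapped records pass through BAQ unchanged with a message", {
  rec <- samRecord(qname = "u", flag = 4L, seq = "ACGT", qual = rep(30L, 4))
  expect_message(adj <- baqAdjust(rec, "ACGTACGT", 0), "unmapped")
  expect_identical(adj, rec$qual)
  mapped <- samRecord(qname = "m", ref_id = 0L, pos = 5,
                      cigar = cigarParse("4M"), seq = "ACGT",
                      qual = rep(30L, 4))
  expect_error(baqAdjust(mapped, "AC", 0), class = "pileup_config")
})

test_that("pileup text format renders markers and reference bases", {
  ref <- genReference(43, lengths = c(chr1 = 200))
  tf <- tempfile(); writeLines(ref$fasta, tf)
  r <- samRecord(qname = "t", ref_id = 0L, pos = 10, mapq = 40L,
                 cigar = cigarParse("3M"), seq = "ACG", qual = c(30L, 31L, 32L))
  pf <- pileupColumns(list(header = hdr_p, records = list(r)))
  txt <- pileupText(pf, hdr_p, fasta = tf)
  expect_length(txt, 3)
  f <- strsplit(txt[1], "\t")[[1]]
  expect_equal(f[1], "chr1")
  expect_equal(f[2], "11")                       # 1-based
  expect_equal(f[3], substr(ref$seqs[["chr1"]], 11, 11))
  expect_equal(f[4], "1")
  expect_match(f[5], "^\\^")
  expect_match(strsplit(txt[3], "\t")[[1]][5], "\\$$")
})
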