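# Shared fixtures, generated in code (deterministic under fixed seeds).

fixture_env <- new.env(parent = emptyenv())

# small simulated cohort: 2 x 20 kb references, 2000 reads
fix_small <- function() {
  if (is.null(fixture_env$small)) {
    ref <- genReference(11, lengths = c(chr1 = 20000, chr2 = 20000))
    al <- genAlignments(ref, 11, n_reads = 2000L)
    dir <- tempfile("fix")
    dir.create(dir)
    fa <- file.path(dir, "ref.fa")
    writeLines(ref$fasta, fa)
    bam <- file.path(dir, "reads.bam")
    wb <- writeBam(al$header, al$records, path = bam, index = TRUE)
    fixture_env$small <- list(ref = ref, header = al$header,
                              records = al$records, truth = al$truth,
                              fa = fa, bam = bam, index = wb$index, dir = dir)
  }
  fixture_env$small
}

# a SAM fixture exercising every CIGAR op, every tag type, unmapped reads,
# absent qualities
fix_full_feature_sam <- function() {
  c("@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    "@SQ\tSN:chr2\tLN:5000",
    "@RG\tID:rg1\tSM:s",
    "@CO\tfree text comment\twith tab",
    paste0("r01\t0\tchr1\t101\t60\t10M\t=\t201\t150\tACGTACGTAC\tIIIIIIIIII",
           "\tNM:i:0\tRG:Z:rg1"),
    "r02\t16\tchr1\t151\t37\t3S4M2I3M1D2M2S\t*\t0\t0\tTTTACGTGGACGAAGG\t*",
    "r03\t0\tchr1\t201\t0\t5M100N5M\t*\t0\t0\tACGTAACGTA\tII@@IIII@@",
    paste0("r04\t0\tchr1\t301\t60\t2H8M\t*\t0\t0\tACGTACGT\tIIIIIIII",
           "\tXF:f:0.25\tXA:A:c\tXZ:Z:hello world\tXH:H:1AFF"),
    paste0("r05\t0\tchr1\t401\t60\t4M2P4M\t*\t0\t0\tACGTACGT\tIIIIIIII",
           "\tXB:B:c,-1,0,2\tXG:B:f,1.5,-0.25\tXU:B:S,0,65535"),
    "r06\t0\tchr1\t501\t60\t8M1D8M\t*\t0\t0\tACGTACGTACGTACGT\t*\tXI:i:-70000",
    "r07\t4\tchr1\t601\t0\t*\t*\t0\t0\tACGT\tIIII",
    "r08\t4\t*\t0\t0\t*\t*\t0\t0\tAACC\t*\tXS:i:300",
    "r09\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")
}

# random valid records for property-style round trips
random_record <- function(header, i) {
  n <- sample(5:30, 1)
  seq <- paste(sample(c("A", "C", "G", "T", "N"), n, TRUE), collapse = "")
  cig <- list(op = "M", len = n)
  if (sample(3, 1) == 1) {
    k <- sample(seq_len(n - 2), 1)
    cig <- list(op = c("M", sample(c("I", "D"), 1), "M"),
                len = c(k, sample(3, 1), n - k))
    if (cig$op[2] == "I") {
      if (cig$len[2] >= cig$len[3]) cig$len[2] <- cig$len[3] - 1
      if (cig$len[2] < 1) cig <- list(op = "M", len = n)
      else cig$len[3] <- cig$len[3] - cig$len[2]
    }
  }
  tags <- list()
  if (sample(2, 1) == 1)
    tags <- list(list(tag = "NM", type = "i", value = as.numeric(sample(0:1000, 1))),
                 list(tag = "XF", type = "f",
                      value = htslite:::float32snap(runif(1))))
  samRecord(qname = sprintf("q%04d", i), flag = sample(c(0L, 16L), 1),
            ref_id = 0L, pos = sample(0:5000, 1), mapq = sample(0:60, 1),
            cigar = cig, seq = seq,
            qual = if (sample(4, 1) == 1) NULL else sample(0:41, n, TRUE),
            tags = tags)
}

# Independent unbanded forward-backward over the same documented model:
# full matrices, no banding, no scaling (small instances keep magnitudes
# sane), written directly from the model description.
oracle_baq <- function(read, quals, exp_col, win, gap_open = 1e-3,
                       gap_ext = 0.1) {
  rb <- strsplit(read, "")[[1]]
  wb <- strsplit(win, "")[[1]]
  m <- length(rb); L <- length(wb)
  eps <- 10^(-quals / 10)
  e <- function(i, j) if (rb[i] == wb[j]) 1 - eps[i] else eps[i] / 3
  a <- gap_open; b <- gap_ext
  tMM <- 1 - 2 * a; tIM <- 1 - b; tDM <- 1 - b
  f <- array(0, c(m, L, 3))  # M, I, D
  for (j in 1:L) {
    f[1, j, 1] <- e(1, j) / (2 * L)
    f[1, j, 2] <- 0.25 / (2 * L)
  }
  for (j in 1:L)
    f[1, j, 3] <- if (j > 1) f[1, j - 1, 1] * a + f[1, j - 1, 3] * b else 0
  if (m > 1) for (i in 2:m) {
    for (j in 1:L) {
      if (j > 1)
        f[i, j, 1] <- e(i, j) * (f[i - 1, j - 1, 1] * tMM +
                                 f[i - 1, j - 1, 2] * tIM +
                                 f[i - 1, j - 1, 3] * tDM)
      f[i, j, 2] <- 0.25 * (f[i - 1, j, 1] * a + f[i - 1, j, 2] * b)
    }
    for (j in 1:L)
      f[i, j, 3] <- if (j > 1) f[i, j - 1, 1] * a + f[i, j - 1, 3] * b else 0
  }
  bk <- array(0, c(m, L, 3))
  bk[m, , 1] <- 1; bk[m, , 2] <- 1
  if (m > 1) for (i in (m - 1):1) {
    for (j in L:1) {
      toM <- if (j < L) e(i + 1, j + 1) * bk[i + 1, j + 1, 1] else 0
      bk[i, j, 3] <- tDM * toM + (if (j < L) b * bk[i, j + 1, 3] else 0)
    }
    for (j in 1:L) {
      toM <- if (j < L) e(i + 1, j + 1) * bk[i + 1, j + 1, 1] else 0
      toI <- 0.25 * bk[i + 1, j, 2]
      bk[i, j, 1] <- tMM * toM + a * toI +
        a * (if (j < L) bk[i, j + 1, 3] else 0)
      bk[i, j, 2] <- tIM * toM + b * toI
    }
  }
  vapply(seq_len(m), function(i) {
    if (is.na(exp_col[i])) return(NA_real_)
    tot <- sum(f[i, , 1] * bk[i, , 1]) + sum(f[i, , 2] * bk[i, , 2])
    f[i, exp_col[i], 1] * bk[i, exp_col[i], 1] / tot
  }, 0)
}

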