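# The mpileup data pivot: row-oriented alignment records to per-position
# columns across one or more inputs, with optional BAQ quality adjustment.

PILEUP_DROP_FLAGS <- FLAG_UNMAP + FLAG_SECONDARY + FLAG_QCFAIL + FLAG_DUP

# per-record CIGAR walk -> parallel entry vectors
.pileup_entries_one <- function(rec, quals) {
  pos <- rec$pos
  n_ops <- length(rec$cigar$op)
  rpos <- pos
  qoff <- 0
  ep <- numeric(0); eb <- character(0); eq <- numeric(0); eo <- numeric(0)
  edel <- logical(0); eskip <- logical(0); eind <- numeric(0)
  bases <- strsplit(rec$seq, "")[[1]]
  for (i in seq_len(n_ops)) {
    op <- rec$cigar$op[i]; len <- rec$cigar$len[i]
    if (op %in% c("M", "=", "X")) {
      idx <- seq_len(len)
      ep <- c(ep, rpos + idx - 1)
      eb <- c(eb, bases[qoff + idx])
      eq <- c(eq, if (is.null(quals)) rep(NA_real_, len) else quals[qoff + idx])
      eo <- c(eo, qoff + idx - 1)
      edel <- c(edel, rep(FALSE, len)); eskip <- c(eskip, rep(FALSE, len))
      eind <- c(eind, rep(0, len))
      rpos <- rpos + len; qoff <- qoff + len
    } else if (op == "I") {
      if (length(eind) > 0) eind[length(eind)] <- len
      qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      if (op == "D" && length(eind) > 0) eind[length(eind)] <- -len
      idx <- seq_len(len)
      ep <- c(ep, rpos + idx - 1)
      eb <- c(eb, rep(if (op == "D") "*" else ">", len))
      eq <- c(eq, rep(NA_real_, len))
      eo <- c(eo, rep(NA_real_, len))
      edel <- c(edel, rep(op == "D", len))
      eskip <- c(eskip, rep(op == "N", len))
      eind <- c(eind, rep(0, len))
      rpos <- rpos + len
    } else if (op == "S") {
      qoff <- qoff + len
    }                                    # H, P consume nothing
  }
  n <- length(ep)
  list(pos = ep, base = eb, qual = eq, qoff = eo, is_del = edel,
       is_refskip = eskip, indel = eind,
       is_start = c(TRUE, rep(FALSE, max(n - 1, 0)))[seq_len(n)],
       is_end = c(rep(FALSE, max(n - 1, 0)), TRUE)[seq_len(n)])
}

.pileup_one_input <- function(input, input_id, region, min_mapq, baq,
                              fasta, fai, baq_params) {
  if (is.character(input)) {
    src <- sniffFormat(input)
    parsed <- if (src == "BAM") {
      if (!is.null(region) && !file.exists(paste0(input, ".bai")))
        message(sprintf("%s: no index found; falling back to full scan",
                        input))
      readBam(input)
    } else readSam(input)
    input <- list(header = parsed$header, records = parsed$records)
  }
  header <- input$header
  recs <- input$records
  flags <- vapply(recs, `[[`, 0L, "flag")
  mapqs <- vapply(recs, `[[`, 0L, "mapq")
  keep <- bitwAnd(flags, PILEUP_DROP_FLAGS) == 0L & mapqs >= min_mapq &
    vapply(recs, function(r) r$ref_id >= 0 && r$pos >= 0 &&
             length(r$cigar$op) > 0, TRUE)
  recs <- recs[keep]
  if (!is.null(region))
    recs <- Filter(function(r) r$ref_id == region$ref_id &&
                     recordOverlaps(r, region$beg, region$end), recs)
  cols <- list()
  for (k in seq_along(recs)) {
    rec <- recs[[k]]
    quals <- rec$qual
    if (baq && !is.null(quals) && rec$seq != "*") {
      wbeg <- max(0, rec$pos - baq_params$band - 1)
      wend <- min(header@refs$length[rec$ref_id + 1],
                  recordEndPos(rec) + baq_params$band + 1)
      refwin <- faiFetch(fasta, list(seq = header@refs$name[rec$ref_id + 1],
                                     beg = wbeg, end = wend), fai = fai)
      quals <- baqAdjust(rec, refwin, wbeg, baq_params)
    }
    e <- .pileup_entries_one(rec, quals)
    e$ref_id <- rep(rec$ref_id, length(e$pos))
    e$mapq <- rep(rec$mapq, length(e$pos))
    e$rec_i <- rep(k, length(e$pos))
    cols[[k]] <- e
  }
  if (length(cols) == 0) return(NULL)
  out <- lapply(names(cols[[1]]), function(f)
    do.call(c, lapply(cols, `[[`, f)))
  names(out) <- names(cols[[1]])
  out$input <- rep(input_id, length(out$pos))
  out
}

#' Pile up alignments into per-position columns
#'
#' Pivots one or more coordinate-sorted inputs (paths to SAM/BAM files, or
#' `list(header=, records=)` pairs) into per-reference-position entries.
#' Records failing the default flag filter (unmapped, secondary, QC-fail,
#' duplicate) are dropped.  A record contributes one entry to every column
#' in its reference span: aligned bases carry base/quality/query-offset,
#' deletion and reference-skip positions carry marker entries (counted in
#' depth, as in classic mpileup output), an insertion of n bases sets
#' `indel = +n` on the entry at the preceding base, a deletion sets
#' `indel = -n` there.
#'
#' With `baq = TRUE` (requires `fasta`) base qualities are capped by base
#' alignment quality computed per record via [baqAdjust()].
#'
#' @param inputs one input or a list of inputs
#' @param region optional parsed region (see [parseRegion()]) restricting
#'   the pileup
#' @param min_mapq,min_baseq mapping/base quality filters (entries below
#'   `min_baseq` are removed after BAQ)
#' @param max_depth per-column depth cap (excess entries dropped with a
#'   message)
#' @param baq apply base alignment quality adjustment
#' @param fasta,fai reference FASTA path and optional prebuilt index
#' @param baq_params see [baqParams()]
#' @return data.frame of entries ordered by (ref_id, pos, input, record):
#'   columns `ref_id`, `pos`, `input`, `base`, `qual`, `qoff`, `mapq`,
#'   `is_del`, `is_refskip`, `indel`, `is_start`, `is_end`
#' @export
pileupColumns <- function(inputs, region = NULL, min_mapq = 0L,
                          min_baseq = 0L, max_depth = 8000L, baq = FALSE,
                          fasta = NULL, fai = NULL,
                          baq_params = baqParams()) {
  if (!is.null(names(inputs)) || is.character(inputs) ||
      (is.list(inputs) && !is.null(inputs$records)))
    inputs <- list(inputs)
  if (baq && is.null(fasta))
    hts_stop("BAQ requires a reference fasta", "pileup_config")
  if (baq && is.null(fai)) fai <- faiBuild(fasta)
  parts <- lapply(seq_along(inputs), function(i)
    .pileup_one_input(inputs[[i]], i, region, min_mapq, baq, fasta, fai,
                      baq_params))
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0)
    return(data.frame(ref_id = integer(0), pos = numeric(0),
                      input = integer(0), base = character(0),
                      qual = numeric(0), qoff = numeric(0), mapq = integer(0),
                      is_del = logical(0), is_refskip = logical(0),
                      indel = numeric(0), is_start = logical(0),
                      is_end = logical(0)))
  df <- data.frame(
    ref_id = do.call(c, lapply(parts, `[[`, "ref_id")),
    pos = do.call(c, lapply(parts, `[[`, "pos")),
    input = do.call(c, lapply(parts, `[[`, "input")),
    base = do.call(c, lapply(parts, `[[`, "base")),
    qual = do.call(c, lapply(parts, `[[`, "qual")),
    qoff = do.call(c, lapply(parts, `[[`, "qoff")),
    mapq = do.call(c, lapply(parts, `[[`, "mapq")),
    is_del = do.call(c, lapply(parts, `[[`, "is_del")),
    is_refskip = do.call(c, lapply(parts, `[[`, "is_refskip")),
    indel = do.call(c, lapply(parts, `[[`, "indel")),
    is_start = do.call(c, lapply(parts, `[[`, "is_start")),
    is_end = do.call(c, lapply(parts, `[[`, "is_end")),
    rec = do.call(c, lapply(parts, `[[`, "rec_i")),
    stringsAsFactors = FALSE)
  if (min_baseq > 0)
    df <- df[df$is_del | df$is_refskip | is.na(df$qual) |
               df$qual >= min_baseq, ]
  df <- df[order(df$ref_id, df$pos, df$input, df$rec), ]
  rownames(df) <- NULL
  # per-column depth cap
  key <- paste(df$ref_id, df$pos)
  cnt <- ave(seq_len(nrow(df)), key, FUN = seq_along)
  if (any(cnt > max_depth)) {
    message(sprintf("%d entries truncated at max depth %d",
                    sum(cnt > max_depth), max_depth))
    df <- df[cnt <= max_depth, ]
    rownames(df) <- NULL
  }
  df
}

#' Per-column depth summary of a pileup
#'
#' @param pf entry data.frame from [pileupColumns()]
#' @return data.frame (ref_id, pos, depth) in (ref, pos) order
#' @export
pileupDepth <- function(pf) {
  if (nrow(pf) == 0)
    return(data.frame(ref_id = integer(0), pos = numeric(0),
                      depth = integer(0)))
  ag <- aggregate(list(depth = pf$pos), by = list(ref_id = pf$ref_id,
                                                  pos = pf$pos), FUN = length)
  ag[order(ag$ref_id, ag$pos), ]
}

#' Classic 6-column text pileup
#'
#' chrom, 1-based position, reference base, depth, bases string with
#' `^`/`$`/`+n`/`-n` markers and `*` for deletion-spanning entries, and the
#' quality string.
#'
#' @param pf entry data.frame from [pileupColumns()]
#' @param header [SamHeader-class] naming the references
#' @param fasta,fai reference source for the REF column ("N" when absent)
#' @return character vector of pileup lines
#' @export
pileupText <- function(pf, header, fasta = NULL, fai = NULL) {
  if (nrow(pf) == 0) return(character(0))
  if (!is.null(fasta) && is.null(fai)) fai <- faiBuild(fasta)
  out <- character(0)
  key <- paste(pf$ref_id, pf$pos)
  for (grp in split(seq_len(nrow(pf)), factor(key, levels = unique(key)))) {
    e <- pf[grp, ]
    nm <- header@refs$name[e$ref_id[1] + 1]
    refbase <- if (is.null(fasta)) "N" else
      toupper(faiFetch(fasta, list(seq = nm, beg = e$pos[1],
                                   end = e$pos[1] + 1), fai = fai))
    bases <- vapply(seq_len(nrow(e)), function(i) {
      b <- if (e$is_del[i]) "*" else if (e$is_refskip[i]) ">" else e$base[i]
      if (e$is_start[i]) b <- paste0("^", intToUtf8(e$mapq[i] + 33), b)
      if (e$indel[i] > 0) b <- sprintf("%s+%d", b, e$indel[i])
      if (e$indel[i] < 0) b <- sprintf("%s-%d", b, -e$indel[i])
      if (e$is_end[i]) b <- paste0(b, "$")
      b
    }, "")
    qs <- vapply(e$qual, function(q)
      if (is.na(q)) "*" else intToUtf8(q + 33), "")
    out <- c(out, sprintf("%s\t%.0f\t%s\t%d\t%s\t%s", nm, e$pos[1] + 1,
                          refbase, nrow(e), paste(bases, collapse = ""),
                          paste(qs, collapse = "")))
  }
  out
}

# ------------------------------------------------------------------ BAQ ----

#' BAQ parameters
#'
#' Gap-open and gap-extension probabilities of the realignment profile-HMM
#' and the band half-width (positions around each base's original column
#' explored by the banded dynamic program).
#'
#' @param gap_open probability of opening an insertion/deletion (default
#'   1e-3, the reference tool's published default)
#' @param gap_ext gap extension probability (default 0.1)
#' @param band band half-width in positions (default 7)
#' @export
baqParams <- function(gap_open = 1e-3, gap_ext = 0.1, band = 7L) {
  stopifnot(gap_open > 0, gap_open < 1, gap_ext > 0, gap_ext < 1, band >= 1)
  list(gap_open = gap_open, gap_ext = gap_ext, band = as.integer(band))
}

# original reference column (0-based) of each aligned query base; NA for
# insertions; soft-clipped bases excluded from the returned index map
.query_columns <- function(rec) {
  qidx <- numeric(0); col <- numeric(0)
  rpos <- rec$pos; qoff <- 0
  for (i in seq_along(rec$cigar$op)) {
    op <- rec$cigar$op[i]; len <- rec$cigar$len[i]
    if (op %in% c("M", "=", "X")) {
      qidx <- c(qidx, qoff + seq_len(len)); col <- c(col, rpos + seq_len(len) - 1)
      rpos <- rpos + len; qoff <- qoff + len
    } else if (op == "I") {
      qidx <- c(qidx, qoff + seq_len(len)); col <- c(col, rep(NA_real_, len))
      qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    } else if (op == "S") {
      qoff <- qoff + len
    }
  }
  list(qidx = qidx, col = col)
}

# Banded forward-backward over the glocal 3-state (match/insert/delete)
# pair HMM of read vs reference window.
#
# States at (read base i, window column j): M = base i aligned to column j,
# I = base i inserted after column j, D = column j deleted after i bases
# consumed (silent with respect to the read; within-row recursion).
# Transitions: M->I = M->D = gap_open; I->I = D->D = gap_ext;
# I->M = D->M = 1 - gap_ext; M->M = 1 - 2*gap_open.  Match emission is
# 1 - eps on agreement and eps/3 on disagreement with eps = 10^(-q/10);
# insert emission is 1/4.  Entry is uniform over M/I at every column; exit
# is uniform from M/I at the last read base.
#
# Returns per read base the posterior of occupying the match state of its
# original reference column (NA for bases without one, i.e. insertions).
# Computed in scaled linear space with per-row renormalization; rows whose
# band covers the whole window make the result exact (unbanded).
.baq_posteriors <- function(rb, eps, exp_col, wb, params) {
  m <- length(rb)
  L <- length(wb)
  a <- params$gap_open; b <- params$gap_ext
  tMM <- 1 - 2 * a; tMI <- a; tMD <- a
  tII <- b; tIM <- 1 - b
  tDD <- b; tDM <- 1 - b
  eI <- 0.25
  ec <- exp_col
  for (i in seq_len(m)) if (is.na(ec[i]))
    ec[i] <- if (i > 1) ec[i - 1] + 1 else 1
  blo <- pmax(1L, as.integer(round(ec)) - params$band)
  bhi <- pmin(L, as.integer(round(ec)) + params$band)
  is_acgt <- wb %in% c("A", "C", "G", "T")
  emit <- function(i, j)
    ifelse(rb[i] == wb[j] & is_acgt[j], 1 - eps[i], eps[i] / 3)
  fM <- matrix(0, m, L); fI <- matrix(0, m, L); fD <- matrix(0, m, L)
  scale <- numeric(m)
  for (i in seq_len(m)) {
    js <- blo[i]:bhi[i]
    if (i == 1) {
      fM[1, js] <- emit(1, js) / (2 * L)
      fI[1, js] <- eI / (2 * L)
    } else {
      jm1 <- js - 1
      ok <- jm1 >= 1
      fM[i, js[ok]] <- emit(i, js[ok]) *
        (fM[i - 1, jm1[ok]] * tMM + fI[i - 1, jm1[ok]] * tIM +
         fD[i - 1, jm1[ok]] * tDM)
      fI[i, js] <- eI * (fM[i - 1, js] * tMI + fI[i - 1, js] * tII)
    }
    for (j in js)   # within-row deletion chain, left to right
      fD[i, j] <- if (j > 1) fM[i, j - 1] * tMD + fD[i, j - 1] * tDD else 0
    s <- sum(fM[i, js]) + sum(fI[i, js]) + sum(fD[i, js])
    if (s <= 0) return(rep(0, m))  # read unalignable inside the band
    fM[i, ] <- fM[i, ] / s; fI[i, ] <- fI[i, ] / s; fD[i, ] <- fD[i, ] / s
    scale[i] <- s
  }
  bM <- matrix(0, m, L); bI <- matrix(0, m, L); bD <- matrix(0, m, L)
  bM[m, blo[m]:bhi[m]] <- 1
  bI[m, blo[m]:bhi[m]] <- 1
  if (m > 1) for (i in (m - 1):1) {
    js <- blo[i]:bhi[i]
    s1 <- scale[i + 1]
    # within-row-i deletion chain runs right to left: D(i,j) sees M(i+1,j+1)
    for (j in rev(seq_len(L))) {
      toM <- if (j < L) emit(i + 1, j + 1) * bM[i + 1, j + 1] / s1 else 0
      bD[i, j] <- tDM * toM + (if (j < L) tDD * bD[i, j + 1] else 0)
    }
    for (j in js) {
      toM <- if (j < L) emit(i + 1, j + 1) * bM[i + 1, j + 1] / s1 else 0
      toI <- eI * bI[i + 1, j] / s1
      bM[i, j] <- tMM * toM + tMI * toI +
        tMD * (if (j < L) bD[i, j + 1] else 0)
      bI[i, j] <- tIM * toM + tII * toI
    }
  }
  post <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (is.na(exp_col[i]) || exp_col[i] < 1 || exp_col[i] > L) next
    row_total <- sum(fM[i, ] * bM[i, ]) + sum(fI[i, ] * bI[i, ])
    pm <- fM[i, exp_col[i]] * bM[i, exp_col[i]]
    post[i] <- if (row_total > 0) pm / row_total else 0
  }
  post
}

#' Base alignment quality adjustment
#'
#' Realigns a mapped read against a reference window with a banded
#' profile-HMM forward-backward and converts, per aligned base, the
#' posterior probability of correct placement into a phred score; the
#' returned quality is the minimum of the original quality and that score,
#' so BAQ can only lower confidence.  Bases without an original reference
#' column (insertions, soft clips) keep their original quality, as do
#' unmapped records (identity, with a message).
#'
#' @param rec a mapped record with non-empty `seq` and `qual`
#' @param refwin reference bases covering the record span plus the band
#' @param window_start 0-based reference position of `refwin`'s first base
#' @param params see [baqParams()]
#' @return integer vector, same length as `rec$qual`
#' @export
baqAdjust <- function(rec, refwin, window_start, params = baqParams()) {
  if (bitwAnd(rec$flag, FLAG_UNMAP) != 0L || rec$ref_id < 0 || rec$pos < 0) {
    message("baqAdjust: unmapped record left unchanged")
    return(rec$qual)
  }
  if (is.null(rec$qual) || rec$seq == "*")
    hts_stop("BAQ needs sequence and qualities", "pileup_config")
  cm <- .query_columns(rec)
  if (length(cm$qidx) == 0) return(rec$qual)
  exp_col <- cm$col - window_start + 1   # 1-based in window, NA for inserts
  need_hi <- max(exp_col, na.rm = TRUE)
  if (nchar(refwin) < need_hi)
    hts_stop("reference window too short for record span", "pileup_config")
  bases <- strsplit(rec$seq, "")[[1]][cm$qidx]
  quals <- rec$qual[cm$qidx]
  post <- .baq_posteriors(bases, 10^(-quals / 10), exp_col,
                          strsplit(refwin, "")[[1]], params)
  phred <- floor(-10 * log10(pmax(1 - post, 1e-30)))
  phred[is.na(post)] <- Inf
  adj <- rec$qual
  adj[cm$qidx] <- pmin(quals, pmin(phred, 93))
  as.integer(adj)
}
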