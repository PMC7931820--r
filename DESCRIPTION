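Package: htslite
Title: Blocked-Gzip Random Access, SAM/BAM, Genomic Indexes, Pileup and
    rANS Entropy Coding
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained R implementation of the core machinery used
    by high-throughput sequencing toolchains: the BGZF blocked-gzip
    container with 64-bit virtual-offset random access, the SAM text and
    BAM binary alignment formats with full header manipulation, the
    hierarchical binning indexes BAI and CSI, generic tabix (TBI)
    indexing of coordinate-sorted tab-delimited text with BED/GFF/VCF
    presets plus an in-memory region intersector, FASTA indexing (FAI)
    with random subsequence fetch, a once-only multi-region record
    iterator, an mpileup-style per-position column engine with optional
    base alignment quality (BAQ) recalibration via a banded profile-HMM,
    and a byte-oriented rANS entropy coder (order 0 and order 1) of the
    kind used for CRAM column compression.  Includes a deterministic
    synthetic-data generator for references, coordinate-sorted
    alignments and interval files, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: methods, stats, utils, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 'bytes.R' 'bgzf.R' 'sam-model.R' 'hts-index.R' 'bam-codec.R'
    'tabix.R' 'faidx.R' 'region-iter.R' 'pileup.R' 'rans.R' 'simdata.R'
    'cli.R' 'RcppExports.R'
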