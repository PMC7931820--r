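---
title: "htslite: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{htslite: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htslite)
```

`htslite` is a self-contained R implementation of the data layer that
high-throughput sequencing toolchains are built on: blocked-gzip random
access, the SAM/BAM alignment formats, the genomic binning indexes, a
per-position pileup engine with base alignment quality, and a rANS entropy
coder.  This vignette explains the models and procedures, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where the design was open.

## BGZF: seekable compression

A BGZF stream is a concatenation of independent gzip members, each carrying
its total on-disk length in a `BC` extra subfield.  Because every block is
at most 64 KiB on disk and decodable from its own bytes alone, a 64-bit
*virtual offset* — upper 48 bits the compressed offset of a block start,
lower 16 bits the offset inside the decompressed block — addresses any byte
in the logical stream, which is what makes compressed alignment files
indexable.

Choices:

* The writer fills blocks to 65280 uncompressed bytes.  This leaves enough
  headroom that even incompressible input, after DEFLATE framing and the
  26 bytes of BGZF wrapper, stays within the 16-bit on-disk size field;
  a block that still would not fit is re-tried at lower compression levels
  and finally stored uncompressed.
* Records may span block boundaries; only offsets used as index anchors
  must be true record starts, which the writer guarantees by reporting its
  position (`$tell()`) before each record is appended.
* The CRC32 of every decoded block is verified; a mismatch is fatal.  A
  missing 28-byte EOF sentinel is a warning only, because truncation at a
  block boundary cannot be proven.
* Plain gzip input (no `BC` subfield) is readable sequentially but flagged
  non-seekable, and is reported distinctly from corruption.
* Packed virtual offsets are carried as R doubles.  They are exact up to
  2^53, i.e. for compressed files up to 2^37 bytes (~137 GiB); larger
  compressed offsets are rejected rather than silently rounded.  R has no
  native 64-bit integer type, and 137 GiB is far beyond what an in-memory
  R handle would be pointed at.

DEFLATE, INFLATE and CRC32 themselves come from zlib through a ~60-line
compiled shim; base R exposes gzip compression but neither the compression
level, raw (headerless) streams, nor crc32.

## SAM/BAM and the coordinate convention

Internally every coordinate is 0-based, half-open; the 1-based SAM text
convention is converted exactly once at the text boundary.  `ref_id = -1`
and `pos = -1` are the "absent" sentinels.  Round trips are designed to be
lossless: unknown header lines and tags are preserved verbatim, quality
strings absent from input (`*`) are stored as absent and serialized back as
`*`, and `B`-array tags keep their declared subtype.  Integer tag subtypes
(`c C s S i I`) are normalized to one internal integer type on decode, and
the narrowest subtype is chosen on encode — SAM text only has `i`, so text
round trips are unaffected.

Float tags are binary32 on disk.  Parsed values are snapped through
binary32 immediately so that a parse/format cycle is the identity for
canonically formatted text (`%.9g`, which round-trips any binary32).

The BAM position fields are signed 32-bit, which is the 2 Gb
reference-length ceiling of the format; positions at or beyond 2^31 are a
hard error rather than any workaround.  The per-record `bin` field is
recomputed on write, never trusted from input, and set to 0 for spans
beyond the 512 Mb range of the fixed binning scheme, where the field has no
defined meaning and readers rely on the index.

## Binning indexes (BAI, CSI) and tabix (TBI)

A binning scheme `(min_shift, depth)` tiles the reference with intervals of
size `2^min_shift * 8^level`; the smallest bin wholly containing a record's
span buckets it, and a linear index keeps, per 2^min_shift window, the
minimum virtual offset of any record overlapping that window.  The maximum
addressable coordinate is `2^(min_shift + 3*depth)`: 512 Mb at the fixed
BAI/TBI scheme (14, 5) and 2^44 bp at (14, 10), which is how this package
realizes the CSI extension (the CSI default stays (14, 5); depth is raised
automatically at build time when a reference exceeds the addressable
span).

Queries take the union of the chunk lists of all bins overlapping the
region, discard chunks ending before the linear-index anchor of the
region's first window, and merge chunks that overlap or abut exactly; no
heuristic gap-coalescing happens at this layer, because the multi-region
iterator coalesces further with knowledge of block boundaries.  Empty
linear-index windows are filled with the preceding anchor, keeping the
array monotone and the pruning conservative.

Zero-length spans (unmapped records carrying a mate's placement) are
indexed as one-base intervals so they remain retrievable by position.  The
metadata pseudo-bin (37450 at depth 5) records each reference's file span
and mapped/unmapped counts.

On-disk formats follow the published layouts: BAI raw little-endian, CSI
BGZF-compressed with per-bin `loffset` anchors in place of a standalone
linear index, TBI BGZF-compressed with the column configuration and
sequence-name block in front.  Because CSI cannot carry the full linear
index, a CSI read back from disk reconstructs its pruning information from
the bin anchors (walking from the leaf bin containing the query start up
towards the root); round-trip identity for CSI is therefore exact at the
serialized-byte level, while BAI round trips are structurally exact.

Tabix presets map columns to intervals: BED uses its 0-based half-open
columns as-is, GFF converts the 1-based inclusive pair, and VCF derives the
end from the REF allele length so deletions remain findable by any covered
base (symbolic-allele `END` tags are not parsed).  The in-memory `regidx`
intersector accepts unsorted input and attaches source line numbers as
payloads — the minimal attachment that lets callers recover their own
records.

## The multi-region iterator

Regions are merged per reference when overlapping or adjacent, chunk lists
are unioned, and chunks are additionally coalesced when the gap between
them lies within one compressed block, so no block is inflated twice.  Each
chunk is scanned once and a record is emitted if it overlaps any merged
region; since coalesced chunks are disjoint and each record lives at one
file position, once-only emission is structural rather than enforced by
hashing.  Output order is file order within each reference, references in
dictionary order.  The BGZF handle counts inflated blocks, which is how the
tests verify that merged iteration does no more I/O than the sum of
independent per-region queries.

## Pileup and BAQ

The pileup engine pivots coordinate-sorted records into per-position
entries.  Records flagged unmapped, secondary, QC-fail or duplicate are
dropped by default.  A record contributes one entry to every column of its
reference span: deletion (`D`) and reference-skip (`N`) positions carry
marker entries that count toward depth — matching classic mpileup output,
where `*` is counted — so the conservation law *total depth = sum of
post-filter reference-consuming spans* holds exactly and is asserted in the
tests.  Insertions attach as `indel = +n` on the entry at the preceding
base and add no columns.

BAQ (base alignment quality) realigns each read against its reference
window with a glocal profile HMM (match/insert/delete states; gap-open
probability 1e-3, gap extension 0.1, band half-width 7 — the reference
tool's published defaults, chosen here because the method's description
names no numbers).  Match states emit the read base with probability
`1 - eps` on agreement and `eps/3` otherwise, where `eps` comes from the
base quality; inserts emit uniformly.  The per-base posterior of occupying
the match state of the base's original reference column is converted to a
phred score, and the returned quality is the minimum of the original and
that score — BAQ can only lower confidence.  Insertion and soft-clipped
bases, which have no original column, keep their qualities.

The forward-backward pass runs in scaled linear space with per-row
renormalization rather than log space: at 100 bp read lengths row scaling
is numerically equivalent, avoids 10^5 log/exp calls per read, and is what
the reference implementation itself does.  The banded recursion is exact
whenever the band covers the window, which the tests exploit by comparing
it against an independently written unbanded forward-backward on sub-band
instances at 1e-9 posterior tolerance.  BAQ is applied lazily per record at
column construction.  Mate-overlap detection and quality halving are out of
scope, as are the extended/partial BAQ variants of the reference tool.

The per-column depth cap defaults to 8000 entries with a logged
truncation, mirroring common practice.

## rANS entropy coder

The byte-oriented rANS coder follows the constants of the CRAM 3.0 family:
frequencies normalized to a 12-bit total (4096) by proportional scaling
with largest-remainder correction (observed symbols never reach zero),
four interleaved states with lower renormalization bound 2^23 and byte-wise
renormalization.  State arithmetic never exceeds 2^31 and is carried
exactly in doubles, so encoder output is deterministic across platforms.
Order 1 conditions each byte on its true predecessor (context 0 for the
first byte) with the same round-robin lane assignment — simpler than
splitting the input into quarters, with the same modelling power.  The
stream header (order flag, sizes, run-length-encoded frequency tables) is
documented in `?ransEncode`; byte-level compatibility with existing CRAM
decoders is not claimed, and an independently written straight-line encoder
in the test suite serves as the byte-exactness oracle instead.

Codec selection is a per-block exhaustive size trial over raw, gzip,
rANS order 0 and order 1, with ties resolved in candidate order; the raw
candidate guarantees the selected encoding never exceeds input size plus
one id byte.  The adaptive method-learning policy that a production CRAM
writer would layer on top is intentionally not reproduced — its exact
policy is not specified in the material this package is built from, so
only the measurable per-block trial is implemented.

## Synthetic data

The generator emulates a resequencing experiment at desk scale: by default
2 references of 100 kb, 10,000 reads of 70–100 bp sampled uniformly, a
0.5% per-base substitution rate, a 10% per-read chance of one 1–5 bp
indel, 10% soft-clipped ends, 2% placeless unmapped reads and 1% unmapped
reads carrying a placement position (exercising zero-span indexing).
Interval files (2000 by default) come sorted, deliberately unsorted, or
clustered around hotspots so that a large fraction overlap — the shape of
an exon-list workload for the multi-region iterator.  Tandem repeats can
be embedded at recorded coordinates to create ambiguously placeable reads
for the BAQ tests.  Generation is integer-only through R's RNG, so a fixed
seed gives byte-identical output on every platform.

What it does not emulate: platform-specific quality profiles, GC bias,
coverage waves, paired-end insert-size structure and chimeric reads.
Passing tests therefore demonstrate format correctness, index completeness
and the pileup/BAQ algebra on realistic record shapes — not robustness to
every artefact of production sequencing data.

## Problem sizes and verification

The shipped checks run the full stack at sizes a laptop handles in
minutes: 1000-case BGZF round trips, a 10,000-read cohort with 1000 random
region queries compared against brute-force scans, a 2000-region
overlap-stress iteration, 10,000-line tabix/regidx oracles, and 64 KiB
known-entropy rANS inputs measured against the Shannon bound.
`scripts/acceptance.R` recomputes all of these from scratch and writes the
numbers as JSON.  Interoperability is checked both ways against samtools
and the tabix tool where available, and every BGZF product is verified
decodable by R's own standard gzip reader.

## Known limitations

* Whole files are held in memory; the handles are not streaming readers.
  At the tool's desk scale this is irrelevant, but multi-GB inputs would
  need a chunked rewrite of the `BgzfFile` state.
* Virtual offsets above 2^53 (compressed files beyond ~137 GiB) are
  rejected, see above.
* CRAM containers, VCF/BCF parsing, sorting/merging of alignments, and
  network transports are out of scope.
* mapq 255 ("unavailable") records pass through unmodified; no validation
  level reinterprets them.
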