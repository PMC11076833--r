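---
title: "Read-level SV evidence, layout and force-calling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-level SV evidence, layout and force-calling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Long-read (PacBio/ONT) whole-genome alignments carry structural-variant
evidence in two complementary forms. Mid-read CIGAR operations encode
small-to-mid events: a deletion appears as a `D` run, an insertion as an
`I` run, an unrepresented breakpoint as a long terminal soft clip.
Larger or more complex events split the read: the aligner emits a
primary alignment plus supplementary records (linked through the `SA`
tag), and the *adjacency* between consecutive segments in read
coordinates encodes the breakpoint. svlook interprets both evidence
channels per read, draws the reads IGV-style around a candidate locus,
and re-genotypes candidate SVs (force-calling): given a VCF/BED of
candidates, it counts supporting versus reference reads at each locus
rather than discovering variants de novo.

# Ingest and quality filtering

Reads overlapping a queried window are fetched from the
coordinate-sorted BAM; primary and supplementary records of one read are
grouped, and partner segments outside the window (e.g. the far end of a
translocation) are reconstructed genome-wide from `SA` tags. Each
segment is kept only if it passes all of:

* mean base quality $\geq$ `min_mean_baseq` (default Phred 20, the
  arithmetic mean of Phred scores — not an error-probability-space mean;
  reads stored without base qualities, common in HiFi BAMs, pass with a
  warning rather than discarding the whole file);
* alignment identity $1 - \mathrm{NM}/(\mathrm{M+I+D}) \geq$
  `min_identity` (default 0.60, inclusive at the boundary);
* reference span $\geq$ `min_map_len` (default 100 bp);
* mapping quality $\geq$ `min_mapq` (default 0; exposed separately
  because the base-quality and mapping-quality filters answer different
  questions).

Filters apply per segment and a read survives if at least one in-window
segment survives: a low-identity supplementary should not discard the
primary evidence. Query coordinates are strand-corrected into the
original read orientation, so the segments of one read are ordered by
`query_start`; rare query-space overlaps between segments are resolved
by trimming the lower-mapq segment (ties trim the later one). All
internal coordinates are 0-based half-open; 1-based conventions exist
only at the parse/serialize boundaries (region strings, VCF).

# Per-read SV interpretation

For each consecutive query-ordered segment pair, with `rgap` the signed
reference gap along the strand and `qgap` the signed query gap, the
split-read signature table is:

| configuration | call | length |
|---|---|---|
| different chromosomes | TRA | — |
| opposite strands, same chromosome | INV | distance between the two junctions |
| same strand, `rgap <= -L` | DUP | `-rgap` |
| same strand, `rgap - qgap >= L` | DEL | `rgap - qgap` |
| same strand, `qgap - rgap >= L` | INS | `qgap - rgap` |

with `L = min_sv_length` (default 50 bp, the conventional SV size
floor). A reference re-visit also reads as an insertion of the
duplicated bases, so the DUP test deliberately precedes DEL/INS: the
tandem-duplication signature wins, as in split-read callers generally.
Only tandem (same-strand) re-visits are called DUP; inverted
duplications surface as INV. CIGAR `D`/`I` runs $\geq L$ contribute DEL
and INS events directly. A read with no qualifying event is `REF`.
Multi-event reads keep every breakpoint for rendering and matching; the
single display label is the type of the largest event, with length-0
translocation junctions labelling the read only when no sized event is
present. The classification is invariant under reversing the sequencing
strand of the read, which the test suite checks by mirroring segment
configurations.

Breakpoints pooled across reads are clustered single-linkage per
(type, chromosome pair), linking two breakpoints when both coordinates
agree within `tol` (default 1000 bp, the same tolerance used by the
genotyper); clusters report median positions and the supporting reads.

# Force-calling genotypes

For each candidate the evaluation window is the SV interval padded by
`max_bp_disparity` (default 1000 bp) — for insertions and breakends, a
window of the same half-width around each breakpoint. Within the window
a read is *informative* only if

* its aligned span (gaps between split segments included, exactly as a
  CIGAR-`D` alignment spans its deletion) covers at least
  `min_overlap_frac` (default 0.5) of the SV interval — for point-like
  SVs, of the ±`breakend_flank` (500 bp) breakend neighborhood; and
* it aligns at least `min_region_align_len` (100 bp) inside the window.

An informative read *supports* the candidate when it carries a
same-type event whose breakpoints each lie within `max_bp_disparity` of
the candidate's and whose length agrees with the candidate's within
`max(0.5 × SVLEN, max_bp_disparity)`. The length-agreement guard
protects against nested or neighbouring events of the same type being
counted as support; it is applied uniformly to DEL/INS/DUP/INV
(translocation junctions have no length). For point-like candidates
(INS/TRA), a non-supporting read whose alignment terminates in a soft
clip of `min_clip_len` (50 bp) or more within the disparity tolerance of
the breakend is treated as *ambiguous* and excluded rather than counted
as reference: such reads typically end inside the unrepresented
(inserted or translocated) sequence and carry no usable allele
information. Without this exclusion, homozygous insertions are
systematically dragged toward heterozygous calls by reads that truncate
inside the insertion.

The allele frequency is `AF = DV / (DV + DR)` over informative reads
only — not raw window depth, since the exclusions above are applied
first. Genotypes follow strict thresholds: `1/1` when AF exceeds
`hom_af` (0.8), `0/1` when it exceeds `het_af` (0.3), `0/0` otherwise,
and `./.` only when no informative read remains. `0/0` with evidence
present is deliberately distinct from `./.` with none. The annotated
VCF preserves record order and all non-genotype fields, adding
`GT:DV:DR:AF`; records whose `SVTYPE` cannot be interpreted pass
through as `./.` with a warning.

# Layout and subsampling

Display spans (one per read: minimum segment start to maximum segment
end on the pane's chromosome) are packed by first-fit on start-sorted
intervals: each span goes to the lowest row whose last end plus `gap`
(default 5 bp; a purely cosmetic separation) does not pass its start.
With `gap = 0` this greedy scheme is optimal for interval graphs — the
row count equals the maximum overlap depth, which the tests verify
against a sweep-line oracle. Over-dense regions are subsampled to
`max_reads` (default 200) before layout: SV-supporting reads are always
retained first and reference reads fill the remainder, sampled under a
private RNG keyed by a per-record seed so batch outputs are independent
of thread scheduling and the caller's RNG stream is untouched.

# Depth, pileup and isoforms

The depth profile is the per-bin mean of per-base coverage from
*filtered* reads, where only reference-and-query-consuming CIGAR
operations (`M`/`=`/`X`) contribute — deletions and introns break
coverage even below the SV length floor, because depth is an alignment
fact, not an SV call. The binned mass therefore conserves the total
aligned bases in the region exactly (partial final bins are averaged
over their true width). Pileup columns count `A/C/G/T/N` per position
plus deleted-base counts and insertion events anchored to the column
left of the insertion; reference bases come from an indexed FASTA when
given. Base-level display is intended for windows under 200 bp and
refuses windows above 1 kb. Isoform chains are maximal runs of
reference-consuming non-`N` operations per read; identical chains are
not collapsed into transcripts — grouping is left to the display, and
no quantification is attempted.

# The simulator and what it does (not) show

Fixtures are generated hermetically: a random reference, a donor
haplotype pair built by applying each SV (`DEL` removes sequence, `INS`
inserts random sequence, `DUP` tandem-duplicates, `INV`
reverse-complements, `TRA` exchanges two reference arms balanced-wise),
uniform read sampling per haplotype, substitution errors, and alignments
synthesized directly from the known donor-to-reference block map —
split records with consistent `SA` tags, no external aligner. Both
sequencing strands are emulated by mirroring half the reads. Defaults
describe a HiFi-like experiment: 10 kb reads, 30× total depth (15× per
haplotype), 0.2% substitution errors, no indel errors (keeping CIGAR
truth crisp), constant Q30 base qualities. Cohort SV lengths are drawn
uniformly from 100–1000 bp — the bulk of the genome-wide SV size
distribution sits in this range — with each SV centred on its own 30 kb
contig so that 10 kb reads see both flanks.

Because alignments are synthesized, passing tests demonstrate the
correctness of the evidence extraction, classification, layout and
genotyping logic under controlled truth; they do not demonstrate
robustness to real aligner behaviour (reference-biased split placement,
micro-homology shifting breakpoints, indel-rich error profiles,
segmental duplications attracting mismapped reads). The 1000 bp
disparity tolerance absorbs modest breakpoint wobble, but alignment
artifacts beyond that are out of the simulator's vocabulary.

# Numerical and design choices

* Problem sizes in the test suite: the recovery experiment uses 100
  loci (20 per type, alternating het/hom) at 30×/10 kb; unit tests use
  ~9 kb contigs at 20×/3 kb reads, which keeps the full suite in a few
  minutes while preserving every code path.
* Degenerate inputs: empty regions return empty results, an empty VCF
  round-trips to an empty annotated VCF with the augmented header, zero
  informative reads yield `./.`, regions beyond the contig end are
  clipped with a warning, and a missing BAM index is an instructive
  error rather than a silent scan.
* Ties: first-fit prefers the lowest row index; equal-mapq query
  overlaps trim the later segment; equal-length events label the read
  by the first encountered.
* The CLI exposes the five subcommands with one figure plus one JSON
  sidecar per record; the sidecar carries exactly the values drawn, so
  the figures are testable without pixel comparison and rendering can
  never alter analysis results. The historical misspelled quality flag
  (`--quanlty`) is accepted as a hidden alias of `--quality`, which
  binds to *mean base quality* (mapq has its own threshold).

# Known limitations

No realignment, local assembly or breakpoint refinement is attempted —
a read is evidence exactly as the aligner left it. INV calls are
emitted from any opposite-strand adjacency without requiring both
inversion breakpoints in-window. Genotyping assumes a diploid sample
and two thresholds; there is no likelihood model, no mosaic fraction
estimation, and depth is not used as an orthogonal CNV signal.
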