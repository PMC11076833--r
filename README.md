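# svlook

IGV-style visualization and force-calling of structural variants (SVs)
from long-read BAM files.

Long-read aligners leave SV evidence in two places: mid-read CIGAR
operations (`D`/`I` runs, long terminal soft clips) and split alignments
(primary + supplementary records linked by `SA` tags, whose adjacencies
in read coordinates encode breakpoints). Manually curating candidate
SVs in a genome browser from this evidence is slow and error-prone, and
read-support-based genotypes from discovery callers are often
unreliable. svlook is for people who already have candidate SV
intervals (a VCF from sniffles/cuteSV/pbsv, or a BED) and want (a)
publication-ready static figures that make the per-read evidence
legible, and (b) re-computed ("force-called") genotypes for those
candidates.

## Method in brief

Reads overlapping a candidate window are filtered per segment (mean
base quality ≥ Q20, alignment identity `1 − NM/(M+I+D)` ≥ 60%,
reference span ≥ 100 bp). Each read is then classified from its
evidence: for every consecutive query-ordered segment pair with signed
reference gap `rgap` and query gap `qgap`,

| signature | call |
|---|---|
| different chromosomes | TRA |
| opposite strands | INV (junction distance) |
| `rgap ≤ −L` | DUP (`−rgap`) |
| `rgap − qgap ≥ L` | DEL |
| `qgap − rgap ≥ L` | INS |

with `L` = 50 bp by default; CIGAR `D`/`I` runs ≥ `L` yield DEL/INS
events directly. For genotyping, a window read is informative if its
aligned span covers ≥ 0.5 of the SV interval (±500 bp breakend
neighborhood for insertions/breakends) and aligns ≥ 100 bp in the
window; it supports the candidate if it carries a same-type event with
every breakpoint within 1000 bp of the candidate's. The allele
frequency `AF = DV/(DV+DR)` over informative reads gives the genotype:
`1/1` if AF > 0.8, `0/1` if AF > 0.3, else `0/0` (`./.` with no
informative reads). Figures lay reads out by greedy first-fit interval
scheduling (optimal row count for interval graphs) and every figure
gets a JSON sidecar with exactly the values drawn.

A hermetic simulator (`simulate_locus()`, `simulate_cohort()`) builds
reference FASTA + truth VCF + aligned BAM with implanted
DEL/INS/DUP/INV/TRA of known genotype — alignments synthesized from the
known coordinates, no aligner needed — so the whole stack is testable
offline.

## Worked example

Simulate a heterozygous 500 bp deletion at 30× with 10 kb reads, then
force-call it and look at the read-level evidence:

```r
library(svlook)

cfg <- sim_config(seed = 7, ref_length = 30000, depth = 30, read_length = 10000,
                  sv_specs = data.frame(type = "DEL", pos = 14750, length = 500,
                                        genotype = "0/1"))
sim <- simulate_locus(cfg, tempdir(), stem = "example")

(q <- read_sv_queries(sim$vcf))
#>         id  chrom start   end sv_type sv_length mate_chrom mate_pos
#> ID example locus1 14750 15250     DEL       500       <NA>       NA

genotype_sv(sim$bam, q[1, ])
#> <genotype> 0/1  DV=22 DR=25 AF=0.468
```

22 reads support the deletion, 25 informative reads look like
reference; AF 0.468 exceeds the 0.3 heterozygous threshold but not the
0.8 homozygous one, so the call is `0/1` — the simulated truth. The
per-read classification and the pooled breakpoint cluster agree with
the implanted event:

```r
groups     <- load_region_reads(sim$bam, "locus1:13000-17000")
structures <- classify_reads(groups, min_sv_length = 50)
table(vapply(structures, `[[`, "", "sv_type"))
#> DEL REF
#>  22  43

cluster_breakpoints(structures, tol = 1000)[, c("sv_type","pos_a","pos_b","sv_length","support")]
#>   sv_type pos_a pos_b sv_length support
#> 1     DEL 14750 15250       500      22

browse_sv(sim$bam, q[1, ], "example_del.png")   # figure + example_del.png.json
```

The sidecar JSON lists each drawn read with its row, type, length and
printed labels, so figure content is scriptable and testable.

## Command line

`exec/svlook` exposes five subcommands mirroring the library:

```sh
svlook sv_browse          -i sample.bam -b candidates.vcf -f vcf -o figs \
                          --quality 20 --sv_min_length 50 -F png --thread 4
svlook snpindel_browse    -i sample.bam -b regions.bed -o figs -r ref.fa
svlook regiondepth_browse -i sample.bam -r chr1:1,500,000-1,600,000 -o figs
svlook rna_browse         -i isoseq.bam -b genes.bed -o figs --genepred models.genePred.gz
svlook sv_genotyping      -i sample.bam -b candidates.vcf -f vcf -o gt
```

`sv_browse` writes one figure + sidecar per record (multiple `-i` BAMs
stack as sub-panels); `sv_genotyping` writes
`<stem>.genotyped.vcf` with `GT:DV:DR:AF` per record, order and INFO
fields preserved.

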