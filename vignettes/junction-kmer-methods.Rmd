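---
title: "Detecting and quantifying splice variants of a targeted gene with junction k-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying splice variants of a targeted gene with junction k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescout)
```

## The problem and the approach

Targeted long-read amplicon sequencing of a single gene — a forward primer
in the first annotated exon, a reverse primer in the last, PCR, then
nanopore sequencing of the product — yields reads that each span an entire
mature mRNA. A single read can therefore witness a complete transcript
structure: which exons were joined, whether an intron was retained, and
which 5' form of the first exon the molecule carries. The catch is the
error profile: per-base substitution/indel rates in the several-percent
range rule out exact full-length sequence comparison.

`splicescout` detects structures through short diagnostic k-mers instead
of alignment. For a gene with $n$ annotated exons, every one of the
$\binom{n}{2}$ ordered exon pairs $(i, j)$, $i < j$, is a possible
splicing event — the $n - 1$ adjacent pairs are the annotated junctions,
the rest are exon-skipping events. Each junction is materialized as the
set of k-mers that straddle the spliced boundary: with k-mer length $k$
and minimum flank $m$, the k-mer at boundary offset
$o \in \{m, \dots, k - m\}$ is the last $o$ bases of the donor exon
followed by the first $k - o$ bases of the acceptor exon, giving
$k - 2m + 1$ k-mers per junction. A junction k-mer occurs in a read if
and only if that read contains the spliced boundary copied without error
over a window of $k$ bases — so the multiple offsets act as independent
chances to survive read errors, and matching stays exact and trivially
verifiable against a sliding-window oracle.

Introns are additionally tiled with k-mers (fixed stride, final tile
right-aligned, introns shorter than $k$ giving one short tile) so that
intron retention shows up as dense tile coverage inside a read. Amplicon
anchors — the first-exon and last-exon segments bounded by the primer
sites — are tiled the same way; their presence at both ends defines a
full-length read. Alternative 5' starts of exon 1 get one probe k-mer per
form, placed at each alternative start position.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `k` | 24 nt | k-mer length for junctions, tiles, anchors, probes |
| `min_flank` | 8 nt | minimum exon sequence on each side of a junction k-mer (9 offsets per junction at the defaults) |
| `stride` | 12 nt | tiling stride for introns and anchors |
| `min_offsets` | 2 | distinct offsets required to call a junction within one read |
| `retention_frac` | 0.8 | fraction of an intron's unambiguous tiles required to call retention |
| `min_support` | 3 reads | pooled support required to report a novel variant |
| `min_len_aa` | 25 aa | minimum ORF length considered |
| `nmd_threshold` | 50 nt | premature-stop distance rule (last-junction model) |
| `pseudocount` | 0.5 | additive constant in the log2FC ratio |

`k = 24` balances two pressures: shorter k-mers survive read errors more
often, longer k-mers are more likely unique within the locus and across
the dictionary. `min_offsets = 2` discounts single chance matches on
error-heavy reads. The retention threshold of 80% of tiles distinguishes a
retained intron from stray intronic fragments. `min_support = 3` encodes
"validated by multiple reads" while the low-support table preserves every
below-threshold group for audit. All are exposed as arguments.

### Ambiguity screening

Exact matching is only meaningful if each retained k-mer is diagnostic of
exactly one event. `screen_ambiguity()` counts each k-mer in the locus
(both strands) and across the dictionary itself: junction k-mers are
expected zero times in the locus (they span spliced boundaries), tiles,
anchors and probes exactly once on the forward strand. Anything in excess
— including any reverse-strand occurrence, which would corrupt the
orientation vote — flags the k-mer ambiguous and removes it from
scanning; entries that share a sequence are tolerated only when they all
mark the same unique exonic position (an exon-1 start probe coinciding
with an anchor tile). A junction that loses all of its k-mers triggers a
warning naming it.

## From hits to structures

Reads are scanned in both orientations (the orientation with more hits
wins; ties go forward — a tie with zero hits is vacuous). Within a read:

* a junction is *observed* if at least `min_offsets` distinct offsets hit;
* an intron is *retained* if at least `retention_frac` of its unambiguous
  tiles hit;
* observed junctions and retentions each contribute an adjacency edge
  donor → acceptor, and the edge set must describe one molecule: no two
  edges share a donor or an acceptor, no interleaving, hit positions
  non-decreasing with exon order, and a spliced junction cannot coexist
  with retention of the same intron. Violations mark the read
  *conflicted* — conflicted reads are data (chimeras, template switches)
  and are counted but never create calls.

The exon chain is rebuilt by walking the edges from exon 1 to the last
exon. The walk never fills gaps silently: if an exon has no observed
outgoing edge before the last exon is reached, the read is unresolvable
and contributes nothing. This is the deliberate conservative choice — a
skipping junction $(i, j)$ asserts that $i$ and $j$ are adjacent in the
mature mRNA, but the exons before $i$ and after $j$ are only included
when their own adjacent junctions were seen in the same read. With
several alternative exon-1 forms, the 5'-most form whose probe k-mer was
seen is assigned; reads of a longer form necessarily contain the shorter
forms' probes, so this rule is exact on error-free reads, while a read
with no probe hit at all is unresolvable rather than guessed.

Full-length (both anchors), conflict-free, resolvable reads are grouped
by identical structure; groups matching an annotated transcript report
under its name, the rest become novel calls when pooled support reaches
`min_support`, numbered `<gene> v.<n>` continuing after the annotated
count, in the deterministic order (exon count descending, lexicographic
chain, retained introns, exon-1 form). The numbering is reproducible but
arbitrary where the published numbering of real variants followed
unstated criteria; a name map can impose any external naming.

## Coding potential

For each called structure the mature mRNA is assembled (retained introns
spliced in, exon 1 truncated to its 5' form) and scanned for all
forward-frame ATG→stop ORFs with an in-frame stop inside the sequence. If
an ORF starts at an annotated initiation codon (genomic coordinates
mapped through the structure), the 5'-most such ORF is selected —
transcripts that keep the annotated start use it even when a longer
downstream ORF exists. Otherwise the longest ORF is selected, modelling
initiation at an alternative codon when skipping removed the annotated
start. A stop codon ending more than 50 nt upstream of the last
exon–exon junction marks the transcript an NMD candidate (treated as
non-coding downstream); a retained intron removes the junction it
replaces, so retention can rescue an otherwise premature stop. Coding
products under 100 aa are flagged micropeptides. The 50-nt rule is the
standard exon-junction-complex model; the threshold is an argument
because the boundary is an empirical convention, not a law.

## Quantification

Abundance is the raw number of full-length supporting reads per variant
and sample. Size factors are median-of-ratios: rows with all-positive
counts define per-row geometric means, and each sample's factor is the
median of its count/geometric-mean ratios (a `poscounts` variant is
available for sparse matrices). Expression of each novel variant is
reported as

$$\log_2 \frac{\mathrm{norm}(v, s) + 0.5}{\sum_{a \in \mathrm{annotated}} \mathrm{norm}(a, s) + 0.5}$$

i.e. the log2 fold change of the novel variant against the summed
annotated transcripts of its gene. The summed denominator (rather than
the single most abundant annotated form) is the package's reading of
"relative to the annotated mRNA(s)"; `denominator = "max"` preserves the
alternative. The pseudocount keeps zeros finite and is reported in the
output metadata. Two properties worth knowing: size factors are invariant
to row permutation and all-zero rows, and rescaling a sample's library
moves all factors by a common geometric-mean renormalization — so
normalized counts are defined up to a global scalar and every log2FC is
scale-invariant, but absolute normalized counts are not comparable across
independently normalized matrices.

## The simulator: what it emulates and what it does not

The generator draws a random-base locus with the requested exon/intron
layout, plants an ATG at the start of exon 2 as the annotated initiation
codon, and redraws (up to 100 times) until the default dictionary screens
with zero ambiguous k-mers — so synthetic loci are k-mer-unique by
construction, unlike real genomic sequence where the screen actively
excludes repeats. Reads are full-length amplicon copies: random
orientation, per-base substitution/insertion/deletion at configured rates
(defaults 1.5% / 2% / 2.5%, the R9.4.1-era regime), optional single-end
truncation, constant placeholder qualities. The `ras_like_preset()`
bundles three gene setups that mirror the targeted-RAS topology — six
exons with two exon-1 5' forms differing by 13 nt, seven exons, and seven
exons with a retainable final intron — with annotated transcripts four
times more abundant than the planted novels and per-sample multipliers
(1, 1.5, 0.5).

Not emulated: signal-level behaviour, quality-score structure, PCR
chimeras, homopolymer-biased indels, and real inter-gene sequence
similarity. Passing tests on this generator therefore demonstrate the
logic of detection, calling, classification and quantification under a
neutral error model; they do not certify recall on real nanopore data,
where error clustering and locus repeats can only make detection harder.

## Sensitivity under the error model: an honest accounting

Exact matching bounds per-read sensitivity. A junction k-mer survives
only if its $k$-base window is error-free; at a total per-base error rate
$e \approx 0.06$ that is $(1 - e)^{24} \approx 0.23$, and the chance that
at least two of the nine offsets survive — equivalently, a clean run of
about 25 nt spanning the boundary — is roughly 0.3. Because a structure
call requires *every* junction of the transcript observed in the same
read, an $n$-junction chain survives with probability $\approx 0.3^n$:
about 3% of reads for a three-junction variant, under 0.3% for a
five-junction chain. At 20× coverage per variant this leaves expected
support below the reporting threshold for most multi-junction
structures, so recall in the 6%-error regime is low (the error-free
regime recovers everything exactly). Precision is high but not perfect
there either: with two exon-1 5' forms, a read of the longer form that
loses its discriminative probe k-mer to errors while keeping the shorter
form's probe is assigned the shorter form, and when enough such reads
agree they can support a chain/5'-form combination that was never
planted. This is a structural property of exact-match detection with a
conservative no-gap-filling rule, not a tuning accident: shortening k
raises per-window survival but destroys dictionary uniqueness, and
filling unobserved adjacent junctions would trade the near-zero
false-positive behaviour for invented structure. The package reports the
measured recall and precision rather than engineering around them; real
deployments of this detection style compensate with sequencing depth in
the thousands of reads per variant, where even percent-level per-read
sensitivity yields many supporting reads.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 I/O converts to
  1-based inclusive. Minus-strand genes store exons in transcription
  order and all sequence operations return 5'→3' mRNA.
* Tiling of a region shorter than $k$ yields one short-flagged tile of
  the whole region; a junction whose flanking exon cannot supply an
  offset skips that offset and errors only when no offset remains.
* Orientation ties go forward; a read of Ns scans to zero hits and empty
  evidence, not an error. Empty evidence yields an empty, exportable call
  set.
* Grouping, naming, scoring and every output table are independent of
  input row order; the simulator is byte-reproducible under a fixed seed
  (integer Mersenne-Twister streams only).
* Problem sizes used by the shipped analyses and checks: the toy 4-exon
  fixture for oracle comparisons; three-gene presets at 50× (error-free)
  and 20× (6% error, ten read-error seeds) with three sample pools —
  sizes chosen so the full suite re-runs comfortably on one CPU.

## Known limitations

* Novel exons and exon extensions are reported as retained intronic tile
  clusters, never assembled into new exon boundaries.
* Exon-1 5' forms are modelled as transcript 5' truncations sharing the
  exon's 3' boundary; per-read form assignment degrades with read errors
  because the longer form's absence of a probe hit is then ambiguous
  (such reads are dropped, never guessed).
* Support for a novel call is pooled across samples; a variant seen once
  in each of three pools counts as three.
* The NMD call is the 50-nt heuristic on the mature structure; it uses no
  expression evidence and no degradation measurements.
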