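---
title: "Structural annotation of full-length transcript isoforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural annotation of full-length transcript isoforms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoforge)
```

## Scope

isoforge structurally annotates full-length transcript reads (Iso-Seq-style
FLNC reads) that have already been error-corrected and spliced-aligned to a
reference genome. It covers the downstream analysis chain: retention
filtering and redundancy collapse of aligned reads, grouping into gene loci,
three-way novelty classification, fusion-transcript calling from chimeric
alignments, alternative-splicing (AS) event typing, splice-site dinucleotide
census, splice-junction context assignment, polyadenylation-site clustering
with APA calling, and the merge of novel isoforms with the reference
annotation into a unified library. Alignment itself, error correction,
coding-potential prediction, expression quantification and functional
annotation are out of scope.

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
BED12 (0-based half-open) conversion happens only in the readers and
writers. This makes interval arithmetic unambiguous — a gene spanning
`[1, 5000)` has size 4999 — and every statistic notes it where it matters.

## Retention and collapse

Aligned single-segment reads are first collapsed into structure groups:
same chromosome and strand, identical intron chain, and terminal exon ends
within a tolerance (`fuzz`, single-linkage on both ends). The intron chain
is the identity of a spliced isoform, so it is matched exactly; only the
transcript ends, which vary with RNA degradation and polyA scatter, are
fuzzed. The default tolerance is 0 bp for multi-exon reads and 10 bp for
single-exon reads (which have no intron chain and are matched
positionally); pipelines running on data with 3'-end scatter should widen
the multi-exon tolerance to about three times the scatter standard
deviation (the analysis scripts use 24 bp against a simulated 8 bp sd).

A group is retained when any of three clauses holds, combined by OR:

1. it contains at least `min_reads` (default 2) FLNC reads;
2. any member read's **global** percent identity is strictly above
   `min_pid` (default 99 — note the strict inequality: 99.0 exactly fails);
3. every intron of the group representative is present, with exact
   boundaries, in the short-read junction-support set or among the
   annotation's introns. Single-exon representatives have no introns and
   satisfy this clause vacuously.

The representative is the member with the longest exonic span. Clause 3
uses exact boundary equality because junction support is meaningful only
when both splice sites agree. Global (not local) identity decides clause 2
since the clause speaks about the read as a whole. Retention is monotone in
the junction-support set by construction.

## Loci and novelty

Retained isoforms and annotation transcripts form the nodes of an overlap
graph. Two transcripts are connected when they are on the same chromosome
and strand, share more than `min_frac` (default 20%) of **both** exonic
lengths, and at least one exon-to-exon overlap exceeds `min_frac` of the
shorter exon. Gene loci are the connected components. Exonic (not
genomic-span) overlap is used: the companion clause "at least one exon
overlap" only makes sense exon-wise, and span overlap would chain genes
through intron-nested neighbours. Making loci strand-specific means an
isoform antisense to a known gene automatically founds its own locus, which
is exactly how the opposite-strand novelty rule is stated.

Each discovered isoform in a locus is labelled:

* **novel** — the locus contains no annotated transcript (sub-threshold
  overlap or opposite strand);
* **known_novel** — the locus is a known gene, but the isoform's splice
  structure is new;
* **known_known** — the isoform reproduces an annotated structure.

What counts as "new structure" was a genuinely open design point. A literal
new-splice-site test (any intron boundary absent from the gene's annotated
boundary set) misses two common cases: a skipped exon joins two boundaries
that are both individually annotated, and a retained intron introduces no
boundary at all. Both are unambiguous novel isoforms. The default
(`new_site_mode = "chain"`) therefore labels an isoform known only when its
intron chain exactly matches an annotated transcript of the gene, with the
single-exon rule below; the literal boundary-level and whole-intron-level
tests remain available as `"boundary"` and `"intron"` modes for comparison.
Single-exon isoforms carry no splice structure, so they are compared by
exon multiplicity: a single-exon isoform in a gene with only multi-exon
annotated transcripts is a novel isoform, and vice versa.

The partition table counts isoforms exactly once per label. For loci two
counting modes exist: `"disjoint"` (default) counts each locus once, under
its most novel member (novel > known_novel > known_known), so locus rows
sum to the total; `"overlapping"` counts a locus under every label it
contains. Annotated genes without any discovered isoform are kept in the
locus set but never counted in the partition.

## Fusion transcripts

Only multi-segment (chimeric) alignments can produce fusion calls. The four
rules, all configurable:

1. the segments hit two or more annotated gene loci, and consecutive
   segments overlap by fewer than 10 bp **in read coordinates** — a clean
   breakpoint. Reading the 10 bp cap genomically would be self-defeating
   (a read overlapping a locus by under 10 bp has not meaningfully hit it),
   so the default applies it at the breakpoint; a genomic variant — the hit
   gene loci may overlap each other by fewer than 10 bp — is available via
   `locus_overlap_mode = "genomic"`.
2. every pair of hit loci is on different chromosomes or more than 50 kb
   apart;
3. global identity ≥ `min_global_pid` (default 10 — deliberately weak,
   since a chimera aligns each half elsewhere and whole-read identity can
   legitimately be low; per-segment identity carries the screen) and every
   segment's local identity ≥ 90;
4. every hit locus is supported by at least 2 short reads. Support is
   evaluated against the junction-support set, which carries read counts:
   counts of junctions exactly matching the introns of the segments
   hitting the locus are summed (for intron-less segments, junctions
   overlapping the segment span). This definition uses only inputs the
   pipeline already has; dedicated breakpoint-spanning evidence is a
   documented limitation.

Calls are typed inter-chromosome when the segments span two or more
chromosomes, intra-chromosome otherwise, and `inter + intra = total` always
holds. All four thresholds act monotonically: tightening any of them can
only shrink the call set.

## AS events

Events are detected between every pair of discovered isoforms of a locus
and deduplicated by (type, coordinates), so one biological event shared by
several pairs counts once. The ten categories:

* **SKIP / MSKIP** — an intron of one isoform spans one / several whole
  exons of the other, with the flanking junction boundaries matching
  exactly. Coordinates are the span of the skipped exons.
* **IR / MIR** — an exon of one isoform spans one / several introns of the
  other exactly, boundary-matched at the flanking exon edges. Coordinates
  are the retained intron span.
* **AE** — two introns share one boundary exactly and differ at the other,
  and no whole intron of either isoform lies inside the differing-boundary
  gap (that guard stops exon-skipping junctions from double-reporting as
  AE). Coordinates are the gap.
* **XSKIP / XMSKIP / XIR / XMIR / XAE** — the same topologies with the
  matched boundaries allowed to differ by up to `fuzz` bp (default 10)
  instead of exactly. For XAE the side with the smaller offset plays the
  shared boundary; choosing the smaller offset keeps the detector monotone
  in `fuzz` (growing the tolerance can only add events) and makes `fuzz = 0`
  empty all X categories.

Differences confined to transcript start/end sites are not AS events.
Events are reported both as event counts and as per-type gene (locus)
counts, since summaries in this field conventionally report gene counts.

## Splice-site census and junction context

For every intron the donor is its first two bases and the acceptor its last
two, read in transcription orientation (reverse-complemented on the minus
strand) and classified as GT-AG, GC-AG, AT-AC (U12-type) or other; `N`
bases never match a canonical motif and land in "other", which keeps masked
genomes deterministic.

Junctions are placed in genomic context by their donor position with
precedence CDS > UTR > intron > intergenic: inside any annotated CDS
genomic span → CDS; otherwise inside an mRNA exon on the 5'/3' side of that
transcript's CDS (side resolved by strand) → UTR; otherwise inside an
annotated transcript span → intron; else intergenic. Span-level CDS
containment (rather than exon-resolved) is deliberate: a junction's donor
base is by definition intronic in its own transcript, so exon-resolved
assignment would send every annotated junction to "intron" and the
CDS-dominated distribution typical of real transcriptomes could never
arise.

## PolyA sites and APA

Single-segment reads are assigned to the locus their exon chain overlaps
most; each read contributes its 3'-terminal aligned base (rightmost on
plus, leftmost on minus). Per gene, ends are single-linkage clustered —
sorted positions split where consecutive ends are more than
`cluster_radius` apart — and clusters with at least `min_support` reads
become sites, represented by the modal member position (ties resolve
downstream in transcription direction). A gene with two or more sites shows
APA.

The defaults (24 bp radius, 2 reads) follow the convention of long-read
polyA pipelines and are declared parameters, not inferences from data. Two
monotonicity caveats are worth knowing: the site count is antitone in
`min_support` always, but antitone in `cluster_radius` only at
`min_support = 1` — at higher support thresholds merging two sub-threshold
clusters can create one supported cluster. The property tests exercise the
radius at `min_support = 1` for that reason.

## The synthetic-data generator

`sim_config()` / `simulate_genome()` / `simulate_flnc()` /
`simulate_junction_support()` build a fully deterministic toy study: the
seed fixes everything, including ground truth. The generator emulates

* a multi-chromosome genome with non-overlapping multi-exon gene models on
  both strands, donor/acceptor motifs stamped per intron from a
  configurable class distribution, and per-transcript CDS spans with UTR
  margins;
* FLNC reads drawn from annotated isoforms, per-gene novel splice variants
  (exactly one injected edit each — skipped exon(s), retained intron(s) or
  a shifted exon end — so recovered events map one-to-one to injections),
  novel-locus transcripts placed in intergenic space, and chimeric fusion
  reads joining two genes > 50 kb apart or on different chromosomes (never
  exon-overlapping, so the breakpoint rule is testable in isolation);
* aligner-style metadata: per-read global and per-segment local percent
  identity are *simulated numbers attached to reads*, not recomputed from
  injected base errors — the pipeline consumes aligner-reported identity,
  and base-level error modelling is out of scope;
* 3' ends scattered around per-gene true polyA sites and optional 5'
  truncation; reads cycle deterministically through their gene's sites
  (counted over emitted, non-chimeric reads) so every true site accrues
  support proportional to depth — a uniform random choice could leave a
  site under any support threshold at finite depth and make exact
  site-count recovery unattainable for reasons unrelated to the caller.
  The ground truth records the emitted read count per site, and recovery is
  judged against sites with at least `min_support` reads, mirroring the
  premise under which site-count recovery is claimed;
* a junction-support set containing each true intron independently with a
  configurable coverage probability, each with a short-read count ≥ 2.

Default study conditions: 3 chromosomes × 300 kb, 30 genes of 3–9 exons
(80–300 bp exons, 120–900 bp introns, a 250 bp 3'-terminal extension
standing in for the 3' UTR), 4–8 reads per expressed isoform, 30% of genes
with a novel splice variant, expected 15% novel loci, 2% chimeric reads,
global identity 95 ± 3% and local 97 ± 2% (post-correction FLNC reads are
near-perfect; a visible tail crosses the 99% retention clause), 1–2 polyA
sites per gene spaced 100–160 bp, 8 bp 3'-end scatter, no 5' truncation
(FLNC reads are presumed full length), and 90% junction-support coverage.
Splice-site classes default to 95% GT-AG, 4% GC-AG, 1% AT-AC, the
canonical-dominated composition typical of plant genomes.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: base-level sequencing error and its interaction
with alignment, reference bias, internal priming artefacts, expression-level
variation across genes, degraded (5'-truncated) read populations beyond the
optional uniform truncation, multi-isoform reference annotations per gene,
and overlapping or nested gene models. Results on real libraries depend on
the upstream aligner and corrector in ways no synthetic test certifies.

## Numerical and degenerate-input choices

Exact integer arithmetic throughout; no floating-point coordinate maths.
Ties: the group representative prefers the longest exonic span, then the
lexicographically smallest read id; modal polyA positions resolve to the
most downstream base; locus ids order components by chromosome and leftmost
start, so outputs are stable across runs and platforms. Degenerate inputs
are first-class: empty annotations, gene-free genomes, single-exon
transcripts (no introns → vacuous junction clause, no census contribution),
empty event sets (fraction maps are empty rather than NaN), and loci whose
components merge several annotated genes (kept, flagged as warnings, and
labelled by the first gene id in sort order).

Problem sizes in the tests and the acceptance script are chosen so a full
run stays in the minutes range on one CPU: unit fixtures are hand-sized;
property suites use 10–40 transcripts per instance; recovery runs use
30–60 genes over 2–3 chromosomes, which already exercise every code path
(multi-chromosome fusions, intergenic placement, APA, all ten AS types
across seeds).

## Known limitations

* Collapse at the default 0 bp terminal tolerance treats 3'-end scatter as
  distinct structures; widen `group_fuzz` (or pre-cluster ends) on real
  scattered data, at the cost of merging genuine close-spaced APA isoforms'
  termini into one model.
* Truncated reads matching a sub-chain of a longer isoform (ISM-type
  fragments) are collapsed into their own groups, not attached to the
  parent isoform; with 5' truncation enabled the isoform count is inflated
  accordingly.
* The novelty chain test compares against the gene's annotated transcripts
  only; a structure matching a transcript of a *different* overlapping gene
  in a merged locus is still called novel for its assigned gene.
* Fusion support (rule 4) reuses splice-junction evidence; breakpoint-
  spanning short-read evidence, which a dedicated fusion caller would use,
  is not modelled.
* The AS detector is pairwise and reports structural events; it does not
  quantify inclusion levels (no PSI) and does not build an event graph
  across more than two isoforms at a time.
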