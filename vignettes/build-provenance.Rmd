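---
title: "Genome-build provenance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-build provenance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buildprov)
```

Track formats that carry nothing but genomic intervals — BED, GFF, WIG,
narrowPeak, broadPeak — are only interpretable relative to a specific
genome build, yet none of them has an obligatory field recording it. The
build is therefore best understood as part of the data, not metadata,
and this package treats it that way: it predicts the build of orphan
files, audits and injects build annotations, and quantifies what goes
wrong when coordinates from different builds are mixed. This vignette
documents the models, parameters and design decisions.

## The chromosome-size registry

A `genome_build` is a build id, species, alias set and a chromosome-size
table. The bundled tables (hg18, hg19, hg38, mm9, mm10, dm3, dm6, plus
the tiny `toyA`/`toyB` builds used by fast tests) are frozen copies of
the standard UCSC `chrom.sizes` tables, shipped as plain text under
`inst/extdata/chromsizes/` so that everything runs offline. The hg19
table is pinned by a strong invariant: its autosomes and sex chromosomes
total 3,095,677,412 bp and segment into exactly 3,095,689 1-kb bins —
both asserted in the test suite.

The *primary set* — the chromosomes used for binning — is the autosomes
and sex chromosomes (`chr1..chrN`, arm names like `chr2L`, `chrX`,
`chrY`). `chrM` and scaffold/Het/unplaced contigs stay in the size table
(they still count for compatibility scoring) but are excluded from
binning. dm3's Het/U contigs are bundled deliberately: they are the
coordinate space unique to dm3 relative to dm6, which the fixture
generator needs for discriminative placement.

Lookup is case-insensitive over ids and aliases, and every alias maps to
exactly one id. Binding the alias vocabulary to builds is a design
choice of this package (`grch37`→hg19, `grch38`→hg38, `ncbi36`/`grch36`→hg18,
`ncbi37`→mm9, `grcm38`→mm10, `bdgp5`→dm3, `bdgp6`→dm6); `ncbi37` in
particular is bound to the mouse build here, since the registry's human
builds are named by their hg ids. Users extend the registry with a YAML
config pointing at two-column `chrom.sizes` files; duplicate ids or
aliases are a hard error rather than a silent override.

Chromosome-name normalization is minimal and auditable: add or strip the
`chr` prefix, map `MT`/`M` to `chrM`, tolerate case differences —
anything else must match exactly, and unknown names are a value (`NA`),
not an error. Normalization is idempotent and never invents a name
absent from the build's table.

## Track I/O conventions

All records are normalized to 0-based half-open intervals. BED-family
formats are taken as-is; GFF is 1-based inclusive, so starts are shifted
down by one on read and restored on write; WIG `fixedStep` /
`variableStep` blocks are expanded to one interval per value honouring
`start`, `step` and `span` (WIG positions are 1-based). narrowPeak and
broadPeak are BED6+4 and BED6+3; their extra columns are preserved
verbatim so round trips are exact.

Leading `#`, `track` and `browser` lines are captured as the header;
`#` comments later in the file are tolerated but do not count as header.
Data lines that fail to parse (wrong field count, non-numeric
coordinates, `start >= end`) are collected with their line numbers,
never silently dropped. A file whose malformed fraction exceeds
`max_malformed` (default 5%) raises a strictness error; `strict = TRUE`
sets the threshold to zero. The default leaves room for the small
format deviations common in public repositories while still failing
loudly on files that are not really in the declared format — the same
failure mode a build predictor must surface rather than mask.

## Scanning and annotating build information

The scanner's vocabulary is the grep-style alternation used in
repository surveys of human, mouse and Drosophila data: `hg17 hg18 hg19
hg38 grch36 grch37 grch38 build37.2 build37.1 build36.3 ncbi35 ncbi36
ncbi37 mm8 mm9 mm10 grcm38 bdgp6 bdgp5 bdgp5.25 build5.41 build5.3
build5 build4.1 dm6 dm3 ncbi`. Matching is case-insensitive, requires no
word boundaries (so `ncbi` matches inside longer strings), and resolves
overlaps longest-token-first: `bdgp5.25` beats `bdgp5`, `build5.41`
beats `build5`, `ncbi36` beats `ncbi`. The bare `ncbi` token names no
build and is carried through flagged `low_specificity`.

`audit_file()` scans the basename — never the directory path, which is
disrupted by almost any transfer — and the first 50 lines of content,
classifying each file as `filename_only`, `header_only`, `both` or
`neither`. Whether a header scan should count only comment lines or any
leading line is genuinely open; this package scans *any* of the first 50
lines, which matches how annotations appear in the wild (track lines,
commented command lines, embedded paths). Unreadable files get an
`error` class and are excluded from percentage denominators rather than
being misreported as `neither`.

`annotate_build()` implements the three recommended repair mechanisms —
`# genome=<id>` as the first header line, a `genome=<id>` attribute on
the browser `track` line, or a `.<id>` filename tag before the
extension. Annotation is idempotent (an alias of the already-recorded
build is a no-op) and a differing existing annotation is a conflict
error: silent overwrites of provenance are worse than no annotation.
The writer emits `genome=<id>` without spaces; the scanner accepts the
spaced `genome = <id>` form too.

## Predicting the build of an orphan file

The score of build $B$ is the fraction of records whose chromosome
resolves in $B$ and whose end does not exceed the chromosome length.
This is a deliberate design: the underlying notion of compatibility is
set-theoretic (a coordinate either exists in a build or it does not),
and a fraction keeps the malformed-file failure mode visible instead of
burying it in a likelihood. The acceptance gate `min_score = 0.95`
mirrors the reader's 5% malformed-line slack.

Most records of a real file are within bounds in *every* related build
— two human builds differ in chromosome length by well under 1% — so
the score alone rarely separates them. Ties at the top score are
therefore broken only by the count of discriminative records: records
within bounds in this build but out of bounds, or on an absent
chromosome, in at least one other candidate. A strictly greater count
wins; otherwise the prediction is `ambiguous` with all tied builds
listed, which is the honest outcome for files whose coordinates are
equally compatible with several builds. Builds with identical
chromosome-size vectors are indistinguishable by construction and will
always tie. If no candidate reaches `min_score`, the file is
`incompatible` with the registry. Candidates are scored in a canonical
order, so the outcome is independent of how the candidate list is
written; species is not pre-filtered — all registry builds compete
unless a candidate list is given. Unique calls carry evidence: up to 10
discriminative records with their source line numbers.

There is no content-based inference (GC, gene models, blacklists) —
only coordinate arithmetic against the registry.

## Chain lift-over

Chains are parsed from the standard UCSC format and validated per chain:
block sizes positive, gaps non-negative, and block sums exactly
reconciling with the header's target and query spans. The best chain for
an interval is chosen by score, then longest target overlap, then lowest
chain id — a deterministic order. Within the chosen chain, block
arithmetic classifies the lift:

- `mapped`: the matched bases form one contiguous query run (no `dq`
  gap between the spanned blocks) covering at least `min_match` of the
  interval; coordinates on a minus-strand query are reflected to the
  plus strand, so outputs are always plus-strand intervals.
- `split`: matched bases span discontiguous query runs.
- `partial_below_threshold`: contiguous but under `min_match`.
- `unmapped`: no overlapping chain, or no base of the interval is
  aligned.

`min_match` defaults to 0.95, the customary same-species lift-over
threshold; it is configurable because published analyses rarely state
it. Target-only (`dt`) gaps inside an interval reduce
`matched_fraction` but do not split it, since the query bases remain
adjacent. Mapping onto a different chromosome is legal and reported as
`mapped`; the distance statistics downstream classify it. The final
short bin of a chromosome uses its true length as the matched-fraction
denominator.

The implementation locates blocks by binary search over precomputed
block offsets with prefix sums for aligned-base counts; the test suite
checks it against an independent per-base oracle that enumerates the
image of every target base, over thousands of random intervals and
chains (including minus-strand and multi-chain cases), and against
`rtracklayer::liftOver` on indel chains.

## Quantifying incompatibility between builds

`liftcheck()` segments the source build's primary set into `bin_size`
bins (default 1000 bp; per chromosome, `ceiling(L / s)` bins, the last
possibly short), lifts every bin, and summarizes:

- `pct_failed` — bins with any non-mapped status. Whether published
  failure counts include split or partial mappings is typically
  unstated; here all non-`mapped` statuses count as failed, which
  matches how the UCSC tool reports them.
- `pct_identical` — mapped bins with the same chromosome, start and
  end.
- `pct_beyond_threshold` — mapped same-chromosome bins whose midpoints
  (`floor((start+end)/2)`) lie more than 30 kb apart, reported over
  *both* denominators (total bins, and mapped bins) because the phrase
  "of the total bins" is ambiguous in the literature; the JSON report
  carries both so either reading is checkable.
- `pct_erroneous` — `100 * (n_total - n_identical) / n_total`: every
  bin that fails to keep exact coordinates would be mis-integrated by
  naive coordinate-based genome arithmetic.

Percentages are rounded to one decimal place; raw counts are always
carried alongside. Cross-chromosome mappings count toward the erroneous
fraction but not toward the beyond-threshold count. A distance histogram
(default breaks at 1, 10, 100, 1 k, 10 k, 30 k, 100 k, 1 M bp) records
the displacement distribution of mapped same-chromosome bins.

The real hg19→hg38 survey requires the public UCSC chain file, which is
not bundled; the README gives the exact command. Offline, the identical
pipeline is validated end-to-end on synthetic build pairs where ground
truth is enumerable: an identity chain must give 100% identical bins and
0% erroneous, a +40-kb bulk shift must put 100% of mapped bins beyond
the 30-kb threshold, and on a rearrangement-rich pair (bulk shift, small
indels, partially aligned bins, a chromosome with no counterpart) every
summary count must equal a per-base-oracle recomputation.

## Synthetic fixtures: what they emulate, and what not

`generate_track()` draws intervals uniformly within a build's primary
chromosomes, weighted by length, with lengths fixed or uniform in a
range (default 100–1000 bp, a typical peak-call scale). Exactly
`discriminative_count` intervals are placed on a chromosome where the
target build strictly exceeds every other candidate's length, with ends
beyond the longest other candidate — verified out-of-bounds everywhere
else by direct registry lookup in the tests. Exactly
`round(malformed_fraction * n)` data lines are corrupted in the
serialized file. Generation is deterministic: one seeded Mersenne
Twister stream per spec, RNG state isolated from the caller, identical
specs giving byte-identical files.

`generate_chain()` emits one chain per shared chromosome — the identity
map modified by ordered, non-overlapping indel edits on the target
(`dt`) or query (`dq`) side; an edit at position 0 offsets the query
start, producing bulk shifts. Generated chains always satisfy the chain
block-sum invariants.

These fixtures emulate coordinate structure only: uniform placement, no
peak shapes, no gene models, no chromatin-driven clustering, and no
realistic inter-build rearrangement spectrum (real chain files carry
thousands of chains with centromere-scale insertions and
strand-flipping segments). Passing the parameter-recovery tests
therefore shows the predictor's coordinate logic is sound — 100 seeded
tracks per bundled build, each with at least one discriminative
interval, predicted uniquely and correctly 100/100, and 100
shared-coordinate tracks flagged ambiguous 100/100 — but says nothing
about enrichment-driven signals in real data, which the predictor
deliberately does not use. The problem sizes in the tests and
acceptance script (200-interval tracks, 1000 oracle intervals over ~20
random chains, megabase-scale degenerate chains) were chosen as the
smallest sizes at which every code path — discriminative placement, all
lift statuses, both threshold denominators — is exercised.

## Known limitations

- Builds with identical chromosome-size vectors cannot be separated and
  are reported as ambiguous by design.
- Binary formats (BAM, bigWig, bigBed, VCF) are out of scope; convert
  to a supported text format first.
- Lift-over is single-hop; A→B→C chaining is not composed.
- Reproducing a specific published lift-over failure count depends on
  the exact tool settings (minimum match, multiple-output handling)
  used there; `min_match` is exposed for that reason.
- The registry bundles primary chromosomes (plus dm3's extra contigs);
  files dominated by alt/random contigs will show depressed scores
  unless the registry is extended with full size tables.
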