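---
title: "genotab: data model and processing semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genotab: data model and processing semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genotab)
```

genotab treats every genomic data file — VCF, BED, GFF/GTF, PSL, WIG, or
arbitrary delimited text — as the same thing: a rectangular table of text
cells. This vignette explains the model behind that choice, the semantics
of each operation, the numerical and design decisions that were genuinely
open, and what the synthetic generators do and do not emulate.

## The table model

A `gtable` holds ordered, equal-length columns of character cells.
Three decisions shape everything else:

* **Cells are verbatim text.** A cell is never rewritten by parsing:
  `1` and `1.0` stay distinct, key joins compare trimmed text, and
  exporting a table reproduces the input bytes cell for cell. Each column
  carries an *inferred type* (`integer`, `real`, `flag`, `text`) used only
  to validate numeric predicates and export bindings. Inference is
  idempotent — re-inferring an inferred column returns the same type —
  and an all-missing column is text.
* **Missing is a singleton sentinel** (`NA`), distinct from the empty
  string. Input dialects map a user-specified symbol (possibly the empty
  string) onto it; exports render it back as whatever symbol the caller
  chooses. Both an empty cell and a symbolic `.` can therefore denote the
  same internal state without ambiguity.
* **Every row knows its source.** Provenance labels (file basenames)
  survive all operations; a horizontally merged row gets
  `left_label+right_label`. Row identity is positional — row names are
  never required of any input.

Column-name collisions (typically after merges) are resolved by
appending `_2`, `_3`, ...; the first occurrence keeps the bare name, and
a suffix that would itself collide keeps incrementing. This is
deterministic and lossless: every input column appears in every output.

Rectangularity is enforced in the single internal constructor, so no
operation can emit a ragged table.

## Reading: dialects, headers, VCF flattening

A `dialect()` bundles delimiter, comment character, missing symbol,
header policy and optional quote character. Two points were open and are
decided as follows:

* **Header auto-detection.** With `header = "auto"`, the first
  non-comment row is promoted to a header exactly when at least one of
  its cells fails numeric parsing while the cell directly below parses as
  a number. A one-row file is never promoted. The heuristic is
  deliberately simple and documented rather than clever: files where it
  guesses wrong can always say `first_row` or `none` explicitly.
* **VCF INFO flattening.** Every key observed in any record — declared in
  a `##INFO` meta line or not — becomes a column `INFO.<KEY>`. Flag keys
  get `TRUE` where present and missing elsewhere; `key=value` pairs keep
  the raw value text. Values are *not* coerced using the `Number=`/`Type=`
  declarations, because the non-canonical keys this feature exists for
  have no declaration to trust; the ordinary column type inference takes
  over instead. Multi-allelic `ALT` cells stay as one comma-joined cell:
  the engine processes tabular text and does not impose variant
  semantics. GTF shares the GFF reader (same nine columns); its
  attribute column is not key-expanded.

WIG `fixedStep`/`variableStep` blocks are expanded to one row per value
line with explicit `(chrom, start, end, value)` columns, honouring
`step` and `span` and converting the 1-based WIG starts to the canonical
convention, so a wiggle track can act as a criteria file like any BED.

## Coordinates

The canonical internal convention is 0-based half-open, chosen because
overlap arithmetic stays closed under zero-length intervals (insertion
points) and because most export targets (the BED family, PSL) already
use it. Location schemas declare how a table encodes coordinates —
three columns, chrom+pos, or `chr:start-end` locus strings — and in
which basis; conversion from 1-based closed is `start - 1`, and
1-based → canonical → 1-based round trips are identities (tested).
A chrom/pos table with a `REF` column (i.e. VCF-derived) spans
`nchar(REF)` bases, so deletions cover their full reference footprint.

Two intervals overlap when they share a chromosome and the intersection
length is positive. The edge cases are pinned down explicitly:

* a zero-length interval `[p, p)` overlaps `b` iff `p ∈ [start(b), end(b))`;
* a zero-length *stored/right* interval never overlaps anything;
* abutting intervals do not overlap.

`min_fraction` demands the intersection be at least that fraction of the
**left** (query) interval's length. The fraction is deliberately not
reciprocal — the typical use is "this variant must lie substantially
inside a region", not region-vs-region similarity — and a reciprocal
mode is out of scope. Chromosome names compare as exact strings; strand
is carried but never restricts a join unless explicitly requested.

The interval index is backed by per-chromosome `IRanges` overlap trees
with `minoverlap = 1`; zero-length queries are widened to the single
base at their point, which realises the insertion-point rule exactly,
and zero-length subjects are excluded. The index is contractually
equivalent to an exhaustive scan with the scalar predicate, and the test
suite asserts that equivalence on random data (1,000 stored intervals,
200 queries, three chromosomes) as well as through the full location
join at 500 × 500 scale.

## Merging

Horizontal joins come in two forms with one shared contract: output
columns are the left table's followed by the right's (collisions
suffixed), rows are ordered by ascending (left index, right index),
`inner` drops unmatched left rows and `left_outer` keeps them with
missing right cells. When one left row matches several right rows,
`expand_pairs` (the default) emits every pair and `first_match` keeps
the lowest right row index — a deterministic, source-order-respecting
tie-break. Key joins accept one to four column pairs; a fifth is a
specification error. Right- and full-outer modes are intentionally
absent: the motivating use cases annotate a left-hand list, and swapping
the arguments gives the right-outer effect.

Vertical merging (`append_tables`) unions column names in first-
appearance order, stacks same-named columns and fills the rest with
missing; it is associative up to cell identity. The first input's
location schema is carried over, since the spec of the operation leaves
schema propagation open.

## Filtering

Numeric predicates (`lt`/`le`/`gt`/`ge`) require a numeric-typed column
and compare cell and operand as reals; `eq`/`ne` and list membership
compare trimmed text; `contains` is a case-sensitive substring.
A row whose cell is missing cannot certify a condition, so
`on_missing = "drop"` is the default; `keep` is available for the
complementary reading. In value-list filtering a missing cell is never a
member of the list — hence it is dropped under the positive filter and
kept under `negate = TRUE` (set-complement semantics).

Criteria filtering indexes an external track (optionally pre-filtered by
a predicate on the criteria rows, e.g. conservation score > 0.85) and
keeps or drops the data rows overlapping at least one criteria interval.
For a fixed specification the two polarities partition the input rows —
a property the tests assert across 20 random fixtures — and raising
`min_fraction` can only shrink the kept set.

The sample-presence filter counts, for each identity tuple, the distinct
sample keys among its rows and divides by the total number of samples.
Two open points are resolved so:

* **Total = observed samples** (distinct sample keys in the table), not
  an external roster, because the input format carries no roster; a
  `total_samples` override supports the declared-roster reading.
* **Identity defaults to all non-sample columns**, matching the intuition
  that the "record" is whatever the remaining columns say it is.
* Rows whose sample cells are missing contribute no sample key (neither
  to the total nor to any identity's presence); a table with *only*
  missing sample cells is a data error.

## Reduction and export

`select_columns` and `deduplicate` (first occurrence wins) implement
data reduction. Tab export writes UTF-8/LF, verbatim cells, and refuses
cells containing the delimiter or a newline rather than quoting them —
a tab file that needs quoting has stopped being the interchange format
this engine exists for.

Track export always derives coordinates from the canonical intervals,
never by copying text columns, and emits them in the target's native
convention (BED family and PSL 0-based half-open, GFF 1-based closed —
so a zero-length insertion point cannot be expressed in GFF and is an
export error). Unbound fields get UCSC-spec defaults: name `.`, score
`0`, strand `.`, narrowPeak point-source `-1`, pgSnp allele count/
frequency/score `1`/`0`/`0`. Scores bound to a column must be numeric
and are clamped to [0, 1000] with a warning rather than an error,
because browser upload is the point of these formats. GFF export writes
a version-2 style group field from a single bound column; GFF3 attribute
assembly is out of scope, as is WIG export (the supported export list
deliberately omits it).

## The pipeline runner and CLI

`run_pipeline()` executes a YAML-described chain of reads, merges,
filters and reductions. The whole configuration is validated before any
data is read and **every** problem is reported at once, not just the
first; the output is written to a temporary file and renamed, so a
failing run never leaves a partial output. Logging (per-step row counts)
goes to standard error, data never does; the CLI exits 0/2/1 for
success/usage/runtime. Step files can be included by path, so itemized
sets of filtering conditions can be shared between pipelines. There is
deliberately no interactive mode: the computational semantics are the
product, the presentation layer is not.

## Synthetic generators: what they emulate, and what not

The three generators produce the inputs the engine's workflows need:

* `make_vcf_fixture()` — VCF 4.2 with declared keys (`DP`, `AF`),
  a non-canonical value key (`MYCALLER_SCORE`) on ~half the records and
  an undeclared flag key (`NOVEL`) on ~40%, multi-allelic ALT on ~10%,
  and per-sample genotype columns.
* `make_track_fixture()` — non-overlapping scored intervals (BED, GFF or
  WIG) with an *exact* count of "conserved" intervals scoring above
  0.85: `round(fraction_conserved * n)`, default 0.3 — mirroring a
  conservation-track criteria file.
* `make_multisample_fixture()` — a (chrom, pos, sample, genotype) table
  with every sample guaranteed observed and known per-locus presence
  fractions.

Both variants and criteria intervals are drawn inside a shared
20 kb-per-chromosome region (`region_length`) so that criteria filtering
has realistic, non-vacuous overlap rates. Every generator writes its
ground truth (expanded INFO maps, canonical intervals and scores,
presence fractions) alongside the file, and the tests always compare the
parsers and filters against that ground truth, never against the parser
itself. Identical seeds give byte-identical files.

What the generators do **not** emulate: linkage or allele-frequency
structure, realistic mutation spectra, chromosome-scale coordinates,
malformed-in-the-wild files (mixed line endings, misquoted cells), or
inputs beyond ~10⁴ rows. Passing tests therefore demonstrate the
correctness of the table algebra — joins, filters, conversions, round
trips — not robustness to every corrupt file or performance at
whole-genome scale.

## Problem sizes and tolerances

The test suite and the acceptance script run the overlap join at
500 × 500 intervals over three chromosomes against a full nested-loop
scan, the criteria-partition property on 20 random fixtures of 100 × 40
intervals, the sample filter on 2,000 rows across thresholds
0.25/0.5/0.75/1, and the conservation scenario at 100 criteria intervals
and 50 variants. These sizes exercise many-to-many joins, empty
chromosomes and boundary thresholds while keeping a full run in tens of
seconds. All comparisons are exact (set equality, byte identity); there
are no numeric tolerances anywhere in the engine, which is what makes
byte-identical pipeline reruns a testable guarantee.

## Known limitations

* No genome liftover, chromosome aliasing, or reciprocal-overlap joins.
* No FORMAT/genotype semantics (GT decoding, allele-depth arithmetic) and
  no record splitting of multi-allelic sites.
* No binary formats (BAM, bigWig/bigBed) and no tabix indexing;
  gzip-compressed text is accepted by suffix.
* No regular-expression predicates — the predicate set is deliberately
  closed so that configurations stay portable and auditable.
* Tables live in memory; capacity is bounded by R's vector limits and
  available RAM, not by an internal cap.
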