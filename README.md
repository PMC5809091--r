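# genotab

High-throughput experiments in genetics — microarrays, exome and genome
sequencing, ChIP and aCGH — all emit character-delimited tabular text:
VCF, BED, GFF/GTF, PSL, WIG and countless ad-hoc tab or comma files.
Real analyses constantly need to combine them: annotate a raw caller's
variant list with an external annotation table, restrict candidate
variants to regions a criteria track says are trustworthy or conserved,
collapse a multi-sample table to records shared by most samples, strip a
richly annotated table down to the columns a genome browser will accept.
Doing this robustly is harder than it sounds, because the files disagree
about delimiters, comment characters, missing-value symbols, header
conventions, coordinate conventions (0-based half-open vs 1-based closed)
and the exact content of the VCF INFO field.

genotab is a scriptable R engine for exactly this work. It is aimed at
analysts who want the operations of interval-aware table processing —
merge, filter, reduce, convert — as composable functions and as a
command-line tool, without imposing any assumptions on the internal
composition of the input files.

## The model

Everything operates on one universal structure, the **table**: ordered,
equal-length columns of verbatim text cells, with

* a distinct missing-value sentinel (never equal to the empty string),
  mapped from a user-specified symbol at read time;
* a per-column inferred type (integer / real / flag / text) that guides
  numeric filtering and export validation but never rewrites a cell;
* a per-row **provenance** label naming the source file;
* an optional **location schema** declaring which columns carry genomic
  coordinates and in which convention.

Coordinates are normalised internally to 0-based half-open intervals
(BED convention). A VCF row with position $p$ and reference allele $r$
occupies $[p-1,\; p-1+|r|)$; a GFF row with 1-based closed $[s, e]$
becomes $[s-1, e)$. Two intervals $a, b$ on the same chromosome overlap
when $\min(e_a,e_b) - \max(s_a,s_b) > 0$, and an overlap join can demand
that this quantity be at least a fraction $f$ of $|a|$. Horizontal merges
are driven either by this predicate (via a per-chromosome interval index
equivalent to an exhaustive scan) or by equality of up to **four** key
columns compared as trimmed text; vertical merging stacks tables by
column-name union. Filtering supports column predicates, external value
lists, external criteria tracks (keep or drop overlapping rows, with an
optional score pre-filter on the criteria, e.g. phastCons > 0.85), and a
sample-presence rule: a record is kept when the distinct samples carrying
it amount to at least a chosen fraction of all observed samples.
Reduction (column selection, deduplication) and export close the loop:
tab-delimited text plus the UCSC/ENCODE custom-track formats (BED, BED
detail, GFF, PSL, pgSnp, BED6+3, narrowPeak, broadPeak, gappedPeak,
peptideMapping), each emitted in its native coordinate convention.

## Worked example

Shortlist variants at conserved positions, then export a browser track —
the inputs here come from the package's own seeded generators, so the
example is fully reproducible:

```r
library(genotab)

spec <- fixture_spec(seed = 7, n_variants = 50, n_criteria_intervals = 100)
make_vcf_fixture(spec, "variants.vcf")
make_track_fixture(spec, "bed", "conservation.bed")

variants <- read_vcf("variants.vcf")$table
variants
#> <gtable: 50 rows x 15 columns>
#>   CHROM <text> | POS <integer> | ID <text> | REF <text> | ALT <text> | ... | INFO.DP <integer> | INFO.MYCALLER_SCORE <real> | INFO.NOVEL <flag> | ...
#>   chr1 | 552 | var1 | A | T | 89.3 | q10 | 76 | 0.772 | 0.92 | TRUE | GT | 0/0 | 0/1 | 1/1
#>   chr1 | 4439 | var2 | AC | T | 80.1 | q10 | 34 | 0.997 | 0.85 | <NA> | GT | 0/1 | 0/0 | 0/0
#>   ... 44 more rows

track <- read_track("conservation.bed", "bed")
kept <- filter_by_criteria(variants, criteria_spec(
  track, "keep_overlapping",
  criteria_predicate = predicate("score", "gt", 0.85)))
n_rows(kept)
#> [1] 8
```

Note the flattened INFO columns: `INFO.MYCALLER_SCORE` was never declared
in a `##INFO` meta line, and `INFO.NOVEL` is a flag key (`TRUE` where
present, missing elsewhere). Of the 50 variants, 8 fall inside the 30
criteria intervals whose conservation score exceeds 0.85. Exporting the
shortlist as a custom track:

```r
export_track(kept, column_mapping("bed", bindings = c(name = "ID")),
             "kept.bed", track_line = "track name=conserved_variants")
readLines("kept.bed")[1:3]
#> [1] "track name=conserved_variants" "chr1\t4438\t4440\tvar2" "chr1\t5174\t5175\tvar3"
```

The same workflow runs from the shell (`inst/exec/genotab`):

```sh
genotab filter --input variants.vcf --output kept.tsv \
    --criteria conservation.bed --criteria-where 'score gt 0.85'
```

or as a YAML pipeline (`genotab pipeline analysis.yaml`) whose steps are
validated — with every problem reported at once — before any data is read.
See `?run_pipeline` for the configuration schema.

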