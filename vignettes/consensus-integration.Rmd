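---
title: "Consensus variant integration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus variant integration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusvc)
```

`consensusvc` re-implements, at desk scale, the integration strategy
used to produce the 1000 Genomes GRCh38 biallelic SNV/INDEL call set:
several imperfect callers over the same samples, canonicalized into a
shared variant representation, hard-filtered on annotations, unioned
into a consensus with provenance, and evaluated against a gold
standard. This vignette documents the procedures, the tunable
parameters, and the choices made where the published pipeline left the
mechanism unstated.

## Variant representation and identity

All comparisons run on the *site key* `(contig, pos, ref, alt)` of a
normalized biallelic record. Two callers agree on a variant exactly
when their canonical keys match; genotype concordance is deliberately
out of scope (site-level comparison, as in the released evaluation
tables).

Coordinates follow both file standards bit-exactly: VCF records are
1-based inclusive, BED intervals 0-based half-open, and the conversion
happens in exactly one place (interval membership of a VCF position).
Contig order is taken from the reference; a call set on a contig the
reference does not carry is an error rather than a silent pass-through,
because normalization needs the sequence anyway.

### Left-alignment

The canonical form of an INDEL is the left-most minimal
representation. The algorithm is the trim/extend loop of the
`bcftools norm` / `vt normalize` family: repeatedly chop a shared
trailing base across all alleles, extending left with the preceding
reference base whenever an allele would become empty; finally strip
shared leading bases while every allele keeps at least one character.
The published pipeline names the tools but not the algorithm; this
loop is the convention those tools implement, and the test suite
verifies both idempotence and edit preservation against a
string-rewrite oracle (applying the variant before and after
normalization must give the same alternate contig), plus a brute-force
enumeration oracle showing the result is the unique left-most minimal
representation within a homopolymer.

A variant requiring extension past position 1 cannot be normalized and
raises an error — such a record contradicts its own contig.

### Decomposition into allelic primitives

MNPs decompose column-wise into one SNV per mismatching position. For
complex substitutions (both alleles longer than one base, different
lengths) no published convention exists, so the package declares one:
after end-trimming, the length-difference gap is placed immediately
after the first (anchor) column, yielding one simple INDEL, and the
remaining columns are compared prefix-first into SNVs. This is
deterministic and oracle-checkable: the test suite asserts that
jointly applying the children reproduces the parent haplotype exactly.
Other placements of the gap (e.g. Smith–Waterman realignment, as some
decomposition tools do) would be equally valid but are not
reproducible without pinning an aligner and its tie-breaks.

### Multiallelic split/merge and deduplication

Splitting re-codes genotype alleles that belong to a *different* row
as an "other allele" sentinel (written `.`), preserving ploidy rather
than discarding the call as missing; merging resolves the sentinel
wherever another row identifies the allele, takes the maximum QUAL,
unions the FILTER sets, and keeps only INFO keys identical across the
merged rows (conflicts are dropped with a warning — conservative and
logged). Duplicate identical keys keep the record with the highest
QUAL, first-in-input on ties; the published chain delegates this to
`vt uniq`, whose tie behaviour is unstated, so the package fixes a
deterministic rule.

The full chain is split → left-align → decompose → sort → dedup →
merge → select biallelic. A consequence worth stating: genuinely
co-located alternate alleles (two alts at one position) are merged
back into a multiallelic row and then *discarded* by the biallelic
selection, exactly as in the released pipeline. The synthetic truth
panel therefore never places two variants at the same position —
"multiallelic source material" is instead an overlapping
deletion + SNV pair at *adjacent* positions, which a merging caller
reports as one multiallelic row and the chain correctly splits back
into two distinct biallelic keys.

## Hard filtering

Filter profiles are OR-lists of threshold rules on `QUAL` or INFO
annotations with strict inequalities, matching the semantics of
`bcftools filter -e`. The released cutoff tables for the four
supporting call sets ship verbatim (`builtin_profiles()`): the
double-sided SGB annotation becomes two independent rules, and a site
missing an annotation passes that rule by default (mirroring the
short-circuit behaviour of the filter expression when a tag is
absent) while a counter records how often this happened.

The Freebayes profile rejects `QUAL < 1`. The released description
says "less than or equal to 1" in prose but `-e 'QUAL<1'` in the
command; the command is taken as authoritative, so a site with QUAL
exactly 1 passes.

Cutoff derivation (`derive_cutoffs()`) formalizes the unstated manual
step of "comparing the TP and FP annotation distributions": each
threshold is the sort-based retention quantile of the TP distribution
on the rejecting side, so a rule at retention *t* rejects at most
`(1 − t)·|TP| + 1` true positives (the order-statistic guarantee).
Annotations are thresholded marginally, one rule per annotation; joint
thresholding would require a model the source never specifies.
Retention defaults to 0.99.

## Consensus and genotypes

The consensus is the union of site keys. Site fields are advisory at
this stage — the released pipeline re-genotypes and re-filters after
the union — so QUAL is the maximum across supporters, FILTER is reset,
and only unanimous INFO keys survive. Genotype reconciliation stands
in for likelihood-based re-genotyping (genotype-given-alleles), which
is out of scope: each (site, sample) cell takes the genotype from the
highest-priority supporting call set with a non-missing call. This is
deterministic, auditable, and documented as a stand-in; it does not
attempt to emulate likelihood arithmetic.

A site is an SNV iff both alleles have length 1; everything else
routes as an INDEL, which is how the SNV-only and INDEL-only branches
are split and later re-joined by concatenation.

## Evaluation

**Concordance** restricts both call sets to the confidence regions,
counts TP/FP/FN by key per contig, and derives the percentage columns
used by the released site-comparison tables. The aggregate row is the
*unweighted mean* of the per-contig values over the autosomes — not
the pooled ratio — which is verified against the printed AVG rows of
those tables; chrX (evaluated only in the pseudo-autosomal regions)
is excluded from the aggregate, following the tables' footnote.

**Switch error** uses only assessable sites: present in both call
sets, identically heterozygous, phased in both. Sites heterozygous in
truth but homozygous or missing in the prediction are genotype errors,
not phase errors, and are excluded. A switch is an orientation change
between consecutive assessable sites; chains never cross contigs, and
no block structure is modelled (the synthetic phasing is
chromosome-scale). Phase is relative, so a global haplotype flip of
either input costs nothing. An isolated flipped site between two
same-orientation neighbours counts as two switches — whether the
published comparator counts it as one or two is not derivable from its
description, so the package documents transition counting and sticks
to it. Under per-site flips at rate *p*, the expected transition rate
is `2p(1 − p)`, which is what the parameter-recovery checks assert.

**FN attribution** looks each false-negative key up in the
pre-selection filtered call set and tallies its filter labels. The
percentage explained uses the count of *distinct* attributed sites, so
it cannot exceed 100 even if labels overlap; for the released tranche
tables (whose labels are mutually exclusive) this coincides with the
column-sum arithmetic.

## The simulator and what it does (not) show

The generator's defaults define the study conditions: 2 000 truth
sites over five contigs (two autosomes of 120 kb, a 40 kb X, a 15 kb
Y, and a 30 kb novel-assembly contig), 20 diploid samples, 15%
INDELs, 6% adjacent-SNV (MNP source) sites, 4% overlapping
deletion+SNV (multiallelic source) sites, allele frequencies from a
Beta(1.5, 3) clamped to [0.05, 0.95] (a low-frequency-skewed site
spectrum), phased Hardy–Weinberg genotypes, confidence regions
covering ~80% of each contig, a central 5% centromere-like exclusion
per autosome, and pseudo-autosomal regions covering 10% of the X at
its ends. The four default caller profiles mirror the supporting call
sets: a sensitive genome-wide caller (0.97/0.02,
canonical), an MNP-reporting caller (0.95/0.05), a low-coverage caller
with off-canonical INDEL placement (0.90/0.05), and an exome-like
caller (0.35/0.02) that merges co-located alleles. Annotation values
are Gaussian with well-separated TP/FP means (e.g. MQ 55 vs 30) so
that cutoff derivation has signal; the laws are configuration, not
code. One caller can be made blind to the novel contig to reproduce
the lift-over situation structurally.

Truth sites are placed on a 12-bp slot grid so that independently
drawn variants can never interact (a right-shifted INDEL cannot
collide with its neighbour); paired variants live inside one slot.
This is the main idealization: real variants cluster, recombine and
overlap in ways the grid forbids. Other deliberate omissions:
read-level errors, genotype-likelihood noise, linkage disequilibrium,
and reference bias. Passing the suite therefore demonstrates that the
*pipeline machinery* is correct — representation differences are
resolved, set algebra and rate estimators recover injected parameters
— not that the filters or callers would perform identically on real
sequencing data.

Problem sizes in the tests and the acceptance script (hundreds to a
few thousand sites, five phasing replicates of ~2 700 assessable het
sites) were chosen so every statistical check has comfortable power
while the whole suite completes in well under a minute per file.

## Numerical and degenerate-input conventions

* Percentages are carried at full precision internally; TSV writers
  round rates to two decimals, matching the released table layout.
* A contig with no gold sites yields undefined percentages, emitted as
  `NA` rather than zero.
* Filter thresholds compare with strict inequality; equality passes.
* Empty FILTER sets mean PASS, and `PASS`/`.` both read back as the
  empty set.
* Haploid sex-chromosome calls do not survive integration: sites on Y
  and outside the X PAR are removed during region exclusion, as in the
  released pipeline, so downstream code may assume diploidy.
* All randomness flows through explicit integer seeds; every generator
  is a pure function of (inputs, seed).

## Known limitations

The genotype reconciliation is a declared stand-in for re-genotyping;
VQSR (the model-based filter applied to the GATK call set and the
final consensus) is consumed only as pre-existing FILTER labels and
never fitted; phasing itself is simulated rather than estimated; and
the evaluation is site-level only. Gzip-compressed VCF is read and
written, but no tabix indexing is provided — call sets at this scale
are read whole.
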