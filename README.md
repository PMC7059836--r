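# consensusvc

Multi-caller consensus variant integration and benchmarking, at desk
scale.

Large joint-genotyping projects rarely trust a single variant caller.
The 1000 Genomes GRCh38 biallelic SNV/INDEL release was built by
running several callers (BCFtools on low-coverage WGS and on exome
data, GATK UnifiedGenotyper, Freebayes) over the same cohort, hard- or
model-filtering each call set, rewriting every set into a shared
canonical representation, taking the union of the biallelic sites, and
then evaluating the result against the Genome in a Bottle (GIAB) gold
standard for NA12878. `consensusvc` re-implements that integration and
evaluation machinery as a tested R package, together with a simulator
that generates multi-caller data with known truth so that every stage
can be verified end to end without any external download.

The package is aimed at people who build or audit variant-integration
pipelines: it makes each step — normalization, filtering, union,
evaluation — an explicit, testable function on plain containers.

## What it implements

**Normalization.** Callers describe the same edit in different ways.
`normalize_callset()` applies the canonical chain: split multiallelic
rows, left-align and trim each variant against the reference (the
`bcftools norm`/`vt normalize` convention: repeatedly chop a shared
trailing base, extending left with the previous reference base when an
allele would empty, then strip shared leading bases), decompose MNPs
and complex substitutions into allelic primitives, sort, deduplicate,
re-merge co-located rows and keep biallelic sites only. The chain is
idempotent and its output is unique by the site key
`(contig, pos, ref, alt)`.

**Hard filtering.** `builtin_profiles()` carries the released
annotation cutoff tables for the four supporting call sets — e.g. for
low-coverage SNVs, reject when `INFO/DP > 24304`, `MQ < 34`,
`MQ0F > 0.049737`, `HOB > 0.1643732`, `SGB > 2347.043`,
`SGB < -64440.286` or `QUAL < 20`, labelling failures `GIABFILTER`
(soft filtering; nothing is removed). `derive_cutoffs()` reproduces
the way such cutoffs are obtained: sites are labelled TP/FP against a
gold standard inside high-confidence regions, and each threshold is
placed at the retention quantile of the TP annotation distribution
(default: retain 99% of TPs per rule).

**Consensus.** `union_sites()` forms the union of normalized biallelic
site keys with per-caller provenance; `contribution_counts()` turns the
provenance into UpSet-style intersection and marginal counts;
`reconcile_genotypes()` fills consensus genotypes by caller priority;
`concat_callsets()` joins the SNV-only and INDEL-only consensus sets.

**Evaluation.** `concordance()` reports per-chromosome TP/FN/FP counts
within confidence regions with the derived percentage columns
(`pct_shared = 100·TP/(TP+FN)` of the gold sites, and so on);
`switch_error()` computes the haplotype switch-error rate — with true
haplotypes `000111|111000` and prediction `000000|111111` over six
heterozygous sites it counts exactly one switch, between sites 3
and 4; `fn_attribution()` explains false negatives by the filter
labels that removed them; `stratify_regions()` counts calls inside
novel-assembly regions versus the pre-existing genome. Per-contig
reports end in an `AVG` row, the unweighted mean over autosomes.

**Simulation.** `generate_truth()` builds a reference, a phased
diploid truth panel (Hardy–Weinberg genotypes at Beta-distributed
allele frequencies) and region sets; `simulate_caller()` derives a
caller's output with configurable sensitivity, false-discovery rate
and representation style (right-shifted INDELs, joined MNPs, merged
multiallelics); `simulate_phasing()` injects haplotype flips at a
controlled rate; `generate_gold()` downsamples the truth into a
synthetic gold standard.

## Worked example

Simulate a cohort, normalize the four callers, and inspect the
consensus and its provenance:

```r
library(consensusvc)

cfg <- simulation_config(seed = 1, n_sites = 1000)
tb  <- generate_truth(cfg)
callers <- lapply(names(cfg$caller_profiles), function(nm) {
  cs <- simulate_caller(tb$truth, cfg$caller_profiles[[nm]], tb$reference,
                        seed = 1 + match(nm, names(cfg$caller_profiles)),
                        novel = tb$regions$novel)
  normalize_callset(cs, tb$reference)
})
u  <- union_sites(callers)
cc <- contribution_counts(u$provenance)
cc$marginals
#> ex_bcftools   freebayes        gatk lc_bcftools
#>         357         993         984         955
head(sort(cc$intersections, decreasing = TRUE), 2)
#>             freebayes+gatk+lc_bcftools ex_bcftools+freebayes+gatk+lc_bcftools
#>                                    523                                    301
```

The marginals are the horizontal bars of an UpSet plot (the exome-like
caller sees far fewer sites); the intersections are the vertical bars
(most consensus sites are supported by the three genome-wide callers).

Benchmark one normalized caller against the truth panel inside the
high-confidence regions:

```r
rep <- concordance(select_class(callers[[3]], "snv"),
                   select_class(tb$truth, "snv"), tb$regions$confidence)
rep[rep$contig %in% c("chr1", "AVG"), c("contig", "tp", "fn", "fp", "pct_shared")]
#>   contig    tp fn     fp pct_shared
#> 1   chr1 241.0 23 10.000      91.29
#> 6    AVG 169.7 15  7.333      92.60
```

`pct_shared` recovers the caller's configured sensitivity (0.90) up to
binomial noise — the core of the package's acceptance checks.

A thin command-line wrapper (`inst/cli/consensusvc.R`) exposes the
same steps as `simulate`, `normalize`, `filter`, `consensus` and
`benchmark` subcommands for shell pipelines.

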