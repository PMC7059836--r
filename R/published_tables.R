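#' Released evaluation tables for the 1000 Genomes GRCh38 call set
#'
#' Small summary tables from the published evaluation of the GRCh38
#' NA12878 call set against the Genome in a Bottle (GIAB) gold
#' standard, shipped with the package so that the report arithmetic
#' (percentage columns, unweighted autosome averages, region shares)
#' can be recomputed from the raw counts and rates:
#'
#' * `switch_error_rates`: per-autosome switch-error rates (percent)
#'   for phased SNVs and INDELs, for the de novo call set
#'   (`this_work`), the lift-over call set and the phase-three call
#'   set.
#' * `fn_attribution_counts`: per-autosome counts of GIAB SNV sites
#'   missed by the de novo call set, with the number assigned to each
#'   VQSR sensitivity tranche.
#' * `site_comparison_snv`: per-chromosome TP/FN/FP counts for the
#'   SNV comparison against GIAB within high-confidence regions
#'   (chrX restricted to the pseudo-autosomal regions).
#' * `novel_contig_snv_counts`: biallelic SNV counts inside the novel
#'   GRCh38 contigs versus the pre-existing genome, for the de novo
#'   and lift-over call sets.
#'
#' @return named list of data.frames
#' @export
released_evaluation_tables <- function() {
  rd <- function(f) read.table(
    system.file("extdata", f, package = "consensusvc", mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  list(switch_error_rates = rd("giab_switch_error_rates.tsv"),
       fn_attribution_counts = rd("giab_fn_attribution_counts.tsv"),
       site_comparison_snv = rd("giab_site_comparison_snv.tsv"),
       novel_contig_snv_counts = rd("novel_contig_snv_counts.tsv"))
}
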