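# Evaluation of a call set against a gold standard: per-contig site
# concordance within confidence regions, switch-error rate of phased
# genotypes, false-negative attribution by filter label, and
# region-class stratification. Reports are data.frames with one row
# per contig plus an unweighted-mean AVG row over autosomes.

#' Unweighted mean summary row over included contigs
#'
#' @param rows a per-contig data.frame whose first column names the
#'   contig; remaining numeric columns are averaged
#' @param exclude contig names left out of the aggregate (the sex
#'   chromosomes, by convention)
#' @param contig_col name of the contig column
#' @return a one-row data.frame with contig `"AVG"`
#' @export
aggregate_report <- function(rows, exclude = c("chrX", "chrY"),
                             contig_col = "contig") {
  keep <- !(rows[[contig_col]] %in% exclude)
  if (!any(keep)) stop("all rows excluded from the aggregate")
  inc <- rows[keep, , drop = FALSE]
  out <- rows[1, , drop = FALSE]
  out[[contig_col]] <- "AVG"
  for (cl in names(rows)) {
    if (cl == contig_col) next
    out[[cl]] <- if (is.numeric(rows[[cl]]))
      mean(inc[[cl]], na.rm = TRUE) else NA
  }
  rownames(out) <- NULL
  out
}

#' Assemble a concordance report from per-contig TP/FN/FP counts
#'
#' Derived columns follow the released site-comparison tables:
#' `total_gold = tp + fn`, `total_query = tp + fp`,
#' `pct_shared = 100 tp / total_gold`,
#' `pct_gold_only = 100 fn / total_gold`,
#' `pct_query_only = 100 fp / total_query`. The AVG row is the
#' unweighted mean over contigs not in `exclude`.
#'
#' @param counts data.frame with columns `contig`, `tp`, `fn`, `fp`
#' @param exclude contigs excluded from the AVG row
#' @return a `ConcordanceReport` data.frame (per-contig rows + AVG)
#' @export
concordance_report <- function(counts, exclude = c("chrX", "chrY")) {
  df <- counts[, c("contig", "tp", "fn", "fp")]
  df$total_gold <- df$tp + df$fn
  df$total_query <- df$tp + df$fp
  df$pct_shared <- ifelse(df$total_gold > 0, 100 * df$tp / df$total_gold, NA)
  df$pct_gold_only <- ifelse(df$total_gold > 0, 100 * df$fn / df$total_gold, NA)
  df$pct_query_only <- ifelse(df$total_query > 0,
                              100 * df$fp / df$total_query, NA)
  out <- rbind(df, aggregate_report(df, exclude))
  class(out) <- c("ConcordanceReport", "data.frame")
  out
}

#' Per-contig site concordance against a gold standard
#'
#' Wraps [label_against_gold()] per contig, restricted to the
#' confidence regions, and derives the percentage columns. Select the
#' variant class (SNV/INDEL) with [select_class()] before calling.
#'
#' @param query,gold normalized biallelic `CallSet`s
#' @param regions confidence `RegionSet` (or `NULL`)
#' @param exclude contigs excluded from the AVG row
#' @return a [concordance_report()]
#' @export
concordance <- function(query, gold, regions = NULL,
                        exclude = c("chrX", "chrY")) {
  contigs <- unique(c(gold$contigs[gold$contigs %in% gold$sites$contig],
                      query$contigs[query$contigs %in% query$sites$contig]))
  rows <- lapply(contigs, function(ctg) {
    lab <- label_against_gold(
      subset_callset(query, which(query$sites$contig == ctg)),
      subset_callset(gold, which(gold$sites$contig == ctg)),
      regions)
    data.frame(contig = ctg, tp = length(lab$tp), fn = length(lab$fn),
               fp = length(lab$fp), stringsAsFactors = FALSE)
  })
  concordance_report(do.call(rbind, rows), exclude)
}

#' Switch-error rate of phased genotypes
#'
#' Assessable sites are those present in both call sets (by site key)
#' where the named sample is heterozygous with the same unphased
#' genotype and phased in both. For each assessable site the relative
#' orientation of the predicted haplotypes against the truth is
#' recorded; a switch is an orientation change between consecutive
#' assessable sites on a contig, so a global haplotype flip costs
#' nothing (phase is relative). Chains never cross contig boundaries.
#'
#' @param truth,pred `CallSet`s carrying phased genotypes for `sample`
#' @param sample sample name
#' @param exclude contigs excluded from the AVG row
#' @return a `SwitchErrorReport` data.frame with per-contig columns
#'   `sites` (assessable), `pairs`, `switches`, `rate` (percent), plus
#'   an AVG row; per-contig orientation runs are attached as attribute
#'   `"orientations"`
#' @export
switch_error <- function(truth, pred, sample, exclude = c("chrX", "chrY")) {
  ti <- match(sample, truth$samples)
  pi <- match(sample, pred$samples)
  if (is.na(ti) || is.na(pi)) stop("sample not present in both call sets: ", sample)
  tk <- site_keys(truth)
  pk <- site_keys(pred)
  common <- match(tk, pk)
  rows_t <- which(!is.na(common))
  rows_p <- common[rows_t]

  t_a1 <- truth$gt$a1[rows_t, ti]; t_a2 <- truth$gt$a2[rows_t, ti]
  p_a1 <- pred$gt$a1[rows_p, pi];  p_a2 <- pred$gt$a2[rows_p, pi]
  het_t <- !truth$gt$miss[rows_t, ti] & !is.na(t_a1) & !is.na(t_a2) & t_a1 != t_a2
  het_p <- !pred$gt$miss[rows_p, pi] & !is.na(p_a1) & !is.na(p_a2) & p_a1 != p_a2
  same_gt <- het_t & het_p &
    (pmin(t_a1, t_a2) == pmin(p_a1, p_a2)) &
    (pmax(t_a1, t_a2) == pmax(p_a1, p_a2))
  ok <- same_gt & truth$gt$phased[rows_t, ti] & pred$gt$phased[rows_p, pi]

  idx <- rows_t[ok]
  ctg <- truth$sites$contig[idx]
  pos <- truth$sites$pos[idx]
  orient <- t_a1[ok] == p_a1[ok]   # TRUE: same orientation, FALSE: flipped

  contigs <- truth$contigs[truth$contigs %in% ctg]
  orientations <- list()
  rows <- lapply(contigs, function(cc) {
    sel <- which(ctg == cc)
    sel <- sel[order(pos[sel])]
    o <- orient[sel]
    orientations[[cc]] <<- o
    n <- length(o)
    pairs <- max(0L, n - 1L)
    switches <- if (n >= 2L) sum(o[-1] != o[-n]) else 0L
    data.frame(contig = cc, sites = n, pairs = pairs, switches = switches,
               rate = if (pairs > 0L) 100 * switches / pairs else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L) stop("no assessable sites for sample ", sample)
  out <- rbind(df, aggregate_report(df, exclude))
  class(out) <- c("SwitchErrorReport", "data.frame")
  attr(out, "orientations") <- orientations
  out
}

#' Assemble a false-negative attribution report from counts
#'
#' One row per contig: the FN count followed by one column per filter
#' label counting FN sites carrying that label.
#' `pct_explained = 100 * (sum of label columns) / fn`, which assumes
#' the labels are mutually exclusive per site (as VQSR tranches are).
#' The AVG row is the unweighted mean over contigs not in `exclude`.
#'
#' @param counts data.frame with columns `contig`, `fn`, then one
#'   integer column per filter label
#' @param exclude contigs excluded from the AVG row
#' @return an `AttributionReport` data.frame
#' @export
attribution_report <- function(counts, exclude = c("chrX", "chrY")) {
  label_cols <- setdiff(names(counts), c("contig", "fn"))
  attributed <- rowSums(counts[, label_cols, drop = FALSE])
  counts$pct_explained <- ifelse(counts$fn > 0, 100 * attributed / counts$fn, 0)
  out <- rbind(counts, aggregate_report(counts, exclude))
  class(out) <- c("AttributionReport", "data.frame")
  out
}

#' Attribute false negatives to filter labels
#'
#' For each FN site key, looks the site up in the pre-selection
#' filtered call set; if present, its filter labels (restricted to
#' `label_names`) are tallied. `pct_explained` uses the count of
#' distinct FN sites carrying at least one of the labels, so it can
#' never exceed 100.
#'
#' @param labels a [label_against_gold()] result (FN keys)
#' @param filtered_query the pre-selection `CallSet` carrying filter
#'   labels
#' @param label_names filter labels to attribute to
#' @param exclude contigs excluded from the AVG row
#' @return an `AttributionReport` data.frame
#' @export
fn_attribution <- function(labels, filtered_query, label_names,
                           exclude = c("chrX", "chrY")) {
  fn <- labels$fn
  kdf <- parse_site_keys(fn)
  fq_keys <- site_keys(filtered_query)
  hit <- match(fn, fq_keys)
  site_labels <- lapply(seq_along(fn), function(i) {
    if (is.na(hit[i])) character() else
      intersect(filtered_query$sites$filters[[hit[i]]], label_names)
  })
  contigs <- filtered_query$contigs[filtered_query$contigs %in% kdf$contig]
  contigs <- unique(c(contigs, kdf$contig))
  rows <- lapply(contigs, function(cc) {
    sel <- which(kdf$contig == cc)
    counts <- vapply(label_names, function(l)
      sum(vapply(site_labels[sel], function(x) l %in% x, logical(1))),
      integer(1))
    attributed <- sum(lengths(site_labels[sel]) > 0L)
    df <- data.frame(contig = cc, fn = length(sel), stringsAsFactors = FALSE)
    for (l in label_names) df[[l]] <- counts[[l]]
    df$attributed <- attributed
    df$pct_explained <- if (length(sel)) 100 * attributed / length(sel) else 0
    df
  })
  df <- do.call(rbind, rows)
  out <- rbind(df, aggregate_report(df, exclude))
  class(out) <- c("AttributionReport", "data.frame")
  out
}

#' Stratify call-set sites by region class (novel vs existing)
#'
#' Counts each call set's biallelic sites inside and outside the novel
#' regions and reports each call set's percentage share of the class
#' total. When a gold standard is supplied, per-contig TP percentages
#' within the novel regions are computed for each call set.
#'
#' @param callsets named list of normalized biallelic `CallSet`s
#' @param novel a `RegionSet` of novel-contig regions
#' @param gold optional gold-standard `CallSet` for the per-contig TP
#'   breakdown inside novel regions
#' @return list with `shares` (data.frame: region class, one count and
#'   one share column per call set) and `tp_by_contig` (data.frame or
#'   `NULL`)
#' @export
stratify_regions <- function(callsets, novel, gold = NULL) {
  labels <- names(callsets)
  stopifnot(length(labels) == length(callsets), !is.null(labels))
  in_novel <- lapply(callsets, function(cs)
    region_member(novel, cs$sites$contig, cs$sites$pos))
  counts <- data.frame(region = c("novel", "existing"))
  for (l in labels) {
    counts[[l]] <- c(sum(in_novel[[l]]), sum(!in_novel[[l]]))
  }
  totals <- rowSums(counts[, labels, drop = FALSE])
  for (l in labels)
    counts[[paste0(l, "_share_pct")]] <-
      ifelse(totals > 0, 100 * counts[[l]] / totals, NA)
  counts$total <- totals

  tp_by_contig <- NULL
  if (!is.null(gold)) {
    g_in <- region_member(novel, gold$sites$contig, gold$sites$pos)
    g_sub <- subset_callset(gold, which(g_in))
    gk <- site_keys(g_sub)
    contigs <- unique(g_sub$sites$contig)
    rows <- lapply(contigs, function(cc) {
      gkeys <- gk[g_sub$sites$contig == cc]
      df <- data.frame(contig = cc, gold_sites = length(gkeys),
                       stringsAsFactors = FALSE)
      for (l in labels) {
        qk <- site_keys(callsets[[l]])[in_novel[[l]] &
                                         callsets[[l]]$sites$contig == cc]
        df[[paste0("tp_pct_", l)]] <-
          if (length(gkeys)) 100 * length(intersect(qk, gkeys)) / length(gkeys)
          else NA_real_
      }
      df
    })
    tp_by_contig <- do.call(rbind, rows)
  }
  list(shares = counts, tp_by_contig = tp_by_contig)
}

#' Write a per-contig report as TSV
#'
#' Numeric rate columns are rounded to two decimals, matching the
#' layout of the released evaluation tables; counts stay integral.
#'
#' @param report a report data.frame
#' @param path output path
#' @param digits decimal places for non-integer numeric columns
#' @export
write_report_tsv <- function(report, path, digits = 2) {
  df <- as.data.frame(report)
  for (cl in names(df)) {
    if (is.numeric(df[[cl]]) && any(df[[cl]] %% 1 != 0, na.rm = TRUE))
      df[[cl]] <- round(df[[cl]], digits)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
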