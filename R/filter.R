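# Annotation-based hard filtering: rule/profile containers, the
# released cutoff tables for the four supporting call sets, soft
# application with a FILTER label, TP/FP labelling against a gold
# standard, and empirical derivation of cutoffs from labelled sites.

#' A single annotation threshold rule
#'
#' @param annotation `"QUAL"` or an INFO key (e.g. `"DP"`)
#' @param direction `"reject_above"` (value > threshold fails) or
#'   `"reject_below"` (value < threshold fails); inequalities are
#'   strict, matching `bcftools filter -e` expressions
#' @param threshold finite numeric cutoff
#' @param missing_policy what a site lacking the annotation does:
#'   `"pass"` (default) or `"fail"`
#' @return an object of class `FilterRule`
#' @export
filter_rule <- function(annotation, direction = c("reject_above", "reject_below"),
                        threshold, missing_policy = c("pass", "fail")) {
  direction <- match.arg(direction)
  missing_policy <- match.arg(missing_policy)
  stopifnot(nzchar(annotation), is.finite(threshold))
  structure(list(annotation = annotation, direction = direction,
                 threshold = threshold, missing_policy = missing_policy),
            class = "FilterRule")
}

#' A named set of filter rules applied as a logical OR
#'
#' A site failing any rule receives `fail_label` in its FILTER set.
#' Double-sided annotations (SGB) are represented as two rules.
#'
#' @param name profile name
#' @param rules list of [filter_rule()] objects (at least one)
#' @param fail_label FILTER label applied on failure
#' @return an object of class `FilterProfile`
#' @export
filter_profile <- function(name, rules, fail_label) {
  stopifnot(length(rules) >= 1L,
            all(vapply(rules, inherits, logical(1), "FilterRule")))
  structure(list(name = name, rules = rules, fail_label = fail_label),
            class = "FilterProfile")
}

#' @export
print.FilterProfile <- function(x, ...) {
  cat(sprintf("FilterProfile '%s' (label %s), %d rule(s):\n",
              x$name, x$fail_label, length(x$rules)))
  for (r in x$rules)
    cat(sprintf("  %s %s %s\n", r$annotation,
                if (r$direction == "reject_above") ">" else "<",
                format(r$threshold)))
  invisible(x)
}

#' The released hard-filter profiles
#'
#' The annotation cutoffs used for the four supporting call sets of the
#' 1000 Genomes GRCh38 release: BCFtools on low-coverage WGS data
#' (`lc_snv`, `lc_indel`), BCFtools on exome data (`ex_snv`,
#' `ex_indel`), each labelling failures `GIABFILTER`, plus the
#' single-rule Freebayes profile (`freebayes`, QUAL < 1, label
#' `QUALFILTER`).
#'
#' @return named list of [filter_profile()] objects
#' @export
builtin_profiles <- function() {
  ra <- function(a, t) filter_rule(a, "reject_above", t)
  rb <- function(a, t) filter_rule(a, "reject_below", t)
  list(
    lc_snv = filter_profile("lc_snv", list(
      ra("DP", 24304), rb("MQ", 34), ra("MQ0F", 0.049737),
      ra("HOB", 0.1643732), ra("SGB", 2347.043), rb("SGB", -64440.286),
      rb("QUAL", 20)), "GIABFILTER"),
    lc_indel = filter_profile("lc_indel", list(
      ra("DP", 23758), rb("MQ", 41), ra("MQ0F", 0.009913696),
      ra("HOB", 0.20265508), ra("SGB", 2143.8876), rb("SGB", -29513.557),
      ra("IDV", 51), rb("IMF", 0.387097), rb("QUAL", 20)), "GIABFILTER"),
    ex_snv = filter_profile("ex_snv", list(
      ra("DP", 656519), rb("MQ", 38), ra("MQ0F", 0.0146629),
      ra("HOB", 0.1536016), ra("SGB", 57489.21), rb("SGB", -226326.93),
      rb("QUAL", 20)), "GIABFILTER"),
    ex_indel = filter_profile("ex_indel", list(
      rb("MQ", 45), ra("MQ0F", 0.002034686), ra("HOB", 0.269603),
      ra("SGB", 53165.5), rb("SGB", -85919.729), rb("IMF", 0.3323922),
      rb("QUAL", 20)), "GIABFILTER"),
    freebayes = filter_profile("freebayes", list(
      rb("QUAL", 1)), "QUALFILTER")
  )
}

rule_values <- function(cs, annotation) {
  if (annotation == "QUAL") cs$sites$qual else info_value(cs, annotation)
}

rule_fails <- function(values, rule) {
  fail <- if (rule$direction == "reject_above") values > rule$threshold
          else values < rule$threshold
  fail[is.na(values)] <- rule$missing_policy == "fail"
  fail
}

#' Apply a filter profile to a call set (soft filtering)
#'
#' Sites failing at least one rule gain the profile's fail label in
#' their FILTER set; no site is removed. Sites missing a rule's
#' annotation follow that rule's `missing_policy` (default pass) and
#' are counted. Per-rule failure and missing counts are attached as
#' attribute `"filter_summary"`.
#'
#' @param cs a `CallSet`
#' @param profile a [filter_profile()]
#' @return the labelled `CallSet`
#' @export
apply_profile <- function(cs, profile) {
  n <- n_sites(cs)
  any_fail <- rep(FALSE, n)
  summary <- data.frame(annotation = character(), direction = character(),
                        threshold = numeric(), n_fail = integer(),
                        n_missing = integer(), stringsAsFactors = FALSE)
  for (rule in profile$rules) {
    v <- rule_values(cs, rule$annotation)
    f <- rule_fails(v, rule)
    any_fail <- any_fail | f
    summary <- rbind(summary, data.frame(
      annotation = rule$annotation, direction = rule$direction,
      threshold = rule$threshold, n_fail = sum(f), n_missing = sum(is.na(v)),
      stringsAsFactors = FALSE))
  }
  cs$sites$filters[any_fail] <- lapply(
    cs$sites$filters[any_fail],
    function(f) sort(unique(c(f, profile$fail_label))))
  message(sprintf("apply_profile(%s): %d/%d site(s) labelled %s",
                  profile$name, sum(any_fail), n, profile$fail_label))
  attr(cs, "filter_summary") <- summary
  cs
}

#' Label query sites as TP/FP/FN against a gold standard
#'
#' Both call sets must be normalized and biallelic. Evaluation is
#' restricted to sites whose position lies inside `regions` (the
#' high-confidence set). TP = query keys also in gold; FP = query keys
#' absent from gold; FN = gold keys absent from the query.
#'
#' @param query,gold biallelic `CallSet`s
#' @param regions a confidence `RegionSet`, or `NULL` for no restriction
#' @param pass_only if `TRUE`, only query sites with an empty FILTER
#'   set are considered
#' @return an object of class `LabeledSites` with components `tp`,
#'   `fp`, `fn` (character vectors of site keys)
#' @export
label_against_gold <- function(query, gold, regions = NULL,
                               pass_only = FALSE) {
  qs <- query
  if (pass_only)
    qs <- subset_callset(qs, which(lengths(qs$sites$filters) == 0L))
  qkeys <- site_keys(qs)
  gkeys <- site_keys(gold)
  if (!is.null(regions)) {
    qkeys <- qkeys[region_member(regions, qs$sites$contig, qs$sites$pos)]
    gkeys <- gkeys[region_member(regions, gold$sites$contig, gold$sites$pos)]
  }
  qkeys <- unique(qkeys); gkeys <- unique(gkeys)
  structure(list(tp = intersect(qkeys, gkeys),
                 fp = setdiff(qkeys, gkeys),
                 fn = setdiff(gkeys, qkeys)),
            class = "LabeledSites")
}

#' @export
print.LabeledSites <- function(x, ...) {
  cat(sprintf("LabeledSites: %d TP, %d FP, %d FN\n",
              length(x$tp), length(x$fp), length(x$fn)))
  invisible(x)
}

# Sort-based empirical quantile: the k-th order statistic such that the
# rejecting side holds at most (1 - retention) of the sample.
retention_threshold <- function(values, direction, retention) {
  values <- sort(values[!is.na(values)])
  n <- length(values)
  if (n == 0L) stop("annotation absent on all true-positive sites")
  if (direction == "reject_above") values[min(n, max(1L, ceiling(retention * n)))]
  else values[max(1L, min(n, floor((1 - retention) * n) + 1L))]
}

#' Derive hard-filter cutoffs from TP/FP-labelled sites
#'
#' For each requested (annotation, direction) pair the threshold is the
#' retention quantile of the annotation's distribution over true
#' positive sites, taken on the rejecting side, so that at most
#' `1 - tp_retention` of true positives would be rejected by the rule.
#' Per-rule counts of rejected TPs and FPs are attached for audit.
#'
#' @param query the biallelic `CallSet` the labels were computed from
#' @param labels a [label_against_gold()] result
#' @param annotations data.frame with columns `name` and `direction`
#'   (or a list of `c(name, direction)` pairs)
#' @param tp_retention fraction of true positives each rule must
#'   retain, in (0.5, 1); default 0.99
#' @param name,fail_label profile naming
#' @return a [filter_profile()] with attribute `"audit"` (a data.frame
#'   of per-rule TP/FP rejection counts)
#' @export
derive_cutoffs <- function(query, labels, annotations, tp_retention = 0.99,
                           name = "derived", fail_label = "GIABFILTER") {
  stopifnot(inherits(labels, "LabeledSites"),
            tp_retention > 0.5, tp_retention < 1)
  if (!is.data.frame(annotations))
    annotations <- data.frame(
      name = vapply(annotations, `[`, "", 1L),
      direction = vapply(annotations, `[`, "", 2L),
      stringsAsFactors = FALSE)
  keys <- site_keys(query)
  is_tp <- keys %in% labels$tp
  is_fp <- keys %in% labels$fp
  rules <- list()
  audit <- data.frame(annotation = character(), direction = character(),
                      threshold = numeric(), tp_rejected = integer(),
                      tp_total = integer(), fp_rejected = integer(),
                      fp_total = integer(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations$name[i]; dir <- annotations$direction[i]
    v <- rule_values(query, ann)
    thr <- retention_threshold(v[is_tp], dir, tp_retention)
    rule <- filter_rule(ann, dir, thr)
    rules[[length(rules) + 1L]] <- rule
    fails <- rule_fails(v, rule)
    audit <- rbind(audit, data.frame(
      annotation = ann, direction = dir, threshold = thr,
      tp_rejected = sum(fails & is_tp), tp_total = sum(is_tp),
      fp_rejected = sum(fails & is_fp), fp_total = sum(is_fp),
      stringsAsFactors = FALSE))
  }
  prof <- filter_profile(name, rules, fail_label)
  attr(prof, "audit") <- audit
  prof
}

#' Serialize a filter profile to JSON
#' @param profile a [filter_profile()]
#' @param path output path
#' @export
write_profile_json <- function(profile, path) {
  obj <- list(name = profile$name, fail_label = profile$fail_label,
              rules = lapply(profile$rules, function(r)
                list(annotation = r$annotation, direction = r$direction,
                     threshold = r$threshold,
                     missing_policy = r$missing_policy)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a filter profile from JSON
#' @param path path to a profile JSON written by [write_profile_json()]
#' @return a [filter_profile()]
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path)
  filter_profile(obj$name,
                 lapply(obj$rules, function(r)
                   filter_rule(r$annotation, r$direction, r$threshold,
                               r$missing_policy %||% "pass")),
                 obj$fail_label)
}
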