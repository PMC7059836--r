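# CallSet: ordered variant sites + sample genotypes + provenance label.
#
# Sites live in a data.frame (contig, pos, id, ref, alts, qual, filters,
# info); alts, filters and info are list columns. Genotypes are four
# site-by-sample matrices: allele1, allele2 (integer allele indices,
# NA = the "other allele" sentinel left behind by multiallelic
# splitting), phased (logical) and miss (logical, a fully missing call).
# An empty `filters` set means PASS, following the VCF convention.

# Default set of INFO annotations parsed as numbers on read. Everything
# else in INFO is ignored: the pipeline's filters only consume these.
DEFAULT_ANNOTATIONS <- c("DP", "MQ", "MQ0F", "HOB", "SGB", "IDV", "IMF")

new_sites <- function(contig = character(), pos = integer(),
                      id = character(), ref = character(),
                      alts = list(), qual = numeric(),
                      filters = list(), info = list()) {
  n <- length(contig)
  if (!length(id)) id <- rep(NA_character_, n)
  if (!length(qual)) qual <- rep(NA_real_, n)
  if (!length(filters)) filters <- rep(list(character()), n)
  if (!length(info)) info <- rep(list(numeric()), n)
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   id = as.character(id), ref = as.character(ref),
                   stringsAsFactors = FALSE)
  df$alts <- alts
  df$qual <- as.numeric(qual)
  df$filters <- filters
  df$info <- info
  df
}

empty_gt <- function(n_sites, samples) {
  m <- matrix(NA_integer_, nrow = n_sites, ncol = length(samples),
              dimnames = list(NULL, samples))
  list(a1 = m, a2 = m,
       phased = matrix(FALSE, n_sites, length(samples),
                       dimnames = list(NULL, samples)),
       miss = matrix(TRUE, n_sites, length(samples),
                     dimnames = list(NULL, samples)))
}

#' Construct a CallSet
#'
#' @param label provenance label (e.g. `"lc_bcftools"`, `"gatk"`)
#' @param samples ordered character vector of sample names
#' @param sites a sites data.frame as built by the package (columns
#'   `contig`, `pos`, `id`, `ref`, `alts`, `qual`, `filters`, `info`)
#' @param gt genotype matrices (`a1`, `a2`, `phased`, `miss`), each
#'   sites-by-samples; omit for a site-only call set
#' @param contigs contig names defining the sort order; defaults to
#'   order of appearance in `sites`
#' @param sorted if `FALSE` (default) sites are re-sorted by
#'   (contig order, pos, ref, alts)
#' @return an object of class `CallSet`
#' @export
callset <- function(label, samples = character(), sites = new_sites(),
                    gt = NULL, contigs = NULL, sorted = FALSE) {
  if (is.null(gt)) gt <- empty_gt(nrow(sites), samples)
  stopifnot(nrow(sites) == nrow(gt$a1),
            length(samples) == ncol(gt$a1))
  if (is.null(contigs)) contigs <- unique(sites$contig)
  if (!all(sites$contig %in% contigs))
    stop("sites on contigs missing from the contig order: ",
         paste(setdiff(sites$contig, contigs), collapse = ", "))
  cs <- structure(list(label = label, samples = samples, sites = sites,
                       gt = gt, contigs = contigs),
                  class = "CallSet")
  if (!sorted) cs <- sort_callset(cs) else cs
}

#' @export
print.CallSet <- function(x, ...) {
  cat(sprintf("CallSet '%s': %d site(s), %d sample(s), %d contig(s)\n",
              x$label, nrow(x$sites), length(x$samples), length(x$contigs)))
  invisible(x)
}

#' Number of sites in a CallSet
#' @param cs a `CallSet`
#' @return integer
#' @export
n_sites <- function(cs) nrow(cs$sites)

alt_strings <- function(sites) {
  vapply(sites$alts, paste, character(1), collapse = ",")
}

site_order <- function(cs) {
  order(match(cs$sites$contig, cs$contigs), cs$sites$pos,
        cs$sites$ref, alt_strings(cs$sites), method = "radix")
}

subset_callset <- function(cs, idx) {
  cs$sites <- cs$sites[idx, , drop = FALSE]
  rownames(cs$sites) <- NULL
  cs$gt <- lapply(cs$gt, function(m) m[idx, , drop = FALSE])
  cs
}

#' Sort a CallSet by (contig order, position, ref, alt)
#'
#' The contig order is the one carried by the call set (from the
#' reference or the VCF header). The sort is stable and total.
#'
#' @param cs a `CallSet`
#' @return the sorted `CallSet`
#' @export
sort_callset <- function(cs) subset_callset(cs, site_order(cs))

is_sorted <- function(cs) {
  ord <- site_order(cs)
  all(ord == seq_along(ord))
}

#' Site keys of a biallelic CallSet
#'
#' The key `contig:pos:ref:alt` is the identity under which union,
#' deduplication and all TP/FP/FN matching operate. It is only defined
#' for biallelic sites.
#'
#' @param cs a `CallSet` whose sites are all biallelic
#' @return character vector of keys
#' @export
site_keys <- function(cs) {
  if (any(lengths(cs$sites$alts) != 1L))
    stop("site keys are only defined for biallelic call sets")
  paste(cs$sites$contig, cs$sites$pos, cs$sites$ref,
        unlist(cs$sites$alts, use.names = FALSE), sep = ":")
}

# Inverse of site_keys: data.frame(contig, pos, ref, alt).
parse_site_keys <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(contig = vapply(parts, `[`, "", 1L),
             pos = as.integer(vapply(parts, `[`, "", 2L)),
             ref = vapply(parts, `[`, "", 3L),
             alt = vapply(parts, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Classify biallelic sites as SNV or INDEL
#'
#' A biallelic site is an SNV iff both alleles have length 1;
#' everything else routes as an INDEL.
#'
#' @param cs a biallelic `CallSet`
#' @return character vector, `"snv"` or `"indel"` per site
#' @export
site_class <- function(cs) {
  if (any(lengths(cs$sites$alts) != 1L))
    stop("site classes are only defined for biallelic call sets")
  alt <- unlist(cs$sites$alts, use.names = FALSE)
  ifelse(nchar(cs$sites$ref) == 1L & nchar(alt) == 1L, "snv", "indel")
}

#' Select the SNV or INDEL subset of a biallelic CallSet
#'
#' @param cs a biallelic `CallSet`
#' @param class `"snv"` or `"indel"`
#' @return a `CallSet`
#' @export
select_class <- function(cs, class = c("snv", "indel")) {
  class <- match.arg(class)
  subset_callset(cs, which(site_class(cs) == class))
}

info_value <- function(cs, key) {
  vapply(cs$sites$info, function(m) {
    if (length(m) && key %in% names(m)) as.numeric(m[[key]]) else NA_real_
  }, numeric(1))
}

# ---------------------------------------------------------------------
# VCF input

extract_info_key <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=[^;]*")
  m <- regexpr(pat, info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  hit <- which(m > 0)
  if (length(hit))
    out[hit] <- sub(paste0("^;?", key, "="), "", regmatches(info, m))
  out
}

#' Read a VCF file into a CallSet
#'
#' Accepts plain or gzip/bgzip-compressed VCF v4.2. Records are
#' re-sorted if the file is out of order (with a warning). Only the GT
#' genotype field is read; INFO values are parsed as numbers for the
#' annotations in `annotations` and all other INFO content is ignored.
#'
#' @param path path to the VCF file
#' @param label provenance label for the resulting call set
#' @param annotations INFO keys to parse as numeric annotations
#' @return a [callset()]
#' @export
read_callset <- function(path, label, annotations = DEFAULT_ANNOTATIONS) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n <- nrow(fix)
  meta <- vcf@meta
  ctg_lines <- grep("^##contig=", meta, value = TRUE)
  contigs <- sub(".*<ID=([^,>]+).*", "\\1", ctg_lines)

  if (n == 0L) {
    smp <- colnames(vcf@gt)
    smp <- if (is.null(smp)) character() else smp[-1]
    return(callset(label, samples = smp, sites = new_sites(),
                   contigs = if (length(contigs)) contigs else character(),
                   sorted = TRUE))
  }

  ref <- fix[, "REF"]
  bad <- grepl("[^ACGTNacgtn]", ref)
  if (any(bad))
    stop("record ", which(bad)[1], " (", fix[which(bad)[1], "CHROM"], ":",
         fix[which(bad)[1], "POS"], "): REF contains non-ACGTN characters")
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos))
    stop("record ", which(is.na(pos))[1], ": malformed POS")

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  id <- fix[, "ID"]
  id[id == "."] <- NA_character_
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  filt <- fix[, "FILTER"]
  filters <- lapply(filt, function(f) {
    if (is.na(f) || f %in% c("PASS", ".")) character() else
      strsplit(f, ";", fixed = TRUE)[[1]]
  })
  info_raw <- fix[, "INFO"]
  info_cols <- lapply(annotations, function(k) {
    s <- extract_info_key(info_raw, k)
    v <- suppressWarnings(as.numeric(s))
    broken <- !is.na(s) & is.na(v)
    if (any(broken))
      stop("record ", which(broken)[1], ": INFO/", k,
           " value '", s[which(broken)[1]], "' is not numeric")
    v
  })
  names(info_cols) <- annotations
  info <- lapply(seq_len(n), function(i) {
    v <- vapply(info_cols, `[`, numeric(1), i)
    v[!is.na(v)]
  })

  smp <- colnames(vcf@gt)
  smp <- if (is.null(smp)) character() else smp[-1]
  gt <- empty_gt(n, smp)
  if (length(smp)) {
    gstr <- sub(":.*$", "", vcf@gt[, -1, drop = FALSE])
    phased <- grepl("|", gstr, fixed = TRUE)
    a1s <- sub("^([^/|]*).*$", "\\1", gstr)
    a2s <- ifelse(grepl("[/|]", gstr),
                  sub("^[^/|]*[/|](.*)$", "\\1", gstr), NA_character_)
    a1 <- suppressWarnings(matrix(as.integer(ifelse(a1s == ".", NA, a1s)),
                                  n, length(smp)))
    a2 <- suppressWarnings(matrix(as.integer(ifelse(a2s == ".", NA, a2s)),
                                  n, length(smp)))
    dimnames(a1) <- dimnames(a2) <- list(NULL, smp)
    miss <- is.na(a1) & is.na(a2)
    phased[miss] <- FALSE
    gt <- list(a1 = a1, a2 = a2,
               phased = matrix(phased, n, length(smp),
                               dimnames = list(NULL, smp)),
               miss = miss)
  }

  sites <- new_sites(contig = fix[, "CHROM"], pos = pos, id = id,
                     ref = toupper(ref), alts = lapply(alts, toupper),
                     qual = qual, filters = filters, info = info)
  if (!length(contigs)) contigs <- unique(sites$contig)
  if (!all(sites$contig %in% contigs))
    contigs <- c(contigs, setdiff(unique(sites$contig), contigs))
  cs <- callset(label, samples = smp, sites = sites, gt = gt,
                contigs = contigs, sorted = TRUE)
  if (!is_sorted(cs)) {
    warning("VCF records out of order in ", path, "; re-sorting")
    cs <- sort_callset(cs)
  }
  cs
}

# ---------------------------------------------------------------------
# VCF output

fmt_num <- function(x) {
  ifelse(is.na(x), ".",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.17g", x)))
}

gt_string <- function(a1, a2, phased, miss) {
  sep <- ifelse(phased, "|", "/")
  s1 <- ifelse(is.na(a1), ".", a1)
  s2 <- ifelse(is.na(a2), ".", a2)
  out <- paste0(s1, sep, s2)
  out[miss] <- "./."
  out
}

#' Write a CallSet as VCF v4.2
#'
#' Emits header lines for every FILTER label and INFO key present in the
#' call set, and a GT-only FORMAT column when the call set has samples.
#' `read_callset(write_callset(cs))` reproduces `cs`.
#'
#' @param cs a `CallSet`
#' @param path output path; a `.gz` suffix triggers gzip compression
#' @param contig_lengths optional named lengths for `##contig` lines
#' @export
write_callset <- function(cs, path, contig_lengths = NULL) {
  stopifnot(inherits(cs, "CallSet"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=consensusvc(", cs$label, ")"))
  for (ctg in cs$contigs) {
    ln <- contig_lengths[[ctg]]
    hdr <- c(hdr, if (is.null(ln)) sprintf("##contig=<ID=%s>", ctg) else
      sprintf("##contig=<ID=%s,length=%d>", ctg, as.integer(ln)))
  }
  flabels <- sort(unique(unlist(cs$sites$filters, use.names = FALSE)))
  for (f in flabels)
    hdr <- c(hdr, sprintf("##FILTER=<ID=%s,Description=\"Failed %s\">", f, f))
  ikeys <- unique(unlist(lapply(cs$sites$info, names), use.names = FALSE))
  for (k in ikeys)
    hdr <- c(hdr, sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, k))
  if (length(cs$samples))
    hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(cs$samples)) cols <- c(cols, "FORMAT", cs$samples)
  hdr <- c(hdr, paste(cols, collapse = "\t"))

  n <- n_sites(cs)
  body <- character(0)
  if (n > 0L) {
    filt_str <- vapply(cs$sites$filters, function(f)
      if (length(f)) paste(f, collapse = ";") else "PASS", character(1))
    info_str <- vapply(cs$sites$info, function(m) {
      if (!length(m)) "." else
        paste(paste0(names(m), "=", fmt_num(unname(m))), collapse = ";")
    }, character(1))
    fields <- list(cs$sites$contig, cs$sites$pos,
                   ifelse(is.na(cs$sites$id), ".", cs$sites$id),
                   cs$sites$ref, alt_strings(cs$sites),
                   fmt_num(cs$sites$qual), filt_str, info_str)
    if (length(cs$samples)) {
      fields <- c(fields, list(rep("GT", n)))
      for (j in seq_along(cs$samples))
        fields <- c(fields, list(gt_string(cs$gt$a1[, j], cs$gt$a2[, j],
                                           cs$gt$phased[, j], cs$gt$miss[, j])))
    }
    body <- do.call(paste, c(fields, sep = "\t"))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
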