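# Canonicalization of variant representation. Different callers report
# the same edit in different ways (un-left-aligned INDELs, MNPs versus
# decomposed SNVs, merged multiallelic rows); these operations rewrite
# every call set into a shared canonical form so that site keys are
# comparable across callers.

# Core left-align/trim loop on (pos, alleles) against one contig string.
# The trim/extend convention: repeatedly chop a shared trailing base
# (extending left with the previous reference base whenever an allele
# would empty), then strip shared leading bases while all alleles keep
# length > 1. Idempotent; never changes the implied edit.
left_align_alleles <- function(pos, alleles, seq) {
  repeat {
    last <- substr(alleles, nchar(alleles), nchar(alleles))
    if (length(unique(last)) != 1L || any(nchar(alleles) == 0L)) break
    if (all(nchar(alleles) > 1L)) {
      alleles <- substr(alleles, 1L, nchar(alleles) - 1L)
    } else {
      if (pos == 1L)
        stop("cannot left-align: variant at contig start needs left extension")
      alleles <- substr(alleles, 1L, nchar(alleles) - 1L)
      pos <- pos - 1L
      alleles <- paste0(substr(seq, pos, pos), alleles)
    }
  }
  repeat {
    first <- substr(alleles, 1L, 1L)
    if (length(unique(first)) != 1L || any(nchar(alleles) == 1L)) break
    alleles <- substr(alleles, 2L, nchar(alleles))
    pos <- pos + 1L
  }
  list(pos = pos, alleles = alleles)
}

#' Left-align and trim a variant site
#'
#' Rewrites a (possibly multiallelic) site into its canonical left-most
#' minimal representation against the reference, the convention used by
#' `bcftools norm` and `vt normalize`. The operation is idempotent and
#' preserves the implied edit.
#'
#' @param site a list with fields `contig`, `pos`, `ref`, `alts` (and
#'   optionally the other site fields, which are passed through)
#' @param ref a [reference_sequence()]
#' @return the site with canonical `pos`, `ref`, `alts`
#' @export
left_align_trim <- function(site, ref) {
  seq <- ref$contigs[[site$contig]]
  if (is.null(seq)) stop("contig not in reference: ", site$contig)
  obs <- ref_slice(ref, site$contig, site$pos,
                   site$pos + nchar(site$ref) - 1L)
  if (obs != site$ref)
    stop(sprintf("REF mismatch at %s:%d: VCF says '%s', reference has '%s'",
                 site$contig, site$pos, site$ref, obs))
  alts <- unlist(site$alts, use.names = FALSE)
  la <- left_align_alleles(site$pos, c(site$ref, alts), seq)
  site$pos <- la$pos
  site$ref <- la$alleles[1]
  site$alts <- list(la$alleles[-1])
  site
}

# Trim shared leading/trailing bases without reference context (safe:
# all alleles keep length >= 1).
trim_alleles <- function(pos, alleles) {
  repeat {
    last <- substr(alleles, nchar(alleles), nchar(alleles))
    if (any(nchar(alleles) == 1L) || length(unique(last)) != 1L) break
    alleles <- substr(alleles, 1L, nchar(alleles) - 1L)
  }
  repeat {
    first <- substr(alleles, 1L, 1L)
    if (any(nchar(alleles) == 1L) || length(unique(first)) != 1L) break
    alleles <- substr(alleles, 2L, nchar(alleles))
    pos <- pos + 1L
  }
  list(pos = pos, alleles = alleles)
}

#' Split multiallelic sites into biallelic rows
#'
#' Every output row carries exactly one alternate allele. Genotype
#' alleles that belong to one of the other rows are re-coded to the
#' "other allele" sentinel (written `.` in VCF), preserving ploidy.
#' Alleles are trimmed per row (reference-free), so the record count
#' equals the total alt count of the input.
#'
#' @param cs a `CallSet`
#' @return a `CallSet` of biallelic rows
#' @export
split_multiallelics <- function(cs) {
  k <- lengths(cs$sites$alts)
  if (all(k == 1L)) return(cs)
  idx <- rep(seq_len(n_sites(cs)), k)
  which_alt <- unlist(lapply(k, seq_len), use.names = FALSE)

  out_sites <- cs$sites[idx, , drop = FALSE]
  rownames(out_sites) <- NULL
  alts_flat <- unlist(cs$sites$alts, use.names = FALSE)
  new_alts <- vector("list", length(idx))
  new_pos <- out_sites$pos
  new_ref <- out_sites$ref
  for (i in seq_along(idx)) {
    tr <- trim_alleles(new_pos[i], c(new_ref[i], alts_flat[i]))
    new_pos[i] <- tr$pos
    new_ref[i] <- tr$alleles[1]
    new_alts[[i]] <- tr$alleles[2]
  }
  out_sites$pos <- new_pos
  out_sites$ref <- new_ref
  out_sites$alts <- new_alts

  gt <- lapply(cs$gt, function(m) m[idx, , drop = FALSE])
  if (length(cs$samples)) for (nm in c("a1", "a2")) {
    a <- gt[[nm]]
    tgt <- matrix(which_alt, nrow(a), ncol(a))
    recoded <- matrix(NA_integer_, nrow(a), ncol(a), dimnames = dimnames(a))
    recoded[!is.na(a) & a == 0L] <- 0L
    recoded[!is.na(a) & a == tgt] <- 1L
    gt[[nm]] <- recoded
  }
  callset(cs$label, cs$samples, out_sites, gt, contigs = cs$contigs)
}

#' Merge co-located biallelic rows into multiallelic records
#'
#' Rows sharing (contig, pos) are merged after extending every allele
#' to the longest REF among them; the merged alts are deduplicated and
#' ordered lexicographically. Merged QUAL is the maximum of the parts,
#' filters are unioned, and INFO keys are kept only when identical
#' across parts (dropped with a warning otherwise). Genotypes are
#' reassembled from the per-row codes; the "other allele" sentinel is
#' resolved wherever another row identifies the allele.
#'
#' @param cs a `CallSet` of normalized rows
#' @return a `CallSet`
#' @export
merge_multiallelics <- function(cs) {
  key <- paste(cs$sites$contig, cs$sites$pos, sep = ":")
  if (!anyDuplicated(key)) return(cs)
  groups <- split(seq_len(n_sites(cs)), key)
  groups <- groups[order(vapply(groups, min, integer(1)))]

  n_out <- length(groups)
  nsmp <- length(cs$samples)
  contig <- character(n_out); pos <- integer(n_out)
  id <- character(n_out); refv <- character(n_out)
  altsv <- vector("list", n_out); qual <- numeric(n_out)
  filters <- vector("list", n_out); info <- vector("list", n_out)
  gt <- empty_gt(n_out, cs$samples)
  dropped_info <- 0L

  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    s <- cs$sites[rows, , drop = FALSE]
    contig[g] <- s$contig[1]; pos[g] <- s$pos[1]
    ids <- s$id[!is.na(s$id)]
    id[g] <- if (length(ids)) ids[1] else NA_character_
    longest <- s$ref[which.max(nchar(s$ref))]
    if (!all(substring(longest, 1L, nchar(s$ref)) == s$ref))
      stop(sprintf("irreconcilable REF alleles at %s:%d",
                   s$contig[1], s$pos[1]))
    refv[g] <- longest
    suffix <- substr(rep(longest, nrow(s)), nchar(s$ref) + 1L, nchar(longest))
    ext_alt <- paste0(vapply(s$alts, `[`, "", 1L), suffix)
    merged_alts <- sort(unique(ext_alt))
    altsv[[g]] <- merged_alts
    qual[g] <- if (all(is.na(s$qual))) NA_real_ else max(s$qual, na.rm = TRUE)
    filters[[g]] <- sort(unique(unlist(s$filters, use.names = FALSE)))
    keys <- Reduce(intersect, lapply(s$info, names))
    kept <- keys[vapply(keys, function(k) {
      v <- vapply(s$info, `[[`, numeric(1), k)
      length(unique(v)) == 1L
    }, logical(1))]
    dropped_info <- dropped_info +
      length(unique(unlist(lapply(s$info, names)))) - length(kept)
    info[[g]] <- if (length(kept)) s$info[[1]][kept] else numeric()

    if (nsmp) {
      row_code <- match(ext_alt, merged_alts)  # row's allele 1 -> merged idx
      for (nm in c("a1", "a2")) {
        vals <- cs$gt[[nm]][rows, , drop = FALSE]
        res <- rep(NA_integer_, nsmp)
        for (r in seq_along(rows)) {
          v <- vals[r, ]
          hit <- !is.na(v) & v == 1L & is.na(res)
          res[hit] <- row_code[r]
          zero <- !is.na(v) & v == 0L & is.na(res)
          res[zero] <- 0L
        }
        gt[[nm]][g, ] <- res
      }
      gt$miss[g, ] <- apply(cs$gt$miss[rows, , drop = FALSE], 2, all)
      gt$phased[g, ] <- cs$gt$phased[rows[1], ]
      gt$a1[g, gt$miss[g, ]] <- NA_integer_
      gt$a2[g, gt$miss[g, ]] <- NA_integer_
    }
  }
  if (dropped_info > 0L)
    warning(dropped_info, " INFO value(s) dropped during multiallelic merge ",
            "(not identical across merged rows)")
  sites <- new_sites(contig, pos, id, refv, altsv, qual, filters, info)
  callset(cs$label, cs$samples, sites, gt, contigs = cs$contigs)
}

# Column-wise decomposition of one biallelic (pos, ref, alt) pair into
# allelic primitives. Returns data.frame(pos, ref, alt).
decompose_alleles <- function(pos, ref, alt) {
  tr <- trim_alleles(pos, c(ref, alt))
  pos <- tr$pos; ref <- tr$alleles[1]; alt <- tr$alleles[2]
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1L && la == 1L)
    return(data.frame(pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE))
  rs <- strsplit(ref, "")[[1]]
  as <- strsplit(alt, "")[[1]]
  if (lr == la) {  # MNP: one SNV per mismatching column
    mm <- which(rs != as)
    return(data.frame(pos = pos + mm - 1L, ref = rs[mm], alt = as[mm],
                      stringsAsFactors = FALSE))
  }
  if (min(lr, la) == 1L && rs[1] == as[1]) {  # pure anchored INDEL
    return(data.frame(pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE))
  }
  # Complex substitution: place the length-difference gap immediately
  # after the first (anchor) column, then compare remaining columns.
  d <- lr - la
  out <- list()
  if (d > 0L) {  # deletion of d bases after the anchor
    out[[1]] <- data.frame(pos = pos, ref = substr(ref, 1L, d + 1L),
                           alt = rs[1], stringsAsFactors = FALSE)
    if (rs[1] != as[1])
      out[[length(out) + 1L]] <- data.frame(pos = pos, ref = rs[1],
                                            alt = as[1],
                                            stringsAsFactors = FALSE)
    for (j in seq_len(la - 1L)) {
      if (rs[d + 1L + j] != as[1L + j])
        out[[length(out) + 1L]] <- data.frame(pos = pos + d + j,
                                              ref = rs[d + 1L + j],
                                              alt = as[1L + j],
                                              stringsAsFactors = FALSE)
    }
  } else {  # insertion of -d bases after the anchor
    d <- -d
    out[[1]] <- data.frame(pos = pos, ref = rs[1],
                           alt = paste0(rs[1], substr(alt, 2L, d + 1L)),
                           stringsAsFactors = FALSE)
    if (rs[1] != as[1])
      out[[length(out) + 1L]] <- data.frame(pos = pos, ref = rs[1],
                                            alt = as[1],
                                            stringsAsFactors = FALSE)
    for (j in seq_len(lr - 1L)) {
      if (rs[1L + j] != as[d + 1L + j])
        out[[length(out) + 1L]] <- data.frame(pos = pos + j,
                                              ref = rs[1L + j],
                                              alt = as[d + 1L + j],
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Decompose a biallelic site into allelic primitives
#'
#' MNPs become one SNV per mismatching column; SNVs and anchored simple
#' INDELs pass through; complex substitutions are aligned with the
#' length-difference gap placed directly after the anchor column
#' (prefix-first) and emitted as one INDEL plus SNVs. QUAL, filters and
#' INFO are copied to every child.
#'
#' @param site a biallelic site list (`contig`, `pos`, `ref`, `alts`,
#'   optionally `id`, `qual`, `filters`, `info`)
#' @return a list of primitive site lists
#' @export
decompose_primitives <- function(site) {
  alts <- unlist(site$alts, use.names = FALSE)
  if (length(alts) != 1L) stop("decompose_primitives requires a biallelic site")
  prim <- decompose_alleles(site$pos, site$ref, alts)
  lapply(seq_len(nrow(prim)), function(i) {
    child <- site
    child$pos <- prim$pos[i]
    child$ref <- prim$ref[i]
    child$alts <- list(prim$alt[i])
    child
  })
}

#' Keep only biallelic sites
#'
#' @param cs a `CallSet`
#' @return a `CallSet` containing exactly the sites with one alt allele,
#'   order preserved
#' @export
select_biallelic <- function(cs) {
  subset_callset(cs, which(lengths(cs$sites$alts) == 1L))
}

#' Remove excluded regions and non-PAR sex-chromosome sites
#'
#' Drops sites inside the exclusion intervals (e.g. centromeres), all
#' sites on the Y chromosome, and X-chromosome sites outside the
#' pseudo-autosomal regions. Removal counts per reason are reported as
#' a message and attached as attribute `"removed"`.
#'
#' @param cs a `CallSet`
#' @param exclusions a `RegionSet` of excluded intervals, or `NULL`
#' @param par a `RegionSet` of pseudo-autosomal intervals, or `NULL`
#'   (with `NULL`, every X site is removed)
#' @param sex_contigs named character vector with entries `x` and `y`
#' @return the filtered `CallSet`
#' @export
exclude_regions <- function(cs, exclusions = NULL, par = NULL,
                            sex_contigs = c(x = "chrX", y = "chrY")) {
  n <- n_sites(cs)
  in_excl <- if (is.null(exclusions)) rep(FALSE, n) else
    region_member(exclusions, cs$sites$contig, cs$sites$pos)
  on_y <- cs$sites$contig == sex_contigs[["y"]]
  on_x <- cs$sites$contig == sex_contigs[["x"]]
  in_par <- if (is.null(par)) rep(FALSE, n) else
    region_member(par, cs$sites$contig, cs$sites$pos)
  x_nonpar <- on_x & !in_par
  drop <- in_excl | on_y | x_nonpar
  removed <- c(exclusion = sum(in_excl), chrY = sum(on_y & !in_excl),
               chrX_nonPAR = sum(x_nonpar & !in_excl & !on_y))
  message(sprintf(
    "exclude_regions: removed %d site(s) (%d in exclusions, %d on %s, %d on non-PAR %s)",
    sum(drop), removed[["exclusion"]], removed[["chrY"]], sex_contigs[["y"]],
    removed[["chrX_nonPAR"]], sex_contigs[["x"]]))
  out <- subset_callset(cs, which(!drop))
  attr(out, "removed") <- removed
  out
}

#' Normalize a CallSet to canonical biallelic form
#'
#' The full canonicalization chain: split multiallelics, left-align and
#' trim against the reference, decompose into allelic primitives, sort,
#' deduplicate identical site keys (keeping the highest QUAL, first on
#' ties), re-merge co-located rows, and keep biallelic sites only. The
#' chain is idempotent and its output is unique by site key.
#'
#' @param cs a `CallSet`
#' @param ref a [reference_sequence()]; every contig with sites must be
#'   present
#' @return the canonical biallelic `CallSet`
#' @export
normalize_callset <- function(cs, ref) {
  missing_ctg <- setdiff(unique(cs$sites$contig), contig_names(ref))
  if (length(missing_ctg))
    stop("call set has sites on contigs absent from the reference: ",
         paste(missing_ctg, collapse = ", "))
  cs <- split_multiallelics(cs)

  n <- n_sites(cs)
  if (n > 0L) {
    seqs <- ref$contigs
    pos <- cs$sites$pos; refa <- cs$sites$ref
    alta <- vapply(cs$sites$alts, `[`, "", 1L)
    ctg <- cs$sites$contig
    # left-align, then decompose, collecting child rows
    child_parent <- integer(0)
    child_pos <- integer(0); child_ref <- character(0); child_alt <- character(0)
    for (i in seq_len(n)) {
      seq <- seqs[[ctg[i]]]
      obs <- substr(seq, pos[i], pos[i] + nchar(refa[i]) - 1L)
      if (obs != refa[i])
        stop(sprintf("REF mismatch at %s:%d: VCF says '%s', reference has '%s'",
                     ctg[i], pos[i], refa[i], obs))
      la <- left_align_alleles(pos[i], c(refa[i], alta[i]), seq)
      prim <- decompose_alleles(la$pos, la$alleles[1], la$alleles[2])
      child_parent <- c(child_parent, rep(i, nrow(prim)))
      child_pos <- c(child_pos, prim$pos)
      child_ref <- c(child_ref, prim$ref)
      child_alt <- c(child_alt, prim$alt)
    }
    sites <- cs$sites[child_parent, , drop = FALSE]
    rownames(sites) <- NULL
    sites$pos <- child_pos
    sites$ref <- child_ref
    sites$alts <- as.list(child_alt)
    gt <- lapply(cs$gt, function(m) m[child_parent, , drop = FALSE])
    cs <- callset(cs$label, cs$samples, sites, gt,
                  contigs = contig_names(ref))
  } else {
    cs$contigs <- contig_names(ref)
  }

  # deduplicate identical site keys: highest qual wins, first on ties
  if (n_sites(cs) > 0L) {
    keys <- site_keys(cs)
    qual_rank <- order(-ifelse(is.na(cs$sites$qual), -Inf, cs$sites$qual))
    keep <- qual_rank[!duplicated(keys[qual_rank])]
    cs <- subset_callset(cs, sort(keep))
  }
  cs <- merge_multiallelics(cs)
  select_biallelic(cs)
}
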