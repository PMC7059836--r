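# Union-based consensus across normalized supporting call sets, with
# per-caller provenance, UpSet-style contribution counts, a
# deterministic genotype-reconciliation rule, and concatenation of the
# SNV-only and INDEL-only consensus sets.

#' Union of biallelic sites across call sets, with provenance
#'
#' Builds the consensus site list as the union of site keys across all
#' inputs. Site-level fields are resolved conservatively: QUAL is the
#' maximum across supporters, the FILTER set is reset (final filtering
#' happens downstream), and INFO keeps only keys identical across all
#' supporters of a site. Genotypes are left missing; see
#' [reconcile_genotypes()].
#'
#' @param callsets list of normalized biallelic `CallSet`s (length >= 1)
#' @param label label for the consensus call set
#' @return list with components `consensus` (a `CallSet`) and
#'   `provenance` (a `ProvenanceTable`: named list mapping each site
#'   key to the labels of the call sets containing it)
#' @export
union_sites <- function(callsets, label = "consensus") {
  stopifnot(length(callsets) >= 1L)
  for (cs in callsets)
    if (any(lengths(cs$sites$alts) != 1L))
      stop("union_sites requires biallelic inputs (call set '", cs$label, "')")
  keysets <- lapply(callsets, site_keys)
  labels <- vapply(callsets, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("call-set labels must be unique")

  all_keys <- unique(unlist(keysets, use.names = FALSE))
  support <- matrix(FALSE, length(all_keys), length(callsets),
                    dimnames = list(all_keys, labels))
  for (j in seq_along(callsets)) support[keysets[[j]], j] <- TRUE

  contigs <- Reduce(function(a, b) c(a, setdiff(b, a)),
                    lapply(callsets, `[[`, "contigs"))
  samples_list <- lapply(callsets, `[[`, "samples")
  samples <- samples_list[[1]]
  if (!all(vapply(samples_list, identical, logical(1), samples))) {
    samples <- Reduce(intersect, samples_list)
    warning("sample sets differ across call sets; using the intersection (",
            length(samples), " sample(s))")
  }

  kdf <- parse_site_keys(all_keys)
  qual <- rep(NA_real_, length(all_keys))
  id <- rep(NA_character_, length(all_keys))
  info <- rep(list(NULL), length(all_keys))
  for (j in seq_along(callsets)) {
    idx <- match(keysets[[j]], all_keys)
    q <- callsets[[j]]$sites$qual
    take <- is.na(qual[idx]) | (!is.na(q) & q > qual[idx])
    qual[idx[take]] <- q[take]
    id_j <- callsets[[j]]$sites$id
    fill <- is.na(id[idx]) & !is.na(id_j)
    id[idx[fill]] <- id_j[fill]
    for (r in seq_along(idx)) {
      i <- idx[r]
      cur <- info[[i]]
      new <- callsets[[j]]$sites$info[[r]]
      info[[i]] <- if (is.null(cur)) new else {
        common <- intersect(names(cur), names(new))
        cur[common[cur[common] == new[common]]]
      }
    }
  }
  info <- lapply(info, function(m) if (is.null(m)) numeric() else m)

  sites <- new_sites(contig = kdf$contig, pos = kdf$pos, id = id,
                     ref = kdf$ref, alts = as.list(kdf$alt), qual = qual,
                     filters = rep(list(character()), length(all_keys)),
                     info = info)
  cons <- callset(label, samples, sites, contigs = contigs)
  prov <- structure(
    lapply(seq_along(all_keys), function(i) labels[support[i, ]]),
    names = all_keys, class = "ProvenanceTable")
  list(consensus = cons, provenance = prov)
}

#' UpSet-style contribution counts from a provenance table
#'
#' Counts consensus sites by the exact subset of call sets supporting
#' them (the vertical bars of an UpSet plot) and per-label marginal
#' totals (the horizontal bars).
#'
#' @param prov a `ProvenanceTable` from [union_sites()]
#' @return list with `intersections` (named integer vector; names are
#'   sorted labels joined with `+`) and `marginals` (named integer
#'   vector per label). Intersection counts sum to the number of keys.
#' @export
contribution_counts <- function(prov) {
  if (!length(prov))
    return(list(intersections = integer(), marginals = integer()))
  subset_id <- vapply(prov, function(x) paste(sort(x), collapse = "+"),
                      character(1))
  inter <- table(subset_id)
  inter <- structure(as.integer(inter), names = names(inter))
  all_labels <- sort(unique(unlist(prov, use.names = FALSE)))
  marg <- vapply(all_labels, function(l)
    sum(vapply(prov, function(x) l %in% x, logical(1))), integer(1))
  list(intersections = inter, marginals = marg)
}

#' Write a provenance table as TSV
#'
#' Two columns: site key, comma-joined supporting labels. Suitable as
#' input to UpSet plotting tools.
#'
#' @param prov a `ProvenanceTable`
#' @param path output path
#' @export
write_provenance_tsv <- function(prov, path) {
  df <- data.frame(key = names(prov),
                   callsets = vapply(prov, paste, character(1),
                                     collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fill consensus genotypes by caller priority
#'
#' A deterministic stand-in for likelihood-based re-genotyping: for
#' every consensus site and sample the genotype is taken from the
#' highest-priority call set that contains the site and has a
#' non-missing call for that sample; otherwise it stays missing.
#'
#' @param consensus the `CallSet` from [union_sites()]
#' @param callsets the supporting `CallSet`s
#' @param priority ordered character vector of call-set labels, highest
#'   priority first; must cover all labels
#' @return the consensus `CallSet` with genotypes filled
#' @export
reconcile_genotypes <- function(consensus, callsets,
                                priority = vapply(callsets, `[[`, "", "label")) {
  labels <- vapply(callsets, `[[`, "", "label")
  if (!setequal(priority, labels))
    stop("priority must cover exactly the call-set labels")
  samples <- consensus$samples
  missing_samples <- lapply(callsets, function(cs) setdiff(samples, cs$samples))
  if (any(lengths(missing_samples) > 0L))
    warning("some call sets lack consensus samples; their cells stay missing")
  ckeys <- site_keys(consensus)
  gt <- empty_gt(length(ckeys), samples)
  for (lab in priority) {
    cs <- callsets[[match(lab, labels)]]
    idx <- match(ckeys, site_keys(cs))        # consensus row -> cs row
    rows <- which(!is.na(idx))
    scols <- match(samples, cs$samples)
    for (j in seq_along(samples)) {
      sj <- scols[j]
      if (is.na(sj)) next
      open <- rows[gt$miss[rows, j] & !cs$gt$miss[idx[rows], sj]]
      if (!length(open)) next
      gt$a1[open, j] <- cs$gt$a1[idx[open], sj]
      gt$a2[open, j] <- cs$gt$a2[idx[open], sj]
      gt$phased[open, j] <- cs$gt$phased[idx[open], sj]
      gt$miss[open, j] <- FALSE
    }
  }
  consensus$gt <- gt
  consensus
}

#' Concatenate two call sets (e.g. SNV-only and INDEL-only consensus)
#'
#' @param a,b `CallSet`s over the same samples. Keys shared between the
#'   two collapse to the record from `a` with a warning. A sample-order
#'   mismatch in `b` is re-ordered with a message.
#' @return the sorted combined `CallSet` (label taken from `a`)
#' @export
concat_callsets <- function(a, b) {
  if (!setequal(a$samples, b$samples))
    stop("concat_callsets requires the same samples in both call sets")
  if (!identical(a$samples, b$samples)) {
    message("concat_callsets: re-ordering samples of '", b$label, "'")
    perm <- match(a$samples, b$samples)
    b$samples <- a$samples
    b$gt <- lapply(b$gt, function(m) m[, perm, drop = FALSE])
  }
  dup <- site_keys(b) %in% site_keys(a)
  if (any(dup)) {
    warning(sum(dup), " duplicate site key(s) in concat; keeping the first")
    b <- subset_callset(b, which(!dup))
  }
  sites <- rbind(a$sites, b$sites)
  rownames(sites) <- NULL
  gt <- Map(rbind, a$gt, b$gt)
  contigs <- c(a$contigs, setdiff(b$contigs, a$contigs))
  callset(a$label, a$samples, sites, gt, contigs = contigs)
}
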