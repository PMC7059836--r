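# Fixture builders and independent oracles shared across the suite.
# All fixtures are built in code; nothing is read from disk except
# files the tests themselves write to tempdir.

# A small biallelic call set from parallel vectors.
toy_callset <- function(contig, pos, ref, alt, label = "toy",
                        samples = character(), qual = NULL,
                        contigs = NULL, gt = NULL, filters = NULL,
                        info = NULL) {
  n <- length(pos)
  sites <- consensusvc:::new_sites(
    contig = rep_len(contig, n), pos = pos, ref = ref,
    alts = as.list(alt),
    qual = if (is.null(qual)) rep(NA_real_, n) else qual,
    filters = if (is.null(filters)) rep(list(character()), n) else filters,
    info = if (is.null(info)) rep(list(numeric()), n) else info)
  callset(label, samples, sites, gt = gt, contigs = contigs)
}

# Apply one biallelic variant to a contig string (1-based pos).
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# Enumerate every (pos, ref, alt) representation of the same edit by
# scanning all anchored windows of the contig; used as the oracle for
# left-alignment (the canonical form is the left-most minimal one).
equivalent_representations <- function(seq, pos, ref, alt, max_width = 8L) {
  target <- apply_variant(seq, pos, ref, alt)
  reps <- list()
  for (p in seq_len(nchar(seq))) {
    for (wr in 0:max_width) {
      if (p + wr > nchar(seq)) break
      r <- substr(seq, p, p + wr)
      for (wa in 0:max_width) {
        cand_alts <- unique(c(
          substr(target, p, p + wa),      # aligned guess
          substr(target, p - 1L, p + wa)))
        for (a in cand_alts) {
          if (!nzchar(a) || a == r) next
          if (!grepl("^[ACGT]+$", a)) next
          if (apply_variant(seq, p, r, a) == target)
            reps[[length(reps) + 1L]] <- list(pos = p, ref = r, alt = a)
        }
      }
    }
  }
  reps
}

# Per-base boolean-array oracle for interval coverage and membership.
brute_cover <- function(intervals, len) {
  covered <- logical(len)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i] + 1L; e <- intervals$end[i]
    covered[s:e] <- TRUE
  }
  covered
}

# A deterministic random reference.
toy_reference <- function(lens = c(chr1 = 1000L), seed = 42L) {
  set.seed(seed)
  reference_sequence(vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1)))
}

# Genotype matrices from "a/b" or "a|b" strings (rows = sites).
gt_from_strings <- function(strs, samples) {
  m <- matrix(strs, ncol = length(samples), byrow = TRUE)
  a1 <- matrix(suppressWarnings(
    as.integer(sub("[/|].*", "", ifelse(m == "./.", NA, m)))),
    nrow(m), ncol(m), dimnames = list(NULL, samples))
  a2 <- matrix(suppressWarnings(
    as.integer(sub(".*[/|]", "", ifelse(m == "./.", NA, m)))),
    nrow(m), ncol(m), dimnames = list(NULL, samples))
  list(a1 = a1, a2 = a2,
       phased = matrix(grepl("|", m, fixed = TRUE), nrow(m), ncol(m),
                       dimnames = list(NULL, samples)),
       miss = matrix(m == "./.", nrow(m), ncol(m),
                     dimnames = list(NULL, samples)))
}

# Exact 99% binomial confidence bounds for an observed proportion.
binom_ci99 <- function(x, n) {
  as.numeric(stats::binom.test(x, n, conf.level = 0.99)$conf.int)
}
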