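# Synthetic multi-caller data with known truth. The generator emulates
# the statistical structure the integration pipeline assumes: a diploid
# truth panel over a toy reference, several callers sharing that truth
# but differing in sensitivity, false-positive rate and variant
# representation, phased predictions with a controlled switch-error
# rate, and the four region classes (confidence, exclusion, novel,
# PAR). Every operation is a pure function of (inputs, seed).

#' Annotation distributions for simulated callers
#'
#' Gaussian (mean, sd) laws per annotation, separately for true and
#' false sites, chosen so that true and false annotation distributions
#' are well separated and empirical cutoff derivation has signal to
#' learn from. Fraction-valued annotations are clamped to [0, 1] after
#' sampling; DP and IDV are rounded to counts.
#'
#' @return nested list: annotation -> list(tp = c(mean, sd),
#'   fp = c(mean, sd))
#' @export
default_annotation_laws <- function() {
  list(
    QUAL = list(tp = c(60, 15), fp = c(8, 5)),
    DP   = list(tp = c(500, 80), fp = c(1500, 200)),
    MQ   = list(tp = c(55, 4), fp = c(30, 6)),
    MQ0F = list(tp = c(0.01, 0.01), fp = c(0.20, 0.08)),
    HOB  = list(tp = c(0.05, 0.03), fp = c(0.30, 0.10)),
    SGB  = list(tp = c(0, 500), fp = c(4000, 800)),
    IDV  = list(tp = c(20, 8), fp = c(80, 15)),
    IMF  = list(tp = c(0.8, 0.1), fp = c(0.1, 0.05))
  )
}

#' A simulated caller's behaviour profile
#'
#' @param label provenance label
#' @param sensitivity probability of emitting each truth site, in (0, 1]
#' @param fdr expected fraction of emitted sites that are false, in
#'   [0, 1)
#' @param representation_style how the caller writes variants:
#'   `"canonical"`, `"right_shifted"` (INDELs shifted off their
#'   left-aligned position), `"mnp_joined"` (adjacent SNVs joined into
#'   MNPs) or `"multiallelic_merged"` (co-located INDEL+SNV pairs
#'   merged into one multiallelic row)
#' @param annotation_laws per-annotation TP/FP sampling laws
#' @param novel_blind if `TRUE` the caller emits nothing inside the
#'   novel regions (emulating a lift-over source that predates the new
#'   contigs)
#' @param fp_indel_fraction fraction of false sites that are INDELs
#' @return a `CallerProfile` list
#' @export
caller_profile <- function(label, sensitivity, fdr,
                           representation_style = c("canonical", "right_shifted",
                                                    "mnp_joined",
                                                    "multiallelic_merged"),
                           annotation_laws = default_annotation_laws(),
                           novel_blind = FALSE, fp_indel_fraction = 0.15) {
  representation_style <- match.arg(representation_style)
  stopifnot(sensitivity > 0, sensitivity <= 1, fdr >= 0, fdr < 1)
  structure(list(label = label, sensitivity = sensitivity, fdr = fdr,
                 representation_style = representation_style,
                 annotation_laws = annotation_laws,
                 novel_blind = novel_blind,
                 fp_indel_fraction = fp_indel_fraction),
            class = "CallerProfile")
}

#' Default caller panel
#'
#' Four callers mirroring the supporting call sets of a multi-caller
#' integration: a sensitive genome-wide caller (`gatk`), a caller that
#' reports MNPs (`freebayes`), a low-coverage caller with off-canonical
#' INDEL placement (`lc_bcftools`), and an exome-like caller with low
#' genome-wide sensitivity that merges co-located alleles
#' (`ex_bcftools`).
#'
#' @return named list of [caller_profile()] objects
#' @export
default_caller_profiles <- function() {
  list(
    gatk = caller_profile("gatk", 0.97, 0.02, "canonical"),
    freebayes = caller_profile("freebayes", 0.95, 0.05, "mnp_joined"),
    lc_bcftools = caller_profile("lc_bcftools", 0.90, 0.05, "right_shifted"),
    ex_bcftools = caller_profile("ex_bcftools", 0.35, 0.02,
                                 "multiallelic_merged")
  )
}

#' Simulation configuration
#'
#' @param seed integer seed; every generator operation derives all its
#'   randomness from it
#' @param contigs named integer vector of contig lengths (each >= 100)
#' @param n_samples number of diploid samples
#' @param n_sites total truth sites across contigs
#' @param indel_fraction fraction of truth sites that are INDELs
#' @param mnp_fraction fraction of truth sites that are members of
#'   adjacent SNV pairs (MNP source material)
#' @param multiallelic_fraction fraction of truth sites that are
#'   members of co-located INDEL+SNV pairs (multiallelic source
#'   material)
#' @param af_beta Beta(a, b) parameters of the allele-frequency law
#' @param caller_profiles named list of [caller_profile()]s
#' @param phase_flip_rate per-het-site haplotype flip probability for
#'   simulated phasing, in [0, 0.5)
#' @param confidence_fraction approximate fraction of each contig
#'   covered by the high-confidence regions
#' @param exclusion_fraction fraction covered by the central exclusion
#'   (centromere-like) interval on each autosome
#' @param par_fraction fraction of the X contig inside the
#'   pseudo-autosomal regions (split across both ends)
#' @param x_contig,y_contig,novel_contig special contig names; set to
#'   `NA` to omit the corresponding structure
#' @return a `SimulationConfig` list
#' @export
simulation_config <- function(seed = 1L,
                              contigs = c(chr1 = 120000L, chr2 = 120000L,
                                          chrX = 40000L, chrY = 15000L,
                                          chr1_KI270706v1_random = 30000L),
                              n_samples = 20L, n_sites = 2000L,
                              indel_fraction = 0.15, mnp_fraction = 0.06,
                              multiallelic_fraction = 0.04,
                              af_beta = c(1.5, 3),
                              caller_profiles = default_caller_profiles(),
                              phase_flip_rate = 0.02,
                              confidence_fraction = 0.8,
                              exclusion_fraction = 0.05,
                              par_fraction = 0.1,
                              x_contig = "chrX", y_contig = "chrY",
                              novel_contig = "chr1_KI270706v1_random") {
  stopifnot(all(contigs >= 100L), n_sites >= 1L, n_samples >= 1L,
            indel_fraction >= 0, indel_fraction <= 1,
            mnp_fraction >= 0, mnp_fraction <= 1,
            multiallelic_fraction >= 0, multiallelic_fraction <= 1,
            indel_fraction + mnp_fraction + multiallelic_fraction <= 1,
            phase_flip_rate >= 0, phase_flip_rate < 0.5,
            confidence_fraction > 0, confidence_fraction <= 1)
  structure(list(seed = as.integer(seed), contigs = contigs,
                 n_samples = as.integer(n_samples),
                 n_sites = as.integer(n_sites),
                 indel_fraction = indel_fraction,
                 mnp_fraction = mnp_fraction,
                 multiallelic_fraction = multiallelic_fraction,
                 af_beta = af_beta, caller_profiles = caller_profiles,
                 phase_flip_rate = phase_flip_rate,
                 confidence_fraction = confidence_fraction,
                 exclusion_fraction = exclusion_fraction,
                 par_fraction = par_fraction,
                 x_contig = x_contig, y_contig = y_contig,
                 novel_contig = novel_contig),
            class = "SimulationConfig")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Windows kept at random until the target fraction is covered.
random_cover <- function(len, fraction, window = 2000L) {
  if (fraction >= 1) return(data.frame(start = 0L, end = len))
  starts <- seq(0L, len - 1L, by = window)
  keep <- runif(length(starts)) < fraction
  if (!any(keep)) keep[sample(length(starts), 1L)] <- TRUE
  data.frame(start = starts[keep], end = pmin(starts[keep] + window, len))
}

#' Generate a diploid truth panel, reference and region sets
#'
#' The truth call set contains canonical biallelic sites: SNVs, simple
#' left-aligned INDELs, adjacent SNV pairs (MNP source material) and
#' co-located INDEL+SNV pairs (multiallelic source material), with
#' phased genotypes drawn from Hardy-Weinberg proportions at Beta-law
#' allele frequencies. Region sets cover the configured fractions:
#' high-confidence windows per contig, a central centromere-like
#' exclusion per autosome, PAR intervals at both ends of the X contig,
#' and the full span of the novel contig. Fully reproducible from the
#' config seed.
#'
#' @param cfg a [simulation_config()]
#' @return list with `reference` (a `ReferenceSequence`), `truth`
#'   (a phased `CallSet`), `regions` (list of `RegionSet`s:
#'   `confidence`, `exclusion`, `novel`, `par`), `allele_freq`
#'   (per-site sampled frequencies) and `config`
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  contigs <- cfg$contigs
  seqs <- vapply(contigs, random_dna, character(1))
  ref <- reference_sequence(seqs)

  # --- region sets -----------------------------------------------------
  autosomes <- setdiff(names(contigs),
                       c(cfg$x_contig, cfg$y_contig, cfg$novel_contig))
  conf <- do.call(rbind, lapply(names(contigs), function(ctg)
    cbind(contig = ctg, random_cover(contigs[[ctg]], cfg$confidence_fraction))))
  conf$start <- as.integer(conf$start); conf$end <- as.integer(conf$end)
  excl <- do.call(rbind, lapply(autosomes, function(ctg) {
    len <- contigs[[ctg]]
    w <- max(1L, as.integer(len * cfg$exclusion_fraction))
    s <- as.integer((len - w) / 2)
    data.frame(contig = ctg, start = s, end = s + w)
  }))
  novel <- if (!is.na(cfg$novel_contig) && cfg$novel_contig %in% names(contigs))
    data.frame(contig = cfg$novel_contig, start = 0L,
               end = contigs[[cfg$novel_contig]]) else NULL
  par <- if (!is.na(cfg$x_contig) && cfg$x_contig %in% names(contigs)) {
    lenx <- contigs[[cfg$x_contig]]
    w <- max(1L, as.integer(lenx * cfg$par_fraction / 2))
    data.frame(contig = cfg$x_contig, start = c(0L, lenx - w),
               end = c(w, lenx))
  } else NULL
  regions <- list(confidence = region_set(conf, "confidence"),
                  exclusion = region_set(excl, "exclusion"),
                  novel = region_set(novel, "novel"),
                  par = region_set(par, "par"))

  # --- site scaffold ---------------------------------------------------
  # Units occupy 12-bp slots so that independently placed variants never
  # interact; pairs (MNP / multiallelic source) live inside one slot.
  n_mnp_pairs <- round(cfg$n_sites * cfg$mnp_fraction / 2)
  n_ma_pairs <- round(cfg$n_sites * cfg$multiallelic_fraction / 2)
  n_single <- cfg$n_sites - 2L * (n_mnp_pairs + n_ma_pairs)
  n_indel <- round(cfg$n_sites * cfg$indel_fraction)
  n_snv <- n_single - n_indel
  stopifnot(n_snv >= 0L)
  n_units <- n_single + n_mnp_pairs + n_ma_pairs
  unit_type <- sample(c(rep("snv", n_snv), rep("indel", n_indel),
                        rep("mnp", n_mnp_pairs), rep("ma", n_ma_pairs)))

  slot_ctg <- rep(names(contigs), times = floor((contigs - 30L) / 12L))
  slot_pos <- unlist(lapply(contigs, function(len)
    seq(15L, by = 12L, length.out = floor((len - 30L) / 12L))),
    use.names = FALSE)
  if (n_units > length(slot_pos))
    stop("site density infeasible for the configured contig lengths")
  pick <- sample(length(slot_pos), n_units)
  u_ctg <- slot_ctg[pick]; u_pos <- slot_pos[pick]

  other_base <- function(b) {
    vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
  }
  rows <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    ctg <- u_ctg[u]; p <- u_pos[u]; seq <- seqs[[ctg]]
    type <- unit_type[u]
    if (type == "snv") {
      rb <- substr(seq, p, p)
      rows[[u]] <- data.frame(contig = ctg, pos = p, ref = rb,
                              alt = other_base(rb), pair = NA,
                              stringsAsFactors = FALSE)
    } else if (type == "mnp") {
      rb1 <- substr(seq, p, p); rb2 <- substr(seq, p + 1L, p + 1L)
      rows[[u]] <- data.frame(contig = ctg, pos = c(p, p + 1L),
                              ref = c(rb1, rb2),
                              alt = c(other_base(rb1), other_base(rb2)),
                              pair = "mnp", stringsAsFactors = FALSE)
    } else if (type == "indel") {
      # draw until the record is already canonical (left-aligned) at p
      for (try in 1:25) {
        L <- sample(1:3, 1L)
        if (runif(1) < 0.5) {  # deletion of L bases after the anchor
          r <- substr(seq, p, p + L); a <- substr(seq, p, p)
        } else {               # insertion of L random bases
          r <- substr(seq, p, p)
          a <- paste0(r, random_dna(L))
        }
        la <- left_align_alleles(p, c(r, a), seq)
        if (la$pos == p && la$alleles[1] == r && la$alleles[2] == a) break
        r <- NULL
      }
      if (is.null(r)) {  # fall back to an SNV in pathological contexts
        rb <- substr(seq, p, p)
        rows[[u]] <- data.frame(contig = ctg, pos = p, ref = rb,
                                alt = other_base(rb), pair = NA,
                                stringsAsFactors = FALSE)
      } else {
        rows[[u]] <- data.frame(contig = ctg, pos = p, ref = r, alt = a,
                                pair = NA, stringsAsFactors = FALSE)
      }
    } else {  # ma: deletion at p plus SNV at p+1 inside the deleted span
      ok <- FALSE
      for (try in 1:25) {
        L <- sample(1:2, 1L)
        r <- substr(seq, p, p + L); a <- substr(seq, p, p)
        la <- left_align_alleles(p, c(r, a), seq)
        if (la$pos == p && la$alleles[1] == r && la$alleles[2] == a) {
          ok <- TRUE; break
        }
      }
      rb2 <- substr(seq, p + 1L, p + 1L)
      if (ok) {
        rows[[u]] <- data.frame(contig = ctg, pos = c(p, p + 1L),
                                ref = c(r, rb2),
                                alt = c(a, other_base(rb2)),
                                pair = "ma", stringsAsFactors = FALSE)
      } else {
        rows[[u]] <- data.frame(contig = ctg, pos = p + 1L, ref = rb2,
                                alt = other_base(rb2), pair = NA,
                                stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  # pair ids: members of one unit share a group number
  df$group <- rep(seq_len(n_units), vapply(rows, nrow, integer(1)))

  # --- allele frequencies and phased genotypes -------------------------
  n <- nrow(df)
  af <- pmin(0.95, pmax(0.05, rbeta(n, cfg$af_beta[1], cfg$af_beta[2])))
  nsmp <- cfg$n_samples
  a1 <- matrix(rbinom(n * nsmp, 1L, rep(af, nsmp)), n, nsmp)
  a2 <- matrix(rbinom(n * nsmp, 1L, rep(af, nsmp)), n, nsmp)
  # pair members represent one mutation event: share AF and genotypes
  # (MNP pairs) or occupy distinct haplotypes (multiallelic pairs)
  for (g in unique(df$group[!is.na(df$pair)])) {
    i <- which(df$group == g)
    if (length(i) != 2L) next
    if (df$pair[i[1]] == "mnp") {
      af[i[2]] <- af[i[1]]
      a1[i[2], ] <- a1[i[1], ]; a2[i[2], ] <- a2[i[1], ]
    } else {  # ma: each haplotype carries at most one of the two alleles
      clash1 <- a1[i[1], ] == 1L & a1[i[2], ] == 1L
      clash2 <- a2[i[1], ] == 1L & a2[i[2], ] == 1L
      a1[i[2], clash1] <- 0L
      a2[i[2], clash2] <- 0L
    }
  }
  smp <- sprintf("S%02d", seq_len(nsmp))
  colnames(a1) <- colnames(a2) <- smp
  gt <- list(a1 = a1, a2 = a2,
             phased = matrix(TRUE, n, nsmp, dimnames = list(NULL, smp)),
             miss = matrix(FALSE, n, nsmp, dimnames = list(NULL, smp)))

  sites <- new_sites(contig = df$contig, pos = df$pos,
                     ref = df$ref, alts = as.list(df$alt))
  truth <- callset("truth", smp, sites, gt, contigs = names(contigs))
  ord <- order(match(df$contig, names(contigs)), df$pos, df$ref, df$alt,
               method = "radix")
  list(reference = ref, truth = truth, regions = regions,
       allele_freq = af[ord], config = cfg)
}

draw_law <- function(law, n) rnorm(n, law[1], law[2])

draw_annotations <- function(laws, is_tp, is_indel) {
  n <- length(is_tp)
  pick <- function(key) {
    v <- numeric(n)
    v[is_tp] <- draw_law(laws[[key]]$tp, sum(is_tp))
    v[!is_tp] <- draw_law(laws[[key]]$fp, sum(!is_tp))
    v
  }
  qual <- pmax(0, pick("QUAL"))
  dp <- pmax(1, round(pick("DP")))
  mq <- pmax(0, pick("MQ"))
  mq0f <- pmin(1, pmax(0, pick("MQ0F")))
  hob <- pmin(1, pmax(0, pick("HOB")))
  sgb <- pick("SGB")
  idv <- pmax(1, round(pick("IDV")))
  imf <- pmin(1, pmax(0, pick("IMF")))
  info <- lapply(seq_len(n), function(i) {
    v <- c(DP = dp[i], MQ = mq[i], MQ0F = mq0f[i], HOB = hob[i], SGB = sgb[i])
    if (is_indel[i]) v <- c(v, IDV = idv[i], IMF = imf[i])
    v
  })
  list(qual = qual, info = info)
}

# One right-shift of an anchored INDEL; NULL when the contig ends.
shift_right_once <- function(pos, r, a, seq) {
  endp <- pos + nchar(r) - 1L
  if (endp + 1L > nchar(seq)) return(NULL)
  if (substr(r, 1L, 1L) != substr(a, 1L, 1L)) return(NULL)
  nxt <- substr(seq, endp + 1L, endp + 1L)
  list(pos = pos + 1L,
       r = paste0(substr(r, 2L, nchar(r)), nxt),
       a = paste0(substr(a, 2L, nchar(a)), nxt))
}

#' Simulate one caller's call set from the truth panel
#'
#' Each truth site is emitted independently with probability
#' `sensitivity`; false sites are added so that the expected false
#' fraction of emitted sites equals `fdr`. The representation style is
#' then applied (right-shifting INDELs, joining adjacent SNVs into
#' MNPs, or merging co-located INDEL+SNV pairs into multiallelic
#' rows), and QUAL plus the filter annotations are drawn from the
#' profile's TP/FP laws. Truth membership of every emitted row is
#' recorded in the attribute `"truth_membership"` (testing side
#' channel only).
#'
#' @param truth the truth `CallSet` from [generate_truth()]
#' @param profile a [caller_profile()]
#' @param ref the matching `ReferenceSequence`
#' @param seed integer seed
#' @param novel optional novel `RegionSet`; required when the profile
#'   is `novel_blind`
#' @return a `CallSet` labelled with the profile's label
#' @export
simulate_caller <- function(truth, profile, ref, seed, novel = NULL) {
  stopifnot(inherits(profile, "CallerProfile"))
  set.seed(seed)
  n <- n_sites(truth)
  sel <- runif(n) < profile$sensitivity
  if (profile$novel_blind) {
    if (is.null(novel)) stop("novel_blind caller needs the novel RegionSet")
    sel <- sel & !region_member(novel, truth$sites$contig, truth$sites$pos)
  }
  tsel <- subset_callset(truth, which(sel))

  # false sites at unoccupied positions, anchored to reference context
  n_tp <- n_sites(tsel)
  n_fp <- round(n_tp * profile$fdr / (1 - profile$fdr))
  fp_rows <- NULL
  if (n_fp > 0L) {
    occupied <- split(truth$sites$pos, truth$sites$contig)
    lens <- contig_lengths(ref)
    ctgs <- names(lens)
    if (profile$novel_blind && length(novel$ranges))
      ctgs <- setdiff(ctgs, names(novel$ranges))
    fp_list <- vector("list", n_fp)
    made <- 0L; budget <- n_fp * 40L
    while (made < n_fp && budget > 0L) {
      budget <- budget - 1L
      ctg <- sample(ctgs, 1L, prob = lens[ctgs])
      p <- sample(10:(lens[[ctg]] - 10L), 1L)
      occ <- occupied[[ctg]] %||% integer()
      if (length(occ) && any(abs(occ - p) <= 6L)) next
      seq <- ref$contigs[[ctg]]
      if (runif(1) < profile$fp_indel_fraction) {
        L <- sample(1:2, 1L)
        if (runif(1) < 0.5) {
          r <- substr(seq, p, p + L); a <- substr(seq, p, p)
        } else {
          r <- substr(seq, p, p); a <- paste0(r, random_dna(L))
        }
        la <- left_align_alleles(p, c(r, a), seq)
        p <- la$pos; r <- la$alleles[1]; a <- la$alleles[2]
      } else {
        r <- substr(seq, p, p)
        a <- sample(setdiff(c("A", "C", "G", "T"), r), 1L)
      }
      made <- made + 1L
      occupied[[ctg]] <- c(occupied[[ctg]], p)
      fp_list[[made]] <- data.frame(contig = ctg, pos = p, ref = r, alt = a,
                                    stringsAsFactors = FALSE)
    }
    fp_rows <- do.call(rbind, fp_list[seq_len(made)])
  }

  # assemble emitted rows (truth subset + false sites)
  sites <- tsel$sites
  gt <- tsel$gt
  is_true <- rep(TRUE, nrow(sites))
  if (!is.null(fp_rows) && nrow(fp_rows)) {
    m <- nrow(fp_rows)
    nsmp <- length(truth$samples)
    f_a1 <- matrix(rbinom(m * nsmp, 1L, 0.15), m, nsmp,
                   dimnames = list(NULL, truth$samples))
    f_a2 <- matrix(rbinom(m * nsmp, 1L, 0.15), m, nsmp,
                   dimnames = list(NULL, truth$samples))
    none <- rowSums(f_a1) + rowSums(f_a2) == 0L
    f_a1[none, 1L] <- 1L
    fsites <- new_sites(contig = fp_rows$contig, pos = fp_rows$pos,
                        ref = fp_rows$ref, alts = as.list(fp_rows$alt))
    sites <- rbind(sites, fsites)
    rownames(sites) <- NULL
    gt <- list(a1 = rbind(gt$a1, f_a1), a2 = rbind(gt$a2, f_a2),
               phased = rbind(gt$phased,
                              matrix(FALSE, m, nsmp,
                                     dimnames = list(NULL, truth$samples))),
               miss = rbind(gt$miss,
                            matrix(FALSE, m, nsmp,
                                   dimnames = list(NULL, truth$samples))))
    is_true <- c(is_true, rep(FALSE, m))
  }
  ord <- order(match(sites$contig, truth$contigs), sites$pos,
               method = "radix")
  sites <- sites[ord, , drop = FALSE]; rownames(sites) <- NULL
  gt <- lapply(gt, function(x) x[ord, , drop = FALSE])
  is_true <- is_true[ord]

  # --- representation style -------------------------------------------
  style <- profile$representation_style
  alt1 <- vapply(sites$alts, `[`, "", 1L)
  drop <- rep(FALSE, nrow(sites))
  fallback <- 0L
  if (style == "right_shifted") {
    for (i in seq_len(nrow(sites))) {
      if (nchar(sites$ref[i]) == nchar(alt1[i])) next
      seq <- ref$contigs[[sites$contig[i]]]
      s <- shift_right_once(sites$pos[i], sites$ref[i], alt1[i], seq)
      if (is.null(s)) { fallback <- fallback + 1L; next }
      s2 <- shift_right_once(s$pos, s$r, s$a, seq)
      if (!is.null(s2) && runif(1) < 0.5) s <- s2
      sites$pos[i] <- s$pos; sites$ref[i] <- s$r; sites$alts[[i]] <- s$a
    }
  } else if (style == "mnp_joined") {
    i <- 1L
    while (i < nrow(sites)) {
      j <- i + 1L
      if (!drop[i] &&
          sites$contig[i] == sites$contig[j] &&
          sites$pos[j] == sites$pos[i] + 1L &&
          nchar(sites$ref[i]) == 1L && nchar(alt1[i]) == 1L &&
          nchar(sites$ref[j]) == 1L && nchar(alt1[j]) == 1L) {
        sites$ref[i] <- paste0(sites$ref[i], sites$ref[j])
        sites$alts[[i]] <- paste0(alt1[i], alt1[j])
        drop[j] <- TRUE
        i <- i + 2L
      } else i <- i + 1L
    }
  } else if (style == "multiallelic_merged") {
    i <- 1L
    while (i < nrow(sites)) {
      j <- i + 1L
      lr <- nchar(sites$ref[i])
      if (!drop[i] && lr > 1L &&
          sites$contig[i] == sites$contig[j] &&
          sites$pos[j] > sites$pos[i] &&
          sites$pos[j] <= sites$pos[i] + lr - 1L &&
          nchar(sites$ref[j]) == 1L && nchar(alt1[j]) == 1L) {
        off <- sites$pos[j] - sites$pos[i] + 1L
        alt2 <- sites$ref[i]
        substr(alt2, off, off) <- alt1[j]
        merged <- sort(c(alt1[i], alt2))
        sites$alts[[i]] <- merged
        # recode genotypes onto the merged allele indexing
        del_idx <- match(alt1[i], merged); snv_idx <- match(alt2, merged)
        for (nm in c("a1", "a2")) {
          vi <- gt[[nm]][i, ]; vj <- gt[[nm]][j, ]
          out <- integer(length(vi))
          out[vi == 1L] <- del_idx
          out[vi == 0L & vj == 1L] <- snv_idx
          gt[[nm]][i, ] <- out
        }
        drop[j] <- TRUE
        i <- i + 2L
      } else i <- i + 1L
    }
  }
  if (fallback > 0L)
    message("simulate_caller(", profile$label, "): ", fallback,
            " INDEL(s) kept canonical (no room to shift)")
  keep <- which(!drop)
  sites <- sites[keep, , drop = FALSE]; rownames(sites) <- NULL
  gt <- lapply(gt, function(x) x[keep, , drop = FALSE])
  is_true <- is_true[keep]

  ann <- draw_annotations(profile$annotation_laws, is_true,
                          nchar(sites$ref) != nchar(vapply(sites$alts, `[`,
                                                           "", 1L)))
  sites$qual <- ann$qual
  sites$info <- ann$info
  gt$phased[] <- FALSE
  out <- callset(profile$label, truth$samples, sites, gt,
                 contigs = truth$contigs, sorted = FALSE)
  # re-derive truth membership after the sort inside callset()
  ord2 <- order(match(sites$contig, truth$contigs), sites$pos, sites$ref,
                vapply(sites$alts, paste, "", collapse = ","),
                method = "radix")
  attr(out, "truth_membership") <- is_true[ord2]
  out
}

#' Simulate phasing with a controlled switch-error source
#'
#' Independently swaps the haplotype assignment of each heterozygous
#' genotype with probability `flip_rate`; homozygous and missing calls
#' are untouched. With per-site flip probability p, the expected
#' orientation-transition rate measured by [switch_error()] is
#' 2 p (1 - p).
#'
#' @param truth a phased `CallSet`
#' @param flip_rate per-site flip probability, in [0, 0.5)
#' @param seed integer seed
#' @return a `CallSet` labelled `<truth label>_phased`
#' @export
simulate_phasing <- function(truth, flip_rate, seed) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5)
  set.seed(seed)
  out <- truth
  out$label <- paste0(truth$label, "_phased")
  het <- !out$gt$miss & !is.na(out$gt$a1) & !is.na(out$gt$a2) &
    out$gt$a1 != out$gt$a2 & out$gt$phased
  flip <- het & matrix(runif(length(het)) < flip_rate,
                       nrow(het), ncol(het))
  tmp <- out$gt$a1[flip]
  out$gt$a1[flip] <- out$gt$a2[flip]
  out$gt$a2[flip] <- tmp
  out
}

#' Generate a synthetic gold-standard call set
#'
#' A downsampled (and optionally augmented) copy of the truth panel
#' standing in for an independently curated gold standard, so that
#' concordance of a simulated caller against it has analytically known
#' expectations.
#'
#' @param truth the truth `CallSet`
#' @param gold_sensitivity fraction of truth sites retained
#' @param gold_fp_rate expected fraction of gold sites absent from the
#'   truth
#' @param seed integer seed
#' @param ref reference, required when `gold_fp_rate > 0`
#' @return a `CallSet` labelled `"gold"`
#' @export
generate_gold <- function(truth, gold_sensitivity = 1, gold_fp_rate = 0,
                          seed = 1L, ref = NULL) {
  set.seed(seed)
  keep <- runif(n_sites(truth)) < gold_sensitivity
  out <- subset_callset(truth, which(keep))
  out$label <- "gold"
  if (gold_fp_rate > 0) {
    stopifnot(!is.null(ref))
    prof <- caller_profile("gold_extra", sensitivity = 1,
                           fdr = gold_fp_rate, "canonical")
    aug <- simulate_caller(out, prof, ref, seed = seed + 1L)
    extra <- subset_callset(aug, which(!attr(aug, "truth_membership")))
    extra$label <- "gold"
    extra$gt$phased[] <- TRUE
    out <- concat_callsets(out, extra)
  }
  out
}
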