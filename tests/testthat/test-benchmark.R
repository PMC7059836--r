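# Evaluation suite: concordance arithmetic, switch-error counting,
# false-negative attribution, region stratification, aggregation.

test_that("concordance report arithmetic matches the released chr1 row", {
  rep <- concordance_report(data.frame(contig = "chr1", tp = 238323,
                                       fn = 8965, fp = 1347))
  r <- rep[rep$contig == "chr1", ]
  expect_equal(r$total_gold, 247288)
  expect_equal(r$total_query, 239670)
  expect_equal(round(r$pct_shared, 2), 96.37)
  expect_equal(round(r$pct_gold_only, 2), 3.63)
  expect_equal(round(r$pct_query_only, 2), 0.56)
})

test_that("perfect concordance and set-algebra oracle", {
  g <- toy_callset("chr1", seq(10L, 200L, by = 10L), rep("A", 20),
                   rep("T", 20), label = "gold")
  rep <- concordance(g, g)
  expect_equal(rep$pct_shared[1], 100)
  expect_equal(rep$pct_gold_only[1], 0)
  expect_equal(rep$pct_query_only[1], 0)

  set.seed(31)
  qpos <- sort(sample(seq(5L, 3000L, by = 5L), 200L))
  gpos <- sort(sample(seq(5L, 3000L, by = 5L), 200L))
  q <- toy_callset(rep(c("chr1", "chr2"), each = 100), c(qpos[1:100], qpos[101:200]),
                   rep("A", 200), rep("T", 200), label = "q",
                   contigs = c("chr1", "chr2"))
  g2 <- toy_callset(rep(c("chr1", "chr2"), each = 100), c(gpos[1:100], gpos[101:200]),
                    rep("A", 200), rep("T", 200), label = "g",
                    contigs = c("chr1", "chr2"))
  rep2 <- concordance(q, g2)
  for (ctg in c("chr1", "chr2")) {
    qk <- site_keys(q)[q$sites$contig == ctg]
    gk <- site_keys(g2)[g2$sites$contig == ctg]
    r <- rep2[rep2$contig == ctg, ]
    expect_equal(r$tp, length(intersect(qk, gk)))
    expect_equal(r$fp, length(setdiff(qk, gk)))
    expect_equal(r$fn, length(setdiff(gk, qk)))
  }
  # symmetry: swapping query and gold exchanges FP and FN, TP fixed
  rep3 <- concordance(g2, q)
  expect_equal(rep3$tp, rep2$tp)
  expect_equal(rep3$fp, rep2$fn)
  expect_equal(rep3$fn, rep2$fp)
})

# Build a two-haplotype phased single-sample call set from 0/1 strings,
# one character per het site.
phased_pair <- function(hap1, hap2 = NULL) {
  h1 <- as.integer(strsplit(hap1, "")[[1]])
  h2 <- if (is.null(hap2)) 1L - h1 else as.integer(strsplit(hap2, "")[[1]])
  n <- length(h1)
  gt <- list(a1 = matrix(h1, n, 1, dimnames = list(NULL, "S1")),
             a2 = matrix(h2, n, 1, dimnames = list(NULL, "S1")),
             phased = matrix(TRUE, n, 1, dimnames = list(NULL, "S1")),
             miss = matrix(FALSE, n, 1, dimnames = list(NULL, "S1")))
  toy_callset("chr1", seq(10L, by = 10L, length.out = n), rep("A", n),
              rep("T", n), label = "ph", samples = "S1", gt = gt)
}

test_that("the worked haplotype example counts one switch between sites 3 and 4", {
  truth <- phased_pair("000111")   # haplotypes 000111 | 111000
  pred <- phased_pair("000000")    # haplotypes 000000 | 111111
  se <- switch_error(truth, pred, "S1")
  expect_equal(se$switches[se$contig == "chr1"], 1L)
  expect_equal(se$pairs[se$contig == "chr1"], 5L)
  o <- attr(se, "orientations")$chr1
  expect_equal(which(o[-1] != o[-length(o)]), 3L)  # between sites 3 and 4
})

test_that("switch error is zero under identical or globally flipped phase", {
  truth <- phased_pair("010011")
  expect_equal(switch_error(truth, truth, "S1")$switches[1], 0L)
  flipped <- truth
  flipped$gt[c("a1", "a2")] <- flipped$gt[c("a2", "a1")]
  names(flipped$gt)[1:2] <- c("a1", "a2")
  expect_equal(switch_error(truth, flipped, "S1")$switches[1], 0L)
  expect_equal(switch_error(flipped, truth, "S1")$switches[1], 0L)
})

test_that("non-assessable sites are excluded from switch chains", {
  truth <- phased_pair("0101")
  pred <- phased_pair("0101")
  pred$gt$a2[2, 1] <- 1L  # hom in prediction -> genotype error, not phase
  pred$gt$a1[2, 1] <- 1L
  pred$gt$phased[3, 1] <- FALSE  # unphased -> not assessable
  se <- switch_error(truth, pred, "S1")
  expect_equal(se$sites[1], 2L)  # sites 1 and 4 only
  expect_equal(se$pairs[1], 1L)
  expect_error(switch_error(truth, pred, "S9"), "sample not present")
})

test_that("simulated flips recover the 2p(1-p) transition rate", {
  p <- 0.02
  expected <- 2 * p * (1 - p)
  n <- 3000L
  set.seed(41)
  h1 <- rbinom(n, 1L, 0.5)
  truth <- phased_pair(paste(h1, collapse = ""))
  rates <- vapply(1:5, function(s) {
    pred <- simulate_phasing(truth, p, seed = 100L + s)
    se <- switch_error(truth, pred, "S1")
    c(se$switches[1], se$pairs[1])
  }, numeric(2))
  # pooled count within the exact binomial 99% CI of 2p(1-p)
  ci <- binom_ci99(sum(rates[1, ]), sum(rates[2, ]))
  expect_gte(expected, ci[1])
  expect_lte(expected, ci[2])
  # exhaustive pairwise oracle on one replicate
  pred <- simulate_phasing(truth, p, seed = 101L)
  se <- switch_error(truth, pred, "S1")
  o <- truth$gt$a1[, 1] == pred$gt$a1[, 1]
  manual <- sum(vapply(2:n, function(i) o[i] != o[i - 1L], logical(1)))
  expect_equal(se$switches[1], manual)
})

test_that("FN attribution arithmetic matches the released chr1 row and AVG", {
  tabs <- released_evaluation_tables()
  rep <- attribution_report(tabs$fn_attribution_counts)
  chr1 <- rep[rep$contig == "chr1", ]
  expect_equal(round(chr1$pct_explained, 2), 72.82)
  avg <- rep[rep$contig == "AVG", ]
  expect_equal(round(avg$pct_explained, 1), 68.7)
})

test_that("FN attribution tallies filter labels from the pre-selection set", {
  filt <- toy_callset("chr1", c(10L, 20L, 30L, 40L), rep("A", 4),
                      rep("T", 4), label = "pre",
                      filters = list("T1", c("T1", "T2"), character(), "T2"))
  lab <- structure(list(tp = character(), fp = character(),
                        fn = c("chr1:10:A:T", "chr1:20:A:T", "chr1:30:A:T",
                               "chr1:50:A:T")), class = "LabeledSites")
  rep <- fn_attribution(lab, filt, c("T1", "T2"))
  r <- rep[rep$contig == "chr1", ]
  expect_equal(r$fn, 4L)
  expect_equal(r$T1, 2L)
  expect_equal(r$T2, 1L)
  expect_equal(r$attributed, 2L)  # distinct FN keys carrying >= 1 label
  expect_equal(r$pct_explained, 50)
  expect_lte(r$attributed, r$fn)

  none <- structure(list(tp = character(), fp = character(),
                         fn = "chr1:30:A:T"), class = "LabeledSites")
  expect_equal(fn_attribution(none, filt, c("T1", "T2"))$pct_explained[1], 0)
})

test_that("region stratification reproduces the released novel-contig shares", {
  tabs <- released_evaluation_tables()
  counts <- tabs$novel_contig_snv_counts
  novel <- counts[counts$region == "novel", ]
  share <- 100 * novel$this_work / (novel$this_work + novel$lift_over)
  expect_equal(round(share, 1), 55.7)

  # membership-based counting against a per-site oracle
  set.seed(51)
  rsnovel <- region_set(data.frame(contig = "chrN", start = 0, end = 5000),
                        "novel")
  mk <- function(lab, n) {
    ctg <- sample(c("chr1", "chrN"), n, replace = TRUE)
    toy_callset(ctg, sample(1:5000, n), rep("A", n), rep("T", n),
                label = lab, contigs = c("chr1", "chrN"))
  }
  cs1 <- mk("de_novo", 300); cs2 <- mk("lift_over", 300)
  st <- stratify_regions(list(de_novo = cs1, lift_over = cs2), rsnovel)
  expect_equal(st$shares$de_novo[st$shares$region == "novel"],
               sum(cs1$sites$contig == "chrN"))
  expect_equal(st$shares$lift_over[st$shares$region == "existing"],
               sum(cs2$sites$contig == "chr1"))
  expect_equal(sum(st$shares[1, c("de_novo_share_pct", "lift_over_share_pct")]),
               100)
  # empty novel set puts everything in "existing"
  st0 <- stratify_regions(list(a = cs1), region_set(NULL, "novel"))
  expect_equal(st0$shares$a, c(0L, n_sites(cs1)))

  # per-contig TP percentages inside novel regions against a gold set
  gold <- mk("gold", 200)
  st2 <- stratify_regions(list(q = cs1), rsnovel, gold = gold)
  gk <- site_keys(gold)[gold$sites$contig == "chrN"]
  qk <- site_keys(cs1)[cs1$sites$contig == "chrN"]
  expect_equal(st2$tp_by_contig$tp_pct_q,
               100 * length(intersect(qk, gk)) / length(gk))
})

test_that("aggregation is the unweighted mean and honours exclusions", {
  tabs <- released_evaluation_tables()
  se <- tabs$switch_error_rates
  expect_equal(round(mean(se$this_work[se$class == "snv"]), 2), 0.71)
  expect_equal(round(mean(se$this_work[se$class == "indel"]), 2), 1.78)

  df <- data.frame(contig = c("chr1", "chr2", "chrX"),
                   rate = c(1, 3, 100), n = c(10L, 20L, 5L))
  avg <- aggregate_report(df)
  expect_equal(avg$rate, 2)          # chrX excluded
  expect_equal(avg$n, 15)
  expect_equal(aggregate_report(df[1, ])$rate, 1)  # single row -> itself
  expect_error(aggregate_report(df[3, , drop = FALSE]), "all rows excluded")
  set.seed(61)
  rnd <- data.frame(contig = paste0("chr", 1:12),
                    a = runif(12), b = rnorm(12))
  avg2 <- aggregate_report(rnd)
  expect_equal(avg2$a, sum(rnd$a) / 12)
  expect_equal(avg2$b, sum(rnd$b) / 12)
})

test_that("reports print as rounded TSV", {
  rep <- concordance_report(data.frame(contig = "chr1", tp = 238323,
                                       fn = 8965, fp = 1347))
  path <- file.path(tempdir(), "rep.tsv")
  write_report_tsv(rep, path)
  lines <- readLines(path)
  expect_match(lines[1], "^contig\ttp\tfn\tfp")
  expect_match(lines[2], "96\\.37")
  expect_match(lines[2], "0\\.56")
})
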