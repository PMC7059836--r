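# Canonicalization: left-alignment, multiallelic split/merge,
# decomposition into allelic primitives, region exclusion, and the
# full normalization chain.

test_that("left-alignment finds the unique left-most minimal form", {
  ref <- reference_sequence(c(chr1 = "ATTTTC"))
  out <- left_align_trim(list(contig = "chr1", pos = 4L, ref = "TT",
                              alts = list("T")), ref)
  expect_equal(out$pos, 1L)
  expect_equal(out$ref, "AT")
  expect_equal(out$alts[[1]], "A")
  # oracle: among all equivalent representations of the edit, the
  # result is the minimal-width one at the left-most position
  reps <- equivalent_representations("ATTTTC", 4L, "TT", "T")
  widths <- vapply(reps, function(r) nchar(r$ref) + nchar(r$alt), numeric(1))
  minimal <- reps[widths == min(widths)]
  best <- minimal[[which.min(vapply(minimal, `[[`, numeric(1), "pos"))]]
  expect_equal(out$pos, best$pos)
  expect_equal(out$ref, best$ref)
  expect_equal(out$alts[[1]], best$alt)

  # SNVs are already minimal; interior shared bases are trimmed
  ref2 <- toy_reference(c(chr1 = 200L), seed = 1)
  snv <- list(contig = "chr1", pos = 100L,
              ref = substr(ref2$contigs[["chr1"]], 100, 100), alts = list("X"))
  snv$alts <- list(setdiff(c("A", "C", "G", "T"), snv$ref)[1])
  expect_equal(left_align_trim(snv, ref2), snv)

  ref3 <- reference_sequence(c(chr1 = paste0(strrep("A", 9), "CAG",
                                             strrep("A", 9))))
  out3 <- left_align_trim(list(contig = "chr1", pos = 10L, ref = "CAG",
                               alts = list("CTG")), ref3)
  expect_equal(out3$pos, 11L)
  expect_equal(out3$ref, "A")
  expect_equal(out3$alts[[1]], "T")
})

test_that("left-alignment errors on REF mismatch and contig-start extension", {
  ref <- reference_sequence(c(chr1 = "TTTTAC"))
  expect_error(left_align_trim(list(contig = "chr1", pos = 2L, ref = "AA",
                                    alts = list("A")), ref), "REF mismatch")
  expect_error(left_align_trim(list(contig = "chr1", pos = 1L, ref = "TT",
                                    alts = list("T")), ref), "contig start")
})

test_that("left-alignment is idempotent and preserves the edit", {
  ref <- toy_reference(c(chr1 = 1000L), seed = 11)
  seq <- ref$contigs[["chr1"]]
  set.seed(12)
  for (i in 1:60) {
    pos <- sample(20:950, 1)
    w <- sample(0:4, 1)
    r <- substr(seq, pos, pos + w)
    a <- if (runif(1) < 0.5) substr(seq, pos, pos) else
      paste0(r, paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                             replace = TRUE), collapse = ""))
    if (a == r) next
    site <- list(contig = "chr1", pos = pos, ref = r, alts = list(a))
    out <- left_align_trim(site, ref)
    # edit preservation: rewriting the contig gives the same string
    expect_equal(apply_variant(seq, out$pos, out$ref, out$alts[[1]]),
                 apply_variant(seq, pos, r, a))
    # idempotence
    out2 <- left_align_trim(out, ref)
    expect_equal(out2[c("pos", "ref", "alts")], out[c("pos", "ref", "alts")])
  }
})

test_that("multiallelic split recodes genotypes with the other-alt sentinel", {
  gt <- gt_from_strings(c("1|2", "0/0"), "S1")
  cs <- callset("m", "S1", consensusvc:::new_sites(
    contig = c("chr1", "chr1"), pos = c(100L, 200L), ref = c("A", "G"),
    alts = list(c("T", "G"), "C")), gt = gt)
  sp <- split_multiallelics(cs)
  expect_equal(n_sites(sp), 3L)
  # the A>G row sorts before A>T after splitting
  expect_equal(unlist(sp$sites$alts), c("G", "T", "C"))
  # row A>G: hap1 carried the T alt -> sentinel; hap2 carried G -> 1
  expect_true(is.na(sp$gt$a1[1, 1]))
  expect_equal(unname(sp$gt$a2[1, 1]), 1L)
  expect_false(sp$gt$miss[1, 1])
  # row A>T: hap1 -> 1, hap2 -> sentinel
  expect_equal(unname(sp$gt$a1[2, 1]), 1L)
  expect_true(is.na(sp$gt$a2[2, 1]))
  # biallelic input is untouched
  bi <- toy_callset("chr1", c(5L, 9L), c("A", "C"), c("T", "G"))
  expect_identical(split_multiallelics(bi), bi)
})

test_that("split and merge are mutually inverse on site sets", {
  expect_warning(
    mg <- merge_multiallelics(toy_callset("chr1", c(100L, 100L), c("A", "A"),
                                          c("T", "G"),
                                          info = list(c(DP = 5), c(DP = 9)))),
    "INFO")
  expect_equal(n_sites(mg), 1L)
  expect_equal(mg$sites$alts[[1]], c("G", "T"))  # lexicographic
  expect_equal(mg$sites$info[[1]], numeric())    # conflicting DP dropped

  # rows with different REF widths extend to the longest REF
  mg2 <- merge_multiallelics(toy_callset("chr1", c(50L, 50L), c("AG", "A"),
                                         c("A", "T")))
  expect_equal(mg2$sites$ref, "AG")
  expect_equal(mg2$sites$alts[[1]], c("A", "TG"))

  set.seed(33)
  for (rep in 1:5) {
    n <- 40L
    pos <- sort(sample(seq(10L, 4000L, by = 5L), n))
    alts <- lapply(seq_len(n), function(i)
      sample(c("T", "G", "C"), sample(1:3, 1)))
    cs <- callset("rnd", character(), consensusvc:::new_sites(
      contig = rep("chr1", n), pos = pos, ref = rep("A", n), alts = alts,
      qual = runif(n, 1, 100)))
    rt <- merge_multiallelics(split_multiallelics(cs))
    expect_equal(rt$sites$pos, cs$sites$pos)
    expect_equal(lapply(rt$sites$alts, sort), lapply(cs$sites$alts, sort))
  }
})

test_that("split genotypes reassemble exactly through merge", {
  set.seed(44)
  samples <- c("S1", "S2", "S3")
  n <- 30L
  alts <- lapply(seq_len(n), function(i) sample(c("T", "G", "C"),
                                                sample(1:3, 1)))
  k <- lengths(alts)
  a1 <- matrix(unlist(lapply(k, function(m) sample(0:m, 3, TRUE))), n, 3,
               byrow = TRUE, dimnames = list(NULL, samples))
  a2 <- matrix(unlist(lapply(k, function(m) sample(0:m, 3, TRUE))), n, 3,
               byrow = TRUE, dimnames = list(NULL, samples))
  gt <- list(a1 = a1, a2 = a2,
             phased = matrix(TRUE, n, 3, dimnames = list(NULL, samples)),
             miss = matrix(FALSE, n, 3, dimnames = list(NULL, samples)))
  cs <- callset("g", samples, consensusvc:::new_sites(
    contig = rep("chr1", n), pos = seq(10L, by = 10L, length.out = n),
    ref = rep("A", n), alts = alts), gt = gt)
  rt <- merge_multiallelics(split_multiallelics(cs))
  # map back: merged alts are sorted, so translate expected indices
  for (i in seq_len(n)) {
    perm <- c(0L, match(cs$sites$alts[[i]], rt$sites$alts[[i]]))
    expect_equal(rt$gt$a1[i, ], setNames(perm[cs$gt$a1[i, ] + 1L], samples))
    expect_equal(rt$gt$a2[i, ], setNames(perm[cs$gt$a2[i, ] + 1L], samples))
  }
})

test_that("decomposition yields column-wise primitives that rebuild the edit", {
  # MNP: two mismatching columns -> two SNVs
  kids <- decompose_primitives(list(contig = "chr1", pos = 100L, ref = "AC",
                                    alts = list("TG"), qual = 55,
                                    info = list(c(DP = 7))))
  expect_equal(vapply(kids, `[[`, numeric(1), "pos"), c(100, 101))
  expect_equal(vapply(kids, `[[`, character(1), "ref"), c("A", "C"))
  expect_equal(vapply(kids, function(k) k$alts[[1]], character(1)),
               c("T", "G"))
  expect_equal(kids[[1]]$qual, 55)           # fields copied to children
  expect_equal(kids[[2]]$info[[1]], c(DP = 7))
  # SNV passes through; shared columns trim first
  expect_length(decompose_primitives(list(contig = "c", pos = 1L, ref = "A",
                                          alts = list("T"))), 1L)
  kids2 <- decompose_primitives(list(contig = "c", pos = 10L, ref = "ATG",
                                     alts = list("ATC")))
  expect_length(kids2, 1L)
  expect_equal(kids2[[1]]$pos, 12L)
  expect_equal(kids2[[1]]$ref, "G")
  expect_equal(kids2[[1]]$alts[[1]], "C")

  # property: joint application of the children reproduces the parent
  # haplotype (applied right-to-left so positions stay valid)
  ref <- toy_reference(c(chr1 = 400L), seed = 21)
  seq <- ref$contigs[["chr1"]]
  set.seed(22)
  for (i in 1:40) {
    pos <- sample(50:300, 1)
    wr <- sample(1:5, 1); wa <- sample(1:5, 1)
    r <- substr(seq, pos, pos + wr - 1L)
    a <- paste(sample(c("A", "C", "G", "T"), wa, replace = TRUE),
               collapse = "")
    if (a == r) next
    kids <- decompose_primitives(list(contig = "chr1", pos = pos, ref = r,
                                      alts = list(a)))
    kpos <- vapply(kids, `[[`, numeric(1), "pos")
    rebuilt <- seq
    for (k in kids[order(kpos, decreasing = TRUE)])
      rebuilt <- apply_variant(rebuilt, k$pos, k$ref, k$alts[[1]])
    expect_equal(rebuilt, apply_variant(seq, pos, r, a))
    # children are primitives: SNVs or anchored simple INDELs
    for (k in kids) {
      lr <- nchar(k$ref); la <- nchar(k$alts[[1]])
      expect_true((lr == 1 && la == 1) ||
                    (min(lr, la) == 1 &&
                       substr(k$ref, 1, 1) == substr(k$alts[[1]], 1, 1)))
    }
  }
})

test_that("biallelic selection keeps exactly the single-alt sites", {
  cs <- callset("m", character(), consensusvc:::new_sites(
    contig = rep("chr1", 3), pos = c(10L, 20L, 30L),
    ref = c("A", "C", "G"), alts = list("T", c("A", "T"), "C")))
  kept <- select_biallelic(cs)
  expect_equal(n_sites(kept), 2L)
  expect_equal(kept$sites$pos, c(10L, 30L))
  set.seed(9)
  alts <- lapply(1:50, function(i) sample(c("T", "G", "C"), sample(1:3, 1)))
  cs2 <- callset("m", character(), consensusvc:::new_sites(
    contig = rep("chr1", 50), pos = seq(5L, by = 7L, length.out = 50),
    ref = rep("A", 50), alts = alts))
  expect_equal(n_sites(select_biallelic(cs2)) +
                 sum(lengths(alts) > 1L), 50L)
})

test_that("region exclusion removes centromeric, chrY and non-PAR chrX sites", {
  cs <- toy_callset(c("chr1", "chr1", "chrY", "chrX", "chrX"),
                    c(100L, 500L, 500L, 10L, 5000L),
                    rep("A", 5), rep("T", 5),
                    contigs = c("chr1", "chrX", "chrY"))
  excl <- region_set(data.frame(contig = "chr1", start = 450, end = 550),
                     "exclusion")
  par <- region_set(data.frame(contig = "chrX", start = 0, end = 100), "par")
  out <- suppressMessages(exclude_regions(cs, excl, par))
  expect_equal(site_keys(out), c("chr1:100:A:T", "chrX:10:A:T"))
  expect_equal(attr(out, "removed"),
               c(exclusion = 1L, chrY = 1L, chrX_nonPAR = 1L))

  # oracle: per-site brute-force membership on random input
  set.seed(55)
  n <- 1000L
  ctg <- sample(c("chr1", "chrX", "chrY"), n, replace = TRUE)
  pos <- sample(1:10000, n, replace = TRUE)
  ivs <- data.frame(contig = "chr1",
                    start = (s <- sample(0:9000, 30)),
                    end = s + sample(50:400, 30, replace = TRUE))
  rs <- region_set(ivs, "exclusion")
  cs2 <- toy_callset(ctg, pos, rep("A", n), rep("T", n),
                     contigs = c("chr1", "chrX", "chrY"))
  out2 <- suppressMessages(exclude_regions(cs2, rs, par))
  cov <- brute_cover(ivs, 10000L)
  keep <- !(cs2$sites$contig == "chr1" & cov[cs2$sites$pos]) &
    cs2$sites$contig != "chrY" &
    !(cs2$sites$contig == "chrX" & cs2$sites$pos > 100)
  expect_equal(site_keys(out2), site_keys(cs2)[keep])
})

test_that("the normalization chain is idempotent and unique by site key", {
  cfg <- simulation_config(seed = 17, n_sites = 300)
  tb <- generate_truth(cfg)
  prof <- caller_profile("p", 1, 0, "right_shifted")
  cs <- suppressMessages(simulate_caller(tb$truth, prof, tb$reference, 3))
  # inject a duplicated record
  dup <- consensusvc:::subset_callset(cs, c(seq_len(n_sites(cs)), 1L))
  nm <- suppressMessages(normalize_callset(dup, tb$reference))
  expect_false(anyDuplicated(site_keys(nm)) > 0)
  expect_setequal(site_keys(nm), site_keys(tb$truth))
  nm2 <- suppressMessages(normalize_callset(nm, tb$reference))
  expect_identical(site_keys(nm2), site_keys(nm))
  expect_identical(nm2$sites$qual, nm$sites$qual)

  # a contig unknown to the reference is an error
  alien <- toy_callset("chrZ", 5L, "A", "T", contigs = "chrZ")
  expect_error(normalize_callset(alien, tb$reference), "absent from the reference")
})

test_that("deduplication keeps the highest-QUAL record, first on ties", {
  ref <- reference_sequence(c(chr1 = "ACGTACGTAC"))
  cs <- callset("d", character(), consensusvc:::new_sites(
    contig = rep("chr1", 3), pos = c(4L, 4L, 4L), ref = rep("T", 3),
    alts = list("G", "G", "G"), qual = c(10, 50, 50),
    info = list(c(DP = 1), c(DP = 2), c(DP = 3))))
  nm <- normalize_callset(cs, ref)
  expect_equal(n_sites(nm), 1L)
  expect_equal(nm$sites$qual, 50)
  expect_equal(nm$sites$info[[1]], c(DP = 2))  # first of the tied pair
})
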