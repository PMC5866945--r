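test_that("isolation filter applies the 35-bp rule", {
  v1 <- data.frame(chrom = "c1", pos = 100L)
  expect_equal(nrow(filterIsolated(v1)), 1L)
  v2 <- data.frame(chrom = "c1", pos = c(100L, 120L))
  expect_equal(nrow(filterIsolated(v2)), 0L)          # gap 20 <= 35
  v3 <- data.frame(chrom = "c1", pos = c(100L, 136L))
  expect_equal(nrow(filterIsolated(v3)), 2L)          # gap 36 > 35
  v4 <- data.frame(chrom = c("c1", "c2"), pos = c(100L, 110L))
  expect_equal(nrow(filterIsolated(v4)), 2L)          # different chrom
  expect_error(filterIsolated(data.frame(chrom = "c1", pos = c(5L, 2L))),
               "sorted")
})

test_that("isolation filter agrees with the all-pairs oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(10:500, 1)
    v <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                    pos = sample.int(3000, n))
    v <- unique(v[order(v$chrom, v$pos), ])
    rownames(v) <- NULL
    expect_identical(filterIsolated(v), bruteIsolated(v))
  }
})

test_that("SSR detection meets its per-motif thresholds", {
  r <- detectSsr(strrep("A", 10))
  expect_equal(r, data.frame(start = 1L, end = 10L, motif = "A"))
  expect_equal(nrow(detectSsr(strrep("A", 9))), 0L)
  r <- detectSsr(strrep("AT", 6))
  expect_equal(r, data.frame(start = 1L, end = 12L, motif = "AT"))
  # ambiguity characters terminate tracts
  expect_equal(nrow(detectSsr(paste0(strrep("A", 5), "N",
                                     strrep("A", 5)))), 0L)
  # non-primitive motifs are reported once, under the shortest period
  r <- detectSsr(strrep("ACG", 8))
  expect_equal(r$motif, "ACG")
})

test_that("SSR detection agrees with exhaustive enumeration", {
  set.seed(103)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    # splice a few real tracts in so the comparison is not vacuous
    if (i %% 2 == 0)
      s <- paste0(substr(s, 1, 300), strrep("AG", 7),
                  substr(s, 301, 700), strrep("T", 12),
                  substr(s, 701, 1000))
    a <- detectSsr(s)
    b <- bruteSsr(s)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})

test_that("GC fraction counts G and C over the window", {
  expect_equal(computeGcFraction("GGCC"), 1.0)
  expect_equal(computeGcFraction("ATAT"), 0.0)
  expect_error(computeGcFraction(""), "empty")
  set.seed(105)
  for (i in 1:20) {
    w <- sample(c("A", "C", "G", "T", "N"), 71, replace = TRUE)
    expect_equal(computeGcFraction(paste(w, collapse = "")),
                 sum(w %in% c("G", "C")) / 71)
  }
})

test_that("MAF computation and its 0.05 boundary", {
  expect_equal(computeMaf(c(429, 429)), 0.5)
  expect_gte(computeMaf(c(858 - 43, 43)), 0.05)   # 0.0501..., passes
  expect_lt(computeMaf(c(858 - 42, 42)), 0.05)    # 0.0489..., fails
  expect_error(computeMaf(c(0, 0)), "zero")
})

test_that("ambiguity detection covers all IUPAC codes", {
  expect_false(hasAmbiguity("ACGT"))
  expect_true(hasAmbiguity("ACNGT"))
  expect_true(hasAmbiguity("ACRGT"))
})

test_that("the filter cascade charges each violator to its own filter", {
  fx <- designFixture()
  res <- applyDesignFilters(fx$variants, fx$seqs)
  expect_equal(res$report@removed, fx$expect_removed)
  expect_equal(nrow(res$survivors), 3L)
  expect_setequal(res$survivors$pos, fx$clean_pos)
  expect_equal(res$report@input,
               res$report@survivors + sum(res$report@removed))
})

test_that("empty and all-passing panels are handled exactly", {
  fx <- designFixture()
  empty <- fx$variants[0, ]
  r0 <- applyDesignFilters(empty, fx$seqs)
  expect_equal(r0$report@input, 0L)
  expect_equal(sum(r0$report@removed), 0L)

  ok <- fx$variants[fx$variants$pos %in% fx$clean_pos, ]
  rAll <- applyDesignFilters(ok, fx$seqs)
  expect_equal(rAll$report@survivors, nrow(ok))
  expect_equal(sum(rAll$report@removed), 0L)
})

test_that("the surviving set is invariant to filter order", {
  g <- makeReference(55, nChrom = 2, chromLength = 40000, geneCount = 4,
                     ssrCount = 3)
  p <- simulatePanel(g, nAccessions = 30, seed = 56)
  res <- applyDesignFilters(p, g)
  flagCols <- paste0("pass_", c("edge", "isolated", "ssr", "indel",
                                "biallelic", "maf", "gc", "ambiguity",
                                "qual"))
  for (perm in 1:5) {
    set.seed(perm)
    shuffled <- sample(flagCols)
    surv <- res$candidates$id[Reduce(`&`, res$candidates[shuffled])]
    expect_setequal(surv, res$survivors$id)
  }
})

test_that("region annotation follows the CDS/gene/intergenic split", {
  fx <- effectFixture("+")
  expect_equal(annotateRegion("chr1", 5, fx$genes), "intergenic")
  expect_equal(annotateRegion("chr1", 14, fx$genes), "coding")
  expect_equal(annotateRegion("chr1", 24, fx$genes), "intronic")
  expect_equal(annotateRegion("chr1", 45, fx$genes), "intergenic")
  expect_equal(annotateRegion(c("chr1", "chr1"), c(14, 24), fx$genes),
               c("coding", "intronic"))
})

test_that("coding effects follow the genetic code, strand-aware", {
  fx <- effectFixture("+")
  # codon GCT -> GCC (Ala -> Ala)
  expect_equal(classifyCodingEffect("chr1", 16, "T", "C", fx$seqs,
                                    fx$genes), "synonymous coding")
  # codon TGG -> TGA
  expect_equal(classifyCodingEffect("chr1", 34, "G", "A", fx$seqs,
                                    fx$genes), "stop gained")
  # ATG -> ATA
  expect_equal(classifyCodingEffect("chr1", 13, "G", "A", fx$seqs,
                                    fx$genes), "start lost")
  # ATG -> CTG: still a recognised start codon
  expect_equal(classifyCodingEffect("chr1", 11, "A", "C", fx$seqs,
                                    fx$genes), "synonymous start")
  # stop codon TAA -> TAG / TCA
  expect_equal(classifyCodingEffect("chr1", 36, "A", "G", fx$seqs,
                                    fx$genes), "synonymous stop")
  expect_equal(classifyCodingEffect("chr1", 36, "A", "C", fx$seqs,
                                    fx$genes), "stop lost")
  # nonsynonymous: GCT -> GTT (Ala -> Val)
  expect_equal(classifyCodingEffect("chr1", 15, "C", "T", fx$seqs,
                                    fx$genes), "nonsynonymous coding")
  # first intron base G -> A: donor; last intron base: acceptor
  expect_equal(classifyCodingEffect("chr1", 20, "G", "A", fx$seqs,
                                    fx$genes), "splice site donor")
  expect_equal(classifyCodingEffect("chr1", 28, "G", "C", fx$seqs,
                                    fx$genes), "splice site acceptor")
  # deeper intronic position has no effect label
  expect_true(is.na(classifyCodingEffect("chr1", 24, "C", "A", fx$seqs,
                                         fx$genes)))
})

test_that("coding effects are identical on the minus strand", {
  fx <- effectFixture("-")
  L <- 47
  flip <- function(p) L - p + 1
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # same biological events as the plus-strand test, mirrored
  expect_equal(classifyCodingEffect("chr1", flip(16), comp[["T"]],
                                    comp[["C"]], fx$seqs, fx$genes),
               "synonymous coding")
  expect_equal(classifyCodingEffect("chr1", flip(34), comp[["G"]],
                                    comp[["A"]], fx$seqs, fx$genes),
               "stop gained")
  expect_equal(classifyCodingEffect("chr1", flip(13), comp[["G"]],
                                    comp[["A"]], fx$seqs, fx$genes),
               "start lost")
  expect_equal(classifyCodingEffect("chr1", flip(20), comp[["G"]],
                                    comp[["A"]], fx$seqs, fx$genes),
               "splice site donor")
  expect_equal(classifyCodingEffect("chr1", flip(28), comp[["G"]],
                                    comp[["C"]], fx$seqs, fx$genes),
               "splice site acceptor")
})

test_that("frame inconsistency in a transcript is an error", {
  fx <- effectFixture("+")
  bad <- fx$genes
  GenomicRanges::end(bad)[2] <- 36  # CDS length 17, not a codon multiple
  expect_error(classifyCodingEffect("chr1", 16, "T", "C", fx$seqs, bad),
               "frame")
})

test_that("deduplication keeps the best record per site", {
  d <- data.frame(chrom = "c1", pos = c(10L, 10L), qual = c(40, 30),
                  alt = c("G", "T"))
  expect_equal(deduplicateCandidates(d)$qual, 40)
  dTie <- data.frame(chrom = "c1", pos = c(10L, 10L), qual = c(40, 40),
                     alt = c("T", "G"))
  expect_equal(deduplicateCandidates(dTie)$alt, "G")
  dNo <- data.frame(chrom = "c1", pos = c(1L, 2L), qual = c(1, 2),
                    alt = c("A", "C"))
  expect_identical(deduplicateCandidates(dNo), dNo)
  set.seed(107)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    d <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                    pos = sample.int(30, n, TRUE),
                    qual = sample(10:60, n, TRUE),
                    alt = sample(c("A", "C", "G", "T"), n, TRUE))
    got <- deduplicateCandidates(d)
    # oracle: group and pick by (max qual, min alt)
    key <- paste(d$chrom, d$pos)
    want <- do.call(rbind, lapply(split(d, key), function(gd) {
      gd <- gd[order(-gd$qual, gd$alt), ]
      gd[1, ]
    }))
    expect_equal(nrow(got), length(unique(key)))
    gotKey <- paste(got$chrom, got$pos)
    expect_identical(got$qual[order(gotKey)],
                     want$qual[order(paste(want$chrom, want$pos))])
    expect_identical(got$alt[order(gotKey)],
                     want$alt[order(paste(want$chrom, want$pos))])
  }
})

test_that("the scoring hook retains scores at or above threshold", {
  d <- data.frame(chrom = "c1", pos = 1:3, qual = 1, alt = "A")
  expect_identical(nrow(scoreHook(d)), 3L)                    # constant 1
  expect_identical(nrow(scoreHook(d, function(x) rep(0, nrow(x)))), 0L)
  got <- scoreHook(d, function(x) c(0.29, 0.30, 0.31))
  expect_equal(got$pos, 2:3)                                  # inclusive
  expect_error(scoreHook(d, function(x) c(0.5, 1.2, 0.1)), "0,1")
})
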