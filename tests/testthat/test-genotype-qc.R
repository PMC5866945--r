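test_that("sample filtering removes DQC failures before call-rate failures", {
  # 245 lines: 3 below DQC 0.82, then 7 more below 97% call rate
  samp <- data.frame(sample = sprintf("s%03d", 1:245),
                     dqc = c(rep(0.70, 3), rep(0.95, 242)),
                     call_rate = c(rep(0.50, 3), rep(0.96, 7),
                                   rep(0.99, 235)))
  res <- filterSamples(samp)
  expect_equal(length(res$removed_dqc), 3L)
  expect_equal(length(res$removed_call_rate), 7L)
  expect_equal(nrow(res$retained), 235L)

  # boundaries retain: the platform thresholds are strict less-than
  edge <- data.frame(sample = c("a", "b"), dqc = c(0.82, 0.9),
                     call_rate = c(0.99, 0.97))
  resE <- filterSamples(edge)
  expect_equal(nrow(resE$retained), 2L)

  allOk <- data.frame(sample = "a", dqc = 0.99, call_rate = 0.999)
  expect_identical(filterSamples(allOk)$retained, allOk)
})

test_that("FLD is the pooled-SD-standardised nearest homozygote distance", {
  cl <- rbind(clusterRow("AA", 40, 1.2, 1, sx = 0.2),
              clusterRow("AB", 20, 0.0, 1, sx = 0.2),
              clusterRow("BB", 40, -1.1, 1, sx = 0.2))
  expect_equal(computeFld(cl), 5.5)
  # coincident AA and het
  cl0 <- rbind(clusterRow("AA", 40, 0, 1), clusterRow("AB", 20, 0, 1),
               clusterRow("BB", 40, -1, 1))
  expect_equal(computeFld(cl0), 0)
  # scale invariance
  clS <- cl
  clS$mean_x <- clS$mean_x * 3.7
  clS$sd_x <- clS$sd_x * 3.7
  expect_equal(computeFld(clS), computeFld(cl))
  expect_error(computeFld(cl[cl$cluster != "AB", ]), "het")
  clZ <- cl; clZ$sd_x <- 0
  expect_error(computeFld(clZ), "zero pooled SD")
})

test_that("HetSO measures the offset from the homozygote chord", {
  collinear <- rbind(clusterRow("AA", 40, 1, 1), clusterRow("AB", 20, 0, 1),
                     clusterRow("BB", 40, -1, 1))
  expect_equal(computeHetSo(collinear), 0)
  above <- collinear; above$mean_y[above$cluster == "AB"] <- 1.2
  expect_equal(computeHetSo(above), 0.2)
  below <- collinear; below$mean_y[below$cluster == "AB"] <- 0.6
  expect_equal(computeHetSo(below), -0.4)
  # tilted chord: AA (1, 1.2), BB (-1, 0.8); chord at x=0 is 1.0
  tilted <- rbind(clusterRow("AA", 40, 1, 1.2), clusterRow("AB", 20, 0, 1.3),
                  clusterRow("BB", 40, -1, 0.8))
  expect_equal(computeHetSo(tilted), 0.3)
  degen <- collinear; degen$mean_x[degen$cluster == "BB"] <- 1
  expect_error(computeHetSo(degen), "degenerate")
})

test_that("HomRO is the signed worst homozygote contrast offset", {
  both <- rbind(clusterRow("AA", 40, 1.0, 1), clusterRow("BB", 40, -0.8, 1))
  expect_equal(computeHomRo(both), 0.8)
  one <- clusterRow("AA", 40, 0.7, 1)
  expect_equal(computeHomRo(one), 0.7)
  wrong <- clusterRow("AA", 40, -0.2, 1)
  expect_equal(computeHomRo(wrong), -0.2)
  expect_error(computeHomRo(clusterRow("AB", 10, 0, 1)), "homozygote")
})

test_that("classification reproduces the category decision tree", {
  expect_equal(classifySnp(mkMetrics(call_rate = 0.96)),
               "CallRateBelowThreshold")
  expect_equal(classifySnp(mkMetrics(fld = 5.5, het_so = 0, hom_ro = 0.5,
                                     call_rate = 0.99, minor_hom = 10L)),
               "PolyHighResolution")
  expect_equal(classifySnp(mkMetrics(n_clusters = 1L, call_rate = 1,
                                     hom_ro = 0.7, fld = NA, het_so = NA,
                                     hom_fld = NA, has_het = FALSE,
                                     vx_BB = NA, vy_BB = NA)),
               "MonoHighResolution")
  expect_equal(classifySnp(mkMetrics(fld = 3.5)), "Other")
  expect_equal(classifySnp(mkMetrics(n_clusters = 2L, has_het = TRUE,
                                     het_so = NA, hom_fld = NA,
                                     minor_hom = 0L, vx_BB = NA,
                                     vy_BB = NA)),
               "NoMinorHom")
  expect_equal(classifySnp(mkMetrics(n_clusters = 2L, has_het = FALSE,
                                     fld = NA, het_so = NA,
                                     minor_hom = 3L)),
               "HomHomResolution")
  expect_equal(classifySnp(mkMetrics(otv_flag = TRUE, het_so_otv = -0.58,
                                     otv_frac = 0.1)), "OTV")
  expect_equal(classifySnp(mkMetrics(vx_AA = 0.9)), "AAvarianceX")
  expect_equal(classifySnp(mkMetrics(vy_BB = 0.9)), "BBvarianceY")
  expect_error(classifySnp(mkMetrics(fld = NA)), "inconsistent")
})

test_that("classification boundaries sit exactly at the printed cutoffs", {
  # call rate 97%
  expect_equal(classifySnp(mkMetrics(call_rate = 0.97)),
               "PolyHighResolution")
  expect_equal(classifySnp(mkMetrics(call_rate = 0.9699)),
               "CallRateBelowThreshold")
  # FLD 3.6
  expect_equal(classifySnp(mkMetrics(fld = 3.6)), "PolyHighResolution")
  expect_equal(classifySnp(mkMetrics(fld = 3.5999)), "Other")
  # HetSO -0.1
  expect_equal(classifySnp(mkMetrics(het_so = -0.1)), "PolyHighResolution")
  expect_equal(classifySnp(mkMetrics(het_so = -0.1001)), "Other")
  # HomRO 0.3 for polymorphic, 0.6 for monomorphic
  expect_equal(classifySnp(mkMetrics(hom_ro = 0.3)), "PolyHighResolution")
  expect_equal(classifySnp(mkMetrics(hom_ro = 0.2999)), "Other")
  mono <- function(hr) mkMetrics(n_clusters = 1L, hom_ro = hr, fld = NA,
                                 het_so = NA, hom_fld = NA,
                                 has_het = FALSE, vx_BB = NA, vy_BB = NA)
  expect_equal(classifySnp(mono(0.6)), "MonoHighResolution")
  expect_equal(classifySnp(mono(0.5999)), "Other")
  # HetSO-OTV -0.3
  expect_equal(classifySnp(mkMetrics(otv_flag = TRUE, otv_frac = 0.1,
                                     het_so_otv = -0.3001)), "OTV")
  expect_equal(classifySnp(mkMetrics(otv_flag = FALSE, otv_frac = 0.1,
                                     het_so_otv = -0.2999)),
               "PolyHighResolution")
})

test_that("every SNP gets exactly one category from the closed set", {
  set.seed(201)
  for (i in 1:200) {
    m <- mkMetrics(call_rate = runif(1, 0.9, 1),
                   n_clusters = sample(1:3, 1),
                   fld = runif(1, 0, 8), het_so = runif(1, -0.5, 0.3),
                   hom_ro = runif(1, -0.2, 1),
                   hom_fld = runif(1, 0, 12),
                   minor_hom = sample(0:10, 1),
                   vx_AA = runif(1, 0, 1), vy_AA = runif(1, 0, 1),
                   vx_BB = runif(1, 0, 1), vy_BB = runif(1, 0, 1))
    m$has_het <- m$n_clusters == 3L || (m$n_clusters == 2L && runif(1) < 0.5)
    cat1 <- classifySnp(m)
    expect_length(cat1, 1L)
    expect_true(cat1 %in% snpCategories())
  }
})

test_that("improving a single metric never fails a passing SNP", {
  passing <- c("PolyHighResolution", "MonoHighResolution", "NoMinorHom",
               "HomHomResolution")
  set.seed(202)
  for (i in 1:200) {
    m <- mkMetrics(call_rate = runif(1, 0.9, 1),
                   n_clusters = sample(1:3, 1),
                   fld = runif(1, 0, 8), het_so = runif(1, -0.5, 0.3),
                   hom_ro = runif(1, -0.2, 1),
                   hom_fld = runif(1, 0, 12), minor_hom = sample(0:10, 1))
    m$has_het <- m$n_clusters == 3L || (m$n_clusters == 2L && runif(1) < 0.5)
    before <- classifySnp(m)
    if (!before %in% passing) next
    for (metric in c("call_rate", "fld", "het_so", "hom_ro", "hom_fld")) {
      m2 <- m
      if (!is.na(m2[[metric]]))
        m2[[metric]] <- m2[[metric]] + runif(1, 0, 0.5)
      m2$call_rate <- min(m2$call_rate, 1)
      expect_true(classifySnp(m2) %in% passing,
                  info = paste("metric", metric, "demoted", before))
    }
  }
})

test_that("category summaries reproduce printed-percentage arithmetic", {
  counts <- c(PolyHighResolution = 13099, MonoHighResolution = 23120)
  sm <- qcSummaryCounts(counts, total = 50590)
  expect_equal(sm$pct[sm$category == "PolyHighResolution"], 25.89)
  expect_equal(sm$pct[sm$category == "MonoHighResolution"], 45.70)
  expect_equal(attr(sm, "polymorphic_usable"), 13099)
  empty <- qcSummary(character(0))
  expect_true(all(empty$n == 0))
})

test_that("high-separation synthetic SNPs classify as their true type", {
  polyOk <- 0L; polyTot <- 0L; monoOk <- 0L; monoTot <- 0L
  for (s in 1:50) {
    tm <- makeTrueMap(nGroups = 1, markersPerGroup = 20, lengthCm = 100,
                      seed = s)
    calls <- simulateRil(c("P1", "P2"), tm, nRil = 120,
                         residualHetRate = 0.05, seed = 400 + s)[, -(1:2)]
    mono <- matrix("A", nrow = 10, ncol = 120,
                   dimnames = list(sprintf("mono%02d", 1:10),
                                   colnames(calls)))
    allCalls <- rbind(calls, mono)
    sig <- simulateClusterSignals(allCalls, separation = 8,
                                  seed = 800 + s)
    qc <- classifySnps(sig$calls, sig$clusters)
    isMono <- grepl("^mono", qc$snp)
    hasAllThree <- qc$n_clusters == 3
    polyTot <- polyTot + sum(!isMono & hasAllThree)
    polyOk <- polyOk + sum(qc$category[!isMono & hasAllThree] ==
                           "PolyHighResolution")
    monoTot <- monoTot + sum(isMono)
    monoOk <- monoOk + sum(qc$category[isMono] == "MonoHighResolution")
  }
  expect_gte(polyOk / polyTot, 0.95)
  expect_gte(monoOk / monoTot, 0.95)
})

test_that("planted off-target variants are flagged OTV downstream", {
  tm <- makeTrueMap(nGroups = 1, markersPerGroup = 10, lengthCm = 60,
                    seed = 61)
  calls <- simulateRil(c("P1", "P2"), tm, nRil = 150,
                       residualHetRate = 0.05, seed = 62)[, -(1:2)]
  otvId <- rownames(calls)[4]
  sig <- simulateClusterSignals(calls, separation = 8, otvFraction = 0.1,
                                otvSnps = otvId, seed = 63)
  qc <- classifySnps(sig$calls, sig$clusters)
  expect_equal(qc$category[qc$snp == otvId], "OTV")
})
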