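test_that("parent-polymorphic selection keeps contrasting homozygotes", {
  calls <- matrix(c("A", "B", "B", "A",
                    "A", "A", "B", "A",
                    "A", "U", "B", "B",
                    "H", "B", "A", "A"),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(paste0("m", 1:4),
                                  c("P1", "P2", "r1", "r2")))
  kept <- selectParentPolymorphic(calls, "P1", "P2")
  expect_equal(rownames(kept), "m1")
  expect_error(selectParentPolymorphic(calls, "P1", "nope"), "parent")
})

test_that("segregation chi-squared matches its closed form", {
  t1 <- segregationChi2(50, 50)
  expect_equal(t1$chi2, 0)
  expect_equal(t1$p, 1)
  t2 <- segregationChi2(70, 30)
  expect_equal(t2$chi2, 16)
  expect_equal(t2$p, 6.334248e-05, tolerance = 1e-6)
  expect_lt(t2$p, 0.01)   # removed at the 1% level
  t3 <- segregationChi2(60, 40)
  expect_equal(t3$chi2, 4)
  expect_equal(t3$p, 0.04550026, tolerance = 1e-6)
  expect_gte(t3$p, 0.01)  # kept
  expect_error(segregationChi2(0, 0), "zero")
})

test_that("duplicate binning collapses identical call vectors", {
  calls <- matrix(c("A", "B", "A", "B",
                    "A", "B", "A", "B",
                    "B", "A", "B", "A"),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(paste0("m", 1:3), paste0("s", 1:4)))
  res <- binDuplicates(calls)
  expect_equal(rownames(res$calls), c("m1", "m3"))
  expect_equal(res$bins$representative, c("m1", "m1", "m3"))

  noDup <- calls[c(1, 3), ]
  expect_identical(binDuplicates(noDup)$calls, noDup)

  # missing-aware: identical on joint support with enough coverage
  withU <- matrix(c("A", "B", "A", "B",
                    "A", "B", "U", "B"),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("x1", "x2"), paste0("s", 1:4)))
  expect_equal(nrow(binDuplicates(withU)$calls), 1L)
  expect_equal(nrow(binDuplicates(withU, minJointCoverage = 0.9)$calls), 2L)
})

test_that("duplicate binning agrees with brute-force grouping", {
  set.seed(301)
  for (i in 1:20) {
    m <- sample(10:60, 1); n <- sample(10:30, 1)
    calls <- matrix(sample(c("A", "B"), m * n, replace = TRUE,
                           prob = c(0.5, 0.5)),
                    nrow = m, dimnames = list(sprintf("m%02d", 1:m),
                                              sprintf("s%02d", 1:n)))
    # force some duplicate blocks
    calls[2, ] <- calls[1, ]
    if (m > 5) calls[5, ] <- calls[4, ]
    got <- binDuplicates(calls)$bins
    want <- bruteBins(calls)
    expect_identical(got, want)
  }
})

test_that("pairwise RIL linkage matches its closed forms", {
  mk <- function(rec, n) {
    a <- rep("A", n)
    b <- a; if (rec > 0) b[seq_len(rec)] <- "B"
    list(a = a, b = b)
  }
  z <- mk(0, 100)
  r0 <- estimateRfRil(z$a, z$b)
  expect_equal(r0$r, 0)
  expect_equal(r0$lod, 100 * log10(2), tolerance = 1e-9)
  expect_equal(round(r0$lod, 2), 30.10)

  x <- mk(20, 100)
  r20 <- estimateRfRil(x$a, x$b)
  expect_equal(r20$R, 0.2)
  expect_equal(r20$r, 0.125)   # R / (2 (1 - R))
  expect_equal(r20$lod, 8.370799, tolerance = 1e-6)

  h <- mk(50, 100)
  r50 <- estimateRfRil(h$a, h$b)
  expect_equal(r50$R, 0.5)
  expect_equal(r50$r, 0.4999)
  expect_equal(r50$lod, 0)

  # H and U are excluded from the informative set
  a <- c("A", "A", "H", "A", "U"); b <- c("A", "B", "A", "A", "B")
  expect_equal(estimateRfRil(a, b)$n, 3)
  expect_error(estimateRfRil(rep("H", 4), rep("A", 4)), "informative")

  # the vectorised all-pairs path agrees with the scalar estimator
  set.seed(302)
  calls <- matrix(sample(c("A", "B", "H", "U"), 5 * 80, replace = TRUE,
                         prob = c(0.45, 0.45, 0.05, 0.05)),
                  nrow = 5, dimnames = list(paste0("m", 1:5), NULL))
  lk <- pairwiseLinkage(calls)
  for (i in 1:4) for (j in (i + 1):5) {
    sc <- estimateRfRil(calls[i, ], calls[j, ])
    expect_equal(lk$r[i, j], sc$r, tolerance = 1e-12)
    expect_equal(lk$lod[i, j], sc$lod, tolerance = 1e-9)
    expect_equal(lk$n[i, j], sc$n)
  }
})

test_that("grouping applies the rf and LOD cutoffs transitively", {
  mkLink <- function(r, lod) list(r = r, lod = lod)
  ids <- c("a", "b", "c")
  base <- matrix(0.5, 3, 3, dimnames = list(ids, ids))
  lodM <- matrix(0, 3, 3, dimnames = list(ids, ids))
  r1 <- base; r1["a", "b"] <- r1["b", "a"] <- 0.1
  l1 <- lodM; l1["a", "b"] <- l1["b", "a"] <- 20
  g <- groupMarkers(mkLink(r1, l1))
  expect_true(any(vapply(g, function(x) setequal(x, c("a", "b")),
                         logical(1))))

  r2 <- base; r2["a", "b"] <- r2["b", "a"] <- 0.4
  g2 <- groupMarkers(mkLink(r2, l1))
  expect_equal(lengths(g2), c(1L, 1L, 1L))   # r too large despite LOD 20

  # chain a-b, b-c linked, a-c not: one group of three
  r3 <- base; r3["a", "b"] <- r3["b", "a"] <- 0.1
  r3["b", "c"] <- r3["c", "b"] <- 0.1
  l3 <- lodM; l3["a", "b"] <- l3["b", "a"] <- 20
  l3["b", "c"] <- l3["c", "b"] <- 20
  g3 <- groupMarkers(mkLink(r3, l3))
  expect_equal(lengths(g3), 3L)

  # grouping is invariant to marker input order
  perm <- c(3, 1, 2)
  g3p <- groupMarkers(mkLink(r3[perm, perm], l3[perm, perm]))
  expect_setequal(g3p[[1]], g3[[1]])
})

test_that("small groups are ordered optimally, larger ones near-optimally", {
  set.seed(303)
  for (i in 1:30) {
    k <- sample(2:3, 1)
    ids <- paste0("m", 1:k)
    r <- matrix(runif(k * k, 0.01, 0.45), k, k,
                dimnames = list(ids, ids))
    r <- (r + t(r)) / 2; diag(r) <- 0
    ord <- orderMarkers(ids, r)
    expect_equal(sarfOf(ord, r), bruteMinSarf(ids, r), tolerance = 1e-12)
  }
  # idempotence on a larger group
  k <- 8; ids <- paste0("m", 1:k)
  pos <- sort(runif(k, 0, 50))
  r <- outer(pos, pos, function(a, b) kosambiInv(abs(a - b)))
  dimnames(r) <- list(ids, ids)
  ord1 <- orderMarkers(ids, r)
  expect_identical(orderMarkers(ord1, r), ord1)
  expect_equal(sarfOf(ord1, r), sarfOf(ids, r), tolerance = 1e-12)
})

test_that("a simulated 10-marker group is reordered correctly", {
  hits <- 0L
  for (s in 1:50) {
    tm <- makeTrueMap(nGroups = 1, markersPerGroup = 10, lengthCm = 60,
                      seed = s)
    calls <- simulateRil(c("P1", "P2"), tm, nRil = 500,
                         seed = 500 + s)[, -(1:2)]
    shuffle <- sample(rownames(calls))
    lk <- pairwiseLinkage(calls[shuffle, ])
    ord <- orderMarkers(shuffle, lk$r)
    truth <- tm$marker
    if (identical(ord, truth) || identical(ord, rev(truth)))
      hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("Kosambi distances match the closed form and its limits", {
  expect_equal(kosambiCm(0), 0)
  expect_equal(kosambiCm(0.25), 25 * log(3))
  expect_equal(round(kosambiCm(0.25), 2), 27.47)
  expect_equal(round(kosambiCm(0.1), 2), 10.14)
  expect_error(kosambiCm(0.5), "0.5")
  grid <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(kosambiCm(grid)) > 0))
  expect_lt(abs(kosambiCm(1e-4) / (100 * 1e-4) - 1), 0.01)
  # inverse really inverts
  expect_equal(kosambiInv(kosambiCm(0.3)), 0.3, tolerance = 1e-12)
})

test_that("map summaries reproduce published-table arithmetic", {
  t2 <- data.frame(
    group = sprintf("CaLG%02d", 1:8),
    n_markers = c(2610L, 1088L, 576L, 5179L, 212L, 1709L, 1837L, 468L),
    length_cm = c(104.02, 97.67, 164.90, 226.43, 94.15, 193.99, 90.27,
                  62.24))
  s2 <- mapSummary(t2)
  expect_equal(s2$totals$n_markers, 13679L)
  expect_equal(s2$totals$length_cm, 1033.67)
  expect_equal(s2$totals$avg_markers_per_group, 1709.88)
  expect_equal(s2$totals$avg_length_cm, 129.21)

  t3 <- data.frame(
    group = sprintf("CaLG%02d", 1:8),
    n_markers = c(2001L, 154L, 1063L, 1516L, 440L, 557L, 1727L, 311L),
    length_cm = c(183.98, 83.16, 144.19, 76.79, 143.76, 141.43, 200.30,
                  102.74))
  s3 <- mapSummary(t3)
  expect_equal(s3$groups$density[s3$groups$group == "CaLG04"], 19.74)
  expect_equal(s3$totals$density, 7.22)
  expect_equal(s3$totals$n_markers, 7769L)
  expect_equal(s3$totals$avg_markers_per_group, 971.13)

  degen <- data.frame(group = "g", n_markers = 1L, length_cm = 0)
  expect_true(is.na(mapSummary(degen)$groups$density))
})

test_that("map construction is invariant to parent relabelling", {
  tm <- makeTrueMap(nGroups = 2, markersPerGroup = 12, lengthCm = 70,
                    seed = 71)
  calls <- simulateRil(c("P1", "P2"), tm, nRil = 200, seed = 72)[, -(1:2)]
  anchor <- setNames(seq_len(nrow(calls)), rownames(calls))
  m1 <- buildGeneticMap(calls, anchor = anchor)
  swapped <- calls
  swapped[calls == "A"] <- "B"
  swapped[calls == "B"] <- "A"
  m2 <- buildGeneticMap(swapped, anchor = anchor)
  expect_equal(mapTable(m1$map)$pos_cm, mapTable(m2$map)$pos_cm)
  expect_equal(mapTable(m1$map)$marker, mapTable(m2$map)$marker)
})
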