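#' Specify a true genetic map for simulation
#'
#' Builds the ground-truth map used by \code{\link{simulateRil}}: marker
#' positions per linkage group (strictly increasing cM, starting at 0) with
#' adjacent meiotic recombination fractions given by the Kosambi inverse of
#' the interval lengths.
#'
#' @param nGroups number of linkage groups
#' @param markersPerGroup markers per group (scalar or vector)
#' @param lengthCm group length in cM (scalar or vector)
#' @param seed integer RNG seed; marker spacing is uniform-random within
#'   the group length
#' @return data.frame with columns group, marker, pos_cm
#' @export
makeTrueMap <- function(nGroups = 8, markersPerGroup = 25, lengthCm = 100,
                        seed = 1) {
  set.seed(as.integer(seed))
  markersPerGroup <- rep(markersPerGroup, length.out = nGroups)
  lengthCm <- rep(lengthCm, length.out = nGroups)
  stopIfNot(all(markersPerGroup >= 2), "need at least two markers per group")
  rows <- lapply(seq_len(nGroups), function(g) {
    m <- markersPerGroup[g]
    # near-even spacing with +/-30% jitter: keeps every adjacent interval
    # well inside the linkage range so the true partition is recoverable
    spacing <- lengthCm[g] / (m - 1L)
    pos <- (seq_len(m) - 1L) * spacing +
      c(0, runif(m - 2L, -0.3, 0.3) * spacing, 0)
    pos <- sort(pos)
    while (any(diff(pos) < 0.05)) {
      i <- which(diff(pos) < 0.05)[1]
      pos[i + 1L] <- pos[i] + 0.05
      pos <- cummax(pos)
    }
    data.frame(group = sprintf("LG%02d", g),
               marker = sprintf("LG%02d_M%03d", g, seq_len(m)),
               pos_cm = pos)
  })
  do.call(rbind, rows)
}

#' Adjacent meiotic recombination fractions of a true map
#'
#' @param trueMap as from \code{\link{makeTrueMap}}
#' @return data.frame group, left, right, r (Kosambi inverse of interval)
#' @export
trueMapRf <- function(trueMap) {
  out <- lapply(split(trueMap, trueMap$group), function(tb) {
    if (nrow(tb) < 2) return(NULL)
    data.frame(group = tb$group[-1],
               left = tb$marker[-nrow(tb)], right = tb$marker[-1],
               r = kosambiInv(diff(tb$pos_cm)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a selfed-RIL genotype matrix from two founders
#'
#' Each RIL is fully homozygous (F-infinity selfing) apart from an optional
#' residual heterozygosity; each marker's allele comes from founder 1 (A)
#' or founder 2 (B). Along a group, adjacent markers recombine
#' independently at the RIL-observed rate \code{R = 2r/(1+2r)} for the
#' map's meiotic \code{r} (no interference), which matches the pairwise
#' rf estimator's model exactly. The two founder columns are included
#' first, coded all-A and all-B.
#'
#' @param founders two founder labels, default c("P1","P2")
#' @param trueMap as from \code{\link{makeTrueMap}}
#' @param nRil number of RILs (>= 10)
#' @param residualHetRate per-call probability of a residual H call
#' @param missingRate per-call probability of a missing (U) call
#' @param seed integer RNG seed
#' @return character matrix (markers x samples) over \{A,B,H,U\}; founder
#'   columns first
#' @export
simulateRil <- function(founders = c("P1", "P2"), trueMap, nRil = 200,
                        residualHetRate = 0, missingRate = 0, seed = 1) {
  stopIfNot(nRil >= 10, "nRil must be >= 10")
  stopIfNot(length(founders) == 2, "exactly two founders")
  set.seed(as.integer(seed))
  groups <- split(trueMap, trueMap$group)
  mats <- lapply(groups, function(tb) {
    m <- nrow(tb)
    R <- meioticToRil(kosambiInv(diff(tb$pos_cm)))
    g <- matrix(0L, nrow = m, ncol = nRil)
    g[1, ] <- rbinom(nRil, 1, 0.5)
    if (m > 1) for (i in 2:m) {
      flip <- rbinom(nRil, 1, R[i - 1L])
      g[i, ] <- (g[i - 1L, ] + flip) %% 2L
    }
    rownames(g) <- tb$marker
    g
  })
  g <- do.call(rbind, mats)
  calls <- matrix(ifelse(g == 0L, "A", "B"), nrow = nrow(g),
                  dimnames = list(rownames(g), NULL))
  if (residualHetRate > 0) {
    het <- matrix(runif(length(calls)) < residualHetRate, nrow = nrow(calls))
    calls[het] <- "H"
  }
  if (missingRate > 0) {
    mis <- matrix(runif(length(calls)) < missingRate, nrow = nrow(calls))
    calls[mis] <- "U"
  }
  out <- cbind(matrix(rep(c("A", "B"), each = nrow(calls)),
                      nrow = nrow(calls)), calls)
  colnames(out) <- c(founders, sprintf("RIL%04d", seq_len(nRil)))
  rownames(out) <- rownames(calls)
  out[match(trueMap$marker, rownames(out)), , drop = FALSE]
}

#' Simulate multi-environment phenotypes with planted additive QTLs
#'
#' Phenotype model per environment: y = sum_k a_k x_k + shift_e +
#' N(0, sigma^2), with x the expected +/-1 QTL genotype interpolated from
#' the flanking markers (no-double-crossover convention, the same used by
#' the interval scanner). QTL positions must lie on the simulated map.
#'
#' @param genotypes marker matrix from \code{\link{simulateRil}} (founder
#'   columns are ignored)
#' @param trueMap the map the genotypes were simulated from
#' @param qtl data.frame with columns trait, group, pos_cm, effect
#' @param residualSd residual standard deviation sigma
#' @param environments data.frame with columns location, year, shift
#' @param founders founder labels to drop from the genotype matrix
#' @param seed integer RNG seed
#' @return data.frame: sample, trait, location, year, environment, value
#' @export
simulatePhenotypes <- function(genotypes, trueMap, qtl, residualSd = 1,
                               environments = data.frame(
                                 location = "L1", year = 2005L, shift = 0),
                               founders = c("P1", "P2"), seed = 1) {
  set.seed(as.integer(seed))
  rils <- genotypes[, !colnames(genotypes) %in% founders, drop = FALSE]
  G <- codeGenotypes(rils)
  samples <- colnames(rils)
  n <- length(samples)
  rows <- list()
  for (tr in unique(qtl$trait)) {
    qk <- qtl[qtl$trait == tr, , drop = FALSE]
    gen <- rep(0, n)
    for (i in seq_len(nrow(qk))) {
      x <- expectedQtlGenotype(G, trueMap, qk$group[i], qk$pos_cm[i])
      gen <- gen + qk$effect[i] * x
    }
    for (e in seq_len(nrow(environments))) {
      y <- gen + environments$shift[e] + rnorm(n, 0, residualSd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples, trait = tr,
        location = environments$location[e],
        year = environments$year[e],
        environment = paste(environments$location[e],
                            environments$year[e], sep = "_"),
        value = y)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected +/-1 genotype at an arbitrary map position
#'
#' Linear interpolation between the flanking markers with weights
#' proportional to the RIL-observed recombinant fractions of the two
#' sub-intervals (no double crossover); reduces to the marker genotype at
#' marker positions. QTL positions must lie within the group's map.
#'
#' @param G coded genotype matrix (markers x samples, +/-1 with H = 0,
#'   missing imputed), as from \code{\link{codeGenotypes}}
#' @param map data.frame with group, marker, pos_cm
#' @param group,posCm scan position
#' @return numeric vector over samples
#' @export
expectedQtlGenotype <- function(G, map, group, posCm) {
  tb <- map[map$group == group, , drop = FALSE]
  stopIfNot(nrow(tb) >= 1, paste("unknown group", group))
  stopIfNot(posCm >= min(tb$pos_cm) - 1e-9 &&
            posCm <= max(tb$pos_cm) + 1e-9,
            "position outside the group's map")
  li <- max(which(tb$pos_cm <= posCm + 1e-9))
  ri <- min(which(tb$pos_cm >= posCm - 1e-9))
  gl <- G[tb$marker[li], ]
  if (li == ri) return(gl)
  gr <- G[tb$marker[ri], ]
  Rl <- meioticToRil(kosambiInv(posCm - tb$pos_cm[li]))
  Rr <- meioticToRil(kosambiInv(tb$pos_cm[ri] - posCm))
  w <- if (Rl + Rr > 0) Rl / (Rl + Rr) else 0.5
  (1 - w) * gl + w * gr
}

#' Simulate Axiom-style cluster signals and per-sample DQC
#'
#' For every SNP row of the call matrix, per-sample (contrast, size)
#' signals are drawn around per-genotype cluster centres (contrast +1 / 0 /
#' -1 for AA / AB / BB, size 1) with within-cluster standard deviation
#' \code{1/separation}, so \code{separation} is the cluster separation in
#' SD units. The heterozygote size can be offset vertically; SNPs listed in
#' \code{otvSnps} divert \code{otvFraction} of samples into a low-size
#' off-target cluster. SNPs in \code{lowCrSnps} have calls blanked to
#' missing at \code{lowCrRate}. Per-sample DQC values come from a mixture
#' with a \code{dqcLowFraction} tail below 0.82.
#'
#' @param genotypes call matrix over \{A,H,B,U\} (markers x samples)
#' @param separation cluster separation |mu_AA - mu_AB| / sigma (> 0)
#' @param sizeOffsetHet vertical offset of the AB cluster (size axis)
#' @param otvFraction fraction of samples diverted to the OTV cluster
#' @param otvSnps marker ids receiving an OTV cluster
#' @param lowCrSnps marker ids whose calls are degraded to missing
#' @param lowCrRate per-call missing probability for \code{lowCrSnps}
#' @param dqcLowFraction fraction of samples with DQC below 0.82
#' @param seed integer RNG seed
#' @return list: \code{clusters} (snp, cluster, n, mean_x, sd_x, mean_y,
#'   sd_y), \code{samples} (sample, dqc), \code{calls} (the possibly
#'   degraded call matrix)
#' @export
simulateClusterSignals <- function(genotypes, separation = 8,
                                   sizeOffsetHet = 0, otvFraction = 0,
                                   otvSnps = NULL, lowCrSnps = NULL,
                                   lowCrRate = 0.05,
                                   dqcLowFraction = 0.02, seed = 1) {
  stopIfNot(separation > 0, "separation must be > 0")
  stopIfNot(otvFraction >= 0 && otvFraction < 1,
            "otvFraction must lie in [0,1)")
  set.seed(as.integer(seed))
  sdX <- 1 / separation
  sdY <- 0.05
  centreX <- c(A = 1, H = 0, B = -1)
  samples <- colnames(genotypes)
  nS <- ncol(genotypes)

  if (length(lowCrSnps)) {
    for (id in intersect(lowCrSnps, rownames(genotypes))) {
      blank <- runif(nS) < lowCrRate
      genotypes[id, blank] <- "U"
    }
  }

  rows <- list()
  for (id in rownames(genotypes)) {
    g <- genotypes[id, ]
    called <- which(g != "U")
    assign <- g[called]
    isOtv <- rep(FALSE, length(called))
    if (id %in% otvSnps && otvFraction > 0) {
      isOtv <- runif(length(called)) < otvFraction
    }
    x <- centreX[assign] + rnorm(length(called), 0, sdX)
    y <- 1 + rnorm(length(called), 0, sdY)
    y[assign == "H"] <- y[assign == "H"] + sizeOffsetHet
    x[isOtv] <- rnorm(sum(isOtv), 0, sdX)
    y[isOtv] <- 0.4 + rnorm(sum(isOtv), 0, sdY)
    lab <- c(A = "AA", H = "AB", B = "BB")[assign]
    lab[isOtv] <- "OTV"
    for (cl in unique(lab)) {
      i <- lab == cl
      rows[[length(rows) + 1L]] <- data.frame(
        snp = id, cluster = cl, n = sum(i),
        mean_x = mean(x[i]), sd_x = if (sum(i) > 1) sd(x[i]) else 0,
        mean_y = mean(y[i]), sd_y = if (sum(i) > 1) sd(y[i]) else 0)
    }
  }
  clusters <- do.call(rbind, rows)
  rownames(clusters) <- NULL

  low <- runif(nS) < dqcLowFraction
  dqc <- ifelse(low, runif(nS, 0.50, 0.8199), runif(nS, 0.95, 0.999))
  list(clusters = clusters,
       samples = data.frame(sample = samples, dqc = dqc),
       calls = genotypes)
}
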