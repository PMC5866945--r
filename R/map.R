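#' Keep markers with contrasting homozygous parental calls
#'
#' @param calls call matrix over \{A,B,H,U\} (markers x samples) whose
#'   columns include the two parents
#' @param parent1,parent2 parent column names
#' @return the subset of rows where both parents are called, homozygous
#'   and different
#' @export
selectParentPolymorphic <- function(calls, parent1, parent2) {
  stopIfNot(all(c(parent1, parent2) %in% colnames(calls)),
            "parent columns not found")
  p1 <- calls[, parent1]; p2 <- calls[, parent2]
  keep <- p1 %in% c("A", "B") & p2 %in% c("A", "B") & p1 != p2
  calls[keep, , drop = FALSE]
}

#' Chi-squared test of 1:1 segregation
#'
#' chi2 = (nA - nB)^2 / (nA + nB) with 1 df. Markers deviating at
#' p < alpha are removed by \code{\link{segregationFilter}}.
#'
#' @param nA,nB homozygote class counts (vectors allowed)
#' @return data.frame with columns chi2, p
#' @export
segregationChi2 <- function(nA, nB) {
  tot <- nA + nB
  stopIfNot(all(tot > 0), "zero informative calls")
  chi2 <- (nA - nB)^2 / tot
  data.frame(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Remove markers deviating from 1:1 segregation
#'
#' @param calls call matrix (markers x samples), parent columns excluded
#' @param alpha removal level (default 0.01; removal iff p < alpha)
#' @return list: calls (retained rows), test (per-marker chi2/p/kept)
#' @export
segregationFilter <- function(calls, alpha = 0.01) {
  nA <- rowSums(calls == "A")
  nB <- rowSums(calls == "B")
  tst <- segregationChi2(nA, nB)
  tst$marker <- rownames(calls)
  tst$kept <- tst$p >= alpha
  list(calls = calls[tst$kept, , drop = FALSE], test = tst)
}

#' Bin duplicate markers
#'
#' Markers whose call vectors are identical on jointly non-missing entries
#' and share at least \code{minJointCoverage} joint coverage collapse into
#' one bin; the first marker of each bin (input order, i.e. genome order)
#' is the representative. Each incoming marker joins the first existing
#' bin whose representative it matches.
#'
#' @param calls call matrix over \{A,B,H,U\} (markers x samples)
#' @param minJointCoverage minimum fraction of jointly non-missing calls
#' @return list: calls (representative rows), bins (data.frame marker,
#'   representative)
#' @export
binDuplicates <- function(calls, minJointCoverage = 0.5) {
  m <- nrow(calls)
  if (!m) return(list(calls = calls,
                      bins = data.frame(marker = character(0),
                                        representative = character(0))))
  X <- matrix(match(calls, c("A", "H", "B")), nrow = m)  # U -> NA
  reps <- integer(0)
  assign <- integer(m)
  nCol <- ncol(calls)
  for (i in seq_len(m)) {
    hit <- 0L
    for (r in reps) {
      both <- !is.na(X[i, ]) & !is.na(X[r, ])
      if (sum(both) < minJointCoverage * nCol) next
      if (all(X[i, both] == X[r, both])) { hit <- r; break }
    }
    if (hit == 0L) { reps <- c(reps, i); assign[i] <- i }
    else assign[i] <- hit
  }
  bins <- data.frame(marker = rownames(calls),
                     representative = rownames(calls)[assign])
  list(calls = calls[reps, , drop = FALSE], bins = bins)
}

#' Pairwise recombination fraction and LOD for two RIL markers
#'
#' Jointly informative RILs are those called homozygous (A or B) at both
#' markers; heterozygous and missing calls are excluded. The observed
#' recombinant fraction R is corrected to the meiotic r = R / (2(1 - R))
#' (selfed-RIL expectation, capped at 0.4999); LOD = n (R log10 R +
#' (1-R) log10(1-R) + log10 2) with 0 log 0 = 0 and R capped at 0.5.
#'
#' @param callsI,callsJ call vectors over \{A,B,H,U\}
#' @return data.frame: n, R, r, lod
#' @export
estimateRfRil <- function(callsI, callsJ) {
  inf <- callsI %in% c("A", "B") & callsJ %in% c("A", "B")
  n <- sum(inf)
  stopIfNot(n > 0, "no jointly informative RILs")
  rec <- sum(callsI[inf] != callsJ[inf])
  R <- rec / n
  Rc <- min(R, 0.5)
  xlx <- function(p) ifelse(p > 0, p * log10(p), 0)
  lod <- n * (xlx(Rc) + xlx(1 - Rc) + log10(2))
  data.frame(n = n, R = R, r = rilToMeiotic(Rc), lod = max(lod, 0))
}

#' All-pairs RIL linkage estimates, vectorised
#'
#' @param calls call matrix over \{A,B,H,U\} (markers x samples)
#' @return list of matrices: n, R, r, lod (markers x markers)
#' @export
pairwiseLinkage <- function(calls) {
  X <- matrix(0, nrow = nrow(calls), ncol = ncol(calls),
              dimnames = dimnames(calls))
  X[calls == "A"] <- 1
  X[calls == "B"] <- -1
  I <- abs(X)
  nInf <- I %*% t(I)
  S <- X %*% t(X)                # matches - mismatches over informative
  R <- (nInf - S) / (2 * pmax(nInf, 1))
  Rc <- pmin(R, 0.5)
  xlx <- function(p) ifelse(p > 0, p * log10(p), 0)
  lod <- nInf * (xlx(Rc) + xlx(1 - Rc) + log10(2))
  lod[nInf == 0] <- 0
  lod <- pmax(lod, 0)
  r <- pmin(Rc / (2 * (1 - Rc)), 0.4999)
  diag(R) <- 0; diag(r) <- 0; diag(lod) <- 0
  list(n = nInf, R = R, r = r, lod = lod)
}

#' Group markers by single-linkage transitive closure
#'
#' Two markers link when r <= rfMax and LOD >= lodMin; groups are the
#' connected components, returned largest first (ties by first marker).
#'
#' @param linkage list from \code{\link{pairwiseLinkage}}
#' @param rfMax maximum corrected recombination fraction (default 0.35)
#' @param lodMin minimum LOD (default 6)
#' @return list of character vectors of marker ids
#' @export
groupMarkers <- function(linkage, rfMax = 0.35, lodMin = 6) {
  adj <- linkage$r <= rfMax & linkage$lod >= lodMin
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ids <- rownames(linkage$r)
  groups <- split(ids, comp)
  first <- vapply(groups, function(x) min(match(x, ids)), numeric(1))
  sizes <- lengths(groups)
  groups <- groups[order(-sizes, first)]
  unname(lapply(groups, unname))
}

#' Order the markers of one linkage group
#'
#' Minimises the sum of adjacent recombination fractions (SARF). Groups of
#' three or fewer markers are solved exhaustively; larger groups are
#' seeded by greedy nearest-neighbour seriation from the best end and
#' polished by ripple (exhaustive permutation of every sliding window of
#' four, repeated to convergence). The orientation is canonicalised so the
#' marker with the smallest anchor value (genome coordinate; input order
#' by default) sits nearest position zero.
#'
#' @param markers character vector of marker ids in the group
#' @param rMat full pairwise r matrix (as from
#'   \code{\link{pairwiseLinkage}})
#' @param anchor optional named numeric of genome coordinates used to
#'   orient the group
#' @return ordered character vector of marker ids
#' @export
orderMarkers <- function(markers, rMat, anchor = NULL) {
  k <- length(markers)
  if (k <= 1) return(markers)
  r <- rMat[markers, markers, drop = FALSE]
  sarf <- function(ordIdx) sum(r[cbind(ordIdx[-k], ordIdx[-1])])
  if (k <= 3) {
    perms <- .permutations(k)
    scores <- apply(perms, 1, sarf)
    best <- perms[which.min(scores), ]
  } else {
    # greedy nearest-neighbour path from each possible start, keep best
    bestScore <- Inf; best <- seq_len(k)
    for (s in seq_len(k)) {
      path <- s; left <- setdiff(seq_len(k), s)
      while (length(left)) {
        nxt <- left[which.min(r[path[length(path)], left])]
        path <- c(path, nxt); left <- setdiff(left, nxt)
      }
      sc <- sarf(path)
      if (sc < bestScore) { bestScore <- sc; best <- path }
    }
    best <- .ripple(best, r, window = 4L)
  }
  ord <- markers[best]
  anchorVal <- if (is.null(anchor)) setNames(seq_len(k), markers)[markers]
               else anchor[markers]
  if (anchorVal[ord[1]] > anchorVal[ord[k]] ||
      (anchorVal[ord[1]] == anchorVal[ord[k]] && ord[1] > ord[k]))
    ord <- rev(ord)
  ord
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- .permutations(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}

.ripple <- function(ordIdx, r, window = 4L) {
  k <- length(ordIdx)
  sarf <- function(o) sum(r[cbind(o[-k], o[-1])])
  perms <- .permutations(min(window, k))
  improved <- TRUE
  cur <- sarf(ordIdx)
  while (improved) {
    improved <- FALSE
    for (s in seq_len(max(1L, k - window + 1L))) {
      idx <- s:min(s + window - 1L, k)
      for (p in seq_len(nrow(perms))) {
        cand <- ordIdx
        cand[idx] <- ordIdx[idx][perms[p, seq_along(idx)]]
        sc <- sarf(cand)
        if (sc < cur - 1e-12) {
          ordIdx <- cand; cur <- sc; improved <- TRUE
        }
      }
    }
  }
  ordIdx
}

#' Kosambi map distance
#'
#' d = 25 ln((1 + 2r) / (1 - 2r)) cM; strictly increasing on [0, 0.5) and
#' approximately 100 r cM for small r.
#'
#' @param r meiotic recombination fraction in [0, 0.5)
#' @return distance in cM
#' @export
kosambiCm <- function(r) {
  stopIfNot(all(r >= 0 & r < 0.5), "r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi function
#'
#' @param d map distance in cM
#' @return meiotic recombination fraction
#' @export
kosambiInv <- function(d) {
  stopIfNot(all(d >= 0), "distance must be non-negative")
  0.5 * tanh(d / 50)
}

#' Build a genetic map from RIL genotype calls
#'
#' Full workflow: optional parental-polymorphism selection, chi-squared
#' 1:1 segregation filter (p < 0.01 removed), duplicate binning, pairwise
#' rf/LOD estimation with selfed-RIL correction, single-linkage grouping
#' (r <= 0.35, LOD >= 6), per-group ordering with ripple, and cumulative
#' Kosambi positions from adjacent-pair r. Groups are renamed LG01, LG02,
#' ... largest first.
#'
#' @param calls call matrix over \{A,B,H,U\} (markers x samples)
#' @param parents optional two parent column names for polymorphism
#'   selection (parents are excluded from estimation either way)
#' @param alpha segregation-removal level (default 0.01)
#' @param rfMax,lodMin grouping thresholds (defaults 0.35, 6)
#' @param minJointCoverage duplicate-binning coverage floor
#' @param anchor optional named genome coordinates for orientation
#' @param minGroupSize groups smaller than this are dropped from the map
#' @return list: map (a \code{\link{GeneticMap}}), bins, segregation (test
#'   table), dropped (markers in undersized groups)
#' @export
buildGeneticMap <- function(calls, parents = NULL, alpha = 0.01,
                            rfMax = 0.35, lodMin = 6,
                            minJointCoverage = 0.5, anchor = NULL,
                            minGroupSize = 2L) {
  if (!is.null(parents)) {
    calls <- selectParentPolymorphic(calls, parents[1], parents[2])
    calls <- calls[, !colnames(calls) %in% parents, drop = FALSE]
  }
  seg <- segregationFilter(calls, alpha)
  binned <- binDuplicates(seg$calls, minJointCoverage)
  lk <- pairwiseLinkage(binned$calls)
  groups <- groupMarkers(lk, rfMax, lodMin)
  keep <- lengths(groups) >= minGroupSize
  dropped <- unlist(groups[!keep])
  groups <- groups[keep]
  rows <- list()
  for (g in seq_along(groups)) {
    ord <- orderMarkers(groups[[g]], lk$r, anchor)
    adjR <- if (length(ord) > 1)
      lk$r[cbind(ord[-length(ord)], ord[-1])] else numeric(0)
    pos <- c(0, cumsum(kosambiCm(adjR)))
    rows[[g]] <- data.frame(group = sprintf("LG%02d", g),
                            marker = ord, pos_cm = pos)
  }
  tb <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), marker = character(0),
               pos_cm = numeric(0))
  rownames(tb) <- NULL
  list(map = new("GeneticMap", table = tb), bins = binned$bins,
       segregation = seg$test, dropped = dropped)
}

#' Per-group and total map statistics
#'
#' Marker counts, lengths, densities (markers/cM, half-up to 2 decimals),
#' group totals and per-group averages, in the shape of a published map
#' summary table. A zero-length group has undefined density (NA).
#'
#' @param x a \code{\link{GeneticMap}}, or a data.frame with columns
#'   group, n_markers, length_cm
#' @return list: groups (per-group data.frame), totals (n_markers,
#'   length_cm, avg_markers_per_group, avg_length_cm, density)
#' @export
mapSummary <- function(x) {
  if (methods::is(x, "GeneticMap")) {
    tb <- mapTable(x)
    sp <- split(tb$pos_cm, tb$group)
    df <- data.frame(group = names(sp),
                     n_markers = as.integer(lengths(sp)),
                     length_cm = vapply(sp, max, numeric(1)))
    rownames(df) <- NULL
    return(mapSummary(df))
  }
  df <- x
  stopIfNot(all(c("group", "n_markers", "length_cm") %in% names(df)),
            "need columns group, n_markers, length_cm")
  df$density <- ifelse(df$length_cm > 0,
                       roundHalfUp(df$n_markers / df$length_cm, 2),
                       NA_real_)
  nGroups <- nrow(df)
  totN <- sum(df$n_markers)
  totL <- sum(df$length_cm)
  totals <- list(
    n_markers = totN, length_cm = totL,
    avg_markers_per_group = roundHalfUp(totN / nGroups, 2),
    avg_length_cm = roundHalfUp(totL / nGroups, 2),
    density = if (totL > 0) roundHalfUp(totN / totL, 2) else NA_real_)
  list(groups = df, totals = totals)
}
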