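#' Code RIL calls as +/-1 with imputation
#'
#' A -> +1, B -> -1, H -> 0; missing calls are imputed with the marker
#' mean.
#'
#' @param calls call matrix over \{A,B,H,U\} (markers x samples)
#' @return numeric matrix of the same shape
#' @export
codeGenotypes <- function(calls) {
  G <- matrix(NA_real_, nrow = nrow(calls), ncol = ncol(calls),
              dimnames = dimnames(calls))
  G[calls == "A"] <- 1
  G[calls == "B"] <- -1
  G[calls == "H"] <- 0
  mu <- rowMeans(G, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx)) G[idx] <- mu[idx[, 1]]
  G
}

#' Forward-backward stepwise marker selection
#'
#' Stepwise linear regression of the phenotype on +/-1-coded markers with
#' partial-F entry and exit tests at \code{pIn} / \code{pOut} (the ICIM
#' cofactor-selection step). Collinear candidates (no residual variance
#' given the current model, e.g. a duplicate of a selected marker) never
#' enter.
#'
#' @param G coded genotype matrix (markers x samples)
#' @param y phenotype vector
#' @param pIn entry p-value (default 0.001)
#' @param pOut exit p-value (default 0.002)
#' @param maxMarkers cap on selected markers (default n/5)
#' @return list: markers (character), coef (named, no intercept), fitted
#'   (named full-model coefficients incl. intercept)
#' @export
stepwiseSelect <- function(G, y, pIn = 0.001, pOut = 0.002,
                           maxMarkers = floor(length(y) / 5)) {
  n <- length(y)
  stopIfNot(n == ncol(G), "phenotype length must match sample count")
  if (sd(y) == 0)
    return(list(markers = character(0), coef = numeric(0),
                fitted = c(`(Intercept)` = mean(y))))
  X <- t(G)
  sel <- integer(0)
  repeat {
    # forward: partial F test for every candidate given current model
    Z <- cbind(1, X[, sel, drop = FALSE])
    qrz <- qr(Z)
    ry <- qr.resid(qrz, y)
    cand <- setdiff(seq_len(nrow(G)), sel)
    if (!length(cand) || length(sel) >= maxMarkers) break
    RX <- qr.resid(qrz, X[, cand, drop = FALSE])
    ss <- colSums(RX^2)
    usable <- ss > 1e-8 * n
    dfRes <- n - length(sel) - 2L
    if (dfRes < 1L) break
    num <- as.vector(crossprod(RX, ry))^2 / pmax(ss, 1e-300)
    rss1 <- sum(ry^2) - num
    fstat <- num / pmax(rss1 / dfRes, 1e-300)
    pval <- stats::pf(fstat, 1, dfRes, lower.tail = FALSE)
    pval[!usable] <- 1
    added <- FALSE
    if (min(pval) <= pIn) {
      sel <- c(sel, cand[which.min(pval)])
      added <- TRUE
    }
    # backward: drop the worst selected marker while above pOut
    repeat {
      if (!length(sel)) break
      Z <- cbind(1, X[, sel, drop = FALSE])
      fit <- stats::lm.fit(Z, y)
      rss <- sum(fit$residuals^2)
      dfr <- n - length(sel) - 1L
      pdrop <- vapply(seq_along(sel), function(j) {
        Zj <- Z[, -(j + 1L), drop = FALSE]
        rssj <- sum(qr.resid(qr(Zj), y)^2)
        f <- (rssj - rss) / (rss / dfr)
        stats::pf(f, 1, dfr, lower.tail = FALSE)
      }, numeric(1))
      if (max(pdrop) > pOut) {
        sel <- sel[-which.max(pdrop)]
      } else break
    }
    if (!added) break
  }
  if (!length(sel))
    return(list(markers = character(0), coef = numeric(0),
                fitted = c(`(Intercept)` = mean(y))))
  Z <- cbind(1, X[, sel, drop = FALSE])
  fit <- stats::lm.fit(Z, y)
  cf <- fit$coefficients
  names(cf) <- c("(Intercept)", rownames(G)[sel])
  list(markers = rownames(G)[sel], coef = cf[-1], fitted = cf)
}

#' Subtract selected-cofactor effects, sparing the scanned interval
#'
#' Removes the fitted effects of every stepwise-selected marker except
#' those flanking the scanned interval, leaving the local signal for the
#' interval scan.
#'
#' @param y phenotype vector
#' @param G coded genotype matrix
#' @param selection result of \code{\link{stepwiseSelect}}
#' @param exclude marker ids flanking the scanned interval
#' @return adjusted phenotype vector
#' @export
adjustPhenotype <- function(y, G, selection, exclude = character(0)) {
  use <- setdiff(selection$markers, exclude)
  if (!length(use)) return(y)
  y - as.vector(t(G[use, , drop = FALSE]) %*% selection$coef[use])
}

#' The 1-cM scan grid of a map
#'
#' @param map data.frame with group, marker, pos_cm
#' @param step scan step in cM (default 1)
#' @return data.frame: group, pos_cm, left, right (flanking marker ids)
#' @export
scanPositions <- function(map, step = 1) {
  rows <- lapply(split(map, map$group), function(tb) {
    lo <- min(tb$pos_cm); hi <- max(tb$pos_cm)
    pos <- sort(unique(c(seq(lo, hi, by = step), hi, tb$pos_cm)))
    li <- findInterval(pos + 1e-9, tb$pos_cm)
    li <- pmin(pmax(li, 1L), nrow(tb))
    ri <- pmin(li + 1L, nrow(tb))
    atMarker <- abs(tb$pos_cm[li] - pos) < 1e-9
    ri[atMarker] <- li[atMarker]
    data.frame(group = tb$group[1], pos_cm = pos,
               left = tb$marker[li], right = tb$marker[ri])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# samples x positions matrix of expected QTL genotypes
.scanGenotypes <- function(G, map, grid) {
  X <- matrix(NA_real_, nrow = ncol(G), ncol = nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tb <- map[map$group == grid$group[i], ]
    X[, i] <- expectedQtlGenotype(G, map, grid$group[i], grid$pos_cm[i])
  }
  X
}

#' Additive inclusive composite interval mapping scan
#'
#' Scans the map at \code{step} cM. At each position the expected +/-1 QTL
#' genotype is interpolated from the flanking markers; the phenotype is
#' first adjusted by the stepwise-selected cofactors excluding the two
#' markers flanking the scanned interval. LOD = (n/2) log10(RSS0/RSS1)
#' from the per-position simple regression, additive effect is the
#' regression slope, and PVE = 100 (1 - RSS1/RSS0).
#'
#' @param y phenotype vector (one environment)
#' @param calls call matrix over \{A,B,H,U\}, or an already-coded matrix
#' @param map data.frame with group, marker, pos_cm
#' @param selection optional \code{\link{stepwiseSelect}} result; when
#'   NULL the scan is plain interval mapping
#' @param step scan step in cM
#' @return data.frame: group, pos_cm, lod, effect, pve
#' @export
intervalScan <- function(y, calls, map, selection = NULL, step = 1) {
  G <- if (is.character(calls)) codeGenotypes(calls) else calls
  stopIfNot(all(map$marker %in% rownames(G)),
            "map markers missing from the genotype matrix")
  n <- length(y)
  grid <- scanPositions(map, step)
  X <- .scanGenotypes(G, map, grid)
  lod <- effect <- pve <- numeric(nrow(grid))
  noCof <- is.null(selection) || !length(selection$markers)
  if (noCof) {
    res <- .profileFromX(X, y)
    return(cbind(grid[, c("group", "pos_cm")], res))
  }
  key <- paste(grid$group, grid$left, grid$right)
  for (k in unique(key)) {
    i <- which(key == k)
    ya <- adjustPhenotype(y, G, selection,
                          exclude = c(grid$left[i[1]], grid$right[i[1]]))
    res <- .profileFromX(X[, i, drop = FALSE], ya)
    lod[i] <- res$lod; effect[i] <- res$effect; pve[i] <- res$pve
  }
  cbind(grid[, c("group", "pos_cm")],
        data.frame(lod = lod, effect = effect, pve = pve))
}

# LOD/effect/PVE of y regressed on each column of X (with intercept)
.profileFromX <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  if (rss0 == 0) stop("zero residual variance", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(Xc^2)
  sxy <- as.vector(crossprod(Xc, yc))
  beta <- ifelse(sxx > 1e-12, sxy / pmax(sxx, 1e-300), 0)
  rss1 <- rss0 - beta * sxy
  ratio <- pmin(pmax(rss1 / rss0, 1e-12), 1)
  data.frame(lod = (n / 2) * log10(1 / ratio),
             effect = beta, pve = 100 * (1 - ratio))
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype against the genotype rows \code{nPerm} times;
#' each permutation re-runs cofactor selection and the full scan, and the
#' threshold is the 100 (1 - alpha) percentile of the per-permutation
#' genome-wide maximum LOD. Reproducible under a fixed seed and invariant
#' to location/scale changes of the phenotype.
#'
#' @param y phenotype vector
#' @param calls call or coded genotype matrix
#' @param map data.frame with group, marker, pos_cm
#' @param nPerm number of permutations (default 1000, >= 100)
#' @param alpha genome-wide level (default 0.05)
#' @param seed integer RNG seed
#' @param pIn,pOut stepwise entry/exit p-values
#' @param step scan step in cM
#' @return LOD threshold (attribute \code{max_lods} holds the null maxima)
#' @export
permutationThreshold <- function(y, calls, map, nPerm = 1000,
                                 alpha = 0.05, seed = 1,
                                 pIn = 0.001, pOut = 0.002, step = 1) {
  stopIfNot(nPerm >= 100, "nPerm must be >= 100")
  G <- if (is.character(calls)) codeGenotypes(calls) else calls
  set.seed(as.integer(seed))
  grid <- scanPositions(map, step)
  X <- .scanGenotypes(G, map, grid)
  n <- length(y)
  maxs <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    yp <- y[sample.int(n)]
    selP <- stepwiseSelect(G[unique(map$marker), , drop = FALSE], yp,
                           pIn = pIn, pOut = pOut)
    if (length(selP$markers)) {
      prof <- intervalScan(yp, G, map, selP, step)
      maxs[b] <- max(prof$lod)
    } else {
      maxs[b] <- max(.profileFromX(X, yp)$lod)
    }
  }
  thr <- unname(quantile(maxs, 1 - alpha, type = 7))
  attr(thr, "max_lods") <- maxs
  thr
}

#' Call QTLs from a scan profile
#'
#' Local maxima above the threshold become QTLs; peaks within
#' \code{mergeCm} on a group merge into the higher one, and each QTL
#' carries a 1-LOD-drop support interval.
#'
#' @param profile scan data.frame from \code{\link{intervalScan}}
#' @param threshold LOD threshold
#' @param mergeCm peak-merge radius in cM (default 5)
#' @param supportDrop LOD drop defining the support interval (default 1)
#' @return data.frame: group, peak_cm, lod, effect, pve, ci_lo, ci_hi
#' @export
callQtls <- function(profile, threshold, mergeCm = 5, supportDrop = 1) {
  out <- list()
  for (g in unique(profile$group)) {
    pf <- profile[profile$group == g, , drop = FALSE]
    pf <- pf[order(pf$pos_cm), , drop = FALSE]
    L <- pf$lod
    k <- length(L)
    isPeak <- L >= threshold &
      L >= c(-Inf, L[-k]) & L >= c(L[-1], -Inf)
    peaks <- which(isPeak)
    if (!length(peaks)) next
    # merge peaks within mergeCm, keeping the higher
    peaks <- peaks[order(-L[peaks])]
    kept <- integer(0)
    for (p in peaks) {
      if (!length(kept) ||
          all(abs(pf$pos_cm[p] - pf$pos_cm[kept]) > mergeCm))
        kept <- c(kept, p)
    }
    kept <- sort(kept)
    for (p in kept) {
      lo <- p; while (lo > 1 && L[lo - 1] > L[p] - supportDrop) lo <- lo - 1
      hi <- p; while (hi < k && L[hi + 1] > L[p] - supportDrop) hi <- hi + 1
      out[[length(out) + 1L]] <- data.frame(
        group = g, peak_cm = pf$pos_cm[p], lod = L[p],
        effect = pf$effect[p], pve = pf$pve[p],
        ci_lo = pf$pos_cm[lo], ci_hi = pf$pos_cm[hi])
    }
  }
  if (!length(out))
    return(data.frame(group = character(0), peak_cm = numeric(0),
                      lod = numeric(0), effect = numeric(0),
                      pve = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag robust, stable and consistent QTLs across environments
#'
#' Robust: PVE > 10\% (strict). Stable: a same-trait QTL co-locates
#' (peaks within \code{colocCm} on the same group) in two or more
#' locations. Consistent: co-locates in two or more years.
#'
#' @param qtls data.frame with columns trait, location, year, group,
#'   peak_cm, pve (one row per QTL per environment)
#' @param colocCm co-location window in cM (default 10)
#' @return the input with logical columns robust, stable, consistent
#' @export
categorizeQtls <- function(qtls, colocCm = 10) {
  n <- nrow(qtls)
  qtls$robust <- qtls$pve > 10
  qtls$stable <- FALSE
  qtls$consistent <- FALSE
  if (!n) return(qtls)
  for (i in seq_len(n)) {
    same <- qtls$trait == qtls$trait[i] & qtls$group == qtls$group[i] &
      abs(qtls$peak_cm - qtls$peak_cm[i]) <= colocCm
    qtls$stable[i] <- length(unique(qtls$location[same])) >= 2
    qtls$consistent[i] <- length(unique(qtls$year[same])) >= 2
  }
  qtls
}

#' Scan every trait and environment and call categorized QTLs
#'
#' Runs stepwise selection, the ICIM scan, the permutation threshold and
#' QTL calling per (trait, environment), then categorizes the pooled
#' results.
#'
#' @param phenotypes long data.frame (sample, trait, location, year,
#'   value) as from \code{\link{simulatePhenotypes}}
#' @param calls call matrix (markers x samples; sample columns must cover
#'   the phenotype samples)
#' @param map data.frame with group, marker, pos_cm
#' @param nPerm,alpha permutation-threshold settings
#' @param seed integer RNG seed
#' @param step scan step in cM
#' @param colocCm stable/consistent co-location window
#' @return list: qtls (categorized table), thresholds (per trait/env),
#'   profiles (list of scan data.frames)
#' @export
mapQtls <- function(phenotypes, calls, map, nPerm = 1000, alpha = 0.05,
                    seed = 1, step = 1, colocCm = 10) {
  G <- codeGenotypes(calls)
  Gm <- G[unique(map$marker), , drop = FALSE]
  combos <- unique(phenotypes[, c("trait", "location", "year")])
  allQ <- list(); thrs <- list(); profiles <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- phenotypes[phenotypes$trait == combos$trait[i] &
                      phenotypes$location == combos$location[i] &
                      phenotypes$year == combos$year[i], ]
    sub <- sub[match(colnames(G), sub$sample), ]
    sub <- sub[!is.na(sub$sample), ]
    y <- sub$value
    Gi <- G[, sub$sample, drop = FALSE]
    sel <- stepwiseSelect(Gi[rownames(Gm), , drop = FALSE], y)
    thr <- permutationThreshold(y, Gi, map, nPerm = nPerm, alpha = alpha,
                                seed = seed + i, step = step)
    prof <- intervalScan(y, Gi, map, sel, step)
    q <- callQtls(prof, thr)
    key <- paste(combos$trait[i], combos$location[i], combos$year[i],
                 sep = "_")
    profiles[[key]] <- prof
    thrs[[key]] <- as.numeric(thr)
    if (nrow(q)) {
      q$trait <- combos$trait[i]
      q$location <- combos$location[i]
      q$year <- combos$year[i]
      q$threshold <- as.numeric(thr)
      allQ[[length(allQ) + 1L]] <- q
    }
  }
  qtls <- if (length(allQ)) do.call(rbind, allQ) else
    data.frame(group = character(0), peak_cm = numeric(0),
               lod = numeric(0), effect = numeric(0), pve = numeric(0),
               ci_lo = numeric(0), ci_hi = numeric(0),
               trait = character(0), location = character(0),
               year = integer(0), threshold = numeric(0))
  list(qtls = categorizeQtls(qtls, colocCm),
       thresholds = unlist(thrs), profiles = profiles)
}
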