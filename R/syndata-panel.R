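#' Simulate a resequencing variant panel over a synthetic genome
#'
#' Draws SNPs at \code{snpRate} per base and indels at \code{indelRate},
#' with per-site quality scores and allele counts over \code{2 *
#' nAccessions} chromosomes (alternate allele frequencies follow a
#' Beta(\code{mafBeta[1]}, \code{mafBeta[2]}) spectrum). A configurable
#' fraction of SNP sites receives a second alternate allele. When
#' \code{plantKillers} is TRUE the panel additionally carries one planted
#' "filter-killer" variant per design filter -- a pair of SNPs 20 bp apart
#' (isolation rule), a SNP beside a planted SSR tract, a SNP 10 bp from a
#' planted indel, a triallelic site, a MAF 0.04 site, a SNP in an
#' out-of-band GC window, a SNP beside an N tract, and a QUAL 29 site --
#' each clean with respect to every earlier filter, so downstream attrition
#' accounting can be checked against ground truth (column \code{planted}).
#'
#' @param genome a \code{\link{SyntheticGenome}}
#' @param nAccessions panel size (>= 2)
#' @param snpRate,indelRate per-base variant rates in (0,1)
#' @param mafBeta shape parameters of the alternate-allele-frequency Beta
#' @param qualMean,qualSd normal parameters of the site quality score
#' @param triallelicFraction fraction of random SNPs given a second alt
#' @param plantKillers plant the eight filter-killer variants?
#' @param seed integer RNG seed
#' @return data.frame with columns chrom, pos, id, ref, alt, qual, ac, an,
#'   type, planted, sorted by (chrom, pos)
#' @export
simulatePanel <- function(genome, nAccessions = 50, snpRate = 1e-3,
                          indelRate = 5e-5, mafBeta = c(0.5, 0.5),
                          qualMean = 45, qualSd = 10,
                          triallelicFraction = 0.01,
                          plantKillers = TRUE, seed = 1) {
  stopIfNot(nAccessions >= 2, "need at least two accessions")
  stopIfNot(snpRate > 0 && snpRate < 1 && indelRate >= 0 && indelRate < 1,
            "rates must lie in (0,1)")
  set.seed(as.integer(seed))
  seqs <- genomeSeqs(genome)
  an <- 2L * as.integer(nAccessions)
  bases <- c("A", "C", "G", "T")

  rows <- list()
  for (ch in names(seqs)) {
    s <- strsplit(as.character(seqs[[ch]]), "")[[1]]
    L <- length(s)
    usable <- which(s %in% bases)
    nSnp <- rbinom(1, L, snpRate)
    nInd <- rbinom(1, L, indelRate)
    posSnp <- sort(sample(usable, min(nSnp, length(usable))))
    posInd <- sort(sample(setdiff(usable, posSnp),
                          min(nInd, length(usable) - length(posSnp))))
    if (length(posSnp)) {
      ref <- s[posSnp]
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1),
                    character(1), USE.NAMES = FALSE)
      af <- rbeta(length(posSnp), mafBeta[1], mafBeta[2])
      ac <- pmin(pmax(rbinom(length(posSnp), an, af), 1L), an - 1L)
      tri <- runif(length(posSnp)) < triallelicFraction
      alt2 <- vapply(seq_along(posSnp), function(i)
        if (tri[i]) sample(setdiff(bases, c(ref[i], alt[i])), 1)
        else NA_character_, character(1))
      acStr <- ifelse(tri, paste(pmax(ac - 1L, 1L), 1L, sep = ","),
                      as.character(ac))
      altStr <- ifelse(tri, paste(alt, alt2, sep = ","), alt)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = posSnp, ref = ref, alt = altStr,
        qual = pmax(round(rnorm(length(posSnp), qualMean, qualSd), 1), 1),
        ac = acStr, an = an, type = "snp", planted = NA_character_)
    }
    if (length(posInd)) {
      isDel <- runif(length(posInd)) < 0.5
      ref <- character(length(posInd)); alt <- character(length(posInd))
      for (i in seq_along(posInd)) {
        p <- posInd[i]; k <- sample(1:4, 1)
        if (isDel[i] && p + k <= L && all(s[p:(p + k)] %in% bases)) {
          ref[i] <- paste(s[p:(p + k)], collapse = ""); alt[i] <- s[p]
        } else {
          ref[i] <- s[p]
          alt[i] <- paste(c(s[p], sample(bases, k, replace = TRUE)),
                          collapse = "")
        }
      }
      af <- rbeta(length(posInd), mafBeta[1], mafBeta[2])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = posInd, ref = ref, alt = alt,
        qual = pmax(round(rnorm(length(posInd), qualMean, qualSd), 1), 1),
        ac = as.character(pmin(pmax(rbinom(length(posInd), an, af), 1L),
                               an - 1L)),
        an = an, type = "indel", planted = NA_character_)
    }
  }
  panel <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), qual = numeric(0), ac = character(0),
               an = integer(0), type = character(0),
               planted = character(0))

  if (plantKillers) {
    planted <- .plantKillers(genome, panel, an, qualMean)
    if (nrow(planted$add)) {
      # clear random variants near planted sites so each killer violates
      # only its own filter
      drop <- rep(FALSE, nrow(panel))
      for (i in seq_len(nrow(planted$add))) {
        drop <- drop | (panel$chrom == planted$add$chrom[i] &
                        abs(panel$pos - planted$add$pos[i]) <= 45L)
      }
      panel <- panel[!drop, , drop = FALSE]
      panel <- rbind(panel, planted$add)
    }
  }
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  panel$id <- .mkId(panel$chrom, panel$pos)
  rownames(panel) <- NULL
  panel[, c("chrom", "pos", "id", "ref", "alt", "qual", "ac", "an",
            "type", "planted")]
}

# choose clean positions and build the eight filter-killer variants
.plantKillers <- function(genome, panel, an, qualMean) {
  seqs <- genomeSeqs(genome)
  flank <- 35L
  bases <- c("A", "C", "G", "T")
  acMid <- max(1L, round(0.25 * an))

  ssrAll <- lapply(names(seqs), function(ch) {
    tr <- detectSsr(seqs[[ch]])
    if (nrow(tr)) cbind(chrom = ch, tr) else NULL
  })
  ssrAll <- do.call(rbind, ssrAll)

  cleanAt <- function(ch, p, skipGc = FALSE, skipSsr = FALSE,
                      skipAmb = FALSE) {
    L <- Biostrings::width(seqs)[match(ch, names(seqs))]
    if (p - flank < 1L || p + flank > L) return(FALSE)
    w <- as.character(Biostrings::subseq(seqs[[ch]], p - flank, p + flank))
    wc <- strsplit(w, "")[[1]]
    if (!wc[flank + 1L] %in% bases) return(FALSE)
    if (!skipAmb && any(!wc %in% bases)) return(FALSE)
    if (!skipGc) {
      g <- computeGcFraction(w)
      if (g < 0.40 || g > 0.70) return(FALSE)
    }
    if (!skipSsr && !is.null(ssrAll)) {
      near <- ssrAll$chrom == ch & ssrAll$start <= p + flank &
        ssrAll$end >= p - flank
      if (any(near)) return(FALSE)
    }
    TRUE
  }
  randomClean <- function(nTry = 400L, ...) {
    for (t in seq_len(nTry)) {
      ch <- sample(names(seqs), 1)
      L <- Biostrings::width(seqs)[match(ch, names(seqs))]
      p <- sample(seq(flank + 1L, L - flank), 1)
      if (cleanAt(ch, p, ...)) return(list(chrom = ch, pos = p))
    }
    NULL
  }
  mkRow <- function(ch, p, label, alt = NULL, qual = NULL, ac = NULL) {
    ref <- as.character(Biostrings::subseq(seqs[[ch]], p, p))
    if (is.null(alt)) alt <- sample(setdiff(bases, ref), 1)
    data.frame(chrom = ch, pos = p, ref = ref, alt = alt,
               qual = if (is.null(qual)) round(qualMean, 1) else qual,
               ac = if (is.null(ac)) as.character(acMid) else ac,
               an = an, type = "snp", planted = label)
  }

  add <- list()
  # (isolation) pair 20 bp apart
  loc <- randomClean()
  if (!is.null(loc) && cleanAt(loc$chrom, loc$pos + 20L)) {
    add <- c(add, list(mkRow(loc$chrom, loc$pos, "isolated"),
                       mkRow(loc$chrom, loc$pos + 20L, "isolated")))
  }
  # (ssr) SNP within 35 bp of a planted SSR tract
  if (length(genome@ssr)) {
    tr <- genome@ssr[1]
    ch <- as.character(GenomicRanges::seqnames(tr))
    for (off in c(10L, 15L, 20L, 25L, 30L)) {
      p <- GenomicRanges::end(tr) + off
      if (cleanAt(ch, p, skipSsr = TRUE, skipGc = TRUE)) {
        add <- c(add, list(mkRow(ch, p, "ssr"))); break
      }
    }
  }
  # (indel) an indel plus a SNP 10 bp away
  loc <- randomClean()
  if (!is.null(loc) && cleanAt(loc$chrom, loc$pos + 10L)) {
    ch <- loc$chrom; p <- loc$pos
    refIns <- as.character(Biostrings::subseq(seqs[[ch]], p, p))
    ind <- data.frame(chrom = ch, pos = p, ref = refIns,
                      alt = paste0(refIns, "ACG"),
                      qual = round(qualMean, 1),
                      ac = as.character(acMid), an = an, type = "indel",
                      planted = "indel_context")
    add <- c(add, list(ind, mkRow(ch, p + 10L, "indel")))
  }
  # (biallelic) triallelic site
  loc <- randomClean()
  if (!is.null(loc)) {
    ref <- as.character(Biostrings::subseq(seqs[[loc$chrom]], loc$pos,
                                           loc$pos))
    alts <- sample(setdiff(bases, ref), 2)
    add <- c(add, list(mkRow(loc$chrom, loc$pos, "biallelic",
                             alt = paste(alts, collapse = ","),
                             ac = paste(max(acMid - 1L, 1L), 1L,
                                        sep = ","))))
  }
  # (maf) minor allele frequency 0.04
  loc <- randomClean()
  if (!is.null(loc)) {
    acLow <- max(1L, floor(0.04 * an))
    if (acLow / an >= 0.05) acLow <- acLow - 1L
    add <- c(add, list(mkRow(loc$chrom, loc$pos, "maf",
                             ac = as.character(acLow))))
  }
  # (gc) window GC outside [0.40, 0.70]: scan for one
  loc <- .findGcOutlier(seqs, flank, cleanAt)
  if (!is.null(loc)) add <- c(add, list(mkRow(loc$chrom, loc$pos, "gc")))
  # (ambiguity) SNP within 35 bp of a planted N tract
  if (length(genome@ambiguity)) {
    aa <- genome@ambiguity[1]
    ch <- as.character(GenomicRanges::seqnames(aa))
    found <- FALSE
    for (off in c(5L, 10L, 15L, 20L, 25L, 30L)) {
      p <- GenomicRanges::end(aa) + off
      if (cleanAt(ch, p, skipAmb = TRUE)) {
        add <- c(add, list(mkRow(ch, p, "ambiguity"))); found <- TRUE
        break
      }
    }
    if (!found) {
      p <- GenomicRanges::end(aa) + 5L
      if (cleanAt(ch, p, skipAmb = TRUE, skipGc = TRUE))
        add <- c(add, list(mkRow(ch, p, "ambiguity")))
    }
  }
  # (qual) QUAL 29 site
  loc <- randomClean()
  if (!is.null(loc))
    add <- c(add, list(mkRow(loc$chrom, loc$pos, "qual", qual = 29)))

  add <- if (length(add)) do.call(rbind, add) else
    panel[integer(0), setdiff(names(panel), "id"), drop = FALSE]
  list(add = add)
}

# first clean-except-GC window centre, scanning with a running GC count
.findGcOutlier <- function(seqs, flank, cleanAt) {
  w <- 2L * flank + 1L
  for (ch in names(seqs)) {
    s <- strsplit(as.character(seqs[[ch]]), "")[[1]]
    isGc <- as.integer(s %in% c("G", "C"))
    if (length(s) < w) next
    cs <- cumsum(isGc)
    gcw <- (cs[w:length(s)] - c(0L, cs)[seq_len(length(s) - w + 1L)]) / w
    cand <- which(gcw < 0.40 | gcw > 0.70) + flank  # window centres
    for (p in cand) {
      if (cleanAt(ch, p, skipGc = TRUE)) return(list(chrom = ch, pos = p))
    }
  }
  NULL
}
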