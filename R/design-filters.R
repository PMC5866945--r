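#' Default minimum copy numbers for SSR detection
#'
#' MISA-convention thresholds for perfect tandem repeats: 10 copies for
#' mononucleotide motifs, 6 for di-, and 5 for tri- to hexanucleotide
#' motifs.
#'
#' @return integer vector indexed by motif length 1..6
#' @export
defaultSsrThresholds <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

.asChars <- function(sequence) {
  if (methods::is(sequence, "DNAString") ||
      methods::is(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)
  if (is.character(sequence) && length(sequence) == 1L)
    sequence <- strsplit(sequence, "")[[1]]
  toupper(sequence)
}

#' Detect perfect SSR tracts in a DNA sequence
#'
#' Finds maximal perfect tandem repeats with motif length 1-6 reaching the
#' per-motif-length minimum copy number. Motifs must be primitive (not a
#' power of a shorter motif, so a poly-A run is reported once as a
#' mononucleotide tract, not again as AA, AAA, ...). Only whole copies count
#' towards the tract; characters outside A/C/G/T terminate tracts. Tracts
#' are reported 1-based inclusive.
#'
#' @param sequence character string, character vector of bases, or
#'   \code{DNAString}
#' @param thresholds minimum copies per motif length, as
#'   \code{\link{defaultSsrThresholds}}
#' @return data.frame with columns start, end, motif (possibly 0 rows)
#' @export
detectSsr <- function(sequence, thresholds = defaultSsrThresholds()) {
  s <- .asChars(sequence)
  n <- length(s)
  ok <- s %in% c("A", "C", "G", "T")
  rows <- list()
  for (m in seq_along(thresholds)) {
    if (n < m * thresholds[m]) next
    i <- seq_len(n - m)
    eq <- s[i] == s[i + m] & ok[i] & ok[i + m]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      a <- starts[j]
      copies <- (r$lengths[j] + m) %/% m
      if (copies < thresholds[m]) next
      motif <- s[a:(a + m - 1L)]
      if (!.isPrimitive(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = a, end = a + m * copies - 1L,
        motif = paste(motif, collapse = ""))
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0)))
  out <- unique(do.call(rbind, rows))
  out[order(out$start, out$end), , drop = FALSE]
}

#' GC fraction of a sequence window
#'
#' @param window character string, base vector or \code{DNAString}
#' @return (G+C)/length in [0,1]
#' @export
computeGcFraction <- function(window) {
  s <- .asChars(window)
  stopIfNot(length(s) > 0, "empty window")
  sum(s %in% c("G", "C")) / length(s)
}

#' Minor allele frequency from per-allele counts
#'
#' For a biallelic site this is \code{min(p, 1-p)}; generally it is one
#' minus the major-allele frequency.
#'
#' @param counts numeric vector of observed allele counts (length >= 2)
#' @return minor allele frequency in [0, 0.5]
#' @export
computeMaf <- function(counts) {
  stopIfNot(length(counts) >= 2, "need counts for at least two alleles")
  tot <- sum(counts)
  stopIfNot(tot > 0, "zero observed alleles")
  1 - max(counts) / tot
}

#' Does a window contain any IUPAC ambiguity character?
#'
#' @param window character string, base vector or \code{DNAString}
#' @return TRUE iff any character outside A/C/G/T (N, R, Y, ...)
#' @export
hasAmbiguity <- function(window) {
  s <- .asChars(window)
  any(!s %in% c("A", "C", "G", "T"))
}

#' Remove SNPs with another SNP within the flanking window
#'
#' A SNP survives iff no other SNP lies within \code{window} bp on either
#' side; a pair at distance <= \code{window} removes both members. All
#' records passed in are treated as SNPs and must be sorted by
#' (chrom, pos).
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos}
#' @param window flank size in bp (default 35)
#' @return the surviving rows of \code{variants}
#' @export
filterIsolated <- function(variants, window = 35L) {
  if (!nrow(variants)) return(variants)
  ord <- order(variants$chrom, variants$pos)
  stopIfNot(identical(ord, seq_len(nrow(variants))),
            "variants must be sorted by (chrom, pos)")
  keep <- isolatedFlags(variants, window)
  variants[keep, , drop = FALSE]
}

# logical flag per (sorted) variant: no neighbouring SNP within window bp
isolatedFlags <- function(variants, window = 35L) {
  n <- nrow(variants)
  if (!n) return(logical(0))
  sameChromPrev <- c(FALSE, variants$chrom[-1] == variants$chrom[-n])
  dPrev <- c(Inf, diff(variants$pos))
  dPrev[!sameChromPrev] <- Inf
  dNext <- c(dPrev[-1], Inf)
  dPrev > window & dNext > window
}

#' Collapse duplicate candidates at the same genomic position
#'
#' Keeps exactly one record per (chrom, pos): the one with the highest
#' quality, ties broken by the lexicographically smallest alternate allele.
#'
#' @param candidates data.frame with \code{chrom}, \code{pos}, \code{qual},
#'   \code{alt}
#' @return non-redundant candidate rows
#' @export
deduplicateCandidates <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  key <- paste(candidates$chrom, candidates$pos, sep = "\r")
  ord <- order(key, -candidates$qual, candidates$alt)
  x <- candidates[ord, , drop = FALSE]
  x[!duplicated(key[ord]), , drop = FALSE]
}

#' Filter candidates through a conversion-probability scoring hook
#'
#' Placeholder for an external per-probe conversion score (such as a
#' vendor's p-convert model): any scorer returning one value in [0,1] per
#' candidate can be plugged in; candidates scoring at or above the
#' threshold are retained. The default scorer returns 1 for every
#' candidate, making the hook a no-op.
#'
#' @param candidates data.frame of probe candidates
#' @param scorer function(candidates) -> numeric vector in [0,1]
#' @param threshold retention threshold (inclusive), default 0.3
#' @return retained candidate rows, with a \code{score} column
#' @export
scoreHook <- function(candidates, scorer = function(x) rep(1, nrow(x)),
                      threshold = 0.3) {
  sc <- scorer(candidates)
  stopIfNot(length(sc) == nrow(candidates),
            "scorer must return one value per candidate")
  if (nrow(candidates))
    stopIfNot(all(sc >= 0 & sc <= 1), "scores must lie in [0,1]")
  candidates$score <- sc
  candidates[sc >= threshold, , drop = FALSE]
}
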