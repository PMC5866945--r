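# Independent brute-force oracles and hand-built fixtures used across the
# suite. These deliberately re-derive each result by the most naive route
# available so they share no code with the implementation under test.

# all-pairs isolation check: survive iff no other record within `window`
# bp on the same chromosome
bruteIsolated <- function(variants, window = 35L) {
  n <- nrow(variants)
  keep <- logical(n)
  for (i in seq_len(n)) {
    d <- abs(variants$pos - variants$pos[i])
    near <- variants$chrom == variants$chrom[i] & d <= window
    keep[i] <- sum(near) == 1L  # itself only
  }
  variants[keep, , drop = FALSE]
}

# exhaustive SSR enumeration over every motif length, start and phase
bruteSsr <- function(sequence, thresholds = defaultSsrThresholds()) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  acgt <- c("A", "C", "G", "T")
  primitive <- function(motif) {
    m <- length(motif)
    if (m == 1L) return(TRUE)
    for (d in seq_len(m - 1L)) {
      if (m %% d) next
      if (identical(motif, rep(motif[seq_len(d)], m / d))) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  for (m in seq_along(thresholds)) {
    if (n < m * thresholds[m]) next
    for (i in seq_len(n - m * thresholds[m] + 1L)) {
      motif <- s[i:(i + m - 1L)]
      if (any(!motif %in% acgt)) next
      if (!primitive(motif)) next
      # anchored: the period must not extend one base to the left
      if (i > 1L && s[i - 1L] %in% acgt && i - 1L + m <= n &&
          s[i - 1L] == s[i - 1L + m]) next
      k <- 1L
      while (i + (k + 1L) * m - 1L <= n &&
             identical(s[(i + k * m):(i + (k + 1L) * m - 1L)], motif))
        k <- k + 1L
      if (k >= thresholds[m])
        rows[[length(rows) + 1L]] <- data.frame(
          start = i, end = i + m * k - 1L,
          motif = paste(motif, collapse = ""))
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0)))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# duplicate grouping by whole-row identity (no missing data)
bruteBins <- function(calls) {
  key <- apply(calls, 1, paste, collapse = "")
  rep_of <- tapply(seq_len(nrow(calls)), key, min)
  data.frame(marker = rownames(calls),
             representative = rownames(calls)[rep_of[key]])
}

# minimum sum of adjacent recombination fractions over all permutations
bruteMinSarf <- function(markers, rMat) {
  k <- length(markers)
  perms <- cicerArrayQTL:::.permutations(k)
  best <- Inf
  for (p in seq_len(nrow(perms))) {
    o <- markers[perms[p, ]]
    sc <- sum(rMat[cbind(o[-k], o[-1])])
    if (sc < best) best <- sc
  }
  best
}

sarfOf <- function(ord, rMat) sum(rMat[cbind(ord[-length(ord)], ord[-1])])

# a one-row cluster summary
clusterRow <- function(cluster, n, mx, my, sx = 0.1, sy = 0.05) {
  data.frame(snp = "s", cluster = cluster, n = n, mean_x = mx,
             sd_x = sx, mean_y = my, sd_y = sy)
}

# a complete metrics row with every gate passing; override as needed
mkMetrics <- function(call_rate = 0.99, n_clusters = 3L, fld = 5,
                      hom_fld = 10, het_so = 0, hom_ro = 0.8,
                      vx_AA = 0.01, vy_AA = 0.01, vx_BB = 0.01,
                      vy_BB = 0.01, minor_hom = 10L,
                      has_het = n_clusters != 2L || NA,
                      otv_frac = 0, het_so_otv = NA_real_,
                      otv_flag = FALSE) {
  if (is.na(has_het)) has_het <- TRUE
  data.frame(call_rate = call_rate, n_clusters = n_clusters, fld = fld,
             hom_fld = hom_fld, het_so = het_so, hom_ro = hom_ro,
             vx_AA = vx_AA, vy_AA = vy_AA, vx_BB = vx_BB, vy_BB = vy_BB,
             minor_hom = minor_hom, has_het = has_het,
             otv_frac = otv_frac, het_so_otv = het_so_otv,
             otv_flag = otv_flag)
}

# hand-laid single-gene genome for effect annotation:
#   pad(10) + exon1 ATGGCTAAA (11..19) + intron GTCCCCCAG (20..28) +
#   exon2 GGGTGGTAA (29..37) + pad(10)
effectFixture <- function(strand = "+") {
  fwd <- paste0("CAGTCAGTCA", "ATGGCTAAA", "GTCCCCCAG", "GGGTGGTAA",
                "TGACTGACTG")
  if (strand == "+") {
    seqs <- Biostrings::DNAStringSet(c(chr1 = fwd))
    gm <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(11, 29), c(19, 37)), strand = "+")
    gm$gene_id <- "g1"; gm$exon_rank <- 1:2
  } else {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))
    seqs <- Biostrings::DNAStringSet(c(chr1 = rc))
    L <- nchar(fwd)
    # exon1 (rank 1) maps to L-19+1 .. L-11+1, exon2 to L-37+1 .. L-29+1
    gm <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(L - 19 + 1, L - 37 + 1), c(L - 11 + 1, L - 29 + 1)),
      strand = "-")
    gm$gene_id <- "g1"; gm$exon_rank <- 1:2
  }
  list(seqs = seqs, genes = gm)
}

# panel fixture: seven variants each violating exactly one numbered design
# filter, plus three clean ones, on a purpose-built chromosome
designFixture <- function() {
  set.seed(4242)
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, 4000, replace = TRUE)
  s[500:511] <- "A"                       # SSR tract (12 x A)
  s[1000] <- "N"                          # ambiguity
  gcPatch <- sample(c("G", "C"), 71, replace = TRUE)
  s[1500:1570] <- gcPatch                 # GC ~ 1 window
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste(s, collapse = "")))

  clean <- function(p) {
    w <- s[(p - 35):(p + 35)]
    if (any(!w %in% bases)) return(FALSE)
    gc <- sum(w %in% c("G", "C")) / 71
    if (gc < 0.40 || gc > 0.70) return(FALSE)
    tr <- bruteSsr(paste(s[(max(1, p - 120)):(p + 120)], collapse = ""))
    if (nrow(tr)) return(FALSE)
    TRUE
  }
  pick <- function(from) { p <- from; while (!clean(p)) p <- p + 1L; p }

  an <- 100L
  mkv <- function(pos, alt = NULL, qual = 45, ac = "25", type = "snp",
                  ref = NULL) {
    if (is.null(ref)) ref <- s[pos]
    if (is.null(alt)) alt <- setdiff(bases, ref)[1]
    data.frame(chrom = "chr1", pos = pos, id = paste0("v", pos),
               ref = ref, alt = alt, qual = qual, ac = ac, an = an,
               type = type, planted = NA_character_)
  }
  pSsr <- 520L                            # inside 35 bp of the tract
  pInd <- pick(1900L); pIndSnp <- pInd + 10L
  while (!clean(pIndSnp)) { pInd <- pick(pInd + 1L); pIndSnp <- pInd + 10L }
  pTri <- pick(2100L); pMaf <- pick(2200L); pQual <- pick(2300L)
  pGc <- 1535L; pAmb <- 1005L
  pOk <- c(pick(2400L), pick(2500L), pick(2600L))
  v <- rbind(
    mkv(pSsr),
    mkv(pInd, ref = s[pInd], alt = paste0(s[pInd], "AC"), type = "indel"),
    mkv(pIndSnp),
    mkv(pTri, alt = paste(setdiff(bases, s[pTri])[1:2], collapse = ","),
        ac = "24,1"),
    mkv(pMaf, ac = "4"),
    mkv(pGc),
    mkv(pAmb),
    mkv(pQual, qual = 29),
    mkv(pOk[1]), mkv(pOk[2]), mkv(pOk[3]))
  v <- v[order(v$pos), ]
  rownames(v) <- NULL
  list(seqs = seqs, variants = v, clean_pos = pOk,
       expect_removed = c(edge = 0L, isolated = 0L, ssr = 1L, indel = 1L,
                          biallelic = 1L, maf = 1L, gc = 1L,
                          ambiguity = 1L, qual = 1L))
}
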