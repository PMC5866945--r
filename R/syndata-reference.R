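#' Simulate a small annotated reference genome
#'
#' Generates a multi-chromosome genome of random sequence at a target GC
#' content, with a requested number of planted protein-coding genes (multi-
#' exon CDS with canonical GT..AG introns, ATG start and stop codon), SSR
#' tracts (perfect tandem repeats sized to clear the \code{\link{detectSsr}}
#' thresholds) and optional short N tracts so that sequence-ambiguity
#' filtering has something to find. All placements are non-overlapping with
#' padding, so every planted feature is recoverable by the corresponding
#' detector. Deterministic for a fixed seed.
#'
#' @param seed integer RNG seed.
#' @param nChrom number of chromosomes (>= 1).
#' @param chromLength length of each chromosome in bp (scalar or vector,
#'   each >= 1000).
#' @param geneCount total genes to plant across the genome.
#' @param ssrCount total SSR tracts to plant.
#' @param gcTarget target GC fraction of background sequence.
#' @param ambiguityCount number of short N tracts to plant (default 1).
#' @param ssrThresholds minimum copy numbers per motif length used to size
#'   planted tracts; see \code{\link{detectSsr}}.
#' @return a \code{\link{SyntheticGenome}}.
#' @export
makeReference <- function(seed, nChrom = 8, chromLength = 200000L,
                          geneCount = 40, ssrCount = 20, gcTarget = 0.5,
                          ambiguityCount = 1,
                          ssrThresholds = defaultSsrThresholds()) {
  stopIfNot(nChrom >= 1, "nChrom must be >= 1")
  chromLength <- as.integer(rep(chromLength, length.out = nChrom))
  stopIfNot(all(chromLength >= 1000L), "chromosome lengths must be >= 1000")
  stopIfNot(gcTarget > 0 && gcTarget < 1, "gcTarget must lie in (0,1)")
  set.seed(as.integer(seed))

  chromNames <- sprintf("Chr%02d", seq_len(nChrom))
  probs <- c(A = (1 - gcTarget) / 2, C = gcTarget / 2,
             G = gcTarget / 2, T = (1 - gcTarget) / 2)
  seqs <- lapply(chromLength, function(L)
    sample(names(probs), L, replace = TRUE, prob = probs))

  # build feature payloads first, then place them without overlap
  genes <- if (geneCount > 0) lapply(seq_len(geneCount), function(i)
    .randomGene(sprintf("gene%03d", i))) else list()
  ssrs <- if (ssrCount > 0) lapply(seq_len(ssrCount), function(i)
    .randomSsr(ssrThresholds)) else list()
  ambs <- if (ambiguityCount > 0) lapply(seq_len(ambiguityCount), function(i)
    list(kind = "amb", seq = rep("N", 5L), id = i)) else list()

  feats <- c(genes, ssrs, ambs)
  # round-robin assignment over chromosomes, then shuffled placement
  chromOf <- rep(seq_len(nChrom), length.out = length(feats))
  geneRows <- list(); ssrRows <- list(); ambRows <- list()
  pad <- 80L
  for (k in seq_len(nChrom)) {
    idx <- which(chromOf == k)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    lens <- vapply(feats[idx], function(f) length(f$seq), integer(1))
    needed <- sum(lens) + pad * (length(idx) + 1L)
    if (needed > chromLength[k])
      stop("infeasible packing: features need ", needed,
           " bp but chromosome ", chromNames[k], " is ",
           chromLength[k], " bp", call. = FALSE)
    slack <- chromLength[k] - needed
    offsets <- sort(sample.int(slack + 1L, length(idx), replace = TRUE)) - 1L
    starts <- pad + offsets + cumsum(c(0L, head(lens, -1) + pad)) + 1L
    for (j in seq_along(idx)) {
      f <- feats[[idx[j]]]
      s <- starts[j]; e <- s + length(f$seq) - 1L
      seqs[[k]][s:e] <- f$seq
      if (f$kind == "gene") {
        ex <- f$exons  # transcript-order exon offsets within the gene
        geneRows[[length(geneRows) + 1L]] <- data.frame(
          chrom = chromNames[k], start = s + ex$start - 1L,
          end = s + ex$end - 1L, strand = f$strand,
          gene_id = f$id, exon_rank = ex$rank)
      } else if (f$kind == "ssr") {
        ssrRows[[length(ssrRows) + 1L]] <- data.frame(
          chrom = chromNames[k], start = s, end = e, motif = f$motif)
      } else {
        ambRows[[length(ambRows) + 1L]] <- data.frame(
          chrom = chromNames[k], start = s, end = e)
      }
    }
  }

  dss <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                         collapse = ""))
  names(dss) <- chromNames
  mkGr <- function(rows, extraCols = character()) {
    if (!length(rows)) {
      gr <- GenomicRanges::GRanges()
      for (cc in extraCols) S4Vectors::mcols(gr)[[cc]] <- character(0)
      return(gr)
    }
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
      strand = if ("strand" %in% names(df)) df$strand else "*")
    for (cc in extraCols) S4Vectors::mcols(gr)[[cc]] <- df[[cc]]
    gr
  }
  genome <- new("SyntheticGenome", seqs = dss,
                genes = mkGr(geneRows, c("gene_id", "exon_rank")),
                ssr = mkGr(ssrRows, "motif"),
                ambiguity = mkGr(ambRows))
  methods::validObject(genome)
  genome
}

# a random multi-exon gene; exon coordinates are genomic offsets (1-based
# within the gene locus), exon_rank in transcription order
.randomGene <- function(id) {
  nExon <- sample(1:3, 1)
  nCodon <- sample(30:80, 1)
  codons <- .randomCodons(nCodon - 2L)
  cds <- c("ATG", codons, sample(c("TAA", "TAG", "TGA"), 1))
  cdsSeq <- unlist(strsplit(paste(cds, collapse = ""), ""))
  # split CDS into exons at codon-unaligned points (any base is fine)
  cuts <- if (nExon > 1)
    sort(sample(seq_len(length(cdsSeq) - 1L), nExon - 1L)) else integer(0)
  bounds <- cbind(c(1L, cuts + 1L), c(cuts, length(cdsSeq)))
  exonSeqs <- lapply(seq_len(nExon),
                     function(i) cdsSeq[bounds[i, 1]:bounds[i, 2]])
  intronSeqs <- if (nExon > 1) lapply(seq_len(nExon - 1L), function(i) {
    mid <- sample(c("A", "C", "G", "T"), sample(36:96, 1), replace = TRUE)
    c("G", "T", mid, "A", "G")
  }) else list()
  pieces <- list(); st <- integer(nExon); en <- integer(nExon); pos <- 0L
  for (i in seq_len(nExon)) {
    st[i] <- pos + 1L
    pieces[[length(pieces) + 1L]] <- exonSeqs[[i]]
    pos <- pos + length(exonSeqs[[i]])
    en[i] <- pos
    if (i < nExon) {
      pieces[[length(pieces) + 1L]] <- intronSeqs[[i]]
      pos <- pos + length(intronSeqs[[i]])
    }
  }
  locus <- unlist(pieces)
  strand <- sample(c("+", "-"), 1)
  if (strand == "-") {
    L <- length(locus)
    locus <- .revComp(locus)
    newSt <- L - en + 1L; newEn <- L - st + 1L
    st <- rev(newSt); en <- rev(newEn)
    rank <- rev(seq_len(nExon))  # genomic order rows, rank 5'->3'
  } else rank <- seq_len(nExon)
  list(kind = "gene", id = id, seq = locus, strand = strand,
       exons = data.frame(start = st, end = en, rank = rank))
}

.randomCodons <- function(n) {
  stops <- c("TAA", "TAG", "TGA")
  all64 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             c("A", "C", "G", "T")), 1, paste, collapse = "")
  sample(setdiff(all64, stops), n, replace = TRUE)
}

.revComp <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

.randomSsr <- function(thresholds) {
  m <- sample(seq_along(thresholds), 1)
  repeat {
    motif <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    if (.isPrimitive(motif)) break
  }
  copies <- thresholds[m] + sample(1:3, 1)
  list(kind = "ssr", seq = rep(motif, copies),
       motif = paste(motif, collapse = ""))
}

# TRUE iff the motif is not a whole-number power of a shorter motif
.isPrimitive <- function(motif) {
  m <- length(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d != 0L) next
    if (all(motif == rep(motif[seq_len(d)], m / d))) return(FALSE)
  }
  TRUE
}

#' Write a SyntheticGenome to FASTA and GFF3
#'
#' The GFF3 carries gene, mRNA and CDS features (1-based inclusive
#' coordinates); planted SSR and N tracts are emitted as \code{repeat_region}
#' features so they survive a round trip.
#'
#' @param genome a \code{\link{SyntheticGenome}}
#' @param fastaPath,gffPath output paths
#' @return invisibly, the paths
#' @export
writeGenome <- function(genome, fastaPath, gffPath) {
  Biostrings::writeXStringSet(genomeSeqs(genome), fastaPath, width = 70L)
  ex <- geneModels(genome)
  grl <- list()
  if (length(ex)) {
    spans <- unlist(range(S4Vectors::split(ex, ex$gene_id)))
    gene <- GenomicRanges::GRanges(GenomicRanges::seqnames(spans),
                                   IRanges::ranges(spans),
                                   strand = GenomicRanges::strand(spans))
    gene$type <- "gene"; gene$ID <- names(spans)
    mrna <- gene
    mrna$type <- "mRNA"; mrna$ID <- paste0(names(spans), ".t1")
    mrna$Parent <- names(spans)
    cds <- ex
    cds$type <- "CDS"
    cds$Parent <- paste0(ex$gene_id, ".t1")
    cds$ID <- paste0(ex$gene_id, ".cds", ex$exon_rank)
    # GFF3 phase: bases to skip before the first complete codon
    cds$phase <- NA_integer_
    for (g in unique(cds$Parent)) {
      i <- which(cds$Parent == g)
      i <- i[order(cds$exon_rank[i])]
      lens <- GenomicRanges::width(cds)[i]
      before <- cumsum(c(0L, head(lens, -1L)))
      cds$phase[i] <- as.integer((3L - before %% 3L) %% 3L)
    }
    grl <- list(gene, mrna, cds)
  }
  if (length(genome@ssr)) {
    rr <- genome@ssr; rr$type <- "repeat_region"
    rr$ID <- paste0("ssr", seq_along(rr))
    grl <- c(grl, list(rr))
  }
  if (length(genome@ambiguity)) {
    aa <- genome@ambiguity; aa$type <- "repeat_region"
    aa$ID <- paste0("amb", seq_along(aa))
    grl <- c(grl, list(aa))
  }
  if (length(grl)) {
    allCols <- unique(unlist(lapply(grl, function(g)
      names(S4Vectors::mcols(g)))))
    grl <- lapply(grl, function(g) {
      for (cc in setdiff(allCols, names(S4Vectors::mcols(g))))
        S4Vectors::mcols(g)[[cc]] <- NA
      g
    })
    gff <- do.call(c, grl)
  } else gff <- GenomicRanges::GRanges()
  rtracklayer::export(gff, gffPath, format = "gff3")
  invisible(c(fastaPath, gffPath))
}

#' Read CDS gene models from a GFF3 file
#'
#' Returns the CDS exons as a \code{GRanges} with \code{gene_id} and
#' \code{exon_rank} metadata columns, the layout \code{annotateRegion} and
#' \code{classifyCodingEffect} expect.
#'
#' @param path GFF3 file
#' @return a \code{GRanges} of CDS exons
#' @export
readGeneModels <- function(path) {
  lines <- readLines(path)
  feat <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in feat) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 9)
      stop("GFF3 ", path, ": fewer than 9 columns at line ", i,
           call. = FALSE)
    st <- suppressWarnings(as.integer(parts[4]))
    en <- suppressWarnings(as.integer(parts[5]))
    if (is.na(st) || is.na(en) || en < st || st < 1L)
      stop("GFF3 ", path, ": invalid coordinates (start ", parts[4],
           ", end ", parts[5], ") at line ", i, call. = FALSE)
  }
  gff <- rtracklayer::import(path, format = "gff3")
  cds <- gff[gff$type == "CDS"]
  if (!length(cds)) {
    gr <- GenomicRanges::GRanges()
    gr$gene_id <- character(0); gr$exon_rank <- integer(0)
    return(gr)
  }
  parent <- vapply(cds$Parent, function(p) p[1], character(1))
  gene_id <- sub("\\.t1$", "", parent)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(cds),
                                IRanges::ranges(cds),
                                strand = GenomicRanges::strand(cds))
  out$gene_id <- gene_id
  # recompute 5'->3' exon rank from coordinates and strand
  out$exon_rank <- NA_integer_
  for (g in unique(gene_id)) {
    i <- which(gene_id == g)
    ord <- order(GenomicRanges::start(out)[i])
    if (as.character(GenomicRanges::strand(out))[i[1]] == "-") ord <- rev(ord)
    out$exon_rank[i[ord]] <- seq_along(i)
  }
  out
}

#' GC fraction of each chromosome of a genome
#' @param genome a \code{\link{SyntheticGenome}}
#' @return named numeric vector of GC fractions
#' @export
genomeGc <- function(genome) {
  freq <- Biostrings::alphabetFrequency(genomeSeqs(genome), baseOnly = TRUE)
  (freq[, "C"] + freq[, "G"]) /
    rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
}
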