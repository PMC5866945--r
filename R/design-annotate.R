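#' Assign a genomic region class to positions
#'
#' Classifies each position as \code{coding} (inside a CDS exon),
#' \code{intronic} (inside a gene span but outside every exon) or
#' \code{intergenic} (everything else, including any untranslated exon
#' sequence, since the three-way split carries no UTR class).
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions
#' @param geneModels a \code{GRanges} of CDS exons with \code{gene_id}, as
#'   from \code{\link{geneModels}} or \code{\link{readGeneModels}}
#' @return character vector over \{intergenic, coding, intronic\}
#' @export
annotateRegion <- function(chrom, pos, geneModels) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  out <- rep("intergenic", length(q))
  if (!length(geneModels)) return(out)
  inCds <- IRanges::overlapsAny(q, geneModels, ignore.strand = TRUE)
  spans <- unlist(range(S4Vectors::split(geneModels, geneModels$gene_id)))
  inGene <- IRanges::overlapsAny(q, spans, ignore.strand = TRUE)
  out[inGene] <- "intronic"
  out[inCds] <- "coding"
  out
}

.startCodons <- c("ATG", "CTG", "TTG")
.stopCodons <- c("TAA", "TAG", "TGA")

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify the coding effect of a SNP
#'
#' Reconstructs the affected codon from the transcript's CDS (strand-aware)
#' and labels the substitution using the standard genetic code. Variants in
#' the first two bases of an intron are labelled \code{splice site donor},
#' in the last two \code{splice site acceptor}; splice labels take
#' precedence within that 2-bp dinucleotide. Labels in the first codon are
#' \code{synonymous start} when the alternate codon is still a recognised
#' start (ATG/CTG/TTG) and \code{start lost} otherwise; in the stop codon,
#' \code{synonymous stop} / \code{stop lost}; elsewhere \code{stop gained},
#' \code{synonymous coding} or \code{nonsynonymous coding}.
#'
#' @param chrom,pos,ref,alt scalar variant fields (SNP; single bases)
#' @param genome a \code{\link{SyntheticGenome}} (or \code{DNAStringSet}
#'   via \code{seqs})
#' @param geneModels CDS exon \code{GRanges} with \code{gene_id} and
#'   \code{exon_rank}
#' @return one effect label, or \code{NA} if the position is in no gene or
#'   beyond the 2-bp splice dinucleotide
#' @export
classifyCodingEffect <- function(chrom, pos, ref, alt, genome, geneModels) {
  seqs <- if (methods::is(genome, "SyntheticGenome")) genomeSeqs(genome)
          else genome
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit <- IRanges::overlapsAny(geneModels, q, ignore.strand = TRUE)
  if (any(hit)) {
    gid <- geneModels$gene_id[which(hit)[1]]
  } else {
    spans <- unlist(range(S4Vectors::split(geneModels,
                                           geneModels$gene_id)))
    inGene <- IRanges::overlapsAny(spans, q, ignore.strand = TRUE)
    if (!any(inGene)) return(NA_character_)
    gid <- names(spans)[which(inGene)[1]]
    return(.spliceLabel(chrom, pos,
                        geneModels[geneModels$gene_id == gid]))
  }
  ex <- geneModels[geneModels$gene_id == gid]
  strand <- as.character(GenomicRanges::strand(ex))[1]
  ex <- ex[order(ex$exon_rank)]
  # CDS sequence in transcription order
  pieces <- lapply(seq_along(ex), function(i) {
    sub <- Biostrings::subseq(seqs[[as.character(
      GenomicRanges::seqnames(ex))[i]]],
      GenomicRanges::start(ex)[i], GenomicRanges::end(ex)[i])
    s <- strsplit(as.character(sub), "")[[1]]
    if (strand == "-") .revComp(s) else s
  })
  cds <- unlist(pieces)
  if (length(cds) %% 3L != 0L)
    stop("frame inconsistency: CDS length of ", gid,
         " is not a multiple of 3", call. = FALSE)
  # CDS coordinate of pos
  lens <- lengths(pieces)
  exIdx <- which(hit)[1]
  rank <- geneModels$exon_rank[exIdx]
  off <- if (strand == "+")
    pos - GenomicRanges::start(geneModels)[exIdx] + 1L
  else
    GenomicRanges::end(geneModels)[exIdx] - pos + 1L
  cdsPos <- sum(head(lens, rank - 1L)) + off
  refT <- if (strand == "-") .complement[[ref]] else ref
  altT <- if (strand == "-") .complement[[alt]] else alt
  if (!identical(cds[cdsPos], refT))
    stop("reference allele does not match the genome at ", chrom, ":", pos,
         call. = FALSE)
  ci <- (cdsPos - 1L) %/% 3L + 1L
  codon <- cds[(3L * ci - 2L):(3L * ci)]
  altCodon <- codon
  altCodon[cdsPos - 3L * (ci - 1L)] <- altT
  classifyCodonChange(paste(codon, collapse = ""),
                      paste(altCodon, collapse = ""),
                      codonIndex = ci, nCodons = length(cds) / 3L)
}

#' Label a codon substitution
#'
#' @param refCodon,altCodon three-base codons (transcript strand)
#' @param codonIndex 1-based codon position in the CDS
#' @param nCodons total codons in the CDS (stop codon included)
#' @return effect label
#' @export
classifyCodonChange <- function(refCodon, altCodon, codonIndex, nCodons) {
  gc <- Biostrings::GENETIC_CODE
  if (codonIndex == 1L && refCodon %in% .startCodons) {
    if (altCodon %in% .startCodons) return("synonymous start")
    return("start lost")
  }
  if (refCodon %in% .stopCodons) {
    if (altCodon %in% .stopCodons) return("synonymous stop")
    return("stop lost")
  }
  if (altCodon %in% .stopCodons) return("stop gained")
  if (identical(gc[[refCodon]], gc[[altCodon]])) return("synonymous coding")
  "nonsynonymous coding"
}

# splice label for an intronic position, or NA when deeper than 2 bp
.spliceLabel <- function(chrom, pos, exons) {
  strand <- as.character(GenomicRanges::strand(exons))[1]
  exons <- exons[order(GenomicRanges::start(exons))]
  if (length(exons) < 2L) return(NA_character_)
  for (i in seq_len(length(exons) - 1L)) {
    intStart <- GenomicRanges::end(exons)[i] + 1L
    intEnd <- GenomicRanges::start(exons)[i + 1L] - 1L
    if (pos < intStart || pos > intEnd) next
    atLeft <- pos - intStart < 2L
    atRight <- intEnd - pos < 2L
    if (!atLeft && !atRight) return(NA_character_)
    if (strand == "+") {
      return(if (atLeft) "splice site donor" else "splice site acceptor")
    }
    return(if (atRight) "splice site donor" else "splice site acceptor")
  }
  NA_character_
}
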