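#' Default thresholds for the probe-design filters
#'
#' All comparisons are inclusive on the passing side: MAF >= 0.05,
#' 0.40 <= GC <= 0.70, QUAL >= 30, flank 35 bp each side of the SNP.
#'
#' @return named list of thresholds
#' @export
designConfig <- function() {
  list(flank = 35L, maf_min = 0.05, gc_min = 0.40, gc_max = 0.70,
       qual_min = 30, ssr_thresholds = defaultSsrThresholds())
}

.filterOrder <- c("edge", "isolated", "ssr", "indel", "biallelic",
                  "maf", "gc", "ambiguity", "qual")

#' Construct a DesignReport from counts
#'
#' @param input variants entering the pipeline
#' @param removed named integer vector of per-filter removals
#' @param survivors variants passing all filters
#' @param regionCounts,effectCounts named survivor breakdowns (optional)
#' @return a \code{\link{DesignReport}}
#' @export
designReport <- function(input, removed = integer(0),
                         survivors = input - sum(removed),
                         regionCounts = integer(0),
                         effectCounts = integer(0)) {
  new("DesignReport", input = as.integer(input),
      removed = setNames(as.integer(removed), names(removed)),
      survivors = as.integer(survivors),
      regionCounts = setNames(as.integer(regionCounts),
                              names(regionCounts)),
      effectCounts = setNames(as.integer(effectCounts),
                              names(effectCounts)))
}

#' Run the probe-selection filters over a variant panel
#'
#' Applies, in order: flank-coverage (edge) check, the 35-bp flanking-SNP
#' isolation rule, then the seven quality filters -- no SSR in the 71-mer
#' window, no indel in the window, biallelic only, MAF >= 0.05,
#' 40--70\% GC, no ambiguity character in the window, and site quality
#' >= 30. Candidates are the SNP records of the panel; indel records serve
#' only as context for the indel filter. Each removed SNP is charged to the
#' first filter it fails; every per-filter flag is also reported so the
#' surviving set can be shown to be order-invariant. Survivors are
#' annotated with genomic region and, where applicable, coding effect.
#'
#' @param variants panel data.frame with columns chrom, pos, id, ref, alt
#'   (comma-separated if multiple), qual, ac (alt allele counts,
#'   comma-separated), an (total called alleles), type ("snp"/"indel")
#' @param genome a \code{\link{SyntheticGenome}} or \code{DNAStringSet}
#' @param geneModels CDS exon \code{GRanges} (optional; region/effect
#'   columns are NA without it)
#' @param config thresholds, as \code{\link{designConfig}}
#' @return list with \code{candidates} (all SNP candidates with windows,
#'   flags, removal reason, region, effect), \code{survivors} (passing
#'   subset) and \code{report} (a \code{\link{DesignReport}})
#' @export
applyDesignFilters <- function(variants, genome, geneModels = NULL,
                               config = designConfig()) {
  seqs <- if (methods::is(genome, "SyntheticGenome")) genomeSeqs(genome)
          else genome
  flank <- config$flank
  snps <- variants[variants$type == "snp", , drop = FALSE]
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  indels <- variants[variants$type == "indel", , drop = FALSE]
  n <- nrow(snps)
  if (!n) {
    rep0 <- designReport(0L, setNames(integer(length(.filterOrder)),
                                      .filterOrder))
    return(list(candidates = snps, survivors = snps, report = rep0))
  }
  chromLen <- setNames(Biostrings::width(seqs), names(seqs))
  stopIfNot(all(snps$chrom %in% names(chromLen)),
            "variant on a chromosome absent from the genome")

  okEdge <- snps$pos - flank >= 1L & snps$pos + flank <= chromLen[snps$chrom]

  windows <- rep(NA_character_, n)
  for (ch in unique(snps$chrom)) {
    i <- which(snps$chrom == ch & okEdge)
    if (!length(i)) next
    v <- Biostrings::Views(seqs[[ch]],
                           start = snps$pos[i] - flank,
                           end = snps$pos[i] + flank)
    windows[i] <- as.character(v)
  }
  centre <- substr(windows, flank + 1L, flank + 1L)
  bad <- okEdge & centre != snps$ref
  if (any(bad))
    stop("reference allele mismatch at ",
         paste(snps$chrom[bad][1], snps$pos[bad][1], sep = ":"),
         call. = FALSE)

  okIso <- isolatedFlags(snps, flank)

  # genome-wide SSR tracts, overlapped against windows
  okSsr <- rep(TRUE, n)
  for (ch in unique(snps$chrom)) {
    tr <- detectSsr(seqs[[ch]], config$ssr_thresholds)
    i <- which(snps$chrom == ch)
    if (!nrow(tr) || !length(i)) next
    ir <- IRanges::IRanges(snps$pos[i] - flank, snps$pos[i] + flank)
    hit <- IRanges::overlapsAny(ir, IRanges::IRanges(tr$start, tr$end))
    okSsr[i] <- !hit
  }

  okIndel <- rep(TRUE, n)
  if (nrow(indels)) {
    for (ch in unique(snps$chrom)) {
      i <- which(snps$chrom == ch)
      j <- which(indels$chrom == ch)
      if (!length(i) || !length(j)) next
      reflen <- nchar(indels$ref[j])
      ir <- IRanges::IRanges(snps$pos[i] - flank, snps$pos[i] + flank)
      jr <- IRanges::IRanges(indels$pos[j], indels$pos[j] + reflen - 1L)
      okIndel[i] <- !IRanges::overlapsAny(ir, jr)
    }
  }

  nAlt <- lengths(strsplit(snps$alt, ","))
  okBi <- nAlt == 1L

  acList <- lapply(strsplit(snps$ac, ","), as.numeric)
  maf <- mapply(function(ac, an) {
    refCount <- an - sum(ac)
    computeMaf(c(refCount, ac))
  }, acList, snps$an)
  okMaf <- maf >= config$maf_min

  gc <- ifelse(is.na(windows), NA_real_,
               vapply(windows, function(w)
                 if (is.na(w)) NA_real_ else computeGcFraction(w),
                 numeric(1), USE.NAMES = FALSE))
  okGc <- !is.na(gc) & gc >= config$gc_min & gc <= config$gc_max

  okAmb <- !is.na(windows) &
    !vapply(windows, function(w) if (is.na(w)) TRUE else hasAmbiguity(w),
            logical(1), USE.NAMES = FALSE)

  okQual <- snps$qual >= config$qual_min

  flags <- cbind(edge = okEdge, isolated = okIso, ssr = okSsr,
                 indel = okIndel, biallelic = okBi, maf = okMaf,
                 gc = okGc, ambiguity = okAmb, qual = okQual)
  firstFail <- apply(flags, 1, function(f)
    if (all(f)) NA_character_ else .filterOrder[which(!f)[1]])

  cand <- snps
  cand$window <- windows
  cand$gc <- gc
  cand$maf <- maf
  for (f in .filterOrder) cand[[paste0("pass_", f)]] <- flags[, f]
  cand$removed_by <- firstFail
  cand$pass <- is.na(firstFail)

  cand$region <- NA_character_
  cand$effect <- NA_character_
  if (!is.null(geneModels)) {
    cand$region <- annotateRegion(cand$chrom, cand$pos, geneModels)
    doEff <- which(cand$region != "intergenic" & okBi)
    for (i in doEff) {
      eff <- tryCatch(
        classifyCodingEffect(cand$chrom[i], cand$pos[i], cand$ref[i],
                             cand$alt[i], genome, geneModels),
        error = function(e) NA_character_)
      cand$effect[i] <- eff
    }
  }

  surv <- cand[cand$pass, , drop = FALSE]
  removed <- vapply(.filterOrder, function(f)
    sum(firstFail == f, na.rm = TRUE), integer(1))
  regionCounts <- if (!is.null(geneModels))
    table(factor(surv$region,
                 levels = c("intergenic", "coding", "intronic")))
  else integer(0)
  effectCounts <- if (!is.null(geneModels) && any(!is.na(surv$effect)))
    table(surv$effect[!is.na(surv$effect)]) else integer(0)
  report <- designReport(n, removed, nrow(surv),
                         regionCounts = unclass(regionCounts),
                         effectCounts = unclass(effectCounts))
  list(candidates = cand, survivors = surv, report = report)
}
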