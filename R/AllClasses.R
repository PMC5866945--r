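#' @import methods
#' @importFrom stats pchisq rbinom rnorm runif rbeta rgamma quantile var coef lm sd setNames
#' @importFrom utils head read.delim write.table
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Synthetic reference genome with gene models and SSR tracts
#'
#' Container for a simulated multi-chromosome genome: chromosome sequences,
#' CDS exon models (one range per exon, grouped by \code{gene_id}), planted
#' simple-sequence-repeat (SSR) tracts, and any planted ambiguity (N) tracts.
#' Produced by \code{\link{makeReference}}; consumed by
#' \code{\link{simulatePanel}} and \code{\link{applyDesignFilters}}.
#'
#' @slot seqs a \code{DNAStringSet}, one entry per chromosome.
#' @slot genes a \code{GRanges} of CDS exons with metadata columns
#'   \code{gene_id} (character) and \code{exon_rank} (integer, 5' to 3' in
#'   transcription order); strand is + or -.
#' @slot ssr a \code{GRanges} of planted SSR tracts with metadata column
#'   \code{motif}.
#' @slot ambiguity a \code{GRanges} of planted N tracts (may be empty).
#' @export
setClass("SyntheticGenome",
  representation(seqs = "DNAStringSet", genes = "GRanges",
                 ssr = "GRanges", ambiguity = "GRanges"))

setValidity("SyntheticGenome", function(object) {
  msgs <- character()
  freq <- Biostrings::alphabetFrequency(object@seqs, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- setdiff(colnames(freq)[colSums(freq) > 0], allowed)
  if (length(bad))
    msgs <- c(msgs, paste0("disallowed characters in sequences: ",
                           paste(bad, collapse = ",")))
  lens <- setNames(Biostrings::width(object@seqs), names(object@seqs))
  for (gr in list(object@genes, object@ssr, object@ambiguity)) {
    if (!length(gr)) next
    chr <- as.character(GenomicRanges::seqnames(gr))
    if (!all(chr %in% names(lens))) {
      msgs <- c(msgs, "range on unknown chromosome")
    } else if (any(GenomicRanges::start(gr) < 1L |
                   GenomicRanges::end(gr) > lens[chr])) {
      msgs <- c(msgs, "range outside chromosome bounds")
    }
  }
  if (length(object@genes)) {
    byGene <- split(object@genes, object@genes$gene_id)
    ov <- vapply(byGene, function(g)
      any(IRanges::countOverlaps(IRanges::ranges(g)) > 1L), logical(1))
    if (any(ov)) msgs <- c(msgs, "overlapping exons within a gene")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SyntheticGenome chromosome sequences as a \code{DNAStringSet}
#' @param x,object a \code{SyntheticGenome}
#' @export
genomeSeqs <- function(x) x@seqs

#' @describeIn SyntheticGenome CDS exon models as a \code{GRanges}
#' @export
geneModels <- function(x) x@genes

#' @describeIn SyntheticGenome planted SSR tracts as a \code{GRanges}
#' @export
ssrTracts <- function(x) x@ssr

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome:", length(object@seqs), "chromosomes,",
      sum(Biostrings::width(object@seqs)), "bp total\n")
  cat("  genes:", length(unique(object@genes$gene_id)),
      " (", length(object@genes), "CDS exons )\n")
  cat("  SSR tracts:", length(object@ssr),
      " ambiguity tracts:", length(object@ambiguity), "\n")
})

#' Genetic map of ordered markers with Kosambi positions
#'
#' Ordered marker lists per linkage group with cumulative Kosambi cM
#' positions. Built by \code{\link{buildGeneticMap}}; summarised by
#' \code{\link{mapSummary}}.
#'
#' @slot table a data.frame with columns \code{group}, \code{marker},
#'   \code{pos_cm} (non-decreasing within group).
#' @export
setClass("GeneticMap", representation(table = "data.frame"))

setValidity("GeneticMap", function(object) {
  tb <- object@table
  need <- c("group", "marker", "pos_cm")
  if (!all(need %in% names(tb)))
    return("table must have columns group, marker, pos_cm")
  if (nrow(tb) && anyDuplicated(tb$marker))
    return("duplicate marker ids")
  bad <- vapply(split(tb$pos_cm, tb$group),
                function(p) any(diff(p) < -1e-9), logical(1))
  if (any(bad)) return("positions must be non-decreasing within a group")
  TRUE
})

#' @describeIn GeneticMap the map as a data.frame (group, marker, pos_cm)
#' @param x,object a \code{GeneticMap}
#' @export
mapTable <- function(x) x@table

#' @describeIn GeneticMap number of mapped markers
#' @export
nMarkers <- function(x) nrow(x@table)

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  cat("GeneticMap:", nrow(tb), "markers in",
      length(unique(tb$group)), "linkage groups\n")
  if (nrow(tb)) {
    len <- vapply(split(tb$pos_cm, tb$group), max, numeric(1))
    cat("  total length:", round(sum(len), 2), "cM\n")
  }
})

#' Probe-design attrition report
#'
#' Records how many panel variants entered the design pipeline, how many
#' each sequential filter removed, how many survived, and the
#' genomic-region / coding-effect breakdown of survivors.
#'
#' @slot input number of variants entering the pipeline.
#' @slot removed named integer vector of per-filter removal counts, in
#'   application order (edge, isolated, ssr, indel, biallelic, maf, gc,
#'   ambiguity, qual).
#' @slot survivors number of variants passing every filter.
#' @slot regionCounts named counts over intergenic/coding/intronic.
#' @slot effectCounts named counts over coding-effect labels.
#' @export
setClass("DesignReport",
  representation(input = "integer", removed = "integer",
                 survivors = "integer", regionCounts = "integer",
                 effectCounts = "integer"))

setValidity("DesignReport", function(object) {
  if (object@input != object@survivors + sum(object@removed))
    return("input count must equal survivors + sum of removals")
  TRUE
})

setMethod("show", "DesignReport", function(object) {
  cat("DesignReport:", object@input, "variants in,",
      object@survivors, "survivors\n")
  rm <- object@removed[object@removed > 0]
  if (length(rm))
    cat("  removed:", paste(names(rm), rm, sep = "=", collapse = ", "), "\n")
  if (length(object@regionCounts)) {
    pc <- regionPercentages(object)
    cat("  regions:", paste(names(pc), paste0(pc, "%"),
                            sep = " ", collapse = ", "), "\n")
  }
})

#' @describeIn DesignReport per-region percentages of survivors (half-up,
#'   2 decimals)
#' @param object a \code{DesignReport}
#' @export
regionPercentages <- function(object) {
  ct <- object@regionCounts
  roundHalfUp(100 * ct / sum(ct), 2)
}
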