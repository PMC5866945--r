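#' Default Axiom-style SNP QC thresholds (diploid defaults)
#'
#' Call-rate cutoff 97\%, FLD cutoff 3.6, HetSO cutoff -0.1, HetSO-OTV
#' cutoff -0.3, HomRO cutoffs 0.6 (one cluster) and 0.3 (two or three
#' clusters). The homozygote-pair FLD gate (6.5), minimum minor-homozygote
#' count (2), cluster-variance ceilings (0.8) and the minimum OTV-cluster
#' fraction (5\%) are not printed platform defaults and are exposed here
#' for configuration.
#'
#' @return named list of thresholds
#' @export
qcThresholds <- function() {
  list(cr = 0.97, fld = 3.6, het_so = -0.1, het_so_otv = -0.3,
       hom_ro_1 = 0.6, hom_ro_2 = 0.3, hom_fld = 6.5, minor_hom = 2L,
       var_x = 0.8, var_y = 0.8, otv_min_frac = 0.05)
}

#' The closed vocabulary of SNP QC categories
#' @return character vector of category labels
#' @export
snpCategories <- function() {
  c("PolyHighResolution", "MonoHighResolution", "NoMinorHom",
    "HomHomResolution", "OTV", "CallRateBelowThreshold",
    "AAvarianceX", "AAvarianceY", "BBvarianceX", "BBvarianceY", "Other")
}

#' Filter samples on DQC then call rate
#'
#' Samples with DQC < \code{dqcMin} are removed first; among the DQC
#' passers, samples with call rate < \code{crMin} are then removed.
#' Equality retains (the platform thresholds are strict less-than).
#'
#' @param samples data.frame with columns sample, dqc, call_rate
#' @param dqcMin DQC threshold (default 0.82)
#' @param crMin call-rate threshold (default 0.97)
#' @return list: retained (data.frame), removed_dqc, removed_call_rate
#'   (character vectors of sample ids, in removal order)
#' @export
filterSamples <- function(samples, dqcMin = 0.82, crMin = 0.97) {
  badDqc <- samples$dqc < dqcMin
  removedDqc <- samples$sample[badDqc]
  rest <- samples[!badDqc, , drop = FALSE]
  badCr <- rest$call_rate < crMin
  removedCr <- rest$sample[badCr]
  list(retained = rest[!badCr, , drop = FALSE],
       removed_dqc = removedDqc, removed_call_rate = removedCr)
}

.clusterRow <- function(clusters, label) {
  i <- which(clusters$cluster == label)
  if (!length(i)) NULL else clusters[i[1], , drop = FALSE]
}

#' Fisher's linear discriminant of the het cluster against the homozygotes
#'
#' FLD = min over present homozygote clusters of |mean_x(het) -
#' mean_x(hom)| / sigma_pooled, where sigma_pooled is the square root of
#' the mean within-cluster contrast variance over the present genotype
#' clusters. Scale-invariant by construction.
#'
#' @param clusters per-cluster summary rows for one SNP (columns cluster,
#'   n, mean_x, sd_x, mean_y, sd_y; clusters AA/AB/BB)
#' @return FLD value
#' @export
computeFld <- function(clusters) {
  het <- .clusterRow(clusters, "AB")
  stopIfNot(!is.null(het), "no het cluster: FLD not applicable")
  homs <- clusters[clusters$cluster %in% c("AA", "BB"), , drop = FALSE]
  stopIfNot(nrow(homs) >= 1, "need at least one homozygote cluster")
  present <- clusters[clusters$cluster %in% c("AA", "AB", "BB"), ,
                      drop = FALSE]
  pooled <- sqrt(mean(present$sd_x^2))
  stopIfNot(pooled > 0, "zero pooled SD")
  min(abs(het$mean_x - homs$mean_x)) / pooled
}

#' FLD between the two homozygote clusters
#'
#' Used to gate the HomHomResolution category when no heterozygote cluster
#' is present: |mean_x(AA) - mean_x(BB)| / sigma_pooled over the two
#' homozygote clusters.
#'
#' @inheritParams computeFld
#' @return homozygote-pair FLD
#' @export
computeHomFld <- function(clusters) {
  aa <- .clusterRow(clusters, "AA"); bb <- .clusterRow(clusters, "BB")
  stopIfNot(!is.null(aa) && !is.null(bb),
            "need both homozygote clusters")
  pooled <- sqrt(mean(c(aa$sd_x^2, bb$sd_x^2)))
  stopIfNot(pooled > 0, "zero pooled SD")
  abs(aa$mean_x - bb$mean_x) / pooled
}

#' Heterozygote size offset (HetSO)
#'
#' Vertical (size-axis) offset of the het cluster mean from the chord
#' joining the two homozygote cluster means in the (contrast, size) plane;
#' 0 when the three means are collinear, negative when the het cluster
#' sits below the chord.
#'
#' @inheritParams computeFld
#' @return HetSO value
#' @export
computeHetSo <- function(clusters) {
  aa <- .clusterRow(clusters, "AA"); bb <- .clusterRow(clusters, "BB")
  het <- .clusterRow(clusters, "AB")
  stopIfNot(!is.null(aa) && !is.null(bb) && !is.null(het),
            "HetSO needs all three genotype clusters")
  .chordOffset(aa, bb, het$mean_x, het$mean_y)
}

.chordOffset <- function(aa, bb, x, y) {
  dx <- bb$mean_x - aa$mean_x
  stopIfNot(abs(dx) > 0, "degenerate chord: homozygote contrasts equal")
  yChord <- aa$mean_y + (bb$mean_y - aa$mean_y) * (x - aa$mean_x) / dx
  y - yChord
}

#' Homozygote ratio offset (HomRO)
#'
#' Signed minimum over the homozygote clusters of the contrast-axis
#' distance from zero, counted positive when the cluster sits on its
#' expected side (AA positive contrast, BB negative).
#'
#' @inheritParams computeFld
#' @return HomRO value
#' @export
computeHomRo <- function(clusters) {
  vals <- numeric(0)
  aa <- .clusterRow(clusters, "AA")
  if (!is.null(aa)) vals <- c(vals, aa$mean_x)
  bb <- .clusterRow(clusters, "BB")
  if (!is.null(bb)) vals <- c(vals, -bb$mean_x)
  stopIfNot(length(vals) >= 1, "need at least one homozygote cluster")
  min(vals)
}

#' Per-SNP QC metrics from calls and cluster summaries
#'
#' Computes call rate, number of genotype clusters, FLD, homozygote-pair
#' FLD, HetSO, HomRO, per-cluster variances, minor-homozygote count and
#' the OTV flag (a low-size extra cluster holding at least
#' \code{otv_min_frac} of samples whose size offset from the
#' homozygote chord is below the HetSO-OTV cutoff).
#'
#' @param calls call vector over \{A,H,B,U\} for one SNP
#' @param clusters cluster-summary rows for that SNP
#' @param thresholds as \code{\link{qcThresholds}} (for the OTV rule)
#' @return one-row data.frame of metrics
#' @export
computeSnpQcMetrics <- function(calls, clusters,
                                thresholds = qcThresholds()) {
  callRate <- mean(calls != "U")
  counts <- c(AA = sum(calls == "A"), AB = sum(calls == "H"),
              BB = sum(calls == "B"))
  present <- clusters$cluster[clusters$cluster %in% c("AA", "AB", "BB") &
                              clusters$n > 0]
  nClusters <- length(present)
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  fld <- safe(computeFld(clusters))
  homFld <- safe(computeHomFld(clusters))
  hetSo <- safe(computeHetSo(clusters))
  homRo <- safe(computeHomRo(clusters))
  getVar <- function(cl, col) {
    r <- .clusterRow(clusters, cl)
    if (is.null(r)) NA_real_ else r[[col]]^2
  }
  minorHom <- if (all(c("AA", "BB") %in% present))
    min(counts["AA"], counts["BB"]) else 0L
  otv <- .clusterRow(clusters, "OTV")
  otvFrac <- if (is.null(otv)) 0 else otv$n / sum(clusters$n)
  hetSoOtv <- NA_real_
  if (!is.null(otv)) {
    aa <- .clusterRow(clusters, "AA"); bb <- .clusterRow(clusters, "BB")
    hetSoOtv <- if (!is.null(aa) && !is.null(bb) &&
                    abs(bb$mean_x - aa$mean_x) > 0)
      .chordOffset(aa, bb, otv$mean_x, otv$mean_y)
    else otv$mean_y - mean(clusters$mean_y[clusters$cluster != "OTV"])
  }
  otvFlag <- otvFrac >= thresholds$otv_min_frac &&
    !is.na(hetSoOtv) && hetSoOtv < thresholds$het_so_otv
  data.frame(call_rate = callRate, n_clusters = nClusters,
             fld = fld, hom_fld = homFld, het_so = hetSo, hom_ro = homRo,
             vx_AA = getVar("AA", "sd_x"), vy_AA = getVar("AA", "sd_y"),
             vx_BB = getVar("BB", "sd_x"), vy_BB = getVar("BB", "sd_y"),
             minor_hom = as.integer(minorHom),
             has_het = "AB" %in% present,
             otv_frac = otvFrac, het_so_otv = hetSoOtv,
             otv_flag = otvFlag)
}

#' Assign the Axiom quality category of one SNP
#'
#' Fixed-order decision tree: (1) call rate below cutoff; (2) flagged OTV;
#' (3) one cluster passing HomRO >= 0.6 and variance checks is
#' MonoHighResolution; (4) het + one homozygote cluster passing FLD and
#' HomRO >= 0.3 is NoMinorHom; (5) two homozygote clusters passing the
#' homozygote-pair FLD gate is HomHomResolution; (6) three clusters
#' passing FLD, HetSO, HomRO >= 0.3 and the minor-homozygote minimum is
#' PolyHighResolution; (7) an AA/BB cluster variance above its ceiling
#' yields the matching variance class; (8) everything else is Other.
#'
#' @param metrics one-row metrics data.frame from
#'   \code{\link{computeSnpQcMetrics}}
#' @param thresholds as \code{\link{qcThresholds}}
#' @return one category label from \code{\link{snpCategories}}
#' @export
classifySnp <- function(metrics, thresholds = qcThresholds()) {
  m <- as.list(metrics)
  th <- thresholds
  stopIfNot(m$n_clusters %in% 0:3, "inconsistent cluster count")
  if (m$n_clusters >= 3 && (is.na(m$fld) || is.na(m$het_so)))
    stop("inconsistent metrics: 3 clusters but FLD/HetSO missing",
         call. = FALSE)
  varFail <- .varianceClass(m, th)
  if (m$call_rate < th$cr) return("CallRateBelowThreshold")
  if (isTRUE(m$otv_flag) && !is.na(m$het_so_otv) &&
      m$het_so_otv < th$het_so_otv) return("OTV")
  if (m$n_clusters == 1L) {
    if (!is.na(varFail)) return(varFail)
    if (!m$has_het && !is.na(m$hom_ro) && m$hom_ro >= th$hom_ro_1)
      return("MonoHighResolution")
    return("Other")
  }
  if (m$n_clusters == 2L && m$has_het) {
    if (!is.na(varFail)) return(varFail)
    if (!is.na(m$fld) && m$fld >= th$fld &&
        !is.na(m$hom_ro) && m$hom_ro >= th$hom_ro_2)
      return("NoMinorHom")
    return("Other")
  }
  if (m$n_clusters == 2L) {  # two homozygote clusters, no het
    if (!is.na(varFail)) return(varFail)
    if (!is.na(m$hom_fld) && m$hom_fld >= th$hom_fld &&
        !is.na(m$hom_ro) && m$hom_ro >= th$hom_ro_2)
      return("HomHomResolution")
    return("Other")
  }
  if (m$n_clusters == 3L) {
    if (!is.na(varFail)) return(varFail)
    if (m$fld >= th$fld && m$het_so >= th$het_so &&
        !is.na(m$hom_ro) && m$hom_ro >= th$hom_ro_2 &&
        m$minor_hom >= th$minor_hom)
      return("PolyHighResolution")
    return("Other")
  }
  "Other"
}

.varianceClass <- function(m, th) {
  if (!is.na(m$vx_AA) && m$vx_AA > th$var_x) return("AAvarianceX")
  if (!is.na(m$vy_AA) && m$vy_AA > th$var_y) return("AAvarianceY")
  if (!is.na(m$vx_BB) && m$vx_BB > th$var_x) return("BBvarianceX")
  if (!is.na(m$vy_BB) && m$vy_BB > th$var_y) return("BBvarianceY")
  NA_character_
}

#' Classify every SNP of a call matrix from its cluster summaries
#'
#' @param calls call matrix over \{A,H,B,U\} (markers x samples)
#' @param clusters cluster-summary data.frame over all SNPs
#' @param thresholds as \code{\link{qcThresholds}}
#' @return data.frame: snp, category, plus all per-SNP metrics
#' @export
classifySnps <- function(calls, clusters, thresholds = qcThresholds()) {
  ids <- rownames(calls)
  rows <- lapply(ids, function(id) {
    met <- computeSnpQcMetrics(calls[id, ],
                               clusters[clusters$snp == id, , drop = FALSE],
                               thresholds)
    cbind(data.frame(snp = id,
                     category = classifySnp(met, thresholds)), met)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Category counts and percentages
#'
#' @param categories character vector of per-SNP categories, or a named
#'   count vector via \code{qcSummaryCounts}
#' @return data.frame: category, n, pct (half-up, 2 decimals), sorted by
#'   descending count; attribute \code{polymorphic_usable} holds the
#'   PolyHighResolution count
#' @export
qcSummary <- function(categories) {
  ct <- table(factor(categories, levels = snpCategories()))
  qcSummaryCounts(unclass(ct))
}

#' @rdname qcSummary
#' @param counts named integer vector of per-category counts
#' @param total denominator for percentages (default sum of counts)
#' @export
qcSummaryCounts <- function(counts, total = sum(counts)) {
  df <- data.frame(category = names(counts), n = as.integer(counts))
  df$pct <- if (total > 0) roundHalfUp(100 * df$n / total, 2) else 0
  df <- df[order(-df$n, df$category), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "polymorphic_usable") <-
    sum(df$n[df$category == "PolyHighResolution"])
  df
}
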