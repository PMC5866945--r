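.callOut <- c(A = "AA", H = "AB", B = "BB", U = "NC")
.callIn <- c(AA = "A", AB = "H", BB = "B", NC = "U")

#' Read and write genotype-call matrices
#'
#' Tab-separated, rows = markers, columns = samples, calls in
#' \{AA, AB, BB, NC\} on disk (internal codes A/H/B/U). Malformed calls
#' are reported with their line number.
#'
#' @param calls internal call matrix
#' @param path file path
#' @return \code{readGenotypes}: internal call matrix
#' @export
writeGenotypes <- function(calls, path) {
  out <- matrix(.callOut[calls], nrow = nrow(calls),
                dimnames = dimnames(calls))
  df <- data.frame(marker = rownames(out), out, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypes
#' @export
readGenotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"marker" %in% names(df))
    stop("genotype file ", path, ": missing 'marker' column (line 1)",
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(matrix(!(m %in% names(.callIn)), nrow = nrow(m)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("genotype file ", path, ": invalid call '",
         m[bad[1, 1], bad[1, 2]], "' at line ", bad[1, 1] + 1L,
         call. = FALSE)
  out <- matrix(.callIn[m], nrow = nrow(m),
                dimnames = list(df$marker, colnames(m)))
  out
}

#' Read and write long phenotype tables
#'
#' Tab-separated with columns sample, trait, location, year, environment,
#' value.
#'
#' @param phenotypes long phenotype data.frame
#' @param path file path
#' @return \code{readPhenotypes}: the data.frame
#' @export
writePhenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("sample", "trait", "location", "year", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), " (line 1)", call. = FALSE)
  if (!"environment" %in% names(df))
    df$environment <- paste(df$location, df$year, sep = "_")
  df
}

#' Read and write genetic-map tables
#'
#' Tab-separated with columns group, marker, pos_cm.
#'
#' @param map a \code{\link{GeneticMap}} or its table
#' @param path file path
#' @return \code{readMap}: a \code{\link{GeneticMap}}
#' @export
writeMap <- function(map, path) {
  tb <- if (methods::is(map, "GeneticMap")) mapTable(map) else map
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMap
#' @export
readMap <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  miss <- setdiff(c("group", "marker", "pos_cm"), names(df))
  if (length(miss))
    stop("map file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), " (line 1)", call. = FALSE)
  new("GeneticMap", table = df)
}

#' Read and write cluster-summary tables
#'
#' Tab-separated with columns snp, cluster, n, mean_x, sd_x, mean_y, sd_y.
#'
#' @param clusters cluster-summary data.frame
#' @param path file path
#' @return \code{readClusters}: the data.frame
#' @export
writeClusters <- function(clusters, path) {
  write.table(clusters, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusters
#' @export
readClusters <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("snp", "cluster", "n", "mean_x", "sd_x", "mean_y", "sd_y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cluster file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), " (line 1)", call. = FALSE)
  df
}

#' Write a variant panel as VCF v4.2
#'
#' Emits an uncompressed VCF with AC, AN, TYPE and (for planted
#' filter-killer variants) PLANTED INFO fields.
#'
#' @param panel panel data.frame from \code{\link{simulatePanel}}
#' @param path file path
#' @return invisibly, the path
#' @export
writePanelVcf <- function(panel, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total called alleles\">",
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"snp or indel\">",
           "##INFO=<ID=PLANTED,Number=1,Type=String,Description=\"Planted filter-killer label\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  info <- paste0("AC=", panel$ac, ";AN=", panel$an, ";TYPE=", panel$type,
                 ifelse(is.na(panel$planted), "",
                        paste0(";PLANTED=", panel$planted)))
  body <- paste(panel$chrom, panel$pos, panel$id, panel$ref, panel$alt,
                panel$qual, "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a variant panel from VCF
#'
#' Uses vcfR when available; the INFO fields written by
#' \code{\link{writePanelVcf}} are restored into panel columns.
#'
#' @param path VCF file path
#' @return panel data.frame (chrom, pos, id, ref, alt, qual, ac, an,
#'   type, planted)
#' @export
readPanelVcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    fix <- read.delim(text = body, header = FALSE,
                      colClasses = "character")[, 1:8]
    names(fix) <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                    "FILTER", "INFO")
  }
  getInfo <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info,
                              gregexpr(paste0("(^|;)", key, "="), info))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
             ref = fix$REF, alt = fix$ALT, qual = as.numeric(fix$QUAL),
             ac = getInfo(fix$INFO, "AC"),
             an = as.integer(getInfo(fix$INFO, "AN")),
             type = getInfo(fix$INFO, "TYPE"),
             planted = getInfo(fix$INFO, "PLANTED"))
}

#' Read and write per-sample QC tables
#'
#' Tab-separated with columns sample, dqc and, when available, call_rate.
#'
#' @param samples data.frame
#' @param path file path
#' @return \code{readSampleQc}: the data.frame
#' @export
writeSampleQc <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleQc
#' @export
readSampleQc <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  miss <- setdiff(c("sample", "dqc"), names(df))
  if (length(miss))
    stop("sample QC file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), " (line 1)", call. = FALSE)
  df
}
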