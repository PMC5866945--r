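#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; printed summary tables in this
#' package use conventional half-up rounding (e.g. 25.885 -> 25.89).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# internal: split "chrom:pos" style ids
.mkId <- function(chrom, pos) paste0(chrom, "_", pos)

# RIL-observed recombinant fraction for meiotic r (selfed RIL, F-infinity)
#' Convert meiotic recombination fraction to the selfed-RIL observed fraction
#'
#' In a population of fully inbred selfed RILs the observed fraction of
#' recombinant lines between two loci with meiotic recombination fraction
#' \code{r} is \code{R = 2r/(1+2r)}; \code{rilToMeiotic} inverts this.
#'
#' @param r meiotic recombination fraction in [0, 0.5)
#' @param R RIL-observed recombinant fraction
#' @param cap upper bound applied to the inverted meiotic fraction
#' @return the transformed fraction
#' @export
meioticToRil <- function(r) {
  stopIfNot(all(r >= 0 & r < 0.5), "meiotic r must lie in [0, 0.5)")
  2 * r / (1 + 2 * r)
}

#' @rdname meioticToRil
#' @export
rilToMeiotic <- function(R, cap = 0.4999) {
  stopIfNot(all(R >= 0 & R <= 1), "observed R must lie in [0, 1]")
  pmin(R / (2 * (1 - R)), cap)
}
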