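#' Generate a synthetic RPKM matrix with designated peak organs
#'
#' For each gene with a peak specification, the expected expression is
#' \code{amplitude} in the designated peak organs and
#' \code{baselineFraction * amplitude} elsewhere; genes without a
#' specification (or with amplitude 0) are all-zero rows, which
#' downstream analysis flags as pseudogenes. Gaussian noise of standard
#' deviation \code{noiseSd} is added and the matrix truncated at zero,
#' so the result is always non-negative. With \code{noiseSd = 0} the
#' matrix equals the expected values exactly, and each designated peak
#' organ carries the gene's maximal value.
#'
#' @param genes Character vector of gene identifiers.
#' @param organs Ordered organ labels (default [hmOrgans()]).
#' @param peakSpec Named list: per gene a list with \code{peaks}
#'   (organ labels) and \code{amplitude} (>= 0).
#' @param noiseSd Noise standard deviation (>= 0, default 0).
#' @param seed Integer seed.
#' @param baselineFraction Off-peak expression as a fraction of the
#'   amplitude (default 0.1).
#' @return Genes-by-organs numeric matrix.
#' @export
makeExpression <- function(genes, organs = hmOrgans(), peakSpec = list(),
                           noiseSd = 0, seed = 1,
                           baselineFraction = 0.1) {
  stopifnot(noiseSd >= 0, baselineFraction >= 0, baselineFraction < 1)
  for (g in names(peakSpec)) {
    sp <- peakSpec[[g]]
    bad <- setdiff(sp$peaks, organs)
    if (length(bad))
      stop("unknown organ(s) in peak spec for ", g, ": ",
           paste(bad, collapse = ", "))
    if (!is.null(sp$amplitude) && sp$amplitude < 0)
      stop("negative amplitude for ", g)
  }
  mat <- matrix(0, nrow = length(genes), ncol = length(organs),
                dimnames = list(genes, organs))
  for (g in genes) {
    sp <- peakSpec[[g]]
    if (is.null(sp) || is.null(sp$amplitude) || sp$amplitude == 0) next
    mat[g, ] <- baselineFraction * sp$amplitude
    mat[g, sp$peaks] <- sp$amplitude
  }
  if (noiseSd > 0) {
    mat <- withSeed(seed, mat + matrix(
      stats::rnorm(length(mat), sd = noiseSd), nrow = nrow(mat)))
    mat[mat < 0] <- 0
  }
  mat
}
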