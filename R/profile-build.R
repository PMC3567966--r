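#' Build a log-odds profile from an aligned domain block
#'
#' Converts an aligned block of domain sequences into a position-specific
#' log-odds profile in bits. Alignment columns with more than 50\% gap
#' characters are dropped; remaining gaps are treated as missing and do
#' not contribute to column totals. The per-position, per-residue score is
#' \deqn{s_i(a) = \log_2\frac{(c_i(a) + \kappa\, b(a)) / (n_i + \kappa)}{b(a)}}
#' where \eqn{c_i(a)} is the residue count in column \eqn{i}, \eqn{n_i}
#' the number of non-gap rows in that column, \eqn{\kappa} the
#' pseudocount and \eqn{b(a)} the background frequency.
#'
#' The returned profile is uncalibrated (its threshold is \code{NA});
#' calibrate it with [calibrateProfile()] before scanning.
#'
#' @param block Aligned residue block: an [Biostrings::AAStringSet], a
#'   character vector of equal-length rows, or a character matrix. Gap
#'   characters are \code{"-"} and \code{"."}.
#' @param domainId Domain label for the profile. Defaults to the name of
#'   the block when available.
#' @param pseudocount Smoothing weight \eqn{\kappa} (default 1).
#' @param background Named background frequencies (default uniform).
#' @return A [DomainProfile-class] object.
#' @examples
#' block <- c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGWIKL")
#' p <- buildProfile(block, domainId = "TOY")
#' consensusResidues(p)
#' @export
buildProfile <- function(block, domainId = NULL, pseudocount = 1,
                         background = uniformBackground()) {
  if (inherits(block, "AAStringSet")) {
    if (is.null(domainId) && !is.null(names(block)))
      domainId <- names(block)[1L]
    block <- as.character(block)
  }
  if (is.character(block)) {
    if (length(block) == 0L) stop("empty alignment block")
    widths <- nchar(block)
    if (length(unique(widths)) != 1L)
      stop("ragged alignment block: rows differ in length")
    block <- do.call(rbind, strsplit(toupper(block), "", fixed = TRUE))
  }
  if (!is.matrix(block)) stop("block must be a matrix, character vector or AAStringSet")
  if (nrow(block) < 2L) stop("alignment block needs at least 2 rows")
  if (is.null(domainId)) domainId <- "domain"
  stopifnot(pseudocount >= 0, abs(sum(background) - 1) < 1e-6)
  background <- background[aaAlphabet()]

  gap <- block %in% c("-", ".")
  dim(gap) <- dim(block)
  keep <- colMeans(gap) <= 0.5
  if (!any(keep)) stop("no informative columns after dropping gap columns")
  block <- block[, keep, drop = FALSE]
  gap <- gap[, keep, drop = FALSE]

  bad <- !gap & !(block %in% aaAlphabet())
  if (any(bad))
    stop("unknown residue(s) in block: ",
         paste(unique(block[bad]), collapse = ", "))

  L <- ncol(block)
  scores <- matrix(0, nrow = 20L, ncol = L,
                   dimnames = list(aaAlphabet(), NULL))
  for (i in seq_len(L)) {
    col <- block[!gap[, i], i]
    n_i <- length(col)
    counts <- table(factor(col, levels = aaAlphabet()))
    freq <- (as.numeric(counts) + pseudocount * background) /
      (n_i + pseudocount)
    scores[, i] <- log2(freq / background)
  }

  new("DomainProfile",
      domainId = domainId,
      scores = scores,
      background = background,
      pseudocount = pseudocount,
      threshold = NA_real_,
      calibration = list())
}

#' Calibrate a profile's detection threshold against a background null
#'
#' Samples \code{nullSequences} random sequences of length
#' \code{nullLength} from the profile's background model, records the
#' best-window score of each, and sets the profile threshold to the given
#' quantile of that best-score distribution. With \code{quantile = 1} the
#' threshold is the maximum null score observed.
#'
#' @param profile An uncalibrated (or previously calibrated)
#'   [DomainProfile-class].
#' @param nullSequences Number of null sequences (default 200).
#' @param nullLength Length of each null sequence (default 400); must be
#'   at least the profile length.
#' @param quantile Calibration quantile in (0, 1] (default 0.99).
#' @param seed Integer seed; calibration is reproducible per seed.
#' @return The profile with its \code{threshold} slot set.
#' @export
calibrateProfile <- function(profile, nullSequences = 200, nullLength = 400,
                             quantile = 0.99, seed = 1) {
  stopifnot(is(profile, "DomainProfile"))
  if (!(quantile > 0 && quantile <= 1))
    stop("quantile must be in (0, 1]")
  L <- profileLength(profile)
  if (nullLength < L)
    stop("nullLength (", nullLength, ") is shorter than the profile (", L, ")")
  best <- withSeed(seed, {
    vapply(seq_len(nullSequences), function(i) {
      s <- randomResidues(nullLength, profile@background)
      max(windowScores(profile, residueIndex(s)))
    }, numeric(1))
  })
  profile@threshold <- stats::quantile(best, probs = quantile, names = FALSE,
                                       type = 7)
  profile@calibration <- list(nullSequences = nullSequences,
                              nullLength = nullLength,
                              quantile = quantile, seed = seed)
  validObject(profile)
  profile
}

# Score every ungapped window of profile length along an integer-encoded
# sequence. Returns numeric(0) when the sequence is shorter than the
# profile.
windowScores <- function(profile, seqIdx) {
  L <- ncol(profile@scores)
  n <- length(seqIdx)
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  out <- numeric(nw)
  S <- profile@scores
  for (j in seq_len(L)) {
    out <- out + S[cbind(seqIdx[j:(j + nw - 1L)], j)]
  }
  out
}
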