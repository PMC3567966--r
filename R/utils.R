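#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues, in the fixed order used for profile score
#' matrices and k-mer vectors.
#'
#' @return Character vector of length 20.
#' @export
aaAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Uniform residue background
#'
#' Background residue frequencies for profile building, calibration and
#' synthetic sequence generation. The default null is uniform 1/20.
#'
#' @return Named numeric vector over [aaAlphabet()] summing to 1.
#' @export
uniformBackground <- function() {
  aa <- aaAlphabet()
  stats::setNames(rep(1 / length(aa), length(aa)), aa)
}

# Fraction of protein length that counts as "terminal" at either end.
TERMINAL_FRACTION <- 0.4

#' Terminal-position tag of a feature
#'
#' A feature is \code{"N-terminal"} when its start lies within the first
#' 40\% of the protein, \code{"C-terminal"} when its end lies within the
#' last 40\%, and \code{"internal"} otherwise. A feature satisfying both
#' conditions is tagged by the terminus it sits closer to.
#'
#' @param start,end 1-based inclusive feature coordinates.
#' @param proteinLength Protein length in residues.
#' @return Character vector of tags.
#' @export
terminalTag <- function(start, end, proteinLength) {
  stopifnot(length(start) == length(end))
  isN <- start <= TERMINAL_FRACTION * proteinLength
  isC <- end >= (1 - TERMINAL_FRACTION) * proteinLength
  tag <- rep("internal", length(start))
  tag[isN & !isC] <- "N-terminal"
  tag[isC & !isN] <- "C-terminal"
  both <- isN & isC
  if (any(both)) {
    nearerN <- (start[both] - 1) <= (proteinLength - end[both])
    tag[both] <- ifelse(nearerN, "N-terminal", "C-terminal")
  }
  tag
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Sample n residues from a background distribution.
randomResidues <- function(n, background = uniformBackground()) {
  sample(names(background), n, replace = TRUE, prob = background)
}

# Split a residue string into a character vector.
splitResidues <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Map residues to integer indices in aaAlphabet(); unknown residues -> NA.
residueIndex <- function(residues) {
  match(residues, aaAlphabet())
}

# Strip a "@N"/"@C" suffix from domain labels, returning id + tag.
parseDomainTag <- function(domains) {
  tag <- rep("internal", length(domains))
  tag[grepl("@N$", domains)] <- "N-terminal"
  tag[grepl("@C$", domains)] <- "C-terminal"
  id <- sub("@[NC]$", "", domains)
  data.frame(domain_id = id, tag = tag, stringsAsFactors = FALSE)
}
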