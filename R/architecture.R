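#' Assemble a protein's domain architecture from its hits
#'
#' Sorts a protein's domain hits by start coordinate, computes the
#' terminal tag of each hit by the 40\% rule (see [terminalTag()]) and,
#' when the sequence is supplied, records short N-terminal motifs (by
#' default the EFWG motif that defines the plant-specific HD2
#' deacetylases).
#'
#' @param hits Hit table rows for a single protein (may be empty).
#' @param proteinLength Protein length in residues.
#' @param sequence Optional protein sequence, used for motif detection.
#' @param proteinId Protein label; defaults to the one in \code{hits}.
#' @param motifPatterns Named character vector of motifs searched for in
#'   the N-terminal 40\% of the sequence.
#' @return An [Architecture-class] object.
#' @export
assembleArchitecture <- function(hits, proteinLength, sequence = NULL,
                                 proteinId = NULL,
                                 motifPatterns = c(EFWG = "EFWG")) {
  if (is.null(proteinId)) {
    proteinId <- if (nrow(hits) > 0L) hits$protein_id[1L] else "protein"
  }
  if (nrow(hits) > 0L) {
    if (length(unique(hits$protein_id)) > 1L)
      stop("hits belong to more than one protein")
    if (any(hits$start < 1L | hits$end > proteinLength))
      stop("hit coordinates outside protein")
    hits <- hits[order(hits$start, hits$domain_id), , drop = FALSE]
    hits$tag <- terminalTag(hits$start, hits$end, proteinLength)
  } else {
    hits <- emptyHitTable()
    hits$tag <- character(0)
  }
  if (!"overlaps_other_hit" %in% names(hits))
    hits$overlaps_other_hit <- FALSE
  motifs <- character()
  if (!is.null(sequence)) {
    if (is(sequence, "AAString") || is(sequence, "XString"))
      sequence <- as.character(sequence)
    nterm <- substr(sequence, 1L,
                    max(1L, floor(TERMINAL_FRACTION * nchar(sequence))))
    found <- vapply(motifPatterns, function(m) grepl(m, nterm, fixed = TRUE),
                    logical(1))
    motifs <- names(motifPatterns)[found]
  }
  hits <- hits[, c("domain_id", "start", "end", "score",
                   "overlaps_other_hit", "tag"), drop = FALSE]
  rownames(hits) <- NULL
  new("Architecture", proteinId = proteinId,
      proteinLength = as.numeric(proteinLength),
      hits = hits,
      motifs = motifs)
}

#' Build an architecture directly from domain labels
#'
#' Constructs an [Architecture-class] from an ordered list of domain
#' labels with optional terminal tags (suffix \code{"@N"} or
#' \code{"@C"}), as used for transcribed catalog entries where residue
#' coordinates are not available.
#'
#' @param proteinId Protein label.
#' @param domains Character vector of domain labels in N-to-C order,
#'   optionally tagged (e.g. \code{c("Hat1_N@N", "AT1", "MOZ_SAS@C")}).
#' @param motifs Character vector of N-terminal motifs (e.g. "EFWG").
#' @param proteinLength Optional length in residues.
#' @return An [Architecture-class] object.
#' @export
architectureFromDomains <- function(proteinId, domains,
                                    motifs = character(),
                                    proteinLength = NA_real_) {
  parsed <- parseDomainTag(domains)
  n <- nrow(parsed)
  hits <- data.frame(domain_id = parsed$domain_id,
                     start = if (n) seq_len(n) else integer(0),
                     end = if (n) seq_len(n) else integer(0),
                     score = rep(NA_real_, n),
                     overlaps_other_hit = rep(FALSE, n),
                     tag = parsed$tag,
                     stringsAsFactors = FALSE)
  new("Architecture", proteinId = proteinId,
      proteinLength = as.numeric(proteinLength),
      hits = hits, motifs = as.character(motifs))
}
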