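#' @import methods
NULL

#' DomainProfile: position-specific log-odds scoring profile
#'
#' An ungapped position-specific scoring profile built from an aligned
#' domain block. Scores are log-odds values in bits relative to a residue
#' background. The detection threshold is unset (\code{NA}) until the
#' profile has been calibrated against a background null
#' (see [calibrateProfile()]).
#'
#' @slot domainId Accession-like domain label.
#' @slot scores Numeric matrix, 20 rows (residues, ordered as
#'   [aaAlphabet()]) by profile length columns, in bits.
#' @slot background Named numeric background frequencies.
#' @slot pseudocount Smoothing weight used at build time.
#' @slot threshold Calibrated minimum hit score in bits, or \code{NA}.
#' @slot calibration List recording calibration parameters (empty before
#'   calibration).
#' @export
setClass("DomainProfile",
  representation(
    domainId = "character",
    scores = "matrix",
    background = "numeric",
    pseudocount = "numeric",
    threshold = "numeric",
    calibration = "list"
  )
)

setValidity("DomainProfile", function(object) {
  msg <- character()
  if (length(object@domainId) != 1L || !nzchar(object@domainId))
    msg <- c(msg, "domainId must be a single non-empty string")
  if (nrow(object@scores) != 20L ||
      !identical(rownames(object@scores), aaAlphabet()))
    msg <- c(msg, "scores must have 20 rows named by aaAlphabet()")
  if (ncol(object@scores) < 1L)
    msg <- c(msg, "profile length must be >= 1")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (length(object@threshold) != 1L)
    msg <- c(msg, "threshold must be a single value (possibly NA)")
  if (length(msg)) msg else TRUE
})

#' Architecture: ordered per-protein domain hit list
#'
#' The ordered domain composition of one protein, with per-hit terminal
#' tags computed by the 40\% rule (or supplied directly when the
#' architecture is transcribed rather than scanned) and any short
#' sequence motifs detected at the N-terminus.
#'
#' @slot proteinId Protein label.
#' @slot proteinLength Length in residues (\code{NA} for transcribed
#'   architectures without coordinates).
#' @slot hits data.frame with columns \code{domain_id}, \code{start},
#'   \code{end}, \code{score}, \code{overlaps_other_hit}, \code{tag},
#'   sorted by start (coordinate columns may be \code{NA} for
#'   transcribed architectures).
#' @slot motifs Character vector of N-terminal motifs present (e.g.
#'   \code{"EFWG"}).
#' @export
setClass("Architecture",
  representation(
    proteinId = "character",
    proteinLength = "numeric",
    hits = "data.frame",
    motifs = "character"
  )
)

setValidity("Architecture", function(object) {
  msg <- character()
  need <- c("domain_id", "start", "end", "score", "overlaps_other_hit", "tag")
  if (!all(need %in% names(object@hits)))
    msg <- c(msg, paste("hits must have columns:", paste(need, collapse = ", ")))
  if (length(object@proteinId) != 1L)
    msg <- c(msg, "proteinId must be a single string")
  s <- object@hits$start
  if (length(s) > 1 && !all(is.na(s)) && is.unsorted(s, na.rm = TRUE))
    msg <- c(msg, "hits must be sorted by start")
  if (length(msg)) msg else TRUE
})

#' HMCatalog: packaged histone-modifier catalog
#'
#' A transcription of a 124-member tomato histone-modifier catalog
#' (member names, domain architectures, family/class labels) together
#' with the named decoy proteins, the canonical 10-organ list, synthetic
#' gene coordinates and a deterministic synthetic RPKM specification.
#' Loaded from the packaged fixture by [loadCatalog()].
#'
#' @slot members data.frame of members and decoys: \code{id},
#'   \code{role} ("member"/"decoy"), \code{superfamily}, \code{family},
#'   \code{class_label}, \code{chromosome}, \code{start}, \code{peaks}
#'   (comma-separated organ list), \code{level}, \code{amplitude},
#'   \code{pseudogene}.
#' @slot architectures Named list; per protein a list with elements
#'   \code{domains} (labels, optionally tagged \code{"@N"}/\code{"@C"})
#'   and \code{motifs}.
#' @slot organs The canonical ordered organ labels.
#' @slot fruitOrgans The ordered fruit-stage subset of \code{organs}.
#' @slot notes Character vector of transcription notes (including
#'   recorded source inconsistencies and which fields are synthetic).
#' @export
setClass("HMCatalog",
  representation(
    members = "data.frame",
    architectures = "list",
    organs = "character",
    fruitOrgans = "character",
    notes = "character"
  )
)

setValidity("HMCatalog", function(object) {
  msg <- character()
  if (length(object@organs) != 10L)
    msg <- c(msg, "organ list must have exactly 10 entries")
  if (!all(object@fruitOrgans %in% object@organs))
    msg <- c(msg, "fruit organs must be a subset of organs")
  if (!all(object@members$id %in% names(object@architectures)))
    msg <- c(msg, "every member needs an architecture entry")
  if (anyDuplicated(object@members$id))
    msg <- c(msg, "member ids must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DomainProfile", function(object) {
  cat("DomainProfile:", object@domainId,
      "| length", ncol(object@scores), "positions",
      "| pseudocount", object@pseudocount, "\n")
  if (is.na(object@threshold)) {
    cat("  uncalibrated (threshold unset)\n")
  } else {
    cat(sprintf("  threshold %.3f bits (quantile %s, %d null sequences)\n",
                object@threshold,
                format(object@calibration$quantile),
                object@calibration$nullSequences))
  }
  cat("  consensus:", paste(consensusResidues(object), collapse = ""), "\n")
})

setMethod("show", "Architecture", function(object) {
  cat("Architecture:", object@proteinId)
  if (!is.na(object@proteinLength))
    cat(" (", object@proteinLength, " aa)", sep = "")
  cat("\n")
  if (nrow(object@hits) == 0L) {
    cat("  no domains\n")
  } else {
    d <- object@hits
    lab <- ifelse(d$tag == "internal", d$domain_id,
                  paste0(d$domain_id, " [", d$tag, "]"))
    cat("  ", paste(lab, collapse = " - "), "\n", sep = "")
  }
  if (length(object@motifs))
    cat("  motifs:", paste(object@motifs, collapse = ", "), "\n")
})

setMethod("show", "HMCatalog", function(object) {
  m <- object@members
  is_member <- m$role == "member"
  cat("HMCatalog:", sum(is_member), "members,",
      sum(!is_member), "decoys\n")
  tab <- table(m$superfamily[is_member])
  cat("  superfamilies:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  organs:", paste(object@organs, collapse = ", "), "\n")
})
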