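#' Scan a protein sequence for domain hits
#'
#' Slides each calibrated profile along the sequence; every ungapped
#' window scoring at or above the profile's threshold is a candidate
#' hit. Overlapping candidates of the same domain are merged keeping the
#' best-scoring window (leftmost on ties); hits of different domains may
#' overlap and are flagged, never merged. Hits are returned sorted by
#' start coordinate (1-based, inclusive).
#'
#' @param sequence Protein sequence: a character string or
#'   [Biostrings::AAString].
#' @param profiles A [DomainProfile-class] or list of them; all must be
#'   calibrated.
#' @param proteinId Protein label recorded in the hit table.
#' @param merge Merge overlapping same-domain candidates (default TRUE).
#'   With \code{merge = FALSE} all above-threshold windows are returned,
#'   which is what an exhaustive all-windows evaluation produces.
#' @return data.frame with columns \code{protein_id}, \code{domain_id},
#'   \code{start}, \code{end}, \code{score}, \code{overlaps_other_hit}.
#' @seealso [scanProteome()], [mergeDomainHits()]
#' @export
scanProtein <- function(sequence, profiles, proteinId = "protein",
                        merge = TRUE) {
  if (is(sequence, "AAString") || is(sequence, "XString"))
    sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is(profiles, "DomainProfile")) profiles <- list(profiles)
  ok <- vapply(profiles, function(p) is(p, "DomainProfile") && isCalibrated(p),
               logical(1))
  if (!all(ok))
    stop("all profiles must be calibrated DomainProfile objects")

  seqIdx <- residueIndex(splitResidues(toupper(sequence)))
  if (anyNA(seqIdx))
    stop("sequence contains non-standard residues")

  cand <- lapply(profiles, function(p) {
    sc <- windowScores(p, seqIdx)
    keep <- which(sc >= profileThreshold(p))
    if (!length(keep)) return(NULL)
    data.frame(protein_id = proteinId,
               domain_id = domainId(p),
               start = keep,
               end = keep + profileLength(p) - 1L,
               score = sc[keep],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, cand)
  if (is.null(hits) || nrow(hits) == 0L)
    return(emptyHitTable())
  if (merge) hits <- mergeDomainHits(hits)
  hits <- flagCrossDomainOverlaps(hits)
  hits <- hits[order(hits$start, hits$domain_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a whole proteome
#'
#' Applies [scanProtein()] to every sequence of a proteome and binds the
#' per-protein hit tables.
#'
#' @param proteome Named character vector or [Biostrings::AAStringSet].
#' @inheritParams scanProtein
#' @return Combined hit table (see [scanProtein()]).
#' @export
scanProteome <- function(proteome, profiles, merge = TRUE) {
  if (inherits(proteome, "AAStringSet")) proteome <- as.character(proteome)
  if (is.null(names(proteome)))
    names(proteome) <- paste0("protein", seq_along(proteome))
  out <- lapply(names(proteome), function(id) {
    scanProtein(proteome[[id]], profiles, proteinId = id, merge = merge)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

emptyHitTable <- function() {
  data.frame(protein_id = character(), domain_id = character(),
             start = integer(), end = integer(), score = numeric(),
             overlaps_other_hit = logical(), stringsAsFactors = FALSE)
}

#' Merge overlapping same-domain hits
#'
#' Within each protein and domain, chains of mutually overlapping hits
#' are collapsed to the single best-scoring window; on equal scores the
#' leftmost window wins. The operation is idempotent, and merged
#' same-domain hits never overlap.
#'
#' @param hits Hit table with columns \code{protein_id},
#'   \code{domain_id}, \code{start}, \code{end}, \code{score}.
#' @return Merged hit table.
#' @export
mergeDomainHits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$protein_id, hits$domain_id, sep = "\r")
  parts <- split(seq_len(nrow(hits)), key)
  keep <- unlist(lapply(parts, function(idx) {
    h <- hits[idx, , drop = FALSE]
    o <- order(h$start, h$end)
    h <- h[o, ]; idx <- idx[o]
    # break into overlap-connected components by chained interval overlap
    comp <- cumsum(c(1L, as.integer(
      h$start[-1L] > cummax(h$end)[-nrow(h)])))
    vapply(split(seq_len(nrow(h)), comp), function(ci) {
      hh <- h[ci, , drop = FALSE]
      best <- ci[order(-hh$score, hh$start)[1L]]
      idx[best]
    }, integer(1))
  }), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Flag hits that overlap a hit of a different domain on the same protein.
flagCrossDomainOverlaps <- function(hits) {
  if (nrow(hits) == 0L) {
    hits$overlaps_other_hit <- logical(0)
    return(hits)
  }
  hits$overlaps_other_hit <- FALSE
  for (pid in unique(hits$protein_id)) {
    idx <- which(hits$protein_id == pid)
    h <- hits[idx, ]
    ir <- IRanges::IRanges(start = h$start, end = h$end)
    ov <- IRanges::findOverlaps(ir, ir)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    cross <- q != s & h$domain_id[q] != h$domain_id[s]
    hits$overlaps_other_hit[idx[unique(q[cross])]] <- TRUE
  }
  hits
}

#' Import a domain hit table from tab-separated text
#'
#' Reads an externally computed hit table (e.g. domain annotations from
#' a full profile-HMM scanner). Threshold checks are skipped for imported
#' hits; malformed rows (start > end, non-positive coordinates, missing
#' values) are dropped and reported in the \code{"errors"} attribute.
#'
#' @param path Path to a TSV file with header columns
#'   \code{protein_id}, \code{domain_id}, \code{start}, \code{end},
#'   \code{score}.
#' @return Validated hit table; rejected rows are reported in
#'   \code{attr(x, "errors")} as a data.frame of row numbers and reasons.
#' @export
importHitTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("protein_id", "domain_id", "start", "end", "score")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("hit table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$start <- suppressWarnings(as.integer(tab$start))
  tab$end <- suppressWarnings(as.integer(tab$end))
  tab$score <- suppressWarnings(as.numeric(tab$score))

  reasons <- rep(NA_character_, nrow(tab))
  bad_na <- is.na(tab$start) | is.na(tab$end) | is.na(tab$score)
  reasons[bad_na] <- "non-numeric or missing value"
  bad_pos <- !bad_na & (tab$start < 1L | tab$end < 1L)
  reasons[bad_pos] <- "non-positive coordinate"
  bad_ord <- !bad_na & !bad_pos & tab$start > tab$end
  reasons[bad_ord] <- "start > end"

  bad <- !is.na(reasons)
  hits <- tab[!bad, need, drop = FALSE]
  hits <- flagCrossDomainOverlaps(hits)
  hits <- hits[order(hits$protein_id, hits$start, hits$domain_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "errors") <- data.frame(row = which(bad),
                                     reason = reasons[bad],
                                     stringsAsFactors = FALSE)
  if (any(bad))
    message(sum(bad), " row(s) rejected; see attr(x, 'errors')")
  hits
}

#' Write a domain hit table to tab-separated text
#'
#' @param hits Hit table as returned by [scanProtein()] or
#'   [importHitTable()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
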