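#' Locate marker sequences on a genome by exact match
#'
#' Resolves the genomic coordinate of each marker sequence by exact
#' string search (a desk-scale stand-in for a BLASTn lookup). A marker
#' matching exactly once is resolved to its chromosome and 1-based start;
#' multi-hit markers are flagged ambiguous, non-matching markers
#' unresolved. Matching is on the given strand only.
#'
#' @param markers Named character vector or [Biostrings::DNAStringSet]
#'   of marker sequences (each at least 20 bp).
#' @param genome Named character vector or [Biostrings::DNAStringSet]
#'   of chromosome sequences.
#' @param maxMismatch Number of tolerated mismatches (default 0; exact
#'   matching keeps resolution deterministic).
#' @return data.frame with columns \code{marker_id}, \code{chromosome},
#'   \code{position}, \code{n_matches}, \code{status}
#'   (\code{"resolved"}, \code{"ambiguous"} or \code{"unresolved"}).
#' @export
locateMarkers <- function(markers, genome, maxMismatch = 0) {
  if (!inherits(markers, "DNAStringSet"))
    markers <- Biostrings::DNAStringSet(markers)
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(markers)))
    names(markers) <- paste0("marker", seq_along(markers))
  if (any(Biostrings::width(markers) < 20L))
    stop("markers must be at least 20 bp")

  out <- lapply(names(markers), function(id) {
    hits <- lapply(seq_along(genome), function(ci) {
      m <- Biostrings::matchPattern(markers[[id]], genome[[ci]],
                                    max.mismatch = maxMismatch)
      if (length(m) == 0L) return(NULL)
      data.frame(chromosome = names(genome)[ci],
                 position = BiocGenerics::start(m),
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    n <- if (is.null(hits)) 0L else nrow(hits)
    status <- if (n == 0L) "unresolved" else if (n > 1L) "ambiguous"
              else "resolved"
    data.frame(marker_id = id,
               chromosome = if (n == 1L) hits$chromosome else NA_character_,
               position = if (n == 1L) hits$position else NA_integer_,
               n_matches = n, status = status, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build introgression-line bins from resolved marker coordinates
#'
#' Each bin is the closed genomic interval between its start and end
#' edge markers, normalized so start <= end. Bins whose edge markers are
#' unresolved or sit on different chromosomes are rejected and reported.
#'
#' @param markerTable data.frame with columns \code{marker_id},
#'   \code{chromosome}, \code{position} (e.g. from [locateMarkers()] or
#'   a pre-resolved table).
#' @param binDefs data.frame with columns \code{bin_id},
#'   \code{start_marker}, \code{end_marker} and optionally
#'   \code{phenotype_keywords} (semicolon-separated).
#' @return List with \code{bins} (a [GenomicRanges::GRanges] carrying
#'   \code{bin_id} and \code{phenotype_keywords} metadata columns) and
#'   \code{rejected} (data.frame of bin_id + reason).
#' @export
buildBins <- function(markerTable, binDefs) {
  if ("status" %in% names(markerTable))
    markerTable <- markerTable[markerTable$status == "resolved", ,
                               drop = FALSE]
  lookup <- function(id) {
    i <- match(id, markerTable$marker_id)
    if (is.na(i)) NULL else markerTable[i, ]
  }
  keep <- list(); rejected <- list()
  for (i in seq_len(nrow(binDefs))) {
    b <- binDefs[i, ]
    s <- lookup(b$start_marker); e <- lookup(b$end_marker)
    if (is.null(s) || is.null(e)) {
      miss <- c(b$start_marker, b$end_marker)[c(is.null(s), is.null(e))]
      rejected[[length(rejected) + 1L]] <-
        data.frame(bin_id = b$bin_id,
                   reason = paste("unresolved edge marker:",
                                  paste(miss, collapse = ", ")),
                   stringsAsFactors = FALSE)
      next
    }
    if (s$chromosome != e$chromosome) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(bin_id = b$bin_id,
                   reason = "edge markers on different chromosomes",
                   stringsAsFactors = FALSE)
      next
    }
    keep[[length(keep) + 1L]] <-
      data.frame(bin_id = b$bin_id, chromosome = s$chromosome,
                 start = min(s$position, e$position),
                 end = max(s$position, e$position),
                 phenotype_keywords =
                   if ("phenotype_keywords" %in% names(b))
                     b$phenotype_keywords else "",
                 stringsAsFactors = FALSE)
  }
  kept <- do.call(rbind, keep)
  if (is.null(kept)) {
    bins <- GenomicRanges::GRanges()
  } else {
    bins <- GenomicRanges::GRanges(
      seqnames = kept$chromosome,
      ranges = IRanges::IRanges(start = kept$start, end = kept$end),
      bin_id = kept$bin_id,
      phenotype_keywords = kept$phenotype_keywords)
  }
  rej <- do.call(rbind, rejected)
  if (is.null(rej))
    rej <- data.frame(bin_id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  list(bins = bins, rejected = rej)
}

#' Assign gene start coordinates to IL bins
#'
#' A gene is associated with every bin whose closed interval contains
#' its start coordinate. Genes without a chromosome are reported
#' unassigned with reason \code{"no chromosome"}; genes whose start
#' falls outside all bins of their chromosome with reason
#' \code{"outside markers"}. Every gene receives at least one record.
#'
#' @param loci data.frame with columns \code{gene_id},
#'   \code{chromosome} (may be \code{NA}), \code{start} (1-based bp).
#' @param bins [GenomicRanges::GRanges] from [buildBins()].
#' @return data.frame with columns \code{gene_id}, \code{bin_id}
#'   (\code{NA} when unassigned) and \code{unassigned_reason}
#'   (\code{"none"}, \code{"no chromosome"} or
#'   \code{"outside markers"}).
#' @export
assignGenes <- function(loci, bins) {
  stopifnot(all(c("gene_id", "chromosome", "start") %in% names(loci)))
  out <- vector("list", nrow(loci))
  binChr <- as.character(GenomicRanges::seqnames(bins))
  binStart <- BiocGenerics::start(bins)
  binEnd <- BiocGenerics::end(bins)
  binId <- if (length(bins)) bins$bin_id else character(0)
  for (i in seq_len(nrow(loci))) {
    g <- loci[i, ]
    if (is.na(g$chromosome) || !nzchar(g$chromosome)) {
      out[[i]] <- data.frame(gene_id = g$gene_id, bin_id = NA_character_,
                             unassigned_reason = "no chromosome",
                             stringsAsFactors = FALSE)
      next
    }
    inBin <- which(binChr == g$chromosome & binStart <= g$start &
                     g$start <= binEnd)
    if (length(inBin)) {
      out[[i]] <- data.frame(gene_id = g$gene_id, bin_id = binId[inBin],
                             unassigned_reason = "none",
                             stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(gene_id = g$gene_id, bin_id = NA_character_,
                             unassigned_reason = "outside markers",
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect tandem duplication clusters within a gene family
#'
#' Single-linkage chaining of same-chromosome gene start coordinates:
#' consecutive genes are chained while the inter-start gap is at most
#' \code{gapKb} kilobases; chains of at least two genes are reported
#' with their member count and span (max start - min start). The
#' chaining is order-independent and idempotent.
#'
#' @param loci data.frame with columns \code{gene_id},
#'   \code{chromosome}, \code{start}, restricted to one gene family.
#' @param gapKb Maximum inter-start gap in kb (default 100).
#' @return data.frame with columns \code{cluster_id}, \code{chromosome},
#'   \code{n_members}, \code{start_bp}, \code{end_bp}, \code{span_bp},
#'   \code{members} (comma-separated gene ids in coordinate order).
#' @export
detectTandemClusters <- function(loci, gapKb = 100) {
  stopifnot(gapKb > 0)
  loci <- loci[!is.na(loci$chromosome) & nzchar(loci$chromosome), ,
               drop = FALSE]
  gap <- gapKb * 1000
  out <- list()
  for (chr in sort(unique(loci$chromosome))) {
    g <- loci[loci$chromosome == chr, , drop = FALSE]
    g <- g[order(g$start, g$gene_id), , drop = FALSE]
    comp <- cumsum(c(1L, as.integer(diff(g$start) > gap)))
    for (ci in split(seq_len(nrow(g)), comp)) {
      if (length(ci) < 2L) next
      gg <- g[ci, ]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr,
        n_members = nrow(gg),
        start_bp = min(gg$start),
        end_bp = max(gg$start),
        span_bp = max(gg$start) - min(gg$start),
        members = paste(gg$gene_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chromosome = character(), n_members = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      span_bp = numeric(), members = character(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$chromosome, res$start_bp), , drop = FALSE]
  res <- cbind(cluster_id = if (nrow(res)) paste0("cluster", seq_len(nrow(res)))
                            else character(0),
               res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Packaged synthetic IL-bin tables
#'
#' Loads the packaged synthetic marker-coordinate table and bin
#' definitions (the real introgression-line bin coordinates are not
#' bundled; these synthetic bins are constrained by the documented
#' gene-to-bin facts, e.g. the fruit-color bin IL4-3-2 on chromosome 4).
#'
#' @return List with \code{markers} (marker coordinate data.frame) and
#'   \code{binDefs} (bin definition data.frame), ready for
#'   [buildBins()].
#' @export
syntheticBinTables <- function() {
  mk <- utils::read.delim(system.file("extdata",
                                      "il_markers_synthetic.tsv",
                                      package = "chromod"),
                          stringsAsFactors = FALSE)
  bd <- utils::read.delim(system.file("extdata",
                                      "il_bins_synthetic.tsv",
                                      package = "chromod"),
                          stringsAsFactors = FALSE)
  list(markers = mk, binDefs = bd)
}
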