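#' Generate a toy genome with embedded bin-edge markers
#'
#' Builds random DNA chromosomes, lays out non-overlapping bins per
#' chromosome, generates a unique edge-marker sequence for each bin
#' boundary and embeds the marker sequences in the genome at their
#' stated coordinates, so that coordinate resolution by exact match
#' succeeds. Gene loci are passed through (a gene may reference an
#' unknown or missing chromosome, modelling genes not assigned to any
#' chromosome).
#'
#' @param nChromosomes Number of chromosomes.
#' @param binsPerChromosome Number of bins per chromosome.
#' @param genes Optional data.frame with columns \code{gene_id},
#'   \code{chromosome}, \code{start}.
#' @param seed Integer seed.
#' @param chromosomeLength Chromosome length in bp (default 100000).
#' @param markerLength Marker length in bp (default 30).
#' @return List with \code{genome} ([Biostrings::DNAStringSet]),
#'   \code{markers} ([Biostrings::DNAStringSet]), \code{markerTable}
#'   (truth coordinates: \code{marker_id}, \code{chromosome},
#'   \code{position}), \code{binDefs} (bin definitions:
#'   \code{bin_id}, \code{start_marker}, \code{end_marker},
#'   \code{phenotype_keywords}) and \code{loci} (the gene table).
#' @export
makeGenomeAndMarkers <- function(nChromosomes = 2, binsPerChromosome = 3,
                                 genes = NULL, seed = 1,
                                 chromosomeLength = 100000,
                                 markerLength = 30) {
  stopifnot(nChromosomes >= 1, binsPerChromosome >= 1,
            markerLength >= 20)
  withSeed(seed, {
    chrNames <- paste0("chr", seq_len(nChromosomes))
    genome <- character(nChromosomes)
    markerTable <- list(); binDefs <- list(); markerSeqs <- character()

    # per-chromosome bin layout: bins tile [margin, L - margin] with
    # a fixed inter-bin gap
    margin <- max(2L * markerLength, round(chromosomeLength * 0.02))
    gapBp <- max(2L * markerLength, round(chromosomeLength * 0.01))
    usable <- chromosomeLength - 2 * margin
    binSpan <- floor((usable - (binsPerChromosome - 1) * gapBp) /
                       binsPerChromosome)
    if (binSpan <= 4 * markerLength)
      stop("chromosomeLength too small for the requested bin layout")

    for (ci in seq_len(nChromosomes)) {
      seq <- sample(c("A", "C", "G", "T"), chromosomeLength, replace = TRUE)
      for (bi in seq_len(binsPerChromosome)) {
        binStart <- margin + (bi - 1L) * (binSpan + gapBp) + 1L
        binEnd <- binStart + binSpan - 1L
        ids <- sprintf("C%dB%d%s", ci, bi, c("S", "E"))
        pos <- c(binStart, binEnd - markerLength + 1L)
        for (k in 1:2) {
          mseq <- paste(sample(c("A", "C", "G", "T"), markerLength,
                               replace = TRUE), collapse = "")
          seq[pos[k]:(pos[k] + markerLength - 1L)] <- splitResidues(mseq)
          markerSeqs[ids[k]] <- mseq
          markerTable[[length(markerTable) + 1L]] <- data.frame(
            marker_id = ids[k], chromosome = chrNames[ci],
            position = pos[k], stringsAsFactors = FALSE)
        }
        binDefs[[length(binDefs) + 1L]] <- data.frame(
          bin_id = sprintf("IL%d-%d", ci, bi),
          start_marker = ids[1], end_marker = ids[2],
          phenotype_keywords = "", stringsAsFactors = FALSE)
      }
      genome[ci] <- paste(seq, collapse = "")
    }
    genomeSet <- Biostrings::DNAStringSet(genome)
    names(genomeSet) <- chrNames
    markerSet <- Biostrings::DNAStringSet(markerSeqs)
    if (is.null(genes))
      genes <- data.frame(gene_id = character(), chromosome = character(),
                          start = numeric(), stringsAsFactors = FALSE)
    list(genome = genomeSet, markers = markerSet,
         markerTable = do.call(rbind, markerTable),
         binDefs = do.call(rbind, binDefs),
         loci = genes)
  })
}
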