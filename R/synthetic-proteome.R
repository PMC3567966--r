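#' Specify a synthetic domain motif
#'
#' A motif specification for the synthetic proteome generator: an
#' accession-like label, a consensus residue string (8-40 residues) and
#' a per-position substitution probability controlling how degenerate
#' sampled instances are.
#'
#' @param domainId Accession-like label (e.g. \code{"PF00583"}).
#' @param consensus Residue string over the 20-letter alphabet, length
#'   8 to 40.
#' @param degeneracy Per-position substitution probability in [0, 1).
#' @return A list of class \code{"MotifSpec"}.
#' @export
motifSpec <- function(domainId, consensus, degeneracy = 0.05) {
  consensus <- toupper(consensus)
  if (!nzchar(consensus) || nchar(consensus) < 8 || nchar(consensus) > 40)
    stop("consensus length must be 8-40 residues")
  if (!all(splitResidues(consensus) %in% aaAlphabet()))
    stop("consensus contains non-standard residues")
  if (!(degeneracy >= 0 && degeneracy < 1))
    stop("degeneracy must be in [0, 1)")
  structure(list(domainId = domainId, consensus = consensus,
                 degeneracy = degeneracy), class = "MotifSpec")
}

# Sample one motif instance: substitute each consensus position with
# probability `degeneracy` by a residue drawn from the other 19.
sampleMotifInstance <- function(consensus, degeneracy) {
  res <- splitResidues(consensus)
  if (degeneracy > 0) {
    sub <- stats::runif(length(res)) < degeneracy
    if (any(sub)) {
      res[sub] <- vapply(res[sub], function(a)
        sample(setdiff(aaAlphabet(), a), 1L), character(1))
    }
  }
  paste(res, collapse = "")
}

#' Generate aligned motif blocks from motif specifications
#'
#' For each specification, samples an aligned block of sequences from
#' the consensus under the stated per-position substitution probability.
#' With degeneracy 0 all block rows equal the consensus. Output is
#' reproducible per seed.
#'
#' @param specs List of [motifSpec()] objects with unique domain ids.
#' @param seed Integer seed.
#' @param blockSize Sequences per block (default 8, minimum 5).
#' @return A named list of class \code{"MotifSet"}; per domain a list
#'   with \code{domainId}, \code{consensus}, \code{degeneracy} and
#'   \code{block} (an [Biostrings::AAStringSet] of aligned rows).
#' @export
makeMotifSet <- function(specs, seed = 1, blockSize = 8) {
  if (inherits(specs, "MotifSpec")) specs <- list(specs)
  stopifnot(blockSize >= 5)
  ids <- vapply(specs, `[[`, character(1), "domainId")
  if (anyDuplicated(ids))
    stop("duplicate domain_id in motif specs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- withSeed(seed, {
    lapply(specs, function(sp) {
      rows <- vapply(seq_len(blockSize), function(i)
        sampleMotifInstance(sp$consensus, sp$degeneracy), character(1))
      block <- Biostrings::AAStringSet(rows)
      names(block) <- paste0(sp$domainId, "_", seq_len(blockSize))
      list(domainId = sp$domainId, consensus = sp$consensus,
           degeneracy = sp$degeneracy, block = block)
    })
  })
  names(out) <- ids
  structure(out, class = "MotifSet")
}

#' Specify a synthetic protein architecture
#'
#' @param proteinId Protein label.
#' @param domains Ordered domain labels with optional position tags
#'   (\code{"@N"} start within the first 40\% of the protein,
#'   \code{"@C"} end within the last 40\%; untagged = internal,
#'   placed anywhere).
#' @param proteinLength Protein length in residues.
#' @param chromosome,start Optional genomic placement carried through
#'   to truth tables.
#' @return A list of class \code{"ArchitectureSpec"}.
#' @export
architectureSpec <- function(proteinId, domains, proteinLength,
                             chromosome = NA_character_,
                             start = NA_real_) {
  structure(list(proteinId = proteinId, domains = domains,
                 proteinLength = as.integer(proteinLength),
                 chromosome = chromosome, start = start),
            class = "ArchitectureSpec")
}

#' Plant motif instances into a synthetic proteome
#'
#' Builds one random-background protein per architecture specification
#' and embeds a sampled instance of each listed motif, at positions
#' consistent with the terminal tags (N-terminal: motif start within
#' the first 40\% of the protein; C-terminal: motif end within the last
#' 40\%) and in strictly increasing, non-overlapping order. Every
#' planted instance is recorded once in the truth table with its exact
#' coordinates.
#'
#' @param archSpecs List of [architectureSpec()] objects.
#' @param motifs A \code{"MotifSet"} from [makeMotifSet()]; every
#'   referenced domain id must exist in it.
#' @param seed Integer seed.
#' @param background Residue background for the random stretch.
#' @return List with \code{proteome} (an [Biostrings::AAStringSet]) and
#'   \code{truth} (data.frame: \code{protein_id}, \code{domain_id},
#'   \code{start}, \code{end}, \code{tag}).
#' @export
plantProteome <- function(archSpecs, motifs, seed = 1,
                          background = uniformBackground()) {
  if (inherits(archSpecs, "ArchitectureSpec")) archSpecs <- list(archSpecs)
  withSeed(seed, {
    seqs <- character(length(archSpecs))
    truth <- list()
    for (i in seq_along(archSpecs)) {
      sp <- archSpecs[[i]]
      parsed <- parseDomainTag(sp$domains)
      unknown <- setdiff(parsed$domain_id, names(motifs))
      if (length(unknown))
        stop("unknown domain_id(s) in architecture spec: ",
             paste(unknown, collapse = ", "))
      L <- sp$proteinLength
      lens <- vapply(parsed$domain_id,
                     function(d) nchar(motifs[[d]]$consensus), integer(1))
      if (any(lens > L))
        stop("motif longer than protein for ", sp$proteinId)
      if (sum(lens) + nrow(parsed) > L)
        stop("protein too short for its motifs: ", sp$proteinId)

      starts <- placeMotifs(lens, parsed$tag, L)
      res <- randomResidues(L, background)
      for (j in seq_len(nrow(parsed))) {
        inst <- splitResidues(sampleMotifInstance(
          motifs[[parsed$domain_id[j]]]$consensus,
          motifs[[parsed$domain_id[j]]]$degeneracy))
        res[starts[j]:(starts[j] + lens[j] - 1L)] <- inst
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = sp$proteinId, domain_id = parsed$domain_id[j],
          start = starts[j], end = starts[j] + lens[j] - 1L,
          tag = parsed$tag[j], stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(res, collapse = "")
    }
    proteome <- Biostrings::AAStringSet(seqs)
    names(proteome) <- vapply(archSpecs, `[[`, character(1), "proteinId")
    tt <- do.call(rbind, truth)
    if (is.null(tt))
      tt <- data.frame(protein_id = character(), domain_id = character(),
                       start = integer(), end = integer(),
                       tag = character(), stringsAsFactors = FALSE)
    list(proteome = proteome, truth = tt)
  })
}

# Choose non-overlapping, strictly increasing start positions honouring
# the terminal tags. Motifs are laid out in order within equal slices of
# the protein, then the tag constraint is intersected with the slice.
placeMotifs <- function(lens, tags, L) {
  k <- length(lens)
  if (k == 0L) return(integer(0))
  starts <- integer(k)
  cursor <- 1L
  for (j in seq_len(k)) {
    sliceEnd <- floor(j * L / k)
    lo <- cursor
    hi <- sliceEnd - lens[j] + 1L
    if (tags[j] == "N-terminal")
      hi <- min(hi, floor(TERMINAL_FRACTION * L))
    if (tags[j] == "C-terminal")
      lo <- max(lo, ceiling((1 - TERMINAL_FRACTION) * L) - lens[j] + 1L)
    hi <- min(hi, L - lens[j] + 1L)
    if (lo > hi)
      stop("cannot place motif ", j, " (tag ", tags[j],
           ") in a protein of length ", L)
    starts[j] <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    cursor <- starts[j] + lens[j] + 1L
  }
  starts
}
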