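#' Load the packaged histone-modifier catalog
#'
#' Reads the packaged 124-member tomato histone-modifier catalog: member
#' names, domain architectures, superfamily/family/class labels, plus
#' the named decoy proteins (two amino-acid-synthesis enzymes carrying
#' AT1 + AAK, and 28 amine-oxidase-only proteins lacking the SWIRM
#' domain). Gene coordinates and the RPKM specification bundled with the
#' catalog are synthetic stand-ins constrained by the documented facts
#' (see [catalogNotes()]).
#'
#' @param path Path to a catalog YAML file (defaults to the packaged
#'   catalog).
#' @return An [HMCatalog-class] object.
#' @examples
#' cat124 <- loadCatalog()
#' nrow(catalogMembers(cat124))
#' @export
loadCatalog <- function(path = system.file("extdata", "hm_catalog.yaml",
                                           package = "chromod")) {
  raw <- yaml::read_yaml(path)
  entries <- c(raw$members, raw$decoys)
  roles <- c(rep("member", length(raw$members)),
             rep("decoy", length(raw$decoys)))
  members <- do.call(rbind, lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    ex <- e$expression
    data.frame(
      id = e$id,
      role = roles[i],
      superfamily = e$superfamily %||% NA_character_,
      family = e$family %||% NA_character_,
      class_label = e$class %||% NA_character_,
      chromosome = e$chromosome %||% NA_character_,
      start = e$start %||% NA_real_,
      peaks = if (is.null(ex)) NA_character_
              else paste(ex$peaks, collapse = ","),
      level = if (is.null(ex)) NA_character_ else ex$level,
      amplitude = if (is.null(ex)) NA_real_ else ex$amplitude,
      pseudogene = if (is.null(ex)) FALSE else isTRUE(ex$pseudogene),
      stringsAsFactors = FALSE)
  }))
  architectures <- lapply(entries, function(e)
    list(domains = as.character(unlist(e$domains)),
         motifs = as.character(unlist(e$motifs))))
  names(architectures) <- members$id
  new("HMCatalog",
      members = members,
      architectures = architectures,
      organs = as.character(raw$organs),
      fruitOrgans = as.character(raw$fruit_organs),
      notes = as.character(unlist(raw$notes)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Architectures of the catalog entries
#'
#' Builds an [Architecture-class] object for every catalog entry from
#' its transcribed domain labels and motifs.
#'
#' @param catalog An [HMCatalog-class].
#' @param includeDecoys Include the decoy proteins (default TRUE), so
#'   the classifier's exclusion rules are exercised.
#' @return Named list of [Architecture-class] objects.
#' @export
catalogArchitectures <- function(catalog, includeDecoys = TRUE) {
  stopifnot(is(catalog, "HMCatalog"))
  m <- catalog@members
  if (!includeDecoys) m <- m[m$role == "member", , drop = FALSE]
  out <- lapply(m$id, function(id) {
    a <- catalog@architectures[[id]]
    architectureFromDomains(id, a$domains, motifs = a$motifs)
  })
  names(out) <- m$id
  out
}

#' Synthetic gene loci of the catalog
#'
#' Gene start coordinates for the catalog members. Coordinates are
#' synthetic but honour the documented placement facts (the chromosome-8
#' tandem cluster, the unanchored gene, the terminal genes beyond the
#' outermost markers).
#'
#' @param catalog An [HMCatalog-class].
#' @return data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{start}.
#' @export
catalogLoci <- function(catalog) {
  m <- catalogMembers(catalog)
  data.frame(gene_id = m$id, chromosome = m$chromosome, start = m$start,
             stringsAsFactors = FALSE)
}

#' Deterministic RPKM matrix for the catalog members
#'
#' Expands the catalog's synthetic expression specification into a
#' genes-by-organs RPKM matrix: each gene takes its amplitude in its
#' peak organs and one tenth of the amplitude elsewhere; pseudogene
#' rows are zero everywhere. The expansion is deterministic (no noise),
#' so documented facts — which genes peak where, which behave as
#' pseudogenes, which gene is the lowest-expressed of its family — hold
#' exactly.
#'
#' @param catalog An [HMCatalog-class].
#' @return Numeric matrix, members by the canonical organ panel.
#' @export
catalogRpkm <- function(catalog) {
  m <- catalogMembers(catalog)
  organs <- catalogOrgans(catalog)
  mat <- matrix(0, nrow = nrow(m), ncol = length(organs),
                dimnames = list(m$id, organs))
  for (i in seq_len(nrow(m))) {
    if (m$pseudogene[i]) next
    peaks <- strsplit(m$peaks[i], ",", fixed = TRUE)[[1]]
    if (identical(peaks, "all")) peaks <- organs
    amp <- m$amplitude[i]
    mat[i, ] <- 0.1 * amp
    mat[i, peaks] <- amp
  }
  mat
}
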