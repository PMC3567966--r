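#' Build a candidate-gene query
#'
#' A query combines up to four screening criteria: a target family (and
#' optionally class), a set of desired peak organs, a phenotype keyword
#' to match against IL-bin annotations, and an optional template RPKM
#' profile (e.g. a ripening-associated profile) to correlate candidate
#' expression against. At least one criterion must be set.
#'
#' @param targetFamily Family label (e.g. \code{"SDG"}).
#' @param targetClass Optional class within the family (e.g.
#'   \code{"II"}).
#' @param desiredPeakOrgans Character vector of organ labels.
#' @param phenotypeKeyword Keyword matched (case-insensitively) against
#'   bin phenotype annotations (e.g. \code{"fruit color"}).
#' @param templateProfile Named numeric RPKM vector over (a subset of)
#'   the organ panel.
#' @return A list of class \code{"hmQuery"}.
#' @export
hmQuery <- function(targetFamily = NULL, targetClass = NULL,
                    desiredPeakOrgans = NULL, phenotypeKeyword = NULL,
                    templateProfile = NULL) {
  if (is.null(targetFamily) && is.null(desiredPeakOrgans) &&
      is.null(phenotypeKeyword) && is.null(templateProfile))
    stop("at least one query criterion must be set")
  if (!is.null(desiredPeakOrgans) &&
      !all(desiredPeakOrgans %in% hmOrgans()))
    stop("unknown organ(s): ",
         paste(setdiff(desiredPeakOrgans, hmOrgans()), collapse = ", "))
  structure(list(targetFamily = targetFamily, targetClass = targetClass,
                 desiredPeakOrgans = desiredPeakOrgans,
                 phenotypeKeyword = phenotypeKeyword,
                 templateProfile = templateProfile),
            class = "hmQuery")
}

#' Rank candidate genes for a phenotype of interest
#'
#' Combines family membership, IL-bin phenotype keywords and expression
#' evidence into a deterministic candidate ranking. The expression score
#' is the Pearson correlation with the template profile mapped to
#' \eqn{[0,1]} when a template is given, otherwise the indicator that
#' the gene's peak stage lies in the desired organ set. The phenotype
#' score is the indicator that the gene's bin carries the keyword. The
#' default combination is
#' \deqn{total = family \times phenotype \times (0.5 + 0.5\,expr)}
#' so that each criterion acts conjunctively while expression
#' discriminates among genes meeting the hard criteria; a weighted-sum
#' mode is available. Ties are broken by gene identifier.
#'
#' @param classification An \code{"HMClassification"} (or its
#'   \code{table}) from [classifyCatalog()].
#' @param associations Gene-to-bin table from [assignGenes()].
#' @param bins [GenomicRanges::GRanges] of bins (from [buildBins()]).
#' @param rpkm Genes-by-organs RPKM matrix.
#' @param query An [hmQuery()].
#' @param combination \code{"product"} (default) or
#'   \code{"weighted"}.
#' @param weights Numeric weights (family, phenotype, expression) for
#'   the weighted-sum mode.
#' @return data.frame ranked by decreasing total score, with columns
#'   \code{gene_id}, \code{family_match}, \code{phenotype_match},
#'   \code{expression_score}, \code{total}, \code{rank},
#'   \code{flagged} (TRUE when the gene was missing from the expression
#'   matrix or is a pseudogene). Genes outside the target family are
#'   not listed.
#' @export
prioritizeCandidates <- function(classification, associations, bins, rpkm,
                                 query,
                                 combination = c("product", "weighted"),
                                 weights = c(1, 1, 1) / 3) {
  combination <- match.arg(combination)
  stopifnot(inherits(query, "hmQuery"))
  tab <- if (inherits(classification, "HMClassification"))
    classification$table else classification

  cand <- tab[tab$status == "assigned", , drop = FALSE]
  if (!is.null(query$targetFamily))
    cand <- cand[cand$family == query$targetFamily, , drop = FALSE]
  if (!is.null(query$targetClass))
    cand <- cand[!is.na(cand$class_label) &
                   cand$class_label == query$targetClass, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(gene_id = character(), family_match = numeric(),
                      phenotype_match = numeric(),
                      expression_score = numeric(), total = numeric(),
                      rank = integer(), flagged = logical(),
                      stringsAsFactors = FALSE))

  binKw <- stats::setNames(
    if (length(bins)) as.character(bins$phenotype_keywords) else character(0),
    if (length(bins)) as.character(bins$bin_id) else character(0))

  scoreGene <- function(gid) {
    # phenotype: any bin holding the gene carries the keyword
    pm <- 1
    if (!is.null(query$phenotypeKeyword)) {
      gb <- associations$bin_id[associations$gene_id == gid &
                                  associations$unassigned_reason == "none"]
      pm <- as.numeric(length(gb) > 0 &&
                         any(grepl(query$phenotypeKeyword, binKw[gb],
                                   ignore.case = TRUE)))
    }
    # expression
    es <- 0; flagged <- FALSE
    if (!gid %in% rownames(rpkm)) {
      flagged <- TRUE
    } else if (!is.null(query$templateProfile)) {
      tp <- query$templateProfile
      organs <- intersect(names(tp), colnames(rpkm))
      if (length(organs) >= 3 && stats::sd(rpkm[gid, organs]) > 0 &&
          stats::sd(tp[organs]) > 0) {
        es <- (stats::cor(rpkm[gid, organs], tp[organs]) + 1) / 2
      } else {
        flagged <- TRUE
      }
    } else if (!is.null(query$desiredPeakOrgans)) {
      if (all(rpkm[gid, ] <= 0)) {
        flagged <- TRUE  # pseudogene: no peak defined
      } else {
        es <- as.numeric(peakStage(rpkm, gid) %in% query$desiredPeakOrgans)
      }
    } else {
      es <- 1
    }
    c(pm = pm, es = es, flagged = as.numeric(flagged))
  }

  sc <- t(vapply(cand$protein_id, scoreGene, numeric(3)))
  fm <- rep(1, nrow(cand))
  total <- if (combination == "product") {
    fm * sc[, "pm"] * (0.5 + 0.5 * sc[, "es"])
  } else {
    weights[1] * fm + weights[2] * sc[, "pm"] + weights[3] * sc[, "es"]
  }
  out <- data.frame(gene_id = cand$protein_id,
                    family_match = fm,
                    phenotype_match = sc[, "pm"],
                    expression_score = sc[, "es"],
                    total = total,
                    flagged = sc[, "flagged"] > 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("gene_id", "family_match", "phenotype_match",
          "expression_score", "total", "rank", "flagged")]
}
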