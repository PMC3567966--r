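#' Canonical organ panel
#'
#' The ten organs/stages of the expression panel, in display order:
#' root, leaf, bud, flower, fruit at 1/2/3 cm, mature green fruit (MG),
#' berry at breaker (B) and berry ten days after breaker (B10).
#'
#' @return Character vector of length 10.
#' @export
hmOrgans <- function() {
  c("root", "leaf", "bud", "flower", "1cm_fruit", "2cm_fruit",
    "3cm_fruit", "MG", "B", "B10")
}

#' Fruit-stage organs
#'
#' The six fruit developmental stages used for expression-profile
#' grouping.
#'
#' @return Character vector of length 6.
#' @export
fruitOrgans <- function() {
  c("1cm_fruit", "2cm_fruit", "3cm_fruit", "MG", "B", "B10")
}

#' Read an RPKM expression matrix
#'
#' Reads a genes-by-organs RPKM table from tab-separated text. The
#' header must contain exactly the canonical organ panel (any order;
#' columns are reordered); the body must be complete and non-negative.
#'
#' @param path Path to a TSV file. The first column (or row names)
#'   holds gene identifiers.
#' @return Numeric matrix, genes in rows, organs in canonical order.
#' @export
readRpkm <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!names(tab)[1] %in% hmOrgans()) {
    genes <- tab[[1]]
    tab <- tab[, -1, drop = FALSE]
  } else {
    genes <- rownames(tab)
  }
  missing_org <- setdiff(hmOrgans(), names(tab))
  if (length(missing_org))
    stop("missing organ column(s): ", paste(missing_org, collapse = ", "))
  extra <- setdiff(names(tab), hmOrgans())
  if (length(extra))
    stop("unexpected column(s): ", paste(extra, collapse = ", "))
  mat <- as.matrix(tab[, hmOrgans(), drop = FALSE])
  rownames(mat) <- genes
  validateRpkm(mat)
  mat
}

validateRpkm <- function(mat) {
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("missing value at gene '", rownames(mat)[bad[1]],
         "', organ '", colnames(mat)[bad[2]], "'")
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop("negative RPKM at gene '", rownames(mat)[bad[1]],
         "', organ '", colnames(mat)[bad[2]], "'")
  }
  invisible(mat)
}

#' Write an RPKM matrix to tab-separated text
#'
#' @param mat Genes-by-organs matrix.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeRpkm <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assign genes to low/middle/high expression tiers
#'
#' Summarizes each gene by a single statistic (default: its maximum
#' RPKM across organs) and cuts the displayed gene set into tertiles of
#' that statistic. Ties at a tertile boundary fall into the lower tier.
#'
#' @param mat Genes-by-organs RPKM matrix with at least 3 genes.
#' @param statistic \code{"max"} (default) or \code{"mean"}.
#' @return Named factor with levels \code{low}, \code{middle},
#'   \code{high}; the three tiers partition the gene set.
#' @export
tierGenes <- function(mat, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  n <- nrow(mat)
  if (n < 3L) stop("tiering needs at least 3 genes")
  stat <- switch(statistic,
                 max = apply(mat, 1L, max),
                 mean = rowMeans(mat))
  sorted <- sort(stat)
  q1 <- sorted[ceiling(n / 3)]
  q2 <- sorted[ceiling(2 * n / 3)]
  tier <- ifelse(stat <= q1, "low", ifelse(stat <= q2, "middle", "high"))
  factor(stats::setNames(tier, rownames(mat)),
         levels = c("low", "middle", "high"))
}

#' Row-normalize an expression matrix to mean zero, variance one
#'
#' Each gene row is centred and scaled using the population
#' (divide-by-n) variance. Constant rows cannot be scaled; they are
#' passed through as all-zero and flagged in the \code{"constant"}
#' attribute.
#'
#' @param mat Genes-by-organs matrix.
#' @return Matrix of the same shape; \code{attr(x, "constant")} is a
#'   named logical vector marking constant input rows.
#' @export
normalizeRows <- function(mat) {
  m <- rowMeans(mat)
  v <- rowMeans((mat - m)^2)
  constant <- v == 0
  out <- (mat - m) / sqrt(ifelse(constant, 1, v))
  out[constant, ] <- 0
  attr(out, "constant") <- stats::setNames(constant, rownames(mat))
  out
}

#' Group genes by their fruit-stage expression profiles
#'
#' Computes Euclidean distances between row-normalized fruit-stage
#' profiles and orders genes by average-linkage hierarchical clustering,
#' emulating a gene-distance-matrix display grouping.
#'
#' @param mat Genes-by-organs RPKM matrix.
#' @param fruitCols Fruit-stage columns (default [fruitOrgans()]).
#' @param k Optional number of groups to cut the tree into.
#' @param method Distance method: \code{"euclidean"} (default) or
#'   \code{"pearson"} (1 - correlation).
#' @return List with \code{distance} (symmetric matrix), \code{order}
#'   (gene display order), \code{tree} (an \code{hclust}), and
#'   \code{groups} (named vector, only when \code{k} is given).
#' @export
fruitProfileGroups <- function(mat, fruitCols = fruitOrgans(), k = NULL,
                               method = c("euclidean", "pearson")) {
  method <- match.arg(method)
  if (!all(fruitCols %in% colnames(mat)))
    stop("fruit columns absent from matrix: ",
         paste(setdiff(fruitCols, colnames(mat)), collapse = ", "))
  sub <- normalizeRows(mat[, fruitCols, drop = FALSE])
  d <- if (method == "euclidean") {
    stats::dist(sub)
  } else {
    stats::as.dist(1 - stats::cor(t(sub)))
  }
  hc <- stats::hclust(d, method = "average")
  out <- list(distance = as.matrix(d),
              order = rownames(sub)[hc$order],
              tree = hc)
  if (!is.null(k)) out$groups <- stats::cutree(hc, k = k)
  out
}

#' Peak expression stage of a gene
#'
#' The organ with maximal RPKM; ties resolve to the earliest organ in
#' the canonical order. Undefined for pseudogenes (rows at or below
#' \code{epsilon} everywhere).
#'
#' @param mat Genes-by-organs RPKM matrix (canonical column order).
#' @param gene Gene identifier.
#' @param epsilon Pseudogene expression ceiling (default 0).
#' @return Organ label.
#' @export
peakStage <- function(mat, gene, epsilon = 0) {
  if (!gene %in% rownames(mat)) stop("unknown gene: ", gene)
  row <- mat[gene, hmOrgans()]
  if (all(row <= epsilon))
    stop("peak stage undefined: '", gene, "' is flagged as a pseudogene")
  hmOrgans()[which.max(row)]
}

#' Flag putative pseudogenes
#'
#' A gene is flagged when every organ value is at or below
#' \code{epsilon} — it does not appear to be expressed in any organ
#' under analysis.
#'
#' @param mat Genes-by-organs RPKM matrix.
#' @param epsilon Non-negative ceiling (default 0 RPKM).
#' @return Character vector of flagged gene identifiers.
#' @export
callPseudogenes <- function(mat, epsilon = 0) {
  stopifnot(epsilon >= 0)
  rownames(mat)[apply(mat, 1L, function(x) all(x <= epsilon))]
}

#' Render an expression heat map
#'
#' Draws a row-normalized heat map with the organ panel in canonical
#' order and genes ordered by their fruit-stage profile grouping.
#' Requires the \pkg{pheatmap} package.
#'
#' @param mat Genes-by-organs RPKM matrix.
#' @param file Optional PNG path; when \code{NULL}, draws to the active
#'   device.
#' @param ... Passed on to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plotExpressionHeatmap <- function(mat, file = NULL, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotExpressionHeatmap requires the 'pheatmap' package")
  ord <- fruitProfileGroups(mat)$order
  z <- normalizeRows(mat)[ord, hmOrgans(), drop = FALSE]
  p <- pheatmap::pheatmap(z, cluster_rows = FALSE, cluster_cols = FALSE,
                          filename = file, ...)
  invisible(p)
}
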