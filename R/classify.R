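#' Classify one protein architecture into the HM taxonomy
#'
#' Applies the ordered rule engine to a protein's domain architecture:
#' exclusion rules first (e.g. AT1 + AAK marks an amino-acid-synthesis
#' enzyme, not a histone acetylase; an amine-oxidase domain without the
#' SWIRM domain rejects an LSD1-like demethylase candidate), then
#' provenance-tagged per-protein overrides, then the architecture rules
#' in priority order (most specific first), and finally an anchor-domain
#' fallback: when no rule matches but a superfamily anchor domain (SET,
#' JmjC, Hist_deacetyl, ...) is present, the class is assigned by
#' [nearestReferenceClass()] against the family's reference
#' architectures. Every input yields exactly one classification record.
#'
#' @param architecture An [Architecture-class] object.
#' @param rules Rule set from [loadFamilyRules()].
#' @return One-row data.frame with columns \code{protein_id},
#'   \code{status} (\code{"assigned"}, \code{"excluded"} or
#'   \code{"unclassified"}), \code{superfamily}, \code{family},
#'   \code{class_label}, \code{rule_id}, \code{evidence} and
#'   \code{reason}.
#' @export
classifyProtein <- function(architecture, rules = loadFamilyRules()) {
  stopifnot(is(architecture, "Architecture"))
  doms <- architecture@hits[, c("domain_id", "tag"), drop = FALSE]
  motifs <- architecture@motifs
  pid <- proteinId(architecture)

  rec <- function(status, superfamily = NA_character_,
                  family = NA_character_, class_label = NA_character_,
                  rule_id = NA_character_, evidence = "",
                  reason = NA_character_) {
    data.frame(protein_id = pid, status = status, superfamily = superfamily,
               family = family, class_label = class_label, rule_id = rule_id,
               evidence = evidence, reason = reason, stringsAsFactors = FALSE)
  }

  # 1. exclusion rules preempt everything
  for (ex in rules$exclusions) {
    if (ruleMatches(ex, doms, motifs)) {
      return(rec("excluded", rule_id = ex$rule_id,
                 evidence = paste(unlist(ex$required), collapse = "+"),
                 reason = ex$reason))
    }
  }

  # 2. per-protein overrides (phylogeny-informed assignments)
  ov <- rules$overrides[[pid]]
  if (!is.null(ov)) {
    return(rec("assigned", superfamily = ov$superfamily, family = ov$family,
               class_label = if (is.null(ov[["class"]])) NA_character_
                             else ov[["class"]],
               rule_id = paste0("override:", pid),
               evidence = if (is.null(ov$provenance)) "" else ov$provenance))
  }

  if (nrow(doms) == 0L && !length(motifs))
    return(rec("unclassified", reason = "no domains"))

  # 3. architecture rules, highest priority (lowest number) first
  for (r in rules$rules) {
    if (ruleMatches(r, doms, motifs)) {
      cls <- if (is.null(r[["class"]])) NA_character_ else r[["class"]]
      evid <- paste(unique(c(unlist(r$required),
                             unlist(r$motif_required))), collapse = "+")
      if (is.na(cls) && isTRUE(r$class_by_reference)) {
        nr <- nearestReferenceClass(doms$domain_id,
                                    rules$references[[r$family]])
        cls <- nr$class
        evid <- paste0(evid, "; nearest-reference:", nr$label)
      }
      return(rec("assigned", superfamily = r$superfamily, family = r$family,
                 class_label = cls, rule_id = r$rule_id, evidence = evid))
    }
  }

  # 4. anchor-domain fallback with nearest-reference class assignment
  for (anchor in names(rules$anchors)) {
    if (anchor %in% doms$domain_id) {
      a <- rules$anchors[[anchor]]
      refs <- rules$references[[a$family]]
      cls <- NA_character_
      evid <- paste0("anchor:", anchor)
      if (!is.null(refs)) {
        nr <- nearestReferenceClass(doms$domain_id, refs)
        cls <- nr$class
        evid <- paste0(evid, "; nearest-reference:", nr$label)
      }
      return(rec("assigned", superfamily = a$superfamily, family = a$family,
                 class_label = cls, rule_id = "nearest-reference",
                 evidence = evid))
    }
  }

  rec("unclassified", reason = "no matching rule")
}

#' Nearest-reference class assignment
#'
#' Assigns a class by similarity to labelled references: maximal shared-
#' domain Jaccard similarity when the query is a domain architecture, or
#' maximal k-mer cosine similarity when the query is a residue sequence.
#' Ties are broken deterministically by the lexicographically smallest
#' reference label.
#'
#' @param query Character vector of domain labels, an
#'   [Architecture-class], or a single residue sequence string.
#' @param references List of references, each a list with \code{label},
#'   \code{class} and \code{domains} and/or \code{sequence}.
#' @param k k-mer size for sequence similarity (default 3).
#' @return List with \code{class}, \code{label} and \code{similarity};
#'   when \code{references} is empty, \code{class} is \code{NA} with a
#'   \code{reason}.
#' @export
nearestReferenceClass <- function(query, references, k = 3) {
  if (is.null(references) || !length(references))
    return(list(class = NA_character_, label = NA_character_,
                similarity = NA_real_, reason = "no references"))
  if (is(query, "Architecture")) query <- architectureDomains(query)
  hasSeq <- any(vapply(references, function(r) !is.null(r$sequence),
                       logical(1)))
  asSequence <- hasSeq && is.character(query) && length(query) == 1L &&
    nchar(query) >= 10L && grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", query)
  sims <- vapply(references, function(ref) {
    if (asSequence && !is.null(ref$sequence)) {
      kmerCosine(query, ref$sequence, k)
    } else {
      jaccard(unique(query), unique(sub("@[NC]$", "",
                                        unlist(ref$domains))))
    }
  }, numeric(1))
  labels <- vapply(references, `[[`, character(1), "label")
  best <- which(sims == max(sims))
  # radix = C-locale byte order, so the tie-break is locale-independent
  pick <- best[order(labels[best], method = "radix")][1L]
  list(class = references[[pick]]$class, label = labels[pick],
       similarity = sims[pick])
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(0)
  length(intersect(a, b)) / length(u)
}

kmerCosine <- function(x, y, k = 3) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1), k:n))
  }
  tx <- km(x); ty <- km(y)
  shared <- intersect(names(tx), names(ty))
  if (!length(shared)) return(0)
  num <- sum(as.numeric(tx[shared]) * as.numeric(ty[shared]))
  num / sqrt(sum(as.numeric(tx)^2) * sum(as.numeric(ty)^2))
}

#' Classify a catalog of architectures and summarize counts
#'
#' Runs [classifyProtein()] on every architecture of a catalog (or an
#' explicit list of architectures) and tabulates membership: counts per
#' superfamily, per family and per class, plus the exclusion list with
#' reasons. Classification is deterministic and independent of input
#' order.
#'
#' @param x An [HMCatalog-class] or a list of [Architecture-class]
#'   objects.
#' @param rules Rule set from [loadFamilyRules()].
#' @return An object of class \code{"HMClassification"}: a list with
#'   \code{table} (one row per protein), \code{superfamilyCounts} (named
#'   integer vector), \code{familyCounts} and \code{classCounts}
#'   (data.frames), \code{exclusions} (data.frame) and \code{total}
#'   (number of proteins assigned to any HM superfamily).
#' @examples
#' cat124 <- loadCatalog()
#' cl <- classifyCatalog(cat124)
#' cl$superfamilyCounts
#' @export
classifyCatalog <- function(x, rules = loadFamilyRules()) {
  archs <- if (is(x, "HMCatalog")) catalogArchitectures(x) else x
  stopifnot(is.list(archs))
  tab <- do.call(rbind, lapply(archs, classifyProtein, rules = rules))
  if (is.null(tab))
    tab <- data.frame(protein_id = character(), status = character(),
                      superfamily = character(), family = character(),
                      class_label = character(), rule_id = character(),
                      evidence = character(), reason = character(),
                      stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  assigned <- tab[tab$status == "assigned", , drop = FALSE]
  sfLevels <- c("HAT", "HDAC", "HMT", "HDM")
  superfamilyCounts <- vapply(sfLevels, function(sf)
    sum(assigned$superfamily == sf), integer(1))

  fam <- unique(assigned[, c("superfamily", "family")])
  fam <- fam[order(fam$superfamily, fam$family), , drop = FALSE]
  fam$n <- mapply(function(sf, f)
    sum(assigned$superfamily == sf & assigned$family == f),
    fam$superfamily, fam$family)
  rownames(fam) <- NULL

  cls <- unique(assigned[, c("superfamily", "family", "class_label")])
  cls <- cls[order(cls$superfamily, cls$family, cls$class_label), ,
             drop = FALSE]
  eqNA <- function(x, y) (is.na(x) & is.na(y)) |
    (!is.na(x) & !is.na(y) & x == y)
  cls$n <- mapply(function(sf, f, cl)
    sum(assigned$superfamily == sf & assigned$family == f &
          eqNA(assigned$class_label, cl)),
    cls$superfamily, cls$family, cls$class_label)
  rownames(cls) <- NULL

  out <- list(table = tab,
              superfamilyCounts = superfamilyCounts,
              familyCounts = fam,
              classCounts = cls,
              exclusions = tab[tab$status == "excluded",
                               c("protein_id", "reason"), drop = FALSE],
              total = nrow(assigned))
  class(out) <- "HMClassification"
  out
}

#' @export
print.HMClassification <- function(x, ...) {
  cat("HM classification:", x$total, "proteins assigned,",
      nrow(x$exclusions), "excluded,",
      sum(x$table$status == "unclassified"), "unclassified\n")
  cat("  superfamilies:",
      paste(sprintf("%s=%d", names(x$superfamilyCounts),
                    x$superfamilyCounts), collapse = ", "), "\n")
  invisible(x)
}

#' Look up a family count from a classification
#'
#' @param classification An \code{"HMClassification"} object.
#' @param family Family label (e.g. \code{"HAG"}).
#' @param class_label Optional class within the family.
#' @return Integer count (0 when absent).
#' @export
familyCount <- function(classification, family, class_label = NULL) {
  a <- classification$table
  a <- a[a$status == "assigned" & a$family == family, , drop = FALSE]
  if (!is.null(class_label))
    a <- a[!is.na(a$class_label) & a$class_label == class_label, ,
           drop = FALSE]
  nrow(a)
}
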