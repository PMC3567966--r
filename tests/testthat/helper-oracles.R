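# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately use naive implementations (double loops, rank
# arithmetic) so they do not share code paths with the package.

# Exhaustive all-windows evaluation of one profile on one protein:
# score every window with an explicit position loop.
oracleWindowScan <- function(profile, sequence) {
  S <- profile@scores
  L <- ncol(S)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < L) return(data.frame(start = integer(), score = numeric()))
  out <- data.frame(start = seq_len(n - L + 1), score = NA_real_)
  for (w in out$start) {
    s <- 0
    for (j in seq_len(L)) s <- s + S[res[w + j - 1], j]
    out$score[w] <- s
  }
  out[out$score >= profile@threshold, , drop = FALSE]
}

# Rank-based tertile oracle: a gene is "low" when its min-rank is at
# most ceiling(n/3), "middle" up to ceiling(2n/3), else "high".
oracleTier <- function(stat) {
  n <- length(stat)
  r <- rank(stat, ties.method = "min")
  ifelse(r <= ceiling(n / 3), "low",
         ifelse(r <= ceiling(2 * n / 3), "middle", "high"))
}

# Brute-force closed-interval containment of gene starts in bins.
oracleAssign <- function(loci, binDf) {
  out <- list()
  for (i in seq_len(nrow(loci))) {
    g <- loci[i, ]
    if (is.na(g$chromosome)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id, bin_id = NA_character_,
        unassigned_reason = "no chromosome", stringsAsFactors = FALSE)
      next
    }
    found <- FALSE
    for (j in seq_len(nrow(binDf))) {
      b <- binDf[j, ]
      if (b$chromosome == g$chromosome && b$start <= g$start &&
          g$start <= b$end) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g$gene_id, bin_id = b$bin_id,
          unassigned_reason = "none", stringsAsFactors = FALSE)
        found <- TRUE
      }
    }
    if (!found)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id, bin_id = NA_character_,
        unassigned_reason = "outside markers", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# O(n^2) pairwise-chaining oracle for tandem clusters: connected
# components of the graph with an edge between same-chromosome genes
# whose starts differ by at most gap, computed by label propagation.
oracleClusters <- function(loci, gapKb) {
  gap <- gapKb * 1000
  loci <- loci[!is.na(loci$chromosome), , drop = FALSE]
  n <- nrow(loci)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && loci$chromosome[i] == loci$chromosome[j] &&
          abs(loci$start[i] - loci$start[j]) <= gap &&
          lab[j] > lab[i]) {
        lab[j] <- lab[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  comps <- split(seq_len(n), lab)
  comps <- Filter(function(x) length(x) >= 2, comps)
  out <- lapply(comps, function(idx) {
    g <- loci[idx, ]
    g <- g[order(g$start, g$gene_id), ]
    data.frame(chromosome = g$chromosome[1], n_members = nrow(g),
               span_bp = max(g$start) - min(g$start),
               members = paste(g$gene_id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(chromosome = character(), n_members = integer(),
                      span_bp = numeric(), members = character()))
  res <- res[order(res$chromosome, res$members), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Exhaustive rule-engine oracle: evaluate *all* exclusions/overrides/
# rules and pick the lowest priority number among matches.
oracleClassify <- function(arch, rules) {
  doms <- architectureHits(arch)[, c("domain_id", "tag")]
  motifs <- architectureMotifs(arch)
  matchesRule <- function(r) {
    ok <- TRUE
    for (req in r$required) {
      pt <- sub("@[NC]$", "", req)
      wantTag <- if (grepl("@N$", req)) "N-terminal"
                 else if (grepl("@C$", req)) "C-terminal" else NA
      hit <- doms$domain_id == pt &
        (is.na(wantTag) | doms$tag == wantTag)
      if (!any(hit)) ok <- FALSE
    }
    if (length(r$forbidden) && any(unlist(r$forbidden) %in% doms$domain_id))
      ok <- FALSE
    if (length(r$motif_required) &&
        !all(unlist(r$motif_required) %in% motifs))
      ok <- FALSE
    ok
  }
  for (ex in rules$exclusions)
    if (matchesRule(ex)) return(list(status = "excluded", reason = ex$reason))
  ov <- rules$overrides[[proteinId(arch)]]
  if (!is.null(ov))
    return(list(status = "assigned", family = ov$family,
                class_label = ov[["class"]]))
  hits <- Filter(matchesRule, rules$rules)
  if (length(hits)) {
    prio <- vapply(hits, function(r) as.integer(r$priority), integer(1))
    r <- hits[[which.min(prio)]]
    return(list(status = "assigned", family = r$family,
                class_label = r[["class"]]))
  }
  list(status = "other")
}
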