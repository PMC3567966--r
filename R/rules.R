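#' Load the family classification rule set
#'
#' Reads the structured rule file that encodes the histone-modifier
#' taxonomy: exclusion rules (evaluated first), per-protein overrides
#' (phylogeny-informed calls, provenance-tagged), ordered
#' architecture rules with explicit priorities, anchor-domain fallbacks,
#' per-family reference architectures for the nearest-reference class
#' assignment, and the Pfam/SMART/InterPro accession of every domain
#' label. The packaged default covers the four superfamilies
#' (HAT, HDAC, HMT, HDM) and their families and classes; users can ship
#' an edited copy to audit or override any rule.
#'
#' @param path Path to a rules YAML file (defaults to the packaged rule
#'   set).
#' @return A list with elements \code{exclusions}, \code{overrides},
#'   \code{rules} (sorted by priority), \code{anchors},
#'   \code{references} and \code{accessions}.
#' @export
loadFamilyRules <- function(path = system.file("extdata",
                                               "hm_family_rules.yaml",
                                               package = "chromod")) {
  raw <- yaml::read_yaml(path)
  rules <- raw$rules
  prio <- vapply(rules, function(r) as.integer(r$priority), integer(1))
  if (anyDuplicated(prio))
    stop("rule priorities must be unique")
  rules <- rules[order(prio)]
  for (r in rules) {
    if (!length(r$required) && !length(r$motif_required))
      stop("rule ", r$rule_id,
           ": required domains empty and no motif requirement")
  }
  ex <- raw$exclusions
  exprio <- vapply(ex, function(r) as.integer(r$priority), integer(1))
  ex <- ex[order(exprio)]
  list(exclusions = ex,
       overrides = raw$overrides,
       rules = rules,
       anchors = raw$anchors,
       references = raw$references,
       accessions = raw$accessions)
}

# Does a rule match an architecture? `doms` is the hits data.frame
# (domain_id, tag), `motifs` the architecture's motif vector.
ruleMatches <- function(rule, doms, motifs) {
  req <- rule$required
  if (length(req)) {
    parsed <- parseDomainTag(unlist(req))
    for (i in seq_len(nrow(parsed))) {
      hit <- doms$domain_id == parsed$domain_id[i] &
        (parsed$tag[i] == "internal" | doms$tag == parsed$tag[i])
      if (!any(hit)) return(FALSE)
    }
  }
  if (length(rule$forbidden) &&
      any(unlist(rule$forbidden) %in% doms$domain_id))
    return(FALSE)
  if (length(rule$motif_required) &&
      !all(unlist(rule$motif_required) %in% motifs))
    return(FALSE)
  TRUE
}
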