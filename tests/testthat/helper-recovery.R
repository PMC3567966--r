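# Shared end-to-end recovery harness: plant a synthetic proteome from
# family-style architecture templates, build + calibrate profiles from
# the same motif set, scan, assemble and classify, and compare against
# the planted truth.

recoveryMotifSpecs <- function(degeneracy = 0.05) {
  cons <- c(
    AT1        = "GLVAEHNGEILGFAMYR",
    BrD        = "KDAWPFMEPVDPNDAPDY",
    Hat1_N     = "WTLFQNEARFIDAYNT",
    MOZ_SAS    = "GYIKEYQGGHLIECAR",
    Chromo     = "YVVEKVLDRRVVKGQV",
    C2H2       = "YKCGLCERSFVEKSAL",
    SIR2       = "GIPDFRSPGSGLYDNLE",
    SWIRM      = "SPMEVRLFHQAFESHI",
    AOD        = "DVVVIGAGISGLTAAKLL",
    AWS        = "CSNCQNPLHDSCAPVW",
    SET        = "NHSCDPNCEIRPVRIGG",
    "Post-SET" = "CYCGSKECRGRIW",
    "F-box"    = "LPDELLVEILSRLPPR",
    JmjC       = "FEDYMRHRGEPVYIFD",
    "RING-finger" = "CAICLSEFEPGEKVRQL")
  lapply(names(cons), function(d) motifSpec(d, cons[[d]], degeneracy))
}

recoveryTemplates <- function() {
  list(
    list(domains = c("AT1"), family = "HAG", class = "HPA2-like"),
    list(domains = c("AT1", "BrD@C"), family = "HAG", class = "GCN5-like"),
    list(domains = c("Hat1_N@N", "AT1", "MOZ_SAS@C"),
         family = "HAG", class = "GML"),
    list(domains = c("Chromo@N", "C2H2", "MOZ_SAS@C"),
         family = "HAM", class = "I"),
    list(domains = c("SIR2"), family = "SRT", class = NA),
    list(domains = c("SWIRM@N", "AOD@C"), family = "HDMA", class = NA),
    list(domains = c("AWS@N", "SET", "Post-SET"),
         family = "SDG", class = "II"),
    list(domains = c("F-box@N", "JmjC@C"), family = "JMJ",
         class = "JMJD6"),
    list(domains = c("RING-finger", "JmjC@C"), family = "JMJ",
         class = "KDM3"))
}

# Returns per-protein family/class truth and predictions plus planted
# coordinate recovery of individual motif instances.
runRecovery <- function(nProteins = 45, degeneracy = 0.05,
                        quantile = 0.99, seed = 7) {
  specs <- recoveryMotifSpecs(degeneracy)
  motifs <- makeMotifSet(specs, seed = seed, blockSize = 8)
  templates <- recoveryTemplates()
  archSpecs <- lapply(seq_len(nProteins), function(i) {
    tpl <- templates[[((i - 1L) %% length(templates)) + 1L]]
    architectureSpec(sprintf("prot%03d", i), tpl$domains,
                     proteinLength = 360 + 20 * (i %% 5))
  })
  planted <- plantProteome(archSpecs, motifs, seed = seed + 1)

  profiles <- lapply(motifs, function(m)
    calibrateProfile(buildProfile(m$block, domainId = m$domainId),
                     quantile = quantile, seed = seed + 2))
  hits <- scanProteome(planted$proteome, profiles)
  rules <- loadFamilyRules()

  truthFam <- vapply(seq_len(nProteins), function(i) {
    tpl <- templates[[((i - 1L) %% length(templates)) + 1L]]
    paste(tpl$family, tpl$class, sep = "/")
  }, character(1))
  predFam <- vapply(seq_len(nProteins), function(i) {
    id <- sprintf("prot%03d", i)
    h <- hits[hits$protein_id == id, , drop = FALSE]
    arch <- assembleArchitecture(h, nchar(as.character(
      planted$proteome[[id]])), proteinId = id)
    cl <- classifyProtein(arch, rules)
    paste(cl$family, cl$class_label, sep = "/")
  }, character(1))

  # coordinate recovery: planted instance found with |start error| <= 2
  tt <- planted$truth
  coordOk <- vapply(seq_len(nrow(tt)), function(k) {
    h <- hits[hits$protein_id == tt$protein_id[k] &
                hits$domain_id == tt$domain_id[k], , drop = FALSE]
    any(abs(h$start - tt$start[k]) <= 2)
  }, logical(1))

  list(truth = truthFam, pred = predFam,
       familyAccuracy = mean(truthFam == predFam),
       coordRecovery = mean(coordOk),
       hits = hits, planted = planted, profiles = profiles)
}

# Case-study fixture: classify the packaged catalog, map loci to the
# synthetic bins and rank fruit-ripening SDG class II candidates.
runCaseStudy <- function() {
  cat124 <- loadCatalog()
  cl <- classifyCatalog(cat124)
  bt <- syntheticBinTables()
  bins <- buildBins(bt$markers, bt$binDefs)$bins
  assoc <- assignGenes(catalogLoci(cat124), bins)
  rpkm <- catalogRpkm(cat124)
  q <- hmQuery(targetFamily = "SDG", targetClass = "II",
               desiredPeakOrgans = c("B", "B10"),
               phenotypeKeyword = "fruit color")
  list(ranked = prioritizeCandidates(cl, assoc, bins, rpkm, q),
       classification = cl, bins = bins, assoc = assoc, rpkm = rpkm)
}
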