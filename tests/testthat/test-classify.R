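rules <- loadFamilyRules()

archOf <- function(domains, motifs = character(), id = "query") {
  architectureFromDomains(id, domains, motifs = motifs)
}

test_that("the rule engine reproduces the documented family assignments", {
  cases <- list(
    list(d = c("Hat1_N@N", "AT1", "MOZ_SAS@C"), sf = "HAT", f = "HAG",
         cl = "GML"),
    list(d = c("AT1"), sf = "HAT", f = "HAG", cl = "HPA2-like"),
    list(d = c("AT1", "BrD@C"), sf = "HAT", f = "HAG", cl = "GCN5-like"),
    list(d = c("ELP@N", "AT1@C"), sf = "HAT", f = "HAG", cl = "ELP3-like"),
    list(d = c("Chromo@N", "C2H2", "MOZ_SAS@C"), sf = "HAT", f = "HAM",
         cl = "I"),
    list(d = c("KAT11", "PHD", "zf-TAZ"), sf = "HAT", f = "HAC", cl = NA),
    list(d = c("TBP-kinase@N", "ubiquitin", "zf-C2HC", "BrD@C"),
         sf = "HAT", f = "HAF", cl = NA),
    list(d = c("SIR2"), sf = "HDAC", f = "SRT", cl = NA),
    list(d = c("SWIRM@N", "AOD@C"), sf = "HDM", f = "HDMA", cl = NA),
    list(d = c("F-box@N", "JmjC@C"), sf = "HDM", f = "JMJ", cl = "JMJD6"),
    list(d = c("JmjC"), sf = "HDM", f = "JMJ", cl = "JmjC-only"),
    list(d = c("RING-finger", "JmjC"), sf = "HDM", f = "JMJ", cl = "KDM3"),
    list(d = c("JmjN@N", "JmjC", "C5HC2@C"), sf = "HDM", f = "JMJ",
         cl = "KDM4"),
    list(d = c("AWS@N", "SET", "Post-SET"), sf = "HMT", f = "SDG",
         cl = "II"),
    list(d = c("PWWP@N", "PHD", "SET", "Post-SET"), sf = "HMT", f = "SDG",
         cl = "III"),
    list(d = c("PHD@N", "SET@C"), sf = "HMT", f = "SDG", cl = "IV"),
    list(d = c("SRA-YDG@N", "Pre-SET", "SET", "Post-SET"), sf = "HMT",
         f = "SDG", cl = "V"),
    list(d = c("AdoMet_Mtase"), sf = "HMT", f = "PRMT", cl = NA))
  for (cs in cases) {
    got <- classifyProtein(archOf(cs$d), rules)
    expect_identical(got$status, "assigned", label = paste(cs$d, collapse = "+"))
    expect_identical(got$superfamily, cs$sf)
    expect_identical(got$family, cs$f)
    if (is.na(cs$cl)) expect_true(is.na(got$class_label))
    else expect_identical(got$class_label, cs$cl)
  }
  # the N-terminal EFWG motif defines the HD2 deacetylases
  hdt <- classifyProtein(archOf(character(), motifs = "EFWG"), rules)
  expect_identical(c(hdt$superfamily, hdt$family), c("HDAC", "HDT"))
})

test_that("exclusion rules preempt every assignment", {
  ex1 <- classifyProtein(archOf(c("AT1", "AAK")), rules)
  expect_identical(ex1$status, "excluded")
  expect_identical(ex1$reason, "AAK co-occurrence")
  ex2 <- classifyProtein(archOf(c("AOD@C")), rules)
  expect_identical(ex2$status, "excluded")
  expect_identical(ex2$reason, "AOD without SWIRM")

  # adding AAK to any AT1-containing architecture flips it to excluded
  at1Archs <- list(c("AT1"), c("AT1", "BrD@C"),
                   c("Hat1_N@N", "AT1", "MOZ_SAS@C"), c("ELP@N", "AT1@C"))
  for (d in at1Archs) {
    before <- classifyProtein(archOf(d), rules)
    after <- classifyProtein(archOf(c(d, "AAK")), rules)
    expect_identical(before$status, "assigned")
    expect_identical(after$status, "excluded")
    expect_identical(after$reason, "AAK co-occurrence")
  }
  # removing SWIRM from an LSD1-like architecture flips it to excluded
  expect_identical(classifyProtein(archOf(c("SWIRM@N", "AOD@C")),
                                   rules)$status, "assigned")
  expect_identical(classifyProtein(archOf(c("AOD@C")), rules)$status,
                   "excluded")
})

test_that("anchored fallbacks use nearest-reference class assignment", {
  # a bare (interrupted) SET architecture matches no rule and falls back
  bare <- classifyProtein(archOf(c("SET")), rules)
  expect_identical(bare$rule_id, "nearest-reference")
  expect_identical(c(bare$superfamily, bare$family), c("HMT", "SDG"))
  expect_identical(bare$class_label, "VI")  # lexicographic tie-break VI < VII
  # a truncated class III architecture (no PWWP) still lands in III
  tr <- classifyProtein(archOf(c("PHD", "PHD", "SET", "Post-SET")), rules)
  expect_identical(tr$class_label, "III")
})

test_that("nearest-reference similarity is exact and tie-broken", {
  refs <- list(list(label = "B_ref", class = "B", domains = c("X", "Y")),
               list(label = "A_ref", class = "A", domains = c("X", "Z")))
  hit <- nearestReferenceClass(c("X", "Y"), refs)
  expect_identical(hit$class, "B")
  expect_equal(hit$similarity, 1)
  # equidistant query: lexicographically smaller label wins
  tie <- nearestReferenceClass(c("X"), refs)
  expect_identical(tie$label, "A_ref")
  expect_identical(nearestReferenceClass("Q", NULL)$reason, "no references")
})

test_that("sequence-based nearest reference recovers classes at 20% divergence", {
  aa <- aaAlphabet()
  refSeqs <- withr::with_seed(42, lapply(1:3, function(i)
    paste(sample(aa, 120, replace = TRUE), collapse = "")))
  refs <- lapply(1:3, function(i)
    list(label = paste0("class", i, "_ref"), class = paste0("class", i),
         sequence = refSeqs[[i]]))
  correct <- withr::with_seed(43, vapply(1:30, function(q) {
    trueClass <- ((q - 1) %% 3) + 1
    res <- strsplit(refSeqs[[trueClass]], "")[[1]]
    mut <- sample(120, 24)  # 20% divergence
    res[mut] <- vapply(res[mut], function(a)
      sample(setdiff(aa, a), 1), character(1))
    pred <- nearestReferenceClass(paste(res, collapse = ""), refs)
    pred$class == paste0("class", trueClass)
  }, logical(1)))
  expect_gte(mean(correct), 0.9)
})

test_that("classification matches an exhaustive rule-evaluation oracle", {
  archs <- catalogArchitectures(loadCatalog())
  got <- classifyCatalog(archs, rules)$table
  for (i in seq_along(archs)) {
    oracle <- oracleClassify(archs[[i]], rules)
    row <- got[got$protein_id == proteinId(archs[[i]]), ]
    if (oracle$status == "excluded") {
      expect_identical(row$status, "excluded")
      expect_identical(row$reason, oracle$reason)
    } else if (oracle$status == "assigned") {
      expect_identical(row$status, "assigned")
      expect_identical(row$family, oracle$family)
      if (!is.null(oracle$class_label))
        expect_identical(row$class_label, oracle$class_label)
    }
  }
})

test_that("classification is deterministic and order-independent", {
  archs <- catalogArchitectures(loadCatalog())
  shuffled <- withr::with_seed(5, sample(archs))
  a <- classifyCatalog(archs, rules)
  b <- classifyCatalog(shuffled, rules)
  expect_identical(a$superfamilyCounts, b$superfamilyCounts)
  expect_identical(a$familyCounts, b$familyCounts)
  ta <- a$table[order(a$table$protein_id), ]
  tb <- b$table[order(b$table$protein_id), ]
  rownames(ta) <- rownames(tb) <- NULL
  expect_identical(ta, tb)
  # single assignment: exactly one record per protein, one outcome each
  expect_identical(sort(a$table$protein_id),
                   sort(names(archs)))
  expect_true(all(a$table$status %in%
                    c("assigned", "excluded", "unclassified")))
  expect_true(all(xor(a$table$status == "assigned",
                      is.na(a$table$superfamily))))
})

test_that("an empty catalog yields empty tables and zero counts", {
  cl <- classifyCatalog(list(), rules)
  expect_equal(cl$total, 0L)
  expect_true(all(cl$superfamilyCounts == 0))
  expect_equal(nrow(cl$exclusions), 0L)
})
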