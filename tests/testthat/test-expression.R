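test_that("RPKM tables round-trip and are validated on read", {
  mat <- makeExpression(c("g1", "g2"), peakSpec = list(
    g1 = list(peaks = "MG", amplitude = 50),
    g2 = list(peaks = "root", amplitude = 5)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRpkm(mat, f)
  back <- readRpkm(f)
  expect_equal(back, mat)

  # a table missing an organ column is rejected, naming the column
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  df$B10 <- NULL
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readRpkm(f), "B10")

  # negative values are rejected with gene and organ named
  bad <- mat; bad["g2", "B"] <- -1
  writeRpkm(bad, f)
  expect_error(readRpkm(f), "g2.*B")
})

test_that("tier cuts match the rank-based tertile oracle", {
  # one gene per tier on well-separated maxima
  mat <- makeExpression(paste0("g", 1:3), peakSpec = list(
    g1 = list(peaks = "MG", amplitude = 1),
    g2 = list(peaks = "MG", amplitude = 10),
    g3 = list(peaks = "MG", amplitude = 100)))
  tiers <- tierGenes(mat)
  expect_identical(unname(as.character(tiers)),
                   c("low", "middle", "high"))

  # oracle agreement on many random genes, including ties
  for (seed in 1:3) {
    stat <- withr::with_seed(seed, round(stats::rexp(333, 0.1), 1))
    m <- matrix(rep(stat, 10), ncol = 10,
                dimnames = list(paste0("r", seq_along(stat)), hmOrgans()))
    got <- as.character(tierGenes(m))
    expect_identical(got, oracleTier(stat))
    # tiers partition the gene set
    expect_equal(sum(table(tierGenes(m))), length(stat))
  }
  expect_error(tierGenes(m[1:2, ]), "at least 3")
})

test_that("the lowest-expressed deacetylase lands in the low tier", {
  cat124 <- loadCatalog()
  rpkm <- catalogRpkm(cat124)
  hdas <- catalogMembers(cat124)
  hdas <- hdas$id[hdas$family == "HDA"]
  tiers <- tierGenes(rpkm[hdas, ])
  expect_identical(unname(as.character(tiers["SlHDA2"])), "low")
  expect_equal(which.min(apply(rpkm[hdas, ], 1, max)),
               stats::setNames(match("SlHDA2", hdas), "SlHDA2"))
})

test_that("row normalization yields mean zero and unit variance", {
  m <- withr::with_seed(1, matrix(stats::rexp(500), nrow = 50,
                                  dimnames = list(paste0("g", 1:50),
                                                  hmOrgans())))
  m[7, ] <- 3.14  # constant row
  z <- normalizeRows(m)
  nonconst <- !attr(z, "constant")
  expect_true(all(abs(rowMeans(z[nonconst, ])) < 1e-9))
  popVar <- rowMeans((z[nonconst, ] - rowMeans(z[nonconst, ]))^2)
  expect_true(all(abs(popVar - 1) < 1e-9))
  # constant rows are zeroed and flagged
  expect_true(attr(z, "constant")[["g7"]])
  expect_true(all(z[7, ] == 0))
  # idempotence
  z2 <- normalizeRows(z)
  expect_true(max(abs(z2 - z)) < 1e-9)
  # a simple row has exactly mean zero
  expect_equal(mean(normalizeRows(rbind(a = 1:10))), 0)
})

test_that("fruit-profile distances match direct pairwise computation", {
  m <- withr::with_seed(2, matrix(stats::runif(400, 0, 50), nrow = 40,
                                  dimnames = list(paste0("g", 1:40),
                                                  hmOrgans())))
  fg <- fruitProfileGroups(m)
  z <- normalizeRows(m[, fruitOrgans()])
  for (i in 1:40) for (j in 1:40) {
    expect_equal(fg$distance[i, j],
                 sqrt(sum((z[i, ] - z[j, ])^2)), tolerance = 1e-9)
  }
  # metric properties
  expect_true(all(diag(fg$distance) == 0))
  expect_equal(fg$distance, t(fg$distance))
  d <- fg$distance
  viol <- 0
  for (i in 1:20) for (j in 1:20) for (k in 1:20)
    if (d[i, k] > d[i, j] + d[j, k] + 1e-9) viol <- viol + 1
  expect_equal(viol, 0)
})

test_that("identical profiles are adjacent; planted groups separate", {
  spec <- list(
    a1 = list(peaks = c("1cm_fruit", "2cm_fruit"), amplitude = 40),
    a2 = list(peaks = c("1cm_fruit", "2cm_fruit"), amplitude = 40),
    a3 = list(peaks = c("1cm_fruit", "2cm_fruit"), amplitude = 30),
    b1 = list(peaks = c("B", "B10"), amplitude = 40),
    b2 = list(peaks = c("B", "B10"), amplitude = 25),
    b3 = list(peaks = c("B", "B10"), amplitude = 35))
  m <- makeExpression(names(spec), peakSpec = spec, noiseSd = 0)
  fg <- fruitProfileGroups(m, k = 2)
  # identical normalized profiles -> zero distance, adjacent display order
  expect_equal(fg$distance["a1", "a2"], 0)
  expect_equal(abs(match("a1", fg$order) - match("a2", fg$order)), 1)
  # the early-fruit and ripening groups split perfectly at noise 0
  expect_length(unique(fg$groups[c("a1", "a2", "a3")]), 1L)
  expect_length(unique(fg$groups[c("b1", "b2", "b3")]), 1L)
  expect_false(fg$groups[["a1"]] == fg$groups[["b1"]])
})

test_that("peak stages follow the documented fixtures and tie-breaks", {
  rpkm <- catalogRpkm(loadCatalog())
  expect_true(peakStage(rpkm, "SlSDG33") %in% c("B", "B10"))
  expect_identical(peakStage(rpkm, "SlHDT1"), "1cm_fruit")
  expect_identical(peakStage(rpkm, "SlSDG34"), "3cm_fruit")
  # constant positive row: earliest organ in canonical order wins
  m <- matrix(5, 1, 10, dimnames = list("flat", hmOrgans()))
  expect_identical(peakStage(m, "flat"), "root")
  # pseudogenes have no defined peak
  expect_error(peakStage(rpkm, "SlHAC3"), "pseudogene")
  expect_error(peakStage(rpkm, "nope"), "unknown gene")
})

test_that("pseudogene calls respect the epsilon ceiling", {
  m <- rbind(zero = rep(0, 10),
             tiny = c(0.4, rep(0, 9)),
             expressed = c(5, rep(0, 9)))
  colnames(m) <- hmOrgans()
  expect_identical(callPseudogenes(m), "zero")
  expect_setequal(callPseudogenes(m, epsilon = 0.5), c("zero", "tiny"))
  # exactly the documented members are flagged within their families
  cat124 <- loadCatalog()
  rpkm <- catalogRpkm(cat124)
  members <- catalogMembers(cat124)
  hacs <- members$id[members$family == "HAC"]
  expect_identical(callPseudogenes(rpkm[hacs, ]), "SlHAC3")
  sdgs <- members$id[members$family == "SDG"]
  expect_setequal(callPseudogenes(rpkm[sdgs, ]),
                  c("SlSDG18", "SlSDG36"))
})
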