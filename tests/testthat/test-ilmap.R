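test_that("planted markers are all resolved at their true coordinates", {
  g <- makeGenomeAndMarkers(nChromosomes = 5, binsPerChromosome = 10,
                            seed = 21)  # 100 markers
  res <- locateMarkers(g$markers, g$genome)
  expect_equal(nrow(res), 100L)
  expect_true(all(res$status == "resolved"))
  merged <- merge(res, g$markerTable, by = "marker_id",
                  suffixes = c("", ".truth"))
  expect_true(all(merged$chromosome == merged$chromosome.truth))
  expect_true(all(merged$position == merged$position.truth))
})

test_that("repeated and absent markers are flagged", {
  marker <- paste(rep(c("A", "C", "G", "T"), 6), collapse = "")  # 24 bp
  filler <- paste(rep("A", 50), collapse = "")
  genome <- c(chr1 = paste0(filler, marker, filler, marker, filler),
              chr2 = paste0(filler, filler))
  res <- locateMarkers(c(dup = marker,
                         absent = paste(rep("G", 25), collapse = "")),
                       genome)
  expect_identical(res$status, c("ambiguous", "unresolved"))
  expect_equal(res$n_matches, c(2L, 0L))
  expect_error(locateMarkers(c(short = "ACGT"), genome), "20 bp")
})

test_that("bins are normalized intervals; broken bins are rejected", {
  mk <- data.frame(marker_id = c("m1", "m2", "m3"),
                   chromosome = c("chr1", "chr1", "chr2"),
                   position = c(5000, 100, 7000),
                   stringsAsFactors = FALSE)
  bd <- data.frame(bin_id = c("IL1-1", "IL1-2", "IL1-3"),
                   start_marker = c("m1", "m1", "m4"),
                   end_marker = c("m2", "m3", "m2"),
                   phenotype_keywords = "", stringsAsFactors = FALSE)
  built <- buildBins(mk, bd)
  # markers given in reverse coordinate order still give [100, 5000]
  expect_equal(length(built$bins), 1L)
  expect_equal(BiocGenerics::start(built$bins), 100)
  expect_equal(BiocGenerics::end(built$bins), 5000)
  expect_setequal(built$rejected$bin_id, c("IL1-2", "IL1-3"))
  expect_match(built$rejected$reason[built$rejected$bin_id == "IL1-2"],
               "different chromosomes")
  expect_match(built$rejected$reason[built$rejected$bin_id == "IL1-3"],
               "m4")
})

test_that("gene assignment honours closed intervals and documented cases", {
  bt <- syntheticBinTables()
  bins <- buildBins(bt$markers, bt$binDefs)$bins
  cat124 <- loadCatalog()
  assoc <- assignGenes(catalogLoci(cat124), bins)

  # boundary inclusion: a gene starting exactly at a bin edge is inside
  edge <- assignGenes(data.frame(gene_id = "e", chromosome = "chr1",
                                 start = 1000000), bins)
  expect_identical(edge$bin_id, "IL1-1")

  # the ripening-candidate methyltransferase maps to the fruit-color bin
  expect_identical(assoc$bin_id[assoc$gene_id == "SlSDG33"], "IL4-3-2")

  # unassigned genes carry the two distinct documented reasons
  expect_identical(assoc$unassigned_reason[assoc$gene_id == "SlHAG15"],
                   "no chromosome")
  terminal <- c("SlJMJ4", "SlPRMT6", "SlSDG5", "SlSDG35", "SlSDG43")
  expect_true(all(assoc$unassigned_reason[assoc$gene_id %in% terminal] ==
                    "outside markers"))

  # assignment is total and unique under non-overlapping bins
  expect_equal(nrow(assoc), 124L)
  expect_true(all(xor(is.na(assoc$bin_id),
                      assoc$unassigned_reason == "none")))
})

test_that("assignment equals the brute-force containment oracle", {
  set.seed(31)
  binDf <- do.call(rbind, lapply(1:50, function(i) {
    chr <- paste0("chr", sample(1:5, 1))
    s <- sample(1e6, 1)
    data.frame(bin_id = paste0("bin", i), chromosome = chr,
               start = s, end = s + sample(5e4, 1),
               stringsAsFactors = FALSE)
  }))
  bins <- GenomicRanges::GRanges(
    seqnames = binDf$chromosome,
    ranges = IRanges::IRanges(binDf$start, binDf$end),
    bin_id = binDf$bin_id, phenotype_keywords = "")
  loci <- data.frame(
    gene_id = paste0("g", 1:1000),
    chromosome = sample(c(paste0("chr", 1:6), NA), 1000, replace = TRUE),
    start = sample(1.1e6, 1000), stringsAsFactors = FALSE)
  got <- assignGenes(loci, bins)
  oracle <- oracleAssign(loci, binDf)
  key <- function(d) sort(paste(d$gene_id, d$bin_id, d$unassigned_reason))
  expect_identical(key(got), key(oracle))
})

test_that("the HPA2 cluster on chromosome 8 is recovered with its span", {
  cat124 <- loadCatalog()
  members <- catalogMembers(cat124)
  hpa2 <- members$id[members$class_label %in% "HPA2-like"]
  loci <- catalogLoci(cat124)
  cl <- detectTandemClusters(loci[loci$gene_id %in% hpa2, ])
  chr8 <- cl[cl$chromosome == "chr8", ]
  expect_equal(nrow(chr8), 1L)
  expect_equal(chr8$n_members, 8L)
  expect_lte(chr8$span_bp, 82000)
  expect_setequal(strsplit(chr8$members, ",")[[1]],
                  c("SlHAG11", "SlHAG19", "SlHAG20", "SlHAG21",
                    "SlHAG22", "SlHAG24", "SlHAG25", "SlHAG26"))
  # a single gene never forms a cluster
  expect_equal(nrow(detectTandemClusters(
    data.frame(gene_id = "solo", chromosome = "chr1", start = 100))), 0L)
})

test_that("cluster chaining equals the O(n^2) oracle and is stable", {
  loci <- withr::with_seed(17, data.frame(
    gene_id = paste0("g", 1:200),
    chromosome = paste0("chr", sample(1:4, 200, replace = TRUE)),
    start = sample(5e6, 200), stringsAsFactors = FALSE))
  got <- detectTandemClusters(loci, gapKb = 100)
  oracle <- oracleClusters(loci, gapKb = 100)
  expect_equal(nrow(got), nrow(oracle))
  expect_setequal(got$members, oracle$members)
  expect_equal(got$span_bp[order(got$members)],
               oracle$span_bp[order(oracle$members)])
  # order independence and idempotence of the chaining
  shuffled <- withr::with_seed(18, loci[sample(nrow(loci)), ])
  got2 <- detectTandemClusters(shuffled, gapKb = 100)
  expect_identical(got, got2)
})
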