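test_that("region location between parental anchors round-trips truth", {
  reg <- buildRegion(small_spec(nCopies = 3, flankLength = 12000))
  anchors <- parentAnchors(reg)
  asm <- Biostrings::DNAStringSet(
    c(chrX = as.character(regionSequence(reg))))
  loc <- locateRegion(asm, anchors$anchor5, anchors$anchor3, pad = 10000)
  p <- reg@parents
  expect_equal(loc$start, BiocGenerics::start(p)[1] - 10000)
  expect_equal(loc$end, BiocGenerics::end(p)[2] + 10000)
  expect_equal(loc$padApplied, 10000)
  expect_false(loc$truncated)

  # truncation at contig edge is recorded
  loc2 <- locateRegion(asm, anchors$anchor5, anchors$anchor3, pad = 50000)
  expect_equal(loc2$start, 1)
  expect_true(loc2$truncated)
})

test_that("fragmented or ambiguous regions raise contract errors", {
  reg <- buildRegion(small_spec(nCopies = 2))
  anchors <- parentAnchors(reg)
  g <- as.character(regionSequence(reg))
  p <- reg@parents
  split_at <- BiocGenerics::start(p)[2]
  asm2 <- Biostrings::DNAStringSet(c(c1 = substr(g, 1, split_at - 1),
                                     c2 = substr(g, split_at, nchar(g))))
  expect_error(locateRegion(asm2, anchors$anchor5, anchors$anchor3),
               "different contigs")
  asm3 <- Biostrings::DNAStringSet(c(c1 = paste0(g, g)))
  expect_error(locateRegion(asm3, anchors$anchor5, anchors$anchor3),
               "ambiguous")
  expect_error(locateRegion(asm3, "ACGTACGT", anchors$anchor3),
               ">= 30 nt")
  expect_error(
    locateRegion(Biostrings::DNAStringSet(c(x = strrep("ACGT", 100))),
                 anchors$anchor5, anchors$anchor3),
    "not found")
})

test_that("exon-1 motif search enumerates copies in order", {
  reg <- buildRegion(small_spec(nCopies = 6,
                                paratypes = c("a", "b", "c", "a", "d", "e"),
                                seed = 11))
  ct <- copyTable(reg)
  p <- reg@parents
  hits <- findCopies(regionSequence(reg), exon1Motif(reg),
                     regionEnd = BiocGenerics::start(p)[2] - 1)
  expect_length(hits, 6)
  # hit = exon-1 start; copy interval runs hit-to-hit
  expect_equal(BiocGenerics::start(hits), ct$start + 500)
  expect_equal(BiocGenerics::end(hits)[-6],
               BiocGenerics::start(hits)[-1] - 1)
  expect_identical(names(hits), as.character(1:6))

  # motif absent from a copy-free region: empty result, not an error
  empty <- findCopies(strrep("ACGT", 100), strrep("AC", 15))
  expect_length(empty, 0)
  expect_error(findCopies(regionSequence(reg), "ACGTACGT"), ">= 20 nt")
})

test_that("ORF calling translates spliced exons and flags premature stops", {
  res <- callOrf("ATGAAATAA")
  expect_identical(res$protein, "MK")
  expect_true(res$orfIntact)
  expect_true(is.na(res$prematureStopOffset))

  # engineered internal stop
  res2 <- callOrf("ATGAAATAAAAATGA")
  expect_false(res2$orfIntact)
  expect_identical(res2$prematureStopOffset, 3L)
  expect_identical(res2$protein, "MK")

  # spliced layout: exons (1-3) + (7-9) of ATGxxxAAAyyyTAA-like sequence
  layout <- IRanges::IRanges(start = c(1, 7), end = c(3, 9))
  expect_identical(callOrf("ATGCCCAAATAG", layout)$protein, "MK")
  expect_error(callOrf("AT"), ">= 3")
})

test_that("TE insertions are recovered by consensus alignment", {
  te_seq <- paste0(strrep("TTAACC", 150), strrep("GGAATT", 50))
  te <- data.frame(copy = 2, offset = 3000, name = "roo",
                   sequence = te_seq)
  reg <- buildRegion(small_spec(nCopies = 3, teInsertions = te, seed = 5))
  copies <- region_copy_seqs(reg)
  cons <- reg@repeatTemplate
  lib <- Biostrings::DNAStringSet(c(roo = te_seq, jockey = strrep("AC", 600)))
  det <- detectTeInsertions(copies, cons, teLibrary = lib,
                            exonLayout = reg@spec@exonLayout)
  expect_equal(nrow(det), 1)
  expect_equal(det$copy, 2)
  expect_equal(det$offset, 3001)
  expect_equal(det$length, nchar(te_seq))
  expect_identical(det$te, "roo")
  expect_identical(det$location, "intronic")

  # identical copy: nothing reported
  expect_equal(nrow(detectTeInsertions(copies[1], cons)), 0)
  expect_error(detectTeInsertions(copies[1], ""), "empty consensus")
})

test_that("TE location is classified against the exon layout", {
  layout <- IRanges::IRanges(start = c(501, 1501), end = c(1000, 2000))
  cons <- tandemCNV:::.cpp_random_seq(2500, 0.42, 33)
  ins <- strrep("TGCA", 60)
  exonic <- paste0(substr(cons, 1, 700), ins, substr(cons, 701, 2500))
  utr <- paste0(substr(cons, 1, 2200), ins, substr(cons, 2201, 2500))
  det <- detectTeInsertions(c(exonic, utr), cons, minInsert = 100,
                            exonLayout = layout)
  expect_identical(det$location, c("exonic", "UTR/intergenic"))
})

test_that("Jukes-Cantor distances follow the closed form", {
  expect_equal(jcDistance(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))["a", "b"],
               0)
  # exactly 10% differing sites -> d = 0.10733
  s1 <- strrep("ACGTACGTAC", 10)
  s2 <- s1
  for (pos in seq(5, 100, by = 10)) s2 <- mutate_base(s2, pos)
  d <- jcDistance(c(x = s1, y = s2))
  expect_equal(d["x", "y"], -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)
  expect_lt(abs(d["x", "y"] - 0.10733), 1e-5)
  expect_identical(d["x", "y"], d["y", "x"])

  # saturation boundary p >= 0.75
  expect_error(jcDistance(c(a = "AAAAAAAA", b = "CCCCCCAA")), ">= 0.75")

  # complete deletion removes gap columns globally
  m <- c(a = "AC-TACGT", b = "ACGTACGA", c = "ACTTACGT")
  dc <- jcDistance(m, completeDeletion = TRUE)
  # column 3 (the only b/c difference inside a gap column) is removed
  # globally, leaving one difference among seven retained sites
  expect_equal(dc["b", "c"], -0.75 * log(1 - 4 * (1 / 7) / 3))
})

test_that("Jukes-Cantor agrees with an independent implementation", {
  skip_if_not_installed("ape")
  msa <- random_msa(5, 600, 0.04, seed = 19)
  d <- jcDistance(msa)
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(msa), ""), identity)))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  expect_equal(unname(d), unname(ref[names(msa), names(msa)]),
               tolerance = 1e-12)
  # JC inflates the raw proportion
  mat <- do.call(rbind, strsplit(msa, ""))
  for (i in 1:4) for (j in (i + 1):5) {
    p <- mean(mat[i, ] != mat[j, ])
    expect_gte(d[i, j], p)
  }
})
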