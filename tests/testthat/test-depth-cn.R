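# Depth-based copy-number genotyping. The heavier parameter-recovery
# study lives in test-acceptance.R; tests here use kb-to-Mb scale builds.

test_that("synthetic single-repeat references honor their invariants", {
  reg <- buildRegion(small_spec(nCopies = 5,
                                paratypes = letters[1:5], seed = 31))
  refs <- buildSyntheticReferences(regionSequence(reg), reg@copies,
                                   reg@parents, exon1Motif(reg))
  expect_length(refs, 5)
  glen <- length(regionSequence(reg))
  anchors <- parentAnchors(reg)
  for (i in seq_along(refs)) {
    # length = contig - (n-1) repeats - both parents
    expect_equal(nchar(refs[[i]]$sequence),
                 glen - 4 * 7600 - 2 * (3800 + 1000))
    expect_equal(IRanges::width(refs[[i]]$target), 7600)
    # retained repeat is the source copy
    tgt <- substr(refs[[i]]$sequence,
                  BiocGenerics::start(refs[[i]]$target),
                  BiocGenerics::end(refs[[i]]$target))
    expect_identical(tgt, region_copy_seqs(reg)[i])
    # no parental anchor sequence survives
    expect_false(grepl(anchors$anchor5, refs[[i]]$sequence, fixed = TRUE))
    expect_false(grepl(anchors$anchor3, refs[[i]]$sequence, fixed = TRUE))
  }
  expect_error(buildSyntheticReferences(regionSequence(reg),
                                        IRanges::IRanges(), reg@parents),
               "zero annotated copies")
})

test_that("depth profiles are normalized to unit reference-wide mean", {
  depth <- c(rep(10, 1000), rep(30, 500), rep(10, 750))
  prof <- profileFromDepth(depth, binSize = 100)
  expect_length(prof@normalized, ceiling(2250 / 100))
  w <- c(rep(100, 22), 50)
  expect_equal(sum(prof@normalized * w) / sum(w), 1, tolerance = 1e-12)
  expect_equal(prof@raw[1], 10)
  expect_error(profileFromDepth(numeric(0)), "empty")
})

test_that("flat profiles yield no call size and unreliable estimates", {
  prof <- profileFromDepth(rep(20, 10000), binSize = 100)
  res <- callTarget(prof, IRanges::IRanges(2001, 4000))
  expect_equal(res$raw, 1)
  expect_equal(res$callSize, 0)
  expect_false(res$reliable)
  expect_error(callTarget(prof, IRanges::IRanges(9000, 12000)),
               "outside profile")
})

test_that("call size filters implausible targets", {
  # elevated run of exactly 7.6 kb intersecting the target: reliable
  d1 <- c(rep(10, 20000), rep(60, 7600), rep(10, 20000))
  r1 <- callTarget(profileFromDepth(d1), IRanges::IRanges(20001, 27600))
  expect_equal(r1$callSize, 7600)
  expect_true(r1$reliable)
  # elevation spread over 10 kb (mis-specified reference): unreliable
  d2 <- c(rep(10, 20000), rep(60, 10000), rep(10, 20000))
  r2 <- callTarget(profileFromDepth(d2), IRanges::IRanges(20001, 27600))
  expect_equal(r2$callSize, 10000)
  expect_false(r2$reliable)
})

test_that("aggregation averages reliable references, rounds, subtracts one", {
  est <- data.frame(raw = c(6.1, 5.9, 6.0, 6.05, 5.95),
                    callSize = 7600, reliable = TRUE)
  cn <- aggregateCn(est)
  expect_equal(anrd(cn), 6, tolerance = 1e-12)
  expect_equal(cn@rounded, 6)
  expect_equal(correctedCN(cn), 5)
  expect_identical(cnStatus(cn), "ok")

  # rounding half away from zero, then the -1 correction
  est2 <- data.frame(raw = rep(7.5, 4), callSize = 7600, reliable = TRUE)
  expect_equal(correctedCN(aggregateCn(est2)), 7)

  # fewer reliable references than the minimum: no call, not an error
  est3 <- data.frame(raw = rep(6, 6), callSize = c(rep(7600, 3), rep(100, 3)),
                     reliable = c(rep(TRUE, 3), rep(FALSE, 3)))
  cn3 <- aggregateCn(est3)
  expect_identical(cnStatus(cn3), "no call")
  expect_true(is.na(correctedCN(cn3)))

  # unreliable references are excluded from the ANRD
  est4 <- data.frame(raw = c(6, 6, 6, 6, 40),
                     reliable = c(rep(TRUE, 4), FALSE))
  expect_equal(anrd(aggregateCn(est4)), 6)
})

test_that("self-mapping a one-copy strain gives unit normalized depth", {
  reg <- buildRegion(tandemRegionSpec(nCopies = 1, flankLength = 30000,
                                      seed = 41))
  reads <- simulateReads(reg, coverage = 10, seed = 8)
  prof <- computeDepth(reads, as.character(regionSequence(reg)), seed = 2)
  expect_gt(prof@mapped / length(reads@sequences), 0.98)
  tgt <- copyTable(reg)
  res <- callTarget(prof, IRanges::IRanges(tgt$start, tgt$end),
                    gainThreshold = 1.5)
  expect_equal(res$raw, 1, tolerance = 0.05)
  expect_error(computeDepth(character(0), "ACGTACGT"), "empty read set")
})

test_that("collapsed-copy depth counts copies plus parental capture", {
  # five copies + both parents captured on a single-repeat reference:
  # normalized target depth approximately 6
  ref_strain <- buildRegion(tandemRegionSpec(
    nCopies = 5, paratypes = letters[1:5], flankLength = 1.5e6,
    seed = 100))
  refs <- buildSyntheticReferences(regionSequence(ref_strain),
                                   ref_strain@copies, ref_strain@parents)
  strain <- buildRegion(tandemRegionSpec(nCopies = 5, flankLength = 1.5e6,
                                         seed = 100))
  reads <- simulateReads(strain, coverage = 12, seed = 55)
  prof <- computeDepth(reads, refs[[2]], seed = 9)
  res <- callTarget(prof, refs[[2]]$target)
  expect_equal(res$raw, 6, tolerance = 0.3)
  expect_true(res$reliable)
  expect_gte(res$callSize, 7200)
  expect_lte(res$callSize, 8000)

  # ANRD from references built from two different strains agrees
  ref_strain2 <- buildRegion(tandemRegionSpec(
    nCopies = 4, paratypes = c("b", "c", "d", "e"), flankLength = 1.5e6,
    seed = 100))
  refs2 <- buildSyntheticReferences(regionSequence(ref_strain2),
                                    ref_strain2@copies,
                                    ref_strain2@parents)
  prof2 <- computeDepth(reads, refs2[[2]], seed = 9)
  res2 <- callTarget(prof2, refs2[[2]]$target)
  expect_equal(res2$raw, res$raw, tolerance = 0.05 * res$raw)
})

test_that("the fused simulate-and-map path matches the two-step pipeline", {
  reg <- buildRegion(tandemRegionSpec(nCopies = 2, flankLength = 30000,
                                      seed = 9))
  g <- as.character(regionSequence(reg))
  refs <- buildSyntheticReferences(g, reg@copies, reg@parents)
  idx <- lapply(refs, buildDepthIndex)
  reads <- simulateReads(g, coverage = 6, seed = 123)
  n_reads <- round(6 * nchar(g) / 100)
  fused <- tandemCNV:::.cpp_sim_and_map(
    lapply(idx, function(x) x$ptr), g, 100L, as.integer(n_reads), 0.001,
    123 * 1000 + 31, 25L, (400 + seq_along(idx)) * 1000 + 47)
  for (i in seq_along(idx)) {
    two <- computeDepth(reads, idx[[i]], seed = 400 + i)
    expect_identical(profileFromDepth(fused[[i]]$depth)@normalized,
                     two@normalized)
  }
})

test_that("per-base depth tables substitute for mapping", {
  tmp <- tempfile(fileext = ".tsv")
  write.table(data.frame(contig = "ref", pos = 1:5000,
                         depth = rep(c(10, 20), c(3000, 2000))),
              tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  depth <- readDepthTsv(tmp)
  prof <- computeDepth(NULL, NULL, depth = depth, binSize = 100)
  expect_length(prof@normalized, 50)
  expect_equal(prof@raw[1], 10)
  unlink(tmp)
})
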