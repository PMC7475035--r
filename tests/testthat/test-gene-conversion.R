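test_that("parental composites occupy their homology intervals", {
  tmpl <- tandemCNV:::.cpp_random_seq(1000, 0.42, 71)
  p5 <- substr(tmpl, 1, 400)
  p3 <- substr(tmpl, 601, 1000)
  comp <- buildComposite(p5, p3, IRanges::IRanges(1, 400),
                         IRanges::IRanges(601, 1000), 1000)
  expect_equal(nchar(comp), 1000)
  expect_identical(substr(comp, 1, 400), p5)
  expect_identical(substr(comp, 601, 1000), p3)
  expect_identical(substr(comp, 401, 600), strrep("-", 200))

  expect_error(buildComposite(p5, p3, IRanges::IRanges(1, 400),
                              IRanges::IRanges(300, 699), 1000),
               "overlapping")
  expect_error(buildComposite(p5, "ACG", IRanges::IRanges(1, 400),
                              IRanges::IRanges(601, 1000), 1000),
               "lengths")
})

test_that("condensation retains exactly the polymorphic gap-free columns", {
  m <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  expect_equal(condenseAlignment(m)$n, 0)

  m2 <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACTTACGT")
  pa2 <- condenseAlignment(m2)
  expect_equal(pa2$n, 1)
  expect_equal(pa2$columns, 3)

  # planted polymorphic columns recovered exactly; gap columns excluded
  set.seed(44)
  L <- 400
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- lapply(1:4, function(i) base)
  poly_cols <- sort(sample(setdiff(1:L, 50), 60))
  for (cc in poly_cols) seqs[[2]][cc] <- setdiff(c("A", "C", "G", "T"),
                                                 base[cc])[1]
  seqs[[3]][50] <- "-"  # gap column must be dropped, polymorphic or not
  msa <- vapply(seqs, paste, character(1), collapse = "")
  pa <- condenseAlignment(msa)
  expect_equal(pa$columns, poly_cols)
  expect_error(condenseAlignment(m2[1:2]), ">= 3 sequences")
})

test_that("zero-mismatch fragments are maximal agreement runs", {
  states <- rbind(s1 = c("A", "A", "A", "A", "A", "A"),
                  s2 = c("A", "A", "C", "A", "A", "A"),
                  s3 = c("C", "G", "A", "C", "G", "C"))
  pa <- list(states = states, columns = c(10, 20, 30, 40, 50, 60), n = 6)
  fr <- findFragments(pa)
  # s1/s2 agree in runs 1-2 and 4-6; s1/s3 and s2/s3 nowhere for >= 2
  f12 <- fr[fr$seq1 == "s1" & fr$seq2 == "s2", ]
  expect_equal(nrow(f12), 2)
  expect_equal(sort(f12$score), c(2, 3))
  expect_equal(f12$start[f12$score == 3], 40)
  expect_equal(f12$end[f12$score == 3], 60)
  expect_equal(nrow(fr[fr$seq2 == "s3" | fr$seq1 == "s3", ]), 0)

  # a pair agreeing everywhere spans all polymorphic sites
  pa2 <- list(states = rbind(x = c("A", "C", "A"), y = c("A", "C", "A"),
                             z = c("C", "A", "G")),
              columns = c(5, 9, 14), n = 3)
  fr2 <- findFragments(pa2)
  expect_equal(fr2$score[fr2$seq1 == "x" & fr2$seq2 == "y"], 3)

  # no internal pairwise mismatch inside any reported fragment
  msa <- random_msa(5, 500, 0.05, seed = 3)
  pa3 <- condenseAlignment(msa)
  fr3 <- findFragments(pa3)
  for (r in sample(nrow(fr3), 25)) {
    i <- fr3$seq1[r]; j <- fr3$seq2[r]
    run <- fr3$startCol[r]:fr3$endCol[r]
    expect_true(all(pa3$states[i, run] == pa3$states[j, run]))
  }
})

test_that("fully homogenized pairs yield the whole-length fragment", {
  # an identical pair agrees at every polymorphic column, so its fragment
  # spans the whole condensed alignment; because column permutation
  # preserves each pair's agreement pattern, such a pair is invariant
  # under the null (p = 1) -- the permutation test detects tracts against
  # residual divergence of the pair, not complete homogenization
  msa <- random_msa(6, 1500, 0.06, seed = 9)
  msa["s2"] <- msa["s1"]
  pa <- condenseAlignment(msa)
  fr <- fragmentSignificance(pa, findFragments(pa), nPerm = 2000, seed = 1)
  full <- fr[fr$seq1 == "s1" & fr$seq2 == "s2", ]
  expect_equal(max(full$score), pa$n)  # whole-length fragment
  expect_equal(full$p[which.max(full$score)], 1)
  # a near-complete tract in a pair that still disagrees elsewhere is
  # flagged
  msa2 <- random_msa(6, 1500, 0.06, seed = 10,
                     convert = list(donor = 1, recipient = 2,
                                    start = 1, end = 1350))
  pa2 <- condenseAlignment(msa2)
  fr2 <- fragmentSignificance(pa2, findFragments(pa2), nPerm = 2000,
                              seed = 1)
  big <- fr2[fr2$seq1 == "s1" & fr2$seq2 == "s2", ]
  expect_true(big$significant[which.max(big$score)])
})

test_that("adjusted p is monotone in fragment score and bounded below", {
  msa <- random_msa(6, 1200, 0.06, seed = 13,
                    convert = list(donor = 1, recipient = 4,
                                   start = 300, end = 700))
  pa <- condenseAlignment(msa)
  fr <- fragmentSignificance(pa, findFragments(pa), nPerm = 2000, seed = 2)
  ord <- order(fr$score)
  expect_true(all(diff(fr$p.adj[ord]) <= 1e-12))
  expect_true(all(fr$p.adj >= fr$p - 1e-12))
  expect_true(all(fr$p > 0))
})

test_that("tiny alignments fall back to exhaustive enumeration", {
  states <- rbind(a = c("A", "A", "A", "A", "A"),
                  b = c("A", "A", "A", "A", "C"),
                  c = c("C", "C", "C", "C", "A"))
  pa <- list(states = states, columns = 1:5, n = 5)
  fr <- findFragments(pa)
  out <- fragmentSignificance(pa, fr, nPerm = 10000, seed = 1)
  # 5! = 120 orders enumerated; a/b agree at 4 of 5 columns, so every
  # order where the disagreeing column is not interior gives a run of 4
  f4 <- out[out$score == 4, ]
  exact <- (2 / 5) * 120  # disagreement at either end preserves a 4-run
  expect_equal(f4$p, (exact + 1) / 121, tolerance = 1e-12)

  # Monte Carlo agrees with enumeration on the same small input
  # (raw proportions compared: the +1/(n+1) corrections differ by design
  # between 120 enumerated orders and 20000 draws)
  mc <- tandemCNV:::.cpp_perm_max_runs(
    tandemCNV:::.pair_agreement_matrix(states)$agree, 20000, 5)
  exh <- tandemCNV:::.cpp_exhaustive_max_runs(
    tandemCNV:::.pair_agreement_matrix(states)$agree)
  raw_mc <- mean(apply(mc, 1, max) >= 4)
  raw_exh <- mean(apply(exh, 1, max) >= 4)
  expect_lt(abs(raw_mc - raw_exh), 4 * sqrt(raw_exh * (1 - raw_exh) / 20000))
})

test_that("permutation engine is seed-deterministic", {
  msa <- random_msa(5, 800, 0.06, seed = 21)
  pa <- condenseAlignment(msa)
  fr <- findFragments(pa)
  a <- fragmentSignificance(pa, fr, nPerm = 1000, seed = 7)
  b <- fragmentSignificance(pa, fr, nPerm = 1000, seed = 7)
  expect_identical(a$p.adj, b$p.adj)
})

test_that("planted tracts are detected and summaries attribute them", {
  hits <- 0
  for (i in 1:12) {
    msa <- random_msa(8, 2500, 0.05, seed = 100 + i,
                      convert = list(donor = 2, recipient = 6,
                                     start = 1000, end = 1500))
    pa <- condenseAlignment(msa)
    fr <- fragmentSignificance(pa, findFragments(pa), nPerm = 1000,
                               seed = i)
    sig <- fr[fr$significant, ]
    if (nrow(sig) && any(sig$seq1 == "s2" & sig$seq2 == "s6"))
      hits <- hits + 1
  }
  expect_gte(hits, 10)

  msa <- random_msa(8, 2500, 0.05, seed = 250,
                    convert = list(donor = 2, recipient = 6,
                                   start = 1000, end = 1500))
  pa <- condenseAlignment(msa)
  fr <- fragmentSignificance(pa, findFragments(pa), nPerm = 2000, seed = 1)
  s <- summarizeEvents(fr, groups = setNames(
    c("e", "x", "x", "x", "x", "x", "x", "x"),
    paste0("s", c(2, 1, 3:8))))
  ev <- s$perSequence
  expect_gt(ev$events[ev$id == "s2"], 0)
  expect_equal(sum(s$histogram$events), nrow(fr[fr$significant, ]))
  # events never involve an uninvolved copy
  expect_equal(ev$events[ev$id == "s3"], 0)
})
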