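cal_cn <- list(sample = "ISO1F", counts = c(sw = 2, shared = 14),
               efficiency = c(sw = 2, shared = 2, Tpi = 2))

# Ct table for samples with given per-X family CN (female pools, 2 X)
ct_for_cn <- function(cn_values, noiseSd = 0, replicates = 3, seed = 1,
                      efficiency = cal_cn$efficiency) {
  qs <- do.call(rbind, lapply(seq_along(cn_values), function(i) {
    data.frame(sample = names(cn_values)[i],
               amplicon = c("sw", "shared", "Tpi"),
               quantity = c(2, 2 + 2 * cn_values[i], 2))
  }))
  qs <- rbind(qs, data.frame(sample = "ISO1F",
                             amplicon = c("sw", "shared", "Tpi"),
                             quantity = c(2, 14, 2)))
  simulateCt(qs, efficiency, noiseSd = noiseSd, replicates = replicates,
             seed = seed)
}

test_that("relative quantities invert the amplification model", {
  ct <- ct_for_cn(c(s6 = 6, s3 = 3))
  r <- relativeQuantity(ct, cal_cn, "shared", "Tpi")
  expect_equal(r[["ISO1F"]], 1)                 # calibrator ratio is 1
  expect_equal(r[["s6"]], 1, tolerance = 1e-9)  # 14 copies = calibrator
  expect_equal(r[["s3"]], 8 / 14, tolerance = 1e-9)

  # E = 2, target one cycle below the calibrator, reference equal -> 2
  ct2 <- data.frame(sample = rep(c("cal", "s"), each = 2),
                    amplicon = rep(c("t", "ref"), 2),
                    replicate = 1,
                    ct = c(20, 18, 19, 18))
  r2 <- relativeQuantity(ct2, list(sample = "cal",
                                   efficiency = c(t = 2, ref = 2)),
                         "t", "ref")
  expect_equal(r2[["s"]], 2)
  expect_error(relativeQuantity(ct2, list(sample = "cal",
                                          efficiency = c(t = 2, ref = 2)),
                                "t", "absent"),
               "missing")
})

test_that("replicate scatter beyond the QC threshold is flagged", {
  ct <- data.frame(sample = "s", amplicon = c("t", "t", "t"),
                   replicate = 1:3, ct = c(20, 21.5, 20.2))
  expect_warning(tandemCNV:::.mean_ct(ct), "SD")
})

test_that("dual-amplicon subtraction recovers absolute copy numbers", {
  # ratios (1, 1) against the 2/14 female calibrator: family 12, per-X 6
  ct <- ct_for_cn(c(s = 6))
  res <- cnFromAmplicons(ct, cal_cn, xDose = 2)
  s <- res[res$sample == "s", ]
  expect_equal(s$swCN, 2, tolerance = 1e-9)
  expect_equal(s$sharedCN, 14, tolerance = 1e-9)
  expect_equal(s$familyCN, 12, tolerance = 1e-9)
  expect_equal(s$perX, 6, tolerance = 1e-9)
  expect_equal(s$cn, 6L)

  # calibrator self-consistency
  iso <- res[res$sample == "ISO1F", ]
  expect_equal(iso$cn, 6L)
  expect_equal(iso$familyCN, 12, tolerance = 1e-9)

  # deletion genotype: shared equals sw, family CN 0
  del <- cnFromAmplicons(ct_for_cn(c(d0 = 0)), cal_cn, xDose = 2)
  expect_equal(del$cn[del$sample == "d0"], 0L)

  # duplication genotype at twice the reference region, hemizygous pool
  qs <- data.frame(sample = rep(c("dup", "ISO1F"), each = 3),
                   amplicon = rep(c("sw", "shared", "Tpi"), 2),
                   quantity = c(1, 13, 2, 2, 14, 2))
  dup <- cnFromAmplicons(simulateCt(qs, cal_cn$efficiency), cal_cn,
                         xDose = 1)
  expect_equal(dup$cn[dup$sample == "dup"], 12L)
})

test_that("noise-free simulator tables invert to planted quantities", {
  planted <- c(a = 2, b = 5, c = 9, d = 12)
  res <- cnFromAmplicons(ct_for_cn(planted), cal_cn, xDose = 2)
  res <- res[match(names(planted), res$sample), ]
  expect_equal(res$perX, unname(planted), tolerance = 1e-6)
  expect_equal(res$cn, unname(as.integer(planted)))
})

test_that("negative family copy numbers trip QC", {
  qs <- data.frame(sample = rep(c("bad", "ISO1F"), each = 3),
                   amplicon = rep(c("sw", "shared", "Tpi"), 2),
                   quantity = c(8, 2, 2, 2, 14, 2))
  ct <- simulateCt(qs, cal_cn$efficiency)
  expect_error(cnFromAmplicons(ct, cal_cn), "negative family")
})

test_that("expression fold changes are efficiency-corrected and calibrated", {
  cal <- list(sample = "ISO1M", efficiency = c(target = 2, clot = 2))
  make_ct <- function(fold) {
    qs <- do.call(rbind, lapply(names(fold), function(s)
      data.frame(sample = s, amplicon = c("target", "clot"),
                 quantity = c(fold[[s]], 1))))
    simulateCt(qs, cal$efficiency, replicates = 4)
  }
  # planted increases mirroring duplication genotypes: 158% and 209% more
  fc <- foldChangeExpression(make_ct(c(ISO1M = 1, dup2T = 2.58,
                                       dup4M = 3.09)),
                             cal, "target", "clot")
  by <- fc$bySample
  expect_equal(by$foldChange[by$sample == "ISO1M"], 1, tolerance = 1e-9)
  expect_equal(by$foldChange[by$sample == "dup2T"], 2.58, tolerance = 1e-6)
  expect_equal(by$foldChange[by$sample == "dup4M"], 3.09, tolerance = 1e-6)
  expect_equal(nrow(fc$perReplicate), 12)
  expect_error(foldChangeExpression(make_ct(c(x = 2)),
                                    list(sample = "absent",
                                         efficiency = cal$efficiency),
                                    "target", "clot"),
               "calibrator")
})

test_that("CN-expression regression behaves at both extremes", {
  cn <- rep(c(4, 6, 8, 10), each = 4)
  # perfectly proportional: doubling per copy on the log2 scale
  fit <- suppressWarnings(regressCnExpression(cn, cn * 1.0 - 3))
  expect_equal(fit$r.squared, 1)
  expect_equal(fit$slope, 1, tolerance = 1e-9)

  # planted independence: type-I error near nominal over 500 simulations
  set.seed(91)
  rejected <- vapply(1:500, function(i) {
    regressCnExpression(cn, rnorm(length(cn)))$p.value < 0.05
  }, logical(1))
  expect_lte(mean(rejected), 0.06)  # >= 94% non-significant
  expect_error(regressCnExpression(rep(5, 8), rnorm(8)), "variance")
  expect_error(regressCnExpression(c(1, 2), c(1, 2)), ">= 3")
})

test_that("one-way ANOVA with Tukey HSD separates strain means", {
  set.seed(17)
  same <- rnorm(12, mean = 1, sd = 0.1)
  g <- rep(c("a", "b", "c"), each = 4)
  null_fit <- anovaTukey(same, g)
  expect_gt(null_fit$p.value, 0.01)

  shifted <- c(rnorm(4, 1, 0.05), rnorm(4, 2, 0.05))
  fit <- anovaTukey(shifted, rep(c("lo", "hi"), each = 4))
  expect_lt(fit$p.value, 0.001)
  expect_lt(fit$pairwise$p.adj[1], 0.001)
  expect_error(anovaTukey(c(1, 2, 3), c("a", "a", "b")), ">= 2 replicates")
})
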