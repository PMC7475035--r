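#' @include AllClasses.R
NULL

# replicate-mean Ct per sample x amplicon with replicate-SD QC
.mean_ct <- function(ct, qcSd = 0.5) {
  stopifnot(all(c("sample", "amplicon", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be > 0")
  agg <- aggregate(ct$ct, by = list(sample = ct$sample,
                                    amplicon = ct$amplicon),
                   FUN = function(x) c(mean = mean(x), sd = sd(x),
                                       n = length(x)))
  out <- data.frame(sample = agg$sample, amplicon = agg$amplicon,
                    ct = agg$x[, "mean"], sd = agg$x[, "sd"],
                    n = agg$x[, "n"])
  flagged <- !is.na(out$sd) & out$sd > qcSd
  if (any(flagged))
    warning(sum(flagged), " sample x amplicon group(s) with replicate Ct",
            " SD > ", qcSd, " cycles")
  out
}

#' @importFrom stats aggregate
NULL

#' Efficiency-corrected relative quantity from Ct values
#'
#' Relative quantity of a target amplicon versus a reference amplicon,
#' calibrated to a reference sample:
#' `ratio = E_t^(Ct_t,cal - Ct_t,sample) / E_r^(Ct_r,cal - Ct_r,sample)`
#' with per-amplicon amplification factors `E` and replicate-mean Cts.
#' The calibrator's own ratio is 1 by construction.
#'
#' @param ct data.frame with columns `sample`, `amplicon`, `replicate`,
#'   `ct`.
#' @param calibrator list with `sample` (calibrator sample id), `counts`
#'   (named known absolute copy counts per amplicon; may be omitted for
#'   expression use) and `efficiency` (named amplification factors in
#'   (1, 2]).
#' @param amplicon target amplicon id.
#' @param referenceAmplicon reference (normalizer) amplicon id.
#' @param qcSd replicate-SD QC threshold in cycles (default 0.5); flagged
#'   groups raise a warning but are still computed.
#' @return named numeric vector of per-sample ratios.
#' @export
relativeQuantity <- function(ct, calibrator, amplicon, referenceAmplicon,
                             qcSd = 0.5) {
  eff <- calibrator$efficiency
  if (any(eff <= 1 | eff > 2)) stop("efficiencies must lie in (1, 2]")
  for (a in c(amplicon, referenceAmplicon))
    if (!a %in% names(eff)) stop("efficiency missing for amplicon ", a)
  m <- .mean_ct(ct, qcSd = qcSd)
  samples <- unique(m$sample)
  get_ct <- function(s, a) {
    v <- m$ct[m$sample == s & m$amplicon == a]
    if (length(v) != 1L)
      stop("missing Ct for sample '", s, "', amplicon '", a, "'")
    v
  }
  if (!calibrator$sample %in% samples)
    stop("calibrator sample '", calibrator$sample, "' absent from table")
  cal_t <- get_ct(calibrator$sample, amplicon)
  cal_r <- get_ct(calibrator$sample, referenceAmplicon)
  ratios <- vapply(samples, function(s) {
    eff[[amplicon]]^(cal_t - get_ct(s, amplicon)) /
      eff[[referenceAmplicon]]^(cal_r - get_ct(s, referenceAmplicon))
  }, numeric(1L))
  names(ratios) <- samples
  ratios
}

#' Copy number from the dual-amplicon subtraction scheme
#'
#' For a tandem family without family-specific primer sites, two assays are
#' run: one specific to the parental gene, one shared by the parent and all
#' family copies. Absolute counts are obtained by multiplying each
#' efficiency-corrected ratio by the calibrator's known counts; the family
#' copy number is the shared count minus the parent-specific count, divided
#' by the X dose (1 for hemizygous males, 2 for homozygous females) and
#' rounded to the nearest integer.
#'
#' @param ct data.frame with columns `sample`, `amplicon`, `replicate`,
#'   `ct`.
#' @param calibrator list with `sample`, `counts` (named, e.g.
#'   `c(sw = 2, shared = 14)` for a six-copies-per-X female calibrator)
#'   and `efficiency` (named, includes the reference amplicon).
#' @param swAmplicon parent-specific amplicon id (default `"sw"`).
#' @param sharedAmplicon parent+family amplicon id (default `"shared"`).
#' @param referenceAmplicon single-copy reference gene id (default
#'   `"Tpi"`).
#' @param xDose 1 or 2 X-chromosome doses in the sample pool.
#' @return data.frame with per-sample `swCN`, `sharedCN`, `familyCN`,
#'   `perX` and the rounded integer call `cn`.
#' @export
cnFromAmplicons <- function(ct, calibrator, swAmplicon = "sw",
                            sharedAmplicon = "shared",
                            referenceAmplicon = "Tpi", xDose = 2L) {
  if (!xDose %in% c(1L, 2L)) stop("xDose must be 1 or 2")
  counts <- calibrator$counts
  for (a in c(swAmplicon, sharedAmplicon))
    if (!a %in% names(counts))
      stop("calibrator count missing for amplicon ", a)
  r_sw <- relativeQuantity(ct, calibrator, swAmplicon, referenceAmplicon)
  r_sh <- relativeQuantity(ct, calibrator, sharedAmplicon,
                           referenceAmplicon)
  sw_cn <- r_sw * counts[[swAmplicon]]
  sh_cn <- r_sh[names(sw_cn)] * counts[[sharedAmplicon]]
  fam <- sh_cn - sw_cn
  if (any(fam < -0.5))
    stop("negative family copy number beyond tolerance (",
         format(min(fam), digits = 3), "); check amplicon assignment")
  fam[fam < 0 & fam > -1e-9] <- 0  # floating-point dust, not a QC issue
  if (any(fam < 0)) {
    warning("family copy number in [-0.5, 0) truncated to 0")
    fam[fam < 0] <- 0
  }
  perx <- fam / xDose
  data.frame(sample = names(sw_cn), swCN = unname(sw_cn),
             sharedCN = unname(sh_cn), familyCN = unname(fam),
             perX = unname(perx),
             cn = as.integer(round_half_away(unname(perx))),
             row.names = NULL)
}

#' Efficiency-corrected expression fold changes
#'
#' Per-replicate efficiency-corrected ratios against a reference gene,
#' calibrated so the calibrator sample sits at fold change 1; the sample
#' fold change is the mean across biological replicates.
#'
#' @param ct data.frame with columns `sample`, `amplicon`, `replicate`,
#'   `ct`; replicates are biological replicates.
#' @param calibrator list with `sample` and `efficiency` (named, for both
#'   amplicons).
#' @param targetAmplicon target gene amplicon id.
#' @param referenceGene reference gene amplicon id (e.g. `"clot"`).
#' @return list with `perReplicate` (data.frame `sample`, `replicate`,
#'   `ratio`, `log2`) and `bySample` (data.frame `sample`, `foldChange`,
#'   `log2`).
#' @export
foldChangeExpression <- function(ct, calibrator, targetAmplicon,
                                 referenceGene) {
  eff <- calibrator$efficiency
  for (a in c(targetAmplicon, referenceGene))
    if (!a %in% names(eff)) stop("efficiency missing for amplicon ", a)
  if (!calibrator$sample %in% ct$sample) stop("missing calibrator sample")
  nrep <- table(ct$sample[ct$amplicon == targetAmplicon])
  if (any(nrep < 2L)) stop("need >= 2 biological replicates per sample")
  m <- .mean_ct(ct[ct$sample == calibrator$sample, , drop = FALSE])
  cal_t <- m$ct[m$amplicon == targetAmplicon]
  cal_r <- m$ct[m$amplicon == referenceGene]
  tgt <- ct[ct$amplicon == targetAmplicon, ]
  ref <- ct[ct$amplicon == referenceGene, ]
  key <- paste(ref$sample, ref$replicate)
  ref_ct <- setNames(ref$ct, key)
  ratio <- eff[[targetAmplicon]]^(cal_t - tgt$ct) /
    eff[[referenceGene]]^(cal_r - ref_ct[paste(tgt$sample, tgt$replicate)])
  per <- data.frame(sample = tgt$sample, replicate = tgt$replicate,
                    ratio = unname(ratio), log2 = log2(unname(ratio)))
  fc <- tapply(per$ratio, per$sample, mean)
  by_sample <- data.frame(sample = names(fc), foldChange = as.numeric(fc),
                          log2 = log2(as.numeric(fc)), row.names = NULL)
  list(perReplicate = per, bySample = by_sample)
}

#' Regress log2 expression fold change on copy number
#'
#' Ordinary least squares with each biological replicate as one point.
#'
#' @param cn numeric copy numbers (one per point).
#' @param log2fc numeric log2 fold changes (one per point).
#' @return list with `slope`, `intercept`, `r.squared`, `p.value` (two
#'   sided, slope).
#' @export
regressCnExpression <- function(cn, log2fc) {
  if (length(cn) < 3L) stop("need >= 3 points")
  if (var(cn) == 0) stop("zero copy-number variance")
  fit <- lm(log2fc ~ cn)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r.squared = s$r.squared,
       p.value = unname(s$coefficients[2L, 4L]))
}

#' @importFrom stats coef
NULL

#' One-way ANOVA with Tukey--Kramer HSD post hoc
#'
#' @param values numeric responses (e.g. expression fold changes).
#' @param groups factor/character group labels (e.g. strain).
#' @return list with `F`, `df`, `p.value` and `pairwise` (data.frame of
#'   Tukey-adjusted pairwise p-values and mean differences).
#' @export
anovaTukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L))
    stop("every group needs >= 2 replicates")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$groups
  pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                         p.adj = tk[, "p adj"], row.names = NULL)
  list(F = s[["F value"]][1L],
       df = c(s[["Df"]][1L], s[["Df"]][2L]),
       p.value = s[["Pr(>F)"]][1L], pairwise = pairwise)
}
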