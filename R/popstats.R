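#' @include AllClasses.R
NULL

.vst_core <- function(cn, population) {
  vT <- var(cn)
  sizes <- tapply(cn, population, length)
  vars <- tapply(cn, population, var)
  vS <- sum(sizes * vars) / sum(sizes)
  list(vT = vT, vS = vS, vst = (vT - vS) / vT)
}

#' V_ST population differentiation of copy-number variation
#'
#' The copy-number analog of F_ST: `V_ST = (V_T - V_S) / V_T`, where `V_T`
#' is the total variance of copy number among all individuals and `V_S`
#' the average within-population variance weighted by population size.
#' Sample variances use the n-1 denominator. Accepts rounded integer CNs,
#' raw read-depth values, or their log2 alike.
#'
#' @param cn numeric copy numbers, one per individual.
#' @param population population labels (>= 2 populations).
#' @return a [VstResult-class] (no p-value; see [vstNull()]).
#' @export
#' @examples
#' vst(c(4, 4, 6, 8, 8, 10), rep(c("p1", "p2"), each = 3))
vst <- function(cn, population) {
  population <- as.character(population)
  stopifnot(length(cn) == length(population))
  if (length(unique(population)) < 2L) stop("need >= 2 populations")
  core <- .vst_core(cn, population)
  if (!is.finite(core$vT) || core$vT == 0)
    stop("total variance is zero: V_ST undefined")
  new("VstResult", vst = core$vst, vT = core$vT, vS = core$vS,
      p = NA_real_, nPerm = 0L, seed = NA_integer_)
}

#' Monte Carlo null for V_ST
#'
#' Resamples population labels (by default permutation without
#' replacement; bootstrap with replacement by flag), recomputes V_ST each
#' time, and reports `p = (#resampled V_ST >= observed + 1) / (n + 1)`,
#' which is never 0.
#'
#' @param cn numeric copy numbers.
#' @param population population labels.
#' @param n number of resamples (default 10000, >= 100).
#' @param method `"permute"` (exchangeability null) or `"bootstrap"`.
#' @param seed integer seed.
#' @return a [VstResult-class] with the Monte Carlo p filled in.
#' @export
vstNull <- function(cn, population, n = 10000L,
                    method = c("permute", "bootstrap"), seed = 1L) {
  method <- match.arg(method)
  if (n < 100L) stop("need >= 100 resamples")
  obs <- vst(cn, population)
  population <- as.character(population)
  pops <- unique(population)
  idx <- lapply(pops, function(p) which(population == p))
  sizes <- lengths(idx)
  N <- length(cn)
  null_vst <- with_seed(seed, vapply(seq_len(n), function(i) {
    x <- if (method == "permute") cn[sample.int(N)] else
      cn[sample.int(N, N, replace = TRUE)]
    vT <- var(x)
    if (vT == 0) return(0)
    pos <- 0L
    vS <- 0
    for (g in seq_along(sizes)) {
      vS <- vS + sizes[g] * var(x[(pos + 1L):(pos + sizes[g])])
      pos <- pos + sizes[g]
    }
    (vT - vS / N) / vT
  }, numeric(1L)))
  # tolerance rescues exact ties computed through a different summation
  # order (integer copy numbers tie often; dropping ties by one ulp would
  # anticonservatively shrink p)
  p <- mc_p(sum(null_vst >= obs@vst - 1e-12), n)
  new("VstResult", vst = obs@vst, vT = obs@vT, vS = obs@vS, p = p,
      nPerm = as.integer(n), seed = as.integer(seed))
}

#' Copy-number summary statistics
#'
#' @param values numeric copy numbers (>= 2).
#' @return list with `mean`, `sd` (n-1 denominator), `median` and `cv`
#'   (coefficient of variation, percent).
#' @export
cnSummary <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero: CV undefined")
  list(mean = m, sd = sd(values), median = median(values),
       cv = 100 * sd(values) / m)
}

#' Structurally distinct copy-number alleles and their frequencies
#'
#' Tabulates distinct (rounded) copy-number values globally and per
#' population, and counts alleles at or above a frequency threshold.
#'
#' @param cn numeric copy numbers.
#' @param population optional population labels.
#' @param threshold frequency threshold (default 0.05).
#' @return list with `global` (data.frame `cn`, `count`, `frequency`),
#'   `perPopulation` (data.frame `population`, `cn`, `count`,
#'   `frequency`), `nAlleles`, `nAboveThreshold` (named by population when
#'   labels are given).
#' @export
alleleSpectrum <- function(cn, population = NULL, threshold = 0.05) {
  cn <- round_half_away(cn)
  tab <- table(cn)
  global <- data.frame(cn = as.integer(names(tab)),
                       count = as.integer(tab),
                       frequency = as.numeric(tab) / length(cn))
  out <- list(global = global, nAlleles = nrow(global),
              nAboveThreshold = sum(global$frequency >= threshold))
  if (!is.null(population)) {
    per <- do.call(rbind, lapply(unique(population), function(p) {
      t2 <- table(cn[population == p])
      data.frame(population = p, cn = as.integer(names(t2)),
                 count = as.integer(t2),
                 frequency = as.numeric(t2) / sum(population == p))
    }))
    out$perPopulation <- per
    out$nAboveThreshold <- vapply(unique(population), function(p)
      sum(per$frequency[per$population == p] >= threshold), integer(1L))
    out$nAllelesPerPopulation <- vapply(unique(population), function(p)
      sum(per$population == p), integer(1L))
  }
  out
}

#' Synthetic five-population copy-number cohort
#'
#' A synthetic stand-in for a global diversity panel of 70 isogenic lines
#' from five collection sites (Beijing n = 11, Ithaca n = 12, the
#' Netherlands n = 19, Tasmania n = 16, Zimbabwe n = 12). Draws respect
#' the documented marginals of such panels: copy numbers span 4--10 with
#' seven distinct alleles overall, three to five alleles per population,
#' at least three at frequency >= 5\% in every population, Beijing shifted
#' low, and the highest copy numbers (9, 10) concentrated in Ithaca and
#' Zimbabwe. The per-individual values are simulated, not real data.
#'
#' @param seed integer seed.
#' @return data.frame with columns `individual`, `population`, `cn`.
#' @export
syntheticGdlCn <- function(seed = 1L) {
  specs <- list(
    Beijing     = c(`4` = 0.50, `5` = 0.32, `6` = 0.18),
    Ithaca      = c(`4` = 0.15, `5` = 0.20, `6` = 0.25, `9` = 0.25,
                    `10` = 0.15),
    Netherlands = c(`4` = 0.20, `5` = 0.30, `6` = 0.25, `7` = 0.15,
                    `8` = 0.10),
    Tasmania    = c(`5` = 0.30, `6` = 0.35, `7` = 0.20, `8` = 0.15),
    Zimbabwe    = c(`5` = 0.15, `6` = 0.20, `7` = 0.20, `9` = 0.25,
                    `10` = 0.20))
  sizes <- c(Beijing = 11L, Ithaca = 12L, Netherlands = 19L,
             Tasmania = 16L, Zimbabwe = 12L)
  simulatePopulationCn(specs, sizes, seed = seed)
}

#' Kruskal--Wallis test with pairwise rank-based post hoc comparisons
#'
#' Global Kruskal--Wallis H test (tie-corrected) followed by pairwise
#' comparisons: by default pairwise Mann--Whitney tests with Holm
#' familywise adjustment (an approximation to the Steel--Dwass procedure),
#' or the Steel--Dwass studentized-range variant.
#'
#' @param values numeric responses.
#' @param groups group labels (>= 2 non-empty groups).
#' @param method `"wilcox-holm"` or `"steel-dwass"`.
#' @return list with `H`, `df`, `p.value` and `pairwise` (data.frame
#'   `group1`, `group2`, `p.adj`).
#' @export
kruskalPairwise <- function(values, groups,
                            method = c("wilcox-holm", "steel-dwass")) {
  method <- match.arg(method)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  kw <- kruskal.test(values, groups)
  levs <- levels(groups)
  pairs <- combn(levs, 2L)
  k <- nlevels(groups)
  praw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    x <- values[groups == pairs[1L, j]]
    y <- values[groups == pairs[2L, j]]
    if (method == "wilcox-holm") {
      praw[j] <- suppressWarnings(wilcox.test(x, y, exact = FALSE))$p.value
    } else {
      # Steel-Dwass: pairwise rank sum referred to the studentized range
      nx <- length(x); ny <- length(y); N <- nx + ny
      r <- rank(c(x, y))
      Rx <- sum(r[seq_len(nx)])
      ex <- nx * (N + 1) / 2
      ties <- table(r)
      tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
      vx <- nx * ny * (N + 1) / 12 * tie_corr
      z <- abs(Rx - ex) / sqrt(vx)
      praw[j] <- 1 - ptukey(z * sqrt(2), k, Inf)
    }
  }
  p_adj <- if (method == "wilcox-holm") p.adjust(praw, "holm") else praw
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         p.adj = p_adj)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p.value = kw$p.value, pairwise = pairwise)
}

#' Sperm-competition P2 analysis with angular transformation
#'
#' P2 is the proportion of a doubly mated female's progeny sired by the
#' second male. The angular (arcsine square root) transformation is
#' applied, and genotypes are compared with [kruskalPairwise()] on the
#' transformed values.
#'
#' @param records data.frame with columns `genotype`, `male2`, `total`.
#' @param unit `"radians"` (default) or `"degrees"` for the transform.
#' @param method pairwise method passed to [kruskalPairwise()].
#' @return list with `records` (with added `p2`, `transformed`) and
#'   `comparison` (the [kruskalPairwise()] result), or `NULL` comparison
#'   with a single genotype.
#' @export
p2Analyze <- function(records, unit = c("radians", "degrees"),
                      method = "wilcox-holm") {
  unit <- match.arg(unit)
  stopifnot(all(c("genotype", "male2", "total") %in% names(records)))
  drop <- records$total <= 0
  if (any(drop)) {
    warning(sum(drop), " record(s) with zero total progeny dropped")
    records <- records[!drop, , drop = FALSE]
  }
  records$p2 <- records$male2 / records$total
  if (any(records$p2 < 0 | records$p2 > 1)) stop("P2 outside [0, 1]")
  tr <- asin(sqrt(records$p2))
  if (unit == "degrees") tr <- tr * 180 / pi
  records$transformed <- tr
  comparison <- if (length(unique(records$genotype)) >= 2L)
    kruskalPairwise(records$transformed, records$genotype,
                    method = method) else NULL
  list(records = records, comparison = comparison)
}
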