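#' @include AllClasses.R
NULL

#' Simulate qPCR Ct tables under an exponential-amplification model
#'
#' Each well's quantification cycle is
#' `Ct = baselineCt - log(quantity) / log(efficiency) + N(0, noiseSd)`,
#' where the efficiency is the per-cycle amplification factor (2 = perfect
#' doubling). With `noiseSd = 0` the model is exactly invertible by the
#' relative-quantification functions.
#'
#' @param quantities data.frame with columns `sample`, `amplicon`,
#'   `quantity` (template copies or transcript units, > 0).
#' @param efficiency named numeric vector of per-amplicon amplification
#'   factors in (1, 2].
#' @param baselineCt cycle at unit quantity (default 34).
#' @param noiseSd Gaussian Ct noise, cycles.
#' @param replicates wells per sample x amplicon.
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `amplicon`, `replicate`, `ct`.
#' @export
#' @examples
#' q <- data.frame(sample = "s1", amplicon = "target", quantity = 4)
#' simulateCt(q, c(target = 2), replicates = 2)
simulateCt <- function(quantities, efficiency, baselineCt = 34,
                       noiseSd = 0, replicates = 3L, seed = 1L) {
  stopifnot(is.data.frame(quantities),
            all(c("sample", "amplicon", "quantity") %in% names(quantities)))
  if (any(quantities$quantity <= 0))
    stop("quantities must be > 0 (Ct undefined at zero template)")
  eff <- efficiency[quantities$amplicon]
  if (any(is.na(eff)))
    stop("efficiency missing for some amplicons")
  if (any(eff <= 1 | eff > 2))
    stop("efficiencies must lie in (1, 2]")
  base <- quantities[rep(seq_len(nrow(quantities)), each = replicates),
                     c("sample", "amplicon", "quantity")]
  base$replicate <- rep(seq_len(replicates), nrow(quantities))
  ct0 <- baselineCt - log(base$quantity) / log(efficiency[base$amplicon])
  noise <- if (noiseSd > 0)
    with_seed(seed, rnorm(nrow(base), 0, noiseSd)) else 0
  data.frame(sample = base$sample, amplicon = base$amplicon,
             replicate = base$replicate, ct = as.numeric(ct0 + noise),
             row.names = NULL)
}

#' Simulate population copy-number samples
#'
#' Draws integer copy numbers per individual from per-population discrete
#' distributions, for exercising the V_ST differentiation machinery.
#'
#' @param popSpecs named list, one element per population: either a single
#'   copy number (point mass) or a named numeric vector of probabilities
#'   (names = copy numbers).
#' @param sizes named integer vector of population sample sizes (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `individual`, `population`, `cn`.
#' @export
simulatePopulationCn <- function(popSpecs, sizes, seed = 1L) {
  if (length(popSpecs) == 0L) stop("empty population specification")
  if (is.null(names(popSpecs))) stop("popSpecs must be named")
  if (any(sizes < 1L)) stop("population sizes must be >= 1")
  with_seed(seed, {
    out <- lapply(names(popSpecs), function(p) {
      spec <- popSpecs[[p]]
      n <- sizes[[p]]
      cn <- if (length(spec) == 1L && is.null(names(spec))) {
        rep(as.integer(spec), n)
      } else {
        vals <- as.integer(names(spec))
        sample(vals, n, replace = TRUE, prob = spec)
      }
      data.frame(individual = paste0(p, "_", seq_len(n)),
                 population = p, cn = cn)
    })
    do.call(rbind, out)
  })
}

#' Simulate sperm-competition progeny counts
#'
#' Per doubly mated female, the number of progeny sired by the second male
#' is binomial with the genotype's success probability; P2 is the resulting
#' proportion.
#'
#' @param probabilities named numeric vector in \[0, 1\], one per male
#'   genotype.
#' @param nFemales females per genotype (recycled).
#' @param progenyPerFemale total progeny scored per female (> 0).
#' @param seed integer seed.
#' @return data.frame with columns `genotype`, `female`, `male2`, `total`.
#' @export
simulateP2 <- function(probabilities, nFemales, progenyPerFemale,
                       seed = 1L) {
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(progenyPerFemale <= 0)) stop("progeny per female must be > 0")
  nFemales <- rep(nFemales, length.out = length(probabilities))
  with_seed(seed, {
    out <- lapply(seq_along(probabilities), function(i) {
      g <- names(probabilities)[i]
      data.frame(genotype = g,
                 female = paste0(g, "_f", seq_len(nFemales[i])),
                 male2 = rbinom(nFemales[i], progenyPerFemale,
                                probabilities[i]),
                 total = progenyPerFemale)
    })
    do.call(rbind, out)
  })
}
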