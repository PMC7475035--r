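#' @import methods
#' @importFrom stats var median sd aov kruskal.test lm p.adjust pnorm
#'   ptukey rbinom rnorm runif setNames wilcox.test TukeyHSD complete.cases
#' @importFrom utils combn read.delim write.table head
#' @importFrom Rcpp sourceCpp
#' @useDynLib tandemCNV, .registration = TRUE
NULL

#' Specification of a synthetic tandem-array region
#'
#' Parameter bundle consumed by [buildRegion()]. It describes a region of
#' head-to-tail repeat copies flanked by two parental genes from which the
#' repeat unit is derived, one chimeric transcription unit per copy whose
#' two most-3' exons carry the paratype-defining motif blocks, plus optional
#' transposable-element insertions and gene-conversion tracts.
#'
#' @slot nCopies integer, number of tandem copies (>= 0).
#' @slot repeatLength integer, repeat unit length in nt.
#' @slot parent5Length,parent3Length integer, lengths of the 5' and 3'
#'   repeat-homologous parental gene segments; together the parents are
#'   homologous to the full repeat unit, so their reads behave as one
#'   extra copy on a collapsed reference.
#' @slot parentUniqueLength integer, length of each parent's
#'   non-homologous anchor section.
#' @slot exonLayout [IRanges::IRanges] of exon intervals relative to the
#'   repeat start (1-based, closed).
#' @slot paratypes character, one paratype label per copy.
#' @slot motifEdits list, per-paratype nucleotide substitutions
#'   (data.frames with columns `pos`, `base`) confined to the two most-3'
#'   exons; `"auto"` plants codon-aware blocks of >= 5 contiguous
#'   amino-acid differences per distinct label.
#' @slot teInsertions data.frame with columns `copy`, `offset`, `name`,
#'   `sequence`.
#' @slot conversionEvents data.frame with columns `donor`, `recipient`,
#'   `start`, `end` (repeat coordinates).
#' @slot flankLength integer, unique sequence flanking the parents on each
#'   side (emulates the chromosomal background the read-depth normalization
#'   sees).
#' @slot gcContent numeric, GC content of generated sequence.
#' @slot parentDivergence numeric, evenly spaced substitution divergence of
#'   the parental segments from the repeat template.
#' @slot seed integer, drives all randomness of the build.
#' @exportClass TandemRegionSpec
setClass("TandemRegionSpec", representation(
  nCopies = "integer", repeatLength = "integer",
  parent5Length = "integer", parent3Length = "integer",
  parentUniqueLength = "integer",
  exonLayout = "ANY", paratypes = "character", motifEdits = "ANY",
  teInsertions = "data.frame", conversionEvents = "data.frame",
  flankLength = "integer", gcContent = "numeric",
  parentDivergence = "numeric", seed = "integer"))

#' Synthetic tandem-array region with truth annotation
#'
#' Result of [buildRegion()]: the emitted genome sequence together with the
#' exact coordinates of every copy, exon, parental segment, TE insertion and
#' conversion tract, usable as ground truth by the annotation and
#' copy-number modules.
#'
#' @slot genome [Biostrings::DNAString] of the whole region (flank, 5'
#'   parent, copies, 3' parent, flank).
#' @slot copies [GenomicRanges::GRanges] of copy intervals with metadata
#'   columns `copy`, `paratype`, `orfIntact`.
#' @slot exons [GenomicRanges::GRanges] of exon intervals (`copy`, `exon`).
#' @slot parents [GenomicRanges::GRanges] of the two parental segments.
#' @slot teInsertions [GenomicRanges::GRanges] of emitted TE intervals.
#' @slot conversions data.frame of planted conversion tracts.
#' @slot repeatTemplate character, the undiverged repeat unit sequence.
#' @slot spec the originating [TandemRegionSpec-class].
#' @exportClass TandemRegion
setClass("TandemRegion", representation(
  genome = "ANY", copies = "ANY", exons = "ANY", parents = "ANY",
  teInsertions = "ANY", conversions = "data.frame",
  repeatTemplate = "character", spec = "TandemRegionSpec"))

#' Simulated short-read set
#'
#' Illumina-like single-end reads with per-read truth (origin, strand) kept
#' for pileup oracles. Qualities follow a constant or two-state Phred model.
#'
#' @slot sequences character vector of read sequences.
#' @slot start integer, 1-based origin of each read on the source genome.
#' @slot minus logical, whether the read was reverse-complemented.
#' @slot quality integer, per-read Phred quality state.
#' @slot readLength integer.
#' @exportClass SimulatedReads
setClass("SimulatedReads", representation(
  sequences = "character", start = "integer", minus = "logical",
  quality = "integer", readLength = "integer"))

#' Binned read-depth profile over a reference contig
#'
#' Per-bin raw depth and depth normalized by the reference-wide mean, the
#' quantity on which collapsed-copy estimates are read off.
#'
#' @slot binSize integer, bin width in nt (default 100).
#' @slot raw numeric, mean per-base depth per bin.
#' @slot normalized numeric, `raw / mean(per-base depth)`.
#' @slot refLength integer, reference length in nt.
#' @slot mapped,unplaced integer, read placement bookkeeping.
#' @exportClass DepthProfile
setClass("DepthProfile", representation(
  binSize = "integer", raw = "numeric", normalized = "numeric",
  refLength = "integer", mapped = "integer", unplaced = "integer"))

#' Copy-number genotype estimate
#'
#' Aggregated copy-number call: per-reference raw estimates with call-size
#' reliability flags, the averaged normalized read depth (ANRD) over
#' reliable references, its rounded value, and the corrected copy number
#' (rounded minus one, removing the parental-gene read capture).
#'
#' @slot perReference data.frame with columns `reference`, `raw`,
#'   `callSize`, `reliable`.
#' @slot anrd numeric, mean of reliable raw estimates.
#' @slot rounded numeric, ANRD rounded half away from zero.
#' @slot corrected numeric, rounded minus 1 (NA when no call).
#' @slot status character, `"ok"` or `"no call"`.
#' @slot method character, `"read-depth"`, `"qPCR"` or `"annotation"`.
#' @exportClass CnEstimate
setClass("CnEstimate", representation(
  perReference = "data.frame", anrd = "numeric", rounded = "numeric",
  corrected = "numeric", status = "character", method = "character"))

#' V_ST population-differentiation result
#'
#' @slot vst numeric, (V_T - V_S) / V_T.
#' @slot vT numeric, total variance of pooled copy numbers.
#' @slot vS numeric, size-weighted mean within-population variance.
#' @slot p numeric, Monte Carlo p-value (NA before [vstNull()]).
#' @slot nPerm integer, number of resamples behind `p`.
#' @slot seed integer, RNG seed behind `p`.
#' @exportClass VstResult
setClass("VstResult", representation(
  vst = "numeric", vT = "numeric", vS = "numeric", p = "numeric",
  nPerm = "integer", seed = "integer"))

setValidity("TandemRegionSpec", function(object) {
  msg <- character()
  if (object@nCopies < 0L) msg <- c(msg, "nCopies must be >= 0")
  if (object@repeatLength < 100L) msg <- c(msg, "repeatLength too short")
  if (length(object@paratypes) != object@nCopies)
    msg <- c(msg, "need one paratype label per copy")
  if (object@parent5Length + object@parent3Length > object@repeatLength +
      2L) msg <- c(msg, "parental segments exceed repeat length")
  if (object@gcContent <= 0 || object@gcContent >= 1)
    msg <- c(msg, "gcContent must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

setValidity("DepthProfile", function(object) {
  if (length(object@raw) != length(object@normalized))
    return("raw and normalized bin counts differ")
  if (length(object@raw) != ceiling(object@refLength / object@binSize))
    return("bin count must equal ceiling(refLength / binSize)")
  m <- mean(rep(object@normalized,
                times = pmin(object@binSize,
                             object@refLength -
                               (seq_along(object@normalized) - 1L) *
                               object@binSize)))
  if (is.finite(m) && abs(m - 1) > 1e-9)
    return("whole-reference mean normalized depth must be 1")
  TRUE
})

setValidity("VstResult", function(object) {
  if (length(object@vst) && is.finite(object@vst) && object@vst > 1)
    return("V_ST cannot exceed 1")
  if (length(object@p) && !is.na(object@p) &&
      (object@p <= 0 || object@p > 1))
    return("permutation p must lie in (0, 1]")
  TRUE
})
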