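#' @include AllClasses.R
NULL

#' Build synthetic single-repeat references
#'
#' For each annotated copy, emits a reference contig in which the tandem
#' region is replaced by exactly that copy and both parental genes are
#' excised, so that reads from all collapsed copies (and most parental
#' reads) pile onto the single retained repeat. Each reference records the
#' retained repeat's coordinates as the call target.
#'
#' @param genome the source contig ([Biostrings::DNAString] or character).
#' @param copies copy intervals ([IRanges::IRanges] or
#'   [GenomicRanges::GRanges]) on the contig.
#' @param parents intervals of the two parental genes to excise.
#' @param exon1Motif optional motif; when given, each reference is checked
#'   to contain exactly one hit (the retained copy).
#' @return list of references, each a list with `sequence` (character),
#'   `target` ([IRanges::IRanges] of the retained repeat), `sourceCopy`.
#' @export
buildSyntheticReferences <- function(genome, copies, parents,
                                     exon1Motif = NULL) {
  genome <- as_character_seq(genome)
  rng <- function(x) {
    if (is(x, "GRanges")) IRanges::ranges(x) else x
  }
  copies <- rng(copies); parents <- rng(parents)
  if (length(copies) == 0L) stop("zero annotated copies")
  drop_all <- c(copies, parents)
  drop_all <- drop_all[order(BiocGenerics::start(drop_all))]
  refs <- vector("list", length(copies))
  for (i in seq_along(copies)) {
    drop <- drop_all[!(BiocGenerics::start(drop_all) ==
                         BiocGenerics::start(copies)[i] &
                       BiocGenerics::end(drop_all) ==
                         BiocGenerics::end(copies)[i])]
    keep_start <- 1L
    parts <- character(0)
    target_start <- NA_integer_
    removed <- 0L
    bounds <- sort(BiocGenerics::start(drop))
    for (j in seq_along(drop)) {
      s <- BiocGenerics::start(drop)[j]; e <- BiocGenerics::end(drop)[j]
      if (s > keep_start) parts <- c(parts,
        substr(genome, keep_start, s - 1L))
      removed <- removed + (e - s + 1L)
      keep_start <- e + 1L
    }
    parts <- c(parts, substr(genome, keep_start, nchar(genome)))
    seq_out <- paste(parts, collapse = "")
    shift <- sum(BiocGenerics::end(drop) <
                   BiocGenerics::start(copies)[i]) # count dropped upstream
    up_removed <- sum(pmax(0L,
      BiocGenerics::end(drop)[BiocGenerics::end(drop) <
                                BiocGenerics::start(copies)[i]] -
        BiocGenerics::start(drop)[BiocGenerics::end(drop) <
                                    BiocGenerics::start(copies)[i]] + 1L))
    target <- IRanges::IRanges(
      start = BiocGenerics::start(copies)[i] - up_removed,
      end = BiocGenerics::end(copies)[i] - up_removed)
    if (!is.null(exon1Motif)) {
      nhit <- length(Biostrings::matchPattern(
        as_character_seq(exon1Motif), Biostrings::DNAString(seq_out)))
      if (nhit != 1L)
        stop("reference for copy ", i, " has ", nhit,
             " exon-1 motif hits (expected exactly 1)")
    }
    refs[[i]] <- list(sequence = seq_out, target = target, sourceCopy = i)
  }
  names(refs) <- paste0("ref", seq_along(refs))
  refs
}

#' Build a k-mer index over a reference contig
#'
#' Precomputes the exact k-mer seed index used by [computeDepth()]; build
#' it once when mapping many read sets against the same reference.
#'
#' @param reference reference sequence (character,
#'   [Biostrings::DNAString], or a reference from
#'   [buildSyntheticReferences()]).
#' @param k seed length (default 31).
#' @return an opaque index object.
#' @export
buildDepthIndex <- function(reference, k = 31L) {
  if (is.list(reference)) reference <- reference$sequence
  idx <- .cpp_build_index(as_character_seq(reference), as.integer(k))
  structure(list(ptr = idx, k = as.integer(k)), class = "DepthIndex")
}

#' Compute a binned depth profile by seeded read placement
#'
#' Places each read at its best exact-k-mer-seeded position (both strands,
#' tolerating up to `maxMismatch` substitutions); reads with several
#' equally good placements are assigned uniformly at random among them
#' (seeded), which is what lets reads from collapsed tandem copies pile
#' onto a single-repeat reference. Per-base depth is binned and normalized
#' by the reference-wide mean.
#'
#' @param reads a [SimulatedReads-class], character vector of read
#'   sequences, or `NULL` when `depth` is supplied.
#' @param reference reference sequence or [buildDepthIndex()] result.
#' @param binSize bin width in nt (default 100).
#' @param maxMismatch maximum substitutions per placement (default 25;
#'   candidate placements still require one exact k-mer seed).
#' @param depth optional precomputed per-base depth vector (skips mapping).
#' @param seed integer seed for tie-breaking.
#' @return a [DepthProfile-class].
#' @export
computeDepth <- function(reads, reference, binSize = 100L,
                         maxMismatch = 25L, depth = NULL, seed = 1L) {
  if (is.null(depth)) {
    if (is(reads, "SimulatedReads")) reads <- reads@sequences
    if (length(reads) == 0L) stop("empty read set")
    if (inherits(reference, "DepthIndex")) idx <- reference
    else idx <- buildDepthIndex(reference)
    res <- .cpp_map_reads(idx$ptr, reads, as.integer(maxMismatch),
                          seed * 1000 + 47)
    depth <- res$depth
    mapped <- res$mapped; unplaced <- res$unplaced
  } else {
    mapped <- NA_integer_; unplaced <- NA_integer_
  }
  profileFromDepth(depth, binSize = binSize, mapped = mapped,
                   unplaced = unplaced)
}

#' Bin a per-base depth vector into a normalized profile
#'
#' @param depth integer/numeric per-base depth along the reference.
#' @param binSize bin width in nt.
#' @param mapped,unplaced optional bookkeeping counts.
#' @return a [DepthProfile-class].
#' @export
profileFromDepth <- function(depth, binSize = 100L,
                             mapped = NA_integer_,
                             unplaced = NA_integer_) {
  n <- length(depth)
  if (n == 0L) stop("empty depth vector")
  bins <- ceiling(n / binSize)
  pad <- bins * binSize - n
  raw <- colMeans(matrix(c(as.numeric(depth), rep(NA_real_, pad)),
                         nrow = binSize), na.rm = TRUE)
  gmean <- mean(depth)
  if (gmean <= 0) stop("reference-wide mean depth is zero")
  new("DepthProfile", binSize = as.integer(binSize), raw = raw,
      normalized = raw / gmean, refLength = as.integer(n),
      mapped = as.integer(mapped), unplaced = as.integer(unplaced))
}

#' Read a per-base depth table (pileup-depth dialect)
#'
#' Three columns: contig, 1-based position, depth. Positions absent from
#' the table get depth 0.
#'
#' @param path TSV file path.
#' @param length reference length (defaults to the maximum position).
#' @return numeric vector of per-base depth.
#' @export
readDepthTsv <- function(path, length = NULL) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("contig", "pos", "depth"))
  if (is.null(length)) length <- max(df$pos)
  out <- numeric(length)
  out[df$pos] <- df$depth
  out
}

#' Raw copy-number estimate and call size over a target interval
#'
#' The raw estimate is the mean normalized depth over the bins overlapping
#' the target. The call size is the total span of maximal runs of
#' consecutive bins with normalized depth at least `gainThreshold` that
#' intersect the target; the estimate is flagged reliable iff the call
#' size lies within `sizeWindow` (default 7.2--8.0 kb, the plausible
#' repeat-unit size range).
#'
#' @param profile a [DepthProfile-class].
#' @param target [IRanges::IRanges] of the repeat on the reference.
#' @param gainThreshold normalized-depth threshold defining the called
#'   gain (default 1.5).
#' @param sizeWindow numeric length-2, reliable call-size bounds in nt.
#' @param trimBins boundary bins of the target excluded from the raw
#'   estimate (default 1): depth ramps over one read length at the
#'   repeat's ends, because reads spanning the strain's copy junctions
#'   have no counterpart on a single-repeat reference and only fully
#'   contained reads place. Set 0 to average all target bins.
#' @return list with `raw`, `callSize` (nt), `reliable`.
#' @export
callTarget <- function(profile, target, gainThreshold = 1.5,
                       sizeWindow = c(7200, 8000), trimBins = 1L) {
  stopifnot(is(profile, "DepthProfile"))
  if (is(target, "GRanges")) target <- IRanges::ranges(target)
  bs <- profile@binSize
  nb <- length(profile@normalized)
  t_start <- BiocGenerics::start(target)[1L]
  t_end <- BiocGenerics::end(target)[1L]
  if (t_start < 1L || t_end > profile@refLength)
    stop("target outside profile")
  b_first <- (t_start - 1L) %/% bs + 1L
  b_last <- (t_end - 1L) %/% bs + 1L
  bf <- b_first; bl <- b_last
  if (bl - bf + 1L > 2L * trimBins + 1L) {
    bf <- bf + trimBins; bl <- bl - trimBins
  }
  raw <- mean(profile@normalized[bf:bl])
  above <- profile@normalized >= gainThreshold
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  call_size <- 0
  for (k in which(r$values)) {
    if (run_start[k] <= b_last && run_end[k] >= b_first) {
      span_start <- (run_start[k] - 1L) * bs + 1L
      span_end <- min(run_end[k] * bs, profile@refLength)
      call_size <- call_size + (span_end - span_start + 1L)
    }
  }
  list(raw = raw, callSize = call_size,
       reliable = call_size >= sizeWindow[1L] &&
         call_size <= sizeWindow[2L])
}

#' Aggregate per-reference estimates into a copy-number call
#'
#' The averaged normalized read depth (ANRD) is the mean of the reliable
#' per-reference raw estimates; it is rounded half away from zero and 1 is
#' subtracted (the two parental genes combined capture reads like one
#' extra copy). If fewer than `minReliable` references are reliable the
#' status is `"no call"` (not an error).
#'
#' @param estimates data.frame with columns `raw`, `callSize`, `reliable`
#'   (one row per reference), e.g. rows of [callTarget()] results.
#' @param minReliable minimum reliable references for a call (default 4).
#' @param useAllReferences average all references instead of reliable only
#'   (the reliability filter is still used for the call/no-call gate).
#' @param method method tag stored on the estimate.
#' @return a [CnEstimate-class].
#' @export
aggregateCn <- function(estimates, minReliable = 4L,
                        useAllReferences = FALSE, method = "read-depth") {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1L,
            all(c("raw", "reliable") %in% names(estimates)))
  if (!"reference" %in% names(estimates))
    estimates$reference <- paste0("ref", seq_len(nrow(estimates)))
  if (!"callSize" %in% names(estimates)) estimates$callSize <- NA_real_
  n_rel <- sum(estimates$reliable)
  use <- if (useAllReferences) rep(TRUE, nrow(estimates))
         else estimates$reliable
  if (n_rel < minReliable) {
    return(new("CnEstimate", perReference = estimates,
               anrd = NA_real_, rounded = NA_real_,
               corrected = NA_real_, status = "no call", method = method))
  }
  anrd <- mean(estimates$raw[use])
  rounded <- round_half_away(anrd)
  corrected <- max(0, rounded - 1)
  new("CnEstimate", perReference = estimates, anrd = anrd,
      rounded = rounded, corrected = corrected, status = "ok",
      method = method)
}

#' Parameter-recovery study for read-depth copy-number genotyping
#'
#' Plants known copy numbers in synthetic strains, simulates reads, and
#' genotypes each strain against synthetic single-repeat references built
#' from a fixed five-copy reference strain. All strains share the
#' reference strain's chromosomal background (`flankLength` of unique
#' sequence per side), so the repeat contributes negligibly to the
#' reference-wide mean depth, as on a real chromosome.
#'
#' @param cnValues integer vector of planted copy numbers.
#' @param nSeeds read-simulation replicates per copy number.
#' @param coverage,readLength read simulation parameters.
#' @param flankLength unique background per side, nt (default 2.5e6).
#' @param refCopies copies in the reference strain (default 5, labelled
#'   paratypes a--e).
#' @param minReliable passed to [aggregateCn()].
#' @param seed integer master seed.
#' @return data.frame with one row per (copy number, seed): `cn`, `seed`,
#'   `anrd`, `corrected`, `status`, `exact` (corrected equals planted).
#' @export
cnRecoveryStudy <- function(cnValues = 2:12, nSeeds = 3L, coverage = 25,
                            readLength = 100L, flankLength = 2.5e6,
                            refCopies = 5L, minReliable = 4L, seed = 1L) {
  base_seed <- as.integer(seed) * 17L + 83L
  refreg <- buildRegion(tandemRegionSpec(
    nCopies = refCopies, flankLength = flankLength,
    paratypes = letters[seq_len(refCopies)], seed = base_seed))
  refs <- buildSyntheticReferences(regionSequence(refreg), refreg@copies,
                                   refreg@parents, exon1Motif(refreg))
  idx <- lapply(refs, buildDepthIndex)
  rm(refreg); gc(verbose = FALSE)
  out <- NULL
  for (cv in cnValues) {
    strain <- buildRegion(tandemRegionSpec(
      nCopies = cv, flankLength = flankLength, seed = base_seed))
    genome <- as.character(regionSequence(strain))
    rm(strain)
    for (s in seq_len(nSeeds)) {
      # fused simulate+map (seed-for-seed equal to simulateReads followed
      # by depthCn with these seeds, without materializing read strings);
      # double arithmetic so large user seeds cannot overflow R integers
      read_seed <- as.numeric(seed) * 100000 + cv * 100 + s
      map_seed <- as.numeric(seed) * 1000 + cv * 10 + s
      n_reads <- round(coverage * nchar(genome) / readLength)
      res <- .cpp_sim_and_map(
        lapply(idx, function(x) x$ptr), genome,
        as.integer(readLength), as.integer(n_reads), 0.001,
        read_seed * 1000 + 31, 25L,
        (map_seed + seq_along(idx)) * 1000 + 47)
      est <- NULL
      for (i in seq_along(refs)) {
        prof <- profileFromDepth(res[[i]]$depth,
                                 mapped = res[[i]]$mapped,
                                 unplaced = res[[i]]$unplaced)
        ct <- callTarget(prof, refs[[i]]$target)
        est <- rbind(est, data.frame(reference = names(refs)[i],
                                     raw = ct$raw, callSize = ct$callSize,
                                     reliable = ct$reliable))
      }
      est <- aggregateCn(est, minReliable = minReliable)
      out <- rbind(out, data.frame(
        cn = cv, seed = s, anrd = est@anrd, corrected = est@corrected,
        status = est@status,
        exact = identical(est@status, "ok") && est@corrected == cv))
      rm(res); gc(verbose = FALSE)
    }
  }
  out
}

#' Copy-number genotype from reads against a reference set
#'
#' Convenience pipeline: map one read set against each synthetic
#' single-repeat reference (or reuse prebuilt indexes), call each target,
#' and aggregate into a [CnEstimate-class].
#'
#' @param reads a [SimulatedReads-class] or character vector.
#' @param references result of [buildSyntheticReferences()].
#' @param indexes optional list of [buildDepthIndex()] objects matching
#'   `references`.
#' @param binSize,gainThreshold,sizeWindow,minReliable,maxMismatch passed
#'   through to [computeDepth()], [callTarget()] and [aggregateCn()].
#' @param seed integer seed.
#' @return a [CnEstimate-class].
#' @export
depthCn <- function(reads, references, indexes = NULL, binSize = 100L,
                    gainThreshold = 1.5, sizeWindow = c(7200, 8000),
                    minReliable = 4L, maxMismatch = 25L, seed = 1L) {
  est <- NULL
  for (i in seq_along(references)) {
    ref <- if (is.null(indexes)) references[[i]] else indexes[[i]]
    prof <- computeDepth(reads, ref, binSize = binSize,
                         maxMismatch = maxMismatch, seed = seed + i)
    ct <- callTarget(prof, references[[i]]$target,
                     gainThreshold = gainThreshold,
                     sizeWindow = sizeWindow)
    est <- rbind(est, data.frame(reference = names(references)[i],
                                 raw = ct$raw, callSize = ct$callSize,
                                 reliable = ct$reliable))
  }
  aggregateCn(est, minReliable = minReliable)
}
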