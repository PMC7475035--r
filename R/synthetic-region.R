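#' @include AllClasses.R
NULL

# 19 codons, one per amino acid class used for planting paratype blocks;
# no stop codons, so planted blocks never truncate the ORF.
.block_palette <- c("GCA", "TGC", "GAC", "GAG", "TTC", "GGA", "CAC",
                    "ATA", "AAA", "CTG", "AAC", "CCA", "CAA", "AGA",
                    "AGC", "ACA", "GTA", "TGG", "TAC")

.sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

.default_exon_layout <- function(repeatLength) {
  if (repeatLength < 6800)
    stop("default exon layout needs repeatLength >= 6800; ",
         "supply exonLayout explicitly")
  IRanges::IRanges(start = c(501L, 1501L, 4001L, 6001L),
                   end = c(752L, 2250L, 4750L, 6750L))
}

#' Describe a synthetic tandem-array region
#'
#' Builds a validated [TandemRegionSpec-class]. Defaults emulate the
#' reference configuration of a young tandem multigene family: six
#' head-to-tail copies of a 7.6 kb repeat (within the 7.2--8.0 kb window
#' typical of reliable calls), flanked by two parental gene segments that
#' jointly cover the repeat unit, each copy carrying a four-exon chimeric
#' transcription unit whose two most-3' exons host the paratype-defining
#' motif blocks.
#'
#' @param nCopies number of tandem copies (>= 0).
#' @param repeatLength repeat unit length in nt (default 7600).
#' @param parent5Length,parent3Length lengths of the repeat-homologous
#'   parental segments in nt; the 5' parent is homologous to the repeat
#'   head, the 3' parent to its tail, and together they capture reads like
#'   one extra copy on a collapsed reference. Each parent additionally
#'   carries a `parentUniqueLength` nt section with no repeat homology
#'   (the 5' section of the upstream gene, the 3' section of the
#'   downstream one) that serves as the region-locating anchor.
#' @param exonLayout [IRanges::IRanges] of exons relative to the repeat
#'   start (1-based, closed); `NULL` uses a packaged four-exon layout.
#' @param paratypes character vector of paratype labels, one per copy.
#' @param motifEdits `"auto"` (plant one block of 6 amino-acid
#'   substitutions in the last exon per distinct label) or a named list of
#'   data.frames with columns `pos`, `base`.
#' @param teInsertions data.frame with columns `copy`, `offset`, `name`,
#'   `sequence` (`offset` in repeat coordinates: TE inserted after that
#'   position).
#' @param conversionEvents data.frame with columns `donor`, `recipient`,
#'   `start`, `end` (1-based closed, repeat coordinates).
#' @param parentUniqueLength length of each parent's non-homologous anchor
#'   section, nt (default 1000).
#' @param flankLength unique flanking sequence per side, nt.
#' @param gcContent GC content of generated sequence (default 0.42).
#' @param parentDivergence divergence of the repeat-homologous parental
#'   segments from the repeat, planted as evenly spaced substitutions
#'   (default 0.005, i.e. one substitution per 200 nt: parental reads
#'   still map onto a collapsed repeat, while any >= 201 nt window --
#'   including the exon-1 motif -- differs from the repeat and cannot be
#'   mistaken for a copy).
#' @param seed integer seed; all randomness of the build flows from it.
#' @return a [TandemRegionSpec-class].
#' @export
#' @examples
#' spec <- tandemRegionSpec(nCopies = 3, flankLength = 2000, seed = 7)
#' region <- buildRegion(spec)
#' copyTable(region)
tandemRegionSpec <- function(nCopies = 6L, repeatLength = 7600L,
                             parent5Length = 3800L, parent3Length = 3800L,
                             parentUniqueLength = 1000L,
                             exonLayout = NULL,
                             paratypes = rep("a", nCopies),
                             motifEdits = "auto",
                             teInsertions = NULL, conversionEvents = NULL,
                             flankLength = 10000L, gcContent = 0.42,
                             parentDivergence = 0.005, seed = 1L) {
  if (is.null(exonLayout)) exonLayout <- .default_exon_layout(repeatLength)
  if (!is(exonLayout, "IRanges")) stop("exonLayout must be an IRanges")
  if (sum(IRanges::width(exonLayout)) %% 3L != 0L)
    stop("spliced exon length must be a multiple of 3")
  if (max(IRanges::end(exonLayout)) > repeatLength)
    stop("exons must lie inside the repeat unit")
  if (is.null(teInsertions))
    teInsertions <- data.frame(copy = integer(), offset = integer(),
                               name = character(), sequence = character())
  if (is.null(conversionEvents))
    conversionEvents <- data.frame(donor = integer(), recipient = integer(),
                                   start = integer(), end = integer())
  spec <- new("TandemRegionSpec", nCopies = as.integer(nCopies),
              repeatLength = as.integer(repeatLength),
              parent5Length = as.integer(parent5Length),
              parent3Length = as.integer(parent3Length),
              parentUniqueLength = as.integer(parentUniqueLength),
              exonLayout = exonLayout,
              paratypes = as.character(paratypes),
              motifEdits = motifEdits,
              teInsertions = as.data.frame(teInsertions),
              conversionEvents = as.data.frame(conversionEvents),
              flankLength = as.integer(flankLength),
              gcContent = gcContent,
              parentDivergence = parentDivergence, seed = as.integer(seed))
  validObject(spec)
  spec
}

# Codon index ranges of the two most-3' exons, 1-based over the spliced CDS.
.threeprime_exon_positions <- function(exonLayout) {
  n <- length(exonLayout)
  idx <- if (n >= 2L) c(n - 1L, n) else n
  unlist(lapply(idx, function(i)
    seq.int(IRanges::start(exonLayout)[i], IRanges::end(exonLayout)[i])))
}

# Auto-generate per-label codon-aware substitution blocks in the two
# most-3' exons. The block position is keyed to the label itself (its rank
# in the alphabet), so regions built from the same seed plant identical
# blocks for the same paratype label -- copies of one paratype in
# different strains then classify jointly under one label.
.auto_motif_edits <- function(labels, exonLayout, tmpl_chars,
                              blockCodons = 6L, spacing = 12L) {
  n_ex <- length(exonLayout)
  ex_start <- IRanges::start(exonLayout)
  ex_end <- IRanges::end(exonLayout)
  cds_pos <- unlist(lapply(seq_len(n_ex), function(i)
    seq.int(ex_start[i], ex_end[i])))
  n_cod <- length(cds_pos) %/% 3L
  allowed <- .threeprime_exon_positions(exonLayout)
  # first codon whose three nucleotides all fall in the 3' exons
  cod_ok <- vapply(seq_len(n_cod), function(ci)
    all(cds_pos[(3L * (ci - 1L) + 1L):(3L * ci)] %in% allowed),
    logical(1L))
  first_cod <- min(which(cod_ok))
  edits <- list()
  for (lab in labels) {
    idx <- match(lab, letters)
    if (is.na(idx))
      stop("auto motif edits support single-letter labels a-z; ",
           "supply motifEdits for label '", lab, "'")
    cod0 <- first_cod + (idx - 1L) * spacing
    if (!all(cod_ok[cod0:(cod0 + blockCodons - 1L)]))
      stop("paratype block for label '", lab,
           "' falls outside the two most-3' exons; supply motifEdits")
    df <- NULL
    for (j in seq_len(blockCodons)) {
      ci <- cod0 + j - 1L
      nt_idx <- cds_pos[(3L * (ci - 1L) + 1L):(3L * ci)]
      old <- paste(tmpl_chars[nt_idx], collapse = "")
      old_aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(old), no.init.codon = TRUE))
      pick <- .block_palette[((idx + j) %% length(.block_palette)) + 1L]
      pick_aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(pick), no.init.codon = TRUE))
      if (pick_aa == old_aa)
        pick <- .block_palette[((idx + j + 1L) %%
                                  length(.block_palette)) + 1L]
      new_chars <- strsplit(pick, "")[[1L]]
      keep <- new_chars != tmpl_chars[nt_idx]
      df <- rbind(df, data.frame(pos = nt_idx[keep], base = new_chars[keep]))
    }
    edits[[lab]] <- df
  }
  edits
}

.apply_edits <- function(chars, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(chars)
  chars[edits$pos] <- edits$base
  chars
}

.transition <- c(A = "G", G = "A", C = "T", T = "C")

# Evenly spaced substitutions guarantee every >= `spacing + 5` nt window of
# a parental segment differs from the repeat template.
.diverge_parent <- function(chars, divergence, phase) {
  if (divergence <= 0) return(chars)
  spacing <- max(2L, round(1 / divergence))
  pos <- seq.int(phase, length(chars), by = spacing)
  chars[pos] <- .transition[chars[pos]]
  chars
}

#' Build a synthetic tandem-array region with known truth
#'
#' Emits the full region sequence (unique flank, 5' parental segment, the
#' head-to-tail copies in order, 3' parental segment, unique flank) plus a
#' truth annotation with the exact coordinates of every copy, exon,
#' parental segment, TE insertion and conversion tract. A six-copy build at
#' the default 7.6 kb repeat spans 45,600 nt between the parents,
#' matching the ~46 kb reference configuration. Deterministic for a fixed
#' spec seed.
#'
#' @param spec a [TandemRegionSpec-class].
#' @return a [TandemRegion-class].
#' @export
buildRegion <- function(spec) {
  stopifnot(is(spec, "TandemRegionSpec"))
  validObject(spec)
  L <- spec@repeatLength
  n <- spec@nCopies
  ex <- spec@exonLayout

  tmpl <- .cpp_random_seq(L, spec@gcContent, spec@seed * 1000 + 17)
  tmpl_chars <- strsplit(tmpl, "")[[1L]]
  # overwrite the spliced CDS with a clean ORF: ATG ... sense codons ... TAA
  cds_pos <- unlist(lapply(seq_along(ex), function(i)
    seq.int(IRanges::start(ex)[i], IRanges::end(ex)[i])))
  n_cod <- length(cds_pos) %/% 3L
  codons <- with_seed(spec@seed + 1L, c("ATG",
    sample(.sense_codons(), n_cod - 2L, replace = TRUE), "TAA"))
  tmpl_chars[cds_pos] <- strsplit(paste(codons, collapse = ""), "")[[1L]]
  tmpl <- paste(tmpl_chars, collapse = "")

  labels <- spec@paratypes
  distinct <- unique(labels)
  if (identical(spec@motifEdits, "auto")) {
    edits <- if (n > 0L) .auto_motif_edits(distinct, ex, tmpl_chars)
    else list()
  } else {
    edits <- spec@motifEdits
    allowed <- .threeprime_exon_positions(ex)
    for (lab in names(edits)) {
      if (nrow(edits[[lab]]) && !all(edits[[lab]]$pos %in% allowed))
        stop("motif edits for paratype '", lab,
             "' fall outside the two most-3' exons")
    }
    if (length(distinct) > 1L) {
      keys <- vapply(distinct, function(lab) {
        e <- edits[[lab]]
        if (is.null(e) || nrow(e) == 0L) "" else
          paste(e$pos, e$base, sep = ":", collapse = ",")
      }, character(1L))
      if (anyDuplicated(keys))
        stop("distinct paratype labels require distinguishing motif edits")
    }
  }

  te <- spec@teInsertions
  if (nrow(te)) {
    if (any(te$copy < 1L | te$copy > n)) stop("TE copy index out of range")
    if (any(te$offset < 1L | te$offset > L))
      stop("TE offset outside repeat bounds")
    key <- paste(te$copy, te$offset)
    if (anyDuplicated(key)) stop("overlapping TE insertions")
  }
  conv <- spec@conversionEvents
  if (nrow(conv)) {
    if (any(conv$start < 1L | conv$end > L | conv$start > conv$end))
      stop("conversion tract outside repeat bounds")
    if (any(conv$donor < 1L | conv$donor > n |
            conv$recipient < 1L | conv$recipient > n))
      stop("conversion copy index out of range")
  }

  # per-copy sequences: paratype edits, then conversion tracts, then TEs
  copies <- lapply(seq_len(n), function(i)
    .apply_edits(tmpl_chars, edits[[labels[i]]]))
  if (nrow(conv)) for (r in seq_len(nrow(conv))) {
    idx <- conv$start[r]:conv$end[r]
    copies[[conv$recipient[r]]][idx] <- copies[[conv$donor[r]]][idx]
  }

  copy_strs <- character(n)
  copy_len <- integer(n)
  te_rel <- NULL  # TE intervals relative to each emitted copy
  ex_rel <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- copies[[i]]
    te_i <- te[te$copy == i, , drop = FALSE]
    te_i <- te_i[order(te_i$offset), , drop = FALSE]
    shift <- 0L
    starts <- IRanges::start(ex); ends <- IRanges::end(ex)
    if (nrow(te_i)) for (r in seq_len(nrow(te_i))) {
      at <- te_i$offset[r] + shift
      ins <- strsplit(te_i$sequence[r], "")[[1L]]
      ch <- append(ch, ins, after = at)
      te_rel <- rbind(te_rel, data.frame(
        copy = i, start = at + 1L, end = at + length(ins),
        name = te_i$name[r]))
      starts <- ifelse(starts > te_i$offset[r], starts + length(ins), starts)
      ends <- ifelse(ends >= te_i$offset[r], ends + length(ins), ends)
      shift <- shift + length(ins)
    }
    ex_rel[[i]] <- IRanges::IRanges(start = starts, end = ends)
    copy_strs[i] <- paste(ch, collapse = "")
    copy_len[i] <- length(ch)
  }

  flank5 <- .cpp_random_seq(spec@flankLength, spec@gcContent,
                            spec@seed * 1000 + 101)
  flank3 <- .cpp_random_seq(spec@flankLength, spec@gcContent,
                            spec@seed * 1000 + 202)
  # each parent = a unique anchor section (the part of the gene absent
  # from the chimeric repeat) plus a repeat-homologous section
  uq <- spec@parentUniqueLength
  uq5 <- .cpp_random_seq(uq, spec@gcContent, spec@seed * 1000 + 303)
  uq3 <- .cpp_random_seq(uq, spec@gcContent, spec@seed * 1000 + 404)
  p5 <- paste0(uq5,
    paste(.diverge_parent(tmpl_chars[seq_len(spec@parent5Length)],
                          spec@parentDivergence, 7L), collapse = ""))
  p3 <- paste0(
    paste(.diverge_parent(tmpl_chars[(L - spec@parent3Length + 1L):L],
                          spec@parentDivergence, 13L), collapse = ""),
    uq3)

  genome <- paste0(flank5, p5, paste(copy_strs, collapse = ""), p3, flank3)

  p5_len <- uq + spec@parent5Length
  p3_len <- uq + spec@parent3Length
  p5_start <- spec@flankLength + 1L
  copy_starts <- p5_start + p5_len +
    c(0L, cumsum(copy_len))[seq_len(max(n, 1L))]
  if (n == 0L) copy_starts <- integer(0)
  copy_ends <- copy_starts + copy_len - 1L
  p3_start <- spec@flankLength + p5_len + sum(copy_len) + 1L

  gr <- function(starts, ends, ...) {
    GenomicRanges::GRanges(rep("region", length(starts)),
      IRanges::IRanges(start = starts, end = ends), ...)
  }
  copies_gr <- gr(copy_starts, copy_ends)
  orf <- rep(NA, n); paratype <- labels
  exons_gr <- GenomicRanges::GRanges()
  for (i in seq_len(n)) {
    eri <- ex_rel[[i]]
    exons_gr <- c(exons_gr, gr(copy_starts[i] + IRanges::start(eri) - 1L,
                               copy_starts[i] + IRanges::end(eri) - 1L,
                               copy = i, exon = seq_along(eri)))
    spliced <- paste(vapply(seq_along(eri), function(j)
      substr(copy_strs[i], IRanges::start(eri)[j], IRanges::end(eri)[j]),
      character(1L)), collapse = "")
    orf[i] <- callOrf(spliced)$orfIntact
  }
  copies_gr$copy <- seq_len(n)
  copies_gr$paratype <- paratype
  copies_gr$orfIntact <- as.logical(orf)

  te_gr <- GenomicRanges::GRanges()
  if (!is.null(te_rel))
    te_gr <- gr(copy_starts[te_rel$copy] + te_rel$start - 1L,
                copy_starts[te_rel$copy] + te_rel$end - 1L,
                copy = te_rel$copy, name = te_rel$name)

  parents_gr <- gr(c(p5_start, p3_start),
                   c(p5_start + p5_len - 1L, p3_start + p3_len - 1L),
                   name = c("parent5", "parent3"))

  new("TandemRegion", genome = Biostrings::DNAString(genome),
      copies = copies_gr, exons = exons_gr, parents = parents_gr,
      teInsertions = te_gr, conversions = conv,
      repeatTemplate = tmpl, spec = spec)
}

#' Exon-1 motif of a synthetic region
#'
#' The first-exon sequence of the repeat template, the anchor used to
#' enumerate copies by motif search.
#'
#' @param region a [TandemRegion-class].
#' @return a character scalar.
#' @export
exon1Motif <- function(region) {
  ex <- region@spec@exonLayout
  substr(region@repeatTemplate, IRanges::start(ex)[1L],
         IRanges::end(ex)[1L])
}

#' Parental anchor sequences of a synthetic region
#'
#' The 5' section of the upstream parental gene and the 3' section of the
#' downstream one -- the parts with no repeat homology -- which are the
#' anchors [locateRegion()] searches for.
#'
#' @param region a [TandemRegion-class].
#' @param length anchor length in nt (default 200, capped at the parents'
#'   unique section length).
#' @return list with `anchor5` and `anchor3` character sequences.
#' @export
parentAnchors <- function(region, length = 200L) {
  length <- min(length, region@spec@parentUniqueLength)
  g <- as.character(region@genome)
  p <- region@parents
  s5 <- BiocGenerics::start(p)[1L]
  e3 <- BiocGenerics::end(p)[2L]
  list(anchor5 = substr(g, s5, s5 + length - 1L),
       anchor3 = substr(g, e3 - length + 1L, e3))
}

#' Simulate Illumina-like single-end reads
#'
#' Uniformly positioned reads with independent per-base substitution
#' errors; the expected read count is `round(coverage * length(genome) /
#' readLength)`. Per-read origin and strand are retained as truth for
#' pileup oracles. Deterministic for a fixed seed.
#'
#' @param genome a [Biostrings::DNAString], character scalar, or
#'   [TandemRegion-class].
#' @param coverage mean fold coverage (> 0).
#' @param readLength read length in nt (default 100).
#' @param errorRate per-base substitution probability.
#' @param bothStrands simulate reads from both strands.
#' @param qualityHigh,qualityLow,lowFraction two-state Phred quality model:
#'   each read is low-quality with probability `lowFraction`.
#' @param seed integer seed.
#' @return a [SimulatedReads-class].
#' @export
simulateReads <- function(genome, coverage, readLength = 100L,
                          errorRate = 0.001, bothStrands = TRUE,
                          qualityHigh = 37L, qualityLow = 12L,
                          lowFraction = 0, seed = 1L) {
  if (is(genome, "TandemRegion")) genome <- genome@genome
  genome <- as_character_seq(genome)
  glen <- nchar(genome)
  if (coverage <= 0) stop("coverage must be > 0")
  if (readLength > glen) stop("readLength exceeds genome length")
  n <- round(coverage * glen / readLength)
  sim <- .cpp_simulate_reads(genome, as.integer(readLength), as.integer(n),
                             errorRate, seed * 1000 + 31, bothStrands)
  qual <- rep(as.integer(qualityHigh), n)
  if (lowFraction > 0) {
    low <- with_seed(seed + 5L, runif(n) < lowFraction)
    qual[low] <- as.integer(qualityLow)
  }
  new("SimulatedReads", sequences = as.character(sim$seq),
      start = as.integer(sim$start), minus = as.logical(sim$minus),
      quality = qual, readLength = as.integer(readLength))
}

#' Per-base depth pileup from read truth
#'
#' Direct pileup of simulated reads on their source genome using the
#' retained origin coordinates (no mapping involved); the independent
#' oracle for depth computations.
#'
#' @param reads a [SimulatedReads-class].
#' @param genomeLength length of the source genome.
#' @return integer vector of per-base depth.
#' @export
pileupTruth <- function(reads, genomeLength) {
  d <- integer(genomeLength + 1L)
  tab <- table(reads@start)
  d[as.integer(names(tab))] <- as.integer(tab)
  ends <- reads@start + reads@readLength
  tabe <- table(ends[ends <= genomeLength + 1L])
  d[as.integer(names(tabe))] <- d[as.integer(names(tabe))] -
    as.integer(tabe)
  head(cumsum(d), genomeLength)
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' @param reads a [SimulatedReads-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeReadsFastq <- function(reads, path) {
  qchar <- vapply(reads@quality, function(q)
    strrep(intToUtf8(q + 33L), reads@readLength), character(1L))
  ids <- sprintf("@read%06d", seq_along(reads@sequences))
  out <- rbind(ids, reads@sequences, "+", qchar)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Export truth annotation as GFF3 and TSV
#'
#' Writes the copy, exon, parental-segment and TE truth of a synthetic
#' region as a GFF3 file (1-based, closed intervals) plus a copy-table TSV.
#'
#' @param region a [TandemRegion-class].
#' @param gffPath,tsvPath output paths (either may be `NULL` to skip).
#' @return invisibly, a list of written paths.
#' @export
writeRegionAnnotation <- function(region, gffPath = NULL, tsvPath = NULL) {
  if (!is.null(gffPath)) {
    feats <- c(
      GenomicRanges::granges(region@copies),
      GenomicRanges::granges(region@exons),
      GenomicRanges::granges(region@parents),
      GenomicRanges::granges(region@teInsertions))
    type <- rep(c("repeat_copy", "exon", "parent_gene", "TE_insertion"),
                c(length(region@copies), length(region@exons),
                  length(region@parents), length(region@teInsertions)))
    df <- data.frame(
      seqid = "region", source = "tandemCNV", type = type,
      start = BiocGenerics::start(feats), end = BiocGenerics::end(feats),
      score = ".", strand = "+", phase = ".",
      attributes = sprintf("ID=%s%04d", type, seq_along(feats)))
    con <- file(gffPath, "w")
    writeLines("##gff-version 3", con)
    write.table(df, con, sep = "\t", quote = FALSE, col.names = FALSE,
                row.names = FALSE)
    close(con)
  }
  if (!is.null(tsvPath))
    write.table(copyTable(region), tsvPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(gff = gffPath, tsv = tsvPath))
}
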