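#' @include AllClasses.R
NULL

# Hits of `pattern` in `subject` with up to max.mismatch substitutions,
# exact search first (fixed-pattern scan; anchors are long and conserved,
# so no local aligner is needed).
.anchor_hits <- function(subject, pattern, maxMismatch) {
  hits <- Biostrings::matchPattern(pattern, subject, max.mismatch = 0)
  if (length(hits) == 0L && maxMismatch > 0)
    hits <- Biostrings::matchPattern(pattern, subject,
                                     max.mismatch = maxMismatch)
  hits
}

#' Locate a tandem region between parental-gene anchors
#'
#' Finds the unique best hit of each anchor (the 5' section of the upstream
#' parental gene and the 3' section of the downstream one) on the same
#' contig, requires the 5' anchor upstream of the 3' anchor, and returns
#' the enclosed interval padded by `pad` nt on each side (truncated at
#' contig edges, with the truncation recorded).
#'
#' @param assembly a [Biostrings::DNAStringSet] (one element per contig).
#' @param anchor5,anchor3 anchor sequences (>= 30 nt).
#' @param maxMismatch maximum Hamming distance for anchor matching.
#' @param pad flank padding in nt (default 10000).
#' @return list with `contig`, `start`, `end` (1-based, closed, padded),
#'   `anchor5`, `anchor3` hit coordinates, `padApplied`, `truncated`.
#' @export
locateRegion <- function(assembly, anchor5, anchor3, maxMismatch = 0L,
                         pad = 10000L) {
  if (!is(assembly, "DNAStringSet"))
    assembly <- Biostrings::DNAStringSet(assembly)
  anchor5 <- as_character_seq(anchor5); anchor3 <- as_character_seq(anchor3)
  if (nchar(anchor5) < 30L || nchar(anchor3) < 30L)
    stop("anchors must be >= 30 nt")
  find_one <- function(anchor, label) {
    hits <- lapply(seq_along(assembly), function(i)
      .anchor_hits(assembly[[i]], anchor, maxMismatch))
    n <- vapply(hits, length, integer(1L))
    if (sum(n) == 0L)
      stop("anchor '", label, "' not found: region absent or fragmented")
    if (sum(n) > 1L) {
      where <- unlist(lapply(which(n > 0L), function(i)
        paste0(names(assembly)[i] %||% i, ":",
               BiocGenerics::start(hits[[i]]))))
      stop("anchor '", label, "' is ambiguous; hits at ",
           paste(where, collapse = ", "))
    }
    i <- which(n == 1L)
    list(contig = i, start = BiocGenerics::start(hits[[i]]),
         end = BiocGenerics::end(hits[[i]]))
  }
  h5 <- find_one(anchor5, "anchor5")
  h3 <- find_one(anchor3, "anchor3")
  if (h5$contig != h3$contig)
    stop("anchors lie on different contigs: region fragmented")
  if (h5$start >= h3$start)
    stop("5' anchor does not precede 3' anchor on the contig")
  clen <- length(assembly[[h5$contig]])
  start <- h5$start - pad
  end <- h3$end + pad
  truncated <- start < 1L || end > clen
  list(contig = names(assembly)[h5$contig] %||% h5$contig,
       start = max(1L, start), end = min(clen, end),
       anchor5 = c(start = h5$start, end = h5$end),
       anchor3 = c(start = h3$start, end = h3$end),
       padApplied = as.integer(pad), truncated = truncated)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate tandem copies by exon-1 motif search
#'
#' Finds all occurrences of the first-exon motif in the region and defines
#' copy intervals from each hit to the next (the last copy runs to
#' `regionEnd`, the 3' parental anchor). Copies are numbered sequentially
#' from the 5' parent toward the 3' parent. Zero hits return an empty
#' result (deletion genotypes exist).
#'
#' @param region region sequence ([Biostrings::DNAString] or character).
#' @param exon1Motif motif sequence (>= 20 nt).
#' @param maxMismatch maximum Hamming distance.
#' @param regionEnd end coordinate of the last copy (defaults to the region
#'   length).
#' @return an [IRanges::IRanges] of ordered copy intervals with integer
#'   names.
#' @export
findCopies <- function(region, exon1Motif, maxMismatch = 0L,
                       regionEnd = NULL) {
  region <- as_dna_string(region)
  exon1Motif <- as_character_seq(exon1Motif)
  if (nchar(exon1Motif) < 20L) stop("exon-1 motif must be >= 20 nt")
  hits <- Biostrings::matchPattern(exon1Motif, region,
                                   max.mismatch = maxMismatch)
  if (length(hits) == 0L) return(IRanges::IRanges())
  s <- sort(BiocGenerics::start(hits))
  w <- nchar(exon1Motif)
  if (any(diff(s) < w)) stop("overlapping exon-1 motif hits")
  if (is.null(regionEnd)) regionEnd <- length(region)
  ends <- c(s[-1L] - 1L, as.integer(regionEnd))
  out <- IRanges::IRanges(start = s, end = ends)
  names(out) <- seq_along(out)
  out
}

#' Splice and translate a copy's coding sequence
#'
#' Translates the spliced exons under the standard genetic code and reports
#' whether the open reading frame is intact (no internal stop before the
#' annotated terminal codon).
#'
#' @param copy copy sequence (character or [Biostrings::DNAString]); if
#'   `exonLayout` is `NULL`, `copy` is taken to be the already-spliced CDS.
#' @param exonLayout optional [IRanges::IRanges] of exon intervals relative
#'   to the copy start (1-based, closed).
#' @return list with `protein` (character, without the terminal stop),
#'   `orfIntact` (logical) and `prematureStopOffset` (residue index of the
#'   first internal stop, or `NA`).
#' @export
callOrf <- function(copy, exonLayout = NULL) {
  copy <- as_character_seq(copy)
  cds <- if (is.null(exonLayout)) copy else
    paste(vapply(seq_along(exonLayout), function(i)
      substr(copy, IRanges::start(exonLayout)[i],
             IRanges::end(exonLayout)[i]), character(1L)), collapse = "")
  if (nchar(cds) < 3L) stop("spliced length must be >= 3")
  cds <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "solve"))
  n <- nchar(aa)
  term <- substr(aa, n, n) == "*"
  body <- if (term) substr(aa, 1L, n - 1L) else aa
  stop_at <- regexpr("*", body, fixed = TRUE)
  intact <- stop_at < 0L
  list(protein = if (intact) body else substr(body, 1L, stop_at - 1L),
       orfIntact = intact,
       prematureStopOffset = if (intact) NA_integer_
       else as.integer(stop_at))
}

#' Detect transposable-element insertions by alignment to a consensus
#'
#' Globally aligns each copy to a consensus repeat; gaps in the consensus
#' of at least `minInsert` nt are reported as insertions. If a TE library
#' is supplied, each insertion is labeled with its best-matching element
#' (>= 80% identity over >= 80% of the insertion length), otherwise
#' `"novel"`. If an exon layout is given, each insertion is located as
#' `"exonic"`, `"intronic"` or `"UTR/intergenic"`.
#'
#' @param copies [Biostrings::DNAStringSet] (or character vector) of copy
#'   sequences.
#' @param consensus consensus repeat sequence.
#' @param minInsert minimum insertion length reported (default 100 nt).
#' @param teLibrary optional named [Biostrings::DNAStringSet] of TE
#'   elements.
#' @param exonLayout optional [IRanges::IRanges] of exons relative to the
#'   consensus.
#' @return data.frame with columns `copy`, `offset` (position in the copy),
#'   `length`, `te`, `location`.
#' @export
detectTeInsertions <- function(copies, consensus, minInsert = 100L,
                               teLibrary = NULL, exonLayout = NULL) {
  if (!is(copies, "DNAStringSet"))
    copies <- Biostrings::DNAStringSet(copies)
  consensus <- as_character_seq(consensus)
  if (nchar(consensus) == 0L) stop("empty consensus")
  out <- NULL
  for (i in seq_along(copies)) {
    aln <- Biostrings::pairwiseAlignment(
      copies[[i]], Biostrings::DNAString(consensus), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 6, gapExtension = 0.2)
    # insertions in the copy appear as gap runs in the aligned consensus
    pch <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sch <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    gaps <- rle(sch == "-")
    col_end <- cumsum(gaps$lengths)
    col_start <- col_end - gaps$lengths + 1L
    runs <- which(gaps$values & gaps$lengths >= minInsert)
    if (length(runs) == 0L) next
    # copy coordinate of each alignment column (position of pattern char)
    ppos <- cumsum(pch != "-")
    spos <- cumsum(sch != "-")
    for (j in runs) {
      off <- ppos[col_start[j]]
      len <- gaps$lengths[j]
      seq_ins <- substr(as.character(copies[[i]]), off, off + len - 1L)
      te <- "novel"
      if (!is.null(teLibrary) && length(teLibrary)) {
        best_id <- 0; best <- NA_character_
        for (k in seq_along(teLibrary)) {
          a2 <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(seq_ins), teLibrary[[k]], type = "local",
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
              match = 1, mismatch = -1, baseOnly = TRUE),
            gapOpening = 2, gapExtension = 1)
          ncol_aln <- Biostrings::nchar(a2)
          pid <- Biostrings::nmatch(a2) / ncol_aln
          if (ncol_aln >= 0.8 * len && pid >= 0.8 && pid > best_id) {
            best_id <- pid
            best <- names(teLibrary)[k] %||% paste0("te", k)
          }
        }
        if (!is.na(best)) te <- best
      }
      loc <- NA_character_
      if (!is.null(exonLayout)) {
        # consensus coordinate immediately 5' of the insertion point
        cpos <- spos[col_start[j]]
        inExon <- any(cpos >= IRanges::start(exonLayout) &
                        cpos < IRanges::end(exonLayout))
        inGene <- cpos >= min(IRanges::start(exonLayout)) &
          cpos < max(IRanges::end(exonLayout))
        loc <- if (inExon) "exonic" else if (inGene) "intronic"
        else "UTR/intergenic"
      }
      out <- rbind(out, data.frame(
        copy = names(copies)[i] %||% i, offset = off, length = len,
        te = te, location = loc))
    }
  }
  if (is.null(out))
    out <- data.frame(copy = character(), offset = integer(),
                      length = integer(), te = character(),
                      location = character())
  out
}

#' Jukes--Cantor pairwise distances from a nucleotide alignment
#'
#' With complete deletion, columns containing any gap or ambiguity
#' character are removed globally before computing, for each pair, the
#' proportion `p` of differing retained sites and the distance
#' `d = -(3/4) ln(1 - (4/3) p)`.
#'
#' @param msa aligned sequences ([Biostrings::DNAStringSet] or character
#'   vector, equal widths).
#' @param completeDeletion remove gap/ambiguity columns globally (default
#'   `TRUE`); otherwise pairwise deletion is used.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
jcDistance <- function(msa, completeDeletion = TRUE) {
  nm <- if (!is.null(names(msa))) names(msa) else NULL
  seqs <- toupper(as.character(msa))
  names(seqs) <- nm
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned (equal column count)")
  mat <- do.call(rbind, strsplit(seqs, ""))
  ok <- mat %in% c("A", "C", "G", "T")
  dim(ok) <- dim(mat)
  if (completeDeletion) {
    keep <- apply(ok, 2L, all)
    if (!any(keep)) stop("zero columns retained after complete deletion")
    mat <- mat[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- ok[i, ] & ok[j, ]
    if (!any(use)) stop("zero retained columns for pair (", i, ",", j, ")")
    p <- mean(mat[i, use] != mat[j, use])
    if (p >= 0.75)
      stop("Jukes-Cantor distance undefined for pair (", i, ",", j,
           "): p = ", format(p, digits = 3), " >= 0.75")
    d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  d
}
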