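#' @include AllClasses.R
NULL

# Core motif distinctive of the pseudogene-like copies (34 nt), embedded in
# a 130-nt query. The flanks packaged here are synthetic filler around the
# published core, present so the query object is usable out of the box;
# supply the real 130-nt context for real-data work.
.default_core <- "ATAGGTCAGTATATACATATTTAACTGTTCCGTT"

#' Motif-anchored query for transcript-evidence counting
#'
#' A query sequence with a designated core interval: reads are counted as
#' transcript evidence when a local alignment spans more than `minSpan - 1`
#' query positions, contains the entire core with no mismatch or gap, and
#' has at most one single-nucleotide mismatch or indel in each extension
#' (upstream and downstream of the core, judged separately).
#'
#' @param query query sequence (character); default packages the 34-nt
#'   core inside synthetic 48-nt flanks to form a 130-nt query.
#' @param coreStart,coreEnd 1-based core interval within the query.
#' @param minSpan minimum aligned span on the query, nt (default 71, i.e.
#'   more than 70 nt).
#' @return list of class `MotifQuery`.
#' @export
motifQuery <- function(query = NULL, coreStart = NULL, coreEnd = NULL,
                       minSpan = 71L) {
  if (is.null(query)) {
    up <- .cpp_random_seq(48L, 0.42, 991)
    down <- .cpp_random_seq(48L, 0.42, 992)
    query <- paste0(up, .default_core, down)
    coreStart <- 49L
    coreEnd <- 49L + nchar(.default_core) - 1L
  }
  query <- toupper(as_character_seq(query))
  if (is.null(coreStart) || is.null(coreEnd))
    stop("coreStart and coreEnd are required for a custom query")
  if (coreStart < 1L || coreEnd > nchar(query) || coreStart > coreEnd)
    stop("core interval must lie inside the query")
  structure(list(query = query, coreStart = as.integer(coreStart),
                 coreEnd = as.integer(coreEnd),
                 minSpan = as.integer(minSpan)),
            class = "MotifQuery")
}

#' Quality and adapter filtering of reads
#'
#' Discards reads whose (mean, by default) Phred quality is at or below
#' `minQ`, and reads containing a supplied adapter substring.
#'
#' @param reads a [SimulatedReads-class] or data.frame with columns `seq`
#'   and `quality` (mean Phred per read).
#' @param minQ quality threshold; reads with quality <= `minQ` are removed
#'   (default 20).
#' @param adapter optional adapter sequence; reads containing it are
#'   removed.
#' @return list with `sequences` (character), `passed`, `removedQuality`,
#'   `removedAdapter`.
#' @export
qcFilter <- function(reads, minQ = 20, adapter = NULL) {
  if (is(reads, "SimulatedReads")) {
    seqs <- reads@sequences; qual <- reads@quality
  } else {
    stopifnot(all(c("seq", "quality") %in% names(reads)))
    seqs <- as.character(reads$seq); qual <- reads$quality
  }
  keep_q <- qual > minQ
  keep_a <- rep(TRUE, length(seqs))
  if (!is.null(adapter))
    keep_a <- !grepl(adapter, seqs, fixed = TRUE)
  keep <- keep_q & keep_a
  list(sequences = seqs[keep], passed = sum(keep),
       removedQuality = sum(!keep_q),
       removedAdapter = sum(keep_q & !keep_a))
}

.screen_alignment <- function(aln, q) {
  # span and per-extension edit budget on the query (subject) side
  pch <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sch <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  spos <- BiocGenerics::start(Biostrings::subject(aln)) - 1L +
    cumsum(sch != "-")
  span <- max(spos) - min(spos) + 1L
  core_cols <- which(spos >= q$coreStart & spos <= q$coreEnd & sch != "-")
  core_cover <- length(core_cols) == (q$coreEnd - q$coreStart + 1L)
  core_clean <- core_cover &&
    all(pch[core_cols] == sch[core_cols]) &&
    !any(sch[min(core_cols):max(core_cols)] == "-") &&
    !any(pch[min(core_cols):max(core_cols)] == "-")
  edits <- function(cols) {
    if (length(cols) == 0L) return(0L)
    sum(pch[cols] != sch[cols])  # mismatches and gap columns alike
  }
  up_cols <- which(spos < q$coreStart | (spos == q$coreStart & sch == "-"))
  down_cols <- which(spos > q$coreEnd)
  up_ok <- edits(up_cols) <= 1L
  down_ok <- edits(down_cols) <= 1L
  counted <- span >= q$minSpan && isTRUE(core_clean) && up_ok && down_ok
  list(counted = counted, span = span, coreIntact = isTRUE(core_clean),
       upEdits = edits(up_cols), downEdits = edits(down_cols))
}

#' Screen one read against a motif-anchored query
#'
#' Locally aligns the read (both strands) against the query (match +1,
#' mismatch -1, first gap base -2, each further gap base -1) and applies
#' the counting conditions of [motifQuery()].
#'
#' @param read read sequence (character scalar).
#' @param q a [motifQuery()] object.
#' @return list with `counted`, `strand`, `span`, `coreIntact`,
#'   `upEdits`, `downEdits` (for the counted orientation, or the better
#'   scoring one).
#' @export
alignAndScreen <- function(read, q) {
  read <- toupper(as_character_seq(read))
  if (nchar(read) < (q$coreEnd - q$coreStart + 1L))
    return(list(counted = FALSE, strand = NA_character_, span = 0L,
                coreIntact = FALSE, upEdits = NA_integer_,
                downEdits = NA_integer_))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  subj <- Biostrings::DNAString(q$query)
  best <- NULL
  for (strand in c("+", "-")) {
    r <- if (strand == "+") read else .cpp_revcomp(read)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(r), subj, type = "local",
      substitutionMatrix = mat, gapOpening = 1, gapExtension = 1)
    res <- .screen_alignment(aln, q)
    res$strand <- strand
    res$score <- Biostrings::score(aln)
    if (res$counted) return(res[c("counted", "strand", "span",
                                  "coreIntact", "upEdits", "downEdits")])
    if (is.null(best) || res$score > best$score) best <- res
  }
  best[c("counted", "strand", "span", "coreIntact", "upEdits",
         "downEdits")]
}

#' Count transcript-evidence reads in a library
#'
#' Applies [qcFilter()] then [alignAndScreen()] to every read; a fast
#' exact-core prefilter skips reads that cannot contain the intact core.
#'
#' @param reads a [SimulatedReads-class], data.frame (`seq`, `quality`),
#'   or character vector (assumed to have passed QC already).
#' @param q a [motifQuery()] object.
#' @param minQ,adapter passed to [qcFilter()].
#' @return list of class `MatchReport` with `readsIn`, `passedQc`,
#'   `counted` and `perRead` (data.frame for reads containing the core).
#' @export
countLibrary <- function(reads, q, minQ = 20, adapter = NULL) {
  if (is.character(reads)) {
    seqs <- toupper(reads)
    n_in <- length(seqs)
    passed <- n_in
  } else {
    n_in <- if (is(reads, "SimulatedReads")) length(reads@sequences)
    else nrow(reads)
    fq <- qcFilter(reads, minQ = minQ, adapter = adapter)
    seqs <- toupper(fq$sequences)
    passed <- fq$passed
  }
  core <- substr(q$query, q$coreStart, q$coreEnd)
  core_rc <- .cpp_revcomp(core)
  cand <- which(grepl(core, seqs, fixed = TRUE) |
                  grepl(core_rc, seqs, fixed = TRUE))
  per <- NULL
  counted <- 0L
  for (i in cand) {
    res <- alignAndScreen(seqs[i], q)
    counted <- counted + as.integer(res$counted)
    per <- rbind(per, data.frame(read = i, counted = res$counted,
                                 strand = res$strand, span = res$span,
                                 coreIntact = res$coreIntact,
                                 upEdits = res$upEdits,
                                 downEdits = res$downEdits))
  }
  if (is.null(per))
    per <- data.frame(read = integer(), counted = logical(),
                      strand = character(), span = integer(),
                      coreIntact = logical(), upEdits = integer(),
                      downEdits = integer())
  structure(list(readsIn = n_in, passedQc = passed, counted = counted,
                 perRead = per), class = "MatchReport")
}
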