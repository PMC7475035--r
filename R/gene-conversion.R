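#' @include AllClasses.R
NULL

#' Build a parental composite sequence in repeat coordinates
#'
#' Concatenates the fragments of the two parental genes that are homologous
#' to the repeat unit, placing each at its homology interval and padding
#' uncovered repeat positions with gap characters, so the composite can be
#' joined column-for-column into a repeat multiple sequence alignment and
#' act as an extra taxon in conversion analysis.
#'
#' @param parent5Segment,parent3Segment parental fragment sequences.
#' @param interval5,interval3 [IRanges::IRanges] homology intervals on the
#'   repeat (1-based, closed, disjoint); widths must match the fragment
#'   lengths.
#' @param repeatLength repeat unit length in nt.
#' @return character scalar of length `repeatLength` with `-` padding.
#' @export
buildComposite <- function(parent5Segment, parent3Segment, interval5,
                           interval3, repeatLength) {
  p5 <- as_character_seq(parent5Segment)
  p3 <- as_character_seq(parent3Segment)
  s5 <- BiocGenerics::start(interval5)[1L]
  e5 <- BiocGenerics::end(interval5)[1L]
  s3 <- BiocGenerics::start(interval3)[1L]
  e3 <- BiocGenerics::end(interval3)[1L]
  if (nchar(p5) != e5 - s5 + 1L || nchar(p3) != e3 - s3 + 1L)
    stop("fragment lengths must match homology interval widths")
  if (max(e5, e3) > repeatLength) stop("intervals exceed repeat length")
  if (s5 <= e3 && s3 <= e5)
    stop("overlapping homology intervals")
  out <- rep("-", repeatLength)
  out[s5:e5] <- strsplit(p5, "")[[1L]]
  out[s3:e3] <- strsplit(p3, "")[[1L]]
  paste(out, collapse = "")
}

#' Condense an alignment to its polymorphic columns
#'
#' Removes gap-containing columns (matching complete-deletion distance
#' handling; pairwise retention by flag) and keeps only columns with at
#' least two states among the sequences, with a bijective map back to the
#' original alignment coordinates.
#'
#' @param msa aligned sequences (character vector or
#'   [Biostrings::DNAStringSet], equal widths, >= 3 sequences).
#' @param dropGapColumns remove columns containing any gap or non-ACGT
#'   character before condensation (default `TRUE`).
#' @return list with `states` (character matrix, sequences x polymorphic
#'   columns), `columns` (original 1-based column indices) and `n` (number
#'   of polymorphic columns); `n = 0` with empty members is valid.
#' @export
condenseAlignment <- function(msa, dropGapColumns = TRUE) {
  nm <- if (!is.null(names(msa))) names(msa) else NULL
  seqs <- toupper(as.character(msa))
  names(seqs) <- nm
  if (length(seqs) < 3L)
    stop("need >= 3 sequences (pairwise conversion needs outgroup context)")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must be aligned (equal column count)")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  keep <- rep(TRUE, ncol(mat))
  if (dropGapColumns) {
    ok <- mat %in% c("A", "C", "G", "T"); dim(ok) <- dim(mat)
    keep <- apply(ok, 2L, all)
  }
  cols <- which(keep)
  sub <- mat[, cols, drop = FALSE]
  poly <- apply(sub, 2L, function(col) length(unique(col)) > 1L)
  list(states = sub[, poly, drop = FALSE], columns = cols[poly],
       n = sum(poly))
}

#' Zero-mismatch candidate conversion fragments
#'
#' For every sequence pair, finds the maximal runs of consecutive
#' polymorphic columns over which the pair agrees, bounded by a
#' disagreement or the alignment ends. The fragment score is the number of
#' polymorphic sites in the run; runs scoring below 2 are discarded.
#'
#' @param pa result of [condenseAlignment()] (>= 2 polymorphic columns).
#' @return data.frame with columns `seq1`, `seq2`, `startCol`, `endCol`
#'   (indices into the polymorphic columns), `start`, `end` (original
#'   alignment coordinates) and `score`.
#' @export
findFragments <- function(pa) {
  if (pa$n < 2L) stop("need >= 2 polymorphic columns")
  st <- pa$states
  ids <- rownames(st)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(st)))
  acc <- list()
  for (i in seq_len(nrow(st) - 1L)) for (j in (i + 1L):nrow(st)) {
    agree <- st[i, ] == st[j, ]
    r <- rle(agree)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values & r$lengths >= 2L)
    if (length(k))
      acc[[length(acc) + 1L]] <- data.frame(
        seq1 = ids[i], seq2 = ids[j],
        startCol = starts[k], endCol = ends[k],
        start = pa$columns[starts[k]], end = pa$columns[ends[k]],
        score = r$lengths[k])
  }
  out <- if (length(acc)) do.call(rbind, acc) else NULL
  if (is.null(out))
    out <- data.frame(seq1 = character(), seq2 = character(),
                      startCol = integer(), endCol = integer(),
                      start = integer(), end = integer(),
                      score = integer())
  out
}

.pair_agreement_matrix <- function(states) {
  n <- nrow(states)
  pairs <- combn(n, 2L)
  agree <- matrix(FALSE, ncol(pairs), ncol(states))
  for (p in seq_len(ncol(pairs)))
    agree[p, ] <- states[pairs[1L, p], ] == states[pairs[2L, p], ]
  list(agree = agree, pairs = pairs)
}

#' Permutation significance of conversion fragments
#'
#' The null is built by permuting the order of the polymorphic columns,
#' which destroys runs while preserving every pair's agreement fraction.
#' Per permutation the maximal fragment score is recorded for each pair;
#' the familywise-adjusted p of an observed fragment is the proportion of
#' permutations whose maximum score across all pairs reaches its score (a
#' max-statistic correction, exact under the permutation null), and the
#' per-pair p uses that pair's own null maxima. On alignments with few
#' enough columns that fewer distinct permutations than `nPerm` exist, all
#' column orders are enumerated exhaustively instead.
#'
#' @param pa result of [condenseAlignment()].
#' @param fragments result of [findFragments()] (may be filtered).
#' @param nPerm number of permutations (default 10000, >= 1000 unless
#'   exhaustive).
#' @param alpha significance level for the verdict (default 0.05).
#' @param seed integer seed.
#' @return `fragments` with added columns `p`, `p.adj`, `significant`.
#' @export
fragmentSignificance <- function(pa, fragments, nPerm = 10000L,
                                 alpha = 0.05, seed = 1L) {
  L <- pa$n
  exhaustive <- L <= 7L && factorial(L) <= nPerm
  if (!exhaustive && nPerm < 1000L) stop("need >= 1000 permutations")
  am <- .pair_agreement_matrix(pa$states)
  maxima <- if (exhaustive) .cpp_exhaustive_max_runs(am$agree)
  else .cpp_perm_max_runs(am$agree, as.integer(nPerm), seed * 1000 + 7)
  n_done <- nrow(maxima)
  overall <- apply(maxima, 1L, max)
  ids <- rownames(pa$states)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(pa$states)))
  pair_key <- paste(ids[am$pairs[1L, ]], ids[am$pairs[2L, ]])
  frag_pair <- match(paste(fragments$seq1, fragments$seq2), pair_key)
  if (anyNA(frag_pair))
    frag_pair[is.na(frag_pair)] <- match(
      paste(fragments$seq2, fragments$seq1)[is.na(frag_pair)], pair_key)
  # counts of null maxima >= score via sorted lookups, per pair
  overall_sorted <- sort(overall)
  count_ge <- function(sorted, s)
    length(sorted) - findInterval(s - 0.5, sorted)
  p <- p_adj <- numeric(nrow(fragments))
  for (pr in unique(frag_pair)) {
    rows <- which(frag_pair == pr)
    pair_sorted <- sort(maxima[, pr])
    p[rows] <- mc_p(vapply(fragments$score[rows], count_ge,
                           numeric(1L), sorted = pair_sorted), n_done)
    p_adj[rows] <- mc_p(vapply(fragments$score[rows], count_ge,
                               numeric(1L), sorted = overall_sorted),
                        n_done)
  }
  fragments$p <- p
  fragments$p.adj <- pmax(p, p_adj)
  fragments$significant <- fragments$p.adj < alpha
  fragments
}

#' Summarize significant conversion events
#'
#' Counts significant fragments touching each sequence, the fraction of
#' events involving each sequence or group label, and a positional
#' histogram of event midpoints over the original alignment coordinates
#' (exportable to Circos-style link tracks).
#'
#' @param fragments result of [fragmentSignificance()].
#' @param groups optional named vector mapping sequence id to a group
#'   label (e.g. paratype).
#' @param breaks histogram breaks over alignment coordinates (default 10
#'   equal bins over the observed range).
#' @return list with `perSequence` (data.frame `id`, `events`),
#'   `contribution` (fraction of events involving each id or group) and
#'   `histogram` (data.frame `start`, `end`, `events`).
#' @export
summarizeEvents <- function(fragments, groups = NULL, breaks = 10L) {
  sig <- fragments[isTRUE_v(fragments$significant), , drop = FALSE]
  ids <- unique(c(fragments$seq1, fragments$seq2))
  events <- vapply(ids, function(id)
    sum(sig$seq1 == id | sig$seq2 == id), integer(1L))
  per_seq <- data.frame(id = ids, events = unname(events))
  n_ev <- nrow(sig)
  contribution <- if (n_ev == 0L) setNames(rep(0, length(ids)), ids)
  else events / n_ev
  if (!is.null(groups)) {
    g1 <- groups[sig$seq1]; g2 <- groups[sig$seq2]
    labs <- unique(groups)
    contribution <- vapply(labs, function(g)
      if (n_ev == 0L) 0 else sum(g1 == g | g2 == g) / n_ev, numeric(1L))
    names(contribution) <- labs
  }
  hist_df <- data.frame(start = numeric(), end = numeric(),
                        events = integer())
  if (n_ev > 0L) {
    mid <- (sig$start + sig$end) / 2
    if (length(breaks) == 1L)
      breaks <- seq(min(fragments$start), max(fragments$end),
                    length.out = breaks + 1L)
    cl <- cut(mid, breaks, include.lowest = TRUE)
    hist_df <- data.frame(start = breaks[-length(breaks)],
                          end = breaks[-1L],
                          events = as.integer(table(cl)))
  }
  list(perSequence = per_seq, contribution = contribution,
       histogram = hist_df)
}

isTRUE_v <- function(x) !is.na(x) & x
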