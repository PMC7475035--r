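#' @include AllClasses.R
NULL

#' Classify tandem copies into paratypes from diagnostic amino-acid blocks
#'
#' Scans an aligned set of predicted proteins for maximal contiguous runs
#' of alignment columns in which at least two sequences disagree; runs of
#' width at least `minBlock` (default 5 residues) are diagnostic blocks. A
#' paratype is the equivalence class of sequences over the tuple of their
#' block states, so disagreements confined to runs shorter than `minBlock`
#' never split a paratype. Labels are assigned alphabetically (`a`, `b`,
#' ...) by first occurrence in input order; classifying copies from several
#' strains jointly therefore yields labels that are comparable across
#' strains. Gap characters count as states, so length variants at the 3'
#' end are diagnostic.
#'
#' @param proteins aligned proteins ([Biostrings::AAStringSet] or character
#'   vector; equal column counts).
#' @param minBlock minimum diagnostic block width in alignment columns.
#' @return list with `labels` (character, per sequence), `blocks`
#'   (data.frame with `start`, `end`, `width` in alignment columns) and
#'   `states` (character matrix, sequences x blocks).
#' @export
#' @examples
#' p <- c(A = "MKLVVNNNNQ", B = "MKLVVWWWWW", C = "MKLVVNNNNQ")
#' classifyParatypes(p)$labels
classifyParatypes <- function(proteins, minBlock = 5L) {
  nm <- if (!is.null(names(proteins))) names(proteins) else NULL
  seqs <- as.character(proteins)
  names(seqs) <- nm
  if (length(seqs) < 1L) stop("no sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("proteins must be aligned (ragged column counts)")
  mat <- do.call(rbind, strsplit(seqs, ""))
  poly <- apply(mat, 2L, function(col) length(unique(col)) > 1L)
  r <- rle(poly)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values & r$lengths >= minBlock)
  blocks <- data.frame(start = run_start[keep], end = run_end[keep],
                       width = r$lengths[keep])
  if (nrow(blocks) == 0L) {
    labels <- rep("a", length(seqs))
    names(labels) <- names(seqs)
    return(list(labels = labels, blocks = blocks,
                states = matrix(character(), length(seqs), 0L)))
  }
  states <- vapply(seq_len(nrow(blocks)), function(b)
    apply(mat[, blocks$start[b]:blocks$end[b], drop = FALSE], 1L,
          paste, collapse = ""), character(length(seqs)))
  if (is.null(dim(states)))
    states <- matrix(states, nrow = length(seqs))
  key <- apply(states, 1L, paste, collapse = "|")
  first <- !duplicated(key)
  lab_map <- setNames(.paratype_labels(sum(first)), key[first])
  labels <- unname(lab_map[key])
  names(labels) <- names(seqs)
  list(labels = labels, blocks = blocks, states = states)
}

# a..z, then aa, ab, ... for pathological numbers of paratypes
.paratype_labels <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  c(letters, as.vector(t(outer(letters, letters, paste0))))[seq_len(n)]
}
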