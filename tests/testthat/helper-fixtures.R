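# Shared fixtures: everything is generated in code at test time.

# Small tandem region for annotation-scale tests (kb-scale flanks).
small_spec <- function(nCopies = 3, paratypes = rep("a", nCopies),
                       seed = 7, flankLength = 1500, ...) {
  tandemRegionSpec(nCopies = nCopies, paratypes = paratypes,
                   flankLength = flankLength, seed = seed, ...)
}

region_copy_seqs <- function(region) {
  ct <- copyTable(region)
  g <- as.character(regionSequence(region))
  vapply(seq_len(nrow(ct)), function(i)
    substr(g, ct$start[i], ct$end[i]), character(1))
}

region_proteins <- function(region) {
  ex <- region@spec@exonLayout
  seqs <- region_copy_seqs(region)
  vapply(seqs, function(s) callOrf(s, ex)$protein, character(1),
         USE.NAMES = FALSE)
}

# Random MSA: n sequences independently mutated from one ancestor, so the
# expected pairwise divergence is about 2 * rate.
random_msa <- function(n, length, rate, seed,
                       convert = NULL) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length, replace = TRUE)
  seqs <- lapply(seq_len(n), function(i) {
    x <- anc
    hit <- which(runif(length) < rate)
    x[hit] <- sample(bases, length(hit), replace = TRUE)
    x
  })
  if (!is.null(convert))  # list(donor, recipient, start, end)
    seqs[[convert$recipient]][convert$start:convert$end] <-
      seqs[[convert$donor]][convert$start:convert$end]
  out <- vapply(seqs, paste, character(1), collapse = "")
  names(out) <- paste0("s", seq_len(n))
  out
}

# The paper-style seven-strain design: 13 paratype labels, 3-5 per strain,
# one label ("e") present in every strain.
strain_paratype_sets <- list(
  s1 = c("a", "b", "c", "e"),
  s2 = c("d", "e", "f"),
  s3 = c("e", "g", "h", "i"),
  s4 = c("e", "j", "k"),
  s5 = c("l", "m", "e", "a"),
  s6 = c("b", "e", "g", "j", "l"),
  s7 = c("c", "f", "i", "m", "e"))

build_strain_panel_proteins <- function(sets = strain_paratype_sets,
                                        seed = 42) {
  prots <- character(0)
  truth <- character(0)
  strain <- character(0)
  for (i in seq_along(sets)) {
    reg <- buildRegion(tandemRegionSpec(
      nCopies = length(sets[[i]]), paratypes = sets[[i]],
      flankLength = 1000, seed = seed))
    p <- region_proteins(reg)
    names(p) <- paste0(names(sets)[i], "_", seq_along(p))
    prots <- c(prots, p)
    truth <- c(truth, copyTable(reg)$paratype)
    strain <- c(strain, rep(names(sets)[i], length(p)))
  }
  list(proteins = prots, truth = truth, strain = strain)
}

# Brute-force Smith-Waterman (match 1, mismatch -1, first gap base 2,
# each further base 1) returning one optimal local alignment as aligned
# column pairs; the independent oracle for the motif screen.
brute_local_align <- function(read, query) {
  r <- strsplit(read, "")[[1]]; q <- strsplit(query, "")[[1]]
  n <- length(r); m <- length(q)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)      # best ending in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)    # gap in query (read char unmatched)
  Y <- matrix(NEG, n + 1, m + 1)    # gap in read (query char unmatched)
  M[1, ] <- 0; M[, 1] <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (r[i] == q[j]) 1 else -1
    M[i + 1, j + 1] <- max(0, M[i, j] + s, X[i, j] + s, Y[i, j] + s)
    X[i + 1, j + 1] <- max(M[i, j + 1] - 2, X[i, j + 1] - 1)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - 2, Y[i + 1, j] - 1)
  }
  best <- max(M)
  hit <- which(M == best, arr.ind = TRUE)[1, ]
  i <- hit[1] - 1; j <- hit[2] - 1
  cols <- NULL  # rows: read index (NA = gap), query index (NA = gap)
  state <- "M"
  repeat {
    if (state == "M") {
      if (i == 0 || j == 0 || M[i + 1, j + 1] == 0) break
      s <- if (r[i] == q[j]) 1 else -1
      prev <- M[i + 1, j + 1] - s
      cols <- rbind(c(i, j), cols)
      if (i >= 1 && j >= 1 && abs(X[i, j] - prev) < 1e-9 &&
          X[i, j] > M[i, j] + 1e-9) state <- "X"
      else if (i >= 1 && j >= 1 && abs(Y[i, j] - prev) < 1e-9 &&
               Y[i, j] > M[i, j] + 1e-9) state <- "Y"
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      cols <- rbind(c(i, NA), cols)
      if (abs(X[i + 1, j + 1] - (M[i, j + 1] - 2)) < 1e-9) state <- "M"
      i <- i - 1
    } else {
      cols <- rbind(c(NA, j), cols)
      if (abs(Y[i + 1, j + 1] - (M[i + 1, j] - 2)) < 1e-9) state <- "M"
      j <- j - 1
    }
  }
  list(score = best, cols = cols)
}

# Apply the motif-screen conditions to a brute-force alignment.
brute_screen <- function(read, q) {
  verdict_for <- function(rd) {
    aln <- brute_local_align(rd, q$query)
    cols <- aln$cols
    if (is.null(cols)) return(FALSE)
    qpos <- cols[, 2]
    span <- max(qpos, na.rm = TRUE) - min(qpos, na.rm = TRUE) + 1
    core_cols <- which(!is.na(qpos) & qpos >= q$coreStart &
                         qpos <= q$coreEnd)
    if (length(core_cols) != q$coreEnd - q$coreStart + 1) return(FALSE)
    rr <- strsplit(rd, "")[[1]]; qq <- strsplit(q$query, "")[[1]]
    core_range <- min(core_cols):max(core_cols)
    if (any(is.na(cols[core_range, 1])) || any(is.na(cols[core_range, 2])))
      return(FALSE)
    if (any(rr[cols[core_cols, 1]] != qq[cols[core_cols, 2]]))
      return(FALSE)
    edits <- function(sel) {
      if (!length(sel)) return(0)
      sum(vapply(sel, function(k) {
        if (is.na(cols[k, 1]) || is.na(cols[k, 2])) return(1L)
        as.integer(rr[cols[k, 1]] != qq[cols[k, 2]])
      }, integer(1)))
    }
    up <- which(seq_len(nrow(cols)) < min(core_cols))
    down <- which(seq_len(nrow(cols)) > max(core_cols))
    span >= q$minSpan && edits(up) <= 1 && edits(down) <= 1
  }
  verdict_for(read) || verdict_for(tandemCNV:::.cpp_revcomp(read))
}

mutate_base <- function(s, pos) {
  old <- substr(s, pos, pos)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(s, pos, pos) <- new
  s
}
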