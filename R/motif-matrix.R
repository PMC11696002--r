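#' Assemble a position count matrix around a seed word
#'
#' Collects every occurrence of the seed (both strands by default;
#' minus-strand windows are reverse-complemented) together with
#' `flank` bp of context on each side, and tallies per-position
#' nucleotide counts. Dyad seeds are written `AAA{n}BBB` and matched
#' with `n` free spacer positions, so the matrix contains both cores at
#' the planted spacing with the spacer filled from the data.
#'
#' @param seed A seed word (character), a `word_stats`/`dyad_stats`
#'   table (its top-ranked entry is used), or a dyad label.
#' @param sequences Character vector or `DNAStringSet`.
#' @param flank Flanking bases included on each side.
#' @param both_strands Also collect reverse-strand occurrences.
#' @param pseudocount Smoothing constant distributed by background
#'   frequencies when the matrix is converted to log-odds.
#' @param background `background_model` attached to the matrix.
#' @return An object of class `count_matrix`: `counts` (4 x width),
#'   `width`, `nsites`, `pseudocount`, `background`, `seed`.
#' @export
assemble_count_matrix <- function(seed, sequences, flank = 0L,
                                  both_strands = TRUE, pseudocount = 1,
                                  background = uniform_background()) {
  if (is.data.frame(seed)) {
    if (nrow(seed) == 0L) stop("no significant seed word")
    seed <- seed$word[1L]
  }
  pattern <- dyad_label_to_pattern(seed)
  seqs <- as_dna_set(sequences)
  windows <- seed_windows(pattern, seqs, flank)
  if (both_strands) {
    rc_hits <- seed_windows(pattern, Biostrings::reverseComplement(seqs), flank)
    windows <- c(windows, rc_hits)
  }
  if (length(windows) == 0L) stop("seed '", seed, "' has no occurrences")
  counts <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
  counts <- counts[DNA, , drop = FALSE]
  structure(list(counts = counts, width = ncol(counts),
                 nsites = length(windows), pseudocount = pseudocount,
                 background = background, seed = seed),
            class = "count_matrix")
}

dyad_label_to_pattern <- function(label) {
  m <- regmatches(label, regexec("^([ACGT]+)\\{(\\d+)\\}([ACGT]+)$", label))[[1L]]
  if (length(m) == 4L) {
    paste0(m[2L], strrep("N", as.integer(m[3L])), m[4L])
  } else {
    label
  }
}

seed_windows <- function(pattern, seqs, flank) {
  hits <- Biostrings::vmatchPattern(pattern, seqs, fixed = "subject")
  out <- character(0)
  w <- nchar(pattern)
  for (i in seq_along(hits)) {
    st <- BiocGenerics::start(hits[[i]]) - flank
    en <- BiocGenerics::start(hits[[i]]) + w - 1L + flank
    ok <- st >= 1L & en <= Biostrings::width(seqs)[i]
    if (any(ok)) {
      out <- c(out, as.character(Biostrings::extractAt(
        seqs[[i]], IRanges::IRanges(st[ok], en[ok]))))
    }
  }
  out
}

#' Position frequency matrix with pseudocounts
#'
#' @param matrix A `count_matrix`.
#' @return 4 x width matrix of smoothed position frequencies.
#' @export
matrix_frequencies <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  bg <- matrix$background$marginal
  num <- matrix$counts + matrix$pseudocount * bg
  sweep(num, 2L, colSums(num), "/")
}

#' Log-odds weights on a discrete score lattice
#'
#' Converts a count matrix into log2 likelihood-ratio weights against
#' the background mononucleotide composition, then quantises the
#' weights onto an integer lattice of `n_bins` steps spanning the full
#' score range. Scoring and the null score distribution both use the
#' quantised weights, so the p-values reported for hits are exact for
#' the scoring scheme actually applied (quantisation perturbs any
#' individual weight by at most half a lattice step).
#'
#' @param matrix A `count_matrix`.
#' @param n_bins Lattice resolution (default 1e4).
#' @return An object of class `pssm`: integer `weights` (4 x width),
#'   `delta` (bits per lattice step), `background` probabilities, and
#'   the exact null `distribution` (support, probability, upper tail).
#' @export
pssm_logodds <- function(matrix, n_bins = 1e4L) {
  freq <- matrix_frequencies(matrix)
  bg <- matrix$background$marginal
  w_real <- log2(freq / bg)
  span <- sum(apply(w_real, 2L, max)) - sum(apply(w_real, 2L, min))
  delta <- if (span > 0) span / n_bins else 1
  weights <- round(w_real / delta)
  storage.mode(weights) <- "integer"
  dist <- pssm_null_distribution(weights, bg)
  structure(list(weights = weights, delta = delta, width = ncol(weights),
                 background = bg, distribution = dist),
            class = "pssm")
}

# Exact distribution of the lattice score under an order-0 background,
# by dynamic-programming convolution across positions.
pssm_null_distribution <- function(weights, bg) {
  lo <- sum(apply(weights, 2L, min))
  hi <- sum(apply(weights, 2L, max))
  probs <- rep(0, hi - lo + 1L)
  # running support starts at "empty prefix" = score 0
  run_lo <- 0L
  run <- 1
  for (i in seq_len(ncol(weights))) {
    wcol <- weights[, i]
    new_lo <- run_lo + min(wcol)
    new_hi <- run_lo + length(run) - 1L + max(wcol)
    acc <- rep(0, new_hi - new_lo + 1L)
    for (b in 1:4) {
      shift <- run_lo + wcol[b] - new_lo
      idx <- (shift + 1L):(shift + length(run))
      acc[idx] <- acc[idx] + run * bg[b]
    }
    run <- acc
    run_lo <- new_lo
  }
  support <- seq.int(run_lo, run_lo + length(run) - 1L)
  keep <- run > 0
  tail_all <- rev(cumsum(rev(run)))
  list(support = support[keep], probability = run[keep],
       tail = tail_all[keep])
}

# Upper-tail p-value of integer lattice scores
pssm_score_pvalue <- function(pssm, score_int) {
  dist <- pssm$distribution
  idx <- findInterval(score_int - 1L, dist$support) + 1L
  # findInterval gives the last support <= score-1; idx is the first
  # support >= score
  p <- ifelse(idx > length(dist$support), 0, dist$tail[pmax(idx, 1L)])
  ifelse(score_int <= dist$support[1L], 1, p)
}

#' Score a set of words with a PSSM
#'
#' @param pssm A `pssm` object.
#' @param words Character vector of words of matching width.
#' @return Data.frame with lattice score (`score_int`), score in bits
#'   (`score`) and the exact p-value `P(background score >= score)`.
#' @export
pssm_score_words <- function(pssm, words) {
  stopifnot(all(nchar(words) == pssm$width))
  ints <- vapply(strsplit(words, "", fixed = TRUE), function(chars) {
    b <- match(chars, DNA)
    if (anyNA(b)) return(NA_integer_)
    sum(pssm$weights[cbind(b, seq_along(chars))])
  }, integer(1))
  data.frame(word = words, score_int = ints, score = ints * pssm$delta,
             pvalue = pssm_score_pvalue(pssm, ints),
             stringsAsFactors = FALSE)
}

#' Scan sequences for PSSM matches with exact p-values
#'
#' Both strands are scanned by default. A hit is reported at every
#' offset whose score p-value -- the exact probability that a background
#' word scores at least as high -- is at or below the threshold.
#' Sequences shorter than the matrix are skipped with a notice.
#'
#' @param matrix A `count_matrix` (or a prebuilt `pssm`).
#' @param sequences Character vector or `DNAStringSet`.
#' @param p_threshold Hit p-value threshold in (0, 1); the stringent
#'   default 1e-5 matches the binding-site prediction cut-off used for
#'   the peak scans.
#' @param both_strands Scan the reverse strand too.
#' @return A data.frame of class `motif_hits`: `sequence_id`, `offset`
#'   (0-based, forward-strand coordinates), `strand`, `score` (bits),
#'   `pvalue`.
#' @export
scan_pssm <- function(matrix, sequences, p_threshold = 1e-5,
                      both_strands = TRUE) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  pssm <- if (inherits(matrix, "pssm")) matrix else pssm_logodds(matrix)
  seqs <- as_dna_set(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(seqs))
  w <- pssm$width
  short <- Biostrings::width(seqs) < w
  if (any(short)) {
    message(sum(short), " sequence(s) shorter than the matrix skipped")
  }
  rows <- list()
  for (i in which(!short)) {
    s <- as.character(seqs[[i]])
    L <- nchar(s)
    base <- match(strsplit(s, "", fixed = TRUE)[[1L]], DNA)
    strands <- if (both_strands) c("+", "-") else "+"
    for (strand in strands) {
      b <- if (strand == "+") base else rev(5L - base)
      n_off <- L - w + 1L
      scores <- rep(0L, n_off)
      valid <- rep(TRUE, n_off)
      for (j in seq_len(w)) {
        bj <- b[j:(j + n_off - 1L)]
        valid <- valid & !is.na(bj)
        wj <- pssm$weights[, j][bj]
        wj[is.na(wj)] <- 0L
        scores <- scores + wj
      }
      pv <- pssm_score_pvalue(pssm, scores)
      hit <- valid & pv <= p_threshold
      if (any(hit)) {
        off0 <- which(hit) - 1L
        if (strand == "-") off0 <- L - w - off0
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = ids[i], offset = off0, strand = strand,
          score = scores[hit] * pssm$delta, pvalue = pv[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence_id = character(0), offset = integer(0),
               strand = character(0), score = numeric(0),
               pvalue = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Motif enrichment in peaks versus control sequences
#'
#' Two-sided Fisher exact test on the 2x2 table of sequences with or
#' without at least one motif hit, peaks versus controls. The odds
#' ratio is the sample odds ratio, with the Haldane half-count
#' correction applied when any cell is zero.
#'
#' @param hits_in_peaks,n_peaks Sequences with hits / total, peak set.
#' @param hits_in_control,n_control Same for the control set.
#' @return A list with `odds_ratio`, `p.value` and the 2x2 `table`.
#' @export
motif_enrichment <- function(hits_in_peaks, n_peaks, hits_in_control,
                             n_control) {
  if (n_peaks == 0L || n_control == 0L) stop("empty sequence set")
  stopifnot(hits_in_peaks <= n_peaks, hits_in_control <= n_control)
  tab <- matrix(c(hits_in_peaks, n_peaks - hits_in_peaks,
                  hits_in_control, n_control - hits_in_control),
                nrow = 2L,
                dimnames = list(hit = c("yes", "no"),
                                set = c("peak", "control")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- if (any(tab == 0)) {
    ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  list(odds_ratio = unname(or), p.value = ft$p.value, table = tab)
}

#' Cluster similar count matrices
#'
#' Pairwise similarity is the maximum Pearson correlation of aligned
#' position-frequency columns over all offsets and both orientations
#' (a matrix is also compared against the reverse complement of the
#' other), requiring at least `min_overlap` aligned columns. Matrices
#' are grouped by single linkage at similarity >= `cor_threshold`
#' (connected components of the similarity graph).
#'
#' @param matrices List of `count_matrix` objects.
#' @param cor_threshold Similarity threshold in (0, 1).
#' @param min_overlap Minimum aligned width.
#' @return A list with `membership` (integer cluster per matrix) and the
#'   pairwise `similarity` matrix.
#' @export
cluster_matrices <- function(matrices, cor_threshold = 0.8, min_overlap = 4L) {
  stopifnot(length(matrices) >= 1L, cor_threshold > 0, cor_threshold < 1)
  freqs <- lapply(matrices, matrix_frequencies)
  n <- length(freqs)
  sim <- diag(1, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        sim[i, j] <- sim[j, i] <- max(
          aligned_correlation(freqs[[i]], freqs[[j]], min_overlap),
          aligned_correlation(freqs[[i]], revcomp_matrix(freqs[[j]]),
                              min_overlap))
      }
    }
  }
  adj <- sim >= cor_threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  membership <- as.integer(igraph::components(g)$membership)
  list(membership = membership, similarity = sim)
}

revcomp_matrix <- function(freq) {
  out <- freq[c("T", "G", "C", "A"), rev(seq_len(ncol(freq))), drop = FALSE]
  rownames(out) <- DNA
  out
}

aligned_correlation <- function(f1, f2, min_overlap) {
  w1 <- ncol(f1); w2 <- ncol(f2)
  best <- -1
  for (shift in (-(w2 - min_overlap)):(w1 - min_overlap)) {
    lo <- max(1L, 1L + shift)
    hi <- min(w1, w2 + shift)
    if (hi - lo + 1L < min_overlap) next
    i1 <- lo:hi
    i2 <- i1 - shift
    r <- suppressWarnings(stats::cor(as.vector(f1[, i1, drop = FALSE]),
                                     as.vector(f2[, i2, drop = FALSE])))
    if (!is.na(r) && r > best) best <- r
  }
  best
}

#' Write count matrices in a minimal MEME-like text format
#'
#' @param matrices List of `count_matrix` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrices <- function(matrices, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    writeLines(sprintf("MOTIF %s w=%d nsites=%d", m$seed, m$width, m$nsites),
               con)
    freq <- t(matrix_frequencies(m))
    utils::write.table(format(freq, digits = 6), con, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines("", con)
  }
  invisible(path)
}
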