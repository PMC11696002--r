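#' Count k-mer occurrences across sequences
#'
#' Overlapping occurrences are counted (no clumping); windows containing
#' non-ACGT characters are skipped. With `both_strands = TRUE` a word and
#' its reverse complement are pooled under the lexicographically smaller
#' key, so pooled counts conserve the total of the two per-strand counts.
#'
#' @param sequences Character vector or `DNAStringSet` over `A,C,G,T,N`.
#' @param k Word length (4--8).
#' @param both_strands Pool each word with its reverse complement.
#' @return Named integer vector of counts over all 4^k words (pooled
#'   keys when `both_strands`), with attribute `n_positions` giving the
#'   number of countable windows (doubled when both strands are read).
#' @export
count_words <- function(sequences, k, both_strands = FALSE) {
  stopifnot(k >= 4L, k <= 8L)
  seqs <- as_dna_set(sequences)
  counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = k))
  n_pos <- sum(counts)
  if (both_strands) {
    words <- names(counts)
    rc <- revcomp(words)
    keys <- pmin(words, rc)
    pooled <- counts + counts[rc]
    counts <- pooled[words <= rc]
    names(counts) <- keys[words <= rc]
    n_pos <- 2L * n_pos
  }
  counts <- as.integer(counts) |> stats::setNames(names(counts))
  attr(counts, "n_positions") <- as.numeric(n_pos)
  counts
}

#' Rank words by binomial over-representation
#'
#' For each word, the expected count under the background is
#' `n_positions * P(word)` and the p-value is the upper binomial tail
#' `P(X >= observed)` with `n = n_positions` trials. E-values multiply
#' the p-value by the number of distinct words tested in this run, and
#' significance is `-log10(evalue)`. Only positively enriched words
#' (`sig > 0`, i.e. e-value < 1) are reported, at most `top_n` of them.
#'
#' @param counts Named count vector from [count_words()] (or compatible),
#'   with an `n_positions` attribute unless given explicitly.
#' @param n_positions Total countable windows.
#' @param background A `background_model` (order 0 for the Bernoulli
#'   word analysis; higher orders are supported).
#' @param top_n Maximum number of reported words (3 mirrors the
#'   hits-per-algorithm cap of the discovery protocol).
#' @param both_strands Whether `counts` are strand-pooled; pooled word
#'   probability is then `P(word) + P(revcomp)` (halved for
#'   reverse-complement palindromes).
#' @param n_tested E-value multiplicity: the number of distinct words
#'   tested in this run. Defaults to `length(counts)`, which is the
#'   full word universe when `counts` comes from [count_words()].
#' @return A data.frame of class `word_stats`: `word`, `observed`,
#'   `expected`, `pvalue`, `evalue`, `sig`, ranked by `sig` descending.
#' @export
word_significance <- function(counts, n_positions = attr(counts, "n_positions"),
                              background = uniform_background(), top_n = 3L,
                              both_strands = FALSE,
                              n_tested = length(counts)) {
  stopifnot(!is.null(n_positions), n_positions > 0)
  words <- names(counts)
  p <- word_probability(words, background)
  if (both_strands) {
    rc <- revcomp(words)
    p_rc <- word_probability(rc, background)
    p <- ifelse(rc == words, p, (p + p_rc) / 2)
    # pooled windows double-count both strands, so the per-window pooled
    # probability is the mean of the two strand probabilities
  }
  if (any(p <= 0)) stop("background assigns zero probability to a word")
  stats_tab <- binomial_enrichment(words, as.numeric(counts), n_positions, p,
                                   n_tested = n_tested)
  rank_enrichment(stats_tab, top_n)
}

binomial_enrichment <- function(label, observed, n, p, n_tested) {
  expected <- n * p
  pvalue <- stats::pbinom(observed - 1, size = n, prob = p, lower.tail = FALSE)
  evalue <- pmin(pvalue * n_tested, Inf)
  data.frame(word = label, observed = observed, expected = expected,
             pvalue = pvalue, evalue = evalue,
             sig = -log10(pmax(evalue, .Machine$double.xmin)),
             stringsAsFactors = FALSE)
}

rank_enrichment <- function(stats_tab, top_n) {
  stats_tab <- stats_tab[order(-stats_tab$sig, stats_tab$word), , drop = FALSE]
  stats_tab <- stats_tab[stats_tab$sig > 0, , drop = FALSE]
  out <- utils::head(stats_tab, top_n)
  rownames(out) <- NULL
  class(out) <- c("word_stats", "data.frame")
  out
}

#' Rank spaced dyads by binomial over-representation
#'
#' A dyad is a pair of 3-bp monads separated by an exact spacer of
#' 0--`max_spacing` background positions, the hallmark arrangement of
#' KNOX TGAC-core binding elements. Occurrences are counted per
#' (monad_a, spacing, monad_b); the expectation under the background is
#' `windows(spacing) * P(a) * P(b)` (monad independence), and binomial
#' tails / e-values follow the word analysis. The e-value multiplicity
#' is the number of distinct dyads tested across all spacings. With
#' `both_strands`, a dyad pools with its reverse complement
#' (`rc(b) .. rc(a)` at the same spacing).
#'
#' @param sequences Character vector or `DNAStringSet`.
#' @param max_spacing Maximum spacer length (<= 20).
#' @param background A `background_model`.
#' @param top_n Maximum reported dyads.
#' @param both_strands Pool dyads with their reverse complements.
#' @param monad_len Monad length (3 for the canonical analysis).
#' @return A data.frame of class `dyad_stats` with columns `word`
#'   (rendered as `AAA{n}BBB`), `monad_a`, `monad_b`, `spacing`,
#'   `observed`, `expected`, `pvalue`, `evalue`, `sig`.
#' @export
dyad_significance <- function(sequences, max_spacing = 10L,
                              background = uniform_background(), top_n = 3L,
                              both_strands = FALSE, monad_len = 3L) {
  stopifnot(max_spacing >= 0L, max_spacing <= 20L, monad_len >= 2L)
  seqs <- as.character(as_dna_set(sequences))
  lens <- nchar(seqs)
  # all monad occurrences per sequence, indexed by start
  monads <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < monad_len) return(character(0))
    starts <- seq_len(n - monad_len + 1L)
    substring(s, starts, starts + monad_len - 1L)
  })
  valid <- lapply(monads, function(m) grepl("^[ACGT]+$", m))
  tallies <- list()
  windows <- numeric(max_spacing + 1L)
  for (s in 0:max_spacing) {
    gap <- monad_len + s
    windows[s + 1L] <- sum(pmax(0L, lens - (2L * monad_len + s) + 1L))
    pairs <- character(0)
    for (i in seq_along(monads)) {
      m <- monads[[i]]
      if (length(m) <= gap) next
      a <- m[seq_len(length(m) - gap)]
      b <- m[(gap + 1L):length(m)]
      ok <- valid[[i]][seq_len(length(m) - gap)] &
        valid[[i]][(gap + 1L):length(m)]
      if (any(ok)) pairs <- c(pairs, paste0(a[ok], ".", b[ok]))
    }
    if (length(pairs)) {
      tab <- table(pairs)
      tallies[[as.character(s)]] <- tab
    } else {
      tallies[[as.character(s)]] <- table(character(0))
    }
  }
  rows <- list()
  for (s in 0:max_spacing) {
    tab <- tallies[[as.character(s)]]
    if (length(tab) == 0L) next
    parts <- strsplit(names(tab), ".", fixed = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      monad_a = vapply(parts, `[`, character(1), 1L),
      monad_b = vapply(parts, `[`, character(1), 2L),
      spacing = s,
      observed = as.numeric(tab),
      windows = windows[s + 1L],
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) stop("no countable dyad windows")
  dy <- do.call(rbind, rows)
  if (both_strands) {
    # a dyad's reverse complement is rc(b)..rc(a) at the same spacing;
    # the pooled count is forward + mirror occurrences (2x for
    # self-mirror dyads, matching a scan of both strands)
    key <- paste(dy$monad_a, dy$spacing, dy$monad_b, sep = ".")
    mirror_a <- revcomp(dy$monad_b)
    mirror_b <- revcomp(dy$monad_a)
    mirror_key <- paste(mirror_a, dy$spacing, mirror_b, sep = ".")
    obs <- stats::setNames(dy$observed, key)
    mirror_obs <- ifelse(mirror_key %in% key, obs[mirror_key], 0)
    dy$observed <- dy$observed + mirror_obs
    dy$windows <- 2 * dy$windows
    keep <- key <= mirror_key
    # mirrors observed without their forward partner surface as keys too
    orphan <- !(pmin(key, mirror_key) %in% key[keep])
    dy <- dy[keep | orphan, , drop = FALSE]
  }
  p_a <- word_probability(unique(c(dy$monad_a, dy$monad_b)), background)
  p <- p_a[dy$monad_a] * p_a[dy$monad_b]
  if (both_strands) {
    rc_a <- revcomp(dy$monad_a)
    rc_b <- revcomp(dy$monad_b)
    p_rc <- word_probability(unique(c(rc_a, rc_b)), background)
    p_mirror <- p_rc[rc_b] * p_rc[rc_a]
    self <- rc_b == dy$monad_a & rc_a == dy$monad_b
    p <- ifelse(self, p, (p + p_mirror) / 2)
  }
  n_spacings <- max_spacing + 1L
  n_tested <- (4L^monad_len)^2 * n_spacings
  label <- sprintf("%s{%d}%s", dy$monad_a, dy$spacing, dy$monad_b)
  out <- cbind(
    binomial_enrichment(label, dy$observed, dy$windows, as.numeric(p),
                        n_tested = n_tested),
    dy[, c("monad_a", "monad_b", "spacing")]
  )
  out <- rank_enrichment(out, top_n)
  class(out) <- c("dyad_stats", class(out))
  out
}

#' Positional concentration of a word around the summit
#'
#' Sequences are assumed aligned on the peak summit (summit at the
#' sequence centre). Occurrences of `word` with start offsets inside the
#' window are binned, and the bin counts are tested against a
#' homogeneous expectation with a chi-square test on `bins - 1` degrees
#' of freedom. A word tied to the binding site concentrates centrally;
#' background words spread evenly.
#'
#' @param sequences Summit-centred sequences.
#' @param word DNA word to locate (exact matches).
#' @param bin_width Bin width in bp; must divide `window_bp`.
#' @param window_bp Even window width centred on the summit.
#' @return A list with `statistic`, `df`, `p.value` and the bin `counts`.
#' @export
position_chi2 <- function(sequences, word, bin_width = 10L, window_bp = 100L) {
  stopifnot(window_bp %% 2L == 0L, window_bp %% bin_width == 0L)
  n_bins <- window_bp %/% bin_width
  if (n_bins < 2L) stop("need at least 2 bins")
  seqs <- as_dna_set(sequences)
  hits <- Biostrings::vmatchPattern(word, seqs)
  centre <- floor(Biostrings::width(seqs) / 2)
  offsets <- unlist(lapply(seq_along(hits), function(i) {
    BiocGenerics::start(hits[[i]]) - 1L - centre[i]
  }))
  half <- window_bp %/% 2L
  offsets <- offsets[offsets >= -half & offsets < half]
  if (length(offsets) == 0L) {
    return(list(statistic = 0, df = n_bins - 1L, p.value = 1,
                counts = rep(0L, n_bins)))
  }
  bins <- findInterval(offsets, seq(-half, half, by = bin_width),
                       rightmost.closed = TRUE)
  counts <- tabulate(bins, nbins = n_bins)
  ct <- suppressWarnings(stats::chisq.test(counts))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, counts = counts)
}
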