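DNA <- c("A", "C", "G", "T")

#' Construct a nucleotide background model
#'
#' Order 0 is a Bernoulli model over `A,C,G,T`; order `m >= 1` is a
#' Markov model whose transition rows condition on the previous `m`
#' nucleotides. Word probabilities start the first `m` positions from
#' the mononucleotide marginal and condition every later position on its
#' context. All probabilities must be strictly positive so that word
#' expectations and binomial tails are always defined.
#'
#' @param probs For order 0 a named numeric vector over `A,C,G,T`; for
#'   order `m` a matrix with one row per length-`m` context (rownames)
#'   and columns `A,C,G,T`.
#' @param order Non-negative integer Markov order.
#' @param marginal Mononucleotide marginal used for the first `m`
#'   positions of a word (order >= 1 only); defaults to uniform.
#' @return An object of class `background_model`.
#' @export
background_model <- function(probs, order = 0L, marginal = NULL) {
  order <- as.integer(order)
  stopifnot(order >= 0L)
  if (order == 0L) {
    stopifnot(is.numeric(probs), setequal(names(probs), DNA))
    probs <- probs[DNA] / sum(probs)
    if (any(probs <= 0)) stop("background probabilities must be positive")
    marginal <- probs
  } else {
    stopifnot(is.matrix(probs), setequal(colnames(probs), DNA),
              nrow(probs) == 4L^order)
    probs <- probs[, DNA, drop = FALSE]
    probs <- probs / rowSums(probs)
    if (any(probs <= 0)) stop("background probabilities must be positive")
    if (is.null(marginal)) marginal <- stats::setNames(rep(0.25, 4L), DNA)
    marginal <- marginal[DNA] / sum(marginal)
  }
  structure(list(order = order, probs = probs, marginal = marginal),
            class = "background_model")
}

#' Uniform Bernoulli background
#' @return A `background_model` of order 0 with equal base probabilities.
#' @export
uniform_background <- function() {
  background_model(stats::setNames(rep(0.25, 4L), DNA), order = 0L)
}

#' Arabidopsis-like Bernoulli background
#'
#' AT-rich mononucleotide composition (A/T 0.32, C/G 0.18) approximating
#' the Arabidopsis nuclear genome; the default background for synthetic
#' control sequences.
#' @return A `background_model` of order 0.
#' @export
arabidopsis_background <- function() {
  background_model(c(A = 0.32, C = 0.18, G = 0.18, T = 0.32), order = 0L)
}

#' Estimate a background model from sequences
#'
#' Maximum-likelihood (k+1)-mer frequencies with one pseudo-observation
#' per k-mer-to-base transition, so estimated models are strictly
#' positive.
#'
#' @param sequences Character vector or `DNAStringSet`.
#' @param order Markov order (0 = Bernoulli).
#' @return A `background_model`.
#' @export
estimate_background <- function(sequences, order = 0L) {
  seqs <- as_dna_set(sequences)
  order <- as.integer(order)
  mono <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = 1L)) + 1
  mono <- mono[DNA] / sum(mono[DNA])
  if (order == 0L) return(background_model(mono, order = 0L))
  counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = order + 1L))
  contexts <- sort(apply(expand.grid(rep(list(DNA), order),
                                     stringsAsFactors = FALSE)[order:1],
                         1L, paste0, collapse = ""))
  mat <- matrix(1, nrow = length(contexts), ncol = 4L,
                dimnames = list(contexts, DNA))
  for (ctx in contexts) {
    mat[ctx, ] <- mat[ctx, ] + counts[paste0(ctx, DNA)]
  }
  background_model(mat, order = order, marginal = mono)
}

#' Probability of a word under a background model
#'
#' @param words Character vector of DNA words (equal lengths not
#'   required).
#' @param background A `background_model`.
#' @return Numeric vector of word probabilities.
#' @export
word_probability <- function(words, background) {
  stopifnot(inherits(background, "background_model"))
  vapply(words, function(w) {
    chars <- strsplit(w, "", fixed = TRUE)[[1L]]
    if (!all(chars %in% DNA)) stop("word contains non-ACGT characters: ", w)
    m <- background$order
    if (m == 0L) return(prod(background$probs[chars]))
    p <- prod(background$marginal[chars[seq_len(min(m, length(chars)))]])
    if (length(chars) > m) {
      for (i in (m + 1L):length(chars)) {
        ctx <- paste0(chars[(i - m):(i - 1L)], collapse = "")
        p <- p * background$probs[ctx, chars[i]]
      }
    }
    p
  }, numeric(1), USE.NAMES = TRUE)
}

#' Sample sequences from a background model
#'
#' @param n Number of sequences.
#' @param length Sequence length (bp).
#' @param background A `background_model` of order 0, 1 or 2.
#' @return Character vector of DNA sequences.
#' @export
sample_background <- function(n, length, background) {
  stopifnot(inherits(background, "background_model"))
  m <- background$order
  if (m == 0L) {
    chars <- sample(DNA, n * length, replace = TRUE, prob = background$probs)
    return(vapply(seq_len(n),
                  function(i) paste0(chars[((i - 1L) * length + 1L):(i * length)],
                                     collapse = ""),
                  character(1)))
  }
  vapply(seq_len(n), function(i) {
    chars <- character(length)
    for (j in seq_len(length)) {
      p <- if (j <= m) {
        background$marginal
      } else {
        ctx <- paste0(chars[(j - m):(j - 1L)], collapse = "")
        background$probs[ctx, ]
      }
      chars[j] <- sample(DNA, 1L, prob = p)
    }
    paste0(chars, collapse = "")
  }, character(1))
}

as_dna_set <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) return(sequences)
  if (length(sequences) == 0L) stop("empty sequence set")
  Biostrings::DNAStringSet(sequences)
}

revcomp <- function(words) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
}
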