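# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: interval overlap by quadratic scan,
# BDeu by direct evaluation of the Gamma-function formula, binomial
# tails by explicit log-space summation.

# all-pairs overlap oracle on 0-based half-open intervals
brute_overlap_any <- function(a, b, min_overlap = 1L) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          pmin(a$end[i], b$end) - pmax(a$start[i], b$start) >= min_overlap)
  }, logical(1))
}

random_peak_set <- function(n, seed, chroms = c("chr1", "chr2")) {
  withr::with_seed(seed, {
    start <- sample.int(10000L, n, replace = TRUE)
    peak_table(sprintf("rp%03d", seq_len(n)),
               sample(chroms, n, replace = TRUE),
               start, start + sample.int(300L, n, replace = TRUE))
  })
}

# direct Gamma-formula BDeu family score
oracle_family_score <- function(child, parents, dm, ess = 1) {
  vals <- dm$values
  r <- dm$levels[[child]]
  q <- if (length(parents)) prod(dm$levels[parents]) else 1L
  cfg <- rep(1L, ncol(vals))
  if (length(parents)) {
    stride <- cumprod(c(1L, unname(dm$levels[parents])))[seq_along(parents)]
    cfg <- as.integer(colSums(vals[parents, , drop = FALSE] * stride)) + 1L
  }
  a_jk <- ess / (q * r)
  a_j <- ess / q
  s <- 0
  for (j in seq_len(q)) {
    njk <- tabulate(vals[child, cfg == j] + 1L, nbins = r)
    s <- s + lgamma(a_j) - lgamma(a_j + sum(njk)) +
      sum(lgamma(a_jk + njk) - lgamma(a_jk))
  }
  s
}

# upper binomial tail P(X >= x) by explicit log-space summation
oracle_binom_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  if (x > n) return(0)
  k <- x:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# naive sliding-window k-mer recount
oracle_count_word <- function(sequences, word) {
  k <- nchar(word)
  sum(vapply(sequences, function(s) {
    n <- nchar(s)
    if (n < k) return(0L)
    starts <- seq_len(n - k + 1L)
    sum(substring(s, starts, starts + k - 1L) == word)
  }, integer(1)))
}

undirected_skeleton <- function(edge_df) {
  if (nrow(edge_df) == 0L) return(character(0))
  unique(vapply(seq_len(nrow(edge_df)), function(i) {
    paste(sort(c(edge_df[i, 1L], edge_df[i, 2L])), collapse = "~")
  }, character(1)))
}

dag_skeleton <- function(dg) undirected_skeleton(stmgrn:::dag_edges(dg))

# a covered edge u->v (parents(v) = parents(u) + u) can be reversed
# without leaving the Markov equivalence class
find_covered_edge <- function(dg) {
  for (v in dg$nodes) {
    for (u in dg$parents[[v]]) {
      if (setequal(setdiff(dg$parents[[v]], u), dg$parents[[u]])) {
        return(c(u, v))
      }
    }
  }
  NULL
}

reverse_edge <- function(dg, u, v) {
  parents <- dg$parents
  parents[[v]] <- setdiff(parents[[v]], u)
  parents[[u]] <- union(parents[[u]], v)
  dag(dg$nodes, parents, max_parents = length(dg$nodes))
}
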