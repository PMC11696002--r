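#' Discretise an expression matrix into equal-frequency levels
#'
#' Per-gene quantile binning into `levels` integer states: each gene's
#' samples are ranked (ties broken stably by sample order) and split
#' into bins of size `n/levels` (+-1). Constant genes cannot be binned
#' and are assigned state 0 throughout, with a warning.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param levels Number of states per gene (>= 2; default 3).
#' @return An object of class `discrete_matrix`: integer `values`
#'   (genes x samples, states in `[0, levels)`), `levels` (per-gene
#'   state counts), `genes`, `samples`.
#' @export
discretise_quantile <- function(mat, levels = 3L) {
  stopifnot(is.matrix(mat), levels >= 2L)
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("empty expression matrix")
  n <- ncol(mat)
  vals <- matrix(0L, nrow = nrow(mat), ncol = n,
                 dimnames = dimnames(mat))
  constant <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    if (length(unique(x)) == 1L) {
      constant[i] <- TRUE
      next
    }
    r <- rank(x, ties.method = "first")
    vals[i, ] <- as.integer(floor((r - 1) * levels / n))
  }
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) assigned state 0")
  }
  structure(list(values = vals,
                 levels = stats::setNames(rep(as.integer(levels), nrow(mat)),
                                          rownames(mat)),
                 genes = rownames(mat), samples = colnames(mat)),
            class = "discrete_matrix")
}

#' Construct a discrete matrix from integer states
#'
#' @param values Integer matrix (genes x samples) of states.
#' @param levels Per-gene state counts (recycled scalar allowed).
#' @return A `discrete_matrix`.
#' @export
discrete_matrix <- function(values, levels = 3L) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "integer"
  levels <- rep_len(as.integer(levels), nrow(values))
  if (any(values < 0L) || any(values >= levels[row(values)])) {
    stop("states must lie in [0, levels) per gene")
  }
  structure(list(values = values, levels = stats::setNames(levels,
                                                           rownames(values)),
                 genes = rownames(values), samples = colnames(values)),
            class = "discrete_matrix")
}
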