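#' Read ChIP-seq peaks from a BED-like file
#'
#' Expects the 0-based half-open BED dialect with columns
#' `chrom start end [name score strand summit fdr]`. The optional 7th
#' column carries the peak summit as an absolute chromosomal position
#' (0-based); the optional 8th column carries a false-discovery-rate
#' value. No coordinate shift is applied: BED already matches the
#' package-internal convention.
#'
#' @param path Path to a tab-delimited BED-like file.
#' @return A data.frame of class `peaks` with columns `peak_id`, `chrom`,
#'   `start`, `end`, `score`, `summit`, `fdr` (the last three `NA` when
#'   absent).
#' @export
read_bed_peaks <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3L) stop("BED file needs at least 3 columns: ", path)
  peaks <- data.frame(
    peak_id = if (ncol(tab) >= 4L) as.character(tab[[4L]])
              else sprintf("peak_%d", seq_len(nrow(tab))),
    chrom = as.character(tab[[1L]]),
    start = as.integer(tab[[2L]]),
    end = as.integer(tab[[3L]]),
    score = if (ncol(tab) >= 5L) suppressWarnings(as.numeric(tab[[5L]]))
            else NA_real_,
    summit = if (ncol(tab) >= 7L) suppressWarnings(as.integer(tab[[7L]]))
             else NA_integer_,
    fdr = if (ncol(tab) >= 8L) suppressWarnings(as.numeric(tab[[8L]]))
          else NA_real_,
    stringsAsFactors = FALSE
  )
  class(peaks) <- c("peaks", "data.frame")
  validate_peaks(peaks)
}

#' Write peaks to a BED-like file
#'
#' Inverse of [read_bed_peaks()]; columns beyond the interval are written
#' only when any peak carries them. Missing summits are written as `-1`
#' only if an 8th (fdr) column forces the summit column to be present;
#' otherwise trailing all-`NA` columns are dropped.
#'
#' @param peaks A `peaks` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  validate_peaks(peaks)
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    ifelse(is.na(peaks$score), 0, peaks$score), ".",
                    peaks$summit, peaks$fdr, stringsAsFactors = FALSE)
  keep <- 6L
  if (any(!is.na(peaks$fdr))) keep <- 8L else if (any(!is.na(peaks$summit))) keep <- 7L
  out <- out[, seq_len(keep), drop = FALSE]
  if (keep >= 7L) out[[7L]][is.na(out[[7L]])] <- -1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("peak_id", "chrom", "start", "end", "summit") %in% names(peaks)))
  if (any(peaks$start < 0L)) stop("negative peak start")
  bad <- peaks$end <= peaks$start
  if (any(bad)) {
    stop("peak interval with end <= start: ",
         paste(peaks$peak_id[bad][1L]))
  }
  has_summit <- !is.na(peaks$summit) & peaks$summit >= 0L
  peaks$summit[!has_summit & !is.na(peaks$summit)] <- NA_integer_
  out <- has_summit &
    (peaks$summit < peaks$start | peaks$summit >= peaks$end)
  if (any(out)) {
    stop("summit outside peak interval for ", peaks$peak_id[out][1L])
  }
  if (anyNA(peaks$fdr)) {
    # fdr is optional metadata
  } else if (any(peaks$fdr < 0 | peaks$fdr > 1)) {
    stop("fdr values must lie in [0, 1]")
  }
  class(peaks) <- c("peaks", "data.frame")
  peaks
}

#' Construct a peak table from vectors
#'
#' Coordinates are 0-based half-open; `summit` is an absolute position
#' inside the interval or `NA`.
#'
#' @param peak_id,chrom,start,end,summit,score,fdr Per-peak vectors.
#' @return A `peaks` data.frame (see [read_bed_peaks()]).
#' @export
peak_table <- function(peak_id, chrom, start, end, summit = NA_integer_,
                       score = NA_real_, fdr = NA_real_) {
  peaks <- data.frame(
    peak_id = as.character(peak_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    score = as.numeric(score),
    summit = as.integer(summit),
    fdr = as.numeric(fdr),
    stringsAsFactors = FALSE
  )
  validate_peaks(peaks)
}

# Reference point used for all distance computations: the summit when
# recorded, else the floor midpoint of the interval.
peak_refpoint <- function(peaks) {
  as.integer(ifelse(is.na(peaks$summit),
                    peaks$start + (peaks$end - peaks$start) %/% 2L,
                    peaks$summit))
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}
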