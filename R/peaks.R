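#' Consensus peaks supported by a second comparison
#'
#' Retains the peaks of `set_a` that overlap at least one peak of
#' `set_b` by at least `min_overlap_bp`. This implements the
#' dual-comparison filter used to keep only the most robust binding
#' sites: peaks called against one control are kept only when an
#' independent comparison also calls an overlapping peak. Output peaks
#' keep the coordinates and metadata of `set_a`.
#'
#' @param set_a,set_b `peaks` data.frames (0-based half-open intervals).
#' @param min_overlap_bp Minimum overlap in base pairs (>= 1).
#' @return The supported subset of `set_a`.
#' @export
consensus_peaks <- function(set_a, set_b, min_overlap_bp = 1L) {
  set_a <- validate_peaks(set_a)
  set_b <- validate_peaks(set_b)
  stopifnot(min_overlap_bp >= 1L)
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(set_a),
                                      peaks_to_granges(set_b),
                                      minoverlap = as.integer(min_overlap_bp))
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- set_a[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peaks", "data.frame")
  out
}

#' Remove peaks present in a control set
#'
#' Discards every peak that overlaps a control peak by at least one
#' base pair, mirroring the subtraction of no-epitope control peaks.
#'
#' @param peaks,control `peaks` data.frames.
#' @return The peaks with no control overlap.
#' @export
subtract_control_peaks <- function(peaks, control) {
  peaks <- validate_peaks(peaks)
  control <- validate_peaks(control)
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(peaks),
                                      peaks_to_granges(control),
                                      minoverlap = 1L)
  drop <- unique(S4Vectors::queryHits(hits))
  out <- if (length(drop)) peaks[-drop, , drop = FALSE] else peaks
  rownames(out) <- NULL
  class(out) <- c("peaks", "data.frame")
  out
}

#' Signed distance from a peak to a gene's TSS
#'
#' Distance from the peak reference point (summit, else floor midpoint)
#' to the transcription start site, in the gene's orientation: negative
#' values lie 5' (upstream) of the TSS, positive values 3' of it, and 0
#' is returned whenever the peak interval spans the TSS (in which case
#' the TSS-overlap flag is also raised).
#'
#' @param peak A single-row `peaks` data.frame.
#' @param gene A single-row `gene_models` data.frame.
#' @return A list with `distance` (signed bp) and `tss_overlap` (logical).
#' @export
signed_tss_distance <- function(peak, gene) {
  stopifnot(nrow(peak) == 1L, nrow(gene) == 1L)
  if (peak$chrom != gene$chrom) {
    stop("peak ", peak$peak_id, " and gene ", gene$gene_id,
         " lie on different chromosomes")
  }
  p <- peak_refpoint(peak)
  overlap <- peak$start <= gene$tss && gene$tss < peak$end
  d <- if (overlap) 0L
       else if (gene$strand == "+") p - gene$tss
       else gene$tss - p
  list(distance = as.integer(d), tss_overlap = overlap)
}

location_categories <- c("upstream_0_1kb", "upstream_1_2kb", "upstream_2_5kb",
                         "gene_body", "downstream_0_3kb", "distal_intergenic")

#' Classify a peak's location relative to a gene model
#'
#' Category precedence: `gene_body` when the reference point falls within
#' the gene interval; otherwise upstream bins at |TSS distance| in
#' (0, 1000], (1000, 2000] and (2000, 5000] bp; otherwise
#' `downstream_0_3kb` when the reference point lies within 3000 bp past
#' the strand-aware 3' end; everything else is `distal_intergenic`.
#' TSS overlap is reported as an independent flag, not a category.
#'
#' @param peak A single-row `peaks` data.frame.
#' @param gene A single-row `gene_models` data.frame.
#' @return A list with `category`, `distance` and `tss_overlap`.
#' @export
classify_location <- function(peak, gene) {
  sd <- signed_tss_distance(peak, gene)
  p <- peak_refpoint(peak)
  in_body <- gene$start <= p && p < gene$end
  # signed distance to TSS ignoring the spanning rule, for binning
  d_raw <- if (gene$strand == "+") p - gene$tss else gene$tss - p
  past3 <- if (gene$strand == "+") p - gene$end + 1L else gene$start - p
  category <-
    if (in_body) "gene_body"
    else if (d_raw < 0L && -d_raw <= 1000L) "upstream_0_1kb"
    else if (d_raw < 0L && -d_raw <= 2000L) "upstream_1_2kb"
    else if (d_raw < 0L && -d_raw <= 5000L) "upstream_2_5kb"
    else if (past3 >= 1L && past3 <= 3000L) "downstream_0_3kb"
    else "distal_intergenic"
  list(category = category, distance = sd$distance,
       tss_overlap = sd$tss_overlap)
}

# distance from a point to a 0-based half-open interval; 0 inside
point_interval_distance <- function(p, start, end) {
  ifelse(p < start, start - p, ifelse(p >= end, p - end + 1L, 0L))
}

#' Assign peaks to their closest locus
#'
#' Each peak is assigned to the gene whose interval is nearest to the
#' peak reference point (distance 0 inside the gene body). When the two
#' nearest genes are approximately equidistant -- their distances differ
#' by no more than the tolerance -- the transcriptionally responsive one
#' wins; when both or neither are responsive the peak is assigned to
#' both loci. The signed TSS distance, location category and TSS-overlap
#' flag are then reported for every assigned gene.
#'
#' The default tolerance is relative: 10% of the larger of the two
#' distances. An absolute tolerance in bp can be given instead via
#' `equidistance_tol_bp`.
#'
#' @param peaks `peaks` data.frame.
#' @param genes `gene_models` data.frame (non-empty).
#' @param responsive Character vector of responsive gene ids.
#' @param equidistance_tol_bp Absolute tolerance in bp, or `NULL` to use
#'   the relative tolerance.
#' @param equidistance_tol_frac Relative tolerance as a fraction of the
#'   larger distance (default 0.10); ignored when an absolute tolerance
#'   is supplied.
#' @return A data.frame of class `peak_assignments` with one row per
#'   (peak, gene) pair: `peak_id`, `gene_id`, `tss_distance`, `category`,
#'   `tss_overlap`, `n_genes`, `primary` (`TRUE` for the row used in
#'   per-peak summaries).
#' @export
assign_peak_to_genes <- function(peaks, genes, responsive = character(0),
                                 equidistance_tol_bp = NULL,
                                 equidistance_tol_frac = 0.10) {
  peaks <- validate_peaks(peaks)
  validate_gene_models(genes)
  if (nrow(genes) == 0L) stop("empty gene set")
  stopifnot(is.null(equidistance_tol_bp) || equidistance_tol_bp >= 0)
  refs <- peak_refpoint(peaks)
  rows <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cand <- which(genes$chrom == peaks$chrom[i])
    if (length(cand) == 0L) {
      stop("no gene on chromosome ", peaks$chrom[i],
           " for peak ", peaks$peak_id[i])
    }
    d <- point_interval_distance(refs[i], genes$start[cand], genes$end[cand])
    ord <- order(d, genes$gene_id[cand])
    chosen <- cand[ord[1L]]
    if (length(cand) >= 2L) {
      d1 <- d[ord[1L]]; d2 <- d[ord[2L]]
      tol <- if (!is.null(equidistance_tol_bp)) equidistance_tol_bp
             else equidistance_tol_frac * max(d1, d2)
      if (d2 - d1 <= tol) {
        pair <- cand[ord[1:2]]
        resp <- genes$gene_id[pair] %in% responsive
        chosen <- if (xor(resp[1L], resp[2L])) pair[resp] else pair
      }
    }
    gene_rows <- genes[chosen, , drop = FALSE]
    loc <- lapply(seq_len(nrow(gene_rows)), function(j)
      classify_location(peaks[i, , drop = FALSE],
                        gene_rows[j, , drop = FALSE]))
    rows[[i]] <- data.frame(
      peak_id = peaks$peak_id[i],
      gene_id = gene_rows$gene_id,
      tss_distance = vapply(loc, `[[`, integer(1), "distance"),
      category = vapply(loc, `[[`, character(1), "category"),
      tss_overlap = vapply(loc, `[[`, logical(1), "tss_overlap"),
      n_genes = nrow(gene_rows),
      primary = seq_len(nrow(gene_rows)) == 1L,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("peak_assignments", "data.frame")
  out
}

#' Summarise the peak location distribution
#'
#' Tabulates location categories as counts and fractions, plus the
#' number of TSS-overlapping peaks as a separate sub-statistic. The
#' summary unit is either unique peaks (using each peak's primary
#' assignment) or unique loci (each locus taking the category of its
#' first assigned peak); locus-level fractions are what a per-locus
#' annotation table reports.
#'
#' @param assignments A `peak_assignments` data.frame.
#' @param unit `"peak"` or `"locus"`.
#' @return A list with `table` (category, count, fraction), `n` (total
#'   units) and `tss_overlap_peaks` (count of distinct TSS-overlapping
#'   peaks).
#' @export
distribution_summary <- function(assignments, unit = c("peak", "locus")) {
  unit <- match.arg(unit)
  if (nrow(assignments) == 0L) stop("no assignments to summarise")
  units <- if (unit == "peak") {
    assignments[assignments$primary, , drop = FALSE]
  } else {
    assignments[!duplicated(assignments$gene_id), , drop = FALSE]
  }
  counts <- table(factor(units$category, levels = location_categories))
  tab <- data.frame(category = location_categories,
                    count = as.integer(counts),
                    fraction = as.numeric(counts) / nrow(units),
                    stringsAsFactors = FALSE)
  stopifnot(abs(sum(tab$fraction) - 1) < 1e-12)
  tss_peaks <- unique(assignments$peak_id[assignments$tss_overlap])
  list(table = tab, n = nrow(units), tss_overlap_peaks = length(tss_peaks))
}
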