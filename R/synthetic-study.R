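#' Synthetic study-scale peak/annotation stand-in
#'
#' Generates a synthetic genome annotation and peak set emulating the
#' published composition of the STM ChIP-seq peak table: 858 peaks over
#' 859 loci, of which 854 loci carry a single peak and 5 carry two; six
#' peaks lie equidistant between two unresponsive loci and are assigned
#' to both; 257 peaks span their target TSS; and per-locus location
#' categories occur at the printed study fractions (56.7% within 1 kb
#' upstream, 10.7% 1-2 kb, 7.2% 2-5 kb, 13.4% gene body, 11.2%
#' downstream within 3 kb, 0.8% distal intergenic). The construction is
#' a labelled synthetic stand-in for the unpublished per-peak
#' supplementary table; it exercises the full assignment/classification
#' pipeline at study scale with a known plan.
#'
#' @param seed Integer seed (shuffles locus order across chromosomes).
#' @param dir Optional output directory for GFF3/BED/responsive files.
#' @return A list: `genes`, `peaks`, `responsive` (empty by design),
#'   `plan` (locus-level data.frame: gene_id, category, tss_overlap,
#'   n_peaks), and `paths` when `dir` is given.
#' @export
synthetic_study_annotation <- function(seed = 1L, dir = NULL) {
  counts <- c(upstream_0_1kb = 487L, upstream_1_2kb = 92L,
              upstream_2_5kb = 62L, gene_body = 115L,
              downstream_0_3kb = 96L, distal_intergenic = 7L)
  n_tss_span <- 257L
  n_two_peak <- 5L
  n_dual <- 6L
  # locus specification: dual-peak loci live in the downstream class
  spec <- data.frame(
    category = rep(names(counts), counts),
    stringsAsFactors = FALSE
  )
  spec$tss_span <- FALSE
  up01 <- which(spec$category == "upstream_0_1kb")
  spec$tss_span[up01[seq_len(n_tss_span)]] <- TRUE
  spec$two_peak <- FALSE
  spec$two_peak[up01[(n_tss_span + 1L):(n_tss_span + n_two_peak)]] <- TRUE
  down <- which(spec$category == "downstream_0_3kb")
  spec$dual <- FALSE
  spec$dual[down[seq_len(2L * n_dual)]] <- TRUE

  withr::with_seed(seed, {
    spec <- spec[sample.int(nrow(spec)), , drop = FALSE]
  })
  # dual loci come in consecutive pairs sharing one peak: regroup them
  dual_idx <- which(spec$dual)
  ordinary <- spec[!spec$dual, , drop = FALSE]

  genes <- list()
  peaks <- list()
  plan <- list()
  glen <- 2000L
  spacing <- 30000L
  chroms <- sprintf("chr%d", 1:5)
  cursor <- stats::setNames(rep(10000L, 5L), chroms)
  next_slot <- function(chrom, span) {
    at <- cursor[[chrom]]
    cursor[[chrom]] <<- at + span
    at
  }
  gi <- 0L
  pi <- 0L
  new_gene_id <- function() {
    gi <<- gi + 1L
    sprintf("LOC%04d", gi)
  }
  new_peak_id <- function() {
    pi <<- pi + 1L
    sprintf("peak_%03d", pi)
  }
  add_gene <- function(id, chrom, start, strand) {
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = id, chrom = chrom, start = start, end = start + glen,
      strand = strand, stringsAsFactors = FALSE)
  }
  add_peak <- function(id, chrom, start, end, summit) {
    peaks[[length(peaks) + 1L]] <<- data.frame(
      peak_id = id, chrom = chrom, start = start, end = end,
      summit = summit, stringsAsFactors = FALSE)
  }
  # summit offset relative to a + strand gene start, per category
  summit_for <- function(cat, S, strand, tss_span) {
    E <- S + glen
    tss <- if (strand == "+") S else E - 1L
    sgn <- if (strand == "+") -1L else 1L
    if (tss_span) return(tss + sgn * 50L)
    switch(cat,
      upstream_0_1kb = tss + sgn * 400L,
      upstream_1_2kb = tss + sgn * 1500L,
      upstream_2_5kb = tss + sgn * 3500L,
      gene_body = S + glen %/% 2L,
      downstream_0_3kb = if (strand == "+") E + 799L else S - 800L,
      distal_intergenic = tss + sgn * 6000L)
  }
  for (i in seq_len(nrow(ordinary))) {
    row <- ordinary[i, ]
    chrom <- chroms[(i %% 5L) + 1L]
    strand <- if (i %% 2L == 0L) "+" else "-"
    S <- as.integer(next_slot(chrom, spacing))
    gid <- new_gene_id()
    add_gene(gid, chrom, S, strand)
    n_pk <- if (row$two_peak) 2L else 1L
    tss <- if (strand == "+") S else S + glen - 1L
    sgn <- if (strand == "+") -1L else 1L
    for (k in seq_len(n_pk)) {
      summit <- if (row$two_peak) {
        tss + sgn * c(300L, 700L)[k]
      } else {
        as.integer(summit_for(row$category, S, strand, row$tss_span))
      }
      width <- 200L
      add_peak(new_peak_id(), chrom, summit - width %/% 2L,
               summit + width %/% 2L, summit)
    }
    plan[[length(plan) + 1L]] <- data.frame(
      gene_id = gid, category = row$category, tss_overlap = row$tss_span,
      n_peaks = n_pk, stringsAsFactors = FALSE)
  }
  # six dual peaks, each equidistant (1201 bp) downstream of a + strand
  # gene and a facing - strand gene; neither locus is responsive, so the
  # peak is assigned to both
  for (d in seq_len(n_dual)) {
    chrom <- chroms[(d %% 5L) + 1L]
    S_a <- as.integer(next_slot(chrom, 2L * spacing))
    E_a <- S_a + glen
    p <- E_a + 1200L
    S_b <- p + 1201L
    gid_a <- new_gene_id()
    gid_b <- new_gene_id()
    add_gene(gid_a, chrom, S_a, "+")
    add_gene(gid_b, chrom, S_b, "-")
    add_peak(new_peak_id(), chrom, p - 100L, p + 100L, p)
    for (gid in c(gid_a, gid_b)) {
      plan[[length(plan) + 1L]] <- data.frame(
        gene_id = gid, category = "downstream_0_3kb", tss_overlap = FALSE,
        n_peaks = 1L, stringsAsFactors = FALSE)
    }
  }
  gene_df <- do.call(rbind, genes)
  peak_df <- do.call(rbind, peaks)
  out <- list(
    genes = gene_models(gene_df$gene_id, gene_df$chrom, gene_df$start,
                        gene_df$end, gene_df$strand),
    peaks = peak_table(peak_df$peak_id, peak_df$chrom, peak_df$start,
                       peak_df$end, peak_df$summit),
    responsive = character(0),
    plan = do.call(rbind, plan)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(gff = file.path(dir, "synthetic_study_genes.gff3"),
                  peaks = file.path(dir, "synthetic_study_peaks.bed"),
                  responsive = file.path(dir, "synthetic_study_responsive.txt"))
    write_gff3(out$genes, paths$gff)
    write_bed_peaks(out$peaks, paths$peaks)
    write_gene_list(out$responsive, paths$responsive)
    out$paths <- paths
  }
  out
}

#' Synthetic study-scale differential-expression stand-in
#'
#' Emulates the published integration counts over a set of bound loci:
#' 74 early-responding genes (4 of them with evidence only in the 3 h
#' direct-target experiment), 358 late-responding genes (72 h / 9 d
#' evidence only), and the remainder unresponsive, for 432 responsive
#' genes of which 428 carry time-course or meta-analysis evidence. A
#' labelled synthetic stand-in for the unpublished supplementary DE
#' table.
#'
#' @param bound_genes Character vector of bound gene ids (>= 432).
#' @param seed Integer seed.
#' @param n_early,n_direct_only,n_late Planted class sizes.
#' @return A list: `records` (DE table) and `response_plan`.
#' @export
synthetic_study_de <- function(bound_genes, seed = 1L, n_early = 74L,
                               n_direct_only = 4L, n_late = 358L) {
  bound_genes <- unique(as.character(bound_genes))
  stopifnot(length(bound_genes) >= n_early + n_late,
            n_direct_only <= n_early)
  withr::with_seed(seed, {
    shuffled <- sample(bound_genes)
    early <- shuffled[seq_len(n_early)]
    direct_only <- early[seq_len(n_direct_only)]
    late <- shuffled[n_early + seq_len(n_late)]
    tc_meta <- c("8h", "24h", "meta")
    recs <- list()
    for (g in early) {
      tps <- if (g %in% direct_only) {
        "3h_direct"
      } else {
        unique(c(sample(tc_meta, sample(1:2, 1L)),
                 if (stats::runif(1) < 0.3) "3h_direct",
                 if (stats::runif(1) < 0.5) sample(c("72h", "9d"), 1L)))
      }
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = g, timepoint = tps,
        direction = sample(c("up", "down"), length(tps), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    for (g in late) {
      tps <- sample(c("72h", "9d"), sample(1:2, 1L))
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = g, timepoint = tps,
        direction = sample(c("up", "down"), length(tps), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    plan <- data.frame(
      gene_id = bound_genes,
      class = ifelse(bound_genes %in% early, "early",
                     ifelse(bound_genes %in% late, "late", "none")),
      direct_only = bound_genes %in% direct_only,
      stringsAsFactors = FALSE)
    list(records = validate_de_records(do.call(rbind, recs)),
         response_plan = plan)
  })
}
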