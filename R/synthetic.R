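#' Random DAG by ordered edge sampling
#'
#' Samples a uniformly random topological order, then includes each
#' forward edge independently with probability `edge_prob`, thinning
#' parent sets that exceed `max_parents`. Acyclic by construction and a
#' pure function of its seed.
#'
#' @param n_nodes Number of nodes (named `n01`, `n02`, ...).
#' @param max_parents In-degree cap.
#' @param edge_prob Forward-edge inclusion probability in [0, 1].
#' @param seed Integer seed.
#' @return A `dag`.
#' @export
random_dag <- function(n_nodes, max_parents = 10L, edge_prob = 0.3,
                       seed = 1L) {
  stopifnot(edge_prob >= 0, edge_prob <= 1, n_nodes >= 1L)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  withr::with_seed(seed, {
    ord <- sample(nodes)
    parents <- list()
    for (j in seq_along(ord)) {
      if (j == 1L) next
      cand <- ord[seq_len(j - 1L)]
      take <- cand[stats::runif(length(cand)) < edge_prob]
      if (length(take) > max_parents) take <- sample(take, max_parents)
      if (length(take) > 0L) parents[[ord[j]]] <- take
    }
    dag(nodes, parents, max_parents = max_parents)
  })
}

#' Ground-truth CPDs for a DAG
#'
#' Builds per-node multinomial conditional distributions whose
#' sharpness is controlled by `strength`: each parent configuration is
#' given a random target state and the row is the mixture
#' `(1 - strength) * uniform + strength * onehot(target)`, so strength
#' 0 is pure noise and strength 1 a deterministic function of the
#' parents. Root nodes keep uniform marginals so that ancestral samples
#' stay diverse at every strength.
#'
#' @param dag A `dag`.
#' @param levels States per node.
#' @param strength Interpolation in [0, 1].
#' @param seed Integer seed.
#' @return An object of class `ground_truth`: `dag`, `cpds` (named list
#'   of q x r row-stochastic matrices), `levels`, `strength`.
#' @export
ground_truth_cpds <- function(dag, levels = 3L, strength = 0.8, seed = 1L) {
  stopifnot(strength >= 0, strength <= 1, levels >= 2L)
  withr::with_seed(seed, {
    cpds <- lapply(dag$nodes, function(nd) {
      np <- length(dag$parents[[nd]])
      q <- levels^np
      if (np == 0L) {
        matrix(1 / levels, nrow = 1L, ncol = levels)
      } else {
        # resample until the target function varies along every parent
        # axis, so no edge of the truth DAG is statistically vacuous
        repeat {
          targets <- sample.int(levels, q, replace = TRUE)
          if (all_parents_active(targets, np, levels)) break
        }
        rows <- matrix((1 - strength) / levels, nrow = q, ncol = levels)
        rows[cbind(seq_len(q), targets)] <-
          rows[cbind(seq_len(q), targets)] + strength
        rows
      }
    })
    names(cpds) <- dag$nodes
    structure(list(dag = dag, cpds = cpds, levels = as.integer(levels),
                   strength = strength),
              class = "ground_truth")
  })
}

# does the target map depend on every one of the np parent axes?
all_parents_active <- function(targets, np, levels) {
  if (np == 1L) return(length(unique(targets)) > 1L)
  arr <- array(targets, dim = rep(levels, np))
  for (i in seq_len(np)) {
    varies <- apply(arr, setdiff(seq_len(np), i), function(x)
      length(unique(x)) > 1L)
    if (!any(varies)) return(FALSE)
  }
  TRUE
}

#' Sample a discrete dataset from a ground truth
#'
#' Ancestral sampling in topological order; every node's state is drawn
#' from its CPD row selected by the sampled parent configuration.
#'
#' @param truth A `ground_truth` from [ground_truth_cpds()].
#' @param n_samples Number of samples (columns).
#' @param seed Integer seed.
#' @return A `discrete_matrix` (genes x samples).
#' @export
sample_discrete_dataset <- function(truth, n_samples, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), n_samples >= 1L)
  dg <- truth$dag
  r <- truth$levels
  el <- dag_edges(dg)
  g <- igraph::graph_from_data_frame(el, directed = TRUE, vertices = dg$nodes)
  topo <- names(igraph::topo_sort(g, mode = "out"))
  vals <- matrix(0L, nrow = length(dg$nodes), ncol = n_samples,
                 dimnames = list(dg$nodes,
                                 sprintf("s%04d", seq_len(n_samples))))
  withr::with_seed(seed, {
    for (nd in topo) {
      ps <- dg$parents[[nd]]
      cpd <- truth$cpds[[nd]]
      if (length(ps) == 0L) {
        vals[nd, ] <- sample.int(r, n_samples, replace = TRUE,
                                 prob = cpd[1L, ]) - 1L
      } else {
        stride <- r^(seq_along(ps) - 1L)
        cfg <- as.integer(colSums(vals[ps, , drop = FALSE] * stride)) + 1L
        for (u in unique(cfg)) {
          idx <- which(cfg == u)
          vals[nd, idx] <- sample.int(r, length(idx), replace = TRUE,
                                      prob = cpd[u, ]) - 1L
        }
      }
    }
  })
  discrete_matrix(vals, levels = r)
}

#' Toy genome fixture covering every peak location category
#'
#' Builds a small annotated genome (17 genes on both strands across
#' three chromosomes) with peaks planted in every location category on
#' each strand, one TSS-spanning peak, one equidistant peak between a
#' responsive and an unresponsive gene, and one between two
#' unresponsive genes. The intended assignment and category of every
#' peak are recorded in `category_plan`, so downstream tests never
#' re-derive the truth from the output.
#'
#' @param seed Integer seed (layout is deterministic; the seed shuffles
#'   nothing here but keeps the generator interface uniform).
#' @param dir Optional directory; when given, GFF3/BED/responsive-list
#'   files are written and their paths returned.
#' @return A list: `genes` (`gene_models`), `peaks` (`peaks`),
#'   `responsive`, `category_plan` (peak_id, gene_id, category,
#'   tss_overlap, n_genes), and file `paths` when `dir` is given.
#' @export
toy_genome_fixture <- function(seed = 1L, dir = NULL) {
  specs <- list()
  genes <- list()
  peaks <- list()
  plan <- list()
  add_gene <- function(id, chrom, start, strand, len = 2000L) {
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = id, chrom = chrom, start = as.integer(start),
      end = as.integer(start + len), strand = strand,
      stringsAsFactors = FALSE)
  }
  add_peak <- function(id, chrom, summit, gene_id, category,
                       tss_overlap = FALSE, n_genes = 1L, width = 200L) {
    peaks[[length(peaks) + 1L]] <<- data.frame(
      peak_id = id, chrom = chrom,
      start = as.integer(summit - width %/% 2L),
      end = as.integer(summit + width %/% 2L),
      summit = as.integer(summit), stringsAsFactors = FALSE)
    plan[[length(plan) + 1L]] <<- data.frame(
      peak_id = id, gene_id = gene_id, category = category,
      tss_overlap = tss_overlap, n_genes = n_genes,
      stringsAsFactors = FALSE)
  }
  cats <- c("upstream_0_1kb", "upstream_1_2kb", "upstream_2_5kb",
            "gene_body", "downstream_0_3kb", "distal_intergenic")
  # one gene + peak per category on each strand
  for (k in seq_along(cats)) {
    S <- 100000L * k
    add_gene(sprintf("gp%02d", k), "chr1", S, "+")
    tss <- S
    summit <- switch(cats[k],
      upstream_0_1kb = tss - 300L,
      upstream_1_2kb = tss - 1500L,
      upstream_2_5kb = tss - 2500L,
      gene_body = S + 1000L,
      downstream_0_3kb = S + 2000L + 499L,
      distal_intergenic = tss - 6000L)
    add_peak(sprintf("pp%02d", k), "chr1", summit, sprintf("gp%02d", k),
             cats[k])
  }
  for (k in seq_along(cats)) {
    S <- 100000L * k
    add_gene(sprintf("gm%02d", k), "chr2", S, "-")
    E <- S + 2000L
    tss <- E - 1L
    summit <- switch(cats[k],
      upstream_0_1kb = tss + 300L,
      upstream_1_2kb = tss + 1500L,
      upstream_2_5kb = tss + 2500L,
      gene_body = S + 1000L,
      downstream_0_3kb = S - 500L,
      distal_intergenic = tss + 6000L)
    add_peak(sprintf("pm%02d", k), "chr2", summit, sprintf("gm%02d", k),
             cats[k])
  }
  # TSS-spanning peak: summit 50 bp upstream, interval spans the TSS
  add_gene("gspan", "chr1", 1300000L, "+")
  add_peak("pspan", "chr1", 1300000L - 50L, "gspan", "upstream_0_1kb",
           tss_overlap = TRUE)
  # equidistant tie, responsive vs unresponsive
  add_gene("gtieA", "chr3", 100000L, "+")
  add_gene("gtieB", "chr3", 104401L, "-")
  add_peak("ptie1", "chr3", 103200L, "gtieA", "downstream_0_3kb")
  # equidistant tie, neither responsive: assigned to both loci
  add_gene("gtieC", "chr3", 200000L, "+")
  add_gene("gtieD", "chr3", 204401L, "-")
  peaks[[length(peaks) + 1L]] <- data.frame(
    peak_id = "ptie2", chrom = "chr3", start = 203100L, end = 203300L,
    summit = 203200L, stringsAsFactors = FALSE)
  plan[[length(plan) + 1L]] <- data.frame(
    peak_id = "ptie2", gene_id = c("gtieC", "gtieD"),
    category = "downstream_0_3kb", tss_overlap = FALSE, n_genes = 2L,
    stringsAsFactors = FALSE)
  gene_df <- do.call(rbind, genes)
  out <- list(
    genes = gene_models(gene_df$gene_id, gene_df$chrom, gene_df$start,
                        gene_df$end, gene_df$strand),
    peaks = do.call(rbind, peaks),
    responsive = "gtieA",
    category_plan = do.call(rbind, plan)
  )
  out$peaks <- peak_table(out$peaks$peak_id, out$peaks$chrom,
                          out$peaks$start, out$peaks$end, out$peaks$summit)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(gff = file.path(dir, "toy_genes.gff3"),
                  peaks = file.path(dir, "toy_peaks.bed"),
                  responsive = file.path(dir, "toy_responsive.txt"))
    write_gff3(out$genes, paths$gff)
    write_bed_peaks(out$peaks, paths$peaks)
    write_gene_list(out$responsive, paths$responsive)
    out$paths <- paths
  }
  out
}

#' Background sequences with a planted motif
#'
#' Samples sequences from a Bernoulli or Markov background and plants
#' the motif once in a `rate` fraction of them, at a uniform position
#' and uniform strand. `N` positions in the motif (dyad spacers) are
#' filled from the background marginal at planting time. Plant
#' positions are recorded so recovery tests use generator bookkeeping,
#' not re-discovery.
#'
#' @param n Number of sequences.
#' @param length Sequence length.
#' @param background A `background_model` (order 0--2).
#' @param motif Motif string over `A,C,G,T,N`, shorter than `length`;
#'   a dyad label of the form `TGAC{3}TGAC` is also accepted.
#' @param rate Planting rate in [0, 1].
#' @param seed Integer seed.
#' @return A list: `sequences` (named character vector) and `plants`
#'   (sequence_id, position (0-based), strand).
#' @export
planted_motif_sequences <- function(n, length, background = arabidopsis_background(),
                                    motif = "TGAC", rate = 0.5, seed = 1L) {
  motif <- dyad_label_to_pattern(motif)
  stopifnot(rate >= 0, rate <= 1, nchar(motif) < length)
  withr::with_seed(seed, {
    seqs <- sample_background(n, length, background)
    names(seqs) <- sprintf("seq_%03d", seq_len(n))
    planted <- which(stats::runif(n) < rate)
    w <- nchar(motif)
    plants <- data.frame(sequence_id = character(0), position = integer(0),
                         strand = character(0), stringsAsFactors = FALSE)
    for (i in planted) {
      chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
      free <- chars == "N"
      if (any(free)) {
        chars[free] <- sample(DNA, sum(free), replace = TRUE,
                              prob = background$marginal)
      }
      strand <- sample(c("+", "-"), 1L)
      insert <- paste0(chars, collapse = "")
      if (strand == "-") insert <- revcomp(insert)
      pos <- sample.int(length - w + 1L, 1L) - 1L
      substr(seqs[i], pos + 1L, pos + w) <- insert
      plants <- rbind(plants, data.frame(
        sequence_id = names(seqs)[i], position = pos, strand = strand,
        stringsAsFactors = FALSE))
    }
    list(sequences = seqs, plants = plants)
  })
}

#' Synthetic differential-expression tables with known classes
#'
#' Assigns an `early_frac` fraction of genes to the early class (at
#' least one record among the 3 h direct, 8 h, 24 h or meta channels,
#' optionally plus late records), a `late_frac` fraction to the late
#' class (records only at 72 h / 9 d), and leaves the remainder without
#' records.
#'
#' @param genes Character vector of gene ids.
#' @param early_frac,late_frac Class fractions (sum <= 1).
#' @param seed Integer seed.
#' @return A list: `records` (DE table) and `response_plan` (gene_id,
#'   class).
#' @export
synthetic_de_tables <- function(genes, early_frac = 0.2, late_frac = 0.3,
                                seed = 1L) {
  stopifnot(early_frac + late_frac <= 1, early_frac >= 0, late_frac >= 0)
  genes <- as.character(genes)
  n <- length(genes)
  withr::with_seed(seed, {
    shuffled <- sample(genes)
    n_early <- round(early_frac * n)
    n_late <- round(late_frac * n)
    early <- shuffled[seq_len(n_early)]
    late <- shuffled[n_early + seq_len(n_late)]
    early_tps <- c("3h_direct", "8h", "24h", "meta")
    late_tps <- c("72h", "9d")
    recs <- list()
    for (g in early) {
      tps <- sample(early_tps, sample(1:2, 1L))
      if (stats::runif(1) < 0.5) tps <- c(tps, sample(late_tps, 1L))
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = g, timepoint = tps,
        direction = sample(c("up", "down"), length(tps), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    for (g in late) {
      tps <- sample(late_tps, sample(1:2, 1L))
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = g, timepoint = tps,
        direction = sample(c("up", "down"), length(tps), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    records <- if (length(recs)) do.call(rbind, recs) else
      data.frame(gene_id = character(0), timepoint = character(0),
                 direction = character(0), stringsAsFactors = FALSE)
    plan <- data.frame(
      gene_id = genes,
      class = ifelse(genes %in% early, "early",
                     ifelse(genes %in% late, "late", "none")),
      stringsAsFactors = FALSE)
    list(records = validate_de_records(records), response_plan = plan)
  })
}
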