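test_that("a single seed occurrence with no flanks yields a one-hot matrix", {
  mat <- assemble_count_matrix("TGAC", "GGTGACGG", flank = 0,
                               both_strands = FALSE)
  expect_equal(mat$width, 4L)
  expect_equal(unname(mat$counts["T", 1L]), 1)
  expect_equal(unname(mat$counts["G", 2L]), 1)
  expect_equal(unname(mat$counts["A", 3L]), 1)
  expect_equal(unname(mat$counts["C", 4L]), 1)
  expect_equal(sum(mat$counts), 4)
  expect_error(assemble_count_matrix("TTTT", "ACGCACGC"), "no occurrences")
})

test_that("flank columns of a heavily sampled seed stay near-uniform", {
  pm <- planted_motif_sequences(1200, 30, uniform_background(),
                                motif = "TGACGTCA", rate = 1, seed = 51)
  mat <- assemble_count_matrix("TGACGTCA", pm$sequences, flank = 2,
                               both_strands = TRUE)
  expect_gte(mat$nsites, 1000L)
  freq <- sweep(mat$counts, 2, colSums(mat$counts), "/")
  flank_cols <- c(1:2, (mat$width - 1L):mat$width)
  expect_lt(max(abs(freq[, flank_cols] - 0.25)), 0.05)
})

test_that("a dyad seed matrix contains both cores at the planted spacing", {
  pm <- planted_motif_sequences(300, 60, uniform_background(),
                                motif = "TGAC{3}TGAC", rate = 1, seed = 52)
  mat <- assemble_count_matrix("TGAC{3}TGAC", pm$sequences, flank = 0,
                               both_strands = TRUE)
  freq <- sweep(mat$counts, 2, colSums(mat$counts), "/")
  core <- c("T", "G", "A", "C")
  for (i in 1:4) {
    expect_gt(freq[core[i], i], 0.95)
    expect_gt(freq[core[i], i + 7L], 0.95)
  }
  # spacer columns reflect the background, not the cores
  expect_lt(max(freq[, 5:7]), 0.5)
})

test_that("scan p-values equal full enumeration over all words", {
  # width 2: p-values are (# of the 16 dinucleotides scoring >= s) / 16
  counts2 <- matrix(c(3, 1, 0, 0,
                      0, 1, 1, 2), nrow = 4,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
  m2 <- structure(list(counts = counts2, width = 2L, nsites = 4L,
                       pseudocount = 1, background = uniform_background(),
                       seed = "xx"), class = "count_matrix")
  pssm2 <- pssm_logodds(m2)
  dinucs <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              stringsAsFactors = FALSE), 1, paste0,
                  collapse = "")
  sw2 <- pssm_score_words(pssm2, dinucs)
  for (i in seq_along(dinucs)) {
    expect_equal(sw2$pvalue[i],
                 sum(sw2$score_int >= sw2$score_int[i]) / 16)
  }

  # wider matrices against a non-uniform background
  pm <- planted_motif_sequences(200, 40, arabidopsis_background(),
                                motif = "TGACTGA", rate = 0.7, seed = 53)
  mat <- assemble_count_matrix("TGACTGA", pm$sequences,
                               background = arabidopsis_background())
  pssm <- pssm_logodds(mat)
  w <- pssm$width
  words <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), w),
                             stringsAsFactors = FALSE), 1, paste0,
                 collapse = "")
  sw <- pssm_score_words(pssm, words)
  bg <- arabidopsis_background()$probs
  word_prob <- vapply(strsplit(words, "", fixed = TRUE),
                      function(ch) prod(bg[ch]), numeric(1))
  ord <- order(sw$score_int, decreasing = TRUE)
  tail_oracle <- numeric(length(words))
  tail_oracle[ord] <- cumsum(word_prob[ord])
  # align ties: oracle tail at a score is total mass at or above it
  for (i in seq_along(words)) {
    oracle <- sum(word_prob[sw$score_int >= sw$score_int[i]])
    expect_equal(sw$pvalue[i], oracle, tolerance = 1e-12)
  }
})

test_that("a flat matrix scores every word identically with p-value one", {
  counts <- matrix(5, nrow = 4, ncol = 6,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- structure(list(counts = counts, width = 6L, nsites = 20L,
                      pseudocount = 1, background = uniform_background(),
                      seed = "flat"), class = "count_matrix")
  hits <- scan_pssm(m, c(s1 = "ACGTACGTACGT"), p_threshold = 0.5)
  expect_equal(nrow(hits), 0L)
  sw <- pssm_score_words(pssm_logodds(m), c("AAAAAA", "TGACTG"))
  expect_equal(sw$pvalue, c(1, 1))
})

test_that("planted motifs are recovered at high recall at the stringent threshold", {
  # the motif must be GC-enriched for a perfect match to clear p <= 1e-5
  # against the AT-rich background (0.18^6 * 0.32^2 ~ 3.5e-6)
  pm <- planted_motif_sequences(250, 200, arabidopsis_background(),
                                motif = "GTGACGCC", rate = 0.5, seed = 54)
  mat <- assemble_count_matrix("GTGACGCC", pm$sequences,
                               background = arabidopsis_background())
  hits <- scan_pssm(mat, pm$sequences, p_threshold = 1e-5)
  hit_keys <- paste(hits$sequence_id, hits$offset)
  plant_keys <- paste(pm$plants$sequence_id, pm$plants$position)
  expect_gte(mean(plant_keys %in% hit_keys), 0.9)
})

test_that("sequences shorter than the matrix are skipped with a notice", {
  mat <- assemble_count_matrix("TGACTGAC", "AATGACTGACAA")
  expect_message(hits <- scan_pssm(mat, c("TGAC", "AATGACTGACAA"),
                                   p_threshold = 0.99),
                 "shorter")
  expect_true(all(hits$sequence_id != "seq_1"))
})

test_that("motif enrichment reduces to the hypergeometric tail and handles edge cases", {
  flat <- motif_enrichment(50, 100, 50, 100)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p.value, 1)

  enr <- motif_enrichment(90, 100, 10, 100)
  # independent two-sided hypergeometric summation
  dens <- dhyper(0:100, 100, 100, 100)
  oracle <- sum(dens[dens <= dhyper(90, 100, 100, 100) * (1 + 1e-7)])
  expect_equal(enr$p.value, oracle, tolerance = 1e-8)
  expect_gt(enr$odds_ratio, 1)

  zero <- motif_enrichment(0, 50, 0, 50)
  expect_equal(zero$p.value, 1)
  expect_equal(zero$odds_ratio, 1)  # Haldane-corrected
  expect_error(motif_enrichment(0, 0, 1, 10), "empty")
})

test_that("matrices export to a readable MEME-like text block", {
  mat <- assemble_count_matrix("TGAC", "GGTGACGGTGACGG", both_strands = FALSE)
  path <- withr::local_tempfile(fileext = ".txt")
  write_matrices(list(mat), path)
  lines <- readLines(path)
  expect_match(lines[1], "^MOTIF TGAC w=4 nsites=2$")
  freq <- read.table(text = lines[2:5])
  expect_equal(dim(freq), c(4L, 4L))
  expect_equal(rowSums(freq), rep(1, 4), tolerance = 1e-6)
})

test_that("matrix clustering groups identical and reverse-complement motifs", {
  pm <- planted_motif_sequences(200, 30, uniform_background(),
                                motif = "TGACGTTGAC", rate = 1, seed = 55)
  m1 <- assemble_count_matrix("TGACGTTGAC", pm$sequences)
  m2 <- assemble_count_matrix("TGACGTTGAC", pm$sequences)
  cl <- cluster_matrices(list(m1, m2), cor_threshold = 0.8)
  expect_equal(cl$membership[1L], cl$membership[2L])

  # reverse complement of the same motif joins the cluster
  rc_seqs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(pm$sequences)))
  m3 <- assemble_count_matrix("GTCAACGTCA", rc_seqs, both_strands = FALSE)
  cl2 <- cluster_matrices(list(m1, m3), cor_threshold = 0.8)
  expect_equal(cl2$membership[1L], cl2$membership[2L])

  # dissimilar one-hot motifs split
  a <- assemble_count_matrix("TGACA", "TGACA", both_strands = FALSE)
  b <- assemble_count_matrix("CCCCC", "CCCCC", both_strands = FALSE)
  cl3 <- cluster_matrices(list(a, b), cor_threshold = 0.5)
  expect_equal(length(unique(cl3$membership)), 2L)
  expect_lte(cl3$similarity[1, 2], 0)
})
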