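test_that("word counting matches hand counts and the sliding-window oracle", {
  counts <- count_words("TGACTGAC", k = 4)
  expect_equal(counts[["TGAC"]], 2L)
  expect_equal(counts[["GACT"]], 1L)
  expect_equal(counts[["ACTG"]], 1L)
  expect_equal(counts[["CTGA"]], 1L)
  expect_equal(sum(counts), 5L)

  seqs <- withr::with_seed(31, sample_background(100, 50, uniform_background()))
  got <- count_words(seqs, k = 5)
  for (w in c("TGACA", "AAAAA", names(got)[got > 0][1:5])) {
    expect_equal(got[[w]], oracle_count_word(seqs, w))
  }
})

test_that("N-containing windows are skipped", {
  counts <- count_words("TGANCTGAC", k = 4)
  expect_equal(counts[["TGAC"]], 1L)
  expect_equal(attr(counts, "n_positions"), 2)  # only CTGA and TGAC windows
})

test_that("strand pooling conserves per-strand totals under the smaller key", {
  seqs <- withr::with_seed(32, sample_background(50, 60, uniform_background()))
  single <- count_words(seqs, k = 4)
  pooled <- count_words(seqs, k = 4, both_strands = TRUE)
  for (w in names(pooled)) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
    expect_true(w <= rc)
    expect_equal(pooled[[w]], single[[w]] + single[[rc]])
  }
  expect_equal(attr(pooled, "n_positions"), 2 * attr(single, "n_positions"))
})

test_that("binomial word significance matches closed forms and the summation oracle", {
  # uniform background, k = 6: expected count is n/4096
  counts <- stats::setNames(c(40L, 10L), c("TGACTG", "AAAAAA"))
  ws <- word_significance(counts, n_positions = 40960,
                          background = uniform_background(), top_n = 3)
  expect_equal(ws$expected[ws$word == "TGACTG"], 40960 / 4096)
  for (i in seq_len(nrow(ws))) {
    expect_equal(ws$pvalue[i],
                 oracle_binom_tail(ws$observed[i], 40960, 1 / 4096),
                 tolerance = 1e-10)
  }
  # a word observed at its expectation is not reported as enriched
  # (multiplicity of a full k = 6 run)
  at_exp <- stats::setNames(10L, "TGACTG")
  expect_equal(nrow(word_significance(at_exp, n_positions = 40960,
                                      background = uniform_background(),
                                      n_tested = 4096L)), 0L)
})

test_that("a word planted in half the sequences ranks first", {
  pm <- planted_motif_sequences(200, 100, uniform_background(),
                                motif = "TGACTG", rate = 0.5, seed = 41)
  ws <- word_significance(count_words(pm$sequences, 6),
                          background = uniform_background())
  expect_equal(ws$word[1L], "TGACTG")
  expect_equal(ws$pvalue[1L],
               oracle_binom_tail(ws$observed[1L],
                                 attr(count_words(pm$sequences, 6), "n_positions"),
                                 0.25^6),
               tolerance = 1e-10)
})

test_that("spacing-zero dyad counts equal the concatenated 6-mer counts", {
  seqs <- withr::with_seed(33, sample_background(40, 80, uniform_background()))
  dy <- dyad_significance(seqs, max_spacing = 0, top_n = Inf)
  six <- count_words(seqs, k = 6)
  for (i in seq_len(min(nrow(dy), 20L))) {
    word <- paste0(dy$monad_a[i], dy$monad_b[i])
    expect_equal(dy$observed[i], six[[word]])
  }
})

test_that("planted dyads are recovered and uniform sequences yield none", {
  pm <- planted_motif_sequences(200, 100, arabidopsis_background(),
                                motif = "TGAC{3}TGAC", rate = 0.4, seed = 5)
  bg <- estimate_background(pm$sequences, order = 0)
  dy <- dyad_significance(pm$sequences, max_spacing = 10, background = bg,
                          both_strands = TRUE, monad_len = 4L)
  expect_true(dy$word[1L] %in% c("TGAC{3}TGAC", "GTCA{3}GTCA"))
  expect_equal(dy$spacing[1L], 3L)

  # under the null, the E-value correction keeps the expected number of
  # dyads with e-value < 1 at about one per run, and confidently
  # significant dyads (e-value < 0.05) essentially never appear
  n_below_1 <- integer(0)
  strong <- 0L
  for (seed in 1:20) {
    seqs <- withr::with_seed(seed, sample_background(50, 100, uniform_background()))
    dy0 <- dyad_significance(seqs, max_spacing = 5,
                             background = uniform_background(), top_n = Inf)
    n_below_1 <- c(n_below_1, nrow(dy0))
    strong <- strong + (nrow(dy0) > 0L && min(dy0$evalue) < 0.05)
  }
  expect_lte(mean(n_below_1), 1.5)
  expect_lte(strong, 1L)
})

test_that("positional chi-square flags central concentration and passes the null mean", {
  # every sequence carries the word only in the central bin
  centre_seqs <- withr::with_seed(34, {
    s <- sample_background(60, 100, uniform_background())
    substr(s, 49, 54) <- "TGACTG"
    s
  })
  res <- position_chi2(centre_seqs, "TGACTG", bin_width = 10, window_bp = 100)
  expect_lt(res$p.value, 1e-5)

  none <- position_chi2("ACGTACGTAC", "TTTTTT", bin_width = 2, window_bp = 8)
  expect_equal(none$statistic, 0)
  expect_equal(none$p.value, 1)

  stats_seen <- withr::with_seed(35, {
    vapply(1:200, function(i) {
      s <- sample_background(80, 120, uniform_background())
      # plant starts spanning the scored window exactly (offsets -50..49)
      pos <- sample(11:110, 80, replace = TRUE)
      substr(s, pos, pos + 5L) <- "TGCCGT"
      position_chi2(s, "TGCCGT", bin_width = 10, window_bp = 100)$statistic
    }, numeric(1))
  })
  expect_equal(mean(stats_seen), 9, tolerance = 0.1)
})
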