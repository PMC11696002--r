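test_that("consensus filtering keeps only set-a peaks supported by set b", {
  a <- peak_table("a1", "chr1", 100L, 200L)
  b <- peak_table("b1", "chr1", 150L, 250L)
  expect_equal(consensus_peaks(a, b)$peak_id, "a1")
  disjoint <- peak_table("b2", "chr1", 300L, 400L)
  expect_equal(nrow(consensus_peaks(a, disjoint)), 0L)
})

test_that("control subtraction respects half-open interval arithmetic", {
  pk <- peak_table("p1", "chr1", 100L, 200L)
  expect_equal(nrow(subtract_control_peaks(pk, peak_table("c1", "chr1", 199L, 300L))), 0L)
  expect_equal(subtract_control_peaks(pk, peak_table("c2", "chr1", 200L, 300L))$peak_id,
               "p1")
})

test_that("interval set operations agree with the all-pairs oracle", {
  for (seed in c(11L, 12L)) {
    a <- random_peak_set(200L, seed)
    b <- random_peak_set(200L, seed + 100L)
    for (min_ov in c(1L, 50L)) {
      got <- consensus_peaks(a, b, min_overlap_bp = min_ov)$peak_id
      want <- a$peak_id[brute_overlap_any(a, b, min_ov)]
      expect_equal(got, want)
    }
    kept <- subtract_control_peaks(a, b)$peak_id
    expect_equal(kept, a$peak_id[!brute_overlap_any(a, b, 1L)])
  }
})

test_that("signed TSS distance is strand-aware and zero when the peak spans the TSS", {
  gplus <- gene_models("g1", "chr1", 1000L, 3000L, "+")
  peak <- peak_table("p", "chr1", 700L, 900L)  # midpoint 800
  expect_equal(signed_tss_distance(peak, gplus)$distance, -200L)

  gminus <- gene_models("g2", "chr1", 500L, 2001L, "-")  # tss 2000
  peak2 <- peak_table("p2", "chr1", 2100L, 2300L)  # midpoint 2200
  expect_equal(signed_tss_distance(peak2, gminus)$distance, -200L)

  spanning <- peak_table("p3", "chr1", 950L, 1050L)
  sd <- signed_tss_distance(spanning, gplus)
  expect_equal(sd$distance, 0L)
  expect_true(sd$tss_overlap)

  other_chrom <- peak_table("p4", "chr2", 700L, 900L)
  expect_error(signed_tss_distance(other_chrom, gplus), "chromosome")
})

test_that("TSS distance is antisymmetric under strand flip with mirrored coordinates", {
  withr::with_seed(21, {
    for (i in 1:20) {
      S <- sample.int(50000L, 1L) + 10000L
      len <- sample(500:5000, 1L)
      off <- sample(-6000:6000, 1L)
      gp <- gene_models("g", "chr1", S, S + len, "+")
      p <- S + off
      pk <- peak_table("p", "chr1", p, p + 1L)  # point peak, midpoint p
      # mirror the layout around position M
      M <- 200000L
      gm <- gene_models("g", "chr1", M - (S + len), M - S, "-")
      pkm <- peak_table("p", "chr1", M - p - 1L, M - p)
      expect_equal(signed_tss_distance(pk, gp)$distance,
                   signed_tss_distance(pkm, gm)$distance)
    }
  })
})

test_that("location categories follow the documented precedence", {
  g <- gene_models("g1", "chr1", 10000L, 12000L, "+")
  up <- peak_table("p", "chr1", 9400L, 9600L)  # midpoint 9500, d = -500
  expect_equal(classify_location(up, g)$category, "upstream_0_1kb")
  down <- peak_table("p", "chr1", 12000L, 12200L)  # midpoint 12100
  expect_equal(classify_location(down, g)$category, "downstream_0_3kb")
  distal <- peak_table("p", "chr1", 3900L, 4100L)  # 6 kb upstream
  expect_equal(classify_location(distal, g)$category, "distal_intergenic")
  body <- peak_table("p", "chr1", 10900L, 11100L)
  expect_equal(classify_location(body, g)$category, "gene_body")
  # bin boundaries are half-open: exactly 2000 bp stays in the 1-2 kb bin
  at2k <- peak_table("p", "chr1", 8000L, 8001L)
  expect_equal(classify_location(at2k, g)$category, "upstream_1_2kb")
})

test_that("toy-genome assignments recover the generator's category plan and tie rules", {
  fx <- toy_genome_fixture(seed = 1)
  asg <- assign_peak_to_genes(fx$peaks, fx$genes, fx$responsive)
  merged <- merge(asg, fx$category_plan, by = c("peak_id", "gene_id"))
  expect_equal(nrow(merged), nrow(fx$category_plan))
  expect_equal(merged$category.x, merged$category.y)
  expect_equal(merged$tss_overlap.x, merged$tss_overlap.y)
  # responsive tie goes to the responsive gene only
  tie1 <- asg[asg$peak_id == "ptie1", ]
  expect_equal(tie1$gene_id, "gtieA")
  # unresponsive tie is assigned to both loci
  tie2 <- asg[asg$peak_id == "ptie2", ]
  expect_setequal(tie2$gene_id, c("gtieC", "gtieD"))
  expect_equal(unique(tie2$n_genes), 2L)
})

test_that("peak assignment is deterministic and files round-trip through the CLI formats", {
  dir <- withr::local_tempdir()
  fx <- toy_genome_fixture(seed = 1, dir = dir)
  genes <- read_gff3(fx$paths$gff)
  peaks <- read_bed_peaks(fx$paths$peaks)
  responsive <- read_gene_list(fx$paths$responsive)
  a1 <- assign_peak_to_genes(peaks, genes, responsive)
  a2 <- assign_peak_to_genes(fx$peaks, fx$genes, fx$responsive)
  expect_equal(a1, a2)
})

test_that("distribution summary fractions sum to one and match planted categories", {
  fx <- toy_genome_fixture(seed = 1)
  asg <- assign_peak_to_genes(fx$peaks, fx$genes, fx$responsive)
  s <- distribution_summary(asg, unit = "peak")
  expect_equal(sum(s$table$fraction), 1)
  expect_equal(sum(s$table$count), length(unique(asg$peak_id)))
  planted <- table(factor(fx$category_plan$category[
    !duplicated(fx$category_plan$peak_id)],
    levels = s$table$category))
  expect_equal(s$table$count, as.integer(planted))
  expect_equal(s$tss_overlap_peaks, 1L)
  expect_error(distribution_summary(asg[0, ]), "no assignments")

  ten <- do.call(rbind, rep(list(asg[asg$peak_id == "pp01", ]), 10))
  ten$peak_id <- sprintf("p%d", 1:10)
  s10 <- distribution_summary(ten, unit = "peak")
  expect_equal(s10$table$fraction[s10$table$category == "upstream_0_1kb"], 1)
})
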