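test_that("motif counting is overlapping, case-insensitive and T == U", {
  expect_equal(count_motifs("TCTCTC"), 3L)   # TCTC@1, CTCT@2, TCTC@3
  expect_equal(count_motifs("AAAAAA"), 0L)
  expect_equal(count_motifs("TCTT"), 1L)
  expect_equal(count_motifs("ucucuc"), 3L)
  expect_equal(count_motifs("TCT"), 0L)
  expect_equal(count_motifs("TCTCTC", overlapping = FALSE), 1L)
})

test_that("motif counts equal the sliding-window oracle on random strings", {
  set.seed(71)
  for (i in 1:1000) {
    n <- sample(0:200, 1)
    s <- if (n == 0) "" else
      random_dna(n, c(A = .15, C = .35, G = .15, T = .35))
    expect_identical(count_motifs(s), oracle_count_motifs(s))
  }
})

test_that("extension sequences follow transcript orientation", {
  g <- Biostrings::DNAStringSet(c(c1 = "AAAATCTCAAAA"))
  ev <- data.frame(chrom = "c1", ext_start = 4L, ext_end = 8L, strand = "+",
                   stringsAsFactors = FALSE)
  expect_equal(extension_sequence(ev[1, ], g), "TCTC")
  ev$strand <- "-"
  expect_equal(extension_sequence(ev[1, ], g), "GAGA")
})

test_that("KS statistic equals the brute-force pooled-ECDF maximum", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(ks_two_sample(c(1, 2), c(5, 6, 7))$statistic, 1)
  set.seed(73)
  for (i in 1:50) {
    x <- round(runif(sample(2:40, 1)), 2)  # rounding forces ties
    y <- round(runif(sample(2:40, 1)), 2)
    expect_equal(ks_two_sample(x, y)$statistic, oracle_ks_D(x, y))
  }
})

test_that("KS p-value matches the asymptotic two-sample reference", {
  set.seed(79)
  for (i in 1:20) {
    x <- rnorm(sample(10:50, 1))
    y <- rnorm(sample(10:50, 1), mean = runif(1, 0, 1.5))
    ours <- ks_two_sample(x, y)
    ref <- stats::ks.test(x, y, exact = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic))
    # the reference truncates its series at a coarser tolerance
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-4)
  }
})

test_that("Wilcoxon p matches exact enumeration for small samples", {
  # fully separated samples: the most extreme assignment
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value,
               oracle_wilcox_exact(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  set.seed(83)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)  # continuous, tie-free
    p <- wilcoxon_rank_sum(x, y)$p.value
    expect_equal(p, oracle_wilcox_exact(x, y), tolerance = 0.1)
  }
})

test_that("degenerate and symmetric Wilcoxon inputs behave", {
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 5))$p.value, 1)
  x <- c(1, 2, 3, 4)
  expect_gt(wilcoxon_rank_sum(x, x)$p.value, 0.99)
  # shifting x far above y mirrors shifting it far below
  y <- rnorm(8)
  p_hi <- wilcoxon_rank_sum(y + 100, y)$p.value
  p_lo <- wilcoxon_rank_sum(y - 100, y)$p.value
  expect_equal(p_hi, p_lo)
})

test_that("donor PWM building tallies 9-mers with pseudocounts", {
  toy <- toy_annotation(rep("CAGGTAAGT", 60))
  pwm <- build_donor_pwm(toy$exons, toy$genome, min_donors = 50)
  expect_equal(unname(rowSums(pwm)), rep(1, 9), tolerance = 1e-12)
  consensus <- strsplit("CAGGTAAGT", "")[[1]]
  for (i in 1:9) expect_gt(pwm[i, consensus[i]], 0.9)
  # hand tally on a 10-donor toy with one variant position
  nine <- c(rep("CAGGTAAGT", 7), rep("AAGGTAAGT", 3))
  toy2 <- toy_annotation(nine)
  pwm2 <- build_donor_pwm(toy2$exons, toy2$genome, pseudocount = 0.5,
                          min_donors = 5)
  expect_equal(unname(pwm2[1, "C"]), (7 + 0.5) / (10 + 2), tolerance = 1e-12)
  expect_equal(unname(pwm2[1, "A"]), (3 + 0.5) / (10 + 2), tolerance = 1e-12)
  expect_error(build_donor_pwm(toy2$exons, toy2$genome, min_donors = 50),
               "donor_pwm_default")
})

test_that("donor scores are percent-scaled between argmin and argmax", {
  pwm <- donor_pwm_default()
  argmax <- paste(colnames(pwm)[apply(pwm, 1, which.max)], collapse = "")
  argmin <- paste(colnames(pwm)[apply(pwm, 1, which.min)], collapse = "")
  expect_equal(score_donor(argmax, pwm), 100)
  expect_equal(score_donor(argmin, pwm), 0)
  # direct formula evaluation on an arbitrary 9-mer
  s <- "CAGGTAAGT"
  b <- strsplit(s, "")[[1]]
  raw <- sum(vapply(1:9, function(i) pwm[i, b[i]], numeric(1)))
  lo <- sum(apply(pwm, 1, min)); hi <- sum(apply(pwm, 1, max))
  expect_equal(score_donor(s, pwm), 100 * (raw - lo) / (hi - lo))
  expect_error(score_donor("CAGGTAAGN", pwm), "9 characters")
})

test_that("donor scores are invariant under matrix rescaling", {
  pwm <- donor_pwm_default()
  set.seed(89)
  # row-wise rescale followed by renormalization to row frequencies
  scaled <- pwm * runif(9, 0.5, 2)
  renorm <- scaled / rowSums(scaled)
  # uniform rescale (min/max bounds recomputed inside the scorer)
  uniform <- pwm * 3.7
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
               collapse = "")
    expect_equal(score_donor(s, renorm), score_donor(s, pwm),
                 tolerance = 1e-9)
    expect_equal(score_donor(s, uniform), score_donor(s, pwm),
                 tolerance = 1e-9)
  }
})

test_that("delta_S keeps its sign under a strand flip of the genome", {
  cfg <- synth_config(n_class1 = 10, n_class2 = 0, n_null = 5, n_cassette = 0,
                      seed = 23)
  ref <- generate_reference(cfg)
  mir <- mirror_dataset(ref)$ref
  pwm <- donor_pwm_default()
  for (i in seq_len(nrow(ref$truth))) {
    tr <- ref$truth[i, ]; tm <- mir$truth[i, ]
    s_u <- score_donor(donor_9mer(ref$genome, tr$chrom, tr$u_site,
                                  tr$strand), pwm)
    s_u_m <- score_donor(donor_9mer(mir$genome, tm$chrom, tm$u_site,
                                    tm$strand), pwm)
    expect_equal(s_u, s_u_m)
    ext1 <- genome_subseq(ref$genome, tr$chrom, tr$ext_start, tr$ext_end,
                          tr$strand)
    ext2 <- genome_subseq(mir$genome, tm$chrom, tm$ext_start, tm$ext_end,
                          tm$strand)
    expect_identical(ext1, ext2)
  }
})

test_that("class comparison reports features, ECDFs and tests per class", {
  cfg <- synth_config(n_class1 = 15, n_class2 = 15, n_null = 30,
                      n_cassette = 0, seed = 27)
  ref <- generate_reference(cfg)
  sim <- simulate_counts(ref)
  run <- run_discover(sim$counts, sim$design, ref$exons, genome = ref$genome,
                      class3_size = 15)
  rep <- run$class_report
  expect_s3_class(run$results, "data.frame")
  expect_true(all(rep$features$class %in% c("class1", "class2", "class3")))
  expect_true(all(rep$features$density >= 0 & rep$features$density <= 1))
  expect_true(all(rep$features$ext_len >= 4))
  # ECDF table ends at 1 per class
  by_cl <- split(rep$ecdf$ecdf, rep$ecdf$class)
  expect_true(all(vapply(by_cl, function(x) max(x) == 1, logical(1))))
  expect_equal(rep$stats$n_class3, 15)
  # class-3 sampling is reproducible under its recorded seed
  sets1 <- build_class_sets(run$results, class3_size = 15, seed = 4)
  sets2 <- build_class_sets(run$results, class3_size = 15, seed = 4)
  expect_identical(sets1$class3, sets2$class3)
})
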