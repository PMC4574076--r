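test_that("summit windows are symmetric, clipped at edges, format-aware", {
  sizes <- chrom_sizes(c(chr1 = 5000L))
  sb <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t1001\tp1\t80",
               "chr1\t10\t11\tp2\t40",       # too close to the start
               "chr1\t4990\t4991\tp3\t40"),  # too close to the end
             sb)
  expect_message(pk <- summit_windows(sb, sizes, h = 64L), "excluded 2")
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 936L)
  expect_equal(pk$end, 1065L)
  expect_equal(pk$end - pk$start, 129L)
  expect_equal(pk$score, 80)

  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t900\t1200\tq1\t0\t.\t7.5\t12\t10\t100",
               "chr1\t2000\t2300\tq2\t0\t.\t3.5\t9\t8\t-1"), np)
  expect_warning(pk2 <- summit_windows(np, sizes, h = 64L), "-1")
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$summit, 1000L)
  expect_equal(pk2$score, 7.5)  # signal column 7

  set.seed(61)
  s <- sample(100:4900, 50)
  sb2 <- tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\tp\t1", s, s + 1L), sb2)
  pk3 <- summit_windows(sb2, sizes, h = 30L)
  expect_true(all(pk3$end - pk3$start == 61L))
  expect_true(all(pk3$summit - pk3$start == 30L))
})

test_that("purified score B is exactly R minus the model prediction", {
  sim <- small_sim()
  grid <- sim$grid
  preds <- sim_predictors(sim)
  model <- staged_decompose(count_reads(sim$chip, grid), preds, width = 129L)
  pk <- sim$truth$peaks
  sb <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\tpk%d\t%.3f", pk$chrom, pk$summit,
                     pk$summit + 1L, seq_len(nrow(pk)), pk$enrichment), sb)
  peaks <- summit_windows(sb, sim$sizes, h = 64L)
  tab <- score_peaks(peaks, sim$chip, model,
                     list(mappability = sim$map_track, gc = sim$gc_track),
                     list(dnase = sim$dnase, idna = sim$idna, igg = sim$igg))
  expect_equal(tab$B + tab$predicted, as.numeric(tab$R), tolerance = 1e-12)
  # width mismatch is refused
  narrow <- summit_windows(sb, sim$sizes, h = 32L)
  expect_error(score_peaks(narrow, sim$chip, model,
                           list(mappability = sim$map_track, gc = sim$gc_track),
                           list(dnase = sim$dnase, idna = sim$idna,
                                igg = sim$igg)),
               "width")
})

test_that("degenerate background models give the expected B", {
  sim <- small_sim()
  grid <- sim$grid
  pk <- sim$truth$peaks[1:20, ]
  peaks <- data.frame(chrom = pk$chrom, summit = pk$summit,
                      start = pk$summit - 64L, end = pk$summit + 65L,
                      id = paste0("p", 1:20), score = pk$enrichment)
  tracks <- list(mappability = sim$map_track, gc = sim$gc_track)
  ctrl <- list(dnase = sim$dnase, idna = sim$idna, igg = sim$igg)
  model <- staged_decompose(count_reads(sim$chip, grid),
                            sim_predictors(sim), width = 129L)
  # zero-coefficient model with intercept c: B = R - c everywhere
  czero <- model
  czero$fit$coefficients[] <- 0
  czero$fit$coefficients[1] <- 3.25
  t0 <- score_peaks(peaks, sim$chip, czero, tracks, ctrl)
  expect_equal(t0$B, as.numeric(t0$R) - 3.25, tolerance = 1e-12)
})

test_that("planted peak enrichment is recovered by background subtraction", {
  cfg <- sim_config(seed = 77, chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                    n_peaks = 500L)
  sim <- suppressMessages(simulate_chipseq(cfg))
  model <- staged_decompose(count_reads(sim$chip, sim$grid),
                            sim_predictors(sim), width = 129L)
  pk <- sim$truth$peaks
  peaks <- data.frame(chrom = pk$chrom, summit = pk$summit,
                      start = pk$summit - 64L, end = pk$summit + 65L,
                      id = paste0("p", seq_len(nrow(pk))),
                      score = pk$enrichment)
  tab <- score_peaks(peaks, sim$chip, model,
                     list(mappability = sim$map_track, gc = sim$gc_track),
                     list(dnase = sim$dnase, idna = sim$idna, igg = sim$igg))
  # mean purified signal close to the mean planted enrichment
  expect_lt(abs(mean(tab$B) - mean(pk$enrichment)) / mean(pk$enrichment), 0.1)
})

test_that("FIMO occurrences are counted by strict containment", {
  fimo <- tempfile(fileext = ".tsv")
  writeLines(c(paste("motif_id", "motif_alt_id", "sequence_name", "start",
                     "stop", "strand", "score", "p-value", "q-value",
                     "matched_sequence", sep = "\t"),
               "M1\tm\tchr1\t101\t110\t+\t12\t1e-5\t0.01\tACGT",
               "M1\tm\tchr1\t95\t104\t-\t11\t1e-5\t0.01\tACGT",
               "M1\tm\tchr2\t11\t18\t+\t10\t1e-4\t0.02\tACGT"),
             fimo)
  occ <- read_fimo_tsv(fimo)
  expect_equal(occ$start, c(100L, 94L, 10L))  # converted to 0-based
  expect_equal(occ$end, c(110L, 104L, 18L))
  peaks <- data.frame(chrom = c("chr1", "chr2", "chr2"),
                      start = c(100L, 0L, 500L), end = c(129L, 129L, 629L))
  M <- count_motifs_in_peaks(occ, peaks)
  expect_equal(M, c(1L, 1L, 0L))  # partial overlap at 94-104 does not count

  bad <- tempfile()
  writeLines(c("a\tb\tc", "1\t2\t3"), bad)
  expect_error(read_fimo_tsv(bad), "column")

  # random occurrences vs a per-pair brute force
  set.seed(71)
  m <- 200L
  st <- sample(0:2000, m, TRUE)
  w <- sample(5:12, m, TRUE)
  occ2 <- data.frame(motif = "M", chrom = sample(c("c1", "c2"), m, TRUE),
                     start = st, end = st + w, strand = "+",
                     score = 1, p_value = 1e-5)
  ps <- sample(0:1900, 40, TRUE)
  peaks2 <- data.frame(chrom = sample(c("c1", "c2"), 40, TRUE),
                       start = ps, end = ps + 129L)
  got <- count_motifs_in_peaks(occ2, peaks2)
  oracle <- vapply(seq_len(40), function(j)
    sum(occ2$chrom == peaks2$chrom[j] & occ2$start >= peaks2$start[j] &
          occ2$end <= peaks2$end[j]), integer(1))
  expect_equal(got, oracle)
})

test_that("estimate-vs-motif correlations match the covariance formula", {
  tab <- data.frame(B = c(1, 2, 3, 4, 5), R = c(2, 1, 4, 3, 5),
                    S = c(5, 4, 3, 2, 1), M = c(1, 2, 3, 4, 5))
  cmp <- correlate_estimates(tab)
  expect_equal(cmp$pcc[cmp$estimate == "B"], 1, tolerance = 1e-12)

  set.seed(81)
  tab2 <- data.frame(B = rnorm(100), R = rnorm(100), S = rnorm(100),
                     M = rpois(100, 2))
  cmp2 <- correlate_estimates(tab2)
  man <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      ((n - 1) * sd(x) * sd(y))
  }
  expect_equal(cmp2$pcc, c(man(tab2$B, tab2$M), man(tab2$R, tab2$M),
                           man(tab2$S, tab2$M)), tolerance = 1e-12)
  # binary mode uses presence/absence
  cmpb <- correlate_estimates(tab2, binary = TRUE)
  expect_equal(cmpb$pcc[1], man(tab2$B, as.numeric(tab2$M > 0)),
               tolerance = 1e-12)
  # zero-variance motif column is flagged undefined
  tab3 <- tab2; tab3$M <- 3L
  expect_false(any(correlate_estimates(tab3)$defined))
  expect_error(correlate_estimates(tab2[1:2, ]), "3 peaks")
})

test_that("ratio test is exact upper-tail binomial and monotone", {
  # the headline worked statistic: 37 wins out of 51 under a 1/3 null
  expect_equal(ratio_test(37, 51, 3), 1.2e-8, tolerance = 0.05)
  expect_equal(ratio_test(0, 51, 3), 1)
  # enumeration oracle at small n
  enum <- sum(vapply(4:6, function(k)
    choose(6, k) * (1 / 3)^k * (2 / 3)^(6 - k), numeric(1)))
  expect_equal(ratio_test(4, 6, 3), enum, tolerance = 1e-12)
  p <- vapply(0:51, ratio_test, numeric(1), trials = 51, n_methods = 3)
  expect_true(all(diff(p) < 0))
})

test_that("the best-estimator tally breaks ties toward B and tests the winner", {
  mk <- function(b, r, s) data.frame(estimate = c("B", "R", "S"),
                                     pcc = c(b, r, s),
                                     p_value = 0, defined = TRUE)
  cmps <- list(d1 = mk(0.4, 0.3, 0.2), d2 = mk(0.3, 0.3, 0.1),  # tie -> B
               d3 = mk(0.1, 0.5, 0.2), d4 = mk(0.2, 0.2, 0.6),
               d5 = mk(0.5, 0.1, 0.1))
  res <- best_estimator_tally(cmps)
  expect_equal(unname(res$best), c("B", "B", "R", "S", "B"))
  expect_equal(unname(res$tally), c(3L, 1L, 1L))
  expect_equal(sum(res$tally), res$n_compared)
  expect_equal(res$winner, "B")
  expect_equal(res$ratio_test_p, ratio_test(3, 5, 3))
  # undefined comparisons are excluded
  cmps$d6 <- mk(NA, NA, NA); cmps$d6$defined <- FALSE
  expect_equal(best_estimator_tally(cmps)$n_compared, 5L)
})

test_that("moving motif fraction equals a sliding brute force and is tie-stable", {
  tab <- data.frame(chrom = "c", start = 1:20, B = c(20:1),
                    has_motif = rep(c(TRUE, FALSE), each = 10))
  cu <- moving_motif_fraction(tab, "B", w = 10L)
  expect_equal(cu$fraction[1], 1)
  expect_equal(cu$fraction[11], 0)
  expect_equal(cu$fraction, seq(1, 0, by = -0.1))

  all1 <- data.frame(chrom = "c", start = 1:30, B = rnorm(30),
                     has_motif = TRUE)
  expect_true(all(moving_motif_fraction(all1, "B", w = 5L)$fraction == 1))

  set.seed(91)
  tb <- data.frame(chrom = "c", start = sample(1000), B = rnorm(1000),
                   has_motif = runif(1000) < 0.4)
  cu2 <- moving_motif_fraction(tb, "B", w = 100L)
  o <- order(-tb$B, tb$chrom, tb$start)
  hm <- tb$has_motif[o]
  oracle <- vapply(1:901, function(j) mean(hm[j:(j + 99)]), numeric(1))
  expect_equal(cu2$fraction, oracle)
  expect_error(moving_motif_fraction(tb, "B", w = 2000L), "smaller")

  # a tie-consistent re-sort leaves the curve unchanged
  tb$B <- round(tb$B)  # create ties
  perm <- sample(1000)
  cu3 <- moving_motif_fraction(tb, "B", w = 100L)
  cu4 <- moving_motif_fraction(tb[perm, ], "B", w = 100L)
  expect_equal(cu3$fraction, cu4$fraction)
})

test_that("sextile overlap is diagonal for equal ranks and conserves counts", {
  set.seed(95)
  tab <- data.frame(chrom = "c", start = sample(600), B = rnorm(600))
  tab$R <- tab$B
  m <- sextile_overlap(tab, "B", "R")
  expect_equal(sum(m) , 600L)
  expect_equal(unname(diag(m)), rep(100L, 6))
  tab$S <- -tab$B
  ma <- sextile_overlap(tab, "B", "S")
  expect_equal(unname(diag(ma[, 6:1])), rep(100L, 6))
  tab$Z <- rnorm(600)
  mr <- sextile_overlap(tab, "B", "Z")
  expect_equal(unname(rowSums(mr)), rep(100L, 6))
  expect_equal(unname(colSums(mr)), rep(100L, 6))
  # remainder spreading: 602 peaks -> first two groups get 101
  tab2 <- data.frame(chrom = "c", start = sample(602), B = rnorm(602))
  tab2$R <- tab2$B
  m2 <- sextile_overlap(tab2, "B", "R")
  expect_equal(unname(diag(m2)), c(101L, 101L, 100L, 100L, 100L, 100L))
})
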