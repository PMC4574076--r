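test_that("BED6 ingest applies the 5'-end convention and drops bad records", {
  sizes <- tiny_sizes()
  path <- tempfile(fileext = ".bed")
  writeLines(c("chrA\t100\t136\tr1\t0\t+",
               "chrA\t100\t136\tr2\t0\t-",
               "chrUn\t5\t41\tr3\t0\t+",      # unknown chromosome
               "chrB\t1290\t1326\tr4\t0\t-"), # 5' pos 1325 >= 1300: rejected
             path)
  expect_message(expect_message(
    reads <- read_bed_reads(path, sizes),
    "dropped 1"), "rejected 1")
  expect_s3_class(reads, "read_set")
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$pos, c(100L, 135L))
  expect_equal(reads$strand, c("+", "-"))
  expect_false(isTRUE(attr(reads, "dedup_applied")))
})

test_that("malformed BED lines raise errors naming the line", {
  sizes <- tiny_sizes()
  p1 <- tempfile(); writeLines(c("chrA\t10\t46\tr\t0\t+", "chrA\t10"), p1)
  expect_error(read_bed_reads(p1, sizes), "line 2")
  p2 <- tempfile(); writeLines("chrA\tfoo\t46\tr\t0\t+", p2)
  expect_error(read_bed_reads(p2, sizes), "line 1")
  p3 <- tempfile(); writeLines("chrA\t10\t46\tr\t0\t*", p3)
  expect_error(read_bed_reads(p3, sizes), "strand")
})

test_that("random BED ingest matches a per-line brute-force parser", {
  sizes <- tiny_sizes()
  fx <- random_reads_bed(1000L, sizes, seed = 5)
  reads <- read_bed_reads(fx$path, sizes)
  expect_equal(nrow(reads), 1000L)
  # independent oracle: recompute each 5' position line by line
  lines <- readLines(fx$path)
  oracle <- t(vapply(strsplit(lines, "\t"), function(f) {
    p <- if (f[6] == "+") as.integer(f[2]) else as.integer(f[3]) - 1L
    c(f[1], p, f[6])
  }, character(3)))
  expect_equal(reads$chrom, oracle[, 1])
  expect_equal(reads$pos, as.integer(oracle[, 2]))
  expect_equal(reads$strand, oracle[, 3])
})

test_that("deduplication keeps one read per (chrom, strand, position) triple", {
  r <- read_set(c("chr1", "chr1", "chr1"), c(50L, 50L, 50L), c("+", "+", "-"))
  d <- deduplicate(r)
  expect_equal(nrow(d), 2L)           # same-strand duplicate collapsed
  expect_true(attr(d, "dedup_applied"))

  set.seed(9)
  n <- 500L
  chrom <- sample(c("c1", "c2"), n, replace = TRUE)
  pos <- sample(0:99, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  d2 <- deduplicate(read_set(chrom, pos, strand))
  # independent set-cardinality oracle
  expect_equal(nrow(d2), length(unique(paste(chrom, strand, pos))))
  # idempotence and order independence
  expect_equal(deduplicate(d2), d2)
  perm <- sample(n)
  expect_equal(deduplicate(read_set(chrom[perm], pos[perm], strand[perm])), d2)
})

test_that("GC track scores G/C as 1 and everything else, including N, as 0", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrA", "GGCC", ">chrB", "AATT", ">chrC", "ACGTN"), fa)
  tr <- gc_track(fa)
  expect_equal(tr$bits$chrA, c(1L, 1L, 1L, 1L))
  expect_equal(tr$bits$chrB, c(0L, 0L, 0L, 0L))
  expect_equal(tr$bits$chrC, c(0L, 1L, 1L, 0L, 0L))
  expect_error(gc_track(fa, sizes = chrom_sizes(c(chrA = 4, chrB = 4, chrC = 99))),
               "chrC")
})

test_that("mappability binarization thresholds per base with uncovered = 0", {
  sizes <- chrom_sizes(c(chrA = 30L))
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("chrA\t0\t10\t1.0", "chrA\t10\t15\t0.5", "chrA\t20\t25\t0.8"), bg)
  tr <- binarize_mappability(bg, sizes)  # default threshold 1.0
  expect_equal(tr$bits$chrA, c(rep(1L, 10), rep(0L, 20)))
  tr7 <- binarize_mappability(bg, sizes, threshold = 0.7)
  # brute-force per-base oracle
  oracle <- numeric(30)
  oracle[1:10] <- 1.0; oracle[11:15] <- 0.5; oracle[21:25] <- 0.8
  covered <- c(rep(TRUE, 15), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(tr7$bits$chrA, as.integer(covered & oracle >= 0.7))
  # conflicting overlap errors
  bad <- tempfile(fileext = ".bedGraph")
  writeLines(c("chrA\t0\t10\t1.0", "chrA\t5\t12\t0.5"), bad)
  expect_error(binarize_mappability(bad, sizes), "conflicting")
})

test_that("fixed-step wiggle input binarizes identically to bedGraph", {
  sizes <- chrom_sizes(c(chrA = 12L))
  wig <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chrA start=1 step=1 span=1",
               rep("1.0", 6), rep("0.25", 4)), wig)
  tr <- binarize_mappability(wig, sizes)
  expect_equal(tr$bits$chrA, c(rep(1L, 6), rep(0L, 6)))
})

test_that("window grids drop partial windows and excluded chromosomes", {
  sizes <- chrom_sizes(c(chr1 = 1000L, chr2 = 128L, chrY = 4000L))
  g <- make_window_grid(sizes, 129L)
  expect_equal(unname(g$n_windows["chr1"]), 7L)   # floor(1000/129)
  expect_equal(unname(g$n_windows["chr2"]), 0L)   # partial dropped
  expect_false("chrY" %in% g$chroms)              # default exclusion
  expect_error(make_window_grid(sizes, 128L), "odd")

  set.seed(21)
  for (i in 1:20) {
    L <- sample(50:5000, 3)
    names(L) <- paste0("c", 1:3)
    w <- 2L * sample(2:40, 1) + 1L
    gg <- make_window_grid(chrom_sizes(L), w, exclude = character())
    expect_equal(unname(gg$n_windows), unname(L %/% w))
  }
})

test_that("windowed read counting matches a per-read loop oracle", {
  sizes <- tiny_sizes()
  set.seed(31)
  n <- 10000L
  chrom <- sample(names(sizes), n, replace = TRUE)
  pos <- floor(runif(n) * unname(sizes[chrom]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  reads <- deduplicate(read_set(chrom, pos, strand))
  grid <- make_window_grid(sizes, 129L)
  v <- count_reads(reads, grid)
  co <- window_coords(grid)
  # independent per-read loop
  oracle <- integer(nrow(co))
  for (i in seq_len(nrow(reads))) {
    hit <- which(co$chrom == reads$chrom[i] & co$start <= reads$pos[i] &
                   reads$pos[i] < co$end)
    if (length(hit)) oracle[hit] <- oracle[hit] + 1L
  }
  expect_equal(as.integer(v), oracle)
  # conservation: total counted = reads inside complete windows
  inside <- sum(mapply(function(ch, p) p < grid$n_windows[[ch]] * 129L,
                       reads$chrom, reads$pos))
  expect_equal(sum(v), inside)
  # 2N bound after dedup
  expect_lte(max(v), 2L * 129L)
  # empty read set gives zeros
  expect_true(all(count_reads(deduplicate(read_set()), grid) == 0L))
})

test_that("track fractions equal brute-force per-base sums and respect bounds", {
  sizes <- chrom_sizes(c(chrA = 700L))
  grid <- make_window_grid(sizes, 129L, exclude = character())
  set.seed(41)
  bits <- as.integer(runif(700) < 0.4)
  tr <- binary_track(list(chrA = bits), "mappability", sizes)
  v <- track_fraction(tr, grid)
  co <- window_coords(grid)
  oracle <- vapply(seq_len(nrow(co)),
                   function(i) sum(bits[(co$start[i] + 1):co$end[i]]) / 129,
                   numeric(1))
  expect_equal(as.numeric(v), oracle)
  expect_true(all(v >= 0 & v <= 1))
  # sum over windows times N = total ones inside complete windows
  expect_equal(sum(v) * 129, sum(bits[1:(5 * 129)]))
  ones <- binary_track(list(chrA = rep(1L, 700)), "gc")
  expect_true(all(track_fraction(ones, grid) == 1))
  zeros <- binary_track(list(chrA = rep(0L, 700)), "gc")
  expect_true(all(track_fraction(zeros, grid) == 0))
})

test_that("interval counting is half-open, overlap-safe, and oracle-exact", {
  r <- read_set("chr1", 100L, "+")
  iv <- data.frame(chrom = "chr1", start = c(100L, 50L), end = c(101L, 150L))
  expect_equal(count_in_intervals(r, iv), c(1L, 1L))
  expect_equal(count_in_intervals(read_set(), iv), c(0L, 0L))
  expect_error(count_in_intervals(r, data.frame(chrom = "chr1", start = 5L,
                                                end = 5L)),
               "start < end")
  set.seed(51)
  n <- 2000L
  reads <- read_set(sample(c("c1", "c2"), n, TRUE),
                    sample(0:999, n, TRUE),
                    sample(c("+", "-"), n, TRUE))
  m <- 60L
  st <- sample(0:900, m, TRUE)
  iv2 <- data.frame(chrom = sample(c("c1", "c2"), m, TRUE),
                    start = st, end = st + sample(1:100, m, TRUE))
  got <- count_in_intervals(reads, iv2)
  oracle <- vapply(seq_len(m), function(j)
    sum(reads$chrom == iv2$chrom[j] & reads$pos >= iv2$start[j] &
          reads$pos < iv2$end[j]), integer(1))
  expect_equal(got, oracle)
})
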