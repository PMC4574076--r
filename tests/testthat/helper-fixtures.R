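# Shared fixture builders.  Everything is generated in code; nothing is
# read from stored data files.

tiny_sizes <- function() chrom_sizes(c(chrA = 2000L, chrB = 1300L))

# Write a BED6 file from vectors; returns the path.
write_bed6 <- function(chrom, start, end, strand, path = tempfile(fileext = ".bed"),
                       name = ".", score = 0L) {
  df <- data.frame(chrom, start, end, name, score, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

random_reads_bed <- function(n, sizes, seed, path = tempfile(fileext = ".bed")) {
  set.seed(seed)
  chrom <- sample(names(sizes), n, replace = TRUE)
  pos <- 36L + floor(runif(n) * (unname(sizes[chrom]) - 80L))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  write_bed6(chrom, ifelse(strand == "+", pos, pos - 35L),
             ifelse(strand == "+", pos + 36L, pos + 1L), strand, path)
  list(path = path, chrom = chrom, pos = pos, strand = strand)
}

# Small ready-made simulation reused by several test files (cached per run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(simulate_chipseq(
        sim_config(seed = 101, chrom_sizes = c(chr1 = 3e5, chr2 = 2e5))))
    cache
  }
})

sim_predictors <- function(sim) {
  list(mappability = sim$map_frac, gc = sim$gc_frac,
       dnase = count_reads(sim$dnase, sim$grid),
       idna = count_reads(sim$idna, sim$grid),
       igg = count_reads(sim$igg, sim$grid))
}
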