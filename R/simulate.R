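#' Simulation configuration with planted parameters
#'
#' Bundles every knob of the synthetic-data generator.  The generator
#' mirrors the composition model the decomposition assumes: window-level
#' expected ChIP counts are a *linear* function of the background features
#' (so the fitted linear model is correctly specified and coefficient
#' recovery is exact in expectation), plus a per-peak enrichment; control
#' read sets are generated from their own coefficient vectors; expression is
#' log-linear in chromatin accessibility, producing the right-skewed count
#' distribution real CAGE data shows.  Negative linear rates are clamped to
#' zero before the Poisson draw — the one deliberate mis-specification knob.
#'
#' Defaults describe a small but realistic genome: human-like GC content
#' (0.41), mappable/unmappable run lengths of 400/25 bp (about 94% of bases
#' uniquely mappable), chromatin accessibility as Gaussian bumps of mean
#' amplitude 1 and width 300-1500 bp over a 0.1 baseline (60 bumps/Mb), and
#' planted coefficients giving a few background ChIP reads per 129-bp
#' window, comparable to deeply sequenced windowed ENCODE-style counts.
#'
#' @param seed integer seed (mandatory; every derived RNG stream is an
#'   offset of it, all below 2^31).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param width window width used for read generation (odd; default 129).
#' @param map_run_mappable,map_run_unmappable mean geometric run lengths
#'   (bp) of mappable / unmappable stretches.
#' @param gc_prob per-base probability of G or C.
#' @param acc_baseline,acc_bumps_per_mb,acc_bump_amp,acc_bump_sd,acc_max
#'   accessibility field: baseline rate, bump density per Mb, mean
#'   (exponential) bump amplitude, range of bump standard deviations (bp),
#'   and saturation ceiling (overlapping bumps saturate, as physical
#'   occupancy does; the cap also keeps the log-linear expression link in a
#'   realistic count range).
#' @param beta planted linear coefficients for the ChIP rate, named
#'   `intercept`, `mappability`, `gc`, `dnase`, `idna`, `igg` (feature units:
#'   fractions for the tracks, window read counts for the controls).
#' @param dnase_rate c(intercept, accessibility-slope) for the DNaseI
#'   window rate.
#' @param idna_rate c(intercept, mappability-slope, gc-slope) for input DNA.
#' @param igg_rate c(intercept, mappability-slope, gc-slope) for IgG.
#' @param n_peaks,peak_delta,motif_per_enrichment,motif_width peak count,
#'   mean planted enrichment (reads per peak window, gamma with shape 2),
#'   expected motif occurrences per unit enrichment (motif count is Poisson
#'   in the true enrichment, an increasing link), motif width in bp.
#' @param n_tss,expr_intercept,expr_acc_coef TSS count and log-linear
#'   CAGE-rate coefficients: E[count] = exp(intercept + coef * accessibility).
#' @param fake_tf_rate,general_tf_rate c(intercept, accessibility-slope) for
#'   the two synthetic TF read sets.
#' @param coupling extra reads per unit realized expression added to the
#'   "general factor" TF at each TSS window; 0 (default) makes both TFs
#'   conditionally independent of expression given accessibility.
#' @param exclude chromosomes excluded from window grids.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       chrom_sizes = c(chr1 = 6e5, chr2 = 4e5),
                       width = 129L,
                       map_run_mappable = 400,
                       map_run_unmappable = 25,
                       gc_prob = 0.41,
                       acc_baseline = 0.1,
                       acc_bumps_per_mb = 60,
                       acc_bump_amp = 1.0,
                       acc_bump_sd = c(300, 1500),
                       acc_max = 2,
                       beta = c(intercept = 1.0, mappability = 2.0,
                                gc = 1.5, dnase = 0.6, idna = 0.3,
                                igg = 0.2),
                       dnase_rate = c(0.5, 20),
                       idna_rate = c(1.0, 1.0, 1.0),
                       igg_rate = c(0.8, 0.8, 0),
                       n_peaks = 300L,
                       peak_delta = 15,
                       motif_per_enrichment = 0.15,
                       motif_width = 8L,
                       n_tss = 2000L,
                       expr_intercept = 0.5,
                       expr_acc_coef = 4,
                       fake_tf_rate = c(0.5, 4),
                       general_tf_rate = c(0.5, 4),
                       coupling = 0,
                       exclude = "chrY") {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(all(c("intercept", "mappability", "gc", "dnase", "idna", "igg")
                %in% names(beta)))
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$chrom_sizes <- chrom_sizes(chrom_sizes)
  structure(cfg, class = "sim_config")
}

#' Simulate genome tracks and the accessibility field
#'
#' Generates the binary mappability track (alternating geometric runs), the
#' binary GC track (i.i.d. Bernoulli bases), and the chromatin-accessibility
#' rate field (Gaussian bumps over a baseline), evaluated per grid window.
#'
#' @param config a [sim_config()].
#' @return list with `sizes`, `grid`, `map_track`, `gc_track`
#'   ([binary_track()]s), `acc` (numeric accessibility per window),
#'   `map_frac`, `gc_frac` (per-window track fractions).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  sizes <- config$chrom_sizes
  grid <- make_window_grid(sizes, config$width, exclude = config$exclude)

  map_bits <- lapply(names(sizes), function(ch) {
    L <- sizes[[ch]]
    bits <- integer(0)
    mu_m <- config$map_run_mappable; mu_u <- config$map_run_unmappable
    while (length(bits) < L) {
      k <- max(16L, ceiling(1.2 * (L - length(bits)) / (mu_m + mu_u)))
      lens <- as.vector(rbind(1L + stats::rgeom(k, 1 / max(mu_m, 1)),
                              1L + stats::rgeom(k, 1 / max(mu_u, 1))))
      bits <- c(bits, inverse.rle(list(lengths = lens,
                                       values = rep(c(1L, 0L), k))))
    }
    bits[seq_len(L)]
  })
  names(map_bits) <- names(sizes)
  map_track <- binary_track(map_bits, "mappability", sizes = sizes)

  gc_bits <- lapply(names(sizes), function(ch)
    as.integer(stats::rbinom(sizes[[ch]], 1L, config$gc_prob)))
  names(gc_bits) <- names(sizes)
  gc_track <- binary_track(gc_bits, "gc", sizes = sizes)

  # accessibility: per-window evaluation of baseline + Gaussian bumps
  co <- window_coords(grid)
  centers <- (co$start + co$end - 1) / 2
  acc <- rep(config$acc_baseline, nrow(co))
  for (ch in grid$chroms) {
    idx <- which(co$chrom == ch)
    L <- sizes[[ch]]
    nb <- stats::rpois(1L, config$acc_bumps_per_mb * L / 1e6)
    if (nb == 0L) next
    bc <- stats::runif(nb, 0, L)
    ba <- stats::rexp(nb, 1 / config$acc_bump_amp)
    bs <- stats::runif(nb, config$acc_bump_sd[1], config$acc_bump_sd[2])
    x <- centers[idx]
    for (b in seq_len(nb)) {
      lo <- bc[b] - 5 * bs[b]; hi <- bc[b] + 5 * bs[b]
      j <- which(x >= lo & x <= hi)
      if (length(j))
        acc[idx[j]] <- acc[idx[j]] + ba[b] * exp(-(x[j] - bc[b])^2 / (2 * bs[b]^2))
    }
  }
  acc <- pmin(acc, config$acc_max)

  list(sizes = sizes, grid = grid,
       map_track = map_track, gc_track = gc_track, acc = acc,
       map_frac = track_fraction(map_track, grid),
       gc_frac = track_fraction(gc_track, grid))
}

# Place per-window read counts as distinct (position, strand) pairs uniform
# over the mappable bases of each window.  Windows without mappable bases
# have their reads suppressed.  `distinct = FALSE` allows duplicates
# (used for CAGE tags, which are not deduplicated downstream).
place_reads <- function(n_per_window, sim, distinct = TRUE, max_iter = 60L) {
  grid <- sim$grid
  co <- window_coords(grid)
  W <- grid$width
  out_chrom <- character(0); out_pos <- integer(0); out_strand <- character(0)
  suppressed <- 0L
  for (ch in grid$chroms) {
    idx <- which(co$chrom == ch)
    n <- n_per_window[idx]
    bits <- sim$map_track$bits[[ch]]
    # cap: a window with m mappable bases holds at most 2m distinct reads
    cs <- c(0L, cumsum(bits))
    m_w <- cs[co$end[idx] + 1L] - cs[co$start[idx] + 1L]
    if (distinct) {
      over <- n > 2L * m_w
      if (any(over)) {
        suppressed <- suppressed + sum(n[over] - 2L * m_w[over])
        n[over] <- 2L * m_w[over]
      }
    } else {
      kill <- m_w == 0L & n > 0L
      suppressed <- suppressed + sum(n[kill]); n[kill] <- 0L
    }
    tot <- sum(n)
    if (tot == 0L) next
    wstart <- rep.int(co$start[idx], n)
    todo <- seq_len(tot)
    pos <- integer(tot); strand <- integer(tot)
    iter <- 0L
    while (length(todo) && iter < max_iter) {
      iter <- iter + 1L
      p <- wstart[todo] + sample.int(W, length(todo), replace = TRUE) - 1L
      s <- sample.int(2L, length(todo), replace = TRUE) - 1L
      ok <- bits[p + 1L] == 1L
      pos[todo[ok]] <- p[ok]; strand[todo[ok]] <- s[ok]
      todo <- todo[!ok]
      if (!length(todo) && distinct) {
        key <- as.numeric(pos) * 2 + strand
        dup <- which(duplicated(key))
        todo <- dup
      }
    }
    if (length(todo)) {
      suppressed <- suppressed + length(todo)
      keep <- setdiff(seq_len(tot), todo)
      pos <- pos[keep]; strand <- strand[keep]; tot <- length(keep)
    }
    out_chrom <- c(out_chrom, rep.int(ch, tot))
    out_pos <- c(out_pos, pos)
    out_strand <- c(out_strand, c("+", "-")[strand + 1L])
  }
  if (suppressed > 0L)
    message(sprintf("place_reads: suppressed %d read(s) in unmappable space",
                    suppressed))
  read_set(out_chrom, out_pos, out_strand, dedup_applied = distinct)
}

#' Simulate control and ChIP read sets with planted coefficients
#'
#' Draws, per complete grid window, Poisson counts for DNaseI (rate linear
#' in accessibility), input DNA and IgG (rates linear in mappability and GC
#' fraction), then the ChIP count with rate
#' `max(0, beta . (1, map_frac, gc_frac, dnase, idna, igg)) + enrichment`,
#' where `enrichment` is nonzero only in the `n_peaks` planted peak windows
#' (gamma-distributed strengths, mean `peak_delta`).  Reads are placed as
#' distinct stranded positions uniform over the mappable bases of their
#' window, so deduplicated recounting reproduces the drawn counts exactly.
#'
#' @param config a [sim_config()].
#' @param sim result of [simulate_tracks()].
#' @return `sim` extended with read sets `chip`, `dnase`, `idna`, `igg` and
#'   a `truth` list (planted `beta`, per-window rates and control counts,
#'   peak table with true enrichments).
#' @export
simulate_reads <- function(config, sim) {
  set.seed(config$seed + 2L)
  grid <- sim$grid
  nW <- n_windows(grid)
  co <- window_coords(grid)
  map_f <- as.numeric(sim$map_frac)
  gc_f <- as.numeric(sim$gc_frac)

  lam_dnase <- pmax(0, config$dnase_rate[1] + config$dnase_rate[2] * sim$acc)
  lam_idna <- pmax(0, config$idna_rate[1] + config$idna_rate[2] * map_f +
                     config$idna_rate[3] * gc_f)
  lam_igg <- pmax(0, config$igg_rate[1] + config$igg_rate[2] * map_f +
                    config$igg_rate[3] * gc_f)
  n_dnase <- stats::rpois(nW, lam_dnase)
  n_idna <- stats::rpois(nW, lam_idna)
  n_igg <- stats::rpois(nW, lam_igg)

  # planted peaks: distinct well-mappable windows, summit at window centre
  enrich <- numeric(nW)
  peak_tab <- NULL
  if (config$n_peaks > 0L) {
    eligible <- which(map_f > 0.5)
    n_pk <- min(config$n_peaks, length(eligible))
    pk <- sort(sample(eligible, n_pk))
    e <- stats::rgamma(n_pk, shape = 2, scale = config$peak_delta / 2)
    enrich[pk] <- e
    peak_tab <- data.frame(window = pk,
                           chrom = co$chrom[pk],
                           summit = co$start[pk] + grid$width %/% 2L,
                           enrichment = e,
                           stringsAsFactors = FALSE)
  }

  b <- config$beta
  lam_chip_bg <- pmax(0, b[["intercept"]] + b[["mappability"]] * map_f +
                        b[["gc"]] * gc_f + b[["dnase"]] * n_dnase +
                        b[["idna"]] * n_idna + b[["igg"]] * n_igg)
  n_chip <- stats::rpois(nW, lam_chip_bg + enrich)

  sim$dnase <- place_reads(n_dnase, sim)
  sim$idna <- place_reads(n_idna, sim)
  sim$igg <- place_reads(n_igg, sim)
  sim$chip <- place_reads(n_chip, sim)
  sim$truth <- list(beta = b,
                    acc = sim$acc,
                    lambda_chip_bg = lam_chip_bg,
                    enrichment = enrich,
                    control_counts = data.frame(dnase = n_dnase,
                                                idna = n_idna, igg = n_igg),
                    peaks = peak_tab)
  sim
}

#' Emit planted peaks as summit BED plus FIMO-format motif occurrences
#'
#' Writes each planted peak's summit as a 1-bp BED row (score column = true
#' enrichment, a perfect-oracle peak-caller score), and draws the motif
#' count of each peak as Poisson(`motif_per_enrichment` * enrichment) — an
#' increasing link between true binding strength and motif frequency.
#' Occurrences are placed at uniform offsets fully inside the summit +/- h
#' window and emitted in FIMO's tab-separated format (1-based inclusive
#' coordinates).
#'
#' @param config a [sim_config()].
#' @param sim result of [simulate_reads()] (needs `truth$peaks`).
#' @param summit_path,fimo_path output paths.
#' @return list with the peak table (plus `M` truth column) and both paths.
#' @export
simulate_peaks_with_motifs <- function(config, sim, summit_path, fimo_path) {
  set.seed(config$seed + 3L)
  pk <- sim$truth$peaks
  if (is.null(pk) || nrow(pk) == 0L) stop("no planted peaks in this simulation")
  h <- config$width %/% 2L
  M <- stats::rpois(nrow(pk), config$motif_per_enrichment * pk$enrichment)
  pk$M <- M

  utils::write.table(data.frame(pk$chrom, pk$summit, pk$summit + 1L,
                                sprintf("peak_%d", seq_len(nrow(pk))),
                                round(pk$enrichment, 3)),
                     summit_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  mw <- config$motif_width
  rows <- list()
  for (i in which(M > 0L)) {
    off <- sample.int(config$width - mw + 1L, M[i], replace = TRUE) - 1L
    st0 <- pk$summit[i] - h + off  # 0-based
    rows[[length(rows) + 1L]] <-
      data.frame(motif_id = "SYN_MOTIF", motif_alt_id = "synthetic",
                 sequence_name = pk$chrom[i],
                 start = st0 + 1L, stop = st0 + mw,  # 1-based inclusive
                 strand = sample(c("+", "-"), M[i], replace = TRUE),
                 score = round(stats::runif(M[i], 8, 20), 3),
                 `p-value` = signif(stats::runif(M[i], 1e-8, 1e-4), 3),
                 `q-value` = NA_real_,
                 matched_sequence = strrep("N", mw),
                 check.names = FALSE)
  }
  occ <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(), motif_alt_id = character(),
               sequence_name = character(), start = integer(),
               stop = integer(), strand = character(), score = numeric(),
               `p-value` = numeric(), `q-value` = numeric(),
               matched_sequence = character(), check.names = FALSE)
  utils::write.table(occ, fimo_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(peaks = pk, summit_path = summit_path, fimo_path = fimo_path)
}

#' Simulate TSSs, CAGE expression, and accessibility-confounded TF signals
#'
#' Selects `n_tss` non-peak grid windows as TSS windows (the TSS at the
#' window centre) and draws the CAGE tag count of each as
#' Poisson(exp(expr_intercept + expr_acc_coef * accessibility)) — a
#' log-linear link producing the heavy right skew of real promoter tag
#' counts.  Two TF-like read sets are generated with window rates linear in
#' accessibility only: the "specific" TF is by construction conditionally
#' independent of expression given accessibility (a pure confound), while
#' the "general" factor additionally receives `coupling` reads per realized
#' CAGE tag at each TSS, giving it genuine information beyond accessibility.
#'
#' @param config a [sim_config()].
#' @param sim result of [simulate_reads()].
#' @return `sim` extended with `tss` (data frame: chrom, tss, start, end,
#'   id, window, mu), `cage`, `fake_tf`, `general_tf` read sets; truth
#'   gains `tss` and `expr_mu`.
#' @export
simulate_expression <- function(config, sim) {
  set.seed(config$seed + 4L)
  grid <- sim$grid
  co <- window_coords(grid)
  nW <- n_windows(grid)
  free <- setdiff(which(as.numeric(sim$map_frac) > 0.5 & sim$truth$enrichment == 0),
                  sim$truth$peaks$window)
  n_tss <- min(config$n_tss, length(free))
  tw <- sort(sample(free, n_tss))
  h <- config$width %/% 2L
  tss <- data.frame(chrom = co$chrom[tw],
                    tss = co$start[tw] + h,
                    start = co$start[tw], end = co$end[tw],
                    id = sprintf("gene_%d", seq_len(n_tss)),
                    window = tw, stringsAsFactors = FALSE)
  mu <- exp(config$expr_intercept + config$expr_acc_coef * sim$acc[tw])
  y <- stats::rpois(n_tss, mu)
  tss$mu <- mu
  tss$cage_count <- y

  cage_n <- integer(nW); cage_n[tw] <- y
  sim$cage <- place_reads(cage_n, sim, distinct = FALSE)

  lam_fake <- pmax(0, config$fake_tf_rate[1] + config$fake_tf_rate[2] * sim$acc)
  sim$fake_tf <- place_reads(stats::rpois(nW, lam_fake), sim)
  lam_gen <- pmax(0, config$general_tf_rate[1] + config$general_tf_rate[2] * sim$acc)
  extra <- numeric(nW)
  if (config$coupling > 0) extra[tw] <- config$coupling * y
  sim$general_tf <- place_reads(stats::rpois(nW, lam_gen + extra), sim)

  sim$tss <- tss
  sim$truth$tss <- tss
  sim
}

#' Run the full synthetic-data generator
#'
#' Chains [simulate_tracks()], [simulate_reads()] and
#' [simulate_expression()] under one master seed.  Each stage uses a fixed
#' small offset of `config$seed` (R's Mersenne-Twister), so the whole bundle
#' is bit-reproducible given the seed.
#'
#' @param config a [sim_config()].
#' @return the full simulation list (tracks, grid, read sets, TSS table,
#'   truth).
#' @export
simulate_chipseq <- function(config) {
  sim <- simulate_tracks(config)
  sim <- simulate_reads(config, sim)
  sim <- simulate_expression(config, sim)
  sim$config <- config
  sim
}

#' Write a simulation bundle to disk
#'
#' Emits every file format the readers consume: genome FASTA (bases drawn
#' to match the binary GC track), chrom.sizes, mappability bedGraph, BED6
#' read sets (ChIP, DNaseI, input DNA, IgG, CAGE, both synthetic TFs),
#' summit BED + FIMO TSV for the planted peaks, TSS BED, and a truth JSON
#' with the planted parameters.
#'
#' @param sim result of [simulate_chipseq()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  paths <- c(chrom_sizes = file.path(dir, "genome.chrom.sizes"),
             fasta = file.path(dir, "genome.fa"),
             mappability = file.path(dir, "mappability.bedGraph"),
             chip = file.path(dir, "chip.bed"),
             dnase = file.path(dir, "dnase.bed"),
             idna = file.path(dir, "idna.bed"),
             igg = file.path(dir, "igg.bed"),
             cage = file.path(dir, "cage.bed"),
             fake_tf = file.path(dir, "fake_tf.bed"),
             general_tf = file.path(dir, "general_tf.bed"),
             summits = file.path(dir, "peaks_summits.bed"),
             fimo = file.path(dir, "fimo.tsv"),
             tss = file.path(dir, "tss.bed"),
             truth = file.path(dir, "truth.json"))

  write_chrom_sizes(sim$sizes, paths[["chrom_sizes"]])

  set.seed(cfg$seed + 5L)
  con <- file(paths[["fasta"]], "w")
  for (ch in names(sim$sizes)) {
    gc <- sim$gc_track$bits[[ch]]
    letters <- ifelse(gc == 1L,
                      c("G", "C")[sample.int(2L, length(gc), replace = TRUE)],
                      c("A", "T")[sample.int(2L, length(gc), replace = TRUE)])
    writeLines(paste0(">", ch), con)
    s <- paste(letters, collapse = "")
    writeLines(substring(s, seq(1, nchar(s), 70),
                         pmin(seq(1, nchar(s), 70) + 69, nchar(s))), con)
  }
  close(con)

  write_track_bedgraph(sim$map_track, paths[["mappability"]])
  for (nm in c("chip", "dnase", "idna", "igg", "cage", "fake_tf", "general_tf"))
    write_bed_reads(sim[[nm]], paths[[nm]])

  pm <- simulate_peaks_with_motifs(cfg, sim, paths[["summits"]],
                                   paths[["fimo"]])
  utils::write.table(data.frame(sim$tss$chrom, sim$tss$tss, sim$tss$tss + 1L,
                                sim$tss$id, 0L, "+"),
                     paths[["tss"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  truth <- list(seed = cfg$seed,
                beta = as.list(cfg$beta),
                width = cfg$width,
                peaks = pm$peaks,
                tss = sim$tss[, c("chrom", "tss", "id", "mu", "cage_count")])
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
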