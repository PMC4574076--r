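#' Summit-centred peak windows
#'
#' Peak calls are asymmetric and vary in width, so each peak is redefined as
#' a symmetric window of `2h + 1` bp centred on its summit: `[summit - h,
#' summit + h]` inclusive, i.e. half-open `[summit - h, summit + h + 1)`.
#' With the default h = 64 this gives 129-bp peak windows, matching the
#' genome-wide analysis scale.  Peaks whose window would cross a chromosome
#' edge are excluded (not truncated) and their count reported, keeping all
#' windows width-consistent with the trained background model.
#'
#' @param path path to a summit BED file (1-bp intervals; column 5 is the
#'   peak-caller score) or a narrowPeak file (10 columns; summit = start +
#'   column-10 offset; column 7 is the signal used as score).  Format is
#'   auto-detected from the column count unless given.
#' @param sizes a [chrom_sizes()] object.
#' @param h half-width in bp (default 64).
#' @param format `"auto"`, `"summit_bed"` or `"narrowPeak"`.
#' @return data frame with columns `chrom`, `summit`, `start`, `end`
#'   (0-based half-open window), `id`, `score` (peak-caller score S).
#' @export
summit_windows <- function(path, sizes, h = 64L,
                           format = c("auto", "summit_bed", "narrowPeak")) {
  format <- match.arg(format)
  stopifnot(inherits(sizes, "chrom_sizes"))
  h <- as.integer(h)
  tab <- read_bed_table(path, min_cols = 4L)
  ncols <- length(tab)
  if (format == "auto")
    format <- if (ncols >= 10L) "narrowPeak" else "summit_bed"
  chrom <- tab[[1]]
  if (format == "narrowPeak") {
    if (ncols < 10L) stop(path, ": narrowPeak requires 10 columns")
    offset <- suppressWarnings(as.integer(tab[[10]]))
    unknown <- !is.na(offset) & offset == -1L
    if (any(unknown)) {
      warning(sprintf("summit_windows: skipped %d peak(s) with unknown summit offset (-1)",
                      sum(unknown)))
    }
    keep <- !is.na(offset) & offset >= 0L
    summit <- tab[[2]][keep] + offset[keep]
    chrom <- chrom[keep]
    id <- tab[[4]][keep]
    score <- suppressWarnings(as.numeric(tab[[7]][keep]))
  } else {
    if (any(tab[[3]] - tab[[2]] != 1L))
      stop(path, ": summit BED rows must be 1-bp intervals")
    summit <- tab[[2]]
    id <- tab[[4]]
    score <- if (ncols >= 5L) suppressWarnings(as.numeric(tab[[5]])) else
      rep(NA_real_, length(summit))
  }
  known <- chrom %in% names(sizes)
  if (any(!known))
    message(sprintf("summit_windows: dropped %d peak(s) on unknown chromosomes",
                    sum(!known)))
  chrom <- chrom[known]; summit <- summit[known]
  id <- id[known]; score <- score[known]
  inb <- summit - h >= 0L & summit + h + 1L <= unname(sizes[chrom])
  if (any(!inb))
    message(sprintf("summit_windows: excluded %d near-edge peak(s)", sum(!inb)))
  data.frame(chrom = chrom[inb], summit = summit[inb],
             start = summit[inb] - h, end = summit[inb] + h + 1L,
             id = id[inb], score = score[inb], stringsAsFactors = FALSE)
}

#' Score peaks with the purified binding estimate
#'
#' For each summit-centred peak window, recomputes the background-model
#' features on the exact window (mappability and GC fractions from the
#' tracks; DNaseI, input-DNA and IgG read counts), predicts the expected
#' background read count, and subtracts it from the raw ChIP count:
#'
#'   B = R - predicted
#'
#' B is the portion of the window's ChIP signal not explained by the
#' non-binding background, the purified binding estimate.  R (raw count)
#' and S (the ingested peak-caller score) are carried as competitors.
#'
#' @param peaks a [summit_windows()] data frame.
#' @param chip_reads deduplicated ChIP [read_set()].
#' @param model a [staged_decompose()] fit trained at window width
#'   `2h + 1`; an error is raised on width mismatch.
#' @param tracks named list of [binary_track()]s for the track predictors
#'   (in training order), e.g. `list(mappability = ..., gc = ...)`.
#' @param control_reads named list of deduplicated [read_set()]s for the
#'   count predictors (in training order), e.g. `dnase`, `idna`, `igg`.
#' @return a `peak_score_table` data frame: peak columns plus `R`,
#'   `predicted`, `B`, `S`.
#' @export
score_peaks <- function(peaks, chip_reads, model, tracks, control_reads) {
  stopifnot(inherits(model, "decomposition"))
  w <- unique(peaks$end - peaks$start)
  if (length(w) != 1L)
    stop("peak windows have inconsistent widths")
  if (!is.null(model$width) && model$width != w)
    stop(sprintf("model window width (%d) does not match peak width (%d)",
                 model$width, w))
  feats <- window_features(peaks, tracks, control_reads)
  if (!identical(colnames(feats), model$predictors))
    feats <- feats[, model$predictors, drop = FALSE]
  pred <- predict_background(model, feats)
  R <- count_in_intervals(chip_reads, peaks)
  out <- peaks
  out$R <- R
  out$predicted <- pred
  out$B <- R - pred
  out$S <- peaks$score
  class(out) <- c("peak_score_table", "data.frame")
  out
}

#' Background-model features on arbitrary intervals
#'
#' Computes, for each interval, the track fractions and control read counts
#' used as predictors by the staged model.  Shared by peak scoring and the
#' TSS expression analysis.
#'
#' @param intervals data frame with `chrom`, `start`, `end` (0-based
#'   half-open; equal widths not required here).
#' @param tracks named list of [binary_track()]s (values become fractions).
#' @param read_sets named list of [read_set()]s (values become counts).
#' @return data frame, one feature column per track then per read set.
#' @export
window_features <- function(intervals, tracks = list(), read_sets = list()) {
  cols <- list()
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    frac <- numeric(nrow(intervals))
    for (ch in unique(intervals$chrom)) {
      idx <- which(intervals$chrom == ch)
      b <- tr$bits[[ch]]
      if (is.null(b)) stop("track '", nm, "' missing chromosome ", ch)
      cs <- c(0, cumsum(b))
      frac[idx] <- (cs[intervals$end[idx] + 1L] - cs[intervals$start[idx] + 1L]) /
        (intervals$end[idx] - intervals$start[idx])
    }
    cols[[nm]] <- frac
  }
  for (nm in names(read_sets))
    cols[[nm]] <- count_in_intervals(read_sets[[nm]], intervals)
  as.data.frame(cols, optional = TRUE)
}

#' Read FIMO motif occurrences
#'
#' Parses the tab-separated occurrence table written by the FIMO motif
#' scanner (header line naming at least sequence/coordinate, start, stop and
#' strand columns; comment lines starting with `#` ignored).  FIMO
#' coordinates are 1-based inclusive; they are converted to 0-based
#' half-open.
#'
#' @param path path to a FIMO TSV file.
#' @return data frame with columns `motif`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `score`, `p_value`.
#' @export
read_fimo_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  nm <- tolower(names(tab))
  pick <- function(cands, what) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop("FIMO header missing column: ", what)
    tab[[i]]
  }
  motif <- pick(c("motif_id", "#pattern name", "pattern name", "motif"),
                "motif_id")
  chrom <- pick(c("sequence_name", "sequence name", "sequence"), "sequence_name")
  start1 <- as.integer(pick("start", "start"))
  stop1 <- as.integer(pick("stop", "stop"))
  strand <- as.character(pick("strand", "strand"))
  score <- as.numeric(pick("score", "score"))
  pval <- as.numeric(pick(c("p-value", "p.value", "pvalue"), "p-value"))
  data.frame(motif = motif, chrom = chrom,
             start = start1 - 1L, end = stop1,
             strand = strand, score = score, p_value = pval,
             stringsAsFactors = FALSE)
}

#' Count motif occurrences fully contained in peak windows
#'
#' An occurrence counts toward a peak when its interval lies entirely inside
#' the peak window; occurrences on either strand count.  M is the per-peak
#' occurrence count.
#'
#' @param occurrences a [read_fimo_tsv()] data frame.
#' @param peaks a [summit_windows()] (or scored) peak data frame.
#' @return integer vector M, one count per peak.
#' @export
count_motifs_in_peaks <- function(occurrences, peaks) {
  M <- integer(nrow(peaks))
  if (!nrow(occurrences)) return(M)
  for (ch in unique(peaks$chrom)) {
    pidx <- which(peaks$chrom == ch)
    occ <- occurrences[occurrences$chrom == ch, , drop = FALSE]
    if (!nrow(occ)) next
    for (j in pidx)
      M[j] <- sum(occ$start >= peaks$start[j] & occ$end <= peaks$end[j])
  }
  M
}

#' Add motif counts to a peak score table
#'
#' @param table a [score_peaks()] result.
#' @param occurrences a [read_fimo_tsv()] data frame.
#' @return the table with columns `M` and `has_motif` added.
#' @export
add_motif_counts <- function(table, occurrences) {
  table$M <- count_motifs_in_peaks(occurrences, table)
  table$has_motif <- table$M > 0L
  table
}

#' Correlate binding estimates with motif counts
#'
#' Pearson correlation (with two-sided p-value) of each binding estimate —
#' B (purified), R (raw count), S (peak-caller score) — against the motif
#' count M, or against motif presence/absence in binary mode.  A stronger
#' true binding signal should co-occur with more motif matches, so the
#' estimate correlating best with M is taken as the best estimator of true
#' binding.
#'
#' @param table a scored peak table with columns `B`, `R`, `S` and `M`.
#' @param binary logical; correlate against `has_motif` (M > 0) instead of
#'   raw counts.
#' @return data frame with one row per estimate: `estimate`, `pcc`,
#'   `p_value`, `defined` (FALSE when either side has zero variance).
#' @export
correlate_estimates <- function(table, binary = FALSE) {
  if (nrow(table) < 3L) stop("need at least 3 peaks")
  target <- if (binary) as.numeric(table$M > 0) else as.numeric(table$M)
  rows <- lapply(c("B", "R", "S"), function(est) {
    x <- as.numeric(table[[est]])
    if (stats::var(x) == 0 || stats::var(target) == 0 ||
        anyNA(x) || anyNA(target))
      return(data.frame(estimate = est, pcc = NA_real_,
                        p_value = NA_real_, defined = FALSE))
    ct <- stats::cor.test(x, target, method = "pearson")
    data.frame(estimate = est, pcc = unname(ct$estimate),
               p_value = ct$p.value, defined = TRUE)
  })
  do.call(rbind, rows)
}

#' Exact upper-tail binomial ratio test
#'
#' Under the null hypothesis that none of `n_methods` competing estimators
#' is better than the others, the number of datasets a given estimator wins
#' is Binomial(trials, 1/n_methods).  The ratio test reports the exact
#' upper-tail probability P(X >= successes).
#'
#' @param successes number of datasets won.
#' @param trials number of datasets compared.
#' @param n_methods number of competing estimators (default 3: B, R, S).
#' @return the exact upper-tail p-value.
#' @export
ratio_test <- function(successes, trials, n_methods = 3L) {
  stopifnot(trials >= successes, successes >= 0, n_methods >= 2)
  stats::pbinom(successes - 1, trials, 1 / n_methods, lower.tail = FALSE)
}

#' Tally the best estimator across datasets
#'
#' For each dataset, the estimator (B, R or S) with the highest Pearson
#' correlation to motif counts wins; ties break toward the earlier of B, R,
#' S.  Datasets where any correlation is undefined are excluded from the
#' tally.  The winning estimator's count is tested against the
#' no-difference null with [ratio_test()].
#'
#' @param comparisons named list of [correlate_estimates()] results, one per
#'   dataset.
#' @return list with `best` (named character vector, winner per dataset),
#'   `tally` (counts per estimator), `n_compared`, `winner`,
#'   `ratio_test_p` (for the winner's count).
#' @export
best_estimator_tally <- function(comparisons) {
  ests <- c("B", "R", "S")
  best <- vapply(comparisons, function(cmp) {
    if (!all(cmp$defined)) return(NA_character_)
    cmp$estimate[which.max(cmp$pcc)]  # which.max = first max: ties to B,R,S order
  }, character(1))
  ok <- !is.na(best)
  tally <- vapply(ests, function(e) sum(best[ok] == e), integer(1))
  n <- sum(ok)
  winner <- ests[which.max(tally)]
  list(best = best, tally = tally, n_compared = n, winner = winner,
       ratio_test_p = if (n > 0) ratio_test(tally[[winner]], n, 3L) else NA_real_)
}

#' Moving-window motif fraction along a peak ranking
#'
#' Ranks peaks from best to worst by a score and slides a window of `w`
#' peaks down the ranking (step 1), recording the fraction of peaks in the
#' window that contain at least one motif.  A good ranking concentrates
#' motif-bearing peaks at the top, giving a curve that starts high and
#' falls.  Ties are broken stably by genomic coordinate.
#'
#' @param table a scored peak table with `has_motif` (see
#'   [add_motif_counts()]).
#' @param score name of the score column to rank by (descending).
#' @param w moving-window size in peaks (default 1000).
#' @return data frame with `rank_start` (1-based index of the window's first
#'   peak) and `fraction`.
#' @export
moving_motif_fraction <- function(table, score = "B", w = 1000L) {
  n <- nrow(table)
  if (n < w)
    stop(sprintf("only %d peaks; choose a moving window smaller than %d", n, w))
  o <- order(-as.numeric(table[[score]]), table$chrom, table$start,
             method = "radix")
  hm <- as.integer(table$has_motif[o])
  cs <- c(0L, cumsum(hm))
  starts <- seq_len(n - w + 1L)
  data.frame(rank_start = starts,
             fraction = (cs[starts + w] - cs[starts]) / w)
}

#' Sextile overlap between two peak rankings
#'
#' Partitions the same peak set into six rank groups under each of two
#' scores (best first; a remainder of r peaks is spread one each into the
#' first r groups) and counts the peaks shared by every pair of groups.
#' Identical rankings give a diagonal matrix.
#'
#' @param table a scored peak table.
#' @param score_a,score_b names of the two score columns.
#' @return 6 x 6 integer matrix; cell (i, j) is the number of peaks in
#'   group i of ranking a and group j of ranking b.
#' @export
sextile_overlap <- function(table, score_a, score_b) {
  n <- nrow(table)
  groups <- function(score) {
    o <- order(-as.numeric(table[[score]]), table$chrom, table$start,
               method = "radix")
    sz <- rep(n %/% 6L, 6L)
    r <- n %% 6L
    if (r > 0) sz[seq_len(r)] <- sz[seq_len(r)] + 1L
    g <- integer(n)
    g[o] <- rep(seq_len(6L), sz)
    g
  }
  ga <- groups(score_a); gb <- groups(score_b)
  m <- matrix(0L, 6L, 6L,
              dimnames = list(paste0("a", 1:6), paste0("b", 1:6)))
  for (i in 1:6) for (j in 1:6) m[i, j] <- sum(ga == i & gb == j)
  m
}

#' Write a scored peak table
#'
#' Tab-separated per-peak table (chrom, start, end, id, R, predicted, B, S,
#' M) plus an optional BED9 with B rescaled into the 0-1000 score range for
#' genome-browser loading.
#'
#' @param table a scored peak table.
#' @param path output path for the TSV.
#' @param bed9 optional output path for the BED9 rendering.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path, bed9 = NULL) {
  cols <- intersect(c("chrom", "start", "end", "id", "R", "predicted",
                      "B", "S", "M"), names(table))
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed9)) {
    b <- table$B
    sc <- if (diff(range(b)) > 0)
      as.integer(round(1000 * (b - min(b)) / diff(range(b)))) else
        rep(0L, length(b))
    df <- data.frame(table$chrom, table$start, table$end, table$id, sc, ".",
                     table$start, table$end, "0,0,0")
    utils::write.table(df, bed9, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
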