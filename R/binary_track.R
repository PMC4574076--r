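#' Per-base binary genome track
#'
#' A `binary_track` holds one bit per base pair per chromosome.  Two
#' semantics are used in the bias model: `mappability` (1 = a read starting
#' here maps uniquely) and `gc` (1 = the base is G or C).  Windowed track
#' values are the exact fraction of 1-bases in the window.
#'
#' @param bits named list of integer (0/1) vectors, one per chromosome.
#' @param label semantics label, e.g. `"mappability"` or `"gc"`.
#' @param sizes optional [chrom_sizes()]; if given, per-chromosome lengths
#'   are checked against it.
#' @return a `binary_track` object.
#' @export
binary_track <- function(bits, label = c("mappability", "gc"), sizes = NULL) {
  label <- match.arg(label)
  stopifnot(is.list(bits), !is.null(names(bits)))
  bits <- lapply(bits, function(b) {
    b <- as.integer(b)
    if (any(b != 0L & b != 1L)) stop("track values must be 0 or 1")
    b
  })
  if (!is.null(sizes)) {
    for (ch in names(bits)) {
      if (!ch %in% names(sizes))
        stop("track chromosome not in sizes: ", ch)
      if (length(bits[[ch]]) != sizes[[ch]])
        stop(sprintf("track length mismatch for %s: %d vs %d",
                     ch, length(bits[[ch]]), sizes[[ch]]))
    }
  }
  structure(list(bits = bits, label = label), class = "binary_track")
}

#' @export
print.binary_track <- function(x, ...) {
  tot <- sum(vapply(x$bits, function(b) sum(as.numeric(b)), numeric(1)))
  len <- sum(vapply(x$bits, length, integer(1)))
  cat(sprintf("binary_track (%s): %d chromosome(s), %.1f%% ones\n",
              x$label, length(x$bits), 100 * tot / max(len, 1)))
  invisible(x)
}

#' Binarized GC-content track from a genome FASTA
#'
#' Each base scores 1 if it is G or C (either case) and 0 otherwise;
#' ambiguity codes, including N, score 0.
#'
#' @param fasta path to a genome FASTA file.
#' @param sizes optional [chrom_sizes()] to validate sequence lengths
#'   against (error names the offending chromosome).
#' @return a [binary_track()] with label `"gc"`.
#' @export
gc_track <- function(fasta, sizes = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bits <- lapply(seq_along(seqs), function(i) {
    as.integer(Biostrings::letterFrequencyInSlidingView(seqs[[i]], 1L, "GC"))
  })
  names(bits) <- names(seqs)
  binary_track(bits, "gc", sizes = sizes)
}

#' Binarized mappability track from bedGraph or wiggle signal
#'
#' Ingests a per-base mappability signal (values in [0, 1]) from a bedGraph
#' or fixed-step wiggle file and thresholds it: a base scores 1 iff its value
#' is `>= threshold`.  Bases not covered by any interval score 0.  The
#' default threshold 1.0 keeps only uniquely mappable bases.
#'
#' @param path path to a bedGraph (`.bedGraph`/`.bg`) or wiggle (`.wig`)
#'   file.
#' @param sizes a [chrom_sizes()] object; defines the chromosomes and
#'   lengths of the output track.
#' @param threshold numeric scalar; bases with value `>= threshold` become 1.
#' @return a [binary_track()] with label `"mappability"`.
#' @export
binarize_mappability <- function(path, sizes, threshold = 1.0) {
  stopifnot(inherits(sizes, "chrom_sizes"))
  fmt <- if (grepl("\\.(bg|bedgraph)$", path, ignore.case = TRUE))
    "bedGraph" else if (grepl("\\.wig$", path, ignore.case = TRUE))
    "wig" else stop("unrecognized mappability format (expect .bedGraph/.bg/.wig): ", path)
  gr <- rtracklayer::import(path, format = fmt)
  bits <- lapply(names(sizes), function(ch) {
    L <- sizes[[ch]]
    val <- rep(NA_real_, L)
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    if (any(sel)) {
      g <- gr[sel]
      st <- GenomicRanges::start(g) - 1L  # to 0-based
      en <- GenomicRanges::end(g)         # half-open end
      if (any(st < 0L) || any(en > L))
        stop("mappability interval outside chromosome bounds on ", ch)
      sc <- as.numeric(g$score)
      for (i in seq_along(st)) {
        span <- (st[i] + 1L):en[i]
        prev <- val[span]
        clash <- !is.na(prev) & prev != sc[i]
        if (any(clash))
          stop("overlapping mappability intervals with conflicting values on ", ch)
        val[span] <- sc[i]
      }
    }
    as.integer(!is.na(val) & val >= threshold)
  })
  names(bits) <- names(sizes)
  binary_track(bits, "mappability", sizes = sizes)
}

#' Write a binary track as bedGraph
#'
#' Runs of equal value are merged into intervals; zero runs are emitted too,
#' so coverage is complete.
#'
#' @param track a [binary_track()].
#' @param path output path (use a `.bedGraph` extension).
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$bits)) {
    b <- track$bits[[ch]]
    r <- rle(b)
    en <- cumsum(r$lengths)
    st <- en - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%d", ch, st, en, r$values), con)
  }
  invisible(path)
}
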