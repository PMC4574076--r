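#' Fixed-width genome window grid
#'
#' Tiles each chromosome into consecutive, non-overlapping, 0-based
#' half-open windows `[i*N, (i+1)*N)` of a fixed odd width N.  The trailing
#' partial window of every chromosome is dropped so that all windows have
#' identical width, and excluded chromosomes (by default chrY, whose read
#' coverage is inconsistent across datasets) contribute no windows.  Odd
#' widths keep every window symmetric about a central base.
#'
#' @param sizes a [chrom_sizes()] object.
#' @param width odd integer window width in bp (>= 3); the multiscale driver
#'   uses widths of the form 2^k + 1.
#' @param exclude character vector of chromosome names to exclude
#'   (default `"chrY"`).
#' @return a `window_grid` object with fields `width`, `chroms`,
#'   `n_windows` (per chromosome), `offsets` (cumulative window offset per
#'   chromosome in the genome-wide concatenation), `excluded`.
#' @export
make_window_grid <- function(sizes, width, exclude = "chrY") {
  stopifnot(inherits(sizes, "chrom_sizes"))
  width <- as.integer(width)
  if (width < 3L || width %% 2L == 0L)
    stop("window width must be an odd integer >= 3")
  keep <- setdiff(names(sizes), exclude)
  n_win <- vapply(keep, function(ch) sizes[[ch]] %/% width, integer(1))
  structure(list(width = width,
                 chroms = keep,
                 n_windows = n_win,
                 offsets = stats::setNames(cumsum(c(0L, unname(n_win)))[seq_along(keep)],
                                           keep),
                 excluded = intersect(exclude, names(sizes))),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: width %d bp, %d windows over %d chromosome(s)",
              x$width, sum(x$n_windows), length(x$chroms)))
  if (length(x$excluded))
    cat(" (excluded: ", paste(x$excluded, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

n_windows <- function(grid) sum(grid$n_windows)

#' Genomic coordinates of every window in a grid
#'
#' @param grid a [make_window_grid()] object.
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), one row per window, in genome-wide concatenation order.
#' @export
window_coords <- function(grid) {
  chrom <- rep(grid$chroms, grid$n_windows)
  idx <- unlist(lapply(unname(grid$n_windows), seq_len), use.names = FALSE) - 1L
  start <- idx * grid$width
  data.frame(chrom = chrom, start = start, end = start + grid$width,
             stringsAsFactors = FALSE)
}

#' Per-window read counts
#'
#' Assigns each read to the window containing its 5' position and counts
#' reads per window.  Reads in the dropped trailing remainder of a
#' chromosome, or on excluded chromosomes, are ignored.  For a deduplicated
#' read set a window of width N can hold at most 2N reads.
#'
#' @param reads a [read_set()]; a warning is issued if not deduplicated.
#' @param grid a [make_window_grid()] object.
#' @return integer vector of length `sum(grid$n_windows)` (class
#'   `window_vector`, kind `"read_count"`).
#' @export
count_reads <- function(reads, grid) {
  stopifnot(inherits(reads, "read_set"), inherits(grid, "window_grid"))
  if (!is_dedup(reads))
    warning("count_reads: read set has not been deduplicated")
  counts <- integer(n_windows(grid))
  for (ch in unique(reads$chrom)) {
    if (!ch %in% grid$chroms) next
    nw <- grid$n_windows[[ch]]
    if (nw == 0L) next
    p <- reads$pos[reads$chrom == ch]
    w <- p %/% grid$width
    w <- w[w < nw]
    if (length(w))
      counts[grid$offsets[[ch]] + seq_len(nw)] <-
        tabulate(w + 1L, nbins = nw)
  }
  window_vector(counts, grid, kind = "read_count")
}

#' Per-window track fraction
#'
#' For each grid window, the exact fraction of base pairs carrying a 1 in
#' the binary track (mappable fraction or GC fraction).
#'
#' @param track a [binary_track()].
#' @param grid a [make_window_grid()] object.
#' @return numeric vector in [0, 1] (class `window_vector`, kind
#'   `"track_fraction"`).
#' @export
track_fraction <- function(track, grid) {
  stopifnot(inherits(track, "binary_track"), inherits(grid, "window_grid"))
  missing <- setdiff(grid$chroms[grid$n_windows > 0], names(track$bits))
  if (length(missing))
    stop("track missing chromosome(s): ", paste(missing, collapse = ", "))
  N <- grid$width
  vals <- numeric(n_windows(grid))
  for (ch in grid$chroms) {
    nw <- grid$n_windows[[ch]]
    if (nw == 0L) next
    b <- track$bits[[ch]][seq_len(nw * N)]
    vals[grid$offsets[[ch]] + seq_len(nw)] <-
      colSums(matrix(b, nrow = N)) / N
  }
  window_vector(vals, grid, kind = "track_fraction")
}

window_vector <- function(values, grid, kind = c("read_count", "track_fraction")) {
  kind <- match.arg(kind)
  structure(values, class = c("window_vector", class(values)),
            kind = kind, width = grid$width)
}

#' Write a window vector as a four-column table
#'
#' Emits tab-separated `chrom start end value`, one row per window.
#'
#' @param values a vector aligned to `grid` (e.g. from [count_reads()]).
#' @param grid the [make_window_grid()] the values are aligned to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_vector <- function(values, grid, path) {
  co <- window_coords(grid)
  stopifnot(length(values) == nrow(co))
  co$value <- as.vector(values)
  utils::write.table(co, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
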