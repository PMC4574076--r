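#' Stranded 5' read positions
#'
#' A `read_set` stores, for each chromosome, the 0-based genomic position of
#' the 5' end of every mapped read together with its strand.  It is the
#' in-memory form of a BED file of mapped short reads (ChIP, DNaseI, input
#' DNA, IgG, CAGE, ...).  Positions, not intervals, are kept: all downstream
#' windowed counting assigns a read to the single window containing its
#' 5' end.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based 5'-end positions.
#' @param strand character vector, "+" or "-".
#' @param dedup_applied logical; whether duplicate (chrom, strand, position)
#'   triples have already been collapsed.
#' @return a `read_set` object: a data frame with columns `chrom`, `pos`,
#'   `strand` and attribute `dedup_applied`.
#' @seealso [read_bed_reads()], [deduplicate()], [count_reads()]
#' @export
read_set <- function(chrom = character(), pos = integer(),
                     strand = character(), dedup_applied = FALSE) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(strand))
  if (length(strand) && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- data.frame(chrom = as.character(chrom),
                   pos = as.integer(pos),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  structure(df, class = c("read_set", "data.frame"),
            dedup_applied = isTRUE(dedup_applied))
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads on %d chromosome(s)%s\n",
              nrow(x), length(unique(x$chrom)),
              if (isTRUE(attr(x, "dedup_applied"))) " (deduplicated)" else ""))
  invisible(x)
}

is_dedup <- function(reads) isTRUE(attr(reads, "dedup_applied"))

#' Read mapped reads from a BED6 file
#'
#' Parses a >=6 column BED file of mapped reads.  The 5' position of each
#' read is the BED start for "+" reads and BED end - 1 for "-" reads
#' (0-based).  Reads on chromosomes absent from `sizes`, and reads whose 5'
#' position falls at or beyond the chromosome end, are dropped and the counts
#' reported via `message()`.
#'
#' @param path path to a BED6 (or wider) file; plain text, tab or space
#'   delimited, no header.
#' @param sizes a [chrom_sizes()] object.
#' @return a [read_set()] with `dedup_applied = FALSE`.
#' @export
read_bed_reads <- function(path, sizes) {
  stopifnot(inherits(sizes, "chrom_sizes"))
  tab <- read_bed_table(path, min_cols = 6L)
  strand <- tab[[6]]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("%s: line %d: invalid strand '%s'", path, bad[1],
                 strand[bad[1]]))
  pos <- ifelse(strand == "+", tab[[2]], tab[[3]] - 1L)
  chrom <- tab[[1]]

  known <- chrom %in% names(sizes)
  n_unknown <- sum(!known)
  if (n_unknown)
    message(sprintf("read_bed_reads: dropped %d read(s) on chromosomes absent from sizes",
                    n_unknown))
  chrom <- chrom[known]; pos <- pos[known]; strand <- strand[known]

  inbounds <- pos >= 0L & pos < unname(sizes[chrom])
  n_oob <- sum(!inbounds)
  if (n_oob)
    message(sprintf("read_bed_reads: rejected %d read(s) with 5' position outside chromosome bounds",
                    n_oob))
  read_set(chrom[inbounds], pos[inbounds], strand[inbounds],
           dedup_applied = FALSE)
}

# Shared tabular BED reader: validates column count and numeric coordinates,
# reporting 1-based line numbers on failure.
read_bed_table <- function(path, min_cols) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) stop(path, ": no records")
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < min_cols))
    stop(sprintf("%s: line %d: expected >= %d columns, found %d",
                 path, which(nf < min_cols)[1], min_cols,
                 nf[which(nf < min_cols)[1]]))
  get_col <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end < start)
  if (length(bad))
    stop(sprintf("%s: line %d: malformed coordinates", path, bad[1]))
  out <- list(get_col(1), start, end)
  for (i in seq_len(max(nf) - 3L) + 3L)
    out[[i]] <- vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_,
                       character(1))
  out
}

#' Collapse duplicate reads
#'
#' Multiple reads mapping to the same position of the same strand of the same
#' chromosome are collapsed into a single representative read.  After
#' collapsing, a genomic window of size N can hold at most 2N reads (one per
#' strand per position).
#'
#' @param reads a [read_set()].
#' @return a [read_set()] with unique (chrom, strand, pos) triples and
#'   `dedup_applied = TRUE`; rows sorted by chromosome, position, strand so
#'   the result is order-independent.
#' @export
deduplicate <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  keep <- !duplicated(paste(reads$chrom, reads$strand, reads$pos))
  out <- reads[keep, , drop = FALSE]
  o <- order(out$chrom, out$pos, out$strand, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  read_set(out$chrom, out$pos, out$strand, dedup_applied = TRUE)
}

#' Write a read_set as BED6
#'
#' Each read becomes a 1-bp interval at its 5' position (name ".", score 0).
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_reads <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  df <- data.frame(reads$chrom, reads$pos, reads$pos + 1L, ".", 0L,
                   reads$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count reads falling in arbitrary intervals
#'
#' Counts, for each half-open 0-based interval `[start, end)`, the number of
#' read 5' positions it contains.  Intervals may overlap each other; each is
#' counted independently, so one read can contribute to several intervals.
#'
#' @param reads a [read_set()].
#' @param intervals data frame with columns `chrom`, `start`, `end`.
#' @return integer vector of per-interval counts.
#' @export
count_in_intervals <- function(reads, intervals) {
  stopifnot(inherits(reads, "read_set"))
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    stop("intervals must satisfy start < end")
  counts <- integer(nrow(intervals))
  pos_by_chrom <- split(reads$pos, reads$chrom)
  for (ch in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == ch)
    p <- pos_by_chrom[[ch]]
    if (is.null(p) || !length(p)) next
    p <- sort(p)
    # reads with pos in [start, end) = #(pos < end) - #(pos < start)
    n_lt <- function(x) findInterval(x - 0.5, p)
    counts[idx] <- n_lt(intervals$end[idx]) - n_lt(intervals$start[idx])
  }
  counts
}
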