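#' Chromosome sizes
#'
#' A named integer vector mapping chromosome names to lengths in base pairs.
#' This is the coordinate frame every other object in the package is
#' validated against.
#'
#' @param x named numeric vector of chromosome lengths (bp), or a two-column
#'   data frame (name, length).
#' @return a `chrom_sizes` object (named integer vector).
#' @examples
#' chrom_sizes(c(chr1 = 1e6, chr2 = 5e5))
#' @export
chrom_sizes <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    v <- as.numeric(x[[2]])
    names(v) <- as.character(x[[1]])
    x <- v
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("chromosome sizes must be named")
  if (anyDuplicated(names(x)))
    stop("duplicate chromosome names: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(!is.finite(x)) || any(x < 1))
    stop("chromosome lengths must be positive integers")
  out <- as.integer(round(x))
  names(out) <- names(x)
  structure(out, class = "chrom_sizes")
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a whitespace-delimited file with columns
#'   chromosome name and length.
#' @return a [chrom_sizes()] object.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  chrom_sizes(tab)
}

#' @export
print.chrom_sizes <- function(x, ...) {
  cat("chrom_sizes:", length(x), "chromosomes,",
      format(sum(as.numeric(x)), big.mark = ","), "bp total\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Write chromosome sizes to a chrom.sizes file
#' @param sizes a [chrom_sizes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(sizes)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
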