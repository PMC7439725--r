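# Plain-text interchange: TSV tables with headers, BED intervals, FASTA
# sequences, JSON reports.

#' Write a data.frame as TSV
#' @param x Data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#' @param path Input path.
#' @return Data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write intervals as BED (0-based half-open)
#' @param x Data.frame with `chromosome`, `start`, `end` and optional
#'   name column as fourth.
#' @param path Output path.
#' @param name_col Optional column to use as the BED name field.
#' @export
write_bed <- function(x, path, name_col = NULL) {
  bed <- x[, c("chromosome", "start", "end")]
  if (!is.null(name_col)) bed$name <- x[[name_col]]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#' @param path Input path.
#' @return Data.frame `chromosome`, `start`, `end` (+ `name` if present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chromosome", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' Write named sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read FASTA sequences
#' @param path Input path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
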