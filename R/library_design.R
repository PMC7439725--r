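# Library design: tile coordinates, oligo assembly, barcode assignment.
# All genomic coordinates are 0-based half-open (BED convention).

TILE_LENGTH <- 144L
BARCODE_LENGTH <- 11L
ADAPTER_LENGTH <- 45L
OLIGO_LENGTH <- 200L

#' Design the two 144-bp tiles for a TSS
#'
#' Every TSS is assayed with two tiles: tile 1 spans 114 bases upstream
#' through 30 bases downstream of the TSS (so it contains the TSS base);
#' tile 2 spans 228 through 84 bases upstream (so it does not). Offsets are
#' strand-aware: on the minus strand "upstream" points to higher genomic
#' coordinates and the intervals are mirrored.
#'
#' @param position 0-based TSS coordinate.
#' @param strand `"+"` or `"-"`.
#' @param chromosome Chromosome identifier carried through to the output.
#' @return A data.frame with one row per tile: `chromosome`, `start`,
#'   `end` (0-based half-open), `tile` (`"tile1"`/`"tile2"`), `strand`.
#' @export
design_tiles <- function(position, strand = "+", chromosome = "chr1") {
  stopifnot(length(position) == 1, length(strand) == 1)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  position <- as.integer(position)
  if (strand == "+") {
    starts <- c(position - 114L, position - 228L)
    ends   <- c(position + 30L,  position - 84L)
  } else {
    # mirror: upstream is rightward; tile1 still contains the TSS base
    starts <- c(position - 29L, position + 85L)
    ends   <- c(position + 115L, position + 229L)
  }
  if (any(starts < 0)) {
    stop("out-of-bounds error: tile coordinates below 0", call. = FALSE)
  }
  out <- data.frame(
    chromosome = chromosome,
    start = starts,
    end = ends,
    tile = c("tile1", "tile2"),
    strand = strand,
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$end - out$start == TILE_LENGTH))
  out
}

#' Assemble a 200-bp MPRA oligonucleotide
#'
#' Concatenates a 144-base regulatory sequence, an 11-base barcode and a
#' 45-base cloning adapter into the fixed 200-base oligo layout.
#'
#' @param regulatory_sequence 144-base string.
#' @param barcode 11-base string.
#' @param adapter 45-base string.
#' @return A list with components `regulatory_sequence`, `barcode`,
#'   `adapter`, `full_sequence` (200 bases).
#' @export
assemble_oligo <- function(regulatory_sequence, barcode, adapter) {
  if (nchar(regulatory_sequence) != TILE_LENGTH) {
    stop("assembly error: regulatory sequence must be ", TILE_LENGTH, " bases",
         call. = FALSE)
  }
  if (nchar(barcode) != BARCODE_LENGTH) {
    stop("assembly error: barcode must be ", BARCODE_LENGTH, " bases",
         call. = FALSE)
  }
  if (nchar(adapter) != ADAPTER_LENGTH) {
    stop("assembly error: adapter must be ", ADAPTER_LENGTH, " bases",
         call. = FALSE)
  }
  full <- paste0(regulatory_sequence, barcode, adapter)
  stopifnot(nchar(full) == OLIGO_LENGTH)
  list(regulatory_sequence = regulatory_sequence,
       barcode = barcode,
       adapter = adapter,
       full_sequence = full)
}

#' Generate unique random barcodes
#'
#' @param n Number of barcodes.
#' @param length Barcode length in bases.
#' @return Character vector of `n` distinct nucleotide strings.
#' @export
generate_barcodes <- function(n, length = BARCODE_LENGTH) {
  seen <- character(0)
  # 4^11 >> any library size; collision loop terminates fast
  while (length(seen) < n) {
    need <- n - length(seen)
    fresh <- vapply(seq_len(need + ceiling(need * 0.05) + 8L), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
    }, character(1))
    seen <- unique(c(seen, fresh))
  }
  seen[seq_len(n)]
}

#' Assign barcodes to catalog elements by class
#'
#' TSS tiles receive 13 barcodes, random negative controls 3, and
#' positive-control tiles 60; no barcode is reused anywhere in the
#' library.
#'
#' @param catalog Data.frame with columns `element_id` and `class`
#'   (values in `names(barcodes_per_class)`).
#' @param barcodes_per_class Named integer vector, e.g.
#'   `c(TSS = 13, negative = 3, positive = 60)`.
#' @param barcodes Optional pool of unique barcode strings; generated if
#'   omitted.
#' @return Data.frame `barcode_id`, `element_id`.
#' @export
assign_barcodes <- function(catalog,
                            barcodes_per_class = c(TSS = 13, negative = 3,
                                                   positive = 60),
                            barcodes = NULL) {
  stopifnot(all(c("element_id", "class") %in% names(catalog)))
  if (!all(catalog$class %in% names(barcodes_per_class))) {
    stop("unknown element class in catalog", call. = FALSE)
  }
  need <- unname(barcodes_per_class[catalog$class])
  total <- sum(need)
  if (is.null(barcodes)) {
    barcodes <- generate_barcodes(total)
  }
  if (anyDuplicated(barcodes)) {
    stop("uniqueness error: duplicate barcodes in pool", call. = FALSE)
  }
  if (length(barcodes) < total) {
    stop("barcode pool exhausted: need ", total, ", have ", length(barcodes),
         call. = FALSE)
  }
  data.frame(
    barcode_id = barcodes[seq_len(total)],
    element_id = rep(catalog$element_id, times = need),
    stringsAsFactors = FALSE
  )
}
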