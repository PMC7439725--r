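# Conservation calls: a reciprocally-mapped TSS is conserved when the
# CAGE coverage around its mapped position in the other species reaches
# the read threshold.

#' Classify a mapped TSS as conserved or non-conserved
#'
#' A TSS is conserved when the maximum CAGE coverage in the closed
#' window of `window` bases either side of the mapped position (101
#' positions at the default) is at least `min_reads`. The coverage track
#' is sparse: positions absent from it count as 0, but the window must
#' lie inside the track's extent.
#'
#' @param position Mapped 0-based TSS position in the other species.
#' @param coverage Data.frame `position`, `value` (per-position maximum
#'   CAGE counts); its position range defines the track extent.
#' @param window Half-window in bases (default 50).
#' @param min_reads Read threshold (default 10).
#' @return `"conserved"` or `"non_conserved"`.
#' @export
classify_conservation <- function(position, coverage, window = 50,
                                  min_reads = 10) {
  lo <- position - window
  hi <- position + window
  if (lo < min(coverage$position) || hi > max(coverage$position)) {
    stop("window [", lo, ", ", hi, "] outside coverage track", call. = FALSE)
  }
  in_win <- coverage$position >= lo & coverage$position <= hi
  peak <- if (any(in_win)) max(coverage$value[in_win]) else 0
  if (peak >= min_reads) "conserved" else "non_conserved"
}

#' Conservation call for an enhancer (two TSSs)
#'
#' Enhancers are transcribed bidirectionally and carry two TSSs; the
#' enhancer is conserved when either TSS window passes the coverage
#' threshold.
#'
#' @param position_a,position_b The two mapped TSS positions.
#' @inheritParams classify_conservation
#' @return `"conserved"` or `"non_conserved"`.
#' @export
classify_enhancer_conservation <- function(position_a, position_b, coverage,
                                           window = 50, min_reads = 10) {
  calls <- c(classify_conservation(position_a, coverage, window, min_reads),
             classify_conservation(position_b, coverage, window, min_reads))
  if (any(calls == "conserved")) "conserved" else "non_conserved"
}

#' Conservation calls for a mapping table
#'
#' @param mapping Data.frame with `id`, `mapped_position`,
#'   `reciprocal_ok` (logical) and optionally `mapped_position_b` for
#'   enhancers (NA for single-TSS elements).
#' @param coverage Coverage track as in [classify_conservation()].
#' @inheritParams classify_conservation
#' @return `mapping` with a `conservation` column; rows failing the
#'   reciprocal-mapping requirement get `NA` (conservation is evaluated
#'   only for sequence orthologs).
#' @export
classify_conservation_table <- function(mapping, coverage, window = 50,
                                        min_reads = 10) {
  mapping$conservation <- NA_character_
  for (i in seq_len(nrow(mapping))) {
    if (!isTRUE(mapping$reciprocal_ok[i])) next
    b <- if ("mapped_position_b" %in% names(mapping)) {
      mapping$mapped_position_b[i]
    } else NA
    mapping$conservation[i] <- if (!is.na(b)) {
      classify_enhancer_conservation(mapping$mapped_position[i], b,
                                     coverage, window, min_reads)
    } else {
      classify_conservation(mapping$mapped_position[i], coverage,
                            window, min_reads)
    }
  }
  mapping
}
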