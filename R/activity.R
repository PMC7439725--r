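# Activity quantification: barcode log-ratios, per-(sequence, environment)
# activity estimates, active/inactive calls against negative controls,
# and representative-tile selection.

#' Filter elements by DNA representation
#'
#' An element is kept when at least 50% of its assigned barcodes are
#' represented at >= `min_count` counts in the pooled input DNA library;
#' the boundary case of exactly 50% passes. Barcodes absent from the DNA
#' table count as zero.
#'
#' @param dna Data.frame `barcode_id`, `count` (one pooled DNA sample).
#' @param barcode_map Data.frame `barcode_id`, `element_id`.
#' @param min_count Minimum DNA count for a barcode to be represented.
#' @param min_fraction Minimum fraction of represented barcodes.
#' @return Character vector of kept element ids; the full per-element
#'   accounting is attached as attribute `"accounting"`.
#' @export
filter_by_dna_representation <- function(dna, barcode_map,
                                         min_count = 10,
                                         min_fraction = 0.5) {
  counts <- stats::setNames(dna$count, dna$barcode_id)
  bc_count <- counts[barcode_map$barcode_id]
  bc_count[is.na(bc_count)] <- 0
  pass <- bc_count >= min_count
  acc <- stats::aggregate(
    cbind(n_pass = pass, n_total = rep(1L, length(pass))),
    by = list(element_id = barcode_map$element_id), FUN = sum)
  acc$kept <- acc$n_pass >= min_fraction * acc$n_total
  kept <- acc$element_id[acc$kept]
  attr(kept, "accounting") <- acc
  kept
}

#' Compute barcode-level log activity ratios
#'
#' Each sample (the pooled DNA library and every RNA environment x
#' replicate) is scaled to counts per million; the barcode log-ratio is
#' `log2((rna_cpm + 1) / (dna_cpm + 1))`.
#'
#' @param dna Data.frame `barcode_id`, `element_id`, `count`.
#' @param rna Data.frame `barcode_id`, `element_id`, `environment`,
#'   `replicate`, `count`.
#' @param elements Optional element ids to restrict to (typically the
#'   DNA-representation filter output).
#' @param pseudocount Added to both CPM values before the ratio.
#' @return Data.frame of barcode observations with `log_ratio`.
#' @export
compute_log_ratios <- function(dna, rna, elements = NULL, pseudocount = 1) {
  if (sum(dna$count) <= 0) stop("zero DNA library size", call. = FALSE)
  dna_cpm <- stats::setNames(dna$count / sum(dna$count) * 1e6, dna$barcode_id)
  out <- do.call(rbind, lapply(split(rna, list(rna$environment, rna$replicate),
                                     drop = TRUE), function(s) {
    tot <- sum(s$count)
    if (tot <= 0) stop("zero RNA library size", call. = FALSE)
    s$rna_cpm <- s$count / tot * 1e6
    s$dna_cpm <- unname(dna_cpm[s$barcode_id])
    s$dna_cpm[is.na(s$dna_cpm)] <- 0
    s
  }))
  rownames(out) <- NULL
  out$log_ratio <- log2((out$rna_cpm + pseudocount) / (out$dna_cpm + pseudocount))
  names(out)[names(out) == "count"] <- "rna_count"
  if (!is.null(elements)) out <- out[out$element_id %in% elements, ]
  out
}

#' Estimate per-(sequence, environment) activity
#'
#' The activity estimate is the mean over replicates of the median over
#' barcodes of the barcode log-ratios: robust to single-barcode outliers,
#' and directly comparable to a planted log2 activity on simulated data.
#'
#' @param observations Output of [compute_log_ratios()].
#' @return Data.frame `element_id`, `environment`, `alpha`, `n_barcodes`.
#' @export
estimate_activity <- function(observations) {
  if (nrow(observations) == 0) stop("no observations", call. = FALSE)
  per_rep <- stats::aggregate(
    log_ratio ~ element_id + environment + replicate,
    data = observations, FUN = stats::median)
  est <- stats::aggregate(log_ratio ~ element_id + environment,
                          data = per_rep, FUN = mean)
  names(est)[names(est) == "log_ratio"] <- "alpha"
  nbc <- stats::aggregate(barcode_id ~ element_id + environment,
                          data = observations,
                          FUN = function(x) length(unique(x)))
  names(nbc)[names(nbc) == "barcode_id"] <- "n_barcodes"
  merge(est, nbc, by = c("element_id", "environment"))
}

#' Call active elements against the negative-control null
#'
#' Random negative-control sequences define the inactive null. The
#' one-sided empirical p-value for an element is
#' `(1 + #{controls with alpha >= observed}) / (1 + #controls)`, computed
#' per environment; Benjamini-Hochberg q-values are computed over all
#' elements in an environment, and an element is called active when
#' `q < q_threshold`.
#'
#' @param activity Output of [estimate_activity()].
#' @param control_ids Element ids of the negative controls.
#' @param q_threshold Activity significance threshold (default 0.05).
#' @param min_controls Minimum negative-control estimates required per
#'   environment.
#' @return `activity` with columns `p_active`, `q_active`, `active`.
#' @export
test_active <- function(activity, control_ids, q_threshold = 0.05,
                        min_controls = 20) {
  out <- do.call(rbind, lapply(split(activity, activity$environment),
                               function(a) {
    ctrl <- a$alpha[a$element_id %in% control_ids]
    if (length(ctrl) < min_controls) {
      stop("too few negative controls (", length(ctrl), " < ", min_controls,
           ")", call. = FALSE)
    }
    a$p_active <- vapply(a$alpha, function(x) {
      (1 + sum(ctrl >= x)) / (1 + length(ctrl))
    }, numeric(1))
    a$q_active <- stats::p.adjust(a$p_active, method = "BH")
    a
  }))
  rownames(out) <- NULL
  out$active <- out$q_active < q_threshold
  out
}

#' Choose each pair's representative tile
#'
#' The TSS-overlapping tile (tile 1) represents a pair unless the upstream
#' tile (tile 2) has strictly higher activity in both native contexts
#' (human sequence in hESCs and mouse sequence in mESCs).
#'
#' @param human_tile1,human_tile2 Activity of the human sequence's two
#'   tiles in hESCs.
#' @param mouse_tile1,mouse_tile2 Activity of the mouse sequence's two
#'   tiles in mESCs.
#' @return `"tile1"` or `"tile2"`. Missing estimates fall back to tile 1
#'   with a warning.
#' @export
select_representative_tile <- function(human_tile1, human_tile2,
                                       mouse_tile1, mouse_tile2) {
  vals <- c(human_tile1, human_tile2, mouse_tile1, mouse_tile2)
  if (any(is.na(vals))) {
    warning("missing tile estimate; defaulting to tile1")
    return("tile1")
  }
  if (human_tile2 > human_tile1 && mouse_tile2 > mouse_tile1) "tile2" else "tile1"
}
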