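# Enhancer redundancy: TAD co-residence counting, expression
# correlations, Otsu thresholding of the correlation histogram, and the
# down-sampled redundancy-vs-compensation comparison.

#' Count TAD-co-resident enhancers per element
#'
#' An enhancer counts for an element when the two share at least one TAD
#' from either source (e.g. TADs called in hESCs or in mESCs). Intervals
#' are 0-based half-open.
#'
#' @param elements Data.frame `id`, `chromosome`, `position`.
#' @param enhancers Data.frame `id`, `chromosome`, `position`.
#' @param tads Data.frame `chromosome`, `start`, `end` (and optionally
#'   `source`).
#' @return List with `counts` (data.frame `id`, `n_tad_enhancers`,
#'   `in_tad`) and `neighbors` (named list of enhancer ids per element).
#' @export
assign_tad_and_count <- function(elements, enhancers, tads) {
  if (any(tads$start >= tads$end)) stop("invalid TAD interval", call. = FALSE)
  tad_gr <- GenomicRanges::GRanges(
    tads$chromosome, IRanges::IRanges(tads$start + 1, tads$end))
  el_gr <- GenomicRanges::GRanges(
    elements$chromosome, IRanges::IRanges(elements$position + 1,
                                          elements$position + 1))
  en_gr <- GenomicRanges::GRanges(
    enhancers$chromosome, IRanges::IRanges(enhancers$position + 1,
                                           enhancers$position + 1))
  # seqlevel mismatches (an element on a chromosome with no TADs) are a
  # legitimate no-overlap case, not a user error
  el_ov <- suppressWarnings(GenomicRanges::findOverlaps(el_gr, tad_gr))
  en_ov <- suppressWarnings(GenomicRanges::findOverlaps(en_gr, tad_gr))
  el_tads <- split(S4Vectors::subjectHits(el_ov), S4Vectors::queryHits(el_ov))
  en_by_tad <- split(S4Vectors::queryHits(en_ov), S4Vectors::subjectHits(en_ov))

  neighbors <- lapply(seq_len(nrow(elements)), function(i) {
    t_ids <- el_tads[[as.character(i)]]
    if (is.null(t_ids)) return(character(0))
    enh_idx <- unique(unlist(en_by_tad[as.character(t_ids)]))
    ids <- enhancers$id[enh_idx]
    setdiff(ids, elements$id[i])  # never count the element's own record
  })
  names(neighbors) <- elements$id
  in_tad <- vapply(seq_len(nrow(elements)),
                   function(i) !is.null(el_tads[[as.character(i)]]),
                   logical(1))
  if (any(!in_tad)) {
    message(sum(!in_tad), " element(s) fall in no TAD; counted as 0")
  }
  counts <- data.frame(id = elements$id,
                       n_tad_enhancers = lengths(neighbors),
                       in_tad = in_tad, stringsAsFactors = FALSE)
  list(counts = counts, neighbors = neighbors)
}

#' Correlate an element's expression with its TAD enhancers
#'
#' Pearson correlation of log(x + 1)-transformed expression between the
#' focal row and each enhancer row. Rows that are constant after the
#' transform have undefined correlation and are dropped with a message.
#'
#' @param expression Numeric matrix, rows named by element/enhancer ids.
#' @param focal_id Row name of the focal element.
#' @param enhancer_ids Row names of its TAD enhancers.
#' @return Named numeric vector of correlations.
#' @export
correlate_expression <- function(expression, focal_id, enhancer_ids) {
  if (!focal_id %in% rownames(expression)) {
    stop("focal element not in expression matrix", call. = FALSE)
  }
  enhancer_ids <- intersect(enhancer_ids, rownames(expression))
  if (ncol(expression) < 3) stop("need >= 3 samples", call. = FALSE)
  f <- log(expression[focal_id, ] + 1)
  if (stats::sd(f) == 0) {
    message("focal element ", focal_id, " has constant expression")
    return(stats::setNames(numeric(0), character(0)))
  }
  r <- vapply(enhancer_ids, function(e) {
    x <- log(expression[e, ] + 1)
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(f, x)
  }, numeric(1))
  dropped <- sum(is.na(r))
  if (dropped > 0) message(dropped, " constant enhancer row(s) dropped")
  r[!is.na(r)]
}

#' Otsu threshold of a correlation histogram
#'
#' Correlations are clipped to `[0, 1]` (negative values to 0) and
#' binned into 100 equal bins; the threshold is the internal bin edge
#' maximising the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`, with ties broken toward the lowest edge.
#' Class means use bin centres.
#'
#' @param correlations Numeric vector.
#' @param n_bins Number of histogram bins over `[0, 1]`.
#' @return The threshold (a bin edge). When all values are identical the
#'   common value is returned with attribute `degenerate = TRUE`.
#' @export
otsu_threshold <- function(correlations, n_bins = 100) {
  x <- correlations[!is.na(correlations)]
  if (length(x) == 0) stop("no correlations", call. = FALSE)
  x <- pmin(pmax(x, 0), 1)
  if (length(unique(x)) < 2) {
    out <- x[1]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  bins <- pmin(floor(x * n_bins) + 1L, n_bins)
  counts <- tabulate(bins, nbins = n_bins)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  n <- length(x)
  best_var <- -Inf
  best_edge <- NA_real_
  for (k in seq_len(n_bins - 1)) {  # internal edges k/n_bins
    n0 <- sum(counts[1:k])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / n; w1 <- n1 / n
    mu0 <- sum(counts[1:k] * centers[1:k]) / n0
    mu1 <- sum(counts[(k + 1):n_bins] * centers[(k + 1):n_bins]) / n1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_var + 1e-15) {
      best_var <- v
      best_edge <- k / n_bins
    }
  }
  best_edge
}

#' Count redundant enhancers above the Otsu cutoff
#'
#' @param correlations Numeric vector of enhancer correlations.
#' @param threshold The Otsu cutoff.
#' @return Number of correlations strictly above the threshold.
#' @export
count_redundant <- function(correlations, threshold) {
  sum(correlations > threshold, na.rm = TRUE)
}

#' Per-element redundancy scores
#'
#' Combines TAD counting, expression correlation, per-element Otsu
#' thresholding and redundant-enhancer counting.
#'
#' @param elements,enhancers,tads As in [assign_tad_and_count()].
#' @param expression Expression matrix (rows named by ids).
#' @param min_enhancers Elements with fewer TAD enhancers than this get
#'   `NA` threshold and 0 redundant.
#' @return Data.frame `id`, `n_tad_enhancers`, `otsu_threshold`,
#'   `n_redundant`.
#' @export
redundancy_scores <- function(elements, enhancers, tads, expression,
                              min_enhancers = 2) {
  tad <- assign_tad_and_count(elements, enhancers, tads)
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    id <- elements$id[i]
    nb <- tad$neighbors[[id]]
    if (length(nb) < min_enhancers) {
      return(data.frame(id = id, n_tad_enhancers = length(nb),
                        otsu_threshold = NA_real_, n_redundant = 0L,
                        stringsAsFactors = FALSE))
    }
    r <- correlate_expression(expression, id, nb)
    if (length(r) < min_enhancers) {
      return(data.frame(id = id, n_tad_enhancers = length(nb),
                        otsu_threshold = NA_real_, n_redundant = 0L,
                        stringsAsFactors = FALSE))
    }
    thr <- otsu_threshold(r)
    data.frame(id = id, n_tad_enhancers = length(nb),
               otsu_threshold = as.numeric(thr),
               n_redundant = count_redundant(r, thr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Redundancy-vs-compensation comparison under TAD de-duplication
#'
#' Elements sharing a TAD are de-duplicated by keeping one per TAD
#' uniformly at random; the comparison of redundant-enhancer counts
#' between directional and compensatory pairs (two-sided Mann-Whitney)
#' is repeated over resamples and the fraction of resamples preserving
#' the full-data effect direction is reported.
#'
#' @param scores Data.frame from [redundancy_scores()] with added
#'   `class` (`directional`/`compensatory`/other) and `tad_id` columns.
#' @param n_resamples Number of de-duplicated resamples.
#' @param seed Integer seed.
#' @return List `direction` (sign of median difference, directional
#'   minus compensatory, on the full data), `fraction_preserved`,
#'   `n_resamples_used`, `p_full` (full-data test).
#' @export
dedupe_downsample <- function(scores, n_resamples = 20, seed = 1L) {
  set.seed(seed)
  both <- scores[scores$class %in% c("directional", "compensatory"), ]
  if (length(unique(both$class)) < 2) {
    stop("need both directional and compensatory elements", call. = FALSE)
  }
  med_diff <- function(df) {
    stats::median(df$n_redundant[df$class == "directional"]) -
      stats::median(df$n_redundant[df$class == "compensatory"])
  }
  full_dir <- sign(med_diff(both))
  wt <- stats::wilcox.test(n_redundant ~ class,
                           data = both[both$class %in%
                                         c("compensatory", "directional"), ],
                           exact = FALSE)
  kept_dirs <- vapply(seq_len(n_resamples), function(i) {
    keep <- unlist(lapply(split(seq_len(nrow(scores)), scores$tad_id),
                          function(idx) idx[sample.int(length(idx), 1)]))
    sub <- scores[keep, ]
    sub <- sub[sub$class %in% c("directional", "compensatory"), ]
    if (length(unique(sub$class)) < 2) return(NA_real_)
    sign(med_diff(sub))
  }, numeric(1))
  used <- !is.na(kept_dirs)
  list(direction = full_dir,
       fraction_preserved = mean(kept_dirs[used] == full_dir),
       n_resamples_used = sum(used),
       p_full = wt$p.value)
}
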