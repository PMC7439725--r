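# Motif association models: sequence composition covariates, the three
# nested linear-model families (activity ~ motif presence, |cis| ~ motif
# disruption, trans ~ motif presence), shared-motif comparison, biotype
# enrichment, and the TF differential-expression direction-agreement join.

#' GC and CpG composition of a sequence
#'
#' `gc_content` is the fraction of G or C bases among A/C/G/T symbols;
#' `cpg_rate` is the number of CG dinucleotides divided by (length - 1).
#' Case-insensitive; non-ACGT symbols are removed before both
#' computations.
#'
#' @param sequence Nucleotide string.
#' @return List `gc_content`, `cpg_rate`.
#' @export
sequence_composition <- function(sequence) {
  if (length(sequence) != 1 || is.na(sequence) || nchar(sequence) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  chars <- chars[chars %in% DNA_BASES]
  if (length(chars) == 0) stop("sequence has no ACGT symbols", call. = FALSE)
  gc <- mean(chars %in% c("G", "C"))
  cpg <- if (length(chars) < 2) 0 else {
    sum(chars[-length(chars)] == "C" & chars[-1] == "G") / (length(chars) - 1)
  }
  list(gc_content = gc, cpg_rate = cpg)
}

#' Composition table for a set of sequences
#'
#' @param sequences Named character vector.
#' @return Data.frame `element_id`, `gc_content`, `cpg_rate`.
#' @export
composition_table <- function(sequences) {
  comp <- lapply(sequences, sequence_composition)
  data.frame(element_id = names(sequences),
             gc_content = vapply(comp, `[[`, numeric(1), "gc_content"),
             cpg_rate = vapply(comp, `[[`, numeric(1), "cpg_rate"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Nested-OLS likelihood-ratio machinery shared by the three families:
# full = y ~ covariates + term, reduced = y ~ covariates.
lrt_nested <- function(y, covariates, term) {
  keep <- stats::complete.cases(cbind(y, covariates, term))
  y <- y[keep]
  covariates <- covariates[keep, , drop = FALSE]
  term <- term[keep]
  if (length(unique(term)) < 2) return(NULL)  # constant term: unidentifiable
  df_full <- data.frame(y = y, covariates, term = as.numeric(term))
  full <- stats::lm(y ~ ., data = df_full)
  reduced <- stats::lm(y ~ ., data = df_full[, -ncol(df_full), drop = FALSE])
  stat <- 2 * (as.numeric(stats::logLik(full)) -
               as.numeric(stats::logLik(reduced)))
  list(beta = unname(stats::coef(full)["term"]),
       p = stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE),
       variance_explained = summary(full)$r.squared -
         summary(reduced)$r.squared,
       n = length(y))
}

#' Motif-activity models
#'
#' For each motif, fits
#' `mean(activity) ~ gc_content + cpg_rate + motif_present` and compares
#' it with the reduced model without the presence indicator by a
#' likelihood-ratio test. Motifs are classed activator (positive
#' coefficient) or repressor; q-values are Benjamini-Hochberg across
#' motifs. The informative set holds motifs with `q < q_threshold` whose
#' transcription factor is expressed in both environments (when an
#' expression table is supplied).
#'
#' @param presence Logical matrix elements x motifs.
#' @param mean_activity Numeric vector named by element (mean of the
#'   element's activities over the environments where measured).
#' @param composition Data.frame from [composition_table()].
#' @param tf_table Optional data.frame `motif_id`, `tf`, `expr_hESC`,
#'   `expr_mESC` used for the informative-motif filter.
#' @param min_group Minimum elements with and without the motif.
#' @param q_threshold FDR threshold for the informative set.
#' @return Data.frame per motif: `motif_id`, `beta`, `p`, `q`,
#'   `variance_explained`, `class`, `n`, `informative`.
#' @export
motif_activity_models <- function(presence, mean_activity, composition,
                                  tf_table = NULL, min_group = 20,
                                  q_threshold = 0.05) {
  ids <- intersect(rownames(presence), names(mean_activity))
  comp <- composition[match(ids, composition$element_id), ]
  covs <- data.frame(gc_content = comp$gc_content, cpg_rate = comp$cpg_rate)
  y <- mean_activity[ids]
  rows <- lapply(colnames(presence), function(m) {
    ind <- presence[ids, m]
    if (sum(ind) < min_group || sum(!ind) < min_group) return(NULL)
    r <- lrt_nested(y, covs, ind)
    if (is.null(r)) return(NULL)
    data.frame(motif_id = m, beta = r$beta, p = r$p,
               variance_explained = r$variance_explained, n = r$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no motif had enough elements in both groups",
                         call. = FALSE)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$class <- ifelse(res$beta > 0, "activator", "repressor")
  res$informative <- res$q < q_threshold
  if (!is.null(tf_table)) {
    expressed <- tf_table$motif_id[tf_table$expr_hESC > 0 &
                                     tf_table$expr_mESC > 0]
    res$informative <- res$informative & res$motif_id %in% expressed
  }
  res
}

#' Per-pair motif indicators
#'
#' @param presence Logical matrix elements x motifs.
#' @param pairs Data.frame with `pair_id` and member element ids
#'   `human_id`, `mouse_id`.
#' @return List of logical matrices pairs x motifs: `maintained`,
#'   `disrupted_in_human` (present in mouse only), `disrupted_in_mouse`
#'   (present in human only), `disrupted` (either).
#' @export
pair_motif_indicators <- function(presence, pairs) {
  ph <- presence[pairs$human_id, , drop = FALSE]
  pm <- presence[pairs$mouse_id, , drop = FALSE]
  rownames(ph) <- rownames(pm) <- pairs$pair_id
  list(maintained = ph & pm,
       disrupted_in_human = pm & !ph,
       disrupted_in_mouse = ph & !pm,
       disrupted = xor(ph, pm))
}

#' Motif-cis models
#'
#' For each motif, fits
#' `|cis| ~ mean(GC) + mean(CpG) + |dGC| + |dCpG| + motif_disrupted`
#' over pairs with a defined assigned cis effect, testing the disruption
#' indicator by likelihood ratio. Motifs with no disrupted pair are
#' skipped.
#'
#' @param disrupted Logical matrix pairs x motifs (motif present in
#'   exactly one member).
#' @param cis_effects Numeric vector named by pair (assigned cis effect).
#' @param pair_composition Data.frame `pair_id`, `mean_gc`, `mean_cpg`,
#'   `abs_d_gc`, `abs_d_cpg`.
#' @param min_disrupted Minimum disrupted pairs per motif.
#' @return Data.frame per motif with `beta`, `p`, `q`,
#'   `variance_explained`, `n`.
#' @export
motif_cis_models <- function(disrupted, cis_effects, pair_composition,
                             min_disrupted = 5) {
  ids <- intersect(rownames(disrupted),
                   names(cis_effects)[!is.na(cis_effects)])
  comp <- pair_composition[match(ids, pair_composition$pair_id), ]
  covs <- data.frame(mean_gc = comp$mean_gc, mean_cpg = comp$mean_cpg,
                     abs_d_gc = comp$abs_d_gc, abs_d_cpg = comp$abs_d_cpg)
  y <- abs(cis_effects[ids])
  rows <- lapply(colnames(disrupted), function(m) {
    ind <- disrupted[ids, m]
    if (sum(ind) < min_disrupted) return(NULL)
    r <- lrt_nested(y, covs, ind)
    if (is.null(r)) return(NULL)
    data.frame(motif_id = m, beta = r$beta, p = r$p,
               variance_explained = r$variance_explained, n = r$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(motif_id = character(0), beta = numeric(0),
                      p = numeric(0), variance_explained = numeric(0),
                      n = integer(0), q = numeric(0)))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Motif-trans models
#'
#' For each motif, fits
#' `trans ~ gc_content + cpg_rate + motif_present` on signed per-sequence
#' trans effects; a positive coefficient associates the motif with
#' mESC-higher activity.
#'
#' @param presence Logical matrix elements x motifs.
#' @param trans_effects Numeric vector named by element.
#' @param composition Data.frame from [composition_table()].
#' @param min_group Minimum elements with and without the motif.
#' @return Data.frame per motif with `beta`, `p`, `q`,
#'   `variance_explained`, `n`.
#' @export
motif_trans_models <- function(presence, trans_effects, composition,
                               min_group = 10) {
  ids <- intersect(rownames(presence),
                   names(trans_effects)[!is.na(trans_effects)])
  comp <- composition[match(ids, composition$element_id), ]
  covs <- data.frame(gc_content = comp$gc_content, cpg_rate = comp$cpg_rate)
  y <- trans_effects[ids]
  rows <- lapply(colnames(presence), function(m) {
    ind <- presence[ids, m]
    if (sum(ind) < min_group || sum(!ind) < min_group) return(NULL)
    r <- lrt_nested(y, covs, ind)
    if (is.null(r)) return(NULL)
    data.frame(motif_id = m, beta = r$beta, p = r$p,
               variance_explained = r$variance_explained, n = r$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(motif_id = character(0), beta = numeric(0),
                      p = numeric(0), variance_explained = numeric(0),
                      n = integer(0), q = numeric(0)))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Shared-motif fraction of a pair
#'
#' Jaccard index of the two members' motif sets: intersection over
#' union. Undefined (NA) when both sets are empty.
#'
#' @param set_a,set_b Character vectors of motif ids.
#' @return Fraction in `[0, 1]` or `NA`.
#' @export
shared_motif_fraction <- function(set_a, set_b) {
  u <- union(set_a, set_b)
  if (length(u) == 0) return(NA_real_)
  length(intersect(set_a, set_b)) / length(u)
}

#' Compare shared-motif fractions between cis and no-cis pairs
#'
#' One-sided Mann-Whitney test that pairs without a cis effect share a
#' larger fraction of motifs than pairs with one.
#'
#' @param presence Logical matrix elements x motifs.
#' @param pairs Data.frame `pair_id`, `human_id`, `mouse_id`.
#' @param cis_sig Logical vector (aligned with `pairs`).
#' @return List `p`, `median_cis`, `median_no_cis`, `fractions`
#'   (per-pair data.frame).
#' @export
compare_shared_motifs <- function(presence, pairs, cis_sig) {
  frac <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- colnames(presence)[presence[pairs$human_id[i], ]]
    b <- colnames(presence)[presence[pairs$mouse_id[i], ]]
    shared_motif_fraction(a, b)
  }, numeric(1))
  keep <- !is.na(frac) & !is.na(cis_sig)
  g_cis <- frac[keep & cis_sig]
  g_no <- frac[keep & !cis_sig]
  wt <- stats::wilcox.test(g_no, g_cis, alternative = "greater",
                           exact = FALSE)
  list(p = wt$p.value,
       median_cis = stats::median(g_cis),
       median_no_cis = stats::median(g_no),
       fractions = data.frame(pair_id = pairs$pair_id,
                              shared_fraction = frac,
                              cis_significant = cis_sig,
                              stringsAsFactors = FALSE))
}

#' Hypergeometric biotype enrichment of motifs
#'
#' Upper-tail hypergeometric test of the overlap between the elements
#' carrying a motif and the elements of each biotype, over the universe
#' of all tested elements; Benjamini-Hochberg across motif x biotype.
#'
#' @param presence Logical matrix elements x motifs.
#' @param biotypes Character vector named by element.
#' @return Data.frame `motif_id`, `biotype`, `overlap`, `n_motif`,
#'   `n_biotype`, `universe`, `p`, `q`.
#' @export
biotype_enrichment <- function(presence, biotypes) {
  ids <- intersect(rownames(presence), names(biotypes))
  bio <- biotypes[ids]
  rows <- list()
  for (m in colnames(presence)) {
    hit <- presence[ids, m]
    k_m <- sum(hit)
    if (k_m == 0) next  # motif absent everywhere: skipped
    for (b in unique(bio)) {
      in_b <- bio == b
      n_b <- sum(in_b)
      if (n_b == 0) next
      ov <- sum(hit & in_b)
      p <- stats::phyper(ov - 1, k_m, length(ids) - k_m, n_b,
                         lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        motif_id = m, biotype = b, overlap = ov, n_motif = k_m,
        n_biotype = n_b, universe = length(ids), p = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(motif_id = character(0), biotype = character(0),
                      overlap = integer(0), n_motif = integer(0),
                      n_biotype = integer(0), universe = integer(0),
                      p = numeric(0), q = numeric(0)))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Direction agreement between trans-motif models and TF expression
#'
#' A transcription factor is differentially expressed when its absolute
#' log2 fold change (mESC vs hESC) is at least `lfc_threshold` with
#' `q < q_threshold`. Among motifs significantly associated with trans
#' effects whose TF is differentially expressed, agreement means the
#' trans coefficient and the expression fold change share a sign.
#'
#' @param trans_results Output of [motif_trans_models()] (needs `q`).
#' @param tf_de Data.frame `gene`, `log2fc_mESC_vs_hESC`, `qvalue`.
#' @param motif_tf Data.frame `motif_id`, `tf`.
#' @param trans_q Significance threshold on the trans model q-value.
#' @param lfc_threshold,q_threshold Differential-expression thresholds.
#' @return List `per_tf` (data.frame with `agree` flags), `n_agree`,
#'   `n_de`, `fraction_agree`, `n_missing` (TFs absent from the DE
#'   table).
#' @export
direction_agreement <- function(trans_results, tf_de, motif_tf,
                                trans_q = 0.05, lfc_threshold = 1,
                                q_threshold = 0.01) {
  sig <- trans_results[!is.na(trans_results$q) & trans_results$q < trans_q, ]
  sig$tf <- motif_tf$tf[match(sig$motif_id, motif_tf$motif_id)]
  # one row per TF: the motif with the strongest association
  sig <- sig[order(sig$q), ]
  sig <- sig[!duplicated(sig$tf) & !is.na(sig$tf), ]
  de_idx <- match(sig$tf, tf_de$gene)
  missing <- is.na(de_idx)
  per <- data.frame(tf = sig$tf, motif_id = sig$motif_id, beta = sig$beta,
                    log2fc = tf_de$log2fc_mESC_vs_hESC[de_idx],
                    de_q = tf_de$qvalue[de_idx],
                    stringsAsFactors = FALSE)
  per$is_de <- !missing & abs(per$log2fc) >= lfc_threshold &
    per$de_q < q_threshold
  per$agree <- per$is_de & sign(per$beta) == sign(per$log2fc)
  list(per_tf = per,
       n_trans_sig = nrow(per),
       n_missing = sum(missing),
       n_de = sum(per$is_de, na.rm = TRUE),
       n_agree = sum(per$agree, na.rm = TRUE),
       fraction_agree = if (sum(per$is_de, na.rm = TRUE) > 0) {
         sum(per$agree, na.rm = TRUE) / sum(per$is_de, na.rm = TRUE)
       } else NA_real_)
}
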