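# Cis-trans compensation: co-occurrence of cis and trans effects,
# compensatory vs directional classification, and the relation of the
# classes to native effects.

#' Fisher test of cis/trans co-occurrence
#'
#' Tests whether significant cis and trans effects co-occur across pairs
#' more often than expected under independence.
#'
#' @param cis_sig,trans_sig Logical vectors over the tested pairs.
#' @return List `odds_ratio` (conditional MLE from the exact test),
#'   `sample_odds` (ad/bc), `p` (two-sided), `table` (2x2 matrix),
#'   `n_both`.
#' @export
cooccurrence_test <- function(cis_sig, trans_sig) {
  keep <- !is.na(cis_sig) & !is.na(trans_sig)
  cis_sig <- cis_sig[keep]; trans_sig <- trans_sig[keep]
  tab <- matrix(c(sum(cis_sig & trans_sig), sum(cis_sig & !trans_sig),
                  sum(!cis_sig & trans_sig), sum(!cis_sig & !trans_sig)),
                nrow = 2, byrow = TRUE,
                dimnames = list(cis = c("sig", "ns"), trans = c("sig", "ns")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, sample_odds = NA_real_, p = NA_real_,
                table = tab, n_both = tab[1, 1], degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate),
       sample_odds = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       p = ft$p.value, table = tab, n_both = tab[1, 1], degenerate = FALSE)
}

#' Classify pairs as compensatory or directional
#'
#' Pairs with both effects significant are compensatory when the assigned
#' cis and trans effects have opposite signs and directional when the
#' signs match; otherwise `cis_only`, `trans_only` or `neither`. A
#' significant effect of exactly zero inherits the sign of the other
#' effect; pairs with both effects exactly zero are excluded.
#'
#' @param effects Data.frame from [assign_effects()] (`pair_id`,
#'   `cis_effect`, `cis_significant`, `trans_effect`,
#'   `trans_significant`), optionally with `biotype` and `conserved`.
#' @return List with `calls` (per-pair class) and, when biotype and
#'   conservation columns are present, `fractions` (per biotype x
#'   conservation group: number with both effects and fraction
#'   compensatory / directional).
#' @export
classify_pairs <- function(effects) {
  eff <- effects
  cls <- character(nrow(eff))
  excluded <- logical(nrow(eff))
  for (i in seq_len(nrow(eff))) {
    cs <- isTRUE(eff$cis_significant[i])
    ts <- isTRUE(eff$trans_significant[i])
    if (cs && ts) {
      ce <- eff$cis_effect[i]; te <- eff$trans_effect[i]
      if (ce == 0 && te == 0) {
        cls[i] <- "neither"; excluded[i] <- TRUE
        next
      }
      if (ce == 0) ce <- te
      if (te == 0) te <- ce
      cls[i] <- if (sign(ce) != sign(te)) "compensatory" else "directional"
    } else if (cs) {
      cls[i] <- "cis_only"
    } else if (ts) {
      cls[i] <- "trans_only"
    } else {
      cls[i] <- "neither"
    }
  }
  calls <- data.frame(pair_id = eff$pair_id,
                      cis_effect = eff$cis_effect,
                      trans_effect = eff$trans_effect,
                      class = cls,
                      excluded = excluded,
                      stringsAsFactors = FALSE)
  if (any(excluded)) {
    message(sum(excluded), " pair(s) with both effects exactly zero excluded")
  }
  out <- list(calls = calls)
  if (all(c("biotype", "conserved") %in% names(eff))) {
    both <- calls$class %in% c("compensatory", "directional")
    grp <- data.frame(biotype = eff$biotype, conserved = eff$conserved,
                      class = calls$class, stringsAsFactors = FALSE)[both, ]
    if (nrow(grp) > 0) {
      agg <- stats::aggregate(class ~ biotype + conserved, data = grp,
                              FUN = function(x) c(
                                n = length(x),
                                frac_compensatory = mean(x == "compensatory"),
                                frac_directional = mean(x == "directional")))
      out$fractions <- do.call(data.frame, agg)
      names(out$fractions) <- c("biotype", "conserved", "n",
                                "frac_compensatory", "frac_directional")
    }
  }
  out
}

#' Compare native effect sizes between compensation classes
#'
#' One-sided Mann-Whitney test that absolute native effects are smaller
#' for compensatory pairs than for directional pairs (compensation
#' stabilises native activity).
#'
#' @param native_effects Named or ordered numeric vector of native
#'   effects, aligned with `classes`.
#' @param classes Character vector with values including
#'   `"compensatory"` and `"directional"`.
#' @param min_per_class Minimum pairs per class.
#' @return List `p`, `median_compensatory`, `median_directional`,
#'   `n_compensatory`, `n_directional`.
#' @export
compare_native_by_class <- function(native_effects, classes,
                                    min_per_class = 3) {
  comp <- abs(native_effects[classes == "compensatory"])
  dire <- abs(native_effects[classes == "directional"])
  comp <- comp[!is.na(comp)]; dire <- dire[!is.na(dire)]
  if (length(comp) < min_per_class || length(dire) < min_per_class) {
    stop("insufficient group sizes (", length(comp), " compensatory, ",
         length(dire), " directional)", call. = FALSE)
  }
  wt <- stats::wilcox.test(comp, dire, alternative = "less", exact = FALSE)
  list(p = wt$p.value,
       median_compensatory = stats::median(comp),
       median_directional = stats::median(dire),
       n_compensatory = length(comp),
       n_directional = length(dire))
}
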