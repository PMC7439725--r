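# Differential activity: cis / trans / native effect scans over barcode
# log-ratios, null differential controls built by down-sampling
# positive-control barcodes, empirical-FDR calibration with an effect
# floor, and per-pair effect assignment.
#
# Sign convention (uniform across axes): a positive effect means the
# mouse sequence, or the mESC environment, has higher activity.

#' Build null differential control pairs
#'
#' Pairs of identical sequences are emulated by splitting one
#' positive-control element's barcode pool (60 barcodes) into two
#' disjoint subsets of `subset_size` barcodes. Each pseudo-pair is pushed
#' through the same effect scans as a real orthologous pair, defining the
#' no-differential-activity null.
#'
#' @param barcode_map Data.frame `barcode_id`, `element_id`.
#' @param control_ids Positive-control element ids.
#' @param n_per_tile Pseudo-pairs drawn per control element.
#' @param subset_size Barcodes per side (default 13, matching a TSS tile).
#' @param seed Integer seed; draws are deterministic given it.
#' @return Data.frame `null_id`, `element_id`, `side` (`A`/`B`),
#'   `barcode_id`.
#' @export
build_null_pairs <- function(barcode_map, control_ids, n_per_tile = 50,
                             subset_size = 13, seed = 1L) {
  set.seed(seed)
  out <- lapply(control_ids, function(el) {
    pool <- barcode_map$barcode_id[barcode_map$element_id == el]
    if (length(pool) < 2 * subset_size) {
      stop("barcode pool too small for element ", el, ": ", length(pool),
           " < ", 2 * subset_size, call. = FALSE)
    }
    lapply(seq_len(n_per_tile), function(i) {
      picked <- sample(pool, 2 * subset_size)
      data.frame(
        null_id = sprintf("null_%s_%03d", el, i),
        element_id = el,
        side = rep(c("A", "B"), each = subset_size),
        barcode_id = picked,
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, unlist(out, recursive = FALSE))
  rownames(out) <- NULL
  out
}

#' Signed effect and p-value for one two-group comparison
#'
#' The effect is the difference of group means of barcode log-ratios
#' (`B - A`). Replicate measurements of one barcode share its DNA
#' sampling noise and are therefore averaged to one observation per
#' barcode before testing; the p-value comes from an F-test of the group
#' indicator in a linear model on the barcode means. When the two groups
#' carry the identical barcode set (the same sequence measured in two
#' environments) the barcodes are paired and the F-test is run on the
#' within-barcode differences.
#'
#' @param obs_a,obs_b Data.frames with `log_ratio`, and optionally
#'   `barcode_id` (rows lacking it are treated as independent
#'   observations) for the two groups (A = human side / hESC side, B =
#'   mouse side / mESC side).
#' @return List `effect`, `p`, `n` (barcodes used); `NULL` when a group
#'   is degenerate (fewer than 2 barcodes).
#' @export
pairwise_effect <- function(obs_a, obs_b) {
  if (is.null(obs_a) || is.null(obs_b)) return(NULL)
  collapse <- function(o) {
    if (is.null(o$barcode_id)) return(o$log_ratio)
    vapply(split(o$log_ratio, o$barcode_id), mean, numeric(1))
  }
  a <- collapse(obs_a)
  b <- collapse(obs_b)
  if (length(a) < 2 || length(b) < 2) return(NULL)
  effect <- mean(b) - mean(a)
  paired <- !is.null(obs_a$barcode_id) && !is.null(obs_b$barcode_id) &&
    length(a) == length(b) && setequal(names(a), names(b))
  if (paired) {
    d <- b[names(a)] - a
    n <- length(d)
    s2 <- stats::var(d)
    p <- if (s2 == 0) {
      if (abs(effect) < 1e-12) 1 else 0
    } else {
      f <- n * mean(d)^2 / s2
      stats::pf(f, 1, n - 1, lower.tail = FALSE)
    }
    return(list(effect = effect, p = p, n = n))
  }
  y <- c(a, b)
  if (stats::var(y) == 0) {
    return(list(effect = 0, p = 1, n = length(y)))
  }
  grp <- rep(c(0, 1), c(length(a), length(b)))
  n <- length(y)
  rss_red <- sum((y - mean(y))^2)
  fit <- stats::lm.fit(cbind(1, grp), y)
  rss_full <- sum(fit$residuals^2)
  df_res <- n - 2
  p <- if (df_res <= 0 || rss_full <= 0) {
    1
  } else {
    f <- (rss_red - rss_full) / (rss_full / df_res)
    stats::pf(max(f, 0), 1, df_res, lower.tail = FALSE)
  }
  if (is.na(p)) p <- 1
  list(effect = effect, p = p, n = n)
}

#' Scan all five effect axes over real pairs and null controls
#'
#' For every retained pair: cis in hESCs and in mESCs (mouse vs human
#' sequence, environment fixed), trans of the human and of the mouse
#' sequence (mESC vs hESC environment, sequence fixed), and the native
#' effect (mouse sequence in mESCs vs human sequence in hESCs). Null
#' pseudo-pairs travel through the identical code path with subset A
#' playing the human side and subset B the mouse side. q-values are
#' Benjamini-Hochberg, computed jointly over real and null units within
#' each axis so both share one scale.
#'
#' Pairs are retained when significantly active (activity q below
#' `active_q`) in at least one native context.
#'
#' @param observations Barcode observations from [compute_log_ratios()].
#' @param catalog Element catalog (needs `element_id`, `pair_id`,
#'   `species`, `class`).
#' @param null_pairs Output of [build_null_pairs()] (or `NULL` to skip).
#' @param activity Output of [test_active()] (or `NULL` to skip the
#'   active filter).
#' @param active_q Activity q-value threshold for the native-context
#'   filter.
#' @return Data.frame `unit_id`, `axis`, `is_null`, `effect`, `p`, `q`.
#' @export
run_effect_scans <- function(observations, catalog, null_pairs = NULL,
                             activity = NULL, active_q = 0.05) {
  obs_split <- split(observations[, c("barcode_id", "environment",
                                      "replicate", "log_ratio")],
                     observations$element_id)
  get_obs <- function(el, env, barcodes = NULL) {
    o <- obs_split[[el]]
    if (is.null(o)) return(NULL)
    o <- o[o$environment == env, ]
    if (!is.null(barcodes)) o <- o[o$barcode_id %in% barcodes, ]
    if (nrow(o) == 0) NULL else o
  }

  pairs <- unique(catalog[catalog$class == "TSS" & !is.na(catalog$pair_id),
                          "pair_id"])
  if (!is.null(activity)) {
    act <- activity[activity$active, ]
    native_active <- function(pid) {
      any(paste0(pid, "_human") == act$element_id[act$environment == "hESC"]) ||
        any(paste0(pid, "_mouse") == act$element_id[act$environment == "mESC"])
    }
    pairs <- pairs[vapply(pairs, native_active, logical(1))]
  }

  one_unit <- function(unit_id, is_null, h_h, h_m, m_h, m_m) {
    # h_h = human-side obs in hESC, h_m = human-side in mESC, etc.
    axes <- list(
      cis_hESC = list(a = h_h, b = m_h),
      cis_mESC = list(a = h_m, b = m_m),
      trans_human_seq = list(a = h_h, b = h_m),
      trans_mouse_seq = list(a = m_h, b = m_m),
      native = list(a = h_h, b = m_m)
    )
    res <- lapply(names(axes), function(ax) {
      r <- pairwise_effect(axes[[ax]]$a, axes[[ax]]$b)
      if (is.null(r)) {
        data.frame(unit_id = unit_id, axis = ax, is_null = is_null,
                   effect = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
      } else {
        data.frame(unit_id = unit_id, axis = ax, is_null = is_null,
                   effect = r$effect, p = r$p, stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, res)
  }

  real <- lapply(pairs, function(pid) {
    hu <- paste0(pid, "_human")
    mo <- paste0(pid, "_mouse")
    one_unit(pid, FALSE,
             get_obs(hu, "hESC"), get_obs(hu, "mESC"),
             get_obs(mo, "hESC"), get_obs(mo, "mESC"))
  })

  nulls <- list()
  if (!is.null(null_pairs) && nrow(null_pairs) > 0) {
    nulls <- lapply(split(null_pairs, null_pairs$null_id), function(np) {
      el <- np$element_id[1]
      bc_a <- np$barcode_id[np$side == "A"]
      bc_b <- np$barcode_id[np$side == "B"]
      one_unit(np$null_id[1], TRUE,
               get_obs(el, "hESC", bc_a), get_obs(el, "mESC", bc_a),
               get_obs(el, "hESC", bc_b), get_obs(el, "mESC", bc_b))
    })
  }

  out <- do.call(rbind, c(real, nulls))
  rownames(out) <- NULL
  out$q <- NA_real_
  for (ax in unique(out$axis)) {
    sel <- out$axis == ax & !is.na(out$p)
    out$q[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out
}

#' Calibrate the empirical-FDR cutoff and effect floor
#'
#' The q-value cutoff is the largest threshold at which fewer than
#' `target` (10%) of the null differential controls are called
#' significant; significant real effects must additionally exceed the
#' minimum significant null absolute effect (the effect floor).
#'
#' @param results Effect results for one axis family (real and null rows,
#'   from [run_effect_scans()]).
#' @param target Tolerated null significant fraction (default 0.10).
#' @param min_nulls Minimum number of null results required.
#' @return List with `q_cutoff`, `effect_floor`, `achieved_null_rate`,
#'   and `results` annotated with a `significant` column.
#' @export
calibrate_empirical_fdr <- function(results, target = 0.10, min_nulls = 50) {
  nulls <- results[results$is_null & !is.na(results$q), ]
  if (nrow(nulls) == 0) stop("no null results to calibrate on", call. = FALSE)
  if (nrow(nulls) < min_nulls) {
    stop("too few null results (", nrow(nulls), " < ", min_nulls, ")",
         call. = FALSE)
  }
  nq <- sort(nulls$q)
  n <- length(nq)
  k_max <- ceiling(target * n) - 1L  # largest count with k/n < target
  q_cutoff <- if (k_max + 1L <= n) nq[k_max + 1L] else Inf
  null_sig <- nulls$q < q_cutoff
  effect_floor <- if (any(null_sig)) min(abs(nulls$effect[null_sig])) else 0
  achieved <- mean(null_sig)
  res <- results
  res$significant <- !is.na(res$q) & res$q < q_cutoff &
    abs(res$effect) > effect_floor
  list(q_cutoff = q_cutoff, effect_floor = effect_floor,
       achieved_null_rate = achieved, results = res)
}

#' Assign one signed effect per pair from an axis family's two models
#'
#' When exactly one of the two models (hESC/mESC for cis; human/mouse
#' sequence for trans) is significant, its effect is assigned; otherwise
#' the effect with the larger absolute value is taken (ties to the first
#' model). The pair is significant when either model is.
#'
#' @param effect_1,effect_2 Signed effects of the two models.
#' @param sig_1,sig_2 Their significance flags.
#' @return List `effect`, `significant`; `NULL` when both effects are
#'   missing.
#' @export
assign_pair_effect <- function(effect_1, effect_2, sig_1, sig_2) {
  if (is.na(effect_1) && is.na(effect_2)) return(NULL)
  if (is.na(effect_1)) return(list(effect = effect_2, significant = isTRUE(sig_2)))
  if (is.na(effect_2)) return(list(effect = effect_1, significant = isTRUE(sig_1)))
  s1 <- isTRUE(sig_1); s2 <- isTRUE(sig_2)
  eff <- if (s1 && !s2) {
    effect_1
  } else if (s2 && !s1) {
    effect_2
  } else if (abs(effect_2) > abs(effect_1)) {
    effect_2
  } else {
    effect_1
  }
  list(effect = eff, significant = s1 || s2)
}

#' Assign per-pair cis, trans and native effects
#'
#' Applies the empirical-FDR calibration per axis family (cis, trans,
#' native) and collapses the two cis models and the two trans models to
#' one signed effect per pair.
#'
#' @param scan Output of [run_effect_scans()].
#' @param target Empirical-FDR target (default 0.10).
#' @param min_nulls Passed to [calibrate_empirical_fdr()].
#' @return List with `effects` (per real pair: `pair_id`, `cis_effect`,
#'   `cis_significant`, `trans_effect`, `trans_significant`,
#'   `native_effect`, `native_significant`) and `calibration` (per
#'   family).
#' @export
assign_effects <- function(scan, target = 0.10, min_nulls = 50) {
  families <- list(cis = c("cis_hESC", "cis_mESC"),
                   trans = c("trans_human_seq", "trans_mouse_seq"),
                   native = "native")
  calib <- list()
  annotated <- list()
  for (fam in names(families)) {
    sub <- scan[scan$axis %in% families[[fam]], ]
    cal <- calibrate_empirical_fdr(sub, target = target,
                                   min_nulls = min_nulls)
    calib[[fam]] <- cal[c("q_cutoff", "effect_floor", "achieved_null_rate")]
    annotated[[fam]] <- cal$results
  }

  pairs <- unique(scan$unit_id[!scan$is_null])
  pick <- function(df, unit, ax) {
    r <- df[df$unit_id == unit & df$axis == ax, ]
    if (nrow(r) == 0) list(effect = NA_real_, significant = NA) else
      list(effect = r$effect[1], significant = r$significant[1])
  }
  rows <- lapply(pairs, function(pid) {
    c1 <- pick(annotated$cis, pid, "cis_hESC")
    c2 <- pick(annotated$cis, pid, "cis_mESC")
    t1 <- pick(annotated$trans, pid, "trans_human_seq")
    t2 <- pick(annotated$trans, pid, "trans_mouse_seq")
    nv <- pick(annotated$native, pid, "native")
    cis <- assign_pair_effect(c1$effect, c2$effect, c1$significant, c2$significant)
    trn <- assign_pair_effect(t1$effect, t2$effect, t1$significant, t2$significant)
    data.frame(
      pair_id = pid,
      cis_effect = if (is.null(cis)) NA_real_ else cis$effect,
      cis_significant = if (is.null(cis)) NA else cis$significant,
      trans_effect = if (is.null(trn)) NA_real_ else trn$effect,
      trans_significant = if (is.null(trn)) NA else trn$significant,
      native_effect = nv$effect,
      native_significant = nv$significant,
      stringsAsFactors = FALSE
    )
  })
  list(effects = do.call(rbind, rows), calibration = calib,
       annotated = annotated)
}
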