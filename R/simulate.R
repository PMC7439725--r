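# Synthetic MPRA generator: element catalog, planted ground truth,
# barcode-level counts. The generator emulates a two-species (human/mouse)
# ESC reporter assay with orthologous sequence pairs, planted cis and
# trans effects, inactive random negative controls and high-barcode
# positive controls.

#' Simulate the element catalog and planted ground truth
#'
#' Draws, for every orthologous pair, a baseline activity, motif presence,
#' and cis/trans effects with a controlled co-occurrence structure. The
#' truth is additive by construction: writing `alpha(seq, env)` for the
#' true log2 activity,
#' `native = alpha(mouse, mESC) - alpha(human, hESC)` equals
#' `cis (in hESC) + trans (mouse sequence)` exactly. A cis effect shifts
#' the mouse sequence in both environments equally; a trans effect shifts
#' both sequences of a pair across environments by the same amount.
#' Negative controls sit at the global minimum activity; positive controls
#' at a high environment-independent activity.
#'
#' Activities are identifiable from count ratios only up to a library-wide
#' additive constant, so the planted activities are centred once (a single
#' global constant over barcodes and environments) so that the
#' barcode-weighted mean linear activity is 1. Differences — the cis,
#' trans and native truth — are unaffected.
#'
#' @param config A [simulation_config()] object.
#' @return A list with `catalog` (element_id, pair_id, species, biotype,
#'   conserved, tile, class), `barcode_map` (barcode_id, element_id) and
#'   `truth` (activities, pair effects, motif table, motif presence,
#'   sign structure).
#' @export
simulate_truth <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_pairs

  pair_id <- sprintf("pair%04d", seq_len(n))
  biotype <- sample(names(config$biotype_proportions), n, replace = TRUE,
                    prob = config$biotype_proportions)
  fc <- config$frac_conserved
  if (length(fc) == 1) fc <- stats::setNames(rep(fc, 3), c("eRNA", "lncRNA", "mRNA"))
  conserved <- stats::runif(n) < fc[biotype]

  # motif table: activator/repressor motifs plus trans-responsive motifs
  n_trans_motifs <- max(2L, as.integer(round(config$n_motifs * 0.3)))
  n_trans_motifs <- n_trans_motifs + (n_trans_motifs %% 2L)  # even: both signs
  n_act <- config$n_motifs - n_trans_motifs
  if (n_act < 1) stop("configuration error: n_motifs too small", call. = FALSE)
  motif_id <- sprintf("M%03d", seq_len(config$n_motifs))
  is_trans_motif <- c(rep(FALSE, n_act), rep(TRUE, n_trans_motifs))
  act_effect <- stats::rnorm(n_act, 0, config$motif_effect_sd)
  trans_dir <- rep(c(1, -1), length.out = n_trans_motifs)
  trans_gamma <- trans_dir *
    config$trans_effect_sd * (0.75 + 0.5 * stats::runif(n_trans_motifs))
  motifs <- data.frame(
    motif_id = motif_id,
    tf = sprintf("TF%03d", seq_len(config$n_motifs)),
    is_trans_motif = is_trans_motif,
    effect = c(act_effect, rep(0, n_trans_motifs)),
    trans_direction = c(rep(0, n_act), trans_dir),
    trans_gamma = c(rep(0, n_act), trans_gamma),
    class = c(ifelse(act_effect > 0, "activator", "repressor"),
              ifelse(trans_dir > 0, "activator", "repressor")),
    stringsAsFactors = FALSE
  )

  # joint cis/trans indicators with odds-ratio coupling
  p11 <- joint_prob_from_odds(config$frac_cis, config$frac_trans,
                              config$cis_trans_odds)
  cls <- sample.int(4, n, replace = TRUE,
                    prob = c(p11,
                             config$frac_cis - p11,
                             config$frac_trans - p11,
                             1 - config$frac_cis - config$frac_trans + p11))
  has_cis <- cls %in% c(1L, 2L)
  has_trans <- cls %in% c(1L, 3L)

  # pair-level presence of activity motifs (shared by both members unless
  # disrupted); trans motifs handled per pair below
  pres_pair <- matrix(stats::runif(n * n_act) < 0.25, nrow = n)
  pres_human <- cbind(pres_pair, matrix(FALSE, n, n_trans_motifs))
  pres_mouse <- pres_human
  colnames(pres_human) <- colnames(pres_mouse) <- motif_id

  cis_extra <- ifelse(has_cis, stats::rnorm(n, 0, config$cis_effect_sd), 0)
  disrupted_motif <- rep(NA_character_, n)
  disrupted_in <- rep(NA_character_, n)
  for (i in which(has_cis)) {
    m <- if (any(pres_pair[i, ])) {
      sample(rep(which(pres_pair[i, ]), 2L), 1L)
    } else {
      sample.int(n_act, 1L)
    }
    side <- sample(c("human", "mouse"), 1L)
    # disruption removes the motif from one member (planting it in the
    # other member first if the pair lacked it)
    pres_human[i, m] <- side != "human"
    pres_mouse[i, m] <- side != "mouse"
    disrupted_motif[i] <- motif_id[m]
    disrupted_in[i] <- side
  }

  base <- stats::rnorm(n, 2, 0.8)
  beta <- motifs$effect
  act_h <- as.numeric(pres_human %*% beta)
  act_m <- as.numeric(pres_mouse %*% beta)
  cis_true <- ifelse(has_cis, (act_m - act_h) + cis_extra, 0)
  # pairs without a planted cis effect have identical motif content
  stopifnot(all(abs((act_m - act_h)[!has_cis]) < 1e-12))

  # trans effects: sign constrained by the compensatory fraction when a
  # cis effect co-occurs, realised through a direction-matched trans motif
  trans_true <- numeric(n)
  trans_motif <- rep(NA_character_, n)
  trans_idx <- which(motifs$is_trans_motif)
  for (i in which(has_trans)) {
    s <- if (has_cis[i] && cis_true[i] != 0) {
      if (stats::runif(1) < config$frac_compensatory) -sign(cis_true[i]) else sign(cis_true[i])
    } else {
      sample(c(-1, 1), 1L)
    }
    cand <- trans_idx[motifs$trans_direction[trans_idx] == s]
    t_m <- sample(rep(cand, 2L), 1L)
    tau <- motifs$trans_gamma[t_m] +
      stats::rnorm(1, 0, 0.15 * config$trans_effect_sd)
    trans_true[i] <- s * abs(tau)
    trans_motif[i] <- motifs$motif_id[t_m]
    pres_human[i, t_m] <- TRUE
    pres_mouse[i, t_m] <- TRUE
  }
  # background presence of trans motifs (carries no effect for pairs
  # without a planted trans shift; adds realistic noise to associations)
  bg <- matrix(stats::runif(n * length(trans_idx)) < 0.05, nrow = n)
  for (j in seq_along(trans_idx)) {
    extra <- bg[, j] & !has_trans
    pres_human[extra, trans_idx[j]] <- TRUE
    pres_mouse[extra, trans_idx[j]] <- TRUE
  }

  compensatory <- has_cis & has_trans & cis_true != 0 & trans_true != 0 &
    sign(cis_true) != sign(trans_true)

  # per (sequence, environment) activities
  a_h_hESC <- base + act_h_current(pres_human, beta)
  a_m_hESC <- base + act_h_current(pres_mouse, beta) + cis_extra * has_cis
  a_h_mESC <- a_h_hESC + trans_true
  a_m_mESC <- a_m_hESC + trans_true
  # recompute cis on realised activities (equals cis_true by construction)
  stopifnot(max(abs((a_m_hESC - a_h_hESC) - cis_true)) < 1e-9)

  neg_id <- sprintf("neg%04d", seq_len(config$n_negative_controls))
  pos_id <- sprintf("pos%02d", seq_len(config$n_positive_controls))
  alpha_min <- min(c(a_h_hESC, a_m_hESC, a_h_mESC, a_m_mESC))
  alpha_pos <- 5

  catalog <- rbind(
    data.frame(element_id = paste0(pair_id, "_human"), pair_id = pair_id,
               species = "human", biotype = biotype, conserved = conserved,
               tile = "tile1", class = "TSS", stringsAsFactors = FALSE),
    data.frame(element_id = paste0(pair_id, "_mouse"), pair_id = pair_id,
               species = "mouse", biotype = biotype, conserved = conserved,
               tile = "tile1", class = "TSS", stringsAsFactors = FALSE),
    data.frame(element_id = neg_id, pair_id = NA_character_,
               species = NA_character_, biotype = "control", conserved = NA,
               tile = "tile1", class = "negative", stringsAsFactors = FALSE),
    data.frame(element_id = pos_id, pair_id = NA_character_,
               species = NA_character_, biotype = "control", conserved = NA,
               tile = "tile1", class = "positive", stringsAsFactors = FALSE)
  )
  barcode_map <- assign_barcodes(catalog, config$barcodes_per_class)

  activity <- rbind(
    data.frame(element_id = paste0(pair_id, "_human"), environment = "hESC",
               alpha = a_h_hESC, stringsAsFactors = FALSE),
    data.frame(element_id = paste0(pair_id, "_mouse"), environment = "hESC",
               alpha = a_m_hESC, stringsAsFactors = FALSE),
    data.frame(element_id = paste0(pair_id, "_human"), environment = "mESC",
               alpha = a_h_mESC, stringsAsFactors = FALSE),
    data.frame(element_id = paste0(pair_id, "_mouse"), environment = "mESC",
               alpha = a_m_mESC, stringsAsFactors = FALSE),
    data.frame(element_id = rep(neg_id, 2),
               environment = rep(c("hESC", "mESC"), each = length(neg_id)),
               alpha = alpha_min, stringsAsFactors = FALSE),
    data.frame(element_id = rep(pos_id, 2),
               environment = rep(c("hESC", "mESC"), each = length(pos_id)),
               alpha = alpha_pos, stringsAsFactors = FALSE)
  )

  # centre on the barcode-weighted mean linear activity (both environments)
  nbc <- config$barcodes_per_class[catalog$class]
  w <- stats::setNames(as.numeric(nbc), catalog$element_id)
  offset <- log2(sum(w[activity$element_id] * 2^activity$alpha) /
                 sum(w[activity$element_id]))
  activity$alpha <- activity$alpha - offset

  pres_all <- rbind(pres_human, pres_mouse)
  rownames(pres_all) <- c(paste0(pair_id, "_human"), paste0(pair_id, "_mouse"))

  pairs <- data.frame(
    pair_id = pair_id,
    biotype = biotype,
    conserved = conserved,
    has_cis = has_cis,
    has_trans = has_trans,
    cis_true = cis_true,
    trans_human_true = trans_true,
    trans_mouse_true = trans_true,
    native_true = cis_true + trans_true,
    compensatory = compensatory,
    disrupted_motif = disrupted_motif,
    disrupted_in = disrupted_in,
    trans_motif = trans_motif,
    stringsAsFactors = FALSE
  )

  truth <- list(activity = activity, pairs = pairs, motifs = motifs,
                presence = pres_all, alpha_offset = offset,
                alpha_negative = alpha_min - offset,
                alpha_positive = alpha_pos - offset)
  list(catalog = catalog, barcode_map = barcode_map, truth = truth)
}

# presence %*% beta, kept as a helper so the two members share one code path
act_h_current <- function(pres, beta) as.numeric(pres %*% beta)

# p11 for a 2x2 with marginals (pc, pt) and odds ratio theta
joint_prob_from_odds <- function(pc, pt, theta) {
  if (abs(theta - 1) < 1e-12) return(pc * pt)
  a <- theta - 1
  b <- -(1 + (pc + pt) * (theta - 1))
  cc <- theta * pc * pt
  disc <- b^2 - 4 * a * cc
  p11 <- (-b - sqrt(disc)) / (2 * a)
  lo <- max(0, pc + pt - 1)
  hi <- min(pc, pt)
  min(max(p11, lo), hi)
}

#' Simulate barcode-level DNA and RNA counts
#'
#' Hierarchical negative-binomial measurement model: each barcode carries a
#' gamma-distributed representation weight; its DNA count is negative
#' binomial around the depth-scaled weight, and its RNA mean in a given
#' environment is the DNA mean times `2^alpha` of its sequence there
#' (scaled to the RNA depth), again negative binomial with the configured
#' dispersion. A single pooled input DNA library is simulated; RNA counts
#' are drawn per environment and replicate.
#'
#' @param sim Output of [simulate_truth()].
#' @param config The same [simulation_config()].
#' @return A list with `dna` (barcode_id, element_id, count) and `rna`
#'   (barcode_id, element_id, environment, replicate, count).
#' @export
simulate_counts <- function(sim, config) {
  validate_config(config)
  set.seed(config$seed + 1L)
  bm <- sim$barcode_map
  nb <- nrow(bm)

  w <- stats::rgamma(nb, shape = 4, rate = 4)
  mu_dna <- config$dna_depth * w / nb
  dna <- data.frame(
    barcode_id = bm$barcode_id,
    element_id = bm$element_id,
    count = rnb(nb, mu_dna, config$nb_dispersion),
    stringsAsFactors = FALSE
  )

  alpha <- sim$truth$activity
  akey <- stats::setNames(alpha$alpha, paste(alpha$element_id, alpha$environment))
  scale <- config$rna_depth / config$dna_depth
  rna <- do.call(rbind, lapply(c("hESC", "mESC"), function(env) {
    a <- akey[paste(bm$element_id, env)]
    mu_rna <- mu_dna * 2^a * scale
    do.call(rbind, lapply(seq_len(config$n_replicates), function(rep) {
      data.frame(barcode_id = bm$barcode_id, element_id = bm$element_id,
                 environment = env, replicate = rep,
                 count = rnb(nb, mu_rna, config$nb_dispersion),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rna) <- NULL
  list(dna = dna, rna = rna)
}

# NB draw parameterised by mean and dispersion (var = mu + disp * mu^2);
# dispersion 0 degenerates to Poisson
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}
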