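# Sequence realisation (planted motif instances in 144-bp tiles) and the
# expression context: TAD-partitioned toy genome, correlated "redundant"
# enhancer ensembles, and a TF differential-expression table.

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

# near-consensus PWM for a consensus string: prob `strength` on the
# consensus base, the rest spread uniformly
consensus_pwm <- function(consensus, strength = 0.85) {
  bases <- strsplit(consensus, "")[[1]]
  pwm <- matrix((1 - strength) / 3, 4, length(bases),
                dimnames = list(DNA_BASES, NULL))
  pwm[cbind(match(bases, DNA_BASES), seq_along(bases))] <- strength
  pwm
}

#' Simulate tile sequences with planted motif instances
#'
#' Every element receives a random 144-base tile; motifs recorded as
#' present in the ground truth are planted as exact consensus insertions
#' at non-overlapping recorded positions. Motif disruption is realised by
#' construction: a disrupted motif is planted in exactly one member of
#' the pair.
#'
#' @param sim Output of [simulate_truth()].
#' @param config The same [simulation_config()].
#' @param motif_width Motif width in bases (must not exceed the tile).
#' @return List with `sequences` (named character vector), `pwms`
#'   (named list of near-consensus PWMs), `consensus` (named character),
#'   `placements` (data.frame element_id, motif_id, start).
#' @export
simulate_sequences <- function(sim, config, motif_width = 8L) {
  validate_config(config)
  if (motif_width > TILE_LENGTH) {
    stop("configuration error: motif longer than tile", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  motifs <- sim$truth$motifs
  consensus <- stats::setNames(random_dna(nrow(motifs), motif_width),
                               motifs$motif_id)
  pwms <- lapply(consensus, consensus_pwm)

  seqs <- stats::setNames(random_dna(nrow(sim$catalog), TILE_LENGTH),
                          sim$catalog$element_id)
  pres <- sim$truth$presence
  placements <- list()
  for (el in rownames(pres)) {
    present <- colnames(pres)[pres[el, ]]
    if (length(present) == 0) next
    # greedy non-overlapping placement
    taken <- integer(0)
    s <- seqs[[el]]
    for (m in present) {
      ok <- FALSE
      for (try in 1:200) {
        st <- sample.int(TILE_LENGTH - motif_width + 1L, 1L)
        span <- st:(st + motif_width - 1L)
        if (!any(span %in% taken)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place motif ", m, " in ", el, call. = FALSE)
      substr(s, st, st + motif_width - 1L) <- consensus[[m]]
      taken <- c(taken, span)
      placements[[length(placements) + 1]] <- data.frame(
        element_id = el, motif_id = m, start = st, stringsAsFactors = FALSE)
    }
    seqs[[el]] <- s
  }
  placements <- if (length(placements) > 0) {
    do.call(rbind, placements)
  } else {
    data.frame(element_id = character(0), motif_id = character(0),
               start = integer(0))
  }
  list(sequences = seqs, pwms = pwms, consensus = consensus,
       placements = placements)
}

#' Simulate the expression context: TADs, enhancers, TF table
#'
#' A toy genome is partitioned into adjacent TADs; each TAD holds
#' `enhancers_per_tad` enhancers and the focal MPRA pairs assigned to it.
#' A planted subset of each focal element's TAD enhancers is "redundant":
#' it shares a latent factor with the focal element so the expected
#' Pearson correlation of log expression equals
#' `redundancy_correlation`; the rest are independent. The planted
#' redundant fraction is higher for directional pairs than compensatory
#' ones, mirroring inter-element compensation around directional
#' elements. The TF table carries log2 fold changes (mESC vs hESC) whose
#' direction matches each planted trans motif for a `frac_tf_agree`
#' subset of trans-motif TFs.
#'
#' @param sim Output of [simulate_truth()].
#' @param config The same [simulation_config()].
#' @param tad_width TAD width in bases on the toy genome.
#' @param redundant_frac Named fractions of TAD enhancers planted as
#'   redundant per pair class (`directional`, `compensatory`, `other`).
#' @return List with `tads` (BED-like data.frame, two sources),
#'   `elements` (focal positions), `enhancers` (positions), `expression`
#'   (matrix, rows = focal pairs then enhancers), `tf_de` (gene, lfc, q,
#'   expression), `redundant_truth` (per focal pair: planted redundant
#'   enhancer ids).
#' @export
simulate_cage_context <- function(sim, config, tad_width = 1e5,
                                  redundant_frac = c(directional = 0.6,
                                                     compensatory = 0.2,
                                                     other = 0.4)) {
  validate_config(config)
  set.seed(config$seed + 3L)
  n_tads <- config$n_tads
  tads <- data.frame(
    chromosome = "chrS",
    start = (seq_len(n_tads) - 1) * tad_width,
    end = seq_len(n_tads) * tad_width,
    tad_id = sprintf("tad%03d", seq_len(n_tads)),
    stringsAsFactors = FALSE
  )
  # both species' TAD calls; identical partitions on the toy genome
  tads_hESC <- transform(tads, source = "hESC")
  tads_mESC <- transform(tads, source = "mESC")

  n_enh <- n_tads * config$enhancers_per_tad
  enh_tad <- rep(seq_len(n_tads), each = config$enhancers_per_tad)
  enhancers <- data.frame(
    enhancer_id = sprintf("enh%04d", seq_len(n_enh)),
    chromosome = "chrS",
    position = as.integer(tads$start[enh_tad] +
                          floor(stats::runif(n_enh) * tad_width)),
    tad_id = tads$tad_id[enh_tad],
    stringsAsFactors = FALSE
  )

  pairs <- sim$truth$pairs
  pair_tad <- rep(seq_len(n_tads), length.out = nrow(pairs))
  elements <- data.frame(
    pair_id = pairs$pair_id,
    chromosome = "chrS",
    position = as.integer(tads$start[pair_tad] +
                          floor(stats::runif(nrow(pairs)) * tad_width)),
    tad_id = tads$tad_id[pair_tad],
    stringsAsFactors = FALSE
  )

  cls <- ifelse(pairs$has_cis & pairs$has_trans,
                ifelse(pairs$compensatory, "compensatory", "directional"),
                "other")
  rho <- config$redundancy_correlation
  ns <- config$n_expression_samples
  z_focal <- matrix(stats::rnorm(nrow(pairs) * ns), nrow(pairs), ns)
  expr <- matrix(NA_real_, nrow(pairs) + n_enh, ns,
                 dimnames = list(c(pairs$pair_id, enhancers$enhancer_id),
                                 sprintf("sample%04d", seq_len(ns))))
  to_counts <- function(z) pmax(exp(z * 1 + 3) - 1, 0)
  expr[seq_len(nrow(pairs)), ] <- to_counts(z_focal)

  redundant_truth <- stats::setNames(vector("list", nrow(pairs)),
                                     pairs$pair_id)
  # each enhancer can be redundant with at most one focal element; walk
  # focal elements and claim unclaimed TAD enhancers
  claimed <- character(0)
  enh_z <- matrix(stats::rnorm(n_enh * ns), n_enh, ns)
  for (i in seq_len(nrow(pairs))) {
    in_tad <- enhancers$enhancer_id[enhancers$tad_id == elements$tad_id[i]]
    free <- setdiff(in_tad, claimed)
    k <- stats::rbinom(1, length(free), redundant_frac[[cls[i]]])
    red <- if (k > 0) sample(rep(free, 2L), k) else character(0)
    claimed <- c(claimed, red)
    redundant_truth[[i]] <- red
    for (e in red) {
      j <- match(e, enhancers$enhancer_id)
      enh_z[j, ] <- rho * z_focal[i, ] +
        sqrt(max(0, 1 - rho^2)) * stats::rnorm(ns)
    }
  }
  expr[nrow(pairs) + seq_len(n_enh), ] <- to_counts(enh_z)

  motifs <- sim$truth$motifs
  lfc <- numeric(nrow(motifs))
  qv <- numeric(nrow(motifs))
  agree <- stats::runif(nrow(motifs)) < config$frac_tf_agree
  for (i in seq_len(nrow(motifs))) {
    if (motifs$is_trans_motif[i]) {
      d <- motifs$trans_direction[i] * ifelse(agree[i], 1, -1)
      lfc[i] <- d * (1 + abs(stats::rnorm(1)))
      qv[i] <- 10^-stats::runif(1, 4, 8)
    } else {
      lfc[i] <- stats::rnorm(1, 0, 0.3)
      qv[i] <- stats::runif(1, 0.2, 1)
    }
  }
  tf_de <- data.frame(
    gene = motifs$tf,
    log2fc_mESC_vs_hESC = lfc,
    qvalue = qv,
    expr_hESC = exp(stats::rnorm(nrow(motifs), 2, 1)),
    expr_mESC = exp(stats::rnorm(nrow(motifs), 2, 1)),
    stringsAsFactors = FALSE
  )

  list(tads = rbind(tads_hESC, tads_mESC), elements = elements,
       enhancers = enhancers, expression = expr, tf_de = tf_de,
       redundant_truth = redundant_truth)
}
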