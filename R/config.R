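#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the
#' synthetic-data generator. Defaults describe a desk-scale version of a
#' two-species embryonic stem cell MPRA: orthologous human/mouse sequence
#' pairs tiled at 144 bp, 13 barcodes per TSS tile, 3 per random negative
#' control, 60 per CMV-style positive control, three replicates per
#' cellular environment, and negative-binomial barcode counts.
#'
#' @param n_pairs Number of orthologous sequence pairs (each pair
#'   contributes one human and one mouse sequence).
#' @param biotype_proportions Named numeric vector over
#'   `c("eRNA","lncRNA","mRNA")`; must sum to 1.
#' @param frac_conserved Named numeric vector (same names) giving the
#'   fraction of pairs of each biotype labelled conserved, or a single
#'   number recycled across biotypes.
#' @param n_negative_controls Number of random inactive control sequences.
#' @param n_positive_controls Number of high-activity control tiles.
#' @param barcodes_per_class Named integer vector
#'   `c(TSS = 13, negative = 3, positive = 60)`.
#' @param n_replicates RNA replicates per environment.
#' @param dna_depth,rna_depth Expected total counts for the pooled input
#'   DNA library and for each RNA sample.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param cis_effect_sd,trans_effect_sd Standard deviation (log2) of
#'   planted cis and trans effects.
#' @param frac_cis,frac_trans Fraction of pairs carrying a cis (resp.
#'   trans) effect.
#' @param frac_compensatory Among pairs carrying both effects, fraction in
#'   which the trans effect opposes the cis effect in sign.
#' @param cis_trans_odds Odds ratio coupling the cis and trans indicators;
#'   1 makes them independent, larger values make co-occurrence more
#'   likely than chance.
#' @param n_motifs Number of transcription factor motifs simulated.
#' @param motif_effect_sd Standard deviation (log2) of per-motif additive
#'   activity effects.
#' @param frac_tf_agree Fraction of trans-motif transcription factors whose
#'   differential expression direction matches the planted motif direction.
#' @param n_tads,enhancers_per_tad,redundancy_correlation Expression-context
#'   parameters: number of TADs in the toy genome, enhancers per TAD, and
#'   the expected Pearson correlation between a redundant enhancer and its
#'   focal element.
#' @param n_expression_samples Columns of the simulated expression matrix.
#' @param seed Integer seed; the whole simulation is deterministic given
#'   the config (including this seed).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_pairs = 500,
                              biotype_proportions = c(eRNA = 1 / 3,
                                                      lncRNA = 1 / 3,
                                                      mRNA = 1 / 3),
                              frac_conserved = 0.5,
                              n_negative_controls = 100,
                              n_positive_controls = 4,
                              barcodes_per_class = c(TSS = 13,
                                                     negative = 3,
                                                     positive = 60),
                              n_replicates = 3,
                              dna_depth = 5e6,
                              rna_depth = 5e6,
                              nb_dispersion = 0.05,
                              cis_effect_sd = 1.0,
                              trans_effect_sd = 0.5,
                              frac_cis = 0.4,
                              frac_trans = 0.18,
                              frac_compensatory = 0.5,
                              cis_trans_odds = 2,
                              n_motifs = 20,
                              motif_effect_sd = 0.5,
                              frac_tf_agree = 0.66,
                              n_tads = 20,
                              enhancers_per_tad = 10,
                              redundancy_correlation = 0.8,
                              n_expression_samples = 200,
                              seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs),
    biotype_proportions = biotype_proportions,
    frac_conserved = frac_conserved,
    n_negative_controls = as.integer(n_negative_controls),
    n_positive_controls = as.integer(n_positive_controls),
    barcodes_per_class = barcodes_per_class,
    n_replicates = as.integer(n_replicates),
    dna_depth = dna_depth,
    rna_depth = rna_depth,
    nb_dispersion = nb_dispersion,
    cis_effect_sd = cis_effect_sd,
    trans_effect_sd = trans_effect_sd,
    frac_cis = frac_cis,
    frac_trans = frac_trans,
    frac_compensatory = frac_compensatory,
    cis_trans_odds = cis_trans_odds,
    n_motifs = as.integer(n_motifs),
    motif_effect_sd = motif_effect_sd,
    frac_tf_agree = frac_tf_agree,
    n_tads = as.integer(n_tads),
    enhancers_per_tad = as.integer(enhancers_per_tad),
    redundancy_correlation = redundancy_correlation,
    n_expression_samples = as.integer(n_expression_samples),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fracs <- c(cfg$frac_cis, cfg$frac_trans, cfg$frac_compensatory,
             cfg$frac_tf_agree, cfg$frac_conserved)
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    stop("configuration error: fractions must lie in [0, 1]", call. = FALSE)
  }
  bp <- cfg$biotype_proportions
  if (is.null(names(bp)) || !setequal(names(bp), c("eRNA", "lncRNA", "mRNA"))) {
    stop("configuration error: biotype_proportions must be named eRNA/lncRNA/mRNA",
         call. = FALSE)
  }
  if (any(bp < 0) || abs(sum(bp) - 1) > 1e-8) {
    stop("configuration error: biotype proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  counts <- c(cfg$n_pairs, cfg$n_negative_controls, cfg$n_positive_controls,
              cfg$barcodes_per_class, cfg$n_replicates, cfg$n_motifs,
              cfg$n_tads, cfg$enhancers_per_tad, cfg$n_expression_samples)
  if (any(counts <= 0)) {
    stop("configuration error: all counts must be positive", call. = FALSE)
  }
  if (!setequal(names(cfg$barcodes_per_class), c("TSS", "negative", "positive"))) {
    stop("configuration error: barcodes_per_class must be named TSS/negative/positive",
         call. = FALSE)
  }
  if (cfg$dna_depth <= 0 || cfg$rna_depth <= 0 || cfg$nb_dispersion < 0) {
    stop("configuration error: depths must be positive and dispersion non-negative",
         call. = FALSE)
  }
  if (cfg$redundancy_correlation < 0 || cfg$redundancy_correlation > 1) {
    stop("configuration error: redundancy_correlation must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$cis_trans_odds <= 0) {
    stop("configuration error: cis_trans_odds must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Fields missing from the file fall back to the defaults of
#' [simulation_config()].
#'
#' @param path Path to a YAML file whose top-level keys are
#'   `simulation_config()` argument names.
#' @return A `sim_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("configuration error: unknown fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("biotype_proportions", "barcodes_per_class", "frac_conserved")) {
    if (!is.null(raw[[nm]]) && is.list(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(simulation_config, raw)
}
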