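# End-to-end pipeline: simulate -> quantify -> differential -> compensation
# -> motifs -> redundancy, with optional TSV/JSON outputs and a
# machine-readable report.

#' Run the full analysis pipeline on simulated data
#'
#' Generates a library with known ground truth from `config`, quantifies
#' activity, scans the five effect axes against null differential
#' controls, calibrates the empirical FDR, classifies cis-trans
#' compensation, fits the motif model families, and scores enhancer
#' redundancy. All stage outputs are returned; when `outdir` is given
#' they are also written as TSV/BED/FASTA/JSON files.
#'
#' @param config A [simulation_config()]; its seed drives every stage.
#' @param outdir Optional output directory (created if missing).
#' @param n_null_per_tile Null pseudo-pairs per positive-control tile.
#' @param scan_sequences Whether to run the PWM scanner over the emitted
#'   sequences to build the motif presence matrix (otherwise the
#'   generator's planted presence is used).
#' @return A list of stage results plus `report` (summary statistics).
#' @export
run_pipeline <- function(config, outdir = NULL, n_null_per_tile = 50,
                         scan_sequences = FALSE) {
  validate_config(config)
  log_note <- function(...) message("[pipeline] ", ...)

  log_note("simulate: ", config$n_pairs, " pairs")
  sim <- simulate_truth(config)
  counts <- simulate_counts(sim, config)
  seqs <- simulate_sequences(sim, config)
  ctx <- simulate_cage_context(sim, config)
  catalog <- sim$catalog

  log_note("quantify")
  kept <- filter_by_dna_representation(counts$dna, sim$barcode_map)
  log_note("DNA filter: ", length(kept), " of ", nrow(catalog),
           " elements kept")
  obs <- compute_log_ratios(counts$dna, counts$rna, elements = kept)
  activity <- estimate_activity(obs)
  neg_ids <- catalog$element_id[catalog$class == "negative"]
  activity <- test_active(activity, neg_ids)

  log_note("differential")
  pos_ids <- intersect(catalog$element_id[catalog$class == "positive"], kept)
  nulls <- build_null_pairs(sim$barcode_map, pos_ids,
                            n_per_tile = n_null_per_tile,
                            seed = config$seed + 4L)
  scan <- run_effect_scans(obs, catalog, nulls, activity)
  assigned <- assign_effects(scan)
  effects <- assigned$effects
  pair_meta <- sim$truth$pairs[, c("pair_id", "biotype", "conserved")]
  effects <- merge(effects, pair_meta, by = "pair_id", sort = TRUE)

  log_note("compensation")
  tested <- !is.na(effects$cis_significant) & !is.na(effects$trans_significant)
  cooc <- cooccurrence_test(effects$cis_significant[tested],
                            effects$trans_significant[tested])
  classes <- classify_pairs(effects)
  native_cmp <- tryCatch(
    compare_native_by_class(
      stats::setNames(effects$native_effect, effects$pair_id),
      stats::setNames(classes$calls$class, classes$calls$pair_id)[
        effects$pair_id]),
    error = function(e) list(p = NA_real_, message = conditionMessage(e)))

  log_note("motifs")
  tss <- catalog[catalog$class == "TSS", ]
  if (scan_sequences) {
    hits <- scan_motif_set(seqs$sequences[tss$element_id], seqs$pwms)
    presence <- build_motif_matrix(hits, tss$element_id,
                                   names(seqs$pwms))
  } else {
    presence <- sim$truth$presence[tss$element_id, , drop = FALSE]
  }
  comp_tab <- composition_table(seqs$sequences[tss$element_id])
  mean_act <- tapply(activity$alpha, activity$element_id, mean)
  mean_act <- stats::setNames(as.numeric(mean_act), names(mean_act))
  tf_table <- data.frame(motif_id = sim$truth$motifs$motif_id,
                         tf = sim$truth$motifs$tf,
                         expr_hESC = ctx$tf_de$expr_hESC,
                         expr_mESC = ctx$tf_de$expr_mESC,
                         stringsAsFactors = FALSE)
  act_models <- tryCatch(
    motif_activity_models(presence, mean_act, comp_tab, tf_table),
    error = function(e) NULL)

  pair_ids <- unique(tss$pair_id)
  pairs_df <- data.frame(pair_id = pair_ids,
                         human_id = paste0(pair_ids, "_human"),
                         mouse_id = paste0(pair_ids, "_mouse"),
                         stringsAsFactors = FALSE)
  ind <- pair_motif_indicators(presence, pairs_df)
  pc <- pair_composition(comp_tab, pairs_df)
  cis_named <- stats::setNames(effects$cis_effect, effects$pair_id)[pair_ids]
  cis_models <- motif_cis_models(ind$disrupted, cis_named, pc)

  # per-sequence trans effects from the calibrated per-axis results
  tr <- assigned$annotated$trans
  tr_real <- tr[!tr$is_null, ]
  trans_by_el <- stats::setNames(
    tr_real$effect,
    ifelse(tr_real$axis == "trans_human_seq",
           paste0(tr_real$unit_id, "_human"),
           paste0(tr_real$unit_id, "_mouse")))
  trans_models <- motif_trans_models(presence, trans_by_el, comp_tab)

  motif_tf <- sim$truth$motifs[, c("motif_id", "tf")]
  agreement <- direction_agreement(trans_models, ctx$tf_de, motif_tf)

  cis_sig_named <- stats::setNames(effects$cis_significant,
                                   effects$pair_id)[pair_ids]
  shared <- tryCatch(
    compare_shared_motifs(presence, pairs_df, unname(cis_sig_named)),
    error = function(e) NULL)
  enrich <- biotype_enrichment(
    presence, stats::setNames(tss$biotype, tss$element_id))

  log_note("redundancy")
  elements <- data.frame(id = ctx$elements$pair_id,
                         chromosome = ctx$elements$chromosome,
                         position = ctx$elements$position,
                         stringsAsFactors = FALSE)
  enhancers <- data.frame(id = ctx$enhancers$enhancer_id,
                          chromosome = ctx$enhancers$chromosome,
                          position = ctx$enhancers$position,
                          stringsAsFactors = FALSE)
  red <- redundancy_scores(elements, enhancers, ctx$tads, ctx$expression)
  red$class <- stats::setNames(classes$calls$class,
                               classes$calls$pair_id)[red$id]
  red$class[is.na(red$class)] <- "untested"
  red$tad_id <- ctx$elements$tad_id[match(red$id, ctx$elements$pair_id)]
  red_cmp <- tryCatch(dedupe_downsample(red, seed = config$seed + 5L),
                      error = function(e) list(message = conditionMessage(e)))

  sig_frac <- function(flag) {
    f <- flag[!is.na(flag)]
    if (length(f) == 0) NA_real_ else mean(f)
  }
  report <- list(
    n_pairs = config$n_pairs,
    n_elements = nrow(catalog),
    n_elements_kept = length(kept),
    n_pairs_tested = nrow(effects),
    n_null_pairs = length(unique(scan$unit_id[scan$is_null])),
    frac_active_hESC = sig_frac(
      activity$active[activity$environment == "hESC" &
                        activity$element_id %in% tss$element_id]),
    frac_active_mESC = sig_frac(
      activity$active[activity$environment == "mESC" &
                        activity$element_id %in% tss$element_id]),
    frac_cis_significant = sig_frac(effects$cis_significant),
    frac_trans_significant = sig_frac(effects$trans_significant),
    frac_native_significant = sig_frac(effects$native_significant),
    calibration = assigned$calibration,
    cooccurrence = cooc[c("odds_ratio", "sample_odds", "p", "n_both")],
    class_counts = as.list(table(classes$calls$class)),
    native_by_class_p = native_cmp$p,
    n_informative_motifs = if (is.null(act_models)) NA_integer_ else
      sum(act_models$informative),
    n_cis_motifs = sum(cis_models$q < 0.05, na.rm = TRUE),
    n_trans_motifs = sum(trans_models$q < 0.05, na.rm = TRUE),
    tf_direction_agreement = agreement[c("n_trans_sig", "n_de", "n_agree",
                                         "fraction_agree")],
    redundancy_comparison = red_cmp,
    seed = config$seed
  )

  result <- list(config = config, sim = sim, counts = counts,
                 sequences = seqs, context = ctx, activity = activity,
                 scan = scan, assigned = assigned, effects = effects,
                 cooccurrence = cooc, classes = classes,
                 native_comparison = native_cmp,
                 motif_presence = presence,
                 motif_activity = act_models, motif_cis = cis_models,
                 motif_trans = trans_models, motif_enrichment = enrich,
                 shared_motifs = shared, tf_agreement = agreement,
                 redundancy = red, redundancy_comparison = red_cmp,
                 report = report)

  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

# mean and absolute-difference composition covariates per pair
pair_composition <- function(composition, pairs) {
  h <- composition[match(pairs$human_id, composition$element_id), ]
  m <- composition[match(pairs$mouse_id, composition$element_id), ]
  data.frame(pair_id = pairs$pair_id,
             mean_gc = (h$gc_content + m$gc_content) / 2,
             mean_cpg = (h$cpg_rate + m$cpg_rate) / 2,
             abs_d_gc = abs(h$gc_content - m$gc_content),
             abs_d_cpg = abs(h$cpg_rate - m$cpg_rate),
             stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tsv(result$sim$catalog, p("catalog.tsv"))
  write_tsv(result$sim$barcode_map, p("barcode_map.tsv"))
  write_tsv(result$counts$dna, p("dna_counts.tsv"))
  write_tsv(result$counts$rna, p("rna_counts.tsv"))
  write_tsv(result$activity, p("activity.tsv"))
  write_tsv(result$scan, p("effects.tsv"))
  write_tsv(result$effects, p("assigned_effects.tsv"))
  write_tsv(result$classes$calls, p("compensation.tsv"))
  if (!is.null(result$motif_activity)) {
    write_tsv(result$motif_activity, p("motif_activity.tsv"))
  }
  write_tsv(result$motif_cis, p("motif_cis.tsv"))
  write_tsv(result$motif_trans, p("motif_trans.tsv"))
  write_tsv(result$motif_enrichment, p("motif_enrichment.tsv"))
  write_tsv(result$redundancy, p("redundancy.tsv"))
  write_tsv(result$context$tf_de, p("tf_de.tsv"))
  write_bed(result$context$tads, p("tads.bed"), name_col = "tad_id")
  write_fasta(result$sequences$sequences, p("sequences.fa"))
  write_meme(result$sequences$pwms, p("motifs.meme"))
  expr <- data.frame(id = rownames(result$context$expression),
                     result$context$expression, check.names = FALSE)
  write_tsv(expr, p("expression.tsv"))
  jsonlite::write_json(truth_as_json(result$sim$truth), p("truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$report, p("report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

truth_as_json <- function(truth) {
  list(activity = truth$activity,
       pairs = truth$pairs,
       motifs = truth$motifs,
       alpha_offset = truth$alpha_offset,
       alpha_negative = truth$alpha_negative,
       alpha_positive = truth$alpha_positive)
}
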