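# Sequence composition, PWM scanning against the exact discretised null,
# MEME/FIMO round-trips, the three model families, shared-motif and
# enrichment analyses, and TF direction agreement.

test_that("composition handles the documented cases", {
  expect_equal(sequence_composition("ACGT")$gc_content, 0.5)
  expect_equal(sequence_composition("CGCG")$cpg_rate, 2 / 3)
  comp <- sequence_composition("AAAA")
  expect_equal(comp$gc_content, 0)
  expect_equal(comp$cpg_rate, 0)
  expect_equal(sequence_composition("acgt")$gc_content, 0.5)
  expect_error(sequence_composition(""), "empty")
  expect_error(sequence_composition("NNNN"), "ACGT")
})

test_that("scanner finds planted consensus on both strands", {
  cons <- "ACGTACGT"
  pwm <- matrix(0.01, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(match(strsplit(cons, "")[[1]], rownames(pwm)), 1:8)] <- 0.97
  seq_fwd <- paste0(strrep("A", 20), cons, strrep("T", 20))
  h <- scan_motifs(seq_fwd, pwm)
  expect_true(any(h$strand == "+" & h$start == 21))
  # reverse complement of the consensus hits on the minus strand
  rc <- "ACGTACGT"  # palindromic-free check below uses a non-palindrome
  cons2 <- "AAACGTTC"
  pwm2 <- matrix(0.01, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm2[cbind(match(strsplit(cons2, "")[[1]], rownames(pwm2)), 1:8)] <- 0.97
  rc2 <- paste(rev(strsplit(chartr("ACGT", "TGCA", cons2), "")[[1]]),
               collapse = "")
  seq_rev <- paste0(strrep("G", 15), rc2, strrep("G", 15))
  h2 <- scan_motifs(seq_rev, pwm2)
  expect_true(any(h2$strand == "-"))
  expect_error(scan_motifs("ACGT", matrix(1, 3, 4)), "malformed")
})

test_that("hit rate on random sequence matches the exact null", {
  set.seed(10)
  pwm <- consensus_pwm_fixture()
  seqs <- vapply(1:1000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 144, replace = TRUE), collapse = "")
  }, character(1))
  n_windows <- 1000 * (144 - 8 + 1) * 2
  hits <- sum(vapply(seqs, function(s) nrow(scan_motifs(s, pwm)),
                     numeric(1)))
  # per-window hit probability is at most the 1e-4 threshold (discrete
  # score support makes it conservative); binomial 3-sigma band
  p_hit <- hits / n_windows
  expect_lt(p_hit, 1e-4 + 3 * sqrt(1e-4 / n_windows))
  expect_gt(hits, 0)
})

test_that("MEME and FIMO round-trips preserve hits", {
  set.seed(11)
  pwms <- list(M1 = consensus_pwm_fixture(),
               M2 = consensus_pwm_fixture("TTGACGTC"))
  path <- tempfile(fileext = ".meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_equal(back$M1, pwms$M1, tolerance = 1e-5)
  expect_equal(back$M2, pwms$M2, tolerance = 1e-5)

  seqs <- c(s1 = paste0(strrep("A", 30), "ACGTACGT", strrep("C", 30)),
            s2 = paste0(strrep("G", 40), "TTGACGTC", strrep("A", 40)))
  hits <- scan_motif_set(seqs, pwms)
  fimo_path <- tempfile(fileext = ".tsv")
  write_fimo(hits, fimo_path)
  ingested <- read_fimo(fimo_path)
  expect_equal(nrow(ingested), nrow(hits))
  expect_equal(ingested$start, hits$start)
  expect_equal(ingested$p.value, hits$p.value, tolerance = 1e-12)
  m <- build_motif_matrix(ingested, names(seqs))
  expect_true(m["s1", "M1"] && m["s2", "M2"])
})

test_that("activity model recovers a planted activator and controls type I error", {
  set.seed(12)
  n <- 300
  gc <- runif(n, 0.3, 0.7)
  cpg <- runif(n, 0, 0.2)
  present <- rbinom(n, 1, 0.4) == 1
  y <- 0.5 + 2 * gc + 1 * present + rnorm(n, 0, 0.4)
  presence <- matrix(present, n, 1,
                     dimnames = list(sprintf("e%03d", 1:n), "M1"))
  comp <- data.frame(element_id = rownames(presence), gc_content = gc,
                     cpg_rate = cpg)
  res <- motif_activity_models(presence, setNames(y, rownames(presence)),
                               comp)
  expect_lt(res$q, 0.05)
  expect_equal(res$beta, 1, tolerance = 0.2)
  expect_equal(res$class, "activator")
  expect_gt(res$variance_explained, 0)

  # permuted indicators: ~5% of p-values under 0.05
  ps <- vapply(1:400, function(i) {
    perm <- matrix(sample(present), n, 1,
                   dimnames = dimnames(presence))
    motif_activity_models(perm, setNames(y, rownames(presence)), comp)$p
  }, numeric(1))
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.5)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("repressors get negative coefficients and collinearity attenuates", {
  set.seed(13)
  n <- 200
  gc <- runif(n, 0.3, 0.7)
  present <- rbinom(n, 1, 0.5) == 1
  y <- 1 - 0.8 * present + rnorm(n, 0, 0.3)
  presence <- matrix(present, n, 1,
                     dimnames = list(sprintf("e%03d", 1:n), "M1"))
  comp <- data.frame(element_id = rownames(presence), gc_content = gc,
                     cpg_rate = 0)
  res <- motif_activity_models(presence, setNames(y, rownames(presence)),
                               comp)
  expect_equal(res$class, "repressor")
  expect_lt(res$beta, 0)
})

test_that("cis model recovers a planted disruption effect", {
  set.seed(14)
  n <- 200
  disrupted <- rbinom(n, 1, 0.3) == 1
  pc <- data.frame(pair_id = sprintf("p%03d", 1:n),
                   mean_gc = runif(n, 0.3, 0.7), mean_cpg = runif(n, 0, 0.1),
                   abs_d_gc = abs(rnorm(n, 0, 0.05)),
                   abs_d_cpg = abs(rnorm(n, 0, 0.02)))
  cis <- setNames(0.2 + 0.8 * disrupted + abs(rnorm(n, 0, 0.2)), pc$pair_id)
  dis <- matrix(disrupted, n, 1, dimnames = list(pc$pair_id, "M1"))
  res <- motif_cis_models(dis, cis, pc)
  expect_equal(res$beta, 0.8, tolerance = 0.2)
  expect_lt(res$q, 0.05)
  # all-zero disruption indicator is skipped
  dis0 <- matrix(FALSE, n, 1, dimnames = list(pc$pair_id, "M1"))
  expect_equal(nrow(motif_cis_models(dis0, cis, pc)), 0)
})

test_that("disruption direction matches the activator sign convention", {
  # planted activator disrupted in human -> mouse keeps the motif ->
  # mouse more active -> positive cis effects for disrupted-in-human
  fx <- full_pipeline()
  tp <- fx$sim$truth$pairs
  motifs <- fx$sim$truth$motifs
  eff <- fx$effects
  act_motifs <- motifs$motif_id[motifs$class == "activator" &
                                  !motifs$is_trans_motif]
  m <- merge(eff, tp, by = "pair_id")
  dh <- m$cis_effect[!is.na(m$disrupted_motif) &
                       m$disrupted_motif %in% act_motifs &
                       m$disrupted_in == "human"]
  dm <- m$cis_effect[!is.na(m$disrupted_motif) &
                       m$disrupted_motif %in% act_motifs &
                       m$disrupted_in == "mouse"]
  expect_gt(mean(dh, na.rm = TRUE), mean(dm, na.rm = TRUE))
})

test_that("trans model recovers planted trans motifs with the right sign", {
  fx <- full_pipeline()
  motifs <- fx$sim$truth$motifs
  res <- fx$motif_trans
  m <- merge(res, motifs, by = "motif_id")
  planted <- m[m$is_trans_motif, ]
  expect_gt(nrow(planted), 0)
  sig <- planted[planted$q < 0.05, ]
  expect_gte(nrow(sig), ceiling(nrow(planted) / 2))
  expect_true(all(sign(sig$beta) == sig$trans_direction))
  # identical presence vectors give identical results
  pres <- fx$motif_presence
  dup <- cbind(pres[, 1, drop = FALSE], pres[, 1, drop = FALSE])
  colnames(dup) <- c("A1", "A2")
  tr <- fx$assigned$annotated$trans
  tr <- tr[!tr$is_null, ]
  trans_by_el <- setNames(tr$effect,
                          ifelse(tr$axis == "trans_human_seq",
                                 paste0(tr$unit_id, "_human"),
                                 paste0(tr$unit_id, "_mouse")))
  comp <- composition_table(fx$sequences$sequences[rownames(pres)])
  r2 <- motif_trans_models(dup, trans_by_el, comp)
  if (nrow(r2) == 2) {
    expect_equal(r2$beta[1], r2$beta[2])
    expect_equal(r2$p[1], r2$p[2])
  }
})

test_that("shared-motif fraction is the Jaccard index", {
  expect_equal(shared_motif_fraction(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(shared_motif_fraction(c("A"), c("A")), 1.0)
  expect_true(is.na(shared_motif_fraction(character(0), character(0))))
})

test_that("no-cis pairs share more motifs when cis truth is motif-driven", {
  fx <- full_pipeline()
  tss <- fx$sim$catalog[fx$sim$catalog$class == "TSS", ]
  pair_ids <- unique(tss$pair_id)
  pairs_df <- data.frame(pair_id = pair_ids,
                         human_id = paste0(pair_ids, "_human"),
                         mouse_id = paste0(pair_ids, "_mouse"),
                         stringsAsFactors = FALSE)
  cis_sig <- setNames(fx$effects$cis_significant,
                      fx$effects$pair_id)[pair_ids]
  r <- compare_shared_motifs(fx$motif_presence, pairs_df, unname(cis_sig))
  expect_lt(r$p, 0.05)
  expect_gte(r$median_no_cis, r$median_cis)
})

test_that("hypergeometric enrichment equals the brute-force tail sum", {
  # exact oracle on a small universe
  brute_tail <- function(k, K, n_b, N) {
    sum(vapply(k:min(K, n_b), function(i) {
      choose(K, i) * choose(N - K, n_b - i) / choose(N, n_b)
    }, numeric(1)))
  }
  set.seed(15)
  for (rep in 1:20) {
    N <- sample(10:30, 1)
    K <- sample(2:(N - 2), 1)
    ids <- sprintf("e%02d", 1:N)
    pres <- matrix(FALSE, N, 1, dimnames = list(ids, "M1"))
    pres[sample(N, K), 1] <- TRUE
    bio <- setNames(sample(c("mRNA", "eRNA"), N, replace = TRUE), ids)
    res <- biotype_enrichment(pres, bio)
    for (i in seq_len(nrow(res))) {
      expect_equal(res$p[i],
                   brute_tail(res$overlap[i], res$n_motif[i],
                              res$n_biotype[i], res$universe[i]),
                   tolerance = 1e-12)
    }
  }
  # motif present everywhere -> p = 1 in every biotype
  presall <- matrix(TRUE, 10, 1,
                    dimnames = list(sprintf("e%02d", 1:10), "M1"))
  bio <- setNames(rep(c("mRNA", "eRNA"), 5), rownames(presall))
  expect_true(all(biotype_enrichment(presall, bio)$p == 1))
})

test_that("direction agreement joins trans betas with the DE table", {
  trans_results <- data.frame(motif_id = c("M1", "M2", "M3", "M4"),
                              beta = c(0.5, 0.4, -0.3, 0.2),
                              p = 1e-4, q = c(0.01, 0.01, 0.01, 0.5),
                              stringsAsFactors = FALSE)
  motif_tf <- data.frame(motif_id = c("M1", "M2", "M3", "M4"),
                         tf = c("TFA", "TFB", "TFC", "TFD"),
                         stringsAsFactors = FALSE)
  tf_de <- data.frame(gene = c("TFA", "TFB", "TFC"),
                      log2fc_mESC_vs_hESC = c(2, -2, 0.5),
                      qvalue = c(1e-5, 1e-5, 1e-5),
                      stringsAsFactors = FALSE)
  r <- direction_agreement(trans_results, tf_de, motif_tf)
  per <- r$per_tf
  expect_true(per$agree[per$tf == "TFA"])    # beta > 0, lfc +2
  expect_false(per$agree[per$tf == "TFB"])   # beta > 0, lfc -2
  expect_false(per$is_de[per$tf == "TFC"])   # |lfc| < 1: not DE
  expect_equal(r$n_de, 2)
  expect_equal(r$n_agree, 1)
  expect_equal(r$fraction_agree, 0.5)
  expect_false("M4" %in% per$motif_id)       # not trans-significant
})

test_that("planted TF direction agreement emerges end to end", {
  fx <- full_pipeline()
  ag <- fx$tf_agreement
  expect_gt(ag$n_de, 0)
  # oracle: the agreement fraction should track the planted fraction of
  # DE TFs whose expression direction matches their motif's planted
  # trans direction (betas recover the planted sign)
  motifs <- fx$sim$truth$motifs
  per <- ag$per_tf[ag$per_tf$is_de %in% TRUE, ]
  planted_dir <- motifs$trans_direction[match(per$motif_id,
                                              motifs$motif_id)]
  planted_agree <- mean(planted_dir == sign(per$log2fc))
  expect_equal(ag$fraction_agree, planted_agree, tolerance = 0.35)
})
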