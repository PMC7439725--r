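# Differential effects: null pseudo-pair construction, the two-group
# effect test, the five-axis scan with its algebraic identities,
# empirical-FDR calibration, and per-pair effect assignment.

test_that("null pseudo-pairs are disjoint 13-barcode subsets of a 60-barcode pool", {
  bm <- data.frame(barcode_id = sprintf("bc%02d", 1:60), element_id = "pos1",
                   stringsAsFactors = FALSE)
  np <- build_null_pairs(bm, "pos1", n_per_tile = 5, seed = 3)
  expect_equal(length(unique(np$null_id)), 5)
  for (id in unique(np$null_id)) {
    sub <- np[np$null_id == id, ]
    a <- sub$barcode_id[sub$side == "A"]
    b <- sub$barcode_id[sub$side == "B"]
    expect_equal(length(a), 13)
    expect_equal(length(b), 13)
    expect_equal(length(intersect(a, b)), 0)
    expect_equal(60 - length(union(a, b)), 34)
  }
  expect_error(build_null_pairs(bm, "pos1", subset_size = 31), "too small")
  expect_identical(build_null_pairs(bm, "pos1", n_per_tile = 3, seed = 7),
                   build_null_pairs(bm, "pos1", n_per_tile = 3, seed = 7))
})

test_that("pairwise effect is the mean difference with an F-test p", {
  set.seed(1)
  jit <- rnorm(4, 0, 1e-3)
  obs <- toy_obs(c(1, 1, 1, 1) + jit, c(2, 2, 2, 2) + jit)
  r <- pairwise_effect(obs$a, obs$b)
  expect_equal(r$effect, 1.0, tolerance = 1e-2)
  expect_lt(r$p, 0.01)
  # identical groups: zero effect, p = 1
  same <- data.frame(log_ratio = c(1, 2, 3, 4), replicate = c(1, 1, 2, 2))
  r0 <- pairwise_effect(same, same)
  expect_equal(r0$effect, 0)
  expect_equal(r0$p, 1)
  # degenerate groups are flagged missing
  expect_null(pairwise_effect(same[1, , drop = FALSE], same))
})

test_that("p-values are uniform under the null (KS test over 1000 null pairs)", {
  # a library rich in positive-control tiles so null pseudo-pairs are
  # close to independent draws
  cfg <- simulation_config(n_pairs = 2, n_negative_controls = 25,
                           n_positive_controls = 250, seed = 99)
  sim <- simulate_truth(cfg)
  counts <- simulate_counts(sim, cfg)
  obs <- compute_log_ratios(counts$dna, counts$rna)
  pos <- sim$catalog$element_id[sim$catalog$class == "positive"]
  nulls <- build_null_pairs(sim$barcode_map, pos, n_per_tile = 4, seed = 7)
  scan <- run_effect_scans(obs, sim$catalog, nulls, activity = NULL)
  for (ax in c("cis_hESC", "trans_human_seq", "native")) {
    ps <- scan$p[scan$is_null & scan$axis == ax]
    expect_gte(length(ps), 1000)
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  }
})

test_that("pure cis truth is recovered on the cis axes and absent on trans", {
  # constructed pair: mouse sequence +1 in both environments
  set.seed(5)
  mk <- function(mu) {
    do.call(rbind, lapply(1:3, function(rep) {
      data.frame(barcode_id = sprintf("b%02d", 1:13),
                 replicate = rep, log_ratio = rnorm(13, mu, 0.2))
    }))
  }
  obs <- rbind(
    transform(mk(0), element_id = "p1_human", environment = "hESC"),
    transform(mk(0), element_id = "p1_human", environment = "mESC"),
    transform(mk(1), element_id = "p1_mouse", environment = "hESC"),
    transform(mk(1), element_id = "p1_mouse", environment = "mESC")
  )
  catalog <- data.frame(element_id = c("p1_human", "p1_mouse"),
                        pair_id = "p1", species = c("human", "mouse"),
                        class = "TSS", stringsAsFactors = FALSE)
  scan <- run_effect_scans(obs, catalog)
  se <- 0.2 / sqrt(39) * sqrt(2)
  cis_h <- scan$effect[scan$axis == "cis_hESC"]
  expect_lt(abs(cis_h - 1), 3 * se)
  expect_lt(abs(scan$effect[scan$axis == "trans_mouse_seq"]), 3 * se)
  # plug-in additivity holds exactly
  expect_equal(scan$effect[scan$axis == "native"],
               scan$effect[scan$axis == "cis_hESC"] +
                 scan$effect[scan$axis == "trans_mouse_seq"])
})

test_that("species swap negates cis and native; environment swap negates trans", {
  fx <- small_quantified()
  cat0 <- fx$sim$catalog
  pid <- unique(cat0$pair_id[cat0$class == "TSS"])[1:5]
  cat <- cat0[cat0$pair_id %in% pid, ]
  obs <- fx$obs[fx$obs$element_id %in% cat$element_id, ]
  scan <- run_effect_scans(obs, cat)

  swap_species <- function(x) {
    sub("_tmp$", "_mouse", sub("_mouse$", "_human", sub("_human$", "_tmp", x)))
  }
  swap_env <- function(x) ifelse(x == "hESC", "mESC", "hESC")

  obs_sw <- transform(obs, element_id = swap_species(element_id))
  key <- function(s) s[order(s$unit_id, s$axis), ]
  s0 <- key(scan)
  s1 <- key(run_effect_scans(obs_sw, cat))
  for (ax in c("cis_hESC", "cis_mESC")) {
    expect_equal(s1$effect[s1$axis == ax], -s0$effect[s0$axis == ax],
                 tolerance = 1e-10)
  }
  # trans axes swap roles between the sequences but keep their sign
  expect_equal(s1$effect[s1$axis == "trans_human_seq"],
               s0$effect[s0$axis == "trans_mouse_seq"], tolerance = 1e-10)

  # swap environments: relabel hESC <-> mESC
  obs_env <- transform(obs, environment = swap_env(environment))
  scan_env <- key(run_effect_scans(obs_env, cat))
  for (ax in c("trans_human_seq", "trans_mouse_seq")) {
    expect_equal(scan_env$effect[scan_env$axis == ax],
                 -s0$effect[s0$axis == ax], tolerance = 1e-10)
  }

  # the native comparison swaps both its sequence and its environment,
  # so it negates under the combined species + environment relabelling
  obs_both <- transform(obs_sw, environment = swap_env(environment))
  scan_both <- key(run_effect_scans(obs_both, cat))
  expect_equal(scan_both$effect[scan_both$axis == "native"],
               -s0$effect[s0$axis == "native"], tolerance = 1e-10)
})

test_that("empirical-FDR calibration follows the order-statistic rule", {
  # 100 nulls: 9 q-values below 0.2, the 10th smallest is 0.25
  nq <- c(seq(0.02, 0.18, length.out = 9), 0.25,
          seq(0.3, 0.99, length.out = 90))
  eff <- seq(0.1, 1.08, length.out = 100)
  nulls <- data.frame(unit_id = sprintf("n%03d", 1:100), axis = "cis_hESC",
                      is_null = TRUE, effect = eff, p = nq, q = nq)
  reals <- data.frame(unit_id = sprintf("r%03d", 1:50), axis = "cis_hESC",
                      is_null = FALSE, effect = rep(c(0.05, 2), 25),
                      p = rep(c(0.01, 0.5), 25), q = rep(c(0.01, 0.5), 25))
  cal <- calibrate_empirical_fdr(rbind(nulls, reals))
  expect_gt(cal$q_cutoff, sort(nq)[9])
  expect_lte(cal$q_cutoff, sort(nq)[10])
  expect_lte(sum(nulls$q < cal$q_cutoff), 9)
  expect_lt(cal$achieved_null_rate, 0.10)
  expect_equal(cal$effect_floor, min(abs(eff[nq < cal$q_cutoff])))
  # significant reals need q under the cutoff AND an effect above the floor
  sig <- cal$results[!cal$results$is_null & cal$results$significant, ]
  expect_true(all(abs(sig$effect) > cal$effect_floor))
  expect_true(all(sig$q < cal$q_cutoff))

  # degenerate: every null at q = 1 -> no null significant, floor 0,
  # every real below the cutoff passes
  nulls_hi <- transform(nulls, q = 1, p = 1)
  cal2 <- calibrate_empirical_fdr(rbind(nulls_hi, reals))
  expect_equal(cal2$effect_floor, 0)
  expect_equal(cal2$achieved_null_rate, 0)
  expect_true(all(cal2$results$significant[!cal2$results$is_null &
                                             cal2$results$q < 1]))
  expect_error(calibrate_empirical_fdr(reals), "no null")
})

test_that("pair effect assignment follows the max-|effect|-unless rule", {
  r <- assign_pair_effect(0.8, 0.5, TRUE, TRUE)
  expect_equal(r$effect, 0.8)
  expect_true(r$significant)
  r <- assign_pair_effect(0.8, -0.5, FALSE, TRUE)
  expect_equal(r$effect, -0.5)
  expect_true(r$significant)
  r <- assign_pair_effect(0.3, -0.6, FALSE, FALSE)
  expect_equal(r$effect, -0.6)
  expect_false(r$significant)
  expect_null(assign_pair_effect(NA, NA, NA, NA))
  # tie in absolute value goes to the first model
  expect_equal(assign_pair_effect(0.5, -0.5, TRUE, TRUE)$effect, 0.5)
})

test_that("assigned effects recover planted cis and trans truth (r >= 0.9)", {
  fx <- small_scanned()
  eff <- fx$assigned$effects
  tp <- fx$sim$truth$pairs
  m <- merge(eff, tp, by = "pair_id")
  expect_gte(cor(m$cis_effect, m$cis_true, use = "complete.obs"), 0.9)
  expect_gte(cor(m$trans_effect, m$trans_mouse_true, use = "complete.obs"),
             0.9)
  # cis estimates agree across environments when truth is shared
  ann <- fx$assigned$annotated$cis
  real <- ann[!ann$is_null, ]
  ch <- real$effect[real$axis == "cis_hESC"]
  cm <- real$effect[real$axis == "cis_mESC"]
  expect_gte(cor(ch, cm, use = "complete.obs"), 0.9)
})

test_that("null significant fraction stays under 10% and null-truth leakage under 15%", {
  fps <- vapply(1:3, function(s) {
    cfg <- simulation_config(n_pairs = 100, n_negative_controls = 40,
                             frac_cis = 0, frac_trans = 0, seed = 100 + s)
    sim <- simulate_truth(cfg)
    counts <- simulate_counts(sim, cfg)
    kept <- filter_by_dna_representation(counts$dna, sim$barcode_map)
    obs <- compute_log_ratios(counts$dna, counts$rna, elements = kept)
    activity <- test_active(estimate_activity(obs),
                            sim$catalog$element_id[sim$catalog$class ==
                                                     "negative"])
    pos <- sim$catalog$element_id[sim$catalog$class == "positive"]
    nulls <- build_null_pairs(sim$barcode_map, pos, n_per_tile = 30,
                              seed = cfg$seed + 4L)
    scan <- run_effect_scans(obs, sim$catalog, nulls, activity)
    assigned <- assign_effects(scan, min_nulls = 50)
    for (fam in c("cis", "trans", "native")) {
      expect_lt(assigned$calibration[[fam]]$achieved_null_rate, 0.10)
    }
    # per-model false-positive rate among null-truth real pairs
    ann <- assigned$annotated$cis
    mean(ann$significant[!ann$is_null], na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(fps), 0.15)
})
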