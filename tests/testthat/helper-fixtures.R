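# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small library: fast, used by most module tests
small_config <- function(seed = 42) {
  simulation_config(n_pairs = 150, n_negative_controls = 60, seed = seed)
}

small_sim <- function() {
  cached("small_sim", function() {
    cfg <- small_config()
    sim <- simulate_truth(cfg)
    counts <- simulate_counts(sim, cfg)
    list(cfg = cfg, sim = sim, counts = counts)
  })
}

small_quantified <- function() {
  cached("small_quantified", function() {
    fx <- small_sim()
    kept <- filter_by_dna_representation(fx$counts$dna, fx$sim$barcode_map)
    obs <- compute_log_ratios(fx$counts$dna, fx$counts$rna, elements = kept)
    activity <- estimate_activity(obs)
    neg <- fx$sim$catalog$element_id[fx$sim$catalog$class == "negative"]
    activity <- test_active(activity, neg)
    c(fx, list(kept = kept, obs = obs, activity = activity))
  })
}

small_scanned <- function() {
  cached("small_scanned", function() {
    fx <- small_quantified()
    pos <- fx$sim$catalog$element_id[fx$sim$catalog$class == "positive"]
    nulls <- build_null_pairs(fx$sim$barcode_map, pos, n_per_tile = 50,
                              seed = fx$cfg$seed + 4L)
    scan <- run_effect_scans(fx$obs, fx$sim$catalog, nulls, fx$activity)
    assigned <- assign_effects(scan)
    c(fx, list(null_pairs = nulls, scan = scan, assigned = assigned))
  })
}

# full-scale run used by the acceptance tests (study-scale conditions:
# 500 pairs, 4 positive-control tiles, 200 null pseudo-pairs)
full_pipeline <- function() {
  cached("full_pipeline", function() {
    run_pipeline(simulation_config(n_pairs = 500, seed = 2024),
                 n_null_per_tile = 50)
  })
}

# a strong near-consensus PWM, built independently of the package
consensus_pwm_fixture <- function(consensus = "ACGTACGT", strength = 0.9) {
  bases <- strsplit(consensus, "")[[1]]
  pwm <- matrix((1 - strength) / 3, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm[cbind(match(bases, rownames(pwm)), seq_along(bases))] <- strength
  pwm
}

# deterministic toy observations for hand-computable effect tests
toy_obs <- function(values_a, values_b, n_rep = 2) {
  stopifnot(length(values_a) %% n_rep == 0, length(values_b) %% n_rep == 0)
  list(
    a = data.frame(log_ratio = values_a,
                   replicate = rep(seq_len(n_rep),
                                   each = length(values_a) / n_rep)),
    b = data.frame(log_ratio = values_b,
                   replicate = rep(seq_len(n_rep),
                                   each = length(values_b) / n_rep))
  )
}
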