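# Shared fixtures, built in code at test time.

# The observed tyrosol derivative pair: light 322.0083 / heavy 324.0063 at
# 9.67 min with the ~0.97 bromine isotopologue intensity ratio.
tyrosol_features <- function(ratio = 0.97, rt_heavy = 9.67) {
  ft <- data.frame(
    feature_id = c("L", "H"),
    rt = c(9.67, rt_heavy),
    mz = c(322.0083, 324.0063),
    A = c(1e6, ratio * 1e6),
    stringsAsFactors = FALSE)
  attr(ft, "sample_cols") <- "A"
  class(ft) <- c("feature_table", "data.frame")
  ft
}

# random CHNO formulas for additivity-style property checks
random_formula <- function() {
  n <- c(C = sample(1:20, 1), H = sample(1:30, 1),
         N = sample(0:3, 1), O = sample(0:6, 1))
  as_element_counts(n[n > 0])
}

quick_sim <- function(n_compounds = 10, n_decoys = 40, seed = 99, ...) {
  cfg <- sim_config(n_compounds = n_compounds, n_decoys = n_decoys,
                    seed = seed, ...)
  sim <- simulate_compounds(cfg)
  run <- simulate_features(sim, cfg)
  list(cfg = cfg, db = sim$db, run = run)
}
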