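# Shared fixtures, built once per test run and memoized. All synthetic, all
# generated in code -- no stored data files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# sensorimotor-strip montage subset: fast to simulate/filter, still gives
# every MRCP channel a full Large-Laplacian neighborhood
test_channels <- function() {
  c("F3", "F1", "Fz", "F2", "F4", "FC3", "FC1", "FCz", "FC2", "FC4",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "CP3", "CP1", "CPz", "CP2",
    "CP4", "P3", "P1", "Pz", "P2", "P4")
}

mrcp_ch <- function() c("FCz", "Cz", "CPz", "C1", "C2")

# calibration-style session (no catch trials) and its epoch set
fix_calib_session <- function() memo("calib_session", {
  generate_session(session_plan(1, trials_per_block = 14, catch_per_block = 0,
                                rng_seed = 101),
                   channels = test_channels())
})

fix_calib_epochs <- function() memo("calib_epochs", {
  make_epochs(filter_chain(fix_calib_session()))
})

# closed-loop-style session: catch trials present, cortical peak leading the
# kinematic onset as in slowed motor execution
fix_online_session <- function() memo("online_session", {
  generate_session(session_plan(1, trials_per_block = 12, catch_per_block = 3,
                                rng_seed = 202),
                   params = mrcp_params(peak_jitter_sd_s = 0.1,
                                        peak_offset_s = -0.4),
                   channels = test_channels())
})

# MRCP amplitude dominating the noise floor: the separability oracle world
fix_separable_epochs <- function() memo("separable_epochs", {
  ses <- generate_session(
    session_plan(1, trials_per_block = 14, catch_per_block = 0,
                 rng_seed = 303),
    params = mrcp_params(amplitude_uV = -12, peak_jitter_sd_s = 0.2),
    noise_level = 0.5, channels = test_channels())
  make_epochs(filter_chain(ses))
})

fix_model <- function() memo("model", {
  cv <- pseudo_online_cv(fix_calib_epochs(), 0.8, mrcp_ch(), C = 100,
                         gamma = 0.5, n_folds = 5, seed = 7)
  select_final_model(cv)
})

expect_balanced <- function(epochs) {
  keep <- !epochs$rejected
  expect_equal(sum(epochs$labels[keep] == "Go"),
               sum(epochs$labels[keep] == "No-go"))
}
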