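# Shared fixtures, built once per test run and cached. Sessions are scaled
# to keep the suite fast; the full-protocol sizes are exercised in
# scripts/acceptance.R and in test-acceptance.R where a criterion needs them.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- build()
  .fx_cache[[name]]
}

# full-protocol training session with strong modulation (d' = 2)
fx_training <- function() fx("training", function() {
  cfg <- synth_config(n_channels = 16, modulated_channels = 1:4,
                      effect_size = 2, seed = 42)
  generate_training_session(cfg)
})

fx_model <- function() fx("model", function() {
  tr <- fx_training()
  train_prediction_model(tr$rec, tr$cues, band = c(8, 12), seed = 7)
})

# chance-level (d' = 0) training session
fx_training_null <- function() fx("training_null", function() {
  cfg <- synth_config(n_channels = 16, modulated_channels = 1:4,
                      effect_size = 0, seed = 43)
  generate_training_session(cfg)
})

# strong-modulation online session, zero reaction delay, decoded end to end
fx_online <- function() fx("online", function() {
  cfg <- synth_config(n_channels = 16, modulated_channels = 1:4,
                      effect_size = 2, seed = 44)
  on <- generate_online_session(cfg, reaction_delay = 0)
  ses <- run_online_session(on$rec, fx_model(), t_i = 0.2, t_w = 0.8)
  list(cues = on$cues, session = ses,
       metrics = session_metrics(on$cues, ses))
})

# small recording builder
mk_rec <- function(n_ch = 3, dur = 2, rate = 64, seed = 1, sd = 10) {
  set.seed(seed)
  eeg_recording(matrix(stats::rnorm(n_ch * round(dur * rate), sd = sd),
                       n_ch), rate)
}

# decoded_session stub from a 0/1 walk vector on the 4 Hz clock (t = 0.75+)
mk_session <- function(walk01, step = 0.25, t0 = 0.75) {
  n <- length(walk01)
  structure(list(
    posterior = data.frame(time = t0 + step * (seq_len(n) - 1),
                           P = as.numeric(walk01),
                           P_bar = as.numeric(walk01)),
    states = data.frame(time = t0 + step * (seq_len(n) - 1),
                        state = ifelse(walk01 == 1, "WALK", "IDLE"),
                        stringsAsFactors = FALSE),
    thresholds = c(t_i = 0.4, t_w = 0.6), step = step),
    class = "decoded_session")
}
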