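# gaitbci

EEG decoding of idling vs. walking kinesthetic motor imagery (KMI) for
brain-computer-interface (BCI) control of robotic gait — offline model
training, online sliding-window decoding through a dual-threshold state
machine, session performance metrics, and a Monte-Carlo significance
control, all exercisable on calibrated synthetic EEG.

**Who it is for:** neural-engineering researchers prototyping self-paced
two-state BCIs, and anyone who needs a fully testable reference
implementation of this decoding chain without access to recordings.

## The method

Training EEG (cue-locked 30-s idle/walk KMI epochs, 256 Hz) is reduced per
0.75-s window to integrated 2-Hz band powers *d* ∈ R^(B×C) over the
analysis band [F_L, F_H). A piecewise-linear classwise-PCA map Φ_C and a
1-D information discriminant T_A yield the scalar feature

    f = T_A Φ_C(d)

on which a linear Bayesian classifier with per-class Gaussians decides
`I` iff P(I|f*) > P(W|f*), otherwise `W`. The band is grown greedily on a
2-Hz grid until stratified 10-fold cross-validated accuracy stops
improving. Online, windows slide every 0.25 s; the walking posterior is
averaged over 2 s (P̄) and drives a hysteretic state machine: idle→walk
when P̄ > T_W, walk→idle when P̄ < T_I. Sessions are scored by the maximum
lagged cue/response cross-correlation, omissions, and false alarms, and
each session's significance is assessed against a saturating
autoregressive surrogate X_{k+1} = αX_k + βW_k (α = lag-1 autocorrelation
of the posteriors, β = 2μ(1−α)) pushed through the identical decoding
chain. See `vignettes/gaitbci-methods.Rmd` for the full account.

## Worked example

```r
library(gaitbci)

# a stated synthetic world: 16 channels, 4 carrying an 8-12 Hz modulation
# with single-window log band-power d' = 2 during walking KMI
cfg   <- synth_config(n_channels = 16, modulated_channels = 1:4,
                      effect_size = 2, seed = 42)
train <- generate_training_session(cfg)        # 600 s, 20 x 30 s cues
model <- train_prediction_model(train$rec, train$cues,
                                band = c(8, 12), seed = 7)
model
#> <prediction_model> band [8, 12) Hz, 16 channel(s), CV 94.4% +/- 2.2%

# online evaluation: 10 alternating 1-min cues, decoded every 0.25 s
online <- generate_online_session(
  synth_config(n_channels = 16, modulated_channels = 1:4,
               effect_size = 2, seed = 44), reaction_delay = 0)
ses <- run_online_session(online$rec, model, t_i = 0.2, t_w = 0.8)
m   <- session_metrics(online$cues, ses)
m
#> <session_metrics> r=0.996 @ 2.00 s lag, 0 omission(s), 0 false alarm(s)

# significance against the AR surrogate null
null <- fit_ar(ses$posterior$P)
empirical_pvalue(m$max_xcorr, binarize(online$cues), null,
                 t_i = 0.2, t_w = 0.8, n_trials = 2000, seed = 5)
#> <mc_pvalue> p < 0.0005 (0/2000 trials above r=0.996; null max 0.034)
```

The cross-correlation of 0.996 at a 2.00-s lag says the decoded walking
epochs track the cues almost perfectly, delayed only by the analysis
window plus the 2-s posterior averaging; no Walk cue was missed, no
walking started during an Idle cue, and the best of 2000 cue-blind
surrogate sessions reached a correlation of only 0.034, so the empirical
p-value is below the 1/2000 reporting floor.

A command-line interface covers the same loop
(`inst/cli/gaitbci.R simulate | train | decode | evaluate | null-test`);
see `?gaitbci_cli`.

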