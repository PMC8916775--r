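# Shared fixtures, all generated in code.

# Bivariate VAR with two gamma-band AR(2) resonators and a one-way coupling
# from x to y at the given lag: the canonical "genuine directed interaction".
gamma_var_coefs <- function(coupling = 0.5, lag = 5, f0 = 45, bw = 20,
                            fs = 1000) {
  p <- max(2, lag)
  A <- array(0, c(2, 2, p))
  r <- exp(-pi * bw / fs)
  w <- 2 * pi * f0 / fs
  A[1, 1, 1] <- 2 * r * cos(w); A[1, 1, 2] <- -r^2
  A[2, 2, 1] <- 2 * r * cos(w); A[2, 2, 2] <- -r^2
  A[2, 1, lag] <- coupling
  A
}

# Instantaneously mixed common source plus independent sensor noise:
# the scenario the reversal test must reject.
common_noise_pair <- function(n_trials = 20, n_bins = 256, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n_trials * (n_bins + 10)), n_trials)
  z <- t(apply(z, 1, function(v) {
    v <- as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
    v[is.na(v)] <- 0
    v
  }))[, seq_len(n_bins)]
  list(x = z + 0.5 * matrix(rnorm(n_trials * n_bins), n_trials),
       y = 0.7 * z + 0.5 * matrix(rnorm(n_trials * n_bins), n_trials))
}

# Epoched container around a per-trial/channel generator function.
make_epoched <- function(gen, n_trials = 1, n_channels = 3, fs = 1000,
                         time_ms = seq(-500, 499), kind = "LFPbp",
                         condition = NULL) {
  d <- array(0, c(n_trials, n_channels, length(time_ms)))
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(n_channels)) d[tr, ch, ] <- gen(tr, ch, time_ms)
  }
  epoched_signal(d, time_ms, fs, kind = kind, condition = condition,
                 usable = rep(TRUE, n_channels))
}

hanning_win <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# One small synthetic session shared across test files (generated once).
.session_cache <- new.env(parent = emptyenv())
small_session <- function() {
  if (is.null(.session_cache$gen)) {
    cfg <- synth_config(n_trials_per_condition = 3, seed = 42)
    gen <- generate_session(cfg)
    lfp <- extract_lfp(gen$session)
    muae <- extract_muae(gen$session)
    .session_cache$gen <- gen
    .session_cache$cfg <- cfg
    .session_cache$lfp_ep <- epoch_trials(lfp, gen$session$events, kind = "LFP")
    .session_cache$muae_ep <- epoch_trials(muae, gen$session$events, kind = "MUAe")
  }
  as.list(.session_cache)
}
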