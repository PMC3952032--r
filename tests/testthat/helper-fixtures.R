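# Shared fixtures: a reduced 25-sensor montage and small sessions, cached
# per test run so expensive generation happens once.

small_montage <- function() {
  ring <- function(n, r, phase = 0) {
    th <- phase + 2 * pi * (seq_len(n) - 1) / n
    data.frame(x = r * sin(th), y = r * cos(th))
  }
  pts <- rbind(data.frame(x = 0, y = 0),
               ring(8, 0.45), ring(8, 0.75), ring(8, 1.0))
  data.frame(label = c("Cz", paste0("E", 1:24)),
             x = round(pts$x, 4), y = round(pts$y, 4),
             peripheral = c(rep(FALSE, 17), rep(TRUE, 8)),
             stringsAsFactors = FALSE)
}

small_tap <- function(n_trials = 12) {
  tap_params(n_trials = n_trials, inter_trial_rest_mean = 3.2,
             trial_length_mean = 1.8, trial_length_sd = 0.2)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  hit <- .fixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .fixture_cache[[key]] <- val
  val
}

# a small session with planted coupling on the reduced montage
small_session <- function(snr = 1, seed = 71, n_trials = 12) {
  key <- paste("ses", snr, seed, n_trials, sep = "_")
  cached(key, {
    m <- small_montage()
    cp <- coupling_spec(default_coupled_channels(m, 3),
                        lags_ms = c(50, 100, 150), snr = snr)
    generate_session(small_tap(n_trials), cp, seed = seed, montage = m)
  })
}

# a full-montage session (used by pipeline-scale tests)
full_session <- function(snr = 1, seed = 91, n_trials = 24) {
  key <- paste("full", snr, seed, n_trials, sep = "_")
  cached(key, {
    generate_session(tap_params(n_trials = n_trials),
                     default_coupling(snr = snr), seed = seed)
  })
}
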