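# Independent oracles and small fixture builders used across the suite.

# O(N^2) direct causal convolution: y[k] = sum_{l=0..k-1} h[l+1] x[k-l]
conv_direct <- function(h, x) {
  n <- length(x)
  out <- numeric(n)
  for (k in seq_len(n)) {
    l <- 0:(min(k, length(h)) - 1)
    out[k] <- sum(h[l + 1] * x[k - l])
  }
  out
}

# Batch kernel ridge regression: prediction of y_new at phi_new from all
# previously seen (Phi, y) with ridge `ridge`.
krr_predict <- function(spec, Phi, y, phi_new, ridge) {
  m <- nrow(Phi)
  K <- matrix(0, m, m)
  for (i in seq_len(m))
    for (j in seq_len(m))
      K[i, j] <- kernel_eval(spec, Phi[i, ], Phi[j, ])
  a <- solve(K + ridge * diag(m), y)
  k_new <- vapply(seq_len(m), function(i)
    kernel_eval(spec, Phi[i, ], phi_new), numeric(1))
  sum(k_new * a)
}

# Minimal hand-assembled record: column i of `hbo`/`hbr` is channel i.
# Paradigm defaults match the standard trial structure at the given fs.
make_record <- function(hbo, hbr, fs = 10, rest_n, task_s = 10, rest_s = 20,
                        n_trials = 1, n_sessions = 1,
                        active = seq_len(ncol(hbo))) {
  n <- nrow(hbo)
  n_trial <- floor((task_s + rest_s) * fs)
  segs <- data.frame(
    segment = c("rest", paste0("session", seq_len(n_sessions))),
    start = c(1L, rest_n + 1L + (seq_len(n_sessions) - 1L) * n_trial * n_trials),
    end = c(rest_n, rest_n + seq_len(n_sessions) * n_trial * n_trials))
  cfg <- synth_config(fs = fs, task_s = task_s, rest_s = rest_s,
                      n_trials = n_trials, n_sessions = n_sessions,
                      rest_prefix_s = rest_n / fs, n_channels = ncol(hbo),
                      active_channels = active)
  colnames(hbo) <- colnames(hbr) <- sprintf("ch%02d", seq_len(ncol(hbo)))
  structure(list(hbo = hbo, hbr = hbr, time_s = (seq_len(n) - 1) / fs,
                 fs = fs, segments = segs,
                 stimulus = stimulus_boxcar(fs, task_s, rest_s,
                                            n_trials * n_sessions,
                                            lead_rest_s = rest_n / fs),
                 active_channels = as.integer(active), config = cfg,
                 seed = NA_integer_),
            class = "fnirs_record")
}

# Steady-state amplitude of a (possibly attenuated) sinusoid: peak of the
# final `tail_s` seconds, long after filter transients have decayed.
steady_amplitude <- function(y, fs, tail_s) {
  n <- length(y)
  max(abs(y[(n - floor(tail_s * fs)):n]))
}
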