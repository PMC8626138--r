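# Fixtures built in code at test time. Recordings are small (seconds to
# minutes); the full default subject is only generated where a test needs
# the reference study conditions.

# single- or multi-tone recording
make_tone_recording <- function(freqs, amps = rep(1, length(freqs)),
                                fs = 256, dur_s = 10, n_channels = 1,
                                noise_sd = 0, intervals = list(),
                                session_id = "T01", seed = 1) {
  with_seed(seed, {
    t <- (seq_len(fs * dur_s) - 1) / fs
    row <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t),
                           freqs, amps))
    data <- matrix(rep(row, n_channels), nrow = n_channels, byrow = TRUE)
    if (noise_sd > 0) data <- data + rnorm(length(data), 0, noise_sd)
    recording(data, fs, paste0("CH", seq_len(n_channels)), intervals,
              session_id)
  })
}

with_seed <- seiztrack:::with_seed

# compact synthetic subject for fast pipeline tests: same structure as the
# default spec, shorter sessions
quick_subject_spec <- function(seed = 7) {
  synthetic_subject_spec(
    session_plan = list(
      list(duration_s = 420, seizures = list(c(180, 220))),
      list(duration_s = 420, seizures = list(c(240, 280))),
      list(duration_s = 420, seizures = list(c(120, 160)))),
    seed = seed)
}

# two well-separated Gaussian classes as a labeled feature
make_gaussian_feature <- function(n, p_pos = 0.2, mean0 = 0, mean1 = 10,
                                  sd = 1, seed = 1) {
  with_seed(seed, {
    labels <- rbinom(n, 1, p_pos)
    values <- rnorm(n, ifelse(labels == 1, mean1, mean0), sd)
    list(values = values, labels = labels)
  })
}

random_stable_combiner <- function(N = 5, seed = 1, ill_cond = FALSE) {
  with_seed(seed, {
    C <- runif(N, 0.5, 1.5)
    C <- C * sqrt(N) / sqrt(sum(C^2))
    R <- if (ill_cond) {
      U <- qr.Q(qr(matrix(rnorm(N * N), N)))
      U %*% diag(10^seq(-5, 5, length.out = N)) %*% t(U)
    } else {
      M <- matrix(rnorm(N * N, 0, 0.1), N)
      diag(runif(N, 0.2, 0.6)) + crossprod(M)
    }
    combiner_params(A = runif(1, 0.8, 0.97), B = rnorm(N), C = C,
                    var_omega = runif(1, 0.05, 0.2), cov_nu = (R + t(R)) / 2)
  })
}

make_pools <- function(n, labels, quality, seed) {
  # quality in [0,1]: correlation of each candidate with the labels
  with_seed(seed, {
    pools <- list()
    for (i in seq_along(quality)) {
      v <- quality[i] * labels * 3 + rnorm(n)
      pools[[sprintf("CH%d|Theta|x", i)]] <-
        feature_series(v - min(v), sprintf("CH%d", i), "Theta", "power", 1)
    }
    pools
  })
}
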