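# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain dense-quadrature loops and closed
# forms.

# Leaky beta-Bernoulli filter on a dense midpoint quadrature grid.
oracle_pstop <- function(outcomes, alpha, m, s, n_quad = 5000) {
  r <- (seq_len(n_quad) - 0.5) / n_quad
  a <- m * s
  b <- (1 - m) * s
  prior <- r^(a - 1) * (1 - r)^(b - 1)
  prior <- prior / sum(prior)
  post <- prior
  p <- numeric(length(outcomes))
  for (k in seq_along(outcomes)) {
    pred <- if (k == 1) prior else alpha * post + (1 - alpha) * prior
    pred <- pred / sum(pred)
    p[k] <- sum(r * pred)
    post <- pred * (if (outcomes[k] == 1) r else 1 - r)
    post <- post / sum(post)
  }
  p
}

# Beta-Bernoulli closed form at alpha = 1: predictive mean before trial k is
# (a + stops so far) / (a + b + trials so far).
conjugate_pstop <- function(outcomes, m, s) {
  a <- m * s
  b <- (1 - m) * s
  k <- seq_along(outcomes)
  (a + c(0, cumsum(outcomes))[k]) / (a + b + (k - 1))
}

# Discrete mean of a Gaussian-shaped component over the +/-24 ms averaging
# window, on the 500 Hz sample grid (the value the peak extractor should
# report for a noiseless on-grid component).
gaussian_window_mean <- function(amp, width, halfwidth = 24, dt = 2) {
  offs <- seq(-halfwidth, halfwidth, by = dt)
  amp * mean(exp(-offs^2 / (2 * width^2)))
}

# Analytic window mean of a two-component (P1 + N1) Gaussian epoch around a
# peak at `center`, on the sample grid.
two_component_window_mean <- function(p1, n1, center, p1_center = 104,
                                      n1_center = 154, p1_width = 12,
                                      n1_width = 15, halfwidth = 24,
                                      dt = 2) {
  t <- center + seq(-halfwidth, halfwidth, by = dt)
  vapply(seq_along(p1), function(i)
    mean(p1[i] * exp(-(t - p1_center)^2 / (2 * p1_width^2)) +
           n1[i] * exp(-(t - n1_center)^2 / (2 * n1_width^2))),
    numeric(1))
}

# Small noiseless epoch container built directly (bypassing render_epochs)
# for extractor unit tests: one trial, two identical channels.
make_epochs <- function(signal, times = seq(-200, 800, by = 2),
                        channels = c("PO7", "PO8"), gains = c(1, 1)) {
  stopifnot(length(signal) == length(times))
  dat <- array(0, dim = c(2L, length(times), 1L))
  dat[1, , 1] <- gains[1] * signal
  dat[2, , 1] <- gains[2] * signal
  structure(list(data = dat, times = times, sampling_rate = 1000 /
                   (times[2] - times[1]),
                 channels = channels,
                 trials = data.frame(subject = 1L, condition = "LR",
                                     trial_index = 1L)),
            class = "sst_epochs")
}
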