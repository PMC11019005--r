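# Single-trial P1/N1 feature extraction from epoched two-channel data:
# baseline correction, artifact screening, windowed peak detection with a
# +/-24 ms mean-amplitude window, channel combination, within-subject
# standardization, and the short-SSD trial exclusion.

#' Baseline-correct an epoch container
#'
#' Subtracts, per channel and trial, the mean voltage over the baseline
#' window (default -200 to 0 ms, right-open) from the whole epoch.
#'
#' @param epochs An \code{"sst_epochs"} object.
#' @param window Baseline window \code{c(lo, hi)} in ms; samples with
#'   \code{lo <= t < hi} are averaged.
#' @return The corrected \code{"sst_epochs"} object.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  stopifnot(inherits(epochs, "sst_epochs"))
  idx <- which(epochs$times >= window[1] & epochs$times < window[2])
  if (length(idx) == 0L)
    stop("baseline window [", window[1], ", ", window[2],
         ") contains no samples")
  d <- dim(epochs$data)
  for (tr in seq_len(d[3])) {
    bl <- rowMeans(epochs$data[, idx, tr, drop = FALSE])
    epochs$data[, , tr] <- epochs$data[, , tr] - bl
  }
  epochs
}

#' Screen epochs for artifacts
#'
#' Applies the two rejection criteria per channel (individual-channel mode;
#' a trial is rejected if either channel fails): a maximal allowed voltage
#' step between adjacent samples of \code{max_step} uV/ms, and a maximal
#' allowed peak-to-peak range within the epoch of \code{max_range} uV.
#'
#' @param epochs A baseline-corrected \code{"sst_epochs"} object.
#' @param max_step Voltage-step limit, uV per ms (default 50).
#' @param max_range Peak-to-peak limit over the epoch, uV (default 80).
#' @return Data frame with one row per trial: \code{trial}, \code{retained},
#'   \code{rejection_reason} ("voltage_step", "range" or "none").
#' @export
screen_artifacts <- function(epochs, max_step = 50, max_range = 80) {
  stopifnot(inherits(epochs, "sst_epochs"))
  dt <- 1000 / epochs$sampling_rate
  d <- dim(epochs$data)
  reason <- character(d[3])
  for (tr in seq_len(d[3])) {
    m <- matrix(epochs$data[, , tr], nrow = d[1])
    step <- max(abs(m[, -1, drop = FALSE] - m[, -d[2], drop = FALSE])) / dt
    rng <- max(apply(m, 1, function(v) diff(range(v))))
    reason[tr] <- if (step > max_step) "voltage_step"
    else if (rng > max_range) "range"
    else "none"
  }
  data.frame(trial = seq_len(d[3]), retained = reason == "none",
             rejection_reason = reason, stringsAsFactors = FALSE)
}

#' Windowed peak latency and mean amplitude of one channel
#'
#' Finds the extreme sample (maximum for positive polarity, minimum for
#' negative) inside the search window — ties resolved toward the earliest
#' sample — and averages the signal from 24 ms before to 24 ms after that
#' peak, truncating the averaging window at the epoch edges.
#'
#' @param x Numeric vector: one channel of one baseline-corrected epoch.
#' @param times Sample times, ms.
#' @param window Search window \code{c(lo, hi)} in ms, inclusive.
#' @param polarity "+" for a positive component (P1), "-" for negative (N1).
#' @param avg_halfwidth Half-width of the mean-amplitude window, ms.
#' @return List with \code{latency} (ms) and \code{mean_amp} (uV).
#' @export
extract_peak <- function(x, times, window, polarity = c("+", "-"),
                         avg_halfwidth = 24) {
  polarity <- match.arg(polarity)
  win <- which(times >= window[1] & times <= window[2])
  if (length(win) == 0L)
    stop("search window [", window[1], ", ", window[2],
         "] lies outside the epoch")
  seg <- x[win]
  pk <- if (polarity == "+") which.max(seg) else which.min(seg)
  latency <- times[win[pk]]
  avg <- which(times >= latency - avg_halfwidth &
                 times <= latency + avg_halfwidth)
  list(latency = latency, mean_amp = mean(x[avg]))
}

#' Combine the two posterior channels
#'
#' Peaks are detected independently per channel; the combined amplitude is
#' the arithmetic mean of the two channels' mean amplitudes. The combined
#' latency (mean of the two latencies) is reported for QC only.
#'
#' @param f1,f2 Per-channel results of [extract_peak()].
#' @return List with \code{latency} and \code{mean_amp}.
#' @export
combine_channels <- function(f1, f2) {
  list(latency = (f1$latency + f2$latency) / 2,
       mean_amp = (f1$mean_amp + f2$mean_amp) / 2)
}

#' Single-trial P1/N1 feature table from an epoch container
#'
#' Full extraction chain: baseline correction, artifact screening, P1 and N1
#' peak detection per channel within their search windows (defaults 90-120
#' and 130-180 ms), +/-24 ms mean amplitudes, and two-channel combination.
#' Rejected trials keep their key columns with \code{NA} features.
#'
#' @param epochs An \code{"sst_epochs"} object (raw; baseline correction is
#'   applied internally).
#' @param p1_window,n1_window Search windows, ms.
#' @param avg_halfwidth Mean-amplitude half-width, ms.
#' @param max_step,max_range Artifact thresholds (see [screen_artifacts()]).
#' @param baseline Baseline window, ms.
#' @return Data frame with the epoch key columns plus \code{p1_latency},
#'   \code{p1_amp}, \code{n1_latency}, \code{n1_amp}, \code{retained},
#'   \code{rejection_reason}.
#' @export
extract_erp_features <- function(epochs, p1_window = c(90, 120),
                                 n1_window = c(130, 180),
                                 avg_halfwidth = 24, max_step = 50,
                                 max_range = 80, baseline = c(-200, 0)) {
  stopifnot(inherits(epochs, "sst_epochs"))
  epochs <- baseline_correct(epochs, baseline)
  screen <- screen_artifacts(epochs, max_step, max_range)
  d <- dim(epochs$data)
  out <- epochs$trials
  out$p1_latency <- out$p1_amp <- out$n1_latency <- out$n1_amp <- NA_real_
  out$retained <- screen$retained
  out$rejection_reason <- screen$rejection_reason
  for (tr in which(screen$retained)) {
    p1 <- combine_channels(
      extract_peak(epochs$data[1, , tr], epochs$times, p1_window, "+",
                   avg_halfwidth),
      extract_peak(epochs$data[2, , tr], epochs$times, p1_window, "+",
                   avg_halfwidth))
    n1 <- combine_channels(
      extract_peak(epochs$data[1, , tr], epochs$times, n1_window, "-",
                   avg_halfwidth),
      extract_peak(epochs$data[2, , tr], epochs$times, n1_window, "-",
                   avg_halfwidth))
    out$p1_latency[tr] <- p1$latency
    out$p1_amp[tr] <- p1$mean_amp
    out$n1_latency[tr] <- n1$latency
    out$n1_amp[tr] <- n1$mean_amp
  }
  out
}

#' Standardize trial-level amplitudes within subject
#'
#' Adds z-scored columns (\code{<col>_z... p1_z}, \code{n1_z}) computed per
#' subject over all retained trials pooled across condition blocks, so that
#' between-block amplitude differences survive standardization.
#'
#' @param features Feature table with a \code{subject} column and amplitude
#'   columns; rows with \code{NA} amplitude are ignored for the moments and
#'   left \code{NA}.
#' @param cols Amplitude columns to standardize.
#' @param min_trials Minimum retained trials per subject.
#' @return \code{features} with \code{p1_z}/\code{n1_z} (or
#'   \code{<col>_z}) columns appended.
#' @export
standardize_amplitudes <- function(features,
                                   cols = c(p1_z = "p1_amp",
                                            n1_z = "n1_amp"),
                                   min_trials = 30L) {
  stopifnot("subject" %in% names(features))
  if (is.null(names(cols))) names(cols) <- paste0(cols, "_z")
  for (zc in names(cols)) {
    src <- features[[cols[[zc]]]]
    z <- rep(NA_real_, length(src))
    for (s in unique(features$subject)) {
      i <- features$subject == s & is.finite(src)
      if (sum(i) < min_trials)
        stop("subject ", s, " has only ", sum(i),
             " retained trials (need >= ", min_trials, ")")
      sd_s <- stats::sd(src[i])
      if (sd_s <= 0)
        stop("subject ", s, " has zero amplitude variance in ", cols[[zc]])
      z[i] <- (src[i] - mean(src[i])) / sd_s
    }
    features[[zc]] <- z
  }
  features
}

#' Drop stop trials with very short stop-signal delays
#'
#' Removes stop trials whose SSD is at or below the threshold (default
#' 150 ms, boundary inclusive) so that early stop-signal processing cannot
#' contaminate go-locked ERP analyses. Go trials are untouched.
#'
#' @param trials Trial table with \code{is_stop} and \code{ssd} columns.
#' @param max_ssd Threshold, ms.
#' @return Filtered trial table.
#' @export
filter_short_ssd <- function(trials, max_ssd = 150) {
  drop <- as.logical(trials$is_stop) & !is.na(trials$ssd) &
    trials$ssd <= max_ssd
  trials[!drop, , drop = FALSE]
}
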