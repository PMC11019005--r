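# Synthetic motivated stop-signal task: trial sequences, adaptive SSD
# staircase, a race-model agent whose go RTs slow with its own DBM-derived
# stop expectation, and single-trial P1/N1 amplitudes/waveforms with a
# configurable condition x P(stop) effect structure.

#' Task configuration for the motivated stop-signal task
#'
#' Defaults follow the standard motivated-SST design: four incentive blocks
#' of 288 trials, 25% stop trials, an adaptive stop-signal-delay (SSD)
#' staircase initialized at 500 ms moving in 50 ms steps within
#' \[50, 1200\] ms, a 1200 ms go-stimulus response window, 600 ms feedback
#' and a 400 ms inter-stimulus interval.
#'
#' @param n_trials_per_block Trials per condition block.
#' @param p_stop Stop-trial proportion (exact count per block).
#' @param ssd_init,ssd_step,ssd_min,ssd_max Staircase parameters, ms.
#' @param go_duration Go response window, ms.
#' @param feedback_duration,isi Feedback screen and inter-stimulus interval,
#'   ms (bookkeeping only; they do not affect simulated behavior).
#' @return Object of class \code{"sst_task_config"}.
#' @export
task_config <- function(n_trials_per_block = 288L, p_stop = 0.25,
                        ssd_init = 500, ssd_step = 50, ssd_min = 50,
                        ssd_max = 1200, go_duration = 1200,
                        feedback_duration = 600, isi = 400) {
  stopifnot(n_trials_per_block >= 1, p_stop > 0, p_stop < 1,
            ssd_min <= ssd_init, ssd_init <= ssd_max, ssd_step > 0,
            go_duration > 0)
  structure(list(n_trials_per_block = as.integer(n_trials_per_block),
                 p_stop = p_stop, ssd_init = ssd_init, ssd_step = ssd_step,
                 ssd_min = ssd_min, ssd_max = ssd_max,
                 go_duration = go_duration,
                 feedback_duration = feedback_duration, isi = isi),
            class = "sst_task_config")
}

#' The four incentive conditions
#'
#' Low/high reward (money gained per successful stop) and low/high
#' punishment (money lost per unsuccessful stop), with stakes of $0.05 (low)
#' and $0.25 (high).
#'
#' @return Data frame with columns \code{condition} (LR, HR, LP, HP),
#'   \code{valence}, \code{stake}, \code{stake_dollars}.
#' @export
sst_conditions <- function() {
  data.frame(
    condition = c("LR", "HR", "LP", "HP"),
    valence = c("reward", "reward", "punishment", "punishment"),
    stake = c("low", "high", "low", "high"),
    stake_dollars = c(0.05, 0.25, 0.05, 0.25),
    stringsAsFactors = FALSE
  )
}

#' Race-model agent configuration
#'
#' The agent tracks the stop-signal rate with its own DBM (shared code with
#' the fitting side, enabling exact parameter-recovery studies) and slows
#' its go process linearly in the resulting expectation P(stop). Go finish
#' times are ex-Gaussian (positively skewed, like empirical RTs): normal
#' component with SD \code{rt_noise_sd} plus an exponential tail with mean
#' \code{exg_tau}, with overall mean \code{rt_base + rt_pstop_slope * P(stop)
#' (+ rt_stake_offset on high-stake blocks)}. On stop trials an independent
#' stop process with latency \code{ssrt_true} (SD \code{ssrt_sd}) races the
#' go process: a response is emitted iff the go process finishes before
#' SSD + SSRT.
#'
#' \code{attention_gain} couples a per-trial latent attentional state (also
#' expressed in the synthetic N1, see [erp_effect_config()]) to stopping
#' efficacy: on stop trials the effective SSRT is shifted by
#' \code{gain * attention * (P(stop) - pstop_center) / pstop_scale} ms,
#' with a condition-specific gain. A positive gain means that on
#' high-expectation trials a *more negative* N1 (lower attention state,
#' by the N1 loading convention) shortens SSRT and helps stopping.
#'
#' @param dbm The agent's internal [dbm_params()].
#' @param rt_base Mean go finish time at P(stop) = 0, low stake, ms.
#' @param rt_pstop_slope Proactive slowing, ms per unit P(stop).
#' @param rt_stake_offset Additional slowing on high-stake blocks, ms.
#' @param rt_noise_sd SD of the Gaussian RT component, ms.
#' @param exg_tau Mean of the exponential RT tail, ms.
#' @param ssrt_true,ssrt_sd Stop-process latency mean and SD, ms.
#' @param omission_rate Probability of not responding on a go trial
#'   (lapses), in addition to responses censored by the response window.
#' @param choice_error_rate Probability of pressing the wrong arrow
#'   direction on a responded go trial.
#' @param attention_gain Named vector of SSRT-shift gains (ms per unit
#'   latent-attention x scaled P(stop)) per condition; 0 disables coupling.
#' @param pstop_center,pstop_scale Centering/scaling applied to P(stop)
#'   inside the attention coupling (nominal mean and SD of the expectation
#'   under the default task).
#' @return Object of class \code{"sst_agent_config"}.
#' @export
agent_config <- function(dbm = dbm_params(0.95, 0.30, 14),
                         rt_base = 680, rt_pstop_slope = 1000,
                         rt_stake_offset = 10, rt_noise_sd = 50,
                         exg_tau = 50, ssrt_true = 300, ssrt_sd = 30,
                         omission_rate = 0.02, choice_error_rate = 0.01,
                         attention_gain = c(LR = -25, HR = 40, LP = -25,
                                            HP = -10),
                         pstop_center = 0.27, pstop_scale = 0.04) {
  stopifnot(inherits(dbm, "dbm_params"), rt_base > 0, ssrt_true > 0,
            rt_noise_sd >= 0, exg_tau >= 0, ssrt_sd >= 0,
            omission_rate >= 0, omission_rate < 0.1,
            choice_error_rate >= 0, choice_error_rate < 1,
            pstop_scale > 0)
  structure(list(dbm = dbm, rt_base = rt_base,
                 rt_pstop_slope = rt_pstop_slope,
                 rt_stake_offset = rt_stake_offset,
                 rt_noise_sd = rt_noise_sd, exg_tau = exg_tau,
                 ssrt_true = ssrt_true, ssrt_sd = ssrt_sd,
                 omission_rate = omission_rate,
                 choice_error_rate = choice_error_rate,
                 attention_gain = attention_gain,
                 pstop_center = pstop_center, pstop_scale = pstop_scale),
            class = "sst_agent_config")
}

# Run `code` under a fixed RNG state without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Randomized trial sequence with an exact stop-trial count
#'
#' Fixes the stop-trial count at \code{round(n * p_stop)} per block (72 of
#' 288 under the defaults) and randomizes trial order; arrow directions are
#' balanced 50/50 and randomized independently.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed (local to this call).
#' @return Data frame with \code{trial_index}, \code{is_stop} (0/1),
#'   \code{arrow} ("L"/"R").
#' @export
generate_trial_sequence <- function(config = task_config(), seed = NULL) {
  n <- config$n_trials_per_block
  n_stop <- round(n * config$p_stop)
  with_seed(seed, {
    is_stop <- sample(rep(c(1L, 0L), c(n_stop, n - n_stop)))
    arrow <- sample(rep(c("L", "R"), length.out = n))
    data.frame(trial_index = seq_len(n), is_stop = is_stop, arrow = arrow,
               stringsAsFactors = FALSE)
  })
}

#' One staircase step of the stop-signal delay
#'
#' Tracking rule targeting 50% stop accuracy: after a successful stop the
#' task gets harder (SSD up one step); after a failed stop it gets easier
#' (SSD down one step); clamped to the configured bounds.
#'
#' @param ssd Current SSD, ms.
#' @param stop_succeeded Logical: was the response withheld?
#' @param config A [task_config()].
#' @return Updated SSD, ms.
#' @export
staircase_update <- function(ssd, stop_succeeded, config = task_config()) {
  step <- if (isTRUE(stop_succeeded)) config$ssd_step else -config$ssd_step
  min(max(ssd + step, config$ssd_min), config$ssd_max)
}

#' Simulate one condition block of the motivated SST
#'
#' Runs the race-model agent through a block: per trial the agent propagates
#' its belief over the stop rate, records its predictive P(stop), draws an
#' ex-Gaussian go finish time slowed by that expectation, and on stop trials
#' races it against SSD + SSRT; the staircase updates after every stop
#' trial, and earnings follow the block's incentive contingency.
#'
#' @param task A [task_config()].
#' @param agent An [agent_config()].
#' @param condition One of "LR", "HR", "LP", "HP".
#' @param subject Subject identifier stored in the output.
#' @param seed Optional integer seed (local to this call).
#' @param ssd_start Optional SSD carried in from a preceding block
#'   (defaults to \code{task$ssd_init}).
#' @param n_grid Rate-grid resolution of the agent's belief filter.
#' @return Data frame of trial records: \code{subject}, \code{condition},
#'   \code{valence}, \code{stake}, \code{trial_index}, \code{is_stop},
#'   \code{arrow}, \code{ssd} (stop trials only), \code{rt} (ms, \code{NA}
#'   when no response), \code{responded}, \code{go_correct} (go trials
#'   only), \code{stop_error} (stop trials only), \code{pstop_agent},
#'   \code{attn} (latent attentional state), \code{earnings_delta}
#'   (dollars).
#' @export
simulate_block <- function(task = task_config(), agent = agent_config(),
                           condition = "LR", subject = 1L, seed = NULL,
                           ssd_start = NULL, n_grid = 200L) {
  conds <- sst_conditions()
  if (!condition %in% conds$condition)
    stop("unknown condition: ", condition)
  cinfo <- conds[conds$condition == condition, ]
  with_seed(seed, {
    seqdf <- generate_trial_sequence(task)
    n <- nrow(seqdf)
    # lean belief filter (same recursion as dbm_pstop, no S3 overhead)
    grid <- rate_grid(as.integer(n_grid))
    prior <- stats::dbeta(grid, agent$dbm$a, agent$dbm$b)
    prior <- prior / sum(prior)
    w <- prior
    al <- agent$dbm$alpha

    ssd_cur <- if (is.null(ssd_start)) task$ssd_init else ssd_start
    stake_off <- if (cinfo$stake == "high") agent$rt_stake_offset else 0
    gain <- agent$attention_gain[[condition]]

    pstop <- rt <- ssd <- earnings <- numeric(n)
    responded <- logical(n)
    go_correct <- stop_error <- rep(NA, n)
    attn <- stats::rnorm(n)
    ssd[] <- NA_real_
    rt[] <- NA_real_

    for (k in seq_len(n)) {
      if (k > 1L) {
        w <- al * w + (1 - al) * prior
        w <- w / sum(w)
      }
      p <- sum(grid * w)
      pstop[k] <- p
      mu <- agent$rt_base + agent$rt_pstop_slope * p + stake_off -
        agent$exg_tau
      finish <- stats::rnorm(1, mu, agent$rt_noise_sd) +
        stats::rexp(1, 1 / agent$exg_tau)
      if (seqdf$is_stop[k] == 1L) {
        ssd[k] <- ssd_cur
        ssrt_k <- agent$ssrt_true + stats::rnorm(1, 0, agent$ssrt_sd) +
          gain * attn[k] * (p - agent$pstop_center) / agent$pstop_scale
        resp <- finish < ssd_cur + ssrt_k && finish <= task$go_duration
        stop_error[k] <- resp
        responded[k] <- resp
        if (resp) rt[k] <- finish
        if (cinfo$valence == "reward") {
          earnings[k] <- if (!resp) cinfo$stake_dollars else 0
        } else {
          earnings[k] <- if (resp) -cinfo$stake_dollars else 0
        }
        ssd_cur <- staircase_update(ssd_cur, !resp, task)
      } else {
        lapse <- stats::runif(1) < agent$omission_rate
        resp <- !lapse && finish <= task$go_duration
        responded[k] <- resp
        if (resp) {
          rt[k] <- finish
          go_correct[k] <- stats::runif(1) >= agent$choice_error_rate
        } else go_correct[k] <- FALSE
      }
      # the agent observes the realized trial type
      w <- w * (if (seqdf$is_stop[k] == 1L) grid else 1 - grid)
      w <- w / sum(w)
    }
    data.frame(subject = subject, condition = condition,
               valence = cinfo$valence, stake = cinfo$stake,
               trial_index = seqdf$trial_index, is_stop = seqdf$is_stop,
               arrow = seqdf$arrow, ssd = ssd, rt = rt,
               responded = responded, go_correct = as.logical(go_correct),
               stop_error = as.logical(stop_error), pstop_agent = pstop,
               attn = attn, earnings_delta = earnings,
               stringsAsFactors = FALSE)
  })
}

#' Simulate one subject (all four incentive blocks)
#'
#' Blocks are run in randomized order; the agent's belief restarts at its
#' prior in each block and the SSD staircase restarts at \code{ssd_init}.
#'
#' @inheritParams simulate_block
#' @param drop_conditions Optional character vector of conditions to omit
#'   (emulating subjects with missing blocks).
#' @return Data frame of trial records (see [simulate_block()]) with a
#'   \code{block_order} column.
#' @export
simulate_subject <- function(task = task_config(), agent = agent_config(),
                             subject = 1L, seed = NULL,
                             drop_conditions = NULL, n_grid = 200L) {
  with_seed(seed, {
    conds <- setdiff(sample(sst_conditions()$condition),
                     drop_conditions %||% character())
    out <- lapply(seq_along(conds), function(i) {
      b <- simulate_block(task, agent, conds[i], subject = subject,
                          n_grid = n_grid)
      b$block_order <- i
      b
    })
    do.call(rbind, out)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort
#'
#' @inheritParams simulate_subject
#' @param n_subjects Number of subjects.
#' @param rt_base_sd Between-subject SD of the agent's baseline RT, ms
#'   (subject random intercepts).
#' @param seed Integer seed controlling the whole cohort.
#' @return Data frame of trial records for all subjects.
#' @export
simulate_experiment <- function(n_subjects, task = task_config(),
                                agent = agent_config(), rt_base_sd = 50,
                                seed = NULL, n_grid = 200L) {
  with_seed(seed, {
    offsets <- stats::rnorm(n_subjects, 0, rt_base_sd)
    out <- lapply(seq_len(n_subjects), function(i) {
      a <- agent
      a$rt_base <- agent$rt_base + offsets[i]
      simulate_subject(task, a, subject = i, n_grid = n_grid)
    })
    do.call(rbind, out)
  })
}

#' Synthetic single-trial ERP effect configuration
#'
#' Defines the generative model of per-trial P1 and N1 mean amplitudes:
#' \deqn{amp = base + \sum coef \times coded\ effect + attention\ loading +
#'   noise}
#' with effect codes valence (punishment = +1, reward = -1), stake
#' (high = +1, low = -1) and the continuous trial-wise P(stop); the named
#' coefficient vectors cover the three main effects and all 2- and 3-way
#' interactions. The defaults encode a P(stop)-by-valence P1 modulation
#' (positive P(stop) slope of ~6 uV/unit in punishment, ~0 in reward) and a
#' P(stop)-by-valence-by-stake N1 modulation (slope +6 in HP, -6 in HR, ~0
#' in low-stake blocks), on top of small condition main effects.
#'
#' \code{n1_attn_load} expresses the shared latent attentional state drawn
#' by [simulate_block()] in the N1 (positive loading: higher latent state =
#' less negative N1), which, combined with the agent's
#' \code{attention_gain}, couples N1 amplitude to stop performance.
#'
#' Waveform fields control [render_epochs()]: Gaussian-shaped components at
#' the given center latencies and widths on two posterior channels
#' (PO7/PO8), epoch window -200..800 ms at 500 Hz. Default centers sit on
#' the sample grid so that noiseless rendering round-trips exactly through
#' the peak extractor.
#'
#' @param p1_base,n1_base Baseline component amplitudes, uV.
#' @param p1_coef,n1_coef Named coefficient vectors (uV per coded unit)
#'   with entries \code{valence, stake, pstop, valence_stake,
#'   valence_pstop, stake_pstop, valence_stake_pstop}.
#' @param n1_attn_load N1 loading of the latent attention state, uV per SD.
#' @param trial_noise_sd Trial-to-trial amplitude noise, uV.
#' @param p1_latency,n1_latency Component centers, ms post go-onset.
#' @param p1_width,n1_width Gaussian SDs of the rendered components, ms.
#' @param latency_jitter Max absolute per-trial center jitter, ms (applied
#'   in whole samples).
#' @param channel_gains Multiplicative gains of the two posterior channels.
#' @param epoch_noise_sd Additive waveform noise per sample, uV.
#' @param window Epoch window, ms relative to go onset.
#' @param sampling_rate Hz.
#' @return Object of class \code{"erp_effect_config"}.
#' @export
erp_effect_config <- function(
    p1_base = 5, n1_base = -5,
    p1_coef = c(valence = 0.2, stake = 0, pstop = 3, valence_stake = 0,
                valence_pstop = 3, stake_pstop = 0, valence_stake_pstop = 0),
    n1_coef = c(valence = -0.3, stake = 0.3, pstop = 0, valence_stake = 0,
                valence_pstop = 3, stake_pstop = 0, valence_stake_pstop = 3),
    n1_attn_load = 1.5, trial_noise_sd = 3,
    p1_latency = 104, n1_latency = 154, p1_width = 12, n1_width = 15,
    latency_jitter = 8, channel_gains = c(PO7 = 1, PO8 = 1),
    epoch_noise_sd = 0, window = c(-200, 800), sampling_rate = 500) {
  stopifnot(p1_base > 0, n1_base < 0, sampling_rate > 0,
            trial_noise_sd >= 0, epoch_noise_sd >= 0,
            length(channel_gains) == 2L)
  need <- c("valence", "stake", "pstop", "valence_stake", "valence_pstop",
            "stake_pstop", "valence_stake_pstop")
  stopifnot(all(need %in% names(p1_coef)), all(need %in% names(n1_coef)))
  structure(list(p1_base = p1_base, n1_base = n1_base,
                 p1_coef = p1_coef[need], n1_coef = n1_coef[need],
                 n1_attn_load = n1_attn_load,
                 trial_noise_sd = trial_noise_sd,
                 p1_latency = p1_latency, n1_latency = n1_latency,
                 p1_width = p1_width, n1_width = n1_width,
                 latency_jitter = latency_jitter,
                 channel_gains = channel_gains,
                 epoch_noise_sd = epoch_noise_sd,
                 window = window, sampling_rate = sampling_rate),
            class = "erp_effect_config")
}

# +1/-1 effect codes used by the amplitude generator
valence_code <- function(valence) ifelse(valence == "punishment", 1, -1)
stake_code <- function(stake) ifelse(stake == "high", 1, -1)

#' Synthesize single-trial P1/N1 mean amplitudes
#'
#' @param trials Trial table carrying \code{valence}, \code{stake},
#'   \code{pstop_agent} and (optionally) the latent \code{attn} column.
#' @param effects An [erp_effect_config()].
#' @param seed Optional integer seed (local to this call).
#' @return \code{trials} with \code{p1_amp} and \code{n1_amp} columns
#'   appended (uV).
#' @export
synthesize_amplitudes <- function(trials, effects = erp_effect_config(),
                                  seed = NULL) {
  stopifnot(all(c("valence", "stake", "pstop_agent") %in% names(trials)))
  v <- valence_code(trials$valence)
  st <- stake_code(trials$stake)
  p <- trials$pstop_agent
  design <- cbind(valence = v, stake = st, pstop = p,
                  valence_stake = v * st, valence_pstop = v * p,
                  stake_pstop = st * p, valence_stake_pstop = v * st * p)
  attn <- if ("attn" %in% names(trials)) trials$attn else 0
  with_seed(seed, {
    n <- nrow(trials)
    trials$p1_amp <- effects$p1_base +
      drop(design %*% effects$p1_coef) +
      stats::rnorm(n, 0, effects$trial_noise_sd)
    trials$n1_amp <- effects$n1_base +
      drop(design %*% effects$n1_coef) +
      effects$n1_attn_load * attn +
      stats::rnorm(n, 0, effects$trial_noise_sd)
    trials
  })
}

#' Render epoched two-channel waveforms from per-trial amplitudes
#'
#' Each epoch is baseline noise plus a positive Gaussian-shaped component
#' centered near the P1 latency scaled to \code{p1_amp} and a negative one
#' near the N1 latency scaled to \code{n1_amp}, replicated on both posterior
#' channels with the configured gains. Per-trial latency jitter is drawn in
#' whole samples within \code{latency_jitter} ms.
#'
#' @param trials Trial table with \code{p1_amp}, \code{n1_amp} (from
#'   [synthesize_amplitudes()]).
#' @param effects An [erp_effect_config()].
#' @param seed Optional integer seed (local to this call).
#' @return Object of class \code{"sst_epochs"}: list with \code{data}
#'   (channels x time x trials array, uV), \code{times} (ms),
#'   \code{sampling_rate}, \code{channels}, and \code{trials} (the key
#'   columns \code{subject}, \code{condition}, \code{trial_index}).
#' @export
render_epochs <- function(trials, effects = erp_effect_config(),
                          seed = NULL) {
  stopifnot(all(c("p1_amp", "n1_amp") %in% names(trials)))
  dt <- 1000 / effects$sampling_rate
  times <- seq(effects$window[1], effects$window[2], by = dt)
  n_time <- length(times)
  n_trials <- nrow(trials)
  with_seed(seed, {
    jitter_steps <- seq(-effects$latency_jitter, effects$latency_jitter,
                        by = dt)
    j1 <- sample(jitter_steps, n_trials, replace = TRUE)
    j2 <- sample(jitter_steps, n_trials, replace = TRUE)
    dat <- array(0, dim = c(2L, n_time, n_trials))
    for (i in seq_len(n_trials)) {
      shape <- trials$p1_amp[i] *
        exp(-(times - (effects$p1_latency + j1[i]))^2 /
              (2 * effects$p1_width^2)) +
        trials$n1_amp[i] *
        exp(-(times - (effects$n1_latency + j2[i]))^2 /
              (2 * effects$n1_width^2))
      for (ch in 1:2) {
        noise <- if (effects$epoch_noise_sd > 0)
          stats::rnorm(n_time, 0, effects$epoch_noise_sd) else 0
        dat[ch, , i] <- effects$channel_gains[[ch]] * shape + noise
      }
    }
    structure(list(data = dat, times = times,
                   sampling_rate = effects$sampling_rate,
                   channels = names(effects$channel_gains) %||%
                     c("PO7", "PO8"),
                   trials = trials[, intersect(
                     c("subject", "condition", "trial_index"),
                     names(trials)), drop = FALSE]),
              class = "sst_epochs")
  })
}

#' @export
print.sst_epochs <- function(x, ...) {
  cat(sprintf("sst_epochs: %d trials x %d channels (%s) x %d samples, %g Hz, %g..%g ms\n",
              dim(x$data)[3], dim(x$data)[1],
              paste(x$channels, collapse = "/"), dim(x$data)[2],
              x$sampling_rate, min(x$times), max(x$times)))
  invisible(x)
}

#' Write / read an epoch container as text
#'
#' The array is stored as a flat CSV (trial, channel, time, value) with a
#' JSON sidecar carrying the sampling metadata (rate, window, channel names,
#' time-locking event).
#'
#' @param epochs An \code{"sst_epochs"} object.
#' @param path Path stem; writes \code{<path>.csv} and \code{<path>.json}.
#' @return \code{write_epochs}: the path stem, invisibly.
#'   \code{read_epochs}: an \code{"sst_epochs"} object.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "sst_epochs"))
  d <- dim(epochs$data)
  flat <- data.frame(
    trial = rep(seq_len(d[3]), each = d[1] * d[2]),
    channel = rep(rep(epochs$channels, each = d[2]), times = d[3]),
    time = rep(epochs$times, times = d[1] * d[3]),
    value = as.vector(aperm(epochs$data, c(2, 1, 3)))
  )
  utils::write.csv(flat, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(sampling_rate = epochs$sampling_rate,
               window = range(epochs$times),
               channels = epochs$channels,
               event = "go_onset",
               trials = epochs$trials)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  flat <- utils::read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  channels <- meta$channels
  times <- sort(unique(flat$time))
  n_trials <- max(flat$trial)
  dat <- array(0, dim = c(length(channels), length(times), n_trials))
  for (ch in seq_along(channels)) {
    sub <- flat[flat$channel == channels[ch], ]
    dat[ch, , ] <- matrix(sub$value[order(sub$trial, sub$time)],
                          nrow = length(times))
  }
  structure(list(data = dat, times = times,
                 sampling_rate = meta$sampling_rate, channels = channels,
                 trials = as.data.frame(meta$trials)),
            class = "sst_epochs")
}
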