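test_that("trial sequences have exact stop counts and balanced arrows", {
  s <- generate_trial_sequence(task_config(), seed = 1)
  expect_equal(nrow(s), 288)
  expect_equal(sum(s$is_stop), 72)
  expect_equal(sum(s$arrow == "L"), 144)

  s4 <- generate_trial_sequence(task_config(n_trials_per_block = 4), seed = 2)
  expect_equal(sum(s4$is_stop), 1)

  a <- generate_trial_sequence(task_config(), seed = 10)
  b <- generate_trial_sequence(task_config(), seed = 11)
  expect_equal(sum(a$is_stop), sum(b$is_stop))
  expect_false(identical(a$is_stop, b$is_stop))
  expect_identical(a, generate_trial_sequence(task_config(), seed = 10))
})

test_that("the staircase steps by 50 ms and clamps at its bounds", {
  cfg <- task_config()
  expect_equal(staircase_update(500, TRUE, cfg), 550)
  expect_equal(staircase_update(500, FALSE, cfg), 450)
  expect_equal(staircase_update(50, FALSE, cfg), 50)
  expect_equal(staircase_update(1200, TRUE, cfg), 1200)
  ssd <- 500
  path <- vapply(1:12, function(i) ssd <<- staircase_update(ssd, FALSE, cfg),
                 numeric(1))
  expect_equal(path, c(seq(450, 50, by = -50), 50, 50, 50))
})

test_that("simulated blocks are deterministic and internally consistent", {
  tr <- simulate_block(seed = 42, condition = "HP")
  expect_identical(tr, simulate_block(seed = 42, condition = "HP"))
  expect_equal(nrow(tr), 288)
  expect_equal(sum(tr$is_stop), 72)
  # SSD only on stop trials, inside bounds
  expect_true(all(is.na(tr$ssd[tr$is_stop == 0])))
  expect_true(all(tr$ssd[tr$is_stop == 1] >= 50 &
                    tr$ssd[tr$is_stop == 1] <= 1200))
  # RTs inside the response window; absent iff no response
  expect_true(all(is.finite(tr$rt) == tr$responded))
  expect_true(all(tr$rt[tr$responded] > 0 &
                    tr$rt[tr$responded] <= 1200))
  # earnings follow the punishment contingency: -$0.25 per failed stop
  stop_tr <- tr[tr$is_stop == 1, ]
  expect_equal(stop_tr$earnings_delta,
               ifelse(stop_tr$stop_error, -0.25, 0))
  # the recorded expectation is the belief-filter prediction
  expect_equal(tr$pstop_agent, dbm_pstop(tr$is_stop, agent_config()$dbm),
               tolerance = 1e-12)
})

test_that("reward blocks pay successful stops", {
  tr <- simulate_block(seed = 43, condition = "LR")
  stop_tr <- tr[tr$is_stop == 1, ]
  expect_equal(stop_tr$earnings_delta,
               ifelse(stop_tr$stop_error, 0, 0.05))
  expect_true(all(tr$earnings_delta[tr$is_stop == 0] == 0))
})

test_that("a lapse-free fast agent responds and chooses correctly on go", {
  agent <- agent_config(rt_base = 500, rt_pstop_slope = 0, rt_noise_sd = 30,
                        exg_tau = 30, omission_rate = 0,
                        choice_error_rate = 0)
  tr <- simulate_block(task_config(), agent, condition = "LR", seed = 3)
  go <- tr[tr$is_stop == 0, ]
  expect_true(all(go$responded))
  expect_true(all(go$go_correct))
})

test_that("proactive slowing is recoverable from the generator's own RTs", {
  tr <- do.call(rbind, lapply(1:3, function(i)
    simulate_block(seed = 200 + i, condition = "LR")))
  el <- tr$is_stop == 0 & is.finite(tr$rt)
  f <- robust_fit(tr$pstop_agent[el], tr$rt[el])
  expect_gt(f$slope, 0)
  expect_gt(f$r_squared, 0.2)
})

test_that("high-stake blocks slow mean go RT", {
  agent <- agent_config(rt_stake_offset = 40, rt_pstop_slope = 0)
  lo <- simulate_block(task_config(), agent, condition = "LR", seed = 7)
  hi <- simulate_block(task_config(), agent, condition = "HR", seed = 7)
  expect_gt(mean(hi$rt[hi$is_stop == 0], na.rm = TRUE),
            mean(lo$rt[lo$is_stop == 0], na.rm = TRUE) + 10)
})

test_that("amplitude synthesis applies the coded effect structure", {
  tr <- simulate_experiment(4, seed = 9, n_grid = 100)

  # all-zero coefficients, zero noise -> constant amplitudes
  zero <- erp_effect_config(
    p1_coef = c(valence = 0, stake = 0, pstop = 0, valence_stake = 0,
                valence_pstop = 0, stake_pstop = 0, valence_stake_pstop = 0),
    n1_coef = c(valence = 0, stake = 0, pstop = 0, valence_stake = 0,
                valence_pstop = 0, stake_pstop = 0, valence_stake_pstop = 0),
    n1_attn_load = 0, trial_noise_sd = 0)
  amp0 <- synthesize_amplitudes(tr, zero, seed = 1)
  expect_equal(amp0$p1_amp, rep(5, nrow(tr)))
  expect_equal(amp0$n1_amp, rep(-5, nrow(tr)))

  # default structure: P1 rises with P(stop) in punishment, not in reward
  amp <- synthesize_amplitudes(tr, erp_effect_config(), seed = 2)
  pun <- amp$valence == "punishment"
  expect_gt(cor(amp$p1_amp[pun], amp$pstop_agent[pun]), 0.03)
  expect_lt(abs(cor(amp$p1_amp[!pun], amp$pstop_agent[!pun])), 0.05)

  # N1 slope sign flips between HR and HP
  hr <- amp$condition == "HR"
  hp <- amp$condition == "HP"
  expect_lt(cor(amp$n1_amp[hr], amp$pstop_agent[hr]), 0)
  expect_gt(cor(amp$n1_amp[hp], amp$pstop_agent[hp]), 0)
})

test_that("rendered epochs carry the injected components", {
  tr <- data.frame(subject = 1, condition = "LR", trial_index = 1:3,
                   p1_amp = c(5, 0, 5), n1_amp = c(0, 0, -4))
  eff <- erp_effect_config(latency_jitter = 0, epoch_noise_sd = 0)
  ep <- render_epochs(tr, eff, seed = 1)
  expect_s3_class(ep, "sst_epochs")
  t_win <- ep$times >= 90 & ep$times <= 120

  # noiseless: max in the P1 window equals the amplitude at the center
  expect_equal(max(ep$data[1, t_win, 1]), 5, tolerance = 1e-9)
  expect_equal(ep$times[which.max(ep$data[1, , 1])], 104)

  # zero amplitudes -> flat epoch
  expect_lt(max(abs(ep$data[, , 2])), 1e-12)

  # determinism
  ep2 <- render_epochs(tr, eff, seed = 1)
  expect_identical(ep$data, ep2$data)
})

test_that("epoch containers round-trip through the text format", {
  tr <- data.frame(subject = 1, condition = "HR", trial_index = 1:2,
                   p1_amp = c(3, 4), n1_amp = c(-2, -5))
  ep <- render_epochs(tr, erp_effect_config(epoch_noise_sd = 1), seed = 4)
  path <- file.path(tempdir(), "epochs_test")
  write_epochs(ep, path)
  ep2 <- read_epochs(path)
  expect_equal(ep2$data, ep$data, tolerance = 1e-9)
  expect_equal(ep2$times, ep$times)
  expect_equal(ep2$channels, ep$channels)
  unlink(paste0(path, c(".csv", ".json")))
})
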