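test_that("stepwise weights recover the kernel geometry on noiseless targets", {
  set.seed(131)
  n <- 6000
  alpha <- 0.35
  ev <- sample(c("left", "right"), n, replace = TRUE)
  target <- kernel_prior(ev, alpha)
  W <- orthogonalize_past(target, ev, K = 8)
  # +/-1 coding halves the per-lag contribution: W_k ~ alpha (1-alpha)^(k-1) / 2
  expect_equal(as.numeric(W), alpha * (1 - alpha)^(0:7) / 2,
               tolerance = 0.06)
  # monotone geometric decay
  expect_true(all(diff(as.numeric(W)) < 0))
  # ratio between successive lags approximates 1 - alpha
  expect_equal(mean(W[2:5] / W[1:4]), 1 - alpha, tolerance = 0.05)
  # K = 1 collapses to a simple regression slope
  ev_num <- ifelse(ev == "right", 1, -1)
  W1 <- orthogonalize_past(target, ev, K = 1)
  slope <- coef(lm(target[-1] ~ ev_num[-n]))[2]
  expect_equal(as.numeric(W1), unname(slope), tolerance = 1e-10)
  # a target independent of the events has vanishing weights
  W0 <- orthogonalize_past(rnorm(n), ev, K = 8)
  expect_lt(max(abs(W0)), 0.05)
  # invariance to adding a constant to the target
  expect_equal(as.numeric(orthogonalize_past(target + 3, ev, K = 8)),
               as.numeric(W), tolerance = 1e-10)
  # constant event columns are flagged, not fitted
  Wc <- orthogonalize_past(target, rep("right", n), K = 2)
  expect_true(all(attr(Wc, "flags")))
  expect_equal(as.numeric(Wc), c(0, 0))
})

test_that("pseudosession null keeps spurious orthogonalization weights in check", {
  s <- fx_session()
  nm <- fx_counts()
  res <- orthogonalization_null(
    s, t(nm$values), agent_fit = agent_params("action_kernel", alpha = 0.3,
                                              sigma_c = 0.1),
    K = 5, M = 15, spec = fx_spec(n_runs = 1), seed = 3)
  expect_length(res$weights, 5)
  expect_equal(dim(res$null_weights), c(15L, 5L))
  # the decoded ideal-observer prior depends on recent stimuli, hence on
  # recent actions of a prior-following agent: lag-1 weight is significant
  expect_true(res$significant[1])
  # stimulus variant needs no behavioural model
  res_s <- orthogonalization_null(s, t(nm$values), K = 3, M = 10,
                                  spec = fx_spec(n_runs = 1),
                                  events = "stimulus", seed = 4)
  expect_length(res_s$weights, 3)
  expect_true(res_s$significant[1])
})

test_that("the neural agent inherits asymmetry only from action-kernel latents", {
  set.seed(141)
  deltas <- sapply(1:8, function(i) {
    s <- generate_session(task_config(), seed = 1100 + i)
    sim <- simulate_agent(s, agent_params("action_kernel", alpha = 0.25,
                                          sigma_c = 0.1), seed = 1200 + i)
    ak_trace <- kernel_prior(sim$choice, 0.25)
    bo_trace <- as.numeric(bayes_optimal_prior(sim))
    c(ak = neural_agent_asymmetry(ak_trace, sim)$delta,
      bo = neural_agent_asymmetry(bo_trace, sim)$delta)
  })
  expect_gt(mean(deltas["ak", ], na.rm = TRUE), 0.05)
  # the ideal-observer trace yields no asymmetry; with greedy choices the
  # "after error" condition may be empty entirely, which also means none
  bo_delta <- mean(deltas["bo", ], na.rm = TRUE)
  expect_true(is.nan(bo_delta) || abs(bo_delta) < 0.08)
  # ties at exactly 0.5 resolve to a left choice
  s <- generate_session(task_config(n_trials = 120), seed = 142)
  out <- neural_agent_asymmetry(rep(0.5, 120), s)
  expect_true(is.na(out$delta) || out$p_correct_after_correct <= 1)
})

test_that("decay-rate unit inclusion enforces all three criteria", {
  set.seed(151)
  n <- 400
  prior <- runif(n)
  silent <- rep(0L, n)
  bursty <- rpois(n, 0.15) * rpois(n, 3)       # median zero, mean above 0.2
  modulated <- rpois(n, 2 + 3 * prior)
  steady <- rpois(n, 2)                        # active but prior-independent
  counts <- rbind(silent, bursty, modulated, steady)
  mask <- decay_unit_mask(counts, prior)
  expect_identical(unname(mask),
                   c(FALSE, FALSE, TRUE, FALSE))
})

test_that("decay fitting recovers kernel parameters from model-generated data", {
  set.seed(161)
  n <- 600
  a <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.45, 0.55))
  # Poisson flavour with known learning rate and scaling factors
  sess <- data.frame(choice = ifelse(a > 0, "right", "left"))
  cfg <- synth_neural_config(n_units = 8, alpha = 0.2, zeta_pos = 5,
                             zeta_neg = 1, seed = 162)
  nm <- gen_ephys_counts(sess, NULL, cfg, flavour = "action_kernel")
  fit <- fit_decay(nm$values, a, modality = "ephys_counts",
                   unit_mask = rep(TRUE, 8), n_starts = 6)
  expect_equal(attr(fit, "session_alpha"), 0.2, tolerance = 0.05)
  expect_equal(mean(fit$zeta_pos), 5, tolerance = 0.6)
  expect_equal(mean(fit$zeta_neg), 1, tolerance = 0.4)
  # alpha -> 1 generator pushes the fit to the fast-coding limit
  cfg1 <- synth_neural_config(n_units = 6, alpha = 0.98, zeta_pos = 6,
                              zeta_neg = 1, seed = 163)
  nm1 <- gen_ephys_counts(sess, NULL, cfg1, flavour = "action_kernel")
  fit1 <- fit_decay(nm1$values, a, modality = "ephys_counts",
                    unit_mask = rep(TRUE, 6), n_starts = 6)
  expect_gt(attr(fit1, "session_alpha"), 0.8)
  # Gaussian flavour recovers (alpha, zeta, sigma) jointly
  cfgw <- synth_neural_config(n_units = 6, alpha = 0.3, zeta = 2,
                              sigma = 0.5, spatial_rank = 1, seed = 164)
  q <- blockprior:::decay_q_trace(0.3, 2 * a, 2 * (2 * mean(a == 1) - 1))
  Xw <- t(sapply(1:6, function(u) rnorm(n, q, 0.5)))
  fitw <- fit_decay(Xw, a, modality = "wfi_dff", n_starts = 6)
  expect_equal(attr(fitw, "session_alpha"), 0.3, tolerance = 0.05)
  expect_equal(mean(fitw$zeta_pos), 2, tolerance = 0.3)
  expect_equal(mean(fitw$sigma), 0.5, tolerance = 0.1)
})

test_that("neural and behavioural timescales correlate when they share a clock", {
  set.seed(171)
  alphas <- seq(0.1, 0.8, length.out = 6)
  neural <- sapply(alphas, function(al) {
    a <- sample(c(-1, 1), 500, replace = TRUE)
    sess <- data.frame(choice = ifelse(a > 0, "right", "left"))
    cfg <- synth_neural_config(n_units = 4, alpha = al, zeta_pos = 6,
                               zeta_neg = 1, seed = round(1000 * al))
    nm <- gen_ephys_counts(sess, NULL, cfg, flavour = "action_kernel")
    fit <- fit_decay(nm$values, a, modality = "ephys_counts",
                     unit_mask = rep(TRUE, 4), n_starts = 5)
    attr(fit, "session_alpha")
  })
  tc <- timescale_correlation(neural, alphas)
  expect_gt(tc$r, 0.9)
  expect_lt(tc$p, 0.05)
  # independent neural rates: no correlation expected
  tc0 <- timescale_correlation(sample(neural), rev(alphas))
  expect_lt(abs(tc0$r), 0.95)
  expect_identical(timescale_correlation(c(1, 2), c(1, 2))$r, NA_real_)
})
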