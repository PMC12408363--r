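test_that("ideal-observer prior matches exhaustive enumeration on toy configs", {
  cfg <- fx_toy_config(6)
  set.seed(21)
  for (rep in 1:5) {
    sides <- sample(c("left", "right"), 6, replace = TRUE)
    expect_equal(as.numeric(bayes_optimal_prior(sides, cfg)),
                 enum_prior_oracle(sides, cfg), tolerance = 1e-10)
  }
  # a longer toy horizon
  cfg9 <- fx_toy_config(9)
  sides <- sample(c("left", "right"), 9, replace = TRUE)
  expect_equal(as.numeric(bayes_optimal_prior(sides, cfg9)),
               enum_prior_oracle(sides, cfg9), tolerance = 1e-10)
})

test_that("ideal-observer prior respects lead-in, bounds and causality", {
  s <- fx_session()
  pr <- as.numeric(bayes_optimal_prior(s))
  expect_true(all(pr[1:90] == 0.5))
  expect_true(all(pr >= 0.2 - 1e-12 & pr <= 0.8 + 1e-12))
  # no look-ahead: truncating the session leaves earlier values unchanged
  pr_trunc <- as.numeric(bayes_optimal_prior(s$stim_side[1:200],
                                             session_config(s)))
  expect_equal(pr_trunc, pr[1:200], tolerance = 1e-12)
  # mirror symmetry
  flipped <- ifelse(s$stim_side == "right", "left", "right")
  expect_equal(as.numeric(bayes_optimal_prior(flipped, session_config(s))),
               1 - pr, tolerance = 1e-12)
  expect_error(bayes_optimal_prior(c("right", "up"), task_config()), "trial 2")
})

test_that("history kernel follows the leaky-integration arithmetic", {
  # printed update: pi = 0.5, alpha = 0.1, last event right -> 0.55
  expect_equal(kernel_prior(c("right", "left"), 0.1)[2], 0.55)
  # unbroken run of right events converges to 1
  pr <- kernel_prior(rep("right", 200), 0.2)
  expect_gt(pr[200], 0.999)
  # weight of the k-back event is alpha (1-alpha)^(k-1): numeric unroll
  alpha <- 0.3
  K <- 8
  base <- kernel_prior(rep("left", K + 1), alpha)
  for (k in 1:K) {
    ev <- rep("left", K + 1)
    ev[K + 1 - k] <- "right"
    expect_equal(kernel_prior(ev, alpha)[K + 1] - base[K + 1],
                 alpha * (1 - alpha)^(k - 1), tolerance = 1e-12)
  }
  # limits: alpha -> 1 repeats the last event; skip markers freeze the prior
  expect_equal(kernel_prior(c("left", "right", "left"), 1), c(0.5, 0, 1))
  expect_equal(kernel_prior(c("right", "none", NA, "left"), 0.5),
               c(0.5, 0.75, 0.75, 0.75))
  expect_error(kernel_prior("right", alpha = 0), "alpha")
})

test_that("within-trial choice probabilities compose prior, likelihood, policy", {
  p <- agent_params("bayes_optimal", sigma_c = 0.1)
  # zero contrast: likelihood uninformative, choice prob equals the prior
  expect_equal(trial_choice_prob(c(0.3, 0.8), 0, p), c(0.3, 0.8))
  # full contrast with vanishing noise: likelihood dominates
  p0 <- agent_params("bayes_optimal", sigma_c = 0.01)
  expect_equal(trial_choice_prob(0.2, 1, p0), 1, tolerance = 1e-6)
  expect_equal(trial_choice_prob(0.8, -1, p0), 0, tolerance = 1e-6)
  # lapse composition at zero contrast: 0.1 + 0.8 * 0.8
  pl <- agent_params("bayes_optimal", sigma_c = 0.1, lapse_left = 0.1,
                     lapse_right = 0.1)
  expect_equal(trial_choice_prob(0.8, 0, pl), 0.74, tolerance = 1e-10)
  # quadrature agrees with a Monte-Carlo marginalisation of the noise
  set.seed(31)
  for (cc in c(0.0625, -0.25)) {
    sig <- 0.15
    chat <- rnorm(2e5, cc, sig)
    lik_r <- dnorm(chat, abs(cc), sig); lik_l <- dnorm(chat, -abs(cc), sig)
    q <- 0.6 * lik_r / (0.6 * lik_r + 0.4 * lik_l)
    mc <- mean(q)
    pq <- agent_params("bayes_optimal", sigma_c = sig)
    expect_equal(trial_choice_prob(0.6, cc, pq), mc, tolerance = 2e-3)
  }
  expect_error(agent_params("bayes_optimal", lapse_left = 0.6,
                            lapse_right = 0.5), "lapse")
})

test_that("simulated agents reproduce their defining accuracies", {
  set.seed(41)
  sessions <- lapply(1:6, function(i)
    generate_session(task_config(), seed = 300 + i))
  # probability matching on the ideal-observer prior at zero contrast
  acc <- unlist(lapply(sessions, function(s) {
    sim <- simulate_agent(s, agent_params("bayes_optimal"), seed = 400 + s$trial[1])
    sim$reward[sim$signed_contrast == 0]
  }))
  expect_gt(mean(acc), 0.55)
  expect_lt(mean(acc), 0.68)
  # greedy omniscient-block agent reaches gamma on biased zero-contrast trials
  accg <- unlist(lapply(sessions, function(s) {
    sim <- simulate_agent(s, agent_params("true_block", policy = "greedy"),
                          seed = 500)
    z <- sim$signed_contrast == 0 & sim$block_p_right != 0.5
    sim$reward[z]
  }))
  expect_equal(mean(accg), 0.8, tolerance = 0.04)
})

test_that("only the action kernel shows the post-outcome asymmetry", {
  set.seed(51)
  mk_cohort <- function(kind, n = 32) {
    do.call(rbind, lapply(1:n, function(i) {
      s <- generate_session(task_config(), seed = 600 + i,
                            session_id = paste0(kind, i), mouse_id = "m1")
      par <- if (kind == "action_kernel")
        agent_params("action_kernel", alpha = 0.3, sigma_c = 0.1)
      else agent_params("bayes_optimal", sigma_c = 0.1)
      sim <- simulate_agent(s, par, seed = 700 + i)
      sim$included <- TRUE
      sim
    }))
  }
  ak <- post_outcome_asymmetry(mk_cohort("action_kernel"))
  bo <- post_outcome_asymmetry(mk_cohort("bayes_optimal"))
  expect_gt(ak$delta, 0.04)          # worse after an error
  # stimulus-driven priors carry no self-confirmatory signature (a small
  # prior-level selection effect remains, far below the kernel effect)
  expect_lt(abs(bo$delta), 0.1)
  expect_gt(ak$delta, bo$delta + 0.02)
})

test_that("action log-likelihoods match the generating probabilities", {
  s <- fx_session()
  # probability matching with prior 0.5 on zero-contrast trials gives log 0.5
  cfg0 <- task_config(n_trials = 50, n_unbiased = 50)
  s0 <- generate_session(cfg0, seed = 61)
  s0$choice <- sample(c("left", "right"), 50, replace = TRUE)
  ll0 <- action_loglik(s0, agent_params("bayes_optimal", sigma_c = 0.1))
  expect_equal(unname(ll0[s0$signed_contrast == 0]),
               rep(log(0.5), sum(s0$signed_contrast == 0)))
  # deterministic greedy agent that matches its own choices has log-lik 0
  grd <- simulate_agent(s, agent_params("true_block", policy = "greedy",
                                        sigma_c = 1e-3), seed = 62)
  nz <- grd$signed_contrast != 0 | grd$block_p_right != 0.5
  llg <- action_loglik(grd, agent_params("true_block", policy = "greedy",
                                         sigma_c = 1e-3))
  expect_equal(sum(llg[nz]), 0, tolerance = 1e-6)
  # log-likelihood agrees with Monte-Carlo choice frequencies at fixed history
  sim <- simulate_agent(s, agent_params("bayes_optimal", sigma_c = 0.1),
                        seed = 63)
  ll <- action_loglik(sim, agent_params("bayes_optimal", sigma_c = 0.1))
  pr <- attr(ll, "prior")
  pc <- trial_choice_prob(pr, sim$signed_contrast,
                          agent_params("bayes_optimal", sigma_c = 0.1))
  manual <- ifelse(sim$choice == "right", log(pc), log(1 - pc))
  expect_equal(as.numeric(ll), manual, tolerance = 1e-12)
  # missed trials are skipped, not counted
  sim$choice[5] <- "none"
  expect_true(is.na(action_loglik(sim, agent_params("bayes_optimal"))[5]))
})
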