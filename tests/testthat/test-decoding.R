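test_that("nested cross-validation recovers realizable targets and rejects noise", {
  set.seed(101)
  X <- matrix(rnorm(300 * 8), 300, 8)
  beta <- rnorm(8)
  y <- drop(X %*% beta)
  spec <- decode_spec("custom", penalty = "L2", lambda = 10^(-6:-3),
                      n_runs = 2, inner_folds = 3)
  r <- nested_cv_decode(X, y, spec, seed = 1)
  expect_gt(r$r2, 0.99)
  expect_length(r$predictions, 300)
  expect_false(anyNA(r$predictions))
  # a permuted target has no signal: held-out score at or below zero
  r_perm <- nested_cv_decode(X, sample(y), spec, seed = 1)
  expect_lt(r_perm$r2, 0.05)
  expect_error(nested_cv_decode(X, rep(1, 300), spec), "degenerate")
  expect_error(nested_cv_decode(X[, 1:3], y, decode_spec("ephys")),
               "features")
})

test_that("single-value grids collapse to a plain cross-validation oracle", {
  set.seed(102)
  X <- matrix(rnorm(200 * 6), 200, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(200, 0, 0.5)
  lam <- 0.01
  spec <- decode_spec("custom", penalty = "L2", lambda = lam,
                      outer_folds = 4, n_runs = 1)
  r <- nested_cv_decode(X, y, spec, seed = 9)
  # oracle: same interleaved folds, one ridge fit per fold at that lambda
  set.seed(9)
  fold <- sample(rep_len(1:4, 200))
  preds <- numeric(200)
  for (f in 1:4) {
    tr <- fold != f
    fit <- glmnet::glmnet(X[tr, ], y[tr], alpha = 0, lambda = lam,
                          standardize = TRUE)
    preds[!tr] <- predict(fit, X[!tr, , drop = FALSE], s = lam)
  }
  oracle_r2 <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  expect_equal(r$r2, oracle_r2, tolerance = 1e-10)
  expect_equal(r$predictions, preds, tolerance = 1e-10)
})

test_that("pseudosession nulls yield smoothed p-values and corrected scores", {
  s <- fx_session()
  nm <- fx_counts()
  spec <- fx_spec(n_runs = 1)
  res <- pseudosession_significance(
    nm, s, function(x) as.numeric(bayes_optimal_prior(x)), spec, M = 19,
    seed = 3, collect_weights = TRUE)
  expect_length(res$null_r2, 19)
  expect_equal(res$p_value, (1 + sum(res$null_r2 >= res$r2)) / 20)
  expect_equal(res$corrected_r2, res$r2 - median(res$null_r2))
  # strongly coupled activity beats every pseudo target
  expect_equal(res$p_value, 1 / 20)
  expect_equal(dim(res$null_weights), c(19L, 12L))
  # corrected score is invariant to adding a constant to all scores
  shifted <- (res$r2 + 1) - median(res$null_r2 + 1)
  expect_equal(shifted, res$corrected_r2)
})

test_that("Fisher's method matches its closed form", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  # chi-square with 4 d.f.: survival = exp(-x/2) (1 + x/2)
  x2 <- -2 * (log(0.5) + log(0.5))
  expect_equal(x2, 2.7726, tolerance = 1e-4)
  expect_equal(fisher_combine(c(0.5, 0.5)), exp(-x2 / 2) * (1 + x2 / 2),
               tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.5, 0.5)), 0.5966, tolerance = 1e-4)
  # a single p-value passes through unchanged
  expect_equal(fisher_combine(0.123), 0.123, tolerance = 1e-12)
  expect_warning(out <- fisher_combine(c(0, 0.5)))
  expect_true(out >= 0 && out < 1e-10)
})

test_that("Benjamini-Hochberg selection matches a brute-force step-up oracle", {
  expect_identical(bh_select(numeric(0)), logical(0))
  expect_false(any(bh_select(rep(1, 20))))
  p <- c(1e-6, runif(241, 0.2, 1))
  expect_true(bh_select(p)[1])
  # direct step-up search oracle on random vectors
  set.seed(103)
  for (i in 1:5) {
    pv <- runif(40)^2
    fdr <- 0.1
    srt <- sort(pv)
    k <- max(c(0, which(srt <= fdr * seq_along(srt) / length(srt))))
    oracle <- if (k == 0) rep(FALSE, 40) else pv <= srt[k]
    expect_identical(bh_select(pv, fdr), oracle)
  }
})

test_that("weight significance flags only genuinely coupled units", {
  # pseudoweights identical to the weights: nothing is flagged
  res <- list(weights = rep(0.3, 6),
              null_weights = matrix(0.3, 50, 6))
  expect_false(any(weight_significance(res)))
  # a weight far outside the pseudo band is flagged
  res$weights[2] <- 5
  expect_identical(which(weight_significance(res)), 2L)
  small <- list(weights = rep(0, 3), null_weights = matrix(rnorm(30), 10))
  expect_warning(weight_significance(small), "40")
})

test_that("session subsampling reduces to the right limits", {
  p <- c(0.2, 0.04, 0.3, 0.6)
  sn <- sessions_needed(p, reps = 200, seed = 5)
  expect_equal(nrow(sn), 4)
  expect_equal(sn$median_p[4], fisher_combine(p))
  expect_equal(sessions_needed(0.37, reps = 10)$median_p, 0.37)
  # oracle: direct resampling at N = 2
  set.seed(5)
  direct <- median(replicate(500, fisher_combine(sample(p, 2))))
  expect_equal(sn$median_p[2], direct, tolerance = 0.1)
})

test_that("residual decoding separates embodied and independent prior signals", {
  s <- fx_session()
  prior <- as.numeric(s$prior)
  spec_cov <- decode_spec("dlc", n_runs = 1, inner_folds = 3,
                          min_features = 1)
  spec_n <- fx_spec(n_runs = 1)
  nm <- fx_counts()
  # covariates that fully explain the prior leave a null residual
  cov_full <- cbind(gen_covariates(s, prior, coupling = 1, noise_sd = 0.01,
                                   seed = 21)[, 1:3])
  rd <- residual_decode(prior, cov_full, nm, spec_cov, spec_n, seed = 7)
  expect_gt(rd$covariate_r2, 0.95)
  expect_lt(rd$residual_r2, 0.2)
  expect_lt(sd(rd$residual), 0.1 * sd(prior))
  # pure-noise covariates leave the residual equal to the prior
  cov_noise <- gen_covariates(s, prior, coupling = 0, seed = 22)
  rd2 <- residual_decode(prior, cov_noise, nm, spec_cov, spec_n, seed = 7)
  expect_gt(cor(rd2$residual, prior - mean(prior)), 0.95)
  expect_equal(rd2$residual_r2, rd2$neural_r2, tolerance = 0.2)
  # constant covariates degrade gracefully
  rd3 <- residual_decode(prior, matrix(1, nrow(s), 3), nm, spec_cov,
                         spec_n, seed = 7)
  expect_equal(rd3$covariate_r2, 0)
  expect_equal(rd3$residual, prior - mean(prior))
})

test_that("decoded-prior deciles track choices built on them", {
  s <- fx_session()
  nm <- fx_counts()
  dec <- nested_cv_decode(nm, s$prior, fx_spec(), seed = 8)
  # choices sampled by probability matching on the decoded prior
  set.seed(104)
  s$choice <- ifelse(runif(nrow(s)) < pmin(pmax(dec$predictions, 0), 1),
                     "right", "left")
  bundle <- list(trials = s, X = t(nm$values), decoded_prior = dec$predictions)
  pc <- prior_choice_coupling(list(bundle), fx_spec(n_runs = 1), M = 8,
                              seed = 9,
                              agent_fits = list(
                                agent_params("action_kernel", alpha = 0.3,
                                             sigma_c = 0.1)))
  cur <- pc$decile_curve
  expect_equal(nrow(cur), 10)
  # decile curve approximates the identity and rises monotonically
  expect_lt(mean(abs(cur$p_right - cur$decoded_prior), na.rm = TRUE), 0.2)
  expect_gt(cor(cur$decile, cur$p_right, use = "complete.obs"), 0.5)
  expect_gt(pc$mean_slope, 0)
  expect_length(pc$null_slopes, 8)
})
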