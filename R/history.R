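#' Stepwise orthogonalization of the decoded prior against past events
#'
#' Regresses the decoded prior on the lag-1 event, takes the residual,
#' regresses it on the lag-2 event, and iterates to lag `K`. The stepwise
#' residualization absorbs autocorrelation among the events, so each weight
#' reflects the marginal contribution of its lag.
#'
#' @param decoded_prior Per-trial (cross-validated) decoded prior.
#' @param events Past events, +/-1 coded (or `"left"`/`"right"`): previous
#'   actions or previous stimulus sides, one per trial.
#' @param K Number of lags.
#' @return Numeric vector of `K` weights, with attribute `flags` marking
#'   lags whose event column was constant (weight forced to 0).
#' @export
orthogonalize_past <- function(decoded_prior, events, K = 10) {
  if (is.character(events))
    events <- ifelse(events == "right", 1, ifelse(events == "left", -1,
                                                  NA_real_))
  n <- length(decoded_prior)
  stopifnot(length(events) == n, K >= 1, n > K)
  target <- as.numeric(decoded_prior)[(K + 1):n]
  W <- numeric(K)
  flags <- logical(K)
  for (k in seq_len(K)) {
    xk <- events[(K + 1 - k):(n - k)]
    ok <- !is.na(xk) & !is.na(target)
    if (stats::var(xk[ok]) == 0) {
      flags[k] <- TRUE
      next
    }
    fit <- stats::lm(target[ok] ~ xk[ok])
    W[k] <- unname(stats::coef(fit)[2])
    target[ok] <- stats::residuals(fit)
  }
  structure(W, flags = flags)
}

#' Pseudosession null for orthogonalization weights
#'
#' Simulates a fitted action-kernel agent on pseudosessions, decodes each
#' pseudosession's prior from the real activity, and reruns the stepwise
#' regression on (pseudoactions, decoded pseudo-prior) pairs. Any non-zero
#' pseudo-weight is by construction spurious, so the across-pseudo 95th
#' percentile per lag is the significance threshold. With
#' `events = "stimulus"`, the pseudosessions' own stimuli are used and no
#' behavioural model is needed.
#'
#' @param session Trial table with choices.
#' @param X Trials x units activity.
#' @param agent_fit An [agent_params()] action-kernel fit for the session
#'   (fitted by a short MH run when `NULL`; ignored for stimuli).
#' @param K Lags.
#' @param M Pseudosessions.
#' @param spec Decoder spec for the pseudo-prior decoding.
#' @param events `"action"` or `"stimulus"`.
#' @param seed Integer seed.
#' @return List with `weights` (actual), `null_weights` (M x K),
#'   `significant` (per lag, actual above the 95th percentile of the null).
#' @export
orthogonalization_null <- function(session, X, agent_fit = NULL, K = 10,
                                   M = 200, spec = decode_spec("ephys"),
                                   events = c("action", "stimulus"),
                                   seed = 1) {
  events <- match.arg(events)
  X <- as_trials_by_features(X)
  prior <- as.numeric(bayes_optimal_prior(session))
  dec <- nested_cv_decode(X, prior, spec, seed = seed)
  ev <- if (events == "action") session$choice else session$stim_side
  W <- orthogonalize_past(dec$predictions, ev, K)
  if (events == "action" && is.null(agent_fit)) {
    mh <- tryCatch(fit_agent_mh(session, "action_kernel", seed = seed,
                                max_steps = 1200, min_steps = 1000),
                   error = function(e) NULL)
    if (is.null(mh)) stop("action-kernel fit failed; session skipped",
                          call. = FALSE)
    agent_fit <- vec_to_params("action_kernel", colMeans(mh$samples))
  }
  pseudo <- generate_pseudosessions(session, M, seed = seed + 1L)
  null_w <- matrix(NA_real_, M, K)
  for (i in seq_len(M)) {
    ps <- pseudo$sessions[[i]]
    pp <- as.numeric(bayes_optimal_prior(ps))
    dps <- nested_cv_decode(X, pp, spec, seed = seed + i)
    ev_i <- if (events == "action") {
      sim <- simulate_agent(ps, agent_fit, seed = seed + 10 * i)
      sim$choice
    } else ps$stim_side
    null_w[i, ] <- as.numeric(orthogonalize_past(dps$predictions, ev_i, K))
  }
  thresh <- apply(null_w, 2, stats::quantile, 0.95, na.rm = TRUE)
  list(weights = as.numeric(W), null_weights = null_w,
       significant = as.numeric(W) > thresh)
}

#' Post-outcome asymmetry of the neural (decoded-prior) agent
#'
#' Simulates an agent that greedily follows the decoded prior (right iff
#' decoded prior > 0.5, ties broken to left) and measures its accuracy
#' conditioned on the previous hypothetical outcome, under the
#' block-conformance filters of [post_outcome_asymmetry()] but without the
#' zero-contrast restriction (the agent only uses pre-stimulus activity).
#'
#' @param decoded_prior Cross-validated decoded prior per trial.
#' @param trials Trial table.
#' @param min_from_reversal Minimum distance from the block start.
#' @return List as in [post_outcome_asymmetry()], computed for the
#'   hypothetical agent within this session.
#' @export
neural_agent_asymmetry <- function(decoded_prior, trials,
                                   min_from_reversal = 10) {
  s <- trials[order(trials$trial), ]
  agent_choice <- ifelse(decoded_prior > 0.5, "right", "left")
  s$choice <- agent_choice
  s$reward <- as.integer(agent_choice == s$stim_side)
  s$included <- TRUE
  n <- nrow(s)
  fav <- block_favoured_side(s$block_p_right)
  conform <- !is.na(fav) & s$stim_side == fav
  block_id <- cumsum(c(1, diff(s$block_p_right) != 0))
  pos_in_block <- stats::ave(seq_len(n), block_id,
                             FUN = function(i) seq_along(i) - 1)
  t <- 3:n
  ok <- conform[t] & conform[t - 1] & conform[t - 2] &
    s$reward[t - 2] == 1 & pos_in_block[t] >= min_from_reversal
  t <- t[ok]
  if (!length(t))
    return(list(p_correct_after_correct = NA_real_,
                p_correct_after_error = NA_real_, delta = NA_real_))
  prev_ok <- s$reward[t - 1] == 1
  pc <- if (any(prev_ok)) mean(s$reward[t[prev_ok]]) else NA_real_
  pe <- if (any(!prev_ok)) mean(s$reward[t[!prev_ok]]) else NA_real_
  list(p_correct_after_correct = pc, p_correct_after_error = pe,
       delta = pc - pe, n_trials = length(t))
}

#' Unit inclusion mask for decay-rate fitting
#'
#' A unit is retained when its median pre-stimulus summed count is non-zero,
#' it fires at least one spike every five trials on average, and the
#' distribution of its counts differs between trials with prior above vs
#' below 0.5 (two-sample Kolmogorov-Smirnov p < 0.05).
#'
#' @param counts Units x trials matrix of summed pre-stimulus counts.
#' @param prior_trace Per-trial prior.
#' @param ks_alpha KS significance level.
#' @return Logical inclusion flag per unit.
#' @export
decay_unit_mask <- function(counts, prior_trace, ks_alpha = 0.05) {
  hi <- prior_trace > 0.5
  lo <- prior_trace < 0.5
  apply(counts, 1, function(x) {
    if (stats::median(x) == 0) return(FALSE)
    if (mean(x) < 0.2) return(FALSE)
    if (!any(hi) || !any(lo)) return(FALSE)
    ks <- suppressWarnings(stats::ks.test(x[hi], x[lo]))
    ks$p.value < ks_alpha
  })
}

# latent trace of the kernel-integration model; targets is the per-trial
# update value (zeta^a or zeta * a), NA for missed trials (no update)
decay_q_trace <- function(alpha, targets, q0) {
  n <- length(targets)
  q <- numeric(n)
  cur <- q0
  for (t in seq_len(n)) {
    q[t] <- cur
    if (!is.na(targets[t])) cur <- (1 - alpha) * cur + alpha * targets[t]
  }
  q
}

# negative log-likelihood of one unit under the kernel-integration model
decay_nll <- function(par, x, a, modality) {
  alpha <- par[1]
  if (modality == "ephys_counts") {
    zp <- par[2]; zn <- par[3]
    p_r <- mean(a == 1, na.rm = TRUE)
    targets <- ifelse(is.na(a), NA_real_, ifelse(a > 0, zp, zn))
    q <- decay_q_trace(alpha, targets, p_r * zp + (1 - p_r) * zn)
    -sum(stats::dpois(x, pmax(q, 1e-9), log = TRUE))
  } else {
    zeta <- par[2]; sigma <- par[3]
    targets <- ifelse(is.na(a), NA_real_, zeta * a)
    q <- decay_q_trace(alpha, targets, zeta * (2 * mean(a == 1,
                                                        na.rm = TRUE) - 1))
    -sum(stats::dnorm(x, q, sigma, log = TRUE))
  }
}

#' Maximum-likelihood neural decay-rate fit
#'
#' Assumes each unit's activity arises from a leaky integration of past
#' actions (or stimulus sides): for spike counts,
#' `X ~ Poisson(Q)` with `Q_t = (1-alpha) Q_{t-1} + alpha * zeta^(a)` and
#' separate scaling factors after right/left events; for widefield,
#' `X ~ Normal(Q, sigma)` with `Q_t = (1-alpha) Q_{t-1} + alpha * zeta * a`.
#' `Q` starts at the stationary mean under the empirical event frequencies;
#' missed trials skip the update. Each unit is fitted by bounded
#' multi-start optimisation; the session-level neural learning rate is the
#' mean fitted `alpha` across included units.
#'
#' @param activity A [neural_matrix()] or units x trials matrix.
#' @param events +/-1 coded events per trial (`NA` = missed), or a trial
#'   table whose choices are used.
#' @param modality `"ephys_counts"` or `"wfi_dff"` (taken from the
#'   container when available).
#' @param unit_mask Optional logical mask; computed by [decay_unit_mask()]
#'   for spike counts when `NULL` (all units for widefield).
#' @param prior_trace Prior trace used by the default unit mask.
#' @param n_starts Optimiser restarts per unit.
#' @return An object of class `decay_fit`: `data.frame` of per-unit
#'   parameters with the session-level `alpha` in attribute
#'   `session_alpha`.
#' @export
fit_decay <- function(activity, events, modality = NULL, unit_mask = NULL,
                      prior_trace = NULL, n_starts = 10) {
  if (inherits(activity, "neural_matrix")) {
    if (is.null(modality)) modality <- activity$modality
    activity <- activity$values
  }
  if (is.null(modality)) modality <- "ephys_counts"
  if (is.data.frame(events)) events <- signed_actions(events)
  nT <- ncol(activity)
  stopifnot(length(events) == nT)
  if (is.null(unit_mask)) {
    unit_mask <- if (modality == "ephys_counts" && !is.null(prior_trace))
      decay_unit_mask(activity, prior_trace) else rep(TRUE, nrow(activity))
  }
  lower <- c(1e-3, if (modality == "ephys_counts") c(1e-6, 1e-6) else
    c(-50, 1e-4))
  upper <- c(1, if (modality == "ephys_counts") c(100, 100) else c(50, 50))
  fits <- lapply(which(unit_mask), function(u) {
    x <- activity[u, ]
    best <- NULL
    for (i in seq_len(n_starts)) {
      st <- c(stats::runif(1, 0.02, 0.9),
              if (modality == "ephys_counts")
                pmax(c(mean(x), mean(x)) * stats::runif(2, 0.5, 2), 0.01)
              else c(mean(x) + stats::rnorm(1, 0, max(stats::sd(x), 0.1)),
                     max(stats::sd(x), 0.05) * stats::runif(1, 0.5, 2)))
      o <- tryCatch(stats::optim(st, decay_nll, x = x, a = events,
                                 modality = modality, method = "L-BFGS-B",
                                 lower = lower, upper = upper),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) return(NULL)
    if (modality == "ephys_counts")
      data.frame(unit = u, alpha = best$par[1], zeta_pos = best$par[2],
                 zeta_neg = best$par[3], sigma = NA_real_,
                 logLik = -best$value)
    else
      data.frame(unit = u, alpha = best$par[1], zeta_pos = best$par[2],
                 zeta_neg = NA_real_, sigma = best$par[3],
                 logLik = -best$value)
  })
  dropped <- sum(vapply(fits, is.null, logical(1)))
  if (dropped) warning(dropped, " unit(s) failed to converge and were dropped")
  out <- do.call(rbind, fits)
  if (is.null(out)) stop("no unit could be fitted", call. = FALSE)
  structure(out, session_alpha = mean(out$alpha), modality = modality,
            class = c("decay_fit", "data.frame"))
}

#' Correlation between neural and behavioural timescales
#'
#' Pearson correlation across sessions between the session-level neural
#' learning rate (mean fitted decay `alpha` over included units) and the
#' behavioural learning rate from the action-kernel fit.
#'
#' @param neural_alpha Session-level neural learning rates.
#' @param behavioural_alpha Matching behavioural learning rates.
#' @return List with `r`, `p`, `n` (`NA`s with fewer than 3 sessions).
#' @export
timescale_correlation <- function(neural_alpha, behavioural_alpha) {
  ok <- stats::complete.cases(neural_alpha, behavioural_alpha)
  if (sum(ok) < 3) return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(neural_alpha[ok], behavioural_alpha[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
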