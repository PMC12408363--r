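#' Agent parameter sets
#'
#' Bundles the parameters of the behavioural models: the Bayes-optimal ideal
#' observer, the exponential action/stimulus history kernels, and an
#' omniscient true-block agent. All agents share the same within-trial
#' decision rule: a posterior over stimulus side is formed from the prior and
#' a noisy contrast percept, then mapped to a choice by probability matching
#' or a greedy rule, with left/right lapses.
#'
#' @param kind One of `"bayes_optimal"`, `"action_kernel"`,
#'   `"stimulus_kernel"`, `"true_block"`.
#' @param alpha Kernel learning rate in (0, 1\] (kernel models only).
#' @param sigma_c Sensory-noise standard deviation on the perceived contrast.
#' @param lapse_left,lapse_right Lapse rates (>= 0, sum < 1).
#' @param policy `"probability_matching"` (sample from the posterior) or
#'   `"greedy"` (pick the maximum-posterior side).
#' @param pi_init Initial kernel prior.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(kind = c("bayes_optimal", "action_kernel",
                                  "stimulus_kernel", "true_block"),
                         alpha = NULL, sigma_c = 0.12, lapse_left = 0,
                         lapse_right = 0,
                         policy = c("probability_matching", "greedy"),
                         pi_init = 0.5) {
  kind <- match.arg(kind)
  policy <- match.arg(policy)
  if (kind %in% c("action_kernel", "stimulus_kernel")) {
    if (is.null(alpha)) alpha <- 0.3
    if (!(alpha > 0 && alpha <= 1))
      stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  if (lapse_left < 0 || lapse_right < 0 || lapse_left + lapse_right >= 1)
    stop("lapse rates must be >= 0 and sum to < 1", call. = FALSE)
  if (sigma_c <= 0) stop("`sigma_c` must be positive", call. = FALSE)
  structure(list(kind = kind, alpha = alpha, sigma_c = sigma_c,
                 lapse_left = lapse_left, lapse_right = lapse_right,
                 policy = policy, pi_init = pi_init),
            class = "agent_params")
}

#' Bayes-optimal prior by forward filtering
#'
#' Exact forward filtering over the hidden state (block side, block age)
#' under the truncated-exponential block-length law. The hazard of a block
#' ending at age `a` is `pmf(a) / P(L >= a)`, with a forced side switch at
#' `block_max`. The prior for trial `t` is the predictive probability of a
#' right-side stimulus given sides `1..t-1` only; the unbiased lead-in
#' returns exactly 0.5 and filtering starts at the first biased trial with
#' equal side probabilities and age 1.
#'
#' @param stim_sides Character vector of observed sides (`"left"`/`"right"`)
#'   or a trial table.
#' @param config A [task_config()]; taken from the trial table if omitted.
#' @return Numeric vector of per-trial prior probabilities of "stimulus
#'   right", with attribute `model = "bayes_optimal"`.
#' @export
bayes_optimal_prior <- function(stim_sides, config = NULL) {
  if (is.data.frame(stim_sides)) {
    if (is.null(config)) config <- session_config(stim_sides)
    stim_sides <- stim_sides$stim_side
  }
  if (is.null(config)) config <- task_config(n_trials = length(stim_sides))
  bad <- !stim_sides %in% c("left", "right")
  if (any(bad))
    stop("unknown stimulus side token at trial ", which(bad)[1], call. = FALSE)
  n <- length(stim_sides)
  gamma <- config$gamma
  n_unb <- min(config$n_unbiased, n)
  prior <- rep(0.5, n)
  if (n > n_unb) {
    haz <- block_length_dist(config)$hazard
    bmax <- config$block_max
    bel <- matrix(0, 2, bmax)   # rows: block side left / right; cols: age
    bel[, 1] <- 0.5
    s_right <- stim_sides == "right"
    for (t in (n_unb + 1):n) {
      p_side <- rowSums(bel)
      prior[t] <- p_side[1] * (1 - gamma) + p_side[2] * gamma
      em <- if (s_right[t]) c(1 - gamma, gamma) else c(gamma, 1 - gamma)
      bel <- bel * em
      bel <- bel / sum(bel)
      stay <- bel * rep(1 - haz, each = 2)
      switched <- rowSums(bel * rep(haz, each = 2))
      bel <- cbind(rev(switched), stay[, -bmax, drop = FALSE])
    }
  }
  structure(prior, model = "bayes_optimal")
}

#' Exponential history-kernel prior
#'
#' Leaky accumulation of past binary events (previous actions for the action
#' kernel, previous stimulus sides for the stimulus kernel):
#' `pi_t = (1 - alpha) * pi_{t-1} + alpha * [event_{t-1} == right]`.
#' Missed trials (`NA` or `"none"`) leave the prior unchanged.
#'
#' @param events Character vector (`"left"`/`"right"`, with `NA`/`"none"`
#'   as skip markers) of the events feeding the kernel, one per trial.
#' @param alpha Learning rate in (0, 1\].
#' @param pi_init Prior before any event.
#' @return Numeric vector: the prior in force on each trial (element `t`
#'   reflects events `1..t-1`).
#' @export
kernel_prior <- function(events, alpha, pi_init = 0.5) {
  if (!(alpha > 0 && alpha <= 1))
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  n <- length(events)
  skip <- is.na(events) | events == "none"
  x <- as.numeric(events == "right")
  if (!any(skip)) {
    # plain AR(1) recursion: vectorised via a recursive filter
    if (n == 1) return(pi_init)
    z <- stats::filter(alpha * x[-n], 1 - alpha, method = "recursive",
                       init = pi_init)
    return(c(pi_init, as.numeric(z)))
  }
  pri <- numeric(n)
  p <- pi_init
  for (t in seq_len(n)) {
    pri[t] <- p
    if (!skip[t]) p <- (1 - alpha) * p + alpha * x[t]
  }
  pri
}

# Gauss-Hermite nodes/weights by Golub-Welsch; weights normalised so that
# sum(w * f(sqrt(2) * sigma * x + mu)) approximates E[f(N(mu, sigma^2))].
# Cached: the quadrature sits inside every likelihood evaluation.
.gh_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(n = 61) {
  key <- as.character(n)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  out <- if (n == 1) list(x = 0, w = 1) else {
    b <- sqrt(seq_len(n - 1) / 2)
    J <- diag(0, n)
    J[cbind(seq_len(n - 1), 2:n)] <- b
    J[cbind(2:n, seq_len(n - 1))] <- b
    e <- eigen(J, symmetric = TRUE)
    idx <- order(e$values)
    list(x = e$values[idx], w = e$vectors[1, idx]^2)
  }
  .gh_cache[[key]] <- out
  out
}

# Likelihood of a noisy percept given each stimulus side, conditioned on the
# trial's contrast magnitude: the percept informs the side, not the
# magnitude, so a zero-contrast percept is uninformative and the posterior
# collapses to the prior. Returns a matrix percepts x 2 (left, right).
percept_likelihood <- function(chat, mag, sigma) {
  cbind(left = stats::dnorm(chat, mean = -mag, sd = sigma),
        right = stats::dnorm(chat, mean = mag, sd = sigma))
}

#' Probability of choosing right on one trial
#'
#' Composes the subjective prior with a noisy-percept likelihood: the
#' perceived contrast is Normal around the true signed contrast with s.d.
#' `sigma_c`; the posterior over sides follows from Bayes' rule with the
#' percept attributed to the trial's contrast magnitude on either side (so a
#' zero-contrast percept is uninformative and the posterior equals the
#' prior); the policy maps the posterior to a choice probability, and lapses
#' mix in stimulus-independent responses. The sensory noise is marginalised
#' by 61-point Gauss-Hermite quadrature.
#'
#' @param p_right_prior Numeric vector of prior probabilities in (0, 1).
#' @param signed_contrast Numeric vector of signed contrasts (recycled).
#' @param params An [agent_params()].
#' @param config A [task_config()] supplying the contrast distribution.
#' @return Numeric vector of probabilities of a rightward choice.
#' @export
trial_choice_prob <- function(p_right_prior, signed_contrast, params,
                              config = task_config()) {
  stopifnot(inherits(params, "agent_params"))
  n <- max(length(p_right_prior), length(signed_contrast))
  p <- rep_len(p_right_prior, n)
  cc <- rep_len(signed_contrast, n)
  gh <- gauss_hermite(61)
  # unique contrasts: likelihood share per (contrast, node) computed once
  uc <- sort(unique(cc))
  m_mat <- matrix(0, length(uc), length(gh$x))
  for (i in seq_along(uc)) {
    chat <- uc[i] + sqrt(2) * params$sigma_c * gh$x
    lik <- percept_likelihood(chat, abs(uc[i]), params$sigma_c)
    denom <- lik[, "left"] + lik[, "right"]
    m_mat[i, ] <- ifelse(denom > 0, lik[, "right"] / denom,
                         as.numeric(chat > 0))
  }
  frac <- m_mat[match(cc, uc), , drop = FALSE]   # trials x nodes
  # clamp away from exact certainty so degenerate prior/likelihood pairs
  # (e.g. a learning rate of 1) cannot produce 0/0
  frac <- pmin(pmax(frac, 1e-12), 1 - 1e-12)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  q <- p * frac / (p * frac + (1 - p) * (1 - frac))
  m <- if (params$policy == "greedy")
    ifelse(q > 0.5, 1, ifelse(q < 0.5, 0, 0.5)) else q
  out <- pmin(pmax(drop(m %*% gh$w), 0), 1)
  params$lapse_right + (1 - params$lapse_left - params$lapse_right) * out
}

# Vectorised choice probabilities for a whole session given a prior trace.
choice_prob_trace <- function(prior, signed_contrast, params, config) {
  trial_choice_prob(prior, signed_contrast, params, config)
}

#' Simulate an agent on a session
#'
#' Samples choices trial by trial from [trial_choice_prob()]. For the action
#' kernel the loop is closed: each sampled choice feeds the next trial's
#' prior. Rewards follow the task rule (`reward = 1` iff the choice matches
#' the drawn stimulus side, zero-contrast trials included). Reaction times
#' are drawn log-normal so the inclusion filters have work to do.
#'
#' @param session Trial table with stimuli (from [generate_session()]).
#' @param params An [agent_params()].
#' @param seed Integer seed.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters.
#' @return The trial table with `choice`, `reward`, `reaction_time` filled
#'   in, a `prior` column holding the agent's prior trace, and the params
#'   attached as attribute `agent_params`.
#' @export
simulate_agent <- function(session, params, seed = NULL,
                           rt_meanlog = log(0.35), rt_sdlog = 0.5) {
  stopifnot(inherits(params, "agent_params"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- session_config(session)
  n <- nrow(session)
  if (params$kind == "action_kernel") {
    prior <- numeric(n)
    choice <- character(n)
    p <- params$pi_init
    for (t in seq_len(n)) {
      prior[t] <- p
      pr <- trial_choice_prob(p, session$signed_contrast[t], params, cfg)
      choice[t] <- if (stats::runif(1) < pr) "right" else "left"
      p <- (1 - params$alpha) * p + params$alpha * (choice[t] == "right")
    }
  } else {
    prior <- switch(params$kind,
      bayes_optimal = as.numeric(bayes_optimal_prior(session, cfg)),
      stimulus_kernel = kernel_prior(session$stim_side, params$alpha,
                                     params$pi_init),
      true_block = session$block_p_right)
    pr <- choice_prob_trace(prior, session$signed_contrast, params, cfg)
    choice <- ifelse(stats::runif(n) < pr, "right", "left")
  }
  session$choice <- choice
  session$reward <- as.integer(choice == session$stim_side)
  session$reaction_time <- stats::rlnorm(n, rt_meanlog, rt_sdlog)
  session$prior <- prior
  attr(session, "agent_params") <- params
  session
}

#' Per-trial action log-likelihoods under an agent model
#'
#' Evaluates `log p(a_t | history, theta)` for the observed choices, with the
#' model's prior trace conditioned on the animal's actual history (observed
#' choices for the action kernel, observed stimulus sides for the stimulus
#' kernel). Trials without a choice contribute `NA` and are skipped by kernel
#' updates.
#'
#' @param session Trial table with choices.
#' @param params An [agent_params()].
#' @return Numeric vector of per-trial log-likelihoods (`NA` for missed
#'   trials), with the prior trace attached as attribute `prior`.
#' @export
action_loglik <- function(session, params) {
  stopifnot(inherits(params, "agent_params"))
  cfg <- session_config(session)
  prior <- switch(params$kind,
    bayes_optimal = {
      # parameter-free trace: reuse a precomputed copy when the caller
      # attached one (repeated likelihood evaluations during sampling)
      cached <- attr(session, "bayes_prior_trace")
      if (is.null(cached)) as.numeric(bayes_optimal_prior(session, cfg))
      else cached
    },
    action_kernel = kernel_prior(session$choice, params$alpha, params$pi_init),
    stimulus_kernel = kernel_prior(session$stim_side, params$alpha,
                                   params$pi_init),
    true_block = session$block_p_right)
  pr <- choice_prob_trace(prior, session$signed_contrast, params, cfg)
  obs <- !is.na(session$choice) & session$choice != "none"
  ll <- rep(NA_real_, nrow(session))
  ll[obs] <- ifelse(session$choice[obs] == "right", log(pr[obs]),
                    log(1 - pr[obs]))
  if (any(is.nan(ll[obs])))
    stop("non-finite action likelihood at trial ",
         which(obs & is.nan(ll))[1], call. = FALSE)
  structure(ll, prior = prior)
}
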