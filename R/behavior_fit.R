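#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within variance ratio form of the convergence diagnostic, one
#' value per parameter.
#'
#' @param chains List of numeric matrices (steps x parameters), one per
#'   chain, all of equal dimensions.
#' @return Numeric vector of PSRF values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) stop("need at least 2 chains", call. = FALSE)
  chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1]])
  if (n < 2) stop("chains must have length >= 2", call. = FALSE)
  d <- ncol(chains[[1]])
  sapply(seq_len(d), function(j) {
    x <- sapply(chains, function(ch) ch[, j])   # n x m
    W <- mean(apply(x, 2, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W == 0) return(if (B_over_n == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  })
}

#' Adaptive Metropolis-Hastings sampling in a box
#'
#' Four parallel Gaussian random-walk chains with proposal covariance adapted
#' during burn-in (frozen afterwards to preserve detailed balance), run for at
#' most `max_steps` steps each with early stopping, checked from
#' `min_steps` on, when every parameter's Gelman-Rubin statistic drops below
#' `rhat_tol`. Proposals outside the box are rejected.
#'
#' @param loglik_fn Function mapping a parameter vector to a log-likelihood
#'   (may return `-Inf`; must never be `NaN` inside the box).
#' @param param_space List with numeric vectors `lower` and `upper`.
#' @param seed Integer seed.
#' @param n_chains Number of chains.
#' @param max_steps,min_steps Maximum steps and earliest early-stop step.
#' @param rhat_tol Gelman-Rubin threshold for early stopping.
#' @return An object of class `mh_result`: list with `samples` (kept,
#'   post-burn-in, all chains stacked), `chains`, `acceptance`, `rhat`,
#'   `n_steps`, `n_kept`, `burn_in`.
#' @export
adaptive_mh <- function(loglik_fn, param_space, seed = 1, n_chains = 4,
                        max_steps = 5000, min_steps = 1000, rhat_tol = 1.1) {
  set.seed(seed)
  lower <- param_space$lower
  upper <- param_space$upper
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  scale0 <- (upper - lower) / 20
  init <- lapply(seq_len(n_chains), function(i)
    lower + stats::runif(d) * (upper - lower))
  ll0 <- vapply(init, loglik_fn, numeric(1))
  if (all(!is.finite(ll0))) {
    # retry a few random points before declaring divergence
    for (k in 1:20) {
      cand <- lower + stats::runif(d) * (upper - lower)
      lc <- loglik_fn(cand)
      if (is.finite(lc)) { init[[1]] <- cand; ll0[1] <- lc; break }
    }
    if (all(!is.finite(ll0)))
      stop("log-likelihood non-finite everywhere in the box", call. = FALSE)
  }
  theta <- do.call(rbind, init)
  ll <- ll0
  store <- lapply(seq_len(n_chains), function(i)
    matrix(NA_real_, max_steps, d))
  accept <- integer(n_chains)
  prop_sd <- matrix(scale0, n_chains, d, byrow = TRUE)
  prop_chol <- vector("list", n_chains)
  adapt_until <- ceiling(max_steps / 2)
  check_every <- 200
  step <- 0
  repeat {
    step <- step + 1
    for (i in seq_len(n_chains)) {
      eps <- if (!is.null(prop_chol[[i]]))
        drop(stats::rnorm(d) %*% prop_chol[[i]]) else
        stats::rnorm(d, sd = prop_sd[i, ])
      cand <- theta[i, ] + eps
      if (all(cand >= lower & cand <= upper)) {
        lc <- loglik_fn(cand)
        if (is.finite(lc) && log(stats::runif(1)) < lc - ll[i]) {
          theta[i, ] <- cand; ll[i] <- lc; accept[i] <- accept[i] + 1L
        }
      }
      store[[i]][step, ] <- theta[i, ]
    }
    # adapt proposal covariance during burn-in only
    if (step <= adapt_until && step %% 100 == 0 && step >= 200) {
      for (i in seq_len(n_chains)) {
        hist_i <- store[[i]][max(1, step - 499):step, , drop = FALSE]
        cv <- stats::cov(hist_i) * (2.38^2 / d)
        diag(cv) <- diag(cv) + (scale0 / 50)^2
        ch <- tryCatch(chol(cv), error = function(e) NULL)
        if (!is.null(ch)) prop_chol[[i]] <- ch
      }
    }
    if (step >= max_steps) break
    if (step >= min_steps && step %% check_every == 0 && step > adapt_until) {
      half <- lapply(store, function(s)
        s[(floor(step / 2) + 1):step, , drop = FALSE])
      if (all(gelman_rubin(half) < rhat_tol)) break
    }
  }
  burn <- floor(step / 2)
  kept <- lapply(store, function(s) s[(burn + 1):step, , drop = FALSE])
  rhat <- gelman_rubin(kept)
  structure(list(samples = do.call(rbind, kept), chains = kept,
                 acceptance = accept / step, rhat = rhat, n_steps = step,
                 n_kept = step - burn, burn_in = burn),
            class = "mh_result")
}

#' Held-out log marginal likelihood from posterior samples
#'
#' Monte-Carlo estimate `log(1/N * sum_n p(A | theta_n))`, i.e. the log of
#' the mean (not the mean of logs) of held-out likelihoods across posterior
#' samples, computed with a numerically stable log-sum-exp.
#'
#' @param samples An `mh_result`, or a matrix of parameter samples.
#' @param heldout_loglik_fn Function mapping a parameter vector to the
#'   held-out data log-likelihood.
#' @return Scalar log marginal likelihood (`-Inf`, with a warning, if every
#'   sample gives zero likelihood).
#' @export
heldout_log_marginal <- function(samples, heldout_loglik_fn) {
  th <- if (inherits(samples, "mh_result")) samples$samples else
    as.matrix(samples)
  lls <- apply(th, 1, heldout_loglik_fn)
  m <- max(lls)
  if (!is.finite(m)) {
    warning("all held-out likelihoods are zero")
    return(-Inf)
  }
  m + log(mean(exp(lls - m)))
}

#' Random-effects Bayesian model selection
#'
#' Variational inference for a Dirichlet population distribution over model
#' identities given a subjects x models log-evidence matrix, following the
#' standard random-effects scheme with a uniform concentration prior.
#' Exceedance probabilities are estimated by Monte-Carlo draws from the
#' fitted Dirichlet.
#'
#' @param lme_matrix Numeric matrix, subjects x models, of log marginal
#'   likelihoods (log evidences).
#' @param seed Integer seed for the exceedance draws.
#' @param alpha0 Prior Dirichlet concentration per model.
#' @param n_draws Monte-Carlo draws for the exceedance probabilities.
#' @return An object of class `bms_result`: list with `frequencies`,
#'   `exceedance`, `alpha` (Dirichlet concentrations), `assignment`
#'   (subjects x models posterior model attributions) and the input matrix.
#' @export
bms <- function(lme_matrix, seed = 1, alpha0 = 1, n_draws = 1e5) {
  lme <- as.matrix(lme_matrix)
  if (ncol(lme) < 2) stop("need at least 2 models", call. = FALSE)
  bad <- apply(lme, 1, function(r) all(!is.finite(r)))
  if (any(bad))
    stop("subject ", which(bad)[1], " has no finite log evidence",
         call. = FALSE)
  K <- ncol(lme)
  alpha <- rep(alpha0, K)
  for (iter in 1:500) {
    lw <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    g <- exp(lw)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-8) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  freq <- alpha / sum(alpha)
  set.seed(seed)
  draws <- matrix(stats::rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                  n_draws, K)
  winner <- max.col(draws, ties.method = "random")
  xp <- tabulate(winner, K) / n_draws
  structure(list(frequencies = freq, exceedance = xp, alpha = alpha,
                 assignment = g, lme = lme),
            class = "bms_result")
}

# Parameter box for each agent kind; order is the canonical vector layout.
agent_param_space <- function(kind) {
  switch(kind,
    action_kernel = ,
    stimulus_kernel = list(
      names = c("alpha", "sigma_c", "lapse_left", "lapse_right"),
      lower = c(1e-3, 0.01, 0, 0), upper = c(1, 2, 0.45, 0.45)),
    bayes_optimal = ,
    true_block = list(
      names = c("sigma_c", "lapse_left", "lapse_right"),
      lower = c(0.01, 0, 0), upper = c(2, 0.45, 0.45)))
}

vec_to_params <- function(kind, v, policy = "probability_matching") {
  sp <- agent_param_space(kind)
  v <- as.list(stats::setNames(v, sp$names))
  agent_params(kind = kind,
               alpha = if (!is.null(v$alpha)) v$alpha else NULL,
               sigma_c = v$sigma_c, lapse_left = v$lapse_left,
               lapse_right = v$lapse_right, policy = policy)
}

#' Fit an agent model to sessions by adaptive MH
#'
#' Posterior sampling of the agent parameters given the observed choices of
#' one or more sessions (log-likelihoods summed across sessions).
#'
#' @param sessions A trial table or list of trial tables with choices.
#' @param kind Agent kind (see [agent_params()]).
#' @param seed,max_steps,min_steps Passed to [adaptive_mh()].
#' @return An `mh_result` with the parameter space and kind attached.
#' @export
fit_agent_mh <- function(sessions, kind = "action_kernel", seed = 1,
                         max_steps = 5000, min_steps = 1000) {
  if (is.data.frame(sessions)) sessions <- list(sessions)
  if (kind == "bayes_optimal")
    sessions <- lapply(sessions, function(s) {
      if (is.null(attr(s, "bayes_prior_trace")))
        attr(s, "bayes_prior_trace") <- as.numeric(bayes_optimal_prior(s))
      s
    })
  sp <- agent_param_space(kind)
  ll_fn <- function(v) {
    p <- tryCatch(vec_to_params(kind, v), error = function(e) NULL)
    if (is.null(p)) return(-Inf)
    sum(unlist(lapply(sessions, function(s)
      sum(action_loglik(s, p), na.rm = TRUE))))
  }
  res <- adaptive_mh(ll_fn, sp, seed = seed, max_steps = max_steps,
                     min_steps = min_steps)
  res$param_names <- sp$names
  res$kind <- kind
  colnames(res$samples) <- sp$names
  res
}

#' Leave-one-session-out log-evidence matrix for a subject cohort
#'
#' For every subject with at least two sessions, holds out each session in
#' turn, fits each candidate model to the remaining sessions by MH, and
#' accumulates the held-out log marginal likelihoods into a subjects x
#' models matrix suitable for [bms()]. Subjects with a single session are
#' excluded.
#'
#' @param cohort Named list: one element per subject, each a list of trial
#'   tables.
#' @param kinds Character vector of model kinds to compare.
#' @param seed Integer seed.
#' @param max_steps,min_steps MH budget per fit.
#' @return Matrix of summed held-out log marginal likelihoods with one row
#'   per retained subject.
#' @export
cohort_log_evidence <- function(cohort,
                                kinds = c("bayes_optimal", "action_kernel",
                                          "stimulus_kernel"),
                                seed = 1, max_steps = 1000, min_steps = 1000) {
  keep <- vapply(cohort, function(ss) length(ss) >= 2, logical(1))
  cohort <- cohort[keep]
  # the ideal-observer trace is parameter-free: compute it once per session
  cohort <- lapply(cohort, function(ss) lapply(ss, function(s) {
    attr(s, "bayes_prior_trace") <- as.numeric(bayes_optimal_prior(s))
    s
  }))
  lme <- matrix(NA_real_, length(cohort), length(kinds),
                dimnames = list(names(cohort), kinds))
  for (n in seq_along(cohort)) {
    sess <- cohort[[n]]
    for (k in seq_along(kinds)) {
      tot <- 0
      for (i in seq_along(sess)) {
        fit <- fit_agent_mh(sess[-i], kinds[k],
                            seed = seed + 1000 * n + 10 * k + i,
                            max_steps = max_steps, min_steps = min_steps)
        # thin the kept samples for the held-out marginal
        th <- fit$samples
        if (nrow(th) > 500) th <- th[seq(1, nrow(th), length.out = 500), ,
                                     drop = FALSE]
        tot <- tot + heldout_log_marginal(th, function(v) {
          p <- tryCatch(vec_to_params(kinds[k], v), error = function(e) NULL)
          if (is.null(p)) return(-Inf)
          sum(action_loglik(sess[[i]], p), na.rm = TRUE)
        })
      }
      lme[n, k] <- tot
    }
  }
  lme
}
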