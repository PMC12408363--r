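#' Decode the signed contrast from neural activity
#'
#' Same nested cross-validation machinery as the prior decoder, with the
#' neurometric regularisation grids, targeting the trial's signed contrast.
#'
#' @param X Trials x units activity or [neural_matrix()].
#' @param contrasts Per-trial signed contrast.
#' @param spec A [decode_spec()]; defaults to the spike-count neurometric
#'   grid.
#' @param seed Integer seed.
#' @return A `decode_result`; `$predictions` holds the held-out continuous
#'   contrast estimate per trial.
#' @export
decode_signed_contrast <- function(X, contrasts,
                                   spec = decode_spec("neurometric_ephys"),
                                   seed = 1) {
  nested_cv_decode(X, contrasts, spec, seed = seed)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# f(c) = gamma + (1 - gamma - lambda) * (erf((c - mu)/sigma) + 1)/2
erf_curve <- function(c, gamma, lambda, mu, sigma) {
  gamma + (1 - gamma - lambda) * (erf((c - mu) / sigma) + 1) / 2
}

# binomial negative log-likelihood of rightward-decoded proportions
nm_nll <- function(k, n, c, gamma, lambda, mu, sigma) {
  p <- pmin(pmax(erf_curve(c, gamma, lambda, mu, sigma), 1e-9), 1 - 1e-9)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

nm_bounds <- list(lower = c(gamma = 0, lambda = 0, mu = -0.5,
                            sigma = 0.011),
                  upper = c(gamma = 0.3, lambda = 0.3, mu = 0.5, sigma = 2))

#' Prior-conditioned neurometric curves
#'
#' Splits trials by the prior being below or above 0.5, computes per signed
#' contrast the proportion of trials whose decoded contrast is positive, and
#' fits erf psychometric functions with two lapse rates by binomial maximum
#' likelihood. In the shared model the lapses and slope are common to the
#' two prior conditions and only the bias `mu` differs; the shift is the
#' vertical gap between the fitted curves at zero contrast,
#' `f_high(0) - f_low(0)`.
#'
#' @param s_hat Held-out decoded signed contrast per trial.
#' @param contrasts True signed contrast per trial.
#' @param prior_trace Per-trial prior; trials at exactly 0.5 are excluded.
#' @param shared Fit the shared-parameter model (`TRUE`) or fully
#'   independent curves per condition.
#' @param n_starts Multi-start count for the bounded optimiser.
#' @param seed Seed for the start draws.
#' @return An object of class `neurometric_fit` with the parameters, the
#'   `shift`, `logLik`, `BIC`, the per-condition proportion tables and the
#'   shared flag.
#' @export
neurometric_fit <- function(s_hat, contrasts, prior_trace, shared = TRUE,
                            n_starts = 10, seed = 1) {
  lowi <- prior_trace < 0.5
  highi <- prior_trace > 0.5
  tab <- function(idx) {
    cs <- sort(unique(contrasts[idx]))
    data.frame(c = cs,
               k = vapply(cs, function(cc)
                 sum(s_hat[idx][contrasts[idx] == cc] > 0), numeric(1)),
               n = vapply(cs, function(cc)
                 sum(contrasts[idx] == cc), numeric(1)))
  }
  lo <- tab(lowi); hi <- tab(highi)
  if (nrow(lo) < 2 || nrow(hi) < 2)
    stop("a prior condition has fewer than 2 populated contrast levels",
         call. = FALSE)
  set.seed(seed)
  fit_box <- function(obj, lower, upper) {
    best <- NULL
    for (i in seq_len(n_starts)) {
      st <- lower + stats::runif(length(lower)) * (upper - lower)
      o <- tryCatch(stats::optim(st, obj, method = "L-BFGS-B",
                                 lower = lower, upper = upper),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("neurometric fit failed", call. = FALSE)
    best
  }
  n_trials <- sum(lo$n) + sum(hi$n)
  if (shared) {
    obj <- function(p)   # p = gamma, lambda, sigma, mu_low, mu_high
      nm_nll(lo$k, lo$n, lo$c, p[1], p[2], p[4], p[3]) +
      nm_nll(hi$k, hi$n, hi$c, p[1], p[2], p[5], p[3])
    best <- fit_box(obj,
                    c(0, 0, nm_bounds$lower["sigma"], -0.5, -0.5),
                    c(0.3, 0.3, nm_bounds$upper["sigma"], 0.5, 0.5))
    p <- best$par
    pars <- list(gamma = p[1], lambda = p[2], sigma = p[3],
                 mu_low = p[4], mu_high = p[5])
    k_par <- 5
    f0 <- function(mu) erf_curve(0, p[1], p[2], mu, p[3])
    shift <- f0(p[5]) - f0(p[4])
  } else {
    one <- function(d) fit_box(function(p)
      nm_nll(d$k, d$n, d$c, p[1], p[2], p[3], p[4]),
      c(0, 0, -0.5, nm_bounds$lower["sigma"]),
      c(0.3, 0.3, 0.5, nm_bounds$upper["sigma"]))
    bl <- one(lo); bh <- one(hi)
    best <- list(value = bl$value + bh$value)
    pars <- list(low = bl$par, high = bh$par)
    k_par <- 8
    shift <- erf_curve(0, bh$par[1], bh$par[2], bh$par[3], bh$par[4]) -
      erf_curve(0, bl$par[1], bl$par[2], bl$par[3], bl$par[4])
  }
  ll <- -best$value
  structure(list(parameters = pars, shift = unname(shift), logLik = ll,
                 BIC = -2 * ll + k_par * log(n_trials), shared = shared,
                 proportions = list(low = lo, high = hi)),
            class = "neurometric_fit")
}

#' @method print neurometric_fit
#' @export
print.neurometric_fit <- function(x, ...) {
  cat(sprintf("neurometric fit (%s): shift = %.4f, BIC = %.1f\n",
              if (x$shared) "shared" else "independent", x$shift, x$BIC))
  invisible(x)
}

#' BIC comparison of shared vs independent neurometric curves
#'
#' @param s_hat,contrasts,prior_trace As in [neurometric_fit()].
#' @param ... Passed to [neurometric_fit()].
#' @return `BIC(independent) - BIC(shared)`; positive values favour the
#'   shared-parameter model.
#' @export
bic_shared_vs_independent <- function(s_hat, contrasts, prior_trace, ...) {
  sh <- neurometric_fit(s_hat, contrasts, prior_trace, shared = TRUE, ...)
  ind <- neurometric_fit(s_hat, contrasts, prior_trace, shared = FALSE, ...)
  ind$BIC - sh$BIC
}

#' Pseudosession significance of the neurometric shift
#'
#' Decodes pseudo signed-contrast sequences from the real activity, fits the
#' shared neurometric model conditioned on the pseudosessions' own priors,
#' and ranks the actual shift in that null.
#'
#' @param X Trials x units activity.
#' @param session Trial table carrying its task config.
#' @param spec A [decode_spec()].
#' @param M Pseudosessions.
#' @param seed Integer seed.
#' @return List with the actual `fit`, `shift`, `null_shifts`, `p_value`.
#' @export
neurometric_significance <- function(X, session,
                                     spec = decode_spec("neurometric_ephys"),
                                     M = 200, seed = 1) {
  X <- as_trials_by_features(X)
  prior <- as.numeric(bayes_optimal_prior(session))
  dec <- decode_signed_contrast(X, session$signed_contrast, spec, seed)
  fit <- neurometric_fit(dec$predictions, session$signed_contrast, prior)
  pseudo <- generate_pseudosessions(session, M, seed = seed + 1L)
  null_shifts <- vapply(seq_len(M), function(i) {
    ps <- pseudo$sessions[[i]]
    dps <- decode_signed_contrast(X, ps$signed_contrast, spec, seed + i)
    pps <- as.numeric(bayes_optimal_prior(ps))
    f <- tryCatch(neurometric_fit(dps$predictions, ps$signed_contrast, pps),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$shift
  }, numeric(1))
  ok <- !is.na(null_shifts)
  p <- (1 + sum(null_shifts[ok] >= fit$shift)) / (sum(ok) + 1)
  list(fit = fit, shift = fit$shift, null_shifts = null_shifts,
       p_value = p)
}
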