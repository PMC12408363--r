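#' Decoder specification
#'
#' Fixes the penalty, regularisation grid and cross-validation geometry of
#' the linear decoders. Defaults follow the modality: L1 with a
#' `10^(-5..-1)` grid and 5x5 nested folds for spike counts; L2 with a
#' `10^(-5..-2)` grid, 50 outer folds and leave-one-out inner selection for
#' widefield pixels; wider grids for behavioural covariates and eye
#' position.
#'
#' @param modality One of `"ephys"`, `"wfi"`, `"dlc"`, `"eye"`,
#'   `"neurometric_ephys"`, `"neurometric_wfi"`, `"custom"`.
#' @param penalty `"L1"` (lasso) or `"L2"` (ridge); default per modality.
#' @param lambda Regularisation grid (decreasing order is handled
#'   internally); default per modality.
#' @param outer_folds,inner_folds Fold counts (`Inf` inner = leave-one-out).
#' @param n_runs Repetitions of the whole nested procedure under different
#'   fold randomisations; the median score across runs is reported.
#' @param window Window tag (`"iti"` = -600..-100 ms, `"post"` = 0..100 ms,
#'   `"narrow"` = -400..-100 ms); informational.
#' @param min_features Minimum number of units/pixels accepted.
#' @return An object of class `decode_spec`.
#' @export
decode_spec <- function(modality = c("ephys", "wfi", "dlc", "eye",
                                     "neurometric_ephys", "neurometric_wfi",
                                     "custom"),
                        penalty = NULL, lambda = NULL, outer_folds = NULL,
                        inner_folds = NULL, n_runs = 10,
                        window = c("iti", "post", "narrow"),
                        min_features = 5) {
  modality <- match.arg(modality)
  window <- match.arg(window)
  defaults <- switch(modality,
    ephys = list(penalty = "L1", lambda = 10^(-5:-1), outer = 5, inner = 5),
    wfi = list(penalty = "L2", lambda = 10^(-5:-2), outer = 50, inner = Inf),
    dlc = list(penalty = "L1", lambda = 10^(-4:2), outer = 5, inner = 5),
    eye = list(penalty = "L2", lambda = 10^(-4:4), outer = 5, inner = 5),
    neurometric_ephys = list(penalty = "L1", lambda = 10^(-5:0), outer = 5,
                             inner = 5),
    neurometric_wfi = list(penalty = "L2", lambda = 10^(-5:-2), outer = 5,
                           inner = 5),
    custom = list(penalty = "L2", lambda = 10^(-4:1), outer = 5, inner = 5))
  spec <- list(modality = modality,
               penalty = if (is.null(penalty)) defaults$penalty else penalty,
               lambda = sort(if (is.null(lambda)) defaults$lambda else lambda,
                             decreasing = TRUE),
               outer_folds = if (is.null(outer_folds)) defaults$outer else
                 outer_folds,
               inner_folds = if (is.null(inner_folds)) defaults$inner else
                 inner_folds,
               n_runs = n_runs, window = window, min_features = min_features)
  stopifnot(spec$penalty %in% c("L1", "L2"), length(spec$lambda) >= 1,
            spec$outer_folds >= 2)
  class(spec) <- "decode_spec"
  spec
}

as_trials_by_features <- function(X) {
  if (inherits(X, "neural_matrix")) X <- t(X$values)
  as.matrix(X)
}

glmnet_alpha <- function(spec) if (spec$penalty == "L1") 1 else 0

# Fit at the full grid, return function(newx, lambda) -> predictions,
# plus coefficients at a given lambda.
fit_path <- function(X, y, spec) {
  glmnet::glmnet(X, y, alpha = glmnet_alpha(spec), lambda = spec$lambda,
                 standardize = TRUE)
}

#' Nested cross-validated linear decoding
#'
#' Outer folds are interleaved random partitions; within each training set an
#' inner cross-validation selects the regularisation weight from the grid by
#' mean squared error; held-out predictions over the outer folds cover every
#' trial. The whole procedure is repeated `n_runs` times under different
#' fold randomisations; the decoding score is the median across runs of the
#' R-squared of the pooled held-out predictions, and the reported prediction
#' per trial is the across-run mean.
#'
#' @param X Trials x features matrix, or a [neural_matrix()] (transposed
#'   internally).
#' @param y Numeric target, one value per trial.
#' @param spec A [decode_spec()].
#' @param seed Integer seed for the fold randomisations.
#' @return An object of class `decode_result`: `r2` (median across runs),
#'   `r2_runs`, `predictions`, `weights` (mean over folds and runs),
#'   `chosen_lambda` table, `spec`, `seed`.
#' @export
nested_cv_decode <- function(X, y, spec = decode_spec("ephys"), seed = 1) {
  X <- as_trials_by_features(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (ncol(X) < spec$min_features)
    stop("fewer than ", spec$min_features, " features", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("degenerate target: fewer than 2 distinct values", call. = FALSE)
  k_out <- min(spec$outer_folds, n)
  grid <- spec$lambda
  preds <- matrix(NA_real_, n, spec$n_runs)
  r2_runs <- numeric(spec$n_runs)
  wsum <- numeric(ncol(X))
  nw <- 0
  lam_hits <- integer(length(grid))
  for (run in seq_len(spec$n_runs)) {
    set.seed(seed + run - 1L)
    fold <- sample(rep_len(seq_len(k_out), n))
    for (f in seq_len(k_out)) {
      tr <- which(fold != f); te <- which(fold == f)
      best_lam <- grid[1]
      if (length(grid) > 1) {
        k_in <- min(if (is.finite(spec$inner_folds)) spec$inner_folds else
          length(tr), length(tr))
        ifold <- sample(rep_len(seq_len(k_in), length(tr)))
        sse <- numeric(length(grid))
        for (g in seq_len(k_in)) {
          itr <- tr[ifold != g]; ite <- tr[ifold == g]
          fitg <- fit_path(X[itr, , drop = FALSE], y[itr], spec)
          ph <- stats::predict(fitg, X[ite, , drop = FALSE], s = grid)
          sse <- sse + colSums((ph - y[ite])^2)
        }
        best_lam <- grid[which.min(sse)]
      }
      lam_hits[match(best_lam, grid)] <- lam_hits[match(best_lam, grid)] + 1L
      fit <- fit_path(X[tr, , drop = FALSE], y[tr], spec)
      preds[te, run] <- stats::predict(fit, X[te, , drop = FALSE],
                                       s = best_lam)
      wsum <- wsum + as.numeric(stats::coef(fit, s = best_lam))[-1]
      nw <- nw + 1
    }
    r2_runs[run] <- 1 - sum((y - preds[, run])^2) / sum((y - mean(y))^2)
  }
  edge <- lam_hits[c(1, length(grid))]
  if (length(grid) > 2 && sum(edge) > 0.9 * sum(lam_hits))
    warning("selected regularisation sits at the bounds of the grid")
  structure(list(r2 = stats::median(r2_runs), r2_runs = r2_runs,
                 predictions = rowMeans(preds), weights = wsum / nw,
                 lambda_hits = stats::setNames(lam_hits, signif(grid, 3)),
                 spec = spec, seed = seed),
            class = "decode_result")
}

#' @method print decode_result
#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: median R2 = %.4f over %d run(s)\n",
              x$r2, length(x$r2_runs)))
  if (!is.null(x$p_value))
    cat(sprintf("  pseudosession p = %.4g, corrected R2 = %.4f (M = %d)\n",
                x$p_value, x$corrected_r2, length(x$null_r2)))
  invisible(x)
}

#' Pseudosession significance of a decoding score
#'
#' Decodes `M` targets rebuilt on pseudosessions with the identical pipeline
#' and compares the actual score against that null distribution. Because the
#' recorded activity is independent of the resampled sequences, any
#' predictive power in the null reflects slow drift or other task-unrelated
#' structure - exactly the confound the test must absorb.
#'
#' @param X Trials x features activity (fixed across pseudosessions).
#' @param session Trial table carrying its task config.
#' @param target_builder Function mapping a trial table to a numeric target
#'   (e.g. `bayes_optimal_prior`).
#' @param spec A [decode_spec()].
#' @param M Number of pseudosessions.
#' @param seed Integer seed.
#' @param collect_weights Keep the pseudo-weight matrix (needed by
#'   [weight_significance()]).
#' @return A `decode_result` additionally carrying `null_r2`, `p_value`
#'   (with add-one smoothing), `corrected_r2` (actual minus median null) and
#'   optionally `null_weights`.
#' @export
pseudosession_significance <- function(X, session, target_builder,
                                       spec = decode_spec("ephys"),
                                       M = 1000, seed = 1,
                                       collect_weights = FALSE) {
  X <- as_trials_by_features(X)
  actual <- nested_cv_decode(X, target_builder(session), spec, seed = seed)
  pseudo <- generate_pseudosessions(session, M, seed = seed + 1L)
  null_r2 <- numeric(M)
  null_w <- if (collect_weights) matrix(NA_real_, M, ncol(X)) else NULL
  for (i in seq_len(M)) {
    yi <- tryCatch(target_builder(pseudo$sessions[[i]]), error = function(e)
      stop("target builder failed on pseudosession ", i, ": ",
           conditionMessage(e), call. = FALSE))
    ri <- nested_cv_decode(X, yi, spec, seed = seed + i)
    null_r2[i] <- ri$r2
    if (collect_weights) null_w[i, ] <- ri$weights
  }
  actual$null_r2 <- null_r2
  actual$p_value <- (1 + sum(null_r2 >= actual$r2)) / (M + 1)
  actual$corrected_r2 <- actual$r2 - stats::median(null_r2)
  actual$null_weights <- null_w
  actual
}

#' Combine p-values by Fisher's method
#'
#' `X2 = -2 * sum(log(p_i))` referred to a chi-squared distribution with
#' `2 * length(p)` degrees of freedom.
#'
#' @param p_values Numeric p-values in (0, 1\].
#' @return Combined p-value.
#' @export
fisher_combine <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) return(NA_real_)
  if (any(p <= 0)) {
    warning("p-value(s) of 0 clipped to the machine floor")
    p <- pmax(p, .Machine$double.xmin)
  }
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg selection
#'
#' Standard step-up false-discovery-rate control; returns the selection
#' flags at the requested FDR.
#'
#' @param p_values Numeric vector.
#' @param fdr Target false-discovery rate.
#' @return Logical vector of selections (empty input gives an empty vector).
#' @export
bh_select <- function(p_values, fdr = 0.01) {
  if (!length(p_values)) return(logical(0))
  stats::p.adjust(p_values, method = "BH") <= fdr
}

#' Significance of individual decoding weights
#'
#' Flags units whose decoding weight falls outside the 2.5th-97.5th
#' percentile band of the pseudo-weight distribution obtained by decoding
#' pseudosession targets from the same activity.
#'
#' @param result A `decode_result` from [pseudosession_significance()] run
#'   with `collect_weights = TRUE` (or supply `null_weights`).
#' @param null_weights Optional M x units pseudo-weight matrix.
#' @return Logical vector, one flag per unit.
#' @export
weight_significance <- function(result, null_weights = NULL) {
  w <- result$weights
  nw <- if (is.null(null_weights)) result$null_weights else null_weights
  if (is.null(nw)) stop("no pseudo-weights available", call. = FALSE)
  if (nrow(nw) < 40)
    warning("fewer than 40 pseudosessions: percentile band is unstable")
  lo <- apply(nw, 2, stats::quantile, 0.025)
  hi <- apply(nw, 2, stats::quantile, 0.975)
  w < lo | w > hi
}

#' Sessions needed for region-level significance
#'
#' For each subsample size `N`, draws `reps` random subsets of the session
#' p-values, Fisher-combines each subset and reports the median combined p.
#'
#' @param per_session_p Numeric vector of session-level p-values for one
#'   region.
#' @param reps Resampling repetitions.
#' @param seed Integer seed.
#' @return `data.frame` with `N` and `median_p`.
#' @export
sessions_needed <- function(per_session_p, reps = 1000, seed = 1) {
  set.seed(seed)
  nr <- length(per_session_p)
  med <- vapply(seq_len(nr), function(N) {
    if (N == nr) return(fisher_combine(per_session_p))
    stats::median(replicate(reps,
      fisher_combine(sample(per_session_p, N))))
  }, numeric(1))
  data.frame(N = seq_len(nr), median_p = med)
}

#' Aggregate session-level decodings into a region map
#'
#' @param region Character region label per session result.
#' @param p_values Session-level pseudosession p-values.
#' @param corrected_r2 Session-level corrected scores.
#' @param fdr FDR for the Benjamini-Hochberg region selection.
#' @return `data.frame` with one row per region: `n_sessions`, `combined_p`
#'   (Fisher), `mean_corrected_r2`, `significant` (BH across regions).
#' @export
region_summary <- function(region, p_values, corrected_r2, fdr = 0.01) {
  sp <- split(seq_along(region), region)
  out <- data.frame(
    region = names(sp),
    n_sessions = vapply(sp, length, integer(1)),
    combined_p = vapply(sp, function(i) fisher_combine(p_values[i]),
                        numeric(1)),
    mean_corrected_r2 = vapply(sp, function(i) mean(corrected_r2[i]),
                               numeric(1)),
    row.names = NULL)
  out$significant <- bh_select(out$combined_p, fdr)
  out
}

decode_r2 <- function(X, y, spec, seed) {
  nested_cv_decode(X, y, spec, seed = seed)
}

#' Residual decoding against behavioural covariates
#'
#' Decodes the prior from behavioural covariates, forms the cross-validated
#' residual (prior minus the covariate prediction), and decodes both the
#' prior and the residual from neural activity. Leave-one-feature-out
#' importances quantify each covariate's contribution.
#'
#' @param prior Per-trial prior target.
#' @param covariates Trials x features table of behavioural covariates.
#' @param X Neural activity (trials x units or [neural_matrix()]).
#' @param spec_cov,spec_neural Decoder specs for the two stages.
#' @param seed Integer seed.
#' @return List with `covariate_r2`, `neural_r2`, `residual_r2`,
#'   `residual`, `covariate_prediction` and `importance` (named per-feature
#'   R-squared drops).
#' @export
residual_decode <- function(prior, covariates, X,
                            spec_cov = decode_spec("dlc", min_features = 1),
                            spec_neural = decode_spec("ephys"),
                            seed = 1) {
  covariates <- as.matrix(covariates)
  prior <- as.numeric(prior)
  constant <- apply(covariates, 2, function(x) stats::var(x) == 0)
  if (all(constant)) {
    cov_pred <- rep(mean(prior), length(prior))
    cov_r2 <- 0
    importance <- stats::setNames(rep(0, ncol(covariates)),
                                  colnames(covariates))
  } else {
    cov_res <- nested_cv_decode(covariates, prior, spec_cov, seed = seed)
    cov_pred <- cov_res$predictions
    cov_r2 <- cov_res$r2
    importance <- vapply(seq_len(ncol(covariates)), function(j) {
      if (ncol(covariates) < 2) return(NA_real_)
      loo <- nested_cv_decode(covariates[, -j, drop = FALSE], prior,
                              spec_cov, seed = seed)
      cov_r2 - loo$r2
    }, numeric(1))
    names(importance) <- colnames(covariates)
  }
  resid <- prior - cov_pred
  neural <- nested_cv_decode(X, prior, spec_neural, seed = seed)
  resid_res <- if (stats::var(resid) == 0) NULL else
    nested_cv_decode(X, resid, spec_neural, seed = seed)
  list(covariate_r2 = cov_r2, neural_r2 = neural$r2,
       residual_r2 = if (is.null(resid_res)) NA_real_ else resid_res$r2,
       residual = resid, covariate_prediction = cov_pred,
       importance = importance)
}

logistic_slope <- function(choice_right, x) {
  if (length(unique(choice_right)) < 2) return(NA_real_)
  fit <- suppressWarnings(stats::glm(choice_right ~ x,
                                     family = stats::binomial()))
  unname(stats::coef(fit)[2])
}

#' Coupling between the decoded prior and choices
#'
#' Pools cross-validated decoded priors over sessions, bins them into
#' deciles and reports the proportion of rightward choices per decile on
#' zero-contrast trials; fits per-session logistic slopes of choice against
#' the decoded prior; and builds a behavioural null by simulating a fitted
#' action-kernel agent on pseudosessions whose pseudo-priors are decoded
#' from the real activity.
#'
#' @param bundles List of sessions, each a list with elements `trials`
#'   (trial table with choices), `X` (trials x units activity) and
#'   `decoded_prior` (cross-validated decoded prior per trial).
#' @param spec A [decode_spec()] for the pseudo-prior decoding.
#' @param M Pseudosessions per session.
#' @param seed Integer seed.
#' @param agent_fits Optional list of [agent_params()] per session (the
#'   fitted action-kernel model); fitted by a short MH run when absent.
#' @return List with `decile_curve`, `slopes` (per session, `NA` when a
#'   session's choices are all identical), `mean_slope`, `null_slopes`
#'   (M-vector of mean pseudo-slopes) and `significant`.
#' @export
prior_choice_coupling <- function(bundles, spec = decode_spec("ephys"),
                                  M = 200, seed = 1, agent_fits = NULL) {
  dp <- unlist(lapply(bundles, function(b) {
    z <- b$trials$signed_contrast == 0
    b$decoded_prior[z]
  }))
  ch <- unlist(lapply(bundles, function(b) {
    z <- b$trials$signed_contrast == 0
    as.numeric(b$trials$choice[z] == "right")
  }))
  dec <- cut(dp, stats::quantile(dp, seq(0, 1, 0.1)), include.lowest = TRUE,
             labels = FALSE)
  decile_curve <- data.frame(
    decile = 1:10,
    decoded_prior = tapply(dp, dec, mean)[as.character(1:10)],
    p_right = tapply(ch, dec, mean)[as.character(1:10)])
  slopes <- vapply(bundles, function(b)
    logistic_slope(as.numeric(b$trials$choice == "right"),
                   b$decoded_prior), numeric(1))
  null_slopes <- matrix(NA_real_, M, length(bundles))
  for (j in seq_along(bundles)) {
    b <- bundles[[j]]
    fitp <- if (!is.null(agent_fits)) agent_fits[[j]] else {
      mh <- fit_agent_mh(b$trials, "action_kernel", seed = seed + j,
                         max_steps = 1200, min_steps = 1000)
      vec_to_params("action_kernel", colMeans(mh$samples))
    }
    pseudo <- generate_pseudosessions(b$trials, M, seed = seed + 100 + j)
    for (i in seq_len(M)) {
      ps <- pseudo$sessions[[i]]
      sim <- simulate_agent(ps, fitp, seed = seed + 1000 * j + i)
      y_ps <- as.numeric(bayes_optimal_prior(ps))
      dec_ps <- nested_cv_decode(b$X, y_ps, spec, seed = seed + i)
      null_slopes[i, j] <- logistic_slope(
        as.numeric(sim$choice == "right"), dec_ps$predictions)
    }
  }
  mean_null <- rowMeans(null_slopes, na.rm = TRUE)
  mean_slope <- mean(slopes, na.rm = TRUE)
  list(decile_curve = decile_curve, slopes = slopes,
       mean_slope = mean_slope, null_slopes = mean_null,
       significant = mean_slope > stats::quantile(mean_null, 0.95,
                                                  na.rm = TRUE))
}
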