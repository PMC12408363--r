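#' Block-conditioned psychometric curves
#'
#' Proportion of rightward choices per signed contrast, conditioned on block
#' identity, computed per mouse and then averaged across mice.
#'
#' @param trials Trial table (possibly many sessions/mice) with choices.
#' @return A `data.frame` with columns `block_p_right`, `signed_contrast`,
#'   `p_right` (across-mouse mean), `sem`, `n_mice`; cells without trials are
#'   absent rather than zero. The zero-contrast right-minus-left block
#'   difference is attached as attribute `zero_contrast_shift`.
#' @export
psychometric_by_block <- function(trials) {
  d <- trials[trials$included & !is.na(trials$choice) &
                trials$choice != "none", ]
  per_mouse <- stats::aggregate(
    list(p = d$choice == "right"),
    by = list(mouse_id = d$mouse_id, block_p_right = d$block_p_right,
              signed_contrast = d$signed_contrast),
    FUN = mean)
  out <- stats::aggregate(
    list(p_right = per_mouse$p),
    by = list(block_p_right = per_mouse$block_p_right,
              signed_contrast = per_mouse$signed_contrast),
    FUN = mean)
  sem <- stats::aggregate(
    list(sem = per_mouse$p),
    by = list(block_p_right = per_mouse$block_p_right,
              signed_contrast = per_mouse$signed_contrast),
    FUN = function(x) stats::sd(x) / sqrt(length(x)))
  nm <- stats::aggregate(
    list(n_mice = per_mouse$p),
    by = list(block_p_right = per_mouse$block_p_right,
              signed_contrast = per_mouse$signed_contrast),
    FUN = length)
  out$sem <- sem$sem
  out$n_mice <- nm$n_mice
  hi <- out$p_right[out$block_p_right > 0.5 & out$signed_contrast == 0]
  lo <- out$p_right[out$block_p_right < 0.5 & out$signed_contrast == 0]
  attr(out, "zero_contrast_shift") <-
    if (length(hi) && length(lo)) hi - lo else NA_real_
  out
}

# First trials of biased blocks that follow another biased block, per session.
reversal_indices <- function(bp) {
  ch <- which(bp[-1] != bp[-length(bp)]) + 1
  ch[bp[ch] != 0.5 & bp[ch - 1] != 0.5]
}

#' Reversal-aligned performance curve
#'
#' Proportion of correct (rewarded) choices on zero-contrast trials as a
#' function of lag around block reversals, aggregated per mouse (pooling
#' sessions).
#'
#' @param trials Trial table with rewards.
#' @param lags Integer lags relative to the reversal trial (lag 0 = first
#'   trial of the new block).
#' @param zero_contrast_only Restrict to zero-contrast trials.
#' @return A `data.frame` with `mouse_id`, `lag`, `p` (proportion correct)
#'   and `n` (trial count).
#' @export
reversal_curve <- function(trials, lags = -5:20, zero_contrast_only = TRUE) {
  pieces <- lapply(split(trials, trials$session_id), function(s) {
    s <- s[order(s$trial), ]
    revs <- reversal_indices(s$block_p_right)
    if (!length(revs)) return(NULL)
    idx <- rep(revs, each = length(lags)) + lags
    lag <- rep(lags, times = length(revs))
    ok <- idx >= 1 & idx <= nrow(s)
    idx <- idx[ok]; lag <- lag[ok]
    if (zero_contrast_only) {
      keep <- s$signed_contrast[idx] == 0
      idx <- idx[keep]; lag <- lag[keep]
    }
    keep <- s$included[idx] & !is.na(s$reward[idx])
    if (!any(keep)) return(NULL)
    data.frame(mouse_id = s$mouse_id[1], lag = lag[keep],
               correct = s$reward[idx[keep]])
  })
  d <- do.call(rbind, pieces)
  if (is.null(d)) stop("no reversal-aligned trials found", call. = FALSE)
  agg <- stats::aggregate(list(p = d$correct),
                          by = list(mouse_id = d$mouse_id, lag = d$lag),
                          FUN = mean)
  n <- stats::aggregate(list(n = d$correct),
                        by = list(mouse_id = d$mouse_id, lag = d$lag),
                        FUN = length)
  agg$n <- n$n
  agg
}

# Pool mouse-level curves into one count-weighted curve.
pool_reversal_curves <- function(curves) {
  agg <- stats::aggregate(list(w = curves$n, pw = curves$p * curves$n),
                          by = list(lag = curves$lag), FUN = sum)
  data.frame(lag = agg$lag, p = agg$pw / agg$w, n = agg$w)
}

#' Exponential fit to a reversal curve
#'
#' Fits `p(correct at t) = (B + (A - B) exp(-t / tau)) * [t >= 0] +
#' B * [t < 0]` to a reversal-aligned performance curve. The asymptote `B` is
#' estimated from the pre-reversal window, where the model states the curve
#' is exactly `B`; `A` and `tau` are then fitted by count-weighted least
#' squares on the post-reversal lags with multi-start bounded optimisation.
#' Anchoring `B` pre-reversal keeps the asymptote estimate free of
#' contamination from subsequent reversals at late lags.
#'
#' @param trials Trial table, or a per-mouse curve from [reversal_curve()],
#'   or a pooled curve with columns `lag`, `p`, `n`.
#' @param lags Fit window.
#' @return An object of class `reversal_fit`: list with `A`, `B`, `tau`,
#'   `loss`, `degenerate` (TRUE when `A` and `B` are indistinguishable and
#'   `tau` is unidentifiable) and the fitted curve.
#' @export
fit_reversal <- function(trials, lags = -5:20) {
  curve <- if (is.data.frame(trials) && all(c("lag", "p", "n") %in%
                                            names(trials))) {
    if ("mouse_id" %in% names(trials)) pool_reversal_curves(trials) else trials
  } else {
    pool_reversal_curves(reversal_curve(trials, lags))
  }
  curve <- curve[curve$lag %in% lags, ]
  if (length(unique(curve$lag)) < 3)
    stop("fewer than 3 distinct lags with data", call. = FALSE)
  pre <- curve[curve$lag < 0, ]
  post <- curve[curve$lag >= 0, ]
  B <- if (nrow(pre)) stats::weighted.mean(pre$p, pre$n) else
    stats::weighted.mean(curve$p[curve$lag >= max(curve$lag) - 5],
                         curve$n[curve$lag >= max(curve$lag) - 5])
  obj <- function(par) {
    pred <- B + (par[1] - B) * exp(-post$lag / par[2])
    sum(post$n * (post$p - pred)^2)
  }
  best <- NULL
  starts <- expand.grid(A = c(0.2, 0.4, 0.6), tau = c(1, 2, 5, 10))
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(c(starts$A[i], starts$tau[i]), obj,
                      method = "L-BFGS-B", lower = c(0, 0.1),
                      upper = c(1, 50))
    if (is.null(best) || o$value < best$value) best <- o
  }
  A <- best$par[1]; tau <- best$par[2]
  structure(list(A = A, B = B, tau = tau, loss = best$value,
                 degenerate = abs(A - B) < 1e-3, curve = curve,
                 lags = lags),
            class = "reversal_fit")
}

#' @method print reversal_fit
#' @export
print.reversal_fit <- function(x, ...) {
  cat(sprintf("reversal fit: A = %.3f, B = %.3f, tau = %.2f trials%s\n",
              x$A, x$B, x$tau,
              if (x$degenerate) " (tau unidentifiable)" else ""))
  invisible(x)
}

#' Leave-one-mouse-out jackknife of the reversal decay constant
#'
#' Refits [fit_reversal()] on the pooled curves of all but one mouse, once
#' per mouse, and reports the replicate decay constants with their median and
#' jackknife standard error.
#'
#' @param trials Trial table covering at least 3 mice (or a per-mouse curve
#'   from [reversal_curve()]).
#' @param lags Fit window.
#' @return List with `tau` (replicate vector, one per mouse), `median`,
#'   `se` (jackknife standard error) and `mice`.
#' @export
jackknife_tau <- function(trials, lags = -5:20) {
  curves <- if (is.data.frame(trials) && "lag" %in% names(trials) &&
                "mouse_id" %in% names(trials)) trials else
    reversal_curve(trials, lags)
  mice <- unique(curves$mouse_id)
  if (length(mice) < 3) stop("need at least 3 mice", call. = FALSE)
  taus <- vapply(mice, function(m) {
    f <- tryCatch(fit_reversal(curves[curves$mouse_id != m, ], lags),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$tau
  }, numeric(1))
  if (any(is.na(taus)))
    warning(sum(is.na(taus)), " jackknife replicate(s) failed and were dropped")
  ok <- !is.na(taus)
  nrep <- sum(ok)
  se <- sqrt((nrep - 1) / nrep * sum((taus[ok] - mean(taus[ok]))^2))
  list(tau = taus, median = stats::median(taus[ok]), se = se, mice = mice)
}

# favoured side of the block (NA in unbiased blocks)
block_favoured_side <- function(bp) {
  ifelse(bp > 0.5, "right", ifelse(bp < 0.5, "left", NA_character_))
}

#' Post-outcome performance asymmetry
#'
#' Compares accuracy on zero-contrast trials conditioned on whether the
#' previous trial was correct or an error, under filters that isolate the
#' effect of the last outcome: stimuli at `t`, `t-1`, `t-2` on the
#' block-conformant side, a correct choice at `t-2`, and at least
#' `min_from_reversal` trials since the start of the current block. Agents
#' whose prior updates use the true stimulus side show no asymmetry; agents
#' integrating their own actions are worse after an error.
#'
#' @param trials Trial table with choices and rewards.
#' @param min_from_reversal Minimum distance (trials) from the block start.
#' @return List with `p_correct_after_correct`, `p_correct_after_error`
#'   (across-session means), `delta`, per-session values, and a paired
#'   Wilcoxon signed-rank test across sessions (`NA`s when no qualifying
#'   trials exist).
#' @export
post_outcome_asymmetry <- function(trials, min_from_reversal = 10) {
  per_session <- lapply(split(trials, trials$session_id), function(s) {
    s <- s[order(s$trial), ]
    n <- nrow(s)
    if (n < 3) return(NULL)
    fav <- block_favoured_side(s$block_p_right)
    conform <- !is.na(fav) & s$stim_side == fav
    # distance from the start of the current block
    block_id <- cumsum(c(1, diff(s$block_p_right) != 0))
    pos_in_block <- stats::ave(seq_len(n), block_id,
                               FUN = function(i) seq_along(i) - 1)
    t <- 3:n
    ok <- s$signed_contrast[t] == 0 &
      conform[t] & conform[t - 1] & conform[t - 2] &
      !is.na(s$reward[t - 2]) & s$reward[t - 2] == 1 &
      pos_in_block[t] >= min_from_reversal &
      s$included[t] & !is.na(s$reward[t]) & !is.na(s$reward[t - 1])
    t <- t[ok]
    if (!length(t)) return(NULL)
    prev_ok <- s$reward[t - 1] == 1
    c(after_correct = if (any(prev_ok)) mean(s$reward[t[prev_ok]]) else NA,
      after_error = if (any(!prev_ok)) mean(s$reward[t[!prev_ok]]) else NA)
  })
  per_session <- do.call(rbind, per_session)
  if (is.null(per_session))
    return(list(p_correct_after_correct = NA_real_,
                p_correct_after_error = NA_real_, delta = NA_real_,
                per_session = NULL, test = NULL))
  cc <- stats::complete.cases(per_session)
  test <- if (sum(cc) >= 3)
    stats::wilcox.test(per_session[cc, 1], per_session[cc, 2],
                       paired = TRUE, exact = FALSE) else NULL
  list(p_correct_after_correct = mean(per_session[, 1], na.rm = TRUE),
       p_correct_after_error = mean(per_session[, 2], na.rm = TRUE),
       delta = mean(per_session[cc, 1] - per_session[cc, 2]),
       per_session = per_session, test = test)
}
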