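#' Bin-wise decoded prior series per region
#'
#' Decodes the prior separately in every within-trial time bin and region
#' from bin-resolved activity, yielding the region x trial x bin tensor of
#' decoded priors that the Granger analysis consumes. Decoding per bin uses
#' the cross-validated linear decoder at the modality's default grid.
#'
#' @param X_binned A [neural_matrix()] with a units x trials x bins array.
#' @param prior Per-trial prior target.
#' @param spec A [decode_spec()]; defaults to L1 for spike counts and L2
#'   for widefield, single run.
#' @param min_units Regions with fewer units are skipped (with a flag).
#' @param seed Integer seed.
#' @return List with `tensor` (regions x trials x bins, decoded prior),
#'   `regions`, `skipped`.
#' @export
binwise_prior_decode <- function(X_binned, prior, spec = NULL,
                                 min_units = 5, seed = 1) {
  stopifnot(inherits(X_binned, "neural_matrix"),
            length(dim(X_binned$values)) == 3)
  if (is.null(spec)) {
    spec <- decode_spec(if (X_binned$modality == "ephys_counts") "ephys"
                        else "wfi",
                        outer_folds = 5, inner_folds = 3, n_runs = 1,
                        min_features = 1)
  }
  regions <- unique(X_binned$regions)
  nb <- dim(X_binned$values)[3]
  nt <- dim(X_binned$values)[2]
  tensor <- array(NA_real_, c(length(regions), nt, nb),
                  dimnames = list(regions, NULL, NULL))
  skipped <- character(0)
  for (r in seq_along(regions)) {
    rows <- which(X_binned$regions == regions[r])
    if (length(rows) < min_units) {
      skipped <- c(skipped, regions[r])
      next
    }
    for (b in seq_len(nb)) {
      Xb <- t(X_binned$values[rows, , b, drop = TRUE])
      res <- nested_cv_decode(Xb, prior, spec, seed = seed + b)
      tensor[r, , b] <- res$predictions
    }
  }
  list(tensor = tensor, regions = regions, skipped = skipped)
}

# OLS VAR fit on a T x 2 matrix; order chosen by AIC up to max_order.
fit_var <- function(z, max_order = 5) {
  n <- nrow(z)
  best <- NULL
  for (p in seq_len(max_order)) {
    Y <- z[(p + 1):n, , drop = FALSE]
    Xl <- do.call(cbind, lapply(seq_len(p), function(k)
      z[(p + 1 - k):(n - k), , drop = FALSE]))
    Xl <- cbind(1, Xl)
    B <- tryCatch(solve(crossprod(Xl), crossprod(Xl, Y)),
                  error = function(e) NULL)
    if (is.null(B)) next
    E <- Y - Xl %*% B
    Sigma <- crossprod(E) / (nrow(Y) - ncol(Xl))
    detS <- det(Sigma)
    if (detS <= 0) next
    aic <- log(detS) + 2 * p * 4 / nrow(Y)
    if (is.null(best) || aic < best$aic)
      best <- list(order = p, B = B, Sigma = Sigma, aic = aic)
  }
  if (is.null(best)) stop("VAR fit failed", call. = FALSE)
  # coefficient matrices A_k (2 x 2): B rows are (const, then lag blocks)
  A <- lapply(seq_len(best$order), function(k)
    t(best$B[1 + (k - 1) * 2 + 1:2, , drop = FALSE]))
  list(order = best$order, A = A, Sigma = best$Sigma)
}

# Geweke frequency-domain causality x -> y from a bivariate VAR, averaged
# over the positive Fourier frequencies of the series.
geweke_score <- function(var_fit, n_freq = 128, from = 1, to = 2) {
  S <- var_fit$Sigma
  omega <- pi * seq_len(n_freq) / (n_freq + 1)
  f <- vapply(omega, function(w) {
    Aw <- diag(2) + 0i
    for (k in seq_along(var_fit$A))
      Aw <- Aw - var_fit$A[[k]] * exp(-1i * k * w)
    H <- solve(Aw)
    Sp <- H %*% S %*% Conj(t(H))
    s_yy <- Re(Sp[to, to])
    h_yx <- H[to, from]
    h_yy <- H[to, to]
    h_t <- h_yy + (S[from, to] / S[from, from]) * h_yx
    s2 <- S[to, to] - S[from, to]^2 / S[from, from]
    intrinsic <- Re(h_t * s2 * Conj(h_t))
    if (intrinsic <= 0 || s_yy <= 0) return(0)
    max(log(s_yy / intrinsic), 0)
  }, numeric(1))
  mean(f)
}

has_unit_root <- function(x) {
  n <- length(x)
  phi <- stats::coef(stats::lm(x[-1] ~ x[-n]))[2]
  is.finite(phi) && abs(phi) >= 0.99
}

#' Spectral Granger score for a directed pair
#'
#' Fits a bivariate vector autoregression (order selected by AIC, at most
#' `max_order`) to the two concatenated bin series, applies the Geweke
#' spectral decomposition, and averages the frequency-wise causality of the
#' `A -> B` direction over the positive frequency grid. Series flagged as
#' unit-root are differenced first.
#'
#' @param series_a,series_b Equal-length numeric series (trials x bins,
#'   concatenated trial-major).
#' @param max_order Maximum VAR order.
#' @param n_freq Number of frequencies in the grid.
#' @return Scalar non-negative score with attribute `differenced`.
#' @export
granger_pair <- function(series_a, series_b, max_order = 5, n_freq = 128) {
  stopifnot(length(series_a) == length(series_b))
  differenced <- FALSE
  if (has_unit_root(series_a) || has_unit_root(series_b)) {
    warning("unit-root series: Granger score computed on differences")
    series_a <- diff(series_a)
    series_b <- diff(series_b)
    differenced <- TRUE
  }
  z <- cbind(series_a, series_b)
  vf <- fit_var(z, max_order)
  structure(geweke_score(vf, n_freq, from = 1, to = 2),
            differenced = differenced)
}

pair_scores <- function(tensor) {
  regions <- dimnames(tensor)[[1]]
  R <- length(regions)
  out <- matrix(NA_real_, R, R, dimnames = list(regions, regions))
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i == j) next
    a <- as.vector(t(tensor[i, , ]))   # trial-major concatenation
    b <- as.vector(t(tensor[j, , ]))
    if (anyNA(a) || anyNA(b)) next
    out[i, j] <- suppressWarnings(as.numeric(granger_pair(a, b)))
  }
  out
}

#' Pseudosession significance of Granger scores
#'
#' Decodes the prior of `M` pseudosessions bin-wise from the real activity,
#' runs the full Granger pipeline on each pseudo tensor, and flags a
#' directed pair when its actual score exceeds the 95th percentile of its
#' pseudo scores. Because both regions decode the same pseudo-prior, the
#' null inherits any shared latent drive - the property that keeps the test
#' calibrated where naive Granger significance is not.
#'
#' @param X_binned A bin-resolved [neural_matrix()].
#' @param session Trial table carrying its task config.
#' @param spec Decoder spec for the bin-wise decoding (default as in
#'   [binwise_prior_decode()]).
#' @param M Pseudosessions.
#' @param seed Integer seed.
#' @return List with `scores`, `null_scores` (M x pairs), `p` (matrix),
#'   `flags` (matrix), `regions`.
#' @export
granger_significance <- function(X_binned, session, spec = NULL, M = 1000,
                                 seed = 1) {
  if (M < 2) warning("M < 2 gives degenerate pseudo p-values")
  prior <- as.numeric(bayes_optimal_prior(session))
  actual <- binwise_prior_decode(X_binned, prior, spec, seed = seed)
  scores <- pair_scores(actual$tensor)
  pseudo <- generate_pseudosessions(session, M, seed = seed + 1L)
  R <- length(actual$regions)
  null_arr <- array(NA_real_, c(M, R, R))
  for (i in seq_len(M)) {
    pp <- as.numeric(bayes_optimal_prior(pseudo$sessions[[i]]))
    dec <- binwise_prior_decode(X_binned, pp, spec, seed = seed + i)
    null_arr[i, , ] <- pair_scores(dec$tensor)
  }
  p <- flags <- matrix(NA, R, R, dimnames = dimnames(scores))
  for (a in seq_len(R)) for (b in seq_len(R)) {
    if (a == b || is.na(scores[a, b])) next
    nulls <- null_arr[, a, b]
    nulls <- nulls[!is.na(nulls)]
    p[a, b] <- (1 + sum(nulls >= scores[a, b])) / (length(nulls) + 1)
    flags[a, b] <- scores[a, b] > stats::quantile(nulls, 0.95)
  }
  list(scores = scores, null_scores = null_arr, p = p,
       flags = flags, regions = actual$regions)
}

#' Fraction of significant edges participating in directed 3-cycles
#'
#' For each significant directed edge `A -> B`, checks membership in at
#' least one directed cycle of length `size` within the significant-edge
#' graph, and reports the participating fraction.
#'
#' @param flags_graph Logical adjacency matrix of significant directed
#'   edges (no self-edges).
#' @param size Cycle length (3 by default).
#' @return Fraction in \[0, 1\] (`NA` when fewer than `size` nodes or no
#'   significant edges).
#' @export
loop_fraction <- function(flags_graph, size = 3) {
  adj <- flags_graph
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  R <- nrow(adj)
  if (R < size) return(NA_real_)
  edges <- which(adj, arr.ind = TRUE)
  if (nrow(edges) == 0) return(NA_real_)
  # walk counts: edge (i,j) is in a directed `size`-cycle iff a path of
  # length size-1 leads from j back to i
  walk <- diag(R)
  for (k in seq_len(size - 1)) walk <- walk %*% (adj * 1)
  in_loop <- vapply(seq_len(nrow(edges)), function(e)
    walk[edges[e, 2], edges[e, 1]] > 0, logical(1))
  mean(in_loop)
}

#' Aggregate per-session Granger p-values
#'
#' Fisher-combines each directed pair's p-values across sessions into a
#' region-level graph, and optionally combines the region pairs within
#' coarse groupings into a coarse-level graph (a second Fisher pass).
#'
#' @param per_session_p List of p-value matrices (regions x regions), all
#'   with identical dimnames.
#' @param coarse Optional named character vector mapping region -> group.
#' @return List with `region_p` and (when `coarse` is given) `coarse_p`.
#' @export
aggregate_granger <- function(per_session_p, coarse = NULL) {
  regions <- rownames(per_session_p[[1]])
  R <- length(regions)
  region_p <- matrix(NA_real_, R, R, dimnames = list(regions, regions))
  for (a in seq_len(R)) for (b in seq_len(R)) {
    if (a == b) next
    ps <- vapply(per_session_p, function(m) m[a, b], numeric(1))
    region_p[a, b] <- fisher_combine(ps)
  }
  out <- list(region_p = region_p)
  if (!is.null(coarse)) {
    groups <- unique(coarse[regions])
    G <- length(groups)
    coarse_p <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
    for (ga in seq_len(G)) for (gb in seq_len(G)) {
      if (ga == gb) next
      ra <- regions[coarse[regions] == groups[ga]]
      rb <- regions[coarse[regions] == groups[gb]]
      ps <- as.vector(region_p[ra, rb, drop = FALSE])
      coarse_p[ga, gb] <- fisher_combine(ps[!is.na(ps)])
    }
    out$coarse_p <- coarse_p
  }
  out
}
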