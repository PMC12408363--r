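#' Neural activity container
#'
#' Holds trial-aligned neural activity: a units/pixels x trials matrix, or a
#' units x trials x bins array for bin-resolved analyses. Spike-count data
#' (`ephys_counts`) must be non-negative integers; widefield fluorescence
#' (`wfi_dff`) is real-valued.
#'
#' @param values Matrix (units x trials) or 3-d array (units x trials x bins).
#' @param modality `"ephys_counts"` or `"wfi_dff"`.
#' @param regions Character region label per unit/pixel.
#' @param bins Optional numeric bin edges (seconds relative to stimulus
#'   onset).
#' @param truth Optional list of generator ground-truth latents (kept for
#'   closed-loop recovery tests).
#' @return An object of class `neural_matrix`.
#' @export
neural_matrix <- function(values, modality = c("ephys_counts", "wfi_dff"),
                          regions = NULL, bins = NULL, truth = NULL) {
  modality <- match.arg(modality)
  if (modality == "ephys_counts" &&
      (any(values < 0) || any(values != round(values))))
    stop("ephys counts must be non-negative integers", call. = FALSE)
  n_units <- dim(values)[1]
  if (is.null(regions)) regions <- rep("region1", n_units)
  stopifnot(length(regions) == n_units)
  structure(list(values = values, modality = modality, regions = regions,
                 bins = bins, truth = truth),
            class = "neural_matrix")
}

#' @method print neural_matrix
#' @export
print.neural_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("neural_matrix [%s]: %d units x %d trials%s, %d region(s)\n",
              x$modality, d[1], d[2],
              if (length(d) == 3) sprintf(" x %d bins", d[3]) else "",
              length(unique(x$regions))))
  invisible(x)
}

#' Configuration for the synthetic neural generators
#'
#' @param n_units Number of units (or pixels).
#' @param gain Coupling of each unit's rate/mean to the latent prior
#'   (scalar, recycled, or per-unit vector).
#' @param baseline Per-unit baseline (scalar or vector).
#' @param drift_amplitude Standard deviation of the slow drift accumulated
#'   over the whole session (0 disables drift).
#' @param drift_form `"random_walk"` or `"linear"`.
#' @param noise_sd Gaussian observation noise (widefield / covariates).
#' @param spatial_rank Rank of the widefield spatial mixing matrix.
#' @param alpha,zeta_pos,zeta_neg,zeta,sigma Parameters of the
#'   action/stimulus-kernel generative flavour (learning rate, Poisson
#'   scaling factors after right/left actions, Gaussian scaling and noise).
#' @param seed Integer seed.
#' @return A plain list of class `synth_neural_config`.
#' @export
synth_neural_config <- function(n_units = 20, gain = 1, baseline = 1,
                                drift_amplitude = 0,
                                drift_form = c("random_walk", "linear"),
                                noise_sd = 0.2, spatial_rank = 3,
                                alpha = 0.2, zeta_pos = 5, zeta_neg = 1,
                                zeta = 1, sigma = 0.5, seed = 1) {
  structure(list(n_units = n_units, gain = gain, baseline = baseline,
                 drift_amplitude = drift_amplitude,
                 drift_form = match.arg(drift_form), noise_sd = noise_sd,
                 spatial_rank = spatial_rank, alpha = alpha,
                 zeta_pos = zeta_pos, zeta_neg = zeta_neg, zeta = zeta,
                 sigma = sigma, seed = seed),
            class = "synth_neural_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# slow per-unit drift, n_units x n_trials
make_drift <- function(cfg, n_trials) {
  if (cfg$drift_amplitude == 0) return(matrix(0, cfg$n_units, n_trials))
  if (cfg$drift_form == "linear") {
    slope <- stats::rnorm(cfg$n_units, 0, cfg$drift_amplitude)
    outer(slope, seq(-0.5, 0.5, length.out = n_trials))
  } else {
    t(apply(matrix(stats::rnorm(cfg$n_units * n_trials, 0,
                                cfg$drift_amplitude / sqrt(n_trials)),
                   cfg$n_units), 1, cumsum))
  }
}

# action-kernel latent Q per unit; actions +/-1 with NA for missed trials
kernel_latent <- function(actions, alpha, update_fn, q0) {
  n <- length(actions)
  q <- numeric(n)
  cur <- q0
  for (t in seq_len(n)) {
    q[t] <- cur
    if (t < n + 1 && !is.na(actions[t]))
      cur <- (1 - alpha) * cur + alpha * update_fn(actions[t])
  }
  q
}

signed_actions <- function(session) {
  a <- rep(NA_real_, nrow(session))
  ok <- !is.na(session$choice) & session$choice != "none"
  a[ok] <- ifelse(session$choice[ok] == "right", 1, -1)
  a
}

#' Synthetic spike counts
#'
#' Two generative flavours. `"prior_coupled"` draws Poisson counts with rate
#' `softplus(baseline + gain * prior + drift)` per unit and trial - the
#' structure the decoders assume, with drift as the confound the
#' pseudosession null exists to defeat. `"action_kernel"` draws Poisson
#' counts whose rate is a leaky integration of past actions,
#' `Q_t = (1 - alpha) Q_{t-1} + alpha * zeta^(a_{t-1})` with separate
#' scaling factors after right and left choices - the generative model the
#' decay-rate fitter inverts. Missed trials skip the update.
#'
#' @param session Trial table (choices needed for the kernel flavour).
#' @param prior_trace Per-trial latent the rates couple to.
#' @param cfg A [synth_neural_config()].
#' @param flavour `"prior_coupled"` or `"action_kernel"`.
#' @return A [neural_matrix()] of modality `ephys_counts` with the true
#'   latent in `$truth`.
#' @export
gen_ephys_counts <- function(session, prior_trace = NULL,
                             cfg = synth_neural_config(),
                             flavour = c("prior_coupled", "action_kernel")) {
  flavour <- match.arg(flavour)
  set.seed(cfg$seed)
  n <- nrow(session)
  gain <- rep_len(cfg$gain, cfg$n_units)
  base <- rep_len(cfg$baseline, cfg$n_units)
  if (flavour == "prior_coupled") {
    stopifnot(length(prior_trace) == n)
    drift <- make_drift(cfg, n)
    rate <- softplus(base + outer(gain, as.numeric(prior_trace)) + drift)
    truth <- list(latent = as.numeric(prior_trace), rate = rate,
                  gain = gain)
  } else {
    a <- signed_actions(session)
    p_right <- mean(a == 1, na.rm = TRUE)
    q0 <- p_right * cfg$zeta_pos + (1 - p_right) * cfg$zeta_neg
    q1 <- kernel_latent(a, cfg$alpha,
                        function(act) if (act > 0) cfg$zeta_pos else
                          cfg$zeta_neg, q0)
    rate <- matrix(rep(q1, each = cfg$n_units), cfg$n_units)
    truth <- list(latent = q1, alpha = cfg$alpha,
                  zeta_pos = cfg$zeta_pos, zeta_neg = cfg$zeta_neg)
  }
  counts <- matrix(stats::rpois(length(rate), pmax(rate, 1e-9)),
                   nrow(rate))
  neural_matrix(counts, "ephys_counts", truth = truth)
}

#' Synthetic widefield fluorescence
#'
#' Pixel means are `baseline + gain * latent`, mixed through a low-rank
#' spatial matrix whose first factor carries the latent (the prior trace, or
#' a Gaussian action-kernel integration `Q_t = (1-alpha) Q_{t-1} +
#' alpha * zeta * a_{t-1}`), with additive Gaussian noise. The latent is
#' recoverable by a linear readout whenever the mixing has full column rank.
#'
#' @inheritParams gen_ephys_counts
#' @return A [neural_matrix()] of modality `wfi_dff`.
#' @export
gen_wfi_dff <- function(session, prior_trace = NULL,
                        cfg = synth_neural_config(noise_sd = 0.2),
                        flavour = c("prior_coupled", "action_kernel")) {
  flavour <- match.arg(flavour)
  set.seed(cfg$seed)
  n <- nrow(session)
  if (cfg$spatial_rank > cfg$n_units)
    stop("`spatial_rank` cannot exceed the number of pixels", call. = FALSE)
  if (flavour == "prior_coupled") {
    stopifnot(length(prior_trace) == n)
    latent <- rep_len(cfg$gain, 1)[1] * as.numeric(prior_trace)
    truth <- list(latent = as.numeric(prior_trace))
  } else {
    a <- signed_actions(session)
    q0 <- cfg$zeta * (2 * mean(a == 1, na.rm = TRUE) - 1)
    latent <- kernel_latent(a, cfg$alpha,
                            function(act) cfg$zeta * act, q0)
    truth <- list(latent = latent, alpha = cfg$alpha, zeta = cfg$zeta,
                  sigma = cfg$sigma)
  }
  factors <- rbind(latent,
                   if (cfg$spatial_rank > 1)
                     matrix(stats::rnorm((cfg$spatial_rank - 1) * n),
                            cfg$spatial_rank - 1))
  mixing <- matrix(stats::rnorm(cfg$n_units * cfg$spatial_rank),
                   cfg$n_units) / sqrt(cfg$spatial_rank)
  mixing[, 1] <- abs(mixing[, 1]) + 0.5   # every pixel sees the latent
  mu <- rep_len(cfg$baseline, cfg$n_units) + mixing %*% factors
  noise_sd <- if (flavour == "action_kernel") cfg$sigma else cfg$noise_sd
  vals <- mu + matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu))
  drift <- make_drift(cfg, n)
  truth$mixing <- mixing
  neural_matrix(vals + drift, "wfi_dff", truth = truth)
}

covariate_names <- c("paw_l", "paw_r", "nose", "wheel", "lick",
                     "whisk_l", "whisk_r", "eye_x", "eye_y")

#' Synthetic embodiment covariates
#'
#' Seven tracked-body features plus two eye-position coordinates, each
#' `baseline + coupling * prior + noise`, averaged over the intertrial
#' interval. Per-feature couplings of zero give the null used to calibrate
#' the embodiment analyses.
#'
#' @param session Trial table.
#' @param prior_trace Per-trial latent prior.
#' @param coupling Numeric vector of length 9 (recycled) of per-feature
#'   couplings.
#' @param noise_sd Observation noise.
#' @param seed Integer seed.
#' @return A trials x 9 `data.frame` of covariates.
#' @export
gen_covariates <- function(session, prior_trace, coupling = 0,
                           noise_sd = 1, seed = 1) {
  set.seed(seed)
  n <- nrow(session)
  coupling <- rep_len(coupling, length(covariate_names))
  out <- sapply(seq_along(covariate_names), function(j)
    coupling[j] * as.numeric(prior_trace) + stats::rnorm(n, 0, noise_sd))
  colnames(out) <- covariate_names
  as.data.frame(out)
}

#' Synthetic multi-region bin-resolved activity
#'
#' Builds per-region latent series over trials x bins (10 bins for spike
#' counts, 9 frames for widefield), each coupled to the prior, with optional
#' directed lag-1 coupling injected between named regions on the
#' concatenated (trial-major) bin series. Emission is Poisson through a
#' softplus link or Gaussian, per modality.
#'
#' @param session Trial table.
#' @param prior_trace Per-trial prior latent.
#' @param regions Character vector of region names.
#' @param n_units Units per region.
#' @param n_bins Bins per trial (10 for `ephys_counts`, 9 for `wfi_dff`).
#' @param gain Prior coupling per region (recycled).
#' @param coupling Optional `data.frame` with columns `from`, `to`, `weight`:
#'   lag-1 directed coupling added on the concatenated bin series.
#' @param modality Emission modality.
#' @param innovation_sd Latent AR innovation scale.
#' @param ar Latent AR(1) coefficient along concatenated bins.
#' @param noise_sd Gaussian emission noise (widefield).
#' @param seed Integer seed.
#' @return A [neural_matrix()] with a units x trials x bins array, region
#'   label per unit, and the per-region latents in `$truth`.
#' @export
gen_region_bin_series <- function(session, prior_trace,
                                  regions = c("A", "B"), n_units = 15,
                                  n_bins = 10, gain = 1, coupling = NULL,
                                  modality = c("ephys_counts", "wfi_dff"),
                                  innovation_sd = 0.3, ar = 0.5,
                                  noise_sd = 0.3, seed = 1) {
  modality <- match.arg(modality)
  if (!is.null(coupling) && any(coupling$from == coupling$to))
    stop("coupling graph must not contain self-loops", call. = FALSE)
  set.seed(seed)
  n <- nrow(session)
  len <- n * n_bins
  gain <- rep_len(gain, length(regions))
  prior_long <- rep(as.numeric(prior_trace), each = n_bins)
  base_lat <- lapply(seq_along(regions), function(r) {
    e <- stats::rnorm(len, 0, innovation_sd)
    z <- stats::filter(e, ar, method = "recursive")
    as.numeric(z) + gain[r] * prior_long
  })
  names(base_lat) <- regions
  lat <- base_lat
  if (!is.null(coupling)) {
    # lag-1 coupling of the full source latent (prior content included):
    # directed flow of prior information is the signal the Granger stage
    # is designed to detect
    for (i in seq_len(nrow(coupling))) {
      fr <- as.character(coupling$from[i]); to <- as.character(coupling$to[i])
      src <- base_lat[[fr]]
      lat[[to]] <- lat[[to]] + coupling$weight[i] * c(0, src[-len])
    }
  }
  vals <- array(0, c(length(regions) * n_units, n, n_bins))
  reg_lab <- rep(regions, each = n_units)
  for (r in seq_along(regions)) {
    z <- matrix(lat[[r]], n_bins, n)          # bins x trials
    for (u in seq_len(n_units)) {
      row <- (r - 1) * n_units + u
      g <- 0.5 + stats::runif(1)
      if (modality == "ephys_counts") {
        rate <- softplus(1 + g * z)
        vals[row, , ] <- t(matrix(stats::rpois(len, rate), n_bins))
      } else {
        vals[row, , ] <- t(matrix(g * z + stats::rnorm(len, 0, noise_sd),
                                  n_bins))
      }
    }
  }
  neural_matrix(vals, modality, regions = reg_lab,
                truth = list(latents = lat, gain = gain))
}

#' Plain-text round trip for neural matrices
#'
#' Serialises a [neural_matrix()] to long-format CSV (`unit`, `region`,
#' `trial`, `bin`, `value` plus a `modality` column) and back, losslessly.
#'
#' @param x A `neural_matrix`.
#' @param path File path.
#' @export
write_neural <- function(x, path) {
  d <- dim(x$values)
  nb <- if (length(d) == 3) d[3] else 1
  long <- data.frame(
    unit = rep(seq_len(d[1]), times = d[2] * nb),
    region = rep(x$regions, times = d[2] * nb),
    trial = rep(rep(seq_len(d[2]), each = d[1]), times = nb),
    bin = rep(seq_len(nb), each = d[1] * d[2]),
    value = as.vector(x$values),
    modality = x$modality)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_neural
#' @export
read_neural <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  nu <- max(long$unit); nt <- max(long$trial); nb <- max(long$bin)
  vals <- array(NA_real_, c(nu, nt, nb))
  vals[cbind(long$unit, long$trial, long$bin)] <- long$value
  if (nb == 1) vals <- vals[, , 1, drop = TRUE]
  if (is.null(dim(vals))) vals <- matrix(vals, nu)
  regions <- long$region[match(seq_len(nu), long$unit)]
  neural_matrix(vals, long$modality[1], regions = regions)
}
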