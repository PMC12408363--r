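#' Task configuration for the biased-block session generator
#'
#' The task presents a lateralised visual grating whose side is drawn from a
#' block-structured Bernoulli process: after an initial unbiased block, the
#' probability that the stimulus appears on the right alternates between
#' `1 - gamma` and `gamma` in blocks whose lengths follow a truncated
#' exponential distribution.
#'
#' @param gamma Probability that the stimulus falls on the block's favoured
#'   side. Must lie in (0.5, 1).
#' @param tau_block Scale (in trials) of the exponential block-length
#'   distribution before truncation.
#' @param block_min,block_max Truncation bounds (in trials) of the block-length
#'   distribution.
#' @param n_unbiased Length of the initial unbiased block during which the
#'   stimulus side is equiprobable.
#' @param contrast_magnitudes Ordered vector of available contrast magnitudes.
#' @param p_zero_contrast Probability of a zero-contrast trial; the remaining
#'   mass is spread uniformly over the non-zero magnitudes.
#' @param n_trials Session length in trials.
#' @param rng_seed Optional integer seed consumed by [generate_session()].
#' @return An object of class `task_config`.
#' @export
task_config <- function(gamma = 0.8, tau_block = 60, block_min = 20,
                        block_max = 100, n_unbiased = 90,
                        contrast_magnitudes = c(0, 0.0625, 0.125, 0.25, 1),
                        p_zero_contrast = 1 / 9, n_trials = 555,
                        rng_seed = NULL) {
  cfg <- list(gamma = gamma, tau_block = tau_block, block_min = block_min,
              block_max = block_max, n_unbiased = n_unbiased,
              contrast_magnitudes = sort(unique(contrast_magnitudes)),
              p_zero_contrast = p_zero_contrast, n_trials = n_trials,
              rng_seed = rng_seed)
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (!(cfg$gamma > 0.5 && cfg$gamma < 1))
    stop("`gamma` must lie in (0.5, 1)", call. = FALSE)
  if (cfg$block_min > cfg$block_max)
    stop("`block_min` must not exceed `block_max`", call. = FALSE)
  if (cfg$block_min < 1 || cfg$tau_block <= 0)
    stop("block-length parameters must be positive", call. = FALSE)
  if (cfg$p_zero_contrast < 0 || cfg$p_zero_contrast > 1)
    stop("`p_zero_contrast` must be a probability", call. = FALSE)
  if (!0 %in% cfg$contrast_magnitudes)
    stop("`contrast_magnitudes` must include 0", call. = FALSE)
  if (cfg$n_trials < 1 || cfg$n_unbiased < 0)
    stop("`n_trials` must be >= 1 and `n_unbiased` >= 0", call. = FALSE)
  invisible(cfg)
}

#' Truncated-exponential block-length distribution
#'
#' Probability mass function proportional to `exp(-N / tau)` on the integer
#' support `block_min..block_max`.
#'
#' @param cfg A [task_config()].
#' @return A list with `support`, `pmf`, and the per-age hazard `hazard`
#'   (probability that a block ends at age `a` given it reached age `a`,
#'   defined on `1..block_max`, with a forced switch at `block_max`).
#' @export
block_length_dist <- function(cfg) {
  support <- cfg$block_min:cfg$block_max
  pmf <- exp(-support / cfg$tau_block)
  pmf <- pmf / sum(pmf)
  full <- numeric(cfg$block_max)
  full[support] <- pmf
  surv <- rev(cumsum(rev(full)))          # P(L >= a)
  hazard <- ifelse(surv > 0, full / surv, 1)
  hazard[cfg$block_max] <- 1
  list(support = support, pmf = pmf, hazard = hazard)
}

contrast_probs <- function(cfg) {
  mags <- cfg$contrast_magnitudes
  nz <- mags[mags != 0]
  p <- numeric(length(mags))
  p[mags == 0] <- cfg$p_zero_contrast
  p[mags != 0] <- (1 - cfg$p_zero_contrast) / length(nz)
  p
}

#' Generate a synthetic biased-block session
#'
#' Draws the block sequence, stimulus sides and signed contrasts of one
#' session. Choices, rewards and reaction times are left empty; use
#' [simulate_agent()] to fill them in.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed (overrides `config$rng_seed`).
#' @param session_id,mouse_id Opaque identifier strings.
#' @return A `data.frame` trial table with columns `session_id`, `mouse_id`,
#'   `trial`, `block_p_right`, `stim_side`, `signed_contrast`, `choice`,
#'   `reward`, `reaction_time`, `included`, and the generating config attached
#'   as attribute `task_config`.
#' @export
generate_session <- function(config = task_config(), seed = NULL,
                             session_id = "s1", mouse_id = "m1") {
  validate_task_config(config)
  if (is.null(seed)) seed <- config$rng_seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  block_p <- rep(0.5, n)
  dist <- block_length_dist(config)
  levels <- round(c(1 - config$gamma, config$gamma), 10)
  t <- config$n_unbiased + 1
  side <- sample(1:2, 1)
  while (t <= n) {
    len <- sample(dist$support, 1, prob = dist$pmf)
    block_p[t:min(t + len - 1, n)] <- levels[side]
    t <- t + len
    side <- 3 - side
  }
  stim_right <- stats::rbinom(n, 1, block_p)
  mag <- sample(config$contrast_magnitudes, n, replace = TRUE,
                prob = contrast_probs(config))
  trials <- data.frame(
    session_id = session_id, mouse_id = mouse_id, trial = seq_len(n),
    block_p_right = block_p,
    stim_side = ifelse(stim_right == 1, "right", "left"),
    signed_contrast = ifelse(stim_right == 1, mag, -mag),
    choice = NA_character_, reward = NA_integer_,
    reaction_time = NA_real_, included = TRUE,
    stringsAsFactors = FALSE)
  attr(trials, "task_config") <- config
  trials
}

#' @rdname generate_session
#' @param trials A trial table.
#' @return `session_config()` returns the `task_config` attached to a trial
#'   table (or a default config matched to its length).
#' @export
session_config <- function(trials) {
  cfg <- attr(trials, "task_config")
  if (is.null(cfg)) cfg <- task_config(n_trials = nrow(trials))
  cfg
}

#' Resample pseudosessions from a session's generative process
#'
#' Pseudosessions are counterfactual block/stimulus/contrast sequences drawn
#' from the same generative law and of the same length as a recorded session.
#' Targets rebuilt on them are statistically exchangeable with the real target
#' but independent of the recorded neural activity, which makes them the null
#' of choice against slowly drifting confounds.
#'
#' @param session A trial table carrying its `task_config`.
#' @param M Number of pseudosessions (the field default is 1000; 200 is used
#'   by the weight- and behaviour-coupled analyses).
#' @param seed Integer seed.
#' @return An object of class `pseudosession_set`: a list of trial tables with
#'   the generator `M` and `seed` recorded.
#' @export
generate_pseudosessions <- function(session, M = 1000, seed = 1) {
  if (M < 1) stop("`M` must be >= 1", call. = FALSE)
  cfg <- session_config(session)
  cfg$n_trials <- nrow(session)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, M)
  out <- lapply(seq_len(M), function(i)
    generate_session(cfg, seed = seeds[i],
                     session_id = paste0("pseudo", i),
                     mouse_id = unique(session$mouse_id)[1]))
  structure(list(sessions = out, M = M, seed = seed),
            class = "pseudosession_set")
}

#' Flag trials and sessions failing inclusion criteria
#'
#' Trials with no registered choice or a reaction time outside \[0.08, 2\]
#' seconds are marked excluded; a session with fewer than 250 included trials
#' is flagged invalid.
#'
#' @param session Trial table with `choice` and `reaction_time` populated.
#' @return The trial table with `included` updated and attribute
#'   `session_valid` set.
#' @export
apply_inclusion_filters <- function(session) {
  rt <- session$reaction_time
  ok <- !is.na(session$choice) & session$choice != "none" &
    !is.na(rt) & rt >= 0.08 & rt <= 2
  session$included <- ok
  attr(session, "session_valid") <- sum(ok) >= 250
  session
}

trial_columns <- c("session_id", "mouse_id", "trial", "block_p_right",
                   "stim_side", "signed_contrast", "choice", "reward",
                   "reaction_time", "included")

#' Read / write trial tables as CSV
#'
#' The on-disk dialect is UTF-8 comma-separated CSV with a mandatory header
#' and `.` decimals; the round-trip is lossless for all columns.
#'
#' @param path File path.
#' @return `read_trials()` returns a trial table `data.frame`.
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty trial table in ", path, call. = FALSE)
  missing <- setdiff(trial_columns, names(tab))
  if (length(missing))
    stop("trial table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tab$choice <- as.character(tab$choice)
  tab$included <- as.logical(tab$included)
  tab[trial_columns]
}

#' @rdname read_trials
#' @param trials Trial table to write.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing))
    stop("trial table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- trials[trial_columns]
  for (col in names(out))   # full double precision so the round trip is exact
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
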