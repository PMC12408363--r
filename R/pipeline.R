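#' Simulate a behavioural cohort
#'
#' Generates `n_mice x sessions_per_mouse` sessions from the task generative
#' model and simulates the given agent on each, returning one combined trial
#' table (with the per-trial agent prior in column `prior`).
#'
#' @param n_mice,sessions_per_mouse Cohort layout.
#' @param task A [task_config()].
#' @param agent An [agent_params()].
#' @param seed Master seed.
#' @return A trial table covering the whole cohort.
#' @export
simulate_cohort <- function(n_mice = 139, sessions_per_mouse = 3,
                            task = task_config(),
                            agent = agent_params("bayes_optimal",
                                                 sigma_c = 0.1),
                            seed = 1) {
  k <- 0
  out <- vector("list", n_mice * sessions_per_mouse)
  for (m in seq_len(n_mice)) for (s in seq_len(sessions_per_mouse)) {
    k <- k + 1
    ses <- generate_session(task, seed = seed + 13 * k,
                            session_id = sprintf("m%03d_s%02d", m, s),
                            mouse_id = sprintf("m%03d", m))
    out[[k]] <- simulate_agent(ses, agent, seed = seed + 13 * k + 5)
  }
  res <- do.call(rbind, out)
  attr(res, "task_config") <- task
  res
}

#' Pipeline configuration
#'
#' Bundles every sub-configuration of a synthetic-cohort experiment:
#' cohort layout, task generator, agent, synthetic neural generator,
#' decoder, analysis toggles and Monte-Carlo sizes.
#'
#' @param n_mice,sessions_per_mouse Cohort layout.
#' @param task A [task_config()].
#' @param agent An [agent_params()] generating the behaviour.
#' @param neural A [synth_neural_config()].
#' @param spec A [decode_spec()].
#' @param M Pseudosessions for significance stages.
#' @param n_decode_sessions How many sessions get the neural stages.
#' @param run_neurometric,run_granger,run_history Stage toggles.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_mice = 2, sessions_per_mouse = 2,
                            task = task_config(n_trials = 400),
                            agent = agent_params("bayes_optimal"),
                            neural = synth_neural_config(n_units = 12,
                                                         gain = 2),
                            spec = decode_spec("ephys", n_runs = 2,
                                               inner_folds = 3),
                            M = 50, n_decode_sessions = 2,
                            run_neurometric = FALSE, run_granger = FALSE,
                            run_history = FALSE, seed = 1) {
  structure(list(n_mice = n_mice, sessions_per_mouse = sessions_per_mouse,
                 task = task, agent = agent, neural = neural, spec = spec,
                 M = M, n_decode_sessions = n_decode_sessions,
                 run_neurometric = run_neurometric,
                 run_granger = run_granger, run_history = run_history,
                 seed = seed),
            class = "pipeline_config")
}

# stable content hash of the config (djb2 over its deparsed form)
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the synthetic-cohort pipeline
#'
#' Simulates a cohort (task + agent), computes the behavioural summaries,
#' runs the decoding stage with pseudosession significance on a subset of
#' sessions, optionally runs the neurometric, Granger and history stages,
#' and writes JSON/CSV results to `out_dir`. Deterministic given the seeds
#' in the config; every artifact records the seed and a config hash.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of stage results (also serialised to disk).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = config$seed, config_hash = config_hash(config),
               package_version = as.character(
                 utils::packageVersion("blockprior")))
  stage <- "simulate"
  res <- tryCatch({
    trials_all <- list()
    k <- 0
    for (m in seq_len(config$n_mice)) for (s in
                                           seq_len(config$sessions_per_mouse)) {
      k <- k + 1
      sess <- generate_session(config$task, seed = config$seed + 7 * k,
                               session_id = sprintf("m%02d_s%02d", m, s),
                               mouse_id = sprintf("m%02d", m))
      sess <- simulate_agent(sess, config$agent,
                             seed = config$seed + 7 * k + 1)
      trials_all[[k]] <- apply_inclusion_filters(sess)
    }
    trials <- do.call(rbind, lapply(trials_all, function(s)
      s[trial_columns]))
    write_trials(trials, file.path(out_dir, "trials.csv"))

    stage <- "behaviour"
    zc <- trials$signed_contrast == 0 & trials$included
    behaviour <- list(
      zero_contrast_accuracy = mean(trials$reward[zc]),
      zero_contrast_fraction = mean(trials$signed_contrast == 0),
      psychometric_shift = attr(psychometric_by_block(trials),
                                "zero_contrast_shift"))
    rev_fit <- tryCatch(fit_reversal(trials), error = function(e) NULL)
    if (!is.null(rev_fit))
      behaviour$reversal <- rev_fit[c("A", "B", "tau")]

    stage <- "decode"
    nds <- min(config$n_decode_sessions, length(trials_all))
    decode <- lapply(seq_len(nds), function(i) {
      sess <- trials_all[[i]]
      ncfg <- config$neural
      ncfg$seed <- config$seed + 100 + i
      nm <- gen_ephys_counts(sess, sess$prior, ncfg)
      sig <- pseudosession_significance(
        nm, sess, function(s) as.numeric(bayes_optimal_prior(s)),
        config$spec, M = config$M, seed = config$seed + 200 + i)
      list(session_id = sess$session_id[1], r2 = sig$r2,
           corrected_r2 = sig$corrected_r2, p_value = sig$p_value)
    })
    regions <- region_summary(
      region = rep("synthetic_region", nds),
      p_values = vapply(decode, `[[`, numeric(1), "p_value"),
      corrected_r2 = vapply(decode, `[[`, numeric(1), "corrected_r2"))
    utils::write.csv(regions, file.path(out_dir, "region_map.csv"),
                     row.names = FALSE)

    extra <- list()
    if (config$run_neurometric) {
      stage <- "neurometric"
      sess <- trials_all[[1]]
      ncfg <- config$neural; ncfg$seed <- config$seed + 300
      nm <- gen_ephys_counts(sess, sess$prior, ncfg)
      dec <- decode_signed_contrast(t(nm$values), sess$signed_contrast,
                                    decode_spec("neurometric_ephys",
                                                n_runs = 2,
                                                inner_folds = 3),
                                    seed = config$seed)
      fit <- neurometric_fit(dec$predictions, sess$signed_contrast,
                             as.numeric(bayes_optimal_prior(sess)))
      extra$neurometric <- list(shift = fit$shift, BIC = fit$BIC)
    }
    if (config$run_granger) {
      stage <- "granger"
      sess <- trials_all[[1]]
      nm <- gen_region_bin_series(sess, sess$prior,
                                 seed = config$seed + 400)
      dec <- binwise_prior_decode(nm, sess$prior, seed = config$seed)
      extra$granger <- list(scores = pair_scores(dec$tensor))
    }
    if (config$run_history) {
      stage <- "history"
      sess <- trials_all[[1]]
      ncfg <- config$neural; ncfg$seed <- config$seed + 500
      nm <- gen_ephys_counts(sess, sess$prior, ncfg)
      dec <- nested_cv_decode(nm, sess$prior, config$spec,
                              seed = config$seed)
      extra$history <- list(
        ortho_weights = as.numeric(
          orthogonalize_past(dec$predictions, sess$choice)),
        asymmetry = neural_agent_asymmetry(dec$predictions, sess))
    }
    list(meta = meta, behaviour = behaviour, decode = decode,
         regions = regions, extra = extra)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(res[setdiff(names(res), "regions")],
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(res)
}

#' Summarise a pipeline result directory
#'
#' Collects the artifacts written by [run_pipeline()] into summary tables;
#' missing stages are listed as absent rather than raising errors.
#'
#' @param result_dir Directory produced by [run_pipeline()].
#' @return List with `present`, `absent`, and the parsed `results`,
#'   `region_map` and `trials_head` when available.
#' @export
make_report <- function(result_dir) {
  expected <- c(results = "results.json", region_map = "region_map.csv",
                trials = "trials.csv")
  paths <- file.path(result_dir, expected)
  names(paths) <- names(expected)
  present <- names(expected)[file.exists(paths)]
  absent <- setdiff(names(expected), present)
  out <- list(present = present, absent = absent)
  if ("results" %in% present)
    out$results <- jsonlite::read_json(paths["results"],
                                       simplifyVector = TRUE)
  if ("region_map" %in% present)
    out$region_map <- utils::read.csv(paths["region_map"])
  if ("trials" %in% present)
    out$trials_head <- utils::head(read_trials(paths["trials"]))
  out
}

#' Read / write configuration objects as YAML
#'
#' @param config Any of the package's configuration objects.
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @param class Class to restore on the read object.
#' @export
read_config_yaml <- function(path, class = NULL) {
  obj <- yaml::read_yaml(path)
  if (!is.null(class)) class(obj) <- class
  obj
}
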