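# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# one mid-sized session with a Bayes-optimal probability-matching agent
fx_session <- function() fixture("session", function() {
  s <- generate_session(task_config(n_trials = 400), seed = 11)
  simulate_agent(s, agent_params("bayes_optimal", sigma_c = 0.1), seed = 12)
})

# prior-coupled spike counts for the fixture session
fx_counts <- function() fixture("counts", function() {
  s <- fx_session()
  gen_ephys_counts(s, s$prior,
                   synth_neural_config(n_units = 12, gain = 3, seed = 13))
})

# a fast decoder spec for tests
fx_spec <- function(n_runs = 2, ...)
  decode_spec("ephys", n_runs = n_runs, inner_folds = 3, ...)

# toy task config with exhaustively enumerable block structure
fx_toy_config <- function(n_trials = 6)
  task_config(gamma = 0.8, tau_block = 1, block_min = 1, block_max = 2,
              n_unbiased = 0, n_trials = n_trials)

# Exhaustive-enumeration oracle for the ideal-observer prior on toy configs:
# sums over every block segmentation (alternating sides, truncated-exponential
# lengths, possibly ongoing last block) of the first t-1 observations.
enum_prior_oracle <- function(stim_sides, cfg) {
  T_ <- length(stim_sides)
  support <- cfg$block_min:cfg$block_max
  pmf_vals <- exp(-support / cfg$tau_block)
  pmf_vals <- pmf_vals / sum(pmf_vals)
  pmf <- function(l) if (l %in% support) pmf_vals[match(l, support)] else 0
  surv <- function(a) sum(pmf_vals[support >= a])
  compositions <- function(total) {
    # all (completed lengths, ongoing length) with sum == total
    out <- list()
    recurse <- function(done, remaining) {
      for (l in support) {
        if (l < remaining) recurse(c(done, l), remaining - l)
        if (l >= remaining) {
          out[[length(out) + 1]] <<- list(done = done, last = remaining)
          break
        }
      }
    }
    recurse(integer(0), total)
    out
  }
  segs <- list()
  for (first_side in c("left", "right")) {
    for (comp in compositions(T_)) {
      lens <- c(comp$done, comp$last)
      sides <- rep(c(first_side, setdiff(c("left", "right"), first_side)),
                   length.out = length(lens))
      b <- rep(sides, times = lens)
      pr <- 0.5 * prod(vapply(comp$done, pmf, numeric(1))) * surv(comp$last)
      segs[[length(segs) + 1]] <- list(b = b, pr = pr)
    }
  }
  emis <- function(b, s) if (b == s) cfg$gamma else 1 - cfg$gamma
  vapply(seq_len(T_), function(t) {
    num <- den <- 0
    for (seg in segs) {
      w <- seg$pr
      if (t > 1)
        for (u in 1:(t - 1)) w <- w * emis(seg$b[u], stim_sides[u])
      p_right_t <- if (seg$b[t] == "right") cfg$gamma else 1 - cfg$gamma
      num <- num + w * p_right_t
      den <- den + w
    }
    num / den
  }, numeric(1))
}
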