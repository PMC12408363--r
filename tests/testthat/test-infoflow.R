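test_that("spectral Granger scores separate directions on a known VAR", {
  set.seed(121)
  n <- 2000
  a <- rnorm(n)
  b <- numeric(n)
  for (t in 2:n) b[t] <- 0.8 * a[t - 1] + rnorm(1, 0, 0.5)
  fwd <- as.numeric(granger_pair(a, b))
  bwd <- as.numeric(granger_pair(b, a))
  expect_gt(fwd, 10 * max(bwd, 0.01))
  expect_gte(bwd, 0)
  # independent white noise: near-zero score
  expect_lt(as.numeric(granger_pair(rnorm(n), rnorm(n))), 0.02)
  # affine rescaling of either series leaves the score unchanged
  expect_equal(as.numeric(granger_pair(3 * a + 5, b)), fwd, tolerance = 1e-5)
  expect_equal(as.numeric(granger_pair(a, -2 * b + 1)), fwd,
               tolerance = 1e-5)
  # independent time-domain oracle agrees on the direction
  if (requireNamespace("lmtest", quietly = TRUE)) {
    p_fwd <- lmtest::grangertest(b ~ a, order = 2)$`Pr(>F)`[2]
    p_bwd <- lmtest::grangertest(a ~ b, order = 2)$`Pr(>F)`[2]
    expect_lt(p_fwd, 0.001)
    expect_gt(p_bwd, 0.01)
  }
})

test_that("unit-root series are flagged and differenced", {
  set.seed(122)
  rw <- cumsum(rnorm(500))
  expect_warning(sc <- granger_pair(rw, cumsum(rnorm(500))), "unit-root")
  expect_true(attr(sc, "differenced"))
  expect_gte(as.numeric(sc), 0)
})

test_that("bin-wise decoding produces the expected tensor", {
  s <- generate_session(task_config(n_trials = 150), seed = 61)
  pr <- as.numeric(bayes_optimal_prior(s))
  nm <- gen_region_bin_series(s, pr, regions = c("A", "B"), n_units = 6,
                              n_bins = 10, gain = 2, modality = "wfi_dff",
                              noise_sd = 0.3, innovation_sd = 0.3,
                              seed = 62)
  dec <- suppressWarnings(binwise_prior_decode(nm, pr, seed = 1))
  expect_equal(dim(dec$tensor), c(2, 150, 10))
  # every bin of a prior-coupled region correlates with the prior
  cors <- apply(dec$tensor[1, , ], 2, cor, y = pr)
  expect_true(all(cors > 0.3))
  expect_gt(mean(cors), 0.5)
  # a region below the unit minimum is skipped with a flag
  nm_small <- nm
  nm_small$regions[nm_small$regions == "B"][1:4] <- "A"
  dec2 <- binwise_prior_decode(nm_small, pr, min_units = 5, seed = 1)
  expect_identical(dec2$skipped, "B")
  expect_true(all(is.na(dec2$tensor["B", , ])))
})

test_that("loop fractions match brute-force cycle enumeration", {
  # complete directed graph on 3 nodes: every edge is in a 3-cycle
  full3 <- matrix(TRUE, 3, 3); diag(full3) <- FALSE
  expect_equal(loop_fraction(full3), 1)
  # pure feed-forward chain has no cycles
  chain <- matrix(FALSE, 4, 4)
  chain[cbind(1:3, 2:4)] <- TRUE
  expect_equal(loop_fraction(chain), 0)
  expect_true(is.na(loop_fraction(matrix(FALSE, 2, 2))))
  # random digraphs against an exhaustive triple-enumeration oracle
  set.seed(123)
  for (i in 1:10) {
    R <- sample(4:7, 1)
    adj <- matrix(runif(R * R) < 0.3, R, R); diag(adj) <- FALSE
    if (!any(adj)) next
    edges <- which(adj, arr.ind = TRUE)
    oracle <- vapply(seq_len(nrow(edges)), function(e) {
      i0 <- edges[e, 1]; j0 <- edges[e, 2]
      any(vapply(seq_len(R), function(k)
        k != i0 && k != j0 && adj[j0, k] && adj[k, i0], logical(1)))
    }, logical(1))
    expect_equal(loop_fraction(adj), mean(oracle))
  }
})

test_that("pseudosession Granger nulls flag injected coupling only", {
  s <- generate_session(task_config(n_trials = 200), seed = 63)
  pr <- as.numeric(bayes_optimal_prior(s))
  cpl <- data.frame(from = "A", to = "B", weight = 1.2)
  nm <- gen_region_bin_series(s, pr, regions = c("A", "B"), n_units = 8,
                              n_bins = 5, gain = 1, coupling = cpl,
                              modality = "wfi_dff", noise_sd = 0.3,
                              innovation_sd = 0.5, seed = 64)
  spec <- decode_spec("wfi", outer_folds = 3, inner_folds = 3, n_runs = 1,
                      min_features = 1)
  res <- suppressWarnings(granger_significance(nm, s, spec, M = 25, seed = 2))
  expect_true(res$flags["A", "B"])
  expect_gt(res$scores["A", "B"], res$scores["B", "A"])
  expect_equal(res$p["A", "B"], (1 + sum(res$null_scores[, 1, 2] >=
                                           res$scores["A", "B"])) / 26)
})

test_that("Fisher aggregation of Granger graphs respects symmetry and strength", {
  regions <- c("A", "B", "C")
  mk <- function(p) {
    m <- matrix(p, 3, 3, dimnames = list(regions, regions))
    diag(m) <- NA
    m
  }
  # single session passes through unchanged
  one <- aggregate_granger(list(mk(0.2)))
  expect_equal(one$region_p["A", "B"], 0.2, tolerance = 1e-12)
  # consistent weak evidence accumulates far below any individual p
  ten <- aggregate_granger(rep(list(mk(0.2)), 10))
  expect_lt(ten$region_p["A", "B"], 0.05)
  # permutation invariance across sessions
  sessions <- list(mk(0.1), mk(0.5), mk(0.9))
  expect_equal(aggregate_granger(sessions)$region_p,
               aggregate_granger(rev(sessions))$region_p)
  # coarse graphs combine region pairs inside group pairs
  coarse <- c(A = "ctx", B = "ctx", C = "sub")
  agg <- aggregate_granger(sessions, coarse = coarse)
  expect_equal(dim(agg$coarse_p), c(2L, 2L))
  expect_true(is.na(agg$coarse_p["ctx", "ctx"]))
})
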