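test_that("loess reproduces polynomials of its own degree exactly", {
  n <- 40
  lin <- 0.1 + 0.02 * seq_len(n)
  for (a in c(0.2, 0.5, 1)) {
    expect_lt(max(abs(loess_fit(lin, a, 1)$fitted - lin)), 1e-10)
    expect_lt(max(abs(loess_fit(lin, a, 2)$fitted - lin)), 1e-10)
  }
  quad <- (seq_len(n) / n)^2
  expect_lt(max(abs(loess_fit(quad, 0.4, 2)$fitted - quad)), 1e-10)
})

test_that("fitted values and trace match the independent per-point WLS oracle", {
  set.seed(42)
  y <- cumsum(rnorm(20, 0, 0.3))
  f <- loess_fit(y, 0.5, 2)
  o <- oracle_loess(y, 0.5, 2)
  expect_lt(max(abs(f$fitted - o$fitted)), 1e-8)

  y15 <- rnorm(15)
  f15 <- loess_fit(y15, 0.6, 2)
  o15 <- oracle_loess(y15, 0.6, 2)
  expect_lt(abs(f15$trace_L - o15$trace), 1e-10)
})

test_that("loess agrees with stats::loess on complete series", {
  set.seed(7)
  n <- 50
  y <- cumsum(rnorm(n))
  ref <- stats::loess(y ~ x, data = data.frame(y = y, x = seq_len(n)),
                      span = 0.5, degree = 2, family = "gaussian",
                      surface = "direct", normalize = FALSE)
  f <- loess_fit(y, 0.5, 2)
  expect_lt(max(abs(f$fitted - fitted(ref))), 1e-8)
})

test_that("loess is affine-equivariant and handles masked frames", {
  set.seed(3)
  y <- cumsum(rnorm(60, 0, 0.2))
  f1 <- loess_fit(y, 0.3, 2)
  f2 <- loess_fit(3 * y - 1, 0.3, 2)
  expect_lt(max(abs(f2$fitted - (3 * f1$fitted - 1))), 1e-9)

  ym <- y
  ym[c(10, 11, 30)] <- NA
  fm <- loess_fit(ym, 0.3, 2)
  expect_false(anyNA(fm$fitted))  # masked frames predicted from neighbours
  expect_identical(fm$n, 57L)
  expect_error(loess_fit(rep(NA_real_, 20), 0.3, 2), "all-missing")
  expect_error(loess_fit(rnorm(100), 0.02, 2), "neighbourhood")
})

test_that("fit indices follow their closed forms and fail on degenerate fits", {
  f <- structure(list(fitted = NULL, alpha = 0.3, degree = 2,
                      trace_L = 6, rss = 0.5, n = 50),
                 class = "loess_fit")
  ix <- fit_indices(f)
  expect_equal(ix$aic, log(0.01) + 12 / 50)
  expect_equal(ix$aicc, log(0.01) + 1 + 14 / 42)
  expect_equal(ix$gcv, 0.01 / (1 - 6 / 50)^2)

  f2 <- f
  f2$rss <- 1.0
  ix2 <- fit_indices(f2)
  expect_equal(ix2$aic - ix$aic, log(2))
  expect_equal(ix2$gcv / ix$gcv, 2)

  f$rss <- 0
  expect_error(fit_indices(f), "degenerate")
  expect_error(fit_indices(structure(list(trace_L = 49, rss = 1, n = 50),
                                     class = "loess_fit")), "AICc")
})

test_that("grid selection minimizes the chosen index and takes the modal consensus", {
  expect_equal(facescore:::consensus_alpha(c(0.13, 0.13, 0.10)), 0.13)
  expect_equal(facescore:::consensus_alpha(c(0.10, 0.10, 0.13, 0.13)), 0.10)

  set.seed(11)
  mk <- function() {
    t <- seq(0, 1, length.out = 125)
    pmin(pmax(4 * t * (1 - t) + rnorm(125, 0, 0.08), 0), 1)
  }
  series <- replicate(3, mk(), simplify = FALSE)
  grid <- seq(0.05, 1, by = 0.05)
  sel <- select_smoothing_parameter(series, grid = grid, degree = 2,
                                    index_used = "aicc")
  expect_true(all(sel$per_trial_best %in% grid))
  expect_true(sel$consensus %in% sel$per_trial_best)
  expect_identical(sel$consensus,
                   facescore:::consensus_alpha(sel$per_trial_best))
  ## single trial: consensus equals that trial's best
  sel1 <- select_smoothing_parameter(series[1], grid = grid)
  expect_identical(sel1$consensus, sel1$per_trial_best)
  ## per-trial best truly minimizes the chosen index on the grid
  tab1 <- sel$table[sel$table$trial == 1, ]
  expect_equal(sel$per_trial_best[1], tab1$alpha[which.min(tab1$aicc)])
})

test_that("smoothing a session preserves the simplex, shaves spikes, keeps constants", {
  cfg <- synth_config(n_participants = 1, noise_sd = 0, spike_prob = 0,
                      missing_prob = 0, reliability_rho = 1)
  g <- generate_session(cfg, 31)
  sm <- smooth_session(g$session, 0.13, 2)
  for (t in sm$trials[c(1, 14, 20)]) {
    sums <- rowSums(t$codes$values[, SIMPLEX_CHANNELS])
    expect_lt(max(abs(sums - 1)), 1e-9)
    expect_gte(min(t$codes$values), 0)
  }
  ## noise-free series are nearly invariant under smoothing
  raw <- g$session$trials[[14]]
  smt <- sm$trials[[14]]
  ch <- raw$meta$trial_kind
  dev <- abs(smt$codes$values[, ch] - raw$codes$values[, ch])
  expect_lt(median(dev), 0.01)
  expect_lt(max(dev), 0.05)    # small rounding at the ramp corners only

  ## an isolated spike is averaged down
  tr <- make_stationary_trial(n = 125, seed = 4)
  tr$codes$values[60, "anger"] <- 0.9
  tr$codes$values[60, ] <- tr$codes$values[60, ] /
    sum(tr$codes$values[60, SIMPLEX_CHANNELS])
  smtr <- facescore:::smooth_trial(tr, 0.13, 2)
  expect_lt(max(smtr$codes$values[, "anger"]),
            max(tr$codes$values[, "anger"]))

  const <- make_trial(50, list(anger = 0.2, neutral = 0.6))
  smc <- facescore:::smooth_trial(const, 0.2, 2)
  expect_equal(smc$codes$values, const$codes$values, tolerance = 1e-10)
})
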