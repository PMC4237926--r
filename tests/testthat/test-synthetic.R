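test_that("generation is deterministic and respects the design counts", {
  cfg <- synth_config(n_participants = 2)
  a <- generate_session(cfg, 77, "P001")
  b <- generate_session(cfg, 77, "P001")
  expect_identical(a, b)

  ca <- generate_cohort(cfg, seed = 4)
  cb <- generate_cohort(cfg, seed = 4)
  expect_identical(ca, cb)
  expect_length(ca$sessions, 2)

  s <- a$session
  tasks <- vapply(s$trials, function(t) t$meta$task, "")
  expect_identical(sum(tasks == "calibration_pre"), 13L)
  expect_identical(sum(tasks == "production"), 12L)
  expect_identical(sum(tasks == "calibration_post"), 12L)
  expect_true(all(vapply(s$trials,
                         function(t) nrow(t$codes$values), 0L) == 125L))
  prod <- vapply(s$trials[tasks == "production"],
                 function(t) t$meta$trial_kind, "")
  expect_true(all(table(prod) == 2))
  expect_length(validate_session(s), 0)
})

test_that("every generated valid frame sits on the simplex", {
  g <- generate_session(synth_config(n_participants = 1), 123)
  worst <- 0
  for (t in g$session$trials) {
    ok <- !t$codes$missing_mask
    if (!any(ok)) next
    sums <- rowSums(t$codes$values[ok, SIMPLEX_CHANNELS, drop = FALSE])
    worst <- max(worst, max(abs(sums - 1)))
    expect_gte(min(t$codes$values[ok, ]), 0)
  }
  expect_lt(worst, 1e-12)
})

test_that("a noise-free trial attains the closed-form softmax plateau", {
  cfg <- synth_config(n_participants = 1, noise_sd = 0, spike_prob = 0,
                      missing_prob = 0, reliability_rho = 1,
                      au_noise_sd = 0)
  g <- generate_session(cfg, 55, "P001")
  ab <- g$truth$abilities
  for (t in facescore:::session_trials(g$session, "production")) {
    e <- t$meta$trial_kind
    a <- ab$ability[ab$emotion == e]
    u <- cfg$resting_level + ab$leak
    names(u) <- ab$emotion
    z <- sum(exp(u)) + exp(cfg$resting_level) + 1  # others + contempt + neutral
    expected <- exp(u[[e]] + a) / (z - exp(u[[e]]) + exp(u[[e]] + a))
    expect_equal(max(t$codes$values[, e]), unname(expected),
                 tolerance = 1e-12)
  }
})

test_that("zero ability variance yields identical noise-free maxima across participants", {
  cfg <- synth_config(n_participants = 3, ability_sd = 0, noise_sd = 0,
                      spike_prob = 0, missing_prob = 0,
                      reliability_rho = 1, baseline_leak_sd = rep(0, 6))
  coh <- generate_cohort(cfg, seed = 9)
  mx <- vapply(coh$sessions, function(s) {
    t <- facescore:::session_trials(s, "production")[[1]]
    max(t$codes$values[, t$meta$trial_kind])
  }, 0)
  expect_lt(diff(range(mx)), 1e-12)
})

test_that("AR(1) utility noise carries the configured lag-1 autocorrelation", {
  set.seed(99)
  for (phi in c(0.3, 0.7)) {
    x <- facescore:::ar1_noise(60000, phi, 0.3)
    expect_equal(cor(x[-1], x[-length(x)]), phi, tolerance = 0.02)
  }
  expect_identical(facescore:::ar1_noise(10, 0.5, 0), rep(0, 10))
})

test_that("spike artifacts and missing runs appear at the configured rates", {
  cfg <- synth_config(n_participants = 1, spike_prob = 0.05,
                      missing_prob = 0.05, missing_run_mean = 3)
  g <- generate_session(cfg, 8)
  prod <- facescore:::session_trials(g$session, "production")
  n_missing <- sum(vapply(prod, function(t) sum(t$codes$missing_mask), 0L))
  expect_gt(n_missing, 0)
  ## spikes: frames where the target code touches the spike magnitude
  n_spike <- sum(vapply(prod, function(t) {
    y <- t$codes$values[, t$meta$trial_kind]
    sum(abs(y - 0.9) < 1e-9, na.rm = TRUE)
  }, 0L))
  expect_gt(n_spike, 10)  # 12 trials x 125 frames x .05 ~ 75 expected
})

test_that("with heavy baseline leak and peak decay, full treatment of the max beats untreated means", {
  cfg <- synth_config(n_participants = 60,
                      baseline_leak_mean = c(anger = 2, disgust = 2,
                                             fear = 2, happiness = 2,
                                             sadness = 2, surprise = 2),
                      baseline_leak_sd = rep(1, 6), decay_floor = 0.3)
  coh <- generate_cohort(cfg, seed = 31)
  cleaned <- suppressWarnings(lapply(coh$sessions, clean_session))
  tab <- apply_treatments(lapply(cleaned, `[[`, "session"))
  rec <- recovery_report(tab, coh$truth)
  rho_full_max <- mean(rec$rho[rec$method == "max" &
                               rec$treatment == "loess_base_plast"])
  rho_untr_arith <- mean(rec$rho[rec$method == "arith" &
                                 rec$treatment == "untreated"])
  expect_gt(rho_full_max, rho_untr_arith)
  ## residualizing the baseline leak helps every method
  for (m in SCORE_METHODS)
    expect_gt(mean(rec$rho[rec$method == m &
                           rec$treatment == "loess_base"]),
              mean(rec$rho[rec$method == m &
                           rec$treatment == "loess"]))
})

test_that("recovery report is exact for monotone scores and null for pure noise", {
  coh <- default_cohort(n = 20, seed = 3)
  ab <- coh$truth$abilities
  tab <- score_table(data.frame(participant_id = ab$participant_id,
                                emotion = ab$emotion, half = 1L,
                                method = "max", treatment = "loess",
                                value = plogis(ab$ability)))
  rec <- recovery_report(tab, coh$truth)
  expect_equal(rec$rho, rep(1, 6))

  cfg0 <- synth_config(n_participants = 40, ability_sd = 0)
  coh0 <- generate_cohort(cfg0, seed = 12)
  ## abilities are constant: correlate scores with an independent draw
  tab0 <- apply_treatments(lapply(
    suppressWarnings(lapply(coh0$sessions, clean_session)), `[[`,
    "session"), treatments = c("untreated", "loess"))
  truth0 <- coh0$truth
  set.seed(1)
  truth0$abilities$ability <- rnorm(nrow(truth0$abilities))
  rec0 <- recovery_report(tab0, truth0)
  expect_lt(mean(abs(rec0$rho[rec0$treatment == "loess"])), 0.2)
})
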