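test_that("residualize matches the hand-worked normal equations", {
  r <- residualize(c(1, 2, 4), c(0, 1, 2))
  expect_equal(r, c(1 / 6, -1 / 3, 1 / 6), tolerance = 1e-12)
  ## slope 1.5, intercept 5/6: adding the intercept back shifts by 5/6
  rk <- residualize(c(1, 2, 4), c(0, 1, 2), keep_intercept = TRUE)
  expect_equal(rk, c(1 / 6, -1 / 3, 1 / 6) + 5 / 6, tolerance = 1e-12)

  expect_equal(residualize(2 * c(3, 1, 7, 5), c(3, 1, 7, 5)),
               rep(0, 4), tolerance = 1e-12)
  expect_error(residualize(c(1, 2, 3), c(2, 2, 2)), "zero-variance")
  expect_error(residualize(c(1, 2), c(1, 3)), "3 complete pairs")
})

test_that("residuals are centered and orthogonal to every covariate", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    x <- cbind(rnorm(n), rnorm(n))
    y <- 0.5 + x %*% c(1.2, -0.7) + rnorm(n)
    r <- residualize(as.numeric(y), x)
    expect_lt(abs(sum(r)), 1e-10)
    expect_lt(abs(sum(r * x[, 1])), 1e-10)
    expect_lt(abs(sum(r * x[, 2])), 1e-10)
  }
  ## zero-slope covariate: residuals reduce to centered target
  y <- c(2, 4, 6, 8)
  x <- c(-1, 1, -1, 1)          # exactly orthogonal to y's trend? no:
  x <- c(1, -1, -1, 1)          # sum(x*y) = 2-4-6+8 = 0, sum(x) = 0
  expect_equal(residualize(y, x), y - mean(y), tolerance = 1e-12)
})

test_that("baseline scores reuse the production scoring path on the smoothed neutral trial", {
  base <- make_trial(125, list(sadness = 0.15, neutral = 0.80, anger = 0),
                     kind = "baseline", task = "calibration_pre")
  fill <- 1 - 0.15 - 0.80
  s <- fes_session("P1", list(base))
  b <- baseline_emotion_scores(list(s), alpha = 0.13)
  get <- function(e, m) b$value[b$emotion == e & b$method == m]
  ## constant leak passes through smoothing untouched
  expect_equal(get("sadness", "arith"), 0.15, tolerance = 1e-9)
  expect_equal(get("sadness", "avg_auc"), 0.15, tolerance = 1e-9)
  expect_equal(get("sadness", "max"), 0.15, tolerance = 1e-9)
  expect_equal(get("anger", "arith"), 0, tolerance = 1e-9)
  expect_equal(get("anger", "geom"), 1e-9, tolerance = 1e-12)
  ## identical fixture scored through the production path gives the same number
  prod_view <- make_trial(125, list(sadness = 0.15, neutral = 0.80,
                                    anger = 0), kind = "sadness")
  sm <- facescore:::smooth_trial(prod_view, 0.13, 2)
  expect_equal(get("sadness", "max"), score_trial(sm, "max")$value,
               tolerance = 1e-12)
})

test_that("plasticity composite z-standardizes per-trial differences across participants", {
  mk <- function(pid, au4_cal) {
    base <- make_trial(50, list(neutral = 0.9, AU4 = 0.1),
                       kind = "baseline", task = "calibration_pre",
                       index = 1, pid = pid)
    cal <- make_trial(50, list(neutral = 0.9, AU4 = 0.1 + au4_cal),
                      kind = "movement_1", task = "calibration_pre",
                      index = 2, pid = pid)
    fes_session(pid, list(base, cal))
  }
  sessions <- list(mk("a", 0.2), mk("b", 0.5), mk("c", 0.8))
  ## constant series: smoothed max differences are exactly (.2, .5, .8);
  ## sample-SD convention: sd = .3 -> z = (-1, 0, 1)
  p <- plasticity_composite(sessions, sd_type = "sample")
  expect_equal(p$composite$composite, c(-1, 0, 1), tolerance = 1e-9)
  expect_equal(p$composite$trials_used, c(1, 1, 1))
  ## population convention scales by sqrt(3/2)
  pp <- plasticity_composite(sessions, sd_type = "population")
  expect_equal(pp$composite$composite, c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-9)
  ## participant at the sample mean scores 0; identical participants tie
  expect_equal(p$composite$composite[p$composite$participant_id == "b"], 0,
               tolerance = 1e-9)
  s4 <- list(mk("a", 0.2), mk("b", 0.5), mk("c", 0.8), mk("d", 0.5))
  p4 <- plasticity_composite(s4)
  cb <- p4$composite$composite
  expect_equal(cb[p4$composite$participant_id == "b"],
               cb[p4$composite$participant_id == "d"], tolerance = 1e-12)

  expect_error(plasticity_composite(list(mk("a", 0.5), mk("b", 0.5),
                                         mk("c", 0.5))),
               "zero cross-participant variance")
})

test_that("treatment tiers build on each other and stay orthogonal to their covariates", {
  cfg <- synth_config(n_participants = 16, missing_prob = 0,
                      spike_prob = 0.002)
  coh <- generate_cohort(cfg, seed = 99)
  cleaned <- suppressWarnings(lapply(coh$sessions, clean_session))
  sessions <- lapply(cleaned, `[[`, "session")
  tab <- apply_treatments(sessions)

  expect_setequal(unique(tab$treatment), TREATMENTS)
  expect_setequal(unique(tab$method), SCORE_METHODS)

  ## untreated tier = scoring the cleaned, unsmoothed trial directly
  s1 <- sessions[[1]]
  t1 <- facescore:::session_trials(s1, "production")[[1]]
  direct <- score_trial(t1, "arith")$value
  got <- tab$value[tab$participant_id == s1$participant_id &
                   tab$emotion == t1$meta$trial_kind & tab$half == 1 &
                   tab$method == "arith" & tab$treatment == "untreated"]
  expect_equal(got, direct, tolerance = 1e-12)

  ## orthogonality of each residual tier to its covariate, within cells
  base <- attr(tab, "baseline_scores")
  plast <- attr(tab, "plasticity")$composite
  for (e in c("anger", "happiness")) for (h in 1:2) {
    cell3 <- tab[tab$emotion == e & tab$half == h & tab$method == "max" &
                 tab$treatment == "loess_base", ]
    bv <- base$value[base$emotion == e & base$method == "max"]
    bv <- bv[match(cell3$participant_id,
                   base$participant_id[base$emotion == e &
                                       base$method == "max"])]
    expect_lt(abs(sum(cell3$value)), 1e-8)
    expect_lt(abs(sum(cell3$value * bv)), 1e-8)
    cell4 <- tab[tab$emotion == e & tab$half == h & tab$method == "max" &
                 tab$treatment == "loess_base_plast", ]
    pv <- plast$composite[match(cell4$participant_id,
                                plast$participant_id)]
    expect_lt(abs(sum(cell4$value * pv)), 1e-8)
  }

  ## residualized sample means sit at zero, below the positive raw means
  sm <- sample_summary(tab)
  m2 <- sm$mean[sm$treatment == "loess" & sm$method == "arith"]
  m3 <- sm$mean[sm$treatment == "loess_base" & sm$method == "arith"]
  expect_true(all(m2 > 0))
  expect_true(all(abs(m3) < 1e-8))
})

test_that("without baseline contamination the baseline tier is a near-identity", {
  cfg <- synth_config(n_participants = 40,
                      baseline_leak_mean = c(anger = 0, disgust = 0,
                                             fear = 0, happiness = 0,
                                             sadness = 0, surprise = 0),
                      baseline_leak_sd = rep(0, 6),
                      missing_prob = 0, spike_prob = 0)
  coh <- generate_cohort(cfg, seed = 17)
  cleaned <- suppressWarnings(lapply(coh$sessions, clean_session))
  tab <- apply_treatments(lapply(cleaned, `[[`, "session"),
                          treatments = c("untreated", "loess",
                                         "loess_base"))
  for (e in BASIC_EMOTIONS) {
    t2 <- tab[tab$emotion == e & tab$half == 1 & tab$method == "arith" &
              tab$treatment == "loess", ]
    t3 <- tab[tab$emotion == e & tab$half == 1 & tab$method == "arith" &
              tab$treatment == "loess_base", ]
    v2 <- t2$value[match(t3$participant_id, t2$participant_id)]
    expect_gt(cor(v2, t3$value), 0.95)
  }
})
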