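#' Configuration of the synthetic session generator
#'
#' The generator emulates the output of an automated expression coder on
#' the three-task expression-ability design: per-frame emotion + neutral
#' proportions on the unit simplex (softmax of latent channel utilities),
#' temporal autocorrelation (AR(1) utility noise), momentary expression
#' peaks that need not be held through the trial (trapezoidal target ramp
#' with optional decay), per-participant baseline contamination of the
#' resting face, multiplicative facial-plasticity differences on the AU
#' channels, spike artifacts, and missing-frame runs.
#'
#' Latent scales are utility (log-odds) units: a target utility `u` at the
#' plateau yields a target code of roughly `exp(u + resting_level) /
#' (exp(u + resting_level) + 1 + 6 exp(resting_level))`.
#'
#' @param n_participants Cohort size (default 200).
#' @param frame_rate Frames per second (default 25).
#' @param trial_duration Trial length in seconds (default 5; 125 frames).
#' @param ability_mean,ability_sd Distribution of the per-participant,
#'   per-emotion latent expression ability (utility units).
#' @param baseline_leak_mean Named per-emotion means of the nonnegative
#'   baseline contamination added to that emotion's resting utility in
#'   every trial (defaults concentrate the leak on anger, fear and sadness,
#'   the emotions most visible in a resting face).
#' @param baseline_leak_sd SD of the leak (draws truncated at 0).
#' @param plasticity_meanlog,plasticity_sdlog Log-normal distribution of
#'   the multiplicative AU range factor.
#' @param resting_level Resting utility of the emotion channels relative to
#'   neutral (negative; the default -2.5 leaves the resting face mostly
#'   neutral-coded with visible emotion leak).
#' @param ar_coef AR(1) coefficient of the utility noise, in [0, 1).
#' @param noise_sd Innovation SD of the utility noise.
#' @param softmax_temperature Temperature of the softmax map.
#' @param spike_prob Per-frame probability of a single-frame spike artifact.
#' @param spike_magnitude Code value the spiked channel is pushed to.
#' @param missing_prob Per-frame probability that a missing run starts.
#' @param missing_run_mean Mean missing-run length in frames.
#' @param onset_window Range (seconds) of the uniformly drawn expression
#'   onset. The recording interval follows a 10-s preparation interval in
#'   which participants already form the expression, so the default window
#'   straddles recording start (negative onsets mean the ramp is already
#'   under way at frame 0).
#' @param rise_time Seconds from onset to plateau.
#' @param peak_decay If TRUE (default) the plateau decays after
#'   `decay_window` seconds to `decay_floor` of its height by trial end,
#'   recreating momentary peaks that are not maintained.
#' @param decay_window Range (seconds) of the decay onset.
#' @param decay_floor Fraction of the ramp height retained at trial end.
#' @param reliability_rho Correlation of the trial-level ability
#'   realizations across the two repetitions of an emotion (sets the
#'   trial-noise SD via the classical true-score model).
#' @param au_amplitude Plateau AU intensity of a calibration movement for a
#'   plasticity factor of 1.
#' @param au_noise_sd,au_resting AU channel noise SD and resting tonus.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_participants = 200, frame_rate = 25,
                         trial_duration = 5,
                         ability_mean = 4, ability_sd = 1.5,
                         baseline_leak_mean = c(anger = 1.5, disgust = 0.6,
                                                fear = 1.5, happiness = 0.3,
                                                sadness = 1.5,
                                                surprise = 0.3),
                         baseline_leak_sd = 0.5 * baseline_leak_mean,
                         plasticity_meanlog = 0, plasticity_sdlog = 0.25,
                         resting_level = -2.5, ar_coef = 0.5,
                         noise_sd = 0.25,
                         softmax_temperature = 1,
                         spike_prob = 0.008, spike_magnitude = 0.9,
                         missing_prob = 0.01, missing_run_mean = 4,
                         onset_window = c(-1.25, 0.25), rise_time = 0.5,
                         peak_decay = TRUE, decay_window = c(1.5, 3),
                         decay_floor = 0.6, reliability_rho = 0.8,
                         au_amplitude = 3, au_noise_sd = 0.15,
                         au_resting = 0.2) {
  stopifnot(n_participants >= 1, frame_rate > 0, trial_duration > 0,
            ar_coef >= 0, ar_coef < 1, noise_sd >= 0,
            spike_prob >= 0, spike_prob <= 1, spike_magnitude > 0,
            spike_magnitude < 1, missing_prob >= 0, missing_prob <= 1,
            missing_run_mean >= 1, reliability_rho > 0,
            reliability_rho <= 1, softmax_temperature > 0,
            decay_floor >= 0, decay_floor <= 1,
            all(BASIC_EMOTIONS %in% names(baseline_leak_mean)))
  structure(as.list(environment()), class = "synth_config")
}

## Stationary AR(1) noise series.
ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd)
  init <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive", init = init))
}

softmax_rows <- function(u, temperature = 1) {
  e <- exp(u / temperature)
  e / rowSums(e)
}

## Trapezoid-with-decay activation template on [0, duration], height 1.
ramp_template <- function(t, onset, rise, decay_at, decay_floor) {
  g <- pmin(pmax((t - onset) / rise, 0), 1)
  if (!is.null(decay_at)) {
    after <- t > decay_at
    span <- max(t) - decay_at
    if (span > 0)
      g[after] <- g[after] * (1 - (1 - decay_floor) *
                                (t[after] - decay_at) / span)
  }
  g
}

## One trial's code matrix given channel utilities (n x 8) and AU intensities.
build_trial_codes <- function(cfg, util, au = NULL, spike_channel = NULL) {
  codes <- softmax_rows(util, cfg$softmax_temperature)
  colnames(codes) <- SIMPLEX_CHANNELS
  n <- nrow(codes)
  if (cfg$spike_prob > 0 && !is.null(spike_channel)) {
    hit <- which(stats::runif(n) < cfg$spike_prob)
    for (f in hit) {
      old <- codes[f, spike_channel]
      s <- cfg$spike_magnitude
      if (old < 1) {
        codes[f, ] <- codes[f, ] * (1 - s) / (1 - old)
        codes[f, spike_channel] <- s
      }
    }
  }
  vals <- if (is.null(au)) codes else cbind(codes, au)
  mask <- rep(FALSE, n)
  if (cfg$missing_prob > 0) {
    f <- 1L
    while (f <= n) {
      if (stats::runif(1) < cfg$missing_prob) {
        len <- 1L + stats::rgeom(1, 1 / cfg$missing_run_mean)
        mask[f:min(n, f + len - 1L)] <- TRUE
        f <- f + len
      } else f <- f + 1L
    }
  }
  vals[mask, ] <- NA_real_
  frame_codes(vals, missing_mask = mask, frame_rate = cfg$frame_rate,
              validate = FALSE)
}

#' Generate one participant's session with known ground truth
#'
#' Builds the full three-task session: pre-calibration (baseline + 6
#' movements x 2 = 13 trials), production (6 emotions x 2 = 12 trials,
#' randomized order), post-calibration (6 movements x 2 = 12 trials).
#' Production trials place a trapezoidal ramp of height `ability +
#' trial noise` on the target channel's utility; calibration trials drive
#' the mapped AU channel scaled by the participant's plasticity factor;
#' everything is perturbed by AR(1) utility noise and mapped through a
#' softmax, so every valid frame's emotion + neutral codes sum to exactly 1.
#'
#' @param cfg A [synth_config()].
#' @param participant_seed Integer seed for this participant's stream.
#' @param participant_id Identifier stored in the session.
#' @param production_order Optional character vector of 12 emotion labels
#'   (two per basic emotion) fixing the production order; drawn from the
#'   participant stream when omitted.
#' @return List with `session` (a [fes_session()]) and `truth` (list of
#'   data frames: `abilities` with per-emotion ability and leak,
#'   `plasticity`, `trials` with per-trial realized ramp height and onset).
#' @export
generate_session <- function(cfg, participant_seed = 1L,
                             participant_id = "P001",
                             production_order = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(participant_seed)
  n <- round(cfg$trial_duration * cfg$frame_rate)
  t_sec <- (seq_len(n) - 1) / cfg$frame_rate
  a_pe <- stats::setNames(stats::rnorm(6, cfg$ability_mean, cfg$ability_sd),
                          BASIC_EMOTIONS)
  b_pe <- stats::setNames(
    pmax(0, stats::rnorm(6, cfg$baseline_leak_mean[BASIC_EMOTIONS],
                         cfg$baseline_leak_sd)), BASIC_EMOTIONS)
  m_p <- stats::rlnorm(1, cfg$plasticity_meanlog, cfg$plasticity_sdlog)
  sigma_trial <- cfg$ability_sd *
    sqrt((1 - cfg$reliability_rho) / cfg$reliability_rho)
  if (is.null(production_order))
    production_order <- sample(rep(BASIC_EMOTIONS, 2))

  resting_util <- function() {
    u <- matrix(0, n, length(SIMPLEX_CHANNELS),
                dimnames = list(NULL, SIMPLEX_CHANNELS))
    u[, EMOTION_CHANNELS] <- cfg$resting_level
    for (e in BASIC_EMOTIONS) u[, e] <- u[, e] + b_pe[[e]]
    for (ch in SIMPLEX_CHANNELS)
      u[, ch] <- u[, ch] + ar1_noise(n, cfg$ar_coef, cfg$noise_sd)
    u
  }
  au_matrix <- function(active = NULL, mult = 1, template = NULL) {
    au <- matrix(0, n, length(AU_CHANNELS),
                 dimnames = list(NULL, AU_CHANNELS))
    for (ch in AU_CHANNELS) {
      lv <- cfg$au_resting * m_p
      au[, ch] <- lv + ar1_noise(n, cfg$ar_coef, cfg$au_noise_sd)
    }
    if (!is.null(active))
      au[, active] <- au[, active] + mult * template
    pmax(au, 0)
  }

  trials <- list()
  truth_trials <- list()
  add_trial <- function(task, idx, kind, rep_, codes, peak = NA, onset = NA) {
    trials[[length(trials) + 1L]] <<-
      fes_trial(trial_meta(participant_id, task, idx, kind, rep_), codes)
    truth_trials[[length(truth_trials) + 1L]] <<-
      data.frame(participant_id = participant_id, task = task,
                 trial_index = idx, trial_kind = kind, repetition = rep_,
                 peak = peak, onset = onset)
  }
  movement_block <- function(task) {
    idx <- 0L
    if (task == "calibration_pre") idx <- 1L  # baseline occupies slot 1
    for (rep_ in 1:2) for (mv in MOVEMENT_KINDS) {
      idx <- idx + 1L
      onset <- stats::runif(1, cfg$onset_window[1], cfg$onset_window[2])
      tmpl <- ramp_template(t_sec, onset, cfg$rise_time, NULL, 1)
      mult <- m_p * cfg$au_amplitude * exp(stats::rnorm(1, 0, 0.1))
      map <- au_calibration_map()
      active <- if (mv %in% names(map)) map[[mv]] else NULL
      codes <- build_trial_codes(cfg, resting_util(),
                                 au = au_matrix(active, mult, tmpl),
                                 spike_channel = sample(EMOTION_CHANNELS, 1))
      add_trial(task, idx, mv, rep_, codes, peak = mult, onset = onset)
    }
  }

  ## Task 1: baseline + movements
  codes <- build_trial_codes(cfg, resting_util(), au = au_matrix(),
                             spike_channel = sample(EMOTION_CHANNELS, 1))
  add_trial("calibration_pre", 1L, "baseline", 1L, codes)
  movement_block("calibration_pre")

  ## Task 2: production
  rep_count <- stats::setNames(integer(6), BASIC_EMOTIONS)
  for (i in seq_along(production_order)) {
    e <- production_order[i]
    rep_count[[e]] <- rep_count[[e]] + 1L
    a_trial <- a_pe[[e]] + stats::rnorm(1, 0, sigma_trial)
    onset <- stats::runif(1, cfg$onset_window[1], cfg$onset_window[2])
    decay_at <- if (cfg$peak_decay)
      stats::runif(1, cfg$decay_window[1], cfg$decay_window[2]) else NULL
    u <- resting_util()
    u[, e] <- u[, e] + a_trial *
      ramp_template(t_sec, onset, cfg$rise_time, decay_at, cfg$decay_floor)
    codes <- build_trial_codes(cfg, u, spike_channel = e)
    add_trial("production", i, e, rep_count[[e]], codes,
              peak = a_trial, onset = onset)
  }

  ## Task 3: movements only
  movement_block("calibration_post")

  list(session = fes_session(participant_id, trials),
       truth = list(
         abilities = data.frame(participant_id = participant_id,
                                emotion = BASIC_EMOTIONS,
                                ability = unname(a_pe),
                                leak = unname(b_pe)),
         plasticity = data.frame(participant_id = participant_id,
                                 m_p = m_p),
         trials = do.call(rbind, truth_trials)))
}

#' Generate a cohort of synthetic sessions
#'
#' Draws one seed per participant from the master seed (so participant
#' streams are independent and the whole cohort regenerates byte-identically
#' from the same seed) and a single production order shared by all
#' participants, mirroring the fixed randomized order of the study design.
#'
#' @param cfg A [synth_config()].
#' @param seed Master seed.
#' @return List with `sessions` (list of [fes_session()]) and `truth`
#'   (combined `abilities`, `plasticity`, `trials` data frames).
#' @export
generate_cohort <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  pseeds <- sample.int(.Machine$integer.max - 1L, cfg$n_participants)
  order_ <- sample(rep(BASIC_EMOTIONS, 2))
  ids <- sprintf("P%03d", seq_len(cfg$n_participants))
  out <- lapply(seq_len(cfg$n_participants), function(i)
    generate_session(cfg, pseeds[i], ids[i], production_order = order_))
  list(sessions = lapply(out, `[[`, "session"),
       truth = list(
         abilities = do.call(rbind, lapply(out, function(x) x$truth$abilities)),
         plasticity = do.call(rbind, lapply(out, function(x) x$truth$plasticity)),
         trials = do.call(rbind, lapply(out, function(x) x$truth$trials))))
}

#' Ability recovery per scoring method and treatment
#'
#' Spearman rank correlation, per emotion, between the generated latent
#' ability and each method x treatment score (participant scores averaged
#' over the available halves). The generator's ground truth acts as the
#' oracle for comparing scoring procedures.
#'
#' @param table A [score_table()] for the cohort.
#' @param truth The `truth` element returned by [generate_cohort()].
#' @return Data frame: emotion, method, treatment, n, rho.
#' @export
recovery_report <- function(table, truth) {
  ab <- truth$abilities
  agg <- stats::aggregate(value ~ participant_id + emotion + method +
                            treatment, data = as.data.frame(table),
                          FUN = mean)
  out <- list()
  for (e in unique(agg$emotion)) for (m in unique(agg$method))
    for (tr in unique(agg$treatment)) {
      sub <- agg[agg$emotion == e & agg$method == m & agg$treatment == tr, ]
      if (!nrow(sub)) next
      tv <- ab$ability[match(paste(sub$participant_id, e),
                             paste(ab$participant_id, ab$emotion))]
      cc <- stats::complete.cases(sub$value, tv)
      out[[length(out) + 1L]] <-
        data.frame(emotion = e, method = m, treatment = tr, n = sum(cc),
                   rho = if (sum(cc) >= 3)
                     stats::cor(sub$value[cc], tv[cc], method = "spearman")
                   else NA_real_)
    }
  do.call(rbind, out)
}
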