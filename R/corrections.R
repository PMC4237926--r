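#' Baseline emotion scores
#'
#' Even a deliberately neutral face is usually coded with a little emotion;
#' this per-person bias ("baseline emotion expression") contaminates
#' ability scores. The baseline trial's emotion channels are smoothed with
#' the same loess settings as the production data, and each scoring method
#' is applied per emotion channel -- the identical code path used for target
#' scores.
#'
#' @param sessions List of cleaned [fes_session()] objects.
#' @param methods Scoring methods to compute.
#' @param alpha,degree Loess settings (shared with the production scoring).
#' @param cfg A [scoring_config()].
#' @return Data frame: `participant_id`, `emotion`, `method`, `value`.
#'   Participants without a baseline trial are absent (and later excluded
#'   from residualization).
#' @export
baseline_emotion_scores <- function(sessions, methods = SCORE_METHODS,
                                    alpha = 0.13, degree = 2,
                                    cfg = scoring_config()) {
  rows <- list()
  for (s in sessions) {
    b <- Filter(function(t) t$meta$trial_kind == "baseline",
                session_trials(s, "calibration_pre"))
    if (!length(b)) next
    t <- tryCatch(smooth_trial(b[[1]], alpha, degree),
                  error = function(e) NULL)
    if (is.null(t)) next
    for (e in BASIC_EMOTIONS)
      for (m in methods)
        rows[[length(rows) + 1L]] <-
          data.frame(participant_id = s$participant_id, emotion = e,
                     method = m,
                     value = score_trial(t, m, channel = e, cfg = cfg)$value)
  }
  if (!length(rows))
    return(data.frame(participant_id = character(), emotion = character(),
                      method = character(), value = numeric()))
  do.call(rbind, rows)
}

#' Residualize scores on nuisance covariates
#'
#' Ordinary-least-squares residuals of `target` on the covariate(s), with
#' intercept, computed across participants within one
#' emotion x method x half cell. Residuals sum to ~0 and are orthogonal to
#' each covariate. Entries with an incomplete pair are returned as `NA`.
#'
#' @param target Numeric vector of scores (one per participant).
#' @param covariates Numeric vector or matrix of nuisance scores.
#' @param keep_intercept If TRUE, the fitted intercept is added back
#'   (`y - b1*x` instead of the raw residual), preserving the score's
#'   location; default FALSE returns plain residuals.
#' @return Numeric vector of residuals aligned with `target`.
#' @export
#' @examples
#' residualize(c(1, 2, 4), c(0, 1, 2))  # (1/6, -1/3, 1/6)
residualize <- function(target, covariates, keep_intercept = FALSE) {
  X <- as.matrix(covariates)
  cc <- stats::complete.cases(target, X)
  if (sum(cc) < 3)
    stop("need at least 3 complete pairs to residualize")
  for (j in seq_len(ncol(X)))
    if (stats::var(X[cc, j]) == 0)
      stop("zero-variance covariate (column ", j, ")")
  fit <- stats::lm(target ~ X)
  out <- rep(NA_real_, length(target))
  out[cc] <- stats::residuals(fit)
  if (keep_intercept) out <- out + stats::coef(fit)[1]
  out
}

#' Facial-plasticity composite from AU calibration trials
#'
#' Faces differ in how far their action units can move at all; this basic
#' plasticity caps attainable expression intensity independent of ability.
#' Each calibration movement type (except nostril widening) isolates one AU
#' (see [au_calibration_map()]). Per relevant calibration trial the mapped
#' AU channel is loess smoothed and its maximum taken; the maximum of that
#' AU's smoothed series on the neutral trial is subtracted (baseline AU
#' tonus); the per-trial differences are z-standardized across
#' participants, averaged across that AU's trials (up to 4: two repetitions
#' in each calibration task), and the per-AU composites averaged into a
#' single plasticity score.
#'
#' @param sessions List of cleaned [fes_session()] objects.
#' @param alpha,degree Loess settings.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`
#'   for the z-standardization.
#' @return List with `composite` (data frame: participant_id, composite,
#'   trials_used) and `per_au` (long data frame of per-trial differences
#'   and z-scores).
#' @export
plasticity_composite <- function(sessions, alpha = 0.13, degree = 2,
                                 sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  map <- au_calibration_map()
  rows <- list()
  for (s in sessions) {
    base <- Filter(function(t) t$meta$trial_kind == "baseline",
                   session_trials(s, "calibration_pre"))
    if (!length(base)) next
    have_au <- intersect(unname(map), colnames(base[[1]]$codes$values))
    if (!length(have_au)) next
    sb <- smooth_trial(base[[1]], alpha, degree)
    base_max <- vapply(have_au, function(a) {
      y <- sb$codes$values[, a]
      y[sb$codes$missing_mask] <- NA
      maximum_score(y)
    }, 0)
    cache <- new.env(parent = emptyenv())
    for (t in session_trials(s)) {
      kind <- t$meta$trial_kind
      if (!kind %in% names(map)) next
      a <- map[[kind]]
      if (!a %in% colnames(t$codes$values)) next
      st <- tryCatch(smooth_trial(t, alpha, degree, cache),
                     error = function(e) NULL)
      if (is.null(st)) next
      y <- st$codes$values[, a]
      y[st$codes$missing_mask] <- NA
      rows[[length(rows) + 1L]] <-
        data.frame(participant_id = s$participant_id, au = a,
                   task = t$meta$task, trial_kind = kind,
                   repetition = t$meta$repetition,
                   diff = maximum_score(y) - base_max[[a]])
    }
  }
  if (!length(rows)) stop("no usable calibration trials with AU channels")
  d <- do.call(rbind, rows)
  cell <- interaction(d$au, d$task, d$trial_kind, d$repetition, drop = TRUE)
  d$z <- NA_real_
  for (lv in levels(cell)) {
    i <- which(cell == lv)
    x <- d$diff[i]
    mu <- mean(x)
    sdv <- stats::sd(x)
    if (sd_type == "population")
      sdv <- sqrt(mean((x - mu)^2))
    if (is.na(sdv) || sdv == 0)
      stop("zero cross-participant variance for calibration cell ", lv)
    d$z[i] <- (x - mu) / sdv
  }
  per_au <- stats::aggregate(z ~ participant_id + au, data = d, FUN = mean)
  comp <- stats::aggregate(z ~ participant_id, data = per_au, FUN = mean)
  names(comp)[2] <- "composite"
  used <- stats::aggregate(z ~ participant_id, data = d, FUN = length)
  comp$trials_used <- used$z[match(comp$participant_id, used$participant_id)]
  list(composite = comp, per_au = d)
}

#' Score a cohort under the four data treatments
#'
#' Builds the full method x treatment score grid per participant x emotion
#' x half:
#' \enumerate{
#'   \item `untreated` -- scoring applied to the cleaned, unsmoothed data;
#'   \item `loess` -- scoring applied after loess smoothing;
#'   \item `loess_base` -- the loess scores residualized on the
#'     emotion-specific baseline scores (per emotion x method x half cell,
#'     across participants);
#'   \item `loess_base_plast` -- additionally residualized on the facial
#'     plasticity composite (sequentially by default; `mode = "joint"` fits
#'     both covariates in one regression).
#' }
#'
#' @param sessions List of *cleaned* [fes_session()] objects (see
#'   [clean_session()]).
#' @param alpha,degree Loess settings applied to every treatment beyond
#'   `untreated`.
#' @param methods Scoring methods to compute.
#' @param treatments Subset of treatments to compute (later tiers require
#'   the earlier ones and are added automatically).
#' @param mode `"sequential"` (default) or `"joint"` residualization for
#'   the final tier.
#' @param sd_type z-standardization convention for the plasticity
#'   composite.
#' @param keep_intercept Passed to [residualize()].
#' @param cfg A [scoring_config()].
#' @return A [score_table()]; attributes `baseline_scores` and `plasticity`
#'   carry the intermediate products.
#' @export
apply_treatments <- function(sessions, alpha = 0.13, degree = 2,
                             methods = SCORE_METHODS,
                             treatments = TREATMENTS,
                             mode = c("sequential", "joint"),
                             sd_type = "sample", keep_intercept = FALSE,
                             cfg = scoring_config()) {
  mode <- match.arg(mode)
  stopifnot(all(treatments %in% TREATMENTS))
  if ("loess_base_plast" %in% treatments)
    treatments <- union(treatments, "loess_base")
  if ("loess_base" %in% treatments)
    treatments <- union(treatments, "loess")
  rows <- list()
  for (s in sessions) {
    halves <- split_halves(s)
    smoothed <- if (any(c("loess", "loess_base", "loess_base_plast")
                        %in% treatments))
      smooth_session(s, alpha, degree) else NULL
    sm_by_key <- if (!is.null(smoothed))
      stats::setNames(smoothed$trials,
                      vapply(smoothed$trials,
                             function(t) trial_key(t$meta), "")) else NULL
    for (h in 1:2) {
      for (t in halves[[h]]) {
        for (m in methods) {
          if ("untreated" %in% treatments)
            rows[[length(rows) + 1L]] <-
              data.frame(participant_id = s$participant_id,
                         emotion = t$meta$trial_kind, half = h, method = m,
                         treatment = "untreated",
                         value = score_trial(t, m, cfg = cfg)$value)
          if (!is.null(sm_by_key)) {
            st <- sm_by_key[[trial_key(t$meta)]]
            rows[[length(rows) + 1L]] <-
              data.frame(participant_id = s$participant_id,
                         emotion = t$meta$trial_kind, half = h, method = m,
                         treatment = "loess",
                         value = score_trial(st, m, cfg = cfg)$value)
          }
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  base <- NULL
  plast <- NULL
  if ("loess_base" %in% treatments) {
    base <- baseline_emotion_scores(sessions, methods, alpha, degree, cfg)
    tab <- rbind(tab, residual_tier(tab, "loess", "loess_base", base = base,
                                    keep_intercept = keep_intercept))
  }
  if ("loess_base_plast" %in% treatments) {
    plast <- plasticity_composite(sessions, alpha, degree, sd_type)
    src <- if (mode == "sequential") "loess_base" else "loess"
    tab <- rbind(tab, residual_tier(tab, src, "loess_base_plast",
                                    base = if (mode == "joint") base else NULL,
                                    plast = plast$composite,
                                    keep_intercept = keep_intercept))
  }
  tab <- tab[!is.na(tab$value), , drop = FALSE]
  out <- score_table(tab)
  attr(out, "baseline_scores") <- base
  attr(out, "plasticity") <- plast
  attr(out, "alpha") <- alpha
  out
}

trial_key <- function(meta)
  paste(meta$task, meta$trial_index, sep = "#")

## One residualization tier: per emotion x method x half cell across
## participants, target = scores of `src`, covariates = baseline score
## and/or plasticity composite.
residual_tier <- function(tab, src, dst, base = NULL, plast = NULL,
                          keep_intercept = FALSE) {
  out <- list()
  sub <- tab[tab$treatment == src, , drop = FALSE]
  for (e in unique(sub$emotion)) for (m in unique(sub$method))
    for (h in unique(sub$half)) {
      cell <- sub[sub$emotion == e & sub$method == m & sub$half == h, ,
                  drop = FALSE]
      if (!nrow(cell)) next
      X <- NULL
      if (!is.null(base)) {
        b <- base[base$emotion == e & base$method == m, , drop = FALSE]
        X <- cbind(X, b$value[match(cell$participant_id, b$participant_id)])
      }
      if (!is.null(plast))
        X <- cbind(X, plast$composite[match(cell$participant_id,
                                            plast$participant_id)])
      res <- tryCatch(residualize(cell$value, X, keep_intercept),
                      error = function(e2)
                        stop("residualization failed for cell ",
                             paste(e, m, h, sep = "/"), ": ",
                             conditionMessage(e2)))
      out[[length(out) + 1L]] <-
        data.frame(participant_id = cell$participant_id, emotion = e,
                   half = h, method = m, treatment = dst, value = res)
    }
  do.call(rbind, out)
}
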