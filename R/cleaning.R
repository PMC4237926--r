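#' Cleaning configuration
#'
#' Thresholds for trial-level missing-data filtering and iterative
#' multivariate outlier replacement.
#'
#' @param missing_threshold Drop a trial when its missing-frame fraction
#'   strictly exceeds this (default 0.20, i.e. "more than 20 % missing").
#' @param outlier_alpha Upper-tail probability of the chi-square cutoff on
#'   squared Mahalanobis distances (default 0.001, the conventional cutoff
#'   for multivariate outlier screening).
#' @param replacement_k SD multiplier for the replacement value
#'   mean +/- k * SD (default 3).
#' @param replacement_sign `"toward_mean"` (default) replaces low-side
#'   outliers at mean - k*SD; `"plus_only"` always uses mean + k*SD.
#' @param max_iterations Iteration cap for the flag-and-replace loop.
#' @param covariance_ridge Small diagonal regularizer added to the
#'   within-trial covariance so near-constant channels stay invertible.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(missing_threshold = 0.20, outlier_alpha = 0.001,
                            replacement_k = 3,
                            replacement_sign = c("toward_mean", "plus_only"),
                            max_iterations = 20, covariance_ridge = 1e-8) {
  stopifnot(missing_threshold > 0, missing_threshold < 1, replacement_k > 0,
            outlier_alpha > 0, outlier_alpha < 1, max_iterations >= 1)
  structure(list(missing_threshold = missing_threshold,
                 outlier_alpha = outlier_alpha,
                 replacement_k = replacement_k,
                 replacement_sign = match.arg(replacement_sign),
                 max_iterations = as.integer(max_iterations),
                 covariance_ridge = covariance_ridge),
            class = "cleaning_config")
}

#' Trial-level missing-data filter
#'
#' A trial is dropped when the fraction of missing frames strictly exceeds
#' the threshold; exactly at the threshold it is kept. The decision depends
#' only on the missingness mask, never on the code values.
#'
#' @param trial A [fes_trial()].
#' @param cfg A [cleaning_config()].
#' @return `"keep"` or `"drop"`.
#' @export
missingness_filter <- function(trial, cfg = cleaning_config()) {
  n <- n_frames(trial$codes)
  stopifnot(n >= 1)
  frac <- sum(trial$codes$missing_mask) / n
  if (frac > cfg$missing_threshold) "drop" else "keep"
}

## Within-trial mean/covariance of the 7 emotion channels over the given
## frames, with ridge. Neutral is excluded: under the simplex constraint the
## 8-channel covariance is singular by construction.
trial_moments <- function(values, frames, ridge) {
  x <- values[frames, EMOTION_CHANNELS, drop = FALSE]
  mu <- colMeans(x)
  S <- stats::cov(x) + diag(ridge, ncol(x))
  list(x = x, mu = mu, S = S)
}

#' Per-frame squared Mahalanobis distances within a trial
#'
#' Distance of each valid frame's 7-emotion code vector to the within-trial
#' channel mean, using the within-trial covariance (plus a small ridge).
#' Missing frames get `NA`. Used to screen for multivariate outliers across
#' time points within each participant and trial.
#'
#' @param trial A [fes_trial()].
#' @param cfg A [cleaning_config()].
#' @param frames Optional integer subset of frame numbers (1-based) to base
#'   the moments on; defaults to all valid frames.
#' @return Numeric vector, length n_frames, of squared distances (`NA` at
#'   missing frames).
#' @export
mahalanobis_distances <- function(trial, cfg = cleaning_config(),
                                  frames = NULL) {
  ok <- valid_frames(trial$codes)
  if (is.null(frames)) frames <- ok
  p <- length(EMOTION_CHANNELS)
  if (length(frames) < p + 2)
    stop("need at least ", p + 2, " valid frames for Mahalanobis screening")
  m <- trial_moments(trial$codes$values, frames, cfg$covariance_ridge)
  d2 <- tryCatch(
    stats::mahalanobis(trial$codes$values[ok, EMOTION_CHANNELS, drop = FALSE],
                       m$mu, m$S),
    error = function(e) {
      v <- diag(m$S)
      stop("degenerate within-trial covariance; near-constant channel(s): ",
           paste(EMOTION_CHANNELS[v <= 2 * cfg$covariance_ridge],
                 collapse = ", "))
    })
  out <- rep(NA_real_, n_frames(trial$codes))
  out[ok] <- d2
  out
}

#' Iterative multivariate outlier flagging and replacement
#'
#' Flags valid frames whose squared Mahalanobis distance exceeds the
#' chi-square(df = 7) upper-`outlier_alpha` quantile, replaces the offending
#' channel values with the within-trial mean +/- `replacement_k` standard
#' deviations (toward the mean), and repeats -- recomputing the moments while
#' excluding already-flagged frames -- until no frame is flagged or
#' `max_iterations` is hit. After replacing emotion channels the neutral
#' code is reset to 1 minus their sum (clipped at 0, renormalized if
#' needed) so the simplex constraint is preserved.
#'
#' Within a flagged frame, only channels lying beyond mean +/- k*SD
#' univariately are replaced (the ones driving the distance); if none is,
#' the channel with the largest |z| is. This keeps replacements minimal and
#' makes the procedure idempotent at its fixpoint.
#'
#' @param trial A [fes_trial()].
#' @param cfg A [cleaning_config()].
#' @return List with `trial` (cleaned), `log` (data frame: frame, channel,
#'   old, new, iteration), `iterations`, and `converged`.
#' @export
flag_and_replace_outliers <- function(trial, cfg = cleaning_config()) {
  vals <- trial$codes$values
  ok <- valid_frames(trial$codes)
  cutoff <- stats::qchisq(1 - cfg$outlier_alpha, df = length(EMOTION_CHANNELS))
  flagged <- integer()
  log <- list()
  iter <- 0L
  converged <- FALSE
  max_d2 <- numeric()
  while (iter < cfg$max_iterations) {
    iter <- iter + 1L
    base <- setdiff(ok, flagged)
    if (length(base) < length(EMOTION_CHANNELS) + 2) break
    tmp <- trial
    tmp$codes$values <- vals
    d2 <- mahalanobis_distances(tmp, cfg, frames = base)
    max_d2 <- c(max_d2, max(d2[base]))
    new_flags <- intersect(which(d2 > cutoff), base)
    if (!length(new_flags)) { converged <- TRUE; break }
    ## replacement statistics exclude the frames flagged this iteration
    keep <- setdiff(base, new_flags)
    if (length(keep) < length(EMOTION_CHANNELS) + 2) keep <- base
    m <- trial_moments(vals, keep, cfg$covariance_ridge)
    sd_ <- sqrt(pmax(diag(stats::cov(m$x)), 0))
    for (f in new_flags) {
      z <- ifelse(sd_ > 0, (vals[f, EMOTION_CHANNELS] - m$mu) / sd_, 0)
      off <- which(abs(z) > cfg$replacement_k)
      ## A frame can exceed the multivariate cutoff with every channel
      ## inside its univariate band (correlation-driven); such frames are
      ## flagged and excluded from subsequent moments but not modified --
      ## mean +/- k*SD would move an in-band value *away* from the mean.
      if (!length(off)) {
        log[[length(log) + 1L]] <-
          data.frame(frame = f - 1L, channel = NA_character_,
                     old = NA_real_, new = NA_real_, iteration = iter)
        next
      }
      for (j in off) {
        ch <- EMOTION_CHANNELS[j]
        old <- vals[f, ch]
        sgn <- if (cfg$replacement_sign == "plus_only") 1
               else sign(old - m$mu[j])
        new <- m$mu[j] + sgn * cfg$replacement_k * sd_[j]
        new <- min(max(new, 0), 1)  # codes are proportions
        vals[f, ch] <- new
        log[[length(log) + 1L]] <-
          data.frame(frame = f - 1L, channel = ch, old = old, new = new,
                     iteration = iter)
      }
      esum <- sum(vals[f, EMOTION_CHANNELS])
      if (esum <= 1) {
        vals[f, NEUTRAL_CHANNEL] <- 1 - esum
      } else {
        vals[f, EMOTION_CHANNELS] <- vals[f, EMOTION_CHANNELS] / esum
        vals[f, NEUTRAL_CHANNEL] <- 0
      }
    }
    flagged <- c(flagged, new_flags)
  }
  if (!converged && !length(flagged)) converged <- TRUE
  if (!converged && iter >= cfg$max_iterations)
    warning("outlier replacement did not converge within ",
            cfg$max_iterations, " iterations")
  trial$codes$values <- vals
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(frame = integer(), channel = character(), old = numeric(),
               new = numeric(), iteration = integer())
  list(trial = trial, log = log, iterations = iter, converged = converged,
       max_d2_by_iter = max_d2)
}

#' Clean a session
#'
#' Removes artifact-flagged trials, applies the trial-level missing-data
#' filter, then runs iterative outlier replacement on each surviving trial.
#'
#' @param s A [fes_session()].
#' @param cfg A [cleaning_config()].
#' @return List with `session` (cleaned), `dropped` (data frame of removed
#'   trials and reasons) and `replacement_log`.
#' @export
clean_session <- function(s, cfg = cleaning_config()) {
  kept <- list()
  dropped <- list()
  logs <- list()
  for (t in s$trials) {
    reason <- NULL
    if (t$artifact_flag) reason <- "artifact"
    else if (missingness_filter(t, cfg) == "drop") reason <- "missingness"
    if (!is.null(reason)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(participant_id = t$meta$participant_id,
                   task = t$meta$task, trial_index = t$meta$trial_index,
                   trial_kind = t$meta$trial_kind, reason = reason)
      next
    }
    if (length(valid_frames(t$codes)) >= length(EMOTION_CHANNELS) + 2) {
      r <- flag_and_replace_outliers(t, cfg)
      t <- r$trial
      if (nrow(r$log)) {
        r$log$participant_id <- t$meta$participant_id
        r$log$task <- t$meta$task
        r$log$trial_index <- t$meta$trial_index
        logs[[length(logs) + 1L]] <- r$log
      }
    }
    kept[[length(kept) + 1L]] <- t
  }
  list(session = fes_session(s$participant_id, kept),
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(participant_id = character(), task = character(),
                    trial_index = integer(), trial_kind = character(),
                    reason = character()),
       replacement_log = if (length(logs)) do.call(rbind, logs) else NULL)
}
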