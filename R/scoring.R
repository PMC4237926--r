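#' Scoring configuration
#'
#' @param geometric_zero_floor Small positive floor applied to code values
#'   before taking logs in the geometric mean (expression proportions can be
#'   exactly 0; default 1e-9 keeps the arithmetic >= geometric ordering
#'   while avoiding a hard zero from a single frame).
#' @param methods Which scoring methods to compute.
#' @return List of class `scoring_config`.
#' @export
scoring_config <- function(geometric_zero_floor = 1e-9,
                           methods = SCORE_METHODS) {
  stopifnot(geometric_zero_floor > 0, all(methods %in% SCORE_METHODS))
  structure(list(geometric_zero_floor = geometric_zero_floor,
                 methods = methods),
            class = "scoring_config")
}

#' Trial scoring methods
#'
#' Four competing summaries of a trial's target-emotion series `y` (valid
#' frames only):
#' \describe{
#'   \item{arithmetic_mean}{`sum(y) / n`.}
#'   \item{geometric_mean}{`(prod y)^(1/n)`, computed in the log domain with
#'     values below the floor raised to it; less sensitive to the range of
#'     the observations than the arithmetic mean.}
#'   \item{average_auc}{linear trapezoidal area under the series divided by
#'     the spanned width, putting the area on the code scale. With complete
#'     data this equals the arithmetic mean with the two endpoint frames
#'     half-weighted; across gaps the trapezoid spans the two nearest valid
#'     frames with the index gap as width.}
#'   \item{maximum_score}{the highest value across the trial.}
#' }
#'
#' @param y Numeric series; `NA` entries are treated as missing frames.
#' @param eps Floor for the geometric mean.
#' @return A single score. `geometric_mean` carries an attribute
#'   `n_floored`, the number of values raised to the floor.
#' @name trial_scores
NULL

#' @rdname trial_scores
#' @export
arithmetic_mean <- function(y) {
  y <- y[!is.na(y)]
  if (!length(y)) stop("no valid frames")
  sum(y) / length(y)
}

#' @rdname trial_scores
#' @export
geometric_mean <- function(y, eps = 1e-9) {
  y <- y[!is.na(y)]
  if (!length(y)) stop("no valid frames")
  if (any(y < 0)) stop("geometric mean undefined for negative values")
  floored <- sum(y < eps)
  g <- exp(mean(log(pmax(y, eps))))
  attr(g, "n_floored") <- floored
  g
}

#' @rdname trial_scores
#' @export
average_auc <- function(y) {
  idx <- which(!is.na(y))
  if (length(idx) < 2) stop("need at least 2 valid frames for average AUC")
  v <- y[idx]
  widths <- diff(idx)
  areas <- (v[-length(v)] + v[-1]) / 2 * widths
  sum(areas) / sum(widths)
}

#' @rdname trial_scores
#' @export
maximum_score <- function(y) {
  y <- y[!is.na(y)]
  if (!length(y)) stop("no valid frames")
  max(y)
}

score_fun <- function(method, cfg = scoring_config()) {
  switch(method,
         arith = arithmetic_mean,
         geom = function(y) as.numeric(geometric_mean(y, cfg$geometric_zero_floor)),
         avg_auc = average_auc,
         max = maximum_score,
         stop("unknown scoring method: ", method))
}

#' Score one trial on its target emotion channel
#'
#' For production trials the target is the trial's own emotion label; for
#' the baseline (neutral) trial any named emotion channel can be scored.
#' The chosen method is applied over the valid frames of that channel.
#'
#' @param trial A [fes_trial()].
#' @param method `"arith"`, `"geom"`, `"avg_auc"` or `"max"`.
#' @param channel Target channel; defaults to the trial's emotion label.
#' @param cfg A [scoring_config()].
#' @return Named list: `participant_id`, `emotion`, `method`, `value`.
#' @export
score_trial <- function(trial, method, channel = NULL,
                        cfg = scoring_config()) {
  method <- match.arg(method, SCORE_METHODS)
  if (is.null(channel)) {
    if (!trial$meta$trial_kind %in% BASIC_EMOTIONS)
      stop("trial has no target emotion; supply `channel`")
    channel <- trial$meta$trial_kind
  }
  if (!channel %in% colnames(trial$codes$values))
    stop("target channel absent: ", channel)
  y <- trial$codes$values[, channel]
  y[trial$codes$missing_mask] <- NA_real_
  list(participant_id = trial$meta$participant_id, emotion = channel,
       method = method, value = score_fun(method, cfg)(y))
}
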