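#' Frame-level expression code matrix
#'
#' Container for one trial's time-by-channel code matrix as emitted by an
#' automated expression coder: one row per video frame, one column per
#' channel. Emotion + neutral channels are proportions in [0, 1] whose
#' per-frame sum is 1 (the coder's simplex constraint); AU channels are
#' unconstrained nonnegative intensities. Frames are 0-based, frame i sits at
#' time i / frame_rate seconds.
#'
#' @param values Numeric matrix, n_frames x n_channels, with channel labels
#'   as column names. Rows for missing frames may be NA.
#' @param missing_mask Logical vector of length n_frames; TRUE marks frames
#'   the coder could not read. Defaults to rows with any NA among the
#'   simplex channels.
#' @param frame_rate Frames per second (default 25).
#' @param validate Check the simplex and range invariants (default TRUE).
#' @param tol Tolerance for the per-frame simplex sum check.
#' @return An object of class `frame_codes`.
#' @export
frame_codes <- function(values, missing_mask = NULL, frame_rate = 25,
                        validate = TRUE, tol = 1e-6) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("`values` must have channel labels as column names")
  simplex <- intersect(SIMPLEX_CHANNELS, colnames(values))
  if (!all(SIMPLEX_CHANNELS %in% colnames(values)))
    stop("missing simplex channel(s): ",
         paste(setdiff(SIMPLEX_CHANNELS, colnames(values)), collapse = ", "))
  if (is.null(missing_mask))
    missing_mask <- apply(values[, simplex, drop = FALSE], 1,
                          function(r) anyNA(r))
  missing_mask <- as.logical(missing_mask)
  if (length(missing_mask) != nrow(values))
    stop("missing_mask length must equal the number of frames")
  x <- structure(list(values = values, missing_mask = missing_mask,
                      frame_rate = frame_rate),
                 class = "frame_codes")
  if (validate) {
    v <- validate_frame_codes(x, tol = tol)
    if (length(v)) stop("invalid frame codes: ", paste(v, collapse = "; "))
  }
  x
}

#' @export
print.frame_codes <- function(x, ...) {
  cat(sprintf("<frame_codes> %d frames x %d channels @ %g fps, %d missing\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              sum(x$missing_mask)))
  invisible(x)
}

n_frames <- function(fc) nrow(fc$values)
valid_frames <- function(fc) which(!fc$missing_mask)

## Violations of the coder's output contract, as messages (empty if clean).
validate_frame_codes <- function(fc, tol = 1e-6) {
  out <- character()
  v <- fc$values[, SIMPLEX_CHANNELS, drop = FALSE]
  ok <- !fc$missing_mask
  if (any(ok)) {
    vv <- v[ok, , drop = FALSE]
    if (anyNA(vv))
      out <- c(out, paste0("NA code on unmasked frame(s) ",
                           fmt_idx(which(ok)[apply(vv, 1, anyNA)])))
    bad_rng <- which(apply(vv, 1, function(r) any(r < -tol | r > 1 + tol, na.rm = TRUE)))
    if (length(bad_rng))
      out <- c(out, paste0("emotion/neutral code outside [0,1] at frame(s) ",
                           fmt_idx(which(ok)[bad_rng])))
    s <- rowSums(vv)
    bad_sum <- which(abs(s - 1) > tol & !is.na(s))
    if (length(bad_sum))
      out <- c(out, paste0("emotion+neutral codes do not sum to 1 at frame(s) ",
                           fmt_idx(which(ok)[bad_sum])))
  }
  au <- setdiff(colnames(fc$values), SIMPLEX_CHANNELS)
  if (length(au)) {
    a <- fc$values[ok, au, drop = FALSE]
    if (length(a) && any(a < -tol, na.rm = TRUE))
      out <- c(out, "negative AU intensity")
  }
  out
}

fmt_idx <- function(i) paste(utils::head(i - 1L, 5), collapse = ",")  # 0-based

#' Trial metadata
#'
#' @param participant_id Opaque participant identifier.
#' @param task One of `"calibration_pre"`, `"production"`,
#'   `"calibration_post"`.
#' @param trial_index Position of the trial within its task (1-based).
#' @param trial_kind `"baseline"`, `"movement_1"`..`"movement_6"`, or one of
#'   the six basic emotion labels.
#' @param repetition 1 or 2.
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(participant_id, task, trial_index, trial_kind,
                       repetition = 1L) {
  task <- match.arg(task, TASKS)
  trial_kind <- match.arg(trial_kind, TRIAL_KINDS)
  if (trial_kind == "baseline" && task != "calibration_pre")
    stop("baseline trials occur only in calibration_pre")
  if (trial_kind %in% MOVEMENT_KINDS && task == "production")
    stop("movement trials occur only in calibration tasks")
  if (trial_kind %in% BASIC_EMOTIONS && task != "production")
    stop("emotion trials occur only in production")
  structure(list(participant_id = as.character(participant_id), task = task,
                 trial_index = as.integer(trial_index),
                 trial_kind = trial_kind,
                 repetition = as.integer(repetition)),
            class = "trial_meta")
}

#' A single expression trial
#'
#' @param meta A [trial_meta()] object.
#' @param codes A [frame_codes()] matrix.
#' @param artifact_flag TRUE when the trial was visually flagged for an
#'   obscuring artifact (glasses, hair, ...). Flagged trials are excluded
#'   from all scoring; the flag is an input, never computed here.
#' @return An object of class `fes_trial`.
#' @export
fes_trial <- function(meta, codes, artifact_flag = FALSE) {
  stopifnot(inherits(meta, "trial_meta"), inherits(codes, "frame_codes"))
  structure(list(meta = meta, codes = codes,
                 artifact_flag = isTRUE(artifact_flag)),
            class = "fes_trial")
}

#' @export
print.fes_trial <- function(x, ...) {
  cat(sprintf("<trial> %s %s #%d (%s, rep %d)%s\n", x$meta$participant_id,
              x$meta$task, x$meta$trial_index, x$meta$trial_kind,
              x$meta$repetition,
              if (x$artifact_flag) " [artifact]" else ""))
  invisible(x)
}

#' One participant's session
#'
#' A complete session mirrors the three-task design: a pre-calibration task
#' (1 baseline + 6 movements x 2 = 13 trials), a production task (6 emotions
#' x 2 = 12 trials), and a post-calibration task (6 movements x 2 = 12
#' trials).
#'
#' @param participant_id Participant identifier.
#' @param trials List of [fes_trial()] objects.
#' @return An object of class `fes_session`.
#' @export
fes_session <- function(participant_id, trials) {
  stopifnot(all(vapply(trials, inherits, TRUE, "fes_trial")))
  ord <- order(match(vapply(trials, function(t) t$meta$task, ""), TASKS),
               vapply(trials, function(t) t$meta$trial_index, 1L))
  structure(list(participant_id = as.character(participant_id),
                 trials = trials[ord]),
            class = "fes_session")
}

#' @export
print.fes_session <- function(x, ...) {
  tk <- vapply(x$trials, function(t) t$meta$task, "")
  cat(sprintf("<session> %s: %d trials (%s)\n", x$participant_id,
              length(x$trials),
              paste(sprintf("%s=%d", TASKS, tabulate(match(tk, TASKS), 3)),
                    collapse = ", ")))
  invisible(x)
}

session_trials <- function(s, task = NULL, drop_artifacts = TRUE) {
  tr <- s$trials
  if (drop_artifacts)
    tr <- Filter(function(t) !t$artifact_flag, tr)
  if (!is.null(task))
    tr <- Filter(function(t) t$meta$task == task, tr)
  tr
}

#' Validate a session against the study-design invariants
#'
#' Reports (rather than errors on) violations: simplex sums off 1, codes
#' outside [0, 1], trial counts per task, and production completeness
#' (exactly two trials per basic emotion).
#'
#' @param s A [fes_session()].
#' @param tol Simplex-sum tolerance.
#' @return Character vector of violation messages; empty iff the session
#'   satisfies every invariant.
#' @export
validate_session <- function(s, tol = 1e-6) {
  out <- character()
  for (t in s$trials) {
    v <- validate_frame_codes(t$codes, tol = tol)
    if (length(v))
      out <- c(out, sprintf("%s/%s#%d: %s", t$meta$task, t$meta$trial_kind,
                            t$meta$trial_index, v))
  }
  tk <- vapply(s$trials, function(t) t$meta$task, "")
  counts <- c(calibration_pre = 13L, production = 12L, calibration_post = 12L)
  for (task in TASKS)
    if (sum(tk == task) != counts[[task]])
      out <- c(out, sprintf("%s incomplete: %d trials (expected %d)", task,
                            sum(tk == task), counts[[task]]))
  prod <- vapply(s$trials[tk == "production"],
                 function(t) t$meta$trial_kind, "")
  for (e in BASIC_EMOTIONS)
    if (sum(prod == e) != 2L)
      out <- c(out, sprintf("production incomplete: %d %s trial(s)",
                            sum(prod == e), e))
  out
}
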