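## Delimited-file plumbing: session frame tables and long-format score tables.
## Numbers are written with %.17g so a write -> read round trip is lossless.

META_COLS <- c("participant_id", "task", "trial_index", "trial_kind",
               "repetition", "artifact", "frame")

#' Read one participant's session from a delimited frame table
#'
#' Expects one row per video frame with the metadata columns
#' `participant_id, task, trial_index, trial_kind, repetition, artifact,
#' frame` and one column per code channel. Column names in the file can be
#' mapped to the canonical vocabulary through `channel_map` (covers coders
#' that label columns differently). Frames with any unreadable/blank simplex
#' cell are missing-masked; valid frames must satisfy the simplex constraint
#' or reading fails, naming the offending frames.
#'
#' @param path File path.
#' @param channel_map Named character vector, canonical label -> file column
#'   name, for channels whose file names differ (e.g.
#'   `c(happiness = "joy")`).
#' @param frame_rate Frames per second of the recording (default 25).
#' @param sep Field delimiter (default `","`).
#' @param tol Simplex-sum tolerance applied to valid frames.
#' @return A [fes_session()].
#' @export
read_session <- function(path, channel_map = NULL, frame_rate = 25,
                         sep = ",", tol = 1e-6) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(channel_map))
    for (canon in names(channel_map)) {
      j <- match(channel_map[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
  need <- c(META_COLS, SIMPLEX_CHANNELS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing required column(s): ",
         paste(miss, collapse = ", "))
  pid <- unique(df$participant_id)
  if (length(pid) != 1)
    stop("format error: expected a single participant per file, found ",
         length(pid))
  chan <- c(SIMPLEX_CHANNELS,
            grep("^AU", setdiff(names(df), c(META_COLS, SIMPLEX_CHANNELS)),
                 value = TRUE))
  key <- interaction(df$task, df$trial_index, drop = TRUE)
  trials <- lapply(split(df, key), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    vals <- as.matrix(d[, chan, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- NULL
    ## AU channels not recorded for this trial (all blank) are dropped
    au <- setdiff(chan, SIMPLEX_CHANNELS)
    absent <- au[colSums(!is.na(vals[, au, drop = FALSE])) == 0]
    if (length(absent))
      vals <- vals[, setdiff(chan, absent), drop = FALSE]
    mask <- apply(vals[, SIMPLEX_CHANNELS, drop = FALSE], 1, anyNA)
    fc <- frame_codes(vals, missing_mask = mask, frame_rate = frame_rate,
                      validate = FALSE)
    v <- validate_frame_codes(fc, tol = tol)
    if (length(v))
      stop(sprintf("validation error in %s trial %d: %s", d$task[1],
                   d$trial_index[1], paste(v, collapse = "; ")))
    fes_trial(trial_meta(d$participant_id[1], d$task[1], d$trial_index[1],
                         d$trial_kind[1], d$repetition[1]),
              fc, artifact_flag = as.logical(d$artifact[1]))
  })
  fes_session(pid, unname(trials))
}

#' Write a session to the delimited frame-table format read by
#' [read_session()]
#'
#' Masked frames are written with blank code cells. Numeric cells carry full
#' double precision so the round trip is exact.
#'
#' @param s A [fes_session()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path, sep = ",") {
  all_chan <- unique(unlist(lapply(s$trials,
                                   function(t) colnames(t$codes$values))))
  all_chan <- c(SIMPLEX_CHANNELS, setdiff(all_chan, SIMPLEX_CHANNELS))
  rows <- lapply(s$trials, function(t) {
    v <- t$codes$values
    miss_chan <- setdiff(all_chan, colnames(v))
    if (length(miss_chan)) {
      pad <- matrix(NA_real_, nrow(v), length(miss_chan),
                    dimnames = list(NULL, miss_chan))
      v <- cbind(v, pad)
    }
    v <- v[, all_chan, drop = FALSE]
    n <- nrow(v)
    out <- data.frame(participant_id = t$meta$participant_id,
                      task = t$meta$task, trial_index = t$meta$trial_index,
                      trial_kind = t$meta$trial_kind,
                      repetition = t$meta$repetition,
                      artifact = t$artifact_flag,
                      frame = seq_len(n) - 1L,
                      stringsAsFactors = FALSE)
    num <- v
    num[t$codes$missing_mask, ] <- NA_real_
    cbind(out, as.data.frame(num))
  })
  df <- do.call(rbind, rows)
  for (j in setdiff(names(df), c(META_COLS, "artifact")))
    if (is.double(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), "", sprintf("%.17g", df[[j]]))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score tables
#'
#' Long-format grid of scores: one row per
#' (participant, emotion, half, method, treatment). Untreated and
#' loess-smoothed values are proportions in [0, 1]; residualized treatments
#' may be negative.
#'
#' @param df Data frame with columns `participant_id, emotion, half, method,
#'   treatment, value`.
#' @return The data frame with class `score_table`, checked for key
#'   uniqueness.
#' @export
score_table <- function(df) {
  need <- c("participant_id", "emotion", "half", "method", "treatment",
            "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("score table missing column(s): ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(df[need[1:5]], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate score-table key(s), e.g.: ",
         gsub("\r", "/", key[anyDuplicated(key)][1]))
  structure(df[need], class = c("score_table", "data.frame"))
}

#' @export
print.score_table <- function(x, n = 8, ...) {
  cat(sprintf("<score_table> %d records, %d participants, treatments: %s\n",
              nrow(x), length(unique(x$participant_id)),
              paste(unique(x$treatment), collapse = ", ")))
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more records\n")
  invisible(x)
}

#' Write a score table to CSV
#'
#' One row per record in a stable column order; read-back with
#' [read_scores()] reproduces the table exactly.
#'
#' @param table A [score_table()] (or coercible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path) {
  table <- score_table(as.data.frame(table))
  if (!nrow(table)) stop("empty score table")
  df <- as.data.frame(table)
  df$value <- sprintf("%.17g", df$value)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df$half <- as.integer(df$half)
  score_table(df)
}
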