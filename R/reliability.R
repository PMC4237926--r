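#' Split the production trials into two parallel halves
#'
#' One trial per emotion in each half: the first surviving occurrence of
#' each emotion (by trial order) goes to half 1, the second to half 2.
#' Emotions whose second trial was removed by cleaning contribute to half 1
#' only, and that participant drops out of the reliability correlation for
#' that emotion.
#'
#' @param s A [fes_session()] (cleaned).
#' @return List of two lists of trials, `half1` and `half2`.
#' @export
split_halves <- function(s) {
  prod <- session_trials(s, "production")
  h1 <- list(); h2 <- list()
  seen <- character()
  for (t in prod[order(vapply(prod, function(t) t$meta$trial_index, 1L))]) {
    e <- t$meta$trial_kind
    if (e %in% seen) h2[[length(h2) + 1L]] <- t
    else { h1[[length(h1) + 1L]] <- t; seen <- c(seen, e) }
  }
  list(half1 = h1, half2 = h2)
}

cell_frame <- function(table) {
  df <- as.data.frame(table)
  cells <- unique(df[c("emotion", "method", "treatment")])
  rownames(cells) <- NULL
  cells
}

#' Split-half reliability of the score grid
#'
#' Pearson correlation, across participants, between first-half and
#' second-half scores for every emotion x method x treatment cell
#' (pairwise-complete). Cells with fewer than 3 complete pairs are marked
#' unavailable (`NA` with `n` reported).
#'
#' @param table A [score_table()] containing both halves.
#' @return Data frame: emotion, method, treatment, n, r.
#' @export
split_half_reliability <- function(table) {
  cells <- cell_frame(table)
  out <- cells
  out$n <- 0L
  out$r <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sub <- table[table$emotion == cells$emotion[i] &
                 table$method == cells$method[i] &
                 table$treatment == cells$treatment[i], , drop = FALSE]
    w <- stats::reshape(sub[c("participant_id", "half", "value")],
                        direction = "wide", idvar = "participant_id",
                        timevar = "half")
    x <- w$value.1; y <- w$value.2
    cc <- stats::complete.cases(x, y)
    out$n[i] <- sum(cc)
    if (sum(cc) >= 3) out$r[i] <- stats::cor(x[cc], y[cc])
  }
  out
}

#' Correlation of each treatment's scores with the untreated scores
#'
#' Pearson r across participants between a treatment's scores and the
#' untreated scores of the same emotion, method and half; halves are then
#' averaged into one r per cell (both per-half values are returned).
#'
#' @param table A [score_table()] containing the untreated tier.
#' @return Data frame: emotion, method, treatment, half, n, r.
#' @export
correlation_with_untreated <- function(table) {
  if (!"untreated" %in% table$treatment)
    stop("untreated tier absent from score table")
  un <- table[table$treatment == "untreated", , drop = FALSE]
  out <- list()
  for (tr in setdiff(unique(table$treatment), "untreated")) {
    sub <- table[table$treatment == tr, , drop = FALSE]
    for (e in unique(sub$emotion)) for (m in unique(sub$method))
      for (h in unique(sub$half)) {
        a <- sub[sub$emotion == e & sub$method == m & sub$half == h, ]
        b <- un[un$emotion == e & un$method == m & un$half == h, ]
        v <- b$value[match(a$participant_id, b$participant_id)]
        cc <- stats::complete.cases(a$value, v)
        out[[length(out) + 1L]] <-
          data.frame(emotion = e, method = m, treatment = tr, half = h,
                     n = sum(cc),
                     r = if (sum(cc) >= 3) stats::cor(a$value[cc], v[cc])
                         else NA_real_)
      }
  }
  do.call(rbind, out)
}

#' Sample-level summary of the score grid
#'
#' Mean and SD across participants per emotion x method x treatment cell,
#' computed on the first production half (the half used for descriptive
#' reporting). Single-participant cells get `NA` SD.
#'
#' @param table A [score_table()].
#' @param half Which half to summarize (default 1).
#' @return Data frame: emotion, method, treatment, n, mean, sd.
#' @export
sample_summary <- function(table, half = 1) {
  if (!nrow(table)) stop("empty score table")
  sub <- table[table$half == half, , drop = FALSE]
  cells <- cell_frame(sub)
  cells$n <- NA_integer_; cells$mean <- NA_real_; cells$sd <- NA_real_
  for (i in seq_len(nrow(cells))) {
    v <- sub$value[sub$emotion == cells$emotion[i] &
                   sub$method == cells$method[i] &
                   sub$treatment == cells$treatment[i]]
    v <- v[!is.na(v)]
    cells$n[i] <- length(v)
    cells$mean[i] <- mean(v)
    cells$sd[i] <- if (length(v) >= 2) stats::sd(v) else NA_real_
  }
  cells
}

#' Correlation of baseline emotion with target emotion scores
#'
#' For each emotion x method: Pearson r across participants between the
#' baseline score (smoothed neutral trial) and the loess-smoothed target
#' score (half 1). High values identify emotions whose ability scores are
#' strongly contaminated by the resting face.
#'
#' @param table A [score_table()] with the `loess` tier.
#' @param baseline Data frame from [baseline_emotion_scores()] (defaults to
#'   the attribute stored by [apply_treatments()]).
#' @param half Production half to use (default 1).
#' @return Data frame: emotion, method, n, r.
#' @export
baseline_target_correlations <- function(table, baseline = NULL, half = 1) {
  if (is.null(baseline)) baseline <- attr(table, "baseline_scores")
  if (is.null(baseline)) stop("no baseline scores supplied")
  sub <- table[table$treatment == "loess" & table$half == half, ]
  out <- list()
  for (e in unique(sub$emotion)) for (m in unique(sub$method)) {
    a <- sub[sub$emotion == e & sub$method == m, ]
    b <- baseline[baseline$emotion == e & baseline$method == m, ]
    v <- b$value[match(a$participant_id, b$participant_id)]
    cc <- stats::complete.cases(a$value, v)
    out[[length(out) + 1L]] <-
      data.frame(emotion = e, method = m, n = sum(cc),
                 r = if (sum(cc) >= 3) stats::cor(a$value[cc], v[cc])
                     else NA_real_)
  }
  do.call(rbind, out)
}

#' Assemble the full reliability report
#'
#' Combines [sample_summary()], [correlation_with_untreated()],
#' [split_half_reliability()] and [baseline_target_correlations()] into the
#' report structure used for rendering: per emotion x method x treatment
#' the half-1 mean and SD, the correlation with the untreated scores, and
#' the split-half reliability; plus the baseline-vs-target correlations per
#' emotion x method.
#'
#' @param table A [score_table()] from [apply_treatments()].
#' @return Object of class `reliability_table` with elements `summary` and
#'   `baseline_target`.
#' @export
reliability_report <- function(table) {
  sm <- sample_summary(table, half = 1)
  rel <- split_half_reliability(table)
  sm$r_split_half <- rel$r[match(
    paste(sm$emotion, sm$method, sm$treatment),
    paste(rel$emotion, rel$method, rel$treatment))]
  cu <- correlation_with_untreated(table)
  cu1 <- cu[cu$half == 1, ]
  sm$r_with_untreated <- cu1$r[match(
    paste(sm$emotion, sm$method, sm$treatment),
    paste(cu1$emotion, cu1$method, cu1$treatment))]
  bt <- tryCatch(baseline_target_correlations(table),
                 error = function(e) NULL)
  structure(list(summary = sm, baseline_target = bt),
            class = "reliability_table")
}

#' @export
print.reliability_table <- function(x, ...) {
  cat("<reliability_table>\n")
  print(utils::head(x$summary, 12))
  if (nrow(x$summary) > 12) cat("...", nrow(x$summary), "cells total\n")
  invisible(x)
}
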