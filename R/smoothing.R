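## Loess (locally weighted polynomial regression) for equally spaced frame
## series, written so the smoother matrix, its trace (effective parameters)
## and the fit indices used for bandwidth selection are available exactly.
## stats::loess() is deliberately not used here: selection needs the exact
## smoother trace on masked series, and tests cross-check this code against
## both an independent brute-force oracle and stats::loess.

#' Build the linear smoother for a loess fit
#'
#' For each output frame the local neighbourhood is the `q = ceiling(alpha *
#' n)` valid frames nearest by index distance; neighbours are tricube
#' weighted, `w = (1 - (d/dmax)^3)^3`, and a degree-`degree` polynomial is
#' fitted by weighted least squares. The result is the n_frames x n_valid
#' matrix `L` with fitted = `L %*% y[valid]`, plus the trace of the smoother
#' restricted to the valid frames (the effective number of parameters).
#'
#' Because the farthest included neighbour gets exact weight zero, `q` must
#' be at least `degree + 2` for the local system to be determined.
#'
#' @param valid_idx Integer positions (1-based) of the valid frames.
#' @param n_out Total number of frames to predict at (missing frames are
#'   predicted from their neighbours).
#' @param alpha Smoothing parameter in (0, 1]: fraction of valid frames in
#'   each local neighbourhood.
#' @param degree Local polynomial degree, 1 (linear) or 2 (quadratic).
#' @return List with `L` and `trace`.
#' @keywords internal
loess_operator <- function(valid_idx, n_out, alpha, degree = 2) {
  m <- length(valid_idx)
  if (m < degree + 3) stop("too few valid observations for loess")
  q <- ceiling(alpha * m)
  if (q > m) q <- m
  if (q < degree + 2)
    stop(sprintf(
      "smoothing parameter %.3g gives a %d-point neighbourhood; need >= %d",
      alpha, q, degree + 2))
  p <- degree + 1L
  L <- matrix(0, n_out, m)
  for (i in seq_len(n_out)) {
    d <- abs(valid_idx - i)
    o <- order(d)[seq_len(q)]           # stable: ties broken by index
    dd <- d[o]
    dmax <- dd[q]
    w <- if (dmax == 0) rep(1, q) else (1 - (dd / dmax)^3)^3
    dx <- valid_idx[o] - i
    X <- matrix(1, q, p)
    if (degree >= 1) X[, 2] <- dx
    if (degree >= 2) X[, 3] <- dx * dx
    A <- crossprod(X, w * X)
    B <- t(X * w)
    lrow <- tryCatch(solve(A, B)[1L, ],
                     error = function(e) (MASS::ginv(A) %*% B)[1L, ])
    L[i, o] <- lrow
  }
  trace <- sum(L[cbind(valid_idx, seq_len(m))])
  list(L = L, trace = trace)
}

#' Loess fit of one frame series
#'
#' Smooths a single channel's time series with locally weighted polynomial
#' regression (tricube weights, index-distance neighbourhoods). Missing
#' frames (`NA`) are excluded from the design but still receive a fitted
#' value from their neighbours.
#'
#' @param y Numeric series (one value per frame; `NA` = missing).
#' @param alpha Smoothing parameter in (0, 1]: the fraction of observations
#'   entering each local fit. Larger values give smoother curves.
#' @param degree Local polynomial degree, 1 or 2 (default 2; a quadratic
#'   protects against flattening local maxima and minima).
#' @param op Optional precomputed [loess_operator()] for this missingness
#'   pattern (used to share work across channels of a trial).
#' @return Object of class `loess_fit`: `fitted` (length of `y`), `alpha`,
#'   `degree`, `trace_L` (smoother trace over valid frames), `rss`
#'   (residual sum of squares over valid frames), `n` (valid frames used).
#' @export
#' @examples
#' y <- sin(seq(0, pi, length.out = 50)) + rnorm(50, sd = 0.05)
#' f <- loess_fit(y, alpha = 0.3)
#' f$trace_L
loess_fit <- function(y, alpha, degree = 2, op = NULL) {
  stopifnot(alpha > 0, alpha <= 1, degree %in% 1:2)
  valid <- which(!is.na(y))
  if (!length(valid)) stop("all-missing series")
  if (length(valid) < degree + 3)
    stop("need at least ", degree + 3, " valid observations")
  if (is.null(op)) op <- loess_operator(valid, length(y), alpha, degree)
  fitted <- as.numeric(op$L %*% y[valid])
  rss <- sum((y[valid] - fitted[valid])^2)
  structure(list(fitted = fitted, alpha = alpha, degree = degree,
                 trace_L = op$trace, rss = rss, n = length(valid)),
            class = "loess_fit")
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf(
    "<loess_fit> alpha=%.3g degree=%d n=%d trace_L=%.2f rss=%.4g\n",
    x$alpha, x$degree, x$n, x$trace_L, x$rss))
  invisible(x)
}

#' Fit indices for smoothing-parameter selection
#'
#' With `sigma2 = rss / n` and `tr` the smoother trace:
#' AIC `= log sigma2 + 2 tr / n`; bias-corrected AIC (AICc)
#' `= log sigma2 + 1 + 2 (tr + 1) / (n - tr - 2)`; generalized
#' cross-validation (GCV) `= sigma2 / (1 - tr/n)^2`. Each index is minimized
#' over the candidate smoothing parameters; only the location of the
#' minimum matters, so the per-observation scaling is immaterial to
#' selection.
#'
#' @param fit A [loess_fit()].
#' @return List of class `fit_indices` with `aic`, `aicc`, `gcv`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "loess_fit"))
  n <- fit$n
  tr <- fit$trace_L
  if (tr >= n - 2)
    stop("AICc undefined: smoother trace ", round(tr, 2), " >= n - 2")
  if (fit$rss <= 0)
    stop("degenerate fit: zero residual sum of squares")
  s2 <- fit$rss / n
  structure(list(aic = log(s2) + 2 * tr / n,
                 aicc = log(s2) + 1 + 2 * (tr + 1) / (n - tr - 2),
                 gcv = s2 / (1 - tr / n)^2),
            class = "fit_indices")
}

#' Grid search for the smoothing parameter with a consensus rule
#'
#' Runs loess over a grid of smoothing parameters (default 0.01 to 1.00 in
#' steps of 0.01) on each supplied target-emotion series, picks the
#' grid value minimizing the chosen fit index per trial, and takes the mode
#' of the per-trial winners as the consensus (ties go to the smaller
#' value). Grid values whose neighbourhood would be underdetermined, or for
#' which the index is undefined, are skipped.
#'
#' @param series List of numeric frame series (typically the target-emotion
#'   channel of each selection trial).
#' @param grid Candidate smoothing parameters.
#' @param degree Local polynomial degree (default 2).
#' @param index_used Fit index to minimize: `"aicc"` (default, most
#'   protective against overfitting), `"aic"`, or `"gcv"`.
#' @return Object of class `selection_result`: `per_trial_best`, `consensus`,
#'   `grid`, `index_used`, and `table` (long data frame of index values).
#' @export
select_smoothing_parameter <- function(series, grid = seq(0.01, 1, by = 0.01),
                                       degree = 2,
                                       index_used = c("aicc", "aic", "gcv")) {
  index_used <- match.arg(index_used)
  if (!length(series)) stop("no series supplied")
  rows <- list()
  best <- numeric(length(series))
  for (k in seq_along(series)) {
    y <- series[[k]]
    vals <- rep(NA_real_, length(grid))
    for (g in seq_along(grid)) {
      f <- tryCatch(loess_fit(y, grid[g], degree), error = function(e) NULL)
      if (is.null(f)) next
      ix <- tryCatch(fit_indices(f), error = function(e) NULL)
      if (is.null(ix)) next
      vals[g] <- ix[[index_used]]
      rows[[length(rows) + 1L]] <-
        data.frame(trial = k, alpha = grid[g], aic = ix$aic, aicc = ix$aicc,
                   gcv = ix$gcv)
    }
    if (all(is.na(vals)))
      stop("no admissible smoothing parameter for trial ", k)
    best[k] <- grid[which.min(vals)]  # which.min: first (smallest) on ties
  }
  structure(list(per_trial_best = best, consensus = consensus_alpha(best),
                 grid = grid,
                 index_used = index_used, table = do.call(rbind, rows)),
            class = "selection_result")
}

## Mode of the per-trial best smoothing parameters; ties -> smallest value.
consensus_alpha <- function(best) {
  tab <- table(best)
  min(as.numeric(names(tab)[tab == max(tab)]))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection> %s over %d trials: consensus alpha = %.2f (bests: %s)\n",
    x$index_used, length(x$per_trial_best), x$consensus,
    paste(format(x$per_trial_best), collapse = " ")))
  invisible(x)
}

## Smooth all channels of one trial with a shared operator cache keyed by
## the missingness pattern. Emotion/neutral codes are clipped at 0 and
## renormalized per frame (local fits can overshoot the simplex slightly);
## AU channels are clipped at 0 only.
smooth_trial <- function(trial, alpha, degree, cache = new.env(parent = emptyenv())) {
  fc <- trial$codes
  valid <- valid_frames(fc)
  key <- paste(n_frames(fc), alpha, degree, paste(valid, collapse = "."),
               sep = "|")
  op <- cache[[key]]
  if (is.null(op)) {
    op <- loess_operator(valid, n_frames(fc), alpha, degree)
    cache[[key]] <- op
  }
  Y <- fc$values[valid, , drop = FALSE]
  Sm <- op$L %*% Y
  sim <- colnames(Sm) %in% SIMPLEX_CHANNELS
  Sm[, sim][Sm[, sim] < 0] <- 0
  rs <- rowSums(Sm[, sim, drop = FALSE])
  Sm[, sim] <- Sm[, sim, drop = FALSE] / rs
  au <- !sim
  if (any(au)) Sm[, au][Sm[, au] < 0] <- 0
  trial$codes$values <- Sm
  trial
}

#' Smooth every channel of every trial in a session
#'
#' Applies [loess_fit()] with a single smoothing parameter to each channel
#' of each (non-artifact) trial independently; the missingness masks are
#' preserved, and masked frames carry the smoother's prediction. Because a
#' local polynomial reproduces constants exactly, the per-frame simplex sum
#' is preserved by smoothing (up to clipping of small overshoots outside
#' [0, 1]).
#'
#' @param s A [fes_session()] (normally cleaned first).
#' @param alpha Smoothing parameter (default 0.13, the package's documented
#'   default consensus for 125-frame trials).
#' @param degree Local polynomial degree (default 2).
#' @return The session with smoothed code matrices.
#' @export
smooth_session <- function(s, alpha = 0.13, degree = 2) {
  cache <- new.env(parent = emptyenv())
  s$trials <- lapply(s$trials, function(t)
    smooth_trial(t, alpha, degree, cache))
  s
}
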