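## Fixture builders and independent oracles shared across the test files.

## A frame-code matrix from a named list of channel series; unspecified
## simplex channels share the remaining mass equally.
make_codes <- function(n = 125, channels = list(), frame_rate = 25,
                       missing = integer()) {
  vals <- matrix(NA_real_, n, length(SIMPLEX_CHANNELS),
                 dimnames = list(NULL, SIMPLEX_CHANNELS))
  given <- intersect(names(channels), SIMPLEX_CHANNELS)
  for (ch in given) vals[, ch] <- rep_len(channels[[ch]], n)
  rest <- setdiff(SIMPLEX_CHANNELS, given)
  if (length(rest)) {
    left <- 1 - rowSums(vals[, given, drop = FALSE])
    for (ch in rest) vals[, ch] <- left / length(rest)
  }
  au <- setdiff(names(channels), SIMPLEX_CHANNELS)
  for (ch in au) vals <- cbind(vals, rep_len(channels[[ch]], n))
  if (length(au)) colnames(vals)[ncol(vals) - rev(seq_along(au)) + 1] <- au
  mask <- rep(FALSE, n)
  mask[missing] <- TRUE
  vals[mask, ] <- NA_real_
  frame_codes(vals, missing_mask = mask, frame_rate = frame_rate,
              validate = FALSE)
}

make_trial <- function(n = 125, channels = list(), kind = "anger",
                       task = "production", index = 1, rep_ = 1,
                       pid = "P001", missing = integer(),
                       artifact = FALSE) {
  fes_trial(trial_meta(pid, task, index, kind, rep_),
            make_codes(n, channels, missing = missing),
            artifact_flag = artifact)
}

## Stationary multivariate-normal-ish simplex trial: softmax of iid normal
## utilities. Light tails => no multivariate outliers at the default cutoff
## (asserted where used).
make_stationary_trial <- function(n = 125, seed = 1, sd = 0.15, ...) {
  set.seed(seed)
  u <- matrix(rnorm(n * 8, 0, sd), n, 8)
  u <- sweep(u, 2, c(rep(-1.2, 7), 0.8), "+")
  codes <- exp(u) / rowSums(exp(u))
  colnames(codes) <- SIMPLEX_CHANNELS
  fes_trial(trial_meta("P001", "production", 1, "anger", 1),
            frame_codes(codes, missing_mask = rep(FALSE, n),
                        validate = FALSE))
}

## Independently coded loess oracle: per-point weighted lm over the tricube
## neighbourhood; hat diagonal via stats::hatvalues. Complete series only.
oracle_loess <- function(y, alpha, degree) {
  n <- length(y)
  x <- seq_len(n)
  q <- ceiling(alpha * n)
  fitted <- numeric(n)
  hat <- numeric(n)
  for (i in x) {
    d <- abs(x - i)
    o <- order(d)[seq_len(q)]
    dmax <- max(d[o])
    w <- if (dmax == 0) rep(1, q) else (1 - (d[o] / dmax)^3)^3
    keep <- w > 0
    dat <- data.frame(yy = y[o][keep], dx = (x[o] - i)[keep])
    fml <- if (degree == 1) yy ~ dx else yy ~ dx + I(dx^2)
    fit <- stats::lm(fml, data = dat, weights = w[keep])
    fitted[i] <- stats::predict(fit, newdata = data.frame(dx = 0))
    self <- which(x[o][keep] == i)
    if (length(self)) hat[i] <- unname(stats::hatvalues(fit)[self])
  }
  list(fitted = fitted, trace = sum(hat))
}

## Naive left-to-right summation oracle for the arithmetic mean.
oracle_mean <- function(y) {
  s <- 0
  for (v in y) s <- s + v
  s / length(y)
}

## Shared default-scenario cohort for the cohort-level tests (built once).
.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function(n = 200, seed = 2026) {
  key <- paste0("coh_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(
      synth_config(n_participants = n), seed = seed)
  .fixture_env[[key]]
}

default_cohort_scores <- function(n = 200, seed = 2026) {
  key <- paste0("scores_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    coh <- default_cohort(n, seed)
    cleaned <- suppressWarnings(lapply(coh$sessions, clean_session))
    .fixture_env[[key]] <- apply_treatments(lapply(cleaned, `[[`, "session"))
  }
  .fixture_env[[key]]
}
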