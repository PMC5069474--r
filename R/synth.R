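standardize_series <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) {
    stop("cannot standardize a (near-)constant series", call. = FALSE)
  }
  (x - mean(x)) / s
}

logistic_iterates <- function(n, r, x0, burn_in) {
  total <- burn_in + n
  x <- numeric(total)
  x[1] <- x0
  for (t in seq_len(total - 1L)) {
    x[t + 1L] <- r * x[t] * (1 - x[t])
  }
  x[(burn_in + 1L):total]
}

#' I.i.d. uniform noise
#'
#' Uniform(0, 1) samples; the continuous distribution guarantees no ties
#' almost surely, the regime in which the horizontal visibility graph's mean
#' degree converges to the exact asymptotic value 4.
#'
#' @param n Series length, `>= 2`.
#' @param seed Integer seed; identical seeds give bitwise-identical series.
#' @return Numeric vector of length `n`.
#' @export
gen_iid <- function(n, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  with_seed(seed, runif(n))
}

#' Periodic signal with optional Gaussian noise
#'
#' @param n Series length.
#' @param period Period in samples, `>= 2`.
#' @param amplitude Sinusoid amplitude.
#' @param noise_sd Standard deviation of additive Gaussian noise (0 = clean).
#' @param seed Integer seed (only consumed by the noise).
#' @return Numeric vector of length `n`.
#' @export
gen_periodic <- function(n, period, amplitude = 1, noise_sd = 0, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  period <- check_count(period, "period", min = 2L)
  stopifnot(noise_sd >= 0)
  # tile one exactly-computed period so the signal is bitwise periodic
  cycle <- amplitude * sin(2 * pi * (seq_len(period) - 1L) / period)
  base <- rep_len(cycle, n)
  if (noise_sd > 0) {
    base <- base + with_seed(seed, rnorm(n, 0, noise_sd))
  }
  base
}

#' Logistic-map trajectory
#'
#' Iterates `x[t+1] = r * x[t] * (1 - x[t])`, discarding `burn_in` initial
#' iterates. At `r = 4` the map is fully chaotic on (0, 1); lower `r` gives
#' periodic orbits (e.g. period 2 at `r = 3.2`).
#'
#' @param n Series length after burn-in.
#' @param r Map parameter in `(0, 4]`.
#' @param x0 Initial condition in `(0, 1)`.
#' @param burn_in Non-negative number of discarded iterates.
#' @return Numeric vector of length `n`, bounded in `[0, 1]`.
#' @export
gen_logistic <- function(n, r = 4, x0 = 0.3, burn_in = 100L) {
  n <- check_count(n, "n", min = 2L)
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 4) {
    stop("r must lie in (0, 4], got ", r, call. = FALSE)
  }
  if (!is.numeric(x0) || length(x0) != 1L || x0 <= 0 || x0 >= 1) {
    stop("x0 must lie in (0, 1), got ", x0, call. = FALSE)
  }
  logistic_iterates(n, r, x0, burn_in)
}

#' Two-class surrogate dataset (background vs ictal-like dynamics)
#'
#' Emulates the benchmark contrast between surface EEG from healthy subjects
#' and intracranial ictal EEG: class 0 is filtered Gaussian noise (an AR(1)
#' process with coefficient 0.9, short-memory linear background activity);
#' class 1 is fully chaotic logistic-map dynamics (`r = 4`), a strongly
#' nonlinear surrogate for seizure activity. Every series is standardized to
#' zero mean and unit variance, so the classes differ only in temporal
#' structure, never in amplitude — the discriminative pathway the multiscale
#' visibility features are designed to capture.
#'
#' @param n_per_class Signals per class, `>= 2` (default 100, the benchmark
#'   set size).
#' @param length Samples per signal (default 4096, the order of the
#'   benchmark's 4097-sample segments).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list with `series` (named list of `2 * n_per_class` numeric
#'   vectors) and `labels` (named integer vector, 0 = background, 1 =
#'   chaotic).
#' @export
gen_two_class_dataset <- function(n_per_class = 100L, length = 4096L,
                                  seed = 1L) {
  n_per_class <- check_count(n_per_class, "n_per_class", min = 2L)
  length <- check_count(length, "length", min = 16L)
  series <- vector("list", 2L * n_per_class)
  ids <- c(sprintf("bg_%03d", seq_len(n_per_class)),
           sprintf("chaos_%03d", seq_len(n_per_class)))
  names(series) <- ids
  with_seed(seed, {
    for (i in seq_len(n_per_class)) {
      series[[i]] <- standardize_series(
        as.numeric(arima.sim(model = list(ar = 0.9), n = length))
      )
    }
    for (i in seq_len(n_per_class)) {
      repeat {
        x0 <- runif(1, 0.05, 0.95)
        traj <- logistic_iterates(length, 4, x0, 100L)
        if (sd(traj) > 1e-6) break  # skip measure-zero degenerate orbits
      }
      series[[n_per_class + i]] <- standardize_series(traj)
    }
  })
  labels <- rep(c(0L, 1L), each = n_per_class)
  names(labels) <- ids
  list(series = series, labels = labels)
}
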