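#' Z-score a fluorescence trace
#'
#' Standardizes by the whole-trace mean and sample standard deviation
#' (denominator n-1), the same sigma_F later used to normalize deconvolved
#' event amplitudes.
#'
#' @param trace numeric vector of fluorescence samples (a.u.).
#' @return numeric vector with mean 0 and SD 1.
#' @export
zscore_trace <- function(trace) {
  if (!is.numeric(trace) || length(trace) < 2L) {
    stop_invalid("trace must be numeric with length >= 2")
  }
  if (any(!is.finite(trace))) stop_invalid("trace contains non-finite values")
  s <- sd(trace)
  if (s == 0) stop_degenerate("constant trace: Z-score undefined")
  (trace - mean(trace)) / s
}

#' Estimate the AR(1) coefficient of a calcium trace
#'
#' Uses the lag-2 / lag-1 autocovariance ratio, which is robust to additive
#' white noise (noise inflates lag-0 only), clipped to \[0.5, 0.99\].
#'
#' @param trace numeric vector, length >= 100.
#' @return gamma estimate in \[0.5, 0.99\].
#' @export
estimate_ar1 <- function(trace) {
  if (!is.numeric(trace) || length(trace) < 100L) {
    stop_invalid("trace must have at least 100 samples")
  }
  x <- trace - mean(trace)
  n <- length(x)
  c1 <- sum(x[-1] * x[-n]) / n
  c2 <- sum(x[-(1:2)] * x[seq_len(n - 2)]) / n
  g <- if (c1 <= 0) 0 else c2 / c1
  min(0.99, max(0.5, g))
}

#' Sparse non-negative AR(1) deconvolution of one fluorescence trace
#'
#' Solves `min 0.5*||F - c||^2 + lambda * sum(s)` with
#' `s_t = c_t - gamma*c_{t-1} >= 0` by an online pool-adjacent-violators
#' scheme (single pass, exact). The trace is assumed baseline-free;
#' [deconvolve_traceset()] subtracts a per-trace median baseline first.
#' Inferred jumps `s_t` above a floor of `0.1 * sigma_F` are reported as
#' events; amplitudes are returned in multiples of sigma_F, the whole-trace
#' SD of the fluorescence.
#'
#' When `lambda = NULL` (default) the penalty is calibrated per trace so the
#' residual SD matches a MAD-based noise estimate from the first-differenced
#' trace, `mad(diff(F))/sqrt(2)`.
#'
#' @param trace raw fluorescence samples (a.u.).
#' @param gamma AR(1) coefficient in (0,1); see [estimate_ar1()].
#' @param lambda sparsity penalty (a.u.), or `NULL` to auto-calibrate.
#' @param rate sampling rate, Hz (for event times).
#' @param min_amp_frac event floor as a fraction of sigma_F.
#' @return list of class `DeconvolutionResult`: `gamma`, `lambda`, `sigma_f`,
#'   `baseline`, `denoised` (the non-negative fit, a.u.), and `events`
#'   (data.frame `time` s, `amplitude` in sigma_F units, `amplitude_au`).
#' @export
deconvolve_ar1 <- function(trace, gamma, lambda = NULL, rate = 10,
                           min_amp_frac = 0.1) {
  if (!is.numeric(trace) || length(trace) < 2L) {
    stop_invalid("trace must be numeric with length >= 2")
  }
  check_number(gamma, "gamma")
  if (gamma <= 0 || gamma >= 1) stop_invalid("gamma must be in (0, 1)")
  if (!is.null(lambda)) check_number(lambda, "lambda", 0)
  check_number(rate, "rate", 1e-9)

  sigma_f <- sd(trace)
  y <- trace

  if (is.null(lambda)) {
    target <- mad(diff(trace)) / sqrt(2)
    if (!is.finite(target) || target <= 0) {
      lambda <- 0
    } else {
      # residual SD is nondecreasing in lambda: bracket then bisect
      resid_sd <- function(l) sd(y - oasis_ar1(y, gamma, l))
      hi <- target
      while (resid_sd(hi) < target && hi < 1e6 * target) hi <- hi * 2
      lo <- 0
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        if (resid_sd(mid) < target) lo <- mid else hi <- mid
      }
      lambda <- (lo + hi) / 2
    }
  }

  c_fit <- oasis_ar1(y, gamma, lambda)
  s <- c_fit - gamma * c(0, c_fit[-length(c_fit)])
  s[s < 0] <- 0 # numerical dust
  floor_au <- min_amp_frac * sigma_f
  idx <- which(s > floor_au)
  events <- data.frame(
    time = (idx - 1) / rate,
    amplitude = s[idx] / sigma_f,
    amplitude_au = s[idx]
  )
  structure(list(
    gamma = gamma, lambda = lambda, sigma_f = sigma_f,
    denoised = c_fit, events = events, rate = rate
  ), class = "DeconvolutionResult")
}

#' @export
print.DeconvolutionResult <- function(x, ...) {
  cat(sprintf(
    "<DeconvolutionResult> gamma=%.3f lambda=%.3g sigma_f=%.3g: %d events\n",
    x$gamma, x$lambda, x$sigma_f, nrow(x$events)
  ))
  invisible(x)
}

#' Deconvolve every trace of a TraceSet
#'
#' @param traceset a `TraceSet`.
#' @param gamma AR(1) coefficient; `NULL` estimates it per trace.
#' @param lambda sparsity penalty; `NULL` auto-calibrates per trace.
#' @param min_amp_frac event floor as a fraction of sigma_F.
#' @return data.frame with columns `neuron`, `time` (s), `amplitude`
#'   (sigma_F units).
#' @export
deconvolve_traceset <- function(traceset, gamma = NULL, lambda = NULL,
                                min_amp_frac = 0.1) {
  stopifnot(inherits(traceset, "TraceSet"))
  out <- vector("list", nrow(traceset$traces))
  for (i in seq_len(nrow(traceset$traces))) {
    tr <- traceset$traces[i, ]
    g <- if (is.null(gamma)) estimate_ar1(tr) else gamma
    d <- deconvolve_ar1(tr - median(tr), g, lambda, rate = traceset$rate,
                        min_amp_frac = min_amp_frac)
    ev <- d$events
    out[[i]] <- if (nrow(ev)) {
      data.frame(neuron = traceset$ids[i], time = ev$time, amplitude = ev$amplitude)
    } else {
      NULL
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(neuron = integer(0), time = numeric(0), amplitude = numeric(0))
  }
  rownames(res) <- NULL
  res
}
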