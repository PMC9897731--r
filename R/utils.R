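#' @useDynLib vtsfear, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd mad rnorm runif rpois rexp qf pf qt pt qnorm pnorm
#'   pchisq pwilcox psignrank median quantile cor
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. All generators route their randomness through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("vtsfear_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_degenerate <- function(...) {
  stop(structure(
    class = c("vtsfear_degenerate_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_dependency <- function(...) {
  stop(structure(
    class = c("vtsfear_dependency_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_invalid(sprintf("`%s` must be a number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Half-open interval membership [start, end), vectorised over x.
in_intervals <- function(x, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (i in seq_along(starts)) {
    out <- out | (x >= starts[i] & x < ends[i])
  }
  out
}
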