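# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a typed graftflow error
#'
#' All user-facing failures in the package are classed conditions so that
#' callers (and the command-line wrapper) can distinguish validation, range,
#' format, convergence, tuning, solver and consistency failures.
#'
#' @param class one of "validation_error", "range_error", "format_error",
#'   "convergence_error", "tuning_error", "solver_error", "consistency_error",
#'   "domain_error", "numeric_error".
#' @param msg message string.
#' @param ... fields attached to the condition object.
#' @keywords internal
stop_graftflow <- function(class, msg, ...) {
  cond <- structure(
    class = c(paste0("graftflow_", class), "graftflow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) stop_graftflow(class, msg, ...)
  invisible(TRUE)
}

# C1 smoothstep: 0 at x<=0, 1 at x>=1, cosine blend in between.
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  (1 - cos(pi * x)) / 2
}

# Cosine bump with C1 endpoints: 1 at xi=0, 0 for |xi|>=1.
cos_bump <- function(xi) {
  out <- numeric(length(xi))
  inside <- abs(xi) < 1
  out[inside] <- (1 + cos(pi * xi[inside])) / 2
  out
}

# Trapezoidal integral of periodic samples over one period T.
# y sampled at uniform times t in [0, T) (no duplicated endpoint).
trapz_periodic <- function(y, T) {
  n <- length(y)
  # uniform periodic trapezoid == mean * T
  mean(y) * T
}

# Plain trapezoid on possibly non-uniform grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Relative L2 difference of two equal-length vectors.
rel_l2 <- function(a, b) {
  d <- sqrt(sum((a - b)^2))
  s <- sqrt(sum(b^2))
  if (s == 0) {
    if (d == 0) 0 else Inf
  } else d / s
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
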