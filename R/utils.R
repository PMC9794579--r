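#' @importFrom rlang abort warn .data
#' @importFrom stats median quantile rnorm runif sd setNames approx
NULL

# Trapezoidal integral of y over (possibly non-uniform) grid t.
trapz_ <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# Set the RNG seed for the remainder of the calling function, restoring
# the previous RNG state on exit. NULL means "leave the RNG alone".
local_seed_ <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::local_seed(as.integer(seed), .local_envir = env)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
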