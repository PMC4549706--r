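# Internal helpers shared across modules.

#' @noRd
stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Mersenne-Twister is pinned so that seeds stay portable across R sessions.
#' @noRd
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_input("'seed' must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Derive a stream of child seeds (< 2^31) from one master seed.
#' @noRd
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max, n))
}

# Small-sample corrected Akaike information criterion from a residual sum of
# squares; k counts the mean-model parameters (the error variance adds one).
#' @noRd
aicc_from_rss <- function(rss, n, k) {
  kk <- k + 1
  n * log(rss / n) + 2 * kk + 2 * kk * (kk + 1) / (n - kk - 1)
}

#' @noRd
check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_input("'%s' must be finite and > 0", name)
  }
  invisible(x)
}

#' @noRd
check_nonnegative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_input("'%s' must be finite and >= 0", name)
  }
  invisible(x)
}

# Inverse-variance weighted mean with a DerSimonian-Laird between-level
# variance component, so one deceptively precise level cannot dominate when
# the levels scatter more than their standard errors claim. Falls back to
# the plain mean when no usable standard errors are supplied.
#' @noRd
ivw_mean <- function(x, se = NULL) {
  if (is.null(se) || any(!is.finite(se)) || any(se <= 0) || length(x) < 2) {
    return(mean(x))
  }
  w <- 1 / se^2
  xbar <- sum(w * x) / sum(w)
  q <- sum(w * (x - xbar)^2)
  tau2 <- max(0, (q - (length(x) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w <- 1 / (se^2 + tau2)
  sum(w * x) / sum(w)
}
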