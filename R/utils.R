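# Internal numerical helpers.

#' Moments and draws of the truncated normal distribution
#'
#' Closed-form mean of a Normal(mu, sd) truncated to (lower, upper), and
#' inverse-CDF sampling from it. Degenerate cases (sd -> 0) collapse to the
#' clamped mean.
#'
#' @param mu,sd latent mean and standard deviation.
#' @param lower,upper truncation bounds (may be -Inf / Inf).
#' @return `truncnorm_mean`: the truncated mean; `truncnorm_draw`: one draw
#'   per element, using the uniforms `u`.
#' @keywords internal
truncnorm_mean <- function(mu, sd, lower, upper) {
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  out <- pmin(pmax(mu, lower), upper)
  pos <- sd > 0
  if (any(pos)) {
    mu_ <- mu[pos]; sd_ <- rep_len(sd, length(mu))[pos]
    a <- (lower - mu_) / sd_
    b <- (upper - mu_) / sd_
    z <- stats::pnorm(b) - stats::pnorm(a)
    # z underflows when the interval is far in a tail; fall back to clamp
    ok <- z > 1e-300
    m <- mu_
    m[ok] <- mu_[ok] + sd_[ok] *
      (stats::dnorm(a[ok]) - stats::dnorm(b[ok])) / z[ok]
    m[!ok] <- pmin(pmax(mu_[!ok], lower), upper)
    out[pos] <- pmin(pmax(m, lower), upper)
  }
  out
}

#' @rdname truncnorm_mean
#' @param u uniforms in (0,1), recycled against `mu`.
#' @keywords internal
truncnorm_draw <- function(mu, sd, lower, upper, u) {
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  pa <- stats::pnorm(lower, mu, sd)
  pb <- stats::pnorm(upper, mu, sd)
  q <- stats::qnorm(pa + u * (pb - pa), mu, sd)
  # guard against qnorm returning +-Inf from rounding at the extremes
  pmin(pmax(q, lower), upper)
}

# Deterministic 31-bit seed derivation from a base seed and a key (patient id
# or label). Pure double arithmetic, stays below 2^31.
derive_seed <- function(seed, key) {
  h <- if (is.numeric(key)) {
    abs(key) %% 2147483647
  } else {
    ch <- utf8ToInt(as.character(key))
    s <- 0
    for (c in ch) s <- (s * 131 + c) %% 2147483647
    s
  }
  x <- (as.numeric(seed) * 48271) %% 2147483647
  as.integer((x + h * 69621 + 1) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
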