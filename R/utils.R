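# Small numeric helpers shared across modules.

# Excess kurtosis (m4/m2^2 - 3), NA-dropping.
excess_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}

# Truncated-normal draws by inverse-CDF; vectorized, bounds are scalars.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Log-density of rows of Y under N(mu, Sigma), small fixed dimension.
dmvnorm_log <- function(Y, mu, Sigma) {
  Y <- rbind(Y)
  U <- chol(Sigma)
  Q <- backsolve(U, t(Y) - mu, transpose = TRUE)
  -0.5 * colSums(Q^2) - sum(log(diag(U))) - 0.5 * ncol(Y) * log(2 * pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
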